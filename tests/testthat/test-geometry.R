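# Coordinate-model geometry: diagonal distances, superposition, rotation
# angles, segment displacements, file parsing.

test_that("an exact C4 tetramer has equal diagonals", {
  m <- synthetic_tetramer()
  dd <- diagonal_distances(m, 30)
  expect_equal(dd$diff, 0, tolerance = 1e-10)
  expect_equal(dd$d1, dd$d2, tolerance = 1e-10)
})

test_that("translating one subunit along its diagonal shifts one diagonal", {
  m <- synthetic_tetramer(diag_offset_A = 2)
  dd <- diagonal_distances(m, 30)
  expect_equal(dd$diff, 2, tolerance = 0.01)
})

test_that("diagonal pairing agrees with brute force over residues and models", {
  for (shift in c(0, 3, 5)) {
    m <- synthetic_tetramer(c2_shift_A = shift, diag_offset_A = shift / 2)
    for (res in c(10, 30, 55)) {
      dd <- diagonal_distances(m, res)
      a <- as.data.frame(m)
      sel <- a[a$resno == res & a$atom == "CA", ]
      xyz <- as.matrix(sel[, c("x", "y", "z")])
      d6 <- as.matrix(stats::dist(xyz))
      # the two diagonals are the two largest of the six pairwise distances
      vals <- sort(d6[upper.tri(d6)], decreasing = TRUE)[1:2]
      expect_equal(sort(c(dd$d1, dd$d2)), sort(vals), tolerance = 1e-9)
    }
  }
})

test_that("diagonal_distances reports missing chains", {
  m <- as.data.frame(synthetic_tetramer())
  m <- m[!(m$chain == "B" & m$resno == 30), ]
  expect_error(diagonal_distances(as_channel_model(m), 30), "chain.*B")
})

test_that("superposition of a model on itself is the identity", {
  m <- synthetic_tetramer()
  sp <- superpose(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
})

test_that("a known 25-degree rotation is recovered exactly", {
  m <- synthetic_tetramer()
  a <- 25 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  mb <- as.data.frame(m)
  xyz <- as.matrix(mb[, c("x", "y", "z")]) %*% t(Rz)
  mb$x <- xyz[, 1] + 4; mb$y <- xyz[, 2] - 2; mb$z <- xyz[, 3] + 7
  sp <- superpose(m, as_channel_model(mb))
  ang <- acos((sum(diag(sp$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 25, tolerance = 0.01)
  expect_lt(sp$rmsd, 1e-8)
})

test_that("noisy-copy RMSD matches the sqrt(3) sigma expectation", {
  m <- synthetic_tetramer(n_res = 40)
  rmsds <- vapply(1:40, function(s) {
    set.seed(s)
    mb <- as.data.frame(m)
    mb$x <- mb$x + stats::rnorm(nrow(mb), sd = 0.5)
    mb$y <- mb$y + stats::rnorm(nrow(mb), sd = 0.5)
    mb$z <- mb$z + stats::rnorm(nrow(mb), sd = 0.5)
    superpose(m, as_channel_model(mb))$rmsd
  }, numeric(1))
  expect_lt(abs(mean(rmsds) - sqrt(3) * 0.5) / (sqrt(3) * 0.5), 0.1)
})

test_that("superpose agrees with the bio3d reference fit", {
  m <- synthetic_tetramer()
  set.seed(3)
  mb <- as.data.frame(m)
  a <- 0.3
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  xyz <- as.matrix(mb[, c("x", "y", "z")]) %*% t(Ry)
  mb[, c("x", "y", "z")] <- xyz + matrix(stats::rnorm(length(xyz), sd = 0.3),
                                         ncol = 3)
  sp <- superpose(m, as_channel_model(mb))
  A <- as.matrix(as.data.frame(m)[, c("x", "y", "z")])
  B <- xyz_b <- as.matrix(mb[, c("x", "y", "z")])
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(A)),
                                            mobile = as.numeric(t(B))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fitted, ncol = 3,
                                          byrow = TRUE) - A)^2)))
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("superpose needs at least 3 matched atoms", {
  m <- synthetic_tetramer()
  expect_error(superpose(m, m, sel_a = "A:1-2:CA"), "3 matched")
})

test_that("relative rotation recovers a constructed 12-degree domain turn", {
  m <- synthetic_tetramer()
  mb <- as.data.frame(m)
  a <- 12 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  idx <- mb$resno <= 30
  mb[idx, c("x", "y", "z")] <-
    as.matrix(mb[idx, c("x", "y", "z")]) %*% t(Rz)
  mc <- as_channel_model(mb)
  ang <- relative_rotation(m, mc, align_sel = "A,B,C,D:40-60:CA",
                           measure_sel = "A,B,C,D:1-30:CA", axis = "z")
  expect_equal(ang, 12, tolerance = 0.1)
  # antisymmetry
  ang_rev <- relative_rotation(mc, m, align_sel = "A,B,C,D:40-60:CA",
                               measure_sel = "A,B,C,D:1-30:CA", axis = "z")
  expect_equal(ang_rev, -ang, tolerance = 0.1)
  # identical models -> 0
  expect_equal(relative_rotation(m, m, "A,B,C,D:40-60:CA",
                                 "A,B,C,D:1-30:CA"), 0, tolerance = 1e-10)
})

test_that("segment displacement measures a constructed 5 A shift", {
  m <- synthetic_tetramer()
  mb <- as.data.frame(m)
  idx <- mb$chain == "A" & mb$resno >= 10 & mb$resno <= 20
  mb$z[idx] <- mb$z[idx] + 5
  mc <- as_channel_model(mb)
  d <- segment_displacement(m, mc, align_sel = "B,C,D::CA",
                            segment_sel = "A:10-20:CA")
  expect_equal(d, 5, tolerance = 1e-6)
  expect_equal(segment_displacement(m, m, "B,C,D::CA", "A:10-20:CA"), 0,
               tolerance = 1e-10)
  expect_error(segment_displacement(m, mc, "B,C,D::CA", "A:99:CA"),
               "empty")
})

test_that("measurements are invariant to joint rigid motion", {
  m <- synthetic_tetramer(c2_shift_A = 4)
  rig <- function(mod) {
    a <- 0.7; b <- 0.2
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) %*%
      matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
    df <- as.data.frame(mod)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df[, c("x", "y", "z")] <- sweep(xyz, 2, c(11, -4, 30), `+`)
    as_channel_model(df)
  }
  dd1 <- diagonal_distances(m, 30)
  dd2 <- diagonal_distances(rig(m), 30)
  expect_equal(dd1$diff, dd2$diff, tolerance = 1e-9)
  mb <- synthetic_tetramer(c2_shift_A = 0)
  d1 <- segment_displacement(m, mb, "B,D::CA", "A::CA")
  d2 <- segment_displacement(rig(m), rig(mb), "B,D::CA", "A::CA")
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("PDB text round-trips through read_channel_model", {
  m <- synthetic_tetramer(n_res = 10)
  df <- as.data.frame(m)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(df)), df$chain, df$resno, df$x, df$y, df$z)
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  m2 <- read_channel_model(path)
  expect_equal(nrow(as.data.frame(m2)), nrow(df))
  expect_equal(m2$x, df$x, tolerance = 1e-3)
  expect_equal(sort(unique(m2$chain)), c("A", "B", "C", "D"))
  dd <- diagonal_distances(m2, 5)
  dd0 <- diagonal_distances(m, 5)
  expect_equal(dd$diff, dd0$diff, tolerance = 1e-3)
  expect_error(read_channel_model(tempfile()), "no such file")
})
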