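# RSC orientation priors and constrained projection matching.

make_prior_fixture <- function(r_px, R_A = 100) {
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = 0, y_px = 0, radius_A = R_A, amplitude = 1,
    background = 0, residual_rms = 0, converged = TRUE, score = 1))
  picks <- data.frame(id = seq_along(r_px), x_px = r_px, y_px = 0,
                      score = 1, nearest_liposome_id = 1L)
  orientation_prior(picks, fits, pixel_size = 1)
}

test_that("tilt prior follows arcsin(r/R) with near/far ambiguity", {
  pr <- make_prior_fixture(c(0, 50, 100), R_A = 100)
  expect_equal(pr$tilt_deg, c(0, 30, 90), tolerance = 1e-10)
  expect_equal(pr$tilt_alt_deg, c(180, 150, 90), tolerance = 1e-10)
  # r slightly beyond R clips to a side view rather than erroring
  pr2 <- make_prior_fixture(104, R_A = 100)
  expect_equal(pr2$tilt_deg, 90)
})

test_that("in-plane prior is the bearing from liposome centre to pick", {
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = 100, y_px = 100, radius_A = 80, amplitude = 1,
    background = 0, residual_rms = 0, converged = TRUE, score = 1))
  picks <- data.frame(id = 1:4,
                      x_px = c(150, 100, 50, 100),
                      y_px = c(100, 150, 100, 50),
                      score = 1, nearest_liposome_id = 1L)
  pr <- orientation_prior(picks, fits, pixel_size = 1)
  expect_equal(pr$psi_deg, c(0, 90, 180, 270), tolerance = 1e-10)
})

test_that("orientation_prior validates inputs", {
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = 0, y_px = 0, radius_A = -5, amplitude = 1,
    background = 0, residual_rms = 0, converged = TRUE, score = 1))
  picks <- data.frame(id = 1, x_px = 10, y_px = 0, score = 1,
                      nearest_liposome_id = 1L)
  expect_error(orientation_prior(picks, fits, 1), "radius")
  picks$nearest_liposome_id <- 99L
  expect_error(orientation_prior(picks, fits, 1), "unknown")
})

test_that("degenerate priors (zero width) return the true angles exactly", {
  ph <- make_channel_phantom(48, 5.6, c2_shift = 5)
  ctf48 <- fix_ctf(5.6)
  truth <- data.frame(rot = c(35, 230), tilt = c(40, 120),
                      psi = c(10, 300))
  st <- fix_projection_stack(ph, truth$rot, truth$tilt, truth$psi, ctf48)
  st$meta$tilt_deg <- ifelse(truth$tilt <= 90, truth$tilt,
                             180 - truth$tilt)
  st$meta$psi_deg <- truth$psi
  st$meta$tilt_width_deg <- 0
  st$meta$psi_width_deg <- 0
  ang <- assign_orientations(st, ph, ctf48, azimuth_step = 5,
                             max_shift_px = 0)
  expect_equal(ang$tilt, truth$tilt)
  expect_equal(ang$psi, truth$psi)
  # azimuth on the 5-degree grid nearest the truth (mod the phantom's C2)
  rerr <- abs(ang$rot - truth$rot) %% 180
  rerr <- pmin(rerr, 180 - rerr)
  expect_lt(max(rerr), 2.5)
})

test_that("noise-free constrained matching recovers angles within half a step", {
  ph <- make_channel_phantom(64, 4.2, c2_shift = 5)
  set.seed(5)
  m <- 10
  truth <- data.frame(rot = runif(m, 0, 360),
                      tilt = acos(runif(m, -1, 1)) * 180 / pi,
                      psi = runif(m, 0, 360))
  ctf <- fix_ctf(4.2)
  st <- fix_projection_stack(ph, truth$rot, truth$tilt, truth$psi, ctf)
  st$meta$tilt_deg <- ifelse(truth$tilt <= 90, truth$tilt,
                             180 - truth$tilt)
  st$meta$psi_deg <- truth$psi
  st$meta$tilt_width_deg <- 10
  st$meta$psi_width_deg <- 10
  ang <- assign_orientations(st, ph, ctf)
  # median errors below half the azimuth step; the near/far branches are
  # genuinely near-degenerate for views close to the equator, so a small
  # minority of side-view flips is inherent to the geometry
  expect_lt(stats::median(abs(ang$tilt - truth$tilt)), 2.5)
  expect_lt(stats::median(pmin(abs(ang$psi - truth$psi) %% 360,
                               360 - abs(ang$psi - truth$psi) %% 360)), 2.5)
  rerr <- abs(ang$rot - truth$rot) %% 180
  rerr <- pmin(rerr, 180 - rerr)
  expect_lt(stats::median(rerr), 2.5)
})

test_that("matched priors score higher than scrambled priors", {
  ph <- make_channel_phantom(64, 4.2, c2_shift = 5)
  set.seed(6)
  m <- 16
  truth <- data.frame(rot = runif(m, 0, 360),
                      tilt = runif(m, 20, 160),
                      psi = runif(m, 0, 360))
  ctf <- fix_ctf(4.2)
  st <- fix_projection_stack(ph, truth$rot, truth$tilt, truth$psi, ctf)
  # degrade with noise so the prior matters
  set.seed(7)
  st$images <- st$images + array(stats::rnorm(length(st$images),
                                              sd = 2 * stats::sd(st$images)),
                                 dim(st$images))
  base <- st$meta
  base$tilt_width_deg <- 8; base$psi_width_deg <- 8
  good <- base
  good$tilt_deg <- ifelse(truth$tilt <= 90, truth$tilt, 180 - truth$tilt)
  good$psi_deg <- truth$psi
  bad <- good
  bad$tilt_deg <- (good$tilt_deg + 45) %% 90
  bad$psi_deg <- (good$psi_deg + 137) %% 360
  st$meta <- good
  sg <- assign_orientations(st, ph, ctf)$score
  st$meta <- bad
  sb <- assign_orientations(st, ph, ctf)$score
  expect_gt(mean(sg - sb), 0)
  expect_lt(stats::wilcox.test(sg, sb, paired = TRUE,
                               alternative = "greater")$p.value, 0.05)
})
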