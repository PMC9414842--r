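# Direct Fourier inversion, symmetrization, FSC.

test_that("backprojection of known projections recovers the phantom", {
  ph <- make_channel_phantom(64, 4.2, c2_shift = 5)
  set.seed(9)
  m <- 120
  ang <- data.frame(rot = runif(m, 0, 360),
                    tilt = acos(runif(m, -1, 1)) * 180 / pi,
                    psi = runif(m, 0, 360))
  st <- fix_projection_stack(ph, ang$rot, ang$tilt, ang$psi)
  rec <- backproject(st, ang, ctf = NULL, symmetry = 1)
  cm <- compare_maps(rec, ph, mask_radius_A = 90)
  expect_gte(cm$correlation, 0.99)
})

test_that("symmetrizing after C1 equals reconstructing with C4 directly", {
  ph <- make_channel_phantom(48, 5.6, c2_shift = 0)   # exactly C4
  set.seed(3)
  m <- 40
  ang <- data.frame(rot = runif(m, 0, 360), tilt = runif(m, 0, 180),
                    psi = runif(m, 0, 360))
  st <- fix_projection_stack(ph, ang$rot, ang$tilt, ang$psi)
  r1 <- backproject(st, ang, symmetry = 1)
  r4 <- backproject(st, ang, symmetry = 4)
  r1s <- symmetrize_map(r1, 4)
  expect_equal(r1s$data, r4$data, tolerance = 1e-10)
})

test_that("duplicating every particle leaves the map unchanged", {
  ph <- make_channel_phantom(48, 5.6, c2_shift = 5)
  set.seed(4)
  m <- 16
  ang <- data.frame(rot = runif(m, 0, 360), tilt = runif(m, 0, 180),
                    psi = runif(m, 0, 360))
  st <- fix_projection_stack(ph, ang$rot, ang$tilt, ang$psi)
  st2 <- particle_stack(st$images[, , rep(1:m, 2)], st$pixel_size,
                        st$meta[rep(1:m, 2), ], st$box_A, st$mask_A)
  r1 <- backproject(st, ang, symmetry = 1, min_particles = 1)
  r2 <- backproject(st2, ang[rep(1:m, 2), ], symmetry = 1,
                    min_particles = 1)
  expect_equal(r1$data, r2$data, tolerance = 1e-8)
})

test_that("backproject validates inputs", {
  ph <- make_channel_phantom(48, 5.6)
  st <- fix_projection_stack(ph, 0, 0, 0)
  expect_error(backproject(st, data.frame(rot = 0, tilt = 0, psi = 0),
                           symmetry = 3), "symmetry")
  expect_warning(backproject(st, data.frame(rot = 0, tilt = 0, psi = 0),
                             symmetry = 1, min_particles = 10), "noisy")
})

test_that("gold-standard halves share no particle and give a valid FSC", {
  ph <- make_channel_phantom(48, 5.6, c2_shift = 5)
  set.seed(8)
  m <- 30
  ang <- data.frame(rot = runif(m, 0, 360), tilt = runif(m, 0, 180),
                    psi = runif(m, 0, 360))
  st <- fix_projection_stack(ph, ang$rot, ang$tilt, ang$psi)
  hv <- reconstruct_halves(st, ang, symmetry = 1, seed = 2)
  expect_s3_class(hv$fsc, "fsc_curve")
  expect_true(all(hv$fsc$fsc <= 1 + 1e-9))
  # determinism of the split
  hv2 <- reconstruct_halves(st, ang, symmetry = 1, seed = 2)
  expect_identical(hv$half1$data, hv2$half1$data)
})

test_that("FSC of a map with itself is 1 in every shell, resolution at Nyquist", {
  set.seed(11)
  mp <- density_map(array(stats::rnorm(32^3), c(32, 32, 32)), 2.1)
  f <- compute_fsc(mp, mp)
  expect_true(all(abs(f$fsc - 1) < 1e-9))
  expect_equal(attr(f, "resolution_A"), 2 * 2.1)
})

test_that("independent white-noise maps have near-zero per-shell FSC", {
  set.seed(12)
  a <- density_map(array(stats::rnorm(48^3), c(48, 48, 48)), 2.1)
  b <- density_map(array(stats::rnorm(48^3), c(48, 48, 48)), 2.1)
  f <- compute_fsc(a, b)
  expect_true(all(abs(f$fsc[-1]) <= 3 / sqrt(f$n_voxels[-1])))
})

test_that("a common band-limited signal crosses 0.143 within one shell of the limit", {
  set.seed(13)
  n <- 64; px <- 2.1
  sig <- array(stats::rnorm(n^3), c(n, n, n))
  Fc <- liporsc:::cfft(sig)
  u <- liporsc:::centered_offsets(n)
  kr <- sqrt(outer(outer(u^2, u^2, `+`), u^2, `+`)) / (n * px)
  Fc[kr > 1 / 10] <- 0
  sig <- Re(liporsc:::icfft(Fc))
  noise_sd <- 0.2 * stats::sd(sig)
  h1 <- density_map(sig + array(stats::rnorm(n^3, sd = noise_sd), dim(sig)), px)
  h2 <- density_map(sig + array(stats::rnorm(n^3, sd = noise_sd), dim(sig)), px)
  f <- compute_fsc(h1, h2)
  # within one shell of the built-in limit, compared in frequency
  expect_lt(abs(1 / attr(f, "resolution_A") - 1 / 10),
            1 / (n * px) + 1e-12)
  expect_error(compute_fsc(h1, density_map(array(0, c(32, 32, 32)), px)),
               "share")
})
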