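# Liposome detection, model fitting, membrane subtraction.

test_that("blank noise micrographs yield (almost) no detections", {
  ctf <- fix_ctf()
  fp <- 0
  n_trials <- 30
  for (s in seq_len(n_trials)) {
    mg <- simulate_micrograph(c(320, 320), fix_px, numeric(0),
                              particle_map = fix_phantom(), ctf = ctf,
                              dose = 60, seed = 1000 + s)
    det <- detect_liposomes(mg, ctf, radius_range = c(75, 200))
    fp <- fp + nrow(det)
  }
  expect_lt(fp / n_trials, 0.1 + 1e-9)
})

test_that("a synthetic 20-nm liposome is detected accurately at default SNR", {
  ctf <- fix_ctf()
  mg <- fix_micro_single(seed = 21, dose = 60)
  det <- detect_liposomes(mg, ctf)
  expect_equal(nrow(det), 1)
  tr <- mg$liposomes
  expect_lt(sqrt((det$x_px - tr$x_px)^2 + (det$y_px - tr$y_px)^2), 1)
  expect_lt(abs(det$radius_A - tr$radius_A) / tr$radius_A, 0.05)
})

test_that("two non-overlapping liposomes give exactly two detections", {
  ctf <- fix_ctf()
  mg <- simulate_micrograph(c(640, 640), fix_px, c(20, 28),
                            particle_map = fix_phantom(), ctf = ctf,
                            dose = 60, seed = 31)
  det <- detect_liposomes(mg, ctf)
  expect_equal(nrow(det), 2)
  d <- sqrt(outer(det$x_px, mg$liposomes$x_px, "-")^2 +
            outer(det$y_px, mg$liposomes$y_px, "-")^2)
  expect_true(all(apply(d, 2, min) < 3))
})

test_that("noise-free fit recovers centre to 0.2 px and radius to 0.5%", {
  ctf <- fix_ctf()
  mg <- fix_micro_single(seed = 3, dose = NULL)
  tr <- mg$liposomes
  init <- data.frame(id = 1L, x_px = tr$x_px + 3, y_px = tr$y_px - 2,
                     radius_A = tr$radius_A * 1.08, score = NA)
  f <- fit_liposome(mg, init, ctf)
  expect_true(f$converged)
  expect_lt(sqrt((f$x_px - tr$x_px)^2 + (f$y_px - tr$y_px)^2), 0.2)
  expect_lt(abs(f$radius_A - tr$radius_A) / tr$radius_A, 0.005)
})

test_that("objective at truth beats random perturbations (noise-free)", {
  ctf <- fix_ctf()
  mg <- fix_micro_single(seed = 3, dose = NULL)
  tr <- mg$liposomes
  f0 <- fit_liposome(mg, data.frame(id = 1, x_px = tr$x_px,
                                    y_px = tr$y_px,
                                    radius_A = tr$radius_A, score = NA),
                     ctf, maxit = 2)
  set.seed(44)
  worse <- 0
  for (k in 1:25) {
    init <- data.frame(id = 1, x_px = tr$x_px + runif(1, -4, 4),
                       y_px = tr$y_px + runif(1, -4, 4),
                       radius_A = tr$radius_A * runif(1, 0.92, 1.08),
                       score = NA)
    fk <- fit_liposome(mg, init, ctf, maxit = 2)
    if (fk$residual_rms >= f0$residual_rms - 1e-12) worse <- worse + 1
  }
  expect_equal(worse, 25)
})

test_that("amplitude on a blank region is statistically null", {
  ctf <- fix_ctf()
  amps <- ts <- numeric(24)
  for (s in seq_len(24)) {
    mg <- simulate_micrograph(c(384, 384), fix_px, numeric(0),
                              particle_map = fix_phantom(), ctf = ctf,
                              dose = 60, seed = 3000 + s)
    init <- data.frame(id = 1, x_px = 191, y_px = 191, radius_A = 100,
                       score = NA)
    f <- fit_liposome(mg, init, ctf, maxit = 40)
    amps[s] <- f$amplitude
    ts[s] <- f$amp_t
  }
  z <- mean(amps) / (stats::sd(amps) / sqrt(length(amps)))
  expect_lt(abs(z), 3)
  # and none reaches the significance kept by fit_liposomes
  expect_lt(max(abs(ts)), 5)
})

test_that("fitting is equivariant to whole-pixel translation", {
  ctf <- fix_ctf()
  mg <- fix_micro_single(seed = 6, dose = 60, grid = 448)
  tr <- mg$liposomes
  shift <- 7L
  mg2 <- mg
  mg2$data <- rbind(mg$data[-(1:shift), ], mg$data[1:shift, ])
  init <- data.frame(id = 1, x_px = tr$x_px, y_px = tr$y_px,
                     radius_A = tr$radius_A, score = NA)
  init2 <- init; init2$x_px <- init$x_px - shift
  f1 <- fit_liposome(mg, init, ctf)
  f2 <- fit_liposome(mg2, init2, ctf)
  expect_lt(abs((f1$x_px - shift) - f2$x_px), 0.05)
  expect_lt(abs(f1$y_px - f2$y_px), 0.05)
  expect_lt(abs(f1$radius_A - f2$radius_A), 0.05)
})

test_that("subtraction of exact fits removes the membrane (noise-free)", {
  ctf <- fix_ctf()
  mg <- fix_micro_single(seed = 8, dose = NULL)
  tr <- mg$liposomes
  # membrane-only scene (no particles, no noise)
  mem <- mg
  mem$data <- apply_ctf(render_scene(tr, NULL, fix_phantom(),
                                     dim(mg$data), fix_px)$image, ctf)
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = tr$x_px, y_px = tr$y_px, radius_A = tr$radius_A,
    amplitude = tr$amp, background = 0, residual_rms = 0,
    converged = TRUE, score = 1))
  sub <- subtract_liposomes(mem, fits, ctf)
  expect_lt(sqrt(mean(sub$data^2)) / sqrt(mean(mem$data^2)), 0.01)
})

test_that("subtraction leaves a particle's density intact (noise-free)", {
  ctf <- fix_ctf()
  ph <- fix_phantom()
  mg <- simulate_micrograph(c(512, 512), fix_px, 22, particle_map = ph,
                            ctf = ctf, dose = NULL, seed = 13)
  # ensure at least one particle exists in this seed
  expect_gt(nrow(mg$particles), 0)
  tr <- mg$liposomes
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = tr$x_px, y_px = tr$y_px, radius_A = tr$radius_A,
    amplitude = tr$amp, background = 0, residual_rms = 0,
    converged = TRUE, score = 1))
  sub <- subtract_liposomes(mg, fits, ctf)
  expected <- apply_ctf(
    render_scene(NULL, mg$particles, ph, c(512, 512), fix_px)$image, ctf)
  expect_lt(sqrt(mean((sub$data - expected)^2)) /
            sqrt(mean(expected^2)), 0.02)
})

test_that("fitted subtraction removes the azimuthal membrane peak at default SNR", {
  ctf <- fix_ctf()
  mg0 <- fix_micro_single(seed = 17, dose = NULL)
  # particle-free vesicle: membrane scene plus shot noise
  mg <- mg0
  mg$data <- add_noise(
    apply_ctf(render_scene(mg0$liposomes, NULL, fix_phantom(),
                           dim(mg0$data), fix_px)$image, ctf),
    60, fix_px, seed = 18)
  fits <- fit_liposomes(mg, ctf)
  expect_equal(nrow(fits), 1)
  sub <- subtract_liposomes(mg, fits, ctf)
  # azimuthally averaged |profile| around the fitted circle
  # azimuthally averaged radial profile: no membrane peak above 3 sigma
  # of the background-bin scatter
  rg <- liporsc:::radius_grid(nrow(sub$data), ncol(sub$data),
                              fits$x_px, fits$y_px) * fix_px
  bin <- floor(rg / 4)
  prof <- tapply(sub$data, bin, mean)
  nb <- tapply(sub$data, bin, length)
  rad <- as.numeric(names(prof)) * 4
  near <- rad > fits$radius_A - 40 & rad < fits$radius_A + 40
  bg <- rad > fits$radius_A + 100 & rad < fits$radius_A + 250
  expect_gt(sum(near), 5)
  # z-score of each near-membrane bin against its own counting noise
  se <- stats::sd(sub$data[rg > fits$radius_A + 100]) / sqrt(nb)
  z <- (prof - mean(prof[bg])) / se
  expect_lt(max(abs(z[near])), 3)
  # before subtraction the membrane peak is conspicuous by the same test
  prof0 <- tapply(mg$data, bin, mean)
  z0 <- (prof0 - mean(prof0[bg])) / se
  expect_gt(max(abs(z0[near])), 10)
})

test_that("subtraction never increases annulus power for converged fits", {
  ctf <- fix_ctf()
  for (s in c(23, 29)) {
    mg <- fix_micro_single(seed = s, dose = 60)
    fits <- fit_liposomes(mg, ctf)
    sub <- subtract_liposomes(mg, fits, ctf)
    for (i in seq_len(nrow(fits))) {
      rg <- liporsc:::radius_grid(nrow(mg$data), ncol(mg$data),
                                  fits$x_px[i], fits$y_px[i]) * fix_px
      w <- abs(rg - fits$radius_A[i]) <= 60
      expect_lt(sum(sub$data[w]^2), sum(mg$data[w]^2))
    }
  }
})
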