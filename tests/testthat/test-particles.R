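# Particle picking, membrane-distance screening, box extraction.

test_that("planting a template noise-free gives a unit correlation peak at the spot", {
  set.seed(10)
  tm <- matrix(0, 48, 48)
  rg <- liporsc:::radius_grid(48, 48, 24, 24)
  tm <- exp(-rg^2 / 60) - 0.3 * exp(-rg^2 / 200)
  img <- matrix(0, 256, 256)
  mic <- micrograph(img, fix_px)
  mic$data[101:148, 141:188] <- tm   # centre at 0-based (124, 164)
  picks <- pick_particles(mic, tm, threshold = 0.5, bin = 1)
  expect_equal(nrow(picks), 1)
  expect_equal(picks$x_px, 124)
  expect_equal(picks$y_px, 164)
  expect_equal(picks$score, 1, tolerance = 1e-9)
})

test_that("blank noise yields under one pick per micrograph at the default threshold", {
  ctf <- fix_ctf()
  tmpl <- liporsc:::make_pick_templates(fix_phantom(), ctf)
  total <- 0
  n_trials <- 25
  for (s in seq_len(n_trials)) {
    mg <- simulate_micrograph(c(320, 320), fix_px, numeric(0),
                              particle_map = fix_phantom(), ctf = ctf,
                              dose = 60, seed = 5000 + s)
    total <- total + nrow(pick_particles(mg, tmpl))
  }
  expect_lt(total / n_trials, 1)
})

test_that("planted particles are recovered after subtraction at default SNR", {
  ctf <- fix_ctf()
  ph <- fix_phantom()
  tmpl <- liporsc:::make_pick_templates(ph, ctf)
  tot_truth <- 0; tot_match <- 0; tot_fp <- 0; tot_lipo <- 0
  for (s in c(11, 42, 77)) {
    mg <- simulate_micrograph(c(768, 768), fix_px, c(20, 20, 25, 18, 20),
                              particle_map = ph, ctf = ctf, dose = 60,
                              seed = s)
    fits <- fit_liposomes(mg, ctf)
    sub <- suppressWarnings(subtract_liposomes(mg, fits, ctf))
    picks <- pick_particles(sub, tmpl)
    kept <- screen_particles(picks, fits, 80, fix_px)
    m <- match_picks(kept, mg$particles, tol_px = 64)
    tot_truth <- tot_truth + nrow(mg$particles)
    tot_match <- tot_match + m$matched
    tot_fp <- tot_fp + m$fp
    tot_lipo <- tot_lipo + nrow(mg$liposomes)
  }
  expect_gte(tot_match / tot_truth, 0.9)
  expect_lte(tot_fp / tot_lipo, 0.2)
})

test_that("membrane-distance screen matches brute force on 1000 random picks", {
  set.seed(77)
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = 0, y_px = 0, radius_A = 100, amplitude = 1,
    background = 0, residual_rms = 0, converged = TRUE, score = 1))
  px <- 1  # work in Angstrom directly
  picks <- data.frame(id = 1:1000,
                      x_px = runif(1000, -250, 250),
                      y_px = runif(1000, -250, 250), score = 1)
  kept <- screen_particles(picks, fits, cutoff_A = 80, pixel_size = px)
  brute <- abs(sqrt(picks$x_px^2 + picks$y_px^2) - 100) <= 80
  expect_equal(sort(kept$id), which(brute))
  expect_equal(kept$membrane_distance_A,
               abs(sqrt(kept$x_px^2 + kept$y_px^2) - 100))
})

test_that("screen boundary: on-circle kept, 81 A excluded at 80 A cutoff", {
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1L, x_px = 0, y_px = 0, radius_A = 100, amplitude = 1,
    background = 0, residual_rms = 0, converged = TRUE, score = 1))
  picks <- data.frame(id = 1:2, x_px = c(100, 181), y_px = 0, score = 1)
  kept <- screen_particles(picks, fits, 80, pixel_size = 1)
  expect_equal(kept$id, 1L)
  expect_equal(kept$membrane_distance_A, 0)
})

test_that("screen is idempotent and order-independent", {
  set.seed(5)
  fits <- liporsc:::new_liposome_fits(data.frame(
    id = 1:3, x_px = c(0, 300, 600), y_px = c(0, 100, -50),
    radius_A = c(90, 120, 200), amplitude = 1, background = 0,
    residual_rms = 0, converged = TRUE, score = 1))
  picks <- data.frame(id = 1:200, x_px = runif(200, -100, 800),
                      y_px = runif(200, -300, 400), score = 1)
  k1 <- screen_particles(picks, fits, 80, 1)
  k2 <- screen_particles(k1, fits, 80, 1)          # idempotent
  expect_equal(k1$id, k2$id)
  perm <- sample(nrow(picks))
  k3 <- screen_particles(picks[perm, ], fits[c(3, 1, 2), ], 80, 1)
  expect_setequal(k1$id, k3$id)
  # cutoff limits
  expect_equal(nrow(screen_particles(picks, fits, Inf, 1)), nrow(picks))
  k0 <- screen_particles(picks, fits, 0, 1)
  expect_true(all(k0$membrane_distance_A == 0))
  expect_error(screen_particles(picks, fits, -1, 1), "cutoff")
  expect_warning(out <- screen_particles(picks, fits[0, ], 80, 1),
                 "no liposome")
  expect_equal(nrow(out), 0)
})

test_that("extraction crops exactly, drops edge picks, and normalizes", {
  set.seed(31)
  mic <- micrograph(matrix(stats::rnorm(512 * 512), 512, 512), fix_px)
  np <- 2 * round(27 * 10 / fix_px / 2)
  picks <- data.frame(id = 1:3,
                      x_px = c(256, np / 2 - 2, 400),
                      y_px = c(256, 256, 300), score = 1)
  st <- extract_boxes(mic, picks, soft_mask = FALSE, normalize = FALSE)
  expect_equal(attr(st, "n_dropped"), 1)
  expect_equal(dim(st$images)[3], 2)
  # crop equals a direct slice (centre pick)
  half <- np / 2
  direct <- mic$data[(256 + 1 - half):(256 + half),
                     (256 + 1 - half):(256 + half)]
  expect_identical(st$images[, , 1], direct)
  # re-insertion reproduces the original pixels
  canvas <- mic$data
  canvas[(256 + 1 - half):(256 + half),
         (256 + 1 - half):(256 + half)] <- st$images[, , 1]
  expect_identical(canvas, mic$data)
  # normalized masked stack: per-image mean ~ 0
  stn <- extract_boxes(mic, picks, soft_mask = TRUE, normalize = TRUE)
  for (i in 1:2)
    expect_lt(abs(mean(stn$images[, , i])), 1e-6)
})

test_that("extraction validates the box size", {
  mic <- micrograph(matrix(0, 64, 64), fix_px)
  picks <- data.frame(id = 1, x_px = 32, y_px = 32, score = 1)
  expect_error(extract_boxes(mic, picks, box_nm = 27), "larger")
})
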