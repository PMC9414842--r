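# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so the whole suite runs quickly on one CPU.

fix_px <- 2.1

fix_ctf <- function(px = fix_px) ctf_params(pixel_size = px)

# Small phantom at the micrograph pixel size (full box 128 px = 26.9 nm).
fix_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_channel_phantom(128, fix_px,
                                                       c2_shift = 5)
    cache
  }
})

# One noise-free micrograph with a single 20-nm liposome and no particles.
fix_micro_single <- function(seed = 3, dose = NULL, diameter_nm = 20,
                             grid = 512) {
  simulate_micrograph(c(grid, grid), fix_px, diameter_nm,
                      particle_map = fix_phantom(), ctf = fix_ctf(),
                      dose = dose, seed = seed)
}

# Brute-force voxelized projection oracle: density sampled at voxel
# centres on an integer z grid and summed along the beam. Independent of
# the implementation's quadrature and profile table.
oracle_project_radial <- function(profile, radius, r, vox = 1) {
  zmax <- radius + profile$headgroup_offset +
    5 * max(profile$headgroup_sigma, profile$tail_sigma)
  z <- seq(-zmax, zmax, by = vox)
  vapply(r, function(ri) {
    rho <- sqrt(ri^2 + z^2)
    sum(profile_density(profile, rho - radius) -
        profile$solvent_level) * vox
  }, numeric(1))
}

# Greedy one-to-one matching of picks to ground-truth particles.
match_picks <- function(picks, truth, tol_px) {
  if (is.null(truth) || nrow(truth) == 0 || nrow(picks) == 0)
    return(list(matched = 0, fp = nrow(picks)))
  d <- sqrt(outer(picks$x_px, truth$x_px, "-")^2 +
            outer(picks$y_px, truth$y_px, "-")^2)
  used_p <- rep(FALSE, nrow(picks)); used_t <- rep(FALSE, nrow(truth))
  m <- 0
  for (ij in order(d)) {
    if (d[ij] > tol_px) break
    i <- (ij - 1) %% nrow(picks) + 1
    j <- (ij - 1) %/% nrow(picks) + 1
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE; m <- m + 1
    }
  }
  list(matched = m, fp = sum(!used_p))
}

# Two-stage liposome fit from a perturbed initial guess: converge on a
# 2x-binned copy, then polish at full resolution.
two_stage_fit <- function(mg, init, ctf) {
  px <- mg$pixel_size
  mb <- micrograph(fourier_bin(mg$data, 2), px * 2)
  cb <- ctf; cb$pixel_size <- px * 2
  ib <- init; ib$x_px <- ib$x_px / 2; ib$y_px <- ib$y_px / 2
  fb <- fit_liposome(mb, ib, cb, maxit = 150)
  i2 <- init
  i2$x_px <- fb$x_px * 2; i2$y_px <- fb$y_px * 2
  i2$radius_A <- fb$radius_A
  fit_liposome(mg, i2, ctf, maxit = 30)
}

# Stack of clean projections of a map at given angles (optionally CTF).
fix_projection_stack <- function(map, rot, tilt, psi, ctf = NULL) {
  n <- dim(map$data)[1]
  ft <- liporsc:::map_cfft(map)
  h <- if (is.null(ctf)) matrix(1, n, n) else {
    c2 <- ctf; c2$pixel_size <- map$pixel_size
    liporsc:::fftshift(liporsc:::ctf_grid(c2, n, n))
  }
  imgs <- array(0, c(n, n, length(rot)))
  for (i in seq_along(rot)) {
    sl <- liporsc:::project_map_f(ft, rot[i], tilt[i], psi[i]) * h
    imgs[, , i] <- Re(liporsc:::icfft(sl))
  }
  particle_stack(imgs, map$pixel_size,
                 data.frame(idx = seq_along(rot)),
                 box_A = n * map$pixel_size * 0.95,
                 mask_A = n * map$pixel_size * 0.6)
}
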