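# The "spherically constrained" core: liposome geometry -> orientation
# priors, and constrained projection matching against a reference.

#' Orientation prior from liposome geometry
#'
#' For a particle embedded in a spherical vesicle of radius R whose centre
#' projects at distance r from the particle, the membrane normal (particle
#' z-axis) makes a tilt angle `theta = arcsin(r / R)` with the beam — with
#' a two-fold near/far ambiguity `{theta, 180 - theta}` because the sphere
#' side is unobservable in projection. The in-plane angle is the bearing
#' from the liposome centre to the pick. The azimuth about the membrane
#' normal is unconstrained (uniform).
#'
#' @param picks a `particle_picks` data frame (with
#'   `nearest_liposome_id` from [screen_particles()]).
#' @param fits a `liposome_fits` data frame.
#' @param pixel_size pixel size (A).
#' @param tilt_width,psi_width prior widths (degrees, sigma).
#' @return the picks with columns tilt_deg, tilt_alt_deg, psi_deg,
#'   tilt_width_deg, psi_width_deg appended.
#' @export
orientation_prior <- function(picks, fits, pixel_size, tilt_width = 10,
                              psi_width = 10) {
  stopifnot(tilt_width >= 0, psi_width >= 0)
  picks <- as.data.frame(picks)
  idx <- match(picks$nearest_liposome_id, fits$id)
  if (anyNA(idx)) stop("picks reference unknown liposome ids")
  R <- fits$radius_A[idx]
  if (any(R <= 0)) stop("non-positive liposome radius")
  dx <- (picks$x_px - fits$x_px[idx]) * pixel_size
  dy <- (picks$y_px - fits$y_px[idx]) * pixel_size
  r <- sqrt(dx^2 + dy^2)
  ratio <- pmin(r / R, 1)
  picks$tilt_deg <- asin(ratio) * 180 / pi
  picks$tilt_alt_deg <- 180 - picks$tilt_deg
  psi <- atan2(dy, dx) * 180 / pi
  picks$psi_deg <- ifelse(psi < 0, psi + 360, psi)
  picks$tilt_width_deg <- tilt_width
  picks$psi_width_deg <- psi_width
  new_particle_picks(picks)
}

# Correlation of a particle's centered FFT with reference slices at a set
# of candidate angles (all candidates interpolated in one batched call).
score_candidates <- function(Fp, ft, hgrid, cand, kmask) {
  n <- ft$n
  u <- centered_offsets(n)
  ki <- which(kmask)
  ux <- rep(u, times = n)[ki]
  uy <- rep(u, each = n)[ki]
  nk <- length(ki)
  m <- nrow(cand)
  pts <- matrix(0, 3, nk * m)
  for (i in seq_len(m)) {
    A <- rot_zyz(cand$rot[i], cand$tilt[i], cand$psi[i])
    cols <- ((i - 1) * nk + 1):(i * nk)
    pts[, cols] <- t(A) %*% rbind(ux, uy, 0) + ctr(n)
  }
  sr <- interp3(ft$re, pts)
  si <- interp3(ft$im, pts)
  hv <- hgrid[ki]
  fp <- Fp[ki]
  fpn <- sqrt(sum(Mod(fp)^2))
  sc <- numeric(m)
  fre <- Re(fp); fim <- Im(fp)
  for (i in seq_len(m)) {
    cols <- ((i - 1) * nk + 1):(i * nk)
    a <- sr[cols] * hv; b <- si[cols] * hv
    sn <- sqrt(sum(a^2 + b^2))
    sc[i] <- if (sn > 0) sum(fre * a + fim * b) / (fpn * sn) else -1
  }
  sc
}

#' Assign orientations by constrained projection matching
#'
#' For each particle, searches reference projections over the
#' unconstrained azimuth (exhaustively, on a coarse-then-fine grid), the
#' discrete near/far ambiguity, and a local neighbourhood of the prior
#' tilt and in-plane angle, scoring by normalized Fourier-domain
#' correlation (CTF applied to the reference slice). Returned angles are
#' restricted to the prior support.
#'
#' @param stack a [particle_stack()] whose `meta` carries orientation
#'   priors (see [orientation_prior()]).
#' @param reference a [density_map()] at the stack's pixel size and box.
#' @param ctf a [ctf_params()] (pixel size is taken from the stack).
#' @param azimuth_step fine azimuth grid step (degrees, default 5).
#' @param local_step local tilt/psi search step (degrees).
#' @param res_limit_A only Fourier components below this resolution are
#'   scored (default 2.5 x pixel size, i.e. slightly inside Nyquist).
#' @param max_shift_px translational search radius (pixels at the stack
#'   scale); picking localizes particles only to a few pixels, so the
#'   residual shift is refined against the best-matching projection and
#'   reported per particle (default box / 16).
#' @return data frame: rot, tilt, psi (degrees), sx, sy (pixels), score,
#'   near_side.
#' @export
assign_orientations <- function(stack, reference, ctf, azimuth_step = 5,
                                local_step = 5, res_limit_A = NULL,
                                max_shift_px = NULL) {
  m <- dim(stack$images)[3]
  if (m == 0) stop("empty particle stack")
  n <- dim(stack$images)[1]
  if (dim(reference$data)[1] != n ||
      abs(reference$pixel_size - stack$pixel_size) > 1e-6)
    stop("reference grid/pixel size must match the stack")
  ft <- map_cfft(reference)
  ctf2 <- ctf; ctf2$pixel_size <- stack$pixel_size
  hgrid <- fftshift(ctf_grid(ctf2, n, n))
  if (is.null(res_limit_A)) res_limit_A <- 2.5 * stack$pixel_size
  u <- centered_offsets(n)
  kr <- sqrt(outer(u^2, u^2, `+`)) / (n * stack$pixel_size)
  kmask <- kr > 0 & kr < 1 / res_limit_A
  if (is.null(max_shift_px)) max_shift_px <- n / 16
  ux <- matrix(rep(u, times = n), n, n)
  uy <- matrix(rep(u, each = n), n, n)
  meta <- stack$meta
  out <- vector("list", m)
  for (i in seq_len(m)) {
    Fp0 <- cfft(stack$images[, , i])
    t0 <- meta$tilt_deg[i]; p0 <- meta$psi_deg[i]
    tw <- meta$tilt_width_deg[i]; pw <- meta$psi_width_deg[i]
    Fp <- Fp0
    sx <- 0; sy <- 0
    best <- NULL
    for (pass in 1:2) {
      # stage 1: exhaustive azimuth on the fine grid, both tilt branches;
      # after the shift refinement only a local azimuth window is rescanned
      rot_c <- if (pass == 1)
        seq(0, 360 - azimuth_step, by = azimuth_step)
      else
        (best$rot + seq(-3 * azimuth_step, 3 * azimuth_step,
                        by = azimuth_step)) %% 360
      c1 <- expand.grid(rot = rot_c, tilt = c(t0, 180 - t0), psi = p0)
      s1 <- score_candidates(Fp, ft, hgrid, c1, kmask)
      # stage 2: local rot/tilt/psi refinement around the best candidate
      # of EACH near/far branch, so off-grid azimuths cannot lock in the
      # wrong sphere side prematurely
      c2l <- lapply(split(seq_len(nrow(c1)), c1$tilt <= 90), function(ix) {
        b <- ix[which.max(s1[ix])]
        rot_f <- c1$rot[b] + c(-azimuth_step, 0, azimuth_step)
        tilt_f <- c1$tilt[b] + seq(-tw, tw, by = local_step)
        psi_f <- p0 + seq(-pw, pw, by = local_step)
        g <- expand.grid(rot = rot_f %% 360, tilt = tilt_f, psi = psi_f)
        g[g$tilt >= 0 & g$tilt <= 180, , drop = FALSE]
      })
      c2 <- do.call(rbind, c2l)
      s2 <- score_candidates(Fp, ft, hgrid, c2, kmask)
      b2 <- which.max(s2)
      best <- data.frame(rot = c2$rot[b2], tilt = c2$tilt[b2],
                         psi = c2$psi[b2] %% 360, score = s2[b2],
                         near_side = c2$tilt[b2] <= 90)
      if (pass == 2 || max_shift_px <= 0) break
      # translational refinement against the winning projection
      sl <- project_map_f(ft, best$rot, best$tilt, best$psi) * hgrid
      cc <- Re(icfft(Fp0 * Conj(sl)))
      win <- abs(ux) <= max_shift_px & abs(uy) <= max_shift_px
      cc[!win] <- -Inf
      pk <- which.max(cc)
      pi_ <- (pk - 1) %% n + 1; pj <- (pk - 1) %/% n + 1
      dx <- pi_ - ctr(n); dy <- pj - ctr(n)
      # parabolic sub-pixel refinement
      if (pi_ > 1 && pi_ < n && is.finite(cc[pi_ - 1, pj]) &&
          is.finite(cc[pi_ + 1, pj])) {
        den <- cc[pi_ - 1, pj] - 2 * cc[pi_, pj] + cc[pi_ + 1, pj]
        if (den < 0) dx <- dx + 0.5 * (cc[pi_ - 1, pj] - cc[pi_ + 1, pj]) / den
      }
      if (pj > 1 && pj < n && is.finite(cc[pi_, pj - 1]) &&
          is.finite(cc[pi_, pj + 1])) {
        den <- cc[pi_, pj - 1] - 2 * cc[pi_, pj] + cc[pi_, pj + 1]
        if (den < 0) dy <- dy + 0.5 * (cc[pi_, pj - 1] - cc[pi_, pj + 1]) / den
      }
      sx <- dx; sy <- dy
      if (abs(sx) < 0.2 && abs(sy) < 0.2) break  # already centred
      # recentre the particle spectrum: I(x - s) -> I(x)
      Fp <- Fp0 * exp(2i * pi * (ux * sx + uy * sy) / n)
    }
    best$sx <- sx; best$sy <- sy
    out[[i]] <- best[, c("rot", "tilt", "psi", "sx", "sy", "score",
                         "near_side")]
  }
  do.call(rbind, out)
}
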