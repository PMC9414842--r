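# Direct Fourier-inversion reconstruction with CTF^2 (Wiener-style)
# weighting, Cn symmetrization, and Fourier shell correlation.

# Zero the u = -n/2 faces (which have no Hermitian mate on an even grid)
# and return the Friedel-flipped array: A[u] -> A[-u].
friedel_flip <- function(a) {
  n <- dim(a)[1]
  a[1, , ] <- 0; a[, 1, ] <- 0; a[, , 1] <- 0
  f <- c(1L, n:2L)
  list(zeroed = a, flipped = a[f, f, f])
}

#' Reconstruct a 3D map by direct Fourier inversion
#'
#' Inserts each particle image's centered 2D Fourier transform as a
#' central slice at its assigned orientation (trilinear spreading), with
#' CTF weighting: the numerator accumulates `CTF * F_image`, the
#' denominator `CTF^2`, and the map is the inverse transform of
#' `numerator / (denominator + lambda)` with a small Wiener constant
#' `lambda = wiener * mean(nonzero weights)`. Hermitian symmetry is
#' enforced before inversion; Cn symmetry is imposed afterwards by
#' real-space averaging over the n rotations about z.
#'
#' @param stack a [particle_stack()].
#' @param angles data frame with rot, tilt, psi (degrees) per particle,
#'   e.g. from [assign_orientations()].
#' @param ctf a [ctf_params()] or NULL for no CTF weighting.
#' @param symmetry 1, 2 or 4 (Cn about z).
#' @param wiener relative Wiener constant.
#' @param min_particles fewer particles than this triggers a warning.
#' @param weights optional per-particle weights (e.g. assignment
#'   correlation scores); negative values are clipped to zero.
#' @return a [density_map()].
#' @export
backproject <- function(stack, angles, ctf = NULL, symmetry = 1,
                        wiener = 0.05, min_particles = 10,
                        weights = NULL) {
  if (!symmetry %in% c(1, 2, 4)) stop("symmetry must be 1, 2 or 4")
  m <- dim(stack$images)[3]
  if (m == 0) stop("empty particle stack")
  if (m < min_particles)
    warning("only ", m, " particles; reconstruction will be noisy")
  if (nrow(angles) != m) stop("angles must have one row per particle")
  n <- dim(stack$images)[1]
  dims <- c(n, n, n)
  hgrid <- if (is.null(ctf)) matrix(1, n, n) else {
    ctf2 <- ctf; ctf2$pixel_size <- stack$pixel_size
    fftshift(ctf_grid(ctf2, n, n))
  }
  NRe <- numeric(n^3); NIm <- numeric(n^3); W <- numeric(n^3)
  u <- centered_offsets(n)
  ux <- matrix(rep(u, times = n), n, n)
  uy <- matrix(rep(u, each = n), n, n)
  has_shift <- all(c("sx", "sy") %in% names(angles))
  pw <- if (is.null(weights)) rep(1, m) else pmax(as.numeric(weights), 0)
  for (i in seq_len(m)) {
    if (pw[i] == 0) next
    Fp <- cfft(stack$images[, , i]) * hgrid
    if (has_shift && (angles$sx[i] != 0 || angles$sy[i] != 0))
      Fp <- Fp * exp(2i * pi * (ux * angles$sx[i] + uy * angles$sy[i]) / n)
    A <- rot_zyz(angles$rot[i], angles$tilt[i], angles$psi[i])
    pts <- slice_indices(n, A)
    sp <- trilinear_spread(pts, dims)
    vre <- Re(Fp)[sp$keep]; vim <- Im(Fp)[sp$keep]
    w2 <- (hgrid^2)[sp$keep]
    NRe <- accumulate_at(NRe, sp$idx, rep(vre, 8) * sp$w * pw[i])
    NIm <- accumulate_at(NIm, sp$idx, rep(vim, 8) * sp$w * pw[i])
    W <- accumulate_at(W, sp$idx, rep(w2, 8) * sp$w * pw[i])
  }
  dim(NRe) <- dims; dim(NIm) <- dims; dim(W) <- dims
  fr <- friedel_flip(NRe); fi <- friedel_flip(NIm); fw <- friedel_flip(W)
  NRe <- (fr$zeroed + fr$flipped) / 2
  NIm <- (fi$zeroed - fi$flipped) / 2
  W <- (fw$zeroed + fw$flipped) / 2
  lam <- wiener * mean(W[W > 0])
  Fmap <- complex(real = NRe, imaginary = NIm) / (W + lam)
  dim(Fmap) <- dims
  map <- density_map(Re(icfft(Fmap)), stack$pixel_size, "C1")
  if (symmetry > 1) map <- symmetrize_map(map, symmetry)
  map
}

#' Gold-standard half-map reconstruction
#'
#' Shuffles the particle order with a seed, assigns even/odd indices to
#' two disjoint halves, backprojects each half independently, and returns
#' both half-maps, the full map and their FSC.
#'
#' @inheritParams backproject
#' @param seed shuffle seed.
#' @return list(map, half1, half2, fsc).
#' @export
reconstruct_halves <- function(stack, angles, ctf = NULL, symmetry = 1,
                               seed = 1, wiener = 0.05, weights = NULL) {
  m <- dim(stack$images)[3]
  ord <- with_seed(seed, sample.int(m))
  h1 <- ord[seq(1, m, by = 2)]
  h2 <- ord[seq(2, m, by = 2)]
  sub_stack <- function(idx) particle_stack(
    stack$images[, , idx, drop = FALSE], stack$pixel_size,
    stack$meta[idx, , drop = FALSE], stack$box_A, stack$mask_A)
  wsub <- function(idx) if (is.null(weights)) NULL else weights[idx]
  map1 <- backproject(sub_stack(h1), angles[h1, , drop = FALSE], ctf,
                      symmetry, wiener, min_particles = 1,
                      weights = wsub(h1))
  map2 <- backproject(sub_stack(h2), angles[h2, , drop = FALSE], ctf,
                      symmetry, wiener, min_particles = 1,
                      weights = wsub(h2))
  full <- backproject(stack, angles, ctf, symmetry, wiener,
                      min_particles = 1, weights = weights)
  list(map = full, half1 = map1, half2 = map2,
       fsc = compute_fsc(map1, map2))
}

#' Fourier shell correlation between two maps
#'
#' Per-shell (1 Fourier voxel wide) normalized cross-correlation of the
#' two maps' Fourier coefficients. The resolution is the reciprocal of the
#' first frequency at which the curve crosses below `threshold` (0.143 for
#' gold-standard half-maps), linearly interpolated between shells; if the
#' curve never crosses, the Nyquist resolution (2 x pixel size) is
#' reported.
#'
#' @param half1,half2 [density_map()] objects on the same grid.
#' @param threshold FSC criterion (default 0.143).
#' @return object of class `fsc_curve`: data frame (freq_invA, fsc,
#'   n_voxels) with attributes resolution_A and threshold.
#' @export
compute_fsc <- function(half1, half2, threshold = 0.143) {
  if (!all(dim(half1$data) == dim(half2$data)) ||
      abs(half1$pixel_size - half2$pixel_size) > 1e-9)
    stop("half-maps must share grid and pixel size")
  n <- dim(half1$data)[1]
  px <- half1$pixel_size
  F1 <- cfft(half1$data); F2 <- cfft(half2$data)
  u <- centered_offsets(n)
  kr <- sqrt(outer(u^2, u^2, `+`))
  kr3 <- sqrt(outer(kr^2, u^2, `+`))
  shell <- as.integer(round(kr3))
  nsh <- n / 2
  keep <- shell >= 0 & shell < nsh
  sidx <- shell[keep] + 1L
  cr <- Re(F1 * Conj(F2))[keep]
  p1 <- (Mod(F1)^2)[keep]
  p2 <- (Mod(F2)^2)[keep]
  num <- rowsum(cr, sidx)[, 1]
  d1 <- rowsum(p1, sidx)[, 1]
  d2 <- rowsum(p2, sidx)[, 1]
  cnt <- rowsum(rep(1, length(sidx)), sidx)[, 1]
  fsc <- num / pmax(sqrt(d1 * d2), .Machine$double.eps)
  freq <- (seq_len(nsh) - 1) / (n * px)
  res <- 2 * px
  below <- which(fsc < threshold & seq_len(nsh) > 1)
  if (length(below) > 0) {
    i <- below[1]
    f0 <- freq[i - 1]; f1 <- freq[i]
    y0 <- fsc[i - 1]; y1 <- fsc[i]
    fc <- if (y0 == y1) f1 else f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
    res <- 1 / fc
  }
  out <- data.frame(freq_invA = freq, fsc = fsc, n_voxels = cnt)
  attr(out, "resolution_A") <- res
  attr(out, "threshold") <- threshold
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC over %d shells; resolution %.2f A at threshold %.3f\n",
              nrow(x), attr(x, "resolution_A"), attr(x, "threshold")))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$freq_invA, x$fsc, type = "l", xlab = "frequency (1/A)",
                 ylab = "FSC", ylim = c(-0.1, 1), ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2)
  invisible(x)
}
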