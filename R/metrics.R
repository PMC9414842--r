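# Rotational-symmetry scoring and map comparison.

# Soft spherical (or shell) mask: 1 inside r_out, raised-cosine edge of
# `edge_A`, optional inner exclusion at r_in (both in Angstrom).
soft_sphere_mask <- function(n, pixel_size, r_out, r_in = 0, edge_A = 10) {
  u <- (seq_len(n) - ctr(n)) * pixel_size
  r2 <- outer(u^2, u^2, `+`)
  r <- sqrt(outer(as.vector(r2), u^2, `+`))
  ramp <- function(d) pmin(pmax(d / edge_A, 0), 1)
  w <- 0.5 - 0.5 * cos(pi * ramp(r_out - r))
  if (r_in > 0) w <- w * (0.5 - 0.5 * cos(pi * ramp(r - r_in)))
  array(w, c(n, n, n))
}

weighted_cor <- function(a, b, w) {
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2); vb <- sum(w * (b - mb)^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
}

#' Rotational symmetry score of a map
#'
#' Masked Pearson correlation between the map and its rotation by
#' `360 / n_fold` degrees about z. A perfectly Cn-symmetric map scores 1
#' (to interpolation tolerance); symmetry breaking lowers the score at the
#' broken order. The mask is a soft spherical shell (default: a ball of
#' `mask_radius_A`) intended to cover the region under test, e.g. the
#' gating ring.
#'
#' @param map a [density_map()].
#' @param n_fold symmetry order to test (>= 1).
#' @param mask_radius_A outer mask radius (A); default 40% of the box.
#' @param mask_inner_A inner exclusion radius (A), default 0.
#' @return object of class `symmetry_report`.
#' @export
symmetry_correlation <- function(map, n_fold, mask_radius_A = NULL,
                                 mask_inner_A = 0) {
  if (!is.numeric(n_fold) || n_fold < 1) stop("n_fold must be >= 1")
  n <- dim(map$data)[1]
  if (is.null(mask_radius_A)) mask_radius_A <- 0.4 * n * map$pixel_size
  if (mask_radius_A > (n / 2) * map$pixel_size)
    stop("mask extends beyond the grid")
  cc <- if (n_fold == 1) 1 else {
    rot <- rotate_map_z(map, 360 / n_fold)
    w <- soft_sphere_mask(n, map$pixel_size, mask_radius_A, mask_inner_A)
    weighted_cor(map$data, rot$data, w)
  }
  structure(list(n_fold = n_fold, correlation = cc,
                 mask_radius_A = mask_radius_A,
                 mask_inner_A = mask_inner_A, axis = "z"),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("C%d symmetry correlation about %s: %.4f (mask %.0f A)\n",
              x$n_fold, x$axis, x$correlation, x$mask_radius_A))
  invisible(x)
}

#' Soft molecular-envelope mask from a reference map
#'
#' The standard mask for map-vs-map correlation: the reference is low-pass
#' filtered and thresholded at a fraction of its maximum, with a soft ramp,
#' so the comparison weights actual density rather than empty solvent.
#'
#' @param map a [density_map()] (typically the reference/phantom).
#' @param lowpass_A smoothing resolution (A) before thresholding.
#' @param threshold_frac mask onset as a fraction of the smoothed maximum.
#' @param soft_frac ramp width as a fraction of the smoothed maximum.
#' @return 3D weight array in [0, 1].
#' @export
envelope_mask <- function(map, lowpass_A = 20, threshold_frac = 0.02,
                          soft_frac = 0.04) {
  sm <- lowpass_map(map, lowpass_A)$data
  mx <- max(sm)
  pmin(pmax((sm - threshold_frac * mx) / (soft_frac * mx), 0), 1)
}

#' Compare two maps
#'
#' Masked real-space Pearson correlation plus the shell-resolved Fourier
#' correlation between two maps on the same grid. The mask is either a
#' soft sphere (`mask_radius_A`) or an arbitrary weight array such as an
#' [envelope_mask()].
#'
#' @param map_a,map_b [density_map()] objects.
#' @param mask_radius_A outer mask radius (A); default 40% of the box.
#' @param mask_inner_A inner exclusion radius (A).
#' @param mask optional weight array overriding the spherical mask.
#' @return list(correlation, shells) where `shells` is an `fsc_curve`.
#' @export
compare_maps <- function(map_a, map_b, mask_radius_A = NULL,
                         mask_inner_A = 0, mask = NULL) {
  if (!all(dim(map_a$data) == dim(map_b$data)) ||
      abs(map_a$pixel_size - map_b$pixel_size) > 1e-9)
    stop("maps must share grid and pixel size (resample first)")
  n <- dim(map_a$data)[1]
  w <- if (!is.null(mask)) {
    if (!all(dim(mask) == dim(map_a$data)))
      stop("mask grid does not match the maps")
    mask
  } else {
    if (is.null(mask_radius_A)) mask_radius_A <- 0.4 * n * map_a$pixel_size
    soft_sphere_mask(n, map_a$pixel_size, mask_radius_A, mask_inner_A)
  }
  list(correlation = weighted_cor(map_a$data, map_b$data, w),
       shells = compute_fsc(map_a, map_b, threshold = 0.143))
}
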