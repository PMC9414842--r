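# Particle operations: template picking on liposome-subtracted
# micrographs, the membrane-distance screen, and boxed extraction.

new_particle_picks <- function(df) {
  class(df) <- c("particle_picks", "data.frame")
  df
}

#' Pick particles by template matching
#'
#' Normalized cross-correlation of the (liposome-subtracted) micrograph
#' against each template over a set of in-plane rotations; the score at
#' each pixel is the maximum over templates and rotations. Picks are local
#' maxima above `threshold` with non-maximum suppression at
#' `min_dist_px`.
#'
#' @param micro a [micrograph()], normally liposome-subtracted.
#' @param templates a list of square matrices (or one matrix) at the
#'   micrograph pixel size.
#' @param threshold NCC threshold, or "auto" for median + `auto_k` * MAD.
#' @param auto_k robust-sigma multiplier for the auto threshold.
#' @param n_rot number of in-plane template rotations spanning 360 deg.
#' @param min_dist_px minimum distance between picks at full resolution
#'   (default: half the template edge).
#' @param bin binning factor for the correlation search (default 2; the
#'   particle signal is concentrated at low resolution, and downstream
#'   orientation assignment refines residual shifts).
#' @return a `particle_picks` data frame: x_px, y_px, score (coordinates
#'   at full resolution).
#' @export
pick_particles <- function(micro, templates, threshold = "auto", auto_k = 8,
                           n_rot = 8, min_dist_px = NULL, bin = 2) {
  if (is.matrix(templates)) templates <- list(templates)
  data_b <- if (bin > 1) fourier_bin(micro$data, bin) else micro$data
  tmpl_b <- lapply(templates, function(tm)
    if (bin > 1) fourier_bin(tm, bin) else tm)
  all_t <- list()
  for (tm in tmpl_b) {
    for (k in seq_len(n_rot)) {
      ang <- 360 * (k - 1) / n_rot
      all_t[[length(all_t) + 1]] <- if (ang == 0) tm else
        rotate_image(tm, ang)
    }
  }
  best <- ncc_map_multi(data_b, all_t)
  thr <- if (identical(threshold, "auto"))
    stats::median(best) + auto_k * score_mad(best) else threshold
  edge <- nrow(tmpl_b[[1]]) %/% 2
  # particles on one vesicle often project close together; suppressing
  # within ~3/8 of the template edge balances crowded-pair recall against
  # duplicate picks
  if (is.null(min_dist_px)) min_dist_px <- (3 * nrow(templates[[1]])) %/% 8
  pk <- find_peaks(best, thr, min_dist_px / bin, exclude_border = edge)
  new_particle_picks(data.frame(
    id = seq_len(nrow(pk)), x_px = pk$x * bin, y_px = pk$y * bin,
    score = pk$score))
}

# In-plane rotation of a square image about its centre (bilinear).
rotate_image <- function(img, angle) {
  n <- nrow(img)
  a <- angle * pi / 180
  cc <- ctr(n)
  u <- seq_len(n) - cc
  x <- rep(u, times = n); y <- rep(u, each = n)
  xs <- cos(a) * x + sin(a) * y
  ys <- -sin(a) * x + cos(a) * y
  matrix(interp2(img, xs + cc, ys + cc), n, n)
}

#' Screen picks by distance to the nearest liposome membrane
#'
#' For each pick the membrane distance is
#' `min over liposomes of | ||pick - centre|| - radius |` (2D distance from
#' the projected membrane circle, not from the vesicle centre — a membrane
#' protein sits in the membrane, and a centre-distance rule would scale
#' with vesicle size). Picks farther than `cutoff_A` from every membrane
#' circle are excluded.
#'
#' @param picks a `particle_picks` data frame.
#' @param fits a `liposome_fits` data frame.
#' @param cutoff_A screen cutoff in Angstrom (default 80).
#' @param pixel_size pixel size (A) used to convert pick/fit coordinates.
#' @param keep_all if TRUE, return all picks annotated with `kept`;
#'   default returns only kept picks (still annotated).
#' @return `particle_picks` with columns membrane_distance_A,
#'   nearest_liposome_id, kept.
#' @export
screen_particles <- function(picks, fits, cutoff_A = 80, pixel_size,
                             keep_all = FALSE) {
  if (cutoff_A < 0) stop("cutoff must be >= 0")
  picks <- as.data.frame(picks)
  if (nrow(fits) == 0) {
    warning("no liposome fits supplied; excluding all picks")
    picks$membrane_distance_A <- Inf
    picks$nearest_liposome_id <- NA_integer_
    picks$kept <- FALSE
    return(new_particle_picks(if (keep_all) picks else picks[FALSE, ]))
  }
  dmat <- vapply(seq_len(nrow(fits)), function(j) {
    abs(sqrt((picks$x_px - fits$x_px[j])^2 +
             (picks$y_px - fits$y_px[j])^2) * pixel_size - fits$radius_A[j])
  }, numeric(nrow(picks)))
  dmat <- matrix(dmat, nrow = nrow(picks))
  jmin <- max.col(-dmat, ties.method = "first")
  picks$membrane_distance_A <- dmat[cbind(seq_len(nrow(picks)), jmin)]
  picks$nearest_liposome_id <- fits$id[jmin]
  picks$kept <- picks$membrane_distance_A <= cutoff_A
  new_particle_picks(if (keep_all) picks else
    picks[picks$kept, , drop = FALSE])
}

#' Particle image stack
#'
#' Boxed particle images plus per-particle metadata. `images` is an
#' `n x n x m` array; `meta` carries pick coordinates, liposome links and
#' (after [orientation_prior()]) orientation priors.
#'
#' @param images n x n x m array.
#' @param pixel_size pixel size (A).
#' @param meta data frame with one row per image.
#' @param box_A,mask_A box edge and circular mask diameter (A).
#' @return object of class `particle_stack`.
#' @export
particle_stack <- function(images, pixel_size, meta, box_A, mask_A) {
  stopifnot(length(dim(images)) == 3, dim(images)[1] == dim(images)[2])
  if (mask_A >= box_A) stop("mask must be smaller than the box")
  structure(list(images = images, pixel_size = pixel_size, meta = meta,
                 box_A = box_A, mask_A = mask_A),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "Particle stack: %d images, %dx%d px (%.3f A/px), box %.0f A, mask %.0f A\n",
    d[3], d[1], d[2], x$pixel_size, x$box_A, x$mask_A))
  invisible(x)
}

#' Extract boxed particle images
#'
#' Crops a square box around each kept pick. Boxes that would cross the
#' micrograph edge are dropped (count recorded in attribute `n_dropped`).
#' Each box is normalized to mean 0 / variance 1 estimated outside the
#' mask radius, and optionally soft-masked (raised-cosine edge at the mask
#' radius).
#'
#' @param micro a [micrograph()] (normally liposome-subtracted).
#' @param picks a `particle_picks` data frame of kept picks.
#' @param box_nm box edge in nm (default 27).
#' @param mask_nm circular mask diameter in nm (default 17).
#' @param soft_mask apply the raised-cosine mask (default TRUE).
#' @param normalize standardize each box from the out-of-mask pixels.
#' @return a [particle_stack()].
#' @export
extract_boxes <- function(micro, picks, box_nm = 27, mask_nm = 17,
                          soft_mask = TRUE, normalize = TRUE) {
  px <- micro$pixel_size
  np <- 2 * round(box_nm * 10 / px / 2)
  if (np > min(dim(micro$data))) stop("box larger than micrograph")
  half <- np / 2
  n1 <- nrow(micro$data); n2 <- ncol(micro$data)
  rmask_px <- mask_nm * 10 / 2 / px
  rg <- radius_grid(np, np, half, half)
  outside <- rg > rmask_px
  edge_w <- 0.1 * np
  soft <- pmin(pmax((rmask_px + edge_w - rg) / edge_w, 0), 1)
  soft <- 0.5 - 0.5 * cos(pi * soft)
  imgs <- list(); kept_rows <- integer(0)
  for (i in seq_len(nrow(picks))) {
    # centre pixel at local 1-based index half + 1 (= ctr(np)), matching
    # the centered-FFT convention used by projection and reconstruction
    xi <- round(picks$x_px[i]); yi <- round(picks$y_px[i])
    r0 <- xi + 1 - half; r1 <- xi + half
    c0 <- yi + 1 - half; c1 <- yi + half
    if (r0 < 1 || c0 < 1 || r1 > n1 || c1 > n2) next
    box <- micro$data[r0:r1, c0:c1]
    if (normalize) {
      mu <- mean(box[outside]); sdv <- stats::sd(box[outside])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      box <- (box - mu) / sdv
    }
    if (soft_mask) {
      box <- box * soft
      if (normalize) box <- box - mean(box)  # exact zero mean after masking
    }
    imgs[[length(imgs) + 1]] <- box
    kept_rows <- c(kept_rows, i)
  }
  meta <- as.data.frame(picks)[kept_rows, , drop = FALSE]
  if (length(kept_rows) > 0) {
    # box centre sits at pixel index half (1-based) = rounded pick
    meta$box_x0 <- round(meta$x_px) - (half - 1) - 1  # 0-based origin
    meta$box_y0 <- round(meta$y_px) - (half - 1) - 1
  }
  arr <- array(if (length(imgs)) unlist(imgs) else numeric(0),
               c(np, np, length(imgs)))
  st <- particle_stack(arr, px, meta, box_nm * 10, mask_nm * 10)
  attr(st, "n_dropped") <- nrow(picks) - length(kept_rows)
  st
}

#' Fourier-crop (bin) a particle stack
#'
#' @param stack a [particle_stack()].
#' @param factor integer binning factor.
#' @return a [particle_stack()] at the coarser pixel size.
#' @export
bin_stack <- function(stack, factor) {
  if (factor == 1) return(stack)
  d <- dim(stack$images)
  m <- d[1] / factor
  out <- array(0, c(m, m, d[3]))
  for (i in seq_len(d[3]))
    out[, , i] <- fourier_bin(stack$images[, , i], factor)
  particle_stack(out, stack$pixel_size * factor, stack$meta, stack$box_A,
                 stack$mask_A)
}
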