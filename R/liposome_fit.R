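# Liposome detection, spherical-bilayer model fitting under the CTF, and
# membrane subtraction.

new_liposome_fits <- function(df) {
  need <- c("id", "x_px", "y_px", "radius_A", "amplitude", "background",
            "residual_rms", "converged", "score")
  for (col in setdiff(need, names(df))) df[[col]] <- rep(NA, nrow(df))
  class(df) <- c("liposome_fits", "data.frame")
  df
}

#' @export
print.liposome_fits <- function(x, ...) {
  cat(sprintf("%d liposome fit(s); %d converged\n", nrow(x),
              sum(x$converged %in% TRUE)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# CTF-convolved model patch of one liposome membrane, unit amplitude.
# center in 0-based patch pixels.
render_liposome_patch <- function(profile, radius, ctf, npatch,
                                  center = NULL) {
  m <- project_sphere_profile(profile, radius, ctf$pixel_size,
                              c(npatch, npatch), center = center)
  apply_ctf(m, ctf)
}

#' Detect liposomes in a micrograph
#'
#' Multi-radius template matching: for a geometric ladder of radii the
#' CTF-convolved spherical-bilayer projection is cross-correlated with the
#' micrograph (normalized cross-correlation); candidate centres are local
#' maxima of the best-over-radii score, pruned so that no two candidate
#' membrane circles overlap.
#'
#' @param micro a [micrograph()].
#' @param ctf a [ctf_params()]; defaults to the micrograph's own.
#' @param radius_range candidate membrane radii (A), within the model
#'   bounds.
#' @param n_radii number of radius steps on a geometric ladder.
#' @param threshold NCC acceptance threshold, or "auto" for
#'   median + `auto_k` * MAD of the score map.
#' @param auto_k robust-sigma multiplier for the auto threshold.
#' @param profile a [bilayer_profile()].
#' @param overlap_frac two candidates closer than
#'   `overlap_frac * (R1 + R2)` are considered the same vesicle.
#' @return a `liposome_fits` data frame of initial (unrefined) fits.
#' @export
detect_liposomes <- function(micro, ctf = micro$ctf,
                             radius_range = c(75, 350), n_radii = 8,
                             threshold = "auto", auto_k = 8,
                             profile = bilayer_profile(),
                             overlap_frac = 0.6, bin = 2) {
  if (is.null(ctf)) stop("ctf required (none attached to micrograph)")
  if (radius_range[1] < 60 || radius_range[2] > 400)
    stop("radius_range outside model bounds [60, 400] A")
  px <- micro$pixel_size
  empty <- new_liposome_fits(
    data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
               radius_A = numeric(0), amplitude = numeric(0),
               background = numeric(0), residual_rms = numeric(0),
               converged = logical(0), score = numeric(0)))
  # coarse stages run on a binned copy (membrane fringes survive easily)
  data_b <- if (bin > 1) fourier_bin(micro$data, bin) else micro$data
  px_b <- px * bin
  ctf_b <- ctf; ctf_b$pixel_size <- px_b
  radii <- exp(seq(log(radius_range[1]), log(radius_range[2]),
                   length.out = n_radii))
  best <- matrix(-Inf, nrow(data_b), ncol(data_b))
  ext <- profile_extent(profile)
  for (r in radii) {
    np <- good_fft_size(2 * (r + ext + 40) / px_b)
    tmpl <- render_liposome_patch(profile, r, ctf_b, np)
    sc <- ncc_map(data_b, tmpl)
    upd <- sc > best
    best[upd] <- sc[upd]
  }
  thr <- if (identical(threshold, "auto"))
    stats::median(best) + auto_k * score_mad(best) else threshold
  border <- ceiling(radius_range[1] / px_b / 2)
  pk <- find_peaks(best, thr, min_dist = radius_range[1] / px_b,
                   exclude_border = border)
  if (nrow(pk) == 0) return(empty)
  # refine each candidate's radius and centre on a denser ladder: the
  # max-over-radii map can mislabel the radius (a small ring template
  # scoring on an arc of a larger vesicle) and then mislocate the centre,
  # so re-run a local NCC per candidate and radius with a shift window
  rfine <- exp(seq(log(radius_range[1]), log(radius_range[2]),
                   length.out = 2 * n_radii))
  pad <- ceiling(26 / px_b)
  best_sc <- rep(-Inf, nrow(pk))
  best_rr <- rep(radii[1], nrow(pk))
  best_x <- pk$x; best_y <- pk$y
  for (j in seq_along(rfine)) {
    r <- rfine[j]
    np <- good_fft_size(2 * (r + ext + 30) / px_b)
    tmpl <- render_liposome_patch(profile, r, ctf_b, np)
    for (i in seq_len(nrow(pk))) {
      gp <- get_patch(data_b, pk$x[i], pk$y[i], good_fft_size(np + 2 * pad))
      if (is.null(gp)) next
      sc <- ncc_map(gp$patch, tmpl)
      cx_l <- pk$x[i] - gp$x0 + 1; cy_l <- pk$y[i] - gp$y0 + 1
      rows <- max(1, cx_l - pad):min(nrow(sc), cx_l + pad)
      cols <- max(1, cy_l - pad):min(ncol(sc), cy_l + pad)
      sub <- sc[rows, cols]
      mx <- which.max(sub)
      if (sub[mx] > best_sc[i]) {
        best_sc[i] <- sub[mx]
        best_rr[i] <- r
        best_x[i] <- rows[(mx - 1) %% length(rows) + 1] - 1 + gp$x0
        best_y[i] <- cols[(mx - 1) %/% length(rows) + 1] - 1 + gp$y0
      }
    }
  }
  # back to full resolution; one full-res NCC at the chosen radius
  # re-centres each candidate to pixel precision
  pk$radius_A <- best_rr
  pk$x <- best_x * bin; pk$y <- best_y * bin
  pk$score <- best_sc
  shift_w <- 2 * bin
  for (i in seq_len(nrow(pk))) {
    r <- pk$radius_A[i]
    np <- good_fft_size(2 * (r + ext + 30) / px)
    gp <- get_patch(micro$data, pk$x[i], pk$y[i], good_fft_size(np + 2 * shift_w))
    if (is.null(gp)) next
    tmpl <- render_liposome_patch(profile, r, ctf, np)
    sc <- ncc_map(gp$patch, tmpl)
    cx_l <- pk$x[i] - gp$x0 + 1; cy_l <- pk$y[i] - gp$y0 + 1
    rows <- max(1, cx_l - shift_w):min(nrow(sc), cx_l + shift_w)
    cols <- max(1, cy_l - shift_w):min(ncol(sc), cy_l + shift_w)
    sub <- sc[rows, cols]
    mx <- which.max(sub)
    ri <- rows[(mx - 1) %% length(rows) + 1]
    ci <- cols[(mx - 1) %/% length(rows) + 1]
    # parabolic sub-pixel interpolation of the correlation peak
    dx <- dy <- 0
    if (ri > 1 && ri < nrow(sc)) {
      den <- sc[ri - 1, ci] - 2 * sc[ri, ci] + sc[ri + 1, ci]
      if (den < 0) dx <- 0.5 * (sc[ri - 1, ci] - sc[ri + 1, ci]) / den
    }
    if (ci > 1 && ci < ncol(sc)) {
      den <- sc[ri, ci - 1] - 2 * sc[ri, ci] + sc[ri, ci + 1]
      if (den < 0) dy <- 0.5 * (sc[ri, ci - 1] - sc[ri, ci + 1]) / den
    }
    pk$x[i] <- ri - 1 + dx + gp$x0
    pk$y[i] <- ci - 1 + dy + gp$y0
    pk$score[i] <- max(sc[ri, ci], pk$score[i])
  }
  # overlap pruning with per-candidate radii (pk already score-ordered)
  keep <- integer(0)
  for (i in seq_len(nrow(pk))) {
    if (length(keep) == 0 ||
        all(sqrt((pk$x[keep] - pk$x[i])^2 + (pk$y[keep] - pk$y[i])^2) * px >
            overlap_frac * (pk$radius_A[keep] + pk$radius_A[i])))
      keep <- c(keep, i)
  }
  pk <- pk[keep, , drop = FALSE]
  new_liposome_fits(data.frame(
    id = seq_len(nrow(pk)), x_px = pk$x, y_px = pk$y,
    radius_A = pk$radius_A, amplitude = NA_real_, background = NA_real_,
    residual_rms = NA_real_, converged = FALSE, score = pk$score))
}

# Extract a square patch (np x np) centred near 0-based (x, y); returns
# list(patch, x0, y0) with the 0-based pixel of patch[1,1], or NULL if the
# patch cannot be placed inside the grid.
get_patch <- function(data, x, y, np) {
  nx <- nrow(data); ny <- ncol(data)
  if (np > nx || np > ny) return(NULL)
  x0 <- min(max(round(x) - np / 2, 0), nx - np)
  y0 <- min(max(round(y) - np / 2, 0), ny - np)
  list(patch = data[(x0 + 1):(x0 + np), (y0 + 1):(y0 + np)],
       x0 = x0, y0 = y0)
}

#' Refine one liposome fit
#'
#' Least-squares refinement of centre, radius, amplitude and background:
#' the CTF-convolved spherical-bilayer projection is compared with the
#' micrograph over an annulus `radius +/- annulus_A` around the membrane
#' circle. Centre and radius are optimized by Nelder-Mead simplex; the
#' amplitude and constant background are solved in closed form (a linear
#' subproblem) at every iterate.
#'
#' @param micro a [micrograph()].
#' @param init a single-row `liposome_fits` entry (or data frame with
#'   x_px, y_px, radius_A).
#' @param ctf a [ctf_params()].
#' @param profile a [bilayer_profile()] (shape fixed, only scaled).
#' @param radius_bounds allowed radius interval (A).
#' @param annulus_A half-width (A) of the fitting annulus around the
#'   membrane circle.
#' @param exclude_px optional data frame (x_px, y_px, r_px) of circular
#'   regions (e.g. picked-particle boxes) masked out of the objective.
#' @param maxit simplex iteration cap.
#' @return the refined single-row `liposome_fits` entry; if the optimizer
#'   fails to converge or hits a bound the best iterate is kept and
#'   `converged` is FALSE.
#' @export
fit_liposome <- function(micro, init, ctf = micro$ctf,
                         profile = bilayer_profile(),
                         radius_bounds = c(60, 400), annulus_A = 60,
                         exclude_px = NULL, maxit = 300) {
  if (is.null(ctf)) stop("ctf required")
  px <- micro$pixel_size
  R0 <- init$radius_A[1]
  if (R0 < radius_bounds[1] || R0 > radius_bounds[2])
    stop("initial radius outside bounds")
  ext <- profile_extent(profile)
  np <- good_fft_size(2 * (min(R0 * 1.15 + 15, radius_bounds[2]) + ext +
                          annulus_A + 56) / px)
  gp <- get_patch(micro$data, init$x_px[1], init$y_px[1], np)
  if (is.null(gp)) {
    out <- new_liposome_fits(as.data.frame(init))
    out$converged <- FALSE
    return(out)
  }
  I <- gp$patch
  h <- ctf_grid(ctf, np, np)
  cx0 <- init$x_px[1] - gp$x0
  cy0 <- init$y_px[1] - gp$y0
  bound_hit <- FALSE
  eval_fit <- function(par, return_all = FALSE) {
    cx <- cx0 + par[1]; cy <- cy0 + par[2]; R <- R0 + par[3]
    if (R < radius_bounds[1] || R > radius_bounds[2] ||
        cx < 2 || cy < 2 || cx > np - 3 || cy > np - 3)
      return(if (return_all) NULL else 1e30 + abs(R))
    if (R + ext > min(cx, cy, np - 1 - cx, np - 1 - cy) * px)
      return(if (return_all) NULL else 1e30 + R)
    m <- project_sphere_profile(profile, R, px, c(np, np),
                                center = c(cx, cy))
    mc <- Re(ifft2(fft2(m) * h))
    rg <- radius_grid(np, np, cx, cy) * px
    w <- abs(rg - R) <= annulus_A
    if (!is.null(exclude_px) && nrow(exclude_px) > 0) {
      for (k in seq_len(nrow(exclude_px))) {
        d2 <- (radius_grid(np, np, exclude_px$x_px[k] - gp$x0,
                           exclude_px$y_px[k] - gp$y0))
        w <- w & (d2 > exclude_px$r_px[k])
      }
    }
    iv <- I[w]; mv <- mc[w]; n <- length(iv)
    if (n < 50) return(if (return_all) NULL else 1e30)
    sm <- sum(mv); si <- sum(iv); smm <- sum(mv^2); smi <- sum(mv * iv)
    det <- n * smm - sm^2
    if (det <= 0) return(if (return_all) NULL else 1e30)
    a <- (n * smi - sm * si) / det
    # during optimization the membrane amplitude is constrained >= 0 (an
    # unconstrained solve admits spurious anticorrelated minima with the
    # model half a CTF fringe off the true radius); the reported final
    # amplitude is the plain LS estimate, unbiased around 0 on blank
    # regions
    a_use <- if (a < 0 && !return_all) 0 else a
    b <- (si - a_use * sm) / n
    rss <- sum((iv - a_use * mv - b)^2)
    if (return_all) {
      # t statistic of the amplitude against the no-membrane null
      se_a <- sqrt(rss / (n - 2) * n / det)
      list(a = a, b = b, rss = rss, n = n, amp_t = a / se_a)
    } else rss
  }
  opt <- stats::optim(c(0, 0, 0), eval_fit, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6,
                                     parscale = c(2, 2, 6)))
  fin <- eval_fit(opt$par, return_all = TRUE)
  # convergence code 1 (iteration cap) still yields a usable best iterate;
  # only simplex degeneracy (10) or bound-hitting marks the fit unusable
  conv <- !is.null(fin) && opt$convergence %in% c(0L, 1L) &&
    R0 + opt$par[3] > radius_bounds[1] + 1e-6 &&
    R0 + opt$par[3] < radius_bounds[2] - 1e-6
  out <- data.frame(
    id = init$id[1] %||% 1L,
    x_px = cx0 + opt$par[1] + gp$x0,
    y_px = cy0 + opt$par[2] + gp$y0,
    radius_A = R0 + opt$par[3],
    amplitude = if (is.null(fin)) NA_real_ else fin$a,
    background = if (is.null(fin)) NA_real_ else fin$b,
    residual_rms = if (is.null(fin)) NA_real_ else sqrt(fin$rss / fin$n),
    converged = conv,
    score = init$score[1] %||% NA_real_)
  out$amp_t <- if (is.null(fin)) NA_real_ else fin$amp_t
  new_liposome_fits(out)
}

#' Detect and refine all liposomes in a micrograph
#'
#' Convenience wrapper: [detect_liposomes()] followed by [fit_liposome()]
#' on every candidate.
#'
#' @inheritParams detect_liposomes
#' @param amp_t_min candidates whose fitted membrane amplitude is not
#'   significantly positive (t below this) are discarded as spurious
#'   detections.
#' @param ... passed to [fit_liposome()].
#' @return a `liposome_fits` data frame.
#' @export
fit_liposomes <- function(micro, ctf = micro$ctf, radius_range = c(75, 350),
                          threshold = "auto", profile = bilayer_profile(),
                          amp_t_min = 5, ...) {
  init <- detect_liposomes(micro, ctf, radius_range, threshold = threshold,
                           profile = profile)
  if (nrow(init) == 0) return(init)
  # two-stage refinement: converge on a 2x-binned copy first, then a short
  # full-resolution polish
  micro_b <- micrograph(fourier_bin(micro$data, 2), micro$pixel_size * 2)
  ctf_b <- ctf; ctf_b$pixel_size <- ctf$pixel_size * 2
  out <- do.call(rbind, lapply(seq_len(nrow(init)), function(i) {
    ib <- init[i, ]
    ib$x_px <- ib$x_px / 2; ib$y_px <- ib$y_px / 2
    fb <- fit_liposome(micro_b, ib, ctf_b, profile, maxit = 150, ...)
    ib2 <- init[i, ]
    ib2$x_px <- fb$x_px * 2; ib2$y_px <- fb$y_px * 2
    ib2$radius_A <- fb$radius_A
    fit_liposome(micro, ib2, ctf, profile, maxit = 50, ...)
  }))
  keep <- is.finite(out$amp_t) & out$amp_t > amp_t_min & out$amplitude > 0
  out <- out[keep, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  new_liposome_fits(out)
}

#' Subtract fitted liposome membranes from a micrograph
#'
#' Renders the sum of all converged fitted spherical-bilayer models,
#' convolves once with the CTF on the full field (matching the imaging
#' model), scales each by its fitted amplitude and subtracts. The local
#' background offsets belong to the image and are not removed. Particle
#' densities are untouched by construction (the model contains membrane
#' only).
#'
#' @param micro a [micrograph()].
#' @param fits a `liposome_fits` data frame; non-converged fits are
#'   ignored with a warning.
#' @param ctf a [ctf_params()].
#' @param profile a [bilayer_profile()].
#' @return a [micrograph()] with the membrane model subtracted; attribute
#'   `overlap` is TRUE when any two fitted circles overlap.
#' @export
subtract_liposomes <- function(micro, fits, ctf = micro$ctf,
                               profile = bilayer_profile()) {
  if (is.null(ctf)) stop("ctf required")
  use <- fits[fits$converged %in% TRUE, , drop = FALSE]
  if (nrow(use) < nrow(fits))
    warning(nrow(fits) - nrow(use), " non-converged fit(s) not subtracted")
  model <- matrix(0, nrow(micro$data), ncol(micro$data))
  px <- micro$pixel_size
  for (i in seq_len(nrow(use))) {
    model <- model + use$amplitude[i] *
      project_sphere_profile(profile, use$radius_A[i], px,
                             dim(micro$data),
                             center = c(use$x_px[i], use$y_px[i]))
  }
  overlap <- FALSE
  if (nrow(use) > 1) {
    dm <- as.matrix(stats::dist(cbind(use$x_px, use$y_px))) * px
    rs <- outer(use$radius_A, use$radius_A, `+`)
    diag(dm) <- Inf
    overlap <- any(dm < rs)
  }
  out <- micro
  out$data <- micro$data - apply_ctf(model, ctf)
  attr(out, "overlap") <- overlap
  attr(out, "subtracted") <- TRUE
  out
}
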