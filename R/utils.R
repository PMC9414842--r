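# Internal numerical helpers: FFT layout conventions, interpolation,
# normalized cross-correlation, seeded RNG.
#
# Conventions used throughout the package:
#  * real-space grids are 1-based R arrays with the object centre at index
#    n/2 + 1 along each (even-length) dimension;
#  * "centered" Fourier grids are fftshift-ed so the zero-frequency voxel
#    also sits at n/2 + 1; voxel offset u at index i is u = i - (n/2 + 1),
#    physical frequency = u / (n * pixel_size) in 1/Angstrom;
#  * pixel coordinates exposed to users are 0-based (index i holds pixel
#    i - 1), physical Angstrom coordinate = pixel * pixel_size.

#' Run an expression with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package internals never disturb user code.
#'
#' @param seed integer seed, or NULL to run without touching the RNG.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from one root seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

even_check <- function(n) {
  if (any(n %% 2L != 0L)) stop("grid dimensions must be even")
  invisible(n)
}

# Centre index of an even-length axis.
ctr <- function(n) n %/% 2L + 1L

# fftshift / ifftshift (identical for even n, which this package requires).
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  even_check(d)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}
ifftshift <- fftshift

# Signed voxel offsets of a centered axis: -n/2 .. n/2 - 1.
centered_offsets <- function(n) seq_len(n) - ctr(n)

# Frequencies (1/A) of an unshifted FFT axis.
fft_freq <- function(n, pixel_size) {
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pixel_size)
  f
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Centered 2D/3D FFT of a real array with the object centre at ctr(n):
# Fc[u] corresponds to frequency u/(n*px), u = centered_offsets(n).
cfft <- function(x) fftshift(stats::fft(ifftshift(x)))
icfft <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)

# Radius grid (in pixels) from a subpixel centre, 0-based. Package axis
# convention: matrix dim 1 is x, dim 2 is y, so cx indexes rows and cy
# columns.
radius_grid <- function(n1, n2, cx, cy) {
  dx <- (seq_len(n1) - 1) - cx
  dy <- (seq_len(n2) - 1) - cy
  sqrt(outer(dx^2, dy^2, `+`))
}

# Bilinear interpolation of matrix z at (row, col) positions given in
# 1-based fractional indices; outside values -> fill.
interp2 <- function(z, ri, ci, fill = 0) {
  nr <- nrow(z); nc <- ncol(z)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  out <- rep(fill, length(ri))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- r0k + (c0k - 1) * nr
    out[ok] <- z[i00] * (1 - frk) * (1 - fck) +
      z[i00 + 1] * frk * (1 - fck) +
      z[i00 + nr] * (1 - frk) * fck +
      z[i00 + nr + 1] * frk * fck
  }
  out
}

# Trilinear interpolation of a 3D array at fractional 1-based indices
# (matrix pts: 3 x m rows i, j, k). Outside -> 0. Works for complex arrays
# split into re/im by the caller.
interp3 <- function(a, pts) {
  d <- dim(a)
  i0 <- floor(pts[1, ]); j0 <- floor(pts[2, ]); k0 <- floor(pts[3, ])
  fi <- pts[1, ] - i0; fj <- pts[2, ] - j0; fk <- pts[3, ] - k0
  ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 &
    i0 <= d[1] - 1 & j0 <= d[2] - 1 & k0 <= d[3] - 1
  out <- numeric(ncol(pts))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; k0k <- k0[ok]
    fik <- fi[ok]; fjk <- fj[ok]; fkk <- fk[ok]
    base <- i0k + (j0k - 1) * d[1] + (k0k - 1) * d[1] * d[2]
    sj <- d[1]; sk <- d[1] * d[2]
    out[ok] <-
      a[base]               * (1 - fik) * (1 - fjk) * (1 - fkk) +
      a[base + 1]           * fik       * (1 - fjk) * (1 - fkk) +
      a[base + sj]          * (1 - fik) * fjk       * (1 - fkk) +
      a[base + sj + 1]      * fik       * fjk       * (1 - fkk) +
      a[base + sk]          * (1 - fik) * (1 - fjk) * fkk +
      a[base + sk + 1]      * fik       * (1 - fjk) * fkk +
      a[base + sk + sj]     * (1 - fik) * fjk       * fkk +
      a[base + sk + sj + 1] * fik       * fjk       * fkk
  }
  out
}

# Scatter-add values v (and weights) into a 3D accumulator with trilinear
# spreading at fractional 1-based indices. Returns list(idx, w) of the 8
# corner contributions so the caller can accumulate several arrays at once.
trilinear_spread <- function(pts, dims) {
  i0 <- floor(pts[1, ]); j0 <- floor(pts[2, ]); k0 <- floor(pts[3, ])
  fi <- pts[1, ] - i0; fj <- pts[2, ] - j0; fk <- pts[3, ] - k0
  ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 &
    i0 <= dims[1] - 1 & j0 <= dims[2] - 1 & k0 <= dims[3] - 1
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  sj <- dims[1]; sk <- dims[1] * dims[2]
  base <- i0 + (j0 - 1) * sj + (k0 - 1) * sk
  idx <- c(base, base + 1, base + sj, base + sj + 1,
           base + sk, base + sk + 1, base + sk + sj, base + sk + sj + 1)
  w <- c((1 - fi) * (1 - fj) * (1 - fk), fi * (1 - fj) * (1 - fk),
         (1 - fi) * fj * (1 - fk),       fi * fj * (1 - fk),
         (1 - fi) * (1 - fj) * fk,       fi * (1 - fj) * fk,
         (1 - fi) * fj * fk,             fi * fj * fk)
  list(idx = idx, w = w, keep = ok)
}

# Sum w (or w*v) into a length-n accumulator, handling repeated indices.
accumulate_at <- function(acc, idx, val) {
  s <- rowsum(val, idx, reorder = FALSE)
  at <- as.integer(rownames(s))
  acc[at] <- acc[at] + s[, 1]
  acc
}

# ZYZ rotation matrix: A = Rz(psi) %*% Ry(tilt) %*% Rz(rot), angles in
# degrees. A maps particle-frame vectors into the lab frame; the particle
# z-axis (membrane normal) lands at
# (sin tilt cos psi, sin tilt sin psi, cos tilt).
rot_zyz <- function(rot, tilt, psi) {
  r <- rot * pi / 180; t <- tilt * pi / 180; p <- psi * pi / 180
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rz(p) %*% Ry(t) %*% Rz(r)
}

# FFT-based normalized cross-correlation of an image with a small centered
# template. Returns a matrix of NCC scores the size of the image; the score
# at (i, j) corresponds to the template centred on pixel (i, j). The image
# is locally standardized over the template support.
ncc_map <- function(image, template) {
  ny <- nrow(image); nx <- ncol(image)
  th <- nrow(template); tw <- ncol(template)
  if (th > ny || tw > nx) stop("template larger than image")
  t0 <- template - mean(template)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm == 0) stop("template has zero variance")
  # embed template (and ones mask) centred on the origin pixel (1,1) with wrap
  ker <- matrix(0, ny, nx); msk <- matrix(0, ny, nx)
  ri <- ((-(ctr(th) - 1)):(th - ctr(th))) %% ny + 1
  ci <- ((-(ctr(tw) - 1)):(tw - ctr(tw))) %% nx + 1
  ker[ri, ci] <- t0
  msk[ri, ci] <- 1
  n_t <- th * tw
  Fi <- fft2(image)
  num <- Re(ifft2(Fi * Conj(fft2(ker))))
  s1 <- Re(ifft2(Fi * Conj(fft2(msk))))
  s2 <- Re(ifft2(fft2(image^2) * Conj(fft2(msk))))
  lvar <- pmax(s2 - s1^2 / n_t, 0)
  denom <- sqrt(lvar) * tnorm
  out <- num / pmax(denom, .Machine$double.eps)
  out[denom < 1e-10 * tnorm] <- 0
  out
}

# Max-over-templates NCC: like ncc_map but amortizes the image FFT and
# local-statistics transforms across many same-sized templates.
ncc_map_multi <- function(image, templates) {
  ny <- nrow(image); nx <- ncol(image)
  th <- nrow(templates[[1]]); tw <- ncol(templates[[1]])
  if (th > ny || tw > nx) stop("template larger than image")
  ri <- ((-(ctr(th) - 1)):(th - ctr(th))) %% ny + 1
  ci <- ((-(ctr(tw) - 1)):(tw - ctr(tw))) %% nx + 1
  msk <- matrix(0, ny, nx); msk[ri, ci] <- 1
  n_t <- th * tw
  Fi <- fft2(image)
  Fm <- Conj(fft2(msk))
  s1 <- Re(ifft2(Fi * Fm))
  s2 <- Re(ifft2(fft2(image^2) * Fm))
  lvar <- pmax(s2 - s1^2 / n_t, 0)
  denom0 <- sqrt(lvar)
  best <- matrix(-Inf, ny, nx)
  for (tm in templates) {
    t0 <- tm - mean(tm)
    tnorm <- sqrt(sum(t0^2))
    if (tnorm == 0) next
    ker <- matrix(0, ny, nx); ker[ri, ci] <- t0
    num <- Re(ifft2(Fi * Conj(fft2(ker))))
    sc <- num / pmax(denom0 * tnorm, .Machine$double.eps)
    sc[denom0 < 1e-10] <- 0
    best <- pmax(best, sc)
  }
  best
}

# Greedy non-maximum suppression on a score map: returns 0-based (x, y)
# pixel coordinates (x = dim 1, y = dim 2 per package convention) and
# scores of accepted local maxima above `threshold`, no two closer than
# `min_dist` pixels. `exclude_border` trims edges.
find_peaks <- function(score, threshold, min_dist, exclude_border = 0) {
  n1 <- nrow(score); n2 <- ncol(score)
  cand <- which(score > threshold)
  if (exclude_border > 0) {
    i1 <- (cand - 1) %% n1 + 1
    i2 <- (cand - 1) %/% n1 + 1
    keep <- i1 > exclude_border & i1 <= n1 - exclude_border &
      i2 > exclude_border & i2 <= n2 - exclude_border
    cand <- cand[keep]
  }
  if (length(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  cand <- cand[order(score[cand], decreasing = TRUE)]
  px <- (cand - 1) %% n1
  py <- (cand - 1) %/% n1
  sc <- score[cand]
  acc_x <- numeric(0); acc_y <- numeric(0); acc_s <- numeric(0)
  for (i in seq_along(cand)) {
    if (length(acc_x) == 0 ||
        all((acc_x - px[i])^2 + (acc_y - py[i])^2 >= min_dist^2)) {
      acc_x <- c(acc_x, px[i]); acc_y <- c(acc_y, py[i]); acc_s <- c(acc_s, sc[i])
    }
  }
  data.frame(x = acc_x, y = acc_y, score = acc_s)
}

# Robust scale (MAD about 0-ish median) of a score map, for auto thresholds.
score_mad <- function(score) stats::mad(score, center = stats::median(score))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Next even 5-smooth integer >= n (mixed-radix FFTs degrade badly on
# sizes with large prime factors).
good_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  n <- n + n %% 2L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}
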