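# 3D density maps: container, tetrameric channel phantom, Fourier-slice
# projection, rotation about z, Fourier cropping (binning).

#' 3D density map
#'
#' A cubic, even-edged voxel grid with a physical pixel size, the unit for
#' simulation references, reconstruction, symmetry scoring and FSC.
#'
#' @param data 3D numeric array, cubic with even edge length.
#' @param pixel_size voxel edge (A).
#' @param symmetry symmetry label, e.g. "C1", "C2", "C4".
#' @return object of class `density_map`.
#' @export
density_map <- function(data, pixel_size, symmetry = "C1") {
  d <- dim(data)
  if (length(d) != 3 || length(unique(d)) != 1) stop("map must be a cubic 3D array")
  even_check(d)
  stopifnot(pixel_size > 0)
  structure(list(data = data, pixel_size = pixel_size, symmetry = symmetry),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Density map %dx%dx%d, %.3f A/voxel (%s), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$pixel_size, x$symmetry,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Tetrameric channel phantom
#'
#' Builds a synthetic tetrameric ion-channel-like density: four subunits
#' arranged with C4 geometry about z, each composed of a large intracellular
#' (gating-ring-like) blob, a mid blob and a smaller transmembrane blob.
#' `c2_shift` displaces two opposing subunits axially by that many Angstrom,
#' breaking C4 down to C2 — the geometry used to study symmetry breaking
#' (a ~5 A inter-subunit displacement of the shoulder region).
#'
#' @param n cubic edge length in voxels (even).
#' @param pixel_size voxel size (A).
#' @param c2_shift axial displacement (A) applied to subunits 1 and 3.
#' @param amplitude peak density of the largest blob (contrast units).
#' @return a [density_map()].
#' @export
make_channel_phantom <- function(n = 64, pixel_size = 4.2, c2_shift = 0,
                                 amplitude = 1) {
  even_check(n)
  # blobs per subunit: (radial offset A, z A, sigma A, relative amp).
  # widths chosen so a ~5 A inter-subunit displacement is resolvable at
  # the default simulation scale (Nyquist ~8 A after 2x binning)
  blobs <- rbind(
    c(30, -42, 7, 1.0),   # gating-ring lobe
    c(36, -14, 6, 0.8),   # shoulder lobe
    c(16,  22, 7, 0.7)    # TM lobe
  )
  cc <- ctr(n)
  ax <- (seq_len(n) - cc) * pixel_size
  vol <- array(0, c(n, n, n))
  g1 <- function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2))
  for (sub in 0:3) {
    ang <- sub * pi / 2
    dz_sub <- if (sub %% 2 == 0) c2_shift else 0
    for (b in seq_len(nrow(blobs))) {
      r0 <- blobs[b, 1]; z0 <- blobs[b, 2] + dz_sub
      s <- blobs[b, 3]; a <- blobs[b, 4] * amplitude
      x0 <- r0 * cos(ang + 0.35); y0 <- r0 * sin(ang + 0.35)
      gx <- g1(ax, x0, s); gy <- g1(ax, y0, s); gz <- g1(ax, z0, s)
      vol <- vol + a * (gx %o% gy %o% gz)
    }
  }
  density_map(vol, pixel_size, if (c2_shift != 0) "C2" else "C4")
}

# Centered complex FFT of a map (cached layout for slice extraction).
map_cfft <- function(map) {
  Fc <- cfft(map$data)
  list(re = Re(Fc), im = Im(Fc), n = dim(map$data)[1],
       pixel_size = map$pixel_size)
}

# Slice coordinates: for image frequency offsets (ux, uy) build the 3D
# fractional 1-based indices at t(A) %*% (ux, uy, 0) + centre.
slice_indices <- function(n, A) {
  u <- centered_offsets(n)
  ux <- rep(u, times = n)
  uy <- rep(u, each = n)
  P <- t(A) %*% rbind(ux, uy, 0)
  P + ctr(n)
}

#' Project a density map at given Euler angles
#'
#' Computes the 2D projection of the map after rotating it by ZYZ Euler
#' angles (`rot` about z, then `tilt` about y, then `psi` about z; degrees),
#' integrating along the beam (z). Implemented by central-slice extraction
#' with trilinear interpolation in Fourier space. The returned image is the
#' physical line integral (density x A).
#'
#' @param map a [density_map()] or a cached transform from `map_cfft`.
#' @param rot,tilt,psi Euler angles in degrees.
#' @return `n x n` matrix.
#' @export
project_map <- function(map, rot, tilt, psi) {
  ft <- if (inherits(map, "density_map")) map_cfft(map) else map
  n <- ft$n
  A <- rot_zyz(rot, tilt, psi)
  pts <- slice_indices(n, A)
  sr <- interp3(ft$re, pts)
  si <- interp3(ft$im, pts)
  Fsl <- matrix(complex(real = sr, imaginary = si), n, n)
  Re(icfft(Fsl)) * ft$pixel_size
}

# Fourier-space central slice (centered layout) at angles; returns complex
# n x n matrix. Used by orientation assignment and backprojection.
project_map_f <- function(ft, rot, tilt, psi) {
  n <- ft$n
  pts <- slice_indices(n, rot_zyz(rot, tilt, psi))
  matrix(complex(real = interp3(ft$re, pts), imaginary = interp3(ft$im, pts)),
         n, n)
}

#' Rotate a map about the z axis
#'
#' Real-space rotation by `angle` degrees (counter-clockwise in the xy
#' plane) about the map centre, by bilinear resampling of each z slice.
#'
#' @param map a [density_map()].
#' @param angle rotation angle in degrees.
#' @return a [density_map()].
#' @export
rotate_map_z <- function(map, angle) {
  a <- angle * pi / 180
  n <- dim(map$data)[1]
  cc <- ctr(n)
  u <- seq_len(n) - cc
  # dims: data[ix, iy, iz]; x = ix - cc, y = iy - cc
  x <- rep(u, times = n)   # ix fast
  y <- rep(u, each = n)
  # source coords = inverse rotation of target coords
  xs <- cos(a) * x + sin(a) * y
  ys <- -sin(a) * x + cos(a) * y
  ri <- xs + cc; ci <- ys + cc
  out <- array(0, dim(map$data))
  for (k in seq_len(n)) {
    out[, , k] <- matrix(interp2(map$data[, , k], ri, ci), n, n)
  }
  density_map(out, map$pixel_size, map$symmetry)
}

#' Impose Cn rotational symmetry about z
#'
#' Averages the map over the n rotations of the cyclic group Cn.
#'
#' @param map a [density_map()].
#' @param n_fold symmetry order (1, 2, 4, ...).
#' @return a [density_map()] with the symmetry label updated.
#' @export
symmetrize_map <- function(map, n_fold) {
  stopifnot(n_fold >= 1)
  if (n_fold == 1) return(map)
  acc <- map$data
  for (k in seq_len(n_fold - 1)) {
    acc <- acc + rotate_map_z(map, 360 * k / n_fold)$data
  }
  density_map(acc / n_fold, map$pixel_size, paste0("C", n_fold))
}

#' Low-pass filter a map
#'
#' Attenuates Fourier components beyond `resolution_A` with a raised-cosine
#' edge (width `edge_frac` of the cutoff frequency). Reconstructions are
#' conventionally filtered to their measured FSC resolution before display
#' or comparison, since beyond it the map is noise by definition.
#'
#' @param map a [density_map()].
#' @param resolution_A cutoff resolution (A).
#' @param edge_frac soft-edge width as a fraction of the cutoff frequency.
#' @return a [density_map()].
#' @export
lowpass_map <- function(map, resolution_A, edge_frac = 0.2) {
  n <- dim(map$data)[1]
  px <- map$pixel_size
  kc <- 1 / resolution_A
  u <- centered_offsets(n) / (n * px)
  kr <- sqrt(outer(outer(u^2, u^2, `+`), u^2, `+`))
  w <- kc * edge_frac
  filt <- 0.5 - 0.5 * cos(pi * pmin(pmax((kc + w - kr) / w, 0), 1))
  Fc <- cfft(map$data) * filt
  density_map(Re(icfft(Fc)), px, map$symmetry)
}

#' Fourier-crop (bin) a map or image stack
#'
#' Downsamples by an integer factor by cropping the centered Fourier
#' transform, which preserves all information below the new Nyquist limit.
#'
#' @param x a [density_map()] or a matrix (single image).
#' @param factor integer binning factor; new edge = n / factor (must be even).
#' @param pixel_size required when `x` is a matrix.
#' @return same type as `x`, with pixel size multiplied by `factor`.
#' @export
fourier_bin <- function(x, factor, pixel_size = NULL) {
  if (factor == 1) return(x)
  crop <- function(Fc, n, m) {
    lo <- ctr(n) - m / 2; hi <- ctr(n) + m / 2 - 1
    if (length(dim(Fc)) == 3) Fc[lo:hi, lo:hi, lo:hi] else Fc[lo:hi, lo:hi]
  }
  if (inherits(x, "density_map")) {
    n <- dim(x$data)[1]; m <- n / factor
    even_check(m)
    Fc <- crop(cfft(x$data), n, m)
    density_map(Re(icfft(Fc)) / factor^3, x$pixel_size * factor, x$symmetry)
  } else {
    n <- nrow(x); m <- n / factor
    even_check(m)
    Fc <- crop(cfft(x), n, m)
    Re(icfft(Fc)) / factor^2
  }
}
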