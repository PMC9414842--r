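# Contrast transfer function: forward model used both to simulate
# micrographs and to convolve the liposome model during fitting.

#' Contrast transfer function parameters
#'
#' Microscope/imaging parameters for the standard phase + amplitude CTF.
#' Underfocus is positive (CTFFIND/RELION sign convention), so at zero
#' frequency `CTF(0) = -amplitude_contrast`.
#'
#' @param defocus_um defocus in micrometres, underfocus positive
#'   (default 3.8, i.e. the -3.8 um underfocus regime where membranes show
#'   strong fringes).
#' @param voltage_kv acceleration voltage in kV.
#' @param cs_mm spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in [0, 1].
#' @param pixel_size pixel size in Angstrom.
#' @return an object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_um = 3.8, voltage_kv = 300, cs_mm = 2.7,
                       amplitude_contrast = 0.07, pixel_size = 2.1) {
  stopifnot(pixel_size > 0, amplitude_contrast >= 0, amplitude_contrast <= 1,
            voltage_kv > 0)
  structure(list(defocus_um = defocus_um, voltage_kv = voltage_kv,
                 cs_mm = cs_mm, amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(
    "CTF: defocus %.2f um (underfocus+), %g kV, Cs %.2f mm, w %.2f, px %.3f A\n",
    x$defocus_um, x$voltage_kv, x$cs_mm, x$amplitude_contrast, x$pixel_size))
  invisible(x)
}

# Relativistic electron wavelength in Angstrom.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF at spatial frequencies
#'
#' `CTF(f) = -(sqrt(1 - w^2) sin(chi) + w cos(chi))` with the standard
#' defocus/spherical-aberration phase
#' `chi(f) = pi lambda z f^2 - (pi/2) Cs lambda^3 f^4`
#' (z underfocus-positive, in Angstrom).
#'
#' @param ctf a [ctf_params()].
#' @param freq spatial frequency (1/A), any shape.
#' @return CTF values, same shape as `freq`.
#' @export
ctf_eval <- function(ctf, freq) {
  lambda <- electron_wavelength(ctf$voltage_kv)
  z <- ctf$defocus_um * 1e4            # A
  cs <- ctf$cs_mm * 1e7                # A
  w <- ctf$amplitude_contrast
  chi <- pi * lambda * z * freq^2 - (pi / 2) * cs * lambda^3 * freq^4
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

# CTF on the unshifted FFT frequency grid of an ny x nx image.
ctf_grid <- function(ctf, ny, nx) {
  fy <- fft_freq(ny, ctf$pixel_size)
  fx <- fft_freq(nx, ctf$pixel_size)
  ctf_eval(ctf, sqrt(outer(fy^2, fx^2, `+`)))
}

#' Apply the CTF to an image
#'
#' Multiplies the image's Fourier transform by the CTF and returns the real
#' part. A linear operator: superposition holds to numerical precision.
#'
#' @param image real-valued matrix.
#' @param ctf a [ctf_params()]; its `pixel_size` must be set.
#' @return matrix of the same shape.
#' @export
apply_ctf <- function(image, ctf) {
  if (is.null(ctf$pixel_size) || !is.finite(ctf$pixel_size))
    stop("ctf pixel_size missing")
  if (!is.numeric(image) || !is.matrix(image)) stop("image must be a real matrix")
  h <- ctf_grid(ctf, nrow(image), ncol(image))
  Re(ifft2(fft2(image) * h))
}

# Inverse filter restricted to |CTF| > min_amp (used in tests as the
# round-trip oracle and nowhere in the analysis path).
unapply_ctf <- function(image, ctf, min_amp = 0.1) {
  h <- ctf_grid(ctf, nrow(image), ncol(image))
  hi <- ifelse(abs(h) > min_amp, 1 / h, 0)
  Re(ifft2(fft2(image) * hi))
}
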