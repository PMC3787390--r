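#' Point-spread-function model
#'
#' Radially symmetric lateral PSF: `"lorentzian"` (the effective STED focal
#' spot, heavy-tailed) or `"gaussian"` (confocal). `fwhm` is the full width at
#' half maximum in nm; the rendered kernel is truncated at `support_radius`
#' and renormalized, so the truncation must be explicit — Lorentzian tails
#' carry non-negligible mass.
#'
#' @param model `"lorentzian"` or `"gaussian"`.
#' @param fwhm full width at half maximum in nm (> 0). Default 80, the
#'   effective STED resolution this package simulates.
#' @param support_radius kernel truncation radius in nm (>= 3 * fwhm;
#'   default 4 * fwhm).
#' @return object of class `psf_spec`.
#' @export
psf_spec <- function(model = c("lorentzian", "gaussian"), fwhm = 80,
                     support_radius = 4 * fwhm) {
  model <- match.arg(model)
  stopifnot_scalar_num(fwhm, "fwhm", 0, strict = TRUE)
  stopifnot_scalar_num(support_radius, "support_radius", 0, strict = TRUE)
  if (support_radius < 3 * fwhm)
    stop("`support_radius` must be >= 3 * fwhm", call. = FALSE)
  structure(list(model = model, fwhm = fwhm, support_radius = support_radius),
            class = "psf_spec")
}

# unnormalized radial profile at radius r (nm) for unit fwhm peak
psf_profile <- function(model, r, fwhm) {
  if (model == "lorentzian") 1 / (1 + (2 * r / fwhm)^2)
  else exp(-4 * log(2) * r^2 / fwhm^2)
}

#' Render a PSF kernel on a pixel grid
#'
#' Evaluates the radial profile at pixel centers on an odd-sized square grid
#' covering +/- `support_radius`, then normalizes the truncated kernel to unit
#' sum. Lorentzian: `k(r) = A / (1 + (2 r / fwhm)^2)`; Gaussian:
#' `k(r) = A exp(-4 ln 2 r^2 / fwhm^2)`.
#'
#' @param spec a [psf_spec()].
#' @param pixel_size pixel edge in nm (> 0).
#' @return an [image2d()] kernel summing to 1.
#' @examples
#' k <- make_psf(psf_spec("lorentzian", 80), pixel_size = 5)
#' sum(k$values)
#' @export
make_psf <- function(spec, pixel_size) {
  stopifnot(inherits(spec, "psf_spec"))
  stopifnot_scalar_num(pixel_size, "pixel_size", 0, strict = TRUE)
  half <- ceiling(spec$support_radius / pixel_size)
  coords <- (-half:half) * pixel_size   # odd-sized, center pixel at r = 0
  r <- sqrt(outer(coords^2, coords^2, "+"))
  k <- psf_profile(spec$model, r, spec$fwhm)
  k[r > spec$support_radius] <- 0
  image2d(k / sum(k), pixel_size)
}

#' Poisson noise parameters
#'
#' Detected counts are `Poisson(signal_scale * expected + background_rate)`
#' per pixel. Defaults give peak signal-to-noise around 10 for the standard
#' simulated structures, comparable to published STED images of labeled
#' carriers.
#'
#' @param signal_scale expected counts per unit of projected label intensity
#'   (>= 0; default 50).
#' @param background_rate expected background counts per pixel (>= 0;
#'   default 5).
#' @param seed integer RNG seed, or NULL.
#' @return object of class `noise_params`.
#' @export
noise_params <- function(signal_scale = 50, background_rate = 5, seed = NULL) {
  stopifnot_scalar_num(signal_scale, "signal_scale", 0)
  stopifnot_scalar_num(background_rate, "background_rate", 0)
  structure(list(signal_scale = signal_scale, background_rate = background_rate,
                 seed = seed), class = "noise_params")
}

# 2D linear convolution with zero padding, central crop to the image size.
# Kernel must be odd-sized so the output is centered.
conv2_zero <- function(img, ker) {
  mi <- nrow(img); ni <- ncol(img)
  mk <- nrow(ker); nk <- ncol(ker)
  if (mk %% 2 == 0 || nk %% 2 == 0)
    stop("kernel must be odd-sized", call. = FALSE)
  M <- mi + mk - 1L; N <- ni + nk - 1L
  A <- matrix(0, M, N); A[1:mi, 1:ni] <- img
  B <- matrix(0, M, N); B[1:mk, 1:nk] <- ker
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (M * N)
  off <- c((mk - 1L) %/% 2L, (nk - 1L) %/% 2L)
  out <- full[off[1] + (1:mi), off[2] + (1:ni)]
  out[out < 0] <- 0   # clip FFT round-off
  out
}

#' Simulate the optical image of a projected structure
#'
#' Convolves a projected label-density image with the PSF (zero-padded
#' boundaries) and, if noise parameters are given, draws Poisson counts with
#' mean `signal_scale * (img (*) psf) + background_rate` per pixel. With
#' `noise = NULL` the noise-free expectation image (without background) is
#' returned.
#'
#' @param img an [image2d()] of projected label density.
#' @param psf a [psf_spec()].
#' @param noise a [noise_params()] or NULL for the noise-free expectation.
#' @return an [image2d()]; counts (integers) when noise is applied.
#' @export
image_structure <- function(img, psf, noise = NULL) {
  stopifnot(inherits(img, "image2d"), inherits(psf, "psf_spec"))
  ker <- make_psf(psf, img$pixel_size)
  blurred <- conv2_zero(img$values, ker$values)
  if (is.null(noise)) return(image2d(blurred, img$pixel_size))
  stopifnot(inherits(noise, "noise_params"))
  lambda <- noise$signal_scale * blurred + noise$background_rate
  counts <- with_seed(noise$seed,
                      stats::rpois(length(lambda), lambda))
  image2d(matrix(counts, nrow(lambda), ncol(lambda)), img$pixel_size)
}
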