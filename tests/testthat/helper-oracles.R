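# independent brute-force oracles used across the suite

# scalar-loop shell rasterization: voxel centers within `shell` nm of the
# structure surface; written independently of the package's vectorized path
oracle_shell <- function(spec, n, voxel, rot = diag(3)) {
  out <- array(0, c(n, n, n))
  coords <- ((seq_len(n) - 0.5) - n / 2) * voxel
  r <- spec$diameter / 2
  h <- if (spec$shape == "tubule") (spec$length - spec$diameter) / 2 else 0
  ax <- as.vector(rot %*% c(0, 0, 1))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    p <- c(coords[i], coords[j], coords[k])
    if (spec$shape == "vesicle") {
      d <- abs(sqrt(sum(p^2)) - r)
    } else {
      t <- sum(p * ax)
      t <- max(min(t, h), -h)
      d <- abs(sqrt(sum((p - t * ax)^2)) - r)
    }
    if (d <= spec$shell_halfwidth) out[i, j, k] <- 1
  }
  out
}

# Monte-Carlo oracle for the background-threshold statistic: mean + sd of the
# maximum of `npix` iid Poisson(rate) draws
oracle_cutoff_poisson <- function(rate, npix, nmax = 4000) {
  maxima <- replicate(nmax, max(rpois(npix, rate)))
  c(mean = mean(maxima), sd = sd(maxima))
}

# direct evaluation of the elliptical spot profile used as a fixture builder
render_elliptical_spot <- function(n, px, fwhm_major, fwhm_minor, theta,
                                   amplitude, offset,
                                   model = c("lorentzian", "gaussian"),
                                   center = c(0, 0)) {
  model <- match.arg(model)
  co <- ((seq_len(n) - 0.5) - n / 2) * px
  X <- matrix(co, n, n) - center[1]
  Y <- matrix(co, n, n, byrow = TRUE) - center[2]
  u <- (X * cos(theta) + Y * sin(theta)) / fwhm_major
  v <- (-X * sin(theta) + Y * cos(theta)) / fwhm_minor
  q2 <- u^2 + v^2
  g <- if (model == "lorentzian") 1 / (1 + 4 * q2) else exp(-4 * log(2) * q2)
  image2d(offset + amplitude * g, px)
}

# a minimal converged spot_fit object for testing the scalar summaries
fake_fit <- function(fwhm_major, fwhm_minor, converged = TRUE) {
  structure(list(center = c(x = 0, y = 0), fwhm_major = fwhm_major,
                 fwhm_minor = fwhm_minor, theta = 0, amplitude = 1,
                 offset = 0, converged = converged, residual_norm = 0,
                 model = "lorentzian", pixel_size = 5, crop = NULL),
            class = "spot_fit")
}
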