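test_that("PSF kernels are normalized with the stated half-maximum radius", {
  for (model in c("lorentzian", "gaussian")) {
    k <- make_psf(psf_spec(model, 80), pixel_size = 5)
    expect_equal(sum(k$values), 1, tolerance = 1e-9)
    expect_equal(nrow(k$values) %% 2, 1)  # odd-sized, center pixel at r = 0
    c0 <- (nrow(k$values) + 1) / 2
    # r = 40 nm = 8 px along the center row: half the central value
    expect_equal(k$values[c0 + 8, c0] / k$values[c0, c0], 0.5,
                 tolerance = 1e-9)
  }
})

test_that("the Lorentzian tail is heavier than the Gaussian tail", {
  kl <- make_psf(psf_spec("lorentzian", 80, support_radius = 400), 5)
  kg <- make_psf(psf_spec("gaussian", 80, support_radius = 400), 5)
  c0 <- (nrow(kl$values) + 1) / 2
  off <- 32  # r = 160 nm
  expect_gt(kl$values[c0 + off, c0] / kl$values[c0, c0],
            kg$values[c0 + off, c0] / kg$values[c0, c0])
})

test_that("rendered kernel FWHM matches the spec within one pixel", {
  k <- make_psf(psf_spec("lorentzian", 80), 5)
  c0 <- (nrow(k$values) + 1) / 2
  prof <- k$values[, c0]
  r <- (seq_along(prof) - c0) * 5
  half <- prof[c0] / 2
  right <- which(r > 0 & prof <= half)[1]
  # linear interpolation between the straddling pixels
  x1 <- r[right - 1]; x2 <- r[right]
  y1 <- prof[right - 1]; y2 <- prof[right]
  hwhm <- x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  expect_equal(2 * hwhm, 80, tolerance = 5)
})

test_that("convolving a point source reproduces the kernel", {
  n <- 129
  img <- image2d(matrix(0, n, n), 5)
  img$values[65, 65] <- 7
  out <- image_structure(img, psf_spec("lorentzian", 80, support_radius = 240))
  k <- make_psf(psf_spec("lorentzian", 80, support_radius = 240), 5)
  kn <- nrow(k$values)
  pad <- (n - kn) / 2
  expected <- matrix(0, n, n)
  expected[pad + seq_len(kn), pad + seq_len(kn)] <- 7 * k$values
  expect_lt(max(abs(out$values - expected)) / max(expected), 1e-9)
})

test_that("noise-free convolution of a centered structure conserves intensity", {
  img <- project_grid(render_structure(structure_spec("vesicle", 110),
                                       grid_params(200, 5)))
  out <- image_structure(img, psf_spec("lorentzian", 80))
  expect_gt(sum(out$values) / sum(img$values), 0.99)
  expect_lte(sum(out$values) / sum(img$values), 1 + 1e-9)
})

test_that("Poisson noise is seed-deterministic with the right moments", {
  img <- image2d(matrix(2, 24, 24), 5)
  psf <- psf_spec("lorentzian", 80, support_radius = 240)
  a <- image_structure(img, psf, noise_params(50, 5, seed = 11))
  b <- image_structure(img, psf, noise_params(50, 5, seed = 11))
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, image_structure(img, psf, noise_params(50, 5, seed = 12))$values))

  # flat-field mean and variance/mean ratio across repeats (Poisson check)
  flat <- image2d(matrix(0, 16, 16), 5)  # background only
  reps <- vapply(1:400, function(s)
    image_structure(flat, psf, noise_params(50, 9, seed = 1000 + s))$values[8, 8],
    numeric(1))
  expect_equal(mean(reps), 9, tolerance = 3 * sqrt(9 / 400))
  expect_equal(var(reps) / mean(reps), 1, tolerance = 0.25)
})

test_that("per-pixel mean of noisy renderings matches the Poisson expectation", {
  n <- 33
  img <- image2d(matrix(0, n, n), 5)
  img$values[17, 17] <- 1
  psf <- psf_spec("lorentzian", 80, support_radius = 240)
  expectation <- 50 * image_structure(img, psf)$values + 5
  acc <- matrix(0, n, n)
  nrep <- 500
  for (s in seq_len(nrep))
    acc <- acc + image_structure(img, psf, noise_params(50, 5, seed = s))$values
  avg <- acc / nrep
  se <- sqrt(expectation / nrep)
  expect_true(all(abs(avg - expectation) <= 3.5 * se + 1e-9))
})
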