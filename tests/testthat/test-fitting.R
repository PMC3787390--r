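test_that("fitting a point source imaged with the STED PSF recovers its FWHM", {
  g <- grid_params(200, 5)
  pt <- render_structure(structure_spec("vesicle", 0, shell_halfwidth = 0), g)
  img <- image_structure(project_grid(pt), psf_spec("lorentzian", 80))
  fit <- fit_spot(img, "lorentzian")
  expect_true(fit$converged)
  expect_equal(fit$fwhm_major, 80, tolerance = 0.02 * 80 / 80)
  expect_equal(fit$fwhm_minor, 80, tolerance = 0.02 * 80 / 80)
  expect_lte(axis_ratio(fit), 1.02)

  # same through the Gaussian path
  imgg <- image_structure(project_grid(pt), psf_spec("gaussian", 80))
  fitg <- fit_spot(imgg, "gaussian")
  expect_equal(spot_size(fitg), 80, tolerance = 5 / 80)
})

test_that("flat or invalid images are rejected", {
  expect_error(fit_spot(image2d(matrix(3, 32, 32), 5), "lorentzian"), "flat")
  bad <- image2d(matrix(1, 32, 32), 5)
  bad$values[5, 5] <- NaN
  expect_error(fit_spot(bad, "lorentzian"), "finite")
})

test_that("elliptical parameters are recovered within 1% from a noise-free render", {
  img <- render_elliptical_spot(200, 5, fwhm_major = 140, fwhm_minor = 100,
                                theta = 0.6, amplitude = 120, offset = 8)
  fit <- fit_spot(img, "lorentzian", crop = Inf)
  expect_true(fit$converged)
  expect_equal(fit$fwhm_major, 140, tolerance = 0.01)
  expect_equal(fit$fwhm_minor, 100, tolerance = 0.01)
  expect_equal(fit$theta, 0.6, tolerance = 0.01)
  expect_equal(fit$amplitude, 120, tolerance = 0.01)
  expect_equal(fit$offset, 8, tolerance = 0.01)
  expect_lt(max(abs(fit$center)), 1)
})

test_that("fit refit round-trips within 0.5%", {
  img <- render_elliptical_spot(128, 5, 130, 95, 1.1, 80, 4)
  fit <- fit_spot(img, "lorentzian", crop = Inf)
  refit_img <- image2d(predict(fit, fit$crop$X, fit$crop$Y), 5)
  refit <- fit_spot(refit_img, "lorentzian", crop = Inf)
  for (p in c("fwhm_major", "fwhm_minor", "amplitude"))
    expect_equal(refit[[p]], fit[[p]], tolerance = 0.005)
  expect_equal(refit$theta, fit$theta, tolerance = 0.005)
})

test_that("fitted size grows strictly with vesicle diameter", {
  g <- grid_params(200, 5)
  psf <- psf_spec("lorentzian", 80)
  sizes <- vapply(c(0, 60, 110, 160), function(d) {
    sp <- if (d == 0) structure_spec("vesicle", 0, shell_halfwidth = 0)
    else structure_spec("vesicle", d)
    spot_size(fit_spot(image_structure(project_grid(render_structure(sp, g)),
                                       psf), "lorentzian", crop = Inf))
  }, numeric(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("in-plane tubules fit as more elongated spots than vesicles", {
  g <- grid_params(200, 5)
  psf <- psf_spec("lorentzian", 80)
  ves <- fit_spot(image_structure(
    project_grid(render_structure(structure_spec("vesicle", 110), g)), psf),
    "lorentzian", crop = Inf)
  rot_y90 <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3, byrow = TRUE)
  tub <- fit_spot(image_structure(
    project_grid(render_structure(structure_spec("tubule", 30, 300), g,
                                  rot_y90)), psf),
    "lorentzian", crop = Inf)  # axis rotated into the focal plane
  # an end-on tubule (axis along the optical axis) projects to a round spot
  endon <- fit_spot(image_structure(
    project_grid(render_structure(structure_spec("tubule", 30, 300), g)), psf),
    "lorentzian", crop = Inf)
  expect_lt(axis_ratio(endon), 1.05)
  expect_gt(axis_ratio(tub), axis_ratio(ves))
  expect_gt(axis_ratio(tub), 1.5)
})

test_that("scalar spot statistics behave as defined", {
  expect_equal(spot_size(fake_fit(114, 114)), 114)
  expect_equal(spot_size(fake_fit(160, 90)), 120)
  expect_equal(spot_size(fake_fit(160, 90)), spot_size(fake_fit(90, 160)))
  expect_equal(axis_ratio(fake_fit(114, 114)), 1)
  expect_gte(axis_ratio(fake_fit(160, 90)), 1)
  expect_error(spot_size(fake_fit(100, 100, converged = FALSE)), "converge")
  expect_error(axis_ratio(fake_fit(100, 100, converged = FALSE)), "converge")
})

test_that("size distributions summarize correctly", {
  fits <- lapply(c(100, 110, 120), function(s) fake_fit(s, s))
  d <- summarize_sizes(fits)
  expect_equal(d$n, 3)
  expect_equal(d$mean, 110)
  expect_equal(d$sd, sd(c(100, 110, 120)))
  expect_equal(d$sizes, c(100, 110, 120))

  single <- summarize_sizes(list(fake_fit(105, 105)))
  expect_equal(single$n, 1)
  expect_true(is.na(single$sd))

  expect_error(summarize_sizes(list()), "no fits")
  expect_error(summarize_sizes(list(fake_fit(1, 1, converged = FALSE))),
               "converged")
})

test_that("model methods are mutually consistent", {
  img <- render_elliptical_spot(96, 5, 120, 100, 0.3, 60, 2)
  fit <- fit_spot(img, "lorentzian", crop = Inf)
  expect_equal(unname(coef(fit)[["fwhm_major"]]), fit$fwhm_major)
  expect_equal(fitted(fit) + residuals(fit), fit$crop$values)
  expect_lt(fit$residual_norm, 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] >= 0))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 3))
})
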