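test_that("threshold of a constant image is the constant with zero spread", {
  est <- estimate_threshold(image2d(matrix(7, 60, 60), 5), n_rois = 100,
                            roi_size = 10, seed = 1)
  expect_equal(est$roi_maxima_mean, 7)
  expect_equal(est$roi_maxima_sd, 0)
  expect_equal(est$cutoff, 7)
  expect_equal(est$n_rois, 100L)
})

test_that("background cutoff matches the Monte-Carlo max-statistic oracle", {
  set.seed(20)
  oracle <- oracle_cutoff_poisson(rate = 10, npix = 100)
  cutoffs <- vapply(1:300, function(s) {
    img <- image2d(matrix(rpois(200 * 200, 10), 200, 200), 5)
    estimate_threshold(img, n_rois = 100, roi_size = 10, seed = s)$cutoff
  }, numeric(1))
  expect_true(all(cutoffs > 10))
  se <- sd(cutoffs) / sqrt(length(cutoffs))
  expect_lt(abs(mean(cutoffs) - (oracle["mean"] + oracle["sd"])),
            3 * se + 0.05)
})

test_that("larger background ROIs give higher cutoffs", {
  set.seed(21)
  img <- image2d(matrix(rpois(300 * 300, 10), 300, 300), 5)
  small <- mean(vapply(1:40, function(s)
    estimate_threshold(img, 100, roi_size = 5, seed = s)$cutoff, numeric(1)))
  large <- mean(vapply(1:40, function(s)
    estimate_threshold(img, 100, roi_size = 20, seed = s)$cutoff, numeric(1)))
  expect_gt(large, small)
})

test_that("exclusion masks are honored and can exhaust the image", {
  img <- image2d(matrix(5, 40, 40), 5)
  mask <- matrix(TRUE, 40, 40)
  expect_error(estimate_threshold(img, 10, 10, exclusion_mask = mask),
               "insufficient background")
  mask[1:20, 1:40] <- FALSE  # ROIs must come from the top half
  est <- estimate_threshold(img, 10, 10, exclusion_mask = mask, seed = 2)
  expect_equal(est$cutoff, 5)
})

test_that("spot detection finds isolated maxima and respects the cutoff", {
  v <- matrix(0, 100, 100)
  v[30, 40] <- 50
  img <- image2d(v, 5)
  det <- detect_spots(img, cutoff = 10, min_separation = 50)
  expect_equal(nrow(det), 1)
  expect_equal(c(det$i, det$j), c(30, 40))

  v2 <- v; v2[80, 40] <- 40  # 250 nm apart = 5x min_separation
  det2 <- detect_spots(image2d(v2, 5), 10, min_separation = 50)
  expect_equal(nrow(det2), 2)
  expect_equal(det2$intensity, c(50, 40))  # decreasing intensity

  # suppression: second peak within min_separation vanishes
  v3 <- v; v3[33, 40] <- 40
  expect_equal(nrow(detect_spots(image2d(v3, 5), 10, min_separation = 50)), 1)

  expect_equal(nrow(detect_spots(image2d(v, 5), cutoff = 100,
                                 min_separation = 50)), 0)
})

test_that("spots are classified by channel cutoffs with a size gate", {
  px <- 5
  n <- 260
  ref <- image2d(matrix(1, n, n), px)
  mk <- function(centers_amps, fwhm = 110) {
    m <- matrix(1, n, n)
    co <- ((seq_len(n) - 0.5) - n / 2) * px
    for (ca in centers_amps) {
      r2 <- outer((co - ca[1])^2, (co - ca[2])^2, "+")
      m <- m + ca[3] / (1 + 4 * r2 / (if (length(ca) > 3) ca[4] else fwhm)^2)
    }
    image2d(m, px)
  }
  centers <- list(c(-400, -400), c(400, -400), c(-400, 400), c(400, 400))
  ref <- mk(list(c(-400, -400, 100), c(400, -400, 100), c(-400, 400, 100),
                 c(400, 400, 100, 300)))  # fourth spot oversize
  chA <- mk(list(c(-400, -400, 80), c(-400, 400, 80)))
  chB <- mk(list(c(400, -400, 80), c(-400, 400, 80)))
  res <- classify_spots(ref, chA, chB,
                        cutoffs = list(reference = 20, A = 10, B = 10),
                        size_max = 150, psf = psf_spec("lorentzian", 80),
                        min_separation = 300)
  expect_equal(res$n_spots_total, 4)
  expect_equal(res$n_excluded_by_size, 1)
  expect_equal(unname(res$counts), c(1, 1, 1))
  expect_equal(sum(res$fractions), 1)
  expect_true(all(res$spots$size < 150))
})

test_that("classification errors on malformed inputs", {
  a <- image2d(matrix(1, 20, 20), 5)
  b <- image2d(matrix(1, 30, 30), 5)
  expect_error(classify_spots(a, b, a, list(reference = 1, A = 1, B = 1)),
               "shape")
  expect_error(classify_spots(a, a, a, list(reference = 1, A = 1)),
               "cutoff")
})

test_that("Pearson coefficient hits its analytic anchors", {
  set.seed(31)
  a <- image2d(matrix(rpois(100 * 100, 20), 100, 100), 5)
  expect_equal(pearson_coloc(a, a), 1)
  inv <- image2d(max(a$values) - a$values, 5)
  expect_equal(pearson_coloc(a, inv), -1)

  b <- image2d(matrix(rpois(100 * 100, 20), 100, 100), 5)
  expect_lt(abs(pearson_coloc(a, b)), 0.05)

  # affine rescaling invariance
  scaled <- image2d(3 * b$values + 7, 5)
  expect_equal(pearson_coloc(a, scaled), pearson_coloc(a, b),
               tolerance = 1e-12)

  expect_error(pearson_coloc(a, image2d(matrix(2, 100, 100), 5)),
               "variance")
  expect_error(pearson_coloc(a, image2d(matrix(1, 10, 10), 5)), "shape")

  mask <- matrix(FALSE, 100, 100); mask[1:50, ] <- TRUE
  expect_equal(pearson_coloc(a, a, mask), 1)
})
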