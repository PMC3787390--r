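test_that("vesicle shell rasterization matches the brute-force distance oracle", {
  g <- grid_params(64, 5)
  spec <- structure_spec("vesicle", 110)
  vg <- render_structure(spec, g)
  expect_identical(vg$values, oracle_shell(spec, 64, 5))

  # every nonzero voxel center lies in the 50..60 nm radial band
  co <- ((seq_len(64) - 0.5) - 32) * 5
  idx <- which(vg$values > 0, arr.ind = TRUE)
  r <- sqrt(co[idx[, 1]]^2 + co[idx[, 2]]^2 + co[idx[, 3]]^2)
  expect_true(all(r >= 50 & r <= 60))
  expect_gt(sum(vg$values), 0)
})

test_that("tubule shell matches the oracle under a random rotation", {
  g <- grid_params(64, 5)
  spec <- structure_spec("tubule", 30, 150)
  rot <- sample_orientation(seed = 42)
  expect_identical(render_structure(spec, g, rot)$values,
                   oracle_shell(spec, 64, 5, rot))
})

test_that("degenerate specs: point source and invalid dimensions", {
  g <- grid_params(64, 5)
  pt <- render_structure(structure_spec("vesicle", 0, shell_halfwidth = 0), g)
  expect_equal(sum(pt$values > 0), 1)
  idx <- which(pt$values > 0, arr.ind = TRUE)
  # nearest voxel to the grid center on an even grid
  expect_true(all(idx %in% c(32, 33)))

  expect_error(structure_spec("vesicle", -10), "diameter")
  expect_error(structure_spec("tubule", 30, 20), "length")
  expect_error(structure_spec("tubule", 30), "length")
  expect_error(
    render_structure(structure_spec("tubule", 30, 400), grid_params(64, 5)),
    "fit")
})

test_that("a 90-degree rotation about y equals transposing the x and z axes", {
  g <- grid_params(64, 5)
  spec <- structure_spec("tubule", 30, 300)
  rot_y90 <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3, byrow = TRUE)
  a <- render_structure(spec, g)$values
  b <- render_structure(spec, g, rot_y90)$values
  expect_identical(b, aperm(a, c(3, 2, 1)))
})

test_that("projection conserves intensity and preserves a point source", {
  g <- grid_params(64, 5)
  vg <- render_structure(structure_spec("vesicle", 110), g)
  img <- project_grid(vg)
  expect_identical(sum(img$values), sum(vg$values))
  expect_equal(img$pixel_size, vg$voxel_size)

  pt <- render_structure(structure_spec("vesicle", 0, shell_halfwidth = 0), g)
  expect_equal(sum(project_grid(pt)$values > 0), 1)
})

test_that("projected vesicle shell is limb-brightened near +/- 55 nm", {
  g <- grid_params(64, 5)
  img <- project_grid(render_structure(structure_spec("vesicle", 110), g))
  co <- ((seq_len(64) - 0.5) - 32) * 5
  profile <- img$values[, 32]  # line through the center
  left <- profile[co < 0]; right <- profile[co > 0]
  expect_lt(abs(co[co < 0][which.max(left)] + 55), 7.6)
  expect_lt(abs(co[co > 0][which.max(right)] - 55), 7.6)
  # central dip between the limbs
  expect_lt(profile[32], max(profile))
})

test_that("orientation sampling is deterministic, orthonormal and isotropic", {
  r1 <- sample_orientation(seed = 7)
  r2 <- sample_orientation(seed = 7)
  expect_identical(r1, r2)
  expect_lt(max(abs(crossprod(r1) - diag(3))), 1e-12)
  expect_equal(det(r1), 1, tolerance = 1e-12)

  set.seed(99)
  n <- 10000
  dirs <- t(vapply(seq_len(n),
                   function(i) as.vector(sample_orientation() %*% c(0, 0, 1)),
                   numeric(3)))
  # E|cos(angle to lab z)| = 1/2 for uniform directions
  expect_equal(mean(abs(dirs[, 3])), 0.5, tolerance = 0.02)
  # each octant receives n/8 +/- 3 sigma
  oct <- table(factor(paste(dirs[, 1] > 0, dirs[, 2] > 0, dirs[, 3] > 0),
                      levels = apply(expand.grid(c(TRUE, FALSE), c(TRUE, FALSE),
                                                 c(TRUE, FALSE)), 1, paste,
                                     collapse = " ")))
  sigma <- sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(oct - n / 8) <= 3 * sigma))
})

test_that("shell voxel counts are rotation-stable", {
  g <- grid_params(64, 5)
  ves <- structure_spec("vesicle", 110)
  n0 <- sum(render_structure(ves, g)$values)
  for (s in 1:4)
    expect_identical(sum(render_structure(ves, g, sample_orientation(s))$values),
                     n0)
  tub <- structure_spec("tubule", 30, 150)
  counts <- vapply(1:8, function(s)
    sum(render_structure(tub, g, sample_orientation(s))$values), numeric(1))
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.05)
})
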