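test_that("mask scaling multiplies each structure by its priority", {
  ss <- random_structures(c(2, 10, 10))
  sc <- scale_masks(ss, priority_vector(2, 3, 5))
  expect_equal(sc$ptv$values, ss$ptv$values * 2)
  expect_equal(sc$bladder$values, ss$bladder$values * 3)
  expect_equal(sc$rectum$values, ss$rectum$values * 5)
  z <- scale_masks(ss, priority_vector(0, 0, 1))
  expect_true(all(z$ptv$values == 0) && all(z$bladder$values == 0))
  # unit priorities are the identity, so applying them twice changes nothing
  once <- scale_masks(ss, priority_vector(1, 1, 1))
  for (nm in names(once))
    expect_equal(once[[nm]]$values * 1, ss[[nm]]$values)
})

test_that("uniform smoothing matches the double-loop oracle, delta and constant cases", {
  g <- voxel_grid(array(5, c(1, 9, 9)))
  expect_equal(smooth_uniform(g, 3)$values[1, 5, 5], 5)
  expect_equal(smooth_uniform(g, 1)$values, g$values)
  delta <- voxel_grid(array(0, c(1, 9, 9))); delta$values[1, 5, 5] <- 1
  sm <- smooth_uniform(delta, 3)$values[1, , ]
  expect_equal(sum(sm != 0), 9)
  expect_true(all(abs(sm[4:6, 4:6] - 1 / 9) < 1e-15))
  set.seed(31)
  m <- matrix(rnorm(16 * 16), 16, 16)
  g16 <- voxel_grid(array(m, c(1, 16, 16)))
  for (k in c(2, 3, 7, 10))
    expect_lt(max(abs(smooth_uniform(g16, k)$values[1, , ] - oracle_conv(m, k))),
              1e-12)
  expect_error(smooth_uniform(g16, 200), class = "paretodose_validation_error")
})

test_that("atrous patches sample the documented row-major offsets with zero padding", {
  colgrid <- voxel_grid(array(0, c(1, 70, 70)))
  colgrid$values[1, , ] <- matrix(rep(1:70, each = 70), 70, 70)  # value = col index
  p <- extract_patch(colgrid, c(1, 35, 60), rate = 1)
  expect_equal(p[41], 60)   # centre
  expect_equal(p[45], 64)   # last element of the centre row
  const <- voxel_grid(array(7, c(2, 30, 30)))
  expect_equal(extract_patch(const, c(2, 15, 15), rate = 3), rep(7, 81))
  corner <- extract_patch(const, c(1, 1, 1), rate = 10)
  expect_true(all(corner[1:40] == 0))   # all offsets with negative coords
  set.seed(32)
  m <- matrix(rnorm(20 * 20), 20, 20)
  g <- voxel_grid(array(m, c(1, 20, 20)))
  for (i in 1:40) {
    r <- sample(20, 1); c <- sample(20, 1); rate <- sample(c(1, 3, 10), 1)
    expect_equal(extract_patch(g, c(1, r, c), rate), oracle_patch(m, r, c, rate))
  }
})

test_that("feature assembly follows the documented order and is linear", {
  ss <- random_structures(c(2, 12, 12))
  pr <- priority_vector(1, 2, 3)
  zero <- voxel_grid(array(0, c(2, 12, 12)), c(3, 2, 2))
  # all-zero grids -> 972 zeros then the priorities
  f0 <- assemble_features(list(ptv = zero, bladder = zero, rectum = zero),
                          zero, pr, c(1, 6, 6))
  expect_length(f0, 975)
  expect_true(all(f0[1:972] == 0))
  expect_equal(f0[973:975], c(1, 2, 3))

  # compositional oracle: per-piece extraction concatenated in order
  set.seed(33)
  dose <- random_grid(c(2, 12, 12))
  sc <- scale_masks(ss, pr)
  spec <- atrous_spec()
  vox <- c(2, 7, 5)
  f <- assemble_features(sc, dose, pr, vox, spec)
  pieces <- list()
  for (ri in 1:3) for (g in list(sc$ptv, sc$bladder, sc$rectum, dose)) {
    sm <- smooth_uniform(g, spec$kernels[ri])
    pieces[[length(pieces) + 1L]] <-
      oracle_patch(sm$values[vox[1], , ], vox[2], vox[3], spec$rates[ri])
  }
  expect_equal(f, c(unlist(pieces), 1, 2, 3), tolerance = 1e-12)

  # linear in the grid inputs (patch portion)
  f2 <- assemble_features(lapply(sc, function(g) voxel_grid(2 * g$values, g$spacing)),
                          voxel_grid(2 * dose$values, dose$spacing), pr, vox, spec)
  expect_equal(f2[1:972], 2 * f[1:972], tolerance = 1e-12)
})

test_that("rate-r patches of an r-smoothed constant field stay constant inside", {
  for (r in c(1, 3, 10)) {
    g <- voxel_grid(array(4, c(1, 100, 100)))
    sm <- smooth_uniform(g, r)
    centre <- extract_patch(sm, c(1, 50, 50), rate = r)
    expect_true(all(abs(centre - 4) < 1e-12))
  }
})

test_that("vectorized slice features agree with the per-voxel path", {
  set.seed(34)
  ss <- random_structures(c(2, 14, 14))
  pr <- priority_vector(2, 1, 4)
  dose <- random_grid(c(2, 14, 14))
  spec <- atrous_spec()
  sc <- scale_masks(ss, pr)
  pd <- asNamespace("paretodose")
  SP <- pd$plan_struct_stack(ss, pr, 1:2, spec)
  D <- rbind(pd$slice_dose_features(dose$values[1, , ], spec),
             pd$slice_dose_features(dose$values[2, , ], spec))
  lay <- pd$feature_layout(spec)
  full <- matrix(0, nrow(SP), lay$total)
  full[, c(lay$struct, lay$priorities)] <- SP
  full[, lay$dose] <- D
  for (k in 1:12) {
    s <- sample(2, 1); r <- sample(14, 1); c <- sample(14, 1)
    row <- (s - 1) * 196 + (c - 1) * 14 + r
    expect_equal(full[row, ], assemble_features(sc, dose, pr, c(s, r, c), spec),
                 tolerance = 1e-12)
  }
})
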