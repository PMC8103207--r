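test_that("loss mask keeps body voxels on structure-bearing slices only", {
  dims <- c(3, 10, 10); sp <- c(3, 2, 2)
  body <- array(0, dims); body[, 3:8, 3:8] <- 1
  ptv <- array(0, dims); ptv[1, 5:6, 5:6] <- 1
  bl <- array(0, dims); bl[1, 3, 3] <- 1
  ss <- structure_set(voxel_grid(ptv, sp), voxel_grid(bl, sp),
                      voxel_grid(array(0, dims), sp), voxel_grid(body, sp))
  m <- loss_mask(list(structures = ss))$values
  expect_equal(m[1, , ], body[1, , ])     # structures live on slice 1 only
  expect_true(all(m[2:3, , ] == 0))
  expect_equal(m[1, 1, 1], 0)             # outside body on a masked slice
})

test_that("masked RMSE matches its definition and a scalar-loop oracle", {
  dims <- c(2, 6, 6)
  ref <- voxel_grid(array(runif(72), dims))
  mask <- voxel_grid(array(as.double(runif(72) < 0.6), dims))
  expect_equal(masked_rmse(ref, ref, mask), 0)
  shifted <- voxel_grid(ref$values + 0.05)
  expect_equal(masked_rmse(shifted, ref, mask), 5, tolerance = 1e-12)
  set.seed(51)
  for (i in 1:100) {
    pred <- array(rnorm(72), dims)
    m <- array(as.double(runif(72) < 0.5), dims)
    m[1, 1, 1] <- 1
    expect_equal(masked_rmse(voxel_grid(pred), ref, voxel_grid(m)),
                 oracle_masked_rmse(pred, ref$values, m), tolerance = 1e-12)
  }
  expect_error(masked_rmse(ref, ref, voxel_grid(array(0, dims))), "no voxels")
})

test_that("diagonal batches stagger depths, stay deterministic and cover all pairs", {
  cfg <- tiny_config(n_patients = 3, n_slices = 4, n_rows = 12, n_cols = 12)
  cohort <- simulate_cohort(cfg, plan_grid = priority_grid()[c(1, 13, 25), ])
  tc <- train_config(batch_slices = 3, seed = 7)
  seen <- character(0)
  for (it in 0:3) {
    b <- diagonal_batches(cohort, tc, it)
    expect_equal(nrow(b), 3)
    expect_equal(sort(unique(b$patient)), 1:3)    # <= 1 slice per patient
    seen <- c(seen, paste(b$patient, b$slice))
  }
  expect_setequal(seen, as.vector(outer(1:3, 1:4, paste)))  # all 12 pairs
  expect_identical(diagonal_batches(cohort, tc, 2), diagonal_batches(cohort, tc, 2))
  # concurrent slices sit at different depths
  b0 <- diagonal_batches(cohort, tc, 0)
  expect_gt(length(unique(b0$slice)), 1)
  expect_error(diagonal_batches(list(), tc, 0), "empty")
})

test_that("training is seed-deterministic and returns the start at 0 iterations", {
  cfg <- tiny_config(n_patients = 2, n_slices = 4, n_rows = 12, n_cols = 12)
  cohort <- simulate_cohort(cfg, plan_grid = priority_grid()[c(1, 25), ])
  ip <- init_params(1.5, 2, 0.8, 0.6)
  tc0 <- train_config(iterations = 0, seed = 3)
  r0 <- train_network(cohort, tc0, init = ip)
  expect_length(r0$trace, 0)
  expect_equal(r0$params$blocks, init_model_glorot(3, init = ip)$blocks)

  tc <- train_config(iterations = 3, batch_slices = 2, seed = 3)
  p0 <- init_model_glorot(3, hidden = c(6, 5), n_blocks = 2, init = ip)
  ra <- train_network(cohort, tc, p0)
  rb <- train_network(cohort, tc, p0)
  expect_identical(ra$trace, rb$trace)
  expect_identical(ra$params$blocks[[2]]$W1, rb$params$blocks[[2]]$W1)
})

test_that("repeated k-fold bookkeeping holds for arbitrary seeds", {
  for (seed in c(1, 99, 12345)) {
    folds <- cv_folds(10, 5, 4, seed)
    for (f in folds) {
      expect_equal(sort(unique(f)), 1:5)
      expect_true(all(table(f) == 2))
    }
  }
  expect_error(cv_folds(4, 10, 1), class = "paretodose_validation_error")
})

test_that("rotation scheme reproduces the printed fold pattern", {
  sch <- rotation_scheme(8)
  expect_equal(sch[[1]]$train, 1:8)
  expect_equal(sch[[1]]$test, c(9, 10))
  expect_equal(sch[[2]]$train, 2:9)
  expect_equal(sch[[2]]$test, c(10, 1))
  counts_train <- table(unlist(lapply(sch, `[[`, "train")))
  counts_test <- table(unlist(lapply(sch, `[[`, "test")))
  expect_true(all(counts_train == 8) && all(counts_test == 2))
  sch5 <- rotation_scheme(5)
  expect_true(all(table(unlist(lapply(sch5, `[[`, "train"))) == 5))
  expect_true(all(table(unlist(lapply(sch5, `[[`, "test"))) == 5))
  expect_error(rotation_scheme(10), class = "paretodose_validation_error")
})

test_that("cross-validation harnesses run end to end on a miniature cohort", {
  cfg <- tiny_config(n_patients = 4, n_slices = 4, n_rows = 12, n_cols = 12)
  cohort <- simulate_cohort(cfg, plan_grid = priority_grid()[c(1, 25), ])
  tc <- train_config(iterations = 2, batch_slices = 2, seed = 5)
  io <- list(iterations = 40)
  rep1 <- crossval_repeated_kfold(cohort, k = 2, repetitions = 1, tc, io)
  expect_equal(nrow(rep1$results), 2)
  expect_true(all(is.finite(rep1$results$test_rmse)))
  rep2 <- crossval_ratio_rotation(cohort, train_subsets = 2, n_subsets = 4,
                                  cfg = tc, init_opts = io)
  expect_equal(nrow(rep2$results), 4)
  expect_output(print(rep2), "cv_report")
})
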