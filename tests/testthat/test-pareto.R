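test_that("DVH percentile follows the descending ceil rule", {
  dims <- c(1, 2, 2)
  mask <- voxel_grid(array(1, dims))
  d <- voxel_grid(array(c(0.1, 0.2, 0.3, 0.4), dims))
  expect_equal(dvh_dose_at_volume(d, mask, 50), 30)
  u <- voxel_grid(array(0.95, dims))
  for (x in c(2, 25, 50, 95, 100))
    expect_equal(dvh_dose_at_volume(u, mask, x), 95)
  expect_equal(dvh_dose_at_volume(d, mask, 100), 10)  # minimum masked dose
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    vals <- array(runif(n), c(1, n, 1))
    x <- runif(1, 1, 100)
    expect_equal(dvh_dose_at_volume(voxel_grid(vals), voxel_grid(array(1, c(1, n, 1))), x),
                 oracle_dvh(vals, array(1, c(1, n, 1)), x))
  }
  # non-increasing in x
  xs <- sort(runif(10, 1, 100))
  dv <- vapply(xs, function(x)
    dvh_dose_at_volume(d, mask, x), numeric(1))
  expect_true(all(diff(dv) <= 0))
  expect_error(dvh_dose_at_volume(d, voxel_grid(array(0, dims)), 50), "no voxels")
  expect_error(dvh_dose_at_volume(d, mask, 0), class = "paretodose_validation_error")
})

test_that("D95 normalization scales exactly once and is a fixed point", {
  set.seed(62)
  dims <- c(2, 8, 8)
  ptv <- voxel_grid(array(as.double(runif(prod(dims)) < 0.4), dims))
  ptv$values[1, 1, 1] <- 1
  d <- voxel_grid(array(runif(prod(dims), 0.5, 1.2), dims))
  n1 <- normalize_to_d95(d, ptv)
  expect_equal(dvh_dose_at_volume(n1, ptv, 95), 100, tolerance = 1e-12)
  n2 <- normalize_to_d95(n1, ptv)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  u <- voxel_grid(array(0.9, dims))
  expect_equal(normalize_to_d95(u, ptv)$values[1], 1)
  expect_error(normalize_to_d95(voxel_grid(array(0, dims)), ptv), "zero")
})

test_that("objectives follow the sorting oracle", {
  dims <- c(1, 10, 10)
  ptv <- array(0, dims); ptv[1, , ] <- 1
  vals <- array(1, dims); vals[1, 1, 1] <- 1.10; vals[1, 10, 10] <- 0.90
  bl <- array(0, c(1, 10, 10)); bl[1, 1:3, 1] <- 1
  ss <- structure_set(voxel_grid(ptv), voxel_grid(bl),
                      voxel_grid(array(0, dims)), voxel_grid(array(1, dims)))
  dose <- voxel_grid(vals)
  expect_error(compute_objectives(dose, ss), "no voxels")  # empty rectum
  re <- array(0, dims); re[1, 5, 5] <- 1
  ss2 <- structure_set(voxel_grid(ptv), voxel_grid(bl), voxel_grid(re),
                       voxel_grid(array(1, dims)))
  dose$values[1, 1:3, 1] <- 0.3
  obj <- compute_objectives(dose, ss2)
  # 100 PTV voxels: D2% = 2nd hottest = 1.10 -> 110; D98% = 98th = ...
  expect_equal(obj[["bladder_d25"]], 30)
  expect_equal(obj[["hi"]],
               oracle_dvh(dose$values, ptv, 2) - oracle_dvh(dose$values, ptv, 98))
  uni <- voxel_grid(array(0.7, dims))
  expect_equal(compute_objectives(uni, ss2)[["hi"]], 0)
})

test_that("surface triangulation counts follow the parameter grid", {
  pg <- priority_grid()
  set.seed(63)
  verts <- matrix(runif(75), 25, 3)
  surf <- build_surface(verts, pg[, c("alpha", "beta")])
  expect_equal(nrow(surf$vertices), 25)
  expect_equal(nrow(surf$simplices), 32)
  expect_setequal(sort(unique(as.vector(surf$simplices))), 1:25)  # every vertex used
  tri <- build_surface(matrix(runif(9), 3, 3))
  expect_equal(nrow(tri$simplices), 1)
  expect_error(build_surface(verts, pg[c(1:24, 1), c("alpha", "beta")]),
               "duplicated")
})

test_that("pareto RMSE/Hausdorff/APD match oracles and metric properties", {
  expect_equal(pareto_rmse(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  A1 <- matrix(c(0, 0, 0), 1, 3); B1 <- matrix(c(3, 0, 0), 1, 3)
  expect_equal(pareto_hausdorff(A1, B1), 3)
  A2 <- rbind(c(0, 0, 0), c(1, 0, 0)); B2 <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(pareto_hausdorff(A2, B2), 4)
  set.seed(64)
  for (i in 1:100) {
    n <- sample(2:12, 1); m <- sample(2:12, 1)
    A <- matrix(rnorm(3 * n), n); B <- matrix(rnorm(3 * m), m)
    expect_equal(pareto_hausdorff(A, B), oracle_hausdorff(A, B), tolerance = 1e-10)
    expect_equal(pareto_hausdorff(A, B), pareto_hausdorff(B, A))
    expect_equal(pareto_hausdorff(A, A), 0)
    C <- matrix(rnorm(3 * 4), 4)
    expect_lte(pareto_hausdorff(A, B),
               pareto_hausdorff(A, C) + pareto_hausdorff(C, B) + 1e-10)
    # matched-pair metrics
    Bm <- matrix(rnorm(3 * n), n)
    expect_equal(pareto_rmse(A, Bm),
                 sqrt(mean(vapply(seq_len(n), function(k) sum((A[k, ] - Bm[k, ])^2), 0))),
                 tolerance = 1e-12)
    if (sqrt(sum(colMeans(A - Bm)^2)) > 1e-8)
      expect_equal(pareto_apd(A, Bm), oracle_apd(A, Bm), tolerance = 1e-10)
  }
})

test_that("APD handles parallel, rotated and degenerate displacement sets", {
  A <- rbind(c(1, 2, 3), c(4, 5, 6), c(0, 1, 0))
  B <- sweep(A, 2, c(0, 1, 0))           # all displacements (0, -1, 0)... A - B = (0,1,0)
  expect_equal(pareto_apd(A, B), 1)
  expect_equal(pareto_apd(rbind(c(1, 0, 0), c(0, 1, 0)),
                          matrix(0, 2, 3)), 1 / sqrt(2))
  expect_error(pareto_apd(rbind(c(0, 1, 0), c(0, -1, 0)), matrix(0, 2, 3)),
               "direction undefined")
  expect_equal(pareto_apd(A, A), 0)      # zero displacements bypass the error
  # invariance under a global rotation of both sets
  set.seed(65)
  th <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A4 <- matrix(rnorm(12), 4); B4 <- matrix(rnorm(12), 4)
  expect_equal(pareto_apd(A4 %*% t(R), B4 %*% t(R)), pareto_apd(A4, B4),
               tolerance = 1e-10)
})

test_that("ANPD is exact for parallel patches, zero on self, below Hausdorff", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  par <- cbind(alpha = c(0, 1, 0, 1), beta = c(0, 0, 1, 1))
  s1 <- build_surface(sq, par)
  s2 <- build_surface(cbind(sq[, 1:2], 1), par)
  expect_equal(nrow(s1$simplices), 2)
  for (dens in c(3, 10, 105))
    expect_equal(pareto_anpd(s1, s2, dens), 1, tolerance = 1e-12)
  expect_equal(pareto_anpd(s1, s1), 0)
  expect_error(pareto_anpd(s1, s2, density = 0), class = "paretodose_validation_error")

  set.seed(66)
  for (i in 1:20) {
    V1 <- matrix(rnorm(9), 3)
    V2 <- matrix(rnorm(9), 3) + matrix(rep(c(3, 0, 0), each = 3), 3)
    t1 <- build_surface(V1); t2 <- build_surface(V2)
    got <- pareto_anpd(t1, t2, density = 105)
    expect_equal(got, oracle_anpd_tri(V1, V2), tolerance = 0.02 * got)
    # average nearest distance cannot exceed the Hausdorff distance of the
    # supersampled clouds
    pd <- asNamespace("paretodose")
    c1 <- pd$sample_complex(t1, 105); c2 <- pd$sample_complex(t2, 105)
    expect_lte(got, pareto_hausdorff(c1, c2) + 1e-9)
  }
})

test_that("all four metrics vanish on self-comparison of a real surface", {
  cfg <- tiny_config(n_slices = 5, n_rows = 16, n_cols = 16)
  cohort <- simulate_cohort(cfg, n_plans = 25)
  surf <- reference_pareto_surface(cohort[[1]])
  m <- pareto_metrics(surf, surf, density = 6)
  expect_equal(unname(m), c(0, 0, 0, 0))
})
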