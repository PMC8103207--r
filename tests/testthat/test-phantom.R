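test_that("anatomy generation is deterministic and respects mask invariants", {
  cfg <- tiny_config(n_patients = 3, n_slices = 5)
  a <- generate_anatomy(cfg, 2)
  b <- generate_anatomy(cfg, 2)
  expect_identical(a$ptv$values, b$ptv$values)
  expect_identical(a$rectum$values, b$rectum$values)
  expect_false(identical(generate_anatomy(cfg, 1)$ptv$values, a$ptv$values))

  expect_equal(dim(a$ptv$values)[1], 5)
  expect_true(all(a$ptv$values <= a$body$values))
  expect_equal(sum(a$ptv$values * a$bladder$values), 0)
  expect_equal(sum(a$ptv$values * a$rectum$values), 0)
  expect_gt(sum(a$ptv$values), 0)
})

test_that("oversized structures are rejected", {
  expect_error(phantom_config(1, n_slices = 6, n_rows = 16, n_cols = 16,
                              ptv_radius_mm = c(500, 500, 500)),
               "too large")
  expect_error(phantom_config(0), class = "paretodose_validation_error")
})

test_that("priority grid spans convex combinations of the bounding vectors", {
  B <- rbind(c(10, 1, 1), c(1, 10, 1), c(1, 1, 10))
  pg <- priority_grid(B, 25)
  expect_equal(nrow(pg), 25)
  # corners: alpha = 1 -> P1 (5 duplicates retained); alpha = 0 picks P2/P3
  top <- pg[pg$alpha == 1, c("w_hi", "w_bladder", "w_rectum")]
  expect_equal(nrow(top), 5)
  for (i in 1:5) expect_equal(unlist(top[i, ], use.names = FALSE), B[1, ])
  p2 <- pg[pg$alpha == 0 & pg$beta == 1, ]
  expect_equal(unlist(p2[c("w_hi", "w_bladder", "w_rectum")], use.names = FALSE), B[2, ])
  p3 <- pg[pg$alpha == 0 & pg$beta == 0, ]
  expect_equal(unlist(p3[c("w_hi", "w_bladder", "w_rectum")], use.names = FALSE), B[3, ])
  # hull membership by solving the barycentric system for every output
  for (i in seq_len(25))
    expect_true(in_priority_hull(unlist(pg[i, 3:5], use.names = FALSE), B))
  expect_true(all(pg[, 3:5] >= 0))
  expect_error(priority_grid(B, 24), "perfect square")
  expect_error(priority_grid(rbind(B[1, ], B[1, ], B[3, ])), "distinct")
})

test_that("degenerate surrogate dose reduces to the initialization formula", {
  cfg <- tiny_config(s_bladder = 0, s_rectum = 0, h = 0, sigma = 0)
  ss <- generate_anatomy(cfg, 1)
  d <- simulate_tps_dose(ss, priority_vector(1, 1, 1), cfg, 9)
  di <- init_dose(compute_distance_maps(ss),
                  do.call(init_params, as.list(cfg$true_params)))
  expect_equal(d$values, di$values, tolerance = 1e-12)
  expect_true(all(abs(d$values[ss$ptv$values != 0] - 1) < 1e-12))
})

test_that("surrogate dose is seed-deterministic and D95-normalized", {
  cfg <- tiny_config()
  ss <- generate_anatomy(cfg, 1)
  d1 <- simulate_tps_dose(ss, priority_vector(2, 5, 1), cfg, 31)
  d2 <- simulate_tps_dose(ss, priority_vector(2, 5, 1), cfg, 31)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values,
                         simulate_tps_dose(ss, priority_vector(2, 5, 1), cfg, 32)$values))
  expect_equal(dvh_dose_at_volume(d1, ss$ptv, 95), 100, tolerance = 1e-6)
})

test_that("organ priority raises lower that organ's D25 monotonically (noise off)", {
  cfg <- tiny_config(n_slices = 8, n_rows = 24, n_cols = 24, sigma = 0)
  ss <- generate_anatomy(cfg, 1)
  for (organ in c("bladder", "rectum")) {
    d25 <- vapply(c(0.5, 1, 2, 5, 10), function(w) {
      pr <- if (organ == "bladder") priority_vector(1, w, 1) else priority_vector(1, 1, w)
      dvh_dose_at_volume(simulate_tps_dose(ss, pr, cfg, 7), ss[[organ]], 25)
    }, numeric(1))
    expect_true(all(diff(d25) <= 1e-9))
  }
  # HI priority flattens the target dose
  hi <- vapply(c(0.5, 1, 2, 5, 10), function(w) {
    d <- simulate_tps_dose(ss, priority_vector(w, 1, 1), cfg, 7)
    compute_objectives(d, ss)[["hi"]]
  }, numeric(1))
  expect_true(all(diff(hi) <= 1e-9))
})

test_that("cohort generation writes a complete, reproducible manifest", {
  cfg <- tiny_config(n_patients = 2, n_slices = 4, n_rows = 16, n_cols = 16)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(cfg, d1, n_plans = 4)
  m2 <- generate_cohort(cfg, d2, n_plans = 4)
  man <- jsonlite::read_json(m1)
  expect_length(man$patients, 2)
  expect_length(man$patients[[1]]$plans, 4)
  c1 <- load_cohort(m1, in_plane = NULL)
  c2 <- load_cohort(m2, in_plane = NULL)
  expect_identical(c1[[2]]$plans[[3]]$dose$values, c2[[2]]$plans[[3]]$dose$values)
  # generated Pareto points are not all identical
  obj <- t(vapply(c1[[1]]$plans, function(pl)
    compute_objectives(pl$dose, c1[[1]]$structures), numeric(3)))
  expect_gt(max(apply(obj, 2, function(x) diff(range(x)))), 0)
})
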