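## Synthetic pelvic-phantom cohort: anatomies with PTV/bladder/rectum
## adjacency, a 5x5 priority grid of plans per patient, and surrogate "TPS"
## doses whose trade-offs respond monotonically to the priorities.

#' Phantom cohort configuration
#'
#' @param n_patients number of patients to generate.
#' @param n_slices,n_rows,n_cols grid dimensions (defaults 40 x 128 x 128).
#' @param spacing `(slice_mm, row_mm, col_mm)`, default 3 mm isotropic.
#' @param true_params the generator's initialization parameters
#'   `(a1, a2, a3, c)`; the surrogate dose uses the analytic initialization
#'   with these values as its base shape.
#' @param s_bladder,s_rectum organ sparing strengths in `[0, 0.5]`: maximal
#'   fractional dose reduction attributable to each organ's priority.
#' @param tau_mm length scale (mm) of the exponential sparing falloff.
#' @param h PTV dose heterogeneity amplitude; the realized amplitude shrinks
#'   as `h / (1 + w_hi)`.
#' @param sigma additive noise amplitude (fraction of prescription).
#' @param noise_kernel uniform smoothing width applied to the white noise,
#'   making it spatially correlated like real TPS dose.
#' @param centre_jitter_mm,radius_jitter anatomy jitter scales: uniform
#'   centre offsets (mm) and fractional radius perturbations per patient.
#' @param ptv_radius_mm,bladder_radius_mm,rectum_radius_mm structure
#'   semi-axes `(slice, row, col)` in mm before jitter.
#' @param seed cohort seed; anatomy and dose fields are deterministic given
#'   `(seed, patient_index)`.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n_patients, n_slices = 40L, n_rows = 128L,
                           n_cols = 128L, spacing = c(3, 3, 3),
                           true_params = c(a1 = 1.5, a2 = 2, a3 = 0.8, c = 0.6),
                           s_bladder = 0.4, s_rectum = 0.4, tau_mm = 25,
                           h = 0.02, sigma = 0.003, noise_kernel = 5L,
                           centre_jitter_mm = 6, radius_jitter = 0.1,
                           ptv_radius_mm = NULL, bladder_radius_mm = NULL,
                           rectum_radius_mm = NULL, seed = 1L) {
  if (n_patients < 1) stop_validation("n_patients must be >= 1")
  if (s_bladder < 0 || s_bladder > 0.5 || s_rectum < 0 || s_rectum > 0.5)
    stop_validation("sparing strengths must lie in [0, 0.5]")
  if (sigma < 0) stop_validation("sigma must be >= 0")
  ext <- c(n_slices, n_rows, n_cols) * spacing
  # default structure sizes scale with the grid so reduced-resolution
  # phantoms keep the same relative anatomy
  if (is.null(ptv_radius_mm)) ptv_radius_mm <- c(0.20, 0.14, 0.14) * ext
  if (is.null(bladder_radius_mm)) bladder_radius_mm <- c(0.22, 0.16, 0.16) * ext
  if (is.null(rectum_radius_mm)) rectum_radius_mm <- c(0.30, 0.07, 0.07) * ext
  for (r in list(ptv_radius_mm, bladder_radius_mm, rectum_radius_mm))
    if (any(r <= 0)) stop_validation("structure radii must be positive")
  if (any(ptv_radius_mm >= ext / 2) || any(bladder_radius_mm >= ext / 2))
    stop_validation("structure radii too large for the grid")
  structure(list(n_patients = as.integer(n_patients),
                 n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), spacing = as.double(spacing),
                 true_params = true_params, s_bladder = s_bladder,
                 s_rectum = s_rectum, tau_mm = tau_mm, h = h, sigma = sigma,
                 noise_kernel = as.integer(noise_kernel),
                 centre_jitter_mm = centre_jitter_mm,
                 radius_jitter = radius_jitter,
                 ptv_radius_mm = ptv_radius_mm,
                 bladder_radius_mm = bladder_radius_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 seed = as.integer(seed)), class = "phantom_config")
}

# voxel-centre coordinate arrays (mm) for a config's grid
grid_coords <- function(config) {
  z <- (seq_len(config$n_slices) - 0.5) * config$spacing[1]
  y <- (seq_len(config$n_rows) - 0.5) * config$spacing[2]
  x <- (seq_len(config$n_cols) - 0.5) * config$spacing[3]
  list(z = z, y = y, x = x)
}

ellipsoid_mask <- function(config, centre, radii) {
  co <- grid_coords(config)
  dz2 <- ((co$z - centre[1]) / radii[1])^2
  dy2 <- ((co$y - centre[2]) / radii[2])^2
  dx2 <- ((co$x - centre[3]) / radii[3])^2
  arr <- outer(outer(dz2, dy2, "+"), dx2, "+")
  array(as.double(arr <= 1), dim(arr))
}

#' Generate one phantom anatomy
#'
#' Body: a large elliptic cylinder. PTV: an ellipsoid near the grid centre,
#' slightly posterior (the prostate). Bladder: an ellipsoid anterior and
#' superior to the PTV. Rectum: a tube running along the slice axis
#' posterior to the PTV. Centres and radii are jittered per patient;
#' deterministic given `(config$seed, patient_index)`. Overlaps are carved
#' so the PTV, bladder and rectum are disjoint and inside the body.
#'
#' @param config a [phantom_config].
#' @param patient_index 1-based patient index.
#' @return a [structure_set].
#' @export
generate_anatomy <- function(config, patient_index) {
  ext <- c(config$n_slices, config$n_rows, config$n_cols) * config$spacing
  jit <- with_seed(derive_seed(config$seed, patient_index), list(
    centre = matrix(stats::runif(9, -config$centre_jitter_mm,
                                 config$centre_jitter_mm), 3, 3),
    radius = matrix(stats::runif(9, -config$radius_jitter,
                                 config$radius_jitter), 3, 3)))
  mid <- ext / 2
  co <- grid_coords(config)
  # body: elliptic cylinder over all slices
  by2 <- ((co$y - mid[2]) / (0.46 * ext[2]))^2
  bx2 <- ((co$x - mid[3]) / (0.46 * ext[3]))^2
  body_sl <- outer(by2, bx2, "+") <= 1
  body <- array(rep(as.double(body_sl), each = config$n_slices),
                c(config$n_slices, config$n_rows, config$n_cols))

  ptv_c <- c(mid[1], mid[2] + 0.06 * ext[2], mid[3]) + jit$centre[, 1]
  ptv_r <- config$ptv_radius_mm * (1 + jit$radius[, 1])
  bl_c <- c(mid[1] - 0.18 * ext[1], mid[2] - 0.22 * ext[2], mid[3]) +
    jit$centre[, 2]
  bl_r <- config$bladder_radius_mm * (1 + jit$radius[, 2])
  re_c <- c(mid[1] + 0.05 * ext[1], mid[2] + 0.30 * ext[2], mid[3]) +
    jit$centre[, 3]
  re_r <- config$rectum_radius_mm * (1 + jit$radius[, 3])

  sp <- config$spacing
  ptv <- ellipsoid_mask(config, ptv_c, ptv_r) * body
  bl <- ellipsoid_mask(config, bl_c, bl_r) * body * (1 - ptv)
  re <- ellipsoid_mask(config, re_c, re_r) * body * (1 - ptv) * (1 - bl)
  if (sum(ptv) == 0) stop_validation("generated PTV is empty; radii too small for the grid")
  structure_set(voxel_grid(ptv, sp), voxel_grid(bl, sp),
                voxel_grid(re, sp), voxel_grid(body, sp))
}

#' Priority grid over the Pareto surface
#'
#' Generates `n_plans` convex combinations of three bounding priority
#' vectors on a deterministic square grid: for
#' `(alpha, beta)` on the `sqrt(n_plans)`-point uniform grid over
#' `[0, 1]^2`, `p = alpha P1 + (1 - alpha) (beta P2 + (1 - beta) P3)`.
#' Duplicates at `alpha = 1` (where `p = P1` regardless of `beta`) are
#' retained so every plan keeps its grid coordinate.
#'
#' @param bounding 3 x 3 matrix of bounding priority vectors (rows), or a
#'   list of three [priority_vector]s. Defaults to one objective-dominant
#'   corner per objective: `(10,1,1)`, `(1,10,1)`, `(1,1,10)`.
#' @param n_plans number of plans; must be a perfect square (default 25).
#' @return data.frame with columns `alpha`, `beta`, `w_hi`, `w_bladder`,
#'   `w_rectum`, one row per plan in row-major `(alpha, beta)` order.
#' @export
priority_grid <- function(bounding = NULL, n_plans = 25L) {
  if (is.null(bounding))
    bounding <- rbind(c(10, 1, 1), c(1, 10, 1), c(1, 1, 10))
  if (is.list(bounding)) bounding <- do.call(rbind, lapply(bounding, as.double))
  if (!is.matrix(bounding) || any(dim(bounding) != c(3, 3)))
    stop_validation("bounding must be three 3-component priority vectors")
  if (any(bounding < 0)) stop_validation("bounding priorities must be nonnegative")
  if (any(duplicated(bounding))) stop_validation("bounding vectors must be pairwise distinct")
  side <- sqrt(n_plans)
  if (side != floor(side) || n_plans < 4)
    stop_validation("n_plans must be a perfect square >= 4 for the grid scheme")
  g <- seq(0, 1, length.out = side)
  rows <- list()
  for (a in g) for (b in g) {
    p <- a * bounding[1, ] + (1 - a) * (b * bounding[2, ] + (1 - b) * bounding[3, ])
    rows[[length(rows) + 1L]] <- c(a, b, p)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("alpha", "beta", "w_hi", "w_bladder", "w_rectum")
  out
}

# smoothed, standardized white-noise field (per-slice uniform smoothing)
smooth_noise_field <- function(config, k, seed) {
  arr <- with_seed(seed, array(stats::rnorm(config$n_slices * config$n_rows *
                                              config$n_cols),
                               c(config$n_slices, config$n_rows, config$n_cols)))
  g <- smooth_uniform(voxel_grid(arr, config$spacing), k)$values
  (g - mean(g)) / stats::sd(g)
}

#' Surrogate TPS dose for one plan
#'
#' Emulates an optimized, calculated and normalized clinical dose:
#' `dose = base * sparing * heterogeneity + noise`, then normalized so PTV
#' D95% equals 100% of prescription.
#' * `base` is the analytic initialization evaluated with the generator's
#'   true parameters (1.0 throughout the PTV).
#' * `sparing`, applied outside the PTV only, is
#'   `1 - sum_o s_o (w_o / sum(w)) exp(-d_o / tau)` over organs o in
#'   (bladder, rectum), `d_o` the in-plane distance to the organ: a higher
#'   organ priority lowers dose near that organ.
#' * `heterogeneity`, inside the PTV, is `1 + h g / (1 + w_hi)` with `g` a
#'   smooth zero-mean unit-variance field: a higher HI priority flattens the
#'   target dose.
#' * `noise` is uniform-kernel-smoothed white noise of amplitude `sigma`.
#'
#' Deterministic given `rng_seed`; plans of one patient should share the
#' seed so that their random fields coincide and trade-offs respond to the
#' priorities alone.
#'
#' @param structures a [structure_set].
#' @param priorities a [priority_vector].
#' @param config a [phantom_config].
#' @param rng_seed integer seed for the heterogeneity and noise fields.
#' @return normalized dose [voxel_grid] in fraction-of-prescription units.
#' @export
simulate_tps_dose <- function(structures, priorities, config, rng_seed) {
  priorities <- as_priority_vector(priorities)
  w <- unname(priorities)
  dm <- compute_distance_maps(structures)
  base <- init_dose(dm, do.call(init_params, as.list(config$true_params)))$values
  ptv <- structures$ptv$values != 0

  f <- w / sum(w)
  spar <- 1
  if (config$s_bladder > 0 || config$s_rectum > 0) {
    db <- inplane_distance_map(structures$bladder)
    dr <- inplane_distance_map(structures$rectum)
    eb <- exp(-db / config$tau_mm); eb[!is.finite(db)] <- 0
    er <- exp(-dr / config$tau_mm); er[!is.finite(dr)] <- 0
    spar <- 1 - config$s_bladder * f[2] * eb - config$s_rectum * f[3] * er
    spar[ptv] <- 1   # target coverage is protected, as the optimizer enforces
  }

  het <- 1
  if (config$h > 0) {
    g <- smooth_noise_field(config, max(3L, config$noise_kernel),
                            derive_seed(rng_seed, 1L, salt = 3L))
    g <- pmin(pmax(g, -2.5), 2.5)
    het <- array(1, dim(base))
    het[ptv] <- 1 + config$h * g[ptv] / (1 + w[1])
  }

  dose <- base * spar * het
  if (config$sigma > 0) {
    noise <- smooth_noise_field(config, config$noise_kernel,
                                derive_seed(rng_seed, 2L, salt = 5L))
    dose <- dose + config$sigma * noise
  }
  dose <- pmax(dose, 0)
  out <- normalize_to_d95(voxel_grid(dose, structures$body$spacing),
                          structures$ptv)
  out$values <- pmin(out$values, 1.5)
  out
}

#' Simulate an in-memory phantom cohort
#'
#' @param config a [phantom_config].
#' @param bounding,n_plans passed to [priority_grid()].
#' @param plan_grid optional explicit plan table (columns `alpha`, `beta`,
#'   `w_hi`, `w_bladder`, `w_rectum`), e.g. a subset of [priority_grid()]
#'   rows for cohorts with fewer plans per patient; overrides `n_plans`.
#' @param patient_indices which patients to realize (default all); patient
#'   `i` is identical whether or not the others are generated.
#' @return a cohort list (see [load_cohort()] for the format) whose plans
#'   carry surrogate reference doses and the priority-grid coordinates as
#'   attributes `alpha`/`beta`.
#' @export
simulate_cohort <- function(config, bounding = NULL, n_plans = 25L,
                            plan_grid = NULL,
                            patient_indices = seq_len(config$n_patients)) {
  pg <- if (is.null(plan_grid)) priority_grid(bounding, n_plans) else plan_grid
  lapply(patient_indices, function(i) {
    ss <- generate_anatomy(config, i)
    dose_seed <- derive_seed(config$seed, i, salt = 7L)
    plans <- lapply(seq_len(nrow(pg)), function(j) {
      pr <- priority_vector(pg$w_hi[j], pg$w_bladder[j], pg$w_rectum[j])
      d <- simulate_tps_dose(ss, pr, config, dose_seed)
      list(plan_id = sprintf("p%03d_plan%02d", i, j), priorities = pr,
           dose = d, alpha = pg$alpha[j], beta = pg$beta[j])
    })
    list(patient_id = sprintf("p%03d", i), structures = ss, plans = plans)
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes per-patient mask grids, per-plan surrogate doses and the cohort
#' manifest JSON (format documented in [load_plan()]). Regeneration with the
#' same config is byte-identical in values.
#'
#' @param config a [phantom_config].
#' @param out_dir output directory (created if missing).
#' @param bounding,n_plans passed to [priority_grid()].
#' @return the manifest path, invisibly.
#' @export
generate_cohort <- function(config, out_dir, bounding = NULL, n_plans = 25L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config, bounding, n_plans)
  patients <- lapply(cohort, function(pat) {
    pdir <- file.path(out_dir, pat$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    masks <- list()
    for (nm in c("ptv", "bladder", "rectum", "body")) {
      rel <- file.path(pat$patient_id, paste0(nm, ".nii.gz"))
      write_grid(pat$structures[[nm]], file.path(out_dir, rel))
      masks[[nm]] <- rel
    }
    plans <- lapply(pat$plans, function(pl) {
      rel <- file.path(pat$patient_id, paste0(pl$plan_id, "_dose.nii.gz"))
      write_grid(pl$dose, file.path(out_dir, rel))
      list(plan_id = pl$plan_id, priorities = unname(unclass(pl$priorities)),
           alpha = pl$alpha, beta = pl$beta, dose = rel)
    })
    list(patient_id = pat$patient_id, masks = masks, plans = plans)
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(patients = patients), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
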