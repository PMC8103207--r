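## Analytic dose initialization: PTV distance maps and the inverse-distance
## dose formula, plus fitting of its parameters to reference doses.

# Exact in-plane Euclidean distance (mm) from every voxel of one slice to the
# nearest set voxel of that slice. `mask_slice` is a rows x cols 0/1 matrix.
# Returns Inf where the slice contains no set voxel. Brute force over the
# set's voxel list, chunked over grid rows to bound memory.
inplane_distance_slice <- function(mask_slice, row_mm, col_mm, chunk = 2048L) {
  R <- nrow(mask_slice); C <- ncol(mask_slice)
  idx <- which(mask_slice != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(Inf, R, C))
  py <- idx[, 1] * row_mm
  px <- idx[, 2] * col_mm
  vy <- rep(seq_len(R), C) * row_mm
  vx <- rep(seq_len(C), each = R) * col_mm
  n <- R * C
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    dy <- outer(vy[start:end], py, "-")
    dx <- outer(vx[start:end], px, "-")
    d2 <- dy * dy + dx * dx
    out[start:end] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  matrix(out, R, C)
}

# In-plane distance map (mm) to a mask for every slice; Inf on slices with
# no mask voxel.
inplane_distance_map <- function(mask) {
  d <- grid_dim(mask)
  out <- array(Inf, d)
  for (s in seq_len(d[1])) {
    sl <- grid_slice(mask, s)
    if (any(sl != 0))
      out[s, , ] <- inplane_distance_slice(sl, mask$spacing[2], mask$spacing[3])
  }
  out
}

#' PTV distance maps
#'
#' Computes the two distance maps that drive the dose initialization:
#' `d_inplane`, the in-plane Euclidean distance (mm) from each voxel to the
#' nearest PTV voxel within the voxel's own slice, and `d_axial`, the
#' distance (mm) along the slice axis to the nearest slice in which the PTV
#' occupies the voxel's (row, col) position. Where the respective PTV set is
#' empty (no PTV in the slice, or the (row, col) column never meets the
#' PTV), the value is capped at the grid diagonal length.
#'
#' @param structures a [structure_set] with a non-empty PTV.
#' @return `list(d_inplane, d_axial)` of [voxel_grid]s, plus the cap `d_max`.
#' @export
compute_distance_maps <- function(structures) {
  if (!inherits(structures, "structure_set"))
    stop_validation("structures must be a structure_set")
  ptv <- structures$ptv
  if (sum(ptv$values) == 0) stop_validation("PTV mask is empty")
  d <- grid_dim(ptv)
  d_max <- grid_diagonal(ptv)

  din <- inplane_distance_map(ptv)
  din[!is.finite(din)] <- d_max

  # axial: 1-D two-pass scan along the slice axis, vectorized over (row, col)
  S <- d[1]; slice_mm <- ptv$spacing[1]
  dax <- array(Inf, d)
  dax[ptv$values != 0] <- 0
  if (S > 1) {
    for (s in 2:S) dax[s, , ] <- pmin(dax[s, , ], dax[s - 1, , ] + slice_mm)
    for (s in (S - 1):1) dax[s, , ] <- pmin(dax[s, , ], dax[s + 1, , ] + slice_mm)
  }
  dax[!is.finite(dax)] <- d_max

  list(d_inplane = voxel_grid(din, ptv$spacing),
       d_axial = voxel_grid(dax, ptv$spacing),
       d_max = d_max)
}

# Distances are rescaled by this factor (10 mm -> 1.0) before exponentiation
# so that fitted exponents act on O(1) quantities.
DIST_SCALE_MM <- 10

#' Initialization parameters
#'
#' @param a1,a2,a3,c strictly positive parameters of the initialization
#'   formula `Di = 1 / (1 + a1 * ISD1^a2 + c * ISD2^a3)`, where ISD1 is the
#'   in-plane and ISD2 the along-axis PTV distance in units of 10 mm.
#' @return named numeric vector of class `init_params`.
#' @export
init_params <- function(a1, a2, a3, c) {
  p <- c(a1 = check_scalar_number(a1, "a1", positive = TRUE),
         a2 = check_scalar_number(a2, "a2", positive = TRUE),
         a3 = check_scalar_number(a3, "a3", positive = TRUE),
         c = check_scalar_number(c, "c", positive = TRUE))
  structure(p, class = "init_params")
}

#' Analytic dose initialization
#'
#' Evaluates `Di = 1 / (1 + a1 * ISD1^a2 + c * ISD2^a3)` voxel-wise, with
#' both distances expressed in units of 10 mm. The result lies in (0, 1] and
#' equals 1 exactly on the PTV (both distances zero), decaying isotropically
#' with distance from the target — the dose shape of a ~360-degree arc.
#'
#' @param dmaps distance maps from [compute_distance_maps()].
#' @param params an [init_params].
#' @return a [voxel_grid] dose in fraction-of-prescription units.
#' @export
init_dose <- function(dmaps, params) {
  if (!inherits(params, "init_params")) params <- do.call(init_params, as.list(params))
  u <- dmaps$d_inplane$values / DIST_SCALE_MM
  v <- dmaps$d_axial$values / DIST_SCALE_MM
  di <- 1 / (1 + params[["a1"]] * u^params[["a2"]] + params[["c"]] * v^params[["a3"]])
  voxel_grid(di, dmaps$d_inplane$spacing)
}

#' Fit the initialization parameters to reference doses
#'
#' Minimises the masked RMSE between the analytic initialization and the
#' reference (TPS) doses jointly over all training plans, using Adam on the
#' log-parameters (which keeps all four parameters positive). The
#' initialization is always fitted before any network training.
#'
#' @param plans a list of [plan_record]s, each with a reference dose, or a
#'   cohort list as returned by [load_cohort()]/[simulate_cohort()].
#' @param opts list of fit options: `iterations` (default 1500), `lr`
#'   (default 0.05), `init` (starting `(a1, a2, a3, c)`, default all 1).
#' @return `list(params, rmse, trace)`: the fitted [init_params], the
#'   achieved masked RMSE in % of prescription, and the loss trace (%).
#' @export
fit_init_params <- function(plans, opts = list()) {
  if (length(plans) == 0) stop_validation("no training plans supplied")
  if (!is.null(plans[[1]]$plans)) plans <- cohort_plans(plans)
  o <- utils::modifyList(list(iterations = 1500L, lr = 0.05,
                              init = c(1, 1, 1, 1)), opts)
  # Pre-extract masked distance/reference vectors; distance maps are shared
  # across plans of one patient, so cache by patient id.
  dm_cache <- new.env(parent = emptyenv())
  us <- vs <- refs <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    if (is.null(pl$reference_dose))
      stop_validation("plan ", pl$plan_id, " has no reference dose")
    key <- pl$patient_id
    if (is.null(dm_cache[[key]]))
      dm_cache[[key]] <- compute_distance_maps(pl$structures)
    dm <- dm_cache[[key]]
    msk <- loss_mask(pl)$values != 0
    us[[i]] <- dm$d_inplane$values[msk] / DIST_SCALE_MM
    vs[[i]] <- dm$d_axial$values[msk] / DIST_SCALE_MM
    refs[[i]] <- pl$reference_dose$values[msk]
  }
  u <- unlist(us); v <- unlist(vs); ref <- unlist(refs)
  n <- length(ref)
  if (n == 0) stop_validation("loss mask is empty across all plans")
  lu <- ifelse(u > 0, log(u), 0)
  lv <- ifelse(v > 0, log(v), 0)

  fn <- function(theta, iter) {
    p <- exp(theta)  # (a1, a2, a3, c)
    tu <- p[1] * u^p[2]
    tv <- p[4] * v^p[3]
    di <- 1 / (1 + tu + tv)
    r <- di - ref
    L <- sqrt(mean(r * r))
    # d L / d di = r / (n * L); d di / d q = -di^2 for q = a1 u^a2 + c v^a3
    w <- if (L > 1e-12) -(r * di * di) / (n * L) else numeric(n)
    g <- c(sum(w * tu),            # wrt log a1  (d tu/d log a1 = tu)
           sum(w * tu * lu),       # wrt log a2  (d tu/d log a2 = tu*a2*log u -> via log-param: *a2)
           sum(w * tv * lv),       # wrt log a3
           sum(w * tv))            # wrt log c
    # log-parameterization chain: d/d log a2 = a2 * d/d a2
    g[2] <- g[2] * p[2]
    g[3] <- g[3] * p[3]
    list(loss = L, grad = g)
  }
  res <- adam_minimize(log(o$init), fn, o$iterations, lr = o$lr)
  p <- exp(res$theta)
  list(params = init_params(p[1], p[2], p[3], p[4]),
       rmse = 100 * fn(res$theta, 0L)$loss,
       trace = 100 * res$trace)
}
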