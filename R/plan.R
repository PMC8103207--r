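#' Structure set
#'
#' The four binary masks describing one patient's anatomy on a shared grid:
#' planning target volume (PTV), bladder, rectum and external body contour.
#' Masks are stored as 0/1 valued [voxel_grid]s so that priority scaling is
#' a plain multiplication.
#'
#' @param ptv,bladder,rectum,body 0/1 [voxel_grid]s on one shared grid.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(ptv, bladder, rectum, body) {
  masks <- list(ptv = ptv, bladder = bladder, rectum = rectum, body = body)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is_voxel_grid(m)) stop_validation(nm, " mask must be a voxel_grid")
    v <- m$values
    if (any(v != 0 & v != 1)) stop_validation(nm, " mask must be binary 0/1")
    if (!same_geometry(m, body))
      stop_validation("all masks must share grid shape and spacing")
  }
  if (sum(masks$ptv$values) == 0) stop_validation("PTV mask is empty")
  for (nm in c("ptv", "bladder", "rectum")) {
    if (any(masks[[nm]]$values > masks$body$values))
      stop_validation(nm, " mask is not a subset of the body mask")
  }
  structure(masks, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  d <- grid_dim(x$body)
  cat(sprintf("<structure_set> grid %d x %d x %d\n", d[1], d[2], d[3]))
  for (nm in names(x))
    cat(sprintf("  %-8s %d voxels\n", nm, sum(x[[nm]]$values)))
  invisible(x)
}

#' Optimization priority vector
#'
#' The weights placed on the three planning objectives during inverse
#' optimization: PTV homogeneity index (HI = D2% - D98%), bladder D25% and
#' rectum D25%. Weights are nonnegative and dimensionless; at least one must
#' be positive.
#'
#' @param w_hi,w_bladder,w_rectum nonnegative weights.
#' @return named numeric vector of class `priority_vector`.
#' @export
priority_vector <- function(w_hi, w_bladder, w_rectum) {
  w <- c(w_hi = check_scalar_number(w_hi, "w_hi", nonneg = TRUE),
         w_bladder = check_scalar_number(w_bladder, "w_bladder", nonneg = TRUE),
         w_rectum = check_scalar_number(w_rectum, "w_rectum", nonneg = TRUE))
  if (sum(w) <= 0) stop_validation("at least one priority must be > 0")
  structure(w, class = "priority_vector")
}

as_priority_vector <- function(x) {
  if (inherits(x, "priority_vector")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(priority_vector(x[[1]], x[[2]], x[[3]]))
  stop_validation("cannot interpret priorities; need 3 nonnegative numbers")
}

#' One patient-plan record
#'
#' Bundles a structure set, an optimization priority vector and (optionally)
#' a reference dose in fraction-of-prescription units.
#'
#' @param structures a [structure_set].
#' @param priorities a [priority_vector] (or length-3 numeric).
#' @param reference_dose optional [voxel_grid]; values must lie in `[0, 1.5]`.
#' @param patient_id,plan_id identifiers.
#' @return an object of class `plan_record`.
#' @export
plan_record <- function(structures, priorities, reference_dose = NULL,
                        patient_id = "p1", plan_id = "plan1") {
  if (!inherits(structures, "structure_set"))
    stop_validation("structures must be a structure_set")
  priorities <- as_priority_vector(priorities)
  if (!is.null(reference_dose)) {
    if (!is_voxel_grid(reference_dose))
      stop_validation("reference_dose must be a voxel_grid")
    if (!same_geometry(reference_dose, structures$body))
      stop_validation("reference_dose must share the structure grid")
    rng <- range(reference_dose$values)
    if (rng[1] < 0 || rng[2] > 1.5)
      stop_validation("reference dose values must lie in [0, 1.5] (fraction of prescription)")
  }
  structure(list(structures = structures, priorities = priorities,
                 reference_dose = reference_dose,
                 patient_id = patient_id, plan_id = plan_id),
            class = "plan_record")
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> patient %s, plan %s, priorities (%.3g, %.3g, %.3g)%s\n",
              x$patient_id, x$plan_id, x$priorities[1], x$priorities[2],
              x$priorities[3],
              if (is.null(x$reference_dose)) "" else ", with reference dose"))
  invisible(x)
}

#' Load one plan from a cohort manifest entry
#'
#' The cohort manifest is a JSON file of the form
#' `{"patients": [{"patient_id", "masks": {"ptv","bladder","rectum","body"},
#' "plans": [{"plan_id", "priorities": [w_hi, w_bladder, w_rectum],
#' "dose"}]}]}` with all grid paths relative to the manifest's directory.
#'
#' @param patient_entry one element of the manifest's `patients` list.
#' @param plan_index which plan of the patient to load.
#' @param base_dir directory against which mask/dose paths are resolved.
#' @param in_plane passed to [read_grid()].
#' @return a [plan_record].
#' @export
load_plan <- function(patient_entry, plan_index = 1L, base_dir = ".",
                      in_plane = c(128, 128)) {
  m <- patient_entry$masks
  for (nm in c("ptv", "bladder", "rectum", "body"))
    if (is.null(m[[nm]])) stop_validation("manifest entry is missing the ", nm, " mask")
  grids <- lapply(m[c("ptv", "bladder", "rectum", "body")], function(p)
    read_grid(file.path(base_dir, p), in_plane = in_plane))
  ss <- structure_set(grids$ptv, grids$bladder, grids$rectum, grids$body)
  plan <- patient_entry$plans[[plan_index]]
  if (is.null(plan)) stop_validation("no plan at index ", plan_index)
  pr <- as_priority_vector(as.double(unlist(plan$priorities)))
  dose <- NULL
  if (!is.null(plan$dose) && !is.na(plan$dose))
    dose <- read_grid(file.path(base_dir, plan$dose), in_plane = in_plane)
  plan_record(ss, pr, dose,
              patient_id = as.character(patient_entry$patient_id),
              plan_id = as.character(plan$plan_id))
}

#' Load a full cohort from a manifest
#'
#' @param manifest_path path to the manifest JSON written by
#'   [generate_cohort()].
#' @param in_plane passed to [read_grid()].
#' @return a list of patients; each patient is a list with `patient_id`,
#'   `structures` (a [structure_set]) and `plans` (a list of
#'   `list(plan_id, priorities, dose)`); the cohort format consumed by the
#'   training and cross-validation functions.
#' @export
load_cohort <- function(manifest_path, in_plane = c(128, 128)) {
  man <- jsonlite::read_json(manifest_path)
  base_dir <- dirname(manifest_path)
  lapply(man$patients, function(pe) {
    first <- load_plan(pe, 1L, base_dir, in_plane)
    plans <- lapply(seq_along(pe$plans), function(i) {
      pl <- load_plan(pe, i, base_dir, in_plane)
      out <- list(plan_id = pl$plan_id, priorities = pl$priorities,
                  dose = pl$reference_dose)
      # sampling-grid coordinates, when the manifest records them
      out$alpha <- pe$plans[[i]]$alpha
      out$beta <- pe$plans[[i]]$beta
      out
    })
    list(patient_id = first$patient_id, structures = first$structures,
         plans = plans)
  })
}

# Flatten a cohort (list of patients) into a list of plan_records.
cohort_plans <- function(cohort) {
  out <- list()
  for (pat in cohort) for (pl in pat$plans)
    out[[length(out) + 1L]] <- plan_record(pat$structures, pl$priorities,
                                           pl$dose, pat$patient_id, pl$plan_id)
  out
}
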