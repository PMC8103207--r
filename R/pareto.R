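## DVH/objective computation, D95% plan normalization, Pareto-surface
## construction over the priority-parameter grid, and the four surface
## distance metrics (matched RMSE, Hausdorff, APD, ANPD).

#' Dose at volume (DVH percentile)
#'
#' `Dx%` is the minimum dose received by the hottest `x%` of the structure's
#' volume: masked doses are sorted descending and element
#' `ceiling(x/100 * N)` (1-based) is taken, with no interpolation.
#'
#' @param dose dose [voxel_grid] in fraction-of-prescription units.
#' @param mask binary [voxel_grid], non-empty.
#' @param x volume percentage in `(0, 100]`.
#' @return dose in % of prescription.
#' @export
dvh_dose_at_volume <- function(dose, mask, x) {
  if (x <= 0 || x > 100) stop_validation("x must be in (0, 100]")
  v <- dose$values[mask$values != 0]
  if (length(v) == 0) stop_validation("mask selects no voxels")
  100 * sort(v, decreasing = TRUE)[ceiling(x / 100 * length(v))]
}

#' Normalize a dose so PTV D95% equals 100% of prescription
#'
#' @param dose dose [voxel_grid].
#' @param ptv binary PTV [voxel_grid]; its D95% must be positive.
#' @return the rescaled [voxel_grid]; applying the function twice is a
#'   fixed point.
#' @export
normalize_to_d95 <- function(dose, ptv) {
  d95 <- dvh_dose_at_volume(dose, ptv, 95) / 100
  if (d95 <= 1e-12) stop_validation("PTV D95% is zero; cannot normalize")
  voxel_grid(dose$values / d95, dose$spacing)
}

#' Plan objectives in Pareto space
#'
#' The three planning objectives: PTV homogeneity index `HI = D2% - D98%`,
#' bladder D25% and rectum D25%, all in % of prescription.
#'
#' @param dose dose [voxel_grid].
#' @param structures a [structure_set].
#' @return named numeric `(hi, bladder_d25, rectum_d25)`.
#' @export
compute_objectives <- function(dose, structures) {
  c(hi = dvh_dose_at_volume(dose, structures$ptv, 2) -
      dvh_dose_at_volume(dose, structures$ptv, 98),
    bladder_d25 = dvh_dose_at_volume(dose, structures$bladder, 25),
    rectum_d25 = dvh_dose_at_volume(dose, structures$rectum, 25))
}

#' Build a Pareto surface from sampled plans
#'
#' Vertices are the plans' objective vectors; the simplicial complex is a
#' triangulation constructed in the 2-D priority-parameter plane
#' `(alpha, beta)` of the sampling grid and carried to objective space
#' (triangulating in objective space directly can flip simplices on a
#' curved surface). A `k x k` parameter grid yields `2 (k-1)^2` triangles
#' (32 for the 5 x 5 grid); exactly 3 points yield a single triangle.
#'
#' @param vertices `n x 3` matrix (or data.frame) of objective vectors
#'   `(hi, bladder_d25, rectum_d25)`.
#' @param params `n x 2` matrix/data.frame of `(alpha, beta)` grid
#'   coordinates; optional when `n == 3`.
#' @param plan_ids optional identifiers carried with the vertices.
#' @return object of class `pareto_surface` with `vertices` (n x 3 matrix)
#'   and `simplices` (m x 3 index matrix).
#' @export
build_surface <- function(vertices, params = NULL, plan_ids = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 3)
    stop_validation("need >= 3 vertices with 3 objectives each")
  if (is.null(params)) {
    if (nrow(vertices) != 3)
      stop_validation("params (alpha, beta) required for more than 3 points")
    tri <- matrix(1:3, 1)
  } else {
    params <- as.matrix(params)
    if (nrow(params) != nrow(vertices) || ncol(params) != 2)
      stop_validation("params must be n x 2 (alpha, beta)")
    if (anyDuplicated(params))
      stop_validation("duplicated (alpha, beta) parameter coordinates")
    ua <- sort(unique(params[, 1])); ub <- sort(unique(params[, 2]))
    if (length(ua) < 2 || length(ub) < 2 ||
        length(ua) * length(ub) != nrow(params))
      stop_validation("params must form a full rectangular (alpha, beta) grid")
    vid <- matrix(NA_integer_, length(ua), length(ub))
    for (i in seq_len(nrow(params)))
      vid[match(params[i, 1], ua), match(params[i, 2], ub)] <- i
    if (anyNA(vid)) stop_validation("params must form a full rectangular grid")
    tri <- list()
    for (ai in seq_len(length(ua) - 1)) for (bi in seq_len(length(ub) - 1)) {
      tri[[length(tri) + 1L]] <- c(vid[ai, bi], vid[ai + 1, bi], vid[ai, bi + 1])
      tri[[length(tri) + 1L]] <- c(vid[ai + 1, bi], vid[ai + 1, bi + 1], vid[ai, bi + 1])
    }
    tri <- do.call(rbind, tri)
  }
  structure(list(vertices = vertices, simplices = tri, params = params,
                 plan_ids = plan_ids), class = "pareto_surface")
}

#' @export
print.pareto_surface <- function(x, ...) {
  cat(sprintf("<pareto_surface> %d vertices, %d simplices\n",
              nrow(x$vertices), nrow(x$simplices)))
  invisible(x)
}

#' Pareto-space RMSE between matched plan points
#'
#' Root of the mean squared 3-D Euclidean distance over matched pairs; the
#' three objective errors accumulate within each pair rather than being
#' averaged, so values run larger than dose-map RMSE.
#'
#' @param A,B `n x 3` matrices of matched objective vectors (same plan
#'   order).
#' @return RMSE in % of prescription.
#' @export
pareto_rmse <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || !all(dim(A) == dim(B)))
    stop_validation("A and B must be matched non-empty point sets")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Hausdorff distance between Pareto vertex sets
#'
#' `max( sup_{x in A} inf_{y in B} |x - y|, sup_{y in B} inf_{x in A}
#' |x - y| )`, computed over the sampled vertices.
#'
#' @param A,B non-empty point matrices (rows = points).
#' @return Hausdorff distance.
#' @export
pareto_hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop_validation("point sets must be non-empty")
  # per-dimension differences: exact zeros for coincident points
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in seq_len(ncol(A))) d2 <- d2 + outer(A[, k], B[, k], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' Average projected distance (APD) between matched point sets
#'
#' Projects each matched displacement `x_i - y_i` onto the direction of the
#' mean displacement and averages the projections; error components along
#' the surfaces cancel, leaving the net shift between the surfaces. If all
#' displacements are (numerically) zero the APD is 0; a non-zero
#' displacement set whose mean vanishes has no defined projection direction
#' and raises an error.
#'
#' @param A,B matched point matrices.
#' @return APD.
#' @export
pareto_apd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || !all(dim(A) == dim(B)))
    stop_validation("A and B must be matched non-empty point sets")
  d <- A - B
  if (max(abs(d)) < 1e-12) return(0)
  m <- colMeans(d)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12)
    stop_validation("mean displacement is zero; APD direction undefined")
  mean(d %*% (m / nm))
}

## --- point-to-triangle geometry -----------------------------------------

# squared distances from points P (n x 3) to segment ab
point_segment_dist2 <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(P, 2, a)
  t <- if (len2 < 1e-300) rep(0, nrow(P)) else pmin(pmax((ap %*% ab) / len2, 0), 1)
  diff <- ap - outer(as.vector(t), ab)
  rowSums(diff^2)
}

# exact squared distances from points P (n x 3) to triangle (a, b, c);
# degenerate triangles fall back to the minimum over the three edges
point_triangle_dist2 <- function(P, a, b, c) {
  ab <- b - a; ac <- c - a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  if (sum(n^2) < 1e-20 * max(sum(ab^2), sum(ac^2), 1e-300)^2) {
    return(pmin(point_segment_dist2(P, a, b), point_segment_dist2(P, a, c),
                point_segment_dist2(P, b, c)))
  }
  ap <- sweep(P, 2, a); bp <- sweep(P, 2, b); cp <- sweep(P, 2, c)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  d3 <- bp %*% ab; d4 <- bp %*% ac
  d5 <- cp %*% ab; d6 <- cp %*% ac
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- rep(NA_real_, nrow(P))
  reg <- function(cond) which(cond & is.na(out))
  i <- reg(d1 <= 0 & d2 <= 0)                       # vertex a
  out[i] <- rowSums(ap[i, , drop = FALSE]^2)
  i <- reg(d3 >= 0 & d4 <= d3)                      # vertex b
  out[i] <- rowSums(bp[i, , drop = FALSE]^2)
  i <- reg(d6 >= 0 & d5 <= d6)                      # vertex c
  out[i] <- rowSums(cp[i, , drop = FALSE]^2)
  i <- reg(vc <= 0 & d1 >= 0 & d3 <= 0)             # edge ab
  t <- d1[i] / (d1[i] - d3[i])
  out[i] <- rowSums((ap[i, , drop = FALSE] - outer(t, ab))^2)
  i <- reg(vb <= 0 & d2 >= 0 & d6 <= 0)             # edge ac
  t <- d2[i] / (d2[i] - d6[i])
  out[i] <- rowSums((ap[i, , drop = FALSE] - outer(t, ac))^2)
  i <- reg(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)  # edge bc
  t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
  out[i] <- rowSums((bp[i, , drop = FALSE] - outer(t, c - b))^2)
  i <- which(is.na(out))                            # face interior
  denom <- va[i] + vb[i] + vc[i]
  v <- vb[i] / denom; w <- vc[i] / denom
  q <- outer(v, ab) + outer(w, ac)
  out[i] <- rowSums((ap[i, , drop = FALSE] - q)^2)
  pmax(out, 0)
}

# minimum distance from each point to a surface's simplicial complex
points_to_complex <- function(P, surf) {
  best <- rep(Inf, nrow(P))
  V <- surf$vertices
  for (t in seq_len(nrow(surf$simplices))) {
    tri <- surf$simplices[t, ]
    best <- pmin(best, point_triangle_dist2(P, V[tri[1], ], V[tri[2], ], V[tri[3], ]))
  }
  sqrt(best)
}

# barycentric supersampling: >= density points per triangle
sample_complex <- function(surf, density) {
  L <- 1L
  while ((L + 1) * (L + 2) / 2 < density) L <- L + 1L
  bc <- list()
  for (i in 0:L) for (j in 0:(L - i))
    bc[[length(bc) + 1L]] <- c(i, j, L - i - j) / L
  bc <- do.call(rbind, bc)
  V <- surf$vertices
  do.call(rbind, lapply(seq_len(nrow(surf$simplices)), function(t) {
    tri <- surf$simplices[t, ]
    bc %*% V[tri, , drop = FALSE]
  }))
}

#' Average nearest-point distance (ANPD) between Pareto surfaces
#'
#' Supersamples each surface's simplicial complex on a barycentric grid
#' (at least `density` points per triangle), computes for every sampled
#' point the exact minimum distance to the other surface's complex
#' (point-to-triangle projection minimized over triangles), averages within
#' each direction and then averages the two directed means.
#'
#' @param surfA,surfB [build_surface()] objects with at least one simplex.
#' @param density sample points per triangle (default 105, a barycentric
#'   subdivision of level 13).
#' @return ANPD.
#' @export
pareto_anpd <- function(surfA, surfB, density = 105L) {
  if (density < 1) stop_validation("density must be >= 1")
  if (nrow(surfA$simplices) < 1 || nrow(surfB$simplices) < 1)
    stop_validation("both surfaces need at least one simplex")
  pa <- sample_complex(surfA, density)
  pb <- sample_complex(surfB, density)
  mean(c(mean(points_to_complex(pa, surfB)),
         mean(points_to_complex(pb, surfA))))
}

#' All four Pareto-surface metrics for one matched surface pair
#'
#' @param surfA,surfB matched [build_surface()] objects (same plan order).
#' @param density passed to [pareto_anpd()].
#' @return named numeric `(rmse, hausdorff, apd, anpd)`; all four are 0 for
#'   a surface compared with itself.
#' @export
pareto_metrics <- function(surfA, surfB, density = 105L) {
  c(rmse = pareto_rmse(surfA$vertices, surfB$vertices),
    hausdorff = pareto_hausdorff(surfA$vertices, surfB$vertices),
    apd = pareto_apd(surfA$vertices, surfB$vertices),
    anpd = pareto_anpd(surfA, surfB, density))
}
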