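## Patch features: priority scaling, uniform-kernel smoothing, atrous
## (dilated) 9x9 patch extraction, and per-voxel feature assembly.
##
## Feature vector layout (length 4 channels x 3 atrous sets x 81 + 3 = 975):
## for each atrous rate (1, 3, 10), for each channel in the fixed order
## (PTV, bladder, rectum, dose), the 81-element row-major patch; then the
## priority triplet (w_hi, w_bladder, w_rectum). Within one 9x9 patch the
## elements run row-major over row offsets {-4r..4r} (outer) and column
## offsets {-4r..4r} (inner); element 41 is the centre voxel.

#' Atrous patch specification
#'
#' @param rates atrous rates of the patch sets (voxel stride between
#'   samples); default `c(1, 3, 10)`.
#' @param kernels uniform smoothing kernel width applied before sampling at
#'   each rate; default equals the rate (1 = no smoothing), so every sampled
#'   voxel summarises the voxels the dilation skips.
#' @param patch_side side length of the square patch (odd), default 9.
#' @return list of class `atrous_spec`.
#' @export
atrous_spec <- function(rates = c(1, 3, 10), kernels = rates, patch_side = 9) {
  if (any(rates < 1)) stop_validation("atrous rates must be >= 1")
  if (length(kernels) != length(rates) || any(kernels < 1))
    stop_validation("one smoothing kernel (>= 1) per rate is required")
  if (patch_side %% 2 != 1) stop_validation("patch_side must be odd")
  structure(list(rates = as.integer(rates), kernels = as.integer(kernels),
                 patch_side = as.integer(patch_side)), class = "atrous_spec")
}

n_feature_cols <- function(spec, n_channels = 4L) {
  n_channels * length(spec$rates) * spec$patch_side^2 + 3L
}

#' Scale structure masks by their optimization priorities
#'
#' @param structures a [structure_set].
#' @param priorities a [priority_vector]; the PTV mask is scaled by `w_hi`,
#'   bladder by `w_bladder`, rectum by `w_rectum`.
#' @return named list of three scaled [voxel_grid]s.
#' @export
scale_masks <- function(structures, priorities) {
  if (!inherits(structures, "structure_set"))
    stop_validation("structures must be a structure_set")
  priorities <- as_priority_vector(priorities)
  list(ptv = voxel_grid(structures$ptv$values * priorities[[1]], structures$ptv$spacing),
       bladder = voxel_grid(structures$bladder$values * priorities[[2]], structures$bladder$spacing),
       rectum = voxel_grid(structures$rectum$values * priorities[[3]], structures$rectum$spacing))
}

# offsets of a width-k uniform window; for even k the anchor sits at the
# top-left of the central 2x2 (offsets -(k/2 - 1) .. k/2)
kernel_offsets <- function(k) {
  a <- if (k %% 2 == 1) (k + 1) %/% 2 else k %/% 2
  seq_len(k) - a
}

# 2-D uniform convolution of one slice matrix, zero-padded borders.
# adjoint = TRUE applies the transpose operator (offsets negated), needed
# for exact backpropagation through the smoothing step.
conv_uniform_slice <- function(m, k, adjoint = FALSE) {
  if (k == 1) return(m)
  off <- kernel_offsets(k)
  if (adjoint) off <- -off
  R <- nrow(m); C <- ncol(m)
  pad <- max(abs(off))
  P <- matrix(0, R + 2 * pad, C + 2 * pad)
  P[pad + seq_len(R), pad + seq_len(C)] <- m
  out <- matrix(0, R, C)
  for (di in off) for (dj in off)
    out <- out + P[pad + di + seq_len(R), pad + dj + seq_len(C)]
  out / (k * k)
}

#' Uniform-kernel smoothing of a voxel grid
#'
#' Per-slice 2-D convolution with a `k x k` kernel of uniform weights
#' `1/k^2`, zero-padded at the slice borders. `k = 1` is the identity. For
#' even `k` the kernel anchor is the top-left element of the central 2x2.
#'
#' @param grid a [voxel_grid].
#' @param k kernel width, `1 <= k <= 128`.
#' @return the smoothed [voxel_grid].
#' @export
smooth_uniform <- function(grid, k) {
  if (!is_voxel_grid(grid)) stop_validation("grid must be a voxel_grid")
  k <- as.integer(k)
  if (k < 1 || k > 128) stop_validation("kernel width must be in 1..128")
  out <- grid$values
  for (s in seq_len(dim(out)[1]))
    out[s, , ] <- conv_uniform_slice(grid_slice(grid, s), k)
  voxel_grid(out, grid$spacing)
}

#' Extract one atrous patch as an 81-element vector
#'
#' Samples the voxel's transverse slice at row/column offsets
#' `{-4r, -3r, ..., +4r}` around the voxel, row-major, with out-of-bounds
#' samples set to 0. Any pre-sampling smoothing is applied by the caller.
#'
#' @param grid a [voxel_grid].
#' @param voxel integer `(slice, row, col)` position.
#' @param rate atrous rate `r` (stride between samples).
#' @param patch_side patch side length (odd), default 9.
#' @return numeric vector of length `patch_side^2`.
#' @export
extract_patch <- function(grid, voxel, rate = 1L, patch_side = 9L) {
  d <- grid_dim(grid)
  if (any(voxel < 1) || any(voxel > d)) stop_validation("voxel outside grid")
  half <- (patch_side - 1L) %/% 2L
  sl <- grid_slice(grid, voxel[1])
  out <- numeric(patch_side^2)
  p <- 1L
  for (i in -half:half) {
    r <- voxel[2] + i * rate
    for (j in -half:half) {
      c <- voxel[3] + j * rate
      if (r >= 1 && r <= d[2] && c >= 1 && c <= d[3]) out[p] <- sl[r, c]
      p <- p + 1L
    }
  }
  out
}

## --- vectorized per-slice machinery -------------------------------------

# Cache of gather index matrices keyed by (R, C, rate, patch_side): an
# N x 81 matrix of linear indices into the zero-padded slice, where N = R*C
# voxels in column-major order.
.gather_cache <- new.env(parent = emptyenv())

gather_index <- function(R, C, rate, patch_side = 9L) {
  key <- paste(R, C, rate, patch_side, sep = "_")
  got <- .gather_cache[[key]]
  if (!is.null(got)) return(got)
  half <- (patch_side - 1L) %/% 2L
  pad <- half * rate
  PR <- R + 2L * pad
  rr <- rep(seq_len(R), C) + pad
  cc <- rep(seq_len(C), each = R) + pad
  idx <- matrix(0L, R * C, patch_side^2)
  p <- 1L
  for (i in -half:half) for (j in -half:half) {
    idx[, p] <- (cc + j * rate - 1L) * PR + (rr + i * rate)
    p <- p + 1L
  }
  out <- list(idx = idx, pad = pad, PR = PR, PC = C + 2L * pad)
  .gather_cache[[key]] <- out
  out
}

# slice matrix -> N x 81 patch matrix (voxels column-major over the slice)
slice_patches <- function(m, rate, patch_side = 9L) {
  gi <- gather_index(nrow(m), ncol(m), rate, patch_side)
  P <- matrix(0, gi$PR, gi$PC)
  P[gi$pad + seq_len(nrow(m)), gi$pad + seq_len(ncol(m))] <- m
  matrix(P[gi$idx], nrow(m) * ncol(m), patch_side^2)
}

# adjoint of slice_patches: N x 81 gradient -> slice-matrix gradient
# (contiguous block adds into the padded plane, one per patch offset)
slice_patches_adjoint <- function(g, R, C, rate, patch_side = 9L) {
  half <- (patch_side - 1L) %/% 2L
  pad <- half * rate
  P <- matrix(0, R + 2L * pad, C + 2L * pad)
  rr <- pad + seq_len(R); cc <- pad + seq_len(C)
  p <- 1L
  for (i in -half:half) for (j in -half:half) {
    P[rr + i * rate, cc + j * rate] <-
      P[rr + i * rate, cc + j * rate] + g[, p]
    p <- p + 1L
  }
  P[rr, cc]
}

# N x 243 dose-feature block for one slice: per rate, smooth then sample
slice_dose_features <- function(dose_slice, spec) {
  do.call(cbind, lapply(seq_along(spec$rates), function(ri) {
    sm <- conv_uniform_slice(dose_slice, spec$kernels[ri])
    slice_patches(sm, spec$rates[ri], spec$patch_side)
  }))
}

# adjoint of slice_dose_features: N x 243 gradient -> dose-slice gradient
slice_dose_features_adjoint <- function(g, R, C, spec) {
  np <- spec$patch_side^2
  out <- matrix(0, R, C)
  for (ri in seq_along(spec$rates)) {
    gb <- g[, (ri - 1L) * np + seq_len(np), drop = FALSE]
    gs <- slice_patches_adjoint(gb, R, C, spec$rates[ri], spec$patch_side)
    out <- out + conv_uniform_slice(gs, spec$kernels[ri], adjoint = TRUE)
  }
  out
}

# N x 729 structure-feature block for one slice of the scaled masks
slice_struct_features <- function(scaled, s, spec) {
  do.call(cbind, lapply(seq_along(spec$rates), function(ri) {
    do.call(cbind, lapply(scaled, function(g) {
      sm <- conv_uniform_slice(grid_slice(g, s), spec$kernels[ri])
      slice_patches(sm, spec$rates[ri], spec$patch_side)
    }))
  }))
}

# column index sets of the full 975-feature layout
feature_layout <- function(spec, n_channels = 4L) {
  np <- spec$patch_side^2
  nr <- length(spec$rates)
  blk <- n_channels * np
  struct_cols <- unlist(lapply(seq_len(nr), function(ri)
    (ri - 1L) * blk + seq_len((n_channels - 1L) * np)))
  dose_cols <- unlist(lapply(seq_len(nr), function(ri)
    (ri - 1L) * blk + (n_channels - 1L) * np + seq_len(np)))
  total <- nr * blk + 3L
  list(struct = struct_cols, dose = dose_cols,
       priorities = (total - 2L):total, total = total)
}

#' Assemble the full feature vector for one voxel
#'
#' Concatenates, for each atrous rate (default 1, 3, 10), the 81-element
#' patches of the priority-scaled PTV, bladder and rectum masks and of the
#' current dose map (each channel smoothed with the rate's kernel first),
#' followed by the priority triplet — 975 values for the default
#' specification. This is the reference per-voxel path; the network uses an
#' equivalent vectorized per-slice implementation.
#'
#' @param scaled_masks list of 3 scaled mask grids from [scale_masks()].
#' @param dose a [voxel_grid] dose map.
#' @param priorities a [priority_vector].
#' @param voxel integer `(slice, row, col)`.
#' @param spec an [atrous_spec].
#' @return numeric feature vector.
#' @export
assemble_features <- function(scaled_masks, dose, priorities, voxel,
                              spec = atrous_spec()) {
  priorities <- as_priority_vector(priorities)
  grids <- c(scaled_masks, list(dose = dose))
  for (g in grids) if (!same_geometry(g, dose))
    stop_validation("all grids must share shape and spacing")
  parts <- list()
  for (ri in seq_along(spec$rates)) {
    for (g in grids) {
      sm <- smooth_uniform(g, spec$kernels[ri])
      parts[[length(parts) + 1L]] <-
        extract_patch(sm, voxel, spec$rates[ri], spec$patch_side)
    }
  }
  c(unlist(parts), unname(priorities))
}
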