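# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / direct formula transcription, never the package's
# vectorized code paths.

tiny_config <- function(n_patients = 1, n_slices = 6, n_rows = 20,
                        n_cols = 20, seed = 42, ...) {
  phantom_config(n_patients = n_patients, n_slices = n_slices,
                 n_rows = n_rows, n_cols = n_cols, seed = seed, ...)
}

random_grid <- function(dims = c(3, 12, 12), spacing = c(3, 2, 2)) {
  voxel_grid(array(stats::rnorm(prod(dims)), dims), spacing)
}

# structure set with random blob masks on a small grid (body = everything)
random_structures <- function(dims = c(3, 12, 12), spacing = c(3, 2, 2)) {
  body <- array(1, dims)
  blob <- function(p) {
    m <- array(as.double(stats::runif(prod(dims)) < p), dims)
    m
  }
  ptv <- blob(0.08)
  ptv[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- 1
  bl <- blob(0.08) * (1 - ptv)
  re <- blob(0.08) * (1 - ptv) * (1 - bl)
  structure_set(voxel_grid(ptv, spacing), voxel_grid(bl, spacing),
                voxel_grid(re, spacing), voxel_grid(body, spacing))
}

# naive double-loop 2-D uniform convolution with zero padding; kernel anchor
# convention: offsets (1:k) - ((k+1) %/% 2) for odd k, (1:k) - k/2 for even k
oracle_conv <- function(m, k) {
  off <- if (k %% 2 == 1) seq_len(k) - (k + 1) %/% 2 else seq_len(k) - k %/% 2
  R <- nrow(m); C <- ncol(m)
  out <- matrix(0, R, C)
  for (r in seq_len(R)) for (c in seq_len(C)) {
    acc <- 0
    for (di in off) for (dj in off) {
      rr <- r + di; cc <- c + dj
      if (rr >= 1 && rr <= R && cc >= 1 && cc <= C) acc <- acc + m[rr, cc]
    }
    out[r, c] <- acc / k^2
  }
  out
}

# naive atrous patch by direct indexing
oracle_patch <- function(slice, r, c, rate) {
  out <- numeric(81)
  p <- 1
  for (i in -4:4) for (j in -4:4) {
    rr <- r + i * rate; cc <- c + j * rate
    if (rr >= 1 && rr <= nrow(slice) && cc >= 1 && cc <= ncol(slice))
      out[p] <- slice[rr, cc]
    p <- p + 1
  }
  out
}

# straight-line matrix arithmetic with explicit unit loops
oracle_block_forward <- function(f, bp) {
  n1 <- length(bp$b1); n2 <- length(bp$b2)
  h1 <- numeric(n1)
  for (u in seq_len(n1)) {
    a <- sum(f * bp$W1[, u]) + bp$b1[u]
    h1[u] <- if (a > 0) a else 0.2 * a
  }
  h2 <- numeric(n2)
  for (u in seq_len(n2)) {
    a <- sum(h1 * bp$W2[, u]) + bp$b2[u]
    h2[u] <- if (a > 0) a else 0.2 * a
  }
  z <- sum(h2 * bp$W3[, 1]) + bp$b3
  0.3 * z / (1 + abs(z))
}

# exhaustive PTV distance maps (loop over voxels x PTV voxel list)
oracle_distance_maps <- function(ptv_arr, spacing) {
  dims <- dim(ptv_arr)
  dmax <- sqrt(sum((dims * spacing)^2))
  idx <- which(ptv_arr != 0, arr.ind = TRUE)
  din <- array(dmax, dims); dax <- array(dmax, dims)
  for (s in seq_len(dims[1])) for (r in seq_len(dims[2])) for (c in seq_len(dims[3])) {
    ins <- idx[idx[, 1] == s, , drop = FALSE]
    if (nrow(ins) > 0)
      din[s, r, c] <- min(sqrt(((ins[, 2] - r) * spacing[2])^2 +
                               ((ins[, 3] - c) * spacing[3])^2))
    col <- idx[idx[, 2] == r & idx[, 3] == c, , drop = FALSE]
    if (nrow(col) > 0)
      dax[s, r, c] <- min(abs(col[, 1] - s)) * spacing[1]
  }
  list(d_inplane = din, d_axial = dax)
}

oracle_dvh <- function(dose_vals, mask_vals, x) {
  v <- sort(dose_vals[mask_vals != 0], decreasing = TRUE)
  100 * v[ceiling(x / 100 * length(v))]
}

oracle_masked_rmse <- function(pred, ref, mask) {
  acc <- 0; n <- 0
  for (i in seq_along(pred)) {
    if (mask[i] != 0) { acc <- acc + (pred[i] - ref[i])^2; n <- n + 1 }
  }
  100 * sqrt(acc / n)
}

oracle_hausdorff <- function(A, B) {
  dmin_ab <- apply(A, 1, function(a) min(apply(B, 1, function(b) sqrt(sum((a - b)^2)))))
  dmin_ba <- apply(B, 1, function(b) min(apply(A, 1, function(a) sqrt(sum((a - b)^2)))))
  max(max(dmin_ab), max(dmin_ba))
}

oracle_apd <- function(A, B) {
  d <- A - B
  m <- colMeans(d)
  u <- m / sqrt(sum(m^2))
  mean(apply(d, 1, function(x) sum(x * u)))
}

# dense point-cloud sampling of a triangle
oracle_tri_cloud <- function(V, n_side = 45) {
  pts <- list()
  for (i in 0:n_side) for (j in 0:(n_side - i)) {
    k <- n_side - i - j
    pts[[length(pts) + 1L]] <- (i * V[1, ] + j * V[2, ] + k * V[3, ]) / n_side
  }
  do.call(rbind, pts)
}

# point-cloud ANPD between two single-triangle surfaces
oracle_anpd_tri <- function(V1, V2, n_side = 45) {
  p1 <- oracle_tri_cloud(V1, n_side)
  p2 <- oracle_tri_cloud(V2, n_side)
  d2 <- function(P, Q) {
    m <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
    sqrt(pmax(m, 0))
  }
  m12 <- d2(p1, p2)
  mean(c(mean(apply(m12, 1, min)), mean(apply(m12, 2, min))))
}

# barycentric hull-membership check against three bounding vectors
in_priority_hull <- function(p, bounding) {
  M <- rbind(t(bounding), c(1, 1, 1))
  lam <- qr.solve(M, c(p, 1))
  all(lam > -1e-9)
}
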