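## Six-block voxel-wise residual network that sequentially updates the
## initialized dose map. Each block is a 3-layer fully connected net applied
## per voxel: two 100-unit leaky-ReLU layers and a single scaled-softsign
## output bounded in (-0.3, 0.3), added to the running dose estimate.

#' Leaky rectified linear unit
#'
#' `x` for `x > 0`, `0.2 x` otherwise.
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
lrelu <- function(x) pmax(x, 0) + 0.2 * pmin(x, 0)

dlrelu <- function(x) 0.2 + 0.8 * (x > 0)

#' Scaled softsign activation
#'
#' `0.3 x / (1 + |x|)`; output strictly inside `(-0.3, 0.3)`, which bounds
#' each block's per-voxel dose shift to under 30% of the prescription.
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
scaled_softsign <- function(x) 0.3 * x / (1 + abs(x))

dscaled_softsign <- function(x) 0.3 / (1 + abs(x))^2

#' Residual block parameters
#'
#' @param W1,b1 first layer (`n_features x hidden1` weights, `hidden1` biases).
#' @param W2,b2 second layer (`hidden1 x hidden2`, `hidden2`).
#' @param W3,b3 output layer (`hidden2 x 1`, scalar bias).
#' @return list of class `block_params`.
#' @export
block_params <- function(W1, b1, W2, b2, W3, b3) {
  if (ncol(W1) != length(b1) || ncol(W2) != length(b2) ||
      nrow(W2) != ncol(W1) || nrow(W3) != ncol(W2) ||
      ncol(W3) != 1L || length(b3) != 1L)
    stop_validation("inconsistent block parameter shapes")
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3),
            class = "block_params")
}

#' Glorot-uniform model initialization
#'
#' Samples every weight matrix from the uniform distribution bounded by
#' `±sqrt(6 / (fan_in + fan_out))`; biases start at zero. Deterministic
#' given the seed.
#'
#' @param seed integer RNG seed.
#' @param spec an [atrous_spec] defining the feature layout.
#' @param hidden widths of the two hidden layers, default `c(100, 100)`.
#' @param n_blocks number of residual blocks, default 6.
#' @param init fitted [init_params] to embed in the model (optional until
#'   training).
#' @return list of class `dose_model_params` with elements `blocks`
#'   (list of [block_params]), `init`, `spec`, `hidden`.
#' @export
init_model_glorot <- function(seed, spec = atrous_spec(), hidden = c(100, 100),
                              n_blocks = 6L, init = NULL) {
  nf <- n_feature_cols(spec)
  glorot <- function(fin, fout) {
    b <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -b, b), fin, fout)
  }
  blocks <- with_seed(seed, lapply(seq_len(n_blocks), function(i) {
    block_params(glorot(nf, hidden[1]), numeric(hidden[1]),
                 glorot(hidden[1], hidden[2]), numeric(hidden[2]),
                 glorot(hidden[2], 1L), 0)
  }))
  structure(list(blocks = blocks, init = init, spec = spec, hidden = hidden),
            class = "dose_model_params")
}

#' Forward pass of one residual block for one voxel
#'
#' `shift = SS(W3' lrelu(W2' lrelu(W1' f + b1) + b2) + b3)`; the result is
#' the block's dose shift for the voxel, bounded in `(-0.3, 0.3)`.
#'
#' @param features feature vector (length `nrow(W1)`).
#' @param params a [block_params].
#' @return scalar dose shift.
#' @export
block_forward <- function(features, params) {
  if (length(features) != nrow(params$W1))
    stop_validation("feature length does not match W1")
  h1 <- lrelu(drop(crossprod(params$W1, features)) + params$b1)
  h2 <- lrelu(drop(crossprod(params$W2, h1)) + params$b2)
  scaled_softsign(drop(crossprod(params$W3, h2)) + params$b3)
}

## --- stacked (vectorized) forward/backward ------------------------------

# Structure+priority feature stack for chosen slices of one plan:
# N_slice*length(slices) x 732 matrix, rows grouped by slice.
plan_struct_stack <- function(structures, priorities, slices, spec) {
  scaled <- scale_masks(structures, priorities)
  pr <- unname(as_priority_vector(priorities))
  do.call(rbind, lapply(slices, function(s) {
    S <- slice_struct_features(scaled, s, spec)
    cbind(S, matrix(pr, nrow(S), 3, byrow = TRUE))
  }))
}

# add a bias row-vector to every row of a matrix (avoids sweep's aperm)
add_bias <- function(A, b) A + rep(b, each = nrow(A))

# Forward through all blocks for stacked slices sharing one in-plane shape.
# SP: N_tot x 732 struct+priority stack; dose_mats: list of R x C matrices
# (one per stacked slice, same order). Returns final dose slices and, when
# keep_cache, the per-block activations needed for backpropagation.
stack_forward <- function(SP, dose_mats, params, keep_cache = FALSE) {
  spec <- params$spec
  lay <- feature_layout(spec)
  R <- nrow(dose_mats[[1]]); C <- ncol(dose_mats[[1]]); N <- R * C
  nsl <- length(dose_mats)
  cache <- if (keep_cache) vector("list", length(params$blocks)) else NULL
  d_cur <- dose_mats
  for (b in seq_along(params$blocks)) {
    bp <- params$blocks[[b]]
    W1sp <- bp$W1[c(lay$struct, lay$priorities), , drop = FALSE]
    W1d <- bp$W1[lay$dose, , drop = FALSE]
    D <- do.call(rbind, lapply(d_cur, slice_dose_features, spec))
    A1 <- add_bias(SP %*% W1sp + D %*% W1d, bp$b1)
    M1 <- dlrelu(A1)
    h1 <- A1 * M1
    A2 <- add_bias(h1 %*% bp$W2, bp$b2)
    M2 <- dlrelu(A2)
    h2 <- A2 * M2
    z <- drop(h2 %*% bp$W3) + bp$b3
    shift <- scaled_softsign(z)
    if (keep_cache)
      cache[[b]] <- list(h1 = h1, M1 = M1, h2 = h2, M2 = M2, z = z, D = D)
    d_cur <- lapply(seq_len(nsl), function(s)
      d_cur[[s]] + matrix(shift[(s - 1L) * N + seq_len(N)], R, C))
  }
  list(dose = d_cur, cache = cache)
}

# Backward pass: g_out is the list of per-slice gradients of the loss wrt
# the final dose slices. Returns per-block parameter gradients (same layout
# as params$blocks). Gradients flow through both the skip connection and the
# re-extracted dose-channel patches of later blocks.
stack_backward <- function(SP, params, fwd, g_out) {
  spec <- params$spec
  lay <- feature_layout(spec)
  nb <- length(params$blocks)
  R <- nrow(g_out[[1]]); C <- ncol(g_out[[1]]); N <- R * C
  nsl <- length(g_out)
  g_d <- g_out
  grads <- vector("list", nb)
  for (b in rev(seq_len(nb))) {
    bp <- params$blocks[[b]]
    ca <- fwd$cache[[b]]
    g_shift <- unlist(lapply(g_d, as.vector), use.names = FALSE)
    gz <- g_shift * dscaled_softsign(ca$z)
    gW3 <- crossprod(ca$h2, gz)
    gb3 <- sum(gz)
    gA2 <- tcrossprod(gz, bp$W3) * ca$M2
    gW2 <- crossprod(ca$h1, gA2)
    gb2 <- colSums(gA2)
    gA1 <- tcrossprod(gA2, bp$W2) * ca$M1
    gb1 <- colSums(gA1)
    gW1 <- matrix(0, lay$total, length(gb1))
    gW1[c(lay$struct, lay$priorities), ] <- crossprod(SP, gA1)
    gW1[lay$dose, ] <- crossprod(ca$D, gA1)
    grads[[b]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                       W3 = gW3, b3 = gb3)
    # gradient wrt the block's input dose: skip connection + feature path
    gD <- gA1 %*% t(bp$W1[lay$dose, , drop = FALSE])
    g_d <- lapply(seq_len(nsl), function(s) {
      g_d[[s]] + slice_dose_features_adjoint(
        gD[(s - 1L) * N + seq_len(N), , drop = FALSE], R, C, spec)
    })
  }
  grads
}

#' Full model forward pass for one plan
#'
#' Computes the analytic initialization from the plan's PTV distance maps,
#' then applies the six residual blocks, re-extracting the dose-channel
#' patches from the updated dose map before each block (structure-channel
#' patches are computed once, as the anatomy does not change).
#'
#' @param plan a [plan_record].
#' @param params a `dose_model_params` with fitted `init`.
#' @param clip clip the final dose to `[0, 1.5]` for reporting (default
#'   `TRUE`); internal bounds like the per-block 0.3 shift limit hold for
#'   the unclipped output.
#' @param slices optional integer subset of slices to evaluate (default all).
#' @return predicted dose [voxel_grid] (on `slices` only if given).
#' @export
model_forward <- function(plan, params, clip = TRUE, slices = NULL) {
  if (is.null(params$init)) stop_validation("model has no fitted init_params")
  dm <- compute_distance_maps(plan$structures)
  d0 <- init_dose(dm, params$init)
  d <- grid_dim(d0)
  if (is.null(slices)) slices <- seq_len(d[1])
  out <- array(0, c(length(slices), d[2], d[3]))
  # chunk slices so the structure-feature stack stays within ~100 MB
  per_slice <- d[2] * d[3] * 732 * 8
  chunk <- max(1L, as.integer(1e8 %/% per_slice))
  for (start in seq(1L, length(slices), by = chunk)) {
    idx <- slices[start:min(start + chunk - 1L, length(slices))]
    SP <- plan_struct_stack(plan$structures, plan$priorities, idx, params$spec)
    dose_mats <- lapply(idx, function(s) grid_slice(d0, s))
    fw <- stack_forward(SP, dose_mats, params)
    for (k in seq_along(idx))
      out[start + k - 1L, , ] <- fw$dose[[k]]
  }
  if (clip) out <- pmin(pmax(out, 0), 1.5)
  voxel_grid(out, d0$spacing)
}
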