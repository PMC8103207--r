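## Masked-RMSE loss, diagonal slice batching, network training with Adam,
## and the repeated k-fold / rotating-subset cross-validation harnesses.

#' Training loss mask for a plan
#'
#' A voxel enters the loss iff it lies inside the body contour and its slice
#' contains at least one voxel of a critical structure (PTV, bladder or
#' rectum).
#'
#' @param plan a [plan_record] (or anything with `$structures`).
#' @return binary [voxel_grid].
#' @export
loss_mask <- function(plan) {
  st <- plan$structures
  comb <- st$ptv$values + st$bladder$values + st$rectum$values
  has_struct <- apply(comb, 1, function(m) any(m != 0))
  mask <- st$body$values * as.double(has_struct[slice.index(comb, 1)])
  voxel_grid(mask, st$body$spacing)
}

#' Masked root-mean-square error between two dose maps
#'
#' `100 * sqrt(mean over masked voxels of (pred - ref)^2)`, in % of the
#' prescription dose.
#'
#' @param pred,ref dose [voxel_grid]s in fraction-of-prescription units.
#' @param mask binary [voxel_grid]; must select at least one voxel.
#' @return RMSE in % of prescription.
#' @export
masked_rmse <- function(pred, ref, mask) {
  if (!identical(dim(pred$values), dim(ref$values)) ||
      !identical(dim(pred$values), dim(mask$values)))
    stop_validation("pred, ref and mask must share one grid shape")
  sel <- mask$values != 0
  if (!any(sel)) stop_validation("mask selects no voxels")
  100 * sqrt(mean((pred$values[sel] - ref$values[sel])^2))
}

#' Training configuration
#'
#' @param iterations Adam steps (default 2000).
#' @param lr,beta1,beta2,eps Adam hyperparameters (defaults 0.001, 0.9,
#'   0.999, 1e-8).
#' @param batch_slices slices per batch; default (`NULL`) resolves to the
#'   median slice count of the cohort, the typical number of slices a
#'   patient has.
#' @param seed RNG seed controlling the patient visiting order and any
#'   weight initialization performed by callers.
#' @return list of class `train_config`.
#' @export
train_config <- function(iterations = 2000L, lr = 0.001, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, batch_slices = NULL,
                         seed = 1L) {
  if (iterations < 0) stop_validation("iterations must be >= 0")
  if (lr <= 0) stop_validation("lr must be > 0")
  structure(list(iterations = as.integer(iterations), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, batch_slices = batch_slices,
                 seed = as.integer(seed)), class = "train_config")
}

#' Diagonal slice batch schedule
#'
#' Deterministic given `(seed, iteration)`: patients are visited in a seeded
#' cyclic order and each batch slot advances one slice per iteration from a
#' staggered starting offset, so concurrent batch slices sit at different
#' depths in different patients and, over enough iterations, every
#' (patient, slice) pair is emitted. Each slot also cycles through the
#' patient's plans.
#'
#' @param cohort cohort list (see [load_cohort()]).
#' @param cfg a [train_config]; `batch_slices` defaults to the cohort's
#'   median slice count.
#' @param iteration 0-based training iteration.
#' @return data.frame with columns `patient`, `plan`, `slice` (indices).
#' @export
diagonal_batches <- function(cohort, cfg, iteration) {
  n <- length(cohort)
  if (n == 0) stop_validation("empty cohort")
  S <- vapply(cohort, function(p) grid_dim(p$structures$body)[1], integer(1))
  B <- cfg$batch_slices
  if (is.null(B)) B <- as.integer(stats::median(S))
  if (B > sum(S)) stop_validation("batch_slices exceeds total slice count")
  perm <- with_seed(cfg$seed, sample(n))
  j <- seq_len(B)
  rank <- ((j - 1L) %% n) + 1L
  pat <- perm[rank]
  Sp <- S[pat]
  slot_within <- (j - 1L) %/% n                      # 0-based per-patient slot
  m <- ((B - rank) %/% n) + 1L                       # slots for this patient
  stagger <- floor((rank - 1L) * Sp / n)
  off <- stagger + slot_within * ceiling(Sp / m)
  slice <- (off + iteration) %% Sp + 1L
  np <- vapply(cohort, function(p) length(p$plans), integer(1))[pat]
  plan <- (iteration + rank - 1L) %% np + 1L
  data.frame(patient = pat, plan = plan, slice = as.integer(slice))
}

## --- cohort preparation cache -------------------------------------------

# Per-patient precomputation shared across iterations: initialization dose,
# loss mask, lazily-built unscaled structure-feature stacks per slice.
prep_cohort <- function(cohort, init, spec) {
  lapply(cohort, function(pat) {
    dm <- compute_distance_maps(pat$structures)
    d0 <- init_dose(dm, init)
    mask <- loss_mask(pat)
    env <- new.env(parent = emptyenv())   # slice -> unscaled N x 729 matrix
    list(patient = pat, d0 = d0, mask = mask, struct_cache = env)
  })
}

# Unscaled structure features for one slice (cached), then scaled by the
# plan's priorities. Scaling commutes with smoothing and patch sampling
# because both are linear, so the cache is shared across plans.
struct_stack_for <- function(prep_pat, s, priorities, spec) {
  key <- as.character(s)
  S0 <- prep_pat$struct_cache[[key]]
  if (is.null(S0)) {
    unscaled <- list(ptv = prep_pat$patient$structures$ptv,
                     bladder = prep_pat$patient$structures$bladder,
                     rectum = prep_pat$patient$structures$rectum)
    S0 <- slice_struct_features(unscaled, s, spec)
    prep_pat$struct_cache[[key]] <- S0
  }
  w <- unname(as_priority_vector(priorities))
  np <- spec$patch_side^2
  S <- S0
  for (ri in seq_along(spec$rates)) for (ch in 1:3) {
    cols <- (ri - 1L) * 3L * np + (ch - 1L) * np + seq_len(np)
    S[, cols] <- S0[, cols] * w[ch]
  }
  cbind(S, matrix(w, nrow(S), 3, byrow = TRUE))
}

# Loss and analytic parameter gradients for one batch of (patient, plan,
# slice) rows. Slices whose loss mask is empty contribute nothing and are
# skipped exactly. Returns loss (fraction of prescription RMSE), per-block
# gradients, and the masked voxel count.
network_loss_grad <- function(prep, cohort, params, batch, want_grad = TRUE) {
  spec <- params$spec
  keep <- logical(nrow(batch))
  mask_sl <- ref_sl <- dose_sl <- vector("list", nrow(batch))
  SP_sl <- vector("list", nrow(batch))
  for (k in seq_len(nrow(batch))) {
    i <- batch$patient[k]; s <- batch$slice[k]
    msk <- grid_slice(prep[[i]]$mask, s)
    if (!any(msk != 0)) next
    pl <- cohort[[i]]$plans[[batch$plan[k]]]
    keep[k] <- TRUE
    mask_sl[[k]] <- msk
    ref_sl[[k]] <- grid_slice(pl$dose, s)
    dose_sl[[k]] <- grid_slice(prep[[i]]$d0, s)
    SP_sl[[k]] <- struct_stack_for(prep[[i]], s, pl$priorities, spec)
  }
  if (!any(keep))
    return(list(loss = 0, grads = zero_grads(params), n_masked = 0L))
  mask_sl <- mask_sl[keep]; ref_sl <- ref_sl[keep]; dose_sl <- dose_sl[keep]
  SP <- do.call(rbind, SP_sl[keep])
  fwd <- stack_forward(SP, dose_sl, params, keep_cache = want_grad)
  res <- mapply(function(p, r, m) (p - r) * m, fwd$dose, ref_sl, mask_sl,
                SIMPLIFY = FALSE)
  M <- sum(vapply(mask_sl, function(m) sum(m != 0), 0))
  ss <- sum(vapply(res, function(r) sum(r * r), 0))
  L <- sqrt(ss / M)
  if (!want_grad) return(list(loss = L, n_masked = M))
  g_out <- if (L > 1e-12) lapply(res, function(r) r / (M * L))
           else lapply(res, function(r) r * 0)
  grads <- stack_backward(SP, params, fwd, g_out)
  list(loss = L, grads = grads, n_masked = M)
}

zero_grads <- function(params) {
  lapply(params$blocks, function(bp)
    list(W1 = bp$W1 * 0, b1 = bp$b1 * 0, W2 = bp$W2 * 0, b2 = bp$b2 * 0,
         W3 = bp$W3 * 0, b3 = bp$b3 * 0))
}

flatten_blocks <- function(blocks)
  unlist(lapply(blocks, function(b) c(b$W1, b$b1, b$W2, b$b2, b$W3, b$b3)),
         use.names = FALSE)

unflatten_blocks <- function(theta, template) {
  pos <- 0L
  lapply(template, function(b) {
    out <- b
    for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
      n <- length(b[[nm]])
      v <- theta[pos + seq_len(n)]
      pos <<- pos + n
      out[[nm]] <- if (is.matrix(b[[nm]])) matrix(v, nrow(b[[nm]]), ncol(b[[nm]])) else v
    }
    out
  })
}

#' Train the residual network on a cohort
#'
#' Runs Adam on batch gradients of the masked RMSE for `cfg$iterations`
#' steps, with batches drawn by [diagonal_batches()]. The initialization
#' parameters must already be fitted (the initialization is always trained
#' before the network) and are held fixed.
#'
#' @param cohort cohort list with reference doses.
#' @param cfg a [train_config].
#' @param params0 starting `dose_model_params`; default Glorot-uniform
#'   initialization seeded by `cfg$seed`.
#' @param init fitted [init_params]; taken from `params0$init` if absent.
#' @return `list(params, trace)`: trained `dose_model_params` and the
#'   per-iteration training loss trace in % of prescription.
#' @export
train_network <- function(cohort, cfg = train_config(), params0 = NULL,
                          init = NULL) {
  if (is.null(params0))
    params0 <- init_model_glorot(cfg$seed, init = init)
  if (!is.null(init)) params0$init <- init
  if (is.null(params0$init)) stop_validation("init_params must be fitted before network training")
  S <- vapply(cohort, function(p) grid_dim(p$structures$body)[1], integer(1))
  if (is.null(cfg$batch_slices)) cfg$batch_slices <- as.integer(stats::median(S))
  prep <- prep_cohort(cohort, params0$init, params0$spec)
  params <- params0
  fn <- function(theta, iter) {
    params$blocks <- unflatten_blocks(theta, params0$blocks)
    batch <- diagonal_batches(cohort, cfg, iter)
    r <- network_loss_grad(prep, cohort, params, batch)
    list(loss = r$loss, grad = flatten_blocks(r$grads))
  }
  res <- adam_minimize(flatten_blocks(params0$blocks), fn, cfg$iterations,
                       lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2,
                       eps = cfg$eps)
  params$blocks <- unflatten_blocks(res$theta, params0$blocks)
  list(params = params, trace = 100 * res$trace)
}

# Predicted dose slices for one prepared patient and one priority vector,
# reusing the patient's cached structure features and initialization.
predict_prepped_slices <- function(prep_pat, priorities, params, slices) {
  spec <- params$spec
  SP <- do.call(rbind, lapply(slices, function(s)
    struct_stack_for(prep_pat, s, priorities, spec)))
  dose_mats <- lapply(slices, function(s) grid_slice(prep_pat$d0, s))
  stack_forward(SP, dose_mats, params)$dose
}

# Aggregate masked dose-map RMSE of a model (or of the initialization alone)
# over all plans of a cohort, evaluated on loss-mask voxels only.
cohort_rmse <- function(cohort, params, init_only = FALSE, prep = NULL) {
  if (is.null(prep)) prep <- prep_cohort(cohort, params$init, params$spec)
  ss <- 0; M <- 0
  per_plan <- list()
  for (i in seq_along(cohort)) {
    pat <- cohort[[i]]
    mask <- prep[[i]]$mask
    msl <- which(apply(mask$values, 1, function(m) any(m != 0)))
    if (length(msl) == 0) next
    mv <- lapply(msl, function(s) grid_slice(mask, s) != 0)
    for (pl in pat$plans) {
      pred <- if (init_only) lapply(msl, function(s) grid_slice(prep[[i]]$d0, s))
              else predict_prepped_slices(prep[[i]], pl$priorities, params, msl)
      r <- unlist(lapply(seq_along(msl), function(k) {
        (pred[[k]] - grid_slice(pl$dose, msl[k]))[mv[[k]]]
      }), use.names = FALSE)
      ss <- ss + sum(r * r); M <- M + length(r)
      per_plan[[length(per_plan) + 1L]] <-
        data.frame(patient_id = pat$patient_id, plan_id = pl$plan_id,
                   rmse = 100 * sqrt(mean(r * r)))
    }
  }
  list(rmse = 100 * sqrt(ss / M), per_plan = do.call(rbind, per_plan))
}

## --- cross-validation ----------------------------------------------------

#' Seeded fold assignments for repeated k-fold cross-validation
#'
#' @param n_patients cohort size.
#' @param k folds per repetition.
#' @param repetitions number of repetitions.
#' @param seed RNG seed.
#' @return list of length `repetitions`; each element an integer vector of
#'   fold labels in `1..k`, one per patient, with nearly equal fold sizes.
#' @export
cv_folds <- function(n_patients, k, repetitions, seed = 1L) {
  if (k > n_patients) stop_validation("k cannot exceed the number of patients")
  lapply(seq_len(repetitions), function(r)
    with_seed(derive_seed(seed, r, salt = 11L),
              rep_len(seq_len(k), n_patients)[sample(n_patients)]))
}

#' Rotating-subset cross-validation scheme
#'
#' With the cohort grouped into `n_subsets` enumerated subsets, validation
#' `j` trains on the cyclic window of `train_subsets` subsets starting at
#' `j` and tests on the remainder; every subset then appears in exactly
#' `train_subsets` training sets and `n_subsets - train_subsets` test sets.
#'
#' @param train_subsets number of training subsets per validation, in
#'   `1..(n_subsets - 1)`.
#' @param n_subsets total subsets (default 10).
#' @return list of `n_subsets` validations, each `list(train, test)` of
#'   subset indices.
#' @export
rotation_scheme <- function(train_subsets, n_subsets = 10L) {
  if (train_subsets < 1 || train_subsets >= n_subsets)
    stop_validation("train_subsets must be in 1..(n_subsets - 1)")
  lapply(seq_len(n_subsets), function(j) {
    idx <- ((j - 1L + seq_len(n_subsets) - 1L) %% n_subsets) + 1L
    list(train = idx[seq_len(train_subsets)],
         test = idx[(train_subsets + 1L):n_subsets])
  })
}

run_validation <- function(cohort, train_idx, test_idx, cfg, init_opts,
                           val_seed) {
  if (length(train_idx) == 0 || length(test_idx) == 0)
    stop_validation("a validation has an empty training or test set; ",
                    "use fewer subsets than patients")
  tr <- cohort[train_idx]
  te <- cohort[test_idx]
  fit <- fit_init_params(tr, init_opts)
  cfg$seed <- val_seed
  tres <- train_network(tr, cfg, init = fit$params)
  data.frame(train_rmse = cohort_rmse(tr, tres$params)$rmse,
             test_rmse = cohort_rmse(te, tres$params)$rmse,
             init_train_rmse = cohort_rmse(tr, tres$params, init_only = TRUE)$rmse,
             init_test_rmse = cohort_rmse(te, tres$params, init_only = TRUE)$rmse)
}

cv_report <- function(results, folds, scheme) {
  structure(list(results = results, folds = folds, scheme = scheme),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d validations\n", x$scheme, nrow(x$results)))
  cat(sprintf("  train RMSE %.3f +/- %.3f %%\n",
              mean(x$results$train_rmse), stats::sd(x$results$train_rmse)))
  cat(sprintf("  test  RMSE %.3f +/- %.3f %%\n",
              mean(x$results$test_rmse), stats::sd(x$results$test_rmse)))
  invisible(x)
}

#' Repeated k-fold cross-validation
#'
#' Per repetition, patients are shuffled (seeded) into `k` folds; the model
#' (initialization fit, then network training) is trained `k` times, each
#' tested on its held-out fold. Each patient is tested exactly once and
#' trained on exactly `k - 1` times per repetition.
#'
#' @param cohort cohort list with reference doses.
#' @param k folds (default 10).
#' @param repetitions repetitions (the full protocol uses 50).
#' @param cfg a [train_config].
#' @param init_opts options for [fit_init_params()].
#' @return a `cv_report` with per-fold train/test RMSE and fold assignments.
#' @export
crossval_repeated_kfold <- function(cohort, k = 10L, repetitions = 1L,
                                    cfg = train_config(),
                                    init_opts = list()) {
  folds <- cv_folds(length(cohort), k, repetitions, cfg$seed)
  rows <- list()
  for (r in seq_len(repetitions)) {
    for (f in seq_len(k)) {
      test_idx <- which(folds[[r]] == f)
      row <- run_validation(cohort, setdiff(seq_along(cohort), test_idx),
                            test_idx, cfg, init_opts,
                            derive_seed(cfg$seed, r * 1000L + f))
      row$repetition <- r; row$fold <- f
      rows[[length(rows) + 1L]] <- row
    }
  }
  cv_report(do.call(rbind, rows), folds,
            sprintf("%d-fold x %d repetitions", k, repetitions))
}

#' Rotating-subset cross-validation at a train:test ratio
#'
#' @param cohort cohort list with reference doses.
#' @param train_subsets training subsets per validation (8 reproduces an
#'   80%:20% split over 10 subsets).
#' @param n_subsets number of subsets (default 10).
#' @param cfg a [train_config].
#' @param init_opts options for [fit_init_params()].
#' @return a `cv_report`; `$folds` holds the subset assignment.
#' @export
crossval_ratio_rotation <- function(cohort, train_subsets,
                                    n_subsets = 10L, cfg = train_config(),
                                    init_opts = list()) {
  scheme <- rotation_scheme(train_subsets, n_subsets)
  assign <- with_seed(derive_seed(cfg$seed, 1L, salt = 17L),
                      rep_len(seq_len(n_subsets), length(cohort))[sample(length(cohort))])
  rows <- list()
  for (j in seq_along(scheme)) {
    tr <- which(assign %in% scheme[[j]]$train)
    te <- which(assign %in% scheme[[j]]$test)
    row <- run_validation(cohort, tr, te, cfg, init_opts,
                          derive_seed(cfg$seed, j, salt = 23L))
    row$validation <- j
    rows[[length(rows) + 1L]] <- row
  }
  cv_report(do.call(rbind, rows), assign,
            sprintf("rotating %d:%d of %d subsets", train_subsets,
                    n_subsets - train_subsets, n_subsets))
}
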