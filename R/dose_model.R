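#' Control parameters for [dose_model()]
#'
#' @param iterations,lr,beta1,beta2,eps,batch_slices,seed network training
#'   settings; see [train_config()].
#' @param init_iterations,init_lr,init_start settings for the
#'   initialization-parameter fit ([fit_init_params()]).
#' @param spec an [atrous_spec]; default rates 1/3/10 with matching kernels.
#' @param hidden hidden-layer widths, default `c(100, 100)`.
#' @param n_blocks residual blocks, default 6.
#' @return list of class `dose_model_control`.
#' @export
dose_model_control <- function(iterations = 2000L, lr = 0.001, beta1 = 0.9,
                               beta2 = 0.999, eps = 1e-8, batch_slices = NULL,
                               seed = 1L, init_iterations = 1500L,
                               init_lr = 0.05, init_start = c(1, 1, 1, 1),
                               spec = atrous_spec(), hidden = c(100, 100),
                               n_blocks = 6L) {
  structure(list(train = train_config(iterations, lr, beta1, beta2, eps,
                                      batch_slices, seed),
                 init_opts = list(iterations = init_iterations, lr = init_lr,
                                  init = init_start),
                 spec = spec, hidden = hidden, n_blocks = as.integer(n_blocks)),
            class = "dose_model_control")
}

#' Fit the priority-conditioned dose-prediction model
#'
#' Two-stage fit on a cohort of plans with reference doses: first the four
#' parameters of the analytic dose initialization are fitted by masked RMSE
#' over all training plans, then the six-block voxel-wise residual network
#' is trained with Adam on diagonally sampled slice batches to predict the
#' shift between the initialization and the reference dose.
#'
#' @param cohort a cohort list ([load_cohort()], [simulate_cohort()]) whose
#'   plans all carry reference doses.
#' @param control a [dose_model_control()].
#' @return an object of class `dose_model` with components `params`
#'   (initialization + network weights), `init_rmse` (% RMSE of the fitted
#'   initialization alone on the training cohort), `trace` (per-iteration
#'   training loss, %), `control` and the training `cohort`.
#' @seealso [predict.dose_model()], [residuals.dose_model()]
#' @examples
#' \donttest{
#' cfg <- phantom_config(n_patients = 2, n_slices = 8, n_rows = 24,
#'                       n_cols = 24, seed = 7)
#' cohort <- simulate_cohort(cfg, n_plans = 4)
#' fit <- dose_model(cohort, dose_model_control(iterations = 5, hidden = c(8, 8),
#'                                              init_iterations = 50))
#' print(fit)
#' }
#' @export
dose_model <- function(cohort, control = dose_model_control()) {
  stopifnot(length(cohort) >= 1)
  init_fit <- fit_init_params(cohort, control$init_opts)
  params0 <- init_model_glorot(control$train$seed, spec = control$spec,
                               hidden = control$hidden,
                               n_blocks = control$n_blocks,
                               init = init_fit$params)
  tr <- train_network(cohort, control$train, params0)
  structure(list(params = tr$params, init_fit = init_fit,
                 init_rmse = init_fit$rmse, trace = tr$trace,
                 control = control, cohort = cohort,
                 call = match.call()), class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  p <- x$params$init
  cat("Priority-conditioned VMAT dose-prediction model\n")
  cat(sprintf("  initialization: a1 = %.4g, a2 = %.4g, a3 = %.4g, c = %.4g (RMSE %.2f%%)\n",
              p[["a1"]], p[["a2"]], p[["a3"]], p[["c"]], x$init_rmse))
  cat(sprintf("  network: %d residual blocks, hidden %s, %d features\n",
              length(x$params$blocks), paste(x$params$hidden, collapse = "/"),
              nrow(x$params$blocks[[1]]$W1)))
  if (length(x$trace))
    cat(sprintf("  trained %d iterations; final batch RMSE %.2f%%\n",
                length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
coef.dose_model <- function(object, ...) unclass(object$params$init)

#' @export
summary.dose_model <- function(object, ...) {
  ev <- cohort_rmse(object$cohort, object$params)
  out <- list(model = object, train_rmse = ev$rmse, per_plan = ev$per_plan,
              init_rmse = object$init_rmse)
  class(out) <- "summary.dose_model"
  out
}

#' @export
print.summary.dose_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training-cohort dose-map RMSE: %.2f%% (initialization alone: %.2f%%)\n",
              x$train_rmse, x$init_rmse))
  invisible(x)
}

#' Predict dose distributions
#'
#' @param object a fitted [dose_model()].
#' @param newdata a [plan_record], a single patient entry (with
#'   `$structures` and `$plans`), or a cohort list; reference doses are not
#'   required.
#' @param clip clip predictions to `[0, 1.5]` (default `TRUE`).
#' @param ... unused.
#' @return a [voxel_grid] for a single plan, otherwise a list of predicted
#'   grids named by `patient_id/plan_id`.
#' @export
predict.dose_model <- function(object, newdata = NULL, clip = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$cohort
  if (inherits(newdata, "plan_record"))
    return(model_forward(newdata, object$params, clip = clip))
  if (!is.null(newdata$structures)) newdata <- list(newdata)
  out <- list()
  for (pat in newdata) for (pl in pat$plans) {
    plan <- plan_record(pat$structures, pl$priorities, NULL,
                        pat$patient_id, pl$plan_id)
    out[[paste(pat$patient_id, pl$plan_id, sep = "/")]] <-
      model_forward(plan, object$params, clip = clip)
  }
  out
}

#' Residual dose errors on loss-mask voxels
#'
#' @param object a fitted [dose_model()].
#' @param cohort cohort to evaluate (default: the training cohort).
#' @param ... unused.
#' @return data.frame of per-plan masked dose-map RMSE (% of prescription),
#'   with the aggregate RMSE as attribute `"rmse"`.
#' @export
residuals.dose_model <- function(object, cohort = NULL, ...) {
  if (is.null(cohort)) cohort <- object$cohort
  ev <- cohort_rmse(cohort, object$params)
  structure(ev$per_plan, rmse = ev$rmse)
}

#' Plot the training loss trace
#'
#' @param x a fitted [dose_model()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.dose_model <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "iteration", ylab = "batch masked RMSE (%)",
                 main = "dose_model training loss", ...)
  graphics::abline(h = x$init_rmse, lty = 2)
  invisible(x)
}

#' Predicted Pareto surface for one patient
#'
#' Predicts doses for every priority combination of a sampling grid,
#' evaluates the three objectives and assembles the surface over the
#' `(alpha, beta)` parameter grid.
#'
#' @param object a fitted [dose_model()].
#' @param patient a patient entry with `$structures`.
#' @param grid priority grid data.frame from [priority_grid()].
#' @return a [build_surface()] object.
#' @export
predict_pareto_surface <- function(object, patient, grid = priority_grid()) {
  params <- object$params
  prep <- prep_cohort(list(patient), params$init, params$spec)[[1]]
  # objectives only involve structure voxels, all of which sit on slices
  # containing structures; restrict prediction to those slices
  msl <- which(apply(prep$mask$values, 1, function(m) any(m != 0)))
  sp <- patient$structures$body$spacing
  sub <- function(g) voxel_grid(g$values[msl, , , drop = FALSE], sp)
  sub_ss <- structure_set(sub(patient$structures$ptv),
                          sub(patient$structures$bladder),
                          sub(patient$structures$rectum),
                          sub(patient$structures$body))
  verts <- t(vapply(seq_len(nrow(grid)), function(j) {
    pr <- priority_vector(grid$w_hi[j], grid$w_bladder[j], grid$w_rectum[j])
    pred <- predict_prepped_slices(prep, pr, params, msl)
    arr <- array(0, c(length(msl), dim(pred[[1]])))
    for (k in seq_along(msl)) arr[k, , ] <- pred[[k]]
    compute_objectives(voxel_grid(pmin(pmax(arr, 0), 1.5), sp), sub_ss)
  }, numeric(3)))
  build_surface(verts, grid[, c("alpha", "beta")])
}

#' Reference Pareto surface from a patient's stored plans
#'
#' @param patient a patient entry whose plans carry doses and `alpha`/`beta`
#'   grid coordinates (as produced by [simulate_cohort()]).
#' @return a [build_surface()] object.
#' @export
reference_pareto_surface <- function(patient) {
  verts <- t(vapply(patient$plans, function(pl)
    compute_objectives(pl$dose, patient$structures), numeric(3)))
  params <- cbind(alpha = vapply(patient$plans, function(pl) pl$alpha, 0),
                  beta = vapply(patient$plans, function(pl) pl$beta, 0))
  build_surface(verts, params,
                plan_ids = vapply(patient$plans, function(pl) pl$plan_id, ""))
}
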