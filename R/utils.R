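#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index; stays within 32-bit range.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 1e6) * 1009 + as.double(index) * 7919 + salt * 104729
  as.integer(s %% 2147483647) + 1L
}

stop_validation <- function(...) {
  stop(structure(class = c("paretodose_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (positive && x <= 0) stop_validation(name, " must be > 0")
  if (nonneg && x < 0) stop_validation(name, " must be >= 0")
  as.double(x)
}

#' Adam optimizer on a flat parameter vector
#'
#' Minimises `fn(theta)` where `fn` returns `list(loss = , grad = )`, using
#' the Adam update with the usual bias correction. Used both for fitting the
#' dose-initialization parameters and for training the residual network.
#'
#' @param theta0 numeric start vector.
#' @param fn function of `(theta, iteration)` returning `list(loss, grad)`;
#'   `iteration` is 0-based.
#' @param iterations number of update steps (0 returns `theta0` untouched).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return `list(theta, trace)` with the per-iteration loss trace.
#' @keywords internal
adam_minimize <- function(theta0, fn, iterations,
                          lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  theta <- as.double(theta0)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  trace <- numeric(iterations)
  if (iterations > 0) {
    for (t in seq_len(iterations)) {
      res <- fn(theta, t - 1L)
      g <- res$grad
      trace[t] <- res$loss
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(theta = theta, trace = trace)
}
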