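#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximization for a `K`-component univariate Gaussian mixture.
#' Initialization is deterministic and quantile-based: component means start
#' at the `(k - 1/2) / K` sample quantiles, variances at the pooled sample
#' variance, weights uniform. Variances are floored at
#' `var_floor` (default `1e-6` times the sample variance) to prevent
#' degenerate collapse; any flooring is flagged.
#'
#' @param values numeric sample (at least `2 K` points).
#' @param K number of components, `>= 1`.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param var_floor variance floor; `NULL` for the data-driven default.
#' @return List of class `t1gad_gmm`: `K`, `weights`, `means`, `variances`,
#'   `log_likelihood` (trace over iterations), `converged`,
#'   `variance_floored`, `n_iter`.
#' @export
fit_gmm_1d <- function(values, K = 2L, tol = 1e-8, max_iter = 200L,
                       var_floor = NULL) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (n < 2L * K) stop("need at least 2*K data points", call. = FALSE)

  v_all <- stats::var(values) * (n - 1) / n   # population variance
  if (is.null(var_floor)) var_floor <- max(1e-6 * v_all, 1e-12)

  if (K == 1L || v_all == 0) {
    # closed form (or degenerate constant sample)
    mu <- mean(values)
    s2 <- max(v_all, var_floor)
    ll <- sum(stats::dnorm(values, mu, sqrt(s2), log = TRUE))
    fit <- list(K = 1L, weights = 1, means = mu, variances = s2,
                log_likelihood = ll, converged = TRUE,
                variance_floored = v_all < var_floor, n_iter = 0L)
    class(fit) <- "t1gad_gmm"
    return(fit)
  }

  mu <- as.numeric(stats::quantile(values, (seq_len(K) - 0.5) / K,
                                   type = 7, names = FALSE))
  s2 <- rep(max(v_all, var_floor), K)
  w <- rep(1 / K, K)

  ll_trace <- numeric(0)
  floored <- FALSE
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E step via log-sum-exp
    logd <- vapply(seq_len(K), function(k) {
      log(w[k]) + stats::dnorm(values, mu[k], sqrt(s2[k]), log = TRUE)
    }, numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)

    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    s2 <- colSums(resp * outer(values, mu, "-")^2) / nk
    if (any(s2 < var_floor)) {
      floored <- TRUE
      s2 <- pmax(s2, var_floor)
    }
  }
  fit <- list(K = as.integer(K), weights = w, means = mu, variances = s2,
              log_likelihood = ll_trace, converged = converged,
              variance_floored = floored, n_iter = it)
  class(fit) <- "t1gad_gmm"
  fit
}

#' @export
print.t1gad_gmm <- function(x, ...) {
  cat(sprintf("<t1gad_gmm> K = %d, converged: %s (%d iterations)\n",
              x$K, x$converged, x$n_iter))
  for (k in seq_len(x$K)) {
    cat(sprintf("  comp %d: w = %.3f, mean = %.4g, sd = %.4g\n",
                k, x$weights[k], x$means[k], sqrt(x$variances[k])))
  }
  invisible(x)
}

#' Posterior component responsibilities of a fitted 1-D mixture
#'
#' @param model a [fit_gmm_1d()] fit.
#' @param values numeric vector.
#' @return Matrix `length(values) x K` of posterior probabilities.
#' @export
gmm_responsibilities <- function(model, values) {
  n <- length(values)
  logd <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) +
      stats::dnorm(values, model$means[k], sqrt(model$variances[k]), log = TRUE)
  }, numeric(n))
  if (n == 1L) logd <- matrix(logd, nrow = 1L)
  m <- apply(logd, 1L, max)
  lse <- m + log(rowSums(exp(logd - m)))
  exp(logd - lse)
}
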