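#' Negative binomial parameters
#'
#' Container for the `(n, p)` parameterization of the negative binomial in
#' which the probability mass at count `k` is
#' \deqn{P(k \mid n, p) = \binom{k + n - 1}{n - 1} p^n (1-p)^k,}
#' generalized to real `n > 0` through the gamma function. Under this
#' convention the mean is `n (1 - p) / p` and the variance `n (1 - p) / p^2`,
#' so the distribution is always overdispersed (variance > mean). This matches
#' `stats::dnbinom(k, size = n, prob = p)`.
#'
#' @param n Dispersion/size parameter, real `> 0`.
#' @param p Success probability in `(0, 1)`.
#' @return An object of class `nb_params`.
#' @examples
#' th <- nb_params(2, 0.7)
#' nb_mean(th)
#' @export
nb_params <- function(n, p) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0) {
    stop("`n` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single number in (0, 1)", call. = FALSE)
  }
  structure(list(n = as.numeric(n), p = as.numeric(p)), class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("<nb_params> n = %.6g, p = %.6g (mean %.4g)\n",
              x$n, x$p, nb_mean(x)))
  invisible(x)
}

#' Negative binomial probability mass function
#'
#' @param k Vector of nonnegative integer counts.
#' @param params An [nb_params()] object.
#' @return Probabilities in `[0, 1]`, one per element of `k`.
#' @seealso [nb_logpmf()] for the numerically safe log form.
#' @export
nb_pmf <- function(k, params) {
  stopifnot(inherits(params, "nb_params"))
  assert_counts(k, "k")
  stats::dnbinom(k, size = params$n, prob = params$p)
}

#' Negative binomial log probability mass function
#'
#' Computed through the log-gamma function (never as `log(nb_pmf())`), so it
#' stays finite far into the tail where the PMF underflows.
#'
#' @inheritParams nb_pmf
#' @return Log-probabilities, one per element of `k`.
#' @export
nb_logpmf <- function(k, params) {
  stopifnot(inherits(params, "nb_params"))
  assert_counts(k, "k")
  stats::dnbinom(k, size = params$n, prob = params$p, log = TRUE)
}

#' Mean of a negative binomial
#' @inheritParams nb_pmf
#' @return `n (1 - p) / p`.
#' @export
nb_mean <- function(params) {
  stopifnot(inherits(params, "nb_params"))
  params$n * (1 - params$p) / params$p
}

#' Median of a negative binomial
#'
#' The smallest integer `m` whose CDF reaches 0.5. Component labels of the
#' fitted mixture are assigned by comparing medians, the higher-median
#' component being the signal.
#'
#' @inheritParams nb_pmf
#' @return A nonnegative integer.
#' @export
nb_median <- function(params) {
  stopifnot(inherits(params, "nb_params"))
  stats::qnbinom(0.5, size = params$n, prob = params$p)
}

#' Optimizer settings for maximum-likelihood fits
#'
#' @param maxit Maximum number of objective evaluations/iterations passed to
#'   [stats::optim()]. Default 500 for single-distribution fits; mixture
#'   drivers raise it.
#' @param reltol Relative convergence tolerance on the negative
#'   log-likelihood. Default `1e-8`.
#' @param method Optimizer, default the derivative-free `"Nelder-Mead"`
#'   simplex. All fits run on transformed coordinates (`log n`, `logit p`,
#'   `logit omega`) so box constraints hold by construction and any
#'   `stats::optim` method is usable.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxit = 500L, reltol = 1e-8, method = "Nelder-Mead") {
  stopifnot(maxit >= 1, reltol > 0)
  structure(list(maxit = as.integer(maxit), reltol = reltol, method = method),
            class = "fit_control")
}

# Shared constructor for per-fit diagnostics; AIC/BIC per their definitions.
fit_diagnostics <- function(nll, n_free, n_obs, converged, iterations) {
  structure(list(
    nll = nll,
    aic = 2 * n_free + 2 * nll,
    bic = n_free * log(n_obs) + 2 * nll,
    n_free = as.integer(n_free),
    sample_size = as.integer(n_obs),
    converged = isTRUE(converged),
    iterations = as.integer(iterations)
  ), class = "fit_diagnostics")
}

#' Maximum-likelihood fit of a single negative binomial
#'
#' Minimizes the negative log-likelihood over `(log n, logit p)`. This is
#' step one of the denoising pipeline: fitted to the negative-control (e.g.
#' VRC01-expressing) cells, it characterizes the technical-noise distribution
#' of an antigen. The default start `n = 1, p = 1` is clipped to
#' `p = 1 - 1e-6` so the likelihood is finite at the start.
#'
#' @param counts Nonnegative integer counts with at least two distinct values.
#' @param init Starting [nb_params()]; default `nb_params(1, 1 - 1e-6)`.
#' @param control A [fit_control()] object.
#' @return A list with elements `params` ([nb_params()]) and `diagnostics`
#'   (NLL, AIC, BIC with 2 free parameters, convergence flag, iteration
#'   count).
#' @examples
#' x <- rnbinom(500, size = 2, prob = 0.6)
#' fit <- fit_nb_mle(x)
#' fit$params
#' @export
fit_nb_mle <- function(counts, init = nb_params(1, 1 - 1e-6),
                       control = fit_control()) {
  counts <- assert_counts(counts)
  stopifnot(inherits(init, "nb_params"), inherits(control, "fit_control"))
  if (length(unique(counts)) < 2L) {
    stop("counts are degenerate (all identical): the NB likelihood has no ",
         "interior maximum; supply data with at least two distinct values",
         call. = FALSE)
  }
  ag <- aggregate_counts(counts)
  nll_fun <- function(theta) {
    n <- exp(theta[1L]); p <- inv_logit(theta[2L])
    -sum(ag$w * stats::dnbinom(ag$k, size = n, prob = p, log = TRUE))
  }
  theta0 <- c(log(init$n), logit(init$p))
  opt <- stats::optim(theta0, nll_fun, method = control$method,
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  params <- nb_params(exp(opt$par[1L]), inv_logit(opt$par[2L]))
  diag <- fit_diagnostics(nll = opt$value, n_free = 2L,
                          n_obs = length(counts),
                          converged = opt$convergence == 0L,
                          iterations = opt$counts[["function"]])
  list(params = params, diagnostics = diag)
}

# Method-of-moments NB estimate; used only as an initialization fallback for
# degenerate partitions. Inflates the variance slightly when var <= mean so
# the estimate stays inside the parameter space.
nb_moment_estimate <- function(values) {
  m <- mean(values)
  v <- stats::var(values)
  if (!is.finite(v) || v <= m) v <- m * 1.5 + 0.5
  if (m <= 0) m <- 0.1
  p <- min(max(m / v, 1e-6), 1 - 1e-6)
  n <- max(m * p / (1 - p), 1e-6)
  nb_params(n, p)
}
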