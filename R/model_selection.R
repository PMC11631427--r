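#' AIC and BIC from a negative log-likelihood
#'
#' @param nll Negative log-likelihood of the fit.
#' @param n_free Number of free parameters.
#' @param n_obs Number of observations (`>= 1`).
#' @return A list with `aic = 2 n_free + 2 nll` and
#'   `bic = n_free log(n_obs) + 2 nll`.
#' @export
information_criteria <- function(nll, n_free, n_obs) {
  stopifnot(n_obs >= 1)
  list(aic = 2 * n_free + 2 * nll, bic = n_free * log(n_obs) + 2 * nll)
}

#' Two-component Poisson mixture fit
#'
#' Alternative count family for model comparison. Percentile initialization
#' reuses the NB mixture's convention: the data are split at the
#' `(1 - omega0) * 100`th percentile and the partition means initialize the
#' two rates. Three free parameters (`omega`, two rates) enter AIC/BIC.
#' Overdispersed antigen-barcode counts (variance far above the mean) are
#' expected to favor the NB mixture under BIC.
#'
#' @param counts Nonnegative integer counts with >= 2 distinct values.
#' @param omega0 Initial weight; default 0.1.
#' @param control A [fit_control()].
#' @return A list with `params` (list `omega`, `lambda1`, `lambda2`) and
#'   `diagnostics`.
#' @export
fit_poisson_mixture <- function(counts, omega0 = 0.1,
                                control = fit_control(maxit = 2000L)) {
  counts <- assert_counts(counts)
  if (length(unique(counts)) < 2L) {
    stop("counts are degenerate (all identical)", call. = FALSE)
  }
  cut <- stats::quantile(counts, probs = 1 - omega0, type = 7, names = FALSE)
  lower <- counts[counts <= cut]; upper <- counts[counts > cut]
  l1 <- max(mean(lower), 1e-3)
  l2 <- if (length(upper)) max(mean(upper), l1 + 1e-3) else l1 * 2 + 1
  ag <- aggregate_counts(counts)
  nll_fun <- function(theta) {
    w <- inv_logit(theta[1L])
    a <- stats::dpois(ag$k, exp(theta[2L]), log = TRUE)
    b <- stats::dpois(ag$k, exp(theta[3L]), log = TRUE)
    val <- -sum(ag$w * logsumexp2(log(w) + a, log1p(-w) + b))
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }
  opt <- stats::optim(c(logit(omega0), log(l1), log(l2)), nll_fun,
                      method = control$method,
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  list(
    params = list(omega = inv_logit(opt$par[1L]),
                  lambda1 = exp(opt$par[2L]),
                  lambda2 = exp(opt$par[3L])),
    diagnostics = fit_diagnostics(opt$value, n_free = 3L,
                                  n_obs = length(counts),
                                  converged = opt$convergence == 0L,
                                  iterations = opt$counts[["function"]])
  )
}

#' Two-component Gaussian mixture fit on raw counts
#'
#' Continuous alternative evaluated directly on the integer counts treated
#' as reals. Failure to converge is reported through the `converged` flag
#' (and `diagnostics$converged`), never raised, so family-comparison tables
#' can record it as a status. Five free parameters.
#'
#' @inheritParams fit_poisson_mixture
#' @return A list with `params` (`omega`, `mu1`, `sd1`, `mu2`, `sd2`),
#'   `diagnostics`, and `converged`.
#' @export
fit_gaussian_mixture <- function(counts, omega0 = 0.1,
                                 control = fit_control(maxit = 2000L)) {
  counts <- assert_counts(counts)
  if (length(unique(counts)) < 2L) {
    stop("counts are degenerate (all identical)", call. = FALSE)
  }
  cut <- stats::quantile(counts, probs = 1 - omega0, type = 7, names = FALSE)
  lower <- counts[counts <= cut]; upper <- counts[counts > cut]
  s_all <- stats::sd(counts)
  init_side <- function(part) {
    mu <- if (length(part)) mean(part) else mean(counts)
    s <- if (length(part) >= 2L) stats::sd(part) else s_all
    if (!is.finite(s) || s <= 0) s <- max(s_all, 0.5)
    c(mu, s)
  }
  i1 <- init_side(lower); i2 <- init_side(upper)
  nll_fun <- function(theta) {
    w <- inv_logit(theta[1L])
    a <- stats::dnorm(counts, theta[2L], exp(theta[3L]), log = TRUE)
    b <- stats::dnorm(counts, theta[4L], exp(theta[5L]), log = TRUE)
    val <- -sum(logsumexp2(log(w) + a, log1p(-w) + b))
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }
  theta0 <- c(logit(omega0), i1[1L], log(i1[2L]), i2[1L], log(i2[2L]))
  opt <- tryCatch(
    stats::optim(theta0, nll_fun, method = control$method,
                 control = list(maxit = control$maxit,
                                reltol = control$reltol)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    diag <- fit_diagnostics(Inf, n_free = 5L, n_obs = length(counts),
                            converged = FALSE, iterations = 0L)
    return(list(params = NULL, diagnostics = diag, converged = FALSE))
  }
  converged <- opt$convergence == 0L && is.finite(opt$value) &&
    opt$value < .Machine$double.xmax
  list(
    params = list(omega = inv_logit(opt$par[1L]),
                  mu1 = opt$par[2L], sd1 = exp(opt$par[3L]),
                  mu2 = opt$par[4L], sd2 = exp(opt$par[5L])),
    diagnostics = fit_diagnostics(opt$value, n_free = 5L,
                                  n_obs = length(counts),
                                  converged = converged,
                                  iterations = opt$counts[["function"]]),
    converged = converged
  )
}

# One mixture fit + labeling; init biased by control counts when available.
fit_and_label <- function(counts, control_counts = NULL, omega0 = 0.1,
                          control = fit_control(maxit = 2000L)) {
  init <- if (!is.null(control_counts) && length(control_counts) >= 2L &&
              length(unique(control_counts)) >= 2L) {
    init_from_control(control_counts, counts, omega0, control = control)
  } else {
    init_percentile(counts, omega0, control = control)
  }
  fit <- fit_mixture(counts, init, control = control)
  fit$params <- assign_labels(fit$params)
  fit
}

#' Bootstrap with resampling: stability of the mean signal probability
#'
#' Each iteration resamples the donor counts with replacement at full size,
#' refits the mixture (control-biased when `control_counts` are supplied,
#' percentile-initialized otherwise), and records the mean posterior signal
#' probability evaluated over the *original* counts. The spread of those
#' means across iterations — their standard deviation, the bootstrap
#' standard error — summarizes how sensitive the model's predictions are to
#' cell sampling.
#'
#' @param counts Donor-cell counts.
#' @param control_counts Optional negative-control counts for biased
#'   initialization.
#' @param n_iter Number of bootstrap iterations; default 100.
#' @param seed Integer seed; mandatory.
#' @param omega0,control Passed to the mixture fit.
#' @return A list of class `bootstrap_result`: `n_iterations`, a
#'   `per_iteration` data frame (omega, component parameters, NLL, BIC,
#'   convergence flag, mean p_signal; failed fits are flagged, not dropped),
#'   and `summary$sem_mean_p_signal`.
#' @export
bootstrap_resample <- function(counts, control_counts = NULL, n_iter = 100L,
                               seed, omega0 = 0.1,
                               control = fit_control(maxit = 2000L)) {
  counts <- assert_counts(counts)
  stopifnot(n_iter >= 1)
  per <- with_rng(seed, {
    do.call(rbind, lapply(seq_len(n_iter), function(i) {
      boot <- sample(counts, length(counts), replace = TRUE)
      res <- tryCatch(suppressWarnings(
        fit_and_label(boot, control_counts, omega0, control)
      ), error = function(e) NULL)
      if (is.null(res)) {
        return(data.frame(iteration = i, ok = FALSE, omega = NA_real_,
                          n_noise = NA_real_, p_noise = NA_real_,
                          n_signal = NA_real_, p_signal_par = NA_real_,
                          nll = NA_real_, bic = NA_real_, converged = FALSE,
                          mean_p_signal = NA_real_))
      }
      nc <- noise_component(res$params)
      sc <- if (res$params$labels[1L] == "signal") {
        list(weight = res$params$omega, params = res$params$comp1)
      } else {
        list(weight = 1 - res$params$omega, params = res$params$comp2)
      }
      mp <- mean(posterior(counts, res$params)$p_signal)
      data.frame(iteration = i, ok = TRUE, omega = nc$weight,
                 n_noise = nc$params$n, p_noise = nc$params$p,
                 n_signal = sc$params$n, p_signal_par = sc$params$p,
                 nll = res$diagnostics$nll, bic = res$diagnostics$bic,
                 converged = res$diagnostics$converged,
                 mean_p_signal = mp)
    }))
  })
  structure(list(
    n_iterations = as.integer(n_iter),
    per_iteration = per,
    summary = list(
      sem_mean_p_signal = stats::sd(per$mean_p_signal, na.rm = TRUE),
      mean_mean_p_signal = mean(per$mean_p_signal, na.rm = TRUE),
      n_failed = sum(!per$ok)
    )
  ), class = "bootstrap_result")
}

#' Bootstrap with downsampling: model stability versus sample size
#'
#' For each requested size, draws `n_iter` subsamples without replacement,
#' refits the mixture (percentile initialization), and records BIC and the
#' subsample's mean signal probability. The coefficient of variation of BIC
#' and the SD of the mean signal probability per size trace how model
#' stability decays as cells are removed; instability typically grows
#' sharply below a few hundred cells.
#'
#' @param counts Donor-cell counts.
#' @param sizes Integer subsample sizes, each `<= length(counts)`.
#' @param n_iter Iterations per size; default 100.
#' @param seed Integer seed; mandatory.
#' @param omega0,control Passed to the mixture fit.
#' @return A list of class `bootstrap_result` with `per_iteration` (size,
#'   iteration, BIC, mean p_signal, convergence) and `summary$per_size`
#'   (CV of BIC and SD of mean p_signal per size).
#' @export
bootstrap_downsample <- function(counts, sizes, n_iter = 100L, seed,
                                 omega0 = 0.1,
                                 control = fit_control(maxit = 2000L)) {
  counts <- assert_counts(counts)
  stopifnot(n_iter >= 1, length(sizes) >= 1)
  if (any(sizes > length(counts))) {
    stop("requested size exceeds the number of available counts",
         call. = FALSE)
  }
  small <- sizes[sizes < 300]
  if (length(small)) {
    warning("fitting on fewer than 300 cells (sizes ",
            paste(small, collapse = ", "),
            ") is typically unstable; interpret with care", call. = FALSE)
  }
  per <- with_rng(seed, {
    do.call(rbind, lapply(sizes, function(sz) {
      do.call(rbind, lapply(seq_len(n_iter), function(i) {
        sub <- sample(counts, sz, replace = FALSE)
        res <- tryCatch(suppressWarnings(
          fit_and_label(sub, NULL, omega0, control)
        ), error = function(e) NULL)
        if (is.null(res)) {
          return(data.frame(size = sz, iteration = i, ok = FALSE,
                            bic = NA_real_, converged = FALSE,
                            mean_p_signal = NA_real_))
        }
        data.frame(size = sz, iteration = i, ok = TRUE,
                   bic = res$diagnostics$bic,
                   converged = res$diagnostics$converged,
                   mean_p_signal = mean(posterior(sub,
                                                  res$params)$p_signal))
      }))
    }))
  })
  per_size <- do.call(rbind, lapply(split(per, per$size), function(d) {
    data.frame(size = d$size[1L],
               cv_bic = stats::sd(d$bic, na.rm = TRUE) /
                 abs(mean(d$bic, na.rm = TRUE)),
               sd_mean_p_signal = stats::sd(d$mean_p_signal, na.rm = TRUE),
               n_failed = sum(!d$ok))
  }))
  per_size <- per_size[order(per_size$size), ]
  rownames(per_size) <- NULL
  structure(list(
    n_iterations = as.integer(n_iter),
    per_iteration = per,
    summary = list(per_size = per_size)
  ), class = "bootstrap_result")
}
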