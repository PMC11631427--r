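#' Two-component negative binomial mixture parameters
#'
#' The mixture density is
#' \deqn{P(k) = \omega\, P_{NB}(k \mid n_1, p_1) +
#'   (1-\omega)\, P_{NB}(k \mid n_2, p_2).}
#' Component slots are not identifiable during fitting; `labels` maps the
#' slots to `"noise"` / `"signal"` and is assigned post hoc by
#' [assign_labels()] (higher median = signal), so every reported quantity is
#' independent of slot order. By convention the first slot holds the
#' noise-flavored initialization (the weight `omega` is attached to it).
#'
#' @param omega Weight in `(0, 1)` on the first component.
#' @param comp1,comp2 [nb_params()] objects.
#' @param labels Either `NULL` (unlabeled) or a character vector of length 2
#'   that is a permutation of `c("noise", "signal")`, giving the label of
#'   each slot.
#' @return An object of class `nb_mixture`.
#' @export
mixture_params <- function(omega, comp1, comp2, labels = NULL) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) ||
      omega <= 0 || omega >= 1) {
    stop("`omega` must be a single number in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(comp1, "nb_params"), inherits(comp2, "nb_params"))
  if (!is.null(labels)) {
    if (!identical(sort(labels), c("noise", "signal"))) {
      stop("`labels` must be a permutation of c(\"noise\", \"signal\")",
           call. = FALSE)
    }
  }
  structure(list(omega = as.numeric(omega), comp1 = comp1, comp2 = comp2,
                 labels = labels),
            class = "nb_mixture")
}

#' @export
print.nb_mixture <- function(x, ...) {
  lab <- if (is.null(x$labels)) c("slot1", "slot2") else x$labels
  cat(sprintf("<nb_mixture> omega = %.4g\n", x$omega))
  cat(sprintf("  %-6s: n = %.5g, p = %.5g (median %d)\n",
              lab[1L], x$comp1$n, x$comp1$p, nb_median(x$comp1)))
  cat(sprintf("  %-6s: n = %.5g, p = %.5g (median %d)\n",
              lab[2L], x$comp2$n, x$comp2$p, nb_median(x$comp2)))
  invisible(x)
}

#' Mixture probability mass function
#'
#' @param k Vector of nonnegative integer counts.
#' @param params An [mixture_params()] object (labels not required).
#' @return `omega * pmf1(k) + (1 - omega) * pmf2(k)`.
#' @export
mixture_pmf <- function(k, params) {
  stopifnot(inherits(params, "nb_mixture"))
  params$omega * nb_pmf(k, params$comp1) +
    (1 - params$omega) * nb_pmf(k, params$comp2)
}

#' Mixture log probability mass function
#'
#' Stable log-sum-exp combination of the weighted component log-PMFs.
#'
#' @inheritParams mixture_pmf
#' @export
mixture_logpmf <- function(k, params) {
  stopifnot(inherits(params, "nb_mixture"))
  logsumexp2(log(params$omega) + nb_logpmf(k, params$comp1),
             log1p(-params$omega) + nb_logpmf(k, params$comp2))
}

#' Mixture negative log-likelihood
#'
#' The per-observation log density is computed by log-sum-exp, so counts deep
#' in either tail do not underflow to `-Inf` unless both components give the
#' count zero mass.
#'
#' @param counts Nonnegative integer counts.
#' @inheritParams mixture_pmf
#' @return A single number, `-sum(mixture_logpmf(counts, params))`.
#' @export
mixture_nll <- function(counts, params) {
  counts <- assert_counts(counts)
  -sum(mixture_logpmf(counts, params))
}

#' Control-biased mixture initialization
#'
#' Fits a single negative binomial to the negative-control cell counts by
#' maximum likelihood and places it in the noise slot; the signal slot is
#' initialized by the percentile procedure on the donor counts (upper
#' partition of [init_percentile()]). If the control counts are missing or
#' degenerate, the whole initialization falls back to [init_percentile()]
#' with a warning.
#'
#' @param control_counts Counts from negative-control cells (may be `NULL` or
#'   empty, in which case the percentile fallback is used).
#' @param donor_counts Counts from donor cells.
#' @param omega0 Initial weight on the noise slot; default 0.1.
#' @param control A [fit_control()] for the inner NB fits.
#' @return An unlabeled [mixture_params()] with `omega = omega0`.
#' @export
init_from_control <- function(control_counts, donor_counts, omega0 = 0.1,
                              control = fit_control()) {
  donor_counts <- assert_counts(donor_counts, "donor_counts")
  fallback <- function(why) {
    warning("control counts ", why,
            "; falling back to percentile initialization", call. = FALSE)
    init_percentile(donor_counts, omega0, control = control)
  }
  if (is.null(control_counts) || length(control_counts) == 0L) {
    return(fallback("are empty"))
  }
  control_counts <- assert_counts(control_counts, "control_counts")
  if (length(unique(control_counts)) < 2L) {
    return(fallback("are degenerate"))
  }
  noise <- fit_nb_mle(control_counts, control = control)$params
  signal <- percentile_partition_fit(donor_counts, omega0,
                                     control = control)$upper
  mixture_params(omega = omega0, comp1 = noise, comp2 = signal)
}

# Split counts at the (1 - omega0) * 100th percentile (linear-interpolation
# convention) and fit an NB to each side; degenerate sides fall back to
# moment estimates of the full data with a warning.
percentile_partition_fit <- function(counts, omega0, control = fit_control()) {
  cut <- stats::quantile(counts, probs = 1 - omega0, type = 7, names = FALSE)
  lower <- counts[counts <= cut]
  upper <- counts[counts > cut]
  fit_side <- function(part, side) {
    if (length(part) >= 2L && length(unique(part)) >= 2L) {
      fit_nb_mle(part, control = control)$params
    } else {
      warning(side, " percentile partition is degenerate; ",
              "initializing from moment estimates of the full data",
              call. = FALSE)
      nb_moment_estimate(counts)
    }
  }
  list(lower = fit_side(lower, "lower"), upper = fit_side(upper, "upper"),
       cut = cut)
}

#' Percentile-based mixture initialization
#'
#' Splits the donor counts at the `(1 - omega0) * 100`th percentile, fits a
#' negative binomial to each partition, and uses the lower-partition fit to
#' initialize the noise slot and the upper-partition fit for the signal slot.
#' Used on its own when no negative-control cells exist, and for the signal
#' side of [init_from_control()].
#'
#' @param donor_counts Nonnegative integer counts.
#' @param omega0 Initial weight in `(0, 1)`; default 0.1.
#' @param control A [fit_control()].
#' @return An unlabeled [mixture_params()] with `omega = omega0`.
#' @export
init_percentile <- function(donor_counts, omega0 = 0.1,
                            control = fit_control()) {
  donor_counts <- assert_counts(donor_counts, "donor_counts")
  if (omega0 <= 0 || omega0 >= 1) {
    stop("`omega0` must be in (0, 1)", call. = FALSE)
  }
  parts <- percentile_partition_fit(donor_counts, omega0, control = control)
  mixture_params(omega = omega0, comp1 = parts$lower, comp2 = parts$upper)
}

#' Maximum-likelihood fit of the two-component NB mixture
#'
#' Jointly optimizes all five free parameters
#' `(omega, n1, p1, n2, p2)` from the supplied initialization by direct
#' minimization of [mixture_nll()] on transformed coordinates
#' (`logit omega`, `log n`, `logit p` per component). No EM step is used.
#' Control-derived noise parameters only initialize the fit; they are free
#' during optimization. Labels are left unassigned — call [assign_labels()]
#' before computing posteriors.
#'
#' @param counts Donor-cell counts with at least two distinct values.
#' @param init An [mixture_params()] initialization, e.g. from
#'   [init_from_control()] or [init_percentile()].
#' @param control A [fit_control()]; the default raises `maxit` to 2000,
#'   which the 5-dimensional simplex typically needs.
#' @return A list with `params` (unlabeled [mixture_params()]) and
#'   `diagnostics` (NLL, AIC/BIC at 5 free parameters, convergence flag,
#'   iteration count). Non-convergence is reported through
#'   `diagnostics$converged`, never as an error.
#' @export
fit_mixture <- function(counts, init, control = fit_control(maxit = 2000L)) {
  counts <- assert_counts(counts)
  stopifnot(inherits(init, "nb_mixture"), inherits(control, "fit_control"))
  if (length(unique(counts)) < 2L) {
    stop("counts are degenerate (all identical); a two-component mixture ",
         "cannot be fitted", call. = FALSE)
  }
  ag <- aggregate_counts(counts)
  nll_fun <- function(theta) {
    w <- inv_logit(theta[1L])
    l1 <- stats::dnbinom(ag$k, size = exp(theta[2L]),
                         prob = inv_logit(theta[3L]), log = TRUE)
    l2 <- stats::dnbinom(ag$k, size = exp(theta[4L]),
                         prob = inv_logit(theta[5L]), log = TRUE)
    val <- -sum(ag$w * logsumexp2(log(w) + l1, log1p(-w) + l2))
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }
  theta0 <- c(logit(init$omega),
              log(init$comp1$n), logit(init$comp1$p),
              log(init$comp2$n), logit(init$comp2$p))
  opt <- stats::optim(theta0, nll_fun, method = control$method,
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  params <- mixture_params(omega = inv_logit(opt$par[1L]),
                           comp1 = nb_params(exp(opt$par[2L]),
                                             inv_logit(opt$par[3L])),
                           comp2 = nb_params(exp(opt$par[4L]),
                                             inv_logit(opt$par[5L])))
  diag <- fit_diagnostics(nll = opt$value, n_free = 5L,
                          n_obs = length(counts),
                          converged = opt$convergence == 0L,
                          iterations = opt$counts[["function"]])
  list(params = params, diagnostics = diag)
}

#' Assign signal/noise labels to mixture components
#'
#' Components are exchangeable during fitting; labels are assigned after the
#' fact: the component with the higher median is the signal, the other the
#' noise. Ties on the median are broken by the higher mean; a complete tie
#' deterministically labels the second slot as signal.
#'
#' @param params An [mixture_params()].
#' @return The same object with `labels` set.
#' @export
assign_labels <- function(params) {
  stopifnot(inherits(params, "nb_mixture"))
  m1 <- nb_median(params$comp1); m2 <- nb_median(params$comp2)
  signal_slot <- if (m1 != m2) {
    if (m1 > m2) 1L else 2L
  } else {
    mu1 <- nb_mean(params$comp1); mu2 <- nb_mean(params$comp2)
    if (mu1 > mu2) 1L else 2L  # complete tie -> slot 2 is signal
  }
  params$labels <- if (signal_slot == 1L) c("signal", "noise") else
    c("noise", "signal")
  params
}

# Weight and parameters of the noise-labeled component.
noise_component <- function(params) {
  if (is.null(params$labels)) {
    stop("mixture is unlabeled; call assign_labels() first", call. = FALSE)
  }
  if (params$labels[1L] == "noise") {
    list(weight = params$omega, params = params$comp1)
  } else {
    list(weight = 1 - params$omega, params = params$comp2)
  }
}

#' Bayes posterior component probabilities
#'
#' For each count `k`, the posterior probability that it arose from the
#' noise component is
#' \deqn{P_N(k) = \frac{\omega_N P_{NB}(k \mid n_N, p_N)}{P_{mix}(k)},}
#' with \eqn{P_S(k) = 1 - P_N(k)}; \eqn{\omega_N} is the weight attached to
#' the noise-labeled component. Computed in log space so extreme counts never
#' produce 0/0, and the two probabilities are exact complements.
#'
#' @param k Vector of nonnegative integer counts.
#' @param params A labeled [mixture_params()] (see [assign_labels()]).
#' @return A list with numeric vectors `p_noise` and `p_signal`.
#' @export
posterior <- function(k, params) {
  stopifnot(inherits(params, "nb_mixture"))
  nc <- noise_component(params)
  log_noise <- log(nc$weight) + nb_logpmf(k, nc$params)
  log_mix <- mixture_logpmf(k, params)
  p_noise <- exp(log_noise - log_mix)
  p_noise <- pmin(pmax(p_noise, 0), 1)
  list(p_noise = p_noise, p_signal = 1 - p_noise)
}

#' Classify counts as signal or noise by posterior threshold
#'
#' A count is called signal when its posterior signal probability reaches the
#' threshold (`>=`, so a posterior exactly at the threshold is signal). The
#' unbiased choice is 0.5; 0.9 is the high-confidence preset used together
#' with the LIBRA-seq score (see [combine_calls()]).
#'
#' @param counts Nonnegative integer counts.
#' @param params A labeled [mixture_params()].
#' @param threshold Signal-probability threshold in `[0, 1]`; default 0.5.
#' @param cell_ids Optional identifiers, recycled onto the result.
#' @return A `posterior_result` data frame with columns `cell_id` (if given),
#'   `k`, `p_signal`, `p_noise`, `call` (`"signal"`/`"noise"`), carrying the
#'   threshold as an attribute.
#' @export
classify <- function(counts, params, threshold = 0.5, cell_ids = NULL) {
  counts <- assert_counts(counts)
  stopifnot(threshold >= 0, threshold <= 1)
  post <- posterior(counts, params)
  out <- data.frame(
    k = counts,
    p_signal = post$p_signal,
    p_noise = post$p_noise,
    call = ifelse(post$p_signal >= threshold, "signal", "noise"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cell_ids)) {
    stopifnot(length(cell_ids) == length(counts))
    out <- cbind(cell_id = as.character(cell_ids), out,
                 stringsAsFactors = FALSE)
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("posterior_result", "data.frame")
  out
}

# Serialize a fitted mixture (params + labels + diagnostics) to a plain list
# suitable for jsonlite.
mixture_to_list <- function(params, diagnostics = NULL, init_strategy = NULL) {
  out <- list(
    omega = params$omega,
    comp1 = list(n = params$comp1$n, p = params$comp1$p),
    comp2 = list(n = params$comp2$n, p = params$comp2$p),
    labels = params$labels
  )
  if (!is.null(diagnostics)) out$diagnostics <- unclass(diagnostics)
  if (!is.null(init_strategy)) out$init_strategy <- init_strategy
  out
}
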