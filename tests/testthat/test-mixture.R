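test_that("mixture pmf equals the naive two-term sum and normalizes", {
  set.seed(21)
  for (i in 1:10) {
    mx <- mixture_params(runif(1, 0.1, 0.9),
                         nb_params(runif(1, 0.5, 5), runif(1, 0.3, 0.9)),
                         nb_params(runif(1, 5, 30), runif(1, 0.1, 0.4)))
    k <- 0:60
    naive <- mx$omega * dnbinom(k, mx$comp1$n, mx$comp1$p) +
      (1 - mx$omega) * dnbinom(k, mx$comp2$n, mx$comp2$p)
    expect_equal(mixture_pmf(k, mx), naive, tolerance = 1e-12)
  }
  # identical components collapse to the single-component pmf
  th <- nb_params(3, 0.4)
  mx <- mixture_params(0.3, th, th)
  expect_equal(mixture_pmf(0:100, mx), nb_pmf(0:100, th))
  expect_lt(abs(sum(mixture_pmf(0:3000, mx)) - 1), 1e-8)
})

test_that("mixture NLL uses a stable log-sum-exp and is additive", {
  th <- nb_params(3, 0.4)
  mx <- mixture_params(0.3, th, th)
  x <- c(0, 1, 2, 5, 9)
  expect_equal(mixture_nll(x, mx), -sum(nb_logpmf(x, th)))
  mx2 <- mixture_params(0.6, nb_params(2, 0.7), nb_params(20, 0.2))
  naive <- -sum(log(mixture_pmf(x, mx2)))
  expect_equal(mixture_nll(x, mx2), naive, tolerance = 1e-9)
  # adding a count duplicates its contribution
  expect_equal(mixture_nll(c(x, 5), mx2),
               mixture_nll(x, mx2) - mixture_logpmf(5, mx2))
})

test_that("control-biased initialization recovers the noise component", {
  set.seed(31)
  ctrl <- rnbinom(1500, size = 2, prob = 0.6)
  donor <- simulate_mixture(2000, 32)$counts
  init <- init_from_control(ctrl, donor, 0.1)
  expect_equal(init$omega, 0.1)
  expect_lt(abs(init$comp1$n - 2) / 2, 0.2)
  expect_lt(abs(init$comp1$p - 0.6), 0.05)
  # empty / degenerate control falls back to the percentile path
  expect_warning(fb <- init_from_control(NULL, donor, 0.1), "falling back")
  ref <- suppressWarnings(init_percentile(donor, 0.1))
  expect_equal(fb, ref)
  expect_warning(init_from_control(rep(2, 50), donor, 0.1), "degenerate")
})

test_that("percentile initialization splits at the right quantile and hits component means", {
  set.seed(41)
  n <- 5000
  noise <- rnbinom(round(0.9 * n), 2, 0.7)   # mean 6/7
  signal <- rnbinom(n - round(0.9 * n), 20, 0.2)  # mean 80
  counts <- sample(c(noise, signal))
  init <- init_percentile(counts, 0.1)
  m_noise <- 2 * 0.3 / 0.7
  m_signal <- 20 * 0.8 / 0.2
  se_lo <- sd(noise) / sqrt(length(noise))
  se_hi <- sd(signal) / sqrt(length(signal))
  expect_lt(abs(nb_mean(init$comp1) - m_noise), max(2 * se_lo, 0.1))
  expect_lt(abs(nb_mean(init$comp2) - m_signal), max(2 * se_hi, 4))
  # split point matches a sort-based order-statistic oracle
  x <- sort(counts)
  h <- (n - 1) * 0.9 + 1
  q <- x[floor(h)] + (h - floor(h)) * (x[min(floor(h) + 1, n)] - x[floor(h)])
  expect_equal(sum(counts <= q) + sum(counts > q), n)
  expect_identical(sum(counts > q) >= 1, TRUE)
  # degenerate data exercise the moment fallback (both partitions warn)
  w <- capture_warnings(ip <- init_percentile(c(rep(4, 99), 5), 0.1))
  expect_true(all(grepl("degenerate", w)))
  expect_length(w, 2L)
  expect_s3_class(ip, "nb_mixture")
})

test_that("mixture MLE recovers a well-separated truth from either init", {
  sim <- simulate_mixture(2000, 7)
  fit <- fit_labeled(sim$counts)
  expect_true(fit$diagnostics$converged)
  nc <- if (fit$params$labels[1] == "noise") fit$params$omega else
    1 - fit$params$omega
  expect_lt(abs(nc - 0.7), 0.05)
  # fitted NLL never exceeds the initialization NLL
  init <- suppressWarnings(init_percentile(sim$counts, 0.1))
  expect_lte(fit$diagnostics$nll, mixture_nll(sim$counts, init))
  # swapping the init slots yields the same labeled parameters
  swapped <- mixture_params(1 - init$omega, init$comp2, init$comp1)
  fit2 <- fit_mixture(sim$counts, swapped)
  fit2$params <- assign_labels(fit2$params)
  get_labeled <- function(p) {
    i <- which(p$labels == "noise")
    noise <- if (i == 1) p$comp1 else p$comp2
    signal <- if (i == 1) p$comp2 else p$comp1
    c(noise$n, noise$p, signal$n, signal$p)
  }
  expect_equal(get_labeled(fit2$params), get_labeled(fit$params),
               tolerance = 0.05)
})

test_that("weight recovery holds over 20 seeded replicates", {
  err <- vapply(1:20, function(s) {
    sim <- simulate_mixture(2000, 500 + s)
    fit <- fit_labeled(sim$counts)
    nc <- if (fit$params$labels[1] == "noise") fit$params$omega else
      1 - fit$params$omega
    abs(nc - 0.7)
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("labels follow the higher-median rule with deterministic ties", {
  mx <- mixture_params(0.5, nb_params(2, 0.7), nb_params(20, 0.2))
  lab <- assign_labels(mx)
  expect_equal(lab$labels, c("noise", "signal"))
  # permutation invariance
  lab2 <- assign_labels(mixture_params(0.5, mx$comp2, mx$comp1))
  expect_equal(lab2$labels, c("signal", "noise"))
  # identical components: deterministic tie-break
  th <- nb_params(3, 0.5)
  tie <- assign_labels(mixture_params(0.4, th, th))
  expect_equal(tie$labels, c("noise", "signal"))
})

test_that("posterior is an exact complement and matches the direct ratio", {
  th <- nb_params(3, 0.5)
  mx <- assign_labels(mixture_params(0.4, th, th))
  post <- posterior(0:50, mx)
  # identical components: p_signal is the constant signal weight
  w_n <- if (mx$labels[1] == "noise") mx$omega else 1 - mx$omega
  expect_equal(post$p_signal, rep(1 - w_n, 51))
  expect_identical(post$p_signal + post$p_noise, rep(1, 51))
  # direct Bayes ratio on a representable grid
  mx2 <- assign_labels(
    mixture_params(0.7, nb_params(2, 0.7), nb_params(20, 0.2)))
  k <- 0:80
  direct <- 0.7 * nb_pmf(k, mx2$comp1) / mixture_pmf(k, mx2)
  p2 <- posterior(k, mx2)
  expect_equal(p2$p_noise, direct, tolerance = 1e-9)
  expect_identical(p2$p_signal + p2$p_noise, rep(1, length(k)))
  # relabeling then posterior == posterior then relabeling
  mx2_swap <- assign_labels(
    mixture_params(0.3, nb_params(20, 0.2), nb_params(2, 0.7)))
  expect_equal(posterior(k, mx2_swap)$p_signal, p2$p_signal,
               tolerance = 1e-12)
  # vanishing noise weight drives p_signal to 1 wherever the signal
  # component carries non-negligible mass
  tiny <- assign_labels(
    mixture_params(1e-12, nb_params(2, 0.7), nb_params(20, 0.2)))
  expect_gt(min(posterior(20:90, tiny)$p_signal), 1 - 1e-9)
})

test_that("posterior is monotone in k for shared-n stochastically ordered components", {
  set.seed(77)
  for (i in 1:25) {
    n <- runif(1, 0.5, 10)
    p_n <- runif(1, 0.4, 0.95)
    p_s <- runif(1, 0.05, p_n - 0.1)
    mx <- assign_labels(
      mixture_params(runif(1, 0.2, 0.9), nb_params(n, p_n),
                     nb_params(n, p_s)))
    ps <- posterior(0:500, mx)$p_signal
    expect_true(all(diff(ps) >= -1e-12))
  }
})

test_that("classification respects thresholds and recovers simulation truth", {
  sim <- simulate_mixture(2000, 13)
  fit <- fit_labeled(sim$counts)
  res <- classify(sim$counts, fit$params, 0.5)
  expect_gte(mean(res$call == sim$labels), 0.95)
  # boundary: p_signal exactly at threshold is called signal
  th <- nb_params(3, 0.5)
  tie <- assign_labels(mixture_params(0.4, th, th))  # p_signal ~ 0.6
  at_boundary <- posterior(0, tie)$p_signal
  expect_true(all(classify(0:5, tie, at_boundary)$call == "signal"))
  expect_true(all(classify(0:5, tie, 0)$call == "signal"))
  expect_true(all(classify(0:5, tie, 1)$call == "noise"))
})

test_that("control-biased and percentile initializations agree on well-separated data", {
  set.seed(55)
  ctrl <- rnbinom(1000, 2, 0.7)
  sim <- simulate_mixture(2000, 56)
  f_biased <- suppressWarnings(fit_labeled(sim$counts, ctrl))
  f_plain <- suppressWarnings(fit_labeled(sim$counts))
  nw <- function(p) if (p$labels[1] == "noise") p$omega else 1 - p$omega
  expect_lt(abs(nw(f_biased$params) - nw(f_plain$params)), 0.02)
  acc_b <- mean(classify(sim$counts, f_biased$params)$call == sim$labels)
  acc_p <- mean(classify(sim$counts, f_plain$params)$call == sim$labels)
  expect_gte(acc_b, 0.95)
  expect_gte(acc_p, 0.95)
})
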