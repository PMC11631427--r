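# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Textbook dynamic-programming edit distance (insert/delete/substitute,
# unit costs); independent of utils::adist.
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1L] <- 0:length(x)
  d[1L, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# Closed-form NB PMF through the exact binomial coefficient; for integer
# n <= 5 and k <= 20 choose() is exact integer arithmetic, so the only
# floating error is the final two multiplications.
exact_nb_pmf <- function(k, n, p) {
  choose(k + n - 1, n - 1) * p^n * (1 - p)^k
}

# Brute-force NB median: scan the cumulative PMF.
median_oracle <- function(n, p) {
  k <- 0L
  acc <- stats::dnbinom(0, size = n, prob = p)
  while (acc < 0.5) {
    k <- k + 1L
    acc <- acc + stats::dnbinom(k, size = n, prob = p)
  }
  k
}

# A small BCR fixture: `dup` cells carry two distinct heavy CDR3s.
make_bcr_fixture <- function(n_cells = 10L, dup = integer(0L)) {
  rows <- lapply(seq_len(n_cells), function(i) {
    id <- sprintf("cell%02d", i)
    cdr3 <- paste(rep(LETTERS[(i %% 20) + 1L], 8L), collapse = "")
    cdr3 <- chartr("BJOUZ", "GGGGG", cdr3)  # keep to the AA alphabet
    r <- data.frame(cell_id = id, chain = "heavy", cdr3_aa = cdr3)
    if (i %in% dup) {
      r <- rbind(r, data.frame(cell_id = id, chain = "heavy",
                               cdr3_aa = paste0(substr(cdr3, 1, 7), "W")))
    }
    r
  })
  bcr_table(do.call(rbind, rows))
}

well_separated_truth <- list(omega_noise = 0.7,
                             noise = nb_params(2, 0.7),
                             signal = nb_params(20, 0.2))

# Simulate from the canonical well-separated mixture; returns counts and
# generating labels.
simulate_mixture <- function(n, seed, truth = well_separated_truth) {
  set.seed(seed)
  is_noise <- runif(n) < truth$omega_noise
  k <- numeric(n)
  k[is_noise] <- rnbinom(sum(is_noise), size = truth$noise$n,
                         prob = truth$noise$p)
  k[!is_noise] <- rnbinom(sum(!is_noise), size = truth$signal$n,
                          prob = truth$signal$p)
  list(counts = k, labels = ifelse(is_noise, "noise", "signal"))
}

# Fit + label, mirroring the pipeline's per-antigen step.
fit_labeled <- function(counts, control_counts = NULL, omega0 = 0.1) {
  init <- if (is.null(control_counts)) {
    init_percentile(counts, omega0)
  } else {
    init_from_control(control_counts, counts, omega0)
  }
  fit <- fit_mixture(counts, init)
  fit$params <- assign_labels(fit$params)
  fit
}
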