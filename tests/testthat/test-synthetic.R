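test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_donor_cells = 200, n_control_cells = 50,
                          omega_true = 0.3, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$bcr, d2$bcr)
  expect_identical(d1$truth$labels, d2$truth$labels)
  # and differs under another seed
  d3 <- generate_dataset(synthetic_config(n_donor_cells = 200,
                                          n_control_cells = 50,
                                          omega_true = 0.3, seed = 43))
  expect_false(identical(unclass(d1$counts), unclass(d3$counts)))
})

test_that("empirical signal fraction and component means match the configuration", {
  cfg <- synthetic_config(n_donor_cells = 5000, n_control_cells = 0,
                          omega_true = 0.3,
                          noise_params = nb_params(2, 0.7),
                          signal_params = nb_params(20, 0.2), seed = 7)
  ds <- generate_dataset(cfg)
  lab <- ds$truth$labels[, 1]
  frac <- mean(lab == "signal")
  se <- sqrt(0.3 * 0.7 / 5000)
  expect_lt(abs(frac - 0.3), 3 * se)
  noise_counts <- ds$counts[lab == "noise", 1]
  m <- nb_mean(nb_params(2, 0.7))
  se_m <- sd(noise_counts) / sqrt(length(noise_counts))
  expect_lt(abs(mean(noise_counts) - m), 2 * se_m)
})

test_that("CDR3 mutation follows its substitution contract", {
  ref <- "ARDGYSSGWYALDYFQHWGS"
  set.seed(3)
  expect_identical(generate_cdr3(ref, 0), ref)
  full <- generate_cdr3(ref, 1)
  expect_equal(nchar(full), nchar(ref))
  expect_true(all(strsplit(full, "")[[1]] != strsplit(ref, "")[[1]]))
  # expected normalized distance ~ substitution rate (substitution-only)
  rate <- 0.15
  d <- replicate(300, normalized_levenshtein(generate_cdr3(ref, rate), ref))
  se <- sqrt(rate * (1 - rate) / nchar(ref)) / sqrt(300)
  expect_lt(abs(mean(d) - rate), 4 * se)
})

test_that("presets cover the documented scenario space and round-trip", {
  ps <- preset_scenarios()
  expect_named(ps, c("well_separated", "low_signal_sparse", "no_control",
                     "small_sample"))
  expect_equal(ps$no_control$n_control_cells, 0L)
  expect_lt(ps$small_sample$n_donor_cells, 300L)
  expect_lte(ps$low_signal_sparse$omega_true, 0.08)
  for (nm in names(ps)) {
    cfg <- ps[[nm]]
    cfg$n_donor_cells <- min(cfg$n_donor_cells, 300L)
    cfg$n_control_cells <- min(cfg$n_control_cells, 100L)
    ds <- generate_dataset(cfg)
    expect_equal(nrow(ds$counts),
                 cfg$n_donor_cells + cfg$n_control_cells)
    expect_s3_class(ds$bcr, "bcr_table")
  }
})

test_that("the CDR3 split recovers control flags exactly on generated data", {
  cfg <- synthetic_config(n_donor_cells = 300, n_control_cells = 200,
                          omega_true = 0.3, cdr3_mutation_rate = 0.04,
                          seed = 17)
  ds <- generate_dataset(cfg)
  sp <- split_control_cells(ds$bcr, cfg$reference_cdr3, 0.05)
  truth_ctrl <- names(ds$truth$is_control)[ds$truth$is_control]
  truth_donor <- names(ds$truth$is_control)[!ds$truth$is_control]
  expect_setequal(sp$control_cell_ids, truth_ctrl)
  expect_setequal(sp$donor_cell_ids, truth_donor)
})

test_that("sticky-cell mode induces cross-antigen correlation, default does not", {
  # judged on control (noise-only) cells, where the shared per-cell
  # multiplier is not masked by independent signal/noise label draws
  mk <- function(sticky_sd) {
    synthetic_config(n_donor_cells = 1, n_control_cells = 2000,
                     omega_true = 0.3, noise_params = nb_params(5, 0.5),
                     n_antigens = 2, sticky_sd = sticky_sd, seed = 23)
  }
  ctrl_counts <- function(cfg) {
    ds <- generate_dataset(cfg)
    ds$counts[ds$truth$is_control, ]
  }
  plain <- ctrl_counts(mk(0))
  sticky <- ctrl_counts(mk(1))
  r_plain <- cor(plain[, 1], plain[, 2], method = "spearman")
  r_sticky <- cor(sticky[, 1], sticky[, 2], method = "spearman")
  expect_lt(abs(r_plain), 0.1)
  expect_gt(r_sticky, r_plain + 0.3)
})

test_that("pipeline recovers generating labels on the well-separated preset", {
  ds <- generate_dataset(preset_scenarios()$well_separated)
  ctrl_ids <- names(ds$truth$is_control)[ds$truth$is_control]
  donor_ids <- names(ds$truth$is_control)[!ds$truth$is_control]
  fit <- suppressWarnings(
    fit_labeled(ds$counts[donor_ids, 1], ds$counts[ctrl_ids, 1]))
  res <- classify(ds$counts[donor_ids, 1], fit$params, 0.5)
  expect_gte(mean(res$call == ds$truth$labels[donor_ids, 1]), 0.95)
})
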