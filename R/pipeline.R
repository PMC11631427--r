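#' Resolved run configuration
#'
#' Collects every tunable of the denoising pipeline with its default:
#' Levenshtein control-split threshold 0.05, outlier percentile 99, LSS
#' count floor 4, LSS binding threshold 1, posterior thresholds 0.5
#' (unbiased) and 0.9 (high confidence), initial mixture weight 0.1. Every
#' run writes the resolved configuration next to its outputs, so a run is a
#' pure function of (inputs, config, seed).
#'
#' @param counts_path,counts_format Count matrix location and dialect
#'   (`"csv"` or `"mtx"`).
#' @param bcr_path BCR chain table (TSV).
#' @param reference_cdr3 Control-antibody heavy CDR3 (`NULL` if the sample
#'   has no engineered control cells).
#' @param levenshtein_threshold,outlier_percentile,lss_floor,lss_pseudocount
#'   Preprocessing and scoring tunables.
#' @param lss_threshold,ps_threshold,ps_threshold_unbiased Call thresholds.
#' @param omega0 Initial mixture weight.
#' @param maxit,reltol Optimizer settings (see [fit_control()]).
#' @param seed Integer seed.
#' @param output_dir Where outputs are written.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts_path = NULL, counts_format = "csv",
                       bcr_path = NULL,
                       reference_cdr3 = SYNTHETIC_REFERENCE_CDR3,
                       levenshtein_threshold = 0.05,
                       outlier_percentile = 99,
                       lss_floor = 4, lss_pseudocount = 1,
                       lss_threshold = 1,
                       ps_threshold = 0.9, ps_threshold_unbiased = 0.5,
                       omega0 = 0.1,
                       maxit = 2000L, reltol = 1e-8,
                       seed = 1L, output_dir = ".") {
  structure(list(
    counts_path = counts_path, counts_format = counts_format,
    bcr_path = bcr_path, reference_cdr3 = reference_cdr3,
    levenshtein_threshold = levenshtein_threshold,
    outlier_percentile = outlier_percentile,
    lss_floor = lss_floor, lss_pseudocount = lss_pseudocount,
    lss_threshold = lss_threshold,
    ps_threshold = ps_threshold,
    ps_threshold_unbiased = ps_threshold_unbiased,
    omega0 = omega0, maxit = as.integer(maxit), reltol = reltol,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file of `run_config` fields; missing fields take their
#'   defaults.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Denoise a sample end to end
#'
#' Runs the full pipeline on one sample: read counts and BCR table, drop
#' multi-heavy-chain cells, split control from donor cells by CDR3
#' similarity (skipped when `reference_cdr3` is `NULL` or no BCR table is
#' given), trim per-antigen count outliers in each population, fit the NB
#' mixture per antigen (control-biased initialization when control cells
#' exist, percentile otherwise), compute per-cell posteriors, LIBRA-seq
#' scores, and combined binding calls.
#'
#' Outputs written to `config$output_dir`: `params.json` (per-antigen fitted
#' mixtures and diagnostics), `calls.tsv` (long-format cell x antigen table
#' with counts, LSS, posterior, and call), `report.json` (per-filter cell
#' counts), `config.json` (the resolved configuration). A per-antigen fit
#' failure is logged in the report and skipped; the run continues.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-antigen `fits`, the `calls` data
#'   frame, and the `report`.
#' @export
run_denoise <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_matrix(config$counts_path,
                              format = config$counts_format)
  report <- list(n_cells_input = nrow(counts),
                 n_antigens = ncol(counts))

  control_ids <- character(0L)
  donor_ids <- rownames(counts)
  if (!is.null(config$bcr_path)) {
    bcr <- read_bcr_table(config$bcr_path)
    flt <- filter_multi_heavy_chain(bcr)
    report$n_multi_heavy_removed <- length(flt$removed_cell_ids)
    if (!is.null(config$reference_cdr3)) {
      split <- split_control_cells(flt$bcr, config$reference_cdr3,
                                   config$levenshtein_threshold)
      control_ids <- intersect(split$control_cell_ids, rownames(counts))
      donor_ids <- intersect(split$donor_cell_ids, rownames(counts))
      report$n_no_heavy_excluded <- length(split$excluded_cell_ids)
    } else {
      donor_ids <- intersect(unique(flt$bcr$cell_id), rownames(counts))
    }
  }
  report$n_control_cells <- length(control_ids)
  report$n_donor_cells <- length(donor_ids)

  ctrl <- fit_control(maxit = config$maxit, reltol = config$reltol)
  fits <- list()
  p_signal <- matrix(NA_real_, nrow = length(donor_ids),
                     ncol = ncol(counts),
                     dimnames = list(donor_ids, colnames(counts)))
  report$antigens <- list()
  for (ag in colnames(counts)) {
    donor_counts <- counts[donor_ids, ag]
    control_counts <- if (length(control_ids)) counts[control_ids, ag]
                      else NULL
    trim_d <- remove_outliers(donor_counts, config$outlier_percentile)
    trim_c <- if (!is.null(control_counts)) {
      remove_outliers(control_counts, config$outlier_percentile)
    } else NULL
    init_strategy <- if (!is.null(trim_c) &&
                         length(unique(trim_c$kept)) >= 2L) {
      "control_biased"
    } else "percentile"
    res <- tryCatch({
      suppressWarnings({
        init <- if (init_strategy == "control_biased") {
          init_from_control(trim_c$kept, trim_d$kept, config$omega0, ctrl)
        } else {
          init_percentile(trim_d$kept, config$omega0, ctrl)
        }
        fit <- fit_mixture(trim_d$kept, init, control = ctrl)
        fit$params <- assign_labels(fit$params)
        fit
      })
    }, error = function(e) e)
    ag_report <- list(
      init_strategy = init_strategy,
      n_donor_outliers_removed = length(trim_d$removed),
      n_control_outliers_removed =
        if (is.null(trim_c)) 0L else length(trim_c$removed)
    )
    if (inherits(res, "error")) {
      ag_report$status <- "fit_failed"
      ag_report$message <- conditionMessage(res)
      message("antigen ", ag, ": fit failed (", conditionMessage(res),
              "); skipped")
    } else {
      ag_report$status <- "ok"
      res$init_strategy <- init_strategy
      fits[[ag]] <- res
      p_signal[, ag] <- posterior(donor_counts, res$params)$p_signal
    }
    report$antigens[[ag]] <- ag_report
  }

  donor_matrix <- umi_matrix(unclass(counts)[donor_ids, , drop = FALSE])
  lss <- compute_lss(donor_matrix, floor = config$lss_floor,
                     pseudocount = config$lss_pseudocount)
  ok_ag <- names(fits)
  calls <- combine_calls(lss[, ok_ag, drop = FALSE],
                         p_signal[, ok_ag, drop = FALSE],
                         lss_threshold = config$lss_threshold,
                         ps_threshold = config$ps_threshold)
  long <- calls_long_format(
    umi_matrix(unclass(counts)[donor_ids, ok_ag, drop = FALSE]),
    lss[, ok_ag, drop = FALSE],
    p_signal[, ok_ag, drop = FALSE], calls)

  write_json_file(
    lapply(fits, function(f)
      mixture_to_list(f$params, f$diagnostics, f$init_strategy)),
    file.path(config$output_dir, "params.json"))
  utils::write.table(long, file.path(config$output_dir, "calls.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_json_file(report, file.path(config$output_dir, "report.json"))
  write_json_file(unclass(config),
                  file.path(config$output_dir, "config.json"))
  invisible(list(fits = fits, calls = long, report = report,
                 p_signal = p_signal, lss = lss))
}

#' Generate and write a synthetic dataset
#'
#' Wraps [generate_dataset()]: writes the count matrix (`counts.csv` or
#' `counts.mtx` plus sidecars), the BCR table (`bcr.tsv`), the generating
#' truth (`truth.json`), and the resolved configuration (`config.json`)
#' into `output_dir`.
#'
#' @param config A [synthetic_config()], or the name of a
#'   [preset_scenarios()] entry.
#' @param output_dir Output directory.
#' @param format Count-matrix dialect, `"csv"` or `"mtx"`.
#' @return Invisibly, the generated dataset.
#' @export
run_simulate <- function(config, output_dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (is.character(config)) {
    presets <- preset_scenarios()
    if (!config %in% names(presets)) {
      stop("unknown preset '", config, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    config <- presets[[config]]
  }
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config)
  counts_file <- file.path(output_dir,
                           if (format == "csv") "counts.csv" else
                             "counts.mtx")
  write_count_matrix(ds$counts, counts_file, format = format)
  write_bcr_table(ds$bcr, file.path(output_dir, "bcr.tsv"))
  truth <- list(
    labels = apply(ds$truth$labels, 2L, identity, simplify = FALSE),
    is_control = as.list(ds$truth$is_control),
    seed = config$seed
  )
  write_json_file(truth, file.path(output_dir, "truth.json"))
  cfg <- unclass(config)
  cfg$noise_params <- lapply(cfg$noise_params, unclass)
  cfg$signal_params <- lapply(cfg$signal_params, unclass)
  write_json_file(cfg, file.path(output_dir, "config.json"))
  invisible(ds)
}

#' Run bootstrap stability analyses and write summaries
#'
#' Reads the sample as in [run_denoise()], then runs the resampling
#' bootstrap on the donor counts of each antigen (and, when `sizes` is
#' given, the downsampling bootstrap), writing `bootstrap_summary.json` and
#' a per-iteration `bootstrap_iterations.tsv`.
#'
#' @param config A [run_config()].
#' @param n_iter Iterations per analysis; default 100.
#' @param sizes Optional integer vector of downsample sizes.
#' @return Invisibly, a list of per-antigen results.
#' @export
run_bootstrap <- function(config, n_iter = 100L, sizes = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_matrix(config$counts_path,
                              format = config$counts_format)
  control_ids <- character(0L)
  donor_ids <- rownames(counts)
  if (!is.null(config$bcr_path) && !is.null(config$reference_cdr3)) {
    bcr <- filter_multi_heavy_chain(read_bcr_table(config$bcr_path))$bcr
    split <- split_control_cells(bcr, config$reference_cdr3,
                                 config$levenshtein_threshold)
    control_ids <- intersect(split$control_cell_ids, rownames(counts))
    donor_ids <- intersect(split$donor_cell_ids, rownames(counts))
  }
  ctrl <- fit_control(maxit = config$maxit, reltol = config$reltol)
  out <- list()
  rows <- list()
  for (ag in colnames(counts)) {
    donor_counts <- remove_outliers(counts[donor_ids, ag],
                                    config$outlier_percentile)$kept
    control_counts <- if (length(control_ids)) {
      remove_outliers(counts[control_ids, ag],
                      config$outlier_percentile)$kept
    } else NULL
    res <- list(resample = suppressWarnings(
      bootstrap_resample(donor_counts, control_counts, n_iter = n_iter,
                         seed = config$seed, omega0 = config$omega0,
                         control = ctrl)))
    if (!is.null(sizes)) {
      res$downsample <- suppressWarnings(
        bootstrap_downsample(donor_counts, sizes = sizes, n_iter = n_iter,
                             seed = config$seed, omega0 = config$omega0,
                             control = ctrl))
    }
    out[[ag]] <- res
    it <- res$resample$per_iteration
    it$antigen <- ag
    it$analysis <- "resample"
    rows[[length(rows) + 1L]] <- it[, c("antigen", "analysis", "iteration",
                                        "ok", "bic", "mean_p_signal")]
    if (!is.null(sizes)) {
      dt <- res$downsample$per_iteration
      dt$antigen <- ag
      dt$analysis <- paste0("downsample_", dt$size)
      rows[[length(rows) + 1L]] <- dt[, c("antigen", "analysis",
                                          "iteration", "ok", "bic",
                                          "mean_p_signal")]
    }
  }
  summary <- lapply(out, function(res) {
    s <- list(sem_mean_p_signal = res$resample$summary$sem_mean_p_signal,
              n_failed = res$resample$summary$n_failed)
    if (!is.null(res$downsample)) s$per_size <- res$downsample$summary$per_size
    s
  })
  write_json_file(summary,
                  file.path(config$output_dir, "bootstrap_summary.json"))
  utils::write.table(do.call(rbind, rows),
                     file.path(config$output_dir,
                               "bootstrap_iterations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
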