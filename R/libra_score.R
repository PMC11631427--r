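#' Zero out unreliable low counts
#'
#' The conventional LIBRA-seq scoring path treats UMI counts below 4 as
#' unreliable and sets them to 0 before the CLR transform. This floor is
#' applied only on the scoring path; the denoising fit uses the raw counts so
#' that the noise structure is preserved.
#'
#' @param matrix A [umi_matrix()].
#' @param floor Counts strictly below this are zeroed; default 4.
#' @return A [umi_matrix()] of the same shape.
#' @export
zero_low_counts <- function(matrix, floor = 4) {
  stopifnot(inherits(matrix, "umi_matrix"), floor >= 0)
  matrix[matrix < floor] <- 0
  matrix
}

#' Centered log-ratio transform, per cell
#'
#' Each cell's counts are shifted by a pseudocount, logged, and centered on
#' the cell's mean log count across the antigen panel, removing per-cell
#' depth effects. Every output row sums to zero.
#'
#' @param matrix A [umi_matrix()].
#' @param pseudocount Added before the log; default 1.
#' @return A numeric `score_matrix` with the same dimnames.
#' @export
clr_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "umi_matrix"), pseudocount > 0)
  lg <- log(unclass(matrix) + pseudocount)
  out <- lg - rowMeans(lg)
  class(out) <- c("score_matrix", "matrix", "array")
  out
}

#' Z-score per antigen
#'
#' Each antigen column is centered on its mean and scaled by its standard
#' deviation (sample convention, `n - 1`, by default) so scores are
#' comparable across cells within an antigen. A zero-variance column is set
#' to all zeros with a warning.
#'
#' @param matrix A `score_matrix` (e.g. from [clr_transform()]) with at
#'   least 2 rows.
#' @param sd_type `"sample"` (divide by `n - 1`; default) or
#'   `"population"` (`n`).
#' @return A `score_matrix` of the same shape.
#' @export
zscore_by_antigen <- function(matrix, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(matrix)
  if (n < 2L) stop("Z-score needs at least 2 cells", call. = FALSE)
  mu <- colMeans(matrix)
  s <- apply(matrix, 2L, stats::sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  out <- sweep(matrix, 2L, mu, "-")
  zero_var <- !is.finite(s) | s == 0
  if (any(zero_var)) {
    warning("zero-variance antigen column(s) set to 0: ",
            paste(colnames(matrix)[zero_var], collapse = ", "),
            call. = FALSE)
    s[zero_var] <- 1
  }
  out <- sweep(out, 2L, s, "/")
  out[, zero_var] <- 0
  class(out) <- c("score_matrix", "matrix", "array")
  out
}

#' LIBRA-seq score (LSS)
#'
#' The baseline binding score: low counts floored to zero, centered
#' log-ratio per cell, then Z-score per antigen. A score of 1 is the
#' conventional binding threshold.
#'
#' @param matrix A [umi_matrix()].
#' @param floor Passed to [zero_low_counts()]; default 4.
#' @param pseudocount Passed to [clr_transform()]; default 1.
#' @param sd_type Passed to [zscore_by_antigen()].
#' @return A `score_matrix` of LSS values.
#' @export
compute_lss <- function(matrix, floor = 4, pseudocount = 1,
                        sd_type = c("sample", "population")) {
  zscore_by_antigen(clr_transform(zero_low_counts(matrix, floor),
                                  pseudocount),
                    sd_type = match.arg(sd_type))
}

#' Combine LSS and posterior signal probability into binding calls
#'
#' A cell-antigen pair is called binding only when both the LIBRA-seq score
#' and the mixture-model posterior clear their thresholds (logical AND).
#' High LSS with low signal probability — the false-positive class the
#' denoiser targets — is therefore not called.
#'
#' @param lss A `score_matrix` of LSS values (cells x antigens).
#' @param p_signal Matrix of posterior signal probabilities with the same
#'   cell and antigen identifiers (any order; aligned by name).
#' @param lss_threshold LSS threshold, default 1 (`>=`).
#' @param ps_threshold Signal-probability threshold, default 0.9 (`>=`).
#' @return A logical matrix of binding calls aligned to `lss`.
#' @export
combine_calls <- function(lss, p_signal, lss_threshold = 1,
                          ps_threshold = 0.9) {
  if (is.null(rownames(lss)) || is.null(rownames(p_signal)) ||
      is.null(colnames(lss)) || is.null(colnames(p_signal))) {
    stop("both matrices need cell and antigen dimnames", call. = FALSE)
  }
  if (!setequal(rownames(lss), rownames(p_signal)) ||
      !setequal(colnames(lss), colnames(p_signal))) {
    stop("cell/antigen sets of `lss` and `p_signal` do not match",
         call. = FALSE)
  }
  p_signal <- p_signal[rownames(lss), colnames(lss), drop = FALSE]
  (lss >= lss_threshold) & (p_signal >= ps_threshold)
}

#' Long-format call table
#'
#' Flattens score, probability, and call matrices into one row per
#' cell-antigen pair for writing to delimited text.
#'
#' @param counts A [umi_matrix()].
#' @param lss LSS `score_matrix`.
#' @param p_signal Posterior signal probability matrix.
#' @param calls Logical call matrix from [combine_calls()].
#' @return A data frame with columns `cell_id`, `antigen`, `k`, `lss`,
#'   `p_signal`, `call`.
#' @export
calls_long_format <- function(counts, lss, p_signal, calls) {
  cells <- rownames(lss); antigens <- colnames(lss)
  data.frame(
    cell_id = rep(cells, times = length(antigens)),
    antigen = rep(antigens, each = length(cells)),
    k = as.vector(unclass(counts)[cells, antigens, drop = FALSE]),
    lss = as.vector(unclass(lss)),
    p_signal = as.vector(p_signal[cells, antigens, drop = FALSE]),
    call = ifelse(as.vector(calls[cells, antigens, drop = FALSE]),
                  "bind", "no_bind"),
    stringsAsFactors = FALSE
  )
}
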