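#' Validate and construct a cell-by-antigen UMI count matrix
#'
#' The container for raw antigen-barcode counts: a base integer matrix with
#' cell barcodes as row names and antigen names as column names. All entries
#' must be nonnegative integers and identifiers unique.
#'
#' @param counts Numeric matrix of nonnegative integers.
#' @param cell_ids,antigen_ids Optional identifier vectors; taken from
#'   `dimnames(counts)` when omitted.
#' @return A validated matrix of class `umi_matrix`.
#' @export
umi_matrix <- function(counts, cell_ids = rownames(counts),
                       antigen_ids = colnames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  bad <- which(counts < 0 | counts != floor(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be nonnegative integers; first offending entry at row %d, column %d (value %g)",
      rc[1L], rc[2L], counts[bad[1L]]), call. = FALSE)
  }
  if (is.null(cell_ids) || is.null(antigen_ids)) {
    stop("cell and antigen identifiers are required", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(antigen_ids)) stop("duplicate antigen ids", call. = FALSE)
  if (length(cell_ids) != nrow(counts) ||
      length(antigen_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(as.character(cell_ids), as.character(antigen_ids))
  class(counts) <- c("umi_matrix", class(matrix()))
  counts
}

#' Read a UMI count matrix
#'
#' CSV dialect: a header row of antigen names and a first column of cell
#' barcodes. MTX dialect: a Matrix Market sparse matrix at `path` with
#' sidecar files `<path>.rows` (cell barcodes) and `<path>.cols` (antigen
#' names), one name per line.
#'
#' @param path Path to the matrix file.
#' @param format `"csv"` or `"mtx"`.
#' @return A validated [umi_matrix()].
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("csv must have a barcode column plus at least one antigen column",
                            call. = FALSE)
    cells <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      stop("non-numeric entries in count matrix ", path, call. = FALSE)
    }
    umi_matrix(m, cell_ids = cells, antigen_ids = colnames(df)[-1L])
  } else {
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("mtx sidecar name files not found: expected ", rows_file,
           " and ", cols_file, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    cells <- readLines(rows_file)
    antigens <- readLines(cols_file)
    umi_matrix(m, cell_ids = cells, antigen_ids = antigens)
  }
}

#' Write a UMI count matrix
#'
#' Inverse of [read_count_matrix()]; the CSV writer emits a `cell_id` header
#' for the barcode column, the MTX writer emits the `.rows`/`.cols`
#' sidecars.
#'
#' @param matrix A [umi_matrix()].
#' @param path Output path.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "umi_matrix"))
  if (format == "csv") {
    df <- data.frame(cell_id = rownames(matrix), unclass(matrix),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(matrix), sparse = TRUE), path)
    writeLines(rownames(matrix), paste0(path, ".rows"))
    writeLines(colnames(matrix), paste0(path, ".cols"))
  }
  invisible(path)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct/validate a BCR chain table
#'
#' One row per receptor chain: `cell_id`, `chain` (`"heavy"`/`"light"`), and
#' the CDR3 amino-acid string `cdr3_aa` (20-letter alphabet plus `X`).
#' Duplicate `(cell_id, chain, cdr3_aa)` triples are collapsed to one row.
#'
#' @param df A data frame with the three columns above.
#' @return A validated data frame of class `bcr_table`.
#' @export
bcr_table <- function(df) {
  need <- c("cell_id", "chain", "cdr3_aa")
  if (!all(need %in% names(df))) {
    stop("BCR table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  df$cell_id <- as.character(df$cell_id)
  df$chain <- as.character(df$chain)
  df$cdr3_aa <- toupper(as.character(df$cdr3_aa))
  if (!all(df$chain %in% c("heavy", "light"))) {
    stop("chain must be 'heavy' or 'light'", call. = FALSE)
  }
  ok <- nchar(df$cdr3_aa) > 0L &
    grepl(sprintf("^[%sX]+$", paste(AA_ALPHABET, collapse = "")), df$cdr3_aa)
  if (!all(ok)) {
    stop("invalid CDR3 amino-acid string at row ", which(!ok)[1L],
         call. = FALSE)
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("bcr_table", "data.frame")
  df
}

#' Read a BCR chain table
#'
#' Tab-delimited with at least `cell_id`, `chain`, `cdr3_aa`. AIRR-style
#' aliases are mapped: `junction_aa` to `cdr3_aa`, and `locus` (IGH vs
#' IGK/IGL) to `chain`.
#'
#' @param path Path to the TSV file.
#' @return A [bcr_table()].
#' @export
read_bcr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"cdr3_aa" %in% names(df) && "junction_aa" %in% names(df)) {
    df$cdr3_aa <- df$junction_aa
  }
  if (!"chain" %in% names(df) && "locus" %in% names(df)) {
    df$chain <- ifelse(toupper(df$locus) == "IGH", "heavy", "light")
  }
  bcr_table(df)
}

#' Write a BCR chain table
#' @param bcr A [bcr_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bcr_table <- function(bcr, path) {
  utils::write.table(bcr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove cells carrying more than one heavy chain
#'
#' Cells with two or more distinct heavy-chain CDR3 records plausibly
#' represent multiplet capture or sequencing error and are removed entirely
#' (all their rows, light chains included) before denoising.
#'
#' @param bcr A [bcr_table()].
#' @return A list with `bcr` (the filtered table) and `removed_cell_ids`.
#' @export
filter_multi_heavy_chain <- function(bcr) {
  bcr <- bcr_table(bcr)
  heavy <- bcr[bcr$chain == "heavy", ]
  n_heavy <- tapply(heavy$cdr3_aa, heavy$cell_id,
                    function(x) length(unique(x)))
  removed <- names(n_heavy)[n_heavy > 1L]
  kept <- bcr[!(bcr$cell_id %in% removed), ]
  rownames(kept) <- NULL
  class(kept) <- c("bcr_table", "data.frame")
  list(bcr = kept, removed_cell_ids = removed)
}

#' Normalized Levenshtein distance
#'
#' Unit-cost edit distance (insert/delete/substitute) divided by the length
#' of the longer string, giving a ratio in `[0, 1]`; the `max(len)`
#' denominator keeps the measure symmetric and maps a threshold of 0.05 onto
#' "at least 95% identity". Vectorized over `a`.
#'
#' @param a Character vector of nonempty strings.
#' @param b A single nonempty string.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
normalized_levenshtein <- function(a, b) {
  if (any(!nzchar(a)) || length(b) != 1L || !nzchar(b)) {
    stop("strings must be nonempty", call. = FALSE)
  }
  d <- as.numeric(utils::adist(a, b))
  d / pmax(nchar(a), nchar(b))
}

#' Split negative-control cells from donor cells by CDR3 similarity
#'
#' Cells whose single heavy-chain CDR3 is within a normalized Levenshtein
#' distance of `threshold` from the control antibody's reference CDR3 are
#' classed as negative controls; all others are donor cells. Cells without a
#' heavy chain cannot be classified and are excluded with a warning.
#'
#' @param bcr A [bcr_table()] already passed through
#'   [filter_multi_heavy_chain()].
#' @param reference_cdr3 Heavy-chain CDR3 of the control antibody.
#' @param threshold Distance threshold in `(0, 1)`; default 0.05, applied
#'   inclusively (`<=`).
#' @return A list of class `split_result` with `control_cell_ids`,
#'   `donor_cell_ids`, `excluded_cell_ids`, and the named `distances` vector
#'   for audit.
#' @export
split_control_cells <- function(bcr, reference_cdr3, threshold = 0.05) {
  bcr <- bcr_table(bcr)
  stopifnot(threshold > 0, threshold < 1)
  heavy <- bcr[bcr$chain == "heavy", ]
  all_cells <- unique(bcr$cell_id)
  excluded <- setdiff(all_cells, heavy$cell_id)
  if (length(excluded)) {
    warning(length(excluded),
            " cell(s) without a heavy chain excluded from the control split",
            call. = FALSE)
  }
  d <- normalized_levenshtein(heavy$cdr3_aa, reference_cdr3)
  names(d) <- heavy$cell_id
  structure(list(
    control_cell_ids = heavy$cell_id[d <= threshold],
    donor_cell_ids = heavy$cell_id[d > threshold],
    excluded_cell_ids = excluded,
    distances = d,
    threshold = threshold
  ), class = "split_result")
}

#' Trim high-count outliers at a percentile
#'
#' Values strictly greater than the stated percentile (linear-interpolation
#' quantile convention, `type = 7`) are removed; ties at the percentile are
#' kept, and the minimum is never removed. Intended to be applied per
#' antigen, separately to the control and donor populations.
#'
#' @param values Nonnegative integer counts.
#' @param percentile Percentile in `(0, 100]`; default 99.
#' @return A list with `kept` and `removed` (multisets; together a
#'   permutation of the input) and the `cutoff` used.
#' @export
remove_outliers <- function(values, percentile = 99) {
  values <- assert_counts(values, "values")
  stopifnot(percentile > 0, percentile <= 100)
  cutoff <- stats::quantile(values, probs = percentile / 100, type = 7,
                            names = FALSE)
  keep <- values <= cutoff
  list(kept = values[keep], removed = values[!keep], cutoff = cutoff)
}
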