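# Internal numeric and validation helpers.

# Elementwise log(exp(a) + exp(b)) without overflow; handles -Inf pairs.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  lo <- pmin(a, b)
  out <- m + log1p(exp(lo - m))
  both_ninf <- is.infinite(m) & m < 0
  out[both_ninf] <- -Inf
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

assert_counts <- function(x, what = "counts") {
  if (length(x) == 0L) stop(what, " must be nonempty", call. = FALSE)
  if (anyNA(x) || !is.numeric(x)) {
    stop(what, " must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < 0) || any(x != floor(x))) {
    stop(what, " must be nonnegative integers", call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Collapse a count vector to unique values + multiplicities: the NB mixture
# NLL is a weighted sum over unique k, which makes optimisation O(#unique).
aggregate_counts <- function(counts) {
  tab <- table(counts)
  list(k = as.numeric(names(tab)), w = as.numeric(tab))
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
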