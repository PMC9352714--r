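# Internal helpers shared across modules.

#' Evaluate code with a temporary, restored RNG state
#'
#' All randomized operations in the package funnel through this helper so that
#' an explicit seed fully determines their output without clobbering the
#' caller's RNG stream.
#'
#' @param seed integer seed; must not be `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("an explicit integer `seed` is required for randomized operations",
         call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Split strings of equal length into a character matrix (one row per string).
str_to_mat <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

# Hamming distances from a single query string to a set given as a char matrix.
hamming_to_set <- function(query_chars, set_mat) {
  rowSums(set_mat != matrix(query_chars, nrow = nrow(set_mat),
                            ncol = length(query_chars), byrow = TRUE))
}

# All-pairs Hamming distance matrix for equal-length strings.
hamming_matrix <- function(x) {
  m <- str_to_mat(x)
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], FUN = "!=")
  }
  d
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Linear-interpolation percentile (R type-7 quantile), the single percentile
# convention used throughout the package.
pctile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
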