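# Per-sample clonal diversity: clone number, Shannon index, Lorenz-curve
# area, each evaluated on a per-million-read basis so that samples sequenced
# to different depths are comparable.

#' Subsample a clone table to a fixed read depth
#'
#' Draws exactly `target_reads` reads without replacement across clones (a
#' multivariate hypergeometric draw; clones drawn to zero are dropped) when
#' the table exceeds the target, and returns the table unchanged otherwise.
#' Clone number is deliberately not rescaled linearly: under heavy-tailed
#' clone sizes the number of clones observed is a non-linear function of
#' depth, so diversity measures are evaluated on an actual subsample.
#'
#' @param table a `CloneTable`.
#' @param target_reads target depth (default 1e6).
#' @param seed integer seed (required when subsampling occurs).
#' @return a `CloneTable` with attribute `subsampled` (logical).
#' @export
per_million_subsample <- function(table, target_reads = 1e6, seed = NULL) {
  stopifnot(inherits(table, "CloneTable"), target_reads >= 1)
  n <- total_reads(table)
  if (n <= target_reads) {
    attr(table, "subsampled") <- FALSE
    return(table)
  }
  counts <- table$reads
  new_counts <- with_seed(seed, {
    remaining <- n
    take <- as.integer(target_reads)
    out <- integer(length(counts))
    for (i in seq_along(counts)) {
      if (take == 0L) break
      remaining <- remaining - counts[i]
      x <- stats::rhyper(1, counts[i], remaining, take)
      out[i] <- x
      take <- take - x
    }
    out
  })
  keep <- new_counts > 0L
  out <- clone_table(data.frame(guide_id = table$guide_id[keep],
                                umi = table$umi[keep],
                                reads = new_counts[keep],
                                stringsAsFactors = FALSE),
                     sample_id = attr(table, "sample_id"))
  attr(out, "subsampled") <- TRUE
  out
}

#' Shannon diversity index of a clone table
#'
#' The entropy \eqn{-\sum_i p_i \ln p_i} (natural log, nats) of the clone
#' read-share distribution \eqn{p_i = \mathrm{reads}_i / \mathrm{total}}: a
#' composite measure of clone number and evenness, maximal at `ln(n)` for
#' `n` equal clones.
#'
#' @param table a `CloneTable` with at least one clone.
#' @return the index in nats.
#' @export
shannon_diversity <- function(table) {
  if (nrow(table) == 0L) stop("cannot compute diversity of an empty clone table",
                              call. = FALSE)
  p <- table$reads / total_reads(table)
  -sum(p * log(p))
}

#' Area under the Lorenz curve of clone sizes
#'
#' Clones are sorted by ascending size; the curve passes through (0, 0) and
#' the points (i/n, cumulative read share of the i smallest clones); the
#' trapezoidal area under it measures clone-size evenness.  Equal clones give
#' the diagonal (area 0.5); heavier-tailed size distributions bow the curve
#' away from the diagonal and shrink the area.
#'
#' @param table a `CloneTable` with at least one clone.
#' @return area in (0, 0.5].
#' @export
lorenz_auc <- function(table) {
  if (nrow(table) == 0L) stop("cannot compute Lorenz area of an empty clone table",
                              call. = FALSE)
  s <- sort(table$reads)
  n <- length(s)
  f <- cumsum(s) / sum(s)
  heights <- (c(0, f[-n]) + f) / 2
  sum(heights) / n
}

#' Per-million diversity summary of a clone table
#'
#' Applies [per_million_subsample()] once, then reports the clone count,
#' Shannon diversity index and Lorenz-curve area of the (sub)sampled table.
#'
#' @param table a `CloneTable`.
#' @param target_reads evaluation depth (default 1e6).
#' @param seed integer seed for the subsample.
#' @return a `DiversitySummary` list: `clones_per_million`, `sdi_per_million`,
#'   `lorenz_auc`, `n_reads_used`, `subsampled`.
#' @export
diversity_summary <- function(table, target_reads = 1e6, seed = 1L) {
  sub <- per_million_subsample(table, target_reads = target_reads, seed = seed)
  structure(list(clones_per_million = nrow(sub),
                 sdi_per_million = shannon_diversity(sub),
                 lorenz_auc = lorenz_auc(sub),
                 n_reads_used = total_reads(sub),
                 subsampled = attr(sub, "subsampled")),
            class = "DiversitySummary")
}

#' @export
print.DiversitySummary <- function(x, ...) {
  cat(sprintf("DiversitySummary: %d clones, SDI %.3f nats, Lorenz AUC %.4f (%s reads%s)\n",
              x$clones_per_million, x$sdi_per_million, x$lorenz_auc,
              format(x$n_reads_used, big.mark = ","),
              if (x$subsampled) ", subsampled" else ""))
  invisible(x)
}
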