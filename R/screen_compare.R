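# Post-inference analysis: normalization, neutrality calls, pairwise screen
# comparison with outlier criteria, Hasse-poset resolution, subsampling.

#' Normalize fitness so the 70th centile of targeting guides is 1
#'
#' Fitness is a relative quantity; to compare datasets and libraries, each
#' dataset is rescaled so that the 70th centile (linear interpolation) of
#' gene-targeting-guide posterior medians sits at the neutral level 1.
#' Control guides are excluded from the scalar but rescaled by it.  The
#' operation is idempotent.
#'
#' @param x a `FitnessPosterior`, or a numeric vector of fitness medians.
#' @param ... passed to methods.
#' @return the normalized object (a `NormalizedFitness` posterior, or a
#'   numeric vector with attribute `norm_scalar`).
#' @export
normalize_fitness <- function(x, ...) UseMethod("normalize_fitness")

#' @param guide_class character vector parallel to `x` (numeric method):
#'   guides with class `"targeting"` define the scalar.
#' @rdname normalize_fitness
#' @export
normalize_fitness.numeric <- function(x, guide_class, ...) {
  stopifnot(length(guide_class) == length(x))
  targ <- guide_class == "targeting"
  if (sum(targ) < 3L) stop("need at least three targeting guides", call. = FALSE)
  scalar <- pctile(x[targ], 0.70)
  if (!is.finite(scalar) || scalar <= 0) {
    stop("normalization scalar must be positive", call. = FALSE)
  }
  structure(x / scalar, norm_scalar = scalar)
}

#' @rdname normalize_fitness
#' @export
normalize_fitness.FitnessPosterior <- function(x, ...) {
  cls <- x$library$guides$guide_class[match(x$guide_id,
                                            x$library$guides$guide_id)]
  targ <- cls == "targeting"
  if (sum(targ) < 3L) stop("need at least three targeting guides", call. = FALSE)
  scalar <- pctile(x$summary$median[targ], 0.70)
  if (!is.finite(scalar) || scalar <= 0) {
    stop("normalization scalar must be positive", call. = FALSE)
  }
  x$f_draws <- x$f_draws / scalar
  for (col in c("median", "lo95", "hi95", "lo90", "hi90")) {
    x$summary[[col]] <- x$summary[[col]] / scalar
  }
  x$norm_scalar <- if (isTRUE(x$normalized)) x$norm_scalar * scalar else scalar
  x$normalized <- TRUE
  class(x) <- unique(c("NormalizedFitness", class(x)))
  x
}

#' Call guides that differ from neutrality
#'
#' Per guide, a posterior tail "p-value" against the neutral level 1 is
#' computed from normalized fitness draws, `p = 2 min(Pr(f <= 1),
#' Pr(f >= 1))`, floored at `1 / n_draws`; Benjamini-Hochberg adjustment is
#' applied across gene-targeting guides (controls are reported unadjusted)
#' and guides with adjusted `p < alpha` are flagged, labelled `low` or
#' `high` by the side of their median.
#'
#' @param normalized a `NormalizedFitness` posterior (see
#'   [normalize_fitness()]).
#' @param alpha false discovery rate threshold (default 0.05).
#' @return data frame: `guide_id`, `guide_class`, `median`, `p`, `p_adj`,
#'   `direction`, `significant`.
#' @export
call_nonneutral <- function(normalized, alpha = 0.05) {
  stopifnot(inherits(normalized, "FitnessPosterior"))
  if (!isTRUE(normalized$normalized)) {
    stop("call_nonneutral() expects a normalized posterior; run normalize_fitness() first",
         call. = FALSE)
  }
  f <- normalized$f_draws
  nd <- ncol(f)
  p_lo <- rowMeans(f <= 1)
  p_hi <- rowMeans(f >= 1)
  p <- pmax(2 * pmin(p_lo, p_hi), 1 / nd)
  p <- pmin(p, 1)
  cls <- normalized$library$guides$guide_class[
    match(normalized$guide_id, normalized$library$guides$guide_id)]
  targ <- cls == "targeting"
  p_adj <- rep(NA_real_, length(p))
  p_adj[targ] <- stats::p.adjust(p[targ], method = "BH")
  med <- normalized$summary$median
  data.frame(guide_id = normalized$guide_id, guide_class = cls,
             median = med, p = p, p_adj = p_adj,
             direction = ifelse(med < 1, "low", "high"),
             significant = !is.na(p_adj) & p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Compare two screens guide by guide
#'
#' Pairs posterior draws by index (chains are independent, so the pairing
#' order is arbitrary but seed-stable) and evaluates, per guide, the three
#' outlier criteria: (c1) the 95\% equal-tailed interval of the normalized
#' fitness differential (B - A) excludes 0; (c2) the guide's median
#' differential lies outside the central 95\% range of control-guide median
#' differentials (significance relative to neutral-guide variability); (c3)
#' the 95\% interval of the within-dataset rank differential excludes 0.
#' A gene is an outlier when at least two of its guides satisfy all three
#' criteria.  Also reports the Spearman correlation of median fitness.
#'
#' @param postA,postB `NormalizedFitness` posteriors over the same library.
#' @return a `ScreenComparison`: `guides` (per-guide flags and differential
#'   summaries), `genes` (per-gene outlier flags), `spearman_rho`,
#'   `degraded` (TRUE when fewer than 5 control guides were available for
#'   c2).
#' @export
compare_datasets <- function(postA, postB) {
  stopifnot(inherits(postA, "FitnessPosterior"), inherits(postB, "FitnessPosterior"))
  if (!isTRUE(postA$normalized) || !isTRUE(postB$normalized)) {
    stop("both posteriors must be normalized before comparison", call. = FALSE)
  }
  if (!identical(postA$guide_id, postB$guide_id)) {
    stop("posteriors must cover the same guides (same library and exclusions)",
         call. = FALSE)
  }
  S <- min(ncol(postA$f_draws), ncol(postB$f_draws))
  dfit <- postB$f_draws[, seq_len(S)] - postA$f_draws[, seq_len(S)]
  drank <- postB$rank_draws[, seq_len(S)] - postA$rank_draws[, seq_len(S)]
  lo <- apply(dfit, 1, pctile, 0.025); hi <- apply(dfit, 1, pctile, 0.975)
  rlo <- apply(drank, 1, pctile, 0.025); rhi <- apply(drank, 1, pctile, 0.975)
  med_diff <- apply(dfit, 1, stats::median)
  c1 <- lo > 0 | hi < 0
  c3 <- rlo > 0 | rhi < 0

  cls <- postA$library$guides$guide_class[
    match(postA$guide_id, postA$library$guides$guide_id)]
  gene <- postA$library$guides$gene[
    match(postA$guide_id, postA$library$guides$guide_id)]
  ctrl <- cls != "targeting"
  degraded <- sum(ctrl) < 5L
  if (degraded) {
    warning("fewer than 5 control guides; criterion c2 unavailable", call. = FALSE)
    c2 <- rep(NA, length(c1))
  } else {
    band <- pctile(med_diff[ctrl], c(0.025, 0.975))
    c2 <- med_diff < band[1] | med_diff > band[2]
  }
  pass <- c1 & !is.na(c2) & c2 & c3
  guides <- data.frame(guide_id = postA$guide_id, gene = gene,
                       guide_class = cls,
                       median_diff = med_diff, lo95_diff = lo, hi95_diff = hi,
                       median_rank_diff = apply(drank, 1, stats::median),
                       c1 = c1, c2 = c2, c3 = c3, outlier = pass,
                       stringsAsFactors = FALSE)
  targ <- guides[guides$guide_class == "targeting" & !is.na(guides$gene), ]
  n_pass <- tapply(targ$outlier, targ$gene, sum)
  genes <- data.frame(gene = names(n_pass),
                      n_outlier_guides = as.integer(n_pass),
                      outlier = as.integer(n_pass) >= 2L,
                      stringsAsFactors = FALSE)
  structure(list(guides = guides, genes = genes,
                 spearman_rho = spearman_guides(postA, postB),
                 degraded = degraded),
            class = "ScreenComparison")
}

#' @export
print.ScreenComparison <- function(x, ...) {
  cat(sprintf("ScreenComparison: %d guides, %d outlier guide(s), %d outlier gene(s); Spearman rho %.3f%s\n",
              nrow(x$guides), sum(x$guides$outlier, na.rm = TRUE),
              sum(x$genes$outlier), x$spearman_rho,
              if (x$degraded) " [degraded: <5 controls]" else ""))
  invisible(x)
}

#' Hasse diagram of the resolved fitness partial order
#'
#' Guide `a` precedes guide `b` when their 95\% credible intervals do not
#' overlap (`hi95(a) < lo95(b)`); this interval order is transitive, and
#' the Hasse edges are its transitive reduction (edges implied by a 2-step
#' path removed).  The number of ordered pairs in the full relation is the
#' count of resolved pairs.
#'
#' @param summaries data frame with columns `guide_id`, `lo95`, `hi95`
#'   (e.g. the `summary` element of a `FitnessPosterior`).
#' @return a `PosetGraph`: `nodes`, `edges` (data frame `from`, `to`),
#'   `resolved_pairs`.
#' @export
hasse_poset <- function(summaries) {
  stopifnot(all(c("guide_id", "lo95", "hi95") %in% names(summaries)))
  n <- nrow(summaries)
  R <- outer(summaries$hi95, summaries$lo95, FUN = "<")
  diag(R) <- FALSE
  # interval orders are transitive; reduction removes edges with a 2-step path
  two_step <- (R %*% R) > 0
  H <- R & !two_step
  idx <- which(H, arr.ind = TRUE)
  edges <- data.frame(from = summaries$guide_id[idx[, 1]],
                      to = summaries$guide_id[idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = summaries$guide_id, edges = edges,
                 resolved_pairs = sum(R)),
            class = "PosetGraph")
}

#' @export
print.PosetGraph <- function(x, ...) {
  cat(sprintf("PosetGraph: %d nodes, %d Hasse edges, %d resolved pairs\n",
              length(x$nodes), nrow(x$edges), x$resolved_pairs))
  invisible(x)
}

#' Serialize a poset graph to DOT format
#'
#' @param poset a `PosetGraph`.
#' @param path optional output file; when `NULL` the DOT text is returned.
#' @export
poset_to_dot <- function(poset, path = NULL) {
  lines <- c("digraph fitness_poset {",
             paste0("  \"", poset$nodes, "\";"),
             if (nrow(poset$edges)) {
               paste0("  \"", poset$edges$from, "\" -> \"", poset$edges$to, "\";")
             },
             "}")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Subsample clones of a screen dataset in silico
#'
#' Uniform without-replacement sample of clones (not reads) across the whole
#' dataset, emulating a lower-diversity transplant; initial counts are
#' unchanged.
#'
#' @param dataset a `ScreenDataset`.
#' @param fraction fraction of clones to retain (exact count
#'   `floor(fraction * n_clones)`), or
#' @param n absolute number of clones to retain.
#' @param seed integer seed.
#' @return a `ScreenDataset`.
#' @export
subsample_clones <- function(dataset, fraction = NULL, n = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  k <- lengths(dataset$clone_sizes)
  total <- sum(k)
  if (is.null(n)) {
    stopifnot(!is.null(fraction), fraction > 0, fraction <= 1)
    n <- floor(fraction * total + 1e-9)
  }
  stopifnot(n >= 0, n <= total)
  if (n == total) return(dataset)
  guide_of <- rep(names(dataset$clone_sizes), k)
  size_of <- unlist(dataset$clone_sizes, use.names = FALSE)
  keep <- with_seed(seed, sort(sample.int(total, n)))
  new_sizes <- split(size_of[keep],
                     factor(guide_of[keep], levels = names(dataset$clone_sizes)))
  out <- dataset
  out$clone_sizes <- lapply(new_sizes, as.integer)
  out
}

#' Combine biological replicate datasets into one
#'
#' Clone lists are concatenated per guide; initial counts come from the
#' shared plasmid table.
#'
#' @param datasets list of `ScreenDataset`s over the same library and
#'   initial counts.
#' @param sample_id label of the combined dataset.
#' @return a `ScreenDataset`.
#' @export
combine_replicates <- function(datasets, sample_id = "combined") {
  if (inherits(datasets, "ScreenDataset")) return(datasets)
  stopifnot(length(datasets) >= 1L)
  lib_names <- unique(vapply(datasets, function(d) d$library$name, ""))
  if (length(lib_names) != 1L) stop("datasets use different libraries", call. = FALSE)
  ic <- datasets[[1]]$initial_counts
  for (d in datasets[-1]) {
    if (!identical(d$initial_counts, ic)) {
      stop("datasets use different initial-count tables", call. = FALSE)
    }
  }
  sizes <- datasets[[1]]$clone_sizes
  for (d in datasets[-1]) {
    for (g in names(sizes)) sizes[[g]] <- c(sizes[[g]], d$clone_sizes[[g]])
  }
  out <- datasets[[1]]
  out$sample_id <- sample_id
  out$clone_sizes <- sizes
  out
}

#' Spearman rank correlation of guide fitness between two fits
#'
#' @param postA,postB `FitnessPosterior`s sharing at least 3 guides.
#' @return Spearman's rho of the median fitness vectors (average ranks for
#'   ties).
#' @export
spearman_guides <- function(postA, postB) {
  shared <- intersect(postA$guide_id, postB$guide_id)
  if (length(shared) < 3L) stop("need at least 3 shared guides", call. = FALSE)
  a <- postA$summary$median[match(shared, postA$guide_id)]
  b <- postB$summary$median[match(shared, postB$guide_id)]
  stats::cor(a, b, method = "spearman")
}
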