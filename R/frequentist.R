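# Frequentist comparator: ratio statistic with delta-method intervals.

#' Delta-method fitness estimates
#'
#' A non-Bayesian reference estimator for cross-checking the posterior.  Per
#' guide, clone sizes are winsorized at the empirical per-guide 98th centile
#' (linear-interpolation quantile) and summed to a winsorized total output
#' `S_t`; the ratio `S_t / I_t` against plasmid initial counts is then
#' normalized so that the 70th centile of the ratio among gene-targeting
#' guides equals 1.  The variance of the ratio comes from a first-order
#' delta expansion treating `S_t` as a sum of `K_t` iid winsorized clone
#' sizes (empirical winsorized variance times `K_t`) and `I_t` as a Poisson
#' count; the 95\% interval is symmetric on the log scale.
#'
#' Guides with no observed clones get estimate 0 with a one-sided interval
#' and are flagged.
#'
#' @param dataset a `ScreenDataset`.
#' @param winsor_upper_fraction upper-tail fraction winsorized (default
#'   0.02).
#' @return data frame of `FrequentistEstimate` rows: `guide_id`,
#'   `estimate`, `lo95`, `hi95`, `n_clones`, `flagged`.
#' @export
delta_method_fitness <- function(dataset, winsor_upper_fraction = 0.02) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  ids <- dataset$library$guides$guide_id
  I <- dataset$initial_counts[ids]
  keep <- I > 0
  if (any(!keep)) {
    message("excluding ", sum(!keep), " guide(s) with zero initial counts")
  }
  ids <- ids[keep]
  I <- as.numeric(I[keep])
  targeting <- dataset$library$guides$guide_class[keep] == "targeting"

  S <- numeric(length(ids))
  vS <- numeric(length(ids))
  K <- integer(length(ids))
  for (i in seq_along(ids)) {
    y <- dataset$clone_sizes[[ids[i]]]
    K[i] <- length(y)
    if (K[i] == 0L) next
    yw <- winsorize_sample(y, upper_fraction = winsor_upper_fraction)
    S[i] <- sum(yw)
    vS[i] <- if (K[i] > 1L) stats::var(yw) * K[i] else yw^2
  }
  ratio <- S / I
  if (sum(targeting) < 3L) {
    stop("need at least three targeting guides for normalization", call. = FALSE)
  }
  Z <- pctile(ratio[targeting], 0.70)
  if (Z <= 0) stop("normalizer is non-positive (no targeting-guide output)",
                   call. = FALSE)
  est <- ratio / Z
  # delta method on log(S/I): var(log R) ~ var(S)/S^2 + var(I)/I^2, I Poisson
  se_log <- ifelse(K > 0, sqrt(vS / pmax(S, 1)^2 + 1 / I), NA_real_)
  lo <- ifelse(K > 0, est * exp(-1.96 * se_log), 0)
  hi <- ifelse(K > 0, est * exp(1.96 * se_log),
               # one-sided bound from zero observed clones: Poisson upper 97.5%
               (3.69 / I) / Z)
  data.frame(guide_id = ids, estimate = est, lo95 = lo, hi95 = hi,
             n_clones = K, flagged = K == 0L, stringsAsFactors = FALSE)
}
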