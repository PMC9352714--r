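# Synthetic-screen simulator.
#
# Emulates the statistical structure the analysis assumes: a skewed plasmid
# library, a Poisson engraftment bottleneck modulated by per-guide
# engraftment factors, heavy-tailed clone sizes from a two-component NB
# mixture scaled by per-guide size factors, and (optionally) paired amplicon
# FASTQ with UMI substitution errors.  Every draw is governed by one seed.

#' Simulation configuration
#'
#' Defaults are calibrated to the screens the package models: log-normal
#' library skew with a 90th/10th guide-count ratio near 4, a few hundred
#' clones per guide, and a two-component negative-binomial clone-size
#' mixture whose minority large-clone component (heavier dispersion) makes
#' clone sizes span three to four orders of magnitude.
#'
#' @param library a `LibraryDesign` or a fixture name (`"signaling"`,
#'   `"notch"`).
#' @param seed mandatory integer seed.
#' @param clones_per_guide expected clones per guide for a neutral guide at
#'   average library representation (default 500).
#' @param library_sigma log-normal sigma of plasmid counts; the default
#'   0.535 gives a 90th/10th centile ratio of ~3.9.
#' @param mean_initial mean plasmid reads per guide (default 1000).
#' @param eps_star,phi_star named vectors of true per-guide engraftment and
#'   clone-size factors (default all 1; unnamed scalars recycle).
#' @param initial_counts optional named vector of plasmid reads per guide.
#'   Biological replicates of one experiment share a single plasmid pool, so
#'   replicate simulations should pass the first replicate's counts here;
#'   when `NULL` (default) counts are drawn from the skewed log-normal.
#' @param likelihood clone-size family for the generator (default
#'   `"mix_nb"`).
#' @param size_params parameter list for the family (default two NB
#'   components: means 5 and 50, dispersions 1 and 0.4, weight 0.7 on the
#'   small component).
#' @param umi_error_rate per-base substitution rate applied to UMIs when
#'   emitting FASTQ (default 0).
#' @param winsor_upper_fraction upper fraction used for the true winsorized
#'   mean recorded in the truth table.
#' @return a `SimulationConfig`.
#' @export
simulation_config <- function(library = "signaling", seed,
                              clones_per_guide = 500,
                              library_sigma = 0.535,
                              mean_initial = 1000,
                              initial_counts = NULL,
                              eps_star = 1, phi_star = 1,
                              likelihood = "mix_nb",
                              size_params = list(mean1 = 5, size1 = 1,
                                                 mean2 = 50, size2 = 0.4,
                                                 w = 0.7),
                              umi_error_rate = 0,
                              winsor_upper_fraction = 0.02) {
  if (is.character(library)) library <- make_fixture(library)
  stopifnot(inherits(library, "LibraryDesign"),
            clones_per_guide > 0, library_sigma >= 0, mean_initial > 0,
            umi_error_rate >= 0, umi_error_rate < 1)
  if (missing(seed)) stop("simulation_config() requires an explicit seed",
                          call. = FALSE)
  ids <- library$guides$guide_id
  expand <- function(x) {
    if (is.null(names(x))) {
      stats::setNames(rep_len(x, length(ids)), ids)
    } else {
      out <- stats::setNames(rep(1, length(ids)), ids)
      out[names(x)] <- x
      out
    }
  }
  if (!is.null(initial_counts)) {
    stopifnot(all(ids %in% names(initial_counts)))
    initial_counts <- initial_counts[ids]
  }
  structure(list(library = library, seed = as.integer(seed),
                 clones_per_guide = clones_per_guide,
                 library_sigma = library_sigma, mean_initial = mean_initial,
                 initial_counts = initial_counts,
                 eps_star = expand(eps_star), phi_star = expand(phi_star),
                 likelihood = likelihood, size_params = size_params,
                 umi_error_rate = umi_error_rate,
                 winsor_upper_fraction = winsor_upper_fraction),
            class = "SimulationConfig")
}

# Scale a family's parameter list by a guide size factor phi.
scale_size_params <- function(likelihood, params, phi) {
  p <- params
  if (likelihood %in% c("mix_nb", "mix_bnb", "mix_bnb_local")) {
    p$mean1 <- params$mean1 * phi
    p$mean2 <- params$mean2 * phi
  } else if (likelihood == "ys") {
    p$rho <- params$rho / phi
  } else {
    p$mean <- params$mean * phi
  }
  p
}

# Draw concrete UMIs from a degenerate template, distinct within the call.
realize_umis <- function(template, n) {
  chars <- strsplit(oriented_pattern(template, "forward"), "", fixed = TRUE)[[1]]
  deg <- which(chars %in% c("N", "S"))
  draw <- function(m) {
    base <- matrix(rep(chars, m), nrow = m, byrow = TRUE)
    for (d in deg) {
      pool <- if (chars[d] == "N") c("A", "C", "G", "T") else c("C", "G")
      base[, d] <- sample(pool, m, replace = TRUE)
    }
    apply(base, 1, paste, collapse = "")
  }
  out <- unique(draw(n))
  while (length(out) < n) out <- unique(c(out, draw(n - length(out))))
  out[seq_len(n)]
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

#' Simulate a synthetic screen
#'
#' Draws plasmid initial counts `I_t` from a skewed log-normal, observed
#' clone numbers `K_t ~ Poisson(base * pi_t * eps*_t)` with `pi_t = I_t /
#' sum(I)`, and clone sizes from the configured zero-truncated family scaled
#' by `phi*_t`.  The truth table records each guide's generative factors and
#' its true fitness `eps*_t` times the winsorized mean of its generative
#' clone-size distribution.  When `fastq_prefix` is given, paired amplicon
#' FASTQ is written: forward reads embed the anchor, a 23-nt spacer and the
#' guide; reverse reads embed the reverse anchor and the reverse-complement
#' UMI, with UMI substitution errors at the configured rate and constant
#' phred 37; one read pair per clone read.
#'
#' @param config a `SimulationConfig`.
#' @param fastq_prefix optional path prefix for `<prefix>_R1.fastq` /
#'   `<prefix>_R2.fastq`.
#' @return list with `dataset` (a `ScreenDataset`), `clone_table` (a
#'   `CloneTable` with simulated UMIs), `truth` (data frame), and `fastq`
#'   (paths or `NULL`).
#' @export
simulate_screen <- function(config, fastq_prefix = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  lib <- config$library
  ids <- lib$guides$guide_id
  TT <- length(ids)
  with_seed(config$seed, {
    I <- if (!is.null(config$initial_counts)) {
      as.integer(config$initial_counts)
    } else {
      pmax(1L, as.integer(round(stats::rlnorm(
        TT, log(config$mean_initial) - config$library_sigma^2 / 2,
        config$library_sigma))))
    }
    names(I) <- ids
    pi_t <- I / sum(I)
    base <- config$clones_per_guide * TT
    K <- stats::rpois(TT, base * pi_t * config$eps_star[ids])
    sizes <- vector("list", TT)
    names(sizes) <- ids
    true_w <- numeric(TT)
    for (t in seq_len(TT)) {
      pars <- scale_size_params(config$likelihood, config$size_params,
                                config$phi_star[ids[t]])
      sizes[[t]] <- if (K[t] > 0) r_count(config$likelihood, pars, K[t])
                    else integer(0)
      true_w[t] <- winsorized_mean_of_pmf(config$likelihood, pars,
                                          config$winsor_upper_fraction)
    }
    truth <- data.frame(guide_id = ids,
                        eps_star = unname(config$eps_star[ids]),
                        phi_star = unname(config$phi_star[ids]),
                        n_clones = K,
                        true_fitness = unname(config$eps_star[ids]) * true_w,
                        stringsAsFactors = FALSE)
    umis <- character(0)
    clone_guides <- rep(ids, K)
    n_clones <- sum(K)
    if (n_clones > 0) {
      # distinct UMIs per guide so the truth clone table has no collisions
      umis <- unlist(lapply(seq_len(TT), function(t) {
        if (K[t] > 0) realize_umis(lib$umi_template, K[t]) else character(0)
      }), use.names = FALSE)
    }
    clone_sizes_flat <- unlist(sizes, use.names = FALSE)
    tab <- clone_table(data.frame(guide_id = clone_guides, umi = umis,
                                  reads = clone_sizes_flat,
                                  stringsAsFactors = FALSE),
                       sample_id = paste0("sim", config$seed))
    fastq <- NULL
    if (!is.null(fastq_prefix)) {
      fastq <- write_sim_fastq(tab, lib, config$umi_error_rate, fastq_prefix)
    }
    dataset <- screen_dataset(tab, I, lib,
                              sample_id = paste0("sim", config$seed))
    list(dataset = dataset, clone_table = tab, truth = truth, fastq = fastq)
  })
}

# Emit paired FASTQ for a simulated clone table (caller provides RNG state).
write_sim_fastq <- function(tab, lib, umi_error_rate, prefix) {
  seq_of <- lib$guides$sequence[match(tab$guide_id, lib$guides$guide_id)]
  reads_per_clone <- tab$reads
  n_reads <- sum(reads_per_clone)
  idx <- rep.int(seq_len(nrow(tab)), reads_per_clone)
  spacer <- random_dna(1, 23)  # constant spacer; only the window rule matters
  fwd <- paste0("ACGTAC", FORWARD_ANCHOR, spacer, seq_of[idx], "TTCAAG")
  umi_rc <- reverse_complement(tab$umi)
  rev_core <- umi_rc[idx]
  if (umi_error_rate > 0) {
    rev_core <- apply_substitutions(rev_core, umi_error_rate)
  }
  rev_pad <- random_dna(1, 10)
  rev_tail <- random_dna(1, 50 - 10 - 27)
  rev <- paste0("TGCATG", REVERSE_ANCHOR, rev_pad, rev_core, rev_tail)
  qual <- function(s) strrep("F", nchar(s))  # phred 37
  ids <- sprintf("@read_%d clone=%d", seq_len(n_reads), idx)
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  writeLines(paste(ids, fwd, "+", qual(fwd), sep = "\n"), p1)
  writeLines(paste(ids, rev, "+", qual(rev), sep = "\n"), p2)
  c(p1, p2)
}

# Random per-base substitutions at the given rate.
apply_substitutions <- function(seqs, rate) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  hits <- which(matrix(stats::runif(n * L) < rate, n, L), arr.ind = TRUE)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      cur <- m[hits[i, 1], hits[i, 2]]
      m[hits[i, 1], hits[i, 2]] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  apply(m, 1, paste, collapse = "")
}

#' Winsorize a sample at an upper quantile
#'
#' Values above the empirical `1 - upper_fraction` quantile (linear
#' interpolation) are revalued to that quantile point; length and order are
#' preserved.
#'
#' @param values numeric vector (nonempty).
#' @param upper_fraction upper-tail fraction (default 0.02); `0` is the
#'   identity.
#' @return the winsorized vector.
#' @export
winsorize_sample <- function(values, upper_fraction = 0.02) {
  stopifnot(length(values) >= 1, upper_fraction >= 0, upper_fraction < 1)
  if (upper_fraction == 0) return(values)
  q <- pctile(values, 1 - upper_fraction)
  pmin(values, q)
}

#' Sampling uncertainty of the mean clone size
#'
#' Repeatedly draws `n` clones without replacement from a clone-size
#' population and records the central 90\% interval of the (optionally
#' winsorized) sample mean across repetitions, for each `n` in a grid.
#' Under a heavy-tailed population the interval widens sharply as `n`
#' falls, and winsorization tempers (but does not remove) the effect.
#'
#' @param clone_sizes numeric population of clone sizes.
#' @param n_grid integer vector of sample sizes (each `<=` population size).
#' @param reps repetitions per grid point (default 200).
#' @param winsorize use the winsorized mean instead of the arithmetic mean.
#' @param upper_fraction winsorization fraction (default 0.02).
#' @param seed integer seed.
#' @return data frame: `n`, `lo`, `hi`, `width` (central 90\% interval of
#'   the mean estimate).
#' @export
sampling_uncertainty_curve <- function(clone_sizes, n_grid, reps = 200,
                                       winsorize = FALSE,
                                       upper_fraction = 0.02, seed = 1L) {
  stopifnot(all(n_grid >= 1), all(n_grid <= length(clone_sizes)))
  with_seed(seed, {
    rows <- lapply(n_grid, function(n) {
      means <- vapply(seq_len(reps), function(r) {
        s <- sample(clone_sizes, n)
        if (winsorize) mean(winsorize_sample(s, upper_fraction)) else mean(s)
      }, 0)
      qsm <- pctile(means, c(0.05, 0.95))
      data.frame(n = n, lo = qsm[1], hi = qsm[2], width = qsm[2] - qsm[1])
    })
    do.call(rbind, rows)
  })
}
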