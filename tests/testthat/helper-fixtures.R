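# Shared helpers: small libraries, simulated screens and cached fits reused
# across test files (fits are expensive; build each once).

tiny_library <- function(n_targeting, n_controls = 0, guides_per_gene = 3,
                         seed = 301L, name = "testlib") {
  n <- n_targeting + n_controls
  genes <- sprintf("gene%02d", seq_len(ceiling(n_targeting / guides_per_gene)))
  gene <- rep(genes, each = guides_per_gene)[seq_len(n_targeting)]
  library_design(
    name,
    data.frame(
      guide_id = c(sprintf("g%03d", seq_len(n_targeting)),
                   if (n_controls) sprintf("ntc%02d", seq_len(n_controls))),
      sequence = synthetic_guides(n, seed = seed),
      gene = c(gene, rep(NA_character_, n_controls)),
      guide_class = c(rep("targeting", n_targeting),
                      rep("non_targeting", n_controls)),
      stringsAsFactors = FALSE))
}

# Mixture parameters used for most well-specified simulations.
mix_params <- list(mean1 = 5, size1 = 1, mean2 = 50, size2 = 1, w = 0.3)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# A neutral (all guides identical) simulated screen plus a mix-NB fit: the
# workhorse for exchangeability, GOF and normalization tests.
neutral_sim <- function() {
  cached("neutral_sim", {
    lib <- tiny_library(48, n_controls = 12, seed = 311L)
    simulate_screen(simulation_config(lib, seed = 21L, clones_per_guide = 150,
                                      size_params = mix_params))
  })
}

neutral_fit <- function() {
  cached("neutral_fit", {
    suppressWarnings(fit_fitness_model(
      neutral_sim()$dataset,
      model_spec(chains = 2, warmup = 400, draws = 400, seed = 31L)))
  })
}

# A screen with genuine fitness spread plus its fit: used for recovery,
# frequentist agreement and poset tests.
spread_sim <- function() {
  cached("spread_sim", {
    lib <- tiny_library(45, n_controls = 10, seed = 313L)
    ids <- lib$guides$guide_id
    fac <- clonefit:::with_seed(99L, exp(stats::rnorm(length(ids), 0, 0.35)))
    names(fac) <- ids
    simulate_screen(simulation_config(lib, seed = 22L, clones_per_guide = 300,
                                      eps_star = fac, phi_star = fac,
                                      size_params = mix_params))
  })
}

spread_fit <- function() {
  cached("spread_fit", {
    suppressWarnings(fit_fitness_model(
      spread_sim()$dataset,
      model_spec(chains = 2, warmup = 400, draws = 400, seed = 32L)))
  })
}

# Larger well-specified screen for the GOF coverage check (200 guides keep
# the binomial noise of the coverage percentage near 2 points).
gof_sim <- function() {
  cached("gof_sim", {
    lib <- tiny_library(200, guides_per_gene = 4, seed = 317L)
    simulate_screen(simulation_config(lib, seed = 23L, clones_per_guide = 300,
                                      size_params = mix_params))
  })
}

gof_fit <- function() {
  cached("gof_fit", {
    suppressWarnings(fit_fitness_model(
      gof_sim()$dataset,
      model_spec(chains = 2, warmup = 400, draws = 400, seed = 33L)))
  })
}

# One all-neutral screen -> fit -> normalize -> neutrality calls -> false
# discovery proportion (every call on a neutral screen is false).
neutral_screen_fdp <- function(seed, n_guides = 40, n_controls = 8,
                               clones_per_guide = 60) {
  lib <- cached("fdp_lib", tiny_library(40, n_controls = 8, seed = 319L))
  sim <- simulate_screen(simulation_config(lib, seed = seed,
                                           clones_per_guide = clones_per_guide,
                                           size_params = mix_params))
  post <- suppressWarnings(fit_fitness_model(
    sim$dataset,
    model_spec(chains = 2, warmup = 250, draws = 250, seed = seed + 1L)))
  calls <- call_nonneutral(normalize_fitness(post), alpha = 0.05)
  n_called <- sum(calls$significant, na.rm = TRUE)
  if (n_called == 0) 0 else 1  # all discoveries are false under neutrality
}

# Minimal hand-built posterior for post-inference tests that need exact
# control over draws (no MCMC involved).
fake_posterior <- function(f_draws, library, rank_draws = NULL,
                           normalized = FALSE) {
  stopifnot(nrow(f_draws) == nrow(library$guides))
  if (is.null(rank_draws)) {
    rank_draws <- apply(f_draws, 2, rank, ties.method = "average")
  }
  qs <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summ <- data.frame(
    guide_id = library$guides$guide_id,
    median = apply(f_draws, 1, stats::median),
    lo95 = apply(f_draws, 1, qs, 0.025), hi95 = apply(f_draws, 1, qs, 0.975),
    lo90 = apply(f_draws, 1, qs, 0.05), hi90 = apply(f_draws, 1, qs, 0.95),
    rank_median = apply(rank_draws, 1, stats::median),
    rank_lo95 = apply(rank_draws, 1, qs, 0.025),
    rank_hi95 = apply(rank_draws, 1, qs, 0.975),
    rhat = 1, n_clones = 100L, stringsAsFactors = FALSE)
  structure(list(summary = summ, f_draws = f_draws, rank_draws = rank_draws,
                 m_draws = list(), hyper_draws = NULL, fam_draws = NULL,
                 chain = rep(1L, ncol(f_draws)),
                 guide_id = library$guides$guide_id, library = library,
                 spec = model_spec(chains = 1, warmup = 1, draws = ncol(f_draws)),
                 K = matrix(100L, nrow(f_draws), 1),
                 obs_mean = matrix(NA_real_, nrow(f_draws), 1),
                 sample_ids = "fake", excluded = character(0),
                 normalized = normalized, norm_scalar = NA_real_,
                 converged = TRUE),
            class = c(if (normalized) "NormalizedFitness", "FitnessPosterior"))
}

phred_string <- function(scores) {
  intToUtf8(as.integer(scores) + 33L, multiple = FALSE)
}
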