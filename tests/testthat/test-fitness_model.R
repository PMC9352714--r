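# Hierarchical Bayesian fitness model: exchangeability, recovery, grouped
# inference, goodness of fit, marginal likelihood.

test_that("exchangeable guides receive statistically indistinguishable fitness", {
  post <- neutral_fit()
  s <- post$summary
  # every median lies inside every other guide's 95% interval
  expect_lte(max(s$median), min(s$hi95))
  expect_gte(min(s$median), max(s$lo95))
  # and near the true winsorized-mean fitness of the shared distribution
  truth <- neutral_sim()$truth$true_fitness[1]
  expect_lt(max(abs(s$median / truth - 1)), 0.15)
})

test_that("rank draws are permutations and the summary is internally consistent", {
  post <- neutral_fit()
  for (sdx in c(1L, ncol(post$rank_draws))) {
    expect_equal(sort(post$rank_draws[, sdx]), seq_len(nrow(post$summary)))
  }
  expect_true(all(post$summary$lo95 <= post$summary$median))
  expect_true(all(post$summary$median <= post$summary$hi95))
  expect_true(all(post$summary$lo95 <= post$summary$lo90))
  expect_true(all(post$summary$hi90 <= post$summary$hi95))
  expect_true(all(is.finite(post$f_draws)) && all(post$f_draws >= 0))
})

test_that("fits are reproducible under the model seed", {
  lib <- tiny_library(10, seed = 601L)
  sim <- simulate_screen(simulation_config(lib, seed = 71L,
                                           clones_per_guide = 60,
                                           size_params = mix_params))
  spec <- model_spec(chains = 2, warmup = 120, draws = 120, seed = 41L)
  a <- suppressWarnings(fit_fitness_model(sim$dataset, spec))
  b <- suppressWarnings(fit_fitness_model(sim$dataset, spec))
  expect_identical(a$f_draws, b$f_draws)
  expect_identical(a$summary, b$summary)
})

test_that("a guide with doubled clone rate and size shows ~4x fitness", {
  lib <- tiny_library(24, seed = 602L)
  ids <- lib$guides$guide_id
  eps <- setNames(rep(1, 24), ids); eps[1] <- 2
  phi <- setNames(rep(1, 24), ids); phi[1] <- 2
  sim <- simulate_screen(simulation_config(lib, seed = 72L,
                                           clones_per_guide = 400,
                                           eps_star = eps, phi_star = phi,
                                           size_params = mix_params))
  post <- suppressWarnings(fit_fitness_model(
    sim$dataset, model_spec(chains = 2, warmup = 400, draws = 400, seed = 42L)))
  others <- post$summary$median[-1]
  ratio <- post$summary$median[1] / stats::median(others)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  # the enhanced guide's true fitness is covered by its 95% interval
  expect_gte(sim$truth$true_fitness[1], post$summary$lo95[1])
  expect_lte(sim$truth$true_fitness[1], post$summary$hi95[1])
})

test_that("a guide with initial representation but no clones ranks lowest", {
  lib <- tiny_library(12, seed = 603L)
  sim <- simulate_screen(simulation_config(lib, seed = 73L,
                                           clones_per_guide = 150,
                                           size_params = mix_params))
  sizes <- sim$dataset$clone_sizes
  sizes[[1]] <- integer(0)  # engraftment failure for guide 1
  ds <- screen_dataset(sizes, sim$dataset$initial_counts, lib)
  post <- suppressWarnings(fit_fitness_model(
    ds, model_spec(chains = 2, warmup = 250, draws = 250, seed = 43L)))
  rich <- post$summary$n_clones >= 100
  expect_lt(post$summary$median[1], min(post$summary$median[rich]))
})

test_that("guides with zero initial counts are excluded with a message", {
  lib <- tiny_library(8, seed = 604L)
  sim <- simulate_screen(simulation_config(lib, seed = 74L,
                                           clones_per_guide = 50,
                                           size_params = mix_params))
  ic <- sim$dataset$initial_counts
  ic[2] <- 0L
  sizes <- sim$dataset$clone_sizes
  sizes[[2]] <- integer(0)
  ds <- screen_dataset(sizes, ic, lib)
  expect_message(
    post <- suppressWarnings(fit_fitness_model(
      ds, model_spec(chains = 1, warmup = 100, draws = 100, seed = 44L))),
    "zero initial counts")
  expect_equal(post$excluded, lib$guides$guide_id[2])
  expect_equal(nrow(post$summary), 7L)
})

test_that("grouped replicate fits narrow the fitness intervals", {
  lib <- tiny_library(20, seed = 605L)
  first <- simulate_screen(simulation_config(lib, seed = 81L,
                                             clones_per_guide = 80,
                                             size_params = mix_params))$dataset
  later <- lapply(82:83, function(s)
    simulate_screen(simulation_config(
      lib, seed = s, clones_per_guide = 80, size_params = mix_params,
      initial_counts = first$initial_counts))$dataset)
  reps <- c(list(first), later)
  spec <- model_spec(chains = 2, warmup = 300, draws = 300, seed = 45L)
  singles <- lapply(reps, function(d)
    suppressWarnings(fit_fitness_model(d, spec)))
  grouped <- suppressWarnings(fit_fitness_model(reps, spec))
  width <- function(p) stats::median(p$summary$hi95 - p$summary$lo95)
  for (p in singles) expect_lte(width(grouped), width(p))
})

test_that("credible intervals widen as clonal diversity falls", {
  lib <- tiny_library(30, seed = 606L)
  spec <- model_spec(chains = 2, warmup = 300, draws = 300, seed = 46L)
  widths <- vapply(c(1000, 100, 30), function(cpg) {
    sim <- simulate_screen(simulation_config(lib, seed = 90L + cpg %% 97,
                                             clones_per_guide = cpg,
                                             size_params = mix_params))
    post <- suppressWarnings(fit_fitness_model(sim$dataset, spec))
    s <- post$summary
    stats::median((s$hi95 - s$lo95) / s$median)
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("posterior 95% intervals cover true fitness at the nominal rate", {
  lib <- tiny_library(200, guides_per_gene = 4, seed = 607L)
  ids <- lib$guides$guide_id
  set.seed(95)
  eps <- setNames(exp(rnorm(200, 0, 0.3)), ids)
  phi <- setNames(exp(rnorm(200, 0, 0.25)), ids)
  sim <- simulate_screen(simulation_config(lib, seed = 96L,
                                           clones_per_guide = 150,
                                           eps_star = eps, phi_star = phi,
                                           size_params = mix_params))
  post <- suppressWarnings(fit_fitness_model(
    sim$dataset, model_spec(chains = 2, warmup = 400, draws = 400, seed = 47L)))
  truth <- sim$truth$true_fitness[match(post$guide_id, sim$truth$guide_id)]
  covered <- truth >= post$summary$lo95 & truth <= post$summary$hi95
  expect_gte(mean(covered) * 100, 90)
  expect_lte(mean(covered) * 100, 100)
  # rank-order recovery of the generative fitness
  expect_gte(stats::cor(truth, post$summary$median, method = "spearman"), 0.9)
})

test_that("well-specified fits reach nominal GOF coverage; rigid ones do not", {
  post <- neutral_fit()
  cov_mix <- gof_coverage(neutral_sim()$dataset, post)
  expect_gte(cov_mix, 80); expect_lte(cov_mix, 100)
  post_pois <- suppressWarnings(fit_fitness_model(
    neutral_sim()$dataset,
    model_spec(likelihood = "poisson", chains = 2, warmup = 250, draws = 250,
               seed = 48L)))
  expect_lt(gof_coverage(neutral_sim()$dataset, post_pois), cov_mix)
})

test_that("alternative likelihood families fit end to end", {
  lib <- tiny_library(8, seed = 608L)
  sim <- simulate_screen(simulation_config(lib, seed = 75L,
                                           clones_per_guide = 40,
                                           size_params = mix_params))
  for (fam in c("nb", "ys", "mix_bnb_local")) {
    post <- suppressWarnings(fit_fitness_model(
      sim$dataset,
      model_spec(likelihood = fam, chains = 1, warmup = 80, draws = 80,
                 seed = 49L)))
    expect_true(all(is.finite(post$summary$median)), info = fam)
    expect_true(all(post$summary$median > 0), info = fam)
  }
})

test_that("stepping-stone estimator matches a conjugate normal marginal", {
  # y_i ~ N(theta, s^2), theta ~ N(0, t^2): the tempered posterior is normal
  # and the marginal likelihood is available in closed form, so the ladder
  # estimator can be checked with exact (iid) rung samples.
  set.seed(50)
  y <- rnorm(12, 1.5, 1); s <- 1; t <- 2; n <- length(y)
  # exact marginal: y ~ N(0, s^2 I + t^2 J) (correlated through theta)
  Sigma <- diag(s^2, n) + t^2
  exact <- -0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus[1] +
                     drop(y %*% solve(Sigma, y)))
  sample_ll <- function(beta) {
    prec <- 1 / t^2 + beta * n / s^2
    mean_p <- (beta * sum(y) / s^2) / prec
    theta <- rnorm(800, mean_p, sqrt(1 / prec))
    vapply(theta, function(th) sum(dnorm(y, th, s, log = TRUE)), 0)
  }
  est <- clonefit:::stepping_stone(sample_ll, (seq(0, 20) / 20)^(1 / 0.3))
  expect_lt(abs(unclass(est) - exact), 3 * attr(est, "se") + 0.05)
})

test_that("marginal likelihood is seeded and prefers the generative family", {
  lib <- tiny_library(10, seed = 609L)
  sim <- simulate_screen(simulation_config(lib, seed = 76L,
                                           clones_per_guide = 40,
                                           size_params = mix_params))
  spec_mix <- model_spec(chains = 1, warmup = 120, draws = 150, seed = 51L)
  spec_poi <- model_spec(likelihood = "poisson", chains = 1, warmup = 120,
                         draws = 150, seed = 51L)
  ml_mix <- log_marginal_likelihood(sim$dataset, spec_mix, rungs = 10)
  ml_poi <- log_marginal_likelihood(sim$dataset, spec_poi, rungs = 10)
  expect_gt(unclass(ml_mix), unclass(ml_poi))
  ml_mix2 <- log_marginal_likelihood(sim$dataset, spec_mix, rungs = 10)
  expect_identical(unclass(ml_mix), unclass(ml_mix2))
})
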