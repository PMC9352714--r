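# Post-inference analysis: normalization, neutrality calls, comparisons,
# Hasse posets, subsampling.

test_that("normalization pins the 70th centile of targeting medians at 1", {
  cls <- c(rep("targeting", 168), rep("non_targeting", 24))
  set.seed(21)
  meds <- exp(rnorm(192, 0, 0.6))
  norm <- normalize_fitness(meds, guide_class = cls)
  expect_equal(unname(quantile(norm[cls == "targeting"], 0.70, type = 7)), 1)
  # controls are rescaled by the same scalar but excluded from it
  expect_equal(norm[cls != "targeting"],
               meds[cls != "targeting"] / attr(norm, "norm_scalar"))
  # all-equal medians all become exactly 1
  expect_equal(as.vector(normalize_fitness(rep(3.7, 10),
                                           rep("targeting", 10))), rep(1, 10))
  expect_error(normalize_fitness(meds[1:2], cls[1:2]), "three targeting")
})

test_that("posterior normalization is idempotent and consistent", {
  post <- neutral_fit()
  n1 <- normalize_fitness(post)
  n2 <- normalize_fitness(n1)
  expect_s3_class(n1, "NormalizedFitness")
  expect_equal(n1$summary$median, n2$summary$median, tolerance = 1e-12)
  cls <- n1$library$guides$guide_class[match(n1$guide_id,
                                             n1$library$guides$guide_id)]
  expect_equal(unname(quantile(n1$summary$median[cls == "targeting"], 0.70,
                               type = 7)), 1)
  # draws were rescaled along with the summaries
  expect_equal(apply(n1$f_draws, 1, median), n1$summary$median)
})

test_that("neutrality calls reproduce a hand-computed Benjamini-Hochberg case", {
  lib <- tiny_library(3, seed = 801L)
  nd <- 1000
  draws <- rbind(rep(2, nd),                        # all above 1 -> floored p
                 c(rep(0.5, nd - 6), rep(1.5, 6)),  # 6/1000 above -> p = 0.012
                 c(rep(0.5, 550), rep(1.5, 450)))   # p = 0.9
  post <- fake_posterior(draws, lib, normalized = TRUE)
  calls <- call_nonneutral(post, alpha = 0.05)
  expect_equal(calls$p, c(0.001, 0.012, 0.9))
  expect_equal(calls$p_adj, c(0.003, 0.018, 0.9))
  expect_equal(calls$significant, c(TRUE, TRUE, FALSE))
  expect_equal(calls$direction, c("high", "low", "low"))
  # discoveries are monotone in alpha
  strict <- call_nonneutral(post, alpha = 0.005)
  expect_true(all(calls$significant[strict$significant]))
  # unnormalized posteriors are rejected
  expect_error(call_nonneutral(fake_posterior(draws, lib)), "normalize")
})

test_that("comparing a posterior with itself finds nothing", {
  lib <- tiny_library(12, n_controls = 6, seed = 802L)
  set.seed(22)
  draws <- matrix(exp(rnorm(18 * 400, 0, 0.2)), 18)
  post <- fake_posterior(draws, lib, normalized = TRUE)
  cmp <- compare_datasets(post, post)
  expect_false(any(cmp$guides$c1))
  expect_false(any(cmp$guides$c3))
  expect_false(any(cmp$genes$outlier))
  expect_equal(cmp$spearman_rho, 1)
})

test_that("a shifted gene is flagged by the two-guide outlier rule", {
  lib <- tiny_library(12, n_controls = 8, seed = 803L)
  TT <- 20; nd <- 500
  set.seed(23)
  # distinct per-guide centers keep within-dataset ranks stable across draws
  centers <- seq(1.2, 2.2, length.out = TT)
  centers[1] <- 1.72; centers[2] <- 1.77  # mid-pack before the shift
  base <- matrix(rep(centers, nd), TT) + matrix(rnorm(TT * nd, 0, 0.01), TT)
  shifted <- base
  # gene01 = guides 1:3; push two guides down hard, leave the third alone
  shifted[1, ] <- base[1, ] - 0.5
  shifted[2, ] <- base[2, ] - 0.5
  postA <- fake_posterior(base, lib, normalized = TRUE)
  postB <- fake_posterior(shifted, lib, normalized = TRUE)
  cmp <- compare_datasets(postA, postB)
  expect_true(all(cmp$guides$outlier[1:2]))
  g <- cmp$genes
  expect_true(g$outlier[g$gene == "gene01"])
  expect_false(any(g$outlier[g$gene != "gene01"]))
  expect_lt(cmp$spearman_rho, 1)
  # with only one shifted guide the gene rule refuses the call
  one <- base; one[1, ] <- base[1, ] - 0.5
  cmp1 <- compare_datasets(postA, fake_posterior(one, lib, normalized = TRUE))
  expect_false(cmp1$genes$outlier[cmp1$genes$gene == "gene01"])
})

test_that("comparisons degrade gracefully without enough control guides", {
  lib <- tiny_library(9, n_controls = 2, seed = 804L)
  set.seed(24)
  draws <- matrix(exp(rnorm(11 * 200, 0, 0.1)), 11)
  post <- fake_posterior(draws, lib, normalized = TRUE)
  expect_warning(cmp <- compare_datasets(post, post), "fewer than 5 control")
  expect_true(cmp$degraded)
  expect_true(all(is.na(cmp$guides$c2)))
})

test_that("hasse_poset resolves strictly separated intervals", {
  summ <- data.frame(guide_id = c("a", "b", "c"),
                     lo95 = c(0, 2, 4), hi95 = c(1, 3, 5),
                     stringsAsFactors = FALSE)
  p <- hasse_poset(summ)
  expect_equal(p$resolved_pairs, 3L)
  expect_equal(p$edges, data.frame(from = c("a", "b"), to = c("b", "c"),
                                   stringsAsFactors = FALSE))
  # fully overlapping and duplicated intervals resolve nothing
  flat <- data.frame(guide_id = c("a", "b", "c"),
                     lo95 = c(0, 0.5, 0), hi95 = c(2, 2.5, 2))
  expect_equal(nrow(hasse_poset(flat)$edges), 0L)
  expect_equal(hasse_poset(flat)$resolved_pairs, 0L)
  dup <- data.frame(guide_id = c("a", "b"), lo95 = c(1, 1), hi95 = c(2, 2))
  expect_equal(nrow(hasse_poset(dup)$edges), 0L)
})

test_that("the Hasse reduction matches brute-force reachability and is acyclic", {
  brute_reduce <- function(lo, hi) {
    n <- length(lo)
    R <- outer(hi, lo, `<`); diag(R) <- FALSE
    reach <- R
    for (i in seq_len(n)) reach <- (reach | (reach %*% R) > 0)
    H <- R
    for (a in 1:n) for (b in 1:n) {
      if (H[a, b]) {
        for (c in 1:n) if (R[a, c] && reach[c, b]) H[a, b] <- FALSE
      }
    }
    H
  }
  set.seed(25)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    lo <- runif(n, 0, 10); hi <- lo + runif(n, 0.1, 4)
    summ <- data.frame(guide_id = sprintf("g%02d", 1:n), lo95 = lo, hi95 = hi)
    p <- hasse_poset(summ)
    H <- brute_reduce(lo, hi)
    idx <- which(H, arr.ind = TRUE)
    oracle <- data.frame(from = summ$guide_id[idx[, 1]],
                         to = summ$guide_id[idx[, 2]],
                         stringsAsFactors = FALSE)
    oracle <- oracle[order(oracle$from, oracle$to), ]
    rownames(oracle) <- NULL
    expect_equal(p$edges, oracle)
    # acyclicity via Kahn-style topological elimination
    nodes <- p$nodes; edges <- p$edges
    while (length(nodes)) {
      sinks <- setdiff(nodes, edges$from)
      expect_gt(length(sinks), 0)
      nodes <- setdiff(nodes, sinks)
      edges <- edges[!(edges$to %in% sinks), , drop = FALSE]
    }
  }
})

test_that("poset DOT output lists every node and edge", {
  summ <- data.frame(guide_id = c("a", "b"), lo95 = c(0, 2), hi95 = c(1, 3))
  dot <- poset_to_dot(hasse_poset(summ))
  expect_match(dot, "digraph")
  expect_match(dot, "\"a\" -> \"b\"")
})

test_that("clone subsampling is exact, seeded and leaves initial counts alone", {
  ds <- neutral_sim()$dataset
  total <- sum(lengths(ds$clone_sizes))
  sub <- subsample_clones(ds, fraction = 0.1, seed = 5)
  expect_equal(sum(lengths(sub$clone_sizes)), floor(0.1 * total))
  expect_identical(sub$initial_counts, ds$initial_counts)
  expect_identical(subsample_clones(ds, fraction = 1, seed = 5), ds)
  again <- subsample_clones(ds, fraction = 0.1, seed = 5)
  expect_identical(sub$clone_sizes, again$clone_sizes)
})

test_that("combining replicates concatenates clone lists per guide", {
  ds <- neutral_sim()$dataset
  comb <- combine_replicates(list(ds, ds))
  expect_equal(lengths(comb$clone_sizes), lengths(ds$clone_sizes) * 2L)
  expect_identical(combine_replicates(ds), ds)
  other <- ds
  other$library <- tiny_library(4, seed = 805L, name = "otherlib")
  expect_error(combine_replicates(list(ds, other)), "different libraries")
})

test_that("spearman_guides matches direct rank correlation", {
  lib <- tiny_library(4, seed = 806L)
  mk <- function(meds) fake_posterior(matrix(rep(meds, 10), 4), lib)
  expect_equal(spearman_guides(mk(c(1, 2, 3, 5)), mk(c(1, 2, 3, 5))), 1)
  expect_equal(spearman_guides(mk(c(1, 2, 3, 5)), mk(c(5, 3, 2, 1))), -1)
  # oracle: cor(rank(x), rank(y)) computed by hand -> 0.8
  expect_equal(spearman_guides(mk(c(1, 2, 3, 5)), mk(c(2, 1, 4, 5))),
               cor(rank(c(1, 2, 3, 5)), rank(c(2, 1, 4, 5))))
  expect_equal(spearman_guides(mk(c(1, 2, 3, 5)), mk(c(2, 1, 4, 5))), 0.8)
})
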