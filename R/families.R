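# Zero-truncated count-likelihood menu for clone sizes.
#
# Observed clones always have size >= 1, so every family with mass at zero
# (Poisson, negative binomial, beta negative binomial) is zero-truncated:
# pmf(k) / (1 - pmf(0)) on k >= 1.  The Yule-Simon family is already supported
# on k >= 1.  Mixture families mix two zero-truncated components of the same
# type with weight `w` on the first component.

COUNT_FAMILIES <- c("poisson", "nb", "bnb", "ys",
                    "mix_nb", "mix_bnb", "mix_bnb_local")

# ---- untruncated component primitives ---------------------------------------
# Each component family provides: lpmf(k), p0, cdf(k), partial(q) = sum_{k<=q}
# k*pmf(k), mean, var, and quant(p) = smallest k with cdf(k) >= p.

comp_poisson <- function(pars) {
  lambda <- pars$mean
  if (!is.finite(lambda) || lambda <= 0) stop("poisson mean must be > 0", call. = FALSE)
  list(lpmf = function(k) stats::dpois(k, lambda, log = TRUE),
       p0 = exp(-lambda),
       cdf = function(k) stats::ppois(k, lambda),
       partial = function(q) lambda * stats::ppois(q - 1, lambda),
       mean = lambda, var = lambda,
       quant = function(p) stats::qpois(p, lambda))
}

comp_nb <- function(pars) {
  mu <- pars$mean; r <- pars$size
  if (!is.finite(mu) || mu <= 0) stop("nb mean must be > 0", call. = FALSE)
  if (!is.finite(r) || r <= 0) stop("nb dispersion (size) must be > 0", call. = FALSE)
  list(lpmf = function(k) stats::dnbinom(k, size = r, mu = mu, log = TRUE),
       p0 = exp(r * (log(r) - log(r + mu))),
       cdf = function(k) stats::pnbinom(k, size = r, mu = mu),
       # k*f(k; r, p) = mu * f(k-1; r+1, p)  =>  closed-form partial mean
       partial = function(q) mu * stats::pnbinom(q - 1, size = r + 1,
                                                 mu = mu * (r + 1) / r),
       mean = mu, var = mu + mu^2 / r,
       quant = function(p) stats::qnbinom(p, size = r, mu = mu))
}

# Beta negative binomial: K ~ NB(r, p) with p ~ Beta(alpha, beta).  Mean
# parameterization: beta = mean * (alpha - 1) / r, requiring alpha > 1.
comp_bnb <- function(pars) {
  mu <- pars$mean; r <- pars$size; alpha <- pars$alpha
  if (!is.finite(mu) || mu <= 0) stop("bnb mean must be > 0", call. = FALSE)
  if (!is.finite(r) || r <= 0) stop("bnb dispersion (size) must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 1) {
    stop("bnb alpha must be > 1 under the mean parameterization", call. = FALSE)
  }
  beta <- mu * (alpha - 1) / r
  lpmf <- function(k) {
    out <- rep(-Inf, length(k))
    ok <- k >= 0 & k == floor(k)
    kk <- k[ok]
    out[ok] <- lgamma(r + kk) - lgamma(kk + 1) - lgamma(r) +
      lbeta(alpha + r, beta + kk) - lbeta(alpha, beta)
    out
  }
  cdf_vec <- local({
    cache_p <- exp(lpmf(0)); cache_k <- 0L
    function(k) {
      k <- floor(k)
      kmax <- max(k, 0L)
      if (kmax > cache_k) {
        extra <- exp(lpmf((cache_k + 1L):kmax))
        cache_p <<- c(cache_p, extra)
        cache_k <<- kmax
      }
      cs <- cumsum(cache_p)
      ifelse(k < 0, 0, pmin(cs[pmin(k, cache_k) + 1L], 1))
    }
  })
  vr <- if (alpha > 2) {
    r * beta * (r + alpha - 1) * (beta + alpha - 1) / ((alpha - 2) * (alpha - 1)^2)
  } else Inf
  list(lpmf = lpmf,
       p0 = exp(lbeta(alpha + r, beta) - lbeta(alpha, beta)),
       cdf = cdf_vec,
       partial = function(q) {
         if (q < 1) return(0)
         ks <- seq_len(q)
         sum(ks * exp(lpmf(ks)))
       },
       mean = mu, var = vr,
       quant = function(p) quant_by_search(cdf_vec, p))
}

# Yule-Simon on k >= 1: pmf(k) = rho * B(k, rho + 1); survival
# S(k) = k * B(k, rho + 1).
comp_ys <- function(pars) {
  rho <- pars$rho
  if (!is.finite(rho) || rho <= 0) stop("ys rho must be > 0", call. = FALSE)
  surv <- function(k) ifelse(k < 1, 1, exp(log(pmax(k, 1)) + lbeta(pmax(k, 1), rho + 1)))
  cdf <- function(k) 1 - surv(floor(k))
  list(lpmf = function(k) {
         out <- rep(-Inf, length(k))
         ok <- k >= 1 & k == floor(k)
         out[ok] <- log(rho) + lbeta(k[ok], rho + 1)
         out
       },
       p0 = 0,
       cdf = cdf,
       partial = function(q) {
         if (q < 1) return(0)
         ks <- seq_len(q)
         sum(ks * rho * exp(lbeta(ks, rho + 1)))
       },
       mean = if (rho > 1) rho / (rho - 1) else Inf,
       var = if (rho > 2) rho^2 / ((rho - 1)^2 * (rho - 2)) else Inf,
       quant = function(p) quant_by_search(cdf, p))
}

# Generic quantile: smallest k with cdf(k) >= p, by doubling then bisection.
quant_by_search <- function(cdf, p, cap = 1e8) {
  hi <- 1
  while (cdf(hi) < p) {
    hi <- hi * 2
    if (hi > cap) stop("quantile search exceeded cap; tail too heavy", call. = FALSE)
  }
  lo <- 0
  while (lo < hi - 1) {
    mid <- floor((lo + hi) / 2)
    if (cdf(mid) >= p) hi <- mid else lo <- mid
  }
  hi
}

component_builder <- function(fam) {
  switch(fam,
         poisson = comp_poisson, nb = comp_nb, bnb = comp_bnb, ys = comp_ys,
         stop("unknown component family: ", fam, call. = FALSE))
}

# Resolve a likelihood name + flat parameter list into component objects.
# Mixtures use suffixed parameters (mean1/size1/..., mean2/size2/...) and `w`.
resolve_family <- function(family, params) {
  if (!family %in% COUNT_FAMILIES) {
    stop("unknown likelihood family: ", family, call. = FALSE)
  }
  if (family %in% c("poisson", "nb", "bnb", "ys")) {
    comp <- component_builder(family)(params)
    list(mix = FALSE, comps = list(comp), w = 1)
  } else {
    base <- sub("mix_", "", sub("_local$", "", family))
    w <- params$w
    if (is.null(w) || !is.finite(w) || w < 0 || w > 1) {
      stop("mixture weight w must lie in [0, 1]", call. = FALSE)
    }
    pick <- function(i) {
      p <- list(mean = params[[paste0("mean", i)]],
                size = params[[paste0("size", i)]],
                alpha = params[[paste0("alpha", i)]],
                rho = params[[paste0("rho", i)]])
      p[!vapply(p, is.null, TRUE)]
    }
    list(mix = TRUE,
         comps = list(component_builder(base)(pick(1)),
                      component_builder(base)(pick(2))),
         w = w)
  }
}

# ---- zero-truncated interface -----------------------------------------------

zt_comp_cdf <- function(comp, k) {
  ifelse(k < 1, 0, (comp$cdf(k) - comp$p0) / (1 - comp$p0))
}

zt_comp_quant <- function(comp, p) {
  max(1, comp$quant(comp$p0 + p * (1 - comp$p0)))
}

#' Zero-truncated count probability mass function
#'
#' Probability of observing a clone of size `k` (support `k >= 1`) under one
#' of the clone-size likelihood families: `"poisson"`, `"nb"` (negative
#' binomial), `"bnb"` (beta negative binomial), `"ys"` (Yule-Simon), or the
#' two-component mixtures `"mix_nb"` / `"mix_bnb"`.  Families with mass at
#' zero are renormalized to `k >= 1`; mixtures mix two zero-truncated
#' components with weight `w` on the first.
#'
#' @param family family name.
#' @param params named list of parameters.  Singles: `mean` (+ `size` for
#'   `nb`; + `size`, `alpha` for `bnb`); `rho` for `ys`.  Mixtures: suffixed
#'   `mean1`, `size1`, ... plus weight `w`.
#' @param k integer vector of clone sizes.
#' @return vector of probabilities.
#' @examples
#' count_pmf("ys", list(rho = 1), 1)  # 1/2
#' @export
count_pmf <- function(family, params, k) {
  fam <- resolve_family(family, params)
  out <- 0
  ws <- c(fam$w, 1 - fam$w)[seq_along(fam$comps)]
  for (i in seq_along(fam$comps)) {
    comp <- fam$comps[[i]]
    p <- ifelse(k >= 1 & k == floor(k),
                exp(comp$lpmf(k)) / (1 - comp$p0), 0)
    out <- out + ws[i] * p
  }
  out
}

#' Zero-truncated count cumulative distribution function
#'
#' @inheritParams count_pmf
#' @return `P(K <= k)` on the zero-truncated scale.
#' @export
count_cdf <- function(family, params, k) {
  fam <- resolve_family(family, params)
  ws <- c(fam$w, 1 - fam$w)[seq_along(fam$comps)]
  out <- 0
  for (i in seq_along(fam$comps)) {
    out <- out + ws[i] * zt_comp_cdf(fam$comps[[i]], floor(k))
  }
  out
}

#' Zero-truncated count quantile
#'
#' Smallest integer `k >= 1` whose zero-truncated CDF reaches `p` (discrete
#' distributions have no exact centile point, so the smallest qualifying
#' integer is used).
#'
#' @inheritParams count_pmf
#' @param p probability in (0, 1).
#' @export
count_quantile <- function(family, params, p) {
  stopifnot(p > 0, p < 1)
  fam <- resolve_family(family, params)
  if (!fam$mix) return(zt_comp_quant(fam$comps[[1]], p))
  hi <- max(vapply(fam$comps, zt_comp_quant, 0, p = p))
  f <- function(k) count_cdf(family, params, k)
  if (f(1) >= p) return(1)
  lo <- 1
  while (lo < hi - 1) {
    mid <- floor((lo + hi) / 2)
    if (f(mid) >= p) hi <- mid else lo <- mid
  }
  hi
}

# Zero-truncated mean and variance (may be Inf for heavy-tailed families).
zt_mean_var <- function(family, params) {
  fam <- resolve_family(family, params)
  ws <- c(fam$w, 1 - fam$w)[seq_along(fam$comps)]
  m <- 0; e2 <- 0
  for (i in seq_along(fam$comps)) {
    comp <- fam$comps[[i]]
    mzt <- comp$mean / (1 - comp$p0)
    e2zt <- (comp$var + comp$mean^2) / (1 - comp$p0)
    m <- m + ws[i] * mzt
    e2 <- e2 + ws[i] * e2zt
  }
  c(mean = m, var = e2 - m^2)
}

#' Winsorized mean of a clone-size distribution
#'
#' With `q` the smallest integer whose zero-truncated CDF reaches
#' `1 - upper_fraction`, returns
#' \eqn{\sum_{k \le q} k\,\mathrm{pmf}(k) + q\,P(K > q)}: the mean after
#' revaluing the upper tail of the distribution to its upper centile point.
#' This is the robust location functional the fitness model reports (default
#' `upper_fraction = 0.02`, i.e. the top 2\% revalued to the 98th centile
#' point), and it is finite even for infinite-mean families such as
#' Yule-Simon with `rho <= 1`.
#'
#' @inheritParams count_pmf
#' @param upper_fraction upper-tail fraction to winsorize, in `[0, 0.5)`;
#'   `0` returns the plain zero-truncated mean (an error for infinite-mean
#'   families).
#' @return the winsorized mean (a number).
#' @export
winsorized_mean_of_pmf <- function(family, params, upper_fraction = 0.02) {
  stopifnot(upper_fraction >= 0, upper_fraction < 0.5)
  fam <- resolve_family(family, params)
  if (family == "ys" && upper_fraction > 0) {
    return(ys_winsorized_mean(params$rho, upper_fraction))
  }
  ws <- c(fam$w, 1 - fam$w)[seq_along(fam$comps)]
  if (upper_fraction == 0) {
    mv <- zt_mean_var(family, params)
    if (!is.finite(mv["mean"])) {
      stop("family has infinite mean; winsorization (upper_fraction > 0) required",
           call. = FALSE)
    }
    return(unname(mv["mean"]))
  }
  q <- count_quantile(family, params, 1 - upper_fraction)
  partial <- 0; cdfq <- 0
  for (i in seq_along(fam$comps)) {
    comp <- fam$comps[[i]]
    partial <- partial + ws[i] * comp$partial(q) / (1 - comp$p0)
    cdfq <- cdfq + ws[i] * zt_comp_cdf(comp, q)
  }
  partial + q * (1 - cdfq)
}

# Winsorized mean of the Yule-Simon distribution.  Uses the identity
# k pmf(k) = rho S(k) with S(k) = k B(k, rho + 1), so
# W = rho * sum_{k<=q} S(k) + q S(q).  For small rho the winsorization point
# q grows like (Gamma(rho+1)/frac)^(1/rho) and exact summation becomes
# infeasible; beyond 5e5 the power-law tail S(k) ~ Gamma(rho+1) k^-rho is
# integrated in closed form instead (relative error < 1e-3 in that regime).
ys_winsorized_mean <- function(rho, frac) {
  if (!is.finite(rho) || rho <= 0) stop("ys rho must be > 0", call. = FALSE)
  surv <- function(k) exp(log(k) + lbeta(k, rho + 1))
  q_asym <- exp((lgamma(rho + 1) - log(frac)) / rho)
  if (is.finite(q_asym) && q_asym <= 5e5) {
    q <- quant_by_search(function(k) 1 - surv(pmax(floor(k), 1)), 1 - frac)
    ks <- seq_len(q)
    rho * sum(surv(ks)) + q * surv(q)
  } else {
    K0 <- 1e4
    head_sum <- rho * sum(surv(seq_len(K0)))
    g <- exp(lgamma(rho + 1))
    tail_sum <- if (abs(rho - 1) > 1e-8) {
      rho * g * (q_asym^(1 - rho) - K0^(1 - rho)) / (1 - rho)
    } else {
      rho * g * log(q_asym / K0)
    }
    head_sum + tail_sum + q_asym * frac
  }
}

# Winsorized mean and variance of Yule-Simon at a (typically extreme)
# winsorization point, for the predictive check when raw moments are
# infinite.  Uses k^2 pmf(k) = rho * k * S(k) and the same power-law tail
# integration as ys_winsorized_mean.
ys_winsorized_meanvar <- function(rho, frac = 1e-4) {
  if (!is.finite(rho) || rho <= 0) stop("ys rho must be > 0", call. = FALSE)
  surv <- function(k) exp(log(k) + lbeta(k, rho + 1))
  q_asym <- exp((lgamma(rho + 1) - log(frac)) / rho)
  if (is.finite(q_asym) && q_asym <= 5e5) {
    q <- quant_by_search(function(k) 1 - surv(pmax(floor(k), 1)), 1 - frac)
    ks <- seq_len(q)
    S <- surv(ks)
    m <- rho * sum(S) + q * surv(q)
    e2 <- rho * sum(ks * S) + q^2 * surv(q)
  } else {
    K0 <- 1e4
    ks <- seq_len(K0)
    S <- surv(ks)
    g <- exp(lgamma(rho + 1))
    tail1 <- if (abs(rho - 1) > 1e-8) {
      rho * g * (q_asym^(1 - rho) - K0^(1 - rho)) / (1 - rho)
    } else rho * g * log(q_asym / K0)
    tail2 <- if (abs(rho - 2) > 1e-8) {
      rho * g * (q_asym^(2 - rho) - K0^(2 - rho)) / (2 - rho)
    } else rho * g * log(q_asym / K0)
    m <- rho * sum(S) + tail1 + q_asym * frac
    e2 <- rho * sum(ks * S) + tail2 + q_asym^2 * frac
  }
  c(mean = m, var = e2 - m^2)
}

#' Draw zero-truncated clone sizes
#'
#' Inverse-CDF sampling restricted to `k >= 1` (`qnbinom`/`qpois` on a uniform
#' draw above the zero mass for NB/Poisson components; beta-mixture sampling
#' for BNB; survival inversion for Yule-Simon).
#'
#' @inheritParams count_pmf
#' @param n number of draws.
#' @return integer vector of clone sizes, all `>= 1`.  Not seeded internally;
#'   callers wrap it in their own seeded context.
#' @export
r_count <- function(family, params, n) {
  fam <- resolve_family(family, params)
  if (fam$mix) {
    take1 <- stats::runif(n) < fam$w
    out <- integer(n)
    base <- sub("mix_", "", sub("_local$", "", family))
    sub_par <- function(i) {
      p <- list(mean = params[[paste0("mean", i)]],
                size = params[[paste0("size", i)]],
                alpha = params[[paste0("alpha", i)]],
                rho = params[[paste0("rho", i)]])
      p[!vapply(p, is.null, TRUE)]
    }
    if (any(take1)) out[take1] <- r_count(base, sub_par(1), sum(take1))
    if (any(!take1)) out[!take1] <- r_count(base, sub_par(2), sum(!take1))
    return(out)
  }
  comp <- fam$comps[[1]]
  if (family == "poisson") {
    u <- stats::runif(n, comp$p0, 1)
    stats::qpois(u, params$mean)
  } else if (family == "nb") {
    u <- stats::runif(n, comp$p0, 1)
    stats::qnbinom(u, size = params$size, mu = params$mean)
  } else if (family == "bnb") {
    r <- params$size; alpha <- params$alpha
    beta <- params$mean * (alpha - 1) / r
    p <- stats::rbeta(n, alpha, beta)
    p0 <- p^r
    u <- stats::runif(n, p0, 1)
    stats::qnbinom(u, size = r, prob = p)
  } else {  # ys
    u <- stats::runif(n)
    vapply(u, function(ui) quant_by_search(comp$cdf, ui), 0)
  }
}

# ---- vectorized helpers for the MCMC hot path (ZT NB mixture) ---------------

# log pmf of the zero-truncated NB (vectorized over k, mu, r of equal length
# or recyclable).
lpmf_ztnb <- function(k, mu, r) {
  lp0 <- r * (log(r) - log(r + mu))
  stats::dnbinom(k, size = r, mu = mu, log = TRUE) - log1p(-exp(lp0))
}

# Same quantity with the expensive lgamma terms precomputed: lgk1 =
# lgamma(k + 1) (fixed by the data) and lgr = lgamma(k + r) (changes only
# when the dispersion does).  This is the MCMC hot path.
lpmf_ztnb_cached <- function(k, lgk1, mu, r, lgr) {
  lrmu <- log(r + mu)
  lp0 <- r * (log(r) - lrmu)
  lgr - lgk1 - lgamma(r) + lp0 + k * (log(mu) - lrmu) - log1p(-exp(lp0))
}

lpmf_ztpois_cached <- function(k, lgk1, lam) {
  k * log(lam) - lam - lgk1 - log1p(-exp(-lam))
}

# log pmf of the two-component ZT NB mixture (w = weight of component 1).
lpmf_ztnbmix <- function(k, mu1, r1, mu2, r2, w) {
  a <- log(w) + lpmf_ztnb(k, mu1, r1)
  b <- log1p(-w) + lpmf_ztnb(k, mu2, r2)
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  # guard the degenerate w = 0 / 1 cases
  if (any(!is.finite(m))) out[!is.finite(m)] <- -Inf
  out
}

# CDF of the ZT NB mixture, vectorized over everything.
cdf_ztnbmix <- function(k, mu1, r1, mu2, r2, w) {
  p01 <- exp(r1 * (log(r1) - log(r1 + mu1)))
  p02 <- exp(r2 * (log(r2) - log(r2 + mu2)))
  f1 <- (stats::pnbinom(k, size = r1, mu = mu1) - p01) / (1 - p01)
  f2 <- (stats::pnbinom(k, size = r2, mu = mu2) - p02) / (1 - p02)
  w * pmax(f1, 0) + (1 - w) * pmax(f2, 0)
}

# Winsorized mean of the ZT NB mixture, vectorized over parameter tuples.
# Used per posterior draw in the fitness model, so it must be fast: component
# quantiles bound the mixture quantile, which is then found by vectorized
# integer bisection; partial means are closed-form.
wmean_ztnbmix <- function(mu1, r1, mu2, r2, w, upper_fraction = 0.02) {
  n <- max(length(mu1), length(mu2), length(r1), length(r2), length(w))
  mu1 <- rep_len(mu1, n); r1 <- rep_len(r1, n)
  mu2 <- rep_len(mu2, n); r2 <- rep_len(r2, n); w <- rep_len(w, n)
  if (upper_fraction == 0) {
    p01 <- exp(r1 * (log(r1) - log(r1 + mu1)))
    p02 <- exp(r2 * (log(r2) - log(r2 + mu2)))
    return(w * mu1 / (1 - p01) + (1 - w) * mu2 / (1 - p02))
  }
  p <- 1 - upper_fraction
  p01 <- exp(r1 * (log(r1) - log(r1 + mu1)))
  p02 <- exp(r2 * (log(r2) - log(r2 + mu2)))
  q1 <- stats::qnbinom(p01 + p * (1 - p01), size = r1, mu = mu1)
  q2 <- stats::qnbinom(p02 + p * (1 - p02), size = r2, mu = mu2)
  hi <- pmax(q1, q2, 1)
  lo <- rep(1, n)
  while (any(lo < hi)) {
    mid <- floor((lo + hi) / 2)
    reached <- cdf_ztnbmix(mid, mu1, r1, mu2, r2, w) >= p
    hi <- ifelse(reached & lo < hi, mid, hi)
    lo <- ifelse(!reached & lo < hi, mid + 1, lo)
  }
  q <- lo
  part1 <- mu1 * stats::pnbinom(q - 1, size = r1 + 1, mu = mu1 * (r1 + 1) / r1) / (1 - p01)
  part2 <- mu2 * stats::pnbinom(q - 1, size = r2 + 1, mu = mu2 * (r2 + 1) / r2) / (1 - p02)
  partial <- w * part1 + (1 - w) * part2
  partial + q * (1 - cdf_ztnbmix(q, mu1, r1, mu2, r2, w))
}

# Mean and variance of the ZT NB mixture, vectorized over parameter tuples.
meanvar_ztnbmix <- function(mu1, r1, mu2, r2, w) {
  p01 <- exp(r1 * (log(r1) - log(r1 + mu1)))
  p02 <- exp(r2 * (log(r2) - log(r2 + mu2)))
  m1 <- mu1 / (1 - p01); m2 <- mu2 / (1 - p02)
  e21 <- (mu1 + mu1^2 / r1 + mu1^2) / (1 - p01)
  e22 <- (mu2 + mu2^2 / r2 + mu2^2) / (1 - p02)
  m <- w * m1 + (1 - w) * m2
  list(mean = m, var = w * e21 + (1 - w) * e22 - m^2)
}
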