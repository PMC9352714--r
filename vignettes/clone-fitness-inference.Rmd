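---
title: "Clone-resolved fitness inference for pooled CRISPR screens"
author: "clonefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-resolved fitness inference for pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefit)
```

## The measurement problem

In a pooled CRISPR screen read out in a transplantable tumour model, each
transduced founder cell carries one sgRNA together with a degenerate DNA
barcode (UMI), so the progeny of every founder — a *clone* — can be counted
by amplicon sequencing. Two features of in-vivo regeneration make naive
count analysis unreliable:

* **Engraftment bottleneck.** Only a minority of transplanted cells found
  clones, so each guide is represented by a limited number of independent
  datapoints (often tens to hundreds).
* **Heavy-tailed clone sizes.** Clone sizes span three to four orders of
  magnitude; a handful of very large clones can dominate a guide's read
  count, so read-level abundance is a noisy proxy for the number and typical
  output of founder cells.

`clonefit` works at the clone level throughout: it extracts (guide, UMI)
clones from paired FASTQ, summarizes clonal diversity, and estimates guide
fitness with a hierarchical Bayesian model whose estimator is the
*winsorized mean* of cellular output — the mean after revaluing the top 2%
of the clone-size distribution to its 98th centile point — which tempers the
influence of outlying clones while retaining interpretability as expected
cellular output per transduced cell.

## Clone extraction

Paired reads pass a quality filter (both mates mean phred >= 30). The guide
is the 20-nt window 24–43 nt (1-based, inclusive) downstream of the
invariant vector anchor `TCTTGTGGAAAGGACGAAACACCG` on the forward read,
assigned to the unique library guide matching exactly, else the unique guide
within a configurable Hamming distance (default 1, up to 3); ties are
discarded as ambiguous. The UMI is the leftmost 27-nt window matching the
reverse-complement template `NNGTTNNACCNNTTTSSATCNNGATNN` within the 50-nt
substring after the reverse anchor `AGCCTCACTGGCCGTCGTTTTACA`, again with a
0-then-<=1-mismatch rule; the window convention (offsets counted from the
first base after the anchor) is chosen so the guide window is exactly 20 nt.
Assigned reads are downsampled to at most 2 × 10^6 so that differently
sequenced samples are comparable, then tallied into (guide, UMI) clones.

Sequencing and PCR errors scatter reads of a true clone across neighbouring
UMIs. Directional merging corrects this per guide: clones whose UMIs differ
at exactly one position are connected when the larger count `n_a` satisfies
`n_a > 2 n_b - 1`, and each connected component collapses to one clone
carrying the component's total reads and the UMI of its largest member
(ties broken by lexicographically smallest UMI, for determinism). Edges are
evaluated on pre-merge counts in a single pass; because merged counts can
create new qualifying pairs, the operation is only guaranteed idempotent
when no qualifying edges remain among merged clones. UMIs are stored
verbatim (including mismatched fixed positions) since merging absorbs
isolated errors.

## Diversity

Diversity statistics are evaluated **per million reads** by drawing an exact
multivariate-hypergeometric subsample of 10^6 reads: under heavy tails the
number of observed clones is a non-linear function of depth, so rescaling
clone counts linearly would bias comparisons between samples of different
depth. On the subsampled table the package reports the clone count, the
Shannon diversity index (natural log, so `n` even clones score `ln n`), and
the area under the Lorenz curve of cumulative read share against cumulative
clone share (ascending clone-size order; 0.5 = perfectly even). A single
seeded subsample is used; repetition over seeds is available to the caller.

## The fitness model

For guide $t$ in dataset $j$ with plasmid (initial) counts $I_t$ and library
proportions $\pi_t = I_t / \sum I$:

$$K_{jt} \sim \mathrm{Poisson}(c_j \pi_t \epsilon_t), \qquad
y_{jti} \mid \phi_t \sim \mathrm{ZT}\text{-}F(\phi_t; \theta_j),$$

where $K_{jt}$ is the observed clone number, $c_j$ a sample engraftment
scale, $\epsilon_t$ a guide engraftment factor, and clone sizes $y$ are iid
from a zero-truncated count family whose component means are scaled by the
guide size factor $\phi_t$. The family menu covers Poisson, negative
binomial (NB), beta negative binomial (BNB), Yule–Simon (YS), and
two-component mixtures `mix_nb` / `mix_bnb` (one mixture weight per sample)
and `mix_bnb_local` (one weight per guide). The default is `mix_nb`: it has
defined moments and the two components accommodate the empirically bimodal
"many small, few large" clone structure expected when more than one
biologically distinct cell type initiates clones.

Priors: $\log \phi_t \sim N(0, \tau_\phi)$ and
$\log \epsilon_t \sim N(0, \tau_\epsilon)$ with half-Normal(0, 1)
hyperpriors on the $\tau$'s (shrinkage toward neutrality, and the prior
centering of $\epsilon$ identifies it against $c_j$); $\log c_j \sim
N(0, 10)$; component log-means $\sim N(2, 3)$, log-dispersions $\sim
N(0, 2)$, mixture weights uniform on $(0,1)$, and the component means are
order-constrained ($\mu_1 < \mu_2$) to fix mixture labels.

Per posterior draw, a guide's fitness is
$f_t = \epsilon_t \, W_t$, with $W_t$ the winsorized mean of the guide's
fitted clone-size distribution — expected cellular output per transduced
cell as engraftment propensity times robust per-clone output. In grouped
(multi-replicate) fits, $\phi_t$, $\epsilon_t$ and the $\tau$'s are shared
while $c_j$ and the family parameters stay per-dataset, and $W_t$ averages
the per-dataset values weighted by dataset clone totals. Within-draw ranks
of $f_t$ are stored alongside, so rank differentials between datasets have
full posteriors.

### Sampling

The sampler is an adaptive Metropolis-within-Gibbs scheme on log/logit
scales, designed around two structural facts: guide-level parameters are
conditionally independent given the shared parameters (so all `z`-scores
are proposed and accepted elementwise in vectorized sweeps), and the
likelihood tabulates into unique (guide, size) pairs (so each sweep costs a
handful of vectorized pmf evaluations). Three less-obvious choices matter
for mixing:

* **Non-centered guide factors.** $\log \phi_t = \tau_\phi z_t$ with
  $z_t \sim N(0,1)$ (same for $\epsilon$) removes the funnel between the
  hyper-scales and the factors, which otherwise freezes $\tau$ when the
  data are nearly neutral.
* **Recentering moves.** The likelihood is invariant to shifting all
  $\log \epsilon_t$ against $\log c_j$, and all $\log \phi_t$ against the
  component log-means; dedicated proposals move along these ridges with
  only prior terms in the acceptance ratio.
* **Adaptive-covariance block proposals.** The shared family parameters are
  strongly correlated; after an initial warmup history a joint proposal
  from the empirical covariance (Haario-style, scaled $2.38^2/d$)
  supplements the coordinate scans.

Negative-binomial log-pmfs cache their `lgamma(k + r)` terms, which change
only when a dispersion is updated, so mean-scale updates avoid `lgamma`
entirely. Proposal scales adapt only during warmup (targets 0.44
elementwise/scalar, 0.25 for blocks). Convergence is monitored by
split-chain R-hat on the fitness draws; the fit is flagged (with a warning,
not an error) when more than 5% of guides exceed 1.05. Defaults are 4
chains × (1000 warmup + 1000 draws); the package's own tests and
acceptance script use 2 chains × (250–400 + 250–400) at their problem
sizes, which keeps R-hat under the flag threshold while fitting in seconds
to a couple of minutes.

### Numerical conventions

* Percentiles are linear-interpolation (type-7) quantiles everywhere.
* The winsorization point of a discrete distribution is the smallest
  integer whose zero-truncated CDF reaches 0.98 (discrete distributions
  have no exact centile point); partial means use the closed-form NB
  identity $k f(k; r, p) = \mu f(k-1; r+1, p)$, and mixture quantiles are
  found by integer bisection between component quantiles.
* Yule–Simon winsorized means use $k\,\mathrm{pmf}(k) = \rho S(k)$ with
  $S(k) = k B(k, \rho + 1)$; when $\rho$ is small enough that the
  winsorization point exceeds $5 \times 10^5$, the power-law tail is
  integrated in closed form instead of summed.
* BNB is mean-parameterized ($\beta = \mu(\alpha - 1)/r$, requiring
  $\alpha > 1$); for infinite-variance settings the predictive check falls
  back to moments winsorized at the $1 - 10^{-4}$ point.
* Guides with $I_t = 0$ are excluded with a message — fitness is undefined
  without initial representation. A guide with initial representation but
  zero observed clones stays in the model; its likelihood forces low
  engraftment and its fitness posterior concentrates below well-represented
  guides.

### Goodness of fit

`gof_coverage()` reports the percentage of guides whose observed arithmetic
mean clone size falls inside the 90% interval of the *modeled* mean: per
posterior draw, the predictive mean of $K_t$ clones drawn from the fitted
sample-level clone-size distribution (guide-specific only through $K_t$;
the CLT approximates the predictive noise of the mean). Close to 90%
indicates the fitted shape reproduces the dispersion of guide means; rigid
single-component likelihoods (Poisson most extremely) understate it and
score far lower. Two alternative definitions were considered and rejected:
the raw posterior of the guide-level model mean is over-shrunk under
correct specification (coverage far below nominal) yet saturates for
misspecified fits whose free guide factors chase each observed mean; and a
mixed predictive that redraws the guide factor from its fitted population
law lets an overdispersed $\tau_\phi$ disguise a misspecified within-guide
shape. The implemented statistic is the only one of the three that is both
calibrated when the model is right and sensitive when it is wrong — it
deliberately treats fitted between-guide heterogeneity as part of what is
being checked, so datasets with strong true fitness spread will score below
90% even under a well-specified family.

### Marginal likelihood

`log_marginal_likelihood()` implements a stepping-stone estimator over the
power-posterior ladder $\beta_k = (k/K)^{1/0.3}$, sampling each rung with
the model's own MCMC (warm-started from the previous rung) and reporting an
autocorrelation-adjusted Monte-Carlo standard error. The ladder exponent
concentrates rungs near $\beta = 0$ where the integrand varies fastest. The
estimator core is validated in the test suite against a conjugate normal
model with exact rung samplers.

## Post-inference analysis

**Normalization.** Fitness is relative; each dataset is rescaled so the
70th centile of gene-targeting-guide posterior medians equals 1 (controls
are rescaled but excluded from the scalar). The choice of a centile above
the median reflects the expectation that knockouts more often reduce than
increase fitness. The operation is idempotent.

**Neutrality calls.** Per guide, a posterior tail probability against 1
(`p = 2 min(Pr(f <= 1), Pr(f >= 1))`, floored at one over the draw count)
is adjusted by Benjamini–Hochberg across targeting guides; guides with
adjusted `p < 0.05` are labelled `low`/`high` by their median side.
Controls are reported unadjusted — the FDR statement concerns
gene-targeting calls.

**Pairwise screen comparison.** Draws are paired by index (chains are
independent; the pairing is arbitrary but seed-stable). A guide is an
outlier when (c1) the 95% interval of its normalized fitness differential
excludes 0, (c2) its median differential lies outside the central 95%
range of control-guide median differentials — a distribution-free reading
of "significant relative to neutral-guide variability" — and (c3) the 95%
interval of its within-dataset rank differential excludes 0; a gene is an
outlier when at least two of its guides pass all three. With fewer than 5
control guides c2 is undefined and the comparison is flagged as degraded.

**Partial-order resolution.** Guide `a` precedes `b` when their 95%
intervals do not overlap; the Hasse diagram is the transitive reduction of
this interval order (for interval orders a single matrix product suffices,
and the graph is acyclic by construction). The number of ordered pairs in
the full relation summarizes a screen's resolving power.

## The simulator

`simulate_screen()` generates data from exactly the structure the model
assumes, plus the read-level artifacts the extractor must undo: log-normal
plasmid skew with sigma 0.535, calibrated once so the 90th/10th centile
guide-count ratio is ~3.9 (the observed range for pooled cloning is 3–5);
a Poisson engraftment bottleneck through skew-weighted proportions;
clone sizes from a configurable family, default a two-component NB mixture
with means 5 and 50; and optional paired FASTQ with per-base UMI
substitution errors and constant phred 37. The default second-component
dispersion is 0.4 rather than 1: with geometric (dispersion-1) tails the
largest of ~10^5 clones is only ~600 reads, and the defaults are required
to reproduce the observed 3–4 orders of magnitude of clone-size span. The
truth table records each guide's generative factors and its true fitness
(engraftment factor × winsorized mean of its generative distribution), the
oracle for all recovery tests.

What the simulator does **not** emulate: PCR amplification noise on read
counts within a clone, guide-specific capture biases, chimeric reads,
spatial or immune interactions between clones, and multiple viral
integrations per cell (screens are modeled as single-infection). Passing
tests therefore certify the inference chain against its own generative
assumptions, not against every artifact of real amplicon data.

The clone-sampling experiment behind the package's motivation is available
as `sampling_uncertainty_curve()`: repeated without-replacement draws of
`n` clones from a heavy-tailed population show the 90% interval of the
sampled mean widening sharply below ~500–1000 clones, with winsorization
partially offsetting the effect.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen once as the smallest sizes at which the statistical claims are
stable: GOF calibration on 200 guides × ~300–500 clones/guide (coverage
standard error ~2 points); false-discovery control on 200 (script) or 40
(tests) all-neutral screens of 48 guides × ~50–60 clones/guide; recovery,
grouped-narrowing and resolution experiments on 20–200 guides. MCMC
geometry in these checks is 2 chains × (200–400 warmup + 250–400 draws).

## Limitations

* Fitness is identified only relatively; the 70th-centile normalization is
  a convention, and screens whose true fitness distribution violates it
  (e.g. most guides strongly depleted) shift the neutral point.
* The plug-in library proportions $\pi_t$ ignore plasmid-count sampling
  noise; very low $I_t$ guides therefore carry extra unmodeled uncertainty
  (and $I_t = 0$ guides are excluded outright).
* The CLT approximation in the GOF predictive is inaccurate for guides
  with very few clones combined with extremely heavy-tailed fits.
* Grouped fits assume replicates share guide-level effects exactly;
  between-replicate biological variation is absorbed by the per-dataset
  nuisances rather than modeled explicitly.
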