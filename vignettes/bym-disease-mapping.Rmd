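---
title: "Small-area disease mapping of method-specific mortality with bymsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping of method-specific mortality with bymsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Suicide rates vary across the neighborhoods of a city, and part of that
variation may track how easy each method is to carry out locally: living
alone makes charcoal burning at home easier, high-rise housing gives
access to heights, a river nearby gives access to water. Testing such
hypotheses requires method-specific rates for small areas — and
small-area counts are sparse. Neighborhoods of a few thousand residents
observe a handful of suicides by any one method even over several years,
so raw standardized mortality ratios (SMRs) are dominated by Poisson
noise. The standard remedy in spatial epidemiology is a Bayesian
hierarchical Poisson model with spatially structured and unstructured
random effects — the Besag–York–Mollié (BYM) model — which shrinks each
area's estimate toward the regional mean and toward its neighbors, and
yields rate ratios for area covariates with full posterior uncertainty.

`bymsmr` implements this analysis end to end: ICD-10 method
classification, indirect age standardization, contiguity and
river-accessibility indicators from planar geometry, the BYM model with
a purpose-built MCMC sampler, and the posterior summaries (smoothed
SMRs, rate ratios with 95% credible intervals, convergence
diagnostics). A synthetic-data generator reproduces the structure of a
432-neighborhood urban study region so every stage can be validated
against known ground truth.

## The model

For area $i$ and a given method, the observed count is

$$O_i \sim \mathrm{Poisson}(E_i \, \theta_i), \qquad
  \log \theta_i = \alpha + x_i^\top \beta + u_i + v_i,$$

where $E_i$ is the expected count under indirect age standardization
(included as an offset, so the model targets the relative risk
$\theta_i$ rather than the raw count), $x_i$ holds standardized area
covariates, $v_i \sim N(0, \sigma_v^2)$ is an exchangeable
(unstructured) effect, and $u$ follows the intrinsic conditional
autoregressive (ICAR) prior on the contiguity graph,

$$p(u \mid \sigma_u) \propto
  \sigma_u^{-\mathrm{rank}(Q)}
  \exp\!\Big(-\tfrac{1}{2\sigma_u^2}
  \sum_{i \sim j} (u_i - u_j)^2\Big),$$

with $Q = D - W$ the graph Laplacian and
$\mathrm{rank}(Q) = n - (\text{number of connected components})$. The
ICAR density is improper (invariant to a constant shift per component),
so $u$ is identified by a sum-to-zero constraint per component; isolated
areas have $u_i = 0$ and contribute only through $v_i$.

**Expected counts.** $E_{i} = \sum_a n_{ia} D_a / N_a$ where $n_{ia}$
are the area's person-periods in 5-year age band $a$ and $D_a / N_a$ is
the region-wide band-specific death rate for the method over the full
aggregation period. Using the study region itself as the standard
population forces $\sum_i E_i = \sum_i O_i$ per method, so smoothed SMRs
center near 1. Age bands run from 10–14 upward; the open-ended top band
is 85+, the conventional cutoff (the source registries do not pin this
down, so it is a package default).

**Method classification.** Certified suicides (X60–X84) are combined
with deaths of undetermined intent (Y10–Y34), suffocation injuries
(W75, W76, W83, W84) and pesticide-poisoning injuries (X48), which
mortality-registry validation studies treat as probable misclassified
suicides. The method groups are charcoal burning (X67, Y17), hanging
(X70, Y20, W75–W76, W83–W84), drowning (X71, Y21), jumping (X80, Y30),
and "other" for everything else in the combined ranges. Records under
age 10 are excluded.

**Priors.** The main analysis puts independent Uniform(0, 5) priors on
the standard deviations $\sigma_u, \sigma_v$; the sensitivity
alternative is Gamma(0.01, 0.01) on the precisions
$\tau = \sigma^{-2}$. The intercept and coefficients get flat improper
priors by default (`prior_spec(normal_sd =)` switches to a vague
normal). Both prior families are exposed throughout
(`--prior` in the command-line front-end).

**Covariate scale.** Continuous covariates are z-scored; columns whose
absolute sample skewness exceeds 1 are natural-log transformed first
(this threshold operationalizes the usual "log if skewed" rule; the
transform applied to each column is recorded and reported). Rate ratios
are therefore "per 1 SD increase" on the analysis scale. The binary
river indicator is z-scored by default so the same reading applies to
all three accessibility indicators; `binary = "raw"` keeps it 0/1.

## The sampler

WinBUGS-style general-purpose samplers handle this model with
single-site updates, and `bymsmr` does the same with an explicit,
testable implementation (in C++ via Rcpp): adaptive Gaussian
random-walk Metropolis updates for $\alpha$, each $\beta_j$, each $u_i$
and each $v_i$. Proposal scales adapt toward an acceptance rate of 0.44
(the classic single-site optimum) in batches during burn-in and are
frozen afterwards; the $u_i$ and $v_i$ proposals are additionally
scaled by the current $\sigma_u, \sigma_v$ so acceptance stays stable
when the scales move after adaptation ends.

The scale parameters are updated by Gibbs steps: under the
gamma-precision prior the conditionals are Gamma; under the uniform-SD
prior the precision conditional is a Gamma truncated below at
$1/\mathrm{upper}^2$ (the Jacobian of $\sigma \to \tau$ contributes
$-3/2$ to the shape), sampled by inverse-CDF. A random-walk fallback on
$\log \sigma$ covers degenerate cases (rank < 2 or zero sum of
squares). Gibbs scale updates matter in practice: the BYM decomposition
identifies only $u_i + v_i$ strongly, so $\sigma_u$ and $\sigma_v$ trade
off and are the slowest-mixing quantities in the model.

After every sweep $u$ is re-centered to sum to zero per component; when
one component spans all areas the subtracted mean is absorbed into
$\alpha$, leaving the likelihood untouched.

Chain 1 starts at $\alpha = \log(\sum O / \sum E)$, $\beta = 0$,
$u = v = 0$, $\sigma = 0.5$; chain 2 is overdispersed (intercept and
coefficients offset by +0.5, scales doubled) so the Gelman–Rubin
statistic is meaningful. Defaults are 2 chains of 20,000 iterations,
10,000 burn-in, thinning 5; convergence is declared at
$\hat{R} < 1.1$ for $\alpha$, all $\beta_j$ and both scales ($\hat R$
computed on retained draws, matching how simulated rate-ratio histories
are usually monitored). Fits failing the threshold are flagged in the
results table, never dropped. Iteration counts are not dictated by the
model — they were chosen so that the slow-mixing scale parameters pass
$\hat R < 1.1$ reliably on the 432-area reference configuration.

## Geometry

No heavy GIS stack is needed for contiguity and river indicators on
projected planar coordinates, so the package implements the few
primitives it needs directly (segment intersection, collinear overlap,
point-in-polygon, shoelace centroids, point-to-segment distance),
reading and writing standard GeoJSON. Rook contiguity (shared boundary
of positive length) is the default neighbor rule, matching the notion
of areas "sharing a common boundary"; queen contiguity (corner contact
counts) is a config option, since GIS join tools differ on this. The
river indicator is 1 when any river polyline crosses the area polygon
or runs along its boundary; the sensitivity variable is the Euclidean
distance from the polygon centroid to the nearest river polyline. The
two are deliberately not cross-constrained (the flag uses the polygon,
the distance uses the centroid). Geodesic coordinates are out of scope:
inputs are assumed projected.

## The synthetic study

`synthetic_config()` defaults define the reference study conditions;
they emulate the *structure* of an urban small-area suicide study, not
any particular city's data:

- **Geography**: 432 areas on an 18 × 24 lattice of unit squares
  (rook-connected, one component), with a river corridor along one edge
  of the lattice covering exactly `round(0.222 × 432) = 96` areas.
- **Population**: area totals are log-normal around a median of 5,050
  residents aged 10+, with log-SD 1.10 so the 5th–95th percentile span
  is roughly 840–31,300 — mirroring the skew of real neighborhood
  systems. A fixed age distribution over the sixteen 5-year bands is
  shared by all areas.
- **Deaths**: a log-linear reference schedule of age-specific rates
  (slope 0.12 per band — rates rising with age; only positivity
  matters for correctness) is scaled so the region-wide 7-year totals
  match the reference method mix (hanging 892, charcoal burning 859,
  jumping 566, drowning 275, other 402). Counts are then Poisson with
  the BYM relative risks applied, and are emitted both aggregated and
  as row-level records with realistic ICD-10 codes (plus a few under-10
  and non-suicide records so the classification filters are exercised).
- **Covariates**: divorced/separated share and single-person-household
  share are strongly right-skewed (log-normal, triggering the log
  transform), median income is symmetric, the high-floor share is
  mildly skewed (below the log threshold), and the river flag is
  binary — so the transform rule produces a definite, testable marking.
- **Ground truth**: per-method ICAR effects are drawn exactly by
  eigen-decomposition of the lattice Laplacian restricted to the
  sum-to-zero subspace ($\sigma_u = 0.3$), unstructured effects are
  i.i.d. normal ($\sigma_v = 0.2$), and the single built-in covariate
  effect is a rate ratio of 1.15 per 1 SD of the single-person share on
  charcoal-burning deaths — one specific, method-matched effect, so
  specificity (no effect on the hanging control) is testable.

What the generator does **not** emulate: real geography (areas are unit
squares), spatially autocorrelated covariates, migration or time trends
within the aggregation period, method substitution, or calibrated
covariate distributions. Passing recovery tests on this generator
demonstrates that the estimation machinery is correct under the model's
own assumptions — not that the model is adequate for any particular
real dataset.

## Numerical choices and edge cases

- Percentiles (5th/50th/95th, CrI bounds) use R's default type-7
  linear-interpolation convention throughout; the mid-90% dispersion
  summary is the 95th percentile divided by the 5th.
- The rate-ratio point summary is the posterior mean of
  $\exp(\beta_j)$, not $\exp$ of the posterior mean — the convention of
  monitoring the transformed node.
- Smoothed SMRs are posterior means of $\theta_i$ from the
  covariate-free model (`smoothed_smr()` refuses a covariate fit, where
  $\theta_i$ would be residual risk). Summaries of the SMR distribution
  precede covariate modelling, which is the standard sequencing.
- "Unadjusted" results come from one single-covariate model per
  covariate; "adjusted" models add the two socioeconomic covariates to
  one accessibility indicator at a time.
- A method with zero deaths region-wide cannot be standardized
  (expected counts undefined) and is skipped with an explicit log
  entry; the "overall" outcome sums the methods that have deaths.
- An area with zero population gets $E_i = 0$ and is rejected at model
  setup; a band with deaths but no population is a data-integrity
  error.
- Sample skewness uses the plain moment coefficient
  $m_3 / m_2^{3/2}$; constant columns are an error, and a skewed
  column containing nonpositive values triggers an instructive error
  rather than a silent `log` of zero.
- Determinism: every stochastic step (generation and each MCMC chain)
  is seeded from the user seed with fixed offsets; identical
  config + seed gives bit-identical output.

## Validation design

The test-suite sizes were chosen to give informative checks at desk
scale: the ICAR density is compared with an independent
constrained-Gaussian eigen-oracle on *all* connected graphs with up to
5 nodes; the sampler's posterior for a single-area, no-random-effects
model is compared with numerical quadrature (KS distance < 0.05 on
5,000 draws); parameter recovery uses the 432-area reference
configuration with 2 × 5,000-iteration fits — 50 replicates for
credible-interval coverage (nominal 95%, accepted 90–100%) and 20
replicates for the specificity check (the charcoal-only effect must
fire for charcoal and not for hanging). The Gelman–Rubin implementation
is pinned by a hand-computable example: two identical chains of
(1, 2, 3) give $\hat R = \sqrt{2/3} \approx 0.8165$.

## Known limitations

- Single-site Metropolis mixes slowly for strongly coupled posteriors;
  the BYM variance split ($\sigma_u$ vs $\sigma_v$) is the worst case,
  and short runs will show it in $\hat R$ for the scales even when the
  rate ratios are stable. BYM2-type reparameterizations would fix this
  but are out of scope.
- The ICAR exact sampler in the generator eigen-decomposes the
  Laplacian, which is fine up to a few thousand areas and cubic beyond.
- Geometry predicates use absolute tolerances (1e-9, with 1e-7 overlap
  length for rook contiguity) appropriate for coordinates of order
  1–1000; degenerate inputs in very different units should be rescaled.
- Proper CAR (Leroux) models, spatially varying coefficients, travel
  -time accessibility and multiple-testing adjustment are non-goals.
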