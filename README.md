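# bymsmr

Bayesian disease mapping of method-specific small-area mortality.

Small-area suicide counts are sparse: a neighborhood of a few thousand
residents sees a handful of deaths by any one method even over several
years, so raw standardized mortality ratios (SMRs) are mostly Poisson
noise. `bymsmr` is for epidemiologists and health-geography analysts who
need stable neighborhood-level estimates of method-specific mortality
and tests of whether area characteristics — in particular *means
accessibility* indicators such as the share of single-person households
(charcoal burning), the share of households on the sixth floor or above
(jumping), or adjacency to rivers (drowning) — are associated with
method-specific rates.

## The model

For each area *i* and method, with `E_i` the expected count from
indirect age standardization (5-year bands, the study region as its own
standard population):

```
O_i ~ Poisson(E_i * theta_i)
log theta_i = alpha + x_i' beta + u_i + v_i
v_i ~ N(0, sigma_v^2)                          (unstructured)
p(u | sigma_u) ∝ sigma_u^(-rank(Q)) exp( -1/(2 sigma_u^2) * sum_{i~j} (u_i - u_j)^2 )
```

the Besag–York–Mollié (BYM) model: an intrinsic CAR (ICAR) effect `u`
over the rook-contiguity graph, identified by a sum-to-zero constraint,
plus an exchangeable effect `v`. Scale priors are Uniform(0, 5) on the
standard deviations (main analysis) or Gamma(0.01, 0.01) on the
precisions (sensitivity). Covariates are z-scored, log-transformed
first when skewed, so `exp(beta_j)` is a rate ratio per 1 SD. The model
is fitted by an adaptive Metropolis-within-Gibbs sampler (Rcpp), with
Gelman–Rubin convergence checks across overdispersed chains. The
package includes a synthetic-data generator (432 neighborhoods on a
lattice, skewed populations and covariates, a river corridor, known BYM
ground truth) so the full pipeline is testable without confidential
registry data.

## Worked example

```r
library(bymsmr)

cfg <- synthetic_config(seed = 1)     # the 432-area reference study
sim <- simulate_study(cfg)
af  <- sim$area_frame
print(af)
#> <area_frame> 432 areas, 16 age bands
#> observed deaths by method:
#>          hanging charcoal_burning          jumping         drowning
#>             1009              843              612              282
#>            other
#>              434

# covariate-free fit -> smoothed SMRs and their distribution
fit0 <- fit_bym(af, sim$graph, bym_model_spec("charcoal_burning"),
                sampler_config(seed = 1))
sm <- smoothed_smr(fit0)
summarize_distribution(sm, n_method = sum(af$observed[, "charcoal_burning"]),
                       n_total = sum(af$observed))
#>     n percent  mean    sd   p5 median  p95 mid90_ratio
#> 1 843    26.5 0.983 0.246 0.65  0.943 1.42        2.19

# adjusted model: accessibility indicator + two socioeconomic covariates
fit1 <- fit_bym(af, sim$graph,
                bym_model_spec("charcoal_burning",
                               c("single_person_pct", "divorced_pct",
                                 "median_income")),
                sampler_config(seed = 2))
rate_ratios(fit1)
#>           covariate    RR    lo   hi excludes_one
#> 1 single_person_pct 1.104 1.013 1.20         TRUE
#> 2      divorced_pct 1.001 0.919 1.09        FALSE
#> 3     median_income 0.993 0.909 1.08        FALSE
convergence_report(fit1)
#>                parameter rhat converged
#> 1                  alpha    1      TRUE
#> ...
```

Reading the output: smoothed SMRs center near 1 by construction (the
region is its own standard), and their 95th/5th percentile ratio
(`mid90_ratio`, here 2.19) summarizes how much method-specific risk
varies across neighborhoods after noise is smoothed away. The adjusted
rate ratio of 1.10 (95% CrI 1.01–1.20) per 1 SD of the single-person
household share recovers the generator's built-in charcoal-burning
effect (truth 1.15); the interval excluding 1 is flagged. The two
control covariates, with no true effect, bracket 1.

`run_model_set()` orchestrates the full table — every method
(overall + five groups), each covariate unadjusted, each accessibility
indicator adjusted for the socioeconomic pair — and
`pipeline_simulate()` / `pipeline_standardize()` /
`pipeline_adjacency()` / `pipeline_fit()` run the same stages over
CSV/GeoJSON files (thin CLI wrapper in `inst/scripts/bym-pipeline.R`,
with `--prior`, `--contiguity` and `--river-covariate` sensitivity
switches).

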