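test_that("Gelman-Rubin PSRF matches hand arithmetic and limits", {
  # two identical chains: B = 0, R-hat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(cbind(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))

  # two long chains from the same distribution: R-hat near 1
  set.seed(77)
  ch <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(gelman_rubin(ch) - 1), 0.02)

  # disjoint supports: far above 1
  expect_gt(gelman_rubin(cbind(rnorm(200), rnorm(200, 10))), 3)

  # degenerate chains: undefined with a warning
  expect_warning(r <- gelman_rubin(cbind(rep(1, 5), rep(1, 5))),
                 "undefined")
  expect_true(is.na(r))
  expect_error(gelman_rubin(matrix(1:5, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("the sampler is deterministic given the seed", {
  sim <- simulate_study(small_config(seed = 14))
  sc <- sampler_config(n_chains = 2, n_iter = 600, burn_in = 300,
                       thin = 3, seed = 99)
  spec <- bym_model_spec("hanging", "single_person_pct")
  f1 <- fit_bym(sim$area_frame, sim$graph, spec, sc)
  f2 <- fit_bym(sim$area_frame, sim$graph, spec, sc)
  expect_identical(f1$chains[[1]]$scalars, f2$chains[[1]]$scalars)
  expect_identical(f1$chains[[2]]$theta, f2$chains[[2]]$theta)
})

test_that("retained draw count follows chains, burn-in and thinning", {
  sim <- simulate_study(small_config(seed = 15))
  sc <- sampler_config(n_chains = 2, n_iter = 700, burn_in = 250, thin = 4,
                       seed = 5)
  fit <- fit_bym(sim$area_frame, sim$graph, bym_model_spec("hanging"), sc)
  expect_equal(fit$n_retained, 2 * floor((700 - 250) / 4))
  expect_equal(nrow(fit$chains[[1]]$theta), floor((700 - 250) / 4))
  expect_equal(length(posterior_draws(fit, "alpha")), fit$n_retained)
})

test_that("acceptance rates after adaptation sit in a healthy band", {
  sim <- simulate_study(small_config(seed = 16))
  fit <- fit_bym(sim$area_frame, sim$graph,
                 bym_model_spec("charcoal_burning", "divorced_pct"),
                 fast_sampler(seed = 2))
  for (ch in fit$chains) {
    rates <- ch$acc_rate[!is.na(ch$acc_rate)]
    expect_true(all(rates > 0.2 & rates < 0.6))
  }
})

test_that("null data recover coefficients near zero", {
  cfg <- small_config(seed = 17, rows = 8, cols = 8,
                      true_beta = list(),
                      true_sigma_u = 0.05, true_sigma_v = 0.05)
  sim <- simulate_study(cfg)
  fit <- fit_bym(sim$area_frame, sim$graph,
                 bym_model_spec("hanging", c("single_person_pct",
                                             "median_income")),
                 fast_sampler(seed = 3))
  for (cv in c("single_person_pct", "median_income")) {
    draws <- posterior_draws(fit, paste0("beta_", cv))
    expect_lt(abs(mean(draws)), 3 * sd(draws) + 0.05)
  }
})

test_that("conjugate Gibbs scales under the gamma prior stay plausible", {
  cfg <- small_config(seed = 18, rows = 8, cols = 8,
                      true_sigma_u = 0.4, true_sigma_v = 0.2)
  sim <- simulate_study(cfg)
  fit <- fit_bym(sim$area_frame, sim$graph,
                 bym_model_spec("hanging",
                                prior = prior_spec("gamma_precision")),
                 fast_sampler(seed = 4))
  su <- posterior_draws(fit, "sigma_u")
  sv <- posterior_draws(fit, "sigma_v")
  expect_true(all(su > 0) && all(sv > 0))
  expect_lt(median(su), 2)   # not drifting to the improper tail
  expect_lt(median(sv), 2)
})

test_that("uniform-SD prior support (0, 5) is enforced in the chain", {
  sim <- simulate_study(small_config(seed = 19))
  fit <- fit_bym(sim$area_frame, sim$graph, bym_model_spec("hanging"),
                 fast_sampler(seed = 6, n_iter = 1000, burn_in = 500))
  expect_true(all(posterior_draws(fit, "sigma_u") < 5))
  expect_true(all(posterior_draws(fit, "sigma_v") < 5))
})

test_that("initialization failures and schema mismatches are reported", {
  sim <- simulate_study(small_config(seed = 20))
  af <- sim$area_frame
  af$observed[, "hanging"] <- 0L
  expect_error(fit_bym(af, sim$graph, bym_model_spec("hanging"),
                       fast_sampler(seed = 1)),
               "initialization")
  expect_error(fit_bym(sim$area_frame, sim$graph,
                       bym_model_spec("hanging", "no_such_covariate"),
                       fast_sampler(seed = 1)),
               "unknown covariate")
  g_bad <- adjacency_from_edges(c("x", "y"), rbind(c(1, 2)))
  expect_error(fit_bym(sim$area_frame, g_bad, bym_model_spec("hanging"),
                       fast_sampler(seed = 1)),
               "node set")
})

test_that("samples persist to the long CSV format", {
  sim <- simulate_study(small_config(seed = 22))
  fit <- fit_bym(sim$area_frame, sim$graph, bym_model_spec("hanging"),
                 fast_sampler(seed = 8, n_iter = 400, burn_in = 200))
  path <- tempfile(fileext = ".csv")
  write_samples_csv(fit, path)
  df <- read.csv(path)
  expect_equal(sort(unique(df$parameter)),
               sort(c("alpha", "sigma_u", "sigma_v")))
  expect_equal(nrow(df), fit$n_retained * 3)
  unlink(path)
})
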