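test_that("smoothed SMRs are posterior means of theta and need the null model", {
  th1 <- matrix(c(1.0, 1.2, 1.4, 0.8, 1.0, 1.2), 3, 2,
                dimnames = list(NULL, c("A1", "A2")))
  th2 <- matrix(c(1.2, 1.4, 1.6, 1.0, 1.2, 1.4), 3, 2,
                dimnames = list(NULL, c("A1", "A2")))
  fit <- fake_fit(theta_by_chain = list(th1, th2))
  expect_equal(smoothed_smr(fit),
               c(A1 = mean(c(th1[, 1], th2[, 1])),
                 A2 = mean(c(th1[, 2], th2[, 2]))))

  # degenerate posterior at alpha = u = v = 0 -> all SMRs 1
  ones <- matrix(1, 4, 2, dimnames = list(NULL, c("A1", "A2")))
  expect_equal(unname(smoothed_smr(fake_fit(theta_by_chain = list(ones, ones)))),
               c(1, 1))

  fit_cov <- fake_fit(beta_draws_by_chain = list(rnorm(5), rnorm(5)))
  expect_error(smoothed_smr(fit_cov), "covariate-free")
})

test_that("single-area posterior mean of theta matches the quadrature oracle", {
  O <- 9; E <- 4
  pop <- matrix(c(1000, 800), 1, 2, dimnames = list("A1", c("b1", "b2")))
  recs <- data.frame(area_id = "A1", age = rep(40, O), icd10_code = "X70")
  af <- make_area_frame(pop, recs, methods = "hanging")
  af$expected[, "hanging"] <- E  # fixed offset for the oracle comparison
  g <- adjacency_from_edges("A1", NULL)
  spec <- bym_model_spec("hanging", include_u = FALSE, include_v = FALSE)
  fit <- fit_bym(af, g, spec,
                 sampler_config(n_chains = 2, n_iter = 30000,
                                burn_in = 5000, thin = 5, seed = 42))
  # oracle: E[exp(alpha)] under p(alpha) propto exp(O alpha - E e^alpha),
  # which is the Gamma(O, E) mean O/E
  sm <- smoothed_smr(fit)
  expect_equal(unname(sm), O / E, tolerance = 0.01)
})

test_that("distribution summaries use type-7 percentiles and the mid-90% ratio", {
  x <- vector_with_percentiles(0.83, 1.27)
  s <- summarize_distribution(x, n_method = 892, n_total = 2994)
  expect_equal(s$p5, 0.83)
  expect_equal(s$p95, 1.27)
  expect_equal(s$mid90_ratio, 1.27 / 0.83)
  expect_equal(round(s$mid90_ratio, 2), 1.53)
  expect_equal(round(s$percent, 1), 29.8)

  const <- summarize_distribution(rep(2, 10), 5, 50)
  expect_equal(const$mid90_ratio, 1)
  expect_equal(const$sd, 0)

  expect_error(summarize_distribution(numeric(0)), "empty")
  expect_error(summarize_distribution(c(1, -1)), "positive")
})

test_that("mid-90% ratio is permutation- and scale-invariant", {
  set.seed(8)
  x <- rlnorm(150, 0, 0.3)
  expect_equal(mid90_ratio(x), mid90_ratio(sample(x)))
  expect_equal(mid90_ratio(3.7 * x), mid90_ratio(x))
  s1 <- summarize_distribution(x)
  s2 <- summarize_distribution(sample(x))
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$mid90_ratio, s2$mid90_ratio)
})

test_that("rate ratios summarize exp(beta) draws with 95% CrIs", {
  # point mass at log 2
  fit <- fake_fit(beta_draws_by_chain = list(rep(log(2), 200),
                                             rep(log(2), 200)))
  rr <- rate_ratios(fit)
  expect_equal(rr$RR, 2)
  expect_equal(c(rr$lo, rr$hi), c(2, 2))
  expect_true(rr$excludes_one)   # the degenerate interval [2, 2] misses 1

  # tight null: CrI brackets 1, flag off; matches normal-quantile form
  set.seed(12)
  draws <- rnorm(10000, 0, 0.01)
  fit2 <- fake_fit(beta_draws_by_chain = list(draws[1:5000],
                                              draws[5001:10000]))
  rr2 <- rate_ratios(fit2)
  expect_false(rr2$excludes_one)
  expect_equal(rr2$lo, exp(quantile(draws, 0.025, names = FALSE)),
               tolerance = 1e-10)
  expect_equal(rr2$hi, exp(quantile(draws, 0.975, names = FALSE)),
               tolerance = 1e-10)
  expect_equal(rr2$RR, mean(exp(draws)), tolerance = 1e-12)

  # warning below 100 retained draws
  fit3 <- fake_fit(beta_draws_by_chain = list(rnorm(20), rnorm(20)))
  expect_warning(rate_ratios(fit3), "100 retained")
})

test_that("the model set runs end to end with flags and skips", {
  cfg <- small_config(seed = 77, rows = 8, cols = 8,
                      method_totals = c(hanging = 400,
                                        charcoal_burning = 0))
  sim <- simulate_study(cfg)
  res <- run_model_set(
    sim$area_frame, sim$graph,
    methods = c("hanging", "charcoal_burning"),
    accessibility = c("single_person_pct", "river"),
    socioeconomic = c("divorced_pct", "median_income"),
    sampler = fast_sampler(seed = 5, n_iter = 1200, burn_in = 600))
  expect_equal(res$skipped, "charcoal_burning")
  # 4 unadjusted + 2 adjusted rows for the one fitted method
  expect_equal(nrow(res$results), 6)
  expect_equal(sort(unique(res$results$model_set)),
               c("adjusted", "unadjusted"))
  expect_true(all(c("RR", "lo", "hi", "excludes_one", "rhat_max",
                    "converged") %in% names(res$results)))
  expect_equal(nrow(res$table1), 1)
  expect_true(all(res$results$lo <= res$results$hi))
  # non-convergence is flagged, not dropped
  expect_true(all(!is.na(res$results$converged)))

  dir <- tempfile()
  paths <- write_results_csv(res, dir)
  expect_true(all(file.exists(paths)))
  unlink(dir, recursive = TRUE)
})

test_that("smoothing shrinks variance relative to raw SMRs", {
  sim <- simulate_study(small_config(seed = 88, rows = 10, cols = 10))
  af <- sim$area_frame
  fit <- fit_bym(af, sim$graph, bym_model_spec("hanging"),
                 fast_sampler(seed = 10))
  sm <- smoothed_smr(fit)
  raw <- raw_smr(af$observed[, "hanging"], af$expected[, "hanging"])
  expect_lt(var(sm), var(raw))
})
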