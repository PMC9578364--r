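test_that("covariate transform z-scores, logs skewed columns, flags binaries", {
  cm <- transform_covariates(data.frame(a = c(1, 2, 3)))
  expect_equal(unname(cm$X[, "a"]), c(-1, 0, 1))
  expect_equal(unname(cm$transforms["a"]), "none")

  expect_error(transform_covariates(data.frame(a = rep(2, 5))), "constant")

  skewed <- data.frame(s = c(1, 1, 1, 100))
  cm2 <- transform_covariates(skewed)
  expect_equal(unname(cm2$transforms["s"]), "log")
  expect_lt(abs(sample_skewness(log(skewed$s))),
            abs(sample_skewness(skewed$s)))
  expect_equal(mean(cm2$X[, "s"]), 0, tolerance = 1e-9)
  expect_equal(sd(cm2$X[, "s"]), 1, tolerance = 1e-9)

  # skewed column with nonpositive values cannot be logged
  expect_error(transform_covariates(data.frame(s = c(0, 1, 1, 100))),
               "nonpositive")

  # binary column: never logged; z-scored by default, raw on request
  b <- data.frame(r = c(0, 0, 1, 1))
  expect_equal(sd(transform_covariates(b)$X[, "r"]), 1)
  expect_equal(transform_covariates(b, binary = "raw")$X[, "r"],
               c(r1 = 0, r2 = 0, r3 = 1, r4 = 1), ignore_attr = TRUE)
})

test_that("covariate transform is idempotent on standardized columns", {
  set.seed(21)
  x <- rnorm(200)
  z <- (x - mean(x)) / sd(x)
  cm <- transform_covariates(data.frame(z = z))
  expect_equal(unname(cm$transforms["z"]), "none")
  expect_equal(unname(cm$X[, "z"]), z, tolerance = 1e-12)
})

test_that("Poisson log-likelihood matches closed forms", {
  E <- c(2, 3, 4)
  expect_equal(poisson_loglik(c(0, 0, 0), E, c(0, 0, 0)), -sum(E))
  expect_equal(poisson_loglik(2, 1, 0), 2 * 0 - 1 - log(2))
  expect_error(poisson_loglik(1, 0, 0), "positive")

  # identifiability symmetry: alpha + c vs v - c leaves eta unchanged
  set.seed(4)
  O <- rpois(10, 5); E2 <- runif(10, 1, 3)
  alpha <- 0.3; v <- rnorm(10, 0, 0.2); cc <- 0.7
  expect_equal(poisson_loglik(O, E2, alpha + v),
               poisson_loglik(O, E2, (alpha + cc) + (v - cc)))

  # decreases as |eta| grows with O fixed
  ll0 <- poisson_loglik(O, E2, rep(0, 10))
  expect_gt(ll0, poisson_loglik(O, E2, rep(8, 10)))
  expect_gt(ll0, poisson_loglik(O, E2, rep(-12, 10)))
})

test_that("ICAR log-density matches hand arithmetic and the eigen oracle", {
  path3 <- adjacency_from_edges(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))
  # constant u: pairwise term vanishes
  expect_equal(icar_logpdf(c(0, 0, 0), path3, 2), 1 * log(1 / 4))
  # u = (0, 1, -1), sigma = 1: pairwise sum 5, exponent -2.5
  expect_equal(icar_logpdf(c(0, 1, -1), path3, 1), -2.5)

  set.seed(31)
  for (g in connected_graphs(4)) {
    u <- rnorm(4); u <- u - mean(u)
    s <- runif(1, 0.3, 2)
    expect_equal(icar_logpdf(u, g, s), icar_oracle(u, g, s),
                 tolerance = 1e-10)
  }
})

test_that("ICAR log-density enforces its support constraints", {
  path3 <- adjacency_from_edges(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))
  expect_error(icar_logpdf(c(1, 1, 1), path3, 1), "sum to zero")
  with_iso <- adjacency_from_edges(c("a", "b", "c"), rbind(c(1, 2)))
  expect_error(icar_logpdf(c(0.5, -0.5, 0.3), with_iso, 1), "solated")
  # ss = (0.5 - (-0.5))^2 = 1, rank = 3 - 2 components = 1
  expect_equal(icar_logpdf(c(0.5, -0.5, 0), with_iso, 1), -0.5)
  # invariance to a per-component constant shift before re-centering
  u <- c(0.4, -0.1, -0.3)
  shifted <- u + 5
  shifted <- shifted - mean(shifted)
  expect_equal(icar_logpdf(shifted, path3, 0.7), icar_logpdf(u, path3, 0.7))
})

test_that("priors on the random-effect scales evaluate correctly", {
  st <- function(su, sv) bym_state(u = c(0, 0), v = c(0, 0),
                                   sigma_u = su, sigma_v = sv)
  unif <- prior_spec("uniform_sd")
  expect_equal(log_prior(st(1, 1), unif), 0)
  expect_equal(log_prior(st(6, 1), unif), -Inf)
  expect_equal(log_prior(st(1, -0.1), unif), -Inf)

  gam <- prior_spec("gamma_precision")
  # tau = 1 for both scales
  expect_equal(log_prior(st(1, 1), gam),
               2 * (0.01 * log(0.01) - lgamma(0.01) + (0.01 - 1) * log(1)
                    - 0.01 * 1))
  # normal prior on alpha/beta when requested
  norm <- prior_spec("uniform_sd", normal_sd = 10)
  s <- st(1, 1); s$alpha <- 2; s$beta <- c(0.5)
  expect_equal(log_prior(s, norm),
               sum(dnorm(c(2, 0.5), sd = 10, log = TRUE)))
})

test_that("model spec round-trips through JSON", {
  spec <- bym_model_spec("drowning", c("river", "median_income"),
                         prior = prior_spec("gamma_precision"),
                         binary = "raw")
  path <- tempfile(fileext = ".json")
  write_model_spec_json(spec, path)
  back <- read_model_spec_json(path)
  expect_equal(back$method, spec$method)
  expect_equal(back$covariates, spec$covariates)
  expect_equal(back$prior$family, "gamma_precision")
  expect_equal(back$binary, "raw")
  unlink(path)
})
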