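# Posterior summaries: smoothed SMRs, distribution summaries with the
# mid-90% ratio, rate ratios with 95% credible intervals, and the
# orchestration of the unadjusted/adjusted model sets.

#' Smoothed SMRs from a covariate-free fit
#'
#' Posterior mean over retained draws of the area relative risk
#' `theta_i = exp(alpha + u_i + v_i)`. Requires the covariate-free
#' (intercept + random effects) model: with covariates in the linear
#' predictor, `theta` would be a residual risk, not the smoothed SMR.
#'
#' @param fit A `bym_fit`.
#' @return Named numeric vector of smoothed SMRs per area.
#' @export
smoothed_smr <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(fit$model$covariates) > 0) {
    stop("smoothed SMRs require the covariate-free model; refit with ",
         "an empty covariate set")
  }
  theta <- do.call(rbind, lapply(fit$chains, function(c) c$theta))
  colMeans(theta)
}

#' Mid-90% ratio of a positive distribution
#'
#' The 95th percentile divided by the 5th percentile (linear
#' interpolation percentiles), a scale-free dispersion summary of
#' small-area relative risks.
#'
#' @param x Positive numeric vector.
#' @return The ratio (>= 1 for nondegenerate input).
#' @export
mid90_ratio <- function(x) {
  if (any(x <= 0)) stop("mid-90% ratio requires positive values")
  q <- quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
  q[2] / q[1]
}

#' Distribution summary of smoothed SMRs for one method
#'
#' Mean, SD, 5th/50th/95th percentiles (linear-interpolation convention,
#' R type 7) and the mid-90% ratio over areas, plus the method's share
#' of all deaths.
#'
#' @param smrs Positive vector of per-area smoothed SMRs.
#' @param n_method Total deaths for this method.
#' @param n_total Total deaths over all methods (for the percent share);
#'   `NA` omits the share.
#' @return One-row data frame (class `distribution_summary`).
#' @export
summarize_distribution <- function(smrs, n_method = NA, n_total = NA) {
  if (length(smrs) == 0) stop("empty SMR vector")
  if (any(smrs <= 0)) {
    stop("smoothed SMRs must be positive (exp link); found nonpositive values")
  }
  q <- quantile(smrs, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  out <- data.frame(
    n = n_method,
    percent = if (is.na(n_total)) NA_real_ else 100 * n_method / n_total,
    mean = mean(smrs), sd = sd(smrs),
    p5 = q[1], median = q[2], p95 = q[3],
    mid90_ratio = q[3] / q[1])
  class(out) <- c("distribution_summary", class(out))
  out
}

#' Rate ratios with 95% credible intervals
#'
#' For each covariate j the rate ratio per 1 SD is summarized as the
#' posterior mean of `exp(beta_j)` with the 2.5th and 97.5th percentiles
#' of the `exp(beta_j)` draws as the credible interval. `excludes_one`
#' marks intervals not containing 1 (the reporting convention for
#' highlighting associations).
#'
#' @param fit A `bym_fit` with at least one covariate.
#' @param covariates Covariates to report (default: all in the model).
#' @return Data frame: `covariate`, `RR`, `lo`, `hi`, `excludes_one`.
#' @export
rate_ratios <- function(fit, covariates = fit$model$covariates) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(covariates) == 0) stop("model has no covariates")
  if (fit$n_retained < 100) {
    warning("fewer than 100 retained draws; credible intervals unstable")
  }
  rows <- lapply(covariates, function(cv) {
    draws <- exp(posterior_draws(fit, paste0("beta_", cv)))
    ci <- quantile(draws, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(covariate = cv, RR = mean(draws), lo = ci[1], hi = ci[2],
               excludes_one = (ci[1] > 1 || ci[2] < 1))
  })
  do.call(rbind, rows)
}

#' Fit the full unadjusted/adjusted model set
#'
#' For each method (optionally including `"overall"`, the sum over
#' methods) fits: (a) the covariate-free model, giving smoothed SMRs and
#' a distribution-summary row; (b) one model per single covariate
#' ("unadjusted"); (c) one model per accessibility indicator with the
#' socioeconomic covariates added ("adjusted"). Methods with zero total
#' deaths are skipped with a message. Fits failing the R-hat threshold
#' are flagged, never dropped.
#'
#' @param area_frame An `area_frame` with covariates.
#' @param graph Matching `adjacency_graph`.
#' @param methods Methods to analyze (default `"overall"` plus all in
#'   the frame).
#' @param accessibility Names of the accessibility covariates.
#' @param socioeconomic Names of the adjustment covariates.
#' @param sampler A [sampler_config()].
#' @param prior A [prior_spec()].
#' @param binary Binary-covariate handling (see
#'   [transform_covariates()]).
#' @param verbose Print progress messages.
#' @return List of class `model_set_results`: `results` (long data
#'   frame: method, covariate, model_set, RR, lo, hi, excludes_one,
#'   rhat_max, converged), `table1` (distribution summaries),
#'   `smoothed` (areas x methods matrix of smoothed SMRs), `skipped`.
#' @export
run_model_set <- function(area_frame, graph,
                          methods = c("overall", area_frame$methods),
                          accessibility = c("single_person_pct",
                                            "high_floor_pct", "river"),
                          socioeconomic = c("divorced_pct",
                                            "median_income"),
                          sampler = sampler_config(),
                          prior = prior_spec("uniform_sd"),
                          binary = "zscore",
                          verbose = FALSE) {
  stopifnot(inherits(area_frame, "area_frame"))
  say <- function(...) if (verbose) message(...)
  all_cov <- c(socioeconomic, accessibility)

  totals <- vapply(methods, function(m) sum(.method_counts(area_frame, m)$O),
                   numeric(1))
  grand_total <- sum(.method_counts(area_frame, "overall")$O)
  skipped <- methods[totals == 0]
  for (m in skipped) say("method ", m, " has zero deaths; skipped")
  methods <- methods[totals > 0]

  smoothed <- matrix(NA_real_, length(area_frame$areas), length(methods),
                     dimnames = list(area_frame$areas, methods))
  table1 <- NULL
  results <- NULL
  fit_seed <- sampler$seed

  one_fit <- function(method, covariates, model_set) {
    fit_seed <<- fit_seed + 1L
    sc <- sampler; sc$seed <- fit_seed
    spec <- bym_model_spec(method, covariates, prior = prior,
                           binary = binary)
    fit <- fit_bym(area_frame, graph, spec, sc)
    fit
  }

  for (m in methods) {
    say("fitting covariate-free model: ", m)
    fit0 <- one_fit(m, character(0), "smoothing")
    smoothed[, m] <- smoothed_smr(fit0)
    t1 <- summarize_distribution(smoothed[, m], n_method = totals[[m]],
                                 n_total = grand_total)
    t1 <- cbind(data.frame(method = m), t1,
                data.frame(rhat_max = max(fit0$rhat, na.rm = TRUE)))
    table1 <- rbind(table1, t1)

    sets <- c(lapply(all_cov, function(cv) {
                list(cov = cv, covs = cv, set = "unadjusted")
              }),
              lapply(accessibility, function(cv) {
                list(cov = cv, covs = unique(c(cv, socioeconomic)),
                     set = "adjusted")
              }))
    for (s in sets) {
      say("fitting ", s$set, " model: ", m, " ~ ", s$cov)
      fit <- one_fit(m, s$covs, s$set)
      rr <- rate_ratios(fit, covariates = s$cov)
      rhat_max <- max(fit$rhat, na.rm = TRUE)
      results <- rbind(results, data.frame(
        method = m, covariate = s$cov, model_set = s$set,
        RR = rr$RR, lo = rr$lo, hi = rr$hi,
        excludes_one = rr$excludes_one,
        rhat_max = rhat_max,
        converged = rhat_max < sampler$rhat_threshold))
    }
  }

  structure(list(results = results, table1 = table1, smoothed = smoothed,
                 skipped = skipped),
            class = "model_set_results")
}

#' @export
print.model_set_results <- function(x, ...) {
  cat("<model_set_results>\n")
  cat("Smoothed-SMR distribution summaries:\n")
  print(x$table1, digits = 3)
  cat("\nRate ratios (per 1 SD):\n")
  print(x$results, digits = 3)
  invisible(x)
}

#' Write model-set results to CSV files
#'
#' @param res A `model_set_results`.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_results_csv <- function(res, dir) {
  stopifnot(inherits(res, "model_set_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "results.csv")
  p2 <- file.path(dir, "table1.csv")
  p3 <- file.path(dir, "smoothed_smr.csv")
  write.csv(res$results, p1, row.names = FALSE)
  write.csv(res$table1, p2, row.names = FALSE)
  sm <- data.frame(area_id = rownames(res$smoothed), res$smoothed,
                   check.names = FALSE)
  write.csv(sm, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
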