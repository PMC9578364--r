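# Fitting the BYM model by MCMC; convergence diagnostics.

#' Sampler configuration
#'
#' @param n_chains Number of chains (>= 2 so R-hat is defined).
#' @param n_iter Total iterations per chain.
#' @param burn_in Discarded iterations (must be < `n_iter`); proposal
#'   adaptation runs only during burn-in.
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed; each chain uses a deterministic offset.
#' @param adapt_interval Iterations between proposal-scale adaptations.
#' @param target_acceptance Adaptation target for scalar random-walk
#'   blocks (0.44, the classic single-site optimum).
#' @param rhat_threshold Convergence cutoff for the Gelman-Rubin
#'   statistic.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2, n_iter = 20000, burn_in = 10000,
                           thin = 5, seed = 1, adapt_interval = 50,
                           target_acceptance = 0.44, rhat_threshold = 1.1) {
  stopifnot(n_chains >= 2, burn_in < n_iter, thin >= 1,
            adapt_interval >= 1, target_acceptance > 0,
            target_acceptance < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 target_acceptance = target_acceptance,
                 rhat_threshold = rhat_threshold),
            class = "sampler_config")
}

#' Fit a BYM model by adaptive Metropolis-within-Gibbs
#'
#' Single-site Gaussian random-walk updates for the intercept, each
#' coefficient, and each structured and unstructured effect, with
#' Robbins-Monro scale adaptation toward the target acceptance rate
#' during burn-in (frozen afterwards). Under the gamma-precision prior
#' the two scales are updated by conjugate Gibbs steps on the
#' precisions; under the uniform-SD prior by random-walk Metropolis on
#' the log scale with the (0, upper) support enforced. The structured
#' effect is re-centered to sum to zero per connected component after
#' every sweep; isolated areas have their structured effect fixed at 0.
#' Chain 1 starts at `alpha = log(sum O / sum E)`, `beta = 0`,
#' `u = v = 0`, `sigma = 0.5`; later chains are overdispersed (offset
#' intercept/coefficients, doubled scales).
#'
#' @param area_frame An `area_frame` from [make_area_frame()].
#' @param graph An `adjacency_graph` over the same areas.
#' @param model A [bym_model_spec()].
#' @param sampler A [sampler_config()].
#' @param store_u Keep the retained draws of the structured effect
#'   (memory-heavy; default `FALSE`).
#' @return Object of class `bym_fit`: per-chain retained draws of the
#'   scalar parameters and of the area relative risks
#'   `theta_i = exp(alpha + u_i + v_i)`, acceptance rates, the
#'   covariate transform record, and a Gelman-Rubin table.
#' @export
fit_bym <- function(area_frame, graph, model, sampler = sampler_config(),
                    store_u = FALSE) {
  stopifnot(inherits(area_frame, "area_frame"),
            inherits(graph, "adjacency_graph"),
            inherits(model, "bym_model_spec"),
            inherits(sampler, "sampler_config"))
  if (!setequal(graph$ids, area_frame$areas)) {
    stop("graph node set must equal the area set of the area frame")
  }
  ord <- match(area_frame$areas, graph$ids)
  graph <- .reorder_graph(graph, ord)

  oe <- .method_counts(area_frame, model$method)
  O <- oe$O; E <- oe$E
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("expected counts must be positive and finite for method ",
         model$method)
  }

  p <- length(model$covariates)
  if (p > 0) {
    if (is.null(area_frame$covariates)) stop("area frame has no covariates")
    missing_cov <- setdiff(model$covariates, names(area_frame$covariates))
    if (length(missing_cov) > 0) {
      stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
    }
    cm <- transform_covariates(
      area_frame$covariates[model$covariates],
      skew_threshold = model$skew_threshold, binary = model$binary)
    X <- cm$X
  } else {
    cm <- NULL
    X <- matrix(numeric(0), length(O), 0)
  }

  comp <- graph_components(graph)
  rank <- length(graph$ids) - max(comp)
  nb0 <- lapply(graph$nb, function(x) as.integer(x - 1L))
  edges0 <- matrix(as.integer(graph$edges - 1L), ncol = 2)

  alpha_init <- log(sum(O) / sum(E))
  if (!is.finite(alpha_init)) {
    stop("non-finite log-posterior at initialization: sum of observed ",
         "counts is zero for method ", model$method)
  }
  prior <- model$prior
  normal_prec <- if (is.finite(prior$normal_sd)) 1 / prior$normal_sd^2 else 0

  param_names <- c("alpha",
                   if (p > 0) paste0("beta_", model$covariates),
                   "sigma_u", "sigma_v")
  block_names <- c("alpha",
                   if (p > 0) paste0("beta_", model$covariates),
                   "u", "v", "log_sigma_u", "log_sigma_v")

  chains <- vector("list", sampler$n_chains)
  for (ch in seq_len(sampler$n_chains)) {
    off <- ch - 1
    set.seed(sampler$seed + 1009L * off)
    res <- .bym_chain_cpp(
      O = as.numeric(O), E = as.numeric(E), X = X,
      nb = nb0, comp = as.integer(comp), rank = as.integer(rank),
      edges = edges0,
      include_u = model$include_u, include_v = model$include_v,
      prior_family = ifelse(prior$family == "gamma_precision", 1L, 0L),
      unif_upper = prior$upper, gam_shape = prior$shape,
      gam_rate = prior$rate, normal_prec = normal_prec,
      n_iter = sampler$n_iter, burn_in = sampler$burn_in,
      thin = sampler$thin, adapt_interval = sampler$adapt_interval,
      target_acc = sampler$target_acceptance,
      alpha0 = alpha_init + 0.5 * off,
      beta0 = rep(0.5 * off, p),
      sigma_u0 = 0.5 * (1 + off), sigma_v0 = 0.5 * (1 + off),
      store_u = store_u)
    colnames(res$scalars) <- param_names
    colnames(res$theta) <- area_frame$areas
    names(res$acc_rate) <- block_names
    names(res$prop_sd) <- block_names
    chains[[ch]] <- res
  }

  monitored <- c("alpha",
                 if (p > 0) paste0("beta_", model$covariates),
                 if (model$include_u) "sigma_u",
                 if (model$include_v) "sigma_v")
  rhat <- vapply(monitored, function(pm) {
    gelman_rubin(sapply(chains, function(c) c$scalars[, pm]))
  }, numeric(1))

  structure(list(chains = chains, model = model, sampler = sampler,
                 areas = area_frame$areas, O = O, E = E,
                 covariate_matrix = cm, rhat = rhat,
                 n_retained = nrow(chains[[1]]$scalars) * sampler$n_chains),
            class = "bym_fit")
}

.reorder_graph <- function(graph, ord) {
  if (all(ord == seq_along(ord))) return(graph)
  inv <- order(ord)
  edges <- graph$edges
  if (nrow(edges) > 0) {
    edges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
  }
  adjacency_from_edges(graph$ids[ord], edges)
}

# observed / expected vectors for one method; "overall" sums the methods
# with any deaths (expected counts are undefined for empty methods)
.method_counts <- function(af, method) {
  if (identical(method, "overall")) {
    ok <- colSums(af$observed) > 0
    list(O = rowSums(af$observed[, ok, drop = FALSE]),
         E = rowSums(af$expected[, ok, drop = FALSE]))
  } else {
    if (!method %in% af$methods) stop("unknown method: ", method)
    list(O = af$observed[, method], E = af$expected[, method])
  }
}

#' Pooled retained draws of a scalar parameter
#'
#' @param fit A `bym_fit`.
#' @param parameter Column name, e.g. `"alpha"` or `"beta_<covariate>"`.
#' @return Numeric vector of draws pooled over chains.
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "bym_fit"))
  unlist(lapply(fit$chains, function(c) {
    if (!parameter %in% colnames(c$scalars)) {
      stop("unknown parameter: ", parameter)
    }
    c$scalars[, parameter]
  }), use.names = FALSE)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("<bym_fit> method=", x$model$method,
      " covariates=[", paste(x$model$covariates, collapse = ", "), "]\n",
      sep = "")
  cat(length(x$chains), "chains,", x$n_retained, "retained draws\n")
  cat("R-hat:\n"); print(round(x$rhat, 3))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from M chains of equal retained length n:
#' `W` = mean within-chain variance, `B/n` = variance of the chain
#' means, `R-hat = sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param chains Matrix with one column per chain (rows = draws), or a
#'   list of equal-length numeric vectors.
#' @return R-hat; `NA` (with a warning) when the within-chain variance
#'   is zero.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2) stop("at least 2 chains are required")
  if (n < 2) stop("at least 2 draws per chain are required")
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(colMeans(chains))
  if (W == 0) {
    warning("within-chain variance is zero; R-hat undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence report for a fitted model
#'
#' @param fit A `bym_fit`.
#' @param threshold R-hat cutoff (defaults to the sampler config value).
#' @return Data frame with columns `parameter`, `rhat`, `converged`.
#' @export
convergence_report <- function(fit, threshold = fit$sampler$rhat_threshold) {
  stopifnot(inherits(fit, "bym_fit"))
  data.frame(parameter = names(fit$rhat),
             rhat = unname(fit$rhat),
             converged = !is.na(fit$rhat) & fit$rhat < threshold,
             row.names = NULL)
}

#' Persist retained scalar draws as a long CSV
#'
#' Columns: `chain`, `iteration` (retained index), `parameter`, `value`.
#'
#' @param fit A `bym_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(fit, path) {
  stopifnot(inherits(fit, "bym_fit"))
  rows <- do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    sc <- fit$chains[[ch]]$scalars
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(sc)), ncol(sc)),
               parameter = rep(colnames(sc), each = nrow(sc)),
               value = as.vector(sc))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
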