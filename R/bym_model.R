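# BYM likelihood, ICAR prior, covariate transforms and prior spec.
#
# Model: O_i ~ Poisson(E_i * exp(eta_i)),
#        eta_i = alpha + x_i' beta + u_i + v_i,
# with u an intrinsic CAR (pairwise-difference) spatial effect and v an
# exchangeable Normal(0, sigma_v^2) effect. The offset log E_i makes the
# model target area relative risk rather than raw counts.

#' Sample skewness
#'
#' Moment coefficient of skewness `m3 / m2^(3/2)` (no small-sample
#' correction).
#'
#' @param x Numeric vector.
#' @return Skewness, or `NA` for constant input.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Transform and standardize area covariates
#'
#' Continuous covariates whose absolute sample skewness exceeds
#' `skew_threshold` are natural-log transformed, then all columns are
#' z-scored (mean 0, sample SD 1). Binary (0/1) columns are never
#' log-transformed; by default they are z-scored too, so rate ratios are
#' uniformly "per 1 SD increase" (set `binary = "raw"` to keep them 0/1).
#'
#' @param raw Data frame (or matrix) of per-area covariate values; row
#'   order defines the area order.
#' @param skew_threshold Absolute skewness above which a log transform is
#'   applied (default 1).
#' @param binary `"zscore"` (default) or `"raw"` handling for 0/1 columns.
#' @return An object of class `covariate_matrix`: list with `X` (the
#'   analysis-scale matrix), `transforms` (named character,
#'   `"none"`/`"log"`), `center`, `scale`, `skewness_raw`, `binary`.
#' @export
transform_covariates <- function(raw, skew_threshold = 1,
                                 binary = c("zscore", "raw")) {
  binary <- match.arg(binary)
  raw <- as.data.frame(raw)
  X <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), names(raw)))
  transforms <- setNames(rep("none", ncol(raw)), names(raw))
  center <- setNames(numeric(ncol(raw)), names(raw))
  scale_ <- setNames(numeric(ncol(raw)), names(raw))
  skew_raw <- setNames(numeric(ncol(raw)), names(raw))
  is_bin <- setNames(logical(ncol(raw)), names(raw))

  for (nm in names(raw)) {
    x <- as.numeric(raw[[nm]])
    if (anyNA(x)) stop("covariate ", nm, " contains missing values")
    vals <- unique(x)
    is_bin[nm] <- length(vals) <= 2 && all(vals %in% c(0, 1))
    skew_raw[nm] <- if (is_bin[nm]) NA_real_ else sample_skewness(x)
    if (!is_bin[nm]) {
      if (sd(x) == 0) stop("covariate ", nm, " is constant (zero SD)")
      if (abs(skew_raw[nm]) > skew_threshold) {
        if (any(x <= 0)) {
          stop("covariate ", nm, " is skewed but contains nonpositive ",
               "values; add an offset or disable the log transform")
        }
        x <- log(x)
        transforms[nm] <- "log"
      }
      center[nm] <- mean(x)
      scale_[nm] <- sd(x)
      X[, nm] <- (x - center[nm]) / scale_[nm]
    } else {
      if (binary == "zscore") {
        if (sd(x) == 0) stop("covariate ", nm, " is constant (zero SD)")
        center[nm] <- mean(x); scale_[nm] <- sd(x)
        X[, nm] <- (x - center[nm]) / scale_[nm]
      } else {
        center[nm] <- 0; scale_[nm] <- 1
        X[, nm] <- x
      }
    }
  }
  structure(list(X = X, transforms = transforms, center = center,
                 scale = scale_, skewness_raw = skew_raw, binary = is_bin),
            class = "covariate_matrix")
}

#' Poisson log-likelihood with expected-count offset
#'
#' `sum_i [ O_i (log E_i + eta_i) - E_i exp(eta_i) - log(O_i!) ]`.
#'
#' @param O Observed counts.
#' @param E Expected counts (offset), positive.
#' @param eta Linear predictor per area.
#' @return Log-likelihood (scalar).
#' @export
poisson_loglik <- function(O, E, eta) {
  if (any(E <= 0)) stop("expected counts must be positive")
  sum(O * (log(E) + eta) - E * exp(eta) - lfactorial(O))
}

#' Unnormalized intrinsic CAR log-density
#'
#' Pairwise-difference form of the ICAR prior:
#' `-(1 / (2 sigma_u^2)) * sum_{(i,j) in edges} (u_i - u_j)^2
#'  + (rank / 2) * log(1 / sigma_u^2)`
#' with `rank = n - (number of connected components)`, the rank of the
#' ICAR precision matrix. The density lives on the sum-to-zero subspace:
#' `u` must sum to zero within each component with at least two nodes,
#' and isolated nodes must have `u = 0` (their conditional is undefined).
#'
#' @param u Numeric vector, one value per graph node.
#' @param graph An `adjacency_graph`.
#' @param sigma_u Positive scale of the structured effect.
#' @return Unnormalized log-density (scalar).
#' @export
icar_logpdf <- function(u, graph, sigma_u) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$ids)
  if (length(u) != n) stop("length(u) must equal the number of nodes")
  if (sigma_u <= 0) stop("sigma_u must be positive")
  comp <- graph_components(graph)
  deg <- lengths(graph$nb)
  if (any(deg == 0 & abs(u) > 1e-9)) {
    stop("isolated node(s) must have structured effect 0")
  }
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) >= 2 && abs(sum(u[idx])) > 1e-6) {
      stop("u must sum to zero within each connected component")
    }
  }
  rank <- n - max(comp)
  ss <- 0
  if (nrow(graph$edges) > 0) {
    di <- u[graph$edges[, 1]] - u[graph$edges[, 2]]
    ss <- sum(di^2)
  }
  -ss / (2 * sigma_u^2) + (rank / 2) * log(1 / sigma_u^2)
}

#' Prior specification for the random-effect scales
#'
#' Two families: `uniform_sd` puts independent Uniform(0, upper) priors
#' on the standard deviations sigma_u and sigma_v (default upper 5);
#' `gamma_precision` puts Gamma(shape, rate) priors on the precisions
#' tau = 1/sigma^2 (default shape = rate = 0.01), the conventional
#' sensitivity-analysis alternative. Intercept and coefficients get flat
#' (improper) priors, or Normal(0, `normal_sd`^2) when `normal_sd` is
#' finite.
#'
#' @param family `"uniform_sd"` or `"gamma_precision"`.
#' @param upper Upper bound for the uniform family.
#' @param shape,rate Gamma parameters (rate parameterization).
#' @param normal_sd SD of the optional normal prior on alpha and beta;
#'   `Inf` (default) means flat.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("uniform_sd", "gamma_precision"),
                       upper = 5, shape = 0.01, rate = 0.01,
                       normal_sd = Inf) {
  family <- match.arg(family)
  stopifnot(upper > 0, shape > 0, rate > 0, normal_sd > 0)
  structure(list(family = family, upper = upper, shape = shape,
                 rate = rate, normal_sd = normal_sd),
            class = "prior_spec")
}

#' A point in BYM parameter space
#'
#' @param alpha Intercept (log scale).
#' @param beta Coefficient vector (log rate ratio per 1 SD).
#' @param u Structured (ICAR) effects.
#' @param v Unstructured effects.
#' @param sigma_u,sigma_v Nonnegative scales.
#' @return Object of class `bym_state`.
#' @export
bym_state <- function(alpha = 0, beta = numeric(0), u, v,
                      sigma_u = 0.5, sigma_v = 0.5) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  structure(list(alpha = alpha, beta = beta, u = u, v = v,
                 sigma_u = sigma_u, sigma_v = sigma_v),
            class = "bym_state")
}

#' Log prior density of a BYM state
#'
#' Under `uniform_sd`, each sigma contributes 0 inside (0, upper) and
#' `-Inf` outside. Under `gamma_precision`, each precision tau = 1/sigma^2
#' contributes the Gamma(shape, rate) log-density evaluated at tau.
#' Alpha and beta contribute 0 (flat) unless the prior has finite
#' `normal_sd`.
#'
#' @param state A [bym_state()].
#' @param prior A [prior_spec()].
#' @return Log prior (scalar; may be `-Inf`).
#' @export
log_prior <- function(state, prior) {
  stopifnot(inherits(state, "bym_state"), inherits(prior, "prior_spec"))
  lp <- 0
  for (s in c(state$sigma_u, state$sigma_v)) {
    if (prior$family == "uniform_sd") {
      if (s <= 0 || s >= prior$upper) return(-Inf)
    } else {
      if (s <= 0) return(-Inf)
      tau <- 1 / s^2
      lp <- lp + dgamma(tau, shape = prior$shape, rate = prior$rate,
                        log = TRUE)
    }
  }
  if (is.finite(prior$normal_sd)) {
    lp <- lp + sum(stats::dnorm(c(state$alpha, state$beta),
                                sd = prior$normal_sd, log = TRUE))
  }
  lp
}

#' BYM model specification
#'
#' Names the outcome method, the covariates entering the linear
#' predictor (empty for the covariate-free smoothing model), the prior
#' family and the covariate-transform options.
#'
#' @param method Method label (a column of the area frame's counts).
#' @param covariates Character vector of covariate names (may be empty).
#' @param prior A [prior_spec()].
#' @param skew_threshold Passed to [transform_covariates()].
#' @param binary Passed to [transform_covariates()].
#' @param include_u,include_v Logical; drop a random-effect term (used by
#'   degenerate-model diagnostics and validation fits).
#' @return Object of class `bym_model_spec`.
#' @export
bym_model_spec <- function(method, covariates = character(0),
                           prior = prior_spec("uniform_sd"),
                           skew_threshold = 1,
                           binary = c("zscore", "raw"),
                           include_u = TRUE, include_v = TRUE) {
  binary <- match.arg(binary)
  structure(list(method = method, covariates = covariates, prior = prior,
                 skew_threshold = skew_threshold, binary = binary,
                 include_u = include_u, include_v = include_v),
            class = "bym_model_spec")
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec A [bym_model_spec()].
#' @param path File path.
#' @return `path` (write) or a `bym_model_spec` (read).
#' @export
write_model_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "bym_model_spec"))
  x <- unclass(spec)
  x$prior <- unclass(x$prior)
  x$prior$normal_sd <- if (is.finite(x$prior$normal_sd)) {
    x$prior$normal_sd
  } else "Inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec_json
#' @export
read_model_spec_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  nsd <- if (identical(x$prior$normal_sd, "Inf")) Inf else x$prior$normal_sd
  bym_model_spec(
    method = x$method,
    covariates = as.character(x$covariates %||% character(0)),
    prior = prior_spec(x$prior$family, upper = x$prior$upper,
                       shape = x$prior$shape, rate = x$prior$rate,
                       normal_sd = nsd),
    skew_threshold = x$skew_threshold, binary = x$binary,
    include_u = x$include_u, include_v = x$include_v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
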