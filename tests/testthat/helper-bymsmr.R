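# Shared fixtures and independent oracles.

# unit-square lattice geometry, row r / col c -> square at (c-1, r-1)
grid_geometry <- function(rows, cols) {
  areas <- list()
  k <- 0
  for (cc in seq_len(cols)) {
    for (r in seq_len(rows)) {
      k <- k + 1
      x0 <- cc - 1; y0 <- r - 1
      areas[[sprintf("A%03d", k)]] <-
        matrix(c(x0, y0, x0 + 1, y0, x0 + 1, y0 + 1, x0, y0 + 1),
               ncol = 2, byrow = TRUE)
    }
  }
  geometry_set(areas)
}

# small synthetic study for fast end-to-end tests
small_config <- function(seed, rows = 6, cols = 6, ...) {
  args <- list(
    n_areas = rows * cols, grid_rows = rows, grid_cols = cols,
    methods = c("hanging", "charcoal_burning"),
    method_totals = c(hanging = 300, charcoal_burning = 280),
    river_fraction = 0.25, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

fast_sampler <- function(seed, n_iter = 4000, burn_in = 2000, thin = 2) {
  sampler_config(n_chains = 2, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed)
}

# all connected labeled graphs on n nodes, as adjacency_graph objects
connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    g <- adjacency_from_edges(as.character(seq_len(n)),
                              pairs[sel, , drop = FALSE])
    if (max(graph_components(g)) == 1) out[[length(out) + 1]] <- g
  }
  out
}

# eigen-decomposition oracle for the ICAR log-density on the
# sum-to-zero subspace (independent of the pairwise-difference route)
icar_oracle <- function(u, graph, sigma_u) {
  n <- length(graph$ids)
  Q <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    Q[i, j] <- Q[i, j] - 1; Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1; Q[j, j] <- Q[j, j] + 1
  }
  eig <- eigen(Q, symmetric = TRUE)
  pos <- eig$values > 1e-9 * max(1, max(eig$values))
  y <- t(eig$vectors[, pos, drop = FALSE]) %*% u
  rank <- sum(pos)
  -sum(eig$values[pos] * y^2) / (2 * sigma_u^2) +
    (rank / 2) * log(1 / sigma_u^2)
}

# a vector of length 20 whose type-7 5th/95th percentiles are exactly
# (p5, p95): duplicated extremes pin the interpolated quantiles
vector_with_percentiles <- function(p5, p95, mid = (p5 + p95) / 2) {
  sort(c(p5, p5, seq(p5, p95, length.out = 16), p95, p95))
}

# quadrature oracle for the single-area Poisson posterior with a flat
# prior on alpha: p(alpha) propto exp(O * alpha - E * exp(alpha))
alpha_posterior_cdf <- function(O, E, grid_n = 20001) {
  mode <- log(O / E)
  half <- 8 / sqrt(max(O, 1))
  g <- seq(mode - half, mode + half, length.out = grid_n)
  lp <- O * g - E * exp(g)
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  function(x) approx(g, cdf, xout = x, yleft = 0, yright = 1)$y
}

ks_distance <- function(draws, cdf_fun) {
  x <- sort(draws)
  n <- length(x)
  Fx <- cdf_fun(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# minimal hand-built bym_fit carrying given scalar/theta draws
fake_fit <- function(beta_draws_by_chain = NULL, theta_by_chain = NULL,
                     covariate = "x") {
  chains <- lapply(seq_along(beta_draws_by_chain %||% theta_by_chain),
                   function(ch) {
    nb <- beta_draws_by_chain[[ch]]
    th <- theta_by_chain[[ch]]
    ndraw <- if (!is.null(nb)) length(nb) else nrow(th)
    sc <- cbind(alpha = rep(0, ndraw),
                beta = if (!is.null(nb)) nb else NULL,
                sigma_u = rep(0.3, ndraw), sigma_v = rep(0.2, ndraw))
    if (!is.null(nb)) colnames(sc)[2] <- paste0("beta_", covariate)
    list(scalars = sc,
         theta = if (!is.null(th)) th else
           matrix(1, ndraw, 2, dimnames = list(NULL, c("A1", "A2"))))
  })
  model <- bym_model_spec(
    "hanging",
    covariates = if (!is.null(beta_draws_by_chain)) covariate
                 else character(0))
  structure(list(chains = chains, model = model,
                 sampler = sampler_config(seed = 1),
                 areas = colnames(chains[[1]]$theta),
                 rhat = c(alpha = 1),
                 n_retained = sum(vapply(chains,
                                         function(c) nrow(c$scalars), 1))),
            class = "bym_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
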