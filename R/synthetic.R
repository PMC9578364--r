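# Synthetic study generator: a lattice of neighborhoods with
# age-structured populations, skewed covariates, a river corridor, and
# method-specific death counts with known BYM structure.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the structure of an urban small-area suicide study:
#' 432 neighborhoods on an 18 x 24 unit-square lattice, a right-skewed
#' population distribution with median population (aged 10+) near 5,050,
#' five method groups with 7-year death totals matching the reported
#' method mix, a river corridor covering 96/432 (22.2%) of areas, and
#' BYM ground truth with structured scale 0.3, unstructured scale 0.2,
#' and one true accessibility effect: rate ratio 1.15 per 1 SD of the
#' single-person-household covariate on charcoal-burning deaths.
#'
#' @param n_areas Number of areas.
#' @param grid_rows,grid_cols Lattice dimensions; product must be >=
#'   `n_areas`.
#' @param age_bands Ordered 5-year band labels from "10-14" upward.
#' @param median_population Target median area population aged 10+.
#' @param pop_log_sd Log-scale SD of the area population distribution
#'   (log-normal); the default spans roughly 840-31,300 between the 5th
#'   and 95th percentiles relative to the median.
#' @param methods Method labels.
#' @param method_totals Expected region-wide death totals per method
#'   over the aggregation period.
#' @param true_alpha Per-method intercept on the log scale.
#' @param true_beta Per-method, per-covariate true coefficients (log
#'   rate ratio per 1 SD on the analysis scale): a named list of named
#'   numeric vectors, `true_beta[[method]][covariate]`.
#' @param true_sigma_u,true_sigma_v Nonnegative SDs of the structured /
#'   unstructured effects.
#' @param river_fraction Proportion of areas flagged river-adjacent.
#' @param age_rate_slope Log-linear slope of the reference age-specific
#'   rate schedule per 5-year band.
#' @param years Length of the aggregation period (metadata).
#' @param seed Integer seed (mandatory).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_areas = 432, grid_rows = 18, grid_cols = 24,
    age_bands = default_age_bands(),
    median_population = 5050, pop_log_sd = 1.10,
    methods = method_levels(),
    method_totals = c(hanging = 892, charcoal_burning = 859,
                      jumping = 566, drowning = 275, other = 402),
    true_alpha = setNames(rep(0, length(methods)), methods),
    true_beta = list(charcoal_burning = c(single_person_pct = log(1.15))),
    true_sigma_u = 0.3, true_sigma_v = 0.2,
    river_fraction = 96 / 432,
    age_rate_slope = 0.12, years = 7, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_areas < 1) stop("n_areas must be positive")
  if (grid_rows * grid_cols < n_areas) {
    stop("grid_rows * grid_cols must be >= n_areas")
  }
  if (median_population <= 0) stop("median_population must be positive")
  if (river_fraction < 0 || river_fraction > 1) {
    stop("river_fraction must be in [0, 1]")
  }
  if (true_sigma_u < 0 || true_sigma_v < 0) {
    stop("true sigmas must be nonnegative")
  }
  true_beta_is_default <- missing(true_beta)
  methods <- as.character(methods)
  method_totals <- unlist(method_totals)
  true_alpha <- unlist(true_alpha)
  true_beta <- lapply(true_beta, unlist)
  if (!all(names(method_totals) %in% methods)) {
    stop("method_totals names must be a subset of methods")
  }
  method_totals <- method_totals[intersect(names(method_totals), methods)]
  if (!setequal(names(method_totals), methods)) {
    stop("method_totals must cover every method")
  }
  covs <- .synthetic_covariate_names()
  if (true_beta_is_default) {
    true_beta <- true_beta[intersect(names(true_beta), methods)]
  }
  for (m in names(true_beta)) {
    if (!m %in% methods) stop("true_beta names a method not simulated: ", m)
    bad <- setdiff(names(true_beta[[m]]), covs)
    if (length(bad) > 0) {
      stop("true_beta references covariate(s) not in the covariate set: ",
           paste(bad, collapse = ", "))
    }
  }
  ta <- setNames(rep(0, length(methods)), methods)
  ta[names(true_alpha)[names(true_alpha) %in% methods]] <-
    true_alpha[names(true_alpha) %in% methods]
  structure(list(n_areas = as.integer(n_areas),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 age_bands = age_bands,
                 median_population = median_population,
                 pop_log_sd = pop_log_sd,
                 methods = methods, method_totals = method_totals,
                 true_alpha = ta, true_beta = true_beta,
                 true_sigma_u = true_sigma_u,
                 true_sigma_v = true_sigma_v,
                 river_fraction = river_fraction,
                 age_rate_slope = age_rate_slope,
                 years = as.integer(years), seed = as.integer(seed)),
            class = "synthetic_config")
}

.synthetic_covariate_names <- function() {
  c("divorced_pct", "median_income", "single_person_pct",
    "high_floor_pct", "river")
}

# fixed age distribution shared by all areas (fractions over the bands)
.age_shares <- function(bands) {
  w <- c(5, 6, 7, 8, 8, 8, 8, 8, 7, 7, 6, 5, 4, 3, 2, 2)
  if (length(bands) != length(w)) {
    w <- rep(1, length(bands))  # uniform fallback for nonstandard bands
  }
  setNames(w / sum(w), bands)
}

# ICD-10 code pools per method, with sampling weights
.icd_pools <- function() {
  list(
    hanging = list(codes = c("X70", "Y20", "W75", "W76", "W83", "W84"),
                   probs = c(0.70, 0.10, 0.05, 0.05, 0.05, 0.05)),
    charcoal_burning = list(codes = c("X67", "Y17"), probs = c(0.85, 0.15)),
    drowning = list(codes = c("X71", "Y21"), probs = c(0.80, 0.20)),
    jumping = list(codes = c("X80", "Y30"), probs = c(0.85, 0.15)),
    other = list(codes = c("X60", "X64", "X68", "X78", "Y11", "Y25", "X48"),
                 probs = rep(1 / 7, 7)))
}

#' Exact draw from the intrinsic CAR prior
#'
#' Samples the ICAR distribution with scale `sigma_u` on the sum-to-zero
#' subspace by eigen-decomposing the ICAR precision `Q = D - W` and
#' scaling independent normals by `1/sqrt(lambda)` along the positive
#' eigenvectors; isolated nodes get 0 and each component is re-centered.
#'
#' @param graph An `adjacency_graph`.
#' @param sigma_u Nonnegative scale (0 returns the zero vector).
#' @param eig Optional precomputed `eigen()` of `Q` (reused across
#'   replicate simulations on the same geometry).
#' @return Numeric vector, one value per node, summing to zero per
#'   component.
#' @export
ricar <- function(graph, sigma_u, eig = NULL) {
  n <- length(graph$ids)
  if (sigma_u == 0) return(numeric(n))
  if (is.null(eig)) eig <- icar_precision_eigen(graph)
  pos <- eig$values > 1e-8 * max(eig$values, 1)
  z <- rnorm(sum(pos))
  u <- as.vector(eig$vectors[, pos, drop = FALSE] %*%
                   (z / sqrt(eig$values[pos]))) * sigma_u
  comp <- graph_components(graph)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) >= 2) u[idx] <- u[idx] - mean(u[idx])
    else u[idx] <- 0
  }
  u
}

#' Eigen-decomposition of the ICAR precision matrix
#'
#' @param graph An `adjacency_graph`.
#' @return `eigen()` result for `Q = D - W` (symmetric).
#' @export
icar_precision_eigen <- function(graph) {
  n <- length(graph$ids)
  Q <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      Q[i, j] <- Q[i, j] - 1
      Q[j, i] <- Q[j, i] - 1
      Q[i, i] <- Q[i, i] + 1
      Q[j, j] <- Q[j, j] + 1
    }
  }
  eigen(Q, symmetric = TRUE)
}

#' Rook adjacency of the generator's lattice
#'
#' Areas are laid out column-major on a `grid_rows` x `grid_cols`
#' lattice of unit squares; this builds the rook graph directly from
#' the lattice indices (identical to [build_adjacency()] on the
#' generated polygons, but O(n)).
#'
#' @param config A [synthetic_config()].
#' @return An `adjacency_graph`.
#' @export
lattice_adjacency <- function(config) {
  n <- config$n_areas
  nr <- config$grid_rows
  ids <- .area_ids(n)
  edges <- NULL
  for (k in seq_len(n)) {
    r <- (k - 1) %% nr + 1
    cc <- (k - 1) %/% nr + 1
    if (r < nr && k + 1 <= n) edges <- rbind(edges, c(k, k + 1))
    if (k + nr <= n) edges <- rbind(edges, c(k, k + nr))
    invisible(cc)
  }
  adjacency_from_edges(ids, edges)
}

.area_ids <- function(n) sprintf("A%03d", seq_len(n))

#' Simulate a complete synthetic study
#'
#' Generates lattice geometry, age-structured area populations,
#' covariates, BYM random effects and method-specific death counts
#' `O[i, m] ~ Poisson(E[i, m] * theta[i, m])` with
#' `theta[i, m] = exp(alpha_m + x_i' beta_m + u_i + v_i)`, where
#' `E[i, m]` follows a fixed log-linear reference schedule of
#' age-specific rates scaled so region totals match
#' `config$method_totals`. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `area_frame` (observed/expected counts via internal
#'   indirect standardization, plus covariates), `geoms` (a
#'   [geometry_set()] with a river polyline), `graph` (lattice rook
#'   adjacency), `records` (row-level death records incl. a few
#'   ineligible ones, for exercising classification/filtering), and
#'   `truth` (true theta, u, v, transformed covariates, generator
#'   expected counts).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_areas
  ids <- .area_ids(n)
  bands <- config$age_bands
  nb_bands <- length(bands)

  # --- geometry: unit squares, column-major fill ------------------------
  nr <- config$grid_rows
  areas <- vector("list", n)
  for (k in seq_len(n)) {
    r <- (k - 1) %% nr
    cc <- (k - 1) %/% nr
    x0 <- cc; y0 <- r
    areas[[k]] <- matrix(c(x0, y0, x0 + 1, y0, x0 + 1, y0 + 1, x0, y0 + 1,
                           x0, y0),
                         ncol = 2, byrow = TRUE)
  }
  names(areas) <- ids
  n_river <- round(config$river_fraction * n)
  # river corridor: a polyline through the first lattice column(s)
  rivers <- if (n_river > 0) {
    list(matrix(c(0.5, 0, 0.5, nr), ncol = 2, byrow = TRUE))
  } else list()
  geoms <- geometry_set(areas, rivers)
  graph <- lattice_adjacency(config)

  # --- populations ------------------------------------------------------
  pop_total <- rlnorm(n, meanlog = log(config$median_population),
                      sdlog = config$pop_log_sd)
  shares <- .age_shares(bands)
  population <- outer(pop_total, shares)
  dimnames(population) <- list(ids, bands)

  # --- covariates -------------------------------------------------------
  river_flag <- integer(n)
  if (n_river > 0) river_flag[seq_len(n_river)] <- 1L  # contiguous columns
  covariates <- data.frame(
    divorced_pct = rlnorm(n, log(5), 0.5),
    median_income = rnorm(n, 600, 100),
    single_person_pct = rlnorm(n, log(10), 0.6),
    high_floor_pct = rlnorm(n, log(30), 0.25),
    river = river_flag,
    row.names = ids)
  if (any(covariates$median_income <= 0)) {
    covariates$median_income <- pmax(covariates$median_income, 1)
  }

  # constant columns (e.g. river_fraction 0 or 1) carry no effect and
  # cannot be z-scored; they are excluded from the design used for truth
  varying <- vapply(covariates, function(x) length(unique(x)) > 1,
                    logical(1))
  for (m in names(config$true_beta)) {
    on_const <- names(config$true_beta[[m]])[config$true_beta[[m]] != 0 &
      !names(config$true_beta[[m]]) %in% names(covariates)[varying]]
    if (length(on_const) > 0) {
      stop("true_beta assigns a nonzero effect to a constant covariate: ",
           paste(on_const, collapse = ", "))
    }
  }
  cm <- transform_covariates(covariates[varying], skew_threshold = 1,
                             binary = "zscore")
  X <- cm$X

  # --- random effects and true relative risks --------------------------
  eig <- if (config$true_sigma_u > 0) icar_precision_eigen(graph) else NULL
  methods <- config$methods
  u <- sapply(methods, function(m) ricar(graph, config$true_sigma_u, eig))
  v <- sapply(methods, function(m) rnorm(n, 0, config$true_sigma_v))
  dimnames(u) <- dimnames(v) <- list(ids, methods)

  theta <- matrix(NA_real_, n, length(methods),
                  dimnames = list(ids, methods))
  for (m in methods) {
    xb <- numeric(n)
    if (!is.null(config$true_beta[[m]])) {
      b <- config$true_beta[[m]]
      b <- b[names(b) %in% colnames(X)]
      if (length(b) > 0) {
        xb <- as.vector(X[, names(b), drop = FALSE] %*% b)
      }
    }
    theta[, m] <- exp(config$true_alpha[m] + xb + u[, m] + v[, m])
  }

  # --- reference schedule and generator expected counts -----------------
  rate_shape <- exp(config$age_rate_slope * (seq_len(nb_bands) - 1))
  w_i <- as.vector(population %*% rate_shape)
  E_gen <- matrix(NA_real_, n, length(methods),
                  dimnames = list(ids, methods))
  for (m in methods) {
    E_gen[, m] <- config$method_totals[m] * w_i / sum(w_i)
  }

  # --- death counts and row-level records -------------------------------
  O <- matrix(rpois(n * length(methods), E_gen * theta), n,
              dimnames = list(ids, methods))
  pools <- .icd_pools()
  band_lo <- c(seq(10, 10 + 5 * (nb_bands - 2), by = 5),
               10 + 5 * (nb_bands - 1))
  recs <- list()
  for (m in methods) {
    pool <- pools[[m]]
    if (is.null(pool)) pool <- pools$other
    for (k in which(O[, m] > 0)) {
      cnt <- O[k, m]
      pr <- population[k, ] * rate_shape
      nb_by_band <- as.vector(rmultinom(1, cnt, pr))
      for (a in which(nb_by_band > 0)) {
        ages <- band_lo[a] + sample.int(5, nb_by_band[a], replace = TRUE) - 1L
        codes <- sample(pool$codes, nb_by_band[a], replace = TRUE,
                        prob = pool$probs)
        recs[[length(recs) + 1]] <- data.frame(
          area_id = ids[k], age = ages, icd10_code = codes, count = 1L)
      }
    }
  }
  records <- if (length(recs) > 0) do.call(rbind, recs) else {
    data.frame(area_id = character(), age = integer(),
               icd10_code = character(), count = integer())
  }
  # a few ineligible records (under-10 and non-suicide causes)
  n_noise <- min(20L, max(2L, n %/% 20L))
  noise <- data.frame(
    area_id = sample(ids, n_noise, replace = TRUE),
    age = sample(c(3:9, 40:70), n_noise, replace = TRUE),
    icd10_code = sample(c("A00", "I21", "C50", "X70", "J18"), n_noise,
                        replace = TRUE),
    count = 1L)
  noise <- noise[noise$age < 10 | !noise$icd10_code %in% "X70", ]
  records <- rbind(records, noise)

  area_frame <- make_area_frame(population, records, covariates,
                                methods = methods)

  truth <- list(theta = theta, u = u, v = v,
                covariates_raw = covariates, X = X,
                transforms = cm$transforms,
                E_gen = E_gen, config = config)

  list(area_frame = area_frame, geoms = geoms, graph = graph,
       records = records, truth = truth)
}

#' Write a simulated study to the pipeline's file formats
#'
#' Produces the same CSV/GeoJSON files the pipeline stages read:
#' `deaths.csv`, `population.csv`, `covariates.csv`, `areas.geojson`,
#' `rivers.geojson`, `truth.json` and `config.json`.
#'
#' @param sim Result of [simulate_study()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulated_study <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  af <- sim$area_frame
  paths <- c(deaths = file.path(out_dir, "deaths.csv"),
             population = file.path(out_dir, "population.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             areas = file.path(out_dir, "areas.geojson"),
             rivers = file.path(out_dir, "rivers.geojson"),
             truth = file.path(out_dir, "truth.json"),
             config = file.path(out_dir, "config.json"))
  write.csv(sim$records, paths["deaths"], row.names = FALSE)
  pop_long <- data.frame(
    area_id = rep(af$areas, times = length(af$age_bands)),
    age_band = rep(af$age_bands, each = length(af$areas)),
    person_years = as.vector(af$population))
  write.csv(pop_long, paths["population"], row.names = FALSE)
  cov <- data.frame(area_id = af$areas, af$covariates,
                    check.names = FALSE)
  write.csv(cov, paths["covariates"], row.names = FALSE)
  write_geojson(sim$geoms, paths["areas"], paths["rivers"])
  tr <- sim$truth
  jsonlite::write_json(
    list(true_alpha = as.list(tr$config$true_alpha),
         true_beta = tr$config$true_beta,
         true_sigma_u = tr$config$true_sigma_u,
         true_sigma_v = tr$config$true_sigma_v,
         transforms = as.list(tr$transforms),
         theta = as.data.frame(tr$theta),
         u = as.data.frame(tr$u), v = as.data.frame(tr$v)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  cfg <- unclass(tr$config)
  cfg$method_totals <- as.list(cfg$method_totals)
  cfg$true_alpha <- as.list(cfg$true_alpha)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
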