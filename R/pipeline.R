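# Pipeline stages over the file formats, with run manifests.
# Stages: simulate -> standardize -> adjacency -> fit -> summarize.

.file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
}

.write_manifest <- function(out_dir, stage, seed, config, inputs = character(0),
                            outputs = character(0), extra = list()) {
  man <- c(list(stage = stage,
                package_version = as.character(packageVersion("bymsmr")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                config = config,
                input_digests = .file_digests(inputs),
                output_digests = .file_digests(outputs)),
           extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.read_config_file <- function(config) {
  if (is.character(config)) {
    if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a list or a YAML/JSON file path")
  }
}

#' Pipeline stage: simulate a synthetic study to disk
#'
#' @param config A [synthetic_config()], a plain list of its arguments,
#'   or a YAML/JSON file path holding them. A seed is mandatory (either
#'   in the config or via `seed`).
#' @param out_dir Output directory.
#' @param seed Overrides the config seed when given.
#' @return Named vector of file paths, invisibly.
#' @export
pipeline_simulate <- function(config = list(), out_dir, seed = NULL) {
  if (!inherits(config, "synthetic_config")) {
    cfg <- .read_config_file(config)
    if (!is.null(seed)) cfg$seed <- seed
    if (is.null(cfg$seed)) stop("seed is mandatory")
    keep <- intersect(names(cfg), names(formals(synthetic_config)))
    config <- do.call(synthetic_config, cfg[keep])
  } else if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  sim <- simulate_study(config)
  paths <- write_simulated_study(sim, out_dir)
  .write_manifest(out_dir, "simulate", config$seed,
                  config = list(n_areas = config$n_areas,
                                methods = config$methods,
                                river_fraction = config$river_fraction),
                  outputs = paths)
  invisible(paths)
}

#' Pipeline stage: standardization
#'
#' Reads `deaths.csv`, `population.csv` and `covariates.csv` from
#' `data_dir`, classifies and filters records, computes expected counts
#' by internal indirect standardization, and writes `area_frame.csv`.
#'
#' @param data_dir Directory with the input CSVs.
#' @param out_dir Output directory (default `data_dir`).
#' @return Path of the area-frame CSV, invisibly.
#' @export
pipeline_standardize <- function(data_dir, out_dir = data_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  deaths_path <- file.path(data_dir, "deaths.csv")
  pop_path <- file.path(data_dir, "population.csv")
  cov_path <- file.path(data_dir, "covariates.csv")
  records <- read_deaths_csv(deaths_path)
  population <- read_population_csv(pop_path)
  covariates <- if (file.exists(cov_path)) read_covariates_csv(cov_path)
                else NULL
  af <- make_area_frame(population, records, covariates)
  out <- file.path(out_dir, "area_frame.csv")
  write_area_frame_csv(af, out)
  .write_manifest(out_dir, "standardize", seed = NULL, config = NULL,
                  inputs = c(deaths_path, pop_path, cov_path),
                  outputs = out)
  invisible(out)
}

#' Pipeline stage: adjacency and river indicators
#'
#' Reads `areas.geojson` (and `rivers.geojson` when present), builds the
#' contiguity graph and the river-accessibility variables, and writes
#' `adjacency.csv` plus `spatial.csv` (river flag and centroid-to-river
#' distance).
#'
#' @param data_dir Directory with the GeoJSON inputs.
#' @param out_dir Output directory (default `data_dir`).
#' @param contiguity `"rook"` or `"queen"`.
#' @return Paths written, invisibly.
#' @export
pipeline_adjacency <- function(data_dir, out_dir = data_dir,
                               contiguity = "rook") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  areas_path <- file.path(data_dir, "areas.geojson")
  rivers_path <- file.path(data_dir, "rivers.geojson")
  has_rivers <- file.exists(rivers_path)
  geoms <- read_geojson(areas_path, if (has_rivers) rivers_path else NULL)
  graph <- build_adjacency(geoms, contiguity = contiguity)
  adj_out <- file.path(out_dir, "adjacency.csv")
  write_adjacency_csv(graph, adj_out)
  outs <- adj_out
  if (has_rivers) {
    sp <- data.frame(area_id = names(geoms$areas),
                     river_flag = unname(river_adjacent(geoms)),
                     river_distance = unname(centroid_river_distance(geoms)))
    sp_out <- file.path(out_dir, "spatial.csv")
    write.csv(sp, sp_out, row.names = FALSE)
    outs <- c(outs, sp_out)
  }
  .write_manifest(out_dir, "adjacency", seed = NULL,
                  config = list(contiguity = contiguity),
                  inputs = c(areas_path, rivers_path), outputs = outs)
  invisible(outs)
}

#' Pipeline stage: fit the model set
#'
#' Reads `area_frame.csv` and `adjacency.csv`, optionally swaps the
#' binary river covariate for the centroid-to-river distance from
#' `spatial.csv`, runs [run_model_set()] and writes `results.csv`,
#' `table1.csv`, `smoothed_smr.csv` and a manifest.
#'
#' @param data_dir Directory with standardize/adjacency outputs.
#' @param out_dir Output directory (default `data_dir`).
#' @param prior `"uniform_sd"` or `"gamma_precision"` (the
#'   sensitivity-analysis alternative).
#' @param river_covariate `"binary"` (the flag) or `"distance"`
#'   (centroid-to-river distance, the sensitivity variable).
#' @param methods Methods to fit (default overall + all groups).
#' @param n_chains,n_iter,burn_in,thin,seed Sampler settings.
#' @param verbose Progress messages.
#' @return The `model_set_results`, invisibly, with attribute
#'   `exit_status` (0 = all converged, 3 = some R-hat failures).
#' @export
pipeline_fit <- function(data_dir, out_dir = data_dir,
                         prior = c("uniform_sd", "gamma_precision"),
                         river_covariate = c("binary", "distance"),
                         methods = NULL,
                         n_chains = 2, n_iter = 20000, burn_in = 10000,
                         thin = 5, seed = 1, verbose = FALSE) {
  prior <- match.arg(prior)
  river_covariate <- match.arg(river_covariate)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  af_path <- file.path(data_dir, "area_frame.csv")
  adj_path <- file.path(data_dir, "adjacency.csv")
  if (!file.exists(af_path)) stop("missing ", af_path,
                                  "; run the standardize stage first")
  if (!file.exists(adj_path)) stop("missing ", adj_path,
                                   "; run the adjacency stage first")
  af <- read_area_frame_csv(af_path)
  graph <- read_adjacency_csv(adj_path, ids = af$areas)

  river_name <- "river"
  if (river_covariate == "distance") {
    sp_path <- file.path(data_dir, "spatial.csv")
    if (!file.exists(sp_path)) {
      stop("river_covariate='distance' needs spatial.csv from the ",
           "adjacency stage")
    }
    sp <- read.csv(sp_path, colClasses = c(area_id = "character"))
    af$covariates$river_distance <-
      sp$river_distance[match(af$areas, sp$area_id)]
    river_name <- "river_distance"
  }
  accessibility <- c("single_person_pct", "high_floor_pct", river_name)

  if (is.null(methods)) {
    methods <- c("overall", af$methods[colSums(af$observed) > 0])
  }
  sampler <- sampler_config(n_chains = n_chains, n_iter = n_iter,
                            burn_in = burn_in, thin = thin, seed = seed)
  res <- run_model_set(af, graph, methods = methods,
                       accessibility = accessibility,
                       sampler = sampler,
                       prior = prior_spec(prior), verbose = verbose)
  outs <- write_results_csv(res, out_dir)
  exit_status <- if (all(res$results$converged)) 0L else 3L
  .write_manifest(out_dir, "fit", seed = seed,
                  config = list(prior = prior,
                                river_covariate = river_covariate,
                                n_chains = n_chains, n_iter = n_iter,
                                burn_in = burn_in, thin = thin),
                  inputs = c(af_path, adj_path), outputs = outs,
                  extra = list(
                    exit_status = exit_status,
                    rhat_max = max(res$results$rhat_max),
                    n_nonconverged = sum(!res$results$converged)))
  attr(res, "exit_status") <- exit_status
  invisible(res)
}

#' Pipeline stage: summarize fitted results
#'
#' Reads `results.csv` and `table1.csv` and prints the model-set tables;
#' returns them invisibly.
#'
#' @param data_dir Directory with fit outputs.
#' @return List with `results` and `table1` data frames.
#' @export
pipeline_summarize <- function(data_dir) {
  res <- read.csv(file.path(data_dir, "results.csv"))
  t1 <- read.csv(file.path(data_dir, "table1.csv"))
  cat("Smoothed-SMR distribution summaries:\n")
  print(t1, digits = 3)
  cat("\nRate ratios (per 1 SD):\n")
  print(res, digits = 3)
  invisible(list(results = res, table1 = t1))
}
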