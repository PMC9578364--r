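# Method classification, indirect age standardization and raw SMRs.

#' Suicide method groups
#'
#' The five method groups used throughout the package, in reporting order.
#'
#' @return Character vector of method labels.
#' @export
method_levels <- function() {
  c("hanging", "charcoal_burning", "jumping", "drowning", "other")
}

#' Default 5-year age bands from 10-14 upward
#'
#' Sixteen 5-year bands covering ages 10 and above, with an open-ended
#' top band at 85+.
#'
#' @return Character vector of band labels.
#' @export
default_age_bands <- function() {
  lo <- seq(10, 80, by = 5)
  c(paste0(lo, "-", lo + 4), "85+")
}

#' Map an age in years to a 5-year age band
#'
#' @param age Integer vector of ages (years), all >= 10.
#' @param bands Band labels as produced by [default_age_bands()].
#' @return Character vector of band labels.
#' @export
age_to_band <- function(age, bands = default_age_bands()) {
  if (any(age < 10)) stop("ages below 10 are outside the study population")
  idx <- pmin(floor((age - 10) / 5) + 1, length(bands))
  bands[idx]
}

#' Classify an ICD-10 cause-of-death code into a suicide method group
#'
#' Certified suicides (X60-X84), deaths of undetermined intent (Y10-Y34),
#' suffocation injuries (W75, W76, W83, W84) and pesticide-poisoning
#' injuries (X48) are treated as suicides and assigned to a method group:
#' charcoal burning (X67, Y17), hanging (X70, Y20, W75, W76, W83, W84),
#' drowning (X71, Y21), jumping (X80, Y30); every other code within those
#' ranges falls into `"other"`. Codes outside the ranges return
#' `"not_suicide"`. A decimal subdivision suffix (e.g. `"X70.1"`) is
#' ignored.
#'
#' @param icd10_code Character vector of ICD-10 codes (letter + 2 digits).
#' @return Character vector with values in `method_levels()` or
#'   `"not_suicide"`.
#' @examples
#' classify_method(c("X67", "W83", "X48", "A00"))
#' @export
classify_method <- function(icd10_code) {
  code <- toupper(trimws(as.character(icd10_code)))
  code <- sub("\\..*$", "", code)
  bad <- !grepl("^[A-Z][0-9]{2}$", code)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(icd10_code[bad]), collapse = ", "))
  }
  letter <- substr(code, 1, 1)
  num <- as.integer(substr(code, 2, 3))

  out <- rep("not_suicide", length(code))
  sui <- letter == "X" & num >= 60 & num <= 84
  und <- letter == "Y" & num >= 10 & num <= 34
  out[sui | und | (letter == "X" & num == 48)] <- "other"
  out[code %in% c("X67", "Y17")] <- "charcoal_burning"
  out[code %in% c("X70", "Y20", "W75", "W76", "W83", "W84")] <- "hanging"
  out[code %in% c("X71", "Y21")] <- "drowning"
  out[code %in% c("X80", "Y30")] <- "jumping"
  out
}

#' Restrict death records to the eligible study population
#'
#' Keeps records aged 10 years and above whose ICD-10 code maps to a
#' suicide method group, and attaches the `method` column.
#'
#' @param records Data frame with columns `area_id`, `age`, `icd10_code`
#'   and optionally `count` (defaults to 1 per row).
#' @return The filtered data frame with an added `method` column.
#' @export
filter_eligible <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("area_id", "age", "icd10_code") %in% names(records)))
  if (nrow(records) == 0) {
    records$method <- character(0)
    return(records)
  }
  if (is.null(records$count)) records$count <- 1L
  records$method <- classify_method(records$icd10_code)
  records[records$age >= 10 & records$method != "not_suicide", , drop = FALSE]
}

#' Expected counts by internal indirect age standardization
#'
#' For each area i and method m, `E[i, m] = sum_a n[i, a] * D[a, m] / N[a]`
#' where `n[i, a]` are area person-periods by age band, `N[a]` their
#' region-wide band totals, and `D[a, m]` the region-wide deaths in band a
#' by method m. The standard population is the study region itself over
#' the aggregated period, so per method `sum_i E[i, m] = sum_i O[i, m]`.
#'
#' @param population Numeric matrix, areas x age bands (person-periods),
#'   with rownames = area ids and colnames = band labels.
#' @param deaths Long-format data frame with columns `area_id`,
#'   `age_band`, `method`, `count`.
#' @param methods Methods to standardize; defaults to those present.
#' @return Numeric matrix of expected counts, areas x methods.
#' @export
expected_counts <- function(population, deaths,
                            methods = sort(unique(deaths$method))) {
  stopifnot(is.matrix(population), !is.null(rownames(population)),
            !is.null(colnames(population)))
  if (any(population < 0)) stop("negative person-periods in population")
  stopifnot(all(c("area_id", "age_band", "method", "count") %in% names(deaths)))
  unknown_band <- setdiff(unique(deaths$age_band), colnames(population))
  if (length(unknown_band) > 0) {
    stop("age band(s) absent from population table: ",
         paste(unknown_band, collapse = ", "))
  }
  unknown_area <- setdiff(unique(deaths$area_id), rownames(population))
  if (length(unknown_area) > 0) {
    stop("area id(s) absent from population table: ",
         paste(unknown_area, collapse = ", "))
  }

  bands <- colnames(population)
  N_a <- colSums(population)
  E <- matrix(0, nrow(population), length(methods),
              dimnames = list(rownames(population), methods))
  for (m in methods) {
    dm <- deaths[deaths$method == m, , drop = FALSE]
    D_a <- setNames(numeric(length(bands)), bands)
    if (nrow(dm) > 0) {
      tot <- tapply(dm$count, factor(dm$age_band, levels = bands), sum)
      tot[is.na(tot)] <- 0
      D_a[] <- tot
    }
    if (any(D_a > 0 & N_a == 0)) {
      stop("deaths recorded in an age band with zero population (method ",
           m, ")")
    }
    rate_a <- ifelse(N_a > 0, D_a / N_a, 0)
    E[, m] <- population %*% rate_a
  }
  E
}

#' Raw standardized mortality ratio
#'
#' @param O Observed count(s), nonnegative.
#' @param E Expected count(s), strictly positive.
#' @return `O / E`.
#' @export
raw_smr <- function(O, E) {
  if (any(E <= 0)) stop("expected counts must be positive")
  if (any(O < 0)) stop("observed counts must be nonnegative")
  O / E
}

#' Assemble the per-area analysis table
#'
#' Aggregates eligible death records over the study period, computes
#' observed and (internally standardized) expected counts per area and
#' method, and attaches area covariates. This is the single table all
#' model fitting consumes.
#'
#' @param population Areas x age-bands matrix of person-periods.
#' @param records Death records (see [filter_eligible()]); already
#'   filtered or raw (filtering is applied either way).
#' @param covariates Data frame of per-area covariates with an `area_id`
#'   column, or rownames matching the population rownames.
#' @param methods Method groups to tabulate (default [method_levels()]).
#' @return An object of class `area_frame`: list with elements `areas`,
#'   `methods`, `age_bands`, `observed` (areas x methods), `expected`
#'   (same shape), `population`, `covariates`.
#' @export
make_area_frame <- function(population, records, covariates = NULL,
                            methods = method_levels()) {
  records <- filter_eligible(records)
  areas <- rownames(population)
  if (anyDuplicated(areas)) stop("duplicate area ids in population table")

  if (nrow(records) > 0) {
    records$age_band <- age_to_band(records$age, colnames(population))
    deaths <- aggregate(count ~ area_id + age_band + method, records, sum)
  } else {
    deaths <- data.frame(area_id = character(), age_band = character(),
                         method = character(), count = numeric())
  }

  O <- matrix(0L, length(areas), length(methods),
              dimnames = list(areas, methods))
  if (nrow(deaths) > 0) {
    keep <- deaths$method %in% methods
    tab <- tapply(deaths$count[keep],
                  list(factor(deaths$area_id[keep], levels = areas),
                       factor(deaths$method[keep], levels = methods)),
                  sum)
    tab[is.na(tab)] <- 0
    O[] <- tab
  }
  present <- methods[colSums(O) > 0]
  E <- matrix(NA_real_, length(areas), length(methods),
              dimnames = list(areas, methods))
  if (length(present) > 0) {
    E[, present] <- expected_counts(population, deaths, methods = present)
  }

  if (!is.null(covariates)) {
    if ("area_id" %in% names(covariates)) {
      rownames(covariates) <- covariates$area_id
      covariates$area_id <- NULL
    }
    missing_cov <- setdiff(areas, rownames(covariates))
    if (length(missing_cov) > 0) {
      stop("covariates missing for area(s): ",
           paste(utils::head(missing_cov, 5), collapse = ", "))
    }
    covariates <- covariates[areas, , drop = FALSE]
  }

  structure(list(areas = areas, methods = methods,
                 age_bands = colnames(population),
                 observed = O, expected = E,
                 population = population, covariates = covariates),
            class = "area_frame")
}

#' @export
print.area_frame <- function(x, ...) {
  cat("<area_frame> ", length(x$areas), " areas, ",
      length(x$age_bands), " age bands\n", sep = "")
  tot <- colSums(x$observed)
  cat("observed deaths by method:\n")
  print(tot)
  invisible(x)
}

# ---- CSV interfaces ---------------------------------------------------

#' Read death records from CSV
#'
#' Expects columns `area_id`, `age`, `icd10_code` and optionally `count`.
#' @param path CSV file path.
#' @return Data frame of records.
#' @export
read_deaths_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(area_id = "character"))
  need <- c("area_id", "age", "icd10_code")
  if (!all(need %in% names(df))) {
    stop("deaths file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  df
}

#' Read the area population table from CSV
#'
#' Long format with columns `area_id`, `age_band`, `person_years`.
#' @param path CSV file path.
#' @param bands Band ordering for the columns of the returned matrix.
#' @return Areas x bands numeric matrix.
#' @export
read_population_csv <- function(path, bands = default_age_bands()) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(area_id = "character"))
  need <- c("area_id", "age_band", "person_years")
  if (!all(need %in% names(df))) {
    stop("population file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  areas <- sort(unique(df$area_id))
  mat <- tapply(df$person_years,
                list(factor(df$area_id, levels = areas),
                     factor(df$age_band, levels = bands)), sum)
  mat[is.na(mat)] <- 0
  matrix(mat, nrow = length(areas), dimnames = list(areas, bands))
}

#' Read per-area covariates from CSV
#'
#' @param path CSV with an `area_id` column; all other columns are
#'   covariates.
#' @return Data frame with rownames = area ids.
#' @export
read_covariates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(area_id = "character"))
  if (!"area_id" %in% names(df)) stop("covariates file needs area_id column")
  rownames(df) <- df$area_id
  df$area_id <- NULL
  df
}

#' Write / read an `area_frame` as a flat CSV
#'
#' The flat form has one row per area: observed and expected counts per
#' method (`O_<method>`, `E_<method>`), population by band
#' (`pop_<band>`), and covariate columns.
#'
#' @param af An `area_frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_frame_csv <- function(af, path) {
  stopifnot(inherits(af, "area_frame"))
  df <- data.frame(area_id = af$areas, stringsAsFactors = FALSE)
  for (m in af$methods) df[[paste0("O_", m)]] <- af$observed[, m]
  for (m in af$methods) df[[paste0("E_", m)]] <- af$expected[, m]
  for (b in af$age_bands) df[[paste0("pop_", b)]] <- af$population[, b]
  if (!is.null(af$covariates)) df <- cbind(df, af$covariates)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_frame_csv
#' @param path CSV produced by [write_area_frame_csv()].
#' @export
read_area_frame_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = c(area_id = "character"))
  areas <- df$area_id
  o_cols <- grep("^O_", names(df), value = TRUE)
  methods <- sub("^O_", "", o_cols)
  pop_cols <- grep("^pop_", names(df), value = TRUE)
  bands <- sub("^pop_", "", pop_cols)
  O <- as.matrix(df[o_cols]); dimnames(O) <- list(areas, methods)
  E <- as.matrix(df[paste0("E_", methods)]); dimnames(E) <- list(areas, methods)
  P <- as.matrix(df[pop_cols]); dimnames(P) <- list(areas, bands)
  cov_cols <- setdiff(names(df),
                      c("area_id", o_cols, paste0("E_", methods), pop_cols))
  covs <- if (length(cov_cols) > 0) {
    cv <- df[cov_cols]; rownames(cv) <- areas; cv
  } else NULL
  structure(list(areas = areas, methods = methods, age_bands = bands,
                 observed = O, expected = E, population = P,
                 covariates = covs),
            class = "area_frame")
}
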