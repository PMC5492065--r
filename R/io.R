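# File formats and validation.
#
# Encounter histories travel as plain CSV, one row per individual x survey
# occasion, with categories from the fixed vocabulary NS, E, L1-L5, P,
# D1-D5.  Temperature covariates, posterior draws, rankings, and
# diagnostics use CSV/JSON; run configuration uses YAML.

ENCOUNTER_COLUMNS <- c("individual_id", "plot_id", "plant_id", "occasion",
                       "day", "category", "length_mm")
FILE_CATEGORY_LABELS <- names(FILE_CATEGORY_INDEX)

#' Validate an encounter-history table
#'
#' Checks column layout, category vocabulary, uniqueness of
#' `(individual_id, occasion)`, that every detected individual is first
#' seen in a live category, and that nothing follows a corpse recovery but
#' "not seen" (dead recovery is terminal).  Row numbers are reported with
#' every violation.
#'
#' @param enc a data frame with columns `individual_id`, `plot_id`,
#'   `plant_id`, `occasion` (1-based), `day` (integer day index from season
#'   start), `category`, `length_mm` (NA when no length was taken).
#' @return The validated data frame (invisibly coerced types), ordered by
#'   individual and occasion.
#' @export
as_encounter_data <- function(enc) {
  stopifnot(is.data.frame(enc))
  missing_cols <- setdiff(ENCOUNTER_COLUMNS, names(enc))
  if (length(missing_cols))
    stop("encounter table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  enc <- as.data.frame(enc)[ENCOUNTER_COLUMNS]
  enc$category <- as.character(enc$category)
  enc$occasion <- as.integer(enc$occasion)

  bad <- which(!enc$category %in% FILE_CATEGORY_LABELS)
  if (length(bad))
    stop("unknown category '", enc$category[bad[1]], "' at row ",
         bad[1], if (length(bad) > 1) paste0(" (and ", length(bad) - 1,
                                             " more rows)"))
  if (any(enc$occasion < 1L, na.rm = TRUE) || anyNA(enc$occasion))
    stop("occasion must be a positive integer")
  dup <- which(duplicated(enc[, c("individual_id", "occasion")]))
  if (length(dup))
    stop("duplicate (individual_id, occasion) at row ", dup[1])

  enc <- enc[order(enc$individual_id, enc$occasion), ]
  idx <- category_index(enc$category)
  for (id in unique(enc$individual_id[idx != 1L])) {
    rows <- which(enc$individual_id == id)
    y <- idx[rows]
    det <- which(y != 1L)
    if (!length(det)) next
    if (y[det[1]] > 8L)
      stop("individual ", id, " first appears as a corpse (row ",
           rows[det[1]], "); individuals must enter the study alive")
    dead <- which(y >= 10L)
    if (length(dead) && any(y[seq_along(y) > dead[1]] != 1L))
      stop("individual ", id, " is recorded after its corpse was found ",
           "(row ", rows[dead[1]], "); dead recovery is terminal")
  }
  enc
}

#' Read an encounter-history CSV file
#'
#' @param path CSV file with the columns described in
#'   [as_encounter_data()].
#' @return Validated encounter-history data frame.
#' @export
read_encounter_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as_encounter_data(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an encounter-history CSV file
#'
#' @param enc encounter-history data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_encounter_file <- function(enc, path) {
  enc <- as_encounter_data(enc)
  write.csv(enc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a plot-by-occasion temperature covariate table
#'
#' CSV with columns `plot_id`, `occasion`, `mean_temp` (3-day mean air
#' temperature in the units of the source series; standardization makes
#' the model unit-free).
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_temperature_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "occasion", "mean_temp")
  if (!all(need %in% names(tt)))
    stop("temperature table needs columns ", paste(need, collapse = ", "))
  tt[need]
}

#' @rdname read_temperature_file
#' @param tt temperature table to write.
#' @export
write_temperature_file <- function(tt, path) {
  write.csv(tt[, c("plot_id", "occasion", "mean_temp")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an hourly temperature series
#'
#' CSV with columns `timestamp` (integer hour since season start) and
#' `temp`; returned with the column names (`hour`, `temp`) the covariate
#' builders use.
#'
#' @param path CSV path.
#' @return Data frame `hour`, `temp`.
#' @export
read_hourly_temperature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp") %in% names(h)))
    stop("hourly series needs columns timestamp, temp")
  data.frame(hour = as.integer(h$timestamp), temp = h$temp)
}

RUN_CONFIG_KEYS <- c("seed", "structure", "grid", "priors", "mcmc",
                     "paths", "density_metric", "death_partition")

#' Read and validate a YAML run configuration
#'
#' Recognized top-level keys: `seed`, `structure` (survival_form,
#' survival_grouping, growth_form), `grid` (option lists for
#' [model_grid()]), `priors` (`coef_sd`, `hatch`, `pupation`), `mcmc`
#' (`chains`, `burn_in`, `samples`), `paths`, `density_metric`,
#' `death_partition`.  Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

# small polynomial rolling hash over the serialized object, for run
# provenance (not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write posterior draws as tidy CSV
#'
#' Long format: one row per (chain, iteration, parameter) with the sampled
#' value, plus rows for the per-draw deviance under parameter name
#' `"deviance"`.
#'
#' @param fit a fitted model from [fit_hmm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "instar_hmm"))
  dr <- fit$draws
  n_iter <- dim(dr)[1]; n_par <- dim(dr)[2]; n_chain <- dim(dr)[3]
  long <- data.frame(
    chain = rep(seq_len(n_chain), each = n_iter * n_par),
    iteration = rep(rep(seq_len(n_iter), each = n_par), n_chain),
    parameter = rep(dimnames(dr)[[2]], n_iter * n_chain),
    value = as.vector(aperm(dr, c(2, 1, 3)))
  )
  dev <- data.frame(
    chain = rep(seq_len(n_chain), each = n_iter),
    iteration = rep(seq_len(n_iter), n_chain),
    parameter = "deviance",
    value = as.vector(fit$deviance)
  )
  write.csv(rbind(long, dev), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a convergence-diagnostics report as JSON
#'
#' Records per-parameter and multivariate Gelman-Rubin statistics,
#' multivariate effective sample size, per-block acceptance rates, seed,
#' configuration hash, and package version.
#'
#' @param fit a fitted model from [fit_hmm()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
diagnostics_report <- function(fit, path) {
  stopifnot(inherits(fit, "instar_hmm"))
  gr <- gelman_rubin(fit$draws)
  mess <- tryCatch(multivariate_ess(fit$draws), error = function(e) NA_real_)
  report <- list(
    psrf = as.list(gr$psrf),
    multivariate_psrf = gr$mpsrf,
    multivariate_ess = mess,
    acceptance_rates = as.list(fit$acceptance),
    seed = fit$settings$seed,
    config_hash = config_hash(list(structure = unclass(fit$structure),
                                   settings = fit$settings)),
    package_version = as.character(packageVersion("instarhmm"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a model-selection ranking table as CSV
#'
#' @param ranking the ranking data frame from [rank_models()] or
#'   [select_models()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.csv(as.data.frame(ranking), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
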