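#' Read a daily series CSV
#'
#' Expects columns `date` (ISO-8601) and `value`.
#'
#' @param path CSV path.
#' @param kind `"temperature"` or `"discharge"`.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path, kind = c("temperature", "discharge")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("date", "value"), path)
  daily_series(df$date, df$value, kind)
}

#' @rdname read_daily_series
#' @param series a [daily_series()] to write.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(data.frame(date = series$date, value = series$value),
                   path, row.names = FALSE)
  invisible(path)
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("'", path, "' is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read individual length records
#'
#' Validates the schema and rejects rows for age-classes above 6 (ages 6+
#' and 7+ are excluded from growth estimation) with a warning naming the
#' rows.
#'
#' @param path CSV with columns `year`, `site`, `age_class`,
#'   `fork_length_mm`, `recapture`.
#' @return validated length-record data.frame.
#' @export
read_lengths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("year", "site", "age_class", "fork_length_mm",
                  "recapture"), path)
  old <- df$age_class > 6
  if (any(old)) {
    warning(sum(old), " record(s) with age_class > 6 rejected at ingestion")
    df <- df[!old, , drop = FALSE]
  }
  length_records(df)
}

#' @rdname read_lengths
#' @param records length records to write.
#' @export
write_lengths <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read depletion catches
#'
#' @param path CSV with columns `year`, `site`, `class`, `pass`, `count`
#'   (optionally `species`).
#' @return validated data.frame.
#' @export
read_catches <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("year", "site", "class", "pass", "count"), path)
  bad <- which(df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("'", path, "' has non-integer or negative counts at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df
}

#' @rdname read_catches
#' @param catches catches to write.
#' @export
write_catches <- function(catches, path) {
  utils::write.csv(catches, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a covariate table CSV
#'
#' Columns `year`, `site`, `stage`, `variable`, `raw_value` and, when
#' standardised, `std_value`, `mu`, `sigma`. Round-trip stable.
#'
#' @param path CSV path.
#' @return a `covariate_table`.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("year", "site", "stage", "variable", "raw_value"), path)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' @rdname read_covariate_table
#' @param table covariate table to write.
#' @export
write_covariate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws in long format
#'
#' One row per (chain, iteration, parameter).
#'
#' @param result a `posterior_result`.
#' @param path CSV path.
#' @export
write_draws <- function(result, path) {
  stopifnot(inherits(result, "posterior_result"))
  long <- do.call(rbind, lapply(seq_along(result$draws), function(ch) {
    d <- result$draws[[ch]]
    data.frame(chain = ch, iter = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Reads a YAML configuration and fills defaults mirroring the production
#' analysis settings: 3 chains; growth model 30,000 iterations / 20,000
#' burn-in / thin 100; abundance model 30,000 / 10,000 / 100; saturated
#' stage variable sets; collinearity threshold 0.7 with the
#' high-temperature-day count in the drop list. The master seed has no
#' default: stochastic commands refuse to run without one.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides named list merged over the file values.
#' @return list of class `run_config` (with the raw YAML text kept for the
#'   log digest).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  raw <- ""
  if (!is.null(path)) {
    raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
    user <- yaml::yaml.load(raw)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg$digest <- config_digest(raw)
  class(cfg) <- "run_config"
  cfg
}

default_run_config <- function() {
  list(
    seed = NULL,
    paths = list(),
    stage_sets = stage_variable_sets(),
    collinearity = list(r_threshold = 0.7, drop = "highT_days"),
    flags = list(literal_equation = FALSE, drop_recaptures = FALSE,
                 batch_removal = FALSE),
    growth_mcmc = list(chains = 3L, iterations = 30000L, burn_in = 20000L,
                       thin = 100L),
    abundance_mcmc = list(chains = 3L, iterations = 30000L,
                          burn_in = 10000L, thin = 100L),
    synthetic = list(n_lengths = 5600L))
}

# order-sensitive polynomial rolling digest of the config text
config_digest <- function(text) {
  h <- 17
  for (b in utf8ToInt(text)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

mcmc_from_config <- function(block, seed) {
  mcmc_settings(chains = block$chains, iterations = block$iterations,
                burn_in = block$burn_in, thin = block$thin, seed = seed)
}

write_log <- function(dir, command, cfg) {
  lines <- c(
    paste0("command: ", command),
    paste0("time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("config_digest: ", cfg$digest),
    paste0("seed: ", if (is.null(cfg$seed)) "none" else cfg$seed),
    paste0("package: stagegrowth ",
           as.character(utils::packageVersion("stagegrowth"))),
    paste0("R: ", R.version.string))
  writeLines(lines, file.path(dir, paste0(command, ".log")))
}
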