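#' Command-line pipeline driver
#'
#' Dispatches the pipeline commands (`simulate`, `covariates`, `abundance`,
#' `fit`, `simplify`, `loo`, `report`) against a YAML run configuration.
#' Every command writes its artifacts into `--out` together with a log
#' recording the config digest, seed and package/R versions. Intended to be
#' called from a thin Rscript wrapper (see
#' `system.file("scripts", "stagegrowth-pipeline.R", package =
#' "stagegrowth")`); returns an exit status instead of quitting so it can be
#' driven programmatically.
#'
#' @param args character vector: `command [--config path] [--out dir]`.
#' @param quiet suppress progress messages.
#' @return integer exit status (0 on success; invisible).
#' @export
pipeline_cli <- function(args = character(), quiet = FALSE) {
  usage <- paste(
    "usage: stagegrowth-pipeline <command> [--config cfg.yaml] [--out dir]",
    "commands: simulate covariates abundance fit simplify loo report",
    sep = "\n")
  say <- function(...) if (!quiet) message(...)
  commands <- c("simulate", "covariates", "abundance", "fit", "simplify",
                "loo", "report")
  if (length(args) == 0L || !(args[1L] %in% commands)) {
    message(usage)
    return(invisible(1L))
  }
  command <- args[1L]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  out <- opt("--out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- opt("--config", NULL)
  status <- tryCatch({
    cfg <- read_run_config(cfg_path)
    if (is.null(cfg$seed))
      stop("config must set a master seed (`seed:`) for command '",
           command, "'")
    switch(command,
           simulate = cmd_simulate(cfg, out),
           covariates = cmd_covariates(cfg, out),
           abundance = cmd_abundance(cfg, out),
           fit = cmd_fit(cfg, out),
           simplify = cmd_simplify(cfg, out),
           loo = cmd_loo(cfg, out),
           report = cmd_report(cfg, out))
    write_log(out, command, cfg)
    say("[", command, "] artifacts written to ", normalizePath(out))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cmd_simulate <- function(cfg, out) {
  truth <- synthetic_truth(n_lengths = cfg$synthetic$n_lengths)
  study <- generate_study(truth, seed = cfg$seed)
  write_lengths(study$records, file.path(out, "lengths.csv"))
  write_catches(study$abundance$catches$grayling,
                file.path(out, "catches_grayling.csv"))
  write_catches(study$abundance$catches$trout,
                file.path(out, "catches_trout.csv"))
  write_covariate_table(study$covariates, file.path(out, "covariates.csv"))
  write_daily_series(study$environment$temperature,
                     file.path(out, "temperature.csv"))
  write_daily_series(study$environment$discharge,
                     file.path(out, "discharge.csv"))
  utils::write.csv(study$environment$habitat,
                   file.path(out, "habitat.csv"), row.names = FALSE)
  truth_txt <- paste(deparse(study$truth), collapse = "")
  jsonlite::write_json(
    list(seed = cfg$seed, truth_digest = config_digest(truth_txt),
         growth = study$truth$growth[c("Linf", "K", "t0", "sigma")]),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

cmd_abundance <- function(cfg, out) {
  path <- cfg$paths$catches %||% file.path(out, "catches_grayling.csv")
  catches <- read_catches(path)
  species <- cfg$species %||% "grayling"
  fit <- fit_abundance(catches, groups = default_capture_groups(species),
                       settings = mcmc_from_config(cfg$abundance_mcmc,
                                                   cfg$seed))
  utils::write.csv(fit$estimates,
                   file.path(out, paste0("abundance_", species, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(fit$p_summary,
                       file.path(out, paste0("capture_p_", species,
                                             ".json")),
                       digits = NA)
  invisible(fit)
}

cmd_covariates <- function(cfg, out) {
  p <- cfg$paths
  temperature <- read_daily_series(p$temperature %||%
                                     file.path(out, "temperature.csv"),
                                   "temperature")
  discharge <- read_daily_series(p$discharge %||%
                                   file.path(out, "discharge.csv"),
                                 "discharge")
  habitat <- utils::read.csv(p$habitat %||% file.path(out, "habitat.csv"))
  abund <- utils::read.csv(p$abundance_covariates %||%
                             file.path(out, "abundance_covariates.csv"))
  annual <- annual_covariates(temperature, discharge, habitat,
                              years = sort(unique(habitat$year)))
  tab <- assemble_covariates(annual, abund, stage_sets = cfg$stage_sets,
                             sites = sort(unique(abund$site)))
  tab <- z_standardise(tab)
  rep <- collinearity_screen(tab, r_threshold = cfg$collinearity$r_threshold,
                             drop = cfg$collinearity$drop)
  write_covariate_table(rep$table, file.path(out, "covariates.csv"))
  jsonlite::write_json(list(flagged = rep$flagged, dropped = rep$dropped),
                       file.path(out, "collinearity.json"), digits = NA)
  invisible(rep)
}

growth_fit_from_config <- function(cfg, out, stage_sets = NULL,
                                   seed = cfg$seed) {
  records <- read_lengths(cfg$paths$lengths %||%
                            file.path(out, "lengths.csv"))
  covariates <- read_covariate_table(cfg$paths$covariates %||%
                                       file.path(out, "covariates.csv"))
  sets <- stage_sets %||% lapply(cfg$stage_sets, function(v)
    intersect(v, unique(covariates$variable)))
  fit_growth(records, covariates, stage_sets = sets,
             settings = mcmc_from_config(cfg$growth_mcmc, seed),
             literal = isTRUE(cfg$flags$literal_equation),
             drop_recaptures = isTRUE(cfg$flags$drop_recaptures))
}

cmd_fit <- function(cfg, out) {
  fit <- growth_fit_from_config(cfg, out)
  write_draws(fit, file.path(out, "growth_draws.csv"))
  utils::write.csv(fit$summary, file.path(out, "growth_summary.csv"),
                   row.names = FALSE)
  if (!fit$converged)
    warning("growth fit not converged (R-hat >= 1.1); see growth_summary.csv")
  invisible(fit)
}

cmd_simplify <- function(cfg, out) {
  covariates <- read_covariate_table(cfg$paths$covariates %||%
                                       file.path(out, "covariates.csv"))
  sets <- lapply(cfg$stage_sets, function(v)
    intersect(v, unique(covariates$variable)))
  fit_fun <- function(stage_sets, fit_index)
    growth_fit_from_config(cfg, out, stage_sets = stage_sets,
                           seed = cfg$seed + 1000L * fit_index)
  full <- staged_simplification(model_spec(sets), fit_fun,
                                batch = isTRUE(cfg$flags$batch_removal),
                                on_nonconvergence = "warn")
  cands <- candidate_full_models(full)
  specs <- c(list(full = full), cands)
  loos <- lapply(seq_along(specs), function(i) {
    f <- if (i == 1L) attr(full, "fit") else
      fit_fun(specs[[i]]$stages, 100L + i)
    psis_loo(f$loglik)
  })
  names(loos) <- names(specs)
  sel <- select_model(loos, specs)
  jsonlite::write_json(
    list(chosen = sel$chosen, comparison = sel$table,
         stages = sel$spec$stages, lineage = full$lineage),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)
  invisible(sel)
}

cmd_loo <- function(cfg, out) {
  fit <- growth_fit_from_config(cfg, out)
  loo <- psis_loo(fit$loglik)
  utils::write.csv(cbind(obs = seq_len(loo$n), loo$pointwise),
                   file.path(out, "loo.csv"), row.names = FALSE)
  jsonlite::write_json(list(elpd = loo$elpd, se = loo$se,
                            looic = loo$looic, n_high_k = loo$n_high_k),
                       file.path(out, "loo.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(loo)
}

cmd_report <- function(cfg, out) {
  fit <- growth_fit_from_config(cfg, out)
  if (!fit$converged) {
    msg <- paste0("WARNING: MCMC not converged (max R-hat = ",
                  format(max(fit$rhat, na.rm = TRUE), digits = 4),
                  "); interpret the report with caution")
    message(msg)
    writeLines(msg, file.path(out, "CONVERGENCE_WARNING.txt"))
  }
  els <- expected_length_series(fit)
  utils::write.csv(els$expected, file.path(out, "expected_length.csv"),
                   row.names = FALSE)
  utils::write.csv(els$trend, file.path(out, "year_trend.csv"),
                   row.names = FALSE)
  coefs <- do.call(rbind, lapply(1:3, function(l) {
    tab <- stage_coef_table(fit, l)
    if (is.null(tab)) return(NULL)
    cbind(stage = l, tab)
  }))
  utils::write.csv(coefs, file.path(out, "coefficients.csv"),
                   row.names = FALSE)
  marg <- list()
  for (l in 1:3) for (v in fit$vars[[l]]) {
    sc <- fit$scales[fit$scales$variable == v, ]
    grid <- seq(sc$mu[1L] - 2 * sc$sigma[1L], sc$mu[1L] + 2 * sc$sigma[1L],
                length.out = 25L)
    m <- marginal_effect(fit, v, l, grid)
    marg[[length(marg) + 1L]] <- cbind(stage = l, variable = v, m)
  }
  utils::write.csv(do.call(rbind, marg),
                   file.path(out, "marginal_effects.csv"),
                   row.names = FALSE)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
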