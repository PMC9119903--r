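#' Daily environmental series
#'
#' Validated container for a daily air-temperature or mean-discharge series.
#' Dates must be strictly increasing with no duplicates; gaps are allowed but
#' recorded in the `"gaps"` attribute. Discharge values must be non-negative.
#'
#' @param date `Date` vector (coerced with `as.Date`).
#' @param value daily value: air temperature (deg C) or mean discharge
#'   (m^3 s^-1).
#' @param kind `"temperature"` or `"discharge"`.
#' @return data.frame of class `daily_series` with columns `date`, `value`.
#' @export
daily_series <- function(date, value, kind = c("temperature", "discharge")) {
  kind <- match.arg(kind)
  date <- as.Date(date)
  stopifnot(length(date) == length(value), !anyNA(date))
  if (is.unsorted(date, strictly = TRUE))
    stop("dates must be strictly increasing with no duplicates")
  if (kind == "discharge" && any(value < 0, na.rm = TRUE))
    stop("discharge values must be >= 0")
  n_gap <- as.integer(max(date) - min(date)) + 1L - length(date)
  out <- data.frame(date = date, value = as.numeric(value))
  class(out) <- c("daily_series", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "gaps") <- n_gap
  out
}

#' Seasonal date window for a growth year
#'
#' The main growing period (`spring_autumn`) of year `y` is the closed
#' interval 1 April to 30 September of `y`; the `autumn_winter` period
#' preceding sampling in year `y` runs 1 October of `y - 1` to 31 March of
#' `y`. Leap days are included when present.
#'
#' @param year calendar year the window is attributed to.
#' @param window `"spring_autumn"` or `"autumn_winter"`.
#' @return length-2 `Date` vector (start, end).
#' @export
season_window <- function(year, window = c("spring_autumn", "autumn_winter")) {
  window <- match.arg(window)
  if (window == "spring_autumn")
    c(as.Date(sprintf("%d-04-01", year)), as.Date(sprintf("%d-09-30", year)))
  else
    c(as.Date(sprintf("%d-10-01", year - 1L)),
      as.Date(sprintf("%d-03-31", year)))
}

window_values <- function(series, year, window, max_missing = 0.1) {
  w <- season_window(year, window)
  v <- series$value[series$date >= w[1L] & series$date <= w[2L]]
  if (length(v) == 0L)
    stop("no observations in ", window, " window of year ", year)
  n_days <- as.integer(w[2L] - w[1L]) + 1L
  frac_missing <- 1 - length(v) / n_days
  if (frac_missing > max_missing)
    warning(sprintf("%.0f%% of days missing in %s window of year %d",
                    100 * frac_missing, window, year))
  v
}

#' Mean of a daily series over a seasonal window
#'
#' @inheritParams season_window
#' @param series a [daily_series()].
#' @param max_missing missing-day fraction above which a warning is issued.
#' @return arithmetic mean of the daily values within the closed window.
#' @export
window_mean <- function(series, year,
                        window = c("spring_autumn", "autumn_winter"),
                        max_missing = 0.1) {
  window <- match.arg(window)
  mean(window_values(series, year, window, max_missing))
}

#' Count days exceeding a temperature threshold
#'
#' Number of spring--autumn days (1 April to 30 September) on which the daily
#' value strictly exceeds `threshold`; the default 20 deg C air temperature
#' corresponds to water temperatures known to depress grayling growth in
#' groundwater-fed chalk streams.
#'
#' @inheritParams window_mean
#' @param threshold exceedance threshold (strict inequality).
#' @return integer day count.
#' @export
count_days_above <- function(series, threshold = 20, year,
                             max_missing = 0.1) {
  stopifnot(is.finite(threshold))
  v <- window_values(series, year, "spring_autumn", max_missing)
  sum(v > threshold)
}

#' Flow-duration percentile thresholds (Q90 and Q10)
#'
#' Computes the discharge values defining low- and high-flow days over a
#' reference period: `q90` is the 10th percentile of all daily discharges
#' (the flow exceeded 90% of the time) and `q10` the 90th percentile.
#' Empirical quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param series a discharge [daily_series()].
#' @param years reference period (calendar years) over which the percentiles
#'   are taken; defaults to all years present.
#' @return list with `q90` and `q10` (m^3 s^-1), `q90 <= q10`.
#' @export
flow_thresholds <- function(series, years = NULL) {
  v <- series$value
  if (!is.null(years)) {
    yr <- as.integer(format(series$date, "%Y"))
    v <- v[yr %in% years]
  }
  if (length(v) == 0L) stop("no daily values in the reference period")
  if (length(v) < 100L)
    stop("need at least 100 daily values to estimate flow percentiles")
  q <- stats::quantile(v, probs = c(0.1, 0.9), names = FALSE)
  if (q[1L] == q[2L])
    warning("constant discharge series: Q90 and Q10 coincide")
  list(q90 = q[1L], q10 = q[2L])
}

#' Count low- or high-flow days in the growing season
#'
#' Spring--autumn days on which mean daily discharge is at or below (`low`)
#' or at or above (`high`) the given flow-duration threshold; comparisons are
#' inclusive.
#'
#' @inheritParams window_mean
#' @param threshold discharge threshold, typically `q90` (low) or `q10`
#'   (high) from [flow_thresholds()].
#' @param direction `"low"` or `"high"`.
#' @return integer day count.
#' @export
count_flow_days <- function(series, year, threshold,
                            direction = c("low", "high"), max_missing = 0.1) {
  direction <- match.arg(direction)
  v <- window_values(series, year, "spring_autumn", max_missing)
  if (direction == "low") sum(v <= threshold) else sum(v >= threshold)
}

#' Impute missing days from a donor gauging series
#'
#' Pre-processing join: dates absent from `series` but present in `donor`
#' (within the span of interest) are filled with the donor's values, mirroring
#' the use of a nearby gauging station to complete a discharge record.
#'
#' @param series primary [daily_series()].
#' @param donor donor [daily_series()] of the same kind.
#' @return a completed [daily_series()].
#' @export
impute_from_donor <- function(series, donor) {
  stopifnot(inherits(series, "daily_series"), inherits(donor, "daily_series"))
  add <- donor[!(donor$date %in% series$date), , drop = FALSE]
  merged <- rbind(as.data.frame(series), as.data.frame(add))
  merged <- merged[order(merged$date), , drop = FALSE]
  daily_series(merged$date, merged$value, kind = attr(series, "kind"))
}

# ---- stage variable sets -------------------------------------------------

#' Default stage-specific explanatory-variable sets
#'
#' The saturated sets of covariates allowed to act on each life stage:
#' juveniles (age 0+, stage 1), sub-adults (age 1+, stage 2) and adults (ages
#' 2+ to 5+, stage 3). Temperature and discharge summaries are year-level;
#' conspecific and heterospecific abundances vary by year and site.
#'
#' @return named list of character vectors (`stage1`, `stage2`, `stage3`).
#' @export
stage_variable_sets <- function() {
  list(
    stage1 = c("meanT_SA", "highT_days", "lowflow_days", "highflow_days",
               "macrophyte", "invert_biomass", "gray_juv", "trout_small"),
    stage2 = c("meanT_SA", "meanT_AW", "lowflow_days", "highflow_days",
               "macrophyte", "invert_biomass", "gray_subadult", "trout_large"),
    stage3 = c("meanT_SA", "meanT_AW", "lowflow_days", "invert_biomass",
               "gray_adult", "trout_large")
  )
}

year_level_variables <- function() {
  c("meanT_SA", "meanT_AW", "highT_days", "lowflow_days", "highflow_days",
    "macrophyte", "invert_biomass")
}

#' Derive annual raw covariates from daily series and habitat data
#'
#' Computes, for every study year, the year-level explanatory variables:
#' mean spring--autumn and autumn--winter air temperature, days above the
#' high-temperature threshold, low- and high-flow day counts against the
#' Q90/Q10 flow-duration thresholds of the full reference period, and the
#' annual macrophyte cover and macroinvertebrate biomass index supplied in
#' `habitat`.
#'
#' @param temperature air-temperature [daily_series()].
#' @param discharge mean daily discharge [daily_series()].
#' @param habitat data.frame with columns `year`, `macrophyte_pct`,
#'   `invert_biomass`.
#' @param years study years.
#' @param temp_threshold high-temperature threshold (deg C, strict).
#' @param flow_years reference period for [flow_thresholds()]; defaults to
#'   `years`.
#' @param max_missing per-window missing-day warning limit.
#' @return data.frame (one row per year) with the year-level variables.
#' @export
annual_covariates <- function(temperature, discharge, habitat, years,
                              temp_threshold = 20, flow_years = years,
                              max_missing = 0.1) {
  stopifnot(all(c("year", "macrophyte_pct", "invert_biomass") %in%
                  names(habitat)))
  if (any(habitat$macrophyte_pct < 0 | habitat$macrophyte_pct > 100))
    stop("macrophyte cover must be a percentage in [0, 100]")
  miss <- setdiff(years, habitat$year)
  if (length(miss))
    stop("habitat table is missing years: ", paste(miss, collapse = ", "))
  th <- flow_thresholds(discharge, years = flow_years)
  out <- data.frame(year = years)
  out$meanT_SA <- vapply(years, function(y)
    window_mean(temperature, y, "spring_autumn", max_missing), 0)
  out$meanT_AW <- vapply(years, function(y)
    window_mean(temperature, y, "autumn_winter", max_missing), 0)
  out$highT_days <- vapply(years, function(y)
    count_days_above(temperature, temp_threshold, y, max_missing), 0L)
  out$lowflow_days <- vapply(years, function(y)
    count_flow_days(discharge, y, th$q90, "low", max_missing), 0L)
  out$highflow_days <- vapply(years, function(y)
    count_flow_days(discharge, y, th$q10, "high", max_missing), 0L)
  i <- match(years, habitat$year)
  out$macrophyte <- habitat$macrophyte_pct[i]
  out$invert_biomass <- habitat$invert_biomass[i]
  attr(out, "flow_thresholds") <- th
  out
}

# ---- covariate table -----------------------------------------------------

#' Assemble the stage-specific covariate table
#'
#' Expands annual year-level variables across sites, joins the year- and
#' site-specific abundance covariates, and restricts each life stage to its
#' allowed variable set. The result is the long design table consumed by the
#' growth model (one row per year x site x stage x variable).
#'
#' @param annual data.frame from [annual_covariates()] (wide, one row per
#'   year).
#' @param abund_long data.frame with columns `year`, `site`, `variable`,
#'   `value` holding the abundance covariates (see
#'   [abundance_covariates()]).
#' @param stage_sets named list as from [stage_variable_sets()].
#' @param sites site identifiers (default 1:6).
#' @return data.frame of class `covariate_table` with columns `year`, `site`,
#'   `stage`, `variable`, `raw_value`.
#' @export
assemble_covariates <- function(annual, abund_long,
                                stage_sets = stage_variable_sets(),
                                sites = 1:6) {
  years <- sort(unique(annual$year))
  ann_vars <- setdiff(names(annual), "year")
  rows <- list()
  for (l in 1:3) {
    vars <- stage_sets[[paste0("stage", l)]]
    for (v in vars) {
      if (v %in% ann_vars) {
        g <- expand.grid(year = years, site = sites, KEEP.OUT.ATTRS = FALSE)
        g$stage <- l
        g$variable <- v
        g$raw_value <- annual[[v]][match(g$year, annual$year)]
        rows[[length(rows) + 1L]] <- g
      } else {
        sel <- abund_long[abund_long$variable == v, , drop = FALSE]
        need <- expand.grid(year = years, site = sites,
                            KEEP.OUT.ATTRS = FALSE)
        key_need <- paste(need$year, need$site)
        key_have <- paste(sel$year, sel$site)
        gaps <- setdiff(key_need, key_have)
        if (length(gaps))
          stop("missing year x site combinations for variable '", v, "': ",
               paste(utils::head(gaps, 10L), collapse = "; "))
        i <- match(key_need, key_have)
        g <- data.frame(year = need$year, site = need$site, stage = l,
                        variable = v, raw_value = sel$value[i])
        rows[[length(rows) + 1L]] <- g
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$stage, out$variable, out$year, out$site), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out$raw_value)) {
    bad <- out[is.na(out$raw_value), c("year", "variable")]
    stop("missing year x variable combinations: ",
         paste(unique(paste(bad$year, bad$variable)), collapse = "; "))
  }
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' z-standardise a covariate table
#'
#' Centres and scales each explanatory variable to mean 0 and (sample)
#' standard deviation 1 over that variable's full year x site support, so
#' that coefficient estimates are comparable across variables measured on
#' different scales. The per-variable mean and sd are stored alongside each
#' row for back-transformation of marginal-effect axes.
#'
#' @param table a `covariate_table` from [assemble_covariates()].
#' @return the table with added columns `std_value`, `mu`, `sigma`.
#' @export
z_standardise <- function(table) {
  stopifnot(all(c("year", "site", "stage", "variable", "raw_value") %in%
                  names(table)))
  table$std_value <- NA_real_
  table$mu <- NA_real_
  table$sigma <- NA_real_
  for (v in unique(table$variable)) {
    i <- table$variable == v
    # one value per (year, site); stages replicate, so scale on the support
    sub <- table[i, c("year", "site", "raw_value")]
    sup <- sub[!duplicated(paste(sub$year, sub$site)), , drop = FALSE]
    m <- mean(sup$raw_value)
    s <- stats::sd(sup$raw_value)
    if (!is.finite(s) || s == 0)
      stop("zero variance: variable '", v, "' cannot be standardised")
    table$std_value[i] <- (table$raw_value[i] - m) / s
    table$mu[i] <- m
    table$sigma[i] <- s
  }
  class(table) <- c("covariate_table", "data.frame")
  table
}

#' Pearson collinearity screen with configured resolution
#'
#' Computes pairwise Pearson correlations between the explanatory variables
#' within each life stage (over each variable's year x site support) and
#' flags pairs with `|r| >= r_threshold`. Flagged pairs must be resolved by
#' the configured drop list; an unresolved pair is an error because the
#' choice of which variable to keep is an ecological judgement, not a rule.
#' The default drop list removes the high-temperature-day count in favour of
#' mean spring--autumn temperature, the more fundamental influence on growth.
#'
#' @param table a standardised `covariate_table`.
#' @param r_threshold absolute correlation at or above which a pair is
#'   flagged (default 0.7).
#' @param drop character vector of variables to remove if flagged.
#' @param require_resolution error on a flagged pair neither member of which
#'   is in `drop` (default TRUE).
#' @return list of class `collinearity_report`: `flagged` (stage, var1, var2,
#'   r), `dropped` (variable, kept_instead), `table` (the screened table).
#' @export
collinearity_screen <- function(table, r_threshold = 0.7,
                                drop = "highT_days",
                                require_resolution = TRUE) {
  val_col <- if ("std_value" %in% names(table)) "std_value" else "raw_value"
  flagged <- list()
  for (l in sort(unique(table$stage))) {
    sub <- table[table$stage == l, , drop = FALSE]
    vars <- sort(unique(sub$variable))
    if (length(vars) < 2L) next
    wide <- sapply(vars, function(v) {
      s <- sub[sub$variable == v, , drop = FALSE]
      s <- s[order(s$year, s$site), , drop = FALSE]
      s[[val_col]]
    })
    r <- stats::cor(wide)
    for (i in seq_along(vars)[-length(vars)]) for (j in (i + 1L):length(vars))
      if (abs(r[i, j]) >= r_threshold)
        flagged[[length(flagged) + 1L]] <-
          data.frame(stage = l, var1 = vars[i], var2 = vars[j],
                     r = r[i, j])
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(stage = integer(), var1 = character(), var2 = character(),
               r = numeric())
  dropped <- data.frame(variable = character(), kept_instead = character())
  for (k in seq_len(nrow(flagged))) {
    v1 <- flagged$var1[k]; v2 <- flagged$var2[k]
    if (v1 %in% drop) {
      dropped <- rbind(dropped, data.frame(variable = v1, kept_instead = v2))
    } else if (v2 %in% drop) {
      dropped <- rbind(dropped, data.frame(variable = v2, kept_instead = v1))
    } else if (require_resolution) {
      stop("collinear pair |r| >= ", r_threshold, " between '", v1,
           "' and '", v2, "' (stage ", flagged$stage[k], ", r = ",
           format(flagged$r[k], digits = 3),
           ") has no configured resolution; add one of them to `drop`")
    }
  }
  dropped <- dropped[!duplicated(dropped$variable), , drop = FALSE]
  out_tab <- table[!(table$variable %in% dropped$variable), , drop = FALSE]
  class(out_tab) <- class(table)
  structure(list(flagged = flagged, dropped = dropped,
                 r_threshold = r_threshold, table = out_tab),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity screen (|r| >= ", x$r_threshold, "): ",
      nrow(x$flagged), " flagged pair(s), ", nrow(x$dropped),
      " variable(s) dropped\n", sep = "")
  if (nrow(x$flagged)) print(x$flagged, row.names = FALSE)
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Extract the stage design matrices from a covariate table
#'
#' Internal helper shared by the growth model and the simulator: returns, per
#' stage, a year x site x variable array of standardised values plus the
#' variable names, in a fixed deterministic order.
#'
#' @param table standardised `covariate_table`.
#' @param stage_sets optional named list restricting each stage to a variable
#'   subset (e.g. a simplified model); defaults to all variables present.
#' @return list with per-stage arrays `X[[l]]` (year x site x variable) and
#'   `vars[[l]]`.
#' @keywords internal
stage_design <- function(table, stage_sets = NULL) {
  stopifnot("std_value" %in% names(table))
  years <- sort(unique(table$year))
  sites <- sort(unique(table$site))
  X <- vector("list", 3L); vars <- vector("list", 3L)
  for (l in 1:3) {
    sub <- table[table$stage == l, , drop = FALSE]
    vs <- sort(unique(sub$variable))
    if (!is.null(stage_sets)) {
      want <- stage_sets[[paste0("stage", l)]]
      bad <- setdiff(want, vs)
      if (length(bad))
        stop("stage ", l, " variables not in covariate table: ",
             paste(bad, collapse = ", "))
      vs <- intersect(vs, want)
    }
    a <- array(NA_real_, c(length(years), length(sites), length(vs)),
               dimnames = list(years, sites, vs))
    for (v in vs) {
      s <- sub[sub$variable == v, , drop = FALSE]
      a[cbind(match(s$year, years), match(s$site, sites),
              match(v, vs))] <- s$std_value
    }
    if (anyNA(a)) stop("incomplete covariate support for stage ", l)
    X[[l]] <- a; vars[[l]] <- vs
  }
  list(X = X, vars = vars, years = years, sites = sites)
}
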