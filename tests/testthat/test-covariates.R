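test_that("seasonal window means use exactly the closed date windows", {
  s <- constant_series(2010, 10)
  expect_equal(window_mean(s, 2010, "spring_autumn"), 10)

  dates <- seq(as.Date("2010-04-01"), as.Date("2010-09-30"), by = "day")
  expect_length(dates, 183L)
  s2 <- daily_series(dates, seq_along(dates), "temperature")
  expect_equal(window_mean(s2, 2010, "spring_autumn"), (1 + 183) / 2)

  # autumn--winter of year y spans 1 Oct y-1 .. 31 Mar y
  dates3 <- seq(as.Date("2010-09-01"), as.Date("2011-04-30"), by = "day")
  s3 <- daily_series(dates3, as.numeric(dates3), "temperature")
  aw <- seq(as.Date("2010-10-01"), as.Date("2011-03-31"), by = "day")
  expect_equal(window_mean(s3, 2011, "autumn_winter"),
               mean(as.numeric(aw)))
  expect_error(window_mean(s3, 1990, "spring_autumn"), "no observations")
})

test_that("high-temperature day counts use a strict exceedance", {
  dates <- seq(as.Date("2012-04-01"), as.Date("2012-09-30"), by = "day")
  v <- rep(0, length(dates))
  v[1:3] <- c(19.9, 20.0, 20.1)
  s <- daily_series(dates, v, "temperature")
  expect_identical(count_days_above(s, 20, 2012), 1L)
  expect_identical(count_days_above(daily_series(dates, rep(15, 183)),
                                    20, 2012), 0L)
  expect_identical(count_days_above(daily_series(dates, rep(25, 183)),
                                    20, 2012), 183L)
})

test_that("flow-duration thresholds are interpolated percentiles", {
  dates <- seq(as.Date("2003-01-01"), by = "day", length.out = 101)
  th <- flow_thresholds(daily_series(dates, seq(0, 100, by = 1),
                                     "discharge"))
  expect_equal(th$q90, 10)
  expect_equal(th$q10, 90)
  expect_error(flow_thresholds(daily_series(dates[1:50], 1:50, "discharge")),
               "100 daily")
  expect_warning(th2 <- flow_thresholds(constant_series(2003, 5,
                                                        "discharge")),
                 "constant")
  expect_equal(th2$q90, th2$q10)

  set.seed(1)
  s <- constant_series(2003:2005, 1, "discharge")
  s$value <- stats::rlnorm(nrow(s), 0, 0.5)
  th3 <- flow_thresholds(s)
  expect_lte(th3$q90, stats::median(s$value))
  expect_gte(th3$q10, stats::median(s$value))
})

test_that("low/high flow day counts use inclusive comparisons", {
  dates <- seq(as.Date("2012-04-01"), as.Date("2012-09-30"), by = "day")
  v <- rep(5, length(dates)); v[1] <- 2  # one day exactly at threshold 2
  s <- daily_series(dates, v, "discharge")
  expect_identical(count_flow_days(s, 2012, 2, "low"), 1L)
  expect_identical(count_flow_days(s, 2012, 5, "high"),
                   length(dates) - 1L)
  zero <- daily_series(dates, rep(0, length(dates)), "discharge")
  expect_identical(count_flow_days(zero, 2012, 1, "low"), 183L)
  inc <- daily_series(dates, seq_along(dates), "discharge")
  expect_identical(count_flow_days(inc, 2012, 200, "high"), 0L)
})

test_that("the Q90 threshold splits the period within one day of 10%", {
  set.seed(42)
  s <- constant_series(2003:2006, 1, "discharge")
  s$value <- stats::rlnorm(nrow(s), 0, 0.6)
  th <- flow_thresholds(s)
  n_below <- sum(s$value <= th$q90)
  expect_lte(abs(n_below - 0.1 * nrow(s)), 1)
})

test_that("donor imputation completes a gapped discharge record", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2010-03-01"), by = "day")
  gappy <- daily_series(dates[-(10:15)], rep(2, length(dates) - 6),
                        "discharge")
  donor <- daily_series(dates, rep(7, length(dates)), "discharge")
  full <- impute_from_donor(gappy, donor)
  expect_equal(nrow(full), length(dates))
  expect_equal(full$value[10:15], rep(7, 6))
  expect_equal(full$value[1:9], rep(2, 9))
})

test_that("covariate assembly replicates year-level values and restricts stages", {
  tab <- assemble_covariates(tiny_annual(), tiny_abundance(), sites = 1:2)
  # year-level variable identical across sites within a year
  sub <- tab[tab$variable == "meanT_SA" & tab$stage == 1 &
               tab$year == 2003, ]
  expect_equal(length(unique(sub$raw_value)), 1L)
  # juvenile stage has no autumn--winter temperature
  expect_false(any(tab$stage == 1 & tab$variable == "meanT_AW"))
  expect_true(any(tab$stage == 2 & tab$variable == "meanT_AW"))
  # abundance covariates vary across sites
  ab <- tab[tab$variable == "gray_adult" & tab$year == 2003, ]
  expect_gt(length(unique(ab$raw_value)), 1L)
  # deterministic: identical inputs give identical tables
  expect_identical(tab, assemble_covariates(tiny_annual(), tiny_abundance(),
                                            sites = 1:2))
  # missing year x site abundance entries are an error listing the gap
  expect_error(assemble_covariates(tiny_annual(),
                                   tiny_abundance(sites = 1), sites = 1:2),
               "missing year x site")
})

test_that("z-standardisation gives mean 0, sample sd 1, and is idempotent", {
  tab <- data.frame(year = rep(2003:2005, 2), site = 1,
                    stage = rep(1:2, each = 3), variable = "v",
                    raw_value = rep(c(1, 2, 3), 2))
  class(tab) <- c("covariate_table", "data.frame")
  z <- z_standardise(tab)
  expect_equal(z$std_value[1:3], c(-1, 0, 1))
  expect_lt(abs(mean(z$std_value[1:3])), 1e-12)
  # idempotent: standardising already-standardised values is a no-op
  tab2 <- tab
  tab2$raw_value <- z$std_value
  z2 <- z_standardise(tab2)
  expect_equal(z2$std_value, z$std_value, tolerance = 1e-12)
  # zero variance errors, naming the variable
  tabc <- tab; tabc$raw_value <- 5
  expect_error(z_standardise(tabc), "zero variance.*'v'")
})

test_that("collinearity screen flags, resolves via the drop list, or demands a choice", {
  set.seed(3)
  n <- 300
  mk <- function(vals) {
    out <- NULL
    for (v in names(vals))
      out <- rbind(out, data.frame(year = seq_len(n), site = 1, stage = 1,
                                   variable = v, raw_value = vals[[v]]))
    class(out) <- c("covariate_table", "data.frame")
    z_standardise(out)
  }
  temp <- stats::rnorm(n)
  tab <- mk(list(meanT_SA = temp,
                 highT_days = 2 * temp + 1,      # duplicated information
                 invert_biomass = stats::rnorm(n)))
  rep1 <- collinearity_screen(tab, drop = "highT_days")
  pair <- rep1$flagged[rep1$flagged$var1 == "highT_days" |
                         rep1$flagged$var2 == "highT_days", ]
  expect_true(any(abs(pair$r) >= 1 - 1e-12))
  expect_true("highT_days" %in% rep1$dropped$variable)
  expect_false("highT_days" %in% rep1$table$variable)
  expect_true("meanT_SA" %in% rep1$table$variable)
  # independent columns stay unflagged
  expect_false(any(rep1$flagged$var1 == "invert_biomass" |
                     rep1$flagged$var2 == "invert_biomass"))
  # an unresolved flagged pair is an error demanding a choice
  expect_error(collinearity_screen(tab, drop = character()),
               "no configured resolution")
})
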