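benchmark_params <- function(sigma = 1)
  growth_params(347.61, 0.14, -2.27, sigma = sigma)

test_that("expected-length formulas match direct arithmetic", {
  p <- benchmark_params()
  # closed-form oracles computed in place
  m1 <- 347.61 * (1 - exp(-0.14 * (1 + 2.27)))
  expect_equal(juvenile_expected_length(p), m1, tolerance = 1e-12)
  m2 <- m1 + (347.61 - m1) * (1 - exp(-0.14 * (2 + 2.27)))
  expect_equal(update_expected_length(p, m1, 2), m2, tolerance = 1e-12)
  # covariate multiplier of exp(ln 2) exactly doubles the juvenile baseline
  p2 <- growth_params(347.61, 0.14, -2.27, 1, theta = list(c(v = log(2)),
                                                           numeric(),
                                                           numeric()))
  expect_equal(juvenile_expected_length(p2, x = 1), 2 * m1)
  expect_equal(juvenile_expected_length(p2, x = 0), m1)
  # literal (non-incremented) variant drops the mu_prev term
  expect_equal(update_expected_length(p, m1, 2, literal = TRUE), m2 - m1)
  # degenerate inputs
  expect_equal(update_expected_length(p, p$Linf, 3), p$Linf)
  expect_error(update_expected_length(p, -5, 2), "positive")
})

test_that("with no covariate effects the recursion is monotone and bounded by Linf", {
  p <- growth_params(350, 0.2, -1.5, 1)
  mu <- numeric(6)
  mu[1] <- juvenile_expected_length(p)
  for (a in 2:6) mu[a] <- update_expected_length(p, mu[a - 1], a)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu < p$Linf))
  # geometric approach: the gap to Linf shrinks by exp(-K (t_a - t0))
  gap <- p$Linf - mu
  expect_equal(gap[-1] / gap[-6],
               exp(-p$K * ((2:6) - p$t0)), tolerance = 1e-12)
})

test_that("pointwise log-likelihood sums to the total and scales with sigma", {
  st <- generate_study(synthetic_truth(years = 2003:2006, sites = 1:2,
                                       n_lengths = 150), seed = 5)
  ll <- growth_loglik(st$params, st$records, st$covariates)
  expect_equal(sum(ll$pointwise), ll$total, tolerance = 1e-9)
  expect_length(ll$pointwise, nrow(st$records))
  # doubling the residual sd changes each term by the closed-form amount
  p2 <- st$params; p2$sigma <- 2 * st$params$sigma
  ll2 <- growth_loglik(p2, st$records, st$covariates)
  mu <- expected_length_grid(st$params, st$covariates)
  ci <- stagegrowth:::cell_index(st$records, sort(unique(st$covariates$year)),
                                 sort(unique(st$covariates$site)))
  resid <- st$records$fork_length_mm - mu[cbind(ci$yi, ci$si, ci$ai)]
  delta <- -log(2) + (resid^2 / (2 * st$params$sigma^2)) * (1 - 1 / 4)
  expect_equal(ll2$pointwise - ll$pointwise, delta, tolerance = 1e-9)
  # a record exactly at its expected length sits at the density mode
  one <- st$records[1, , drop = FALSE]
  one$fork_length_mm <- mu[ci$yi[1], ci$si[1], ci$ai[1]]
  ll3 <- growth_loglik(st$params, one, st$covariates)
  expect_equal(ll3$pointwise[1],
               stats::dnorm(0, 0, st$params$sigma, log = TRUE))
})

test_that("the C++ recursion agrees with the R reference implementation", {
  st <- generate_study(synthetic_truth(years = 2003:2008, sites = 1:3,
                                       n_lengths = 300), seed = 8)
  design <- stagegrowth:::stage_design(st$covariates)
  mu_r <- expected_length_grid(st$params, design)
  p <- st$params
  m <- vapply(design$X, function(a) dim(a)[3], 1L)
  par_row <- c(p$Linf, log(p$K), p$t0, unlist(p$theta),
               as.vector(p$mu_init), 1 / p$sigma^2)
  mu_c <- growth_mu_draws_cpp(matrix(par_row, nrow = 1),
                              length(design$years), length(design$sites), 6L,
                              as.numeric(design$X[[1]]), m[1],
                              as.numeric(design$X[[2]]), m[2],
                              as.numeric(design$X[[3]]), m[3], FALSE)
  expect_equal(as.vector(mu_c), as.vector(mu_r), tolerance = 1e-10)
})

test_that("growth fits are reproducible and carry pointwise log-likelihoods", {
  st <- generate_study(synthetic_truth(years = 2003:2008, sites = 1:2,
                                       n_lengths = 250), seed = 12)
  sets <- list(stage1 = "meanT_SA", stage2 = "gray_subadult",
               stage3 = "gray_adult")
  f1 <- fit_growth(st$records, st$covariates, stage_sets = sets,
                   settings = quick_settings(3))
  f2 <- fit_growth(st$records, st$covariates, stage_sets = sets,
                   settings = quick_settings(3))
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$loglik),
               c(3 * stagegrowth:::n_retained(f1$settings),
                 nrow(st$records)))
  expect_true(all(is.finite(f1$loglik)))
  expect_true(all(c("Linf", "K", "t0", "tau_eps") %in%
                    f1$summary$parameter))
})

test_that("expected-length series are flat in time when covariates are constant", {
  st <- generate_study(synthetic_truth(years = 2003:2008, sites = 1:2,
                                       n_lengths = 300), seed = 21)
  fit <- fit_growth(st$records, st$covariates,
                    stage_sets = list(stage1 = "meanT_SA",
                                      stage2 = "meanT_AW",
                                      stage3 = "invert_biomass"),
                    settings = quick_settings(6))
  # zero out the covariate columns: recursion becomes year-invariant
  flat <- fit
  for (l in 1:3) flat$design$X[[l]][] <- 0
  els <- expected_length_series(flat)
  # juvenile expected length identical every year => slope ~ 0
  juv <- els$expected[els$expected$age_class == 1, ]
  expect_lt(max(juv$mean) - min(juv$mean), 1e-9)
  expect_lt(abs(els$trend$slope[1]), 1e-9)
})

test_that("marginal effects reduce to the baseline at the covariate mean", {
  st <- generate_study(synthetic_truth(years = 2003:2008, sites = 1:2,
                                       n_lengths = 300), seed = 23)
  sets <- list(stage1 = c("meanT_SA", "gray_juv"), stage2 = "meanT_AW",
               stage3 = "gray_adult")
  fit <- fit_growth(st$records, st$covariates, stage_sets = sets,
                    settings = quick_settings(7))
  sc <- fit$scales[fit$scales$variable == "meanT_SA", ]
  grid <- c(sc$mu - sc$sigma, sc$mu, sc$mu + sc$sigma)
  me <- marginal_effect(fit, "meanT_SA", 1, grid)
  pooled <- pooled_draws(fit)
  base <- pooled[, "Linf"] *
    (1 - exp(-pooled[, "K"] * (1 - pooled[, "t0"])))
  th <- pooled[, "theta1[meanT_SA]"]
  # per-draw algebra: curve at +-1 sd is baseline times exp(+-theta)
  expect_equal(me$mean[2], mean(base), tolerance = 1e-9)
  expect_equal(me$mean[3], mean(base * exp(th)), tolerance = 1e-9)
  expect_equal(me$mean[1], mean(base * exp(-th)), tolerance = 1e-9)
  expect_error(marginal_effect(fit, "macrophyte", 1, grid), "not retained")
  # a clearly negative coefficient gives a strictly decreasing curve
  th_neg <- fit
  i <- match("theta1[gray_juv]", colnames(pooled))
  for (ch in seq_along(th_neg$draws))
    th_neg$draws[[ch]][, i] <- -abs(th_neg$draws[[ch]][, i]) - 0.05
  sc2 <- fit$scales[fit$scales$variable == "gray_juv", ]
  me2 <- marginal_effect(th_neg, "gray_juv", 1,
                         seq(sc2$mu - 2 * sc2$sigma, sc2$mu + 2 * sc2$sigma,
                             length.out = 9))
  expect_true(all(diff(me2$mean) < 0))
})

test_that("removing recaptures does not flip clearly supported coefficient signs", {
  st <- generate_study(synthetic_truth(n_lengths = 1500), seed = 31)
  sets <- list(stage1 = c("meanT_SA", "gray_juv"),
               stage2 = c("meanT_AW", "gray_subadult"),
               stage3 = c("meanT_AW", "gray_adult"))
  f_all <- fit_growth(st$records, st$covariates, stage_sets = sets,
                      settings = quick_settings(41))
  f_no <- fit_growth(st$records, st$covariates, stage_sets = sets,
                     settings = quick_settings(42), drop_recaptures = TRUE)
  expect_lt(nrow(f_no$records), nrow(f_all$records))
  for (l in 1:3) {
    a <- stagegrowth:::stage_coef_table(f_all, l)
    b <- stagegrowth:::stage_coef_table(f_no, l)
    strong <- a$lo95 > 0 | a$hi95 < 0
    expect_true(all(sign(a$mean[strong]) == sign(b$mean[strong])))
  }
})

test_that("length ingestion enforces the study frame", {
  bad <- data.frame(year = 2003, site = 1, age_class = 7,
                    fork_length_mm = 300, recapture = FALSE)
  expect_error(length_records(bad), "1..6")
  neg <- data.frame(year = 2003, site = 1, age_class = 2,
                    fork_length_mm = -10, recapture = FALSE)
  expect_error(length_records(neg), "positive")
})
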