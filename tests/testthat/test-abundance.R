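toy_catches <- function(counts, year = 1, site = 1, cls = 1) {
  data.frame(year = year, site = site, class = cls,
             pass = seq_along(counts), count = counts)
}

test_that("depletion units validate counts and pass structure", {
  expect_error(depletion_units(toy_catches(c(5, -1)), c("1" = 1)),
               "non-negative integers")
  bad <- toy_catches(c(5, 3)); bad$pass <- c(1, 3)
  expect_error(depletion_units(bad, c("1" = 1)), "contiguous")
  expect_error(depletion_units(toy_catches(c(5, 3)), c("2" = 1)),
               "no capture-probability group")
  du <- depletion_units(toy_catches(c(50, 25, 12)), c("1" = 1))
  expect_equal(du$units$total, 87)
  expect_equal(du$units$wsum, 0 * 50 + 1 * 25 + 2 * 12)
})

test_that("the log joint equals direct Poisson x sequential-binomial evaluation", {
  du <- depletion_units(toy_catches(c(50, 25, 12)), c("1" = 1))
  alpha <- log(150)
  # independent oracle: direct pmf products
  direct <- stats::dpois(100, exp(alpha), log = TRUE) +
    stats::dbinom(50, 100, 0.5, log = TRUE) +
    stats::dbinom(25, 50, 0.5, log = TRUE) +
    stats::dbinom(12, 25, 0.5, log = TRUE) +
    stats::dnorm(alpha, 0, 10, log = TRUE) +
    stats::dbeta(0.5, 1, 1, log = TRUE)
  expect_equal(nmixture_logjoint(alpha, 100, 0.5, du), direct,
               tolerance = 1e-12)
  # impossible depletion
  expect_equal(nmixture_logjoint(alpha, 80, 0.5, du), -Inf)
  # perfect capture: binomial terms contribute log 1 = 0
  du1 <- depletion_units(toy_catches(c(60, 0, 0)), c("1" = 1))
  lp <- nmixture_logjoint(alpha, 60, 1, du1)
  expect_equal(lp, stats::dpois(60, exp(alpha), log = TRUE) +
                 stats::dnorm(alpha, 0, 10, log = TRUE), tolerance = 1e-12)
})

test_that("the marginal likelihood agrees with summing the joint over N", {
  counts <- c(14, 6, 2)
  du <- depletion_units(toy_catches(counts), c("1" = 1))
  alpha <- log(30); p <- 0.45
  joint_sum <- log(sum(vapply(sum(counts):400, function(N)
    exp(nmixture_logjoint(alpha, N, p, du) -
          stats::dnorm(alpha, 0, 10, log = TRUE) -
          stats::dbeta(p, 1, 1, log = TRUE)), 0)))
  marg <- stagegrowth:::nmix_marg_ll(alpha, p, du$units) -
    sum(lgamma(counts + 1))
  expect_equal(joint_sum, marg, tolerance = 1e-8)
})

test_that("abundance fits are seed-reproducible and respect the catch floor", {
  catches <- toy_catches(c(50, 25, 12))
  f1 <- fit_abundance(catches, c("1" = 1), quick_settings(31))
  f2 <- fit_abundance(catches, c("1" = 1), quick_settings(31))
  expect_identical(f1$draws, f2$draws)
  N_draws <- pooled_draws(f1)[, "N[1,1,1]"]
  expect_true(all(N_draws >= 87))
  expect_true(all(f1$estimates$lo95 <= f1$estimates$mean &
                    f1$estimates$mean <= f1$estimates$hi95))
})

test_that("capture probability is recovered from simulated depletion surveys", {
  set.seed(9)
  rows <- lapply(1:100, function(u) {
    r <- 200; cts <- integer(3)
    for (j in 1:3) { cts[j] <- stats::rbinom(1, r, 0.6); r <- r - cts[j] }
    toy_catches(cts, year = u)
  })
  fit <- fit_abundance(do.call(rbind, rows), c("1" = 1),
                       quick_settings(11, iterations = 6000,
                                      burn_in = 2000))
  expect_lt(abs(fit$p_summary$mean - 0.6), 0.05)
  expect_true(all(fit$p_summary$lo95 < fit$p_summary$hi95))
})

test_that("single-pass units share capture probability with multi-pass units", {
  set.seed(4)
  rows <- list()
  for (u in 1:60) {
    N <- stats::rpois(1, 100)
    if (u <= 20) {  # single-pass early years
      rows[[u]] <- toy_catches(stats::rbinom(1, N, 0.55), year = u)
    } else {
      r <- N; cts <- integer(3)
      for (j in 1:3) { cts[j] <- stats::rbinom(1, r, 0.55); r <- r - cts[j] }
      rows[[u]] <- toy_catches(cts, year = u)
    }
  }
  fit <- fit_abundance(do.call(rbind, rows), c("1" = 1),
                       quick_settings(21, iterations = 6000,
                                      burn_in = 2000))
  expect_lt(abs(fit$p_summary$mean - 0.55), 0.07)
  # single-pass abundances are informed through the shared p
  est1 <- fit$estimates[fit$estimates$year == 1, ]
  expect_gt(est1$mean, sum(rows[[1]]$count))
})

test_that("abundance covariates aggregate posterior means by life stage", {
  est <- expand.grid(year = 1:2, site = 1:2, class = 1:6,
                     KEEP.OUT.ATTRS = FALSE)
  est$mean <- est$class * 10 + est$site
  est$lo95 <- est$mean - 1; est$hi95 <- est$mean + 1; est$rhat <- 1
  fake <- structure(list(estimates = est), class = "abundance_fit")
  cov <- abundance_covariates(fake)
  juv <- cov[cov$variable == "gray_juv" & cov$year == 1 & cov$site == 2, ]
  expect_equal(juv$value, 12)
  ad <- cov[cov$variable == "gray_adult" & cov$year == 1 & cov$site == 1, ]
  expect_equal(ad$value, sum((3:6) * 10 + 1))
  # covariates vary across sites
  expect_gt(length(unique(cov$value[cov$variable == "gray_adult"])), 1L)
  # missing year x site is an error
  fake2 <- structure(list(estimates = est[est$site == 1 | est$class > 1, ]),
                     class = "abundance_fit")
  expect_error(abundance_covariates(fake2), "missing year x site")
})
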