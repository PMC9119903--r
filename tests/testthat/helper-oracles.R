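# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Exhaustive grid posterior for a single depletion unit: latent N and capture
# probability p on grids, log mean abundance integrated over its Normal prior
# by quadrature.
grid_nmixture_posterior <- function(counts, N_range = 87:600,
                                    p_grid = seq(0.0005, 0.9995,
                                                 length.out = 999),
                                    alpha_grid = seq(-15, 15,
                                                     length.out = 601),
                                    alpha_sd = 10) {
  wa <- stats::dnorm(alpha_grid, 0, alpha_sd)
  prior_N <- vapply(N_range, function(n)
    sum(wa * stats::dpois(n, exp(alpha_grid))), 0)
  lik <- outer(N_range, p_grid, function(n, p) {
    out <- stats::dbinom(counts[1L], n, p)
    removed <- counts[1L]
    for (j in seq_along(counts)[-1L]) {
      out <- out * stats::dbinom(counts[j], n - removed, p)
      removed <- removed + counts[j]
    }
    out
  })
  post <- prior_N * lik
  z <- sum(post)
  list(mean_N = sum(rowSums(post) * N_range) / z,
       mean_p = sum(colSums(post) * p_grid) / z)
}

# Monte-Carlo standard error of a (possibly autocorrelated) draw vector via
# an AR(1) effective-sample-size approximation.
mcse <- function(x) {
  n <- length(x)
  rho <- stats::cor(x[-1L], x[-n])
  if (!is.finite(rho)) rho <- 0
  rho <- min(max(rho, 0), 0.99)
  ess <- n * (1 - rho) / (1 + rho)
  stats::sd(x) / sqrt(ess)
}

quick_settings <- function(seed, chains = 3L, iterations = 4000L,
                           burn_in = 1500L, thin = 10L) {
  mcmc_settings(chains = chains, iterations = iterations, burn_in = burn_in,
                thin = thin, seed = seed)
}

# A small daily temperature series covering given calendar years.
constant_series <- function(years, value, kind = "temperature") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  daily_series(dates, rep(value, length(dates)), kind)
}

# Minimal annual + abundance fixtures for assembling covariate tables.
tiny_annual <- function(years = 2003:2006) {
  data.frame(year = years,
             meanT_SA = c(13, 14, 13.5, 15)[seq_along(years)],
             meanT_AW = c(5, 6, 5.5, 7)[seq_along(years)],
             highT_days = c(3, 8, 5, 12)[seq_along(years)],
             lowflow_days = c(20, 5, 12, 2)[seq_along(years)],
             highflow_days = c(4, 18, 9, 25)[seq_along(years)],
             macrophyte = c(35, 45, 40, 50)[seq_along(years)],
             invert_biomass = c(110, 95, 100, 80)[seq_along(years)])
}

tiny_abundance <- function(years = 2003:2006, sites = 1:2) {
  set.seed(2024)
  grid <- expand.grid(year = years, site = sites, KEEP.OUT.ATTRS = FALSE)
  out <- NULL
  for (v in c("gray_juv", "gray_subadult", "gray_adult", "trout_small",
              "trout_large")) {
    g <- grid
    g$variable <- v
    g$value <- stats::rlnorm(nrow(g), 2.5, 0.7)
    out <- rbind(out, g)
  }
  out
}
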