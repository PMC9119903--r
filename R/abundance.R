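#' Validate and group depletion catch data
#'
#' Checks a table of per-pass removal counts and groups it into sampling
#' units (year x site x class). Counts must be non-negative integers and
#' pass indices contiguous from 1 within each unit; units may have different
#' numbers of passes (single-pass years sit alongside 3-pass years in one
#' joint model).
#'
#' @param catches data.frame with columns `year`, `site`, `class`, `pass`,
#'   `count` (a `species` column, if present, must be constant).
#' @param groups integer vector mapping class id to capture-probability
#'   group, e.g. `c("1" = 1, "2" = 2, ...)`; classes absent from `groups`
#'   are an error.
#' @return list with `units` (data.frame year/site/class/group/k/total/wsum),
#'   `C` (list of per-unit catch vectors) — `total` is the summed catch and
#'   `wsum` the pass-weighted sum used by the marginal likelihood.
#' @export
depletion_units <- function(catches, groups) {
  need <- c("year", "site", "class", "pass", "count")
  miss <- setdiff(need, names(catches))
  if (length(miss)) stop("catches is missing column(s): ",
                         paste(miss, collapse = ", "))
  if ("species" %in% names(catches) &&
      length(unique(catches$species)) > 1L)
    stop("fit one species at a time")
  if (any(catches$count < 0) || any(catches$count != round(catches$count)))
    stop("counts must be non-negative integers")
  gmap <- groups
  if (is.null(names(gmap))) names(gmap) <- seq_along(gmap)
  bad <- setdiff(unique(catches$class), names(gmap))
  if (length(bad)) stop("no capture-probability group for class(es): ",
                        paste(bad, collapse = ", "))
  key <- paste(catches$year, catches$site, catches$class, sep = "|")
  ord <- order(key, catches$pass)
  catches <- catches[ord, , drop = FALSE]
  key <- key[ord]
  idx <- split(seq_len(nrow(catches)), key)
  C <- lapply(idx, function(i) {
    p <- catches$pass[i]
    if (!identical(as.integer(p), seq_along(p)))
      stop("pass indices must be contiguous from 1 (unit ",
           key[i[1L]], ")")
    as.integer(catches$count[i])
  })
  first <- vapply(idx, `[`, 1L, 1L)
  units <- data.frame(
    year = catches$year[first], site = catches$site[first],
    class = catches$class[first],
    group = as.integer(gmap[as.character(catches$class[first])]),
    k = vapply(C, length, 1L),
    total = vapply(C, sum, 1L),
    wsum = vapply(C, function(x) sum((seq_along(x) - 1L) * x), 1),
    row.names = NULL)
  list(units = units, C = C)
}

#' Log joint density of the depletion N-mixture model
#'
#' The hierarchical model for a k-pass removal survey:
#' `N_u ~ Poisson(lambda_u)` with `log(lambda_u) = alpha_u`, and sequential
#' binomial catches `C_{u,j} ~ Binomial(p_g, N_u - sum_{i<j} C_{u,i})` with a
#' shared capture probability per group `g`. Priors are weakly informative:
#' `alpha ~ Normal(0, sd 10)` and `p_g ~ Beta(1, 1)`. Returns `-Inf` when a
#' latent abundance is below the catches already removed.
#'
#' @param alpha numeric vector of log mean abundances, one per unit (order of
#'   `du$units`).
#' @param N integer latent abundances, one per unit.
#' @param p capture probabilities, one per group.
#' @param du grouped data from [depletion_units()].
#' @param alpha_prior_sd prior standard deviation of `alpha`.
#' @return scalar log joint density.
#' @export
nmixture_logjoint <- function(alpha, N, p, du, alpha_prior_sd = 10) {
  u <- du$units
  stopifnot(length(alpha) == nrow(u), length(N) == nrow(u),
            length(p) >= max(u$group))
  if (any(N != round(N))) stop("latent abundances must be integers")
  if (any(p < 0 | p > 1)) return(-Inf)
  lp <- sum(stats::dnorm(alpha, 0, alpha_prior_sd, log = TRUE)) +
    sum(stats::dbeta(p, 1, 1, log = TRUE))
  lp <- lp + sum(stats::dpois(N, exp(alpha), log = TRUE))
  for (i in seq_len(nrow(u))) {
    Ci <- du$C[[i]]
    pool <- N[i] - c(0, cumsum(Ci))[seq_along(Ci)]
    if (any(pool < Ci)) return(-Inf)
    lp <- lp + sum(stats::dbinom(Ci, pool, p[u$group[i]], log = TRUE))
  }
  lp
}

# Marginal log-likelihood of one iteration state, by unit. Marginalising the
# latent Poisson abundance through the sequential binomial observation model
# gives independent Poisson catches C_j ~ Pois(lambda * p * (1-p)^(j-1)),
# so up to a constant the unit log-likelihood is
#   total*log(lambda) + total*log(p) + wsum*log(1-p) - lambda*(1-(1-p)^k).
nmix_marg_ll <- function(alpha, p_unit, units) {
  lam <- exp(alpha)
  units$total * (alpha + log(p_unit)) + units$wsum * log1p(-p_unit) -
    lam * (1 - (1 - p_unit)^units$k)
}

#' Fit the depletion N-mixture abundance model
#'
#' Joint Bayesian fit across all sampling units (year x site x class) with a
#' capture probability shared within each group. The sampler is an adaptive
#' Metropolis-within-Gibbs on the exact marginal likelihood (latent N
#' integrated out analytically via Poisson thinning); latent abundances are
#' reconstructed per retained draw as `N = total + Poisson(lambda*(1-p)^k)`,
#' which is their exact conditional posterior. Reproducible given the seed.
#'
#' @inheritParams depletion_units
#' @param settings [mcmc_settings()]; the production default for this model
#'   is 30,000 iterations with 10,000 burn-in, thin 100, 3 chains.
#' @param alpha_prior_sd prior sd of the log mean abundance.
#' @return object of classes `abundance_fit` and `posterior_result`, with
#'   additional elements `estimates` (year, site, class, mean, lo95, hi95,
#'   rhat of N), `p_summary`, `units`, `groups`.
#' @examples
#' catches <- data.frame(year = 1, site = 1, class = 1,
#'                       pass = 1:3, count = c(50, 25, 12))
#' fit <- fit_abundance(catches, groups = c("1" = 1),
#'                      settings = mcmc_settings(chains = 3, iterations = 4000,
#'                                               burn_in = 1000, thin = 10,
#'                                               seed = 1))
#' fit$estimates
#' @export
fit_abundance <- function(catches, groups,
                          settings = mcmc_settings(iterations = 30000L,
                                                   burn_in = 10000L,
                                                   thin = 100L),
                          alpha_prior_sd = 10) {
  require_seed(settings)
  du <- depletion_units(catches, groups)
  u <- du$units
  nu <- nrow(u)
  ng <- max(u$group)
  gidx <- split(seq_len(nu), u$group)
  u_g <- lapply(gidx, function(i) u[i, , drop = FALSE])
  keep <- n_retained(settings)
  if (keep < 1L) stop("settings retain no draws")
  an <- sprintf("alpha[%s,%s,%s]", u$year, u$site, u$class)
  Nn <- sprintf("N[%s,%s,%s]", u$year, u$site, u$class)
  pn <- sprintf("p[%d]", seq_len(ng))
  draws <- vector("list", settings$chains)

  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + ch - 1L)
    # overdispersed start around the depletion-naive estimate
    alpha <- log(pmax(u$total, 0.5)) + stats::rnorm(nu, 0, 0.3)
    p <- stats::runif(ng, 0.3, 0.8)
    lsd_a <- rep(0, nu); lsd_p <- rep(-1, ng)
    ll <- nmix_marg_ll(alpha, p[u$group], u)
    out <- matrix(NA_real_, keep, nu * 2L + ng,
                  dimnames = list(NULL, c(an, pn, Nn)))
    k <- 0L
    for (it in seq_len(settings$iterations)) {
      # per-unit alpha updates (independent given p): vectorised accept
      prop <- alpha + stats::rnorm(nu, 0, exp(lsd_a))
      llp <- nmix_marg_ll(prop, p[u$group], u)
      lr <- llp - ll +
        (stats::dnorm(prop, 0, alpha_prior_sd, log = TRUE) -
           stats::dnorm(alpha, 0, alpha_prior_sd, log = TRUE))
      acc <- log(stats::runif(nu)) < lr
      alpha[acc] <- prop[acc]
      ll[acc] <- llp[acc]
      if (it <= settings$burn_in)
        lsd_a <- lsd_a + (pmin(exp(lr), 1) - 0.44) / sqrt(it)
      # per-group p updates on the logit scale (Beta(1,1) prior + jacobian)
      for (g in seq_len(ng)) {
        i <- gidx[[g]]
        z <- stats::qlogis(p[g]) + stats::rnorm(1L, 0, exp(lsd_p[g]))
        pg <- stats::plogis(z)
        lli <- nmix_marg_ll(alpha[i], pg, u_g[[g]])
        lr1 <- sum(lli) - sum(ll[i]) +
          log(pg * (1 - pg)) - log(p[g] * (1 - p[g]))
        a1 <- min(1, exp(lr1))
        if (stats::runif(1L) < a1) {
          p[g] <- pg; ll[i] <- lli
        }
        if (it <= settings$burn_in)
          lsd_p[g] <- lsd_p[g] + (a1 - 0.234) / sqrt(it)
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        k <- k + 1L
        lam <- exp(alpha)
        N <- u$total + stats::rpois(nu, lam * (1 - p[u$group])^u$k)
        out[k, ] <- c(alpha, p, N)
      }
    }
    draws[[ch]] <- out[seq_len(k), , drop = FALSE]
  }
  res <- posterior_result(draws, settings)
  s <- res$summary
  iN <- match(Nn, s$parameter)
  estimates <- data.frame(year = u$year, site = u$site, class = u$class,
                          mean = s$mean[iN], lo95 = s$lo95[iN],
                          hi95 = s$hi95[iN], rhat = s$rhat[iN])
  ip <- match(pn, s$parameter)
  p_summary <- data.frame(group = seq_len(ng), mean = s$mean[ip],
                          lo95 = s$lo95[ip], hi95 = s$hi95[ip],
                          rhat = s$rhat[ip])
  res$estimates <- estimates
  res$p_summary <- p_summary
  res$units <- u
  res$groups <- groups
  class(res) <- c("abundance_fit", class(res))
  res
}

#' Default capture-probability groups
#'
#' Grayling: age-class 1 (age 0+) has its own capture probability (g = 1),
#' classes 2 to 6 (ages 1+ to 5+) share g = 2. Trout: both size classes share
#' a single group.
#'
#' @param species `"grayling"` or `"trout"`.
#' @return named integer vector mapping class id to group.
#' @export
default_capture_groups <- function(species = c("grayling", "trout")) {
  species <- match.arg(species)
  if (species == "grayling") c("1" = 1L, "2" = 2L, "3" = 2L, "4" = 2L,
                               "5" = 2L, "6" = 2L)
  else c("1" = 1L, "2" = 1L)
}

#' Abundance covariates from fitted N-mixture models
#'
#' Converts posterior-mean abundances into the year- and site-specific
#' competitor covariates used by the growth model: grayling stage 1 = class 1
#' (age 0+), stage 2 = class 2 (age 1+), stage 3 = the sum of classes 3 to 6
#' (ages 2+ to 5+); trout small / large are the two trout size classes.
#'
#' @param grayling an `abundance_fit` for grayling (classes 1..6).
#' @param trout optional `abundance_fit` for trout (classes 1 = small,
#'   2 = large).
#' @return long data.frame (`year`, `site`, `variable`, `value`) with
#'   variables `gray_juv`, `gray_subadult`, `gray_adult` and, if `trout` is
#'   given, `trout_small`, `trout_large`.
#' @export
abundance_covariates <- function(grayling, trout = NULL) {
  stopifnot(inherits(grayling, "abundance_fit"))
  est <- grayling$estimates
  years <- sort(unique(est$year)); sites <- sort(unique(est$site))
  grid <- expand.grid(year = years, site = sites, KEEP.OUT.ATTRS = FALSE)
  pick <- function(est, classes) {
    sel <- est[est$class %in% classes, , drop = FALSE]
    agg <- stats::aggregate(mean ~ year + site, data = sel, FUN = sum)
    i <- match(paste(grid$year, grid$site), paste(agg$year, agg$site))
    if (anyNA(i))
      stop("missing year x site abundance estimates for classes ",
           paste(classes, collapse = ","))
    agg$mean[i]
  }
  out <- rbind(
    data.frame(grid, variable = "gray_juv", value = pick(est, 1)),
    data.frame(grid, variable = "gray_subadult", value = pick(est, 2)),
    data.frame(grid, variable = "gray_adult", value = pick(est, 3:6)))
  if (!is.null(trout)) {
    stopifnot(inherits(trout, "abundance_fit"))
    tes <- trout$estimates
    out <- rbind(out,
      data.frame(grid, variable = "trout_small", value = pick(tes, 1)),
      data.frame(grid, variable = "trout_large", value = pick(tes, 2)))
  }
  rownames(out) <- NULL
  out
}
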