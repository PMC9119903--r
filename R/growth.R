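#' Life stage of an age-class
#'
#' Age-class 1 (age 0+) is juvenile (stage 1), age-class 2 (age 1+) is
#' sub-adult (stage 2) and age-classes 3 to 6 (ages 2+ to 5+) are adult
#' (stage 3).
#'
#' @param a age-class vector (1..6).
#' @return integer stage vector.
#' @export
stage_of_age <- function(a) {
  stopifnot(all(a %in% 1:6))
  c(1L, 2L, 3L, 3L, 3L, 3L)[a]
}

vb_factor <- function(a, K, t0) 1 - exp(-K * (a - t0))

#' Growth-model parameter set
#'
#' Bundles a complete parameter set for the stage-covariate von Bertalanffy
#' model: asymptotic length `Linf` (mm), Brody growth coefficient `K`
#' (per year), theoretical age at zero length `t0` (years), residual standard
#' deviation `sigma` (mm), per-stage coefficient vectors `theta` acting on
#' standardised covariates, and the initial-year expected lengths `mu_init`
#' (site x age-classes 2..6) that anchor cohort chains entering the study
#' frame.
#'
#' @param Linf asymptotic length, mm (> 0).
#' @param K Brody growth coefficient, per year (> 0).
#' @param t0 theoretical age at length zero, years.
#' @param sigma residual (observation) standard deviation, mm (> 0).
#' @param theta list of three named numeric vectors (may be empty) of
#'   standardised-covariate coefficients, one per life stage.
#' @param mu_init matrix (sites x 5) of initial-year expected lengths for
#'   age-classes 2..6; may be NULL for purely deterministic use at y = 1.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(Linf, K, t0, sigma,
                          theta = list(numeric(), numeric(), numeric()),
                          mu_init = NULL) {
  stopifnot(Linf > 0, K > 0, sigma > 0, is.list(theta), length(theta) == 3L,
            all(vapply(theta, function(x) all(is.finite(x)), TRUE)))
  structure(list(Linf = Linf, K = K, t0 = t0, sigma = sigma, theta = theta,
                 mu_init = mu_init),
            class = "growth_params")
}

#' Expected juvenile length
#'
#' Expected fork length of age 0+ fish in a given year and site:
#' `Linf * (1 - exp(-K (t_1 - t0))) * exp(theta_1 . x)` with `t_1 = 1`.
#' Reduces to the baseline von Bertalanffy length when all standardised
#' covariates are at their means (`x = 0`).
#'
#' @param params a [growth_params()].
#' @param x standardised covariate vector for the juvenile stage (defaults to
#'   the all-means baseline).
#' @return expected length, mm.
#' @export
juvenile_expected_length <- function(params, x = NULL) {
  th <- params$theta[[1L]]
  if (is.null(x)) x <- rep(0, length(th))
  stopifnot(length(x) == length(th))
  params$Linf * vb_factor(1, params$K, params$t0) * exp(sum(th * x))
}

#' Expected length of a subsequent age-class
#'
#' Advances an expected length one year: the growth increment
#' `(Linf - mu_prev) * (1 - exp(-K (t_a - t0)))`, scaled by the stage-specific
#' covariate multiplier `exp(theta_l . x)` with `l` the stage of the
#' destination age-class, is added to `mu_prev` (Fabens increment form).
#' `literal = TRUE` instead returns the bare scaled increment without adding
#' `mu_prev` (a non-accumulating variant retained for comparison).
#'
#' @param params a [growth_params()].
#' @param mu_prev expected length of the previous age-class, mm (> 0).
#' @param a destination age-class (2..6).
#' @param x standardised covariate vector for stage `stage_of_age(a)`.
#' @param literal use the non-incremented form.
#' @return expected length, mm.
#' @export
update_expected_length <- function(params, mu_prev, a, x = NULL,
                                   literal = FALSE) {
  stopifnot(a %in% 2:6)
  if (any(mu_prev <= 0)) stop("mu_prev must be positive")
  l <- stage_of_age(a)
  th <- params$theta[[l]]
  if (is.null(x)) x <- rep(0, length(th))
  stopifnot(length(x) == length(th))
  inc <- (params$Linf - mu_prev) * vb_factor(a, params$K, params$t0) *
    exp(sum(th * x))
  if (literal) inc else mu_prev + inc
}

#' Expected-length grid over the full study frame
#'
#' Pure-R reference implementation of the cohort recursion: juvenile lengths
#' from the closed form each year, initial-year lengths of older age-classes
#' from `mu_init`, and every other cell from the previous year's previous
#' age-class via [update_expected_length()].
#'
#' @param params a [growth_params()] whose `theta` names match the design.
#' @param design a stage design as returned by `stage_design()` (internal) or
#'   a standardised `covariate_table`.
#' @param literal use the non-incremented recursion.
#' @return array (year x site x age-class) of expected lengths, mm.
#' @export
expected_length_grid <- function(params, design, literal = FALSE) {
  if (inherits(design, "covariate_table")) design <- stage_design(design)
  X <- design$X
  Y <- length(design$years); S <- length(design$sites); A <- 6L
  for (l in 1:3)
    stopifnot(length(params$theta[[l]]) == dim(X[[l]])[3L])
  if (is.null(params$mu_init))
    stop("mu_init required to anchor initial-year age-classes 2..6")
  stopifnot(nrow(params$mu_init) == S, ncol(params$mu_init) == 5L)
  mu <- array(NA_real_, c(Y, S, A))
  for (s in seq_len(S)) {
    for (y in seq_len(Y))
      mu[y, s, 1L] <- juvenile_expected_length(params, X[[1L]][y, s, ])
    mu[1L, s, 2:6] <- params$mu_init[s, ]
    for (y in 2:Y) for (a in 2:A) {
      l <- stage_of_age(a)
      mu[y, s, a] <- update_expected_length(params, mu[y - 1L, s, a - 1L],
                                            a, X[[l]][y, s, ],
                                            literal = literal)
    }
  }
  dimnames(mu) <- list(design$years, design$sites, 1:6)
  mu
}

#' Validate individual length records
#'
#' @param records data.frame with columns `year`, `site`, `age_class`,
#'   `fork_length_mm`, `recapture`.
#' @return the validated data.frame.
#' @export
length_records <- function(records) {
  need <- c("year", "site", "age_class", "fork_length_mm", "recapture")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("length records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(records$fork_length_mm <= 0)) stop("fork lengths must be positive")
  if (!all(records$age_class %in% 1:6))
    stop("age_class must be in 1..6 (ages 0+ to 5+); older fish are ",
         "excluded at ingestion")
  records$recapture <- as.logical(records$recapture)
  records
}

cell_index <- function(records, years, sites) {
  yi <- match(records$year, years)
  si <- match(records$site, sites)
  if (anyNA(yi) || anyNA(si))
    stop("length records outside the covariate year x site frame")
  ai <- as.integer(records$age_class)
  list(yi = yi, si = si, ai = ai,
       cell = (yi - 1L) + length(years) * ((si - 1L) + length(sites) *
                                             (ai - 1L)))
}

cell_stats <- function(records, years, sites) {
  Y <- length(years); S <- length(sites); A <- 6L
  ci <- cell_index(records, years, sites)
  n <- ybar <- ss <- numeric(Y * S * A)
  f <- factor(ci$cell, levels = 0:(Y * S * A - 1L))
  n <- as.numeric(tabulate(f, nbins = Y * S * A))
  sums <- vapply(split(records$fork_length_mm, f), sum, 0)
  ybar <- ifelse(n > 0, sums / pmax(n, 1), 0)
  dev <- records$fork_length_mm - ybar[ci$cell + 1L]
  ss_by <- vapply(split(dev^2, f), sum, 0)
  list(n = n, ybar = ybar, ss = as.numeric(ss_by), cell = ci$cell)
}

#' Prior settings for the growth model
#'
#' All priors are weakly informative on each parameter's natural scale:
#' zero-centred Normals for `Linf`, `t0`, the covariate coefficients and the
#' initial-year expected lengths, `K ~ Gamma(1, 1)`, and
#' `tau ~ Gamma(0.01, 0.01)` for the Normal precision of the length
#' likelihood. The default standard deviations are 1000 mm for the
#' length-scale parameters (`Linf`, `mu_init`) and `1/sqrt(0.001) ~ 31.6`
#' for `t0` and the coefficients. A zero-centred prior with sd of order
#' 30 mm is *not* weak for quantities of 200--350 mm: simulation shows it
#' shrinks the initial-year lengths enough to bias `K` and `t0` upward, so
#' it is not used as the length-scale default; pass
#' `growth_priors(Linf_sd = 1/sqrt(0.001), mu_init_sd = 1/sqrt(0.001))` to
#' reproduce that narrower precision-notation reading.
#'
#' @param Linf_mean,Linf_sd,t0_mean,t0_sd,beta_sd,mu_init_mean,mu_init_sd
#'   Normal prior settings (mean / sd scale).
#' @param K_shape,K_rate Gamma prior on `K`.
#' @param tau_shape,tau_rate Gamma prior on the likelihood precision.
#' @return named list of class `growth_priors`.
#' @export
growth_priors <- function(Linf_mean = 0, Linf_sd = 1000,
                          K_shape = 1, K_rate = 1,
                          t0_mean = 0, t0_sd = 1 / sqrt(0.001),
                          beta_sd = 1 / sqrt(0.001),
                          mu_init_mean = 0, mu_init_sd = 1000,
                          tau_shape = 0.01, tau_rate = 0.01) {
  structure(list(Linf_mean = Linf_mean, Linf_sd = Linf_sd,
                 K_shape = K_shape, K_rate = K_rate, t0_mean = t0_mean,
                 t0_sd = t0_sd, beta_sd = beta_sd,
                 mu_init_mean = mu_init_mean, mu_init_sd = mu_init_sd,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "growth_priors")
}

theta_names <- function(vars) {
  unlist(lapply(1:3, function(l)
    if (length(vars[[l]])) sprintf("theta%d[%s]", l, vars[[l]])
    else character()))
}

mu_init_names <- function(sites) {
  as.vector(outer(sites, 2:6, function(s, a) sprintf("mu_init[%s,%d]", s, a)))
}

flatten_X <- function(Xl) as.numeric(Xl)

#' Fit the stage-covariate von Bertalanffy growth model
#'
#' Bayesian fit of the growth model to individual fork lengths. Expected
#' lengths follow the cohort recursion of [expected_length_grid()]; lengths
#' are Normal around their cell's expected value with a common precision.
#' The sampler is an adaptive Metropolis-within-Gibbs (random-walk updates
#' for `Linf`, `log K`, `t0`, the stage coefficients and the initial-year
#' expected lengths; a conjugate Gibbs draw for the precision), implemented
#' in C++, with per-chain seeds and data-driven overdispersed starting
#' values. The pointwise log-likelihood matrix over retained draws is kept
#' for leave-one-out model comparison.
#'
#' @param records length records (see [length_records()]).
#' @param covariates standardised `covariate_table`.
#' @param stage_sets optional named list restricting each stage's covariates
#'   (a simplified model); default uses every variable present per stage.
#' @param priors a [growth_priors()].
#' @param settings [mcmc_settings()]; production default 30,000 iterations
#'   with 20,000 burn-in, thin 100, 3 chains.
#' @param literal fit the non-incremented recursion variant.
#' @param drop_recaptures refit excluding recapture-flagged records (the
#'   recapture sensitivity check).
#' @param keep_loglik retain the pointwise log-likelihood matrix.
#' @return object of classes `growth_fit` and `posterior_result`; extra
#'   elements: `vars` (per-stage covariate names), `scales` (per-variable
#'   mean/sd for back-transformation), `design`, `records`, `literal`.
#' @export
fit_growth <- function(records, covariates, stage_sets = NULL,
                       priors = growth_priors(),
                       settings = mcmc_settings(iterations = 30000L,
                                                burn_in = 20000L,
                                                thin = 100L),
                       literal = FALSE, drop_recaptures = FALSE,
                       keep_loglik = TRUE) {
  require_seed(settings)
  records <- length_records(records)
  if (drop_recaptures)
    records <- records[!records$recapture, , drop = FALSE]
  if (nrow(records) == 0L) stop("no length records to fit")
  design <- stage_design(covariates, stage_sets)
  Y <- length(design$years); S <- length(design$sites); A <- 6L
  cs <- cell_stats(records, design$years, design$sites)
  m <- vapply(design$X, function(a) dim(a)[3L], 1L)
  pv <- with(priors, c(Linf_mean, Linf_sd, K_shape, K_rate, t0_mean, t0_sd,
                       beta_sd, mu_init_mean, mu_init_sd, tau_shape,
                       tau_rate))
  pn <- c("Linf", "K", "t0", theta_names(design$vars),
          mu_init_names(design$sites), "tau_eps")
  P <- 3L + sum(m) + S * 5L

  # data-driven overdispersed inits: asymptote near the largest fish,
  # first-year cell means for the initial-length parameters
  len_max <- max(records$fork_length_mm)
  y1 <- matrix(NA_real_, S, 5L)
  for (s in seq_len(S)) for (a in 2:6) {
    i <- cs$n[1L + Y * ((s - 1L) + S * (a - 1L))]
    y1[s, a - 1L] <- if (i > 0) cs$ybar[1L + Y * ((s - 1L) + S * (a - 1L))]
    else NA_real_
  }
  pooled_sd <- sqrt(sum(cs$ss) / max(1, sum(cs$n) - sum(cs$n > 0)))
  if (!is.finite(pooled_sd) || pooled_sd <= 0) pooled_sd <- 10

  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + ch - 1L)
    Linf0 <- len_max * stats::runif(1L, 1.0, 1.2)
    K0 <- stats::runif(1L, 0.08, 0.35)
    t00 <- stats::runif(1L, -3, -0.8)
    th0 <- stats::rnorm(sum(m), 0, 0.02)
    mui0 <- y1
    for (a in 2:6) {
      fallback <- Linf0 * vb_factor(a, K0, t00)
      mui0[, a - 1L][is.na(mui0[, a - 1L])] <- fallback
    }
    mui0 <- mui0 + stats::rnorm(length(mui0), 0, 3)
    init <- c(Linf0, log(K0), t00, th0, as.vector(mui0))
    tau0 <- 1 / pooled_sd^2 * exp(stats::rnorm(1L, 0, 0.2))
    res <- growth_chain_cpp(cs$n, cs$ybar, cs$ss, Y, S, A,
                            flatten_X(design$X[[1L]]), m[1L],
                            flatten_X(design$X[[2L]]), m[2L],
                            flatten_X(design$X[[3L]]), m[3L],
                            pv, init, tau0,
                            settings$iterations, settings$burn_in,
                            settings$thin, literal)
    d <- res$draws
    d[, 2L] <- exp(d[, 2L])  # report K, not log K
    colnames(d) <- pn
    chains[[ch]] <- d
  }
  out <- posterior_result(chains, settings)
  out$vars <- design$vars
  out$design <- design
  out$records <- records
  out$literal <- literal
  out$priors <- priors
  # per-variable centring constants for marginal-effect axes
  sc <- unique(covariates[, c("variable", "mu", "sigma")])
  out$scales <- sc[!duplicated(sc$variable), , drop = FALSE]
  if (keep_loglik) {
    pooled <- pooled_draws(out)
    out$loglik <- growth_pointwise_matrix(pooled, design, cs$cell,
                                          records$fork_length_mm, literal)
  }
  class(out) <- c("growth_fit", class(out))
  out
}

# pooled draws (K on natural scale) -> pointwise loglik matrix
growth_pointwise_matrix <- function(pooled, design, rec_cell, rec_len,
                                    literal) {
  m <- vapply(design$X, function(a) dim(a)[3L], 1L)
  internal <- pooled
  internal[, 2L] <- log(internal[, 2L])
  mu_d <- growth_mu_draws_cpp(internal, length(design$years),
                              length(design$sites), 6L,
                              flatten_X(design$X[[1L]]), m[1L],
                              flatten_X(design$X[[2L]]), m[2L],
                              flatten_X(design$X[[3L]]), m[3L], literal)
  P <- 3L + sum(m) + length(design$sites) * 5L
  growth_pointwise_cpp(pooled_tau_last(internal, P), mu_d,
                       as.integer(rec_cell), rec_len, P)
}

pooled_tau_last <- function(draws, P) {
  # the sampler's layout already has tau in column P + 1
  draws[, seq_len(P + 1L), drop = FALSE]
}

#' Growth log-likelihood of a parameter set
#'
#' Normal log-density of every length record around its cell's expected
#' length (via the cohort recursion), plus the total. The pointwise vector is
#' the quantity leave-one-out cross-validation operates on.
#'
#' @param params a [growth_params()] with `theta` matching the covariate
#'   table's per-stage variables and `mu_init` set.
#' @param records length records.
#' @param covariates standardised `covariate_table`.
#' @param literal use the non-incremented recursion.
#' @return list with `total` and `pointwise` (one entry per record).
#' @export
growth_loglik <- function(params, records, covariates, literal = FALSE) {
  records <- length_records(records)
  design <- stage_design(covariates)
  mu <- expected_length_grid(params, design, literal = literal)
  ci <- cell_index(records, design$years, design$sites)
  mu_i <- mu[cbind(ci$yi, ci$si, ci$ai)]
  pw <- stats::dnorm(records$fork_length_mm, mu_i, params$sigma, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Expected length at age over time, with a post-hoc year trend
#'
#' Per retained draw, the expected-length grid is averaged across sites for
#' each year and age-class; posterior means and 95% credible intervals are
#' reported, together with an ordinary least-squares linear year slope per
#' age-class (computed per draw, so the trend carries posterior uncertainty).
#' The trend is a post-fit description of the fitted series, not a model
#' term.
#'
#' @param fit a `growth_fit`.
#' @return list with `expected` (year, age_class, mean, lo95, hi95) and
#'   `trend` (age_class, slope, lo95, hi95, slope mm per year).
#' @export
expected_length_series <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  design <- fit$design
  Y <- length(design$years); S <- length(design$sites); A <- 6L
  pooled <- pooled_draws(fit)
  mu_d <- {
    m <- vapply(design$X, function(a) dim(a)[3L], 1L)
    internal <- pooled
    internal[, 2L] <- log(internal[, 2L])
    growth_mu_draws_cpp(internal, Y, S, A,
                        flatten_X(design$X[[1L]]), m[1L],
                        flatten_X(design$X[[2L]]), m[2L],
                        flatten_X(design$X[[3L]]), m[3L], fit$literal)
  }
  ndraw <- nrow(mu_d)
  yr <- seq_len(Y)
  yc <- yr - mean(yr)
  expected <- list(); trend <- list()
  for (a in seq_len(A)) {
    cols <- sapply(seq_len(Y), function(y)
      ((a - 1L) * S + seq_len(S) - 1L) * Y + y)
    site_avg <- sapply(seq_len(Y), function(y)
      rowMeans(mu_d[, cols[, y], drop = FALSE]))  # ndraw x Y
    qs <- apply(site_avg, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    expected[[a]] <- data.frame(year = design$years, age_class = a,
                                mean = colMeans(site_avg), lo95 = qs[1L, ],
                                hi95 = qs[2L, ])
    slopes <- as.vector(site_avg %*% yc / sum(yc^2))
    trend[[a]] <- data.frame(age_class = a, slope = mean(slopes),
                             lo95 = stats::quantile(slopes, 0.025,
                                                    names = FALSE),
                             hi95 = stats::quantile(slopes, 0.975,
                                                    names = FALSE))
  }
  list(expected = do.call(rbind, expected), trend = do.call(rbind, trend))
}

#' Marginal effect of one covariate on expected length
#'
#' Expected length across a grid of raw-unit covariate values, holding all
#' other covariates at their means (standardised 0) and, for sub-adult and
#' adult stages, the expected length of the previous age-class fixed at its
#' covariates-at-means baseline (computed per draw). The grid is converted to
#' standardised units with the stored mean/sd of the variable.
#'
#' @param fit a `growth_fit`.
#' @param variable covariate name (must be retained for `stage`).
#' @param stage life stage (1, 2 or 3).
#' @param grid raw-unit values of the covariate.
#' @param age representative age-class; defaults to 1, 2 and 3 for stages 1,
#'   2 and 3 (the youngest age of the stage).
#' @return data.frame with `raw`, `z`, `mean`, `lo95`, `hi95` (mm).
#' @export
marginal_effect <- function(fit, variable, stage, grid, age = NULL) {
  stopifnot(inherits(fit, "growth_fit"), stage %in% 1:3)
  vars <- fit$vars[[stage]]
  if (!(variable %in% vars))
    stop("variable '", variable, "' is not retained for stage ", stage)
  if (is.null(age)) age <- c(1L, 2L, 3L)[stage]
  stopifnot(stage_of_age(age) == stage)
  sc <- fit$scales[fit$scales$variable == variable, , drop = FALSE]
  z <- (grid - sc$mu[1L]) / sc$sigma[1L]
  pooled <- pooled_draws(fit)
  Linf <- pooled[, "Linf"]; K <- pooled[, "K"]; t0 <- pooled[, "t0"]
  th <- pooled[, sprintf("theta%d[%s]", stage, variable)]
  # covariates-at-means baseline of the previous age-class, per draw
  mu_prev <- Linf * vb_factor(1, K, t0)
  if (age > 1L) for (a in 2:age) {
    if (a < age) {
      inc <- (Linf - mu_prev) * vb_factor(a, K, t0)
      mu_prev <- if (fit$literal) inc else mu_prev + inc
    }
  }
  curve <- sapply(z, function(zi) {
    if (stage == 1L) Linf * vb_factor(1, K, t0) * exp(th * zi)
    else {
      inc <- (Linf - mu_prev) * vb_factor(age, K, t0) * exp(th * zi)
      if (fit$literal) inc else mu_prev + inc
    }
  })
  if (is.null(dim(curve))) curve <- matrix(curve, nrow = 1L)
  qs <- apply(curve, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  data.frame(raw = grid, z = z, mean = colMeans(curve), lo95 = qs[1L, ],
             hi95 = qs[2L, ])
}
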