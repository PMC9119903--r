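#' MCMC sampler settings
#'
#' Container for the Markov chain Monte Carlo run configuration shared by all
#' model-fitting functions in the package. Defaults follow the long-run
#' production settings (three parallel chains, 30,000 iterations, 20,000
#' burn-in, thinned to every 100th iteration); fitting functions override
#' `burn_in` where their own defaults differ.
#'
#' @param chains number of parallel chains (>= 2 required for the
#'   Gelman--Rubin diagnostic).
#' @param iterations total iterations per chain, including burn-in.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer master seed; mandatory for every stochastic run. Chain
#'   `c` uses `seed + c - 1`.
#' @return an object of class `mcmc_settings`.
#' @examples
#' mcmc_settings(iterations = 3000, burn_in = 1000, thin = 10, seed = 1)
#' @export
mcmc_settings <- function(chains = 3L, iterations = 30000L, burn_in = 20000L,
                          thin = 100L, seed = NULL) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  stopifnot(chains >= 1L, iterations >= 1L, thin >= 1L)
  if (burn_in >= iterations)
    stop("burn_in (", burn_in, ") must be smaller than iterations (",
         iterations, ")")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 thin = thin, seed = seed),
            class = "mcmc_settings")
}

n_retained <- function(settings) {
  (settings$iterations - settings$burn_in) %/% settings$thin
}

require_seed <- function(settings) {
  if (is.null(settings$seed))
    stop("an explicit seed is required for every stochastic run; ",
         "set it in mcmc_settings(seed = ...)")
  invisible(settings$seed)
}

#' Adaptive Metropolis-within-Gibbs sampler for a generic log-joint
#'
#' Runs `settings$chains` independent chains of a component-wise Gaussian
#' random-walk Metropolis sampler against an arbitrary log joint density.
#' Proposal standard deviations adapt on the log scale during burn-in
#' (Robbins--Monro, targeting an acceptance rate of 0.44) and are frozen
#' afterwards, so retained draws come from a fixed-kernel chain. Runs are
#' reproducible: chain `c` is seeded with `seed + c - 1`.
#'
#' @param log_joint function mapping a named numeric parameter vector to the
#'   log joint density (unnormalised).
#' @param init either a numeric vector of initial values (jittered per chain)
#'   or a `function(chain)` returning one (e.g. draws from the priors).
#' @param settings an [mcmc_settings()] object (seed required).
#' @param lower,upper optional named vectors of box constraints; proposals
#'   outside the box are rejected.
#' @param max_init_tries attempts to find a finite starting log-joint before
#'   giving up.
#' @return a `posterior_result`: list with `draws` (list of matrices, one per
#'   chain, retained iteration x parameter), `summary` (per-parameter mean,
#'   2.5/97.5 percentiles, R-hat), `rhat`, `converged`
#'   (all R-hat < 1.1), `accept_rate` and the settings used.
#' @seealso [gelman_rubin()], [summarise_draws()]
#' @export
run_mcmc <- function(log_joint, init, settings, lower = NULL, upper = NULL,
                     max_init_tries = 20L) {
  stopifnot(inherits(settings, "mcmc_settings"))
  require_seed(settings)
  init_fun <- if (is.function(init)) init else function(chain) {
    x <- init
    if (chain > 1L) x + stats::rnorm(length(x), 0, 0.1 * (abs(x) + 1))
    else x
  }
  probe <- if (is.function(init)) init(1L) else init
  pn <- names(probe)
  if (is.null(pn)) pn <- paste0("par", seq_along(probe))
  lo <- rep(-Inf, length(probe)); hi <- rep(Inf, length(probe))
  names(lo) <- names(hi) <- pn
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  keep <- n_retained(settings)
  draws <- vector("list", settings$chains)
  acc_all <- numeric(settings$chains)

  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + ch - 1L)
    x <- NULL
    for (try in seq_len(max_init_tries)) {
      cand <- init_fun(ch)
      names(cand) <- pn
      if (all(cand >= lo & cand <= hi) && is.finite(log_joint(cand))) {
        x <- cand; break
      }
    }
    if (is.null(x))
      stop("could not find a finite starting log-joint in ",
           max_init_tries, " attempts (chain ", ch, ")")
    lp <- log_joint(x)
    P <- length(x)
    lsd <- rep(0, P)  # log proposal sd
    out <- matrix(NA_real_, keep, P, dimnames = list(NULL, pn))
    n_acc <- 0L; n_prop <- 0L; k <- 0L
    for (it in seq_len(settings$iterations)) {
      for (j in seq_len(P)) {
        prop <- x
        prop[j] <- x[j] + stats::rnorm(1L, 0, exp(lsd[j]))
        ok <- prop[j] >= lo[j] && prop[j] <= hi[j]
        lpp <- if (ok) log_joint(prop) else -Inf
        alpha <- if (is.finite(lpp)) min(1, exp(lpp - lp)) else 0
        if (stats::runif(1L) < alpha) {
          x <- prop; lp <- lpp; n_acc <- n_acc + 1L
        }
        n_prop <- n_prop + 1L
        if (it <= settings$burn_in)
          lsd[j] <- lsd[j] + (alpha - 0.44) / sqrt(it)
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        k <- k + 1L
        out[k, ] <- x
      }
    }
    draws[[ch]] <- out[seq_len(k), , drop = FALSE]
    acc_all[ch] <- n_acc / n_prop
  }
  posterior_result(draws, settings, accept_rate = mean(acc_all))
}

#' Construct a posterior result object
#'
#' Bundles multi-chain draws with per-parameter summaries and convergence
#' diagnostics. Used by all fitting functions.
#'
#' @param draws list of per-chain matrices (retained iteration x parameter),
#'   identical column names across chains.
#' @param settings the [mcmc_settings()] used.
#' @param loglik optional pointwise log-likelihood matrix (pooled draw x
#'   observation) retained for leave-one-out cross-validation.
#' @param accept_rate optional mean Metropolis acceptance rate.
#' @return object of class `posterior_result` with elements `draws`,
#'   `summary`, `rhat`, `converged`, `loglik`, `settings`.
#' @export
posterior_result <- function(draws, settings, loglik = NULL,
                             accept_rate = NULL) {
  stopifnot(is.list(draws), length(draws) >= 1L)
  pn <- colnames(draws[[1L]])
  for (d in draws) stopifnot(identical(colnames(d), pn))
  rhat <- if (length(draws) >= 2L) {
    # a parameter whose chain never moved has zero within-chain variance;
    # treat that as (extreme) non-convergence rather than a hard failure
    tryCatch(gelman_rubin(draws),
             error = function(e) stats::setNames(rep(Inf, length(pn)), pn))
  } else stats::setNames(rep(NA_real_, length(pn)), pn)
  smry <- summarise_draws(draws)
  smry$rhat <- rhat[smry$parameter]
  converged <- all(is.na(rhat)) || all(rhat < 1.1, na.rm = TRUE)
  structure(list(draws = draws, summary = smry, rhat = rhat,
                 converged = converged, loglik = loglik,
                 accept_rate = accept_rate, settings = settings),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  nch <- length(x$draws)
  cat("Posterior result: ", nch, " chain(s) x ", nrow(x$draws[[1L]]),
      " retained draws, ", ncol(x$draws[[1L]]), " parameters\n", sep = "")
  if (!x$converged)
    cat("WARNING: convergence not reached (max R-hat = ",
        format(max(x$rhat, na.rm = TRUE), digits = 4), " >= 1.1)\n", sep = "")
  print(utils::head(x$summary, 12L), row.names = FALSE)
  if (nrow(x$summary) > 12L) cat("... ", nrow(x$summary) - 12L,
                                 " more parameters\n", sep = "")
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param x a `posterior_result`.
#' @return a matrix (pooled draw x parameter).
#' @export
pooled_draws <- function(x) {
  stopifnot(inherits(x, "posterior_result"))
  do.call(rbind, x$draws)
}

#' Gelman--Rubin potential scale reduction diagnostic
#'
#' Classic (non-split) R-hat comparing between- and within-chain variances:
#' with `m` chains of `n` draws, `W` the mean within-chain variance and `B/n`
#' the variance of chain means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.
#' Values below 1.1 are conventionally taken to indicate convergence and
#' well-mixed chains. A split-chain variant is available via `split = TRUE`.
#'
#' @param draws list of per-chain draw matrices (iteration x parameter), or a
#'   `posterior_result`.
#' @param split split each chain in half before computing (halves the
#'   within-chain sample but detects trends within chains).
#' @return named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(draws, split = FALSE) {
  if (inherits(draws, "posterior_result")) draws <- draws$draws
  stopifnot(is.list(draws), length(draws) >= 2L)
  if (split) {
    draws <- unlist(lapply(draws, function(d) {
      n2 <- nrow(d) %/% 2L
      list(d[seq_len(n2), , drop = FALSE],
           d[(n2 + 1L):(2L * n2), , drop = FALSE])
    }), recursive = FALSE)
  }
  n <- vapply(draws, nrow, 1L)
  if (any(n < 10L)) stop("need at least 10 retained draws per chain")
  if (length(unique(n)) != 1L) stop("chains have unequal lengths")
  n <- n[1L]
  pn <- colnames(draws[[1L]])
  means <- vapply(draws, colMeans, numeric(length(pn)))
  vars <- vapply(draws, function(d) apply(d, 2L, stats::var),
                 numeric(length(pn)))
  if (length(pn) == 1L) {
    means <- matrix(means, nrow = 1L); vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  if (any(W <= 0 | !is.finite(W)))
    stop("degenerate within-chain variance for parameter(s): ",
         paste(pn[W <= 0 | !is.finite(W)], collapse = ", "))
  B_over_n <- apply(means, 1L, stats::var)  # = B/n
  rhat <- sqrt((n - 1) / n + B_over_n / W)
  stats::setNames(rhat, pn)
}

#' Summarise posterior draws
#'
#' Posterior mean and equal-tailed 95% credible interval (2.5 and 97.5
#' empirical percentiles, linear-interpolation quantiles) per parameter from
#' pooled post-burn-in draws.
#'
#' @param draws list of per-chain matrices, a pooled matrix, or a
#'   `posterior_result`.
#' @return data.frame with columns `parameter`, `mean`, `lo95`, `hi95`.
#' @export
summarise_draws <- function(draws) {
  if (inherits(draws, "posterior_result")) draws <- draws$draws
  if (is.list(draws)) draws <- do.call(rbind, draws)
  q <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE)
  data.frame(parameter = colnames(draws), mean = colMeans(draws),
             lo95 = q[1L, ], hi95 = q[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}
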