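#' Model specification for the staged covariate structure
#'
#' Records, per life stage, the retained explanatory variables and the
#' lineage of removals that produced them (most recent last), so that the
#' simplification path is replayable and the last-removed variable per stage
#' can be re-added when building candidate full models.
#'
#' @param stages named list `stage1`/`stage2`/`stage3` of character vectors.
#' @param lineage named list of character vectors (removal order per stage).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(stages, lineage = list(stage1 = character(),
                                              stage2 = character(),
                                              stage3 = character())) {
  stopifnot(all(c("stage1", "stage2", "stage3") %in% names(stages)))
  structure(list(stages = stages, lineage = lineage), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  for (l in 1:3) {
    s <- x$stages[[paste0("stage", l)]]
    cat("stage ", l, ": ",
        if (length(s)) paste(s, collapse = ", ") else "(none)", "\n",
        sep = "")
    rem <- x$lineage[[paste0("stage", l)]]
    if (length(rem)) cat("  removed: ", paste(rem, collapse = " -> "), "\n",
                         sep = "")
  }
  invisible(x)
}

n_covariates <- function(spec) sum(lengths(spec$stages))

# 95% CrI and |mean|/sd of the stage-l coefficients of a fit
stage_coef_table <- function(fit, stage) {
  vars <- fit$vars[[stage]]
  if (!length(vars)) return(NULL)
  nm <- sprintf("theta%d[%s]", stage, vars)
  pooled <- pooled_draws(fit)[, nm, drop = FALSE]
  q <- apply(pooled, 2L, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE)
  data.frame(variable = vars, mean = colMeans(pooled),
             sd = apply(pooled, 2L, stats::sd), lo95 = q[1L, ],
             hi95 = q[2L, ], row.names = NULL)
}

#' Iterative within-stage covariate removal
#'
#' Repeatedly fits the model and removes stage-`stage` covariates whose 95%
#' credible interval contains zero ("intercepts zero"), until every retained
#' coefficient's interval excludes zero or the stage set is empty. By default
#' one variable is removed per refit — the one whose interval most centrally
#' straddles zero (smallest `|posterior mean| / sd`); `batch = TRUE` removes
#' all zero-straddling variables at once.
#'
#' @param spec a [model_spec()] holding the current per-stage sets.
#' @param stage the stage being simplified (1, 2 or 3).
#' @param fit_fun `function(stage_sets, fit_index)` returning a `growth_fit`;
#'   `fit_index` increments across refits so fit seeds can be derived from a
#'   master seed plus lineage position.
#' @param batch remove all zero-straddling variables per refit.
#' @param on_nonconvergence `"abort"` (error carrying the lineage so far) or
#'   `"warn"`.
#' @return the simplified [model_spec()] with updated lineage; the last fit
#'   is attached as attribute `"fit"`.
#' @export
simplify_stage <- function(spec, stage, fit_fun, batch = FALSE,
                           on_nonconvergence = c("abort", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  key <- paste0("stage", stage)
  fit_index <- 0L
  last_fit <- NULL
  repeat {
    if (!length(spec$stages[[key]])) break
    fit_index <- fit_index + 1L
    fit <- fit_fun(spec$stages, fit_index)
    last_fit <- fit
    if (!fit$converged) {
      msg <- paste0("non-convergence while simplifying stage ", stage,
                    " (lineage so far: ",
                    paste(spec$lineage[[key]], collapse = " -> "), ")")
      if (on_nonconvergence == "abort") stop(msg) else warning(msg)
    }
    tab <- stage_coef_table(fit, stage)
    straddle <- tab$lo95 <= 0 & tab$hi95 >= 0
    if (!any(straddle)) break
    zrat <- abs(tab$mean) / tab$sd
    drop_vars <- if (batch) tab$variable[straddle] else
      tab$variable[straddle][which.min(zrat[straddle])]
    spec$stages[[key]] <- setdiff(spec$stages[[key]], drop_vars)
    spec$lineage[[key]] <- c(spec$lineage[[key]], drop_vars)
  }
  attr(spec, "fit") <- last_fit
  spec
}

#' Staged simplification: juvenile, then sub-adult, then adult
#'
#' The saturated juvenile model is fitted with sub-adult and adult
#' covariates omitted and simplified; the retained juvenile variables are
#' carried forward while the saturated sub-adult set is simplified (adult
#' covariates still omitted); finally the saturated adult set is simplified
#' with the earlier stages fixed at their retained sets. The result is the
#' best-fitting full model.
#'
#' @param saturated a [model_spec()] with the saturated per-stage sets.
#' @param fit_fun `function(stage_sets, fit_index)` returning a `growth_fit`.
#' @inheritParams simplify_stage
#' @return the final [model_spec()]; the last (full-model) fit is attached as
#'   attribute `"fit"`.
#' @export
staged_simplification <- function(saturated, fit_fun, batch = FALSE,
                                  on_nonconvergence = c("abort", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  spec <- model_spec(list(stage1 = saturated$stages$stage1,
                          stage2 = character(), stage3 = character()),
                     saturated$lineage)
  offset <- 0L
  for (l in 1:3) {
    key <- paste0("stage", l)
    spec$stages[[key]] <- saturated$stages[[key]]
    wrapped <- local({
      off <- offset
      function(stage_sets, fit_index) fit_fun(stage_sets, off + fit_index)
    })
    spec <- simplify_stage(spec, l, wrapped, batch = batch,
                           on_nonconvergence = on_nonconvergence)
    offset <- offset + length(spec$lineage[[key]]) + 1L
  }
  spec
}

#' Candidate full models by last-removal re-addition
#'
#' One candidate per life stage: the full model plus the last explanatory
#' variable removed for that stage during simplification. Stages with no
#' removals yield no candidate (noted by absence from the result).
#'
#' @param full the final [model_spec()] from [staged_simplification()].
#' @return named list of [model_spec()] objects (possibly empty), names
#'   `"stage1"`, `"stage2"`, `"stage3"`.
#' @export
candidate_full_models <- function(full) {
  out <- list()
  for (l in 1:3) {
    key <- paste0("stage", l)
    lin <- full$lineage[[key]]
    if (!length(lin)) next
    cand <- full
    cand$stages[[key]] <- c(cand$stages[[key]], lin[length(lin)])
    cand$lineage <- lapply(cand$lineage, function(x) x)  # keep lineage
    out[[key]] <- cand
  }
  out
}

# ---- PSIS-LOO ------------------------------------------------------------

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalised Pareto fit to exceedances (profile posterior-mean estimator
# of Zhang & Stephens 2009, with the weak shape prior of the published PSIS
# algorithm). x must be positive.
gpd_fit <- function(x) {
  x <- sort.int(x)
  N <- length(x)
  if (N < 5L || x[N] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  kj <- vapply(theta, function(a) -mean(log1p(-a * x)), 0)
  l_theta <- N * (log(theta / kj) + kj - 1)
  w <- exp(l_theta - log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (k * N + 5) / (N + 10)  # weakly informative shape prior
  list(k = k, sigma = sigma)
}

q_gpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * ((1 - p)^(-k) - 1) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out cross-validation from a pointwise log-likelihood matrix
#' over posterior draws, using Pareto-smoothed importance sampling: per
#' observation, the importance ratios `1 / p(y_i | theta_s)` have their
#' largest 20% (capped at `3 sqrt(S)`) replaced by expected order statistics
#' of a generalised Pareto distribution fitted to the tail, then truncated
#' at the raw maximum. The tail-shape diagnostic `k` is reported per
#' observation; estimates with `k > 0.7` are unreliable.
#'
#' @param loglik matrix of pointwise log-likelihoods (draw x observation).
#' @return object of class `loo_result`: `pointwise` (elpd_i, pareto_k),
#'   `elpd`, `se`, `looic` (`= -2 elpd`), `n_high_k`, `unreliable` (flag set
#'   when more than 10% of observations have `k > 0.7`).
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), all(is.finite(loglik)))
  S <- nrow(loglik); n <- ncol(loglik)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  elpd_i <- numeric(n); khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    k <- NA_real_
    if (tail_len >= 5L && stats::sd(lw) > 0) {
      ord <- order(lw)
      tail_ids <- ord[(S - tail_len + 1L):S]
      cut <- lw[ord[S - tail_len]]
      exc <- exp(lw[tail_ids]) - exp(cut)
      fit <- gpd_fit(exc)
      k <- fit$k
      if (is.finite(k)) {
        p <- (seq_len(tail_len) - 0.5) / tail_len
        smoothed <- log(q_gpd(p, k, fit$sigma) + exp(cut))
        lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
      }
    }
    khat[i] <- k
    elpd_i[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
  }
  n_high <- sum(khat > 0.7, na.rm = TRUE)
  unreliable <- n_high > 0.1 * n
  if (unreliable)
    warning(n_high, " of ", n, " observations have Pareto k > 0.7; ",
            "PSIS-LOO estimates may be unreliable")
  structure(list(pointwise = data.frame(elpd = elpd_i, pareto_k = khat),
                 elpd = sum(elpd_i),
                 se = sqrt(n * stats::var(elpd_i)),
                 looic = -2 * sum(elpd_i), n_high_k = n_high,
                 unreliable = unreliable, n = n, S = S),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("PSIS-LOO (", x$S, " draws, ", x$n, " observations)\n", sep = "")
  cat("  elpd = ", format(x$elpd, digits = 6), " (se ",
      format(x$se, digits = 3), ")\n", sep = "")
  cat("  LOOIC = ", format(x$looic, digits = 6), "\n", sep = "")
  cat("  Pareto k > 0.7: ", x$n_high_k, " observation(s)\n", sep = "")
  if (x$unreliable) cat("  WARNING: estimates may be unreliable\n")
  invisible(x)
}

#' Select the inference model by LOOIC
#'
#' Picks the model with the lowest LOOIC; when models are within one
#' standard error of the pairwise elpd difference from the best, the most
#' parsimonious (fewest covariates) of those is chosen.
#'
#' @param loos named list of `loo_result` objects over the same
#'   observations; the first is conventionally the full model.
#' @param specs named list of matching [model_spec()] objects.
#' @return list with `chosen` (name), `spec`, and a comparison `table`
#'   (name, looic, elpd, se_diff vs best, n_covariates).
#' @export
select_model <- function(loos, specs) {
  stopifnot(length(loos) >= 1L, identical(names(loos), names(specs)))
  ns <- vapply(loos, function(l) l$n, 1L)
  if (length(unique(ns)) != 1L)
    stop("models were evaluated on different observation sets")
  elpd <- vapply(loos, function(l) l$elpd, 0)
  looic <- vapply(loos, function(l) l$looic, 0)
  npar <- vapply(specs, n_covariates, 0L)
  best <- which.max(elpd)
  se_diff <- vapply(seq_along(loos), function(i) {
    if (i == best) return(0)
    d <- loos[[i]]$pointwise$elpd - loos[[best]]$pointwise$elpd
    sqrt(length(d) * stats::var(d))
  }, 0)
  eligible <- which(elpd[best] - elpd <= se_diff | seq_along(loos) == best)
  chosen <- eligible[order(npar[eligible], -elpd[eligible])][1L]
  tab <- data.frame(model = names(loos), looic = looic, elpd = elpd,
                    se_diff_vs_best = se_diff, n_covariates = npar,
                    row.names = NULL)
  list(chosen = names(loos)[chosen], spec = specs[[chosen]],
       table = tab[order(tab$looic), , drop = FALSE])
}
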