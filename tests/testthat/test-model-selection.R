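# Build a stand-in growth fit whose stage coefficients have prescribed
# posterior means/sds, so the removal logic can be tested deterministically
# without MCMC.
fake_fit <- function(stage_sets, means, sds, seed = 1, ndraw = 400) {
  set.seed(seed)
  cols <- list()
  for (l in 1:3) for (v in stage_sets[[paste0("stage", l)]]) {
    nm <- sprintf("theta%d[%s]", l, v)
    key <- paste0(l, ".", v)
    cols[[nm]] <- stats::rnorm(2 * ndraw, means[[key]], sds[[key]])
  }
  m <- do.call(cbind, cols)
  draws <- list(m[seq_len(ndraw), , drop = FALSE],
                m[ndraw + seq_len(ndraw), , drop = FALSE])
  structure(list(draws = draws, vars = unname(stage_sets),
                 converged = TRUE),
            class = c("growth_fit", "posterior_result"))
}

test_that("within-stage removal drops the most central zero-straddler first", {
  sets <- list(stage1 = c("A", "B", "C"), stage2 = character(),
               stage3 = character())
  means <- list("1.A" = 1, "1.B" = 0.01, "1.C" = 0.3)
  sds <- list("1.A" = 0.1, "1.B" = 1, "1.C" = 1)
  calls <- list()
  fit_fun <- function(stage_sets, fit_index) {
    calls[[length(calls) + 1]] <<- stage_sets
    fake_fit(stage_sets, means, sds, seed = 10 + fit_index)
  }
  out <- simplify_stage(model_spec(sets), 1, fit_fun)
  expect_identical(out$stages$stage1, "A")
  expect_identical(out$lineage$stage1, c("B", "C"))
  expect_length(calls, 3L)  # saturated, after B removed, after C removed
  # empty saturated set returned unchanged without fitting
  empty <- model_spec(list(stage1 = character(), stage2 = character(),
                           stage3 = character()))
  expect_identical(simplify_stage(empty, 1, fit_fun)$stages$stage1,
                   character())
})

test_that("batch removal drops every zero-straddler per refit", {
  sets <- list(stage1 = c("A", "B", "C"), stage2 = character(),
               stage3 = character())
  means <- list("1.A" = 1, "1.B" = 0.01, "1.C" = 0.3)
  sds <- list("1.A" = 0.1, "1.B" = 1, "1.C" = 1)
  n_fits <- 0
  fit_fun <- function(stage_sets, fit_index) {
    n_fits <<- n_fits + 1
    fake_fit(stage_sets, means, sds, seed = 20 + fit_index)
  }
  out <- simplify_stage(model_spec(sets), 1, fit_fun, batch = TRUE)
  expect_identical(out$stages$stage1, "A")
  expect_setequal(out$lineage$stage1, c("B", "C"))
  expect_identical(n_fits, 2)  # saturated + confirmation refit
})

test_that("staged simplification omits later stages while earlier ones are simplified", {
  sets <- list(stage1 = c("A", "B"), stage2 = c("D", "E"),
               stage3 = c("F"))
  means <- list("1.A" = 1, "1.B" = 0, "2.D" = 0, "2.E" = -1, "3.F" = 1)
  sds <- list("1.A" = 0.1, "1.B" = 0.5, "2.D" = 0.5, "2.E" = 0.1,
              "3.F" = 0.1)
  seen <- list()
  fit_fun <- function(stage_sets, fit_index) {
    seen[[length(seen) + 1]] <<- stage_sets
    fake_fit(stage_sets, means, sds, seed = 30 + fit_index)
  }
  full <- staged_simplification(model_spec(sets), fit_fun)
  expect_identical(full$stages$stage1, "A")
  expect_identical(full$stages$stage2, "E")
  expect_identical(full$stages$stage3, "F")
  # while stage 1 was being simplified, stages 2 and 3 were omitted
  first_calls <- seen[vapply(seen, function(s) length(s$stage3) == 0 &&
                               length(s$stage2) == 0, TRUE)]
  expect_gte(length(first_calls), 2L)
  # candidate construction: one per stage with removals, differing by one
  cands <- candidate_full_models(full)
  expect_named(cands, c("stage1", "stage2"))
  expect_setequal(cands$stage1$stages$stage1, c("A", "B"))
  expect_identical(cands$stage1$stages$stage2, full$stages$stage2)
  expect_identical(candidate_full_models(model_spec(sets)), list())
})

test_that("PSIS-LOO reduces to the plain log-likelihood under zero-variance weights", {
  ll <- matrix(rep(c(-1.3, -2.1, -0.7), each = 50), nrow = 50)
  res <- psis_loo(ll)
  expect_equal(res$pointwise$elpd, c(-1.3, -2.1, -0.7))
  expect_equal(res$looic, -2 * sum(c(-1.3, -2.1, -0.7)))
})

test_that("PSIS-LOO matches analytic leave-one-out for a conjugate Normal mean", {
  # y_i ~ N(mu, 1), mu ~ N(0, 10^2): every leave-one-out posterior and
  # predictive density is available in closed form
  set.seed(14)
  n <- 30; y <- stats::rnorm(n, 1.2, 1)
  prior_prec <- 1 / 100
  post <- function(yy) {
    prec <- prior_prec + length(yy)
    list(m = sum(yy) / prec, v = 1 / prec)
  }
  S <- 4000
  pst <- post(y)
  mu_draws <- stats::rnorm(S, pst$m, sqrt(pst$v))
  ll <- outer(mu_draws, y, function(m, yi) stats::dnorm(yi, m, 1,
                                                        log = TRUE))
  res <- psis_loo(ll)
  exact <- vapply(seq_len(n), function(i) {
    p <- post(y[-i])
    stats::dnorm(y[i], p$m, sqrt(1 + p$v), log = TRUE)
  }, 0)
  d <- res$pointwise$elpd - exact
  expect_lt(abs(sum(d)), 2 * max(sqrt(n * stats::var(d)), 0.05))
  expect_true(all(res$pointwise$pareto_k < 0.7, na.rm = TRUE))
  expect_equal(res$se, sqrt(n * stats::var(res$pointwise$elpd)))
})

test_that("model selection prefers parsimony within one elpd standard error", {
  set.seed(5)
  base <- matrix(stats::rnorm(200 * 20, -1.5, 0.3), 200, 20)
  loo_a <- psis_loo(base)
  loo_b <- psis_loo(base)      # exactly tied with loo_a
  loo_c <- psis_loo(base - 0.8)  # clearly worse
  spec_small <- model_spec(list(stage1 = "A", stage2 = character(),
                                stage3 = character()))
  spec_big <- model_spec(list(stage1 = c("A", "B", "C"),
                              stage2 = "D", stage3 = character()))
  sel <- select_model(list(big = loo_a, small = loo_b),
                      list(big = spec_big, small = spec_small))
  expect_identical(sel$chosen, "small")
  sel2 <- select_model(list(good = loo_a, bad = loo_c),
                       list(good = spec_big, bad = spec_small))
  expect_identical(sel2$chosen, "good")
  one <- select_model(list(only = loo_a), list(only = spec_small))
  expect_identical(one$chosen, "only")
  short <- psis_loo(base[, 1:10])
  expect_error(select_model(list(a = loo_a, b = short),
                            list(a = spec_big, b = spec_small)),
               "different observation")
})
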