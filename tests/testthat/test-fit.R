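test_that("probit transforms round-trip all bounded parameters", {
  for (model in c("vpp", "pvl_delta", "pvl_decay")) {
    pt <- get_model(model)$params
    set.seed(3)
    for (i in 1:20) {
      v <- setNames(runif(nrow(pt), pmax(pt$lower, -3) + 0.01,
                          pmin(pt$upper, 3) - 0.01), pt$param)
      z <- igtrl:::to_unconstrained(as.list(v), model)
      back <- igtrl:::to_natural(z, model)
      expect_equal(unname(back), unname(v), tolerance = 1e-10)
    }
  }
})

test_that("MAP fitting is deterministic and labels its subjects", {
  sched <- igt_schedule(seed = 2)
  coh <- generate_cohort(
    cohort_spec("G", 3, means = c(A = 0.2, alpha = 1, cons = 1.5, lambda = 1),
                sds = c(A = 0.05, alpha = 0.1, cons = 0.2, lambda = 0.2),
                model = "pvl_delta"),
    sched, seed = 3)
  f1 <- fit_map(coh$trials, "pvl_delta", seed = 5)
  f2 <- fit_map(coh$trials, "pvl_delta", seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$estimates$subjID, coh$truth$subjID)
  long <- tidy(f1)
  expect_setequal(unique(long$param), c("A", "alpha", "cons", "lambda"))
  g <- glance(f1)
  expect_identical(g$n_subjects, 3L)
  expect_identical(g$n_failed, 0L)
})

test_that("MAP recovers generating parameters from a long history", {
  sched <- igt_schedule(seed = 0, n_trials = 2000)
  truth <- pvl_delta_params(0.2, 1.0, 1.5, 1.0)
  ag <- simulate_agent(truth, "pvl_delta", sched, seed = 3, n_trials = 2000)
  fit <- fit_map(ag, "pvl_delta", seed = 1)
  expect_lt(abs(fit$estimates$cons - 1.5) / 1.5, 0.2)
  expect_lt(abs(fit$estimates$alpha - 1.0) / 1.0, 0.2)
})

test_that("random responding yields a near-zero consistency estimate", {
  sched <- igt_schedule(seed = 2)
  ag <- simulate_agent(vpp_params(0.5, 1, 0, 1), "vpp", sched, seed = 4)
  fit <- fit_map(ag, "pvl_delta", seed = 2)
  expect_lt(fit$estimates$cons, 0.5)
  expect_false(fit$diagnostics$failed)
})

test_that("the optimum is at least as good as the generating parameters", {
  sched <- igt_schedule(seed = 2)
  coh <- generate_cohort(mud_cohort_spec(n = 10), sched, seed = 8)
  fit <- fit_map(coh$trials, "vpp", seed = 3)
  pt <- get_model("vpp")$params
  hits <- 0
  for (i in 1:10) {
    d <- dplyr::filter(coh$trials, subjID == coh$truth$subjID[i])
    z_true <- igtrl:::to_unconstrained(as.list(coh$truth[i, pt$param]), "vpp")
    obj <- igtrl:::make_objective(igtrl:::single_subject_trials(d), "vpp",
                                  prior_spec("vpp"), 100)
    hits <- hits + (fit$diagnostics$logpost[i] >= obj(z_true) - 1e-6)
  }
  expect_gte(hits, 9.5)
})

test_that("Laplace draws give valid pointwise log-likelihood matrices", {
  sched <- igt_schedule(seed = 2)
  coh <- generate_cohort(
    cohort_spec("G", 3, means = c(A = 0.2, alpha = 1, cons = 1.5, lambda = 1),
                sds = c(A = 0.05, alpha = 0.1, cons = 0.2, lambda = 0.2),
                model = "pvl_delta"),
    sched, seed = 3)
  fit <- fit_map(coh$trials, "pvl_delta", seed = 5, laplace_draws = 50)
  for (pw in fit$pointwise) {
    expect_identical(dim(pw), c(50L, 100L))
    expect_true(all(pw <= 0))
  }
  for (dr in fit$draws) {
    pt <- get_model("pvl_delta")$params
    for (i in seq_len(nrow(pt))) {
      expect_true(all(dr[, pt$param[i]] >= pt$lower[i] &
                        dr[, pt$param[i]] <= pt$upper[i]))
    }
  }
})

test_that("hierarchical sampling is seeded, shrinks estimates and flags R-hat", {
  sched <- igt_schedule(seed = 2)
  coh <- generate_cohort(
    cohort_spec("G", 8, means = c(A = 0.2, alpha = 1, cons = 1.5, lambda = 1),
                sds = c(A = 0.05, alpha = 0.1, cons = 0.3, lambda = 0.3),
                model = "pvl_delta"),
    sched, seed = 13)
  h1 <- suppressWarnings(fit_hierarchical(coh$trials, "pvl_delta", seed = 5,
                                          chains = 2, iter = 300, warmup = 150))
  h2 <- suppressWarnings(fit_hierarchical(coh$trials, "pvl_delta", seed = 5,
                                          chains = 2, iter = 300, warmup = 150))
  expect_identical(h1$estimates, h2$estimates)
  expect_identical(h1$settings$n_draws, 300L)
  expect_true(all(c("rhat", "ess") %in% names(h1$diagnostics_mcmc)))
  # every sampled quantity is covered: 4 group means + 4 scales + 8 x 4 subject
  expect_identical(nrow(h1$diagnostics_mcmc), 40L)
  # shrinkage: hierarchical subject estimates vary less than MAP estimates
  m <- fit_map(coh$trials, "pvl_delta", seed = 5)
  shrunk <- sum(sapply(c("A", "alpha", "cons", "lambda"), function(p)
    var(h1$estimates[[p]]) <= var(m$estimates[[p]])))
  expect_gte(shrunk, 3)
  # pointwise draws exist for downstream criteria
  expect_identical(dim(h1$pointwise[[1]]), c(300L, 100L))
})

test_that("hierarchical group-level mean covers the truth for the learning rate", {
  sched <- igt_schedule(seed = 0)
  coh <- generate_cohort(hc_cohort_spec(n = 15), sched, seed = 5)
  fit <- suppressWarnings(fit_hierarchical(coh$trials, "vpp", seed = 9,
                                           iter = 600, warmup = 300))
  mu_A <- 1 * pnorm(fit$group_draws$mu[, "A"])
  ci <- quantile(mu_A, c(0.025, 0.975))
  expect_gte(mean(coh$truth$A), ci[1] - 0.02)
  expect_lte(mean(coh$truth$A), ci[2] + 0.02)
})

test_that("a one-subject cohort degrades gracefully", {
  sched <- igt_schedule(seed = 2)
  ag <- simulate_agent(pvl_delta_params(0.3, 1, 1.5, 1), "pvl_delta",
                       sched, seed = 6)
  fit <- suppressWarnings(fit_hierarchical(ag, "pvl_delta", seed = 3,
                                           chains = 2, iter = 200,
                                           warmup = 100))
  expect_identical(nrow(fit$estimates), 1L)
  expect_true(all(is.finite(as.matrix(fit$group_draws$mu))))
})

test_that("posterior prediction reproduces the fitted cohort's learning curve", {
  sched <- igt_schedule(seed = 2)
  coh <- generate_cohort(
    cohort_spec("G", 6, means = c(A = 0.25, alpha = 1, cons = 2, lambda = 2),
                sds = c(A = 0.03, alpha = 0.05, cons = 0.2, lambda = 0.2),
                model = "pvl_delta"),
    sched, seed = 7)
  fit <- fit_map(coh$trials, "pvl_delta", seed = 5)
  empty <- posterior_predict(fit, coh$trials, sched, n_reps = 0)
  expect_identical(nrow(empty$blocks), 0L)
  pp1 <- posterior_predict(fit, coh$trials, sched, n_reps = 10, seed = 3)
  pp2 <- posterior_predict(fit, coh$trials, sched, n_reps = 10, seed = 3)
  expect_identical(pp1$blocks, pp2$blocks)
  expect_identical(nrow(pp1$blocks), 5L)
  # plug-in predictive tracks the observed curve reasonably closely
  expect_lt(mean(abs(pp1$blocks$observed - pp1$blocks$predicted)), 0.15)
  expect_equal(sum(pp1$decks$predicted), 1, tolerance = 1e-10)
})
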