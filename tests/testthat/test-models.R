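test_that("prospect utility follows the gain/loss power form", {
  expect_identical(utility_pv(0, 0.5, 2), 0)
  expect_identical(utility_pv(100, 1, 3), 100)
  expect_identical(utility_pv(-100, 0.5, 2), -20)
  expect_equal(utility_pv(c(4, -4), 0.5, 1.5), c(2, -3))
})

test_that("EV utility weighs gains against losses linearly", {
  expect_identical(utility_ev(100, 0, 0.5), 50)
  expect_identical(utility_ev(0, 1250, 0.5), -625)
  expect_identical(utility_ev(100, 100, 1), 100)
})

test_that("delta rule moves toward the utility and contracts onto it", {
  expect_identical(delta_update(0, 1, 0.5), 0.5)
  expect_identical(delta_update(3, 7, 0), 3)
  expect_identical(delta_update(3, 7, 1), 7)
  # repeated application with constant u converges to u
  e <- -5
  for (i in 1:200) e <- delta_update(e, 2, 0.3)
  expect_equal(e, 2, tolerance = 1e-10)
  # bounded between E_prev and u
  for (a in seq(0, 1, by = 0.1)) {
    v <- delta_update(-1, 4, a)
    expect_true(v >= -1 && v <= 4)
  }
})

test_that("decay rule discounts all decks and credits the chosen one", {
  expect_equal(decay_update(c(1, 1, 1, 1), 0, 1, 0.5), rep(0.5, 4))
  expect_equal(decay_update(c(0, 0, 0, 0), 2, 3, 0.9), c(0, 0, 2, 0))
  expect_equal(decay_update(c(5, 5, 5, 5), 2, 2, 0), c(0, 2, 0, 0))
})

test_that("perseverance decays globally and pulses on the chosen deck", {
  expect_equal(perseverance_update(c(0, 0, 0, 0), 1, 50, 0.5, 1, -1),
               c(1, 0, 0, 0))
  expect_equal(perseverance_update(c(3, 3, 3, 3), 2, 10, 0, 2, -2),
               c(0, 2, 0, 0))
  # loss pulse on a decayed previous strength: 0.5 * 2 - 0.5
  expect_equal(perseverance_update(c(2, 0, 0, 0), 1, -1250, 0.5, 1, -0.5)[1],
               0.5)
  # break-even counts as a gain
  expect_equal(perseverance_update(c(0, 0, 0, 0), 4, 0, 0.5, 7, -7)[4], 7)
})

test_that("value combination interpolates expectancy and perseverance", {
  E <- c(2, 0, 0, 0)
  P <- c(0, 2, 0, 0)
  expect_equal(combine_value(E, P, 1), E)
  expect_equal(combine_value(E, P, 0), P)
  expect_equal(combine_value(E, P, 0.5), c(1, 1, 0, 0))
})

test_that("sensitivity is 3^cons - 1", {
  expect_identical(sensitivity(0), 0)
  expect_identical(sensitivity(1), 2)
  expect_identical(sensitivity(5), 242)
  cons <- seq(0, 5, by = 0.25)
  expect_true(all(diff(sensitivity(cons)) > 0))
})

test_that("softmax probabilities are proper, shift-invariant and safe", {
  expect_equal(choice_probs(rep(3.7, 4), 5), rep(0.25, 4))
  expect_equal(choice_probs(c(9, -4, 0, 2), 0), rep(0.25, 4))
  p <- choice_probs(c(1, 0, 0, 0), log(3))
  expect_equal(p, c(0.5, 1 / 6, 1 / 6, 1 / 6))
  set.seed(1)
  for (i in 1:20) {
    V <- rnorm(4, sd = 5)
    th <- runif(1, 0, 10)
    expect_equal(sum(choice_probs(V, th)), 1, tolerance = 1e-12)
    expect_equal(choice_probs(V, th), choice_probs(V + 123.4, th),
                 tolerance = 1e-12)
  }
  # extreme values do not overflow
  expect_equal(sum(choice_probs(c(500, -500, 0, 0), 242)), 1)
  expect_error(choice_probs(c(1, NA, 0, 0), 1), "Non-finite")
})

test_that("a zero-consistency model gives uniform sequence likelihood", {
  sched <- igt_schedule(seed = 1)
  tr <- withr::with_seed(2, random_trials(sched))
  p <- vpp_params(0.5, 1, 0, 1, 1, -1, 0.5, 0.5)
  expect_equal(sequence_loglik(tr, p)$total, 100 * log(1 / 4),
               tolerance = 1e-12)
})

test_that("five-trial toy sequence matches a step-by-step hand computation", {
  toy <- tibble::tibble(
    subjID = "t", trial = 1:5,
    choice = c("B", "B", "A", "C", "D"),
    gain = c(100, 100, 100, 50, 50),
    loss = c(0, 1250, 0, 0, 0)
  )
  p <- list(A = 0.5, alpha = 1, cons = 1, lambda = 1,
            epP = 0, epN = 0, K = 0, w = 1)
  got <- sequence_loglik(toy, vpp_params(0.5, 1, 1, 1, 0, 0, 0, 1))
  # hand computation: theta = 2, outcomes scaled by 100
  E <- c(0, 0, 0, 0)
  expected <- log(0.25)                              # trial 1, all E = 0
  E[2] <- 0.5 * 1                                    # u(+100/100) = 1
  expected <- expected + (2 * E[2] - log(sum(exp(2 * E))))  # trial 2 on B
  E[2] <- E[2] + 0.5 * (-11.5 - E[2])                # u(-1150/100) = -11.5
  expected <- expected + (2 * E[1] - log(sum(exp(2 * E))))  # trial 3 on A
  E[1] <- 0.5 * 1
  expected <- expected + (2 * E[3] - log(sum(exp(2 * E))))  # trial 4 on C
  E[3] <- 0.5 * 0.5
  expected <- expected + (2 * E[4] - log(sum(exp(2 * E))))  # trial 5 on D
  expect_equal(got$total, expected, tolerance = 1e-12)
  oracle <- oracle_loglik(toy, p, "vpp")
  expect_equal(got$total, oracle$total, tolerance = 1e-12)
})

test_that("vectorized likelihood agrees with the scalar oracle on random draws", {
  sched <- igt_schedule(seed = 5)
  set.seed(11)
  for (i in 1:100) {
    model <- sample(c("vpp", "pvl_delta", "pvl_decay"), 1)
    pars <- random_params(model)
    tr <- random_trials(sched)
    got <- sequence_loglik(tr, pars, model)
    want <- oracle_loglik(tr, pars, model)
    expect_equal(got$total, want$total, tolerance = 1e-10)
    expect_equal(got$pointwise, want$pointwise, tolerance = 1e-10)
  }
})

test_that("VPP with w = 1 and no perseverance impacts nests PVL-Delta", {
  sched <- igt_schedule(seed = 9)
  set.seed(21)
  for (i in 1:50) {
    base <- random_params("pvl_delta")
    tr <- random_trials(sched)
    ll_vpp <- sequence_loglik(
      tr, vpp_params(base$A, base$alpha, base$cons, base$lambda,
                     epP = 0, epN = 0, K = runif(1), w = 1))
    ll_pvl <- sequence_loglik(
      tr, pvl_delta_params(base$A, base$alpha, base$cons, base$lambda))
    expect_identical(ll_vpp$total, ll_pvl$total)
  }
})

test_that("higher consistency raises the likelihood of greedy sequences", {
  # a sequence generated by a very consistent agent should become more
  # likely as cons grows toward the generating value
  sched <- igt_schedule(seed = 4)
  greedy <- simulate_agent(vpp_params(0.3, 1, 4, 1), "vpp", sched, seed = 8)
  lls <- sapply(seq(0, 4, by = 0.5), function(cons)
    sequence_loglik(greedy, vpp_params(0.3, 1, cons, 1))$total)
  expect_true(all(diff(lls) > 0))
})

test_that("parameter constructors reject out-of-bound values", {
  expect_error(vpp_params(1.2, 1, 1, 1), "out of bounds")
  expect_error(pvl_delta_params(0.5, 2.5, 1, 1), "out of bounds")
  expect_error(pvl_decay_params(0.5, 1, 6, 1), "out of bounds")
  expect_error(vpp_params(0.5, 1, 1, 1, K = 1.4), "out of bounds")
  expect_error(sequence_loglik(tibble::tibble(
    subjID = "s", trial = 1:2, choice = c("A", "B"), gain = 0, loss = 0),
    list(A = 0.5), "no_such_model"), "Unknown model")
})

test_that("plug-in models join the registry and dispatch through it", {
  def <- list(
    params = tibble::tibble(param = "bias", lower = 0, upper = 1,
                            bounded = TRUE),
    loglik = function(trials, params, outcome_scale) {
      n <- nrow(trials)
      pw <- ifelse(trials$choice == "A", log(params$bias),
                   log((1 - params$bias) / 3))
      list(total = sum(pw), pointwise = pw)
    }
  )
  register_igt_model("biased_coin", def)
  withr::defer(
    assign("models",
           igtrl:::.igtrl_registry$models[
             setdiff(names(igtrl:::.igtrl_registry$models), "biased_coin")],
           envir = igtrl:::.igtrl_registry))
  tr <- tibble::tibble(subjID = "s", trial = 1:4,
                       choice = c("A", "A", "B", "C"), gain = 0, loss = 0)
  got <- sequence_loglik(tr, list(bias = 0.4), "biased_coin")
  expect_equal(got$total, 2 * log(0.4) + 2 * log(0.2))
})
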