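#' Prospect-valence utility of a net outcome
#'
#' Evaluates the prospect-theory utility used by the PVL and VPP models:
#' gains of magnitude `x` map to `x^alpha`, losses to `-lambda * |x|^alpha`.
#' `alpha < 1` compresses large amplitudes; `lambda > 1` makes losses loom
#' larger than equal gains. Vectorised over `x`.
#'
#' @param x Net outcome(s), typically rescaled (see `outcome_scale` in
#'   [sequence_loglik()]).
#' @param alpha Outcome sensitivity, (0, 2).
#' @param lambda Loss aversion, \[0, 5\].
#' @return Numeric utility, same length as `x`.
#' @export
#' @examples
#' utility_pv(c(100, -100), alpha = 0.5, lambda = 2)
utility_pv <- function(x, alpha, lambda) {
  stopifnot(alpha >= 0, alpha <= 2, lambda >= 0, lambda <= 5)
  ifelse(x >= 0, abs(x)^alpha, -lambda * abs(x)^alpha)
}

#' Expectancy-valence utility of a gain/loss pair
#'
#' The linear utility that weighs gains against losses with a single weight:
#' `w_ev * win - (1 - w_ev) * loss`. Provided as an alternative utility
#' option; no standalone EV model fit is offered.
#'
#' @param win,loss Non-negative gain and loss magnitudes.
#' @param w_ev Gain-versus-loss weight in \[0, 1\].
#' @return Numeric utility.
#' @export
utility_ev <- function(win, loss, w_ev) {
  stopifnot(w_ev >= 0, w_ev <= 1, all(win >= 0), all(loss >= 0))
  w_ev * win - (1 - w_ev) * loss
}

#' Delta-rule expectancy update
#'
#' Moves the chosen deck's expectancy toward the received utility by fraction
#' `A`: `E + A * (u - E)`. Unchosen decks are unchanged by convention; this
#' helper operates on the chosen deck's scalar expectancy.
#'
#' @param E_prev Previous expectancy.
#' @param u Received utility.
#' @param A Learning rate in \[0, 1\].
#' @return Updated expectancy, bounded between `E_prev` and `u`.
#' @export
delta_update <- function(E_prev, u, A) {
  stopifnot(A >= 0, A <= 1)
  E_prev + A * (u - E_prev)
}

#' Decay-rule expectancy update
#'
#' All four deck expectancies decay multiplicatively by `A`; the chosen deck
#' additionally receives the full utility of the outcome.
#'
#' @param E Length-4 expectancy vector.
#' @param u Received utility.
#' @param chosen Chosen deck index 1-4.
#' @param A Decay rate in \[0, 1\].
#' @return Updated length-4 expectancy vector.
#' @export
decay_update <- function(E, u, chosen, A) {
  stopifnot(length(E) == 4, chosen %in% 1:4, A >= 0, A <= 1)
  E <- A * E
  E[chosen] <- E[chosen] + u
  E
}

#' Perseverance-strength update
#'
#' All decks' perseverance strengths decay by `K`; the chosen deck then
#' receives an impulse `epP` after a non-negative net outcome or `epN` after
#' a loss. Positive impulses favour staying with the same deck, negative ones
#' favour switching.
#'
#' @param P Length-4 perseverance vector.
#' @param chosen Chosen deck index 1-4.
#' @param net Net outcome of the trial (sign decides the impulse).
#' @param K Decay rate in \[0, 1\].
#' @param epP,epN Gain / loss perseverance impacts.
#' @return Updated length-4 perseverance vector.
#' @export
perseverance_update <- function(P, chosen, net, K, epP, epN) {
  stopifnot(length(P) == 4, chosen %in% 1:4, K >= 0, K <= 1)
  P <- K * P
  P[chosen] <- P[chosen] + if (net >= 0) epP else epN
  P
}

#' Combine expectancy and perseverance into deck values
#'
#' The VPP value rule: `V = w * E + (1 - w) * P`, elementwise.
#'
#' @param E,P Length-4 expectancy and perseverance vectors.
#' @param w Reinforcement-learning weight in \[0, 1\].
#' @return Length-4 value vector.
#' @export
combine_value <- function(E, P, w) {
  stopifnot(w >= 0, w <= 1)
  w * E + (1 - w) * P
}

#' Softmax sensitivity from response consistency
#'
#' `theta = 3^cons - 1`; zero consistency gives fully random responding,
#' higher values increasingly deterministic choice of the highest-valued
#' deck.
#'
#' @param cons Response consistency in \[0, 5\].
#' @return Sensitivity `theta >= 0`.
#' @export
sensitivity <- function(cons) {
  stopifnot(cons >= 0, cons <= 5)
  3^cons - 1
}

#' Softmax choice probabilities over deck values
#'
#' `p_j = exp(theta * V_j) / sum_k exp(theta * V_k)`, computed with
#' max-subtraction for overflow safety.
#'
#' @param V Length-4 value vector (finite).
#' @param theta Sensitivity, `>= 0`.
#' @return Length-4 probability vector summing to 1.
#' @export
choice_probs <- function(V, theta) {
  if (!all(is.finite(V))) abort("Non-finite deck values in choice_probs()")
  stopifnot(theta >= 0)
  z <- theta * V
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Sequence log-likelihood of observed choices under a model
#'
#' Iterates a subject's trials in order from zero initial expectancy and
#' perseverance, computing the softmax probability of each observed choice
#' before updating the latent state with the observed outcome. Net outcomes
#' are divided by `outcome_scale` before the prospect utility (RMB payoffs
#' are conventionally rescaled so that utilities stay in a numerically
#' benign range).
#'
#' @param trials Trial tibble for a single subject-session (columns `trial`,
#'   `choice`, `gain`, `loss`).
#' @param params An [igt_params][vpp_params()] vector or named list valid for
#'   `model`.
#' @param model `"vpp"`, `"pvl_delta"` or `"pvl_decay"` (or a registered
#'   plug-in model providing its own `loglik`).
#' @param outcome_scale Divisor applied to net RMB before the utility
#'   (default 100).
#' @return A list with `total` (sum of per-trial log-likelihoods) and
#'   `pointwise` (numeric vector, one entry per trial).
#' @export
#' @examples
#' sched <- igt_schedule(seed = 1)
#' agent <- simulate_agent(vpp_params(0.2, 1, 2, 1), "vpp", sched, seed = 1)
#' sequence_loglik(agent, vpp_params(0.2, 1, 2, 1), "vpp")$total
sequence_loglik <- function(trials, params, model = attr(params, "model"),
                            outcome_scale = 100) {
  m <- get_model(model)
  trials <- single_subject_trials(trials)
  if (!is.null(m$loglik)) {  # plug-in model path
    return(m$loglik(trials, params, outcome_scale))
  }
  p <- check_params(as.list(params), model)
  pw <- cpp_seq_loglik(match(trials$choice, DECKS),
                       trials$net / outcome_scale, p, m$id)
  list(total = sum(pw), pointwise = pw)
}
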