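#' Simulate one agent playing the IGT
#'
#' Plays `n_trials` selections: at each trial the deck is sampled from the
#' model's softmax choice probabilities given the current latent state, the
#' outcome is drawn from the payoff schedule via a per-deck position counter,
#' and the state is updated with that outcome. Reproducible from `seed`.
#'
#' @param params Model parameters ([vpp_params()] etc.).
#' @param model Model name; defaults to the parameters' model attribute.
#' @param schedule An [igt_schedule()].
#' @param seed Integer seed for the choice sampling.
#' @param subjID,group,session Identifier columns stamped on the output.
#' @param n_trials Number of trials (default: the schedule's setting).
#' @param outcome_scale Net-RMB divisor before the utility (default 100).
#' @return A trial tibble: `subjID`, `group`, `session`, `trial`, `choice`,
#'   `gain`, `loss`, `net`, `bankroll_after`, `block`.
#' @export
#' @examples
#' sched <- igt_schedule(seed = 7)
#' simulate_agent(vpp_params(0.2, 1, 2, 1), "vpp", sched, seed = 1)
simulate_agent <- function(params, model = attr(params, "model"), schedule,
                           seed = 1L, subjID = "S01", group = NA_character_,
                           session = "pre", n_trials = schedule$n_trials,
                           outcome_scale = 100) {
  stopifnot(inherits(schedule, "igt_schedule"))
  m <- get_model(model)
  if (!is.null(m$simulate)) {
    return(m$simulate(params, schedule, seed, subjID = subjID, group = group,
                      session = session, n_trials = n_trials))
  }
  p <- check_params(as.list(params), model)
  is_vpp <- identical(m$id, 3L)
  theta <- 3^p[["cons"]] - 1
  # per-deck card orders as plain matrices for fast indexing
  orders <- lapply(DECKS, function(d) {
    co <- schedule$card_orders[schedule$card_orders$deck == d, ]
    cbind(co$gain, co$loss)
  })
  withr::with_seed(as.integer(seed), {
    E <- P <- numeric(4)
    pos <- integer(4)
    choice <- character(n_trials)
    gain <- loss <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      V <- if (is_vpp) p[["w"]] * E + (1 - p[["w"]]) * P else E
      pr <- choice_probs(V, theta)
      c_i <- sample.int(4L, 1L, prob = pr)
      pos[c_i] <- pos[c_i] + 1L
      n_cards <- nrow(orders[[c_i]])
      card <- orders[[c_i]][((pos[c_i] - 1L) %% n_cards) + 1L, ]
      choice[t] <- DECKS[c_i]
      gain[t] <- card[1]
      loss[t] <- card[2]
      x <- (card[1] - card[2]) / outcome_scale
      u <- utility_pv(x, p[["alpha"]], p[["lambda"]])
      if (m$id == 2L) {
        E <- p[["A"]] * E
        E[c_i] <- E[c_i] + u
      } else {
        E[c_i] <- E[c_i] + p[["A"]] * (u - E[c_i])
      }
      if (is_vpp) {
        P <- p[["K"]] * P
        P[c_i] <- P[c_i] + if (x >= 0) p[["epP"]] else p[["epN"]]
      }
    }
    net <- gain - loss
    tibble::tibble(
      subjID = subjID, group = group, session = session,
      trial = seq_len(n_trials), choice = choice, gain = gain, loss = loss,
      net = net,
      bankroll_after = schedule$principal + cumsum(net),
      block = as.integer(ceiling(seq_len(n_trials) / schedule$block_size))
    )
  })
}
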