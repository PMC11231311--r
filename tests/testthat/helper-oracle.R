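# Independent scalar-loop oracles, written against the model equations
# directly and kept deliberately naive. They share no code with the package
# likelihood path (which is compiled), so agreement is a genuine cross-check.

oracle_loglik <- function(trials, params, model, outcome_scale = 100) {
  E <- c(0, 0, 0, 0)
  P <- c(0, 0, 0, 0)
  theta <- 3^params$cons - 1
  total <- 0
  pointwise <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    deck <- match(trials$choice[t], c("A", "B", "C", "D"))
    if (model == "vpp") {
      V <- params$w * E + (1 - params$w) * P
    } else {
      V <- E
    }
    den <- 0
    for (j in 1:4) den <- den + exp(theta * V[j] - max(theta * V))
    pointwise[t] <- (theta * V[deck] - max(theta * V)) - log(den)
    total <- total + pointwise[t]
    x <- (trials$gain[t] - trials$loss[t]) / outcome_scale
    if (x >= 0) {
      u <- x^params$alpha
    } else {
      u <- -params$lambda * (-x)^params$alpha
    }
    if (model == "pvl_decay") {
      for (j in 1:4) E[j] <- params$A * E[j]
      E[deck] <- E[deck] + u
    } else {
      E[deck] <- E[deck] + params$A * (u - E[deck])
    }
    if (model == "vpp") {
      for (j in 1:4) P[j] <- params$K * P[j]
      if (x >= 0) {
        P[deck] <- P[deck] + params$epP
      } else {
        P[deck] <- P[deck] + params$epN
      }
    }
  }
  list(total = total, pointwise = pointwise)
}

# random valid parameter list for a model, away from hard bounds
random_params <- function(model) {
  p <- list(A = runif(1, 0.05, 0.95), alpha = runif(1, 0.2, 1.8),
            cons = runif(1, 0.1, 3), lambda = runif(1, 0.1, 4.5))
  if (model == "vpp") {
    p <- c(p, list(epP = rnorm(1), epN = rnorm(1),
                   K = runif(1, 0.05, 0.95), w = runif(1)))
  }
  p
}

# random 100-trial sequence drawn uniformly from a schedule
random_trials <- function(schedule, n = 100) {
  ch <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  pos <- integer(4)
  gain <- loss <- numeric(n)
  for (t in seq_len(n)) {
    i <- match(ch[t], c("A", "B", "C", "D"))
    pos[i] <- pos[i] + 1L
    card <- igt_draw(schedule, ch[t], pos[i])
    gain[t] <- card$gain
    loss[t] <- card$loss
  }
  tibble::tibble(subjID = "S01", trial = seq_len(n), choice = ch,
                 gain = gain, loss = loss)
}

# build a trial tibble realising given deck counts (for QC tests)
trials_with_counts <- function(counts) {
  ch <- rep(c("A", "B", "C", "D"), counts)
  tibble::tibble(subjID = "S01", trial = seq_along(ch), choice = ch,
                 gain = 0, loss = 0)
}
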