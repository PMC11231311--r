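#' Posterior (or plug-in) predictive simulation
#'
#' Simulates replicate task runs from a fitted model and compares the
#' predicted block-wise advantageous-choice curve and deck frequencies with
#' those observed in the data the model was fitted to. For MCMC (or
#' Laplace-augmented MAP) fits each replicate uses a randomly drawn posterior
#' sample per subject; for plain MAP fits the point estimates are used.
#'
#' @param fit An `igt_fit`.
#' @param trials The observed trial data the fit was computed on.
#' @param schedule An [igt_schedule()].
#' @param n_reps Number of predictive replicates (0 gives an empty summary).
#' @param seed Integer seed.
#' @return A list with `blocks` (tibble: `block`, `observed`, `predicted`,
#'   `pred_lo`, `pred_hi`) and `decks` (tibble: `deck`, `observed`,
#'   `predicted`).
#' @export
posterior_predict <- function(fit, trials, schedule, n_reps = 20, seed = 1L) {
  stopifnot(inherits(fit, "igt_fit"))
  if (n_reps == 0) {
    return(list(blocks = tibble::tibble(block = integer(), observed = numeric(),
                                        predicted = numeric(),
                                        pred_lo = numeric(), pred_hi = numeric()),
                decks = tibble::tibble(deck = character(), observed = numeric(),
                                       predicted = numeric())))
  }
  trials <- normalize_trials(trials)
  obs_blocks <- block_advantage_rates(trials, schedule$block_size) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(observed = mean(.data$adv_rate), .groups = "drop")
  obs_decks <- prop.table(table(factor(trials$choice, levels = DECKS)))
  pt <- get_model(fit$model)$params
  est <- fit$estimates
  n <- nrow(est)
  sim_seeds <- withr::with_seed(as.integer(seed),
                                matrix(sample.int(.Machine$integer.max,
                                                  n_reps * n), n_reps))
  draw_idx <- withr::with_seed(as.integer(seed) + 1L, {
    ns <- purrr::map_int(fit$draws %||% list(), function(d)
      if (is.null(d)) 0L else nrow(d))
    if (length(ns) == n && all(ns > 0)) {
      matrix(purrr::map_int(rep(ns, n_reps), function(s) sample.int(s, 1L)),
             n_reps, byrow = TRUE)
    } else NULL
  })
  rep_out <- purrr::map(seq_len(n_reps), function(r) {
    sims <- purrr::map_dfr(seq_len(n), function(i) {
      p <- if (!is.null(draw_idx)) {
        setNames(as.numeric(fit$draws[[i]][draw_idx[r, i], pt$param]),
                 pt$param)
      } else {
        setNames(as.numeric(est[i, pt$param]), pt$param)
      }
      simulate_agent(p, fit$model, schedule, seed = sim_seeds[r, i],
                     subjID = est$subjID[i], session = est$session[i],
                     outcome_scale = fit$outcome_scale)
    })
    list(
      blocks = block_advantage_rates(sims, schedule$block_size) |>
        dplyr::group_by(.data$block) |>
        dplyr::summarise(rate = mean(.data$adv_rate), .groups = "drop"),
      decks = prop.table(table(factor(sims$choice, levels = DECKS)))
    )
  })
  pred_blocks <- purrr::map_dfr(rep_out, "blocks", .id = "rep") |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(predicted = mean(.data$rate),
                     pred_lo = unname(quantile(.data$rate, 0.05)),
                     pred_hi = unname(quantile(.data$rate, 0.95)),
                     .groups = "drop")
  pred_decks <- colMeans(do.call(rbind, purrr::map(rep_out, function(r)
    as.numeric(r$decks))))
  list(
    blocks = dplyr::left_join(obs_blocks, pred_blocks, by = "block"),
    decks = tibble::tibble(deck = DECKS, observed = as.numeric(obs_decks),
                           predicted = pred_decks)
  )
}
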