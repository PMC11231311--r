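#' Deck payoff specifications for the Iowa Gambling Task
#'
#' Returns the per-deck payoff structure of the task: decks A and B pay a
#' constant 100 RMB per draw, decks C and D pay 50 RMB, and each deck carries
#' probabilistic losses realised exactly within a fixed-length cycle of cards.
#' Over a full cycle the expected net per draw is -25 RMB for A and B
#' (disadvantageous) and +25 RMB for C and D (advantageous).
#'
#' @return A tibble with one row per deck: `deck`, `win` (constant gain, RMB),
#'   `cycle_length` (cards over which loss frequencies are realised exactly),
#'   and `losses` (list-column of the loss multiset for one cycle, RMB).
#' @export
#' @examples
#' deck_specs()
deck_specs <- function() {
  tibble::tibble(
    deck = c("A", "B", "C", "D"),
    win = c(100, 100, 50, 50),
    cycle_length = c(10L, 10L, 8L, 10L),
    losses = list(
      c(150, 200, 250, 300, 350, rep(0, 5)),
      c(1250, rep(0, 9)),
      c(25, 50, 50, 75, rep(0, 4)),
      c(250, rep(0, 9))
    )
  )
}

#' Build a deterministic IGT payoff schedule
#'
#' Generates, for each deck, an ordered list of (gain, loss) cards realising
#' the deck's loss frequencies exactly within every contiguous cycle
#' (A/B/D: 10 cards, C: 8 cards). Card positions within each cycle are
#' shuffled deterministically from `seed`, emulating the predetermined card
#' order shown identically to every participant.
#'
#' @param seed Non-negative integer; fixes the within-cycle shuffles.
#' @param n_trials Total number of selections a subject makes (default 100).
#' @param block_size Trials per block (default 20, giving 5 blocks).
#' @param principal Starting bankroll in RMB (default 2000).
#' @return An object of class `igt_schedule`: a list with `card_orders`
#'   (tibble: `deck`, `position`, `gain`, `loss`), `deck_info` (see
#'   [deck_specs()]), and the `seed`, `n_trials`, `block_size`, `principal`
#'   settings.
#' @export
#' @examples
#' sched <- igt_schedule(seed = 0)
#' igt_draw(sched, "B", 1:10)
igt_schedule <- function(seed = 0L, n_trials = 100L, block_size = 20L,
                         principal = 2000) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  stopifnot(n_trials >= 1, block_size >= 1)
  specs <- deck_specs()
  orders <- withr::with_seed(as.integer(seed), {
    purrr::pmap(specs, function(deck, win, cycle_length, losses) {
      n_cycles <- ceiling(n_trials / cycle_length)
      loss_seq <- unlist(lapply(seq_len(n_cycles), function(i) sample(losses)))
      tibble::tibble(
        deck = deck,
        position = seq_along(loss_seq),
        gain = win,
        loss = loss_seq
      )
    })
  })
  structure(
    list(
      card_orders = dplyr::bind_rows(orders),
      deck_info = specs,
      seed = as.integer(seed),
      n_trials = as.integer(n_trials),
      block_size = as.integer(block_size),
      principal = principal
    ),
    class = "igt_schedule"
  )
}

#' @export
print.igt_schedule <- function(x, ...) {
  cat("<igt_schedule> seed", x$seed, "|", x$n_trials, "trials, blocks of",
      x$block_size, "| principal", x$principal, "RMB\n")
  invisible(x)
}

#' Draw cards from a deck of a payoff schedule
#'
#' Returns the (gain, loss) outcome at the given draw position(s) of a deck's
#' predetermined card order. Positions beyond the stored order wrap around by
#' whole cycles, so loss frequencies stay exact indefinitely.
#'
#' @param schedule An [igt_schedule()].
#' @param deck Single deck label in `"A".."D"`.
#' @param position Integer vector of per-deck draw counts (1-based).
#' @return A tibble with columns `deck`, `position`, `gain`, `loss`.
#' @export
igt_draw <- function(schedule, deck, position) {
  stopifnot(inherits(schedule, "igt_schedule"))
  if (length(deck) != 1 || !deck %in% c("A", "B", "C", "D")) {
    abort(paste0("Unknown deck label: ", paste(deck, collapse = ", ")))
  }
  stopifnot(all(position >= 1), all(position == floor(position)))
  cards <- schedule$card_orders[schedule$card_orders$deck == deck, ]
  idx <- ((as.integer(position) - 1L) %% nrow(cards)) + 1L
  tibble::tibble(
    deck = deck,
    position = as.integer(position),
    gain = cards$gain[idx],
    loss = cards$loss[idx]
  )
}

#' Export a payoff schedule to JSON
#'
#' Writes the per-deck card orders plus the generating seed and settings, so
#' the exact task administered to (simulated) subjects can be archived and
#' reloaded elsewhere.
#'
#' @param schedule An [igt_schedule()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
export_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "igt_schedule"))
  out <- list(
    seed = schedule$seed,
    n_trials = schedule$n_trials,
    block_size = schedule$block_size,
    principal = schedule$principal,
    card_orders = split(
      schedule$card_orders[c("position", "gain", "loss")],
      schedule$card_orders$deck
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-block advantageous-choice rates
#'
#' The classic IGT learning curve: per block of trials, the proportion of
#' choices from the advantageous decks C and D. Accepts trial data for one or
#' many subjects/sessions in long format.
#'
#' @param trials A data frame of trial records with at least `subjID`,
#'   `trial`, `choice` (deck letters); a `session` column is honoured if
#'   present.
#' @param block_size Trials per block (default 20).
#' @return A tibble with `subjID` (and `session` if present), `block`,
#'   `adv_rate`.
#' @export
block_advantage_rates <- function(trials, block_size = 20L) {
  trials <- normalize_trials(trials)
  keys <- intersect(c("subjID", "group", "session"), names(trials))
  dplyr::group_by(trials, dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, k) {
      n <- nrow(d)
      if (n %% block_size != 0) {
        abort(sprintf(
          "Incomplete block: subject has %d trials, not a multiple of %d",
          n, block_size
        ))
      }
      d <- d[order(d$trial), ]
      blk <- ceiling(seq_len(n) / block_size)
      tibble::tibble(
        block = seq_len(max(blk)),
        adv_rate = as.numeric(tapply(d$choice %in% c("C", "D"), blk, mean))
      )
    }) |>
    dplyr::ungroup()
}

#' Quality-control filter on deck exploration
#'
#' Excludes subjects who failed to explore the task: a subject (per session)
#' is excluded if any deck was selected `floor(min_fraction * n_trials)` times
#' or fewer — on 100 trials with the default 5% threshold, "five times or
#' less". Decks never chosen count as zero selections.
#'
#' @param trials Long trial data for a cohort (see [read_igt_trials()]).
#' @param min_fraction Exploration threshold as a fraction of trials
#'   (default 0.05).
#' @return An object of class `igt_qc`: list with `kept` and `excluded` trial
#'   tibbles and a `log` tibble (`subjID`, `session`, `min_deck`,
#'   `min_count`, `excluded`, `reason`).
#' @export
qc_filter <- function(trials, min_fraction = 0.05) {
  trials <- normalize_trials(trials)
  if (nrow(trials) == 0) abort("Empty cohort: no trials to filter")
  keys <- intersect(c("subjID", "session"), names(trials))
  log <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, k) {
      counts <- table(factor(d$choice, levels = c("A", "B", "C", "D")))
      thr <- floor(min_fraction * nrow(d))
      mi <- which.min(counts)
      tibble::tibble(
        min_deck = names(counts)[mi],
        min_count = as.integer(counts[mi]),
        threshold = as.integer(thr),
        excluded = counts[mi] <= thr
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(reason = dplyr::if_else(
      .data$excluded,
      sprintf("deck %s selected %d times (<= %d)",
              .data$min_deck, .data$min_count, .data$threshold),
      NA_character_
    ))
  bad <- dplyr::filter(log, .data$excluded)[keys]
  excluded <- dplyr::semi_join(trials, bad, by = keys)
  kept <- dplyr::anti_join(trials, bad, by = keys)
  structure(list(kept = kept, excluded = excluded, log = log),
            class = "igt_qc")
}

#' @export
print.igt_qc <- function(x, ...) {
  cat("<igt_qc>", sum(!x$log$excluded), "subject-sessions kept,",
      sum(x$log$excluded), "excluded\n")
  invisible(x)
}

#' @rdname qc_filter
#' @param x An `igt_qc` object.
#' @param ... Unused.
#' @method tidy igt_qc
#' @export
tidy.igt_qc <- function(x, ...) x$log
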