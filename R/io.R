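DECKS <- c("A", "B", "C", "D")

# Coerce a trial table to the package's canonical long layout: deck choices
# as letters, numeric gain/loss, net = gain - loss, integer trial index.
normalize_trials <- function(trials) {
  if (!is.data.frame(trials)) abort("`trials` must be a data frame")
  need <- c("trial", "choice", "gain", "loss")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(paste0("Trial data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  trials <- tibble::as_tibble(trials)
  ch <- trials$choice
  if (is.numeric(ch)) {
    if (!all(ch %in% 1:4)) abort("Numeric deck codes must be in 1..4")
    ch <- DECKS[ch]
  } else {
    ch <- toupper(as.character(ch))
    if (!all(ch %in% DECKS)) abort("Deck labels must be A-D (or 1-4)")
  }
  trials$choice <- ch
  trials$gain <- as.numeric(trials$gain)
  trials$loss <- abs(as.numeric(trials$loss))
  trials$net <- trials$gain - trials$loss
  trials$trial <- as.integer(trials$trial)
  if (!"subjID" %in% names(trials)) trials$subjID <- "S01"
  trials
}

# Order-checked single-subject extraction used by likelihood code.
single_subject_trials <- function(trials) {
  trials <- normalize_trials(trials)
  keys <- intersect(c("subjID", "session"), names(trials))
  if (nrow(dplyr::distinct(trials[keys])) != 1) {
    abort("Expected trials from a single subject-session")
  }
  trials <- trials[order(trials$trial), ]
  if (!identical(as.integer(trials$trial), seq_len(nrow(trials)))) {
    abort("Trials must be indexed 1..n with no gaps")
  }
  trials
}

#' Read long-format IGT trial data
#'
#' Reads a delimited text file with one row per choice, the column convention
#' of common IGT datasets: `subjID`, optional `group` and `session`, `trial`,
#' `choice` (deck letter A-D or code 1-4), `gain`, `loss`. Deck coding is
#' normalised to letters and a `net = gain - loss` column is added; losses
#' may be recorded with either sign.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header).
#' @return A tibble of trial records.
#' @export
read_igt_trials <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  trials <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  normalize_trials(trials)
}

#' Write IGT trial data
#'
#' @param trials A trial tibble.
#' @param path Output CSV path.
#' @param deck_coding `"letter"` (default) or `"numeric"` (1-4).
#' @return `path`, invisibly.
#' @export
write_igt_trials <- function(trials, path, deck_coding = c("letter", "numeric")) {
  deck_coding <- match.arg(deck_coding)
  trials <- normalize_trials(trials)
  if (deck_coding == "numeric") trials$choice <- match(trials$choice, DECKS)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}
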