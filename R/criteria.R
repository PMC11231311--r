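log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_ll_matrix <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2) abort("At least 2 posterior draws are required")
  if (!all(is.finite(ll))) abort("Non-finite pointwise log-likelihoods")
  ll
}

#' Widely applicable information criterion
#'
#' Computes WAIC from a draws-by-observations pointwise log-likelihood
#' matrix: `lppd_i = log mean_s exp(ll_si)`, effective parameters
#' `p_i = var_s(ll_si)`, `waic = -2 * sum(lppd_i - p_i)`, with the standard
#' error taken over observation-wise components.
#'
#' @param ll Matrix of pointwise log-likelihoods, draws in rows,
#'   observations in columns (at least 2 draws).
#' @return A list with `waic`, `se`, `p_waic`, `elpd`, and the `pointwise`
#'   tibble of per-observation components.
#' @export
waic <- function(ll) {
  ll <- check_ll_matrix(ll)
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, log_sum_exp) - log(S)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(ll)
  list(waic = -2 * sum(elpd_i), se = 2 * sqrt(n * var(elpd_i)),
       p_waic = sum(p_i), elpd = sum(elpd_i),
       pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i,
                                  elpd = elpd_i))
}

# Generalized Pareto fit to exceedances (profile-posterior-mean method of
# Zhang & Stephens 2009, the estimator standard PSIS uses). Returns k and
# sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0 || sd(x) < .Machine$double.eps) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[floor(n / 4 + 0.5)])
  ks <- sapply(bs, function(b) -mean(log1p(-b * x)))
  L <- n * (log(bs / ks) + ks - 1)
  w <- 1 / sapply(seq_len(m), function(i) sum(exp(L - L[i])))
  b <- sum(bs * w)
  k_zs <- -mean(log1p(-b * x))
  # flip from the Zhang-Stephens shape to the tail-index convention the
  # 0.7 diagnostic threshold is stated in (positive k = heavy tail)
  list(k = -k_zs, sigma = -(-k_zs) / b)
}

# Pareto-smoothed importance weights for one observation's log ratios.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  fit <- gpd_fit(exc)
  if (is.na(fit$k)) return(list(lw = lw, k = fit$k))
  # replace tail by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  q <- exp(cutoff) + fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
  lw[tail_ids[order(lw[tail_ids])]] <- log(q)
  lw <- pmin(lw, 0)  # truncate at the raw maximum (max was shifted to 0)
  list(lw = lw - max(lw), k = fit$k)
}

#' Leave-one-out information criterion via PSIS
#'
#' Pareto-smoothed importance-sampling leave-one-out cross-validation:
#' per-observation importance ratios `1/p(y_i | theta_s)` are tail-smoothed
#' by a generalized Pareto fit, and `elpd_loo_i` is the log of the
#' weighted-mean likelihood. Observations whose Pareto shape `k` exceeds
#' 0.7 are flagged as unreliable but still returned.
#'
#' @inheritParams waic
#' @return A list with `looic`, `se`, `elpd_loo`, `p_loo`, `pareto_k`
#'   (per-observation shape estimates), `n_high_k` (count with k > 0.7),
#'   and the `pointwise` tibble.
#' @export
looic <- function(ll) {
  ll <- check_ll_matrix(ll)
  S <- nrow(ll)
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - log_sum_exp(sm$lw)  # normalise
    elpd_i[i] <- log_sum_exp(lw + ll[, i])
    k_i[i] <- sm$k
  }
  lppd_i <- apply(ll, 2, log_sum_exp) - log(S)
  list(looic = -2 * sum(elpd_i), se = 2 * sqrt(n * var(elpd_i)),
       elpd_loo = sum(elpd_i), p_loo = sum(lppd_i - elpd_i),
       pareto_k = k_i, n_high_k = sum(k_i > 0.7, na.rm = TRUE),
       pointwise = tibble::tibble(elpd_loo = elpd_i, pareto_k = k_i))
}

# Assemble one draws x observations matrix from an igt_fit's per-subject
# pointwise log-likelihood blocks (trial-level observations).
pointwise_matrix <- function(fit) {
  blocks <- fit$pointwise
  if (any(vapply(blocks, is.null, TRUE))) {
    abort("Fit has subjects without pointwise log-likelihoods")
  }
  S <- unique(vapply(blocks, nrow, 0L))
  if (length(S) != 1) abort("Unequal draw counts across subjects")
  do.call(cbind, blocks)
}

#' Compare fitted models by information criteria
#'
#' Builds one row per candidate fit with WAIC and PSIS-LOO criteria computed
#' from trial-level pointwise log-likelihoods, ranked by LOOIC (lower is
#' better) with WAIC as tie-break. All fits must be on the identical cohort.
#'
#' @param fits Named list of `igt_fit` objects (names are model labels).
#'   Fits need posterior or Laplace draws (`laplace_draws > 0` for MAP).
#' @return An `igt_comparison` tibble: `model`, `looic`, `looic_se`, `waic`,
#'   `waic_se`, `p_waic`, `p_loo`, `max_pareto_k`, `n_high_k`, `rank`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- purrr::map_chr(fits, "model")
  }
  ref <- fits[[1]]$subjects[c("subjID", "session", "n_trials")]
  for (f in fits[-1]) {
    if (!identical(f$subjects[c("subjID", "session", "n_trials")], ref)) {
      abort("Fits were not computed on the identical cohort")
    }
  }
  rows <- purrr::imap_dfr(fits, function(f, nm) {
    ll <- pointwise_matrix(f)
    w <- waic(ll)
    l <- looic(ll)
    tibble::tibble(
      model = nm, looic = l$looic, looic_se = l$se,
      waic = w$waic, waic_se = w$se, p_waic = w$p_waic, p_loo = l$p_loo,
      max_pareto_k = suppressWarnings(max(l$pareto_k, na.rm = TRUE)),
      n_high_k = l$n_high_k
    )
  })
  rows$max_pareto_k[!is.finite(rows$max_pareto_k)] <- NA_real_
  rows <- rows[order(rows$looic, rows$waic), ]
  rows$rank <- seq_len(nrow(rows))
  structure(rows, class = c("igt_comparison", class(rows)))
}

#' @rdname compare_models
#' @param x An `igt_comparison` table.
#' @param ... Unused.
#' @method tidy igt_comparison
#' @export
tidy.igt_comparison <- function(x, ...) tibble::as_tibble(x)
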