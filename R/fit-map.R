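#' Prior specification for model fitting
#'
#' Priors are placed on the unconstrained (probit) scale: each bounded
#' parameter is represented as `upper * pnorm(z)` and `z` receives a
#' `Normal(location, scale)` prior; the unbounded perseverance impacts use an
#' identity link with the same normal form. The default standard-normal
#' prior makes each bounded parameter uniform over its range a priori.
#'
#' @param model Model name.
#' @param location,scale Scalars or named vectors over the model's
#'   parameters.
#' @return A `prior_spec` object (tibble: `param`, `location`, `scale`).
#' @export
prior_spec <- function(model, location = 0, scale = 1) {
  pt <- get_model(model)$params
  loc <- setNames(rep(0, nrow(pt)), pt$param)
  sc <- setNames(rep(1, nrow(pt)), pt$param)
  if (!is.null(names(location))) loc[names(location)] <- location else loc[] <- location
  if (!is.null(names(scale))) sc[names(scale)] <- scale else sc[] <- scale
  stopifnot(all(sc > 0))
  structure(tibble::tibble(param = pt$param, location = loc, scale = sc),
            class = c("prior_spec", class(tibble::tibble())),
            model = model)
}

split_subjects <- function(trials) {
  trials <- normalize_trials(trials)
  if (!"session" %in% names(trials)) trials$session <- "pre"
  if (!"group" %in% names(trials)) trials$group <- NA_character_
  key <- paste(trials$subjID, trials$session, sep = "\r")
  lapply(split(trials, factor(key, levels = unique(key))),
         single_subject_trials)
}

subject_index <- function(subjects) {
  purrr::map_dfr(subjects, function(d) {
    tibble::tibble(subjID = d$subjID[1], session = d$session[1],
                   group = d$group[1], n_trials = nrow(d))
  })
}

# log posterior on the unconstrained scale for one subject; bounds and
# choice/outcome vectors are captured once so the optimiser's inner loop
# stays cheap
make_objective <- function(d, model, prior, outcome_scale) {
  m <- get_model(model)
  bounded <- m$params$bounded
  upper <- m$params$upper
  id <- m$id
  ch <- match(d$choice, DECKS)
  net <- d$net / outcome_scale
  loc <- prior$location
  sc <- prior$scale
  function(z) {
    v <- z
    v[bounded] <- upper[bounded] * pnorm(z[bounded])
    sum(cpp_seq_loglik(ch, net, v, id)) + sum(dnorm(z, loc, sc, log = TRUE))
  }
}

#' Per-subject MAP estimation
#'
#' Maximises log-likelihood plus log-prior on the unconstrained scale for
#' each subject-session independently, with multiple restarts drawn from the
#' prior. Ties are broken by the highest objective, then the lowest restart
#' index. Deterministic given `seed`.
#'
#' @param trials Long trial data (a cohort); subjects are split by
#'   `subjID` x `session`.
#' @param model Model name.
#' @param prior A [prior_spec()] (default: standard normal on the
#'   unconstrained scale).
#' @param n_restarts Optimiser restarts per subject (default 8).
#' @param seed Integer seed (restart initialisation and Laplace draws).
#' @param laplace_draws If > 0, draws this many parameter samples per subject
#'   from the Laplace (normal) approximation at the optimum and stores the
#'   corresponding per-trial log-likelihood draws, enabling WAIC/LOO on MAP
#'   fits.
#' @param outcome_scale Net-RMB divisor before the utility (default 100).
#' @return An `igt_fit` object. `tidy()` gives per-subject estimates in long
#'   form; `glance()` a one-row fit summary.
#' @export
fit_map <- function(trials, model = "vpp", prior = prior_spec(model),
                    n_restarts = 8, seed = 1L, laplace_draws = 0,
                    outcome_scale = 100) {
  m <- get_model(model)
  subjects <- split_subjects(trials)
  idx <- subject_index(subjects)
  k <- nrow(m$params)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max,
                                       length(subjects)))
  res <- purrr::map(seq_along(subjects), function(i) {
    d <- subjects[[i]]
    obj <- make_objective(d, model, prior, outcome_scale)
    withr::with_seed(seeds[i], {
      starts <- matrix(rnorm(n_restarts * k, prior$location, prior$scale),
                       nrow = n_restarts, byrow = TRUE)
      best <- NULL
      n_fail <- 0L
      for (r in seq_len(n_restarts)) {
        fit <- tryCatch(
          optim(starts[r, ], obj, method = "BFGS",
                control = list(fnscale = -1, maxit = 200)),
          error = function(e) NULL)
        if (is.null(fit)) {
          fit <- tryCatch(
            optim(starts[r, ], obj, method = "Nelder-Mead",
                  control = list(fnscale = -1, maxit = 1000)),
            error = function(e) NULL)
        }
        if (is.null(fit)) {
          n_fail <- n_fail + 1L
        } else if (is.null(best) || fit$value > best$value) {
          best <- fit
        }
      }
      if (is.null(best)) {
        warn(paste0("All restarts failed for subject ", d$subjID[1]))
        return(list(failed = TRUE, n_fail = n_fail))
      }
      z_hat <- best$par
      est <- to_natural(z_hat, model)
      ch <- match(d$choice, DECKS)
      net <- d$net / outcome_scale
      pw_map <- cpp_seq_loglik(ch, net, est, m$id)
      pointwise <- matrix(pw_map, nrow = 1)
      draws <- NULL
      if (laplace_draws > 0) {
        H <- tryCatch(optimHess(z_hat, obj), error = function(e) NULL)
        Sigma <- laplace_cov(H, k)
        L <- chol(Sigma)
        zd <- matrix(rnorm(laplace_draws * k), laplace_draws) %*% L +
          matrix(z_hat, laplace_draws, k, byrow = TRUE)
        draws <- t(apply(zd, 1, to_natural, model = model))
        colnames(draws) <- m$params$param
        pointwise <- t(apply(draws, 1, function(p)
          cpp_seq_loglik(ch, net, p, m$id)))
      }
      list(failed = FALSE, estimate = est, z = z_hat,
           logpost = best$value, loglik = sum(pw_map),
           pointwise = pointwise, draws = draws, n_fail = n_fail,
           converged = isTRUE(best$convergence == 0))
    })
  })
  failed <- purrr::map_lgl(res, "failed")
  est_tbl <- dplyr::bind_cols(
    idx,
    purrr::map_dfr(res, function(r) {
      if (r$failed) {
        tibble::as_tibble(as.list(setNames(rep(NA_real_, k), m$params$param)))
      } else {
        tibble::as_tibble(as.list(r$estimate))
      }
    })
  )
  structure(list(
    method = "map", model = model, estimates = est_tbl,
    pointwise = purrr::map(res, function(r) if (r$failed) NULL else r$pointwise),
    draws = purrr::map(res, function(r) if (r$failed) NULL else r$draws),
    diagnostics = dplyr::bind_cols(
      idx[c("subjID", "session")],
      tibble::tibble(
        failed = failed,
        converged = purrr::map_lgl(res, function(r) isTRUE(r$converged)),
        n_restart_failures = purrr::map_int(res, "n_fail"),
        logpost = purrr::map_dbl(res, function(r)
          if (r$failed) NA_real_ else r$logpost),
        loglik = purrr::map_dbl(res, function(r)
          if (r$failed) NA_real_ else r$loglik)
      )),
    subjects = idx, seed = as.integer(seed), outcome_scale = outcome_scale,
    settings = list(n_restarts = n_restarts, laplace_draws = laplace_draws)
  ), class = "igt_fit")
}

# Covariance of the Laplace approximation: negate and invert the Hessian of
# the log posterior, jittering if not positive definite. Eigenvalues are
# capped at the prior variance: along likelihood-flat directions the exact
# posterior is no wider than the standard-normal prior, and an uncapped
# numerical inverse can explode there.
laplace_cov <- function(H, k, max_var = 1) {
  ok <- function(S) !is.null(S) && all(is.finite(S))
  S <- if (is.null(H)) NULL else tryCatch(solve(-H), error = function(e) NULL)
  jit <- 1e-6
  while (!ok(S) && !is.null(H) && jit < 1) {
    S <- tryCatch(solve(-(H - diag(jit, k))), error = function(e) NULL)
    jit <- jit * 10
  }
  if (!ok(S)) S <- diag(k)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmin(pmax(e$values, 1e-8), max_var)
  e$vectors %*% (vals * t(e$vectors))
}

#' @export
print.igt_fit <- function(x, ...) {
  cat("<igt_fit>", x$model, "via", x$method, "|",
      nrow(x$subjects), "subject-sessions\n")
  invisible(x)
}

#' @rdname fit_map
#' @param x An `igt_fit` object.
#' @param ... Unused.
#' @method tidy igt_fit
#' @export
tidy.igt_fit <- function(x, ...) {
  pt <- get_model(x$model)$params
  tidyr::pivot_longer(x$estimates, dplyr::all_of(pt$param),
                      names_to = "param", values_to = "estimate")
}

#' @rdname fit_map
#' @method glance igt_fit
#' @export
glance.igt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, method = x$method,
    n_subjects = nrow(x$subjects),
    n_trials = sum(x$subjects$n_trials),
    total_loglik = sum(x$diagnostics$loglik, na.rm = TRUE),
    n_failed = sum(x$diagnostics$failed)
  )
}
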