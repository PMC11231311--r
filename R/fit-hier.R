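#' Hierarchical Bayesian estimation
#'
#' Samples subject-level parameters under a group-level normal prior on the
#' unconstrained (probit) scale: `z_i ~ Normal(mu, sigma)` per parameter,
#' with `mu ~ Normal(0, 1)` and `sigma ~ half-Normal(0, sigma_prior_sd)`.
#' The sampler is an adaptive random-walk Metropolis-within-Gibbs scheme:
#' subject vectors and group scales move by Metropolis steps (proposal
#' scales adapted during warmup), group means by conjugate Gibbs draws.
#' Two or more chains are run from the given seed; split R-hat and effective
#' sample size are reported for every sampled quantity, and a fit whose
#' worst R-hat exceeds 1.1 carries a non-convergence warning.
#'
#' @inheritParams fit_map
#' @param chains Number of chains (default 2).
#' @param iter Total iterations per chain (default 500).
#' @param warmup Warmup (adaptation) iterations discarded per chain
#'   (default 250); must be `< iter`.
#' @param sigma_prior_sd Scale of the half-normal hyperprior on group SDs
#'   (default 0.2).
#' @return An `igt_fit` object with posterior draws, per-subject posterior
#'   mean estimates, group-level summaries in `$group_means`, pointwise
#'   log-likelihood draws, and `$diagnostics_mcmc` (R-hat/ESS table).
#' @export
fit_hierarchical <- function(trials, model = "vpp", prior = prior_spec(model),
                             chains = 2, iter = 500, warmup = 250,
                             seed = 1L, sigma_prior_sd = 0.2,
                             outcome_scale = 100) {
  stopifnot(iter > warmup, chains >= 1)
  m <- get_model(model)
  pt <- m$params
  k <- nrow(pt)
  subjects <- split_subjects(trials)
  idx <- subject_index(subjects)
  n <- length(subjects)
  dat <- lapply(subjects, function(d)
    list(ch = match(d$choice, DECKS), net = d$net / outcome_scale))
  bounded <- pt$bounded
  upper <- pt$upper
  ll_fun <- function(i, z) {
    v <- z
    v[bounded] <- upper[bounded] * pnorm(z[bounded])
    sum(cpp_seq_loglik(dat[[i]]$ch, dat[[i]]$net, v, m$id))
  }
  n_keep <- iter - warmup

  run_chain <- function(chain_seed) withr::with_seed(chain_seed, {
    mu <- rnorm(k, 0, 0.1)
    sigma <- rep(sigma_prior_sd, k)
    z <- matrix(rep(mu, each = n), n, k) + matrix(rnorm(n * k, 0, 0.1), n, k)
    ll_cur <- vapply(seq_len(n), function(i) ll_fun(i, z[i, ]), 0)
    step_z <- matrix(0.2, n, k)
    step_s <- rep(0.3, k)
    step_t <- rep(0.3, k)
    keep_mu <- matrix(NA_real_, n_keep, k)
    keep_sigma <- matrix(NA_real_, n_keep, k)
    keep_z <- array(NA_real_, c(n_keep, n, k))
    for (it in seq_len(iter)) {
      adapt <- it <= warmup
      gamma <- if (adapt) min(0.5, 10 / it) else 0
      # subject-level Metropolis updates, one coordinate at a time
      for (i in seq_len(n)) {
        for (j in seq_len(k)) {
          zp <- z[i, ]
          zp[j] <- zp[j] + rnorm(1, 0, step_z[i, j])
          llp <- ll_fun(i, zp)
          logr <- llp + dnorm(zp[j], mu[j], sigma[j], log = TRUE) -
            ll_cur[i] - dnorm(z[i, j], mu[j], sigma[j], log = TRUE)
          acc <- is.finite(logr) && log(runif(1)) < logr
          if (acc) {
            z[i, ] <- zp
            ll_cur[i] <- llp
          }
          if (adapt) step_z[i, j] <- step_z[i, j] * exp(gamma * ((acc) - 0.44))
        }
      }
      # group means: conjugate Gibbs given z and sigma, prior Normal(0, 1)
      prec <- n / sigma^2 + 1
      mu <- rnorm(k, (colSums(z) / sigma^2) / prec, sqrt(1 / prec))
      # joint translation of (mu_j, z[, j]): moves the whole group along
      # weakly identified directions that coordinate-wise updates cannot
      # traverse when the group scale is small
      for (j in seq_len(k)) {
        delta <- rnorm(1, 0, step_t[j])
        zp_all <- z
        zp_all[, j] <- z[, j] + delta
        llp_all <- vapply(seq_len(n), function(i) ll_fun(i, zp_all[i, ]), 0)
        logr <- sum(llp_all) - sum(ll_cur) +
          dnorm(mu[j] + delta, 0, 1, log = TRUE) -
          dnorm(mu[j], 0, 1, log = TRUE)
        acc <- is.finite(logr) && log(runif(1)) < logr
        if (acc) {
          mu[j] <- mu[j] + delta
          z <- zp_all
          ll_cur <- llp_all
        }
        if (adapt) step_t[j] <- step_t[j] * exp(gamma * ((acc) - 0.25))
      }
      # group scales: Metropolis on log sigma with half-normal prior
      for (j in seq_len(k)) {
        sp <- sigma[j] * exp(rnorm(1, 0, step_s[j]))
        logr <- sum(dnorm(z[, j], mu[j], sp, log = TRUE)) -
          sum(dnorm(z[, j], mu[j], sigma[j], log = TRUE)) +
          dnorm(sp, 0, sigma_prior_sd, log = TRUE) -
          dnorm(sigma[j], 0, sigma_prior_sd, log = TRUE) +
          log(sp) - log(sigma[j])
        acc <- is.finite(logr) && log(runif(1)) < logr
        if (acc) sigma[j] <- sp
        if (adapt) step_s[j] <- step_s[j] * exp(gamma * ((acc) - 0.3))
      }
      if (it > warmup) {
        keep_mu[it - warmup, ] <- mu
        keep_sigma[it - warmup, ] <- sigma
        keep_z[it - warmup, , ] <- z
      }
    }
    list(mu = keep_mu, sigma = keep_sigma, z = keep_z)
  })

  chain_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max, chains))
  chains_out <- lapply(chain_seeds, run_chain)

  # ---- diagnostics over every sampled quantity -----------------------------
  diag_rows <- list()
  for (j in seq_len(k)) {
    dm <- sapply(chains_out, function(ch) ch$mu[, j])
    ds <- sapply(chains_out, function(ch) ch$sigma[, j])
    diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
      quantity = paste0("mu[", pt$param[j], "]"),
      rhat = split_rhat(dm), ess = ess_basic(dm))
    diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
      quantity = paste0("sigma[", pt$param[j], "]"),
      rhat = split_rhat(ds), ess = ess_basic(ds))
    for (i in seq_len(n)) {
      dz <- sapply(chains_out, function(ch) ch$z[, i, j])
      diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
        quantity = paste0("z[", idx$subjID[i], ",", pt$param[j], "]"),
        rhat = split_rhat(dz), ess = ess_basic(dz))
    }
  }
  diagnostics_mcmc <- dplyr::bind_rows(diag_rows)
  converged <- all(diagnostics_mcmc$rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    warn(paste0("MCMC non-convergence: max R-hat = ",
                round(max(diagnostics_mcmc$rhat, na.rm = TRUE), 3)))
  }

  # pooled draws across chains
  mu_draws <- do.call(rbind, lapply(chains_out, function(ch) ch$mu))
  sigma_draws <- do.call(rbind, lapply(chains_out, function(ch) ch$sigma))
  colnames(mu_draws) <- colnames(sigma_draws) <- pt$param
  z_draws <- do.call(abind1, lapply(chains_out, function(ch) ch$z))
  S <- nrow(mu_draws)

  # per-subject natural-scale draws, estimates, pointwise log-likelihoods
  draws <- vector("list", n)
  pointwise <- vector("list", n)
  est <- matrix(NA_real_, n, k, dimnames = list(NULL, pt$param))
  for (i in seq_len(n)) {
    nat <- t(apply(z_draws[, i, , drop = TRUE], 1, to_natural, model = model))
    colnames(nat) <- pt$param
    draws[[i]] <- nat
    est[i, ] <- colMeans(nat)
    pointwise[[i]] <- t(apply(nat, 1, function(p)
      cpp_seq_loglik(dat[[i]]$ch, dat[[i]]$net, p, m$id)))
  }
  # group-level natural-scale location: bounded params via upper * pnorm(mu)
  mu_nat <- sapply(seq_len(k), function(j) {
    if (pt$bounded[j]) mean(pt$upper[j] * pnorm(mu_draws[, j]))
    else mean(mu_draws[, j])
  })
  group_means <- tibble::tibble(
    param = pt$param,
    posterior_group_mean = mu_nat,
    mean_of_subject_means = colMeans(est),
    group_sigma_unconstrained = colMeans(sigma_draws)
  )

  structure(list(
    method = "mcmc", model = model,
    estimates = dplyr::bind_cols(idx, tibble::as_tibble(est)),
    draws = draws, pointwise = pointwise,
    group_draws = list(mu = mu_draws, sigma = sigma_draws),
    group_means = group_means,
    diagnostics = tibble::tibble(
      subjID = idx$subjID, session = idx$session,
      failed = FALSE, converged = converged,
      loglik = purrr::map_dbl(seq_len(n), function(i)
        mean(rowSums(pointwise[[i]])))),
    diagnostics_mcmc = diagnostics_mcmc, converged = converged,
    subjects = idx, seed = as.integer(seed), outcome_scale = outcome_scale,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    sigma_prior_sd = sigma_prior_sd, n_draws = S)
  ), class = "igt_fit")
}

# bind 3-d arrays along the first dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)),
                           d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
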