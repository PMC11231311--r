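#' Specify a synthetic cohort
#'
#' A cohort specification holds the group label, size, and per-parameter
#' (mean, sd) of the true-parameter distribution on the natural scale.
#' Subjects' true parameters are drawn from normals truncated at the
#' parameter bounds (the unbounded perseverance impacts are drawn
#' untruncated), which is the minimal distributional assumption honouring
#' both the reported group means/SDs and the bounds.
#'
#' @param group Group label (e.g. `"HC"`, `"MUD"`, `"MUD-t"`).
#' @param n Number of subjects (>= 1).
#' @param means,sds Named numeric vectors over the model's parameters.
#' @param model Model name the parameters belong to (default `"vpp"`).
#' @param sessions Character vector of session labels, `"pre"` or
#'   `c("pre", "post")`.
#' @param post_shift Named additive shift applied to post-session true
#'   parameters (ignored for single-session specs).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, n, means, sds, model = "vpp",
                        sessions = "pre", post_shift = NULL) {
  pt <- get_model(model)$params
  stopifnot(n >= 1, all(pt$param %in% names(means)),
            all(pt$param %in% names(sds)), all(sds[pt$param] >= 0))
  mu <- means[pt$param]
  if (any(mu < pt$lower | mu > pt$upper)) {
    abort("Cohort mean(s) outside parameter bounds")
  }
  if (!is.null(post_shift)) {
    shifted <- mu + ifelse(is.na(post_shift[pt$param]), 0,
                           post_shift[pt$param])
    if (any(shifted < pt$lower | shifted > pt$upper)) {
      abort("post_shift pushes a mean outside parameter bounds")
    }
  }
  structure(list(group = group, n = as.integer(n), means = mu,
                 sds = sds[pt$param], model = model, sessions = sessions,
                 post_shift = post_shift),
            class = "cohort_spec")
}

#' Reference cohort specifications
#'
#' Ready-made cohort specs whose parameter means/SDs follow published
#' group-level VPP summaries for healthy controls (`hc_cohort_spec`),
#' methamphetamine users at baseline (`mud_cohort_spec`), and the treated
#' subgroup before stimulation (`mud_t_pre_spec`). `rtms_post_shift()` is
#' the corresponding pre-to-post mean change: learning rate, outcome
#' sensitivity and RL weight fall after treatment while consistency, loss
#' aversion, loss impact and perseverance decay rise.
#'
#' @param n Cohort size (defaults follow the study group sizes: 39 HC,
#'   50 MUD, 24 treated).
#' @return A [cohort_spec()] (or, for `rtms_post_shift()`, a named numeric
#'   shift vector).
#' @export
hc_cohort_spec <- function(n = 39) {
  cohort_spec(
    "HC", n,
    means = c(A = 0.04, alpha = 0.95, cons = 1.62, lambda = 0.26,
              epP = 0.25, epN = -0.5, K = 0.4, w = 0.74),
    sds = c(A = 0.01, alpha = 0.05, cons = 0.1, lambda = 0.16,
            epP = 1.18, epN = 1.23, K = 0.17, w = 0.03)
  )
}

#' @rdname hc_cohort_spec
#' @export
mud_cohort_spec <- function(n = 50) {
  cohort_spec(
    "MUD", n,
    means = c(A = 0.17, alpha = 1.1, cons = 1.01, lambda = 0.1,
              epP = 0.86, epN = -0.21, K = 0.36, w = 0.64),
    sds = c(A = 0.07, alpha = 0.07, cons = 0.2, lambda = 0.18,
            epP = 1.81, epN = 1.31, K = 0.17, w = 0.12)
  )
}

#' @rdname hc_cohort_spec
#' @export
mud_t_pre_spec <- function(n = 24) {
  cohort_spec(
    "MUD-t", n,
    means = c(A = 0.19, alpha = 1.09, cons = 1.01, lambda = 0.13,
              epP = 0.62, epN = -0.28, K = 0.34, w = 0.65),
    sds = c(A = 0.08, alpha = 0.09, cons = 0.18, lambda = 0.25,
            epP = 1.89, epN = 1.23, K = 0.16, w = 0.11),
    sessions = c("pre", "post"),
    post_shift = rtms_post_shift()
  )
}

#' @rdname hc_cohort_spec
#' @export
rtms_post_shift <- function() {
  c(A = -0.14, alpha = -0.38, cons = 0.13, lambda = 0.38,
    epP = 0.41, epN = 0.49, K = 0.13, w = -0.11)
}

#' Craving-score generator settings
#'
#' Group/session means and SDs of the 1-100 self-report craving scale.
#' Defaults follow the treated group's published pre/post summaries
#' (pre 66.0 (17.6), post 34.6 (13.8)). Values are drawn from a normal,
#' rounded to the nearest integer (optionally the nearest 10, mirroring the
#' tendency of patients to report round numbers) and clipped to \[1, 100\].
#'
#' @param pre_mean,pre_sd,post_mean,post_sd Normal moments per session.
#' @param round_to 1 (default) or 10.
#' @return A list of class `craving_model`.
#' @export
craving_model <- function(pre_mean = 66.0, pre_sd = 17.6,
                          post_mean = 34.6, post_sd = 13.8, round_to = 1) {
  stopifnot(round_to %in% c(1, 10), pre_sd >= 0, post_sd >= 0)
  structure(list(pre_mean = pre_mean, pre_sd = pre_sd,
                 post_mean = post_mean, post_sd = post_sd,
                 round_to = round_to),
            class = "craving_model")
}

draw_craving <- function(n, mean, sd, round_to = 1) {
  x <- round(rnorm(n, mean, sd) / round_to) * round_to
  as.integer(pmin(pmax(x, 1), 100))
}

# Truncated-normal draw by inverse-CDF, exact within the bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  if (!is.finite(lower) && !is.finite(upper)) return(rnorm(n, mean, sd))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

draw_true_params <- function(spec, n = spec$n) {
  pt <- get_model(spec$model)$params
  draws <- purrr::map(seq_len(nrow(pt)), function(i) {
    rtruncnorm(n, spec$means[[pt$param[i]]], spec$sds[[pt$param[i]]],
               pt$lower[i], pt$upper[i])
  })
  names(draws) <- pt$param
  tibble::as_tibble(draws)
}

#' Generate a synthetic cohort of IGT players
#'
#' Draws each subject's true parameters from the spec's truncated-normal
#' distributions, then simulates a full task run per subject with
#' [simulate_agent()]. The true parameters are returned alongside the trial
#' data so downstream fits can be scored for parameter recovery.
#'
#' @param spec A [cohort_spec()].
#' @param schedule An [igt_schedule()].
#' @param seed Master seed: fixes both the parameter draws and every
#'   subject's choice stream.
#' @param outcome_scale Net-RMB divisor used by the simulated agents.
#' @return A list with `trials` (long tibble over all subjects) and `truth`
#'   (tibble: `subjID`, `group`, `session`, one column per parameter).
#' @export
#' @examples
#' sched <- igt_schedule(seed = 1)
#' coh <- generate_cohort(hc_cohort_spec(n = 3), sched, seed = 1)
#' dplyr::count(coh$trials, subjID)
generate_cohort <- function(spec, schedule, seed = 1L, outcome_scale = 100) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- withr::with_seed(as.integer(seed), draw_true_params(spec))
  ids <- sprintf("%s%03d", gsub("[^A-Za-z]", "", spec$group), seq_len(spec$n))
  sub_seeds <- withr::with_seed(as.integer(seed) + 1L,
                                sample.int(.Machine$integer.max, spec$n))
  trials <- purrr::map_dfr(seq_len(spec$n), function(i) {
    p <- check_params(as.list(truth[i, ]), spec$model)
    simulate_agent(p, spec$model, schedule, seed = sub_seeds[i],
                   subjID = ids[i], group = spec$group, session = "pre",
                   outcome_scale = outcome_scale)
  })
  truth <- dplyr::bind_cols(
    tibble::tibble(subjID = ids, group = spec$group, session = "pre"), truth)
  list(trials = trials, truth = truth)
}

#' Generate a paired pre/post treatment cohort
#'
#' Each subject receives pre-session true parameters drawn from `pre_spec`
#' and post-session parameters equal to pre + `post_shift` (truncated at the
#' bounds), plays the task in both sessions on the same payoff schedule, and
#' receives paired craving scores from the craving model. Optionally drops
#' `drop_post` randomly chosen post sessions to emulate attrition.
#'
#' @param pre_spec A [cohort_spec()] for the pre session.
#' @param post_shift Named additive shift of true parameters
#'   (default [rtms_post_shift()]).
#' @param schedule An [igt_schedule()].
#' @param seed Master seed.
#' @param craving A [craving_model()].
#' @param drop_post Number of post sessions to drop at random (default 0).
#' @param outcome_scale Net-RMB divisor used by the simulated agents.
#' @return A list with `trials`, `truth` (both sessions), and `craving`
#'   (tibble: `subjID`, `session`, `craving`).
#' @export
generate_treatment_cohort <- function(pre_spec,
                                      post_shift = rtms_post_shift(),
                                      schedule, seed = 1L,
                                      craving = craving_model(),
                                      drop_post = 0,
                                      outcome_scale = 100) {
  stopifnot(inherits(pre_spec, "cohort_spec"))
  pt <- get_model(pre_spec$model)$params
  shift <- setNames(rep(0, nrow(pt)), pt$param)
  shift[names(post_shift)] <- post_shift
  shifted_mean <- pre_spec$means + shift
  if (any(shifted_mean < pt$lower | shifted_mean > pt$upper)) {
    abort("post_shift pushes a mean outside parameter bounds")
  }
  n <- pre_spec$n
  pre_truth <- withr::with_seed(as.integer(seed), draw_true_params(pre_spec))
  post_truth <- pre_truth
  for (i in seq_len(nrow(pt))) {
    post_truth[[pt$param[i]]] <- pmin(
      pmax(pre_truth[[pt$param[i]]] + shift[i], pt$lower[i]), pt$upper[i])
  }
  ids <- sprintf("%s%03d", gsub("[^A-Za-z]", "", pre_spec$group), seq_len(n))
  seeds <- withr::with_seed(as.integer(seed) + 1L,
                            matrix(sample.int(.Machine$integer.max, 2 * n), n))
  sim_session <- function(truth, session, col) {
    purrr::map_dfr(seq_len(n), function(i) {
      p <- check_params(as.list(truth[i, ]), pre_spec$model)
      simulate_agent(p, pre_spec$model, schedule, seed = seeds[i, col],
                     subjID = ids[i], group = pre_spec$group,
                     session = session, outcome_scale = outcome_scale)
    })
  }
  trials <- dplyr::bind_rows(sim_session(pre_truth, "pre", 1),
                             sim_session(post_truth, "post", 2))
  truth <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(subjID = ids, group = pre_spec$group,
                                    session = "pre"), pre_truth),
    dplyr::bind_cols(tibble::tibble(subjID = ids, group = pre_spec$group,
                                    session = "post"), post_truth))
  craving_tbl <- withr::with_seed(as.integer(seed) + 2L, tibble::tibble(
    subjID = rep(ids, 2),
    session = rep(c("pre", "post"), each = n),
    craving = c(draw_craving(n, craving$pre_mean, craving$pre_sd,
                             craving$round_to),
                draw_craving(n, craving$post_mean, craving$post_sd,
                             craving$round_to))
  ))
  if (drop_post > 0) {
    dropped <- withr::with_seed(as.integer(seed) + 3L,
                                sample(ids, min(drop_post, n)))
    trials <- dplyr::filter(trials,
                            !(.data$session == "post" & .data$subjID %in% dropped))
    truth <- dplyr::filter(truth,
                           !(.data$session == "post" & .data$subjID %in% dropped))
    craving_tbl <- dplyr::filter(craving_tbl,
                                 !(.data$session == "post" & .data$subjID %in% dropped))
  }
  list(trials = trials, truth = truth, craving = craving_tbl)
}
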