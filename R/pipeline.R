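default_config <- function() {
  list(
    input = list(trials_csv = NULL, synthetic = NULL, craving_csv = NULL),
    models = c("pvl_delta", "pvl_decay", "vpp"),
    method = "map",
    qc_min_fraction = 0.05,
    seed = 1L,
    outdir = NULL,
    outcome_scale = 100,
    fit = list(n_restarts = 8, laplace_draws = 200,
               chains = 2, iter = 500, warmup = 250),
    schedule_seed = 0L,
    winner_preference = c("vpp", "pvl_delta", "pvl_decay")
  )
}

#' Validate a pipeline run configuration
#'
#' Merges a user configuration (a list, or a path to a YAML/JSON file) over
#' the defaults and validates it; unknown keys are rejected.
#'
#' @param config A named list or path to a YAML/JSON config file.
#' @return The validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(config)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      utils::modifyList(base[[nm]], config[[nm]])
    } else {
      config[[nm]]
    }
  }
  if (length(base$models) == 0) abort("Config must list at least one model")
  for (mn in base$models) get_model(mn)
  if (!base$method %in% c("map", "mcmc")) {
    abort("method must be 'map' or 'mcmc'")
  }
  stopifnot(base$qc_min_fraction >= 0, base$qc_min_fraction < 1)
  base
}

log_line <- function(lines, stage, msg) {
  c(lines, sprintf("[%s] %-8s %s",
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load or simulate trial data; exploration
#' quality control; fit every configured model; rank by LOOIC/WAIC; select
#' the winner; and run the group statistics on the winner's parameter
#' estimates (between-group contrasts per parameter, paired pre/post
#' contrasts where both sessions exist, craving mixed ANOVA and the
#' advantageous-rate repeated-measures ANOVA when the relevant data are
#' present, plus correlations of parameter change with craving change).
#' Artifacts (CSV/JSON) and a provenance log are written to `outdir` when
#' configured.
#'
#' @param config A configuration list or file path (see [validate_config()]).
#' @return A `report bundle` list: `config`, `qc`, `fits`, `comparison`,
#'   `winner`, `stats`, `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  lines <- character()
  schedule <- igt_schedule(seed = cfg$schedule_seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # ---- input ---------------------------------------------------------------
  craving <- NULL
  truth <- NULL
  trials <- stage("input", {
    if (!is.null(cfg$input$trials_csv)) {
      lines <- log_line(lines, "input", paste("reading", cfg$input$trials_csv))
      tr <- read_igt_trials(cfg$input$trials_csv)
      if (!is.null(cfg$input$craving_csv)) {
        craving <<- readr::read_csv(cfg$input$craving_csv,
                                    show_col_types = FALSE, progress = FALSE)
      }
      tr
    } else if (!is.null(cfg$input$synthetic)) {
      syn <- cfg$input$synthetic
      parts <- purrr::imap(syn$groups, function(g, nm) {
        spec <- cohort_spec(nm, g$n, unlist(g$means), unlist(g$sds),
                            model = syn$model %||% "vpp")
        if (isTRUE(g$treated)) {
          tc <- generate_treatment_cohort(
            spec, schedule = schedule, seed = cfg$seed,
            drop_post = g$drop_post %||% 0)
          craving <<- dplyr::bind_rows(craving, tc$craving)
          truth <<- dplyr::bind_rows(truth, tc$truth)
          tc$trials
        } else {
          coh <- generate_cohort(spec, schedule, seed = cfg$seed)
          truth <<- dplyr::bind_rows(truth, coh$truth)
          coh$trials
        }
      })
      dplyr::bind_rows(parts)
    } else {
      abort("Config needs input$trials_csv or input$synthetic")
    }
  })
  lines <- log_line(lines, "input", sprintf(
    "%d trials, %d subject-sessions", nrow(trials),
    nrow(dplyr::distinct(trials[intersect(c("subjID", "session"),
                                          names(trials))]))))

  # ---- QC ------------------------------------------------------------------
  qc <- stage("qc", qc_filter(trials, cfg$qc_min_fraction))
  lines <- log_line(lines, "qc", sprintf("%d kept, %d excluded",
                                         sum(!qc$log$excluded),
                                         sum(qc$log$excluded)))

  # ---- fits ----------------------------------------------------------------
  fits <- stage("fit", {
    setNames(lapply(cfg$models, function(mn) {
      if (cfg$method == "map") {
        fit_map(qc$kept, mn, n_restarts = cfg$fit$n_restarts,
                seed = cfg$seed, laplace_draws = cfg$fit$laplace_draws,
                outcome_scale = cfg$outcome_scale)
      } else {
        fit_hierarchical(qc$kept, mn, chains = cfg$fit$chains,
                         iter = cfg$fit$iter, warmup = cfg$fit$warmup,
                         seed = cfg$seed, outcome_scale = cfg$outcome_scale)
      }
    }), cfg$models)
  })

  # ---- comparison and winner ----------------------------------------------
  comparison <- stage("compare", compare_models(fits))
  winner <- stage("select", {
    top <- comparison$model[comparison$rank == 1]
    if (nrow(comparison) > 1) {
      second <- comparison[comparison$rank == 2, ]
      first <- comparison[comparison$rank == 1, ]
      if (abs(second$looic - first$looic) <= first$looic_se) {
        pref <- intersect(cfg$winner_preference, c(first$model, second$model))
        if (length(pref)) top <- pref[1]
        lines <- log_line(lines, "select", sprintf(
          "top two within 1 SE; preference order picked %s", top))
      }
    }
    top
  })
  lines <- log_line(lines, "select", paste("winner:", winner))

  # ---- group statistics on the winner's parameters -------------------------
  stats_out <- stage("stats", pipeline_stats(fits[[winner]], qc$kept, craving))

  bundle <- list(config = cfg, schedule = schedule, qc = qc, fits = fits,
                 comparison = comparison, winner = winner,
                 stats = stats_out, truth = truth, craving = craving,
                 log = lines)
  if (!is.null(cfg$outdir)) {
    stage("report", write_bundle(bundle, cfg$outdir))
  }
  bundle
}

# The statistical battery applied to a winning fit: between-group parameter
# contrasts, paired pre/post contrasts, craving mixed ANOVA, block-rate
# repeated-measures ANOVA, parameter-delta vs craving-delta correlations.
pipeline_stats <- function(fit, trials, craving = NULL) {
  est <- fit$estimates
  pt <- get_model(fit$model)$params
  out <- list()

  pre <- dplyr::filter(est, .data$session == "pre")
  groups <- setdiff(unique(pre$group), NA)
  if (length(groups) == 2) {
    g1 <- dplyr::filter(pre, .data$group == groups[1])
    g2 <- dplyr::filter(pre, .data$group == groups[2])
    out$between_group <- purrr::map_dfr(pt$param, function(p) {
      dplyr::bind_cols(tibble::tibble(param = p, group1 = groups[1],
                                      group2 = groups[2]),
                       independent_t(g1[[p]], g2[[p]]))
    })
  }

  paired <- dplyr::filter(est, .data$session %in% c("pre", "post"))
  both <- dplyr::group_by(paired, .data$subjID) |>
    dplyr::filter(dplyr::n() == 2) |> dplyr::ungroup()
  if (nrow(both) > 0 && length(unique(both$session)) == 2) {
    wide <- split(both[order(both$subjID), ], both$session[order(both$subjID)])
    out$pre_post <- purrr::map_dfr(pt$param, function(p) {
      dplyr::bind_cols(tibble::tibble(param = p),
                       paired_t(wide$pre[[p]], wide$post[[p]]))
    })
    deltas <- tibble::tibble(subjID = wide$pre$subjID)
    for (p in pt$param) deltas[[p]] <- wide$pre[[p]] - wide$post[[p]]
    out$param_deltas <- deltas
  }

  if (!is.null(craving) && all(c("subjID", "session", "craving") %in%
                               names(craving))) {
    cr <- dplyr::distinct(craving, .data$subjID, .data$session,
                          .keep_all = TRUE)
    grp_map <- dplyr::distinct(est, .data$subjID, .data$group)
    cr <- dplyr::left_join(cr, grp_map, by = "subjID")
    two_sessions <- dplyr::group_by(cr, .data$subjID) |>
      dplyr::filter(dplyr::n() == 2) |> dplyr::ungroup()
    if (length(setdiff(unique(cr$group), NA)) == 2 &&
        nrow(two_sessions) > 0) {
      out$craving_anova <- mixed_anova(
        dplyr::transmute(two_sessions, subject = .data$subjID,
                         time = .data$session, group = .data$group,
                         value = .data$craving))
    }
    if (!is.null(out$param_deltas)) {
      crw <- tidyr::pivot_wider(cr, id_cols = "subjID",
                                names_from = "session",
                                values_from = "craving")
      if (all(c("pre", "post") %in% names(crw))) {
        crw$craving_delta <- crw$pre - crw$post
        out$craving_correlations <- craving_correlation_analysis(
          out$param_deltas, crw[c("subjID", "craving_delta")])
      }
    }
  }

  rates <- tryCatch(block_advantage_rates(trials), error = function(e) NULL)
  if (!is.null(rates) && "session" %in% names(rates) &&
      length(intersect(c("pre", "post"), unique(rates$session))) == 2) {
    complete <- dplyr::group_by(rates, .data$subjID) |>
      dplyr::filter(length(unique(.data$session)) == 2) |>
      dplyr::ungroup()
    if (nrow(complete) > 0) {
      out$block_rate_anova <- rm_anova(
        dplyr::transmute(complete, subject = .data$subjID,
                         time = .data$session, block = .data$block,
                         value = .data$adv_rate))
    }
  }
  out
}

#' Correlate per-subject parameter changes with craving change
#'
#' Pearson correlation (with `df = n - 2`) of each parameter-change column
#' against the craving change, matched by `subjID`.
#'
#' @param params_delta Tibble with `subjID` plus one column per parameter
#'   change.
#' @param clinical Tibble with `subjID` and `craving_delta` (plus any other
#'   covariate columns, which are correlated too).
#' @return A tibble: `variable`, `r`, `df`, `p.value`, `n`.
#' @export
craving_correlation_analysis <- function(params_delta, clinical) {
  joined <- dplyr::inner_join(params_delta, clinical, by = "subjID")
  if (nrow(joined) < 3) abort("Need at least 3 matched subjects")
  vars <- setdiff(names(joined), c("subjID", "craving_delta"))
  purrr::map_dfr(vars, function(v) {
    ok <- complete.cases(joined[[v]], joined$craving_delta)
    dplyr::bind_cols(
      tibble::tibble(variable = v),
      pearson_r(joined[[v]][ok], joined$craving_delta[ok]),
      tibble::tibble(n = sum(ok)))
  })
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$qc$log, file.path(outdir, "qc_log.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(bundle$comparison),
                   file.path(outdir, "model_comparison.csv"), progress = FALSE)
  for (nm in names(bundle$fits)) {
    readr::write_csv(tidy(bundle$fits[[nm]]),
                     file.path(outdir, paste0("params_", nm, ".csv")),
                     progress = FALSE)
  }
  stats_json <- purrr::map(bundle$stats, function(x) {
    if (is.data.frame(x)) as.list(tibble::as_tibble(x)) else x
  })
  jsonlite::write_json(stats_json, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(bundle$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  provenance <- c(
    sprintf("seed: %s", bundle$config$seed),
    sprintf("schedule_seed: %s", bundle$config$schedule_seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("winner: %s", bundle$winner),
    bundle$log
  )
  writeLines(provenance, file.path(outdir, "provenance.log"))
  invisible(outdir)
}
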