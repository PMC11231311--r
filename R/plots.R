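#' Plot the IGT learning curve
#'
#' Block-wise advantageous-choice rates, one line per group/session mean
#' with per-subject points, the classic way IGT performance is displayed.
#'
#' @param trials Long trial data.
#' @param block_size Trials per block (default 20).
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(trials, block_size = 20L) {
  rates <- block_advantage_rates(trials, block_size)
  grp_cols <- intersect(c("group", "session"), names(rates))
  rates$curve <- if (length(grp_cols)) {
    interaction(rates[grp_cols], drop = TRUE, sep = " / ")
  } else {
    factor("all")
  }
  means <- dplyr::summarise(dplyr::group_by(rates, .data$curve, .data$block),
                            adv_rate = mean(.data$adv_rate), .groups = "drop")
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$block, y = .data$adv_rate,
                                      colour = .data$curve)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::geom_point(data = means, size = 2) +
    ggplot2::labs(x = "Block", y = "Advantageous-choice rate (C or D)",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_map Parameter-estimate dot plot by group/session.
#' @param object An `igt_fit`.
#' @method autoplot igt_fit
#' @export
autoplot.igt_fit <- function(object, ...) {
  long <- tidy(object)
  long$panel <- interaction(long$group, long$session, drop = TRUE, sep = " / ")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$panel, y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Estimate",
                  title = paste(object$model, "parameter estimates")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn compare_models Information-criterion dot plot with SE bars.
#' @param object An `igt_comparison`.
#' @method autoplot igt_comparison
#' @export
autoplot.igt_comparison <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  tbl$model <- stats::reorder(tbl$model, -tbl$looic)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$looic, y = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$looic - .data$looic_se,
                                         xmax = .data$looic + .data$looic_se),
                            height = 0.15) +
    ggplot2::labs(x = "LOOIC (lower is better)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive block-rate check
#'
#' Observed block-wise advantageous-choice curve with the predictive mean
#' and 90% band from [posterior_predict()].
#'
#' @param pp Output of [posterior_predict()].
#' @return A ggplot object.
#' @export
plot_posterior_predictive <- function(pp) {
  ggplot2::ggplot(pp$blocks, ggplot2::aes(x = .data$block)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lo,
                                      ymax = .data$pred_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linetype = 2) +
    ggplot2::labs(x = "Block", y = "Advantageous-choice rate") +
    ggplot2::theme_minimal()
}
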