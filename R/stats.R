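ttest_row <- function(statistic, df, p, d, variant, levene_p = NA_real_) {
  tibble::tibble(statistic = statistic, df = df, p.value = p, cohen_d = d,
                 variant = variant, levene_p = levene_p)
}

#' Independent two-sample t test with a Levene gate
#'
#' Runs Levene's test for equality of variances (mean-centred by default;
#' median-centring gives the Brown-Forsythe variant) and, when gated,
#' switches to Welch's t with Satterthwaite degrees of freedom if the Levene
#' p-value falls below `alpha`; otherwise the classic pooled-variance t with
#' `n1 + n2 - 2` df is used. Cohen's d uses the pooled SD in both cases.
#'
#' @param x,y Numeric samples (each `n >= 2`).
#' @param gate_by_levene Apply the Levene gate (default TRUE). If FALSE the
#'   pooled test is always used.
#' @param levene_center `"mean"` (default) or `"median"`.
#' @param alpha Gate threshold on the Levene p-value (default 0.05).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `cohen_d`,
#'   `variant`, `levene_p`.
#' @export
#' @examples
#' independent_t(rnorm(20), rnorm(20, 1))
independent_t <- function(x, y, gate_by_levene = TRUE,
                          levene_center = c("mean", "median"), alpha = 0.05) {
  levene_center <- match.arg(levene_center)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    abort("t statistic undefined: both samples constant with equal means")
  }
  centre <- if (levene_center == "mean") mean else stats::median
  lev <- car::leveneTest(
    c(x, y), factor(rep(c("x", "y"), c(length(x), length(y)))),
    center = centre)
  levene_p <- lev[["Pr(>F)"]][1]
  use_welch <- gate_by_levene && !is.na(levene_p) && levene_p < alpha
  tt <- t.test(x, y, var.equal = !use_welch)
  sp <- pooled_sd(sd(x), length(x), sd(y), length(y))
  d <- (mean(x) - mean(y)) / sp
  ttest_row(unname(tt$statistic), unname(tt$parameter), tt$p.value, d,
            if (use_welch) "welch" else "pooled", levene_p)
}

pooled_sd <- function(sd1, n1, sd2, n2) {
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Two-sample t test from summary statistics
#'
#' Computes the pooled or Welch t statistic, degrees of freedom, two-sided
#' p-value and pooled-SD Cohen's d directly from group means, SDs and sizes
#' — the form needed to check statistics reported alongside summary tables.
#'
#' @param m1,sd1,n1 Mean, SD and size of the first sample.
#' @param m2,sd2,n2 Mean, SD and size of the second sample.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A one-row tibble as in [independent_t()].
#' @export
#' @examples
#' t_from_summaries(15.83, 13.54, 24, 16.19, 8.88, 26)
t_from_summaries <- function(m1, sd1, n1, m2, sd2, n2,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0 && m1 == m2) {
    abort("t statistic undefined: zero variance and equal means")
  }
  if (variant == "pooled") {
    sp <- pooled_sd(sd1, n1, sd2, n2)
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  d <- (m1 - m2) / pooled_sd(sd1, n1, sd2, n2)
  ttest_row(t, df, 2 * pt(-abs(t), df), d, variant)
}

#' Paired t test
#'
#' t test on within-subject differences with `n - 1` degrees of freedom;
#' Cohen's d is the mean difference divided by the SD of the differences.
#'
#' @param pre,post Matched numeric samples of equal length (`n >= 2`).
#' @return A one-row tibble as in [independent_t()], `variant = "paired"`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  diffs <- pre - post
  if (sd(diffs) == 0) {
    abort("t statistic undefined: all paired differences are equal")
  }
  tt <- t.test(pre, post, paired = TRUE)
  ttest_row(unname(tt$statistic), unname(tt$parameter), tt$p.value,
            mean(diffs) / sd(diffs), "paired")
}

anova_rows <- function(effects, ss_eff, ss_err, df_num, df_den) {
  # constant data gives 0/0; report F = 0 rather than NaN
  tol <- .Machine$double.eps^0.75
  f <- ifelse(ss_eff < tol, 0, (ss_eff / df_num) / (ss_err / df_den))
  tibble::tibble(
    effect = effects, F = f, df_num = df_num, df_den = df_den,
    p.value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
    partial_eta_sq = ifelse(ss_eff < tol, 0,
                            ss_eff / (ss_eff + ss_err))
  )
}

check_factor_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
}

#' Two-by-two mixed ANOVA
#'
#' Mixed-design ANOVA with one within-subjects factor (`time`) and one
#' between-subjects factor (`group`), via the standard within/between
#' sums-of-squares decomposition (subjects nested in groups). Reports F,
#' degrees of freedom, p and partial eta squared for the Group, Time and
#' Time x Group effects.
#'
#' @param data Long data frame with columns `subject`, `time`, `group`,
#'   `value`; every subject must have every time point.
#' @return A tibble with one row per effect.
#' @export
mixed_anova <- function(data) {
  check_factor_cols(data, c("subject", "time", "group", "value"))
  data <- tibble::as_tibble(data)
  data$subject <- as.character(data$subject)
  tab <- table(data$subject, data$time)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    abort(paste0("Missing/duplicated cell(s) for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  a <- length(unique(data$group))   # between levels
  b <- length(unique(data$time))    # within levels
  n_sub <- length(unique(data$subject))
  gm <- mean(data$value)
  cell <- dplyr::summarise(dplyr::group_by(data, .data$group, .data$time),
                           m = mean(.data$value), n = dplyr::n(),
                           .groups = "drop")
  grp <- dplyr::summarise(dplyr::group_by(data, .data$group),
                          m = mean(.data$value), n = dplyr::n(), .groups = "drop")
  tim <- dplyr::summarise(dplyr::group_by(data, .data$time),
                          m = mean(.data$value), n = dplyr::n(), .groups = "drop")
  subj <- dplyr::summarise(dplyr::group_by(data, .data$subject, .data$group),
                           m = mean(.data$value), n = dplyr::n(), .groups = "drop")
  ss_group <- sum(grp$n * (grp$m - gm)^2)
  ss_time <- sum(tim$n * (tim$m - gm)^2)
  ss_cells <- sum(cell$n * (cell$m - gm)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_subj <- sum(subj$n * (subj$m - gm)^2)
  ss_subj_within <- ss_subj - ss_group          # error for Group
  ss_total <- sum((data$value - gm)^2)
  ss_within_err <- ss_total - ss_subj - ss_time - ss_int  # error for Time
  df_group <- a - 1
  df_time <- b - 1
  df_int <- df_group * df_time
  df_err_between <- n_sub - a
  df_err_within <- (n_sub - a) * df_time
  anova_rows(
    c("group", "time", "time:group"),
    c(ss_group, ss_time, ss_int),
    c(ss_subj_within, ss_within_err, ss_within_err),
    c(df_group, df_time, df_int),
    c(df_err_between, df_err_within, df_err_within)
  )
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subjects design with factors `time` and `block`; each effect
#' is tested against its own effect-by-subject interaction stratum (the
#' univariate repeated-measures decomposition). Reports F, df, p and partial
#' eta squared for Time, Block and Time x Block.
#'
#' @param data Long data frame with columns `subject`, `time`, `block`,
#'   `value`; every subject needs the complete time x block crossing.
#' @return A tibble with one row per effect.
#' @export
rm_anova <- function(data) {
  check_factor_cols(data, c("subject", "time", "block", "value"))
  data <- tibble::as_tibble(data)
  data$subject <- as.character(data$subject)
  tab <- table(data$subject, paste(data$time, data$block))
  if (any(tab != 1)) abort("Incomplete time x block crossing for some subject")
  n <- length(unique(data$subject))
  a <- length(unique(data$time))
  b <- length(unique(data$block))
  gm <- mean(data$value)
  m_s <- tapply(data$value, data$subject, mean)
  m_a <- tapply(data$value, data$time, mean)
  m_b <- tapply(data$value, data$block, mean)
  m_ab <- tapply(data$value, list(data$time, data$block), mean)
  m_as <- tapply(data$value, list(data$time, data$subject), mean)
  m_bs <- tapply(data$value, list(data$block, data$subject), mean)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - gm)^2) - ss_a - ss_b
  ss_as <- b * sum((m_as - gm)^2) - ss_a - ss_s
  ss_bs <- a * sum((m_bs - gm)^2) - ss_b - ss_s
  ss_total <- sum((data$value - gm)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  anova_rows(
    c("time", "block", "time:block"),
    c(ss_a, ss_b, ss_ab),
    c(ss_as, ss_bs, ss_abs),
    c(a - 1, b - 1, (a - 1) * (b - 1)),
    c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1))
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`), non-degenerate.
#' @return A one-row tibble: `r`, `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in correlation input")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p.value = ct$p.value)
}
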