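test_that("independent t handles identity, hand-computed and gated cases", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  got <- independent_t(x, y, gate_by_levene = FALSE)
  # hand computation: pooled sd = 1, se = sqrt(2/3)
  expect_equal(got$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(got$df, 4)
  expect_identical(got$variant, "pooled")
  expect_equal(got$cohen_d, -3, tolerance = 1e-12)

  same <- independent_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$cohen_d, 0)

  set.seed(1)
  a <- rnorm(40, sd = 10)
  b <- rnorm(40, sd = 1)
  gated <- independent_t(a, b)
  expect_identical(gated$variant, "welch")
  expect_lt(gated$levene_p, 0.05)
  ungated <- independent_t(a, b, gate_by_levene = FALSE)
  expect_identical(ungated$variant, "pooled")

  expect_error(independent_t(c(1, 1, 1), c(1, 1, 1)), "undefined")
})

test_that("summary-statistic t agrees with the raw-sample computation", {
  set.seed(3)
  x <- rnorm(14, 1)
  y <- rnorm(19, 0.4)
  raw <- independent_t(x, y, gate_by_levene = FALSE)
  summ <- t_from_summaries(mean(x), sd(x), 14, mean(y), sd(y), 19)
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(summ$df, raw$df, tolerance = 1e-10)
  expect_equal(summ$p.value, raw$p.value, tolerance = 1e-10)
  expect_equal(summ$cohen_d, raw$cohen_d, tolerance = 1e-10)

  raw_w <- independent_t(x, y, levene_center = "median", alpha = 1)
  summ_w <- t_from_summaries(mean(x), sd(x), 14, mean(y), sd(y), 19,
                             variant = "welch")
  expect_equal(summ_w$statistic, raw_w$statistic, tolerance = 1e-10)
  expect_equal(summ_w$df, raw_w$df, tolerance = 1e-10)

  expect_equal(t_from_summaries(5, 1, 10, 5, 2, 12)$statistic, 0)
  expect_error(t_from_summaries(1, 0, 5, 1, 0, 5), "undefined")
})

test_that("Welch df never exceeds pooled df and coincides for equal-var equal-n", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(5:30, 1)
    n2 <- sample(5:30, 1)
    s1 <- runif(1, 0.5, 3)
    s2 <- runif(1, 0.5, 3)
    welch <- t_from_summaries(0.3, s1, n1, 0, s2, n2, variant = "welch")
    expect_lte(welch$df, n1 + n2 - 2)
  }
  a <- t_from_summaries(1, 2, 15, 0, 2, 15, variant = "welch")
  b <- t_from_summaries(1, 2, 15, 0, 2, 15, variant = "pooled")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$df, b$df, tolerance = 1e-12)
})

test_that("paired t matches hand-computed differences and rejects degeneracy", {
  pre <- c(1, 2, 3, 4)
  post <- c(2, 2, 5, 6)
  got <- paired_t(pre, post)
  d <- pre - post                      # (-1, 0, -2, -2)
  expect_equal(got$statistic, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_equal(got$cohen_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "undefined")
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "undefined")
})

test_that("mixed ANOVA recovers constructed effects and the t-square identity", {
  base <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                             time = c("pre", "post"))
  base$group <- rep(rep(c("g1", "g2"), each = 2), 8)

  const <- dplyr::mutate(base, value = 7)
  res <- mixed_anova(const)
  expect_equal(res$F, rep(0, 3))
  expect_equal(res$partial_eta_sq, rep(0, 3))

  set.seed(2)
  shift <- dplyr::mutate(base, value = rep(rnorm(16), each = 2) +
                           ifelse(group == "g2", 5, 0))
  res2 <- mixed_anova(shift)
  expect_gt(res2$F[res2$effect == "group"], 50)
  expect_equal(res2$F[res2$effect == "time"], 0)
  expect_equal(res2$F[res2$effect == "time:group"], 0)

  set.seed(4)
  d <- dplyr::mutate(base, value = rnorm(32) +
                       ifelse(time == "post" & group == "g2", 1.5, 0))
  res3 <- mixed_anova(d)
  wide <- tidyr::pivot_wider(d, names_from = time, values_from = value)
  tt <- independent_t(wide$pre[wide$group == "g1"] - wide$post[wide$group == "g1"],
                      wide$pre[wide$group == "g2"] - wide$post[wide$group == "g2"],
                      gate_by_levene = FALSE)
  expect_equal(res3$F[res3$effect == "time:group"], tt$statistic^2,
               tolerance = 1e-10)
  expect_error(mixed_anova(d[-1, ]), "s01")
})

test_that("mixed ANOVA sums of squares match the aov Error-stratum oracle", {
  set.seed(5)
  d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                          time = c("pre", "post"))
  d$group <- rep(rep(c("g1", "g2"), each = 2), 6)
  d$value <- rnorm(24, sd = 2) + ifelse(d$time == "post", 0.8, 0) +
    ifelse(d$group == "g2", -0.5, 0)
  got <- mixed_anova(d)
  ref <- summary(aov(value ~ group * time + Error(subject / time), data = d))
  f_group <- ref[["Error: subject"]][[1]]["group", "F value"]
  f_time <- ref[["Error: subject:time"]][[1]]["time", "F value"]
  f_int <- ref[["Error: subject:time"]][[1]]["group:time", "F value"]
  expect_equal(got$F[got$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "time"], f_time, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "time:group"], f_int, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA matches aov and recognises constructions", {
  grid <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                             time = c("pre", "post"), block = 1:5)
  const <- dplyr::mutate(grid, value = 3)
  expect_equal(rm_anova(const)$F, rep(0, 3))

  set.seed(6)
  lin <- dplyr::mutate(grid, value = 0.1 * block + rnorm(100, sd = 0.05))
  res <- rm_anova(lin)
  expect_gt(res$F[res$effect == "block"], 10)
  expect_lt(res$p.value[res$effect == "block"], 0.01)
  expect_gt(res$p.value[res$effect == "time"], 0.05)

  set.seed(7)
  d <- dplyr::mutate(grid, value = rnorm(100) + 0.2 * block +
                       ifelse(time == "post", 0.4, 0))
  got <- rm_anova(d)
  ref <- summary(aov(value ~ time * factor(block) +
                       Error(subject / (time * factor(block))), data = d))
  expect_equal(got$F[got$effect == "time"],
               ref[["Error: subject:time"]][[1]]["time", "F value"],
               tolerance = 1e-10)
  expect_equal(got$F[got$effect == "block"],
               ref[["Error: subject:factor(block)"]][[1]]["factor(block)", "F value"],
               tolerance = 1e-10)
  expect_equal(got$F[got$effect == "time:block"],
               ref[["Error: subject:time:factor(block)"]][[1]][
                 "time:factor(block)", "F value"],
               tolerance = 1e-10)
  expect_error(rm_anova(d[-1, ]), "Incomplete")
})

test_that("ANOVA outputs stay within probability and effect-size ranges", {
  set.seed(11)
  for (i in 1:10) {
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:8),
                            time = c("pre", "post"))
    d$group <- rep(rep(c("g1", "g2"), each = 2), 4)
    d$value <- rnorm(16, sd = runif(1, 0.1, 3))
    res <- mixed_anova(d)
    expect_true(all(res$p.value >= 0 & res$p.value <= 1))
    expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
    expect_true(all(res$F >= 0))
  }
})

test_that("Pearson correlation handles exact, null and degenerate inputs", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  got <- pearson_r(x, c(2, 1, 5, 4, 8))
  expect_equal(got$df, 3)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "n >= 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "Zero variance")
  # null calibration: |r| under independence stays below the critical value
  # (0.28 at n = 50, alpha = .05) in about 95% of replicates
  set.seed(12)
  inside <- mean(replicate(300, abs(pearson_r(rnorm(50), rnorm(50))$r) < 0.28))
  expect_gt(inside, 0.90)
  expect_lt(inside, 0.99)
})
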