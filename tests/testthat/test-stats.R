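test_that("accuracy tables score 'don't know' as incorrect and drop faceless observers", {
  log <- tibble::tibble(
    observer = rep(c("a", "b", "c"), each = 20),
    class = rep("max", 60),
    kind = c(rep("face", 40), rep("object", 20)),
    truth = rep("happy", 60),
    response = c(rep(c("happy", "neutral"), 10),   # a: 10/20
                 rep("dont_know", 20),             # b: 0/20
                 rep("happy", 20))                 # c: objects only
  )
  expect_warning(acc <- accuracy_table(log), "no face trials")
  expect_equal(nrow(acc), 2)
  expect_equal(acc$accuracy_pct[acc$observer == "a"], 50)
  expect_equal(acc$accuracy_pct[acc$observer == "b"], 0)
  expect_error(accuracy_table(log[0, ]), "empty")
  expect_error(accuracy_table(log[, 1:2]), "columns")
})

test_that("the classical one-way ANOVA matches the textbook formula oracle", {
  withr::with_seed(10, {
    df <- tibble::tibble(
      g = rep(c("a", "b", "c"), times = c(30, 25, 35)),
      v = rnorm(90, mean = c(a = 10, b = 12, c = 9)[rep(c("a", "b", "c"),
                times = c(30, 25, 35))], sd = 2)
    )
  })
  fit <- oneway_anova(df, v, g)
  # independent direct evaluation of the sums of squares
  gm <- mean(df$v)
  m_g <- tapply(df$v, df$g, mean)
  n_g <- table(df$g)
  ssb <- sum(n_g * (m_g - gm)^2)
  ssw <- sum((df$v - m_g[df$g])^2)
  f_oracle <- (ssb / 2) / (ssw / 87)
  expect_lt(abs(fit$ss_effect - ssb), 1e-9)
  expect_lt(abs(fit$ss_resid - ssw), 1e-9)
  expect_lt(abs(fit$statistic - f_oracle), 1e-9)
  expect_equal(fit$ms_effect, fit$ss_effect / fit$df1)
  expect_equal(fit$ms_resid, fit$ss_resid / fit$df2)

  # two identical groups -> F = 0
  df0 <- tibble::tibble(g = rep(c("a", "b"), each = 5), v = rep(1:5, 2))
  expect_equal(oneway_anova(df0, v, g)$statistic, 0)

  expect_error(oneway_anova(df[df$g == "a", ], v, g), "2 groups")
})

test_that("Brown-Forsythe reduces exactly to classical F under equal variances; Welch in the limit", {
  # identical group variances, equal n, small sample
  base <- c(2.3, 4.1, 0.7, 5.2, 3.3, 1.9, 2.8, 4.6, 0.2, 3.9)
  df <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 10),
    v = c(base, base + 1, base + 2.5)
  )
  f_none <- oneway_anova(df, v, g)
  f_bf <- brown_forsythe_anova(df, v, g)
  expect_lt(abs(f_bf$statistic - f_none$statistic), 1e-9)
  expect_lt(abs(f_bf$df2 - f_none$df2), 1e-9)

  # Welch agrees with classical F in the large equal-n limit
  withr::with_seed(11, base_l <- rnorm(2e5))
  df_l <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 2e5),
    v = c(base_l, base_l + 0.01, base_l + 0.02)
  )
  f_none_l <- oneway_anova(df_l, v, g)
  f_w_l <- welch_anova(df_l, v, g)
  expect_lt(abs(f_w_l$statistic - f_none_l$statistic) / f_none_l$statistic, 1e-5)

  # Welch denominator df never exceeds N - k
  withr::with_seed(12, {
    dfh <- tibble::tibble(
      g = rep(c("a", "b", "c"), times = c(13, 12, 13)),
      v = rnorm(38, sd = rep(c(3, 1, 1), times = c(13, 12, 13)))
    )
  })
  expect_lte(welch_anova(dfh, v, g)$df2, 38 - 3)
  expect_lte(brown_forsythe_anova(dfh, v, g)$df2, 38 - 3)
})

test_that("Levene's test detects variance heterogeneity and is zero for identical groups", {
  df0 <- tibble::tibble(g = rep(c("a", "b"), each = 6), v = rep(c(1, 4, 2, 5, 3, 6), 2))
  expect_equal(levene_test(df0, v, g)$statistic, 0)
  withr::with_seed(13, {
    dfh <- tibble::tibble(
      g = rep(c("a", "b"), each = 50),
      v = c(rnorm(50, sd = 1), rnorm(50, sd = 5))
    )
  })
  expect_lt(levene_test(dfh, v, g)$p_value, 0.01)
  # mean- and median-centered variants agree on large symmetric samples
  withr::with_seed(14, {
    dfs <- tibble::tibble(g = rep(c("a", "b", "c"), each = 1000), v = rnorm(3000))
  })
  p_mean <- levene_test(dfs, v, g, "mean")$p_value
  p_median <- levene_test(dfs, v, g, "median")$p_value
  expect_lt(abs(p_mean - p_median), 0.2)
})

test_that("effect sizes follow the closed forms", {
  es <- effect_sizes(1, 1)
  expect_equal(es$eta_p_sq, 0.5)
  expect_equal(es$cohens_f, 1)
  expect_warning(effect_sizes(1, 0), "infinite")
})

test_that("Tukey post hocs match TukeyHSD and the adjustment identities", {
  withr::with_seed(15, {
    df <- tibble::tibble(
      g = factor(rep(c("a", "b", "c"), times = c(13, 12, 13))),
      v = rnorm(38, mean = rep(c(60, 35, 8), times = c(13, 12, 13)), sd = 15)
    )
  })
  ph <- tukey_posthoc(df, v, g)
  # cross-check every pair against stats::TukeyHSD
  hsd <- TukeyHSD(aov(v ~ g, data = df))$g
  for (i in seq_len(nrow(ph))) {
    key1 <- paste0(ph$group_1[i], "-", ph$group_2[i])
    key2 <- paste0(ph$group_2[i], "-", ph$group_1[i])
    row <- if (key1 %in% rownames(hsd)) hsd[key1, ] else -hsd[key2, c(1, 3, 2, 4)]
    expect_lt(abs(abs(ph$mean_difference[i]) - abs(row[1])), 1e-8)
    expect_lt(abs(ph$p_tukey[i] - abs(row[4])), 1e-8)
  }
  # t = diff / SE; telescoping identity of ordered-mean differences
  expect_equal(ph$statistic, ph$mean_difference / ph$se)
  d <- function(a, b) ph$mean_difference[ph$group_1 == a & ph$group_2 == b]
  expect_equal(d("a", "c"), d("a", "b") + d("b", "c"))
  # Holm never exceeds Bonferroni
  expect_true(all(ph$p_holm <= ph$p_bonf + 1e-15))

  # equal-mean groups: t = 0, all corrected p = 1
  df0 <- tibble::tibble(g = rep(c("a", "b"), each = 5), v = rep(c(1, 2, 3, 4, 5), 2))
  ph0 <- tukey_posthoc(df0, v, g)
  expect_equal(ph0$statistic, 0)
  expect_equal(ph0$p_tukey, 1)
  expect_equal(ph0$p_bonf, 1)
})

test_that("Holm is never above Bonferroni across random datasets", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      df <- tibble::tibble(
        g = rep(c("a", "b", "c", "d"), each = 8),
        v = rnorm(32, mean = rep(c(0, 0.3, 0.8, 1.2), each = 8))
      )
    })
    ph <- tukey_posthoc(df, v, g)
    expect_true(all(ph$p_holm <= ph$p_bonf + 1e-15))
  }
})

test_that("Clopper-Pearson intervals match the beta-quantile closed form", {
  ci <- binomial_ci(c(0, 61, 100), c(10, 100, 100))
  expect_equal(ci$lower[1], 0)
  expect_equal(ci$upper[3], 1)
  # oracle: exact beta quantiles
  expect_lt(abs(ci$lower[2] - qbeta(0.025, 61, 40)), 1e-10)
  expect_lt(abs(ci$upper[2] - qbeta(0.975, 62, 39)), 1e-10)
  expect_true(ci$lower[2] < 0.61 && ci$upper[2] > 0.61)
  expect_error(binomial_ci(5, 3), "k <= n")
})

test_that("the full battery reproduces itself coherently through tidy and glance", {
  logs <- simulate_response_logs(seed = 21)
  acc <- accuracy_table(logs)
  fit <- nl_anova(acc, accuracy_pct, class)
  tab <- tidy(fit)
  expect_equal(tab$correction, c("none", "brown_forsythe", "welch"))
  # the three variants share the sums of squares; only df2/F/p differ
  expect_equal(tab$ss_effect, rep(tab$ss_effect[1], 3))
  expect_equal(tab$ss_resid, rep(tab$ss_resid[1], 3))
  expect_equal(tab$eta_p_sq, rep(tab$eta_p_sq[1], 3))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 38)
  expect_equal(gl$statistic, tab$statistic[1])
  expect_equal(gl$cohens_f, sqrt(gl$eta_p_sq / (1 - gl$eta_p_sq)))
  # group means recovered in the generating order
  gm <- fit$groups$mean[match(c("min", "med", "max"), fit$groups$group)]
  expect_true(all(diff(gm) > 0))
  # posthoc groups ordered by descending mean -> positive differences
  expect_true(all(fit$posthoc$mean_difference > 0))
})
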