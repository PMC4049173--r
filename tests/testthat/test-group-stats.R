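test_that("pooled t from summaries equals pooled t from raw samples", {
  set.seed(61)
  a <- rnorm(20, 10, 2)
  b <- rnorm(25, 8, 3)
  from_raw <- two_sample_t(a, b)
  from_sum <- two_sample_t(group_summary(mean(a), sd(a), 20),
                           group_summary(mean(b), sd(b), 25))
  expect_equal(from_raw$value, from_sum$value)
  expect_equal(from_raw$p, from_sum$p)
  # oracle: stats::t.test with pooled variance
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(from_raw$value, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(from_raw$p, tt$p.value, tolerance = 1e-12)
  # identical summaries -> t = 0
  s <- group_summary(5, 1, 10)
  expect_equal(two_sample_t(s, s)$value, 0)
  expect_error(two_sample_t(1, b), class = "zt_invalid_input")
})

test_that("one-sided t option halves the consistent tail", {
  s1 <- group_summary(10, 2, 12)
  s2 <- group_summary(8, 2, 12)
  two <- two_sample_t(s1, s2)
  one <- two_sample_t(s1, s2, alternative = "greater")
  expect_equal(one$p, two$p / 2)
})

test_that("paired t matches the hand-computed example and flags degeneracy", {
  expect_equal(paired_t(c(5, 6, 7), c(3, 5, 4))$value, 2 * sqrt(3),
               tolerance = 1e-12)
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$value, 0)
  deg <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_error(paired_t(1:3, 1:4), class = "zt_invalid_input")
})

test_that("Pearson chi-squared matches hand values without correction", {
  # direct evaluation with E = [[2.5, 7.5], [2.5, 7.5]]
  expect_equal(pearson_chi2(matrix(c(5, 0, 5, 10), 2))$value, 20 / 3,
               tolerance = 1e-12)
  # oracle: stats::chisq.test without continuity correction
  tab <- matrix(c(17, 6, 30, 51), 2)
  expect_equal(pearson_chi2(tab)$value,
               unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-12)
  # transposition invariance and null table
  expect_equal(pearson_chi2(t(tab))$value, pearson_chi2(tab)$value)
  expect_equal(pearson_chi2(matrix(c(10, 20, 5, 10), 2))$value, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 10), 2)),
               class = "zt_invalid_input")
})

test_that("correlation handles monotone, tied and constant input", {
  expect_equal(correlate(1:5, c(2, 4, 9, 16, 30))$value, 1)
  expect_equal(correlate(1:5, -(1:5))$value, -1)
  # hand value: d^2 = 2 -> rho = 1 - 12/60
  expect_equal(correlate(1:4, c(1, 3, 2, 4))$value, 0.8)
  expect_equal(correlate(1:4, c(1, 3, 2, 4), method = "pearson")$value,
               cor(1:4, c(1, 3, 2, 4)))
  expect_error(correlate(rep(1, 5), 1:5), class = "zt_undefined_metric")
  expect_error(correlate(1:2, 1:2), class = "zt_invalid_input")
})

test_that("one-way ANOVA matches the hand example and the F = t^2 identity", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(res$value, 3, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  # two groups: F = t^2 exactly
  set.seed(62)
  g1 <- rnorm(11, 5, 2)
  g2 <- rnorm(14, 6, 2)
  f2 <- one_way_anova(list(g1 = g1, g2 = g2))
  t2 <- two_sample_t(g1, g2)
  expect_equal(f2$value, t2$value^2, tolerance = 1e-9)
  # near-identical groups with internal variance -> F ~ 0
  g <- c(1, 2, 3, 4)
  expect_lt(one_way_anova(list(g, g, g))$value, 1e-20)
  # post hoc tables
  ph <- one_way_anova(list(a = g1, b = g2, c = g2 + 2), posthoc = "tukey")
  expect_identical(nrow(ph$posthoc), 3L)
  phb <- one_way_anova(list(a = g1, b = g2, c = g2 + 2),
                       posthoc = "bonferroni")
  expect_true(all(phb$posthoc$p_adjusted <= 1))
})

test_that("wash-in effect uses the 2-min pre and 5-7-min post windows", {
  # constant rate -> 0%
  expect_equal(washin_effect(regular_train(40, 600), 120,
                             duration = 600)$percent_reduction, 0,
               tolerance = 0.5)
  # rate steps to half at onset -> 50%
  stepped <- c(regular_train(40, 120), 120 + regular_train(20, 480))
  expect_equal(washin_effect(stepped, 120, duration = 600)$percent_reduction,
               50, tolerance = 0.5)
  # rate-series input
  series <- data.frame(time_s = seq(0, 600, by = 10),
                       rate_hz = rep(c(50, 25), c(13, 48)))
  expect_equal(washin_effect(series, 120)$percent_reduction, 50)
  # insufficient coverage
  expect_error(washin_effect(regular_train(40, 300), 120, duration = 300),
               class = "zt_undefined_metric")
  expect_error(washin_effect(regular_train(40, 300), 60, duration = 300),
               class = "zt_undefined_metric")
})

test_that("f-I slope is the least-squares slope", {
  expect_equal(fi_slope(c(0.1, 0.2, 0.3), c(10, 30, 50))$slope_spk_per_nA,
               200, tolerance = 1e-9)
  expect_equal(fi_slope(seq(0.1, 1, by = 0.1),
                        100 * seq(0.1, 1, by = 0.1))$slope_spk_per_nA, 100)
  expect_equal(fi_slope(c(0.1, 0.5, 0.9), c(0, 0, 0))$slope_spk_per_nA, 0)
  expect_error(fi_slope(rep(0.5, 4), 1:4), class = "zt_invalid_input")
  expect_error(fi_slope(c(0.1, 0.2), c(1, 2)), class = "zt_invalid_input")
})

test_that("lobule aggregation joins intensities and feeds correlation", {
  metrics <- data.frame(
    lobule = rep(c("I", "III", "VI", "IX", "X"), each = 4),
    ss_rate = rep(c(100, 90, 75, 62, 55), each = 4) + rep(c(-2, -1, 1, 2), 5),
    cf_pause_ms = rep(c(8, 9, 11, 13, 15), each = 4),
    ss_mean_cv2 = 0.5)
  intensity <- data.frame(lobule = c("I", "III", "VI", "IX", "X"),
                          intensity = c(1.0, 0.9, 0.7, 0.5, 0.4))
  agg <- aggregate_by_lobule(metrics, intensity)
  expect_identical(nrow(agg), 5L)
  expect_true(all(agg$n == 4))
  # rates fall as staining strengthens (low intensity = strong staining):
  # monotone by construction, so Spearman rho on aggregates is exactly 1
  expect_equal(correlate(agg$intensity, agg$mean_ss_rate)$value, 1)
  expect_equal(correlate(agg$intensity, agg$mean_cf_pause_ms)$value, -1)
  # unmapped labels are dropped with a warning
  metrics2 <- rbind(metrics,
                    data.frame(lobule = "nonsense", ss_rate = 50,
                               cf_pause_ms = 10, ss_mean_cv2 = 0.5))
  expect_warning(aggregate_by_lobule(metrics2, intensity), "unmapped")
  expect_error(aggregate_by_lobule(metrics[0, ], intensity),
               class = "zt_invalid_input")
})
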