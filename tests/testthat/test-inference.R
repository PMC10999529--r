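test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # all censored: survival stays at 1
  all_cens <- data.frame(event = c(0, 0, 0), time_days = c(10, 20, 30))
  expect_true(all(km_curve(all_cens)$survival == 1))
  # one event at 10, one censored at 20: S(10) = 1/2
  mix <- data.frame(event = c(1, 0), time_days = c(10, 20))
  expect_equal(km_curve(mix)$survival[1], 0.5)
  # two events in n = 2: S reaches 0
  both <- data.frame(event = c(1, 1), time_days = c(10, 20))
  expect_equal(km_curve(both)$survival, c(0.5, 0))
  expect_error(km_curve(data.frame(event = integer(0),
                                   time_days = integer(0))), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      t <- sample(30:90, 12, replace = TRUE)
      rec <- data.frame(event = 1, time_days = t)
      km <- km_curve(rec)
      emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
      expect_equal(km$survival, emp)
      expect_true(all(diff(km$survival) <= 1e-12))
      expect_true(all(km$survival >= 0 & km$survival <= 1))
    }
  })
})

test_that("KM agrees with an independent product-limit oracle under censoring", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      t <- sample(30:90, 15, replace = TRUE)
      e <- rbinom(15, 1, 0.7)
      km <- km_curve(data.frame(event = e, time_days = t))
      orc <- oracle_km(t, e)
      expect_equal(km$survival, orc$survival[match(km$time, orc$time)])
    }
  })
})

test_that("log-rank test behaves at its symmetric and separated extremes", {
  a <- data.frame(event = 1, time_days = c(40, 50, 60, 70))
  res <- logrank_test(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # complete separation at n = 12/group is decisive
  early <- data.frame(event = 1, time_days = seq(36, 58, by = 2))
  late <- data.frame(event = 1, time_days = seq(60, 82, by = 2))
  expect_lt(logrank_test(early, late)$p_value, 0.05)
  none <- data.frame(event = 0, time_days = c(91, 91))
  expect_error(logrank_test(none, none), "no events")
})

test_that("log-rank p agrees with a permutation oracle at small n", {
  a <- data.frame(event = 1, time_days = c(40, 42, 46, 50, 54, 58))
  b <- data.frame(event = 1, time_days = c(48, 56, 64, 72, 80, 88))
  res <- logrank_test(a, b)
  perm <- oracle_logrank_perm(
    c(a$time_days, b$time_days), c(a$event, b$event),
    rep(c("A", "B"), each = 6), n_perm = 4000)
  expect_lt(abs(res$p_value - perm), 0.02)
})

test_that("log-rank trend is zero for identical groups and detects order", {
  g <- data.frame(event = 1, time_days = c(40, 50, 60))
  res <- logrank_trend_test(list(g, g, g))
  expect_equal(res$statistic, 0)
  # ordered shift produces a strong 1-df trend
  g1 <- data.frame(event = 1, time_days = c(40, 44, 48, 52))
  g2 <- data.frame(event = 1, time_days = c(54, 58, 62, 66))
  g3 <- data.frame(event = 1, time_days = c(68, 72, 76, 80))
  trend <- logrank_trend_test(list(g1, g2, g3))
  expect_lt(trend$p_value, 0.01)
  # trend uses the scores: reversing them leaves the 1-df statistic unchanged
  rev_trend <- logrank_trend_test(list(g1, g2, g3), scores = c(3, 2, 1))
  expect_equal(trend$statistic, rev_trend$statistic)
})

test_that("Mann-Whitney exact mode reproduces full enumeration", {
  res <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2 / choose(6, 3)
  withr::with_seed(17, {
    for (rep in 1:8) {
      x <- sample(seq(1, 200, by = 2), sample(3:6, 1))
      y <- sample(seq(2, 200, by = 2), sample(3:6, 1))
      got <- mann_whitney_test(x, y)
      expect_equal(got$p_value, oracle_mw_exact(x, y))
    }
  })
})

test_that("Mann-Whitney identities and tie handling", {
  x <- c(40, 45, 50, 55)
  expect_equal(mann_whitney_test(x, x)$p_value, 1)
  # U_A + U_B = n_A * n_B for any pair of samples
  y <- c(42, 47, 52, 60, 70)
  u_a <- mann_whitney_test(x, y)$statistic
  u_b <- mann_whitney_test(y, x)$statistic
  expect_equal(u_a + u_b, length(x) * length(y))
  # grid-valued onset days: mid-rank normal approximation, p still in [0, 1]
  tied <- mann_whitney_test(c(63, 63, 66, 70), c(70, 70, 73, 77))
  expect_match(tied$method, "tie-corrected")
  expect_gte(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("two-way ANOVA matches closed-form balanced sums of squares", {
  # balanced 2 x 2 with 3 replicates per cell
  value <- c(12, 14, 13, 18, 19, 21, 22, 24, 23, 30, 29, 33)
  geno <- rep(c("WT", "WT", "G93A", "G93A"), each = 3)
  act <- rep(c("sed", "tr", "sed", "tr"), each = 3)
  fit <- anova2_tukey(value, geno, act)
  orc <- oracle_anova_2x2(value, geno, act)
  expect_equal(fit$anova$statistic[fit$anova$term == "genotype"],
               unname(orc["F1"]), tolerance = 1e-8)
  expect_equal(fit$anova$statistic[fit$anova$term == "activity"],
               unname(orc["F2"]), tolerance = 1e-8)
  expect_equal(fit$anova$statistic[fit$anova$term == "genotype:activity"],
               unname(orc["F12"]), tolerance = 1e-8)
  expect_equal(nrow(fit$tukey), 6)  # all pairs of 4 cells
  expect_true(all(fit$tukey$p_adj >= 0 & fit$tukey$p_adj <= 1))
})

test_that("ANOVA F is invariant to affine response transforms and relabeling", {
  withr::with_seed(41, {
    value <- rnorm(24, mean = 20, sd = 3)
    geno <- rep(c("WT", "G93A"), each = 12)
    act <- rep(rep(c("sed", "tr"), each = 6), 2)
    f0 <- anova2_tukey(value, geno, act)$anova
    f1 <- anova2_tukey(2 * value + 7, geno, act)$anova
    expect_equal(f0$statistic, f1$statistic)
    # swapping factor roles swaps the main effects, same F values
    f2 <- anova2_tukey(value, act, geno)$anova
    expect_setequal(round(f0$statistic[1:2], 10), round(f2$statistic[1:2], 10))
    expect_equal(f0$statistic[3], f2$statistic[3])
  })
  # all observations equal: zero effect sums of squares
  const <- anova2_tukey(rep(5, 12), rep(c("a", "b"), each = 6),
                        rep(c("x", "y"), 6))
  expect_equal(const$anova$sum_sq, rep(0, 3))
  expect_error(anova2_tukey(1:4, c("a", "a", "a", "a"), c("x", "x", "y", "y")),
               "2 levels")
  expect_error(anova2_tukey(1:4, c("a", "a", "b", "b"), c("x", "x", "y", "y")),
               "cell")
})

test_that("Shapiro-Wilk wrapper enforces its domain and detects bimodality", {
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
  expect_error(shapiro_normality(rep(3, 10)), "identical")
  withr::with_seed(61, {
    hits <- 0
    for (rep in 1:20) {
      bimodal <- c(rnorm(24, -3, 0.5), rnorm(24, 3, 0.5))
      if (shapiro_normality(bimodal)$p_value < 0.05) hits <- hits + 1
    }
    expect_gte(hits, 18)  # rejected in the vast majority of draws
    # normal data: W near 1, rejection uncommon
    norm_p <- vapply(1:20, function(i) shapiro_normality(rnorm(50))$p_value,
                     numeric(1))
    expect_lte(mean(norm_p < 0.05), 0.2)
  })
})

test_that("group_summary computes mean and sd/sqrt(n)", {
  s <- group_summary(c(4, 6), c("a", "a"))
  expect_equal(s$mean, 5)
  expect_equal(s$sem, 1)
  s2 <- group_summary(c(1, 5, 5, 5), c("solo", "g", "g", "g"))
  expect_equal(s2$sem[s2$group == "solo"], 0)  # single value: SEM 0
  expect_equal(s2$sem[s2$group == "g"], 0)     # constant group: SEM 0
  expect_error(group_summary(numeric(0), character(0)), "empty")
})
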