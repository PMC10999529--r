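test_that("normalize_grip is mean of three attempts over weight", {
  expect_equal(normalize_grip(c(2, 2, 2), 20), 0.1)
  expect_equal(normalize_grip(c(0, 0, 0), 25), 0)
  expect_equal(normalize_grip(c(1, 2, 3), 2), 1)
  expect_error(normalize_grip(c(1, 2), 20), "3 grip attempts")
  expect_error(normalize_grip(c(1, 2, 3), 0), "positive")
})

test_that("indicators use strict 20% thresholds", {
  expect_equal(weight_indicator(16.0, 20.0), 0)   # exactly 80%: no deficit
  expect_equal(weight_indicator(15.9, 20.0), 1)
  expect_equal(weight_indicator(20.0, 20.0), 0)
  expect_error(weight_indicator(10, 0), "positive")

  expect_equal(grip_indicator(0.08, 0.10), 0)     # boundary
  expect_equal(grip_indicator(0.079, 0.10), 1)
  expect_equal(grip_indicator(0.12, 0.10), 0)     # improvement
  expect_error(grip_indicator(0.1, -1), "positive")

  expect_equal(motor_indicator(5), 0)
  expect_equal(motor_indicator(4.75), 1)
  expect_equal(motor_indicator(3), 1)
  expect_error(motor_indicator(4.6), "rubric")
})

test_that("composite totals are the weighted sum, over all 16 combinations", {
  expect_equal(composite_score(0, 0, 0, 0), 0)
  expect_equal(composite_score(1, 1, 0, 0), 6)
  expect_equal(composite_score(1, 0, 1, 1), 6)
  grid <- expand.grid(w = 0:1, g = 0:1, r = 0:1, ga = 0:1)
  totals <- composite_score(grid$w, grid$g, grid$r, grid$ga)
  expect_equal(totals, 3 * grid$w + 3 * grid$g + 1.5 * grid$r + 1.5 * grid$ga)
  expect_true(all(totals %in% c(0, 1.5, 3, 4.5, 6, 7.5, 9)))
  # monotone: switching any flag on never lowers the total
  for (j in 1:4) {
    on <- grid; on[[j]] <- 1
    expect_true(all(composite_score(on$w, on$g, on$r, on$ga) >= totals))
  }
  expect_error(composite_score(2, 0, 0, 0), "0 or 1")
})

test_that("exactly six indicator combinations reach the onset threshold", {
  reach <- onset_reaching_combinations(6)
  expect_equal(nrow(reach), 6)
  key <- apply(reach[, 1:4], 1, paste, collapse = "")
  expected <- c("1100", "1110", "1101", "1111", "1011", "0111")
  expect_setequal(key, expected)
  # every qualifying combination has both quantitative flags or three flags
  expect_true(all(reach$i_weight + reach$i_grip == 2 |
                    rowSums(reach[, 1:4]) >= 3))
  expect_equal(nrow(onset_reaching_combinations(9)), 1)
  expect_equal(nrow(onset_reaching_combinations(0.5)), 15)
})

test_that("detect_onset matches a brute-force scan on random series", {
  days <- default_schedule()
  totals_pool <- c(0, 1.5, 3, 4.5, 6, 7.5, 9)
  withr::with_seed(99, {
    for (rep in 1:50) {
      totals <- sample(totals_pool, length(days), replace = TRUE)
      k <- sample(1:3, 1)
      got <- detect_onset(days, totals, threshold = 6, persistence = k)
      idx <- oracle_first_run(totals >= 6, k)
      if (is.na(idx)) {
        expect_false(got$event)
        expect_equal(got$time, days[length(days)])
      } else {
        expect_true(got$event)
        expect_equal(got$time, days[idx])
      }
    }
  })
})

test_that("detect_onset handles the documented edge cases", {
  expect_equal(detect_onset(c(35, 38, 42), c(0, 0, 0)),
               list(event = FALSE, time = 42))
  expect_equal(detect_onset(c(35, 38, 42), c(3, 6, 9)),
               list(event = TRUE, time = 38))
  expect_equal(detect_onset(c(35, 38, 42), c(6, 3, 6), persistence = 2),
               list(event = FALSE, time = 42))
  expect_equal(detect_onset(c(35, 38, 42, 45), c(3, 6, 6, 3), persistence = 2),
               list(event = TRUE, time = 38))
  expect_error(detect_onset(numeric(0), numeric(0)), "empty")
  expect_error(detect_onset(c(35, 38), c(6, 6), threshold = 10), "\\(0, 9]")
})

test_that("lowering the threshold never delays onset", {
  days <- default_schedule()
  totals_pool <- c(0, 1.5, 3, 4.5, 6, 7.5, 9)
  withr::with_seed(123, {
    for (rep in 1:25) {
      totals <- sample(totals_pool, length(days), replace = TRUE)
      hi <- detect_onset(days, totals, threshold = 7.5)
      lo <- detect_onset(days, totals, threshold = 4.5)
      if (hi$event) {
        expect_true(lo$event)
        expect_lte(lo$time, hi$time)
      }
    }
  })
})

test_that("zero-noise default WT mice never fire an indicator", {
  co <- simulate_cohort(study_design(n_per_group = 4),
                        zero_noise(default_params()), seed = 21)
  scores <- score_cohort(co$longitudinal)
  wt <- scores[scores$genotype == "WT", ]
  expect_true(all(wt[, c("i_weight", "i_grip", "i_reflex", "i_gait")] == 0))
  onsets <- cohort_onsets(scores)
  wt_on <- onsets[onsets$genotype == "WT", ]
  expect_true(all(wt_on$event == 0))
  expect_true(all(wt_on$time_days == 91))
})

test_that("zero-noise trained G93A onset precedes sedentary for every mouse", {
  co <- simulate_cohort(study_design(n_per_group = 4),
                        zero_noise(default_params()), seed = 22)
  onsets <- cohort_onsets(score_cohort(co$longitudinal))
  tr <- onsets[onsets$genotype == "G93A" & onsets$activity == "trained", ]
  sd_ <- onsets[onsets$genotype == "G93A" & onsets$activity == "sedentary", ]
  expect_true(all(tr$event == 1))
  expect_true(all(sd_$event == 1))
  expect_true(all(max(tr$time_days) < min(sd_$time_days)))
})

test_that("reference policies change the grip baseline as documented", {
  co <- simulate_cohort(study_design(n_per_group = 4), seed = 31)
  long <- co$longitudinal
  s_run <- score_cohort(long, reference_policy(grip_ref = "running_max"))
  s_base <- score_cohort(long, reference_policy(grip_ref = "baseline"))
  s_wt <- score_cohort(long, reference_policy(grip_ref = "wt_mean"))
  # running max >= day-one baseline, so it can only fire earlier or equally
  m <- s_run$mouse_id[1]
  g <- s_run$norm_grip[s_run$mouse_id == m]
  expect_equal(g, s_base$norm_grip[s_base$mouse_id == m])
  first_fire <- function(s) {
    f <- s$day[s$mouse_id == m & s$i_grip == 1]
    if (length(f)) min(f) else Inf
  }
  expect_lte(first_fire(s_run), first_fire(s_base))
  expect_false(identical(s_run$i_grip, s_wt$i_grip))
})

test_that("latched indicators stay on once fired", {
  co <- simulate_cohort(study_design(n_per_group = 4), seed = 33)
  s <- score_cohort(co$longitudinal, reference_policy(latch = TRUE))
  for (m in unique(s$mouse_id)) {
    sub <- s[s$mouse_id == m, ]
    sub <- sub[order(sub$day), ]
    for (col in c("i_weight", "i_grip", "i_reflex", "i_gait")) {
      expect_true(all(diff(sub[[col]]) >= 0))
    }
  }
})

test_that("pooled-WT weight reference uses all wild-type mice", {
  co <- simulate_cohort(study_design(n_per_group = 6), seed = 35)
  long <- co$longitudinal
  s <- score_cohort(long, reference_policy(weight_ref = "pooled_wt"))
  wt <- long[long$genotype == "WT", ]
  ref <- tapply(wt$weight_g, wt$day, mean)
  d <- long$day[1]
  row1 <- long[1, ]
  expect_equal(s$i_weight[s$mouse_id == row1$mouse_id & s$day == d],
               weight_indicator(row1$weight_g, unname(ref[as.character(d)])))
})
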