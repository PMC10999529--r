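#' Weight-normalized grip strength
#'
#' The mean of the three grip attempts divided by the animal's body weight
#' measured the same day.
#'
#' @param attempts Numeric vector of exactly three grip-force values.
#' @param weight Body weight in g, strictly positive.
#' @return Normalized grip (force per g).
#' @export
#' @examples
#' normalize_grip(c(2, 2, 2), 20)
normalize_grip <- function(attempts, weight) {
  if (length(attempts) != 3) {
    stop("exactly 3 grip attempts are required", call. = FALSE)
  }
  if (length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    stop("`weight` must be a single positive value", call. = FALSE)
  }
  mean(attempts) / weight
}

#' Impairment indicators
#'
#' Binary flags feeding the composite score.  A mouse is flagged:
#' * `weight_indicator()` — when its weight is more than 20% below the
#'   reference (wild-type mean) weight: `w < 0.8 * ref`, strict.
#' * `grip_indicator()` — when its normalized grip is more than 20% below
#'   its baseline: `g < 0.8 * baseline`, strict.
#' * `motor_indicator()` — when a rubric score has reached 4.75 or worse.
#'
#' @param w,ref Weight and reference weight (g), `ref > 0`.
#' @param g,baseline Normalized grip and its reference, `baseline > 0`.
#' @param score A rubric level (see [rubric_levels()]).
#' @return 0 or 1 (vectorized over the first argument).
#' @name indicators
#' @export
#' @examples
#' weight_indicator(15.9, 20)   # 1: below 80% of reference
#' weight_indicator(16.0, 20)   # 0: exactly 80% is not a deficit
#' motor_indicator(4.75)        # 1
weight_indicator <- function(w, ref) {
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("`ref` must be positive", call. = FALSE)
  }
  # tiny relative slack so exactly-80% never fires through rounding
  as.integer(w < 0.8 * ref * (1 - 1e-9))
}

#' @rdname indicators
#' @export
grip_indicator <- function(g, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("`baseline` must be positive", call. = FALSE)
  }
  as.integer(g < 0.8 * baseline * (1 - 1e-9))
}

#' @rdname indicators
#' @export
motor_indicator <- function(score) {
  if (any(!is_rubric_level(score))) {
    stop("`score` must be a rubric level", call. = FALSE)
  }
  as.integer(score <= 4.75)
}

#' Weighted composite impairment score
#'
#' The quantitative indicators (weight, grip strength) carry weight 3 and
#' the observer-scored motor indicators (extension reflex, gait) weight
#' 1.5, giving a total between 0 (no impairment) and 9 (impaired in every
#' category).  Disease onset is declared at a total of 6, which requires at
#' least one quantitative deficit or all but one category.
#'
#' @param i_weight,i_grip,i_reflex,i_gait Binary indicator flags
#'   (vectorized).
#' @return Numeric vector of totals in `{0, 1.5, 3, 4.5, 6, 7.5, 9}`.
#' @export
#' @examples
#' composite_score(1, 1, 0, 0)  # 6: onset from the two quantitative tests
#' composite_score(1, 0, 1, 1)  # 6
composite_score <- function(i_weight, i_grip, i_reflex, i_gait) {
  flags <- cbind(i_weight, i_grip, i_reflex, i_gait)
  if (any(!flags %in% c(0, 1))) {
    stop("indicator flags must be 0 or 1", call. = FALSE)
  }
  3 * i_weight + 3 * i_grip + 1.5 * i_reflex + 1.5 * i_gait
}

#' Indicator combinations that reach the onset threshold
#'
#' Enumerates all 16 combinations of the four impairment indicators and
#' returns those whose composite total reaches `threshold`.  Diagnostic for
#' understanding which deficit patterns can trigger onset.
#'
#' @param threshold Onset threshold on the composite total (default 6).
#' @return data.frame with the four flag columns and `total`, one row per
#'   qualifying combination.
#' @export
#' @examples
#' onset_reaching_combinations()        # 6 combinations at threshold 6
onset_reaching_combinations <- function(threshold = 6) {
  grid <- expand.grid(i_weight = 0:1, i_grip = 0:1,
                      i_reflex = 0:1, i_gait = 0:1)
  grid$total <- composite_score(grid$i_weight, grid$i_grip,
                                grid$i_reflex, grid$i_gait)
  out <- grid[grid$total >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference policy for the weight and grip criteria
#'
#' The onset criteria compare each animal against a reference.  The weight
#' reference is the contemporaneous wild-type mean weight: by default the
#' sedentary wild-type group mean at the same measurement day
#' (`"sedentary_wt"`), optionally all wild-type mice pooled (`"pooled_wt"`).
#' The grip baseline (the 100% level a 20% reduction is measured against)
#' is, by default, the running maximum of the animal's own normalized grip
#' up to the current day (`"running_max"`); alternatives are the animal's
#' own day-one value (`"baseline"`) or the contemporaneous wild-type mean
#' normalized grip (`"wt_mean"`).
#'
#' @param weight_ref "sedentary_wt" or "pooled_wt".
#' @param grip_ref "running_max", "baseline" or "wt_mean".
#' @param latch If `TRUE`, an indicator stays on from the first day it
#'   fires (off by default: indicators are re-evaluated each day).
#' @return An object of class `reference_policy`.
#' @export
reference_policy <- function(weight_ref = c("sedentary_wt", "pooled_wt"),
                             grip_ref = c("running_max", "baseline", "wt_mean"),
                             latch = FALSE) {
  structure(
    list(
      weight_ref = match.arg(weight_ref),
      grip_ref = match.arg(grip_ref),
      latch = isTRUE(latch)
    ),
    class = "reference_policy"
  )
}

#' Score a longitudinal cohort
#'
#' Computes, for every mouse x day, the four impairment indicators and the
#' weighted composite total, under a fixed [reference_policy()].
#'
#' @param longitudinal A longitudinal table with columns `mouse_id`,
#'   `genotype`, `activity`, `day`, `weight_g`, `grip1`..`grip3`,
#'   `reflex_score`, `gait_score` (the schema written by
#'   [simulate_cohort()] / [write_longitudinal()]).
#' @param policy A [reference_policy()].
#' @return data.frame with columns `mouse_id`, `genotype`, `activity`,
#'   `day`, `norm_grip`, `i_weight`, `i_grip`, `i_reflex`, `i_gait`,
#'   `total`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' scores <- score_cohort(cohort$longitudinal)
#' head(scores)
score_cohort <- function(longitudinal, policy = reference_policy()) {
  validate_longitudinal(longitudinal)
  if (!inherits(policy, "reference_policy")) {
    stop("`policy` must be a reference_policy", call. = FALSE)
  }
  df <- longitudinal[order(longitudinal$mouse_id, longitudinal$day), ]

  df$norm_grip <- rowMeans(df[, c("grip1", "grip2", "grip3")]) / df$weight_g

  # per-day wild-type reference weight (and grip, if requested)
  wt_rows <- if (policy$weight_ref == "sedentary_wt") {
    df$genotype == "WT" & df$activity == "sedentary"
  } else {
    df$genotype == "WT"
  }
  if (!any(wt_rows)) {
    stop("no wild-type reference mice found for weight criterion",
         call. = FALSE)
  }
  ref_w <- tapply(df$weight_g[wt_rows], df$day[wt_rows], mean)
  day_key <- as.character(df$day)
  if (any(!day_key %in% names(ref_w))) {
    stop("missing wild-type reference weight for some measurement days",
         call. = FALSE)
  }
  df$i_weight <- weight_indicator(df$weight_g, unname(ref_w[day_key]))

  grip_base <- switch(policy$grip_ref,
    running_max = stats::ave(df$norm_grip, df$mouse_id, FUN = cummax),
    baseline = stats::ave(df$norm_grip, df$mouse_id, FUN = function(x) x[1]),
    wt_mean = {
      ref_g <- tapply(df$norm_grip[wt_rows], df$day[wt_rows], mean)
      unname(ref_g[day_key])
    }
  )
  df$i_grip <- grip_indicator(df$norm_grip, grip_base)

  df$i_reflex <- motor_indicator(df$reflex_score)
  df$i_gait <- motor_indicator(df$gait_score)

  if (policy$latch) {
    for (col in c("i_weight", "i_grip", "i_reflex", "i_gait")) {
      df[[col]] <- as.integer(stats::ave(df[[col]], df$mouse_id, FUN = cummax))
    }
  }
  df$total <- composite_score(df$i_weight, df$i_grip, df$i_reflex, df$i_gait)
  out <- df[, c("mouse_id", "genotype", "activity", "day", "norm_grip",
                "i_weight", "i_grip", "i_reflex", "i_gait", "total")]
  rownames(out) <- NULL
  out
}

#' Detect disease onset from a composite-score series
#'
#' Onset is the first measurement day from which the composite total is at
#' least `threshold` for `persistence` consecutive measurements.  A mouse
#' whose series never qualifies is right-censored at its last observed day.
#'
#' @param day Measurement days, sorted increasing.
#' @param total Composite totals at those days.
#' @param threshold Onset threshold in `(0, 9]` (default 6).
#' @param persistence Number of consecutive qualifying measurements
#'   required (default 1: the first qualifying day).
#' @return A list with `event` (logical) and `time` (onset day, or the last
#'   observed day if censored).
#' @export
#' @examples
#' detect_onset(c(35, 38, 42), c(3, 6, 9))           # event at 38
#' detect_onset(c(35, 38, 42), c(6, 3, 6), persistence = 2)  # censored
detect_onset <- function(day, total, threshold = 6, persistence = 1) {
  if (length(day) == 0) stop("empty score series", call. = FALSE)
  if (length(day) != length(total)) {
    stop("`day` and `total` must have equal length", call. = FALSE)
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop("`day` must be strictly increasing", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 9) {
    stop("`threshold` must lie in (0, 9]", call. = FALSE)
  }
  persistence <- as.integer(persistence)
  if (persistence < 1) stop("`persistence` must be >= 1", call. = FALSE)

  qual <- total >= threshold
  n <- length(qual)
  if (persistence <= n) {
    for (i in seq_len(n - persistence + 1L)) {
      if (all(qual[i:(i + persistence - 1L)])) {
        return(list(event = TRUE, time = day[i]))
      }
    }
  }
  list(event = FALSE, time = day[n])
}

#' Per-mouse onset records for a scored cohort
#'
#' Applies [detect_onset()] to every mouse in a [score_cohort()] table.
#'
#' @param scores Output of [score_cohort()].
#' @param threshold,persistence Passed to [detect_onset()].
#' @return data.frame with columns `mouse_id`, `genotype`, `activity`,
#'   `event` (0/1) and `time_days`.
#' @export
cohort_onsets <- function(scores, threshold = 6, persistence = 1) {
  required <- c("mouse_id", "genotype", "activity", "day", "total")
  missing <- setdiff(required, names(scores))
  if (length(missing)) {
    stop("score table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  scores <- scores[order(scores$mouse_id, scores$day), ]
  ids <- unique(scores$mouse_id)
  rows <- lapply(ids, function(id) {
    s <- scores[scores$mouse_id == id, ]
    rec <- detect_onset(s$day, s$total, threshold, persistence)
    data.frame(mouse_id = id, genotype = s$genotype[1],
               activity = s$activity[1], event = as.integer(rec$event),
               time_days = rec$time, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landmark detectors on mean curves
#'
#' `weight_plateau_day()` finds the age at which a mean weight curve stops
#' rising: the first scheduled day whose value is never exceeded (beyond
#' `tol`) by any later scheduled value.  `decline_onset_day()` finds the
#' first scheduled day at which a mean motor-score curve has dropped below
#' the normal level of 5, or `NA` if it never does.
#'
#' @param day Scheduled days, sorted increasing.
#' @param value Curve values at those days.
#' @param tol Tolerance (g) for "no later value exceeds" (default 0).
#' @return A day, or `NA` for `decline_onset_day()` when no decline occurs.
#' @name landmarks
#' @export
#' @examples
#' d <- default_schedule()
#' weight_plateau_day(d, mean_weight_curve(default_params(), "G93A", "trained", d))
weight_plateau_day <- function(day, value, tol = 0) {
  if (length(day) == 0) stop("empty curve", call. = FALSE)
  if (length(day) != length(value)) {
    stop("`day` and `value` must have equal length", call. = FALSE)
  }
  later_max <- rev(cummax(rev(value)))
  day[which(later_max <= value + tol)[1L]]
}

#' @rdname landmarks
#' @export
decline_onset_day <- function(day, value) {
  if (length(day) == 0) stop("empty curve", call. = FALSE)
  if (length(day) != length(value)) {
    stop("`day` and `value` must have equal length", call. = FALSE)
  }
  i <- which(value < 5)
  if (length(i) == 0) return(NA_integer_)
  day[i[1L]]
}
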