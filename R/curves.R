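#' Noise-free mean body-weight curve
#'
#' Piecewise-linear growth: weight rises from its 35-day starting mean at
#' `weight_growth_rate` g/day and becomes constant from the group's plateau
#' day on (transgenic groups only; wild-type mice keep gaining weight).
#'
#' @param params A `trajectory_params` table.
#' @param genotype,activity Group selectors.
#' @param day Numeric vector of ages (days).
#' @return Mean weight (g) at each `day`.
#' @export
#' @examples
#' mean_weight_curve(default_params(), "G93A", "trained", c(35, 70, 84))
mean_weight_curve <- function(params, genotype, activity, day) {
  p <- param_row(params, genotype, activity)
  start_day <- 35
  eff <- if (is.na(p$weight_plateau_day)) day else pmin(day, p$weight_plateau_day)
  p$weight_start_mean + p$weight_growth_rate * (eff - start_day)
}

#' Latent motor-score curve
#'
#' The continuous impairment score underlying the ordinal rubric.  The
#' score holds at 5 (normal) until the group's decline-start day; from that
#' day the animal is impaired, losing `motor_decline_rate` score units per
#' day, with the decline anchored so the score is already below 5 on the
#' decline-start day itself (the first impaired observation falls on the
#' landmark age).  The score floors at 0.5, the humane-endpoint level.
#'
#' @param params A `trajectory_params` table.
#' @param genotype,activity Group selectors.
#' @param day Numeric vector of ages (days).
#' @param test Which rubric: "reflex" (hind-limb extension reflex) or "gait".
#' @return Latent score in `[0.5, 5]` at each `day`.
#' @export
#' @examples
#' latent_motor_curve(default_params(), "G93A", "trained", c(49, 52, 91), "reflex")
latent_motor_curve <- function(params, genotype, activity, day,
                               test = c("reflex", "gait")) {
  test <- match.arg(test)
  p <- param_row(params, genotype, activity)
  start <- if (test == "reflex") p$reflex_decline_start else p$gait_decline_start
  if (is.na(start)) return(rep(5, length(day)))
  val <- ifelse(day < start, 5,
                5 - p$motor_decline_rate * (day - start + 1))
  pmin(5, pmax(0.5, val))
}
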