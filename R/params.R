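#' Calibrated default trajectory parameters
#'
#' Group-level generative parameters for the synthetic cohort.  The
#' landmark ages are fixed by the study the simulator emulates: transgenic
#' mice stop gaining weight at 70 (trained) and 77 (sedentary) days of age;
#' the hind-limb extension-reflex score starts decreasing at 52 (trained)
#' and 66 (sedentary) days; the gait score at 59 (trained) and 70
#' (sedentary) days; wild-type mice show no decline.  Endpoint ventral-horn
#' motor-neuron percentages are centred at 100/100/80/50 (SD WT / TR WT /
#' SD G93A / TR G93A) relative to the sedentary wild-type mean.  Grip
#' slopes, the motor decline rate and the noise scales are calibrated so
#' that composite-score onset lands at 63 days (trained G93A) and 70 days
#' (sedentary G93A) on the default twice-weekly grid in the absence of
#' noise.
#'
#' @return An object of class `trajectory_params`: a data.frame with one
#'   row per group.  Columns:
#'   \describe{
#'     \item{weight_start_mean, weight_start_sd}{Body weight at 35 days (g).}
#'     \item{weight_growth_rate}{Weight gain (g/day) before the plateau.}
#'     \item{weight_plateau_day}{Age (days) at which weight gain stops;
#'       `NA` for no plateau.}
#'     \item{weight_noise_sd}{Per-measurement weighing error SD (g).}
#'     \item{grip_start_mean, grip_start_sd}{Normalized grip strength
#'       (force per g body weight, arbitrary consistent units) at 35 days.}
#'     \item{grip_slope}{Change in normalized grip per day.}
#'     \item{grip_noise_sd}{Per-attempt grip-force error SD (force units).}
#'     \item{reflex_decline_start, gait_decline_start}{Age (days) at which
#'       the latent rubric score starts to fall; `NA` for never.}
#'     \item{motor_decline_rate}{Latent score units lost per day.}
#'     \item{observer_flip_prob}{Probability that a recorded rubric score is
#'       off by one level (split evenly up/down, clamped to the scale).}
#'     \item{mn_pct_mean, mn_pct_sd}{Endpoint motor-neuron percentage vs the
#'       sedentary wild-type mean.}
#'   }
#' @export
#' @examples
#' default_params()
default_params <- function() {
  g <- design_groups()
  p <- data.frame(
    genotype = g$genotype,
    activity = g$activity,
    label = g$label,
    weight_start_mean = 18,
    weight_start_sd = 1,
    weight_growth_rate = 0.10,
    weight_plateau_day = c(NA, NA, 77, 70),
    weight_noise_sd = 0.5,
    grip_start_mean = 1.0,
    grip_start_sd = 0.08,
    grip_slope = c(0, 0.003, -0.006, -0.0075),
    grip_noise_sd = 0.4,
    reflex_decline_start = c(NA, NA, 66, 52),
    gait_decline_start = c(NA, NA, 70, 59),
    motor_decline_rate = 0.15,
    observer_flip_prob = 0.08,
    mn_pct_mean = c(100, 100, 80, 50),
    mn_pct_sd = 8,
    stringsAsFactors = FALSE
  )
  new_trajectory_params(p)
}

new_trajectory_params <- function(df) {
  required <- c("genotype", "activity", "weight_start_mean", "weight_start_sd",
                "weight_growth_rate", "weight_plateau_day", "weight_noise_sd",
                "grip_start_mean", "grip_start_sd", "grip_slope",
                "grip_noise_sd", "reflex_decline_start", "gait_decline_start",
                "motor_decline_rate", "observer_flip_prob",
                "mn_pct_mean", "mn_pct_sd")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trajectory params missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- group_label(df$genotype, df$activity)
  sds <- c("weight_start_sd", "weight_noise_sd", "grip_start_sd",
           "grip_noise_sd", "mn_pct_sd")
  for (s in sds) {
    if (any(df[[s]] < 0)) stop("`", s, "` must be >= 0", call. = FALSE)
  }
  if (any(df$motor_decline_rate <= 0)) {
    stop("`motor_decline_rate` must be > 0", call. = FALSE)
  }
  if (any(df$observer_flip_prob < 0 | df$observer_flip_prob > 0.5)) {
    stop("`observer_flip_prob` must lie in [0, 0.5]", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("trajectory_params", "data.frame"))
}

#' Look up the parameter row for one group
#'
#' @param params A [default_params()]-style `trajectory_params` table.
#' @param genotype "WT" or "G93A".
#' @param activity "sedentary" or "trained".
#' @return A one-row data.frame.
#' @export
param_row <- function(params, genotype, activity) {
  i <- which(params$genotype == genotype & params$activity == activity)
  if (length(i) != 1) {
    stop("unknown group: ", genotype, " / ", activity, call. = FALSE)
  }
  params[i, , drop = FALSE]
}

#' Strip all stochastic components from trajectory parameters
#'
#' Sets every noise and between-animal variability parameter (start SDs,
#' measurement noise SDs, observer flip probability, endpoint SD) to zero,
#' so that simulated values equal the analytic mean curves exactly.
#'
#' @param params A `trajectory_params` table.
#' @return The table with all stochastic parameters zeroed.
#' @export
zero_noise <- function(params) {
  for (s in c("weight_start_sd", "weight_noise_sd", "grip_start_sd",
              "grip_noise_sd", "observer_flip_prob", "mn_pct_sd")) {
    params[[s]] <- 0
  }
  params
}
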