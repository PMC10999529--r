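#' Default twice-weekly measurement schedule
#'
#' Ages (days) at which phenotypes are measured: from training start at 35
#' days of age to the experimental endpoint at 91 days, alternating +3/+4 day
#' intervals so every measurement falls twice a week on the same weekdays.
#'
#' @return Integer vector of measurement ages in days.
#' @export
default_schedule <- function() {
  as.integer(c(35, 38, 42, 45, 49, 52, 56, 59, 63, 66, 70, 73, 77, 80, 84, 87, 91))
}

#' Group table of the four-arm design
#'
#' @return data.frame with columns `genotype` ("WT"/"G93A"), `activity`
#'   ("sedentary"/"trained") and the conventional short `label`
#'   ("SD WT", "TR WT", "SD G93A", "TR G93A").
#' @export
design_groups <- function() {
  g <- data.frame(
    genotype = c("WT", "WT", "G93A", "G93A"),
    activity = c("sedentary", "trained", "sedentary", "trained"),
    stringsAsFactors = FALSE
  )
  g$label <- group_label(g$genotype, g$activity)
  g
}

#' Short group label
#'
#' @param genotype "WT" or "G93A".
#' @param activity "sedentary" or "trained".
#' @return Character vector such as "SD G93A".
#' @export
group_label <- function(genotype, activity) {
  paste(ifelse(activity == "trained", "TR", "SD"), genotype)
}

#' Construct a study design
#'
#' Describes the four-group (genotype x activity) cohort layout, the group
#' size and the measurement schedule.  Defaults reproduce the study design
#' the simulator is calibrated to: n = 12 mice per group measured twice a
#' week from 35 to 91 days of age.
#'
#' @param n_per_group Mice per group (default 12).
#' @param measurement_days Strictly increasing integer ages in days; the
#'   first day is the training start.  Default [default_schedule()].
#' @param endpoint_day Terminal age in days; must be at least the last
#'   measurement day (default 91).
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design()
study_design <- function(n_per_group = 12,
                         measurement_days = default_schedule(),
                         endpoint_day = 91) {
  if (length(n_per_group) != 1 || n_per_group < 1) {
    stop("`n_per_group` must be a single count >= 1", call. = FALSE)
  }
  measurement_days <- as.integer(measurement_days)
  if (length(measurement_days) < 1 || any(diff(measurement_days) <= 0)) {
    stop("`measurement_days` must be strictly increasing", call. = FALSE)
  }
  if (endpoint_day < max(measurement_days)) {
    stop("`endpoint_day` must be >= the last measurement day", call. = FALSE)
  }
  structure(
    list(
      groups = design_groups(),
      n_per_group = as.integer(n_per_group),
      measurement_days = measurement_days,
      endpoint_day = as.integer(endpoint_day)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: 4 groups (WT/G93A x sedentary/trained), n =",
      x$n_per_group, "per group\n")
  cat("Measurement days:", paste(x$measurement_days, collapse = ", "), "\n")
  cat("Endpoint day:", x$endpoint_day, "\n")
  invisible(x)
}
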