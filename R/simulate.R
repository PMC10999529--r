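#' Simulate a synthetic four-group cohort
#'
#' Generates one seeded cohort of longitudinal phenotype measurements plus a
#' per-animal endpoint table.  Each mouse follows its group's noise-free
#' trajectory ([mean_weight_curve()], [latent_motor_curve()]) with:
#' Gaussian between-animal variation in the 35-day weight and normalized
#' grip; Gaussian per-measurement weighing error; three grip attempts drawn
#' around the latent normalized grip times the measured weight, with
#' Gaussian per-attempt force error; rubric scores obtained by snapping the
#' latent motor score to the observer scale ([discretize_score()]) and then,
#' with probability `observer_flip_prob`, shifting the recorded level one
#' rubric step up or down (clamped to the scale); and an endpoint
#' motor-neuron percentage drawn from a Gaussian truncated at zero.
#'
#' With the same seed the output is identical; with all stochastic
#' parameters zeroed (see [zero_noise()]) every value equals its analytic
#' mean curve.
#'
#' @param design A [study_design()].
#' @param params A `trajectory_params` table (default [default_params()]).
#' @param protocol A [training_protocol()] (recorded in the attributes; the
#'   simulator does not model a physiological dose-response).
#' @param seed Integer RNG seed; required.
#' @return A list with class `cohort`:
#'   \describe{
#'     \item{longitudinal}{data.frame with one row per mouse x measurement
#'       day: `mouse_id`, `genotype`, `activity`, `day`, `weight_g`,
#'       `grip1`, `grip2`, `grip3`, `reflex_score`, `gait_score`.}
#'     \item{endpoint}{data.frame with one row per mouse: `mouse_id`,
#'       `genotype`, `activity`, `mn_pct`.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(study_design(), seed = 1)
#' nrow(cohort$longitudinal)  # 4 x 12 x 17 = 816
simulate_cohort <- function(design = study_design(),
                            params = default_params(),
                            protocol = training_protocol(),
                            seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for reproducible simulation", call. = FALSE)
  }
  if (!inherits(design, "study_design")) {
    stop("`design` must be a study_design", call. = FALSE)
  }
  params <- new_trajectory_params(as.data.frame(params))
  check_params_window(params, design)

  days <- design$measurement_days
  n <- design$n_per_group
  lv <- rubric_levels()  # decreasing

  withr::with_seed(as.integer(seed), {
    long <- list()
    endp <- list()
    for (gi in seq_len(nrow(design$groups))) {
      geno <- design$groups$genotype[gi]
      act <- design$groups$activity[gi]
      p <- param_row(params, geno, act)
      ids <- sprintf("%s-%s-%02d",
                     ifelse(act == "trained", "TR", "SD"), geno, seq_len(n))

      w_mean <- mean_weight_curve(params, geno, act, days)
      g_mean_latent <- p$grip_slope * (days - days[1])
      reflex_latent <- latent_motor_curve(params, geno, act, days, "reflex")
      gait_latent <- latent_motor_curve(params, geno, act, days, "gait")
      reflex_base <- discretize_score(reflex_latent)
      gait_base <- discretize_score(gait_latent)

      w0 <- stats::rnorm(n, 0, p$weight_start_sd)
      g0 <- p$grip_start_mean + stats::rnorm(n, 0, p$grip_start_sd)

      nd <- length(days)
      for (mi in seq_len(n)) {
        weight <- w_mean + w0[mi] + stats::rnorm(nd, 0, p$weight_noise_sd)
        weight <- pmax(weight, 1)  # weights are strictly positive
        grip_latent <- pmax(g0[mi] + g_mean_latent, 0.01)
        grip <- matrix(stats::rnorm(3 * nd, 0, p$grip_noise_sd), nrow = nd)
        grip <- pmax(grip + grip_latent * weight, 0)
        reflex <- observer_flip(reflex_base, p$observer_flip_prob, lv)
        gait <- observer_flip(gait_base, p$observer_flip_prob, lv)
        long[[length(long) + 1L]] <- data.frame(
          mouse_id = ids[mi], genotype = geno, activity = act, day = days,
          weight_g = weight, grip1 = grip[, 1], grip2 = grip[, 2],
          grip3 = grip[, 3], reflex_score = reflex, gait_score = gait,
          stringsAsFactors = FALSE
        )
      }
      mn <- rnorm_truncated_pos(n, p$mn_pct_mean, p$mn_pct_sd)
      endp[[length(endp) + 1L]] <- data.frame(
        mouse_id = ids, genotype = geno, activity = act, mn_pct = mn,
        stringsAsFactors = FALSE
      )
    }
    out <- list(
      longitudinal = do.call(rbind, long),
      endpoint = do.call(rbind, endp)
    )
    rownames(out$longitudinal) <- NULL
    rownames(out$endpoint) <- NULL
    attr(out, "seed") <- as.integer(seed)
    attr(out, "protocol") <- protocol
    class(out) <- "cohort"
    out
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort (seed", attr(x, "seed"), "):",
      length(unique(x$longitudinal$mouse_id)), "mice,",
      nrow(x$longitudinal), "longitudinal rows,",
      nrow(x$endpoint), "endpoint rows\n")
  invisible(x)
}

# one-step ordinal observer error, clamped to the rubric
observer_flip <- function(scores, prob, levels_desc) {
  idx <- match(scores, levels_desc)
  u <- stats::runif(length(scores))
  shift <- integer(length(scores))
  shift[u < prob / 2] <- -1L            # one level better
  shift[u >= prob / 2 & u < prob] <- 1L # one level worse
  idx <- pmin(pmax(idx + shift, 1L), length(levels_desc))
  levels_desc[idx]
}

# Gaussian truncated at zero (redraw; with sd = 0 returns the mean)
rnorm_truncated_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  if (any(x <= 0)) stop("failed to draw positive endpoint values", call. = FALSE)
  x
}

check_params_window <- function(params, design) {
  lo <- min(design$measurement_days)
  hi <- max(design$measurement_days)
  for (col in c("weight_plateau_day", "reflex_decline_start",
                "gait_decline_start")) {
    v <- params[[col]]
    v <- v[!is.na(v)]
    if (any(v < lo | v > hi)) {
      stop("`", col, "` must lie within the measurement window [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  invisible(TRUE)
}
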