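#' Ordinal motor-rubric levels
#'
#' The observer rubric used for both the hind-limb extension reflex and the
#' gait test runs from 5 (normal function) down to 0.5 (humane endpoint), in
#' steps of 0.25 near the top of the scale and 0.5 below.
#'
#' @return Numeric vector of the admissible rubric levels, decreasing.
#' @export
#' @examples
#' rubric_levels()
rubric_levels <- function() {
  c(5, 4.75, 4.5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5)
}

#' Snap a latent motor score to the nearest rubric level
#'
#' Maps a continuous latent impairment score onto the discrete observer
#' rubric.  Ties between two levels round down, toward the worse score: an
#' observer confronted with a borderline animal records the impairment.
#'
#' @param latent Numeric vector of latent scores, each in `[0, 5]`.
#' @return Numeric vector of rubric levels (see [rubric_levels()]).
#' @export
#' @examples
#' discretize_score(c(5, 4.8, 4.875, 0.1))
discretize_score <- function(latent) {
  if (!is.numeric(latent)) stop("`latent` must be numeric", call. = FALSE)
  if (any(!is.finite(latent)) || any(latent < 0) || any(latent > 5)) {
    stop("latent scores must lie in [0, 5]", call. = FALSE)
  }
  lv <- sort(rubric_levels())  # increasing, so ties resolve to the lower level
  vapply(latent, function(x) {
    d <- abs(lv - x)
    lv[which(d <= min(d) + 1e-9)[1L]]
  }, numeric(1))
}

#' Check rubric membership
#'
#' @param score Numeric vector.
#' @return Logical vector: is each value an admissible rubric level?
#' @export
is_rubric_level <- function(score) {
  score %in% rubric_levels()
}
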