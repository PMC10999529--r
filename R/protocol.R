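#' Default intense endurance treadmill protocol
#'
#' The eight-week, five-day-a-week motorized-treadmill schedule used for the
#' trained groups.  Speed ramps from 10 to 22 m/min, slope from 5 to 15
#' degrees and session duration from 15 to 60 minutes.
#'
#' @return An object of class `training_protocol`: a data.frame with 40 rows
#'   (8 weeks x 5 days) and columns `week`, `day`, `speed_m_per_min`,
#'   `slope_deg`, `time_min`.
#' @export
#' @examples
#' p <- training_protocol()
#' weekly_distance(p, 1)
training_protocol <- function() {
  speed <- c(rep(10, 5),
             c(10, 10, 12, 12, 12),
             rep(12, 5),
             rep(13, 5),
             rep(17, 5),
             rep(19, 5),
             rep(22, 5),
             rep(22, 5))
  slope <- c(c(5, 5, 10, 10, 10),
             rep(10, 5),
             rep(10, 5),
             rep(15, 5),
             rep(15, 5),
             rep(15, 5),
             rep(15, 5),
             rep(15, 5))
  time <- c(rep(15, 5),
            c(15, 15, 15, 30, 30),
            c(30, 30, 30, 45, 45),
            c(45, 60, 60, 60, 60),
            rep(60, 5),
            rep(60, 5),
            rep(60, 5),
            rep(60, 5))
  new_training_protocol(data.frame(
    week = rep(1:8, each = 5),
    day = rep(1:5, times = 8),
    speed_m_per_min = speed,
    slope_deg = slope,
    time_min = time
  ))
}

new_training_protocol <- function(df) {
  required <- c("week", "day", "speed_m_per_min", "slope_deg", "time_min")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("protocol is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$week, df$day), required]
  if (nrow(df) != 40 || !identical(as.integer(df$week), rep(1:8, each = 5)) ||
      !identical(as.integer(df$day), rep(1:5, times = 8))) {
    stop("protocol must contain exactly 8 weeks x 5 days of sessions",
         call. = FALSE)
  }
  vals <- df[, c("speed_m_per_min", "slope_deg", "time_min")]
  if (any(!is.finite(as.matrix(vals))) || any(as.matrix(vals) < 0)) {
    stop("protocol speeds, slopes and durations must be nonnegative finite",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("training_protocol", "data.frame"))
}

#' Treadmill distance prescribed in one training week
#'
#' Sum over a week's five sessions of speed (m/min) times duration (min),
#' i.e. the nominal distance run that week in meters.  Useful as a training
#' dose covariate.
#'
#' @param protocol A [training_protocol()].
#' @param week Week number, 1 to 8.
#' @return Distance in meters.
#' @export
weekly_distance <- function(protocol, week) {
  if (!inherits(protocol, "training_protocol")) {
    stop("`protocol` must be a training_protocol", call. = FALSE)
  }
  if (length(week) != 1 || !week %in% 1:8) {
    stop("`week` must be a single integer in 1..8", call. = FALSE)
  }
  rows <- protocol[protocol$week == week, ]
  sum(rows$speed_m_per_min * rows$time_min)
}

#' Read / write a training protocol file
#'
#' Protocols are stored as YAML with one `week<N>` mapping per week, each
#' holding per-day `speed_m_per_min`, `slope_deg` and `time_min` lists.
#'
#' @param path File path.
#' @return `read_protocol()` returns a [training_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  raw <- yaml::read_yaml(path)
  weeks <- sprintf("week%d", 1:8)
  missing <- setdiff(weeks, names(raw))
  if (length(missing)) {
    stop("protocol file is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(1:8, function(w) {
    wk <- raw[[sprintf("week%d", w)]]
    data.frame(
      week = w, day = 1:5,
      speed_m_per_min = as.numeric(wk$speed_m_per_min),
      slope_deg = as.numeric(wk$slope_deg),
      time_min = as.numeric(wk$time_min)
    )
  })
  new_training_protocol(do.call(rbind, rows))
}

#' @rdname read_protocol
#' @param protocol A [training_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  if (!inherits(protocol, "training_protocol")) {
    stop("`protocol` must be a training_protocol", call. = FALSE)
  }
  out <- lapply(1:8, function(w) {
    rows <- protocol[protocol$week == w, ]
    list(
      speed_m_per_min = rows$speed_m_per_min,
      slope_deg = rows$slope_deg,
      time_min = rows$time_min
    )
  })
  names(out) <- sprintf("week%d", 1:8)
  yaml::write_yaml(out, path)
  invisible(path)
}
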