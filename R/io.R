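# CSV schemas: comma-separated, UTF-8, header row, '.' decimal separator.

long_schema <- c("mouse_id", "genotype", "activity", "day", "weight_g",
                 "grip1", "grip2", "grip3", "reflex_score", "gait_score")
endpoint_schema <- c("mouse_id", "genotype", "activity", "mn_pct")
onset_schema <- c("mouse_id", "genotype", "activity", "event", "time_days")
score_schema <- c("mouse_id", "genotype", "activity", "day", "norm_grip",
                  "i_weight", "i_grip", "i_reflex", "i_gait", "total")

check_schema <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a longitudinal phenotype table
#'
#' Checks the column schema, positivity of weights, rubric membership of
#' the motor scores and uniqueness of mouse x day rows.  Called by every
#' consumer of longitudinal data; exported so external lab exports can be
#' checked directly.
#'
#' @param df A longitudinal table (see [score_cohort()] for the schema).
#' @return `df`, invisibly, if valid; otherwise an error naming the
#'   offending column.
#' @export
validate_longitudinal <- function(df) {
  check_schema(df, long_schema, "longitudinal")
  if (any(!is.finite(df$weight_g)) || any(df$weight_g <= 0)) {
    stop("column `weight_g` must be strictly positive", call. = FALSE)
  }
  for (col in c("reflex_score", "gait_score")) {
    if (any(!is_rubric_level(df[[col]]))) {
      stop("column `", col, "` contains values outside the rubric level set",
           call. = FALSE)
    }
  }
  if (anyDuplicated(df[, c("mouse_id", "day")])) {
    stop("duplicated mouse_id x day rows", call. = FALSE)
  }
  invisible(df)
}

#' Read and write the pipeline's CSV tables
#'
#' Readers validate the schema and value constraints; writers emit plain
#' UTF-8 CSV with a header row and '.' decimals.
#'
#' @param path File path.
#' @param df The table to write.
#' @return Readers return the validated data.frame; writers return `path`
#'   invisibly.
#' @name table_io
#' @export
read_longitudinal <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_longitudinal(df)
  df
}

#' @rdname table_io
#' @export
write_longitudinal <- function(df, path) {
  validate_longitudinal(df)
  write_csv_plain(df[, long_schema], path)
}

#' @rdname table_io
#' @export
read_endpoint <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, endpoint_schema, "endpoint")
  if (any(!is.finite(df$mn_pct)) || any(df$mn_pct <= 0)) {
    stop("column `mn_pct` must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(df$mouse_id)) {
    stop("duplicated mouse_id rows in endpoint table", call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_endpoint <- function(df, path) {
  check_schema(df, endpoint_schema, "endpoint")
  write_csv_plain(df[, endpoint_schema], path)
}

#' @rdname table_io
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, score_schema, "score")
  df
}

#' @rdname table_io
#' @export
write_scores <- function(df, path) {
  check_schema(df, score_schema, "score")
  write_csv_plain(df[, score_schema], path)
}

#' @rdname table_io
#' @export
read_onsets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, onset_schema, "onset")
  if (any(!df$event %in% c(0, 1))) {
    stop("column `event` must be 0 or 1", call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_onsets <- function(df, path) {
  check_schema(df, onset_schema, "onset")
  write_csv_plain(df[, onset_schema], path)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' A pipeline run is described by a YAML configuration with the top-level
#' keys `design` (`n_per_group`, `measurement_days`, `endpoint_day`),
#' `params` (`"default"` for the calibrated defaults, or a full per-group
#' parameter table), `reference_policy` (`weight_ref`, `grip_ref`,
#' `latch`), `onset` (`threshold`, `persistence`), `seed` and `outdir`.
#' Unknown keys are rejected.  `default_config()` returns the default
#' configuration; `read_config()`/`write_config()` round-trip it
#' losslessly.
#'
#' @param path File path for `read_config()` / `write_config()`.
#' @return A `pipeline_config` list.
#' @name config
#' @export
default_config <- function() {
  structure(
    list(
      design = list(
        n_per_group = 12L,
        measurement_days = default_schedule(),
        endpoint_day = 91L
      ),
      params = "default",
      reference_policy = list(
        weight_ref = "sedentary_wt",
        grip_ref = "running_max",
        latch = FALSE
      ),
      onset = list(threshold = 6, persistence = 1L),
      seed = 1L,
      outdir = "."
    ),
    class = "pipeline_config"
  )
}

#' @rdname config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname config
#' @param config A `pipeline_config` list.
#' @export
write_config <- function(config, path) {
  config <- validate_config(unclass(config))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(raw) {
  allowed <- c("design", "params", "reference_policy", "onset", "seed",
               "outdir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- unclass(default_config())
  for (k in intersect(names(raw), allowed)) {
    if (k %in% c("design", "reference_policy", "onset")) {
      sub <- raw[[k]]
      bad <- setdiff(names(sub), names(cfg[[k]]))
      if (length(bad)) {
        stop("unknown config key(s) under `", k, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      cfg[[k]][names(sub)] <- sub
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  cfg$design$measurement_days <- as.integer(cfg$design$measurement_days)
  cfg$design$n_per_group <- as.integer(cfg$design$n_per_group)
  cfg$design$endpoint_day <- as.integer(cfg$design$endpoint_day)
  cfg$seed <- as.integer(cfg$seed)
  # constructor validation catches inconsistent values early
  config_design(cfg)
  config_policy(cfg)
  structure(cfg, class = "pipeline_config")
}

config_design <- function(cfg) {
  study_design(
    n_per_group = cfg$design$n_per_group,
    measurement_days = cfg$design$measurement_days,
    endpoint_day = cfg$design$endpoint_day
  )
}

config_params <- function(cfg) {
  if (identical(cfg$params, "default")) {
    default_params()
  } else {
    new_trajectory_params(as.data.frame(do.call(cbind.data.frame, cfg$params)))
  }
}

config_policy <- function(cfg) {
  reference_policy(
    weight_ref = cfg$reference_policy$weight_ref,
    grip_ref = cfg$reference_policy$grip_ref,
    latch = cfg$reference_policy$latch
  )
}
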