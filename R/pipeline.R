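#' Pipeline stages
#'
#' File-to-file stages tying the simulator, the scoring module and the
#' statistical stage into a reproducible pipeline.  Each stage consumes and
#' produces only the documented CSV schemas, writes a run manifest, and is
#' byte-identical across runs with the same configuration and seed.
#'
#' * `cmd_simulate(config)` writes `longitudinal.csv` and `endpoint.csv`.
#' * `cmd_score(longitudinal_csv, config)` writes `scores.csv`.
#' * `cmd_onset(scores_csv, config)` writes `onsets.csv`.
#' * `cmd_stats(onsets_csv, endpoint_csv, config)` writes `km.csv`,
#'   `tests.csv` and `summary.csv`.
#' * `cmd_report(dir)` reads a stats output directory and returns (and
#'   prints) a compact run summary.
#'
#' @param config A `pipeline_config` (list, or path to a YAML config file);
#'   see [default_config()].
#' @param outdir Output directory; overrides the config's `outdir`.
#' @param seed Optional seed override.
#' @return Each stage returns (invisibly) the character vector of files it
#'   wrote; `cmd_report()` returns a summary list.
#' @name pipeline
NULL

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    read_config(config)
  } else {
    validate_config(unclass(config))
  }
}

stage_log <- function(stage, seed, rows_in, rows_out) {
  message(sprintf("[%s] seed=%s rows_in=%s rows_out=%s",
                  stage, seed, rows_in, rows_out))
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(config = default_config(), outdir = NULL,
                         seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir <- if (is.null(outdir)) cfg$outdir else outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(
    design = config_design(cfg),
    params = config_params(cfg),
    seed = cfg$seed
  )
  files <- c(
    write_longitudinal(cohort$longitudinal, file.path(dir, "longitudinal.csv")),
    write_endpoint(cohort$endpoint, file.path(dir, "endpoint.csv"))
  )
  write_manifest(dir, cfg, "simulate", files)
  stage_log("simulate", cfg$seed, 0, nrow(cohort$longitudinal))
  invisible(files)
}

#' @rdname pipeline
#' @param longitudinal_csv Path to a longitudinal CSV.
#' @export
cmd_score <- function(longitudinal_csv, config = default_config(),
                      outdir = NULL) {
  cfg <- resolve_config(config)
  dir <- if (is.null(outdir)) cfg$outdir else outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- read_longitudinal(longitudinal_csv)
  scores <- score_cohort(long, config_policy(cfg))
  files <- write_scores(scores, file.path(dir, "scores.csv"))
  write_manifest(dir, cfg, "score", files)
  stage_log("score", cfg$seed, nrow(long), nrow(scores))
  invisible(files)
}

#' @rdname pipeline
#' @param scores_csv Path to a scores CSV.
#' @export
cmd_onset <- function(scores_csv, config = default_config(), outdir = NULL) {
  cfg <- resolve_config(config)
  dir <- if (is.null(outdir)) cfg$outdir else outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores <- read_scores(scores_csv)
  onsets <- cohort_onsets(scores, threshold = cfg$onset$threshold,
                          persistence = cfg$onset$persistence)
  files <- write_onsets(onsets, file.path(dir, "onsets.csv"))
  write_manifest(dir, cfg, "onset", files)
  stage_log("onset", cfg$seed, nrow(scores), nrow(onsets))
  invisible(files)
}

#' @rdname pipeline
#' @param onsets_csv,endpoint_csv Paths to onset and endpoint CSVs.
#' @export
cmd_stats <- function(onsets_csv, endpoint_csv, config = default_config(),
                      outdir = NULL) {
  cfg <- resolve_config(config)
  dir <- if (is.null(outdir)) cfg$outdir else outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onsets <- read_onsets(onsets_csv)
  endp <- read_endpoint(endpoint_csv)

  onsets$group <- group_label(onsets$genotype, onsets$activity)
  endp$group <- group_label(endp$genotype, endp$activity)
  order4 <- c("SD WT", "TR WT", "SD G93A", "TR G93A")

  # Kaplan-Meier per group
  km <- do.call(rbind, lapply(order4, function(g) {
    sub <- onsets[onsets$group == g, ]
    if (nrow(sub) == 0) return(NULL)
    cbind(group = g, km_curve(sub))
  }))

  tests <- list()
  sd93 <- onsets[onsets$group == "SD G93A", ]
  tr93 <- onsets[onsets$group == "TR G93A", ]
  if (nrow(sd93) && nrow(tr93) && sum(sd93$event) + sum(tr93$event) > 0) {
    lr <- logrank_test(sd93, tr93)
    tests[[length(tests) + 1L]] <- data.frame(
      method = lr$method, statistic = lr$statistic, p_value = lr$p_value,
      groups = "SD G93A vs TR G93A")
    grp_list <- lapply(order4, function(g) onsets[onsets$group == g, ])
    grp_list <- grp_list[vapply(grp_list, nrow, integer(1)) > 0]
    if (length(grp_list) >= 2) {
      tr <- logrank_trend_test(grp_list)
      tests[[length(tests) + 1L]] <- data.frame(
        method = tr$method, statistic = tr$statistic, p_value = tr$p_value,
        groups = paste(order4, collapse = " < "))
    }
    a <- sd93$time_days[sd93$event == 1]
    b <- tr93$time_days[tr93$event == 1]
    if (length(a) && length(b)) {
      mw <- mann_whitney_test(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        method = mw$method, statistic = mw$statistic, p_value = mw$p_value,
        groups = "SD G93A vs TR G93A (events only)")
    }
  }
  av <- anova2_tukey(endp$mn_pct, endp$genotype, endp$activity)
  tests[[length(tests) + 1L]] <- data.frame(
    method = paste("two-way ANOVA:", av$anova$term),
    statistic = av$anova$statistic, p_value = av$anova$p_value,
    groups = "mn_pct ~ genotype * activity")
  tests[[length(tests) + 1L]] <- data.frame(
    method = paste("Tukey HSD:", av$tukey$comparison),
    statistic = av$tukey$diff, p_value = av$tukey$p_adj,
    groups = "mn_pct cell means")
  for (g in order4) {
    v <- endp$mn_pct[endp$group == g]
    if (length(v) >= 3 && diff(range(v)) > 0) {
      sw <- shapiro_normality(v)
      tests[[length(tests) + 1L]] <- data.frame(
        method = sw$method, statistic = sw$statistic, p_value = sw$p_value,
        groups = paste0("mn_pct, ", g))
    }
  }
  tests <- do.call(rbind, tests)

  onset_events <- onsets[onsets$event == 1, ]
  summaries <- rbind(
    cbind(measure = "onset_days",
          group_summary(onset_events$time_days, onset_events$group)),
    cbind(measure = "mn_pct", group_summary(endp$mn_pct, endp$group))
  )

  files <- c(
    write_csv_plain(km, file.path(dir, "km.csv")),
    write_csv_plain(tests, file.path(dir, "tests.csv")),
    write_csv_plain(summaries, file.path(dir, "summary.csv"))
  )
  write_manifest(dir, cfg, "stats", files)
  stage_log("stats", cfg$seed, nrow(onsets) + nrow(endp), nrow(tests))
  invisible(files)
}

#' @rdname pipeline
#' @param dir A directory containing `cmd_stats()` outputs.
#' @export
cmd_report <- function(dir) {
  summary_path <- file.path(dir, "summary.csv")
  tests_path <- file.path(dir, "tests.csv")
  if (!file.exists(summary_path) || !file.exists(tests_path)) {
    stop("`", dir, "` does not contain cmd_stats() outputs", call. = FALSE)
  }
  summaries <- utils::read.csv(summary_path, stringsAsFactors = FALSE)
  tests <- utils::read.csv(tests_path, stringsAsFactors = FALSE)
  onset <- summaries[summaries$measure == "onset_days", ]
  cat("Groups summarized:", length(unique(summaries$group)), "\n")
  for (i in seq_len(nrow(onset))) {
    cat(sprintf("  onset %-8s mean %.2f +/- %.2f d (n = %d)\n",
                onset$group[i], onset$mean[i], onset$sem[i], onset$n[i]))
  }
  invisible(list(summaries = summaries, tests = tests))
}

#' Run manifest
#'
#' Every pipeline stage appends a manifest entry recording the stage name,
#' the MD5 hash of the canonicalized configuration, the seed, the package
#' version and the output files with their MD5 checksums.  Identical
#' configuration and seed therefore yield identical data outputs and
#' identical output hashes.
#'
#' @param dir Output directory.
#' @param cfg A validated `pipeline_config`.
#' @param stage Stage name.
#' @param files Files written by the stage.
#' @return Path of `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, cfg, stage, files) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(validate_config(unclass(cfg))), tmp)
  entry <- list(
    stage = stage,
    config_hash = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("alsonset")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    list()
  }
  manifest[[stage]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
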