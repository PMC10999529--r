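#' Kaplan-Meier onset curve
#'
#' Product-limit estimate of the probability of remaining onset-free, from
#' per-animal onset records with right censoring.
#'
#' @param onsets data.frame with columns `event` (0/1 or logical) and
#'   `time_days` (onset day if event, else last observed day).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`: one row per distinct observed time.
#' @export
#' @examples
#' km_curve(data.frame(event = c(1, 0), time_days = c(10, 20)))
km_curve <- function(onsets) {
  check_onsets(onsets)
  fit <- survival::survfit(
    survival::Surv(onsets$time_days, as.integer(onsets$event)) ~ 1
  )
  data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' @param onsets_a,onsets_b Onset record data.frames (columns `event`,
#'   `time_days`) for the two groups.
#' @return A `test_result` list: `statistic` (chi-square, 1 df), `p_value`,
#'   `method`, `n` (per-group sizes).
#' @export
logrank_test <- function(onsets_a, onsets_b) {
  check_onsets(onsets_a)
  check_onsets(onsets_b)
  if (sum(onsets_a$event) + sum(onsets_b$event) == 0) {
    stop("log-rank statistic undefined: no events in either group",
         call. = FALSE)
  }
  time <- c(onsets_a$time_days, onsets_b$time_days)
  event <- as.integer(c(onsets_a$event, onsets_b$event))
  grp <- rep(c("A", "B"), c(nrow(onsets_a), nrow(onsets_b)))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  test_result(
    statistic = unname(fit$chisq),
    p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
    method = "log-rank (Mantel-Cox)",
    n = c(nrow(onsets_a), nrow(onsets_b))
  )
}

#' Log-rank test for trend across ordered groups
#'
#' Tests for a monotone trend in onset distributions across groups in the
#' supplied order, using the classical 1-df contrast of the groupwise
#' observed-minus-expected event counts with numeric group scores.
#'
#' @param onsets_list List of onset record data.frames, in increasing order
#'   of the hypothesized trend.
#' @param scores Numeric group scores (default `1, 2, ...`).
#' @return A `test_result` list (chi-square statistic, 1 df).
#' @export
logrank_trend_test <- function(onsets_list, scores = seq_along(onsets_list)) {
  if (length(onsets_list) < 2) {
    stop("at least two groups are required", call. = FALSE)
  }
  if (length(scores) != length(onsets_list)) {
    stop("`scores` must match the number of groups", call. = FALSE)
  }
  for (o in onsets_list) check_onsets(o)
  sizes <- vapply(onsets_list, nrow, integer(1))
  time <- unlist(lapply(onsets_list, function(o) o$time_days))
  event <- as.integer(unlist(lapply(onsets_list, function(o) o$event)))
  if (sum(event) == 0) {
    stop("log-rank trend statistic undefined: no events", call. = FALSE)
  }
  grp <- factor(rep(seq_along(onsets_list), sizes))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  d <- fit$obs - fit$exp
  v <- as.numeric(t(scores) %*% fit$var %*% scores)
  stat <- if (v <= 0) 0 else (sum(scores * d))^2 / v
  test_result(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    method = "log-rank test for trend",
    n = sizes
  )
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of onset ages
#'
#' Two-sided comparison of observed onset ages between two groups.  With
#' small samples (min n <= 12) and no ties the exact distribution is used;
#' otherwise the normal approximation with mid-ranks and tie correction
#' (onset ages fall on a discrete measurement grid, so ties are expected).
#'
#' @param x,y Numeric vectors of onset ages (events only).
#' @return A `test_result` list with the Mann-Whitney `statistic` (U for
#'   `x`), `p_value`, `method`, `n`.
#' @export
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  test_result(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "Mann-Whitney U (exact)" else
      "Mann-Whitney U (normal approximation, tie-corrected)",
    n = c(length(x), length(y))
  )
}

#' Two-way ANOVA with Tukey HSD post hoc
#'
#' Fits `value ~ genotype * activity` on the (balanced) four-group layout
#' and returns F tests for both main effects and the interaction, plus
#' Tukey studentized-range adjusted pairwise comparisons of the four cell
#' means.
#'
#' @param value Numeric response.
#' @param genotype,activity Factors (or coercible) of the same length.
#' @return A list with components `anova` (data.frame: `term`, `df`,
#'   `sum_sq`, `statistic`, `p_value`) and `tukey` (data.frame:
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova2_tukey <- function(value, genotype, activity) {
  genotype <- factor(genotype)
  activity <- factor(activity)
  if (length(value) != length(genotype) || length(value) != length(activity)) {
    stop("`value`, `genotype` and `activity` must have equal length",
         call. = FALSE)
  }
  if (nlevels(genotype) < 2 || nlevels(activity) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cell_n <- table(genotype, activity)
  if (any(cell_n == 0)) stop("empty design cell", call. = FALSE)
  if (any(cell_n < 2)) {
    stop("at least 2 observations per cell are required for the interaction",
         call. = FALSE)
  }
  dat <- data.frame(value = value, genotype = genotype, activity = activity)
  fit <- stats::aov(value ~ genotype * activity, data = dat)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  an <- data.frame(
    term = terms[keep],
    df = tab$Df[keep],
    sum_sq = tab$`Sum Sq`[keep],
    statistic = tab$`F value`[keep],
    p_value = tab$`Pr(>F)`[keep]
  )
  tk <- stats::TukeyHSD(fit, "genotype:activity")[["genotype:activity"]]
  tukey <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  rownames(tukey) <- NULL
  list(anova = an, tukey = tukey)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, not all identical.
#' @return A `test_result` list with `statistic` (W) and `p_value`.
#' @export
shapiro_normality <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("sample is degenerate: all values identical", call. = FALSE)
  }
  st <- stats::shapiro.test(x)
  test_result(
    statistic = unname(st$statistic),
    p_value = st$p.value,
    method = "Shapiro-Wilk normality test",
    n = n
  )
}

#' Mean and SEM by group
#'
#' @param value Numeric vector.
#' @param group Grouping vector of the same length.
#' @return data.frame with columns `group`, `n`, `mean`, `sem`.  SEM is
#'   `sd / sqrt(n)`; a single-observation group has SEM 0 by convention.
#' @export
#' @examples
#' group_summary(c(4, 6), c("a", "a"))  # mean 5, SEM 1
group_summary <- function(value, group) {
  if (length(value) != length(group)) {
    stop("`value` and `group` must have equal length", call. = FALSE)
  }
  if (length(value) == 0) stop("empty input", call. = FALSE)
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    v <- value[group == g]
    s <- if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
    data.frame(group = g, n = length(v), mean = mean(v), sem = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

test_result <- function(statistic, p_value, method, n) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(statistic = statistic, p_value = min(p_value, 1),
         method = method, n = n),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format(x$p_value),
      " n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

check_onsets <- function(onsets) {
  if (!is.data.frame(onsets) ||
      !all(c("event", "time_days") %in% names(onsets))) {
    stop("onset records need columns `event` and `time_days`", call. = FALSE)
  }
  if (nrow(onsets) == 0) stop("empty onset records", call. = FALSE)
  invisible(TRUE)
}
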