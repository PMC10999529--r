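# Independent oracles, deliberately naive: brute force / enumeration / hand
# formulas, kept separate from the implementation paths they check.

# first index from which `qual` holds for k consecutive entries, else NA
oracle_first_run <- function(qual, k) {
  n <- length(qual)
  if (k > n) return(NA_integer_)
  for (i in 1:(n - k + 1)) {
    if (all(qual[i:(i + k - 1)])) return(i)
  }
  NA_integer_
}

# hand product-limit estimator at each distinct time
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (j in seq_along(ts)) {
    at_risk <- sum(time >= ts[j])
    d <- sum(time == ts[j] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[j] <- s
  }
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# permutation tail probability of the log-rank chi-square statistic
oracle_logrank_perm <- function(time, event, group, n_perm = 2000, seed = 42) {
  stat <- function(g) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(fit$chisq)
  }
  obs <- stat(group)
  withr::with_seed(seed, {
    perms <- replicate(n_perm, stat(sample(group)))
  })
  mean(perms >= obs - 1e-12)
}

# closed-form balanced two-way ANOVA F statistics (a = b = 2, r reps/cell)
oracle_anova_2x2 <- function(value, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  r <- length(value) / 4
  g <- mean(value)
  m1 <- tapply(value, f1, mean)
  m2 <- tapply(value, f2, mean)
  m12 <- tapply(value, interaction(f1, f2), mean)
  ss1 <- 2 * r * sum((m1 - g)^2)
  ss2 <- 2 * r * sum((m2 - g)^2)
  cell_means <- tapply(value, list(f1, f2), mean)
  ss12 <- r * sum((sweep(sweep(cell_means, 1, m1), 2, m2) + g)^2)
  sse <- sum((value - ave(value, f1, f2))^2)
  dfe <- length(value) - 4
  mse <- sse / dfe
  c(F1 = ss1 / 1 / mse, F2 = ss2 / 1 / mse, F12 = ss12 / 1 / mse)
}

# small default-design cohort helpers shared by several test files
tiny_design <- function(n = 3) study_design(n_per_group = n)
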