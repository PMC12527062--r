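# Independent oracles: these deliberately avoid the package's code paths.

# DTW by exhaustive enumeration of every monotone warping path (steps:
# right, down, diagonal) from (1,1) to (n,m); no dynamic programming.
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
  }
  walk(1L, 1L, 0)
  best
}

# Mann-Whitney U by direct pair counting (ties count 1/2).
u_pair_count <- function(x, y) {
  u1 <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(u1, length(x) * length(y) - u1)
}

# Exact two-sided p by enumeration of group assignments, using the
# pair-counting statistic (not ranks).
exact_p_enumerate <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), n1)
  obs <- u_pair_count(x, y)
  us <- apply(idx, 2L, function(i) u_pair_count(pool[i], pool[-i]))
  mean(us <= obs + 1e-9)
}

# Two-way ANOVA mean squares computed via stats::aov.
anova_ms <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  list(MSR = tab["subject", "Mean Sq"],
       MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"])
}

# Build a gait_cycles object directly from swing windows.
make_cycles <- function(swings, duration, fs) {
  structure(
    lapply(swings, function(s) {
      structure(list(start_idx = 1L, end_idx = 1L + round(duration * fs),
                     heel_strike_idx = 1L + length(s),
                     swing_accel = s, duration = duration,
                     sample_rate = fs),
                class = "gait_cycle")
    }),
    class = "gait_cycles", sample_rate = fs)
}

fixture_tables <- function() bundled_participant_table()
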