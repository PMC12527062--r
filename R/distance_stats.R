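#' Estimation accuracy
#'
#' \eqn{Accuracy = (1 - |actual - estimated| / actual) \times 100\%}.
#' Values are negative when the estimate errs by more than 100\% of the
#' actual outcome.
#'
#' @param actual Actual outcome(s), strictly positive.
#' @param estimated Estimated outcome(s), recycled against `actual`.
#' @param digits Rounding used for the table-parity value (default 2).
#' @return A list with `percent` (rounded) and `raw` (unrounded) vectors.
#' @examples
#' accuracy(610.88, 616.93)$percent  # 99.01
#' @export
accuracy <- function(actual, estimated, digits = 2) {
  actual <- check_numeric_vector(actual, "actual")
  estimated <- check_numeric_vector(estimated, "estimated")
  if (any(actual <= 0)) {
    stop_is("invalid_input", "`actual` must be strictly positive")
  }
  raw <- (1 - abs(actual - estimated) / actual) * 100
  list(percent = round(raw, digits), raw = raw)
}

#' Median and interquartile range
#'
#' The median is the standard sample median. The interquartile range is
#' \eqn{Q_3 - Q_1} under the SPSS weighted-average percentile rule
#' (position \eqn{(n+1)p}; R quantile type 6, the default) or Tukey hinges.
#'
#' @param values Non-empty numeric vector.
#' @param type `"spss"` (default) or `"tukey"`.
#' @return A list with `median`, `iqr`, `q1`, `q3`.
#' @export
median_iqr <- function(values, type = c("spss", "tukey")) {
  type <- match.arg(type)
  values <- check_numeric_vector(values, "values")
  if (type == "spss") {
    q <- stats::quantile(values, c(0.25, 0.75), type = 6, names = FALSE)
  } else {
    f <- stats::fivenum(values)
    q <- f[c(2, 4)]
  }
  list(median = stats::median(values), iqr = q[2] - q[1],
       q1 = q[1], q3 = q[2])
}

#' Mann-Whitney U test (midranks, SPSS-style reporting)
#'
#' U statistics are computed from midranks (tie-corrected);
#' \eqn{U_1 = R_1 - n_1(n_1+1)/2} and the reported statistic is
#' \eqn{\min(U_1, U_2)}. The exact two-sided p-value is the permutation
#' tail \eqn{P(\min(U_1, U_2) \le U_{obs})} over all group assignments of
#' the pooled sample (used when both groups have at most `exact_limit`
#' observations); the asymptotic p uses the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param p_mode `"auto"` (exact when feasible, default), `"exact"` or
#'   `"normal"`.
#' @param exact_limit Largest per-group size for exact enumeration
#'   (default 10).
#' @return A list with `U`, `U1`, `U2`, `p_value`, `p_exact`, `p_normal`
#'   and `method`. `p_exact` is `NA` when not enumerated.
#' @export
mann_whitney_u <- function(x, y, p_mode = c("auto", "exact", "normal"),
                           exact_limit = 10L) {
  p_mode <- match.arg(p_mode)
  x <- check_numeric_vector(x, "x")
  y <- check_numeric_vector(y, "y")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ranks <- rank(c(x, y))
  U1 <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)

  p_normal <- {
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) 1 else {
      z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(-abs(z)))
    }
  }

  do_exact <- p_mode == "exact" || (p_mode == "auto" &&
                                    n1 <= exact_limit && n2 <= exact_limit)
  p_exact <- NA_real_
  if (do_exact) {
    idx <- utils::combn(N, n1)
    offset <- n1 * (n1 + 1) / 2
    u_min <- apply(idx, 2L, function(i) {
      u1 <- sum(ranks[i]) - offset
      min(u1, n1 * n2 - u1)
    })
    p_exact <- mean(u_min <= U + 1e-9)
  }
  method <- if (do_exact) "exact" else "normal"
  list(U = U, U1 = U1, U2 = U2,
       p_value = if (method == "exact") p_exact else p_normal,
       p_exact = p_exact, p_normal = p_normal, method = method)
}

#' Intraclass correlation coefficient with confidence interval
#'
#' Single-measures ICC from the two-way (or one-way) ANOVA decomposition of
#' a complete subjects-by-raters matrix, with a 95\% confidence interval
#' from F-distribution bounds (McGraw & Wong conventions) and the
#' interpretation band: excellent (> 0.90), good (0.75-0.90), moderate
#' (0.50-0.74), poor (< 0.50).
#'
#' @param m Numeric matrix, subjects in rows (>= 2), raters/methods in
#'   columns (>= 2), no missing cells.
#' @param form `"twoway_random_abs"` (ICC(2,1) / ICC(A,1), the default),
#'   `"twoway_mixed_consistency"` (ICC(3,1) / ICC(C,1)) or `"oneway"`
#'   (ICC(1,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `icc`, `ci_low`, `ci_high`, `band`, `form` and the
#'   mean squares `ms` (MSR, MSC, MSE, MSW).
#' @export
icc <- function(m, form = c("twoway_random_abs", "twoway_mixed_consistency",
                            "oneway"),
                conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) {
    stop_is("invalid_input", "`m` must be a complete numeric matrix")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop_is("invalid_input", "need >= 2 subjects and >= 2 raters")
  }
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - gm)^2)
  SSC <- n * sum((col_m - gm)^2)
  SST <- sum((m - gm)^2)
  SSE <- SST - SSR - SSC
  SSW <- SST - SSR
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  MSW <- SSW / (n * (k - 1))
  if (MSR <= 0) {
    stop_is("degenerate", "zero between-subject variance; ICC undefined")
  }
  alpha <- 1 - conf_level
  if (form == "oneway") {
    est <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    Fobs <- MSR / MSW
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    FU <- Fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else if (form == "twoway_mixed_consistency") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      lo <- hi <- est  # perfect consistency: degenerate CI
    } else {
      Fobs <- MSR / MSE
      FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (FL - 1) / (FL + k - 1)
      hi <- (FU - 1) / (FU + k - 1)
    }
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == MSE) {
      lo <- hi <- est
    } else {
      # Satterthwaite df for the ICC(A,1) interval (McGraw & Wong 1996)
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      F_L <- stats::qf(1 - alpha / 2, n - 1, v)
      F_U <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - F_L * MSE) /
        (F_L * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (F_U * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * F_U * MSR)
    }
  }
  list(icc = est, ci_low = lo, ci_high = hi, band = icc_band(est),
       form = form, ms = list(MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW))
}

#' Interpretation band for an ICC value
#'
#' @param value ICC estimate.
#' @return `"excellent"` (> 0.90), `"good"` (0.75-0.90), `"moderate"`
#'   (0.50-0.74) or `"poor"` (< 0.50).
#' @export
icc_band <- function(value) {
  if (value > 0.90) "excellent"
  else if (value >= 0.75) "good"
  else if (value >= 0.50) "moderate"
  else "poor"
}

#' Per-participant summary table
#'
#' Combines a stride-length table and a total-distance table (one row per
#' participant) into a validated `participant_table`. Column layouts match
#' the bundled fixtures; see [read_stride_table()] and
#' [read_distance_table()].
#'
#' @param stride A stride-length data frame.
#' @param distance A total-distance data frame.
#' @return An object of class `participant_table` (a list of the two data
#'   frames).
#' @export
participant_table <- function(stride, distance) {
  need_s <- c("participant", "actual_n_strides", "actual_stride_length_m",
              "gaitup_right_m", "gaitup_left_m",
              "insole_n_strides_right", "insole_n_strides_left",
              "approach1_right_m", "approach1_left_m",
              "approach2_right_m", "approach2_left_m")
  need_d <- c("participant", "actual_m", "gaitup_right_m", "gaitup_left_m",
              "approach1_right_m", "approach1_left_m",
              "approach2_right_m", "approach2_left_m")
  miss_s <- setdiff(need_s, names(stride))
  miss_d <- setdiff(need_d, names(distance))
  if (length(miss_s) || length(miss_d)) {
    stop_is("format_error",
            paste("participant table is missing columns:",
                  paste(c(miss_s, miss_d), collapse = ", ")))
  }
  if (!identical(as.character(stride$participant),
                 as.character(distance$participant))) {
    stop_is("invalid_input", "stride and distance tables list different participants")
  }
  num_s <- setdiff(need_s, "participant")
  if (any(stride[num_s] <= 0) || any(distance[setdiff(need_d, "participant")] <= 0)) {
    stop_is("invalid_input", "lengths, counts and distances must be positive")
  }
  structure(list(stride = stride[need_s], distance = distance[need_d]),
            class = "participant_table")
}

#' Build the full validation report
#'
#' From a [participant_table()] computes, per side and method
#' (Gait Up, Approach 1, Approach 2):
#' per-participant accuracies against the actual outcome, column medians
#' and interquartiles, Mann-Whitney U tests (actual vs each estimated
#' distance, and Approach 1 vs Approach 2 stride lengths) with exact and
#' asymptotic p-values, and single-measures ICCs with confidence intervals
#' and interpretation bands.
#'
#' @param table A [participant_table()].
#' @param icc_form ICC form passed to [icc()] (default two-way random,
#'   absolute agreement).
#' @param quantile_type Quantile rule for [median_iqr()].
#' @return An object of class `validation_report`: a list with data frames
#'   `stride_accuracy`, `distance_accuracy`, `medians`, `u_tests` and
#'   `icc`.
#' @export
build_validation_report <- function(table, icc_form = "twoway_random_abs",
                                    quantile_type = "spss") {
  stopifnot(inherits(table, "participant_table"))
  s <- table$stride; d <- table$distance
  methods <- c(gaitup = "gaitup", approach1 = "approach1",
               approach2 = "approach2")
  sides <- c(right = "right", left = "left")

  est_cols <- function(df, what) {
    cols <- expand.grid(method = methods, side = sides,
                        stringsAsFactors = FALSE)
    cols$column <- paste0(cols$method, "_", cols$side, "_m")
    cols
  }

  acc_table <- function(df, actual_col) {
    cols <- est_cols(df)
    out <- data.frame(participant = df$participant)
    for (i in seq_len(nrow(cols))) {
      out[[paste(cols$method[i], cols$side[i], sep = "_")]] <-
        accuracy(df[[actual_col]], df[[cols$column[i]]])$percent
    }
    out
  }
  stride_acc <- acc_table(s, "actual_stride_length_m")
  dist_acc <- acc_table(d, "actual_m")

  med_rows <- list()
  add_med <- function(outcome, label, values) {
    mi <- median_iqr(values, type = quantile_type)
    med_rows[[length(med_rows) + 1L]] <<-
      data.frame(outcome = outcome, column = label,
                 median = mi$median, iqr = mi$iqr)
  }
  add_med("stride_length", "actual", s$actual_stride_length_m)
  add_med("distance", "actual", d$actual_m)
  for (i in seq_len(nrow(est_cols(s)))) {
    cl <- est_cols(s)[i, ]
    add_med("stride_length", paste(cl$method, cl$side, sep = "_"),
            s[[cl$column]])
    add_med("distance", paste(cl$method, cl$side, sep = "_"),
            d[[cl$column]])
  }
  medians <- do.call(rbind, med_rows)

  u_rows <- list()
  add_u <- function(outcome, comparison, side, x, y) {
    u <- mann_whitney_u(x, y)
    u_rows[[length(u_rows) + 1L]] <<-
      data.frame(outcome = outcome, comparison = comparison, side = side,
                 U = u$U, p_exact = u$p_exact, p_normal = u$p_normal)
  }
  add_u("stride_length", "approach1_vs_approach2", "right",
        s$approach1_right_m, s$approach2_right_m)
  add_u("stride_length", "approach1_vs_approach2", "left",
        s$approach1_left_m, s$approach2_left_m)
  for (mth in methods) {
    for (sd in sides) {
      add_u("distance", paste0("actual_vs_", mth), sd,
            d$actual_m, d[[paste0(mth, "_", sd, "_m")]])
    }
  }
  u_tests <- do.call(rbind, u_rows)

  icc_rows <- list()
  add_icc <- function(outcome, mth, sd, actual, est) {
    r <- icc(cbind(actual, est), form = icc_form)
    icc_rows[[length(icc_rows) + 1L]] <<-
      data.frame(outcome = outcome, method = mth, side = sd,
                 icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
                 band = r$band)
  }
  for (mth in methods) {
    for (sd in sides) {
      add_icc("stride_length", mth, sd, s$actual_stride_length_m,
              s[[paste0(mth, "_", sd, "_m")]])
      add_icc("distance", mth, sd, d$actual_m,
              d[[paste0(mth, "_", sd, "_m")]])
    }
  }
  icc_df <- do.call(rbind, icc_rows)

  structure(list(stride_accuracy = stride_acc, distance_accuracy = dist_acc,
                 medians = medians, u_tests = u_tests, icc = icc_df,
                 icc_form = icc_form, quantile_type = quantile_type),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("-- distance accuracies (%) --\n")
  print(x$distance_accuracy, row.names = FALSE)
  cat("-- Mann-Whitney U --\n")
  print(x$u_tests, row.names = FALSE, digits = 4)
  cat(sprintf("-- ICC (%s) --\n", x$icc_form))
  print(x$icc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a validation report to CSV files
#'
#' Writes one CSV per report component into `dir`
#' (`stride_accuracy.csv`, `distance_accuracy.csv`, `medians.csv`,
#' `u_tests.csv`, `icc.csv`) plus a human-readable `report.txt`.
#'
#' @param report A [build_validation_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("stride_accuracy", "distance_accuracy", "medians",
               "u_tests", "icc")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  invisible(dir)
}
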