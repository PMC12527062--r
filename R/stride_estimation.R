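#' Slope of the swing-phase acceleration line
#'
#' Ordinary least-squares fit of a straight line to the AP acceleration
#' over a swing window; the slope is the measured director coefficient.
#' Mean-centering both axes (default) leaves the OLS slope unchanged but
#' mirrors the centering step of the estimation algorithms.
#'
#' @param swing_accel Acceleration samples, m/s^2 (length >= 2).
#' @param sample_rate Sampling rate, Hz.
#' @param center Mean-center time and acceleration before fitting.
#' @return Slope in (m/s^2)/s.
#' @export
swing_slope <- function(swing_accel, sample_rate, center = TRUE) {
  swing_accel <- check_numeric_vector(swing_accel, "swing_accel", 2L)
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop_is("invalid_parameter", "`sample_rate` must be > 0")
  }
  tt <- (seq_along(swing_accel) - 1) / sample_rate
  a <- swing_accel
  if (center) {
    tt <- tt - mean(tt)
    a <- a - mean(a)
  }
  sxx <- sum((tt - mean(tt))^2)
  if (sxx == 0) stop_is("invalid_input", "zero time variance in swing window")
  sum((tt - mean(tt)) * (a - mean(a))) / sxx
}

#' Stride length by the director-coefficient ratio (Approach 1)
#'
#' For each gait cycle the straight line best fitting the swing-phase AP
#' acceleration is compared with the reference model's linear acceleration:
#' the ratio of the two director coefficients, averaged over cycles and
#' multiplied by the model stride length \eqn{P_x}, gives the average
#' stride length \eqn{L = P_x \bar R}.
#'
#' With `time_normalize = TRUE` (default) the model's director coefficient
#' is re-timed to each cycle's measured duration
#' (\eqn{6 c_1 (T_m / T_i)^3}), so the ratio compares amplitudes at matched
#' cadence rather than conflating stride length with cycle duration (the
#' director coefficient scales as \eqn{T^{-3}}). Set to `FALSE` for the
#' literal un-normalized ratio against the model's own period.
#'
#' @param cycles A [gait_cycles][segment_cycles] object (>= 1 cycle).
#' @param model A [reference_model][analytic_reference_model] with non-zero
#'   director coefficient.
#' @param ratio_convention `"insole_over_model"` (default) forms
#'   \eqn{R_i = |slope_i| / |6 c_1|}; `"model_over_insole"` inverts it.
#' @param time_normalize See Details.
#' @return An object of class `stride_estimate` with fields `method`,
#'   `per_cycle_values` (the ratios \eqn{R_i}), `mean_R`,
#'   `stride_length_L` (m) and `n_cycles`.
#' @export
approach1_stride_length <- function(cycles, model,
                                    ratio_convention = c("insole_over_model",
                                                         "model_over_insole"),
                                    time_normalize = TRUE) {
  ratio_convention <- match.arg(ratio_convention)
  stopifnot(inherits(cycles, "gait_cycles"))
  validate_reference_model(model)
  if (length(cycles) < 1L) stop_is("invalid_input", "need at least one cycle")
  if (model$model_stride_Px == 0 || model$c1 == 0) {
    stop_is("degenerate", "reference model has zero stride length / director coefficient")
  }
  dc_model <- model_director_coefficient(model, absolute = TRUE)
  r <- vapply(cycles, function(cy) {
    slope <- swing_slope(cy$swing_accel, cy$sample_rate, center = TRUE)
    denom <- if (time_normalize) {
      dc_model * (model$period_T / cy$duration)^3
    } else dc_model
    if (slope == 0) {
      warn_is("zero_slope", "a cycle has zero swing slope; its ratio is 0")
    }
    if (ratio_convention == "insole_over_model") abs(slope) / denom
    else if (slope == 0) 0 else denom / abs(slope)
  }, numeric(1))
  mean_r <- mean(r)
  new_stride_estimate(method = "approach1", per_cycle_values = r,
                      mean_R = mean_r,
                      stride_length_L = model$model_stride_Px * mean_r,
                      n_cycles = length(r))
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two sequences with
#' absolute-difference local cost, unconstrained band and the usual
#' match/insert/delete steps. Returns the cumulative cost of the optimal
#' monotone warping path; optionally normalized by path length.
#'
#' @param a,b Non-empty numeric sequences.
#' @param local_cost `"abs"` (default) or `"squared"` pointwise cost.
#' @param path_normalize Divide the cumulative cost by the optimal path
#'   length (default `FALSE`: raw cumulative cost).
#' @return The alignment cost (non-negative; 0 iff the sequences are equal
#'   under `"abs"` cost).
#' @examples
#' dtw_distance(c(1, 2, 3), c(2, 3, 4))  # 2
#' @export
dtw_distance <- function(a, b, local_cost = c("abs", "squared"),
                         path_normalize = FALSE) {
  local_cost <- match.arg(local_cost)
  a <- check_numeric_vector(a, "a")
  b <- check_numeric_vector(b, "b")
  n <- length(a); m <- length(b)
  cost <- abs(outer(a, b, "-"))
  if (local_cost == "squared") cost <- cost^2
  D <- matrix(Inf, n + 1L, m + 1L)
  steps <- matrix(0L, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])
      k <- which.min(prev)
      D[i + 1L, j + 1L] <- cost[i, j] + prev[k]
      steps[i + 1L, j + 1L] <- 1L +
        c(steps[i, j], steps[i, j + 1L], steps[i + 1L, j])[k]
    }
  }
  if (path_normalize) D[n + 1L, m + 1L] / steps[n + 1L, m + 1L]
  else D[n + 1L, m + 1L]
}

#' Swing-acceleration scaling coefficient (Approach 2)
#'
#' \eqn{S = 1 / \lVert A_{sxn} \rVert}, where the norm of the swing-phase
#' AP acceleration defaults to its mean absolute value (alternatives:
#' Euclidean norm, maximum absolute value).
#'
#' @param swing_accel Swing-phase acceleration samples (non-empty, not all
#'   zero).
#' @param norm One of `"mean_abs"` (default), `"euclidean"`, `"max_abs"`.
#' @return The scalar \eqn{S} (1 / (m/s^2)).
#' @examples
#' scaling_coefficient(c(2, -2, 2, -2))  # 0.5
#' @export
scaling_coefficient <- function(swing_accel,
                                norm = c("mean_abs", "euclidean", "max_abs")) {
  norm <- match.arg(norm)
  swing_accel <- check_numeric_vector(swing_accel, "swing_accel")
  v <- switch(norm,
              mean_abs = mean(abs(swing_accel)),
              euclidean = sqrt(sum(swing_accel^2)),
              max_abs = max(abs(swing_accel)))
  if (v == 0) {
    stop_is("degenerate",
            "swing acceleration is all zero; scaling coefficient S undefined")
  }
  1 / v
}

#' Stride length by DTW scaling (Approach 2)
#'
#' For each cycle the DTW distance \eqn{d_i} between the model's
#' swing-phase acceleration and the insole's swing-phase acceleration is
#' computed; the scaling coefficient \eqn{S} is computed once from the
#' pooled swing acceleration of all cycles; \eqn{E = \overline{d}\, S} and
#' \eqn{L = P_x E}. Note the literal formulation yields \eqn{L = 0} when
#' insole and model accelerations coincide -- flagged with a
#' degenerate-similarity warning.
#'
#' The model swing acceleration is sampled at the insole rate over
#' `[0, swing_fraction * T]`; with `time_normalize = TRUE` (default) each
#' insole swing window is resampled by linear interpolation onto that model
#' grid before alignment so DTW cost does not grow with cadence.
#'
#' @inheritParams approach1_stride_length
#' @param swing_fraction Model swing window as a fraction of the cycle
#'   (default 0.6).
#' @param norm Norm used in the scaling coefficient (see
#'   [scaling_coefficient()]).
#' @param pooled_S Compute \eqn{S} once from the pooled swing windows
#'   (default, as the algorithm computes \eqn{S} before its loop);
#'   `FALSE` uses a per-cycle \eqn{S} averaged with the distances.
#' @return A `stride_estimate` with `per_cycle_values` (the \eqn{d_i}),
#'   `scaling_S`, `E`, `stride_length_L` and `n_cycles`.
#' @export
approach2_stride_length <- function(cycles, model, swing_fraction = 0.6,
                                    norm = "mean_abs", pooled_S = TRUE,
                                    time_normalize = TRUE) {
  stopifnot(inherits(cycles, "gait_cycles"))
  validate_reference_model(model)
  if (length(cycles) < 1L) stop_is("invalid_input", "need at least one cycle")
  fs <- attr(cycles, "sample_rate") %||% cycles[[1L]]$sample_rate
  model_swing <- model_swing_acceleration(model, swing_fraction, fs)
  pooled <- unlist(lapply(cycles, `[[`, "swing_accel"))
  d <- vapply(cycles, function(cy) {
    insole <- cy$swing_accel
    if (time_normalize) insole <- resample_linear(insole, length(model_swing))
    dtw_distance(model_swing, insole)
  }, numeric(1))
  if (pooled_S) {
    S <- scaling_coefficient(pooled, norm = norm)
    E <- mean(d) * S
  } else {
    S_i <- vapply(cycles, function(cy)
      scaling_coefficient(cy$swing_accel, norm = norm), numeric(1))
    S <- mean(S_i)
    E <- mean(d * S_i)
  }
  if (all(d == 0)) {
    warn_is("degenerate_similarity",
            "all DTW distances are zero (insole identical to model); L = 0 by construction")
  }
  new_stride_estimate(method = "approach2", per_cycle_values = d,
                      scaling_S = S, E = E,
                      stride_length_L = model$model_stride_Px * E,
                      n_cycles = length(d))
}

new_stride_estimate <- function(method, per_cycle_values, stride_length_L,
                                n_cycles, mean_R = NULL, scaling_S = NULL,
                                E = NULL) {
  if (stride_length_L < 0) stop_is("invalid_parameter", "stride length must be >= 0")
  structure(
    list(method = method, per_cycle_values = per_cycle_values,
         mean_R = mean_R, scaling_S = scaling_S, E = E,
         stride_length_L = stride_length_L, n_cycles = n_cycles),
    class = "stride_estimate"
  )
}

#' @export
print.stride_estimate <- function(x, ...) {
  cat(sprintf("<stride_estimate> %s: L = %.4f m over %d cycle(s)\n",
              x$method, x$stride_length_L, x$n_cycles))
  if (!is.null(x$mean_R)) cat(sprintf("  mean ratio R = %.4f\n", x$mean_R))
  if (!is.null(x$E)) cat(sprintf("  E = %.4f (S = %.4f)\n", x$E, x$scaling_S))
  invisible(x)
}

#' Total distance covered
#'
#' \eqn{T_d = L N_s}: average stride length times stride count, reported at
#' two decimals for table parity (the unrounded value is returned as an
#' attribute `"raw"`).
#'
#' @param stride_length_L Average stride length, m (>= 0).
#' @param stride_count_Ns Number of strides (non-negative integer).
#' @return Distance in metres, rounded to 2 decimals.
#' @examples
#' total_distance(1.681, 367)  # 616.93
#' @export
total_distance <- function(stride_length_L, stride_count_Ns) {
  if (!is.numeric(stride_length_L) || any(stride_length_L < 0) ||
      anyNA(stride_length_L)) {
    stop_is("invalid_parameter", "`stride_length_L` must be >= 0")
  }
  if (!is.numeric(stride_count_Ns) || any(stride_count_Ns < 0) ||
      any(stride_count_Ns != round(stride_count_Ns))) {
    stop_is("invalid_parameter", "`stride_count_Ns` must be a non-negative integer")
  }
  raw <- stride_length_L * stride_count_Ns
  structure(round(raw, 2), raw = raw)
}

#' Export stride estimates as CSV
#'
#' Writes rows `method,side,n_cycles,mean_R_or_E,stride_length_m,total_distance_m`.
#'
#' @param estimates A list of `stride_estimate` objects.
#' @param stride_counts Stride counts used for the distances, one per
#'   estimate.
#' @param path Output path.
#' @param sides Optional side labels (recycled), default `""`.
#' @return The written data frame, invisibly.
#' @export
write_estimates_csv <- function(estimates, stride_counts, path, sides = "") {
  if (inherits(estimates, "stride_estimate")) estimates <- list(estimates)
  sides <- rep_len(sides, length(estimates))
  stride_counts <- rep_len(stride_counts, length(estimates))
  df <- do.call(rbind, lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(method = e$method, side = sides[i], n_cycles = e$n_cycles,
               mean_R_or_E = e$mean_R %||% e$E,
               stride_length_m = e$stride_length_L,
               total_distance_m = as.numeric(total_distance(e$stride_length_L,
                                                            stride_counts[i])))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
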