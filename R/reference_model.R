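#' Boundary-constrained cubic reference gait model
#'
#' The antero-posterior (AP) foot position over one stride cycle is modelled
#' as a cubic polynomial \eqn{P(t) = c_1 t^3 + c_2 t^2 + c_3 t + c_4} on
#' \eqn{t \in [0, T]}, where \eqn{t = 0} is the toe-off opening the cycle and
#' \eqn{T} is the cycle period (toe-off to next toe-off). The physiological
#' boundary conditions -- zero position at toe-off and zero velocity at both
#' toe-offs -- force \eqn{c_3 = c_4 = 0} and determine the remaining
#' coefficients from the stride length \eqn{L = P(T)} alone:
#' \eqn{c_1 = -2L/T^3}, \eqn{c_2 = 3L/T^2}. Velocity and acceleration follow
#' by differentiation; the acceleration is linear in time with slope
#' \eqn{6 c_1} (the model's director coefficient).
#'
#' @param stride_length Displacement over one cycle, metres (\eqn{\ge 0}).
#' @param period Cycle duration \eqn{T} in seconds (> 0).
#' @param n_samples Number of samples of the model grid; defaults to
#'   `round(period * sample_rate) + 1`.
#' @param sample_rate Model grid rate in Hz (default 100, a typical motion
#'   capture rate).
#'
#' @return An object of class `reference_model`: a list with elements
#'   `c1`, `c2`, `c3`, `c4` (polynomial coefficients), `period_T` (s),
#'   `model_stride_Px` (m), `n_samples`, `sample_rate` (Hz),
#'   `residual_rms` (m; `NA` for analytic models) and `source`.
#' @examples
#' m <- analytic_reference_model(1.5, 1.0)
#' m$c1; m$c2                      # -3, 4.5
#' model_director_coefficient(m)   # -18
#' @seealso [fit_reference_polynomial()], [model_kinematics()]
#' @export
analytic_reference_model <- function(stride_length, period,
                                     n_samples = NULL, sample_rate = 100) {
  if (!is_scalar_number(stride_length) || stride_length < 0) {
    stop_is("invalid_parameter", "`stride_length` must be a finite number >= 0")
  }
  if (!is_scalar_number(period) || period <= 0) {
    stop_is("invalid_parameter", "`period` must be a finite number > 0")
  }
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop_is("invalid_parameter", "`sample_rate` must be > 0")
  }
  n_samples <- n_samples %||% (round(period * sample_rate) + 1)
  if (!is_scalar_number(n_samples) || n_samples < 4) {
    stop_is("invalid_parameter", "`n_samples` must be >= 4")
  }
  new_reference_model(
    c1 = -2 * stride_length / period^3,
    c2 = 3 * stride_length / period^2,
    c3 = 0, c4 = 0,
    period_T = period,
    n_samples = as.integer(n_samples),
    sample_rate = sample_rate,
    residual_rms = NA_real_,
    source = "analytic"
  )
}

new_reference_model <- function(c1, c2, c3, c4, period_T, n_samples,
                                sample_rate, residual_rms, source) {
  m <- structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
         period_T = period_T,
         model_stride_Px = c1 * period_T^3 + c2 * period_T^2 +
           c3 * period_T + c4,
         n_samples = n_samples, sample_rate = sample_rate,
         residual_rms = residual_rms, source = source),
    class = "reference_model"
  )
  validate_reference_model(m)
  m
}

validate_reference_model <- function(m) {
  stopifnot(inherits(m, "reference_model"))
  if (m$period_T <= 0) stop_is("invalid_parameter", "period_T must be > 0")
  if (m$n_samples < 4) stop_is("invalid_parameter", "n_samples must be >= 4")
  invisible(m)
}

#' Fit the cubic reference polynomial to a measured trajectory
#'
#' Least-squares cubic fit of AP position over one segmented gait cycle
#' (e.g. from a motion capture reference recording). With
#' `enforce_constraints = TRUE` (the default) the fit is re-based to the
#' cycle start (time and position of the first sample subtracted), `c3` and
#' `c4` are pinned to zero and the terminal zero-velocity condition
#' \eqn{V(T) = 0}, i.e. \eqn{3 c_1 T^2 + 2 c_2 T = 0}, is imposed as an
#' exact linear constraint by variable elimination
#' (\eqn{c_2 = -\tfrac{3}{2} c_1 T}), leaving a one-parameter least-squares
#' problem solved in closed form. Without constraints an ordinary cubic
#' regression is used.
#'
#' @param times Sample times in seconds, strictly increasing, length >= 4.
#' @param positions AP positions in metres, same length as `times`.
#' @param enforce_constraints Apply the boundary conditions exactly
#'   (default `TRUE`).
#' @return A [reference_model][analytic_reference_model] whose
#'   `residual_rms` reports the root-mean-square fit residual in metres.
#' @export
fit_reference_polynomial <- function(times, positions,
                                     enforce_constraints = TRUE) {
  times <- check_numeric_vector(times, "times", min_len = 4L)
  positions <- check_numeric_vector(positions, "positions", min_len = 4L)
  if (length(times) != length(positions)) {
    stop_is("invalid_input", "`times` and `positions` must have equal length")
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop_is("invalid_input", "`times` must be strictly increasing")
  }
  period <- times[length(times)] - times[1]
  sample_rate <- 1 / stats::median(dt)
  if (enforce_constraints) {
    tt <- times - times[1]
    pp <- positions - positions[1]
    # P(t) = c1 t^3 + c2 t^2 with c2 = -1.5 c1 T  =>  P(t) = c1 * b(t)
    b <- tt^3 - 1.5 * period * tt^2
    denom <- sum(b^2)
    c1 <- if (denom > 0) sum(b * pp) / denom else 0
    c2 <- -1.5 * c1 * period
    fitted <- c1 * tt^3 + c2 * tt^2
    rms <- sqrt(mean((pp - fitted)^2))
    new_reference_model(c1, c2, 0, 0, period,
                        n_samples = length(times),
                        sample_rate = sample_rate,
                        residual_rms = rms, source = "fit_constrained")
  } else {
    tt <- times - times[1]
    fit <- stats::lm(positions ~ poly(tt, 3, raw = TRUE))
    cf <- rev(unname(stats::coef(fit)))  # c1, c2, c3, c4
    cf[is.na(cf)] <- 0
    rms <- sqrt(mean(stats::residuals(fit)^2))
    new_reference_model(cf[1], cf[2], cf[3], cf[4], period,
                        n_samples = length(times),
                        sample_rate = sample_rate,
                        residual_rms = rms, source = "fit")
  }
}

#' Evaluate position, velocity and acceleration of a reference model
#'
#' @param model A [reference_model][analytic_reference_model].
#' @param t Times in seconds, all within `[0, period_T]` (tolerance 1e-9).
#' @return A list with numeric vectors `position` (m), `velocity` (m/s)
#'   and `acceleration` (m/s^2), each the length of `t`.
#' @export
model_kinematics <- function(model, t) {
  validate_reference_model(model)
  t <- check_numeric_vector(t, "t")
  tol <- 1e-9 * max(1, model$period_T)
  if (any(t < -tol) || any(t > model$period_T + tol)) {
    stop_is("out_of_range",
            sprintf("`t` must lie within [0, %g]", model$period_T))
  }
  list(
    position = model$c1 * t^3 + model$c2 * t^2 + model$c3 * t + model$c4,
    velocity = 3 * model$c1 * t^2 + 2 * model$c2 * t + model$c3,
    acceleration = 6 * model$c1 * t + 2 * model$c2
  )
}

#' Director coefficient of the reference model
#'
#' The model's AP acceleration is linear in time; its slope, \eqn{6 c_1},
#' is the director coefficient used by the ratio-based stride length
#' estimator. Under the boundary conditions it equals \eqn{-12 L / T^3}.
#'
#' @param model A [reference_model][analytic_reference_model].
#' @param absolute Return the absolute value (default `FALSE`).
#' @return The slope `6 * c1` (per second cubed scale; treated as unitless
#'   in the ratio).
#' @export
model_director_coefficient <- function(model, absolute = FALSE) {
  validate_reference_model(model)
  d <- 6 * model$c1
  if (absolute) abs(d) else d
}

#' Model swing-phase acceleration on a uniform grid
#'
#' Samples the model's linear AP acceleration over the swing portion
#' `[0, swing_fraction * period_T]` of the cycle at `sample_rate`
#' (defaulting to the model's own grid rate). Used to build the reference
#' sequence for slope ratios and dynamic time warping.
#'
#' @inheritParams model_director_coefficient
#' @param swing_fraction Fraction of the cycle taken as swing (default 0.6).
#' @param sample_rate Output grid rate in Hz; default `model$sample_rate`.
#' @return Numeric vector of accelerations (m/s^2); at least 2 samples.
#' @export
model_swing_acceleration <- function(model, swing_fraction = 0.6,
                                     sample_rate = NULL) {
  validate_reference_model(model)
  if (!is_scalar_number(swing_fraction) ||
      swing_fraction <= 0 || swing_fraction >= 1) {
    stop_is("invalid_parameter", "`swing_fraction` must be in (0, 1)")
  }
  sample_rate <- sample_rate %||% model$sample_rate
  t_end <- swing_fraction * model$period_T
  # grid at exactly the sample period over [0, t_end)
  n <- max(2L, as.integer(round(t_end * sample_rate)))
  tt <- (seq_len(n) - 1) / sample_rate
  6 * model$c1 * tt + 2 * model$c2
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model> (", x$source, ")\n", sep = "")
  cat(sprintf("  P(t) = %.6g t^3 + %.6g t^2 + %.6g t + %.6g\n",
              x$c1, x$c2, x$c3, x$c4))
  cat(sprintf("  period T = %g s, stride Px = %.6g m, director 6c1 = %.6g\n",
              x$period_T, x$model_stride_Px, 6 * x$c1))
  if (!is.na(x$residual_rms)) {
    cat(sprintf("  fit residual RMS = %.3g m over %d samples\n",
                x$residual_rms, x$n_samples))
  }
  invisible(x)
}

#' Read a reference trajectory from CSV
#'
#' Expects a two-column CSV with header `time_s,position_m`.
#'
#' @param path CSV file path.
#' @return A data frame with columns `time_s` and `position_m`.
#' @export
read_reference_trajectory <- function(path) {
  if (!file.exists(path)) stop_is("format_error", paste("file not found:", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "position_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_is("format_error",
            paste("reference trajectory is missing columns:",
                  paste(miss, collapse = ", ")))
  }
  df[need]
}

#' Serialize / restore reference-model parameters
#'
#' The model is written as a flat JSON key-value object (`c1..c4`,
#' `period_T`, `model_stride_Px`, `n_samples`, `sample_rate`, `source`).
#'
#' @param model A reference model.
#' @param path Output (or input) file path.
#' @return `write_reference_model()` returns `path` invisibly;
#'   `read_reference_model()` returns a `reference_model`.
#' @export
write_reference_model <- function(model, path) {
  validate_reference_model(model)
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_reference_model(v$c1, v$c2, v$c3, v$c4, v$period_T,
                      as.integer(v$n_samples), v$sample_rate,
                      v$residual_rms %||% NA_real_,
                      v$source %||% "restored")
}
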