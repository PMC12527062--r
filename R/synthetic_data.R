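#' Synthetic gait profile
#'
#' Describes the stylized walk the generator emulates: a six-minute-walk
#' style bout at insole rate (default 40 Hz) with per-stride lengths and
#' cycle durations. Defaults follow the healthy-adult regime of the
#' validation study the package reproduces: stride length 1.591 m (the
#' cohort median), cycle duration 0.9 s (walking speed 1.77 m/s), swing
#' fraction 0.6.
#'
#' @param n_strides Number of complete gait cycles to generate (>= 0).
#' @param stride_lengths Per-stride lengths in metres (recycled to
#'   `n_strides`).
#' @param cycle_durations Per-stride cycle durations in seconds (recycled).
#' @param swing_fraction Swing phase as a fraction of the cycle, in (0, 1).
#' @param sample_rate Hz (default 40, the insole rate).
#' @param noise_sd_accel Gaussian noise sd added to acceleration, m/s^2.
#' @param noise_sd_pressure Gaussian noise sd on pressures, as a fraction
#'   of the pulse amplitude.
#' @param seed Integer seed; the generator uses one private RNG stream.
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(n_strides = 10L, stride_lengths = 1.591,
                         cycle_durations = 0.9, swing_fraction = 0.6,
                         sample_rate = 40, noise_sd_accel = 0,
                         noise_sd_pressure = 0, seed = 1L) {
  if (!is_scalar_number(n_strides) || n_strides < 0 ||
      n_strides != round(n_strides)) {
    stop_is("invalid_parameter", "`n_strides` must be a non-negative integer")
  }
  n_strides <- as.integer(n_strides)
  if (n_strides > 0) {
    stride_lengths <- rep_len(as.numeric(stride_lengths), n_strides)
    cycle_durations <- rep_len(as.numeric(cycle_durations), n_strides)
  } else {
    stride_lengths <- numeric(0)
    cycle_durations <- numeric(0)
  }
  if (any(stride_lengths < 0)) {
    stop_is("invalid_parameter", "stride lengths must be >= 0")
  }
  if (n_strides > 0 && any(cycle_durations <= 0)) {
    stop_is("invalid_parameter", "cycle durations must be > 0")
  }
  if (!is_scalar_number(swing_fraction) || swing_fraction <= 0 ||
      swing_fraction >= 1) {
    stop_is("invalid_parameter", "`swing_fraction` must be in (0, 1)")
  }
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop_is("invalid_parameter", "`sample_rate` must be > 0")
  }
  if (noise_sd_accel < 0 || noise_sd_pressure < 0) {
    stop_is("invalid_parameter", "noise standard deviations must be >= 0")
  }
  structure(list(n_strides = n_strides, stride_lengths = stride_lengths,
                 cycle_durations = cycle_durations,
                 swing_fraction = swing_fraction, sample_rate = sample_rate,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_pressure = noise_sd_pressure,
                 seed = as.integer(seed)),
            class = "gait_profile")
}

new_ground_truth <- function(toe_off_idx, heel_strike_idx,
                             true_stride_lengths, seed) {
  structure(list(toe_off_idx = as.integer(toe_off_idx),
                 heel_strike_idx = as.integer(heel_strike_idx),
                 true_stride_lengths = true_stride_lengths,
                 true_total_distance = sum(true_stride_lengths),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Raised-cosine ramp from 0 to 1 over n samples.
cos_ramp <- function(n) (1 - cos(pi * seq(0, 1, length.out = n))) / 2

#' Generate a synthetic insole recording with ground truth
#'
#' Builds an insole-like multichannel recording from a [gait_profile()].
#' Event times are snapped to the sampling grid first so every ground-truth
#' index is exact. Per stride: the swing-phase AP acceleration is the
#' reference model's linear acceleration for that stride's (L, T); the
#' heel-strike is a short positive acceleration spike (the impact peak the
#' detector looks for); stance acceleration is zero. The great-toe pressure
#' is a raised-cosine-rise plateau pulse that ends exactly at toe-off; the
#' heel pressure pulse starts at heel-strike; metatarsal pulses sit
#' mid-stance. Pulse amplitude is 100 arbitrary units. Gaussian noise is
#' added per the profile; output is deterministic given the profile seed.
#'
#' The recording contains `n_strides + 1` toe-offs (the last one closes the
#' final cycle) and `n_strides` heel-strikes.
#'
#' @param profile A [gait_profile()].
#' @return A list with elements `recording` (a [sensor_recording()]) and
#'   `truth` (class `ground_truth`: `toe_off_idx`, `heel_strike_idx`,
#'   `true_stride_lengths`, `true_total_distance`, `seed`).
#' @export
generate_recording <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  fs <- profile$sample_rate
  sf <- profile$swing_fraction
  N <- profile$n_strides
  amp_p <- 100

  if (N == 0L) {
    rec <- sensor_recording(accel_ap = numeric(0), sample_rate = fs,
                            accel_v = numeric(0), accel_ml = numeric(0),
                            p_heel = numeric(0), p_toe = numeric(0),
                            p_met1 = numeric(0), p_met5 = numeric(0))
    return(list(recording = rec,
                truth = new_ground_truth(integer(0), integer(0),
                                         numeric(0), profile$seed)))
  }

  n_cyc <- pmax(4L, as.integer(round(profile$cycle_durations * fs)))
  durations <- n_cyc / fs           # grid-snapped cycle durations
  lead <- as.integer(round(0.5 * fs))
  tail_n <- as.integer(round(0.5 * fs))
  to_idx <- lead + 1L + c(0L, cumsum(n_cyc))        # N + 1 toe-offs
  hs_off <- pmax(2L, as.integer(round(sf * n_cyc)))
  hs_idx <- to_idx[seq_len(N)] + hs_off
  n_total <- to_idx[N + 1L] + tail_n

  accel <- numeric(n_total)
  p_toe <- numeric(n_total)
  p_heel <- numeric(n_total)
  p_met1 <- numeric(n_total)
  p_met5 <- numeric(n_total)

  for (k in seq_len(N)) {
    L <- profile$stride_lengths[k]
    Tk <- durations[k]
    c1 <- -2 * L / Tk^3
    c2 <- 3 * L / Tk^2
    swing <- to_idx[k]:(hs_idx[k] - 1L)
    tau <- (swing - to_idx[k]) / fs
    accel[swing] <- 6 * c1 * tau + 2 * c2
    # heel-strike impact spike: dominates the window and is a local max
    spike <- if (L > 0) 1.6 * (6 * L / Tk^2) else 1
    accel[hs_idx[k]] <- spike
    if (hs_idx[k] + 1L <= n_total) accel[hs_idx[k] + 1L] <- spike / 2
    # heel pressure pulse starting at heel-strike
    w_h <- max(3L, as.integer(round(0.3 * n_cyc[k])))
    hseg <- hs_idx[k]:min(n_total, hs_idx[k] + w_h - 1L)
    p_heel[hseg] <- p_heel[hseg] +
      amp_p * sin(pi * seq(0, 1, length.out = length(hseg)))
    # metatarsal pulses mid-stance
    mid <- as.integer(round((hs_idx[k] + to_idx[k + 1L]) / 2))
    w_m <- max(3L, as.integer(round(0.2 * n_cyc[k])))
    mseg <- max(1L, mid - w_m %/% 2):min(n_total, mid + w_m %/% 2)
    bump <- 60 * sin(pi * seq(0, 1, length.out = length(mseg)))
    p_met1[mseg] <- p_met1[mseg] + bump
    p_met5[mseg] <- p_met5[mseg] + 0.8 * bump
  }

  # great-toe pressure: rise + plateau pulse occupying [to - w, to), so the
  # first sample below half-maximum after the plateau is the toe-off itself
  for (k in seq_len(N + 1L)) {
    Tk_n <- n_cyc[min(k, N)]
    w <- max(4L, as.integer(round(0.35 * Tk_n)))
    w <- min(w, to_idx[k] - 1L)
    seg <- (to_idx[k] - w):(to_idx[k] - 1L)
    r <- max(2L, as.integer(round(0.6 * w)))
    pulse <- c(amp_p * cos_ramp(r), rep(amp_p, w - r))
    p_toe[seg] <- pmax(p_toe[seg], pulse)
  }

  with_seed(profile$seed, {
    if (profile$noise_sd_accel > 0) {
      accel <- accel + stats::rnorm(n_total, 0, profile$noise_sd_accel)
    }
    accel_v <- stats::rnorm(n_total, 0, profile$noise_sd_accel)
    accel_ml <- stats::rnorm(n_total, 0, profile$noise_sd_accel)
    if (profile$noise_sd_pressure > 0) {
      sdp <- profile$noise_sd_pressure * amp_p
      p_toe <- pmax(0, p_toe + stats::rnorm(n_total, 0, sdp))
      p_heel <- pmax(0, p_heel + stats::rnorm(n_total, 0, sdp))
      p_met1 <- pmax(0, p_met1 + stats::rnorm(n_total, 0, sdp))
      p_met5 <- pmax(0, p_met5 + stats::rnorm(n_total, 0, sdp))
    }
  })

  rec <- sensor_recording(accel_ap = accel, sample_rate = fs,
                          accel_v = accel_v, accel_ml = accel_ml,
                          p_heel = p_heel, p_toe = p_toe,
                          p_met1 = p_met1, p_met5 = p_met5)
  list(recording = rec,
       truth = new_ground_truth(to_idx, hs_idx, profile$stride_lengths,
                                profile$seed))
}

#' Generate a synthetic motion-capture reference trajectory
#'
#' Emulates a 100 Hz capture of a short reference walk (default: six cycles
#' of 0.5 m, the 3 m calibration walk regime). Per cycle the AP
#' displacement follows the boundary-constrained cubic over the swing
#' window `[0, swing_fraction * period]` and then holds constant (stance
#' plateau); displacement accumulates across cycles. The vertical channel
#' is a smooth arch with its unique per-cycle minimum exactly at toe-off.
#' A short stationary tail is appended so the last toe-off search window is
#' complete. Ground-truth toe-offs are the cycle starts; ground-truth
#' heel-strikes are the plateau onsets (swing ends).
#'
#' @param stride_length Metres per cycle (default 0.5).
#' @param period Cycle duration, seconds (default 0.7; keep below the
#'   0.8 s toe-off search upper lag of [detect_mocap_events()]).
#' @param n_cycles Number of cycles (default 6).
#' @param noise_sd Gaussian displacement noise sd in metres (default 0).
#' @param sample_rate Hz (default 100).
#' @param seed Integer seed.
#' @param swing_fraction Swing fraction of the cycle (default 0.6).
#' @return A list with `times`, `displacement_ap`, `displacement_v`
#'   (numeric vectors) and `truth` (class `ground_truth`).
#' @export
generate_mocap_trajectory <- function(stride_length = 0.5, period = 0.7,
                                      n_cycles = 6L, noise_sd = 0,
                                      sample_rate = 100, seed = 1L,
                                      swing_fraction = 0.6) {
  if (!is_scalar_number(stride_length) || stride_length <= 0 ||
      !is_scalar_number(period) || period <= 0 ||
      !is_scalar_number(n_cycles) || n_cycles < 1 ||
      !is_scalar_number(sample_rate) || sample_rate <= 0 || noise_sd < 0) {
    stop_is("invalid_parameter",
            "stride_length, period, n_cycles and sample_rate must be positive; noise_sd >= 0")
  }
  n_cycles <- as.integer(n_cycles)
  fs <- sample_rate
  n_cyc <- max(4L, as.integer(round(period * fs)))
  period <- n_cyc / fs
  sw_n <- max(2L, as.integer(round(swing_fraction * n_cyc)))
  t_sw <- sw_n / fs
  tail_n <- as.integer(round(max(0.2, 0.85 - period) * fs))
  n_total <- n_cycles * n_cyc + 1L + tail_n

  ap <- numeric(n_total)
  vv <- numeric(n_total)
  c1 <- -2 * stride_length / t_sw^3
  c2 <- 3 * stride_length / t_sw^2
  amp_v <- 0.05

  to_idx <- 1L + (0:n_cycles) * n_cyc
  hs_idx <- to_idx[seq_len(n_cycles)] + sw_n
  for (k in seq_len(n_cycles)) {
    seg <- to_idx[k]:(to_idx[k + 1L] - 1L)
    tau <- (seg - to_idx[k]) / fs
    offset <- (k - 1) * stride_length
    ap[seg] <- offset + ifelse(tau < t_sw,
                               c1 * tau^3 + c2 * tau^2,
                               stride_length)
    vv[seg] <- amp_v * (1 - cos(2 * pi * tau / period)) / 2
  }
  ap[(n_cycles * n_cyc + 1L):n_total] <- n_cycles * stride_length
  vv[(n_cycles * n_cyc + 1L):n_total] <- 0

  if (noise_sd > 0) {
    with_seed(seed, {
      ap <- ap + stats::rnorm(n_total, 0, noise_sd)
      vv <- vv + stats::rnorm(n_total, 0, noise_sd)
    })
  }
  list(times = (seq_len(n_total) - 1) / fs,
       displacement_ap = ap, displacement_v = vv,
       truth = new_ground_truth(to_idx, hs_idx,
                                rep(stride_length, n_cycles), seed))
}

#' Write a recording and its ground truth to CSV
#'
#' The recording uses the standard reader schema
#' (`time_s,ax,ay,az,p_heel,p_toe,p_met1,p_met5`); the truth sidecar has
#' columns `event_type,sample_idx` plus per-stride rows
#' `stride,stride_length_m`.
#'
#' @param recording A [sensor_recording()].
#' @param truth A `ground_truth` object (or `NULL` to skip the sidecar).
#' @param path Recording CSV path.
#' @param truth_path Sidecar path; default `paste0(path, ".truth.csv")`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, truth = NULL, path,
                            truth_path = paste0(path, ".truth.csv")) {
  stopifnot(inherits(recording, "sensor_recording"))
  n <- length(recording$t)
  zero <- rep(0, n)
  df <- data.frame(time_s = recording$t,
                   ax = recording$accel_ap,
                   ay = recording$accel_v %||% zero,
                   az = recording$accel_ml %||% zero,
                   p_heel = recording$p_heel %||% zero,
                   p_toe = recording$p_toe %||% zero,
                   p_met1 = recording$p_met1 %||% zero,
                   p_met5 = recording$p_met5 %||% zero)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    tdf <- rbind(
      data.frame(record = "toe_off", index = truth$toe_off_idx,
                 value = NA_real_),
      data.frame(record = "heel_strike", index = truth$heel_strike_idx,
                 value = NA_real_),
      data.frame(record = "stride_length",
                 index = seq_along(truth$true_stride_lengths),
                 value = truth$true_stride_lengths),
      data.frame(record = "total_distance", index = 1L,
                 value = truth$true_total_distance)
    )
    utils::write.csv(tdf, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_recording()]
#'
#' @param path Sidecar CSV path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path)
  new_ground_truth(
    df$index[df$record == "toe_off"],
    df$index[df$record == "heel_strike"],
    df$value[df$record == "stride_length"],
    seed = NA_integer_
  )
}
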