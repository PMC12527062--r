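#' Multichannel smart-insole recording
#'
#' Container for a uniform-rate insole recording: antero-posterior (AP)
#' acceleration plus optional vertical / medio-lateral acceleration and four
#' plantar pressure channels (heel, great toe, first and fifth metatarsal).
#' Time must be uniform to within 1e-6 s jitter and pressures non-negative.
#' Sample indices are 1-based throughout the package.
#'
#' @param accel_ap AP acceleration, m/s^2.
#' @param sample_rate Sampling rate, Hz (> 0).
#' @param t Sample times in seconds; defaults to `(0:(n-1))/sample_rate`.
#' @param accel_v,accel_ml Optional vertical / medio-lateral acceleration.
#' @param p_heel,p_toe,p_met1,p_met5 Optional pressure channels
#'   (sensor units, >= 0).
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(accel_ap, sample_rate, t = NULL,
                             accel_v = NULL, accel_ml = NULL,
                             p_heel = NULL, p_toe = NULL,
                             p_met1 = NULL, p_met5 = NULL) {
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop_is("invalid_parameter", "`sample_rate` must be > 0")
  }
  accel_ap <- as.numeric(accel_ap)
  n <- length(accel_ap)
  t <- if (is.null(t)) seq(0, length.out = n, by = 1 / sample_rate)
       else as.numeric(t)
  channels <- list(accel_v = accel_v, accel_ml = accel_ml,
                   p_heel = p_heel, p_toe = p_toe,
                   p_met1 = p_met1, p_met5 = p_met5)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.null(ch)) {
      if (length(ch) != n) {
        stop_is("invalid_input",
                sprintf("channel `%s` length %d != %d", nm, length(ch), n))
      }
      if (startsWith(nm, "p_") && any(ch < 0)) {
        stop_is("invalid_input", sprintf("pressure channel `%s` has negative values", nm))
      }
      channels[[nm]] <- as.numeric(ch)
    }
  }
  if (length(t) != n) stop_is("invalid_input", "`t` length mismatch")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop_is("invalid_input", "time must be strictly increasing")
    if (max(abs(dt - 1 / sample_rate)) > 1e-6) {
      stop_is("invalid_input", "time grid is not uniform at `sample_rate` (jitter > 1e-6 s)")
    }
  }
  structure(c(list(sample_rate = sample_rate, t = t, accel_ap = accel_ap),
              channels),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  present <- names(x)[!vapply(x, is.null, logical(1))]
  present <- setdiff(present, c("sample_rate", "t"))
  cat(sprintf("<sensor_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$sample_rate,
              if (length(x$t)) length(x$t) / x$sample_rate else 0))
  cat("  channels:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

#' Gait event set
#'
#' Validated pair of strictly increasing toe-off and heel-strike sample
#' indices (1-based); each heel-strike must lie strictly between the
#' consecutive toe-offs it is assigned to.
#'
#' @param toe_off_idx,heel_strike_idx Integer sample indices.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(toe_off_idx, heel_strike_idx = integer(0)) {
  to <- as.integer(toe_off_idx)
  hs <- as.integer(heel_strike_idx)
  if (is.unsorted(to, strictly = TRUE)) {
    stop_is("invalid_input", "toe-off indices must be strictly increasing")
  }
  if (is.unsorted(hs, strictly = TRUE)) {
    stop_is("invalid_input", "heel-strike indices must be strictly increasing")
  }
  structure(list(toe_off_idx = to, heel_strike_idx = hs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d toe-offs, %d heel-strikes\n",
              length(x$toe_off_idx), length(x$heel_strike_idx)))
  invisible(x)
}

#' Detect toe-off events from great-toe pressure
#'
#' Peaks of the great-toe pressure channel are found with a minimum
#' separation and a prominence threshold expressed as a fraction of the
#' channel range; each toe-off is then placed at the first sample after the
#' peak where pressure drops below `drop_frac` of the peak value ("the end
#' of the maximum pressure under the toe").
#'
#' @param recording A [sensor_recording()] with a `p_toe` channel.
#' @param min_separation Minimum peak separation in seconds (default 0.4,
#'   comfortably below one stride at the fastest walking speeds).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   channel range (default 0.2).
#' @param drop_frac Fraction of the peak amplitude defining the end of the
#'   pressure maximum (default 0.5).
#' @return Sorted integer sample indices (possibly empty; a flat channel
#'   yields an empty result with a warning).
#' @export
detect_toe_offs <- function(recording, min_separation = 0.4,
                            prominence_frac = 0.2, drop_frac = 0.5) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (is.null(recording$p_toe)) {
    stop_is("channel_error", "recording has no `p_toe` channel")
  }
  if (!is_scalar_number(min_separation) || min_separation <= 0) {
    stop_is("invalid_parameter", "`min_separation` must be > 0")
  }
  p <- recording$p_toe
  rng <- diff(range(p))
  if (length(p) == 0 || rng <= 0) {
    warn_is("flat_channel", "great-toe pressure is flat; no toe-offs detected")
    return(integer(0))
  }
  peaks <- find_peaks(p,
                      min_separation = max(1L, round(min_separation * recording$sample_rate)),
                      min_prominence = prominence_frac * rng)
  events <- vapply(peaks, function(pk) {
    thr <- drop_frac * p[pk]
    after <- which(p[(pk + 1L):length(p)] < thr)
    if (length(after)) pk + after[1L] else NA_integer_
  }, integer(1))
  sort(unique(events[!is.na(events)]))
}

#' Detect heel-strike events from AP acceleration
#'
#' Within each window between two adjacent toe-offs, the heel-strike is the
#' sample of maximum AP acceleration that is also a local maximum (the
#' impact peak). Windows with no local maximum (e.g. monotone acceleration)
#' are skipped with a warning.
#'
#' @param recording A [sensor_recording()].
#' @param toe_offs At least two toe-off sample indices.
#' @return Integer heel-strike sample indices, one per resolvable window.
#' @export
detect_heel_strikes <- function(recording, toe_offs) {
  stopifnot(inherits(recording, "sensor_recording"))
  toe_offs <- as.integer(toe_offs)
  if (length(toe_offs) < 2L) {
    stop_is("invalid_input", "need at least two toe-offs to form a window")
  }
  a <- recording$accel_ap
  out <- integer(0)
  skipped <- 0L
  for (k in seq_len(length(toe_offs) - 1L)) {
    lo <- toe_offs[k]
    hi <- toe_offs[k + 1L]
    # local maxima computed on the open window (lo, hi)
    seg <- a[lo:hi]
    lm <- local_maxima(seg)
    lm <- lm[lm > 1L & lm < length(seg)]
    if (!length(lm)) { skipped <- skipped + 1L; next }
    best <- lm[which.max(seg[lm])]
    out <- c(out, lo + best - 1L)
  }
  if (skipped > 0L) {
    warn_is("window_skipped",
            sprintf("%d toe-off window(s) had no acceleration local maximum and were skipped",
                    skipped))
  }
  out
}

#' Segment a recording into gait cycles
#'
#' One cycle per adjacent toe-off pair that contains a heel-strike; windows
#' are half-open `[toe_off, next_toe_off)` and the swing acceleration is the
#' AP acceleration over `[toe_off, heel_strike)` so the heel-strike impact
#' sample itself is excluded from the swing fit. Pairs without a
#' heel-strike are dropped.
#'
#' @param recording A [sensor_recording()].
#' @param events A [gait_events()] (empty events give an empty result).
#' @return An object of class `gait_cycles`: a list of cycles, each with
#'   `start_idx`, `end_idx`, `heel_strike_idx`, `swing_accel`, `duration`
#'   (s) and `sample_rate`.
#' @export
segment_cycles <- function(recording, events) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(events, "gait_events"))
  to <- events$toe_off_idx
  hs <- events$heel_strike_idx
  cycles <- list()
  if (length(to) >= 2L) {
    for (k in seq_len(length(to) - 1L)) {
      inside <- hs[hs > to[k] & hs < to[k + 1L]]
      if (!length(inside)) next
      h <- inside[1L]
      swing <- recording$accel_ap[to[k]:(h - 1L)]
      cycles[[length(cycles) + 1L]] <- structure(
        list(start_idx = to[k], end_idx = to[k + 1L], heel_strike_idx = h,
             swing_accel = swing,
             duration = (to[k + 1L] - to[k]) / recording$sample_rate,
             sample_rate = recording$sample_rate),
        class = "gait_cycle")
    }
  }
  structure(cycles, class = "gait_cycles",
            sample_rate = recording$sample_rate)
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf("<gait_cycles> %d cycle(s)", length(x)))
  if (length(x)) {
    cat(sprintf(", durations %.3f-%.3f s",
                min(vapply(x, `[[`, numeric(1), "duration")),
                max(vapply(x, `[[`, numeric(1), "duration"))))
  }
  cat("\n")
  invisible(x)
}

#' Detect gait events on a motion-capture reference trajectory
#'
#' Toe-offs are minima of the vertical displacement searched cycle by cycle
#' in a lag window after the previous toe-off (first event: global minimum
#' within `[0, max_lag]`); ties resolve to the earliest sample.
#' Heel-strikes are the onset of the per-cycle AP-displacement plateau: the
#' first sample after the cycle's velocity maximum whose AP derivative stays
#' below `plateau_thresh` for at least `plateau_run` consecutive samples.
#'
#' @param times Sample times, seconds, uniform.
#' @param displacement_v Vertical displacement, metres.
#' @param displacement_ap AP displacement, metres.
#' @param min_lag,max_lag Toe-off search window after the previous toe-off,
#'   seconds (defaults 0.1 and 0.8).
#' @param plateau_thresh AP plateau derivative threshold, m/s (default 0.02).
#' @param plateau_run Required consecutive below-threshold samples (default 3).
#' @return A [gait_events()] object.
#' @export
detect_mocap_events <- function(times, displacement_v, displacement_ap,
                                min_lag = 0.1, max_lag = 0.8,
                                plateau_thresh = 0.02, plateau_run = 3L) {
  times <- check_numeric_vector(times, "times", 2L)
  displacement_v <- check_numeric_vector(displacement_v, "displacement_v", 2L)
  displacement_ap <- check_numeric_vector(displacement_ap, "displacement_ap", 2L)
  n <- length(times)
  if (length(displacement_v) != n || length(displacement_ap) != n) {
    stop_is("invalid_input", "displacement channels must match `times` length")
  }
  fs <- 1 / stats::median(diff(times))
  t0 <- times[1]

  # --- toe-offs: iterative windowed vertical minima ---
  to <- integer(0)
  win <- which(times - t0 <= max_lag)
  if (length(win)) {
    to <- which.min(displacement_v[win]) + win[1L] - 1L
    repeat {
      prev_t <- times[to[length(to)]]
      win <- which(times > prev_t + min_lag & times <= prev_t + max_lag)
      if (!length(win) || max(times) < prev_t + max_lag) break
      to <- c(to, win[which.min(displacement_v[win])])
    }
  }

  # --- heel-strikes: AP plateau onset per cycle ---
  hs <- integer(0)
  vel <- c(diff(displacement_ap) * fs, 0)
  if (length(to) >= 2L) {
    for (k in seq_len(length(to) - 1L)) {
      lo <- to[k]; hi <- to[k + 1L] - 1L
      seg <- lo:hi
      mid <- seg[which.max(abs(vel[seg]))]
      cand <- seg[seg > mid]
      flat <- abs(vel[cand]) < plateau_thresh
      onset <- NA_integer_
      run <- 0L
      for (i in seq_along(cand)) {
        run <- if (flat[i]) run + 1L else 0L
        if (run >= plateau_run) { onset <- cand[i - run + 1L]; break }
      }
      if (!is.na(onset)) hs <- c(hs, onset)
    }
    if (length(hs) < length(to) - 1L) {
      warn_is("no_plateau",
              "some cycles had no anterior-posterior displacement plateau; heel-strikes skipped")
    }
  }
  gait_events(to, hs)
}

#' Export detected events as CSV
#'
#' Writes rows `event_type,sample_idx,time_s` (indices 1-based).
#'
#' @param events A [gait_events()].
#' @param sample_rate Sampling rate used to convert indices to seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, sample_rate, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- rbind(
    data.frame(event_type = rep("toe_off", length(events$toe_off_idx)),
               sample_idx = events$toe_off_idx),
    data.frame(event_type = rep("heel_strike", length(events$heel_strike_idx)),
               sample_idx = events$heel_strike_idx)
  )
  df <- df[order(df$sample_idx), ]
  df$time_s <- (df$sample_idx - 1) / sample_rate
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
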