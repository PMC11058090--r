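# Touchdown/lift-off detection from foot acceleration and temporal gait
# parameters (stance/swing time, cadence, duty factor, CV).

#' Construct a set of gait events
#'
#' Touchdown and lift-off times must interleave strictly:
#' `td_i < lo_i < td_{i+1}`, one lift-off per complete cycle. A trailing
#' touchdown without a successor carries no lift-off.
#'
#' @param touchdowns Ascending touchdown times in seconds.
#' @param liftoffs Ascending lift-off times in seconds; length must be
#'   `length(touchdowns) - 1` (complete cycles only) or equal if the last
#'   cycle's lift-off was observed before a final touchdown.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(touchdowns, liftoffs) {
  touchdowns <- as.numeric(touchdowns)
  liftoffs <- as.numeric(liftoffs)
  if (is.unsorted(touchdowns, strictly = TRUE) ||
      is.unsorted(liftoffs, strictly = TRUE)) {
    stop("event times must be strictly ascending", call. = FALSE)
  }
  n_lo <- length(liftoffs)
  if (n_lo > length(touchdowns)) {
    stop("more lift-offs than touchdowns", call. = FALSE)
  }
  for (i in seq_len(n_lo)) {
    ok <- liftoffs[i] > touchdowns[i] &&
      (i + 1L > length(touchdowns) || liftoffs[i] < touchdowns[i + 1L])
    if (!ok) {
      stop(sprintf("events not interleaved at cycle %d (td=%.4f, lo=%.4f)",
                   i, touchdowns[i], liftoffs[i]), call. = FALSE)
    }
  }
  structure(list(touchdowns = touchdowns, liftoffs = liftoffs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d touchdowns, %d lift-offs\n",
              length(x$touchdowns), length(x$liftoffs)))
  invisible(x)
}

# 4th-order Butterworth zero-phase low-pass at 15 Hz, the standard
# conditioning for foot-mounted accelerometry before event detection.
filter_accel <- function(x, fs, cutoff = 15) {
  if (cutoff >= fs / 2) {
    stop(sprintf("accelerometer low-pass cutoff %g Hz is not below Nyquist (fs = %g Hz)",
                 cutoff, fs), call. = FALSE)
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  # remove the mean before forward-backward filtering to avoid step-response
  # transients at the trace edges, then restore it
  mu <- mean(x)
  as.numeric(signal::filtfilt(bf, x - mu)) + mu
}

# Local-minima candidates of the filtered vertical acceleration, at least
# `min_separation` seconds apart (deepest kept on conflict). Returns integer
# sample indices; empty on (near-)flat traces.
find_cycle_minima <- function(v, fs, min_separation = 0.6) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  rng <- max(v) - min(v)
  if (rng < 1e-8) return(integer(0))
  is_min <- which(v[2:(n - 1L)] <= v[1:(n - 2L)] &
                  v[2:(n - 1L)] <= v[3:n]) + 1L
  depth_ok <- v[is_min] <= min(v) + 0.25 * rng
  cand <- is_min[depth_ok]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand])]           # deepest first
  keep <- integer(0)
  min_gap <- round(min_separation * fs)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect touchdowns from foot acceleration
#'
#' For each gait cycle the minimal vertical acceleration is located, an
#' interval of −150 to +100 ms is built around it, and touchdown is taken as
#' the characteristic maximum of the vertical acceleration within that
#' interval. The trace is conditioned by a 4th-order Butterworth zero-phase
#' 15 Hz low-pass unless `prefiltered = TRUE`.
#'
#' @param trace An [accel_trace()].
#' @param prefiltered Set `TRUE` if the trace is already low-pass filtered.
#' @param min_separation Minimum spacing in seconds between cycle minima
#'   (default 0.6).
#' @return Numeric vector of touchdown times in seconds (empty, with a
#'   warning, when no cycles are detectable).
#' @export
detect_touchdowns <- function(trace, prefiltered = FALSE,
                              min_separation = 0.6) {
  stopifnot(inherits(trace, "accel_trace"))
  v <- if (prefiltered) trace$vertical else filter_accel(trace$vertical, trace$fs)
  minima <- find_cycle_minima(v, trace$fs, min_separation)
  if (!length(minima)) {
    warning("no gait cycles detectable in vertical acceleration")
    return(numeric(0))
  }
  fs <- trace$fs
  n <- length(v)
  tds <- vapply(minima, function(i) {
    lo <- max(1L, i + as.integer(round(-0.150 * fs)))
    hi <- min(n, i + as.integer(round(0.100 * fs)))
    win <- lo:hi
    (win[which.max(v[win])] - 1L) / fs
  }, numeric(1))
  sort(unique(tds))
}

#' Detect lift-offs from foot acceleration
#'
#' For each consecutive touchdown pair an interval is built from 300 ms after
#' the touchdown until 200 ms before the subsequent touchdown; lift-off is
#' the minimum of the anteroposterior acceleration within that interval. A
#' fixed correction (default +3 ms, the detector's validated average
#' deviation from force-plate lift-off) is added to each detected event.
#'
#' @param trace An [accel_trace()].
#' @param touchdowns Ascending touchdown times in seconds (>= 2).
#' @param prefiltered Set `TRUE` if the trace is already low-pass filtered.
#' @param correction Additive correction in seconds (default 0.003; set 0 for
#'   the uncorrected detector).
#' @return Numeric vector of lift-off times, one per complete cycle; cycles
#'   too short to hold the search window are skipped with a warning.
#' @export
detect_liftoffs <- function(trace, touchdowns, prefiltered = FALSE,
                            correction = 0.003) {
  stopifnot(inherits(trace, "accel_trace"))
  if (length(touchdowns) < 2L) {
    stop("at least 2 touchdowns are required", call. = FALSE)
  }
  ap <- if (prefiltered) trace$anteroposterior else
    filter_accel(trace$anteroposterior, trace$fs)
  fs <- trace$fs
  n <- length(ap)
  out <- numeric(0)
  for (i in seq_len(length(touchdowns) - 1L)) {
    t_lo <- touchdowns[i] + 0.300
    t_hi <- touchdowns[i + 1L] - 0.200
    i_lo <- max(1L, as.integer(ceiling(t_lo * fs)) + 1L)
    i_hi <- min(n, as.integer(floor(t_hi * fs)) + 1L)
    if (i_hi < i_lo) {
      warning(sprintf("cycle %d shorter than the lift-off search window; skipped", i))
      next
    }
    win <- i_lo:i_hi
    out <- c(out, (win[which.min(ap[win])] - 1L) / fs + correction)
  }
  out
}

#' Detect all gait events from an accelerometer trace
#'
#' Convenience wrapper running [detect_touchdowns()] then [detect_liftoffs()]
#' and assembling a validated [gait_events()] object.
#'
#' @inheritParams detect_liftoffs
#' @inheritParams detect_touchdowns
#' @return A `gait_events` object.
#' @export
detect_gait_events <- function(trace, prefiltered = FALSE,
                               min_separation = 0.6, correction = 0.003) {
  tds <- detect_touchdowns(trace, prefiltered, min_separation)
  los <- detect_liftoffs(trace, tds, prefiltered, correction)
  gait_events(tds, los)
}

#' Temporal gait parameters per cycle
#'
#' For each complete cycle computes stance time `t_st = lo − td`, swing time
#' `t_sw = td_next − lo`, cadence in steps per minute (two steps per gait
#' cycle: `2 * 60 / (t_st + t_sw)`) and the duty factor, the fraction of the
#' cycle the foot spends on the ground: `t_st / (t_st + t_sw)`.
#'
#' @param events A [gait_events()] object.
#' @return Data frame with columns `cycle`, `t_st`, `t_sw`, `cadence`,
#'   `duty_factor`.
#' @export
temporal_parameters <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  n <- min(length(events$liftoffs), length(events$touchdowns) - 1L)
  if (n < 1L) stop("no complete cycles in `events`", call. = FALSE)
  td <- events$touchdowns
  lo <- events$liftoffs
  t_st <- lo[seq_len(n)] - td[seq_len(n)]
  t_sw <- td[seq_len(n) + 1L] - lo[seq_len(n)]
  data.frame(cycle = seq_len(n),
             t_st = t_st,
             t_sw = t_sw,
             cadence = 2 * 60 / (t_st + t_sw),
             duty_factor = t_st / (t_st + t_sw))
}

#' Coefficient of variation
#'
#' The quotient of the (sample) standard deviation to the mean of a group of
#' values; dimensionless and invariant to positive rescaling.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @return `sd(values) / mean(values)`.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) {
    stop("coefficient of variation undefined for zero mean", call. = FALSE)
  }
  stats::sd(values) / m
}
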