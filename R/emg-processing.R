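# EMG conditioning: zero-phase Butterworth filtering, full-wave
# rectification, amplitude normalization and 200-point time normalization.

# 4th-order Butterworth designed once, applied forward-backward (zero-phase).
zero_phase_butter <- function(x, fs, cutoff, type) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = type)
  as.numeric(signal::filtfilt(bf, x))
}

#' Condition raw EMG into non-negative envelopes
#'
#' Applies the standard surface-EMG envelope chain to every channel: a
#' 4th-order IIR Butterworth zero-phase high-pass at 50 Hz, full-wave
#' rectification, then a 4th-order IIR Butterworth zero-phase low-pass at
#' 20 Hz. Zero-phase (forward-backward) filtering introduces no lag, so a
#' temporally symmetric burst keeps its peak sample. Small negative
#' undershoots of the final low-pass are clipped to zero.
#'
#' @param trial An [emg_trial()]. Sampling rate must exceed twice the
#'   high-pass cutoff.
#' @param highpass High-pass cutoff in Hz (default 50).
#' @param lowpass Envelope low-pass cutoff in Hz (default 20).
#' @return An `emg_trial` of non-negative envelopes, same shape and metadata.
#' @export
preprocess_emg <- function(trial, highpass = 50, lowpass = 20) {
  stopifnot(inherits(trial, "emg_trial"))
  if (trial$fs <= 2 * highpass) {
    stop(sprintf(
      "sampling rate %g Hz violates the Nyquist constraint for the %g Hz high-pass (need fs > %g Hz)",
      trial$fs, highpass, 2 * highpass), call. = FALSE)
  }
  env <- t(apply(trial$samples, 1L, function(x) {
    # the high-pass removes DC anyway; subtracting the mean first avoids
    # forward-backward step-response transients at the trace edges
    hp <- zero_phase_butter(x - mean(x), trial$fs, highpass, "high")
    pmax(zero_phase_butter(abs(hp), trial$fs, lowpass, "low"), 0)
  }))
  out <- trial
  out$samples <- env
  rownames(out$samples) <- trial$muscle_labels
  out
}

#' Normalize envelope amplitudes per muscle over a trial
#'
#' For each muscle the minimum over the whole trial (all consecutive gait
#' cycles) is subtracted and the result divided by the trial-wide maximum, so
#' each channel spans `[0, 1]` over the trial. A cycle whose local maximum is
#' below the trial maximum therefore retains a normalized maximum below 1.
#' Invariant to per-muscle affine rescaling `a*x + b` (`a > 0`) of the input.
#'
#' @param trial An [emg_trial()] of envelopes.
#' @return An `emg_trial` with every channel normalized to `[0, 1]`.
#' @export
normalize_amplitude <- function(trial) {
  stopifnot(inherits(trial, "emg_trial"))
  rng <- apply(trial$samples, 1L, range)
  flat <- which(rng[2L, ] - rng[1L, ] < .Machine$double.eps * 100)
  if (length(flat)) {
    stop("constant EMG channel(s), amplitude normalization undefined: ",
         paste(trial$muscle_labels[flat], collapse = ", "), call. = FALSE)
  }
  out <- trial
  out$samples <- (trial$samples - rng[1L, ]) / (rng[2L, ] - rng[1L, ])
  out
}

#' Time-normalize one gait cycle to the fixed 200-point grid
#'
#' Resamples one muscle-by-time envelope segment onto 200 points per cycle,
#' stance and swing each receiving an equal distribution of 100 points
#' regardless of their real durations. Point 1 falls on the touchdown sample
#' and the next touchdown is excluded (half-open cycle). Resampling is
#' piecewise-linear; the stance grid is interpolated from samples in
#' `[td, lo]` and the swing grid from samples in `[lo, td_next]`.
#'
#' @param trial An [emg_trial()] of (normalized) envelopes covering the cycle.
#' @param touchdown,liftoff,next_touchdown Event times in seconds,
#'   `touchdown < liftoff < next_touchdown`.
#' @param cycle_index Index recorded on the output (default 1).
#' @param n_points Total grid size (default 200, split half stance / half
#'   swing).
#' @return A `normalized_cycle`: muscles x `n_points` matrix.
#' @export
time_normalize_cycle <- function(trial, touchdown, liftoff, next_touchdown,
                                 cycle_index = 1L, n_points = 200L) {
  stopifnot(inherits(trial, "emg_trial"))
  if (!(touchdown < liftoff && liftoff < next_touchdown)) {
    stop("events out of order: require touchdown < liftoff < next_touchdown",
         call. = FALSE)
  }
  fs <- trial$fs
  n <- ncol(trial$samples)
  t_all <- (seq_len(n) - 1L) / fs
  if (touchdown < t_all[1L] - 1e-9 || next_touchdown > t_all[n] + 1e-9) {
    stop("trial does not cover the full cycle", call. = FALSE)
  }
  stance_idx <- which(t_all >= touchdown - 1e-12 & t_all <= liftoff + 1e-12)
  swing_idx <- which(t_all >= liftoff - 1e-12 & t_all <= next_touchdown + 1e-12)
  if (length(stance_idx) < 2L || length(swing_idx) < 2L) {
    stop("stance or swing phase covers fewer than 2 samples", call. = FALSE)
  }
  stance_points <- n_points %/% 2L
  grid <- grid_times(touchdown, liftoff, next_touchdown, n_points,
                     stance_points)
  V <- matrix(0, nrow = nrow(trial$samples), ncol = n_points,
              dimnames = list(trial$muscle_labels, NULL))
  s_grid <- seq_len(stance_points)
  for (m in seq_len(nrow(V))) {
    V[m, s_grid] <- stats::approx(t_all[stance_idx],
                                  trial$samples[m, stance_idx],
                                  xout = grid[s_grid], rule = 2)$y
    V[m, -s_grid] <- stats::approx(t_all[swing_idx],
                                   trial$samples[m, swing_idx],
                                   xout = grid[-s_grid], rule = 2)$y
  }
  new_normalized_cycle(V, cycle_index, stance_points)
}

#' Segment a trial into normalized gait cycles
#'
#' Applies [time_normalize_cycle()] to every complete cycle defined by a set
#' of gait events.
#'
#' @param trial An [emg_trial()] of envelopes.
#' @param events A [gait_events()] object.
#' @param n_points Grid size per cycle (default 200).
#' @return List of `normalized_cycle` matrices, one per complete cycle.
#' @export
segment_cycles <- function(trial, events, n_points = 200L) {
  stopifnot(inherits(events, "gait_events"))
  n <- min(length(events$liftoffs), length(events$touchdowns) - 1L)
  if (n < 1L) stop("no complete cycles in `events`", call. = FALSE)
  lapply(seq_len(n), function(i) {
    time_normalize_cycle(trial, events$touchdowns[i], events$liftoffs[i],
                         events$touchdowns[i + 1L], cycle_index = i,
                         n_points = n_points)
  })
}
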