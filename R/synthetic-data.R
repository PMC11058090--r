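# Seeded synthetic-data generator: planted synergy factors, gait-cycle EMG
# matrices, raw EMG/accelerometer traces and 12-cycle perturbation series
# with known ground truth for every downstream stage.

#' Specification for a synthetic perturbed-walking trial
#'
#' Collects every parameter of the synthetic-data generator: the gait-cycle
#' grid, the planted synergy prototypes, the amplitude-noise level, the trial
#' layout (unperturbed, perturbed and recovery cycles) and the planted
#' perturbation response (a circular shift of the activation timing and a
#' multiplicative widening of the activation patterns).
#'
#' The default prototypes are the four fundamental walking synergies: weight
#' acceptance (knee extensors and glutei, centred at 10% of the cycle),
#' propulsion (plantar flexors, 40%), early swing (foot dorsiflexors, 60%)
#' and late swing (knee flexors, 90%). The default trial layout is 12
#' consecutive gait cycles: three unperturbed cycles, the perturbed cycle
#' (index 4) and eight recovery cycles, with the planted perturbation
#' decaying geometrically back to baseline over four recovery cycles.
#'
#' @param n_muscles Number of EMG channels (default 13).
#' @param n_points Points per time-normalized gait cycle (default 200; the
#'   first half is stance, the second half swing).
#' @param prototypes List of prototype descriptions, each a list with fields
#'   `label`, `phase_center` (fraction of the cycle in `[0, 1)`),
#'   `concentration` (dimensionless von Mises-type width parameter, larger =
#'   narrower) and `dominant_muscles` (character vector of muscle codes).
#' @param noise_sd Standard deviation of the additive zero-truncated Gaussian
#'   amplitude noise, in units of the maximum envelope amplitude (default
#'   0.05).
#' @param n_cycles Number of gait cycles in a trial (default 12).
#' @param perturbed_cycle_index Index of the perturbed cycle (default 4:
#'   three unperturbed cycles precede it).
#' @param coa_shift Circular shift, in radians, applied to the prototype
#'   phase centres at the perturbed cycle (default −0.3; negative values move
#'   activity earlier in the cycle).
#' @param widen_factor Multiplicative widening (>= 1) of the prototype
#'   activation width at the perturbed cycle (default 1.5).
#' @param recovery_cycles Number of recovery cycles over which the planted
#'   perturbation decays back to baseline (default 4).
#' @param recovery_decay Geometric decay ratio per recovery cycle for the
#'   planted effects (default 0.5).
#' @param seed Integer seed; every stochastic operation is reproducible given
#'   the spec.
#'
#' @return An object of class `synergy_spec`.
#' @export
synergy_spec <- function(n_muscles = 13L,
                         n_points = 200L,
                         prototypes = default_prototypes(),
                         noise_sd = 0.05,
                         n_cycles = 12L,
                         perturbed_cycle_index = 4L,
                         coa_shift = -0.3,
                         widen_factor = 1.5,
                         recovery_cycles = 4L,
                         recovery_decay = 0.5,
                         seed = 1L) {
  stopifnot_scalar_number(n_muscles, "n_muscles", lower = 1)
  stopifnot_scalar_number(n_points, "n_points", lower = 4)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(n_cycles, "n_cycles", lower = 1)
  stopifnot_scalar_number(perturbed_cycle_index, "perturbed_cycle_index",
                          lower = 1, upper = n_cycles)
  stopifnot_scalar_number(widen_factor, "widen_factor", lower = 1)
  stopifnot_scalar_number(recovery_cycles, "recovery_cycles", lower = 0)
  stopifnot_scalar_number(recovery_decay, "recovery_decay", lower = 0, upper = 1)
  stopifnot_scalar_number(coa_shift, "coa_shift")
  if (!is.list(prototypes) || length(prototypes) < 1L) {
    stop("`prototypes` must be a non-empty list", call. = FALSE)
  }
  labels <- vapply(prototypes, function(p) p$label, character(1))
  if (anyDuplicated(labels)) {
    stop("prototype labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  for (p in prototypes) {
    if (p$phase_center < 0 || p$phase_center >= 1) {
      stop(sprintf("prototype '%s': phase_center must be in [0, 1)", p$label),
           call. = FALSE)
    }
    if (p$concentration <= 0) {
      stop(sprintf("prototype '%s': concentration must be > 0", p$label),
           call. = FALSE)
    }
  }
  structure(
    list(n_muscles = as.integer(n_muscles),
         n_points = as.integer(n_points),
         prototypes = prototypes,
         noise_sd = noise_sd,
         n_cycles = as.integer(n_cycles),
         perturbed_cycle_index = as.integer(perturbed_cycle_index),
         coa_shift = coa_shift,
         widen_factor = widen_factor,
         recovery_cycles = as.integer(recovery_cycles),
         recovery_decay = recovery_decay,
         seed = as.integer(seed)),
    class = "synergy_spec"
  )
}

#' Default fundamental-synergy prototypes
#'
#' Four phase-locked prototypes for the walking synergies: weight acceptance,
#' propulsion, early swing and late swing, with dominant muscles drawn from
#' the standard 13-muscle montage ([muscle_codes()]). Phase centres at 0.10,
#' 0.40, 0.60 and 0.90 of the cycle place the first two in stance and the
#' last two in swing on the 100/100 normalized grid.
#'
#' @return List of four prototype descriptions.
#' @export
default_prototypes <- function() {
  list(
    list(label = "weight_acceptance", phase_center = 0.10, concentration = 6,
         dominant_muscles = c("RF", "VM", "VL", "ME", "MA")),
    list(label = "propulsion", phase_center = 0.40, concentration = 6,
         dominant_muscles = c("PL", "GM", "GL", "SO")),
    list(label = "early_swing", phase_center = 0.60, concentration = 6,
         dominant_muscles = c("TA")),
    list(label = "late_swing", phase_center = 0.90, concentration = 6,
         dominant_muscles = c("ST", "BF"))
  )
}

# Unimodal circular bump on the n-point cycle grid: a von Mises-type kernel
# exp(kappa * (cos(theta - mu) - 1)), which peaks at 1 exactly at mu and
# wraps around the cycle boundary.
circular_bump <- function(n_points, phase_center, concentration) {
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  mu <- 2 * pi * phase_center
  exp(concentration * (cos(theta - mu) - 1))
}

#' Generate ground-truth synergy factors
#'
#' Builds the planted muscle-weight matrix `M_true` (muscles x synergies) and
#' activation-pattern matrix `P_true` (synergies x points) for a spec.
#' Pattern rows are unimodal circular bumps, max-normalized to 1; weight
#' columns give each prototype's dominant muscles weights near 1 and all
#' other muscles small positive weights. `M_true` is scaled once so that the
#' noiseless baseline reconstruction `M_true %*% P_true` has maximum exactly
#' 1, keeping synthetic cycle matrices on the `[0, 1]` scale of normalized
#' EMG envelopes.
#'
#' @param spec A [synergy_spec()].
#' @return A list of class `ground_truth` with elements `M_true`, `P_true`,
#'   `labels` and `spec`.
#' @export
generate_synergy_prototypes <- function(spec) {
  stopifnot(inherits(spec, "synergy_spec"))
  labels <- vapply(spec$prototypes, function(p) p$label, character(1))
  p <- length(labels)
  muscles <- if (spec$n_muscles == 13L) muscle_codes() else
    paste0("m", seq_len(spec$n_muscles))

  P_true <- t(vapply(spec$prototypes, function(pr) {
    circular_bump(spec$n_points, pr$phase_center, pr$concentration)
  }, numeric(spec$n_points)))
  rownames(P_true) <- labels

  M_true <- with_seed(spec$seed, {
    M <- matrix(0, nrow = spec$n_muscles, ncol = p,
                dimnames = list(muscles, labels))
    for (j in seq_len(p)) {
      dom <- spec$prototypes[[j]]$dominant_muscles
      missing <- setdiff(dom, muscles)
      if (length(missing)) {
        stop("unknown dominant muscle code(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      M[, j] <- stats::runif(spec$n_muscles, 0.02, 0.10)
      M[dom, j] <- stats::runif(length(dom), 0.85, 0.95)
    }
    M
  })
  M_true <- M_true / max(M_true %*% P_true)

  structure(list(M_true = M_true, P_true = P_true,
                 labels = labels, spec = spec),
            class = "ground_truth")
}

# Per-cycle multiplier of the planted perturbation: 0 before the perturbed
# cycle, 1 at it, geometric decay across the recovery cycles, 0 afterwards.
perturbation_multiplier <- function(spec, cycle_index) {
  k <- cycle_index - spec$perturbed_cycle_index
  if (k < 0 || k > spec$recovery_cycles) return(0)
  spec$recovery_decay^k
}

# Prototype patterns for one cycle with the planted perturbation applied:
# the phase centre is shifted by coa_shift * mult radians and the
# concentration reduced so the bump width grows by the widening factor.
cycle_patterns <- function(spec, cycle_index) {
  mult <- perturbation_multiplier(spec, cycle_index)
  widen <- 1 + (spec$widen_factor - 1) * mult
  t(vapply(spec$prototypes, function(pr) {
    center <- (pr$phase_center + mult * spec$coa_shift / (2 * pi)) %% 1
    circular_bump(spec$n_points, center, pr$concentration / widen^2)
  }, numeric(spec$n_points)))
}

new_normalized_cycle <- function(V, cycle_index,
                                 stance_points = ncol(V) %/% 2L) {
  structure(V, class = c("normalized_cycle", "matrix", "array"),
            cycle_index = as.integer(cycle_index),
            stance_points = as.integer(stance_points),
            swing_points = as.integer(ncol(V) - stance_points))
}

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf("<normalized_cycle> %d muscles x %d points (cycle %d, %d/%d stance/swing)\n",
              nrow(x), ncol(x), attr(x, "cycle_index"),
              attr(x, "stance_points"), attr(x, "swing_points")))
  invisible(x)
}

#' Synthesize a trial of normalized gait-cycle EMG matrices
#'
#' Generates `n_cycles` muscle-by-time matrices `V = M_true %*% P_cycle` plus
#' zero-truncated Gaussian amplitude noise. Cycles at and after the perturbed
#' cycle use prototypes with the planted timing shift and widening applied,
#' decaying geometrically back to baseline over the recovery cycles. With
#' `noise_sd = 0` and no perturbation (`coa_shift = 0`, `widen_factor = 1`)
#' every cycle equals `M_true %*% P_true` exactly.
#'
#' @param spec A [synergy_spec()].
#' @return A list of class `synthetic_trial` with `cycles` (list of
#'   `normalized_cycle` matrices) and `ground_truth` (the planted factors,
#'   including the per-cycle pattern matrices `P_cycles` and perturbation
#'   multipliers).
#' @export
synthesize_trial <- function(spec) {
  stopifnot(inherits(spec, "synergy_spec"))
  gt <- generate_synergy_prototypes(spec)
  P_cycles <- lapply(seq_len(spec$n_cycles), function(c) cycle_patterns(spec, c))
  mults <- vapply(seq_len(spec$n_cycles), function(c)
    perturbation_multiplier(spec, c), numeric(1))

  cycles <- with_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_cycles), function(c) {
      V <- gt$M_true %*% P_cycles[[c]]
      if (spec$noise_sd > 0) {
        V <- V + matrix(stats::rnorm(length(V), sd = spec$noise_sd),
                        nrow = nrow(V))
        V <- pmin(pmax(V, 0), 1)
      }
      new_normalized_cycle(V, c)
    })
  })

  gt$P_cycles <- P_cycles
  gt$perturbation_multipliers <- mults
  structure(list(cycles = cycles, ground_truth = gt),
            class = "synthetic_trial")
}

new_emg_trial <- function(samples, fs, muscle_labels = rownames(samples),
                          direction = "mediolateral",
                          predictability = "unpredictable",
                          note = "") {
  stopifnot(is.matrix(samples), fs > 0,
            length(muscle_labels) == nrow(samples))
  if (!all(is.finite(samples))) stop("EMG samples must be finite", call. = FALSE)
  rownames(samples) <- muscle_labels
  structure(list(samples = samples, fs = fs, muscle_labels = muscle_labels,
                 direction = direction, predictability = predictability,
                 note = note),
            class = "emg_trial")
}

#' Construct an EMG trial
#'
#' Bundles a muscles-by-time sample matrix with its sampling rate, muscle
#' labels and condition metadata (perturbation direction and predictability).
#'
#' @param samples Numeric matrix, one row per muscle.
#' @param fs Sampling rate in Hz.
#' @param muscle_labels Character vector of muscle codes (defaults to the
#'   matrix rownames).
#' @param direction `"mediolateral"` or `"anteroposterior"`.
#' @param predictability `"predictable"` or `"unpredictable"`.
#' @param note Free-text metadata.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(samples, fs, muscle_labels = rownames(samples),
                      direction = "mediolateral",
                      predictability = "unpredictable",
                      note = "") {
  direction <- match.arg(direction, c("mediolateral", "anteroposterior"))
  predictability <- match.arg(predictability, c("unpredictable", "predictable"))
  new_emg_trial(samples, fs, muscle_labels, direction, predictability, note)
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %d muscles x %d samples @ %g Hz (%s, %s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              x$direction, x$predictability))
  invisible(x)
}

#' Construct a foot-accelerometer trace
#'
#' @param fs Sampling rate in Hz.
#' @param vertical,anteroposterior,mediolateral Equal-length numeric sample
#'   vectors (m s^-2).
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(fs, vertical, anteroposterior,
                        mediolateral = numeric(length(vertical))) {
  stopifnot_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- length(vertical)
  if (length(anteroposterior) != n || length(mediolateral) != n) {
    stop("accelerometer axes must have equal lengths", call. = FALSE)
  }
  structure(list(fs = fs, vertical = vertical,
                 anteroposterior = anteroposterior,
                 mediolateral = mediolateral),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$vertical), x$fs, length(x$vertical) / x$fs))
  invisible(x)
}

# Sample times (s) of the 200-point cycle grid laid into real time: points
# 1..stance_points span [td, lo), the rest [lo, td_next).
grid_times <- function(td, lo, td_next, n_points = 200L,
                       stance_points = n_points %/% 2L) {
  swing_points <- n_points - stance_points
  c(td + (seq_len(stance_points) - 1L) / stance_points * (lo - td),
    lo + (seq_len(swing_points) - 1L) / swing_points * (td_next - lo))
}

#' Synthesize raw EMG and accelerometer signals with known events
#'
#' Renders a synthetic trial back into raw recordings: per-muscle EMG is a
#' band-limited (50 Hz to just under Nyquist) noise carrier
#' amplitude-modulated by the muscle's planted envelope mapped into real
#' time; the accelerometer vertical axis carries a smooth impact transient at
#' each true touchdown preceded by a pronounced swing-end minimum, and the
#' anteroposterior axis a clear minimum at each true lift-off. True event
#' times are returned as the oracle for event-detection tests.
#'
#' @param spec A [synergy_spec()].
#' @param fs_emg EMG sampling rate in Hz (>= 500; default 2000).
#' @param fs_accel Accelerometer sampling rate in Hz (>= 50; default 143).
#' @param t_stance,t_swing Stance and swing durations in seconds per cycle
#'   (defaults 0.65 and 0.40, a typical older-adult cycle at 1.1 m s^-1).
#' @param accel_noise_sd Standard deviation of additive Gaussian noise on the
#'   accelerometer axes (m s^-2; default 0, noise-free).
#' @return A list of class `synthetic_recording` with elements `emg`
#'   ([emg_trial()]), `accel` ([accel_trace()]), `events` (true
#'   [gait_events()]), `envelope` (planted per-muscle envelope at the EMG
#'   rate), and `trial` (the underlying [synthesize_trial()] output).
#' @export
synthesize_raw_signals <- function(spec, fs_emg = 2000, fs_accel = 143,
                                   t_stance = 0.65, t_swing = 0.40,
                                   accel_noise_sd = 0) {
  stopifnot(inherits(spec, "synergy_spec"))
  if (fs_emg < 500) stop("`fs_emg` must be >= 500 Hz", call. = FALSE)
  if (fs_accel < 50) stop("`fs_accel` must be >= 50 Hz", call. = FALSE)
  if (t_stance < 2 / fs_accel || t_swing < 2 / fs_accel) {
    stop("stance/swing durations are not representable at `fs_accel`",
         call. = FALSE)
  }

  trial <- synthesize_trial(spec)
  cycle_T <- t_stance + t_swing
  pad <- 1.0
  touchdowns <- pad + (seq_len(spec$n_cycles + 1L) - 1L) * cycle_T
  liftoffs <- touchdowns[seq_len(spec$n_cycles)] + t_stance
  total <- 2 * pad + (spec$n_cycles) * cycle_T

  # planted envelope: cycle grids concatenated, zero outside the walking bout
  knot_t <- c(pad - 0.05)
  knot_idx <- list()
  for (c in seq_len(spec$n_cycles)) {
    knot_t <- c(knot_t, grid_times(touchdowns[c], liftoffs[c],
                                   touchdowns[c + 1L], spec$n_points))
  }
  knot_t <- c(knot_t, touchdowns[spec$n_cycles + 1L] + 0.05)
  n_emg <- floor(total * fs_emg)
  t_emg <- (seq_len(n_emg) - 1L) / fs_emg

  envelope <- matrix(0, nrow = spec$n_muscles, ncol = n_emg,
                     dimnames = list(rownames(trial$ground_truth$M_true), NULL))
  for (m in seq_len(spec$n_muscles)) {
    vals <- unlist(lapply(trial$cycles, function(V) V[m, ]))
    knot_v <- c(0, vals, 0)
    envelope[m, ] <- stats::approx(knot_t, knot_v, xout = t_emg,
                                   yleft = 0, yright = 0)$y
  }

  ny <- fs_emg / 2
  bp <- signal::butter(4, c(50 / ny, min(500, 0.9 * ny) / ny), type = "pass")
  raw <- with_seed(spec$seed + 2L, {
    out <- matrix(0, nrow = spec$n_muscles, ncol = n_emg)
    for (m in seq_len(spec$n_muscles)) {
      carrier <- signal::filtfilt(bp, stats::rnorm(n_emg))
      carrier <- carrier / stats::sd(carrier)
      out[m, ] <- carrier * envelope[m, ]
    }
    out
  })
  rownames(raw) <- rownames(envelope)
  emg <- emg_trial(raw, fs_emg)

  n_acc <- floor(total * fs_accel)
  t_acc <- (seq_len(n_acc) - 1L) / fs_accel
  gauss <- function(t, mu, sd) exp(-(t - mu)^2 / (2 * sd^2))
  vertical <- numeric(n_acc)
  for (td in touchdowns) {
    vertical <- vertical + 30 * gauss(t_acc, td, 0.02) -
      20 * gauss(t_acc, td - 0.055, 0.02)
  }
  ap <- numeric(n_acc)
  for (lo in liftoffs) ap <- ap - 15 * gauss(t_acc, lo, 0.03)
  if (accel_noise_sd > 0) {
    noise <- with_seed(spec$seed + 3L, {
      matrix(stats::rnorm(2L * n_acc, sd = accel_noise_sd), nrow = 2L)
    })
    vertical <- vertical + noise[1L, ]
    ap <- ap + noise[2L, ]
  }
  accel <- accel_trace(fs_accel, vertical, ap)

  events <- gait_events(touchdowns, liftoffs)
  structure(list(emg = emg, accel = accel, events = events,
                 envelope = envelope, trial = trial,
                 t_stance = t_stance, t_swing = t_swing),
            class = "synthetic_recording")
}
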