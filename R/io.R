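# Delimited-text readers and writers for trials, traces, events, synergy
# sets, metrics tables and the ground-truth sidecar.

#' Write / read an EMG trial as delimited text
#'
#' Tab-separated, first column `time` in seconds, remaining columns headed by
#' the muscle codes in recording order.
#'
#' @param trial An [emg_trial()].
#' @param path Output file.
#' @return `write_emg_trial()` returns `path` invisibly; `read_emg_trial()`
#'   returns an `emg_trial`.
#' @export
write_emg_trial <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  n <- ncol(trial$samples)
  df <- data.frame(time = (seq_len(n) - 1L) / trial$fs,
                   t(trial$samples), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg_trial
#' @param fs Sampling rate; inferred from the time column when `NULL`.
#' @param require_muscles Optional character vector of muscle codes that must
#'   all be present (e.g. [muscle_codes()]); a missing code is an error
#'   naming it.
#' @param ... Metadata passed to [emg_trial()].
#' @export
read_emg_trial <- function(path, fs = NULL, require_muscles = NULL, ...) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing `time` column", call. = FALSE)
  if (!is.null(require_muscles)) {
    absent <- setdiff(require_muscles, names(df))
    if (length(absent)) {
      stop("missing muscle column(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time))
  labels <- setdiff(names(df), "time")
  samples <- t(as.matrix(df[labels]))
  emg_trial(samples, fs = fs, muscle_labels = labels, ...)
}

#' Write / read an accelerometer trace as delimited text
#'
#' Tab-separated columns `time`, `vertical`, `anteroposterior`,
#' `mediolateral`.
#'
#' @param trace An [accel_trace()].
#' @param path Output file.
#' @export
write_accel_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$vertical)
  df <- data.frame(time = (seq_len(n) - 1L) / trace$fs,
                   vertical = trace$vertical,
                   anteroposterior = trace$anteroposterior,
                   mediolateral = trace$mediolateral)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_trace
#' @param fs Sampling rate; inferred from the time column when `NULL`.
#' @export
read_accel_trace <- function(path, fs = NULL) {
  df <- utils::read.delim(path)
  need <- c("time", "vertical", "anteroposterior", "mediolateral")
  if (!all(need %in% names(df))) {
    stop("accelerometer file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time))
  accel_trace(fs, df$vertical, df$anteroposterior, df$mediolateral)
}

#' Write gait events as delimited text
#'
#' Columns `cycle`, `touchdown_s`, `liftoff_s`, one row per complete cycle.
#'
#' @param events A [gait_events()] object.
#' @param path Output file.
#' @export
write_gait_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  n <- min(length(events$liftoffs), length(events$touchdowns))
  df <- data.frame(cycle = seq_len(n),
                   touchdown_s = events$touchdowns[seq_len(n)],
                   liftoff_s = events$liftoffs[seq_len(n)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a synergy set as structured text
#'
#' Header lines (`cycle`, `rank`, `r_squared`, `n_repetitions`, `seed`)
#' followed by the muscle-weight block `M` (muscles x rank) and the
#' activation-pattern block `P` (rank x points); round-trippable.
#'
#' @param set A `synergy_set`.
#' @param path Output file.
#' @export
write_synergy_set <- function(set, path) {
  stopifnot(inherits(set, "synergy_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# synergy_set"),
    sprintf("cycle\t%s", set$cycle_index),
    sprintf("rank\t%d", set$rank),
    sprintf("r_squared\t%.15g", set$r_squared),
    sprintf("n_repetitions\t%d", set$n_repetitions),
    sprintf("seed\t%s", set$seed),
    "# M (muscles x rank)"), con)
  utils::write.table(set$M, con, sep = "\t", col.names = FALSE, quote = FALSE)
  writeLines("# P (rank x points)", con)
  utils::write.table(set$P, con, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synergy_set
#' @export
read_synergy_set <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, "\t"), lines, value = TRUE)[1L]
    strsplit(ln, "\t")[[1L]][2L]
  }
  rank <- as.integer(hdr("rank"))
  m_start <- which(lines == "# M (muscles x rank)") + 1L
  p_start <- which(lines == "# P (rank x points)") + 1L
  m_lines <- lines[m_start:(p_start - 2L)]
  M <- as.matrix(utils::read.table(text = m_lines, sep = "\t",
                                   row.names = 1L))
  colnames(M) <- NULL
  P <- as.matrix(utils::read.table(text = lines[p_start:length(lines)],
                                   sep = "\t"))
  dimnames(P) <- NULL
  cyc <- suppressWarnings(as.integer(hdr("cycle")))
  seed <- suppressWarnings(as.integer(hdr("seed")))
  new_synergy_set(M, P, r_squared = as.numeric(hdr("r_squared")),
                  n_repetitions = as.integer(hdr("n_repetitions")),
                  cycle_index = cyc, seed = seed)
}

#' Write the ground-truth sidecar of a synthetic recording
#'
#' Structured text (YAML) with the true event times and the planted
#' prototype parameters, for test harnesses and audit.
#'
#' @param recording Output of [synthesize_raw_signals()].
#' @param path Output file.
#' @export
write_ground_truth <- function(recording, path) {
  stopifnot(inherits(recording, "synthetic_recording"))
  spec <- recording$trial$ground_truth$spec
  yaml::write_yaml(list(
    touchdowns_s = as.numeric(recording$events$touchdowns),
    liftoffs_s = as.numeric(recording$events$liftoffs),
    prototypes = lapply(spec$prototypes, function(p) {
      list(label = p$label, phase_center = p$phase_center,
           concentration = p$concentration,
           dominant_muscles = as.list(p$dominant_muscles))
    }),
    noise_sd = spec$noise_sd,
    perturbed_cycle_index = spec$perturbed_cycle_index,
    coa_shift = spec$coa_shift,
    widen_factor = spec$widen_factor,
    seed = spec$seed
  ), path)
  invisible(path)
}
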