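#' Experimental protocol specification
#'
#' Bundles the timing constants of a cue-based motor-imagery session: two
#' mental tasks (relax, pedaling imagery) cued in randomized order, separated
#' by a fixation cross, repeated over several trials per session and several
#' daily sessions. Defaults reproduce the study protocol: 5.8 s tasks, 3 s
#' crosses, 10 cues per task per trial, 10 trials per session of which the
#' first 4 train the classifier, 1 s analysis epochs advanced by 200 ms, with
#' the first 2 s of every task discarded, sampled at 500 Hz over 5 days.
#'
#' @param task_duration_s Duration of each Relax/Imagine cue, seconds.
#' @param inter_cue_duration_s Duration of the fixation cross between cues.
#' @param tasks_per_type_per_trial Cues per task type within one trial.
#' @param trials_per_session Trials per daily session.
#' @param training_trials Leading trials used to train the classifier.
#' @param discard_initial_s Lead-in of each task excluded from analysis.
#' @param epoch_length_s Analysis window length, seconds.
#' @param epoch_shift_s Analysis window advance, seconds.
#' @param sampling_rate_hz EEG sampling rate, Hz.
#' @param n_days Number of daily sessions.
#' @return An object of class `protocol_spec` (a validated list).
#' @examples
#' spec <- protocol_spec()
#' epochs_per_task(spec)
#' @export
protocol_spec <- function(task_duration_s = 5.8,
                          inter_cue_duration_s = 3.0,
                          tasks_per_type_per_trial = 10L,
                          trials_per_session = 10L,
                          training_trials = 4L,
                          discard_initial_s = 2.0,
                          epoch_length_s = 1.0,
                          epoch_shift_s = 0.2,
                          sampling_rate_hz = 500,
                          n_days = 5L) {
  spec <- list(
    task_duration_s = task_duration_s,
    inter_cue_duration_s = inter_cue_duration_s,
    tasks_per_type_per_trial = as.integer(tasks_per_type_per_trial),
    trials_per_session = as.integer(trials_per_session),
    training_trials = as.integer(training_trials),
    discard_initial_s = discard_initial_s,
    epoch_length_s = epoch_length_s,
    epoch_shift_s = epoch_shift_s,
    sampling_rate_hz = sampling_rate_hz,
    n_days = as.integer(n_days)
  )
  class(spec) <- "protocol_spec"
  validate_protocol_spec(spec)
  spec
}

validate_protocol_spec <- function(spec) {
  durs <- c(spec$task_duration_s, spec$inter_cue_duration_s,
            spec$epoch_length_s, spec$epoch_shift_s, spec$sampling_rate_hz)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("protocol_spec: durations and sampling rate must be positive",
         call. = FALSE)
  if (spec$discard_initial_s < 0)
    stop("protocol_spec: discard_initial_s must be non-negative", call. = FALSE)
  if (spec$epoch_shift_s > spec$epoch_length_s)
    stop("protocol_spec: epoch_shift_s must not exceed epoch_length_s",
         call. = FALSE)
  if (spec$discard_initial_s + spec$epoch_length_s > spec$task_duration_s)
    stop("protocol_spec: no epoch fits after the discarded lead-in",
         call. = FALSE)
  if (spec$tasks_per_type_per_trial < 1L || spec$trials_per_session < 1L ||
      spec$n_days < 1L)
    stop("protocol_spec: counts must be at least 1", call. = FALSE)
  if (spec$training_trials >= spec$trials_per_session)
    stop("protocol_spec: training_trials must be below trials_per_session",
         call. = FALSE)
  invisible(spec)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Motor-imagery protocol:\n")
  cat(sprintf("  %d trials/session (%d training), %d cues per task per trial\n",
              x$trials_per_session, x$training_trials,
              x$tasks_per_type_per_trial))
  cat(sprintf("  task %.1f s, cross %.1f s; epochs %.1f s / shift %.1f s, discard %.1f s\n",
              x$task_duration_s, x$inter_cue_duration_s, x$epoch_length_s,
              x$epoch_shift_s, x$discard_initial_s))
  cat(sprintf("  %g Hz sampling, %d days\n", x$sampling_rate_hz, x$n_days))
  invisible(x)
}

#' Serialize / restore a protocol specification
#'
#' `protocol_to_json()` writes all fields as a JSON config block;
#' `protocol_from_json()` restores it, applying defaults for absent fields.
#'
#' @param spec A [protocol_spec()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json A JSON string or path to a JSON file.
#' @return `protocol_to_json()`: the JSON string (invisibly if written to a
#'   file); `protocol_from_json()`: a `protocol_spec`.
#' @export
protocol_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  txt <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(json) {
  vals <- jsonlite::fromJSON(json)
  do.call(protocol_spec, vals[names(vals) %in% names(formals(protocol_spec))])
}

# Task labels used throughout the package.
TASK_LABELS <- c("RELAX", "IMAGINE")
CUE_LABEL <- "CUE_CROSS"

#' Randomized cue schedule for one trial
#'
#' Draws a balanced random order of Relax and Imagine cues subject to the
#' protocol's predictability constraint: the same task never appears more than
#' twice in a row. Orders are drawn by rejection sampling of balanced
#' permutations, so every admissible order is equally likely. Each task cue is
#' preceded by a fixation-cross event (the cross is also shown before the
#' first cue of a trial).
#'
#' @param spec A [protocol_spec()].
#' @param seed Integer seed; the schedule is deterministic given `seed`.
#' @return A data frame of class `mi_schedule` with columns `label`
#'   (`"RELAX"`, `"IMAGINE"` or `"CUE_CROSS"`), `onset_s` and `duration_s`,
#'   ordered by onset, starting at 0.
#' @examples
#' sched <- build_trial_schedule(protocol_spec(), seed = 1)
#' table(sched$label)
#' @export
build_trial_schedule <- function(spec, seed) {
  validate_protocol_spec(spec)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  labels <- with_local_seed(seed, draw_task_order(spec$tasks_per_type_per_trial))
  schedule_from_labels(labels, spec)
}

# Balanced RELAX/IMAGINE permutation with no run of 3, by rejection sampling.
draw_task_order <- function(n_per_type) {
  pool <- rep(TASK_LABELS, each = n_per_type)
  repeat {
    order <- sample(pool)
    if (max_run_length(order) <= 2L) return(order)
  }
}

max_run_length <- function(x) max(rle(as.character(x))$lengths)

schedule_from_labels <- function(labels, spec) {
  n <- length(labels)
  lab <- character(2L * n)
  dur <- numeric(2L * n)
  lab[seq(1L, 2L * n, by = 2L)] <- CUE_LABEL
  dur[seq(1L, 2L * n, by = 2L)] <- spec$inter_cue_duration_s
  lab[seq(2L, 2L * n, by = 2L)] <- labels
  dur[seq(2L, 2L * n, by = 2L)] <- spec$task_duration_s
  onset <- cumsum(c(0, dur[-length(dur)]))
  out <- data.frame(label = lab, onset_s = onset, duration_s = dur,
                    stringsAsFactors = FALSE)
  class(out) <- c("mi_schedule", "data.frame")
  out
}

#' Randomized cue schedule for a full session
#'
#' Concatenates independently randomized trial schedules back to back and
#' tags every event with its trial number.
#'
#' @inheritParams build_trial_schedule
#' @return An `mi_schedule` data frame with an extra `trial` column.
#' @export
build_session_schedule <- function(spec, seed) {
  validate_protocol_spec(spec)
  trials <- lapply(seq_len(spec$trials_per_session), function(tr) {
    s <- build_trial_schedule(spec, seed = seed_stream(seed, 17L, tr))
    s$trial <- tr
    s
  })
  offset <- 0
  for (i in seq_along(trials)) {
    trials[[i]]$onset_s <- trials[[i]]$onset_s + offset
    offset <- offset + sum(trials[[i]]$duration_s)
  }
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  class(out) <- c("mi_schedule", "data.frame")
  out
}

#' Export a schedule as a delimited annotation table
#'
#' Writes the three annotation columns (`label`, `onset_s`, `duration_s`) as
#' tab-separated text, the package's interchange form for cue annotations.
#'
#' @param schedule An `mi_schedule`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule[c("label", "onset_s", "duration_s")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Current density of a circular stimulation electrode
#'
#' Stimulation current divided by the area of a circular gel electrode,
#' `I / (pi * r^2)`. At the study's 0.4 mA through a 1 cm radius electrode
#' this gives 0.127 mA/cm^2.
#'
#' @param intensity_mA Stimulation intensity, milliamps (> 0).
#' @param electrode_radius_cm Electrode radius, centimeters (> 0).
#' @return Current density in mA/cm^2.
#' @examples
#' current_density(0.4, 1)
#' @export
current_density <- function(intensity_mA, electrode_radius_cm) {
  if (!is.finite(intensity_mA) || intensity_mA <= 0)
    stop("intensity_mA must be positive", call. = FALSE)
  if (!is.finite(electrode_radius_cm) || electrode_radius_cm <= 0)
    stop("electrode_radius_cm must be positive", call. = FALSE)
  intensity_mA / (pi * electrode_radius_cm^2)
}

#' Number of analysis epochs per task cue
#'
#' Counts window start times `t = discard_initial_s + k * epoch_shift_s` with
#' `t + epoch_length_s <= task_duration_s` (within a 1e-9 s tolerance so that
#' exactly reachable end points are included). 15 with the default protocol.
#'
#' @param spec A [protocol_spec()].
#' @return Integer epoch count.
#' @export
epochs_per_task <- function(spec) {
  validate_protocol_spec(spec)
  usable <- spec$task_duration_s - spec$discard_initial_s - spec$epoch_length_s
  as.integer(floor(usable / spec$epoch_shift_s + 1e-9)) + 1L
}

# Epoch start offsets (s) within one task, relative to task onset.
epoch_offsets <- function(spec) {
  spec$discard_initial_s + (seq_len(epochs_per_task(spec)) - 1L) * spec$epoch_shift_s
}
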