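# Shared fixture builders: everything is generated in code at test time.

# A reduced protocol for fast tests; scientific structure (balanced cues,
# crosses, 4 training trials) is unchanged, only counts shrink.
small_spec <- function(...) {
  protocol_spec(tasks_per_type_per_trial = 2, trials_per_session = 5,
                training_trials = 4, ...)
}

# Wrap a samples x channels x epochs array (or a single epoch vector) as an
# epoch_set without going through a recording.
make_epoch_set <- function(x, channels = "CZ", fs = 500,
                           labels = NULL, trial = NULL) {
  if (is.null(dim(x))) x <- array(x, c(length(x), 1, 1))
  if (is.null(labels)) labels <- rep("RELAX", dim(x)[3])
  structure(list(epochs = x, labels = labels,
                 epoch_start_s = seq_len(dim(x)[3]) - 1,
                 channel_labels = channels, sampling_rate_hz = fs,
                 trial = trial),
            class = "epoch_set")
}

# A power_table with prescribed values (epoch x electrode x frequency).
make_power_table <- function(values, labels,
                             electrodes = paste0("E", seq_len(dim(values)[2])),
                             frequencies = feature_frequencies(),
                             normalized = FALSE) {
  structure(list(values = values, frequencies_hz = frequencies,
                 electrode_labels = electrodes, labels = labels,
                 trial = NULL, epoch_start_s = seq_len(dim(values)[1]) - 1,
                 normalized = normalized),
            class = "power_table")
}

# A one-event recording with a prescribed sample matrix, for slicing tests.
make_recording <- function(samples, events, fs = 500,
                           channels = rownames(samples)) {
  structure(list(samples = samples, sampling_rate_hz = fs,
                 channel_labels = channels, events = events, day = 1L),
            class = "session_recording")
}

simple_events <- function(label = "RELAX", onset = 0, duration = 5.8,
                          trial = 1L) {
  data.frame(label = label, onset_s = onset, duration_s = duration,
             trial = trial, stringsAsFactors = FALSE)
}
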