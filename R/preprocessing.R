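#' Filter chain configuration
#'
#' Temporal filters applied to every analysis epoch before spectral
#' estimation: a 4th-order Butterworth high-pass at 0.05 Hz (DC removal), a
#' narrow IIR notch at the 50 Hz power-line frequency, and a 4th-order
#' Butterworth low-pass at 45 Hz. All filters are applied zero-phase
#' (forward-backward with odd-reflection padding and steady-state initial
#' conditions); on a 1 s window the 0.05 Hz high-pass then acts essentially
#' as epoch-mean removal, which is its intended effect.
#'
#' @param hp_cutoff_hz High-pass cutoff, Hz.
#' @param hp_order High-pass Butterworth order.
#' @param notch_hz Notch center frequency, Hz.
#' @param notch_q Notch quality factor (center / -3 dB bandwidth). The
#'   default 10 keeps the notch's ring-down short enough to stay contained
#'   within a 1 s window (a much narrower notch cannot settle in 1 s and
#'   leaks transient energy across the epoch) while perturbing the 6-30 Hz
#'   feature band by less than 0.5%.
#' @param lp_cutoff_hz Low-pass cutoff, Hz.
#' @param lp_order Low-pass Butterworth order.
#' @return An object of class `filter_chain_config`.
#' @export
filter_chain_config <- function(hp_cutoff_hz = 0.05, hp_order = 4,
                                notch_hz = 50, notch_q = 10,
                                lp_cutoff_hz = 45, lp_order = 4) {
  cfg <- list(hp_cutoff_hz = hp_cutoff_hz, hp_order = as.integer(hp_order),
              notch_hz = notch_hz, notch_q = notch_q,
              lp_cutoff_hz = lp_cutoff_hz, lp_order = as.integer(lp_order))
  if (cfg$hp_cutoff_hz <= 0 || cfg$lp_cutoff_hz <= cfg$hp_cutoff_hz)
    stop("need 0 < hp_cutoff_hz < lp_cutoff_hz", call. = FALSE)
  if (cfg$hp_order < 1 || cfg$lp_order < 1)
    stop("filter orders must be at least 1", call. = FALSE)
  class(cfg) <- "filter_chain_config"
  cfg
}

# --- epoch container ---------------------------------------------------------

new_epoch_set <- function(epochs, labels, epoch_start_s, channel_labels,
                          sampling_rate_hz, trial = NULL) {
  structure(list(epochs = epochs, labels = labels,
                 epoch_start_s = epoch_start_s,
                 channel_labels = channel_labels,
                 sampling_rate_hz = sampling_rate_hz,
                 trial = trial),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples (%g Hz)\n",
              dim(x$epochs)[3], dim(x$epochs)[2], dim(x$epochs)[1],
              x$sampling_rate_hz))
  print(table(x$labels))
  invisible(x)
}

#' Slice a recording into labeled analysis epochs
#'
#' Cuts fixed-length windows (`epoch_length_s`, advanced by `epoch_shift_s`)
#' out of every Relax/Imagine cue of the recording, skipping the first
#' `discard_initial_s` of each cue (visual-cue transient) and all fixation
#' crosses. Sample indices are obtained by rounding `t * fs`, exact for the
#' default 200 ms shift at 500 Hz.
#'
#' @param rec A `session_recording`.
#' @param spec The [protocol_spec()] the recording follows.
#' @param trials Optional integer vector restricting to those trial numbers.
#' @return An `epoch_set`: `epochs` is a samples x channels x epochs array,
#'   `labels`, `epoch_start_s` and `trial` run per epoch.
#' @export
slice_epochs <- function(rec, spec, trials = NULL) {
  stopifnot(inherits(rec, "session_recording"))
  validate_protocol_spec(spec)
  fs <- rec$sampling_rate_hz
  ev <- rec$events
  ev <- ev[ev$label %in% TASK_LABELS, , drop = FALSE]
  if (!is.null(trials)) {
    if (is.null(ev$trial)) stop("events carry no trial numbers", call. = FALSE)
    ev <- ev[ev$trial %in% trials, , drop = FALSE]
  }
  if (nrow(ev) == 0) stop("no task events to slice", call. = FALSE)
  n_total <- ncol(rec$samples)
  ends <- round((ev$onset_s + ev$duration_s) * fs)
  if (any(ends > n_total))
    stop("event extends past the end of the recording", call. = FALSE)

  offs <- epoch_offsets(spec)
  n_s <- round(spec$epoch_length_s * fs)
  starts_s <- as.vector(outer(offs, ev$onset_s, "+"))       # epoch-major per event
  start_idx <- round(starts_s * fs) + 1L
  labels <- rep(ev$label, each = length(offs))
  trial <- if (!is.null(ev$trial)) rep(ev$trial, each = length(offs)) else NULL

  ne <- length(start_idx)
  nc <- nrow(rec$samples)
  epochs <- array(0, dim = c(n_s, nc, ne))
  for (i in seq_len(ne)) {
    idx <- start_idx[i]:(start_idx[i] + n_s - 1L)
    epochs[, , i] <- t(rec$samples[, idx, drop = FALSE])
  }
  new_epoch_set(epochs, labels, starts_s, rec$channel_labels, fs, trial)
}

# --- temporal filters --------------------------------------------------------

# Steady-state initial conditions for direct-form-II-transposed filtering
# (the scipy lfilter_zi construction): the state that makes the response to a
# unit step transient-free.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)                 # companion matrix of a
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(1, n - 1) - t(comp), B)
}

# RBJ biquad notch at f0 with quality factor Q.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Butterworth design as cascaded second-order sections (bilinear transform of
# the analog prototype, conjugate pole pairs per biquad). The single
# transfer-function form is numerically useless at extreme cutoffs (a 0.05 Hz
# high-pass at 500 Hz has an ill-conditioned coefficient sum and a spurious
# DC gain of ~0.4%); per-section zeros sit exactly at z = +/-1, so each
# biquad's DC (high-pass) or Nyquist (low-pass) null is exact.
design_butter_sos <- function(order, W, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, W > 0, W < 1)
  Omega <- tan(pi * W / 2)
  k <- seq_len(order)
  s <- exp(1i * pi * (2 * k - 1 + order) / (2 * order))  # left-half-plane
  pa <- if (type == "low") Omega * s else Omega / s
  pz <- (1 + pa) / (1 - pa)
  zz <- if (type == "low") -1 else 1                     # digital zeros
  pair <- pz[Im(pz) > 1e-12]
  real <- Re(pz[abs(Im(pz)) <= 1e-12])
  secs <- lapply(pair, function(p) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    b <- c(1, -2 * zz, 1)
    ref <- if (type == "low") c(1, 1, 1) else c(1, -1, 1)  # z = +/-1
    list(b = b * sum(a * ref) / sum(b * ref), a = a)
  })
  for (p in real) {
    a <- c(1, -p)
    b <- c(1, -zz)
    ref <- if (type == "low") c(1, 1) else c(1, -1)
    secs <- c(secs, list(list(b = b * sum(a * ref) / sum(b * ref), a = a)))
  }
  secs
}

design_chain <- function(cfg, fs) {
  nyq <- fs / 2
  if (cfg$lp_cutoff_hz >= nyq || cfg$notch_hz >= nyq)
    stop("filter cutoff at or above the Nyquist frequency", call. = FALSE)
  c(design_butter_sos(cfg$hp_order, cfg$hp_cutoff_hz / nyq, "high"),
    list(design_notch(cfg$notch_hz, fs, cfg$notch_q)),
    design_butter_sos(cfg$lp_order, cfg$lp_cutoff_hz / nyq, "low"))
}

# Zero-phase application of one (b, a) stage to the columns of a matrix.
zero_phase <- function(stage, X, padlen = NULL) {
  n <- nrow(X)
  if (is.null(padlen)) padlen <- min(n - 1L, 500L)
  zi <- lfilter_zi(stage$b, stage$a)
  .filtfilt_cols(stage$b, stage$a, X, zi, as.integer(padlen))
}

#' Apply the temporal filter chain to every epoch
#'
#' Runs high-pass, notch and low-pass over each epoch of each channel,
#' zero-phase (forward-backward with odd-reflection padding and steady-state
#' initial conditions, so a constant epoch maps to zero and no phase
#' distortion is introduced).
#'
#' @param epochs An `epoch_set`.
#' @param cfg A [filter_chain_config()].
#' @param fs Sampling rate, Hz; defaults to the epoch set's.
#' @return An `epoch_set` of the same shape, filtered.
#' @export
apply_filter_chain <- function(epochs, cfg = filter_chain_config(),
                               fs = epochs$sampling_rate_hz) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  stages <- design_chain(cfg, fs)
  X <- epochs$epochs
  dim(X) <- c(d[1], d[2] * d[3])
  for (st in stages) X <- zero_phase(st, X)
  dim(X) <- d
  out <- epochs
  out$epochs <- X
  out
}

#' Causal filtering of a continuous recording
#'
#' Streaming alternative to the per-epoch zero-phase chain: each filter runs
#' causally over the whole session with its state carried forward (as an
#' online system would), after which epochs can be sliced with
#' [slice_epochs()]. Initial states are set to the step steady state of the
#' first sample to suppress the startup DC transient.
#'
#' @param rec A `session_recording`.
#' @param cfg A [filter_chain_config()].
#' @return The recording with filtered samples.
#' @export
apply_filter_chain_causal <- function(rec, cfg = filter_chain_config()) {
  stopifnot(inherits(rec, "session_recording"))
  stages <- design_chain(cfg, rec$sampling_rate_hz)
  X <- rec$samples
  for (st in stages) {
    zi <- lfilter_zi(st$b, st$a)
    # warm the filter up on a constant prefix: the analytic steady state of
    # the very slow high-pass is ill-conditioned, so a settling run refines it
    warm <- settle_samples(st$a)
    for (ch in seq_len(nrow(X))) {
      y <- .filter_df2t(st$b, st$a, c(rep(X[ch, 1], warm), X[ch, ]),
                        zi * X[ch, 1])
      X[ch, ] <- y[-seq_len(warm)]
    }
  }
  out <- rec
  out$samples <- X
  out
}

# Samples needed for a filter's slowest pole to decay by ~e^-9.
settle_samples <- function(a) {
  r <- max(Mod(polyroot(rev(a))))
  if (r >= 1) return(30000L)
  min(30000L, as.integer(ceiling(-9 / log(r))))
}

# --- spatial filter ----------------------------------------------------------

# Row-normalized inverse-distance weight matrix W (zero diagonal) over the
# projected montage; the Laplacian operator is I - W.
laplacian_weights <- function(labels, coords = NULL) {
  if (is.null(coords)) coords <- electrode_positions(labels)
  stopifnot(nrow(coords) == length(labels))
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  diag(d) <- Inf
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate electrode coordinates (zero distance)", call. = FALSE)
  W <- 1 / d
  W / rowSums(W)
}

#' Surface Laplacian re-referencing
#'
#' Replaces each channel by itself minus the distance-weighted average of all
#' other channels (weights proportional to 1/distance over the projected
#' montage, normalized to sum to one per target channel). Sharpens local
#' sources and cancels signals common to the whole montage; applied to the
#' full montage before electrode selection.
#'
#' @param epochs An `epoch_set`.
#' @param coords Optional data frame of per-channel `x`, `y` positions in the
#'   channel order of `epochs`; defaults to the standard layout of
#'   [electrode_positions()].
#' @return An `epoch_set` of the same shape.
#' @export
laplacian_reference <- function(epochs, coords = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  L <- diag(length(epochs$channel_labels)) -
    laplacian_weights(epochs$channel_labels, coords)
  d <- dim(epochs$epochs)
  out <- epochs
  for (e in seq_len(d[3]))
    out$epochs[, , e] <- epochs$epochs[, , e] %*% t(L)
  out
}

#' Keep a subset of electrodes
#'
#' Reduces the channel dimension to the named electrodes, in the order given.
#' The default keeps the nine central electrodes used for classification.
#'
#' @param epochs An `epoch_set`.
#' @param names Electrode labels to keep.
#' @return An `epoch_set` with the reduced channel dimension.
#' @export
select_electrodes <- function(epochs, names = motor_electrodes()) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(toupper(names), toupper(epochs$channel_labels))
  if (anyNA(idx))
    stop("unknown electrode name(s): ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- epochs
  out$epochs <- epochs$epochs[, idx, , drop = FALSE]
  out$channel_labels <- epochs$channel_labels[idx]
  out
}

#' Standard preprocessing for one set of trials
#'
#' Convenience wrapper running the full chain of the online system on a
#' recording: slice epochs, temporal filters, surface Laplacian over the full
#' montage, then electrode selection.
#'
#' @inheritParams slice_epochs
#' @param cfg A [filter_chain_config()].
#' @param electrodes Electrodes kept after the Laplacian.
#' @return An `epoch_set` restricted to `electrodes`.
#' @export
preprocess_session <- function(rec, spec, cfg = filter_chain_config(),
                               trials = NULL, electrodes = motor_electrodes()) {
  ep <- slice_epochs(rec, spec, trials = trials)
  ep <- apply_filter_chain(ep, cfg)
  ep <- laplacian_reference(ep)
  select_electrodes(ep, electrodes)
}
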