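#' Burg autoregressive power spectral density
#'
#' Fits an autoregressive model to a single-channel epoch by the Burg
#' recursion (via [stats::ar.burg()]) and evaluates the AR spectral density
#' at the requested frequencies:
#' `S(f) = sigma2 / (fs * |1 - sum_k phi_k exp(-2 pi i f k / fs)|^2)`.
#' Burg's method gives smooth spectra from short (1 s) windows, which is why
#' it is used for the 1 Hz-resolved 6-30 Hz feature grid.
#'
#' @param x Numeric vector, one epoch of one channel.
#' @param ar_order AR model order (default 16 for 500-sample epochs, roughly
#'   fs/30 — enough poles to resolve separate mu and beta peaks).
#' @param frequencies_hz Frequencies at which to evaluate the density, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of non-negative power densities, one per frequency.
#' @examples
#' x <- sin(2 * pi * 10 * (0:499) / 500) + rnorm(500, 0, 0.1)
#' p <- burg_psd(x, fs = 500)
#' feature_frequencies()[which.max(p)]
#' @export
burg_psd <- function(x, ar_order = 16, frequencies_hz = feature_frequencies(),
                     fs = 500) {
  if (ar_order >= length(x))
    stop("ar_order must be below the number of samples", call. = FALSE)
  if (any(frequencies_hz >= fs / 2))
    stop("requested frequencies must lie below the Nyquist frequency",
         call. = FALSE)
  if (all(x == x[1]))
    stop("degenerate (constant) signal: no spectrum to estimate",
         call. = FALSE)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = ar_order, demean = TRUE)
  ar_spectrum(fit$ar, fit$var.pred, frequencies_hz, fs)
}

# Evaluate an AR(p) spectral density at arbitrary frequencies.
ar_spectrum <- function(phi, sigma2, freqs, fs) {
  k <- seq_along(phi)
  den <- vapply(freqs, function(f) {
    h <- 1 - sum(phi * exp(-2i * pi * f * k / fs))
    Mod(h)^2
  }, numeric(1))
  as.numeric(sigma2 / (fs * den))
}

#' Power table: Burg spectra for every epoch and electrode
#'
#' Computes the Burg spectral density of each (epoch, electrode) signal on
#' the integer frequency grid. The raw table carries absolute densities;
#' [normalize_powers()] converts each (epoch, electrode) spectrum to relative
#' power summing to one.
#'
#' @param epochs An `epoch_set` (typically after [preprocess_session()]).
#' @param ar_order AR model order passed to [burg_psd()].
#' @param frequencies_hz Analysis grid, Hz (default 6-30 in 1 Hz steps).
#' @return An object of class `power_table`: `values` is an epoch x
#'   electrode x frequency array; `frequencies_hz`, `electrode_labels`,
#'   `labels` (task per epoch) and `normalized` accompany it.
#' @export
power_table <- function(epochs, ar_order = 16,
                        frequencies_hz = feature_frequencies()) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  fs <- epochs$sampling_rate_hz
  nf <- length(frequencies_hz)
  vals <- array(0, dim = c(d[3], d[2], nf))
  for (e in seq_len(d[3]))
    for (ch in seq_len(d[2]))
      vals[e, ch, ] <- burg_psd(epochs$epochs[, ch, e], ar_order,
                                frequencies_hz, fs)
  structure(list(values = vals, frequencies_hz = frequencies_hz,
                 electrode_labels = epochs$channel_labels,
                 labels = epochs$labels, trial = epochs$trial,
                 epoch_start_s = epochs$epoch_start_s,
                 normalized = FALSE),
            class = "power_table")
}

#' Per-epoch, per-electrode relative power
#'
#' Divides every (epoch, electrode) spectrum by its sum over the frequency
#' grid, so each slice sums to one. Idempotent; features become invariant to
#' any common rescaling of the raw signal.
#'
#' @param raw A `power_table`.
#' @return A `power_table` with `normalized = TRUE`.
#' @export
normalize_powers <- function(raw) {
  stopifnot(inherits(raw, "power_table"))
  if (isTRUE(raw$normalized)) return(raw)
  if (any(raw$values < 0)) stop("powers must be non-negative", call. = FALSE)
  tot <- apply(raw$values, c(1, 2), sum)
  if (any(tot <= 0))
    stop("degenerate all-zero spectrum in at least one (epoch, electrode)",
         call. = FALSE)
  out <- raw
  out$values <- raw$values / as.vector(tot)   # recycles over frequency dim
  out$normalized <- TRUE
  out
}

#' Per-electrode optimal discriminative frequency
#'
#' For each electrode, averages the normalized power at each frequency
#' separately over Relax and Imagine epochs and picks the frequency with the
#' largest absolute difference between the two task means — the electrode's
#' "optimal frequency". Ties break toward the lowest frequency.
#'
#' @param training A `power_table` built from the training trials (it is
#'   normalized first if it is not already).
#' @return An object of class `optimal_frequency_map`: data frame with
#'   columns `electrode`, `frequency_hz`, `abs_diff` (the achieved mean
#'   absolute normalized-power difference).
#' @export
select_optimal_frequencies <- function(training) {
  stopifnot(inherits(training, "power_table"))
  if (length(unique(training$labels)) < 2)
    stop("training table must contain both task labels", call. = FALSE)
  pt <- normalize_powers(training)
  rel <- pt$labels == "RELAX"
  mean_relax <- apply(pt$values[rel, , , drop = FALSE], c(2, 3), mean)
  mean_imag <- apply(pt$values[!rel, , , drop = FALSE], c(2, 3), mean)
  diff <- abs(mean_relax - mean_imag)          # electrode x frequency
  pick <- apply(diff, 1, which.max)            # first max = lowest frequency
  out <- data.frame(electrode = pt$electrode_labels,
                    frequency_hz = pt$frequencies_hz[pick],
                    abs_diff = diff[cbind(seq_len(nrow(diff)), pick)],
                    stringsAsFactors = FALSE)
  class(out) <- c("optimal_frequency_map", "data.frame")
  out
}

#' Classification features: power at each electrode's optimal frequency
#'
#' For every epoch, reads the normalized power of each mapped electrode at
#' that electrode's optimal frequency — nine features per epoch with the
#' default montage.
#'
#' @param powers A `power_table` (normalized first if raw).
#' @param map An `optimal_frequency_map` covering all electrodes of `powers`.
#' @return Numeric matrix, epochs x electrodes, with electrode column names.
#' @export
extract_features <- function(powers, map) {
  stopifnot(inherits(powers, "power_table"),
            inherits(map, "optimal_frequency_map"))
  pt <- normalize_powers(powers)
  ei <- match(pt$electrode_labels, map$electrode)
  if (anyNA(ei))
    stop("map does not cover electrode(s): ",
         paste(pt$electrode_labels[is.na(ei)], collapse = ", "),
         call. = FALSE)
  fi <- match(map$frequency_hz[ei], pt$frequencies_hz)
  if (anyNA(fi))
    stop("map frequency outside the table's frequency grid", call. = FALSE)
  ne <- dim(pt$values)[1]
  feats <- vapply(seq_along(ei), function(ch) pt$values[, ch, fi[ch]],
                  numeric(ne))
  feats <- matrix(feats, nrow = ne)
  colnames(feats) <- pt$electrode_labels
  feats
}

#' Periodogram power spectrum (reference estimator)
#'
#' Plain FFT periodogram of one epoch, evaluated on a frequency grid by
#' nearest FFT bin. Used in the package's tests as an independent check on
#' the Burg estimator; not part of the online pipeline.
#'
#' @inheritParams burg_psd
#' @return Numeric vector of periodogram powers at `frequencies_hz`.
#' @export
periodogram_psd <- function(x, frequencies_hz = feature_frequencies(),
                            fs = 500) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / (n * fs)
  bins <- round(frequencies_hz * n / fs) + 1L
  as.numeric(P[bins])
}
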