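#' Synthetic subject profile
#'
#' Parameters of the generative model for one subject's EEG: a narrowband mu
#' rhythm (and optionally a beta rhythm) radiating from a motor-cortex source
#' under the vertex, whose band power drops by a controlled fraction during
#' pedaling-imagery cues (event-related desynchronization, ERD), on top of
#' 1/f background noise and optional 50 Hz line interference.
#'
#' The ERD is parameterized on the power scale: during Imagine cues the
#' rhythm amplitude is multiplied by `sqrt(1 - rho_day)` where
#' `rho_day = erd_power_fraction * day_curve[day]`, so band power drops by
#' exactly `rho_day` and the ERD statistic has ground truth
#' `-100 * rho_day` percent.
#'
#' @param mu_center_hz Mu rhythm center frequency, Hz (8-12).
#' @param mu_amplitude Mu rhythm source amplitude, microvolts.
#' @param beta_center_hz Beta rhythm center frequency, Hz (13-30).
#' @param beta_amplitude Beta rhythm source amplitude, microvolts (0 disables).
#' @param erd_power_fraction Fraction `rho` of rhythm band power suppressed
#'   during Imagine cues at full expression (`day_curve` multiplier 1).
#' @param noise_amplitude Standard deviation of the per-channel 1/f
#'   background, microvolts; an independent common-mode 1/f component of the
#'   same scale is added across all channels.
#' @param line_noise_amplitude Amplitude of the common 50 Hz line component,
#'   microvolts.
#' @param day_curve Per-day multipliers on `rho`, length = number of days.
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile(erd_power_fraction = 0.3, noise_amplitude = 0)
#' @export
subject_profile <- function(mu_center_hz = 10,
                            mu_amplitude = 10,
                            beta_center_hz = 20,
                            beta_amplitude = 0,
                            erd_power_fraction = 0.3,
                            noise_amplitude = 2,
                            line_noise_amplitude = 1,
                            day_curve = rep(1, 5)) {
  p <- list(mu_center_hz = mu_center_hz, mu_amplitude = mu_amplitude,
            beta_center_hz = beta_center_hz, beta_amplitude = beta_amplitude,
            erd_power_fraction = erd_power_fraction,
            noise_amplitude = noise_amplitude,
            line_noise_amplitude = line_noise_amplitude,
            day_curve = day_curve)
  if (p$erd_power_fraction < 0 || p$erd_power_fraction > 1)
    stop("erd_power_fraction must lie in [0, 1]", call. = FALSE)
  if (p$mu_amplitude < 0 || p$beta_amplitude < 0 || p$noise_amplitude < 0 ||
      p$line_noise_amplitude < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (any(p$day_curve < 0))
    stop("day_curve entries must be non-negative", call. = FALSE)
  class(p) <- "subject_profile"
  p
}

#' Per-day ERD expression presets for the two study arms
#'
#' The active-stimulation preset expresses the subject's full ERD from day 1
#' (multiplier 1 on all days); the sham preset ramps up over the first three
#' days, emulating un-stimulated subjects who need training before their
#' imagery produces a comparable desynchronization. The sham ramp values are
#' illustrative (chosen to reproduce the qualitative learning pattern, not
#' calibrated against measurements).
#'
#' @param group `"TDCS"` or `"SHAM"`.
#' @param n_days Number of days (the preset is recycled/truncated to length).
#' @return Numeric vector of multipliers in `[0, 1]`.
#' @export
day_curve_preset <- function(group = c("TDCS", "SHAM"), n_days = 5L) {
  group <- match.arg(toupper(group), c("TDCS", "SHAM"))
  base <- switch(group,
                 TDCS = rep(1, n_days),
                 SHAM = c(0.1, 0.55, 0.9, 1, 1))
  out <- rep_len(base, n_days)
  if (group == "SHAM" && n_days > 5L) out[6:n_days] <- 1
  out
}

#' Generate one synthetic cue-locked EEG session
#'
#' Simulates a full multichannel session for one subject and day: a
#' randomized cue schedule is drawn, a mu (and optional beta) rhythm source
#' with random phase and slow narrowband amplitude jitter is synthesized,
#' amplitude-scaled by `sqrt(1 - rho_day)` inside Imagine cues (100 ms
#' raised-cosine ramps at task boundaries avoid broadband clicks), projected
#' to the scalp with a Gaussian spatial profile centered at Cz, and summed
#' with per-channel 1/f noise, a common-mode 1/f component and common 50 Hz
#' line interference. Bit-identical output for a fixed seed.
#'
#' @param profile A [subject_profile()].
#' @param spec A [protocol_spec()].
#' @param day Day index in `1..length(day_curve)`.
#' @param seed Integer seed.
#' @return An object of class `session_recording`: list with `samples`
#'   (channels x time matrix, microvolts), `sampling_rate_hz`,
#'   `channel_labels`, `events` (the schedule, with trial numbers) and `day`.
#' @examples
#' spec <- protocol_spec(tasks_per_type_per_trial = 2, trials_per_session = 5)
#' rec <- generate_session(subject_profile(), spec, day = 1, seed = 7)
#' dim(rec$samples)
#' @export
generate_session <- function(profile, spec = protocol_spec(), day = 1L,
                             seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  validate_protocol_spec(spec)
  if (day < 1L || day > length(profile$day_curve))
    stop("day must index into profile$day_curve", call. = FALSE)
  rho_day <- profile$erd_power_fraction * profile$day_curve[day]
  if (rho_day > 1)
    stop("erd_power_fraction * day_curve[day] exceeds 1", call. = FALSE)

  events <- build_session_schedule(spec, seed = seed_stream(seed, 1L))
  fs <- spec$sampling_rate_hz
  n <- round(sum(events$duration_s) * fs)
  channels <- acquisition_channels()
  nc <- length(channels)

  samples <- with_local_seed(seed_stream(seed, 2L), {
    t <- (seq_len(n) - 1) / fs
    env <- imagery_envelope(events, n, fs, sqrt(1 - rho_day))
    src <- rhythm_source(n, fs, profile$mu_center_hz, profile$mu_amplitude)
    if (profile$beta_amplitude > 0)
      src <- src + rhythm_source(n, fs, profile$beta_center_hz,
                                 profile$beta_amplitude)
    src <- src * env
    w <- source_projection_weights(channels)
    out <- outer(w, src)  # nc x n
    if (profile$noise_amplitude > 0) {
      common <- one_over_f_noise(n, fs, profile$noise_amplitude)
      for (ch in seq_len(nc))
        out[ch, ] <- out[ch, ] + common +
          one_over_f_noise(n, fs, profile$noise_amplitude)
    }
    if (profile$line_noise_amplitude > 0) {
      line <- profile$line_noise_amplitude *
        sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      out <- sweep(out, 2, line, "+")
    }
    out
  })
  rownames(samples) <- channels
  structure(list(samples = samples, sampling_rate_hz = fs,
                 channel_labels = channels, events = events, day = day,
                 profile = profile),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("session_recording: %d channels x %d samples (%.1f s at %g Hz), %d task cues\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$sampling_rate_hz, x$sampling_rate_hz,
              sum(x$events$label %in% TASK_LABELS)))
  invisible(x)
}

# Amplitude envelope: `scale` inside IMAGINE cues, 1 elsewhere, smoothed by a
# raised-cosine (Hann) kernel of 100 ms so transitions ramp over ~100 ms.
imagery_envelope <- function(events, n, fs, scale, ramp_s = 0.1) {
  env <- rep(1, n)
  im <- events[events$label == "IMAGINE", , drop = FALSE]
  for (k in seq_len(nrow(im))) {
    i0 <- round(im$onset_s[k] * fs) + 1L
    i1 <- min(n, round((im$onset_s[k] + im$duration_s[k]) * fs))
    env[i0:i1] <- scale
  }
  L <- max(3L, round(ramp_s * fs))
  kern <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  kern <- kern / sum(kern)
  padded <- c(rep(env[1], L), env, rep(env[n], L))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(L + 1):(L + n)])
}

# Narrowband oscillation: sinusoid with random phase, amplitude-modulated by
# slow (< 1 Hz) jitter so spectral energy spreads about +/- 1 Hz around the
# center frequency. The modest modulation depth keeps realized band power
# tightly controlled (the point of a deterministic-amplitude source) while
# still avoiding an unrealistically pure spectral line.
rhythm_source <- function(n, fs, f0, amplitude, jitter_depth = 0.1) {
  phase <- stats::runif(1, 0, 2 * pi)
  z <- slow_noise(n, fs, cutoff_hz = 1)
  jit <- pmax(0, 1 + jitter_depth * z)
  amplitude * jit * sin(2 * pi * f0 * (seq_len(n) - 1) / fs + phase)
}

# Unit-variance noise low-passed below `cutoff_hz` (FFT brick-wall).
slow_noise <- function(n, fs, cutoff_hz) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  X[f > cutoff_hz] <- 0
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

# Gaussian projection of the central source onto the montage; sigma is about
# one inter-electrode spacing so Cz and its immediate ring carry most power.
source_projection_weights <- function(channels, sigma = 0.35) {
  pos <- electrode_positions(channels)
  cz <- electrode_positions("CZ")
  d2 <- (pos$x - cz$x)^2 + (pos$y - cz$y)^2
  exp(-d2 / (2 * sigma^2))
}

# 1/f ("pink") background noise with standard deviation `sd_uV`.
one_over_f_noise <- function(n, fs, sd_uV) {
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  X <- (stats::rnorm(n) + 1i * stats::rnorm(n)) * shape
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out * (sd_uV / stats::sd(out))
}

#' Generate a synthetic two-arm cohort
#'
#' Draws `n_subjects` randomized subject profiles (rhythm frequency,
#' amplitudes, ERD depth, noise levels) and simulates every (subject, day)
#' session for the requested study arm. The arm determines the per-day ERD
#' expression via [day_curve_preset()]: active stimulation expresses full ERD
#' from day 1, sham ramps up over the first days.
#'
#' @param group `"TDCS"` or `"SHAM"`.
#' @param n_subjects Number of subjects.
#' @param spec A [protocol_spec()]; `spec$n_days` sessions per subject.
#' @param seed Integer seed; profiles and sessions are reproducible.
#' @param materialize If `FALSE`, recordings are not generated; entries then
#'   carry only the profile and the per-session seed, and
#'   [realize_cohort_session()] generates a recording on demand (keeps memory
#'   flat for full-size cohorts).
#' @return An object of class `mi_cohort`: a list of entries, each a list
#'   with `group`, `subject`, `day`, `profile`, `seed` and (if materialized)
#'   `recording`.
#' @examples
#' spec <- protocol_spec(tasks_per_type_per_trial = 2, trials_per_session = 5,
#'                       n_days = 1)
#' coh <- generate_cohort("SHAM", 2, spec, seed = 3)
#' length(coh)
#' @export
generate_cohort <- function(group = c("TDCS", "SHAM"), n_subjects, spec = protocol_spec(),
                            seed = 1L, materialize = TRUE) {
  group <- match.arg(toupper(group), c("TDCS", "SHAM"))
  if (n_subjects < 1L) stop("n_subjects must be at least 1", call. = FALSE)
  validate_protocol_spec(spec)
  curve <- day_curve_preset(group, spec$n_days)
  profiles <- with_local_seed(seed_stream(seed, 3L), {
    lapply(seq_len(n_subjects), function(s) {
      amp <- stats::runif(1, 6, 14)
      subject_profile(
        mu_center_hz = stats::runif(1, 8, 12),
        mu_amplitude = amp,
        beta_center_hz = stats::runif(1, 16, 24),
        beta_amplitude = stats::runif(1, 0.2, 0.4) * amp,
        erd_power_fraction = stats::runif(1, 0.2, 0.45),
        noise_amplitude = stats::runif(1, 1.5, 3),
        line_noise_amplitude = stats::runif(1, 0.5, 1.5),
        day_curve = curve)
    })
  })
  entries <- list()
  for (s in seq_len(n_subjects)) {
    for (d in seq_len(spec$n_days)) {
      e <- list(group = group, subject = s, day = d,
                profile = profiles[[s]],
                seed = seed_stream(seed, 100L + s, d))
      if (materialize)
        e$recording <- generate_session(profiles[[s]], spec, day = d,
                                        seed = e$seed)
      entries[[length(entries) + 1L]] <- e
    }
  }
  structure(entries, class = "mi_cohort", spec = spec)
}

#' @rdname generate_cohort
#' @param cohort An `mi_cohort` built with `materialize = FALSE`.
#' @param index Entry index into the cohort list.
#' @export
realize_cohort_session <- function(cohort, index) {
  e <- cohort[[index]]
  if (!is.null(e$recording)) return(e$recording)
  generate_session(e$profile, attr(cohort, "spec"), day = e$day, seed = e$seed)
}
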