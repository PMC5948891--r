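#' Event-related desynchronization (ERD)
#'
#' Relative power change of the imagery state with respect to the relax
#' reference, in percent: `100 * (P - R) / R`, where `P` is the mean power
#' over pedaling-imagery epochs and `R` the mean power over relax epochs at
#' the same electrode and frequency. Negative values indicate
#' desynchronization (imagery power below relax power); the statistic is
#' bounded below by -100 for non-negative powers and is invariant to a
#' common positive rescaling of both powers.
#'
#' @param P Mean imagery-epoch power (non-negative); vectorized.
#' @param R Mean relax-epoch power (strictly positive); vectorized.
#' @return ERD in percent.
#' @examples
#' erd(0.8, 1.0)   # -20: a 20% power suppression
#' @export
erd <- function(P, R) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("reference power R must be positive", call. = FALSE)
  (P - R) / R * 100
}

#' ERD matrix over electrodes and frequencies
#'
#' Averages the table's power at each (electrode, frequency) separately over
#' Imagine and Relax epochs and applies [erd()]. Meaningful on raw (absolute)
#' powers: normalizing per epoch changes the imagery/relax power ratio and
#' would bias the statistic.
#'
#' @param powers A `power_table` containing both task labels.
#' @return An `erd_matrix`: electrode x frequency matrix of ERD percentages
#'   with label/frequency dimnames.
#' @export
erd_matrix <- function(powers) {
  stopifnot(inherits(powers, "power_table"))
  if (length(unique(powers$labels)) < 2)
    stop("both task labels are required", call. = FALSE)
  rel <- powers$labels == "RELAX"
  R <- apply(powers$values[rel, , , drop = FALSE], c(2, 3), mean)
  P <- apply(powers$values[!rel, , , drop = FALSE], c(2, 3), mean)
  out <- erd(P, R)
  dimnames(out) <- list(powers$electrode_labels, powers$frequencies_hz)
  class(out) <- c("erd_matrix", class(out))
  out
}

#' Mu-band motor-cortex ERD summary
#'
#' Unweighted mean of the ERD matrix over the mu frequencies (8-12 Hz) and
#' the five central electrodes over the leg motor area (Cz, C1, C2, C3, C4)
#' — 25 cells in total.
#'
#' @param m An `erd_matrix`.
#' @param electrodes,frequencies_hz Cells to average.
#' @return Mean ERD in percent.
#' @export
mu_motor_erd <- function(m, electrodes = c("CZ", "C1", "C2", "C3", "C4"),
                         frequencies_hz = mu_band()) {
  stopifnot(inherits(m, "erd_matrix"))
  ei <- match(toupper(electrodes), toupper(rownames(m)))
  fi <- match(as.character(frequencies_hz), colnames(m))
  if (anyNA(ei) || anyNA(fi))
    stop("ERD matrix does not cover the requested electrodes/frequencies",
         call. = FALSE)
  mean(m[ei, fi])
}

#' Histogram of optimal frequencies over standard bands
#'
#' Counts how many per-electrode optimal frequencies fall in each of the
#' three reporting bands: 6-12 Hz (high theta and mu), 13-20 Hz (low/mid
#' beta) and 21-30 Hz (high beta); band edges are integer-closed. With one
#' map per subject (9 electrodes each), counts sum to
#' `9 * n_subjects` — 63 for a 7-subject group-day.
#'
#' @param maps One `optimal_frequency_map` or a list of them (e.g. one per
#'   subject of a group-day).
#' @return Named integer vector of counts (`"6-12"`, `"13-20"`, `"21-30"`).
#' @export
optimal_frequency_histogram <- function(maps) {
  if (inherits(maps, "optimal_frequency_map")) maps <- list(maps)
  freqs <- unlist(lapply(maps, function(m) m$frequency_hz))
  if (any(freqs < 6 | freqs > 30))
    stop("optimal frequency outside the 6-30 Hz grid", call. = FALSE)
  counts <- c(`6-12` = sum(freqs <= 12),
              `13-20` = sum(freqs >= 13 & freqs <= 20),
              `21-30` = sum(freqs >= 21))
  storage.mode(counts) <- "integer"
  counts
}

#' Cohort accuracy summary
#'
#' Summarizes per-session real-time accuracies the way study results are
#' reported: the multi-day mean per subject and the group mean with its
#' standard deviation across subjects (n/a for a single subject).
#'
#' @param acc Data frame with columns `subject`, `day`, `accuracy_pct` and
#'   optionally `group` (a single group is assumed if absent). Every subject
#'   must have every day.
#' @return A list of class `accuracy_summary`: `per_subject` (subject,
#'   group, mean accuracy) and `per_group` (group, mean, sd, n_subjects).
#' @export
accuracy_summary <- function(acc) {
  stopifnot(is.data.frame(acc),
            all(c("subject", "day", "accuracy_pct") %in% names(acc)))
  if (any(acc$accuracy_pct < 0 | acc$accuracy_pct > 100))
    stop("accuracies must lie in [0, 100]", call. = FALSE)
  if (is.null(acc$group)) acc$group <- "all"
  days <- sort(unique(acc$day))
  combos <- split(acc, list(acc$group, acc$subject), drop = TRUE)
  for (g in combos)
    if (!setequal(g$day, days))
      stop("incomplete cohort: subject ", g$subject[1], " (", g$group[1],
           ") is missing days", call. = FALSE)
  per_subject <- do.call(rbind, lapply(combos, function(g)
    data.frame(group = g$group[1], subject = g$subject[1],
               mean_accuracy_pct = mean(g$accuracy_pct),
               stringsAsFactors = FALSE)))
  per_subject <- per_subject[order(per_subject$group, per_subject$subject), ]
  rownames(per_subject) <- NULL
  per_group <- do.call(rbind, lapply(split(per_subject, per_subject$group),
                                     function(g)
    data.frame(group = g$group[1],
               mean_accuracy_pct = mean(g$mean_accuracy_pct),
               sd_accuracy_pct = if (nrow(g) > 1) stats::sd(g$mean_accuracy_pct)
                                 else NA_real_,
               n_subjects = nrow(g), stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  structure(list(per_subject = per_subject, per_group = per_group),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("Per-subject multi-day mean real-time accuracy (%):\n")
  print(x$per_subject, row.names = FALSE)
  cat("\nGroup summary:\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
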