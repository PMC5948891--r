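#' Standard 10-10 electrode layout used by the package
#'
#' Idealized scalp positions for the 30-channel acquisition montage. Each
#' electrode is placed on a unit sphere from two angles of the 10-10 grid
#' (lateral angle from the midline, anterior angle from the central coronal
#' plane, in steps of about 18-20 degrees per 10% arc division) and projected
#' to the plane with an azimuthal equidistant projection about the vertex, so
#' planar distance is proportional to arc length from Cz. The units are
#' radians of scalp arc; only relative distances are ever used (Laplacian
#' weighting, synthetic source projection).
#'
#' @param labels Optional subset of channel labels to return, in that order.
#' @return A data frame with columns `label`, `x`, `y` (projected plane
#'   coordinates, radians; +x right, +y anterior).
#' @examples
#' head(electrode_positions())
#' @export
electrode_positions <- function(labels = NULL) {
  tab <- montage_angles()
  lat <- tab$lat * pi / 180
  ant <- tab$ant * pi / 180
  vx <- sin(lat)
  vy <- cos(lat) * sin(ant)
  vz <- cos(lat) * cos(ant)
  gamma <- acos(pmin(1, pmax(-1, vz)))      # arc distance from vertex
  hyp <- sqrt(vx^2 + vy^2)
  scale <- ifelse(hyp > 0, gamma / hyp, 0)
  out <- data.frame(label = tab$label, x = vx * scale, y = vy * scale,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    idx <- match(toupper(labels), out$label)
    if (anyNA(idx))
      stop("unknown electrode label(s): ",
           paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Angular grid: lat = lateral angle (deg, +right of midline), ant = anterior
# angle (deg, + in front of the central coronal plane).
montage_angles <- function() {
  data.frame(
    label = c("FP1", "FP2", "AF3", "AF4", "F3", "FZ", "F4",
              "FC5", "FC1", "FC2", "FC6",
              "C3", "C1", "CZ", "C2", "C4",
              "CP5", "CP1", "CP2", "CP6",
              "P7", "P3", "PZ", "P4", "P8",
              "PO3", "PO4", "O1", "OZ", "O2"),
    lat = c(-18, 18, -25, 25, -40, 0, 40,
            -60, -20, 20, 60,
            -40, -20, 0, 20, 40,
            -60, -20, 20, 60,
            -65, -40, 0, 40, 65,
            -25, 25, -18, 0, 18),
    ant = c(72, 72, 54, 54, 36, 36, 36,
            18, 18, 18, 18,
            0, 0, 0, 0, 0,
            -18, -18, -18, -18,
            -36, -36, -36, -36, -36,
            -54, -54, -72, -72, -72),
    stringsAsFactors = FALSE
  )
}

#' Default channel sets
#'
#' `acquisition_channels()` lists the 30 channels of the recording montage;
#' `motor_electrodes()` the nine central electrodes over premotor, motor and
#' somatosensory cortex kept for classification (Cz, CP1, CP2, C1, C2, C3,
#' C4, FC1, FC2); `mu_band()` the 8-12 Hz mu frequencies and
#' `feature_frequencies()` the 6-30 Hz analysis grid at 1 Hz resolution.
#'
#' @return Character vector of labels, or integer vector of frequencies (Hz).
#' @export
acquisition_channels <- function() {
  c("P7", "P4", "CZ", "PZ", "P3", "P8", "O1", "O2", "C2", "C4", "F4", "FP2",
    "FZ", "C3", "F3", "FP1", "C1", "OZ", "PO4", "FC6", "FC2", "AF4", "CP6",
    "CP2", "CP1", "CP5", "FC1", "FC5", "AF3", "PO3")
}

#' @rdname acquisition_channels
#' @export
motor_electrodes <- function() {
  c("CZ", "CP1", "CP2", "C1", "C2", "C3", "C4", "FC1", "FC2")
}

#' @rdname acquisition_channels
#' @export
mu_band <- function() 8:12

#' @rdname acquisition_channels
#' @export
feature_frequencies <- function() 6:30
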