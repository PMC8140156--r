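#' Retrospective cine phases per cardiac cycle
#'
#' Number of reconstructed phases of a segmented cine acquisition. The
#' implemented reading divides the cardiac cycle duration by the segment
#' block duration (TR x segments) and doubles it (view sharing):
#' \code{p = floor((60/HR) / (TR_s x segments) x 2)}, which reproduces the
#' protocol's 25-40 phase range at the cohort's heart rates. The literal
#' one-line formula \code{p = 60/(HR x TR) x 2} is retained behind
#' \code{literal = TRUE}; with TR in milliseconds or seconds it falls far
#' outside that range, so it is provided for reference only. Out-of-range
#' results are returned with a warning, not clamped.
#'
#' @param hr Heart rate (beats/min).
#' @param tr Repetition time (ms).
#' @param segments Number of segments (k-space lines per cardiac phase per
#'   heartbeat).
#' @param literal Use the literal formula instead of the segment-block
#'   interpretation.
#' @return Number of phases (integer for the default interpretation).
#' @export
phases_per_cycle <- function(hr, tr = 6.48, segments = 5, literal = FALSE) {
  stopifnot(hr > 0, tr > 0, segments >= 1)
  if (literal) return(60 / (hr * tr) * 2)
  p <- floor((60 / hr) / (tr / 1000 * segments) * 2)
  if (p < 25 || p > 40)
    warning("phases per cycle (", p, ") outside the typical 25-40 range")
  p
}

#' Radial Nyquist undersampling factor
#'
#' Ratio of the number of spokes required for Nyquist sampling of a radial
#' acquisition, \code{pi/2 x base_resolution}, to the spokes actually
#' acquired per frame; reported to one decimal.
#'
#' @param base_resolution Base matrix size.
#' @param spokes_per_frame Radial spokes acquired per frame (>= 1).
#' @return Dimensionless undersampling factor, rounded to one decimal.
#' @export
radial_undersampling_factor <- function(base_resolution, spokes_per_frame) {
  stopifnot(base_resolution > 0, spokes_per_frame >= 1)
  round((pi / 2 * base_resolution) / spokes_per_frame, 1)
}

#' Real-time frame and slice timing
#'
#' @param tr Repetition time per spoke (ms).
#' @param spokes_per_frame Spokes per frame.
#' @param frames_per_slice Frames per slice.
#' @return List with \code{frame_time_ms} (TR x spokes) and
#'   \code{slice_scan_time_s} (frame time x frames).
#' @export
rt_frame_timing <- function(tr = 2.89, spokes_per_frame = 13,
                            frames_per_slice = 210) {
  stopifnot(tr > 0, spokes_per_frame >= 1, frames_per_slice >= 1)
  ft <- tr * spokes_per_frame
  list(frame_time_ms = ft,
       slice_scan_time_s = ft * frames_per_slice / 1000)
}

#' Cine per-slice pure acquisition time
#'
#' Data for one cine slice are recorded over a fixed number of heartbeats,
#' so the pure acquisition time per slice is \code{heartbeats x 60 / HR}
#' seconds.
#'
#' @param hr Heart rate (beats/min).
#' @param heartbeats Heartbeats recorded per slice.
#' @return Acquisition time per slice (s).
#' @export
cine_slice_time <- function(hr, heartbeats = 26) {
  stopifnot(hr > 0, heartbeats >= 1)
  heartbeats * 60 / hr
}
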