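#' Analytic beating-ventricle phantom model
#'
#' Defines the ground-truth left ventricle used by the synthetic-data
#' generator: a truncated half-ellipsoid cavity surrounded by an
#' incompressible myocardial shell, contracting periodically at the heart
#' rate and modulated by pressure-controlled ventilation (higher EDV/ESV
#' during inspiration).
#'
#' The cavity at end-diastole during expiration is a half-ellipsoid
#' (apex to equatorial base plane) with long semi-axis \code{long_axis_mm}
#' and short semi-axis \code{short_axis_mm}, so its analytic volume is
#' \eqn{V = (2/3)\pi a^2 c}. When \code{short_axis_mm} is omitted it is
#' derived from \code{edv_exp} so that the analytic volume matches exactly.
#'
#' @param edv_exp End-diastolic cavity volume during expiration (mL).
#' @param esv_exp End-systolic cavity volume during expiration (mL).
#' @param insp_gain_edv,insp_gain_esv Fractional increase of EDV / ESV during
#'   inspiration relative to expiration (0 to 0.5).
#' @param wall_volume Myocardial shell volume (mL), conserved over the cycle.
#' @param pm_volume Total papillary-muscle volume (mL).
#' @param hr Heart rate (beats/min), 40 to 200.
#' @param resp_rate Ventilation rate (breaths/min); 0 emulates breath hold.
#' @param insp_fraction Fraction of the breath cycle spent in inspiration
#'   (ramp up plus inspiratory plateau).
#' @param systole_fraction Fraction of the cardiac cycle occupied by the
#'   contraction from ED to ES.
#' @param long_axis_mm Long semi-axis of the cavity at ED-expiration (mm);
#'   equals the apex-to-base cavity length.
#' @param short_axis_mm Short semi-axis (mm); derived from \code{edv_exp}
#'   when \code{NULL}, otherwise checked for consistency (0.1%).
#' @param ramp_fraction Fraction of the breath cycle taken by each
#'   (cosine-eased) transition ramp of the trapezoidal respiratory profile.
#' @param hr_jitter,resp_jitter Optional beat-to-beat / breath-to-breath
#'   period variability (fractional s.d. of log-normal cycle durations);
#'   default 0 (none).
#' @param jitter_seed Seed for the jittered cycle boundaries (only used when
#'   a jitter is positive).
#' @return An object of class \code{ventricle_model}.
#' @examples
#' m <- ventricle_model()
#' cavity_volume_at(m, 0)   # EDV at expiration
#' @export
ventricle_model <- function(edv_exp = 14.8, esv_exp = 6.3,
                            insp_gain_edv = 0.15, insp_gain_esv = 0.15,
                            wall_volume = 11.2, pm_volume = 0.62,
                            hr = 105, resp_rate = 8,
                            insp_fraction = 0.4, systole_fraction = 0.35,
                            long_axis_mm = 41, short_axis_mm = NULL,
                            ramp_fraction = 0.15,
                            hr_jitter = 0, resp_jitter = 0,
                            jitter_seed = 1L) {
  stopifnot(edv_exp > esv_exp, esv_exp > 0,
            insp_gain_edv >= 0, insp_gain_edv <= 0.5,
            insp_gain_esv >= 0, insp_gain_esv <= 0.5,
            pm_volume < wall_volume, wall_volume > 0,
            hr >= 40, hr <= 200, resp_rate >= 0,
            insp_fraction > 0, insp_fraction < 1,
            systole_fraction > 0, systole_fraction < 1,
            long_axis_mm > 0, ramp_fraction > 0,
            insp_fraction > ramp_fraction,
            insp_fraction + ramp_fraction < 1)
  a_derived <- sqrt(3 * edv_exp * 1000 / (2 * pi * long_axis_mm))
  if (is.null(short_axis_mm)) {
    short_axis_mm <- a_derived
  } else {
    v_analytic <- (2 / 3) * pi * short_axis_mm^2 * long_axis_mm / 1000
    if (abs(v_analytic - edv_exp) / edv_exp > 1e-3)
      stop("short_axis_mm inconsistent with edv_exp: analytic cavity volume ",
           signif(v_analytic, 5), " mL differs from edv_exp by more than 0.1%")
  }
  stopifnot(hr_jitter >= 0, resp_jitter >= 0)
  beat_times <- breath_times <- NULL
  if (hr_jitter > 0 || resp_jitter > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(jitter_seed)
    if (hr_jitter > 0)
      beat_times <- cumsum(c(0, (60 / hr) *
                               exp(stats::rnorm(20000, 0, hr_jitter))))
    if (resp_jitter > 0 && resp_rate > 0)
      breath_times <- cumsum(c(0, (60 / resp_rate) *
                                 exp(stats::rnorm(4000, 0, resp_jitter))))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  structure(list(edv_exp = edv_exp, esv_exp = esv_exp,
                 insp_gain_edv = insp_gain_edv, insp_gain_esv = insp_gain_esv,
                 wall_volume = wall_volume, pm_volume = pm_volume,
                 hr = hr, resp_rate = resp_rate,
                 insp_fraction = insp_fraction,
                 systole_fraction = systole_fraction,
                 long_axis_mm = long_axis_mm, short_axis_mm = short_axis_mm,
                 ramp_fraction = ramp_fraction,
                 hr_jitter = hr_jitter, resp_jitter = resp_jitter,
                 beat_times = beat_times, breath_times = breath_times),
            class = "ventricle_model")
}

#' @export
print.ventricle_model <- function(x, ...) {
  cat("Analytic ventricle phantom\n")
  cat(sprintf("  EDV/ESV (expiration): %.1f / %.1f mL  (EF %.0f%%)\n",
              x$edv_exp, x$esv_exp, 100 * (1 - x$esv_exp / x$edv_exp)))
  cat(sprintf("  inspiratory gain EDV/ESV: %.0f%% / %.0f%%\n",
              100 * x$insp_gain_edv, 100 * x$insp_gain_esv))
  cat(sprintf("  wall %.1f mL, papillary %.2f mL\n", x$wall_volume, x$pm_volume))
  cat(sprintf("  HR %g bpm, ventilation %g /min (insp fraction %.2f)\n",
              x$hr, x$resp_rate, x$insp_fraction))
  cat(sprintf("  cavity semi-axes %.1f (long) x %.1f (short) mm\n",
              x$long_axis_mm, x$short_axis_mm))
  invisible(x)
}

#' Respiratory activation profile
#'
#' Trapezoidal ventilation profile with cosine-eased ramps: 1 on the
#' inspiratory plateau, 0 on the expiratory plateau. With
#' \code{resp_rate = 0} the lung is held at expiration (activation 0).
#'
#' @param model A \code{ventricle_model}.
#' @param t Time in seconds (vectorised).
#' @return Activation in [0, 1].
#' @export
resp_activation <- function(model, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (model$resp_rate <= 0) return(rep(0, length(t)))
  psi <- cycle_phase(t, 60 / model$resp_rate, model$breath_times)
  ramp <- model$ramp_fraction
  fi <- model$insp_fraction
  a <- numeric(length(psi))
  up <- psi < ramp
  a[up] <- (1 - cos(pi * psi[up] / ramp)) / 2
  plateau <- psi >= ramp & psi < fi
  a[plateau] <- 1
  down <- psi >= fi & psi < fi + ramp
  a[down] <- (1 + cos(pi * (psi[down] - fi) / ramp)) / 2
  a
}

# fractional phase within the current cycle, from either a fixed period or
# precomputed (jittered) cycle boundary times
cycle_phase <- function(t, period, boundaries = NULL) {
  if (is.null(boundaries)) return((t / period) %% 1)
  k <- findInterval(t, boundaries)
  k[k < 1] <- 1
  (t - boundaries[k]) / (boundaries[k + 1] - boundaries[k])
}

# end-diastole / end-systole event times falling inside a time window
ed_es_times <- function(model, w0, w1) {
  sf <- model$systole_fraction
  if (is.null(model$beat_times)) {
    tc <- 60 / model$hr
    ks <- seq(ceiling(w0 / tc), floor(w1 / tc))
    ks <- ks[ks >= 0]
    data.frame(ed = ks * tc, es = (ks + sf) * tc)
  } else {
    bt <- model$beat_times
    i <- which(bt >= w0 & bt <= w1)
    i <- i[i < length(bt)]
    data.frame(ed = bt[i], es = bt[i] + sf * (bt[i + 1] - bt[i]))
  }
}

# cardiac shape factor: 1 at ED (phase 0), 0 at ES (phase = systole_fraction),
# cosine-eased contraction and relaxation limbs
cardiac_shape <- function(model, t) {
  phi <- cycle_phase(t, 60 / model$hr, model$beat_times)
  sf <- model$systole_fraction
  f <- numeric(length(phi))
  sys <- phi < sf
  f[sys] <- (1 + cos(pi * phi[sys] / sf)) / 2
  f[!sys] <- (1 - cos(pi * (phi[!sys] - sf) / (1 - sf))) / 2
  f
}

#' True cavity volume at a time point
#'
#' Evaluates the analytic cavity volume waveform: a smooth periodic
#' contraction between the phase-appropriate EDV and ESV, with both volumes
#' scaled up by the inspiratory gains while the respiratory activation is
#' high.
#'
#' @param model A \code{ventricle_model}.
#' @param t Time in seconds (vectorised, finite, non-negative).
#' @return Cavity volume in mL.
#' @export
cavity_volume_at <- function(model, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  a <- resp_activation(model, t)
  edv <- model$edv_exp * (1 + model$insp_gain_edv * a)
  esv <- model$esv_exp * (1 + model$insp_gain_esv * a)
  f <- cardiac_shape(model, t)
  esv + (edv - esv) * f
}

#' Default acquisition geometry
#'
#' Short-axis stack geometry of the real-time protocol: 12-14 slices of
#' 3 mm with a 0.3-0.6 mm gap, 0.9 x 0.9 mm in-plane resolution and 210
#' frames of 37 ms per slice, slices acquired sequentially (each slice's
#' frames therefore belong to different heart cycles).
#'
#' @param n_slices Number of short-axis slices (apex first).
#' @param slice_thickness Slice thickness (mm).
#' @param slice_gap Inter-slice gap (mm).
#' @param pixel_spacing In-plane pixel spacing (mm), length-2.
#' @param frames_per_slice Frames acquired per slice.
#' @param frame_duration Acquisition time per frame (ms).
#' @param matrix_size In-plane matrix size (pixels, square).
#' @param sequential_slices Logical; slices acquired one after another.
#' @return An object of class \code{acquisition_geometry}.
#' @export
acquisition_geometry <- function(n_slices = 13, slice_thickness = 3,
                                 slice_gap = 0.5,
                                 pixel_spacing = c(0.9, 0.9),
                                 frames_per_slice = 210, frame_duration = 37,
                                 matrix_size = 64,
                                 sequential_slices = TRUE) {
  stopifnot(slice_thickness > 0, slice_gap >= 0, frames_per_slice >= 1,
            n_slices >= 3, all(pixel_spacing > 0), length(pixel_spacing) == 2,
            frame_duration > 0, matrix_size >= 8)
  structure(list(n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 pixel_spacing = pixel_spacing,
                 frames_per_slice = as.integer(frames_per_slice),
                 frame_duration = frame_duration,
                 matrix_size = as.integer(matrix_size),
                 sequential_slices = isTRUE(sequential_slices)),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("Short-axis acquisition: %d slices x %d frames, %g mm + %g mm gap,\n",
              x$n_slices, x$frames_per_slice, x$slice_thickness, x$slice_gap))
  cat(sprintf("  %g x %g mm pixels (%d x %d), %g ms/frame, %s slice ordering\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$matrix_size,
              x$matrix_size, x$frame_duration,
              if (x$sequential_slices) "sequential" else "interleaved"))
  invisible(x)
}

#' Mid-acquisition frame times for a slice
#'
#' @param geom An \code{acquisition_geometry}.
#' @param slice Slice index (1 = apex).
#' @param mode \code{"rt"} (sequential real time) or \code{"cine"}
#'   (retrospective phases of one averaged cycle; requires \code{hr}).
#' @param hr Heart rate (beats/min), needed for cine phase times.
#' @return Numeric vector of times (s), one per frame.
#' @export
frame_times <- function(geom, slice, mode = c("rt", "cine"), hr = NULL) {
  mode <- match.arg(mode)
  j <- seq_len(geom$frames_per_slice) - 1
  if (mode == "cine") {
    if (is.null(hr)) stop("hr required for cine frame times")
    tc <- 60 / hr
    return((j + 0.5) / geom$frames_per_slice * tc)
  }
  dt <- geom$frame_duration / 1000
  offset <- if (geom$sequential_slices) (slice - 1) * geom$frames_per_slice else 0
  (offset + j + 0.5) * dt
}
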