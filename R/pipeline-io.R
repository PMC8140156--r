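#' Write a mask series as NIfTI plus JSON sidecar
#'
#' The 4D label volume (x, y, slice, frame) is written as integer NIfTI
#' with the voxel dimensions in the header; the acquisition parameters that
#' NIfTI cannot carry (frame duration, slice gap, label map, mode) go into
#' a JSON sidecar next to it.
#'
#' @param series A \code{mask_series}.
#' @param prefix Output path prefix; writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>.json}.
#' @return The prefix, invisibly.
#' @export
write_mask_series <- function(series, prefix) {
  geom <- series$geom
  arr <- array(as.integer(series$data), dim = dim(series$data))
  attr(arr, "pixdim") <- c(geom$pixel_spacing,
                           geom$slice_thickness + geom$slice_gap,
                           geom$frame_duration / 1000)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  sidecar <- list(
    labels = as.list(series$labels),
    frame_duration = geom$frame_duration,
    slice_thickness = geom$slice_thickness,
    slice_gap = geom$slice_gap,
    pixel_spacing = geom$pixel_spacing,
    n_slices = geom$n_slices,
    frames_per_slice = geom$frames_per_slice,
    matrix_size = geom$matrix_size,
    sequential_slices = geom$sequential_slices,
    mode = series$mode,
    hr = series$hr)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a mask series written by \code{write_mask_series}
#'
#' Validates the sidecar (all required fields present), the label values
#' (integers from the declared map) and the volume dimensions against the
#' declared slice/frame counts; frame timestamps are reconstructed from the
#' geometry.
#'
#' @param prefix Path prefix used at write time.
#' @return A \code{mask_series}.
#' @export
read_mask_series <- function(prefix) {
  nii_path <- paste0(prefix, ".nii.gz")
  json_path <- paste0(prefix, ".json")
  if (!file.exists(nii_path)) stop("missing volume file: ", nii_path)
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path)
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("labels", "frame_duration", "slice_thickness", "slice_gap",
                "pixel_spacing", "n_slices", "frames_per_slice",
                "matrix_size", "sequential_slices", "mode")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop("sidecar missing field(s): ", paste(missing, collapse = ", "))
  arr <- as.array(RNifti::readNifti(nii_path))
  d <- dim(arr)
  if (length(d) != 4)
    stop("expected a 4D volume, got ", length(d), " dimensions")
  if (d[3] != sc$n_slices)
    stop("inconsistent slice count: volume has ", d[3],
         " slices, sidecar declares ", sc$n_slices)
  if (d[4] != sc$frames_per_slice)
    stop("truncated volume: ", d[4], " frames found at slice dimension 4, ",
         "sidecar declares ", sc$frames_per_slice)
  labels <- unlist(sc$labels)
  if (any(arr != round(arr)))
    stop("non-integer labels in volume")
  bad <- setdiff(unique(as.vector(arr)), unname(labels))
  if (length(bad))
    stop("label value(s) not in sidecar label map: ",
         paste(bad, collapse = ", "))
  geom <- acquisition_geometry(
    n_slices = sc$n_slices, slice_thickness = sc$slice_thickness,
    slice_gap = sc$slice_gap, pixel_spacing = sc$pixel_spacing,
    frames_per_slice = sc$frames_per_slice,
    frame_duration = sc$frame_duration, matrix_size = sc$matrix_size,
    sequential_slices = sc$sequential_slices)
  hr <- if (!is.null(sc$hr)) sc$hr else NULL
  tmat <- t(vapply(seq_len(geom$n_slices), function(s)
    frame_times(geom, s, mode = sc$mode, hr = hr),
    numeric(geom$frames_per_slice)))
  structure(list(data = array(as.integer(arr), dim = d), geom = geom,
                 labels = stats::setNames(as.integer(labels), names(labels)),
                 mode = sc$mode, hr = hr, frame_times = tmat),
            class = "mask_series")
}

#' Write phantom ground truth as CSV + JSON
#'
#' @param truth A \code{phantom_truth}.
#' @param prefix Output prefix; writes \code{<prefix>_frames.csv},
#'   \code{<prefix>_events.csv} and \code{<prefix>_truth.json}.
#' @return The prefix, invisibly.
#' @export
write_phantom_truth <- function(truth, prefix) {
  utils::write.csv(truth$per_frame, paste0(prefix, "_frames.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$events, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  scalars <- list(phases = truth$phases, wall_volume = truth$wall_volume,
                  pm_volume = truth$pm_volume, hr = truth$hr,
                  resp_rate = truth$resp_rate, mode = truth$mode)
  jsonlite::write_json(scalars, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults equal to
#' the documented design decisions.
#'
#' @param n_subjects Number of simulated subjects (when no input is given).
#' @param input_prefixes Optional character vector of mask-series prefixes
#'   to analyse instead of simulating.
#' @param mode Acquisition mode for simulation.
#' @param model Base \code{ventricle_model} for the cohort.
#' @param geom \code{acquisition_geometry} used throughout.
#' @param low,high Respiratory classification thresholds.
#' @param pm_mode,density,disk_height,icc_form,min_enclosure Analysis
#'   settings (see the respective functions).
#' @param edv_spread,ef_spread,hr_range Cohort parameter spread: log-normal
#'   s.d. of EDV, s.d. of the logit-scale EF perturbation, and the uniform
#'   heart-rate range (beats/min).
#' @param seed Seed for all randomness.
#' @param out_dir Output directory.
#' @param verbose Print log lines to the console as well.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(n_subjects = 10, input_prefixes = NULL, mode = "rt",
                       model = ventricle_model(),
                       geom = acquisition_geometry(),
                       low = 0.3, high = 0.7,
                       pm_mode = "pm_in_cavity", density = 1.05,
                       disk_height = "thickness_plus_gap",
                       icc_form = "ICC2_1", min_enclosure = 0.5,
                       edv_spread = 0.15, ef_spread = 0.05,
                       hr_range = c(79, 134),
                       seed = 1L, out_dir = tempfile("rtlv_run_"),
                       verbose = FALSE) {
  structure(list(n_subjects = n_subjects, input_prefixes = input_prefixes,
                 mode = mode, model = model, geom = geom, low = low,
                 high = high, pm_mode = pm_mode, density = density,
                 disk_height = disk_height, icc_form = icc_form,
                 min_enclosure = min_enclosure, edv_spread = edv_spread,
                 ef_spread = ef_spread, hr_range = hr_range,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

# short deterministic FNV-1a hash of the resolved settings, carried as
# provenance in every output row
settings_hash <- function(config) {
  keep <- config[c("mode", "low", "high", "pm_mode", "density",
                   "disk_height", "icc_form", "min_enclosure",
                   "edv_spread", "ef_spread", "seed")]
  s <- paste(names(keep), vapply(keep, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1e9
  sprintf("%09d", h)
}

# draw a cohort of per-subject phantom models around the base model
cohort_models <- function(config) {
  base <- config$model
  lapply(seq_len(config$n_subjects), function(i) {
    scale_edv <- exp(stats::rnorm(1, 0, config$edv_spread))
    ef0 <- 1 - base$esv_exp / base$edv_exp
    ef <- stats::plogis(stats::qlogis(ef0) +
                          stats::rnorm(1, 0, config$ef_spread * 4))
    edv <- base$edv_exp * scale_edv
    ventricle_model(
      edv_exp = edv, esv_exp = edv * (1 - ef),
      insp_gain_edv = base$insp_gain_edv,
      insp_gain_esv = base$insp_gain_esv,
      wall_volume = base$wall_volume * scale_edv,
      pm_volume = base$pm_volume * scale_edv,
      hr = round(stats::runif(1, config$hr_range[1], config$hr_range[2])),
      resp_rate = base$resp_rate, insp_fraction = base$insp_fraction,
      systole_fraction = base$systole_fraction,
      long_axis_mm = base$long_axis_mm)
  })
}

#' Sort a real-time mask series into labelled heart cycles
#'
#' Runs the cardiorespiratory sorting for every slice of a series: the
#' blood-pool area trace provides the ED/ES events, the liver-area trace
#' the respiratory labels. Slices whose blood signal is too weak for
#' detection (outside the ventricle) are skipped.
#'
#' @param series A \code{mask_series}.
#' @param hr_hint Heart rate hint for peak detection (defaults to the
#'   series' recorded rate).
#' @param low,high Respiratory thresholds.
#' @return A \code{cycle_events} data frame covering all analysable slices.
#' @export
sort_series <- function(series, hr_hint = NULL, low = 0.3, high = 0.7) {
  if (is.null(hr_hint)) hr_hint <- series$hr
  if (is.null(hr_hint)) stop("heart-rate hint required")
  S <- series$geom$n_slices
  res <- lapply(seq_len(S), function(s) {
    lv <- extract_roi_signal(series, "blood", s)
    liver <- extract_roi_signal(series, "liver", s)
    tryCatch({
      ev <- detect_cardiac_phases(lv, hr_hint)
      labels <- classify_respiration(normalize_trace(liver), low, high)
      assemble_cycles(ev, labels, slice = s)
    }, error = function(e) NULL)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) stop("no analysable slices in series")
  class(out) <- c("cycle_events", "data.frame")
  out
}

#' Cine left-ventricular function
#'
#' The cine analysis path: ED and ES phases are picked from the cavity-area
#' curve of a mid-ventricular slice, then volumes and masses are computed
#' on those two phases over the included slice range.
#'
#' @param series A cine-mode \code{mask_series}.
#' @param hr Heart rate (beats/min) for cardiac output.
#' @inheritParams lv_function
#' @return An \code{lv_function} object with a single expiration row.
#' @export
lv_function_cine <- function(series, hr, pm_mode = "pm_in_cavity",
                             density = 1.05,
                             disk_height = "thickness_plus_gap",
                             min_enclosure = 0.5) {
  S <- series$geom$n_slices
  areas_mid <- vapply(seq_len(S), function(s)
    slice_area(series$data[, , s, 1], "cavity", pm_mode,
               series$geom$pixel_spacing, series$labels), numeric(1))
  mid <- which.max(areas_mid)
  curve <- vapply(seq_len(dim(series$data)[4]), function(f)
    slice_area(series$data[, , mid, f], "cavity", pm_mode,
               series$geom$pixel_spacing, series$labels), numeric(1))
  phases <- cine_ed_es_frames(curve)
  cyc <- data.frame(slice = seq_len(S), cycle = 1,
                    ed_frame = phases[["ed"]], es_frame = phases[["es"]],
                    resp_phase = "expiration", valid = TRUE)
  class(cyc) <- c("cycle_events", "data.frame")
  lv_function(series, cyc, hr = hr, pm_mode = pm_mode, density = density,
              phases = "expiration", disk_height = disk_height,
              min_enclosure = min_enclosure)
}

#' Run the full analysis pipeline
#'
#' Chains phantom simulation (or reading of supplied series), per-slice
#' cardiorespiratory sorting, per-phase volumetry and the
#' inspiration-versus-expiration agreement analysis into one reproducible
#' run. Writes four artifacts to the output directory: per-phase LV
#' function (\code{lv_function.csv}), a mid-ventricular beat-by-beat table
#' (\code{beat_by_beat.csv}), the agreement table (\code{agreement.csv})
#' and a timestamped log (\code{run.log}). Every output row carries the
#' subject, settings hash and seed as provenance; given a seed the CSV
#' outputs are byte-identical across runs.
#'
#' @param config A \code{run_config}.
#' @return Invisibly, a list with the three tables and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(level, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, paste0(...))
    writeLines(line, log_con)
    if (isTRUE(config$verbose)) message(line)
  }
  hash <- settings_hash(config)
  logmsg("INFO", "rtlv ", as.character(utils::packageVersion("rtlv")),
         " pipeline start; settings hash ", hash)
  for (k in c("mode", "low", "high", "pm_mode", "density", "disk_height",
              "icc_form", "min_enclosure", "seed"))
    logmsg("INFO", "config ", k, " = ", paste(format(config[[k]]),
                                              collapse = ","))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(config$input_prefixes)) {
    models <- stage("simulate", cohort_models(config))
    subjects <- lapply(seq_along(models), function(i)
      stage("simulate", render_mask_series(models[[i]], config$geom,
                                           mode = config$mode,
                                           noise_seed = config$seed + i)))
    sers <- lapply(subjects, `[[`, "series")
    hrs <- vapply(models, `[[`, numeric(1), "hr")
  } else {
    sers <- lapply(config$input_prefixes, function(p)
      stage("read", read_mask_series(p)))
    hrs <- vapply(sers, function(s)
      if (is.null(s$hr)) stop("series without heart rate") else s$hr,
      numeric(1))
  }
  logmsg("INFO", "analysing ", length(sers), " subject(s)")
  lv_rows <- list(); beat_rows <- list()
  for (i in seq_along(sers)) {
    cyc <- stage("sort", sort_series(sers[[i]], hr_hint = hrs[i],
                                     low = config$low, high = config$high))
    lf <- stage("quantify", lv_function(
      sers[[i]], cyc, hr = hrs[i], pm_mode = config$pm_mode,
      density = config$density, disk_height = config$disk_height,
      min_enclosure = config$min_enclosure))
    lf <- as.data.frame(lf)
    lf$subject <- i
    lf$settings_hash <- hash
    lf$seed <- config$seed
    lv_rows[[i]] <- lf
    mid <- unique(cyc$slice)[which.min(abs(unique(cyc$slice) -
                                             stats::median(unique(cyc$slice))))]
    bb <- stage("quantify", beat_by_beat_curve(sers[[i]], cyc, mid,
                                               pm_mode = config$pm_mode,
                                               disk_height = config$disk_height))
    bb <- as.data.frame(bb)
    bb$subject <- i
    bb$slice <- mid
    bb$settings_hash <- hash
    beat_rows[[i]] <- bb
    logmsg("INFO", "subject ", i, ": ", nrow(bb), " cycles on slice ", mid)
  }
  lv_tab <- do.call(rbind, lv_rows)
  beat_tab <- do.call(rbind, beat_rows)
  agree_tab <- NULL
  both <- c("inspiration", "expiration")
  n_both <- sum(vapply(split(lv_tab, lv_tab$subject), function(d)
    all(both %in% d$resp_phase), logical(1)))
  if (n_both >= 3) {
    long <- lv_tab[lv_tab$resp_phase %in% both,
                   c("subject", "resp_phase", "edv", "esv", "sv", "ef",
                     "lvwm")]
    long <- stats::reshape(long, direction = "long",
                           varying = c("edv", "esv", "sv", "ef", "lvwm"),
                           v.names = "value", timevar = "parameter",
                           times = c("edv", "esv", "sv", "ef", "lvwm"),
                           idvar = c("subject", "resp_phase"))
    names(long)[names(long) == "resp_phase"] <- "condition"
    long$condition <- factor(long$condition, levels = rev(both))
    agree_tab <- stage("compare",
                       compare_conditions(long, icc_form = config$icc_form))
    agree_tab <- as.data.frame(agree_tab)
    agree_tab$comparison <- "expiration_vs_inspiration"
    agree_tab$settings_hash <- hash
  } else {
    logmsg("WARN", "fewer than 3 subjects with both phases; ",
           "agreement analysis skipped")
    agree_tab <- data.frame()
  }
  paths <- c(lv_function = file.path(config$out_dir, "lv_function.csv"),
             beat_by_beat = file.path(config$out_dir, "beat_by_beat.csv"),
             agreement = file.path(config$out_dir, "agreement.csv"),
             log = log_path)
  utils::write.csv(lv_tab, paths[["lv_function"]], row.names = FALSE)
  utils::write.csv(beat_tab, paths[["beat_by_beat"]], row.names = FALSE)
  utils::write.csv(agree_tab, paths[["agreement"]], row.names = FALSE)
  logmsg("INFO", "pipeline complete")
  invisible(list(lv_function = lv_tab, beat_by_beat = beat_tab,
                 agreement = agree_tab, paths = paths))
}
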