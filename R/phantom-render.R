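#' Label codes used by the phantom and the volumetry routines
#'
#' @return Named integer vector mapping compartment names to label codes.
#' @export
lv_labels <- function() {
  c(background = 0L, blood = 1L, myocardium = 2L, papillary = 3L,
    liver = 4L, lung = 5L)
}

# tissue intensity constants (a.u.) for the two acquisition modes; the
# real-time blood/myocardium intensity ratio is 10% below the cine ratio
intensity_model <- function(mode = c("cine", "rt")) {
  mode <- match.arg(mode)
  blood <- if (mode == "rt") 180 else 200
  c(background = 0, blood = blood, myocardium = 100, papillary = 100,
    liver = 150, lung = 20)
}

# separable Gaussian blur of a matrix (reflective edge handling through
# row-normalised band matrices); used to soften label boundaries in rt mode
gaussian_blur <- function(m, sigma) {
  n <- nrow(m)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (d in -h:h) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx, idx + d)] <- w[d + h + 1]
    else K[cbind(idx - d, idx)] <- w[d + h + 1]
  }
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

# axial layout of the phantom within the slice stack: the cavity base plane
# is aligned with the nearest disk-cell boundary so that the stack tiles the
# cavity apex-to-base, with at least one slice beyond each end
phantom_layout <- function(model, geom) {
  delta <- geom$slice_thickness + geom$slice_gap
  lz <- geom$n_slices * delta
  cc <- model$long_axis_mm
  z_base <- delta * round((lz + cc) / 2 / delta)
  z_apex <- z_base - cc
  cap <- 2                                  # wall thickness beyond the apex, mm
  if (z_apex < 0 || (lz - z_base) < delta / 2)
    stop("slice stack does not cover the ventricle apex-to-base with margin")
  fov <- geom$matrix_size * geom$pixel_spacing[1]
  a_max <- model$short_axis_mm * sqrt(1 + model$insp_gain_edv)
  A_max <- sqrt((3 * model$wall_volume * 1000 / (2 * pi) +
                   a_max^2 * cc) / (cc + cap))
  if (A_max > fov / 2 - 1)
    stop("in-plane FOV too small to contain the ventricle: need > ",
         signif(2 * (A_max + 1), 3), " mm")
  list(delta = delta, z_base = z_base, z_apex = z_apex, cap = cap,
       slice_z = (seq_len(geom$n_slices) - 0.5) * delta, fov = fov,
       y_liver = -0.35 * fov, liver_excursion = 0.1 * fov)
}

# in-plane squared radii of the endo- and epicardial boundaries for one
# slice at cavity volume v (mL); myocardium is incompressible
phantom_radii <- function(model, layout, slice_z, v) {
  cc <- model$long_axis_mm
  a2 <- model$short_axis_mm^2 * v / model$edv_exp
  h_in <- slice_z - layout$z_apex
  rin2 <- if (h_in > 0 && h_in < cc && slice_z <= layout$z_base)
    a2 * (1 - ((h_in - cc) / cc)^2) else 0
  C <- cc + layout$cap
  h_out <- slice_z - (layout$z_base - C)
  A2 <- (3 * model$wall_volume * 1000 / (2 * pi) + a2 * cc) / C
  rout2 <- if (h_out > 0 && h_out < C && slice_z <= layout$z_base)
    A2 * (1 - ((h_out - C) / C)^2) else 0
  list(rin2 = max(rin2, 0), rout2 = max(rout2, 0))
}

# papillary cylinder parameters: two cylinders attached to the endocardial
# wall over the mid 40% of the long axis, total volume pm_volume
pm_params <- function(model) {
  cc <- model$long_axis_mm
  len <- 0.4 * cc
  r <- sqrt(model$pm_volume * 1000 / (2 * pi * len))
  list(h_lo = 0.25 * cc, h_hi = 0.25 * cc + len, r = r,
       angles = c(3, -3) * pi / 4)
}

#' Render a synthetic short-axis label-mask series
#'
#' Voxelises the analytic phantom onto the acquisition grid, sampling the
#' model at the true acquisition time of every frame. In \code{rt} mode the
#' slices are acquired sequentially so each slice's frames belong to
#' different heart cycles, and label boundaries are degraded by Gaussian
#' smoothing of the boundary probability map before thresholding (emulating
#' the lower sharpness and systematic boundary under-segmentation of
#' real-time imaging). In \code{cine} mode the frames are retrospective
#' phases of a single averaged cycle acquired during an expiratory breath
#' hold (no respiratory modulation).
#'
#' @param model A \code{ventricle_model}.
#' @param geom An \code{acquisition_geometry}.
#' @param mode \code{"rt"} or \code{"cine"}.
#' @param noise_seed Integer seed governing all randomness of the render.
#' @param rt_sigma Boundary smoothing s.d. in pixels (rt mode).
#' @param rt_threshold Threshold applied to the smoothed boundary
#'   probability map; values above 0.5 erode the segmented compartments
#'   slightly, reproducing the real-time under-segmentation bias.
#' @return A list with components \code{series} (a \code{mask_series}) and
#'   \code{truth} (a \code{phantom_truth} with per-frame volumes and labels,
#'   cardiac events per slice, and per-phase true parameters).
#' @export
render_mask_series <- function(model, geom, mode = c("rt", "cine"),
                               noise_seed = 1L, rt_sigma = 1.2,
                               rt_threshold = 0.55) {
  mode <- match.arg(mode)
  layout <- phantom_layout(model, geom)
  lab <- lv_labels()
  n <- geom$matrix_size
  px <- geom$pixel_spacing[1]
  coord <- ((seq_len(n) - 0.5) * px) - layout$fov / 2
  X <- matrix(coord, n, n)
  Y <- matrix(coord, n, n, byrow = TRUE)
  R2 <- X^2 + Y^2
  pm <- pm_params(model)
  cine <- mode == "cine"
  eff_model <- if (cine) {
    m2 <- model; m2$resp_rate <- 0; m2
  } else model
  S <- geom$n_slices; Fn <- geom$frames_per_slice
  arr <- array(lab[["lung"]], dim = c(n, n, S, Fn))
  tmat <- matrix(0, S, Fn)
  vol <- act <- matrix(0, S, Fn)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(noise_seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (s in seq_len(S)) {
    tt <- frame_times(geom, s, mode = mode, hr = model$hr)
    tmat[s, ] <- tt
    a_s <- resp_activation(eff_model, tt)
    v_s <- cavity_volume_at(eff_model, tt)
    act[s, ] <- a_s
    vol[s, ] <- v_s
    for (j in seq_len(Fn)) {
      rr <- phantom_radii(eff_model, layout, layout$slice_z[s], v_s[j])
      img <- matrix(lab[["lung"]], n, n)
      y_int <- layout$y_liver - layout$liver_excursion * a_s[j]
      img[Y < y_int] <- lab[["liver"]]
      if (rr$rout2 > 0) {
        if (!cine) {
          outm <- gaussian_blur((R2 <= rr$rout2) + 0, rt_sigma) >= rt_threshold
          cavm <- if (rr$rin2 > 0)
            gaussian_blur((R2 <= rr$rin2) + 0, rt_sigma) >= rt_threshold
          else matrix(FALSE, n, n)
        } else {
          outm <- R2 <= rr$rout2
          cavm <- if (rr$rin2 > 0) R2 <= rr$rin2 else matrix(FALSE, n, n)
        }
        img[outm] <- lab[["myocardium"]]
        img[cavm] <- lab[["blood"]]
        h_in <- layout$slice_z[s] - layout$z_apex
        # the papillary cross-section shrinks slightly with cavity volume:
        # at end-systole the contracted muscle partly merges with the wall,
        # so less of it protrudes into the blood pool
        r_pm <- pm$r * (v_s[j] / model$edv_exp)^0.1
        if (rr$rin2 > 0 && h_in >= pm$h_lo && h_in <= pm$h_hi &&
            sqrt(rr$rin2) > 1.5 * r_pm) {
          d <- sqrt(rr$rin2) - r_pm
          for (th in pm$angles) {
            pmm <- ((X - d * cos(th))^2 + (Y - d * sin(th))^2 <= r_pm^2) & cavm
            img[pmm] <- lab[["papillary"]]
          }
        }
      }
      arr[, , s, j] <- img
    }
  }
  series <- structure(list(data = arr, geom = geom, labels = lab,
                           mode = mode, hr = model$hr, frame_times = tmat),
                      class = "mask_series")
  truth <- phantom_truth(eff_model, geom, mode, tmat, vol, act)
  list(series = series, truth = truth)
}

#' Ground-truth tables without voxelisation
#'
#' Computes the phantom's per-frame volumes, respiratory labels and cardiac
#' event times for a given geometry directly from the analytic model (no
#' mask rendering), e.g. to validate trace-level sorting.
#'
#' @param model A \code{ventricle_model}.
#' @param geom An \code{acquisition_geometry}.
#' @param mode \code{"rt"} or \code{"cine"}.
#' @return A \code{phantom_truth}.
#' @export
phantom_truth_tables <- function(model, geom, mode = c("rt", "cine")) {
  mode <- match.arg(mode)
  eff <- if (mode == "cine") { m2 <- model; m2$resp_rate <- 0; m2 } else model
  S <- geom$n_slices; Fn <- geom$frames_per_slice
  tmat <- t(vapply(seq_len(S), function(s)
    frame_times(geom, s, mode = mode, hr = model$hr), numeric(Fn)))
  vol <- t(apply(tmat, 1, function(tt) cavity_volume_at(eff, tt)))
  act <- t(apply(tmat, 1, function(tt) resp_activation(eff, tt)))
  phantom_truth(eff, geom, mode, tmat, vol, act)
}

# assemble the ground-truth tables for a rendered series
phantom_truth <- function(model, geom, mode, tmat, vol, act) {
  S <- geom$n_slices; Fn <- geom$frames_per_slice
  resp_label <- ifelse(act >= 0.7, "inspiration",
                       ifelse(act <= 0.3, "expiration", "transition"))
  per_frame <- data.frame(
    slice = rep(seq_len(S), times = Fn),
    frame = rep(seq_len(Fn), each = S),
    time = as.vector(tmat), volume_ml = as.vector(vol),
    activation = as.vector(act), resp_label = as.vector(resp_label),
    stringsAsFactors = FALSE)
  per_frame <- per_frame[order(per_frame$slice, per_frame$frame), ]
  rownames(per_frame) <- NULL
  dt <- geom$frame_duration / 1000
  events <- list()
  if (mode == "rt") {
    for (s in seq_len(S)) {
      w0 <- tmat[s, 1] - dt / 2; w1 <- tmat[s, Fn] + dt / 2
      ev <- ed_es_times(model, w0, w1)
      if (!nrow(ev)) next
      # the discrete event frame is the frame of extremal sampled volume
      # near the continuous event time (ties to the earliest frame, the
      # same convention a peak detector uses on the sampled trace)
      tc <- if (is.null(model$beat_times)) 60 / model$hr else
        mean(diff(model$beat_times))
      to_frame <- function(t, half_w, which_fun) {
        vapply(t, function(ti) {
          j <- which(abs(tmat[s, ] - ti) <= half_w)
          if (!length(j)) return(NA_integer_)
          as.integer(j[which_fun(vol[s, j])])
        }, integer(1))
      }
      ed_t <- ev$ed; es_t <- ev$es
      ed_f <- to_frame(ed_t, 0.45 * tc, which.max)
      es_f <- to_frame(es_t, 0.45 * tc * min(model$systole_fraction,
                                             1 - model$systole_fraction),
                       which.min)
      nxt <- c(ed_f[-1], NA)
      lbl <- vapply(seq_along(ed_t), function(i) {
        if (is.na(ed_f[i]) || is.na(es_f[i])) return(NA_character_)
        span <- resp_label[s, ed_f[i]:es_f[i]]
        u <- unique(span)
        if (length(u) == 1 && u != "transition") u else "transition"
      }, character(1))
      events[[s]] <- data.frame(
        slice = s, cycle = seq_along(ed_t), ed_time = ed_t, es_time = es_t,
        ed_frame = ed_f, es_frame = es_f, next_ed_frame = nxt,
        resp_phase = lbl, valid = !is.na(lbl) & lbl != "transition",
        stringsAsFactors = FALSE)
    }
  } else {
    ed_f <- which.max(vol[1, ]); es_f <- which.min(vol[1, ])
    events[[1]] <- data.frame(slice = seq_len(S), cycle = 1,
                              ed_time = tmat[, ed_f], es_time = tmat[, es_f],
                              ed_frame = ed_f, es_frame = es_f,
                              next_ed_frame = NA_integer_,
                              resp_phase = "expiration", valid = TRUE,
                              stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, events)
  phases <- data.frame(resp_phase = "expiration", edv = model$edv_exp,
                       esv = model$esv_exp, stringsAsFactors = FALSE)
  if (model$resp_rate > 0)
    phases <- rbind(phases, data.frame(
      resp_phase = "inspiration",
      edv = model$edv_exp * (1 + model$insp_gain_edv),
      esv = model$esv_exp * (1 + model$insp_gain_esv)))
  phases$sv <- phases$edv - phases$esv
  phases$ef <- phases$sv / phases$edv
  structure(list(per_frame = per_frame, events = events, phases = phases,
                 wall_volume = model$wall_volume, pm_volume = model$pm_volume,
                 hr = model$hr, resp_rate = model$resp_rate, mode = mode),
            class = "phantom_truth")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Short-axis label-mask series (%s mode): %d x %d px, %d slices x %d frames\n",
              x$mode, d[1], d[2], d[3], d[4]))
  cat(sprintf("  labels: %s\n", paste(names(x$labels), x$labels,
                                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom ground truth (%s): HR %g bpm, ventilation %g /min\n",
              x$mode, x$hr, x$resp_rate))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Analytic signal-time traces from the phantom
#'
#' Emulates the two manually drawn regions of interest used for
#' cardiorespiratory sorting: a left-ventricular blood-pool ROI on a
#' mid-ventricular slice (bright-blood signal proportional to the in-slice
#' cavity area) and an ROI at the lung-liver interface (two-level signal
#' high in expiration, low in inspiration, with smooth transitions).
#'
#' @param model A \code{ventricle_model}.
#' @param geom An \code{acquisition_geometry}.
#' @param noise_sd Additive Gaussian noise s.d. (a.u.).
#' @param seed Integer seed for the noise.
#' @param slice Slice whose time window is used; default mid-ventricular.
#' @return List with \code{lv} and \code{liver} \code{signal_trace}s.
#' @export
make_signal_traces <- function(model, geom, noise_sd = 0, seed = 1L,
                               slice = NULL) {
  stopifnot(noise_sd >= 0)
  layout <- phantom_layout(model, geom)
  if (is.null(slice))
    slice <- which.min(abs(layout$slice_z - (layout$z_apex +
                                               model$long_axis_mm / 2)))
  tt <- frame_times(geom, slice, mode = "rt")
  v <- cavity_volume_at(model, tt)
  rin2 <- vapply(v, function(vi)
    phantom_radii(model, layout, layout$slice_z[slice], vi)$rin2, numeric(1))
  lv_vals <- pi * rin2                     # blood-pool area, mm^2
  a <- resp_activation(model, tt)
  inten <- intensity_model("rt")
  liver_vals <- inten[["lung"]] +
    (inten[["liver"]] - inten[["lung"]]) * (1 - a)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  if (noise_sd > 0) {
    lv_vals <- lv_vals + stats::rnorm(length(tt), 0, noise_sd)
    liver_vals <- liver_vals + stats::rnorm(length(tt), 0, noise_sd)
  }
  list(lv = signal_trace(tt, lv_vals, source = "lv_pool"),
       liver = signal_trace(tt, liver_vals, source = "lung_liver"))
}

#' Map a label image or series to tissue intensities
#'
#' @param series A \code{mask_series}, or an integer label array/matrix.
#' @param mode Intensity model to use; defaults to the series' own mode.
#' @param noise_sd Additive Gaussian noise s.d. (a.u.).
#' @param seed Seed for the noise.
#' @return Numeric array of the same shape with per-tissue intensities.
#' @export
render_intensity <- function(series, mode = NULL, noise_sd = 0, seed = 1L) {
  labels <- if (inherits(series, "mask_series")) series$data else series
  if (is.null(mode))
    mode <- if (inherits(series, "mask_series")) series$mode else "cine"
  inten <- intensity_model(mode)
  lab <- lv_labels()
  out <- array(0, dim = if (is.null(dim(labels))) length(labels)
               else dim(labels))
  for (nm in names(lab)) out[labels == lab[[nm]]] <- inten[[nm]]
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    out <- out + stats::rnorm(length(out), 0, noise_sd)
  }
  out
}

#' Blood/myocardium contrast ratio
#'
#' Mean blood-pool intensity divided by mean myocardial intensity, the
#' tissue-contrast figure used to compare real-time and cine image quality.
#'
#' @param intensity Numeric array of intensities.
#' @param masks Integer label array of the same shape.
#' @param labels Label map; default \code{lv_labels()}.
#' @return Dimensionless ratio.
#' @export
contrast_ratio <- function(intensity, masks, labels = lv_labels()) {
  stopifnot(length(intensity) == length(masks))
  bl <- intensity[masks == labels[["blood"]]]
  my <- intensity[masks == labels[["myocardium"]]]
  if (!length(bl)) stop("empty blood-pool label region")
  if (!length(my)) stop("empty myocardium label region")
  mean(bl) / mean(my)
}
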