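#' Cross-sectional compartment area of a short-axis label image
#'
#' Area is the labelled-pixel count times the pixel area. Papillary pixels
#' are routed to the cavity (\code{pm_in_cavity}, papillary muscle excluded
#' from the myocardium) or to the wall (\code{pm_in_wall}, included in the
#' myocardium), so they are accounted in exactly one compartment.
#'
#' @param mask 2-D integer label image.
#' @param compartment \code{"cavity"}, \code{"wall"} or \code{"pm"}.
#' @param pm_mode Papillary handling, \code{"pm_in_cavity"} or
#'   \code{"pm_in_wall"}.
#' @param pixel_spacing In-plane pixel spacing (mm), length 2.
#' @param labels Label map; default \code{lv_labels()}.
#' @return Area in mm^2.
#' @export
slice_area <- function(mask, compartment = c("cavity", "wall", "pm"),
                       pm_mode = c("pm_in_cavity", "pm_in_wall"),
                       pixel_spacing = c(0.9, 0.9), labels = lv_labels()) {
  compartment <- match.arg(compartment)
  pm_mode <- match.arg(pm_mode)
  stopifnot(all(pixel_spacing > 0))
  unknown <- setdiff(unique(as.vector(mask)), unname(labels))
  if (length(unknown))
    stop("unknown label in image: ", paste(unknown, collapse = ", "))
  codes <- switch(compartment,
    cavity = c(labels[["blood"]],
               if (pm_mode == "pm_in_cavity") labels[["papillary"]]),
    wall = c(labels[["myocardium"]],
             if (pm_mode == "pm_in_wall") labels[["papillary"]]),
    pm = labels[["papillary"]])
  sum(mask %in% codes) * prod(pixel_spacing)
}

#' Simpson's method of disks
#'
#' Sums per-slice cross-sectional areas times the disk height. The default
#' disk height is slice thickness plus gap (contiguous coverage of the
#' stack); \code{disk_height = "thickness"} uses the slice thickness alone.
#'
#' @param areas Per-slice areas (mm^2), apex to base.
#' @param thickness Slice thickness (mm).
#' @param gap Inter-slice gap (mm).
#' @param disk_height Summation convention.
#' @return Volume in mL.
#' @export
simpsons_volume <- function(areas, thickness, gap = 0,
                            disk_height = c("thickness_plus_gap",
                                            "thickness")) {
  disk_height <- match.arg(disk_height)
  stopifnot(length(areas) >= 1, thickness > 0, gap >= 0)
  if (any(areas < 0)) stop("negative slice area")
  h <- thickness + if (disk_height == "thickness_plus_gap") gap else 0
  sum(areas) * h / 1000
}

# fraction of blood-pool boundary pixels (4-connectivity) adjacent to
# myocardium; 0 when there is no blood on the slice
enclosure_fraction <- function(mask, labels = lv_labels()) {
  blood <- mask == labels[["blood"]] | mask == labels[["papillary"]]
  if (!any(blood)) return(NA_real_)
  myo <- mask == labels[["myocardium"]]
  shift <- function(m, di, dj) {
    n <- nrow(m); p <- ncol(m)
    out <- matrix(FALSE, n, p)
    out[max(1, 1 + di):min(n, n + di), max(1, 1 + dj):min(p, p + dj)] <-
      m[max(1, 1 - di):min(n, n - di), max(1, 1 - dj):min(p, p - dj)]
    out
  }
  nb_nonblood <- !shift(blood, 1, 0) | !shift(blood, -1, 0) |
    !shift(blood, 0, 1) | !shift(blood, 0, -1)
  boundary <- blood & nb_nonblood
  nb_myo <- shift(myo, 1, 0) | shift(myo, -1, 0) |
    shift(myo, 0, 1) | shift(myo, 0, -1)
  sum(boundary & nb_myo) / sum(boundary)
}

#' Select the analysed basal-to-apical slice range
#'
#' Applies the standard inclusion rules: the most basal analysed slice is
#' the most basal slice whose blood-pool boundary is at least
#' \code{min_enclosure} (default 50%) adjacent to myocardium, and the most
#' apical slice is the last slice containing any blood.
#'
#' @param stack 3-D integer label array (x, y, slice), slice 1 = apex.
#' @param min_enclosure Required myocardial enclosure fraction.
#' @param labels Label map.
#' @return Named integer vector \code{c(basal, apical)}; the analysed range
#'   is \code{apical:basal}.
#' @export
select_slice_range <- function(stack, min_enclosure = 0.5,
                               labels = lv_labels()) {
  S <- dim(stack)[3]
  has_blood <- vapply(seq_len(S), function(s)
    any(stack[, , s] == labels[["blood"]] |
          stack[, , s] == labels[["papillary"]]), logical(1))
  if (!any(has_blood)) stop("no blood-pool label anywhere in the stack")
  basal <- NA_integer_
  for (s in rev(which(has_blood))) {
    if (enclosure_fraction(stack[, , s], labels) >= min_enclosure) {
      basal <- s
      break
    }
  }
  if (is.na(basal)) stop("no slice satisfies the basal enclosure rule")
  apical <- min(which(has_blood))
  c(basal = basal, apical = apical)
}

#' Cine end-diastolic and end-systolic phase selection
#'
#' The cine ED and ES phases are the phases with the highest and lowest
#' blood volume of a mid-ventricular slice; ties go to the earliest phase.
#'
#' @param areas Mid-ventricular cavity area per phase (mm^2), >= 3 phases.
#' @return Named integer vector \code{c(ed, es)} of phase indices.
#' @export
cine_ed_es_frames <- function(areas) {
  stopifnot(length(areas) >= 3)
  if (diff(range(areas)) == 0)
    stop("constant area curve: cannot select ED/ES phases")
  c(ed = which.max(areas), es = which.min(areas))
}

#' Derived left-ventricular function parameters
#'
#' Applies the defining relations: stroke volume SV = EDV - ESV, ejection
#' fraction EF = SV / EDV, and cardiac output CO = SV x HR.
#'
#' @param edv,esv End-diastolic and end-systolic volumes (mL).
#' @param hr Heart rate (beats/min); \code{NULL} leaves CO as \code{NA}.
#' @return List with \code{sv} (mL), \code{ef} (fraction) and \code{co}
#'   (L/min).
#' @export
lv_derived <- function(edv, esv, hr = NULL) {
  stopifnot(edv > 0, esv >= 0, edv >= esv)
  sv <- edv - esv
  list(sv = sv, ef = sv / edv,
       co = if (is.null(hr)) NA_real_ else sv * hr / 1000)
}

#' Left-ventricular function from a sorted mask series
#'
#' The central quantification: per slice, the end-diastolic and end-systolic
#' cross-sectional areas of every valid heart cycle are averaged within each
#' respiratory phase (slice-wise averaging, since sequentially acquired
#' slices belong to different heart cycles), the basal/apical inclusion
#' rules are applied, and the averaged areas are summed into volumes by
#' Simpson's method of disks. Derived parameters follow their definitions:
#' SV = EDV - ESV, EF = SV/EDV, CO = SV x HR. Wall and papillary masses are
#' the corresponding disk volumes averaged over the ED and ES phases times
#' the myocardial density; LVM = LVWM + PM.
#'
#' @param series A \code{mask_series}.
#' @param cycles A \code{cycle_events} data frame (or list of them, one per
#'   slice) as returned by \code{\link{assemble_cycles}}.
#' @param hr Heart rate (beats/min) used for cardiac output; supplied, not
#'   estimated, so CO is deterministic.
#' @param pm_mode Papillary handling for the cavity/wall areas.
#' @param density Myocardial density (g/mL) for mass conversion.
#' @param phases Respiratory phases to report.
#' @param averaging \code{"slice_wise"} (areas averaged across cycles per
#'   slice before Simpson summation) or \code{"per_cycle"} (per-cycle
#'   single-slice disk volumes averaged, then summed); the two coincide by
#'   linearity of the disk sum.
#' @param disk_height Disk-height convention for \code{simpsons_volume}.
#' @param min_enclosure Basal slice inclusion threshold.
#' @return An object of class \code{lv_function}: a data frame with one row
#'   per respiratory phase (columns \code{resp_phase}, \code{edv},
#'   \code{esv}, \code{sv}, \code{ef}, \code{co}, \code{lvwm}, \code{pm},
#'   \code{lvm}, \code{n_cycles}) and the analysis settings as attributes.
#'   Phases without valid cycles are reported absent (no row), not as zero.
#' @export
lv_function <- function(series, cycles, hr, pm_mode = c("pm_in_cavity",
                                                        "pm_in_wall"),
                        density = 1.05,
                        phases = c("inspiration", "expiration"),
                        averaging = c("slice_wise", "per_cycle"),
                        disk_height = c("thickness_plus_gap", "thickness"),
                        min_enclosure = 0.5) {
  pm_mode <- match.arg(pm_mode)
  averaging <- match.arg(averaging)
  disk_height <- match.arg(disk_height)
  if (is.list(cycles) && !is.data.frame(cycles))
    cycles <- do.call(rbind, cycles)
  geom <- series$geom
  px <- geom$pixel_spacing
  th <- geom$slice_thickness; gp <- geom$slice_gap
  area <- function(s, f, comp) slice_area(series$data[, , s, f], comp,
                                          pm_mode, px, series$labels)
  rows <- list()
  for (ph in phases) {
    cyc <- cycles[cycles$valid & cycles$resp_phase == ph, , drop = FALSE]
    if (!nrow(cyc)) next
    slices <- sort(unique(cyc$slice))
    per_slice <- lapply(slices, function(s) {
      cs <- cyc[cyc$slice == s, , drop = FALSE]
      ed_cav <- vapply(cs$ed_frame, function(f) area(s, f, "cavity"),
                       numeric(1))
      es_cav <- vapply(cs$es_frame, function(f) area(s, f, "cavity"),
                       numeric(1))
      list(ed_cav = mean(ed_cav), es_cav = mean(es_cav),
           ed_wall = mean(vapply(cs$ed_frame, function(f)
             slice_area(series$data[, , s, f], "wall", "pm_in_cavity", px,
                        series$labels), numeric(1))),
           es_wall = mean(vapply(cs$es_frame, function(f)
             slice_area(series$data[, , s, f], "wall", "pm_in_cavity", px,
                        series$labels), numeric(1))),
           ed_pm = mean(vapply(cs$ed_frame, function(f) area(s, f, "pm"),
                               numeric(1))),
           es_pm = mean(vapply(cs$es_frame, function(f) area(s, f, "pm"),
                               numeric(1))),
           per_cycle_edv = ed_cav, per_cycle_esv = es_cav, n = nrow(cs))
    })
    names(per_slice) <- as.character(slices)
    # representative ED stack (first valid cycle per slice) for the
    # basal/apical inclusion rules
    stack <- array(series$labels[["lung"]],
                   dim = c(dim(series$data)[1:2], geom$n_slices))
    for (s in slices) {
      f <- cyc$ed_frame[cyc$slice == s][1]
      stack[, , s] <- series$data[, , s, f]
    }
    rng <- select_slice_range(stack, min_enclosure, series$labels)
    keep <- as.character(intersect(slices, rng[["apical"]]:rng[["basal"]]))
    get_v <- function(field) {
      a <- vapply(per_slice[keep], function(z) z[[field]], numeric(1))
      simpsons_volume(a, th, gp, disk_height)
    }
    if (averaging == "slice_wise") {
      edv <- get_v("ed_cav"); esv <- get_v("es_cav")
    } else {
      h <- th + if (disk_height == "thickness_plus_gap") gp else 0
      edv <- sum(vapply(per_slice[keep], function(z)
        mean(z$per_cycle_edv * h / 1000), numeric(1)))
      esv <- sum(vapply(per_slice[keep], function(z)
        mean(z$per_cycle_esv * h / 1000), numeric(1)))
    }
    lvwm <- density * (get_v("ed_wall") + get_v("es_wall")) / 2
    pm_m <- density * (get_v("ed_pm") + get_v("es_pm")) / 2
    par <- lv_derived(edv, esv, hr)
    rows[[ph]] <- data.frame(
      resp_phase = ph, edv = edv, esv = esv, sv = par$sv, ef = par$ef,
      co = par$co, lvwm = lvwm, pm = pm_m, lvm = lvwm + pm_m,
      n_cycles = sum(vapply(per_slice[keep], function(z) z$n, numeric(1))),
      basal = unname(rng[["basal"]]), apical = unname(rng[["apical"]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no valid heart cycles in any requested respiratory phase")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("lv_function", "data.frame"),
            settings = list(pm_mode = pm_mode, density = density, hr = hr,
                            averaging = averaging, disk_height = disk_height,
                            min_enclosure = min_enclosure))
}

#' @export
print.lv_function <- function(x, digits = 3, ...) {
  s <- attr(x, "settings")
  cat("Left-ventricular function (Simpson's method of disks)\n")
  cat(sprintf("  pm_mode = %s, density = %g g/mL, HR = %g bpm\n",
              s$pm_mode, s$density, s$hr))
  df <- as.data.frame(x)
  df$ef <- sprintf("%.1f%%", 100 * df$ef)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lv_function <- function(object, ...) {
  s <- attr(object, "settings")
  cat("LV function per respiratory phase:\n")
  for (i in seq_len(nrow(object)))
    cat(sprintf(
      "  %-11s EDV %5.2f  ESV %5.2f  SV %5.2f mL  EF %4.1f%%  CO %.2f L/min  LVM %.2f g (n=%d cycles)\n",
      object$resp_phase[i], object$edv[i], object$esv[i], object$sv[i],
      100 * object$ef[i], object$co[i], object$lvm[i], object$n_cycles[i]))
  cat(sprintf("  settings: %s, disk height = %s\n", s$pm_mode, s$disk_height))
  invisible(object)
}

#' @export
coef.lv_function <- function(object, ...) {
  m <- as.matrix(object[, c("edv", "esv", "sv", "ef", "co", "lvwm", "pm",
                            "lvm")])
  rownames(m) <- object$resp_phase
  m
}

#' Beat-by-beat function-time curve for one slice
#'
#' Per-cycle EDV, ESV, SV and EF from single-slice disk volumes over
#' consecutive heart cycles, including invalid (transition) cycles, which
#' are flagged rather than dropped.
#'
#' @param series A \code{mask_series}.
#' @param cycles A \code{cycle_events} data frame for the slice (>= 2
#'   cycles).
#' @param slice Slice index.
#' @inheritParams lv_function
#' @return Data frame of class \code{beat_curve}, one row per cycle.
#' @export
beat_by_beat_curve <- function(series, cycles, slice,
                               pm_mode = c("pm_in_cavity", "pm_in_wall"),
                               disk_height = c("thickness_plus_gap",
                                               "thickness")) {
  pm_mode <- match.arg(pm_mode)
  disk_height <- match.arg(disk_height)
  cyc <- cycles[cycles$slice == slice | is.na(cycles$slice), , drop = FALSE]
  if (nrow(cyc) < 2) stop("need at least 2 cycles on the slice")
  geom <- series$geom
  h_area <- function(f) slice_area(series$data[, , slice, f], "cavity",
                                   pm_mode, geom$pixel_spacing,
                                   series$labels)
  edv <- vapply(cyc$ed_frame, function(f)
    simpsons_volume(h_area(f), geom$slice_thickness, geom$slice_gap,
                    disk_height), numeric(1))
  esv <- vapply(cyc$es_frame, function(f)
    simpsons_volume(h_area(f), geom$slice_thickness, geom$slice_gap,
                    disk_height), numeric(1))
  out <- data.frame(cycle = cyc$cycle, ed_frame = cyc$ed_frame,
                    es_frame = cyc$es_frame, resp_phase = cyc$resp_phase,
                    valid = cyc$valid, edv = edv, esv = esv,
                    sv = edv - esv, ef = (edv - esv) / edv,
                    ed_time = series$frame_times[slice, cyc$ed_frame])
  class(out) <- c("beat_curve", "data.frame")
  out
}

#' @export
plot.beat_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("edv", "esv", "sv", "ef")) {
    graphics::plot(x$ed_time, x[[p]], type = "b",
                   pch = ifelse(x$valid, 19, 1),
                   col = ifelse(x$resp_phase == "inspiration", "firebrick",
                                ifelse(x$resp_phase == "expiration",
                                       "steelblue", "grey50")),
                   xlab = "time (s)", ylab = toupper(p), ...)
  }
  invisible(x)
}
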