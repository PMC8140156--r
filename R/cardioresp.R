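#' Construct a signal-time trace
#'
#' A time-stamped scalar signal extracted from a region of interest, either
#' the left-ventricular blood pool (cardiac signal) or the lung-liver
#' interface (respiratory signal).
#'
#' @param time Strictly increasing timestamps (s).
#' @param values Signal values (a.u.), same length as \code{time}.
#' @param source \code{"lv_pool"} or \code{"lung_liver"}.
#' @param normalized Logical; whether the trace has been normalised.
#' @return An object of class \code{signal_trace}.
#' @export
signal_trace <- function(time, values, source = c("lv_pool", "lung_liver"),
                         normalized = FALSE) {
  source <- match.arg(source)
  stopifnot(length(time) == length(values), all(is.finite(time)),
            all(diff(time) > 0))
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 source = source, normalized = isTRUE(normalized)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace (%s%s): %d samples over %.2f s, range [%.3g, %.3g]\n",
              x$source, if (x$normalized) ", normalized" else "",
              length(x$time), diff(range(x$time)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.signal_trace <- function(x, ...) {
  graphics::plot(x$time, x$values, type = "l", xlab = "time (s)",
                 ylab = sprintf("%s signal (a.u.)", x$source), ...)
  invisible(x)
}

#' Extract an ROI signal-time curve from a series
#'
#' For a label-mask series and a compartment name the trace is the labelled
#' area (mm^2) per frame (the bright-blood area proxy); for a pixel-set ROI
#' the trace is the mean value of those pixels per frame, which applies to
#' intensity series as well.
#'
#' @param series A \code{mask_series}, or a list with elements \code{data}
#'   (4D array x,y,slice,frame) and \code{frame_times} (slice x frame).
#' @param roi A compartment name (e.g. \code{"blood"}, \code{"liver"}) or a
#'   logical matrix selecting in-plane pixels.
#' @param slice Slice index.
#' @return A \code{signal_trace}.
#' @export
extract_roi_signal <- function(series, roi, slice) {
  arr <- series$data
  d <- dim(arr)
  stopifnot(length(d) == 4, slice >= 1, slice <= d[3])
  tt <- series$frame_times[slice, ]
  if (is.character(roi)) {
    if (!inherits(series, "mask_series"))
      stop("label-name ROI requires a mask_series")
    code <- series$labels[[roi]]
    if (is.null(code)) stop("unknown label: ", roi)
    px_area <- prod(series$geom$pixel_spacing)
    vals <- vapply(seq_len(d[4]),
                   function(j) sum(arr[, , slice, j] == code) * px_area,
                   numeric(1))
    src <- if (roi %in% c("blood", "papillary")) "lv_pool" else "lung_liver"
    return(signal_trace(tt, vals, source = src))
  }
  roi <- as.matrix(roi)
  if (!is.logical(roi)) stop("pixel ROI must be a logical matrix")
  if (!all(dim(roi) == d[1:2])) stop("roi outside image: dimension mismatch")
  if (!any(roi)) stop("roi is empty on this slice")
  vals <- vapply(seq_len(d[4]),
                 function(j) mean(arr[, , slice, j][roi]), numeric(1))
  signal_trace(tt, vals, source = "lung_liver")
}

#' Normalise a respiratory trace to its plateau levels
#'
#' Affine rescaling that sends the mean of the expiration-plateau maxima to
#' 1 and the mean of the inspiration-trough minima to 0 (plateaus estimated
#' as samples within \code{edge_frac} of the trace range from either
#' extreme). Noisy values may slightly exceed [0, 1].
#'
#' @param trace A \code{signal_trace}.
#' @param edge_frac Fraction of the range defining the plateau windows.
#' @return The normalised \code{signal_trace} (idempotent within 1e-9).
#' @export
normalize_trace <- function(trace, edge_frac = 0.05) {
  v <- trace$values
  rng <- diff(range(v))
  if (rng == 0) stop("no respiratory modulation: trace is constant")
  hi <- mean(v[v >= max(v) - edge_frac * rng])
  lo <- mean(v[v <= min(v) + edge_frac * rng])
  out <- trace
  out$values <- (v - lo) / (hi - lo)
  out$normalized <- TRUE
  out
}

# local maxima (earliest sample of a tied run) with their topographic
# prominence; interior extrema only
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  idx <- which(r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                 r$values[2:(k - 1)] > r$values[3:k]) + 1
  starts[idx]
}

peak_prominence <- function(v, p) {
  left <- if (p > 1) {
    higher <- which(v[1:(p - 1)] > v[p])
    lo <- if (length(higher)) max(higher) + 1 else 1
    min(v[lo:p])
  } else v[p]
  n <- length(v)
  right <- if (p < n) {
    higher <- which(v[(p + 1):n] > v[p])
    hi <- if (length(higher)) p + min(higher) - 1 else n
    min(v[p:hi])
  } else v[p]
  v[p] - max(left, right)
}

#' Detect end-diastolic and end-systolic frames in a blood-pool trace
#'
#' End-diastole is taken at local maxima of the LV blood-pool signal
#' (largest in-slice blood area), end-systole at the minimum between
#' consecutive end-diastoles. Peaks must exceed a prominence of
#' \code{prominence_frac} times the interquartile range of the trace and be
#' separated by at least 0.6 cardiac periods at the supplied heart-rate
#' hint; ties go to the earliest frame. Detection is invariant to positive
#' rescaling of the trace.
#'
#' @param trace A \code{signal_trace} spanning at least two cardiac periods.
#' @param hr_hint Approximate heart rate (beats/min).
#' @param prominence_frac Prominence threshold as a fraction of the IQR.
#' @return Data frame with columns \code{ed} and \code{es} (frame indices,
#'   1-based); the last detected ED has \code{es = NA}. The number of EDs is
#'   available as attribute \code{n_ed}.
#' @export
detect_cardiac_phases <- function(trace, hr_hint, prominence_frac = 0.25) {
  v <- trace$values
  n <- length(v)
  if (n < 8) stop("trace too short for peak detection (need >= 8 samples)")
  period <- 60 / hr_hint
  if (diff(range(trace$time)) < 2 * period)
    stop("trace shorter than two cardiac periods at hr_hint")
  cand <- local_maxima(v)
  if (length(cand)) {
    prom <- vapply(cand, function(p) peak_prominence(v, p), numeric(1))
    cand <- cand[prom >= prominence_frac * stats::IQR(v)]
  }
  if (length(cand) >= 2) {
    min_sep <- 0.6 * period
    ord <- cand[order(-v[cand], cand)]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) ||
          all(abs(trace$time[kept] - trace$time[p]) >= min_sep))
        kept <- c(kept, p)
    cand <- sort(kept)
  }
  if (length(cand) < 2)
    stop("fewer than 2 end-diastolic maxima detected")
  es <- vapply(seq_len(length(cand) - 1), function(i) {
    span <- (cand[i] + 1):(cand[i + 1] - 1)
    span[which.min(v[span])]
  }, integer(1))
  out <- data.frame(ed = cand, es = c(es, NA_integer_))
  attr(out, "n_ed") <- length(cand)
  out
}

#' Classify frames into respiratory phases by thresholding
#'
#' On a normalised respiratory trace (expiration plateau near 1,
#' inspiration trough near 0), frames at or above \code{high} are labelled
#' expiration, frames at or below \code{low} inspiration, and everything in
#' between transition.
#'
#' @param trace A normalised \code{signal_trace}.
#' @param low,high Thresholds on the normalised signal, 0 <= low < high <= 1.
#' @return Character vector of per-frame labels (class \code{resp_labels})
#'   with the thresholds stored as an attribute.
#' @export
classify_respiration <- function(trace, low = 0.3, high = 0.7) {
  stopifnot(low >= 0, high <= 1, low < high)
  if (!isTRUE(trace$normalized))
    stop("trace must be normalised first (see normalize_trace)")
  v <- trace$values
  if (diff(range(v)) == 0) stop("constant trace: no respiratory modulation")
  lab <- ifelse(v >= high, "expiration",
                ifelse(v <= low, "inspiration", "transition"))
  structure(lab, thresholds = c(low = low, high = high),
            class = "resp_labels")
}

#' Assemble heart cycles with their respiratory phase
#'
#' Combines detected ED/ES events with per-frame respiratory labels. A
#' cycle's phase is the label shared by all frames from its ED to its ES
#' (inclusive); cycles with mixed labels or any transition frame are marked
#' transition and invalid, mirroring the rule that heart cycles in the
#' transition between inspiration and expiration are discarded.
#'
#' @param events Output of \code{\link{detect_cardiac_phases}}.
#' @param labels A \code{resp_labels} vector covering all frames.
#' @param slice Slice index recorded with each cycle.
#' @param span \code{"ed_es"} (default; phase membership judged over the
#'   ED-to-ES frames actually read by the volumetry) or \code{"full_cycle"}
#'   (ED to next ED).
#' @return Data frame of class \code{cycle_events} with columns
#'   \code{slice}, \code{cycle}, \code{ed_frame}, \code{es_frame},
#'   \code{resp_phase}, \code{valid}.
#' @export
assemble_cycles <- function(events, labels, slice = NA_integer_,
                            span = c("ed_es", "full_cycle")) {
  span <- match.arg(span)
  done <- which(!is.na(events$es))
  out <- data.frame(slice = slice, cycle = seq_along(done),
                    ed_frame = events$ed[done], es_frame = events$es[done])
  out$resp_phase <- vapply(done, function(i) {
    last <- if (span == "ed_es") events$es[i] else events$ed[i + 1] - 1
    u <- unique(labels[events$ed[i]:last])
    if (length(u) == 1 && u != "transition") u else "transition"
  }, character(1))
  out$valid <- out$resp_phase != "transition"
  class(out) <- c("cycle_events", "data.frame")
  out
}
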