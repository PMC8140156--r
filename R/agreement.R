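#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC computed
#' from the analysis-of-variance mean squares of a complete subjects x
#' conditions table, the form appropriate for both test-retest and
#' inter-observer questions. The estimate is clipped to [-1, 1]. A
#' consistency form, ICC(3,1), is available via \code{form}.
#'
#' @param values Numeric matrix or data frame, one row per subject (>= 3)
#'   and one column per condition (>= 2), no missing entries.
#' @param form \code{"ICC2_1"} (absolute agreement, default) or
#'   \code{"ICC3_1"} (consistency).
#' @return The ICC (dimensionless, in [-1, 1]).
#' @export
icc <- function(values, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  m <- as.matrix(values)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3, k >= 2)
  if (anyNA(m)) stop("complete table required")
  if (diff(range(m)) == 0) stop("zero total variance: ICC undefined")
  long <- data.frame(value = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     condition = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used, so the F-test warning on perfectly
  # agreeing tables is irrelevant here
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + condition,
                            data = long))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  est <- if (form == "ICC2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  max(-1, min(1, est))
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean paired difference \code{a - b}; the limits of agreement
#' are bias +/- 1.96 times the sample standard deviation of the
#' differences (no small-sample t correction, following the original
#' method).
#'
#' @param a,b Paired measurements, equal length >= 3.
#' @return List with \code{bias}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{n}.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Per-subject percentage differences
#'
#' 100 x (reference - comparison) / reference for each subject, with the
#' mean and sample standard deviation across subjects. Subjects with a zero
#' reference are reported as NA with a warning and excluded from the
#' summary.
#'
#' @param reference,comparison Paired values; the first-named condition is
#'   the reference (e.g. cine, test, expiration).
#' @return List with \code{per_subject} (%), \code{mean}, \code{sd}.
#' @export
percent_difference <- function(reference, comparison) {
  stopifnot(length(reference) == length(comparison))
  pct <- rep(NA_real_, length(reference))
  bad <- reference == 0
  if (any(bad))
    warning("zero reference for subject(s) ",
            paste(which(bad), collapse = ", "), "; reported as NA")
  pct[!bad] <- 100 * (reference[!bad] - comparison[!bad]) / reference[!bad]
  list(per_subject = pct, mean = mean(pct, na.rm = TRUE),
       sd = stats::sd(pct, na.rm = TRUE))
}

#' Agreement analysis between two measurement conditions
#'
#' Bundles the repeatability and method-comparison statistics for paired
#' measurements: ICC, Bland-Altman bias and limits of agreement,
#' ordinary-least-squares regression of the comparison on the reference,
#' and percentage differences, per parameter.
#'
#' @param data Data frame with columns \code{subject}, \code{condition}
#'   (exactly two levels; the first-named is the reference), \code{parameter}
#'   and \code{value}; each subject appears once per condition per
#'   parameter, with at least 3 subjects.
#' @param icc_form ICC form, see \code{\link{icc}}.
#' @return Data frame of class \code{lv_agreement}, one row per parameter,
#'   with columns \code{parameter}, \code{n}, \code{icc}, \code{bias},
#'   \code{loa_low}, \code{loa_high}, \code{slope}, \code{intercept},
#'   \code{r}, \code{mean_pct_diff}, \code{sd_pct_diff}; the condition pair
#'   is stored as an attribute.
#' @export
compare_conditions <- function(data, icc_form = "ICC2_1") {
  stopifnot(all(c("subject", "condition", "parameter", "value") %in%
                  names(data)))
  conds <- if (is.factor(data$condition)) levels(droplevels(data$condition))
  else unique(as.character(data$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  rows <- lapply(unique(as.character(data$parameter)), function(p) {
    dp <- data[data$parameter == p, ]
    w <- stats::reshape(
      dp[, c("subject", "condition", "value")], direction = "wide",
      idvar = "subject", timevar = "condition")
    ref <- w[[paste0("value.", conds[1])]]
    cmp <- w[[paste0("value.", conds[2])]]
    if (anyNA(ref) || anyNA(cmp))
      stop("each subject must appear once per condition (parameter ", p, ")")
    if (length(ref) < 3)
      stop("need >= 3 subjects per parameter (parameter ", p, ")")
    ba <- bland_altman(ref, cmp)
    fit <- stats::lm(cmp ~ ref)
    pd <- percent_difference(ref, cmp)
    data.frame(parameter = p, n = length(ref),
               icc = icc(cbind(ref, cmp), form = icc_form),
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = stats::cor(ref, cmp),
               mean_pct_diff = pd$mean, sd_pct_diff = pd$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("lv_agreement", "data.frame"),
            conditions = conds, icc_form = icc_form)
}

#' @export
print.lv_agreement <- function(x, digits = 3, ...) {
  conds <- attr(x, "conditions")
  cat(sprintf("Agreement analysis: %s (reference) vs %s [%s]\n",
              conds[1], conds[2], attr(x, "icc_form")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman plots for an agreement analysis
#'
#' One panel per parameter: paired means against differences with the bias
#' and limits of agreement drawn as horizontal lines. Requires the original
#' paired data.
#'
#' @param x An \code{lv_agreement} object.
#' @param data The paired data frame used to build \code{x}.
#' @param ... Passed to \code{plot}.
#' @export
plot.lv_agreement <- function(x, data, ...) {
  conds <- attr(x, "conditions")
  np <- nrow(x)
  op <- graphics::par(mfrow = c(ceiling(np / 2), min(np, 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(np)) {
    p <- x$parameter[i]
    dp <- data[data$parameter == p, ]
    a <- dp$value[dp$condition == conds[1]]
    b <- dp$value[dp$condition == conds[2]]
    graphics::plot((a + b) / 2, a - b, pch = 19, main = p,
                   xlab = "mean of pair", ylab = sprintf("%s - %s",
                                                         conds[1], conds[2]),
                   ylim = range(c(a - b, x$loa_low[i], x$loa_high[i])), ...)
    graphics::abline(h = c(x$bias[i], x$loa_low[i], x$loa_high[i]),
                     lty = c(1, 2, 2))
  }
  invisible(x)
}
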