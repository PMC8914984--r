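#' Required sample size for a proportion estimate
#'
#' Closed-form sample size for estimating a proportion `rho` with a
#' two-sided confidence interval of full width `d`:
#' `N = 4 * z^2 * rho * (1 - rho) / d^2`. With `z = 1.96`, `rho = 0.89`
#' (the mean accuracy of comparable published detectors) and `d = 0.2`
#' (a 95% interval of +/-10%) this gives 37.6, i.e. 38 subjects.
#'
#' @param rho Proportional estimate in (0, 1).
#' @param d Confidence-interval full width (> 0).
#' @param z_crit Significance criterion (default 1.96).
#' @return List with `raw` (un-rounded value) and `n` (its ceiling).
#' @examples
#' sample_size(rho = 0.89, d = 0.2)  # raw 37.6, n 38
#' @export
sample_size <- function(rho, d = 0.2, z_crit = 1.96) {
  if (!is.numeric(rho) || rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(d) || d <= 0) stop("`d` must be positive", call. = FALSE)
  raw <- 4 * z_crit^2 * rho * (1 - rho) / d^2
  list(raw = raw, n = ceiling(raw))
}

#' Confusion counts from a session label table
#'
#' Tallies the last two segments of every usable muscle row against the
#' session-level ground truth that fatigue was reached exactly at the
#' final segment: a fatigue label at the last segment is a true positive
#' (else a false negative), and a non-fatigue label at the second-to-last
#' segment is a true negative (else a false positive). Earlier segments
#' contribute no counts. Rows flagged not-examined are skipped.
#'
#' @param table A `label_table` from [read_label_table()].
#' @return A `confusion_counts` list: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_from_labels <- function(table) {
  stopifnot(inherits(table, "label_table"))
  label_cols <- attr(table, "label_cols")
  lab <- as.matrix(table[table$usable, label_cols, drop = FALSE])
  if (nrow(lab) == 0L) stop("no usable rows in label table", call. = FALSE)
  if (ncol(lab) < 2L)
    stop("need at least 2 segment columns per row", call. = FALSE)
  last <- lab[, ncol(lab)]
  penult <- lab[, ncol(lab) - 1L]
  structure(list(tp = sum(last == "fatigue"),
                 fn = sum(last == "non-fatigue"),
                 tn = sum(penult == "non-fatigue"),
                 fp = sum(penult == "fatigue")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and accuracy `(tp+tn)/total`. A metric
#' whose denominator is zero is returned as `NA` with a warning naming
#' it.
#'
#' @param counts A `confusion_counts` object (or a list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return A `classifier_metrics` list of four proportions in \[0, 1\].
#' @examples
#' classifier_metrics(list(tp = 70, tn = 72, fp = 3, fn = 5))
#' @export
classifier_metrics <- function(counts) {
  cc <- lapply(counts[c("tp", "tn", "fp", "fn")], as.numeric)
  if (any(vapply(cc, function(v) length(v) != 1L || is.na(v) || v < 0,
                 logical(1))))
    stop("counts must be nonnegative scalars tp, tn, fp, fn",
         call. = FALSE)
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("all counts are zero", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(
    sensitivity = ratio(cc$tp, cc$tp + cc$fn, "sensitivity"),
    specificity = ratio(cc$tn, cc$tn + cc$fp, "specificity"),
    ppv = ratio(cc$tp, cc$tp + cc$fp, "positive predictive value"),
    accuracy = (cc$tp + cc$tn) / total
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.4f  specificity %.4f  ",
                     "PPV %.4f  accuracy %.4f\n"),
              x$sensitivity, x$specificity, x$ppv, x$accuracy))
  invisible(x)
}

#' Ordinary least-squares slope of an IEMG series
#'
#' Slope of IEMG against segment number (unit spacing). A positive slope
#' over a session indicates sustained contraction with progressing
#' fatigue; a relaxed or non-fatiguing muscle yields a slope near zero.
#'
#' @param values Ordered numeric series of per-segment IEMG values
#'   (length >= 2).
#' @return The OLS slope.
#' @examples
#' iemg_slope(c(1, 2, 3, 4))  # 1
#' @export
iemg_slope <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 points", call. = FALSE)
  idx <- seq_along(values)
  unname(stats::coef(stats::lm(values ~ idx))[2L])
}

#' Paired two-tailed t-test
#'
#' Standard paired t on the differences `a - b` with `n - 1` degrees of
#' freedom; used to compare per-muscle IEMG slopes between the fatigue
#' and non-fatigue conditions.
#'
#' @param a,b Numeric series of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::var(d) == 0)
    stop("zero variance of differences: t statistic undefined",
         call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
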