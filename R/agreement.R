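# Validation machinery: sensor/annotation alignment, 5 Hz resampling,
# percentage agreement, confusion matrices, ICC(A,1).

#' Align a sensor clock to an annotation clock by the first movement peak
#'
#' The sensors start recording before the reference annotations, so both
#' clocks are aligned on the first transition of the protocol, which shows
#' as the first strong rise of the SMA. The offset is the centre of the
#' first suprathreshold SMA excursion (the excess-over-threshold-weighted
#' centroid, robust to a flat or noisy peak) minus the midpoint of the
#' first annotated transition interval; subtracting it from sensor
#' timestamps moves them onto the annotation clock. The centre-to-midpoint
#' pairing is unbiased: movement velocity (and hence SMA) peaks
#' mid-transition, whereas the threshold-crossing time leads the annotated
#' start by an amount set by the zero-phase gravity filter's anticipation
#' and the SMA window, not by the clock offset.
#'
#' @param sma An `sma_series` (chest or thigh).
#' @param reference An [annotation_track] containing at least one
#'   `TRANSITION` interval.
#' @param threshold Rest-activity threshold in g (default 0.03).
#' @return The clock offset in seconds (sensor minus annotation clock).
#' @export
align_by_first_peak <- function(sma, reference, threshold = 0.03) {
  stopifnot(inherits(sma, "sma_series"), inherits(reference, "annotation_track"))
  above <- sma$values > threshold
  if (!any(above))
    stop("alignment failure: no SMA value exceeds the threshold")
  tr <- which(reference$label == "TRANSITION")
  if (length(tr) == 0L)
    stop("alignment failure: reference contains no transition interval")
  first <- which(above)[1]
  run_end <- first
  while (run_end < length(above) && above[run_end + 1L]) run_end <- run_end + 1L
  idx <- first:run_end
  w <- sma$values[idx] - threshold
  center <- sum(sma$times[idx] * w) / sum(w)
  mid <- (reference$start_s[tr[1]] + reference$end_s[tr[1]]) / 2
  center - mid
}

#' Resample an annotation track to a 5 Hz label stream
#'
#' Each 0.2 s epoch takes the label of the half-open interval
#' `[start_s, end_s)` covering the epoch's centre instant; epoch centres
#' covered by no interval are labelled `UNKNOWN`. The centre-instant rule
#' makes the discretisation deterministic (no ties, unlike majority vote).
#'
#' @param track An [annotation_track].
#' @param rate Output epoch rate (default 5).
#' @param duration_s Stream duration; defaults to the last interval end.
#' @return A [label_stream] with `source = "rater"` starting at time 0.
#' @export
resample_annotations <- function(track, rate = 5, duration_s = NULL) {
  stopifnot(inherits(track, "annotation_track"))
  if (nrow(track) == 0L) stop("annotation track is empty")
  if (is.null(duration_s)) duration_s <- max(track$end_s)
  n <- floor(duration_s * rate + 1e-9)
  centers <- (seq_len(n) - 0.5) / rate
  labels <- rep("UNKNOWN", n)
  for (i in seq_len(nrow(track))) {
    hit <- centers >= track$start_s[i] & centers < track$end_s[i]
    labels[hit] <- track$label[i]
  }
  label_stream(labels, rate = rate, start_s = 0, source = "rater")
}

#' Per-class percentage agreement between two label streams
#'
#' Computes the percentage of reference epochs of each class that the test
#' stream labels identically, the overall agreement, and the full confusion
#' matrix (reference class by test class). The measure is asymmetric: the
#' first argument is the reference (the ground truth, or rater one). Classes
#' absent from the reference are reported as `NA` (not applicable).
#'
#' @param reference,test [label_stream]s of equal length and rate (plain
#'   character vectors are accepted).
#' @return An object of class `agreement_report`: `per_class` (named percent
#'   vector over [activity_levels]), `overall` (percent), `confusion`
#'   (counts, reference rows by test columns), `n_epochs`.
#' @export
percent_agreement <- function(reference, test) {
  as_labels <- function(x) {
    if (inherits(x, "label_stream")) x$labels
    else factor(as.character(x), levels = activity_levels)
  }
  if (inherits(reference, "label_stream") && inherits(test, "label_stream") &&
      reference$rate != test$rate)
    stop("reference and test streams must share a rate")
  ref <- as_labels(reference); tst <- as_labels(test)
  if (length(ref) != length(tst))
    stop("reference and test streams must have equal length")
  if (length(ref) == 0L) stop("empty streams")
  confusion <- table(reference = ref, test = tst)
  row_n <- rowSums(confusion)
  per_class <- ifelse(row_n > 0, 100 * diag(confusion) / row_n, NA_real_)
  names(per_class) <- rownames(confusion)
  structure(
    list(per_class = per_class,
         overall = 100 * mean(as.character(ref) == as.character(tst)),
         confusion = confusion,
         n_epochs = length(ref)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d epochs, overall %%Agr %.1f\n",
              x$n_epochs, x$overall))
  pc <- x$per_class[!is.na(x$per_class)]
  for (nm in names(pc)) cat(sprintf("  %-16s %6.1f%%\n", nm, pc[nm]))
  invisible(x)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed model, absolute agreement, single measures: the reliability
#' of per-subject totals (e.g. seconds spent in an activity) between two
#' raters. From the two-way ANOVA decomposition with n subjects and k
#' raters,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater, and
#' residual mean squares. The 95% confidence interval uses the standard
#' F-based construction for absolute-agreement single measures. Absolute
#' agreement penalises a constant shift between raters, unlike consistency.
#'
#' @param ratings Numeric matrix or data frame, n subjects by k raters
#'   (k = 2 in the intended use); no missing cells, n >= 3.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci95 = c(low, high)`,
#'   `model`, `n`, `k`, and the mean squares. All ratings equal across the
#'   board yields `icc = 1` with a degenerate interval and a warning.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop("ratings must be numeric")
  if (anyNA(x)) stop("ratings must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(x)
  rmean <- rowMeans(x); cmean <- colMeans(x)
  MSR <- k * sum((rmean - grand)^2) / (n - 1)
  MSC <- n * sum((cmean - grand)^2) / (k - 1)
  resid <- x - outer(rmean, rep(1, k)) - outer(rep(1, n), cmean) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))

  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < 1e-300) {
    warning("zero total variance: all ratings identical; ICC reported as 1")
    return(structure(list(icc = 1, ci95 = c(NA_real_, NA_real_),
                          model = "ICC(A,1): two-way mixed, absolute agreement, single measures",
                          n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
                     class = "icc_result"))
  }
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  if (MSE < 1e-300 && MSC < 1e-300) {
    ci <- c(icc, icc)  # perfect agreement with between-subject variance
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci95 = ci,
         model = "ICC(A,1): two-way mixed, absolute agreement, single measures",
         n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.4f, 95%% CI [%.4f, %.4f] (n = %d, k = %d)\n",
              x$icc, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}
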