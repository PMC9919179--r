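# Core containers shared across the pipeline.

#' Activity labels
#'
#' The closed label set used throughout the package. `SIDE_SEMI_LEFT` /
#' `SIDE_SEMI_RIGHT` are the merged side-lying + semi-lying categories and
#' `SIT` merges sitting on the edge of the bed with sitting in a chair, the
#' two category merges applied before validation. `UNKNOWN` covers epochs the
#' classifier declines (non-finite input, gravity-magnitude guard).
#'
#' @format A character vector of the eleven label names.
#' @export
activity_levels <- c(
  "SUPINE", "PRONE", "SIDE_SEMI_LEFT", "SIDE_SEMI_RIGHT", "SEMI_SIT",
  "SIT", "STAND", "WALK", "CYCLE", "TRANSITION", "UNKNOWN"
)

#' Tri-axial accelerometer signal
#'
#' Uniformly sampled tri-axial acceleration, in g, for one sensor site.
#' Device frame: x = longitudinal (toward the head), y = mediolateral,
#' z = anterior (away from the skin).
#'
#' @param xyz Numeric matrix with n rows and 3 columns (x, y, z), in g.
#' @param rate Sampling rate in samples/second (default 20).
#' @param site One of `"chest_left"`, `"chest_right"`, `"thigh_left"`,
#'   `"thigh_right"`.
#' @param start_offset Seconds relative to the session clock at which the
#'   first sample was taken.
#' @return An object of class `accel_signal`.
#' @export
accel_signal <- function(xyz, rate = 20,
                         site = c("chest_left", "chest_right",
                                  "thigh_left", "thigh_right"),
                         start_offset = 0) {
  site <- match.arg(site)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("`xyz` must have exactly three columns (x, y, z)")
  if (!is.numeric(xyz)) stop("`xyz` must be numeric")
  if (nrow(xyz) < 3L) stop("accel_signal needs at least 3 samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(xyz = xyz, rate = rate, site = site, start_offset = start_offset),
    class = "accel_signal"
  )
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("<accel_signal> %s: %d samples @ %g Hz (%.1f s), t0 = %.3f s\n",
              x$site, nrow(x$xyz), x$rate, nrow(x$xyz) / x$rate,
              x$start_offset))
  invisible(x)
}

n_samples <- function(signal) nrow(signal$xyz)

signal_times <- function(signal) {
  signal$start_offset + (seq_len(n_samples(signal)) - 1L) / signal$rate
}

#' @export
print.gravity_series <- function(x, ...) {
  cat(sprintf("<gravity_series> %s: %d samples @ %g Hz\n",
              x$site, nrow(x$xyz), x$rate))
  invisible(x)
}

new_gravity_series <- function(signal, xyz) {
  structure(
    list(xyz = xyz, rate = signal$rate, site = signal$site,
         start_offset = signal$start_offset),
    class = "gravity_series"
  )
}

new_orientation_series <- function(theta, psi, phi, rate, start_offset,
                                   corrected = FALSE,
                                   flagged = logical(length(theta))) {
  structure(
    list(theta = theta, psi = psi, phi = phi, rate = rate,
         start_offset = start_offset, corrected = corrected,
         flagged = flagged),
    class = "orientation_series"
  )
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf(
    "<orientation_series> %d samples @ %g Hz, %s\n",
    length(x$theta), x$rate,
    if (x$corrected) "baseline-corrected" else "uncorrected"))
  invisible(x)
}

new_sma_series <- function(values, times, window_s, step_s) {
  structure(
    list(values = values, times = times, window_s = window_s, step_s = step_s),
    class = "sma_series"
  )
}

#' @export
print.sma_series <- function(x, ...) {
  cat(sprintf(
    "<sma_series> %d windows of %g s every %g s; SMA range [%.4f, %.4f] g\n",
    length(x$values), x$window_s, x$step_s,
    min(x$values), max(x$values)))
  invisible(x)
}

#' 5 Hz activity label stream
#'
#' @param labels Character vector or factor of labels from
#'   [activity_levels].
#' @param rate Epoch rate in labels/second (default 5).
#' @param start_s Session time of the first epoch's start (default 0).
#' @param source `"algorithm"` or `"rater"`.
#' @return An object of class `label_stream`.
#' @export
label_stream <- function(labels, rate = 5, start_s = 0,
                         source = c("algorithm", "rater")) {
  source <- match.arg(source)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), activity_levels)
  if (length(bad) > 0)
    stop("unknown activity labels: ", paste(bad, collapse = ", "))
  structure(
    list(labels = factor(labels, levels = activity_levels), rate = rate,
         start_s = start_s, source = source),
    class = "label_stream"
  )
}

#' @export
print.label_stream <- function(x, ...) {
  cat(sprintf("<label_stream> %d epochs @ %g Hz (%s), %.1f s\n",
              length(x$labels), x$rate, x$source, length(x$labels) / x$rate))
  print(table(droplevels(x$labels)))
  invisible(x)
}

#' @export
length.label_stream <- function(x) length(x$labels)

#' Annotation track
#'
#' Reference activity annotations as non-overlapping, half-open time
#' intervals `[start_s, end_s)` at arbitrary resolution (video coding runs at
#' 0.004 s).
#'
#' @param start_s,end_s Interval bounds in seconds on the annotation clock.
#' @param label Activity label per interval (see [activity_levels]).
#' @return A `data.frame` of class `annotation_track`.
#' @export
annotation_track <- function(start_s, end_s, label) {
  if (length(start_s) != length(end_s) || length(end_s) != length(label))
    stop("start_s, end_s and label must have equal length")
  if (any(end_s <= start_s)) stop("every interval needs start_s < end_s")
  ord <- order(start_s)
  start_s <- start_s[ord]; end_s <- end_s[ord]; label <- as.character(label)[ord]
  if (length(start_s) > 1 && any(start_s[-1] < end_s[-length(end_s)] - 1e-9))
    stop("annotation intervals must not overlap")
  structure(
    data.frame(start_s = start_s, end_s = end_s, label = label,
               stringsAsFactors = FALSE),
    class = c("annotation_track", "data.frame")
  )
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
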