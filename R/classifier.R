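# Rule-based decision flowchart mapping epoch angles + SMA to activity
# labels, plus bout extraction.

#' Classifier configuration
#'
#' All boundaries of the decision flowchart are tunable. Defaults are chosen
#' from posture geometry: 45 degrees of trunk inclination separates upright
#' from reclined, 70 degrees separates reclined (semi-sitting) from
#' horizontal; a thigh within 45 degrees of vertical distinguishes standing
#' from sitting; a roll within 45 degrees of face-up is supine and beyond
#' 135 degrees prone. The rest-activity threshold separating static postures
#' from movement defaults to an SMA of 0.03 g (`preset = "default"`); the
#' `"conservative"` preset raises it to 0.04 g.
#'
#' @param rest_activity_threshold SMA cut-off in g; epochs with both sensors
#'   at or below it are static, strictly above is dynamic. Default 0.03.
#' @param upright_phi_max Chest phi below which the trunk counts as upright
#'   (deg, default 45).
#' @param horizontal_phi_min Chest phi at or above which the trunk counts as
#'   horizontal (deg, default 70). The band between `upright_phi_max` and
#'   `horizontal_phi_min` is the semi-sitting band.
#' @param thigh_vertical_max Thigh phi below which the thigh counts as
#'   vertical (deg, default 45).
#' @param semi_sit_phi Length-2 numeric, the semi-sitting chest band (deg,
#'   default `c(45, 70)`); must equal
#'   `c(upright_phi_max, horizontal_phi_min)`.
#' @param supine_roll_max Absolute chest roll below which a horizontal trunk
#'   is supine (deg, default 45).
#' @param prone_roll_min Absolute chest roll at or above which a horizontal
#'   trunk is prone (deg, default 135).
#' @param cycle_freq_band Length-2 numeric, pedalling frequency band in Hz
#'   (default `c(0.2, 2)`).
#' @param walk_min_run_s Minimum dynamic-run duration for walking, in
#'   seconds (default 3; self-initiated transfers take about 3-5 s, so only
#'   sustained upright movement is walking).
#' @param magnitude_guard_g Epochs whose gravity magnitude deviates from 1 g
#'   by more than this are labelled UNKNOWN (default 0.3).
#' @param cycle_min_amp_deg Minimum peak thigh-angle oscillation amplitude
#'   for cycling detection (deg, default 5), so sensor noise cannot satisfy
#'   the spectral criterion.
#' @param roll_positive_right If `TRUE` (default) positive roll means
#'   rotation toward the participant's right side; flipping it swaps the
#'   left/right side-lying labels and nothing else.
#' @param min_bout_s Optional post-hoc minimum bout duration in seconds;
#'   bouts shorter than this are merged into their neighbours. Off (0) by
#'   default.
#' @param preset `"default"` (threshold 0.03) or `"conservative"`
#'   (threshold 0.04). An explicitly supplied
#'   `rest_activity_threshold` wins over the preset.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(rest_activity_threshold = NULL,
                              upright_phi_max = 45,
                              horizontal_phi_min = 70,
                              thigh_vertical_max = 45,
                              semi_sit_phi = c(upright_phi_max, horizontal_phi_min),
                              supine_roll_max = 45,
                              prone_roll_min = 135,
                              cycle_freq_band = c(0.2, 2),
                              walk_min_run_s = 3,
                              magnitude_guard_g = 0.3,
                              cycle_min_amp_deg = 5,
                              roll_positive_right = TRUE,
                              min_bout_s = 0,
                              preset = c("default", "conservative")) {
  preset <- match.arg(preset)
  if (is.null(rest_activity_threshold))
    rest_activity_threshold <- switch(preset, default = 0.03,
                                      conservative = 0.04)
  if (rest_activity_threshold <= 0) stop("threshold must be positive")
  if (!(upright_phi_max <= semi_sit_phi[1] &&
        semi_sit_phi[2] <= horizontal_phi_min))
    stop("semi-sit band must lie between upright_phi_max and horizontal_phi_min")
  if (cycle_freq_band[1] <= 0 || cycle_freq_band[2] <= cycle_freq_band[1])
    stop("cycle_freq_band must be an increasing positive pair")
  structure(
    list(rest_activity_threshold = rest_activity_threshold,
         upright_phi_max = upright_phi_max,
         horizontal_phi_min = horizontal_phi_min,
         thigh_vertical_max = thigh_vertical_max,
         semi_sit_phi = semi_sit_phi,
         supine_roll_max = supine_roll_max,
         prone_roll_min = prone_roll_min,
         cycle_freq_band = cycle_freq_band,
         walk_min_run_s = walk_min_run_s,
         magnitude_guard_g = magnitude_guard_g,
         cycle_min_amp_deg = cycle_min_amp_deg,
         roll_positive_right = roll_positive_right,
         min_bout_s = min_bout_s),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm,
                                   paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Classify a single 5 Hz epoch
#'
#' One pass through the decision flowchart. The epoch is static when both
#' SMA values are at or below the rest-activity threshold, dynamic when
#' either is strictly above it.
#'
#' Static branch: an upright chest with a vertical thigh is STAND, with a
#' horizontal thigh SIT; a chest in the semi-sitting band is SEMI_SIT when
#' not rolled to the side, otherwise SIDE_SEMI left/right by roll sign; a
#' horizontal chest is SUPINE (small roll), PRONE (roll beyond
#' `prone_roll_min`), or SIDE_SEMI left/right in between.
#'
#' Dynamic branch: CYCLE when the context reports sustained thigh
#' periodicity with a non-upright, quiet chest; WALK when the dynamic run
#' lasts at least `walk_min_run_s` with an upright chest, vertical thigh and
#' a dynamic thigh; otherwise TRANSITION.
#'
#' UNKNOWN when any input is non-finite or the gravity-magnitude wear guard
#' trips (a warning is issued, never an error).
#'
#' @param epoch A one-row `epoch_frame` slice, or a named list with at least
#'   `phi_mc`, `theta_mc`, `phi_t`, `sma_mc`, `sma_t` (optionally `gmag_mc`,
#'   `gmag_t`).
#' @param config A [classifier_config].
#' @param context Dynamic context: a list with `run_s`, the duration of the
#'   dynamic run containing this epoch (0 for static epochs), and `cycling`,
#'   logical from [detect_cycling()].
#' @return A single label from [activity_levels].
#' @export
classify_epoch <- function(epoch, config = classifier_config(),
                           context = list(run_s = 0, cycling = FALSE)) {
  needed <- c(epoch$phi_mc, epoch$theta_mc, epoch$phi_t,
              epoch$sma_mc, epoch$sma_t)
  if (length(needed) < 5L || !all(is.finite(needed))) {
    warning("non-finite epoch input: labelled UNKNOWN")
    return("UNKNOWN")
  }
  gmag <- c(if (is.null(epoch$gmag_mc)) 1 else epoch$gmag_mc,
            if (is.null(epoch$gmag_t)) 1 else epoch$gmag_t)
  if (any(!is.finite(gmag)) || any(abs(gmag - 1) > config$magnitude_guard_g))
    return("UNKNOWN")

  thr <- config$rest_activity_threshold
  roll <- if (config$roll_positive_right) epoch$theta_mc else -epoch$theta_mc
  dynamic <- epoch$sma_mc > thr || epoch$sma_t > thr

  if (!dynamic) {
    if (epoch$phi_mc < config$upright_phi_max) {
      if (epoch$phi_t < config$thigh_vertical_max) return("STAND")
      return("SIT")
    }
    side <- if (roll > 0) "SIDE_SEMI_RIGHT" else "SIDE_SEMI_LEFT"
    if (epoch$phi_mc < config$horizontal_phi_min) {
      if (abs(roll) <= config$supine_roll_max) return("SEMI_SIT")
      return(side)
    }
    if (abs(roll) <= config$supine_roll_max) return("SUPINE")
    if (abs(roll) >= config$prone_roll_min) return("PRONE")
    return(side)
  }

  cycling <- isTRUE(context$cycling)
  if (cycling &&
      epoch$phi_mc >= config$upright_phi_max &&
      epoch$sma_mc <= thr && epoch$sma_t > thr)
    return("CYCLE")
  run_s <- if (is.null(context$run_s)) 0 else context$run_s
  if (run_s >= config$walk_min_run_s &&
      epoch$phi_mc < config$upright_phi_max &&
      epoch$phi_t < config$thigh_vertical_max &&
      epoch$sma_t > thr)
    return("WALK")
  "TRANSITION"
}

#' Detect sustained thigh periodicity (bed cycling)
#'
#' Decides whether a window of thigh inclination shows pedalling: the
#' dominant spectral peak of the detrended window (periodogram via FFT) must
#' lie inside `cycle_freq_band`, carry at least half the in-band power
#' (within one bin), and the in-band power must be at least half the total;
#' the peak oscillation amplitude must exceed `cycle_min_amp_deg` and the
#' mean thigh SMA must be above the rest-activity threshold. Windows shorter
#' than 4 s return `FALSE`.
#'
#' @param thigh_sma_window Numeric, thigh SMA values over the context window.
#' @param thigh_angle_window Numeric, thigh inclination (deg) at 5 Hz over
#'   the same window; use the raw-signal inclination (`phi_t_inst`), since
#'   the gravity low-pass removes pedalling frequencies from the tilt
#'   angles.
#' @param config A [classifier_config].
#' @param rate Sample rate of the window in Hz (default 5).
#' @return Logical scalar.
#' @export
detect_cycling <- function(thigh_sma_window, thigh_angle_window,
                           config = classifier_config(), rate = 5) {
  n <- length(thigh_angle_window)
  if (n < 4 * rate) return(FALSE)
  if (!all(is.finite(thigh_angle_window))) return(FALSE)
  if (length(thigh_sma_window) > 0 &&
      mean(thigh_sma_window) <= config$rest_activity_threshold) return(FALSE)
  x <- thigh_angle_window - mean(thigh_angle_window)
  if (sqrt(2) * stats::sd(x) < config$cycle_min_amp_deg) return(FALSE)
  pgram <- Mod(stats::fft(x))^2
  nf <- n %/% 2
  power <- pgram[2:(nf + 1)]
  freq <- (1:nf) * rate / n
  band <- freq >= config$cycle_freq_band[1] & freq <= config$cycle_freq_band[2]
  if (!any(band)) return(FALSE)
  peak <- which.max(power)
  if (!band[peak]) return(FALSE)
  neighbours <- intersect((peak - 1):(peak + 1), seq_len(nf))
  peak_power <- sum(power[neighbours])
  if (peak_power < 0.5 * sum(power[band])) return(FALSE)
  if (sum(power[band]) < 0.5 * sum(power)) return(FALSE)
  TRUE
}

#' Classify a full epoch frame
#'
#' Two-pass procedure: pass one marks each epoch static or dynamic against
#' the rest-activity threshold and measures the duration of each maximal
#' dynamic run and the cycling context (a sliding ~4 s window of
#' `phi_t_inst` around each dynamic epoch); pass two applies
#' [classify_epoch()] with that context. Optionally merges bouts shorter
#' than `config$min_bout_s` into their neighbours (off by default).
#'
#' @param frame An `epoch_frame` from [build_epoch_frame()].
#' @param config A [classifier_config].
#' @return A [label_stream] of the same length as the frame.
#' @export
classify_recording <- function(frame, config = classifier_config()) {
  if (!inherits(frame, "epoch_frame") && is.data.frame(frame))
    class(frame) <- c("epoch_frame", "data.frame")
  n <- nrow(frame)
  if (is.null(n) || n == 0L) stop("epoch frame is empty")
  rate <- attr(frame, "rate")
  if (is.null(rate)) rate <- 5
  thr <- config$rest_activity_threshold

  sma_mc <- frame$sma_mc; sma_t <- frame$sma_t
  dyn <- (sma_mc > thr | sma_t > thr)
  dyn[is.na(dyn)] <- FALSE

  runs <- rle(as.vector(dyn))
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  run_len_s <- (runs$lengths / rate)[run_id]
  run_s <- ifelse(dyn, run_len_s, 0)

  phi_inst <- if (!is.null(frame$phi_t_inst)) frame$phi_t_inst else frame$phi_t
  half <- as.integer(2 * rate)  # 4 s context window
  cycling <- logical(n)
  for (i in which(dyn)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    # keep a full-length window near the edges by sliding it inward
    if (hi - lo < 2L * half) {
      if (lo == 1L) hi <- min(n, lo + 2L * half)
      if (hi == n) lo <- max(1L, hi - 2L * half)
    }
    cycling[i] <- detect_cycling(sma_t[lo:hi], phi_inst[lo:hi], config,
                                 rate = rate)
  }

  labels <- character(n)
  n_bad <- 0L
  for (i in seq_len(n)) {
    lbl <- withCallingHandlers(
      classify_epoch(frame[i, , drop = FALSE], config,
                     context = list(run_s = run_s[i], cycling = cycling[i])),
      warning = function(w) {
        n_bad <<- n_bad + 1L
        invokeRestart("muffleWarning")
      })
    labels[i] <- lbl
  }
  if (n_bad > 0L)
    warning(sprintf("%d epochs had non-finite input and were labelled UNKNOWN",
                    n_bad))
  stream <- label_stream(labels, rate = rate, start_s = frame$epoch_s[1],
                         source = "algorithm")
  if (config$min_bout_s > 0) stream <- smooth_short_bouts(stream, config$min_bout_s)
  stream
}

# merge bouts shorter than min_s into the preceding bout (the following one
# for a short leading bout), repeating until stable
smooth_short_bouts <- function(stream, min_s) {
  repeat {
    r <- rle(as.character(stream$labels))
    short <- which(r$lengths / stream$rate < min_s)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    j <- short[which.min(r$lengths[short])]
    r$values[j] <- if (j > 1L) r$values[j - 1L] else r$values[j + 1L]
    stream$labels <- factor(inverse.rle(r), levels = activity_levels)
  }
  stream
}

#' Extract activity bouts from a label stream
#'
#' Run-length encodes the stream into maximal runs of one label. Bout counts
#' per label give activity frequency; bout durations give activity duration.
#' The encoding is lossless: [stream_from_bouts()] reconstructs the stream
#' exactly.
#'
#' @param stream A [label_stream].
#' @return A `data.frame` with `label`, `start_s`, `duration_s`,
#'   `epoch_count`; consecutive rows always differ in label and the
#'   durations sum to the stream duration.
#' @export
extract_bouts <- function(stream) {
  stopifnot(inherits(stream, "label_stream"))
  if (length(stream$labels) == 0L) stop("label stream is empty")
  r <- rle(as.character(stream$labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(
    label = r$values,
    start_s = stream$start_s + starts / stream$rate,
    duration_s = r$lengths / stream$rate,
    epoch_count = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Rebuild a label stream from its bouts
#'
#' Inverse of [extract_bouts()].
#'
#' @param bouts A bout `data.frame` from [extract_bouts()].
#' @param rate Epoch rate (default 5).
#' @param source Stream provenance tag.
#' @return A [label_stream].
#' @export
stream_from_bouts <- function(bouts, rate = 5, source = "algorithm") {
  label_stream(rep(bouts$label, bouts$epoch_count), rate = rate,
               start_s = bouts$start_s[1], source = source)
}

#' Per-activity frequency and total duration
#'
#' @param stream A [label_stream] (or a bout data frame).
#' @return A `data.frame` with one row per label present: `label`, `n_bouts`
#'   (frequency), `total_s` (duration), `mean_bout_s`.
#' @export
summarize_activity <- function(stream) {
  bouts <- if (is.data.frame(stream)) stream else extract_bouts(stream)
  agg <- aggregate(cbind(duration_s, n = 1) ~ label, data = bouts, FUN = sum)
  data.frame(
    label = agg$label,
    n_bouts = agg$n,
    total_s = agg$duration_s,
    mean_bout_s = agg$duration_s / agg$n,
    stringsAsFactors = FALSE
  )
}
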