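# File round-tripping: RFC 4180 CSV, UTF-8, times as seconds from session
# start at 6 decimal places, labels as uppercase enum strings.

fmt6 <- function(x) formatC(x, format = "f", digits = 6)

read_numeric_csv <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  for (col in expected_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("%s: malformed value in column '%s' at data row %d",
                     path, col, bad[1]))
      df[[col]] <- num
    }
  }
  df
}

#' Write / read a raw sensor CSV
#'
#' Columns `time_s,ax_g,ay_g,az_g`, six decimal places. A JSON sidecar
#' (`<path>.json`) records the site, rate, and session id so the file can be
#' read back without guessing.
#'
#' @param signal An [accel_signal].
#' @param path Output CSV path.
#' @param session Free-form session identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(signal, path, session = "session") {
  stopifnot(inherits(signal, "accel_signal"))
  df <- data.frame(time_s = fmt6(signal_times(signal)),
                   ax_g = fmt6(signal$xyz[, 1]),
                   ay_g = fmt6(signal$xyz[, 2]),
                   az_g = fmt6(signal$xyz[, 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(site = signal$site, rate = signal$rate,
         start_offset = signal$start_offset, session = session),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_accel_csv
#' @param site,rate Overrides when no sidecar exists; by default both come
#'   from the sidecar, or (for the rate) from the median timestamp spacing.
#' @export
read_accel_csv <- function(path, site = NULL, rate = NULL) {
  df <- read_numeric_csv(path, c("time_s", "ax_g", "ay_g", "az_g"))
  if (nrow(df) < 3L)
    stop(path, ": fewer than 3 samples; not a usable recording")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(site)) site <- meta$site
  if (is.null(site)) stop(path, ": sensor site unknown; supply `site`")
  if (is.null(rate)) rate <- meta$rate
  if (is.null(rate)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) stop(path, ": cannot infer sampling rate")
    rate <- round(1 / dt)
  }
  accel_signal(as.matrix(df[, c("ax_g", "ay_g", "az_g")]), rate = rate,
               site = site, start_offset = df$time_s[1])
}

#' Write / read an epoch-frame CSV
#'
#' @param frame An `epoch_frame`.
#' @param path CSV path.
#' @return `path` (writer) or the `epoch_frame` (reader).
#' @export
write_epoch_csv <- function(frame, path) {
  out <- as.data.frame(lapply(frame, fmt6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path) {
  df <- read_numeric_csv(path, c("epoch_s", "phi_mc", "theta_mc", "psi_mc",
                                 "phi_t", "theta_t", "psi_t",
                                 "sma_mc", "sma_t"))
  class(df) <- c("epoch_frame", "data.frame")
  attr(df, "rate") <- if (nrow(df) > 1) round(1 / stats::median(diff(df$epoch_s))) else 5
  df
}

#' Write / read a 5 Hz label CSV (`epoch_s,label`)
#'
#' @param stream A [label_stream].
#' @param path CSV path.
#' @return `path` (writer) or a [label_stream] (reader).
#' @export
write_labels_csv <- function(stream, path) {
  t <- stream$start_s + (seq_along(stream$labels) - 1L) / stream$rate
  df <- data.frame(epoch_s = fmt6(t), label = as.character(stream$labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_labels_csv
#' @param source Stream provenance tag for the reader.
#' @export
read_labels_csv <- function(path, source = "algorithm") {
  df <- read_numeric_csv(path, "epoch_s")
  if (!"label" %in% names(df)) stop(path, ": missing column 'label'")
  rate <- if (nrow(df) > 1) round(1 / stats::median(diff(df$epoch_s))) else 5
  label_stream(df$label, rate = rate, start_s = df$epoch_s[1], source = source)
}

#' Write / read an annotation CSV (`start_s,end_s,label`)
#'
#' @param track An [annotation_track].
#' @param path CSV path.
#' @return `path` (writer) or an [annotation_track] (reader).
#' @export
write_annotation_csv <- function(track, path) {
  df <- data.frame(start_s = fmt6(track$start_s), end_s = fmt6(track$end_s),
                   label = track$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- read_numeric_csv(path, c("start_s", "end_s"))
  if (!"label" %in% names(df)) stop(path, ": missing column 'label'")
  annotation_track(df$start_s, df$end_s, df$label)
}
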