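# End-to-end runs tying the modules together, mirrored 1:1 by the
# command-line entry point in inst/cli/icumotion.

#' Process a dual-sensor recording into an epoch frame
#'
#' Runs the full feature pipeline on both sensors: three-point median
#' filter, gravity extraction (0.25 Hz zero-phase low-pass), tilt angles,
#' supine baseline correction over `calibration_window`, SMA (1 s window,
#' 0.2 s hop), and the 5 Hz chest/thigh fusion. Warns when the calibration
#' window is not at rest (its SMA exceeds the rest-activity threshold).
#'
#' @param chest,thigh [accel_signal]s sharing the session clock.
#' @param calibration_window `c(start_s, end_s)` of the supine rest used for
#'   baseline correction (default `c(5, 22)`, matching the default
#'   protocols' opening rest).
#' @param config A [classifier_config] (only the rest-activity threshold is
#'   used here, for the calibration-rest check).
#' @param cutoff_hz Gravity low-pass cutoff (default 0.25).
#' @return An `epoch_frame`; the per-sensor intermediates are attached as
#'   attribute `"sensors"` (a list with `chest` and `thigh`, each holding
#'   `gravity`, `angles`, `offsets`, `sma`).
#' @export
process_recording <- function(chest, thigh, calibration_window = c(5, 22),
                              config = classifier_config(),
                              cutoff_hz = 0.25) {
  one <- function(signal) {
    if (n_samples(signal) < signal$rate)
      stop("sensor ", signal$site, ": less than 1 s of data")
    filtered <- median_filter3(signal)
    gravity <- extract_gravity(filtered, cutoff_hz = cutoff_hz)
    cal <- calibrate_supine(compute_tilt_angles(gravity), calibration_window)
    sma <- compute_sma(filtered, gravity)
    rest <- sma$values[sma$times >= calibration_window[1] &
                         sma$times <= calibration_window[2]]
    if (length(rest) > 0 &&
        stats::median(rest) > config$rest_activity_threshold)
      warning(signal$site,
              ": calibration window is not at rest (SMA above threshold)")
    list(raw = filtered, gravity = gravity, angles = cal$angles,
         offsets = cal$offsets, sma = sma)
  }
  chest_p <- one(chest)
  thigh_p <- one(thigh)
  frame <- build_epoch_frame(chest_p, thigh_p)
  attr(frame, "sensors") <- list(chest = chest_p, thigh = thigh_p)
  frame
}

manifest_for <- function(config, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  c(list(package = "icumotion",
         version = as.character(utils::packageVersion("icumotion")),
         config = jsonlite::fromJSON(cfg_json),
         config_md5 = hash,
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
}

#' Process raw sensor CSVs into an epoch-frame CSV
#'
#' @param chest_csv,thigh_csv Raw sensor CSVs (see [read_accel_csv()]).
#' @param out_csv Output epoch-frame CSV path.
#' @param calibration_window Supine rest window, seconds.
#' @param config A [classifier_config].
#' @return The epoch frame, invisibly. A provenance manifest
#'   (`<out_csv>.manifest.json`) records the configuration hash and package
#'   version.
#' @export
cmd_process <- function(chest_csv, thigh_csv, out_csv,
                        calibration_window = c(5, 22),
                        config = classifier_config()) {
  chest <- read_accel_csv(chest_csv)
  thigh <- read_accel_csv(thigh_csv)
  if (!grepl("^chest", chest$site)) stop(chest_csv, " is not a chest sensor")
  if (!grepl("^thigh", thigh$site)) stop(thigh_csv, " is not a thigh sensor")
  frame <- process_recording(chest, thigh,
                             calibration_window = calibration_window,
                             config = config)
  write_epoch_csv(frame, out_csv)
  jsonlite::write_json(
    manifest_for(config, list(inputs = c(chest_csv, thigh_csv),
                              calibration_window = calibration_window)),
    paste0(out_csv, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(frame)
}

#' Classify an epoch-frame CSV into labels, bouts, and a summary
#'
#' @param frame_csv Epoch-frame CSV from [cmd_process()].
#' @param out_prefix Output path prefix; writes `<prefix>_labels.csv`,
#'   `<prefix>_bouts.csv`, `<prefix>_summary.json`.
#' @param config A [classifier_config].
#' @return The [label_stream], invisibly.
#' @export
cmd_classify <- function(frame_csv, out_prefix, config = classifier_config()) {
  frame <- read_epoch_csv(frame_csv)
  stream <- classify_recording(frame, config)
  bouts <- extract_bouts(stream)
  write_labels_csv(stream, paste0(out_prefix, "_labels.csv"))
  utils::write.csv(
    data.frame(label = bouts$label, start_s = fmt6(bouts$start_s),
               duration_s = fmt6(bouts$duration_s)),
    paste0(out_prefix, "_bouts.csv"), row.names = FALSE, quote = FALSE)
  summ <- summarize_activity(stream)
  jsonlite::write_json(summ, paste0(out_prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(stream)
}

#' Validate algorithm labels against reference annotations
#'
#' Resamples the annotations to 5 Hz, optionally aligns the two clocks by a
#' supplied offset, trims both streams to their common length, and writes a
#' JSON agreement report (per-class and overall percentage agreement plus
#' the confusion matrix).
#'
#' @param labels_csv Algorithm label CSV (see [write_labels_csv()]).
#' @param annotation_csv Reference annotation CSV
#'   (see [read_annotation_csv()]).
#' @param out_json Output report path.
#' @param offset_s Clock offset to subtract from the sensor labels' clock
#'   (e.g. from [align_by_first_peak()]); default 0.
#' @return The `agreement_report`, invisibly.
#' @export
cmd_validate <- function(labels_csv, annotation_csv, out_json, offset_s = 0) {
  test <- read_labels_csv(labels_csv)
  track <- read_annotation_csv(annotation_csv)
  reference <- resample_annotations(track, rate = test$rate)
  # shift the sensor stream onto the annotation clock, then overlay epochs
  shift_epochs <- round((test$start_s - offset_s) * test$rate)
  ref_labels <- as.character(reference$labels)
  test_labels <- as.character(test$labels)
  if (shift_epochs > 0) {
    test_labels <- c(rep("UNKNOWN", shift_epochs), test_labels)
  } else if (shift_epochs < 0) {
    test_labels <- test_labels[(-shift_epochs + 1L):length(test_labels)]
  }
  n <- min(length(ref_labels), length(test_labels))
  if (n == 0L) stop("no overlap between labels and annotations")
  report <- percent_agreement(ref_labels[seq_len(n)], test_labels[seq_len(n)])
  jsonlite::write_json(
    list(per_class = as.list(report$per_class[!is.na(report$per_class)]),
         overall = report$overall,
         n_epochs = report$n_epochs,
         confusion = as.data.frame(report$confusion)),
    out_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

#' Simulate a protocol and write the sensor, truth, and manifest files
#'
#' @param protocol One of `"natural"`, `"strict"`, `"healthcare_provider"`,
#'   `"bed_cycling"`.
#' @param out_dir Output directory (created if missing); writes `chest.csv`,
#'   `thigh.csv` (+ sidecars), `truth_labels.csv`, `truth_annotations.csv`,
#'   and `manifest.json` sufficient for exact regeneration.
#' @param seed Integer seed.
#' @param noise A [noise_model]; its seed is replaced by `seed`.
#' @param configuration Sensor diagonal, `"MCL-TR"` or `"MCR-TL"`.
#' @return The `synthetic_recording`, invisibly.
#' @export
cmd_simulate <- function(protocol, out_dir, seed = 1L,
                         noise = noise_model(),
                         configuration = "MCL-TR") {
  scripts <- default_protocols()
  if (!protocol %in% names(scripts))
    stop("unknown protocol '", protocol, "'; choose one of ",
         paste(names(scripts), collapse = ", "))
  noise$seed <- as.integer(seed)
  rec <- simulate_recording(scripts[[protocol]], noise,
                            configuration = configuration)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_accel_csv(rec$chest, file.path(out_dir, "chest.csv"),
                  session = protocol)
  write_accel_csv(rec$thigh, file.path(out_dir, "thigh.csv"),
                  session = protocol)
  write_labels_csv(rec$truth, file.path(out_dir, "truth_labels.csv"))
  write_annotation_csv(truth_annotations(rec),
                       file.path(out_dir, "truth_annotations.csv"))
  jsonlite::write_json(
    list(protocol = protocol, seed = as.integer(seed),
         configuration = configuration, noise = unclass(noise),
         calibration_s = rec$calibration_s,
         package = "icumotion",
         version = as.character(utils::packageVersion("icumotion"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
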