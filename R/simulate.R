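# Seeded synthetic dual-sensor recordings with ground truth, emulating the
# four scripted ICU activity protocols.

# Script-level activity vocabulary. Scripts may name unmerged postures
# (side lying vs semi lying); truth labels use the merged label set.
script_truth_label <- function(activity) {
  switch(activity,
    SIDE_LYING_LEFT = , SEMI_LYING_LEFT = "SIDE_SEMI_LEFT",
    SIDE_LYING_RIGHT = , SEMI_LYING_RIGHT = "SIDE_SEMI_RIGHT",
    CYCLE_FLAT = , CYCLE_SEMI = "CYCLE",
    activity
  )
}

# canonical gravity direction for any scripted activity, including the
# internal centre orientations of walking and cycling
script_orientation <- function(activity, site = c("chest", "thigh")) {
  site <- match.arg(site)
  d <- function(deg) deg * pi / 180
  recline <- d(57.5)  # chest inclination in the middle of the semi-sit band
  sit_lean <- d(10)   # slight backward trunk lean when sitting
  chest <- switch(activity,
    SUPINE = c(0, 0, 1),
    PRONE = c(0, 0, -1),
    SIDE_LYING_LEFT = c(0, -1, 0),
    SIDE_LYING_RIGHT = c(0, 1, 0),
    SIDE_SEMI_LEFT = c(0, -1, 0),
    SIDE_SEMI_RIGHT = c(0, 1, 0),
    SEMI_SIT = c(cos(recline), 0, sin(recline)),
    SEMI_LYING_LEFT = c(cos(recline), -sin(recline) * sin(d(60)),
                        sin(recline) * cos(d(60))),
    SEMI_LYING_RIGHT = c(cos(recline), sin(recline) * sin(d(60)),
                         sin(recline) * cos(d(60))),
    SIT = c(cos(sit_lean), 0, sin(sit_lean)),
    STAND = c(1, 0, 0),
    WALK = c(1, 0, 0),
    CYCLE_FLAT = c(0, 0, 1),
    CYCLE_SEMI = c(cos(recline), 0, sin(recline)),
    stop("no orientation for activity ", activity)
  )
  thigh <- switch(activity,
    SUPINE = c(0, 0, 1),
    PRONE = c(0, 0, -1),
    SIDE_LYING_LEFT = c(0, -1, 0),
    SIDE_LYING_RIGHT = c(0, 1, 0),
    SIDE_SEMI_LEFT = c(0, -1, 0),
    SIDE_SEMI_RIGHT = c(0, 1, 0),
    SEMI_SIT = c(sin(d(10)), 0, cos(d(10))),
    SEMI_LYING_LEFT = c(0, -sin(d(30)), cos(d(30))),
    SEMI_LYING_RIGHT = c(0, sin(d(30)), cos(d(30))),
    SIT = c(0, 0, 1),
    STAND = c(1, 0, 0),
    WALK = c(1, 0, 0),
    CYCLE_FLAT = c(sin(d(30)), 0, cos(d(30))),
    CYCLE_SEMI = c(sin(d(30)), 0, cos(d(30))),
    stop("no orientation for activity ", activity)
  )
  if (site == "chest") chest else thigh
}

#' Canonical gravity direction of a static posture
#'
#' The unit gravity-reaction vector a perfectly worn sensor measures in a
#' given static posture: e.g. supine chest (0, 0, 1) (anterior axis up),
#' standing chest (1, 0, 0) (longitudinal axis up), right side-lying chest
#' (0, 1, 0) under the positive-right roll convention. These anchors close
#' the simulate-then-classify loop: running [compute_tilt_angles()] on the
#' returned vector always lands inside the classifier's static region for
#' the posture.
#'
#' @param activity A static label from [activity_levels], or one of the
#'   unmerged script postures (`"SIDE_LYING_LEFT"`, `"SEMI_LYING_RIGHT"`,
#'   ...). Dynamic classes (WALK, CYCLE, TRANSITION, UNKNOWN) are an error.
#' @param site `"chest"` or `"thigh"`.
#' @return A length-3 unit vector (x, y, z) in the device frame.
#' @export
orientation_for_activity <- function(activity, site = c("chest", "thigh")) {
  if (activity %in% c("WALK", "CYCLE", "CYCLE_FLAT", "CYCLE_SEMI",
                      "TRANSITION", "UNKNOWN"))
    stop("'", activity, "' is not a static posture")
  script_orientation(activity, site)
}

#' Sensor noise model
#'
#' @param accel_noise_sd White accelerometer noise SD per axis, in g
#'   (default 0.005).
#' @param angle_jitter_sd SD of the slow-varying postural sway applied to
#'   the sensor orientation, in degrees (default 2).
#' @param baseline_offset_deg Half-range of the fixed per-sensor mounting
#'   misalignment, drawn uniformly per axis, in degrees (default 5); removed
#'   downstream by the supine baseline correction.
#' @param seed Integer seed making the recording reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(accel_noise_sd = 0.005, angle_jitter_sd = 2,
                        baseline_offset_deg = 5, seed = 1L) {
  stopifnot(accel_noise_sd >= 0, angle_jitter_sd >= 0,
            baseline_offset_deg >= 0)
  structure(
    list(accel_noise_sd = accel_noise_sd, angle_jitter_sd = angle_jitter_sd,
         baseline_offset_deg = baseline_offset_deg, seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Build a protocol script
#'
#' An ordered list of posture segments with transitions inserted wherever
#' the orientation changes between consecutive segments (standing to walking
#' needs none).
#'
#' @param kind One of `"natural"`, `"strict"`, `"healthcare_provider"`,
#'   `"bed_cycling"`.
#' @param postures A `data.frame` with `activity` (script posture names) and
#'   `duration_s`.
#' @param transition_s Duration of each inserted transition, in seconds.
#' @param assisted Logical: transitions performed by a healthcare provider
#'   (brief, low-SMA, gently eased) rather than self-initiated.
#' @param burst_amp Rectified-mean amplitude of the movement burst during a
#'   transition, in g (0.10 self-initiated, 0.02 assisted).
#' @param ease_s For assisted transitions, the span over which the provider
#'   eases the posture change, centred on the labelled transition (default
#'   12 s); `NA` (self-initiated) rotates within the labelled window.
#' @return An object of class `protocol_script`: a `data.frame` of segments
#'   (`activity`, `label`, `duration_s`, `is_transition`) with the
#'   generation parameters as attributes.
#' @export
protocol_script <- function(kind, postures, transition_s,
                            assisted = FALSE,
                            burst_amp = if (assisted) 0.02 else 0.10,
                            ease_s = if (assisted) 12 else NA_real_) {
  kind <- match.arg(kind, c("natural", "strict", "healthcare_provider",
                            "bed_cycling"))
  stopifnot(is.data.frame(postures),
            all(c("activity", "duration_s") %in% names(postures)))
  if (any(postures$duration_s <= 0)) stop("zero-duration segment in script")
  segs <- list()
  for (i in seq_len(nrow(postures))) {
    act <- postures$activity[i]
    if (i > 1L) {
      prev <- postures$activity[i - 1L]
      moved <- any(vapply(c("chest", "thigh"), function(s)
        sum(abs(script_orientation(prev, s) - script_orientation(act, s))) > 1e-9,
        logical(1)))
      if (moved)
        segs[[length(segs) + 1L]] <- data.frame(
          activity = "TRANSITION", label = "TRANSITION",
          duration_s = transition_s, is_transition = TRUE)
    }
    segs[[length(segs) + 1L]] <- data.frame(
      activity = act, label = script_truth_label(act),
      duration_s = postures$duration_s[i], is_transition = FALSE)
  }
  out <- do.call(rbind, segs)
  structure(out,
            class = c("protocol_script", "data.frame"),
            kind = kind, assisted = assisted, burst_amp = burst_amp,
            ease_s = ease_s, burst_freq = 3,
            walk_freq = 2, walk_amp = 0.15,
            cycle_freq = 0.7, cycle_amp_deg = 20, cycle_accel_amp = 0.05,
            calibration_s = c(5, 22))
}

#' @export
print.protocol_script <- function(x, ...) {
  cat(sprintf("<protocol_script> %s: %d segments, %.1f s total%s\n",
              attr(x, "kind"), nrow(x), sum(x$duration_s),
              if (attr(x, "assisted")) " (provider-assisted transitions)" else ""))
  print(as.data.frame(x))
  invisible(x)
}

#' The four default activity protocols
#'
#' Scripts reconstructing the scripted study conditions: natural and strict
#' protocols run the full posture set (lying postures, semi-sitting,
#' sitting, standing, a brief walk) with self-initiated transitions of about
#' 3 s; the healthcare-provider protocol covers the in-bed postures and
#' sitting with brief (1.85 s), low-amplitude assisted transfers and no
#' prone lying, standing, or walking; the bed-cycling protocol has two
#' cycling segments of about two minutes each, flat and semi-sitting. The
#' first three total roughly eight minutes, bed cycling roughly four. Every
#' script opens with a supine rest long enough for the baseline-correction
#' window (5-22 s).
#'
#' @return A named list of four [protocol_script] objects: `natural`,
#'   `strict`, `healthcare_provider`, `bed_cycling`.
#' @export
default_protocols <- function() {
  posture_df <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(activity = m[, 1], duration_s = as.numeric(m[, 2]))
  }
  natural <- posture_df(
    "SUPINE", 35, "SIDE_LYING_LEFT", 31, "PRONE", 33, "SIDE_LYING_RIGHT", 32,
    "SEMI_LYING_RIGHT", 33, "SEMI_SIT", 34, "SEMI_LYING_LEFT", 32,
    "SUPINE", 37, "SIT", 33, "STAND", 36, "WALK", 6.5, "STAND", 25, "SIT", 30)
  strict <- posture_df(
    "SUPINE", 33, "SIDE_LYING_LEFT", 31, "PRONE", 33, "SIDE_LYING_RIGHT", 32,
    "SEMI_LYING_RIGHT", 33, "SEMI_SIT", 33, "SEMI_LYING_LEFT", 33,
    "SUPINE", 33, "SIT", 33, "STAND", 35, "WALK", 6, "STAND", 25, "SIT", 30)
  healthcare <- posture_df(
    "SUPINE", 39, "SIDE_LYING_LEFT", 33, "SUPINE", 35, "SIDE_LYING_RIGHT", 34,
    "SUPINE", 33, "SEMI_SIT", 37, "SIT", 34, "SEMI_SIT", 30, "SUPINE", 40,
    "SIDE_LYING_LEFT", 28, "SUPINE", 30)
  cycling <- posture_df(
    "SUPINE", 25, "CYCLE_FLAT", 126, "CYCLE_SEMI", 126)
  list(
    natural = protocol_script("natural", natural, transition_s = 3.4),
    strict = protocol_script("strict", strict, transition_s = 3.0),
    healthcare_provider = protocol_script("healthcare_provider", healthcare,
                                          transition_s = 1.85,
                                          assisted = TRUE),
    bed_cycling = protocol_script("bed_cycling", cycling, transition_s = 2.5)
  )
}

# spherical linear interpolation between unit vectors a, b at fractions u
slerp <- function(a, b, u) {
  dotab <- max(-1, min(1, sum(a * b)))
  omega <- acos(dotab)
  if (omega < 1e-9)
    return(matrix(rep(a, each = length(u)), ncol = 3))
  if (pi - omega < 1e-6)
    stop("antipodal postures cannot be interpolated; route via an intermediate posture")
  (outer(sin((1 - u) * omega), a) + outer(sin(u * omega), b)) / sin(omega)
}

min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

# elementwise rotations of row vectors (x, y, z) about the device axes
rot_y <- function(xyz, a) {
  cbind(cos(a) * xyz[, 1] + sin(a) * xyz[, 3], xyz[, 2],
        -sin(a) * xyz[, 1] + cos(a) * xyz[, 3])
}
rot_z <- function(xyz, a) {
  cbind(cos(a) * xyz[, 1] - sin(a) * xyz[, 2],
        sin(a) * xyz[, 1] + cos(a) * xyz[, 2], xyz[, 3])
}
rot_x <- function(xyz, a) {
  cbind(xyz[, 1], cos(a) * xyz[, 2] - sin(a) * xyz[, 3],
        sin(a) * xyz[, 2] + cos(a) * xyz[, 3])
}

# run code with a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# one sensor's gravity-direction timeline plus body acceleration, noiseless
sensor_tracks <- function(script, site, t) {
  n <- length(t)
  segs <- as.data.frame(script)
  ends <- cumsum(segs$duration_s)
  starts <- ends - segs$duration_s
  seg_of <- findInterval(t, starts, rightmost.closed = FALSE)
  seg_of[seg_of < 1L] <- 1L
  seg_of[seg_of > nrow(segs)] <- nrow(segs)

  dir <- matrix(0, n, 3)
  for (j in seq_len(nrow(segs))) {
    act <- if (segs$is_transition[j]) {
      segs$activity[min(j + 1L, nrow(segs))]  # overwritten by rotation below
    } else segs$activity[j]
    idx <- seg_of == j
    if (any(idx)) dir[idx, ] <- matrix(script_orientation(act, site),
                                       sum(idx), 3, byrow = TRUE)
  }

  ease <- attr(script, "ease_s")
  for (j in which(segs$is_transition)) {
    o_a <- script_orientation(segs$activity[j - 1L], site)
    o_b <- script_orientation(segs$activity[j + 1L], site)
    if (sum(abs(o_a - o_b)) < 1e-12) next
    if (is.na(ease)) {
      r0 <- starts[j]; r1 <- ends[j]
    } else {
      tc <- (starts[j] + ends[j]) / 2
      r0 <- max(tc - ease / 2, starts[j - 1L])
      r1 <- min(tc + ease / 2, ends[j + 1L])
    }
    idx <- which(t >= r0 & t <= r1)
    if (length(idx) == 0L) next
    u <- min_jerk((t[idx] - r0) / (r1 - r0))
    dir[idx, ] <- slerp(o_a, o_b, u)
  }

  # cycling: thigh pivots about the mediolateral axis at the pedalling rate
  amp <- attr(script, "cycle_amp_deg") * pi / 180
  f_c <- attr(script, "cycle_freq")
  if (site == "thigh") {
    for (j in which(segs$activity %in% c("CYCLE_FLAT", "CYCLE_SEMI"))) {
      idx <- which(seg_of == j)
      a <- amp * sin(2 * pi * f_c * (t[idx] - starts[j]))
      dir[idx, ] <- rot_y(dir[idx, , drop = FALSE], a)
    }
  }

  body <- matrix(0, n, 3)
  f_b <- attr(script, "burst_freq")
  b_amp <- attr(script, "burst_amp")
  for (j in which(segs$is_transition)) {
    idx <- which(seg_of == j)
    body[idx, 3] <- body[idx, 3] +
      (pi / 2) * b_amp * sin(2 * pi * f_b * (t[idx] - starts[j]))
  }
  w_amp <- attr(script, "walk_amp"); f_w <- attr(script, "walk_freq")
  for (j in which(segs$activity == "WALK")) {
    idx <- which(seg_of == j)
    body[idx, 1] <- body[idx, 1] +
      (pi / 2) * w_amp * sin(2 * pi * f_w * (t[idx] - starts[j]))
  }
  if (site == "thigh") {
    c_amp <- attr(script, "cycle_accel_amp")
    for (j in which(segs$activity %in% c("CYCLE_FLAT", "CYCLE_SEMI"))) {
      idx <- which(seg_of == j)
      body[idx, 3] <- body[idx, 3] +
        (pi / 2) * c_amp * sin(2 * pi * f_c * (t[idx] - starts[j]))
    }
  }
  list(dir = dir, body = body, seg_of = seg_of, starts = starts, ends = ends)
}

# slow-varying zero-mean series with the requested SD (postural sway)
slow_jitter <- function(n, rate, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  y <- zero_phase_lowpass(x, rate, cutoff_hz = 0.1)
  s <- stats::sd(y)
  if (s < 1e-12) return(numeric(n))
  y * (sd_target / s)
}

#' Simulate a dual-sensor recording
#'
#' Generates chest and thigh tri-axial accelerometer signals at 20 Hz plus a
#' 5 Hz ground-truth label stream for a scripted protocol. Static segments
#' hold the posture's gravity direction, perturbed by slow postural sway
#' (SD `angle_jitter_sd`) and white accelerometer noise; transitions rotate
#' between consecutive postures along the great circle with a minimum-jerk
#' profile and carry a movement burst whose rectified mean equals the
#' script's `burst_amp` (0.10 g self-initiated, 0.02 g assisted). Assisted
#' transfers are eased by the provider over `ease_s` seconds centred on the
#' brief labelled transition, so their SMA straddles the rest-activity
#' threshold from below — the mechanism behind their poor detectability.
#' Walking adds 2 Hz body-acceleration bursts on both sensors; bed cycling
#' oscillates the thigh orientation at the pedalling rate with a matching
#' body acceleration while the chest stays still. A fixed per-sensor
#' mounting misalignment (up to `baseline_offset_deg`) is applied, to be
#' removed by the supine baseline correction downstream.
#'
#' Identical `(script, noise, configuration)` inputs give bit-identical
#' recordings; the caller's RNG state is left untouched.
#'
#' @param script A [protocol_script].
#' @param noise A [noise_model].
#' @param configuration `"MCL-TR"` (chest midclavicular left + right thigh)
#'   or `"MCR-TL"`; both diagonals run through the same algorithm. The
#'   second diagonal is an independent draw (distinct sub-seed).
#' @param rate Sampling rate in Hz (default 20).
#' @return An object of class `synthetic_recording`: list with `chest` and
#'   `thigh` ([accel_signal]), `truth` ([label_stream] at 5 Hz), `script`,
#'   `noise`, `configuration`, `mount_offsets_deg`, and `calibration_s`, the
#'   supine rest window to calibrate against.
#' @export
simulate_recording <- function(script, noise = noise_model(),
                               configuration = c("MCL-TR", "MCR-TL"),
                               rate = 20) {
  stopifnot(inherits(script, "protocol_script"))
  configuration <- match.arg(configuration)
  if (any(script$duration_s <= 0)) stop("zero-duration segment in script")
  total <- sum(script$duration_s)
  n <- round(total * rate)
  t <- (seq_len(n) - 1L) / rate

  seed <- noise$seed + 1000L * (match(configuration, c("MCL-TR", "MCR-TL")) - 1L)
  sites <- if (configuration == "MCL-TR") c("chest_left", "thigh_right")
           else c("chest_right", "thigh_left")

  out <- with_seed(seed, {
    make_sensor <- function(site_kind, site_name) {
      tr <- sensor_tracks(script, site_kind, t)
      off <- stats::runif(3, -noise$baseline_offset_deg,
                          noise$baseline_offset_deg) * pi / 180
      j1 <- slow_jitter(n, rate, noise$angle_jitter_sd) * pi / 180
      j2 <- slow_jitter(n, rate, noise$angle_jitter_sd) * pi / 180
      dir <- rot_z(rot_y(tr$dir, j1), j2)
      dir <- rot_z(rot_y(rot_x(dir, off[1]), off[2]), off[3])
      xyz <- dir + tr$body +
        matrix(stats::rnorm(3 * n, sd = noise$accel_noise_sd), n, 3)
      list(signal = accel_signal(xyz, rate = rate, site = site_name),
           offset_deg = off * 180 / pi)
    }
    chest <- make_sensor("chest", sites[1])
    thigh <- make_sensor("thigh", sites[2])
    list(chest = chest, thigh = thigh)
  })

  n5 <- floor(total * 5)
  centers <- (seq_len(n5) - 0.5) / 5
  ends <- cumsum(script$duration_s)
  starts <- ends - script$duration_s
  seg_of <- findInterval(centers, starts)
  truth <- label_stream(script$label[seg_of], rate = 5, start_s = 0,
                        source = "rater")

  structure(
    list(chest = out$chest$signal, thigh = out$thigh$signal, truth = truth,
         script = script, noise = noise, configuration = configuration,
         mount_offsets_deg = list(chest = out$chest$offset_deg,
                                  thigh = out$thigh$offset_deg),
         calibration_s = attr(script, "calibration_s")),
    class = "synthetic_recording"
  )
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %s protocol (%s), %.1f s, seed %d\n",
    attr(x$script, "kind"), x$configuration,
    n_samples(x$chest) / x$chest$rate, x$noise$seed))
  invisible(x)
}

#' Ground-truth annotations of a recording
#'
#' Converts a recording's 5 Hz truth stream into an interval-based
#' [annotation_track], optionally shifted in time (to emulate an annotation
#' clock that started before or after the sensors).
#'
#' @param x A `synthetic_recording` or a [label_stream].
#' @param shift_s Seconds added to every interval (default 0).
#' @return An [annotation_track].
#' @export
truth_annotations <- function(x, shift_s = 0) {
  stream <- if (inherits(x, "synthetic_recording")) x$truth else x
  bouts <- extract_bouts(stream)
  annotation_track(bouts$start_s + shift_s,
                   bouts$start_s + bouts$duration_s + shift_s,
                   bouts$label)
}
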