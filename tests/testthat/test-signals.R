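# Feature pipeline: median filter, gravity extraction, tilt angles,
# baseline correction, SMA, epoch fusion.

test_that("median filter smooths spikes, preserves constants, matches a brute-force oracle", {
  const <- constant_signal(c(0.1, 0.1, 0.1), secs = 1)
  expect_equal(median_filter3(const)$xyz, const$xyz)

  spike <- accel_signal(cbind(c(0, 10, 0), 0, 1), rate = 20, site = "chest_left")
  expect_equal(unname(median_filter3(spike)$xyz[, 1]), c(0, 0, 0))

  set.seed(42)
  x <- matrix(rnorm(600), 200, 3)
  sig <- accel_signal(x, rate = 20, site = "thigh_left")
  filtered <- median_filter3(sig)
  for (j in 1:3)
    expect_equal(unname(filtered$xyz[, j]), oracle_median3(x[, j]))

  too_short <- constant_signal(secs = 1)
  too_short$xyz <- too_short$xyz[1:2, ]
  expect_error(median_filter3(too_short), "3 samples")
})

test_that("gravity low-pass passes DC exactly and rejects movement frequencies", {
  # DC passthrough
  const <- constant_signal(c(0, 0, 1), secs = 60)
  g <- extract_gravity(const)
  expect_lt(max(abs(g$xyz[, 3] - 1)), 1e-6)
  expect_lt(max(abs(g$xyz[, 1:2])), 1e-6)

  # analytic DC gain of the designed coefficients
  bf <- signal::butter(2, 0.25 / 10, type = "low")
  expect_lt(abs(sum(bf$b) / sum(bf$a) - 1), 1e-9)

  # 2 Hz ripple attenuated by >= 20 dB (analytically it is ~72 dB one-way)
  rate <- 20; t <- (0:(60 * rate - 1)) / rate
  rippled <- accel_signal(cbind(0, 0, 1 + 0.5 * sin(2 * pi * 2 * t)),
                          rate = rate, site = "chest_left")
  gz <- extract_gravity(rippled)$xyz[, 3]
  interior <- seq(10 * rate, 50 * rate)
  ripple_out <- stats::sd(gz[interior] - mean(gz[interior]))
  ripple_in <- stats::sd(0.5 * sin(2 * pi * 2 * t[interior]))
  expect_lt(ripple_out / ripple_in, 10^(-20 / 20))

  # 0.01 Hz drift passes with < 5% amplitude error
  t2 <- (0:(200 * rate - 1)) / rate
  drift <- 0.2 * sin(2 * pi * 0.01 * t2)
  sig <- accel_signal(cbind(0, 0, 1 + drift), rate = rate, site = "chest_left")
  out <- extract_gravity(sig)$xyz[, 3] - 1
  basis <- cbind(sin(2 * pi * 0.01 * t2), cos(2 * pi * 0.01 * t2))
  amp <- sqrt(sum(stats::lm.fit(basis, out)$coefficients^2))
  expect_lt(abs(amp / 0.2 - 1), 0.05)

  expect_error(extract_gravity(const, cutoff_hz = 10), "rate/2")
})

test_that("tilt angles match the axis-aligned anchors and the exact 45-degree case", {
  angles_of <- function(g) {
    sig <- constant_signal(g, secs = 1)
    grav <- extract_gravity(sig, cutoff_hz = 0.25)
    a <- compute_tilt_angles(grav)
    c(theta = a$theta[10], psi = a$psi[10], phi = a$phi[10])
  }
  expect_equal(angles_of(c(0, 0, 1)), c(theta = 0, psi = 0, phi = 90),
               tolerance = 1e-9)
  expect_equal(angles_of(c(1, 0, 0))[["phi"]], 0, tolerance = 1e-9)
  expect_equal(angles_of(c(0, sqrt(2) / 2, sqrt(2) / 2)),
               c(theta = 45, psi = 45, phi = 90), tolerance = 1e-9)
})

test_that("zero-magnitude gravity samples are flagged and carry the previous angles", {
  sig <- constant_signal(c(0, 0, 1), secs = 1)
  grav <- extract_gravity(sig)
  grav$xyz[5, ] <- 0
  a <- compute_tilt_angles(grav)
  expect_true(a$flagged[5])
  expect_equal(a$phi[5], a$phi[4])
  grav$xyz[] <- 0
  expect_error(compute_tilt_angles(grav), "zero everywhere")
})

test_that("tilt angles invert exactly: random gravity directions are recovered", {
  set.seed(2024)
  n <- 1000
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  sig <- constant_signal(secs = n / 20)
  grav <- extract_gravity(sig)
  grav$xyz <- v
  a <- compute_tilt_angles(grav)
  rad <- pi / 180
  rebuilt <- cbind(cos(a$phi * rad),
                   sin(a$phi * rad) * sin(a$theta * rad),
                   sin(a$phi * rad) * cos(a$theta * rad))
  expect_lt(max(abs(rebuilt - v)), 1e-9)
})

test_that("supine baseline correction recovers (0, 0, 90) and is idempotent", {
  mk_angles <- function(theta, psi, phi, secs = 30, rate = 20) {
    structure(
      list(theta = rep(theta, secs * rate), psi = rep(psi, secs * rate),
           phi = rep(phi, secs * rate), rate = rate, start_offset = 0,
           corrected = FALSE, flagged = logical(secs * rate)),
      class = "orientation_series")
  }
  ideal <- mk_angles(0, 0, 90)
  out <- calibrate_supine(ideal, c(5, 25))
  expect_equal(out$offsets$d_theta, 0)
  expect_equal(out$offsets$d_psi, 0)
  expect_equal(out$offsets$d_phi, 0)
  expect_equal(out$angles$theta, ideal$theta)

  shifted <- mk_angles(3, -2, 87)
  out2 <- calibrate_supine(shifted, c(5, 25))
  expect_equal(unlist(out2$offsets[c("d_theta", "d_psi", "d_phi")],
                      use.names = FALSE), c(3, -2, -3))
  win <- (5 * 20):(25 * 20)
  expect_equal(mean(out2$angles$theta[win]), 0)
  expect_equal(mean(out2$angles$phi[win]), 90)

  # noisy window: corrected window mean within 0.1 degrees at a 10 s window
  set.seed(7)
  n <- 10 * 20
  noisy <- mk_angles(0, 0, 0, secs = 10)
  noisy$theta <- 5 + rnorm(n, sd = 0.5)
  noisy$psi <- 1 + rnorm(n, sd = 0.5)
  noisy$phi <- 92 + rnorm(n, sd = 0.5)
  out3 <- calibrate_supine(noisy, c(0, 10))
  expect_lt(abs(mean(out3$angles$theta)), 0.1)
  expect_lt(abs(mean(out3$angles$psi)), 0.1)
  expect_lt(abs(mean(out3$angles$phi) - 90), 0.1)

  # idempotence: re-calibrating a corrected series yields zero offsets
  again <- calibrate_supine(out2$angles, c(5, 25))
  expect_equal(again$offsets$d_theta, 0, tolerance = 1e-12)
  expect_equal(again$offsets$d_phi, 0, tolerance = 1e-12)

  expect_error(calibrate_supine(ideal, c(25, 40)), "outside")
  expect_error(calibrate_supine(ideal, c(5, 6)), "at least 2 s")
})

test_that("SMA is zero without body acceleration and matches the rectified-sine value", {
  const <- constant_signal(c(0, 0, 1), secs = 30)
  grav <- extract_gravity(const)
  sma0 <- compute_sma(const, grav)
  expect_lt(max(sma0$values), 1e-8)

  # A sin(2 pi 2 t): mean rectified value is 2A/pi; fine grid so the
  # trapezoidal discretisation error is well under the 1% tolerance
  rate <- 100; A <- 0.1
  t <- (0:(60 * rate - 1)) / rate
  sig <- accel_signal(cbind(A * sin(2 * pi * 2 * t), 0, 1), rate = rate,
                      site = "chest_left")
  sma <- compute_sma(sig, extract_gravity(sig))
  expect_lt(abs(mean(sma$values) / (2 * A / pi) - 1), 0.01)

  # white sensor noise stays under the rest-activity threshold
  set.seed(11)
  noisy <- constant_signal(c(0, 0, 1), secs = 120)
  noisy$xyz <- noisy$xyz + matrix(rnorm(3 * n_samples(noisy), sd = 0.005),
                                  ncol = 3)
  sman <- compute_sma(median_filter3(noisy), extract_gravity(median_filter3(noisy)))
  expect_gte(mean(sman$values < 0.03), 0.99)
})

test_that("SMA is shift-invariant and exactly homogeneous in the body acceleration", {
  set.seed(5)
  n <- 600
  base <- matrix(rnorm(3 * n, sd = 0.05), n, 3)
  raw <- accel_signal(sweep(base, 2, c(0, 0, 1), "+"), rate = 20,
                      site = "thigh_left")
  grav <- extract_gravity(constant_signal(c(0, 0, 1), secs = n / 20))
  s1 <- compute_sma(raw, grav)

  shift <- c(0.3, -0.2, 0.5)
  raw2 <- raw; raw2$xyz <- sweep(raw$xyz, 2, shift, "+")
  grav2 <- grav; grav2$xyz <- sweep(grav$xyz, 2, shift, "+")
  expect_equal(compute_sma(raw2, grav2)$values, s1$values)

  k <- 3.7
  raw3 <- raw; raw3$xyz <- grav$xyz + k * (raw$xyz - grav$xyz)
  expect_equal(compute_sma(raw3, grav)$values, k * s1$values)

  short <- constant_signal(secs = 5)
  expect_error(compute_sma(short, grav), "equal length")
})

test_that("epoch frame covers the sensor overlap at 5 Hz and passes constants through", {
  feats <- function(g, secs, start = 0) {
    sig <- constant_signal(g, secs = secs, start_offset = start)
    grav <- extract_gravity(sig)
    list(angles = compute_tilt_angles(grav), sma = compute_sma(sig, grav),
         gravity = grav, raw = sig)
  }
  chest <- feats(c(0, 0, 1), 10)
  thigh <- feats(c(0, 0, 1), 10)
  frame <- build_epoch_frame(chest, thigh)
  expect_equal(nrow(frame), 50)
  expect_equal(unique(round(diff(frame$epoch_s), 9)), 0.2)
  expect_equal(frame$phi_mc, rep(90, 50), tolerance = 1e-9)
  # on a 10 s fixture the reflection pad is capped at n-1 samples, leaving a
  # ~1e-6 startup transient in the gravity magnitude
  expect_equal(frame$gmag_mc, rep(1, 50), tolerance = 1e-5)

  late_chest <- feats(c(0, 0, 1), 10, start = 1)
  frame2 <- build_epoch_frame(late_chest, thigh)
  expect_equal(nrow(frame2), 45)
  expect_equal(frame2$epoch_s[1], 1)

  apart <- feats(c(0, 0, 1), 10, start = 100)
  expect_error(build_epoch_frame(apart, thigh), "overlap")
})
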