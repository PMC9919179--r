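# Independent oracles and fixture builders used across the suite.

# brute-force 3-point median with edge replication
oracle_median3 <- function(x) {
  n <- length(x)
  xp <- c(x[1], x, x[n])
  vapply(seq_len(n), function(i) sort(xp[i:(i + 2)])[2], numeric(1))
}

# ICC(A,1) via stats::aov (independent route: model-fit mean squares)
oracle_icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(
    y = as.vector(x),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ subject + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# constant-orientation accel signal
constant_signal <- function(g = c(0, 0, 1), secs = 10, rate = 20,
                            site = "chest_left", start_offset = 0) {
  n <- round(secs * rate)
  accel_signal(matrix(rep(g, each = n), n, 3), rate = rate, site = site,
               start_offset = start_offset)
}

# epoch frame with every column constant (classifier fixtures)
constant_frame <- function(n, phi_mc = 90, theta_mc = 0, phi_t = 90,
                           sma_mc = 0.01, sma_t = 0.01) {
  frame <- data.frame(
    epoch_s = (seq_len(max(n, 1L)) - 1) * 0.2,
    phi_mc = phi_mc, theta_mc = theta_mc, psi_mc = 0,
    phi_t = phi_t, theta_t = 0, psi_t = 0,
    sma_mc = sma_mc, sma_t = sma_t,
    phi_t_inst = phi_t, gmag_mc = 1, gmag_t = 1
  )
  frame <- frame[seq_len(n), , drop = FALSE]
  class(frame) <- c("epoch_frame", "data.frame")
  attr(frame, "rate") <- 5
  frame
}

# simulate -> process -> classify -> agreement against ground truth
run_protocol <- function(script, seed, config = classifier_config(),
                         configuration = "MCL-TR") {
  rec <- simulate_recording(script, noise_model(seed = seed),
                            configuration = configuration)
  frame <- process_recording(rec$chest, rec$thigh,
                             calibration_window = rec$calibration_s,
                             config = config)
  stream <- classify_recording(frame, config)
  n <- min(length(rec$truth$labels), length(stream$labels))
  report <- percent_agreement(as.character(rec$truth$labels)[seq_len(n)],
                              as.character(stream$labels)[seq_len(n)])
  list(recording = rec, frame = frame, stream = stream, report = report)
}
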