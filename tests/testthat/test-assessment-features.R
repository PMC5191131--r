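fs <- 32

test_that("the assessment feature vector has the canonical 39 names", {
  nm <- assessment_feature_names()
  expect_length(nm, 39)
  expect_length(grep("^duration_", nm), 6)
  expect_length(grep("^STS5_", nm), 10)
  expect_false(anyDuplicated(nm) > 0)
})

test_that("peak detection finds prominent peaks and preceding feet", {
  u <- seq(0, 1, length.out = 200)
  x <- numeric(200)
  centers <- c(0.2, 0.5, 0.8)
  for (c0 in centers) x <- x + exp(-(u - c0)^2 / (2 * 0.03^2))
  pk <- detect_peaks(x, 3)
  expect_length(pk$peak_indices, 3)
  expect_equal(u[pk$peak_indices], centers, tolerance = 0.02)
  expect_true(all(pk$foot_indices < pk$peak_indices))
  expect_true(all(pk$foot_values < pk$peak_values))
  expect_false(pk$shortfall)
  # asking for more peaks than exist flags a shortfall
  pk2 <- detect_peaks(x, 5)
  expect_true(pk2$shortfall)
  expect_length(pk2$peak_indices, 3)
  # prominence ranking: tiny riders on a big bump are not selected
  y <- exp(-(u - 0.5)^2 / (2 * 0.1^2)) + 0.01 * sin(40 * pi * u)
  pk3 <- detect_peaks(y, 1)
  expect_equal(u[pk3$peak_indices], 0.5, tolerance = 0.05)
})

test_that("transition features recover slope and residual structure", {
  N <- 3 * fs
  t <- (0:(N - 1)) / fs
  seg <- cbind(0.1 + 0.2 * t, rep(0.3, N))
  f <- transition_features(seg, fs)
  expect_equal(unname(f[1]), max(seg[, 1]))       # max acceleration
  expect_equal(unname(f[2]), 0.2, tolerance = 1e-9)  # slope in g/s
  expect_equal(unname(f[3]), 0, tolerance = 1e-12)   # residual variance
  expect_equal(unname(f[4]), 0, tolerance = 1e-12)   # ch2 variance
  # adding sinusoidal residual raises resid var but keeps the slope
  seg2 <- seg
  seg2[, 1] <- seg2[, 1] + 0.05 * sin(2 * pi * 3 * t)
  f2 <- transition_features(seg2, fs)
  expect_equal(unname(f2[2]), 0.2, tolerance = 0.05)
  expect_gt(f2[3], f[3])
})

test_that("repeated-activity features measure peaks and timing", {
  set.seed(40)
  seg <- clean_burst("pen5", 8)
  f <- repeated_features(seg, "pen5", fs)
  expect_length(f, 5)
  expect_gt(f["pen5_avg_peak"], 0.5)
  expect_gt(f["pen5_mean_ptp"], 0.5)       # 5 bumps over 8 s: ~1.6 s
  expect_lt(f["pen5_mean_ptp"], 3)
  expect_gt(f["pen5_mean_ftp"], 1 / fs)
  fr <- repeated_features(clean_burst("reach5", 7), "reach5", fs)
  expect_length(fr, 6)
  expect_true("reach5_avg_peak_ch2" %in% names(fr))
})

test_that("slower repetitions increase peak-to-peak durations", {
  set.seed(41)
  fast <- clean_burst("pen5", 6, seed = 1)
  slow <- clean_burst("pen5", 12, seed = 1)
  f_fast <- repeated_features(fast, "pen5", fs)
  f_slow <- repeated_features(slow, "pen5", fs)
  expect_gt(f_slow["pen5_mean_ptp"], f_fast["pen5_mean_ptp"])
})

test_that("sit-to-stand features separate the two peak families", {
  set.seed(42)
  seg <- clean_burst("STS5", 10)
  f <- sts_features(seg, fs)
  expect_length(f, 10)
  # family 1 amplitudes (1.0 / 0.5) dominate family 2 (0.6 / 0.3)
  expect_gt(f["STS5_sit_peak_ch1"], f["STS5_stand_peak_ch1"])
  expect_gt(f["STS5_sit_peak_ch2"], f["STS5_stand_peak_ch2"])
  expect_true(all(f[c("STS5_hp_var_ch1", "STS5_hp_var_ch2")] >= 0))
})

test_that("the high-pass filter attenuates a 0.6 Hz tone by at least 40 dB", {
  # independent frequency-response check of the 4th-order 2.4 Hz
  # Butterworth: evaluate the transfer function on the unit circle directly
  bt <- signal::butter(4, 2.4 / (fs / 2), type = "high")
  H_at <- function(f_hz) {
    w <- 2 * pi * f_hz / fs
    z <- exp(-1i * w * (seq_along(bt$b) - 1))
    abs(sum(bt$b * z) / sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1))))
  }
  expect_lt(20 * log10(H_at(0.6)), -40)
  # and the passband is essentially flat at 8 Hz
  expect_gt(H_at(8), 0.9)
  # time-domain confirmation inside sts_features' filter path
  n <- 10 * fs
  t <- (0:(n - 1)) / fs
  low <- sin(2 * pi * 0.6 * t)
  filt <- signal::filter(bt, low)
  tail_part <- filt[(2 * fs):n]     # skip the transient
  expect_lt(sqrt(mean(tail_part^2)) / sqrt(mean(low^2)), 0.01)
})

test_that("patient vectors average repetitions and order canonically", {
  set.seed(43)
  segs <- list(
    getup = list(clean_burst("getup", 3, seed = 1),
                 clean_burst("getup", 3.2, seed = 2)),
    liedown = list(clean_burst("liedown", 3.5, seed = 3)),
    maxreach = list(clean_burst("maxreach", 2.5, seed = 4)),
    pen5 = list(clean_burst("pen5", 8, seed = 5)),
    reach5 = list(clean_burst("reach5", 7, seed = 6)),
    STS5 = list(clean_burst("STS5", 10, seed = 7)))
  v <- assemble_patient_vector(segs, fs)
  expect_identical(names(v), assessment_feature_names())
  expect_true(all(is.finite(v)))
  d1 <- nrow(segs$getup[[1]]) / fs
  d2 <- nrow(segs$getup[[2]]) / fs
  expect_equal(unname(v["duration_getup"]), mean(c(d1, d2)))
  segs$pen5 <- NULL
  expect_error(assemble_patient_vector(segs, fs), "pen5")
})
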