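#' Canonical recognition feature names
#'
#' The fixed order of the 39 recognition features: 18 pattern features
#' (matching cost and per-channel correlations against each of the six
#' activity templates, in canonical class order) followed by 21 window
#' features.
#'
#' @return character vector of length 39.
#' @export
recognition_feature_names <- function() {
  c(paste0("cost_", ACTIVITIES),
    paste0("r_ch1_", ACTIVITIES),
    paste0("r_ch2_", ACTIVITIES),
    "duration_s", "mean_ch1", "mean_ch2",
    paste0("bin", rep(1:3, each = 2), "_mean_ch", rep(1:2, 3)),
    "std_ch1", "std_ch2", "power_ch1", "power_ch2",
    "range_ch1", "range_ch2", "line_length_ch1", "line_length_ch2",
    "spectral_entropy_ch1", "spectral_entropy_ch2",
    "avg_autocorr_ch1", "avg_autocorr_ch2")
}

# one-sided periodogram (DC included) normalized to sum 1
normalized_power_spectrum <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(floor(n / 2) + 1L)]
  tot <- sum(half)
  if (tot == 0) return(rep(0, length(half)))
  half / tot
}

#' Spectral entropy of a signal
#'
#' Shannon entropy, in base-10 (Briggs) logarithm, of the one-sided
#' periodogram normalized to unit sum; \eqn{0 \log 0 := 0}. A spectrum with
#' all power in a single bin gives 0; uniform power over K bins gives
#' \eqn{\log_{10} K}. Zero-variance signals are defined to have entropy 0.
#'
#' @param x numeric vector (the raw, mean-retained signal).
#' @return non-negative scalar.
#' @export
spectral_entropy <- function(x) {
  if (stats::sd(x) == 0) return(0)
  ps <- normalized_power_spectrum(x)
  ps <- ps[ps > 0]
  -sum(ps * log10(ps))
}

#' Line length of a signal
#'
#' \eqn{L = \sum_{i=2}^N |S_i - S_{i-1}|}, a complexity measure.
#'
#' @param x numeric vector.
#' @return non-negative scalar.
#' @export
line_length <- function(x) sum(abs(diff(x)))

# mean of the normalized (biased) autocorrelation coefficients at lags
# 1 .. round(N/7); 0 for zero-variance signals
avg_autocorr <- function(x) {
  n <- length(x)
  lags <- round(n / 7)
  if (lags < 1L) stop("avg_autocorr: series too short (need N >= 7)")
  if (stats::sd(x) == 0) return(0)
  ac <- stats::acf(x, lag.max = lags, type = "correlation", plot = FALSE,
                   demean = TRUE)$acf[-1L]
  mean(ac)
}

#' Window features of a two-channel segment
#'
#' The 21 statistical signal features: duration \eqn{N/f_s}; per-channel
#' means of the raw signal (orientation via the gravity component); means of
#' three uniform time bins per channel; per-channel standard deviation,
#' power (mean squared amplitude), range, [line_length()],
#' [spectral_entropy()], and the average autocorrelation over
#' \code{round(N/7)} lags.
#'
#' @param segment numeric matrix (N x 2), raw acceleration in g.
#' @param sample_rate sampling frequency in Hz.
#' @return named numeric vector of length 21, in canonical order.
#' @export
window_features <- function(segment, sample_rate) {
  seg <- as_channel_matrix(segment)
  n <- nrow(seg)
  if (n < 7L) stop("window_features: segment must have at least 7 samples")
  b1 <- round(n / 3); b2 <- round(2 * n / 3)
  bins <- list(1:b1, (b1 + 1L):b2, (b2 + 1L):n)
  out <- c(duration_s = n / sample_rate,
           mean_ch1 = mean(seg[, 1L]), mean_ch2 = mean(seg[, 2L]))
  for (b in 1:3) {
    for (ch in 1:2) {
      out[paste0("bin", b, "_mean_ch", ch)] <- mean(seg[bins[[b]], ch])
    }
  }
  for (stat in c("std", "power", "range", "line_length",
                 "spectral_entropy", "avg_autocorr")) {
    for (ch in 1:2) {
      x <- seg[, ch]
      v <- switch(stat,
                  std = stats::sd(x),
                  power = mean(x^2),
                  range = max(x) - min(x),
                  line_length = line_length(x),
                  spectral_entropy = spectral_entropy(x),
                  avg_autocorr = avg_autocorr(x))
      out[paste0(stat, "_ch", ch)] <- v
    }
  }
  out
}

#' Pattern features of a segment against the six activity templates
#'
#' For each activity class in canonical order, [match_to_template()] yields
#' the path-length-normalized DTW matching cost and the two per-channel
#' Pearson correlations along the warping path: 6 + 12 = 18 features.
#'
#' @param segment numeric matrix (N x 2).
#' @param templates named list with exactly one \code{"actcap_template"}
#'   per activity class.
#' @param band optional DTW band radius.
#' @return named numeric vector of length 18, in canonical order.
#' @export
pattern_features <- function(segment, templates, band = Inf) {
  if (!setequal(names(templates), ACTIVITIES) ||
      length(templates) != length(ACTIVITIES)) {
    stop("pattern_features: need exactly one template per activity class; ",
         "missing/extra: ",
         paste(c(setdiff(ACTIVITIES, names(templates)),
                 setdiff(names(templates), ACTIVITIES)), collapse = ", "))
  }
  costs <- numeric(6); r1 <- numeric(6); r2 <- numeric(6)
  for (k in seq_along(ACTIVITIES)) {
    m <- match_to_template(segment, templates[[ACTIVITIES[k]]], band = band)
    costs[k] <- m$norm_cost; r1[k] <- m$r[1L]; r2[k] <- m$r[2L]
  }
  out <- c(costs, r1, r2)
  names(out) <- c(paste0("cost_", ACTIVITIES),
                  paste0("r_ch1_", ACTIVITIES),
                  paste0("r_ch2_", ACTIVITIES))
  out
}

#' Full 39-dimensional recognition feature vector
#'
#' Concatenates [pattern_features()] and [window_features()] in the
#' canonical order of [recognition_feature_names()].
#'
#' @inheritParams pattern_features
#' @inheritParams window_features
#' @return named numeric vector of length 39.
#' @export
extract_recognition_features <- function(segment, templates, sample_rate,
                                         band = Inf) {
  out <- c(pattern_features(segment, templates, band = band),
           window_features(segment, sample_rate))
  stopifnot(identical(names(out), recognition_feature_names()))
  out
}
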