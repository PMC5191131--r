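#' Canonical assessment feature names
#'
#' The 39 interpretable per-patient features: six activity durations; for
#' each single-transition activity (getup, liedown, maxreach) the maximal
#' longitudinal acceleration, the slope of a linear fit, the residual
#' variance around it and the second-channel variance; five repeated-peak
#' features for pen5 and six for reach5; and ten sit-to-stand features
#' (sit/stand peak values and foot-to-peak durations per channel, plus
#' high-pass-filtered channel variances).
#'
#' @return character vector of length 39.
#' @export
assessment_feature_names <- function() {
  c(paste0("duration_", ACTIVITIES),
    as.vector(t(outer(c("getup", "liedown", "maxreach"),
                      c("max_acc_long", "slope_long", "resid_var_long", "var_ch2"),
                      paste, sep = "_"))),
    paste0("pen5_", c("avg_peak", "mean_ptp", "std_ptp", "mean_ftp", "mean_slope")),
    paste0("reach5_", c("avg_peak", "mean_ptp", "std_ptp", "mean_ftp",
                        "mean_slope", "avg_peak_ch2")),
    paste0("STS5_", c("sit_peak_ch1", "sit_peak_ch2", "stand_peak_ch1",
                      "stand_peak_ch2", "ftp_sit_ch1", "ftp_sit_ch2",
                      "ftp_stand_ch1", "ftp_stand_ch2", "hp_var_ch1",
                      "hp_var_ch2")))
}

# prominence of a local maximum at index p: height above the higher of the
# two minima separating it from higher terrain (or the signal edges)
peak_prominence <- function(x, p) {
  left <- x[seq_len(p)]
  higher_l <- which(left > x[p])
  lo_l <- if (length(higher_l)) min(x[(max(higher_l)):p]) else min(left)
  right <- x[p:length(x)]
  higher_r <- which(right > x[p])
  lo_r <- if (length(higher_r)) min(right[1:(min(higher_r))]) else min(right)
  x[p] - max(lo_l, lo_r)
}

#' Detect the most prominent local maxima and their feet
#'
#' Finds all strict local maxima (plateau centers), keeps the
#' \code{expected_count} with the highest topographic prominence, returns
#' them in time order, and pairs each with its foot: the nearest preceding
#' local minimum (or the segment start). If fewer maxima exist than
#' requested, all are returned and \code{shortfall} is set.
#'
#' @param channel numeric vector (length >= 3).
#' @param expected_count number of peaks sought.
#' @return list of class \code{"actcap_peaks"} with \code{peak_indices},
#'   \code{peak_values}, \code{foot_indices}, \code{foot_values} (1-based
#'   sample indices, strictly increasing) and \code{shortfall}.
#' @export
detect_peaks <- function(channel, expected_count) {
  x <- as.numeric(channel)
  n <- length(x)
  if (n < 3L) stop("detect_peaks: channel must have at least 3 samples")
  # strict local maxima, plateaus represented by their center
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) {
    return(structure(list(peak_indices = integer(0), peak_values = numeric(0),
                          foot_indices = integer(0), foot_values = numeric(0),
                          shortfall = TRUE),
                     class = "actcap_peaks"))
  }
  prom <- vapply(cand, function(p) peak_prominence(x, p), 0)
  ord <- order(prom, decreasing = TRUE)
  keep <- sort(cand[ord[seq_len(min(expected_count, length(cand)))]])
  feet <- vapply(keep, function(p) {
    # nearest preceding local minimum (or segment start)
    i <- p
    while (i > 1L && x[i - 1L] <= x[i]) i <- i - 1L
    i
  }, 0L)
  # feet coinciding with the peak (monotone rise from start) map to start
  feet[feet >= keep] <- 1L
  structure(list(peak_indices = keep, peak_values = x[keep],
                 foot_indices = feet, foot_values = x[feet],
                 shortfall = length(keep) < expected_count),
            class = "actcap_peaks")
}

#' Features of a single-transition activity segment
#'
#' For getup, liedown and maxreach: the maximum acceleration of the
#' longitudinal channel, the slope (g/s) of a least-squares line fit to it,
#' the variance of the residuals around that line, and the plain variance of
#' the second channel.
#'
#' @param segment numeric matrix (N x 2), raw acceleration in g.
#' @param sample_rate sampling frequency in Hz.
#' @return named numeric vector of length 4.
#' @export
transition_features <- function(segment, sample_rate) {
  seg <- as_channel_matrix(segment)
  t <- (seq_len(nrow(seg)) - 1L) / sample_rate
  fit <- stats::lm.fit(cbind(1, t), seg[, 1L])
  c(max_acc_long = max(seg[, 1L]),
    slope_long = unname(fit$coefficients[2L]),
    resid_var_long = mean(fit$residuals^2),
    var_ch2 = stats::var(seg[, 2L]))
}

#' Features of a repeated-peak activity segment (pen5 / reach5)
#'
#' Peaks are detected on the longitudinal channel (expected 5). Features:
#' the average peak value, the mean and standard deviation of the
#' peak-to-peak durations, the mean foot-to-peak duration, and the mean of
#' the per-repetition slopes (peak value minus foot value over foot-to-peak
#' duration). For reach5 the average second-channel peak value is added.
#'
#' @inheritParams transition_features
#' @param which \code{"pen5"} or \code{"reach5"}.
#' @param expected_peaks peaks sought per channel (default 5).
#' @return named numeric vector of length 5 (pen5) or 6 (reach5), with
#'   attribute \code{"shortfall"} when fewer peaks were found.
#' @export
repeated_features <- function(segment, which = c("pen5", "reach5"),
                              sample_rate, expected_peaks = 5L) {
  which <- match.arg(which)
  seg <- as_channel_matrix(segment)
  pk <- detect_peaks(seg[, 1L], expected_peaks)
  if (length(pk$peak_indices) == 0L) {
    n_out <- if (which == "reach5") 6L else 5L
    out <- rep(NA_real_, n_out)
  } else {
    ptp <- diff(pk$peak_indices) / sample_rate
    ftp <- (pk$peak_indices - pk$foot_indices) / sample_rate
    ftp_pos <- pmax(ftp, 1 / sample_rate)
    slopes <- (pk$peak_values - pk$foot_values) / ftp_pos
    out <- c(mean(pk$peak_values),
             if (length(ptp)) mean(ptp) else NA_real_,
             if (length(ptp) > 1L) stats::sd(ptp) else 0,
             mean(ftp_pos), mean(slopes))
    if (which == "reach5") {
      pk2 <- detect_peaks(seg[, 2L], expected_peaks)
      out <- c(out, if (length(pk2$peak_indices)) mean(pk2$peak_values) else NA_real_)
    }
  }
  names(out) <- paste0(which, "_",
                       c("avg_peak", "mean_ptp", "std_ptp", "mean_ftp",
                         "mean_slope", if (which == "reach5") "avg_peak_ch2"))
  attr(out, "shortfall") <- pk$shortfall
  out
}

#' Features of a repeated sit-to-stand segment (STS5)
#'
#' The STS5 acceleration pattern has two alternating peak families per
#' channel (towards sitting and towards standing). Peaks (expected 10 per
#' channel) are partitioned into the two families by strict alternation
#' starting from the first detected peak; family one is taken as the sit
#' family. Features: per-family mean peak values on both channels (4),
#' per-family mean foot-to-peak durations on both channels (4), and the
#' variance of each channel after a forward-only fourth-order high-pass
#' Butterworth filter with 2.4 Hz cutoff (2), measuring non-smoothness.
#'
#' @inheritParams transition_features
#' @param expected_peaks total peaks sought per channel (default 10).
#' @param zero_phase apply the Butterworth filter forward-backward
#'   (zero-phase) instead of forward-only (default FALSE).
#' @return named numeric vector of length 10 with attribute
#'   \code{"shortfall"}.
#' @export
sts_features <- function(segment, sample_rate, expected_peaks = 10L,
                         zero_phase = FALSE) {
  seg <- as_channel_matrix(segment)
  out <- numeric(0)
  shortfall <- FALSE
  for (ch in 1:2) {
    pk <- detect_peaks(seg[, ch], expected_peaks)
    shortfall <- shortfall || pk$shortfall
    np <- length(pk$peak_indices)
    fam <- rep_len(c(1L, 2L), np)  # alternation; family 1 = sit
    val <- function(f) if (any(fam == f)) mean(pk$peak_values[fam == f]) else NA_real_
    ftp <- (pk$peak_indices - pk$foot_indices) / sample_rate
    ftp <- pmax(ftp, 1 / sample_rate)
    ftpm <- function(f) if (any(fam == f)) mean(ftp[fam == f]) else NA_real_
    out[paste0("sit_peak_ch", ch)] <- val(1L)
    out[paste0("stand_peak_ch", ch)] <- val(2L)
    out[paste0("ftp_sit_ch", ch)] <- ftpm(1L)
    out[paste0("ftp_stand_ch", ch)] <- ftpm(2L)
  }
  bf <- signal::butter(4, 2.4 / (sample_rate / 2), type = "high")
  for (ch in 1:2) {
    hp <- if (zero_phase) {
      signal::filtfilt(bf, seg[, ch])
    } else {
      as.numeric(signal::filter(bf, seg[, ch]))
    }
    out[paste0("hp_var_ch", ch)] <- stats::var(hp)
  }
  ord <- c("sit_peak_ch1", "sit_peak_ch2", "stand_peak_ch1", "stand_peak_ch2",
           "ftp_sit_ch1", "ftp_sit_ch2", "ftp_stand_ch1", "ftp_stand_ch2",
           "hp_var_ch1", "hp_var_ch2")
  out <- stats::setNames(out[ord], paste0("STS5_", ord))
  attr(out, "shortfall") <- shortfall
  out
}

#' Assemble the per-patient 39-feature assessment vector
#'
#' Takes, per activity, one or more labeled segments (repetitions) from a
#' subject's recording, computes the activity-specific features on each
#' repetition, averages them over the repetitions, and concatenates the six
#' duration features and the per-activity features in canonical order.
#'
#' @param segments_by_activity named list (one entry per activity class) of
#'   lists of numeric N x 2 matrices, the raw signal of each repetition.
#' @param sample_rate sampling frequency in Hz.
#' @return named numeric vector of length 39 in the order of
#'   [assessment_feature_names()].
#' @export
assemble_patient_vector <- function(segments_by_activity, sample_rate) {
  missing <- setdiff(ACTIVITIES,
                     names(segments_by_activity)[
                       vapply(segments_by_activity, length, 0L) > 0])
  if (length(missing)) {
    stop("assemble_patient_vector: no segment for: ",
         paste(missing, collapse = ", "))
  }
  avg_reps <- function(act, fn) {
    reps <- segments_by_activity[[act]]
    vals <- do.call(rbind, lapply(reps, fn))
    colMeans(vals, na.rm = TRUE)
  }
  out <- numeric(0)
  for (act in ACTIVITIES) {
    reps <- segments_by_activity[[act]]
    out[paste0("duration_", act)] <-
      mean(vapply(reps, nrow, 0L)) / sample_rate
  }
  for (act in c("getup", "liedown", "maxreach")) {
    f <- avg_reps(act, function(s) transition_features(s, sample_rate))
    names(f) <- paste0(act, "_", c("max_acc_long", "slope_long",
                                   "resid_var_long", "var_ch2"))
    out <- c(out, f)
  }
  out <- c(out, avg_reps("pen5", function(s)
    repeated_features(s, "pen5", sample_rate)))
  out <- c(out, avg_reps("reach5", function(s)
    repeated_features(s, "reach5", sample_rate)))
  out <- c(out, avg_reps("STS5", function(s)
    sts_features(s, sample_rate)))
  out <- out[assessment_feature_names()]
  stopifnot(length(out) == 39L, !anyNA(names(out)))
  out
}
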