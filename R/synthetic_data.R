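#' Protocol configuration for the synthetic cohort generator
#'
#' Describes the acquisition protocol the generator emulates: a cohort of
#' subjects each performing the six transition activities a fixed number of
#' times in randomized order, with static postural regions between bursts,
#' posture-dependent gravity offsets, white sensor noise and occasional
#' non-informative distractor movements.
#'
#' @param n_subjects number of subjects (default 28).
#' @param activities the six activity names; must be exactly the canonical
#'   set returned by [activity_classes()] (order is normalized).
#' @param repetitions_per_activity repetitions of each activity (default 2).
#' @param sample_rate sampling frequency in Hz (default 32).
#' @param static_gap_duration length-2 numeric, range in seconds of the
#'   static gaps between bursts (default 3 to 6 s).
#' @param distractor_rate expected number of distractor bursts per recording
#'   (Poisson; default 1).
#' @param noise_sd white-noise standard deviation in g (default 0.02).
#' @param capacity_range,capacity_mean range and mean of the BASFI-like
#'   capacity distribution (defaults 0 to 8.1 with mean 3.14, drawn from a
#'   scaled Beta distribution).
#' @param seed integer seed used by [generate_cohort()].
#' @return list of class \code{"actcap_protocol_config"}.
#' @export
protocol_config <- function(n_subjects = 28L,
                            activities = activity_classes(),
                            repetitions_per_activity = 2L,
                            sample_rate = 32,
                            static_gap_duration = c(3, 6),
                            distractor_rate = 1,
                            noise_sd = 0.02,
                            capacity_range = c(0, 8.1),
                            capacity_mean = 3.14,
                            seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (repetitions_per_activity < 1L) stop("repetitions_per_activity must be >= 1")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (!setequal(activities, ACTIVITIES)) {
    stop("activities must be exactly: ", paste(ACTIVITIES, collapse = ", "))
  }
  if (length(static_gap_duration) != 2L || any(static_gap_duration <= 0) ||
      diff(static_gap_duration) < 0) {
    stop("static_gap_duration must be an increasing positive range")
  }
  if (distractor_rate < 0) stop("distractor_rate must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 activities = ACTIVITIES,
                 repetitions_per_activity = as.integer(repetitions_per_activity),
                 sample_rate = sample_rate,
                 static_gap_duration = static_gap_duration,
                 distractor_rate = distractor_rate,
                 noise_sd = noise_sd,
                 capacity_range = capacity_range,
                 capacity_mean = capacity_mean,
                 seed = as.integer(seed)),
            class = "actcap_protocol_config")
}

#' Subject profile: capacity and per-activity modulation
#'
#' Impairment slows movement and weakens its intensity: the per-activity
#' duration multiplier grows with the capacity score (0 best, 10 worst) and
#' the peak-amplitude multiplier shrinks. Multiplicative log-normal jitter
#' individualizes activities within a subject.
#'
#' @param subject_id identifier string.
#' @param capacity BASFI-like capacity score in \[0, 10\].
#' @param duration_jitter_sd,amplitude_jitter_sd sd of the log-normal
#'   per-activity jitter.
#' @return list of class \code{"actcap_subject_profile"} with named
#'   per-activity \code{duration_multiplier} and \code{amplitude_multiplier}.
#' @export
subject_profile <- function(subject_id, capacity,
                            duration_jitter_sd = 0.05,
                            amplitude_jitter_sd = 0.08) {
  if (capacity < 0 || capacity > 10) stop("capacity must be in [0, 10]")
  dur <- (1 + 0.10 * capacity) *
    exp(stats::rnorm(length(ACTIVITIES), 0, duration_jitter_sd))
  amp <- 1 / (1 + 0.06 * capacity) *
    exp(stats::rnorm(length(ACTIVITIES), 0, amplitude_jitter_sd))
  names(dur) <- names(amp) <- ACTIVITIES
  structure(list(subject_id = subject_id, capacity = capacity,
                 duration_multiplier = dur, amplitude_multiplier = amp),
            class = "actcap_subject_profile")
}

new_recording <- function(subject_id, sample_rate, channels) {
  stopifnot(is.matrix(channels), ncol(channels) == 2L)
  colnames(channels) <- c("ch1", "ch2")
  structure(list(subject_id = subject_id, sample_rate = sample_rate,
                 channels = channels, n_samples = nrow(channels)),
            class = "actcap_recording")
}

#' @export
print.actcap_recording <- function(x, ...) {
  cat(sprintf("<actcap_recording> subject '%s': %d samples (%.1f s) at %g Hz, 2 channels\n",
              x$subject_id, x$n_samples, x$n_samples / x$sample_rate,
              x$sample_rate))
  invisible(x)
}

new_annotation <- function(start, end, label, sample_rate) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    if (any(df$end <= df$start)) stop("annotation: end must exceed start")
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)])) {
      stop("annotation: segments overlap")
    }
  }
  attr(df, "sample_rate") <- sample_rate
  class(df) <- c("actcap_annotation", "data.frame")
  df
}

# posture -> constant gravity offsets per channel (g)
POSTURES <- list(lying = c(0.05, 0.95), sitting = c(0.85, 0.25),
                 standing = c(0.98, 0.08))

# posture after completing each activity
POSTURE_AFTER <- c(getup = "standing", liedown = "lying",
                   maxreach = "standing", pen5 = "standing",
                   reach5 = "standing", STS5 = "standing")

# base burst durations in seconds (unimpaired subject)
BASE_DURATION <- c(getup = 3.0, liedown = 3.5, maxreach = 2.5,
                   pen5 = 8.0, reach5 = 7.0, STS5 = 10.0)

gauss_bump <- function(u, center, width) exp(-(u - center)^2 / (2 * width^2))

dgauss_bump <- function(u, center, width) {
  v <- -(u - center) * exp(-(u - center)^2 / (2 * width^2))
  v / max(abs(v))
}

# smooth bump train with per-repetition jitter; returns values on u in [0,1]
bump_train <- function(u, n_bumps, amps, width = 0.045, center_jitter = 0,
                       width_jitter = 0) {
  centers <- (seq_len(n_bumps) - 0.5) / n_bumps
  if (center_jitter > 0) centers <- centers + stats::rnorm(n_bumps, 0, center_jitter)
  widths <- rep(width, n_bumps)
  if (width_jitter > 0) widths <- widths * exp(stats::rnorm(n_bumps, 0, width_jitter))
  out <- numeric(length(u))
  for (b in seq_len(n_bumps)) {
    out <- out + amps[b] * gauss_bump(u, centers[b], widths[b])
  }
  out
}

# burst morphology for one activity; returns n x 2 matrix in g (zero baseline)
activity_burst <- function(activity, n, amp_mult) {
  u <- seq(0, 1, length.out = n)
  jit <- function(sd) exp(stats::rnorm(1, 0, sd))
  if (activity == "getup") {
    ch1 <- 0.8 * amp_mult * jit(0.05) * dgauss_bump(u, 0.45, 0.16)
    ch2 <- 0.30 * amp_mult * jit(0.1) * gauss_bump(u, 0.5, 0.2)
  } else if (activity == "liedown") {
    ch1 <- -0.7 * amp_mult * jit(0.05) * dgauss_bump(u, 0.5, 0.18)
    ch2 <- 0.35 * amp_mult * jit(0.1) * gauss_bump(u, 0.65, 0.18)
  } else if (activity == "maxreach") {
    ch1 <- 0.45 * amp_mult * jit(0.05) *
      (gauss_bump(u, 0.3, 0.1) - 0.6 * gauss_bump(u, 0.75, 0.12))
    ch2 <- 0.60 * amp_mult * jit(0.08) * gauss_bump(u, 0.5, 0.18)
  } else if (activity == "pen5") {
    a1 <- 0.9 * amp_mult * exp(stats::rnorm(5, 0, 0.08))
    ch1 <- bump_train(u, 5, a1, width = 0.04, center_jitter = 0.008,
                      width_jitter = 0.08)
    ch2 <- 0.20 * amp_mult * jit(0.1) *
      bump_train(u, 5, exp(stats::rnorm(5, 0, 0.1)), width = 0.05,
                 center_jitter = 0.01)
  } else if (activity == "reach5") {
    a1 <- 0.5 * amp_mult * exp(stats::rnorm(5, 0, 0.08))
    a2 <- 0.7 * amp_mult * exp(stats::rnorm(5, 0, 0.08))
    ch1 <- bump_train(u, 5, a1, width = 0.05, center_jitter = 0.008,
                      width_jitter = 0.08)
    ch2 <- bump_train(u, 5, a2, width = 0.05, center_jitter = 0.008,
                      width_jitter = 0.08)
  } else if (activity == "STS5") {
    # ten bumps, two alternating peak families (stand high, sit low)
    a1 <- rep(c(1.0, 0.6), 5) * amp_mult * exp(stats::rnorm(10, 0, 0.07))
    a2 <- rep(c(0.5, 0.3), 5) * amp_mult * exp(stats::rnorm(10, 0, 0.07))
    ch1 <- bump_train(u, 10, a1, width = 0.022, center_jitter = 0.004,
                      width_jitter = 0.07)
    ch2 <- bump_train(u, 10, a2, width = 0.025, center_jitter = 0.004,
                      width_jitter = 0.07)
  } else {
    stop("unknown activity: ", activity)
  }
  cbind(ch1, ch2)
}

# short irregular movement from a different pulse family (1-3 s)
distractor_burst <- function(n, amp_mult = 1) {
  u <- seq(0, 1, length.out = n)
  k <- sample(2:3, 1)
  ch1 <- numeric(n); ch2 <- numeric(n)
  for (i in seq_len(k)) {
    c0 <- stats::runif(1, 0.15, 0.85)
    w <- stats::runif(1, 0.06, 0.15)
    ch1 <- ch1 + stats::runif(1, -0.6, 0.6) * amp_mult * gauss_bump(u, c0, w)
    ch2 <- ch2 + stats::runif(1, -0.6, 0.6) * amp_mult * gauss_bump(u, c0 + stats::runif(1, -0.1, 0.1), w)
  }
  # keep distractors clearly above detection thresholds
  m <- max(abs(c(ch1, ch2)))
  if (m < 0.35) {
    ch1 <- ch1 * 0.35 / m
    ch2 <- ch2 * 0.35 / m
  }
  cbind(ch1, ch2)
}

#' Generate one synthetic recording with ground-truth annotation
#'
#' Emits, in randomized order, \code{repetitions_per_activity} bursts of each
#' of the six activities, separated by static regions with posture-dependent
#' constant gravity offsets plus white noise. Distractor bursts (short
#' non-informative movements) are inserted at the configured rate and
#' annotated with label \code{"DISTRACTOR"}. Burst baselines ramp smoothly
#' from the current posture's gravity offsets to the post-activity posture,
#' so offset changes always fall inside dynamic regions.
#'
#' Randomness is drawn from R's current RNG stream; call \code{set.seed()}
#' first (or use [generate_cohort()], which seeds once) for reproducibility.
#'
#' @param profile an \code{"actcap_subject_profile"}.
#' @param config an \code{"actcap_protocol_config"}.
#' @return list with \code{recording} (class \code{"actcap_recording"}) and
#'   \code{annotation} (class \code{"actcap_annotation"}; 0-based half-open
#'   sample intervals).
#' @export
generate_recording <- function(profile, config) {
  stopifnot(inherits(profile, "actcap_subject_profile"),
            inherits(config, "actcap_protocol_config"))
  fs <- config$sample_rate
  seq_acts <- sample(rep(ACTIVITIES, config$repetitions_per_activity))
  n_dist <- stats::rpois(1, config$distractor_rate)
  items <- as.list(seq_acts)
  for (d in seq_len(n_dist)) {
    pos <- sample(seq_len(length(items) + 1L), 1)
    items <- append(items, list(DISTRACTOR_LABEL), after = pos - 1L)
  }

  gap_len <- function() {
    max(1L, round(stats::runif(1, config$static_gap_duration[1],
                               config$static_gap_duration[2]) * fs))
  }

  posture <- "standing"
  pieces <- list()
  starts <- integer(0); ends <- integer(0); labels <- character(0)
  total <- 0L
  add_gap <- function(n) {
    off <- POSTURES[[posture]]
    pieces[[length(pieces) + 1L]] <<-
      cbind(rep(off[1], n), rep(off[2], n))
    total <<- total + n
  }
  add_gap(gap_len())
  for (item in items) {
    if (item == DISTRACTOR_LABEL) {
      n <- max(2L, round(stats::runif(1, 1, 3) * fs))
      burst <- distractor_burst(n)
      new_posture <- posture
    } else {
      n <- max(2L, round(BASE_DURATION[[item]] *
                           profile$duration_multiplier[[item]] * fs))
      burst <- activity_burst(item, n, profile$amplitude_multiplier[[item]])
      new_posture <- POSTURE_AFTER[[item]]
    }
    off0 <- POSTURES[[posture]]
    off1 <- POSTURES[[new_posture]]
    ramp <- seq(0, 1, length.out = n)
    base <- cbind(off0[1] + (off1[1] - off0[1]) * ramp,
                  off0[2] + (off1[2] - off0[2]) * ramp)
    starts <- c(starts, total)
    ends <- c(ends, total + n)
    labels <- c(labels, item)
    pieces[[length(pieces) + 1L]] <- burst + base
    total <- total + n
    posture <- new_posture
    if (total > 5e7) stop("generate_recording: configured burst+gap budget exceeds representable length")
    add_gap(gap_len())
  }
  channels <- do.call(rbind, pieces)
  channels <- channels + matrix(stats::rnorm(length(channels), 0, config$noise_sd),
                                ncol = 2L)
  list(recording = new_recording(profile$subject_id, fs, channels),
       annotation = new_annotation(starts, ends, labels, fs))
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from \code{config$seed}, draws per-subject capacity scores
#' from a Beta distribution scaled to \code{capacity_range} with mean
#' \code{capacity_mean}, builds one [subject_profile()] per subject and one
#' recording per subject via [generate_recording()]. With the default
#' protocol (28 subjects, 2 repetitions) the cohort holds 336 labeled
#' activity segments, 56 per class.
#'
#' @param config an \code{"actcap_protocol_config"}.
#' @return list of class \code{"actcap_cohort"} with \code{recordings},
#'   \code{annotations}, \code{profiles} (parallel lists) and \code{config}.
#' @export
generate_cohort <- function(config = protocol_config()) {
  stopifnot(inherits(config, "actcap_protocol_config"))
  set.seed(config$seed)
  lo <- config$capacity_range[1]; hi <- config$capacity_range[2]
  mu <- (config$capacity_mean - lo) / (hi - lo)
  a <- 2
  b <- a * (1 - mu) / mu
  caps <- lo + (hi - lo) * stats::rbeta(config$n_subjects, a, b)
  recordings <- vector("list", config$n_subjects)
  annotations <- vector("list", config$n_subjects)
  profiles <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    profiles[[s]] <- subject_profile(sprintf("S%02d", s), caps[s])
    ra <- generate_recording(profiles[[s]], config)
    recordings[[s]] <- ra$recording
    annotations[[s]] <- ra$annotation
  }
  structure(list(recordings = recordings, annotations = annotations,
                 profiles = profiles, config = config),
            class = "actcap_cohort")
}

#' @export
print.actcap_cohort <- function(x, ...) {
  nseg <- sum(vapply(x$annotations,
                     function(a) sum(a$label != DISTRACTOR_LABEL), 0))
  cat(sprintf("<actcap_cohort> %d subjects, %d labeled activity segments\n",
              length(x$recordings), nseg))
  invisible(x)
}
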