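#' Segmenter configuration
#'
#' Parameters of the three-step dynamic-region detector: rough windowed
#' thresholding, static-boundary refinement and channel merging/filtering.
#' The std/range thresholds and the mean-similarity tolerance are empirical
#' and exposed here: the defaults sit below typical transition intensity and
#' above sensor noise.
#'
#' @param window_len rough-segmentation window length in seconds (default 1).
#' @param window_overlap fractional window overlap (default 0.5).
#' @param std_threshold,range_threshold per-window standard-deviation and
#'   range thresholds in g; both must be exceeded for a dynamic window.
#' @param refine_step boundary refinement step in seconds (default 0.25).
#' @param refine_window variance comparison window in seconds (default 0.5).
#' @param refine_ratio relative variance tolerance (default 0.10): extension
#'   of a static region is accepted when the shifted window's variance is at
#'   most 10 percent above baseline, shrinking when at least 10 percent below.
#' @param max_refine_passes refinement passes per boundary (default 8, i.e.
#'   at most 2 s of total shift).
#' @param merge_gap maximal gap in seconds joined during merging (default 0.5).
#' @param merge_mean_tolerance maximal channel-mean difference in g for two
#'   regions to be joined (default 0.1).
#' @param min_segment_len minimal dynamic segment length in seconds kept
#'   after filtering (default 1).
#' @return list of class \code{"actcap_segmenter_config"}.
#' @export
segmenter_config <- function(window_len = 1, window_overlap = 0.5,
                             std_threshold = 0.05, range_threshold = 0.20,
                             refine_step = 0.25, refine_window = 0.5,
                             refine_ratio = 0.10, max_refine_passes = 8L,
                             merge_gap = 0.5, merge_mean_tolerance = 0.1,
                             min_segment_len = 1) {
  stopifnot(window_len > 0, window_overlap > 0, window_overlap < 1,
            std_threshold > 0, range_threshold > 0, refine_step > 0,
            refine_window > 0, refine_ratio > 0, merge_gap > 0,
            merge_mean_tolerance > 0, min_segment_len > 0)
  structure(as.list(environment()), class = "actcap_segmenter_config")
}

empty_segments <- function() {
  data.frame(start = integer(0), end = integer(0))
}

seg_df <- function(start, end) {
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# logical mask (length n) -> 0-based half-open runs of TRUE
mask_to_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  seg_df(starts[keep], ends[keep])
}

#' Rough per-channel segmentation by windowed thresholds
#'
#' Splits the channel into windows of \code{window_len} seconds with the
#' configured overlap; a window is dynamic when BOTH its standard deviation
#' and its range exceed their thresholds. Overlapping dynamic windows are
#' merged into maximal runs.
#'
#' @param channel numeric vector of acceleration samples (g).
#' @param config an \code{"actcap_segmenter_config"}.
#' @param sample_rate sampling frequency in Hz.
#' @return data frame with columns \code{start}, \code{end} (0-based,
#'   half-open sample intervals), sorted and non-overlapping.
#' @export
rough_segment <- function(channel, config, sample_rate) {
  n <- length(channel)
  w <- round(config$window_len * sample_rate)
  if (n < w) {
    warning("rough_segment: channel shorter than one window")
    return(empty_segments())
  }
  step <- max(1L, round(w * (1 - config$window_overlap)))
  starts <- seq(1L, n - w + 1L, by = step)
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)
  mask <- logical(n)
  for (s in starts) {
    win <- channel[s:(s + w - 1L)]
    if (stats::sd(win) > config$std_threshold &&
        (max(win) - min(win)) > config$range_threshold) {
      mask[s:(s + w - 1L)] <- TRUE
    }
  }
  mask_to_segments(mask)
}

# complement of dynamic segments within [0, n): the static regions
static_regions <- function(segments, n) {
  if (nrow(segments) == 0L) return(seg_df(0L, n))
  starts <- c(0L, segments$end)
  ends <- c(segments$start, n)
  keep <- ends > starts
  seg_df(starts[keep], ends[keep])
}

var_win <- function(channel, start0, len) {
  # variance of the half-open 0-based window [start0, start0 + len)
  stats::var(channel[(start0 + 1L):(start0 + len)])
}

#' Refine dynamic/static boundaries by variance comparison
#'
#' For every static region (between dynamic segments), the variance of its
#' initial (final) half second is the baseline for the region's start (end)
#' boundary. The boundary is moved outward by \code{refine_step} (the static
#' region grows, eating into the neighboring dynamic segment) when the half
#' second starting a quarter second earlier has variance at most
#' \code{1 + refine_ratio} times the baseline; it is moved inward (the
#' dynamic segment grows) when the half second starting a quarter second
#' later has variance at most \code{1 - refine_ratio} times the baseline.
#' Extension is tested before shrinking and the first satisfied criterion
#' wins. One adjustment per boundary per pass; passes repeat until no
#' boundary moves or \code{max_refine_passes} is reached. Static regions
#' shorter than the comparison window are left unchanged.
#'
#' @param regions data frame of dynamic segments (0-based half-open), sorted
#'   and non-overlapping.
#' @inheritParams rough_segment
#' @return refined dynamic segments in the same format.
#' @export
refine_static_boundaries <- function(regions, channel, config, sample_rate) {
  n <- length(channel)
  if (nrow(regions) == 0L) return(regions)
  half <- round(config$refine_window * sample_rate)
  q <- round(config$refine_step * sample_rate)
  stat <- static_regions(regions, n)
  for (pass in seq_len(config$max_refine_passes)) {
    changed <- FALSE
    for (r in seq_len(nrow(stat))) {
      s <- stat$start[r]; e <- stat$end[r]
      if (e - s < half) next
      # start boundary (only if a dynamic segment precedes it)
      if (s > 0L) {
        prev_dyn_start <- if (r > 1L) stat$end[r - 1L] else 0L
        base <- var_win(channel, s, half)
        if (s - q >= prev_dyn_start + 2L &&
            var_win(channel, s - q, half) <= (1 + config$refine_ratio) * base) {
          s <- s - q; changed <- TRUE
        } else if (s + q + half <= e &&
                   var_win(channel, s + q, half) <= (1 - config$refine_ratio) * base) {
          s <- s + q; changed <- TRUE
        }
      }
      # end boundary (only if a dynamic segment follows it)
      if (e < n) {
        next_dyn_end <- if (r < nrow(stat)) stat$start[r + 1L] else n
        base <- var_win(channel, e - half, half)
        if (e + q <= next_dyn_end - 2L &&
            var_win(channel, e + q - half, half) <= (1 + config$refine_ratio) * base) {
          e <- e + q; changed <- TRUE
        } else if (e - q - half >= s &&
                   var_win(channel, e - q - half, half) <= (1 - config$refine_ratio) * base) {
          e <- e - q; changed <- TRUE
        }
      }
      stat$start[r] <- s; stat$end[r] <- e
    }
    if (!changed) break
  }
  # dynamic = complement of the refined static regions
  dyn_starts <- c(if (stat$start[1L] > 0L) 0L else NULL, stat$end)
  dyn_ends <- c(if (stat$start[1L] > 0L) stat$start[1L] else NULL,
                c(stat$start[-1L], n))
  # drop the trailing pseudo-segment when the recording ends statically
  keep <- dyn_ends > dyn_starts
  seg_df(dyn_starts[keep], dyn_ends[keep])
}

interval_union <- function(a, b) {
  both <- rbind(a, b)
  if (nrow(both) == 0L) return(empty_segments())
  both <- both[order(both$start), , drop = FALSE]
  starts <- both$start[1L]; ends <- both$end[1L]
  for (r in seq_len(nrow(both))[-1L]) {
    k <- length(starts)
    if (both$start[r] <= ends[k]) {
      ends[k] <- max(ends[k], both$end[r])
    } else {
      starts <- c(starts, both$start[r]); ends <- c(ends, both$end[r])
    }
  }
  seg_df(starts, ends)
}

#' Merge per-channel dynamic regions and filter short segments
#'
#' A region is dynamic if it is dynamic in at least one channel (interval
#' union). Neighboring regions closer than \code{merge_gap} whose per-channel
#' signal means differ by at most \code{merge_mean_tolerance} in every
#' channel are joined (repeatedly, until stable, so the operation is
#' idempotent). Segments shorter than \code{min_segment_len} are discarded.
#'
#' @param regions_ch1,regions_ch2 per-channel dynamic segment data frames.
#' @param recording the \code{"actcap_recording"} the regions refer to
#'   (needed for the mean-similarity test).
#' @param config an \code{"actcap_segmenter_config"}.
#' @return merged, filtered dynamic segments (0-based half-open).
#' @export
merge_and_filter <- function(regions_ch1, regions_ch2, recording, config) {
  fs <- recording$sample_rate
  segs <- interval_union(regions_ch1, regions_ch2)
  gap_max <- round(config$merge_gap * fs)
  seg_mean <- function(s, e, ch) mean(recording$channels[(s + 1L):e, ch])
  repeat {
    joined <- FALSE
    r <- 1L
    while (r < nrow(segs)) {
      gap <- segs$start[r + 1L] - segs$end[r]
      if (gap < gap_max) {
        sim <- all(vapply(1:2, function(ch) {
          abs(seg_mean(segs$start[r], segs$end[r], ch) -
              seg_mean(segs$start[r + 1L], segs$end[r + 1L], ch)) <=
            config$merge_mean_tolerance
        }, logical(1)))
        if (sim) {
          segs$end[r] <- segs$end[r + 1L]
          segs <- segs[-(r + 1L), , drop = FALSE]
          joined <- TRUE
          next
        }
      }
      r <- r + 1L
    }
    if (!joined) break
  }
  rownames(segs) <- NULL
  min_len <- round(config$min_segment_len * fs)
  segs <- segs[segs$end - segs$start >= min_len, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Detect dynamic regions in a two-channel recording
#'
#' Composition of the three steps: [rough_segment()] and
#' [refine_static_boundaries()] per channel, then [merge_and_filter()].
#'
#' @param recording an \code{"actcap_recording"}.
#' @param config an \code{"actcap_segmenter_config"}.
#' @return data frame of dynamic segments (columns \code{start}, \code{end};
#'   0-based half-open sample intervals), sorted, non-overlapping, each at
#'   least \code{min_segment_len} long.
#' @export
detect_dynamic_regions <- function(recording, config = segmenter_config()) {
  stopifnot(inherits(recording, "actcap_recording"))
  fs <- recording$sample_rate
  per_ch <- lapply(1:2, function(ch) {
    rough <- rough_segment(recording$channels[, ch], config, fs)
    refine_static_boundaries(rough, recording$channels[, ch], config, fs)
  })
  merge_and_filter(per_ch[[1L]], per_ch[[2L]], recording, config)
}
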