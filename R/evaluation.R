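#' Sørensen–Dice coefficient of two sample intervals
#'
#' \eqn{SDC(X, Y) = 2 |X \cap Y| / (|X| + |Y|)} evaluated on sample counts
#' of half-open intervals.
#'
#' @param x,y length-2 numeric vectors \code{c(start, end)}, 0-based
#'   half-open.
#' @return overlap coefficient in \[0, 1\].
#' @export
sdc <- function(x, y) {
  if (x[2] <= x[1] || y[2] <= y[1]) stop("sdc: zero-length interval")
  inter <- max(0, min(x[2], y[2]) - max(x[1], y[1]))
  2 * inter / ((x[2] - x[1]) + (y[2] - y[1]))
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Match detected segments to ground-truth segments
#'
#' Greedy one-to-one matching by largest overlap: candidate (ground truth,
#' detection) pairs with positive overlap are taken in decreasing overlap
#' order, each ground-truth segment and each detection matched at most
#' once. Detections with zero overlap against every ground-truth segment
#' are false detections; ground-truth segments with no overlapping
#' detection are missed.
#'
#' @param gt ground-truth annotation (data frame with \code{start},
#'   \code{end} and optionally \code{label}).
#' @param detected data frame of detected segments (\code{start},
#'   \code{end}).
#' @return list with \code{pairs} (data frame: gt_index, det_index,
#'   overlap, sdc), \code{missed_gt}, \code{false_detections} (indices into
#'   \code{detected}), and \code{unmatched_overlapping} (detections that
#'   overlap only already-matched ground truth).
#' @export
match_detections <- function(gt, detected) {
  ng <- nrow(gt); nd <- nrow(detected)
  if (ng == 0L || nd == 0L) {
    return(list(pairs = data.frame(gt_index = integer(0),
                                   det_index = integer(0),
                                   overlap = numeric(0), sdc = numeric(0)),
                missed_gt = seq_len(ng),
                false_detections = seq_len(nd),
                unmatched_overlapping = integer(0)))
  }
  ov <- outer(seq_len(ng), seq_len(nd), function(g, d) {
    overlap_len(gt$start[g], gt$end[g], detected$start[d], detected$end[d])
  })
  cand <- which(ov > 0, arr.ind = TRUE)
  ord <- order(ov[cand], decreasing = TRUE)
  used_g <- logical(ng); used_d <- logical(nd)
  pairs <- list()
  for (k in ord) {
    g <- cand[k, 1L]; d <- cand[k, 2L]
    if (used_g[g] || used_d[d]) next
    used_g[g] <- TRUE; used_d[d] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      gt_index = g, det_index = d, overlap = ov[g, d],
      sdc = sdc(c(gt$start[g], gt$end[g]),
                c(detected$start[d], detected$end[d])))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gt_index = integer(0), det_index = integer(0),
               overlap = numeric(0), sdc = numeric(0))
  pairs <- pairs[order(pairs$gt_index), , drop = FALSE]
  rownames(pairs) <- NULL
  has_any_overlap <- colSums(ov) > 0
  list(pairs = pairs,
       missed_gt = setdiff(seq_len(ng), pairs$gt_index),
       false_detections = which(!has_any_overlap),
       unmatched_overlapping = setdiff(which(has_any_overlap),
                                       pairs$det_index))
}

#' Detection report: DTPR, false detections, segmentation precision
#'
#' Computes the detection true positive rate (correctly detected ground
#' truth segments over all ground-truth segments), the number of false
#' detections, and the mean and standard deviation of the Sørensen–Dice
#' coefficient over matched pairs; per recording and, when ground truth is
#' labeled, per activity.
#'
#' @param gt ground-truth annotation data frame (activity segments only).
#' @param detected detected segments data frame.
#' @return list of class \code{"actcap_detection_report"} with \code{dtpr},
#'   \code{nr_fd}, \code{sdc_mean}, \code{sdc_sd}, \code{matching} and a
#'   \code{per_activity} data frame.
#' @export
detection_report <- function(gt, detected) {
  m <- match_detections(gt, detected)
  per_act <- NULL
  if (!is.null(gt$label)) {
    acts <- unique(gt$label)
    per_act <- do.call(rbind, lapply(acts, function(a) {
      idx <- which(gt$label == a)
      pa <- m$pairs[m$pairs$gt_index %in% idx, , drop = FALSE]
      data.frame(activity = a, n_gt = length(idx), detected = nrow(pa),
                 dtpr = nrow(pa) / length(idx),
                 sdc_mean = if (nrow(pa)) mean(pa$sdc) else NA_real_,
                 sdc_sd = if (nrow(pa) > 1L) stats::sd(pa$sdc) else NA_real_)
    }))
  }
  structure(list(dtpr = nrow(m$pairs) / max(nrow(gt), 1L),
                 nr_fd = length(m$false_detections),
                 sdc_mean = if (nrow(m$pairs)) mean(m$pairs$sdc) else NA_real_,
                 sdc_sd = if (nrow(m$pairs) > 1L) stats::sd(m$pairs$sdc) else NA_real_,
                 matching = m, per_activity = per_act),
            class = "actcap_detection_report")
}

#' @export
print.actcap_detection_report <- function(x, ...) {
  cat(sprintf("<actcap_detection_report> DTPR %.1f%%, %d false detection(s), mean SDC %.2f\n",
              100 * x$dtpr, x$nr_fd, x$sdc_mean))
  invisible(x)
}

#' Pure and actual recognition accuracy
#'
#' The pure accuracy ACCp is conditional on correct detection: among ground
#' truth segments with a matched detection, the fraction whose predicted
#' label equals the true label. The actual accuracy ACCa evaluates the
#' seven-class problem: correct predictions over the number of ground-truth
#' segments plus the false detections NOT rejected by the classifier (a
#' rejected false detection is correct behavior; a ground-truth segment
#' whose detection is rejected counts as an error in both measures, and a
#' missed segment counts against ACCa).
#'
#' @param gt ground-truth annotation with \code{label}.
#' @param detected detected segments data frame.
#' @param predicted_labels character vector, one label per detected segment
#'   (an activity or \code{"REJECT"}).
#' @return list with \code{acc_pure}, \code{acc_actual}, \code{n_correct},
#'   \code{n_detected}, \code{n_gt}, \code{n_accepted_fd} (an accuracy is
#'   NA when its denominator is zero).
#' @export
recognition_accuracies <- function(gt, detected, predicted_labels) {
  if (length(predicted_labels) != nrow(detected)) {
    stop("recognition_accuracies: one predicted label per detection required")
  }
  m <- match_detections(gt, detected)
  correct <- 0L
  for (r in seq_len(nrow(m$pairs))) {
    g <- m$pairs$gt_index[r]; d <- m$pairs$det_index[r]
    if (identical(predicted_labels[d], gt$label[g])) correct <- correct + 1L
  }
  accepted_fd <- sum(predicted_labels[m$false_detections] != REJECT_LABEL)
  n_det <- nrow(m$pairs)
  acc_p <- if (n_det > 0L) correct / n_det else NA_real_
  denom_a <- nrow(gt) + accepted_fd
  acc_a <- if (denom_a > 0L) correct / denom_a else NA_real_
  list(acc_pure = acc_p, acc_actual = acc_a, n_correct = correct,
       n_detected = n_det, n_gt = nrow(gt), n_accepted_fd = accepted_fd)
}
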