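#' Dynamic time warping alignment of two multichannel sequences
#'
#' Computes the minimal-cost warping path between two sequences under the
#' standard step pattern (diagonal, horizontal, vertical predecessors) with
#' boundary conditions: the path starts at (1, 1) and ends at (N, M). The
#' local cost of matching sample \eqn{i} of \code{x} to sample \eqn{j} of
#' \code{y} is the squared difference summed over channels, so the
#' accumulated path cost is \eqn{C_W = \sum_k (x_{i_k} - y_{j_k})^2}.
#'
#' @param x,y numeric matrices (samples x channels) with the same number of
#'   columns, or numeric vectors (treated as single-channel).
#' @param band optional Sakoe-Chiba band radius on \eqn{|i - j|};
#'   \code{Inf} (the default) disables the constraint. When the sequence
#'   lengths differ the band is widened to \eqn{|N - M|} so a path exists.
#' @return a list of class \code{"actcap_dtw"} with elements \code{cost}
#'   (non-negative accumulated cost of the optimal path), \code{path} (a
#'   K x 2 integer matrix of index pairs) and \code{K} (path length).
#' @examples
#' a <- sin(seq(0, pi, length.out = 20))
#' b <- sin(seq(0, pi, length.out = 30))
#' dtw_align(a, b)$cost
#' @export
dtw_align <- function(x, y, band = Inf) {
  x <- as_channel_matrix(x)
  y <- as_channel_matrix(y)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    stop("dtw_align: sequences must be non-empty")
  }
  if (ncol(x) != ncol(y)) {
    stop("dtw_align: channel-count mismatch (", ncol(x), " vs ", ncol(y), ")")
  }
  band_i <- if (is.finite(band)) as.integer(band) else -1L
  res <- .dtw_core(x, y, band_i)
  path <- cbind(i = res$i, j = res$j)
  structure(list(cost = res$cost, path = path, K = nrow(path)),
            class = "actcap_dtw")
}

as_channel_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

#' Standardize a multichannel series per channel
#'
#' Centers and scales each channel to zero mean and unit variance. Channels
#' with zero variance are mapped to all-zeros and flagged.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @return list with \code{series} (standardized matrix) and
#'   \code{zero_variance} (logical per channel).
#' @export
standardize_channels <- function(x) {
  x <- as_channel_matrix(x)
  zv <- logical(ncol(x))
  out <- x
  for (c in seq_len(ncol(x))) {
    s <- stats::sd(x[, c])
    if (!is.finite(s) || s == 0) {
      zv[c] <- TRUE
      out[, c] <- 0
    } else {
      out[, c] <- (x[, c] - mean(x[, c])) / s
    }
  }
  list(series = out, zero_variance = zv)
}

#' Build an activity template from training examples
#'
#' Training examples are standardized per channel and jointly aligned by an
#' iterative barycenter procedure: the reference is initialized as the medoid
#' example (minimal summed DTW cost to all others), every example is aligned
#' to the reference by [dtw_align()], samples mapped to the same reference
#' position are averaged, and the per-position average over examples becomes
#' the new reference. The final average, re-standardized per channel, is the
#' template representing the class.
#'
#' @param examples list of numeric matrices (samples x channels), all with
#'   the same channel count and at least 2 samples; at least 2 examples.
#' @param label activity name the template represents.
#' @param max_iter maximum barycenter iterations (default 5).
#' @param tol stop when the relative L2 change of the reference drops below
#'   this value (default 1e-6).
#' @param medoid_max medoid search is restricted to the first
#'   \code{medoid_max} examples when there are more (cost control; all
#'   examples still contribute to the average).
#' @param band optional DTW band radius, see [dtw_align()].
#' @return an object of class \code{"actcap_template"}: list with
#'   \code{label}, \code{channels} (L x C standardized matrix),
#'   \code{length}, \code{n_examples}.
#' @export
build_template <- function(examples, label, max_iter = 5L, tol = 1e-6,
                           medoid_max = Inf, band = Inf) {
  if (length(examples) < 2L) stop("build_template: need at least 2 examples")
  std <- vector("list", length(examples))
  for (e in seq_along(examples)) {
    m <- as_channel_matrix(examples[[e]])
    if (nrow(m) < 2L) stop("build_template: example ", e, " has fewer than 2 samples")
    s <- standardize_channels(m)
    if (any(s$zero_variance)) {
      stop("build_template: zero-variance channel in example ", e)
    }
    std[[e]] <- s$series
  }
  n_med <- min(length(std), medoid_max)
  idx <- seq_len(n_med)
  costs <- matrix(0, n_med, n_med)
  for (a in idx) {
    for (b in idx) {
      if (b > a) {
        cc <- dtw_align(std[[a]], std[[b]], band = band)$cost
        costs[a, b] <- cc
        costs[b, a] <- cc
      }
    }
  }
  medoid <- idx[which.min(rowSums(costs))]
  ref <- std[[medoid]]
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, nrow(ref), ncol(ref))
    cnt <- numeric(nrow(ref))
    for (e in seq_along(std)) {
      al <- dtw_align(ref, std[[e]], band = band)
      # average example samples mapped to each reference position
      warped <- matrix(0, nrow(ref), ncol(ref))
      wcnt <- numeric(nrow(ref))
      for (k in seq_len(al$K)) {
        i <- al$path[k, 1L]; j <- al$path[k, 2L]
        warped[i, ] <- warped[i, ] + std[[e]][j, ]
        wcnt[i] <- wcnt[i] + 1
      }
      warped <- warped / wcnt
      acc <- acc + warped
      cnt <- cnt + 1
    }
    new_ref <- acc / cnt
    delta <- sqrt(sum((new_ref - ref)^2)) / max(sqrt(sum(ref^2)), .Machine$double.eps)
    ref <- new_ref
    if (delta < tol) break
  }
  ref <- standardize_channels(ref)$series
  structure(list(label = label, channels = ref, length = nrow(ref),
                 n_examples = length(std)),
            class = "actcap_template")
}

#' @export
print.actcap_template <- function(x, ...) {
  cat(sprintf("<actcap_template> class '%s': %d samples x %d channels, from %d examples\n",
              x$label, x$length, ncol(x$channels), x$n_examples))
  invisible(x)
}

#' Match a segment against an activity template
#'
#' The segment is standardized per channel and aligned to the template with
#' [dtw_align()]. The matching cost is the optimal path cost divided by the
#' path length K (removing the duration dependence, which is captured by a
#' separate feature), and per-channel Pearson correlations are computed
#' between the aligned sample pairs along the warping path.
#'
#' @param segment numeric matrix (samples x channels) with the template's
#'   channel count.
#' @param template an \code{"actcap_template"}.
#' @param band optional DTW band radius.
#' @return list with \code{norm_cost}, \code{r} (correlation per channel),
#'   and \code{flag} (TRUE if a zero-variance channel was encountered; that
#'   channel is treated as all-zeros and its correlation defined as 0).
#' @export
match_to_template <- function(segment, template, band = Inf) {
  stopifnot(inherits(template, "actcap_template"))
  seg <- as_channel_matrix(segment)
  if (nrow(seg) == 0L) stop("match_to_template: empty segment")
  if (ncol(seg) != ncol(template$channels)) {
    stop("match_to_template: channel-count mismatch")
  }
  s <- standardize_channels(seg)
  al <- dtw_align(s$series, template$channels, band = band)
  r <- numeric(ncol(seg))
  for (c in seq_len(ncol(seg))) {
    if (s$zero_variance[c]) {
      r[c] <- 0
    } else {
      a <- s$series[al$path[, 1L], c]
      b <- template$channels[al$path[, 2L], c]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        r[c] <- 0
      } else {
        r[c] <- stats::cor(a, b)
      }
    }
  }
  list(norm_cost = al$cost / al$K, r = r, flag = any(s$zero_variance))
}

#' Write / read a template set as JSON
#'
#' A trained template set is a named list of templates, one per activity
#' class. Each template is stored as one JSON file \code{<label>.json} in
#' \code{dir} with fields label, n_examples and channels.
#'
#' @param templates named list of \code{"actcap_template"} objects.
#' @param dir directory to write into (created if missing).
#' @return \code{write_template_set} returns the file paths invisibly;
#'   \code{read_template_set} returns the named list of templates.
#' @export
write_template_set <- function(templates, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tp in templates) {
    p <- file.path(dir, paste0(tp$label, ".json"))
    jsonlite::write_json(
      list(label = tp$label, n_examples = tp$n_examples,
           channels = lapply(seq_len(ncol(tp$channels)),
                             function(c) tp$channels[, c])),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  out <- list()
  for (p in files) {
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    # channels were written as a list of per-channel vectors; jsonlite
    # simplifies equal-length vectors to a channels x samples matrix
    ch <- if (is.matrix(j$channels)) t(j$channels) else
      do.call(cbind, lapply(j$channels, as.numeric))
    out[[j$label]] <- structure(
      list(label = j$label, channels = ch, length = nrow(ch),
           n_examples = j$n_examples),
      class = "actcap_template")
  }
  out
}
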