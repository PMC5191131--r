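#' Read / write a two-channel recording CSV
#'
#' The on-disk format is a headered CSV with columns \code{time_s},
#' \code{ch1_g}, \code{ch2_g}. On reading, the time column must be uniform
#' (maximal jitter 1e-6 s) and free of NaNs; the sample rate is inferred
#' from the time step.
#'
#' @param path file path.
#' @param subject_id subject identifier attached to the recording (defaults
#'   to the file name).
#' @return an \code{"actcap_recording"}.
#' @export
read_recording <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ch1_g", "ch2_g")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_recording: missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !is.finite(df$ch1_g) | !is.finite(df$ch2_g) |
                 !is.finite(df$time_s))
  if (length(bad)) {
    stop("read_recording: non-finite value at row ", bad[1L])
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("read_recording: time column not strictly increasing")
  if (max(dt) - min(dt) > 1e-6) {
    stop("read_recording: non-uniform sampling (jitter ",
         format(max(dt) - min(dt)), " s)")
  }
  fs <- 1 / stats::median(dt)
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path))
  new_recording(subject_id, fs, cbind(df$ch1_g, df$ch2_g))
}

#' @rdname read_recording
#' @param recording an \code{"actcap_recording"} to write.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "actcap_recording"))
  df <- data.frame(
    time_s = (seq_len(recording$n_samples) - 1L) / recording$sample_rate,
    ch1_g = recording$channels[, 1L],
    ch2_g = recording$channels[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write segment annotations
#'
#' Annotations are stored as JSON: \code{sample_rate} plus a list of
#' \code{\{start, end, label\}} segments in 0-based half-open sample
#' indices. A CSV with columns \code{start}, \code{end}, \code{label} is
#' also accepted on reading (sample rate passed separately).
#'
#' @param path file path (\code{.json} or \code{.csv}).
#' @param sample_rate required when reading CSV.
#' @return an \code{"actcap_annotation"}.
#' @export
read_annotation <- function(path, sample_rate = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    segs <- as.data.frame(j$segments)
    new_annotation(segs$start, segs$end, segs$label, j$sample_rate)
  } else {
    if (is.null(sample_rate)) {
      stop("read_annotation: sample_rate required for CSV input")
    }
    df <- utils::read.csv(path)
    new_annotation(df$start, df$end, df$label, sample_rate)
  }
}

#' @rdname read_annotation
#' @param annotation an \code{"actcap_annotation"} (or a plain segments
#'   data frame, in which case unlabeled segments are written as
#'   \code{"UNKNOWN"}).
#' @export
write_annotation <- function(annotation, path, sample_rate = NULL) {
  label <- if (!is.null(annotation$label)) annotation$label else
    rep("UNKNOWN", nrow(annotation))
  fs <- if (!is.null(attr(annotation, "sample_rate")))
    attr(annotation, "sample_rate") else sample_rate
  if (is.null(fs)) stop("write_annotation: sample rate unknown")
  jsonlite::write_json(
    list(sample_rate = fs,
         segments = data.frame(start = annotation$start,
                               end = annotation$end, label = label)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One recording CSV and one annotation JSON per subject plus a YAML
#' manifest (subject ids, file paths, capacity scores).
#'
#' @param cohort an \code{"actcap_cohort"}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subjects <- list()
  for (s in seq_along(cohort$recordings)) {
    id <- cohort$recordings[[s]]$subject_id
    rec_path <- file.path(dir, paste0(id, ".csv"))
    ann_path <- file.path(dir, paste0(id, "_annotation.json"))
    write_recording(cohort$recordings[[s]], rec_path)
    write_annotation(cohort$annotations[[s]], ann_path)
    subjects[[id]] <- list(recording = basename(rec_path),
                           annotation = basename(ann_path),
                           capacity = cohort$profiles[[s]]$capacity)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(sample_rate = cohort$config$sample_rate,
                        subjects = subjects), manifest)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a \code{manifest.yaml} written by
#'   [write_cohort()].
#' @return list with \code{recordings}, \code{annotations},
#'   \code{capacities}.
#' @export
read_cohort <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  ids <- names(m$subjects)
  recordings <- lapply(ids, function(id) {
    read_recording(file.path(dir, m$subjects[[id]]$recording), subject_id = id)
  })
  annotations <- lapply(ids, function(id) {
    read_annotation(file.path(dir, m$subjects[[id]]$annotation))
  })
  list(recordings = recordings, annotations = annotations,
       capacities = vapply(ids, function(id) m$subjects[[id]]$capacity, 0))
}
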