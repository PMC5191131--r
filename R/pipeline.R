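# Segment every recording once, match detections against the ground truth
# and derive training labels: matched detections inherit the activity label,
# zero-overlap detections become rejection-class examples (this includes
# detected distractor movements), detections overlapping already-matched
# ground truth are excluded from training (NA).
prepare_detections <- function(cohort, seg_config) {
  lapply(seq_along(cohort$recordings), function(s) {
    rec <- cohort$recordings[[s]]
    ann <- cohort$annotations[[s]]
    gt <- ann[ann$label != DISTRACTOR_LABEL, , drop = FALSE]
    det <- detect_dynamic_regions(rec, seg_config)
    m <- match_detections(gt, det)
    lab <- rep(NA_character_, nrow(det))
    lab[m$pairs$det_index] <- gt$label[m$pairs$gt_index]
    lab[m$false_detections] <- REJECT_LABEL
    slices <- lapply(seq_len(nrow(det)), function(d) {
      rec$channels[(det$start[d] + 1L):det$end[d], , drop = FALSE]
    })
    list(subject = rec$subject_id, detections = det, gt = gt,
         matching = m, labels = lab, slices = slices,
         sample_rate = rec$sample_rate)
  })
}

#' Leave-one-subject-out recognition evaluation
#'
#' Runs the full patient-independent recognition pipeline on a cohort: all
#' recordings are segmented; for each left-out subject, activity templates
#' are built by multiple DTW alignment of the training subjects' correctly
#' detected segments, the 39 recognition features are extracted, the
#' three-stage cascade is trained (rejection examples are the training
#' folds' false detections) and the held-out subject's detections are
#' classified. Detection and recognition metrics are reported per subject
#' and per activity.
#'
#' @param cohort an \code{"actcap_cohort"}.
#' @param seg_config segmentation parameters ([segmenter_config()]).
#' @param casc_config cascade parameters ([cascade_config()]).
#' @param template_examples_max examples per class used for template
#'   building (default 16; alignment cost grows quadratically in the
#'   medoid search).
#' @param medoid_max examples considered in the medoid search
#'   (default 10).
#' @param band optional DTW band radius.
#' @param verbose print per-fold progress.
#' @return list of class \code{"actcap_recognition_eval"} with
#'   \code{per_subject} (nrFD, DTPR, SDC mean/sd, ACCp, ACCa),
#'   \code{per_activity}, \code{average} (cohort means) and
#'   \code{detections} (per-subject detections, labels and predictions).
#' @export
evaluate_recognition_loso <- function(cohort,
                                      seg_config = segmenter_config(),
                                      casc_config = cascade_config(),
                                      template_examples_max = 16L,
                                      medoid_max = 10L, band = Inf,
                                      verbose = FALSE) {
  stopifnot(inherits(cohort, "actcap_cohort"))
  fs <- cohort$config$sample_rate
  prep <- prepare_detections(cohort, seg_config)
  # window features are fold-independent; cache them
  for (s in seq_along(prep)) {
    prep[[s]]$wf <- t(vapply(prep[[s]]$slices,
                             function(sl) window_features(sl, fs),
                             numeric(21L)))
  }
  n <- length(prep)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    examples <- stats::setNames(vector("list", 6L), ACTIVITIES)
    for (t in tr) {
      lab <- prep[[t]]$labels
      for (d in which(!is.na(lab) & lab != REJECT_LABEL)) {
        examples[[lab[d]]] <- c(examples[[lab[d]]],
                                list(prep[[t]]$slices[[d]]))
      }
    }
    templates <- lapply(ACTIVITIES, function(a) {
      ex <- examples[[a]]
      if (length(ex) < 2L) {
        stop("evaluate_recognition_loso: fewer than 2 training examples for ", a)
      }
      if (length(ex) > template_examples_max) {
        ex <- ex[round(seq(1L, length(ex), length.out = template_examples_max))]
      }
      build_template(ex, a, medoid_max = medoid_max, band = band)
    })
    names(templates) <- ACTIVITIES
    feat_block <- function(idx_sub) {
      do.call(rbind, lapply(idx_sub, function(t) {
        pf <- t(vapply(prep[[t]]$slices,
                       function(sl) pattern_features(sl, templates, band = band),
                       numeric(18L)))
        cbind(pf, prep[[t]]$wf)
      }))
    }
    train_feat <- feat_block(tr)
    train_lab <- unlist(lapply(tr, function(t) prep[[t]]$labels))
    keep <- !is.na(train_lab)
    model <- train_cascade(train_feat[keep, , drop = FALSE], train_lab[keep],
                           casc_config)
    test_feat <- feat_block(s)
    pred <- if (nrow(prep[[s]]$detections)) {
      predict_cascade(model, test_feat)
    } else character(0)
    prep[[s]]$predicted <- pred
    rep_s <- detection_report(prep[[s]]$gt, prep[[s]]$detections)
    acc <- recognition_accuracies(prep[[s]]$gt, prep[[s]]$detections, pred)
    rows[[s]] <- data.frame(subject = prep[[s]]$subject,
                            n_gt = nrow(prep[[s]]$gt),
                            nr_fd = rep_s$nr_fd, dtpr = rep_s$dtpr,
                            sdc_mean = rep_s$sdc_mean, sdc_sd = rep_s$sdc_sd,
                            acc_pure = acc$acc_pure,
                            acc_actual = acc$acc_actual)
    if (verbose) {
      message(sprintf("fold %s: DTPR %.0f%%, nrFD %d, ACCa %.1f%%",
                      prep[[s]]$subject, 100 * rep_s$dtpr, rep_s$nr_fd,
                      100 * acc$acc_actual))
    }
  }
  per_subject <- do.call(rbind, rows)
  # per-activity detection metrics pooled over subjects
  pooled <- do.call(rbind, lapply(seq_len(n), function(s) {
    r <- detection_report(prep[[s]]$gt, prep[[s]]$detections)$per_activity
    r
  }))
  per_activity <- do.call(rbind, lapply(split(pooled, pooled$activity),
                                        function(g) {
    data.frame(activity = g$activity[1L], n_gt = sum(g$n_gt),
               detected = sum(g$detected), dtpr = sum(g$detected) / sum(g$n_gt),
               sdc_mean = stats::weighted.mean(g$sdc_mean, g$detected,
                                               na.rm = TRUE))
  }))
  rownames(per_activity) <- NULL
  structure(list(per_subject = per_subject, per_activity = per_activity,
                 average = list(dtpr = mean(per_subject$dtpr),
                                nr_fd = mean(per_subject$nr_fd),
                                sdc_mean = mean(per_subject$sdc_mean, na.rm = TRUE),
                                acc_pure = mean(per_subject$acc_pure, na.rm = TRUE),
                                acc_actual = mean(per_subject$acc_actual, na.rm = TRUE)),
                 detections = prep),
            class = "actcap_recognition_eval")
}

#' @export
print.actcap_recognition_eval <- function(x, ...) {
  cat(sprintf("<actcap_recognition_eval> %d subjects: DTPR %.1f%%, mean SDC %.2f, ACCp %.1f%%, ACCa %.1f%%\n",
              nrow(x$per_subject), 100 * x$average$dtpr, x$average$sdc_mean,
              100 * x$average$acc_pure, 100 * x$average$acc_actual))
  invisible(x)
}

#' Per-patient assessment feature matrix from a cohort
#'
#' Slices each subject's recording into labeled activity segments and
#' assembles the 39-feature assessment vector per subject. Segments come
#' from the ground-truth annotation (\code{segments = "truth"}) or from the
#' detections and predicted labels of a recognition evaluation
#' (\code{segments = "predicted"}; activities that were entirely missed or
#' rejected for a subject fall back to that subject's ground-truth
#' segments, counted in the \code{fallbacks} attribute).
#'
#' @param cohort an \code{"actcap_cohort"}.
#' @param segments \code{"truth"} or \code{"predicted"}.
#' @param recognition an \code{"actcap_recognition_eval"} (required for
#'   \code{segments = "predicted"}).
#' @return numeric matrix (subjects x 39) with subject ids as row names and
#'   attributes \code{basfi} (capacity scores) and \code{fallbacks}.
#' @export
extract_assessment_features <- function(cohort, segments = c("truth", "predicted"),
                                        recognition = NULL) {
  segments <- match.arg(segments)
  if (segments == "predicted" && is.null(recognition)) {
    stop("extract_assessment_features: recognition evaluation required")
  }
  fs <- cohort$config$sample_rate
  n <- length(cohort$recordings)
  out <- matrix(NA_real_, n, 39L,
                dimnames = list(vapply(cohort$recordings,
                                       function(r) r$subject_id, ""),
                                assessment_feature_names()))
  fallbacks <- 0L
  for (s in seq_len(n)) {
    rec <- cohort$recordings[[s]]
    ann <- cohort$annotations[[s]]
    gt <- ann[ann$label %in% ACTIVITIES, , drop = FALSE]
    gt_slices <- function(act) {
      idx <- which(gt$label == act)
      lapply(idx, function(i) {
        rec$channels[(gt$start[i] + 1L):gt$end[i], , drop = FALSE]
      })
    }
    by_act <- stats::setNames(vector("list", 6L), ACTIVITIES)
    if (segments == "truth") {
      for (a in ACTIVITIES) by_act[[a]] <- gt_slices(a)
    } else {
      p <- recognition$detections[[s]]
      for (a in ACTIVITIES) {
        idx <- which(p$predicted == a)
        if (length(idx)) {
          by_act[[a]] <- p$slices[idx]
        } else {
          by_act[[a]] <- gt_slices(a)
          fallbacks <- fallbacks + 1L
        }
      }
    }
    out[s, ] <- assemble_patient_vector(by_act, fs)
  }
  attr(out, "basfi") <- vapply(cohort$profiles, function(p) p$capacity, 0)
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate, segment, recognize in leave-one-subject-out fashion, extract
#' assessment features from the recognized segments, run the
#' leave-one-subject-out ICS assessment, and write reports: a per-subject
#' recognition report (nrFD, DTPR, SDC, ACCp, ACCa), a per-activity report,
#' the assessment feature table, the LOSO assessment predictions, and a
#' score card fit on the full cohort. All randomness flows from the configs'
#' seeds, so outputs are byte-identical across reruns.
#'
#' @param out_dir output directory (created if missing).
#' @param protocol,seg,casc,ics stage configurations.
#' @param write_raw also write each subject's recording/annotation files.
#' @param run_assessment run the ICS assessment stage (skipped with a
#'   warning when the cohort has fewer than 4 subjects).
#' @param verbose print stage progress.
#' @return invisible list with \code{recognition}, \code{features},
#'   \code{assessment}, \code{card} and the output file paths.
#' @export
run_pipeline <- function(out_dir, protocol = protocol_config(),
                         seg = segmenter_config(), casc = cascade_config(),
                         ics = ics_config(), write_raw = FALSE,
                         run_assessment = TRUE, verbose = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (verbose) message("simulating cohort (", protocol$n_subjects, " subjects)")
  cohort <- generate_cohort(protocol)
  if (write_raw) write_cohort(cohort, file.path(out_dir, "raw"))
  if (verbose) message("leave-one-subject-out recognition")
  rec_eval <- evaluate_recognition_loso(cohort, seg, casc, verbose = verbose)
  paths <- list(per_subject = file.path(out_dir, "recognition_per_subject.csv"),
                per_activity = file.path(out_dir, "recognition_per_activity.csv"),
                features = file.path(out_dir, "assessment_features.csv"))
  ps <- rec_eval$per_subject
  avg <- data.frame(subject = "Average", n_gt = mean(ps$n_gt),
                    nr_fd = mean(ps$nr_fd), dtpr = mean(ps$dtpr),
                    sdc_mean = mean(ps$sdc_mean, na.rm = TRUE),
                    sdc_sd = NA_real_,
                    acc_pure = mean(ps$acc_pure, na.rm = TRUE),
                    acc_actual = mean(ps$acc_actual, na.rm = TRUE))
  utils::write.csv(rbind(ps, avg), paths$per_subject, row.names = FALSE)
  utils::write.csv(rec_eval$per_activity, paths$per_activity, row.names = FALSE)
  feats <- extract_assessment_features(cohort, "predicted",
                                       recognition = rec_eval)
  basfi <- attr(feats, "basfi")
  fdf <- data.frame(subject = rownames(feats), basfi = basfi,
                    as.data.frame(feats), check.names = FALSE)
  utils::write.csv(fdf, paths$features, row.names = FALSE)
  assessment <- NULL
  card <- NULL
  if (run_assessment) {
    if (protocol$n_subjects < 4L) {
      warning("run_pipeline: fewer than 4 subjects; assessment stage skipped")
    } else {
      if (verbose) message("leave-one-subject-out ICS assessment")
      assessment <- loso_assessment(feats, basfi, ics, verbose = verbose)
      paths$assessment <- file.path(out_dir, "assessment_predictions.csv")
      utils::write.csv(
        data.frame(subject = rownames(feats), basfi = basfi,
                   truth = assessment$truth,
                   predicted = assessment$predictions),
        paths$assessment, row.names = FALSE)
      if (verbose) message("fitting cohort score card")
      fit <- fit_ics(feats, ifelse(basfi >= ics$basfi_threshold, 1, -1),
                     config = ics)
      card <- fit$system
      paths$card_md <- file.path(out_dir, "score_card.md")
      paths$card_json <- file.path(out_dir, "score_card.json")
      write_score_card(card, paths$card_md, paths$card_json)
    }
  }
  summary <- list(
    n_subjects = protocol$n_subjects,
    dtpr_pct = 100 * rec_eval$average$dtpr,
    mean_sdc = rec_eval$average$sdc_mean,
    acc_pure_pct = 100 * rec_eval$average$acc_pure,
    acc_actual_pct = 100 * rec_eval$average$acc_actual,
    assessment_accuracy_pct = if (!is.null(assessment))
      100 * assessment$accuracy else NA)
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(list(cohort = cohort, recognition = rec_eval, features = feats,
                 assessment = assessment, card = card, paths = paths,
                 summary = summary))
}
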