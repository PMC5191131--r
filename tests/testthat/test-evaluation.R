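seg <- function(start, end, label = NULL) {
  if (is.null(label)) data.frame(start = start, end = end)
  else data.frame(start = start, end = end, label = label)
}

test_that("the Dice coefficient matches hand-computed cases", {
  expect_equal(sdc(c(0, 10), c(0, 10)), 1)
  expect_equal(sdc(c(0, 10), c(10, 20)), 0)
  expect_equal(sdc(c(0, 10), c(5, 15)), 2 * 5 / 20)
  expect_equal(sdc(c(0, 8), c(2, 6)), 2 * 4 / 12)
  expect_error(sdc(c(3, 3), c(0, 1)), "zero-length")
})

test_that("greedy matching is one-to-one and prefers the largest overlap", {
  gt <- seg(c(0, 100), c(50, 150))
  det <- seg(c(10, 40, 200), c(45, 140, 220))
  m <- match_detections(gt, det)
  # detection 2 overlaps both gt segments but more with gt 2
  expect_equal(m$pairs$det_index[m$pairs$gt_index == 2], 2)
  expect_equal(m$pairs$det_index[m$pairs$gt_index == 1], 1)
  expect_equal(m$false_detections, 3)
  expect_length(m$missed_gt, 0)
  # a detection overlapping only an already-matched gt is not a false
  # detection but also not a pair
  det2 <- seg(c(0, 30), c(40, 50))
  m2 <- match_detections(seg(0, 50), det2)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$unmatched_overlapping, 2)
  expect_length(m2$false_detections, 0)
})

test_that("detection report aggregates DTPR, nrFD and SDC", {
  gt <- seg(c(0, 100, 200), c(50, 150, 250), c("getup", "pen5", "getup"))
  det <- seg(c(5, 300), c(55, 320))
  r <- detection_report(gt, det)
  expect_equal(r$dtpr, 1 / 3)
  expect_equal(r$nr_fd, 1)
  expect_equal(r$sdc_mean, sdc(c(0, 50), c(5, 55)))
  expect_equal(r$per_activity$dtpr[r$per_activity$activity == "getup"], 0.5)
  expect_equal(r$per_activity$dtpr[r$per_activity$activity == "pen5"], 0)
})

test_that("worked accuracy example: 12 gt, 9 correct, 1 accepted FD gives 69.2%", {
  # 12 ground-truth segments; 10 detected, 9 classified correctly, 1
  # wrongly; 1 false detection the classifier accepts as an activity
  gt <- seg(100 * 0:11, 100 * 0:11 + 50,
            rep(c("getup", "liedown", "maxreach", "pen5", "reach5", "STS5"), 2))
  det <- rbind(seg(100 * 0:9, 100 * 0:9 + 50), seg(2000, 2050))
  pred <- c(gt$label[1:9], "getup", "pen5")  # det 10 wrong, FD accepted
  a <- recognition_accuracies(gt, det, pred)
  expect_equal(a$n_gt, 12)
  expect_equal(a$n_correct, 9)
  expect_equal(a$n_accepted_fd, 1)
  expect_equal(round(100 * a$acc_actual, 1), 69.2)
  expect_equal(a$acc_pure, 9 / 10)
})

test_that("worked accuracy example: 12 correct with 3 accepted FDs gives 80.0%", {
  gt <- seg(100 * 0:11, 100 * 0:11 + 50,
            rep(c("getup", "liedown", "maxreach", "pen5", "reach5", "STS5"), 2))
  det <- rbind(seg(100 * 0:11, 100 * 0:11 + 50), seg(c(2000, 2100, 2200),
                                                     c(2050, 2150, 2250)))
  pred <- c(gt$label, "getup", "STS5", "pen5")
  a <- recognition_accuracies(gt, det, pred)
  expect_equal(a$acc_actual, 12 / 15)
  expect_equal(round(100 * a$acc_actual, 1), 80.0)
  expect_equal(a$acc_pure, 1)
})

test_that("rejected false detections do not count against actual accuracy", {
  gt <- seg(c(0, 100), c(50, 150), c("getup", "pen5"))
  det <- rbind(seg(c(0, 100), c(50, 150)), seg(c(300, 400), c(350, 450)))
  pred_rejected <- c("getup", "pen5", reject_label(), reject_label())
  pred_accepted <- c("getup", "pen5", "STS5", reject_label())
  a1 <- recognition_accuracies(gt, det, pred_rejected)
  a2 <- recognition_accuracies(gt, det, pred_accepted)
  expect_equal(a1$acc_actual, 1)
  expect_equal(a2$acc_actual, 2 / 3)
  # a matched detection classified as REJECT is an error in both measures
  pred_miss <- c(reject_label(), "pen5", reject_label(), reject_label())
  a3 <- recognition_accuracies(gt, det, pred_miss)
  expect_equal(a3$acc_pure, 1 / 2)
  expect_equal(a3$acc_actual, 1 / 2)
})

test_that("edge cases: empty detections and empty ground truth", {
  gt <- seg(0, 50, "getup")
  none <- seg(integer(0), integer(0))
  m <- match_detections(gt, none)
  expect_equal(m$missed_gt, 1)
  r <- detection_report(gt, none)
  expect_equal(r$dtpr, 0)
  expect_true(is.na(r$sdc_mean))
  a <- recognition_accuracies(gt, none, character(0))
  expect_true(is.na(a$acc_pure))
  expect_equal(a$acc_actual, 0)
})
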