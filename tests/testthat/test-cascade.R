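# Well-separated Gaussian feature clouds stand in for real feature vectors:
# cascade behavior is tested structurally, end-to-end behavior in
# test-pipeline.R / test-acceptance.R.
make_clouds <- function(n_per, d = 8, sep = 4, seed = 30) {
  set.seed(seed)
  labs <- c(activity_classes(), reject_label())
  centers <- matrix(rnorm(length(labs) * d, 0, sep), length(labs), d)
  X <- do.call(rbind, lapply(seq_along(labs), function(k)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[k, ], `+`)))
  colnames(X) <- paste0("f", 1:d)
  list(X = X, y = rep(labs, each = n_per), centers = centers)
}

test_that("own LDA agrees with MASS::lda on posterior argmax", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 2), 30, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c("p", "q"), each = 30)
  own <- fit_lda(X, y)
  ref <- MASS::lda(X, grouping = y)
  Xt <- matrix(rnorm(100, 1), 50, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_lda(own, Xt),
               as.character(predict(ref, Xt)$class))
  # posteriors agree numerically
  expect_equal(unname(lda_posterior(own, Xt)),
               unname(predict(ref, Xt)$posterior), tolerance = 1e-6)
})

test_that("LDA validates inputs and records shrinkage", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lda(X, rep("a", 10)), "2 classes")
  expect_error(fit_lda(X, c(rep("a", 9), "b")), "2 samples")
  # perfectly collinear features force shrinkage
  Xc <- cbind(1:10, (1:10) * 2)
  expect_warning(m <- fit_lda(Xc, rep(c("a", "b"), 5)), "shrinkage")
  expect_true(m$shrinkage)
  expect_silent(fit_lda(Xc, rep(c("a", "b"), 5), warn = FALSE))
})

test_that("cascade trains on 7 classes and predicts cleanly separated data", {
  d <- make_clouds(25)
  model <- train_cascade(d$X, d$y, cascade_config(n_trees = 100, seed = 2))
  expect_s3_class(model, "actcap_cascade")
  pred <- predict_cascade(model, d$X)
  expect_gt(mean(pred == d$y), 0.95)
  expect_true(all(pred %in% c(activity_classes(), reject_label())))
})

test_that("training requires all activities and warns without rejection examples", {
  d <- make_clouds(10)
  keep <- d$y != "getup"
  expect_error(train_cascade(d$X[keep, ], d$y[keep]), "getup")
  keep2 <- d$y != reject_label()
  expect_warning(m <- train_cascade(d$X[keep2, ], d$y[keep2],
                                    cascade_config(n_trees = 40)),
                 "never reject")
  # without rejection examples nothing is ever rejected
  pred <- predict_cascade(m, d$X)
  expect_false(any(pred == reject_label()))
})

test_that("stage-1 posterior re-applies the 2:1 rejection weight", {
  d <- make_clouds(20, seed = 33)
  model <- train_cascade(d$X, d$y, cascade_config(n_trees = 80, seed = 3))
  # a point exactly between an activity center and the reject center gets
  # pushed toward rejection by the weighting
  p <- actcap:::stage1_posterior(model, d$X)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  raw <- predict(model$stage1, data.frame(d$X), num.threads = 1)$predictions
  w <- model$class_weights[colnames(raw)]
  manual <- raw * rep(w, each = nrow(raw))
  manual <- manual / rowSums(manual)
  expect_equal(unname(p), unname(manual[, colnames(p)]), tolerance = 1e-9)
})

test_that("rejection gate is monotone in its threshold", {
  d <- make_clouds(20, sep = 1.2, seed = 34)   # overlapping clouds
  model <- train_cascade(d$X, d$y, cascade_config(n_trees = 80, seed = 4))
  n_rejected <- sapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    m <- model
    m$config$reject_confidence <- thr
    sum(predict_cascade(m, d$X) == reject_label())
  })
  expect_true(all(diff(n_rejected) <= 0))
})

test_that("borderline rejections are reconsidered by stages 2 and 3", {
  d <- make_clouds(20, sep = 1.0, seed = 35)
  model <- train_cascade(d$X, d$y, cascade_config(n_trees = 80, seed = 5))
  p <- actcap:::stage1_posterior(model, d$X)
  border <- which(p[, reject_label()] > 0.4 & p[, reject_label()] <= 0.7)
  # overlapping clouds at this seed must produce borderline samples
  expect_gt(length(border), 0)
  pred <- predict_cascade(model, d$X[border, , drop = FALSE])
  # below the gate the sample is never auto-rejected by stage 1 alone:
  # any rejection must come from the stage-3 binary model, so some
  # borderline samples can still be accepted as activities
  expect_true(any(pred %in% activity_classes()))
})

test_that("cascade training is deterministic given the seed", {
  d <- make_clouds(15, seed = 36)
  m1 <- train_cascade(d$X, d$y, cascade_config(n_trees = 60, seed = 9))
  m2 <- train_cascade(d$X, d$y, cascade_config(n_trees = 60, seed = 9))
  expect_identical(predict_cascade(m1, d$X), predict_cascade(m2, d$X))
})
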