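test_that("equal-frequency binning and binarization behave as specified", {
  set.seed(50)
  X <- cbind(a = rnorm(120), b = runif(120))
  sch <- make_binning(X, bins_per_variable = 6)
  expect_s3_class(sch, "actcap_binning")
  expect_equal(sch$bin_counts, c(a = 6, b = 6))
  # roughly equal occupancy (bin index computed directly from thresholds)
  bin_of <- function(v) 1L + sum(v > sch$thresholds$a)
  bins <- vapply(X[, "a"], bin_of, integer(1))
  expect_true(all(table(bins) >= 10))
  # tie handling: values exactly at a threshold fall in the lower bin
  thr <- sch$thresholds$a[2]
  expect_equal(bin_of(thr), 2L)
  expect_equal(bin_of(thr), bin_of(thr - 1e-9))
  expect_equal(bin_of(thr + 1e-9), 3L)
  # binarize agrees with the direct computation on full samples
  z <- binarize(X[1, ], sch)
  expect_equal(which(z[1:6] == 1), bin_of(X[1, "a"]))
  # one-hot expansion has exactly one 1 per (sample, variable)
  Z <- binarize_matrix(X, sch)
  expect_equal(ncol(Z), 12)
  expect_true(all(rowSums(Z[, 1:6]) == 1))
  expect_true(all(rowSums(Z[, 7:12]) == 1))
  # constant variables collapse to a single bin with a warning
  expect_warning(make_binning(cbind(c = rep(1, 20))), "constant")
})

test_that("the difference matrix anchors each variable and takes adjacent differences", {
  D <- make_difference_matrix(c(3, 2))
  expect_equal(dim(D), c(5, 5))
  w <- c(2, 5, 4, -1, 3)
  expect_equal(as.numeric(D %*% w), c(2, 3, -1, -1, 4))
})

test_that("the simplex solver matches exhaustive vertex enumeration", {
  set.seed(51)
  for (k in 1:25) {
    m <- sample(2:3, 1); n <- m + sample(2:4, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    # guarantee feasibility (b = A x0, x0 >= 0) and boundedness (c >= 0)
    x0 <- round(runif(n), 2)
    b <- as.numeric(A %*% x0)
    cvec <- abs(round(rnorm(n), 2))
    ref <- lp_vertex_minimum(cvec, A, b)
    expect_true(is.finite(ref))
    # solve via big-M: append an artificial identity as the start basis
    sgn <- ifelse(b < 0, -1, 1)
    A2 <- cbind(A * sgn, diag(m))
    b2 <- b * sgn
    big <- 1e5 * (1 + max(abs(cvec)))
    sol <- actcap:::simplex_solve(c(cvec, rep(big, m)), A2, b2,
                                  basis = n + seq_len(m))
    expect_equal(sol$status, "optimal")
    expect_true(all(sol$x[n + seq_len(m)] < 1e-7))
    expect_equal(sol$objective, ref, tolerance = 1e-6)
  }
})

test_that("the ICS linear program matches exhaustive vertex enumeration", {
  set.seed(52)
  done <- 0
  for (k in 1:12) {
    if (done >= 6) break
    n <- sample(4:5, 1)
    X <- cbind(rnorm(n), rnorm(n))
    colnames(X) <- c("u", "v")
    y <- ifelse(X[, 1] + rnorm(n, 0, 0.3) > 0, 1, -1)
    if (length(unique(y)) < 2) next
    done <- done + 1
    sch <- suppressWarnings(make_binning(X, bins_per_variable = 3))
    Z <- binarize_matrix(X, sch)
    gamma <- sample(c(0.1, 1, 10), 1)
    sol <- solve_ics_core(Z, y, sch$bin_counts, gamma)
    ref <- ics_vertex_objective(Z, y, sch$bin_counts, gamma)
    expect_equal(sol$objective, ref, tolerance = 1e-6)
    # the returned solution is feasible and consistent
    expect_true(all(sol$eps >= -1e-9))
    expect_equal(as.numeric(make_difference_matrix(sch$bin_counts) %*% sol$w),
                 sol$v, tolerance = 1e-8)
  }
  expect_gte(done, 4)
})

test_that("gamma trades errors against total variation", {
  set.seed(53)
  n <- 40
  X <- cbind(f = rnorm(n))
  y <- ifelse(X[, 1] + rnorm(n, 0, 0.8) > 0, 1, -1)
  sch <- make_binning(X, 6)
  Z <- binarize_matrix(X, sch)
  lo <- solve_ics_core(Z, y, sch$bin_counts, gamma = 1e-4)
  hi <- solve_ics_core(Z, y, sch$bin_counts, gamma = 100)
  # tiny gamma: cheapest to absorb all errors, weights collapse to zero
  expect_lt(sum(abs(lo$v)), 1e-6)
  # large gamma: errors expensive, so the slack total shrinks
  expect_lt(sum(hi$eps), sum(lo$eps))
  expect_gt(sum(abs(hi$v)), sum(abs(lo$v)))
})

test_that("iterative reweighting sparsifies without losing the signal variable", {
  set.seed(54)
  n <- 60
  X <- cbind(sig = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- ifelse(X[, "sig"] > 0.2, 1, -1)
  sch <- make_binning(X, 6)
  Z <- binarize_matrix(X, sch)
  rw <- reweight_iterate(Z, y, sch$bin_counts, gamma = 5, seed = 3)
  expect_s3_class(rw$solution, "actcap_ics_solution")
  sel <- selected_variables(rw$solution, sch)
  expect_true("sig" %in% sel)
  expect_true(is.data.frame(rw$table))
  expect_true(all(c("n_vars", "n_intervals", "cv_accuracy") %in% names(rw$table)))
  # noise variables are pruned on this cleanly separable problem
  expect_lt(length(sel), 3)
})

test_that("scoring systems round to integers and map scores to risk", {
  set.seed(55)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- ifelse(X[, "a"] + 0.5 * X[, "b"] > 0, 1, -1)
  fit <- fit_ics(X, y, config = ics_config(sa_evals = 20, seed = 9))
  sys <- fit$system
  expect_s3_class(sys, "actcap_scoring_system")
  for (v in sys$variables) {
    iv <- sys$intervals[[v]]
    expect_true(all(iv$weight == round(iv$weight)))
    expect_equal(iv$lower[1], -Inf)
    expect_equal(iv$upper[nrow(iv)], Inf)
    if (nrow(iv) > 1) {
      expect_equal(iv$lower[-1], iv$upper[-nrow(iv)])
    }
  }
  # risk is monotone nondecreasing in the total score
  scores <- actcap:::score_range(sys)
  risks <- plogis(sys$logistic["intercept"] + sys$logistic["slope"] * scores)
  expect_true(all(diff(risks) >= -1e-9))
  sc <- score_sample(sys, X[1, ])
  expect_true(is.finite(sc$score))
  expect_true(sc$risk >= 0 && sc$risk <= 1)
  expect_true(sc$class %in% c(-1, 1))
  # training accuracy beats chance comfortably on separable data
  preds <- apply(X, 1, function(r) score_sample(sys, r)$class)
  expect_gt(mean(preds == y), 0.8)
})

test_that("score card rendering includes intervals, points and risk", {
  set.seed(56)
  X <- cbind(a = rnorm(50))
  y <- ifelse(X[, 1] > 0, 1, -1)
  fit <- fit_ics(X, y, config = ics_config(sa_evals = 10, seed = 2))
  txt <- paste(format_score_card(fit$system), collapse = "\n")
  expect_match(txt, "interval")
  expect_match(txt, "risk")
  f_md <- tempfile(fileext = ".md"); f_js <- tempfile(fileext = ".json")
  write_score_card(fit$system, f_md, f_js)
  expect_true(file.exists(f_md) && file.exists(f_js))
  back <- jsonlite::read_json(f_js, simplifyVector = TRUE)
  expect_true("variables" %in% names(back))
  unlink(c(f_md, f_js))
})

test_that("gamma selection is deterministic and stays in range", {
  set.seed(57)
  n <- 40
  X <- cbind(a = rnorm(n))
  y <- ifelse(X[, 1] > 0, 1, -1)
  sch <- make_binning(X, 4)
  Z <- binarize_matrix(X, sch)
  g1 <- select_gamma(Z, y, sch$bin_counts, evals = 15, seed = 4)
  g2 <- select_gamma(Z, y, sch$bin_counts, evals = 15, seed = 4)
  expect_identical(g1, g2)
  expect_gte(g1, 1e-3)
  expect_lte(g1, 1e3)
})

test_that("LOSO assessment predicts every subject exactly once", {
  set.seed(58)
  n <- 10
  X <- cbind(a = rnorm(n), b = rnorm(n))
  basfi <- runif(n, 0, 8)
  # guarantee both classes
  basfi[1:3] <- c(1, 5, 6)
  cfg <- ics_config(sa_evals = 6, sa_folds = 3, subset_reweight_iter = 2,
                    max_subsets = 10, seed = 5)
  res <- loso_assessment(X, basfi, cfg)
  expect_s3_class(res, "actcap_loso_assessment")
  expect_length(res$predictions, n)
  expect_identical(res$truth, ifelse(basfi >= 3, 1, -1))
  expect_true(all(res$predictions %in% c(-1, 1, NA)))
  expect_equal(res$accuracy,
               mean(res$predictions == res$truth, na.rm = TRUE))
  expect_equal(dim(res$selection_frequencies), c(n, 2))
})
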