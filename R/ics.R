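#' Equal-frequency binning scheme for interval coded scoring
#'
#' Per variable, thresholds are the equal-frequency (quantile) cut points of
#' the training distribution; duplicate thresholds are collapsed, so a
#' variable ends up with at most \code{bins_per_variable} bins. A constant
#' variable keeps a single bin (with a warning). Raw vectors are expanded to
#' a concatenated one-hot binary vector, one active bin per variable.
#'
#' @param X numeric matrix (samples x variables) with column names.
#' @param bins_per_variable maximal bins per variable (default 6).
#' @return object of class \code{"actcap_binning"}: \code{thresholds}
#'   (named list of strictly increasing cut points), \code{bin_counts},
#'   \code{variables}.
#' @export
make_binning <- function(X, bins_per_variable = 6L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  thresholds <- list()
  for (p in seq_len(ncol(X))) {
    x <- X[, p]
    if (length(unique(x)) < 2L) {
      warning("make_binning: variable '", colnames(X)[p],
              "' is constant; single bin")
      thresholds[[colnames(X)[p]]] <- numeric(0)
      next
    }
    q <- stats::quantile(x, probs = seq_len(bins_per_variable - 1L) /
                           bins_per_variable, names = FALSE, type = 7)
    thresholds[[colnames(X)[p]]] <- unique(q)
  }
  structure(list(thresholds = thresholds,
                 bin_counts = vapply(thresholds, length, 0L) + 1L,
                 variables = colnames(X)),
            class = "actcap_binning")
}

#' Expand a raw vector into the one-hot binary bin space
#'
#' The active bin for variable p is \code{1 + sum(x_p > thresholds_p)}:
#' values at or below a threshold fall in the lower bin, values at or below
#' the first threshold in the first bin.
#'
#' @param x named numeric vector (or unnamed in scheme variable order).
#' @param scheme an \code{"actcap_binning"}.
#' @return binary vector of length \code{sum(bin_counts)}.
#' @export
binarize <- function(x, scheme) {
  if (length(x) != length(scheme$variables)) {
    stop("binarize: expected ", length(scheme$variables), " variables, got ",
         length(x))
  }
  if (!is.null(names(x))) x <- x[scheme$variables]
  z <- numeric(sum(scheme$bin_counts))
  off <- 0L
  for (p in seq_along(scheme$variables)) {
    bin <- 1L + sum(x[p] > scheme$thresholds[[p]])
    z[off + bin] <- 1
    off <- off + scheme$bin_counts[p]
  }
  z
}

#' @rdname binarize
#' @param X numeric matrix of raw samples.
#' @return for \code{binarize_matrix}, the binary matrix Z (samples x bins).
#' @export
binarize_matrix <- function(X, scheme) {
  X <- as.matrix(X)
  t(apply(X, 1L, binarize, scheme = scheme))
}

bin_names <- function(scheme) {
  unlist(lapply(seq_along(scheme$variables), function(p) {
    paste0(scheme$variables[p], ".bin", seq_len(scheme$bin_counts[p]))
  }), use.names = FALSE)
}

# decision values y_hat = Z w + b; sign ties (0) go to the positive
# (decreased-capacity) class
ics_decision <- function(solution, Z) {
  drop(Z %*% solution$w) + solution$b
}

sign_pos <- function(x) ifelse(x >= 0, 1, -1)

make_cv_folds <- function(y, k) {
  # stratified fold assignment; requires set.seed upstream for determinism
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_error <- function(Z, y, bin_counts, gamma, folds, theta = NULL,
                     reweight = FALSE, max_iter = 10L, delta = 1e-4) {
  errs <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    sol <- if (reweight) {
      reweight_iterate(Z[tr, , drop = FALSE], y[tr], bin_counts, gamma,
                       max_iter = max_iter, delta = delta,
                       compute_cv = FALSE)$solution
    } else {
      solve_ics_core(Z[tr, , drop = FALSE], y[tr], bin_counts, gamma,
                     theta = theta)
    }
    pred <- sign_pos(ics_decision(sol, Z[!tr, , drop = FALSE]))
    errs <- errs + sum(pred != y[!tr])
  }
  errs / length(y)
}

#' Select the ICS hyperparameter by simulated annealing
#'
#' Minimizes the k-fold cross-validated misclassification rate of the ICS
#' classifier over \eqn{\log_{10} \gamma} with simulated annealing:
#' Gaussian proposal steps, geometric cooling, fixed seed for
#' reproducibility. By default each CV fit runs the full iterative
#' reweighting (the estimator actually used downstream), so the selected
#' \eqn{\gamma} reflects the generalization of the sparsified model rather
#' than of the dense unit-weight solution, which tends to interpolate small
#' samples and makes the CV criterion uninformative.
#'
#' @inheritParams solve_ics_core
#' @param search_range positive range \code{c(lo, hi)} for gamma
#'   (default 1e-3 to 1e3).
#' @param evals number of annealing evaluations (default 60).
#' @param t0,cooling initial temperature and geometric cooling factor.
#' @param step_sd proposal standard deviation in log10 units.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed.
#' @param cv_reweight cross-validate the reweighted (sparsified) classifier
#'   rather than the dense unit-weight solve (default \code{TRUE}).
#' @return the selected gamma (scalar within \code{search_range}).
#' @export
select_gamma <- function(Z, y, bin_counts, search_range = c(1e-3, 1e3),
                         evals = 60L, t0 = 1.0, cooling = 0.85,
                         step_sd = 0.5, folds = 5L, seed = 1L,
                         cv_reweight = TRUE) {
  stopifnot(search_range[1] > 0, search_range[2] >= search_range[1])
  set.seed(seed)
  lo <- log10(search_range[1]); hi <- log10(search_range[2])
  fold_id <- make_cv_folds(y, min(folds, length(y)))
  eval_g <- function(g) cv_error(Z, y, bin_counts, 10^g, fold_id,
                                 reweight = cv_reweight)
  g <- (lo + hi) / 2
  e <- eval_g(g)
  best_g <- g; best_e <- e
  temp <- t0
  for (i in seq_len(evals - 1L)) {
    g2 <- min(hi, max(lo, g + stats::rnorm(1, 0, step_sd)))
    e2 <- eval_g(g2)
    if (e2 < e || stats::runif(1) < exp(-(e2 - e) / temp)) {
      g <- g2; e <- e2
    }
    if (e2 < best_e || (e2 == best_e && abs(g2) < abs(best_g))) {
      best_g <- g2; best_e <- e2
    }
    temp <- temp * cooling
  }
  10^best_g
}

support_of <- function(v, tol = 1e-8) which(abs(v) > tol)

solution_complexity <- function(sol, tol = 1e-8) {
  off <- 0L
  n_vars <- 0L; n_intervals <- 0L
  for (p in seq_along(sol$bin_counts)) {
    B <- sol$bin_counts[p]
    v <- sol$v[off + seq_len(B)]
    if (any(abs(v) > tol)) {
      n_vars <- n_vars + 1L
      # intervals = runs of equal weight = 1 + nonzero differences past anchor
      n_intervals <- n_intervals + 1L + sum(abs(v[-1L]) > tol)
    }
    off <- off + B
  }
  c(n_vars = n_vars, n_intervals = n_intervals)
}

#' Iterative reweighting of the ICS total-variation penalty
#'
#' Adaptive-L1 refinement: after an initial solve with unit penalty weights,
#' each difference row r is reweighted as \eqn{\theta_r = 1 / (|{(Dw)}_r| +
#' \delta)} and the LP re-solved, until the support of Dw is unchanged
#' between iterations or \code{max_iter} iterations (non-convergence is
#' flagged). Every iteration yields a candidate model; the emitted table
#' reports each candidate's complexity (number of selected variables and
#' intervals) and, when \code{compute_cv} is set, its k-fold CV accuracy,
#' supporting the complexity-performance trade-off review. The automatic
#' pick is the simplest candidate within one standard error of the best CV
#' accuracy (\code{pick = "1se"}); \code{pick = "best"} takes the highest
#' CV accuracy, and an integer picks a table row directly (interactive use).
#'
#' @inheritParams solve_ics_core
#' @param max_iter maximal reweighting iterations (default 10).
#' @param delta reweighting stabilizer (default 1e-4).
#' @param compute_cv compute the CV column of the candidate table.
#' @param cv_folds,seed CV fold count and RNG seed for fold assignment.
#' @param pick \code{"1se"} (default), \code{"best"}, or a row number.
#' @return list with \code{solution} (the picked
#'   \code{"actcap_ics_solution"}), \code{table} (candidate data frame
#'   ordered by complexity), \code{converged}, \code{iterations}.
#' @export
reweight_iterate <- function(Z, y, bin_counts, gamma, max_iter = 10L,
                             delta = 1e-4, compute_cv = TRUE, cv_folds = 5L,
                             seed = 1L, pick = "1se") {
  if (compute_cv) set.seed(seed)
  fold_id <- if (compute_cv) make_cv_folds(y, min(cv_folds, length(y)))
  sols <- list()
  theta <- NULL
  supp_prev <- NULL
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    sol <- solve_ics_core(Z, y, bin_counts, gamma, theta = theta)
    sols[[it]] <- sol
    supp <- support_of(sol$v)
    if (!is.null(supp_prev) && identical(supp, supp_prev)) {
      converged <- TRUE
      break
    }
    supp_prev <- supp
    theta <- 1 / (abs(sol$v) + delta)
  }
  comp <- t(vapply(sols, solution_complexity, c(n_vars = 0L, n_intervals = 0L)))
  cv_acc <- rep(NA_real_, length(sols))
  cv_se <- rep(NA_real_, length(sols))
  if (compute_cv) {
    for (i in seq_along(sols)) {
      fold_acc <- numeric(0)
      for (f in sort(unique(fold_id))) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2L) next
        s <- solve_ics_core(Z[tr, , drop = FALSE], y[tr], bin_counts, gamma,
                            theta = sols[[i]]$theta)
        pred <- sign_pos(ics_decision(s, Z[!tr, , drop = FALSE]))
        fold_acc <- c(fold_acc, mean(pred == y[!tr]))
      }
      cv_acc[i] <- mean(fold_acc)
      cv_se[i] <- stats::sd(fold_acc) / sqrt(length(fold_acc))
    }
  }
  tab <- data.frame(iteration = seq_along(sols),
                    n_vars = comp[, "n_vars"],
                    n_intervals = comp[, "n_intervals"],
                    cv_accuracy = cv_acc, cv_se = cv_se)
  tab <- tab[order(tab$n_intervals, tab$n_vars, tab$iteration), ]
  rownames(tab) <- NULL
  chosen <- if (is.numeric(pick)) {
    tab$iteration[pick]
  } else if (!compute_cv || all(is.na(tab$cv_accuracy))) {
    length(sols)  # last iterate
  } else if (pick == "best") {
    cand <- tab[which(tab$cv_accuracy == max(tab$cv_accuracy, na.rm = TRUE)), ]
    cand$iteration[1L]
  } else {  # one-standard-error rule
    best <- which.max(tab$cv_accuracy)
    limit <- tab$cv_accuracy[best] - tab$cv_se[best]
    cand <- tab[!is.na(tab$cv_accuracy) & tab$cv_accuracy >= limit, ]
    cand$iteration[1L]
  }
  list(solution = sols[[chosen]], table = tab, converged = converged,
       iterations = iters, picked_iteration = chosen)
}

#' Convert an ICS solution into an integer score card
#'
#' Adjacent bins with equal weight are merged into intervals; weights are
#' scaled by the factor in \code{\{1, ..., 20\} / max|w|} that minimizes the
#' disagreement with the unrounded model's training predictions after
#' rounding to integers; variables whose weights are all zero are dropped.
#' A logistic regression of the class on the integer training score maps
#' the score to a risk of decreased capacity; classification thresholds the
#' risk at 0.5 (a tie counts as decreased capacity).
#'
#' @param solution an \code{"actcap_ics_solution"}.
#' @param scheme the \code{"actcap_binning"} that produced Z.
#' @param X,y raw training matrix and labels in \{-1, +1\} (+1 = decreased
#'   capacity).
#' @return object of class \code{"actcap_scoring_system"}.
#' @export
to_scoring_system <- function(solution, scheme, X, y) {
  X <- as.matrix(X)
  Z <- binarize_matrix(X, scheme)
  w <- solution$w
  wmax <- max(abs(w))
  degenerate <- wmax < 1e-8
  if (degenerate) {
    W <- round(w)  # all zeros
    b_int <- 0
    scale <- 1
    majority <- sign_pos(sum(y))
  } else {
    ref <- sign_pos(ics_decision(solution, Z))
    best_k <- 1L; best_dis <- Inf
    for (k in 1:20) {
      s <- k / wmax
      Wk <- round(s * w)
      bk <- round(s * solution$b)
      pred <- sign_pos(drop(Z %*% Wk) + bk)
      dis <- sum(pred != ref)
      if (dis < best_dis) {
        best_dis <- dis; best_k <- k
      }
    }
    scale <- best_k / wmax
    W <- round(scale * w)
    b_int <- round(scale * solution$b)
    majority <- NULL
  }
  # merge equal-weight adjacent bins into intervals, drop all-zero variables
  intervals <- list()
  off <- 0L
  for (p in seq_along(scheme$variables)) {
    B <- scheme$bin_counts[p]
    wp <- W[off + seq_len(B)]
    off <- off + B
    if (all(wp == 0)) next
    thr <- scheme$thresholds[[p]]
    lowers <- c(-Inf, thr)
    uppers <- c(thr, Inf)
    r <- rle(wp)
    hi_idx <- cumsum(r$lengths)
    lo_idx <- hi_idx - r$lengths + 1L
    intervals[[scheme$variables[p]]] <-
      data.frame(lower = lowers[lo_idx], upper = uppers[hi_idx],
                 weight = as.integer(r$values))
  }
  score_train <- as.integer(round(drop(Z %*% W)))
  y01 <- as.integer(y > 0)
  logistic <- c(intercept = 0, slope = 0)
  if (!degenerate && length(unique(score_train)) > 1L &&
      length(unique(y01)) > 1L) {
    fit <- suppressWarnings(stats::glm(y01 ~ score_train,
                                       family = stats::binomial()))
    logistic <- c(intercept = unname(stats::coef(fit)[1L]),
                  slope = unname(stats::coef(fit)[2L]))
  } else if (!degenerate) {
    # all scores equal or single class: flat risk at the empirical rate
    p1 <- max(min(mean(y01), 1 - 1e-6), 1e-6)
    logistic <- c(intercept = stats::qlogis(p1), slope = 0)
  }
  structure(list(variables = names(intervals), intervals = intervals,
                 weights = W, bias = b_int, scale = scale,
                 logistic = logistic, threshold = 0.5,
                 degenerate = degenerate, majority = majority,
                 scheme = scheme),
            class = "actcap_scoring_system")
}

#' @export
print.actcap_scoring_system <- function(x, ...) {
  cat(format_score_card(x), sep = "\n")
  invisible(x)
}

#' Score a new sample with a score card
#'
#' Sums the interval weights matched by the sample's raw values, maps the
#' integer score to a risk of decreased capacity through the fitted logistic
#' model, and classifies by thresholding the risk at 0.5 (ties count as
#' decreased capacity).
#'
#' @param system an \code{"actcap_scoring_system"}.
#' @param x named raw feature vector covering the system's variables.
#' @return list with integer \code{score}, \code{risk} in \[0, 1\] and
#'   \code{class} in \{-1, +1\} (+1 = decreased capacity).
#' @export
score_sample <- function(system, x) {
  if (system$degenerate) {
    return(list(score = 0L, risk = if (system$majority > 0) 1 else 0,
                class = system$majority))
  }
  missing <- setdiff(system$variables, names(x))
  if (length(missing)) {
    stop("score_sample: missing variables: ", paste(missing, collapse = ", "))
  }
  score <- 0L
  for (v in system$variables) {
    iv <- system$intervals[[v]]
    row <- which(x[[v]] > iv$lower & x[[v]] <= iv$upper)
    score <- score + iv$weight[row]
  }
  risk <- stats::plogis(system$logistic["intercept"] +
                          system$logistic["slope"] * score)
  list(score = as.integer(score), risk = unname(risk),
       class = if (risk >= system$threshold) 1 else -1)
}

#' Render a score card as text
#'
#' @param system an \code{"actcap_scoring_system"}.
#' @return character vector of lines (markdown-flavored table).
#' @export
format_score_card <- function(system) {
  out <- "## Activity capacity score card"
  if (system$degenerate) {
    return(c(out, "(degenerate: all weights zero; predicts the majority class)"))
  }
  for (v in system$variables) {
    out <- c(out, "", paste0("**", v, "**"), "| interval | points |",
             "|---|---|")
    iv <- system$intervals[[v]]
    for (r in seq_len(nrow(iv))) {
      out <- c(out, sprintf("| %s < x <= %s | %+d |",
                            format(iv$lower[r], digits = 4),
                            format(iv$upper[r], digits = 4),
                            iv$weight[r]))
    }
  }
  scores <- score_range(system)
  risks <- stats::plogis(system$logistic["intercept"] +
                           system$logistic["slope"] * scores)
  out <- c(out, "", "| total score | risk of decreased capacity |", "|---|---|",
           sprintf("| %d | %.2f |", scores, risks))
  out
}

# all achievable total scores (sum over variables of their weight sets)
score_range <- function(system) {
  lo <- sum(vapply(system$intervals, function(iv) min(iv$weight), 0))
  hi <- sum(vapply(system$intervals, function(iv) max(iv$weight), 0))
  seq.int(lo, hi)
}

#' Write a score card to disk
#'
#' Writes the human-readable markdown card and a machine-readable JSON
#' description (variables, intervals, weights, logistic risk map).
#'
#' @param system an \code{"actcap_scoring_system"}.
#' @param path_md,path_json output paths (either may be NULL).
#' @export
write_score_card <- function(system, path_md = NULL, path_json = NULL) {
  if (!is.null(path_md)) writeLines(format_score_card(system), path_md)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(variables = system$variables,
           intervals = system$intervals,
           bias = system$bias,
           logistic = as.list(system$logistic),
           threshold = system$threshold,
           degenerate = system$degenerate),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(NULL)
}

#' ICS assessment configuration
#'
#' @param bins_per_variable maximal bins per variable (default 6).
#' @param basfi_threshold capacity class cut point on the BASFI scale
#'   (default 3: scores at or above are the decreased-capacity class).
#' @param gamma_range simulated-annealing search range for gamma.
#' @param sa_evals,sa_folds annealing evaluations and CV folds.
#' @param reweight_max_iter maximal reweighting iterations.
#' @param subset_reweight_iter reweighting iterations inside the per-subset
#'   variable-selection fits (no CV table is needed there).
#' @param selection_threshold selection frequency above which a variable is
#'   retained (default 0.25).
#' @param max_subsets optional cap on the number of leave-two-out subsets
#'   per fold (all \code{choose(n-1, n-3)} by default; a cap draws a seeded
#'   random sample, intended for cohorts larger than the 28-subject
#'   protocol).
#' @param pick complexity-performance pick rule, see [reweight_iterate()].
#' @param seed RNG seed.
#' @return list of class \code{"actcap_ics_config"}.
#' @export
ics_config <- function(bins_per_variable = 6L, basfi_threshold = 3,
                       gamma_range = c(1e-3, 1e3), sa_evals = 60L,
                       sa_folds = 5L, reweight_max_iter = 10L,
                       subset_reweight_iter = 10L,
                       selection_threshold = 0.25, max_subsets = NULL,
                       pick = "1se", seed = 1L) {
  structure(as.list(environment()), class = "actcap_ics_config")
}

#' Fit a full ICS model on a training set
#'
#' Convenience pipeline: equal-frequency binning, gamma selection by
#' simulated annealing (unless given), iterative reweighting with the
#' complexity-performance pick, and conversion to an integer score card.
#'
#' @param X raw feature matrix (samples x variables, named columns).
#' @param y labels in \{-1, +1\} (+1 = decreased capacity).
#' @param config an \code{"actcap_ics_config"}.
#' @param gamma optional fixed gamma (skips the annealing).
#' @return list of class \code{"actcap_ics_fit"} with \code{system},
#'   \code{solution}, \code{scheme}, \code{gamma}, \code{table}.
#' @export
fit_ics <- function(X, y, config = ics_config(), gamma = NULL) {
  X <- as.matrix(X)
  scheme <- make_binning(X, config$bins_per_variable)
  Z <- binarize_matrix(X, scheme)
  if (is.null(gamma)) {
    gamma <- select_gamma(Z, y, scheme$bin_counts,
                          search_range = config$gamma_range,
                          evals = config$sa_evals, folds = config$sa_folds,
                          seed = config$seed)
  }
  rw <- reweight_iterate(Z, y, scheme$bin_counts, gamma,
                         max_iter = config$reweight_max_iter,
                         cv_folds = config$sa_folds, seed = config$seed,
                         pick = config$pick)
  system <- to_scoring_system(rw$solution, scheme, X, y)
  structure(list(system = system, solution = rw$solution, scheme = scheme,
                 gamma = gamma, table = rw$table,
                 converged = rw$converged),
            class = "actcap_ics_fit")
}

#' @export
print.actcap_ics_fit <- function(x, ...) {
  cat(sprintf("<actcap_ics_fit> gamma = %.4g; %d variable(s) selected: %s\n",
              x$gamma, length(x$system$variables),
              paste(x$system$variables, collapse = ", ")))
  invisible(x)
}

#' Variables with any nonzero bin weight in an ICS solution
#'
#' A variable is eliminated by the optimization when all its bin weights
#' are zero; the remaining ones form the selected set.
#'
#' @param solution an \code{"actcap_ics_solution"}.
#' @param scheme the \code{"actcap_binning"} that produced the design.
#' @param tol magnitude below which a weight counts as zero.
#' @return character vector of selected variable names.
#' @export
selected_variables <- function(solution, scheme, tol = 1e-6) {
  off <- 0L
  sel <- character(0)
  for (p in seq_along(scheme$variables)) {
    B <- scheme$bin_counts[p]
    if (any(abs(solution$w[off + seq_len(B)]) > tol)) {
      sel <- c(sel, scheme$variables[p])
    }
    off <- off + B
  }
  sel
}

#' Leave-one-subject-out ICS assessment with bootstrap-like variable selection
#'
#' The per-patient assessment procedure: class labels are obtained by
#' thresholding the BASFI score; for each left-out subject, every subset of
#' the training fold obtained by dropping two further subjects (all
#' \code{choose(n-1, n-3)} of them, 351 for the 28-subject protocol) is fit
#' with ICS, the per-subset variable selections are tallied, variables
#' selected in more than \code{selection_threshold} of the subsets are
#' retained, a final ICS model restricted to the retained variables is fit
#' on the full fold, and the held-out subject is classified with its score
#' card.
#'
#' @param features numeric matrix (subjects x assessment variables, named
#'   columns).
#' @param basfi numeric BASFI-like capacity scores in \[0, 10\].
#' @param config an \code{"actcap_ics_config"}.
#' @param verbose print per-fold progress.
#' @return list of class \code{"actcap_loso_assessment"}: \code{predictions}
#'   and \code{truth} (\{-1, +1\}; +1 = decreased capacity), \code{accuracy},
#'   \code{selection_frequencies} (folds x variables), \code{retained}
#'   (per-fold list), \code{systems} (per-fold score cards),
#'   \code{n_subsets}.
#' @export
loso_assessment <- function(features, basfi, config = ics_config(),
                            verbose = FALSE) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 4L) stop("loso_assessment: need at least 4 subjects")
  if (any(basfi < 0 | basfi > 10)) stop("loso_assessment: BASFI must be in [0, 10]")
  y <- ifelse(basfi >= config$basfi_threshold, 1, -1)
  preds <- rep(NA_real_, n)
  sel_freq <- matrix(0, n, ncol(X), dimnames = list(NULL, colnames(X)))
  retained <- vector("list", n)
  systems <- vector("list", n)
  n_subsets <- NA_integer_
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2L) {
      warning("loso_assessment: fold ", i, " has a single class; skipped")
      next
    }
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    scheme <- make_binning(Xtr, config$bins_per_variable)
    Z <- binarize_matrix(Xtr, scheme)
    gamma <- select_gamma(Z, ytr, scheme$bin_counts,
                          search_range = config$gamma_range,
                          evals = config$sa_evals, folds = config$sa_folds,
                          seed = config$seed + i)
    m <- length(tr)
    drop_pairs <- utils::combn(m, 2L)
    if (!is.null(config$max_subsets) &&
        ncol(drop_pairs) > config$max_subsets) {
      set.seed(config$seed + i)
      drop_pairs <- drop_pairs[, sample(ncol(drop_pairs),
                                        config$max_subsets), drop = FALSE]
    }
    n_subsets <- ncol(drop_pairs)
    counts <- stats::setNames(numeric(ncol(X)), colnames(X))
    used <- 0L
    for (s in seq_len(ncol(drop_pairs))) {
      keep <- setdiff(seq_len(m), drop_pairs[, s])
      if (length(unique(ytr[keep])) < 2L) next
      rw <- reweight_iterate(Z[keep, , drop = FALSE], ytr[keep],
                             scheme$bin_counts, gamma,
                             max_iter = config$subset_reweight_iter,
                             compute_cv = FALSE)
      sel <- selected_variables(rw$solution, scheme)
      counts[sel] <- counts[sel] + 1
      used <- used + 1L
    }
    freq <- counts / max(used, 1L)
    sel_freq[i, ] <- freq
    keep_vars <- names(freq)[freq > config$selection_threshold]
    retained[[i]] <- keep_vars
    if (!length(keep_vars)) {
      preds[i] <- sign_pos(sum(ytr))
      if (verbose) message("fold ", i, ": no variables retained; majority class")
      next
    }
    fit <- fit_ics(Xtr[, keep_vars, drop = FALSE], ytr,
                   config = within_config(config, seed = config$seed + i),
                   gamma = gamma)
    systems[[i]] <- fit$system
    xi <- stats::setNames(as.numeric(X[i, keep_vars]), keep_vars)
    preds[i] <- score_sample(fit$system, xi)$class
    if (verbose) {
      message(sprintf("fold %d: retained [%s]; pred %+d truth %+d",
                      i, paste(keep_vars, collapse = ", "), preds[i], y[i]))
    }
  }
  ok <- !is.na(preds)
  structure(list(predictions = preds, truth = y,
                 accuracy = mean(preds[ok] == y[ok]),
                 selection_frequencies = sel_freq, retained = retained,
                 systems = systems, n_subsets = n_subsets),
            class = "actcap_loso_assessment")
}

within_config <- function(config, ...) {
  mod <- list(...)
  config[names(mod)] <- mod
  config
}

#' @export
print.actcap_loso_assessment <- function(x, ...) {
  cat(sprintf("<actcap_loso_assessment> %d subjects, %d subsets/fold, accuracy %.1f%%\n",
              length(x$predictions), x$n_subsets, 100 * x$accuracy))
  invisible(x)
}
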