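#' Fit a linear discriminant model with pooled covariance
#'
#' Classic Gaussian discriminant analysis: each class k is modeled as
#' \eqn{N(\mu_k, \Sigma)} with a common (pooled within-class) covariance,
#' and a new observation is assigned the class maximizing the posterior
#' probability, giving linear decision boundaries. When the pooled
#' covariance is ill-conditioned (condition number above 1e10) diagonal
#' shrinkage \eqn{\Sigma + \delta I} with \eqn{\delta = 10^{-6}
#' \mathrm{tr}(\Sigma)/d} is applied and a warning emitted. Posterior ties
#' are broken toward the lexicographically first class label.
#'
#' @param features numeric matrix (samples x features).
#' @param labels class label per row (coerced to character).
#' @param warn emit a warning when shrinkage is applied (the fitted model
#'   always records it in \code{$shrinkage}); the cascade trainer sets this
#'   to \code{FALSE} because shrinkage is routine there.
#' @param priors optional named prior probabilities; defaults to empirical
#'   class frequencies.
#' @return object of class \code{"actcap_lda"}.
#' @export
fit_lda <- function(features, labels, priors = NULL, warn = TRUE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("fit_lda: need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) stop("fit_lda: need at least 2 samples per class")
  d <- ncol(features)
  mu <- matrix(0, length(classes), d,
               dimnames = list(classes, colnames(features)))
  pooled <- matrix(0, d, d)
  for (k in seq_along(classes)) {
    xk <- features[labels == classes[k], , drop = FALSE]
    mu[k, ] <- colMeans(xk)
    pooled <- pooled + crossprod(sweep(xk, 2L, mu[k, ]))
  }
  pooled <- pooled / (nrow(features) - length(classes))
  ev <- eigen(pooled, symmetric = TRUE, only.values = TRUE)$values
  shrinkage <- min(ev) <= 0 ||
    max(ev) / max(min(ev), .Machine$double.eps) > 1e10
  if (shrinkage) {
    delta <- 1e-6 * sum(diag(pooled)) / d
    if (delta <= 0) delta <- 1e-8
    pooled <- pooled + diag(delta, d)
    if (warn) {
      warning("fit_lda: ill-conditioned pooled covariance; diagonal shrinkage applied")
    }
  }
  if (is.null(priors)) {
    priors <- as.numeric(counts) / length(labels)
    names(priors) <- classes
  } else {
    priors <- priors[classes] / sum(priors[classes])
  }
  structure(list(classes = classes, means = mu, cov = pooled,
                 cov_inv = solve(pooled), priors = priors, d = d,
                 shrinkage = shrinkage),
            class = "actcap_lda")
}

#' Posterior class probabilities under an LDA model
#'
#' @param model an \code{"actcap_lda"}.
#' @param features numeric matrix or vector of observations.
#' @return matrix (samples x classes) of posteriors summing to 1 per row.
#' @export
lda_posterior <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(x) != model$d) stop("lda_posterior: feature-length mismatch")
  # log discriminant: x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log prior
  scores <- matrix(0, nrow(x), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (k in seq_along(model$classes)) {
    m <- model$means[k, ]
    sm <- model$cov_inv %*% m
    scores[, k] <- x %*% sm - 0.5 * drop(crossprod(m, sm)) +
      log(model$priors[k])
  }
  scores <- scores - apply(scores, 1L, max)
  p <- exp(scores)
  p / rowSums(p)
}

#' Predict class labels under an LDA model
#'
#' @inheritParams lda_posterior
#' @return character vector of predicted labels; posterior ties go to the
#'   lexicographically first class.
#' @export
predict_lda <- function(model, features) {
  p <- lda_posterior(model, features)
  # which.max returns the first maximum; classes are sorted lexicographically
  model$classes[apply(p, 1L, which.max)]
}

#' Cascade configuration
#'
#' @param n_trees random-forest ensemble size (default 250).
#' @param subsample_fraction fraction of the training data drawn without
#'   replacement per tree (default 0.85).
#' @param rejection_prior_ratio class-weight ratio favoring the rejection
#'   class (default 2, i.e. 2:1 against each activity class).
#' @param reject_confidence stage-1 posterior above which a rejection is
#'   immediate (default 0.7); below it the sample is reconsidered by the
#'   closed-world LDA and the activity-specific binary LDA.
#' @param tree_max_depth depth limit of each tree (default 5).
#' @param features_per_split variables tried per split (default
#'   \code{ceiling(sqrt(39))}).
#' @param seed RNG seed for forest training.
#' @return list of class \code{"actcap_cascade_config"}.
#' @export
cascade_config <- function(n_trees = 250L, subsample_fraction = 0.85,
                           rejection_prior_ratio = 2,
                           reject_confidence = 0.7,
                           tree_max_depth = 5L,
                           features_per_split = ceiling(sqrt(39)),
                           seed = 1L) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1,
            reject_confidence > 0, reject_confidence < 1,
            rejection_prior_ratio > 0, n_trees >= 1)
  structure(as.list(environment()), class = "actcap_cascade_config")
}

#' Train the three-stage cascade with rejection
#'
#' Stage 1 is a random forest over the seven classes (six activities plus
#' the rejection class) of depth-limited trees, each grown on a random
#' subsample drawn without replacement; class weights favor the rejection
#' class with the configured ratio both in tree growing and in posterior
#' aggregation. Stage 2 is a closed-world six-class LDA trained on the
#' activity classes only. Stage 3 is one binary LDA per activity class
#' (class k vs rejection).
#'
#' @param features numeric matrix (samples x features).
#' @param labels character labels covering all six activities and at least
#'   one \code{"REJECT"} example.
#' @param config an \code{"actcap_cascade_config"}.
#' @return object of class \code{"actcap_cascade"}.
#' @export
train_cascade <- function(features, labels, config = cascade_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  missing <- setdiff(ACTIVITIES, labels)
  if (length(missing)) {
    stop("train_cascade: missing classes: ", paste(missing, collapse = ", "))
  }
  if (!REJECT_LABEL %in% labels) {
    warning("train_cascade: no rejection examples; the cascade will never reject")
  }
  needed <- c(ACTIVITIES, intersect(REJECT_LABEL, unique(labels)))
  cls <- factor(labels, levels = needed)
  w <- stats::setNames(rep(1, length(needed)), needed)
  w[REJECT_LABEL] <- config$rejection_prior_ratio
  df <- as.data.frame(features)
  feat_names <- colnames(df)
  df$.class <- cls
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = config$n_trees,
    sample.fraction = config$subsample_fraction, replace = FALSE,
    max.depth = config$tree_max_depth,
    mtry = min(config$features_per_split, ncol(features)),
    class.weights = as.numeric(w[levels(cls)]),
    probability = TRUE, seed = config$seed, num.threads = 1L)
  act_idx <- labels %in% ACTIVITIES
  stage2 <- fit_lda(features[act_idx, , drop = FALSE], labels[act_idx], warn = FALSE)
  stage3 <- list()
  for (a in ACTIVITIES) {
    idx <- labels %in% c(a, REJECT_LABEL)
    # the binary reconsideration model needs at least 2 examples per class;
    # with fewer rejection examples it is omitted and the stage-2 label
    # is accepted as-is at prediction time
    tab3 <- table(factor(labels[idx], levels = c(a, REJECT_LABEL)))
    stage3[[a]] <- if (all(tab3 >= 2L)) {
      fit_lda(features[idx, , drop = FALSE], labels[idx], warn = FALSE)
    } else NULL
  }
  structure(list(stage1 = forest, stage2 = stage2, stage3 = stage3,
                 class_weights = w, feature_names = feat_names,
                 config = config),
            class = "actcap_cascade")
}

#' @export
print.actcap_cascade <- function(x, ...) {
  cat(sprintf("<actcap_cascade> %d-tree forest + 6-class LDA + 6 binary LDAs (%d features)\n",
              x$config$n_trees, length(x$feature_names)))
  invisible(x)
}

# stage-1 posterior over the 7 classes, rejection-prior-weighted
stage1_posterior <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(x) != length(model$feature_names)) {
    stop("predict_cascade: feature-length mismatch")
  }
  colnames(x) <- model$feature_names
  p <- stats::predict(model$stage1, data = as.data.frame(x),
                      num.threads = 1L)$predictions
  p <- sweep(p, 2L, as.numeric(model$class_weights[colnames(p)]), `*`)
  p / rowSums(p)
}

#' Predict with the cascade
#'
#' A sample whose stage-1 posterior argmax is an activity gets that label.
#' Otherwise, if the rejection posterior exceeds \code{reject_confidence} it
#' is immediately rejected; otherwise the closed-world LDA proposes a
#' tentative activity and the corresponding activity-vs-rejection binary
#' LDA makes the final acceptance or rejection.
#'
#' @param model an \code{"actcap_cascade"}.
#' @param features numeric matrix or vector of recognition features.
#' @return character vector of labels in
#'   \code{c(activity_classes(), "REJECT")}.
#' @export
predict_cascade <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1L) else as.matrix(features)
  p <- stage1_posterior(model, x)
  out <- character(nrow(x))
  for (r in seq_len(nrow(x))) {
    top <- colnames(p)[which.max(p[r, ])]
    if (top != REJECT_LABEL) {
      out[r] <- top
    } else if (p[r, REJECT_LABEL] > model$config$reject_confidence) {
      out[r] <- REJECT_LABEL
    } else {
      tentative <- predict_lda(model$stage2, x[r, ])
      out[r] <- if (is.null(model$stage3[[tentative]])) tentative else
        predict_lda(model$stage3[[tentative]], x[r, ])
    }
  }
  out
}
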