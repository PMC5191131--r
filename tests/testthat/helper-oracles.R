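# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately naive: correctness over speed.

# Exhaustive DTW: enumerate every monotone warping path from (1,1) to
# (N,M) with steps (+1,0), (0,1), (+1,+1) and return the minimal
# accumulated local cost. Exponential; use only for lengths <= ~7.
brute_dtw_cost <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X); M <- nrow(Y)
  local <- function(i, j) sum((X[i, ] - Y[j, ])^2)
  rec <- function(i, j) {
    c0 <- local(i, j)
    if (i == N && j == M) return(c0)
    best <- Inf
    if (i < N) best <- min(best, rec(i + 1L, j))
    if (j < M) best <- min(best, rec(i, j + 1L))
    if (i < N && j < M) best <- min(best, rec(i + 1L, j + 1L))
    c0 + best
  }
  rec(1L, 1L)
}

# Exhaustive LP: enumerate all basic solutions of min c'x, Ax = b, x >= 0
# and return the smallest feasible objective. Only for tiny instances.
lp_vertex_minimum <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  best <- Inf
  combos <- utils::combn(n, m)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    B <- A[, idx, drop = FALSE]
    x <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x)) || any(x < -tol)) next
    best <- min(best, sum(cvec[idx] * pmax(x, 0)))
  }
  best
}

# Reference objective of the ICS linear program via exhaustive vertex
# enumeration of the equality form: variables
# (v+, v-, b+, b-, eps, surplus) >= 0 with constraints
# y .* (Acum (v+ - v-) + (b+ - b-)) + eps - surplus = 1.
# Only for tiny instances (n <= 5, few bins).
ics_vertex_objective <- function(Z, y, bin_counts, gamma, theta = NULL) {
  R <- sum(bin_counts)
  n <- nrow(Z)
  if (is.null(theta)) theta <- rep(1, R)
  Acum <- actcap:::cumulative_design(Z, bin_counts)
  YA <- Acum * y
  A <- cbind(YA, -YA, y, -y, diag(n), -diag(n))
  cvec <- c(theta, theta, 0, 0, rep(gamma, n), rep(0, n))
  lp_vertex_minimum(cvec, A, rep(1, n))
}

# Cohort cache shared across test files (test_dir runs in one process).
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n_subjects, seed = 1L) {
  key <- sprintf("n%d_s%d", n_subjects, seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      protocol_config(n_subjects = n_subjects, seed = seed))
  }
  .cohort_cache[[key]]
}

# A clean synthetic repetition burst (no noise) for feature tests.
clean_burst <- function(activity, seconds = 8, fs = 32, seed = 1) {
  set.seed(seed)
  n <- round(seconds * fs)
  actcap:::activity_burst(activity, n, amp_mult = 1)
}
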