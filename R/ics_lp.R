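# Revised simplex for LPs in equality standard form:
#   min c'x  s.t.  A x = b,  x >= 0
# given an initial feasible basis (1-based column indices). Thin wrapper
# over the compiled core (Dantzig pricing with a permanent switch to
# Bland's rule after a degeneracy stall, which guarantees termination).
simplex_solve <- function(cvec, A, b, basis, max_iter = 20000L, tol = 1e-9) {
  stopifnot(length(basis) == nrow(A))
  res <- .simplex_core(cvec, A, b, as.integer(basis),
                       as.integer(max_iter), tol)
  res$x <- if (is.null(res$x)) NULL else drop(res$x)
  res
}

# Cumulative-sum design: Z is one-hot over bins; column (p, j) of the result
# indicates bin_index(i, p) >= j, so Z w = A_cum v with v the anchored
# per-variable weight differences.
cumulative_design <- function(Z, bin_counts) {
  n <- nrow(Z)
  Acum <- matrix(0, n, sum(bin_counts))
  off <- 0L
  for (p in seq_along(bin_counts)) {
    B <- bin_counts[p]
    block <- Z[, off + seq_len(B), drop = FALSE]
    # reverse cumulative sum across bins
    rc <- t(apply(block[, rev(seq_len(B)), drop = FALSE], 1L, cumsum))
    Acum[, off + seq_len(B)] <- rc[, rev(seq_len(B)), drop = FALSE]
    off <- off + B
  }
  Acum
}

# v (anchored differences) -> bin weights w by per-variable cumulative sum
diffs_to_weights <- function(v, bin_counts) {
  off <- 0L
  w <- numeric(length(v))
  for (p in seq_along(bin_counts)) {
    B <- bin_counts[p]
    w[off + seq_len(B)] <- cumsum(v[off + seq_len(B)])
    off <- off + B
  }
  w
}

#' Anchored difference matrix of a binning scheme
#'
#' For variable p with bin weights \eqn{w_{p,1..B_p}}, the matrix has one
#' anchoring row \eqn{w_{p,1}} and rows \eqn{w_{p,j+1} - w_{p,j}}. The
#' anchor ensures a constant per-variable offset is penalized (otherwise it
#' could hide in the bins instead of the bias and a variable could never
#' reach the all-zero state that allows discarding it).
#'
#' @param bin_counts integer vector of bins per variable.
#' @return sparse-pattern dense matrix D with \code{sum(bin_counts)} rows
#'   and columns.
#' @export
make_difference_matrix <- function(bin_counts) {
  R <- sum(bin_counts)
  D <- matrix(0, R, R)
  off <- 0L
  for (p in seq_along(bin_counts)) {
    B <- bin_counts[p]
    D[off + 1L, off + 1L] <- 1
    for (j in seq_len(B - 1L)) {
      D[off + j + 1L, off + j] <- -1
      D[off + j + 1L, off + j + 1L] <- 1
    }
    off <- off + B
  }
  D
}

#' Solve the core interval-coded-scoring optimization
#'
#' Finds the global optimum of the linear program
#' \deqn{\min_{w,b,\varepsilon} \sum_r \theta_r |(Dw)_r| +
#'   \gamma \sum_n \varepsilon_n \quad \mathrm{s.t.}\quad
#'   y_n (z_n^\top w + b) \ge 1 - \varepsilon_n,\ \varepsilon \ge 0}
#' where D is the anchored difference matrix of the binning scheme (see
#' [make_difference_matrix()]): hinge-loss classification with total
#' variation minimization on the bin weights in place of margin
#' maximization. Internally the problem is reparameterized in the weight
#' differences \eqn{v = Dw} (an L1-penalized hinge LP with one equality row
#' per sample) and solved exactly by a revised simplex.
#'
#' @param Z binary one-hot matrix (samples x total bins).
#' @param y labels in \{-1, +1\}.
#' @param bin_counts bins per variable; \code{sum(bin_counts) == ncol(Z)}.
#' @param gamma non-negative error-cost hyperparameter.
#' @param theta optional per-row penalty weights on \eqn{|Dw|} (all ones by
#'   default; used by the iterative reweighting).
#' @return object of class \code{"actcap_ics_solution"}: bin weights
#'   \code{w}, differences \code{v} (= Dw), bias \code{b}, slacks
#'   \code{eps}, \code{gamma}, \code{objective}, \code{theta},
#'   \code{bin_counts}.
#' @export
solve_ics_core <- function(Z, y, bin_counts, gamma, theta = NULL) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  n <- nrow(Z)
  R <- sum(bin_counts)
  stopifnot(ncol(Z) == R, length(y) == n, all(y %in% c(-1, 1)), gamma >= 0)
  if (is.null(theta)) theta <- rep(1, R)
  stopifnot(length(theta) == R, all(theta >= 0))
  Acum <- cumulative_design(Z, bin_counts)
  # columns: v+ (R), v- (R), b+, b-, eps (n), surplus (n)
  YA <- Acum * y
  A <- cbind(YA, -YA, y, -y, diag(n), -diag(n))
  cvec <- c(theta, theta, 0, 0, rep(gamma, n), rep(0, n))
  b <- rep(1, n)
  basis <- 2L * R + 2L + seq_len(n)  # eps columns: identity, feasible at eps = 1
  sol <- simplex_solve(cvec, A, b, basis)
  if (sol$status != "optimal") {
    stop("solve_ics_core: LP solver status '", sol$status, "'")
  }
  x <- sol$x
  v <- x[seq_len(R)] - x[R + seq_len(R)]
  bb <- x[2L * R + 1L] - x[2L * R + 2L]
  w <- diffs_to_weights(v, bin_counts)
  eps <- pmax(0, 1 - y * (drop(Acum %*% v) + bb))
  structure(list(w = w, v = v, b = bb, eps = eps, gamma = gamma,
                 objective = sum(theta * abs(v)) + gamma * sum(eps),
                 theta = theta, bin_counts = bin_counts),
            class = "actcap_ics_solution")
}

#' @export
print.actcap_ics_solution <- function(x, ...) {
  cat(sprintf("<actcap_ics_solution> %d bins over %d variables; gamma = %g; objective = %g; %d nonzero differences\n",
              length(x$w), length(x$bin_counts), x$gamma, x$objective,
              sum(abs(x$v) > 1e-8)))
  invisible(x)
}
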