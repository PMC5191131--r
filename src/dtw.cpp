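#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dynamic time warping of two multichannel sequences.
// X is N x C, Y is M x C. Local cost at (i, j) is the squared Euclidean
// distance over channels; the accumulated cost uses the standard
// diagonal/horizontal/vertical step pattern with boundary conditions
// (1,1) -> (N,M). band < 0 disables the Sakoe-Chiba constraint.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix X, NumericMatrix Y, int band) {
  const int N = X.nrow(), M = Y.nrow(), C = X.ncol();
  if (Y.ncol() != C) stop("channel count mismatch");
  if (N < 1 || M < 1) stop("empty sequence");
  const double INF = std::numeric_limits<double>::infinity();
  int eff_band = band;
  if (band >= 0 && eff_band < std::abs(N - M)) eff_band = std::abs(N - M);

  std::vector<double> D((size_t)N * M, INF);
  auto at = [&](int i, int j) -> double& { return D[(size_t)i * M + j]; };

  for (int i = 0; i < N; ++i) {
    int jlo = 0, jhi = M - 1;
    if (band >= 0) {
      jlo = std::max(0, i - eff_band);
      jhi = std::min(M - 1, i + eff_band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = 0.0;
      for (int c = 0; c < C; ++c) {
        double diff = X(i, c) - Y(j, c);
        d += diff * diff;
      }
      if (i == 0 && j == 0) {
        at(i, j) = d;
      } else {
        double best = INF;
        if (i > 0 && j > 0 && at(i - 1, j - 1) < best) best = at(i - 1, j - 1);
        if (i > 0 && at(i - 1, j) < best) best = at(i - 1, j);
        if (j > 0 && at(i, j - 1) < best) best = at(i, j - 1);
        at(i, j) = d + best;
      }
    }
  }

  // Backtrack; ties broken diagonal > horizontal (i-1) > vertical (j-1)
  std::vector<int> pi, pj;
  int i = N - 1, j = M - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double dd = (i > 0 && j > 0) ? at(i - 1, j - 1) : INF;
    double dh = (i > 0) ? at(i - 1, j) : INF;
    double dv = (j > 0) ? at(i, j - 1) : INF;
    if (dd <= dh && dd <= dv) { --i; --j; }
    else if (dh <= dv) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["cost"] = at(N - 1, M - 1),
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}
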