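#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// symmetric2 DTW under a Sakoe-Chiba band for one pair of equal-length
// series; returns the cumulative (unnormalized) cost. T is expected to be
// tiny (4-5), so a dense T*T workspace is used.
static double dtw_cost(const double* a, const double* b, int T, int window,
                       bool squared, std::vector<double>& acm) {
  const double INF = R_PosInf;
  std::fill(acm.begin(), acm.begin() + (size_t)T * T, INF);
  for (int i = 0; i < T; ++i) {
    int jlo = i - window < 0 ? 0 : i - window;
    int jhi = i + window >= T ? T - 1 : i + window;
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(a[i] - b[j]);
      if (squared) c *= c;
      if (i == 0 && j == 0) { acm[0] = 2.0 * c; continue; }
      double best = INF;
      if (i > 0 && j > 0) {
        double v = acm[(size_t)(i - 1) * T + (j - 1)] + 2.0 * c;
        if (v < best) best = v;
      }
      if (i > 0) {
        double v = acm[(size_t)(i - 1) * T + j] + c;
        if (v < best) best = v;
      }
      if (j > 0) {
        double v = acm[(size_t)i * T + (j - 1)] + c;
        if (v < best) best = v;
      }
      acm[(size_t)i * T + j] = best;
    }
  }
  return acm[(size_t)T * T - 1];
}

//' Normalized symmetric2 DTW cost of one pair of series (compiled kernel)
//'
//' @param a,b equal-length numeric vectors.
//' @param window Sakoe-Chiba band half-width.
//' @param squared use squared local cost instead of absolute difference.
//' @return list with cumulative and normalized cost.
//' @keywords internal
// [[Rcpp::export]]
List dtwCostCpp(NumericVector a, NumericVector b, int window = 1,
                bool squared = false) {
  int T = a.size();
  if (b.size() != T) stop("series must have equal length");
  for (int i = 0; i < T; ++i)
    if (!R_finite(a[i]) || !R_finite(b[i]))
      stop("series must be finite with no missing values");
  if (window < 0) stop("window must be non-negative");
  std::vector<double> acm((size_t)T * T);
  double cost = dtw_cost(REAL(a), REAL(b), T, window, squared, acm);
  return List::create(_["cumulativeCost"] = cost,
                      _["normalizedDistance"] = cost / (2.0 * T));
}

//' All pairwise normalized DTW distances among the columns of a series matrix
//'
//' @param z T x P matrix: column p holds the standardized scores of item p
//'   over the participant's T complete waves.
//' @param window Sakoe-Chiba band half-width (default 1).
//' @param squared use squared local cost instead of absolute difference.
//' @return symmetric P x P matrix of normalized distances, zero diagonal.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix dtwPairwiseCpp(NumericMatrix z, int window = 1,
                             bool squared = false) {
  int T = z.nrow(), P = z.ncol();
  if (window < 0) stop("window must be non-negative");
  for (int i = 0; i < T * P; ++i)
    if (!R_finite(z[i])) stop("series must be finite with no missing values");
  NumericMatrix D(P, P);
  std::vector<double> acm((size_t)T * T);
  const double* base = REAL(z);
  for (int p = 0; p < P; ++p) {
    for (int q = p + 1; q < P; ++q) {
      double cost = dtw_cost(base + (size_t)p * T, base + (size_t)q * T,
                             T, window, squared, acm);
      double d = cost / (2.0 * T);
      D(p, q) = d;
      D(q, p) = d;
    }
  }
  return D;
}
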