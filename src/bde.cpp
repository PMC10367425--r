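#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Log marginal likelihood of one node's family under the BDeu prior.
// x holds 0-based state codes, one column per variable; the Dirichlet
// pseudo-counts are ess/q per parent configuration and ess/(q*r) per cell.
// [[Rcpp::export]]
double bde_family_score_cpp(const IntegerMatrix& x, int node,
                            const IntegerVector& parents,
                            const IntegerVector& arity, double ess) {
  const int n = x.nrow();
  const int r = arity[node];
  const int np = parents.size();

  long long q = 1;
  std::vector<long long> stride(np);
  for (int p = 0; p < np; ++p) {
    stride[p] = q;
    q *= arity[parents[p]];
    if (q > 1000000LL) stop("parent configuration count overflow (q > 1e6)");
  }

  std::vector<int> njk((size_t)(q * r), 0);
  for (int i = 0; i < n; ++i) {
    long long j = 0;
    for (int p = 0; p < np; ++p) j += (long long)x(i, parents[p]) * stride[p];
    ++njk[(size_t)(j * r + x(i, node))];
  }

  const double aij = ess / (double)q;
  const double aijk = ess / ((double)q * r);
  const double lg_aij = std::lgamma(aij);
  const double lg_aijk = std::lgamma(aijk);

  double score = 0.0;
  for (long long j = 0; j < q; ++j) {
    int nij = 0;
    double s = 0.0;
    for (int k = 0; k < r; ++k) {
      const int c = njk[(size_t)(j * r + k)];
      nij += c;
      s += std::lgamma(aijk + c) - lg_aijk;
    }
    if (nij > 0) score += lg_aij - std::lgamma(aij + nij) + s;
  }
  return score;
}
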