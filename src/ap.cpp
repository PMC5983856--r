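#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affinity-propagation message passing: damped responsibility /
// availability updates until the exemplar set is stable for `convits`
// consecutive iterations (with at least one exemplar) or `maxit` is hit.
// [[Rcpp::export(name = ".ap_run")]]
List ap_run(NumericMatrix S, double lambda, int maxit, int convits) {
  const int n = S.nrow();
  NumericMatrix A(n, n), R(n, n);
  std::vector<int> e(n, -1);
  int unchanged = 0, it = 0;
  bool converged = false;

  for (it = 1; it <= maxit; ++it) {
    // responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    for (int i = 0; i < n; ++i) {
      double m1 = -INFINITY, m2 = -INFINITY;
      int k1 = -1;
      for (int k = 0; k < n; ++k) {
        const double v = A(i, k) + S(i, k);
        if (v > m1) { m2 = m1; m1 = v; k1 = k; }
        else if (v > m2) { m2 = v; }
      }
      for (int k = 0; k < n; ++k) {
        const double rnew = S(i, k) - (k == k1 ? m2 : m1);
        R(i, k) = lambda * R(i, k) + (1.0 - lambda) * rnew;
      }
    }
    // availabilities: a(i,k) = min(0, r(k,k) + sum_{i' != i,k} max(0, r(i',k)))
    //                 a(k,k) = sum_{i' != k} max(0, r(i',k))
    for (int k = 0; k < n; ++k) {
      double sum = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k) sum += std::max(0.0, R(i, k));
      for (int i = 0; i < n; ++i) {
        double anew;
        if (i == k) anew = sum;
        else anew = std::min(0.0, R(k, k) + sum - std::max(0.0, R(i, k)));
        A(i, k) = lambda * A(i, k) + (1.0 - lambda) * anew;
      }
    }
    // exemplar indicator and convergence bookkeeping
    bool same = true;
    int count = 0;
    for (int i = 0; i < n; ++i) {
      const int ex = (A(i, i) + R(i, i)) > 0.0 ? 1 : 0;
      if (ex != e[i]) same = false;
      e[i] = ex;
      count += ex;
    }
    if (same) {
      if (++unchanged >= convits && count > 0) { converged = true; break; }
    } else {
      unchanged = 0;
    }
  }

  LogicalVector is_exemplar(n);
  for (int i = 0; i < n; ++i) is_exemplar[i] = e[i] > 0;
  return List::create(_["is_exemplar"] = is_exemplar,
                      _["iterations"] = std::min(it, maxit),
                      _["converged"] = converged);
}
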