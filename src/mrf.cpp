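#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact sum-product on a rooted tree-structured Markov random field with a
// discrete per-node state space of size k.  States that are clamped (observed)
// are encoded by setting `allowed` to FALSE for the excluded states.  All
// arithmetic is in the log domain so the partition function can never
// overflow; -Inf marks impossible states.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static double lsevec(const double *x, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (m == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// parent: 1-based parent index per node, 0 for the root
// postorder: 1-based node indices, children before parents, root last
// node_pot: n x k log-potentials (clamping handled via `allowed`)
// edge_pot: k x k x n array; slice v holds the log edge potential between
//           parent(v) (rows) and v (cols); the root slice is ignored
// allowed:  n x k, 1 if the node may occupy the state
// [[Rcpp::export]]
double mrf_logZ_cpp(IntegerVector parent, IntegerVector postorder,
                    NumericMatrix node_pot, NumericVector edge_pot,
                    IntegerMatrix allowed) {
  const int n = node_pot.nrow(), k = node_pot.ncol();
  // acc[v*k + s] accumulates node potential + messages from children
  std::vector<double> acc(n * k);
  for (int v = 0; v < n; ++v)
    for (int s = 0; s < k; ++s)
      acc[v * k + s] = allowed(v, s) ? node_pot(v, s) : R_NegInf;

  std::vector<double> tmp(k);
  for (int i = 0; i < n; ++i) {
    int v = postorder[i] - 1;
    int p = parent[v] - 1;
    if (p < 0) { // root: close the recursion
      for (int s = 0; s < k; ++s) tmp[s] = acc[v * k + s];
      return lsevec(tmp.data(), k);
    }
    const double *ep = &edge_pot[(std::size_t)v * k * k];
    for (int sp = 0; sp < k; ++sp) {
      double m = R_NegInf;
      for (int sc = 0; sc < k; ++sc) {
        double val = acc[v * k + sc];
        if (val == R_NegInf) continue;
        m = lse2(m, val + ep[sp + k * sc]);
      }
      acc[p * k + sp] += m; // message from v into its parent
    }
  }
  stop("postorder did not terminate at the root");
  return NA_REAL; // unreachable
}

// Upward pass returning, besides log Z, the downward sampling tables:
// cond[v, sp, sc] = P(state(v) = sc | state(parent(v)) = sp, evidence below v)
// and the root posterior.  Used by the exact ancestral sampler.
// [[Rcpp::export]]
List mrf_messages_cpp(IntegerVector parent, IntegerVector postorder,
                      NumericMatrix node_pot, NumericVector edge_pot,
                      IntegerMatrix allowed) {
  const int n = node_pot.nrow(), k = node_pot.ncol();
  std::vector<double> acc(n * k);
  for (int v = 0; v < n; ++v)
    for (int s = 0; s < k; ++s)
      acc[v * k + s] = allowed(v, s) ? node_pot(v, s) : R_NegInf;

  NumericVector cond(n * k * k); // [v + n*sp + n*k*sc]
  NumericVector root_dist(k);
  double logZ = NA_REAL;
  std::vector<double> tmp(k);

  for (int i = 0; i < n; ++i) {
    int v = postorder[i] - 1;
    int p = parent[v] - 1;
    if (p < 0) {
      for (int s = 0; s < k; ++s) tmp[s] = acc[v * k + s];
      logZ = lsevec(tmp.data(), k);
      for (int s = 0; s < k; ++s)
        root_dist[s] = (logZ == R_NegInf) ? NA_REAL : std::exp(tmp[s] - logZ);
      break;
    }
    const double *ep = &edge_pot[(std::size_t)v * k * k];
    for (int sp = 0; sp < k; ++sp) {
      for (int sc = 0; sc < k; ++sc) {
        double val = acc[v * k + sc];
        tmp[sc] = (val == R_NegInf) ? R_NegInf : val + ep[sp + k * sc];
      }
      double msg = lsevec(tmp.data(), k);
      for (int sc = 0; sc < k; ++sc)
        cond[v + (std::size_t)n * sp + (std::size_t)n * k * sc] =
          (msg == R_NegInf) ? NA_REAL : std::exp(tmp[sc] - msg);
      acc[p * k + sp] += msg;
    }
  }
  cond.attr("dim") = IntegerVector::create(n, k, k);
  return List::create(_["logZ"] = logZ, _["cond"] = cond,
                      _["root_dist"] = root_dist);
}
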