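#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// k-NN information-theoretic estimators with the Chebyshev (max) norm.
// Brute-force neighbour search over raw column pointers: the package caps
// embedding-vector counts at a few thousand, where O(n^2) with tight inner
// loops beats tree construction for the d <= 3 spaces used here.
//
// All estimators apply a Theiler exclusion window: points closer than
// `theiler` in original sample time (vector `tidx`) are excluded from
// neighbour searches and range counts, so serially correlated embedding
// vectors do not masquerade as independent recurrences.

namespace {

struct KHeap {
  std::vector<double> v;
  int k, filled;
  explicit KHeap(int k_) : v((size_t) k_), k(k_), filled(0) {}
  void reset() { filled = 0; }
  inline void push(double d) {
    if (filled < k) {
      v[filled++] = d;
      if (filled == k) std::make_heap(v.begin(), v.end());
    } else if (d < v.front()) {
      std::pop_heap(v.begin(), v.end());
      v[k - 1] = d;
      std::push_heap(v.begin(), v.end());
    }
  }
  inline double top() const { return v.front(); }
  inline bool full() const { return filled == k; }
};

// Chebyshev distance between rows i and j given column pointers
inline double cheb(const std::vector<const double*>& cols, int i, int j) {
  double m = 0.0;
  for (size_t c = 0; c < cols.size(); ++c) {
    double v = std::fabs(cols[c][i] - cols[c][j]);
    if (v > m) m = v;
  }
  return m;
}

inline std::vector<const double*> col_ptrs(const NumericMatrix& X) {
  std::vector<const double*> p((size_t) X.ncol());
  for (int c = 0; c < X.ncol(); ++c) p[c] = &X(0, c);
  return p;
}

} // namespace

// Kozachenko-Leonenko differential entropy (nats), Chebyshev norm:
// H = psi(N_eff) - psi(k) + d * mean(log(2 * eps_i)),
// where N_eff is one plus the average number of admissible neighbours.
// [[Rcpp::export(name = ".kl_entropy_cpp")]]
double kl_entropy_cpp(NumericMatrix X, int k, IntegerVector tidx,
                      int theiler) {
  const int n = X.nrow(), d = X.ncol();
  if (n <= k) stop("need more points than neighbours");
  if (tidx.size() != n) stop("tidx length mismatch");
  const std::vector<const double*> cols = col_ptrs(X);
  const int* tt = &tidx[0];
  KHeap heap(k);
  double acc = 0.0, n_adm = 0.0;
  int used = 0;
  for (int i = 0; i < n; ++i) {
    heap.reset();
    int adm = 0;
    const int ti = tt[i];
    for (int j = 0; j < n; ++j) {
      if (j == i || std::abs(ti - tt[j]) < theiler) continue;
      ++adm;
      heap.push(cheb(cols, i, j));
    }
    if (!heap.full()) continue; // too few admissible neighbours
    double e = heap.top();
    if (e <= 0) e = 1e-300;
    acc += std::log(2.0 * e);
    n_adm += adm;
    ++used;
  }
  if (used == 0) stop("no points with enough admissible neighbours");
  return R::digamma(n_adm / used + 1.0) - R::digamma((double) k) +
    d * acc / used;
}

// Frenzel-Pompe / KSG-style conditional mutual information I(X;Y|Z) (nats)
// for scalar X, Y, Z (the package embeds one lag per signal):
// eps_i = distance to the k-th admissible neighbour in the joint space;
// I = psi(k) + mean( psi(n_z+1) - psi(n_xz+1) - psi(n_yz+1) )
// with strict-inequality range counts over admissible points.
// [[Rcpp::export(name = ".ksg_cmi_cpp")]]
double ksg_cmi_cpp(NumericVector x, NumericVector y, NumericVector z, int k,
                   IntegerVector tidx, int theiler) {
  const int n = x.size();
  if (y.size() != n || z.size() != n) stop("length mismatch");
  if (n <= k) stop("need more points than neighbours");
  if (tidx.size() != n) stop("tidx length mismatch");
  const double* xp = &x[0];
  const double* yp = &y[0];
  const double* zp = &z[0];
  const int* tt = &tidx[0];

  std::vector<double> ddx((size_t) n), ddy((size_t) n), ddz((size_t) n);
  std::vector<char> adm((size_t) n);
  KHeap heap(k);
  double acc = 0.0;
  int used = 0;
  for (int i = 0; i < n; ++i) {
    heap.reset();
    const double xi = xp[i], yi = yp[i], zi = zp[i];
    const int ti = tt[i];
    for (int j = 0; j < n; ++j) {
      if (j == i || std::abs(ti - tt[j]) < theiler) {
        adm[j] = 0;
        continue;
      }
      adm[j] = 1;
      const double vx = std::fabs(xi - xp[j]);
      const double vy = std::fabs(yi - yp[j]);
      const double vz = std::fabs(zi - zp[j]);
      ddx[j] = vx; ddy[j] = vy; ddz[j] = vz;
      double joint = vx > vy ? vx : vy;
      if (vz > joint) joint = vz;
      heap.push(joint);
    }
    if (!heap.full()) continue;
    const double eps = heap.top();
    int n_xz = 0, n_yz = 0, n_z = 0;
    for (int j = 0; j < n; ++j) {
      if (adm[j] && ddz[j] < eps) {
        ++n_z;
        if (ddx[j] < eps) ++n_xz;
        if (ddy[j] < eps) ++n_yz;
      }
    }
    acc += R::digamma(n_z + 1.0) - R::digamma(n_xz + 1.0) -
      R::digamma(n_yz + 1.0);
    ++used;
  }
  if (used == 0) stop("no points with enough admissible neighbours");
  return R::digamma((double) k) + acc / used;
}

// Sample-entropy template-match counts: templates are rows of T (m+1 columns,
// already lag-embedded and restricted to admissible windows). Returns
// c(A, B): B = pairs matching on the first m columns within tolerance r,
// A = pairs also matching on column m+1 (Chebyshev, self-pairs and pairs
// closer than `theiler` in time excluded).
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericMatrix T, int m, double r,
                                IntegerVector tidx, int theiler) {
  const int n = T.nrow(), d = T.ncol();
  if (d != m + 1) stop("template width must be m+1");
  if (tidx.size() != n) stop("tidx length mismatch");
  const std::vector<const double*> cols = col_ptrs(T);
  const int* tt = &tidx[0];
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(tt[i] - tt[j]) < theiler) continue;
      double dm = 0.0;
      for (int c = 0; c < m; ++c) {
        double v = std::fabs(cols[c][i] - cols[c][j]);
        if (v > dm) dm = v;
      }
      if (dm <= r) {
        B += 1.0;
        double v = std::fabs(cols[m][i] - cols[m][j]);
        if ((v > dm ? v : dm) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Greedy minimum-gap subsampling of a sorted index vector.
// [[Rcpp::export(name = ".thin_gap_cpp")]]
IntegerVector thin_gap_cpp(IntegerVector idx, int min_gap) {
  const int n = idx.size();
  std::vector<int> out;
  out.reserve((size_t) n);
  bool have_last = false;
  int last = 0;
  for (int i = 0; i < n; ++i) {
    if (!have_last || idx[i] - last >= min_gap) {
      out.push_back(idx[i]);
      last = idx[i];
      have_last = true;
    }
  }
  return wrap(out);
}
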