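// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// Tie-averaged ranks (matches base R rank(x, ties.method = "average")).
// `ord` is caller-provided scratch of length n.
static void rank_avg_into(const double* x, int n, int* ord, double* r) {
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord, ord + n, [x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    const double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

static arma::vec rank_avg(const arma::vec& x) {
  const int n = (int)x.n_elem;
  std::vector<int> ord(n);
  arma::vec r(n);
  rank_avg_into(x.memptr(), n, ord.data(), r.memptr());
  return r;
}

// Searchlight partial-Spearman fit map for one subject.
//
// X: trials x vertices x time source amplitudes (passed flat, dims attached).
// nb: per-vertex spatial searchlight members (1-based vertex indices,
//     self included); halfwin: temporal radius in samples.
// mresid: residualized, mean-zero, unit-norm model ranks over the
//     column-wise lower triangle of the trial x trial distance matrix.
// Q: orthonormal basis (intercept + covariate ranks) to project out of the
//     data ranks, n_pairs x k.
//
// Per center: member amplitudes are flattened per trial, the data RDM is
// 1 - Pearson between trial vectors (zero-variance vectors give distance 1),
// the lower triangle is tie-rank-transformed, residualized on Q, and
// correlated with mresid. Centers are independent; evaluation order cannot
// affect the result.
// [[Rcpp::export]]
arma::mat sl_fit_map_cpp(NumericVector X, List nb, int halfwin,
                         const arma::vec& mresid, const arma::mat& Q) {
  IntegerVector dims = X.attr("dim");
  const int n_trials = dims[0], n_vert = dims[1], n_time = dims[2];
  const double* xp = X.begin();
  const int P = n_trials * (n_trials - 1) / 2;
  arma::mat out(n_vert, n_time);
  const arma::mat Qt = Q.t();

  std::vector<std::vector<int>> nbv(n_vert);
  for (int v = 0; v < n_vert; ++v) {
    IntegerVector m = nb[v];
    nbv[v].assign(m.begin(), m.end());
    for (auto& e : nbv[v]) e -= 1;
  }

  // Per vertex: cumulative (over time) per-trial sums / sums of squares and
  // per-pair cross-products of the amplitudes pooled over the spatial
  // members, so each center's windowed Pearson statistics are O(1) column
  // differences instead of a fresh feature gather.
  arma::mat cumS(n_trials, n_time + 1), cumSS(n_trials, n_time + 1);
  arma::mat cumP(P, n_time + 1);
  arma::vec d(P), r(P), rr(P);
  std::vector<int> ordbuf(P);
  for (int v = 0; v < n_vert; ++v) {
    const std::vector<int>& mv = nbv[v];
    cumS.col(0).zeros(); cumSS.col(0).zeros(); cumP.col(0).zeros();
    for (int t = 0; t < n_time; ++t) {
      double* s = cumS.colptr(t + 1);
      double* ss = cumSS.colptr(t + 1);
      double* pp = cumP.colptr(t + 1);
      std::memcpy(s, cumS.colptr(t), n_trials * sizeof(double));
      std::memcpy(ss, cumSS.colptr(t), n_trials * sizeof(double));
      std::memcpy(pp, cumP.colptr(t), P * sizeof(double));
      for (int vv : mv) {
        const double* col = xp + (size_t)t * n_vert * n_trials +
                            (size_t)vv * n_trials;
        for (int i = 0; i < n_trials; ++i) {
          s[i] += col[i];
          ss[i] += col[i] * col[i];
        }
        int p = 0;
        for (int j = 0; j < n_trials; ++j) {
          const double cj = col[j];
          for (int i = j + 1; i < n_trials; ++i, ++p) pp[p] += col[i] * cj;
        }
      }
    }
    const int m = (int)mv.size();
    for (int t = 0; t < n_time; ++t) {
      const int t0 = std::max(0, t - halfwin);
      const int t1 = std::min(n_time - 1, t + halfwin);
      const double nf = (double)m * (t1 - t0 + 1);
      const double* sA = cumS.colptr(t1 + 1);
      const double* sB = cumS.colptr(t0);
      const double* ssA = cumSS.colptr(t1 + 1);
      const double* ssB = cumSS.colptr(t0);
      const double* pA = cumP.colptr(t1 + 1);
      const double* pB = cumP.colptr(t0);
      int p = 0;
      for (int j = 0; j < n_trials; ++j) {
        const double Sj = sA[j] - sB[j];
        const double Vj = (ssA[j] - ssB[j]) - Sj * Sj / nf;
        for (int i = j + 1; i < n_trials; ++i, ++p) {
          const double Si = sA[i] - sB[i];
          const double Vi = (ssA[i] - ssB[i]) - Si * Si / nf;
          const double cov = (pA[p] - pB[p]) - Si * Sj / nf;
          const double den = Vi * Vj;
          double dd = (den > 1e-24) ? 1.0 - cov / std::sqrt(den) : 1.0;
          if (dd < 0.0) dd = 0.0;        // clamp FP noise to the [0, 2]
          if (dd > 2.0) dd = 2.0;        // contract of a data RDM
          d(p) = dd;
        }
      }
      rank_avg_into(d.memptr(), P, ordbuf.data(), r.memptr());
      rr = r - Q * (Qt * r);
      const double nr = arma::norm(rr);
      out(v, t) = (nr > 1e-12) ? arma::dot(mresid, rr) / nr : 0.0;
    }
  }
  return out;
}

// Connected-component labeling of supra-threshold (vertex, time) points.
// Adjacency: mesh edge at the same sample, or the same vertex at an
// adjacent sample. NA t-values count as sub-threshold.
// Returns labels (0 = below threshold) and per-cluster summed t ("mass").
// [[Rcpp::export]]
List cluster_label_cpp(const NumericMatrix& tmap, double thr, List nb) {
  const int V = tmap.nrow(), T = tmap.ncol();
  IntegerMatrix lab(V, T);
  std::vector<double> masses;
  std::vector<std::vector<int>> nbv(V);
  for (int v = 0; v < V; ++v) {
    IntegerVector m = nb[v];
    nbv[v].assign(m.begin(), m.end());
    for (auto& e : nbv[v]) e -= 1;
  }
  auto supra = [&](int v, int t) {
    const double x = tmap(v, t);
    return !NumericMatrix::is_na(x) && x >= thr;
  };
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int t = 0; t < T; ++t) {
    for (int v = 0; v < V; ++v) {
      if (lab(v, t) != 0 || !supra(v, t)) continue;
      ++next;
      double mass = 0.0;
      stack.clear();
      stack.emplace_back(v, t);
      lab(v, t) = next;
      while (!stack.empty()) {
        auto [cv, ct] = stack.back();
        stack.pop_back();
        mass += tmap(cv, ct);
        for (int w : nbv[cv]) {
          if (lab(w, ct) == 0 && supra(w, ct)) {
            lab(w, ct) = next;
            stack.emplace_back(w, ct);
          }
        }
        for (int dt = -1; dt <= 1; dt += 2) {
          const int tt = ct + dt;
          if (tt >= 0 && tt < T && lab(cv, tt) == 0 && supra(cv, tt)) {
            lab(cv, tt) = next;
            stack.emplace_back(cv, tt);
          }
        }
      }
      masses.push_back(mass);
    }
  }
  return List::create(_["labels"] = lab,
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// Maximum-cluster-mass null: for each column of `signs` (n_subjects x n_perm,
// entries +/-1), flip each subject's whole fit map, recompute the one-sample
// t-map and return the largest cluster mass (0 when nothing is supra).
// fits: n_subjects x n_centers (centers in vertex-major order, V x T grid).
// [[Rcpp::export]]
NumericVector perm_max_mass_cpp(const arma::mat& fits, const arma::mat& signs,
                                int n_vert, int n_time, double thr, List nb) {
  const int n_sub = fits.n_rows;
  const arma::rowvec ssq = arma::sum(arma::square(fits), 0); // sign-invariant
  const int n_perm = signs.n_cols;
  NumericVector out(n_perm);
  NumericMatrix tmap(n_vert, n_time);
  for (int p = 0; p < n_perm; ++p) {
    arma::rowvec m = (signs.col(p).t() * fits) / n_sub;
    for (int c = 0; c < n_vert * n_time; ++c) {
      const double var = (ssq(c) - n_sub * m(c) * m(c)) / (n_sub - 1);
      tmap[c] = (var > 0.0) ? m(c) / std::sqrt(var / n_sub) : NA_REAL;
    }
    List cl = cluster_label_cpp(tmap, thr, nb);
    NumericVector masses = cl["masses"];
    out[p] = masses.size() ? Rcpp::max(masses) : 0.0;
  }
  return out;
}
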