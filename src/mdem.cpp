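// Numerical kernels: pairwise bead distances, 6D grid interpolation,
// and the sequential Gaussian simulation inner loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minimum distance between bead sets A (nA x 3) and B (nB x 3).
// [[Rcpp::export]]
double cpp_min_dist(const arma::mat& A, const arma::mat& B) {
  double best = arma::datum::inf;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      double dx = A(i,0)-B(j,0), dy = A(i,1)-B(j,1), dz = A(i,2)-B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Number of bead pairs closer than thresh.
// [[Rcpp::export]]
int cpp_count_within(const arma::mat& A, const arma::mat& B, double thresh) {
  double t2 = thresh * thresh;
  int n = 0;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      double dx = A(i,0)-B(j,0), dy = A(i,1)-B(j,1), dz = A(i,2)-B(j,2);
      if (dx*dx + dy*dy + dz*dz < t2) ++n;
    }
  }
  return n;
}

// Min distance between A and rotated B placed at many translations T (m x 3).
// Brot is the pre-rotated B bead set (nB x 3).
// [[Rcpp::export]]
arma::vec cpp_min_dist_many(const arma::mat& A, const arma::mat& Brot,
                            const arma::mat& T) {
  arma::vec out(T.n_rows);
  for (arma::uword k = 0; k < T.n_rows; ++k) {
    double best = arma::datum::inf;
    double tx = T(k,0), ty = T(k,1), tz = T(k,2);
    for (arma::uword j = 0; j < Brot.n_rows; ++j) {
      double bx = Brot(j,0)+tx, by = Brot(j,1)+ty, bz = Brot(j,2)+tz;
      for (arma::uword i = 0; i < A.n_rows; ++i) {
        double dx = A(i,0)-bx, dy = A(i,1)-by, dz = A(i,2)-bz;
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) best = d2;
      }
    }
    out(k) = std::sqrt(best);
  }
  return out;
}

// Multilinear interpolation on a 6D grid.
// value: flat array in column-major axis order (x fastest);
// n, mn, step: per-axis node count, minimum and spacing;
// periodic: per-axis flag (angles). Queries outside a non-periodic
// axis extent return 0.
// [[Rcpp::export]]
NumericVector cpp_interp6(const NumericVector& value,
                          const IntegerVector& n, const NumericVector& mn,
                          const NumericVector& step,
                          const LogicalVector& periodic,
                          const NumericMatrix& q) {
  const int D = 6;
  int nq = q.nrow();
  NumericVector out(nq);
  long stride[6];
  stride[0] = 1;
  for (int d = 1; d < D; ++d) stride[d] = stride[d-1] * n[d-1];
  for (int k = 0; k < nq; ++k) {
    int i0[6]; double fr[6]; bool outside = false;
    for (int d = 0; d < D; ++d) {
      double u = (q(k,d) - mn[d]) / step[d];
      if (periodic[d]) {
        double period = n[d];
        u -= period * std::floor(u / period);
        if (u >= period) u -= period;
        i0[d] = (int)std::floor(u); fr[d] = u - i0[d];
        if (i0[d] >= n[d]) { i0[d] = 0; }
      } else {
        if (u < 0.0 || u > n[d] - 1) { outside = true; break; }
        i0[d] = (int)std::floor(u);
        if (i0[d] >= n[d] - 1) i0[d] = n[d] - 2 < 0 ? 0 : n[d] - 2;
        fr[d] = u - i0[d];
      }
    }
    if (outside) { out[k] = 0.0; continue; }
    double acc = 0.0;
    for (int c = 0; c < 64; ++c) {
      double w = 1.0; long idx = 0;
      for (int d = 0; d < D; ++d) {
        int bit = (c >> d) & 1;
        int id = i0[d] + bit;
        if (periodic[d] && id >= n[d]) id -= n[d];
        if (n[d] == 1) { id = 0; if (bit) { w = 0.0; break; } }
        w *= bit ? fr[d] : (1.0 - fr[d]);
        idx += (long)id * stride[d];
      }
      if (w != 0.0) acc += w * value[idx];
    }
    out[k] = acc;
  }
  return out;
}

// Sequential Gaussian simulation with simple kriging (known zero mean)
// and a Gaussian-covariance residual C(h) = psill * exp(-(h/range)^2).
// coords: node coordinates (n x d); path: 1-based visiting order;
// z: pre-drawn standard normals (length n, from the R RNG);
// maxneigh: neighborhood cap; cutoff: search radius.
// [[Rcpp::export]]
arma::vec cpp_sgs(const arma::mat& coords, const IntegerVector& path,
                  double psill, double range_, const arma::vec& z,
                  int maxneigh, double cutoff) {
  int n = coords.n_rows, d = coords.n_cols;
  arma::vec values(n, arma::fill::zeros);
  std::vector<int> done; done.reserve(n);
  double c2 = cutoff * cutoff, r2 = range_ * range_;
  for (int s = 0; s < n; ++s) {
    int node = path[s] - 1;
    // gather candidate neighbors within cutoff
    std::vector<std::pair<double,int> > cand;
    for (size_t t = 0; t < done.size(); ++t) {
      int j = done[t];
      double h2 = 0;
      for (int kk = 0; kk < d; ++kk) {
        double dd = coords(node,kk) - coords(j,kk); h2 += dd*dd;
      }
      if (h2 < c2) cand.push_back(std::make_pair(h2, j));
    }
    int m = std::min((int)cand.size(), maxneigh);
    double mean = 0.0, var = psill;
    if (m > 0) {
      std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
      arma::mat C(m, m); arma::vec c0(m), zv(m);
      for (int a = 0; a < m; ++a) {
        int ja = cand[a].second;
        c0(a) = psill * std::exp(-cand[a].first / r2);
        zv(a) = values(ja);
        for (int b = 0; b <= a; ++b) {
          int jb = cand[b].second;
          double h2 = 0;
          for (int kk = 0; kk < d; ++kk) {
            double dd = coords(ja,kk) - coords(jb,kk); h2 += dd*dd;
          }
          C(a,b) = C(b,a) = psill * std::exp(-h2 / r2);
        }
        C(a,a) += 1e-8 * psill;  // jitter against singular SK systems
      }
      arma::vec w;
      bool ok = arma::solve(w, C, c0, arma::solve_opts::likely_sympd +
                                        arma::solve_opts::no_approx);
      if (!ok) w = arma::pinv(C) * c0;
      mean = arma::dot(w, zv);
      var = psill - arma::dot(w, c0);
      if (var < 0) var = 0;
    }
    values(node) = mean + std::sqrt(var) * z[s];
    done.push_back(node);
  }
  return values;
}
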