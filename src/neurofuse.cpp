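// Hot loops: IIR filtering, rank statistics, KDE/KL networks, linear SVM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Direct-form-II-transposed linear filter with initial conditions.
static arma::vec lfilter_df2t(const arma::vec& b, const arma::vec& a,
                              const arma::vec& x, const arma::vec& zi) {
  const int n = b.n_elem;          // b and a padded to equal length upstream
  const int T = x.n_elem;
  arma::vec z = zi;                // length n-1
  arma::vec y(T);
  for (int t = 0; t < T; ++t) {
    double yt = b[0] * x[t] + (n > 1 ? z[0] : 0.0);
    for (int i = 0; i < n - 2; ++i)
      z[i] = b[i + 1] * x[t] + z[i + 1] - a[i + 1] * yt;
    if (n > 1)
      z[n - 2] = b[n - 1] * x[t] - a[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Steady-state initial conditions for a unit-step input (scipy lfilter_zi).
// [[Rcpp::export]]
arma::vec cpp_lfilter_zi(const arma::vec& b, const arma::vec& a) {
  const int n = b.n_elem;
  arma::mat C(n - 1, n - 1, arma::fill::zeros); // companion of a
  for (int j = 0; j < n - 1; ++j) C(0, j) = -a[j + 1] / a[0];
  for (int i = 1; i < n - 1; ++i) C(i, i - 1) = 1.0;
  arma::mat IminusA = arma::eye(n - 1, n - 1) - C.t();
  arma::vec B = b.subvec(1, n - 1) - a.subvec(1, n - 1) * b[0];
  return arma::solve(IminusA, B);
}

static arma::vec filtfilt_one(const arma::vec& b, const arma::vec& a,
                              const arma::vec& zi, const arma::vec& x,
                              int padlen) {
  const int T = x.n_elem;
  if (T <= padlen)
    stop("filtfilt: series length (%d) must exceed pad length (%d)", T, padlen);
  arma::vec ext(T + 2 * padlen);
  for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * x[0] - x[padlen - i];
  ext.subvec(padlen, padlen + T - 1) = x;
  for (int i = 0; i < padlen; ++i)
    ext[padlen + T + i] = 2.0 * x[T - 1] - x[T - 2 - i];
  arma::vec y = lfilter_df2t(b, a, ext, zi * ext[0]);
  y = arma::reverse(y);
  y = lfilter_df2t(b, a, y, zi * y[0]);
  y = arma::reverse(y);
  return y.subvec(padlen, padlen + T - 1);
}

// Zero-phase filtering of each column of X (time along rows).
// [[Rcpp::export]]
arma::mat cpp_filtfilt_mat(const arma::vec& b, const arma::vec& a,
                           const arma::mat& X, int padlen) {
  arma::vec zi = cpp_lfilter_zi(b, a);
  arma::mat Y(X.n_rows, X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j)
    Y.col(j) = filtfilt_one(b, a, zi, X.col(j), padlen);
  return Y;
}

// ---------------------------------------------------------------------------
// Average ranks (ties -> mean rank) of a vector.
static arma::vec avg_rank(const arma::vec& x) {
  const int n = x.n_elem;
  arma::uvec ord = arma::sort_index(x);
  arma::vec r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0; // mean of ranks i+1..j+1
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
  return r;
}

// Kendall's W over each voxel's neighbourhood. X is T x V (cleaned series),
// nbr is a V x maxnb integer matrix of 0-based voxel column indices, -1 pad;
// the voxel itself must be included by the caller. No tie correction.
// [[Rcpp::export]]
arma::vec cpp_reho(const arma::mat& X, const IntegerMatrix& nbr) {
  const int T = X.n_rows, V = X.n_cols;
  if (T < 2) stop("ReHo requires at least 2 timepoints");
  arma::mat R(T, V);
  for (int v = 0; v < V; ++v) R.col(v) = avg_rank(X.col(v));
  arma::vec W(V);
  const double denom_t = (double)T * ((double)T * T - 1.0);
  for (int v = 0; v < V; ++v) {
    arma::vec rs(T, arma::fill::zeros);
    int K = 0;
    for (int j = 0; j < nbr.ncol(); ++j) {
      int idx = nbr(v, j);
      if (idx < 0) continue;
      rs += R.col(idx);
      ++K;
    }
    double rbar = K * (T + 1.0) / 2.0;
    double s = arma::accu(arma::square(rs - rbar));
    W[v] = 12.0 * s / ((double)K * K * denom_t);
  }
  return W;
}

// ---------------------------------------------------------------------------
// Type-7 quantile (R default) of a sorted vector.
static double quantile7(const arma::vec& xs, double p) {
  const int n = xs.n_elem;
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  return xs[lo] + (h - lo) * (xs[hi] - xs[lo]);
}

// Silverman bandwidth with a degeneracy floor of 1e-3 * (range or 1).
static double silverman_bw(const arma::vec& x) {
  const int n = x.n_elem;
  arma::vec xs = arma::sort(x);
  double sd = arma::stddev(x);
  double iqr = quantile7(xs, 0.75) - quantile7(xs, 0.25);
  double spread = std::min(sd, iqr / 1.34);
  double rng = xs[n - 1] - xs[0];
  double floor_bw = 1e-3 * (rng > 0 ? rng : 1.0);
  double h = 0.9 * spread * std::pow((double)n, -0.2);
  return std::max(h, floor_bw);
}

static arma::vec kde_on_grid(const arma::vec& x, const arma::vec& grid,
                             double h) {
  arma::vec pdf(grid.n_elem, arma::fill::zeros);
  const double c = 1.0 / (h * std::sqrt(2.0 * M_PI) * x.n_elem);
  for (arma::uword g = 0; g < grid.n_elem; ++g) {
    double s = 0.0;
    for (arma::uword i = 0; i < x.n_elem; ++i) {
      double u = (grid[g] - x[i]) / h;
      s += std::exp(-0.5 * u * u);
    }
    pdf[g] = c * s;
  }
  return pdf;
}

static double trapz(const arma::vec& grid, const arma::vec& y) {
  double s = 0.0;
  for (arma::uword i = 1; i < grid.n_elem; ++i)
    s += 0.5 * (grid[i] - grid[i - 1]) * (y[i] + y[i - 1]);
  return s;
}

// exp(-symmetrized KL) similarity matrix between region value distributions.
// vals: list of numeric vectors (one per region), common pairwise grids.
// [[Rcpp::export]]
arma::mat cpp_morph_network(const List& vals, int grid_size) {
  const int R = vals.size();
  std::vector<arma::vec> v(R);
  std::vector<double> bw(R);
  for (int r = 0; r < R; ++r) {
    v[r] = as<arma::vec>(vals[r]);
    if (v[r].n_elem == 0) stop("empty region %d", r + 1);
    bw[r] = silverman_bw(v[r]);
  }
  arma::mat S(R, R, arma::fill::ones);
  const double floor_pdf = 1e-12;
  for (int i = 0; i < R; ++i) {
    for (int j = i + 1; j < R; ++j) {
      double pad = 3.0 * std::max(bw[i], bw[j]);
      double lo = std::min(v[i].min(), v[j].min()) - pad;
      double hi = std::max(v[i].max(), v[j].max()) + pad;
      arma::vec grid = arma::linspace(lo, hi, grid_size);
      arma::vec p = kde_on_grid(v[i], grid, bw[i]);
      arma::vec q = kde_on_grid(v[j], grid, bw[j]);
      p /= trapz(grid, p);
      q /= trapz(grid, q);
      p.transform([&](double x) { return std::max(x, floor_pdf); });
      q.transform([&](double x) { return std::max(x, floor_pdf); });
      arma::vec ipq = p % arma::log(p / q);
      arma::vec iqp = q % arma::log(q / p);
      double kls = trapz(grid, ipq) + trapz(grid, iqp);
      double sim = std::exp(-kls);
      S(i, j) = sim;
      S(j, i) = sim;
    }
  }
  return S;
}

// ---------------------------------------------------------------------------
// Linear C-SVM (hinge loss) by dual coordinate descent (LIBLINEAR algorithm).
// X is n x d and must already carry a bias column if one is wanted; y in
// {-1,+1}. Deterministic given `seed`.
// [[Rcpp::export]]
List cpp_svm_dcd(const arma::mat& X, const arma::vec& y, double C,
                 double tol, int max_epoch, int seed) {
  const int n = X.n_rows, d = X.n_cols;
  arma::mat Xt = X.t(); // d x n: samples become contiguous columns
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec w(d, arma::fill::zeros);
  arma::vec Qii(n);
  for (int i = 0; i < n; ++i) Qii[i] = arma::dot(Xt.col(i), Xt.col(i));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(seed);
  double* wp = w.memptr();
  int epoch = 0;
  for (; epoch < max_epoch; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      const double* xi = Xt.colptr(i);
      double f = 0.0;
      for (int j = 0; j < d; ++j) f += wp[j] * xi[j];
      double G = y[i] * f - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (PG != 0.0) {
        pg_max = std::max(pg_max, PG);
        pg_min = std::min(pg_min, PG);
      }
      if (std::fabs(PG) > 1e-12 && Qii[i] > 0.0) {
        double a_new = std::min(std::max(alpha[i] - G / Qii[i], 0.0), C);
        if (a_new != alpha[i]) {
          double delta = (a_new - alpha[i]) * y[i];
          for (int j = 0; j < d; ++j) wp[j] += delta * xi[j];
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max <= pg_min + tol) break; // also covers the all-zero-PG epoch
  }
  return List::create(_["w"] = w, _["alpha"] = alpha,
                      _["epochs"] = epoch + 1);
}

// ---------------------------------------------------------------------------
// Exhaustive integer-coefficient search for soft voting on cached
// probabilities. P is n x M patient probabilities, y01 in {0,1} (1=patient),
// fold 0-based inner-fold ids. Maximizes mean per-fold balanced accuracy;
// enumeration is lexicographic from (1,...,1) with strict improvement, so
// ties resolve to the lexicographically smallest vector.
// [[Rcpp::export]]
IntegerVector cpp_coeff_grid(const arma::mat& P, const IntegerVector& y01,
                             const IntegerVector& fold, int cmax) {
  const int n = P.n_rows, M = P.n_cols;
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, fold[i] + 1);
  std::vector<int> c(M, 1), best(M, 1);
  double best_bac = -1.0;
  arma::vec tp(K), fn(K), tn(K), fp(K);
  bool done = false;
  while (!done) {
    double csum = 0.0;
    for (int m = 0; m < M; ++m) csum += c[m];
    tp.zeros(); fn.zeros(); tn.zeros(); fp.zeros();
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += c[m] * P(i, m);
      int pred = (s / csum >= 0.5) ? 1 : 0; // patient wins exact ties
      int f = fold[i];
      if (y01[i] == 1) { if (pred == 1) tp[f]++; else fn[f]++; }
      else             { if (pred == 0) tn[f]++; else fp[f]++; }
    }
    double bac = 0.0;
    for (int f = 0; f < K; ++f) {
      double sen = (tp[f] + fn[f]) > 0 ? tp[f] / (tp[f] + fn[f]) : 0.0;
      double spec = (tn[f] + fp[f]) > 0 ? tn[f] / (tn[f] + fp[f]) : 0.0;
      bac += 0.5 * (sen + spec);
    }
    bac /= K;
    if (bac > best_bac) { best_bac = bac; best = c; }
    // lexicographic counter: last index varies fastest; increment from the
    // rightmost digit so visiting order is lexicographic ascending
    int pos = M - 1;
    while (pos >= 0) {
      if (c[pos] < cmax) { c[pos]++; break; }
      c[pos] = 1;
      --pos;
    }
    if (pos < 0) done = true;
  }
  return IntegerVector(best.begin(), best.end());
}
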