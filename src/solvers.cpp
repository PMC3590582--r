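// Minimal solvers (normalized 8-point, normalized DLT), point-to-model
// residuals, and the adaptive hypothesize-and-verify loop. All randomness
// comes from R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Similarity transform taking pts to centroid (0,0), mean radius sqrt(2).
// Returns false when all points coincide (zero spread).
static bool hartley_transform(const arma::mat& pts, arma::mat33& T) {
  arma::rowvec c = arma::mean(pts, 0);
  arma::mat d = pts.each_row() - c;
  double md = arma::mean(arma::sqrt(arma::sum(arma::square(d), 1)));
  if (md <= 0.0) return false;
  double sc = std::sqrt(2.0) / md;
  T.zeros();
  T(0, 0) = sc;
  T(1, 1) = sc;
  T(2, 2) = 1.0;
  T(0, 2) = -sc * c(0);
  T(1, 2) = -sc * c(1);
  return true;
}

// Unit Frobenius norm, largest-magnitude entry positive.
static void canonicalize(arma::mat33& M) {
  double f = arma::norm(M, "fro");
  if (f > 0.0) M /= f;
  arma::vec v = arma::vectorise(M);
  if (v(arma::abs(v).index_max()) < 0.0) M = -M;
}

// Normalized 8-point fundamental-matrix solver on >= 8 correspondences.
// Returns false on degenerate configurations (null space dim > 1, i.e. the
// design matrix drops below rank 8, or zero point spread).
static bool fm_8pt(const arma::mat& p1, const arma::mat& p2, arma::mat33& F) {
  const arma::uword n = p1.n_rows;
  if (n < 8) return false;
  arma::mat33 T1, T2;
  if (!hartley_transform(p1, T1) || !hartley_transform(p2, T2)) return false;
  arma::mat A(n, 9);
  for (arma::uword i = 0; i < n; ++i) {
    double u1 = T1(0, 0) * p1(i, 0) + T1(0, 2);
    double v1 = T1(1, 1) * p1(i, 1) + T1(1, 2);
    double u2 = T2(0, 0) * p2(i, 0) + T2(0, 2);
    double v2 = T2(1, 1) * p2(i, 1) + T2(1, 2);
    A(i, 0) = u2 * u1; A(i, 1) = u2 * v1; A(i, 2) = u2;
    A(i, 3) = v2 * u1; A(i, 4) = v2 * v1; A(i, 5) = v2;
    A(i, 6) = u1;      A(i, 7) = v1;      A(i, 8) = 1.0;
  }
  arma::mat U, V;
  arma::vec sv;
  if (!arma::svd(U, sv, V, A)) return false;
  if (sv(7) < 1e-8 * sv(0)) return false;  // rank < 8: ambiguous null space
  arma::vec f = V.col(8);
  arma::mat33 Fn;
  Fn(0, 0) = f(0); Fn(0, 1) = f(1); Fn(0, 2) = f(2);
  Fn(1, 0) = f(3); Fn(1, 1) = f(4); Fn(1, 2) = f(5);
  Fn(2, 0) = f(6); Fn(2, 1) = f(7); Fn(2, 2) = f(8);
  arma::mat33 Fd = T2.t() * Fn * T1;  // denormalize, then enforce rank 2
  arma::mat33 Uf, Vf;
  arma::vec sf;
  if (!arma::svd(Uf, sf, Vf, arma::mat(Fd))) return false;
  sf(2) = 0.0;
  F = Uf * arma::diagmat(sf) * Vf.t();
  canonicalize(F);
  return true;
}

// Normalized DLT homography solver on >= 4 correspondences.
static bool h_dlt(const arma::mat& p1, const arma::mat& p2, arma::mat33& H) {
  const arma::uword n = p1.n_rows;
  if (n < 4) return false;
  arma::mat33 T1, T2;
  if (!hartley_transform(p1, T1) || !hartley_transform(p2, T2)) return false;
  arma::mat A(2 * n, 9, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double u1 = T1(0, 0) * p1(i, 0) + T1(0, 2);
    double v1 = T1(1, 1) * p1(i, 1) + T1(1, 2);
    double u2 = T2(0, 0) * p2(i, 0) + T2(0, 2);
    double v2 = T2(1, 1) * p2(i, 1) + T2(1, 2);
    A(2 * i, 0) = -u1; A(2 * i, 1) = -v1; A(2 * i, 2) = -1.0;
    A(2 * i, 6) = u2 * u1; A(2 * i, 7) = u2 * v1; A(2 * i, 8) = u2;
    A(2 * i + 1, 3) = -u1; A(2 * i + 1, 4) = -v1; A(2 * i + 1, 5) = -1.0;
    A(2 * i + 1, 6) = v2 * u1; A(2 * i + 1, 7) = v2 * v1; A(2 * i + 1, 8) = v2;
  }
  arma::mat U, V;
  arma::vec sv;
  if (!arma::svd(U, sv, V, A)) return false;
  if (sv(7) < 1e-8 * sv(0)) return false;
  arma::vec h = V.col(8);
  arma::mat33 Hn;
  Hn(0, 0) = h(0); Hn(0, 1) = h(1); Hn(0, 2) = h(2);
  Hn(1, 0) = h(3); Hn(1, 1) = h(4); Hn(1, 2) = h(5);
  Hn(2, 0) = h(6); Hn(2, 1) = h(7); Hn(2, 2) = h(8);
  arma::mat33 T2i;
  if (!arma::inv(T2i, arma::mat(T2))) return false;
  H = T2i * Hn * T1;
  canonicalize(H);
  if (std::abs(arma::det(H)) < 1e-12) return false;
  return true;
}

// First-order (Sampson) distance to the epipolar constraint, in pixels.
// NaN where all four gradient terms vanish.
static void sampson_vec(const arma::mat33& F, const arma::mat& p1,
                        const arma::mat& p2, arma::vec& out) {
  const arma::uword n = p1.n_rows;
  out.set_size(n);
  for (arma::uword i = 0; i < n; ++i) {
    double x1 = p1(i, 0), y1 = p1(i, 1), x2 = p2(i, 0), y2 = p2(i, 1);
    double l0 = F(0, 0) * x1 + F(0, 1) * y1 + F(0, 2);
    double l1 = F(1, 0) * x1 + F(1, 1) * y1 + F(1, 2);
    double l2 = F(2, 0) * x1 + F(2, 1) * y1 + F(2, 2);
    double m0 = F(0, 0) * x2 + F(1, 0) * y2 + F(2, 0);
    double m1 = F(0, 1) * x2 + F(1, 1) * y2 + F(2, 1);
    double num = x2 * l0 + y2 * l1 + l2;
    double den = l0 * l0 + l1 * l1 + m0 * m0 + m1 * m1;
    out(i) = (den > 0.0) ? std::sqrt(num * num / den)
                         : std::numeric_limits<double>::quiet_NaN();
  }
}

// Symmetric transfer error sqrt((|q - Hp|^2 + |p - H^-1 q|^2) / 2).
// NaN where a point maps to the line at infinity.
static bool transfer_vec(const arma::mat33& H, const arma::mat& p1,
                         const arma::mat& p2, arma::vec& out) {
  arma::mat33 Hi;
  if (!arma::inv(Hi, arma::mat(H))) return false;
  const arma::uword n = p1.n_rows;
  out.set_size(n);
  for (arma::uword i = 0; i < n; ++i) {
    double x1 = p1(i, 0), y1 = p1(i, 1), x2 = p2(i, 0), y2 = p2(i, 1);
    double a0 = H(0, 0) * x1 + H(0, 1) * y1 + H(0, 2);
    double a1 = H(1, 0) * x1 + H(1, 1) * y1 + H(1, 2);
    double a2 = H(2, 0) * x1 + H(2, 1) * y1 + H(2, 2);
    double b0 = Hi(0, 0) * x2 + Hi(0, 1) * y2 + Hi(0, 2);
    double b1 = Hi(1, 0) * x2 + Hi(1, 1) * y2 + Hi(1, 2);
    double b2 = Hi(2, 0) * x2 + Hi(2, 1) * y2 + Hi(2, 2);
    if (std::abs(a2) < 1e-12 || std::abs(b2) < 1e-12) {
      out(i) = std::numeric_limits<double>::quiet_NaN();
      continue;
    }
    double ex = x2 - a0 / a2, ey = y2 - a1 / a2;
    double fx = x1 - b0 / b2, fy = y1 - b1 / b2;
    out(i) = std::sqrt((ex * ex + ey * ey + fx * fx + fy * fy) / 2.0);
  }
  return true;
}

// Adaptive iteration bound N = ceil(log(1-p)/log(1-phi^s)), clamped to
// [1, n_max]; phi = 0 -> n_max, phi = 1 -> 1.
static int req_iters(double p, double phi, int s, int n_max) {
  if (phi <= 0.0) return n_max;
  if (phi >= 1.0) return 1;
  double ps = std::pow(phi, (double)s);
  double den = std::log1p(-ps);
  if (!(den < 0.0)) return n_max;  // phi^s underflowed
  double N = std::ceil(std::log1p(-p) / den);
  if (N < 1.0) return 1;
  if (N >= (double)n_max) return n_max;
  return (int)N;
}

// [[Rcpp::export(name = ".fm_8pt_cpp")]]
List fm_8pt_cpp(const arma::mat& p1, const arma::mat& p2) {
  arma::mat33 F;
  bool ok = fm_8pt(p1, p2, F);
  return List::create(_["ok"] = ok, _["m"] = ok ? wrap(arma::mat(F)) : R_NilValue);
}

// [[Rcpp::export(name = ".h_dlt_cpp")]]
List h_dlt_cpp(const arma::mat& p1, const arma::mat& p2) {
  arma::mat33 H;
  bool ok = h_dlt(p1, p2, H);
  return List::create(_["ok"] = ok, _["m"] = ok ? wrap(arma::mat(H)) : R_NilValue);
}

// [[Rcpp::export(name = ".sampson_cpp")]]
arma::vec sampson_cpp(const arma::mat& F, const arma::mat& p1,
                      const arma::mat& p2) {
  arma::mat33 Ff(F);
  arma::vec out;
  sampson_vec(Ff, p1, p2, out);
  return out;
}

// [[Rcpp::export(name = ".transfer_cpp")]]
arma::vec transfer_cpp(const arma::mat& H, const arma::mat& p1,
                       const arma::mat& p2) {
  arma::mat33 Hf(H);
  arma::vec out;
  if (!transfer_vec(Hf, p1, p2, out)) {
    out.set_size(p1.n_rows);
    out.fill(std::numeric_limits<double>::quiet_NaN());
  }
  return out;
}

// [[Rcpp::export(name = ".req_iters_cpp")]]
int req_iters_cpp(double p, double phi, int s, int n_max) {
  return req_iters(p, phi, s, n_max);
}

// Hypothesize-and-verify loop. `buckets` is a list of 1-based index vectors
// (non-empty buckets of the spatial grid); when it holds fewer than s
// buckets, sampling falls back to uniform draws over all rows. A degenerate
// sample consumes an iteration. Ties on the inlier count keep the earlier
// model. After the loop the best model is refit by the same solver on its
// inliers (when >= s of them) and the mask is recomputed.
// [[Rcpp::export(name = ".ransac_loop_cpp")]]
List ransac_loop_cpp(const arma::mat& p1, const arma::mat& p2,
                     const std::string& model_kind, int s, double conf,
                     double threshold, int n_max, const List& buckets) {
  const int n = (int)p1.n_rows;
  const bool is_f = (model_kind == "fundamental");
  const int nb = buckets.size();
  std::vector<IntegerVector> bk(nb);
  for (int i = 0; i < nb; ++i) bk[i] = buckets[i];
  const bool use_buckets = nb >= s;
  bool bucket_fallback = (nb > 0 && !use_buckets);

  arma::mat33 best_model;
  int best_count = -1;
  arma::uvec best_idx;
  int N = n_max;
  int iter = 0;
  arma::mat sp1(s, 2), sp2(s, 2);
  arma::vec res;

  while (iter < std::min(N, n_max)) {
    ++iter;
    // --- draw a minimal sample ---
    arma::uvec idx((arma::uword)s);
    if (use_buckets) {
      IntegerVector bsel = Rcpp::sample(nb, s, false);  // distinct buckets
      for (int j = 0; j < s; ++j) {
        const IntegerVector& mem = bk[bsel[j] - 1];
        int pick = (mem.size() == 1) ? 0 : (Rcpp::sample((int)mem.size(), 1, false)[0] - 1);
        idx(j) = (arma::uword)(mem[pick] - 1);
      }
    } else {
      IntegerVector u = Rcpp::sample(n, s, false);
      for (int j = 0; j < s; ++j) idx(j) = (arma::uword)(u[j] - 1);
    }
    for (int j = 0; j < s; ++j) {
      sp1(j, 0) = p1(idx(j), 0); sp1(j, 1) = p1(idx(j), 1);
      sp2(j, 0) = p2(idx(j), 0); sp2(j, 1) = p2(idx(j), 1);
    }
    // --- hypothesize ---
    arma::mat33 M;
    bool ok = is_f ? fm_8pt(sp1, sp2, M) : h_dlt(sp1, sp2, M);
    if (!ok) continue;  // degenerate sample still consumes an iteration
    // --- verify ---
    if (is_f) {
      sampson_vec(M, p1, p2, res);
    } else if (!transfer_vec(M, p1, p2, res)) {
      continue;
    }
    int count = 0;
    for (int i = 0; i < n; ++i)
      if (res(i) <= threshold) ++count;  // NaN compares false
    if (count > best_count) {
      best_count = count;
      best_model = M;
      best_idx = idx;
      N = req_iters(conf, (double)count / (double)n, s, n_max);
    }
  }

  if (best_count < 0) {
    return List::create(_["found"] = false, _["iterations"] = iter,
                        _["N_final"] = N,
                        _["bucket_fallback"] = bucket_fallback);
  }

  // --- refit on the winning model's inliers ---
  if (is_f) {
    sampson_vec(best_model, p1, p2, res);
  } else {
    transfer_vec(best_model, p1, p2, res);
  }
  // Iterated consensus refit: refit on the current inliers, reclassify,
  // repeat while support does not drop (cap 10 rounds). A plain
  // least-squares refit on a contaminated set can drift, so a refit losing
  // consensus is discarded and the previous model kept.
  {
    int cur_count = 0;
    for (int i = 0; i < n; ++i)
      if (res(i) <= threshold) ++cur_count;
    for (int round = 0; round < 10; ++round) {
      std::vector<arma::uword> in;
      for (int i = 0; i < n; ++i)
        if (res(i) <= threshold) in.push_back((arma::uword)i);
      if ((int)in.size() < s) break;
      arma::uvec iin(in);
      arma::mat33 Mr;
      bool ok = is_f ? fm_8pt(p1.rows(iin), p2.rows(iin), Mr)
                     : h_dlt(p1.rows(iin), p2.rows(iin), Mr);
      if (!ok) break;
      arma::vec res_r;
      if (is_f) {
        sampson_vec(Mr, p1, p2, res_r);
      } else if (!transfer_vec(Mr, p1, p2, res_r)) {
        break;
      }
      int count_r = 0;
      for (int i = 0; i < n; ++i)
        if (res_r(i) <= threshold) ++count_r;
      if (count_r < cur_count) break;
      bool improved = count_r > cur_count;
      best_model = Mr;
      cur_count = count_r;
      res = res_r;
      if (!improved) break;
    }
  }
  if (is_f) {
    sampson_vec(best_model, p1, p2, res);
  } else {
    transfer_vec(best_model, p1, p2, res);
  }
  LogicalVector mask(n);
  int final_count = 0;
  for (int i = 0; i < n; ++i) {
    bool v = res(i) <= threshold;
    mask[i] = v;
    if (v) ++final_count;
  }
  return List::create(
      _["found"] = true, _["model"] = wrap(arma::mat(best_model)),
      _["mask"] = mask, _["count"] = final_count, _["iterations"] = iter,
      _["N_final"] = N, _["bucket_fallback"] = bucket_fallback);
}
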