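// Compute-heavy kernels: constrained spherical deconvolution, probabilistic
// streamline tracking, LiFE design-matrix assembly and coordinate-descent
// NNLS. All randomness goes through R's RNG so set.seed() governs results.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Constrained spherical deconvolution (iterated constrained least squares)
// ---------------------------------------------------------------------------

// att_t: ndir x nvox attenuations; fwd: ndir x ncoef forward convolution
// matrix; Bcon: ncon x ncoef amplitude basis at constraint directions;
// init_cols: 1-based columns of the low-order initial fit.
// [[Rcpp::export]]
List csd_fit_cpp(const arma::mat& att_t, const arma::mat& fwd,
                 const arma::mat& Bcon, const arma::uvec& init_cols,
                 double lambda, double tau_rel, int max_iter) {
  const arma::uword nvox = att_t.n_cols, ncoef = fwd.n_cols;
  arma::mat coef(ncoef, nvox, arma::fill::zeros);
  arma::ivec converged(nvox, arma::fill::zeros);
  arma::uvec ic = init_cols - 1;
  arma::mat fwd_i = fwd.cols(ic);
  arma::mat FtF_i = fwd_i.t() * fwd_i;
  FtF_i.diag() += 1e-10;
  arma::mat FtF = fwd.t() * fwd;
  arma::mat Ft = fwd.t();
  const double l2 = lambda * lambda;

  for (arma::uword v = 0; v < nvox; ++v) {
    arma::vec s = att_t.col(v);
    arma::vec f(ncoef, arma::fill::zeros);
    arma::vec fi = arma::solve(FtF_i, fwd_i.t() * s,
                               arma::solve_opts::likely_sympd);
    f.elem(ic) = fi;
    arma::vec amp = Bcon * f;
    double tau = tau_rel * arma::mean(amp);
    if (tau < 0) tau = 0;
    arma::uvec prev;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      arma::uvec neg = arma::find(amp < tau);
      if (it > 0 && neg.n_elem == prev.n_elem &&
          arma::all(neg == prev)) { ok = true; break; }
      prev = neg;
      arma::mat A = FtF;
      if (neg.n_elem > 0) {
        arma::mat Bn = Bcon.rows(neg);
        A += l2 * (Bn.t() * Bn);
      }
      A.diag() += 1e-10;
      f = arma::solve(A, Ft * s, arma::solve_opts::likely_sympd);
      amp = Bcon * f;
    }
    coef.col(v) = f;
    converged(v) = ok ? 1 : 0;
  }
  return List::create(_["coef"] = coef, _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Probabilistic tracking on a precomputed FOD-amplitude grid
// ---------------------------------------------------------------------------

static inline long vox_lin(int i, int j, int k, const int* dim) {
  return (long)i + (long)dim[0] * ((long)j + (long)dim[1] * (long)k);
}

// trilinear interpolation support at a voxel-space point (0-based, center
// convention): up to 8 (linear index, weight) pairs; corners outside the
// grid are dropped (amplitude 0 there)
struct TriCorners {
  long lin[8];
  double w[8];
  int n;
};

static TriCorners tri_corners(const double* v, const int* dim) {
  TriCorners tc;
  tc.n = 0;
  int i0[3]; double fr[3];
  for (int a = 0; a < 3; ++a) {
    double fl = std::floor(v[a]);
    i0[a] = (int)fl;
    fr[a] = v[a] - fl;
  }
  for (int c = 0; c < 8; ++c) {
    int ii = i0[0] + (c & 1), jj = i0[1] + ((c >> 1) & 1),
        kk = i0[2] + ((c >> 2) & 1);
    if (ii < 0 || jj < 0 || kk < 0 ||
        ii >= dim[0] || jj >= dim[1] || kk >= dim[2]) continue;
    double w = ((c & 1) ? fr[0] : 1 - fr[0]) *
               (((c >> 1) & 1) ? fr[1] : 1 - fr[1]) *
               (((c >> 2) & 1) ? fr[2] : 1 - fr[2]);
    if (w <= 0) continue;
    tc.lin[tc.n] = vox_lin(ii, jj, kk, dim);
    tc.w[tc.n] = w;
    ++tc.n;
  }
  return tc;
}

static inline double amp_at(const double* amp, long nvox, int d,
                            const TriCorners& tc) {
  double out = 0;
  for (int c = 0; c < tc.n; ++c)
    out += tc.w[c] * amp[tc.lin[c] + nvox * (long)d];
  return out;
}

static inline void mm_to_vox(const double* ia, const double* p, double* v) {
  for (int r = 0; r < 3; ++r)
    v[r] = ia[r] * p[0] + ia[r + 3] * p[1] + ia[r + 6] * p[2] + ia[r + 9];
}

static bool in_wm(const double* ia, const double* p, const int* dim,
                  const int* wm) {
  double v[3];
  mm_to_vox(ia, p, v);
  int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]),
      k = (int)std::lround(v[2]);
  if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] || k >= dim[2])
    return false;
  return wm[vox_lin(i, j, k, dim)] != 0;
}

// categorical draw proportional to w (size n); returns -1 if total mass 0
static int draw_cat(const std::vector<double>& w) {
  double tot = 0;
  for (double x : w) tot += x;
  if (tot <= 0) return -1;
  double u = R::unif_rand() * tot, c = 0;
  for (size_t i = 0; i < w.size(); ++i) {
    c += w[i];
    if (u <= c) return (int)i;
  }
  return (int)w.size() - 1;
}

// grow one half of a streamline; returns points appended after the seed
static std::vector<double> grow_half(
    const double* amp, long nvox, const NumericMatrix& dirs,
    const std::vector<std::vector<int>>& cone, const double* ia,
    const int* dim, const int* wm, const double* seed_mm, int d0,
    double step, double stop_amp, int max_steps) {
  std::vector<double> pts;
  double p[3] = {seed_mm[0], seed_mm[1], seed_mm[2]};
  int d = d0;
  for (int s = 0; s < max_steps; ++s) {
    double np[3];
    for (int a = 0; a < 3; ++a) np[a] = p[a] + step * dirs(d, a);
    pts.push_back(np[0]); pts.push_back(np[1]); pts.push_back(np[2]);
    if (!in_wm(ia, np, dim, wm)) break;    // exit point kept, then stop
    double v[3];
    mm_to_vox(ia, np, v);
    TriCorners tc = tri_corners(v, dim);
    const std::vector<int>& cand = cone[d];
    std::vector<double> w(cand.size());
    bool any = false;
    for (size_t c = 0; c < cand.size(); ++c) {
      double a = amp_at(amp, nvox, cand[c], tc);
      w[c] = (a >= stop_amp) ? a : 0.0;
      if (w[c] > 0) any = true;
    }
    if (!any) break;
    int pick = draw_cat(w);
    if (pick < 0) break;
    d = cand[pick];
    p[0] = np[0]; p[1] = np[1]; p[2] = np[2];
  }
  return pts;
}

// [[Rcpp::export]]
List track_cpp(const NumericMatrix& amp, const NumericMatrix& dirs,
               const List& cone_list, const IntegerVector& antipode,
               const IntegerVector& dim3, const NumericMatrix& affine,
               const NumericMatrix& inv_affine, const IntegerVector& wm_mask,
               const IntegerVector& seed_vox, double step, double stop_amp,
               double min_len, double max_len, int n_streamlines,
               int max_attempts) {
  const long nvox = amp.nrow();
  const int ndir = dirs.nrow();
  int dim[3] = {dim3[0], dim3[1], dim3[2]};
  // column-major 3x4: [R | t] of the mm->voxel map
  double ia[12];
  for (int c = 0; c < 4; ++c)
    for (int r = 0; r < 3; ++r) ia[r + 3 * c] = inv_affine(r, c);
  std::vector<std::vector<int>> cone(ndir);
  for (int d = 0; d < ndir; ++d) {
    IntegerVector cv = cone_list[d];
    cone[d] = std::vector<int>(cv.begin(), cv.end());
  }
  std::vector<int> wm(wm_mask.begin(), wm_mask.end());
  const double* A = amp.begin();
  const int max_steps_total = (int)std::floor(max_len / step);
  List out(n_streamlines);
  int n_ok = 0, attempts = 0;
  while (n_ok < n_streamlines && attempts < max_attempts) {
    ++attempts;
    // uniform point inside a uniformly chosen seed voxel
    int sv = seed_vox[(int)(R::unif_rand() * seed_vox.size()) %
                      seed_vox.size()];
    int si = sv % dim[0], sj = (sv / dim[0]) % dim[1],
        sk = sv / (dim[0] * dim[1]);
    double vx[3] = {si + R::unif_rand() - 0.5, sj + R::unif_rand() - 0.5,
                    sk + R::unif_rand() - 0.5};
    double seed_mm[3];
    for (int r = 0; r < 3; ++r)
      seed_mm[r] = affine(r, 0) * vx[0] + affine(r, 1) * vx[1] +
                   affine(r, 2) * vx[2] + affine(r, 3);
    // first direction: full-sphere draw over amplitudes >= stop_amp
    double v[3];
    mm_to_vox(ia, seed_mm, v);
    TriCorners tc = tri_corners(v, dim);
    std::vector<double> w(ndir);
    bool any = false;
    for (int d = 0; d < ndir; ++d) {
      double a = amp_at(A, nvox, d, tc);
      w[d] = (a >= stop_amp) ? a : 0.0;
      if (w[d] > 0) any = true;
    }
    if (!any) continue;
    int d0 = draw_cat(w);
    if (d0 < 0) continue;
    std::vector<double> h1 = grow_half(A, nvox, dirs, cone, ia, dim,
                                       wm.data(), seed_mm, d0, step,
                                       stop_amp, max_steps_total);
    int left = max_steps_total - (int)(h1.size() / 3);
    std::vector<double> h2;
    if (left > 0)
      h2 = grow_half(A, nvox, dirs, cone, ia, dim, wm.data(), seed_mm,
                     antipode[d0], step, stop_amp, left);
    int n1 = (int)(h1.size() / 3), n2 = (int)(h2.size() / 3);
    int npts = n1 + n2 + 1;
    double len = step * (n1 + n2);
    if (npts < 2 || len < min_len) continue;
    NumericMatrix sl(npts, 3);
    for (int i = 0; i < n2; ++i)          // reversed second half
      for (int a = 0; a < 3; ++a)
        sl(i, a) = h2[3 * (n2 - 1 - i) + a];
    for (int a = 0; a < 3; ++a) sl(n2, a) = seed_mm[a];
    for (int i = 0; i < n1; ++i)
      for (int a = 0; a < 3; ++a) sl(n2 + 1 + i, a) = h1[3 * i + a];
    out[n_ok++] = sl;
    if (n_ok % 256 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_ok < n_streamlines) {
    List trimmed(n_ok);
    for (int i = 0; i < n_ok; ++i) trimmed[i] = out[i];
    out = trimmed;
  }
  return List::create(_["streamlines"] = out, _["attempts"] = attempts);
}

// ---------------------------------------------------------------------------
// LiFE design matrix: per-voxel mean stick attenuation per streamline,
// demeaned over the diffusion-weighted directions of each voxel block
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List life_matrix_cpp(const List& streamlines, const NumericMatrix& inv_affine,
                     const IntegerVector& dim3, const IntegerVector& wm_mask,
                     const NumericMatrix& grad, const NumericVector& bvals_dw,
                     double d_axial) {
  const int ndir = grad.nrow();
  int dim[3] = {dim3[0], dim3[1], dim3[2]};
  double ia[12];
  for (int c = 0; c < 4; ++c)
    for (int r = 0; r < 3; ++r) ia[r + 3 * c] = inv_affine(r, c);
  std::unordered_map<long, int> vox_rank;
  std::vector<long> vox_list;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  std::vector<int> zero_cols;
  const int ns = streamlines.size();
  for (int s = 0; s < ns; ++s) {
    NumericMatrix pts = streamlines[s];
    const int np = pts.nrow();
    // accumulate per-voxel summed attenuation over this streamline's segments
    std::unordered_map<long, std::pair<std::vector<double>, int>> acc;
    for (int q = 0; q + 1 < np; ++q) {
      double t[3] = {pts(q + 1, 0) - pts(q, 0), pts(q + 1, 1) - pts(q, 1),
                     pts(q + 1, 2) - pts(q, 2)};
      double nrm = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      if (nrm <= 0) continue;
      for (int a = 0; a < 3; ++a) t[a] /= nrm;
      double mid[3] = {0.5 * (pts(q, 0) + pts(q + 1, 0)),
                       0.5 * (pts(q, 1) + pts(q + 1, 1)),
                       0.5 * (pts(q, 2) + pts(q + 1, 2))};
      double v[3];
      mm_to_vox(ia, mid, v);
      int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]),
          k = (int)std::lround(v[2]);
      if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] ||
          k >= dim[2]) continue;
      long lin = vox_lin(i, j, k, dim);
      if (!wm_mask[lin]) continue;
      auto& slot = acc[lin];
      if (slot.first.empty()) slot.first.assign(ndir, 0.0);
      for (int d = 0; d < ndir; ++d) {
        double dp = grad(d, 0) * t[0] + grad(d, 1) * t[1] +
                    grad(d, 2) * t[2];
        slot.first[d] += std::exp(-bvals_dw[d] * d_axial * dp * dp);
      }
      slot.second += 1;
    }
    if (acc.empty()) { zero_cols.push_back(s + 1); continue; }
    for (auto& kv : acc) {
      long lin = kv.first;
      auto it = vox_rank.find(lin);
      int rank;
      if (it == vox_rank.end()) {
        rank = (int)vox_list.size();
        vox_rank[lin] = rank;
        vox_list.push_back(lin);
      } else rank = it->second;
      std::vector<double>& c = kv.second.first;
      double mean = 0;
      for (int d = 0; d < ndir; ++d) mean += c[d];
      mean /= (double)ndir * kv.second.second;
      for (int d = 0; d < ndir; ++d) {
        double val = c[d] / kv.second.second - mean;
        ti.push_back(rank * ndir + d + 1);   // 1-based for Matrix
        tj.push_back(s + 1);
        tx.push_back(val);
      }
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["i"] = IntegerVector(ti.begin(), ti.end()),
      _["j"] = IntegerVector(tj.begin(), tj.end()),
      _["x"] = NumericVector(tx.begin(), tx.end()),
      _["voxels"] = IntegerVector(vox_list.begin(), vox_list.end()),
      _["zero_columns"] = IntegerVector(zero_cols.begin(), zero_cols.end()));
}

// ---------------------------------------------------------------------------
// Non-negative least squares by cyclic coordinate descent on a CSC matrix
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nnls_cd_cpp(const IntegerVector& p, const IntegerVector& ridx,
                 const NumericVector& x, int nrow, int ncol,
                 const NumericVector& y, NumericVector w0, int max_iter,
                 double tol) {
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> r(y.begin(), y.end());
  // residual r = y - M w for warm starts
  for (int j = 0; j < ncol; ++j) {
    if (w[j] == 0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) r[ridx[k]] -= x[k] * w[j];
  }
  std::vector<double> nj(ncol, 0.0);
  for (int j = 0; j < ncol; ++j)
    for (int k = p[j]; k < p[j + 1]; ++k) nj[j] += x[k] * x[k];
  double obj = 0;
  for (int i = 0; i < nrow; ++i) obj += r[i] * r[i];
  obj *= 0.5;
  auto sweep = [&](const std::vector<int>& cols) {
    for (int j : cols) {
      if (nj[j] <= 0) continue;
      double g = 0;
      for (int k = p[j]; k < p[j + 1]; ++k) g += x[k] * r[ridx[k]];
      double wn = w[j] + g / nj[j];
      if (wn < 0) wn = 0;
      double d = wn - w[j];
      if (d != 0) {
        for (int k = p[j]; k < p[j + 1]; ++k) r[ridx[k]] -= x[k] * d;
        w[j] = wn;
      }
    }
    double o = 0;
    for (int i = 0; i < nrow; ++i) o += r[i] * r[i];
    return 0.5 * o;
  };
  std::vector<int> all(ncol);
  for (int j = 0; j < ncol; ++j) all[j] = j;
  bool conv = false;
  int it = 0;
  while (it < max_iter) {
    // full sweep over every coordinate
    double nobj = sweep(all);
    ++it;
    bool done = (obj - nobj) < tol * std::max(obj, 1e-300);
    obj = nobj;
    if (done) { conv = true; break; }
    // cheap inner sweeps restricted to the current active set
    std::vector<int> act;
    for (int j = 0; j < ncol; ++j) if (w[j] > 0) act.push_back(j);
    while (it < max_iter && !act.empty()) {
      nobj = sweep(act);
      ++it;
      bool idone = (obj - nobj) < tol * std::max(obj, 1e-300);
      obj = nobj;
      if (idone) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["objective"] = obj, _["iterations"] = it,
                      _["converged"] = conv);
}
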