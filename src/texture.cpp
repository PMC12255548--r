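// Compiled kernel for voxel-wise texture-map extraction.
//
// Mirrors the R reference implementations in R/texture-matrices.R exactly
// (same matrix conventions, feature formulas, direction averaging and
// degenerate-window rules); the R path is retained as the per-window oracle
// and the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int N_FEATURES = 59;
static const double INV_LOG2 = 1.4426950408889634; // 1/ln(2)

static inline double ent_term(double p) {
  return p > 0 ? -p * std::log(p) * INV_LOG2 : 0.0;
}

// Eigenvalues of a small symmetric matrix by cyclic Jacobi rotations.
static void jacobi_eigenvalues(std::vector<double>& A, int n,
                               std::vector<double>& eig) {
  for (int sweep = 0; sweep < 100; ++sweep) {
    double off = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) off += A[i * n + j] * A[i * n + j];
    if (off < 1e-22) break;
    for (int p = 0; p < n - 1; ++p) {
      for (int q = p + 1; q < n; ++q) {
        double apq = A[p * n + q];
        if (std::fabs(apq) < 1e-300) continue;
        double app = A[p * n + p], aqq = A[q * n + q];
        double theta = (aqq - app) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < n; ++k) {
          double akp = A[k * n + p], akq = A[k * n + q];
          A[k * n + p] = c * akp - s * akq;
          A[k * n + q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; ++k) {
          double apk = A[p * n + k], aqk = A[q * n + k];
          A[p * n + k] = c * apk - s * aqk;
          A[q * n + k] = s * apk + c * aqk;
        }
      }
    }
  }
  eig.resize(n);
  for (int i = 0; i < n; ++i) eig[i] = A[i * n + i];
}

struct Window {
  std::vector<int> li;   // level index per cell (0-based)
  std::vector<double> lv; // sorted distinct level values
  int nr, nc;
  int at(int r, int c) const { return li[r + nr * c]; }
};

// 24 GLCM features for one direction, accumulated into acc (order matches
// glcm_feature_names).
static void glcm_dir(const Window& w, int dr, int dc, double* acc) {
  int n = (int)w.lv.size();
  std::vector<double> M(n * n, 0.0);
  double tot = 0.0;
  for (int c = 0; c < w.nc; ++c) {
    for (int r = 0; r < w.nr; ++r) {
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= w.nr || c2 < 0 || c2 >= w.nc) continue;
      int a = w.at(r, c), b = w.at(r2, c2);
      M[a * n + b] += 1.0; M[b * n + a] += 1.0;
      tot += 2.0;
    }
  }
  // drop levels with zero marginal for this direction
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) rs += M[i * n + j];
    if (rs > 0) keep.push_back(i);
  }
  int m = (int)keep.size();
  if (m <= 1 || tot == 0) {
    double val = (m == 1) ? w.lv[keep[0]] : 0.0;
    acc[0] += val * val;              // Autocorrelation
    acc[5] += 1.0;                    // Correlation
    acc[9] += 1.0; acc[10] += 1.0; acc[11] += 1.0; acc[12] += 1.0; // Id*
    acc[16] += val;                   // JointAverage
    acc[17] += 1.0;                   // JointEnergy
    acc[19] += 1.0;                   // MCC
    acc[20] += 1.0;                   // MaximumProbability
    acc[21] += 2.0 * val;             // SumAverage
    return;
  }
  std::vector<double> p(m * m), px(m, 0.0), v(m);
  for (int i = 0; i < m; ++i) v[i] = w.lv[keep[i]];
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      p[i * m + j] = M[keep[i] * n + keep[j]] / tot;
      px[i] += p[i * m + j];
    }
  double mu = 0.0;
  for (int i = 0; i < m; ++i) mu += px[i] * v[i];
  double sig2 = 0.0;
  for (int i = 0; i < m; ++i) sig2 += px[i] * (v[i] - mu) * (v[i] - mu);

  double autoc = 0, prom = 0, shade = 0, tend = 0, contrast = 0;
  double da = 0, id = 0, idm = 0, idmn = 0, idn = 0, invvar = 0;
  double je = 0, hxy = 0, maxp = 0, corr_num = 0;
  // grouped distributions over |vi - vj| and vi + vj (labels are integers)
  int vmin = (int)v[0], vmax = (int)v[m - 1];
  std::vector<double> pdiff(vmax - vmin + 1, 0.0);
  std::vector<double> psum(2 * vmax + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      double pij = p[i * m + j];
      double vi = v[i], vj = v[j];
      double ad = std::fabs(vi - vj), vs = vi + vj;
      autoc += pij * vi * vj;
      double ctr = vs - 2.0 * mu;
      prom += pij * ctr * ctr * ctr * ctr;
      shade += pij * ctr * ctr * ctr;
      tend += pij * ctr * ctr;
      contrast += pij * (vi - vj) * (vi - vj);
      corr_num += pij * vi * vj;
      da += pij * ad;
      id += pij / (1.0 + ad);
      idm += pij / (1.0 + ad * ad);
      idmn += pij / (1.0 + ad * ad / ((double)m * m));
      idn += pij / (1.0 + ad / m);
      if (ad > 0) invvar += pij / (ad * ad);
      je += pij * pij;
      hxy += ent_term(pij);
      if (pij > maxp) maxp = pij;
      pdiff[(int)(ad + 0.5)] += pij;
      psum[(int)(vs + 0.5) - 2 * vmin] += pij;
    }
  }
  double dent = 0, dvar = 0;
  for (size_t k = 0; k < pdiff.size(); ++k) {
    dent += ent_term(pdiff[k]);
    dvar += pdiff[k] * ((double)k - da) * ((double)k - da);
  }
  double sent = 0, savg = 0;
  for (size_t k = 0; k < psum.size(); ++k) {
    sent += ent_term(psum[k]);
    savg += psum[k] * ((double)k + 2 * vmin);
  }
  double hx = 0;
  for (int i = 0; i < m; ++i) hx += ent_term(px[i]);
  double hxy1 = 0, hxy2 = 0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      double pxy = px[i] * px[j];
      if (p[i * m + j] > 0 && pxy > 0)
        hxy1 += -p[i * m + j] * std::log(pxy) * INV_LOG2;
      hxy2 += ent_term(pxy);
    }
  double imc1 = hx > 0 ? (hxy - hxy1) / hx : 0.0;
  double imc2arg = 1.0 - std::exp(-2.0 * (hxy2 - hxy));
  double imc2 = imc2arg > 0 ? std::sqrt(imc2arg) : 0.0;
  // MCC via the symmetric similarity transform S = D^-1/2 P D^-1/2 of the
  // row-stochastic A = D^-1 P: eig(Q) = eig(S)^2
  std::vector<double> S(m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      S[i * m + j] = p[i * m + j] / std::sqrt(px[i] * px[j]);
  std::vector<double> eig;
  jacobi_eigenvalues(S, m, eig);
  std::vector<double> q(m);
  for (int i = 0; i < m; ++i) q[i] = eig[i] * eig[i];
  std::sort(q.begin(), q.end(), std::greater<double>());
  double mcc = std::sqrt(std::min(std::max(q[1], 0.0), 1.0));
  double corr = sig2 > 0 ? (corr_num - mu * mu) / sig2 : 1.0;

  acc[0] += autoc;  acc[1] += prom;   acc[2] += shade; acc[3] += tend;
  acc[4] += contrast; acc[5] += corr; acc[6] += da;    acc[7] += dent;
  acc[8] += dvar;   acc[9] += id;     acc[10] += idm;  acc[11] += idmn;
  acc[12] += idn;   acc[13] += imc1;  acc[14] += imc2; acc[15] += invvar;
  acc[16] += mu;    acc[17] += je;    acc[18] += hxy;  acc[19] += mcc;
  acc[20] += maxp;  acc[21] += savg;  acc[22] += sent; acc[23] += sig2;
}

// 16 GLRLM features for one direction, accumulated into acc.
static void glrlm_dir(const Window& w, int dir, double* acc) {
  int n = (int)w.lv.size();
  int lmax = std::max(w.nr, w.nc);
  std::vector<double> P(n * lmax, 0.0); // P[i + n*(len-1)]
  // walk scan lines
  auto add_line = [&](int r0, int c0, int dr, int dc) {
    int prev = -1, len = 0;
    int r = r0, c = c0;
    while (r >= 0 && r < w.nr && c >= 0 && c < w.nc) {
      int v = w.at(r, c);
      if (v == prev) {
        ++len;
      } else {
        if (prev >= 0) P[prev + n * (len - 1)] += 1.0;
        prev = v; len = 1;
      }
      r += dr; c += dc;
    }
    if (prev >= 0) P[prev + n * (len - 1)] += 1.0;
  };
  if (dir == 0) {                 // (0,1): rows
    for (int r = 0; r < w.nr; ++r) add_line(r, 0, 0, 1);
  } else if (dir == 1) {          // (1,0): columns
    for (int c = 0; c < w.nc; ++c) add_line(0, c, 1, 0);
  } else if (dir == 2) {          // (1,1): diagonals
    for (int r = 0; r < w.nr; ++r) add_line(r, 0, 1, 1);
    for (int c = 1; c < w.nc; ++c) add_line(0, c, 1, 1);
  } else {                        // (1,-1): anti-diagonals
    for (int r = 0; r < w.nr; ++r) add_line(r, w.nc - 1, 1, -1);
    for (int c = 0; c < w.nc - 1; ++c) add_line(0, c, 1, -1);
  }
  double nr_runs = 0.0;
  for (double x : P) nr_runs += x;
  double np = (double)(w.nr * w.nc);
  double gln = 0, rln = 0, glv = 0, rv = 0, re = 0;
  double hgl = 0, lgl = 0, lre = 0, sre = 0;
  double lrhgl = 0, lrlgl = 0, srhgl = 0, srlgl = 0;
  double mu_g = 0, mu_r = 0;
  for (int i = 0; i < n; ++i) {
    double rs = 0;
    for (int l = 0; l < lmax; ++l) rs += P[i + n * l];
    gln += rs * rs;
  }
  for (int l = 0; l < lmax; ++l) {
    double cs = 0;
    for (int i = 0; i < n; ++i) cs += P[i + n * l];
    rln += cs * cs;
  }
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < lmax; ++l) {
      double pn = P[i + n * l] / nr_runs;
      mu_g += pn * w.lv[i];
      mu_r += pn * (l + 1.0);
    }
  for (int i = 0; i < n; ++i) {
    double v = w.lv[i], v2 = v * v;
    for (int l = 0; l < lmax; ++l) {
      double cnt = P[i + n * l];
      if (cnt == 0) continue;
      double rl = l + 1.0, rl2 = rl * rl;
      double pn = cnt / nr_runs;
      glv += pn * (v - mu_g) * (v - mu_g);
      rv += pn * (rl - mu_r) * (rl - mu_r);
      re += ent_term(pn);
      hgl += cnt * v2; lgl += cnt / v2;
      lre += cnt * rl2; sre += cnt / rl2;
      lrhgl += cnt * v2 * rl2; lrlgl += cnt * rl2 / v2;
      srhgl += cnt * v2 / rl2; srlgl += cnt / (v2 * rl2);
    }
  }
  acc[0] += gln / nr_runs;
  acc[1] += gln / (nr_runs * nr_runs);
  acc[2] += glv;
  acc[3] += hgl / nr_runs;
  acc[4] += lre / nr_runs;
  acc[5] += lrhgl / nr_runs;
  acc[6] += lrlgl / nr_runs;
  acc[7] += lgl / nr_runs;
  acc[8] += re;
  acc[9] += rln / nr_runs;
  acc[10] += rln / (nr_runs * nr_runs);
  acc[11] += nr_runs / np;
  acc[12] += rv;
  acc[13] += sre / nr_runs;
  acc[14] += srhgl / nr_runs;
  acc[15] += srlgl / nr_runs;
}

// 14 GLDM + 5 NGTDM features (8-neighbourhood), written into out.
static void gldm_ngtdm(const Window& w, double* gldm_out, double* ngtdm_out) {
  int n = (int)w.lv.size();
  int np = w.nr * w.nc;
  int jmax = 9; // dependence d in 0..8 -> j = d+1 in 1..9
  std::vector<double> P(n * jmax, 0.0);
  std::vector<double> s(n, 0.0);
  std::vector<double> cnt_lv(n, 0.0);
  for (int c = 0; c < w.nc; ++c) {
    for (int r = 0; r < w.nr; ++r) {
      int me = w.at(r, c);
      int d = 0, nb = 0;
      double sum = 0.0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= w.nr || c2 < 0 || c2 >= w.nc) continue;
          int o = w.at(r2, c2);
          ++nb; sum += w.lv[o];
          if (o == me) ++d;
        }
      P[me + n * d] += 1.0;
      s[me] += std::fabs(w.lv[me] - sum / nb);
      cnt_lv[me] += 1.0;
    }
  }
  double nz = (double)np;
  double de = 0, dnu = 0, dv = 0, gln = 0, glv = 0;
  double hgl = 0, lgl = 0, lde = 0, sde = 0;
  double ldhgl = 0, ldlgl = 0, sdhgl = 0, sdlgl = 0;
  double mu_j = 0, mu_g = 0;
  for (int i = 0; i < n; ++i) {
    double rs = 0;
    for (int j = 0; j < jmax; ++j) rs += P[i + n * j];
    gln += rs * rs;
  }
  for (int j = 0; j < jmax; ++j) {
    double cs = 0;
    for (int i = 0; i < n; ++i) cs += P[i + n * j];
    dnu += cs * cs;
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < jmax; ++j) {
      double pn = P[i + n * j] / nz;
      mu_g += pn * w.lv[i];
      mu_j += pn * (j + 1.0);
    }
  for (int i = 0; i < n; ++i) {
    double v = w.lv[i], v2 = v * v;
    for (int j = 0; j < jmax; ++j) {
      double cnt = P[i + n * j];
      if (cnt == 0) continue;
      double jj = j + 1.0, j2 = jj * jj;
      double pn = cnt / nz;
      de += ent_term(pn);
      dv += pn * (jj - mu_j) * (jj - mu_j);
      glv += pn * (v - mu_g) * (v - mu_g);
      hgl += cnt * v2; lgl += cnt / v2;
      lde += cnt * j2; sde += cnt / j2;
      ldhgl += cnt * v2 * j2; ldlgl += cnt * j2 / v2;
      sdhgl += cnt * v2 / j2; sdlgl += cnt / (v2 * j2);
    }
  }
  gldm_out[0] = de;
  gldm_out[1] = dnu / nz;
  gldm_out[2] = dnu / (nz * nz);
  gldm_out[3] = dv;
  gldm_out[4] = gln / nz;
  gldm_out[5] = glv;
  gldm_out[6] = hgl / nz;
  gldm_out[7] = lde / nz;
  gldm_out[8] = ldhgl / nz;
  gldm_out[9] = ldlgl / nz;
  gldm_out[10] = lgl / nz;
  gldm_out[11] = sde / nz;
  gldm_out[12] = sdhgl / nz;
  gldm_out[13] = sdlgl / nz;

  // NGTDM: order Busyness, Coarseness, Complexity, Contrast, Strength
  double nvp = (double)np;
  double ps = 0, ssum = 0;
  for (int i = 0; i < n; ++i) {
    ps += (cnt_lv[i] / nvp) * s[i];
    ssum += s[i];
  }
  int ngp = 0;
  for (int i = 0; i < n; ++i) if (cnt_lv[i] > 0) ++ngp;
  double busy = 0, coarse, cplx = 0, contr = 0, strength = 0;
  coarse = ps > 0 ? 1.0 / ps : 1e6;
  if (ngp > 1) {
    double bden = 0, csum = 0, stn = 0;
    for (int i = 0; i < n; ++i) {
      if (cnt_lv[i] == 0) continue;
      double pi = cnt_lv[i] / nvp, vi = w.lv[i];
      for (int j = 0; j < n; ++j) {
        if (cnt_lv[j] == 0) continue;
        double pj = cnt_lv[j] / nvp, vj = w.lv[j];
        double vd = vi - vj;
        bden += std::fabs(vi * pi - vj * pj);
        contr += pi * pj * vd * vd;
        csum += std::fabs(vd) * (pi * s[i] + pj * s[j]) / (pi + pj);
        stn += (pi + pj) * vd * vd;
      }
    }
    busy = bden > 0 ? ps / bden : 0.0;
    contr = contr / (ngp * (ngp - 1.0)) * (ssum / nvp);
    cplx = csum / nvp;
    strength = ssum > 0 ? stn / ssum : 0.0;
  }
  ngtdm_out[0] = busy;
  ngtdm_out[1] = coarse;
  ngtdm_out[2] = cplx;
  ngtdm_out[3] = contr;
  ngtdm_out[4] = strength;
}

static void window_features(const std::vector<int>& cells, int nr, int nc,
                            double* out) {
  Window w;
  w.nr = nr; w.nc = nc;
  std::vector<int> sorted(cells);
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  w.lv.assign(sorted.begin(), sorted.end());
  w.li.resize(cells.size());
  for (size_t i = 0; i < cells.size(); ++i) {
    w.li[i] = (int)(std::lower_bound(sorted.begin(), sorted.end(), cells[i]) -
                    sorted.begin());
  }
  std::fill(out, out + N_FEATURES, 0.0);
  const int drs[4] = {0, 1, 1, 1};
  const int dcs[4] = {1, 0, 1, -1};
  for (int d = 0; d < 4; ++d) {
    glcm_dir(w, drs[d], dcs[d], out);
    glrlm_dir(w, d, out + 24);
  }
  for (int k = 0; k < 24 + 16; ++k) out[k] /= 4.0;
  gldm_ngtdm(w, out + 40, out + 54);
}

// [[Rcpp::export(name = ".cpp_window_features")]]
NumericVector cpp_window_features(IntegerMatrix W) {
  std::vector<int> cells(W.begin(), W.end());
  NumericVector out(N_FEATURES);
  window_features(cells, W.nrow(), W.ncol(), REAL(out));
  return out;
}

// Extract all 59 features for every masked voxel. labels: integer 3D array
// (NA allowed); idx: 1-based linear indices of the window centres; half:
// window half-width in voxels. Windows are cropped at slice edges; windows
// containing NA yield NA rows.
// [[Rcpp::export(name = ".cpp_extract_features")]]
List cpp_extract_features(IntegerVector labels, IntegerVector dims,
                          IntegerVector idx, int half) {
  int d1 = dims[0], d2 = dims[1];
  int slice = d1 * d2;
  NumericMatrix out((int)idx.size(), N_FEATURES);
  std::fill(out.begin(), out.end(), NA_REAL);
  int n_degenerate = 0;
  std::vector<int> cells;
  for (int r = 0; r < (int)idx.size(); ++r) {
    int lin = idx[r] - 1;
    int k = lin / slice;
    int rem = lin % slice;
    int j = rem / d1;
    int i = rem % d1;
    int i0 = std::max(0, i - half), i1 = std::min(d1 - 1, i + half);
    int j0 = std::max(0, j - half), j1 = std::min(d2 - 1, j + half);
    int nr = i1 - i0 + 1, nc = j1 - j0 + 1;
    cells.clear();
    bool has_na = false;
    for (int cc = j0; cc <= j1 && !has_na; ++cc)
      for (int rr = i0; rr <= i1; ++rr) {
        int v = labels[rr + d1 * cc + slice * k];
        if (v == NA_INTEGER) { has_na = true; break; }
        cells.push_back(v);
      }
    if (has_na) continue;
    std::vector<double> feats(N_FEATURES);
    window_features(cells, nr, nc, feats.data());
    bool degen = true;
    for (size_t t = 1; t < cells.size(); ++t)
      if (cells[t] != cells[0]) { degen = false; break; }
    if (degen) ++n_degenerate;
    for (int f = 0; f < N_FEATURES; ++f) out(r, f) = feats[f];
  }
  return List::create(_["values"] = out, _["n_degenerate"] = n_degenerate);
}
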