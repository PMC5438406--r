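// Linear-kernel SVM trained in the dual by coordinate descent
// (Hsieh et al., ICML 2008), with an unregularised bias handled as an
// augmented constant feature, plus Platt sigmoid calibration fitted by the
// regularised Newton method of Lin, Weng & Keerthi (2007).  A hand-rolled
// solver is used because the exhaustive descriptor-subset search refits the
// classifier millions of times; correctness is cross-checked against
// e1071/libsvm in the test suite.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Dual coordinate descent for L1-loss linear SVM.
// X row-major (n x d), y in {-1,+1}.  Returns w of length d+1 (last = bias).
// ---------------------------------------------------------------------------
static void dcd_fit(const double *X, int n, int d, const int *y, double C,
                    std::vector<double> &w, int max_epochs = 200,
                    double tol = 0.01) {
  w.assign(d + 1, 0.0);
  std::vector<double> alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * d;
    double q = 1.0;  // bias feature
    for (int j = 0; j < d; ++j) q += xi[j] * xi[j];
    Qii[i] = q;
  }
  // randomised coordinate order and gradient-based shrinking, both from the
  // reference dual coordinate descent algorithm; the shuffle uses a local
  // xorshift generator with a fixed seed, so fits are fully deterministic
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) index[i] = i;
  uint64_t state = 88172645463325252ull ^ (uint64_t)(n * 2654435761u);
  auto rnd = [&state](int m) {
    state ^= state << 13;
    state ^= state >> 7;
    state ^= state << 17;
    return (int)(state % (uint64_t)m);
  };
  int active = n;
  double pg_max_old = 1e300, pg_min_old = -1e300;
  for (int ep = 0; ep < max_epochs; ++ep) {
    double pg_max = -1e300, pg_min = 1e300;
    for (int s = 0; s < active; ++s) {
      int r = s + rnd(active - s);
      std::swap(index[s], index[r]);
      int i = index[s];
      const double *xi = X + (size_t)i * d;
      double f = w[d];
      for (int j = 0; j < d; ++j) f += w[j] * xi[j];
      double G = y[i] * f - 1.0;
      double PG;
      if (alpha[i] <= 0.0) {
        if (G > pg_max_old) {          // shrink: optimal at the lower bound
          std::swap(index[s], index[--active]);
          --s;
          continue;
        }
        PG = std::min(G, 0.0);
      } else if (alpha[i] >= C) {
        if (G < pg_min_old) {          // shrink: optimal at the upper bound
          std::swap(index[s], index[--active]);
          --s;
          continue;
        }
        PG = std::max(G, 0.0);
      } else {
        PG = G;
      }
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(std::max(alpha[i] - G / Qii[i], 0.0), C);
        double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) {
      if (active == n) break;          // converged on the full problem
      active = n;                      // unshrink and re-check everything
      pg_max_old = 1e300;
      pg_min_old = -1e300;
      continue;
    }
    pg_max_old = (pg_max <= 0) ? 1e300 : pg_max;
    pg_min_old = (pg_min >= 0) ? -1e300 : pg_min;
  }
}

static inline double decision(const std::vector<double> &w, const double *x,
                              int d) {
  double f = w[d];
  for (int j = 0; j < d; ++j) f += w[j] * x[j];
  return f;
}

// ---------------------------------------------------------------------------
// Platt sigmoid: fit A, B in P(y=1|f) = 1 / (1 + exp(A f + B))
// ---------------------------------------------------------------------------
static void platt_fit(const std::vector<double> &f, const std::vector<int> &y01,
                      double &A, double &B) {
  int n = (int)f.size();
  double prior1 = 0, prior0 = 0;
  for (int i = 0; i < n; ++i) (y01[i] ? prior1 : prior0) += 1;
  double hi = (prior1 + 1.0) / (prior1 + 2.0);
  double lo = 1.0 / (prior0 + 2.0);
  std::vector<double> t(n);
  for (int i = 0; i < n; ++i) t[i] = y01[i] ? hi : lo;
  A = 0.0;
  B = std::log((prior0 + 1.0) / (prior1 + 1.0));
  const double min_step = 1e-10, sigma = 1e-12;
  double fval = 0.0;
  for (int i = 0; i < n; ++i) {
    double fApB = f[i] * A + B;
    if (fApB >= 0) fval += t[i] * fApB + std::log1p(std::exp(-fApB));
    else fval += (t[i] - 1.0) * fApB + std::log1p(std::exp(fApB));
  }
  for (int it = 0; it < 100; ++it) {
    double h11 = sigma, h22 = sigma, h21 = 0, g1 = 0, g2 = 0;
    for (int i = 0; i < n; ++i) {
      double fApB = f[i] * A + B, p, q;
      if (fApB >= 0) {
        p = std::exp(-fApB) / (1.0 + std::exp(-fApB));
        q = 1.0 / (1.0 + std::exp(-fApB));
      } else {
        p = 1.0 / (1.0 + std::exp(fApB));
        q = std::exp(fApB) / (1.0 + std::exp(fApB));
      }
      double d2 = p * q;
      h11 += f[i] * f[i] * d2;
      h22 += d2;
      h21 += f[i] * d2;
      double d1 = t[i] - p;
      g1 += f[i] * d1;
      g2 += d1;
    }
    if (std::fabs(g1) < 1e-5 && std::fabs(g2) < 1e-5) break;
    double det = h11 * h22 - h21 * h21;
    double dA = -(h22 * g1 - h21 * g2) / det;
    double dB = -(-h21 * g1 + h11 * g2) / det;
    double gd = g1 * dA + g2 * dB;
    double step = 1.0;
    bool ok = false;
    while (step >= min_step) {
      double nA = A + step * dA, nB = B + step * dB, nf = 0.0;
      for (int i = 0; i < n; ++i) {
        double fApB = f[i] * nA + nB;
        if (fApB >= 0) nf += t[i] * fApB + std::log1p(std::exp(-fApB));
        else nf += (t[i] - 1.0) * fApB + std::log1p(std::exp(fApB));
      }
      if (nf < fval + 1e-4 * step * gd) {
        A = nA; B = nB; fval = nf; ok = true; break;
      }
      step /= 2.0;
    }
    if (!ok) break;
  }
}

static inline double platt_prob(double f, double A, double B) {
  double fApB = f * A + B;
  if (fApB >= 0) {
    double e = std::exp(-fApB);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(fApB));
}

// ---------------------------------------------------------------------------
// One train/test evaluation: min-max scaling on the training rows, SVM fit,
// Platt calibration from 3-fold internal cross-validation decision values.
// Buffers are raw (unscaled) row-major matrices.
// ---------------------------------------------------------------------------
struct FitResult {
  std::vector<double> prob;   // calibrated P(positive) per test row
  std::vector<double> dec;    // decision values per test row
  bool skipped;
};

static void minmax_scale(std::vector<double> &tr, std::vector<double> &te,
                         int n_tr, int n_te, int d) {
  for (int j = 0; j < d; ++j) {
    double mn = 1e300, mx = -1e300;
    for (int i = 0; i < n_tr; ++i) {
      double v = tr[(size_t)i * d + j];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    double rng = mx - mn;
    if (rng <= 0) {  // constant training column maps to 0 everywhere
      for (int i = 0; i < n_tr; ++i) tr[(size_t)i * d + j] = 0.0;
      for (int i = 0; i < n_te; ++i) te[(size_t)i * d + j] = 0.0;
    } else {
      for (int i = 0; i < n_tr; ++i)
        tr[(size_t)i * d + j] = (tr[(size_t)i * d + j] - mn) / rng;
      for (int i = 0; i < n_te; ++i)
        te[(size_t)i * d + j] = (te[(size_t)i * d + j] - mn) / rng;
    }
  }
}

static FitResult fit_predict_core(std::vector<double> tr, std::vector<int> ytr,
                                  std::vector<double> te, int d, double C,
                                  bool calibrate, int max_epochs, double tol) {
  FitResult out;
  int n_tr = (int)ytr.size();
  int n_te = (int)(te.size() / std::max(d, 1));
  int n_pos = 0;
  for (int v : ytr) n_pos += v;
  if (n_pos == 0 || n_pos == n_tr) {
    out.skipped = true;
    return out;
  }
  out.skipped = false;
  minmax_scale(tr, te, n_tr, n_te, d);
  std::vector<int> ypm(n_tr);
  for (int i = 0; i < n_tr; ++i) ypm[i] = ytr[i] ? 1 : -1;

  double A = -1.0, B = 0.0;
  if (calibrate) {
    // 3-fold internal CV decision values for the sigmoid fit
    std::vector<double> f_cv;
    std::vector<int> y_cv;
    std::vector<double> sub;
    std::vector<int> ysub;
    std::vector<double> w;
    for (int fold = 0; fold < 3; ++fold) {
      sub.clear(); ysub.clear();
      int npos_sub = 0;
      for (int i = 0; i < n_tr; ++i) {
        if (i % 3 == fold) continue;
        sub.insert(sub.end(), tr.begin() + (size_t)i * d,
                   tr.begin() + (size_t)(i + 1) * d);
        ysub.push_back(ypm[i]);
        npos_sub += ytr[i];
      }
      if (npos_sub == 0 || npos_sub == (int)ysub.size()) continue;
      dcd_fit(sub.data(), (int)ysub.size(), d, ysub.data(), C, w,
              max_epochs, tol);
      for (int i = 0; i < n_tr; ++i) {
        if (i % 3 != fold) continue;
        f_cv.push_back(decision(w, tr.data() + (size_t)i * d, d));
        y_cv.push_back(ytr[i]);
      }
    }
    if ((int)f_cv.size() >= 2) platt_fit(f_cv, y_cv, A, B);
  }

  std::vector<double> w;
  dcd_fit(tr.data(), n_tr, d, ypm.data(), C, w, max_epochs, tol);
  out.prob.resize(n_te);
  out.dec.resize(n_te);
  for (int i = 0; i < n_te; ++i) {
    double f = decision(w, te.data() + (size_t)i * d, d);
    out.dec[i] = f;
    out.prob[i] = calibrate ? platt_prob(f, A, B) : f;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pooled AUC = Mann-Whitney statistic with average ranks for ties
// ---------------------------------------------------------------------------
static double auc_rank(const std::vector<double> &p, const std::vector<int> &y) {
  int n = (int)p.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return p[a] < p[b]; });
  double rank_pos = 0;
  long n1 = 0, n0 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && p[ord[j + 1]] == p[ord[i]]) ++j;
    double avg = (i + j) / 2.0 + 1.0;  // 1-based average rank of the tie group
    for (int k = i; k <= j; ++k)
      if (y[ord[k]]) rank_pos += avg;
    i = j + 1;
  }
  for (int k = 0; k < n; ++k) (y[k] ? n1 : n0) += 1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rank_pos - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}

// [[Rcpp::export]]
double cpp_auc(NumericVector prob, IntegerVector label) {
  std::vector<double> p(prob.begin(), prob.end());
  std::vector<int> y(label.begin(), label.end());
  return auc_rank(p, y);
}

// ---------------------------------------------------------------------------
// Exported single-split fit (used by fit_predict_one)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fit_predict(NumericMatrix Xtr, IntegerVector ytr, NumericMatrix Xte,
                     double C, bool calibrate, int max_epochs, double tol) {
  int n_tr = Xtr.nrow(), n_te = Xte.nrow(), d = Xtr.ncol();
  std::vector<double> tr((size_t)n_tr * d), te((size_t)n_te * d);
  for (int i = 0; i < n_tr; ++i)
    for (int j = 0; j < d; ++j) tr[(size_t)i * d + j] = Xtr(i, j);
  for (int i = 0; i < n_te; ++i)
    for (int j = 0; j < d; ++j) te[(size_t)i * d + j] = Xte(i, j);
  std::vector<int> y(ytr.begin(), ytr.end());
  FitResult r = fit_predict_core(tr, y, te, d, C, calibrate, 1000, 0.001);
  if (r.skipped) return List::create(_["skipped"] = true);
  return List::create(_["skipped"] = false,
                      _["prob"] = NumericVector(r.prob.begin(), r.prob.end()),
                      _["decision"] = NumericVector(r.dec.begin(), r.dec.end()));
}

// ---------------------------------------------------------------------------
// Repeated random-subsampling evaluation of one descriptor subset
// test_sets: list of 1-based row-index vectors
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_eval_repeats(NumericMatrix X, IntegerVector y, List test_sets,
                      double C, bool calibrate, int max_epochs, double tol) {
  int n = X.nrow(), d = X.ncol(), R = test_sets.size();
  std::vector<double> prob, dec;
  std::vector<int> lab, rep, row;
  int n_skipped = 0;
  std::vector<char> in_test(n);
  for (int r = 0; r < R; ++r) {
    IntegerVector te_idx = test_sets[r];
    std::fill(in_test.begin(), in_test.end(), 0);
    for (int i = 0; i < te_idx.size(); ++i) in_test[te_idx[i] - 1] = 1;
    std::vector<double> tr, te;
    std::vector<int> ytr, yte, te_rows;
    for (int i = 0; i < n; ++i) {
      if (in_test[i]) continue;
      for (int j = 0; j < d; ++j) tr.push_back(X(i, j));
      ytr.push_back(y[i]);
    }
    for (int i = 0; i < te_idx.size(); ++i) {
      int ri = te_idx[i] - 1;
      for (int j = 0; j < d; ++j) te.push_back(X(ri, j));
      yte.push_back(y[ri]);
      te_rows.push_back(ri + 1);
    }
    FitResult fr = fit_predict_core(tr, ytr, te, d, C, calibrate,
                                    max_epochs, tol);
    if (fr.skipped) { ++n_skipped; continue; }
    for (size_t i = 0; i < fr.prob.size(); ++i) {
      prob.push_back(fr.prob[i]);
      dec.push_back(fr.dec[i]);
      lab.push_back(yte[i]);
      rep.push_back(r + 1);
      row.push_back(te_rows[i]);
    }
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["prob"] = NumericVector(prob.begin(), prob.end()),
                      _["decision"] = NumericVector(dec.begin(), dec.end()),
                      _["label"] = IntegerVector(lab.begin(), lab.end()),
                      _["repeat_index"] = IntegerVector(rep.begin(), rep.end()),
                      _["row"] = IntegerVector(row.begin(), row.end()),
                      _["n_skipped"] = n_skipped);
}

// ---------------------------------------------------------------------------
// Exhaustive subset search: pooled AUC per mask, shared splits across masks.
// masks: n_masks x d 0/1 matrix.
//
// Refitting the SVM for every (mask, repeat) dominates the search cost, so
// this path avoids building per-mask submatrices: min-max scaling is fitted
// per repeat on the full columns once (it is column-wise, so restricting to
// a mask commutes with scaling), and the solver gathers the masked columns
// through an index vector.  All scratch buffers are reused across masks.
// The arithmetic (operation order included) matches fit_predict_core.
// ---------------------------------------------------------------------------

// reusable scratch for one dual coordinate descent fit
struct DcdScratch {
  std::vector<double> alpha, Qii;
  std::vector<int> index;
};

// DCD on the rows `rows` (stride-D matrix Xs) restricted to columns `cols`
static void dcd_fit_gather(const double *Xs, int D, const int *rows, int n,
                           const int *cols, int d, const int *y, double C,
                           std::vector<double> &w, DcdScratch &s,
                           int max_epochs, double tol) {
  w.assign(d + 1, 0.0);
  s.alpha.assign(n, 0.0);
  s.Qii.resize(n);
  s.index.resize(n);
  std::vector<double> &alpha = s.alpha;
  std::vector<double> &Qii = s.Qii;
  std::vector<int> &index = s.index;
  for (int i = 0; i < n; ++i) {
    const double *xi = Xs + (size_t)rows[i] * D;
    double q = 1.0;  // bias feature
    for (int j = 0; j < d; ++j) q += xi[cols[j]] * xi[cols[j]];
    Qii[i] = q;
  }
  for (int i = 0; i < n; ++i) index[i] = i;
  uint64_t state = 88172645463325252ull ^ (uint64_t)(n * 2654435761u);
  auto rnd = [&state](int m) {
    state ^= state << 13;
    state ^= state >> 7;
    state ^= state << 17;
    return (int)(state % (uint64_t)m);
  };
  int active = n;
  double pg_max_old = 1e300, pg_min_old = -1e300;
  for (int ep = 0; ep < max_epochs; ++ep) {
    double pg_max = -1e300, pg_min = 1e300;
    for (int sN = 0; sN < active; ++sN) {
      int r = sN + rnd(active - sN);
      std::swap(index[sN], index[r]);
      int i = index[sN];
      const double *xi = Xs + (size_t)rows[i] * D;
      double f = w[d];
      for (int j = 0; j < d; ++j) f += w[j] * xi[cols[j]];
      double G = y[i] * f - 1.0;
      double PG;
      if (alpha[i] <= 0.0) {
        if (G > pg_max_old) {
          std::swap(index[sN], index[--active]);
          --sN;
          continue;
        }
        PG = std::min(G, 0.0);
      } else if (alpha[i] >= C) {
        if (G < pg_min_old) {
          std::swap(index[sN], index[--active]);
          --sN;
          continue;
        }
        PG = std::max(G, 0.0);
      } else {
        PG = G;
      }
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(std::max(alpha[i] - G / Qii[i], 0.0), C);
        double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[cols[j]];
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) {
      if (active == n) break;
      active = n;
      pg_max_old = 1e300;
      pg_min_old = -1e300;
      continue;
    }
    pg_max_old = (pg_max <= 0) ? 1e300 : pg_max;
    pg_min_old = (pg_min >= 0) ? -1e300 : pg_min;
  }
}

static inline double decision_gather(const std::vector<double> &w,
                                     const double *xi, const int *cols,
                                     int d) {
  double f = w[d];
  for (int j = 0; j < d; ++j) f += w[j] * xi[cols[j]];
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_search_aucs(NumericMatrix X, IntegerVector y, List test_sets,
                              IntegerMatrix masks, double C, bool calibrate,
                              int max_epochs, double tol) {
  int n = X.nrow(), D = X.ncol(), R = test_sets.size();
  int M = masks.nrow();
  // per repeat: scaled full-column train/test matrices (row-major, stride D),
  // +/-1 and 0/1 train labels, calibration-fold row lists, degeneracy flags
  std::vector<std::vector<double>> tr_s(R), te_s(R);
  std::vector<std::vector<int>> ypm_all(R), yte_all(R);
  std::vector<std::vector<int>> fold_rows(R * 3), eval_rows(R * 3);
  std::vector<std::vector<int>> fold_ypm(R * 3);
  std::vector<char> rep_skip(R, 0), fold_skip(R * 3, 0);
  std::vector<char> in_test(n);
  for (int r = 0; r < R; ++r) {
    IntegerVector te_idx = test_sets[r];
    std::fill(in_test.begin(), in_test.end(), 0);
    for (int i = 0; i < te_idx.size(); ++i) in_test[te_idx[i] - 1] = 1;
    std::vector<int> ytr;
    for (int i = 0; i < n; ++i) {
      if (in_test[i]) continue;
      for (int j = 0; j < D; ++j) tr_s[r].push_back(X(i, j));
      ytr.push_back(y[i]);
    }
    for (int i = 0; i < te_idx.size(); ++i) {
      int ri = te_idx[i] - 1;
      for (int j = 0; j < D; ++j) te_s[r].push_back(X(ri, j));
      yte_all[r].push_back(y[ri]);
    }
    int n_tr = (int)ytr.size(), n_te = (int)yte_all[r].size();
    minmax_scale(tr_s[r], te_s[r], n_tr, n_te, D);
    int n_pos = 0;
    for (int v : ytr) n_pos += v;
    if (n_pos == 0 || n_pos == n_tr) rep_skip[r] = 1;
    ypm_all[r].resize(n_tr);
    for (int i = 0; i < n_tr; ++i) ypm_all[r][i] = ytr[i] ? 1 : -1;
    for (int fold = 0; fold < 3; ++fold) {
      int k = r * 3 + fold, npos_sub = 0;
      for (int i = 0; i < n_tr; ++i) {
        if (i % 3 == fold) {
          eval_rows[k].push_back(i);
        } else {
          fold_rows[k].push_back(i);
          fold_ypm[k].push_back(ypm_all[r][i]);
          npos_sub += ytr[i];
        }
      }
      if (npos_sub == 0 || npos_sub == (int)fold_rows[k].size())
        fold_skip[k] = 1;
    }
  }
  NumericVector aucs(M);
  DcdScratch scratch;
  std::vector<double> w, f_cv, pool_p;
  std::vector<int> y_cv, pool_y, cols, all_rows;
  for (int mi = 0; mi < M; ++mi) {
    cols.clear();
    for (int j = 0; j < D; ++j)
      if (masks(mi, j)) cols.push_back(j);
    int d = (int)cols.size();
    pool_p.clear();
    pool_y.clear();
    for (int r = 0; r < R; ++r) {
      if (rep_skip[r]) continue;
      int n_tr = (int)ypm_all[r].size(), n_te = (int)yte_all[r].size();
      const double *Xtr = tr_s[r].data();
      double A = -1.0, B = 0.0;
      if (calibrate) {
        f_cv.clear();
        y_cv.clear();
        for (int fold = 0; fold < 3; ++fold) {
          int k = r * 3 + fold;
          if (fold_skip[k]) continue;
          dcd_fit_gather(Xtr, D, fold_rows[k].data(),
                         (int)fold_rows[k].size(), cols.data(), d,
                         fold_ypm[k].data(), C, w, scratch, max_epochs, tol);
          for (int i : eval_rows[k]) {
            f_cv.push_back(decision_gather(w, Xtr + (size_t)i * D,
                                           cols.data(), d));
            y_cv.push_back(ypm_all[r][i] > 0 ? 1 : 0);
          }
        }
        if ((int)f_cv.size() >= 2) platt_fit(f_cv, y_cv, A, B);
      }
      if ((int)all_rows.size() < n_tr) {
        all_rows.resize(n_tr);
        for (int i = 0; i < n_tr; ++i) all_rows[i] = i;
      }
      dcd_fit_gather(Xtr, D, all_rows.data(), n_tr, cols.data(), d,
                     ypm_all[r].data(), C, w, scratch, max_epochs, tol);
      for (int i = 0; i < n_te; ++i) {
        double f = decision_gather(w, te_s[r].data() + (size_t)i * D,
                                   cols.data(), d);
        pool_p.push_back(calibrate ? platt_prob(f, A, B) : f);
        pool_y.push_back(yte_all[r][i]);
      }
    }
    aucs[mi] = pool_p.empty() ? NA_REAL : auc_rank(pool_p, pool_y);
    if ((mi & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return aucs;
}
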