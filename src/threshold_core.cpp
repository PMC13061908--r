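// Core resampling kernels for threshold-classifier search.
//
// A threshold model is (orientation, cutoff): predict high-stress iff
// score >= cutoff (orientation +1) or score < cutoff (orientation -1).
// The cutoff is chosen by maximising the Youden index J = sens + spec - 1
// over all midpoints between consecutive distinct sorted scores plus the
// two infinite boundaries. Ties in J are broken by higher specificity,
// then the smaller cutoff, then orientation +1; all comparisons use
// integer-scaled counts so results are exactly deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Fit {
  int orient;       // +1 high predicts positive, -1 low predicts positive
  double cutoff;
  long jnum;        // J scaled by n1*n0
  long specnum;     // specificity scaled by n0
  int n1, n0;
};

struct Obs {
  double score;
  int label;        // 1 = high-stress
  int slot;         // resampling unit slot (-1 = none)
};

static inline bool obs_less(const Obs &a, const Obs &b) {
  return a.score < b.score;
}

// Evaluate one cut position (pos_below, neg_below counts of the training
// set strictly below the cutoff) for both orientations, updating best.
static inline void eval_position(long pos_below, long neg_below,
                                 double cutoff, int n1, int n0, Fit &best) {
  // orientation +1: positive iff score >= cutoff
  long j_high = neg_below * n1 - pos_below * n0;
  long spec_high = neg_below;
  if (j_high > best.jnum ||
      (j_high == best.jnum && spec_high > best.specnum)) {
    best.jnum = j_high; best.specnum = spec_high;
    best.cutoff = cutoff; best.orient = 1;
  }
  // orientation -1: positive iff score < cutoff
  long j_low = -j_high;
  long spec_low = (long)n0 - neg_below;
  if (j_low > best.jnum ||
      (j_low == best.jnum && spec_low > best.specnum)) {
    best.jnum = j_low; best.specnum = spec_low;
    best.cutoff = cutoff; best.orient = -1;
  }
}

// Youden scan over a sorted observation array, skipping observations whose
// slot equals skip (-1 skips nothing). n1/n0 are the training class counts
// after the skip.
static Fit youden_scan_n(const Obs *sorted, int n, int skip,
                         int n1, int n0) {
  Fit best;
  best.jnum = -1; best.specnum = -1; best.cutoff = R_NegInf;
  best.orient = 1; best.n1 = n1; best.n0 = n0;
  long pos_below = 0, neg_below = 0;
  bool have_prev = false;
  double prev = 0.0;
  eval_position(0, 0, R_NegInf, n1, n0, best);
  for (int i = 0; i < n; ++i) {
    if (sorted[i].slot == skip) continue;
    if (have_prev && sorted[i].score > prev) {
      eval_position(pos_below, neg_below, (prev + sorted[i].score) / 2.0,
                    n1, n0, best);
    }
    if (sorted[i].label == 1) ++pos_below; else ++neg_below;
    prev = sorted[i].score;
    have_prev = true;
  }
  eval_position(pos_below, neg_below, R_PosInf, n1, n0, best);
  return best;
}

static Fit youden_scan(const std::vector<Obs> &sorted, int skip,
                       int n1, int n0) {
  return youden_scan_n(sorted.data(), (int)sorted.size(), skip, n1, n0);
}

static inline bool fit_predict(const Fit &f, double score) {
  return f.orient == 1 ? (score >= f.cutoff) : (score < f.cutoff);
}

static double median_of(std::vector<double> v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// rank-based AUC with tie handling (average ranks); labels 1/0
static double auc_rank(const std::vector<double> &s,
                       const std::vector<int> &y) {
  size_t m = s.size();
  std::vector<size_t> idx(m);
  for (size_t i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return s[a] < s[b]; });
  std::vector<double> rank(m);
  size_t i = 0;
  while (i < m) {
    size_t j = i;
    while (j + 1 < m && s[idx[j + 1]] == s[idx[i]]) ++j;
    double r = (double)(i + j) / 2.0 + 1.0;
    for (size_t t = i; t <= j; ++t) rank[idx[t]] = r;
    i = j + 1;
  }
  double rsum = 0.0;
  long n1 = 0;
  for (size_t t = 0; t < m; ++t)
    if (y[t] == 1) { rsum += rank[t]; ++n1; }
  long n0 = (long)m - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - (double)n1 * (n1 + 1) / 2.0) / ((double)n1 * n0);
}

// Full LOOCV over resampling slots for one score vector.
// scores: per sample; slot: 0-based slot id per sample; slot_label: per slot.
// Returns held-out median scores, predictions (NA = skipped fold) and the
// full-data fit, plus pooled metrics (AUC oriented by the full-data fit).
static List loocv_one(const std::vector<double> &scores,
                      const std::vector<int> &slot,
                      const std::vector<int> &slot_label,
                      bool want_detail) {
  int n = scores.size();
  int m = slot_label.size();
  std::vector<Obs> sorted(n);
  int N1 = 0, N0 = 0;
  std::vector<int> slot_n1(m, 0), slot_n0(m, 0);
  std::vector<std::vector<double> > slot_scores(m);
  for (int i = 0; i < n; ++i) {
    sorted[i].score = scores[i];
    sorted[i].label = slot_label[slot[i]];
    sorted[i].slot = slot[i];
    if (sorted[i].label == 1) { ++N1; ++slot_n1[slot[i]]; }
    else { ++N0; ++slot_n0[slot[i]]; }
    slot_scores[slot[i]].push_back(scores[i]);
  }
  if (N1 == 0 || N0 == 0) stop("both classes must be present");
  std::sort(sorted.begin(), sorted.end(), obs_less);
  Fit full = youden_scan(sorted, -1, N1, N0);

  std::vector<double> med(m);
  std::vector<int> pred(m, NA_INTEGER);
  int tp = 0, tn = 0, fp = 0, fn = 0, used = 0;
  std::vector<double> held;
  std::vector<int> held_lab;
  for (int j = 0; j < m; ++j) {
    med[j] = median_of(slot_scores[j]);
    int n1 = N1 - slot_n1[j], n0 = N0 - slot_n0[j];
    if (n1 == 0 || n0 == 0) continue;  // single-class fold: skipped
    Fit f = youden_scan(sorted, j, n1, n0);
    bool p = fit_predict(f, med[j]);
    pred[j] = p ? 1 : 0;
    ++used;
    if (slot_label[j] == 1) { if (p) ++tp; else ++fn; }
    else { if (p) ++fp; else ++tn; }
    held.push_back(full.orient * med[j]);
    held_lab.push_back(slot_label[j]);
  }
  double acc = used > 0 ? (double)(tp + tn) / used : NA_REAL;
  long f1den = 2L * tp + fp + fn;
  double f1 = f1den > 0 ? 2.0 * tp / (double)f1den : 1.0;
  double auc = auc_rank(held, held_lab);
  List out = List::create(
    _["auc"] = auc, _["accuracy"] = acc, _["f1"] = f1,
    _["orientation"] = full.orient, _["cutoff"] = full.cutoff,
    _["J"] = (double)full.jnum / ((double)full.n1 * full.n0),
    _["n_folds_used"] = used);
  if (want_detail) {
    out["heldout_score"] = NumericVector(med.begin(), med.end());
    out["prediction"] = IntegerVector(pred.begin(), pred.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_youden(NumericVector scores, IntegerVector labels) {
  int n = scores.size();
  if (labels.size() != n) stop("scores and labels differ in length");
  std::vector<Obs> sorted(n);
  int n1 = 0, n0 = 0;
  for (int i = 0; i < n; ++i) {
    sorted[i].score = scores[i];
    sorted[i].label = labels[i];
    sorted[i].slot = -2;
    if (labels[i] == 1) ++n1; else ++n0;
  }
  if (n1 == 0 || n0 == 0) stop("both classes must be present");
  std::sort(sorted.begin(), sorted.end(), obs_less);
  Fit f = youden_scan(sorted, -1, n1, n0);
  double J = (double)f.jnum / ((double)n1 * n0);
  double spec = (double)f.specnum / n0;
  return List::create(
    _["orientation"] = f.orient, _["cutoff"] = f.cutoff,
    _["J"] = J,
    _["sensitivity"] = J + 1.0 - spec,
    _["specificity"] = spec);
}

// [[Rcpp::export]]
List cpp_loocv(NumericVector scores, IntegerVector slot,
               IntegerVector slot_label) {
  std::vector<double> s(scores.begin(), scores.end());
  std::vector<int> sl(slot.begin(), slot.end());
  std::vector<int> lab(slot_label.begin(), slot_label.end());
  return loocv_one(s, sl, lab, true);
}

// Column-wise type-7 quantiles (the stats::quantile default), NA removed.
// [[Rcpp::export]]
NumericMatrix cpp_col_quantiles(NumericMatrix x, NumericVector probs) {
  int C = x.ncol(), P = probs.size();
  NumericMatrix out(P, C);
  std::vector<double> col;
  col.reserve(x.nrow());
  for (int c = 0; c < C; ++c) {
    col.clear();
    for (int i = 0; i < x.nrow(); ++i)
      if (!ISNAN(x(i, c))) col.push_back(x(i, c));
    int n = col.size();
    if (n == 0) {
      for (int p = 0; p < P; ++p) out(p, c) = NA_REAL;
      continue;
    }
    std::sort(col.begin(), col.end());
    for (int p = 0; p < P; ++p) {
      double h = (n - 1) * probs[p];
      int lo = (int)std::floor(h);
      int hi = std::min(lo + 1, n - 1);
      out(p, c) = col[lo] + (h - lo) * (col[hi] - col[lo]);
    }
  }
  return out;
}

// Bootstrap-LOOCV evaluation of many candidate score vectors.
// scoremat: n_samples x n_candidates; unit: 0-based unit per sample;
// unit_label: per original unit; boot_units: m x B matrix of 0-based unit
// ids (columns are bootstrap replicates). Returns B x C matrices of AUC,
// accuracy and F1. The inner loop runs over ~10^5 candidate x replicate
// pairs, so all buffers are hoisted out of it.
// [[Rcpp::export]]
List cpp_eval_candidates(NumericMatrix scoremat, IntegerVector unit,
                         IntegerVector unit_label, IntegerMatrix boot_units) {
  int n = scoremat.nrow(), C = scoremat.ncol();
  int M = unit_label.size();
  int m = boot_units.nrow(), B = boot_units.ncol();
  std::vector<std::vector<int> > samples_of(M);
  for (int i = 0; i < n; ++i) {
    if (unit[i] < 0 || unit[i] >= M) stop("unit index out of range");
    samples_of[unit[i]].push_back(i);
  }
  NumericMatrix aucm(B, C), accm(B, C), f1m(B, C);
  // reusable buffers (worst-case replicate size: every unit has the most
  // samples any unit has)
  size_t max_per = 1;
  for (int u = 0; u < M; ++u) max_per = std::max(max_per,
                                                 samples_of[u].size());
  int cap = (int)(max_per * m);
  std::vector<int> samp_idx(cap), samp_slot(cap), slot_off(m + 1);
  std::vector<int> slab(m), slot_n1(m), slot_n0(m);
  std::vector<Obs> sorted(cap);
  std::vector<double> medbuf(max_per), med(m), held(m);
  std::vector<int> held_lab(m);
  for (int b = 0; b < B; ++b) {
    int nb = 0, N1 = 0, N0 = 0;
    for (int j = 0; j < m; ++j) {
      int u = boot_units(j, b);
      if (u < 0 || u >= M) stop("bootstrap unit index out of range");
      slab[j] = unit_label[u];
      slot_off[j] = nb;
      int ns = (int)samples_of[u].size();
      for (int t = 0; t < ns; ++t) {
        samp_idx[nb] = samples_of[u][t];
        samp_slot[nb] = j;
        ++nb;
      }
      if (slab[j] == 1) { slot_n1[j] = ns; slot_n0[j] = 0; N1 += ns; }
      else { slot_n1[j] = 0; slot_n0[j] = ns; N0 += ns; }
    }
    slot_off[m] = nb;
    if (N1 == 0 || N0 == 0) stop("bootstrap replicate lost a class");
    for (int c = 0; c < C; ++c) {
      const double *sc = &REAL(scoremat)[(size_t)c * n];
      for (int i = 0; i < nb; ++i) {
        sorted[i].score = sc[samp_idx[i]];
        sorted[i].label = slab[samp_slot[i]];
        sorted[i].slot = samp_slot[i];
      }
      std::sort(sorted.begin(), sorted.begin() + nb, obs_less);
      Fit full = youden_scan_n(sorted.data(), nb, -1, N1, N0);
      int tp = 0, tn = 0, fp = 0, fn = 0, used = 0, nheld = 0;
      for (int j = 0; j < m; ++j) {
        int ns = slot_off[j + 1] - slot_off[j];
        for (int t = 0; t < ns; ++t)
          medbuf[t] = sc[samp_idx[slot_off[j] + t]];
        std::sort(medbuf.begin(), medbuf.begin() + ns);
        double mj = (ns % 2 == 1) ? medbuf[ns / 2]
          : (medbuf[ns / 2 - 1] + medbuf[ns / 2]) / 2.0;
        med[j] = mj;
        int n1 = N1 - slot_n1[j], n0 = N0 - slot_n0[j];
        if (n1 == 0 || n0 == 0) continue;
        Fit f = youden_scan_n(sorted.data(), nb, j, n1, n0);
        bool p = fit_predict(f, mj);
        ++used;
        if (slab[j] == 1) { if (p) ++tp; else ++fn; }
        else { if (p) ++fp; else ++tn; }
        held[nheld] = full.orient * mj;
        held_lab[nheld] = slab[j];
        ++nheld;
      }
      accm(b, c) = used > 0 ? (double)(tp + tn) / used : NA_REAL;
      long f1den = 2L * tp + fp + fn;
      f1m(b, c) = f1den > 0 ? 2.0 * tp / (double)f1den : 1.0;
      std::vector<double> hs(held.begin(), held.begin() + nheld);
      std::vector<int> hl(held_lab.begin(), held_lab.begin() + nheld);
      aucm(b, c) = auc_rank(hs, hl);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["auc"] = aucm, _["accuracy"] = accm, _["f1"] = f1m);
}
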