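// Chip-scale melt-peak scanner.  Mirrors the reference R implementation in
// R/meltcall.R (findPeaks + estimateTmFwhm + the two-scale composition in
// callWell) row by row; a unit test pins the two code paths to each other.
//
// Detection (apex, Tm, prominence) runs on the mildly smoothed derivative
// `deriv`; width measurement runs on the heavily smoothed derivative
// `deriv_f`, whose column j corresponds to detection column j + off, and is
// mapped back through the exact kernel calibration (cal_raw -> cal_true).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (hi + v[n / 2 - 1]);
}

// first-difference MAD: structure-free noise floor (see R/meltcall.R)
static double robust_sigma(const std::vector<double>& y,
                           std::vector<double>& scratch) {
  const size_t n = y.size();
  if (n < 2) return 0.0;
  scratch.resize(n - 1);
  for (size_t i = 0; i + 1 < n; ++i) scratch[i] = y[i + 1] - y[i];
  std::vector<double> tmp(scratch);
  double med = median_inplace(tmp);
  for (size_t i = 0; i < scratch.size(); ++i)
    scratch[i] = std::fabs(scratch[i] - med);
  return 1.4826 * median_inplace(scratch) / std::sqrt(2.0);
}

static double prominence_at(const std::vector<double>& y, int i) {
  const int n = (int)y.size();
  double lmin = y[i];
  for (int j = i - 1; j >= 0; --j) {
    if (y[j] > y[i]) break;
    lmin = std::min(lmin, y[j]);
  }
  double rmin = y[i];
  for (int j = i + 1; j < n; ++j) {
    if (y[j] > y[i]) break;
    rmin = std::min(rmin, y[j]);
  }
  return y[i] - std::max(lmin, rmin);
}

// half-height crossing walk; returns crossing temperature or NA; sets
// truncated when the walk runs off the grid before crossing
static double walk_half(const std::vector<double>& y, int apex, int step,
                        double half, double valley_tol, double t_apex0,
                        double h, bool& truncated) {
  // t of index j is t_apex0 + (j - apex) * h
  const int n = (int)y.size();
  int j = apex;
  double run_min = y[apex];
  while (true) {
    int jn = j + step;
    if (jn < 0 || jn >= n) { truncated = true; return NA_REAL; }
    double yj = y[jn];
    if (yj <= half) {
      double frac = (y[j] - half) / (y[j] - yj);
      return t_apex0 + (j - apex) * h + step * frac * h;
    }
    run_min = std::min(run_min, yj);
    if (yj - run_min > valley_tol) return NA_REAL;  // overlapping peak
    j = jn;
  }
}

static double fwhm_from_raw(double raw, const NumericVector& cal_raw,
                            const NumericVector& cal_true) {
  const int n = cal_raw.size();
  if (raw <= cal_raw[0]) return cal_true[0];
  if (raw >= cal_raw[n - 1]) return cal_true[n - 1] + (raw - cal_raw[n - 1]);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (cal_raw[mid] <= raw) lo = mid; else hi = mid;
  }
  double f = (raw - cal_raw[lo]) / (cal_raw[hi] - cal_raw[lo]);
  return cal_true[lo] + f * (cal_true[hi] - cal_true[lo]);
}

// local max of y within +/- steps of i0, walked uphill if clipped;
// -1 when no interior local maximum is reachable
static int relocalize_apex(const std::vector<double>& y, int i0,
                           int steps = 4) {
  const int n = (int)y.size();
  int lo = std::max(1, i0 - steps), hi = std::min(n - 2, i0 + steps);
  if (lo > hi) return -1;
  int best = lo;
  for (int j = lo + 1; j <= hi; ++j) if (y[j] > y[best]) best = j;
  while (best > 0 && best < n - 1 &&
         (y[best - 1] > y[best] || y[best + 1] > y[best]))
    best = (y[best - 1] > y[best]) ? best - 1 : best + 1;
  if (best <= 0 || best >= n - 1) return -1;
  return best;
}

// [[Rcpp::export]]
DataFrame scan_peaks(NumericMatrix deriv, NumericMatrix deriv_f,
                     NumericVector temps, int off, double k_mad,
                     double min_prom, double min_height, int merge_steps,
                     NumericVector cal_raw, NumericVector cal_true) {
  const int n_row = deriv.nrow(), n = deriv.ncol(), nf = deriv_f.ncol();
  if (n != temps.size()) stop("derivative/temperature length mismatch");
  if (deriv_f.nrow() != n_row) stop("derivative matrices disagree in rows");
  const double h = (n > 1) ? (temps[1] - temps[0]) : 1.0;

  std::vector<int> o_row;
  std::vector<double> o_tm, o_fwhm, o_height, o_prom;
  std::vector<int> o_trunc;
  std::vector<double> y(n), yf(nf), scratch;
  std::vector<int> cand;
  std::vector<double> prom;

  for (int r = 0; r < n_row; ++r) {
    for (int c = 0; c < n; ++c) y[c] = deriv(r, c);
    double sigma = robust_sigma(y, scratch);
    double thr = std::max(min_prom, k_mad * sigma);

    cand.clear(); prom.clear();
    for (int i = 1; i < n - 1; ++i) {
      if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] >= min_height) {
        double p = prominence_at(y, i);
        if (p >= thr) { cand.push_back(i); prom.push_back(p); }
      }
    }
    // merge apexes within merge_steps (higher wins; tie: lower temperature)
    size_t m = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      if (m > 0 && cand[i] - cand[m - 1] <= merge_steps) {
        if (y[cand[i]] > y[cand[m - 1]]) {
          cand[m - 1] = cand[i]; prom[m - 1] = prom[i];
        }
      } else {
        cand[m] = cand[i]; prom[m] = prom[i]; ++m;
      }
    }
    cand.resize(m); prom.resize(m);
    if (cand.empty()) continue;

    for (int c = 0; c < nf; ++c) yf[c] = deriv_f(r, c);
    double sigma_f = robust_sigma(yf, scratch);

    for (size_t kk = 0; kk < cand.size(); ++kk) {
      int i = cand[kk];
      // Tm and height on the detection scale
      double y0 = y[i], ym = y[i - 1], yp = y[i + 1];
      double den = ym - 2.0 * y0 + yp;
      double delta = (den < 0) ? 0.5 * (ym - yp) / den : 0.0;
      delta = std::max(-0.5, std::min(0.5, delta));
      double tm = temps[i] + delta * h;
      double height = y0 - 0.25 * (ym - yp) * delta;

      // FWHM on the width-measurement scale
      double fwhm = NA_REAL;
      bool truncated = false;
      int iH = relocalize_apex(yf, i - off);
      if (iH < 0) truncated = true;
      else {
        double f0 = yf[iH], fm = yf[iH - 1], fp = yf[iH + 1];
        double denf = fm - 2.0 * f0 + fp;
        double deltaf = (denf < 0) ? 0.5 * (fm - fp) / denf : 0.0;
        deltaf = std::max(-0.5, std::min(0.5, deltaf));
        double heightf = f0 - 0.25 * (fm - fp) * deltaf;
        double tmf = temps[iH + off] + deltaf * h;
        double half = heightf / 2.0;
        double valley_tol = std::max(3.0 * sigma_f, 0.05 * heightf);
        bool trunc_l = false, trunc_r = false;
        double tl = walk_half(yf, iH, -1, half, valley_tol,
                              temps[iH + off], h, trunc_l);
        double tr = walk_half(yf, iH, +1, half, valley_tol,
                              temps[iH + off], h, trunc_r);
        truncated = trunc_l || trunc_r;
        double wl = ISNA(tl) ? NA_REAL : tmf - tl;
        double wr = ISNA(tr) ? NA_REAL : tr - tmf;
        if (ISNA(wl)) wl = wr;
        if (ISNA(wr)) wr = wl;
        if (!ISNA(wl)) fwhm = fwhm_from_raw(wl + wr, cal_raw, cal_true);
      }
      o_row.push_back(r + 1);
      o_tm.push_back(tm);
      o_fwhm.push_back(fwhm);
      o_height.push_back(height);
      o_prom.push_back(prom[kk]);
      o_trunc.push_back(truncated ? 1 : 0);
    }
  }
  return DataFrame::create(
      _["row"] = wrap(o_row), _["tm"] = wrap(o_tm), _["fwhm"] = wrap(o_fwhm),
      _["height"] = wrap(o_height), _["prominence"] = wrap(o_prom),
      _["truncated"] = LogicalVector(o_trunc.begin(), o_trunc.end()));
}
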