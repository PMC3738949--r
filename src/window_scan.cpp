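#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// sorted-window maintenance: values kept ascending with a parallel
// chip-membership flag; insert/erase by binary search + memmove
static inline void win_insert(double* vals, unsigned char* chip, int n,
                              double v, unsigned char c) {
  int lo = static_cast<int>(std::lower_bound(vals, vals + n, v) - vals);
  std::memmove(vals + lo + 1, vals + lo, (n - lo) * sizeof(double));
  std::memmove(chip + lo + 1, chip + lo, (n - lo) * sizeof(unsigned char));
  vals[lo] = v;
  chip[lo] = c;
}

static inline void win_erase(double* vals, unsigned char* chip, int n,
                             double v, unsigned char c) {
  int lo = static_cast<int>(std::lower_bound(vals, vals + n, v) - vals);
  while (chip[lo] != c || vals[lo] != v) ++lo;  // same-value, other sample
  std::memmove(vals + lo, vals + lo + 1, (n - lo - 1) * sizeof(double));
  std::memmove(chip + lo, chip + lo + 1, (n - lo - 1) * sizeof(unsigned char));
}

// Per-window summaries for the sliding-window scan of one chromosome.
// For every window start (stride `step`) over two equal-length binned
// tracks, computes the ChIP window sum, control window sum, ChIP maximum,
// and the one-sided Wilcoxon rank-sum p-value (ChIP greater), using
// midranks, tie-corrected variance and continuity correction. Exact small-n
// testing is handled in R; this kernel is only called with >= 10 bins per
// side.
//
// Returns a matrix with columns: chip_sum, control_sum, chip_max, pvalue.
// [[Rcpp::export]]
NumericMatrix cpp_window_scan(NumericVector chip, NumericVector control,
                              int window, int step) {
  const int n = chip.size();
  if (control.size() != n)
    stop("chip and control tracks differ in length");
  if (window < 2 || window > n)
    return NumericMatrix(0, 4);
  const int nw = (n - window) / step + 1;
  NumericMatrix out(nw, 4);

  const int m = 2 * window;
  std::vector<double> vals(m);
  std::vector<unsigned char> isChip(m);

  const double n1 = window, n2 = window;
  const double mu = n1 * n2 / 2.0;
  const double N = m;
  const bool sliding = (step == 1);

  // initialize the sorted window at start 0
  for (int j = 0; j < window; ++j) {
    vals[j] = chip[j];
    vals[window + j] = control[j];
  }
  {
    std::vector<int> idx(m);
    for (int j = 0; j < m; ++j) idx[j] = j;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return vals[a] < vals[b]; });
    std::vector<double> sv(m);
    for (int j = 0; j < m; ++j) {
      sv[j] = vals[idx[j]];
      isChip[j] = idx[j] < window ? 1 : 0;
    }
    vals = sv;
  }

  for (int wi = 0; wi < nw; ++wi) {
    const int s = wi * step;
    if (wi > 0) {
      if (sliding) {
        win_erase(vals.data(), isChip.data(), m, chip[s - 1], 1);
        win_insert(vals.data(), isChip.data(), m - 1, chip[s + window - 1], 1);
        win_erase(vals.data(), isChip.data(), m, control[s - 1], 0);
        win_insert(vals.data(), isChip.data(), m - 1,
                   control[s + window - 1], 0);
      } else {
        // arbitrary stride: rebuild the sorted window
        std::vector<std::pair<double, unsigned char> > tmp(m);
        for (int j = 0; j < window; ++j) {
          tmp[j] = std::make_pair(chip[s + j], (unsigned char)1);
          tmp[window + j] = std::make_pair(control[s + j], (unsigned char)0);
        }
        std::sort(tmp.begin(), tmp.end());
        for (int j = 0; j < m; ++j) {
          vals[j] = tmp[j].first;
          isChip[j] = tmp[j].second;
        }
      }
    }

    double csum = 0.0, usum = 0.0, cmax = R_NegInf;
    for (int j = 0; j < window; ++j) {
      const double cv = chip[s + j];
      csum += cv;
      usum += control[s + j];
      if (cv > cmax) cmax = cv;
    }

    // one pass over the sorted window: rank sum of chip via midranks,
    // plus the tie-correction term sum(t^3 - t)
    double W = 0.0, tiesum = 0.0;
    int j = 0;
    while (j < m) {
      int k = j;
      int nchip = isChip[j];
      while (k + 1 < m && vals[k + 1] == vals[j]) {
        ++k;
        nchip += isChip[k];
      }
      const double t = k - j + 1;
      const double midrank = (j + k) / 2.0 + 1.0;
      W += midrank * nchip;
      tiesum += t * t * t - t;
      j = k + 1;
    }

    const double U = W - n1 * (n1 + 1) / 2.0;
    const double sigma2 =
        (n1 * n2 / 12.0) * ((N + 1.0) - tiesum / (N * (N - 1.0)));
    double p;
    if (sigma2 <= 0.0) {
      p = 1.0;  // every pooled value tied
    } else {
      const double z = (U - mu - 0.5) / std::sqrt(sigma2);
      p = R::pnorm(z, 0.0, 1.0, 0, 0);  // upper tail
      if (p > 1.0) p = 1.0;
      if (p <= 0.0) p = DBL_MIN;
    }
    out(wi, 0) = csum;
    out(wi, 1) = usum;
    out(wi, 2) = cmax;
    out(wi, 3) = p;
  }
  return out;
}
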