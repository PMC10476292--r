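// Hartigan & Hartigan dip statistic via the iterative greatest-convex-
// minorant / least-concave-majorant algorithm on the sorted sample.
// Returns the statistic together with the modal interval and the hull
// touch points needed to reconstruct the closest unimodal CDF for
// bootstrap resampling.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".dip_cpp")]]
List dip_cpp(NumericVector xs) {
  const int n = xs.size();
  if (n < 2) stop("dip: need at least 2 observations");
  const double* x = REAL(xs) - 1; // 1-based indexing to mirror the algorithm

  for (int i = 2; i <= n; ++i)
    if (x[i] < x[i - 1]) stop("dip: input must be sorted");

  if (x[n] == x[1]) {
    return List::create(_["dip"] = 0.0, _["low"] = 1, _["high"] = n,
                        _["lower_touch"] = IntegerVector::create(1),
                        _["upper_touch"] = IntegerVector::create(n));
  }

  std::vector<int> mn(n + 1), mj(n + 1);
  // GCM predecessor pointers over points (x_i, i)
  mn[1] = 1;
  for (int j = 2; j <= n; ++j) {
    mn[j] = j - 1;
    for (;;) {
      int mnj = mn[j];
      if (mnj == 1) break;
      int mnmnj = mn[mnj];
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break;
      mn[j] = mnmnj;
    }
  }
  // LCM successor pointers
  mj[n] = n;
  for (int k = n - 1; k >= 1; --k) {
    mj[k] = k + 1;
    for (;;) {
      int mjk = mj[k];
      if (mjk == n) break;
      int mjmjk = mj[mjk];
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break;
      mj[k] = mjmjk;
    }
  }

  int low = 1, high = n;
  double dip = 1.0; // in count units; statistic = dip / (2n)
  std::vector<int> gcm(n + 2), lcm(n + 2);

  for (;;) {
    // hull change points restricted to [low, high]
    int l_gcm = 1;
    gcm[1] = high;
    while (gcm[l_gcm] > low) { gcm[l_gcm + 1] = mn[gcm[l_gcm]]; ++l_gcm; }
    int l_lcm = 1;
    lcm[1] = low;
    while (lcm[l_lcm] < high) { lcm[l_lcm + 1] = mj[lcm[l_lcm]]; ++l_lcm; }

    int ix = l_gcm - 1, iv = 2;
    int ig = l_gcm, ih = l_lcm;
    double d = 0.0;
    if (l_gcm != 2 || l_lcm != 2) {
      for (;;) {
        int gcm_ix = gcm[ix], lcm_iv = lcm[iv];
        double dx;
        if (gcm_ix > lcm_iv) {
          // LCM touch next: gap at x[lcm_iv]
          int igcm1 = gcm[ix + 1];
          dx = (lcm_iv - igcm1 + 1) -
               (x[lcm_iv] - x[igcm1]) * (gcm_ix - igcm1) / (x[gcm_ix] - x[igcm1]);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // GCM touch next: gap at x[gcm_ix]
          int lcm_iv1 = lcm[iv - 1];
          dx = (x[gcm_ix] - x[lcm_iv1]) * (lcm_iv - lcm_iv1) /
                 (x[lcm_iv] - x[lcm_iv1]) - (gcm_ix - lcm_iv1 - 1);
          --ix;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 1) ix = 1;
        if (iv > l_lcm) iv = l_lcm;
        if (gcm[ix] == lcm[iv]) break;
      }
    } else {
      d = 1.0;
    }
    if (d < dip) break;

    // max deviation of the ECDF above the minorant, between new and old low
    double dip_l = 0.0;
    for (int j = ig; j < l_gcm; ++j) {
      double max_t = 1.0;
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1 && x[je] != x[jb]) {
        double C = (je - jb) / (x[je] - x[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (jj - jb + 1) - (x[jj] - x[jb]) * C;
          if (max_t < t) max_t = t;
        }
      }
      if (dip_l < max_t) dip_l = max_t;
    }
    // max deviation of the ECDF below the majorant, between new and old high
    double dip_u = 0.0;
    for (int j = ih; j < l_lcm; ++j) {
      double max_t = 1.0;
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1 && x[je] != x[jb]) {
        double C = (je - jb) / (x[je] - x[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (x[jj] - x[jb]) * C - (jj - jb - 1);
          if (max_t < t) max_t = t;
        }
      }
      if (dip_u < max_t) dip_u = max_t;
    }
    double dipnew = dip_l > dip_u ? dip_l : dip_u;
    if (dip < dipnew) dip = dipnew;
    if (low == gcm[ig] && high == lcm[ih]) break;
    low = gcm[ig];
    high = lcm[ih];
  }

  // Touch points of the convex minorant on [1, low] (following mn from low)
  // and of the concave majorant on [high, n] (following mj from high); the
  // closest unimodal CDF is piecewise linear through these with a straight
  // bridge across the modal interval.
  std::vector<int> lt, ut;
  for (int i = low; ; i = mn[i]) { lt.push_back(i); if (i == mn[i]) break; }
  std::reverse(lt.begin(), lt.end());
  for (int i = high; ; i = mj[i]) { ut.push_back(i); if (i == mj[i]) break; }

  return List::create(_["dip"] = dip / (2.0 * n),
                      _["low"] = low, _["high"] = high,
                      _["lower_touch"] = wrap(lt),
                      _["upper_touch"] = wrap(ut));
}
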