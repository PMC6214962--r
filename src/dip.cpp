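#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Hartigans' dip statistic for a sorted sample.
//
// The dip is the maximum distance between the empirical CDF and the closest
// unimodal CDF. The computation follows the classic modal-interval scheme:
// fit the greatest convex minorant (GCM) and least concave majorant (LCM) of
// the empirical CDF over a shrinking modal interval [low, high]; at each
// cycle, the largest GCM-LCM separation either certifies the current dip or
// shrinks the interval, while the deviations of the CDF from the two hull
// fits outside the new interval update the dip. Distances are kept in count
// units (steps of 1/n) and halved at the end, since the optimal unimodal CDF
// runs midway between the hull fits.

// value of the line through (x1, y1), (x2, y2) at x; for a vertical segment
// return the lower count y1 (the hull jumps there)
static inline long double interp(double x1, long double y1, double x2,
                                 long double y2, double x) {
  if (x2 == x1) return y1;
  return y1 + (y2 - y1) * ((long double)(x - x1)) / (x2 - x1);
}

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
  const int n = xs.size();
  if (n < 2) return 0.0;
  const double *x = xs.begin() - 1;  // 1-based access
  if (x[n] == x[1]) return 0.0;      // all values equal: perfectly unimodal

  std::vector<int> mn(n + 2), mj(n + 2), gcm(n + 2), lcm(n + 2);

  // previous-vertex pointers for the GCM over the full range
  mn[1] = 1;
  for (int j = 2; j <= n; ++j) {
    mn[j] = j - 1;
    for (;;) {
      int mnj = mn[j], mnmnj = mn[mnj];
      if (mnj == 1 ||
          (x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  // next-vertex pointers for the LCM
  mj[n] = n;
  for (int k = n - 1; k >= 1; --k) {
    mj[k] = k + 1;
    for (;;) {
      int mjk = mj[k], mjmjk = mj[mjk];
      if (mjk == n ||
          (x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  int low = 1, high = n;
  long double dip = 1.0;  // count units; final dip >= 1/(2n)

  for (int cycle = 0; cycle < 10000; ++cycle) {
    // GCM change points from high down to low
    gcm[1] = high;
    int l_gcm = 1;
    while (gcm[l_gcm] > low) { gcm[l_gcm + 1] = mn[gcm[l_gcm]]; ++l_gcm; }
    // LCM change points from low up to high
    lcm[1] = low;
    int l_lcm = 1;
    while (lcm[l_lcm] < high) { lcm[l_lcm + 1] = mj[lcm[l_lcm]]; ++l_lcm; }

    int ig = l_gcm, ih = l_lcm;
    long double d = 0.0;
    if (l_gcm != 2 || l_lcm != 2) {
      int ix = l_gcm - 1, iv = 2;
      do {
        int gcmix = gcm[ix], lcmiv = lcm[iv];
        if (gcmix > lcmiv) {
          // LCM vertex lies inside the GCM segment (gcm[ix+1], gcm[ix])
          int gcmi1 = gcm[ix + 1];
          long double g = interp(x[gcmi1], (long double)gcmi1, x[gcmix],
                                 (long double)gcmix, x[lcmiv]);
          long double dx = (lcmiv + 1.0L - g);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // GCM vertex lies inside the LCM segment (lcm[iv-1], lcm[iv])
          int lcmiv1 = lcm[iv - 1];
          long double lcm_hi = (x[lcmiv] == x[lcmiv1])
                                 ? (long double)lcmiv
                                 : interp(x[lcmiv1], (long double)lcmiv1,
                                          x[lcmiv], (long double)lcmiv,
                                          x[gcmix]);
          long double dx = lcm_hi - gcmix + 1.0L;
          --ix;
          if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 1) ix = 1;
        if (iv > l_lcm) iv = l_lcm;
      } while (gcm[ix] != lcm[iv]);
    } else {
      d = 1.0;
    }
    if (d < dip) break;

    // deviation of the CDF above the GCM fit, over segments outside [ig..]
    long double dip_l = 0.0;
    for (int j = ig; j < l_gcm; ++j) {
      long double max_t = 1.0;
      int j_l = gcm[j + 1], j_u = gcm[j];
      if (x[j_u] != x[j_l]) {
        for (int jb = j_l + 1; jb < j_u; ++jb) {
          long double g = interp(x[j_l], (long double)j_l, x[j_u],
                                 (long double)j_u, x[jb]);
          long double t = jb + 1.0L - g;
          if (t > max_t) max_t = t;
        }
      }
      if (max_t > dip_l) dip_l = max_t;
    }
    // deviation of the CDF below the LCM fit
    long double dip_u = 0.0;
    for (int j = ih; j < l_lcm; ++j) {
      long double max_t = 1.0;
      int j_l = lcm[j], j_u = lcm[j + 1];
      if (x[j_u] != x[j_l]) {
        for (int jb = j_l + 1; jb < j_u; ++jb) {
          long double g = interp(x[j_l], (long double)j_l, x[j_u],
                                 (long double)j_u, x[jb]);
          long double t = g - (jb - 1.0L);
          if (t > max_t) max_t = t;
        }
      }
      if (max_t > dip_u) dip_u = max_t;
    }
    long double dipnew = dip_l > dip_u ? dip_l : dip_u;
    if (dipnew > dip) dip = dipnew;
    int new_low = gcm[ig], new_high = lcm[ih];
    if (new_low == low && new_high == high) break;
    low = new_low;
    high = new_high;
  }
  return (double)(dip / (2.0L * n));
}
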