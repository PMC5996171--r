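#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Equal-frequency binning of a numeric vector into B bins.
// Average ranks for ties; bin index = ceil(r * B / n) - 1, clamped to B-1.
static void bin_ranks(const std::vector<double> &x, int B,
                      std::vector<int> &bins,
                      std::vector<int> &ord /* scratch */) {
  const int n = (int)x.size();
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  bins.resize(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    // ranks i+1 .. j+1 tied; average rank:
    double r = 0.5 * ((i + 1) + (j + 1));
    int b = (int)std::ceil(r * (double)B / (double)n) - 1;
    if (b < 0) b = 0;
    if (b > B - 1) b = B - 1;
    for (int k = i; k <= j; ++k) bins[ord[k]] = b;
    i = j + 1;
  }
}

// (C - D) / (n(n-1)/2) over all sample pairs, strict orders only.
static double nc_from_bins(const std::vector<int> &a, const std::vector<int> &b) {
  const int n = (int)a.size();
  long cd = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      int da = (a[i] > a[j]) - (a[i] < a[j]);
      int db = (b[i] > b[j]) - (b[i] < b[j]);
      cd += da * db;
    }
  return (double)cd / ((double)n * (n - 1) / 2.0);
}

// [[Rcpp::export(name = ".bin_profile_cpp")]]
IntegerVector bin_profile_cpp(NumericVector x, int B) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> bins, ord;
  bin_ranks(xv, B, bins, ord);
  return IntegerVector(bins.begin(), bins.end());
}

// [[Rcpp::export(name = ".nc_score_cpp")]]
double nc_score_cpp(IntegerVector a, IntegerVector b) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  return nc_from_bins(av, bv);
}

// ReBoot machinery: permutation null (with per-sample renormalization against
// the rest of the composition) and bootstrap distribution of the NC-score.
// `rest` is the per-sample summed relative abundance of all other taxa, so the
// renormalized pair values after permuting are xp/(rest+xp+yp), yp/(rest+xp+yp).
// Uses R's RNG (deterministic under set.seed()).
// [[Rcpp::export(name = ".reboot_stats_cpp")]]
List reboot_stats_cpp(NumericVector x, NumericVector y, NumericVector rest,
                      int B, int n_iter) {
  const int n = x.size();
  RNGScope scope;
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<double> xp(xv), yp(yv), xr(n), yr(n);
  std::vector<int> ba, bb, ord;

  bin_ranks(xv, B, ba, ord);
  bin_ranks(yv, B, bb, ord);
  double nc_obs = nc_from_bins(ba, bb);

  NumericVector null_s(n_iter), boot_s(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    // --- permutation null with renormalization ---
    std::copy(xv.begin(), xv.end(), xp.begin());
    std::copy(yv.begin(), yv.end(), yp.begin());
    for (int i = n - 1; i > 0; --i) { // independent Fisher-Yates shuffles
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(xp[i], xp[j]);
    }
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(yp[i], yp[j]);
    }
    for (int i = 0; i < n; ++i) {
      double s = rest[i] + xp[i] + yp[i];
      if (s <= 0) s = 1.0;
      xr[i] = xp[i] / s;
      yr[i] = yp[i] / s;
    }
    bin_ranks(xr, B, ba, ord);
    bin_ranks(yr, B, bb, ord);
    null_s[it] = nc_from_bins(ba, bb);

    // --- bootstrap (samples with replacement; columns keep their sums) ---
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j == n) j = n - 1;
      xr[i] = xv[j];
      yr[i] = yv[j];
    }
    bin_ranks(xr, B, ba, ord);
    bin_ranks(yr, B, bb, ord);
    boot_s[it] = nc_from_bins(ba, bb);
  }

  return List::create(_["nc_obs"] = nc_obs,
                      _["null"] = null_s,
                      _["boot"] = boot_s);
}
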