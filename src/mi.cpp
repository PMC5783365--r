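#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Bin a window of samples into nbins equal-width bins over its own [min, max].
// A zero-range (constant) window maps every sample to bin 0, which makes the
// plug-in MI exactly 0 through the single-occupied-marginal route.
static inline void bin_window(const double* x, int n, int nbins, int* out) {
  double lo = x[0], hi = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  double range = hi - lo;
  if (range <= 0.0) {
    std::memset(out, 0, n * sizeof(int));
    return;
  }
  double scale = nbins / range;
  for (int i = 0; i < n; ++i) {
    int b = (int)((x[i] - lo) * scale);
    if (b >= nbins) b = nbins - 1;   // x == max lands in the top bin
    out[i] = b;
  }
}

// Plug-in MI (nats) from two bin-index vectors.
static double mi_from_bins(const int* bx, const int* by, int n, int nbins) {
  std::vector<int> joint(nbins * nbins, 0);
  std::vector<int> mx(nbins, 0), my(nbins, 0);
  for (int i = 0; i < n; ++i) {
    joint[bx[i] * nbins + by[i]]++;
    mx[bx[i]]++;
    my[by[i]]++;
  }
  double mi = 0.0, dn = (double)n;
  for (int i = 0; i < nbins; ++i) {
    if (mx[i] == 0) continue;
    for (int j = 0; j < nbins; ++j) {
      int c = joint[i * nbins + j];
      if (c == 0) continue;
      double pxy = c / dn;
      mi += pxy * std::log(pxy * dn * dn / ((double)mx[i] * (double)my[j]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;   // clip -0.0 / rounding dust
}

// Occupied-cell counts for the Miller-Madow bias correction.
static void occupancy(const int* bx, const int* by, int n, int nbins,
                      int& kx, int& ky, int& kxy) {
  std::vector<int> joint(nbins * nbins, 0);
  std::vector<int> mx(nbins, 0), my(nbins, 0);
  for (int i = 0; i < n; ++i) {
    joint[bx[i] * nbins + by[i]]++;
    mx[bx[i]]++;
    my[by[i]]++;
  }
  kx = ky = kxy = 0;
  for (int i = 0; i < nbins; ++i) {
    if (mx[i]) kx++;
    if (my[i]) ky++;
  }
  for (int i = 0; i < nbins * nbins; ++i) if (joint[i]) kxy++;
}

// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(NumericVector x, NumericVector y, int nbins,
                   bool miller_madow) {
  int n = x.size();
  std::vector<int> bx(n), by(n);
  bin_window(REAL(x), n, nbins, bx.data());
  bin_window(REAL(y), n, nbins, by.data());
  double mi = mi_from_bins(bx.data(), by.data(), n, nbins);
  if (miller_madow) {
    int kx, ky, kxy;
    occupancy(bx.data(), by.data(), n, nbins, kx, ky, kxy);
    mi -= (kxy - kx - ky + 1) / (2.0 * n);
  }
  return mi;
}

// Sliding-window MI over all requested channel pairs.
// sig: time x channels matrix (band-filtered), pairs: P x 2 (0-based column
// indices into sig). Returns windows x P matrix of MI in nats.
// [[Rcpp::export(name = ".sliding_mi_cpp")]]
NumericMatrix sliding_mi_cpp(NumericMatrix sig, IntegerMatrix pairs,
                             int win, int step, int nbins,
                             bool miller_madow) {
  int nsamp = sig.nrow();
  int nchan = sig.ncol();
  int npair = pairs.nrow();
  int nwin = (nsamp - win) / step + 1;
  if (nwin < 1) stop("recording shorter than one window");

  // which channels are actually used
  std::vector<int> used(nchan, 0);
  for (int p = 0; p < npair; ++p) {
    used[pairs(p, 0)] = 1;
    used[pairs(p, 1)] = 1;
  }

  NumericMatrix out(nwin, npair);
  std::vector<int> bins((size_t)nchan * win);

  for (int w = 0; w < nwin; ++w) {
    int start = w * step;
    for (int c = 0; c < nchan; ++c) {
      if (!used[c]) continue;
      bin_window(&sig(0, c) + start, win, nbins, &bins[(size_t)c * win]);
    }
    for (int p = 0; p < npair; ++p) {
      const int* bx = &bins[(size_t)pairs(p, 0) * win];
      const int* by = &bins[(size_t)pairs(p, 1) * win];
      double mi = mi_from_bins(bx, by, win, nbins);
      if (miller_madow) {
        int kx, ky, kxy;
        occupancy(bx, by, win, nbins, kx, ky, kxy);
        mi -= (kxy - kx - ky + 1) / (2.0 * win);
      }
      out(w, p) = mi;
    }
  }
  return out;
}
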