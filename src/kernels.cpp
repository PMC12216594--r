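#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Integrate a per-sample velocity signal (deg/s) into gaze position (deg)
// with instantaneous saccadic resets: whenever |x| exceeds the reset
// eccentricity the eye snaps back to the centre in a single sample.
// [[Rcpp::export]]
NumericVector integrate_okn_position(NumericVector v, double dt,
                                     double reset_ecc_deg) {
  int n = v.size();
  NumericVector x(n);
  double cur = 0.0;
  for (int i = 0; i < n; ++i) {
    cur += v[i] * dt;
    if (std::fabs(cur) > reset_ecc_deg) cur = 0.0;  // fast-phase reset
    x[i] = cur;
  }
  return x;
}

// type-7 quantile of a sorted buffer
static inline double quantile7(const std::vector<double> &s, double p) {
  int m = (int)s.size();
  if (m == 1) return s[0];
  double h = (m - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= m - 1) return s[m - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Bagged velocity profile on a cumulative pursuit series.
//
// y          : cumulative pursuit position (deg) on the full sample grid
// seg_start  : 0-based inclusive start index of each slow segment
// seg_end    : 0-based inclusive end index of each slow segment
// B          : bootstrap resamples
// halfwin    : half-width of the local linear fit, in samples
// stride     : evaluation stride in samples (profile interpolated in R)
// dt         : sample interval in seconds
//
// Each resample draws segment multiplicities from a multinomial (segments
// resampled with replacement); the velocity at a grid point is the
// count-weighted local linear slope over the window, using only slow-segment
// samples (interpolated gap filler carries no information of its own).
// Windows overlapping a single segment yield the same slope in every
// resample that retains the segment; windows spanning several segments vary
// with the multiplicities, so the CI widens at joins and gaps.
// Returns an (n_out x 3) matrix: median, 2.5% and 97.5% percentiles, with
// NaN rows where no segment sample falls in the window.
// [[Rcpp::export]]
NumericMatrix bag_profile_kernel(NumericVector y, IntegerVector seg_start,
                                 IntegerVector seg_end, int B, int halfwin,
                                 int stride, double dt) {
  int n = y.size();
  int nseg = seg_start.size();
  int n_out = (n + stride - 1) / stride;
  NumericMatrix out(n_out, 3);

  // prefix sums of t, y, t*y, t*t with t = i * dt
  std::vector<double> Pt(n + 1, 0.0), Py(n + 1, 0.0), Pty(n + 1, 0.0),
      Ptt(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    Pt[i + 1] = Pt[i] + t;
    Py[i + 1] = Py[i] + y[i];
    Pty[i + 1] = Pty[i] + t * y[i];
    Ptt[i + 1] = Ptt[i] + t * t;
  }

  // multinomial segment counts for every resample
  std::vector<int> counts((size_t)B * nseg, 0);
  if (nseg > 0) {
    for (int b = 0; b < B; ++b) {
      int *cb = &counts[(size_t)b * nseg];
      for (int j = 0; j < nseg; ++j) {
        int k = (int)(unif_rand() * nseg);
        if (k >= nseg) k = nseg - 1;
        cb[k]++;
      }
    }
  }

  std::vector<double> scratch;
  scratch.reserve(B);
  int ptr = 0;  // first segment whose end may reach the window

  for (int o = 0; o < n_out; ++o) {
    int c = o * stride;
    int a = std::max(0, c - halfwin);
    int b2 = std::min(n - 1, c + halfwin);
    while (ptr < nseg && seg_end[ptr] < a) ++ptr;
    int first = ptr, last = ptr - 1;
    for (int s = ptr; s < nseg && seg_start[s] <= b2; ++s) last = s;
    int k = last - first + 1;

    double med = NA_REAL, lo = NA_REAL, hi = NA_REAL;
    if (k == 1) {
      int s0 = std::max(a, (int)seg_start[first]);
      int e0 = std::min(b2, (int)seg_end[first]);
      int cnt = e0 - s0 + 1;
      if (cnt >= 2) {
        double Sw = cnt, St = Pt[e0 + 1] - Pt[s0], Sy = Py[e0 + 1] - Py[s0];
        double Sty = Pty[e0 + 1] - Pty[s0], Stt = Ptt[e0 + 1] - Ptt[s0];
        double Dxx = Stt - St * St / Sw;
        if (Dxx > 1e-12) {
          double slope = (Sty - St * Sy / Sw) / Dxx;
          med = lo = hi = slope;  // identical in every retaining resample
        }
      }
    } else if (k >= 2) {
      scratch.clear();
      for (int b = 0; b < B; ++b) {
        const int *cb = &counts[(size_t)b * nseg];
        double Sw = 0, St = 0, Sy = 0, Sty = 0, Stt = 0;
        for (int s = first; s <= last; ++s) {
          int f = cb[s];
          if (f == 0) continue;
          int s0 = std::max(a, (int)seg_start[s]);
          int e0 = std::min(b2, (int)seg_end[s]);
          int cnt = e0 - s0 + 1;
          Sw += (double)f * cnt;
          St += f * (Pt[e0 + 1] - Pt[s0]);
          Sy += f * (Py[e0 + 1] - Py[s0]);
          Sty += f * (Pty[e0 + 1] - Pty[s0]);
          Stt += f * (Ptt[e0 + 1] - Ptt[s0]);
        }
        if (Sw < 2) continue;
        double Dxx = Stt - St * St / Sw;
        if (Dxx <= 1e-12) continue;
        scratch.push_back((Sty - St * Sy / Sw) / Dxx);
      }
      if (!scratch.empty()) {
        std::sort(scratch.begin(), scratch.end());
        med = quantile7(scratch, 0.5);
        lo = quantile7(scratch, 0.025);
        hi = quantile7(scratch, 0.975);
      }
    }
    out(o, 0) = med;
    out(o, 1) = lo;
    out(o, 2) = hi;
  }
  return out;
}

// Savitzky-Golay order-1 derivative (local linear slope) by convolution,
// centred, window 2h+1 samples; edges are padded with the nearest interior
// estimate. x in deg, dt in s -> deg/s.
// [[Rcpp::export]]
NumericVector sg_derivative(NumericVector x, int h, double dt) {
  int n = x.size();
  NumericVector v(n);
  if (n < 2 * h + 1) {
    double slope = n > 1 ? (x[n - 1] - x[0]) / ((n - 1) * dt) : 0.0;
    for (int i = 0; i < n; ++i) v[i] = slope;
    return v;
  }
  double denom = 0.0;
  for (int j = 1; j <= h; ++j) denom += 2.0 * j * j;
  denom *= dt;
  for (int i = h; i < n - h; ++i) {
    double acc = 0.0;
    for (int j = 1; j <= h; ++j) acc += j * (x[i + j] - x[i - j]);
    v[i] = acc / denom;
  }
  for (int i = 0; i < h; ++i) v[i] = v[h];
  for (int i = n - h; i < n; ++i) v[i] = v[n - h - 1];
  return v;
}
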