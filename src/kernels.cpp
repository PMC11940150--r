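#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy with embedding dimension m and Chebyshev tolerance r.
// Self-matches excluded. Returns NA when no template pairs match at
// length m or m+1 (short/degenerate series); downstream imputation
// handles it.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  long long B = 0, A = 0;
  int nm = n - m;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int l = 0; l < m; ++l) {
        d = std::fabs(x[i + l] - x[j + l]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

static double quantile7(const std::vector<double>& xs, double p) {
  int n = xs.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return xs[lo] + (h - lo) * (xs[hi] - xs[lo]);
}

static double median_of(std::vector<double> v) {
  int n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// The 42 time-domain statistics of one channel segment, in registry
// order (names are attached on the R side). Semantics match the
// documented registry: type-7 quantiles, unbiased sd/variance,
// population moment skewness/kurtosis, per-sample event rates,
// autocorrelation at fixed lags, sample entropy on up to the first
// 600 samples (m = 2, r = 0.2 sd), and 16-bin histogram entropy.
// [[Rcpp::export]]
NumericVector cpp_time_features(NumericVector x) {
  int n = x.size();
  NumericVector out(42);
  double m = 0, energy = 0, mean_abs = 0, max_abs = 0;
  for (int i = 0; i < n; ++i) {
    m += x[i];
    energy += x[i] * x[i];
    double a = std::fabs(x[i]);
    mean_abs += a;
    if (a > max_abs) max_abs = a;
  }
  m /= n; mean_abs /= n;
  double rms = std::sqrt(energy / n);
  double m2 = 0, m3 = 0, m4 = 0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - m;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
  }
  double varb = m2 / (n - 1);       // unbiased
  double s = std::sqrt(varb);
  double denom = m2;                // sum of squared deviations
  m2 /= n; m3 /= n; m4 /= n;        // population moments
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  double p5 = quantile7(xs, 0.05), p25 = quantile7(xs, 0.25);
  double p75 = quantile7(xs, 0.75), p95 = quantile7(xs, 0.95);
  double med = quantile7(xs, 0.50);
  int tl = (int)std::floor(0.1 * n);
  double trimmed = 0;
  for (int i = tl; i < n - tl; ++i) trimmed += xs[i];
  trimmed /= (n - 2 * tl);
  std::vector<double> ad(n);
  for (int i = 0; i < n; ++i) ad[i] = std::fabs(x[i] - med);
  double mad = 1.4826 * median_of(ad);
  double skew = m2 > 0 ? m3 / std::pow(m2, 1.5) : NA_REAL;
  double kurt = m2 > 0 ? m4 / (m2 * m2) : NA_REAL;
  double cv = std::fabs(m) > 1e-12 ? s / std::fabs(m) : NA_REAL;
  int zc = 0, mc = 0;
  for (int i = 0; i + 1 < n; ++i) {
    if (x[i] * x[i + 1] < 0) ++zc;
    if ((x[i] - m) * (x[i + 1] - m) < 0) ++mc;
  }
  int pk = 0;
  for (int i = 1; i + 1 < n; ++i)
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) ++pk;
  double peak_rate = n >= 3 ? (double)pk / (n - 2) : 0.0;
  // first differences
  int nd = n - 1;
  double d_sum_abs = 0, d_sum = 0, d_sum2 = 0, d_max_abs = 0;
  int ssc = 0;
  double prev = x[1] - x[0];
  for (int i = 0; i < nd; ++i) {
    double d = x[i + 1] - x[i];
    d_sum_abs += std::fabs(d); d_sum += d; d_sum2 += d * d;
    if (std::fabs(d) > d_max_abs) d_max_abs = std::fabs(d);
    if (i > 0 && prev * d < 0) ++ssc;
    prev = d;
  }
  double diff_sd = nd >= 2 ?
    std::sqrt((d_sum2 - d_sum * d_sum / nd) / (nd - 1)) : NA_REAL;
  double slope_rate = nd >= 2 ? (double)ssc / (nd - 1) : 0.0;
  // second differences
  int nd2 = n - 2;
  double d2_sum_abs = 0, d2_sum2 = 0;
  for (int i = 0; i < nd2; ++i) {
    double d = x[i + 2] - 2 * x[i + 1] + x[i];
    d2_sum_abs += std::fabs(d); d2_sum2 += d * d;
  }
  double acf[5];
  int lags[5] = {1, 2, 5, 10, 20};
  for (int l = 0; l < 5; ++l) {
    int lag = lags[l];
    if (n <= lag + 1 || denom <= 0) { acf[l] = NA_REAL; continue; }
    double acc = 0;
    for (int i = 0; i + lag < n; ++i)
      acc += (x[i] - m) * (x[i + lag] - m);
    acf[l] = acc / denom;
  }
  NumericVector xh(x.begin(), x.begin() + std::min(n, 600));
  double sampen = cpp_sampen(xh, 2, 0.2 * s);
  double hent = 0;
  if (s > 0) {
    double lo = xs[0], hi = xs[n - 1];
    int cnt[16] = {0};
    for (int i = 0; i < n; ++i) {
      int b = (int)std::floor((x[i] - lo) / (hi - lo) * 16);
      if (b < 0) b = 0;
      if (b > 15) b = 15;
      ++cnt[b];
    }
    for (int b = 0; b < 16; ++b)
      if (cnt[b] > 0) {
        double p = (double)cnt[b] / n;
        hent -= p * std::log(p);
      }
  }
  double mean_sqrt_abs = 0;
  for (int i = 0; i < n; ++i) mean_sqrt_abs += std::sqrt(std::fabs(x[i]));
  mean_sqrt_abs /= n;
  int j = 0;
  out[j++] = m; out[j++] = med; out[j++] = s; out[j++] = varb;
  out[j++] = mad; out[j++] = p75 - p25; out[j++] = xs[0];
  out[j++] = xs[n - 1]; out[j++] = xs[n - 1] - xs[0]; out[j++] = rms;
  out[j++] = mean_abs; out[j++] = max_abs; out[j++] = energy;
  out[j++] = skew; out[j++] = kurt; out[j++] = cv; out[j++] = p5;
  out[j++] = p25; out[j++] = p75; out[j++] = p95; out[j++] = trimmed;
  out[j++] = (double)zc / (n - 1); out[j++] = (double)mc / (n - 1);
  out[j++] = peak_rate; out[j++] = slope_rate;
  out[j++] = d_sum_abs / nd;
  out[j++] = diff_sd;
  out[j++] = std::sqrt(d_sum2 / nd);
  out[j++] = d_max_abs;
  out[j++] = nd2 > 0 ? d2_sum_abs / nd2 : NA_REAL;
  out[j++] = nd2 > 0 ? std::sqrt(d2_sum2 / nd2) : NA_REAL;
  for (int l = 0; l < 5; ++l) out[j++] = acf[l];
  out[j++] = sampen;
  out[j++] = rms > 0 ? max_abs / rms : NA_REAL;
  out[j++] = mean_abs > 0 ? max_abs / mean_abs : NA_REAL;
  out[j++] = mean_abs > 0 ? rms / mean_abs : NA_REAL;
  out[j++] = mean_abs > 0 ?
    max_abs / (mean_sqrt_abs * mean_sqrt_abs) : NA_REAL;
  out[j++] = hent;
  return out;
}

// Classical Lomb-Scargle normalised periodogram at the supplied
// frequencies (Hz). The per-sample sin/cos terms are generated by a
// rotation recurrence when the time grid is uniform (the common case
// here), with periodic renormalisation to keep the recurrence stable;
// non-uniform grids fall back to direct evaluation.
// [[Rcpp::export]]
NumericVector cpp_lsp(NumericVector x, NumericVector t, NumericVector freqs) {
  int n = x.size();
  NumericVector out(freqs.size());
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += (x[i] - mean) * (x[i] - mean);
  var /= (n - 1);
  if (var <= 0.0) { std::fill(out.begin(), out.end(), 0.0); return out; }
  bool uniform = n >= 3;
  double dt = n >= 2 ? t[1] - t[0] : 0.0;
  for (int i = 2; i < n && uniform; ++i)
    if (std::fabs((t[i] - t[i - 1]) - dt) > 1e-9 * std::fabs(dt))
      uniform = false;
  std::vector<double> xc(n);
  for (int i = 0; i < n; ++i) xc[i] = x[i] - mean;
  for (int k = 0; k < freqs.size(); ++k) {
    double w = 2.0 * M_PI * freqs[k];
    double s2 = 0.0, c2 = 0.0, cs = 0.0, sc = 0.0, cc = 0.0, ss = 0.0;
    if (uniform) {
      double dc = std::cos(w * dt), ds = std::sin(w * dt);
      double c = std::cos(w * t[0]), s = std::sin(w * t[0]);
      for (int i = 0; i < n; ++i) {
        // accumulate sums for the unshifted phase first
        double c2i = c * c - s * s, s2i = 2.0 * s * c;  // cos/sin(2wt)
        s2 += s2i; c2 += c2i;
        cs += xc[i] * c;
        sc += xc[i] * s;
        cc += c * c;
        ss += s * s;
        double cn = c * dc - s * ds;
        s = s * dc + c * ds;
        c = cn;
        if ((i & 255) == 255) {  // renormalise the rotation
          double r = std::sqrt(c * c + s * s);
          c /= r; s /= r;
        }
      }
      // rotate the accumulated sums by the time offset tau
      double tau = std::atan2(s2, c2) / (2.0 * w);
      double ct = std::cos(w * tau), st = std::sin(w * tau);
      double csr = cs * ct + sc * st;
      double scr = sc * ct - cs * st;
      double cc2 = 0.5 * (n + c2 * std::cos(2 * w * tau) +
                          s2 * std::sin(2 * w * tau));
      double ss2 = n - cc2;
      double p = 0.0;
      if (cc2 > 0.0) p += csr * csr / cc2;
      if (ss2 > 0.0) p += scr * scr / ss2;
      out[k] = p / (2.0 * var);
    } else {
      for (int i = 0; i < n; ++i) {
        s2 += std::sin(2.0 * w * t[i]);
        c2 += std::cos(2.0 * w * t[i]);
      }
      double tau = std::atan2(s2, c2) / (2.0 * w);
      for (int i = 0; i < n; ++i) {
        double arg = w * (t[i] - tau);
        double ct = std::cos(arg), st = std::sin(arg);
        cs += xc[i] * ct;
        sc += xc[i] * st;
        cc += ct * ct;
        ss += st * st;
      }
      double p = 0.0;
      if (cc > 0.0) p += cs * cs / cc;
      if (ss > 0.0) p += sc * sc / ss;
      out[k] = p / (2.0 * var);
    }
  }
  return out;
}

// Maximum absolute normalised cross-correlation between two equal-length
// series over lags -max_lag..max_lag (normalisation by sd over the
// overlapping windows).
// [[Rcpp::export]]
double cpp_max_xcorr(NumericVector a, NumericVector b, int max_lag) {
  int n = a.size();
  if (n < 2) return NA_REAL;
  if (max_lag > n - 2) max_lag = n - 2;
  // prefix sums of a, a^2, b, b^2 for O(1) window moments per lag
  std::vector<double> sa(n + 1, 0), sa2(n + 1, 0), sb(n + 1, 0),
      sb2(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    sa[i + 1] = sa[i] + a[i];
    sa2[i + 1] = sa2[i] + a[i] * a[i];
    sb[i + 1] = sb[i] + b[i];
    sb2[i + 1] = sb2[i] + b[i] * b[i];
  }
  double best = 0.0;
  for (int lag = -max_lag; lag <= max_lag; ++lag) {
    int lo = std::max(0, -lag);
    int hi = std::min(n, n - lag);
    int m = hi - lo;
    if (m < 2) continue;
    double dot = 0.0;
    for (int i = lo; i < hi; ++i) dot += a[i] * b[i + lag];
    double suma = sa[hi] - sa[lo], suma2 = sa2[hi] - sa2[lo];
    double sumb = sb[hi + lag] - sb[lo + lag];
    double sumb2 = sb2[hi + lag] - sb2[lo + lag];
    double va = suma2 - suma * suma / m;
    double vb = sumb2 - sumb * sumb / m;
    if (va <= 0.0 || vb <= 0.0) continue;
    double num = dot - suma * sumb / m;
    double r = std::fabs(num / std::sqrt(va * vb));
    if (r > best) best = r;
  }
  return best;
}

// Mutual information (nats) between each continuous column of X and a
// discrete label vector y, by the k-nearest-neighbour estimator for
// mixed discrete/continuous pairs: for each point, take the distance to
// its k-th nearest neighbour within the same class, count all points
// within that distance, and combine the counts through digamma terms.
// Columns are expected to be pre-jittered to break ties. Estimates are
// clipped at zero.
// [[Rcpp::export]]
NumericVector cpp_mi_disc(NumericMatrix X, IntegerVector y, int k) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  // class sizes
  std::map<int, int> csize;
  for (int i = 0; i < n; ++i) csize[y[i]]++;
  std::vector<int> nx(n);
  for (int i = 0; i < n; ++i) nx[i] = csize[y[i]];
  std::vector<double> d(n);
  for (int j = 0; j < p; ++j) {
    double acc = 0.0;
    int used = 0;
    for (int i = 0; i < n; ++i) {
      if (nx[i] < 2) continue;
      int ki = std::min(k, nx[i] - 1);
      // distances to same-class points
      int cnt = 0;
      for (int l = 0; l < n; ++l) {
        if (l == i || y[l] != y[i]) continue;
        d[cnt++] = std::fabs(X(l, j) - X(i, j));
      }
      std::nth_element(d.begin(), d.begin() + (ki - 1), d.begin() + cnt);
      double radius = d[ki - 1];
      // count all points (any class, excluding self) within radius
      int m = 0;
      for (int l = 0; l < n; ++l) {
        if (l == i) continue;
        if (std::fabs(X(l, j) - X(i, j)) <= radius) ++m;
      }
      acc += R::digamma((double)n) - R::digamma((double)nx[i]) +
             R::digamma((double)ki) - R::digamma((double)m);
      ++used;
    }
    double mi = used > 0 ? acc / used : 0.0;
    out[j] = mi > 0.0 ? mi : 0.0;
  }
  return out;
}

// Column medians over finite observed values; NA cells (missing) and
// non-finite cells are skipped; columns with nothing observed give NA.
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  std::vector<double> v;
  v.reserve(n);
  for (int j = 0; j < p; ++j) {
    v.clear();
    for (int i = 0; i < n; ++i) {
      double z = X(i, j);
      if (R_IsNA(z) || !std::isfinite(z)) continue;
      v.push_back(z);
    }
    int m = v.size();
    if (m == 0) { out[j] = NA_REAL; continue; }
    std::sort(v.begin(), v.end());
    out[j] = (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
  }
  return out;
}

// Per-column screen used by table preprocessing. NA means "missing"
// (to be imputed) and is ignored; NaN/Inf count as non-finite values
// and flag the column. Returns a 2-column integer matrix:
// has_nonfinite, is_constant (all-missing counts as constant).
// [[Rcpp::export]]
IntegerMatrix cpp_col_screen(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  IntegerMatrix out(p, 2);
  for (int j = 0; j < p; ++j) {
    bool nonfin = false;
    double lo = R_PosInf, hi = R_NegInf;
    int seen = 0;
    for (int i = 0; i < n; ++i) {
      double z = X(i, j);
      if (R_IsNA(z)) continue;
      if (!std::isfinite(z)) { nonfin = true; continue; }
      if (z < lo) lo = z;
      if (z > hi) hi = z;
      ++seen;
    }
    out(j, 0) = nonfin ? 1 : 0;
    out(j, 1) = (seen == 0 || lo == hi) ? 1 : 0;
  }
  return out;
}

// Direct-form II transposed IIR filter with explicit initial state zi
// (length = length(b) - 1, coefficients normalised so a[0] = 1).
// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x,
                      NumericVector zi) {
  int n = x.size(), nb = b.size();
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j < nb - 1; ++j)
      z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    z[nb - 2] = b[nb - 1] * xi - a[nb - 1] * yi;
    y[i] = yi;
  }
  return y;
}
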