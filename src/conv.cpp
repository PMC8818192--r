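#include <Rcpp.h>
using namespace Rcpp;

// y(t) = int_0^t exp(-rate*(t-s)) x(s) ds on a uniform grid, trapezoid rule.
// Recursive form: y_n = e*y_{n-1} + (dt/2)*(e*x_{n-1} + x_n), e = exp(-rate*dt).
static void exp_conv_into(const double* x, int n, double rate, double dt, double* y) {
  double e = std::exp(-rate * dt);
  double h = 0.5 * dt;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) y[i] = e * y[i - 1] + h * (e * x[i - 1] + x[i]);
}

// [[Rcpp::export(name = ".exp_conv_trapz")]]
NumericVector exp_conv_trapz(NumericVector x, double rate, double dt) {
  NumericVector y(x.size());
  exp_conv_into(x.begin(), x.size(), rate, dt, y.begin());
  return y;
}

// Frame averages of a gridded curve: trapezoid integral over each index
// window [i0, i1] (1-based, frame boundaries aligned with grid nodes)
// divided by the window length.
// [[Rcpp::export(name = ".frame_averages")]]
NumericVector frame_averages(NumericVector y, IntegerVector i0, IntegerVector i1) {
  int nf = i0.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    int a = i0[f] - 1, b = i1[f] - 1;
    double s = 0.5 * (y[a] + y[b]);
    for (int k = a + 1; k < b; ++k) s += y[k];
    out[f] = s / (double)(b - a);
  }
  return out;
}

// Tissue curve of the dual-input two-tissue model on the grid.
// arterial/portal sampled on a uniform grid with spacing dt_s seconds,
// rates in 1/min, hpi in [0,1]. Returns C_T on the same grid.
// [[Rcpp::export(name = ".model_tac_core")]]
NumericVector model_tac_core(NumericVector arterial, NumericVector portal,
                             double k1, double k2, double k3, double k4,
                             double hpi, double dt_s) {
  int n = arterial.size();
  double s = k2 + k3 + k4;
  double disc = s * s - 4.0 * k2 * k4;
  if (disc < 0.0) disc = 0.0;  // guards fp noise; analytically >= 0
  double rt = std::sqrt(disc);
  double a1 = 0.5 * (s - rt), a2 = 0.5 * (s + rt);
  double dt = dt_s / 60.0;  // convolution clock runs in minutes

  std::vector<double> cb(n);
  for (int i = 0; i < n; ++i) cb[i] = hpi * arterial[i] + (1.0 - hpi) * portal[i];

  NumericVector ct(n);
  std::vector<double> y1(n), y2(n);
  if ((a2 - a1) >= 1e-9) {
    exp_conv_into(cb.data(), n, a1, dt, y1.data());
    exp_conv_into(cb.data(), n, a2, dt, y2.data());
    double c1 = k1 * (k3 + k4 - a1) / (a2 - a1);
    double c2 = k1 * (a2 - k3 - k4) / (a2 - a1);
    for (int i = 0; i < n; ++i) ct[i] = c1 * y1[i] + c2 * y2[i];
  } else {
    // repeated root a1 = a2 = a: impulse response K1*(1+(k3+k4-a)t)e^{-at}.
    // t*e^{-at} (x) cb = t*(e^{-at} (x) cb) - e^{-at} (x) (t*cb).
    double a = a1;
    exp_conv_into(cb.data(), n, a, dt, y1.data());
    std::vector<double> tcb(n);
    for (int i = 0; i < n; ++i) tcb[i] = (i * dt) * cb[i];
    exp_conv_into(tcb.data(), n, a, dt, y2.data());
    double b = k3 + k4 - a;
    for (int i = 0; i < n; ++i) ct[i] = k1 * (y1[i] + b * ((i * dt) * y1[i] - y2[i]));
  }
  return ct;
}

// Sum of squared per-frame residuals for one candidate parameter vector.
// observed has one value per frame window.
// [[Rcpp::export(name = ".model_rss_core")]]
double model_rss_core(NumericVector arterial, NumericVector portal,
                      double k1, double k2, double k3, double k4, double hpi,
                      double dt_s, IntegerVector i0, IntegerVector i1,
                      NumericVector observed) {
  NumericVector ct = model_tac_core(arterial, portal, k1, k2, k3, k4, hpi, dt_s);
  NumericVector fr = frame_averages(ct, i0, i1);
  double rss = 0.0;
  for (int f = 0; f < fr.size(); ++f) {
    double d = observed[f] - fr[f];
    rss += d * d;
  }
  return rss;
}
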