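#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Separable Gaussian convolution of a rows x cols x frames stack with
// replicated (edge-value) boundaries. Frames are filtered independently.
// [[Rcpp::export(name = ".gauss3d_cpp")]]
NumericVector gauss3d_cpp(NumericVector stack, int ny, int nx, int nf,
                          double sigma) {
  int hw = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * hw + 1);
  double s = 0.0;
  for (int i = -hw; i <= hw; ++i) {
    k[i + hw] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + hw];
  }
  for (double &w : k) w /= s;

  NumericVector out(stack.size());
  std::vector<double> tmp((size_t)ny * nx);
  const double *in = stack.begin();
  double *o = out.begin();
  for (int f = 0; f < nf; ++f) {
    const double *fr = in + (size_t)f * ny * nx;
    double *fo = o + (size_t)f * ny * nx;
    // rows (first dimension)
    for (int c = 0; c < nx; ++c) {
      const double *col = fr + (size_t)c * ny;
      double *tc = tmp.data() + (size_t)c * ny;
      for (int r = 0; r < ny; ++r) {
        double acc = 0.0;
        for (int i = -hw; i <= hw; ++i) {
          int rr = r + i;
          rr = rr < 0 ? 0 : (rr >= ny ? ny - 1 : rr);
          acc += k[i + hw] * col[rr];
        }
        tc[r] = acc;
      }
    }
    // cols (second dimension)
    for (int r = 0; r < ny; ++r) {
      for (int c = 0; c < nx; ++c) {
        double acc = 0.0;
        for (int i = -hw; i <= hw; ++i) {
          int cc = c + i;
          cc = cc < 0 ? 0 : (cc >= nx ? nx - 1 : cc);
          acc += k[i + hw] * tmp[(size_t)cc * ny + r];
        }
        fo[(size_t)c * ny + r] = acc;
      }
    }
  }
  return out;
}

// Add isotropic Gaussian flashes to a rows x cols x frames stack in place.
// cy/cx are pixel-centre coordinates (1-based, fractional), one entry per
// stamp; frame is 1-based.
// [[Rcpp::export(name = ".stamp_flashes_cpp")]]
void stamp_flashes_cpp(NumericVector stack, int ny, int nx, int nf,
                       NumericVector cy, NumericVector cx,
                       IntegerVector frame, NumericVector amp,
                       double sig_px) {
  int hw = (int)std::ceil(4.0 * sig_px);
  double inv2s2 = 1.0 / (2.0 * sig_px * sig_px);
  double *s = stack.begin();
  for (int i = 0; i < cy.size(); ++i) {
    int f = frame[i] - 1;
    if (f < 0 || f >= nf) continue;
    double *fr = s + (size_t)f * ny * nx;
    int r0 = std::max(0, (int)std::floor(cy[i]) - 1 - hw);
    int r1 = std::min(ny - 1, (int)std::floor(cy[i]) - 1 + hw);
    int c0 = std::max(0, (int)std::floor(cx[i]) - 1 - hw);
    int c1 = std::min(nx - 1, (int)std::floor(cx[i]) - 1 + hw);
    for (int c = c0; c <= c1; ++c) {
      double dx = (c + 1) - cx[i];
      double ex = std::exp(-dx * dx * inv2s2);
      for (int r = r0; r <= r1; ++r) {
        double dy = (r + 1) - cy[i];
        fr[(size_t)c * ny + r] +=
            amp[i] * ex * std::exp(-dy * dy * inv2s2);
      }
    }
  }
}

// Per-pixel temporal median and MAD (scaled to SD) of a pixels x frames
// matrix; returns a 2-column matrix (median, 1.4826 * MAD).
// [[Rcpp::export(name = ".temporal_mad_cpp")]]
NumericMatrix temporal_mad_cpp(NumericMatrix flat) {
  int np = flat.nrow(), nf = flat.ncol();
  NumericMatrix out(np, 2);
  std::vector<double> buf(nf);
  for (int p = 0; p < np; ++p) {
    for (int f = 0; f < nf; ++f) buf[f] = flat(p, f);
    std::nth_element(buf.begin(), buf.begin() + nf / 2, buf.end());
    double med = buf[nf / 2];
    if (nf % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + nf / 2);
      med = 0.5 * (med + lo);
    }
    for (int f = 0; f < nf; ++f) buf[f] = std::fabs(flat(p, f) - med);
    std::nth_element(buf.begin(), buf.begin() + nf / 2, buf.end());
    double mad = buf[nf / 2];
    if (nf % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + nf / 2);
      mad = 0.5 * (mad + lo);
    }
    out(p, 0) = med;
    out(p, 1) = 1.4826 * mad;
  }
  return out;
}
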