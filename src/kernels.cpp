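#include <Rcpp.h>
using namespace Rcpp;

// Deposit point scatterers onto a pixel grid with bilinear weights.
// Positions are 0-based pixel coordinates (row = axial, col = lateral);
// sub-pixel positions spread amplitude over the 4 neighbouring pixels so
// that the first moment (hence centroid) of each scatterer is preserved.
// [[Rcpp::export]]
NumericMatrix cpp_splat_bilinear(NumericVector row_px, NumericVector col_px,
                                 NumericVector amp, int nrow, int ncol) {
  NumericMatrix out(nrow, ncol);
  const int n = row_px.size();
  for (int i = 0; i < n; ++i) {
    double r = row_px[i], c = col_px[i];
    if (!R_finite(r) || !R_finite(c)) continue;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double fr = r - r0, fc = c - c0;
    for (int dr = 0; dr <= 1; ++dr) {
      int rr = r0 + dr;
      if (rr < 0 || rr >= nrow) continue;
      double wr = dr ? fr : 1.0 - fr;
      for (int dc = 0; dc <= 1; ++dc) {
        int cc = c0 + dc;
        if (cc < 0 || cc >= ncol) continue;
        double wc = dc ? fc : 1.0 - fc;
        out(rr, cc) += amp[i] * wr * wc;
      }
    }
  }
  return out;
}

// Separable 2-D convolution with reflecting borders; kr runs along rows
// (axial), kc along columns (lateral). Kernel lengths must be odd. Both
// passes are structured as contiguous column AXPYs so the inner loops
// vectorize; reflection is handled by index folding per tap.
static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kr, NumericVector kc) {
  const int H = img.nrow(), W = img.ncol();
  const int hr = (kr.size() - 1) / 2, hc = (kc.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  const double *src = img.begin();
  double *t = tmp.begin(), *o = out.begin();

  // vertical pass: tmp(:,j) += kr[k] * img(shifted rows, j)
  for (int j = 0; j < W; ++j) {
    const double *col = src + (size_t)j * H;
    double *tc = t + (size_t)j * H;
    for (int k = -hr; k <= hr; ++k) {
      const double w = kr[k + hr];
      const int lo = std::max(0, -k), hi = std::min(H, H - k);
      const double *s = col + k;
      for (int i = lo; i < hi; ++i) tc[i] += w * s[i];
      for (int i = 0; i < lo; ++i) tc[i] += w * col[reflect(i + k, H)];
      for (int i = hi; i < H; ++i) tc[i] += w * col[reflect(i + k, H)];
    }
  }
  // horizontal pass: out(:,j) += kc[k] * tmp(:, reflected j+k)
  for (int j = 0; j < W; ++j) {
    double *oc = o + (size_t)j * H;
    for (int k = -hc; k <= hc; ++k) {
      const double w = kc[k + hc];
      const double *tc = t + (size_t)reflect(j + k, W) * H;
      for (int i = 0; i < H; ++i) oc[i] += w * tc[i];
    }
  }
  return out;
}

// Log compression of an envelope image to quantized 8-bit levels:
// round(255 * log1p(alpha * env / ref) / log1p(alpha)), clamped to [0, 255].
// [[Rcpp::export]]
NumericMatrix cpp_log8(NumericMatrix env, double ref, double alpha) {
  const double denom = std::log1p(alpha);
  NumericMatrix out(env.nrow(), env.ncol());
  const double *e = env.begin();
  double *o = out.begin();
  const R_xlen_t n = env.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = 255.0 * std::log1p(alpha * e[i] / ref) / denom;
    if (x < 0.0) x = 0.0;
    if (x > 255.0) x = 255.0;
    o[i] = std::nearbyint(x);
  }
  return out;
}

// Zero-normalized cross-correlation of `templ` against every integer
// placement inside `search`. Returns an (Hs-Ht+1) x (Ws-Wt+1) map of
// correlation coefficients in [-1, 1]; placements where the image patch
// has zero variance yield 0.
// [[Rcpp::export]]
NumericMatrix cpp_zncc_map(NumericMatrix search, NumericMatrix templ) {
  const int Hs = search.nrow(), Ws = search.ncol();
  const int Ht = templ.nrow(), Wt = templ.ncol();
  const int Hm = Hs - Ht + 1, Wm = Ws - Wt + 1;
  if (Hm < 1 || Wm < 1) stop("template larger than search window");
  const int n = Ht * Wt;

  double tsum = 0.0, tsq = 0.0;
  for (int j = 0; j < Wt; ++j)
    for (int i = 0; i < Ht; ++i) { tsum += templ(i, j); tsq += templ(i, j) * templ(i, j); }
  const double tmean = tsum / n;
  const double tvar = tsq - tsum * tsum / n;
  if (tvar <= 0.0) stop("template has zero intensity variance");

  NumericMatrix out(Hm, Wm);
  for (int dc = 0; dc < Wm; ++dc) {
    for (int dr = 0; dr < Hm; ++dr) {
      double ssum = 0.0, ssq = 0.0, cross = 0.0;
      for (int j = 0; j < Wt; ++j) {
        for (int i = 0; i < Ht; ++i) {
          double s = search(dr + i, dc + j);
          ssum += s; ssq += s * s;
          cross += s * templ(i, j);
        }
      }
      double svar = ssq - ssum * ssum / n;
      if (svar <= 0.0) { out(dr, dc) = 0.0; continue; }
      out(dr, dc) = (cross - ssum * tmean) / std::sqrt(svar * tvar);
    }
  }
  return out;
}
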