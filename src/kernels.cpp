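#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Patches are stored one per COLUMN (length 3*npx: R, G, B channel blocks,
// each column-major within the image), so each patch is contiguous in
// memory.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline double mod_pos(double x, double m) {
  return x - m * std::floor(x / m);
}

// Photometric + geometric training jitter, one patch per column. perm holds
// one 1-based within-channel source-index permutation per COLUMN; combo
// selects the column (1-based) realizing each patch's rotation/flip. Order:
// geometry, brightness, saturation, hue (HSV space), contrast about the
// patch mean, clip to [0,1]. Identity steps are skipped so pure geometry is
// exact.
// [[Rcpp::export]]
NumericMatrix augment_cols_cpp(NumericMatrix X, int npx,
                               IntegerVector combo,
                               IntegerMatrix perm,
                               NumericVector d_bright,
                               NumericVector d_sat,
                               NumericVector d_hue,
                               NumericVector f_contrast) {
  int n = X.ncol();
  NumericMatrix out(3 * npx, n);
  for (int j = 0; j < n; ++j) {
    const double* src = &X(0, j);
    double* dst = &out(0, j);
    const int* pr = &perm(0, combo[j] - 1);
    double db = d_bright[j], ds = d_sat[j], dh = d_hue[j], fc = f_contrast[j];
    bool bright = db != 0.0, hsv = (ds != 0.0 || dh != 0.0);
    double colsum = 0.0;
    for (int p = 0; p < npx; ++p) {
      int q = pr[p] - 1;
      double r = src[q], g = src[npx + q], b = src[2 * npx + q];
      if (bright) {
        r = clamp01(r + db); g = clamp01(g + db); b = clamp01(b + db);
      }
      if (hsv) {
        double M = r > g ? (r > b ? r : b) : (g > b ? g : b);
        double m = r < g ? (r < b ? r : b) : (g < b ? g : b);
        double d = M - m;
        double v = M;
        double s = M > 0.0 ? d / M : 0.0;
        double h;
        if (d <= 0.0) h = 0.0;
        else if (M == r) h = (g - b) / d;
        else if (M == g) h = (b - r) / d + 2.0;
        else h = (r - g) / d + 4.0;
        h /= 6.0;
        if (h < 0.0) h += 1.0;
        h = mod_pos(h + dh, 1.0);
        s = clamp01(s + ds);
        double h6 = h * 6.0;
        double ks[3] = {5.0, 3.0, 1.0};
        double rgb[3];
        for (int c = 0; c < 3; ++c) {
          double k = mod_pos(ks[c] + h6, 6.0);
          double kk = k < 4.0 - k ? k : 4.0 - k;
          rgb[c] = v - v * s * clamp01(kk);
        }
        r = rgb[0]; g = rgb[1]; b = rgb[2];
      }
      dst[p] = r; dst[npx + p] = g; dst[2 * npx + p] = b;
      colsum += r + g + b;
    }
    if (fc != 1.0) {
      double mu = colsum / (3.0 * npx);
      for (int c = 0; c < 3 * npx; ++c) {
        dst[c] = clamp01(mu + fc * (dst[c] - mu));
      }
    }
  }
  return out;
}

// Summary statistics, one patch per column; returns one ROW of 11 features
// per patch: channel means and sds, luminance gradient energies, coarse
// block-mean sd, luminance skewness and kurtosis.
// [[Rcpp::export]]
NumericMatrix patch_stats_cols_cpp(NumericMatrix X, int size) {
  int n = X.ncol();
  int npx = size * size;
  int block = size / 4; if (block < 1) block = 1;
  int nb_side = size / block;
  int nb = nb_side * nb_side;
  NumericMatrix out(n, 11);
  std::vector<double> L(npx);
  std::vector<double> bsum(nb), bcnt(nb);
  for (int j = 0; j < n; ++j) {
    const double* src = &X(0, j);
    double sums[3] = {0, 0, 0}, sq[3] = {0, 0, 0};
    for (int p = 0; p < npx; ++p) {
      double r = src[p], g = src[npx + p], b = src[2 * npx + p];
      sums[0] += r; sums[1] += g; sums[2] += b;
      sq[0] += r * r; sq[1] += g * g; sq[2] += b * b;
      L[p] = (r + g + b) / 3.0;
    }
    for (int c = 0; c < 3; ++c) {
      double mu = sums[c] / npx;
      double var = sq[c] / npx - mu * mu;
      out(j, c) = mu;
      out(j, 3 + c) = var > 0 ? std::sqrt(var) : 0.0;
    }
    // horizontal neighbour is +size (next image column), vertical +1
    double gh = 0.0, gv = 0.0;
    int nh = 0, nv = 0;
    for (int p = 0; p < npx; ++p) {
      if (p + size < npx) { gh += std::fabs(L[p + size] - L[p]); ++nh; }
      if ((p + 1) % size != 0) { gv += std::fabs(L[p + 1] - L[p]); ++nv; }
    }
    out(j, 6) = gh / nh;
    out(j, 7) = gv / nv;
    std::fill(bsum.begin(), bsum.end(), 0.0);
    std::fill(bcnt.begin(), bcnt.end(), 0.0);
    double lsum = 0.0;
    for (int p = 0; p < npx; ++p) {
      int r = p % size, c = p / size;
      int bi = (r / block) + nb_side * (c / block);
      if (bi >= nb) bi = nb - 1;
      bsum[bi] += L[p]; bcnt[bi] += 1.0;
      lsum += L[p];
    }
    double bmu = 0.0;
    for (int k = 0; k < nb; ++k) { bsum[k] /= bcnt[k]; bmu += bsum[k]; }
    bmu /= nb;
    double bvar = 0.0;
    for (int k = 0; k < nb; ++k) bvar += (bsum[k] - bmu) * (bsum[k] - bmu);
    out(j, 8) = std::sqrt(bvar / nb);
    double lmu = lsum / npx, m2 = 0.0, m3 = 0.0, m4 = 0.0;
    for (int p = 0; p < npx; ++p) {
      double d = L[p] - lmu;
      double dd = d * d;
      m2 += dd; m3 += dd * d; m4 += dd * dd;
    }
    m2 /= npx; m3 /= npx; m4 /= npx;
    double sd = std::sqrt(m2 > 0 ? m2 : 0);
    if (sd < 1e-8) sd = 1e-8;
    out(j, 9) = m3 / (sd * sd * sd);
    out(j, 10) = m4 / (sd * sd * sd * sd);
  }
  return out;
}
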