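#include <Rcpp.h>
using namespace Rcpp;

// Separable 2-D convolution with replicate (clamp-to-edge) borders.
// img is h x w (rows = y), kx filters along x (columns), ky along y (rows).
// Kernels must have odd length. Interior pixels take a branch-free fast
// path; borders are clamped.
// [[Rcpp::export(name = ".conv_sep_cpp")]]
NumericMatrix conv_sep_cpp(NumericMatrix img, NumericVector kx, NumericVector ky) {
  const int h = img.nrow(), w = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double *src = img.begin();
  double *t = tmp.begin();

  // horizontal pass: out column x from source columns x-rx..x+rx
  for (int x = 0; x < w; ++x) {
    double *tc = t + (size_t)x * h;
    for (int y = 0; y < h; ++y) tc[y] = 0.0;
    for (int k = -rx; k <= rx; ++k) {
      int xs = x + k;
      if (xs < 0) xs = 0; else if (xs >= w) xs = w - 1;
      const double *sc = src + (size_t)xs * h;
      const double kv = kx[k + rx];
      for (int y = 0; y < h; ++y) tc[y] += kv * sc[y];
    }
  }
  // vertical pass
  double *o = out.begin();
  for (int x = 0; x < w; ++x) {
    const double *tc = t + (size_t)x * h;
    double *oc = o + (size_t)x * h;
    for (int y = 0; y < std::min(ry, h); ++y) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int ys = y + k;
        if (ys < 0) ys = 0;
        acc += ky[k + ry] * tc[ys];
      }
      oc[y] = acc;
    }
    for (int y = ry; y < h - ry; ++y) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k) acc += ky[k + ry] * tc[y + k];
      oc[y] = acc;
    }
    for (int y = std::max(h - ry, ry); y < h; ++y) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int ys = y + k;
        if (ys >= h) ys = h - 1;
        acc += ky[k + ry] * tc[ys];
      }
      oc[y] = acc;
    }
  }
  return out;
}

// Bilinear sampling of img (h x w) at continuous positions (x, y) in pixel
// units with (1, 1) at the centre of the top-left pixel. Positions outside
// the image return `fill`.
// [[Rcpp::export(name = ".bilinear_sample_cpp")]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector x,
                                  NumericVector y, double fill) {
  const int h = img.nrow(), w = img.ncol();
  const int n = x.size();
  const double *src = img.begin();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    if (!R_finite(xi) || !R_finite(yi) ||
        xi < 1.0 || xi > (double)w || yi < 1.0 || yi > (double)h) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)xi, y0 = (int)yi;
    if (x0 >= w) x0 = w - 1;
    if (y0 >= h) y0 = h - 1;
    const double fx = xi - x0, fy = yi - y0;
    const double *c0 = src + (size_t)(x0 - 1) * h + (y0 - 1);
    const double *c1 = c0 + h;
    const double v00 = c0[0], v10 = c0[1], v01 = c1[0], v11 = c1[1];
    out[i] = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
             fy * ((1 - fx) * v10 + fx * v11);
  }
  return out;
}

// Strict-in-3x3-neighbourhood local maxima of a response matrix above a
// threshold, excluding a border margin. Returns 1-based linear indices.
// [[Rcpp::export(name = ".local_max_cpp")]]
IntegerVector local_max_cpp(NumericMatrix resp, double thr, int border) {
  const int h = resp.nrow(), w = resp.ncol();
  const double *r = resp.begin();
  std::vector<int> idx;
  for (int x = border; x < w - border; ++x) {
    const double *c = r + (size_t)x * h;
    const double *cl = c - h, *cr = c + h;
    for (int y = border; y < h - border; ++y) {
      const double v = c[y];
      if (v <= thr) continue;
      if (v >= c[y - 1] && v >= c[y + 1] &&
          v >= cl[y - 1] && v >= cl[y] && v >= cl[y + 1] &&
          v >= cr[y - 1] && v >= cr[y] && v >= cr[y + 1])
        idx.push_back(x * h + y + 1);
    }
  }
  return wrap(idx);
}

// Mutual-best descriptor matching with a displacement gate. desc_* are
// n x d row-normalized descriptor matrices; scores are dot products.
// Returns for each row of a: the best b (1-based, 0 = none) if mutual and
// score >= min_score, plus the score.
// [[Rcpp::export(name = ".match_desc_cpp")]]
List match_desc_cpp(NumericMatrix desc_a, NumericVector xa, NumericVector ya,
                    NumericMatrix desc_b, NumericVector xb, NumericVector yb,
                    double max_disp, double min_score) {
  const int na = desc_a.nrow(), nb = desc_b.nrow(), d = desc_a.ncol();
  const double md2 = max_disp * max_disp;
  std::vector<int> best_b(na, -1), best_a(nb, -1);
  std::vector<double> sc_a(na, -2.0), sc_b(nb, -2.0);
  const double *A = desc_a.begin(), *B = desc_b.begin();
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
      if (dx * dx + dy * dy > md2) continue;
      double s = 0.0;
      // descriptors are stored column-major: stride na / nb per dim
      const double *ai = A + i, *bj = B + j;
      for (int k = 0; k < d; ++k)
        s += ai[(size_t)k * na] * bj[(size_t)k * nb];
      if (s > sc_a[i]) { sc_a[i] = s; best_b[i] = j; }
      if (s > sc_b[j]) { sc_b[j] = s; best_a[j] = i; }
    }
  }
  IntegerVector out(na);
  NumericVector osc(na);
  for (int i = 0; i < na; ++i) {
    const int j = best_b[i];
    if (j >= 0 && best_a[j] == i && sc_a[i] >= min_score) {
      out[i] = j + 1;
      osc[i] = sc_a[i];
    } else {
      out[i] = 0;
      osc[i] = NA_REAL;
    }
  }
  return List::create(_["match"] = out, _["score"] = osc);
}

// Subpixel refinement of matched positions: for each match, ZNCC of the
// (normalized) template row against img_b patches at the 3x3 integer
// shifts around (xb0, yb0), then a 1-D quadratic peak fit per axis.
// Returns refined xb, yb.
// [[Rcpp::export(name = ".refine_match_cpp")]]
List refine_match_cpp(NumericMatrix img_b, NumericMatrix tmpl,
                      IntegerVector xb0, IntegerVector yb0, int half) {
  const int h = img_b.nrow(), w = img_b.ncol();
  const int n = tmpl.nrow(), k = 2 * half + 1, d = k * k;
  const double *I = img_b.begin(), *T = tmpl.begin();
  NumericVector ox(n), oy(n);
  std::vector<double> patch(d);
  for (int m = 0; m < n; ++m) {
    double sc[3][3];
    bool fin[3][3];
    for (int sy = -1; sy <= 1; ++sy) {
      for (int sx = -1; sx <= 1; ++sx) {
        const int cx = xb0[m] + sx, cy = yb0[m] + sy;
        fin[sy + 1][sx + 1] = false;
        sc[sy + 1][sx + 1] = 0.0;
        if (cx - half < 1 || cx + half > w || cy - half < 1 || cy + half > h)
          continue;
        double mean = 0.0;
        int p = 0;
        for (int ddx = -half; ddx <= half; ++ddx) {
          const double *col = I + (size_t)(cx + ddx - 1) * h + (cy - half - 1);
          for (int ddy = 0; ddy < k; ++ddy, ++p) {
            patch[p] = col[ddy];
            mean += col[ddy];
          }
        }
        mean /= d;
        double nrm = 0.0, dot = 0.0;
        for (int p2 = 0; p2 < d; ++p2) {
          const double v = patch[p2] - mean;
          nrm += v * v;
          dot += T[(size_t)p2 * n + m] * v;
        }
        if (nrm < 1e-12) continue;
        sc[sy + 1][sx + 1] = dot / std::sqrt(nrm);
        fin[sy + 1][sx + 1] = true;
      }
    }
    double cx = 0.0, cy = 0.0;
    if (fin[1][1]) {
      if (fin[1][0] && fin[1][2]) {
        const double den = sc[1][0] - 2 * sc[1][1] + sc[1][2];
        if (std::fabs(den) > 1e-12) {
          cx = 0.5 * (sc[1][0] - sc[1][2]) / den;
          if (cx > 0.5) cx = 0.5; else if (cx < -0.5) cx = -0.5;
        }
      }
      if (fin[0][1] && fin[2][1]) {
        const double den = sc[0][1] - 2 * sc[1][1] + sc[2][1];
        if (std::fabs(den) > 1e-12) {
          cy = 0.5 * (sc[0][1] - sc[2][1]) / den;
          if (cy > 0.5) cy = 0.5; else if (cy < -0.5) cy = -0.5;
        }
      }
    }
    ox[m] = xb0[m] + cx;
    oy[m] = yb0[m] + cy;
  }
  return List::create(_["xb"] = ox, _["yb"] = oy);
}
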