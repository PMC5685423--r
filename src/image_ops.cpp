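// Low-level raster operations for stimulus rendering and the observer
// front end. Images are plain numeric matrices; row 0 is the top of the
// image (largest y), columns increase with x. All geometry arguments are
// in arcmin unless the name says pixels.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Separable Gaussian blur with edge replication. sigma_px in pixels;
// kernel truncated at 3 sigma and renormalized.
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur(const arma::mat& img, double sigma_px) {
  if (sigma_px <= 0.0) return img;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma_px));
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)i * i / (sigma_px * sigma_px));
  k /= arma::accu(k);
  const int n = img.n_rows, m = img.n_cols;
  arma::mat tmp(n, m), out(n, m, arma::fill::zeros);
  // vertical pass: convolve each (contiguous) column via an edge-padded buffer
  std::vector<double> buf(n + 2 * r);
  for (int j = 0; j < m; ++j) {
    const double* src = img.colptr(j);
    for (int i = 0; i < r; ++i) buf[i] = src[0];
    std::copy(src, src + n, buf.begin() + r);
    for (int i = 0; i < r; ++i) buf[n + r + i] = src[n - 1];
    double* dst = tmp.colptr(j);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t <= 2 * r; ++t) s += k(t) * buf[i + t];
      dst[i] = s;
    }
  }
  // horizontal pass: whole-column AXPY over clamped neighbor columns
  for (int j = 0; j < m; ++j) {
    arma::vec acc(n, arma::fill::zeros);
    for (int t = -r; t <= r; ++t) {
      int jj = j + t;
      if (jj < 0) jj = 0; else if (jj >= m) jj = m - 1;
      acc += k(t + r) * tmp.col(jj);
    }
    out.col(j) = acc;
  }
  return out;
}

// Translate image content by (drow, dcol) pixels with bilinear
// interpolation; out(r, c) = in(r - drow, c - dcol), `pad` outside.
// [[Rcpp::export]]
arma::mat cpp_translate(const arma::mat& img, double drow, double dcol,
                        double pad) {
  const int n = img.n_rows, m = img.n_cols;
  arma::mat out(n, m);
  const int ir = (int)std::floor(drow), ic = (int)std::floor(dcol);
  const double fr = drow - ir, fc = dcol - ic;
  for (int c = 0; c < m; ++c) {
    const int c0 = c - ic - 1, c1 = c - ic; // source cols for this output col
    const bool ok0 = c0 >= 0 && c0 < m, ok1 = c1 >= 0 && c1 < m;
    const double* s0 = ok0 ? img.colptr(c0) : nullptr;
    const double* s1 = ok1 ? img.colptr(c1) : nullptr;
    double* dst = out.colptr(c);
    for (int r = 0; r < n; ++r) {
      const int r0 = r - ir - 1, r1 = r - ir;
      const bool okr0 = r0 >= 0 && r0 < n, okr1 = r1 >= 0 && r1 < n;
      const double v00 = (okr0 && ok0) ? s0[r0] : pad; // (r-ir-1, c-ic-1)
      const double v10 = (okr1 && ok0) ? s0[r1] : pad; // (r-ir,   c-ic-1)
      const double v01 = (okr0 && ok1) ? s1[r0] : pad; // (r-ir-1, c-ic)
      const double v11 = (okr1 && ok1) ? s1[r1] : pad; // (r-ir,   c-ic)
      // source row is r - ir - fr: lies between r-ir-1 (weight fr) and
      // r-ir (weight 1-fr); likewise for columns
      dst[r] = fr * (fc * v00 + (1 - fc) * v01) +
               (1 - fr) * (fc * v10 + (1 - fc) * v11);
    }
  }
  return out;
}

// Average over p x p pixel blocks anchored on the canvas sampling lattice,
// then replicate the block mean back to pixel resolution. off_r/off_c give
// the 0-based offset of the image's first pixel within its lattice block.
// Models a coarse, canvas-fixed sampling mosaic.
// [[Rcpp::export]]
arma::mat cpp_block_sample(const arma::mat& img, int p, int off_r, int off_c) {
  if (p <= 1) return img;
  const int n = img.n_rows, m = img.n_cols;
  const int nb = (n + off_r + p - 1) / p, mb = (m + off_c + p - 1) / p;
  arma::mat sum(nb, mb, arma::fill::zeros);
  arma::mat cnt(nb, mb, arma::fill::zeros);
  for (int r = 0; r < n; ++r) {
    const int br = (r + off_r) / p;
    for (int c = 0; c < m; ++c) {
      const int bc = (c + off_c) / p;
      sum(br, bc) += img(r, c);
      cnt(br, bc) += 1.0;
    }
  }
  arma::mat out(n, m);
  for (int r = 0; r < n; ++r) {
    const int br = (r + off_r) / p;
    for (int c = 0; c < m; ++c) {
      const int bc = (c + off_c) / p;
      out(r, c) = sum(br, bc) / cnt(br, bc);
    }
  }
  return out;
}

// Coverage in [0, 1] of a Landolt ring (annulus of outer diameter `diam`,
// ring width diam/5, with a square-profile slot of width diam/5 cut along
// the unit gap axis (ux, uy)) rasterized by ss x ss supersampling.
// (x_tl, y_tl) are the arcmin coordinates of the center of the top-left
// pixel; app is arcmin per pixel; (cx, cy) the ring center.
// [[Rcpp::export]]
arma::mat cpp_render_landolt(int nrow, int ncol, double x_tl, double y_tl,
                             double app, double cx, double cy, double diam,
                             double ux, double uy, int ss) {
  arma::mat out(nrow, ncol, arma::fill::zeros);
  const double r_out = 0.5 * diam;
  const double r_in = 0.3 * diam;
  const double half_w = 0.1 * diam;
  const double sub = app / ss;
  // cheap reject radius: pixel centers farther than r_out + pixel diagonal
  const double rej = r_out + app * 1.5;
  for (int r = 0; r < nrow; ++r) {
    const double py = y_tl - r * app;
    for (int c = 0; c < ncol; ++c) {
      const double px = x_tl + c * app;
      const double ddx = px - cx, ddy = py - cy;
      if (ddx * ddx + ddy * ddy > rej * rej) continue;
      int hit = 0;
      for (int sy = 0; sy < ss; ++sy) {
        const double y = py + (0.5 * (ss - 1) - sy) * sub;
        const double dy = y - cy;
        for (int sx = 0; sx < ss; ++sx) {
          const double x = px + (sx - 0.5 * (ss - 1)) * sub;
          const double dx = x - cx;
          const double rr = dx * dx + dy * dy;
          if (rr < r_in * r_in || rr > r_out * r_out) continue;
          const double proj = dx * ux + dy * uy;
          const double perp = -dx * uy + dy * ux;
          if (proj > 0.0 && std::fabs(perp) <= half_w) continue;  // gap
          ++hit;
        }
      }
      out(r, c) = (double)hit / (ss * ss);
    }
  }
  return out;
}

// Coverage in [0, 1] of the opaque elements of an element-grid mask.
// `pattern` is the n_side x n_side 0/1 opacity matrix (row 0 = top row of
// the mask, i.e. largest y). The mask occupies the square of side
// n_side * elem whose top-left corner is (mask_x0, mask_y0) with y
// decreasing downwards. Supersampled ss x ss per pixel.
// [[Rcpp::export]]
arma::mat cpp_mask_coverage(int nrow, int ncol, double x_tl, double y_tl,
                            double app, double mask_x0, double mask_y0,
                            double elem, const arma::imat& pattern, int ss) {
  arma::mat out(nrow, ncol, arma::fill::zeros);
  const int n_side = pattern.n_rows;
  const double ext = n_side * elem;
  const double sub = app / ss;
  for (int r = 0; r < nrow; ++r) {
    const double py = y_tl - r * app;
    for (int c = 0; c < ncol; ++c) {
      const double px = x_tl + c * app;
      // reject pixels fully outside the mask square
      if (px < mask_x0 - app || px > mask_x0 + ext + app ||
          py > mask_y0 + app || py < mask_y0 - ext - app)
        continue;
      int hit = 0;
      for (int sy = 0; sy < ss; ++sy) {
        const double y = py + (0.5 * (ss - 1) - sy) * sub;
        const int ei = (int)std::floor((mask_y0 - y) / elem);
        if (ei < 0 || ei >= n_side) continue;
        for (int sx = 0; sx < ss; ++sx) {
          const double x = px + (sx - 0.5 * (ss - 1)) * sub;
          const int ej = (int)std::floor((x - mask_x0) / elem);
          if (ej < 0 || ej >= n_side) continue;
          if (pattern(ei, ej)) ++hit;
        }
      }
      out(r, c) = (double)hit / (ss * ss);
    }
  }
  return out;
}

// Subsample-to-element index map for a mask at a fixed position: for each
// pixel, the 1-based linear element index hit by each of the ss x ss
// subsamples, 0 when outside the mask. Rows of the result are pixels in
// column-major order, columns the subsamples.
// [[Rcpp::export]]
arma::imat cpp_mask_index(int nrow, int ncol, double x_tl, double y_tl,
                          double app, double mask_x0, double mask_y0,
                          double elem, int n_side, int ss) {
  arma::imat out(nrow * ncol, ss * ss, arma::fill::zeros);
  const double sub = app / ss;
  for (int c = 0; c < ncol; ++c) {
    const double px = x_tl + c * app;
    for (int r = 0; r < nrow; ++r) {
      const double py = y_tl - r * app;
      const int pix = c * nrow + r;
      int s = 0;
      for (int sy = 0; sy < ss; ++sy) {
        const double y = py + (0.5 * (ss - 1) - sy) * sub;
        const int ei = (int)std::floor((mask_y0 - y) / elem);
        for (int sx = 0; sx < ss; ++sx, ++s) {
          if (ei < 0 || ei >= n_side) continue;
          const double x = px + (sx - 0.5 * (ss - 1)) * sub;
          const int ej = (int)std::floor((x - mask_x0) / elem);
          if (ej < 0 || ej >= n_side) continue;
          out(pix, s) = 1 + ej * n_side + ei; // column-major linear index
        }
      }
    }
  }
  return out;
}

// Resolve an index map against an opacity pattern: per-pixel mean opacity
// over the subsamples (out-of-mask subsamples count as transparent).
// [[Rcpp::export]]
arma::vec cpp_mask_cov_indexed(const arma::imat& map,
                               const arma::imat& pattern) {
  const int npix = map.n_rows, nss = map.n_cols;
  const arma::sword* pat = pattern.memptr();
  arma::vec out(npix);
  for (int p = 0; p < npix; ++p) {
    int hit = 0;
    for (int s = 0; s < nss; ++s) {
      const long long e = map(p, s);
      if (e > 0 && pat[e - 1]) ++hit;
    }
    out(p) = (double)hit / nss;
  }
  return out;
}

// Add i.i.d. zero-mean Gaussian noise of standard deviation sd to every
// pixel, drawing from R's RNG stream (Marsaglia polar method), so results
// are reproducible from set.seed().
// [[Rcpp::export]]
arma::mat cpp_add_noise(const arma::mat& img, double sd) {
  arma::mat out = img;
  double* p = out.memptr();
  const int n = out.n_elem;
  int i = 0;
  while (i < n) {
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    p[i++] += sd * f * u;
    if (i < n) p[i++] += sd * f * v;
  }
  return out;
}
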