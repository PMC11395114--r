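#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Activation tensors are stored as N x C matrices with N = H*W*B and
// row index r = h + H*(w + W*b) (column-major within each sample,
// samples stacked along rows). All kernels below respect that layout.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int H, int W, int B,
                         int k, int pad) {
  const int C = X.ncol();
  const int N = H * W * B;
  NumericMatrix out(N, k * k * C);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const int r = h + H * (w + W * b);
        for (int c = 0; c < C; ++c) {
          for (int dj = 0; dj < k; ++dj) {
            const int ws = w + dj - pad;
            const bool win = (ws >= 0 && ws < W);
            for (int di = 0; di < k; ++di) {
              const int hs = h + di - pad;
              double v = 0.0;
              if (win && hs >= 0 && hs < H)
                v = X(hs + H * (ws + W * b), c);
              out(r, di + k * (dj + k * c)) = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add column gradients back to pixels.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int H, int W, int B,
                         int k, int pad, int C) {
  const int N = H * W * B;
  NumericMatrix out(N, C);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const int r = h + H * (w + W * b);
        for (int c = 0; c < C; ++c) {
          for (int dj = 0; dj < k; ++dj) {
            const int ws = w + dj - pad;
            if (ws < 0 || ws >= W) continue;
            for (int di = 0; di < k; ++di) {
              const int hs = h + di - pad;
              if (hs < 0 || hs >= H) continue;
              out(hs + H * (ws + W * b), c) += cols(r, di + k * (dj + k * c));
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled matrix and 1-based argmax
// row indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(const NumericMatrix& X, int H, int W, int B) {
  const int C = X.ncol();
  const int H2 = H / 2, W2 = W / 2;
  NumericMatrix out(H2 * W2 * B, C);
  IntegerMatrix idx(H2 * W2 * B, C);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        const int r = h + H2 * (w + W2 * b);
        const int h0 = 2 * h, w0 = 2 * w;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int bestr = -1;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int rr = (h0 + di) + H * ((w0 + dj) + W * b);
              const double v = X(rr, c);
              if (v > best) { best = v; bestr = rr; }
            }
          }
          out(r, c) = best;
          idx(r, c) = bestr + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_backward(const NumericMatrix& dout,
                                    const IntegerMatrix& idx, int N) {
  const int C = dout.ncol();
  NumericMatrix dx(N, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < dout.nrow(); ++r)
      dx(idx(r, c) - 1, c) += dout(r, c);
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& X, int H, int W, int B) {
  const int C = X.ncol();
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(H2 * W2 * B, C);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const int rs = (h / 2) + H * ((w / 2) + W * b);
        const int r = h + H2 * (w + W2 * b);
        for (int c = 0; c < C; ++c) out(r, c) = X(rs, c);
      }
  return out;
}

// Adjoint of cpp_upsample2: sum each 2x2 block.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2_backward(const NumericMatrix& dout,
                                     int H2, int W2, int B) {
  const int C = dout.ncol();
  const int H = H2 / 2, W = W2 / 2;
  NumericMatrix dx(H * W * B, C);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const int rt = (h / 2) + H * ((w / 2) + W * b);
        const int r = h + H2 * (w + W2 * b);
        for (int c = 0; c < C; ++c) dx(rt, c) += dout(r, c);
      }
  return dx;
}

static inline int reflect_idx(int i, int n) {
  // symmetric reflection: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Median filter with odd square window and reflected borders.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int k) {
  const int H = img.nrow(), W = img.ncol();
  const int half = k / 2, m = k * k;
  IntegerMatrix out(H, W);
  std::vector<int> buf(m);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -half; dj <= half; ++dj) {
        const int jj = reflect_idx(j + dj, W);
        for (int di = -half; di <= half; ++di)
          buf[n++] = img(reflect_idx(i + di, H), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}

// Binary dilation by an odd square structuring element; pixels outside
// the image are background (set-theoretic convention on the padded plane).
// [[Rcpp::export]]
IntegerMatrix cpp_binary_dilate(const IntegerMatrix& m, int k) {
  const int H = m.nrow(), W = m.ncol(), half = k / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int v = 0;
      for (int dj = -half; dj <= half && !v; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -half; di <= half; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          if (m(ii, jj)) { v = 1; break; }
        }
      }
      out(i, j) = v;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_binary_erode(const IntegerMatrix& m, int k) {
  const int H = m.nrow(), W = m.ncol(), half = k / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int v = 1;
      for (int dj = -half; dj <= half && v; ++dj) {
        const int jj = j + dj;
        for (int di = -half; di <= half; ++di) {
          const int ii = i + di;
          if (jj < 0 || jj >= W || ii < 0 || ii >= H || !m(ii, jj)) {
            v = 0; break;
          }
        }
      }
      out(i, j) = v;
    }
  return out;
}

// Zhang-Suen thinning of a 0/1 matrix to a one-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int i = 0; i < H; ++i) {
        for (int j = 0; j < W; ++j) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise starting north
          const int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          const int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          const int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          const int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          const int bsum = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (bsum < 2 || bsum > 6) continue;
          int a = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int s = 0; s < 8; ++s)
            if (seq[s] == 0 && seq[s + 1] == 1) ++a;
          if (a != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t s = 0; s < del.size(); ++s)
        img(del[s].first, del[s].second) = 0;
    }
  }
  return img;
}

// 8-connected component labelling (BFS); labels start at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      lab(i0, j0) = ++next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        const int i = q.front().first, j = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Stamp a tube: mark all pixels within `radius` of any centerline sample.
// xs/ys are 0-based (x = column, y = row) continuous coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_stamp_tube(int H, int W, const NumericVector& xs,
                             const NumericVector& ys, double radius) {
  IntegerMatrix out(H, W);
  const double r2 = radius * radius;
  for (int s = 0; s < xs.size(); ++s) {
    const double x = xs[s], y = ys[s];
    const int i0 = std::max(0, (int)std::floor(y - radius));
    const int i1 = std::min(H - 1, (int)std::ceil(y + radius));
    const int j0 = std::max(0, (int)std::floor(x - radius));
    const int j1 = std::min(W - 1, (int)std::ceil(x + radius));
    for (int j = j0; j <= j1; ++j) {
      const double dx = j - x;
      for (int i = i0; i <= i1; ++i) {
        const double dy = i - y;
        if (dx * dx + dy * dy <= r2) out(i, j) = 1;
      }
    }
  }
  return out;
}

// Bilinear sampling at continuous (x, y) = (col, row), 0-based.
// Out-of-bounds positions return `fill`.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img, const NumericVector& xs,
                           const NumericVector& ys, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const int n = xs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    const double x = xs[s], y = ys[s];
    if (x < 0 || y < 0 || x > W - 1 || y > H - 1) { out[s] = fill; continue; }
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
    const double fx = x - x0, fy = y - y0;
    out[s] = img(y0, x0) * (1 - fx) * (1 - fy) +
             img(y0, x1) * fx * (1 - fy) +
             img(y1, x0) * (1 - fx) * fy +
             img(y1, x1) * fx * fy;
  }
  return out;
}

// Bilinear resize with corner alignment (identity when sizes match).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int outH, int outW) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(outH, outW);
  const double sy = (outH > 1) ? (double)(H - 1) / (outH - 1) : 0.0;
  const double sx = (outW > 1) ? (double)(W - 1) / (outW - 1) : 0.0;
  for (int j = 0; j < outW; ++j) {
    const double x = j * sx;
    const int x0 = (int)std::floor(x);
    const int x1 = std::min(x0 + 1, W - 1);
    const double fx = x - x0;
    for (int i = 0; i < outH; ++i) {
      const double y = i * sy;
      const int y0 = (int)std::floor(y);
      const int y1 = std::min(y0 + 1, H - 1);
      const double fy = y - y0;
      out(i, j) = img(y0, x0) * (1 - fx) * (1 - fy) +
                  img(y0, x1) * fx * (1 - fy) +
                  img(y1, x0) * (1 - fx) * fy +
                  img(y1, x1) * fx * fy;
    }
  }
  return out;
}
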