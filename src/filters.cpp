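#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Pixel-grid conventions used throughout: images are R matrices indexed
// [row, col] = [y + 1, x + 1] with the origin at the top-left pixel centre;
// 0-based (x, y) coordinates address pixel centres.

// Per-pixel Shannon entropy (base 2) of the 256-bin intensity histogram in a
// disk neighbourhood, restricted to pixels inside the frame. Input values
// must already be integers in [0, 255].
// [[Rcpp::export]]
NumericMatrix entropy_filter_cpp(IntegerMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int noff = (int)dy.size();
  NumericMatrix out(nr, nc);
  std::vector<int> count(256, 0);
  std::vector<int> touched;
  touched.reserve(noff);
  const double log2e = 1.0 / std::log(2.0);
  // tabulate c * log2(c) and log2(n) so the inner loop avoids log calls;
  // H = log2(n) - (1/n) * sum_c count_c * log2(count_c)
  std::vector<double> clog(noff + 1), nlog(noff + 1);
  clog[0] = 0.0;
  nlog[0] = 0.0;
  for (int c = 1; c <= noff; ++c) {
    nlog[c] = std::log((double)c) * log2e;
    clog[c] = c * nlog[c];
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int k = 0; k < noff; ++k) {
        const int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const int v = img(ii, jj);
        if (count[v] == 0) touched.push_back(v);
        ++count[v];
        ++n;
      }
      if (touched.size() == 1) {  // constant neighbourhood: exactly 0 bits
        count[touched[0]] = 0;
        touched.clear();
        out(i, j) = 0.0;
        continue;
      }
      double s = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        s += clog[count[touched[t]]];
        count[touched[t]] = 0;
      }
      touched.clear();
      const double h = nlog[n] - s / n;
      out(i, j) = h > 0.0 ? h : 0.0;
    }
  }
  return out;
}

// Separable Gaussian blur with reflected boundaries (kernel radius 3*sigma).
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// Sobel gradient: returns magnitude and the two components.
// [[Rcpp::export]]
List sobel_gradient_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc), mag(nr, nc);
  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, nr), ip = clampi(i + 1, nr);
      const int jm = clampi(j - 1, nc), jp = clampi(j + 1, nc);
      const double sx = (img(im, jp) + 2.0 * img(i, jp) + img(ip, jp)) -
                        (img(im, jm) + 2.0 * img(i, jm) + img(ip, jm));
      const double sy = (img(ip, jm) + 2.0 * img(ip, j) + img(ip, jp)) -
                        (img(im, jm) + 2.0 * img(im, j) + img(im, jp));
      gx(i, j) = sx;
      gy(i, j) = sy;
      mag(i, j) = std::sqrt(sx * sx + sy * sy);
    }
  return List::create(_["mag"] = mag, _["gx"] = gx, _["gy"] = gy);
}

// Non-maximum suppression (4 quantized directions) followed by hysteresis
// thresholding (8-connected flood from strong pixels through weak ones).
// [[Rcpp::export]]
LogicalMatrix canny_nms_hysteresis_cpp(NumericMatrix mag, NumericMatrix gx,
                                       NumericMatrix gy, double low,
                                       double high) {
  const int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix thin(nr, nc);
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 1; i < nr - 1; ++i) {
      const double m = mag(i, j);
      if (m <= 0) continue;
      const double ang = std::atan2(gy(i, j), gx(i, j));
      // quantize to one of 4 neighbour axes; gx is the x (column) derivative
      double a = ang < 0 ? ang + M_PI : ang;  // [0, pi)
      double m1, m2;
      if (a < M_PI / 8 || a >= 7 * M_PI / 8) {        // horizontal gradient
        m1 = mag(i, j - 1); m2 = mag(i, j + 1);
      } else if (a < 3 * M_PI / 8) {                  // diagonal
        m1 = mag(i - 1, j - 1); m2 = mag(i + 1, j + 1);
      } else if (a < 5 * M_PI / 8) {                  // vertical gradient
        m1 = mag(i - 1, j); m2 = mag(i + 1, j);
      } else {                                        // other diagonal
        m1 = mag(i - 1, j + 1); m2 = mag(i + 1, j - 1);
      }
      if (m >= m1 && m >= m2) thin(i, j) = true;
    }
  LogicalMatrix edge(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (thin(i, j) && mag(i, j) > high && high > 0) {
        edge(i, j) = true;
        q.push(std::make_pair(i, j));
      }
  while (!q.empty()) {
    const int i = q.front().first, j = q.front().second;
    q.pop();
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        const int ii = i + a, jj = j + b;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!edge(ii, jj) && thin(ii, jj) && mag(ii, jj) > low) {
          edge(ii, jj) = true;
          q.push(std::make_pair(ii, jj));
        }
      }
  }
  return edge;
}

// Bilinear resampling with pixel-centre alignment (output centre i maps to
// input coordinate (i + .5) * n_in / n_out - .5), edges clamped.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int nr_out, int nc_out) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr_out, nc_out);
  const double ry = (double)nr / nr_out, rx = (double)nc / nc_out;
  for (int j = 0; j < nc_out; ++j) {
    double x = (j + 0.5) * rx - 0.5;
    if (x < 0) x = 0;
    if (x > nc - 1) x = nc - 1;
    const int x0 = (int)std::floor(x), x1 = std::min(x0 + 1, nc - 1);
    const double fx = x - x0;
    for (int i = 0; i < nr_out; ++i) {
      double y = (i + 0.5) * ry - 0.5;
      if (y < 0) y = 0;
      if (y > nr - 1) y = nr - 1;
      const int y0 = (int)std::floor(y), y1 = std::min(y0 + 1, nr - 1);
      const double fy = y - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Nearest-neighbour resampling for label masks.
// [[Rcpp::export]]
IntegerMatrix resize_nearest_cpp(IntegerMatrix img, int nr_out, int nc_out) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr_out, nc_out);
  const double ry = (double)nr / nr_out, rx = (double)nc / nc_out;
  for (int j = 0; j < nc_out; ++j) {
    int x = (int)std::floor((j + 0.5) * rx);
    if (x < 0) x = 0;
    if (x > nc - 1) x = nc - 1;
    for (int i = 0; i < nr_out; ++i) {
      int y = (int)std::floor((i + 0.5) * ry);
      if (y < 0) y = 0;
      if (y > nr - 1) y = nr - 1;
      out(i, j) = img(y, x);
    }
  }
  return out;
}

static bool on_segment(double px, double py, double ax, double ay, double bx,
                       double by) {
  const double cross = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
  if (std::fabs(cross) > 1e-9) return false;
  const double dot = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
  const double len2 = (bx - ax) * (bx - ax) + (by - ay) * (by - ay);
  return dot >= -1e-9 && dot <= len2 + 1e-9;
}

// Even-odd rule point-in-polygon over all pixel centres of an nr x nc frame;
// pixels whose centre lies exactly on the polygon boundary count as inside.
// poly is an n x 2 matrix of (x, y) vertices, 0-based pixel coordinates.
// [[Rcpp::export]]
LogicalMatrix rasterize_polygon_cpp(NumericMatrix poly, int nr, int nc) {
  const int n = poly.nrow();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double px = j;
    for (int i = 0; i < nr; ++i) {
      const double py = i;
      bool inside = false, boundary = false;
      for (int v = 0; v < n && !boundary; ++v) {
        const int w = (v + 1) % n;
        const double ax = poly(v, 0), ay = poly(v, 1);
        const double bx = poly(w, 0), by = poly(w, 1);
        if (on_segment(px, py, ax, ay, bx, by)) { boundary = true; break; }
        if ((ay > py) != (by > py)) {
          const double xint = ax + (py - ay) / (by - ay) * (bx - ax);
          if (px < xint) inside = !inside;
        }
      }
      out(i, j) = inside || boundary;
    }
  }
  return out;
}

// Minimum distance from each of a set of pixels to a polyline (closed),
// used to check that detected edges hug ground-truth interfaces.
// [[Rcpp::export]]
NumericVector dist_to_polygon_cpp(NumericMatrix pts, NumericMatrix poly) {
  const int m = pts.nrow(), n = poly.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    const double px = pts(p, 0), py = pts(p, 1);
    double best = R_PosInf;
    for (int v = 0; v < n; ++v) {
      const int w = (v + 1) % n;
      const double ax = poly(v, 0), ay = poly(v, 1);
      const double bx = poly(w, 0), by = poly(w, 1);
      const double dx = bx - ax, dy = by - ay;
      const double len2 = dx * dx + dy * dy;
      double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      const double qx = ax + t * dx - px, qy = ay + t * dy - py;
      const double d = std::sqrt(qx * qx + qy * qy);
      if (d < best) best = d;
    }
    out[p] = best;
  }
  return out;
}
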