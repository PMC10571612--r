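// Voxel-grid primitives for the 3D image metrics: connected-component
// labeling (26-connectivity in 3D, 8 in 2D), binary ball dilation/erosion,
// separable Gaussian smoothing and box min/max filters (grayscale opening
// with a cube structuring element, used for background subtraction).
//
// Arrays arrive as flat vectors with a dim attribute of length 2 or 3,
// column-major (R layout): index = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

struct Dims {
  int nx, ny, nz;
  bool is3d;
};

static Dims getDims(const IntegerVector& dim) {
  Dims d;
  if (dim.size() == 3) {
    d.nx = dim[0]; d.ny = dim[1]; d.nz = dim[2]; d.is3d = true;
  } else if (dim.size() == 2) {
    d.nx = dim[0]; d.ny = dim[1]; d.nz = 1; d.is3d = false;
  } else {
    stop("expected a 2D or 3D array");
  }
  return d;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim) {
  Dims d = getDims(dim);
  size_t n = static_cast<size_t>(d.nx) * d.ny * d.nz;
  if (static_cast<size_t>(mask.size()) != n) stop("mask/dim mismatch");
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front();
      q.pop();
      int x = cur % d.nx;
      int y = (cur / d.nx) % d.ny;
      int z = cur / (static_cast<size_t>(d.nx) * d.ny);
      for (int dz = -1; dz <= 1; ++dz) {
        if (!d.is3d && dz != 0) continue;
        int zz = z + dz;
        if (zz < 0 || zz >= d.nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= d.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= d.nx) continue;
            size_t idx = xx + static_cast<size_t>(d.nx) * (yy + static_cast<size_t>(d.ny) * zz);
            if (mask[idx] && !labels[idx]) {
              labels[idx] = next;
              q.push(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

static std::vector<std::array<int, 3> > ballOffsets(int radius, bool is3d) {
  std::vector<std::array<int, 3> > off;
  int r2 = radius * radius;
  for (int dz = (is3d ? -radius : 0); dz <= (is3d ? radius : 0); ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r2) off.push_back({dx, dy, dz});
  return off;
}

// [[Rcpp::export]]
IntegerVector dilate_ball_cpp(IntegerVector mask, IntegerVector dim,
                              int radius) {
  Dims d = getDims(dim);
  auto off = ballOffsets(radius, d.is3d);
  IntegerVector out(mask.size(), 0);
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        size_t idx = x + static_cast<size_t>(d.nx) * (y + static_cast<size_t>(d.ny) * z);
        if (!mask[idx]) continue;
        for (auto& o : off) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= d.nx || yy < 0 || yy >= d.ny || zz < 0 ||
              zz >= d.nz)
            continue;
          out[xx + static_cast<size_t>(d.nx) * (yy + static_cast<size_t>(d.ny) * zz)] = 1;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
IntegerVector erode_ball_cpp(IntegerVector mask, IntegerVector dim,
                             int radius) {
  Dims d = getDims(dim);
  auto off = ballOffsets(radius, d.is3d);
  IntegerVector out(mask.size(), 0);
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        size_t idx = x + static_cast<size_t>(d.nx) * (y + static_cast<size_t>(d.ny) * z);
        if (!mask[idx]) continue;
        bool keep = true;
        for (auto& o : off) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= d.nx || yy < 0 || yy >= d.ny || zz < 0 ||
              zz >= d.nz) {
            keep = false;  // outside the grid counts as background
            break;
          }
          if (!mask[xx + static_cast<size_t>(d.nx) * (yy + static_cast<size_t>(d.ny) * zz)]) {
            keep = false;
            break;
          }
        }
        if (keep) out[idx] = 1;
      }
  out.attr("dim") = dim;
  return out;
}

// separable 1D pass along a given axis with a generic reducer
template <typename F>
static void axisPass(std::vector<double>& v, const Dims& d, int axis,
                     int radius, F reduce, double init) {
  int n[3] = {d.nx, d.ny, d.nz};
  size_t stride[3] = {1, static_cast<size_t>(d.nx),
                      static_cast<size_t>(d.nx) * d.ny};
  int len = n[axis];
  std::vector<double> line(len), outline(len);
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  for (int a = 0; a < n[o1]; ++a)
    for (int b = 0; b < n[o2]; ++b) {
      size_t base = a * stride[o1] + b * stride[o2];
      for (int i = 0; i < len; ++i) line[i] = v[base + i * stride[axis]];
      for (int i = 0; i < len; ++i) {
        double acc = init;
        int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
        for (int j = lo; j <= hi; ++j) acc = reduce(acc, line[j]);
        outline[i] = acc;
      }
      for (int i = 0; i < len; ++i) v[base + i * stride[axis]] = outline[i];
    }
}

// [[Rcpp::export]]
NumericVector box_min_cpp(NumericVector img, IntegerVector dim, int radius) {
  Dims d = getDims(dim);
  std::vector<double> v(img.begin(), img.end());
  auto mn = [](double a, double b) { return std::min(a, b); };
  axisPass(v, d, 0, radius, mn, R_PosInf);
  axisPass(v, d, 1, radius, mn, R_PosInf);
  if (d.is3d) axisPass(v, d, 2, radius, mn, R_PosInf);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector box_max_cpp(NumericVector img, IntegerVector dim, int radius) {
  Dims d = getDims(dim);
  std::vector<double> v(img.begin(), img.end());
  auto mx = [](double a, double b) { return std::max(a, b); };
  axisPass(v, d, 0, radius, mx, R_NegInf);
  axisPass(v, d, 1, radius, mx, R_NegInf);
  if (d.is3d) axisPass(v, d, 2, radius, mx, R_NegInf);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector img, IntegerVector dim,
                                double sigma) {
  Dims d = getDims(dim);
  std::vector<double> v(img.begin(), img.end());
  if (sigma <= 0) {
    NumericVector out(v.begin(), v.end());
    out.attr("dim") = dim;
    return out;
  }
  int radius = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + radius];
  }
  for (auto& k : kern) k /= s;

  int n[3] = {d.nx, d.ny, d.nz};
  size_t stride[3] = {1, static_cast<size_t>(d.nx),
                      static_cast<size_t>(d.nx) * d.ny};
  int nAxes = d.is3d ? 3 : 2;
  for (int axis = 0; axis < nAxes; ++axis) {
    int len = n[axis];
    int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
    std::vector<double> line(len);
    for (int a = 0; a < n[o1]; ++a)
      for (int b = 0; b < n[o2]; ++b) {
        size_t base = a * stride[o1] + b * stride[o2];
        for (int i = 0; i < len; ++i) line[i] = v[base + i * stride[axis]];
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int k = -radius; k <= radius; ++k) {
            int j = i + k;
            if (j < 0) j = -j - 1;          // reflect
            if (j >= len) j = 2 * len - j - 1;
            j = std::max(0, std::min(len - 1, j));
            acc += kern[k + radius] * line[j];
          }
          v[base + i * stride[axis]] = acc;
        }
      }
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}
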