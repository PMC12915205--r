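#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Neighbour offsets for a given dimensionality/connectivity.
// 2D: connectivity 4 (edge) or 8 (edge+vertex).
// 3D: connectivity 6 (face) or 26 (face+edge+vertex).
static std::vector<std::vector<int> > neighbour_offsets(int ndim, int connectivity) {
  std::vector<std::vector<int> > offs;
  if (ndim == 2) {
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int manhattan = std::abs(di) + std::abs(dj);
        if (connectivity == 4 && manhattan > 1) continue;
        std::vector<int> o(2); o[0] = di; o[1] = dj;
        offs.push_back(o);
      }
  } else {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int manhattan = std::abs(di) + std::abs(dj) + std::abs(dk);
          if (connectivity == 6 && manhattan > 1) continue;
          std::vector<int> o(3); o[0] = di; o[1] = dj; o[2] = dk;
          offs.push_back(o);
        }
  }
  return offs;
}

// Connected-component labelling by breadth-first search over a 1-voxel
// zero-padded copy (no per-voxel bounds checks; neighbour steps become
// constant linear offsets). Labels are assigned in ascending linear-index
// (array storage) order of each component's first-encountered element, so
// the result is fully deterministic.
// [[Rcpp::export(.cc_label)]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int ndim = dims.size();
  if (ndim != 2 && ndim != 3) stop("mask must be 2D or 3D");
  R_xlen_t n = mask.size();
  std::vector<R_xlen_t> pdims(ndim), pstride(ndim), stride(ndim);
  R_xlen_t pn = 1;
  for (int d = 0; d < ndim; ++d) { pdims[d] = dims[d] + 2; pn *= pdims[d]; }
  pstride[0] = 1; stride[0] = 1;
  for (int d = 1; d < ndim; ++d) {
    pstride[d] = pstride[d - 1] * pdims[d - 1];
    stride[d] = stride[d - 1] * dims[d - 1];
  }
  // copy mask into the padded volume (labels: -1 = foreground unlabelled)
  std::vector<int> plab(pn, 0);
  {
    std::vector<int> coord(ndim, 0);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (mask[i]) {
        R_xlen_t pidx = 0;
        for (int d = 0; d < ndim; ++d) pidx += pstride[d] * (coord[d] + 1);
        plab[pidx] = -1;
      }
      // increment mixed-radix coordinate
      for (int d = 0; d < ndim; ++d) {
        if (++coord[d] < dims[d]) break;
        coord[d] = 0;
      }
    }
  }
  std::vector<std::vector<int> > offs = neighbour_offsets(ndim, connectivity);
  std::vector<R_xlen_t> loff(offs.size());
  for (size_t o = 0; o < offs.size(); ++o) {
    R_xlen_t s = 0;
    for (int d = 0; d < ndim; ++d) s += pstride[d] * offs[o][d];
    loff[o] = s;
  }
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t start = 0; start < pn; ++start) {
    if (plab[start] != -1) continue;
    plab[start] = ++next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      for (size_t o = 0; o < loff.size(); ++o) {
        R_xlen_t nidx = idx + loff[o];
        if (plab[nidx] == -1) { plab[nidx] = next_label; stack.push_back(nidx); }
      }
    }
  }
  // copy back to unpadded layout
  IntegerVector labels(n);
  {
    std::vector<int> coord(ndim, 0);
    for (R_xlen_t i = 0; i < n; ++i) {
      R_xlen_t pidx = 0;
      for (int d = 0; d < ndim; ++d) pidx += pstride[d] * (coord[d] + 1);
      labels[i] = plab[pidx];
      for (int d = 0; d < ndim; ++d) {
        if (++coord[d] < dims[d]) break;
        coord[d] = 0;
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Separable convolution along each axis with symmetric (reflected) boundary.
// `kernels` holds one numeric kernel per axis (odd length); length-1 kernels
// are skipped. Axis 0 is the fastest-varying (first) array dimension.
// [[Rcpp::export(.sep_convolve)]]
NumericVector sep_convolve(NumericVector arr, IntegerVector dims, List kernels) {
  int ndim = dims.size();
  if ((int)kernels.size() != ndim) stop("one kernel per axis required");
  R_xlen_t n = arr.size();
  NumericVector cur = clone(arr);
  std::vector<R_xlen_t> stride(ndim);
  stride[0] = 1;
  for (int d = 1; d < ndim; ++d) stride[d] = stride[d - 1] * dims[d - 1];

  for (int ax = 0; ax < ndim; ++ax) {
    NumericVector k = kernels[ax];
    int klen = k.size();
    if (klen <= 1) continue;
    if (klen % 2 == 0) stop("kernels must have odd length");
    int half = klen / 2;
    int len = dims[ax];
    R_xlen_t s = stride[ax];
    NumericVector out(n);
    R_xlen_t nlines = n / len;
    std::vector<double> line(len);
    for (R_xlen_t l = 0; l < nlines; ++l) {
      // base index of this line: decompose l over the remaining axes
      R_xlen_t rem = l, base = 0;
      for (int d = 0; d < ndim; ++d) {
        if (d == ax) continue;
        R_xlen_t c = rem % dims[d]; rem /= dims[d];
        base += stride[d] * c;
      }
      for (int i = 0; i < len; ++i) line[i] = cur[base + s * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -half; t <= half; ++t) {
          int j = i + t;
          if (j < 0) j = -j - 1;            // symmetric reflection
          else if (j >= len) j = 2 * len - 1 - j;
          acc += line[j] * k[t + half];
        }
        out[base + s * i] = acc;
      }
    }
    cur = out;
  }
  return cur;
}

// Local maxima over the full (8- or 26-) neighbourhood; border elements use
// the available neighbours. Plateaus are reported at every member; the caller
// deduplicates via minimum-separation suppression.
// [[Rcpp::export(.local_maxima)]]
LogicalVector local_maxima(NumericVector arr, IntegerVector dims) {
  int ndim = dims.size();
  R_xlen_t n = arr.size();
  LogicalVector out(n);
  std::vector<std::vector<int> > offs = neighbour_offsets(ndim, ndim == 2 ? 8 : 26);
  std::vector<R_xlen_t> stride(ndim);
  stride[0] = 1;
  for (int d = 1; d < ndim; ++d) stride[d] = stride[d - 1] * dims[d - 1];
  std::vector<int> coord(ndim);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    R_xlen_t rem = idx;
    for (int d = 0; d < ndim; ++d) { coord[d] = rem % dims[d]; rem /= dims[d]; }
    double v = arr[idx];
    bool is_max = true;
    for (size_t o = 0; o < offs.size() && is_max; ++o) {
      bool ok = true;
      R_xlen_t nidx = 0;
      for (int d = 0; d < ndim; ++d) {
        int c = coord[d] + offs[o][d];
        if (c < 0 || c >= dims[d]) { ok = false; break; }
        nidx += stride[d] * c;
      }
      if (ok && arr[nidx] > v) is_max = false;
    }
    out[idx] = is_max;
  }
  return out;
}

// One-dimensional lower envelope of parabolas (Felzenszwalb & Huttenlocher),
// generalised to physical sample spacing w along the axis.
static void dt_1d(std::vector<double> &f, std::vector<double> &d, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;   // no parabola at unreachable samples
    double xq = q * w;
    while (true) {
      double xv = v[k] * w;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF; break;
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[kk + 1] < xq) ++kk;
    double xv = v[kk] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

// Exact Euclidean distance transform on an anisotropic grid: distance (in the
// units of `spacing`) from every element to the nearest TRUE element.
// [[Rcpp::export(.edt)]]
NumericVector edt(LogicalVector feature, IntegerVector dims, NumericVector spacing) {
  int ndim = dims.size();
  if ((int)spacing.size() != ndim) stop("one spacing per axis required");
  R_xlen_t n = feature.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector dist2(n);
  for (R_xlen_t i = 0; i < n; ++i) dist2[i] = feature[i] ? 0.0 : INF;
  std::vector<R_xlen_t> stride(ndim);
  stride[0] = 1;
  for (int d = 1; d < ndim; ++d) stride[d] = stride[d - 1] * dims[d - 1];

  for (int ax = 0; ax < ndim; ++ax) {
    int len = dims[ax];
    R_xlen_t s = stride[ax];
    R_xlen_t nlines = n / len;
    std::vector<double> f(len), d(len);
    for (R_xlen_t l = 0; l < nlines; ++l) {
      R_xlen_t rem = l, base = 0;
      for (int dd = 0; dd < ndim; ++dd) {
        if (dd == ax) continue;
        R_xlen_t c = rem % dims[dd]; rem /= dims[dd];
        base += stride[dd] * c;
      }
      bool any_finite = false;
      for (int i = 0; i < len; ++i) { f[i] = dist2[base + s * i]; if (f[i] < INF) any_finite = true; }
      if (!any_finite) continue;
      // shift origin to the first finite parabola to keep dt_1d simple
      dt_1d(f, d, len, spacing[ax]);
      for (int i = 0; i < len; ++i) dist2[base + s * i] = d[i];
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) dist2[i] = std::sqrt(dist2[i]);
  return dist2;
}
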