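#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample) reflection of index i into [0, n).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// Convolve a 3D array (column-major, dims d0 fastest) with a 1D kernel
// along one axis, reflect boundary.  Kernel taps are applied centred.
static void conv_axis3(const std::vector<double>& in, std::vector<double>& out,
                       const int d0, const int d1, const int d2,
                       const int axis, const NumericVector& k) {
  const int nk = k.size();
  const int r = (nk - 1) / 2;
  const int n[3] = {d0, d1, d2};
  const long s[3] = {1, (long)d0, (long)d0 * d1};
  const int na = n[axis];
  const long sa = s[axis];
  // iterate over the two non-convolved axes
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  // each line is copied into a reflect-padded buffer so the inner loop
  // is contiguous and boundary-free
  std::vector<double> buf(na + 2 * r);
  std::vector<int> pad(na + 2 * r);
  for (int e = 0; e < na + 2 * r; ++e) pad[e] = reflect_idx(e - r, na);
  for (int i2 = 0; i2 < n[b2]; ++i2) {
    for (int i1 = 0; i1 < n[b1]; ++i1) {
      const long base = (long)i1 * s[b1] + (long)i2 * s[b2];
      for (int e = 0; e < na + 2 * r; ++e)
        buf[e] = in[base + (long)pad[e] * sa];
      for (int ia = 0; ia < na; ++ia) {
        double acc = 0.0;
        const double* p = &buf[ia];
        for (int j = 0; j < nk; ++j) acc += k[j] * p[j];
        out[base + (long)ia * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".cf_conv_sep3")]]
NumericVector cf_conv_sep3(NumericVector vol, IntegerVector dims,
                           List kernels) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long n = (long)d0 * d1 * d2;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    if (Rf_isNull(kernels[axis])) continue;
    NumericVector k(kernels[axis]);
    if (k.size() == 0) continue;
    conv_axis3(a, b, d0, d1, d2, axis, k);
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cf_conv_sep2")]]
NumericMatrix cf_conv_sep2(NumericMatrix img, NumericVector k0,
                           NumericVector k1) {
  const int d0 = img.nrow(), d1 = img.ncol();
  const long n = (long)d0 * d1;
  std::vector<double> a(img.begin(), img.end()), b(n);
  if (k0.size() > 0) { conv_axis3(a, b, d0, d1, 1, 0, k0); std::swap(a, b); }
  if (k1.size() > 0) { conv_axis3(a, b, d0, d1, 1, 1, k1); std::swap(a, b); }
  NumericMatrix out(d0, d1);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// Local maxima of a 3D volume within an ellipsoidal neighbourhood of
// radii `radii` (in index units along dims 0,1,2).  A voxel is a
// candidate when its value exceeds `threshold` and no voxel within the
// ellipsoid is greater.  Plateaus (26-connected components of equal
// value whose members are all candidates) yield one detection at the
// rounded plateau centroid (ties toward the lower index).  Returns a
// matrix with 0-based columns i0, i1, i2 and the plateau value.
// [[Rcpp::export(name = ".cf_local_maxima3")]]
NumericMatrix cf_local_maxima3(NumericVector vol, IntegerVector dims,
                               NumericVector radii, double threshold) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long n = (long)d0 * d1 * d2;
  const double r0 = radii[0], r1 = radii[1], r2 = radii[2];
  const int m0 = (int)std::floor(r0), m1 = (int)std::floor(r1),
            m2 = (int)std::floor(r2);

  // ellipsoid offsets (excluding origin)
  std::vector<int> off0, off1, off2;
  for (int a = -m0; a <= m0; ++a)
    for (int b = -m1; b <= m1; ++b)
      for (int c = -m2; c <= m2; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        const double q = (double)a * a / (r0 * r0) +
                         (double)b * b / (r1 * r1) +
                         (double)c * c / (r2 * r2);
        if (q <= 1.0) { off0.push_back(a); off1.push_back(b); off2.push_back(c); }
      }
  const int noff = off0.size();

  std::vector<unsigned char> cand(n, 0);
  const double* v = vol.begin();
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1)
      for (int i0 = 0; i0 < d0; ++i0) {
        const long idx = i0 + (long)d0 * (i1 + (long)d1 * i2);
        const double val = v[idx];
        if (!(val > threshold)) continue;
        bool ok = true;
        for (int j = 0; j < noff; ++j) {
          const int a = i0 + off0[j];
          if (a < 0 || a >= d0) continue;
          const int b = i1 + off1[j];
          if (b < 0 || b >= d1) continue;
          const int c = i2 + off2[j];
          if (c < 0 || c >= d2) continue;
          if (v[a + (long)d0 * (b + (long)d1 * c)] > val) { ok = false; break; }
        }
        if (ok) cand[idx] = 1;
      }

  // group equal-valued 26-connected plateaus among candidates
  std::vector<unsigned char> seen(n, 0);
  std::vector<double> o0, o1, o2, oval;
  std::vector<long> stack;
  for (long start = 0; start < n; ++start) {
    if (!cand[start] || seen[start]) continue;
    const double val = v[start];
    bool valid = true;
    double s0 = 0, s1 = 0, s2 = 0;
    long cnt = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      const long idx = stack.back();
      stack.pop_back();
      const int i0 = idx % d0;
      const int i1 = (idx / d0) % d1;
      const int i2 = idx / ((long)d0 * d1);
      s0 += i0; s1 += i1; s2 += i2; ++cnt;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            const int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
            if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 ||
                j2 < 0 || j2 >= d2) continue;
            const long jdx = j0 + (long)d0 * (j1 + (long)d1 * j2);
            if (v[jdx] != val) continue;
            if (!cand[jdx]) { valid = false; continue; }
            if (!seen[jdx]) { seen[jdx] = 1; stack.push_back(jdx); }
          }
    }
    if (valid) {
      // round half toward the lower index
      o0.push_back(std::ceil(s0 / cnt - 0.5));
      o1.push_back(std::ceil(s1 / cnt - 0.5));
      o2.push_back(std::ceil(s2 / cnt - 0.5));
      oval.push_back(val);
    }
  }

  NumericMatrix out(o0.size(), 4);
  for (size_t i = 0; i < o0.size(); ++i) {
    out(i, 0) = o0[i]; out(i, 1) = o1[i]; out(i, 2) = o2[i]; out(i, 3) = oval[i];
  }
  return out;
}

// Separable box minimum/maximum filter over a (2r+1)^3 window, used for
// binary morphological erosion/dilation in the active-contour step.
// [[Rcpp::export(name = ".cf_box_extremum3")]]
NumericVector cf_box_extremum3(NumericVector vol, IntegerVector dims,
                               IntegerVector radii, bool take_max) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const long n = (long)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const long s[3] = {1, (long)d[0], (long)d[0] * d[1]};
  for (int axis = 0; axis < 3; ++axis) {
    const int r = radii[axis];
    if (r <= 0) continue;
    const int na = d[axis];
    const long sa = s[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    for (int i2 = 0; i2 < d[b2]; ++i2)
      for (int i1 = 0; i1 < d[b1]; ++i1) {
        const long base = (long)i1 * s[b1] + (long)i2 * s[b2];
        for (int ia = 0; ia < na; ++ia) {
          const int lo = std::max(0, ia - r), hi = std::min(na - 1, ia + r);
          double ext = a[base + (long)lo * sa];
          for (int j = lo + 1; j <= hi; ++j) {
            const double x = a[base + (long)j * sa];
            if (take_max ? (x > ext) : (x < ext)) ext = x;
          }
          b[base + (long)ia * sa] = ext;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Marker-based watershed on a 3D elevation map (priority flood,
// 6-connectivity).  Flooding starts from labelled marker voxels and is
// confined to `mask`.  Returns the label volume.
// [[Rcpp::export(name = ".cf_marker_watershed3")]]
IntegerVector cf_marker_watershed3(NumericVector elev, IntegerVector dims,
                                   IntegerVector markers, LogicalVector mask) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long n = (long)d0 * d1 * d2;
  IntegerVector labels(n);
  typedef std::pair<double, std::pair<long, long> > QE; // (elev, (order, idx))
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  long order = 0;
  for (long i = 0; i < n; ++i) {
    labels[i] = markers[i];
    if (markers[i] > 0)
      pq.push(QE(elev[i], std::make_pair(order++, i)));
  }
  const int doff[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (!pq.empty()) {
    const long idx = pq.top().second.second;
    pq.pop();
    const int i0 = idx % d0;
    const int i1 = (idx / d0) % d1;
    const int i2 = idx / ((long)d0 * d1);
    const int lab = labels[idx];
    for (int k = 0; k < 6; ++k) {
      const int j0 = i0 + doff[k][0], j1 = i1 + doff[k][1], j2 = i2 + doff[k][2];
      if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2)
        continue;
      const long jdx = j0 + (long)d0 * (j1 + (long)d1 * j2);
      if (!mask[jdx] || labels[jdx] != 0) continue;
      labels[jdx] = lab;
      pq.push(QE(elev[jdx], std::make_pair(order++, jdx)));
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
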