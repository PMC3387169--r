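#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact voxel traversal of a polyline on a regular grid.
//
// Coordinate contract: mm space with the grid origin at the corner of voxel
// (0,0,0); voxel k on axis a spans the half-open interval
// [k * s_a, (k+1) * s_a). A point exactly on a boundary therefore belongs to
// the higher-index voxel, which is what floor(p/s) gives.
//
// For every segment the arc values of all axis-plane crossings are computed
// in closed form; each inter-crossing interval is attributed to the voxel
// containing its midpoint. Entry arcs are exact crossing arcs, so downstream
// length-weighted statistics carry no sampling error. Consecutive duplicate
// voxels are collapsed (keeping the first entry arc); voxels outside the
// grid are dropped while the arc length keeps accumulating.

static inline int ivox(double x, double s) {
  return (int)std::floor(x / s);
}

// [[Rcpp::export(name = ".walk_polyline_cpp")]]
NumericMatrix walk_polyline_cpp(NumericMatrix pts, NumericVector voxel_size,
                                IntegerVector dims) {
  const int np = pts.nrow();
  if (np < 2) stop("polyline must have at least 2 points");
  const double sx = voxel_size[0], sy = voxel_size[1], sz = voxel_size[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];

  std::vector<double> out;  // rows of (i, j, k, arc_entry)
  out.reserve(256);
  double arc0 = 0.0;              // cumulative arc at start of current segment
  int last_i = INT_MIN, last_j = INT_MIN, last_k = INT_MIN;
  bool have_last = false;

  // emit the voxel of the very first point (arc 0) via a zero-length lead-in:
  // handled naturally below by attributing interval starts, so seed the first
  // interval with the starting point itself.
  for (int seg = 0; seg < np - 1; ++seg) {
    const double px = pts(seg, 0), py = pts(seg, 1), pz = pts(seg, 2);
    const double qx = pts(seg + 1, 0), qy = pts(seg + 1, 1), qz = pts(seg + 1, 2);
    const double dx = qx - px, dy = qy - py, dz = qz - pz;
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0.0) continue;

    // collect crossing arcs within (0, L]
    std::vector<double> t;
    t.push_back(0.0);
    t.push_back(L);
    const double d[3] = {dx, dy, dz};
    const double p[3] = {px, py, pz};
    const double s[3] = {sx, sy, sz};
    for (int a = 0; a < 3; ++a) {
      if (d[a] == 0.0) continue;
      const double lo = std::min(p[a], p[a] + d[a]);
      const double hi = std::max(p[a], p[a] + d[a]);
      // boundaries m*s in (lo, hi)
      int m0 = (int)std::ceil(lo / s[a]);
      int m1 = (int)std::floor(hi / s[a]);
      for (int m = m0; m <= m1; ++m) {
        const double b = m * s[a];
        if (b <= lo || b >= hi) continue;
        const double tt = L * (b - p[a]) / d[a];
        if (tt > 0.0 && tt < L) t.push_back(tt);
      }
    }
    std::sort(t.begin(), t.end());

    for (size_t w = 0; w + 1 < t.size(); ++w) {
      const double t0 = t[w], t1 = t[w + 1];
      if (t1 - t0 < 1e-12) continue;  // degenerate sliver at a corner crossing
      const double tm = 0.5 * (t0 + t1);
      const double mx = px + dx * tm / L;
      const double my = py + dy * tm / L;
      const double mz = pz + dz * tm / L;
      const int vi = ivox(mx, sx), vj = ivox(my, sy), vk = ivox(mz, sz);
      const bool inside = vi >= 0 && vi < nx && vj >= 0 && vj < ny &&
                          vk >= 0 && vk < nz;
      if (!inside) { have_last = false; continue; }
      if (have_last && vi == last_i && vj == last_j && vk == last_k) continue;
      out.push_back((double)vi);
      out.push_back((double)vj);
      out.push_back((double)vk);
      out.push_back(arc0 + t0);
      last_i = vi; last_j = vj; last_k = vk; have_last = true;
    }
    arc0 += L;
  }

  const int nrow = (int)(out.size() / 4);
  NumericMatrix res(nrow, 4);
  for (int r = 0; r < nrow; ++r) {
    res(r, 0) = out[4 * r];
    res(r, 1) = out[4 * r + 1];
    res(r, 2) = out[4 * r + 2];
    res(r, 3) = out[4 * r + 3];
  }
  colnames(res) = CharacterVector::create("i", "j", "k", "arc");
  return res;
}

// [[Rcpp::export(name = ".walk_polylines_cpp")]]
List walk_polylines_cpp(List lines, NumericVector voxel_size,
                        IntegerVector dims) {
  const int n = lines.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = lines[i];
    out[i] = walk_polyline_cpp(m, voxel_size, dims);
  }
  return out;
}

// Per-streamline label summary used by the structural connectivity measure:
// for each line, the first-entry arc into every label (0 = background is
// skipped, labels deduplicated at first visit), plus the arc at the last
// sample carrying one of the seed labels before that first entry (for
// boundary-origin length measurement).
//
// labels: 3D integer array (R column-major), flattened.
// Returns a list of matrices with columns (label, arc_first_entry).

// [[Rcpp::export(name = ".label_walk_cpp")]]
List label_walk_cpp(List lines, NumericVector voxel_size, IntegerVector dims,
                    IntegerVector labels) {
  const int n = lines.size();
  const int nx = dims[0], ny = dims[1];
  List out(n);
  for (int li = 0; li < n; ++li) {
    NumericMatrix vox = walk_polyline_cpp(lines[li], voxel_size, dims);
    const int nv = vox.nrow();
    std::vector<int> seen;
    std::vector<double> arcs;
    for (int r = 0; r < nv; ++r) {
      const int idx = (int)vox(r, 0) + nx * ((int)vox(r, 1) + ny * (int)vox(r, 2));
      const int lab = labels[idx];
      if (lab == 0) continue;
      bool dup = false;
      for (size_t q = 0; q < seen.size(); ++q)
        if (seen[q] == lab) { dup = true; break; }
      if (dup) continue;
      seen.push_back(lab);
      arcs.push_back(vox(r, 3));
    }
    NumericMatrix m((int)seen.size(), 2);
    for (size_t r = 0; r < seen.size(); ++r) {
      m((int)r, 0) = seen[r];
      m((int)r, 1) = arcs[r];
    }
    colnames(m) = CharacterVector::create("label", "arc");
    out[li] = m;
  }
  return out;
}

// 3D connected-component labelling of a logical mask under a 6-, 18- or
// 26-neighbourhood. Returns an integer array of component ids (0 outside).

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  IntegerVector lab(N, 0);

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }
  const int noff = (int)offs.size() / 3;

  int comp = 0;
  std::queue<int> q;
  for (int start = 0; start < N; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++comp;
    lab[start] = comp;
    q.push(start);
    while (!q.empty()) {
      const int cur = q.front();
      q.pop();
      const int cz = cur / (nx * ny);
      const int cy = (cur - cz * nx * ny) / nx;
      const int cx = cur - cz * nx * ny - cy * nx;
      for (int o = 0; o < noff; ++o) {
        const int x = cx + offs[3 * o], y = cy + offs[3 * o + 1],
                  z = cz + offs[3 * o + 2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const int id = x + nx * (y + ny * z);
        if (mask[id] && lab[id] == 0) {
          lab[id] = comp;
          q.push(id);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
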