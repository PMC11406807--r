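#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Volumes are passed as flat vectors in R's column-major layout with
// dimensions d = (d1, d2, d3); voxel (i, j, k), 0-based, lives at
// i + d1 * (j + d2 * k).

static inline R_xlen_t lin(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * (R_xlen_t)k);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dim, int w) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int h = w / 2;
  NumericVector out(vol.size());
  std::vector<double> buf((size_t)w * w * w);
  for (int k = 0; k < d[2]; ++k) {
    for (int j = 0; j < d[1]; ++j) {
      for (int i = 0; i < d[0]; ++i) {
        size_t n = 0;
        for (int dk = -h; dk <= h; ++dk) {
          int kk = clampi(k + dk, 0, d[2] - 1);
          for (int dj = -h; dj <= h; ++dj) {
            int jj = clampi(j + dj, 0, d[1] - 1);
            for (int di = -h; di <= h; ++di) {
              int ii = clampi(i + di, 0, d[0] - 1);
              buf[n++] = vol[lin(ii, jj, kk, d)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
        out[lin(i, j, k, d)] = buf[n / 2];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_local_range3(NumericVector vol, IntegerVector dim, int w) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int h = w / 2;
  NumericVector out(vol.size());
  for (int k = 0; k < d[2]; ++k) {
    for (int j = 0; j < d[1]; ++j) {
      for (int i = 0; i < d[0]; ++i) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int dk = -h; dk <= h; ++dk) {
          int kk = clampi(k + dk, 0, d[2] - 1);
          for (int dj = -h; dj <= h; ++dj) {
            int jj = clampi(j + dj, 0, d[1] - 1);
            for (int di = -h; di <= h; ++di) {
              int ii = clampi(i + di, 0, d[0] - 1);
              double v = vol[lin(ii, jj, kk, d)];
              if (v < mn) mn = v;
              if (v > mx) mx = v;
            }
          }
        }
        out[lin(i, j, k, d)] = mx - mn;
      }
    }
  }
  return out;
}

// Dilation by an arbitrary structuring element given as integer offsets
// (n x 3). Out-of-bounds contributions are dropped.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  LogicalVector out(mask.size(), FALSE);
  const int no = offsets.nrow();
  for (int k = 0; k < d[2]; ++k) {
    for (int j = 0; j < d[1]; ++j) {
      for (int i = 0; i < d[0]; ++i) {
        if (!mask[lin(i, j, k, d)]) continue;
        for (int o = 0; o < no; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
          out[lin(ii, jj, kk, d)] = TRUE;
        }
      }
    }
  }
  return out;
}

// Erosion: voxel survives iff every offset lands on foreground. Outside the
// grid counts as background, so objects shrink at the image border.
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  LogicalVector out(mask.size(), FALSE);
  const int no = offsets.nrow();
  for (int k = 0; k < d[2]; ++k) {
    for (int j = 0; j < d[1]; ++j) {
      for (int i = 0; i < d[0]; ++i) {
        if (!mask[lin(i, j, k, d)]) continue;
        bool keep = true;
        for (int o = 0; o < no && keep; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2] ||
              !mask[lin(ii, jj, kk, d)]) keep = false;
        }
        if (keep) out[lin(i, j, k, d)] = TRUE;
      }
    }
  }
  return out;
}

// Connected-component labelling (BFS), connectivity 6 or 26.
// Returns 0 for background, components labelled 1..n in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        nb.push_back({di, dj, dk});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        R_xlen_t p = lin(i, j, k, d);
        if (!mask[p] || lab[p] != 0) continue;
        lab[p] = ++next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back();
          stack.pop_back();
          int qk = (int)(q / ((R_xlen_t)d[0] * d[1]));
          R_xlen_t r = q % ((R_xlen_t)d[0] * d[1]);
          int qj = (int)(r / d[0]), qi = (int)(r % d[0]);
          for (size_t o = 0; o < nb.size(); ++o) {
            int ii = qi + nb[o][0], jj = qj + nb[o][1], kk = qk + nb[o][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
            R_xlen_t s = lin(ii, jj, kk, d);
            if (mask[s] && lab[s] == 0) {
              lab[s] = next;
              stack.push_back(s);
            }
          }
        }
      }
  return lab;
}

// Morphological two-phase (Chan-Vese style) active contour on a binary
// level set u. Each sweep: recompute the inside/outside means, reassign
// voxels on the 6-connected interface by region competition, then apply
// `smoothing` passes of a 3x3x3 binary majority filter (a discrete
// curvature-flow surrogate).
// [[Rcpp::export]]
LogicalVector cpp_chan_vese(NumericVector img, LogicalVector init, IntegerVector dim,
                            int iterations, int smoothing) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = img.size();
  std::vector<char> u(n), v(n);
  for (R_xlen_t p = 0; p < n; ++p) u[p] = init[p] ? 1 : 0;

  const int n6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

  for (int it = 0; it < iterations; ++it) {
    double s_in = 0, s_out = 0;
    R_xlen_t n_in = 0, n_out = 0;
    for (R_xlen_t p = 0; p < n; ++p) {
      if (u[p]) { s_in += img[p]; ++n_in; } else { s_out += img[p]; ++n_out; }
    }
    if (n_in == 0 || n_out == 0) break;
    double c_in = s_in / n_in, c_out = s_out / n_out;

    // region competition on the interface
    std::copy(u.begin(), u.end(), v.begin());
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          R_xlen_t p = lin(i, j, k, d);
          bool boundary = false;
          for (int o = 0; o < 6 && !boundary; ++o) {
            int ii = i + n6[o][0], jj = j + n6[o][1], kk = k + n6[o][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
            if (u[lin(ii, jj, kk, d)] != u[p]) boundary = true;
          }
          if (!boundary) continue;
          double din = img[p] - c_in, dout = img[p] - c_out;
          v[p] = (din * din <= dout * dout) ? 1 : 0;
        }
    std::swap(u, v);

    // curvature smoothing: binary majority over centre + 6 neighbours
    // (a small kernel, so thin wraps and notches survive refinement)
    for (int s = 0; s < smoothing; ++s) {
      std::copy(u.begin(), u.end(), v.begin());
      for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
          for (int i = 0; i < d[0]; ++i) {
            R_xlen_t p = lin(i, j, k, d);
            int cnt = u[p], tot = 1;
            for (int o = 0; o < 6; ++o) {
              int ii = i + n6[o][0], jj = j + n6[o][1], kk = k + n6[o][2];
              if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
              ++tot;
              cnt += u[lin(ii, jj, kk, d)];
            }
            v[p] = (2 * cnt > tot) ? 1 : 0;
          }
      std::swap(u, v);
    }
  }

  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = u[p] != 0;
  return out;
}

static double directed_hausdorff(const NumericMatrix& a, const NumericMatrix& b, double cmax2) {
  const int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    double mind2 = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind2) {
        mind2 = d2;
        if (mind2 <= cmax2) break;  // cannot raise the running max
      }
    }
    if (mind2 > cmax2 && mind2 < R_PosInf) cmax2 = mind2;
  }
  return cmax2;
}

// Symmetric Hausdorff distance between two point sets (rows = points).
// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix a, NumericMatrix b) {
  double m2 = 0.0;
  m2 = directed_hausdorff(a, b, m2);
  m2 = directed_hausdorff(b, a, m2);
  return std::sqrt(m2);
}

// For each row of src, index (1-based) of the nearest row of tgt.
// [[Rcpp::export]]
IntegerVector cpp_nearest_idx(NumericMatrix src, NumericMatrix tgt) {
  const int ns = src.nrow(), nt = tgt.nrow();
  IntegerVector idx(ns);
  for (int i = 0; i < ns; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    for (int j = 0; j < nt; ++j) {
      double dx = sx - tgt(j, 0), dy = sy - tgt(j, 1), dz = sz - tgt(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
  }
  return idx;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra iso-surface at a given level.
//
// Each grid cell is split into six tetrahedra sharing the main diagonal;
// every tetrahedron contributes 0, 1 or 2 triangles with vertices linearly
// interpolated on the crossing edges. Vertices are shared through an edge
// hash, so the mesh of a single solid component is watertight. Triangles are
// oriented so normals point from the >level side outwards.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector vol, IntegerVector dim, double level) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  // cube corners (di, dj, dk)
  const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;  // grid coordinates (i, j, k)
  std::vector<int> f1, f2, f3;

  R_xlen_t gid[8];
  double val[8];
  double ci[8], cj[8], ck[8];

  auto edge_point = [&](int a, int b) -> int {
    R_xlen_t ga = gid[a], gb = gid[b];
    uint64_t key = ga < gb
      ? ((uint64_t)ga << 32) | (uint64_t)gb
      : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - val[a]) / (val[b] - val[a]);
    int id = (int)vx.size();
    vx.push_back(ci[a] + t * (ci[b] - ci[a]));
    vy.push_back(cj[a] + t * (cj[b] - cj[a]));
    vz.push_back(ck[a] + t * (ck[b] - ck[a]));
    edge_vertex.emplace(key, id);
    return id;
  };

  auto add_tri = [&](int p1, int p2, int p3,
                     double ox, double oy, double oz,
                     double ix, double iy, double iz) {
    // orient: normal should point from inside (value > level) to outside
    double ux = vx[p2] - vx[p1], uy = vy[p2] - vy[p1], uz = vz[p2] - vz[p1];
    double wx = vx[p3] - vx[p1], wy = vy[p3] - vy[p1], wz = vz[p3] - vz[p1];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    double rx = ox - ix, ry = oy - iy, rz = oz - iz;
    if (nx * rx + ny * ry + nz * rz < 0) std::swap(p2, p3);
    f1.push_back(p1 + 1); f2.push_back(p2 + 1); f3.push_back(p3 + 1);
  };

  for (int k = 0; k + 1 < d[2]; ++k)
    for (int j = 0; j + 1 < d[1]; ++j)
      for (int i = 0; i + 1 < d[0]; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          gid[c] = lin(ii, jj, kk, d);
          val[c] = vol[gid[c]];
          ci[c] = ii; cj[c] = jj; ck[c] = kk;
        }
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int inside[4], nin = 0, outside[4], nout = 0;
          for (int m = 0; m < 4; ++m) {
            if (val[tv[m]] > level) inside[nin++] = tv[m];
            else outside[nout++] = tv[m];
          }
          if (nin == 0 || nin == 4) continue;
          // centroids of the inside / outside corners for orientation
          double ixc = 0, iyc = 0, izc = 0, oxc = 0, oyc = 0, ozc = 0;
          for (int m = 0; m < nin; ++m) { ixc += ci[inside[m]]; iyc += cj[inside[m]]; izc += ck[inside[m]]; }
          for (int m = 0; m < nout; ++m) { oxc += ci[outside[m]]; oyc += cj[outside[m]]; ozc += ck[outside[m]]; }
          ixc /= nin; iyc /= nin; izc /= nin;
          oxc /= nout; oyc /= nout; ozc /= nout;
          if (nin == 1) {
            int p1 = edge_point(inside[0], outside[0]);
            int p2 = edge_point(inside[0], outside[1]);
            int p3 = edge_point(inside[0], outside[2]);
            add_tri(p1, p2, p3, oxc, oyc, ozc, ixc, iyc, izc);
          } else if (nin == 3) {
            int p1 = edge_point(outside[0], inside[0]);
            int p2 = edge_point(outside[0], inside[1]);
            int p3 = edge_point(outside[0], inside[2]);
            add_tri(p1, p2, p3, oxc, oyc, ozc, ixc, iyc, izc);
          } else {  // nin == 2
            int p1 = edge_point(inside[0], outside[0]);
            int p2 = edge_point(inside[0], outside[1]);
            int p3 = edge_point(inside[1], outside[1]);
            int p4 = edge_point(inside[1], outside[0]);
            add_tri(p1, p2, p3, oxc, oyc, ozc, ixc, iyc, izc);
            add_tri(p1, p3, p4, oxc, oyc, ozc, ixc, iyc, izc);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = vx[v]; verts(v, 1) = vy[v]; verts(v, 2) = vz[v];
  }
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; ++f) {
    faces(f, 0) = f1[f]; faces(f, 1) = f2[f]; faces(f, 2) = f3[f];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
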