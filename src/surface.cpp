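#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// Kuhn/Freudenthal subdivision of the unit cube into 6 tetrahedra sharing
// the main diagonal corner0-corner7. Corner c encodes offset (c&1, (c>>1)&1,
// (c>>2)&1). The identical per-cube pattern tiles space crack-free.
const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc; // 0-based
  std::unordered_map<uint64_t, int> edgeVert;
};

} // namespace

// Isosurface of the binary indicator (voxels == label) at level 0.5 by
// marching tetrahedra. The indicator is padded by 2 background layers.
// Surface topology (which grid edges are crossed) always follows the binary
// indicator, so one-voxel-thin structures never vanish; when smooth = TRUE
// the vertex positions along those edges are interpolated from a separable
// 3x3x3 box mean of the indicator, which removes the staircase area bias so
// surface areas of digitised solids converge to the continuous values.
// Vertices are returned in world mm (voxel-center convention).
// [[Rcpp::export]]
List cpp_marching_tets(IntegerVector vox, IntegerVector dims, int label,
                       NumericVector spacing, NumericVector origin, bool smooth) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int pad = 2;
  const int px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  const size_t N = (size_t)px * py * pz;
  std::vector<double> f(N, 0.0);      // vertex-placement field
  std::vector<unsigned char> bin(N, 0); // topology field (binary indicator)
  // R arrays are column-major: index (i,j,k) -> i + nx*(j + ny*k)
  auto pidx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)px * ((size_t)j + (size_t)py * (size_t)k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t src = (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
      size_t dst = pidx(pad, j + pad, k + pad);
      for (int i = 0; i < nx; ++i) {
        bool in = (vox[src + i] == label);
        f[dst + i] = in ? 1.0 : 0.0;
        bin[dst + i] = in ? 1 : 0;
      }
    }
  if (smooth) {
    std::vector<double> g(N);
    // x pass
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j)
        for (int i = 0; i < px; ++i) {
          double s = f[pidx(i, j, k)];
          if (i > 0) s += f[pidx(i - 1, j, k)];
          if (i < px - 1) s += f[pidx(i + 1, j, k)];
          g[pidx(i, j, k)] = s / 3.0;
        }
    // y pass
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j)
        for (int i = 0; i < px; ++i) {
          double s = g[pidx(i, j, k)];
          if (j > 0) s += g[pidx(i, j - 1, k)];
          if (j < py - 1) s += g[pidx(i, j + 1, k)];
          f[pidx(i, j, k)] = s / 3.0;
        }
    // z pass
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j)
        for (int i = 0; i < px; ++i) {
          double s = f[pidx(i, j, k)];
          if (k > 0) s += f[pidx(i, j, k - 1)];
          if (k < pz - 1) s += f[pidx(i, j, k + 1)];
          g[pidx(i, j, k)] = s / 3.0;
        }
    f.swap(g);
  }

  const double iso = 0.5;
  MeshAccum M;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  auto nodePos = [&](size_t id, double* p) {
    int i = (int)(id % px);
    size_t r = id / px;
    int j = (int)(r % py);
    int k = (int)(r / py);
    p[0] = ox + (i - pad) * sx;
    p[1] = oy + (j - pad) * sy;
    p[2] = oz + (k - pad) * sz;
  };

  auto edgeVertex = [&](size_t na, size_t nb) -> int {
    uint64_t lo = na < nb ? na : nb, hi = na < nb ? nb : na;
    uint64_t key = lo * (uint64_t)N + hi;
    auto it = M.edgeVert.find(key);
    if (it != M.edgeVert.end()) return it->second;
    double pa[3], pb[3];
    nodePos(na, pa); nodePos(nb, pb);
    double va = f[na], vb = f[nb];
    double t = (iso - va) / (vb - va);
    // the smoothed field may not straddle the iso level on this (binary)
    // crossing edge; fall back to the midpoint there
    if (!(t > 0.0 && t < 1.0)) t = 0.5;
    int id = (int)M.vx.size();
    M.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    M.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    M.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    M.edgeVert.emplace(key, id);
    return id;
  };

  auto emitTri = [&](int a, int b, int c, const double* insideRef) {
    // orient the normal away from the inside of the body
    double ax = M.vx[a], ay = M.vy[a], az = M.vz[a];
    double ux = M.vx[b] - ax, uy = M.vy[b] - ay, uz = M.vz[b] - az;
    double wx = M.vx[c] - ax, wy = M.vy[c] - ay, wz = M.vz[c] - az;
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
    double cx = (ax + M.vx[b] + M.vx[c]) / 3.0 - insideRef[0];
    double cy = (ay + M.vy[b] + M.vy[c]) / 3.0 - insideRef[1];
    double cz = (az + M.vz[b] + M.vz[c]) / 3.0 - insideRef[2];
    if (nxv * cx + nyv * cy + nzv * cz < 0.0) { int t = b; b = c; c = t; }
    M.fa.push_back(a); M.fb.push_back(b); M.fc.push_back(c);
  };

  size_t corner[8];
  bool inFlag[8];
  for (int k = 0; k < pz - 1; ++k)
    for (int j = 0; j < py - 1; ++j)
      for (int i = 0; i < px - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = pidx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          inFlag[c] = bin[corner[c]] != 0;
          if (inFlag[c]) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int code = 0;
          for (int c = 0; c < 4; ++c)
            if (inFlag[T[c]]) code |= (1 << c);
          if (code == 0 || code == 15) continue;
          int ins[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (code & (1 << c)) ins[ni++] = c; else out[no++] = c;
          }
          // reference point inside the body: mean of inside corners
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c) {
            double p[3];
            nodePos(corner[T[ins[c]]], p);
            ref[0] += p[0] / ni; ref[1] += p[1] / ni; ref[2] += p[2] / ni;
          }
          if (ni == 1 || ni == 3) {
            int lone = (ni == 1) ? ins[0] : out[0];
            int rest[3], nr = 0;
            for (int c = 0; c < 4; ++c) if (c != lone) rest[nr++] = c;
            int e0 = edgeVertex(corner[T[lone]], corner[T[rest[0]]]);
            int e1 = edgeVertex(corner[T[lone]], corner[T[rest[1]]]);
            int e2 = edgeVertex(corner[T[lone]], corner[T[rest[2]]]);
            emitTri(e0, e1, e2, ref);
          } else {
            int q0 = edgeVertex(corner[T[ins[0]]], corner[T[out[0]]]);
            int q1 = edgeVertex(corner[T[ins[0]]], corner[T[out[1]]]);
            int q2 = edgeVertex(corner[T[ins[1]]], corner[T[out[1]]]);
            int q3 = edgeVertex(corner[T[ins[1]]], corner[T[out[0]]]);
            emitTri(q0, q1, q2, ref);
            emitTri(q0, q2, q3, ref);
          }
        }
      }

  int nv = (int)M.vx.size(), nf = (int)M.fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; V(i, 2) = M.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = M.fa[i] + 1; F(i, 1) = M.fb[i] + 1; F(i, 2) = M.fc[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Morphological dilation of a binary mask by the exact anisotropic Euclidean
// ball of radius margin_mm; offsets are precomputed in R (voxel offsets whose
// mm length is <= margin).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  const int nOff = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
        if (!mask[id]) continue;
        for (int o = 0; o < nOff; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * (size_t)kk)] = true;
        }
      }
  return out;
}
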