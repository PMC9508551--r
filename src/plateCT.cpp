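// Core voxel routines: 3D connected-component labelling (6/18/26), per-blob
// statistics, and iso-surface extraction on binary fields by marching
// tetrahedra over the Kuhn (6-tetrahedra) cube decomposition.
//
// Arrays follow the R layout dim = (nz, ny, nx): linear index
// idx = z + nz * (y + ny * x), 0-based here.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <cstdlib>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

static inline int64_t lindex(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * x);
}

// neighbour offsets for the requested connectivity
static std::vector<std::array<int, 3>> neighbourOffsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (a == 0) continue;
        if (connectivity == 6 && a != 1) continue;
        if (connectivity == 18 && a == 3) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  auto off = neighbourOffsets(connectivity);
  std::vector<int64_t> stack;
  int next = 0;
  // raster order: slices (z), then rows (y), then columns (x)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int64_t i = lindex(z, y, x, nz, ny);
        if (!mask[i] || labels[i]) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int64_t c = stack.back();
          stack.pop_back();
          int cz = (int)(c % nz);
          int64_t rest = c / nz;
          int cy = (int)(rest % ny);
          int cx = (int)(rest / ny);
          for (auto &o : off) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                xx >= nx)
              continue;
            int64_t j = lindex(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return labels;
}

// [[Rcpp::export]]
List cpp_blob_stats(IntegerVector labels, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  int k = 0;
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > k) k = labels[i];
  IntegerVector count(k, 0), z0(k, nz + 1), z1(k, 0), y0(k, ny + 1), y1(k, 0),
      x0(k, nx + 1), x1(k, 0);
  NumericVector cz(k, 0.0), cy(k, 0.0), cx(k, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int lab = labels[lindex(z, y, x, nz, ny)];
        if (!lab) continue;
        int g = lab - 1;
        ++count[g];
        // 1-based indices for the R side
        int zi = z + 1, yi = y + 1, xi = x + 1;
        if (zi < z0[g]) z0[g] = zi;
        if (zi > z1[g]) z1[g] = zi;
        if (yi < y0[g]) y0[g] = yi;
        if (yi > y1[g]) y1[g] = yi;
        if (xi < x0[g]) x0[g] = xi;
        if (xi > x1[g]) x1[g] = xi;
        cz[g] += zi;
        cy[g] += yi;
        cx[g] += xi;
      }
  for (int g = 0; g < k; ++g) {
    cz[g] /= count[g];
    cy[g] /= count[g];
    cx[g] /= count[g];
  }
  return List::create(_["count"] = count, _["z0"] = z0, _["z1"] = z1,
                      _["y0"] = y0, _["y1"] = y1, _["x0"] = x0, _["x1"] = x1,
                      _["cz"] = cz, _["cy"] = cy, _["cx"] = cx);
}

// ---- iso-surface extraction (marching tetrahedra on the Kuhn subdivision) --
//
// Each grid cell (cube of 8 lattice nodes) is split into the six Kuhn
// tetrahedra sharing the main diagonal; this subdivision is globally
// face-consistent across the lattice, so the piecewise-linear level-0.5
// surface of a binary field is a closed 2-manifold. Surface vertices lie at
// tetrahedron-edge midpoints (the 0.5 interpolant between a 0 and a 1 node).

struct VertexBank {
  std::map<std::pair<int64_t, int64_t>, int> seen;
  std::vector<double> coords;  // x, y, z triplets
  int add(int64_t a, int64_t b, const double *pa, const double *pb) {
    if (a > b) {
      std::swap(a, b);
      const double *t = pa;
      pa = pb;
      pb = t;
    }
    auto key = std::make_pair(a, b);
    auto it = seen.find(key);
    if (it != seen.end()) return it->second;
    int id = (int)(coords.size() / 3);
    seen[key] = id;
    coords.push_back(0.5 * (pa[0] + pb[0]));
    coords.push_back(0.5 * (pa[1] + pb[1]));
    coords.push_back(0.5 * (pa[2] + pb[2]));
    return id;
  }
};

// [[Rcpp::export]]
List cpp_march_tets(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  VertexBank bank;
  std::vector<int> faces;  // vertex-id triples, 0-based

  // corner id c = dx + 2*dy + 4*dz; the six Kuhn tetrahedra (bit-add paths)
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  int64_t nodeId[8];
  double pos[8][3];  // x, y, z of each corner (lattice coordinates)
  int val[8];

  auto emitTri = [&](int v1, int v2, int v3, const double *insideCentroid) {
    const double *p1 = &bank.coords[3 * v1];
    const double *p2 = &bank.coords[3 * v2];
    const double *p3 = &bank.coords[3 * v3];
    double u[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double w[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
    double nvec[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                      u[0] * w[1] - u[1] * w[0]};
    double tc[3] = {(p1[0] + p2[0] + p3[0]) / 3.0,
                    (p1[1] + p2[1] + p3[1]) / 3.0,
                    (p1[2] + p2[2] + p3[2]) / 3.0};
    double d = nvec[0] * (tc[0] - insideCentroid[0]) +
               nvec[1] * (tc[1] - insideCentroid[1]) +
               nvec[2] * (tc[2] - insideCentroid[2]);
    // outward orientation: normal points away from the inside region
    if (d < 0) std::swap(v2, v3);
    faces.push_back(v1);
    faces.push_back(v2);
    faces.push_back(v3);
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        int any1 = 0, any0 = 0;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          nodeId[c] = lindex(z + dz, y + dy, x + dx, nz, ny);
          val[c] = mask[nodeId[c]] ? 1 : 0;
          pos[c][0] = x + dx;
          pos[c][1] = y + dy;
          pos[c][2] = z + dz;
          if (val[c])
            any1 = 1;
          else
            any0 = 1;
        }
        if (!any1 || !any0) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            int c = tets[t][k];
            if (val[c])
              in[nin++] = c;
            else
              out[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double ic[3] = {0, 0, 0};
          for (int k = 0; k < nin; ++k)
            for (int a = 0; a < 3; ++a) ic[a] += pos[in[k]][a] / nin;
          if (nin == 1 || nin == 3) {
            int A = (nin == 1) ? in[0] : out[0];
            int B = (nin == 1) ? out[0] : in[0];
            int C = (nin == 1) ? out[1] : in[1];
            int D = (nin == 1) ? out[2] : in[2];
            int vAB = bank.add(nodeId[A], nodeId[B], pos[A], pos[B]);
            int vAC = bank.add(nodeId[A], nodeId[C], pos[A], pos[C]);
            int vAD = bank.add(nodeId[A], nodeId[D], pos[A], pos[D]);
            emitTri(vAB, vAC, vAD, ic);
          } else {  // nin == 2: quad between the two inside-outside pairs
            int A = in[0], B = in[1], C = out[0], D = out[1];
            int vAC = bank.add(nodeId[A], nodeId[C], pos[A], pos[C]);
            int vAD = bank.add(nodeId[A], nodeId[D], pos[A], pos[D]);
            int vBD = bank.add(nodeId[B], nodeId[D], pos[B], pos[D]);
            int vBC = bank.add(nodeId[B], nodeId[C], pos[B], pos[C]);
            emitTri(vAC, vAD, vBD, ic);
            emitTri(vAC, vBD, vBC, ic);
          }
        }
      }

  int nv = (int)(bank.coords.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = bank.coords[3 * i];
    verts(i, 1) = bank.coords[3 * i + 1];
    verts(i, 2) = bank.coords[3 * i + 2];
  }
  int nf = (int)(faces.size() / 3);
  IntegerMatrix fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    fm(i, 0) = faces[3 * i] + 1;  // 1-based for R
    fm(i, 1) = faces[3 * i + 1] + 1;
    fm(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = fm);
}
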