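#include <Rcpp.h>
#include <vector>
#include <queue>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline size_t vidx(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
}

// ---------------------------------------------------------------------------
// seeded region growing: voxels >= threshold connected to a seed
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dim,
                              double threshold, IntegerMatrix seeds,
                              int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nt = (size_t)nx * ny * nz;
  std::vector<uint8_t> out(nt, 0);
  std::queue<size_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    size_t id = vidx(seeds(s, 0), seeds(s, 1), seeds(s, 2), nx, ny);
    if (!out[id] && vol[id] >= threshold) {
      out[id] = 1;
      q.push(id);
    }
  }
  while (!q.empty()) {
    size_t id = q.front();
    q.pop();
    int x = (int)(id % nx);
    int y = (int)((id / nx) % ny);
    int z = (int)(id / ((size_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (connectivity == 6 && man != 1) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          size_t nid = vidx(xx, yy, zz, nx, ny);
          if (!out[nid] && vol[nid] >= threshold) {
            out[nid] = 1;
            q.push(nid);
          }
        }
  }
  LogicalVector res(nt);
  for (size_t i = 0; i < nt; ++i) res[i] = out[i] != 0;
  return res;
}

// ---------------------------------------------------------------------------
// connected-component labelling (6 or 26)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nt = (size_t)nx * ny * nz;
  IntegerVector lab(nt, 0);
  int cur = 0;
  std::queue<size_t> q;
  for (size_t i = 0; i < nt; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    q.push(i);
    while (!q.empty()) {
      size_t id = q.front();
      q.pop();
      int x = (int)(id % nx);
      int y = (int)((id / nx) % ny);
      int z = (int)(id / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            size_t nid = vidx(xx, yy, zz, nx, ny);
            if (mask[nid] && !lab[nid]) {
              lab[nid] = cur;
              q.push(nid);
            }
          }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// 3D topological thinning
//
// A voxel is "simple" for the (26, 6) connectivity pair iff (a) the object
// voxels of its 26-neighborhood form exactly one 26-connected component and
// (b) the background voxels of its 18-neighborhood form exactly one
// 6-connected component touching a face neighbor (Bertrand & Malandain).
// Directional subiterations delete simple, non-end, non-anchor border voxels
// sequentially (re-checked at deletion time), which preserves topology.
// ---------------------------------------------------------------------------

// precomputed neighborhood geometry for the 3x3x3 cube, center excluded
struct CubeGeom {
  int off[27][3];
  bool adj26[27][27];
  bool adj6[27][27];
  bool in18[27];
  bool face[27];
  CubeGeom() {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          off[c][0] = dx; off[c][1] = dy; off[c][2] = dz;
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          in18[c] = (man >= 1 && man <= 2);
          face[c] = (man == 1);
          ++c;
        }
    for (int i = 0; i < 27; ++i)
      for (int j = 0; j < 27; ++j) {
        int ax = std::abs(off[i][0] - off[j][0]);
        int ay = std::abs(off[i][1] - off[j][1]);
        int az = std::abs(off[i][2] - off[j][2]);
        bool same = (i == j);
        adj26[i][j] = !same && ax <= 1 && ay <= 1 && az <= 1;
        adj6[i][j] = !same && (ax + ay + az) == 1;
      }
  }
};
static CubeGeom CG;

static inline uint8_t getvox(const std::vector<uint8_t> &img, int x, int y,
                             int z, int nx, int ny, int nz) {
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
  return img[vidx(x, y, z, nx, ny)];
}

static int neighbor_count26(const std::vector<uint8_t> &img, int x, int y,
                            int z, int nx, int ny, int nz) {
  int n = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13) continue;
    if (getvox(img, x + CG.off[c][0], y + CG.off[c][1], z + CG.off[c][2], nx,
               ny, nz))
      ++n;
  }
  return n;
}

static bool is_simple(const std::vector<uint8_t> &img, int x, int y, int z,
                      int nx, int ny, int nz) {
  uint8_t nb[27];
  for (int c = 0; c < 27; ++c)
    nb[c] = getvox(img, x + CG.off[c][0], y + CG.off[c][1], z + CG.off[c][2],
                   nx, ny, nz);

  // (a) one 26-component of object voxels in N26*
  int compObj = 0;
  bool seen[27] = {false};
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++compObj;
    if (compObj > 1) return false;
    // BFS
    int stack[27], top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top) {
      int u = stack[--top];
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || seen[v] || !nb[v]) continue;
        if (CG.adj26[u][v]) {
          seen[v] = true;
          stack[top++] = v;
        }
      }
    }
  }
  if (compObj != 1) return false;

  // (b) one 6-component of background voxels in N18 touching a face neighbor
  bool seenB[27] = {false};
  int compBg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !CG.in18[i] || nb[i] || seenB[i]) continue;
    // grow the component
    int stack[27], top = 0;
    stack[top++] = i;
    seenB[i] = true;
    bool touches = CG.face[i];
    while (top) {
      int u = stack[--top];
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || seenB[v] || !CG.in18[v] || nb[v]) continue;
        if (CG.adj6[u][v]) {
          seenB[v] = true;
          if (CG.face[v]) touches = true;
          stack[top++] = v;
        }
      }
    }
    if (touches) {
      ++compBg;
      if (compBg > 1) return false;
    }
  }
  return compBg == 1;
}

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalVector thin_cpp(LogicalVector mask, IntegerVector dim,
                       IntegerMatrix anchors) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nt = (size_t)nx * ny * nz;
  std::vector<uint8_t> img(nt, 0), anc(nt, 0);
  for (size_t i = 0; i < nt; ++i) img[i] = mask[i] ? 1 : 0;
  for (int a = 0; a < anchors.nrow(); ++a)
    anc[vidx(anchors(a, 0), anchors(a, 1), anchors(a, 2), nx, ny)] = 1;

  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t id = vidx(x, y, z, nx, ny);
            if (!img[id] || anc[id]) continue;
            if (getvox(img, x + dirs[d][0], y + dirs[d][1], z + dirs[d][2],
                       nx, ny, nz))
              continue;  // not a border voxel for this direction
            int nc = neighbor_count26(img, x, y, z, nx, ny, nz);
            if (nc <= 1) continue;  // curve endpoint (or isolated): keep
            if (is_simple(img, x, y, z, nx, ny, nz)) cand.push_back(id);
          }
      // sequential deletion with re-check keeps the thinning homotopic
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t id = cand[k];
        int x = (int)(id % nx);
        int y = (int)((id / nx) % ny);
        int z = (int)(id / ((size_t)nx * ny));
        int nc = neighbor_count26(img, x, y, z, nx, ny, nz);
        if (nc <= 1) continue;
        if (!is_simple(img, x, y, z, nx, ny, nz)) continue;
        img[id] = 0;
        changed = true;
      }
    }
  }
  LogicalVector res(nt);
  for (size_t i = 0; i < nt; ++i) res[i] = img[i] != 0;
  return res;
}

// ---------------------------------------------------------------------------
// tube rasterization: voxel centers within the (arc-length interpolated)
// radius of the polyline
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".rasterize_mask_cpp")]]
LogicalVector rasterize_mask_cpp(NumericMatrix pts, NumericVector radii,
                                 IntegerVector dim, NumericVector spacing,
                                 NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nt = (size_t)nx * ny * nz;
  std::vector<uint8_t> out(nt, 0);
  const int np = pts.nrow();
  for (int s = 0; s + 1 < np; ++s) {
    double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
    double ra = radii[s], rb = radii[s + 1];
    double rmax = std::max(ra, rb);
    double lox = std::min(ax, bx) - rmax, hix = std::max(ax, bx) + rmax;
    double loy = std::min(ay, by) - rmax, hiy = std::max(ay, by) + rmax;
    double loz = std::min(az, bz) - rmax, hiz = std::max(az, bz) + rmax;
    int x0 = std::max(0, (int)std::floor((lox - origin[0]) / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::floor((loy - origin[1]) / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / spacing[1]));
    int z0 = std::max(0, (int)std::floor((loz - origin[2]) / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / spacing[2]));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double px = origin[0] + x * spacing[0];
          double py = origin[1] + y * spacing[1];
          double pz = origin[2] + z * spacing[2];
          double t = 0.0;
          if (L2 > 0.0) {
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
          }
          double qx = ax + t * ux, qy = ay + t * uy, qz = az + t * uz;
          double dx = px - qx, dy = py - qy, dz = pz - qz;
          double d2 = dx * dx + dy * dy + dz * dz;
          double r = ra + t * (rb - ra);
          if (d2 <= r * r + 1e-12) out[vidx(x, y, z, nx, ny)] = 1;
        }
  }
  LogicalVector res(nt);
  for (size_t i = 0; i < nt; ++i) res[i] = out[i] != 0;
  return res;
}

// ---------------------------------------------------------------------------
// 26-adjacency edge list of a skeleton voxel set (for the path graph)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".skeleton_edges_cpp")]]
List skeleton_edges_cpp(IntegerMatrix vox, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1];
  const int n = vox.nrow();
  std::map<size_t, int> id_of;
  for (int i = 0; i < n; ++i)
    id_of[vidx(vox(i, 0), vox(i, 1), vox(i, 2), nx, ny)] = i;
  std::vector<int> from, to;
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    int x = vox(i, 0), y = vox(i, 1), z = vox(i, 2);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
              zz >= dim[2])
            continue;
          std::map<size_t, int>::iterator it =
              id_of.find(vidx(xx, yy, zz, nx, ny));
          if (it == id_of.end() || it->second <= i) continue;
          from.push_back(i + 1);
          to.push_back(it->second + 1);
          double wx = dx * spacing[0], wy = dy * spacing[1],
                 wz = dz * spacing[2];
          w.push_back(std::sqrt(wx * wx + wy * wy + wz * wz));
        }
  }
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["weight"] = wrap(w));
}
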