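#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel volumes are stored column-major (R array layout): idx = x + nx*(y + ny*z).

static inline bool in_bounds(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Co-occurrence counts for a set of voxel offsets. `levels` holds quantized
// gray levels 1..G inside the ROI and 0 outside. One G*G count matrix per
// offset, symmetric by accumulating both (i,j) and (j,i).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                              IntegerMatrix offsets, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  NumericMatrix out(G * G, K);
  for (int k = 0; k < K; ++k) {
    const int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int l1 = levels[x + nx * (y + ny * z)];
          if (l1 == 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!in_bounds(x2, y2, z2, nx, ny, nz)) continue;
          const int l2 = levels[x2 + nx * (y2 + ny * z2)];
          if (l2 == 0) continue;
          out((l1 - 1) + G * (l2 - 1), k) += 1.0;
          out((l2 - 1) + G * (l1 - 1), k) += 1.0;
        }
  }
  return out;
}

// Run-length counts per direction: maximal collinear runs of equal level.
// Returns a (G * Lmax) x ndirs matrix, Lmax = longest possible run.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                               IntegerMatrix dirs, int G, int Lmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = dirs.nrow();
  NumericMatrix out(G * Lmax, K);
  for (int k = 0; k < K; ++k) {
    const int dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int l = levels[x + nx * (y + ny * z)];
          if (l == 0) continue;
          // run starts here iff predecessor is absent or differs
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (in_bounds(xp, yp, zp, nx, ny, nz) &&
              levels[xp + nx * (yp + ny * zp)] == l) continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (in_bounds(xn, yn, zn, nx, ny, nz) &&
                 levels[xn + nx * (yn + ny * zn)] == l) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          if (len > Lmax) len = Lmax;
          out((l - 1) + G * (len - 1), k) += 1.0;
        }
  }
  return out;
}

// Binary erosion by an explicit offset set (the discretized ball). Voxels
// whose structuring element leaves the volume are eroded (outside counts as
// background).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int idx = x + nx * (y + ny * z);
        if (!mask[idx]) { out[idx] = false; continue; }
        bool keep = true;
        for (int k = 0; k < K; ++k) {
          const int x2 = x + offsets(k, 0), y2 = y + offsets(k, 1),
                    z2 = z + offsets(k, 2);
          if (!in_bounds(x2, y2, z2, nx, ny, nz) ||
              !mask[x2 + nx * (y2 + ny * z2)]) { keep = false; break; }
        }
        out[idx] = keep;
      }
  return out;
}

// ---- marching tetrahedra surface area ------------------------------------

static const int TET[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets, vertex v: (x + CX[v], y + CY[v], z + CZ[v])
static const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  const double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  const double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  const double w[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2],
                       u[0]*v[1]-u[1]*v[0]};
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

// Area and enclosed volume of the `iso`-level surface of a scalar field,
// by marching tetrahedra with linear edge interpolation. Out-of-bounds
// samples are 0, so surfaces close at the volume border. Triangles are
// oriented outward (toward decreasing field) and the enclosed volume comes
// from the divergence theorem over the closed mesh.
// [[Rcpp::export]]
NumericVector cpp_surface_mesh(NumericVector field, IntegerVector dims,
                               NumericVector spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol6 = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8];
        int nin_cube = 0;
        for (int v = 0; v < 8; ++v) {
          const int xx = x + CX[v], yy = y + CY[v], zz = z + CZ[v];
          val[v] = in_bounds(xx, yy, zz, nx, ny, nz) ?
                   field[xx + nx * (yy + ny * zz)] : 0.0;
          if (val[v] > iso) ++nin_cube;
        }
        if (nin_cube == 0 || nin_cube == 8) continue;
        double pos[8][3];
        for (int v = 0; v < 8; ++v) {
          pos[v][0] = (x + CX[v]) * sx;
          pos[v][1] = (y + CY[v]) * sy;
          pos[v][2] = (z + CZ[v]) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          const int *tv = TET[t];
          bool ins[4];
          int nin = 0;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int v = 0; v < 4; ++v) {
            ins[v] = val[tv[v]] > iso;
            for (int d = 0; d < 3; ++d) {
              if (ins[v]) cin[d] += pos[tv[v]][d];
              else cout[d] += pos[tv[v]][d];
            }
            if (ins[v]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          for (int d = 0; d < 3; ++d) { cin[d] /= nin; cout[d] /= (4 - nin); }
          // edge crossings by linear interpolation
          double pt[4][3];
          int np = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b)
              if (ins[a] != ins[b]) {
                const double va = val[tv[a]], vb = val[tv[b]];
                const double tt = (iso - va) / (vb - va);
                for (int d = 0; d < 3; ++d)
                  pt[np][d] = pos[tv[a]][d] + tt * (pos[tv[b]][d] - pos[tv[a]][d]);
                ++np;
              }
          int tris[2][3];
          int ntri = 0;
          if (np == 3) {
            tris[0][0] = 0; tris[0][1] = 1; tris[0][2] = 2; ntri = 1;
          } else if (np == 4) {
            // crossings from edges (a0,b0),(a0,b1),(a1,b0),(a1,b1):
            // 0-1 and 2-3 share a tet vertex, so 0-1-3 and 0-3-2 tile the quad
            tris[0][0] = 0; tris[0][1] = 1; tris[0][2] = 3;
            tris[1][0] = 0; tris[1][1] = 3; tris[1][2] = 2; ntri = 2;
          }
          for (int m = 0; m < ntri; ++m) {
            double *p0 = pt[tris[m][0]], *p1 = pt[tris[m][1]],
                   *p2 = pt[tris[m][2]];
            double u[3], v[3], nvec[3];
            for (int d = 0; d < 3; ++d) { u[d] = p1[d]-p0[d]; v[d] = p2[d]-p0[d]; }
            nvec[0] = u[1]*v[2]-u[2]*v[1];
            nvec[1] = u[2]*v[0]-u[0]*v[2];
            nvec[2] = u[0]*v[1]-u[1]*v[0];
            const double dir = nvec[0]*(cout[0]-cin[0]) +
                               nvec[1]*(cout[1]-cin[1]) +
                               nvec[2]*(cout[2]-cin[2]);
            double *q1 = p1, *q2 = p2;
            double sgn = 1.0;
            if (dir < 0) { q1 = p2; q2 = p1; sgn = -1.0; }
            area += 0.5 * std::sqrt(nvec[0]*nvec[0] + nvec[1]*nvec[1] +
                                    nvec[2]*nvec[2]);
            vol6 += p0[0]*(q1[1]*q2[2]-q1[2]*q2[1]) +
                    p0[1]*(q1[2]*q2[0]-q1[0]*q2[2]) +
                    p0[2]*(q1[0]*q2[1]-q1[1]*q2[0]);
            (void)sgn;
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}

// ---- incremental 3D convex hull volume -----------------------------------

struct Face {
  int a, b, c;        // vertex indices, outward orientation
  double nx, ny, nz;  // outward normal (not unit)
  double d;           // plane offset: dot(n, p) = d
  bool alive;
};

static inline void face_plane(Face &f, const std::vector<double> &px,
                              const std::vector<double> &py,
                              const std::vector<double> &pz,
                              double cx, double cy, double cz) {
  const double ux = px[f.b]-px[f.a], uy = py[f.b]-py[f.a], uz = pz[f.b]-pz[f.a];
  const double vx = px[f.c]-px[f.a], vy = py[f.c]-py[f.a], vz = pz[f.c]-pz[f.a];
  f.nx = uy*vz - uz*vy; f.ny = uz*vx - ux*vz; f.nz = ux*vy - uy*vx;
  f.d = f.nx*px[f.a] + f.ny*py[f.a] + f.nz*pz[f.a];
  // orient away from interior point
  if (f.nx*cx + f.ny*cy + f.nz*cz > f.d) {
    std::swap(f.b, f.c);
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.d = -f.d;
  }
  f.alive = true;
}

// Volume of the convex hull of a point cloud (n x 3). Returns 0 for
// degenerate (coplanar) input.
// [[Rcpp::export]]
double cpp_convhull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i]=pts(i,0); py[i]=pts(i,1); pz[i]=pts(i,2); }

  // initial tetrahedron: four affinely independent points
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  const double eps = 1e-9;
  for (int i = 1; i < n && i1 < 0; ++i) {
    const double dx=px[i]-px[i0], dy=py[i]-py[i0], dz=pz[i]-pz[i0];
    if (dx*dx+dy*dy+dz*dz > eps) i1 = i;
  }
  if (i1 < 0) return 0.0;
  for (int i = 1; i < n && i2 < 0; ++i) {
    const double ux=px[i1]-px[i0], uy=py[i1]-py[i0], uz=pz[i1]-pz[i0];
    const double vx=px[i]-px[i0], vy=py[i]-py[i0], vz=pz[i]-pz[i0];
    const double cx=uy*vz-uz*vy, cy=uz*vx-ux*vz, cz=ux*vy-uy*vx;
    if (cx*cx+cy*cy+cz*cz > eps) i2 = i;
  }
  if (i2 < 0) return 0.0;
  double best = 0.0;
  for (int i = 1; i < n; ++i) {
    const double ux=px[i1]-px[i0], uy=py[i1]-py[i0], uz=pz[i1]-pz[i0];
    const double vx=px[i2]-px[i0], vy=py[i2]-py[i0], vz=pz[i2]-pz[i0];
    const double cx=uy*vz-uz*vy, cy=uz*vx-ux*vz, cz=ux*vy-uy*vx;
    const double vol = cx*(px[i]-px[i0]) + cy*(py[i]-py[i0]) + cz*(pz[i]-pz[i0]);
    if (std::fabs(vol) > std::fabs(best)) { best = vol; i3 = i; }
  }
  if (i3 < 0 || std::fabs(best) < eps) return 0.0;

  const double cx = (px[i0]+px[i1]+px[i2]+px[i3]) / 4.0;
  const double cy = (py[i0]+py[i1]+py[i2]+py[i3]) / 4.0;
  const double cz = (pz[i0]+pz[i1]+pz[i2]+pz[i3]) / 4.0;

  std::vector<Face> faces;
  int tet[4] = {i0, i1, i2, i3};
  const int ftab[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
  for (int f = 0; f < 4; ++f) {
    Face fc; fc.a = tet[ftab[f][0]]; fc.b = tet[ftab[f][1]]; fc.c = tet[ftab[f][2]];
    face_plane(fc, px, py, pz, cx, cy, cz);
    faces.push_back(fc);
  }

  const double tol = 1e-7;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      const Face &fc = faces[f];
      const double nn = std::sqrt(fc.nx*fc.nx + fc.ny*fc.ny + fc.nz*fc.nz);
      if ((fc.nx*px[i] + fc.ny*py[i] + fc.nz*pz[i] - fc.d) > tol * (nn + 1.0))
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int,int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face &fc = faces[visible[v]];
      const int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; ++k) {
        bool cancelled = false;
        for (size_t j = 0; j < edges.size(); ++j)
          if (edges[j].first == e[k][1] && edges[j].second == e[k][0]) {
            edges.erase(edges.begin() + j); cancelled = true; break;
          }
        if (!cancelled) edges.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (size_t j = 0; j < edges.size(); ++j) {
      Face fc; fc.a = edges[j].first; fc.b = edges[j].second; fc.c = i;
      face_plane(fc, px, py, pz, cx, cy, cz);
      faces.push_back(fc);
    }
  }

  double vol6 = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    const double ax = px[fc.a]-cx, ay = py[fc.a]-cy, az = pz[fc.a]-cz;
    const double bx = px[fc.b]-cx, by = py[fc.b]-cy, bz = pz[fc.b]-cz;
    const double gx = px[fc.c]-cx, gy = py[fc.c]-cy, gz = pz[fc.c]-cz;
    vol6 += ax*(by*gz - bz*gy) + ay*(bz*gx - bx*gz) + az*(bx*gy - by*gx);
  }
  return vol6 / 6.0;
}

// ---- direction-averaged texture features (fast path) ---------------------

static inline double xlog2(double x) { return x > 0 ? x * std::log2(x) : 0.0; }

// bounding box of nonzero levels; returns false when the ROI is empty
static bool roi_bbox(const IntegerVector &levels, int nx, int ny, int nz,
                     int bb[6]) {
  bb[0] = nx; bb[1] = -1; bb[2] = ny; bb[3] = -1; bb[4] = nz; bb[5] = -1;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (levels[x + nx * (y + ny * z)] != 0) {
          if (x < bb[0]) bb[0] = x;
          if (x > bb[1]) bb[1] = x;
          if (y < bb[2]) bb[2] = y;
          if (y > bb[3]) bb[3] = y;
          if (z < bb[4]) bb[4] = z;
          if (z > bb[5]) bb[5] = z;
        }
  return bb[1] >= 0;
}

// 22 GLCM features averaged over the given offsets (skipping offsets with
// no valid pair). Returns NaN-filled vector when every offset is degenerate.
// Feature order matches glcm_feature_names().
// [[Rcpp::export]]
NumericVector cpp_glcm_dirmean(IntegerVector levels, IntegerVector dims,
                               IntegerMatrix offsets, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  NumericVector acc(22, 0.0);
  int nvalid = 0;
  int bb[6];
  if (!roi_bbox(levels, nx, ny, nz, bb)) {
    for (int f = 0; f < 22; ++f) acc[f] = NA_REAL;
    return acc;
  }
  std::vector<double> cnt(G * G), px(G), pdiff(G), psum(2 * G - 1);
  for (int k = 0; k < K; ++k) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    const int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
    double tot = 0.0;
    for (int z = bb[4]; z <= bb[5]; ++z)
      for (int y = bb[2]; y <= bb[3]; ++y)
        for (int x = bb[0]; x <= bb[1]; ++x) {
          const int l1 = levels[x + nx * (y + ny * z)];
          if (l1 == 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!in_bounds(x2, y2, z2, nx, ny, nz)) continue;
          const int l2 = levels[x2 + nx * (y2 + ny * z2)];
          if (l2 == 0) continue;
          cnt[(l1 - 1) + G * (l2 - 1)] += 1.0;
          cnt[(l2 - 1) + G * (l1 - 1)] += 1.0;
          tot += 2.0;
        }
    if (tot <= 0) continue;
    ++nvalid;
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);
    std::fill(psum.begin(), psum.end(), 0.0);
    double energy = 0, je = 0, maxp = 0, ac = 0, contrast = 0, dissim = 0,
           homog = 0, invdiff = 0, invvar = 0;
    for (int j = 0; j < G; ++j)
      for (int i = 0; i < G; ++i) {
        const double p = cnt[i + G * j] / tot;
        if (p <= 0) continue;
        const int di = i - j, ad = di < 0 ? -di : di;
        px[i] += p;
        pdiff[ad] += p;
        psum[i + j] += p;
        energy += p * p;
        je -= xlog2(p);
        if (p > maxp) maxp = p;
        ac += p * (i + 1.0) * (j + 1.0);
        contrast += p * di * di;
        dissim += p * ad;
        homog += p / (1.0 + di * di);
        invdiff += p / (1.0 + ad);
        if (ad > 0) invvar += p / (double)(ad * ad);
      }
    double mu = 0, m2 = 0, hx = 0;
    for (int i = 0; i < G; ++i) {
      mu += px[i] * (i + 1.0);
      m2 += px[i] * (i + 1.0) * (i + 1.0);
      hx -= xlog2(px[i]);
    }
    const double sig2 = m2 - mu * mu;
    double da = 0, de = 0;
    for (int d = 0; d < G; ++d) { da += pdiff[d] * d; de -= xlog2(pdiff[d]); }
    double dv = 0;
    for (int d = 0; d < G; ++d) dv += pdiff[d] * (d - da) * (d - da);
    double sa = 0, se = 0;
    for (int s = 0; s < 2 * G - 1; ++s) {
      sa += psum[s] * (s + 2.0); se -= xlog2(psum[s]);
    }
    double sv = 0, cl2 = 0, cl3 = 0, cl4 = 0;
    for (int s = 0; s < 2 * G - 1; ++s) {
      const double dvn = (s + 2.0) - sa;
      sv += psum[s] * dvn * dvn;
      const double dc = (s + 2.0) - 2.0 * mu;
      cl2 += psum[s] * dc * dc;
      cl3 += psum[s] * dc * dc * dc;
      cl4 += psum[s] * dc * dc * dc * dc;
    }
    double jointvar = 0;
    for (int i = 0; i < G; ++i)
      jointvar += px[i] * ((i + 1.0) - mu) * ((i + 1.0) - mu);
    const double corr = sig2 > 1e-14 ? (ac - mu * mu) / sig2 : 0.0;
    // HXY1 = HXY2 = HX + HY = 2 HX for a symmetric matrix
    const double imc1 = hx > 1e-14 ? (je - 2.0 * hx) / hx : 0.0;
    double imc2arg = 1.0 - std::exp(-2.0 * (2.0 * hx - je));
    if (imc2arg < 0) imc2arg = 0;
    const double feats[22] = {
      ac, cl4, cl3, cl2, contrast, corr, da, de, dv, dissim, energy, je,
      homog, imc1, std::sqrt(imc2arg), invdiff, maxp, sa, se, sv,
      jointvar, invvar
    };
    for (int f = 0; f < 22; ++f) acc[f] += feats[f];
  }
  if (nvalid == 0) {
    for (int f = 0; f < 22; ++f) acc[f] = NA_REAL;
    return acc;
  }
  for (int f = 0; f < 22; ++f) acc[f] /= nvalid;
  return acc;
}

// 7 Galloway run-length features averaged over the offsets.
// Order: sre, lre, gln, rln, rp, lgre, hgre.
// [[Rcpp::export]]
NumericVector cpp_glrlm_dirmean(IntegerVector levels, IntegerVector dims,
                                IntegerMatrix dirs, int G, int np) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = dirs.nrow();
  const int Lmax = std::max(nx, std::max(ny, nz));
  NumericVector acc(7, 0.0);
  int bb[6];
  if (!roi_bbox(levels, nx, ny, nz, bb)) return acc;
  std::vector<double> ri(G), rj(Lmax);
  for (int k = 0; k < K; ++k) {
    const int dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    std::fill(ri.begin(), ri.end(), 0.0);
    std::fill(rj.begin(), rj.end(), 0.0);
    double nr = 0, sre = 0, lre = 0, lgre = 0, hgre = 0;
    for (int z = bb[4]; z <= bb[5]; ++z)
      for (int y = bb[2]; y <= bb[3]; ++y)
        for (int x = bb[0]; x <= bb[1]; ++x) {
          const int l = levels[x + nx * (y + ny * z)];
          if (l == 0) continue;
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (in_bounds(xp, yp, zp, nx, ny, nz) &&
              levels[xp + nx * (yp + ny * zp)] == l) continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (in_bounds(xn, yn, zn, nx, ny, nz) &&
                 levels[xn + nx * (yn + ny * zn)] == l) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          nr += 1.0;
          ri[l - 1] += 1.0;
          rj[len - 1] += 1.0;
          sre += 1.0 / ((double)len * len);
          lre += (double)len * len;
          lgre += 1.0 / ((double)l * l);
          hgre += (double)l * l;
        }
    if (nr <= 0) continue;
    double gln = 0, rln = 0;
    for (int i = 0; i < G; ++i) gln += ri[i] * ri[i];
    for (int j = 0; j < Lmax; ++j) rln += rj[j] * rj[j];
    acc[0] += sre / nr;
    acc[1] += lre / nr;
    acc[2] += gln / nr;
    acc[3] += rln / nr;
    acc[4] += nr / (double)np;
    acc[5] += lgre / nr;
    acc[6] += hgre / nr;
  }
  for (int f = 0; f < 7; ++f) acc[f] /= K;
  return acc;
}

// Which query points lie inside (or on) the convex hull of `pts`?
// Rebuilds the hull incrementally, then tests each query point against all
// face planes. Degenerate hulls (volume ~0) return all-false.
// [[Rcpp::export]]
LogicalVector cpp_hull_contains(NumericMatrix pts, NumericMatrix query) {
  const int n = pts.nrow(), m = query.nrow();
  LogicalVector res(m);
  if (n < 4) return res;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i]=pts(i,0); py[i]=pts(i,1); pz[i]=pts(i,2); }
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  const double eps = 1e-9;
  for (int i = 1; i < n && i1 < 0; ++i) {
    const double dx=px[i]-px[i0], dy=py[i]-py[i0], dz=pz[i]-pz[i0];
    if (dx*dx+dy*dy+dz*dz > eps) i1 = i;
  }
  if (i1 < 0) return res;
  for (int i = 1; i < n && i2 < 0; ++i) {
    const double ux=px[i1]-px[i0], uy=py[i1]-py[i0], uz=pz[i1]-pz[i0];
    const double vx=px[i]-px[i0], vy=py[i]-py[i0], vz=pz[i]-pz[i0];
    const double cx=uy*vz-uz*vy, cy=uz*vx-ux*vz, cz=ux*vy-uy*vx;
    if (cx*cx+cy*cy+cz*cz > eps) i2 = i;
  }
  if (i2 < 0) return res;
  double best = 0.0;
  for (int i = 1; i < n; ++i) {
    const double ux=px[i1]-px[i0], uy=py[i1]-py[i0], uz=pz[i1]-pz[i0];
    const double vx=px[i2]-px[i0], vy=py[i2]-py[i0], vz=pz[i2]-pz[i0];
    const double cx=uy*vz-uz*vy, cy=uz*vx-ux*vz, cz=ux*vy-uy*vx;
    const double vol = cx*(px[i]-px[i0]) + cy*(py[i]-py[i0]) + cz*(pz[i]-pz[i0]);
    if (std::fabs(vol) > std::fabs(best)) { best = vol; i3 = i; }
  }
  if (i3 < 0 || std::fabs(best) < eps) return res;
  const double cx = (px[i0]+px[i1]+px[i2]+px[i3]) / 4.0;
  const double cy = (py[i0]+py[i1]+py[i2]+py[i3]) / 4.0;
  const double cz = (pz[i0]+pz[i1]+pz[i2]+pz[i3]) / 4.0;
  std::vector<Face> faces;
  int tet[4] = {i0, i1, i2, i3};
  const int ftab[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
  for (int f = 0; f < 4; ++f) {
    Face fc; fc.a = tet[ftab[f][0]]; fc.b = tet[ftab[f][1]]; fc.c = tet[ftab[f][2]];
    face_plane(fc, px, py, pz, cx, cy, cz);
    faces.push_back(fc);
  }
  const double tol = 1e-7;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      const Face &fc = faces[f];
      const double nn = std::sqrt(fc.nx*fc.nx + fc.ny*fc.ny + fc.nz*fc.nz);
      if ((fc.nx*px[i] + fc.ny*py[i] + fc.nz*pz[i] - fc.d) > tol * (nn + 1.0))
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    std::vector<std::pair<int,int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face &fc = faces[visible[v]];
      const int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; ++k) {
        bool cancelled = false;
        for (size_t j = 0; j < edges.size(); ++j)
          if (edges[j].first == e[k][1] && edges[j].second == e[k][0]) {
            edges.erase(edges.begin() + j); cancelled = true; break;
          }
        if (!cancelled) edges.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (size_t j = 0; j < edges.size(); ++j) {
      Face fc; fc.a = edges[j].first; fc.b = edges[j].second; fc.c = i;
      face_plane(fc, px, py, pz, cx, cy, cz);
      faces.push_back(fc);
    }
  }
  for (int q = 0; q < m; ++q) {
    const double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    bool inside = true;
    for (size_t f = 0; f < faces.size() && inside; ++f) {
      if (!faces[f].alive) continue;
      const Face &fc = faces[f];
      const double nn = std::sqrt(fc.nx*fc.nx + fc.ny*fc.ny + fc.nz*fc.nz);
      if ((fc.nx*qx + fc.ny*qy + fc.nz*qz - fc.d) > 1e-7 * (nn + 1.0))
        inside = false;
    }
    res[q] = inside;
  }
  return res;
}
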