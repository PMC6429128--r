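// Molecular-surface machinery: distance field over a union of spheres,
// marching-tetrahedra isosurface extraction (Kuhn 6-tetrahedra cube
// decomposition -- face-consistent across the grid, hence watertight
// output), nearest-sphere queries, and quadric edge-collapse decimation.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- distance field ------------------------------------------------------

// field(x) = min_i (|x - c_i| - r_i), evaluated on a regular grid, capped at
// +cap away from all spheres (the cap only matters farther than `margin`
// from every sphere surface, where the isosurface cannot pass).
// [[Rcpp::export(name = ".sphere_sdf_grid_cpp")]]
NumericVector sphere_sdf_grid_cpp(const NumericMatrix& centers,
                                  const NumericVector& radii,
                                  const NumericVector& origin,
                                  double spacing,
                                  const IntegerVector& dims,
                                  double margin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cap = margin;
  NumericVector field(static_cast<R_xlen_t>(nx) * ny * nz, cap);
  const int na = centers.nrow();
  for (int a = 0; a < na; ++a) {
    const double cx = centers(a, 0), cy = centers(a, 1), cz = centers(a, 2);
    const double r = radii[a], reach = r + margin;
    int i0 = std::max(0, (int)std::floor((cx - reach - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + reach - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::floor((cy - reach - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + reach - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::floor((cz - reach - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + reach - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing - cy;
        double dyz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing - cx;
          double d = std::sqrt(dx * dx + dyz) - r;
          if (d < field[base + i]) field[base + i] = d;
        }
      }
    }
  }
  return field;
}

// index of the sphere whose surface is nearest to each query point
// [[Rcpp::export(name = ".nearest_sphere_cpp")]]
IntegerVector nearest_sphere_cpp(const NumericMatrix& points,
                                 const NumericMatrix& centers,
                                 const NumericVector& radii) {
  const int np = points.nrow(), na = centers.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf; int bi = 0;
    for (int a = 0; a < na; ++a) {
      double dx = points(p, 0) - centers(a, 0);
      double dy = points(p, 1) - centers(a, 1);
      double dz = points(p, 2) - centers(a, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
      if (d < best) { best = d; bi = a; }
    }
    out[p] = bi + 1;
  }
  return out;
}

// ---- marching tetrahedra -------------------------------------------------

namespace {
struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

inline uint64_t ekey(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}
}

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(const NumericVector& field, const IntegerVector& dims,
                    const NumericVector& origin, double spacing,
                    double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)k * nx * ny + (uint64_t)j * nx + i;
  };
  auto fval = [&](uint64_t g) { return field[(R_xlen_t)g]; };
  MTState st;

  auto edge_point = [&](uint64_t ga, uint64_t gb) -> int {
    uint64_t key = ekey(ga, gb);
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double fa = fval(ga), fb = fval(gb);
    double t = (iso - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    int ia = ga % nx, ja = (ga / nx) % ny, ka = ga / ((uint64_t)nx * ny);
    int ib = gb % nx, jb = (gb / nx) % ny, kb = gb / ((uint64_t)nx * ny);
    st.vx.push_back(origin[0] + spacing * (ia + t * (ib - ia)));
    st.vy.push_back(origin[1] + spacing * (ja + t * (jb - ja)));
    st.vz.push_back(origin[2] + spacing * (ka + t * (kb - ka)));
    int id = (int)st.vx.size() - 1;
    st.edge_vertex[key] = id;
    return id;
  };

  // emit triangle oriented so its normal points towards the outside
  auto emit = [&](int a, int b, int c,
                  double ox, double oy, double oz) {
    double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
    double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
    double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double cxv = (ax + st.vx[b] + st.vx[c]) / 3.0;
    double cyv = (ay + st.vy[b] + st.vy[c]) / 3.0;
    double czv = (az + st.vz[b] + st.vz[c]) / 3.0;
    double dot = nxv * (ox - cxv) + nyv * (oy - cyv) + nzv * (oz - czv);
    if (dot >= 0) { st.tri.push_back(a); st.tri.push_back(b); st.tri.push_back(c); }
    else          { st.tri.push_back(a); st.tri.push_back(c); st.tri.push_back(b); }
  };

  // Kuhn decomposition: 6 tetrahedra per cube, all sharing diagonal 0-7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t corner[8];
        double cf[8];
        bool allin = true, allout = true;
        for (int c = 0; c < 8; ++c) {
          corner[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cf[c] = fval(corner[c]);
          if (cf[c] < iso) allout = false; else allin = false;
        }
        if (allin || allout) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t g[4]; double f[4]; int in[4], nin = 0, nout = 0;
          int ins[4], outs[4];
          for (int v = 0; v < 4; ++v) {
            g[v] = corner[tets[t][v]];
            f[v] = cf[tets[t][v]];
            in[v] = f[v] < iso;
            if (in[v]) ins[nin++] = v; else outs[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;
          // reference "outside" point: mean of outside corners
          double ox = 0, oy = 0, oz = 0;
          for (int q = 0; q < nout; ++q) {
            uint64_t gg = g[outs[q]];
            ox += origin[0] + spacing * (double)(gg % nx);
            oy += origin[1] + spacing * (double)((gg / nx) % ny);
            oz += origin[2] + spacing * (double)(gg / ((uint64_t)nx * ny));
          }
          ox /= nout; oy /= nout; oz /= nout;
          if (nin == 1) {
            int v = ins[0];
            int p0 = edge_point(g[v], g[outs[0]]);
            int p1 = edge_point(g[v], g[outs[1]]);
            int p2 = edge_point(g[v], g[outs[2]]);
            emit(p0, p1, p2, ox, oy, oz);
          } else if (nin == 3) {
            int v = outs[0];
            int p0 = edge_point(g[v], g[ins[0]]);
            int p1 = edge_point(g[v], g[ins[1]]);
            int p2 = edge_point(g[v], g[ins[2]]);
            emit(p0, p1, p2, ox, oy, oz);
          } else {
            int va = ins[0], vb = ins[1], wa = outs[0], wb = outs[1];
            int p00 = edge_point(g[va], g[wa]);
            int p01 = edge_point(g[va], g[wb]);
            int p10 = edge_point(g[vb], g[wa]);
            int p11 = edge_point(g[vb], g[wb]);
            emit(p00, p01, p11, ox, oy, oz);
            emit(p00, p11, p10, ox, oy, oz);
          }
        }
      }

  int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  int nt = (int)st.tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = st.tri[3 * t] + 1;
    F(t, 1) = st.tri[3 * t + 1] + 1;
    F(t, 2) = st.tri[3 * t + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("triangles") = F);
}

// ---- quadric edge-collapse decimation ------------------------------------

namespace {
struct Quadric {
  double m[10] = {0}; // symmetric 4x4: xx,xy,xz,xw,yy,yz,yw,zz,zw,ww
  void add_plane(double a, double b, double c, double d, double w) {
    m[0] += w * a * a; m[1] += w * a * b; m[2] += w * a * c; m[3] += w * a * d;
    m[4] += w * b * b; m[5] += w * b * c; m[6] += w * b * d;
    m[7] += w * c * c; m[8] += w * c * d; m[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) m[i] += o.m[i]; }
  double eval(double x, double y, double z) const {
    return m[0]*x*x + 2*m[1]*x*y + 2*m[2]*x*z + 2*m[3]*x +
           m[4]*y*y + 2*m[5]*y*z + 2*m[6]*y +
           m[7]*z*z + 2*m[8]*z + m[9];
  }
  // solve grad = 0; returns false if near-singular
  bool optimal(double& x, double& y, double& z) const {
    double a11=m[0],a12=m[1],a13=m[2],a22=m[4],a23=m[5],a33=m[7];
    double b1=-m[3],b2=-m[6],b3=-m[8];
    double det = a11*(a22*a33-a23*a23) - a12*(a12*a33-a23*a13)
               + a13*(a12*a23-a22*a13);
    double scale = std::fabs(a11)+std::fabs(a22)+std::fabs(a33);
    if (std::fabs(det) < 1e-9 * scale * scale * scale) return false;
    x = (b1*(a22*a33-a23*a23) - a12*(b2*a33-a23*b3) + a13*(b2*a23-a22*b3)) / det;
    y = (a11*(b2*a33-a23*b3) - b1*(a12*a33-a13*a23) + a13*(a12*b3-b2*a13)) / det;
    z = (a11*(a22*b3-b2*a23) - a12*(a12*b3-b2*a13) + b1*(a12*a23-a22*a13)) / det;
    return true;
  }
};

struct HeapItem {
  double cost;
  int v1, v2;
  uint64_t stamp;
  bool operator<(const HeapItem& o) const { return cost > o.cost; }
};
}

// [[Rcpp::export(name = ".decimate_cpp")]]
List decimate_cpp(const NumericMatrix& Vin, const IntegerMatrix& Fin,
                  int target_faces) {
  const int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int v = 0; v < nv; ++v) { X[v]=Vin(v,0); Y[v]=Vin(v,1); Z[v]=Vin(v,2); }
  std::vector<std::array<int,3>> F(nf);
  std::vector<bool> fdead(nf, false), vdead(nv, false);
  std::vector<std::set<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f) {
    F[f] = {Fin(f,0)-1, Fin(f,1)-1, Fin(f,2)-1};
    for (int c = 0; c < 3; ++c) vfaces[F[f][c]].insert(f);
  }
  std::vector<Quadric> Q(nv);
  auto face_plane = [&](int f, double* pl) -> double {
    const auto& t = F[f];
    double ux=X[t[1]]-X[t[0]], uy=Y[t[1]]-Y[t[0]], uz=Z[t[1]]-Z[t[0]];
    double wx=X[t[2]]-X[t[0]], wy=Y[t[2]]-Y[t[0]], wz=Z[t[2]]-Z[t[0]];
    double nxv=uy*wz-uz*wy, nyv=uz*wx-ux*wz, nzv=ux*wy-uy*wx;
    double len = std::sqrt(nxv*nxv+nyv*nyv+nzv*nzv);
    if (len < 1e-300) { pl[0]=pl[1]=pl[2]=pl[3]=0; return 0; }
    pl[0]=nxv/len; pl[1]=nyv/len; pl[2]=nzv/len;
    pl[3] = -(pl[0]*X[t[0]] + pl[1]*Y[t[0]] + pl[2]*Z[t[0]]);
    return 0.5 * len;
  };
  for (int f = 0; f < nf; ++f) {
    double pl[4];
    double area = face_plane(f, pl);
    for (int c = 0; c < 3; ++c) Q[F[f][c]].add_plane(pl[0],pl[1],pl[2],pl[3], area);
  }
  std::vector<uint64_t> vstamp(nv, 0);
  std::priority_queue<HeapItem> heap;
  auto edge_cost = [&](int a, int b, double& px, double& py, double& pz) {
    Quadric q = Q[a]; q.add(Q[b]);
    double x, y, z;
    if (q.optimal(x, y, z)) { px=x; py=y; pz=z; return q.eval(x,y,z); }
    double mx=(X[a]+X[b])/2, my=(Y[a]+Y[b])/2, mz=(Z[a]+Z[b])/2;
    double cm = q.eval(mx,my,mz), ca = q.eval(X[a],Y[a],Z[a]),
           cb = q.eval(X[b],Y[b],Z[b]);
    if (cm <= ca && cm <= cb) { px=mx; py=my; pz=mz; return cm; }
    if (ca <= cb) { px=X[a]; py=Y[a]; pz=Z[a]; return ca; }
    px=X[b]; py=Y[b]; pz=Z[b]; return cb;
  };
  auto push_vertex_edges = [&](int v) {
    std::set<int> nbrs;
    for (int f : vfaces[v])
      for (int c = 0; c < 3; ++c)
        if (F[f][c] != v) nbrs.insert(F[f][c]);
    for (int u : nbrs) {
      if (u < v) continue;
      double px, py, pz;
      double cst = edge_cost(v, u, px, py, pz);
      heap.push({cst, v, u, vstamp[v] + (vstamp[u] << 20)});
    }
  };
  for (int v = 0; v < nv; ++v) push_vertex_edges(v);

  int alive_faces = nf;
  auto neighbors = [&](int v) {
    std::set<int> nbrs;
    for (int f : vfaces[v])
      for (int c = 0; c < 3; ++c)
        if (F[f][c] != v) nbrs.insert(F[f][c]);
    return nbrs;
  };

  while (alive_faces > target_faces && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int a = it.v1, b = it.v2;
    if (vdead[a] || vdead[b]) continue;
    if (it.stamp != vstamp[a] + (vstamp[b] << 20)) continue;
    // must currently be an edge
    std::vector<int> shared;
    for (int f : vfaces[a]) if (vfaces[b].count(f)) shared.push_back(f);
    if (shared.size() != 2) continue;
    // link condition: common neighbours must be exactly the two apexes
    std::set<int> na = neighbors(a), nb = neighbors(b), common;
    for (int u : na) if (nb.count(u)) common.insert(u);
    if (common.size() != 2) continue;
    double px, py, pz;
    edge_cost(a, b, px, py, pz);
    // normal-flip guard
    bool flip = false;
    double ox = X[a], oy = Y[a], oz = Z[a];
    double obx = X[b], oby = Y[b], obz = Z[b];
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int v = pass == 0 ? a : b;
      for (int f : vfaces[v]) {
        if (fdead[f]) continue;
        bool is_shared = false;
        for (int s : shared) if (s == f) is_shared = true;
        if (is_shared) continue;
        double pl[4];
        face_plane(f, pl);
        X[a]=px; Y[a]=py; Z[a]=pz; X[b]=px; Y[b]=py; Z[b]=pz;
        double pl2[4];
        double area2 = face_plane(f, pl2);
        X[a]=ox; Y[a]=oy; Z[a]=oz; X[b]=obx; Y[b]=oby; Z[b]=obz;
        (void)area2;
        if (pl[0]*pl2[0]+pl[1]*pl2[1]+pl[2]*pl2[2] < 0.2) { flip = true; break; }
      }
    }
    if (flip) continue;
    // perform collapse b -> a at (px,py,pz)
    X[a]=px; Y[a]=py; Z[a]=pz;
    Q[a].add(Q[b]);
    for (int f : shared) {
      if (fdead[f]) continue;
      fdead[f] = true; --alive_faces;
      for (int c = 0; c < 3; ++c) vfaces[F[f][c]].erase(f);
    }
    std::vector<int> bf(vfaces[b].begin(), vfaces[b].end());
    for (int f : bf) {
      if (fdead[f]) continue;
      for (int c = 0; c < 3; ++c) if (F[f][c] == b) F[f][c] = a;
      vfaces[b].erase(f);
      vfaces[a].insert(f);
    }
    vdead[b] = true;
    ++vstamp[a];
    push_vertex_edges(a);
    for (int u : neighbors(a)) { ++vstamp[u]; push_vertex_edges(u); }
    if ((alive_faces & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int v = 0; v < nv; ++v) if (!vdead[v]) vmap[v] = nvo++;
  NumericMatrix Vout(nvo, 3);
  for (int v = 0; v < nv; ++v) if (!vdead[v]) {
    Vout(vmap[v],0)=X[v]; Vout(vmap[v],1)=Y[v]; Vout(vmap[v],2)=Z[v];
  }
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (!fdead[f]) ++nfo;
  IntegerMatrix Fout(nfo, 3);
  int fi = 0;
  for (int f = 0; f < nf; ++f) if (!fdead[f]) {
    for (int c = 0; c < 3; ++c) Fout(fi, c) = vmap[F[f][c]] + 1;
    ++fi;
  }
  return List::create(Named("vertices") = Vout, Named("triangles") = Fout);
}
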