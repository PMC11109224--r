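#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// Iso-surface extraction by marching tetrahedra on a regular grid.
// Each grid cube is split into the six Kuhn tetrahedra (the six vertex
// orderings compatible with the main diagonal); this decomposition is
// face-consistent across neighbouring cubes, so the extracted surface is
// watertight by construction. Triangle vertices lie on tetrahedron edges and
// are deduplicated through a global edge key, and each triangle is oriented
// so its normal points from the high-value (interior) side to the low side.

using namespace Rcpp;

static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double *chi;
  int n1, n2, n3;
  double iso;

  double val(int64_t idx) const { return chi[idx]; }

  void coords(int64_t idx, double *p) const {
    p[0] = (double)(idx % n1);
    p[1] = (double)((idx / n1) % n2);
    p[2] = (double)(idx / ((int64_t)n1 * n2));
  }

  int edge_point(int64_t a, int64_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)(n1 * (int64_t)n2 * n3) + (uint64_t)b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val(a), vb = val(b);
    double t = (iso - va) / (vb - va);
    double pa[3], pb[3];
    coords(a, pa); coords(b, pb);
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)vx.size();  // 1-based
    edge_vertex.emplace(key, id);
    return id;
  }

  // orient triangle (i0,i1,i2) so its normal points away from `inside`
  void emit(int i0, int i1, int i2, const double *inside) {
    double a[3] = {vx[i0 - 1], vy[i0 - 1], vz[i0 - 1]};
    double b[3] = {vx[i1 - 1], vy[i1 - 1], vz[i1 - 1]};
    double c[3] = {vx[i2 - 1], vy[i2 - 1], vz[i2 - 1]};
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nrm[3] = {u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    double ctr[3] = {(a[0] + b[0] + c[0]) / 3 - inside[0],
                     (a[1] + b[1] + c[1]) / 3 - inside[1],
                     (a[2] + b[2] + c[2]) / 3 - inside[2]};
    double d = nrm[0] * ctr[0] + nrm[1] * ctr[1] + nrm[2] * ctr[2];
    if (d < 0) std::swap(i1, i2);
    tri.push_back(i0); tri.push_back(i1); tri.push_back(i2);
  }

  void do_tet(const int64_t *node) {
    bool in[4];
    int nin = 0;
    for (int m = 0; m < 4; ++m) {
      in[m] = val(node[m]) > iso;
      if (in[m]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    double ic[3] = {0, 0, 0};
    double p[3];
    for (int m = 0; m < 4; ++m) {
      if (in[m]) {
        coords(node[m], p);
        ic[0] += p[0]; ic[1] += p[1]; ic[2] += p[2];
      }
    }
    ic[0] /= nin; ic[1] /= nin; ic[2] /= nin;
    if (nin == 1 || nin == 3) {
      int apex = -1;
      for (int m = 0; m < 4; ++m)
        if (in[m] == (nin == 1)) apex = m;
      int e[3], k = 0;
      for (int m = 0; m < 4; ++m)
        if (m != apex) e[k++] = edge_point(node[apex], node[m]);
      emit(e[0], e[1], e[2], ic);
    } else {  // nin == 2: quad split into two triangles
      int a = -1, b = -1, c = -1, d = -1;
      for (int m = 0; m < 4; ++m) {
        if (in[m]) { if (a < 0) a = m; else b = m; }
        else       { if (c < 0) c = m; else d = m; }
      }
      int eac = edge_point(node[a], node[c]);
      int ead = edge_point(node[a], node[d]);
      int ebc = edge_point(node[b], node[c]);
      int ebd = edge_point(node[b], node[d]);
      emit(eac, ead, ebd, ic);
      emit(eac, ebd, ebc, ic);
    }
  }
};

// [[Rcpp::export]]
List marching_tets(NumericVector chi, double iso) {
  IntegerVector dims = chi.attr("dim");
  if (dims.size() != 3) stop("chi must be a 3D array");
  MTState st;
  st.chi = REAL(chi);
  st.n1 = dims[0]; st.n2 = dims[1]; st.n3 = dims[2];
  st.iso = iso;
  const int64_t sx = 1, sy = st.n1, sz = (int64_t)st.n1 * st.n2;
  const int64_t step[3] = {sx, sy, sz};

  for (int k = 0; k < st.n3 - 1; ++k) {
    for (int j = 0; j < st.n2 - 1; ++j) {
      int64_t base0 = (int64_t)j * sy + (int64_t)k * sz;
      for (int i = 0; i < st.n1 - 1; ++i) {
        int64_t c0 = base0 + i;
        // quick reject: all eight corners on one side
        bool any_in = false, any_out = false;
        for (int dz = 0; dz < 2 && !(any_in && any_out); ++dz)
          for (int dy = 0; dy < 2 && !(any_in && any_out); ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double v = st.val(c0 + dx * sx + dy * sy + dz * sz);
              if (v > iso) any_in = true; else any_out = true;
            }
        if (!(any_in && any_out)) continue;
        for (int tpi = 0; tpi < 6; ++tpi) {
          int64_t node[4];
          node[0] = c0;
          node[1] = node[0] + step[PERMS[tpi][0]];
          node[2] = node[1] + step[PERMS[tpi][1]];
          node[3] = node[2] + step[PERMS[tpi][2]];
          st.do_tet(node);
        }
      }
    }
  }

  int nv = (int)st.vx.size();
  NumericMatrix verts(nv, 3);
  for (int m = 0; m < nv; ++m) {
    verts(m, 0) = st.vx[m];
    verts(m, 1) = st.vy[m];
    verts(m, 2) = st.vz[m];
  }
  int nf = (int)st.tri.size() / 3;
  IntegerMatrix faces(nf, 3);
  for (int m = 0; m < nf; ++m) {
    faces(m, 0) = st.tri[3 * m];
    faces(m, 1) = st.tri[3 * m + 1];
    faces(m, 2) = st.tri[3 * m + 2];
  }
  return List::create(Named("vertices") = verts, Named("faces") = faces);
}
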