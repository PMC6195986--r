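#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Volumes follow the package's (z, y, x) axis contract: an R array with
// dim = c(nz, ny, nx), linear index iz + nz*(iy + ny*ix) (0-based).
// Mesh vertices are world-mm (x, y, z) rows.

namespace {

struct MeshAccum {
  // weld vertices by the lattice edge they sit on
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  int vertex_on_edge(uint64_t ga, uint64_t gb, double t,
                     const std::vector<double>& px,
                     const std::vector<double>& py,
                     const std::vector<double>& pz,
                     int ia, int ib) {
    uint64_t key;
    if (ga < gb) key = (ga << 32) | gb; else { key = (gb << 32) | ga; t = 1.0 - t; std::swap(ia, ib); }
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    int id = (int)vx.size();
    vx.push_back(px[ia] + t * (px[ib] - px[ia]));
    vy.push_back(py[ia] + t * (py[ib] - py[ia]));
    vz.push_back(pz[ia] + t * (pz[ib] - pz[ia]));
    edge_vertex.emplace(key, id);
    return id;
  }

  void triangle(int a, int b, int c,
                double rx, double ry, double rz, bool toward) {
    // orient so the normal points toward (toward=true) or away from the
    // reference point r (a point strictly on the outside of the solid when
    // toward=true)
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    double dx = rx - vx[a], dy = ry - vy[a], dz = rz - vz[a];
    double d = nx * dx + ny * dy + nz * dz;
    bool flip = toward ? (d < 0) : (d > 0);
    if (flip) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
};

// 6-tet decomposition of the cube around the 0-7 diagonal; corner bit
// layout b0 = +x, b1 = +y, b2 = +z. Face diagonals are translation
// consistent, so the global surface is watertight.
const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

} // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dim,
                       double iso, NumericVector spacing, NumericVector origin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double oz = origin[0], oy = origin[1], ox = origin[2];
  MeshAccum M;

  std::vector<uint64_t> gid(8);
  std::vector<double> px(8), py(8), pz(8), val(8);

  for (int ix = 0; ix + 1 < nx; ++ix) {
    for (int iy = 0; iy + 1 < ny; ++iy) {
      for (int iz = 0; iz + 1 < nz; ++iz) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int dxc = c & 1, dyc = (c >> 1) & 1, dzc = (c >> 2) & 1;
          int jz = iz + dzc, jy = iy + dyc, jx = ix + dxc;
          uint64_t g = (uint64_t)jz + (uint64_t)nz * ((uint64_t)jy + (uint64_t)ny * (uint64_t)jx);
          gid[c] = g;
          val[c] = values[(R_xlen_t)g];
          px[c] = ox + jx * sx;
          py[c] = oy + jy * sy;
          pz[c] = oz + jz * sz;
          if (val[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = TETS[t][0], b = TETS[t][1], c = TETS[t][2], d = TETS[t][3];
          int corner[4] = {a, b, c, d};
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[corner[k]] >= iso) in[nin++] = corner[k];
            else out[nout++] = corner[k];
          }
          if (nin == 0 || nin == 4) continue;
          auto cross_v = [&](int A, int B) {
            double tt = (iso - val[A]) / (val[B] - val[A]);
            if (tt < 0) tt = 0; if (tt > 1) tt = 1;
            return M.vertex_on_edge(gid[A], gid[B], tt, px, py, pz, A, B);
          };
          if (nin == 1) {
            int A = in[0];
            int q1 = cross_v(A, out[0]);
            int q2 = cross_v(A, out[1]);
            int q3 = cross_v(A, out[2]);
            // outward normal points away from the interior vertex A
            M.triangle(q1, q2, q3, px[A], py[A], pz[A], false);
          } else if (nin == 3) {
            int D = out[0];
            int q1 = cross_v(D, in[0]);
            int q2 = cross_v(D, in[1]);
            int q3 = cross_v(D, in[2]);
            M.triangle(q1, q2, q3, px[D], py[D], pz[D], true);
          } else { // 2 in, 2 out -> quad
            int A = in[0], B = in[1], C = out[0], D = out[1];
            int qAC = cross_v(A, C), qAD = cross_v(A, D);
            int qBD = cross_v(B, D), qBC = cross_v(B, C);
            double rx = 0.5 * (px[C] + px[D]) + (0.5 * (px[C] + px[D]) - 0.5 * (px[A] + px[B]));
            double ry = 0.5 * (py[C] + py[D]) + (0.5 * (py[C] + py[D]) - 0.5 * (py[A] + py[B]));
            double rz = 0.5 * (pz[C] + pz[D]) + (0.5 * (pz[C] + pz[D]) - 0.5 * (pz[A] + pz[B]));
            M.triangle(qAC, qAD, qBD, rx, ry, rz, true);
            M.triangle(qAC, qBD, qBC, rx, ry, rz, true);
          }
        }
      }
    }
  }

  int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; V(i, 2) = M.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = M.f0[i] + 1; F(i, 1) = M.f1[i] + 1; F(i, 2) = M.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                int iterations, double lambda, double mu) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> nbr(nv);
  auto add_edge = [&](int a, int b) {
    nbr[a].push_back(b); nbr[b].push_back(a);
  };
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    add_edge(a, b); add_edge(b, c); add_edge(c, a);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  std::vector<double> X(nv), Y(nv), Z(nv), X2(nv), Y2(nv), Z2(nv);
  for (int i = 0; i < nv; ++i) { X[i] = V(i, 0); Y[i] = V(i, 1); Z[i] = V(i, 2); }
  auto pass = [&](double w) {
    for (int i = 0; i < nv; ++i) {
      size_t k = nbr[i].size();
      if (k == 0) { X2[i] = X[i]; Y2[i] = Y[i]; Z2[i] = Z[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j : nbr[i]) { mx += X[j]; my += Y[j]; mz += Z[j]; }
      mx /= k; my /= k; mz /= k;
      X2[i] = X[i] + w * (mx - X[i]);
      Y2[i] = Y[i] + w * (my - Y[i]);
      Z2[i] = Z[i] + w * (mz - Z[i]);
    }
    X.swap(X2); Y.swap(Y2); Z.swap(Z2);
  };
  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) { out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i]; }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> offz, offy, offx;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  int nnb = (int)offz.size();
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int iy = (int)(rest % ny);
      int ix = (int)(rest / ny);
      for (int k = 0; k < nnb; ++k) {
        int jz = iz + offz[k], jy = iy + offy[k], jx = ix + offx[k];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        R_xlen_t j = (R_xlen_t)jz + (R_xlen_t)nz * ((R_xlen_t)jy + (R_xlen_t)ny * jx);
        if (mask[j] && labels[j] == 0) { labels[j] = next_label; stack.push_back(j); }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nvert) {
  int nf = F.nrow();
  // map undirected edge -> incident faces
  std::unordered_map<uint64_t, std::vector<int>> edge_faces;
  edge_faces.reserve((size_t)nf * 2);
  auto key = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return ((uint64_t)a << 32) | (uint64_t)b;
  };
  for (int i = 0; i < nf; ++i) {
    int v[3] = {F(i, 0), F(i, 1), F(i, 2)};
    edge_faces[key(v[0], v[1])].push_back(i);
    edge_faces[key(v[1], v[2])].push_back(i);
    edge_faces[key(v[2], v[0])].push_back(i);
  }
  IntegerVector comp(nf, 0);
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < nf; ++s) {
    if (comp[s] != 0) continue;
    ++next; comp[s] = next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int v[3] = {F(cur, 0), F(cur, 1), F(cur, 2)};
      for (int e = 0; e < 3; ++e) {
        auto& fl = edge_faces[key(v[e], v[(e + 1) % 3])];
        for (int f : fl) if (comp[f] == 0) { comp[f] = next; stack.push_back(f); }
      }
    }
  }
  comp.attr("n_components") = next;
  return comp;
}

// [[Rcpp::export]]
IntegerMatrix cpp_boundary_edges(IntegerMatrix F) {
  // directed edges that have no opposite partner (consistent winding assumed)
  int nf = F.nrow();
  std::unordered_map<uint64_t, int> count; // undirected use count
  auto ukey = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return ((uint64_t)a << 32) | (uint64_t)b;
  };
  for (int i = 0; i < nf; ++i) {
    int v[3] = {F(i, 0), F(i, 1), F(i, 2)};
    for (int e = 0; e < 3; ++e) count[ukey(v[e], v[(e + 1) % 3])]++;
  }
  std::vector<int> ea, eb;
  for (int i = 0; i < nf; ++i) {
    int v[3] = {F(i, 0), F(i, 1), F(i, 2)};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      if (count[ukey(a, b)] == 1) { ea.push_back(a); eb.push_back(b); }
    }
  }
  IntegerMatrix out((int)ea.size(), 2);
  for (size_t i = 0; i < ea.size(); ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}
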