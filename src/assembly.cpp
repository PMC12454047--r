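// Element assembly for the mixed Taylor-Hood (P2 velocity / P1 pressure)
// discretisation of incompressible Stokes / Navier-Stokes flow on
// tetrahedral meshes.  Returns COO triplets; sparse matrices are built on
// the R side with Matrix::sparseMatrix.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// local edge numbering of a tetrahedron
static const int EDGE[6][2] = {{0, 1}, {0, 2}, {0, 3},
                               {1, 2}, {1, 3}, {2, 3}};

// ---------------------------------------------------------------------------
// Grundmann-Moller degree-5 quadrature on the reference tetrahedron
// (15 points; weights sum to 1/6, the reference volume).

struct Quadrature {
  std::vector<std::array<double, 4>> lam;
  std::vector<double> w;
};

static Quadrature gm5() {
  Quadrature q;
  const int n = 3, s = 2, d = 2 * s + 1;
  double fact[12];
  fact[0] = 1.0;
  for (int i = 1; i < 12; ++i) fact[i] = fact[i - 1] * i;
  for (int i = 0; i <= s; ++i) {
    double denom = d + n - 2 * i;
    double w = std::pow(2.0, -2.0 * s) * std::pow(denom, d) /
               (fact[i] * fact[d + n - i]);
    if (i % 2 == 1) w = -w;
    // all multi-indices k >= 0 over 4 coordinates with |k| = s - i
    int rem = s - i;
    for (int k0 = 0; k0 <= rem; ++k0)
      for (int k1 = 0; k1 <= rem - k0; ++k1)
        for (int k2 = 0; k2 <= rem - k0 - k1; ++k2) {
          int k3 = rem - k0 - k1 - k2;
          std::array<double, 4> lam = {
            (2.0 * k0 + 1.0) / denom, (2.0 * k1 + 1.0) / denom,
            (2.0 * k2 + 1.0) / denom, (2.0 * k3 + 1.0) / denom};
          q.lam.push_back(lam);
          q.w.push_back(w);
        }
  }
  return q;
}

// [[Rcpp::export]]
List fem_quadrature_gm5() {
  Quadrature q = gm5();
  int m = q.w.size();
  NumericMatrix lam(m, 4);
  NumericVector w(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < 4; ++j) lam(i, j) = q.lam[i][j];
    w[i] = q.w[i];
  }
  return List::create(_["lambda"] = lam, _["w"] = w);
}

// ---------------------------------------------------------------------------
// unique edge extraction

// [[Rcpp::export]]
List fem_build_edges(IntegerMatrix tets) {
  int nt = tets.nrow();
  std::unordered_map<uint64_t, int> emap;
  emap.reserve(static_cast<size_t>(nt) * 3);
  std::vector<int> ea, eb;
  IntegerMatrix tet_edges(nt, 6);
  for (int t = 0; t < nt; ++t) {
    for (int e = 0; e < 6; ++e) {
      int a = tets(t, EDGE[e][0]), b = tets(t, EDGE[e][1]);
      int lo = a < b ? a : b, hi = a < b ? b : a;
      uint64_t key = (static_cast<uint64_t>(lo) << 32) |
                     static_cast<uint64_t>(hi);
      auto it = emap.find(key);
      int id;
      if (it == emap.end()) {
        id = ea.size();
        emap.emplace(key, id);
        ea.push_back(lo);
        eb.push_back(hi);
      } else {
        id = it->second;
      }
      tet_edges(t, e) = id + 1;  // 1-based
    }
  }
  int ne = ea.size();
  IntegerMatrix edges(ne, 2);
  for (int i = 0; i < ne; ++i) {
    edges(i, 0) = ea[i];
    edges(i, 1) = eb[i];
  }
  return List::create(_["edges"] = edges, _["tet_edges"] = tet_edges);
}

// ---------------------------------------------------------------------------
// shape function helpers (evaluated at one quadrature point)

static inline void p2_basis(const std::array<double, 4>& lam,
                            const double g[4][3], double N[10],
                            double dN[10][3]) {
  for (int i = 0; i < 4; ++i) {
    N[i] = lam[i] * (2.0 * lam[i] - 1.0);
    for (int d = 0; d < 3; ++d) dN[i][d] = (4.0 * lam[i] - 1.0) * g[i][d];
  }
  for (int e = 0; e < 6; ++e) {
    int a = EDGE[e][0], b = EDGE[e][1];
    N[4 + e] = 4.0 * lam[a] * lam[b];
    for (int d = 0; d < 3; ++d)
      dN[4 + e][d] = 4.0 * (lam[a] * g[b][d] + lam[b] * g[a][d]);
  }
}

static inline double jacobian(const NumericMatrix& verts,
                              const IntegerMatrix& tets, int t,
                              double g[4][3]) {
  double J[3][3];
  int v0 = tets(t, 0) - 1;
  for (int c = 0; c < 3; ++c) {
    int vc = tets(t, c + 1) - 1;
    for (int d = 0; d < 3; ++d) J[d][c] = verts(vc, d) - verts(v0, d);
  }
  double det =
      J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
      J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
      J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  double inv[3][3];
  double id = 1.0 / det;
  inv[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
  inv[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) * id;
  inv[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
  inv[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) * id;
  inv[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
  inv[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) * id;
  inv[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
  inv[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) * id;
  inv[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
  // gradients of barycentric coordinates: rows of inv for lam_1..3
  for (int d = 0; d < 3; ++d) {
    g[1][d] = inv[0][d];
    g[2][d] = inv[1][d];
    g[3][d] = inv[2][d];
    g[0][d] = -(inv[0][d] + inv[1][d] + inv[2][d]);
  }
  return det;  // 6 * tet volume (positive for positively oriented tets)
}

// ---------------------------------------------------------------------------
// Stokes operators: scalar P2 stiffness A, P1xP2 divergence blocks Bx,By,Bz,
// lumped P1 mass.

// [[Rcpp::export]]
List fem_assemble_stokes(NumericMatrix verts, IntegerMatrix tets,
                         IntegerMatrix tet_edges) {
  static Quadrature q = gm5();
  int nt = tets.nrow();
  int nv = verts.nrow();
  int nq = q.w.size();
  std::vector<int> ai, aj, bi, bj;
  std::vector<double> ax, bx, by, bz;
  ai.reserve(static_cast<size_t>(nt) * 55);
  ax.reserve(static_cast<size_t>(nt) * 55);
  bi.reserve(static_cast<size_t>(nt) * 40);
  NumericVector mp(nv);
  double g[4][3], N[10], dN[10][3];
  int dof[10];
  for (int t = 0; t < nt; ++t) {
    double det = jacobian(verts, tets, t, g);
    for (int i = 0; i < 4; ++i) dof[i] = tets(t, i);
    for (int e = 0; e < 6; ++e) dof[4 + e] = nv + tet_edges(t, e);
    double Ae[10][10] = {{0}};
    double Be[4][10][3] = {{{0}}};
    for (int iq = 0; iq < nq; ++iq) {
      p2_basis(q.lam[iq], g, N, dN);
      double wdet = q.w[iq] * det;
      for (int i = 0; i < 10; ++i)
        for (int j = i; j < 10; ++j) {
          double v = wdet * (dN[i][0] * dN[j][0] + dN[i][1] * dN[j][1] +
                             dN[i][2] * dN[j][2]);
          Ae[i][j] += v;
        }
      for (int k = 0; k < 4; ++k) {
        double lk = q.lam[iq][k] * wdet;
        for (int j = 0; j < 10; ++j)
          for (int d = 0; d < 3; ++d) Be[k][j][d] += lk * dN[j][d];
      }
    }
    for (int i = 0; i < 10; ++i)
      for (int j = i; j < 10; ++j) {
        ai.push_back(dof[i]);
        aj.push_back(dof[j]);
        ax.push_back(Ae[i][j]);
        if (j > i) {
          ai.push_back(dof[j]);
          aj.push_back(dof[i]);
          ax.push_back(Ae[i][j]);
        }
      }
    for (int k = 0; k < 4; ++k) {
      mp[dof[k] - 1] += det / 6.0 / 4.0;
      for (int j = 0; j < 10; ++j) {
        bi.push_back(dof[k]);
        bj.push_back(dof[j]);
        bx.push_back(Be[k][j][0]);
        by.push_back(Be[k][j][1]);
        bz.push_back(Be[k][j][2]);
      }
    }
  }
  return List::create(
      _["ai"] = wrap(ai), _["aj"] = wrap(aj), _["ax"] = wrap(ax),
      _["bi"] = wrap(bi), _["bj"] = wrap(bj), _["bx"] = wrap(bx),
      _["by"] = wrap(by), _["bz"] = wrap(bz), _["mp"] = mp);
}

// ---------------------------------------------------------------------------
// convection matrix C[i][j] = int N_i (w . grad N_j) for a given P2 velocity
// field w (n_s x 3, vertex dofs first then edge dofs)

// [[Rcpp::export]]
List fem_assemble_convection(NumericMatrix verts, IntegerMatrix tets,
                             IntegerMatrix tet_edges, NumericMatrix wfield) {
  static Quadrature q = gm5();
  int nt = tets.nrow();
  int nv = verts.nrow();
  int nq = q.w.size();
  std::vector<int> ci, cj;
  std::vector<double> cx;
  ci.reserve(static_cast<size_t>(nt) * 100);
  double g[4][3], N[10], dN[10][3];
  int dof[10];
  for (int t = 0; t < nt; ++t) {
    double det = jacobian(verts, tets, t, g);
    for (int i = 0; i < 4; ++i) dof[i] = tets(t, i);
    for (int e = 0; e < 6; ++e) dof[4 + e] = nv + tet_edges(t, e);
    double Ce[10][10] = {{0}};
    for (int iq = 0; iq < nq; ++iq) {
      p2_basis(q.lam[iq], g, N, dN);
      double wdet = q.w[iq] * det;
      double wq[3] = {0, 0, 0};
      for (int l = 0; l < 10; ++l) {
        int dl = dof[l] - 1;
        wq[0] += wfield(dl, 0) * N[l];
        wq[1] += wfield(dl, 1) * N[l];
        wq[2] += wfield(dl, 2) * N[l];
      }
      for (int j = 0; j < 10; ++j) {
        double adv = wq[0] * dN[j][0] + wq[1] * dN[j][1] + wq[2] * dN[j][2];
        double s = wdet * adv;
        for (int i = 0; i < 10; ++i) Ce[i][j] += s * N[i];
      }
    }
    for (int i = 0; i < 10; ++i)
      for (int j = 0; j < 10; ++j) {
        ci.push_back(dof[i]);
        cj.push_back(dof[j]);
        cx.push_back(Ce[i][j]);
      }
  }
  return List::create(_["ci"] = wrap(ci), _["cj"] = wrap(cj),
                      _["cx"] = wrap(cx));
}
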