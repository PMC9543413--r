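// Compiled core: RC-graph evaluation and reverse-mode force propagation,
// tensor-product cubic B-spline evaluation on free-energy grids, the toy
// MD engine (flexible TIP3P-style water dimer + analytic particles), and
// the biased replica run loop. All hot paths live here; the R layer owns
// validation, bookkeeping and analysis.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TO_DEG = 57.29577951308232;
static const double TO_RAD = 0.017453292519943295;
static const double KB      = 0.0019872041;   // kcal/mol/K
static const double TIMEFAC = 48.88821;       // fs per internal (AKMA) time unit
static const double DEGEN_EPS = 1e-8;         // vector-norm threshold for degenerate geometry

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------------------
// RC graph: node-table representation
//   kind codes: 0 atom_point, 1 center_of_mass, 2 vector, 3 cross_vector,
//               4 distance, 5 angle, 6 dihedral
//   dihedral conv codes: 0 arccos [0,180], 1 signed (-180,180], 2 signed [0,360)
// ---------------------------------------------------------------------------
struct Graph {
  int n;
  std::vector<int> kind;
  std::vector<std::vector<int> > parents;   // 0-based node ids, topological order
  std::vector<int> atom;                    // 0-based atom index (atom_point) or -1
  std::vector<std::vector<double> > weights;
  std::vector<int> conv;                    // dihedral convention per node
  std::vector<int> axis;                    // 0-based shared-axis node id (dihedral) or -1
  std::vector<int> rc;                      // 0-based ids of RC nodes
};

static Graph graph_from_list(List g) {
  Graph gr;
  IntegerVector kind = g["kind"];
  List par = g["parents"];
  IntegerVector atom = g["atom_index"];
  List wts = g["weights"];
  IntegerVector conv = g["conv"];
  IntegerVector axis = g["axis"];
  IntegerVector rc = g["rc_ids"];
  gr.n = kind.size();
  gr.kind.assign(kind.begin(), kind.end());
  gr.parents.resize(gr.n);
  gr.weights.resize(gr.n);
  gr.atom.resize(gr.n);
  gr.conv.assign(conv.begin(), conv.end());
  gr.axis.resize(gr.n);
  for (int i = 0; i < gr.n; ++i) {
    IntegerVector p = par[i];
    for (int j = 0; j < p.size(); ++j) gr.parents[i].push_back(p[j] - 1);
    gr.atom[i] = (atom[i] == NA_INTEGER) ? -1 : atom[i] - 1;
    gr.axis[i] = (axis[i] == NA_INTEGER || axis[i] == 0) ? -1 : axis[i] - 1;
    if (gr.kind[i] == 1) {
      NumericVector w = wts[i];
      gr.weights[i].assign(w.begin(), w.end());
    }
  }
  for (int j = 0; j < rc.size(); ++j) gr.rc.push_back(rc[j] - 1);
  return gr;
}

struct GraphWork {
  std::vector<V3> val;      // value per node (scalar nodes use .x)
  std::vector<double> sval; // scalar value (external units: Angstrom / degrees)
  std::vector<V3> adj;      // reverse-pass adjoints (vector nodes)
};

// forward pass: positions is length-3N (x1,y1,z1,...)
static int graph_forward(const Graph& g, const double* pos, GraphWork& w) {
  int ndegen = 0;
  w.val.assign(g.n, v3(0, 0, 0));
  w.sval.assign(g.n, 0.0);
  for (int i = 0; i < g.n; ++i) {
    switch (g.kind[i]) {
    case 0: { // atom_point
      int a = g.atom[i];
      w.val[i] = v3(pos[3 * a], pos[3 * a + 1], pos[3 * a + 2]);
      break; }
    case 1: { // center_of_mass
      V3 c = v3(0, 0, 0);
      for (size_t j = 0; j < g.parents[i].size(); ++j)
        c = c + g.weights[i][j] * w.val[g.parents[i][j]];
      w.val[i] = c;
      break; }
    case 2: // vector: head - tail, parents (tail, head)
      w.val[i] = w.val[g.parents[i][1]] - w.val[g.parents[i][0]];
      break;
    case 3: // cross_vector: a x b
      w.val[i] = cross(w.val[g.parents[i][0]], w.val[g.parents[i][1]]);
      break;
    case 4: { // distance between point-like parents (p, q)
      V3 d = w.val[g.parents[i][1]] - w.val[g.parents[i][0]];
      w.sval[i] = norm3(d);
      break; }
    case 5: { // angle between vector parents, degrees
      V3 u = w.val[g.parents[i][0]], v = w.val[g.parents[i][1]];
      double nu = norm3(u), nv = norm3(v);
      if (nu < DEGEN_EPS || nv < DEGEN_EPS) { w.sval[i] = NA_REAL; ++ndegen; break; }
      double c = dot(u, v) / (nu * nv);
      c = std::max(-1.0, std::min(1.0, c));
      w.sval[i] = std::acos(c) * TO_DEG;
      break; }
    case 6: { // dihedral between cross-vector parents (m, n), degrees
      V3 m = w.val[g.parents[i][0]], n = w.val[g.parents[i][1]];
      double nm = norm3(m), nn = norm3(n);
      if (nm < DEGEN_EPS || nn < DEGEN_EPS) { w.sval[i] = NA_REAL; ++ndegen; break; }
      if (g.conv[i] == 0) {
        double c = dot(m, n) / (nm * nn);
        c = std::max(-1.0, std::min(1.0, c));
        w.sval[i] = std::acos(c) * TO_DEG;
      } else {
        V3 ax = w.val[g.axis[i]];
        double na = norm3(ax);
        if (na < DEGEN_EPS) { w.sval[i] = NA_REAL; ++ndegen; break; }
        V3 rh = (1.0 / na) * ax;
        double S = dot(cross(m, n), rh);
        double C = dot(m, n);
        double phi = std::atan2(S, C) * TO_DEG;
        if (g.conv[i] == 2 && phi < 0) phi += 360.0;
        w.sval[i] = phi;
      }
      break; }
    }
  }
  return ndegen;
}

// reverse pass: seeds are dL/d(xi_i) in external units (per Angstrom / per
// degree); accumulates grad[3N] = sum_i seed_i * d(xi_i)/dx. Degenerate
// geometries contribute zero (counted).
static int graph_reverse(const Graph& g, const GraphWork& w, const double* seeds,
                         double* grad, int natoms) {
  int ndegen = 0;
  std::vector<V3> adj(g.n, v3(0, 0, 0));
  // seed scalar RC nodes: push directly to their (vector/point) parents
  for (size_t k = 0; k < g.rc.size(); ++k) {
    int i = g.rc[k];
    double s = seeds[k];
    if (s == 0.0) continue;
    switch (g.kind[i]) {
    case 4: { // distance
      int p = g.parents[i][0], q = g.parents[i][1];
      V3 d = w.val[q] - w.val[p];
      double r = norm3(d);
      if (r < DEGEN_EPS) { ++ndegen; break; }
      V3 u = (1.0 / r) * d;
      adj[q] = adj[q] + s * u;
      adj[p] = adj[p] - s * u;
      break; }
    case 5: { // angle (degrees): d(theta)/du = -(vhat - cos*uhat)/(|u| sin) * TO_DEG
      int pu = g.parents[i][0], pv = g.parents[i][1];
      V3 u = w.val[pu], v = w.val[pv];
      double nu = norm3(u), nv = norm3(v);
      if (nu < DEGEN_EPS || nv < DEGEN_EPS) { ++ndegen; break; }
      V3 uh = (1.0 / nu) * u, vh = (1.0 / nv) * v;
      double c = std::max(-1.0, std::min(1.0, dot(uh, vh)));
      double sn = std::sqrt(std::max(0.0, 1.0 - c * c));
      if (sn < DEGEN_EPS) { ++ndegen; break; }
      double fu = -s * TO_DEG / (nu * sn), fv = -s * TO_DEG / (nv * sn);
      adj[pu] = adj[pu] + fu * (vh - c * uh);
      adj[pv] = adj[pv] + fv * (uh - c * vh);
      break; }
    case 6: { // dihedral (degrees)
      int pm = g.parents[i][0], pn = g.parents[i][1];
      V3 m = w.val[pm], n = w.val[pn];
      double nm = norm3(m), nn = norm3(n);
      if (nm < DEGEN_EPS || nn < DEGEN_EPS) { ++ndegen; break; }
      if (g.conv[i] == 0) { // arccos form: angle rule on (m, n)
        V3 mh = (1.0 / nm) * m, nh = (1.0 / nn) * n;
        double c = std::max(-1.0, std::min(1.0, dot(mh, nh)));
        double sn = std::sqrt(std::max(0.0, 1.0 - c * c));
        if (sn < DEGEN_EPS) { ++ndegen; break; }
        double fm = -s * TO_DEG / (nm * sn), fn = -s * TO_DEG / (nn * sn);
        adj[pm] = adj[pm] + fm * (nh - c * mh);
        adj[pn] = adj[pn] + fn * (mh - c * nh);
      } else { // signed atan2 form; m x n is parallel to the shared axis,
               // so the explicit axis partial vanishes
        V3 ax = w.val[g.axis[i]];
        double na = norm3(ax);
        if (na < DEGEN_EPS) { ++ndegen; break; }
        V3 rh = (1.0 / na) * ax;
        double S = dot(cross(m, n), rh);
        double C = dot(m, n);
        double Q = S * S + C * C;
        if (Q < DEGEN_EPS * DEGEN_EPS) { ++ndegen; break; }
        double f = s * TO_DEG / Q;
        // dphi/dm = [C (n x rh) - S n]/Q ; dphi/dn = [C (rh x m) - S m]/Q
        adj[pm] = adj[pm] + f * (C * cross(n, rh) - S * n);
        adj[pn] = adj[pn] + f * (C * cross(rh, m) - S * m);
      }
      break; }
    }
  }
  // flow vector adjoints down to atoms (reverse topological order)
  for (int i = g.n - 1; i >= 0; --i) {
    V3 a = adj[i];
    if (a.x == 0 && a.y == 0 && a.z == 0 && g.kind[i] != 0) continue;
    switch (g.kind[i]) {
    case 0: { // atom_point: accumulate gradient
      int at = g.atom[i];
      grad[3 * at] += a.x; grad[3 * at + 1] += a.y; grad[3 * at + 2] += a.z;
      break; }
    case 1:
      for (size_t j = 0; j < g.parents[i].size(); ++j)
        adj[g.parents[i][j]] = adj[g.parents[i][j]] + g.weights[i][j] * a;
      break;
    case 2:
      adj[g.parents[i][1]] = adj[g.parents[i][1]] + a;
      adj[g.parents[i][0]] = adj[g.parents[i][0]] - a;
      break;
    case 3: { // c = va x vb: dL/dva = vb x adj, dL/dvb = adj x va
      V3 va = w.val[g.parents[i][0]], vb = w.val[g.parents[i][1]];
      adj[g.parents[i][0]] = adj[g.parents[i][0]] + cross(vb, a);
      adj[g.parents[i][1]] = adj[g.parents[i][1]] + cross(a, va);
      break; }
    default: break;
    }
  }
  (void)natoms;
  return ndegen;
}

// [[Rcpp::export]]
List graph_eval_cpp(List graph, NumericVector positions) {
  Graph g = graph_from_list(graph);
  GraphWork w;
  int ndegen = graph_forward(g, positions.begin(), w);
  NumericVector values(g.rc.size());
  for (size_t k = 0; k < g.rc.size(); ++k) values[k] = w.sval[g.rc[k]];
  NumericVector node_scalar(g.n);
  NumericMatrix node_vec(g.n, 3);
  for (int i = 0; i < g.n; ++i) {
    node_scalar[i] = w.sval[i];
    node_vec(i, 0) = w.val[i].x; node_vec(i, 1) = w.val[i].y; node_vec(i, 2) = w.val[i].z;
  }
  return List::create(_["values"] = values, _["n_degenerate"] = ndegen,
                      _["node_scalar"] = node_scalar, _["node_vec"] = node_vec);
}

// [[Rcpp::export]]
List graph_gradient_cpp(List graph, NumericVector positions, NumericVector seeds) {
  Graph g = graph_from_list(graph);
  GraphWork w;
  int nd1 = graph_forward(g, positions.begin(), w);
  int natoms = positions.size() / 3;
  NumericVector grad(positions.size());
  int nd2 = graph_reverse(g, w, seeds.begin(), grad.begin(), natoms);
  return List::create(_["grad"] = grad, _["n_degenerate"] = nd1 + nd2);
}

// Jacobian d(xi)/dx as a d x 3N matrix (external units)
// [[Rcpp::export]]
NumericMatrix graph_jacobian_cpp(List graph, NumericVector positions) {
  Graph g = graph_from_list(graph);
  GraphWork w;
  graph_forward(g, positions.begin(), w);
  int natoms = positions.size() / 3;
  int d = g.rc.size();
  NumericMatrix J(d, positions.size());
  std::vector<double> seeds(d, 0.0), grad(positions.size());
  for (int k = 0; k < d; ++k) {
    std::fill(seeds.begin(), seeds.end(), 0.0);
    std::fill(grad.begin(), grad.end(), 0.0);
    seeds[k] = 1.0;
    graph_reverse(g, w, &seeds[0], &grad[0], natoms);
    for (int j = 0; j < (int)positions.size(); ++j) J(k, j) = grad[j];
  }
  return J;
}

// ---------------------------------------------------------------------------
// tensor-product cubic B-spline over grid bin centers
//   coefficients solved in R (one banded/cyclic solve per dimension);
//   evaluation here. Non-periodic dims use natural-end ghost coefficients
//   (linear extrapolation of the coefficient sequence); periodic dims wrap.
// ---------------------------------------------------------------------------
struct GridSpec {
  int d;
  std::vector<double> lo, hi, h;  // h = bin width
  std::vector<int> nb;
  std::vector<int> periodic;
  std::vector<int> stride;        // column-major strides
};

static GridSpec grid_from_list(List spec) {
  GridSpec gs;
  NumericVector lo = spec["min"], hi = spec["max"];
  IntegerVector nb = spec["n_bins"];
  LogicalVector per = spec["periodic"];
  gs.d = lo.size();
  gs.lo.assign(lo.begin(), lo.end());
  gs.hi.assign(hi.begin(), hi.end());
  gs.nb.assign(nb.begin(), nb.end());
  gs.periodic.resize(gs.d);
  gs.h.resize(gs.d);
  gs.stride.resize(gs.d);
  int s = 1;
  for (int k = 0; k < gs.d; ++k) {
    gs.periodic[k] = per[k] ? 1 : 0;
    gs.h[k] = (gs.hi[k] - gs.lo[k]) / gs.nb[k];
    gs.stride[k] = s;
    s *= gs.nb[k];
  }
  return gs;
}

static inline double wrap_coord(double x, double lo, double hi) {
  double L = hi - lo;
  double y = (x - lo) - L * std::floor((x - lo) / L);
  if (y >= L) y -= L; // guard against floating round-up
  return lo + y;
}

// coefficient lookup with boundary handling along one dim
static inline int coef_index_1d(int i, int n, int periodic) {
  if (periodic) {
    int j = i % n; if (j < 0) j += n;
    return j;
  }
  return i; // caller applies natural ghost combination
}

// cubic B-spline basis and derivative on local u in [0,1)
static inline void bspline_basis(double u, double* b, double* db) {
  double u2 = u * u, u3 = u2 * u;
  b[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  b[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  b[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  b[3] = u3 / 6.0;
  db[0] = (-3 + 6 * u - 3 * u2) / 6.0;
  db[1] = (-12 * u + 9 * u2) / 6.0;
  db[2] = (3 + 6 * u - 9 * u2) / 6.0;
  db[3] = 3 * u2 / 6.0;
}

// fetch coefficient c[idx vector], with natural ghost extension per dim
static double coef_get(const double* coef, const GridSpec& gs, const int* idx) {
  // natural extension: c[-j] = 2 c[0] - c[j], c[n-1+j] = 2 c[n-1] - c[n-1-j]
  // handled recursively per dimension via reflection weights; since at most
  // one-step-out indices occur (stencil spans 4), expand directly.
  double wsign = 1.0;
  double base = 0.0;
  int flat = 0;
  // first check for out-of-range dims needing the 2*edge - mirror expansion
  for (int k = 0; k < gs.d; ++k) {
    int i = idx[k], n = gs.nb[k];
    if (gs.periodic[k]) continue;
    if (i < 0 || i >= n) {
      // expand: c[i] = 2 c[e] - c[m]; do it by recursion on two corrected points
      int e = (i < 0) ? 0 : n - 1;
      int m = (i < 0) ? -i : 2 * (n - 1) - i;
      std::vector<int> idx_e(idx, idx + gs.d), idx_m(idx, idx + gs.d);
      idx_e[k] = e; idx_m[k] = m;
      return 2.0 * coef_get(coef, gs, &idx_e[0]) - coef_get(coef, gs, &idx_m[0]);
    }
  }
  for (int k = 0; k < gs.d; ++k) {
    int i = coef_index_1d(idx[k], gs.nb[k], gs.periodic[k]);
    flat += i * gs.stride[k];
  }
  (void)wsign; (void)base;
  return coef[flat];
}

// evaluate spline value and gradient at a point (external units);
// returns false if point outside a non-periodic dimension's grid
static bool spline_eval_point(const double* coef, const GridSpec& gs,
                              const double* x, double* value, double* grad) {
  const int d = gs.d;
  int i0[8];
  double bas[8][4], dbas[8][4];
  for (int k = 0; k < d; ++k) {
    double xk = x[k];
    if (gs.periodic[k]) xk = wrap_coord(xk, gs.lo[k], gs.hi[k]);
    else if (xk < gs.lo[k] || xk > gs.hi[k]) return false;
    // node i sits at lo + (i + 0.5) h ; s is position in node-index space
    double s = (xk - gs.lo[k]) / gs.h[k] - 0.5;
    double fl = std::floor(s);
    double u = s - fl;
    i0[k] = (int)fl;
    bspline_basis(u, bas[k], dbas[k]);
  }
  double val = 0.0;
  std::vector<double> gr(d, 0.0);
  int idx[8];
  int count = 1;
  for (int k = 0; k < d; ++k) count *= 4;
  for (int t = 0; t < count; ++t) {
    int tt = t;
    double wprod = 1.0;
    for (int k = 0; k < d; ++k) {
      int ok = tt % 4; tt /= 4;
      idx[k] = i0[k] - 1 + ok;
      wprod *= bas[k][ok];
    }
    double c = coef_get(coef, gs, idx);
    val += c * wprod;
    // gradient: replace basis with derivative basis in dim k
    tt = t;
    int offs[8];
    for (int k = 0; k < d; ++k) { offs[k] = tt % 4; tt /= 4; }
    for (int k = 0; k < d; ++k) {
      double wp = 1.0;
      for (int j = 0; j < d; ++j)
        wp *= (j == k) ? dbas[j][offs[j]] : bas[j][offs[j]];
      gr[k] += c * wp;
    }
  }
  *value = val;
  for (int k = 0; k < d; ++k) grad[k] = gr[k] / gs.h[k];
  return true;
}

// [[Rcpp::export]]
List spline_eval_cpp(NumericVector coef, List grid, NumericMatrix points) {
  GridSpec gs = grid_from_list(grid);
  int np = points.nrow();
  NumericVector value(np);
  NumericMatrix grad(np, gs.d);
  LogicalVector inside(np);
  std::vector<double> x(gs.d), gr(gs.d);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < gs.d; ++k) x[k] = points(i, k);
    double v;
    bool ok = spline_eval_point(coef.begin(), gs, &x[0], &v, &gr[0]);
    inside[i] = ok;
    value[i] = ok ? v : NA_REAL;
    for (int k = 0; k < gs.d; ++k) grad(i, k) = ok ? gr[k] : NA_REAL;
  }
  return List::create(_["value"] = value, _["gradient"] = grad, _["inside"] = inside);
}

// ---------------------------------------------------------------------------
// force fields
// ---------------------------------------------------------------------------
struct WaterFF {
  double qO, qH, epsO, epsH, rminO2, rminH2; // rmin/2 per type
  double kb, r0, ktheta, theta0;             // theta0 radians
  double coulomb, cutoff;
  int boundary;                              // 0 cavity, 1 periodic
  double box, cavity_radius, k_cavity;
};

static WaterFF ff_from_list(List ff) {
  WaterFF f;
  f.qO = ff["q_O"]; f.qH = ff["q_H"];
  f.epsO = ff["lj_epsilon_O"]; f.epsH = ff["lj_epsilon_H"];
  f.rminO2 = ff["lj_rmin_half_O"]; f.rminH2 = ff["lj_rmin_half_H"];
  f.kb = ff["bond_k"]; f.r0 = ff["bond_r0"];
  f.ktheta = ff["angle_k"]; f.theta0 = (double)ff["angle_theta0_deg"] * TO_RAD;
  f.coulomb = ff["coulomb_constant"]; f.cutoff = ff["cutoff"];
  std::string b = as<std::string>(ff["boundary"]);
  f.boundary = (b == "periodic") ? 1 : 0;
  f.box = ff["box_edge"]; f.cavity_radius = ff["cavity_radius"];
  f.k_cavity = ff["k_cavity"];
  return f;
}

// flexible TIP3P-style dimer: atoms O H H O H H
static double water_forces(const WaterFF& f, const double* pos, double* frc) {
  double E = 0.0;
  for (int i = 0; i < 18; ++i) frc[i] = 0.0;
  const int bonds[4][2] = { {0, 1}, {0, 2}, {3, 4}, {3, 5} };
  for (int b = 0; b < 4; ++b) {
    int i = bonds[b][0], j = bonds[b][1];
    V3 d = v3(pos[3 * j] - pos[3 * i], pos[3 * j + 1] - pos[3 * i + 1], pos[3 * j + 2] - pos[3 * i + 2]);
    double r = norm3(d);
    double dr = r - f.r0;
    E += f.kb * dr * dr;                    // CHARMM convention: K (r - r0)^2
    double fmag = -2.0 * f.kb * dr / r;     // force on j along +d
    frc[3 * j] += fmag * d.x; frc[3 * j + 1] += fmag * d.y; frc[3 * j + 2] += fmag * d.z;
    frc[3 * i] -= fmag * d.x; frc[3 * i + 1] -= fmag * d.y; frc[3 * i + 2] -= fmag * d.z;
  }
  const int angles[2][3] = { {1, 0, 2}, {4, 3, 5} }; // H-O-H
  for (int a = 0; a < 2; ++a) {
    int i = angles[a][0], j = angles[a][1], k = angles[a][2];
    V3 u = v3(pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1], pos[3 * i + 2] - pos[3 * j + 2]);
    V3 v = v3(pos[3 * k] - pos[3 * j], pos[3 * k + 1] - pos[3 * j + 1], pos[3 * k + 2] - pos[3 * j + 2]);
    double nu = norm3(u), nv = norm3(v);
    double c = std::max(-1.0, std::min(1.0, dot(u, v) / (nu * nv)));
    double sn = std::sqrt(std::max(1e-12, 1.0 - c * c));
    double th = std::acos(c);
    double dth = th - f.theta0;
    E += f.ktheta * dth * dth;
    double dEdth = 2.0 * f.ktheta * dth;
    V3 uh = (1.0 / nu) * u, vh = (1.0 / nv) * v;
    V3 gi = (-1.0 / (nu * sn)) * (vh - c * uh);  // dth/d(atom i)
    V3 gk = (-1.0 / (nv * sn)) * (uh - c * vh);
    V3 fi = (-dEdth) * gi, fk = (-dEdth) * gk;
    frc[3 * i] += fi.x; frc[3 * i + 1] += fi.y; frc[3 * i + 2] += fi.z;
    frc[3 * k] += fk.x; frc[3 * k + 1] += fk.y; frc[3 * k + 2] += fk.z;
    frc[3 * j] -= fi.x + fk.x; frc[3 * j + 1] -= fi.y + fk.y; frc[3 * j + 2] -= fi.z + fk.z;
  }
  // intermolecular nonbonded, all 9 pairs
  const double q[3] = { f.qO, f.qH, f.qH };
  const double eps[3] = { f.epsO, f.epsH, f.epsH };
  const double rm2[3] = { f.rminO2, f.rminH2, f.rminH2 };
  for (int i = 0; i < 3; ++i) {
    for (int j = 3; j < 6; ++j) {
      V3 d = v3(pos[3 * j] - pos[3 * i], pos[3 * j + 1] - pos[3 * i + 1], pos[3 * j + 2] - pos[3 * i + 2]);
      if (f.boundary == 1) { // minimum image
        d.x -= f.box * std::round(d.x / f.box);
        d.y -= f.box * std::round(d.y / f.box);
        d.z -= f.box * std::round(d.z / f.box);
      }
      double r2 = dot(d, d);
      double r = std::sqrt(r2);
      if (f.cutoff > 0 && r > f.cutoff) continue;
      int ti = i % 3, tj = j % 3;
      double epsij = std::sqrt(eps[ti] * eps[tj]);
      double rminij = rm2[ti] + rm2[tj];
      double sr2 = (rminij * rminij) / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      double elj = epsij * (sr12 - 2.0 * sr6);
      double ec = f.coulomb * q[ti] * q[tj] / r;
      E += elj + ec;
      // dE/dr; force on j = -(dE/dr) * dhat
      double dEdr = epsij * (-12.0 * sr12 + 12.0 * sr6) / r - ec / r;
      double fmag = -dEdr / r;
      frc[3 * j] += fmag * d.x; frc[3 * j + 1] += fmag * d.y; frc[3 * j + 2] += fmag * d.z;
      frc[3 * i] -= fmag * d.x; frc[3 * i + 1] -= fmag * d.y; frc[3 * i + 2] -= fmag * d.z;
    }
  }
  // spherical cavity restraint about the origin
  if (f.boundary == 0 && f.k_cavity > 0) {
    for (int i = 0; i < 6; ++i) {
      V3 p = v3(pos[3 * i], pos[3 * i + 1], pos[3 * i + 2]);
      double r = norm3(p);
      if (r > f.cavity_radius) {
        double ex = r - f.cavity_radius;
        E += f.k_cavity * ex * ex;
        double fmag = -2.0 * f.k_cavity * ex / r;
        frc[3 * i] += fmag * p.x; frc[3 * i + 1] += fmag * p.y; frc[3 * i + 2] += fmag * p.z;
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List water_forces_cpp(NumericVector positions, List ff) {
  WaterFF f = ff_from_list(ff);
  NumericVector frc(18);
  double E = water_forces(f, positions.begin(), frc.begin());
  return List::create(_["forces"] = frc, _["energy"] = E);
}

// analytic single-particle potentials on RC coordinates
//   code 1: double_well_1d  V = a (x^2 - 1)^2
//   code 2: harmonic        V = sum 0.5 k_i x_i^2
static double analytic_forces(int code, const std::vector<double>& par,
                              const double* x, double* frc, int d) {
  double E = 0.0;
  if (code == 1) {
    double a = par[0];
    double s = x[0] * x[0] - 1.0;
    E = a * s * s;
    frc[0] = -4.0 * a * x[0] * s;
  } else {
    for (int k = 0; k < d; ++k) {
      double kk = par[k < (int)par.size() ? k : par.size() - 1];
      E += 0.5 * kk * x[k] * x[k];
      frc[k] = -kk * x[k];
    }
  }
  return E;
}

// [[Rcpp::export]]
List analytic_forces_cpp(NumericVector x, int code, NumericVector params) {
  int d = x.size();
  NumericVector frc(d);
  std::vector<double> par(params.begin(), params.end());
  double E = analytic_forces(code, par, x.begin(), frc.begin(), d);
  return List::create(_["forces"] = frc, _["energy"] = E);
}

// [[Rcpp::export]]
NumericVector mb_velocities_cpp(NumericVector masses_per_dof, double temperature, int seed) {
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> N(0.0, 1.0);
  int n = masses_per_dof.size();
  NumericVector v(n);
  for (int i = 0; i < n; ++i) v[i] = N(rng) * std::sqrt(KB * temperature / masses_per_dof[i]);
  return v;
}

// ---------------------------------------------------------------------------
// biased replica run loop
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_replica_cpp(List system, Nullable<List> graph_, List grid,
                     Nullable<NumericVector> bias_coef_, List conditions,
                     int n_steps, int seed,
                     int rc_stride, int traj_stride, int energy_stride) {
  // system
  std::string skind = as<std::string>(system["kind"]);
  NumericVector pos0 = system["positions"];
  NumericVector vel0 = system["velocities"];
  NumericVector mass_atom = system["masses"]; // per atom (water) or per dof (analytic)
  bool is_water = (skind == "water_dimer");
  WaterFF wf;
  int acode = 0; std::vector<double> apar;
  if (is_water) {
    wf = ff_from_list(system["force_field"]);
  } else {
    acode = as<int>(system["potential_code"]);
    NumericVector p = system["potential_params"];
    apar.assign(p.begin(), p.end());
  }
  int ndof = pos0.size();
  int natoms = is_water ? ndof / 3 : ndof;
  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<double> vel(vel0.begin(), vel0.end());
  std::vector<double> m(ndof); // mass per dof
  if (is_water) {
    for (int a = 0; a < natoms; ++a)
      for (int c = 0; c < 3; ++c) m[3 * a + c] = mass_atom[a];
  } else {
    for (int i = 0; i < ndof; ++i)
      m[i] = mass_atom[i < mass_atom.size() ? i : mass_atom.size() - 1];
  }

  // graph (water systems)
  Graph g; GraphWork w;
  bool has_graph = false;
  if (graph_.isNotNull()) { g = graph_from_list(List(graph_)); has_graph = true; }

  // grid + bias
  GridSpec gs = grid_from_list(grid);
  int nbins_total = 1;
  for (int k = 0; k < gs.d; ++k) nbins_total *= gs.nb[k];
  bool has_bias = bias_coef_.isNotNull();
  NumericVector bias_coef;
  if (has_bias) bias_coef = NumericVector(bias_coef_);
  double k_wall = as<double>(grid["k_wall"]);

  // conditions
  double Temp = as<double>(conditions["temperature"]);
  double dt_fs = as<double>(conditions["timestep_fs"]);
  double dt = dt_fs / TIMEFAC;
  std::string thermo = as<std::string>(conditions["thermostat"]);
  int tcode = 0;
  if (thermo == "langevin") tcode = 1;
  else if (thermo == "velocity_scale") tcode = 2;
  else if (thermo == "nose_hoover") tcode = 3;
  double friction_fs = as<double>(conditions["friction_fs"]);       // fs^-1
  double tau_ps = as<double>(conditions["tau_ps"]);
  int nsub = as<int>(conditions["n_substeps"]);
  double gamma = friction_fs * TIMEFAC;                              // per internal unit
  double c1 = std::exp(-gamma * dt);
  double tau = tau_ps * 1000.0 / TIMEFAC;
  double gdof = (double)ndof;
  double Q = gdof * KB * Temp * tau * tau;
  double nh_xi = 0.0;

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::normal_distribution<double> N(0.0, 1.0);

  // outputs
  IntegerVector counts(nbins_total);
  int n_out = 0, n_degen = 0;
  int nrc_frames = (rc_stride > 0) ? n_steps / rc_stride : 0;
  NumericMatrix rc_series(std::max(nrc_frames, 0), gs.d);
  NumericVector rc_times(std::max(nrc_frames, 0));
  int ntraj = (traj_stride > 0) ? n_steps / traj_stride : 0;
  NumericMatrix traj(std::max(ntraj, 0), ndof);
  NumericVector traj_times(std::max(ntraj, 0));
  int nen = (energy_stride > 0) ? n_steps / energy_stride : 0;
  NumericMatrix energies(std::max(nen, 0), 4); // PE, KE, Etot, T_inst
  NumericVector en_times(std::max(nen, 0));
  double temp_sum = 0.0;

  std::vector<double> frc(ndof), xi(gs.d), seeds(gs.d), bias_grad(gs.d);

  // force evaluation at current positions: system + bias + wall
  double PE = 0.0, Ubias = 0.0;
  bool in_grid = false;
  int flat_idx = -1;
  bool track_rc = !is_water || has_graph; // water without a graph: plain MD
  auto eval_forces = [&](bool count_sample) {
    if (is_water) PE = water_forces(wf, &pos[0], &frc[0]);
    else PE = analytic_forces(acode, apar, &pos[0], &frc[0], ndof);
    if (!track_rc) { in_grid = false; Ubias = 0.0; return; }
    // RC values
    if (is_water && has_graph) {
      n_degen += graph_forward(g, &pos[0], w);
      for (int k = 0; k < gs.d; ++k) xi[k] = w.sval[g.rc[k]];
    } else {
      for (int k = 0; k < gs.d; ++k) xi[k] = pos[k];
    }
    // binning + wall
    in_grid = true;
    bool any_na = false;
    std::fill(seeds.begin(), seeds.end(), 0.0);
    flat_idx = 0;
    for (int k = 0; k < gs.d; ++k) {
      double x = xi[k];
      if (ISNAN(x)) { any_na = true; in_grid = false; break; }
      if (gs.periodic[k]) {
        x = wrap_coord(x, gs.lo[k], gs.hi[k]);
      } else if (x < gs.lo[k]) {
        in_grid = false; seeds[k] += 2.0 * k_wall * (x - gs.lo[k]); // dVwall/dxi
        continue;
      } else if (x >= gs.hi[k]) {
        in_grid = false; seeds[k] += 2.0 * k_wall * (x - gs.hi[k]);
        continue;
      }
      int b = (int)std::floor((x - gs.lo[k]) / gs.h[k]);
      if (b < 0) b = 0; if (b >= gs.nb[k]) b = gs.nb[k] - 1;
      flat_idx += b * gs.stride[k];
    }
    Ubias = 0.0;
    if (in_grid && has_bias) {
      double uval;
      if (spline_eval_point(bias_coef.begin(), gs, &xi[0], &uval, &bias_grad[0])) {
        Ubias = uval;
        for (int k = 0; k < gs.d; ++k) seeds[k] += bias_grad[k];
      }
    }
    // map RC-space gradient to atomic forces: F += -(dU/dxi)(dxi/dx)
    bool any_seed = false;
    for (int k = 0; k < gs.d; ++k) if (seeds[k] != 0.0) { any_seed = true; break; }
    if (any_seed && !any_na) {
      if (is_water && has_graph) {
        std::vector<double> gr(ndof, 0.0);
        n_degen += graph_reverse(g, w, &seeds[0], &gr[0], natoms);
        for (int i = 0; i < ndof; ++i) frc[i] -= gr[i];
      } else {
        for (int k = 0; k < gs.d; ++k) frc[k] -= seeds[k];
      }
    }
    if (count_sample) {
      if (in_grid) counts[flat_idx]++;
      else ++n_out;
    }
  };

  eval_forces(false);
  int rc_i = 0, tr_i = 0, en_i = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // velocity Verlet with thermostat coupling
    if (tcode == 3) { // Nose-Hoover half coupling, nsub substeps
      double dth = 0.5 * dt / nsub;
      for (int s = 0; s < nsub; ++s) {
        double KE2 = 0.0;
        for (int i = 0; i < ndof; ++i) KE2 += m[i] * vel[i] * vel[i];
        nh_xi += dth * (KE2 - gdof * KB * Temp) / Q;
        double sc = std::exp(-nh_xi * dth);
        for (int i = 0; i < ndof; ++i) vel[i] *= sc;
      }
    }
    for (int i = 0; i < ndof; ++i) vel[i] += 0.5 * dt * frc[i] / m[i];
    for (int i = 0; i < ndof; ++i) pos[i] += dt * vel[i];
    eval_forces(true);
    for (int i = 0; i < ndof; ++i) vel[i] += 0.5 * dt * frc[i] / m[i];
    if (tcode == 1) { // Langevin O-step
      for (int i = 0; i < ndof; ++i) {
        double c2 = std::sqrt((1.0 - c1 * c1) * KB * Temp / m[i]);
        vel[i] = c1 * vel[i] + c2 * N(rng);
      }
    } else if (tcode == 2) { // velocity rescale
      double KE2 = 0.0;
      for (int i = 0; i < ndof; ++i) KE2 += m[i] * vel[i] * vel[i];
      if (KE2 > 0) {
        double sc = std::sqrt(gdof * KB * Temp / KE2);
        for (int i = 0; i < ndof; ++i) vel[i] *= sc;
      }
    } else if (tcode == 3) {
      double dth = 0.5 * dt / nsub;
      for (int s = 0; s < nsub; ++s) {
        double sc = std::exp(-nh_xi * dth);
        for (int i = 0; i < ndof; ++i) vel[i] *= sc;
        double KE2 = 0.0;
        for (int i = 0; i < ndof; ++i) KE2 += m[i] * vel[i] * vel[i];
        nh_xi += dth * (KE2 - gdof * KB * Temp) / Q;
      }
    }
    double KE = 0.0;
    for (int i = 0; i < ndof; ++i) KE += 0.5 * m[i] * vel[i] * vel[i];
    double Tinst = 2.0 * KE / (gdof * KB);
    temp_sum += Tinst;
    if (rc_stride > 0 && step % rc_stride == 0 && rc_i < nrc_frames) {
      for (int k = 0; k < gs.d; ++k) rc_series(rc_i, k) = xi[k];
      rc_times[rc_i] = step * dt_fs;
      ++rc_i;
    }
    if (traj_stride > 0 && step % traj_stride == 0 && tr_i < ntraj) {
      for (int i = 0; i < ndof; ++i) traj(tr_i, i) = pos[i];
      traj_times[tr_i] = step * dt_fs;
      ++tr_i;
    }
    if (energy_stride > 0 && step % energy_stride == 0 && en_i < nen) {
      energies(en_i, 0) = PE; energies(en_i, 1) = KE;
      energies(en_i, 2) = PE + KE + Ubias; energies(en_i, 3) = Tinst;
      en_times[en_i] = step * dt_fs;
      ++en_i;
    }
  }

  return List::create(
    _["counts"] = counts,
    _["positions"] = NumericVector(pos.begin(), pos.end()),
    _["velocities"] = NumericVector(vel.begin(), vel.end()),
    _["rc_series"] = rc_series, _["rc_times"] = rc_times,
    _["trajectory"] = traj, _["traj_times"] = traj_times,
    _["energies"] = energies, _["energy_times"] = en_times,
    _["n_out_of_grid"] = n_out, _["n_degenerate"] = n_degen,
    _["mean_temperature"] = temp_sum / n_steps);
}
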