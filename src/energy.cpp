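// Compiled core: energy, analytic gradient and finite-difference Hessian of
// the vertex-model energy, in Cartesian and polar (r, theta) coordinates.
// The polar form backs the equilibrium solver, where the vitelline
// confinement r <= R is a box constraint.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct System {
  int n;
  std::vector<double> w, K_lat, K_act, rest_a, rest_b, rest_l, V0;
  double Ka, Kb, Kv, KY, V0y, R;

  explicit System(const List& sys) {
    n = as<int>(sys["n"]);
    w = as<std::vector<double>>(sys["w"]);
    K_lat = as<std::vector<double>>(sys["K_lat"]);
    K_act = as<std::vector<double>>(sys["K_act"]);
    rest_a = as<std::vector<double>>(sys["rest_a"]);
    rest_b = as<std::vector<double>>(sys["rest_b"]);
    rest_l = as<std::vector<double>>(sys["rest_l"]);
    V0 = as<std::vector<double>>(sys["V0"]);
    Ka = as<double>(sys["Ka"]);
    Kb = as<double>(sys["Kb"]);
    Kv = as<double>(sys["Kv"]);
    KY = as<double>(sys["KY"]);
    V0y = as<double>(sys["V0y"]);
    R = as<double>(sys["R"]);
  }
};

// Energy and (optionally) Cartesian gradient. A, B, gA, gB are length-2n
// arrays in column-major (x..., y...) layout.
double energy_grad(const System& s, const double* A, const double* B,
                   double* gA, double* gB, double* terms) {
  const int n = s.n;
  const double* Ax = A; const double* Ay = A + n;
  const double* Bx = B; const double* By = B + n;
  double E_con = 0, E_ap = 0, E_ba = 0, E_lp = 0, E_la = 0, E_cv = 0;

  if (gA) {
    std::fill(gA, gA + 2 * n, 0.0);
    std::fill(gB, gB + 2 * n, 0.0);
  }
  double* gAx = gA; double* gAy = gA ? gA + n : nullptr;
  double* gBx = gB; double* gBy = gB ? gB + n : nullptr;

  double Vy = 0.0;
  std::vector<double> V(n), q(n);

  for (int i = 0; i < n; ++i) {
    const int j = (i + 1 == n) ? 0 : i + 1;
    // apical edge of cell i
    const double eax = Ax[j] - Ax[i], eay = Ay[j] - Ay[i];
    const double a = std::sqrt(eax * eax + eay * eay);
    E_con += s.w[i] * a * a;
    const double da = a - s.rest_a[i];
    E_ap += s.Ka * da * da;
    // basal edge
    const double ebx = Bx[j] - Bx[i], eby = By[j] - By[i];
    const double b = std::sqrt(ebx * ebx + eby * eby);
    const double db = b - s.rest_b[i];
    E_ba += s.Kb * db * db;
    // lateral edge i (apical i -- basal i)
    const double elx = Ax[i] - Bx[i], ely = Ay[i] - By[i];
    const double l = std::sqrt(elx * elx + ely * ely);
    const double dl = l - s.rest_l[i];
    E_lp += s.K_lat[i] * dl * dl;
    E_la += s.K_act[i] * l * l;
    // cell area (shoelace of quad A_i, A_j, B_j, B_i)
    const double Vi = 0.5 * (Ax[i] * Ay[j] - Ax[j] * Ay[i]
                           + Ax[j] * By[j] - Bx[j] * Ay[j]
                           + Bx[j] * By[i] - Bx[i] * By[j]
                           + Bx[i] * Ay[i] - Ax[i] * By[i]);
    V[i] = Vi;
    const double dv = Vi - s.V0[i];
    E_cv += s.Kv * dv * dv;
    // yolk polygon contribution
    Vy += 0.5 * (Bx[i] * By[j] - Bx[j] * By[i]);

    if (gA) {
      const double ca = 2.0 * s.w[i] + 2.0 * s.Ka * da / a;
      gAx[j] += ca * eax; gAy[j] += ca * eay;
      gAx[i] -= ca * eax; gAy[i] -= ca * eay;
      const double cb = 2.0 * s.Kb * db / b;
      gBx[j] += cb * ebx; gBy[j] += cb * eby;
      gBx[i] -= cb * ebx; gBy[i] -= cb * eby;
      const double cl = 2.0 * s.K_lat[i] * dl / l + 2.0 * s.K_act[i];
      gAx[i] += cl * elx; gAy[i] += cl * ely;
      gBx[i] -= cl * elx; gBy[i] -= cl * ely;
      q[i] = 2.0 * s.Kv * dv;
    }
  }
  const double dvy = Vy - s.V0y;
  const double E = E_con + E_ap + E_ba + E_lp + E_la + E_cv + s.KY * dvy * dvy;

  if (terms) {
    terms[0] = E_con; terms[1] = E_ap; terms[2] = E_ba;
    terms[3] = E_lp; terms[4] = E_la; terms[5] = E_cv;
    terms[6] = s.KY * dvy * dvy;
  }
  if (!gA) return E;

  // area-penalty gradients (shoelace derivative of each quad) and yolk term
  const double qy = 2.0 * s.KY * dvy;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1 == n) ? 0 : i + 1;
    const int p = (i == 0) ? n - 1 : i - 1;
    const double qi = q[i];
    // d/dA_i (vertex 1 of quad i): next A_j, prev B_i
    gAx[i] += qi * 0.5 * (Ay[j] - By[i]);
    gAy[i] += qi * 0.5 * (Bx[i] - Ax[j]);
    // d/dA_j (vertex 2): next B_j, prev A_i
    gAx[j] += qi * 0.5 * (By[j] - Ay[i]);
    gAy[j] += qi * 0.5 * (Ax[i] - Bx[j]);
    // d/dB_j (vertex 3): next B_i, prev A_j
    gBx[j] += qi * 0.5 * (By[i] - Ay[j]);
    gBy[j] += qi * 0.5 * (Ax[j] - Bx[i]);
    // d/dB_i (vertex 4): next A_i, prev B_j
    gBx[i] += qi * 0.5 * (Ay[i] - By[j]);
    gBy[i] += qi * 0.5 * (Bx[j] - Ax[i]);
    // yolk polygon
    gBx[i] += qy * 0.5 * (By[j] - By[p]);
    gBy[i] += qy * 0.5 * (Bx[p] - Bx[j]);
  }
  return E;
}

// polar state layout: z = (rA, rB, thA, thB), each length n.
void polar_to_cart(const System& s, const double* z, double* A, double* B) {
  const int n = s.n;
  for (int i = 0; i < n; ++i) {
    A[i] = z[i] * std::cos(z[2 * n + i]);
    A[n + i] = z[i] * std::sin(z[2 * n + i]);
    B[i] = z[n + i] * std::cos(z[3 * n + i]);
    B[n + i] = z[n + i] * std::sin(z[3 * n + i]);
  }
}

double polar_energy_grad(const System& s, const double* z, double* g) {
  const int n = s.n;
  std::vector<double> A(2 * n), B(2 * n);
  polar_to_cart(s, z, A.data(), B.data());
  if (!g) return energy_grad(s, A.data(), B.data(), nullptr, nullptr, nullptr);
  std::vector<double> gA(2 * n), gB(2 * n);
  const double E = energy_grad(s, A.data(), B.data(), gA.data(), gB.data(),
                               nullptr);
  for (int i = 0; i < n; ++i) {
    const double ctA = std::cos(z[2 * n + i]), stA = std::sin(z[2 * n + i]);
    const double ctB = std::cos(z[3 * n + i]), stB = std::sin(z[3 * n + i]);
    g[i] = gA[i] * ctA + gA[n + i] * stA;
    g[n + i] = gB[i] * ctB + gB[n + i] * stB;
    g[2 * n + i] = z[i] * (-gA[i] * stA + gA[n + i] * ctA);
    g[3 * n + i] = z[n + i] * (-gB[i] * stB + gB[n + i] * ctB);
  }
  return E;
}

// Mirror-symmetric subspace. The reflection about the ventral midline maps
// ring vertex i (0-based) to (n - i) % n, so vertices 0 and n/2 are their
// own mirrors (pinned to the midline axis, theta fixed) and vertices
// 1..n/2-1 carry their mirror partners implicitly. Half-state layout
// (h = n/2):
//   zh = (rA[0..h], rB[0..h], thA[1..h-1], thB[1..h-1])
// giving 2(h+1) + 2(h-1) = 2n coordinates. Mirrored angles are -pi - theta.
void sym_expand(int n, const double* zh, std::vector<double>& z) {
  const int h = n / 2;
  const int nr = h + 1;          // radii stored per layer
  const int nth = h - 1;         // free angles per layer
  z.assign(4 * n, 0.0);
  const double* rA = zh;
  const double* rB = zh + nr;
  const double* thA = zh + 2 * nr;
  const double* thB = zh + 2 * nr + nth;
  for (int i = 0; i <= h; ++i) {
    z[i] = rA[i];
    z[n + i] = rB[i];
  }
  const double half_pi = std::asin(1.0);
  z[2 * n + 0] = -half_pi;
  z[3 * n + 0] = -half_pi;
  z[2 * n + h] = half_pi;
  z[3 * n + h] = half_pi;
  for (int i = 1; i < h; ++i) {
    z[2 * n + i] = thA[i - 1];
    z[3 * n + i] = thB[i - 1];
    const int j = n - i;
    z[j] = rA[i];
    z[n + j] = rB[i];
    z[2 * n + j] = -M_PI - thA[i - 1];
    z[3 * n + j] = -M_PI - thB[i - 1];
  }
}

// Contract a full polar gradient onto the half coordinates.
void sym_contract(int n, const double* g, double* gh) {
  const int h = n / 2;
  const int nr = h + 1;
  const int nth = h - 1;
  double* grA = gh;
  double* grB = gh + nr;
  double* gthA = gh + 2 * nr;
  double* gthB = gh + 2 * nr + nth;
  grA[0] = g[0]; grB[0] = g[n];
  grA[h] = g[h]; grB[h] = g[n + h];
  for (int i = 1; i < h; ++i) {
    const int j = n - i;
    grA[i] = g[i] + g[j];
    grB[i] = g[n + i] + g[n + j];
    gthA[i - 1] = g[2 * n + i] - g[2 * n + j];
    gthB[i - 1] = g[3 * n + i] - g[3 * n + j];
  }
}

double polar_energy_grad_sym(const System& s, const double* zh, double* gh) {
  std::vector<double> z;
  sym_expand(s.n, zh, z);
  if (!gh) return polar_energy_grad(s, z.data(), nullptr);
  std::vector<double> g(4 * s.n);
  const double E = polar_energy_grad(s, z.data(), g.data());
  sym_contract(s.n, g.data(), gh);
  return E;
}

}  // namespace

// [[Rcpp::export(name = ".energy_grad_cpp")]]
List energy_grad_cpp(NumericMatrix A, NumericMatrix B, List sys,
                     bool want_grad = true) {
  System s(sys);
  const int n = s.n;
  if (A.nrow() != n || B.nrow() != n) stop("vertex array size mismatch");
  std::vector<double> gA(want_grad ? 2 * n : 0), gB(want_grad ? 2 * n : 0);
  NumericVector terms(7);
  const double E = energy_grad(s, A.begin(), B.begin(),
                               want_grad ? gA.data() : nullptr,
                               want_grad ? gB.data() : nullptr,
                               terms.begin());
  terms.names() = CharacterVector({"apical_contractility", "apical_elastic",
                                   "basal_elastic", "lateral_passive",
                                   "lateral_active", "cell_area_penalty",
                                   "yolk_penalty"});
  List out = List::create(_["E"] = E, _["terms"] = terms);
  if (want_grad) {
    NumericMatrix GA(n, 2), GB(n, 2);
    std::copy(gA.begin(), gA.end(), GA.begin());
    std::copy(gB.begin(), gB.end(), GB.begin());
    out["gA"] = GA;
    out["gB"] = GB;
  }
  return out;
}

// [[Rcpp::export(name = ".polar_energy_cpp")]]
double polar_energy_cpp(NumericVector z, List sys) {
  System s(sys);
  return polar_energy_grad(s, z.begin(), nullptr);
}

// [[Rcpp::export(name = ".polar_grad_cpp")]]
NumericVector polar_grad_cpp(NumericVector z, List sys) {
  System s(sys);
  NumericVector g(z.size());
  polar_energy_grad(s, z.begin(), g.begin());
  return g;
}

// [[Rcpp::export(name = ".sym_expand_cpp")]]
NumericVector sym_expand_cpp(NumericVector zh, int n) {
  std::vector<double> z;
  sym_expand(n, zh.begin(), z);
  return NumericVector(z.begin(), z.end());
}

// [[Rcpp::export(name = ".sym_energy_cpp")]]
double sym_energy_cpp(NumericVector zh, List sys) {
  System s(sys);
  return polar_energy_grad_sym(s, zh.begin(), nullptr);
}

// [[Rcpp::export(name = ".sym_grad_cpp")]]
NumericVector sym_grad_cpp(NumericVector zh, List sys) {
  System s(sys);
  NumericVector g(zh.size());
  polar_energy_grad_sym(s, zh.begin(), g.begin());
  return g;
}

// [[Rcpp::export(name = ".sym_hess_cpp")]]
NumericMatrix sym_hess_cpp(NumericVector zh, List sys, double h = 1e-6) {
  System s(sys);
  const int N = zh.size();
  std::vector<double> g0(N), gi(N), zp(zh.begin(), zh.end());
  polar_energy_grad_sym(s, zp.data(), g0.data());
  NumericMatrix H(N, N);
  for (int i = 0; i < N; ++i) {
    const double zi = zp[i];
    zp[i] = zi + h;
    polar_energy_grad_sym(s, zp.data(), gi.data());
    zp[i] = zi;
    for (int k = 0; k < N; ++k) H(k, i) = (gi[k] - g0[k]) / h;
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < i; ++k) {
      const double v = 0.5 * (H(i, k) + H(k, i));
      H(i, k) = v;
      H(k, i) = v;
    }
  return H;
}

// Finite-difference Hessian of the polar gradient (forward differences,
// symmetrized). Dimension 4n is small (320 for the 80-cell ring), so a
// dense matrix is fine.
// [[Rcpp::export(name = ".polar_hess_cpp")]]
NumericMatrix polar_hess_cpp(NumericVector z, List sys, double h = 1e-6) {
  System s(sys);
  const int N = z.size();
  std::vector<double> g0(N), gi(N), zp(z.begin(), z.end());
  polar_energy_grad(s, zp.data(), g0.data());
  NumericMatrix H(N, N);
  for (int i = 0; i < N; ++i) {
    const double zi = zp[i];
    zp[i] = zi + h;
    polar_energy_grad(s, zp.data(), gi.data());
    zp[i] = zi;
    for (int k = 0; k < N; ++k) H(k, i) = (gi[k] - g0[k]) / h;
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < i; ++k) {
      const double v = 0.5 * (H(i, k) + H(k, i));
      H(i, k) = v;
      H(k, i) = v;
    }
  return H;
}
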