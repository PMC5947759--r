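// Inner loops of the distance-geometry generator and of ensemble
// clustering.  Kept in C++ because they dominate runtime: a 500-member
// ensemble needs ~10^8 pairwise corrections.
#include <RcppArmadillo.h>
#include <random>
#include <unordered_set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long long pairKey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

// One distance-geometry sampling run: perturb the start coordinates with
// isotropic Gaussian noise, then sweep over violated bounds, moving both
// atoms of each violated pair along the pair axis by half the excess until
// every constraint and every exclusion floor is satisfied within tol.
// A chirality guard mirrors the coordinates if the majority of Calpha
// centres invert relative to the reference signs.  Runs that stop making
// progress receive a small seeded jitter to escape correction cycles.
// [[Rcpp::export(name = ".dg_sample")]]
List dg_sample(NumericMatrix start,
               IntegerVector ci, IntegerVector cj,
               NumericVector lo, NumericVector up,
               NumericVector radii, double exclFactor,
               double sigma, int seed, int maxSweeps, double tol,
               IntegerMatrix chir, NumericVector chirRef) {
  const int n = start.nrow();
  const int nc = ci.size();
  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      x[3 * i + k] = start(i, k) + (sigma > 0 ? sigma * gauss(rng) : 0.0);

  auto dist2 = [&](int i, int j) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    return dx * dx + dy * dy + dz * dz;
  };

  // exclusion pair list: all pairs not covered by a constraint
  std::unordered_set<long long> constrained;
  constrained.reserve(nc * 2);
  std::vector<int> c_i(nc), c_j(nc);
  for (int c = 0; c < nc; ++c) {
    c_i[c] = ci[c] - 1; c_j[c] = cj[c] - 1;
    constrained.insert(pairKey(c_i[c], c_j[c], n));
  }
  std::vector<int> ei, ej;
  std::vector<double> elo;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (!constrained.count(pairKey(i, j, n))) {
        ei.push_back(i); ej.push_back(j);
        elo.push_back(exclFactor * (radii[i] + radii[j]));
      }
  const int ne = (int)ei.size();

  const int nch = chir.nrow();
  auto chirSign = [&](int r) {
    const int ca = chir(r, 0) - 1, na = chir(r, 1) - 1,
              cc = chir(r, 2) - 1, cb = chir(r, 3) - 1;
    double a0 = x[3 * na] - x[3 * ca], a1 = x[3 * na + 1] - x[3 * ca + 1],
           a2 = x[3 * na + 2] - x[3 * ca + 2];
    double b0 = x[3 * cc] - x[3 * ca], b1 = x[3 * cc + 1] - x[3 * ca + 1],
           b2 = x[3 * cc + 2] - x[3 * ca + 2];
    double c0 = x[3 * cb] - x[3 * ca], c1 = x[3 * cb + 1] - x[3 * ca + 1],
           c2 = x[3 * cb + 2] - x[3 * ca + 2];
    double det = a0 * (b1 * c2 - b2 * c1) - a1 * (b0 * c2 - b2 * c0)
               + a2 * (b0 * c1 - b1 * c0);
    return det >= 0 ? 1.0 : -1.0;
  };

  // reflect CB of a flipped centre across the N-CA-C plane: restores the
  // reference handedness while keeping its distances to N, CA, C
  auto fixCentre = [&](int r) {
    const int ca = chir(r, 0) - 1, na = chir(r, 1) - 1,
              cc = chir(r, 2) - 1, cb = chir(r, 3) - 1;
    double u0 = x[3 * na] - x[3 * ca], u1 = x[3 * na + 1] - x[3 * ca + 1],
           u2 = x[3 * na + 2] - x[3 * ca + 2];
    double v0 = x[3 * cc] - x[3 * ca], v1 = x[3 * cc + 1] - x[3 * ca + 1],
           v2 = x[3 * cc + 2] - x[3 * ca + 2];
    double n0 = u1 * v2 - u2 * v1, n1 = u2 * v0 - u0 * v2,
           n2 = u0 * v1 - u1 * v0;
    double nn = std::sqrt(n0 * n0 + n1 * n1 + n2 * n2);
    if (nn < 1e-9) return;
    n0 /= nn; n1 /= nn; n2 /= nn;
    double w0 = x[3 * cb] - x[3 * ca], w1 = x[3 * cb + 1] - x[3 * ca + 1],
           w2 = x[3 * cb + 2] - x[3 * ca + 2];
    double p = w0 * n0 + w1 * n1 + w2 * n2;
    x[3 * cb] -= 2 * p * n0; x[3 * cb + 1] -= 2 * p * n1;
    x[3 * cb + 2] -= 2 * p * n2;
  };

  std::vector<int> viol;   // 0..nc-1 constraints, nc..nc+ne-1 exclusions
  std::vector<int> flipped;
  viol.reserve(nc + ne);
  bool converged = false;
  int sweep = 0;
  size_t bestViol = (size_t)-1;
  int stall = 0;
  double kick = 0.1;
  for (; sweep < maxSweeps; ++sweep) {
    viol.clear();
    for (int c = 0; c < nc; ++c) {
      double d2 = dist2(c_i[c], c_j[c]);
      double l = lo[c] - tol, u = up[c] + tol;
      if (d2 < l * l || d2 > u * u) viol.push_back(c);
    }
    for (int e = 0; e < ne; ++e) {
      double l = elo[e] - tol;
      if (l > 0 && dist2(ei[e], ej[e]) < l * l) viol.push_back(nc + e);
    }
    flipped.clear();
    for (int r = 0; r < nch; ++r)
      if (chirSign(r) != chirRef[r]) flipped.push_back(r);
    if (viol.empty() && flipped.empty()) { converged = true; break; }

    if ((int)flipped.size() * 2 > nch) {  // global inversion: mirror all
      for (double &v : x) v = -v;
    } else {
      for (int r : flipped) fixCentre(r);
    }

    // jitter escape: if the violation count has not improved for a while,
    // the Gauss-Seidel corrections are cycling; a seeded kick on the atoms
    // of the violated pairs breaks the cycle without altering the fixed
    // point (all bounds satisfied, handedness preserved)
    size_t sz = viol.size() + flipped.size();
    if (sz < bestViol) { bestViol = sz; stall = 0; kick = 0.1; }
    else if (++stall >= 20) {
      for (int v : viol) {
        int i = (v < nc) ? c_i[v] : ei[v - nc];
        int j = (v < nc) ? c_j[v] : ej[v - nc];
        for (int k = 0; k < 3; ++k) {
          x[3 * i + k] += kick * gauss(rng);
          x[3 * j + k] += kick * gauss(rng);
        }
      }
      stall = 0;
      kick = std::min(kick * 1.5, 1.0);
      bestViol = (size_t)-1;
    }

    std::shuffle(viol.begin(), viol.end(), rng);
    for (int v : viol) {
      int i, j; double l, u;
      if (v < nc) { i = c_i[v]; j = c_j[v]; l = lo[v]; u = up[v]; }
      else { i = ei[v - nc]; j = ej[v - nc]; l = elo[v - nc]; u = 1e30; }
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
      double t;
      if (dd < l) t = l; else if (dd > u) t = u; else continue;
      double ax, ay, az;
      if (dd < 1e-9) {
        ax = gauss(rng); ay = gauss(rng); az = gauss(rng);
        double nn = std::sqrt(ax * ax + ay * ay + az * az);
        ax /= nn; ay /= nn; az /= nn;
      } else { ax = dx / dd; ay = dy / dd; az = dz / dd; }
      double step = (t - dd) / 2.0;  // positive: push apart
      x[3 * i] += step * ax; x[3 * i + 1] += step * ay; x[3 * i + 2] += step * az;
      x[3 * j] -= step * ax; x[3 * j + 1] -= step * ay; x[3 * j + 2] -= step * az;
    }
  }

  // final worst violation
  double maxViol = 0.0;
  for (int c = 0; c < nc; ++c) {
    double dd = std::sqrt(dist2(c_i[c], c_j[c]));
    maxViol = std::max(maxViol, std::max(lo[c] - dd, dd - up[c]));
  }
  for (int e = 0; e < ne; ++e) {
    double dd = std::sqrt(dist2(ei[e], ej[e]));
    maxViol = std::max(maxViol, elo[e] - dd);
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(_["xyz"] = out, _["converged"] = converged,
                      _["nSweeps"] = sweep, _["maxViolation"] = maxViol);
}

// Least-squares (Kabsch) RMSD between two point sets, proper rotation.
static double kabschRmsd(const arma::mat &A, const arma::mat &B) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - ca, B0 = B.each_row() - cb;
  arma::mat C = A0.t() * B0;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, C);
  double sgn = (arma::det(U) * arma::det(V) < 0) ? -1.0 : 1.0;
  double tr = s(0) + s(1) + sgn * s(2);
  double e = (arma::accu(A0 % A0) + arma::accu(B0 % B0) - 2.0 * tr) / A.n_rows;
  return std::sqrt(std::max(e, 0.0));
}

// Pairwise Calpha RMSD matrix over ensemble members.
// xyz: (nca * 3) x m matrix, columns are flattened member coordinates.
// [[Rcpp::export(name = ".pairwise_rmsd")]]
NumericMatrix pairwise_rmsd(NumericMatrix xyz, int nca) {
  const int m = xyz.ncol();
  NumericMatrix out(m, m);
  std::vector<arma::mat> pts(m);
  for (int a = 0; a < m; ++a) {
    arma::mat P(nca, 3);
    for (int i = 0; i < nca; ++i)
      for (int k = 0; k < 3; ++k) P(i, k) = xyz(i + k * nca, a);
    pts[a] = P;
  }
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      double r = kabschRmsd(pts[a], pts[b]);
      out(a, b) = r; out(b, a) = r;
    }
  return out;
}
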