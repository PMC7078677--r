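// Core numerics for the 2D spine-membrane simulator.
//
// The membrane is a closed, counterclockwise polygon.  All distances are in
// micrometres, forces in piconewtons, times in seconds.  Stochastic kernels
// draw exclusively from R's RNG (unif_rand) so that set.seed() at the R level
// makes whole simulations bitwise reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Signed discrete curvature at vertex b of the triangle (a, b, c): inverse
// circumradius, sign given by the cross product of the adjacent edges
// (positive = locally convex for a counterclockwise polygon).  Collinear
// points give zero curvature.
static inline double curv3(double ax, double ay, double bx, double by,
                           double cx, double cy) {
  const double e1x = bx - ax, e1y = by - ay;
  const double e2x = cx - bx, e2y = cy - by;
  const double e3x = cx - ax, e3y = cy - ay;
  const double cross = e1x * e2y - e1y * e2x;
  const double l1 = std::sqrt(e1x * e1x + e1y * e1y);
  const double l2 = std::sqrt(e2x * e2x + e2y * e2y);
  const double l3 = std::sqrt(e3x * e3x + e3y * e3y);
  const double denom = l1 * l2 * l3;
  if (denom == 0.0) return 0.0;
  return 2.0 * cross / denom;
}

static double shoelace_vec(const std::vector<double>& x,
                           const std::vector<double>& y) {
  const int n = (int)x.size();
  double a = 0.0;
  for (int k = 0; k < n; ++k) {
    const int j = (k + 1) % n;
    a += x[k] * y[j] - x[j] * y[k];
  }
  return 0.5 * a;
}

// ---------------------------------------------------------------------------
// Membrane force: minus the gradient of the discretised Helfrich energy
//   E = P*Omega + tau*S + 2*kappa*sum_j H_j^2 ds_j
// All three gradients are analytic.  For the bending term, the contribution
// of vertex k collects the three curvature terms j = k-1, k, k+1 in which
// x_k plays the role of next, centre, and previous vertex respectively.
// ---------------------------------------------------------------------------

// Scratch arrays shared by force evaluations (one allocation per move call).
struct ForceScratch {
  std::vector<double> ex, ey, el, iel;   // edges and inverse lengths
  std::vector<double> Hj, iLj, il3, e3x, e3y, dsj;  // per-centre curvature data
  std::vector<int> im1, ip1;             // cyclic neighbour indices
};

// The bending gradient of vertex k collects the three curvature terms
// centred at j = k-1, k, k+1; per-centre quantities (curvature H_j, chord
// e3 = e1+e2 and its length, ds_j, and 1/(l1 l2 l3)) are precomputed once
// per force evaluation in `S`.
static void mem_force_vec(const std::vector<double>& x,
                          const std::vector<double>& y, double P, double tau,
                          double kappa, std::vector<double>& fx,
                          std::vector<double>& fy, ForceScratch& S,
                          const std::vector<char>* skip = nullptr) {
  const int n = (int)x.size();
  if ((int)fx.size() != n) {
    fx.resize(n); fy.resize(n);
    S.ex.resize(n); S.ey.resize(n); S.el.resize(n); S.iel.resize(n);
    S.Hj.resize(n); S.iLj.resize(n); S.il3.resize(n);
    S.e3x.resize(n); S.e3y.resize(n); S.dsj.resize(n);
    S.im1.resize(n); S.ip1.resize(n);
    for (int k = 0; k < n; ++k) {
      S.im1[k] = k == 0 ? n - 1 : k - 1;
      S.ip1[k] = k == n - 1 ? 0 : k + 1;
    }
  }
  for (int k = 0; k < n; ++k) {          // edge k: vertex k -> k+1
    const int j = S.ip1[k];
    S.ex[k] = x[j] - x[k];
    S.ey[k] = y[j] - y[k];
    S.el[k] = std::sqrt(S.ex[k] * S.ex[k] + S.ey[k] * S.ey[k]);
    S.iel[k] = S.el[k] > 0.0 ? 1.0 / S.el[k] : 0.0;
  }
  for (int j = 0; j < n; ++j) {          // chord e3 centred at j (always used)
    const int p = S.im1[j];
    S.e3x[j] = S.ex[p] + S.ex[j];
    S.e3y[j] = S.ey[p] + S.ey[j];
  }
  if (kappa != 0.0) {
    for (int j = 0; j < n; ++j) {        // curvature triple centred at j
      const int p = S.im1[j];
      const double ax = S.e3x[j];
      const double ay = S.e3y[j];
      const double l3 = std::sqrt(ax * ax + ay * ay);
      const double L = S.el[p] * S.el[j] * l3;
      S.il3[j] = l3 > 0.0 ? 1.0 / l3 : 0.0;
      S.iLj[j] = L > 0.0 ? 1.0 / L : 0.0;
      const double C = S.ex[p] * S.ey[j] - S.ey[p] * S.ex[j];
      S.Hj[j] = 2.0 * C * S.iLj[j];
      S.dsj[j] = 0.5 * (S.el[p] + S.el[j]);
    }
  }
  const double* ex = S.ex.data();
  const double* ey = S.ey.data();
  const double* el = S.el.data();
  const double* iel = S.iel.data();
  for (int k = 0; k < n; ++k) {
    if (skip && (*skip)[k]) { fx[k] = 0.0; fy[k] = 0.0; continue; }
    const int p = S.im1[k], q = S.ip1[k];
    // pressure: dOmega/dx_k = 0.5*(y_q - y_p), dOmega/dy_k = 0.5*(x_p - x_q),
    // and (x_q - x_p, y_q - y_p) is the precomputed chord e3 centred at k
    double gx = -P * 0.5 * S.e3y[k];
    double gy = P * 0.5 * S.e3x[k];
    // tension: dS/dx_k = e_prev/|e_prev| - e_next/|e_next|
    gx -= tau * (ex[p] * iel[p] - ex[k] * iel[k]);
    gy -= tau * (ey[p] * iel[p] - ey[k] * iel[k]);
    if (kappa != 0.0) {
      // collect d(H_j^2 ds_j)/dx_k over the triples j = k-1, k, k+1 in
      // which x_k is the next (c), centre (b), and previous (a) vertex;
      // r* denotes dl*/l* so that dl* = r* l*
      double bx = 0.0, by = 0.0;
      const int pp = S.im1[p];
      {                          // j = k-1, role c; edges (pp, p)
        const double H = S.Hj[p], iL = S.iLj[p];
        if (iL != 0.0) {
          const double r2 = iel[p] * iel[p], r3 = S.il3[p] * S.il3[p];
          const double r2x = ex[p] * r2, r2y = ey[p] * r2;
          const double r3x = S.e3x[p] * r3, r3y = S.e3y[p] * r3;
          const double dHx = -2.0 * ey[pp] * iL - H * (r2x + r3x);
          const double dHy = 2.0 * ex[pp] * iL - H * (r2y + r3y);
          const double tds = 2.0 * H * S.dsj[p], h2 = 0.5 * H * H * el[p];
          bx += tds * dHx + h2 * r2x;
          by += tds * dHy + h2 * r2y;
        }
      }
      {                          // j = k, role b; edges (p, k)
        const double H = S.Hj[k], iL = S.iLj[k];
        if (iL != 0.0) {
          const double r1 = iel[p] * iel[p], r2 = iel[k] * iel[k];
          const double r1x = ex[p] * r1, r1y = ey[p] * r1;
          const double r2x = -ex[k] * r2, r2y = -ey[k] * r2;
          const double dHx = 2.0 * S.e3y[k] * iL - H * (r1x + r2x);
          const double dHy = -2.0 * S.e3x[k] * iL - H * (r1y + r2y);
          const double tds = 2.0 * H * S.dsj[k], h2 = 0.5 * H * H;
          bx += tds * dHx + h2 * (r1x * el[p] + r2x * el[k]);
          by += tds * dHy + h2 * (r1y * el[p] + r2y * el[k]);
        }
      }
      {                          // j = k+1, role a; edges (k, q)
        const double H = S.Hj[q], iL = S.iLj[q];
        if (iL != 0.0) {
          const double r1 = iel[k] * iel[k], r3 = S.il3[q] * S.il3[q];
          const double r1x = -ex[k] * r1, r1y = -ey[k] * r1;
          const double r3x = -S.e3x[q] * r3, r3y = -S.e3y[q] * r3;
          const double dHx = -2.0 * ey[q] * iL - H * (r1x + r3x);
          const double dHy = 2.0 * ex[q] * iL - H * (r1y + r3y);
          const double tds = 2.0 * H * S.dsj[q], h2 = 0.5 * H * H * el[k];
          bx += tds * dHx + h2 * r1x;
          by += tds * dHy + h2 * r1y;
        }
      }
      gx -= 2.0 * kappa * bx;
      gy -= 2.0 * kappa * by;
    }
    fx[k] = gx;
    fy[k] = gy;
  }
}

// Reusable buffers for the RK4 integrator (one allocation per move call).
struct RK4Buf {
  std::vector<double> fx, fy, k1x, k1y, k2x, k2y, k3x, k3y, tx, ty;
  ForceScratch S;
};

// One classical RK4 step of dx/dt = zeta * (F_mem(x) + F_fil) over interval
// h, in place.  F_fil is held constant; F_mem is re-evaluated at every
// stage.  Fixed vertices do not move.  Returns the maximum free-vertex
// displacement.
static double rk4_step_vec(std::vector<double>& x, std::vector<double>& y,
                           const std::vector<char>& fixed,
                           const std::vector<double>& ffx,
                           const std::vector<double>& ffy, double P,
                           double tau, double kappa, double zeta, double h,
                           RK4Buf& B) {
  const int n = (int)x.size();
  mem_force_vec(x, y, P, tau, kappa, B.fx, B.fy, B.S, &fixed);
  B.k1x.resize(n); B.k1y.resize(n); B.k2x.resize(n); B.k2y.resize(n);
  B.k3x.resize(n); B.k3y.resize(n); B.tx.resize(n); B.ty.resize(n);
  for (int i = 0; i < n; ++i) {
    B.k1x[i] = fixed[i] ? 0.0 : zeta * (B.fx[i] + ffx[i]);
    B.k1y[i] = fixed[i] ? 0.0 : zeta * (B.fy[i] + ffy[i]);
    B.tx[i] = x[i] + 0.5 * h * B.k1x[i];
    B.ty[i] = y[i] + 0.5 * h * B.k1y[i];
  }
  mem_force_vec(B.tx, B.ty, P, tau, kappa, B.fx, B.fy, B.S, &fixed);
  for (int i = 0; i < n; ++i) {
    B.k2x[i] = fixed[i] ? 0.0 : zeta * (B.fx[i] + ffx[i]);
    B.k2y[i] = fixed[i] ? 0.0 : zeta * (B.fy[i] + ffy[i]);
    B.tx[i] = x[i] + 0.5 * h * B.k2x[i];
    B.ty[i] = y[i] + 0.5 * h * B.k2y[i];
  }
  mem_force_vec(B.tx, B.ty, P, tau, kappa, B.fx, B.fy, B.S, &fixed);
  for (int i = 0; i < n; ++i) {
    B.k3x[i] = fixed[i] ? 0.0 : zeta * (B.fx[i] + ffx[i]);
    B.k3y[i] = fixed[i] ? 0.0 : zeta * (B.fy[i] + ffy[i]);
    B.tx[i] = x[i] + h * B.k3x[i];
    B.ty[i] = y[i] + h * B.k3y[i];
  }
  mem_force_vec(B.tx, B.ty, P, tau, kappa, B.fx, B.fy, B.S, &fixed);
  double maxd2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (fixed[i]) continue;
    const double k4x = zeta * (B.fx[i] + ffx[i]);
    const double k4y = zeta * (B.fy[i] + ffy[i]);
    const double dx = h / 6.0 * (B.k1x[i] + 2.0 * B.k2x[i] + 2.0 * B.k3x[i] + k4x);
    const double dy = h / 6.0 * (B.k1y[i] + 2.0 * B.k2y[i] + 2.0 * B.k3y[i] + k4y);
    x[i] += dx;
    y[i] += dy;
    const double d2 = dx * dx + dy * dy;
    if (d2 > maxd2) maxd2 = d2;
  }
  return std::sqrt(maxd2);
}

// Integrate over h, recursively halving any interval whose maximum
// free-vertex displacement exceeds d_tol.  `hint` pre-splits the interval to
// the depth suggested by the instantaneous velocity, so that most trial
// steps are accepted; the displacement check still guards every accepted
// interval.  Returns the maximum accepted displacement.
static double rk4_adaptive_vec(std::vector<double>& x, std::vector<double>& y,
                               const std::vector<char>& fixed,
                               const std::vector<double>& ffx,
                               const std::vector<double>& ffy, double P,
                               double tau, double kappa, double zeta,
                               double h, double d_tol, int depth,
                               int max_depth, int hint, RK4Buf& B,
                               std::vector<double>& sx,
                               std::vector<double>& sy) {
  if (depth < hint && depth < max_depth) {
    const double d1 = rk4_adaptive_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                       zeta, 0.5 * h, d_tol, depth + 1,
                                       max_depth, hint, B, sx, sy);
    const double d2 = rk4_adaptive_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                       zeta, 0.5 * h, d_tol, depth + 1,
                                       max_depth, hint, B, sx, sy);
    return std::max(d1, d2);
  }
  sx = x;                        // save state for possible rollback
  sy = y;
  const double disp = rk4_step_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                   zeta, h, B);
  if (disp <= d_tol) return disp;
  if (depth >= max_depth)
    stop("membrane integration unstable: displacement %g um above tolerance after %d halvings",
         disp, depth);
  x = sx;                        // roll back and split
  y = sy;
  const double d1 = rk4_adaptive_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                     zeta, 0.5 * h, d_tol, depth + 1,
                                     max_depth, hint, B, sx, sy);
  const double d2 = rk4_adaptive_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                     zeta, 0.5 * h, d_tol, depth + 1,
                                     max_depth, hint, B, sx, sy);
  return std::max(d1, d2);
}

// Full adaptive move over one interval h, with the initial split depth
// estimated from the stage-1 velocity.  Returns the maximum per-interval
// displacement; `net_disp`, when non-null, receives the maximum net
// free-vertex displacement over the whole interval (start to end), the
// quantity relevant for stationarity checks.
static double rk4_move_vec(std::vector<double>& x, std::vector<double>& y,
                           const std::vector<char>& fixed,
                           const std::vector<double>& ffx,
                           const std::vector<double>& ffy, double P,
                           double tau, double kappa, double zeta, double h,
                           double d_tol, int max_depth, RK4Buf& B,
                           std::vector<double>& sx, std::vector<double>& sy,
                           double* net_disp = nullptr, int min_depth = 0) {
  const int n = (int)x.size();
  std::vector<double> x0, y0;
  if (net_disp) { x0 = x; y0 = y; }
  mem_force_vec(x, y, P, tau, kappa, B.fx, B.fy, B.S, &fixed);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (fixed[i]) continue;
    const double vx = zeta * (B.fx[i] + ffx[i]);
    const double vy = zeta * (B.fy[i] + ffy[i]);
    const double v = vx * vx + vy * vy;
    if (v > vmax) vmax = v;
  }
  // Pre-split to the depth suggested by (a) the displacement tolerance at
  // the current peak velocity and (b) linear stability of the stiffest
  // discrete mode (the edge-scale bending zigzag, rate ~ zeta*16*kappa/l^3).
  // Without (b) the splitting is discovered through failed trial steps,
  // which wastes most of the force evaluations; the displacement check
  // still guards every accepted interval.
  if (kappa > 0.0 || tau > 0.0) {
    double lmin = R_PosInf;
    for (int k = 0; k < n; ++k) {
      const int j = k + 1 == n ? 0 : k + 1;
      if (fixed[k] && fixed[j]) continue;
      const double L = B.S.el.empty() ? 0.0 : B.S.el[k];
      if (L > 0.0 && L < lmin) lmin = L;
    }
    if (std::isfinite(lmin)) {
      const double lam = zeta * (16.0 * kappa / (lmin * lmin * lmin) +
                                 4.0 * tau / lmin);
      int d = 0;
      double hs = h;
      // the hint is an optimisation only: cap it and let the displacement
      // rule discover anything deeper (degenerate meshes with very short
      // free-adjacent edges would otherwise explode the pre-split)
      while (lam * hs > 1.2 && d < 8) { hs *= 0.5; ++d; }
      if (d > min_depth) min_depth = d;
    }
  }
  double est = h * std::sqrt(vmax);
  int hint = min_depth;
  est /= (double)(1 << (min_depth > 30 ? 30 : min_depth));
  while (est > d_tol && hint < max_depth) { est *= 0.5; ++hint; }
  const double disp = rk4_adaptive_vec(x, y, fixed, ffx, ffy, P, tau, kappa,
                                       zeta, h, d_tol, 0, max_depth, hint, B,
                                       sx, sy);
  if (net_disp) {
    double m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) continue;
      const double dx = x[i] - x0[i], dy = y[i] - y0[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 > m2) m2 = d2;
    }
    *net_disp = std::sqrt(m2);
  }
  return disp;
}

// ---------------------------------------------------------------------------
// Remeshing on raw vectors
// ---------------------------------------------------------------------------

// Edge-based remeshing: split edges longer than d_max at their midpoint
// (midpoint fixed iff both endpoints fixed), then drop one endpoint of edges
// shorter than d_min (never a fixed vertex; if both are free, the second in
// cyclic order goes).  Repeated until no rule fires.
static bool remesh_vec(std::vector<double>& x, std::vector<double>& y,
                       std::vector<char>& fx, double d_min, double d_max) {
  bool changed_any = false;
  for (int pass = 0; pass < 200; ++pass) {
    bool changed = false;
    {
      std::vector<double> nx, ny;
      std::vector<char> nf;
      const int n = (int)x.size();
      nx.reserve(n + 8); ny.reserve(n + 8); nf.reserve(n + 8);
      for (int k = 0; k < n; ++k) {
        const int j = (k + 1) % n;
        nx.push_back(x[k]); ny.push_back(y[k]); nf.push_back(fx[k]);
        const double L = std::hypot(x[j] - x[k], y[j] - y[k]);
        if (L > d_max) {
          nx.push_back(0.5 * (x[k] + x[j]));
          ny.push_back(0.5 * (y[k] + y[j]));
          nf.push_back((fx[k] && fx[j]) ? 1 : 0);
          changed = true;
        }
      }
      x.swap(nx); y.swap(ny); fx.swap(nf);
    }
    {
      int k = 0;
      while (k < (int)x.size()) {
        const int n = (int)x.size();
        if (n <= 3) {
          // a triangle cannot lose a vertex; a collapse rule that still
          // fires means the caller's polygon has degenerated
          for (int e = 0; e < n; ++e) {
            const int f = (e + 1) % n;
            if (std::hypot(x[f] - x[e], y[f] - y[e]) < d_min && !(fx[e] && fx[f]))
              stop("remeshing would reduce the polygon below 3 vertices");
          }
          break;
        }
        const int j = (k + 1) % n;
        const double L = std::hypot(x[j] - x[k], y[j] - y[k]);
        if (L < d_min && !(fx[k] && fx[j])) {
          int drop;
          if (fx[k]) drop = j;
          else if (fx[j]) drop = k;
          else drop = j;                  // both free: second in cyclic order
          x.erase(x.begin() + drop);
          y.erase(y.begin() + drop);
          fx.erase(fx.begin() + drop);
          changed = true;
          if (drop < k) --k;              // stay on the merged edge
        } else {
          ++k;
        }
      }
    }
    if (!changed) break;
    changed_any = true;
  }
  if ((int)x.size() < 3)
    stop("remeshing reduced the polygon below 3 vertices");
  return changed_any;
}

// ---------------------------------------------------------------------------
// Rcpp interface
// ---------------------------------------------------------------------------

static void mat_to_vec(const NumericMatrix& pos, std::vector<double>& x,
                       std::vector<double>& y) {
  const int n = pos.nrow();
  x.resize(n); y.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
}

static NumericMatrix vec_to_mat(const std::vector<double>& x,
                                const std::vector<double>& y) {
  const int n = (int)x.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return out;
}

// [[Rcpp::export(rng = false)]]
List geom_report_cpp(NumericMatrix pos) {
  const int n = pos.nrow();
  NumericVector edge(n), curv(n), ds(n);
  double slen = 0.0, area = 0.0;
  for (int k = 0; k < n; ++k) {
    const int j = wrap(k + 1, n);
    const double dx = pos(j, 0) - pos(k, 0);
    const double dy = pos(j, 1) - pos(k, 1);
    edge[k] = std::sqrt(dx * dx + dy * dy);
    slen += edge[k];
    area += pos(k, 0) * pos(j, 1) - pos(j, 0) * pos(k, 1);
  }
  for (int k = 0; k < n; ++k) {
    const int p = wrap(k - 1, n), q = wrap(k + 1, n);
    curv[k] = curv3(pos(p, 0), pos(p, 1), pos(k, 0), pos(k, 1),
                    pos(q, 0), pos(q, 1));
    ds[k] = 0.5 * (edge[wrap(k - 1, n)] + edge[k]);
  }
  return List::create(_["area"] = 0.5 * area,
                      _["boundary_length"] = slen,
                      _["curvature"] = curv,
                      _["ds"] = ds,
                      _["edge_lengths"] = edge);
}

// [[Rcpp::export(rng = false)]]
double membrane_energy_cpp(NumericMatrix pos, double P, double tau,
                           double kappa) {
  const int n = pos.nrow();
  double slen = 0.0, bend = 0.0;
  std::vector<double> edge(n);
  for (int k = 0; k < n; ++k) {
    const int j = wrap(k + 1, n);
    const double dx = pos(j, 0) - pos(k, 0);
    const double dy = pos(j, 1) - pos(k, 1);
    edge[k] = std::sqrt(dx * dx + dy * dy);
    slen += edge[k];
  }
  for (int k = 0; k < n; ++k) {
    const int p = wrap(k - 1, n), q = wrap(k + 1, n);
    const double H = curv3(pos(p, 0), pos(p, 1), pos(k, 0), pos(k, 1),
                           pos(q, 0), pos(q, 1));
    const double ds = 0.5 * (edge[wrap(k - 1, n)] + edge[k]);
    bend += H * H * ds;
  }
  std::vector<double> x, y;
  mat_to_vec(pos, x, y);
  return P * shoelace_vec(x, y) + tau * slen + 2.0 * kappa * bend;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix membrane_force_cpp(NumericMatrix pos, double P, double tau,
                                 double kappa) {
  std::vector<double> x, y, fx, fy;
  ForceScratch S;
  mat_to_vec(pos, x, y);
  mem_force_vec(x, y, P, tau, kappa, fx, fy, S);
  return vec_to_mat(fx, fy);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix rk4_move_cpp(NumericMatrix pos, LogicalVector fixed,
                           NumericMatrix ffil, double P, double tau,
                           double kappa, double zeta, double dt, double d_tol,
                           int max_depth) {
  const int n = pos.nrow();
  std::vector<double> x, y, ffx(n), ffy(n), sx, sy;
  std::vector<char> fxd(n);
  mat_to_vec(pos, x, y);
  for (int i = 0; i < n; ++i) {
    ffx[i] = ffil(i, 0);
    ffy[i] = ffil(i, 1);
    fxd[i] = fixed[i] ? 1 : 0;
  }
  RK4Buf B;
  rk4_move_vec(x, y, fxd, ffx, ffy, P, tau, kappa, zeta, dt, d_tol,
               max_depth, B, sx, sy);
  return vec_to_mat(x, y);
}

// [[Rcpp::export(rng = false)]]
List remesh_cpp(NumericMatrix pos, LogicalVector fixed, double d_min,
                double d_max) {
  const int n0 = pos.nrow();
  std::vector<double> x, y;
  std::vector<char> fx(n0);
  mat_to_vec(pos, x, y);
  for (int i = 0; i < n0; ++i) fx[i] = fixed[i] ? 1 : 0;
  const bool changed = remesh_vec(x, y, fx, d_min, d_max);
  const int n = (int)x.size();
  LogicalVector outf(n);
  for (int i = 0; i < n; ++i) outf[i] = fx[i] == 1;
  return List::create(_["positions"] = vec_to_mat(x, y), _["fixed"] = outf,
                      _["changed"] = changed);
}

// Relax the mesh under membrane forces alone (gradient flow to the resting
// shape), remeshing each step, until the per-step maximum free-vertex
// displacement drops below tol.
// [[Rcpp::export(rng = false)]]
List relax_cpp(NumericMatrix pos, LogicalVector fixed, double P, double tau,
               double kappa, double zeta, double dt, double d_tol,
               double d_min, double d_max, double tol, int max_iter,
               int max_depth) {
  const int n0 = pos.nrow();
  std::vector<double> x, y, sx, sy;
  std::vector<char> fx(n0);
  mat_to_vec(pos, x, y);
  for (int i = 0; i < n0; ++i) fx[i] = fixed[i] ? 1 : 0;
  RK4Buf B;
  std::vector<double> zx, zy;
  std::vector<double> areas;
  areas.reserve(max_iter > 0 ? max_iter : 1);
  bool plateau = false;
  double maxdisp = R_PosInf;
  int it = 0;
  for (; it < max_iter; ++it) {
    remesh_vec(x, y, fx, d_min, d_max);
    zx.assign(x.size(), 0.0);
    zy.assign(x.size(), 0.0);
    double net = R_PosInf;
    rk4_move_vec(x, y, fx, zx, zy, P, tau, kappa, zeta, dt, d_tol,
                 max_depth, B, sx, sy, &net);
    maxdisp = net;               // stationarity is judged on net motion per dt
    if (maxdisp < tol) break;
    // Plateau stop: tangential vertex drift and remeshing churn keep the
    // per-step displacement above any tight tolerance indefinitely, while
    // shape and energy are long stationary.  Treat the flow as converged
    // once the enclosed area has stopped moving on a 200-iteration window.
    areas.push_back(shoelace_vec(x, y));
    const int w = 200;
    if ((int)areas.size() >= 2 * w) {
      const int m = (int)areas.size();
      double lo = areas[m - w], hi = lo;
      for (int j = m - w; j < m; ++j) {
        lo = std::min(lo, areas[j]);
        hi = std::max(hi, areas[j]);
      }
      double lo0 = areas[m - 2 * w], hi0 = lo0;
      for (int j = m - 2 * w; j < m - w; ++j) {
        lo0 = std::min(lo0, areas[j]);
        hi0 = std::max(hi0, areas[j]);
      }
      if (hi - lo < 1e-3 && std::fabs(0.5 * (hi + lo) - 0.5 * (hi0 + lo0)) < 1e-3) {
        plateau = true;
        break;
      }
    }
  }
  const int n = (int)x.size();
  LogicalVector outf(n);
  for (int i = 0; i < n; ++i) outf[i] = fx[i] == 1;
  return List::create(_["positions"] = vec_to_mat(x, y), _["fixed"] = outf,
                      _["iterations"] = it + 1, _["max_disp"] = maxdisp,
                      _["converged"] = (maxdisp < tol) || plateau,
                      _["plateau"] = plateau);
}

// ---------------------------------------------------------------------------
// Stochastic actin focus dynamics
// ---------------------------------------------------------------------------

// One time-step of the per-filament event sweep.  Filaments present at the
// start of the step are visited once each, in the order: branch, cap
// (removal), minus-end uncap, sever (removal).  The branch probability is
// dt * gamma0 * exp(-fnorm*delta/(kBT*B)) / B with B frozen at step start;
// daughters enter the minus-capped class and are not visited this step.
static void focus_sweep(int& m_c, int& m_u, double fnorm, double dt,
                        double gamma0, double delta, double kBT, double g_cap,
                        double g_uncap, double g_sever) {
  const int B = m_c + m_u;
  if (B <= 0) return;
  const double rate = gamma0 * std::exp(-fnorm * delta / (kBT * B)) / B;
  const double p_branch = std::min(1.0, dt * rate);
  const double p_cap = std::min(1.0, dt * g_cap);
  const double p_uncap = std::min(1.0, dt * g_uncap);
  const double p_sever = std::min(1.0, dt * g_sever);
  int new_mc = 0;
  // visit the minus-capped class, then the minus-uncapped class
  for (int cls = 0; cls < 2; ++cls) {
    const int count = cls == 0 ? m_c : m_u;
    for (int fidx = 0; fidx < count; ++fidx) {
      bool capped_minus = (cls == 0);
      if (unif_rand() < p_branch) ++new_mc;
      if (unif_rand() < p_cap) {           // barbed end capped -> eliminated
        if (capped_minus) --m_c; else --m_u;
        continue;
      }
      if (capped_minus && unif_rand() < p_uncap) {
        --m_c; ++m_u;
        capped_minus = false;
      }
      if (!capped_minus && unif_rand() < p_sever) {
        --m_u;
      }
    }
  }
  m_c += new_mc;
}

// [[Rcpp::export]]
IntegerVector step_focus_cpp(int m_c, int m_u, double fnorm, double dt,
                             double gamma0, double delta, double kBT,
                             double g_cap, double g_uncap, double g_sever) {
  focus_sweep(m_c, m_u, fnorm, dt, gamma0, delta, kBT, g_cap, g_uncap,
              g_sever);
  return IntegerVector::create(m_c, m_u);
}

// [[Rcpp::export]]
List simulate_focus_cpp(int B0, double fnorm, double dt, double gamma0,
                        double delta, double kBT, double g_cap, double g_uncap,
                        double g_sever, int max_steps, bool record) {
  int m_c = B0, m_u = 0;
  std::vector<int> trace;
  if (record) trace.reserve(1024);
  long double bsum = 0.0;
  int steps = 0;
  bool died = false;
  while (steps < max_steps) {
    focus_sweep(m_c, m_u, fnorm, dt, gamma0, delta, kBT, g_cap, g_uncap,
                g_sever);
    ++steps;
    const int B = m_c + m_u;
    if (record) trace.push_back(B);
    if (B == 0) { died = true; break; }
    bsum += B;
  }
  const int alive_steps = died ? steps - 1 : steps;
  const double mean_b = alive_steps > 0 ? (double)(bsum / alive_steps) : 0.0;
  return List::create(_["lifetime"] = steps * dt, _["died"] = died,
                      _["mean_B"] = mean_b,
                      _["trace"] = record ? wrap(trace) : R_NilValue);
}

// ---------------------------------------------------------------------------
// Geometry queries for focus nucleation
// ---------------------------------------------------------------------------

static bool point_in_poly(const NumericMatrix& pos, double px, double py) {
  const int n = pos.nrow();
  bool inside = false;
  for (int k = 0, j = n - 1; k < n; j = k++) {
    const double xi = pos(k, 0), yi = pos(k, 1);
    const double xj = pos(j, 0), yj = pos(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

static double dist_seg(double px, double py, double ax, double ay, double bx,
                       double by) {
  const double dx = bx - ax, dy = by - ay;
  const double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) t = std::max(0.0, std::min(1.0, ((px - ax) * dx + (py - ay) * dy) / L2));
  return std::hypot(px - (ax + t * dx), py - (ay + t * dy));
}

static double dist_boundary(const NumericMatrix& pos, double px, double py) {
  const int n = pos.nrow();
  double d = R_PosInf;
  for (int k = 0; k < n; ++k) {
    const int j = (k + 1) % n;
    const double dk = dist_seg(px, py, pos(k, 0), pos(k, 1), pos(j, 0), pos(j, 1));
    if (dk < d) d = dk;
  }
  return d;
}

// Uniform candidate points inside the polygon (rejection sampling in the
// bounding box), with distances to the membrane boundary and to the PSD
// segment.  Used by the nucleation rule.
// [[Rcpp::export]]
List candidate_points_cpp(NumericMatrix pos, int n_cand, double psd_ax,
                          double psd_ay, double psd_bx, double psd_by) {
  const int n = pos.nrow();
  double xmin = pos(0, 0), xmax = xmin, ymin = pos(0, 1), ymax = ymin;
  for (int k = 1; k < n; ++k) {
    xmin = std::min(xmin, pos(k, 0)); xmax = std::max(xmax, pos(k, 0));
    ymin = std::min(ymin, pos(k, 1)); ymax = std::max(ymax, pos(k, 1));
  }
  NumericMatrix pts(n_cand, 2);
  NumericVector d_mem(n_cand), d_psd(n_cand);
  int got = 0;
  long tries = 0;
  const long max_tries = 1000L * (long)n_cand + 10000L;
  while (got < n_cand && tries < max_tries) {
    ++tries;
    const double px = xmin + unif_rand() * (xmax - xmin);
    const double py = ymin + unif_rand() * (ymax - ymin);
    if (!point_in_poly(pos, px, py)) continue;
    pts(got, 0) = px;
    pts(got, 1) = py;
    d_mem[got] = dist_boundary(pos, px, py);
    d_psd[got] = dist_seg(px, py, psd_ax, psd_ay, psd_bx, psd_by);
    ++got;
  }
  if (got < n_cand) {
    pts = pts(Range(0, std::max(0, got - 1)), _);
    d_mem = head(d_mem, got);
    d_psd = head(d_psd, got);
  }
  return List::create(_["points"] = pts, _["d_membrane"] = d_mem,
                      _["d_psd"] = d_psd);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix actin_force_cpp(NumericMatrix pos, NumericMatrix centers,
                              NumericMatrix xn, IntegerVector B, double alpha,
                              double sigma) {
  const int n = pos.nrow();
  const int nf = centers.nrow();
  NumericMatrix out(n, 2);
  const double w0 = alpha / (sigma * std::sqrt(2.0 * M_PI));
  for (int i = 0; i < nf; ++i) {
    for (int k = 0; k < n; ++k) {
      const double dcx = pos(k, 0) - centers(i, 0);
      const double dcy = pos(k, 1) - centers(i, 1);
      const double d2 = dcx * dcx + dcy * dcy;
      const double w = w0 * std::exp(-d2 / (2.0 * sigma * sigma));
      const double vx = pos(k, 0) - xn(i, 0);
      const double vy = pos(k, 1) - xn(i, 1);
      const double vn = std::sqrt(vx * vx + vy * vy);
      if (vn == 0.0) continue;            // vertex coincides with X_n
      out(k, 0) += w * B[i] * vx / vn;
      out(k, 1) += w * B[i] * vy / vn;
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
LogicalVector points_in_polygon_cpp(NumericMatrix pos, NumericMatrix pts) {
  const int m = pts.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = point_in_poly(pos, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector dist_to_boundary_cpp(NumericMatrix pos, NumericMatrix pts) {
  const int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = dist_boundary(pos, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector dist_to_segment_cpp(NumericMatrix pts, double ax, double ay,
                                  double bx, double by) {
  const int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = dist_seg(pts(i, 0), pts(i, 1), ax, ay, bx, by);
  return out;
}
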