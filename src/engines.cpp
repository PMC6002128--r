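#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tridiagonal (Thomas) solver with reusable factorization. The implicit
// diffusion operators are constant in time, so forward-elimination
// coefficients are computed once and reused every step.
// ---------------------------------------------------------------------------
struct Tridiag {
  int n;
  std::vector<double> sub, cp, denom; // cp: modified upper diag
  void factor(const std::vector<double>& lo, const std::vector<double>& di,
              const std::vector<double>& up) {
    n = (int)di.size();
    sub = lo; cp.resize(n); denom.resize(n);
    denom[0] = di[0]; cp[0] = up[0] / denom[0];
    for (int i = 1; i < n; ++i) {
      denom[i] = di[i] - lo[i] * cp[i - 1];
      if (i < n - 1) cp[i] = up[i] / denom[i];
    }
  }
  void solve(double* d) const {
    d[0] /= denom[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] - sub[i] * d[i - 1]) / denom[i];
    for (int i = n - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
  }
};

// One-shot Thomas for matrices rebuilt every step (reduced model).
static void thomas_once(std::vector<double>& lo, std::vector<double>& di,
                        std::vector<double>& up, double* d, int n) {
  for (int i = 1; i < n; ++i) {
    double w = lo[i] / di[i - 1];
    di[i] -= w * up[i - 1];
    d[i]  -= w * d[i - 1];
  }
  d[n - 1] /= di[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - up[i] * d[i + 1]) / di[i];
}

// Finite-volume no-flux diffusion factors on a node/cell grid.
// geometry 0: Cartesian, volumes vol[i]; face areas fa[i] (i = 0..n, outer
// faces have fa = 0 so no-flux is automatic).
static void build_diffusion(Tridiag& T, double Dc, double dt, double dx,
                            const std::vector<double>& vol,
                            const std::vector<double>& fa, double decay) {
  int n = (int)vol.size();
  std::vector<double> lo(n, 0.0), di(n, 0.0), up(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double aw = Dc * fa[i] / dx;       // face i (between i-1 and i)
    double ae = Dc * fa[i + 1] / dx;   // face i+1
    lo[i] = -dt * aw / vol[i];
    up[i] = -dt * ae / vol[i];
    di[i] = 1.0 + dt * (aw + ae) / vol[i] + dt * decay;
  }
  T.factor(lo, di, up);
}

static double interp1(const std::vector<double>& xg,
                      const std::vector<double>& yg, double x) {
  int n = (int)xg.size();
  if (x <= xg[0]) return yg[0];
  if (x >= xg[n - 1]) return yg[n - 1];
  double t = (x - xg[0]) / (xg[1] - xg[0]); // uniform grid
  int i = (int)t;
  if (i > n - 2) i = n - 2;
  double f = t - i;
  return yg[i] * (1 - f) + yg[i + 1] * f;
}

// ---------------------------------------------------------------------------
// Velocity-jump ensemble with frozen switching rates: mean squared
// displacement oracle for the effective-diffusion formula. d = 1 or 2.
// Returns a matrix (time, msd, moving_fraction).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix vj_msd_cpp(int n_agents, double T, double dt, double lam,
                         double mu, double s0, int d, int n_record) {
  std::vector<double> x(n_agents, 0.0), y(n_agents, 0.0);
  std::vector<double> cx(n_agents), cy(n_agents, 0.0);
  std::vector<int> moving(n_agents, 1);
  for (int i = 0; i < n_agents; ++i) {
    if (d == 1) cx[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
    else { double th = 2 * M_PI * unif_rand(); cx[i] = cos(th); cy[i] = sin(th); }
  }
  int nsteps = (int)std::round(T / dt);
  int every = nsteps / n_record; if (every < 1) every = 1;
  double pl = 1.0 - std::exp(-lam * dt), pm = 1.0 - std::exp(-mu * dt);
  NumericMatrix out(n_record, 3);
  int rec = 0;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n_agents; ++i) {
      if (moving[i]) {
        x[i] += s0 * cx[i] * dt;
        if (d == 2) y[i] += s0 * cy[i] * dt;
        if (unif_rand() < pl) moving[i] = 0;
      } else if (unif_rand() < pm) {
        moving[i] = 1;
        if (d == 1) cx[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
        else { double th = 2 * M_PI * unif_rand(); cx[i] = cos(th); cy[i] = sin(th); }
      }
    }
    if (s % every == 0 && rec < n_record) {
      double msd = 0.0; int nm = 0;
      for (int i = 0; i < n_agents; ++i) {
        msd += x[i] * x[i] + y[i] * y[i];
        nm += moving[i];
      }
      out(rec, 0) = s * dt;
      out(rec, 1) = msd / n_agents;
      out(rec, 2) = (double)nm / n_agents;
      ++rec;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 1D hybrid simulator. Cells carry (x, dir, moving, z); methylation is at
// its quasi-steady level so the switching rates are tabulated functions of
// z alone. Fields h, n live on a node-centred grid over [-L, L] with
// no-flux boundaries; implicit diffusion; nearest-node delta deposition.
// Outer loop at dt_field: internal update -> motion substeps -> division ->
// field update. Snapshots at the requested outer-step indices.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List hybrid_run_cpp(NumericVector x0, NumericVector dir0,
                    IntegerVector moving0, NumericVector z0,
                    double L, double dx,
                    NumericVector ztab, NumericVector lamtab,
                    NumericVector mutab,
                    double s0, double Zw, double h0_thresh,
                    double r, double Dh, double Dn, double alpha_d,
                    double beta, double gamma_d,
                    double dt_motion, double dt_field, double T_end,
                    IntegerVector snap_steps, bool freeze_internal,
                    bool no_growth) {
  int M = (int)std::round(2 * L / dx) + 1;
  std::vector<double> h(M, 0.0), n(M, 1.0);
  std::vector<double> vol(M, dx), fa(M + 1, 1.0);
  vol[0] = vol[M - 1] = dx / 2; fa[0] = fa[M] = 0.0;
  Tridiag Th, Tn;
  build_diffusion(Th, Dh, dt_field, dx, vol, fa, 0.0);
  build_diffusion(Tn, Dn, dt_field, dx, vol, fa, 0.0);
  double hdecay = std::exp(-beta * dt_field);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> dir(dir0.begin(), dir0.end());
  std::vector<int> moving(moving0.begin(), moving0.end());
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> zg(ztab.begin(), ztab.end());
  std::vector<double> lamg(lamtab.begin(), lamtab.end());
  std::vector<double> mug(mutab.begin(), mutab.end());

  int nsteps = (int)std::round(T_end / dt_field);
  int nsub = (int)std::round(dt_field / dt_motion);
  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  List out;

  std::vector<double> pl, pm;
  std::vector<int> node;
  std::vector<double> counts(M);

  auto take_snapshot = [&](int step) {
    out.push_back(List::create(
      _["t"] = step * dt_field,
      _["x"] = NumericVector(x.begin(), x.end()),
      _["dir"] = NumericVector(dir.begin(), dir.end()),
      _["moving"] = IntegerVector(moving.begin(), moving.end()),
      _["z"] = NumericVector(z.begin(), z.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["n"] = NumericVector(n.begin(), n.end())));
  };
  if (snaps.count(0)) take_snapshot(0);

  for (int step = 1; step <= nsteps; ++step) {
    size_t N = x.size();
    node.resize(N); pl.resize(N); pm.resize(N);
    // internal states + per-cell switching probabilities for this window
    for (size_t i = 0; i < N; ++i) {
      int j = (int)std::lround((x[i] + L) / dx);
      if (j < 0) j = 0; if (j > M - 1) j = M - 1;
      node[i] = j;
      double kV = r * n[j];
      if (!freeze_internal) {
        double e = std::exp(-kV * dt_field);
        z[i] = (h[j] < h0_thresh) ? Zw + (z[i] - Zw) * e : z[i] * e;
      }
      double lam = interp1(zg, lamg, z[i]);
      double mu  = interp1(zg, mug,  z[i]);
      pl[i] = 1.0 - std::exp(-lam * dt_motion);
      pm[i] = 1.0 - std::exp(-mu * dt_motion);
    }
    // velocity-jump motion
    for (int s = 0; s < nsub; ++s) {
      for (size_t i = 0; i < N; ++i) {
        if (moving[i]) {
          x[i] += s0 * dir[i] * dt_motion;
          if (x[i] > L)  { x[i] = 2 * L - x[i];  dir[i] = -dir[i]; }
          if (x[i] < -L) { x[i] = -2 * L - x[i]; dir[i] = -dir[i]; }
          if (unif_rand() < pl[i]) moving[i] = 0;
        } else if (unif_rand() < pm[i]) {
          moving[i] = 1;
          dir[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
        }
      }
    }
    // division: exact Bernoulli for a Poisson event in dt_field
    if (!no_growth) {
      for (size_t i = 0; i < N; ++i) {
        double kV = r * n[node[i]];
        if (unif_rand() < 1.0 - std::exp(-kV * dt_field)) {
          x.push_back(x[i]);
          dir.push_back((unif_rand() < 0.5) ? -1.0 : 1.0);
          moving.push_back(moving[i]);
          z.push_back(z[i]);
        }
      }
    }
    // fields: deposit, consume, diffuse/decay implicitly
    std::fill(counts.begin(), counts.end(), 0.0);
    for (size_t i = 0; i < x.size(); ++i) {
      int j = (int)std::lround((x[i] + L) / dx);
      if (j < 0) j = 0; if (j > M - 1) j = M - 1;
      counts[j] += 1.0;
    }
    for (int j = 0; j < M; ++j) {
      h[j] = (h[j] + dt_field * alpha_d * counts[j] / vol[j]) * hdecay;
      n[j] *= std::exp(-gamma_d * counts[j] / vol[j] * dt_field);
    }
    Th.solve(h.data());
    Tn.solve(n.data());
    for (int j = 0; j < M; ++j) {
      if (h[j] < 0 && h[j] > -1e-12) h[j] = 0;
      if (h[j] < 0 || n[j] < 0) stop("hybrid field step produced negative concentration");
    }
    if (snaps.count(step)) take_snapshot(step);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean-field PDE engine for rho^z(x, z, t) coupled to h, n.
// geometry 0: Cartesian on [-L, L]; 1: radially symmetric on (0, R].
// Operator-split IMEX step: implicit space diffusion per z-level,
// conservative first-order upwind advection in z with velocity kappa*g(z,h),
// exact exponential growth factor, then field update.
// rho is stored column-major as Nx x Nz.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List pde_run_cpp(NumericMatrix rho_init, NumericVector h_init,
                 NumericVector n_init,
                 int geometry, double dx, NumericVector zc,
                 NumericVector Dz, double kappa, double r, double Zw,
                 double h0_thresh, double Dh, double Dn, double alpha,
                 double beta, double gamma, double dt, int nsteps,
                 IntegerVector snap_steps, bool store_rhoz) {
  int Nx = rho_init.nrow(), Nz = rho_init.ncol();
  double dz = (Nz > 1) ? (zc[1] - zc[0]) : 1.0;

  // geometry: volumes and face areas
  std::vector<double> vol(Nx), fa(Nx + 1);
  if (geometry == 0) {
    for (int i = 0; i < Nx; ++i) vol[i] = dx;
    for (int i = 0; i <= Nx; ++i) fa[i] = 1.0;
    fa[0] = fa[Nx] = 0.0;
  } else {
    for (int i = 0; i < Nx; ++i) vol[i] = (i + 0.5) * dx * dx; // xi_i * dx
    for (int i = 0; i <= Nx; ++i) fa[i] = i * dx;              // face radius
    fa[Nx] = 0.0;  // no-flux at the outer wall
  }

  std::vector<Tridiag> Trho(Nz);
  for (int j = 0; j < Nz; ++j)
    build_diffusion(Trho[j], Dz[j], dt, dx, vol, fa, 0.0);
  Tridiag Th, Tn;
  build_diffusion(Th, Dh, dt, dx, vol, fa, 0.0);
  build_diffusion(Tn, Dn, dt, dx, vol, fa, 0.0);
  double hdecay = std::exp(-beta * dt);

  std::vector<double> rho(Nx * (size_t)Nz);
  for (int j = 0; j < Nz; ++j)
    for (int i = 0; i < Nx; ++i) rho[j * (size_t)Nx + i] = rho_init(i, j);
  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> n(n_init.begin(), n_init.end());
  std::vector<double> col(Nx), flux(Nz + 1), rhobar(Nx);

  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  List out;
  auto marginal = [&](void) {
    for (int i = 0; i < Nx; ++i) {
      double s = 0;
      for (int j = 0; j < Nz; ++j) s += rho[j * (size_t)Nx + i];
      rhobar[i] = s * dz;
    }
  };
  auto take_snapshot = [&](int step) {
    marginal();
    List sn = List::create(
      _["t"] = step * dt,
      _["rho"] = NumericVector(rhobar.begin(), rhobar.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["n"] = NumericVector(n.begin(), n.end()));
    if (store_rhoz) {
      NumericMatrix rz(Nx, Nz);
      for (int j = 0; j < Nz; ++j)
        for (int i = 0; i < Nx; ++i) rz(i, j) = rho[j * (size_t)Nx + i];
      sn["rho_z"] = rz;
    }
    out.push_back(sn);
  };
  if (snaps.count(0)) take_snapshot(0);

  for (int step = 1; step <= nsteps; ++step) {
    // (i) implicit spatial diffusion, one tridiagonal solve per z-level
    for (int j = 0; j < Nz; ++j) Trho[j].solve(&rho[j * (size_t)Nx]);
    // (ii) conservative upwind advection in z, zero flux at both z ends
    for (int i = 0; i < Nx; ++i) {
      double kV = r * n[i];
      bool on = h[i] < h0_thresh;
      flux[0] = flux[Nz] = 0.0;
      for (int f = 1; f < Nz; ++f) {
        double zf = zc[0] - 0.5 * dz + f * dz;
        double v = kappa * (on ? kV * (Zw - zf) : -kV * zf);
        flux[f] = (v > 0) ? v * rho[(f - 1) * (size_t)Nx + i]
                          : v * rho[f * (size_t)Nx + i];
      }
      for (int j = 0; j < Nz; ++j)
        rho[j * (size_t)Nx + i] -= dt / dz * (flux[j + 1] - flux[j]);
    }
    // (iii) growth (exact exponential factor per step)
    if (r > 0) {
      for (int i = 0; i < Nx; ++i) {
        double gfac = std::exp(r * n[i] * dt);
        for (int j = 0; j < Nz; ++j) rho[j * (size_t)Nx + i] *= gfac;
      }
    }
    // (iv) AHL and nutrient
    marginal();
    for (int i = 0; i < Nx; ++i) {
      h[i] = (h[i] + dt * alpha * rhobar[i]) * hdecay;
      n[i] *= std::exp(-gamma * rhobar[i] * dt);
    }
    Th.solve(h.data());
    Tn.solve(n.data());

    if ((step & 63) == 0) {
      double mn = 0;
      for (size_t k = 0; k < rho.size(); ++k) if (rho[k] < mn) mn = rho[k];
      if (mn < -1e-12) stop("pde step produced negative density (%g)", mn);
    }
    if (snaps.count(step)) take_snapshot(step);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Reduced switch-diffusivity model: d rho / dt = Lap(Dbar(h) rho) + r n rho,
// Dbar = D(Zw) below the AHL threshold and D(0) above it. Note the flux is
// grad(Dbar * rho), not Dbar * grad(rho); the tridiagonal system is rebuilt
// each step because Dbar follows h.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List reduced_run_cpp(NumericVector rho_init, NumericVector h_init,
                     NumericVector n_init, int geometry, double dx,
                     double D_on, double D_off, double r,
                     double h0_thresh, double Dh, double Dn, double alpha,
                     double beta, double gamma, double dt, int nsteps,
                     IntegerVector snap_steps) {
  int Nx = rho_init.size();
  std::vector<double> vol(Nx), fa(Nx + 1);
  if (geometry == 0) {
    for (int i = 0; i < Nx; ++i) vol[i] = dx;
    for (int i = 0; i <= Nx; ++i) fa[i] = 1.0;
    fa[0] = fa[Nx] = 0.0;
  } else {
    for (int i = 0; i < Nx; ++i) vol[i] = (i + 0.5) * dx * dx;
    for (int i = 0; i <= Nx; ++i) fa[i] = i * dx;
    fa[Nx] = 0.0;
  }
  Tridiag Th, Tn;
  build_diffusion(Th, Dh, dt, dx, vol, fa, 0.0);
  build_diffusion(Tn, Dn, dt, dx, vol, fa, 0.0);
  double hdecay = std::exp(-beta * dt);

  std::vector<double> rho(rho_init.begin(), rho_init.end());
  std::vector<double> h(h_init.begin(), h_init.end());
  std::vector<double> n(n_init.begin(), n_init.end());
  std::vector<double> Dbar(Nx), lo(Nx), di(Nx), up(Nx);
  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  List out;
  auto take_snapshot = [&](int step) {
    out.push_back(List::create(
      _["t"] = step * dt,
      _["rho"] = NumericVector(rho.begin(), rho.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["n"] = NumericVector(n.begin(), n.end())));
  };
  if (snaps.count(0)) take_snapshot(0);

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < Nx; ++i) Dbar[i] = (h[i] < h0_thresh) ? D_on : D_off;
    // implicit solve of rho_new - dt * Lap(Dbar rho_new) = rho_old
    for (int i = 0; i < Nx; ++i) {
      double aw = fa[i] / dx, ae = fa[i + 1] / dx;
      lo[i] = (i > 0) ? -dt * aw * Dbar[i - 1] / vol[i] : 0.0;
      up[i] = (i < Nx - 1) ? -dt * ae * Dbar[i + 1] / vol[i] : 0.0;
      di[i] = 1.0 + dt * (aw + ae) * Dbar[i] / vol[i];
    }
    thomas_once(lo, di, up, rho.data(), Nx);
    if (r > 0)
      for (int i = 0; i < Nx; ++i) rho[i] *= std::exp(r * n[i] * dt);
    for (int i = 0; i < Nx; ++i) {
      h[i] = (h[i] + dt * alpha * rho[i]) * hdecay;
      n[i] *= std::exp(-gamma * rho[i] * dt);
    }
    Th.solve(h.data());
    Tn.solve(n.data());
    if (snaps.count(step)) take_snapshot(step);
  }
  return out;
}
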