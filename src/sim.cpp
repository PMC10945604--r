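#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimum-image displacement component for box length L.
static inline double min_image(double dx, double L) {
  dx -= L * std::round(dx / L);
  return dx;
}

// Hertz force magnitude for overlap h between disks of radii Ri, Rj.
// F = h^{3/2} / [ (3/2) ((1-nu^2)/E) sqrt(1/Ri + 1/Rj) ]
static inline double hertz_mag(double h, double Ri, double Rj,
                               double E, double nu) {
  if (h <= 0.0) return 0.0;
  const double pref = 1.5 * (1.0 - nu * nu) / E;
  return h * std::sqrt(h) / (pref * std::sqrt(1.0 / Ri + 1.0 / Rj));
}

// Internal state for the force loop: flat arrays + reusable cell list.
struct ForceWork {
  int N;
  double L, E, nu;
  std::vector<double> x, y, r;     // positions (wrapped), radii
  std::vector<double> fx, fy;
  std::vector<int> head, nxt;
  double pxy, pyx;

  ForceWork(int N_, double L_, double E_, double nu_)
    : N(N_), L(L_), E(E_), nu(nu_), x(N_), y(N_), r(N_),
      fx(N_), fy(N_), nxt(N_) {}

  // forces + off-diagonal virial with radii scaled by rs
  void compute(double rs) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    pxy = 0.0; pyx = 0.0;
    double rmax = 0.0;
    for (int i = 0; i < N; ++i) rmax = std::max(rmax, r[i]);
    rmax *= rs;
    double cutoff = 2.0 * rmax;
    int nc = (int)std::floor(L / cutoff);
    if (nc >= 3) {
      double cw = L / nc;
      head.assign(nc * nc, -1);
      for (int i = 0; i < N; ++i) {
        int cx = (int)(x[i] / cw); if (cx >= nc) cx = nc - 1;
        int cy = (int)(y[i] / cw); if (cy >= nc) cy = nc - 1;
        int c = cy * nc + cx;
        nxt[i] = head[c]; head[c] = i;
      }
      for (int cy = 0; cy < nc; ++cy) for (int cx = 0; cx < nc; ++cx) {
        int c = cy * nc + cx;
        for (int i = head[c]; i >= 0; i = nxt[i]) {
          for (int j = nxt[i]; j >= 0; j = nxt[j]) pair(i, j, rs);
          static const int offs[4][2] = { {1, 0}, {-1, 1}, {0, 1}, {1, 1} };
          for (int k = 0; k < 4; ++k) {
            int nx2 = cx + offs[k][0]; if (nx2 < 0) nx2 += nc; else if (nx2 >= nc) nx2 -= nc;
            int ny2 = cy + offs[k][1]; if (ny2 >= nc) ny2 -= nc;
            for (int j = head[ny2 * nc + nx2]; j >= 0; j = nxt[j])
              pair(i, j, rs);
          }
        }
      }
    } else {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) pair(i, j, rs);
    }
    double A = L * L;
    pxy /= A; pyx /= A;
  }

  inline void pair(int i, int j, double rs) {
    double dx = min_image(x[i] - x[j], L);
    double dy = min_image(y[i] - y[j], L);
    double Ri = r[i] * rs, Rj = r[j] * rs;
    double sum = Ri + Rj;
    double d2 = dx * dx + dy * dy;
    if (d2 >= sum * sum) return;
    double d = std::sqrt(d2);
    double h = sum - d;
    if (h <= 0.0) return;
    if (d == 0.0) stop("coincident cell centers (overlapping pair with d = 0)");
    double fm = hertz_mag(h, Ri, Rj, E, nu) / d;
    double px = fm * dx, py = fm * dy;   // force on i, along j -> i
    fx[i] += px; fy[i] += py;
    fx[j] -= px; fy[j] -= py;
    // virial: r_ij,mu f_ij,nu summed over i<j (f_ij = force on i from j)
    pxy += dx * py;
    pyx += dy * px;
  }
};

// [[Rcpp::export]]
List forces_stress_cpp(NumericMatrix pos, NumericVector radii,
                       double L, double E, double nu) {
  int N = pos.nrow();
  ForceWork w(N, L, E, nu);
  for (int i = 0; i < N; ++i) {
    w.x[i] = pos(i, 0); w.y[i] = pos(i, 1); w.r[i] = radii[i];
  }
  w.compute(1.0);
  NumericMatrix F(N, 2);
  for (int i = 0; i < N; ++i) { F(i, 0) = w.fx[i]; F(i, 1) = w.fy[i]; }
  return List::create(_["forces"] = F, _["pxy"] = w.pxy, _["pyx"] = w.pyx);
}

// Overdamped Euler-Maruyama production/equilibration loop.
// dr_i = F_i/(gamma0 R_i) dt + mu sqrt(dt) xi_i, xi ~ N(0, I2).
// Records a frame every save_every steps (frame 0 = initial state).
// [[Rcpp::export]]
List simulate_cpp(NumericMatrix pos0, NumericVector radii,
                  double L, double E, double nu,
                  double gamma0, double mu, double dt,
                  int n_steps, int save_every, double max_disp,
                  double t0 = 0.0, int stress_every = 1) {
  int N = pos0.nrow();
  ForceWork w(N, L, E, nu);
  std::vector<double> ux(N), uy(N), mob(N);
  for (int i = 0; i < N; ++i) {
    w.x[i] = pos0(i, 0); w.y[i] = pos0(i, 1); w.r[i] = radii[i];
    ux[i] = w.x[i]; uy[i] = w.y[i];
    mob[i] = dt / (gamma0 * radii[i]);
  }
  int n_frames = (save_every > 0 && n_steps > 0) ? n_steps / save_every + 1 : 1;
  if (stress_every < 1) stress_every = 1;
  int n_stress = n_steps / stress_every + 1;

  NumericVector times(n_frames);
  NumericVector stress_xy(n_stress);
  NumericVector wr(N * 2 * n_frames), uw(N * 2 * n_frames);  // N x 2 x F
  double sdt = mu * std::sqrt(dt);

  auto record = [&](int f, double t) {
    times[f] = t;
    double* wp = REAL(wr) + (size_t)f * 2 * N;
    double* up = REAL(uw) + (size_t)f * 2 * N;
    for (int i = 0; i < N; ++i) {
      wp[i] = w.x[i]; wp[N + i] = w.y[i];
      up[i] = ux[i];  up[N + i] = uy[i];
    }
  };

  GetRNGstate();
  w.compute(1.0);
  record(0, t0);
  stress_xy[0] = w.pxy;
  int f = 1;
  for (int s = 1; s <= n_steps; ++s) {
    if (s > 1) {
      w.compute(1.0);
      // config after s-1 moves
      if ((s - 1) % stress_every == 0)
        stress_xy[(s - 1) / stress_every] = w.pxy;
    }
    for (int i = 0; i < N; ++i) {
      double dx = w.fx[i] * mob[i] + sdt * norm_rand();
      double dy = w.fy[i] * mob[i] + sdt * norm_rand();
      if (std::fabs(dx) > max_disp || std::fabs(dy) > max_disp) {
        PutRNGstate();
        stop("per-step displacement exceeded %.3g um at step %d: dt too large for this configuration", max_disp, s);
      }
      ux[i] += dx; uy[i] += dy;
      double xx = w.x[i] + dx, yy = w.y[i] + dy;
      xx -= L * std::floor(xx / L);
      yy -= L * std::floor(yy / L);
      w.x[i] = xx; w.y[i] = yy;
    }
    if (save_every > 0 && s % save_every == 0 && f < n_frames) {
      record(f, t0 + s * dt);
      ++f;
    }
  }
  if (n_steps > 0) {
    w.compute(1.0);
    if (n_steps % stress_every == 0)
      stress_xy[n_steps / stress_every] = w.pxy;
  }
  PutRNGstate();

  NumericMatrix fin(N, 2), finu(N, 2);
  for (int i = 0; i < N; ++i) {
    fin(i, 0) = w.x[i]; fin(i, 1) = w.y[i];
    finu(i, 0) = ux[i]; finu(i, 1) = uy[i];
  }
  wr.attr("dim") = IntegerVector::create(N, 2, n_frames);
  uw.attr("dim") = IntegerVector::create(N, 2, n_frames);
  return List::create(_["times"] = times, _["stress_xy"] = stress_xy,
                      _["pos_wrapped"] = wr, _["pos_unwrapped"] = uw,
                      _["final_wrapped"] = fin, _["final_unwrapped"] = finu);
}

// Zero-noise relaxation with the radii linearly ramped from
// ramp_from * R to R over the first n_ramp steps; per-step displacements
// are capped (not an error) because the start may be an arbitrary random
// placement with severe overlaps.
// [[Rcpp::export]]
NumericMatrix relax_cpp(NumericMatrix pos0, NumericVector radii,
                        double L, double E, double nu,
                        double gamma0, double dt,
                        int n_steps, int n_ramp, double ramp_from,
                        double cap) {
  int N = pos0.nrow();
  ForceWork w(N, L, E, nu);
  std::vector<double> mob(N);
  for (int i = 0; i < N; ++i) {
    w.x[i] = pos0(i, 0); w.y[i] = pos0(i, 1); w.r[i] = radii[i];
    mob[i] = dt / (gamma0 * radii[i]);
  }
  for (int s = 1; s <= n_steps; ++s) {
    double rs = (s >= n_ramp) ? 1.0
      : ramp_from + (1.0 - ramp_from) * (double)s / (double)n_ramp;
    w.compute(rs);
    for (int i = 0; i < N; ++i) {
      double dx = w.fx[i] * mob[i], dy = w.fy[i] * mob[i];
      double m = std::max(std::fabs(dx), std::fabs(dy));
      if (m > cap) { dx *= cap / m; dy *= cap / m; }
      double xx = w.x[i] + dx, yy = w.y[i] + dy;
      xx -= L * std::floor(xx / L);
      yy -= L * std::floor(yy / L);
      w.x[i] = xx; w.y[i] = yy;
    }
  }
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = w.x[i]; out(i, 1) = w.y[i]; }
  return out;
}

// Histogram counts of all minimum-image pair distances below r_max.
// [[Rcpp::export]]
NumericVector gr_counts_cpp(NumericMatrix pos, double L,
                            double bin_width, double r_max) {
  int N = pos.nrow();
  int nb = (int)std::ceil(r_max / bin_width);
  NumericVector counts(nb);
  for (int i = 0; i < N; ++i) for (int j = i + 1; j < N; ++j) {
    double dx = min_image(pos(i, 0) - pos(j, 0), L);
    double dy = min_image(pos(i, 1) - pos(j, 1), L);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < r_max) {
      int b = (int)(d / bin_width);
      if (b >= 0 && b < nb) counts[b] += 2.0;  // ordered pairs
    }
  }
  return counts;
}

// Positive pair overlaps h_ij = max(0, Ri + Rj - d_ij) over all pairs.
// [[Rcpp::export]]
NumericVector overlaps_cpp(NumericMatrix pos, NumericVector radii, double L) {
  int N = pos.nrow();
  std::vector<double> out;
  for (int i = 0; i < N; ++i) for (int j = i + 1; j < N; ++j) {
    double dx = min_image(pos(i, 0) - pos(j, 0), L);
    double dy = min_image(pos(i, 1) - pos(j, 1), L);
    double d = std::sqrt(dx * dx + dy * dy);
    double h = radii[i] + radii[j] - d;
    if (h > 0.0) out.push_back(h);
  }
  return wrap(out);
}
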