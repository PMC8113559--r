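#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flat parameter block shared by the force kernel and the integrator.
// Order must match engine_par() on the R side.
struct Par {
  double A_f, B_f, omega, k_f, h, L;   // flow
  double R, m, k, DA, B, delta0, mu, r_cut; // mechanics
};

static Par unpack(const NumericVector& p) {
  Par q;
  q.A_f = p[0]; q.B_f = p[1]; q.omega = p[2]; q.k_f = p[3];
  q.h = p[4]; q.L = p[5];
  q.R = p[6]; q.m = p[7]; q.k = p[8]; q.DA = p[9]; q.B = p[10];
  q.delta0 = p[11]; q.mu = p[12]; q.r_cut = p[13];
  return q;
}

static inline double uflow(const Par& P, double t, double x, double y) {
  return (P.A_f * std::sin(P.omega * t - P.k_f * x) + P.B_f) *
         (1.0 - 4.0 * y * y / (P.h * P.h));
}

// Morse repulsion is frozen below this overlap (elastic term dominates there)
static const double OVERLAP_GUARD = -0.5e-6;

// Signed pair-force magnitude along n_ij (j -> i); >0 repulsive.
static inline double pair_force_mag(const Par& P, double d) {
  double delta = d - 2.0 * P.R;
  double f = 0.0;
  if (delta <= P.r_cut) {
    double de = delta < OVERLAP_GUARD ? OVERLAP_GUARD : delta;
    double e1 = std::exp(P.B * (P.delta0 - de));
    f += 2.0 * P.DA * P.B * (e1 * e1 - e1);
  }
  if (d < 2.0 * P.R) {
    f += P.k * std::pow(2.0 * P.R - d, 1.5);
  }
  return f;
}

// Hertzian contact against a mirror particle reflected across the wall:
// center distance to the mirror is 2*(h/2 - |y|).
static inline double wall_force_y(const Par& P, double y) {
  double gap = P.h / 2.0 - std::fabs(y);
  double ov = 2.0 * P.R - 2.0 * gap;
  if (ov <= 0.0) return 0.0;
  double mag = P.k * std::pow(ov, 1.5);
  return y > 0.0 ? -mag : mag;
}

// Linked-cell neighbor structure over the axially periodic domain.
struct CellList {
  int ncx, ncy;
  double cw, ch;
  std::vector<int> head, next;
  void build(const NumericMatrix& pos, const Par& P) {
    double min_cell = 2.0 * P.R + P.r_cut;
    ncx = std::max(1, (int)std::floor(P.L / min_cell));
    ncy = std::max(1, (int)std::floor(P.h / min_cell));
    cw = P.L / ncx;
    ch = P.h / ncy;
    head.assign((size_t)ncx * ncy, -1);
    next.assign(pos.nrow(), -1);
    for (int i = 0; i < pos.nrow(); ++i) {
      int cx = (int)std::floor(pos(i, 0) / cw);
      cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor((pos(i, 1) + P.h / 2.0) / ch);
      if (cy < 0) cy = 0;
      if (cy >= ncy) cy = ncy - 1;
      int c = cx + ncx * cy;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

static inline double min_image_dx(double dx, double L) {
  return dx - L * std::round(dx / L);
}

static void add_pair(const Par& P, const NumericMatrix& pos,
                     int i, int j, std::vector<double>& fx,
                     std::vector<double>& fy) {
  double dx = min_image_dx(pos(i, 0) - pos(j, 0), P.L);
  double dy = pos(i, 1) - pos(j, 1);
  double d2 = dx * dx + dy * dy;
  double reach = 2.0 * P.R + P.r_cut;
  if (d2 > reach * reach) return;
  double d = std::sqrt(d2);
  if (d == 0.0) stop("coincident particle centers (pair %d, %d)", i + 1, j + 1);
  double f = pair_force_mag(P, d);
  if (f == 0.0) return;
  double ux = dx / d, uy = dy / d;
  fx[i] += f * ux; fy[i] += f * uy;
  fx[j] -= f * ux; fy[j] -= f * uy;
}

static void pair_forces(const Par& P, const NumericMatrix& pos,
                        bool all_pairs, bool include_wall,
                        std::vector<double>& fx, std::vector<double>& fy,
                        CellList& cl) {
  int n = pos.nrow();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  if (all_pairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        add_pair(P, pos, i, j, fx, fy);
  } else {
    cl.build(pos, P);
    for (int cy = 0; cy < cl.ncy; ++cy) {
      for (int cx = 0; cx < cl.ncx; ++cx) {
        for (int i = cl.head[cx + cl.ncx * cy]; i >= 0; i = cl.next[i]) {
          for (int oy = -1; oy <= 1; ++oy) {
            int ny_ = cy + oy;
            if (ny_ < 0 || ny_ >= cl.ncy) continue;
            for (int ox = -1; ox <= 1; ++ox) {
              int nx_ = ((cx + ox) % cl.ncx + cl.ncx) % cl.ncx;
              for (int j = cl.head[nx_ + cl.ncx * ny_]; j >= 0; j = cl.next[j]) {
                if (j <= i) continue;
                add_pair(P, pos, i, j, fx, fy);
              }
            }
          }
        }
      }
    }
  }
  if (include_wall) {
    for (int i = 0; i < n; ++i) fy[i] += wall_force_y(P, pos(i, 1));
  }
}

// [[Rcpp::export]]
NumericMatrix pair_forces_cpp(NumericMatrix pos, NumericVector par,
                              bool all_pairs, bool include_wall) {
  Par P = unpack(par);
  int n = pos.nrow();
  std::vector<double> fx(n), fy(n);
  CellList cl;
  // with fewer than 3 cells along an axis the 3x3 stencil revisits cells;
  // use the exact all-pairs path instead
  {
    double min_cell = 2.0 * P.R + P.r_cut;
    if ((int)std::floor(P.L / min_cell) < 3 ||
        (int)std::floor(P.h / min_cell) < 3)
      all_pairs = true;
  }
  pair_forces(P, pos, all_pairs, include_wall, fx, fy, cl);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// All pairs with center distance strictly below `cutoff`, using the axially
// periodic minimum-image metric. Cell-list accelerated; falls back to all
// pairs when the domain is too small for a 3x3 stencil.
// [[Rcpp::export]]
IntegerMatrix close_pairs_cpp(NumericMatrix pos, double L, double h,
                              double cutoff) {
  int n = pos.nrow();
  std::vector<int> pi, pj;
  int ncx = std::max(1, (int)std::floor(L / cutoff));
  int ncy = std::max(1, (int)std::floor(h / cutoff));
  bool all_pairs = (ncx < 3 || ncy < 3);
  double c2 = cutoff * cutoff;
  auto check = [&](int i, int j) {
    double dx = min_image_dx(pos(i, 0) - pos(j, 0), L);
    double dy = pos(i, 1) - pos(j, 1);
    if (dx * dx + dy * dy < c2) {
      pi.push_back(std::min(i, j) + 1);
      pj.push_back(std::max(i, j) + 1);
    }
  };
  if (all_pairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) check(i, j);
  } else {
    double cw = L / ncx, ch = h / ncy;
    std::vector<int> head((size_t)ncx * ncy, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(pos(i, 0) / cw); cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor((pos(i, 1) + h / 2.0) / ch);
      if (cy < 0) cy = 0;
      if (cy >= ncy) cy = ncy - 1;
      nxt[i] = head[cx + ncx * cy];
      head[cx + ncx * cy] = i;
    }
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx)
        for (int i = head[cx + ncx * cy]; i >= 0; i = nxt[i])
          for (int oy = -1; oy <= 1; ++oy) {
            int ny_ = cy + oy;
            if (ny_ < 0 || ny_ >= ncy) continue;
            for (int ox = -1; ox <= 1; ++ox) {
              int nx_ = ((cx + ox) % ncx + ncx) % ncx;
              for (int j = head[nx_ + ncx * ny_]; j >= 0; j = nxt[j]) {
                if (j <= i) continue;
                check(i, j);
              }
            }
          }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) { out(r, 0) = pi[r]; out(r, 1) = pj[r]; }
  return out;
}

// Advance the particle system with the splitting integrator: pairwise +
// wall forces and the local flow velocity are frozen over the step, and the
// linear drag ODE  m v' = F + 6 pi mu R (u - v)  is solved exactly;
// positions advance with the exact velocity integral. Unconditionally
// stable for the stiff drag term (tau = m / 6 pi mu R ~ 3 us).
// [[Rcpp::export]]
List run_sim_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector par,
                 double t0, double dt, int n_steps, int stride) {
  Par P = unpack(par);
  int n = pos0.nrow();
  bool all_pairs;
  {
    double min_cell = 2.0 * P.R + P.r_cut;
    all_pairs = ((int)std::floor(P.L / min_cell) < 3 ||
                 (int)std::floor(P.h / min_cell) < 3);
  }
  double gamma = 6.0 * M_PI * P.mu * P.R;
  double tau = P.m / gamma;
  double efac = std::exp(-dt / tau);
  double ymax = P.h / 2.0 - P.R;
  // Displacement limiter for the stiff Morse core: the drift velocity
  // F_pair/gamma is capped so one step cannot move a particle further than
  // half the Morse decay length 1/B, which keeps deeply compressed pairs
  // from overshooting across the potential well and ringing. Forces at or
  // below the attraction scale are far from the cap.
  double vcap = 0.5 / (P.B * dt);

  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
  }

  int n_snap = n_steps / stride + 1;
  NumericVector times(n_snap);
  // snapshots stored as [particle, coord, snapshot]
  NumericVector posA(Dimension(n, 2, n_snap)), velA(Dimension(n, 2, n_snap));
  CellList cl;
  NumericMatrix cur(n, 2);

  int isnap = 0;
  auto record = [&](double t) {
    times[isnap] = t;
    size_t off = (size_t)isnap * n * 2;
    for (int i = 0; i < n; ++i) {
      posA[off + i] = x[i];       posA[off + n + i] = y[i];
      velA[off + i] = vx[i];      velA[off + n + i] = vy[i];
    }
    ++isnap;
  };
  record(t0);

  for (int s = 1; s <= n_steps; ++s) {
    double t = t0 + (s - 1) * dt;
    for (int i = 0; i < n; ++i) { cur(i, 0) = x[i]; cur(i, 1) = y[i]; }
    pair_forces(P, cur, all_pairs, true, fx, fy, cl);
    for (int i = 0; i < n; ++i) {
      double u = uflow(P, t, x[i], y[i]);
      double dvx = fx[i] / gamma, dvy = fy[i] / gamma;
      double dv = std::sqrt(dvx * dvx + dvy * dvy);
      if (dv > vcap) { dvx *= vcap / dv; dvy *= vcap / dv; }
      double vix = u + dvx;                 // terminal velocity, x
      double viy = dvy;                     // terminal velocity, y
      double dxv = vx[i] - vix, dyv = vy[i] - viy;
      x[i] += vix * dt + dxv * tau * (1.0 - efac);
      y[i] += viy * dt + dyv * tau * (1.0 - efac);
      vx[i] = vix + dxv * efac;
      vy[i] = viy + dyv * efac;
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i]))
        stop("non-finite state for particle %d at step %d", i + 1, s);
      // periodic wrap in x; hard containment in y as a safety net behind
      // the Hertzian wall contact
      x[i] -= P.L * std::floor(x[i] / P.L);
      if (y[i] > ymax) y[i] = ymax;
      else if (y[i] < -ymax) y[i] = -ymax;
    }
    if (s % stride == 0) record(t0 + s * dt);
  }

  return List::create(_["times"] = times, _["pos"] = posA, _["vel"] = velA);
}
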