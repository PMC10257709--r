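// Discrete-element core: self-propelled soft disks with actively
// oscillating radii in a box with a bottom orifice.
//
// Forces (Helbing-Farkas-Vicsek type):
//   driving  F_d = m (v_f e_d - v) / tau,  e_d = (0,-1)
//   contact  F_c = sum_j g(xi_ij) [ k_n e^n + k_t ((v_j-v_i).e^t) e^t ]
//            + sum_b g(xi_ib) [ k_n e^n + k_t (-v_i.e^t) e^t ]
// with xi = (r_i + r_j) - d_ij (particle-particle) or r_i - d_ib
// (particle-boundary), g(z) = z for z >= 0 and 0 otherwise, e^n pointing
// from j (or the boundary contact point) toward i, e^t = rot90(e^n).
//
// Radii are kinematically prescribed: r_i(t) = r0 (1 + A sin(w t + phi_i)).
//
// Integration: velocity Verlet with a velocity predictor for the
// velocity-dependent force terms; one force evaluation per step, the
// end-of-step acceleration is cached for the next step.
//
// Pair search: Verlet neighbour list (cutoff = two maximal radii plus a
// skin) built through a uniform cell grid and rebuilt only when any
// particle has moved more than half the skin since the last build; force
// results are identical to an all-pairs evaluation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Params {
  int    N;
  double m, r0, tau, kn, kt, vf, A, omega;
  double W, H, D, orifice_cx;
  double exit_y, removal_y;
  double reinj_x0, reinj_x1, reinj_y0, reinj_y1;
  double dt;
  bool   recycle_keep_velocity;
  int    recycle_cap;
};

Params read_params(const List& cfg) {
  Params p;
  p.N  = as<int>(cfg["N"]);
  p.m  = as<double>(cfg["m"]);
  p.r0 = as<double>(cfg["r0"]);
  p.tau = as<double>(cfg["tau"]);
  p.kn = as<double>(cfg["k_n"]);
  p.kt = as<double>(cfg["k_t"]);
  p.vf = as<double>(cfg["v_f"]);
  p.A  = as<double>(cfg["A"]);
  p.omega = as<double>(cfg["omega"]);
  p.W  = as<double>(cfg["box_width"]);
  p.H  = as<double>(cfg["box_height"]);
  p.D  = as<double>(cfg["D"]);
  p.orifice_cx = as<double>(cfg["orifice_cx"]);
  p.exit_y = as<double>(cfg["exit_y"]);
  p.removal_y = as<double>(cfg["removal_y"]);
  NumericVector rx = cfg["reinjection_x_range"], ry = cfg["reinjection_y_range"];
  p.reinj_x0 = rx[0]; p.reinj_x1 = rx[1];
  p.reinj_y0 = ry[0]; p.reinj_y1 = ry[1];
  p.dt = as<double>(cfg["dt"]);
  p.recycle_keep_velocity = as<bool>(cfg["recycle_keep_velocity"]);
  p.recycle_cap = as<int>(cfg["recycle_cap"]);
  return p;
}

// Wall segments: left wall, right wall, and the two bottom segments
// flanking the orifice.  The orifice lips are the inner endpoints of the
// bottom segments; point-segment distance handles them as corner contacts.
struct Segment { double x1, y1, x2, y2; };

std::vector<Segment> make_walls(const Params& p) {
  const double gl = p.orifice_cx - p.D / 2.0;
  const double gr = p.orifice_cx + p.D / 2.0;
  std::vector<Segment> w;
  w.push_back({0.0, 0.0, 0.0, p.H});      // left wall
  w.push_back({p.W, 0.0, p.W, p.H});      // right wall
  w.push_back({0.0, 0.0, gl, 0.0});       // bottom, left of orifice
  w.push_back({gr, 0.0, p.W, 0.0});       // bottom, right of orifice
  return w;
}

// closest point on a segment to (px,py)
inline void closest_on_segment(const Segment& s, double px, double py,
                               double& cx, double& cy) {
  const double dx = s.x2 - s.x1, dy = s.y2 - s.y1;
  const double L2 = dx * dx + dy * dy;
  double t = ((px - s.x1) * dx + (py - s.y1) * dy) / L2;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  cx = s.x1 + t * dx;
  cy = s.y1 + t * dy;
}

// Verlet neighbour list built through a uniform cell grid
struct NeighborList {
  double cutoff, skin;
  std::vector<int> pi, pj;        // candidate pairs (d < cutoff + skin)
  std::vector<double> ref_x, ref_y;  // positions at last build
  // cell grid scratch
  double x0, y0, h;
  int ncx, ncy;
  std::vector<int> head, nxt;

  void init(const Params& p, double skin_) {
    cutoff = 2.0 * p.r0 * (1.0 + p.A);
    skin = skin_;
    h = cutoff + skin;
    x0 = -h;
    y0 = p.removal_y - 2.0;
    ncx = (int)std::ceil((p.W + 2.0 * h - x0) / h) + 1;
    ncy = (int)std::ceil((p.H + 2.0 - y0) / h) + 1;
    head.assign((size_t)ncx * ncy, -1);
    nxt.assign(p.N, -1);
    ref_x.assign(p.N, 0.0);
    ref_y.assign(p.N, 0.0);
    pi.reserve(8 * p.N);
    pj.reserve(8 * p.N);
  }

  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }

  void build(const std::vector<double>& x, const std::vector<double>& y, int N) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < N; ++i) {
      const int cx = clampi((int)std::floor((x[i] - x0) / h), ncx);
      const int cy = clampi((int)std::floor((y[i] - y0) / h), ncy);
      const int c = cy * ncx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
    pi.clear(); pj.clear();
    const double rc2 = h * h;
    for (int i = 0; i < N; ++i) {
      const int ci = clampi((int)std::floor((x[i] - x0) / h), ncx);
      const int cj = clampi((int)std::floor((y[i] - y0) / h), ncy);
      for (int oy = -1; oy <= 1; ++oy) {
        const int gy = cj + oy;
        if (gy < 0 || gy >= ncy) continue;
        for (int ox = -1; ox <= 1; ++ox) {
          const int gx = ci + ox;
          if (gx < 0 || gx >= ncx) continue;
          for (int j = head[gy * ncx + gx]; j != -1; j = nxt[j]) {
            if (j <= i) continue;
            const double dx = x[i] - x[j], dy = y[i] - y[j];
            if (dx * dx + dy * dy < rc2) { pi.push_back(i); pj.push_back(j); }
          }
        }
      }
    }
    ref_x.assign(x.begin(), x.end());
    ref_y.assign(y.begin(), y.end());
  }

  bool stale(const std::vector<double>& x, const std::vector<double>& y,
             int N) const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      const double dx = x[i] - ref_x[i], dy = y[i] - ref_y[i];
      if (dx * dx + dy * dy > lim2) return true;
    }
    return false;
  }
};

// Total force on every particle given the current candidate pair list.
void compute_forces(const Params& p, const std::vector<Segment>& walls,
                    const NeighborList& nl, double t,
                    const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& vx, const std::vector<double>& vy,
                    const std::vector<double>& r,
                    std::vector<double>& fx, std::vector<double>& fy) {
  const int N = p.N;
  const double inv_tau = 1.0 / p.tau;
  const double rmax = p.r0 * (1.0 + p.A);

  for (int i = 0; i < N; ++i) {
    // driving force toward -y
    fx[i] = p.m * (-vx[i]) * inv_tau;
    fy[i] = p.m * (-p.vf - vy[i]) * inv_tau;
    // bulk particles (strictly inside, away from every wall) skip the scan
    if (x[i] > rmax && x[i] < p.W - rmax && y[i] > rmax && y[i] < p.H - rmax)
      continue;
    for (const Segment& s : walls) {
      double cx, cy;
      closest_on_segment(s, x[i], y[i], cx, cy);
      const double dx = x[i] - cx, dy = y[i] - cy;
      const double d2 = dx * dx + dy * dy;
      if (d2 >= r[i] * r[i]) continue;
      if (d2 == 0.0)
        stop("degenerate geometry: particle %d center lies on a wall at t=%g",
             i + 1, t);
      const double d = std::sqrt(d2);
      const double xi = r[i] - d;
      const double nx = dx / d, ny = dy / d;   // boundary -> particle
      const double tx = -ny, ty = nx;
      const double vt = -(vx[i] * tx + vy[i] * ty);
      fx[i] += xi * (p.kn * nx + p.kt * vt * tx);
      fy[i] += xi * (p.kn * ny + p.kt * vt * ty);
    }
  }

  const size_t np = nl.pi.size();
  for (size_t k = 0; k < np; ++k) {
    const int i = nl.pi[k], j = nl.pj[k];
    const double dx = x[i] - x[j], dy = y[i] - y[j];
    const double rsum = r[i] + r[j];
    const double d2 = dx * dx + dy * dy;
    if (d2 >= rsum * rsum) continue;
    if (d2 == 0.0)
      stop("degenerate geometry: particles %d and %d coincide at t=%g",
           i + 1, j + 1, t);
    const double d = std::sqrt(d2);
    const double xi = rsum - d;
    const double nx = dx / d, ny = dy / d;  // j -> i
    const double tx = -ny, ty = nx;
    const double vt = (vx[j] - vx[i]) * tx + (vy[j] - vy[i]) * ty;
    const double Fx = xi * (p.kn * nx + p.kt * vt * tx);
    const double Fy = xi * (p.kn * ny + p.kt * vt * ty);
    fx[i] += Fx; fy[i] += Fy;   // Newton's third law: equal and opposite
    fx[j] -= Fx; fy[j] -= Fy;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_total_forces")]]
NumericMatrix cpp_total_forces(NumericVector x, NumericVector y,
                               NumericVector vx, NumericVector vy,
                               NumericVector phases, double t, List cfg) {
  Params p = read_params(cfg);
  std::vector<Segment> walls = make_walls(p);
  NeighborList nl; nl.init(p, 0.0);
  const int N = p.N;
  std::vector<double> X(x.begin(), x.end()), Y(y.begin(), y.end()),
      VX(vx.begin(), vx.end()), VY(vy.begin(), vy.end()), R(N), FX(N), FY(N);
  for (int i = 0; i < N; ++i)
    R[i] = p.r0 * (1.0 + p.A * std::sin(p.omega * t + phases[i]));
  nl.build(X, Y, N);
  compute_forces(p, walls, nl, t, X, Y, VX, VY, R, FX, FY);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = FX[i]; out(i, 1) = FY[i]; }
  return out;
}

// Advance the system n_steps from time t0.  Returns the final state, the
// exit-event log (downward center crossings of exit_y, times linearly
// interpolated within the step), recorded frames (every record_every
// steps, plus the state at t0 when record_initial), and recycling
// bookkeeping.  Recycling draws from R's RNG, so runs are reproducible
// under set.seed().
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(NumericVector x0, NumericVector y0,
             NumericVector vx0, NumericVector vy0,
             NumericVector phases, double t0, int n_steps, List cfg,
             int record_every, bool record_initial) {
  Params p = read_params(cfg);
  std::vector<Segment> walls = make_walls(p);
  NeighborList nl; nl.init(p, 0.4 * p.r0);
  const int N = p.N;
  const double dt = p.dt, half_dt2 = 0.5 * dt * dt, inv_m = 1.0 / p.m;

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      vx(vx0.begin(), vx0.end()), vy(vy0.begin(), vy0.end()),
      r(N), ax(N), ay(N), axn(N), ayn(N), vpx(N), vpy(N);

  // radius oscillation: per-particle (sin, cos) rotated by (omega dt) each
  // step, refreshed from std::sin/cos periodically to remove drift
  std::vector<double> osc_s(N), osc_c(N);
  const double cd = std::cos(p.omega * dt), sdt = std::sin(p.omega * dt);
  const int refresh_every = 4096;
  auto osc_refresh = [&](double t) {
    for (int i = 0; i < N; ++i) {
      osc_s[i] = std::sin(p.omega * t + phases[i]);
      osc_c[i] = std::cos(p.omega * t + phases[i]);
    }
  };
  auto set_radii = [&]() {
    for (int i = 0; i < N; ++i) {
      double s = osc_s[i];
      if (s > 1.0) s = 1.0; else if (s < -1.0) s = -1.0;
      r[i] = p.r0 * (1.0 + p.A * s);
    }
  };

  // frame storage
  const bool rec = record_every > 0;
  std::vector<double> ft, fx_, fy_, fvx, fvy, fr;
  std::vector<int> fid;
  if (rec) {
    const size_t cap =
        (size_t)(n_steps / record_every + (record_initial ? 1 : 0)) * N;
    ft.reserve(cap); fid.reserve(cap); fx_.reserve(cap); fy_.reserve(cap);
    fvx.reserve(cap); fvy.reserve(cap); fr.reserve(cap);
  }
  auto record_frame = [&](double t) {
    for (int i = 0; i < N; ++i) {
      ft.push_back(t); fid.push_back(i + 1);
      fx_.push_back(x[i]); fy_.push_back(y[i]);
      fvx.push_back(vx[i]); fvy.push_back(vy[i]); fr.push_back(r[i]);
    }
  };

  std::vector<double> ev_t;
  std::vector<int> ev_id;
  long n_recycled = 0, n_recycle_deferred = 0;

  osc_refresh(t0);
  set_radii();
  if (rec && record_initial) record_frame(t0);
  nl.build(x, y, N);
  compute_forces(p, walls, nl, t0, x, y, vx, vy, r, ax, ay);
  for (int i = 0; i < N; ++i) { ax[i] *= inv_m; ay[i] *= inv_m; }

  for (int step = 0; step < n_steps; ++step) {
    const double t  = t0 + step * dt;
    const double t1 = t0 + (step + 1) * dt;

    for (int i = 0; i < N; ++i) {
      const double yprev = y[i];
      x[i] += vx[i] * dt + ax[i] * half_dt2;
      y[i] += vy[i] * dt + ay[i] * half_dt2;
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
        stop("integration blow-up: particle %d has non-finite position at t=%g",
             i + 1, t1);
      if (yprev >= p.exit_y && y[i] < p.exit_y) {
        // downward center crossing of the exit line
        const double frac = (yprev - p.exit_y) / (yprev - y[i]);
        ev_t.push_back(t + frac * dt);
        ev_id.push_back(i + 1);
      }
      // predictor velocities for the velocity-dependent force terms
      vpx[i] = vx[i] + ax[i] * dt;
      vpy[i] = vy[i] + ay[i] * dt;
    }

    // advance prescribed radii to t1
    if ((step + 1) % refresh_every == 0) {
      osc_refresh(t1);
    } else {
      for (int i = 0; i < N; ++i) {
        const double s = osc_s[i] * cd + osc_c[i] * sdt;
        osc_c[i] = osc_c[i] * cd - osc_s[i] * sdt;
        osc_s[i] = s;
      }
    }
    set_radii();

    if (nl.stale(x, y, N)) nl.build(x, y, N);
    compute_forces(p, walls, nl, t1, x, y, vpx, vpy, r, axn, ayn);
    for (int i = 0; i < N; ++i) {
      axn[i] *= inv_m; ayn[i] *= inv_m;
      vx[i] += 0.5 * (ax[i] + axn[i]) * dt;
      vy[i] += 0.5 * (ay[i] + ayn[i]) * dt;
      ax[i] = axn[i]; ay[i] = ayn[i];
    }

    // recycle particles that fell past the removal line
    bool recycled_now = false;
    for (int i = 0; i < N; ++i) {
      if (y[i] > p.removal_y) continue;
      bool placed = false;
      for (int att = 0; att < p.recycle_cap; ++att) {
        const double cx = p.reinj_x0 + unif_rand() * (p.reinj_x1 - p.reinj_x0);
        const double cy = p.reinj_y0 + unif_rand() * (p.reinj_y1 - p.reinj_y0);
        bool ok = true;
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          const double dx = cx - x[j], dy = cy - y[j];
          const double rs = r[i] + r[j];
          if (dx * dx + dy * dy < rs * rs) { ok = false; break; }
        }
        if (ok) {
          x[i] = cx; y[i] = cy;
          if (!p.recycle_keep_velocity) { vx[i] = 0.0; vy[i] = 0.0; }
          // freshly placed particle has no contacts: driving force only
          ax[i] = (-vx[i]) / p.tau;
          ay[i] = (-p.vf - vy[i]) / p.tau;
          ++n_recycled;
          placed = true;
          recycled_now = true;
          break;
        }
      }
      if (!placed) ++n_recycle_deferred;  // parked below removal_y, retried next step
    }
    if (recycled_now) nl.build(x, y, N);

    if (rec && (step + 1) % record_every == 0) record_frame(t1);
    if ((step & 0xFFFF) == 0xFFFF) Rcpp::checkUserInterrupt();
  }

  const double t_end = t0 + (double)n_steps * dt;
  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["vx"] = NumericVector(vx.begin(), vx.end()),
      _["vy"] = NumericVector(vy.begin(), vy.end()),
      _["radii"] = NumericVector(r.begin(), r.end()),
      _["t"] = t_end,
      _["events_t"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["events_id"] = IntegerVector(ev_id.begin(), ev_id.end()),
      _["frames"] = rec ? (SEXP)DataFrame::create(
                              _["t"] = NumericVector(ft.begin(), ft.end()),
                              _["id"] = IntegerVector(fid.begin(), fid.end()),
                              _["x"] = NumericVector(fx_.begin(), fx_.end()),
                              _["y"] = NumericVector(fy_.begin(), fy_.end()),
                              _["vx"] = NumericVector(fvx.begin(), fvx.end()),
                              _["vy"] = NumericVector(fvy.begin(), fvy.end()),
                              _["r"] = NumericVector(fr.begin(), fr.end()))
                        : (SEXP)R_NilValue,
      _["n_recycled"] = (double)n_recycled,
      _["n_recycle_deferred"] = (double)n_recycle_deferred);
}
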