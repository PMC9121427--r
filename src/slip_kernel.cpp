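// Stride integrator for the bipedal SLIP model with passive torsional-spring
// swing legs.  State layout z[8] = (x, y, alpha_l, alpha_r, xdot, ydot,
// alphadot_l, alphadot_r); all quantities dimensionless (m = lo = g = 1 in
// normal use, but the parameters are kept general).
//
// Hybrid structure: per-leg contact mode (0 = swing, 1 = stance, with a
// stationary foot anchor in stance).  Events:
//   touchdown  g_i = y - lo*cos(alpha_i) crossing 0 from above (swing leg)
//   liftoff    same function crossing 0 from below (stance leg, spring back
//              to rest length)
//   apex       ydot crossing 0 from above while both legs swing
// Event times are refined to |g| < ~1e-12 by an Illinois secant on exact
// re-integration from the start of the accepted step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  double m, lo, g, k, w;
  double phi[2];
};

const int NS = 8;

inline void deriv(const double* z, const int* modes, const Params& P,
                  double* dz) {
  const double y = z[1], vx = z[4], vy = z[5];
  const double a[2] = {z[2], z[3]};
  const double wv[2] = {z[6], z[7]};
  double Fx = 0.0, Fy = 0.0;
  for (int i = 0; i < 2; ++i) {
    if (modes[i] == 1) {
      const double ca = std::cos(a[i]);
      const double li = y / ca;
      const double f = P.k * (P.lo - li);  // compression force >= 0
      Fx += -f * std::sin(a[i]);
      Fy += f * ca;
    }
  }
  const double ax = Fx / P.m;
  const double ay = Fy / P.m - P.g;
  dz[0] = vx;
  dz[1] = vy;
  dz[2] = wv[0];
  dz[3] = wv[1];
  dz[4] = ax;
  dz[5] = ay;
  for (int i = 0; i < 2; ++i) {
    double wd;
    if (modes[i] == 0) {
      // swing leg: pendulum coupled to body acceleration + torsional spring
      wd = -(ax * std::cos(a[i]) + (P.g + ay) * std::sin(a[i])) / P.lo -
           P.w * P.w * (a[i] - P.phi[i]);
    } else {
      // stance leg: second derivative of the holonomic foot constraint
      const double ta = std::tan(a[i]);
      const double ca = std::cos(a[i]);
      wd = -2.0 * wv[i] * wv[i] * ta - 2.0 * wv[i] * vy / y -
           (ax + ay * ta) * ca * ca / y;
    }
    dz[6 + i] = wd;
  }
}

inline double energy(const double* z, const int* modes, const Params& P) {
  double E = 0.5 * P.m * (z[4] * z[4] + z[5] * z[5]) + P.m * P.g * z[1];
  for (int i = 0; i < 2; ++i) {
    if (modes[i] == 1) {
      const double li = z[1] / std::cos(z[2 + i]);
      E += 0.5 * P.k * (P.lo - li) * (P.lo - li);
    }
  }
  return E;
}

// Dormand-Prince 5(4) step.  k1 must hold f(t,z) on entry (FSAL); on
// acceptance k1 is updated to f(t+h, znew).  Returns scaled error norm.
struct Stepper {
  Params P;
  int modes[2];
  double rtol, atol;
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];

  double step(const double* z, double h, double* znew) {
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                        a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                        a65 = -5103.0 / 18656;
    static const double a71 = 35.0 / 384, a73 = 500.0 / 1113,
                        a74 = 125.0 / 192, a75 = -2187.0 / 6784,
                        a76 = 11.0 / 84;
    static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                        e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                        e6 = 22.0 / 525, e7 = -1.0 / 40;
    double tmp[NS];
    for (int i = 0; i < NS; ++i) tmp[i] = z[i] + h * a21 * k1[i];
    deriv(tmp, modes, P, k2);
    for (int i = 0; i < NS; ++i)
      tmp[i] = z[i] + h * (a31 * k1[i] + a32 * k2[i]);
    deriv(tmp, modes, P, k3);
    for (int i = 0; i < NS; ++i)
      tmp[i] = z[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(tmp, modes, P, k4);
    for (int i = 0; i < NS; ++i)
      tmp[i] = z[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                           a54 * k4[i]);
    deriv(tmp, modes, P, k5);
    for (int i = 0; i < NS; ++i)
      tmp[i] = z[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                           a64 * k4[i] + a65 * k5[i]);
    deriv(tmp, modes, P, k6);
    for (int i = 0; i < NS; ++i)
      znew[i] = z[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i] +
                            a75 * k5[i] + a76 * k6[i]);
    deriv(znew, modes, P, k7);
    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(z[i]), std::fabs(znew[i]));
      err += (ei / sc) * (ei / sc);
    }
    return std::sqrt(err / NS);
  }
};

// Integrate from (t0, z0) to t1 (>= t0) with fixed modes, adaptive steps.
// Returns false on step underflow.
bool advance_to(Stepper& S, double t0, const double* z0, double t1,
                double* zout, double h_init) {
  double t = t0, h = std::min(h_init, t1 - t0);
  double z[NS];
  for (int i = 0; i < NS; ++i) z[i] = z0[i];
  deriv(z, S.modes, S.P, S.k1);
  if (t1 - t0 < 1e-15) {
    for (int i = 0; i < NS; ++i) zout[i] = z[i];
    return true;
  }
  int guard = 0;
  while (t < t1 - 1e-14) {
    if (++guard > 100000) return false;
    if (h < 1e-14) return false;
    if (t + h > t1) h = t1 - t;
    double znew[NS];
    const double err = S.step(z, h, znew);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) z[i] = znew[i];
      // k1 <- k7 (FSAL)
      for (int i = 0; i < NS; ++i) S.k1[i] = S.k7[i];
    } else {
      deriv(z, S.modes, S.P, S.k1);  // restore (k1 was fine, but be safe)
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
  }
  for (int i = 0; i < NS; ++i) zout[i] = z[i];
  return true;
}

enum EvType { EV_TD_L = 0, EV_TD_R = 1, EV_LO_L = 2, EV_LO_R = 3, EV_APEX = 4 };

inline double evfun(int type, const double* z, const Params& P) {
  switch (type) {
    case EV_TD_L:
    case EV_LO_L:
      return z[1] - P.lo * std::cos(z[2]);
    case EV_TD_R:
    case EV_LO_R:
      return z[1] - P.lo * std::cos(z[3]);
    default:
      return z[5];  // apex: ydot
  }
}

// Illinois method for the event time within (t0, t1], integrating from
// (t0, z0) each evaluation.  g0 = g(t0), g1 = g(t1) with opposite signs.
bool refine_event(Stepper& S, int type, double t0, const double* z0,
                  double t1, double g0, double g1, double h_init,
                  double* t_ev, double* z_ev) {
  double a = t0, b = t1, fa = g0, fb = g1;
  double z[NS];
  double tm = b, fm = fb;
  int side = 0;
  for (int it = 0; it < 80; ++it) {
    tm = b - fb * (b - a) / (fb - fa);
    if (!(tm > a && tm < b)) tm = 0.5 * (a + b);
    if (!advance_to(S, t0, z0, tm, z, h_init)) return false;
    fm = evfun(type, z, S.P);
    if (std::fabs(fm) < 1e-13 || (b - a) < 1e-14) break;
    if ((fm > 0) == (fb > 0)) {
      b = tm;
      fb = fm;
      if (side == -1) fa *= 0.5;
      side = -1;
    } else {
      a = tm;
      fa = fm;
      if (side == 1) fb *= 0.5;
      side = 1;
    }
  }
  if (!advance_to(S, t0, z0, tm, z, h_init)) return false;
  *t_ev = tm;
  for (int i = 0; i < NS; ++i) z_ev[i] = z[i];
  return true;
}

}  // namespace

// Single evaluation of the hybrid vector field (for unit tests / oracles).
// [[Rcpp::export]]
NumericVector slip_deriv_cpp(NumericVector z, IntegerVector modes,
                             NumericVector par) {
  Params P;
  P.m = par[0];
  P.lo = par[1];
  P.g = par[2];
  P.k = par[3];
  P.w = par[4];
  P.phi[0] = par[5];
  P.phi[1] = par[6];
  int md[2] = {modes[0], modes[1]};
  NumericVector out(NS);
  double dz[NS];
  deriv(REAL(z), md, P, dz);
  for (int i = 0; i < NS; ++i) out[i] = dz[i];
  return out;
}

// [[Rcpp::export]]
double slip_energy_cpp(NumericVector z, IntegerVector modes,
                       NumericVector par) {
  Params P;
  P.m = par[0];
  P.lo = par[1];
  P.g = par[2];
  P.k = par[3];
  P.w = par[4];
  P.phi[0] = par[5];
  P.phi[1] = par[6];
  int md[2] = {modes[0], modes[1]};
  return energy(REAL(z), md, P);
}

// Event-driven integration of the hybrid system.
//
// stop_mode: 0 = full stride (stop at first flight apex after each leg has
//            had >= 1 touchdown and >= 1 liftoff), 1 = first flight apex,
//            2 = first contact event (phase integration), 3 = run to t_max,
//            4 = n-th ydot zero crossing in any phase (n = max_events slot
//            n_cross; used by the reversibility / symmetric-orbit shooting).
// Status codes: 0 ok, 1 fell, 2 premature touchdown, 3 event overflow,
//               4 t_max reached, 5 step underflow, 6 invalid start.
// [[Rcpp::export]]
List slip_stride_cpp(NumericVector z0_, IntegerVector modes0,
                     NumericVector anchors0, NumericVector par,
                     int stop_mode, double t_max, int max_events,
                     double rtol, double atol, NumericVector t_eval,
                     double wtol_prem, bool check_premature,
                     bool record_steps, int n_cross = 1,
                     bool detect_events = true) {
  Stepper S;
  S.P.m = par[0];
  S.P.lo = par[1];
  S.P.g = par[2];
  S.P.k = par[3];
  S.P.w = par[4];
  S.P.phi[0] = par[5];
  S.P.phi[1] = par[6];
  S.rtol = rtol;
  S.atol = atol;
  S.modes[0] = modes0[0];
  S.modes[1] = modes0[1];
  double anchors[2] = {anchors0[0], anchors0[1]};

  double z[NS];
  for (int i = 0; i < NS; ++i) z[i] = z0_[i];
  double t = 0.0;

  int status = 4;  // default: t_max reached
  int n_td[2] = {0, 0}, n_lo[2] = {0, 0};
  int n_events = 0, n_crossed = 0;

  std::vector<double> ev_t;
  std::vector<int> ev_leg, ev_type;  // type 0 td, 1 lo, 2 apex

  std::vector<double> rec_t;
  std::vector<double> rec_z;
  std::vector<int> rec_m;
  const int n_eval = t_eval.size();
  int i_eval = 0;
  NumericMatrix dense(n_eval, 1 + NS + 2);

  const double E0 = energy(z, S.modes, S.P);
  double e_drift = 0.0, c_max = 0.0, amp_max = 0.0;
  // anterior-scuff monitor: a swing foot crossing the ground going down
  // while the leg still rotates in the direction of travel marks a
  // premature (earlier-than-intended) touchdown of the candidate orbit
  int n_anterior_scuff = 0;
  auto scuff_check = [&](const double* z0s, const double* z1s) {
    for (int i = 0; i < 2; ++i) {
      if (S.modes[i] != 0) continue;
      const double g0 = z0s[1] - S.P.lo * std::cos(z0s[2 + i]);
      const double g1 = z1s[1] - S.P.lo * std::cos(z1s[2 + i]);
      if (g0 > 1e-12 && g1 < -1e-12) {
        const double dir =
            (z1s[4] > 1e-8) ? 1.0 : ((z1s[4] < -1e-8) ? -1.0 : 0.0);
        if (dir * z1s[6 + i] > wtol_prem) ++n_anterior_scuff;
      }
    }
  };

  // validity of start (skipped for fixed-mode segment integration, where
  // trial candidates may violate clearance away from the converged solution)
  for (int i = 0; i < 2; ++i) {
    if (S.modes[i] == 0) {
      if (detect_events &&
          evfun(i == 0 ? EV_TD_L : EV_TD_R, z, S.P) < -1e-10)
        status = 6;
    } else {
      if (z[1] <= 0 || std::fabs(z[2 + i]) >= M_PI / 2) status = 6;
      if (!R_finite(anchors[i]))
        anchors[i] = z[0] + z[1] * std::tan(z[2 + i]);
    }
  }

  auto track = [&](const double* zz) {
    const double E = energy(zz, S.modes, S.P);
    e_drift = std::max(e_drift, std::fabs(E - E0));
    for (int i = 0; i < 2; ++i) {
      if (S.modes[i] == 1) {
        const double c = anchors[i] - zz[0] - zz[1] * std::tan(zz[2 + i]);
        c_max = std::max(c_max, std::fabs(c));
      }
      amp_max = std::max(amp_max, std::fabs(zz[2 + i]));
    }
  };
  auto record = [&](double tt, const double* zz) {
    if (!record_steps) return;
    rec_t.push_back(tt);
    for (int i = 0; i < NS; ++i) rec_z.push_back(zz[i]);
    rec_m.push_back(S.modes[0]);
    rec_m.push_back(S.modes[1]);
  };
  auto fill_eval = [&](double tt, const double* zz) {
    // exact landing: steps are capped to hit t_eval points
    while (i_eval < n_eval && t_eval[i_eval] <= tt + 1e-13) {
      dense(i_eval, 0) = t_eval[i_eval];
      for (int i = 0; i < NS; ++i) dense(i_eval, 1 + i) = zz[i];
      dense(i_eval, 9) = S.modes[0];
      dense(i_eval, 10) = S.modes[1];
      ++i_eval;
    }
  };

  track(z);
  record(t, z);
  fill_eval(t, z);

  double h = 1e-4;
  deriv(z, S.modes, S.P, S.k1);
  int guard = 0;
  bool done = (status == 6);

  while (!done && t < t_max) {
    if (++guard > 2000000) {
      status = 5;
      break;
    }
    if (h < 1e-13) {
      status = 5;
      break;
    }
    double h_try = std::min(h, t_max - t);
    if (i_eval < n_eval && t + h_try > t_eval[i_eval])
      h_try = t_eval[i_eval] - t;
    if (h_try < 1e-14) h_try = 1e-14;
    double znew[NS];
    const double err = S.step(z, h_try, znew);
    if (err > 1.0) {
      double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
      h = h_try * fac;
      deriv(z, S.modes, S.P, S.k1);
      continue;
    }
    const double t1 = t + h_try;

    // detect events over [t, t1]
    const bool flight = (S.modes[0] == 0 && S.modes[1] == 0);
    int cand_type[5];
    double cand_g0[5], cand_g1[5];
    int n_cand = 0;
    if (detect_events)
    for (int i = 0; i < 2; ++i) {
      const int ft = (i == 0) ? EV_TD_L : EV_TD_R;
      const double g0v = evfun(ft, z, S.P), g1v = evfun(ft, znew, S.P);
      if (S.modes[i] == 0) {
        if (g0v > 1e-13 && g1v <= 0) {
          cand_type[n_cand] = ft;
          cand_g0[n_cand] = g0v;
          cand_g1[n_cand] = g1v;
          ++n_cand;
        }
      } else {
        if (g0v < -1e-13 && g1v >= 0) {
          cand_type[n_cand] = (i == 0) ? EV_LO_L : EV_LO_R;
          cand_g0[n_cand] = g0v;
          cand_g1[n_cand] = g1v;
          ++n_cand;
        }
      }
    }
    if (!detect_events) {
      // no event interruption (fixed-mode segment integration)
    } else if (stop_mode == 4) {
      // any ydot zero crossing, either direction, any contact mode
      if ((z[5] > 1e-13 && znew[5] <= 0) || (z[5] < -1e-13 && znew[5] >= 0)) {
        cand_type[n_cand] = EV_APEX;
        cand_g0[n_cand] = z[5];
        cand_g1[n_cand] = znew[5];
        ++n_cand;
      }
    } else if (flight && z[5] > 1e-13 && znew[5] <= 0) {
      cand_type[n_cand] = EV_APEX;
      cand_g0[n_cand] = z[5];
      cand_g1[n_cand] = znew[5];
      ++n_cand;
    }

    if (n_cand == 0) {
      scuff_check(z, znew);
      t = t1;
      for (int i = 0; i < NS; ++i) z[i] = znew[i];
      for (int i = 0; i < NS; ++i) S.k1[i] = S.k7[i];
      track(z);
      record(t, z);
      fill_eval(t, z);
      // failure checks (during event-driven simulation only)
      if (detect_events && z[1] <= 0) {
        status = 1;
        break;
      }
      for (int i = 0; i < 2; ++i)
        if (S.modes[i] == 1 &&
            (z[1] <= 1e-6 || std::fabs(z[2 + i]) >= M_PI / 2 - 1e-9)) {
          status = 1;
          done = true;
        }
      if (done) break;
      double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(err, 1e-10), -0.2)));
      h = h_try * fac;
      continue;
    }

    // refine all candidate events, take the earliest (plus simultaneous ones)
    double tev[5], zev[5][NS];
    bool okev[5];
    double t_first = t1 + 1.0;
    for (int c = 0; c < n_cand; ++c) {
      okev[c] = refine_event(S, cand_type[c], t, z, t1, cand_g0[c],
                             cand_g1[c], h_try, &tev[c], zev[c]);
      if (okev[c]) t_first = std::min(t_first, tev[c]);
    }
    if (t_first > t1) {
      status = 5;
      break;
    }
    // gather simultaneous events (within 1e-9), touchdowns before liftoffs
    double zatev[NS];
    bool have_state = false;
    int apply[5], n_apply = 0;
    for (int pass = 0; pass < 3; ++pass) {  // 0: td, 1: lo, 2: apex
      for (int c = 0; c < n_cand; ++c) {
        if (!okev[c] || tev[c] > t_first + 1e-9) continue;
        const int ty = cand_type[c];
        const bool is_td = (ty == EV_TD_L || ty == EV_TD_R);
        const bool is_lo = (ty == EV_LO_L || ty == EV_LO_R);
        if ((pass == 0 && is_td) || (pass == 1 && is_lo) ||
            (pass == 2 && ty == EV_APEX))
          apply[n_apply++] = c;
      }
    }
    // state at the (first) event time
    {
      const int c0 = apply[0];
      if (std::fabs(tev[c0] - t_first) < 1e-12) {
        for (int i = 0; i < NS; ++i) zatev[i] = zev[c0][i];
        have_state = true;
      }
    }
    if (!have_state) {
      if (!advance_to(S, t, z, t_first, zatev, h_try)) {
        status = 5;
        break;
      }
    }
    t = t_first;
    for (int i = 0; i < NS; ++i) z[i] = zatev[i];

    bool stop_now = false;
    for (int c2 = 0; c2 < n_apply && !done; ++c2) {
      const int ty = cand_type[apply[c2]];
      if (ty == EV_APEX) {
        const bool all_cycled = (n_td[0] >= 1 && n_lo[0] >= 1 &&
                                 n_td[1] >= 1 && n_lo[1] >= 1);
        ev_t.push_back(t);
        ev_leg.push_back(-1);
        ev_type.push_back(2);
        if (stop_mode == 4) {
          ++n_crossed;
          if (n_crossed >= n_cross) {
            status = 0;
            stop_now = true;
            done = true;
          }
        } else if (stop_mode == 1 || (stop_mode == 0 && all_cycled)) {
          status = 0;
          stop_now = true;
          done = true;
        }
        continue;
      }
      const int leg = (ty == EV_TD_L || ty == EV_LO_L) ? 0 : 1;
      const bool is_td = (ty == EV_TD_L || ty == EV_TD_R);
      if (is_td) {
        const double a = z[2 + leg];
        if (std::fabs(a) >= M_PI / 2 - 1e-9) {
          status = 1;
          done = true;
          break;
        }
        // premature touchdown: leg still rotating in the direction of travel
        if (check_premature) {
          const double dir =
              (z[4] > 1e-8) ? 1.0 : ((z[4] < -1e-8) ? -1.0 : 0.0);
          if (dir * z[6 + leg] > wtol_prem) {
            ev_t.push_back(t);
            ev_leg.push_back(leg);
            ev_type.push_back(0);
            status = 2;
            done = true;
            break;
          }
        }
        const double ta = std::tan(a), ca = std::cos(a);
        z[6 + leg] = -(z[4] + z[5] * ta) * ca * ca / z[1];
        anchors[leg] = z[0] + z[1] * ta;
        S.modes[leg] = 1;
        ++n_td[leg];
        ev_t.push_back(t);
        ev_leg.push_back(leg);
        ev_type.push_back(0);
        ++n_events;
      } else {
        S.modes[leg] = 0;
        anchors[leg] = NA_REAL;
        ++n_lo[leg];
        ev_t.push_back(t);
        ev_leg.push_back(leg);
        ev_type.push_back(1);
        ++n_events;
      }
      if (stop_mode == 2) {
        status = 0;
        stop_now = true;
        done = true;
      }
    }
    track(z);
    record(t, z);
    fill_eval(t, z);
    if (stop_now || done) break;
    if (n_events > max_events) {
      status = 3;
      break;
    }
    h = std::min(h_try, 1e-3);
    deriv(z, S.modes, S.P, S.k1);
  }

  if (i_eval < n_eval) fill_eval(t_max + 1.0, z);  // pad trailing (shouldn't happen)

  List out = List::create(
      _["status"] = status, _["t_end"] = t,
      _["z_end"] = NumericVector(z, z + NS),
      _["modes_end"] = IntegerVector::create(S.modes[0], S.modes[1]),
      _["anchors_end"] = NumericVector::create(anchors[0], anchors[1]),
      _["ev_time"] = wrap(ev_t), _["ev_leg"] = wrap(ev_leg),
      _["ev_type"] = wrap(ev_type), _["energy0"] = E0,
      _["energy_drift"] = e_drift, _["constraint_max"] = c_max,
      _["amp_max"] = amp_max, _["anterior_scuff"] = n_anterior_scuff);
  if (n_eval > 0) out["dense"] = dense;
  if (record_steps) {
    const int n = rec_t.size();
    NumericMatrix M(n, 1 + NS + 2);
    for (int r = 0; r < n; ++r) {
      M(r, 0) = rec_t[r];
      for (int i = 0; i < NS; ++i) M(r, 1 + i) = rec_z[r * NS + i];
      M(r, 9) = rec_m[2 * r];
      M(r, 10) = rec_m[2 * r + 1];
    }
    out["steps"] = M;
  }
  return out;
}
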