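// Lagrangian parcel tracking under Stokes drag + effective-dipole magnetic
// force, with capture / wall-trap / escape event detection and optional
// accumulation of the reaction momentum sink for two-way coupling.
//
// The drag ODE  m_p du_p/dt = gamma (u - u_p) + F_m  is stiff (response time
// tau_p = m_p/gamma ~ 1e-7 s at nominal parameters).  The default integrator
// freezes u and F_m over a step and advances the ODE exactly:
//   u_p(t+dt) = v_t + (u_p - v_t) exp(-dt/tau),   v_t = u + F_m/gamma
//   x(t+dt)   = x + v_t dt + tau (u_p - v_t) (1 - exp(-dt/tau))
// with dt bounded so the displacement stays below a spatial resolution target
// (fine near the elements, coarser elsewhere).  A classical RK4 integrator on
// the full stiff system (dt << tau) is provided as a cross-check oracle.

#include "field_core.h"
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Flow {
  bool analytic;
  double u_avg, Hc;
  // node grid (cell-corner velocities), present when !analytic
  std::vector<double> xn, yn;
  NumericMatrix Un, Vn;
  double x0w, x1w; // window; analytic profile outside

  double poiseuille(double y) const {
    if (y < 0.0 || y > Hc) return 0.0;
    const double s = y / Hc;
    return 6.0 * u_avg * s * (1.0 - s);
  }

  static int locate(const std::vector<double>& g, double v) {
    int i = int(std::upper_bound(g.begin(), g.end(), v) - g.begin()) - 1;
    if (i < 0) i = 0;
    if (i > int(g.size()) - 2) i = int(g.size()) - 2;
    return i;
  }

  void sample(double x, double y, double* u, double* v) const {
    if (y < 0.0) y = 0.0;
    if (y > Hc) y = Hc;
    if (analytic || x < x0w || x > x1w) {
      *u = poiseuille(y);
      *v = 0.0;
      return;
    }
    const int i = locate(xn, x), j = locate(yn, y);
    const double tx = (x - xn[i]) / (xn[i + 1] - xn[i]);
    const double ty = (y - yn[j]) / (yn[j + 1] - yn[j]);
    *u = (1 - tx) * (1 - ty) * Un(i, j) + tx * (1 - ty) * Un(i + 1, j)
       + (1 - tx) * ty * Un(i, j + 1) + tx * ty * Un(i + 1, j + 1);
    *v = (1 - tx) * (1 - ty) * Vn(i, j) + tx * (1 - ty) * Vn(i + 1, j)
       + (1 - tx) * ty * Vn(i, j + 1) + tx * ty * Vn(i + 1, j + 1);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_track(NumericMatrix init, NumericVector mdot, List flow_spec,
               NumericMatrix elems, double Hbias, List part, List settings) {
  Flow flow;
  flow.analytic = as<bool>(flow_spec["analytic"]);
  flow.u_avg = as<double>(flow_spec["u_avg"]);
  flow.Hc = as<double>(flow_spec["Hc"]);
  const double Lc = as<double>(flow_spec["Lc"]);
  if (!flow.analytic) {
    flow.xn = as<std::vector<double> >(flow_spec["xn"]);
    flow.yn = as<std::vector<double> >(flow_spec["yn"]);
    flow.Un = as<NumericMatrix>(flow_spec["Un"]);
    flow.Vn = as<NumericMatrix>(flow_spec["Vn"]);
    flow.x0w = flow.xn.front();
    flow.x1w = flow.xn.back();
  }

  const double Vp = as<double>(part["Vp"]);
  const double mp = as<double>(part["mp"]);
  const double gamma = as<double>(part["gamma"]);
  const double Msp = as<double>(part["Msp"]);
  const double chia = as<double>(part["chia"]);
  const double tau = mp / gamma;

  const double rex = as<double>(settings["rex"]);
  const double cd = as<double>(settings["capture_dist"]);
  const double ds_near = as<double>(settings["ds_near"]);
  const double ds_far = as<double>(settings["ds_far"]);
  NumericVector nb = as<NumericVector>(settings["near_box"]); // x0,x1,y0,y1
  const double dt_max = as<double>(settings["dt_max"]);
  const double t_max = as<double>(settings["t_max"]);
  const int integrator = as<int>(settings["integrator"]); // 0 exp, 1 rk4
  const double rk4_dt = as<double>(settings["rk4_dt"]);
  const int stride = as<int>(settings["stride"]);
  const bool record = as<bool>(settings["record"]);
  const bool do_sink = as<bool>(settings["do_sink"]);
  const long max_steps = 200000000L;

  const int ne = elems.nrow();
  const int n = init.nrow();
  IntegerVector fate(n), elem_idx(n, NA_INTEGER), face(n, NA_INTEGER);
  NumericMatrix final_state(n, 5);
  IntegerVector nsteps(n);
  List trajs(record ? n : 0);

  // sink accumulators on the flow grid cells
  int snx = 0, sny = 0;
  NumericMatrix Su, Sv;
  if (do_sink) {
    snx = int(flow.xn.size()) - 1;
    sny = int(flow.yn.size()) - 1;
    Su = NumericMatrix(snx, sny);
    Sv = NumericMatrix(snx, sny);
  }

  for (int ip = 0; ip < n; ++ip) {
    double x = init(ip, 0), y = init(ip, 1);
    double up = init(ip, 2), vp = init(ip, 3);
    double t = 0.0;
    int f8 = 0, eidx = NA_INTEGER, fface = NA_INTEGER;
    long step = 0;

    std::vector<double> tr;
    if (record) {
      tr.reserve(4096);
      tr.push_back(t); tr.push_back(x); tr.push_back(y);
      tr.push_back(up); tr.push_back(vp);
    }

    while (t < t_max && step < max_steps) {
      ++step;
      double uf, vf, Fx, Fy;
      flow.sample(x, y, &uf, &vf);
      force_excl(elems, Hbias, Vp, Msp, chia, rex, x, y, &Fx, &Fy);

      if (integrator == 0) {
        const double vtx = uf + Fx / gamma, vty = vf + Fy / gamma;
        const double spd = std::max(std::hypot(vtx, vty), std::hypot(up, vp));
        const double ds = (x >= nb[0] && x <= nb[1] && y >= nb[2] && y <= nb[3])
                            ? ds_near : ds_far;
        double dt = std::min(dt_max, ds / std::max(spd, 1e-12));
        if (t + dt > t_max) dt = t_max - t;
        const double e = std::exp(-dt / tau);
        const double up0 = up, vp0 = vp;
        up = vtx + (up0 - vtx) * e;
        vp = vty + (vp0 - vty) * e;
        const double dxs = vtx * dt + tau * (up0 - vtx) * (1.0 - e);
        const double dys = vty * dt + tau * (vp0 - vty) * (1.0 - e);
        if (do_sink && mdot[ip] > 0.0) {
          const double xm = x + 0.5 * dxs, ym = y + 0.5 * dys;
          if (xm >= flow.x0w && xm <= flow.x1w && ym >= 0 && ym <= flow.Hc) {
            const int ci = Flow::locate(flow.xn, xm);
            const int cj = Flow::locate(flow.yn, ym);
            const double Vc = (flow.xn[ci + 1] - flow.xn[ci]) *
                              (flow.yn[cj + 1] - flow.yn[cj]);
            const double wgt = (mdot[ip] / mp) * dt / Vc;
            Su(ci, cj) -= gamma * (uf - 0.5 * (up0 + up)) * wgt;
            Sv(ci, cj) -= gamma * (vf - 0.5 * (vp0 + vp)) * wgt;
          }
        }
        x += dxs; y += dys;
        t += dt;
      } else {
        // classical RK4 on (x, y, up, vp); dt fixed well below stability limit
        double dt = std::min(rk4_dt, t_max - t);
        const double s0[4] = {x, y, up, vp};
        double k[4][4], st[4];
        for (int m = 0; m < 4; ++m) {
          const double c = (m == 3) ? 1.0 : 0.5;
          for (int q = 0; q < 4; ++q)
            st[q] = (m == 0) ? s0[q] : s0[q] + c * dt * k[m - 1][q];
          double ufs, vfs, Fxs, Fys;
          flow.sample(st[0], st[1], &ufs, &vfs);
          force_excl(elems, Hbias, Vp, Msp, chia, rex, st[0], st[1], &Fxs, &Fys);
          k[m][0] = st[2];
          k[m][1] = st[3];
          k[m][2] = (gamma * (ufs - st[2]) + Fxs) / mp;
          k[m][3] = (gamma * (vfs - st[3]) + Fys) / mp;
        }
        x = s0[0] + dt / 6.0 * (k[0][0] + 2 * k[1][0] + 2 * k[2][0] + k[3][0]);
        y = s0[1] + dt / 6.0 * (k[0][1] + 2 * k[1][1] + 2 * k[2][1] + k[3][1]);
        up = s0[2] + dt / 6.0 * (k[0][2] + 2 * k[1][2] + 2 * k[2][2] + k[3][2]);
        vp = s0[3] + dt / 6.0 * (k[0][3] + 2 * k[1][3] + 2 * k[2][3] + k[3][3]);
        t += dt;
      }

      // --- event detection ---
      if (x > Lc) { f8 = 4; break; }

      bool captured = false;
      for (int e = 0; e < ne && !captured; ++e) {
        const double cx = elems(e, 0), cy = elems(e, 1);
        const double w = elems(e, 2), h = elems(e, 3);
        if (x >= cx - w - cd && x <= cx + w + cd &&
            y >= cy - h - cd && y <= cy + h + cd) {
          captured = true;
          eidx = e + 1;
          // face: dominant normalized excursion from the center
          const double ex = (x - cx) / w, ey = (y - cy) / h;
          if (std::fabs(ey) >= std::fabs(ex)) fface = (ey >= 0) ? 1 : 2;
          else fface = (ex >= 0) ? 4 : 3;
        }
      }
      if (captured) { f8 = 1; break; }

      // wall contact: trapped only if the net wall-normal force (magnetic
      // plus drag from the local fluid motion, quasi-static contact) points
      // into the wall; otherwise the parcel slides along the wall
      if (y < cd) {
        double Fxw, Fyw, ufw, vfw;
        force_excl(elems, Hbias, Vp, Msp, chia, rex, x, cd, &Fxw, &Fyw);
        flow.sample(x, cd, &ufw, &vfw);
        if (Fyw + gamma * vfw < 0.0) { f8 = 2; y = cd; break; }
        y = cd;
        if (vp < 0.0) vp = 0.0;
      } else if (y > flow.Hc - cd) {
        double Fxw, Fyw, ufw, vfw;
        force_excl(elems, Hbias, Vp, Msp, chia, rex, x, flow.Hc - cd,
                   &Fxw, &Fyw);
        flow.sample(x, flow.Hc - cd, &ufw, &vfw);
        if (Fyw + gamma * vfw > 0.0) { f8 = 3; y = flow.Hc - cd; break; }
        y = flow.Hc - cd;
        if (vp > 0.0) vp = 0.0;
      }

      if (record && (step % stride == 0)) {
        tr.push_back(t); tr.push_back(x); tr.push_back(y);
        tr.push_back(up); tr.push_back(vp);
      }
    }

    fate[ip] = f8;
    elem_idx[ip] = eidx;
    face[ip] = fface;
    final_state(ip, 0) = x; final_state(ip, 1) = y;
    final_state(ip, 2) = up; final_state(ip, 3) = vp;
    final_state(ip, 4) = t;
    nsteps[ip] = (step > INT_MAX) ? INT_MAX : int(step);

    if (record) {
      tr.push_back(t); tr.push_back(x); tr.push_back(y);
      tr.push_back(up); tr.push_back(vp);
      const int nr = int(tr.size() / 5);
      NumericMatrix m(nr, 5);
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < 5; ++c) m(r, c) = tr[size_t(r) * 5 + c];
      colnames(m) = CharacterVector::create("t", "x", "y", "u_p", "v_p");
      trajs[ip] = m;
    }
  }

  List out = List::create(
    _["fate"] = fate, _["element"] = elem_idx, _["face"] = face,
    _["final"] = final_state, _["nsteps"] = nsteps);
  if (record) out["trajectories"] = trajs;
  if (do_sink) { out["Su"] = Su; out["Sv"] = Sv; }
  return out;
}
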