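// Shared closed-form field/force kernels (see field.cpp for the derivation).
#ifndef MAGSEP_FIELD_CORE_H
#define MAGSEP_FIELD_CORE_H

#include <Rcpp.h>

static const double MAGSEP_MU0 = 4e-7 * M_PI;

struct FieldGrad {
  double Hx, Hy;
  double dHxdx, dHxdy; // dHydx = dHxdy, dHydy = -dHxdx
};

static inline FieldGrad elem_field_grad(double x, double y,
                                        double w, double h, double Mes) {
  const double xp = x + w, xm = x - w, yp = y + h, ym = y - h;
  const double r1 = xp * xp + ym * ym;
  const double r2 = xp * xp + yp * yp;
  const double r3 = xm * xm + ym * ym;
  const double r4 = xm * xm + yp * yp;
  FieldGrad f;
  const double c4 = Mes / (4.0 * M_PI), c2 = Mes / (2.0 * M_PI);
  f.Hx = c4 * (std::log(r1) - std::log(r3) - std::log(r2) + std::log(r4));
  f.Hy = c2 * (std::atan(xp / ym) - std::atan(xm / ym)
             - std::atan(xp / yp) + std::atan(xm / yp));
  f.dHxdx = c2 * (xp / r1 - xp / r2 - xm / r3 + xm / r4);
  f.dHxdy = c2 * (ym / r1 - yp / r2 - ym / r3 + yp / r4);
  return f;
}

static inline FieldGrad total_field_grad(const Rcpp::NumericMatrix& elems,
                                         double Hbias, double x, double y) {
  FieldGrad t;
  t.Hx = 0.0; t.Hy = Hbias; t.dHxdx = 0.0; t.dHxdy = 0.0;
  for (int e = 0; e < elems.nrow(); ++e) {
    FieldGrad f = elem_field_grad(x - elems(e, 0), y - elems(e, 1),
                                  elems(e, 2), elems(e, 3), elems(e, 4));
    t.Hx += f.Hx; t.Hy += f.Hy; t.dHxdx += f.dHxdx; t.dHxdy += f.dHxdy;
  }
  return t;
}

static inline double f_of_H_cpp(double Hmag, double Msp, double chia) {
  const double Hsat = Msp / chia;
  return (Hmag < Hsat) ? chia : Msp / Hmag;
}

static inline void force_at(const Rcpp::NumericMatrix& elems, double Hbias,
                            double Vp, double Msp, double chia,
                            double x, double y, double* Fx, double* Fy) {
  FieldGrad t = total_field_grad(elems, Hbias, x, y);
  const double Hmag = std::hypot(t.Hx, t.Hy);
  const double c = MAGSEP_MU0 * Vp * f_of_H_cpp(Hmag, Msp, chia);
  *Fx = c * (t.Hx * t.dHxdx + t.Hy * t.dHxdy);
  *Fy = c * (t.Hx * t.dHxdy - t.Hy * t.dHxdx);
}

static inline bool apply_corner_exclusion(const Rcpp::NumericMatrix& elems,
                                          double rex, double* x, double* y) {
  if (rex <= 0.0) return false;
  bool moved = false;
  for (int e = 0; e < elems.nrow(); ++e) {
    const double cx = elems(e, 0), cy = elems(e, 1);
    const double w = elems(e, 2), h = elems(e, 3);
    const double corners[4][2] = {
      {cx - w, cy - h}, {cx + w, cy - h}, {cx - w, cy + h}, {cx + w, cy + h}};
    for (int k = 0; k < 4; ++k) {
      const double dx = *x - corners[k][0], dy = *y - corners[k][1];
      const double d = std::hypot(dx, dy);
      if (d < rex) {
        if (d == 0.0) {
          const double sx = (*x >= cx) ? 1.0 : -1.0;
          const double sy = (*y >= cy) ? 1.0 : -1.0;
          *x = corners[k][0] + rex * M_SQRT1_2 * sx;
          *y = corners[k][1] + rex * M_SQRT1_2 * sy;
        } else {
          *x = corners[k][0] + dx / d * rex;
          *y = corners[k][1] + dy / d * rex;
        }
        moved = true;
      }
    }
  }
  return moved;
}

static inline void force_excl(const Rcpp::NumericMatrix& elems, double Hbias,
                              double Vp, double Msp, double chia, double rex,
                              double x, double y, double* Fx, double* Fy) {
  apply_corner_exclusion(elems, rex, &x, &y);
  force_at(elems, Hbias, Vp, Msp, chia, x, y, Fx, Fy);
}

#endif
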