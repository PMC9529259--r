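#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dynamic-threshold ODE:  tau * dx/dt = sign(u - x) * |u - x|^b
// u(t) is linear between stimulus samples. Classical RK4 with adaptive
// sub-stepping: the sub-step is bounded both by the 10%-of-gap rule and
// by the local linearized decay rate lambda = b*|u-x|^(b-1)/tau. When the
// dynamics are so stiff that the accuracy rule would demand more than ~64
// sub-steps per sample (e.g. b << 1 where the threshold rides at a
// vanishing lag), stepping switches to the exact constant-force
// relaxation toward the end-of-substep force, which is unconditionally
// stable and exact on flat segments; the committed lag error is below the
// per-sample force increment.

static inline double drift(double u, double x, double b, double tau) {
  double w = u - x;
  if (w == 0.0) return 0.0;
  double s = (w > 0.0) ? 1.0 : -1.0;
  return s * std::pow(std::fabs(w), b) / tau;
}

// closed-form relaxation of x toward constant u over time hs
static inline double relax_exact(double u, double x, double b, double tau,
                                 double hs) {
  double w0 = std::fabs(u - x);
  if (w0 == 0.0) return u;
  double s = (u > x) ? 1.0 : -1.0;
  double w;
  if (b == 1.0) {
    w = w0 * std::exp(-hs / tau);
  } else {
    double base = std::pow(w0, 1.0 - b) - (1.0 - b) * hs / tau;
    if (b < 1.0 && base <= 0.0) {
      w = 0.0;
    } else {
      w = std::pow(base, 1.0 / (1.0 - b));
    }
  }
  return u - s * w;
}

// [[Rcpp::export]]
NumericVector integrate_threshold_cpp(NumericVector t, NumericVector u,
                                      double b, double tau, double x0,
                                      double max_frac, double absorb_tol,
                                      int max_substeps) {
  R_xlen_t n = t.size();
  if (u.size() != n) stop("time and force vectors must have equal length");
  NumericVector x(n);
  double xc = x0;
  x[0] = xc;
  for (R_xlen_t i = 0; i + 1 < n; ++i) {
    double h = t[i + 1] - t[i];
    if (!(h > 0.0)) stop("time grid must be strictly increasing");
    double u0 = u[i];
    double du = (u[i + 1] - u0) / h;
    bool flat = (u[i + 1] == u0);
    double hs_floor = h / 64.0;
    double tl = 0.0;
    int nsub = 0;
    while (tl < h) {
      if (++nsub > max_substeps)
        stop("sub-stepping budget exceeded at sample %d (gap %.3e, b %.3g, tau %.3g)",
             (int)(i + 1), std::fabs(u0 + du * tl - xc), b, tau);
      double uc = u0 + du * tl;
      double w = std::fabs(uc - xc);
      double hs;
      if (w <= absorb_tol) {
        // absorption clamp: snap onto u; for a constant segment x stays there
        xc = uc;
        if (flat) { xc = u0; break; }
        // gap regrows linearly from ~0: choose hs so that the predicted
        // end-of-step stiffness satisfies lambda(w_pred) * hs <= max_frac
        double adu = std::fabs(du);
        hs = std::pow(max_frac * tau / (b * std::pow(adu, b - 1.0)), 1.0 / b);
        if (!(hs > 0.0) || !std::isfinite(hs)) hs = h - tl;
      } else {
        double lambda = b * std::pow(w, b - 1.0) / tau;   // local decay rate
        double speed = std::pow(w, b) / tau + std::fabs(du);
        double h_lam = max_frac / lambda;
        double h_gap = max_frac * w / speed;
        hs = (h_lam < h_gap) ? h_lam : h_gap;
      }
      if (hs < hs_floor) {
        // stiff regime: exact relaxation toward the frozen end force
        hs = hs_floor;
        if (hs > h - tl) hs = h - tl;
        double uf = u0 + du * (tl + hs);
        xc = relax_exact(uf, xc, b, tau, hs);
        tl += hs;
        continue;
      }
      if (hs > h - tl) hs = h - tl;
      // guard against underflow-small steps that cannot advance tl
      if (tl + hs == tl) hs = h - tl;
      double k1 = drift(uc, xc, b, tau);
      double um = u0 + du * (tl + 0.5 * hs);
      double k2 = drift(um, xc + 0.5 * hs * k1, b, tau);
      double k3 = drift(um, xc + 0.5 * hs * k2, b, tau);
      double ue = u0 + du * (tl + hs);
      double k4 = drift(ue, xc + hs * k3, b, tau);
      double xn = xc + hs / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      // never overshoot the fixed point within a constant-force segment
      if (flat && (u0 - xc) * (u0 - xn) < 0.0) xn = u0;
      xc = xn;
      tl += hs;
    }
    x[i + 1] = xc;
  }
  return x;
}
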