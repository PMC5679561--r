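#include <Rcpp.h>
using namespace Rcpp;

// Two-mass vocal-fold model right-hand side and fixed-step RK4 driver.
//
// State layout: x1l, v1l, x2l, v2l, x1r, v1r, x2r, v2r
// (displacement cm, velocity cm/ms; lower mass = 1, upper mass = 2).
//
// Parameter vector layout (internal cgs-ms units):
//  [0..8]  left side : m1, m2, k1, k2, kc, c1, c2, r1, r2
//  [9..17] right side: m1, m2, k1, k2, kc, c1, c2, r1, r2
//  [18] x01  [19] x02  [20] a01  [21] a02  [22] d1  [23] l
//  [24] Ps (g cm^-1 ms^-2)  [25] smoothing width for the unit step (0 = sharp)

static inline double theta(double x, double eps) {
  if (eps <= 0.0) return x > 0.0 ? 1.0 : 0.0;
  return 0.5 * (1.0 + std::tanh(x / eps));
}

// Composite constants derived once per integration so the inner right-hand
// side needs no divisions except the Bernoulli area ratio.
struct tmm_consts {
  double a01, a02, l, Ps_ld1, eps;
  // per side: spring/damper rows divided by mass, collision gains,
  // pressure-force gain
  double k1kc_m1[2], r1_m1[2], kc_m1[2], inv_m1[2];
  double kc_m2[2], k2kc_m2[2], r2_m2[2];
  double c1_gain[2], c2_gain[2];
};

static tmm_consts make_consts(const double *p) {
  tmm_consts c;
  c.a01 = p[20]; c.a02 = p[21]; c.l = p[23];
  c.Ps_ld1 = p[24] * p[23] * p[22];
  c.eps = p[25];
  for (int side = 0; side < 2; ++side) {
    const double *q = p + 9 * side;
    const double m1 = q[0], m2 = q[1], k1 = q[2], k2 = q[3], kc = q[4];
    const double c1 = q[5], c2 = q[6], r1 = q[7], r2 = q[8];
    c.k1kc_m1[side] = (k1 + kc) / m1;
    c.r1_m1[side] = r1 / m1;
    c.kc_m1[side] = kc / m1;
    c.inv_m1[side] = 1.0 / m1;
    c.kc_m2[side] = kc / m2;
    c.k2kc_m2[side] = (k2 + kc) / m2;
    c.r2_m2[side] = r2 / m2;
    c.c1_gain[side] = c1 / (m1 * 2.0 * c.l);
    c.c2_gain[side] = c2 / (m2 * 2.0 * c.l);
  }
  return c;
}

static inline void tmm_rhs(const double *s, const tmm_consts &c,
                           double *ds) {
  const double a1 = c.a01 + c.l * (s[0] + s[4]);
  const double a2 = c.a02 + c.l * (s[2] + s[6]);
  const double amin = a1 < a2 ? a1 : a2;

  // Bernoulli force on the lower masses; zero once the lower glottis
  // closes, and zero for a rectangular open glottis (amin = a1).
  double F1 = 0.0;
  const double th1 = theta(a1, c.eps);
  if (th1 > 0.0) {
    const double ratio = amin / a1;
    F1 = c.Ps_ld1 * (1.0 - theta(amin, c.eps) * ratio * ratio) * th1;
  }

  // Collision terms: restoring accelerations active only while a_i < 0.
  const double th_n1 = theta(-a1, c.eps), th_n2 = theta(-a2, c.eps);

  for (int side = 0; side < 2; ++side) {
    const double *x = s + 4 * side;
    double *dx = ds + 4 * side;
    const double I1 = -th_n1 * c.c1_gain[side] * a1;
    const double I2 = -th_n2 * c.c2_gain[side] * a2;
    dx[0] = x[1];
    dx[1] = -c.k1kc_m1[side] * x[0] - c.r1_m1[side] * x[1] +
            c.kc_m1[side] * x[2] + I1 + F1 * c.inv_m1[side];
    dx[2] = x[3];
    dx[3] = c.kc_m2[side] * x[0] - c.k2kc_m2[side] * x[2] -
            c.r2_m2[side] * x[3] + I2;
  }
}

// [[Rcpp::export]]
List tmm_integrate_cpp(NumericVector params, NumericVector state0,
                       double dt, int n_steps, int transient_steps,
                       int decim) {
  if (params.size() != 26) stop("expected 26 model parameters");
  if (state0.size() != 8) stop("expected 8 state entries");
  if (dt <= 0.0 || n_steps <= 0 || decim <= 0 || transient_steps < 0)
    stop("invalid integration controls");

  const double *p = params.begin();
  const tmm_consts cst = make_consts(p);
  double s[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int i = 0; i < 8; ++i) s[i] = state0[i];

  const int n_out = (n_steps - transient_steps + decim - 1) / decim;
  if (n_out <= 0) stop("no output samples after transient");
  NumericMatrix out(n_out, 8);
  NumericVector time(n_out), a1v(n_out), a2v(n_out);

  const double l = p[23];
  int k_out = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step >= transient_steps && (step - transient_steps) % decim == 0 &&
        k_out < n_out) {
      for (int i = 0; i < 8; ++i) out(k_out, i) = s[i];
      time[k_out] = step * dt;
      a1v[k_out] = p[20] + l * (s[0] + s[4]);
      a2v[k_out] = p[21] + l * (s[2] + s[6]);
      ++k_out;
    }
    if (step == n_steps) break;

    tmm_rhs(s, cst, k1);
    for (int i = 0; i < 8; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    tmm_rhs(tmp, cst, k2);
    for (int i = 0; i < 8; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    tmm_rhs(tmp, cst, k3);
    for (int i = 0; i < 8; ++i) tmp[i] = s[i] + dt * k3[i];
    tmm_rhs(tmp, cst, k4);
    bool bad = false;
    for (int i = 0; i < 8; ++i) {
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(s[i]) || std::fabs(s[i]) > 1e3) bad = true;
    }
    if (bad)
      return List::create(_["blowup"] = true,
                          _["blowup_time_ms"] = (step + 1) * dt);
  }

  return List::create(_["blowup"] = false, _["time"] = time,
                      _["state"] = out, _["a1"] = a1v, _["a2"] = a2v);
}
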