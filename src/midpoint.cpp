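#include <Rcpp.h>
#include <cmath>

// Fixed-step midpoint (improved Euler) integration of the delayed
// three-variable CTC system.  The parameter vector is flattened by the R
// wrapper (see .flatten_params in R/integrate.R); both sides must agree on
// the layout below.
enum Par {
  R_CONST, R_DYN, P_CONST, P_DYN, T_DAY, M_FB, DELAY,
  SPIKE_START, SPIKE_DURATION, SPIKE_FACTOR,
  K_DEAD, K_DEADC, K_MET, K_METC, N_C,
  PLACEMENT, T_DEV, R_VOL, EFF_DEV, EFF_DEVC, N_CDEV,
  WINDOW_START, WINDOW_END,
  P_LYMPH, P_LYMPHC, L_PASS, L_PASSC, L_META, L_METAC,
  T_PEAK, N_PAR
};

static inline double base_rate(double t, double cst, double dyn,
                               const double *q) {
  double v = cst + 0.5 * dyn *
    (1.0 + std::cos(2.0 * M_PI * (t - q[T_PEAK]) / q[T_DAY]));
  if (q[SPIKE_FACTOR] != 1.0 && t >= q[SPIKE_START] &&
      t < q[SPIKE_START] + q[SPIKE_DURATION])
    v *= q[SPIKE_FACTOR];
  return v;
}

static inline bool dev_on(double t, const double *q) {
  if (q[PLACEMENT] == 0.0 || q[T_DEV] <= 0.0) return false;
  if (q[WINDOW_START] >= 0.0)            // one-off absolute window
    return t >= q[WINDOW_START] && t < q[WINDOW_END];
  double tm = t - std::floor(t / q[T_DAY]) * q[T_DAY];  // t mod T_day
  return tm < q[T_DEV];
}

// instantaneous release of singles (r) and clusters (p) given delayed burden
static inline void release(double t, double md, const double *q,
                           double *r, double *p) {
  double br = base_rate(t, q[R_CONST], q[R_DYN], q);
  double bp = base_rate(t, q[P_CONST], q[P_DYN], q);
  if (q[PLACEMENT] == 2.0) {             // implanted: primary release passes
    double on = dev_on(t, q) ? 1.0 : 0.0;  // the device, metastatic bypasses
    *r = br * ((1.0 - q[EFF_DEV]  * on) + q[M_FB] * md);
    *p = bp * ((1.0 - q[EFF_DEVC] * on) + q[M_FB] * md);
  } else {
    *r = br * (1.0 + q[M_FB] * md);
    *p = bp * (1.0 + q[M_FB] * md);
  }
}

static inline void rhs(double t, double n, double c, double md,
                       const double *q, double *dn, double *dc, double *dm) {
  double r, p;
  release(t, md, q, &r, &p);
  double fdyn = -n * (q[K_MET] + q[K_DEAD]) + c * q[K_DEADC] * q[N_C];
  double gdyn = -c * (q[K_METC] + q[K_DEADC]);
  double fdev = 0.0, gdev = 0.0;
  if (dev_on(t, q)) {
    fdev = q[R_VOL] * (-n * q[EFF_DEV] + c * q[EFF_DEVC] * q[N_CDEV]);
    gdev = -q[R_VOL] * c * q[EFF_DEVC];
  }
  *dn = r * ((1.0 - q[P_LYMPH])  + q[P_LYMPH]  * q[L_PASS])  + fdyn + fdev;
  *dc = p * ((1.0 - q[P_LYMPHC]) + q[P_LYMPHC] * q[L_PASSC]) + gdyn + gdev;
  *dm = q[K_MET] * n + q[K_METC] * c +
        r * q[P_LYMPH]  * q[L_META] +
        p * q[P_LYMPHC] * q[L_METAC];
}

// [[Rcpp::export(name = ".midpoint_core")]]
Rcpp::List midpoint_core(Rcpp::NumericVector y0, double t0, int n_steps,
                         double h, Rcpp::NumericVector m_hist,
                         Rcpp::NumericVector par) {
  if (par.size() != N_PAR) Rcpp::stop("parameter vector has wrong length");
  if (n_steps < 0) Rcpp::stop("n_steps must be non-negative");
  const double *q = par.begin();

  // delay measured in whole steps; m_hist holds m on [t0 - d*h, t0]
  const int d = m_hist.size() - 1;
  if (d < 0) Rcpp::stop("m_hist must contain at least the value at t0");

  std::vector<double> m_full(d + n_steps + 1);
  for (int i = 0; i <= d; ++i) m_full[i] = m_hist[i];

  Rcpp::NumericVector ns(n_steps + 1), cs(n_steps + 1), ms(n_steps + 1),
                      rs(n_steps + 1), ps(n_steps + 1);
  double n = y0[0], c = y0[1], m = y0[2];
  long clipped = 0;

  for (int k = 0; k <= n_steps; ++k) {
    double t = t0 + k * h;
    double md_k = (d == 0) ? m : m_full[k];
    ns[k] = n; cs[k] = c; ms[k] = m;
    release(t, md_k, q, &rs[k], &ps[k]);
    if (k == n_steps) break;

    // stage 1: slope at t_k
    double dn1, dc1, dm1;
    rhs(t, n, c, md_k, q, &dn1, &dc1, &dm1);
    double nh = n + 0.5 * h * dn1;
    double ch = c + 0.5 * h * dc1;
    double mh = m + 0.5 * h * dm1;

    // stage 2: slope at the interval midpoint; the delayed burden at
    // t_k + h/2 - delay is linearly interpolated between stored grid values
    double md_h = (d == 0) ? mh : 0.5 * (m_full[k] + m_full[k + 1]);
    double dn2, dc2, dm2;
    rhs(t + 0.5 * h, nh, ch, md_h, q, &dn2, &dc2, &dm2);

    n += h * dn2; c += h * dc2; m += h * dm2;
    if (n < 0.0) { n = 0.0; ++clipped; }
    if (c < 0.0) { c = 0.0; ++clipped; }
    if (m < 0.0) { m = 0.0; ++clipped; }
    if (!std::isfinite(n) || !std::isfinite(c) || !std::isfinite(m))
      Rcpp::stop("non-finite state at t = %f min (step %d)", t + h, k + 1);
    m_full[d + k + 1] = m;
  }

  return Rcpp::List::create(
    Rcpp::Named("n") = ns, Rcpp::Named("c") = cs, Rcpp::Named("m") = ms,
    Rcpp::Named("r") = rs, Rcpp::Named("p") = ps,
    Rcpp::Named("clipped") = (double)clipped);
}
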