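// Trial-level simulation core for continuous-time rate networks.
//
// Explicit Euler integration of
//   tau dx/dt = -x + J r + B u,   r = f(x)
// with additive activation perturbations, four clamped bias neurons, and
// (optionally) per-step accumulation of the supralinear Hebbian eligibility
// trace  e_ij += S(r_j(t-1) * (x_i(t) - xbar_i(t))).
//
// All supported S kinds are multiplicative (S(ab) = S(a)S(b)), so the per-step
// accumulation is performed as a rank-1 outer product S(x - xbar) S(r_prev)^T.
// The R-level accumulate_eligibility() evaluates the elementwise definition
// and the test suite asserts equality of the two routes.
//
// Randomness goes through R's RNG (unif_rand) so that set.seed() at the R
// level makes whole trials bitwise reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double s_apply(double v, int s_kind) {
  switch (s_kind) {
  case 0: return v * v * v;                          // cubic
  case 1: return v * std::fabs(v);                   // signed square
  case 2: return v;                                  // identity
  default: {                                         // signed square root
      double a = std::sqrt(std::fabs(v));
      return v >= 0 ? a : -a;
    }
  }
}

// variant: 0 = canonical (tanh), 1 = dale (nonnegative piecewise linear)
static inline void response_vec(const arma::vec& x, arma::vec& r, int variant,
                                double m, double Msat) {
  const arma::uword n = x.n_elem;
  if (variant == 0) {
    for (arma::uword i = 0; i < n; ++i) r[i] = std::tanh(x[i]);
  } else {
    for (arma::uword i = 0; i < n; ++i) {
      double v = x[i] + m;
      r[i] = v < 0.0 ? 0.0 : (v > Msat ? Msat : v);
    }
  }
}

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(const arma::mat& J, const arma::mat& B,
                   const arma::mat& inputs,        // T x M
                   const arma::uvec& bias_idx,     // 0-based
                   int variant, double m, double Msat,
                   double dt, double tau,
                   double pert_prob, double pert_lo, double pert_hi,
                   bool plast_on, int s_kind, double alpha_avg,
                   bool record_full,
                   int sched_step, int sched_neuron, double sched_amp,
                   Nullable<NumericVector> x_init,
                   const arma::uvec& output_idx) {   // 0-based
  const arma::uword N = J.n_rows;
  const arma::uword T = inputs.n_rows;
  const double a = dt / tau;

  std::vector<bool> is_bias(N, false);
  for (arma::uword k = 0; k < bias_idx.n_elem; ++k) is_bias[bias_idx[k]] = true;

  arma::vec x(N);
  if (x_init.isNotNull()) {
    NumericVector x0(x_init);
    for (arma::uword i = 0; i < N; ++i) x[i] = x0[i];
  } else {
    for (arma::uword i = 0; i < N; ++i) x[i] = -0.1 + 0.2 * unif_rand();
  }
  for (arma::uword k = 0; k < bias_idx.n_elem; ++k) x[bias_idx[k]] = 1.0;

  arma::vec r(N), xbar = x, v(N), sv(N), sr(N);
  response_vec(x, r, variant, m, Msat);
  arma::vec x0_out = x, r0_out = r;

  arma::mat e;
  if (plast_on) e.zeros(N, N);

  arma::mat act, pot, xbars;
  if (record_full) { act.set_size(T, N); pot.set_size(T, N); xbars.set_size(T, N); }
  arma::mat outtr(T, output_idx.n_elem);

  std::vector<int> p_step, p_neuron;
  std::vector<double> p_amp;

  double r_min = r.min(), r_max = r.max();

  arma::vec drive(N);
  for (arma::uword t = 0; t < T; ++t) {
    // Euler update uses r from the previous step
    drive = J * r + B * inputs.row(t).t();
    arma::vec r_prev = r;
    x += a * (-x + drive);

    // exploratory perturbations (bias neurons exempt)
    if (pert_prob > 0.0) {
      for (arma::uword i = 0; i < N; ++i) {
        if (is_bias[i]) continue;
        if (unif_rand() < pert_prob) {
          double amp = pert_lo + (pert_hi - pert_lo) * unif_rand();
          x[i] += amp;
          p_step.push_back((int)t + 1);
          p_neuron.push_back((int)i + 1);
          p_amp.push_back(amp);
        }
      }
    }
    if ((int)t == sched_step && sched_neuron >= 0) {
      x[sched_neuron] += sched_amp;
      p_step.push_back((int)t + 1);
      p_neuron.push_back(sched_neuron + 1);
      p_amp.push_back(sched_amp);
    }

    for (arma::uword k = 0; k < bias_idx.n_elem; ++k) x[bias_idx[k]] = 1.0;

    if (!x.is_finite())
      stop("numerical failure: non-finite activation at step %d", (int)t + 1);

    response_vec(x, r, variant, m, Msat);
    xbar = alpha_avg * xbar + (1.0 - alpha_avg) * x;

    // step-t eligibility pairs x(t) with the updated running average; the
    // alternative (pre-update) pairing rescales every increment by exactly
    // 1/alpha and is therefore absorbed into the learning rate
    if (plast_on) {
      v = x - xbar;
      for (arma::uword i = 0; i < N; ++i) sv[i] = s_apply(v[i], s_kind);
      for (arma::uword i = 0; i < N; ++i) sr[i] = s_apply(r_prev[i], s_kind);
      e += sv * sr.t();
    }
    if (record_full) {
      act.row(t) = r.t();
      pot.row(t) = x.t();
      xbars.row(t) = xbar.t();
    }
    for (arma::uword k = 0; k < output_idx.n_elem; ++k)
      outtr(t, k) = r[output_idx[k]];
    double mn = r.min(), mx = r.max();
    if (mn < r_min) r_min = mn;
    if (mx > r_max) r_max = mx;
  }

  List out = List::create(
    _["x0"] = x0_out, _["r0"] = r0_out,
    _["x_final"] = x, _["r_final"] = r, _["xbar_final"] = xbar,
    _["pert_step"] = wrap(p_step), _["pert_neuron"] = wrap(p_neuron),
    _["pert_amp"] = wrap(p_amp),
    _["r_range"] = NumericVector::create(r_min, r_max),
    _["output_trace"] = outtr);
  if (plast_on) out["eligibility"] = e;
  if (record_full) {
    out["activity"] = act;
    out["potentials"] = pot;
    out["xbars"] = xbars;
  }
  return out;
}
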