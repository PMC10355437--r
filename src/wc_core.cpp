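#include <Rcpp.h>
using namespace Rcpp;

// Wilson-Cowan network integrator.
//
// Explicit Euler at step dt (ms) on
//   tau_E drE_i = -rE_i + F(cEE rE_i - cEI_i rI_i + C sum_j W_ij rE_j(t - tau_ij) + xi + P)
//   tau_I drI_i = -rI_i + F(cIE rE_i + xi)
// with F(x) = 1/(1+exp(-(x-mu)/sigma)) and, when plasticity is on,
//   cEI_i <- cEI_i + dt * rI_i (rE_i - rho) / tau_homeo   (clamped at cei_floor).
//
// xi is an independent N(0, noise_sd^2) draw per node, per population, per step,
// injected inside the sigmoid argument; it is deliberately NOT scaled by
// sqrt(dt) (discrete-time input-fluctuation convention).
//
// The rates entering the plasticity product are slow-averaged (exponential
// moving average with time constant tau_sense, ms) before the update:
// homeostatic scaling senses activity integrated over timescales much longer
// than a gamma cycle. With tau_sense = 0 the product is taken on the
// instantaneous rates, which controls the rI-weighted average of rE instead
// of its plain time average (biased low by cov(rE, rI)/mean(rI) in an
// oscillatory regime).
//
// Delays enter through a ring buffer of past rE values; `buf` column `buf_pos`
// holds rE at the current time. Edges are a directed list (from = source j,
// to = target i) carrying integer step delays.
//
// RNG: R's own generator (set.seed() on the R side gives bit-reproducibility).

static inline double sigm(double x, double mu, double inv_sigma) {
  return 1.0 / (1.0 + std::exp(-(x - mu) * inv_sigma));
}

// [[Rcpp::export(name = ".wc_sim_cpp")]]
List wc_sim_cpp(IntegerVector edge_from, IntegerVector edge_to,
                NumericVector edge_w, IntegerVector edge_delay,
                int n, double tau_E, double tau_I, double c_EE, double c_IE,
                double P, double mu, double sigma, double C_glob,
                double noise_sd, double dt,
                NumericVector rE0, NumericVector rI0, NumericVector cei0,
                NumericMatrix buf0, int buf_pos0,
                double duration_ms,
                bool plasticity, double rho, double tau_homeo, double cei_floor,
                double tau_sense, NumericVector rEf0, NumericVector rIf0,
                int record_every, bool record_rI, int cei_every) {
  const int n_edge = edge_from.size();
  const int depth = buf0.ncol();
  const long n_steps = (long)std::floor(duration_ms / dt + 0.5);
  const double inv_sigma = 1.0 / sigma;
  const double aE = dt / tau_E, aI = dt / tau_I;
  const double ah = plasticity ? (dt / tau_homeo) : 0.0;
  const double af = tau_sense > 0.0 ? dt / tau_sense : 1.0; // 1 => instantaneous

  std::vector<double> rE(rE0.begin(), rE0.end());
  std::vector<double> rI(rI0.begin(), rI0.end());
  std::vector<double> cei(cei0.begin(), cei0.end());
  std::vector<double> rEf(rEf0.begin(), rEf0.end());
  std::vector<double> rIf(rIf0.begin(), rIf0.end());
  std::vector<double> buf(buf0.begin(), buf0.end()); // n x depth, column-major
  std::vector<double> coup(n), xe(n), xi(n), rEn(n), rIn(n);
  int pos = buf_pos0;

  const long n_rec = record_every > 0 ? n_steps / record_every : 0;
  const long n_cei = cei_every > 0 ? n_steps / cei_every : 0;
  NumericMatrix rE_rec(n_rec > 0 ? n : 0, n_rec);
  NumericMatrix rI_rec(record_rI && n_rec > 0 ? n : 0, record_rI ? n_rec : 0);
  NumericMatrix cei_rec(n_cei > 0 ? n : 0, n_cei);
  long i_rec = 0, i_cei = 0;

  const bool noisy = noise_sd > 0.0;

  for (long step = 1; step <= n_steps; ++step) {
    std::fill(coup.begin(), coup.end(), 0.0);
    for (int e = 0; e < n_edge; ++e) {
      int idx = pos - edge_delay[e];
      if (idx < 0) idx += depth;
      coup[edge_to[e]] += edge_w[e] * buf[edge_from[e] + (size_t)n * idx];
    }
    if (noisy) {
      for (int i = 0; i < n; ++i) xe[i] = noise_sd * norm_rand();
      for (int i = 0; i < n; ++i) xi[i] = noise_sd * norm_rand();
    } else {
      std::fill(xe.begin(), xe.end(), 0.0);
      std::fill(xi.begin(), xi.end(), 0.0);
    }
    for (int i = 0; i < n; ++i) {
      double de = c_EE * rE[i] - cei[i] * rI[i] + C_glob * coup[i] + xe[i] + P;
      double di = c_IE * rE[i] + xi[i];
      rEn[i] = rE[i] + aE * (-rE[i] + sigm(de, mu, inv_sigma));
      rIn[i] = rI[i] + aI * (-rI[i] + sigm(di, mu, inv_sigma));
      rEf[i] += af * (rE[i] - rEf[i]);
      rIf[i] += af * (rI[i] - rIf[i]);
      if (plasticity) {
        cei[i] += ah * rIf[i] * (rEf[i] - rho);
        if (cei[i] < cei_floor) cei[i] = cei_floor;
      }
    }
    pos = (pos + 1) % depth;
    for (int i = 0; i < n; ++i) {
      rE[i] = rEn[i];
      rI[i] = rIn[i];
      buf[i + (size_t)n * pos] = rEn[i];
    }
    if (record_every > 0 && step % record_every == 0 && i_rec < n_rec) {
      for (int i = 0; i < n; ++i) rE_rec(i, i_rec) = rE[i];
      if (record_rI) for (int i = 0; i < n; ++i) rI_rec(i, i_rec) = rI[i];
      ++i_rec;
    }
    if (cei_every > 0 && step % cei_every == 0 && i_cei < n_cei) {
      for (int i = 0; i < n; ++i) cei_rec(i, i_cei) = cei[i];
      ++i_cei;
    }
    if (step % 50000 == 0) {
      for (int i = 0; i < n; ++i)
        if (!R_finite(rE[i]) || !R_finite(rI[i]) || !R_finite(cei[i]))
          stop("simulation diverged (non-finite state) at t = %f ms", step * dt);
    }
  }

  NumericMatrix buf_out(n, depth);
  std::copy(buf.begin(), buf.end(), buf_out.begin());
  return List::create(
    _["rE"] = rE_rec, _["rI"] = rI_rec, _["cei"] = cei_rec,
    _["rE_end"] = NumericVector(rE.begin(), rE.end()),
    _["rI_end"] = NumericVector(rI.begin(), rI.end()),
    _["cei_end"] = NumericVector(cei.begin(), cei.end()),
    _["rEf_end"] = NumericVector(rEf.begin(), rEf.end()),
    _["rIf_end"] = NumericVector(rIf.begin(), rIf.end()),
    _["buf"] = buf_out, _["buf_pos"] = pos, _["n_steps"] = (double)n_steps);
}

// Balloon-Windkessel hemodynamic forward model, per region:
//   ds/dt   = r - kappa s - gamma (f - 1)
//   df/dt   = s
//   tau_h dv/dt = f - v^{1/alpha}
//   tau_h dq/dt = f (1 - (1-rho_h)^{1/f})/rho_h - v^{1/alpha} q / v
//   y = V0 (7 rho_h (1 - q) + 2 (1 - q/v) + (2 rho_h - 0.2)(1 - v))
// integrated with Euler at the sampling step of the input rate series.
// [[Rcpp::export(name = ".balloon_cpp")]]
NumericMatrix balloon_cpp(NumericMatrix r, double dt_s, double kappa,
                          double gamma, double tau_h, double alpha,
                          double rho_h, double V0) {
  const int n = r.nrow(), T = r.ncol();
  const double inv_alpha = 1.0 / alpha;
  NumericMatrix y(n, T);
  std::vector<double> s(n, 0.0), f(n, 1.0), v(n, 1.0), q(n, 1.0);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double fi = f[i] > 1e-4 ? f[i] : 1e-4;
      double vi = v[i] > 1e-4 ? v[i] : 1e-4;
      double vpow = std::pow(vi, inv_alpha);
      double ds = r(i, t) - kappa * s[i] - gamma * (fi - 1.0);
      double df = s[i];
      double dv = (fi - vpow) / tau_h;
      double dq = (fi * (1.0 - std::pow(1.0 - rho_h, 1.0 / fi)) / rho_h -
                   vpow * q[i] / vi) / tau_h;
      s[i] += dt_s * ds;
      f[i] += dt_s * df;
      v[i] += dt_s * dv;
      q[i] += dt_s * dq;
      y(i, t) = V0 * (7.0 * rho_h * (1.0 - q[i]) + 2.0 * (1.0 - q[i] / v[i]) +
                      (2.0 * rho_h - 0.2) * (1.0 - v[i]));
      if (!R_finite(y(i, t)))
        stop("hemodynamic integration diverged at sample %d", t + 1);
    }
  }
  return y;
}
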