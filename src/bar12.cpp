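// Core numerics for the stage-wise toxicity/efficacy dose-response model:
// the frailty-marginalized likelihood, an adaptive component-wise
// random-walk Metropolis sampler with spike-and-slab stage priors, and
// per-draw dose summaries used by the decision rules.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double inv_logit(double z) {
  if (z > 0) { double e = std::exp(-z); return 1.0 / (1.0 + e); }
  double e = std::exp(z); return e / (1.0 + e);
}

static inline double log_sum_exp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Outcome-cell index: yT + 2*yE in {0,1,2,3}.
// counts are stored as counts[(k*J + j)*4 + cell].

// Log-likelihood of one stage's data given that stage's parameter block
// (b0, b1, g0, g1, g2, g3, tau) and the shared frailty SD, with the
// frailty integrated out by Gauss-Hermite quadrature.
static double stage_loglik(const int* cnt, int J, const double* x,
                           const double* th, double sigma,
                           const arma::vec& ghz, const arma::vec& ghw) {
  const int Q = ghz.n_elem;
  const double s2s = M_SQRT2 * sigma;
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    const int* c = cnt + j * 4;
    int tot = c[0] + c[1] + c[2] + c[3];
    if (tot == 0) continue;
    double xj = x[j];
    double lpT0 = th[0] + std::exp(th[1]) * xj;
    double hinge = xj > th[6] ? (xj - th[6]) : 0.0;
    double lpE0 = th[2] + std::exp(th[3]) * xj + th[4] * hinge + th[5] * xj * xj;
    double p00 = 0, p10 = 0, p01 = 0, p11 = 0;
    for (int q = 0; q < Q; ++q) {
      double e = s2s * ghz[q];
      double pT = inv_logit(lpT0 + e);
      double pE = inv_logit(lpE0 + e);
      double w = ghw[q];
      p00 += w * (1 - pT) * (1 - pE);
      p10 += w * pT * (1 - pE);
      p01 += w * (1 - pT) * pE;
      p11 += w * pT * pE;
    }
    if (c[0]) ll += c[0] * std::log(std::max(p00, 1e-300));
    if (c[1]) ll += c[1] * std::log(std::max(p10, 1e-300));
    if (c[2]) ll += c[2] * std::log(std::max(p01, 1e-300));
    if (c[3]) ll += c[3] * std::log(std::max(p11, 1e-300));
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_stage_loglik(IntegerVector counts, NumericVector x,
                        NumericVector theta, double sigma,
                        NumericVector gh_z, NumericVector gh_w) {
  int J = x.size();
  arma::vec z(gh_z.begin(), gh_z.size());
  arma::vec w(gh_w.begin(), gh_w.size());
  return stage_loglik(INTEGER(counts), J, REAL(x), REAL(theta), sigma, z, w);
}

struct MvnBlock {
  arma::vec mean;
  arma::mat prec;     // inverse covariance
  double logdet;      // log |cov|
  double log_trunc;   // log normalization removed by tau truncation (0 if none)
  double tau_sd;      // marginal SD of the tau coordinate (eff blocks)
  int dim;
  double ld(const double* v) const {
    arma::vec d(dim);
    for (int i = 0; i < dim; ++i) d[i] = v[i] - mean[i];
    double q = arma::as_scalar(d.t() * prec * d);
    return -0.5 * (dim * LOG2PI + logdet + q) - log_trunc;
  }
  // density with the mean replaced by another parameter vector (the
  // autoregressive conditional spike); tau truncation renormalized at
  // the current conditioning tau (last coordinate) on [lo, hi]
  double ld_at(const double* v, const double* mu, double lo, double hi) const {
    arma::vec d(dim);
    for (int i = 0; i < dim; ++i) d[i] = v[i] - mu[i];
    double q = arma::as_scalar(d.t() * prec * d);
    double lt = 0.0;
    if (dim == 5)
      lt = std::log(std::max(R::pnorm(hi, mu[4], tau_sd, 1, 0) -
                             R::pnorm(lo, mu[4], tau_sd, 1, 0), 1e-12));
    return -0.5 * (dim * LOG2PI + logdet + q) - lt;
  }
};

struct PriorSpec {
  arma::vec slab_tox_mean, slab_tox_sd;   // length 2
  arma::vec slab_eff_mean, slab_eff_sd;   // length 4 (gamma0..gamma3)
  double tau_loc, tau_sd, tau_lo, tau_hi, tau_log_trunc;
  double phi;                              // Half-Cauchy scale
  bool frailty_on_var;                     // HC on sigma^2 rather than sigma
  double wa, wb;                           // Beta hyperparameters of omega
  std::vector<MvnBlock> spike_tox, spike_eff;  // one per stage >= 2
  double omega_fix_T, omega_fix_E;         // NA_REAL when sampled
  bool spike_dynamic;                      // spike mean = current theta_{k-1}
};

static double slab_tox_ld(const PriorSpec& pr, const double* th) {
  double ld = 0;
  for (int i = 0; i < 2; ++i)
    ld += R::dnorm(th[i], pr.slab_tox_mean[i], pr.slab_tox_sd[i], 1);
  return ld;
}

static double slab_eff_ld(const PriorSpec& pr, const double* th) {
  // th = (g0, g1, g2, g3, tau)
  double ld = 0;
  for (int i = 0; i < 4; ++i)
    ld += R::dnorm(th[i], pr.slab_eff_mean[i], pr.slab_eff_sd[i], 1);
  ld += R::dnorm(th[4], pr.tau_loc, pr.tau_sd, 1) - pr.tau_log_trunc;
  return ld;
}

// Mixture (or slab-only for stage 1) log prior for one stage's block pair.
// prev: the previous stage's block (conditioning values for the
// autoregressive spike), or NULL for stage 1.
static double stage_block_ld(const PriorSpec& pr, int k /*0-based*/,
                             const double* th, const double* prev,
                             double wT, double wE) {
  const double* tox = th;         // b0, b1
  double eff[5] = {th[2], th[3], th[4], th[5], th[6]};  // g0..g3, tau
  if (th[6] < pr.tau_lo || th[6] > pr.tau_hi) return R_NegInf;
  double ldT, ldE;
  if (k == 0) {
    ldT = slab_tox_ld(pr, tox);
    ldE = slab_eff_ld(pr, eff);
  } else {
    const MvnBlock& st = pr.spike_tox[k - 1];
    const MvnBlock& se = pr.spike_eff[k - 1];
    double sT, sE;
    if (pr.spike_dynamic) {
      double prev_eff[5] = {prev[2], prev[3], prev[4], prev[5], prev[6]};
      sT = st.ld_at(tox, prev, pr.tau_lo, pr.tau_hi);
      sE = se.ld_at(eff, prev_eff, pr.tau_lo, pr.tau_hi);
    } else {
      sT = st.ld(tox);
      sE = se.ld(eff);
    }
    double bT = slab_tox_ld(pr, tox);
    double bE = slab_eff_ld(pr, eff);
    if (wT >= 1.0 - 1e-12)      ldT = sT;
    else if (wT <= 1e-12)       ldT = bT;
    else ldT = log_sum_exp(std::log(wT) + sT, std::log1p(-wT) + bT);
    if (wE >= 1.0 - 1e-12)      ldE = sE;
    else if (wE <= 1e-12)       ldE = bE;
    else ldE = log_sum_exp(std::log(wE) + sE, std::log1p(-wE) + bE);
  }
  return ldT + ldE;
}

// Full log prior over the sampled state (theta blocks, log sigma, logit omegas).
static double log_prior(const PriorSpec& pr, int K, const double* state) {
  double wT = 0.5, wE = 0.5, lp = 0.0;
  if (K >= 2) {
    double zT = NumericVector::is_na(pr.omega_fix_T) ? state[7 * K + 1] : R_PosInf;
    double zE = NumericVector::is_na(pr.omega_fix_E) ? state[7 * K + 2] : R_PosInf;
    wT = NumericVector::is_na(pr.omega_fix_T) ? inv_logit(zT) : pr.omega_fix_T;
    wE = NumericVector::is_na(pr.omega_fix_E) ? inv_logit(zE) : pr.omega_fix_E;
    if (NumericVector::is_na(pr.omega_fix_T))
      lp += R::dbeta(wT, pr.wa, pr.wb, 1) + std::log(wT) + std::log1p(-wT);
    if (NumericVector::is_na(pr.omega_fix_E))
      lp += R::dbeta(wE, pr.wa, pr.wb, 1) + std::log(wE) + std::log1p(-wE);
  }
  for (int k = 0; k < K; ++k) {
    double ld = stage_block_ld(pr, k, state + 7 * k,
                               k ? state + 7 * (k - 1) : (const double*)0,
                               wT, wE);
    if (ld == R_NegInf) return R_NegInf;
    lp += ld;
  }
  // frailty scale prior, sampled as log sigma.  Either
  // sigma ~ Half-Cauchy(0, phi) (Jacobian sigma) or
  // sigma^2 ~ Half-Cauchy(0, phi) (Jacobian 2 sigma^2)
  double lsig = state[7 * K];
  if (pr.frailty_on_var) {
    double v = std::exp(2.0 * lsig);
    lp += std::log(2.0 / M_PI) - std::log(pr.phi) -
          std::log1p((v / pr.phi) * (v / pr.phi)) +
          std::log(2.0) + 2.0 * lsig;
  } else {
    double sig = std::exp(lsig);
    lp += std::log(2.0 / M_PI) - std::log(pr.phi) -
          std::log1p((sig / pr.phi) * (sig / pr.phi)) + lsig;
  }
  return lp;
}

static MvnBlock make_block(const arma::vec& m, const arma::mat& S,
                           double log_trunc) {
  MvnBlock b;
  b.mean = m;
  b.prec = arma::inv_sympd(S);
  double sign;
  arma::log_det(b.logdet, sign, S);
  b.log_trunc = log_trunc;
  b.tau_sd = m.n_elem == 5 ? std::sqrt(S(4, 4)) : 0.0;
  b.dim = m.n_elem;
  return b;
}

// Adaptive component-wise random-walk Metropolis for the stage-wise model.
// counts: K*J*4 outcome-cell counts; init: n_chains x P start values on the
// sampling scale.  Proposal SDs adapt toward 44% acceptance during warmup
// (Robbins-Monro) and are frozen afterwards.
// [[Rcpp::export]]
List cpp_mh_sample(IntegerVector counts, int K, NumericVector x,
                   List prior, NumericMatrix init,
                   int n_chains, int n_warmup, int n_keep,
                   NumericVector gh_z, NumericVector gh_w) {
  const int J = x.size();
  const int P = 7 * K + 1 + (K >= 2 ? 2 : 0);
  if (init.ncol() != P || init.nrow() != n_chains)
    stop("init must be n_chains x P");
  arma::vec ghz(gh_z.begin(), gh_z.size()), ghw(gh_w.begin(), gh_w.size());

  PriorSpec pr;
  pr.slab_tox_mean = as<arma::vec>(prior["slab_tox_mean"]);
  pr.slab_tox_sd   = as<arma::vec>(prior["slab_tox_sd"]);
  pr.slab_eff_mean = as<arma::vec>(prior["slab_eff_mean"]);
  pr.slab_eff_sd   = as<arma::vec>(prior["slab_eff_sd"]);
  pr.tau_loc = as<double>(prior["tau_loc"]);
  pr.tau_sd  = as<double>(prior["tau_sd"]);
  pr.tau_lo  = as<double>(prior["tau_lo"]);
  pr.tau_hi  = as<double>(prior["tau_hi"]);
  pr.tau_log_trunc = std::log(
      R::pnorm(pr.tau_hi, pr.tau_loc, pr.tau_sd, 1, 0) -
      R::pnorm(pr.tau_lo, pr.tau_loc, pr.tau_sd, 1, 0));
  pr.phi = as<double>(prior["phi"]);
  pr.frailty_on_var = as<bool>(prior["frailty_on_var"]);
  pr.wa  = as<double>(prior["weight_a"]);
  pr.wb  = as<double>(prior["weight_b"]);
  pr.omega_fix_T = as<double>(prior["omega_fix_T"]);
  pr.omega_fix_E = as<double>(prior["omega_fix_E"]);
  pr.spike_dynamic = as<bool>(prior["spike_dynamic"]);
  if (K >= 2) {
    List spikes = prior["spikes"];
    if ((int)spikes.size() != K - 1) stop("need K-1 spike blocks");
    for (int s = 0; s < K - 1; ++s) {
      List sp = spikes[s];
      arma::vec tm = as<arma::vec>(sp["tox_mean"]);
      arma::mat tc = as<arma::mat>(sp["tox_cov"]);
      arma::vec em = as<arma::vec>(sp["eff_mean"]);
      arma::mat ec = as<arma::mat>(sp["eff_cov"]);
      double s5 = std::sqrt(ec(4, 4));
      double lt = std::log(
          std::max(R::pnorm(pr.tau_hi, em[4], s5, 1, 0) -
                   R::pnorm(pr.tau_lo, em[4], s5, 1, 0), 1e-12));
      pr.spike_tox.push_back(make_block(tm, tc, 0.0));
      pr.spike_eff.push_back(make_block(em, ec, lt));
    }
  }

  std::vector<bool> update(P, true);
  if (K >= 2) {
    if (!NumericVector::is_na(pr.omega_fix_T)) update[7 * K + 1] = false;
    if (!NumericVector::is_na(pr.omega_fix_E)) update[7 * K + 2] = false;
  }

  const int P_out = P;  // natural-scale output has the same layout
  NumericMatrix draws(n_chains * n_keep, P_out);
  IntegerVector chain_id(n_chains * n_keep);
  NumericMatrix acc_rate(n_chains, P);

  RNGScope scope;
  const int n_iter = n_warmup + n_keep;
  std::vector<double> cur(P), lsd(P), ll(K), prop_ll(K);
  const int* cnt = INTEGER(counts);
  const double* xp = REAL(x);

  for (int ch = 0; ch < n_chains; ++ch) {
    for (int i = 0; i < P; ++i) { cur[i] = init(ch, i); lsd[i] = std::log(0.3); }
    double sig = std::exp(cur[7 * K]);
    for (int k = 0; k < K; ++k)
      ll[k] = stage_loglik(cnt + k * J * 4, J, xp, &cur[7 * k], sig, ghz, ghw);
    double lp = log_prior(pr, K, cur.data());
    if (lp == R_NegInf) stop("initial state has zero prior density");
    std::vector<long> acc(P, 0), tries(P, 0);

    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < P; ++i) {
        if (!update[i]) continue;
        ++tries[i];
        double old = cur[i];
        cur[i] = old + std::exp(lsd[i]) * norm_rand();
        double lp_new = log_prior(pr, K, cur.data());
        bool ok = false;
        if (lp_new != R_NegInf) {
          double dll = 0.0;
          if (i < 7 * K) {
            int k = i / 7;
            prop_ll[k] = stage_loglik(cnt + k * J * 4, J, xp, &cur[7 * k],
                                      sig, ghz, ghw);
            dll = prop_ll[k] - ll[k];
          } else if (i == 7 * K) {
            double sig_new = std::exp(cur[i]);
            for (int k = 0; k < K; ++k) {
              prop_ll[k] = stage_loglik(cnt + k * J * 4, J, xp, &cur[7 * k],
                                        sig_new, ghz, ghw);
              dll += prop_ll[k] - ll[k];
            }
          }
          double lr = (lp_new - lp) + dll;
          if (lr >= 0 || std::log(unif_rand()) < lr) {
            ok = true;
            lp = lp_new;
            if (i < 7 * K) { int k = i / 7; ll[k] = prop_ll[k]; }
            else if (i == 7 * K) {
              for (int k = 0; k < K; ++k) ll[k] = prop_ll[k];
              sig = std::exp(cur[i]);
            }
          }
        }
        if (!ok) cur[i] = old; else ++acc[i];
        if (it < n_warmup) {
          double step = 1.0 / std::sqrt(1.0 + it);
          lsd[i] += step * ((ok ? 1.0 : 0.0) - 0.44);
          if (lsd[i] < -8) lsd[i] = -8;
          if (lsd[i] > 4) lsd[i] = 4;
        }
      }
      if (it >= n_warmup) {
        int row = ch * n_keep + (it - n_warmup);
        for (int k = 0; k < K; ++k)
          for (int i = 0; i < 7; ++i)
            draws(row, 7 * k + i) = cur[7 * k + i];
        draws(row, 7 * K) = std::exp(cur[7 * K]);  // sigma_eps
        if (K >= 2) {
          draws(row, 7 * K + 1) = NumericVector::is_na(pr.omega_fix_T)
            ? inv_logit(cur[7 * K + 1]) : pr.omega_fix_T;
          draws(row, 7 * K + 2) = NumericVector::is_na(pr.omega_fix_E)
            ? inv_logit(cur[7 * K + 2]) : pr.omega_fix_E;
        }
        chain_id[row] = ch + 1;
      }
      if (it % 256 == 0) Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i < P; ++i)
      acc_rate(ch, i) = tries[i] ? (double)acc[i] / tries[i] : NA_REAL;
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept"] = acc_rate);
}

// Per-draw, per-dose unconditional marginals and mean utility for one
// stage block.  theta: n x 7 (b0,b1,g0,g1,g2,g3,tau); sigma: n frailty SDs.
// util: (u10, u00, u11, u01).
// [[Rcpp::export]]
List cpp_dose_summaries(NumericMatrix theta, NumericVector sigma,
                        NumericVector x, NumericVector util,
                        NumericVector gh_z, NumericVector gh_w) {
  const int n = theta.nrow(), J = x.size(), Q = gh_z.size();
  NumericMatrix piT(n, J), piE(n, J), mu(n, J);
  const double u10 = util[0], u00 = util[1], u11 = util[2], u01 = util[3];
  for (int r = 0; r < n; ++r) {
    const double b0 = theta(r, 0), eb1 = std::exp(theta(r, 1));
    const double g0 = theta(r, 2), eg1 = std::exp(theta(r, 3));
    const double g2 = theta(r, 4), g3 = theta(r, 5), tau = theta(r, 6);
    const double s2s = M_SQRT2 * sigma[r];
    for (int j = 0; j < J; ++j) {
      double xj = x[j];
      double lpT0 = b0 + eb1 * xj;
      double hinge = xj > tau ? (xj - tau) : 0.0;
      double lpE0 = g0 + eg1 * xj + g2 * hinge + g3 * xj * xj;
      double mT = 0, mE = 0, p11 = 0;
      for (int q = 0; q < Q; ++q) {
        double e = s2s * gh_z[q];
        double pT = inv_logit(lpT0 + e);
        double pE = inv_logit(lpE0 + e);
        mT += gh_w[q] * pT;
        mE += gh_w[q] * pE;
        p11 += gh_w[q] * pT * pE;
      }
      double p10 = mT - p11, p01 = mE - p11, p00 = 1 - mT - mE + p11;
      piT(r, j) = mT;
      piE(r, j) = mE;
      mu(r, j) = u10 * p10 + u00 * p00 + u11 * p11 + u01 * p01;
    }
  }
  return List::create(_["piT"] = piT, _["piE"] = piE, _["utility"] = mu);
}
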