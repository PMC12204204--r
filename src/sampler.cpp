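#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs samplers for the EXNEX model family and the
// multi-level mixture (product-space) model, plus deterministic grid
// integrals used by the quadrature oracle.  All random numbers come from
// R's RNG stream so set.seed() gives bit-identical draws.

static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// binomial log-likelihood without the binomial coefficient
static inline double bin_ll(double y, double n, double p) {
  if (p <= 0.0) return (y == 0.0) ? 0.0 : R_NegInf;
  if (p >= 1.0) return (y == n) ? 0.0 : R_NegInf;
  return y * std::log(p) + (n - y) * std::log1p(-p);
}

static inline double dnorm_log(double x, double m, double sd) {
  double z = (x - m) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727; // log sqrt(2*pi)
}

// log target for log(sigma) random walk: half-normal(scale) prior on sigma,
// normal likelihood of the theta vector, plus the log-Jacobian of s = log(sigma)
static double sigma_logpost(double sigma, double scale, double mu,
                            const std::vector<double>& th) {
  double lp = -0.5 * (sigma * sigma) / (scale * scale) + std::log(sigma);
  for (size_t k = 0; k < th.size(); ++k) lp += dnorm_log(th[k], mu, sigma);
  return lp;
}

struct RwAdapt {
  double sd;
  int acc, tries;
  RwAdapt(double s) : sd(s), acc(0), tries(0) {}
  void maybe_adapt(bool adapting) {
    if (!adapting || tries < 50) return;
    double rate = (double)acc / (double)tries;
    if (rate < 0.20) sd *= 0.80;
    else if (rate > 0.45) sd *= 1.25;
    acc = 0; tries = 0;
  }
};

// Random-walk Metropolis step for a logit-scale parameter with normal prior
// (m, sd) and, when active, the binomial likelihood.  Returns new value.
static inline double rw_theta(double th, double y, double n, double m,
                              double sd, bool lik, RwAdapt& rw) {
  double prop = th + rw.sd * norm_rand();
  double la = dnorm_log(prop, m, sd) - dnorm_log(th, m, sd);
  if (lik) la += bin_ll(y, n, expit(prop)) - bin_ll(y, n, expit(th));
  rw.tries++;
  if (std::log(unif_rand()) < la) { rw.acc++; return prop; }
  return th;
}

// Generic EXNEX-family sampler.  NEX component per basket is either a
// logit-normal prior (nex_type 0: mean nex_m, variance nex_nu) or a Beta
// prior (nex_type 1: shapes nex_a, nex_b) updated by exact conjugate draws.
// [[Rcpp::export]]
List exnex_mcmc(NumericVector y, NumericVector n, NumericVector pi,
                IntegerVector nex_type, NumericVector nex_m,
                NumericVector nex_nu, NumericVector nex_a, NumericVector nex_b,
                double m_mu, double nu_mu, double sigma_scale,
                int n_iter, int n_burn, int thin, double prop_sd, bool adapt) {
  int K = y.size();
  std::vector<double> th1(K), th2(K), pb2(K);
  std::vector<int> del(K);
  std::vector<RwAdapt> rw1, rw2;
  for (int k = 0; k < K; ++k) {
    double el = std::log((y[k] + 0.5) / (n[k] - y[k] + 0.5));
    th1[k] = el; th2[k] = el; del[k] = 1;
    if (nex_type[k] == 1)
      pb2[k] = (nex_a[k] + y[k]) / (nex_a[k] + nex_b[k] + n[k]);
    else
      pb2[k] = expit(el);
    rw1.push_back(RwAdapt(prop_sd));
    rw2.push_back(RwAdapt(prop_sd));
    if (!R_finite(bin_ll(y[k], n[k], expit(th1[k]))))
      stop("non-finite log-likelihood at initialization for basket %d", k + 1);
  }
  double mu = m_mu, sigma = 0.5;
  double sd_mu_pr = std::sqrt(nu_mu);
  RwAdapt rws(prop_sd);

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix P(n_keep, K), TH1(n_keep, K);
  IntegerMatrix D(n_keep, K);
  NumericVector MU(n_keep), SIG(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = adapt && it < n_burn;
    for (int k = 0; k < K; ++k) {
      double M1 = expit(th1[k]);
      double M2 = (nex_type[k] == 1) ? pb2[k] : expit(th2[k]);
      // (i) delta full conditional
      if (pi[k] <= 0.0) del[k] = 0;
      else if (pi[k] >= 1.0) del[k] = 1;
      else {
        double lo = std::log(pi[k]) - std::log1p(-pi[k]) +
          bin_ll(y[k], n[k], M1) - bin_ll(y[k], n[k], M2);
        del[k] = (unif_rand() < expit(lo)) ? 1 : 0;
      }
      // (ii) EX component: RW-MH when selected, prior refresh otherwise
      if (del[k] == 1) {
        th1[k] = rw_theta(th1[k], y[k], n[k], mu, sigma, true, rw1[k]);
        rw1[k].maybe_adapt(adapting);
      } else {
        th1[k] = mu + sigma * norm_rand();
      }
      // (iii) NEX component
      if (nex_type[k] == 1) {
        int s = 1 - del[k]; // component selected when delta = 0
        pb2[k] = R::rbeta(nex_a[k] + s * y[k], nex_b[k] + s * (n[k] - y[k]));
      } else {
        double psd = std::sqrt(nex_nu[k]);
        if (del[k] == 0) {
          th2[k] = rw_theta(th2[k], y[k], n[k], nex_m[k], psd, true, rw2[k]);
          rw2[k].maybe_adapt(adapting);
        } else {
          th2[k] = nex_m[k] + psd * norm_rand();
        }
      }
    }
    // (iv) mu conjugate normal given all theta_1k
    double s2 = sigma * sigma;
    double prec = 1.0 / nu_mu + K / s2, sum = 0.0;
    for (int k = 0; k < K; ++k) sum += th1[k];
    mu = (m_mu / nu_mu + sum / s2) / prec + std::sqrt(1.0 / prec) * norm_rand();
    (void)sd_mu_pr;
    // (v) sigma by RW on log sigma
    {
      double prop = sigma * std::exp(rws.sd * norm_rand());
      double la = sigma_logpost(prop, sigma_scale, mu, th1) -
        sigma_logpost(sigma, sigma_scale, mu, th1);
      rws.tries++;
      if (std::log(unif_rand()) < la) { sigma = prop; rws.acc++; }
      rws.maybe_adapt(adapting);
    }
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int k = 0; k < K; ++k) {
        double M2 = (nex_type[k] == 1) ? pb2[k] : expit(th2[k]);
        P(kept, k) = del[k] ? expit(th1[k]) : M2;
        D(kept, k) = del[k];
        TH1(kept, k) = th1[k];
      }
      MU[kept] = mu; SIG[kept] = sigma;
      kept++;
    }
  }
  NumericVector acc1(K);
  for (int k = 0; k < K; ++k)
    acc1[k] = rw1[k].tries > 0 ? (double)rw1[k].acc / rw1[k].tries : NA_REAL;
  return List::create(_["p"] = P, _["delta"] = D, _["theta_ex"] = TH1,
                      _["mu"] = MU, _["sigma"] = SIG, _["accept_ex"] = acc1);
}

// State of one EXNEX sub-model of the multi-level mixture, over all units
// (current baskets followed by historical baskets).
struct SubModel {
  std::vector<double> th1, pb2;
  std::vector<int> del;
  double mu, sigma;
  std::vector<RwAdapt> rw;
  RwAdapt rws;
  SubModel(int I, double prop_sd) : th1(I), pb2(I), del(I, 1), mu(0), sigma(0.5),
    rws(prop_sd) {
    for (int i = 0; i < I; ++i) rw.push_back(RwAdapt(prop_sd));
  }
};

// Multi-level mixture sampler over the two EXNEX sub-models.  Units
// i = 1..I are the K current baskets followed by the historical baskets;
// psi flags historical units, owner maps every unit to its current basket
// (1-based).  NEX components are Beta on the probability scale: sub-model
// "all" uses shapes (a2_all, b2_all) (informative for current units with
// history), sub-model "curr" uses the flat (a0, b0).
//
// With distinct = true (the default coupling) both sub-models are fitted
// with the full likelihood on every sweep and lambda_k only selects which
// sub-model's basket-k draw is recorded, with per-sweep odds
// pi_lambda * Bin(y_k | p_all_k) vs (1 - pi_lambda) * Bin(y_k | p_curr_k).
// With distinct = false the sampler runs a Carlin-Chib product space: a
// current basket's likelihood feeds only the sub-model its lambda selects
// and the other sub-model's parameters refresh from their priors.
// [[Rcpp::export]]
List mlmix_mcmc(NumericVector y, NumericVector n, IntegerVector psi,
                IntegerVector owner, int K,
                NumericVector pi_all, NumericVector pi_curr,
                NumericVector a2_all, NumericVector b2_all,
                NumericVector a0, NumericVector b0,
                NumericVector pi_lambda,
                double m_mu, double nu_mu,
                double sigma_scale_all, double sigma_scale_curr,
                int n_iter, int n_burn, int thin, double prop_sd, bool adapt,
                bool distinct) {
  int I = y.size();
  SubModel A(I, prop_sd), C(I, prop_sd);
  std::vector<int> lam(K, 1);
  for (int i = 0; i < I; ++i) {
    double el = std::log((y[i] + 0.5) / (n[i] - y[i] + 0.5));
    A.th1[i] = C.th1[i] = el;
    A.pb2[i] = (a2_all[i] + y[i]) / (a2_all[i] + b2_all[i] + n[i]);
    C.pb2[i] = (a0[i] + y[i]) / (a0[i] + b0[i] + n[i]);
    if (psi[i] == 1) C.del[i] = 0;
  }
  A.mu = C.mu = m_mu;

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix P(n_keep, K), PA(n_keep, K), PC(n_keep, K);
  IntegerMatrix L(n_keep, K), DA(n_keep, K), DC(n_keep, K);
  NumericVector MUA(n_keep), SIGA(n_keep), MUC(n_keep), SIGC(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = adapt && it < n_burn;
    for (int sm = 0; sm < 2; ++sm) {
      SubModel& S = sm == 0 ? A : C;
      double scale = sm == 0 ? sigma_scale_all : sigma_scale_curr;
      const NumericVector& pa = sm == 0 ? a2_all : a0;
      const NumericVector& pb = sm == 0 ? b2_all : b0;
      for (int i = 0; i < I; ++i) {
        // historical units contribute to both sub-models; a current unit's
        // likelihood feeds both when the sub-models are fitted distinctly,
        // otherwise only the sub-model its lambda selects
        bool active = distinct || psi[i] == 1 ||
          (sm == 0 ? lam[owner[i] - 1] == 1 : lam[owner[i] - 1] == 0);
        double pri = sm == 0 ? pi_all[i] : (psi[i] == 1 ? 0.0 : pi_curr[i]);
        double M1 = expit(S.th1[i]), M2 = S.pb2[i];
        if (pri <= 0.0) S.del[i] = 0;
        else if (pri >= 1.0) S.del[i] = 1;
        else if (active) {
          double lo = std::log(pri) - std::log1p(-pri) +
            bin_ll(y[i], n[i], M1) - bin_ll(y[i], n[i], M2);
          S.del[i] = (unif_rand() < expit(lo)) ? 1 : 0;
        } else {
          S.del[i] = (unif_rand() < pri) ? 1 : 0;
        }
        if (S.del[i] == 1 && active) {
          S.th1[i] = rw_theta(S.th1[i], y[i], n[i], S.mu, S.sigma, true, S.rw[i]);
          S.rw[i].maybe_adapt(adapting);
        } else {
          S.th1[i] = S.mu + S.sigma * norm_rand();
        }
        int sel = (S.del[i] == 0 && active) ? 1 : 0;
        S.pb2[i] = R::rbeta(pa[i] + sel * y[i], pb[i] + sel * (n[i] - y[i]));
      }
      double s2 = S.sigma * S.sigma;
      double prec = 1.0 / nu_mu + I / s2, sum = 0.0;
      for (int i = 0; i < I; ++i) sum += S.th1[i];
      S.mu = (m_mu / nu_mu + sum / s2) / prec +
        std::sqrt(1.0 / prec) * norm_rand();
      double prop = S.sigma * std::exp(S.rws.sd * norm_rand());
      double la = sigma_logpost(prop, scale, S.mu, S.th1) -
        sigma_logpost(S.sigma, scale, S.mu, S.th1);
      S.rws.tries++;
      if (std::log(unif_rand()) < la) { S.sigma = prop; S.rws.acc++; }
      S.rws.maybe_adapt(adapting);
    }
    // lambda_k full conditional from the two sub-model response rates
    for (int k = 0; k < K; ++k) {
      double p_all = A.del[k] ? expit(A.th1[k]) : A.pb2[k];
      double p_curr = C.del[k] ? expit(C.th1[k]) : C.pb2[k];
      if (pi_lambda[k] <= 0.0) lam[k] = 0;
      else if (pi_lambda[k] >= 1.0) lam[k] = 1;
      else {
        double lo = std::log(pi_lambda[k]) - std::log1p(-pi_lambda[k]) +
          bin_ll(y[k], n[k], p_all) - bin_ll(y[k], n[k], p_curr);
        lam[k] = (unif_rand() < expit(lo)) ? 1 : 0;
      }
    }
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int k = 0; k < K; ++k) {
        double p_all = A.del[k] ? expit(A.th1[k]) : A.pb2[k];
        double p_curr = C.del[k] ? expit(C.th1[k]) : C.pb2[k];
        P(kept, k) = lam[k] ? p_all : p_curr;
        PA(kept, k) = p_all; PC(kept, k) = p_curr;
        L(kept, k) = lam[k]; DA(kept, k) = A.del[k]; DC(kept, k) = C.del[k];
      }
      MUA[kept] = A.mu; SIGA[kept] = A.sigma;
      MUC[kept] = C.mu; SIGC[kept] = C.sigma;
      kept++;
    }
  }
  return List::create(_["p"] = P, _["p_all"] = PA, _["p_curr"] = PC,
                      _["lambda"] = L, _["delta_all"] = DA,
                      _["delta_curr"] = DC, _["mu_all"] = MUA,
                      _["sigma_all"] = SIGA, _["mu_curr"] = MUC,
                      _["sigma_curr"] = SIGC);
}

// splitmix64-style hash used to derive independent replicate seeds from
// (stream, index); returned value lies in [1, 2^30].
// [[Rcpp::export]]
double seed_mix(double stream, double index) {
  uint64_t z = (uint64_t)(int64_t)stream * 0x9E3779B97F4A7C15ULL +
    (uint64_t)(int64_t)index;
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return (double)(z & 0x3FFFFFFFULL) + 1.0;
}

// Grid integrals for the quadrature oracle.  For every (mu, sigma) node and
// basket k, computes by trapezoidal quadrature in z (theta = mu + sigma z,
// with a node inserted exactly at the q0 cut):
//   ell[k]  = Int Bin(y_k | n_k, expit(theta)) N(theta; mu, sigma^2) dtheta
//   tau[k]  = the same integral restricted to theta > logit(q0)
// Binomial coefficients are included so values are absolute likelihoods.
// [[Rcpp::export]]
List ex_grid_integrals(NumericVector y, NumericVector n,
                       NumericVector mu_grid, NumericVector sigma_grid,
                       double q0, int n_z) {
  int K = y.size(), M = mu_grid.size(), S = sigma_grid.size();
  double t0 = std::log(q0 / (1.0 - q0));
  double zlo = -8.0, zhi = 8.0;
  std::vector<double> lchoose_k(K);
  for (int k = 0; k < K; ++k) lchoose_k[k] = R::lchoose(n[k], y[k]);
  // output: K matrices M x S for ell and tau
  List ell(K), tau(K);
  std::vector<NumericMatrix> E, T;
  for (int k = 0; k < K; ++k) {
    E.push_back(NumericMatrix(M, S));
    T.push_back(NumericMatrix(M, S));
  }
  std::vector<double> zg(n_z);
  double h = (zhi - zlo) / (n_z - 1);
  for (int j = 0; j < n_z; ++j) zg[j] = zlo + j * h;
  const double c = 0.3989422804014327; // 1/sqrt(2*pi)
  for (int s = 0; s < S; ++s) {
    double sig = sigma_grid[s];
    for (int m = 0; m < M; ++m) {
      double mu = mu_grid[m];
      double z0 = (t0 - mu) / sig; // cut in z units
      for (int k = 0; k < K; ++k) {
        double lc = lchoose_k[k];
        double acc_full = 0.0, acc_tail = 0.0;
        double prev_z = zg[0];
        double prev_f = c * std::exp(-0.5 * prev_z * prev_z + lc +
          bin_ll(y[k], n[k], expit(mu + sig * prev_z)));
        for (int j = 1; j < n_z; ++j) {
          double zj = zg[j];
          double fj = c * std::exp(-0.5 * zj * zj + lc +
            bin_ll(y[k], n[k], expit(mu + sig * zj)));
          if (z0 > prev_z && z0 < zj) {
            // split the cell at the cut so the tail indicator is exact
            double f0 = c * std::exp(-0.5 * z0 * z0 + lc +
              bin_ll(y[k], n[k], expit(t0)));
            double a1 = 0.5 * (prev_f + f0) * (z0 - prev_z);
            double a2 = 0.5 * (f0 + fj) * (zj - z0);
            acc_full += a1 + a2;
            acc_tail += a2;
          } else {
            double a = 0.5 * (prev_f + fj) * (zj - prev_z);
            acc_full += a;
            if (prev_z >= z0) acc_tail += a;
          }
          prev_z = zj; prev_f = fj;
        }
        if (z0 <= zlo) acc_tail = acc_full;
        if (z0 >= zhi) acc_tail = 0.0;
        E[k](m, s) = acc_full;
        T[k](m, s) = acc_tail;
      }
    }
  }
  for (int k = 0; k < K; ++k) { ell[k] = E[k]; tau[k] = T[k]; }
  return List::create(_["ell"] = ell, _["tau"] = tau);
}
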