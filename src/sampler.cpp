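// Metropolis-within-Gibbs sampler for joint response / response-time
// cognitive diagnostic models with an optional rapid-guessing mixture.
//
// The response model enters only through a C x J mastery matrix
// (C = 2^K latent classes), so DINA and DINO share one sampler.
// All conditional draws use R's RNG (seeded from the R side).

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Beta draw truncated to (lo, hi) by inverse CDF, with degenerate-range
// fallbacks (constraints can be numerically saturated at large counts).
static double rbeta_trunc(double a, double b, double lo, double hi) {
  double plo = (lo <= 0.0) ? 0.0 : R::pbeta(lo, a, b, 1, 0);
  double phi = (hi >= 1.0) ? 1.0 : R::pbeta(hi, a, b, 1, 0);
  if (phi - plo < 1e-12) return 0.5 * (lo + hi);
  double u = R::runif(plo, phi);
  double x = R::qbeta(u, a, b, 1, 0);
  if (x <= lo) x = lo + 1e-12;
  if (x >= hi) x = hi - 1e-12;
  return x;
}

// Normal draw truncated to (lo, hi) by inverse CDF.
static double rnorm_trunc(double mean, double sd, double lo, double hi) {
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  if (phi - plo < 1e-14) {
    double mid = std::max(lo, std::min(hi, mean));
    return mid;
  }
  double u = R::runif(plo, phi);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

static inline double logsumexp2(double a, double b) {
  double m = std::max(a, b);
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Per-class mastered-item index lists; classes mastering more than half
// the items store the complement instead (sum = total - complement sum).
struct MasteryIndex {
  std::vector<std::vector<int>> idx;
  std::vector<bool> complement;
  explicit MasteryIndex(const IntegerMatrix& M) {
    const int C = M.nrow(), J = M.ncol();
    idx.resize(C);
    complement.resize(C);
    for (int c = 0; c < C; ++c) {
      int n1 = 0;
      for (int j = 0; j < J; ++j) n1 += M(c, j);
      complement[c] = n1 > J / 2;
      for (int j = 0; j < J; ++j) {
        if (complement[c] ? M(c, j) == 0 : M(c, j) == 1) idx[c].push_back(j);
      }
    }
  }
  // sum over mastered items of w[j]
  inline double mastered_sum(int c, const double* w, double wtot) const {
    double acc = 0.0;
    for (int j : idx[c]) acc += w[j];
    return complement[c] ? wtot - acc : acc;
  }
};

// Marginal log-likelihood based deviance: -2 * sum_i log p(Y_i, RT_i),
// with attribute class and (if rg) the behaviour indicator summed out,
// conditional on item parameters, person speeds and class probabilities.
// Densities are on the observed response-time scale.
static double deviance_marginal_impl(
    const IntegerMatrix& Y, const NumericMatrix& logRT,
    const IntegerMatrix& M, const MasteryIndex& MX,
    const NumericVector& loglam,
    const NumericVector& g, const NumericVector& s,
    const NumericVector& beta, const NumericVector& kappa2,
    const NumericVector& tau, bool rg, const NumericVector& pi,
    double beta0, double kappa02) {
  const int I = Y.nrow(), J = Y.ncol(), C = M.nrow();
  std::vector<double> dlt(J), ll(C);
  std::vector<double> lp1(J), lp0(J), lc1(J), lc0(J),
      lym1(J), lym0(J), lyn1(J), lyn0(J);
  const double lnorm = -0.5 * std::log(2.0 * M_PI);
  double lc0_ = 0.5 * std::log(kappa02) + lnorm;
  for (int j = 0; j < J; ++j) {
    if (rg) { lp1[j] = std::log(pi[j]); lp0[j] = std::log1p(-pi[j]); }
    lc1[j] = 0.5 * std::log(kappa2[j]) + lnorm;
    lym1[j] = std::log1p(-s[j]);
    lym0[j] = std::log(s[j]);
    lyn1[j] = std::log(g[j]);
    lyn0[j] = std::log1p(-g[j]);
  }
  double dev = 0.0;
  for (int i = 0; i < I; ++i) {
    double base = 0.0;
    for (int j = 0; j < J; ++j) {
      double ly_m = Y(i, j) ? lym1[j] : lym0[j];
      double ly_n = Y(i, j) ? lyn1[j] : lyn0[j];
      double lrt = logRT(i, j);
      double z1 = lrt - (beta[j] - tau[i]);
      double lf1 = lc1[j] - 0.5 * kappa2[j] * z1 * z1 - lrt;
      double lm1, lm0;
      if (rg) {
        double z0 = lrt - beta0;
        double lf0 = lc0_ - 0.5 * kappa02 * z0 * z0 - lrt;
        lm1 = logsumexp2(lp1[j] + lf1 + ly_m, lp0[j] + lf0 + ly_n);
        lm0 = logsumexp2(lp1[j] + lf1 + ly_n, lp0[j] + lf0 + ly_n);
      } else {
        lm1 = lf1 + ly_m;
        lm0 = lf1 + ly_n;
      }
      dlt[j] = lm1 - lm0;
      base += lm0;
    }
    double wtot = 0.0;
    for (int j = 0; j < J; ++j) wtot += dlt[j];
    double best = NEG_INF;
    for (int c = 0; c < C; ++c) {
      double v = loglam[c] + MX.mastered_sum(c, dlt.data(), wtot);
      ll[c] = v;
      if (v > best) best = v;
    }
    double acc = 0.0;
    for (int c = 0; c < C; ++c) acc += std::exp(ll[c] - best);
    dev += base + best + std::log(acc);
  }
  return -2.0 * dev;
}

// [[Rcpp::export(name = ".deviance_marginal")]]
double deviance_marginal_cpp(IntegerMatrix Y, NumericMatrix logRT,
                             IntegerMatrix M, NumericVector lambda,
                             NumericVector g, NumericVector s,
                             NumericVector beta, NumericVector kappa2,
                             NumericVector tau, bool rg, NumericVector pi,
                             double beta0, double kappa02) {
  NumericVector loglam = log(lambda);
  MasteryIndex MX(M);
  return deviance_marginal_impl(Y, logRT, M, MX, loglam, g, s, beta, kappa2,
                                tau, rg, pi, beta0, kappa02);
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(IntegerMatrix Y, NumericMatrix logRT, IntegerMatrix M,
                 IntegerMatrix classbits, bool rg, List priors, List init,
                 int n_iter, int n_burnin, int thin,
                 bool constrain_beta0, bool store_deviance) {
  const int I = Y.nrow(), J = Y.ncol(), C = M.nrow(), K = classbits.ncol();

  // priors
  const double g_a = priors["g_a"], g_b = priors["g_b"];
  const double s_a = priors["s_a"], s_b = priors["s_b"];
  const double pi_a = priors["pi_a"], pi_b = priors["pi_b"];
  const double b_mean = priors["beta_mean"], b_sd = priors["beta_sd"];
  const double k_shape = priors["kappa2_shape"], k_rate = priors["kappa2_rate"];
  const double dir_conc = priors["dirichlet"];
  const double st_sd = priors["sigma_tau_sd"];  // half-normal sd on sigma_tau
  const double b_prec = 1.0 / (b_sd * b_sd);

  // state
  std::vector<int> cls = as<std::vector<int>>(init["alpha_class"]);
  NumericVector g = clone(as<NumericVector>(init["g"]));
  NumericVector s = clone(as<NumericVector>(init["s"]));
  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  NumericVector kappa2 = clone(as<NumericVector>(init["kappa2"]));
  NumericVector tau = clone(as<NumericVector>(init["tau"]));
  NumericVector pi = clone(as<NumericVector>(init["pi"]));
  NumericVector lambda = clone(as<NumericVector>(init["lambda"]));
  double beta0 = init["beta0"], kappa02 = init["kappa02"];
  double sigma_tau = init["sigma_tau"];
  IntegerMatrix xi(I, J);
  std::fill(xi.begin(), xi.end(), 1);

  const int n_kept = (n_iter - n_burnin) / thin;
  NumericMatrix d_g(n_kept, J), d_s(n_kept, J), d_beta(n_kept, J),
      d_kappa(n_kept, J), d_pi(rg ? n_kept : 0, rg ? J : 0),
      d_lambda(n_kept, C);
  NumericVector d_beta0(rg ? n_kept : 0), d_kappa0(rg ? n_kept : 0),
      d_sigma_tau(n_kept), d_dev(store_deviance ? n_kept : 0);
  NumericMatrix alpha_prob(I, K), xi_prob(I, J);
  NumericVector tau_sum(I), tau_sumsq(I);
  int mh_accept = 0, mh_total = 0, kept = 0;

  std::vector<double> w(J), ll(C), loglam(C);
  std::vector<double> lym1(J), lym0(J), lyn1(J), lyn0(J);
  const MasteryIndex MX(M);
  const double lnorm = -0.5 * std::log(2.0 * M_PI);

  for (int iter = 0; iter < n_iter; ++iter) {
    // cached response log-probabilities per item
    for (int j = 0; j < J; ++j) {
      lym1[j] = std::log1p(-s[j]);  // mastery, Y = 1
      lym0[j] = std::log(s[j]);     // mastery, Y = 0
      lyn1[j] = std::log(g[j]);     // non-mastery (or RG), Y = 1
      lyn0[j] = std::log1p(-g[j]);
    }
    for (int c = 0; c < C; ++c) loglam[c] = std::log(lambda[c]);

    // -- attribute profiles: exact draw over all 2^K classes ------------
    // log p(class c | .) = log lambda_c + sum_{j: xi=1} log p(Y_ij | c)
    //                    = const_i + sum_j M(c,j) * w_ij
    std::vector<int> class_count(C, 0);
    for (int i = 0; i < I; ++i) {
      double wtot = 0.0;
      for (int j = 0; j < J; ++j) {
        w[j] = xi(i, j)
                   ? (Y(i, j) ? (lym1[j] - lyn1[j]) : (lym0[j] - lyn0[j]))
                   : 0.0;
        wtot += w[j];
      }
      double best = NEG_INF;
      for (int c = 0; c < C; ++c) {
        double v = loglam[c] + MX.mastered_sum(c, w.data(), wtot);
        ll[c] = v;
        if (v > best) best = v;
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { ll[c] = std::exp(ll[c] - best); tot += ll[c]; }
      double u = R::runif(0.0, tot);
      int c = 0;
      double acc = ll[0];
      while (acc < u && c < C - 1) acc += ll[++c];
      cls[i] = c;
      ++class_count[c];
    }

    // -- behaviour indicators -------------------------------------------
    if (rg) {
      const double lc0 = 0.5 * std::log(kappa02) + lnorm;
      for (int j = 0; j < J; ++j) {
        double lp1 = std::log(pi[j]), lp0 = std::log1p(-pi[j]);
        double lc1 = 0.5 * std::log(kappa2[j]) + lnorm;
        for (int i = 0; i < I; ++i) {
          double lrt = logRT(i, j);
          bool m = M(cls[i], j);
          double ly1 = Y(i, j) ? (m ? lym1[j] : lyn1[j])
                               : (m ? lym0[j] : lyn0[j]);
          double ly0 = Y(i, j) ? lyn1[j] : lyn0[j];
          double z1 = lrt - (beta[j] - tau[i]);
          double z0 = lrt - beta0;
          double l1 = lp1 + ly1 + lc1 - 0.5 * kappa2[j] * z1 * z1;
          double l0 = lp0 + ly0 + lc0 - 0.5 * kappa02 * z0 * z0;
          double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
          xi(i, j) = (R::unif_rand() < p1) ? 1 : 0;
        }
      }
    }

    // -- guessing / slipping: conjugate beta with g < 1 - s -------------
    for (int j = 0; j < J; ++j) {
      int g1 = 0, g0 = 0, m1 = 0, m0 = 0;
      for (int i = 0; i < I; ++i) {
        bool solution_mastery = xi(i, j) && M(cls[i], j);
        if (solution_mastery) { Y(i, j) ? ++m1 : ++m0; }
        else                  { Y(i, j) ? ++g1 : ++g0; }
      }
      g[j] = rbeta_trunc(g_a + g1, g_b + g0, 1e-12, 1.0 - s[j]);
      double one_minus_s = rbeta_trunc(s_a + m1, s_b + m0, g[j], 1.0 - 1e-12);
      s[j] = 1.0 - one_minus_s;
    }

    // -- solution-attempt probabilities ---------------------------------
    if (rg) {
      for (int j = 0; j < J; ++j) {
        int n1 = 0;
        for (int i = 0; i < I; ++i) n1 += xi(i, j);
        pi[j] = R::rbeta(pi_a + n1, pi_b + (I - n1));
        if (pi[j] >= 1.0) pi[j] = 1.0 - 1e-12;
        if (pi[j] <= 0.0) pi[j] = 1e-12;
      }
    }

    // -- person speeds: normal-normal -----------------------------------
    double st2 = sigma_tau * sigma_tau;
    for (int i = 0; i < I; ++i) {
      double prec = 1.0 / st2, num = 0.0;
      for (int j = 0; j < J; ++j) {
        if (xi(i, j)) {
          prec += kappa2[j];
          num += kappa2[j] * (beta[j] - logRT(i, j));
        }
      }
      tau[i] = R::rnorm(num / prec, std::sqrt(1.0 / prec));
    }

    // -- item time intensities / discriminations ------------------------
    double min_beta = R_PosInf;
    for (int j = 0; j < J; ++j) {
      int n = 0;
      double sum = 0.0;
      for (int i = 0; i < I; ++i) {
        if (xi(i, j)) { ++n; sum += logRT(i, j) + tau[i]; }
      }
      double prec = b_prec + kappa2[j] * n;
      double mean = (b_mean * b_prec + kappa2[j] * sum) / prec;
      double sd = std::sqrt(1.0 / prec);
      beta[j] = (rg && constrain_beta0)
                    ? rnorm_trunc(mean, sd, beta0, R_PosInf)
                    : R::rnorm(mean, sd);
      if (beta[j] < min_beta) min_beta = beta[j];
      double ssr = 0.0;
      for (int i = 0; i < I; ++i) {
        if (xi(i, j)) {
          double z = logRT(i, j) - beta[j] + tau[i];
          ssr += z * z;
        }
      }
      kappa2[j] = R::rgamma(k_shape + 0.5 * n, 1.0 / (k_rate + 0.5 * ssr));
      if (kappa2[j] < 1e-8) kappa2[j] = 1e-8;
    }

    // -- rapid-guessing state time parameters ---------------------------
    if (rg) {
      int n0 = 0;
      double sum0 = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
          if (!xi(i, j)) { ++n0; sum0 += logRT(i, j); }
      double prec = b_prec + kappa02 * n0;
      double mean = (b_mean * b_prec + kappa02 * sum0) / prec;
      double sd = std::sqrt(1.0 / prec);
      beta0 = constrain_beta0 ? rnorm_trunc(mean, sd, R_NegInf, min_beta)
                              : R::rnorm(mean, sd);
      double ssr0 = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
          if (!xi(i, j)) {
            double z = logRT(i, j) - beta0;
            ssr0 += z * z;
          }
      kappa02 = R::rgamma(k_shape + 0.5 * n0, 1.0 / (k_rate + 0.5 * ssr0));
      if (kappa02 < 1e-8) kappa02 = 1e-8;
    }

    // -- speed scale: random-walk Metropolis on log sigma_tau -----------
    {
      double cur = std::log(sigma_tau);
      double prop = cur + R::rnorm(0.0, 0.1);
      double s_cur = sigma_tau, s_prop = std::exp(prop);
      double ll_cur = 0.0, ll_prop = 0.0;
      double ssq = 0.0;
      for (int i = 0; i < I; ++i) ssq += tau[i] * tau[i];
      ll_cur = -I * std::log(s_cur) - 0.5 * ssq / (s_cur * s_cur);
      ll_prop = -I * std::log(s_prop) - 0.5 * ssq / (s_prop * s_prop);
      // half-normal prior on sigma_tau + Jacobian of the log transform
      ll_cur += -0.5 * s_cur * s_cur / (st_sd * st_sd) + cur;
      ll_prop += -0.5 * s_prop * s_prop / (st_sd * st_sd) + prop;
      ++mh_total;
      if (std::log(R::unif_rand()) < ll_prop - ll_cur) {
        sigma_tau = s_prop;
        ++mh_accept;
      }
    }

    // -- class probabilities: Dirichlet ---------------------------------
    {
      double tot = 0.0;
      for (int c = 0; c < C; ++c) {
        lambda[c] = R::rgamma(dir_conc + class_count[c], 1.0);
        if (lambda[c] < 1e-300) lambda[c] = 1e-300;
        tot += lambda[c];
      }
      for (int c = 0; c < C; ++c) lambda[c] /= tot;
    }

    // -- bookkeeping -----------------------------------------------------
    if (iter >= n_burnin && ((iter - n_burnin) % thin == 0)) {
      for (int j = 0; j < J; ++j) {
        d_g(kept, j) = g[j];
        d_s(kept, j) = s[j];
        d_beta(kept, j) = beta[j];
        d_kappa(kept, j) = std::sqrt(kappa2[j]);
        if (rg) d_pi(kept, j) = pi[j];
      }
      for (int c = 0; c < C; ++c) d_lambda(kept, c) = lambda[c];
      if (rg) {
        d_beta0[kept] = beta0;
        d_kappa0[kept] = std::sqrt(kappa02);
      }
      d_sigma_tau[kept] = sigma_tau;
      for (int i = 0; i < I; ++i) {
        tau_sum[i] += tau[i];
        tau_sumsq[i] += tau[i] * tau[i];
        for (int k = 0; k < K; ++k) alpha_prob(i, k) += classbits(cls[i], k);
        for (int j = 0; j < J; ++j) xi_prob(i, j) += xi(i, j);
      }
      if (store_deviance) {
        for (int c = 0; c < C; ++c) loglam[c] = std::log(lambda[c]);
        NumericVector loglam_nv(loglam.begin(), loglam.end());
        d_dev[kept] = deviance_marginal_impl(Y, logRT, M, MX, loglam_nv, g,
                                             s, beta, kappa2, tau, rg, pi,
                                             beta0, kappa02);
      }
      ++kept;
    }
  }

  for (int i = 0; i < I; ++i) {
    tau_sum[i] /= n_kept;
    tau_sumsq[i] = std::sqrt(std::max(0.0, tau_sumsq[i] / n_kept -
                                               tau_sum[i] * tau_sum[i]));
    for (int k = 0; k < K; ++k) alpha_prob(i, k) /= n_kept;
    for (int j = 0; j < J; ++j) xi_prob(i, j) /= n_kept;
  }

  return List::create(
      _["g"] = d_g, _["s"] = d_s, _["beta"] = d_beta, _["kappa"] = d_kappa,
      _["pi"] = d_pi, _["beta0"] = d_beta0, _["kappa0"] = d_kappa0,
      _["sigma_tau"] = d_sigma_tau, _["lambda"] = d_lambda,
      _["deviance"] = d_dev, _["alpha_prob"] = alpha_prob,
      _["xi_prob"] = xi_prob, _["tau_mean"] = NumericVector(tau_sum),
      _["tau_sd"] = NumericVector(tau_sumsq),
      _["mh_accept_rate"] = double(mh_accept) / double(mh_total));
}
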