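#include <Rcpp.h>
using namespace Rcpp;

// Event-level log-likelihood of a feeding sequence with analytic gradient
// on the natural parameter scale. Parameter order:
// 0 lambda_F, 1 mu_F, 2 sigma_F, 3 lambda_S, 4 T1, 5 T2, 6 L1, 7 L2.
// law: 0 = sqrt emptying, 1 = linear (exponential) emptying.

static inline double log1p_exp(double a) {
  if (a > 35.0) return a;
  if (a < -35.0) return std::exp(a);
  return std::log1p(std::exp(a));
}

// cumulative IMI hazard and its partials wrt L1, L2 for the sqrt law
static void imi_hazard_sqrt(double x0, double t, double L1, double L2,
                            double k, double &Lam, double &dL1, double &dL2,
                            double &xt) {
  if (x0 <= 0.0 || L2 <= 0.0) {
    // constant-hazard limit with first-order L2 correction through x(t)
    double s0 = std::sqrt(std::max(x0, 0.0));
    double te = 2.0 * s0 / k;
    double tin = std::min(t, te);
    double u = std::max(s0 - k * tin / 2.0, 0.0);
    double X1 = 2.0 / (3.0 * k) * (s0 * s0 * s0 - u * u * u);
    xt = (t < te) ? u * u : 0.0;
    if (L2 <= 0.0) {
      Lam = t / L1 - L2 * X1 / (L1 * L1);
      dL1 = -t / (L1 * L1) + 2.0 * L2 * X1 / (L1 * L1 * L1);
      dL2 = -X1 / (L1 * L1);
      return;
    }
  }
  double s0 = std::sqrt(x0);
  double te = 2.0 * s0 / k;
  double tin = std::min(t, te);
  double tex = std::max(t - te, 0.0);
  double u = std::max(s0 - k * tin / 2.0, 0.0);
  double b = std::sqrt(L2 / L1);
  if (b * s0 < 1e-7) {
    // series branch: hazard ~ (1 - L2 x / L1)/L1
    double X1 = 2.0 / (3.0 * k) * (s0 * s0 * s0 - u * u * u);
    Lam = t / L1 - L2 * X1 / (L1 * L1);
    dL1 = -t / (L1 * L1) + 2.0 * L2 * X1 / (L1 * L1 * L1);
    dL2 = -X1 / (L1 * L1);
    xt = (t < te) ? u * u : 0.0;
    return;
  }
  // stable arctan difference: atan(b s0) - atan(b u)
  double datan = std::atan(b * (s0 - u) / (1.0 + b * b * s0 * u));
  Lam = 2.0 / (k * L1 * b) * datan + tex / L1;
  double sqLL = std::sqrt(L1 * L2);
  double Fd = s0 / (2.0 * L1 * (L1 + L2 * s0 * s0)) -
              u / (2.0 * L1 * (L1 + L2 * u * u)) +
              datan / (2.0 * L1 * sqLL);
  double I1 = 2.0 / k * Fd;
  double Gd = (datan / sqLL - L1 * Fd) / L2;
  double I2 = 2.0 / k * Gd;
  dL1 = -I1 - tex / (L1 * L1);
  dL2 = -I2;
  xt = (t < te) ? u * u : 0.0;
}

// same for the linear (exponential-decay) law
static void imi_hazard_linear(double x0, double t, double L1, double L2,
                              double k, double &Lam, double &dL1, double &dL2,
                              double &xt) {
  double em = std::exp(-k * t);
  xt = x0 * em;
  double c = L2 * x0;
  double D0 = L1 + c;
  double Dt = L1 + c * em;
  double lg = std::log1p(c * std::expm1(-k * t) / D0);
  Lam = (t + lg / k) / L1;
  dL1 = -Lam / L1 + (1.0 / Dt - 1.0 / D0) / (L1 * k);
  dL2 = (x0 * em / Dt - x0 / D0) / (L1 * k);
}

// shared accumulation core for the grouped likelihood: adds per-individual
// log-likelihood into val[j] and natural-scale gradients into g (8 x J,
// column-major)
static void accum_group_loglik(const NumericVector &bout_dur,
                               const LogicalVector &bout_cens,
                               const NumericVector &rate,
                               const IntegerVector &bout_id,
                               const NumericVector &route_x,
                               const LogicalVector &route_L,
                               const IntegerVector &route_id,
                               const NumericVector &s_dur,
                               const LogicalVector &s_cens,
                               const IntegerVector &s_id,
                               const NumericVector &imi_dur,
                               const NumericVector &imi_x0,
                               const LogicalVector &imi_cens,
                               const IntegerVector &imi_id,
                               const double *theta, int J, int law, double k,
                               double *val, double *g) {
  std::vector<double> logZ(J), mills(J);
  for (int j = 0; j < J; ++j) {
    double a = theta[8 * j + 1] / theta[8 * j + 2];
    logZ[j] = R::pnorm(a, 0.0, 1.0, 1, 1);
    mills[j] = std::exp(R::dnorm(a, 0.0, 1.0, 1) - logZ[j]);
  }
  for (int i = 0; i < bout_dur.size(); ++i) {
    int j = bout_id[i];
    const double *th = theta + 8 * j;
    double *gj = g + 8 * j;
    double lamF = th[0], muF = th[1], sigF = th[2];
    double d = bout_dur[i];
    if (bout_cens[i]) {
      val[j] += -lamF * d;
      gj[0] += -d;
    } else {
      val[j] += std::log(lamF) - lamF * d;
      gj[0] += 1.0 / lamF - d;
    }
    double z = (rate[i] - muF) / sigF;
    double alpha = muF / sigF;
    val[j] += -std::log(sigF) - 0.5 * z * z - 0.5 * std::log(2.0 * M_PI) -
              logZ[j];
    gj[1] += z / sigF - mills[j] / sigF;
    gj[2] += (-1.0 + z * z) / sigF + mills[j] * alpha / sigF;
  }
  for (int i = 0; i < route_x.size(); ++i) {
    int j = route_id[i];
    const double *th = theta + 8 * j;
    double *gj = g + 8 * j;
    double T1 = th[4], T2 = th[5];
    double a = T1 * (route_x[i] - T2);
    double p = 1.0 / (1.0 + std::exp(-a));
    if (route_L[i]) {
      val[j] += -log1p_exp(-a);
      gj[4] += (1.0 - p) * (route_x[i] - T2);
      gj[5] += -(1.0 - p) * T1;
    } else {
      val[j] += -log1p_exp(a);
      gj[4] += -p * (route_x[i] - T2);
      gj[5] += p * T1;
    }
  }
  for (int i = 0; i < s_dur.size(); ++i) {
    int j = s_id[i];
    double lamS = theta[8 * j + 3];
    double d = s_dur[i];
    if (s_cens[i]) {
      val[j] += -lamS * d;
      g[8 * j + 3] += -d;
    } else {
      val[j] += std::log(lamS) - lamS * d;
      g[8 * j + 3] += 1.0 / lamS - d;
    }
  }
  for (int i = 0; i < imi_dur.size(); ++i) {
    int j = imi_id[i];
    const double *th = theta + 8 * j;
    double *gj = g + 8 * j;
    double L1 = th[6], L2 = th[7];
    double Lam, dL1, dL2, xt;
    if (law == 0)
      imi_hazard_sqrt(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    else
      imi_hazard_linear(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    val[j] += -Lam;
    gj[6] += -dL1;
    gj[7] += -dL2;
    if (!imi_cens[i]) {
      double denom = L1 + L2 * xt;
      val[j] += -std::log(denom);
      gj[6] += -1.0 / denom;
      gj[7] += -xt / denom;
    }
  }
}

// Full hierarchical log posterior and gradient over the unconstrained
// vector q = [mu(8), log_tau(8) if has_tau, y(28), z(8J)], with the
// non-centred transform theta_tilde_j = mu + tau * (L z_j), LKJ(eta) prior
// through the canonical-partial-correlation transform, Half-Cauchy scales
// and componentwise normal prior on mu. log10 transform on components where
// log_flag is true.
// [[Rcpp::export(name = "hier_target_cpp")]]
List hier_target_cpp(NumericVector q,
                     NumericVector bout_dur, LogicalVector bout_cens,
                     NumericVector rate, IntegerVector bout_id,
                     NumericVector route_x, LogicalVector route_L,
                     IntegerVector route_id,
                     NumericVector s_dur, LogicalVector s_cens,
                     IntegerVector s_id,
                     NumericVector imi_dur, NumericVector imi_x0,
                     LogicalVector imi_cens, IntegerVector imi_id,
                     int J, int law, double k,
                     NumericVector mu_star, double mu_prior_sd,
                     double tau_scale, double lkj_eta,
                     LogicalVector log_flag,
                     bool has_tau, NumericVector fixed_tau,
                     bool prior_only) {
  const int K = 8;
  const int ny = K * (K - 1) / 2;
  const int ntau = has_tau ? K : 0;
  const double ln10 = std::log(10.0);
  const double *mu = q.begin();
  const double *lt = has_tau ? q.begin() + K : nullptr;
  const double *yv = q.begin() + K + ntau;
  const double *zv = q.begin() + K + ntau + ny;
  NumericVector grad(q.size());
  double *gmu = grad.begin();
  double *glt = has_tau ? grad.begin() + K : nullptr;
  double *gy = grad.begin() + K + ntau;
  double *gz = grad.begin() + K + ntau + ny;

  std::vector<double> tau(K);
  for (int i = 0; i < K; ++i) tau[i] = has_tau ? std::exp(lt[i]) : fixed_tau[i];

  // build L from w = tanh(y), row-major rows 2..K
  std::vector<double> w(ny), L(K * K, 0.0);  // L column-major L[i + K*jcol]
  L[0] = 1.0;
  {
    int idx = 0;
    for (int i = 1; i < K; ++i) {
      double r = 1.0;
      for (int j = 0; j < i; ++j, ++idx) {
        w[idx] = std::tanh(yv[idx]);
        L[i + K * j] = w[idx] * std::sqrt(r);
        r *= (1.0 - w[idx] * w[idx]);
      }
      L[i + K * i] = std::sqrt(r);
    }
  }
  // theta_tilde and theta
  std::vector<double> Lz(K * J), theta(K * J);
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < K; ++i) {
      double acc = 0.0;
      for (int m = 0; m <= i; ++m) acc += L[i + K * m] * zv[K * j + m];
      Lz[K * j + i] = acc;
      double tt = mu[i] + tau[i] * acc;
      theta[K * j + i] = log_flag[i] ? std::pow(10.0, tt) : tt;
    }
  }
  std::vector<double> val(J, 0.0), gth(K * J, 0.0);
  double ll = 0.0;
  if (!prior_only) {
    accum_group_loglik(bout_dur, bout_cens, rate, bout_id, route_x, route_L,
                       route_id, s_dur, s_cens, s_id, imi_dur, imi_x0,
                       imi_cens, imi_id, theta.data(), J, law, k,
                       val.data(), gth.data());
    for (int j = 0; j < J; ++j) {
      ll += val[j];
      for (int i = 0; i < K; ++i)
        if (log_flag[i]) gth[K * j + i] *= theta[K * j + i] * ln10;
    }
  }
  double lp = ll;
  // priors: mu ~ N(mu_star, sd)
  for (int i = 0; i < K; ++i) {
    double r = (mu[i] - mu_star[i]) / mu_prior_sd;
    lp += -0.5 * r * r - std::log(mu_prior_sd) - 0.5 * std::log(2.0 * M_PI);
    double acc = 0.0;
    for (int j = 0; j < J; ++j) acc += gth[K * j + i];
    gmu[i] = acc - r / mu_prior_sd;
  }
  // z ~ N(0, 1); grad_z = L^T (tau * g) - z
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < K; ++i) {
      double zij = zv[K * j + i];
      lp += -0.5 * zij * zij - 0.5 * std::log(2.0 * M_PI);
      double acc = 0.0;
      for (int m = i; m < K; ++m)
        acc += L[m + K * i] * tau[m] * gth[K * j + m];
      gz[K * j + i] = acc - zij;
    }
  }
  // tau ~ HalfCauchy(tau_scale) with log-Jacobian
  if (has_tau) {
    for (int i = 0; i < K; ++i) {
      double tr = tau[i] / tau_scale;
      lp += std::log(2.0 / M_PI) - std::log(tau_scale) -
            std::log1p(tr * tr) + lt[i];
      double acc = 0.0;
      for (int j = 0; j < J; ++j) acc += gth[K * j + i] * Lz[K * j + i];
      glt[i] = acc * tau[i] - 2.0 * tr * tr / (1.0 + tr * tr) + 1.0;
    }
  }
  // LKJ prior on L plus transform Jacobian, and likelihood pullback to y
  {
    // grad wrt L from likelihood: GL[i][m] = sum_j tau_i g_ij z_mj
    std::vector<double> GL(K * K, 0.0);
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < K; ++i) {
        double tg = tau[i] * gth[K * j + i];
        for (int m = 0; m <= i; ++m)
          GL[i + K * m] += tg * zv[K * j + m];
      }
    int idx0 = 0;
    for (int i = 1; i < K; ++i) {
      double logr = 0.0;
      // recompute r_j prefix products and Li row
      std::vector<double> rpow(i + 1);
      rpow[0] = 1.0;
      for (int j = 0; j < i; ++j)
        rpow[j + 1] = rpow[j] * (1.0 - w[idx0 + j] * w[idx0 + j]);
      for (int j = 0; j < i; ++j) {
        double l1mw2 = std::log1p(-w[idx0 + j] * w[idx0 + j]);
        lp += 0.5 * logr + l1mw2;  // Jacobian of y -> L
        logr += l1mw2;
      }
      lp += (K - (i + 1) + 2.0 * lkj_eta - 2.0) * 0.5 * logr;  // LKJ on L_ii
      // gradient wrt y for this row: likelihood part
      for (int kk = 0; kk < i; ++kk) {
        double wk = w[idx0 + kk];
        double acc = std::sqrt(rpow[kk]) * GL[i + K * kk];
        double tailsum = 0.0;
        for (int j = kk + 1; j <= i; ++j) {
          double Lij = (j < i) ? L[i + K * j] : L[i + K * i];
          double GLij = (j < i) ? GL[i + K * j] : GL[i + K * i];
          tailsum += Lij * GLij;
        }
        acc -= wk / (1.0 - wk * wk) * tailsum;
        gy[idx0 + kk] = acc * (1.0 - wk * wk);
        // prior + Jacobian part (closed form): -w * (K - col - 1 + 2 eta)
        gy[idx0 + kk] += -wk * (K - (kk + 1) - 1 + 2.0 * lkj_eta);
      }
      idx0 += i;
    }
  }
  return List::create(_["value"] = lp, _["grad"] = grad);
}

// Grouped version: terms from all individuals concatenated, with 0-based
// individual ids per term and an 8 x J matrix of natural-scale parameters.
// Returns the total log-likelihood, per-individual values, and an 8 x J
// gradient matrix. Used by the hierarchical sampler (one call per posterior
// evaluation).
// [[Rcpp::export(name = "group_loglik_cpp")]]
List group_loglik_cpp(NumericVector bout_dur, LogicalVector bout_cens,
                      NumericVector rate, IntegerVector bout_id,
                      NumericVector route_x, LogicalVector route_L,
                      IntegerVector route_id,
                      NumericVector s_dur, LogicalVector s_cens,
                      IntegerVector s_id,
                      NumericVector imi_dur, NumericVector imi_x0,
                      LogicalVector imi_cens, IntegerVector imi_id,
                      NumericMatrix theta, int law, double k) {
  const int J = theta.ncol();
  NumericVector val(J);
  NumericMatrix g(8, J);
  // per-individual truncation constants for the rate density
  std::vector<double> logZ(J), mills(J);
  for (int j = 0; j < J; ++j) {
    double a = theta(1, j) / theta(2, j);
    logZ[j] = R::pnorm(a, 0.0, 1.0, 1, 1);
    mills[j] = std::exp(R::dnorm(a, 0.0, 1.0, 1) - logZ[j]);
  }
  for (int i = 0; i < bout_dur.size(); ++i) {
    int j = bout_id[i];
    double lamF = theta(0, j), muF = theta(1, j), sigF = theta(2, j);
    double d = bout_dur[i];
    if (bout_cens[i]) {
      val[j] += -lamF * d;
      g(0, j) += -d;
    } else {
      val[j] += std::log(lamF) - lamF * d;
      g(0, j) += 1.0 / lamF - d;
    }
    double z = (rate[i] - muF) / sigF;
    double alpha = muF / sigF;
    val[j] += -std::log(sigF) - 0.5 * z * z - 0.5 * std::log(2.0 * M_PI) -
              logZ[j];
    g(1, j) += z / sigF - mills[j] / sigF;
    g(2, j) += (-1.0 + z * z) / sigF + mills[j] * alpha / sigF;
  }
  for (int i = 0; i < route_x.size(); ++i) {
    int j = route_id[i];
    double T1 = theta(4, j), T2 = theta(5, j);
    double a = T1 * (route_x[i] - T2);
    double p = 1.0 / (1.0 + std::exp(-a));
    if (route_L[i]) {
      val[j] += -log1p_exp(-a);
      g(4, j) += (1.0 - p) * (route_x[i] - T2);
      g(5, j) += -(1.0 - p) * T1;
    } else {
      val[j] += -log1p_exp(a);
      g(4, j) += -p * (route_x[i] - T2);
      g(5, j) += p * T1;
    }
  }
  for (int i = 0; i < s_dur.size(); ++i) {
    int j = s_id[i];
    double lamS = theta(3, j);
    double d = s_dur[i];
    if (s_cens[i]) {
      val[j] += -lamS * d;
      g(3, j) += -d;
    } else {
      val[j] += std::log(lamS) - lamS * d;
      g(3, j) += 1.0 / lamS - d;
    }
  }
  for (int i = 0; i < imi_dur.size(); ++i) {
    int j = imi_id[i];
    double L1 = theta(6, j), L2 = theta(7, j);
    double Lam, dL1, dL2, xt;
    if (law == 0)
      imi_hazard_sqrt(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    else
      imi_hazard_linear(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    val[j] += -Lam;
    g(6, j) += -dL1;
    g(7, j) += -dL2;
    if (!imi_cens[i]) {
      double denom = L1 + L2 * xt;
      val[j] += -std::log(denom);
      g(6, j) += -1.0 / denom;
      g(7, j) += -xt / denom;
    }
  }
  double total = 0.0;
  for (int j = 0; j < J; ++j) total += val[j];
  return List::create(_["value"] = total, _["per_individual"] = val,
                      _["grad"] = g);
}

// [[Rcpp::export(name = "seq_loglik_cpp")]]
List seq_loglik_cpp(NumericVector bout_dur, LogicalVector bout_cens,
                    NumericVector rate,
                    NumericVector route_x, LogicalVector route_L,
                    NumericVector s_dur, LogicalVector s_cens,
                    NumericVector imi_dur, NumericVector imi_x0,
                    LogicalVector imi_cens,
                    NumericVector params, int law, double k) {
  const double lamF = params[0], muF = params[1], sigF = params[2];
  const double lamS = params[3], T1 = params[4], T2 = params[5];
  const double L1 = params[6], L2 = params[7];
  double ll = 0.0;
  NumericVector g(8);

  // bout durations: Exponential(lamF), censored -> survival
  for (int i = 0; i < bout_dur.size(); ++i) {
    double d = bout_dur[i];
    if (bout_cens[i]) {
      ll += -lamF * d;
      g[0] += -d;
    } else {
      ll += std::log(lamF) - lamF * d;
      g[0] += 1.0 / lamF - d;
    }
  }
  // per-bout rates: Normal(muF, sigF) truncated below at 0
  if (rate.size() > 0) {
    double alpha = muF / sigF;
    double logZ = R::pnorm(alpha, 0.0, 1.0, 1, 1);
    double mills = std::exp(R::dnorm(alpha, 0.0, 1.0, 1) - logZ);
    for (int i = 0; i < rate.size(); ++i) {
      double z = (rate[i] - muF) / sigF;
      ll += -std::log(sigF) - 0.5 * z * z - 0.5 * std::log(2.0 * M_PI) - logZ;
      g[1] += z / sigF - mills / sigF;
      g[2] += (-1.0 + z * z) / sigF + mills * alpha / sigF;
    }
  }
  // meal-termination routing: sigmoid in fullness at bout end
  for (int i = 0; i < route_x.size(); ++i) {
    double a = T1 * (route_x[i] - T2);
    double p = 1.0 / (1.0 + std::exp(-a));
    if (route_L[i]) {
      ll += -log1p_exp(-a);
      g[4] += (1.0 - p) * (route_x[i] - T2);
      g[5] += -(1.0 - p) * T1;
    } else {
      ll += -log1p_exp(a);
      g[4] += -p * (route_x[i] - T2);
      g[5] += p * T1;
    }
  }
  // short pauses: Exponential(lamS)
  for (int i = 0; i < s_dur.size(); ++i) {
    double d = s_dur[i];
    if (s_cens[i]) {
      ll += -lamS * d;
      g[3] += -d;
    } else {
      ll += std::log(lamS) - lamS * d;
      g[3] += 1.0 / lamS - d;
    }
  }
  // intermeal intervals: time-varying hazard along the emptying curve
  for (int i = 0; i < imi_dur.size(); ++i) {
    double Lam, dL1, dL2, xt;
    if (law == 0)
      imi_hazard_sqrt(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    else
      imi_hazard_linear(imi_x0[i], imi_dur[i], L1, L2, k, Lam, dL1, dL2, xt);
    ll += -Lam;
    g[6] += -dL1;
    g[7] += -dL2;
    if (!imi_cens[i]) {
      double denom = L1 + L2 * xt;
      ll += -std::log(denom);
      g[6] += -1.0 / denom;
      g[7] += -xt / denom;
    }
  }
  return List::create(_["value"] = ll, _["grad"] = g);
}
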