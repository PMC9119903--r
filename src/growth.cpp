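// Stage-covariate von Bertalanffy growth model: expected-length recursion,
// sufficient-statistic likelihood and an adaptive Metropolis-within-Gibbs
// sampler. The Normal likelihood with a common precision depends on the data
// only through per-cell (year x site x age) counts, means and sums of
// squares, so one likelihood evaluation costs O(cells), not O(records).
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  int Y, S, A;
  // cell stats, index [y + Y*(s + S*a)]
  std::vector<double> n, ybar, ss;
  // stage designs, index [y + Y*(s + S*m)], m within stage
  std::vector<double> X1, X2, X3;
  int m1, m2, m3;
  double n_tot;
  bool literal;
};

inline int cidx(const Model& M, int y, int s, int a) {
  return y + M.Y * (s + M.S * a);
}

// exp(theta_l . X_l[y,s,]) for all (y,s)
void stage_mult(const std::vector<double>& X, int m, const double* theta,
                int Y, int S, std::vector<double>& E) {
  const int YS = Y * S;
  for (int i = 0; i < YS; ++i) {
    double acc = 0.0;
    for (int j = 0; j < m; ++j) acc += theta[j] * X[i + YS * j];
    E[i] = std::exp(acc);
  }
}

// growth curve factors 1 - exp(-K (t_a - t0)) with t_a = a (age-class index)
void growth_factors(double K, double t0, int A, double* G) {
  for (int a = 0; a < A; ++a) G[a] = 1.0 - std::exp(-K * ((a + 1) - t0));
}

// expected-length recursion; mu indexed like cells
void compute_mu(const Model& M, double Linf, const double* G,
                const std::vector<double>& E1, const std::vector<double>& E2,
                const std::vector<double>& E3, const double* mu_init,
                std::vector<double>& mu) {
  const int Y = M.Y, S = M.S, A = M.A, YS = Y * S;
  for (int s = 0; s < S; ++s) {
    for (int y = 0; y < Y; ++y)
      mu[cidx(M, y, s, 0)] = Linf * G[0] * E1[y + Y * s];
    for (int a = 1; a < A; ++a)
      mu[cidx(M, 0, s, a)] = mu_init[s + S * (a - 1)];
    for (int y = 1; y < Y; ++y)
      for (int a = 1; a < A; ++a) {
        double prev = mu[cidx(M, y - 1, s, a - 1)];
        double mult = (a == 1) ? E2[y + Y * s] : E3[y + Y * s];
        double inc = (Linf - prev) * G[a] * mult;
        mu[cidx(M, y, s, a)] = M.literal ? inc : prev + inc;
      }
  }
  (void)YS;
}

// total weighted sum of squares sum_c [ ss_c + n_c (ybar_c - mu_c)^2 ]
double total_ss(const Model& M, const std::vector<double>& mu) {
  double acc = 0.0;
  const int n = (int)M.n.size();
  for (int i = 0; i < n; ++i) {
    if (M.n[i] > 0) {
      double d = M.ybar[i] - mu[i];
      acc += M.ss[i] + M.n[i] * d * d;
    }
  }
  return acc;
}

}  // namespace

// [[Rcpp::export]]
List growth_chain_cpp(NumericVector n_cell, NumericVector ybar_cell,
                      NumericVector ss_cell, int Y, int S, int A,
                      NumericVector X1, int m1, NumericVector X2, int m2,
                      NumericVector X3, int m3, NumericVector prior,
                      NumericVector init, double tau_init, int iterations,
                      int burn_in, int thin, bool literal) {
  Model M;
  M.Y = Y; M.S = S; M.A = A; M.literal = literal;
  M.n = as<std::vector<double>>(n_cell);
  M.ybar = as<std::vector<double>>(ybar_cell);
  M.ss = as<std::vector<double>>(ss_cell);
  M.X1 = as<std::vector<double>>(X1);
  M.X2 = as<std::vector<double>>(X2);
  M.X3 = as<std::vector<double>>(X3);
  M.m1 = m1; M.m2 = m2; M.m3 = m3;
  M.n_tot = 0.0;
  for (double v : M.n) M.n_tot += v;

  const double linf_mean = prior[0], linf_sd = prior[1];
  const double k_shape = prior[2], k_rate = prior[3];
  const double t0_mean = prior[4], t0_sd = prior[5];
  const double beta_sd = prior[6];
  const double mui_mean = prior[7], mui_sd = prior[8];
  const double tau_shape = prior[9], tau_rate = prior[10];

  const int n_mui = S * (A - 1);
  const int P = 3 + m1 + m2 + m3 + n_mui;  // Metropolis-updated parameters
  if ((int)init.size() != P) stop("init length mismatch");
  std::vector<double> par = as<std::vector<double>>(init);  // [Linf, logK, t0, thetas, mu_init]
  double tau = tau_init;

  // log-prior of the Metropolis block (constants dropped); logK carries the
  // Gamma prior on K plus the log-Jacobian of the log transform
  auto log_prior = [&](const std::vector<double>& p) {
    double lp = 0.0;
    double d = (p[0] - linf_mean) / linf_sd; lp += -0.5 * d * d;
    double logK = p[1];
    lp += k_shape * logK - k_rate * std::exp(logK);
    d = (p[2] - t0_mean) / t0_sd; lp += -0.5 * d * d;
    for (int j = 0; j < m1 + m2 + m3; ++j) {
      d = p[3 + j] / beta_sd; lp += -0.5 * d * d;
    }
    for (int j = 0; j < n_mui; ++j) {
      d = (p[3 + m1 + m2 + m3 + j] - mui_mean) / mui_sd; lp += -0.5 * d * d;
    }
    return lp;
  };

  const int YS = Y * S;
  std::vector<double> E1(YS), E2(YS, 1.0), E3(YS, 1.0);
  std::vector<double> G(A), mu(Y * S * A);
  std::vector<double> E1p(YS), E2p(YS), E3p(YS), Gp(A), mup(Y * S * A);

  auto refresh = [&](const std::vector<double>& p, std::vector<double>& e1,
                     std::vector<double>& e2, std::vector<double>& e3,
                     std::vector<double>& g, std::vector<double>& m_out) {
    stage_mult(M.X1, m1, p.data() + 3, Y, S, e1);
    stage_mult(M.X2, m2, p.data() + 3 + m1, Y, S, e2);
    stage_mult(M.X3, m3, p.data() + 3 + m1 + m2, Y, S, e3);
    growth_factors(std::exp(p[1]), p[2], A, g.data());
    compute_mu(M, p[0], g.data(), e1, e2, e3,
               p.data() + 3 + m1 + m2 + m3, m_out);
  };

  refresh(par, E1, E2, E3, G, mu);
  double cur_ss = total_ss(M, mu);
  double cur_lp = log_prior(par);
  if (!std::isfinite(cur_ss) || !std::isfinite(cur_lp))
    stop("non-finite log joint at initial values");

  std::vector<double> lsd(P, -1.0);
  const int keep = (iterations - burn_in) / thin;
  NumericMatrix draws(keep, P + 1);
  long n_acc = 0, n_prop = 0;
  int kept = 0;

  // running mean/covariance of (Linf, logK, t0) for an adaptive joint step:
  // the three curve parameters ride a narrow posterior ridge that
  // component-wise proposals traverse slowly
  double rm[3] = {par[0], par[1], par[2]};
  double rc[3][3] = {{0}};
  long rn = 1;
  double joint_lscale = std::log(2.38 / std::sqrt(3.0));

  RNGScope scope;
  std::vector<double> prop(P);
  for (int it = 1; it <= iterations; ++it) {
    for (int j = 0; j < P; ++j) {
      prop = par;
      prop[j] = par[j] + R::rnorm(0.0, std::exp(lsd[j]));
      // recompute only the caches parameter j touches
      const double* mui = prop.data() + 3 + m1 + m2 + m3;
      double new_ss;
      double new_lp = log_prior(prop);
      if (j == 1 || j == 2) {
        growth_factors(std::exp(prop[1]), prop[2], A, Gp.data());
        compute_mu(M, prop[0], Gp.data(), E1, E2, E3, mui, mup);
      } else if (j >= 3 && j < 3 + m1) {
        stage_mult(M.X1, m1, prop.data() + 3, Y, S, E1p);
        compute_mu(M, prop[0], G.data(), E1p, E2, E3, mui, mup);
      } else if (j >= 3 + m1 && j < 3 + m1 + m2) {
        stage_mult(M.X2, m2, prop.data() + 3 + m1, Y, S, E2p);
        compute_mu(M, prop[0], G.data(), E1, E2p, E3, mui, mup);
      } else if (j >= 3 + m1 + m2 && j < 3 + m1 + m2 + m3) {
        stage_mult(M.X3, m3, prop.data() + 3 + m1 + m2, Y, S, E3p);
        compute_mu(M, prop[0], G.data(), E1, E2, E3p, mui, mup);
      } else {
        compute_mu(M, prop[0], G.data(), E1, E2, E3, mui, mup);
      }
      new_ss = total_ss(M, mup);
      double lr = -0.5 * tau * (new_ss - cur_ss) + (new_lp - cur_lp);
      double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
      if (R::unif_rand() < alpha) {
        par = prop; cur_ss = new_ss; cur_lp = new_lp;
        mu.swap(mup);
        if (j == 1 || j == 2) G.swap(Gp);
        else if (j >= 3 && j < 3 + m1) E1.swap(E1p);
        else if (j >= 3 + m1 && j < 3 + m1 + m2) E2.swap(E2p);
        else if (j >= 3 + m1 + m2 && j < 3 + m1 + m2 + m3) E3.swap(E3p);
        ++n_acc;
      }
      ++n_prop;
      if (it <= burn_in) lsd[j] += (alpha - 0.44) / std::sqrt((double)it);
    }
    // joint update of the curve-parameter block from the adapted covariance
    {
      ++rn;
      double d0[3];
      for (int j = 0; j < 3; ++j) {
        d0[j] = par[j] - rm[j];
        rm[j] += d0[j] / rn;
      }
      for (int j = 0; j < 3; ++j)
        for (int l = 0; l <= j; ++l)
          rc[j][l] += d0[j] * (par[l] - rm[l]);
      for (int rep = 0; rep < 3 && rn > 100; ++rep) {
        double C[3][3], L[3][3] = {{0}};
        double s2 = std::exp(2.0 * joint_lscale);
        for (int j = 0; j < 3; ++j)
          for (int l = 0; l <= j; ++l)
            C[j][l] = C[l][j] = s2 * rc[j][l] / (rn - 1);
        for (int j = 0; j < 3; ++j) C[j][j] += 1e-10 * s2;
        bool ok = true;
        for (int j = 0; j < 3 && ok; ++j) {
          double acc = C[j][j];
          for (int l = 0; l < j; ++l) acc -= L[j][l] * L[j][l];
          if (acc <= 0) { ok = false; break; }
          L[j][j] = std::sqrt(acc);
          for (int r = j + 1; r < 3; ++r) {
            double a2 = C[r][j];
            for (int l = 0; l < j; ++l) a2 -= L[r][l] * L[j][l];
            L[r][j] = a2 / L[j][j];
          }
        }
        if (ok) {
          double z[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
          prop = par;
          for (int j = 0; j < 3; ++j)
            for (int l = 0; l <= j; ++l) prop[j] += L[j][l] * z[l];
          growth_factors(std::exp(prop[1]), prop[2], A, Gp.data());
          compute_mu(M, prop[0], Gp.data(), E1, E2, E3,
                     prop.data() + 3 + m1 + m2 + m3, mup);
          double new_ss = total_ss(M, mup);
          double new_lp = log_prior(prop);
          double lr = -0.5 * tau * (new_ss - cur_ss) + (new_lp - cur_lp);
          double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr))
                                           : 0.0;
          if (R::unif_rand() < alpha) {
            par = prop; cur_ss = new_ss; cur_lp = new_lp;
            mu.swap(mup); G.swap(Gp);
          }
          if (it <= burn_in)
            joint_lscale += (alpha - 0.234) / std::sqrt((double)it);
        }
      }
    }
    // conjugate Gibbs draw for the Normal precision
    tau = R::rgamma(tau_shape + 0.5 * M.n_tot,
                    1.0 / (tau_rate + 0.5 * cur_ss));
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < P; ++j) draws(kept, j) = par[j];
      draws(kept, P) = tau;
      ++kept;
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept"] = (double)n_acc / (double)n_prop);
}

// Per-draw expected-length grids: rows = draws, cols = cells
// [y + Y*(s + S*a)]. Column layout of `draws` matches growth_chain_cpp.
// [[Rcpp::export]]
NumericMatrix growth_mu_draws_cpp(NumericMatrix draws, int Y, int S, int A,
                                  NumericVector X1, int m1, NumericVector X2,
                                  int m2, NumericVector X3, int m3,
                                  bool literal) {
  Model M;
  M.Y = Y; M.S = S; M.A = A; M.literal = literal;
  M.n.assign(Y * S * A, 0.0);
  M.ybar.assign(Y * S * A, 0.0);
  M.ss.assign(Y * S * A, 0.0);
  M.X1 = as<std::vector<double>>(X1);
  M.X2 = as<std::vector<double>>(X2);
  M.X3 = as<std::vector<double>>(X3);
  M.m1 = m1; M.m2 = m2; M.m3 = m3;
  const int YS = Y * S, n_mui = S * (A - 1);
  const int P = 3 + m1 + m2 + m3 + n_mui;
  if (draws.ncol() < P) stop("draws matrix too narrow");
  NumericMatrix out(draws.nrow(), Y * S * A);
  std::vector<double> E1(YS), E2(YS), E3(YS), G(A), mu(Y * S * A), par(P);
  for (int d = 0; d < draws.nrow(); ++d) {
    for (int j = 0; j < P; ++j) par[j] = draws(d, j);
    stage_mult(M.X1, m1, par.data() + 3, Y, S, E1);
    stage_mult(M.X2, m2, par.data() + 3 + m1, Y, S, E2);
    stage_mult(M.X3, m3, par.data() + 3 + m1 + m2, Y, S, E3);
    growth_factors(std::exp(par[1]), par[2], A, G.data());
    compute_mu(M, par[0], G.data(), E1, E2, E3,
               par.data() + 3 + m1 + m2 + m3, mu);
    for (int i = 0; i < Y * S * A; ++i) out(d, i) = mu[i];
  }
  return out;
}

// Pointwise Normal log-likelihood matrix (draw x observation) for LOO.
// rec_cell holds each record's 0-based cell index; the tau column of
// `draws` is the last used column (index P).
// [[Rcpp::export]]
NumericMatrix growth_pointwise_cpp(NumericMatrix draws, NumericMatrix mu_draws,
                                   IntegerVector rec_cell,
                                   NumericVector rec_len, int P) {
  const int n = rec_cell.size();
  NumericMatrix out(draws.nrow(), n);
  for (int d = 0; d < draws.nrow(); ++d) {
    double tau = draws(d, P);
    double sd = 1.0 / std::sqrt(tau);
    for (int i = 0; i < n; ++i)
      out(d, i) = R::dnorm(rec_len[i], mu_draws(d, rec_cell[i]), sd, 1);
  }
  return out;
}
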