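// Adaptive single-site Metropolis-within-Gibbs sampler for the BYM
// Poisson model:
//   O_i ~ Poisson(E_i exp(eta_i)), eta_i = alpha + x_i'beta + u_i + v_i
//   u ~ ICAR(sigma_u) on the contiguity graph (sum-to-zero), v ~ N(0, sigma_v^2).
//
// Scalar blocks (alpha, each beta_j, log sigma) and the u/v vectors each
// carry one Gaussian random-walk proposal scale, adapted toward a target
// acceptance rate during burn-in and frozen afterwards. Under the
// gamma-precision prior the scales are updated by conjugate Gibbs steps.
// Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rw_step(double sd) { return norm_rand() * sd; }

// Gibbs draw of sigma under a Uniform(0, upper) prior on the SD given a
// Gaussian/ICAR sum of squares: the precision tau = sigma^-2 has
// p(tau) ~ Gamma((k - 1)/2, ss/2) truncated to tau > upper^-2
// (the extra -3/2 in the shape is the Jacobian of sigma -> tau).
// Returns a negative value when the draw is unavailable (k < 2 or a
// degenerate truncation), signalling the caller to fall back to a
// random-walk update.
static double gibbs_sigma_unif(int k, double ss, double upper) {
  if (k < 2 || ss <= 0.0) return -1.0;
  double shape = 0.5 * (k - 1);
  double rate = 0.5 * ss;
  double tau_lo = 1.0 / (upper * upper);
  double p_lo = R::pgamma(tau_lo, shape, 1.0 / rate, 1, 0);
  if (p_lo > 1.0 - 1e-12) return -1.0;
  double uu = p_lo + unif_rand() * (1.0 - p_lo);
  double tau = R::qgamma(uu, shape, 1.0 / rate, 1, 0);
  if (!std::isfinite(tau) || tau <= 0.0) return -1.0;
  double s = 1.0 / std::sqrt(tau);
  if (s >= upper) s = upper * (1.0 - 1e-12);
  return s;
}

// [[Rcpp::export(name = ".bym_chain_cpp")]]
List bym_chain_cpp(NumericVector O, NumericVector E, NumericMatrix X,
                   List nb, IntegerVector comp, int rank,
                   IntegerMatrix edges,
                   bool include_u, bool include_v,
                   int prior_family,            // 0 uniform_sd, 1 gamma_precision
                   double unif_upper, double gam_shape, double gam_rate,
                   double normal_prec,          // 0 => flat prior on alpha/beta
                   int n_iter, int burn_in, int thin,
                   int adapt_interval, double target_acc,
                   double alpha0, NumericVector beta0,
                   double sigma_u0, double sigma_v0,
                   bool store_u) {
  const int n = O.size();
  const int p = X.ncol();
  const int n_edges = edges.nrow();

  // neighbor lists as plain vectors (0-based)
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    nbr[i].assign(v.begin(), v.end());
  }
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (int)nbr[i].size();

  // component bookkeeping (1-based labels in `comp`)
  int n_comp = 0;
  for (int i = 0; i < n; ++i) n_comp = std::max(n_comp, comp[i]);
  std::vector< std::vector<int> > comp_members(n_comp);
  for (int i = 0; i < n; ++i) comp_members[comp[i] - 1].push_back(i);
  int n_big_comp = 0, big_comp_idx = -1;
  for (int c = 0; c < n_comp; ++c) {
    if ((int)comp_members[c].size() >= 2) { ++n_big_comp; big_comp_idx = c; }
  }

  // state
  double alpha = alpha0;
  NumericVector beta = clone(beta0);
  std::vector<double> u(n, 0.0), v(n, 0.0);
  double sigma_u = include_u ? sigma_u0 : 0.0;
  double sigma_v = include_v ? sigma_v0 : 0.0;
  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double xb = 0.0;
    for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
    eta[i] = alpha + xb;
  }
  double sumO = 0.0;
  for (int i = 0; i < n; ++i) sumO += O[i];

  // blocks: 0 = alpha, 1..p = beta, p+1 = u, p+2 = v,
  //         p+3 = log sigma_u, p+4 = log sigma_v
  const int n_blocks = p + 5;
  std::vector<double> prop_sd(n_blocks, 0.1);
  prop_sd[0] = 0.05;
  std::vector<long> acc(n_blocks, 0), att(n_blocks, 0);
  std::vector<long> acc_post(n_blocks, 0), att_post(n_blocks, 0);
  int batch = 0;

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  NumericMatrix scal(n_keep, p + 3);           // alpha, beta..., sigma_u, sigma_v
  NumericMatrix theta(n_keep, n);
  NumericMatrix u_draws(store_u ? n_keep : 0, store_u ? n : 0);
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;

    // ---- alpha --------------------------------------------------------
    {
      double eps = rw_step(prop_sd[0]);
      double sumEexp = 0.0;
      for (int i = 0; i < n; ++i) sumEexp += E[i] * std::exp(eta[i]);
      double dlp = sumO * eps - (std::exp(eps) - 1.0) * sumEexp;
      if (normal_prec > 0.0) {
        dlp += -0.5 * normal_prec *
               ((alpha + eps) * (alpha + eps) - alpha * alpha);
      }
      att[0]++; if (!adapting) att_post[0]++;
      if (std::log(unif_rand()) < dlp) {
        alpha += eps;
        for (int i = 0; i < n; ++i) eta[i] += eps;
        acc[0]++; if (!adapting) acc_post[0]++;
      }
    }

    // ---- beta ---------------------------------------------------------
    for (int j = 0; j < p; ++j) {
      double eps = rw_step(prop_sd[1 + j]);
      double dlp = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = eps * X(i, j);
        dlp += O[i] * de - E[i] * (std::exp(eta[i] + de) - std::exp(eta[i]));
      }
      if (normal_prec > 0.0) {
        dlp += -0.5 * normal_prec *
               ((beta[j] + eps) * (beta[j] + eps) - beta[j] * beta[j]);
      }
      att[1 + j]++; if (!adapting) att_post[1 + j]++;
      if (std::log(unif_rand()) < dlp) {
        beta[j] += eps;
        for (int i = 0; i < n; ++i) eta[i] += eps * X(i, j);
        acc[1 + j]++; if (!adapting) acc_post[1 + j]++;
      }
    }

    // ---- u (structured) ----------------------------------------------
    if (include_u) {
      const double inv2s2 = 1.0 / (2.0 * sigma_u * sigma_u);
      for (int i = 0; i < n; ++i) {
        if (deg[i] == 0) continue;           // isolates fixed at 0
        // proposal scaled by the current sigma_u so the acceptance rate
        // stays stable when the scale moves after adaptation freezes
        double eps = rw_step(prop_sd[p + 1] * sigma_u);
        double sdiff = 0.0;
        for (int k : nbr[i]) sdiff += (u[i] - u[k]);
        double dprior = -inv2s2 * (deg[i] * eps * eps + 2.0 * eps * sdiff);
        double dlik = O[i] * eps -
          E[i] * (std::exp(eta[i] + eps) - std::exp(eta[i]));
        att[p + 1]++; if (!adapting) att_post[p + 1]++;
        if (std::log(unif_rand()) < dprior + dlik) {
          u[i] += eps; eta[i] += eps;
          acc[p + 1]++; if (!adapting) acc_post[p + 1]++;
        }
      }
      // re-center per component; when one component spans all areas the
      // mean is absorbed into alpha so the likelihood is unchanged
      if (n_big_comp == 1 && (int)comp_members[big_comp_idx].size() == n) {
        const std::vector<int>& mem = comp_members[big_comp_idx];
        double m = 0.0;
        for (int i : mem) m += u[i];
        m /= mem.size();
        for (int i : mem) u[i] -= m;
        alpha += m;                          // eta unchanged
      } else if (n_big_comp >= 1) {
        for (int c = 0; c < n_comp; ++c) {
          const std::vector<int>& mem = comp_members[c];
          if ((int)mem.size() < 2) continue;
          double m = 0.0;
          for (int i : mem) m += u[i];
          m /= mem.size();
          for (int i : mem) { u[i] -= m; eta[i] -= m; }
        }
      }
    }

    // ---- v (unstructured) --------------------------------------------
    if (include_v) {
      const double inv2s2 = 1.0 / (2.0 * sigma_v * sigma_v);
      for (int i = 0; i < n; ++i) {
        double eps = rw_step(prop_sd[p + 2] * sigma_v);
        double dprior = -inv2s2 * ((v[i] + eps) * (v[i] + eps) - v[i] * v[i]);
        double dlik = O[i] * eps -
          E[i] * (std::exp(eta[i] + eps) - std::exp(eta[i]));
        att[p + 2]++; if (!adapting) att_post[p + 2]++;
        if (std::log(unif_rand()) < dprior + dlik) {
          v[i] += eps; eta[i] += eps;
          acc[p + 2]++; if (!adapting) acc_post[p + 2]++;
        }
      }
    }

    // ---- scales -------------------------------------------------------
    if (include_u) {
      double ss_u = 0.0;
      for (int e = 0; e < n_edges; ++e) {
        double d = u[edges(e, 0)] - u[edges(e, 1)];
        ss_u += d * d;
      }
      if (prior_family == 1) {               // conjugate Gibbs on tau_u
        double shape = gam_shape + 0.5 * rank;
        double rate = gam_rate + 0.5 * ss_u;
        double tau = R::rgamma(shape, 1.0 / rate);
        sigma_u = 1.0 / std::sqrt(tau);
      } else {                               // Uniform(0, upper) prior on sigma_u
        double s_gibbs = gibbs_sigma_unif(rank, ss_u, unif_upper);
        if (s_gibbs > 0.0) {
          sigma_u = s_gibbs;
        } else {
        // fallback: RW on log sigma with the support enforced
        double ls = std::log(sigma_u);
        double eps = rw_step(prop_sd[p + 3]);
        double s_new = std::exp(ls + eps);
        att[p + 3]++; if (!adapting) att_post[p + 3]++;
        if (s_new < unif_upper) {
          // target on sigma: -rank*log(sigma) - ss/(2 sigma^2); Jacobian log(sigma)
          double f_old = (1.0 - rank) * std::log(sigma_u) -
            ss_u / (2.0 * sigma_u * sigma_u);
          double f_new = (1.0 - rank) * std::log(s_new) -
            ss_u / (2.0 * s_new * s_new);
          if (std::log(unif_rand()) < f_new - f_old) {
            sigma_u = s_new;
            acc[p + 3]++; if (!adapting) acc_post[p + 3]++;
          }
        }
        }
      }
    }
    if (include_v) {
      double ss_v = 0.0;
      for (int i = 0; i < n; ++i) ss_v += v[i] * v[i];
      if (prior_family == 1) {
        double shape = gam_shape + 0.5 * n;
        double rate = gam_rate + 0.5 * ss_v;
        double tau = R::rgamma(shape, 1.0 / rate);
        sigma_v = 1.0 / std::sqrt(tau);
      } else {                               // Uniform(0, upper) prior on sigma_v
        double s_gibbs = gibbs_sigma_unif(n, ss_v, unif_upper);
        if (s_gibbs > 0.0) {
          sigma_v = s_gibbs;
        } else {
        double ls = std::log(sigma_v);
        double eps = rw_step(prop_sd[p + 4]);
        double s_new = std::exp(ls + eps);
        att[p + 4]++; if (!adapting) att_post[p + 4]++;
        if (s_new < unif_upper) {
          double f_old = (1.0 - n) * std::log(sigma_v) -
            ss_v / (2.0 * sigma_v * sigma_v);
          double f_new = (1.0 - n) * std::log(s_new) -
            ss_v / (2.0 * s_new * s_new);
          if (std::log(unif_rand()) < f_new - f_old) {
            sigma_v = s_new;
            acc[p + 4]++; if (!adapting) acc_post[p + 4]++;
          }
        }
        }
      }
    }

    // ---- adaptation (burn-in only) ------------------------------------
    if (adapting && iter % adapt_interval == 0) {
      ++batch;
      double step = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int b = 0; b < n_blocks; ++b) {
        if (att[b] == 0) continue;
        double rate = (double)acc[b] / (double)att[b];
        double ls = std::log(prop_sd[b]);
        ls += (rate > target_acc) ? step : -step;
        prop_sd[b] = std::exp(ls);
        acc[b] = 0; att[b] = 0;
      }
    }

    // ---- storage ------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      scal(keep, 0) = alpha;
      for (int j = 0; j < p; ++j) scal(keep, 1 + j) = beta[j];
      scal(keep, p + 1) = sigma_u;
      scal(keep, p + 2) = sigma_v;
      for (int i = 0; i < n; ++i) theta(keep, i) = std::exp(alpha + u[i] + v[i]);
      if (store_u) for (int i = 0; i < n; ++i) u_draws(keep, i) = u[i];
      ++keep;
    }

    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(n_blocks), final_sd(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    acc_rate[b] = att_post[b] > 0 ?
      (double)acc_post[b] / (double)att_post[b] : NA_REAL;
    final_sd[b] = prop_sd[b];
  }

  return List::create(
    _["scalars"] = scal,
    _["theta"] = theta,
    _["u"] = u_draws,
    _["acc_rate"] = acc_rate,
    _["prop_sd"] = final_sd);
}
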