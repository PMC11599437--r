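#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical von
// Bertalanffy model:
//
//   R_j ~ Normal(Rinf_i (1 - exp(-k_i (age_j + s0_i))), sd_obs)
//   Rinf_i, k_i, s0_i ~ Gamma(mean mu_Xg, precision tau_Xg)   (shape = mu^2 tau,
//                                                              rate = mu tau)
//   mu_Xg ~ Gamma(shape 4, rate 4 / center_X)
//   tau_Xg ~ HalfNormal(ht_X);  sd_obs ~ HalfNormal(obs_scale)
//
// The three individual parameters of one fish form a strongly correlated
// ridge (the curve is far from its asymptote over observable ages), so
// each fish's (log Rinf, log k, log s0) is updated as one joint block with
// a proposal covariance adapted from the pooled chain history; group-level
// (log mu, log tau) pairs and log sd_obs get their own adaptive blocks.
// All parameters are sampled on the log scale (Jacobians included).
// Adaptation runs only during burn-in, so the post-burn-in chain is a
// fixed Markov kernel.

static inline double vb_mean(double Rinf, double k, double s0, double age) {
  return Rinf * (1.0 - std::exp(-k * (age + s0)));
}

// log Gamma(mean mu, precision tau) density of x, without terms constant
// in everything (full form: kept complete because mu, tau are sampled)
static inline double lgamma_dens(double x, double mu, double tau) {
  const double a = mu * mu * tau, b = mu * tau;
  return (a - 1.0) * std::log(x) - b * x + a * std::log(b) - ::Rf_lgammafn(a);
}

// [[Rcpp::export]]
List vb_chain_cpp(NumericVector R, NumericVector age, IntegerVector fish,
                  IntegerVector grp, int G, NumericVector centers,
                  NumericVector ht, double obs_scale, NumericVector init_ind,
                  NumericVector init_grp, double init_sd, int n_iter,
                  int n_burnin, int thin) {
  const int Nobs = R.size();
  const int Nfish = init_ind.size() / 3;
  // state on log scale
  NumericMatrix th(Nfish, 3);      // log Rinf, log k, log s0
  for (int i = 0; i < Nfish; ++i)
    for (int p = 0; p < 3; ++p) th(i, p) = std::log(init_ind[i + p * Nfish]);
  NumericMatrix gmu(G, 3), gtau(G, 3);  // log mu, log tau per group/param
  for (int g = 0; g < G; ++g)
    for (int p = 0; p < 3; ++p) {
      gmu(g, p) = std::log(init_grp[g + p * G]);
      gtau(g, p) = std::log(1.0 / (0.3 * 0.3));  // start at moderate precision
    }
  double lsd = std::log(init_sd);

  // per-fish observation index ranges (fish assumed grouped consecutively)
  std::vector<int> obs_start(Nfish, -1), obs_end(Nfish, -1);
  for (int j = 0; j < Nobs; ++j) {
    int f = fish[j] - 1;
    if (obs_start[f] < 0) obs_start[f] = j;
    obs_end[f] = j + 1;
  }
  std::vector<std::vector<int> > members(G);
  for (int i = 0; i < Nfish; ++i) members[grp[i] - 1].push_back(i);

  // cached per-fish Gaussian log-likelihood (without -log(sd) * n term,
  // tracked separately via SSE) -- we cache SSE per fish
  std::vector<double> sse(Nfish);
  auto fish_sse = [&](int i, double Rinf, double k, double s0) {
    double s = 0.0;
    for (int j = obs_start[i]; j < obs_end[i]; ++j) {
      const double d = R[j] - vb_mean(Rinf, k, s0, age[j]);
      s += d * d;
    }
    return s;
  };
  for (int i = 0; i < Nfish; ++i)
    sse[i] = fish_sse(i, std::exp(th(i, 0)), std::exp(th(i, 1)), std::exp(th(i, 2)));

  // individual-level prior (+ Jacobian of the log transform)
  auto ind_prior = [&](int i, double lR, double lk, double ls) {
    const int g = grp[i] - 1;
    double lp = 0.0;
    const double v[3] = {lR, lk, ls};
    for (int p = 0; p < 3; ++p) {
      const double x = std::exp(v[p]);
      lp += lgamma_dens(x, std::exp(gmu(g, p)), std::exp(gtau(g, p))) + v[p];
    }
    return lp;
  };

  // adaptation state: pooled 3x3 covariance of fish blocks (Welford over
  // the chain history of all fish), per-fish scalar step; 2x2 per group
  // block; scalar for sd_obs
  double C[3][3] = {{0.04, 0, 0}, {0, 0.04, 0}, {0, 0, 0.04}};
  double mean_th[3] = {0, 0, 0};
  double n_ad = 0;
  std::vector<double> lam_fish(Nfish, 0.5), lam_grp(G * 3, 0.5),
    lam_tr(G * 3, 0.1);
  double lam_sd = 0.5;
  double Lc[3][3];  // Cholesky of C (lower)
  auto chol3 = [&]() {
    double A[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) A[a][b] = C[a][b] + (a == b ? 1e-8 : 0.0);
    Lc[0][0] = std::sqrt(A[0][0]);
    Lc[1][0] = A[1][0] / Lc[0][0];
    Lc[2][0] = A[2][0] / Lc[0][0];
    Lc[1][1] = std::sqrt(std::max(A[1][1] - Lc[1][0] * Lc[1][0], 1e-10));
    Lc[2][1] = (A[2][1] - Lc[2][0] * Lc[1][0]) / Lc[1][1];
    Lc[2][2] = std::sqrt(std::max(A[2][2] - Lc[2][0] * Lc[2][0] - Lc[2][1] * Lc[2][1], 1e-10));
  };
  chol3();

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix out(n_keep, G * 6 + 1);
  int kept = 0;
  const double g_adapt = 0.05, target = 0.30;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    const double sd = std::exp(lsd), inv2s2 = 1.0 / (2.0 * sd * sd);
    // --- fish blocks ---
    for (int i = 0; i < Nfish; ++i) {
      double z[3];
      for (int p = 0; p < 3; ++p) z[p] = ::norm_rand();
      double prop[3];
      for (int p = 0; p < 3; ++p) {
        double step = 0.0;
        for (int q = 0; q <= p; ++q) step += Lc[p][q] * z[q];
        prop[p] = th(i, p) + lam_fish[i] * step;
      }
      const double sse_new = fish_sse(i, std::exp(prop[0]), std::exp(prop[1]),
                                      std::exp(prop[2]));
      const double delta = -(sse_new - sse[i]) * inv2s2 +
        ind_prior(i, prop[0], prop[1], prop[2]) -
        ind_prior(i, th(i, 0), th(i, 1), th(i, 2));
      const bool acc = std::log(::unif_rand()) < delta;
      if (acc) {
        for (int p = 0; p < 3; ++p) th(i, p) = prop[p];
        sse[i] = sse_new;
      }
      if (it < n_burnin) {
        lam_fish[i] *= std::exp(g_adapt * ((acc ? 1.0 : 0.0) - target));
        // pooled Welford update of the 3x3 covariance
        n_ad += 1.0;
        double d0[3], d1[3];
        for (int p = 0; p < 3; ++p) d0[p] = th(i, p) - mean_th[p];
        for (int p = 0; p < 3; ++p) mean_th[p] += d0[p] / n_ad;
        for (int p = 0; p < 3; ++p) d1[p] = th(i, p) - mean_th[p];
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q)
            C[p][q] += (d0[p] * d1[q] - C[p][q]) / n_ad;
      }
    }
    if (it < n_burnin && it % 20 == 19) chol3();

    // --- group-level blocks: (log mu, log tau) per group and parameter ---
    for (int g = 0; g < G; ++g) {
      for (int p = 0; p < 3; ++p) {
        double sum_lx = 0.0, sum_x = 0.0;
        const int ng = members[g].size();
        for (int m = 0; m < ng; ++m) {
          sum_lx += th(members[g][m], p);
          sum_x += std::exp(th(members[g][m], p));
        }
        auto grp_post = [&](double lmu, double ltau) {
          const double mu = std::exp(lmu), tau = std::exp(ltau);
          const double a = mu * mu * tau, b = mu * tau;
          double lp = (a - 1.0) * sum_lx - b * sum_x +
            ng * (a * std::log(b) - ::Rf_lgammafn(a));
          lp += 3.0 * lmu - (4.0 / centers[p]) * mu + lmu;        // gamma(4) prior + Jac
          lp += -tau * tau / (2.0 * ht[p] * ht[p]) + ltau;        // half-normal + Jac
          return lp;
        };
        const double lam = lam_grp[g * 3 + p];
        const double pm = gmu(g, p) + lam * ::norm_rand();
        const double pt = gtau(g, p) + lam * 2.0 * ::norm_rand();
        const double delta = grp_post(pm, pt) - grp_post(gmu(g, p), gtau(g, p));
        const bool acc = std::log(::unif_rand()) < delta;
        if (acc) { gmu(g, p) = pm; gtau(g, p) = pt; }
        if (it < n_burnin)
          lam_grp[g * 3 + p] *= std::exp(g_adapt * ((acc ? 1.0 : 0.0) - target));
      }
    }

    // --- group translation moves: slide a group's parameter and its
    // group mean together in log space (cures the slow joint drift of a
    // hierarchy where individuals and their mean must move in lockstep) ---
    for (int g = 0; g < G; ++g) {
      for (int p = 0; p < 3; ++p) {
        const double lam = lam_tr[g * 3 + p];
        const double eps = lam * ::norm_rand();
        const int ng = members[g].size();
        const double mu_new = std::exp(gmu(g, p) + eps);
        const double mu_old = std::exp(gmu(g, p));
        const double tau = std::exp(gtau(g, p));
        double delta = 0.0;
        std::vector<double> sse_new(ng);
        for (int m = 0; m < ng; ++m) {
          const int i = members[g][m];
          double v[3] = {std::exp(th(i, 0)), std::exp(th(i, 1)), std::exp(th(i, 2))};
          const double x_old = v[p], x_new = v[p] * std::exp(eps);
          v[p] = x_new;
          sse_new[m] = fish_sse(i, v[0], v[1], v[2]);
          delta += -(sse_new[m] - sse[i]) * inv2s2 +
            lgamma_dens(x_new, mu_new, tau) - lgamma_dens(x_old, mu_old, tau);
        }
        delta += 3.0 * eps - (4.0 / centers[p]) * (mu_new - mu_old);  // hyperprior
        delta += (ng + 1.0) * eps;  // log-scale Jacobian terms (x_i's and mu)
        const bool acc = std::log(::unif_rand()) < delta;
        if (acc) {
          gmu(g, p) += eps;
          for (int m = 0; m < ng; ++m) {
            th(members[g][m], p) += eps;
            sse[members[g][m]] = sse_new[m];
          }
        }
        if (it < n_burnin)
          lam_tr[g * 3 + p] *= std::exp(g_adapt * ((acc ? 1.0 : 0.0) - target));
      }
    }

    // --- observation sd ---
    {
      double sse_tot = 0.0;
      for (int i = 0; i < Nfish; ++i) sse_tot += sse[i];
      auto sd_post = [&](double l) {
        const double s = std::exp(l);
        return -Nobs * l - sse_tot / (2.0 * s * s) -
          s * s / (2.0 * obs_scale * obs_scale) + l;
      };
      const double prop = lsd + lam_sd * ::norm_rand();
      const bool acc = std::log(::unif_rand()) < sd_post(prop) - sd_post(lsd);
      if (acc) lsd = prop;
      if (it < n_burnin)
        lam_sd *= std::exp(g_adapt * ((acc ? 1.0 : 0.0) - target));
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int p = 0; p < 3; ++p)
        for (int g = 0; g < G; ++g) out(kept, c++) = std::exp(gmu(g, p));
      for (int p = 0; p < 3; ++p)
        for (int g = 0; g < G; ++g) out(kept, c++) = std::exp(gtau(g, p));
      out(kept, c) = std::exp(lsd);
      ++kept;
    }
  }
  return List::create(_["draws"] = out);
}
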