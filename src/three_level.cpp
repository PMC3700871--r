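// Metropolis-within-Gibbs chain for the three-level observation model.
//
// Latent state per turbine-night: collisions N, fall-ins Nfa, remaining
// Nre; availability Na follows the carry-over recursion
//   Na[t] = Nre[t-1] - c[t-1] + Nfa[t]   (Na[1] = Nfa[1]).
//
// Update scheme (one iteration):
//  * Nfa[t]: exact discrete Gibbs.  Marginalising the collision count N
//    out of Binom(Nfa | N, a) with N ~ Poisson(lambda) leaves
//    Nfa ~ Poisson(lambda a), so the full conditional of Nfa given the
//    rest of the chain is proportional to
//      Pois(Nfa; lambda a) * Binom(Nre | Na(Nfa), s),
//    enumerated over its (finite in practice) support.  Sampling Nfa
//    with N integrated out is what lets kills move freely between
//    nights; a random-walk update of Nfa conditional on N stalls,
//    because N - Nfa ~ Poisson(lambda (1 - a)) is almost always 0 at
//    realistic collision rates.
//  * N[t]: exact conditional N = Nfa + Poisson(lambda (1 - a)).
//  * Nre[t]: exact discrete Gibbs on [lower, Na(t)], with the
//    persistence term of night t+1 (whose availability depends on
//    Nre[t]) included.
//  * a kill-time shift move: Metropolis proposal exchanging a kill at
//    night t for a kill at night t-1 that persisted one extra night,
//    preserving all observed counts (tunnels directly between
//    kill-time allocations).
//  * s, f: conjugate Beta updates; coefficients: per-coordinate
//    Gaussian random walks, step sizes adapted during burn-in only.
//
// The inner loops dominate run time at paper-scale iteration counts,
// hence C++.

#include <Rcpp.h>
using namespace Rcpp;

// log-factorial table, grown on demand
static std::vector<double> lf_tab(1, 0.0);
static inline void lf_ensure(int n) {
  while ((int)lf_tab.size() <= n) {
    int m = lf_tab.size();
    lf_tab.push_back(lf_tab[m - 1] + std::log((double)m));
  }
}
static inline double lfac(int n) { return lf_tab[n]; }

// log Binomial(k | n, p) with cached log(p), log(1-p); p = 1 (or 0)
// handled so that 0 * log(0) contributes nothing
static inline double ldbinom_c(int k, int n, double lp, double l1mp) {
  if (k < 0 || k > n) return -INFINITY;
  double out = lfac(n) - lfac(k) - lfac(n - k);
  if (k > 0) out += k * lp;
  if (n - k > 0) out += (n - k) * l1mp;
  return out;
}

// log Poisson(k | mu) with cached log(mu)
static inline double ldpois_c(int k, double mu, double lmu) {
  if (k == 0) return -mu;
  return k * lmu - mu - lfac(k);
}

// [[Rcpp::export]]
List chain_three_level_cpp(IntegerVector cc, LogicalVector searched,
                           IntegerVector tindex, NumericMatrix X,
                           NumericVector a_n, IntegerVector night,
                           LogicalVector is_first, LogicalVector is_last,
                           NumericVector s_init, NumericVector f_init,
                           NumericVector s_alpha, NumericVector s_beta,
                           NumericVector f_alpha, NumericVector f_beta,
                           LogicalVector s_free, LogicalVector f_free,
                           NumericVector alpha_init, LogicalVector coef_free,
                           int n_iterations, int burn_in, int thin,
                           double proposal_scale, int adapt_interval,
                           Nullable<IntegerMatrix> latent_init = R_NilValue) {
  const int n = cc.size();
  int n_turb = 0;
  for (int j = 0; j < n; ++j) n_turb = std::max(n_turb, tindex[j]);

  NumericVector s = clone(s_init), f = clone(f_init);
  NumericVector alpha = clone(alpha_init);
  std::vector<int> N(n), Nfa(n), Nre(n), Na(n);
  if (latent_init.isNotNull()) {
    IntegerMatrix li(latent_init);
    for (int j = 0; j < n; ++j) {
      N[j] = li(j, 0);
      Nfa[j] = li(j, 1);
      Nre[j] = li(j, 2);
      Na[j] = is_first[j] ? Nfa[j] : Nre[j - 1] - cc[j - 1] + Nfa[j];
    }
  } else {
    for (int j = 0; j < n; ++j) N[j] = Nfa[j] = Nre[j] = Na[j] = cc[j];
  }

  std::vector<double> la(n), l1ma(n); // log a, log(1 - a) per night
  for (int j = 0; j < n; ++j) {
    la[j] = std::log(a_n[j]);
    l1ma[j] = std::log1p(-a_n[j]);
  }
  std::vector<double> ls(n_turb), l1ms(n_turb), lff(n_turb), l1mf(n_turb);
  auto refresh_sf_logs = [&]() {
    for (int i = 0; i < n_turb; ++i) {
      ls[i] = std::log(s[i]);
      l1ms[i] = std::log1p(-s[i]);
      lff[i] = std::log(f[i]);
      l1mf[i] = std::log1p(-f[i]);
    }
  };
  refresh_sf_logs();
  {
    int lf_need = 256;
    for (int j = 0; j < n; ++j) lf_need = std::max(lf_need, cc[j] + 192);
    lf_ensure(lf_need);
  }

  std::vector<double> eta(n), lambda(n);
  auto refresh_eta = [&]() {
    for (int j = 0; j < n; ++j) {
      double e = alpha[0] + alpha[1] * X(j, 1) + alpha[2] * X(j, 2) +
                 alpha[3] * X(j, 3);
      eta[j] = e;
      lambda[j] = std::exp(e);
    }
  };
  refresh_eta();

  NumericVector scales(4, proposal_scale);
  NumericVector acc(4);
  const int n_keep = (n_iterations - burn_in) / thin;
  NumericMatrix out_alpha(n_keep, 4), out_s(n_keep, n_turb),
      out_f(n_keep, n_turb), out_Ntot(n_keep, n_turb);
  int keep = 0;

  std::vector<double> sum_rem(n_turb), sum_gone(n_turb), sum_found(n_turb),
      sum_over(n_turb);

  for (int iter = 1; iter <= n_iterations; ++iter) {
    // collisions: exact conditional
    for (int j = 0; j < n; ++j) {
      N[j] = Nfa[j] + (int)R::rpois(lambda[j] * (1.0 - a_n[j]));
    }

    // fall-in counts: exact Gibbs with N marginalised out
    for (int j = 0; j < n; ++j) {
      int ti = tindex[j] - 1;
      int base = Na[j] - Nfa[j]; // Nre[t-1] - c[t-1], 0 on first nights
      int lower = std::max(0, Nre[j] - base);
      // support: Poisson(mu) mass K steps above `lower` is negligible
      // once the binomial factor stops growing (nfa beyond ~Nre - base)
      double mu = lambda[j] * a_n[j];
      double lmu = eta[j] + la[j];
      int K = std::max(8, Nre[j] - base - lower + 8);
      K = std::min(K, 60);
      lf_ensure(base + lower + K + 1);
      std::vector<double> w(K + 1);
      double wmax = -INFINITY;
      for (int v = 0; v <= K; ++v) {
        int nfa = lower + v;
        w[v] = ldpois_c(nfa, mu, lmu) + ldbinom_c(Nre[j], base + nfa, ls[ti], l1ms[ti]);
        if (w[v] > wmax) wmax = w[v];
      }
      double tot = 0.0;
      for (int v = 0; v <= K; ++v) {
        w[v] = std::exp(w[v] - wmax);
        tot += w[v];
      }
      double u = unif_rand() * tot;
      int v = 0;
      for (; v < K; ++v) {
        u -= w[v];
        if (u <= 0) break;
      }
      int nfa_new = lower + v;
      Na[j] += nfa_new - Nfa[j];
      Nfa[j] = nfa_new;
      // complete the joint (Nfa, N) Gibbs draw with N's exact conditional
      N[j] = Nfa[j] + (int)R::rpois(lambda[j] * (1.0 - a_n[j]));
    }

    // remaining counts: exact Gibbs on [lower, Na], sequential sweep
    for (int j = 0; j < n; ++j) {
      int ti = tindex[j] - 1;
      bool has_next = !is_last[j];
      int lower = searched[j] ? cc[j] : 0;
      if (has_next) {
        // availability of night t+1 must stay >= its remaining count
        lower = std::max(lower, Nre[j + 1] - Nfa[j + 1] + cc[j]);
      }
      int upper = Na[j];
      if (lower > upper) continue; // cannot happen for a valid state
      int m = upper - lower;
      std::vector<double> w(m + 1);
      double wmax = -INFINITY;
      for (int v = 0; v <= m; ++v) {
        int nre = lower + v;
        double lw = ldbinom_c(nre, Na[j], ls[ti], l1ms[ti]);
        if (searched[j]) lw += ldbinom_c(cc[j], nre, lff[ti], l1mf[ti]);
        if (has_next) {
          int tn = tindex[j + 1] - 1;
          lw += ldbinom_c(Nre[j + 1], nre - cc[j] + Nfa[j + 1], ls[tn], l1ms[tn]);
        }
        w[v] = lw;
        if (lw > wmax) wmax = lw;
      }
      double tot = 0.0;
      for (int v = 0; v <= m; ++v) {
        w[v] = std::exp(w[v] - wmax);
        tot += w[v];
      }
      double u = unif_rand() * tot;
      int v = 0;
      for (; v < m; ++v) {
        u -= w[v];
        if (u <= 0) break;
      }
      int nre_new = lower + v;
      if (has_next) Na[j + 1] += nre_new - Nre[j];
      Nre[j] = nre_new;
    }

    // kill-time shift: exchange a kill at night t for a kill at night
    // t-1 that persisted one extra night (symmetric Metropolis move,
    // observed counts unchanged)
    for (int j = 0; j < n; ++j) {
      if (is_first[j]) continue;
      int ti = tindex[j] - 1, tp = tindex[j - 1] - 1;
      if (unif_rand() < 0.5) {
        // backward: kill at j becomes kill at j-1 persisting into j
        if (Nfa[j] < 1) continue;
        lf_ensure(std::max(N[j - 1] + 2, Na[j - 1] + 2));
        double logr =
            ldpois_c(N[j - 1] + 1, lambda[j - 1], eta[j - 1]) -
            ldpois_c(N[j - 1], lambda[j - 1], eta[j - 1]) +
            ldpois_c(N[j] - 1, lambda[j], eta[j]) - ldpois_c(N[j], lambda[j], eta[j]) +
            ldbinom_c(Nfa[j - 1] + 1, N[j - 1] + 1, la[j - 1], l1ma[j - 1]) -
            ldbinom_c(Nfa[j - 1], N[j - 1], la[j - 1], l1ma[j - 1]) +
            ldbinom_c(Nfa[j] - 1, N[j] - 1, la[j], l1ma[j]) -
            ldbinom_c(Nfa[j], N[j], la[j], l1ma[j]) +
            ldbinom_c(Nre[j - 1] + 1, Na[j - 1] + 1, ls[tp], l1ms[tp]) -
            ldbinom_c(Nre[j - 1], Na[j - 1], ls[tp], l1ms[tp]);
        if (searched[j - 1]) {
          logr += ldbinom_c(cc[j - 1], Nre[j - 1] + 1, lff[tp], l1mf[tp]) -
                  ldbinom_c(cc[j - 1], Nre[j - 1], lff[tp], l1mf[tp]);
        }
        if (std::log(unif_rand()) < logr) {
          N[j - 1] += 1; Nfa[j - 1] += 1; Nre[j - 1] += 1; Na[j - 1] += 1;
          N[j] -= 1; Nfa[j] -= 1;
          // Na[j] = Nre[j-1] - c[j-1] + Nfa[j] is unchanged (+1 - 1)
        }
      } else {
        // forward: kill at j-1 that persisted into j becomes kill at j
        if (Nfa[j - 1] < 1 || Nre[j - 1] < 1) continue;
        int lower_prev = searched[j - 1] ? cc[j - 1] : 0;
        if (Nre[j - 1] - 1 < lower_prev) continue;
        lf_ensure(std::max(N[j] + 2, Na[j - 1] + 1));
        double logr =
            ldpois_c(N[j - 1] - 1, lambda[j - 1], eta[j - 1]) -
            ldpois_c(N[j - 1], lambda[j - 1], eta[j - 1]) +
            ldpois_c(N[j] + 1, lambda[j], eta[j]) - ldpois_c(N[j], lambda[j], eta[j]) +
            ldbinom_c(Nfa[j - 1] - 1, N[j - 1] - 1, la[j - 1], l1ma[j - 1]) -
            ldbinom_c(Nfa[j - 1], N[j - 1], la[j - 1], l1ma[j - 1]) +
            ldbinom_c(Nfa[j] + 1, N[j] + 1, la[j], l1ma[j]) -
            ldbinom_c(Nfa[j], N[j], la[j], l1ma[j]) +
            ldbinom_c(Nre[j - 1] - 1, Na[j - 1] - 1, ls[tp], l1ms[tp]) -
            ldbinom_c(Nre[j - 1], Na[j - 1], ls[tp], l1ms[tp]);
        if (searched[j - 1]) {
          logr += ldbinom_c(cc[j - 1], Nre[j - 1] - 1, lff[tp], l1mf[tp]) -
                  ldbinom_c(cc[j - 1], Nre[j - 1], lff[tp], l1mf[tp]);
        }
        if (std::log(unif_rand()) < logr) {
          N[j - 1] -= 1; Nfa[j - 1] -= 1; Nre[j - 1] -= 1; Na[j - 1] -= 1;
          N[j] += 1; Nfa[j] += 1;
        }
      }
    }

    // persistence and searcher efficiency: conjugate Beta
    std::fill(sum_rem.begin(), sum_rem.end(), 0.0);
    std::fill(sum_gone.begin(), sum_gone.end(), 0.0);
    std::fill(sum_found.begin(), sum_found.end(), 0.0);
    std::fill(sum_over.begin(), sum_over.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      int ti = tindex[j] - 1;
      sum_rem[ti] += Nre[j];
      sum_gone[ti] += Na[j] - Nre[j];
      if (searched[j]) {
        sum_found[ti] += cc[j];
        sum_over[ti] += Nre[j] - cc[j];
      }
    }
    for (int i = 0; i < n_turb; ++i) {
      if (s_free[i]) s[i] = R::rbeta(s_alpha[i] + sum_rem[i], s_beta[i] + sum_gone[i]);
      if (f_free[i]) f[i] = R::rbeta(f_alpha[i] + sum_found[i], f_beta[i] + sum_over[i]);
    }
    refresh_sf_logs();

    // coefficients: per-coordinate random walk, Normal(0, 100) prior
    for (int k = 0; k < 4; ++k) {
      if (!coef_free[k]) continue;
      double prop = alpha[k] + norm_rand() * scales[k];
      double diff = prop - alpha[k];
      double dll = 0.0;
      bool ok = true;
      for (int j = 0; j < n; ++j) {
        double eta_new = eta[j] + diff * X(j, k);
        double lam_new = std::exp(eta_new);
        if (!std::isfinite(lam_new)) { ok = false; break; }
        dll += N[j] * (eta_new - eta[j]) - (lam_new - lambda[j]);
      }
      if (!ok) continue;
      dll += R::dnorm(prop, 0.0, 10.0, 1) - R::dnorm(alpha[k], 0.0, 10.0, 1);
      if (std::log(unif_rand()) < dll) {
        alpha[k] = prop;
        for (int j = 0; j < n; ++j) {
          eta[j] += diff * X(j, k);
          lambda[j] = std::exp(eta[j]);
        }
        acc[k] += 1.0;
      }
    }
    if (iter <= burn_in && iter % adapt_interval == 0) {
      for (int k = 0; k < 4; ++k) {
        if (!coef_free[k]) continue;
        double rate = acc[k] / adapt_interval;
        double fac = std::exp(std::min(std::max(rate - 0.3, -0.5), 0.5));
        scales[k] = std::min(std::max(scales[k] * fac, 1e-4), 10.0);
        acc[k] = 0.0;
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int k = 0; k < 4; ++k) out_alpha(keep, k) = alpha[k];
      for (int i = 0; i < n_turb; ++i) {
        out_s(keep, i) = s[i];
        out_f(keep, i) = f[i];
        out_Ntot(keep, i) = 0.0;
      }
      for (int j = 0; j < n; ++j) out_Ntot(keep, tindex[j] - 1) += N[j];
      ++keep;
    }
  }

  return List::create(_["alpha"] = out_alpha, _["s"] = out_s, _["f"] = out_f,
                      _["Ntot"] = out_Ntot);
}
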