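// Gibbs sampler for the joint accuracy + response-time model with two latent
// response states (1 = construct-driven, 2 = erratic).
//
// Accuracy:  X_ji ~ Bernoulli(logistic(theta_js - beta_is)), s = state of cell
// Log RT:    lnRT_ji ~ N(tau_j - gamma_i, sigma2_s)            (residual modes)
//            lnRT_ji ~ N(tau_js - gamma_i, sigma2)             (speed-shift mode)
// States:    lag-1 Markov chain (forward filtering / backward sampling), or a
//            per-person change point k_j with a uniform prior over 1..I
//            (items <= k_j construct-driven, items > k_j erratic; k_j = I
//            means no transition).
//
// Priors: theta, beta ~ N(0, prior_var_ability); tau, gamma ~
// N(0, prior_var_speed); residual precisions ~
// Gamma(gam_shape, gam_rate); initial-state and transition-probability rows ~
// Dirichlet(1,1). Identification: mean(beta) = 0 within state, mean(gamma) =
// 0 (recentred each sweep with the compensating shift applied to theta / tau,
// which leaves the likelihood invariant), and sigma2_1 < sigma2_2 (by label
// swapping under the Markov structure; by order-constrained precision draws
// under the change-point structure, where swapping would break the step
// pattern of the states).
//
// Logistic parameters are updated by univariate slice sampling (stepping out
// + shrinkage), which needs no tuning; all other updates are conjugate.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 35.0 ? x : log1p(exp(x));
}

// Bernoulli log-likelihood term, numerically stable in eta = theta - beta
static inline double bern_ll(int x, double eta) {
  return x * eta - softplus(eta);
}

static inline double norm_ll(double y, double mu, double s2) {
  double e = y - mu;
  return -0.5 * (log(2.0 * M_PI * s2) + e * e / s2);
}

template <class F>
static double slice_sample(double x0, F logf, double w, int m) {
  double y = logf(x0) + log(R::runif(0.0, 1.0));
  double u = R::runif(0.0, 1.0);
  double L = x0 - w * u;
  double Rr = L + w;
  int j = (int)std::floor(m * R::runif(0.0, 1.0));
  int kk = m - 1 - j;
  while (j-- > 0 && y < logf(L)) L -= w;
  while (kk-- > 0 && y < logf(Rr)) Rr += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = R::runif(L, Rr);
    if (y < logf(x1)) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// precision draw from Gamma(shape, rate) truncated to (lo, hi)
static double rgamma_trunc(double shape, double rate, double lo, double hi) {
  double scale = 1.0 / rate;
  double Flo = lo <= 0.0 ? 0.0 : R::pgamma(lo, shape, scale, 1, 0);
  double Fhi = R::pgamma(hi, shape, scale, 1, 0);
  if (Fhi - Flo < 1e-12) {
    double mid = shape / rate;
    if (mid <= lo) return lo * 1.0000001 + 1e-300;
    if (mid >= hi) return hi * 0.9999999;
    return mid;
  }
  double u = R::runif(Flo, Fhi);
  double v = R::qgamma(u, shape, scale, 1, 0);
  if (v < lo) v = lo * 1.0000001 + 1e-300;
  if (v > hi) v = hi * 0.9999999;
  return v;
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
List joint_gibbs_cpp(IntegerMatrix X, NumericMatrix lnRT,
                     int structure,        // 0 markov, 1 cp-residual, 2 cp-speed
                     bool single_state,
                     int n_burn, int n_keep, int n_warmup, bool share_beta,
                     IntegerVector k_init, bool spike_slab, double min_var_ratio,
                     double prior_var_erratic,
                     double prior_var_ability, double prior_var_speed,
                     double gam_shape, double gam_rate,
                     double slice_w, int slice_m) {
  const int J = X.nrow(), I = X.ncol();
  const bool cp = structure != 0;
  const bool speed_mode = structure == 2;
  const double S2_LO = 1e-8, S2_HI = 1e8;
  // an erratic state with no cells is re-born only well away from the
  // construct-state variance: tails of ordinary residual noise must not be
  // able to seed a barely-separated second state
  const double BIRTH_RATIO = std::max(min_var_ratio, 25.0);

  // parameters
  NumericMatrix theta(J, 2), beta(I, 2), tau(J, 2);
  NumericVector gamma_(I);
  double sigma2[2] = {0.2, 2.0};
  double mu2 = 0.0;   // hierarchical mean of erratic-state abilities
  double omega = 0.5; // P(no transition) under the spike-and-slab k prior
  double initp[2] = {0.9, 0.1};
  double P[2][2] = {{0.95, 0.05}, {0.05, 0.95}};
  IntegerMatrix xi(J, I);        // 0 = construct-driven, 1 = erratic
  IntegerVector k(J, I);         // change point (1..I); I = no transition

  // initialize tau at person mean lnRT
  for (int j = 0; j < J; ++j) {
    double s = 0; int n = 0;
    for (int i = 0; i < I; ++i)
      if (!ISNAN(lnRT(j, i))) { s += lnRT(j, i); ++n; }
    double m = n ? s / n : 0.0;
    tau(j, 0) = m; tau(j, 1) = m;
  }

  // storage
  NumericMatrix sigma2_d(n_keep, 2), gamma_d(n_keep, I);
  NumericMatrix theta1_d(n_keep, J), theta2_d(n_keep, J);
  NumericMatrix beta1_d(n_keep, I), beta2_d(n_keep, I);
  NumericMatrix tau_d(n_keep, J), tau2_d(speed_mode ? n_keep : 1, speed_mode ? J : 1);
  NumericMatrix initp_d(cp ? 1 : n_keep, cp ? 1 : 2);
  NumericMatrix trans_d(cp ? 1 : n_keep, cp ? 1 : 4);
  IntegerMatrix k_d(cp ? n_keep : 1, cp ? J : 1);
  NumericMatrix occupancy_d(n_keep, I);
  NumericMatrix state_prob(J, I);
  NumericVector deviance_d(n_keep);

  std::vector<double> ll0(I), ll1(I), fwd0(I), fwd1(I);

  const double lga = gam_shape;  // prior shape/rate shorthand for marginals
  const double lgb = gam_rate;
  // log marginal likelihood of N erratic-state residual cells with summed
  // squares S, the erratic precision integrated against its gamma prior
  // *truncated below the current construct-state precision* (the
  // identification constraint sigma2_1 < sigma2_2). The truncation is what
  // keeps a handful of low-variance cells from faking an ultra-precise
  // second state under the vague prior.
  auto lmarg2 = [&](double N, double S, double lam1) {
    double sh = lga + N / 2.0, rt = lgb + S / 2.0;
    return R::lgammafn(sh) - sh * log(rt) + R::pgamma(lam1, sh, 1.0 / rt, 1, 1);
  };

  // log prior mass of a change point at k (1..I); k = I means no transition
  auto k_logprior = [&](int kk) {
    if (!spike_slab) return 0.0;                       // uniform prior
    double slab = (1.0 - omega) / I;
    return kk == I ? log(omega + slab) : log(slab);
  };

  const int n_total = n_burn + n_keep;
  std::vector<double> pa0(I + 1), pa1(I + 1), pe(I + 1), pc(I + 1), E2(I);
  for (int sweep = 0; sweep < n_total; ++sweep) {
    // ---- 1. sample states given everything else ----------------------------
    // at warm-up release, change points start from the supplied
    // initialization (a per-person variance change-point scan) so the first
    // collapsed sweep sees a well-separated erratic state
    if (cp && !single_state && sweep == n_warmup)
      for (int j = 0; j < J; ++j) {
        k[j] = k_init[j];
        for (int i = 0; i < I; ++i) xi(j, i) = (i + 1 <= k[j]) ? 0 : 1;
      }
    const bool collapsed_cp = (structure == 1) && !single_state && sweep >= n_warmup;
    if (collapsed_cp) {
      // change points with the residual variances integrated out: the
      // per-person conditional update of k_j given a point value of sigma2
      // mixes poorly (a sigma2_2 just above sigma2_1 makes k moves nearly
      // free and the two states drift into splitting the population), so
      // k_j is sampled from its normal-gamma marginal given all other
      // persons' assignments, and sigma2 is redrawn right afterwards.
      double N2 = 0, S2 = 0;
      NumericMatrix E2m(J, I);
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < I; ++i)
          if (!ISNAN(lnRT(j, i))) {
            double e = lnRT(j, i) - (tau(j, 0) - gamma_[i]);
            E2m(j, i) = e * e;
            if (i + 1 > k[j]) { N2 += 1; S2 += E2m(j, i); }
          } else E2m(j, i) = NA_REAL;
      for (int j = 0; j < J; ++j) {
        pa0[0] = pa1[0] = pe[0] = pc[0] = 0.0;
        for (int i = 0; i < I; ++i) {
          double a0 = 0, a1 = 0;
          int x = X(j, i);
          if (x >= 0) {
            a0 = bern_ll(x, theta(j, 0) - beta(i, 0));
            a1 = bern_ll(x, theta(j, 1) - beta(i, share_beta ? 0 : 1));
          }
          pa0[i + 1] = pa0[i] + a0;
          pa1[i + 1] = pa1[i] + a1;
          bool o = !ISNAN(lnRT(j, i));
          pe[i + 1] = pe[i] + (o ? E2m(j, i) : 0.0);
          pc[i + 1] = pc[i] + (o ? 1.0 : 0.0);
        }
        // remove person j's current contribution from the erratic state
        double N2r = N2 - (pc[I] - pc[k[j]]), S2r = S2 - (pe[I] - pe[k[j]]);
        double lam1 = 1.0 / (sigma2[0] * min_var_ratio);
        double mx = -INFINITY;
        std::vector<double> lw(I);
        for (int kk2 = 1; kk2 <= I; ++kk2) {
          // construct-state cells conditioned on the current sigma2_1;
          // erratic-state cells under the truncated normal-gamma marginal
          lw[kk2 - 1] = k_logprior(kk2) + pa0[kk2] + (pa1[I] - pa1[kk2]) -
            0.5 * (pc[kk2] * log(sigma2[0]) + pe[kk2] / sigma2[0]) +
            lmarg2(N2r + (pc[I] - pc[kk2]), S2r + (pe[I] - pe[kk2]), lam1);
          if (lw[kk2 - 1] > mx) mx = lw[kk2 - 1];
        }
        double tot = 0;
        for (int i = 0; i < I; ++i) { lw[i] = exp(lw[i] - mx); tot += lw[i]; }
        double u = R::runif(0, tot), acc = 0;
        int kj = I;
        for (int i = 0; i < I; ++i) {
          acc += lw[i];
          if (u <= acc) { kj = i + 1; break; }
        }
        k[j] = kj;
        N2 = N2r + (pc[I] - pc[kj]); S2 = S2r + (pe[I] - pe[kj]);
        for (int i = 0; i < I; ++i) xi(j, i) = (i + 1 <= kj) ? 0 : 1;
      }
    } else
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < I; ++i) {
        double a0 = 0, a1 = 0, r0 = 0, r1 = 0;
        int x = X(j, i);
        if (x >= 0) {
          a0 = bern_ll(x, theta(j, 0) - beta(i, 0));
          a1 = bern_ll(x, theta(j, 1) - beta(i, share_beta ? 0 : 1));
        }
        if (!ISNAN(lnRT(j, i))) {
          if (speed_mode) {
            r0 = norm_ll(lnRT(j, i), tau(j, 0) - gamma_[i], sigma2[0]);
            r1 = norm_ll(lnRT(j, i), tau(j, 1) - gamma_[i], sigma2[0]);
          } else {
            r0 = norm_ll(lnRT(j, i), tau(j, 0) - gamma_[i], sigma2[0]);
            r1 = norm_ll(lnRT(j, i), tau(j, 0) - gamma_[i], sigma2[1]);
          }
        }
        ll0[i] = a0 + r0;
        ll1[i] = a1 + r1;
      }
      if (single_state || sweep < n_warmup) {
        // warm-up: fit the construct-driven structure before releasing states
        for (int i = 0; i < I; ++i) xi(j, i) = 0;
        k[j] = I;
      } else if (!cp) {
        // forward filtering
        double m0 = std::max(ll0[0], ll1[0]);
        fwd0[0] = initp[0] * exp(ll0[0] - m0);
        fwd1[0] = initp[1] * exp(ll1[0] - m0);
        double z = fwd0[0] + fwd1[0];
        fwd0[0] /= z; fwd1[0] /= z;
        for (int i = 1; i < I; ++i) {
          double p0 = fwd0[i - 1] * P[0][0] + fwd1[i - 1] * P[1][0];
          double p1 = fwd0[i - 1] * P[0][1] + fwd1[i - 1] * P[1][1];
          double mm = std::max(ll0[i], ll1[i]);
          fwd0[i] = p0 * exp(ll0[i] - mm);
          fwd1[i] = p1 * exp(ll1[i] - mm);
          z = fwd0[i] + fwd1[i];
          if (z <= 0) { fwd0[i] = fwd1[i] = 0.5; z = 1.0; }
          fwd0[i] /= z; fwd1[i] /= z;
        }
        // backward sampling
        xi(j, I - 1) = (R::runif(0, 1) < fwd1[I - 1]) ? 1 : 0;
        for (int i = I - 2; i >= 0; --i) {
          int nxt = xi(j, i + 1);
          double w0 = fwd0[i] * P[0][nxt];
          double w1 = fwd1[i] * P[1][nxt];
          double zz = w0 + w1;
          xi(j, i) = (zz <= 0) ? 0 : ((R::runif(0, 1) < w1 / zz) ? 1 : 0);
        }
      } else {
        // change point: enumerate the discrete full conditional of k_j
        // loglik(k) = sum_{i<=k} ll0 + sum_{i>k} ll1 (1-based k)
        double c0 = 0, tot1 = 0;
        for (int i = 0; i < I; ++i) tot1 += ll1[i];
        double mx = -INFINITY;
        std::vector<double> lw(I);
        double c1 = 0;
        for (int kk2 = 1; kk2 <= I; ++kk2) {
          c0 += ll0[kk2 - 1];
          c1 += ll1[kk2 - 1];
          lw[kk2 - 1] = k_logprior(kk2) + c0 + (tot1 - c1);
          if (lw[kk2 - 1] > mx) mx = lw[kk2 - 1];
        }
        double tot = 0;
        for (int i = 0; i < I; ++i) { lw[i] = exp(lw[i] - mx); tot += lw[i]; }
        double u = R::runif(0, tot), acc = 0;
        int kj = I;
        for (int i = 0; i < I; ++i) {
          acc += lw[i];
          if (u <= acc) { kj = i + 1; break; }
        }
        k[j] = kj;
        for (int i = 0; i < I; ++i) xi(j, i) = (i + 1 <= kj) ? 0 : 1;
      }
    }

    // spike-and-slab weight: persons at k = I are attributed to the spike
    // with probability omega / (omega + (1-omega)/I), then omega ~ Beta
    if (cp && spike_slab && !single_state && sweep >= n_warmup) {
      int n_spike = 0;
      double p_spike = omega / (omega + (1.0 - omega) / I);
      for (int j = 0; j < J; ++j)
        if (k[j] == I && R::runif(0, 1) < p_spike) ++n_spike;
      omega = R::rbeta(1.0 + n_spike, 1.0 + (J - n_spike));
    }

    // ---- 2. residual variances (immediately after the state update, so the
    //         collapsed change-point step below stays a valid partially
    //         collapsed Gibbs scheme) ----------------------------------------
    double sse[2] = {0, 0};
    double nn[2] = {0, 0};
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i)
        if (!ISNAN(lnRT(j, i))) {
          int s = xi(j, i);
          double mu = speed_mode ? tau(j, s) - gamma_[i] : tau(j, 0) - gamma_[i];
          double e = lnRT(j, i) - mu;
          int slot = speed_mode ? 0 : s;
          sse[slot] += e * e;
          nn[slot] += 1.0;
        }
    if (speed_mode) {
      double lam = R::rgamma(gam_shape + nn[0] / 2.0, 1.0 / (gam_rate + sse[0] / 2.0));
      sigma2[0] = clamp(1.0 / lam, S2_LO, S2_HI);
      sigma2[1] = sigma2[0];
    } else if (!cp) {
      {
        double lam0 = (nn[0] > 0)
          ? rgamma_trunc(gam_shape + nn[0] / 2.0, gam_rate + sse[0] / 2.0,
                         min_var_ratio / sigma2[1], 1.0 / S2_LO)
          : rgamma_trunc(gam_shape, gam_rate, min_var_ratio / sigma2[1], 1.0 / S2_LO);
        sigma2[0] = clamp(1.0 / lam0, S2_LO, S2_HI);
        double lam1 = (nn[1] > 0)
          ? rgamma_trunc(gam_shape + nn[1] / 2.0, gam_rate + sse[1] / 2.0,
                         1.0 / S2_HI, 1.0 / (sigma2[0] * min_var_ratio))
          : rgamma_trunc(gam_shape, gam_rate, 1.0 / S2_HI, 1.0 / (sigma2[0] * BIRTH_RATIO));
        sigma2[1] = clamp(1.0 / lam1, S2_LO, S2_HI);
      }
      if (!single_state && sweep >= n_warmup && sigma2[0] > sigma2[1]) {
        // relabel: state 1 must be the low-variance (construct-driven) state
        std::swap(sigma2[0], sigma2[1]);
        for (int j = 0; j < J; ++j) {
          std::swap(theta(j, 0), theta(j, 1));
          for (int i = 0; i < I; ++i) xi(j, i) = 1 - xi(j, i);
        }
        for (int i = 0; i < I; ++i) std::swap(beta(i, 0), beta(i, 1));
        { double m2 = 0; for (int j = 0; j < J; ++j) m2 += theta(j, 1);
          mu2 = m2 / J; }
        std::swap(initp[0], initp[1]);
        double Pn[2][2];
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b) Pn[a][b] = P[1 - a][1 - b];
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b) P[a][b] = Pn[a][b];
      }
    } else {
      // cp-residual: order-constrained draws (swapping would break Eq-13 step)
      double lam0 = (nn[0] > 0)
        ? rgamma_trunc(gam_shape + nn[0] / 2.0, gam_rate + sse[0] / 2.0,
                       min_var_ratio / sigma2[1], 1.0 / S2_LO)
        : rgamma_trunc(gam_shape, gam_rate, min_var_ratio / sigma2[1], 1.0 / S2_LO);
      sigma2[0] = clamp(1.0 / lam0, S2_LO, S2_HI);
      double lam1 = (nn[1] > 0)
        ? rgamma_trunc(gam_shape + nn[1] / 2.0, gam_rate + sse[1] / 2.0,
                       1.0 / S2_HI, 1.0 / (sigma2[0] * min_var_ratio))
        : rgamma_trunc(gam_shape, gam_rate, 1.0 / S2_HI, 1.0 / (sigma2[0] * BIRTH_RATIO));
      sigma2[1] = clamp(1.0 / lam1, S2_LO, S2_HI);
    }


    // ---- 3. initial-state and transition probabilities (Markov only) -------
    if (!cp && !single_state && sweep >= n_warmup) {
      int n1 = 0;
      for (int j = 0; j < J; ++j) if (xi(j, 0) == 0) ++n1;
      initp[0] = R::rbeta(1.0 + n1, 1.0 + (J - n1));
      initp[1] = 1.0 - initp[0];
      double cnt[2][2] = {{0, 0}, {0, 0}};
      for (int j = 0; j < J; ++j)
        for (int i = 1; i < I; ++i) cnt[xi(j, i - 1)][xi(j, i)] += 1.0;
      for (int s = 0; s < 2; ++s) {
        double g0 = R::rgamma(1.0 + cnt[s][0], 1.0);
        double g1 = R::rgamma(1.0 + cnt[s][1], 1.0);
        P[s][0] = g0 / (g0 + g1);
        P[s][1] = 1.0 - P[s][0];
      }
    }

    // ---- 4. ability and difficulty parameters (slice sampling) -------------
    for (int j = 0; j < J; ++j) {
      for (int s = 0; s < 2; ++s) {
        // state-1 abilities have a N(0, prior_var_ability) prior; state-2
        // (erratic) abilities are hierarchically centered, theta_j2 ~
        // N(mu2, prior_var_erratic), so a single free level describes the
        // erratic success rate and per-person erratic abilities cannot
        // overfit chance runs of incorrect answers
        double pm = (s == 1) ? mu2 : 0.0;
        double pv = (s == 1) ? prior_var_erratic : prior_var_ability;
        bool any = false;
        for (int i = 0; i < I && !any; ++i)
          if (xi(j, i) == s && X(j, i) >= 0) any = true;
        if (!any) { theta(j, s) = R::rnorm(pm, sqrt(pv)); continue; }
        int bcol = (share_beta && s == 1) ? 0 : s;
        auto logf = [&](double th) {
          double v = -(th - pm) * (th - pm) / (2.0 * pv);
          for (int i = 0; i < I; ++i)
            if (xi(j, i) == s && X(j, i) >= 0)
              v += bern_ll(X(j, i), th - beta(i, bcol));
          return v;
        };
        theta(j, s) = slice_sample(theta(j, s), logf, slice_w, slice_m);
      }
    }
    {   // conjugate update of the erratic-ability level mu2 ~ N(0, pv_ability)
      double prec = 1.0 / prior_var_ability + J / prior_var_erratic;
      double num = 0;
      for (int j = 0; j < J; ++j) num += theta(j, 1);
      num /= prior_var_erratic;
      mu2 = R::rnorm(num / prec, sqrt(1.0 / prec));
    }
    for (int s = 0; s < (share_beta ? 1 : 2); ++s) {
      for (int i = 0; i < I; ++i) {
        bool any = false;
        for (int j = 0; j < J && !any; ++j)
          if ((share_beta || xi(j, i) == s) && X(j, i) >= 0) any = true;
        if (!any) { beta(i, s) = R::rnorm(0.0, sqrt(prior_var_ability)); continue; }
        auto logf = [&](double b) {
          double v = -b * b / (2.0 * prior_var_ability);
          for (int j = 0; j < J; ++j) {
            if (X(j, i) < 0) continue;
            if (share_beta)
              v += bern_ll(X(j, i), theta(j, xi(j, i)) - b);
            else if (xi(j, i) == s)
              v += bern_ll(X(j, i), theta(j, s) - b);
          }
          return v;
        };
        beta(i, s) = slice_sample(beta(i, s), logf, slice_w, slice_m);
      }
      // identification: mean(beta_s) = 0, compensating shift on theta_s
      double m = 0;
      for (int i = 0; i < I; ++i) m += beta(i, s);
      m /= I;
      for (int i = 0; i < I; ++i) beta(i, s) -= m;
      for (int j = 0; j < J; ++j) theta(j, s) -= m;
      if (s == 1) mu2 -= m;
      if (share_beta) {
        for (int i = 0; i < I; ++i) beta(i, 1) = beta(i, 0);
        for (int j = 0; j < J; ++j) theta(j, 1) -= m;
        mu2 -= m;
      }
    }

    // ---- 5. speed parameters (conjugate normal) -----------------------------
    if (!speed_mode) {
      for (int j = 0; j < J; ++j) {
        double prec = 1.0 / prior_var_speed, num = 0;
        for (int i = 0; i < I; ++i)
          if (!ISNAN(lnRT(j, i))) {
            double s2 = sigma2[xi(j, i)];
            prec += 1.0 / s2;
            num += (lnRT(j, i) + gamma_[i]) / s2;
          }
        tau(j, 0) = R::rnorm(num / prec, sqrt(1.0 / prec));
        tau(j, 1) = tau(j, 0);
      }
    } else {
      for (int j = 0; j < J; ++j)
        for (int s = 0; s < 2; ++s) {
          double prec = 1.0 / prior_var_speed, num = 0;
          bool any = false;
          for (int i = 0; i < I; ++i)
            if (xi(j, i) == s && !ISNAN(lnRT(j, i))) {
              any = true;
              prec += 1.0 / sigma2[0];
              num += (lnRT(j, i) + gamma_[i]) / sigma2[0];
            }
          tau(j, s) = any ? R::rnorm(num / prec, sqrt(1.0 / prec))
                          : R::rnorm(0.0, sqrt(prior_var_speed));
        }
    }

    // ---- 6. time intensities (conjugate normal), centered -------------------
    for (int i = 0; i < I; ++i) {
      double prec = 1.0 / prior_var_speed, num = 0;
      for (int j = 0; j < J; ++j)
        if (!ISNAN(lnRT(j, i))) {
          double s2 = speed_mode ? sigma2[0] : sigma2[xi(j, i)];
          double tj = speed_mode ? tau(j, xi(j, i)) : tau(j, 0);
          prec += 1.0 / s2;
          num += (tj - lnRT(j, i)) / s2;
        }
      gamma_[i] = R::rnorm(num / prec, sqrt(1.0 / prec));
    }
    {
      double m = 0;
      for (int i = 0; i < I; ++i) m += gamma_[i];
      m /= I;
      for (int i = 0; i < I; ++i) gamma_[i] -= m;
      for (int j = 0; j < J; ++j) { tau(j, 0) -= m; tau(j, 1) -= m; }
    }

    // ---- 7. store -----------------------------------------------------------
    if (sweep >= n_burn) {
      int d = sweep - n_burn;
      double dev = 0;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < I; ++i) {
          int s = xi(j, i);
          if (X(j, i) >= 0)
            dev += bern_ll(X(j, i), theta(j, s) - beta(i, share_beta ? 0 : s));
          if (!ISNAN(lnRT(j, i))) {
            double mu = speed_mode ? tau(j, s) - gamma_[i] : tau(j, 0) - gamma_[i];
            double s2 = speed_mode ? sigma2[0] : sigma2[s];
            dev += norm_ll(lnRT(j, i), mu, s2);
          }
        }
      deviance_d[d] = -2.0 * dev;
      sigma2_d(d, 0) = sigma2[0];
      sigma2_d(d, 1) = sigma2[1];
      for (int i = 0; i < I; ++i) {
        gamma_d(d, i) = gamma_[i];
        beta1_d(d, i) = beta(i, 0);
        beta2_d(d, i) = beta(i, 1);
      }
      for (int j = 0; j < J; ++j) {
        theta1_d(d, j) = theta(j, 0);
        theta2_d(d, j) = theta(j, 1);
        tau_d(d, j) = tau(j, 0);
        if (speed_mode) tau2_d(d, j) = tau(j, 1);
      }
      if (!cp) {
        initp_d(d, 0) = initp[0]; initp_d(d, 1) = initp[1];
        trans_d(d, 0) = P[0][0]; trans_d(d, 1) = P[0][1];
        trans_d(d, 2) = P[1][0]; trans_d(d, 3) = P[1][1];
      } else {
        for (int j = 0; j < J; ++j) k_d(d, j) = k[j];
      }
      for (int i = 0; i < I; ++i) {
        double occ = 0;
        for (int j = 0; j < J; ++j) occ += xi(j, i);
        occupancy_d(d, i) = occ / J;
      }
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < I; ++i)
          state_prob(j, i) += xi(j, i);
    }
  }
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) state_prob(j, i) /= n_keep;

  List out = List::create(
    _["sigma2"] = sigma2_d, _["gamma"] = gamma_d,
    _["theta1"] = theta1_d, _["theta2"] = theta2_d,
    _["beta1"] = beta1_d, _["beta2"] = beta2_d,
    _["tau"] = tau_d, _["occupancy"] = occupancy_d,
    _["state_prob"] = state_prob, _["deviance"] = deviance_d);
  if (speed_mode) out["tau2"] = tau2_d;
  if (!cp) {
    out["initp"] = initp_d;
    out["trans"] = trans_d;
  } else {
    out["k"] = k_d;
  }
  return out;
}
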