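// Adaptive Metropolis-within-Gibbs sampler for the beta-likelihood BYM model:
//   y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi),
//   logit(mu_i) = beta0 + x_i' beta + w_i + v_i,
//   w ~ ICAR(sigma_w2) (per-component sum-to-zero), v_i ~ N(0, sigma_v2).
//
// Updates per iteration:
//   - scalar random walks for beta0 and each beta_j (on centred covariates:
//     the caller passes X with column means removed and the intercept as
//     beta0c = beta0 + xbar' beta; draws are mapped back on the R side);
//   - for connected graphs, a joint "shift" move beta_j += d,
//     w -= d * xc_j that leaves the likelihood invariant and breaks the
//     beta/ICAR-field confounding;
//   - single-site random walks for w_i and v_i on alternating sweeps, with
//     w re-centred to the constraint after every w sweep (the component
//     mean is absorbed into the intercept);
//   - exact conjugate Gibbs draws for sigma_w2 and sigma_v2 (Gamma
//     posteriors on the precisions);
//   - scalar random walk for log phi.
// Proposal scales adapt by Robbins-Monro up to adapt_until only.
// Uses R's RNG throughout, so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// per-area log likelihood; -Inf when mu saturates in double precision
static inline double area_ll(double y, double eta, double phi) {
  double mu = invlogit(eta);
  double a = mu * phi, b = (1.0 - mu) * phi;
  if (!(a > 0.0) || !(b > 0.0)) return R_NegInf;
  return R::dbeta(y, a, b, 1);
}

struct AdaptScale {
  double ls;
  double attempts;
  AdaptScale(double s = 1.0) : ls(std::log(s)), attempts(0.0) {}
  double sd() const { return std::exp(ls); }
  void adapt(double alpha, double target, bool adapting) {
    attempts += 1.0;
    if (!adapting) return;
    ls += (alpha - target) / std::pow(attempts, 0.7);
    if (ls < -12.0) ls = -12.0;
    if (ls > 5.0) ls = 5.0;
  }
};

// [[Rcpp::export(name = ".bym_chain")]]
List bym_chain(NumericVector y, NumericMatrix X, List nb_list,
               IntegerMatrix edges, IntegerVector comp, LogicalVector mask,
               double beta0, NumericVector beta_init, NumericVector w_init,
               NumericVector v_init, double sw2, double sv2, double phi,
               double beta_sd, double beta0_sd,
               double prec_a, double prec_b, double phi_a, double phi_b,
               int n_iter, int burnin, int thin, int adapt_until,
               double target_accept,
               bool include_v, bool sample_sw2, bool sample_sv2,
               bool sample_phi, bool use_lik) {
  const int n = y.size();
  const int k = X.ncol();
  const int n_edges = edges.nrow();

  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector vv = nb_list[i];
    nb[i].assign(vv.begin(), vv.end());
  }
  int n_comp = 0;
  for (int i = 0; i < n; ++i) if (comp[i] + 1 > n_comp) n_comp = comp[i] + 1;
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < n; ++i) comp_size[comp[i]]++;
  const bool has_edges = n_edges > 0;
  const bool connected = n_comp == 1;
  const double n_eff = (double)(n - n_comp);  // ICAR rank

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> v(v_init.begin(), v_init.end());
  double th_phi = std::log(phi);

  std::vector<double> eta(n), ll(n);
  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = beta0 + w[i] + v[i];
      for (int j = 0; j < k; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
    }
  };
  auto ll_one = [&](int i, double eta_i) -> double {
    if (!use_lik || !mask[i]) return 0.0;
    return area_ll(y[i], eta_i, phi);
  };
  auto recompute_ll = [&]() {
    for (int i = 0; i < n; ++i) ll[i] = ll_one(i, eta[i]);
  };
  recompute_eta();
  recompute_ll();

  auto ssw = [&]() -> double {
    double s = 0.0;
    for (int r = 0; r < n_edges; ++r) {
      double d = w[edges(r, 0)] - w[edges(r, 1)];
      s += d * d;
    }
    return s;
  };
  // N(0, beta0_sd) log prior on the intercept (0 when flat)
  auto lp_beta0 = [&](double b) -> double {
    if (!R_finite(beta0_sd)) return 0.0;
    return -b * b / (2.0 * beta0_sd * beta0_sd);
  };

  AdaptScale s_beta0(0.1);
  std::vector<AdaptScale> s_beta(k), s_shift(k);
  for (int j = 0; j < k; ++j) {
    double mx = 0.0, sdx = 0.0;
    for (int i = 0; i < n; ++i) mx += X(i, j);
    mx /= n;
    for (int i = 0; i < n; ++i) sdx += (X(i, j) - mx) * (X(i, j) - mx);
    sdx = std::sqrt(sdx / std::max(1, n - 1));
    double s0 = sdx > 1e-12 ? 0.1 / sdx : 0.1;
    s_beta[j] = AdaptScale(s0);
    s_shift[j] = AdaptScale(s0);
  }
  std::vector<AdaptScale> s_w(n, AdaptScale(0.3)), s_v(n, AdaptScale(0.3));
  AdaptScale s_thphi(0.3), s_scale_w(0.2), s_scale_v(0.2);

  double acc_beta0 = 0, att_beta0 = 0, acc_beta = 0, att_beta = 0;
  double acc_shift = 0, att_shift = 0;
  double acc_w = 0, att_w = 0, acc_v = 0, att_v = 0;
  double acc_phi = 0, att_phi = 0, acc_scale = 0, att_scale = 0;

  const int n_keep = (n_iter - burnin) / thin;
  const int ncol_out = 1 + k + n + n + 3 + n;
  NumericMatrix out(n_keep, ncol_out);
  int row = 0;

  std::vector<double> eta_new(n), ll_new(n);

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= adapt_until;

    // ---- beta0 (random walk over the full likelihood) ----
    {
      double d = R::rnorm(0.0, s_beta0.sd());
      double delta = lp_beta0(beta0 + d) - lp_beta0(beta0);
      for (int i = 0; i < n; ++i) {
        ll_new[i] = ll_one(i, eta[i] + d);
        delta += ll_new[i] - ll[i];
      }
      double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      att_beta0 += 1;
      if (R::runif(0.0, 1.0) < alpha) {
        beta0 += d;
        for (int i = 0; i < n; ++i) { eta[i] += d; ll[i] = ll_new[i]; }
        acc_beta0 += 1;
      }
      s_beta0.adapt(alpha, target_accept, adapting);
    }

    // ---- beta_j random walks ----
    for (int j = 0; j < k; ++j) {
      double d = R::rnorm(0.0, s_beta[j].sd());
      double b1 = beta[j] + d;
      double delta = (-b1 * b1 + beta[j] * beta[j]) /
                     (2.0 * beta_sd * beta_sd);
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + d * X(i, j);
        ll_new[i] = ll_one(i, eta_new[i]);
        delta += ll_new[i] - ll[i];
      }
      double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      att_beta += 1;
      if (R::runif(0.0, 1.0) < alpha) {
        beta[j] = b1;
        for (int i = 0; i < n; ++i) { eta[i] = eta_new[i]; ll[i] = ll_new[i]; }
        acc_beta += 1;
      }
      s_beta[j].adapt(alpha, target_accept, adapting);
    }

    // ---- joint beta_j / w shift (likelihood-invariant; connected graphs,
    //      centred covariates: sum_i xc_ij = 0 keeps w in the constraint) ----
    if (connected && has_edges) {
      for (int j = 0; j < k; ++j) {
        double d = R::rnorm(0.0, s_shift[j].sd());
        double b1 = beta[j] + d;
        double delta = (-b1 * b1 + beta[j] * beta[j]) /
                       (2.0 * beta_sd * beta_sd);
        // ICAR kernel difference for w' = w - d * xc_j
        double dss = 0.0;
        for (int r = 0; r < n_edges; ++r) {
          int a = edges(r, 0), b = edges(r, 1);
          double wd = w[a] - w[b], xd = X(a, j) - X(b, j);
          double nd = wd - d * xd;
          dss += nd * nd - wd * wd;
        }
        delta -= dss / (2.0 * sw2);
        double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
        att_shift += 1;
        if (R::runif(0.0, 1.0) < alpha) {
          beta[j] = b1;
          for (int i = 0; i < n; ++i) w[i] -= d * X(i, j);
          acc_shift += 1;
        }
        s_shift[j].adapt(alpha, target_accept, adapting);
      }
    }

    // ---- w and v single-site updates, alternating sweeps ----
    bool do_w = has_edges && (!include_v || (it % 2 == 1));
    bool do_v = include_v && (!has_edges || (it % 2 == 0));
    if (do_w) {
      for (int i = 0; i < n; ++i) {
        if (nb[i].empty()) continue;  // isolated: w_i pinned at 0
        double d = R::rnorm(0.0, s_w[i].sd());
        double wi1 = w[i] + d;
        double dprior = 0.0;
        for (size_t t = 0; t < nb[i].size(); ++t) {
          double wj = w[nb[i][t]];
          dprior += (wi1 - wj) * (wi1 - wj) - (w[i] - wj) * (w[i] - wj);
        }
        double lli1 = ll_one(i, eta[i] + d);
        double delta = lli1 - ll[i] - dprior / (2.0 * sw2);
        double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
        att_w += 1;
        if (R::runif(0.0, 1.0) < alpha) {
          w[i] = wi1; eta[i] += d; ll[i] = lli1; acc_w += 1;
        }
        s_w[i].adapt(alpha, target_accept, adapting);
      }
      // re-centre each component, absorbing the mean into the intercept
      // (exact for a connected graph: eta is unchanged)
      std::vector<double> m(n_comp, 0.0);
      for (int i = 0; i < n; ++i) m[comp[i]] += w[i];
      double mbar = 0.0;
      for (int cidx = 0; cidx < n_comp; ++cidx) {
        m[cidx] /= comp_size[cidx];
        mbar += m[cidx] * comp_size[cidx];
      }
      mbar /= n;
      for (int i = 0; i < n; ++i) w[i] -= m[comp[i]];
      beta0 += mbar;
      recompute_eta();
      recompute_ll();
    }
    if (do_v) {
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, s_v[i].sd());
        double vi1 = v[i] + d;
        double lli1 = ll_one(i, eta[i] + d);
        double delta = lli1 - ll[i] +
                       (-vi1 * vi1 + v[i] * v[i]) / (2.0 * sv2);
        double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
        att_v += 1;
        if (R::runif(0.0, 1.0) < alpha) {
          v[i] = vi1; eta[i] += d; ll[i] = lli1; acc_v += 1;
        }
        s_v[i].adapt(alpha, target_accept, adapting);
      }
    }

    // ---- joint scale moves: (w, sigma_w2) -> (c w, c^2 sigma_w2) and
    //      (v, sigma_v2) -> (c v, c^2 sigma_v2). The Gaussian kernels are
    //      invariant, so only the likelihood, the variance prior and the
    //      Jacobian (+2 eps) enter; lets the field scale jump between
    //      regimes the single-site updates traverse slowly. ----
    if (has_edges && sample_sw2) {
      double eps = R::rnorm(0.0, s_scale_w.sd());
      double c = std::exp(eps);
      double sw2p = c * c * sw2;
      double delta = 2.0 * eps
        - (prec_a + 1.0) * 2.0 * eps - prec_b * (1.0 / sw2p - 1.0 / sw2);
      for (int i = 0; i < n; ++i) {
        ll_new[i] = ll_one(i, eta[i] + (c - 1.0) * w[i]);
        delta += ll_new[i] - ll[i];
      }
      double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      att_scale += 1;
      if (R::runif(0.0, 1.0) < alpha) {
        for (int i = 0; i < n; ++i) {
          eta[i] += (c - 1.0) * w[i];
          w[i] *= c;
          ll[i] = ll_new[i];
        }
        sw2 = sw2p;
        acc_scale += 1;
      }
      s_scale_w.adapt(alpha, target_accept, adapting);
    }
    if (include_v && sample_sv2) {
      double eps = R::rnorm(0.0, s_scale_v.sd());
      double c = std::exp(eps);
      double sv2p = c * c * sv2;
      double delta = 2.0 * eps
        - (prec_a + 1.0) * 2.0 * eps - prec_b * (1.0 / sv2p - 1.0 / sv2);
      for (int i = 0; i < n; ++i) {
        ll_new[i] = ll_one(i, eta[i] + (c - 1.0) * v[i]);
        delta += ll_new[i] - ll[i];
      }
      double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      if (R::runif(0.0, 1.0) < alpha) {
        for (int i = 0; i < n; ++i) {
          eta[i] += (c - 1.0) * v[i];
          v[i] *= c;
          ll[i] = ll_new[i];
        }
        sv2 = sv2p;
      }
      s_scale_v.adapt(alpha, target_accept, adapting);
    }

    // ---- variance Gibbs draws (conjugate Gamma on the precisions) ----
    if (has_edges && sample_sw2) {
      double tau = R::rgamma(prec_a + 0.5 * n_eff,
                             1.0 / (prec_b + 0.5 * ssw()));
      if (tau > 0 && R_finite(tau)) sw2 = 1.0 / tau;
    }
    if (include_v && sample_sv2) {
      double ssv = 0.0;
      for (int i = 0; i < n; ++i) ssv += v[i] * v[i];
      double tau = R::rgamma(prec_a + 0.5 * n,
                             1.0 / (prec_b + 0.5 * ssv));
      if (tau > 0 && R_finite(tau)) sv2 = 1.0 / tau;
    }

    // ---- log phi random walk ----
    if (sample_phi) {
      double d = R::rnorm(0.0, s_thphi.sd());
      double th1 = th_phi + d;
      double phi1 = std::exp(th1);
      double delta = 0.0;
      if (use_lik) {
        for (int i = 0; i < n; ++i) {
          if (!mask[i]) { ll_new[i] = 0.0; continue; }
          ll_new[i] = area_ll(y[i], eta[i], phi1);
          delta += ll_new[i] - ll[i];
        }
      } else {
        for (int i = 0; i < n; ++i) ll_new[i] = 0.0;
      }
      // Gamma(a, b) prior on phi, sampled on the log scale (Jacobian e^th)
      delta += phi_a * (th1 - th_phi) - phi_b * (phi1 - phi);
      double alpha = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      att_phi += 1;
      if (R::runif(0.0, 1.0) < alpha) {
        th_phi = th1; phi = phi1;
        for (int i = 0; i < n; ++i) ll[i] = ll_new[i];
        acc_phi += 1;
      }
      s_thphi.adapt(alpha, target_accept, adapting);
    }

    // ---- store ----
    if (it > burnin && (it - burnin) % thin == 0) {
      int c0 = 0;
      out(row, c0++) = beta0;
      for (int j = 0; j < k; ++j) out(row, c0++) = beta[j];
      for (int i = 0; i < n; ++i) out(row, c0++) = w[i];
      for (int i = 0; i < n; ++i) out(row, c0++) = v[i];
      out(row, c0++) = sw2;
      out(row, c0++) = sv2;
      out(row, c0++) = phi;
      for (int i = 0; i < n; ++i) out(row, c0++) = invlogit(eta[i]);
      ++row;
    }
  }

  auto rate = [](double a, double b) { return b > 0 ? a / b : NA_REAL; };
  return List::create(
    _["draws"] = out,
    _["acceptance"] = List::create(
      _["beta0"] = rate(acc_beta0, att_beta0),
      _["beta"] = rate(acc_beta, att_beta),
      _["beta_w_shift"] = rate(acc_shift, att_shift),
      _["w"] = rate(acc_w, att_w),
      _["v"] = rate(acc_v, att_v),
      _["w_scale"] = rate(acc_scale, att_scale),
      _["log_phi"] = rate(acc_phi, att_phi)));
}
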