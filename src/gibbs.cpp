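#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for multi-block Gaussian linear models with
// Bayesian ridge (BRR), Bayes B and Bayes C priors on the regressor blocks.
// Fixed-effect columns get flat priors. Variances follow scaled-inverse
// chi-square full conditionals; inclusion indicators (Bayes B/C) follow the
// Bernoulli conditional obtained by integrating the effect out; the
// inclusion probability gets a Beta full conditional when estimated.
// Uses R's RNG so seeded chains are bit-reproducible from set.seed().

static inline double rinvchisq(double df, double num) {
  // draw sigma^2 with nu*S = num, nu = df
  return num / R::rchisq(df);
}

// [[Rcpp::export]]
List gibbs_sampler(NumericVector y, NumericMatrix Xf, List blocks,
                   double df_e, double S_e, bool fix_sige, double sige0,
                   int niter, int burnin, int thin, bool save_effects) {
  const int n = y.size();
  const int pf = Xf.ncol();
  const int nb = blocks.size();

  // unpack blocks
  std::vector<NumericMatrix> X(nb);
  std::vector<int> prior(nb), p(nb);
  std::vector<double> df(nb), S(nb), var0(nb), piA(nb), piB(nb), probIn(nb);
  std::vector<bool> var_fixed(nb), pi_est(nb);
  int ptot = 0;
  for (int b = 0; b < nb; ++b) {
    List bl = blocks[b];
    X[b] = as<NumericMatrix>(bl["X"]);
    if (X[b].nrow() != n) stop("block design rows must match y");
    prior[b] = as<int>(bl["prior"]);      // 0 BRR, 1 BayesB, 2 BayesC
    df[b] = as<double>(bl["df"]);
    S[b] = as<double>(bl["S"]);
    var_fixed[b] = as<bool>(bl["var_fixed"]);
    var0[b] = as<double>(bl["var0"]);
    pi_est[b] = as<bool>(bl["pi_est"]);
    probIn[b] = as<double>(bl["pi0"]);
    piA[b] = as<double>(bl["pi_a"]);
    piB[b] = as<double>(bl["pi_b"]);
    p[b] = X[b].ncol();
    ptot += p[b];
  }

  // precompute column squared norms
  NumericVector xtxf(pf);
  for (int j = 0; j < pf; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += Xf(i, j) * Xf(i, j);
    xtxf[j] = s;
  }
  std::vector<NumericVector> xtx(nb);
  for (int b = 0; b < nb; ++b) {
    xtx[b] = NumericVector(p[b]);
    for (int j = 0; j < p[b]; ++j) {
      double s = 0; for (int i = 0; i < n; ++i) s += X[b](i, j) * X[b](i, j);
      xtx[b][j] = s;
    }
  }

  // state
  NumericVector bf(pf, 0.0);
  std::vector<NumericVector> m(nb);
  std::vector<std::vector<int> > delta(nb);
  std::vector<NumericVector> vj(nb);   // per-regressor variances (Bayes B)
  std::vector<double> vcommon(nb);     // common variance (BRR / Bayes C)
  for (int b = 0; b < nb; ++b) {
    m[b] = NumericVector(p[b], 0.0);
    delta[b] = std::vector<int>(p[b], 1);
    double v0 = var_fixed[b] ? var0[b] : S[b];
    vcommon[b] = v0;
    if (prior[b] == 1) vj[b] = NumericVector(p[b], v0);
  }
  double sige = fix_sige ? sige0 : (S_e > 0 ? S_e : 1.0);

  NumericVector e = clone(y);  // residual = y - Xf bf - sum_b X_b m_b

  // accumulators
  const int nsave = (niter - burnin) / thin;
  NumericVector dev_save(nsave), sige_save(nsave);
  NumericMatrix var_save(nsave, nb), pi_save(nsave, nb), vareta_save(nsave, nb);
  NumericMatrix eta_block_sum(n, nb);
  NumericVector eta_sum(n, 0.0);
  NumericVector bf_sum(pf, 0.0), bf_sum2(pf, 0.0);
  std::vector<NumericVector> m_sum(nb), m_sum2(nb), incl_sum(nb);
  for (int b = 0; b < nb; ++b) {
    m_sum[b] = NumericVector(p[b], 0.0);
    m_sum2[b] = NumericVector(p[b], 0.0);
    incl_sum[b] = NumericVector(p[b], 0.0);
  }
  NumericMatrix eff_save;
  if (save_effects) eff_save = NumericMatrix(nsave, pf + ptot);

  NumericVector eta_b(n);
  int isave = 0;
  const double log2pi = std::log(2.0 * M_PI);

  for (int it = 0; it < niter; ++it) {
    // --- fixed effects, flat priors ---
    for (int j = 0; j < pf; ++j) {
      if (xtxf[j] <= 0) continue;
      double c = 0; for (int i = 0; i < n; ++i) c += Xf(i, j) * e[i];
      c += xtxf[j] * bf[j];
      double bnew = c / xtxf[j] + R::norm_rand() * std::sqrt(sige / xtxf[j]);
      double dmj = bnew - bf[j];
      if (dmj != 0) for (int i = 0; i < n; ++i) e[i] -= Xf(i, j) * dmj;
      bf[j] = bnew;
    }

    // --- regressor blocks ---
    for (int b = 0; b < nb; ++b) {
      NumericMatrix& Xb = X[b];
      const int pb = p[b];
      if (prior[b] == 0) {
        // BRR: plain Gaussian shrinkage, common variance
        double ss = 0;
        for (int j = 0; j < pb; ++j) {
          if (xtx[b][j] <= 0) { m[b][j] = 0; continue; }
          double c = 0; for (int i = 0; i < n; ++i) c += Xb(i, j) * e[i];
          c += xtx[b][j] * m[b][j];
          double l = xtx[b][j] + sige / vcommon[b];
          double mnew = c / l + R::norm_rand() * std::sqrt(sige / l);
          double dmj = mnew - m[b][j];
          if (dmj != 0) for (int i = 0; i < n; ++i) e[i] -= Xb(i, j) * dmj;
          m[b][j] = mnew;
          ss += mnew * mnew;
        }
        if (!var_fixed[b]) vcommon[b] = rinvchisq(df[b] + pb, df[b] * S[b] + ss);
      } else {
        // Bayes B (own variance per regressor) / Bayes C (common variance)
        int k_in = 0;
        double ss_in = 0;
        bool always_in = probIn[b] >= 1.0;
        double lo_prior = always_in ? 0.0 : std::log(probIn[b] / (1.0 - probIn[b]));
        for (int j = 0; j < pb; ++j) {
          if (xtx[b][j] <= 0) { m[b][j] = 0; delta[b][j] = 0; continue; }
          // remove current contribution
          if (delta[b][j] && m[b][j] != 0) {
            double mj = m[b][j];
            for (int i = 0; i < n; ++i) e[i] += Xb(i, j) * mj;
          }
          double c = 0; for (int i = 0; i < n; ++i) c += Xb(i, j) * e[i];
          double v = (prior[b] == 1) ? vj[b][j] : vcommon[b];
          double l = xtx[b][j] + sige / v;
          int din;
          if (always_in) {
            din = 1;
          } else {
            // log Bayes factor for inclusion, effect integrated out
            double logbf = 0.5 * (std::log(sige / (l * v)) + c * c / (sige * l));
            double lo = lo_prior + logbf;
            double pin = 1.0 / (1.0 + std::exp(-lo));
            din = (unif_rand() < pin) ? 1 : 0;
          }
          delta[b][j] = din;
          if (din) {
            double mnew = c / l + R::norm_rand() * std::sqrt(sige / l);
            m[b][j] = mnew;
            for (int i = 0; i < n; ++i) e[i] -= Xb(i, j) * mnew;
            ++k_in; ss_in += mnew * mnew;
          } else {
            m[b][j] = 0;
          }
        }
        if (!var_fixed[b]) {
          if (prior[b] == 1) {
            for (int j = 0; j < pb; ++j) {
              if (delta[b][j])
                vj[b][j] = rinvchisq(df[b] + 1, df[b] * S[b] + m[b][j] * m[b][j]);
              else
                vj[b][j] = rinvchisq(df[b], df[b] * S[b]);
            }
          } else {
            vcommon[b] = rinvchisq(df[b] + k_in, df[b] * S[b] + ss_in);
          }
        }
        if (pi_est[b]) {
          probIn[b] = R::rbeta(piA[b] + k_in, piB[b] + (pb - k_in));
          if (probIn[b] < 1e-6) probIn[b] = 1e-6;
          if (probIn[b] > 1 - 1e-6) probIn[b] = 1 - 1e-6;
        }
      }
    }

    // --- residual variance ---
    double sse = 0; for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    if (!fix_sige) sige = rinvchisq(df_e + n, df_e * S_e + sse);

    // --- save ---
    if (it >= burnin && ((it - burnin) % thin) == 0 && isave < nsave) {
      dev_save[isave] = n * (log2pi + std::log(sige)) + sse / sige;
      sige_save[isave] = sige;
      double eta_tot_i;
      // per-block predictors
      for (int b = 0; b < nb; ++b) {
        std::fill(eta_b.begin(), eta_b.end(), 0.0);
        NumericMatrix& Xb = X[b];
        for (int j = 0; j < p[b]; ++j) {
          double mj = m[b][j];
          if (mj != 0) for (int i = 0; i < n; ++i) eta_b[i] += Xb(i, j) * mj;
        }
        double mu = 0, s2 = 0;
        for (int i = 0; i < n; ++i) mu += eta_b[i];
        mu /= n;
        for (int i = 0; i < n; ++i) {
          double dd = eta_b[i] - mu; s2 += dd * dd;
          eta_block_sum(i, b) += eta_b[i];
        }
        vareta_save(isave, b) = s2 / (n - 1);
        double vrep;
        if (prior[b] == 1) {
          double sv = 0; for (int j = 0; j < p[b]; ++j) sv += vj[b][j];
          vrep = sv / p[b];
        } else vrep = vcommon[b];
        var_save(isave, b) = vrep;
        pi_save(isave, b) = (prior[b] == 0) ? NA_REAL : probIn[b];
      }
      for (int i = 0; i < n; ++i) {
        eta_tot_i = y[i] - e[i];
        eta_sum[i] += eta_tot_i;
      }
      for (int j = 0; j < pf; ++j) { bf_sum[j] += bf[j]; bf_sum2[j] += bf[j] * bf[j]; }
      for (int b = 0; b < nb; ++b)
        for (int j = 0; j < p[b]; ++j) {
          m_sum[b][j] += m[b][j]; m_sum2[b][j] += m[b][j] * m[b][j];
          incl_sum[b][j] += delta[b][j];
        }
      if (save_effects) {
        int col = 0;
        for (int j = 0; j < pf; ++j) eff_save(isave, col++) = bf[j];
        for (int b = 0; b < nb; ++b)
          for (int j = 0; j < p[b]; ++j) eff_save(isave, col++) = m[b][j];
      }
      ++isave;
    }
  }

  List m_mean(nb), m_sd(nb), incl(nb);
  for (int b = 0; b < nb; ++b) {
    NumericVector mm(p[b]), ms(p[b]), ic(p[b]);
    for (int j = 0; j < p[b]; ++j) {
      mm[j] = m_sum[b][j] / nsave;
      double v = m_sum2[b][j] / nsave - mm[j] * mm[j];
      ms[j] = v > 0 ? std::sqrt(v) : 0.0;
      ic[j] = incl_sum[b][j] / nsave;
    }
    m_mean[b] = mm; m_sd[b] = ms; incl[b] = ic;
  }
  NumericVector bf_mean(pf), bf_sd(pf);
  for (int j = 0; j < pf; ++j) {
    bf_mean[j] = bf_sum[j] / nsave;
    double v = bf_sum2[j] / nsave - bf_mean[j] * bf_mean[j];
    bf_sd[j] = v > 0 ? std::sqrt(v) : 0.0;
  }
  for (int i = 0; i < n; ++i) eta_sum[i] /= nsave;
  for (int b = 0; b < nb; ++b)
    for (int i = 0; i < n; ++i) eta_block_sum(i, b) /= nsave;

  return List::create(
    _["nsave"] = nsave,
    _["deviance"] = dev_save,
    _["sige"] = sige_save,
    _["varcomp"] = var_save,
    _["pi"] = pi_save,
    _["var_eta"] = vareta_save,
    _["eta_mean"] = eta_sum,
    _["eta_block_mean"] = eta_block_sum,
    _["fixed_mean"] = bf_mean, _["fixed_sd"] = bf_sd,
    _["effect_mean"] = m_mean, _["effect_sd"] = m_sd,
    _["inclusion"] = incl,
    _["effect_samples"] = save_effects ? eff_save : NumericMatrix(0, 0)
  );
}

// Gene-dropping Monte-Carlo estimate of the additive relationship matrix.
// Parents are 1-based indices (0 = unknown); unknown parents contribute a
// fresh unrelated founder allele per offspring. Returns the mean and the
// Monte-Carlo standard error of each entry. Serves as an independent oracle
// for the tabular pedigree recurrence.
// [[Rcpp::export]]
List gene_drop_relationship(IntegerVector sire, IntegerVector dam, int nreps) {
  const int n = sire.size();
  NumericMatrix sum(n, n), sum2(n, n);
  std::vector<int> a1(n), a2(n);
  for (int rep = 0; rep < nreps; ++rep) {
    int next_allele = 0;
    for (int i = 0; i < n; ++i) {
      int s = sire[i], d = dam[i];
      if (s > 0) {
        int si = s - 1;
        a1[i] = (unif_rand() < 0.5) ? a1[si] : a2[si];
      } else a1[i] = next_allele++;
      if (d > 0) {
        int di = d - 1;
        a2[i] = (unif_rand() < 0.5) ? a1[di] : a2[di];
      } else a2[i] = next_allele++;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        double c = 0.5 * ((a1[i] == a1[j]) + (a1[i] == a2[j]) +
                          (a2[i] == a1[j]) + (a2[i] == a2[j]));
        sum(i, j) += c; sum2(i, j) += c * c;
      }
    }
  }
  NumericMatrix mean(n, n), se(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double mu = sum(i, j) / nreps;
      double v = sum2(i, j) / nreps - mu * mu;
      double s = std::sqrt((v > 0 ? v : 0) / nreps);
      mean(i, j) = mean(j, i) = mu;
      se(i, j) = se(j, i) = s;
    }
  return List::create(_["mean"] = mean, _["se"] = se);
}
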