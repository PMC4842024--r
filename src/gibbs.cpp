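// Inner Gibbs sweep loop for the animal-model sampler.
//
// All model structure (eigenbases, mother index, priors) is prepared in R;
// this routine only iterates the conjugate updates.  Random numbers come
// from R's generator (RNGScope), so set.seed() on the R side makes chains
// reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Draw a structured block in its eigenbasis, conditioned by kriging on
// s'w = 0.  P = 1/sig_u + lambda/sig_e (diagonal full-conditional
// precision).
static arma::vec draw_block(const arma::mat& T, const arma::vec& lambda,
                            const arma::vec& s, const arma::vec& resid,
                            double sig_u, double sig_e, bool constrain) {
  arma::vec P = 1.0 / sig_u + lambda / sig_e;
  arma::vec mu = (T.t() * resid) / (sig_e * P);
  arma::vec w(mu.n_elem);
  for (arma::uword i = 0; i < w.n_elem; ++i)
    w(i) = mu(i) + R::norm_rand() / std::sqrt(P(i));
  if (constrain) {
    arma::vec sP = s / P;
    w -= sP * (arma::dot(s, w) / arma::dot(s, sP));
  }
  return w;
}

static double rinvgamma1(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::vec& y,
                 bool use_a, const arma::mat& Ta, const arma::vec& la,
                 const arma::vec& sa_con, const arma::mat& Ga,
                 bool use_m, const arma::mat& Tm, const arma::vec& lm,
                 const arma::vec& sm_con, const arma::mat& Gm,
                 bool use_p, const arma::ivec& mom_idx, int nm,
                 double prior_shape, double prior_rate, double b0_prec,
                 int iterations, int burnin, int thin) {
  RNGScope scope;
  const int nd = y.n_elem;
  const int np = use_a ? Ga.n_rows : (use_m ? Gm.n_rows : 0);

  double sig_a = 0.5, sig_m = 0.5, sig_p = 0.5;
  double sig_e = std::max(arma::var(y) / 2.0, 1e-3);
  double beta0 = arma::mean(y);
  arma::vec w_a, w_m;
  arma::vec p_eff = arma::zeros(std::max(nm, 1));
  arma::vec fit_a = arma::zeros(nd), fit_m = arma::zeros(nd),
            fit_p = arma::zeros(nd);

  // per-mother observation counts
  arma::vec mom_cnt = arma::zeros(std::max(nm, 1));
  if (use_p)
    for (int i = 0; i < nd; ++i)
      if (mom_idx(i) > 0) mom_cnt(mom_idx(i) - 1) += 1.0;

  const int nkeep = (iterations - burnin) / thin;
  const int npar = use_a + use_m + use_p + 3; // variances + sig_e, beta0, dev
  arma::mat draws(nkeep, npar);
  arma::vec mu_sum = arma::zeros(nd);
  arma::vec a_sum = arma::zeros(std::max(np, 1)),
            m_sum = arma::zeros(std::max(np, 1));
  arma::vec p_sum = arma::zeros(std::max(nm, 1));
  double max_con = 0.0;
  int krow = 0;

  for (int it = 1; it <= iterations; ++it) {
    if (use_a) {
      arma::vec r = y - beta0 - fit_m - fit_p;
      w_a = draw_block(Ta, la, sa_con, r, sig_a, sig_e, true);
      fit_a = Ta * w_a;
      sig_a = rinvgamma1(prior_shape + (np - 1) / 2.0,
                         prior_rate + arma::dot(w_a, w_a) / 2.0);
    }
    if (use_m) {
      arma::vec r = y - beta0 - fit_a - fit_p;
      w_m = draw_block(Tm, lm, sm_con, r, sig_m, sig_e, true);
      fit_m = Tm * w_m;
      sig_m = rinvgamma1(prior_shape + (np - 1) / 2.0,
                         prior_rate + arma::dot(w_m, w_m) / 2.0);
    }
    if (use_p) {
      arma::vec r = y - beta0 - fit_a - fit_m;
      arma::vec sums = arma::zeros(nm);
      for (int i = 0; i < nd; ++i)
        if (mom_idx(i) > 0) sums(mom_idx(i) - 1) += r(i);
      double ssq = 0.0;
      for (int j = 0; j < nm; ++j) {
        double pv = 1.0 / (mom_cnt(j) / sig_e + 1.0 / sig_p);
        p_eff(j) = sums(j) / sig_e * pv + R::norm_rand() * std::sqrt(pv);
        ssq += p_eff(j) * p_eff(j);
      }
      for (int i = 0; i < nd; ++i)
        fit_p(i) = mom_idx(i) > 0 ? p_eff(mom_idx(i) - 1) : 0.0;
      sig_p = rinvgamma1(prior_shape + nm / 2.0, prior_rate + ssq / 2.0);
    }
    arma::vec r = y - fit_a - fit_m - fit_p;
    double prec0 = nd / sig_e + b0_prec;
    beta0 = arma::sum(r) / sig_e / prec0 + R::norm_rand() / std::sqrt(prec0);
    double ssr = arma::dot(r - beta0, r - beta0);
    sig_e = rinvgamma1(prior_shape + nd / 2.0, prior_rate + ssr / 2.0);

    if (it > burnin && (it - burnin) % thin == 0) {
      arma::vec eta = beta0 + fit_a + fit_m + fit_p;
      arma::vec resid = y - eta;
      double dev = nd * std::log(2.0 * M_PI * sig_e) +
        arma::dot(resid, resid) / sig_e;
      int c = 0;
      if (use_a) draws(krow, c++) = sig_a;
      if (use_m) draws(krow, c++) = sig_m;
      if (use_p) draws(krow, c++) = sig_p;
      draws(krow, c++) = sig_e;
      draws(krow, c++) = beta0;
      draws(krow, c++) = dev;
      mu_sum += eta;
      if (use_a) {
        arma::vec a_full = Ga * w_a;
        a_sum += a_full;
        max_con = std::max(max_con, std::abs(arma::sum(a_full)));
      }
      if (use_m) {
        arma::vec m_full = Gm * w_m;
        m_sum += m_full;
        max_con = std::max(max_con, std::abs(arma::sum(m_full)));
      }
      if (use_p) p_sum += p_eff;
      ++krow;
    }
  }
  return List::create(_["draws"] = draws, _["mu_sum"] = mu_sum,
                      _["a_sum"] = a_sum, _["m_sum"] = m_sum,
                      _["p_sum"] = p_sum, _["max_con"] = max_con);
}
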