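// Single-site Gibbs sampler for BayesR / BayesRC mixture-prior
// whole-genome regression: y = 1*mu + W s + e, with SNP effects from a
// four-component normal mixture N(0, gamma_k * sigma2_beta),
// gamma = (0, 0.01, 0.1, 1).  BayesRC gives each annotation class its
// own mixing proportions, updated from class-specific Dirichlet counts.
// Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  // scaled inverse chi-square draw: df * scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesrGibbs")]]
List bayesrGibbs(const arma::vec& y, const arma::mat& W,
                 const arma::ivec& classOf, const arma::vec& gamma,
                 const arma::mat& piInit, bool fixPi, int nIter,
                 int burnIn, double nu0, double s0e, double s0b,
                 double dirichletAlpha) {
  const int n = W.n_rows, m = W.n_cols;
  const int nk = gamma.n_elem;
  const int nc = piInit.n_rows;

  arma::vec wtw(m);
  for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  double vary = arma::var(y);
  double mu = arma::mean(y);
  arma::vec s(m, arma::fill::zeros);
  arma::vec e = y - mu;
  double sigE = 0.5 * vary;
  double sigB = s0b;
  arma::mat pi = piInit;

  arma::vec sMean(m, arma::fill::zeros);
  arma::vec incl(m, arma::fill::zeros);
  arma::mat piMean(nc, nk, arma::fill::zeros);
  double muMean = 0, sigEMean = 0, sigBMean = 0;
  arma::vec sigETrace(nIter);
  int nPost = 0;

  arma::vec logl(nk), prob(nk);

  for (int it = 0; it < nIter; ++it) {
    // intercept
    double rbar = mu + arma::mean(e);
    double muNew = rbar + R::rnorm(0.0, std::sqrt(sigE / n));
    e += mu - muNew;
    mu = muNew;

    double ssqScaled = 0.0;   // sum s_j^2 / gamma_k(j) over nonzero
    int q = 0;
    arma::mat counts(nc, nk, arma::fill::zeros);

    for (int j = 0; j < m; ++j) {
      if (wtw(j) <= 0) { counts(classOf(j), 0) += 1; continue; }
      double sOld = s(j);
      double rhs = arma::dot(W.col(j), e) + wtw(j) * sOld;
      int cc = classOf(j);

      for (int k = 0; k < nk; ++k) {
        double pk = pi(cc, k);
        if (pk <= 0.0) { logl(k) = -INFINITY; continue; }
        if (gamma(k) == 0.0) { logl(k) = std::log(pk); continue; }
        double v = gamma(k) * sigB;
        double denom = wtw(j) * v + sigE;
        logl(k) = std::log(pk) - 0.5 * std::log(denom / sigE)
                + 0.5 * rhs * rhs * v / (sigE * denom);
      }
      double mx = logl.max();
      prob = arma::exp(logl - mx);
      prob /= arma::accu(prob);
      double u = unif_rand();
      int k = nk - 1;
      double cum = 0;
      for (int kk = 0; kk < nk; ++kk) {
        cum += prob(kk);
        if (u <= cum) { k = kk; break; }
      }
      counts(cc, k) += 1;

      double sNew = 0.0;
      if (gamma(k) > 0.0) {
        double v = gamma(k) * sigB;
        double C = wtw(j) + sigE / v;
        double mean = rhs / C;
        sNew = mean + R::rnorm(0.0, std::sqrt(sigE / C));
        ssqScaled += sNew * sNew / gamma(k);
        ++q;
      }
      if (sNew != sOld) e += W.col(j) * (sOld - sNew);
      s(j) = sNew;
    }

    // variances (scaled inverse chi-square)
    sigB = rinvchisq(nu0 + q, (nu0 * s0b + ssqScaled) / (nu0 + q));
    double sse = arma::dot(e, e);
    sigE = rinvchisq(nu0 + n, (nu0 * s0e + sse) / (nu0 + n));
    sigETrace(it) = sigE;

    // mixing proportions
    if (!fixPi) {
      for (int c = 0; c < nc; ++c) {
        double tot = 0;
        arma::vec g(nk);
        for (int k = 0; k < nk; ++k) {
          g(k) = R::rgamma(dirichletAlpha + counts(c, k), 1.0);
          tot += g(k);
        }
        for (int k = 0; k < nk; ++k) pi(c, k) = g(k) / tot;
      }
    }

    if (it >= burnIn) {
      ++nPost;
      sMean += s;
      for (int j = 0; j < m; ++j) if (s(j) != 0.0) incl(j) += 1;
      piMean += pi;
      muMean += mu;
      sigEMean += sigE;
      sigBMean += sigB;
    }
  }

  sMean /= nPost;
  incl /= nPost;
  piMean /= nPost;

  return List::create(
    _["effects"] = sMean, _["inclusion"] = incl,
    _["mu"] = muMean / nPost, _["sigma2e"] = sigEMean / nPost,
    _["sigma2beta"] = sigBMean / nPost, _["pi"] = piMean,
    _["sigma2eTrace"] = sigETrace);
}
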