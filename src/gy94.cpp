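// GY94 codon-model pruning likelihood.
//
// Site likelihoods under a Goldman-Yang codon substitution process with one
// or more omega site classes sharing kappa and codon frequencies. The rate
// matrix for each class is scaled by a single factor (the weighted mean rate
// over classes) so branch lengths are expected substitutions per codon under
// the mixture. Felsenstein pruning runs over a postorder edge list; per-site
// log-scaling keeps 61-state partials in range on larger trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the unscaled GY94 rate matrix for one omega class.
// pairs: rows (i, j, pos, transition, synonymous), 1-based codon indices.
static arma::mat build_q(const arma::vec& pi, double kappa, double omega,
                         const IntegerMatrix& pairs) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0) - 1;
    int j = pairs(r, 1) - 1;
    double rate = pi(j);
    if (pairs(r, 3) == 1) rate *= kappa;
    if (pairs(r, 4) == 0) rate *= omega;
    Q(i, j) = rate;
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Mean substitution rate of an unscaled Q at stationarity.
static double mean_rate(const arma::mat& Q, const arma::vec& pi) {
  return -arma::dot(pi, Q.diag());
}

// [[Rcpp::export]]
double gy94_scale_factor(const arma::vec& pi, double kappa,
                         const arma::vec& omegas, const arma::vec& weights,
                         const IntegerMatrix& pairs) {
  double rbar = 0.0;
  for (arma::uword k = 0; k < omegas.n_elem; ++k) {
    rbar += weights(k) * mean_rate(build_q(pi, kappa, omegas(k), pairs), pi);
  }
  return rbar;
}

// Per-site log-likelihoods, one column per omega class.
//
// tip_states: ntip x nsites, 1-based codon states, 0 = gap/missing.
// edge: postorder edge matrix (parent, child), 1-based ape node numbering
//       (tips 1..ntip, root ntip+1).
// Returns nsites x nclass matrix of log f(site | class).
// [[Rcpp::export]]
arma::mat gy94_site_loglik(const IntegerMatrix& tip_states,
                           const IntegerMatrix& edge,
                           const arma::vec& edge_length,
                           const arma::vec& pi, double kappa,
                           const arma::vec& omegas,
                           const arma::vec& weights,
                           const IntegerMatrix& pairs) {
  const int ntip = tip_states.nrow();
  const int nsites = tip_states.ncol();
  const int nclass = omegas.n_elem;
  const int nstate = pi.n_elem;
  const int nedge = edge.nrow();
  const int nnode = ntip + nedge + 1; // upper bound on node count

  double rbar = gy94_scale_factor(pi, kappa, omegas, weights, pairs);
  if (rbar <= 0) stop("degenerate rate matrix (mean rate <= 0)");

  arma::vec sqp = arma::sqrt(pi);
  arma::mat out(nsites, nclass);

  for (int k = 0; k < nclass; ++k) {
    arma::mat Q = build_q(pi, kappa, omegas(k), pairs) / rbar;
    arma::mat B = arma::diagmat(sqp) * Q * arma::diagmat(1.0 / sqp);
    B = 0.5 * (B + B.t());
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, B)) stop("eigendecomposition failed");
    arma::mat left = arma::diagmat(1.0 / sqp) * evec;
    arma::mat right = evec.t() * arma::diagmat(sqp);

    std::vector<arma::mat> partial(nnode);
    std::vector<bool> seen(nnode, false);
    arma::rowvec logscale(nsites, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      int parent = edge(e, 0) - 1;
      int child = edge(e, 1) - 1;
      arma::mat P = left * arma::diagmat(arma::exp(eval * edge_length(e))) *
        right;
      P.clamp(0.0, arma::datum::inf);
      arma::mat msg(nstate, nsites);
      if (child < ntip) {
        for (int s = 0; s < nsites; ++s) {
          int st = tip_states(child, s);
          if (st == 0) {
            msg.col(s).ones();
          } else {
            msg.col(s) = P.col(st - 1);
          }
        }
      } else {
        msg = P * partial[child];
      }
      if (!seen[parent]) {
        partial[parent] = msg;
        seen[parent] = true;
      } else {
        partial[parent] %= msg;
        // rescale columns drifting toward underflow
        arma::rowvec mx = arma::max(partial[parent], 0);
        for (int s = 0; s < nsites; ++s) {
          if (mx(s) > 0 && mx(s) < 1e-200) {
            partial[parent].col(s) /= mx(s);
            logscale(s) += std::log(mx(s));
          }
        }
      }
    }
    int root = edge(nedge - 1, 0) - 1;
    arma::rowvec lik = pi.t() * partial[root];
    for (int s = 0; s < nsites; ++s) {
      out(s, k) = (lik(s) > 0 ? std::log(lik(s)) : -1e30) + logscale(s);
    }
  }
  return out;
}
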