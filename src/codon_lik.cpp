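// Fast evaluation of the branch-class codon-model likelihood used inside the
// ML optimizer. The R-level codon_log_likelihood() is the reference
// implementation; the two are held together by tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// GY-style generator: q_ij = pi_j * kappa^[ts] * omega^[nonsyn] for
// single-nucleotide steps, scaled to one expected substitution per codon.
static mat build_q(const vec& pi, double kappa, double omega,
                   const mat& single_step, const mat& is_ts,
                   const mat& is_syn) {
  mat Q = single_step % repmat(pi.t(), 61, 1);
  Q = Q % (1.0 + (kappa - 1.0) * is_ts);
  Q = Q % (1.0 + (omega - 1.0) * (1.0 - is_syn) % single_step);
  Q.diag() -= sum(Q, 1);
  double scale = -dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

struct EigSys { mat U; vec lam; };

static EigSys eig_of_q(const mat& Q, const vec& sq) {
  mat S = Q % (sq * (1.0 / sq).t());
  S = 0.5 * (S + S.t());
  EigSys e;
  eig_sym(e.lam, e.U, S);
  return e;
}

static mat pmat(const EigSys& e, const vec& sq, double t) {
  mat P = (e.U.each_row() % exp(e.lam * t).t()) * e.U.t();
  P = P % ((1.0 / sq) * sq.t());
  P.elem(find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export]]
double cpp_loglik(const arma::vec& pi, double kappa,
                  const arma::vec& omega_edge, const arma::vec& tlen,
                  const arma::ivec& parent, const arma::ivec& child,
                  int n_tips, int n_nodes,
                  const arma::imat& states, const arma::vec& weights,
                  const arma::mat& single_step, const arma::mat& is_ts,
                  const arma::mat& is_syn) {
  const int E = parent.n_elem, npat = states.n_cols;
  vec sq = sqrt(clamp(pi, 1e-300, datum::inf));

  // one eigendecomposition per distinct omega (kappa, pi shared)
  vec uo = unique(omega_edge);
  std::vector<EigSys> sys(uo.n_elem);
  for (uword k = 0; k < uo.n_elem; ++k)
    sys[k] = eig_of_q(build_q(pi, kappa, uo(k), single_step, is_ts, is_syn), sq);

  std::vector<mat> partial(n_nodes);
  for (int nd = n_tips; nd < n_nodes; ++nd)
    partial[nd] = mat(61, npat, fill::ones);
  rowvec scale_log(npat, fill::zeros);

  for (int e = 0; e < E; ++e) {
    uword k = index_min(abs(uo - omega_edge(e)));
    mat P = pmat(sys[k], sq, tlen(e));
    int ch = child(e) - 1, pa = parent(e) - 1;
    mat up(61, npat, fill::ones);
    if (ch < n_tips) {
      for (int j = 0; j < npat; ++j) {
        int s = states(ch, j);
        if (s > 0) up.col(j) = P.col(s - 1);
      }
    } else {
      mat L = partial[ch];
      for (int j = 0; j < npat; ++j) {
        double m = L.col(j).max();
        if (m > 0) { L.col(j) /= m; scale_log(j) += std::log(m); }
        else scale_log(j) = -datum::inf;
      }
      up = P * L;
    }
    partial[pa] %= up;
  }
  rowvec rootL = pi.t() * partial[n_tips];   // root is node n_tips+1 (0-based n_tips)
  rowvec colL = log(rootL) + scale_log;
  return dot(colL, weights.t());
}

// Two-sequence likelihood: sum_j w_j log(pi_a P(t)[a,b]); states are the
// 1-based codon indices of the gap-free pattern pairs.
// [[Rcpp::export]]
double cpp_pair_loglik(const arma::vec& pi, double kappa, double omega,
                       double t, const arma::ivec& sa, const arma::ivec& sb,
                       const arma::vec& weights,
                       const arma::mat& single_step, const arma::mat& is_ts,
                       const arma::mat& is_syn) {
  vec sq = sqrt(clamp(pi, 1e-300, datum::inf));
  EigSys e = eig_of_q(build_q(pi, kappa, omega, single_step, is_ts, is_syn), sq);
  mat P = pmat(e, sq, t);
  double ll = 0;
  for (uword j = 0; j < sa.n_elem; ++j) {
    double p = pi(sa(j) - 1) * P(sa(j) - 1, sb(j) - 1);
    ll += weights(j) * std::log(std::max(p, 1e-300));
  }
  return ll;
}
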