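// Likelihood engine: Felsenstein pruning over the 61 sense codons with
// site-class mixtures (free-ratio and branch-site parameterisations), plus a
// generic n-state pruning routine used for amino-acid models.
//
// Conventions shared with the R side:
//  - tip data are 1-based sense-codon (or residue) indices, 0 = missing;
//  - edges are given postorder (children before parents), ape node numbering
//    (tips 1..ntip, root = ntip + 1);
//  - branch times are *effective* times: the R side divides branch lengths
//    (expected substitutions per codon) by the appropriate mean rate of the
//    unscaled generator, so this file exponentiates raw GY94 generators.
//
// Eigendecompositions and transition matrices are memoised across calls
// (keyed by kappa, omega and a frequency hash); optimiser gradients perturb
// one parameter at a time, so most lookups hit.

#include <RcppArmadillo.h>
#include <array>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct EigQ {
  vec lam;   // eigenvalues of the symmetrised generator
  mat left;  // D^{-1/2} V
  mat right; // V' D^{1/2}
};

typedef std::array<double, 3> EigKey; // kappa, omega, pi-hash
typedef std::array<double, 4> PKey;   // kappa, omega, pi-hash, t

std::map<EigKey, EigQ> eig_cache;
std::map<PKey, mat> p_cache;

void trim_caches() {
  if (p_cache.size() > 4096) p_cache.clear();
  if (eig_cache.size() > 1024) eig_cache.clear();
}

double pi_hash(const vec& pi) {
  double h = 0;
  for (uword i = 0; i < pi.n_elem; ++i) h += pi(i) * (i + 1.0);
  return h;
}

// GY94-style unscaled generator + symmetric eigendecomposition.
const EigQ& eig_codon_q(const imat& type, const vec& pi, double kappa,
                        double omega, double ph) {
  EigKey key = {kappa, omega, ph};
  auto it = eig_cache.find(key);
  if (it != eig_cache.end()) return it->second;
  const int n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double f;
      switch (type(i, j)) {
        case 1: f = kappa; break;          // synonymous transition
        case 2: f = 1.0; break;            // synonymous transversion
        case 3: f = kappa * omega; break;  // nonsynonymous transition
        case 4: f = omega; break;          // nonsynonymous transversion
        default: continue;
      }
      Q(i, j) = f * pi(j);
    }
  }
  Q.diag() = -sum(Q, 1);
  EigQ e;
  vec d = sqrt(pi);
  mat S = Q;
  S.each_col() %= d;
  S.each_row() /= d.t();
  S = 0.5 * (S + S.t());
  vec lam;
  mat V;
  eig_sym(lam, V, S);
  e.lam = lam;
  e.left = V;
  e.left.each_col() /= d;
  e.right = V.t();
  e.right.each_row() %= d.t();
  return eig_cache.emplace(key, std::move(e)).first->second;
}

const mat& pmat_cached(const imat& type, const vec& pi, double kappa,
                       double omega, double ph, double t) {
  PKey key = {kappa, omega, ph, t};
  auto it = p_cache.find(key);
  if (it != p_cache.end()) return it->second;
  const EigQ& e = eig_codon_q(type, pi, kappa, omega, ph);
  mat tmp = e.left;
  tmp.each_row() %= exp(e.lam.t() * t);
  mat P = tmp * e.right;
  P.clamp(0.0, datum::inf);
  P.each_col() /= sum(P, 1);
  return p_cache.emplace(key, std::move(P)).first->second;
}

// One pruning pass; P[e] points at the transition matrix of postorder edge
// e. Returns per-pattern log-likelihood.
rowvec prune_pass(const std::vector<const mat*>& P, const imat& edge,
                  const std::vector<mat>& tipL, const vec& pi, int nnode,
                  int ntip) {
  const int npat = tipL.empty() ? 0 : tipL[0].n_cols;
  const int nstate = pi.n_elem;
  cube L(nstate, npat, nnode);
  std::vector<bool> seen(nnode, false);
  rowvec logscale(npat, fill::zeros);
  const int nedge = edge.n_rows;
  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    mat msg = (c < ntip) ? (*P[e]) * tipL[c] : (*P[e]) * L.slice(c);
    if (!seen[p]) {
      L.slice(p) = msg;
      seen[p] = true;
    } else {
      L.slice(p) %= msg;
      rowvec m = max(L.slice(p), 0);
      m.clamp(datum::eps, datum::inf);
      L.slice(p).each_row() /= m;
      logscale += log(m);
    }
  }
  const int root = ntip; // 0-based index of ape root node ntip+1
  rowvec site = pi.t() * L.slice(root);
  site.clamp(1e-300, datum::inf);
  return log(site) + logscale;
}

std::vector<mat> tip_partials(const imat& tipdata, int nstate) {
  const int ntip = tipdata.n_rows, npat = tipdata.n_cols;
  std::vector<mat> tipL(ntip);
  for (int i = 0; i < ntip; ++i) {
    mat Lt(nstate, npat, fill::zeros);
    for (int s = 0; s < npat; ++s) {
      const int st = tipdata(i, s);
      if (st > 0)
        Lt(st - 1, s) = 1.0;
      else
        Lt.col(s).ones(); // gap / ambiguous codon: missing data
    }
    tipL[i] = Lt;
  }
  return tipL;
}

} // namespace

// Mixture codon log-likelihood. omega_edge and tmat are nedge x nclass
// (effective times, pre-scaled in R); weights are the class proportions.
// [[Rcpp::export]]
Rcpp::List cpp_codon_loglik(const arma::imat& tipdata, const arma::vec& counts,
                            const arma::imat& edge, const arma::mat& tmat,
                            const arma::mat& omega_edge,
                            const arma::vec& weights, double kappa,
                            const arma::vec& pi, const arma::imat& type,
                            bool per_pattern) {
  const int nedge = edge.n_rows, nclass = omega_edge.n_cols;
  const int ntip = tipdata.n_rows, npat = tipdata.n_cols;
  const int nnode = edge.max();
  const double ph = pi_hash(pi);
  trim_caches();

  std::vector<mat> tipL = tip_partials(tipdata, pi.n_elem);
  mat classll(nclass, npat);
  for (int c = 0; c < nclass; ++c) {
    std::vector<const mat*> P(nedge);
    for (int e = 0; e < nedge; ++e)
      P[e] = &pmat_cached(type, pi, kappa, omega_edge(e, c), ph, tmat(e, c));
    classll.row(c) = prune_pass(P, edge, tipL, pi, nnode, ntip);
  }

  rowvec mix(npat);
  if (nclass == 1) {
    mix = classll.row(0);
  } else {
    rowvec mx = max(classll, 0);
    rowvec acc(npat, fill::zeros);
    for (int c = 0; c < nclass; ++c)
      acc += weights(c) * exp(classll.row(c) - mx);
    mix = mx + log(acc);
  }
  const double total = dot(counts, mix);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = total,
                                      Rcpp::Named("pattern_loglik") = mix);
  if (per_pattern) out["class_loglik"] = classll;
  return out;
}

// Generic pruning with caller-supplied transition matrices (cube slice per
// postorder edge); used for amino-acid models and as an internal cross-check.
// [[Rcpp::export]]
Rcpp::List cpp_prune_loglik(const arma::imat& tipdata, const arma::vec& counts,
                            const arma::imat& edge, const arma::cube& P,
                            const arma::vec& pi) {
  const int ntip = tipdata.n_rows;
  const int nnode = edge.max();
  std::vector<const mat*> Pv(edge.n_rows);
  std::vector<mat> slices(edge.n_rows);
  for (size_t e = 0; e < Pv.size(); ++e) {
    slices[e] = P.slice(e);
    Pv[e] = &slices[e];
  }
  std::vector<mat> tipL = tip_partials(tipdata, pi.n_elem);
  rowvec ll = prune_pass(Pv, edge, tipL, pi, nnode, ntip);
  return Rcpp::List::create(Rcpp::Named("loglik") = dot(counts, ll),
                            Rcpp::Named("pattern_loglik") = ll);
}
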