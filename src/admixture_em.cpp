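// Monotone EM for the binomial admixture model.
//
// Data enter as reference-allele counts A (= 2 * numeric genotype) and
// alternate counts B (= 2 - A); missing entries carry A = B = 0 and so
// contribute nothing to the likelihood or the updates.  Given current
// (Q, F) the E-step attributes each observed allele to an ancestor and
// the M-step renormalises; both parameter blocks are refreshed from the
// same E-step, which is the classic frappe/ADMIXTURE EM and never
// decreases the log-likelihood.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double admix_loglik(const mat& A, const mat& B, const mat& P) {
  // A,B are zero at missing entries, so those terms vanish exactly.
  return accu(A % log(P)) + accu(B % log(1.0 - P));
}

// [[Rcpp::export(name = ".admixture_em_cpp")]]
Rcpp::List admixture_em_cpp(const arma::mat& A, const arma::mat& B,
                            arma::mat Q, arma::mat F,
                            double tol, int max_iter, double eps) {
  const uword n = A.n_rows, L = A.n_cols, K = Q.n_cols;

  F = clamp(F, eps, 1.0 - eps);
  mat P = clamp(Q * F, eps, 1.0 - eps);
  double ll = admix_loglik(A, B, P);
  std::vector<double> trace;
  trace.push_back(ll);

  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat RA = A / P;            // n x L
    mat RB = B / (1.0 - P);

    mat Qn = Q % (RA * F.t() + RB * (1.0 - F).t());
    // normalise by the realised row sums (equal to the per-row allele
    // totals except where the frequency clamp was active) so Q rows sum
    // to exactly 1 and clamp-induced drift cannot accumulate
    vec rs = sum(Qn, 1);
    uvec dead = find(rs == 0.0);     // all-missing accession
    rs.elem(dead).fill(1.0);
    Qn.each_col() /= rs;
    for (uword d = 0; d < dead.n_elem; ++d) Qn.row(dead(d)) = Q.row(dead(d));

    mat num = F % (Q.t() * RA);            // K x L
    mat den = num + (1.0 - F) % (Q.t() * RB);
    den.elem(find(den == 0.0)).fill(1.0);  // unobserved locus/ancestor combo
    mat Fn = clamp(num / den, eps, 1.0 - eps);

    Q = Qn;
    F = Fn;
    P = clamp(Q * F, eps, 1.0 - eps);
    double ll_new = admix_loglik(A, B, P);
    trace.push_back(ll_new);
    double delta = ll_new - ll;
    ll = ll_new;
    if (std::fabs(delta) < tol) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("Q") = Q,
    Rcpp::Named("F") = F,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = it);
}
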