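#include <Rcpp.h>
using namespace Rcpp;

// One SGD pass over the training samples in the given order. Mutates the
// factor matrices and bias vectors in place (the caller owns fresh copies).
// The four updates use the pre-update values of p_i and q_j on their
// right-hand sides, matching the reference R implementation sgd_update().
// [[Rcpp::export]]
void sgd_epoch(NumericMatrix P, NumericMatrix Q, NumericVector b_row,
               NumericVector b_col, double mu, IntegerVector ii,
               IntegerVector jj, NumericVector aa, IntegerVector ord,
               double gamma, double lambda) {
  const int k = P.ncol();
  const int n = ord.size();
  for (int t = 0; t < n; ++t) {
    const int s = ord[t] - 1;
    const int i = ii[s] - 1;
    const int j = jj[s] - 1;
    double dot = 0.0;
    for (int f = 0; f < k; ++f) dot += P(i, f) * Q(f, j);
    const double e = aa[s] - (mu + b_row[i] + b_col[j] + dot);
    const double bi = b_row[i], bj = b_col[j];
    b_row[i] = bi + gamma * (e - lambda * bi);
    b_col[j] = bj + gamma * (e - lambda * bj);
    for (int f = 0; f < k; ++f) {
      const double pif = P(i, f), qfj = Q(f, j);
      P(i, f) = pif + gamma * (e * qfj - lambda * pif);
      Q(f, j) = qfj + gamma * (e * pif - lambda * qfj);
    }
  }
}
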