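#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Multiplicative-update sparse NMF: minimize ||X - A S||_F^2 + sparsity * sum(|S|)
// over A >= 0 (n x k), S >= 0 (k x m). L1 penalty on S only (mechanism loadings).
// Updates are the standard Frobenius multiplicative rules with the penalty
// absorbed into the S denominator; the objective is non-increasing.
// [[Rcpp::export]]
Rcpp::List snmf_cpp(const arma::mat& X, int k, double sparsity,
                    double tol, int max_iter,
                    const arma::mat& A0, const arma::mat& S0) {
  mat A = A0, S = S0;
  const double eps = 1e-12;
  std::vector<double> obj;
  obj.reserve(64);
  double prev = accu(square(X - A * S)) + sparsity * accu(S);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // A <- A .* (X S') ./ (A S S')
    mat SSt = S * S.t();
    A %= (X * S.t()) / (A * SSt + eps);
    // S <- S .* (A' X) ./ (A' A S + sparsity)
    mat AtA = A.t() * A;
    S %= (A.t() * X) / (AtA * S + sparsity + eps);
    double f = accu(square(X - A * S)) + sparsity * accu(S);
    obj.push_back(f);
    if ((prev - f) <= tol * std::max(1.0, std::abs(prev))) { prev = f; break; }
    prev = f;
  }
  return Rcpp::List::create(
    Rcpp::Named("A") = A,
    Rcpp::Named("S") = S,
    Rcpp::Named("objective") = prev,
    Rcpp::Named("trace") = obj,
    Rcpp::Named("iterations") = (int) obj.size());
}

// Cophenetic distances of an hclust tree (merge: (n-1) x 2, height: n-1),
// returned as a dist-style lower-triangle vector (column-major, as stats::dist).
// [[Rcpp::export]]
Rcpp::NumericVector cophenetic_cpp(const Rcpp::IntegerMatrix& merge,
                                   const Rcpp::NumericVector& height,
                                   int n) {
  int nm = merge.nrow();
  std::vector< std::vector<int> > members(nm);
  Rcpp::NumericVector d((double) n * (n - 1) / 2);
  for (int s = 0; s < nm; ++s) {
    std::vector<int> left, right;
    for (int col = 0; col < 2; ++col) {
      int v = merge(s, col);
      std::vector<int>& tgt = (col == 0) ? left : right;
      if (v < 0) tgt.push_back(-v - 1);            // leaf, 0-based
      else tgt = members[v - 1];                    // earlier cluster
    }
    double h = height[s];
    for (size_t a = 0; a < left.size(); ++a)
      for (size_t b = 0; b < right.size(); ++b) {
        int i = std::min(left[a], right[b]);
        int j = std::max(left[a], right[b]);
        // dist index for pair (i < j), 0-based
        R_xlen_t idx = (R_xlen_t) n * i - ((R_xlen_t) i * (i + 1)) / 2 + (j - i) - 1;
        d[idx] = h;
      }
    members[s] = left;
    members[s].insert(members[s].end(), right.begin(), right.end());
  }
  return d;
}
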