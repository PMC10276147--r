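// Single-pass genotype standardization: x_ij = (w_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)).

#include <Rcpp.h>

// [[Rcpp::export(name = ".standardize_geno")]]
Rcpp::NumericMatrix standardize_geno(const Rcpp::IntegerMatrix& geno,
                                     const Rcpp::NumericVector& maf) {
  const int n = geno.nrow(), p = geno.ncol();
  Rcpp::NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double mu = 2.0 * maf[j];
    const double sd = std::sqrt(2.0 * maf[j] * (1.0 - maf[j]));
    const int* gj = &geno(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) oj[i] = (gj[i] - mu) / sd;
  }
  return out;
}
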