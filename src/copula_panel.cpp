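// Latent-Gaussian-copula genotype generation. Each haplotype follows a
// first-order autoregressive latent process along the SNPs of a block
// (blocks independent); an allele is called where the latent value falls
// below the normal quantile of the SNP's minor allele frequency. Genotypes
// are the sum of two independent haplotypes (Hardy-Weinberg marginally).
//
// Draws use Armadillo's seeded generator rather than R's: the acceptance
// cohorts need billions of deviates and R-level generation would dominate
// the runtime. The seed is derived from the R RNG by the caller, so
// reproducibility under a single user-facing seed is preserved.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".copula_genotypes")]]
Rcpp::IntegerMatrix copula_genotypes(int n, const arma::vec& thr,
                                     const arma::ivec& block_id,
                                     double ld_decay, unsigned int seed) {
  const uword p = thr.n_elem;
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> rnormal(0.0, 1.0);
  Rcpp::IntegerMatrix geno((int)n, (int)p);
  const double innov_sd = std::sqrt(1.0 - ld_decay * ld_decay);
  vec z(n);
  for (int hap = 0; hap < 2; ++hap) {
    for (uword j = 0; j < p; ++j) {
      if (j == 0 || block_id(j) != block_id(j - 1)) {
        for (int i = 0; i < n; ++i) z(i) = rnormal(rng);
      } else {
        for (int i = 0; i < n; ++i)
          z(i) = ld_decay * z(i) + innov_sd * rnormal(rng);
      }
      const double t = thr(j);
      int* col = &geno(0, (int)j);
      for (int i = 0; i < n; ++i) col[i] += (z(i) < t);
    }
  }
  return geno;
}
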