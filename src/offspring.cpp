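#include <Rcpp.h>
using namespace Rcpp;

// Mendelian transmission at unlinked biallelic loci: each offspring i draws
// one allele from its mother's and one from its father's dosage,
// Bernoulli(dosage / 2) each, using R's RNG stream.
// [[Rcpp::export(name = ".mendelian_offspring")]]
IntegerMatrix mendelian_offspring(IntegerMatrix geno, IntegerVector mothers,
                                  IntegerVector fathers) {
  const int n = mothers.size();
  const int L = geno.ncol();
  IntegerMatrix out(n, L);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) {
      const double pm = geno(mothers[i] - 1, l) / 2.0;
      const double pf = geno(fathers[i] - 1, l) / 2.0;
      out(i, l) = (unif_rand() < pm) + (unif_rand() < pf);
    }
  }
  return out;
}

// Hardy-Weinberg genotypes for n diploids at loci with frequencies p.
// [[Rcpp::export(name = ".hwe_genotypes")]]
IntegerMatrix hwe_genotypes(NumericVector p, int n) {
  const int L = p.size();
  IntegerMatrix out(n, L);
  for (int l = 0; l < L; ++l) {
    const double pl = p[l];
    for (int i = 0; i < n; ++i) {
      out(i, l) = (unif_rand() < pl) + (unif_rand() < pl);
    }
  }
  return out;
}
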