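#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the cohort simulator. All randomness goes through R's RNG
// (unif_rand) so results are reproducible from set.seed() alone.

// Sample n x p genotype matrix under HWE: each entry Binomial(2, freq_j),
// realized as the sum of two Bernoulli allele draws.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_genotypes(NumericVector freqs, int n) {
  int p = freqs.size();
  IntegerMatrix g(n, p);
  for (int j = 0; j < p; ++j) {
    double f = freqs[j];
    for (int i = 0; i < n; ++i) {
      int a = (unif_rand() < f) + (unif_rand() < f);
      g(i, j) = a;
    }
  }
  return g;
}

// Mendelian transmission: offspring i receives, at each SNP independently,
// one allele from parent pa[i] and one from parent pb[i]; a parent with
// dosage d transmits the minor allele with probability d/2.
// Parent indices are 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_mate(IntegerMatrix pool, IntegerVector pa, IntegerVector pb) {
  int m = pa.size();
  int p = pool.ncol();
  IntegerMatrix off(m, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < m; ++i) {
      double fa = pool(pa[i], j) / 2.0;
      double fb = pool(pb[i], j) / 2.0;
      int a = (unif_rand() < fa) + (unif_rand() < fb);
      off(i, j) = a;
    }
  }
  return off;
}

// Column-standardize a dosage matrix for genotype PCA: center by the column
// mean and divide by sqrt(pm * (1 - pm)) where pm = mean dosage / 2.
// Monomorphic columns (pm == 0 or 1) get scale 0 and are reported in `keep`
// as FALSE so the caller can drop them.
// [[Rcpp::export]]
List cpp_normalize_genotypes(IntegerMatrix g) {
  int n = g.nrow(), p = g.ncol();
  NumericMatrix x(n, p);
  NumericVector mu(p), sc(p);
  LogicalVector keep(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += g(i, j);
    double m = s / n;
    double pm = m / 2.0;
    double v = pm * (1.0 - pm);
    mu[j] = m;
    if (v <= 0.0) {
      keep[j] = false;
      sc[j] = 0.0;
      for (int i = 0; i < n; ++i) x(i, j) = 0.0;
    } else {
      keep[j] = true;
      double inv = 1.0 / std::sqrt(v);
      sc[j] = std::sqrt(v);
      for (int i = 0; i < n; ++i) x(i, j) = (g(i, j) - m) * inv;
    }
  }
  return List::create(_["x"] = x, _["mean"] = mu, _["scale"] = sc,
                      _["keep"] = keep);
}

// Armitage trend statistic N * cor(g, y)^2 for every column of a dosage
// matrix against a binary phenotype. Constant columns return NA.
// [[Rcpp::export]]
NumericVector cpp_trend_statistics(IntegerMatrix g, IntegerVector y) {
  int n = g.nrow(), p = g.ncol();
  double sy = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) { sy += y[i]; syy += (double)y[i] * y[i]; }
  double vy = syy - sy * sy / n;
  NumericVector t(p);
  for (int j = 0; j < p; ++j) {
    double sg = 0.0, sgg = 0.0, sgy = 0.0;
    for (int i = 0; i < n; ++i) {
      double gij = g(i, j);
      sg += gij;
      sgg += gij * gij;
      sgy += gij * y[i];
    }
    double vg = sgg - sg * sg / n;
    double cgy = sgy - sg * sy / n;
    if (vg <= 0.0 || vy <= 0.0) {
      t[j] = NA_REAL;
    } else {
      t[j] = n * (cgy * cgy) / (vg * vy);
    }
  }
  return t;
}
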