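#include <Rcpp.h>
using namespace Rcpp;

// Non-inbred dyadic IBD model: a dyad shares 0, 1 or 2 alleles identical by
// descent with probabilities k = (k0, k1, k2).  Per locus, the probability of
// the observed unordered genotype pair is linear in k, so the log-likelihood
// over loci is concave in k on the 2-simplex and EM converges to the global
// maximum.  Allele codes are 1-based indices into the locus frequency vector;
// NA marks a missing genotype (the locus is skipped for that dyad).

// P(genotype {a,b}) under HWE
static inline double geno_prob(int a, int b, const NumericVector &p) {
  return (a == b) ? p[a - 1] * p[a - 1] : 2.0 * p[a - 1] * p[b - 1];
}

// Mode probabilities for one locus: pr[0] = P(pair | 0 IBD), etc.
// P1 uses the gene-assignment sum: over the four cross choices of one allele
// from each individual, matching choices contribute p(shared) * p(other1) *
// p(other2); the sum is divided by 2 per homozygous individual so unordered
// heterozygotes are counted once per phase.
static void mode_probs(int a, int b, int c, int d, const NumericVector &p,
                       double pr[3]) {
  pr[0] = geno_prob(a, b, p) * geno_prob(c, d, p);
  double s = 0.0;
  const int x[2] = {a, b}, y[2] = {c, d};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      if (x[i] == y[j])
        s += p[x[i] - 1] * p[x[1 - i] - 1] * p[y[1 - j] - 1];
  int hom = (a == b ? 1 : 0) + (c == d ? 1 : 0);
  pr[1] = s / double(1 << hom);
  pr[2] = ((a == c && b == d) || (a == d && b == c)) ? geno_prob(a, b, p) : 0.0;
}

static double loglik_at(const std::vector<double> &P, int L, const double k[3]) {
  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    double den = k[0] * P[3 * l] + k[1] * P[3 * l + 1] + k[2] * P[3 * l + 2];
    if (den <= 0.0) return R_NegInf;
    ll += std::log(den);
  }
  return ll;
}

// EM over mixture weights; ties within tol are broken toward the k0 = 1
// boundary (the unrelated solution) for determinism.
static void em_fit(const std::vector<double> &P, int L, double tol, int maxit,
                   double kout[3], double &llout) {
  double k[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
  double ll = loglik_at(P, L, k);
  for (int it = 0; it < maxit; ++it) {
    double acc[3] = {0.0, 0.0, 0.0};
    for (int l = 0; l < L; ++l) {
      double p0 = k[0] * P[3 * l], p1 = k[1] * P[3 * l + 1],
             p2 = k[2] * P[3 * l + 2];
      double den = p0 + p1 + p2;
      if (den <= 0.0) continue;
      acc[0] += p0 / den;
      acc[1] += p1 / den;
      acc[2] += p2 / den;
    }
    double tot = acc[0] + acc[1] + acc[2];
    if (tot <= 0.0) break;
    k[0] = acc[0] / tot; k[1] = acc[1] / tot; k[2] = acc[2] / tot;
    double llnew = loglik_at(P, L, k);
    if (llnew - ll < tol && it > 2) { ll = llnew; break; }
    ll = llnew;
  }
  const double corner[3] = {1.0, 0.0, 0.0};
  double llc = loglik_at(P, L, corner);
  if (llc >= ll - 1e-8) {
    kout[0] = 1.0; kout[1] = 0.0; kout[2] = 0.0; llout = llc;
  } else {
    kout[0] = k[0]; kout[1] = k[1]; kout[2] = k[2]; llout = ll;
  }
}

// Fill per-locus mode probabilities for dyad d; returns number of usable loci.
static int fill_probs(const IntegerMatrix &ga1, const IntegerMatrix &ga2,
                      const IntegerMatrix &gb1, const IntegerMatrix &gb2,
                      int d, const std::vector<NumericVector> &freqs,
                      std::vector<double> &P) {
  int L = ga1.ncol(), used = 0;
  for (int l = 0; l < L; ++l) {
    int a = ga1(d, l), b = ga2(d, l), c = gb1(d, l), e = gb2(d, l);
    if (a == NA_INTEGER || c == NA_INTEGER) continue;
    double pr[3];
    mode_probs(a, b, c, e, freqs[l], pr);
    P[3 * used] = pr[0]; P[3 * used + 1] = pr[1]; P[3 * used + 2] = pr[2];
    ++used;
  }
  return used;
}

// [[Rcpp::export(name = ".ml_dyads_cpp")]]
List ml_dyads_cpp(IntegerMatrix ga1, IntegerMatrix ga2, IntegerMatrix gb1,
                  IntegerMatrix gb2, List freqs, double tol = 1e-11,
                  int maxit = 3000) {
  int n = ga1.nrow(), L = ga1.ncol();
  std::vector<NumericVector> fv(L);
  for (int l = 0; l < L; ++l) fv[l] = freqs[l];
  NumericVector r(n), ll(n);
  IntegerVector nloci(n);
  NumericMatrix k(n, 3);
  std::vector<double> P(3 * L);
  for (int d = 0; d < n; ++d) {
    int used = fill_probs(ga1, ga2, gb1, gb2, d, fv, P);
    nloci[d] = used;
    if (used == 0) {
      r[d] = NA_REAL; ll[d] = NA_REAL;
      k(d, 0) = NA_REAL; k(d, 1) = NA_REAL; k(d, 2) = NA_REAL;
      continue;
    }
    double kk[3], l0;
    em_fit(P, used, tol, maxit, kk, l0);
    k(d, 0) = kk[0]; k(d, 1) = kk[1]; k(d, 2) = kk[2];
    r[d] = kk[2] + 0.5 * kk[1];
    ll[d] = l0;
  }
  return List::create(_["r"] = r, _["k"] = k, _["loglik"] = ll,
                      _["nloci"] = nloci);
}

// Triadic (reference-augmented) ML: each reference individual's two gene
// copies are added to the allele-frequency estimate (counts-weighted with the
// locus's 2*n_typed gene copies), acting as a control for identity in state;
// the dyadic likelihood is maximized under the augmented frequencies and r is
// averaged over reference draws.
// ra1/ra2: nref x L allele indices of the sampled references (NA = missing).
// [[Rcpp::export(name = ".ml_dyads_ref_cpp")]]
List ml_dyads_ref_cpp(IntegerMatrix ga1, IntegerMatrix ga2, IntegerMatrix gb1,
                      IntegerMatrix gb2, IntegerMatrix ra1, IntegerMatrix ra2,
                      List freqs, NumericVector two_n, double tol = 1e-11,
                      int maxit = 3000, bool return_all = false) {
  int n = ga1.nrow(), L = ga1.ncol(), nref = ra1.nrow();
  std::vector<NumericVector> fv(L);
  for (int l = 0; l < L; ++l) fv[l] = freqs[l];

  // per-reference augmented frequencies
  std::vector<std::vector<NumericVector> > aug(nref,
                                               std::vector<NumericVector>(L));
  for (int rf = 0; rf < nref; ++rf) {
    for (int l = 0; l < L; ++l) {
      NumericVector p = clone(fv[l]);
      int a = ra1(rf, l), b = ra2(rf, l);
      if (a != NA_INTEGER) {
        double tn = two_n[l];
        for (int i = 0; i < p.size(); ++i) p[i] = tn * p[i] / (tn + 2.0);
        p[a - 1] += 1.0 / (tn + 2.0);
        p[b - 1] += 1.0 / (tn + 2.0);
      }
      aug[rf][l] = p;
    }
  }

  NumericVector r_mean(n);
  NumericMatrix k_mean(n, 3);
  IntegerVector nloci(n);
  NumericMatrix r_all(return_all ? n : 1, return_all ? nref : 1);
  std::vector<double> P(3 * L);
  for (int d = 0; d < n; ++d) {
    double rsum = 0.0, ksum[3] = {0.0, 0.0, 0.0};
    int used0 = 0;
    bool any = false;
    for (int rf = 0; rf < nref; ++rf) {
      int used = fill_probs(ga1, ga2, gb1, gb2, d, aug[rf], P);
      used0 = used;
      if (used == 0) break;
      any = true;
      double kk[3], l0;
      em_fit(P, used, tol, maxit, kk, l0);
      double rr = kk[2] + 0.5 * kk[1];
      rsum += rr;
      ksum[0] += kk[0]; ksum[1] += kk[1]; ksum[2] += kk[2];
      if (return_all) r_all(d, rf) = rr;
    }
    nloci[d] = used0;
    if (!any) {
      r_mean[d] = NA_REAL;
      k_mean(d, 0) = NA_REAL; k_mean(d, 1) = NA_REAL; k_mean(d, 2) = NA_REAL;
      if (return_all) for (int rf = 0; rf < nref; ++rf) r_all(d, rf) = NA_REAL;
      continue;
    }
    r_mean[d] = rsum / nref;
    for (int m = 0; m < 3; ++m) k_mean(d, m) = ksum[m] / nref;
  }
  List out = List::create(_["r"] = r_mean, _["k"] = k_mean,
                          _["nloci"] = nloci);
  if (return_all) out["r_all"] = r_all;
  return out;
}
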