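#include <Rcpp.h>
using namespace Rcpp;

// Binomial pmf with exact handling of p = 0 / p = 1 boundaries.
// lch = lchoose(n, k) precomputed.
static inline double binom_pmf(int k, int n, double p, double lch) {
  if (p <= 0.0) return k == 0 ? 1.0 : 0.0;
  if (p >= 1.0) return k == n ? 1.0 : 0.0;
  return std::exp(lch + k * std::log(p) + (n - k) * std::log1p(-p));
}

// Composite log-likelihoods for one scan window.
//
// Per SNP i the neutral allele-frequency density in the object population is
// a normal around the reference frequency p1[i] with variance
// omega * p1 (1 - p1), truncated to (0,1) with the clipped tails collapsed
// to atoms at 0 and 1. It is discretised as exact cell masses on nq midpoint
// cells (mass[, i], atom0[i], atom1[i], computed in R with pnorm). The sweep
// model mixes the neutral density (escape probability c = 1 - exp(-r/s))
// with a hitchhiking map of the neutral variable u: with probability p1 the
// beneficial background carries the derived allele and u -> 1 - c + c u,
// otherwise u -> c u.
//
// Returns: ll0 (weighted neutral log-likelihood) and ll1[s] per s-grid value.
// sigma[i] == 0 marks a point-mass density at p1[i] (omega == 0 degenerate
// case).
// [[Rcpp::export(name = ".xpclr_window_ll")]]
List xpclr_window_ll(IntegerVector k, IntegerVector n, NumericVector p1,
                     NumericVector r, NumericVector w, NumericVector sigma,
                     NumericMatrix mass, NumericVector mid,
                     NumericVector atom0, NumericVector atom1,
                     NumericVector s_grid) {
  const int m = k.size();
  const int nq = mid.size();
  const int ns = s_grid.size();
  const double floor_lik = 1e-300;

  std::vector<double> lch(m), L0(m);
  for (int i = 0; i < m; ++i) {
    lch[i] = R::lchoose(n[i], k[i]);
    if (sigma[i] == 0.0) {
      L0[i] = binom_pmf(k[i], n[i], p1[i], lch[i]);
    } else {
      double acc = atom0[i] * binom_pmf(k[i], n[i], 0.0, lch[i]) +
                   atom1[i] * binom_pmf(k[i], n[i], 1.0, lch[i]);
      for (int j = 0; j < nq; ++j)
        acc += mass(j, i) * binom_pmf(k[i], n[i], mid[j], lch[i]);
      L0[i] = acc;
    }
  }

  double ll0 = 0.0;
  for (int i = 0; i < m; ++i)
    ll0 += w[i] * std::log(std::max(L0[i], floor_lik));

  NumericVector ll1(ns);
  for (int si = 0; si < ns; ++si) {
    const double s = s_grid[si];
    double acc_ll = 0.0;
    for (int i = 0; i < m; ++i) {
      const double c = 1.0 - std::exp(-r[i] / s);
      double dragged;
      if (sigma[i] == 0.0) {
        const double u = p1[i];
        dragged = p1[i] * binom_pmf(k[i], n[i], 1.0 - c + c * u, lch[i]) +
                  (1.0 - p1[i]) * binom_pmf(k[i], n[i], c * u, lch[i]);
      } else {
        double d1 = atom0[i] * binom_pmf(k[i], n[i], 1.0 - c, lch[i]) +
                    atom1[i] * binom_pmf(k[i], n[i], 1.0, lch[i]);
        double d0 = atom0[i] * binom_pmf(k[i], n[i], 0.0, lch[i]) +
                    atom1[i] * binom_pmf(k[i], n[i], c, lch[i]);
        for (int j = 0; j < nq; ++j) {
          const double mj = mass(j, i);
          if (mj == 0.0) continue;
          d1 += mj * binom_pmf(k[i], n[i], 1.0 - c + c * mid[j], lch[i]);
          d0 += mj * binom_pmf(k[i], n[i], c * mid[j], lch[i]);
        }
        dragged = p1[i] * d1 + (1.0 - p1[i]) * d0;
      }
      const double L1 = c * L0[i] + (1.0 - c) * dragged;
      acc_ll += w[i] * std::log(std::max(L1, floor_lik));
    }
    ll1[si] = acc_ll;
  }

  return List::create(_["ll0"] = ll0, _["ll1"] = ll1);
}

// Assemble one Wright-Fisher offspring generation from parental haplotypes.
// H: S x 2N haplotype matrix (sites in rows, one column per haplotype, so a
// haplotype copy is contiguous); pos: sorted site positions; parent: 1-based
// parent individual per gamete; first: 1 or 2, the haplotype the gamete
// starts on; bp: concatenated crossover positions with offsets bp_off
// (length nhap + 1). All randomness is drawn in R so runs stay reproducible
// under set.seed().
// [[Rcpp::export(name = ".wf_next_gen")]]
IntegerMatrix wf_next_gen(IntegerMatrix H, IntegerVector pos,
                          IntegerVector parent, IntegerVector first,
                          NumericVector bp, IntegerVector bp_off) {
  const int S = H.nrow(), nhap = H.ncol();
  IntegerMatrix child(S, nhap);
  const int* h = H.begin();
  int* ch = child.begin();
  std::vector<double> cuts;
  for (int i = 0; i < nhap; ++i) {
    const int p = parent[i] - 1;
    const int f = first[i] - 1;
    const int* c1 = h + (size_t)(2 * p + f) * S;
    const int* c2 = h + (size_t)(2 * p + (1 - f)) * S;
    int* out = ch + (size_t)i * S;
    const int nb = bp_off[i + 1] - bp_off[i];
    if (nb == 0) {
      std::copy(c1, c1 + S, out);
      continue;
    }
    cuts.assign(bp.begin() + bp_off[i], bp.begin() + bp_off[i + 1]);
    std::sort(cuts.begin(), cuts.end());
    int bi = 0;
    for (int j = 0; j < S; ++j) {
      while (bi < nb && pos[j] > cuts[bi]) ++bi;
      out[j] = (bi % 2 == 0) ? c1[j] : c2[j];
    }
  }
  return child;
}
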