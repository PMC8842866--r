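#include <Rcpp.h>
using namespace Rcpp;

// Bivalent-only polyploid meiosis.
//
// A gamete is formed chromosome by chromosome: the ploidy homologues are
// paired uniformly at random into ploidy/2 bivalents, and each bivalent
// yields one recombinant chromatid via a two-state Markov walk along the
// ordered markers.  The walk starts on either homologue with probability 1/2
// and switches between adjacent markers with probability equal to the
// Haldane recombination fraction for that interval (no interference).
// Founder labels ride along with the walk, so identity-by-descent is
// propagated segment-wise for free.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() gives
// bit-reproducible simulations.

// Uniformly random perfect matching of 0..(ploidy-1): Fisher-Yates shuffle,
// then consecutive entries form the pairs.
static void random_pairing(int ploidy, std::vector<int> &perm) {
  perm.resize(ploidy);
  for (int i = 0; i < ploidy; ++i) perm[i] = i;
  for (int i = ploidy - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
}

// One recombinant chromatid for the bivalent (h1, h2) over markers
// [lo, hi) of `labels` (rows = homologues of one parent), written into
// row `orow` of `out`.
static void walk_chromatid(const IntegerMatrix &labels, int h1, int h2,
                           const NumericVector &r_adj, int lo, int hi,
                           IntegerMatrix &out, int orow) {
  int cur = (unif_rand() < 0.5) ? h1 : h2;
  out(orow, lo) = labels(cur, lo);
  for (int j = lo + 1; j < hi; ++j) {
    if (unif_rand() < r_adj[j - 1]) cur = (cur == h1) ? h2 : h1;
    out(orow, j) = labels(cur, j);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_chromatid(IntegerMatrix parent, int h1, int h2,
                            NumericVector r_adj) {
  // single-chromosome walk over all columns of `parent`; h1/h2 0-based
  int m = parent.ncol();
  IntegerMatrix out(1, m);
  walk_chromatid(parent, h1, h2, r_adj, 0, m, out, 0);
  return out;
}

// One gamete from `parent` (ploidy x m labels).  chrom_start holds the
// 0-based first-marker index of each chromosome plus a terminal m.
// r_adj[j] is the recombination fraction between markers j and j+1
// (entries at chromosome boundaries are never read).
static void gamete_into(const IntegerMatrix &parent, int ploidy,
                        const IntegerVector &chrom_start,
                        const NumericVector &r_adj,
                        IntegerMatrix &out, int orow0) {
  int nchrom = chrom_start.size() - 1;
  std::vector<int> perm;
  for (int c = 0; c < nchrom; ++c) {
    int lo = chrom_start[c], hi = chrom_start[c + 1];
    random_pairing(ploidy, perm);          // fresh pairing per chromosome
    for (int b = 0; b < ploidy / 2; ++b)
      walk_chromatid(parent, perm[2 * b], perm[2 * b + 1], r_adj, lo, hi,
                     out, orow0 + b);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_gamete(IntegerMatrix parent, IntegerVector chrom_start,
                         NumericVector r_adj) {
  int ploidy = parent.nrow(), m = parent.ncol();
  IntegerMatrix out(ploidy / 2, m);
  gamete_into(parent, ploidy, chrom_start, r_adj, out, 0);
  return out;
}

// Batch crossing: pop_labels stacks individuals' homologues
// ((n_ind * ploidy) x m); mother_idx / father_idx are 1-based individual
// indices, one per offspring.  Output stacks offspring homologues in the
// same layout: maternal gamete rows first, then paternal.
// [[Rcpp::export]]
IntegerMatrix cpp_cross_batch(IntegerMatrix pop_labels, int ploidy,
                              IntegerVector mother_idx,
                              IntegerVector father_idx,
                              IntegerVector chrom_start,
                              NumericVector r_adj) {
  int m = pop_labels.ncol();
  int n_off = mother_idx.size();
  int half = ploidy / 2;
  IntegerMatrix out(n_off * ploidy, m);
  IntegerMatrix parent(ploidy, m);
  for (int o = 0; o < n_off; ++o) {
    int mi = mother_idx[o] - 1, fi = father_idx[o] - 1;
    for (int h = 0; h < ploidy; ++h)
      for (int j = 0; j < m; ++j) parent(h, j) = pop_labels(mi * ploidy + h, j);
    gamete_into(parent, ploidy, chrom_start, r_adj, out, o * ploidy);
    for (int h = 0; h < ploidy; ++h)
      for (int j = 0; j < m; ++j) parent(h, j) = pop_labels(fi * ploidy + h, j);
    gamete_into(parent, ploidy, chrom_start, r_adj, out, o * ploidy + half);
  }
  return out;
}
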