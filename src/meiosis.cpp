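#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis under the Haldane model: per chromosome the crossover count is
// Poisson with mean equal to the chromosome length in Morgans, crossover
// positions are independent uniform on (0, L), the starting strand is chosen
// with probability 1/2, and the active strand switches at every crossover.
// Uses R's RNG stream so that set.seed() makes whole simulations reproducible.
//
// H1, H2: haplotype matrices (individuals x markers), markers ordered by
// chromosome then map position, `mpc` markers per chromosome, all chromosomes
// equal length `chrom_len` (cM) with within-chromosome marker positions `pos`.
// `parent` holds 1-based row indices into H1/H2; one gamete is produced per
// entry, in order.
// cache-blocked transpose between an R column-major matrix (nr x nc) and a
// row-contiguous buffer (nr rows of length nc)
static void to_rowmajor(const IntegerMatrix& X, std::vector<int>& buf) {
  const int nr = X.nrow(), nc = X.ncol(), B = 64;
  buf.resize((size_t) nr * nc);
  for (int j0 = 0; j0 < nc; j0 += B)
    for (int i0 = 0; i0 < nr; i0 += B) {
      const int j1 = std::min(j0 + B, nc), i1 = std::min(i0 + B, nr);
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i)
          buf[(size_t) i * nc + j] = X(i, j);
    }
}

static IntegerMatrix from_rowmajor(const std::vector<int>& buf, int nr, int nc) {
  IntegerMatrix out(nr, nc);
  const int B = 64;
  for (int j0 = 0; j0 < nc; j0 += B)
    for (int i0 = 0; i0 < nr; i0 += B) {
      const int j1 = std::min(j0 + B, nc), i1 = std::min(i0 + B, nr);
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i)
          out(i, j) = buf[(size_t) i * nc + j];
    }
  return out;
}

// one gamete from parent haplotypes s1/s2 into dst (all length M, contiguous)
static void meiose(const int* s1, const int* s2, int* dst, int n_chrom,
                   int mpc, double chrom_len, const double* pos,
                   double morgans, std::vector<double>& xo) {
  for (int c = 0; c < n_chrom; ++c) {
    const int off = c * mpc;
    int k = (int) R::rpois(morgans);
    bool strand1 = unif_rand() < 0.5;  // true: read s1
    if (k == 0) {
      const int* src = strand1 ? s1 + off : s2 + off;
      std::copy(src, src + mpc, dst + off);
      continue;
    }
    xo.resize(k);
    for (int i = 0; i < k; ++i) xo[i] = unif_rand() * chrom_len;
    std::sort(xo.begin(), xo.end());
    int ptr = 0;
    for (int j = 0; j < mpc; ++j) {
      while (ptr < k && xo[ptr] < pos[j]) { strand1 = !strand1; ++ptr; }
      dst[off + j] = strand1 ? s1[off + j] : s2[off + j];
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& H1, const IntegerMatrix& H2,
                          const IntegerVector& parent, int n_chrom, int mpc,
                          double chrom_len, const NumericVector& pos) {
  const int n = parent.size();
  const int np = H1.nrow();
  const int M = n_chrom * mpc;
  if (H1.ncol() != M || H2.ncol() != M)
    stop("haplotype matrices do not match the genetic map");
  for (int g = 0; g < n; ++g)
    if (parent[g] < 1 || parent[g] > np) stop("parent index out of range");
  std::vector<int> h1t, h2t;
  to_rowmajor(H1, h1t);
  to_rowmajor(H2, h2t);
  std::vector<int> res((size_t) n * M);
  const double morgans = chrom_len / 100.0;
  std::vector<double> xo;
  for (int g = 0; g < n; ++g) {
    const size_t p = (size_t) (parent[g] - 1) * M;
    meiose(&h1t[p], &h2t[p], &res[(size_t) g * M], n_chrom, mpc, chrom_len,
           pos.begin(), morgans, xo);
  }
  return from_rowmajor(res, n, M);
}

// two independent gametes per parent entry, united into one offspring
// (selfing); returns a list with the two haplotype matrices
// [[Rcpp::export]]
List cpp_self_gametes(const IntegerMatrix& H1, const IntegerMatrix& H2,
                      const IntegerVector& parent, int n_chrom, int mpc,
                      double chrom_len, const NumericVector& pos) {
  const int n = parent.size();
  const int np = H1.nrow();
  const int M = n_chrom * mpc;
  if (H1.ncol() != M || H2.ncol() != M)
    stop("haplotype matrices do not match the genetic map");
  for (int g = 0; g < n; ++g)
    if (parent[g] < 1 || parent[g] > np) stop("parent index out of range");
  std::vector<int> h1t, h2t;
  to_rowmajor(H1, h1t);
  to_rowmajor(H2, h2t);
  std::vector<int> r1((size_t) n * M), r2((size_t) n * M);
  const double morgans = chrom_len / 100.0;
  std::vector<double> xo;
  for (int g = 0; g < n; ++g) {
    const size_t p = (size_t) (parent[g] - 1) * M;
    meiose(&h1t[p], &h2t[p], &r1[(size_t) g * M], n_chrom, mpc, chrom_len,
           pos.begin(), morgans, xo);
    meiose(&h1t[p], &h2t[p], &r2[(size_t) g * M], n_chrom, mpc, chrom_len,
           pos.begin(), morgans, xo);
  }
  return List::create(_["H1"] = from_rowmajor(r1, n, M),
                      _["H2"] = from_rowmajor(r2, n, M));
}

// Row sums of donor allele counts (H1 + H2) over a column block [a, b]
// (1-based, inclusive). Avoids materialising sub-matrix copies in R during
// per-generation selection-index evaluation.
// [[Rcpp::export]]
NumericVector cpp_block_rowsums(const IntegerMatrix& H1, const IntegerMatrix& H2,
                                int a, int b) {
  const int n = H1.nrow();
  NumericVector out(n);
  for (int j = a - 1; j < b; ++j)
    for (int i = 0; i < n; ++i) out[i] += H1(i, j) + H2(i, j);
  return out;
}

// Number of maximal marker intervals within which the joint genotype pattern
// of all rows (haplotypes) is constant, per chromosome block, i.e. distinct
// internal breakpoints + 1 for each chromosome, summed.
// [[Rcpp::export]]
int cpp_pattern_intervals(const IntegerMatrix& H, int n_chrom, int mpc) {
  const int n = H.nrow();
  int total = 0;
  for (int c = 0; c < n_chrom; ++c) {
    const int off = c * mpc;
    int segs = 1;
    for (int j = 1; j < mpc; ++j) {
      for (int i = 0; i < n; ++i) {
        if (H(i, off + j) != H(i, off + j - 1)) { ++segs; break; }
      }
    }
    total += segs;
  }
  return total;
}
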