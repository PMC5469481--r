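// Bit-packed genotype comparison kernels.
//
// Genotypes over the fingerprint panel are stored two bits per SNP in paired
// 64-bit words (hi, lo):
//   00 hom allele1, 01 het, 10 hom allele2, 11 missing.
// This code table makes "missing" = hi & lo and "homozygous" = !lo, so the
// pairwise counts reduce to a handful of bitwise ops plus popcounts:
//   valid    = ~(hiA & loA) & ~(hiB & loB)        both genotyped
//   mismatch = ((hiA ^ hiB) | (loA ^ loB)) & valid genotypes differ (IBS < 2)
//   bothhom  = ~loA & ~loB & valid                 two homozygous genotypes
//   DO       = bothhom & (hiA ^ hiB)               different homozygotes
// Words are held column-wise in raw matrices (8 bytes per word); pad bits
// beyond the panel are set to missing so no length masking is needed.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

static inline uint64_t load_word(const Rbyte* p) {
  uint64_t x;
  std::memcpy(&x, p, 8);
  return x;
}

static inline int popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// Pack an S x n genotype matrix (codes 0/1/2/NA) into hi/lo raw word matrices.
// [[Rcpp::export]]
List cpp_pack(IntegerMatrix geno) {
  const int S = geno.nrow(), n = geno.ncol();
  const int W = (S + 63) / 64;
  RawMatrix hi(8 * W, n), lo(8 * W, n);
  IntegerVector ngen(n);
  Rbyte* H = hi.begin();
  Rbyte* L = lo.begin();
  for (int j = 0; j < n; ++j) {
    int cnt = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t hw = 0, lw = 0;
      const int base = w * 64;
      for (int b = 0; b < 64; ++b) {
        const int i = base + b;
        const uint64_t bit = 1ULL << b;
        int g = (i < S) ? geno(i, j) : NA_INTEGER;
        if (g == NA_INTEGER) {
          hw |= bit; lw |= bit;
        } else if (g == 0) {
          ++cnt;
        } else if (g == 1) {
          lw |= bit; ++cnt;
        } else if (g == 2) {
          hw |= bit; ++cnt;
        } else {
          stop("genotype codes must be 0, 1, 2 or NA");
        }
      }
      std::memcpy(H + (size_t)j * 8 * W + 8 * w, &hw, 8);
      std::memcpy(L + (size_t)j * 8 * W + 8 * w, &lw, 8);
    }
    ngen[j] = cnt;
  }
  return List::create(_["hi"] = hi, _["lo"] = lo, _["n_genotyped"] = ngen);
}

// Inverse of cpp_pack, used for round-trip checks and persistence.
// [[Rcpp::export]]
IntegerMatrix cpp_unpack(RawMatrix hi, RawMatrix lo, int S) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  IntegerMatrix geno(S, n);
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  for (int j = 0; j < n; ++j) {
    for (int w = 0; w < W; ++w) {
      const uint64_t hw = load_word(H + (size_t)j * 8 * W + 8 * w);
      const uint64_t lw = load_word(L + (size_t)j * 8 * W + 8 * w);
      const int base = w * 64;
      for (int b = 0; b < 64 && base + b < S; ++b) {
        const uint64_t bit = 1ULL << b;
        const bool h = hw & bit, l = lw & bit;
        int g;
        if (h && l) g = NA_INTEGER;
        else if (h) g = 2;
        else if (l) g = 1;
        else g = 0;
        geno(base + b, j) = g;
      }
    }
  }
  return geno;
}

struct PairCounts {
  long long nc, nm, nb, ndo;
};

static inline PairCounts pair_counts(const Rbyte* H, const Rbyte* L,
                                     size_t colbytes, int W, int a, int b) {
  const Rbyte* ha = H + (size_t)a * colbytes;
  const Rbyte* la = L + (size_t)a * colbytes;
  const Rbyte* hb = H + (size_t)b * colbytes;
  const Rbyte* lb = L + (size_t)b * colbytes;
  PairCounts c = {0, 0, 0, 0};
  for (int w = 0; w < W; ++w) {
    const uint64_t hiA = load_word(ha + 8 * w), loA = load_word(la + 8 * w);
    const uint64_t hiB = load_word(hb + 8 * w), loB = load_word(lb + 8 * w);
    const uint64_t valid = ~(hiA & loA) & ~(hiB & loB);
    const uint64_t mism = ((hiA ^ hiB) | (loA ^ loB)) & valid;
    const uint64_t both = ~loA & ~loB & valid;
    const uint64_t dow = both & (hiA ^ hiB);
    c.nc += popcnt(valid);
    c.nm += popcnt(mism);
    c.nb += popcnt(both);
    c.ndo += popcnt(dow);
  }
  return c;
}

// Counts for an explicit list of (0-based) index pairs.
// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(RawMatrix hi, RawMatrix lo,
                              IntegerVector ii, IntegerVector jj) {
  const int W = hi.nrow() / 8;
  const size_t colbytes = 8 * (size_t)W;
  const int np = ii.size();
  NumericMatrix out(np, 4);
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  for (int p = 0; p < np; ++p) {
    PairCounts c = pair_counts(H, L, colbytes, W, ii[p], jj[p]);
    out(p, 0) = (double)c.nc;
    out(p, 1) = (double)c.nm;
    out(p, 2) = (double)c.nb;
    out(p, 3) = (double)c.ndo;
  }
  return out;
}

// Exhaustive all-pairs counts: n(n-1)/2 rows of (i, j, counts), 1-based ids.
// [[Rcpp::export]]
NumericMatrix cpp_all_pair_counts(RawMatrix hi, RawMatrix lo) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  const size_t colbytes = 8 * (size_t)W;
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  NumericMatrix out(np, 6);
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  R_xlen_t r = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      PairCounts c = pair_counts(H, L, colbytes, W, i, j);
      out(r, 0) = i + 1;
      out(r, 1) = j + 1;
      out(r, 2) = (double)c.nc;
      out(r, 3) = (double)c.nm;
      out(r, 4) = (double)c.nb;
      out(r, 5) = (double)c.ndo;
    }
  }
  return out;
}

// Full-panel exhaustive duplicate scan: returns rows (i, j, counts) for pairs
// with n_compared >= min_compared and AGMR < cutoff (1-based indices).
// [[Rcpp::export]]
NumericMatrix cpp_naive_scan(RawMatrix hi, RawMatrix lo,
                             double agmr_cutoff, int min_compared) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  const size_t colbytes = 8 * (size_t)W;
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  std::vector<double> rows;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      PairCounts c = pair_counts(H, L, colbytes, W, i, j);
      if (c.nc >= min_compared &&
          (double)c.nm < agmr_cutoff * (double)c.nc) {
        rows.push_back(i + 1);
        rows.push_back(j + 1);
        rows.push_back((double)c.nc);
        rows.push_back((double)c.nm);
        rows.push_back((double)c.nb);
        rows.push_back((double)c.ndo);
      }
    }
  }
  const R_xlen_t np = rows.size() / 6;
  NumericMatrix out(np, 6);
  for (R_xlen_t r = 0; r < np; ++r)
    for (int k = 0; k < 6; ++k) out(r, k) = rows[r * 6 + k];
  return out;
}

// Early-termination screen: per pair, accumulate 64-SNP blocks until at least
// m non-missing comparisons are seen; the pair survives when fewer than k
// mismatches were observed by then (or over all blocks if fewer than m
// non-missing comparisons exist). Survivors are verified over the full panel
// by the caller. Returns a 2-column matrix of surviving 1-based index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_quadratic_screen(RawMatrix hi, RawMatrix lo, int m, int k) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  const size_t colbytes = 8 * (size_t)W;
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  std::vector<int> rows;
  for (int i = 0; i < n - 1; ++i) {
    const Rbyte* ha = H + (size_t)i * colbytes;
    const Rbyte* la = L + (size_t)i * colbytes;
    for (int j = i + 1; j < n; ++j) {
      const Rbyte* hb = H + (size_t)j * colbytes;
      const Rbyte* lb = L + (size_t)j * colbytes;
      long long nc = 0, nm = 0;
      bool keep = true;
      for (int w = 0; w < W; ++w) {
        const uint64_t hiA = load_word(ha + 8 * w), loA = load_word(la + 8 * w);
        const uint64_t hiB = load_word(hb + 8 * w), loB = load_word(lb + 8 * w);
        const uint64_t valid = ~(hiA & loA) & ~(hiB & loB);
        const uint64_t mism = ((hiA ^ hiB) | (loA ^ loB)) & valid;
        nc += popcnt(valid);
        nm += popcnt(mism);
        if (nm >= k) { keep = false; break; }
        if (nc >= m) break;
      }
      if (keep) {
        rows.push_back(i + 1);
        rows.push_back(j + 1);
      }
    }
  }
  const int np = rows.size() / 2;
  IntegerMatrix out(np, 2);
  for (int r = 0; r < np; ++r) {
    out(r, 0) = rows[2 * r];
    out(r, 1) = rows[2 * r + 1];
  }
  return out;
}

// Sort keys for the sub-quadratic scan: pack the 2-bit genotype codes of the
// selected SNPs (0-based indices into the panel) into one number per sample.
// Any missing genotype among the selected SNPs yields NA (sentinel).
// Exact for m <= 26 (keys < 2^52 fit a double).
// [[Rcpp::export]]
NumericVector cpp_sort_keys(RawMatrix hi, RawMatrix lo, IntegerVector snps) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  const size_t colbytes = 8 * (size_t)W;
  const int m = snps.size();
  if (m > 26) stop("at most 26 SNPs per sort key");
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  NumericVector key(n);
  for (int j = 0; j < n; ++j) {
    const Rbyte* hj = H + (size_t)j * colbytes;
    const Rbyte* lj = L + (size_t)j * colbytes;
    double acc = 0;
    bool ok = true;
    for (int s = 0; s < m; ++s) {
      const int idx = snps[s];
      const int w = idx >> 6, b = idx & 63;
      const uint64_t bit = 1ULL << b;
      const bool h = load_word(hj + 8 * w) & bit;
      const bool l = load_word(lj + 8 * w) & bit;
      if (h && l) { ok = false; break; }
      acc = acc * 4.0 + (h ? 2.0 : (l ? 1.0 : 0.0));
    }
    key[j] = ok ? acc : NA_REAL;
  }
  return key;
}

// Per-SNP missing counts across samples (for the sub-quadratic SNP pool).
// [[Rcpp::export]]
IntegerVector cpp_missing_counts(RawMatrix hi, RawMatrix lo, int S) {
  const int W = hi.nrow() / 8, n = hi.ncol();
  const size_t colbytes = 8 * (size_t)W;
  const Rbyte* H = hi.begin();
  const Rbyte* L = lo.begin();
  IntegerVector cnt(S);
  for (int j = 0; j < n; ++j) {
    for (int w = 0; w < W; ++w) {
      uint64_t miss = load_word(H + (size_t)j * colbytes + 8 * w) &
                      load_word(L + (size_t)j * colbytes + 8 * w);
      const int base = w * 64;
      while (miss) {
        const int b = __builtin_ctzll(miss);
        if (base + b < S) ++cnt[base + b];
        miss &= miss - 1;
      }
    }
  }
  return cnt;
}
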