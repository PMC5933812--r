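#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Haplotypes are bit-packed per row: allele words (NA -> 0) and validity
// words (NA -> 0), so the difference count for a pair is
// popcount((a_i ^ a_j) & v_i & v_j) summed over words.

static void pack_rows(const IntegerMatrix& haps,
                      std::vector<std::vector<uint64_t> >& alleles,
                      std::vector<std::vector<uint64_t> >& valid) {
  int n = haps.nrow(), S = haps.ncol();
  int W = (S + 63) / 64;
  alleles.assign(n, std::vector<uint64_t>(W, 0));
  valid.assign(n, std::vector<uint64_t>(W, 0));
  for (int s = 0; s < S; ++s) {
    int w = s >> 6;
    uint64_t bit = 1ULL << (s & 63);
    for (int i = 0; i < n; ++i) {
      int a = haps(i, s);  // inner loop over rows: column-major friendly
      if (a == NA_INTEGER) continue;
      valid[i][w] |= bit;
      if (a) alleles[i][w] |= bit;
    }
  }
}

// Pairwise difference counts between all haplotype rows; NA alleles are
// skipped (a site contributes only when both haplotypes are called).
// [[Rcpp::export]]
NumericMatrix cpp_pair_diff_counts(IntegerMatrix haps) {
  int n = haps.nrow(), S = haps.ncol();
  NumericMatrix K(n, n);
  if (S == 0) return K;
  std::vector<std::vector<uint64_t> > A, V;
  pack_rows(haps, A, V);
  int W = (S + 63) / 64;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      long k = 0;
      const uint64_t *ai = A[i].data(), *aj = A[j].data();
      const uint64_t *vi = V[i].data(), *vj = V[j].data();
      for (int w = 0; w < W; ++w) {
        k += __builtin_popcountll((ai[w] ^ aj[w]) & vi[w] & vj[w]);
      }
      K(i, j) = (double) k;
      K(j, i) = (double) k;
    }
  }
  return K;
}

// Maximum identity-by-state tract length over all cross-population pairs.
// Tracts are the gaps between consecutive difference positions plus the two
// window flanks; a pair without differences spans the whole window.
// [[Rcpp::export]]
double cpp_ibs_max_cross(IntegerMatrix haps, NumericVector pos, int n1,
                         double L) {
  int n = haps.nrow(), S = haps.ncol();
  if (S == 0 || n1 >= n) return L;
  std::vector<std::vector<uint64_t> > A, V;
  pack_rows(haps, A, V);
  int W = (S + 63) / 64;
  double best = 0.0;
  for (int i = 0; i < n1; ++i) {
    for (int j = n1; j < n; ++j) {
      double prev = 0.0, mx = 0.0;
      const uint64_t *ai = A[i].data(), *aj = A[j].data();
      const uint64_t *vi = V[i].data(), *vj = V[j].data();
      for (int w = 0; w < W; ++w) {
        uint64_t d = (ai[w] ^ aj[w]) & vi[w] & vj[w];
        while (d) {
          int b = __builtin_ctzll(d);
          d &= d - 1;
          double p = pos[(w << 6) + b];
          double gap = p - prev;
          if (gap > mx) mx = gap;
          prev = p;
        }
      }
      double tail = L - prev;
      if (tail > mx) mx = tail;
      if (mx > best) best = mx;
      if (best >= L) return L;
    }
  }
  return best;
}

// Mean r^2 over all pairs of sites (columns), computed from 2x2 counts on
// bit-packed columns; missing alleles handled with pairwise-complete
// observations. Pairs whose complete subset has fewer than 2 haplotypes or
// zero variance at either site are skipped. Returns 0 when no usable pair.
// [[Rcpp::export]]
double cpp_mean_r2(IntegerMatrix haps) {
  int n = haps.nrow(), S = haps.ncol();
  if (S < 2) return 0.0;
  int W = (n + 63) / 64;
  std::vector<uint64_t> A((size_t) S * W, 0), V((size_t) S * W, 0);
  bool any_na = false;
  for (int s = 0; s < S; ++s) {
    uint64_t *a = &A[(size_t) s * W], *v = &V[(size_t) s * W];
    for (int i = 0; i < n; ++i) {
      int x = haps(i, s);
      if (x == NA_INTEGER) { any_na = true; continue; }
      v[i >> 6] |= 1ULL << (i & 63);
      if (x) a[i >> 6] |= 1ULL << (i & 63);
    }
  }
  double tot = 0.0;
  long cnt = 0;
  for (int s = 0; s < S - 1; ++s) {
    const uint64_t *as = &A[(size_t) s * W], *vs = &V[(size_t) s * W];
    for (int t = s + 1; t < S; ++t) {
      const uint64_t *at = &A[(size_t) t * W], *vt = &V[(size_t) t * W];
      long m = 0, ca = 0, cb = 0, cab = 0;
      for (int w = 0; w < W; ++w) {
        uint64_t both = vs[w] & vt[w];
        if (any_na) m += __builtin_popcountll(both);
        ca += __builtin_popcountll(as[w] & both);
        cb += __builtin_popcountll(at[w] & both);
        cab += __builtin_popcountll(as[w] & at[w] & both);
      }
      if (!any_na) m = n;
      if (m < 2) continue;
      double va = (double) m * ca - (double) ca * ca;
      double vb = (double) m * cb - (double) cb * cb;
      if (va <= 0 || vb <= 0) continue;
      double cov = (double) m * cab - (double) ca * cb;
      tot += cov * cov / (va * vb);
      ++cnt;
    }
  }
  return cnt > 0 ? tot / cnt : 0.0;
}
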