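// Compiled kernels: CRC-32, PRBS keystream, LDPC construction and GF(2)
// linear algebra, belief-propagation decoding, unit-cost global alignment,
// channel corruption and per-position vote counting.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (xorshift64*), platform-stable so that seeded results are
// identical across machines regardless of the C++ standard library.
// ---------------------------------------------------------------------------

static inline uint64_t xs64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 0x2545F4914F6CDD1DULL;
}

static inline uint64_t seed_init(double seed) {
  uint64_t s = (uint64_t)(int64_t)seed;
  s ^= 0x9E3779B97F4A7C15ULL;
  if (s == 0) s = 0x106689D45497FDB5ULL;
  // warm up
  for (int i = 0; i < 8; ++i) xs64(s);
  return s;
}

static inline double runif01(uint64_t &s) {
  return (double)(xs64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// random integer in [0, n)
static inline int rint(uint64_t &s, int n) {
  return (int)(xs64(s) % (uint64_t)n);
}

// ---------------------------------------------------------------------------
// CRC-32 (IEEE 802.3, reflected, poly 0xEDB88320, init/final 0xFFFFFFFF).
// Operates bit-by-bit on a 0/1 vector; when the vector is the rawToBits()
// expansion of a byte stream (LSB-first within each byte) the result equals
// the standard byte-wise CRC-32 check value.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double crc32_bits_cpp(IntegerVector bits) {
  uint32_t crc = 0xFFFFFFFFu;
  R_xlen_t n = bits.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    uint32_t b = (uint32_t)(bits[i] & 1);
    uint32_t x = (crc ^ b) & 1u;
    crc >>= 1;
    if (x) crc ^= 0xEDB88320u;
  }
  return (double)(crc ^ 0xFFFFFFFFu);
}

// ---------------------------------------------------------------------------
// Pseudo-random binary keystream for payload randomization (xorshift64*,
// 64 bits drawn per state update, emitted LSB-first).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector prbs_bits_cpp(double nbits, double seed) {
  R_xlen_t n = (R_xlen_t)nbits;
  IntegerVector out(n);
  uint64_t s = seed_init(seed);
  R_xlen_t i = 0;
  while (i < n) {
    uint64_t w = xs64(s);
    for (int b = 0; b < 64 && i < n; ++b, ++i) out[i] = (int)((w >> b) & 1ULL);
  }
  return out;
}

// ---------------------------------------------------------------------------
// LDPC construction: for each of n variable nodes place `wc` edges onto the m
// check nodes so that no two columns share more than one check (girth >= 6)
// while keeping check degrees as even as possible.  When wc is even the
// first column receives wc+1 edges: with a constant even column weight every
// row of H sums to zero over GF(2), so one odd-weight column is required for
// H to reach full rank.  Deterministic for a given seed.  Returns a matrix
// of 0-based check indices (-1 padding), or an empty matrix when no
// placement was found within the retry budget.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix ldpc_construct_cpp(int m, int n, int wc, double seed,
                                 int maxRestarts) {
  int wcMax = (wc % 2 == 0) ? wc + 1 : wc;
  if ((double)n * wc * (wc - 1) / 2.0 > (double)m * (m - 1) / 2.0)
    return IntegerMatrix(0, 0); // pair budget provably insufficient
  std::vector<char> pairUsed;
  std::vector<int> degree(m);
  IntegerMatrix edges(wcMax, n);
  for (int restart = 0; restart < maxRestarts; ++restart) {
    uint64_t s = seed_init(seed + 1000003.0 * restart);
    pairUsed.assign((size_t)m * m, 0);
    std::fill(degree.begin(), degree.end(), 0);
    std::fill(edges.begin(), edges.end(), -1);
    std::vector<int> order(m), picked(wcMax);
    std::vector<uint64_t> key(m);
    bool failed = false;
    for (int j = 0; j < n && !failed; ++j) {
      int w = (j == 0) ? wcMax : wc;
      bool placed = false;
      for (int attempt = 0; attempt < 12 && !placed; ++attempt) {
        // sort candidate checks by (degree, random jitter)
        for (int r = 0; r < m; ++r) {
          order[r] = r;
          key[r] = ((uint64_t)degree[r] << 48) | (xs64(s) >> 16);
        }
        std::sort(order.begin(), order.end(),
                  [&](int a, int b) { return key[a] < key[b]; });
        int got = 0;
        for (int t = 0; t < m && got < w; ++t) {
          int r = order[t];
          bool ok = true;
          for (int q = 0; q < got; ++q) {
            if (pairUsed[(size_t)picked[q] * m + r]) { ok = false; break; }
          }
          if (ok) picked[got++] = r;
        }
        if (got == w) {
          for (int q = 0; q < w; ++q) {
            edges(q, j) = picked[q];
            degree[picked[q]] += 1;
            for (int p = 0; p < q; ++p) {
              pairUsed[(size_t)picked[p] * m + picked[q]] = 1;
              pairUsed[(size_t)picked[q] * m + picked[p]] = 1;
            }
          }
          placed = true;
        }
      }
      if (!placed) failed = true;
    }
    if (!failed) return edges;
  }
  return IntegerMatrix(0, 0);
}

// ---------------------------------------------------------------------------
// GF(2) elimination on the m x n parity-check matrix given as edge lists.
// Pivots are searched from the rightmost column leftwards and reduced to RREF,
// so the parity positions end up late in the column order.  Returns the rank,
// the pivot columns, one original row per missing pivot (for rank repair),
// and the packed parity-solver matrix P (m rows, one bit per information
// column) such that for a codeword x (columns permuted to
// [non-pivot asc, pivot asc]) the i-th parity bit is P[i,] . info.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gf2_parity_cpp(IntegerVector erow, IntegerVector ecol, int m, int n) {
  int W = (n + 63) / 64;
  std::vector<uint64_t> Rm((size_t)m * W, 0ULL);
  for (R_xlen_t e = 0; e < erow.size(); ++e) {
    int r = erow[e], c = ecol[e];
    Rm[(size_t)r * W + (c >> 6)] ^= (1ULL << (c & 63));
  }
  std::vector<int> orig(m);
  for (int r = 0; r < m; ++r) orig[r] = r;
  std::vector<int> pivCol;
  pivCol.reserve(m);
  int piv = 0;
  for (int c = n - 1; c >= 0 && piv < m; --c) {
    int w = c >> 6;
    uint64_t mask = 1ULL << (c & 63);
    int sel = -1;
    for (int r = piv; r < m; ++r) {
      if (Rm[(size_t)r * W + w] & mask) { sel = r; break; }
    }
    if (sel < 0) continue;
    if (sel != piv) {
      for (int t = 0; t < W; ++t)
        std::swap(Rm[(size_t)sel * W + t], Rm[(size_t)piv * W + t]);
      std::swap(orig[sel], orig[piv]);
    }
    for (int r = 0; r < m; ++r) {
      if (r != piv && (Rm[(size_t)r * W + w] & mask)) {
        uint64_t *dst = &Rm[(size_t)r * W];
        const uint64_t *src = &Rm[(size_t)piv * W];
        for (int t = 0; t < W; ++t) dst[t] ^= src[t];
      }
    }
    pivCol.push_back(c);
    ++piv;
  }
  int rank = piv;
  IntegerVector deficientRows(m - rank);
  for (int r = rank; r < m; ++r) deficientRows[r - rank] = orig[r];
  if (rank < m) {
    return List::create(_["rank"] = rank,
                        _["pivotCols"] = IntegerVector(pivCol.begin(), pivCol.end()),
                        _["deficientRows"] = deficientRows,
                        _["p"] = RawVector(0),
                        _["infoCols"] = IntegerVector(0),
                        _["parityCols"] = IntegerVector(0));
  }
  // info columns = non-pivot columns ascending; parity columns = pivots asc.
  std::vector<char> isPiv(n, 0);
  for (int i = 0; i < m; ++i) isPiv[pivCol[i]] = 1;
  int k = n - m;
  std::vector<int> infoCols;
  infoCols.reserve(k);
  for (int c = 0; c < n; ++c) if (!isPiv[c]) infoCols.push_back(c);
  // rows sorted by ascending pivot column
  std::vector<int> rowOrder(m);
  for (int i = 0; i < m; ++i) rowOrder[i] = i;
  std::sort(rowOrder.begin(), rowOrder.end(),
            [&](int a, int b) { return pivCol[a] < pivCol[b]; });
  int Wb = (k + 7) / 8;
  RawVector p((R_xlen_t)m * Wb);
  std::fill(p.begin(), p.end(), (Rbyte)0);
  for (int i = 0; i < m; ++i) {
    int r = rowOrder[i];
    for (int j = 0; j < k; ++j) {
      int c = infoCols[j];
      if (Rm[(size_t)r * W + (c >> 6)] & (1ULL << (c & 63)))
        p[(R_xlen_t)i * Wb + (j >> 3)] |= (Rbyte)(1 << (j & 7));
    }
  }
  IntegerVector parityColsSorted(m);
  for (int i = 0; i < m; ++i) parityColsSorted[i] = pivCol[rowOrder[i]];
  return List::create(_["rank"] = rank,
                      _["pivotCols"] = IntegerVector(pivCol.begin(), pivCol.end()),
                      _["deficientRows"] = deficientRows,
                      _["p"] = p,
                      _["infoCols"] = IntegerVector(infoCols.begin(), infoCols.end()),
                      _["parityCols"] = parityColsSorted);
}

// ---------------------------------------------------------------------------
// Systematic LDPC encoding from the packed parity solver: info is a k x C
// 0/1 matrix, result is the m x C parity block.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix ldpc_encode_cpp(RawVector p, int m, int k, IntegerMatrix info) {
  if (info.nrow() != k) stop("info must have k rows");
  int C = info.ncol();
  int Wb = (k + 7) / 8;
  int W8 = (Wb + 7) / 8; // whole uint64 words covering Wb bytes
  std::vector<uint64_t> col(W8);
  IntegerMatrix parity(m, C);
  std::vector<uint64_t> prow((size_t)m * W8, 0ULL);
  for (int i = 0; i < m; ++i) {
    unsigned char *dst = (unsigned char *)&prow[(size_t)i * W8];
    for (int b = 0; b < Wb; ++b) dst[b] = (unsigned char)p[(R_xlen_t)i * Wb + b];
  }
  for (int cidx = 0; cidx < C; ++cidx) {
    std::fill(col.begin(), col.end(), 0ULL);
    unsigned char *cb = (unsigned char *)col.data();
    for (int j = 0; j < k; ++j)
      if (info(j, cidx)) cb[j >> 3] |= (unsigned char)(1 << (j & 7));
    for (int i = 0; i < m; ++i) {
      const uint64_t *pr = &prow[(size_t)i * W8];
      uint64_t acc = 0;
      for (int t = 0; t < W8; ++t) {
        uint64_t v = pr[t] & col[t];
        // popcount parity
        v ^= v >> 32; v ^= v >> 16; v ^= v >> 8;
        v ^= v >> 4;  v ^= v >> 2;  v ^= v >> 1;
        acc ^= v;
      }
      parity(i, cidx) = (int)(acc & 1ULL);
    }
  }
  return parity;
}

// ---------------------------------------------------------------------------
// Flooding sum-product (log-domain) decoder.  llr is an n x C matrix of
// channel LLRs with the convention LLR = ln P(bit=0)/P(bit=1) (positive means
// 0 more likely).  Edge lists are 0-based and grouped by check row.
// The syndrome of the current hard decision is tested before each message
// round, so a clean input converges with 0 iterations used.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bp_decode_cpp(IntegerVector erow, IntegerVector ecol, int m, int n,
                   NumericMatrix llr, int maxIter, double clip) {
  R_xlen_t E = erow.size();
  int C = llr.ncol();
  if (llr.nrow() != n) stop("llr must have n rows");
  // edges sorted by row
  std::vector<int> ord(E);
  for (R_xlen_t e = 0; e < E; ++e) ord[e] = (int)e;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return erow[a] < erow[b]; });
  std::vector<int> eR(E), eC(E), rowStart(m + 1, 0);
  for (R_xlen_t e = 0; e < E; ++e) {
    eR[e] = erow[ord[e]];
    eC[e] = ecol[ord[e]];
    rowStart[eR[e] + 1]++;
  }
  for (int r = 0; r < m; ++r) rowStart[r + 1] += rowStart[r];

  IntegerMatrix hard(n, C);
  LogicalVector converged(C);
  IntegerVector iters(C);
  std::vector<double> v2c(E), c2v(E), total(n), t(E);
  std::vector<int> hb(n);

  for (int cw = 0; cw < C; ++cw) {
    const double *L = &llr(0, cw);
    for (R_xlen_t e = 0; e < E; ++e) { v2c[e] = L[eC[e]]; c2v[e] = 0.0; }
    for (int i = 0; i < n; ++i) total[i] = L[i];
    bool ok = false;
    int used = 0;
    for (int it = 0; it <= maxIter; ++it) {
      // hard decision + syndrome
      for (int i = 0; i < n; ++i) hb[i] = (total[i] < 0.0) ? 1 : 0;
      bool zero = true;
      for (int r = 0; r < m && zero; ++r) {
        int s = 0;
        for (int e = rowStart[r]; e < rowStart[r + 1]; ++e) s ^= hb[eC[e]];
        if (s) zero = false;
      }
      if (zero) { ok = true; used = it; break; }
      if (it == maxIter) { used = it; break; }
      // check update with prefix/suffix products of tanh(v2c/2)
      for (R_xlen_t e = 0; e < E; ++e) t[e] = std::tanh(0.5 * v2c[e]);
      for (int r = 0; r < m; ++r) {
        int a = rowStart[r], b = rowStart[r + 1];
        double pre = 1.0;
        for (int e = a; e < b; ++e) { c2v[e] = pre; pre *= t[e]; }
        double suf = 1.0;
        for (int e = b - 1; e >= a; --e) {
          double prod = c2v[e] * suf;
          suf *= t[e];
          if (prod > 0.9999999999999) prod = 0.9999999999999;
          if (prod < -0.9999999999999) prod = -0.9999999999999;
          c2v[e] = 2.0 * std::atanh(prod);
        }
      }
      // variable update
      for (int i = 0; i < n; ++i) total[i] = L[i];
      for (R_xlen_t e = 0; e < E; ++e) total[eC[e]] += c2v[e];
      for (R_xlen_t e = 0; e < E; ++e) {
        double v = total[eC[e]] - c2v[e];
        if (v > clip) v = clip;
        if (v < -clip) v = -clip;
        v2c[e] = v;
      }
    }
    for (int i = 0; i < n; ++i) hard(i, cw) = hb[i];
    converged[cw] = ok;
    iters[cw] = used;
  }
  return List::create(_["bits"] = hard, _["converged"] = converged,
                      _["iterations"] = iters);
}

// ---------------------------------------------------------------------------
// Global alignment with unit costs (match 0, mismatch 1, indel 1).
// Deterministic traceback preference: diagonal, then gap in b (up), then gap
// in a (left).  Returns the two gapped strings; '-' is the gap symbol.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector nw_align_cpp(std::string a, std::string b) {
  int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> D((size_t)(la + 1) * (lb + 1));
  for (int i = 0; i <= la; ++i) D[(size_t)i * (lb + 1)] = i;
  for (int j = 0; j <= lb; ++j) D[j] = j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int d = D[(size_t)(i - 1) * (lb + 1) + (j - 1)] + (a[i - 1] != b[j - 1]);
      int u = D[(size_t)(i - 1) * (lb + 1) + j] + 1;
      int l = D[(size_t)i * (lb + 1) + (j - 1)] + 1;
      int v = d < u ? d : u;
      if (l < v) v = l;
      D[(size_t)i * (lb + 1) + j] = v;
    }
  }
  std::string ra, rb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int cur = D[(size_t)i * (lb + 1) + j];
    if (i > 0 && j > 0 &&
        cur == D[(size_t)(i - 1) * (lb + 1) + (j - 1)] + (a[i - 1] != b[j - 1])) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && cur == D[(size_t)(i - 1) * (lb + 1) + j] + 1) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return CharacterVector::create(ra, rb);
}

// ---------------------------------------------------------------------------
// Channel corruption.  One left-to-right pass per source oligo: a base may be
// deleted (skipped), emitted with a substitution, and may be followed by an
// inserted uniform base.  The substitution rate at the final source base is
// multiplied by lastMult.  Phred scores are drawn from the correct-base or
// error-base discrete distribution (values + cumulative probabilities).
// With probability artifactRate the read is truncated to a uniform length in
// [artMin, artMax], emulating merge/trim artifacts shorter than 150 nt.
// ---------------------------------------------------------------------------

static inline int draw_q(uint64_t &s, const NumericVector &cum,
                         const IntegerVector &vals) {
  double u = runif01(s);
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cum[mid]) hi = mid; else lo = mid + 1;
  }
  return vals[lo];
}

// [[Rcpp::export]]
List corrupt_reads_cpp(CharacterVector oligos, double subRate, double insRate,
                       double delRate, double lastMult, double artifactRate,
                       NumericVector qcCum, IntegerVector qcVals,
                       NumericVector qeCum, IntegerVector qeVals,
                       int artMin, int artMax, double seed) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  uint64_t s = seed_init(seed);
  R_xlen_t N = oligos.size();
  CharacterVector seqs(N), quals(N);
  std::string out, qual;
  for (R_xlen_t r = 0; r < N; ++r) {
    const char *src = CHAR(STRING_ELT(oligos, r));
    int L = (int)LENGTH(STRING_ELT(oligos, r));
    out.clear(); qual.clear();
    for (int p = 0; p < L; ++p) {
      if (runif01(s) < delRate) {
        // deletion: base skipped
      } else {
        double sr = (p == L - 1) ? subRate * lastMult : subRate;
        char base = src[p];
        bool err = false;
        if (runif01(s) < sr) {
          int v = 0;
          switch (base) { case 'A': v = 0; break; case 'C': v = 1; break;
                          case 'G': v = 2; break; default: v = 3; }
          base = BASES[(v + 1 + rint(s, 3)) & 3];
          err = true;
        }
        out.push_back(base);
        qual.push_back((char)(33 + (err ? draw_q(s, qeCum, qeVals)
                                        : draw_q(s, qcCum, qcVals))));
      }
      if (runif01(s) < insRate) {
        out.push_back(BASES[rint(s, 4)]);
        qual.push_back((char)(33 + draw_q(s, qeCum, qeVals)));
      }
    }
    if (artifactRate > 0.0 && runif01(s) < artifactRate) {
      int tl = artMin + rint(s, artMax - artMin + 1);
      if ((int)out.size() > tl) { out.resize(tl); qual.resize(tl); }
    }
    seqs[r] = out;
    quals[r] = qual;
  }
  return List::create(_["seq"] = seqs, _["qual"] = quals);
}

// ---------------------------------------------------------------------------
// Thresholded edit distance: banded Levenshtein (Ukkonen cutoff) returning
// min(ED, dTh + 1).  Used by the abnormal-read eviction rule, which only
// needs to know whether a read is within dTh of some other cluster member.
// ---------------------------------------------------------------------------

static int bounded_ed(const char *a, int la, const char *b, int lb, int dTh) {
  if (la > lb) { std::swap(a, b); std::swap(la, lb); }
  if (lb - la > dTh) return dTh + 1;
  const int big = dTh + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= dTh) ? j : big;
  for (int i = 1; i <= la; ++i) {
    int lo = std::max(1, i - dTh);
    int hi = std::min(lb, i + dTh);
    std::fill(cur.begin(), cur.end(), big);
    if (i <= dTh) cur[0] = i;
    int rowMin = cur[0];
    for (int j = lo; j <= hi; ++j) {
      int d = prev[j - 1] + (a[i - 1] != b[j - 1]);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      int v = d < u ? d : u;
      if (l < v) v = l;
      if (v > big) v = big;
      cur[j] = v;
      if (v < rowMin) rowMin = v;
    }
    if (rowMin > dTh) return big;
    std::swap(prev, cur);
  }
  return prev[lb] < big ? prev[lb] : big;
}

// [[Rcpp::export]]
LogicalVector ed_filter_keep_cpp(CharacterVector seqs, int dTh) {
  int nm = (int)seqs.size();
  LogicalVector keep(nm);
  if (nm < 2) { std::fill(keep.begin(), keep.end(), true); return keep; }
  std::vector<const char *> s(nm);
  std::vector<int> l(nm);
  for (int i = 0; i < nm; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    l[i] = (int)LENGTH(STRING_ELT(seqs, i));
  }
  for (int i = 0; i < nm; ++i) {
    bool ok = false;
    for (int j = 0; j < nm && !ok; ++j) {
      if (j == i) continue;
      if (bounded_ed(s[i], l[i], s[j], l[j], dTh) <= dTh) ok = true;
    }
    keep[i] = ok;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Vote counting.  Each contributing read is a (possibly gapped) 152-character
// row positioned on the oligo frame: 16 index characters then 136 payload
// bases.  Characters other than A/C/G/T vote erasure.  When gateLast is true,
// the payload's final base (the last two bits) only collects 0/1 votes from
// reads whose last-base Phred score exceeds qGate; other reads vote erasure
// there.  Returns K0/K1 count matrices (nOligos x 272) and the number of
// contributing reads per oligo.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List count_votes_cpp(CharacterVector rows, IntegerVector ordinal,
                     IntegerVector lastQ, int nOligos, bool gateLast,
                     int qGate) {
  IntegerMatrix K0(nOligos, 272), K1(nOligos, 272);
  IntegerVector contrib(nOligos);
  R_xlen_t N = rows.size();
  for (R_xlen_t r = 0; r < N; ++r) {
    const char *sq = CHAR(STRING_ELT(rows, r));
    int L = (int)LENGTH(STRING_ELT(rows, r));
    int ord = ordinal[r];
    if (ord < 0 || ord >= nOligos) stop("ordinal out of range");
    contrib[ord] += 1;
    int lim = L < 152 ? L : 152;
    for (int p = 16; p < lim; ++p) {
      int v;
      switch (sq[p]) { case 'A': v = 0; break; case 'C': v = 1; break;
                       case 'G': v = 2; break; case 'T': v = 3; break;
                       default: v = -1; }
      if (v < 0) continue; // gap / unknown base -> erasure
      if (p == 151 && gateLast && lastQ[r] <= qGate) continue;
      int hi = (v >> 1) & 1, lo = v & 1;
      int b1 = 2 * (p - 16), b2 = b1 + 1; // 0-based bit columns
      if (hi) K1(ord, b1)++; else K0(ord, b1)++;
      if (lo) K1(ord, b2)++; else K0(ord, b2)++;
    }
  }
  return List::create(_["k0"] = K0, _["k1"] = K1, _["contributors"] = contrib);
}
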