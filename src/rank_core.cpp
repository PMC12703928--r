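// Word-level core: packed bit storage, popcount, mask/shift block counting,
// directory construction and rank evaluation for all layouts, and the
// flattened bit-plane string machinery.
//
// Bit order convention: position j of a vector lives in byte j>>3, bit j&7,
// i.e. bit (j & 63) of 64-bit word j>>6.  Words are materialized from raw
// bytes little-endian, so the raw byte stream is also the serialized form.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int pc64(uint64_t x) { return __builtin_popcountll(x); }

static inline uint64_t load_word(const uint8_t* p, uint64_t t) {
  const uint8_t* q = p + 8 * t;
  uint64_t w = 0;
  for (int k = 0; k < 8; ++k) w |= (uint64_t)q[k] << (8 * k);
  return w;
}

static inline void store_word(uint8_t* p, uint64_t t, uint64_t w) {
  uint8_t* q = p + 8 * t;
  for (int k = 0; k < 8; ++k) q[k] = (uint8_t)(w >> (8 * k));
}

static inline uint64_t as_u64(double x) {
  if (ISNAN(x) || x < 0) stop("size must be a non-negative number");
  return (uint64_t)x;
}

// ---- mask tables --------------------------------------------------------
// 2w+1 masks per width w.  Index j in [0, w): suffix mask with ones at bit
// positions j..w-1 (left-block case).  Index j in [w, 2w]: prefix mask with
// ones at positions 0..(j-w)-1 (right-block case).  mask[w] is all-zero.

static void build_masks(int w, std::vector<uint64_t>& m) {
  int ww = w / 64;
  m.assign((size_t)(2 * w + 1) * ww, 0ULL);
  for (int j = 0; j <= 2 * w; ++j) {
    uint64_t* row = &m[(size_t)j * ww];
    if (j < w) {
      for (int b = j; b < w; ++b) row[b >> 6] |= 1ULL << (b & 63);
    } else {
      for (int b = 0; b < j - w; ++b) row[b >> 6] |= 1ULL << (b & 63);
    }
  }
}

static const std::vector<uint64_t>& mask_cache(int w) {
  static std::vector<uint64_t> m64, m512;
  if (w == 64) {
    if (m64.empty()) build_masks(64, m64);
    return m64;
  }
  if (w == 512) {
    if (m512.empty()) build_masks(512, m512);
    return m512;
  }
  stop("unsupported block width (must be 64 or 512)");
}

// ---- block counting -----------------------------------------------------
// pair_pos in [0, 2w]: < w counts the suffix of a left block starting at
// pair_pos; >= w counts the first (pair_pos - w) bits of a right block.

static int count_shift(const uint64_t* blk, int w, int pair_pos) {
  int ww = w / 64, c = 0;
  if (pair_pos < w) {
    for (int t = 0; t < ww; ++t) {
      int lo = 64 * t;
      if (pair_pos <= lo) c += pc64(blk[t]);
      else if (pair_pos < lo + 64) c += pc64(blk[t] >> (pair_pos - lo));
    }
  } else {
    int m = pair_pos - w;
    for (int t = 0; t < ww; ++t) {
      int lo = 64 * t;
      if (m >= lo + 64) c += pc64(blk[t]);
      else if (m > lo) c += pc64(blk[t] << (64 - (m - lo)));
    }
  }
  return c;
}

static inline int count_masked_row(const uint64_t* blk, int ww,
                                   const uint64_t* row) {
  int c = 0;
  for (int t = 0; t < ww; ++t) c += pc64(blk[t] & row[t]);
  return c;
}

static inline int pair_count(const uint64_t* blk, int w, int pair_pos,
                             int strategy) {
  if (strategy == 0) {
    const std::vector<uint64_t>& M = mask_cache(w);
    return count_masked_row(blk, w / 64, &M[(size_t)pair_pos * (w / 64)]);
  }
  return count_shift(blk, w, pair_pos);
}

// ---- directory construction --------------------------------------------
// P is the per-block popcount prefix array, P[j] = ones in blocks 0..j-1.

static List dir_from_prefix(const std::vector<double>& P, int w1, int w0,
                            bool paired, int layers) {
  uint64_t nb = P.size() - 1;
  uint64_t bpsb = (uint64_t)(w0 / w1);  // blocks per superblock
  NumericVector L0, L1;
  if (layers == 1) {
    if (!paired) {
      L0 = NumericVector(nb);
      for (uint64_t j = 0; j < nb; ++j) L0[j] = P[j];
    } else {
      uint64_t np = nb / 2;
      L0 = NumericVector(np);
      for (uint64_t p = 0; p < np; ++p) L0[p] = P[2 * p + 1];
    }
  } else {
    if (!paired) {
      uint64_t nsb = nb / bpsb;
      L0 = NumericVector(nsb);
      L1 = NumericVector(nb);
      for (uint64_t s = 0; s < nsb; ++s) L0[s] = P[s * bpsb];
      for (uint64_t j = 0; j < nb; ++j) {
        double v = P[j] - P[(j / bpsb) * bpsb];
        if (v >= 65536) stop("L1 entry exceeds 16-bit range");
        L1[j] = v;
      }
    } else {
      uint64_t npsb = nb / bpsb / 2;  // superblock pairs
      uint64_t nbp = nb / 2;          // block pairs
      L0 = NumericVector(npsb);
      L1 = NumericVector(nbp);
      // L0[p]: absolute count through the end of the pair's left superblock
      for (uint64_t p = 0; p < npsb; ++p) L0[p] = P[(2 * p + 1) * bpsb];
      // L1[q]: right superblock -> prefix from superblock start through the
      // pair's left block; left superblock -> postfix from the pair's right
      // block to the end of the superblock
      for (uint64_t q = 0; q < nbp; ++q) {
        uint64_t s = (2 * q) / bpsb;  // superblock holding block pair q
        double v = (s & 1) ? P[2 * q + 1] - P[s * bpsb]
                           : P[(s + 1) * bpsb] - P[2 * q + 1];
        if (v >= 65536) stop("L1 entry exceeds 16-bit range");
        L1[q] = v;
      }
    }
  }
  return List::create(_["L0"] = L0, _["L1"] = L1, _["ones"] = P[nb]);
}

// ---- rank evaluation ----------------------------------------------------

template <class LoadBlock>
static double rank_one(uint64_t i, uint64_t n_padded, double ones,
                       const double* L0, const double* L1, int w1, int w0,
                       bool paired, int layers, int strategy,
                       LoadBlock load_block) {
  if (i == 0) return 0.0;
  if (i >= n_padded) return ones;  // i == n == padded span
  uint64_t buf[8];
  uint64_t W1 = (uint64_t)w1, W0 = (uint64_t)w0;
  if (layers == 2) {
    if (!paired) {
      uint64_t il0 = i / W0, il1 = i / W1;
      int pos = (int)(i - il1 * W1);
      load_block(il1, buf);
      return L0[il0] + L1[il1] + pair_count(buf, w1, w1 + pos, strategy);
    }
    uint64_t ib = i / W1, il1 = i / (2 * W1), il0 = i / (2 * W0);
    int pos = (int)(i - il1 * 2 * W1);
    bool right_sb = (i / W0) & 1ULL;
    load_block(ib, buf);
    double c = pair_count(buf, w1, pos, strategy);
    double v = right_sb ? L1[il1] : -L1[il1];
    return L0[il0] + v + (pos >= w1 ? c : -c);
  }
  if (!paired) {
    uint64_t il0 = i / W1;
    int pos = (int)(i - il0 * W1);
    load_block(il0, buf);
    return L0[il0] + pair_count(buf, w1, w1 + pos, strategy);
  }
  uint64_t ib = i / W1, il0 = i / (2 * W1);
  int pos = (int)(i - il0 * 2 * W1);
  load_block(ib, buf);
  double c = pair_count(buf, w1, pos, strategy);
  return L0[il0] + (pos >= w1 ? c : -c);
}

// ---- exported: packed bits ---------------------------------------------

// [[Rcpp::export]]
RawVector cpp_pack_bits(IntegerVector bits, double n_padded) {
  uint64_t n = bits.size();
  uint64_t np = std::max(as_u64(n_padded), n);
  uint64_t nbytes = ((np + 63) / 64) * 8;
  RawVector out(nbytes);  // zero-initialized
  uint8_t* q = RAW(out);
  for (uint64_t j = 0; j < n; ++j) {
    int b = bits[j];
    if (b == NA_INTEGER || (b != 0 && b != 1)) stop("bits must be 0 or 1");
    if (b) q[j >> 3] |= (uint8_t)(1u << (j & 7));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_bits(RawVector words, double n_d) {
  uint64_t n = as_u64(n_d);
  if ((uint64_t)words.size() * 8 < n) stop("raw buffer too short");
  const uint8_t* p = RAW(words);
  IntegerVector out(n);
  for (uint64_t j = 0; j < n; ++j) out[j] = (p[j >> 3] >> (j & 7)) & 1;
  return out;
}

// [[Rcpp::export]]
double cpp_popcount_raw(RawVector words) {
  const uint8_t* p = RAW(words);
  double c = 0;
  for (R_xlen_t b = 0; b < words.size(); ++b)
    c += __builtin_popcount((unsigned)p[b]);
  return c;
}

// [[Rcpp::export]]
IntegerVector cpp_get_bits(RawVector words, NumericVector pos) {
  const uint8_t* p = RAW(words);
  uint64_t nb = (uint64_t)words.size() * 8;
  IntegerVector out(pos.size());
  for (R_xlen_t k = 0; k < pos.size(); ++k) {
    uint64_t j = as_u64(pos[k]);
    if (j >= nb) stop("bit position out of range");
    out[k] = (p[j >> 3] >> (j & 7)) & 1;
  }
  return out;
}

// ---- exported: mask and count ------------------------------------------

// [[Rcpp::export]]
RawVector cpp_make_mask_table(int w) {
  const std::vector<uint64_t>& M = mask_cache(w);
  RawVector out((size_t)(2 * w + 1) * (w / 8));
  uint8_t* q = RAW(out);
  for (size_t t = 0; t < M.size(); ++t) store_word(q, t, M[t]);
  return out;
}

static void load_block_raw(RawVector block, int w, uint64_t* buf) {
  if ((int)block.size() != w / 8) stop("block must contain w/8 bytes");
  const uint8_t* p = RAW(block);
  for (int t = 0; t < w / 64; ++t) buf[t] = load_word(p, t);
}

// [[Rcpp::export]]
int cpp_masked_count(RawVector block, RawVector table, int pair_pos, int w) {
  if (pair_pos < 0 || pair_pos > 2 * w) stop("pair_pos out of [0, 2w]");
  if ((int)table.size() != (2 * w + 1) * (w / 8))
    stop("mask table has wrong size for this width");
  uint64_t buf[8];
  load_block_raw(block, w, buf);
  const uint8_t* tp = RAW(table);
  uint64_t row[8];
  for (int t = 0; t < w / 64; ++t)
    row[t] = load_word(tp, (uint64_t)pair_pos * (w / 64) + t);
  return count_masked_row(buf, w / 64, row);
}

// [[Rcpp::export]]
int cpp_shifted_count(RawVector block, int pair_pos, int w) {
  if (pair_pos < 0 || pair_pos > 2 * w) stop("pair_pos out of [0, 2w]");
  uint64_t buf[8];
  load_block_raw(block, w, buf);
  return count_shift(buf, w, pair_pos);
}

// ---- exported: bit-vector directories and rank -------------------------

// [[Rcpp::export]]
List cpp_build_bv(RawVector words, double n_padded_d, int w1, int w0,
                  bool paired, int layers) {
  uint64_t np = as_u64(n_padded_d);
  if ((uint64_t)words.size() * 8 < np) stop("word buffer too short");
  const uint8_t* p = RAW(words);
  uint64_t nb = np / w1;
  int wpb = w1 / 64;
  std::vector<double> P(nb + 1, 0.0);
  for (uint64_t j = 0; j < nb; ++j) {
    int c = 0;
    for (int t = 0; t < wpb; ++t) c += pc64(load_word(p, j * wpb + t));
    P[j + 1] = P[j] + c;
  }
  return dir_from_prefix(P, w1, w0, paired, layers);
}

// [[Rcpp::export]]
NumericVector cpp_rank_bv(RawVector words, double n_d, double n_padded_d,
                          NumericVector L0, NumericVector L1, double ones,
                          int w1, int w0, bool paired, int layers,
                          int strategy, NumericVector iv) {
  const uint8_t* p = RAW(words);
  uint64_t n = as_u64(n_d), np = as_u64(n_padded_d);
  int wpb = w1 / 64;
  const double* l0 = L0.size() ? &L0[0] : nullptr;
  const double* l1 = L1.size() ? &L1[0] : nullptr;
  NumericVector out(iv.size());
  for (R_xlen_t k = 0; k < iv.size(); ++k) {
    double id = iv[k];
    if (ISNAN(id) || id < 0 || id > (double)n)
      stop("rank position out of range [0, n]");
    out[k] = rank_one((uint64_t)id, np, ones, l0, l1, w1, w0, paired, layers,
                      strategy, [&](uint64_t b, uint64_t* buf) {
                        for (int t = 0; t < wpb; ++t)
                          buf[t] = load_word(p, b * wpb + t);
                      });
  }
  return out;
}

// ---- exported: flattened bit planes ------------------------------------

// [[Rcpp::export]]
List cpp_encode_planes(IntegerVector codes, int k, double n_padded_d) {
  uint64_t np = as_u64(n_padded_d);
  uint64_t n = codes.size();
  if (np < n) stop("padded length shorter than text");
  uint64_t nbytes = ((np + 63) / 64) * 8;
  List out(k);
  for (int b = 0; b < k; ++b) {
    RawVector pl(nbytes);
    uint8_t* q = RAW(pl);
    for (uint64_t j = 0; j < n; ++j)
      if ((codes[j] >> b) & 1) q[j >> 3] |= (uint8_t)(1u << (j & 7));
    out[b] = pl;
  }
  return out;
}

static std::vector<const uint8_t*> plane_ptrs(List planes, int k) {
  std::vector<const uint8_t*> pl(k);
  for (int b = 0; b < k; ++b) {
    RawVector r = planes[b];
    pl[b] = RAW(r);
  }
  return pl;
}

// Reconstruct the 64-bit indicator word for symbol `code` at word t:
// AND of plane words (complemented where the code bit is 0), with bits at
// positions >= n forced to zero so padding never becomes phantom symbols.
static inline uint64_t rec_word(const std::vector<const uint8_t*>& pl, int k,
                                int code, uint64_t t, uint64_t n) {
  uint64_t r = ~0ULL;
  for (int b = 0; b < k; ++b) {
    uint64_t w = load_word(pl[b], t);
    r &= ((code >> b) & 1) ? w : ~w;
  }
  uint64_t base = t * 64;
  if (base >= n) return 0ULL;
  uint64_t rem = n - base;
  if (rem < 64) r &= (1ULL << rem) - 1;
  return r;
}

// [[Rcpp::export]]
RawVector cpp_reconstruct_word(List planes, int k, int code, double t_d,
                               double n_d) {
  uint64_t t = as_u64(t_d), n = as_u64(n_d);
  RawVector first = planes[0];
  if ((t + 1) * 8 > (uint64_t)first.size()) stop("word index out of range");
  std::vector<const uint8_t*> pl = plane_ptrs(planes, k);
  RawVector out(8);
  store_word(RAW(out), 0, rec_word(pl, k, code, t, n));
  return out;
}

// [[Rcpp::export]]
List cpp_build_str_dirs(IntegerVector codes, int sigma, double n_padded_d,
                        int w1, int w0, bool paired) {
  uint64_t np = as_u64(n_padded_d);
  uint64_t n = codes.size();
  uint64_t nb = np / w1;
  std::vector<std::vector<double>> P(sigma,
                                     std::vector<double>(nb + 1, 0.0));
  std::vector<double> run(sigma, 0.0);
  uint64_t pos = 0;
  for (uint64_t j = 0; j < nb; ++j) {
    uint64_t end = std::min<uint64_t>((j + 1) * (uint64_t)w1, n);
    for (; pos < end; ++pos) {
      int c = codes[pos];
      if (c == NA_INTEGER || c < 0 || c >= sigma)
        stop("symbol code out of alphabet range");
      run[c] += 1;
    }
    for (int c = 0; c < sigma; ++c) P[c][j + 1] = run[c];
  }
  List out(sigma);
  for (int c = 0; c < sigma; ++c)
    out[c] = dir_from_prefix(P[c], w1, w0, paired, 2);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rank_flat(List planes, int k, double n_d, double n_padded_d,
                            NumericVector L0, NumericVector L1, double ones,
                            int code, int w1, int w0, bool paired,
                            int strategy, NumericVector iv) {
  uint64_t n = as_u64(n_d), np = as_u64(n_padded_d);
  std::vector<const uint8_t*> pl = plane_ptrs(planes, k);
  int wpb = w1 / 64;
  const double* l0 = L0.size() ? &L0[0] : nullptr;
  const double* l1 = L1.size() ? &L1[0] : nullptr;
  NumericVector out(iv.size());
  for (R_xlen_t q = 0; q < iv.size(); ++q) {
    double id = iv[q];
    if (ISNAN(id) || id < 0 || id > (double)n)
      stop("rank position out of range [0, n]");
    out[q] = rank_one((uint64_t)id, np, ones, l0, l1, w1, w0, paired, 2,
                      strategy, [&](uint64_t b, uint64_t* buf) {
                        for (int t = 0; t < wpb; ++t)
                          buf[t] = rec_word(pl, k, code, b * wpb + t, n);
                      });
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_access_planes(List planes, int k, NumericVector iv) {
  std::vector<const uint8_t*> pl = plane_ptrs(planes, k);
  RawVector first = planes[0];
  uint64_t nb = (uint64_t)first.size() * 8;
  IntegerVector out(iv.size());
  for (R_xlen_t q = 0; q < iv.size(); ++q) {
    uint64_t i = as_u64(iv[q]);
    if (i >= nb) stop("position out of range");
    int code = 0;
    for (int b = 0; b < k; ++b)
      code |= ((pl[b][i >> 3] >> (i & 7)) & 1) << b;
    out[q] = code;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tabulate_planes(List planes, int k, int sigma, double n_d) {
  uint64_t n = as_u64(n_d);
  std::vector<const uint8_t*> pl = plane_ptrs(planes, k);
  NumericVector out(sigma);
  for (uint64_t i = 0; i < n; ++i) {
    int code = 0;
    for (int b = 0; b < k; ++b)
      code |= ((pl[b][i >> 3] >> (i & 7)) & 1) << b;
    if (code < sigma) out[code] += 1;
  }
  return out;
}
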