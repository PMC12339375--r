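#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Hashes live in a 53-bit space so that every retained value is exactly
// representable as an R double: the 64-bit mix is truncated to its top 53
// bits (M = 2^53). The FracMinHash keep rule h < floor(M/c) is evaluated on
// that truncation, identically here and in R.
static const int HASH_SHIFT = 11;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t keep_threshold53(double c) {
  long double t = 9007199254740992.0L / (long double) c; // 2^53 / c
  return (uint64_t) floorl(t);
}

// Scan one sequence; call f(pos0, h53) for every window of k ACGT bases.
// Canonical form = min(forward, reverse-complement) of the 2-bit encoding.
template <typename F>
static void scan_kmers(const char *s, R_xlen_t n, int k, uint64_t seedmix,
                       F &&f) {
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rc = (rc >> 2) | ((uint64_t) (3 - b) << shift);
    if (++filled >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      uint64_t h = splitmix64(canon ^ seedmix) >> HASH_SHIFT;
      f(i - k + 1, h);
    }
  }
}

static void check_k(int k) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 1 and 31");
}

// [[Rcpp::export(name = ".cpp_keep_threshold")]]
double cpp_keep_threshold(double c) {
  if (c < 1) stop("c must be >= 1");
  return (double) keep_threshold53(c);
}

// [[Rcpp::export(name = ".cpp_kmer_hashes")]]
List cpp_kmer_hashes(std::string seq, int k, double seed) {
  check_k(k);
  uint64_t seedmix = splitmix64((uint64_t) (int64_t) seed);
  std::vector<double> hashes;
  std::vector<int> pos;
  scan_kmers(seq.c_str(), (R_xlen_t) seq.size(), k, seedmix,
             [&](R_xlen_t p, uint64_t h) {
               pos.push_back((int) p);
               hashes.push_back((double) h);
             });
  return List::create(_["pos"] = wrap(pos), _["hash"] = wrap(hashes));
}

// Hash arbitrary k-mer strings one by one (test oracle path); NA for any
// string containing a non-ACGT base or of the wrong length.
// [[Rcpp::export(name = ".cpp_hash_kmers")]]
NumericVector cpp_hash_kmers(CharacterVector kmers, int k, double seed) {
  check_k(k);
  uint64_t seedmix = splitmix64((uint64_t) (int64_t) seed);
  NumericVector out(kmers.size(), NA_REAL);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP el = STRING_ELT(kmers, i);
    if (el == NA_STRING) continue;
    const char *s = CHAR(el);
    R_xlen_t n = (R_xlen_t) LENGTH(el);
    if (n != k) continue;
    double val = NA_REAL;
    scan_kmers(s, n, k, seedmix,
               [&](R_xlen_t, uint64_t h) { val = (double) h; });
    out[i] = val;
  }
  return out;
}

// Genome sketching: FracMinHash selection, then removal of all copies of
// multicopy k-mers (all copies of a k-mer hash identically, so counting
// retained windows counts genome-wide multiplicity), then a per-contig
// greedy spacing filter on the start coordinates of surviving k-mers.
// [[Rcpp::export(name = ".cpp_sketch_genome")]]
List cpp_sketch_genome(CharacterVector seqs, int k, double c, double seed,
                       int spacing) {
  check_k(k);
  if (spacing < 0) stop("spacing must be >= 0");
  uint64_t seedmix = splitmix64((uint64_t) (int64_t) seed);
  uint64_t thresh = keep_threshold53(c);

  double genome_length = 0;
  std::vector<std::vector<std::pair<int, uint64_t>>> retained(seqs.size());
  std::unordered_map<uint64_t, uint32_t> mult;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    SEXP el = STRING_ELT(seqs, j);
    if (el == NA_STRING) stop("NA sequence in genome input");
    const char *s = CHAR(el);
    R_xlen_t n = (R_xlen_t) LENGTH(el);
    genome_length += (double) n;
    scan_kmers(s, n, k, seedmix, [&](R_xlen_t p, uint64_t h) {
      if (h < thresh) {
        retained[j].push_back({(int) p, h});
        ++mult[h];
      }
    });
  }

  std::vector<double> kept;
  for (auto &contig : retained) {
    long last = -(long) spacing - 1;
    for (auto &ph : contig) {
      if (mult[ph.second] != 1) continue;     // multicopy: drop all copies
      if ((long) ph.first < last + spacing) continue;
      last = ph.first;
      kept.push_back((double) ph.second);
    }
  }
  std::sort(kept.begin(), kept.end());
  kept.erase(std::unique(kept.begin(), kept.end()), kept.end());
  return List::create(_["hashes"] = wrap(kept),
                      _["genome_length"] = genome_length);
}

// ---- PCR-duplicate membership store -----------------------------------
// Approximate set membership backed by 64-bit tuple fingerprints in a hash
// set. False-positive probability per query is ~n/2^64, far below any
// configured target rate; false positives can only drop observations.

struct DedupStore {
  std::unordered_set<uint64_t> set;
  uint64_t salt;
};

static inline uint64_t encode32(const char *s, R_xlen_t n, R_xlen_t start) {
  // 2-bit encode 32 bases starting at `start`; non-ACGT encodes as A.
  uint64_t code = 0;
  for (R_xlen_t i = start; i < start + 32 && i < n; ++i) {
    int b = base_code(s[i]);
    code = (code << 2) | (uint64_t) (b < 0 ? 0 : b);
  }
  return code;
}

static inline void alt_masks(uint64_t code32, uint32_t &even, uint32_t &odd) {
  // Alternating base masks 1010..10 / 0101..01 over a 32-mer: keep the 16
  // bases at even (resp. odd) positions, each a 32-bit 2-bit-encoded 16-mer.
  even = 0; odd = 0;
  for (int i = 0; i < 32; ++i) {
    uint32_t b = (uint32_t) ((code32 >> (2 * (31 - i))) & 3ULL);
    if (i % 2 == 0) even = (even << 2) | b; else odd = (odd << 2) | b;
  }
}

static inline uint64_t tuple_fp(uint64_t salt, uint64_t x, uint32_t y,
                                uint32_t z) {
  return splitmix64(x ^ splitmix64((((uint64_t) y << 32) | z) ^ salt));
}

// Query-and-insert for one FracMinHash k-mer observation given the two
// flanking 32-mer windows. Returns true when the observation is a duplicate
// (present already); otherwise inserts both tuples and returns false.
static bool dedup_check_insert(DedupStore *st, uint64_t x,
                               const char *w1, R_xlen_t n1, R_xlen_t s1,
                               const char *w2, R_xlen_t n2, R_xlen_t s2) {
  uint64_t c1 = encode32(w1, n1, s1), c2 = encode32(w2, n2, s2);
  uint32_t y1, y2, z1, z2;
  alt_masks(c1, y2, y1); // y1 from 0101..01 (odd positions), y2 from 1010..10
  alt_masks(c2, z2, z1);
  uint64_t t1 = tuple_fp(st->salt, x, y1, z1);
  uint64_t t2 = tuple_fp(st->salt, x, y2, z2);
  if (st->set.count(t1) || st->set.count(t2)) return true;
  st->set.insert(t1);
  st->set.insert(t2);
  return false;
}

// [[Rcpp::export(name = ".cpp_dedup_new")]]
SEXP cpp_dedup_new(double seed) {
  DedupStore *st = new DedupStore();
  st->salt = splitmix64((uint64_t) (int64_t) seed ^ 0xD1B54A32D192ED03ULL);
  XPtr<DedupStore> p(st, true);
  return p;
}

// [[Rcpp::export(name = ".cpp_dedup_check")]]
bool cpp_dedup_check(SEXP store, double kmer_hash, std::string read1,
                     std::string read2, bool single_end, int multiplicity) {
  XPtr<DedupStore> st(store);
  uint64_t x = (uint64_t) kmer_hash;
  const char *s1 = read1.c_str();
  R_xlen_t n1 = (R_xlen_t) read1.size();
  if (single_end) {
    if (n1 > 400 || n1 < 32) return false;
    if (multiplicity >= 4) return false;
    R_xlen_t mid = n1 / 2; if (mid > n1 - 32) mid = n1 - 32;
    return dedup_check_insert(st.get(), x, s1, n1, 0, s1, n1, mid);
  }
  const char *s2 = read2.c_str();
  R_xlen_t n2 = (R_xlen_t) read2.size();
  if (n1 < 32 || n2 < 32) return false;
  return dedup_check_insert(st.get(), x, s1, n1, 0, s2, n2, 0);
}

// Read sketching. Paired mode: a k-mer seen twice across one pair counts
// once; PCR dedup uses the first 32-mers of both mates. Single-end mode:
// reads > 400 bp never dedup, the second window starts at the read middle,
// and dedup applies only while the k-mer's running multiplicity is < 4.
// [[Rcpp::export(name = ".cpp_sketch_reads")]]
List cpp_sketch_reads(CharacterVector reads1, Nullable<CharacterVector> reads2,
                      int k, double c, double seed, bool dedup) {
  check_k(k);
  uint64_t seedmix = splitmix64((uint64_t) (int64_t) seed);
  uint64_t thresh = keep_threshold53(c);
  bool paired = reads2.isNotNull();
  CharacterVector r2;
  if (paired) {
    r2 = reads2.get();
    if (r2.size() != reads1.size())
      stop("paired read streams differ in length: %d vs %d",
           (int) reads1.size(), (int) r2.size());
  }

  DedupStore store;
  store.salt = splitmix64((uint64_t) (int64_t) seed ^ 0xD1B54A32D192ED03ULL);
  std::unordered_map<uint64_t, int> counts;
  double total_bases = 0, n_reads = 0;
  std::vector<uint64_t> buf;

  for (R_xlen_t i = 0; i < reads1.size(); ++i) {
    SEXP e1 = STRING_ELT(reads1, i);
    if (e1 == NA_STRING) stop("NA read at record %d", (int) i + 1);
    const char *s1 = CHAR(e1);
    R_xlen_t n1 = (R_xlen_t) LENGTH(e1);
    total_bases += (double) n1;
    n_reads += 1;
    if (paired) {
      SEXP e2 = STRING_ELT(r2, i);
      if (e2 == NA_STRING) stop("NA read at record %d", (int) i + 1);
      const char *s2 = CHAR(e2);
      R_xlen_t n2 = (R_xlen_t) LENGTH(e2);
      total_bases += (double) n2;
      n_reads += 1;
      buf.clear();
      scan_kmers(s1, n1, k, seedmix, [&](R_xlen_t, uint64_t h) {
        if (h < thresh) buf.push_back(h);
      });
      scan_kmers(s2, n2, k, seedmix, [&](R_xlen_t, uint64_t h) {
        if (h < thresh) buf.push_back(h);
      });
      std::sort(buf.begin(), buf.end());
      buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
      bool can_dedup = dedup && n1 >= 32 && n2 >= 32;
      for (uint64_t h : buf) {
        if (can_dedup &&
            dedup_check_insert(&store, h, s1, n1, 0, s2, n2, 0))
          continue;
        ++counts[h];
      }
    } else {
      bool can_dedup = dedup && n1 <= 400 && n1 >= 32;
      R_xlen_t mid = 0;
      if (can_dedup) { mid = n1 / 2; if (mid > n1 - 32) mid = n1 - 32; }
      scan_kmers(s1, n1, k, seedmix, [&](R_xlen_t, uint64_t h) {
        if (h >= thresh) return;
        if (can_dedup) {
          auto it = counts.find(h);
          int cur = (it == counts.end()) ? 0 : it->second;
          if (cur < 4 &&
              dedup_check_insert(&store, h, s1, n1, 0, s1, n1, mid))
            return;
        }
        ++counts[h];
      });
    }
  }

  std::vector<std::pair<uint64_t, int>> items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  NumericVector hashes(items.size());
  IntegerVector mult(items.size());
  for (size_t j = 0; j < items.size(); ++j) {
    hashes[j] = (double) items[j].first;
    mult[j] = items[j].second;
  }
  return List::create(_["hashes"] = hashes, _["counts"] = mult,
                      _["total_bases"] = total_bases,
                      _["n_reads"] = n_reads,
                      _["mean_read_length"] =
                          n_reads > 0 ? total_bases / n_reads : 0.0);
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    if (el == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(el);
    R_xlen_t n = (R_xlen_t) LENGTH(el);
    buf.assign((size_t) n, 'N');
    for (R_xlen_t j = 0; j < n; ++j) {
      char b;
      switch (s[n - 1 - j]) {
      case 'A': b = 'T'; break; case 'a': b = 't'; break;
      case 'C': b = 'G'; break; case 'c': b = 'g'; break;
      case 'G': b = 'C'; break; case 'g': b = 'c'; break;
      case 'T': b = 'A'; break; case 't': b = 'a'; break;
      default: b = 'N';
      }
      buf[(size_t) j] = b;
    }
    out[i] = buf;
  }
  return out;
}
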