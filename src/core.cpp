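#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <set>
#include <vector>
#include <string>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hashing primitives.
//
// All randomness in the sketching pipeline is counter-based: a 64-bit mix
// function (splitmix64 finaliser) applied to keys derived from the master
// seed.  This makes every draw a pure function of its indices, so sketches
// are reproducible across calls, platforms and process counts.
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// strictly inside (0,1); safe for log()
static inline double u01(uint64_t h) {
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// domain tags keep the bin-assignment, count-min and CWS hash streams
// independent even though they share one master seed
static const uint64_t TAG_BIN = 0x42494E5F54414731ULL;
static const uint64_t TAG_CMS = 0x434D535F54414232ULL;
static const uint64_t TAG_CWS = 0x4357535F54414733ULL;

static inline uint64_t master64(int seed) {
  return mix64((uint64_t)(int64_t)seed);
}

// ---------------------------------------------------------------------------
// Canonical k-mer encoding: 2-bit packed (A=0, C=1, G=2, T=3), first base in
// the most significant bits; canonical value = min(forward, revcomp).
// Windows containing non-ACGT symbols are skipped.
// ---------------------------------------------------------------------------

static inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// rolling encoder; calls emit(canonical) for each valid window
template <typename F>
static void canonical_kmers(const char* s, size_t n, int k, F emit) {
  if ((size_t)k > n) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fw = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fw = 0; rc = 0; continue; }
    fw = ((fw << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) emit(fw < rc ? fw : rc);
  }
}

// [[Rcpp::export]]
NumericVector cpp_encode_canonical(std::string seq, int k) {
  std::vector<double> out;
  canonical_kmers(seq.c_str(), seq.size(), k,
                  [&](uint64_t v) { out.push_back((double)v); });
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_assign_bin(NumericVector kmers, int X, int seed) {
  uint64_t sb = mix64(master64(seed) ^ TAG_BIN);
  int n = kmers.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t key = (uint64_t)kmers[i];
    out[i] = (int)(mix64(key ^ sb) % (uint64_t)X) + 1;  // 1-based
  }
  return out;
}

// bins for every valid k-mer window across a vector of sequences
// [[Rcpp::export]]
IntegerVector cpp_seqs_to_bins(CharacterVector seqs, int k, int X, int seed) {
  uint64_t sb = mix64(master64(seed) ^ TAG_BIN);
  std::vector<int> out;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    canonical_kmers(s, strlen(s), k, [&](uint64_t v) {
      out.push_back((int)(mix64(v ^ sb) % (uint64_t)X) + 1);
    });
  }
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// Count-min sketch addressing: table t hashes the key with its own derived
// seed; returns 1-based column indices (depth x n).
// ---------------------------------------------------------------------------

static inline uint64_t cms_seed(uint64_t m64, int t) {
  return mix64(m64 ^ (TAG_CMS + (uint64_t)t));
}

// [[Rcpp::export]]
IntegerMatrix cpp_cms_cols(NumericVector keys, int depth, int width, int seed) {
  uint64_t m = master64(seed);
  int n = keys.size();
  IntegerMatrix out(depth, n);
  for (int t = 0; t < depth; ++t) {
    uint64_t st = cms_seed(m, t);
    for (int i = 0; i < n; ++i) {
      uint64_t key = (uint64_t)keys[i];
      out(t, i) = (int)(mix64(key ^ st) % (uint64_t)width) + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Consistent weighted sampling.
//
// Draws (r, c, beta) for histogram bin i and sketch slot j are a pure
// function of (i, j, master_seed): r and c are Gamma(shape = 2, scale = 1)
// (sum of two unit exponentials), beta is Uniform(0, 1).  The hash of a bin
// with weight w is a = exp(log c - (log w - r*beta) - r); the slot keeps the
// bin attaining the minimum, which selects bins with probability
// proportional to their weight.
// ---------------------------------------------------------------------------

struct Draw { double r, c, beta; };

static inline Draw cws_draw_ij(uint64_t seed_cws, int i, int j) {
  uint64_t s = mix64(mix64(seed_cws + (uint64_t)i) + (uint64_t)j);
  double u1 = u01(mix64(s + 1)), u2 = u01(mix64(s + 2));
  double u3 = u01(mix64(s + 3)), u4 = u01(mix64(s + 4));
  double u5 = u01(mix64(s + 5));
  Draw d;
  d.r = -std::log(u1) - std::log(u2);
  d.c = -std::log(u3) - std::log(u4);
  d.beta = u5;
  return d;
}

static inline uint64_t cws_seed(int seed) {
  return mix64(master64(seed) ^ TAG_CWS);
}

static inline double cws_a(double logw, const Draw& d) {
  return std::exp(std::log(d.c) - (logw - d.r * d.beta) - d.r);
}

// [[Rcpp::export]]
List cpp_cws_draw(IntegerVector i, IntegerVector j, int seed) {
  uint64_t sc = cws_seed(seed);
  int n = i.size();
  NumericVector r(n), c(n), beta(n);
  for (int q = 0; q < n; ++q) {
    Draw d = cws_draw_ij(sc, i[q], j[q]);
    r[q] = d.r; c[q] = d.c; beta[q] = d.beta;
  }
  return List::create(_["r"] = r, _["c"] = c, _["beta"] = beta);
}

// one-shot sketch of a (sparse) spectrum: bins ascending, weights > 0
// [[Rcpp::export]]
List cpp_create_sketch(IntegerVector bins, NumericVector weights, int Z,
                       int seed) {
  uint64_t sc = cws_seed(seed);
  int nb = bins.size();
  IntegerVector S(Z, NA_INTEGER);
  NumericVector A(Z, R_PosInf);
  std::vector<double> logw(nb);
  for (int b = 0; b < nb; ++b) logw[b] = std::log(weights[b]);
  for (int b = 0; b < nb; ++b) {
    int i = bins[b];
    for (int j = 0; j < Z; ++j) {
      double a = cws_a(logw[b], cws_draw_ij(sc, i, j + 1));
      if (a < A[j]) { A[j] = a; S[j] = i; }  // strict: ties keep lower bin
    }
  }
  return List::create(_["S"] = S, _["A"] = A);
}

// incremental update of one bin at cumulative frequency f
// [[Rcpp::export]]
List cpp_update_slots(IntegerVector S, NumericVector A, int bin, double f,
                      int seed) {
  uint64_t sc = cws_seed(seed);
  int Z = S.size();
  IntegerVector S2 = clone(S);
  NumericVector A2 = clone(A);
  double logw = std::log(f);
  for (int j = 0; j < Z; ++j) {
    double a = cws_a(logw, cws_draw_ij(sc, bin, j + 1));
    if (a < A2[j]) { A2[j] = a; S2[j] = bin; }
  }
  return List::create(_["S"] = S2, _["A"] = A2);
}

// ---------------------------------------------------------------------------
// Element-wise incremental sketching: each (bin, amount) arrival is credited
// to a persistent count-min sketch and the slots are re-evaluated at the
// bin's cumulative frequency estimate.  Used for replaying pre-binned
// streams; equivalent to one-shot creation when the count-min estimates are
// exact.
// ---------------------------------------------------------------------------

struct Cms {
  int depth, width;
  std::vector<uint64_t> seeds;
  std::vector<double> counters;  // depth x width, row-major
  Cms(int d, int w, uint64_t m) : depth(d), width(w), counters((size_t)d * w, 0.0) {
    for (int t = 0; t < d; ++t) seeds.push_back(cms_seed(m, t));
  }
  void add(uint64_t key, double amt) {
    for (int t = 0; t < depth; ++t)
      counters[(size_t)t * width + (mix64(key ^ seeds[t]) % (uint64_t)width)] += amt;
  }
  double estimate(uint64_t key) const {
    double m = R_PosInf;
    for (int t = 0; t < depth; ++t) {
      double v = counters[(size_t)t * width + (mix64(key ^ seeds[t]) % (uint64_t)width)];
      if (v < m) m = v;
    }
    return m;
  }
  void scale(double f) {
    for (auto& v : counters) v *= f;
  }
};

// [[Rcpp::export]]
List cpp_sketch_bin_stream(IntegerVector bins, NumericVector amounts, int Z,
                           int depth, int width, int seed) {
  uint64_t m = master64(seed);
  uint64_t sc = cws_seed(seed);
  Cms cms(depth, width, m);
  std::vector<int> S(Z, NA_INTEGER);
  std::vector<double> A(Z, R_PosInf);
  int n = bins.size();
  for (int e = 0; e < n; ++e) {
    int bin = bins[e];
    cms.add((uint64_t)bin, amounts[e]);
    double logw = std::log(cms.estimate((uint64_t)bin));
    for (int j = 0; j < Z; ++j) {
      double a = cws_a(logw, cws_draw_ij(sc, bin, j + 1));
      if (a < A[j]) { A[j] = a; S[j] = bin; }
    }
  }
  NumericMatrix counters(depth, width);
  for (int t = 0; t < depth; ++t)
    for (int w = 0; w < width; ++w) counters(t, w) = cms.counters[(size_t)t * width + w];
  return List::create(_["S"] = IntegerVector(S.begin(), S.end()),
                      _["A"] = NumericVector(A.begin(), A.end()),
                      _["counters"] = counters);
}

// ---------------------------------------------------------------------------
// Streaming sketcher: n independent counting workers, each with a local
// count-min sketch keyed by histogram bin, feeding one sketching process.
// Reads are dealt round-robin to the workers; when a worker has consumed
// `interval` reads it flushes its touched (bin, estimate) elements to the
// sketcher, which credits them to a persistent count-min sketch, applies
// decay (once per flush, if enabled), re-evaluates the slots at the
// cumulative estimates, and snapshots the sketch.  Flushed bins are
// processed in ascending order; with decay off the final sketch is
// independent of worker count and read order.
// ---------------------------------------------------------------------------

struct Sketcher {
  int k, Z, X, depth, width, seed, interval, ncount;
  double decay;
  uint64_t seed_bin, seed_cws;
  Cms pcms;
  std::vector<Cms> lcms;
  std::vector<std::set<int>> touched;
  std::vector<long long> worker_reads;
  long long reads = 0, kmers = 0;
  std::vector<int> S;
  std::vector<double> A;

  Sketcher(int k_, int Z_, int X_, int depth_, int width_, int seed_,
           int interval_, int ncount_, double decay_)
      : k(k_), Z(Z_), X(X_), depth(depth_), width(width_), seed(seed_),
        interval(interval_), ncount(ncount_), decay(decay_),
        pcms(depth_, width_, master64(seed_)) {
    seed_bin = mix64(master64(seed) ^ TAG_BIN);
    seed_cws = cws_seed(seed);
    for (int c = 0; c < ncount; ++c) lcms.emplace_back(depth, width, master64(seed));
    touched.resize(ncount);
    worker_reads.assign(ncount, 0);
    S.assign(Z, NA_INTEGER);
    A.assign(Z, R_PosInf);
  }

  void count_read(const char* s, size_t n) {
    int c = (int)(reads % ncount);
    canonical_kmers(s, n, k, [&](uint64_t v) {
      int bin = (int)(mix64(v ^ seed_bin) % (uint64_t)X) + 1;
      lcms[c].add((uint64_t)bin, 1.0);
      touched[c].insert(bin);
      ++kmers;
    });
    ++reads;
    ++worker_reads[c];
  }

  bool worker_due(int c) const {
    return interval > 0 && worker_reads[c] > 0 && worker_reads[c] % interval == 0;
  }

  void flush(int c) {
    if (decay > 0) {
      double w = 1.0 - decay;
      pcms.scale(w);
      for (int j = 0; j < Z; ++j) A[j] /= w;  // +Inf stays +Inf
    }
    for (int bin : touched[c]) {
      double est = lcms[c].estimate((uint64_t)bin);
      pcms.add((uint64_t)bin, est);
      double logw = std::log(pcms.estimate((uint64_t)bin));
      for (int j = 0; j < Z; ++j) {
        double a = cws_a(logw, cws_draw_ij(seed_cws, bin, j + 1));
        if (a < A[j]) { A[j] = a; S[j] = bin; }
      }
    }
    touched[c].clear();
    std::fill(lcms[c].counters.begin(), lcms[c].counters.end(), 0.0);
    worker_reads[c] = 0;
  }

  List snapshot() const {
    return List::create(_["S"] = IntegerVector(S.begin(), S.end()),
                        _["A"] = NumericVector(A.begin(), A.end()),
                        _["reads_consumed"] = (double)reads,
                        _["kmers"] = (double)kmers);
  }
};

// [[Rcpp::export]]
SEXP cpp_sketcher_new(int k, int Z, int X, int depth, int width, int seed,
                      int interval, int ncount, double decay) {
  XPtr<Sketcher> p(new Sketcher(k, Z, X, depth, width, seed, interval, ncount,
                                decay), true);
  return p;
}

// feed a batch of reads; returns snapshots produced by interval flushes
// [[Rcpp::export]]
List cpp_sketcher_add(SEXP ptr, CharacterVector bases) {
  XPtr<Sketcher> p(ptr);
  List out;
  for (R_xlen_t i = 0; i < bases.size(); ++i) {
    const char* s = CHAR(STRING_ELT(bases, i));
    int c = (int)(p->reads % p->ncount);
    p->count_read(s, strlen(s));
    if (p->worker_due(c)) {
      p->flush(c);
      out.push_back(p->snapshot());
    }
  }
  return out;
}

// flush all pending counts and return the final snapshot
// [[Rcpp::export]]
List cpp_sketcher_finalize(SEXP ptr) {
  XPtr<Sketcher> p(ptr);
  for (int c = 0; c < p->ncount; ++c)
    if (!p->touched[c].empty()) p->flush(c);
  return p->snapshot();
}

// [[Rcpp::export]]
double cpp_sketcher_kmers(SEXP ptr) {
  XPtr<Sketcher> p(ptr);
  return (double)p->kmers;
}
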