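// Core scanning engine: 2-bit DNA packing, seeded m-mer hashing, sliding
// window minimizer selection, super-k-mer accounting, partition building and
// greedy reassembly. Everything here assumes pure A/C/G/T input; splitting at
// ambiguous bases happens on the R side.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>
#include <deque>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// hash values live in [0, 2^53) so they stay exact in an R double
static const double HSPACE53 = 9007199254740992.0;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct HashCtx {
  int m;
  uint64_t seedmix;
  bool canonical;
  bool lex;     // lexicographic order: hash = 2-bit packed value on [0, 4^m)
  double space; // size of the hash space
};

static HashCtx make_ctx(int m, double seed, bool canonical, bool lex) {
  HashCtx ctx;
  ctx.m = m;
  ctx.seedmix = splitmix64((uint64_t)(int64_t)seed);
  ctx.canonical = canonical;
  ctx.lex = lex;
  ctx.space = lex ? std::pow(4.0, m) : HSPACE53;
  if (lex && m > 26) stop("lexicographic order requires m <= 26");
  return ctx;
}

static inline double hash_packed(uint64_t fwd, uint64_t rc, const HashCtx& ctx) {
  if (ctx.lex) {
    uint64_t v = (ctx.canonical && rc < fwd) ? rc : fwd;
    return (double)v;
  }
  uint64_t h = splitmix64(fwd ^ ctx.seedmix) >> 11;
  if (ctx.canonical) {
    uint64_t h2 = splitmix64(rc ^ ctx.seedmix) >> 11;
    if (h2 < h) h = h2;
  }
  return (double)h;
}

static void check_acgt(const std::string& s, const char* what) {
  for (size_t i = 0; i < s.size(); ++i)
    if (base_code(s[i]) < 0)
      stop("invalid DNA alphabet in %s: character '%c' (only A/C/G/T allowed)",
           what, s[i]);
}

// hashes of all m-mer start positions of a pure-ACGT fragment
static void mmer_hash_vector(const std::string& s, const HashCtx& ctx,
                             std::vector<double>& out) {
  int m = ctx.m;
  int n = (int)s.size() - m + 1;
  out.clear();
  if (n <= 0) return;
  out.resize(n);
  uint64_t mask = (m == 32) ? ~0ULL : ((1ULL << (2 * m)) - 1);
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (m - 1)));
    if (i >= m - 1) out[i - m + 1] = hash_packed(fwd, rc, ctx);
  }
}

// ---- decycling set membership (complex embedding criterion) ----------------

static bool decycling_digits(const std::vector<int>& d) {
  int m = (int)d.size();
  double re = 0.0, im = 0.0;
  for (int j = 0; j < m; ++j) {
    double a = 2.0 * M_PI * j / m;
    re += d[j] * std::cos(a);
    im += d[j] * std::sin(a);
  }
  if (re * re + im * im > 1e-12) {
    double a = std::atan2(im, re);
    double step = 2.0 * M_PI / m;
    return a > 1e-9 && a <= step + 1e-9;
  }
  // zero embedding (e.g. periodic words): keep the word iff it equals its
  // lexicographically minimal rotation, which still hits every rotation class
  for (int r = 1; r < m; ++r) {
    for (int j = 0; j < m; ++j) {
      int a = d[(j + r) % m], b = d[j];
      if (a < b) return false;
      if (a > b) break;
    }
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_decycling_member(CharacterVector mmers) {
  int n = mmers.size();
  LogicalVector out(n);
  std::vector<int> d;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(mmers[i]);
    check_acgt(s, "m-mer");
    d.resize(s.size());
    for (size_t j = 0; j < s.size(); ++j) d[j] = base_code(s[j]);
    out[i] = decycling_digits(d);
  }
  return out;
}

static void decycling_mask(const std::string& s, int m, std::vector<char>& ok) {
  int n = (int)s.size() - m + 1;
  ok.clear();
  if (n <= 0) return;
  ok.resize(n);
  std::vector<int> d(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) d[j] = base_code(s[i + j]);
    ok[i] = decycling_digits(d) ? 1 : 0;
  }
}

// ---- m-mer hashing (exported) ----------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_hash_mmers(CharacterVector mmers, double seed, bool canonical,
                             bool lex) {
  int n = mmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(mmers[i]);
    check_acgt(s, "m-mer");
    int m = (int)s.size();
    if (m < 1 || m > 26) stop("m-mer length must be in [1, 26]");
    HashCtx ctx = make_ctx(m, seed, canonical, lex);
    uint64_t fwd = 0, rc = 0;
    for (int j = 0; j < m; ++j) {
      int c = base_code(s[j]);
      fwd = (fwd << 2) | (uint64_t)c;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (m - 1)));
    }
    out[i] = hash_packed(fwd, rc, ctx);
  }
  return out;
}

// ---- sliding-window minimizer scan -----------------------------------------

// Calls f(kmer_start, minimizer_pos, minimizer_hash) for every k-mer of the
// fragment. Leftmost position wins ties. With `uhs`, only decycling-set
// members are eligible; a window with no eligible m-mer reports the leftmost
// position with hash +Inf (never small).
template <class F>
static void scan_kmers(const std::string& s, int k, int m, const HashCtx& ctx,
                       bool uhs, double, F&& f) {
  int L = (int)s.size();
  int nk = L - k + 1;
  if (nk <= 0) return;
  int w = k - m + 1;
  std::vector<double> hv;
  mmer_hash_vector(s, ctx, hv);
  if (uhs) {
    std::vector<char> ok;
    decycling_mask(s, m, ok);
    for (size_t i = 0; i < hv.size(); ++i)
      if (!ok[i]) hv[i] = R_PosInf;
  }
  std::deque<int> dq; // indices with increasing hash; front = current minimum
  for (int i = 0; i < (int)hv.size(); ++i) {
    while (!dq.empty() && hv[dq.back()] > hv[i]) dq.pop_back();
    dq.push_back(i);
    int kstart = i - w + 1; // k-mer whose window ends at m-mer i
    if (kstart < 0) continue;
    while (dq.front() < kstart) dq.pop_front();
    f(kstart, dq.front(), hv[dq.front()]);
  }
}

// [[Rcpp::export]]
List cpp_scan_kmers(std::string seq, int k, int m, double seed, bool canonical,
                    bool lex, bool uhs, double t) {
  check_acgt(seq, "sequence");
  HashCtx ctx = make_ctx(m, seed, canonical, lex);
  int nk = (int)seq.size() - k + 1;
  if (nk < 0) nk = 0;
  IntegerVector minpos(nk);
  NumericVector minhash(nk);
  LogicalVector small(nk);
  scan_kmers(seq, k, m, ctx, uhs, t, [&](int i, int mp, double h) {
    minpos[i] = mp;
    minhash[i] = h;
    small[i] = h < t;
  });
  return List::create(_["minpos"] = minpos, _["minhash"] = minhash,
                      _["small"] = small);
}

// ---- density / coverage / maximal-proportion accounting --------------------

// [[Rcpp::export]]
List cpp_density_stats(CharacterVector seqs, int k, int m, double seed,
                       bool canonical, bool lex, bool uhs, double t) {
  HashCtx ctx = make_ctx(m, seed, canonical, lex);
  int w = k - m + 1;
  double mmer_positions = 0, kmers = 0, covered_kmers = 0;
  double covered_mmer_positions = 0;
  double superkmers_small = 0, maximal_small = 0;
  double superkmers_all = 0, maximal_all = 0;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    check_acgt(s, "sequence");
    if ((int)s.size() >= m) mmer_positions += (double)(s.size() - m + 1);
    if ((int)s.size() < k) continue;
    int last_mp = -1;
    int run_len = 0;          // k-mers in current super-k-mer
    bool run_small = false;
    int cov_run = 0;          // consecutive covered k-mers
    auto close_skm = [&]() {
      if (run_len == 0) return;
      superkmers_all += 1;
      if (run_len == w) maximal_all += 1;
      if (run_small) {
        superkmers_small += 1;
        if (run_len == w) maximal_small += 1;
      }
    };
    scan_kmers(s, k, m, ctx, uhs, t, [&](int i, int mp, double h) {
      kmers += 1;
      bool cov = h < t;
      if (cov) {
        covered_kmers += 1;
        cov_run += 1;
      } else {
        if (cov_run > 0) covered_mmer_positions += (double)(cov_run - 1 + w);
        cov_run = 0;
      }
      if (mp != last_mp) {
        close_skm();
        run_len = 1;
        run_small = cov;
        last_mp = mp;
      } else {
        run_len += 1;
      }
      (void)i;
    });
    close_skm();
    if (cov_run > 0) covered_mmer_positions += (double)(cov_run - 1 + w);
  }
  return List::create(
      _["mmer_positions"] = mmer_positions, _["kmers"] = kmers,
      _["covered_kmers"] = covered_kmers,
      _["covered_mmer_positions"] = covered_mmer_positions,
      _["superkmers_small"] = superkmers_small,
      _["maximal_small"] = maximal_small,
      _["superkmers_all"] = superkmers_all, _["maximal_all"] = maximal_all);
}

// ---- partition building ----------------------------------------------------

struct KmerInfo {
  int offset; // minimizer occurrence offset within the k-mer
  int count;  // occurrences across the whole input
};

// [[Rcpp::export]]
List cpp_build_partitions(CharacterVector seqs, int k, int m, double seed,
                          bool canonical, bool lex, bool uhs, double t) {
  HashCtx ctx = make_ctx(m, seed, canonical, lex);
  std::unordered_map<std::string, KmerInfo> kmap;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    check_acgt(s, "sequence");
    scan_kmers(s, k, m, ctx, uhs, t, [&](int i, int mp, double h) {
      if (h >= t) return;
      std::string kmer = s.substr(i, k);
      auto it = kmap.find(kmer);
      if (it == kmap.end()) {
        kmap.emplace(std::move(kmer), KmerInfo{mp - i, 1});
      } else {
        it->second.count += 1;
      }
    });
  }
  // deterministic order: by minimizer string, then k-mer string
  std::vector<const std::pair<const std::string, KmerInfo>*> items;
  items.reserve(kmap.size());
  for (auto& kv : kmap) items.push_back(&kv);
  std::sort(items.begin(), items.end(), [&](const auto* a, const auto* b) {
    int c = a->first.compare(a->second.offset, m, b->first, b->second.offset, m);
    if (c != 0) return c < 0;
    return a->first < b->first;
  });
  int n = (int)items.size();
  CharacterVector kmer(n), minimizer(n);
  IntegerVector offset(n), count(n);
  for (int i = 0; i < n; ++i) {
    kmer[i] = items[i]->first;
    minimizer[i] = items[i]->first.substr(items[i]->second.offset, m);
    offset[i] = items[i]->second.offset;
    count[i] = items[i]->second.count;
  }
  return List::create(_["kmer"] = kmer, _["minimizer"] = minimizer,
                      _["offset"] = offset, _["count"] = count);
}

// ---- greedy super-k-mer reassembly -----------------------------------------

// Input: distinct k-mers of one partition with their minimizer offsets.
// Chains are seeded at k-mers with no available predecessor (processing
// offsets high to low, so minimizer-as-suffix seeds come first) and extended
// rightwards greedily; within a super-k-mer the shared minimizer occurrence
// offset decreases by one per step.
// [[Rcpp::export]]
List cpp_reassemble(CharacterVector kmers, IntegerVector offsets, int k, int m) {
  int n = kmers.size();
  int w = k - m + 1;
  std::unordered_map<std::string, int> idx; // kmer -> input index
  std::vector<std::string> ks(n);
  for (int i = 0; i < n; ++i) {
    ks[i] = as<std::string>(kmers[i]);
    if ((int)ks[i].size() != k) stop("k-mer of wrong length");
    idx[ks[i]] = i;
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (offsets[a] != offsets[b]) return offsets[a] > offsets[b];
    return ks[a] < ks[b];
  });
  std::vector<char> used(n, 0);
  std::vector<std::string> out_seq;
  std::vector<int> out_off, out_nk;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (used[i]) continue;
    used[i] = 1;
    std::string sk = ks[i];
    int q = offsets[i];
    int q0 = q;
    int len = 1;
    std::string cur = ks[i];
    while (q > 0) {
      bool ext = false;
      for (int b = 0; b < 4; ++b) {
        std::string cand = cur.substr(1) + BASES[b];
        auto it = idx.find(cand);
        if (it != idx.end() && !used[it->second] &&
            offsets[it->second] == q - 1) {
          used[it->second] = 1;
          sk.push_back(BASES[b]);
          cur = cand;
          q -= 1;
          len += 1;
          ext = true;
          break;
        }
      }
      if (!ext) break;
    }
    out_seq.push_back(sk);
    out_off.push_back(q0);
    out_nk.push_back(len);
  }
  int nout = (int)out_seq.size();
  CharacterVector rs(nout);
  IntegerVector ro(nout), rn(nout);
  LogicalVector rm(nout);
  for (int i = 0; i < nout; ++i) {
    rs[i] = out_seq[i];
    ro[i] = out_off[i];
    rn[i] = out_nk[i];
    rm[i] = out_nk[i] == w;
  }
  return List::create(_["superkmer"] = rs, _["offset"] = ro,
                      _["nkmers"] = rn, _["maximal"] = rm);
}

// ---- misc k-mer utilities --------------------------------------------------

// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> cnt;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    check_acgt(s, "sequence");
    int nk = (int)s.size() - k + 1;
    for (int i = 0; i < nk; ++i) cnt[s.substr(i, k)] += 1;
  }
  std::vector<const std::pair<const std::string, int>*> items;
  items.reserve(cnt.size());
  for (auto& kv : cnt) items.push_back(&kv);
  std::sort(items.begin(), items.end(),
            [](const auto* a, const auto* b) { return a->first < b->first; });
  int n = (int)items.size();
  CharacterVector kmer(n);
  IntegerVector count(n);
  for (int i = 0; i < n; ++i) {
    kmer[i] = items[i]->first;
    count[i] = items[i]->second;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// [[Rcpp::export]]
CharacterVector cpp_superkmers_to_kmers(CharacterVector sks, int k) {
  std::vector<std::string> out;
  for (int si = 0; si < sks.size(); ++si) {
    std::string s = as<std::string>(sks[si]);
    int nk = (int)s.size() - k + 1;
    for (int i = 0; i < nk; ++i) out.push_back(s.substr(i, k));
  }
  return wrap(out);
}

// ---- 2-bit packing for serialization ---------------------------------------

// [[Rcpp::export]]
List cpp_pack_dna(CharacterVector seqs) {
  List out(seqs.size());
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    check_acgt(s, "sequence");
    int nb = ((int)s.size() + 3) / 4;
    RawVector rv(nb);
    for (int i = 0; i < nb; ++i) rv[i] = 0;
    for (int i = 0; i < (int)s.size(); ++i)
      rv[i / 4] |= (Rbyte)(base_code(s[i]) << (2 * (3 - i % 4)));
    out[si] = rv;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_unpack_dna(List raws, IntegerVector lens) {
  int n = raws.size();
  CharacterVector out(n);
  for (int si = 0; si < n; ++si) {
    RawVector rv = raws[si];
    int len = lens[si];
    std::string s(len, 'A');
    for (int i = 0; i < len; ++i)
      s[i] = BASES[(rv[i / 4] >> (2 * (3 - i % 4))) & 3];
    out[si] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pack_value(CharacterVector mmers) {
  int n = mmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(mmers[i]);
    check_acgt(s, "m-mer");
    if (s.size() > 26) stop("packed value exact only up to 26 bases");
    uint64_t v = 0;
    for (size_t j = 0; j < s.size(); ++j)
      v = (v << 2) | (uint64_t)base_code(s[j]);
    out[i] = (double)v;
  }
  return out;
}
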