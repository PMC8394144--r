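// Low-level sequence kernels: canonical k-mer hashing for MinHash sketches,
// seed-and-extend fragment mapping for ANI, and unique-anchor block finding
// for conspecific whole-genome alignment.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static const uint64_t MASK53 = ((uint64_t)1 << 53) - 1;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

// 2-bit base code preserving lexicographic order (A<C<G<T); -1 for non-ACGT
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate canonical k-mer codes of one sequence; calls f(pos, canon, is_forward)
// for every valid (all-ACGT) k-mer. pos is 0-based within seq.
template <typename F>
static void scan_canonical(const std::string& seq, int k, F f) {
  const int n = (int)seq.size();
  if (n < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t kmask = (k == 32) ? ~0ULL : (((uint64_t)1 << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & kmask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      bool isfwd = fwd <= rev;
      f(i - k + 1, isfwd ? fwd : rev, isfwd);
    }
  }
}

// Bottom-s MinHash sketch over canonical k-mers of a set of contigs.
// Hash values are 64-bit mixes masked to 53 bits (exact as R doubles).
// [[Rcpp::export]]
NumericVector cpp_minhash_sketch(CharacterVector contigs, int k, int s,
                                 double hash_seed) {
  uint64_t seedmix = mix64((uint64_t)hash_seed);
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> hashes;
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    scan_canonical(seq, k, [&](int, uint64_t canon, bool) {
      uint64_t h = mix64(canon ^ seedmix) & MASK53;
      if (seen.insert(h).second) hashes.push_back(h);
    });
  }
  if (hashes.empty()) stop("no k-mers: all contigs shorter than k or non-ACGT");
  if ((int)hashes.size() > s) {
    std::partial_sort(hashes.begin(), hashes.begin() + s, hashes.end());
    hashes.resize(s);
  } else {
    std::sort(hashes.begin(), hashes.end());
  }
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
  return out;
}

// All distinct canonical k-mer hashes (sorted); the full-set side of the
// exact-Jaccard comparison.
// [[Rcpp::export]]
NumericVector cpp_all_kmer_hashes(CharacterVector contigs, int k,
                                  double hash_seed) {
  uint64_t seedmix = mix64((uint64_t)hash_seed);
  std::unordered_set<uint64_t> seen;
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    scan_canonical(seq, k, [&](int, uint64_t canon, bool) {
      seen.insert(mix64(canon ^ seedmix) & MASK53);
    });
  }
  std::vector<uint64_t> hashes(seen.begin(), seen.end());
  std::sort(hashes.begin(), hashes.end());
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
  return out;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Banded fitting alignment of a window against a reference segment (free
// leading/trailing gaps on the reference side), maximizing match count with
// mismatch/gap penalties; returns identical columns.
static int banded_matches(const std::string& w, const std::string& r, int band) {
  const int n = (int)w.size(), m = (int)r.size();
  const double NEG = -1e18, MATCH = 1.0, MISMATCH = -1.0, GAP = -1.5;
  std::vector<double> prev(2 * band + 1, NEG), cur(2 * band + 1, NEG);
  std::vector<int> pm(2 * band + 1, 0), cm(2 * band + 1, 0);
  // state: row i (0..n over w), offset j-i in [-band, band];
  // the window is expected to start near r[0], so offsets >= 0 start free
  for (int d = 0; d <= band; ++d) { prev[band + d] = 0.0; pm[band + d] = 0; }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int o = -band; o <= band; ++o) {
      int j = i + o;
      if (j < 0 || j > m) continue;
      double best = NEG; int bm = 0;
      if (j >= 1 && prev[band + o] > NEG) { // diagonal
        bool eq = w[i - 1] == r[j - 1] && w[i - 1] != 'N';
        double sc = prev[band + o] + (eq ? MATCH : MISMATCH);
        if (sc > best) { best = sc; bm = pm[band + o] + (eq ? 1 : 0); }
      }
      if (o + 1 <= band && prev[band + o + 1] > NEG) { // gap in r (advance i)
        double sc = prev[band + o + 1] + GAP;
        if (sc > best) { best = sc; bm = pm[band + o + 1]; }
      }
      if (j >= 1 && o - 1 >= -band && cur[band + o - 1] > NEG) { // gap in w
        double sc = cur[band + o - 1] + GAP;
        if (sc > best) { best = sc; bm = cm[band + o - 1]; }
      }
      cur[band + o] = best; cm[band + o] = bm;
    }
    std::swap(prev, cur); std::swap(pm, cm);
  }
  int best_m = 0; double best_s = NEG;
  for (int o = -band; o <= band; ++o) {
    int j = n + o;
    if (j < 0 || j > m || prev[band + o] <= NEG) continue;
    if (prev[band + o] > best_s) { best_s = prev[band + o]; best_m = pm[band + o]; }
  }
  return best_m;
}

// Map frag_len windows of the query onto the reference by exact seed k-mers
// plus banded extension. Returns per-window length, identity and mapped flag.
// [[Rcpp::export]]
List cpp_fragment_map(CharacterVector query_contigs, CharacterVector ref_contigs,
                      int frag_len, int min_frag, int seed_k, double min_ident,
                      int band, int max_occ) {
  // reference: concatenated string + per-contig canonical seed index
  std::string refcat;
  std::vector<std::string> refs(ref_contigs.size());
  for (int i = 0; i < ref_contigs.size(); ++i) {
    refs[i] = as<std::string>(ref_contigs[i]);
    refcat += refs[i];
  }
  struct Hit { int pos; bool fwd; };
  std::unordered_map<uint64_t, std::vector<Hit>> index;
  std::vector<long long> cbounds; // ref contig start offsets + total length
  {
    long offset = 0;
    for (size_t ci = 0; ci < refs.size(); ++ci) {
      cbounds.push_back(offset);
      scan_canonical(refs[ci], seed_k, [&](int p, uint64_t canon, bool isfwd) {
        auto& v = index[canon];
        if ((int)v.size() <= max_occ) v.push_back({(int)(offset + p), isfwd});
      });
      offset += refs[ci].size();
    }
    cbounds.push_back(offset);
    for (auto it = index.begin(); it != index.end();) {
      if ((int)it->second.size() > max_occ) it = index.erase(it); else ++it;
    }
  }
  std::vector<int> wlens; std::vector<double> idents; std::vector<int> mapped;
  for (int qi = 0; qi < query_contigs.size(); ++qi) {
    std::string q = as<std::string>(query_contigs[qi]);
    for (size_t start = 0; start < q.size(); start += frag_len) {
      int wlen = std::min((size_t)frag_len, q.size() - start);
      if (wlen < min_frag) break;
      std::string w = q.substr(start, wlen);
      // vote on (orientation, diagonal)
      std::unordered_map<long long, int> votes_f, votes_r;
      scan_canonical(w, seed_k, [&](int p, uint64_t canon, bool isfwd) {
        auto it = index.find(canon);
        if (it == index.end()) return;
        for (const Hit& h : it->second) {
          if (h.fwd == isfwd) votes_f[(long long)h.pos - p] += 1;
          else votes_r[(long long)h.pos + p] += 1;
        }
      });
      long long best_d = 0; int best_v = 0; bool best_fwd = true;
      for (auto& kv : votes_f)
        if (kv.second > best_v) { best_v = kv.second; best_d = kv.first; best_fwd = true; }
      for (auto& kv : votes_r)
        if (kv.second > best_v) { best_v = kv.second; best_d = kv.first; best_fwd = false; }
      wlens.push_back(wlen);
      if (best_v < 2) { idents.push_back(0.0); mapped.push_back(0); continue; }
      std::string ww = w;
      long long rstart;
      if (best_fwd) {
        rstart = best_d;
      } else {
        // reverse-complement the window; anti-diagonal c = rpos + qpos means
        // rc-window position p' = wlen - seed_k - p aligns at c - wlen + seed_k + p'
        std::string rc(ww.rbegin(), ww.rend());
        for (auto& ch : rc) ch = comp_base(ch);
        ww = rc;
        rstart = best_d - wlen + seed_k;
      }
      // clip the comparison to the ref contig the diagonal lands in, so a
      // window overlapping a contig junction in the concatenated reference
      // is scored only over the region it can genuinely align to
      long long mid = rstart + wlen / 2;
      if (mid < 0) mid = 0;
      if (mid >= (long long)refcat.size()) mid = refcat.size() - 1;
      auto it_c = std::upper_bound(cbounds.begin(), cbounds.end(), mid);
      long long cend = *it_c;
      long long cstart_ref = *(it_c - 1);
      long long lo = std::max(rstart, cstart_ref);
      long long p0 = lo - rstart;                  // skipped window prefix
      long long cmp_len = std::min((long long)wlen - p0, cend - lo);
      if (cmp_len < std::max(min_frag / 2, seed_k)) {
        idents.push_back(0.0); mapped.push_back(0);
        wlens.back() = (int)std::max(cmp_len, (long long)0);
        continue;
      }
      // ungapped comparison at the voted diagonal is exact when the window
      // holds no indel; fall back to banded DP only when it looks gappy
      int direct = 0;
      for (long long p = 0; p < cmp_len; ++p)
        if (ww[p0 + p] == refcat[lo + p]) ++direct;
      int matches = direct;
      if ((double)direct / cmp_len < 0.9) {
        long long hi = std::min(lo + cmp_len + band, cend);
        std::string wsub = ww.substr(p0, cmp_len);
        std::string rseg = refcat.substr(lo, hi - lo);
        matches = std::max(direct, banded_matches(wsub, rseg, band));
      }
      double ident = (double)matches / (double)cmp_len;
      wlens.back() = (int)cmp_len; // effective compared length
      idents.push_back(ident);
      mapped.push_back(ident >= min_ident ? 1 : 0);
    }
  }
  return List::create(_["wlen"] = wrap(wlens), _["identity"] = wrap(idents),
                      _["mapped"] = wrap(mapped));
}

// Fenwick tree for maximum prefix queries (weighted LIS chaining)
struct FenwickMax {
  std::vector<double> val; std::vector<int> arg;
  FenwickMax(int n) : val(n + 1, -1.0), arg(n + 1, -1) {}
  void update(int i, double v, int a) {
    for (++i; i < (int)val.size(); i += i & (-i))
      if (v > val[i]) { val[i] = v; arg[i] = a; }
  }
  std::pair<double, int> query(int i) { // max over [0, i]
    double v = -1.0; int a = -1;
    for (++i; i > 0; i -= i & (-i))
      if (val[i] > v) { v = val[i]; a = arg[i]; }
    return {v, a};
  }
};

// Maximal blocks of exact matches anchored by k-mers unique in both genomes,
// chained collinearly (weighted LIS on g-coordinates). Coordinates are 0-based
// and global over the concatenation of each genome's contigs.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_blocks(CharacterVector rep_contigs,
                                CharacterVector g_contigs, int anchor_len) {
  const int k = anchor_len;
  if (k < 2 || k > 32) stop("anchor_len must be in [2, 32]");
  struct Occ { int count; int pos; };
  auto build = [&](CharacterVector contigs) {
    std::unordered_map<uint64_t, Occ> map;
    long offset = 0;
    for (int ci = 0; ci < contigs.size(); ++ci) {
      std::string seq = as<std::string>(contigs[ci]);
      // forward-strand k-mers only: conspecific genomes share orientation
      const int n = (int)seq.size();
      uint64_t fwd = 0;
      const uint64_t kmask = (k == 32) ? ~0ULL : (((uint64_t)1 << (2 * k)) - 1);
      int valid = 0;
      for (int i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & kmask;
        if (++valid >= k) {
          auto it = map.find(fwd);
          if (it == map.end()) map[fwd] = {1, (int)(offset + i - k + 1)};
          else it->second.count += 1;
        }
      }
      offset += n;
    }
    return map;
  };
  auto rmap = build(rep_contigs);
  auto gmap = build(g_contigs);
  std::vector<std::pair<int, int>> anchors; // (rpos, gpos)
  for (const auto& kv : rmap) {
    if (kv.second.count != 1) continue;
    auto it = gmap.find(kv.first);
    if (it == gmap.end() || it->second.count != 1) continue;
    anchors.push_back({kv.second.pos, it->second.pos});
  }
  if (anchors.empty()) return IntegerMatrix(0, 3);
  std::sort(anchors.begin(), anchors.end());
  // merge diagonal runs into maximal blocks
  struct Block { int r, g, len; };
  std::vector<Block> blocks;
  Block cur{anchors[0].first, anchors[0].second, k};
  for (size_t i = 1; i < anchors.size(); ++i) {
    int r = anchors[i].first, g = anchors[i].second;
    int exp_r = cur.r + cur.len - k + 1;
    if (r <= exp_r && (r - cur.r) == (g - cur.g)) {
      int newlen = r - cur.r + k;
      if (newlen > cur.len) cur.len = newlen;
    } else {
      blocks.push_back(cur);
      cur = {r, g, k};
    }
  }
  blocks.push_back(cur);
  // collinear chaining: maximize total length with strictly increasing g
  const int nb = (int)blocks.size();
  std::vector<int> gs(nb);
  for (int i = 0; i < nb; ++i) gs[i] = blocks[i].g;
  std::vector<int> sorted_g(gs); std::sort(sorted_g.begin(), sorted_g.end());
  sorted_g.erase(std::unique(sorted_g.begin(), sorted_g.end()), sorted_g.end());
  auto rank = [&](int g) {
    return (int)(std::lower_bound(sorted_g.begin(), sorted_g.end(), g)
                 - sorted_g.begin());
  };
  FenwickMax fw((int)sorted_g.size());
  std::vector<double> score(nb); std::vector<int> prev(nb, -1);
  for (int i = 0; i < nb; ++i) { // blocks already sorted by r
    int ri = rank(blocks[i].g);
    auto best = ri > 0 ? fw.query(ri - 1) : std::make_pair(-1.0, -1);
    score[i] = blocks[i].len + (best.first > 0 ? best.first : 0.0);
    prev[i] = best.first > 0 ? best.second : -1;
    fw.update(ri, score[i], i);
  }
  int besti = 0;
  for (int i = 1; i < nb; ++i) if (score[i] > score[besti]) besti = i;
  std::vector<int> chain;
  for (int i = besti; i >= 0; i = prev[i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());
  // drop overlaps on r or g between consecutive chained blocks (trim left edge)
  IntegerMatrix out((int)chain.size(), 3);
  int last_r = -1, last_g = -1, row = 0;
  for (int idx : chain) {
    Block b = blocks[idx];
    int trim = 0;
    if (b.r <= last_r) trim = last_r - b.r + 1;
    if (b.g + trim <= last_g) trim = last_g - b.g + 1;
    b.r += trim; b.g += trim; b.len -= trim;
    if (b.len < 1) continue;
    out(row, 0) = b.r; out(row, 1) = b.g; out(row, 2) = b.len;
    last_r = b.r + b.len - 1; last_g = b.g + b.len - 1;
    ++row;
  }
  if (row == 0) return IntegerMatrix(0, 3);
  return out(Range(0, row - 1), Range(0, 2));
}
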