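#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small utilities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return NA_INTEGER;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// Hamming distance of each string in `xs` against a single pattern `pat`
// (strings shorter than the pattern count as no-match: distance = length(pat)).
// [[Rcpp::export]]
IntegerVector cpp_hamming_vec(CharacterVector xs, std::string pat) {
  int n = xs.size(), m = pat.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (xs[i] == NA_STRING) { out[i] = m; continue; }
    std::string x = as<std::string>(xs[i]);
    if ((int)x.size() != m) { out[i] = m; continue; }
    int d = 0;
    for (int j = 0; j < m; ++j) if (x[j] != pat[j]) ++d;
    out[i] = d;
  }
  return out;
}

static inline bool iupac_match(char pat, char base) {
  switch (pat) {
    case 'A': return base == 'A';
    case 'C': return base == 'C';
    case 'G': return base == 'G';
    case 'T': return base == 'T';
    case 'R': return base == 'A' || base == 'G';
    case 'Y': return base == 'C' || base == 'T';
    case 'S': return base == 'C' || base == 'G';
    case 'W': return base == 'A' || base == 'T';
    case 'K': return base == 'G' || base == 'T';
    case 'M': return base == 'A' || base == 'C';
    case 'B': return base != 'A';
    case 'D': return base != 'C';
    case 'H': return base != 'G';
    case 'V': return base != 'T';
    case 'N': return true;
    default:  return pat == base;
  }
}

// Mismatches of an IUPAC pattern placed at 1-based `offsets[i]` inside seqs[i].
// Out-of-range placements score the full pattern length.
// [[Rcpp::export]]
IntegerVector cpp_iupac_mismatch(CharacterVector seqs, std::string pat,
                                 IntegerVector offsets) {
  int n = seqs.size(), m = pat.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int off = offsets[i] - 1;
    if (off < 0 || off + m > (int)s.size()) { out[i] = m; continue; }
    int d = 0;
    for (int j = 0; j < m; ++j) if (!iupac_match(pat[j], s[off + j])) ++d;
    out[i] = d;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read preparation
// ---------------------------------------------------------------------------

// Trimmomatic-style TRAILING + MINLEN on Phred+33 records.
// [[Rcpp::export]]
List cpp_quality_trim(CharacterVector seqs, CharacterVector quals,
                      int trailing_q, int min_len) {
  int n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size())
      stop("record %d: sequence and quality lengths differ", i + 1);
    size_t len = s.size();
    while (len > 0 && (q[len - 1] - 33) < trailing_q) --len;
    oseq[i] = s.substr(0, len);
    oqual[i] = q.substr(0, len);
    keep[i] = (int)len >= min_len;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual, _["keep"] = keep);
}

// Per-base substitution errors using R's RNG (so set.seed() governs output).
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        char cur = s[j];
        char sub = cur;
        while (sub == cur) sub = bases[(int)(unif_rand() * 4) & 3];
        s[j] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}

// FLASH-style ungapped overlap merge. `rev_rc` mates are already
// reverse-complemented (and their qualities reversed). Offset o is the start
// of the reverse mate relative to the forward mate; o < 0 is the "outie"
// configuration (insert shorter than the read), where only the overlapping
// region is reported. Best overlap maximises matches - mismatches, ties going
// to the longer overlap, then the smaller |o|.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd_seq, CharacterVector fwd_qual,
                     CharacterVector rev_rc_seq, CharacterVector rev_rc_qual,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd_seq.size();
  CharacterVector oseq(n), oqual(n);
  LogicalVector merged(n);
  IntegerVector ovlen(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(fwd_seq[i]);
    std::string qa = as<std::string>(fwd_qual[i]);
    std::string b = as<std::string>(rev_rc_seq[i]);
    std::string qb = as<std::string>(rev_rc_qual[i]);
    int La = a.size(), Lb = b.size();
    if (La == 0 || Lb == 0) {
      merged[i] = false; oseq[i] = ""; oqual[i] = ""; ovlen[i] = 0;
      continue;
    }
    int best_score = INT_MIN, best_ov = -1, best_o = 0;
    for (int o = -(Lb - min_overlap); o <= La - min_overlap; ++o) {
      int s = std::max(0, o), e = std::min(La, o + Lb);
      int ov = e - s;
      if (ov < min_overlap) continue;
      int mm = 0;
      for (int p = s; p < e; ++p) if (a[p] != b[p - o]) ++mm;
      if (mm > max_mismatch_frac * ov) continue;
      int score = ov - 2 * mm;
      if (score > best_score ||
          (score == best_score && (ov > best_ov ||
            (ov == best_ov && std::abs(o) < std::abs(best_o))))) {
        best_score = score; best_ov = ov; best_o = o;
      }
    }
    if (best_ov < 0) {
      merged[i] = false; oseq[i] = ""; oqual[i] = ""; ovlen[i] = 0;
      continue;
    }
    int o = best_o;
    int s = std::max(0, o), e = std::min(La, o + Lb);
    std::string ms, mq;
    if (o >= 0) { ms = a.substr(0, s); mq = qa.substr(0, s); }
    for (int p = s; p < e; ++p) {
      char ca = a[p], cb = b[p - o];
      char ka = qa[p], kb = qb[p - o];
      if (ca == cb) { ms += ca; mq += std::max(ka, kb); }
      else if (kb > ka) { ms += cb; mq += kb; }
      else { ms += ca; mq += ka; }
    }
    if (o >= 0 && o + Lb > La) {
      ms += b.substr(La - o); mq += qb.substr(La - o);
    }
    oseq[i] = ms; oqual[i] = mq; merged[i] = true; ovlen[i] = best_ov;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual,
                      _["merged"] = merged, _["overlap"] = ovlen);
}

// cutadapt-style end trimming: remove a read prefix matching a suffix of the
// 5' adapter, and a read suffix matching a prefix of the 3' adapter, allowing
// floor(error_rate * overlap) mismatches over >= min_overlap bases. The
// longest qualifying overlap at each end is removed.
// [[Rcpp::export]]
List cpp_trim_adapters(CharacterVector seqs, CharacterVector quals,
                       std::string a5, std::string a3,
                       double error_rate, int min_overlap) {
  int n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  IntegerVector cut5(n), cut3(n);
  int m5 = a5.size(), m3 = a3.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = quals[i] == NA_STRING ? std::string(s.size(), 'I')
                                          : as<std::string>(quals[i]);
    int L = s.size();
    int c5 = 0;
    for (int ov = std::min(m5, L); ov >= min_overlap; --ov) {
      int allowed = (int)(error_rate * ov);
      int mm = 0;
      for (int j = 0; j < ov; ++j)
        if (!iupac_match(a5[m5 - ov + j], s[j])) ++mm;
      if (mm <= allowed) { c5 = ov; break; }
    }
    s = s.substr(c5); q = q.substr(c5); L = s.size();
    int c3 = 0;
    for (int ov = std::min(m3, L); ov >= min_overlap; --ov) {
      int allowed = (int)(error_rate * ov);
      int mm = 0;
      for (int j = 0; j < ov; ++j)
        if (!iupac_match(a3[j], s[L - ov + j])) ++mm;
      if (mm <= allowed) { c3 = ov; break; }
    }
    oseq[i] = s.substr(0, L - c3);
    oqual[i] = q.substr(0, L - c3);
    cut5[i] = c5; cut3[i] = c3;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual,
                      _["cut5"] = cut5, _["cut3"] = cut3);
}

// ---------------------------------------------------------------------------
// Edit distance and single-linkage clustering
// ---------------------------------------------------------------------------

// Banded Levenshtein distance, capped at d+1. Only the diagonal band of
// width 2d+1 is evaluated; cells just outside the band are kept at INF so
// band-edge reads are well defined.
static int bounded_edit(const std::string &a, const std::string &b, int d) {
  int la = a.size(), lb = b.size();
  if (std::abs(la - lb) > d) return d + 1;
  const int INF = d + 1;
  std::vector<int> prev(lb + 2, INF), cur(lb + 2, INF);
  for (int j = 0; j <= std::min(lb, d); ++j) prev[j] = j;
  if (d + 1 <= lb) prev[d + 1] = INF;
  for (int i = 1; i <= la; ++i) {
    int lo = std::max(1, i - d), hi = std::min(lb, i + d);
    cur[lo - 1] = (lo == 1) ? std::min(i, INF) : INF;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int best = prev[j - 1] + (a[i - 1] != b[j - 1]);
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (best > INF) best = INF;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (hi + 1 <= lb) cur[hi + 1] = INF;
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], INF);
}

// [[Rcpp::export]]
int cpp_bounded_edit(std::string a, std::string b, int d) {
  return bounded_edit(a, b, d);
}

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

static IntegerVector components_to_labels(UnionFind &uf, int n) {
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = next; lab[i] = next; ++next; }
    else lab[i] = it->second;
  }
  return lab;
}

// Connected components of the <=1-edit graph. Candidate pairs come from a
// shared rolling hash over {sequence itself} U {all single-deletion
// variants} (two strings at edit distance <= 1 necessarily share one such
// key); every candidate is verified with the banded edit distance, so hash
// collisions cannot create false links.
// [[Rcpp::export]]
IntegerVector cpp_cluster_d1(CharacterVector seqs) {
  int n = seqs.size();
  UnionFind uf(n);
  const uint64_t B = 1315423911ULL;
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  // (hash, seq index) pairs
  std::vector<std::pair<uint64_t, int>> keys;
  size_t total = 0;
  for (int i = 0; i < n; ++i) total += ss[i].size() + 1;
  keys.reserve(total);
  size_t maxlen = 0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, ss[i].size());
  std::vector<uint64_t> powB(maxlen + 1);
  powB[0] = 1;
  for (size_t j = 1; j <= maxlen; ++j) powB[j] = powB[j - 1] * B;
  std::vector<uint64_t> pre, suf;
  for (int i = 0; i < n; ++i) {
    const std::string &s = ss[i];
    size_t L = s.size();
    pre.assign(L + 1, 0);
    suf.assign(L + 1, 0);
    for (size_t t = 0; t < L; ++t) pre[t + 1] = pre[t] * B + (uint8_t)s[t];
    for (size_t t = L; t-- > 0;) suf[t] = (uint8_t)s[t] * powB[L - 1 - t] + suf[t + 1];
    keys.emplace_back(pre[L], i);                       // the string itself
    for (size_t t = 0; t < L; ++t)                      // deletion variants
      keys.emplace_back(pre[t] * powB[L - 1 - t] + suf[t + 1], i);
  }
  std::sort(keys.begin(), keys.end());
  size_t g0 = 0;
  for (size_t idx = 1; idx <= keys.size(); ++idx) {
    if (idx == keys.size() || keys[idx].first != keys[g0].first) {
      // verify pairs within the bucket (skip indices already united)
      for (size_t p = g0; p < idx; ++p) {
        for (size_t q = p + 1; q < idx; ++q) {
          int i = keys[p].second, j = keys[q].second;
          if (i == j || uf.find(i) == uf.find(j)) continue;
          if (bounded_edit(ss[i], ss[j], 1) <= 1) uf.unite(i, j);
        }
      }
      g0 = idx;
    }
  }
  return components_to_labels(uf, n);
}

// All-pairs fallback for d >= 2 (used at small n and by the brute-force
// oracle in tests).
// [[Rcpp::export]]
IntegerVector cpp_cluster_bruteforce(CharacterVector seqs, int d) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  UnionFind uf(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (uf.find(i) != uf.find(j) && bounded_edit(ss[i], ss[j], d) <= d)
        uf.unite(i, j);
  return components_to_labels(uf, n);
}

// ---------------------------------------------------------------------------
// Seed-and-extend ungapped read mapping
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

// End-to-end ungapped best placement of each read against the reference set,
// trying both strands. Seeds: non-overlapping k-mers along the read (plus the
// final k-mer), looked up in a hash index of all reference k-mer positions.
// Reads whose best placement is tied across >= 2 distinct locations are
// flagged non-unique; reads whose best mismatch fraction exceeds
// max_mismatch_frac are unaligned (ref = NA).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int k, double max_mismatch_frac) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int r = 0; r < nref; ++r) R[r] = as<std::string>(refs[r]);
  // index
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  index.reserve(1 << 20);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::string &s = R[r];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bit(s[p]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        index[key].push_back(((uint64_t)r << 32) | (uint64_t)(p - k + 1));
    }
  }
  int n = reads.size();
  IntegerVector ref_out(n), start_out(n), mm_out(n), nbest_out(n), len_out(n);
  CharacterVector strand_out(n);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = fwd.size();
    len_out[i] = L;
    int best_mm = INT_MAX, n_best = 0;
    int best_ref = -1, best_start = -1;
    char best_strand = '+';
    if (L >= k) {
      for (int strand = 0; strand < 2; ++strand) {
        std::string q = strand == 0 ? fwd : revcomp(fwd);
        std::unordered_set<uint64_t> seen;
        std::vector<int> offs;
        for (int o = 0; o + k <= L; o += k) offs.push_back(o);
        if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
        for (int off : offs) {
          uint64_t key = 0;
          bool ok = true;
          for (int j = 0; j < k; ++j) {
            int b = base2bit(q[off + j]);
            if (b < 0) { ok = false; break; }
            key = ((key << 2) | (uint64_t)b) & mask;
          }
          if (!ok) continue;
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (uint64_t hit : it->second) {
            int r = (int)(hit >> 32);
            int64_t start = (int64_t)(uint32_t)hit - off;
            if (start < 0 || start + L > (int64_t)R[r].size()) continue;
            uint64_t pk = ((uint64_t)r << 33) | ((uint64_t)start << 1) | strand;
            if (!seen.insert(pk).second) continue;
            const std::string &ref = R[r];
            int mm = 0;
            for (int j = 0; j < L && mm <= best_mm; ++j)
              if (q[j] != ref[start + j]) ++mm;
            if (mm < best_mm) {
              best_mm = mm; n_best = 1;
              best_ref = r; best_start = (int)start;
              best_strand = strand == 0 ? '+' : '-';
            } else if (mm == best_mm) {
              ++n_best;
            }
          }
        }
      }
    }
    if (best_ref < 0 || best_mm > max_mismatch_frac * L) {
      ref_out[i] = NA_INTEGER; start_out[i] = NA_INTEGER;
      mm_out[i] = NA_INTEGER; nbest_out[i] = 0; strand_out[i] = NA_STRING;
    } else {
      ref_out[i] = best_ref + 1;
      start_out[i] = best_start;
      mm_out[i] = best_mm;
      nbest_out[i] = n_best;
      strand_out[i] = std::string(1, best_strand);
    }
  }
  return DataFrame::create(_["ref"] = ref_out, _["start"] = start_out,
                           _["mismatches"] = mm_out, _["n_best"] = nbest_out,
                           _["read_length"] = len_out,
                           _["strand"] = strand_out,
                           _["stringsAsFactors"] = false);
}
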