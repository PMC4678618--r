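// Sequence kernels: translation, pairwise alignment, seed-and-extend local
// searches (nucleotide and translated), inverted-repeat scanning, consensus.
// All coordinates in this file are 0-based half-open; R wrappers convert.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// ---------------------------------------------------------------------------
// Translation (standard code). Stop -> '*', any codon containing N -> 'X'.
// ---------------------------------------------------------------------------
static const char AA_TABLE[65] =
  // index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline char translate_codon(char a, char b, char c) {
  int i = base_code(a), j = base_code(b), k = base_code(c);
  if (i < 0 || j < 0 || k < 0) return 'X';
  return AA_TABLE[16 * i + 4 * j + k];
}

static std::string translate_frame(const std::string& s, int offset) {
  std::string out;
  size_t n = s.size();
  if (n < (size_t)(offset + 3)) return out;
  out.reserve((n - offset) / 3);
  for (size_t i = offset; i + 2 < n; i += 3)
    out.push_back(translate_codon(s[i], s[i + 1], s[i + 2]));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_translate_six_frames(std::string s) {
  std::string rc = revcomp_str(s);
  CharacterVector out(6);
  out[0] = translate_frame(s, 0);
  out[1] = translate_frame(s, 1);
  out[2] = translate_frame(s, 2);
  out[3] = translate_frame(rc, 0);
  out[4] = translate_frame(rc, 1);
  out[5] = translate_frame(rc, 2);
  out.names() = CharacterVector::create("1", "2", "3", "-1", "-2", "-3");
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise alignment with linear gap cost. type: 0 = global (NW), 1 = local
// (SW). Traceback preference: diagonal, then up (gap in b), then left.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, double match = 1.0,
               double mismatch = -1.0, double gap = -2.0,
               int type = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up,3 left
  const bool local = (type == 1);

  double best = local ? 0.0 : R_NegInf;
  int bi = 0, bj = 0;
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    prev[j] = local ? 0.0 : j * gap;
    if (!local) tb[j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = local ? 0.0 : i * gap;
    if (!local) tb[(size_t)i * (m + 1)] = 2;
    const char ai = a[i - 1];
    const int ac = base_code(ai);
    for (int j = 1; j <= m; ++j) {
      const int bc = base_code(b[j - 1]);
      const bool is_match = (ac >= 0 && ac == bc) ||
        (ac < 0 && bc < 0 && ai == b[j - 1] && ai != 'N' && ai != 'n');
      double sd = prev[j - 1] + (is_match ? match : mismatch);
      double su = prev[j] + gap;
      double sl = cur[j - 1] + gap;
      double v = sd; unsigned char t = 1;
      if (su > v) { v = su; t = 2; }
      if (sl > v) { v = sl; t = 3; }
      if (local && v <= 0.0) { v = 0.0; t = 0; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = t;
      if (local && v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (!local) { best = prev[m]; bi = n; bj = m; }

  // traceback
  std::string aa, bb;
  int i = bi, j = bj;
  int matches = 0, mism = 0, gaps = 0;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (local && t == 0) break;
    if (!local && t == 0 && i == 0 && j == 0) break;
    if (t == 1) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      int ac = base_code(a[i - 1]), bc = base_code(b[j - 1]);
      bool is_match = (ac >= 0 && ac == bc);
      if (is_match) ++matches; else ++mism;
      --i; --j;
    } else if (t == 2) {
      aa.push_back(a[i - 1]); bb.push_back('-'); ++gaps; --i;
    } else if (t == 3) {
      aa.push_back('-'); bb.push_back(b[j - 1]); ++gaps; --j;
    } else break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int cols = matches + mism + gaps;
  return List::create(
    _["score"] = best,
    _["aligned_a"] = aa, _["aligned_b"] = bb,
    _["a_start"] = i, _["a_end"] = bi,
    _["b_start"] = j, _["b_end"] = bj,
    _["matches"] = matches, _["mismatches"] = mism,
    _["gap_cols"] = gaps, _["columns"] = cols);
}

// ---------------------------------------------------------------------------
// Nucleotide seed-and-extend ungapped local search (BLASTN-like stand-in).
// ---------------------------------------------------------------------------
struct NtHit {
  int qs, qe, ss, se, matches;
  double score;
  char strand;
};

static void search_nt_one(const std::string& q, const std::string& s,
                          int word, double match, double mismatch,
                          double xdrop, double min_score, char strand,
                          int orig_qlen, std::vector<NtHit>& out) {
  const int qn = (int)q.size(), sn = (int)s.size();
  if (qn < word || sn < word) return;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  // index query words
  {
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < qn; ++i) {
      int c = base_code(q[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= word) idx[key].push_back(i - word + 1);
    }
  }
  std::unordered_map<int, int> covered; // diagonal -> subject end covered
  uint64_t key = 0; int run = 0;
  for (int j = 0; j < sn; ++j) {
    int c = base_code(s[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < word) continue;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    int sp = j - word + 1;
    for (int qp : it->second) {
      int diag = sp - qp;
      auto cov = covered.find(diag);
      if (cov != covered.end() && sp < cov->second) continue;
      // extend right from seed end
      double sc = word * match, bestsc = sc;
      int qi = qp + word, sj = sp + word;
      int best_r_q = qi;
      while (qi < qn && sj < sn) {
        int qc = base_code(q[qi]), scd = base_code(s[sj]);
        sc += (qc >= 0 && qc == scd) ? match : mismatch;
        ++qi; ++sj;
        if (sc > bestsc) { bestsc = sc; best_r_q = qi; }
        else if (bestsc - sc > xdrop) break;
      }
      // extend left from seed start
      double sc2 = bestsc, bestsc2 = bestsc;
      int qi2 = qp - 1, sj2 = sp - 1;
      int best_l_q = qp;
      while (qi2 >= 0 && sj2 >= 0) {
        int qc = base_code(q[qi2]), scd = base_code(s[sj2]);
        sc2 += (qc >= 0 && qc == scd) ? match : mismatch;
        if (sc2 > bestsc2) { bestsc2 = sc2; best_l_q = qi2; }
        else if (bestsc2 - sc2 > xdrop) break;
        --qi2; --sj2;
      }
      int hqs = best_l_q, hqe = best_r_q;
      int hss = hqs + diag, hse = hqe + diag;
      covered[diag] = hse;
      if (bestsc2 < min_score) continue;
      int matches = 0;
      for (int t = 0; t < hqe - hqs; ++t) {
        int qc = base_code(q[hqs + t]), scd = base_code(s[hss + t]);
        if (qc >= 0 && qc == scd) ++matches;
      }
      NtHit h;
      if (strand == '+') { h.qs = hqs; h.qe = hqe; }
      else { h.qs = orig_qlen - hqe; h.qe = orig_qlen - hqs; }
      h.ss = hss; h.se = hse; h.matches = matches;
      h.score = bestsc2; h.strand = strand;
      out.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_search_nt(std::string query, std::string subject, int min_word,
                        bool both_strands = true, double match = 1.0,
                        double mismatch = -2.0, double xdrop = 12.0,
                        double min_score = 20.0) {
  std::vector<NtHit> hits;
  search_nt_one(query, subject, min_word, match, mismatch, xdrop, min_score,
                '+', (int)query.size(), hits);
  if (both_strands) {
    std::string qrc = revcomp_str(query);
    search_nt_one(qrc, subject, min_word, match, mismatch, xdrop, min_score,
                  '-', (int)query.size(), hits);
  }
  std::sort(hits.begin(), hits.end(), [](const NtHit& a, const NtHit& b) {
    if (a.ss != b.ss) return a.ss < b.ss;
    if (a.se != b.se) return a.se < b.se;
    return a.strand < b.strand;
  });
  // drop exact duplicates (same interval found from several seeds)
  std::vector<NtHit> uniq;
  for (auto& h : hits) {
    if (!uniq.empty()) {
      NtHit& p = uniq.back();
      if (p.ss == h.ss && p.se == h.se && p.qs == h.qs && p.strand == h.strand)
        continue;
    }
    uniq.push_back(h);
  }
  int n = (int)uniq.size();
  IntegerVector qs(n), qe(n), ss(n), se(n);
  NumericVector score(n), ident(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = uniq[i].qs; qe[i] = uniq[i].qe;
    ss[i] = uniq[i].ss; se[i] = uniq[i].se;
    score[i] = uniq[i].score;
    ident[i] = (double)uniq[i].matches / (double)(uniq[i].qe - uniq[i].qs);
    strand[i] = std::string(1, uniq[i].strand);
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = strand, _["score"] = score, _["identity"] = ident,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// BLOSUM62 for the translated search.
// ---------------------------------------------------------------------------
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int B62[24][24] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static int aa_index_tab[128];
static bool aa_tab_init = false;
static void init_aa_tab() {
  if (aa_tab_init) return;
  for (int i = 0; i < 128; ++i) aa_index_tab[i] = -1;
  for (int i = 0; AA_ORDER[i]; ++i) aa_index_tab[(int)AA_ORDER[i]] = i;
  aa_tab_init = true;
}
static inline int aa_index(char c) {
  if (c >= 0 && c < 127) {
    int v = aa_index_tab[(int)c];
    if (v >= 0) return v;
  }
  return 22; // X
}
static inline int b62_score(char a, char b) { return B62[aa_index(a)][aa_index(b)]; }

struct AaHit {
  int query; int qs, qe, ss, se; int frame; int matches; double score; char strand;
};

// scan one translated frame against the multi-query 4-mer index
static void search_frame(const std::string& prot,
                         const std::vector<std::string>& queries,
                         const std::unordered_map<uint32_t, std::vector<std::pair<int,int>>>& idx,
                         int word, double xdrop, double min_score,
                         int frame, int nt_len, std::vector<AaHit>& out) {
  const int pn = (int)prot.size();
  if (pn < word) return;
  std::unordered_map<int64_t, int> covered; // (query, diag) -> prot end
  uint32_t key = 0; int run = 0;
  const uint32_t mask = (1u << (5 * word)) - 1u;
  for (int j = 0; j < pn; ++j) {
    int ci = aa_index(prot[j]);
    if (ci >= 22) { run = 0; key = 0; continue; } // X or *
    key = ((key << 5) | (uint32_t)ci) & mask;
    if (++run < word) continue;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    int sp = j - word + 1;
    for (auto& qq : it->second) {
      int qidx = qq.first, qp = qq.second;
      const std::string& q = queries[qidx];
      const int qn = (int)q.size();
      int diag = sp - qp;
      int64_t ck = ((int64_t)qidx << 32) ^ (int64_t)(diag + 1000000);
      auto cov = covered.find(ck);
      if (cov != covered.end() && sp < cov->second) continue;
      double sc = 0;
      for (int t = 0; t < word; ++t) sc += b62_score(q[qp + t], prot[sp + t]);
      double bestsc = sc;
      int qi = qp + word, sj = sp + word, best_r = qi;
      while (qi < qn && sj < pn && prot[sj] != '*') {
        sc += b62_score(q[qi], prot[sj]);
        ++qi; ++sj;
        if (sc > bestsc) { bestsc = sc; best_r = qi; }
        else if (bestsc - sc > xdrop) break;
      }
      double sc2 = bestsc, bestsc2 = bestsc;
      int qi2 = qp - 1, sj2 = sp - 1, best_l = qp;
      while (qi2 >= 0 && sj2 >= 0 && prot[sj2] != '*') {
        sc2 += b62_score(q[qi2], prot[sj2]);
        if (sc2 > bestsc2) { bestsc2 = sc2; best_l = qi2; }
        else if (bestsc2 - sc2 > xdrop) break;
        --qi2; --sj2;
      }
      int hqs = best_l, hqe = best_r;
      int pss = hqs + diag, pse = hqe + diag;
      covered[ck] = pse;
      if (bestsc2 < min_score) continue;
      int matches = 0;
      for (int t = 0; t < hqe - hqs; ++t)
        if (q[hqs + t] == prot[pss + t]) ++matches;
      // protein frame coords -> nucleotide plus-strand coords
      int off = std::abs(frame) - 1;
      int nt_s = off + 3 * pss, nt_e = off + 3 * pse;
      AaHit h;
      h.query = qidx; h.qs = hqs; h.qe = hqe; h.frame = frame;
      h.matches = matches; h.score = bestsc2;
      if (frame > 0) { h.ss = nt_s; h.se = nt_e; h.strand = '+'; }
      else { h.ss = nt_len - nt_e; h.se = nt_len - nt_s; h.strand = '-'; }
      out.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_search_translated(CharacterVector queries, std::string subject,
                                int word = 4, double xdrop = 18.0,
                                double min_score = 60.0) {
  init_aa_tab();
  int nq = queries.size();
  std::vector<std::string> qs(nq);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> idx;
  for (int i = 0; i < nq; ++i) {
    const std::string& q = qs[i];
    uint32_t key = 0; int run = 0;
    const uint32_t mask = (1u << (5 * word)) - 1u;
    for (int p = 0; p < (int)q.size(); ++p) {
      int ci = aa_index(q[p]);
      if (ci >= 22) { run = 0; key = 0; continue; }
      key = ((key << 5) | (uint32_t)ci) & mask;
      if (++run >= word) idx[key].push_back({i, p - word + 1});
    }
  }
  std::vector<AaHit> hits;
  int nt_len = (int)subject.size();
  std::string rc = revcomp_str(subject);
  for (int f = 1; f <= 3; ++f) {
    std::string prot = translate_frame(subject, f - 1);
    search_frame(prot, qs, idx, word, xdrop, min_score, f, nt_len, hits);
  }
  for (int f = 1; f <= 3; ++f) {
    std::string prot = translate_frame(rc, f - 1);
    search_frame(prot, qs, idx, word, xdrop, min_score, -f, nt_len, hits);
  }
  std::sort(hits.begin(), hits.end(), [](const AaHit& a, const AaHit& b) {
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.se < b.se;
  });
  int n = (int)hits.size();
  IntegerVector qidx(n), q_start(n), q_end(n), s_start(n), s_end(n), frame(n);
  NumericVector score(n), ident(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qidx[i] = hits[i].query + 1;
    q_start[i] = hits[i].qs; q_end[i] = hits[i].qe;
    s_start[i] = hits[i].ss; s_end[i] = hits[i].se;
    frame[i] = hits[i].frame; score[i] = hits[i].score;
    ident[i] = (double)hits[i].matches / (double)(hits[i].qe - hits[i].qs);
    strand[i] = std::string(1, hits[i].strand);
  }
  return DataFrame::create(
    _["query_idx"] = qidx, _["q_start"] = q_start, _["q_end"] = q_end,
    _["s_start"] = s_start, _["s_end"] = s_end, _["strand"] = strand,
    _["frame"] = frame, _["score"] = score, _["identity"] = ident,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Inverted-repeat scan: maximal exact inverted matches of >= min_word whose
// arms do not overlap and whose internal span is <= max_span.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_find_inverted_repeats(std::string s, int min_word = 11,
                                    int max_span = 750) {
  const int n = (int)s.size();
  std::unordered_map<uint64_t, std::vector<int>> idx;
  const uint64_t mask = (min_word >= 32) ? ~0ULL : ((1ULL << (2 * min_word)) - 1);
  {
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= min_word) idx[key].push_back(i - min_word + 1);
    }
  }
  auto pairs_ok = [&](int t, int u) {
    if (t < 0 || u >= n) return false;
    int a = base_code(s[t]), b = base_code(s[u]);
    return a >= 0 && b >= 0 && a == (3 - b);
  };
  std::unordered_set<int64_t> seen;
  std::vector<int> L1, L2, R1, R2, AL, SP;
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (run + 1 < min_word) { ++run; continue; }
    ++run;
    int start = i - min_word + 1;
    // reverse complement of this word
    uint64_t rckey = 0, tmp = key;
    for (int t = 0; t < min_word; ++t) {
      rckey = (rckey << 2) | (3 - (tmp & 3ULL));
      tmp >>= 2;
    }
    auto it = idx.find(rckey);
    if (it == idx.end()) continue;
    for (int j : it->second) {
      if (j < start + min_word) continue;              // arms must not overlap
      if (j - (start + min_word) > max_span) continue; // seed span bound
      int64_t S = (int64_t)start + j + min_word - 1;   // anti-diagonal
      // maximal run on this anti-diagonal containing [start, start+min_word)
      int lo = start;
      while (pairs_ok(lo - 1, (int)(S - (lo - 1)))) --lo;
      int hi = start + min_word - 1;
      while (hi + 1 < (int)(S - (hi + 1)) && pairs_ok(hi + 1, (int)(S - (hi + 1)))) ++hi;
      int64_t kk = S * (int64_t)(n + 1) + lo;
      if (seen.count(kk)) continue;
      seen.insert(kk);
      int arm = hi - lo + 1;
      int ls = lo, le = hi + 1;
      int rs = (int)(S - hi), re = (int)(S - lo) + 1;
      int span = rs - le;
      if (arm < min_word || span < 0 || span > max_span) continue;
      L1.push_back(ls); L2.push_back(le);
      R1.push_back(rs); R2.push_back(re);
      AL.push_back(arm); SP.push_back(span);
    }
  }
  return DataFrame::create(
    _["left_start"] = L1, _["left_end"] = L2,
    _["right_start"] = R1, _["right_end"] = R2,
    _["arm_len"] = AL, _["span"] = SP,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Majority-rule consensus over equal-length gapped rows. Ties base vs '-'
// resolved toward the base ("keep the longest elements"); ties among bases by
// alphabet order A<C<G<T; plurality-'-' columns dropped.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
std::string cpp_consensus(CharacterVector rows) {
  int n = rows.size();
  if (n == 0) return "";
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(rows[i]);
  size_t L = v[0].size();
  for (int i = 1; i < n; ++i)
    if (v[i].size() != L) stop("consensus rows must have equal length");
  std::string out;
  out.reserve(L);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (size_t j = 0; j < L; ++j) {
    int cnt[4] = {0, 0, 0, 0};
    int gapc = 0;
    for (int i = 0; i < n; ++i) {
      char c = v[i][j];
      if (c == '-') { ++gapc; continue; }
      int b = base_code(c);
      if (b >= 0) ++cnt[b];
      // N and other symbols cast no vote
    }
    int bi = 0;
    for (int b = 1; b < 4; ++b) if (cnt[b] > cnt[bi]) bi = b;
    if (cnt[bi] == 0 || gapc > cnt[bi]) continue; // gap plurality: drop column
    out.push_back(bases[bi]);
  }
  return out;
}

// As cpp_consensus, but reports which input columns were kept (0-based), so
// positions on the consensus can be mapped back to row coordinates.
// [[Rcpp::export]]
List cpp_consensus_cols(CharacterVector rows) {
  int n = rows.size();
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(rows[i]);
  size_t L = n ? v[0].size() : 0;
  for (int i = 1; i < n; ++i)
    if (v[i].size() != L) stop("consensus rows must have equal length");
  std::string out;
  std::vector<int> kept;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (size_t j = 0; j < L; ++j) {
    int cnt[4] = {0, 0, 0, 0};
    int gapc = 0;
    for (int i = 0; i < n; ++i) {
      char c = v[i][j];
      if (c == '-') { ++gapc; continue; }
      int b = base_code(c);
      if (b >= 0) ++cnt[b];
    }
    int bi = 0;
    for (int b = 1; b < 4; ++b) if (cnt[b] > cnt[bi]) bi = b;
    if (cnt[bi] == 0 || gapc > cnt[bi]) continue;
    out.push_back(bases[bi]);
    kept.push_back((int)j);
  }
  return List::create(_["consensus"] = out, _["kept"] = kept);
}

// ---------------------------------------------------------------------------
// Star projection: align each member globally to a center sequence and report
// the member residues mapped onto center coordinates (insertions relative to
// the center are discarded). Rows come back center-length, gap-padded.
// ---------------------------------------------------------------------------
// Returns gap-padded member rows in center coordinates plus, per member, the
// 1-based member-string index of the residue at (or last before) each center
// column -- the anchor used to read true member coordinates off the star
// alignment.
// [[Rcpp::export]]
List cpp_star_project(std::string center, CharacterVector members,
                      double match = 1.0, double mismatch = -1.0,
                      double gap = -2.0) {
  int n = members.size();
  int L = (int)center.size();
  CharacterVector rows(n);
  IntegerMatrix idx(n, L);
  for (int i = 0; i < n; ++i) {
    std::string m = as<std::string>(members[i]);
    List al = cpp_align(center, m, match, mismatch, gap, 0);
    std::string ac = as<std::string>(al["aligned_a"]);
    std::string am = as<std::string>(al["aligned_b"]);
    std::string row;
    row.reserve(L);
    int mcount = 0, cidx = 0;
    for (size_t k = 0; k < ac.size(); ++k) {
      if (ac[k] == '-') { ++mcount; continue; } // insertion in member: drop
      if (am[k] == '-') {
        row.push_back('-');
        idx(i, cidx) = mcount;
      } else {
        ++mcount;
        row.push_back(am[k]);
        idx(i, cidx) = mcount;
      }
      ++cidx;
    }
    rows[i] = row;
  }
  return List::create(_["rows"] = rows, _["idx"] = idx);
}

// pairwise mismatch counts over positions where both rows have a base
// [[Rcpp::export]]
List cpp_hamming_pairs(CharacterVector rows) {
  int n = rows.size();
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(rows[i]);
  NumericMatrix diff(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      size_t L = std::min(v[i].size(), v[j].size());
      int d = 0, c = 0;
      for (size_t k = 0; k < L; ++k) {
        int a = base_code(v[i][k]), b = base_code(v[j][k]);
        if (a < 0 || b < 0) continue;
        ++c;
        if (a != b) ++d;
      }
      diff(i, j) = diff(j, i) = d;
      comp(i, j) = comp(j, i) = c;
    }
  }
  return List::create(_["diff"] = diff, _["comparable"] = comp);
}
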