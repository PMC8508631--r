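#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend ungapped local search. Sequences are compared as
// upper-case nucleotide strings; any character outside {A,C,G,T} never
// matches and never seeds (so N and IUPAC ambiguity codes break seeds).

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct RawHit {
  int qidx, sidx;
  int qstart, qend, sstart, send; // 0-based half-open, in searched orientation
  int score, matches, length;
};

// Extend a seed [qpos, qpos+k) x [spos, spos+k) ungapped in both directions
// with an x-drop criterion; returns the max-score extent.
static RawHit extend_seed(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                          int qpos, int spos, int k,
                          int match, int mismatch, int xdrop) {
  const int qlen = (int)q.size(), slen = (int)s.size();
  int score = k * match, best = score, mcount = k;
  int bqe = qpos + k, bse = spos + k, best_m_r = 0, m_r = 0;
  // rightward
  int i = qpos + k, j = spos + k, cur = score;
  while (i < qlen && j < slen) {
    bool eq = (q[i] >= 0) && (q[i] == s[j]);
    cur += eq ? match : mismatch;
    m_r += eq ? 1 : 0;
    ++i; ++j;
    if (cur > best) { best = cur; bqe = i; bse = j; best_m_r = m_r; }
    if (best - cur > xdrop) break;
  }
  // leftward
  int bqs = qpos, bss = spos, best_m_l = 0, m_l = 0;
  cur = best;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    bool eq = (q[i] >= 0) && (q[i] == s[j]);
    cur += eq ? match : mismatch;
    m_l += eq ? 1 : 0;
    if (cur > best) { best = cur; bqs = i; bss = j; best_m_l = m_l; }
    if (best - cur > xdrop) break;
    --i; --j;
  }
  RawHit h;
  h.qstart = bqs; h.qend = bqe; h.sstart = bss; h.send = bse;
  h.score = best; h.matches = mcount + best_m_l + best_m_r;
  h.length = bqe - bqs;
  return h;
}

// [[Rcpp::export]]
DataFrame cpp_seed_search(CharacterVector qseqs, CharacterVector sseqs,
                          int k, int match, int mismatch, int xdrop,
                          int min_raw_score) {
  std::vector<RawHit> hits;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int si = 0; si < sseqs.size(); ++si) {
    const char* sc = CHAR(STRING_ELT(sseqs, si));
    int slen = (int)LENGTH(STRING_ELT(sseqs, si));
    std::vector<int8_t> s(slen);
    for (int i = 0; i < slen; ++i) s[i] = (int8_t)enc_base(sc[i]);

    // k-mer index of the subject
    std::unordered_map<uint64_t, std::vector<int32_t> > index;
    index.reserve(slen > k ? (size_t)(slen - k + 1) : 1);
    {
      uint64_t kmer = 0; int run = 0;
      for (int i = 0; i < slen; ++i) {
        if (s[i] < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)s[i]) & mask;
        if (++run >= k) index[kmer].push_back(i - k + 1);
      }
    }
    if (index.empty()) continue;

    for (int qi = 0; qi < qseqs.size(); ++qi) {
      const char* qc = CHAR(STRING_ELT(qseqs, qi));
      int qlen = (int)LENGTH(STRING_ELT(qseqs, qi));
      if (qlen < k) continue;
      std::vector<int8_t> q(qlen);
      for (int i = 0; i < qlen; ++i) q[i] = (int8_t)enc_base(qc[i]);

      // per-diagonal coverage to avoid re-extending inside a found HSP
      std::unordered_map<int64_t, int32_t> covered;
      uint64_t kmer = 0; int run = 0;
      for (int i = 0; i < qlen; ++i) {
        if (q[i] < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)q[i]) & mask;
        if (++run < k) continue;
        int qpos = i - k + 1;
        auto it = index.find(kmer);
        if (it == index.end()) continue;
        for (int32_t spos : it->second) {
          int64_t diag = (int64_t)spos - (int64_t)qpos;
          auto cv = covered.find(diag);
          if (cv != covered.end() && qpos < cv->second) continue;
          RawHit h = extend_seed(q, s, qpos, spos, k, match, mismatch, xdrop);
          covered[diag] = h.qend;
          if (h.score >= min_raw_score) {
            h.qidx = qi; h.sidx = si;
            hits.push_back(h);
          }
        }
      }
    }
  }

  const int n = (int)hits.size();
  IntegerVector qidx(n), sidx(n), qstart(n), qend(n), sstart(n), send(n),
                score(n), matches(n), length(n);
  for (int i = 0; i < n; ++i) {
    qidx[i] = hits[i].qidx + 1; sidx[i] = hits[i].sidx + 1;
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    sstart[i] = hits[i].sstart; send[i] = hits[i].send;
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    length[i] = hits[i].length;
  }
  return DataFrame::create(_["qidx"] = qidx, _["sidx"] = sidx,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["sstart"] = sstart, _["send"] = send,
                           _["score"] = score, _["matches"] = matches,
                           _["length"] = length);
}

// Sliding-window position-specific score: aa coded 0..19, -1 for anything
// else (unknown residues score the background, i.e. 0 log-odds).
// [[Rcpp::export]]
NumericVector cpp_pssm_scan(IntegerVector aa, NumericMatrix pssm) {
  int W = pssm.ncol(), n = aa.size();
  if (n < W) return NumericVector(0);
  NumericVector out(n - W + 1);
  for (int i = 0; i + W <= n; ++i) {
    double sc = 0.0;
    for (int j = 0; j < W; ++j) {
      int a = aa[i + j];
      if (a >= 0) sc += pssm(a, j);
    }
    out[i] = sc;
  }
  return out;
}
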