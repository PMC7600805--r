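// Seed-and-extend local alignment of a mitochondrial query against nuclear
// scaffolds. Exact k-mer seeds, ungapped x-drop extension to delimit a
// window, then full Smith-Waterman (Gotoh affine) with traceback inside the
// window, so every reported hit carries the optimal local score for its
// region. Gap of length L costs gap_open + L * gap_ext.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int basecode(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return 4;   // N and anything else: scores as mismatch, breaks seeds
  }
}

static std::vector<int8_t> encode(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) basecode(s[i]);
  return v;
}

struct AlnResult {
  int score, s_begin, s_end, q_begin, q_end, matches, alnlen;
  bool ok;
};

// Full local alignment (Gotoh) of subject[s0,s1) x query[q0,q1) with packed
// one-byte-per-cell traceback. Coordinates in the result are absolute.
static AlnResult sw_region(const std::vector<int8_t> &S, const std::vector<int8_t> &Q,
                           int s0, int s1, int q0, int q1,
                           int match, int mismatch, int gap_open, int gap_ext) {
  const int ns = s1 - s0, nq = q1 - q0;
  AlnResult res; res.ok = false; res.score = 0;
  if (ns <= 0 || nq <= 0) return res;
  const int NEG = -(1 << 28);
  const int go = gap_open + gap_ext;      // cost of a length-1 gap
  std::vector<int> prevM(nq + 1, NEG), prevX(nq + 1, NEG), prevY(nq + 1, NEG);
  std::vector<int> curM(nq + 1, NEG), curX(nq + 1, NEG), curY(nq + 1, NEG);
  // trace byte: bits 0-1 = M predecessor (0 start, 1 M, 2 X, 3 Y);
  // bit 2 = X extends X; bit 3 = Y extends Y
  std::vector<uint8_t> tb((size_t) ns * nq, 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= ns; ++i) {
    curM[0] = NEG; curX[0] = NEG; curY[0] = NEG;
    const int8_t a = S[s0 + i - 1];
    uint8_t *trow = &tb[(size_t)(i - 1) * nq];
    for (int j = 1; j <= nq; ++j) {
      const int8_t b = Q[q0 + j - 1];
      const int sub = (a == b && a < 4) ? match : mismatch;
      // M state
      int diag = 0; uint8_t mdir = 0;
      if (prevM[j - 1] > diag) { diag = prevM[j - 1]; mdir = 1; }
      if (prevX[j - 1] > diag) { diag = prevX[j - 1]; mdir = 2; }
      if (prevY[j - 1] > diag) { diag = prevY[j - 1]; mdir = 3; }
      const int m = diag + sub;
      // X: gap consuming subject (vertical)
      int x = prevM[j] - go; uint8_t xdir = 0;
      if (prevX[j] - gap_ext > x) { x = prevX[j] - gap_ext; xdir = 4; }
      // Y: gap consuming query (horizontal)
      int y = curM[j - 1] - go; uint8_t ydir = 0;
      if (curY[j - 1] - gap_ext > y) { y = curY[j - 1] - gap_ext; ydir = 8; }
      curM[j] = m; curX[j] = x; curY[j] = y;
      trow[j - 1] = (uint8_t)(mdir | xdir | ydir);
      if (m > best) { best = m; bi = i; bj = j; }
    }
    std::swap(prevM, curM); std::swap(prevX, curX); std::swap(prevY, curY);
  }
  if (best <= 0) return res;
  // traceback from (bi, bj), state M
  int i = bi, j = bj, state = 1, matches = 0, alnlen = 0;
  int si = bi, sj = bj;
  while (state != 0) {
    const uint8_t t = tb[(size_t)(i - 1) * nq + (j - 1)];
    if (state == 1) {            // M: consume both
      const int8_t a = S[s0 + i - 1], b = Q[q0 + j - 1];
      if (a == b && a < 4) ++matches;
      ++alnlen; si = i; sj = j;
      state = t & 3; --i; --j;
      if (state == 0) break;
    } else if (state == 2) {     // X: consume subject
      ++alnlen;
      state = (t & 4) ? 2 : 1; --i;
    } else {                     // Y: consume query
      ++alnlen;
      state = (t & 8) ? 3 : 1; --j;
    }
  }
  res.ok = true;
  res.score = best;
  res.s_begin = s0 + si - 1; res.s_end = s0 + bi;
  res.q_begin = q0 + sj - 1; res.q_end = q0 + bj;
  res.matches = matches; res.alnlen = alnlen;
  return res;
}

// Ungapped x-drop extension; returns extents [sl, sr) x [ql, qr) around the
// seed at subject pos i, query pos qpos (seed length k) and the best total
// ungapped score. Never extends across a run of >= 10 Ns.
static int xdrop_extend(const std::vector<int8_t> &S, const std::vector<int8_t> &Q,
                        int i, int qpos, int k, int match, int mismatch,
                        int xdrop, int &sl, int &sr, int &ql, int &qr) {
  const int ns = (int) S.size(), nq = (int) Q.size();
  int score = k * match, bestsc = score;
  int s = i + k, q = qpos + k, bs = s, bq = q, nrun = 0;
  while (s < ns && q < nq) {
    const bool isn = (S[s] >= 4 || Q[q] >= 4);
    nrun = isn ? nrun + 1 : 0;
    if (nrun >= 10) break;
    score += (S[s] == Q[q] && S[s] < 4) ? match : mismatch;
    ++s; ++q;
    if (score > bestsc) { bestsc = score; bs = s; bq = q; }
    if (score <= bestsc - xdrop) break;
  }
  sr = bs; qr = bq;
  score = bestsc; int curs = score;
  int s2 = i - 1, q2 = qpos - 1, bs2 = i, bq2 = qpos;
  curs = 0; int best2 = 0; nrun = 0;
  while (s2 >= 0 && q2 >= 0) {
    const bool isn = (S[s2] >= 4 || Q[q2] >= 4);
    nrun = isn ? nrun + 1 : 0;
    if (nrun >= 10) break;
    curs += (S[s2] == Q[q2] && S[s2] < 4) ? match : mismatch;
    if (curs > best2) { best2 = curs; bs2 = s2; bq2 = q2; }
    if (curs <= best2 - xdrop) break;
    --s2; --q2;
  }
  sl = bs2; ql = bq2;
  return bestsc + best2;
}

// [[Rcpp::export(name = ".scan_pair_cpp", rng = false)]]
DataFrame scan_pair_cpp(std::string subject, std::string query,
                        int k, int match, int mismatch,
                        int gap_open, int gap_ext, int xdrop,
                        int pad, int min_score, int max_window) {
  const std::vector<int8_t> S = encode(subject), Q = encode(query);
  const int ns = (int) S.size(), nq = (int) Q.size();
  std::vector<int> hs, he, qs, qe, sc, mt, al;
  if (ns < k || nq < k) {
    return DataFrame::create(_["sstart"] = hs, _["send"] = he,
                             _["qstart"] = qs, _["qend"] = qe,
                             _["score"] = sc, _["matches"] = mt,
                             _["alnlen"] = al);
  }
  // index query k-mers
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(nq * 2);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  {
    uint64_t km = 0; int run = 0;
    for (int j = 0; j < nq; ++j) {
      const int c = Q[j];
      if (c >= 4) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t) c) & mask;
      if (++run >= k) idx[km].push_back(j - k + 1);
    }
  }
  std::vector<int> cover(ns, -1);
  struct HitRec { int ss, se, qs, qe; };
  std::vector<HitRec> hits;
  uint64_t km = 0; int run = 0;
  for (int i = 0; i < ns; ++i) {
    const int c = S[i];
    if (c >= 4) { run = 0; km = 0; continue; }
    km = ((km << 2) | (uint64_t) c) & mask;
    if (++run < k) continue;
    const int spos = i - k + 1;
    auto it = idx.find(km);
    if (it == idx.end()) continue;
    for (int qpos : it->second) {
      const int cv = cover[spos];
      if (cv >= 0 && hits[cv].qs <= qpos && qpos < hits[cv].qe) continue;
      int sl, sr, ql, qr;
      const int ug = xdrop_extend(S, Q, spos, qpos, k, match, mismatch, xdrop,
                                  sl, sr, ql, qr);
      // gapped alignment can only add to the ungapped optimum through
      // indels, which cost at least gap_open + gap_ext; a 10-point margin
      // keeps borderline gapped hits while skipping hopeless seeds
      if (ug < min_score - 10) continue;
      int ws0 = std::max(0, sl - pad), ws1 = std::min(ns, sr + pad);
      int wq0 = std::max(0, ql - pad), wq1 = std::min(nq, qr + pad);
      if (ws1 - ws0 > max_window) {   // clamp huge windows around the seed
        ws0 = std::max(0, spos - max_window / 2);
        ws1 = std::min(ns, spos + max_window / 2);
      }
      if (wq1 - wq0 > max_window) {
        wq0 = std::max(0, qpos - max_window / 2);
        wq1 = std::min(nq, qpos + max_window / 2);
      }
      AlnResult r = sw_region(S, Q, ws0, ws1, wq0, wq1,
                              match, mismatch, gap_open, gap_ext);
      if (!r.ok || r.score < min_score) continue;
      bool dup = false;
      for (const HitRec &h : hits) {
        if (h.ss == r.s_begin && h.se == r.s_end &&
            h.qs == r.q_begin && h.qe == r.q_end) { dup = true; break; }
      }
      if (dup) continue;
      HitRec h; h.ss = r.s_begin; h.se = r.s_end; h.qs = r.q_begin; h.qe = r.q_end;
      hits.push_back(h);
      const int hidx = (int) hits.size() - 1;
      for (int p = r.s_begin; p < r.s_end; ++p) cover[p] = hidx;
      hs.push_back(r.s_begin); he.push_back(r.s_end);
      qs.push_back(r.q_begin); qe.push_back(r.q_end);
      sc.push_back(r.score); mt.push_back(r.matches); al.push_back(r.alnlen);
    }
  }
  return DataFrame::create(_["sstart"] = hs, _["send"] = he,
                           _["qstart"] = qs, _["qend"] = qe,
                           _["score"] = sc, _["matches"] = mt,
                           _["alnlen"] = al);
}

// [[Rcpp::export(name = ".sw_align_cpp", rng = false)]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const std::vector<int8_t> A = encode(a), B = encode(b);
  AlnResult r = sw_region(A, B, 0, (int) A.size(), 0, (int) B.size(),
                          match, mismatch, gap_open, gap_ext);
  if (!r.ok) {
    return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["matches"] = 0,
                        _["alnlen"] = 0);
  }
  return List::create(_["score"] = r.score, _["a_start"] = r.s_begin,
                      _["a_end"] = r.s_end, _["b_start"] = r.q_begin,
                      _["b_end"] = r.q_end, _["matches"] = r.matches,
                      _["alnlen"] = r.alnlen);
}
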