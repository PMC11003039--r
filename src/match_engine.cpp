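#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-chain-extend local similarity engine.
//
// Sequences are 2-bit encoded; any non-ACGT base gets code -1 and breaks
// k-mer seeds (ambiguity codes are tolerated as mismatches during extension
// and alignment, matching the documented contract).
//
// Pipeline per (query, target, strand):
//   1. exact k-mer seed hits against a hash index of the target
//   2. seeds bucketed by diagonal (bucket width = `band`), chained when the
//      query-position gap is <= max_gap
//   3. cheap pre-filters: seed count, seed span, seed coverage of the span
//   4. X-drop ungapped extension outward from the chained region
//   5. scoring: single-diagonal chains are evaluated gaplessly; chains whose
//      seeds disagree on the diagonal are re-aligned with a banded global DP
//      over the chained rectangle (match +1, mismatch -1, gap -2)
//
// Identity is matches / alignment columns (gap columns included).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) base_code(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_enc(const std::vector<int8_t>& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int8_t b = s[s.size() - 1 - i];
    v[i] = (b < 0) ? (int8_t) -1 : (int8_t) (3 - b);
  }
  return v;
}

struct SeedHit { int32_t qpos, spos; };

struct MatchRec {
  int qid, tid, strand;       // strand +1 / -1
  int qs, qe, ss, se;         // 0-based half-open; ss/se in strand-local coords
  int matches, columns, nseeds;
};

typedef std::unordered_map<uint64_t, std::vector<int32_t> > KmerIndex;

static void build_index(const std::vector<int8_t>& s, int k, KmerIndex& idx) {
  idx.clear();
  if ((int) s.size() < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) s[i]) & mask;
    if (++valid >= k) idx[kmer].push_back((int32_t) (i - k + 1));
  }
}

// ungapped match count over parallel regions (assumes equal lengths)
static void count_ungapped(const std::vector<int8_t>& q, int qs, int qe,
                           const std::vector<int8_t>& s, int ss,
                           int& matches, int& columns) {
  matches = 0; columns = qe - qs;
  for (int i = qs, j = ss; i < qe; ++i, ++j)
    if (q[i] >= 0 && q[i] == s[j]) ++matches;
}

// banded global alignment over q[qs,qe) x s[ss,se); returns matches/columns
// via traceback. Band is defined around diagonals [dmin, dmax] (j - i offsets
// relative to region origin) widened by `pad`.
static void banded_global(const std::vector<int8_t>& q, int qs, int qe,
                          const std::vector<int8_t>& s, int ss, int se,
                          int dmin, int dmax, int pad,
                          int& matches, int& columns) {
  const int n = qe - qs, m = se - ss;
  const int lo = std::min(dmin, m - n) - pad, hi = std::max(dmax, m - n) + pad;
  const int W = hi - lo + 1;
  const int NEG = -1000000000;
  // dp[i][j - i - lo]
  std::vector<int> prev((size_t) W, NEG), cur((size_t) W, NEG);
  std::vector<uint8_t> tb((size_t) (n + 1) * W, 0); // 1 diag, 2 up(del q), 3 left(ins)
  const int GAP = -2;
  for (int d = 0; d < W; ++d) {
    int j = 0 + d + lo;
    if (j >= 0 && j <= m) { prev[d] = GAP * j; tb[d] = 3; }
  }
  if (0 >= lo && 0 <= hi) tb[-lo] = 0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int d = 0; d < W; ++d) {
      int j = i + d + lo;
      if (j < 0 || j > m) continue;
      int best = NEG; uint8_t dir = 0;
      if (j > 0) { // diagonal
        int sc = prev[d]; // prev row, same offset => (i-1, j-1)
        if (sc > NEG) {
          int8_t a = q[qs + i - 1], b = s[ss + j - 1];
          sc += (a >= 0 && a == b) ? 1 : -1;
          if (sc > best) { best = sc; dir = 1; }
        }
      }
      if (d + 1 < W) { // up: (i-1, j) => offset j - (i-1) - lo = d + 1
        int sc = prev[d + 1];
        if (sc > NEG && sc + GAP > best) { best = sc + GAP; dir = 2; }
      }
      if (d - 1 >= 0 && j > 0) { // left: (i, j-1) => offset d - 1
        int sc = cur[d - 1];
        if (sc > NEG && sc + GAP > best) { best = sc + GAP; dir = 3; }
      }
      if (i == 0 && j == 0) { best = 0; dir = 0; }
      cur[d] = best;
      tb[(size_t) i * W + d] = dir;
    }
    std::swap(prev, cur);
  }
  // traceback from (n, m)
  matches = 0; columns = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int d = j - i - lo;
    if (d < 0 || d >= W) break; // out of band; shouldn't happen
    uint8_t dir = tb[(size_t) i * W + d];
    if (dir == 1 && i > 0 && j > 0) {
      int8_t a = q[qs + i - 1], b = s[ss + j - 1];
      if (a >= 0 && a == b) ++matches;
      --i; --j; ++columns;
    } else if (dir == 2 && i > 0) { --i; ++columns; }
    else if (dir == 3 && j > 0) { --j; ++columns; }
    else break;
  }
  columns += i + j; // any remainder as gaps
}

// X-drop ungapped extension; returns new boundary (exclusive on right side)
static void xdrop_left(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                       int& qlo, int& slo, double xdrop, double penalty) {
  double sc = 0, best = 0; int bi = qlo, bj = slo;
  int i = qlo - 1, j = slo - 1;
  while (i >= 0 && j >= 0) {
    sc += (q[i] >= 0 && q[i] == s[j]) ? 1.0 : -penalty;
    if (sc > best) { best = sc; bi = i; bj = j; }
    if (sc < best - xdrop) break;
    --i; --j;
  }
  qlo = bi; slo = bj;
}

static void xdrop_right(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                        int& qhi, int& shi, double xdrop, double penalty) {
  double sc = 0, best = 0; int bi = qhi, bj = shi;
  int i = qhi, j = shi;
  while (i < (int) q.size() && j < (int) s.size()) {
    sc += (q[i] >= 0 && q[i] == s[j]) ? 1.0 : -penalty;
    ++i; ++j;
    if (sc > best) { best = sc; bi = i; bj = j; }
    if (sc < best - xdrop) break;
  }
  qhi = bi; shi = bj;
}

// Maximal-scoring segment (match +1, mismatch -2) of the gapless alignment
// of q[qlo,qhi) against the diagonal at offset `off` (t position = q + off).
// Returns the best segment boundaries and its match count.
static bool kadane_segment(const std::vector<int8_t>& q, int qlo, int qhi,
                           const std::vector<int8_t>& t, long off, double penalty,
                           int& best_s, int& best_e, int& best_matches) {
  double sc = 0; int m = 0, seg_s = qlo;
  double best = 0; best_s = qlo; best_e = qlo; best_matches = 0;
  int best_m = 0;
  for (int i = qlo; i < qhi; ++i) {
    bool hit = (q[i] >= 0 && q[i] == t[i + off]);
    if (sc == 0) { seg_s = i; m = 0; }
    sc += hit ? 1.0 : -penalty;
    if (hit) ++m;
    if (sc <= 0) { sc = 0; continue; }
    if (sc > best) { best = sc; best_s = seg_s; best_e = i + 1; best_m = m; }
  }
  best_matches = best_m;
  return best > 0;
}

static void process_pair(const std::vector<int8_t>& q, int qid,
                         const std::vector<int8_t>& t, const KmerIndex& idx,
                         int tid, int strand, int k, int max_gap, int band,
                         int min_seeds, int min_seed_span, double min_cov,
                         double penalty, bool drop_self_diag,
                         std::vector<MatchRec>& out) {
  if ((int) q.size() < k || (int) t.size() < k) return;
  // collect seed hits
  std::vector<SeedHit> hits;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i] < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) q[i]) & mask;
    if (++valid < k) continue;
    KmerIndex::const_iterator it = idx.find(kmer);
    if (it == idx.end()) continue;
    int32_t qpos = (int32_t) (i - k + 1);
    for (size_t z = 0; z < it->second.size(); ++z) {
      int32_t spos = it->second[z];
      if (drop_self_diag && spos <= qpos) continue; // self fwd: keep one mirror half
      SeedHit h; h.qpos = qpos; h.spos = spos;
      hits.push_back(h);
    }
  }
  if ((int) hits.size() < min_seeds) return;
  // group seeds by exact diagonal (substitutions do not shift the diagonal),
  // splitting a diagonal's run when the query-position gap exceeds max_gap
  std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
    long da = (long) a.qpos - a.spos, db = (long) b.qpos - b.spos;
    if (da != db) return da < db;
    return a.qpos < b.qpos;
  });
  std::vector<MatchRec> segs;
  size_t i0 = 0;
  while (i0 < hits.size()) {
    long d0 = (long) hits[i0].qpos - hits[i0].spos;
    size_t i1 = i0;
    while (i1 + 1 < hits.size() &&
           ((long) hits[i1 + 1].qpos - hits[i1 + 1].spos) == d0 &&
           hits[i1 + 1].qpos - hits[i1].qpos <= max_gap) {
      ++i1;
    }
    const int nseeds = (int) (i1 - i0 + 1);
    if (nseeds >= min_seeds) {
      int qlo = hits[i0].qpos, qhi = hits[i1].qpos + k;
      int slo = qlo - (int) d0, shi = qhi - (int) d0;
      double xdrop = 12.0 > 3 * penalty ? 12.0 : 3 * penalty;
      xdrop_left(q, t, qlo, slo, xdrop, penalty);
      xdrop_right(q, t, qhi, shi, xdrop, penalty);
      int bs, be, bm;
      if (kadane_segment(q, qlo, qhi, t, -d0, penalty, bs, be, bm) &&
          be - bs >= min_seed_span) {
        // seed coverage (union) of the reported segment: a distant stray
        // seed on the same diagonal must not dilute the estimate
        int cov = 0, cend = -1;
        for (size_t z = i0; z <= i1; ++z) {
          int a = hits[z].qpos, b = hits[z].qpos + k;
          if (a < bs) a = bs;
          if (b > be) b = be;
          if (b <= a) continue;
          if (a > cend) { cov += b - a; cend = b; }
          else if (b > cend) { cov += b - cend; cend = b; }
        }
        if ((double) cov / (double) (be - bs) >= min_cov) {
          MatchRec r;
          r.qid = qid; r.tid = tid; r.strand = strand;
          r.qs = bs; r.qe = be;
          r.ss = bs - (int) d0; r.se = be - (int) d0;
          r.matches = bm; r.columns = be - bs; r.nseeds = nseeds;
          segs.push_back(r);
        }
      }
    }
    i0 = i1 + 1;
  }
  // merge colinear segments on nearby diagonals (the indel case) with a
  // banded global alignment over the union rectangle
  std::sort(segs.begin(), segs.end(), [](const MatchRec& a, const MatchRec& b) {
    return a.qs < b.qs;
  });
  std::vector<bool> merged(segs.size(), false);
  for (size_t a = 0; a < segs.size(); ++a) {
    if (merged[a]) continue;
    size_t chain_end = a;
    int qe = segs[a].qe, se = segs[a].se;
    long da = (long) segs[a].qs - segs[a].ss;
    for (size_t b = a + 1; b < segs.size(); ++b) {
      if (merged[b]) continue;
      long db = (long) segs[b].qs - segs[b].ss;
      if (db == da) continue;                       // same diagonal: separate arrays
      if (std::labs(db - da) > band) continue;
      if (segs[b].qs < qe - 10 || segs[b].qs - qe > max_gap) continue;
      if (segs[b].ss < se - 10 || segs[b].ss - se > max_gap) continue;
      qe = segs[b].qe; se = segs[b].se;
      merged[b] = true; merged[a] = true;
      chain_end = b;
    }
    if (chain_end != a) {
      int qs = segs[a].qs, ss = segs[a].ss;
      // local diagonal offsets (j - i relative to the region origin)
      long dlast = (long) segs[chain_end].qs - segs[chain_end].ss;
      int l2 = (int) (da - dlast);
      int dminL = l2 < 0 ? l2 : 0, dmaxL = l2 > 0 ? l2 : 0;
      int matches = 0, columns = 0;
      banded_global(q, qs, qe, t, ss, se, dminL, dmaxL, band, matches, columns);
      MatchRec r;
      r.qid = qid; r.tid = tid; r.strand = strand;
      r.qs = qs; r.qe = qe; r.ss = ss; r.se = se;
      r.matches = matches; r.columns = columns; r.nseeds = 0;
      out.push_back(r);
      merged[a] = false; // also report the parts; caller dedups by score
    }
  }
  for (size_t a = 0; a < segs.size(); ++a) out.push_back(segs[a]);
}

// [[Rcpp::export]]
DataFrame cpp_match_pool(CharacterVector queries, CharacterVector targets,
                         int k, int max_gap, int band, int min_seeds,
                         int min_seed_span, double min_cov,
                         double mismatch_penalty,
                         bool both_strands, bool self_mode) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::vector<int8_t> > qenc(nq);
  for (int i = 0; i < nq; ++i) qenc[i] = encode_seq(as<std::string>(queries[i]));
  std::vector<MatchRec> out;
  KmerIndex idx;
  for (int t = 0; t < nt; ++t) {
    std::vector<int8_t> tf = encode_seq(as<std::string>(targets[t]));
    const int tlen = (int) tf.size();
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::vector<int8_t> tt = (strand == 0) ? tf : revcomp_enc(tf);
      build_index(tt, k, idx);
      for (int qi = 0; qi < nq; ++qi) {
        if (self_mode && qi > t) continue;       // unordered pairs once
        bool drop_diag = self_mode && qi == t && strand == 0;
        size_t before = out.size();
        process_pair(qenc[qi], qi, tt, idx, t, strand == 0 ? 1 : -1,
                     k, max_gap, band, min_seeds, min_seed_span, min_cov,
                     mismatch_penalty, drop_diag, out);
        // map reverse-strand subject coords back to forward coordinates
        if (strand == 1) {
          for (size_t z = before; z < out.size(); ++z) {
            int ss = out[z].ss, se = out[z].se;
            out[z].ss = tlen - se; out[z].se = tlen - ss;
          }
        }
      }
    }
  }
  const int n = (int) out.size();
  IntegerVector qid(n), tid(n), strand(n), qs(n), qe(n), ss(n), se(n),
      matches(n), columns(n), nseeds(n);
  for (int i = 0; i < n; ++i) {
    qid[i] = out[i].qid + 1; tid[i] = out[i].tid + 1; strand[i] = out[i].strand;
    qs[i] = out[i].qs; qe[i] = out[i].qe; ss[i] = out[i].ss; se[i] = out[i].se;
    matches[i] = out[i].matches; columns[i] = out[i].columns;
    nseeds[i] = out[i].nseeds;
  }
  return DataFrame::create(_["qid"] = qid, _["tid"] = tid, _["strand"] = strand,
                           _["q_start"] = qs, _["q_end"] = qe,
                           _["t_start"] = ss, _["t_end"] = se,
                           _["matches"] = matches, _["columns"] = columns,
                           _["n_seeds"] = nseeds);
}

// Tandem-array scanner: for each candidate period p, positions i with
// seq[i] == seq[i - p] score +2, mismatches -7 (TRF match/mismatch weights);
// maximal positive-scoring segments are candidate arrays. percent_match is
// the adjacent-copy agreement matches / compared positions.
// [[Rcpp::export]]
DataFrame cpp_tandem_scan(std::string seq, int min_unit, int max_unit,
                          double min_match, int min_copies) {
  std::vector<int8_t> s = encode_seq(seq);
  const int n = (int) s.size();
  struct Cand { int start, end, period, matches, compared, score; };
  std::vector<Cand> cands;
  for (int p = min_unit; p <= std::min(max_unit, n / 2); ++p) {
    int sc = 0, m = 0, mm = 0, segstart = -1;
    int best = 0, best_i = -1, best_m = 0, best_mm = 0;
    for (int i = p; i <= n; ++i) {
      bool flushed = (i == n);
      if (!flushed) {
        bool hit = (s[i] >= 0 && s[i] == s[i - p]);
        if (sc == 0 && !hit) continue;
        if (sc == 0) { segstart = i; m = 0; mm = 0; best = 0; best_i = -1; }
        sc += hit ? 2 : -7;
        if (hit) ++m; else ++mm;
        if (sc > best) { best = sc; best_i = i; best_m = m; best_mm = mm; }
        if (sc < 0 || sc < best - 40) flushed = true;
      }
      if (flushed && best_i >= 0) {
        int arr_start = segstart - p, arr_end = best_i + 1;
        int compared = best_m + best_mm;
        if (arr_end - arr_start >= min_copies * p && compared > 0 &&
            (double) best_m / compared >= min_match) {
          Cand c; c.start = arr_start; c.end = arr_end; c.period = p;
          c.matches = best_m; c.compared = compared; c.score = best;
          cands.push_back(c);
        }
        sc = 0; best = 0; best_i = -1;
      }
    }
  }
  // greedy dedup: best score first, drop candidates overlapping a kept one
  std::vector<int> ord(cands.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cands[a].score != cands[b].score) return cands[a].score > cands[b].score;
    return cands[a].start < cands[b].start;
  });
  std::vector<Cand> kept;
  for (size_t z = 0; z < ord.size(); ++z) {
    const Cand& c = cands[ord[z]];
    bool clash = false;
    for (size_t w = 0; w < kept.size(); ++w) {
      int ov = std::min(c.end, kept[w].end) - std::max(c.start, kept[w].start);
      if (ov > (c.end - c.start) / 2) { clash = true; break; }
    }
    if (!clash) kept.push_back(c);
  }
  // flag arrays better explained by a microsatellite-range period (1..6)
  const int nk = (int) kept.size();
  IntegerVector start(nk), end(nk), period(nk), matches(nk), compared(nk), score(nk);
  LogicalVector ssr_like(nk);
  for (int i = 0; i < nk; ++i) {
    const Cand& c = kept[i];
    start[i] = c.start; end[i] = c.end; period[i] = c.period;
    matches[i] = c.matches; compared[i] = c.compared; score[i] = c.score;
    double own = (double) c.matches / c.compared;
    bool fl = false;
    for (int p2 = 1; p2 <= 6 && !fl; ++p2) {
      int m2 = 0, t2 = 0;
      for (int j = c.start + p2; j < c.end; ++j) {
        if (s[j] >= 0 && s[j] == s[j - p2]) ++m2;
        ++t2;
      }
      if (t2 > 0 && (double) m2 / t2 >= own) fl = true;
    }
    ssr_like[i] = fl;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["period"] = period, _["matches"] = matches,
                           _["compared"] = compared, _["score"] = score,
                           _["ssr_like"] = ssr_like);
}
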