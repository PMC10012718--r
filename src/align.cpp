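// Pairwise alignment kernels: affine-gap Smith-Waterman and Needleman-Wunsch,
// plus word-seeded local search (seed -> diagonal clustering -> gapped
// extension by optimal alignment within a padded window).
//
// Sequences arrive as 0-based integer codes; -1 marks a masked position
// (excluded from seeding, scored normally during extension via the unmasked
// code supplied separately). Gap of length k costs open + k * extend.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int a_start, a_end, b_start, b_end; // 1-based inclusive; 0 if empty
  int matches, columns;
  std::vector<int> a_idx, b_idx;      // per-column positions, 0 = gap
};

// Affine-gap local alignment with full traceback.
// Tie order in traceback: diagonal > up (gap in b) > left (gap in a).
// Optionally banded: only cells with dlo <= j - i <= dhi are computed
// (defaults cover the full matrix). Out-of-band neighbours read as -inf;
// local alignments may still start fresh anywhere inside the band.
static AlnResult sw_core(const std::vector<int>& a, const std::vector<int>& b,
                         const NumericMatrix& sub, double gap_open,
                         double gap_extend, bool want_path,
                         int dlo = INT_MIN / 2, int dhi = INT_MAX / 2) {
  const int m = (int)a.size(), n = (int)b.size();
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  const int asz = sub.ncol();
  std::vector<double> subf((size_t)sub.nrow() * asz);
  for (int r = 0; r < sub.nrow(); ++r)
    for (int c2 = 0; c2 < asz; ++c2) subf[(size_t)r * asz + c2] = sub(r, c2);
  AlnResult res; res.score = 0; res.a_start = res.a_end = res.b_start = res.b_end = 0;
  res.matches = 0; res.columns = 0;
  if (m == 0 || n == 0) return res;
  // DP matrices: M = match/mismatch end, X = gap in b (consume a), Y = gap in a.
  std::vector<double> Mrow(n + 1), Xrow(n + 1), Yrow(n + 1);
  std::vector<double> Mprev(n + 1), Xprev(n + 1), Yprev(n + 1);
  // traceback: 2 bits per state per cell
  std::vector<uint8_t> tbM, tbX, tbY;
  if (want_path) { tbM.assign((size_t)(m + 1) * (n + 1), 0);
                   tbX.assign((size_t)(m + 1) * (n + 1), 0);
                   tbY.assign((size_t)(m + 1) * (n + 1), 0); }
  for (int j = 0; j <= n; ++j) { Mprev[j] = 0; Xprev[j] = NEG_INF; Yprev[j] = NEG_INF; }
  for (int j = 0; j <= n; ++j) { Mrow[j] = NEG_INF; Xrow[j] = NEG_INF; Yrow[j] = NEG_INF; }
  double best = 0; int bi = 0, bj = 0; int bstate = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
    if (jlo > jhi) { std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev); continue; }
    Mrow[jlo - 1] = (jlo - 1 == 0) ? 0 : NEG_INF;
    Xrow[jlo - 1] = NEG_INF; Yrow[jlo - 1] = NEG_INF;
    const double* srow = &subf[(size_t)a[i - 1] * asz];
    for (int j = jlo; j <= jhi; ++j) {
      const double s = srow[b[j - 1]];
      // M: from M/X/Y diagonal, or fresh start (0)
      double mM = Mprev[j - 1], mX = Xprev[j - 1], mY = Yprev[j - 1];
      double mbest = 0; uint8_t mfrom = 3; // 3 = local start
      if (mM >= mbest) { mbest = mM; mfrom = 0; }
      if (mX > mbest)  { mbest = mX; mfrom = 1; }
      if (mY > mbest)  { mbest = mY; mfrom = 2; }
      double Mv = mbest + s;
      if (Mv < 0) { Mv = 0; mfrom = 3; }
      // X: gap in b (a[i-1] aligned to gap): from M (open) or X (extend), row i-1
      double xo = Mprev[j] - gap_open - gap_extend;
      double xe = Xprev[j] - gap_extend;
      double Xv; uint8_t xfrom;
      if (xo >= xe) { Xv = xo; xfrom = 0; } else { Xv = xe; xfrom = 1; }
      // Y: gap in a: from M (open) or Y (extend), column j-1
      double yo = Mrow[j - 1] - gap_open - gap_extend;
      double ye = Yrow[j - 1] - gap_extend;
      double Yv; uint8_t yfrom;
      if (yo >= ye) { Yv = yo; yfrom = 0; } else { Yv = ye; yfrom = 1; }
      Mrow[j] = Mv; Xrow[j] = Xv; Yrow[j] = Yv;
      if (want_path) {
        size_t idx = (size_t)i * (n + 1) + j;
        tbM[idx] = mfrom; tbX[idx] = xfrom; tbY[idx] = yfrom;
      }
      // local best ends in M (ending in a gap never helps with positive penalties)
      if (Mv > best) { best = Mv; bi = i; bj = j; bstate = 0; }
    }
    // right sentinel so the next row cannot read stale out-of-band values
    if (jhi < n) { Mrow[jhi + 1] = NEG_INF; Xrow[jhi + 1] = NEG_INF; Yrow[jhi + 1] = NEG_INF; }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }
  res.score = best;
  if (best <= 0 || !want_path) { res.score = best; return res; }
  // traceback from (bi, bj, M)
  int i = bi, j = bj, state = bstate;
  std::vector<int> ai, bidx;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t f = tbM[idx];
      ai.push_back(i); bidx.push_back(j);
      if (a[i - 1] == b[j - 1]) res.matches++;
      --i; --j;
      if (f == 3) break;      // local start
      state = f;              // 0=M,1=X,2=Y
    } else if (state == 1) {
      uint8_t f = tbX[idx];
      ai.push_back(i); bidx.push_back(0);
      --i;
      state = (f == 0) ? 0 : 1;
    } else {
      uint8_t f = tbY[idx];
      ai.push_back(0); bidx.push_back(j);
      --j;
      state = (f == 0) ? 0 : 1 + 1; // stay Y if extend
      if (f == 0) state = 0; else state = 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bidx.begin(), bidx.end());
  res.a_idx = ai; res.b_idx = bidx;
  res.columns = (int)ai.size();
  // endpoints
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0) { res.a_start = ai[k]; break; } }
  for (size_t k = ai.size(); k-- > 0;) {
    if (ai[k] > 0) { res.a_end = ai[k]; break; } }
  for (size_t k = 0; k < bidx.size(); ++k) {
    if (bidx[k] > 0) { res.b_start = bidx[k]; break; } }
  for (size_t k = bidx.size(); k-- > 0;) {
    if (bidx[k] > 0) { res.b_end = bidx[k]; break; } }
  return res;
}

static std::vector<int> as_codes(const IntegerVector& v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

static List aln_to_list(const AlnResult& r) {
  return List::create(_["score"] = r.score,
                      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["a_idx"] = wrap(r.a_idx), _["b_idx"] = wrap(r.b_idx));
}

// [[Rcpp::export]]
List sw_align_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gap_open, double gap_extend, bool traceback = true) {
  AlnResult r = sw_core(as_codes(a), as_codes(b), sub, gap_open, gap_extend, traceback);
  return aln_to_list(r);
}

// Global (Needleman-Wunsch) affine alignment, terminal gaps charged.
// [[Rcpp::export]]
List nw_align_c(IntegerVector av, IntegerVector bv, NumericMatrix sub,
                double gap_open, double gap_extend) {
  std::vector<int> a = as_codes(av), b = as_codes(bv);
  const int m = (int)a.size(), n = (int)b.size();
  const int asz = sub.ncol();
  std::vector<double> subf((size_t)sub.nrow() * asz);
  for (int r = 0; r < sub.nrow(); ++r)
    for (int c2 = 0; c2 < asz; ++c2) subf[(size_t)r * asz + c2] = sub(r, c2);
  std::vector<double> Mp(n + 1), Xp(n + 1), Yp(n + 1), Mr(n + 1), Xr(n + 1), Yr(n + 1);
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), 0),
                       tbX((size_t)(m + 1) * (n + 1), 0),
                       tbY((size_t)(m + 1) * (n + 1), 0);
  Mp[0] = 0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = -gap_open - gap_extend * j;
    tbY[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    Mr[0] = NEG_INF; Yr[0] = NEG_INF;
    Xr[0] = -gap_open - gap_extend * i;
    tbX[(size_t)i * (n + 1)] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= n; ++j) {
      const double s = subf[(size_t)a[i - 1] * asz + b[j - 1]];
      double c0 = Mp[j - 1], c1 = Xp[j - 1], c2 = Yp[j - 1];
      double mb = c0; uint8_t mf = 0;
      if (c1 > mb) { mb = c1; mf = 1; }
      if (c2 > mb) { mb = c2; mf = 2; }
      Mr[j] = mb + s;
      double xo = std::max(Mp[j], Yp[j]) - gap_open - gap_extend;
      uint8_t xfromM = (Mp[j] >= Yp[j]) ? 0 : 2;
      double xe = Xp[j] - gap_extend;
      if (xo >= xe) { Xr[j] = xo; tbX[(size_t)i * (n + 1) + j] = xfromM; }
      else { Xr[j] = xe; tbX[(size_t)i * (n + 1) + j] = 1; }
      double yo = std::max(Mr[j - 1], Xr[j - 1]) - gap_open - gap_extend;
      uint8_t yfromM = (Mr[j - 1] >= Xr[j - 1]) ? 0 : 1;
      double ye = Yr[j - 1] - gap_extend;
      if (yo >= ye) { Yr[j] = yo; tbY[(size_t)i * (n + 1) + j] = yfromM == 0 ? 0 : 3; }
      else { Yr[j] = ye; tbY[(size_t)i * (n + 1) + j] = 1; }
      tbM[(size_t)i * (n + 1) + j] = mf;
    }
    std::swap(Mr, Mp); std::swap(Xr, Xp); std::swap(Yr, Yp);
  }
  double sM = Mp[n], sX = Xp[n], sY = Yp[n];
  int state = 0; double best = sM;
  if (sX > best) { best = sX; state = 1; }
  if (sY > best) { best = sY; state = 2; }
  // traceback
  int i = m, j = n;
  std::vector<int> ai, bi;
  int matches = 0;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0 && i > 0 && j > 0) {
      ai.push_back(i); bi.push_back(j);
      if (a[i - 1] == b[j - 1]) matches++;
      uint8_t f = tbM[idx]; --i; --j; state = f;
    } else if (state == 1 && i > 0) {
      ai.push_back(i); bi.push_back(0);
      uint8_t f = tbX[idx]; --i;
      state = (f == 1) ? 1 : (f == 2 ? 2 : 0);
    } else if (state == 2 && j > 0) {
      ai.push_back(0); bi.push_back(j);
      uint8_t f = tbY[idx]; --j;
      state = (f == 1) ? 2 : (f == 3 ? 1 : 0);
    } else if (i > 0) { state = 1; } else { state = 2; }
  }
  std::reverse(ai.begin(), ai.end()); std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = (int)ai.size(),
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi));
}

// Word-seeded local search. `qseed`/`sseed` are codes with masked positions
// set to -1 (seeding only); `q`/`s` are unmasked codes used for extension.
// Returns a list of HSPs from diagonal-clustered seeds, each the optimal
// local alignment within a window padded by `pad` around the seed cluster.
// [[Rcpp::export]]
List seeded_search_c(IntegerVector qv, IntegerVector qseedv,
                     IntegerVector sv, IntegerVector sseedv,
                     NumericMatrix sub, double gap_open, double gap_extend,
                     int word_size, int diag_tol, int join_gap, int pad,
                     int alphabet_size, double min_score) {
  std::vector<int> q = as_codes(qv), s = as_codes(sv);
  std::vector<int> qs = as_codes(qseedv), ss = as_codes(sseedv);
  const int m = (int)q.size(), n = (int)s.size();
  const int asz2 = sub.ncol();
  std::vector<double> subf2((size_t)sub.nrow() * asz2);
  for (int r = 0; r < sub.nrow(); ++r)
    for (int c2 = 0; c2 < asz2; ++c2) subf2[(size_t)r * asz2 + c2] = sub(r, c2);
  List empty = List::create();
  if (m < word_size || n < word_size) return empty;
  // hash words of query
  long base = 1; for (int k = 1; k < word_size; ++k) base *= alphabet_size;
  std::map<long, std::vector<int> > words; // word -> query positions (0-based)
  long h = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    if (qs[i] < 0) { run = 0; h = 0; continue; }
    h = (run >= word_size ? h % base : h) * alphabet_size + qs[i];
    ++run;
    if (run >= word_size) {
      if (run > word_size) h = h % (base * alphabet_size);
      // recompute cleanly to avoid drift
      long hh = 0; for (int k = i - word_size + 1; k <= i; ++k) hh = hh * alphabet_size + qs[k];
      words[hh].push_back(i - word_size + 1);
    }
  }
  if (words.empty()) return empty;
  // seeds: (diag, qpos, spos)
  struct Seed { int diag, qpos, spos; };
  std::vector<Seed> seeds;
  run = 0;
  for (int j = 0; j < n; ++j) {
    if (ss[j] < 0) { run = 0; continue; }
    ++run;
    if (run >= word_size) {
      long hh = 0; for (int k = j - word_size + 1; k <= j; ++k) hh = hh * alphabet_size + ss[k];
      std::map<long, std::vector<int> >::iterator it = words.find(hh);
      if (it != words.end()) {
        for (size_t t = 0; t < it->second.size(); ++t) {
          int qp = it->second[t], sp = j - word_size + 1;
          Seed sd; sd.diag = sp - qp; sd.qpos = qp; sd.spos = sp;
          seeds.push_back(sd);
        }
      }
    }
  }
  if (seeds.empty()) return empty;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    if (x.diag != y.diag) return x.diag < y.diag;
    return x.spos < y.spos;
  });
  // cluster seeds: same band of diagonals (within diag_tol) and subject
  // positions within join_gap of the cluster's running extent
  struct Clust { int dmin, dmax, qmin, qmax, smin, smax, nseeds, q0, s0; };
  std::vector<Clust> clusters;
  for (size_t k = 0; k < seeds.size(); ++k) {
    const Seed& sd = seeds[k];
    bool placed = false;
    for (size_t c = clusters.size(); c-- > 0;) {
      Clust& cl = clusters[c];
      if (sd.diag >= cl.dmin - diag_tol && sd.diag <= cl.dmax + diag_tol &&
          sd.spos >= cl.smin - join_gap && sd.spos <= cl.smax + join_gap &&
          sd.qpos >= cl.qmin - join_gap && sd.qpos <= cl.qmax + join_gap) {
        cl.dmin = std::min(cl.dmin, sd.diag); cl.dmax = std::max(cl.dmax, sd.diag);
        cl.qmin = std::min(cl.qmin, sd.qpos); cl.qmax = std::max(cl.qmax, sd.qpos + word_size - 1);
        cl.smin = std::min(cl.smin, sd.spos); cl.smax = std::max(cl.smax, sd.spos + word_size - 1);
        cl.nseeds += 1;
        placed = true; break;
      }
    }
    if (!placed) {
      Clust cl; cl.dmin = cl.dmax = sd.diag;
      cl.qmin = sd.qpos; cl.qmax = sd.qpos + word_size - 1;
      cl.smin = sd.spos; cl.smax = sd.spos + word_size - 1;
      cl.nseeds = 1; cl.q0 = sd.qpos; cl.s0 = sd.spos;
      clusters.push_back(cl);
    }
  }
  // merge overlapping clusters (bounding boxes)
  bool merged = true;
  while (merged) {
    merged = false;
    for (size_t i2 = 0; i2 < clusters.size() && !merged; ++i2)
      for (size_t j2 = i2 + 1; j2 < clusters.size() && !merged; ++j2) {
        Clust& A = clusters[i2]; Clust& B = clusters[j2];
        bool dov = !(B.dmin > A.dmax + diag_tol || B.dmax < A.dmin - diag_tol);
        bool sov = !(B.smin > A.smax + join_gap || B.smax < A.smin - join_gap);
        bool qov = !(B.qmin > A.qmax + join_gap || B.qmax < A.qmin - join_gap);
        if (dov && sov && qov) {
          A.dmin = std::min(A.dmin, B.dmin); A.dmax = std::max(A.dmax, B.dmax);
          A.qmin = std::min(A.qmin, B.qmin); A.qmax = std::max(A.qmax, B.qmax);
          A.smin = std::min(A.smin, B.smin); A.smax = std::max(A.smax, B.smax);
          A.nseeds += B.nseeds;
          clusters.erase(clusters.begin() + j2);
          merged = true;
        }
      }
  }
  // ungapped x-drop extension along a seed's diagonal: the cheap first
  // stage that discards chance word matches before any gapped alignment
  const double x_drop = 20.0;
  auto pair_score = [&](int qc, int sc2) {
    return subf2[(size_t)qc * asz2 + sc2];
  };
  auto ungapped_score = [&](int qpos, int spos, int len) {
    double sc = 0;
    for (int k = 0; k < len; ++k)
      sc += pair_score(q[qpos + k], s[spos + k]);
    return sc;
  };
  List out;
  for (size_t c = 0; c < clusters.size(); ++c) {
    const Clust& cl = clusters[c];
    if (cl.nseeds < 4) {
      // two-directional ungapped x-drop from the founding seed
      double sc = ungapped_score(cl.q0, cl.s0, word_size);
      double bestu = sc;
      int qi = cl.q0 + word_size, si = cl.s0 + word_size;
      double cur = sc;
      while (qi < m && si < n) {
        cur += pair_score(q[qi], s[si]);
        if (cur > bestu) bestu = cur;
        if (cur < bestu - x_drop) break;
        ++qi; ++si;
      }
      double right_gain = bestu - sc;
      qi = cl.q0 - 1; si = cl.s0 - 1;
      cur = 0; double bestl = 0;
      while (qi >= 0 && si >= 0) {
        cur += pair_score(q[qi], s[si]);
        if (cur > bestl) bestl = cur;
        if (cur < bestl - x_drop) break;
        --qi; --si;
      }
      double usc = sc + right_gain + bestl;
      if (usc < std::min(min_score * 0.5, 24.0)) continue;
    }
    // extension window scales with seed support: a lone chance word match
    // gets a short extension, well-seeded homology the full pad
    int p_eff = (cl.nseeds >= 4) ? pad
              : std::min(pad, 48 * cl.nseeds + 16);
    int q0 = std::max(0, cl.qmin - p_eff), q1 = std::min(m, cl.qmax + 1 + p_eff);
    int s0 = std::max(0, cl.smin - p_eff), s1 = std::min(n, cl.smax + 1 + p_eff);
    std::vector<int> qa(q.begin() + q0, q.begin() + q1);
    std::vector<int> sa(s.begin() + s0, s.begin() + s1);
    // diagonal band around the cluster's seed diagonals (with slack for
    // indel drift), in window coordinates: diag' = diag - (s0 - q0)
    int slack = diag_tol + 48;
    int bdlo = cl.dmin - (s0 - q0) - slack;
    int bdhi = cl.dmax - (s0 - q0) + slack;
    // cheap score-only pass for sparsely seeded windows; well-seeded
    // clusters are almost always real, so align them directly
    if (cl.nseeds < 4) {
      AlnResult probe = sw_core(qa, sa, sub, gap_open, gap_extend, false,
                                bdlo, bdhi);
      if (probe.score < min_score) continue;
    }
    AlnResult r = sw_core(qa, sa, sub, gap_open, gap_extend, true,
                          bdlo, bdhi);
    if (r.score <= 0 || r.columns == 0) continue;
    if (r.score < min_score) continue;
    out.push_back(List::create(
      _["score"] = r.score,
      _["q_start"] = r.a_start + q0, _["q_end"] = r.a_end + q0,
      _["s_start"] = r.b_start + s0, _["s_end"] = r.b_end + s0,
      _["matches"] = r.matches, _["columns"] = r.columns));
  }
  return out;
}
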