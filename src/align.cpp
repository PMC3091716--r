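#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// DNA is handled as integer codes 0..3 (A,C,G,T); anything else is 4 and
// never matches, never seeds, and is unscorable by a PWM.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// ---------------------------------------------------------------------------
// Seed finding: exact shared k-mers (degeneracy 0).
// ---------------------------------------------------------------------------

// k-mer -> packed integer; -1 if the word contains a non-ACGT base
static inline long word_at(const std::vector<int> &v, int pos, int k) {
  long w = 0;
  for (int i = 0; i < k; ++i) {
    int c = v[pos + i];
    if (c > 3) return -1;
    w = (w << 2) | c;
  }
  return w;
}

// direct-indexed word table: 4^k buckets (k is small)
typedef std::vector<std::vector<int> > WordIndex;

static WordIndex index_words(const std::vector<int> &O, int k) {
  if (k > 12) stop("word_len larger than 12 is not supported");
  WordIndex idx(1L << (2 * k));
  for (int j = 0; j + k <= (int)O.size(); ++j) {
    long w = word_at(O, j, k);
    if (w >= 0) idx[w].push_back(j);
  }
  return idx;
}

// [[Rcpp::export]]
DataFrame cpp_find_seeds(std::string h, std::string o, int word_len) {
  std::vector<int> H = encode(h), O = encode(o);
  std::vector<int> hs, os;
  if ((int)H.size() >= word_len && (int)O.size() >= word_len) {
    WordIndex idx = index_words(O, word_len);
    for (int i = 0; i + word_len <= (int)H.size(); ++i) {
      long w = word_at(H, i, word_len);
      if (w < 0) continue;
      const std::vector<int> &hits = idx[w];
      for (size_t t = 0; t < hits.size(); ++t) {
        hs.push_back(i);
        os.push_back(hits[t]);
      }
    }
  }
  return DataFrame::create(_["h_pos"] = hs, _["o_pos"] = os);
}

// ---------------------------------------------------------------------------
// Gapped x-drop extension with affine gaps.
//
// Scores: match m (>0), mismatch mm (<0), a gap run of length L costs
// open + L*ext. The DP keeps a sliding window of columns whose score is
// within xdrop of the running best; cells outside any row's window are
// never read (guarded by the filled range of the previous row), so work
// per row is proportional to the window width, not the sequence length.
//
// The optimal path's column counts (matches, mismatches, gap opens, gap
// columns) are carried along only when TRACK is set; retained segments are
// re-extended with TRACK to obtain counts, so the common case (a seed that
// dies quickly) stays cheap. Ties prefer the aligned state over a gap in
// the ortholog over a gap in the human sequence, and the earliest
// endpoint.
// ---------------------------------------------------------------------------

// path column counts packed into one word: nm | nmm<<16 | ngo<<32 | nge<<48
typedef unsigned long long Cnt;
static const Cnt CNT0 = 0ULL;
static const Cnt C_NM = 1ULL;
static const Cnt C_NMM = 1ULL << 16;
static const Cnt C_NGO = 1ULL << 32;
static const Cnt C_NGE = 1ULL << 48;
static inline int cnt_nm(Cnt c) { return (int)(c & 0xFFFF); }
static inline int cnt_nmm(Cnt c) { return (int)((c >> 16) & 0xFFFF); }
static inline int cnt_ngo(Cnt c) { return (int)((c >> 32) & 0xFFFF); }
static inline int cnt_nge(Cnt c) { return (int)((c >> 48) & 0xFFFF); }

struct ExtRes {
  double score;
  int di, dj;   // columns consumed in h and o
  Cnt cnt;
};

static const double NEG = -1e30;

struct Ws {
  std::vector<double> M, Ix, Iy, Mn, Ixn, Iyn;
  std::vector<Cnt> Mc, Ixc, Iyc, Mnc, Ixnc, Iync;
  void ensure(size_t n, bool track) {
    if (M.size() < n) {
      M.resize(n); Ix.resize(n); Iy.resize(n);
      Mn.resize(n); Ixn.resize(n); Iyn.resize(n);
    }
    if (track && Mc.size() < n) {
      Mc.resize(n); Ixc.resize(n); Iyc.resize(n);
      Mnc.resize(n); Ixnc.resize(n); Iync.resize(n);
    }
  }
};

template <bool TRACK>
static ExtRes extend_dir_t(const std::vector<int> &A,
                           const std::vector<int> &B,
                           int ai, int bi, int dir,
                           double m, double mm, double open, double ext,
                           double xdrop, Ws &ws) {
  ExtRes best; best.score = 0.0; best.di = 0; best.dj = 0; best.cnt = CNT0;
  int maxI = (dir > 0) ? ((int)A.size() - ai) : (ai + 1);
  int maxJ = (dir > 0) ? ((int)B.size() - bi) : (bi + 1);
  if (maxI <= 0 || maxJ <= 0) return best;
  int width = maxJ + 1;
  ws.ensure(width, TRACK);
  std::vector<double> &M = ws.M, &Ix = ws.Ix, &Iy = ws.Iy,
    &Mn = ws.Mn, &Ixn = ws.Ixn, &Iyn = ws.Iyn;
  std::vector<Cnt> &Mc = ws.Mc, &Ixc = ws.Ixc, &Iyc = ws.Iyc,
    &Mnc = ws.Mnc, &Ixnc = ws.Ixnc, &Iync = ws.Iync;

  int gapspan = (int)(xdrop / ext) + 2;
  // row 0: only gap-in-A (consume B) cells are reachable
  M[0] = 0.0; Ix[0] = NEG; Iy[0] = NEG;
  if (TRACK) { Mc[0] = CNT0; }
  int fillHi = 0;
  for (int j = 1; j < width && j <= gapspan; ++j) {
    double s = (j == 1) ? (0.0 - open - ext) : (Iy[j - 1] - ext);
    if (s < -xdrop) break;
    M[j] = NEG; Ix[j] = NEG; Iy[j] = s;
    if (TRACK)
      Iyc[j] = (j == 1) ? (C_NGO + C_NGE) : (Iyc[j - 1] + C_NGE);
    fillHi = j;
  }
  int lo = 0, hi = fillHi, pLo = 0, pHi = fillHi;
  double bestScore = 0.0;

  for (int i = 1; i <= maxI; ++i) {
    int ca = (dir > 0) ? A[ai + i - 1] : A[ai - i + 1];
    int jend = std::min(width - 1, hi + gapspan);
    int nlo = -1, nhi = -1, jlast = lo;
    for (int j = lo; j <= jend; ++j) {
      bool pv = (j >= pLo && j <= pHi);         // prev row filled at j
      bool pd = (j - 1 >= pLo && j - 1 <= pHi); // prev row filled at j-1
      // Ix: gap in B (consume A), from row i-1 same column
      double ixo = pv && M[j] > NEG / 2 ? M[j] - open - ext : NEG;
      double ixe = pv && Ix[j] > NEG / 2 ? Ix[j] - ext : NEG;
      if (ixo >= ixe && ixo > NEG / 2) {
        Ixn[j] = ixo;
        if (TRACK) Ixnc[j] = Mc[j] + C_NGO + C_NGE;
      } else if (ixe > NEG / 2) {
        Ixn[j] = ixe;
        if (TRACK) Ixnc[j] = Ixc[j] + C_NGE;
      } else Ixn[j] = NEG;
      if (j >= 1) {
        // M: diagonal from row i-1, column j-1
        double prev = NEG; int which = -1;
        if (pd) {
          if (M[j - 1] > NEG / 2) { prev = M[j - 1]; which = 0; }
          if (Ix[j - 1] > prev) { prev = Ix[j - 1]; which = 1; }
          if (Iy[j - 1] > prev) { prev = Iy[j - 1]; which = 2; }
        }
        if (which >= 0) {
          int cb = (dir > 0) ? B[bi + j - 1] : B[bi - j + 1];
          bool ismatch = (ca == cb && ca < 4);
          Mn[j] = prev + (ismatch ? m : mm);
          if (TRACK)
            Mnc[j] = ((which == 0) ? Mc[j - 1] : (which == 1) ? Ixc[j - 1]
                      : Iyc[j - 1]) + (ismatch ? C_NM : C_NMM);
        } else Mn[j] = NEG;
        // Iy: gap in A (consume B), along this row
        bool cd = (j - 1 >= lo);                 // current row filled at j-1
        double iyo = cd && Mn[j - 1] > NEG / 2 ? Mn[j - 1] - open - ext : NEG;
        double iye = cd && Iyn[j - 1] > NEG / 2 ? Iyn[j - 1] - ext : NEG;
        if (iyo >= iye && iyo > NEG / 2) {
          Iyn[j] = iyo;
          if (TRACK) Iync[j] = Mnc[j - 1] + C_NGO + C_NGE;
        } else if (iye > NEG / 2) {
          Iyn[j] = iye;
          if (TRACK) Iync[j] = Iync[j - 1] + C_NGE;
        } else Iyn[j] = NEG;
      } else { Mn[j] = NEG; Iyn[j] = NEG; }
      double cell = std::max(Mn[j], std::max(Ixn[j], Iyn[j]));
      if (cell >= bestScore - xdrop && cell > NEG / 2) {
        if (nlo < 0) nlo = j;
        nhi = j;
        if (Mn[j] > bestScore) {
          bestScore = Mn[j];
          best.score = Mn[j]; best.di = i; best.dj = j;
          if (TRACK) best.cnt = Mnc[j];
        }
      } else {
        Mn[j] = Ixn[j] = Iyn[j] = NEG;
        // beyond the previous window only a gap run along this row
        // can stay alive; once it dies the row is finished
        if (j > hi + 1) { jlast = j; break; }
      }
      jlast = j;
    }
    if (nlo < 0) break;
    M.swap(Mn); Ix.swap(Ixn); Iy.swap(Iyn);
    if (TRACK) { Mc.swap(Mnc); Ixc.swap(Ixnc); Iyc.swap(Iync); }
    pLo = lo; pHi = jlast;
    lo = nlo; hi = nhi;
  }
  return best;
}

struct Seg {
  int h_start, h_end, o_start, o_end;
  double score;
  Cnt cnt;
};

// Cheap ungapped x-drop extension along the seed diagonal; used as the
// trigger for the gapped DP (the gapped optimum is never below the
// ungapped one, so triggering at the retention score loses nothing that
// an ungapped path could retain).
static double ungapped_dir(const std::vector<int> &A,
                           const std::vector<int> &B,
                           int ai, int bi, int dir,
                           double m, double mm, double xdrop) {
  int maxT = (dir > 0)
    ? std::min((int)A.size() - ai, (int)B.size() - bi)
    : std::min(ai + 1, bi + 1);
  double s = 0.0, best = 0.0;
  for (int t = 0; t < maxT; ++t) {
    int ca = A[ai + dir * t], cb = B[bi + dir * t];
    s += (ca == cb && ca < 4) ? m : mm;
    if (s > best) best = s;
    else if (s < best - xdrop) break;
  }
  return best;
}

static bool extend_one(const std::vector<int> &H, const std::vector<int> &O,
                       int hpos, int opos, int k,
                       double m, double mm, double open, double ext,
                       double xdrop, double min_score, Ws &ws, Seg &out,
                       bool gapped_trigger) {
  if (gapped_trigger) {
    double s0 = k * m +
      ungapped_dir(H, O, hpos + k, opos + k, +1, m, mm, xdrop) +
      ungapped_dir(H, O, hpos - 1, opos - 1, -1, m, mm, xdrop);
    if (s0 < min_score) return false;
  } else {
    // score-only gapped pass; counts recovered only when retained
    ExtRes r0 = extend_dir_t<false>(H, O, hpos + k, opos + k, +1, m, mm,
                                    open, ext, xdrop, ws);
    ExtRes l0 = extend_dir_t<false>(H, O, hpos - 1, opos - 1, -1, m, mm,
                                    open, ext, xdrop, ws);
    if (k * m + r0.score + l0.score < min_score) return false;
  }
  ExtRes right = extend_dir_t<true>(H, O, hpos + k, opos + k, +1, m, mm,
                                    open, ext, xdrop, ws);
  ExtRes left = extend_dir_t<true>(H, O, hpos - 1, opos - 1, -1, m, mm,
                                   open, ext, xdrop, ws);
  if (k * m + right.score + left.score < min_score) return false;
  out.h_start = hpos - left.di;
  out.h_end   = hpos + k + right.di;
  out.o_start = opos - left.dj;
  out.o_end   = opos + k + right.dj;
  out.score = k * m + right.score + left.score;
  out.cnt = right.cnt + left.cnt + (Cnt)k * C_NM;
  return true;
}

// [[Rcpp::export]]
List cpp_extend_seed(std::string h, std::string o, int hpos, int opos,
                     int word_len, double match, double mismatch,
                     double gap_open, double gap_ext, double xdrop,
                     double min_score) {
  std::vector<int> H = encode(h), O = encode(o);
  Ws ws;
  Seg s;
  if (!extend_one(H, O, hpos, opos, word_len, match, mismatch, gap_open,
                  gap_ext, xdrop, min_score, ws, s, false))
    return List::create();
  return List::create(
    _["h_start"] = s.h_start, _["h_end"] = s.h_end,
    _["o_start"] = s.o_start, _["o_end"] = s.o_end,
    _["score"] = s.score, _["n_match"] = cnt_nm(s.cnt),
    _["n_mismatch"] = cnt_nmm(s.cnt), _["n_gap_open"] = cnt_ngo(s.cnt),
    _["n_gap_ext"] = cnt_nge(s.cnt));
}

// Align one strand into a segment vector (codes already prepared).
static void align_strand_codes(const std::vector<int> &H,
                               const std::vector<int> &O, int word_len,
                               double match, double mismatch,
                               double gap_open, double gap_ext,
                               double xdrop, double min_score, Ws &ws,
                               int strand, int o_len,
                               std::vector<Seg> &out,
                               std::vector<int> &strands) {
  if ((int)H.size() < word_len || (int)O.size() < word_len) return;
  WordIndex idx = index_words(O, word_len);
  std::vector<Seg> kept;
  for (int i = 0; i + word_len <= (int)H.size(); ++i) {
    long w = word_at(H, i, word_len);
    if (w < 0) continue;
    const std::vector<int> &hits = idx[w];
    for (size_t t = 0; t < hits.size(); ++t) {
      int j = hits[t];
      bool covered = false;
      for (size_t q = kept.size(); q-- > 0;) {
        const Seg &s = kept[q];
        if (i >= s.h_start && i + word_len <= s.h_end &&
            j >= s.o_start && j + word_len <= s.o_end) { covered = true; break; }
      }
      if (covered) continue;
      Seg s;
      if (extend_one(H, O, i, j, word_len, match, mismatch, gap_open,
                     gap_ext, xdrop, min_score, ws, s, true))
        kept.push_back(s);
    }
  }
  for (size_t q = 0; q < kept.size(); ++q) {
    Seg s = kept[q];
    if (strand == 1) {           // map back to forward ortholog coords
      int os = o_len - s.o_end, oe = o_len - s.o_start;
      s.o_start = os; s.o_end = oe;
    }
    out.push_back(s);
    strands.push_back(strand);
  }
}

// Both strands of one sequence pair, seeds extended and deduplicated,
// overlaps on the human sequence resolved greedily by score (ties:
// smaller human start, forward strand first). Columns: h_start, h_end,
// o_start, o_end, strand (0='+', 1='-'), score, n_match, n_mismatch,
// n_gap_open, n_gap_ext.
// [[Rcpp::export]]
NumericMatrix cpp_align_pair(std::string h, std::string o, int word_len,
                             double match, double mismatch,
                             double gap_open, double gap_ext, double xdrop,
                             double min_score) {
  std::vector<int> H = encode(h), O = encode(o);
  int o_len = (int)O.size();
  std::vector<int> Orc(o_len);
  for (int i = 0; i < o_len; ++i) {
    int c = O[o_len - 1 - i];
    Orc[i] = (c < 4) ? 3 - c : 4;
  }
  Ws ws;
  std::vector<Seg> segs;
  std::vector<int> strands;
  align_strand_codes(H, O, word_len, match, mismatch, gap_open, gap_ext,
                     xdrop, min_score, ws, 0, o_len, segs, strands);
  align_strand_codes(H, Orc, word_len, match, mismatch, gap_open, gap_ext,
                     xdrop, min_score, ws, 1, o_len, segs, strands);
  // greedy overlap resolution on the human sequence
  std::vector<int> ord(segs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (segs[a].score != segs[b].score) return segs[a].score > segs[b].score;
    if (segs[a].h_start != segs[b].h_start)
      return segs[a].h_start < segs[b].h_start;
    return strands[a] < strands[b];
  });
  std::vector<int> keep;
  std::vector<std::pair<int, int> > taken;
  for (size_t q = 0; q < ord.size(); ++q) {
    const Seg &s = segs[ord[q]];
    bool clash = false;
    for (size_t t = 0; t < taken.size(); ++t)
      if (s.h_start < taken[t].second && s.h_end > taken[t].first) {
        clash = true; break;
      }
    if (clash) continue;
    keep.push_back(ord[q]);
    taken.push_back(std::make_pair(s.h_start, s.h_end));
  }
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    return segs[a].h_start < segs[b].h_start;
  });
  NumericMatrix out((int)keep.size(), 10);
  for (size_t i = 0; i < keep.size(); ++i) {
    const Seg &s = segs[keep[i]];
    out(i, 0) = s.h_start; out(i, 1) = s.h_end;
    out(i, 2) = s.o_start; out(i, 3) = s.o_end;
    out(i, 4) = strands[keep[i]];
    out(i, 5) = s.score;
    out(i, 6) = cnt_nm(s.cnt); out(i, 7) = cnt_nmm(s.cnt);
    out(i, 8) = cnt_ngo(s.cnt); out(i, 9) = cnt_nge(s.cnt);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Discontiguous-similarity window scoring: for each 1-kb human window
// anchored at ws[i], the best sum of segment scores over all ortholog
// windows (sweep over segment-eligibility endpoints).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector ws, IntegerVector we,
                                IntegerVector hs, IntegerVector he,
                                IntegerVector os, IntegerVector oe,
                                NumericVector sc, int window) {
  int n = ws.size(), m = hs.size();
  NumericVector out(n);
  std::vector<std::pair<int, double> > ev;
  for (int i = 0; i < n; ++i) {
    ev.clear();
    for (int k = 0; k < m; ++k) {
      if (hs[k] < ws[i] || he[k] > we[i]) continue;
      if (oe[k] - os[k] > window) continue;
      ev.push_back(std::make_pair(oe[k] - window, sc[k]));
      ev.push_back(std::make_pair(os[k] + 1, -sc[k]));
    }
    if (ev.empty()) { out[i] = 0.0; continue; }
    std::sort(ev.begin(), ev.end());   // removes before adds at equal pos
    double run = 0.0, best = 0.0;
    for (size_t t = 0; t < ev.size(); ++t) {
      run += ev[t].second;
      if (run > best) best = run;
    }
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// PWM scanning: log-odds score of every window; windows containing a
// non-ACGT base are unscorable (-Inf).
// ---------------------------------------------------------------------------

// Pooled forward-strand scores of many sequences (windows with non-ACGT
// bases are dropped); used for cutoff calibration.
// [[Rcpp::export]]
NumericVector cpp_pwm_scan_pool(std::vector<std::string> seqs,
                                NumericMatrix lo) {
  int w = lo.ncol();
  std::vector<double> out;
  for (size_t q = 0; q < seqs.size(); ++q) {
    std::vector<int> S = encode(seqs[q]);
    int n = (int)S.size() - w + 1;
    for (int i = 0; i < n; ++i) {
      double s = 0.0; bool ok = true;
      for (int j = 0; j < w; ++j) {
        int c = S[i + j];
        if (c > 3) { ok = false; break; }
        s += lo(c, j);
      }
      if (ok) out.push_back(s);
    }
  }
  return wrap(out);
}

// Scan one sequence with a whole motif library on both strands; returns a
// matrix of hits (score strictly above each motif's cutoff): columns
// motif (1-based index), start (0-based, forward coords), strand
// (0='+', 1='-'), score.
// [[Rcpp::export]]
NumericMatrix cpp_scan_hits(std::string seq, List lo_list,
                            NumericVector cutoffs) {
  std::vector<int> S = encode(seq);
  int len = (int)S.size();
  std::vector<int> R(len);
  for (int i = 0; i < len; ++i) {
    int c = S[len - 1 - i];
    R[i] = (c < 4) ? 3 - c : 4;
  }
  std::vector<double> mo, st, sd, sc;
  for (int q = 0; q < lo_list.size(); ++q) {
    NumericMatrix lo = lo_list[q];
    int w = lo.ncol();
    double cut = cutoffs[q];
    int n = len - w + 1;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int> &V = strand ? R : S;
      for (int i = 0; i < n; ++i) {
        double s = 0.0; bool ok = true;
        for (int j = 0; j < w; ++j) {
          int c = V[i + j];
          if (c > 3) { ok = false; break; }
          s += lo(c, j);
        }
        if (!ok || s <= cut) continue;
        mo.push_back(q + 1);
        st.push_back(strand ? (len - i - w) : i);
        sd.push_back(strand);
        sc.push_back(s);
      }
    }
  }
  NumericMatrix out((int)mo.size(), 4);
  for (size_t i = 0; i < mo.size(); ++i) {
    out(i, 0) = mo[i]; out(i, 1) = st[i]; out(i, 2) = sd[i];
    out(i, 3) = sc[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pwm_scan(std::string seq, NumericMatrix lo) {
  int w = lo.ncol();              // lo is 4 x width, rows A,C,G,T
  std::vector<int> S = encode(seq);
  int n = (int)S.size() - w + 1;
  if (n < 1) return NumericVector(0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0; bool ok = true;
    for (int j = 0; j < w; ++j) {
      int c = S[i + j];
      if (c > 3) { ok = false; break; }
      s += lo(c, j);
    }
    out[i] = ok ? s : R_NegInf;
  }
  return out;
}
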