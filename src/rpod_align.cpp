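#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared encodings
// ---------------------------------------------------------------------------

// IUPAC code -> 4-bit mask over {A=1, C=2, G=4, T=8}; 0 for anything else.
static int iupac_mask_of(char c) {
  switch (toupper(c)) {
  case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
  case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
  case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
  case 'H': return 11; case 'V': return 7;  case 'N': return 15;
  default:  return 0;
  }
}

// Template base -> mask. Only unambiguous A/C/G/T bases get a bit; any
// ambiguity code (N etc.) in the template maps to 0 and therefore always
// counts as a mismatch against the primer.
static int base_mask_of(char c) {
  switch (toupper(c)) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  default:  return 0;
  }
}

static char comp_base(char c) {
  switch (toupper(c)) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
  case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
  case 'D': return 'H'; case 'H': return 'D';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// 2-bit base code, -1 for non-ACGT
static inline int code2(char c) {
  switch (toupper(c)) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Degenerate primer site scan
// ---------------------------------------------------------------------------
//
// Aligns the primer starting at every template offset with at most max_mm
// substitutions and at most max_ind single-base indels, counted separately.
// Insertions (extra template base) are internal only; deletion of a primer
// base is allowed at any primer position.  For each start offset the best
// within-budget alignment (fewest total edits, then end closest to the
// gapless end, then smallest end) is reported.

struct SiteHit { int start, end, mm, ind; };

static void scan_one_strand(const std::string& seq, const std::string& primer,
                            int max_mm, int max_ind, std::vector<SiteHit>& out) {
  const int L = (int) seq.size();
  const int n = (int) primer.size();
  std::vector<int> pmask(n);
  for (int i = 0; i < n; ++i) pmask[i] = iupac_mask_of(primer[i]);
  const int MM = max_mm + 1, IN = max_ind + 1;
  const int jmax = n + max_ind;        // template bases consumed
  // reachable[i][j][mm][ind]
  std::vector<char> reach((size_t)(n + 1) * (jmax + 1) * MM * IN);
  auto idx = [&](int i, int j, int mm, int in) {
    return (((size_t)i * (jmax + 1) + j) * MM + mm) * IN + in;
  };
  for (int p = 0; p < L; ++p) {
    std::fill(reach.begin(), reach.end(), 0);
    reach[idx(0, 0, 0, 0)] = 1;
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= jmax && p + j <= L; ++j) {
        for (int mm = 0; mm < MM; ++mm) for (int in = 0; in < IN; ++in) {
          if (!reach[idx(i, j, mm, in)]) continue;
          if (i < n && p + j < L) {                 // consume both
            bool ok = (pmask[i] & base_mask_of(seq[p + j])) != 0;
            if (ok) reach[idx(i + 1, j + 1, mm, in)] = 1;
            else if (mm + 1 < MM) reach[idx(i + 1, j + 1, mm + 1, in)] = 1;
          }
          if (i < n && in + 1 < IN)                 // primer base deleted
            reach[idx(i + 1, j, mm, in + 1)] = 1;
          if (i > 0 && i < n && p + j < L && in + 1 < IN) // internal template insertion
            reach[idx(i, j + 1, mm, in + 1)] = 1;
        }
      }
    }
    int best_tot = INT_MAX, best_j = -1, best_mm = 0, best_in = 0;
    for (int j = 0; j <= jmax && p + j <= L; ++j) {
      if (j == 0) continue;                          // zero-width match impossible
      for (int mm = 0; mm < MM; ++mm) for (int in = 0; in < IN; ++in) {
        if (!reach[idx(n, j, mm, in)]) continue;
        int tot = mm + in;
        int dev = std::abs(j - n), bdev = best_j < 0 ? INT_MAX : std::abs(best_j - n);
        if (tot < best_tot || (tot == best_tot && (dev < bdev ||
            (dev == bdev && j < best_j)))) {
          best_tot = tot; best_j = j; best_mm = mm; best_in = in;
        }
      }
    }
    if (best_j >= 0) out.push_back({p, p + best_j, best_mm, best_in});
  }
}

// [[Rcpp::export(name = ".cpp_scan_primer")]]
DataFrame cpp_scan_primer(std::string templ, std::string primer,
                          int max_mm, int max_ind, bool both_strands) {
  std::vector<SiteHit> fwd, rev;
  scan_one_strand(templ, primer, max_mm, max_ind, fwd);
  const int L = (int) templ.size();
  std::vector<int> start, end, mm, ind; std::vector<std::string> strand;
  for (auto& h : fwd) {
    start.push_back(h.start); end.push_back(h.end);
    mm.push_back(h.mm); ind.push_back(h.ind); strand.push_back("+");
  }
  if (both_strands) {
    std::string rc = revcomp_str(templ);
    scan_one_strand(rc, primer, max_mm, max_ind, rev);
    for (auto& h : rev) {   // map [h.start, h.end) on rc to forward coords
      start.push_back(L - h.end); end.push_back(L - h.start);
      mm.push_back(h.mm); ind.push_back(h.ind); strand.push_back("-");
    }
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["strand"] = strand, _["mismatches"] = mm,
                           _["indels"] = ind, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Unit-cost global alignment identity
// ---------------------------------------------------------------------------
// Minimises edit distance (substitution 1, gap 1), diagonal-preferring
// traceback; returns matches and alignment columns.

// [[Rcpp::export(name = ".cpp_global_identity")]]
NumericVector cpp_global_identity(std::string a, std::string b) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1)); // 0 diag, 1 up(del a), 2 left(ins)
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (toupper(a[i - 1]) == toupper(b[j - 1]) ? 0 : 1);
      int del = prev[j] + 1, ins = cur[j - 1] + 1;
      int best = sub; uint8_t t = 0;
      if (del < best) { best = del; t = 1; }
      if (ins < best) { best = ins; t = 2; }
      cur[j] = best; tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m; long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      if (toupper(a[i - 1]) == toupper(b[j - 1])) ++matches;
      --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) { --i; }
    else { --j; }
    ++cols;
  }
  return NumericVector::create((double) matches, (double) cols);
}

// ---------------------------------------------------------------------------
// Seeded banded local alignment of reads against a small reference set
// ---------------------------------------------------------------------------

struct RefIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > kmers; // kmer -> (ref, pos)
};

static void index_refs(const std::vector<std::string>& refs, int k, RefIndex& ix) {
  ix.k = k; ix.seqs = refs;
  for (int r = 0; r < (int) refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int) s.size() < k) continue;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int p = 0; p < (int) s.size(); ++p) {
      int c = code2(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (++run >= k) ix.kmers[key].push_back(std::make_pair(r, p - k + 1));
    }
  }
}

struct MateHit { int ref; double score; int start, end; }; // ref coords 0-based half-open

// Banded local alignment of read vs ref around diagonal d0 (ref = read + d).
static bool banded_sw(const std::string& read, const std::string& ref, int d0,
                      int band, double match, double mismatch, double gap_open,
                      double gap_ext, double& best, int& bstart, int& bend) {
  const int m = (int) read.size(), L = (int) ref.size();
  const int W = 2 * band + 1;
  const double NEG = -1e18;
  std::vector<double> Hp(W, 0), Hc(W, 0), Ep(W, NEG), Ec(W, NEG), Fc(W, NEG);
  std::vector<int> SHp(W, 0), SHc(W, 0), SEp(W, 0), SEc(W, 0), SFc(W, 0);
  // offset o corresponds to ref col j = i + d0 + (o - band), row i (1-based read)
  best = 0; bstart = -1; bend = -1;
  // initialise row 0: H = 0 with start at j
  for (int o = 0; o < W; ++o) { Hp[o] = 0; SHp[o] = d0 + (o - band); Ep[o] = NEG; }
  for (int i = 1; i <= m; ++i) {
    int cr = code2(read[i - 1]);
    for (int o = 0; o < W; ++o) {
      int j = i + d0 + (o - band);
      if (j < 1 || j > L) { Hc[o] = NEG; Ec[o] = NEG; Fc[o] = NEG; continue; }
      // E: gap in read (move along ref): from column j-1 same row -> offset o-1
      double e = NEG; int se = 0;
      if (o >= 1 && Hc[o - 1] > NEG/2) { e = Hc[o - 1] + gap_open; se = SHc[o - 1]; }
      if (o >= 1 && Ec[o - 1] > NEG/2 && Ec[o - 1] + gap_ext > e) { e = Ec[o - 1] + gap_ext; se = SEc[o - 1]; }
      // F: gap in ref (consume read base): from row i-1 same column -> offset o+1
      double f = NEG; int sf = 0;
      if (o + 1 < W && Hp[o + 1] > NEG/2) { f = Hp[o + 1] + gap_open; sf = SHp[o + 1]; }
      if (o + 1 < W && Fc[o + 1] > NEG/2) {
        // note: Fc still holds previous row's value at o+1 because we overwrite
        // left-to-right and F depends on o+1 (not yet overwritten this row)
        if (Fc[o + 1] + gap_ext > f) { f = Fc[o + 1] + gap_ext; sf = SFc[o + 1]; }
      }
      // H: diagonal from (i-1, j-1) -> previous row, same offset
      int cj = code2(ref[j - 1]);
      double sc = (cr >= 0 && cr == cj) ? match : mismatch;
      double h = 0; int sh = j - 1;            // fresh local start before column j
      if (Hp[o] > NEG/2 && Hp[o] + sc > h) { h = Hp[o] + sc; sh = SHp[o]; }
      if (e > h) { h = e; sh = se; }
      if (f > h) { h = f; sh = sf; }
      Hc[o] = h; SHc[o] = sh; Ec[o] = e; SEc[o] = se;
      double fprev = Fc[o + 1 < W ? o + 1 : o]; (void) fprev;
      Fc[o] = f; SFc[o] = sf;
      if (h > best) { best = h; bstart = sh; bend = j; }
    }
    std::swap(Hp, Hc); std::swap(SHp, SHc);
    std::swap(Ep, Ec); std::swap(SEp, SEc);
    std::fill(Ec.begin(), Ec.end(), NEG);
  }
  return bstart >= 0;
}

// Ungapped local alignment along a fixed diagonal (ref = read + d0):
// maximal-scoring segment by running-sum reset (exact equivalent of the
// banded DP when the optimal path has no gaps).
static bool diag_score(const std::string& read, const std::string& ref, int d0,
                       double match, double mismatch, double& best,
                       int& bstart, int& bend) {
  const int m = (int) read.size(), L = (int) ref.size();
  best = 0; bstart = -1; bend = -1;
  double run = 0; int run_start = -1;
  for (int i = 1; i <= m; ++i) {
    int j = i + d0;
    if (j < 1 || j > L) { run = 0; run_start = -1; continue; }
    int cr = code2(read[i - 1]), cj = code2(ref[j - 1]);
    double sc = (cr >= 0 && cr == cj) ? match : mismatch;
    if (run <= 0) { run = sc; run_start = j - 1; }
    else run += sc;
    if (run < 0) { run = 0; run_start = -1; }
    else if (run > best) { best = run; bstart = run_start; bend = j; }
  }
  return bstart >= 0;
}

// Per-mate scratch for seed voting, reset by epoch stamping.
struct VoteScratch {
  std::vector<int> stamp, tot, diag1, cnt1, diag2, cnt2;
  int epoch = 0;
  void ensure(size_t n) {
    if (stamp.size() < n) {
      stamp.assign(n, 0); tot.assign(n, 0);
      diag1.assign(n, 0); cnt1.assign(n, 0);
      diag2.assign(n, 0); cnt2.assign(n, 0);
    }
  }
};

// Collect per-reference best hit of one mate in one orientation.
static void mate_hits(const RefIndex& ix, const std::string& read, int band,
                      double floor_score, double match, double mismatch,
                      double gap_open, double gap_ext, int min_seed,
                      double cand_frac, int max_cand, VoteScratch& vs,
                      std::vector<MateHit>& out) {
  const int k = ix.k, m = (int) read.size();
  if (m < k) return;
  vs.ensure(ix.seqs.size());
  ++vs.epoch;
  std::vector<int> touched;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int p = 0; p < m; ++p) {
    int c = code2(read[p]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run < k) continue;
    auto it = ix.kmers.find(key);
    if (it == ix.kmers.end()) continue;
    int rpos = p - k + 1;
    for (auto& pr : it->second) {
      int r = pr.first, d = pr.second - rpos;
      if (vs.stamp[r] != vs.epoch) {
        vs.stamp[r] = vs.epoch; vs.tot[r] = 0;
        vs.cnt1[r] = 0; vs.cnt2[r] = 0;
        touched.push_back(r);
      }
      vs.tot[r]++;
      // keep counts for the two most-voted diagonals per reference
      if (vs.cnt1[r] > 0 && vs.diag1[r] == d) vs.cnt1[r]++;
      else if (vs.cnt2[r] > 0 && vs.diag2[r] == d) {
        if (++vs.cnt2[r] > vs.cnt1[r]) {
          std::swap(vs.diag1[r], vs.diag2[r]); std::swap(vs.cnt1[r], vs.cnt2[r]);
        }
      } else if (vs.cnt1[r] == 0) { vs.diag1[r] = d; vs.cnt1[r] = 1; }
      else if (vs.cnt2[r] == 0) { vs.diag2[r] = d; vs.cnt2[r] = 1; }
      // else: a third diagonal, dropped; the band absorbs small shifts
    }
  }
  // candidate selection: require min_seed total votes and a fixed fraction
  // of the best candidate's votes, keep at most max_cand references (by
  // descending votes, ties by reference order) — near neighbours with
  // substantial seed sharing survive, so the second-best concordant
  // reference used by the uniqueness score is retained
  int best_votes = 0;
  for (int r : touched) if (vs.tot[r] > best_votes) best_votes = vs.tot[r];
  int cut = std::max(min_seed, (int) std::ceil(cand_frac * best_votes));
  std::vector<std::pair<int,int> > keep; // (ref, votes)
  for (int r : touched) if (vs.tot[r] >= cut)
    keep.push_back(std::make_pair(r, vs.tot[r]));
  std::sort(keep.begin(), keep.end(), [](const std::pair<int,int>& a,
                                         const std::pair<int,int>& b) {
    if (a.second != b.second) return a.second > b.second;
    return a.first < b.first;
  });
  if ((int) keep.size() > max_cand) keep.resize(max_cand);
  std::vector<int> cand;
  for (auto& t : keep) cand.push_back(t.first);
  std::sort(cand.begin(), cand.end());   // deterministic order
  for (int r : cand) {
    int d0 = vs.diag1[r];
    double sc; int s, e;
    // fast path: ungapped scoring on the dominant diagonal; fall back to
    // the banded gapped DP when votes are split across diagonals (possible
    // indel) or the ungapped score is marginal
    bool clean = vs.cnt1[r] >= vs.tot[r] - 1;
    bool got = diag_score(read, ix.seqs[r], d0, match, mismatch, sc, s, e);
    if (!clean || !got || sc < floor_score) {
      double sc2; int s2, e2;
      if (banded_sw(read, ix.seqs[r], d0, band, match, mismatch, gap_open,
                    gap_ext, sc2, s2, e2) && sc2 > sc) {
        sc = sc2; s = s2; e = e2; got = true;
      }
    }
    if (got && sc >= floor_score) out.push_back({r, sc, s, e});
  }
}

// [[Rcpp::export(name = ".cpp_align_mate")]]
DataFrame cpp_align_mate(CharacterVector refs, std::string mate, int k, int band,
                         double floor_frac, double match, double mismatch,
                         double gap_open, double gap_ext, int min_seed,
                         double cand_frac, int max_cand,
                         bool both_orientations) {
  RefIndex ix;
  std::vector<std::string> rs(refs.size());
  for (int i = 0; i < refs.size(); ++i) rs[i] = as<std::string>(refs[i]);
  index_refs(rs, k, ix);
  double floor_score = floor_frac * match * (double) mate.size();
  std::vector<MateHit> hf, hr;
  VoteScratch vs;
  mate_hits(ix, mate, band, floor_score, match, mismatch, gap_open, gap_ext,
            min_seed, cand_frac, max_cand, vs, hf);
  if (both_orientations)
    mate_hits(ix, revcomp_str(mate), band, floor_score, match, mismatch,
              gap_open, gap_ext, min_seed, cand_frac, max_cand, vs, hr);
  std::vector<int> ref; std::vector<double> score; std::vector<int> st, en;
  std::vector<std::string> strand;
  for (auto& h : hf) { ref.push_back(h.ref + 1); score.push_back(h.score);
    st.push_back(h.start + 1); en.push_back(h.end); strand.push_back("+"); }
  for (auto& h : hr) { ref.push_back(h.ref + 1); score.push_back(h.score);
    st.push_back(h.start + 1); en.push_back(h.end); strand.push_back("-"); }
  return DataFrame::create(_["ref"] = ref, _["score"] = score,
                           _["start"] = st, _["end"] = en, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Classify a batch of pairs.  Status codes: 1 assigned-candidate (concordant,
// Q computed), 2 discordant (hits but no concordant reference), 3 no_hit.
// [[Rcpp::export(name = ".cpp_classify_pairs")]]
List cpp_classify_pairs(CharacterVector refs, CharacterVector r1, CharacterVector r2,
                        int k, int band, double floor_frac, double match,
                        double mismatch, double gap_open, double gap_ext,
                        int min_seed, double cand_frac, int max_cand,
                        double q_scale, double q_cap,
                        double frag_min, double frag_max) {
  RefIndex ix;
  std::vector<std::string> rs(refs.size());
  for (int i = 0; i < refs.size(); ++i) rs[i] = as<std::string>(refs[i]);
  index_refs(rs, k, ix);
  const int np = r1.size();
  VoteScratch vs;
  IntegerVector best_ref(np, NA_INTEGER), status(np), frag(np, NA_INTEGER);
  NumericVector qual(np, NA_REAL), score(np, NA_REAL);
  for (int p = 0; p < np; ++p) {
    std::string m1 = as<std::string>(r1[p]), m2 = as<std::string>(r2[p]);
    double fl1 = floor_frac * match * (double) m1.size();
    double fl2 = floor_frac * match * (double) m2.size();
    std::vector<MateHit> h1f, h1r, h2f, h2r;
    mate_hits(ix, m1, band, fl1, match, mismatch, gap_open, gap_ext, min_seed, cand_frac, max_cand, vs, h1f);
    mate_hits(ix, revcomp_str(m1), band, fl1, match, mismatch, gap_open, gap_ext, min_seed, cand_frac, max_cand, vs, h1r);
    mate_hits(ix, m2, band, fl2, match, mismatch, gap_open, gap_ext, min_seed, cand_frac, max_cand, vs, h2f);
    mate_hits(ix, revcomp_str(m2), band, fl2, match, mismatch, gap_open, gap_ext, min_seed, cand_frac, max_cand, vs, h2r);
    if (h1f.empty() && h1r.empty() && h2f.empty() && h2r.empty()) {
      status[p] = 3; continue;
    }
    // per-ref lookup tables
    auto by_ref = [](const std::vector<MateHit>& v) {
      std::unordered_map<int, MateHit> m;
      for (auto& h : v) { auto it = m.find(h.ref);
        if (it == m.end() || h.score > it->second.score) m[h.ref] = h; }
      return m;
    };
    auto t1f = by_ref(h1f), t1r = by_ref(h1r), t2f = by_ref(h2f), t2r = by_ref(h2r);
    // concordant: mate1 fwd + mate2 rev, or mate1 rev + mate2 fwd, same ref,
    // combined footprint span within fragment window
    std::vector<std::pair<int,double> > conc; // (ref, combined score)
    std::vector<int> cfrag;
    std::vector<int> refs_seen;
    for (auto& kv : t1f) refs_seen.push_back(kv.first);
    for (auto& kv : t1r) refs_seen.push_back(kv.first);
    std::sort(refs_seen.begin(), refs_seen.end());
    refs_seen.erase(std::unique(refs_seen.begin(), refs_seen.end()), refs_seen.end());
    for (int r : refs_seen) {
      double bestS = -1; int bestF = 0;
      // combo A: m1 forward, m2 reverse
      auto a1 = t1f.find(r); auto a2 = t2r.find(r);
      if (a1 != t1f.end() && a2 != t2r.end()) {
        int s = std::min(a1->second.start, a2->second.start);
        int e = std::max(a1->second.end, a2->second.end);
        int fr = e - s;
        if (fr >= frag_min && fr <= frag_max) {
          double S = a1->second.score + a2->second.score;
          if (S > bestS) { bestS = S; bestF = fr; }
        }
      }
      // combo B: m1 reverse, m2 forward
      auto b1 = t1r.find(r); auto b2 = t2f.find(r);
      if (b1 != t1r.end() && b2 != t2f.end()) {
        int s = std::min(b1->second.start, b2->second.start);
        int e = std::max(b1->second.end, b2->second.end);
        int fr = e - s;
        if (fr >= frag_min && fr <= frag_max) {
          double S = b1->second.score + b2->second.score;
          if (S > bestS) { bestS = S; bestF = fr; }
        }
      }
      if (bestS >= 0) { conc.push_back(std::make_pair(r, bestS)); cfrag.push_back(bestF); }
    }
    if (conc.empty()) { status[p] = 2; continue; }
    int ib = 0; double s1 = -1, s2 = -1;
    for (int i = 0; i < (int) conc.size(); ++i) {
      if (conc[i].second > s1) { s2 = s1; s1 = conc[i].second; ib = i; }
      else if (conc[i].second > s2) { s2 = conc[i].second; }
    }
    if (s2 < 0) s2 = fl1 + fl2;  // single concordant ref: second-best at floor
    double q = q_scale * (s1 - s2);
    if (q < 0) q = 0;
    if (q > q_cap) q = q_cap;
    status[p] = 1; best_ref[p] = conc[ib].first + 1;
    qual[p] = q; score[p] = s1; frag[p] = cfrag[ib];
  }
  return List::create(_["ref"] = best_ref, _["q"] = qual, _["score"] = score,
                      _["fragment"] = frag, _["status"] = status);
}
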