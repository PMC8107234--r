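// Alignment kernels: banded overlap alignment (linear-gap nucleotide and
// affine BLOSUM62 protein), fragment-based ANI with 16-mer seeding, seeded
// best-hit search for RBH-AAI, and greedy incremental orthogroup clustering.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline int nt_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// BLOSUM62 over the 24-letter alphabet ARNDCQEGHILKMFPSTWYVBZX* (NCBI layout).
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int BLOSUM62[24][24] = {
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
  for (int i = 0; i < 128; i++) aa_index_tab[i] = 22;  // unknown -> X
  for (int i = 0; i < 24; i++) aa_index_tab[(int)AA_ORDER[i]] = i;
  aa_tab_init = true;
}

static inline int subst_score(char a, char b, bool dna) {
  if (dna) return (a == b && a != 'N') ? 1 : -1;
  return BLOSUM62[aa_index_tab[(int)(unsigned char)a]][aa_index_tab[(int)(unsigned char)b]];
}

static inline bool is_match(char a, char b, bool dna) {
  if (a != b) return false;
  return dna ? (a != 'N') : (a != 'X');
}

struct AlnResult {
  int score, matches, columns;
  int a0, a1, b0, b1;   // 0-based half-open aligned spans
  bool ok;
};

// Overlap (free-end-gap) alignment of a vs b restricted to the band
// |j - i - center| <= band.  Affine gaps: opening costs open+ext, each
// further column ext.  Linear gaps are open=0.  Identity statistics are
// collected by traceback over the aligned region (terminal free gaps
// excluded; internal gap columns included).
static AlnResult band_align(const std::string& a, const std::string& b,
                            int center, int band, bool dna,
                            int gap_open, int gap_ext) {
  init_aa_tab();
  AlnResult res; res.ok = false;
  res.score = NEG_INF; res.matches = 0; res.columns = 0;
  res.a0 = res.a1 = res.b0 = res.b1 = 0;
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return res;
  const int W = 2 * band + 1;
  static std::vector<int> Mv, Xv, Yv;
  static std::vector<uint8_t> Mp, Xp, Yp;
  size_t need = (size_t)(m + 1) * W;
  if (Mv.size() < need) {
    Mv.resize(need); Xv.resize(need); Yv.resize(need);
    Mp.resize(need); Xp.resize(need); Yp.resize(need);
  }
  const int go = gap_open + gap_ext;  // cost of first gap column
  // tags: 0=M, 1=X, 2=Y, 3=start
  auto idx = [&](int i, int jj) { return (size_t)i * W + jj; };
  auto jlo = [&](int i) { return std::max(0, i + center - band); };
  auto jhi = [&](int i) { return std::min(n, i + center + band); };

  // row 0 is implicit (start boundary B = 0 when i==0 or j==0)
  for (int jj = 0; jj < W; jj++) {
    Mv[idx(0, jj)] = NEG_INF; Xv[idx(0, jj)] = NEG_INF; Yv[idx(0, jj)] = NEG_INF;
  }
  int best = NEG_INF, best_i = -1, best_j = -1, best_state = -1;
  for (int i = 1; i <= m; i++) {
    int lo = jlo(i), hi = jhi(i);
    if (lo > hi) continue;
    for (int jj = 0; jj < W; jj++) {
      Mv[idx(i, jj)] = NEG_INF; Xv[idx(i, jj)] = NEG_INF; Yv[idx(i, jj)] = NEG_INF;
    }
    for (int j = lo; j <= hi; j++) {
      int jj = j - (i + center - band);
      // --- M: consume a[i-1], b[j-1]
      if (j >= 1) {
        int pj = j - 1;
        int v = NEG_INF; uint8_t t = 3;
        int plo = jlo(i - 1), phi = jhi(i - 1);
        if (pj >= plo && pj <= phi && i - 1 >= 1) {
          int pjj = pj - ((i - 1) + center - band);
          size_t pi = idx(i - 1, pjj);
          if (Mv[pi] > v) { v = Mv[pi]; t = 0; }
          if (Xv[pi] > v) { v = Xv[pi]; t = 1; }
          if (Yv[pi] > v) { v = Yv[pi]; t = 2; }
        }
        if ((i - 1 == 0 || pj == 0) && 0 > v) { v = 0; t = 3; }
        if (v > NEG_INF / 2) {
          Mv[idx(i, jj)] = v + subst_score(a[i - 1], b[j - 1], dna);
          Mp[idx(i, jj)] = t;
        }
      }
      // --- X: consume a[i-1], gap in b (predecessor (i-1, j))
      {
        int plo = jlo(i - 1), phi = jhi(i - 1);
        int v = NEG_INF; uint8_t t = 3;
        if (j >= plo && j <= phi && i - 1 >= 1 && j >= 1) {
          int pjj = j - ((i - 1) + center - band);
          size_t pi = idx(i - 1, pjj);
          if (Mv[pi] - go > v) { v = Mv[pi] - go; t = 0; }
          if (Xv[pi] - gap_ext > v) { v = Xv[pi] - gap_ext; t = 1; }
          if (Yv[pi] - go > v) { v = Yv[pi] - go; t = 2; }
        }
        // starting with a gap from the boundary is never better than
        // starting later under free ends; omit B here.
        if (v > NEG_INF / 2) { Xv[idx(i, jj)] = v; Xp[idx(i, jj)] = t; }
      }
      // --- Y: consume b[j-1], gap in a (predecessor (i, j-1))
      if (j >= 1) {
        int pj = j - 1;
        int lo_i = jlo(i), hi_i = jhi(i);
        int v = NEG_INF; uint8_t t = 3;
        if (pj >= lo_i && pj <= hi_i) {
          int pjj = pj - (i + center - band);
          size_t pi = idx(i, pjj);
          if (Mv[pi] - go > v) { v = Mv[pi] - go; t = 0; }
          if (Yv[pi] - gap_ext > v) { v = Yv[pi] - gap_ext; t = 1; } // tag1 = Y here
          if (Xv[pi] - go > v) { v = Xv[pi] - go; t = 2; }           // tag2 = X here
        }
        if (v > NEG_INF / 2) { Yv[idx(i, jj)] = v; Yp[idx(i, jj)] = t; }
      }
      // end states: free trailing gaps -> best over last row / last column
      if (i == m || j == n) {
        size_t ci = idx(i, jj);
        if (Mv[ci] > best) { best = Mv[ci]; best_i = i; best_j = j; best_state = 0; }
        if (Xv[ci] > best) { best = Xv[ci]; best_i = i; best_j = j; best_state = 1; }
        if (Yv[ci] > best) { best = Yv[ci]; best_i = i; best_j = j; best_state = 2; }
      }
    }
  }
  if (best_i < 0) return res;
  // traceback
  int i = best_i, j = best_j, state = best_state;
  res.a1 = i; res.b1 = j;
  int matches = 0, columns = 0;
  while (true) {
    int jj = j - (i + center - band);
    size_t ci = idx(i, jj);
    if (state == 0) {
      columns++;
      if (is_match(a[i - 1], b[j - 1], dna)) matches++;
      uint8_t t = Mp[ci];
      i--; j--;
      if (t == 3) break;
      state = t;
    } else if (state == 1) {  // X: a vs gap
      columns++;
      uint8_t t = Xp[ci];
      i--;
      if (t == 3) break;
      state = t;
    } else {  // Y: gap vs b
      columns++;
      uint8_t t = Yp[ci];
      j--;
      if (t == 3) break;
      state = (t == 0) ? 0 : (t == 1 ? 2 : 1);  // undo local tag remap
    }
  }
  res.a0 = i; res.b0 = j;
  res.score = best; res.matches = matches; res.columns = columns;
  res.ok = true;
  return res;
}

static AlnResult overlap_align_auto(const std::string& a, const std::string& b,
                                    bool dna, int band_extra) {
  int m = (int)a.size(), n = (int)b.size();
  int center = (n - m) / 2;
  int band;
  if (band_extra < 0) {  // effectively unbanded
    band = (m + n) / 2 + 1;
  } else {
    band = std::abs(n - m) / 2 + band_extra + 1;
  }
  int gap_open = dna ? 0 : 11;
  int gap_ext = dna ? 2 : 1;
  return band_align(a, b, center, band, dna, gap_open, gap_ext);
}

// [[Rcpp::export]]
NumericVector cpp_align_pair(std::string a, std::string b, bool dna, int band_extra) {
  AlnResult r = overlap_align_auto(a, b, dna, band_extra);
  NumericVector out = NumericVector::create(
    _["score"] = r.ok ? r.score : NA_REAL,
    _["matches"] = r.matches, _["columns"] = r.columns,
    _["a_start"] = r.a0, _["a_end"] = r.a1,
    _["b_start"] = r.b0, _["b_end"] = r.b1);
  return out;
}

// Specialized banded overlap aligner for nucleotide fragments: linear gap
// (match +1 / mismatch -1 / gap -2), single DP matrix, 2-bit traceback.
// Identical contract to band_align but ~5x faster; used by the ANI kernel.
static AlnResult band_align_nt_linear(const std::string& a, const std::string& b,
                                      int center, int band) {
  AlnResult res; res.ok = false;
  res.score = NEG_INF; res.matches = 0; res.columns = 0;
  res.a0 = res.a1 = res.b0 = res.b1 = 0;
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return res;
  const int W = 2 * band + 1;
  static std::vector<int> prev_row, cur_row;
  static std::vector<uint8_t> ptr;          // 0=diag,1=up,2=left,3=start
  if ((int)prev_row.size() < W + 2) { prev_row.resize(W + 2); cur_row.resize(W + 2); }
  if (ptr.size() < (size_t)(m + 1) * W) ptr.resize((size_t)(m + 1) * W);
  int best = NEG_INF, best_i = -1, best_j = -1;
  for (int jj = 0; jj < W; jj++) prev_row[jj] = NEG_INF;
  for (int i = 1; i <= m; i++) {
    const int lo = std::max(0, i + center - band);
    const int hi = std::min(n, i + center + band);
    const int base = i + center - band;       // j of storage slot 0
    const int pbase = base - 1;               // previous row's slot-0 j
    for (int jj = 0; jj < W; jj++) cur_row[jj] = NEG_INF;
    if (lo > hi) { std::swap(prev_row, cur_row); continue; }
    const char ai = a[i - 1];
    uint8_t* prow = &ptr[(size_t)i * W];
    for (int j = lo; j <= hi; j++) {
      const int jj = j - base;
      int v = NEG_INF; uint8_t t = 3;
      if (j >= 1) {
        // diagonal predecessor (i-1, j-1): slot (j-1) - pbase = jj
        int pv = (i - 1 >= 1) ? prev_row[jj] : NEG_INF;
        if (i - 1 == 0 || j - 1 == 0) pv = std::max(pv, 0);
        if (pv > NEG_INF / 2) {
          int sc = pv + ((ai == b[j - 1] && ai != 'N') ? 1 : -1);
          if (sc > v) { v = sc; t = 0; }
        }
      }
      // up predecessor (i-1, j): slot j - pbase = jj + 1
      if (jj + 1 < W && i - 1 >= 1 && j >= 1) {
        int pv = prev_row[jj + 1];
        if (pv > NEG_INF / 2 && pv - 2 > v) { v = pv - 2; t = 1; }
      }
      // left predecessor (i, j-1): slot jj - 1
      if (jj - 1 >= 0 && j - 1 >= 1) {
        int pv = cur_row[jj - 1];
        if (pv > NEG_INF / 2 && pv - 2 > v) { v = pv - 2; t = 2; }
      }
      cur_row[jj] = v; prow[jj] = t;
      if ((i == m || j == n) && v > best) { best = v; best_i = i; best_j = j; }
    }
    std::swap(prev_row, cur_row);
  }
  if (best_i < 0) return res;
  int i = best_i, j = best_j;
  res.a1 = i; res.b1 = j;
  int matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    int jj = j - (i + center - band);
    uint8_t t = ptr[(size_t)i * W + jj];
    if (t == 0) {
      columns++;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') matches++;
      i--; j--;
      if (i == 0 || j == 0) break;
    } else if (t == 1) { columns++; i--; if (i == 0) break; }
    else if (t == 2) { columns++; j--; if (j == 0) break; }
    else break;
  }
  res.a0 = i; res.b0 = j;
  res.score = best; res.matches = matches; res.columns = columns;
  res.ok = true;
  return res;
}

// Order-3 Markov chain sampler over bases 1..4 given the 64 x 4 cumulative
// transition matrix (rows indexed by 16*(b1-1)+4*(b2-1)+(b3-1)).
// [[Rcpp::export]]
IntegerVector cpp_markov_seq(NumericMatrix cum_p, int L) {
  IntegerVector s(L);
  for (int i = 0; i < 3 && i < L; i++)
    s[i] = std::min(3, (int)(unif_rand() * 4.0)) + 1;
  if (L <= 3) return s;
  int ctx = (s[0] - 1) * 16 + (s[1] - 1) * 4 + (s[2] - 1);
  for (int i = 3; i < L; i++) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cum_p(ctx, b)) b++;
    s[i] = b + 1;
    ctx = (ctx % 16) * 4 + b;
  }
  return s;
}

// ---------------------------------------------------------------- ANI ----

typedef std::unordered_map<uint64_t, std::vector<int> > NtIndex;

static void index_nt_kmers(const std::string& s, int k, NtIndex& idx) {
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (size_t i = 0; i < s.size(); i++) {
    int c = nt_code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    run++;
    if (run >= k) idx[h].push_back((int)(i - k + 1));
  }
}

// One direction of fragment-based ANI: query contigs are cut into
// consecutive frag_len fragments (a trailing piece >= frag_len/2 is kept),
// each fragment is placed on the reference by the most-voted shared-k-mer
// diagonal and aligned in a band; fragments with identity >= min_id over
// >= min_frac of their length are retained.
// [[Rcpp::export]]
List cpp_ani_directional(CharacterVector query_contigs, CharacterVector ref_contigs,
                         int frag_len = 1020, int k = 16, int band = 64,
                         double min_id = 0.3, double min_frac = 0.7,
                         int max_kmer_hits = 64, int min_seed_votes = 2) {
  std::string ref;
  for (int i = 0; i < ref_contigs.size(); i++) {
    if (i > 0) ref.append((size_t)k, 'N');
    ref.append(as<std::string>(ref_contigs[i]));
  }
  NtIndex idx;
  index_nt_kmers(ref, k, idx);
  double sum_id = 0.0;
  int n_kept = 0, n_frags = 0;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ci = 0; ci < query_contigs.size(); ci++) {
    std::string contig = as<std::string>(query_contigs[ci]);
    int L = (int)contig.size();
    for (int s = 0; s + frag_len / 2 <= L; s += frag_len) {
      int flen = std::min(frag_len, L - s);
      if (flen < frag_len / 2) break;
      n_frags++;
      std::string frag = contig.substr(s, flen);
      // diagonal votes with anchor extent (votes, min qpos, max qpos)
      std::unordered_map<int, std::array<int, 3> > votes;
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < flen; i++) {
        int c = nt_code(frag[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        run++;
        if (run >= k) {
          NtIndex::const_iterator it = idx.find(h);
          if (it != idx.end() && (int)it->second.size() <= max_kmer_hits) {
            int qpos = i - k + 1;
            for (size_t u = 0; u < it->second.size(); u++) {
              int d = it->second[u] - qpos;
              std::unordered_map<int, std::array<int, 3> >::iterator v = votes.find(d);
              if (v == votes.end()) {
                std::array<int, 3> rec = {1, qpos, qpos};
                votes[d] = rec;
              } else {
                v->second[0]++;
                if (qpos < v->second[1]) v->second[1] = qpos;
                if (qpos > v->second[2]) v->second[2] = qpos;
              }
            }
          }
        }
      }
      if (votes.empty()) continue;
      int best_d = 0, best_v = -1, best_span = 0;
      for (std::unordered_map<int, std::array<int, 3> >::iterator it = votes.begin();
           it != votes.end(); ++it) {
        if (it->second[0] > best_v || (it->second[0] == best_v && it->first < best_d)) {
          best_v = it->second[0]; best_d = it->first;
          best_span = it->second[2] - it->second[1] + k;
        }
      }
      // a placement needs anchors spread along the fragment; one isolated
      // chance repeat shared between unrelated sequences is not homology
      if (best_v < min_seed_votes || best_span < flen / 4) continue;
      int wstart = std::max(0, best_d - band);
      int wend = std::min((int)ref.size(), best_d + flen + band);
      if (wend <= wstart) continue;
      std::string win = ref.substr(wstart, wend - wstart);
      int center = best_d - wstart;
      AlnResult r = band_align_nt_linear(frag, win, center, band);
      if (!r.ok || r.columns == 0) continue;
      double id = (double)r.matches / (double)r.columns;
      double cov = (double)(r.a1 - r.a0) / (double)flen;
      if (id >= min_id && cov >= min_frac) {
        sum_id += id;
        n_kept++;
      }
    }
  }
  return List::create(_["sum_identity"] = sum_id, _["n_retained"] = n_kept,
                      _["n_fragments"] = n_frags);
}

// ------------------------------------------------------------- protein ----

typedef std::unordered_map<uint32_t, std::vector<int> > AaIndex;

static bool aa_kmer_at(const std::string& s, int pos, int k, uint32_t& out) {
  uint32_t h = 0;
  for (int i = 0; i < k; i++) {
    char c = s[pos + i];
    if (c < 'A' || c > 'Z' || c == 'X') return false;
    h = h * 26u + (uint32_t)(c - 'A');
  }
  out = h;
  return true;
}

static void index_aa_kmers(const std::string& s, int k, int id, AaIndex& idx) {
  if ((int)s.size() < k) return;
  for (int i = 0; i + k <= (int)s.size(); i++) {
    uint32_t h;
    if (aa_kmer_at(s, i, k, h)) {
      std::vector<int>& v = idx[h];
      if (v.empty() || v.back() != id) v.push_back(id);
    }
  }
}

static void vote_targets(const std::string& q, int k, const AaIndex& idx,
                         std::unordered_map<int, int>& votes) {
  if ((int)q.size() < k) return;
  for (int i = 0; i + k <= (int)q.size(); i++) {
    uint32_t h;
    if (!aa_kmer_at(q, i, k, h)) continue;
    AaIndex::const_iterator it = idx.find(h);
    if (it == idx.end()) continue;
    for (size_t u = 0; u < it->second.size(); u++) votes[it->second[u]]++;
  }
}

// Best seeded hit per query against a target set; identity over aligned
// columns, coverage relative to the shorter sequence.  Returns 1-based best
// target index (0 = none) and its identity.
// [[Rcpp::export]]
List cpp_best_hits(CharacterVector queries, CharacterVector targets,
                   int k = 5, double min_id = 0.3, double min_cov = 0.7,
                   int max_candidates = 8, int band_extra = 48,
                   int min_votes = 2, double vote_frac = 0.2) {
  int nq = queries.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  AaIndex idx;
  for (int t = 0; t < nt; t++) {
    tg[t] = as<std::string>(targets[t]);
    index_aa_kmers(tg[t], k, t, idx);
  }
  IntegerVector best_idx(nq, 0);
  NumericVector best_id(nq, NA_REAL);
  for (int q = 0; q < nq; q++) {
    std::string qs = as<std::string>(queries[q]);
    std::unordered_map<int, int> votes;
    vote_targets(qs, k, idx, votes);
    if (votes.empty()) continue;
    std::vector<std::pair<int, int> > cand;  // (-votes, id) for stable sort
    cand.reserve(votes.size());
    for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
      cand.push_back(std::make_pair(-it->second, it->first));
    std::sort(cand.begin(), cand.end());
    int ncand = std::min((int)cand.size(), max_candidates);
    // seed-vote filter: candidates well below the best-supported one are
    // almost never the best alignment and are skipped
    double cut = std::max((double)min_votes, vote_frac * (double)(-cand[0].first));
    double bid = -1.0; int bt = -1;
    for (int c = 0; c < ncand; c++) {
      if ((double)(-cand[c].first) < cut) break;
      int t = cand[c].second;
      AlnResult r = overlap_align_auto(qs, tg[t], false, band_extra);
      if (!r.ok || r.columns == 0) continue;
      double id = (double)r.matches / (double)r.columns;
      int shorter = std::min((int)qs.size(), (int)tg[t].size());
      int span = ((int)qs.size() <= (int)tg[t].size()) ? (r.a1 - r.a0) : (r.b1 - r.b0);
      double cov = (double)span / (double)shorter;
      if (id >= min_id && cov >= min_cov && (id > bid || (id == bid && t < bt))) {
        bid = id; bt = t;
      }
    }
    if (bt >= 0) { best_idx[q] = bt + 1; best_id[q] = bid; }
  }
  return List::create(_["target"] = best_idx, _["identity"] = best_id);
}

// Greedy incremental clustering: sequences are visited in the given order
// (caller sorts by length descending, then ID); each joins the
// earliest-founded cluster whose representative it matches at
// >= min_id over >= min_cov of the shorter sequence, else founds a cluster.
// Returns 1-based cluster ids in founding order.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, int k = 5,
                                 double min_id = 0.8, double min_cov = 0.8,
                                 int band_extra = 48, int min_votes = 2,
                                 double vote_frac = 0.1) {
  int n = seqs.size();
  IntegerVector assign(n, 0);
  std::vector<std::string> reps;
  AaIndex idx;
  int n_clusters = 0;
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    std::unordered_map<int, int> votes;
    vote_targets(s, k, idx, votes);
    int best_v = 0;
    for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
      if (it->second > best_v) best_v = it->second;
    double cut = std::max((double)min_votes, vote_frac * (double)best_v);
    std::vector<int> cand;
    cand.reserve(votes.size());
    for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
      if ((double)it->second >= cut) cand.push_back(it->first);
    std::sort(cand.begin(), cand.end());  // founding order
    int joined = 0;
    for (size_t c = 0; c < cand.size(); c++) {
      const std::string& rep = reps[cand[c]];
      AlnResult r = overlap_align_auto(s, rep, false, band_extra);
      if (!r.ok || r.columns == 0) continue;
      double id = (double)r.matches / (double)r.columns;
      int shorter = std::min((int)s.size(), (int)rep.size());
      int span = ((int)s.size() <= (int)rep.size()) ? (r.a1 - r.a0) : (r.b1 - r.b0);
      double cov = (double)span / (double)shorter;
      if (id >= min_id && cov >= min_cov) { joined = cand[c] + 1; break; }
    }
    if (joined == 0) {
      reps.push_back(s);
      index_aa_kmers(s, k, n_clusters, idx);
      n_clusters++;
      joined = n_clusters;
    }
    assign[i] = joined;
  }
  return assign;
}
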