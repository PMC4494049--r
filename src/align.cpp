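// Seeded banded local alignment (Smith-Waterman/Gotoh) and a pattern-global
// "fit" aligner. Sequences arrive as 0-based integer codes; scoring is an
// integer matrix. A gap of length g costs gap_open + g * gap_extend.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Aln {
  bool found;
  int score;
  int a_start, a_end, b_start, b_end; // 1-based inclusive
  int matches, cols, mismatches, gap_opens;
  std::vector<int> apos, bpos;        // per-column positions, 0 = gap
  Aln() : found(false), score(0), a_start(0), a_end(0), b_start(0), b_end(0),
          matches(0), cols(0), mismatches(0), gap_opens(0) {}
};

static void count_gap_opens(Aln &r) {
  int g = 0;
  for (size_t t = 0; t < r.apos.size(); ++t) {
    if (r.apos[t] == 0 && (t == 0 || r.apos[t - 1] != 0)) ++g;
    if (r.bpos[t] == 0 && (t == 0 || r.bpos[t - 1] != 0)) ++g;
  }
  r.gap_opens = g;
}

// Local alignment restricted to the diagonal band dlo <= j - i <= dhi
// (DP indices i = 1..m over a, j = 1..n over b).
static Aln band_local(const std::vector<int> &a, const std::vector<int> &b,
                      const IntegerMatrix &smat, int go, int ge,
                      int dlo, int dhi, bool want_path) {
  Aln res;
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return res;
  if (dlo < 1 - m) dlo = 1 - m;
  if (dhi > n - 1) dhi = n - 1;
  if (dlo > dhi) return res;
  int w = dhi - dlo + 1;
  size_t sz = (size_t)(m + 1) * (size_t)w;
  std::vector<int> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  std::vector<unsigned char> tH(sz, 0), tE(sz, 0), tF(sz, 0);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
    size_t row = (size_t)i * w, prow = (size_t)(i - 1) * w;
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i - dlo;
      size_t idx = row + k;
      int e = NEG; unsigned char te = 0;
      if (k - 1 >= 0 && j - 1 >= 1) {
        size_t p = row + (k - 1);
        int fh = (H[p] == NEG) ? NEG : H[p] - go - ge;
        int fe = (E[p] == NEG) ? NEG : E[p] - ge;
        if (fh >= fe) { e = fh; te = 1; } else { e = fe; te = 0; }
      }
      int f = NEG; unsigned char tf = 0;
      if (k + 1 < w && i - 1 >= 1) {
        size_t p = prow + (k + 1);
        int fh = (H[p] == NEG) ? NEG : H[p] - go - ge;
        int ff = (F[p] == NEG) ? NEG : F[p] - ge;
        if (fh >= ff) { f = fh; tf = 1; } else { f = ff; tf = 0; }
      }
      int hd = (i == 1 || j == 1) ? 0 : H[prow + k];
      int diag = (hd == NEG) ? NEG : hd + smat(a[i - 1], b[j - 1]);
      int h = 0; unsigned char th = 0;
      if (diag > h) { h = diag; th = 1; }
      if (e > h)    { h = e;    th = 2; }
      if (f > h)    { h = f;    th = 3; }
      H[idx] = h; E[idx] = e; F[idx] = f;
      tH[idx] = th; tE[idx] = te; tF[idx] = tf;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;

  res.found = true;
  res.score = best;
  res.a_end = bi; res.b_end = bj;
  std::vector<int> ap, bp;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    size_t idx = (size_t)i * w + (j - i - dlo);
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 0) break;
      if (t == 1) {
        ap.push_back(i); bp.push_back(j);
        if (a[i - 1] == b[j - 1]) res.matches++; else res.mismatches++;
        --i; --j;
        if (i == 0 || j == 0) break;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tE[idx];
      ap.push_back(0); bp.push_back(j);
      --j;
      state = (t == 1) ? 0 : 1;
      if (j == 0) break;
    } else {
      unsigned char t = tF[idx];
      ap.push_back(i); bp.push_back(0);
      --i;
      state = (t == 1) ? 0 : 2;
      if (i == 0) break;
    }
  }
  res.a_start = i + 1;
  res.b_start = j + 1;
  std::reverse(ap.begin(), ap.end());
  std::reverse(bp.begin(), bp.end());
  res.cols = (int)ap.size();
  res.apos = ap; res.bpos = bp;
  count_gap_opens(res);
  if (!want_path) { res.apos.clear(); res.bpos.clear(); }
  return res;
}

static std::vector<int> as_vec(const IntegerVector &x) {
  return std::vector<int>(x.begin(), x.end());
}

static List aln_to_list(const Aln &r, bool path) {
  if (!r.found) return List::create(Named("found") = false);
  List out = List::create(
    Named("found") = true,
    Named("score") = r.score,
    Named("a_start") = r.a_start, Named("a_end") = r.a_end,
    Named("b_start") = r.b_start, Named("b_end") = r.b_end,
    Named("matches") = r.matches, Named("cols") = r.cols,
    Named("mismatches") = r.mismatches, Named("gap_opens") = r.gap_opens);
  if (path) {
    out["apos"] = IntegerVector(r.apos.begin(), r.apos.end());
    out["bpos"] = IntegerVector(r.bpos.begin(), r.bpos.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_banded(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                      int gap_open, int gap_extend, int dlo, int dhi,
                      bool path) {
  Aln r = band_local(as_vec(a), as_vec(b), smat, gap_open, gap_extend,
                     dlo, dhi, path);
  return aln_to_list(r, path);
}

// Version-stamped flat word index reused across calls (single-threaded R):
// avoids rebuilding a hash table for every query/subject pair.
struct SeedIndex {
  std::vector<int> head, version;
  std::vector<std::pair<int, int> > entries; // (position, next)
  int cur;
  SeedIndex() : cur(0) {}
};
static SeedIndex g_idx;

// Exact-word seeds between a and b; words containing codes >= seed_alpha
// never seed. Returns (diagonal = j0 - i0, subject position j0) pairs,
// sorted by diagonal then position (0-based).
static std::vector<std::pair<int, int> > seed_positions(
    const std::vector<int> &a, const std::vector<int> &b,
    int word, int seed_alpha) {
  std::vector<std::pair<int, int> > seeds;
  int m = (int)a.size(), n = (int)b.size();
  if (m < word || n < word) return seeds;
  long long K = 1;
  for (int t = 0; t < word; ++t) {
    K *= seed_alpha;
    if (K > (1LL << 26)) break;
  }
  long long mod = 1;
  for (int t = 0; t < word - 1; ++t) mod *= seed_alpha;

  if (K <= (1LL << 26)) {
    if ((long long)g_idx.head.size() < K) {
      g_idx.head.resize((size_t)K);
      g_idx.version.assign((size_t)K, 0);
      g_idx.cur = 0;
    }
    ++g_idx.cur;
    if (g_idx.cur == INT_MAX) {
      std::fill(g_idx.version.begin(), g_idx.version.end(), 0);
      g_idx.cur = 1;
    }
    int cur = g_idx.cur;
    g_idx.entries.clear();
    long long key = 0;
    int bad = 0;
    for (int i = 0; i < m; ++i) {
      if (a[i] >= seed_alpha) bad = word;
      else if (bad > 0) --bad;
      key = (i >= word) ? (key - a[i - word] * mod) * seed_alpha + a[i]
                        : key * seed_alpha + a[i];
      if (i >= word - 1 && bad == 0) {
        if (g_idx.version[key] != cur) {
          g_idx.version[key] = cur;
          g_idx.head[key] = -1;
        }
        g_idx.entries.push_back(std::make_pair(i - word + 1,
                                               g_idx.head[key]));
        g_idx.head[key] = (int)g_idx.entries.size() - 1;
      }
    }
    key = 0; bad = 0;
    for (int j = 0; j < n; ++j) {
      if (b[j] >= seed_alpha) bad = word;
      else if (bad > 0) --bad;
      key = (j >= word) ? (key - b[j - word] * mod) * seed_alpha + b[j]
                        : key * seed_alpha + b[j];
      if (j >= word - 1 && bad == 0 && g_idx.version[key] == cur) {
        int j0 = j - word + 1;
        for (int e = g_idx.head[key]; e != -1; e = g_idx.entries[e].second)
          seeds.push_back(std::make_pair(j0 - g_idx.entries[e].first, j0));
      }
    }
  } else {
    std::unordered_map<long long, std::vector<int> > index;
    long long key = 0;
    int bad = 0;
    for (int i = 0; i < m; ++i) {
      if (a[i] >= seed_alpha) bad = word;
      else if (bad > 0) --bad;
      key = (i >= word) ? (key - a[i - word] * mod) * seed_alpha + a[i]
                        : key * seed_alpha + a[i];
      if (i >= word - 1 && bad == 0) index[key].push_back(i - word + 1);
    }
    key = 0; bad = 0;
    for (int j = 0; j < n; ++j) {
      if (b[j] >= seed_alpha) bad = word;
      else if (bad > 0) --bad;
      key = (j >= word) ? (key - b[j - word] * mod) * seed_alpha + b[j]
                        : key * seed_alpha + b[j];
      if (j >= word - 1 && bad == 0) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          index.find(key);
        if (it != index.end()) {
          int j0 = j - word + 1;
          for (size_t t = 0; t < it->second.size(); ++t)
            seeds.push_back(std::make_pair(j0 - it->second[t], j0));
        }
      }
    }
  }
  std::sort(seeds.begin(), seeds.end());
  return seeds;
}

// Ungapped X-drop extension of a seed along its diagonal; returns the
// best ungapped score and (via hw) the rightmost subject position
// reached, used as a per-diagonal high-water mark.
static int ungapped_extend(const std::vector<int> &a,
                           const std::vector<int> &b,
                           const IntegerMatrix &smat,
                           int i0, int j0, int word, int xdrop, int *hw) {
  int m = (int)a.size(), n = (int)b.size();
  int score = 0;
  for (int t = 0; t < word; ++t) score += smat(a[i0 + t], b[j0 + t]);
  int best = score;
  int i = i0 + word, j = j0 + word, jbest = j0 + word - 1;
  while (i < m && j < n) {
    score += smat(a[i], b[j]);
    if (score > best) { best = score; jbest = j; }
    if (score < best - xdrop) break;
    ++i; ++j;
  }
  *hw = jbest;
  score = best;
  i = i0 - 1; j = j0 - 1;
  while (i >= 0 && j >= 0) {
    score += smat(a[i], b[j]);
    if (score > best) best = score;
    if (score < best - xdrop) break;
    --i; --j;
  }
  return best;
}

// Best seeded banded local alignment between one pair of sequences.
// Seed diagonals closer than 2*band_margin are merged into one band;
// a band is extended only when some single diagonal in it carries at
// least min_seed_count seeds (a BLAST-style two-hit heuristic; pass 1
// to disable).
static Aln search_pair(const std::vector<int> &a, const std::vector<int> &b,
                       const IntegerMatrix &smat, int go, int ge, int word,
                       int seed_alpha, int band_margin, int min_seed_count,
                       int ungapped_gate, int xdrop, bool want_path) {
  Aln best;
  std::vector<std::pair<int, int> > seeds =
      seed_positions(a, b, word, seed_alpha);
  if (seeds.empty()) return best;
  size_t t0 = 0;
  for (size_t t = 1; t <= seeds.size(); ++t) {
    if (t == seeds.size() ||
        seeds[t].first - seeds[t - 1].first > 2 * band_margin) {
      // two-hit rule: some single diagonal carries >= min_seed_count seeds
      int run = 1, maxrun = 1;
      for (size_t u = t0 + 1; u < t; ++u) {
        run = (seeds[u].first == seeds[u - 1].first) ? run + 1 : 1;
        if (run > maxrun) maxrun = run;
      }
      bool qualify = maxrun >= min_seed_count;
      if (qualify && ungapped_gate >= 0) {
        // gate on the best ungapped seed extension within the cluster;
        // a per-diagonal high-water mark avoids re-extending overlapping
        // seeds of one exact run
        int best_ung = 0, hw = -1, cur_diag = seeds[t0].first - 1;
        for (size_t u = t0; u < t; ++u) {
          if (seeds[u].first != cur_diag) { cur_diag = seeds[u].first; hw = -1; }
          if (seeds[u].second <= hw) continue;
          int s = ungapped_extend(a, b, smat, seeds[u].second - cur_diag,
                                  seeds[u].second, word, xdrop, &hw);
          if (s > best_ung) best_ung = s;
          if (best_ung >= ungapped_gate) break;
        }
        qualify = best_ung >= ungapped_gate;
      }
      if (qualify) {
        Aln r = band_local(a, b, smat, go, ge,
                           seeds[t0].first - band_margin,
                           seeds[t - 1].first + band_margin, want_path);
        if (r.found && r.score > best.score) best = r;
      }
      t0 = t;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_search_pair(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                     int gap_open, int gap_extend, int word, int seed_alpha,
                     int band_margin, int min_seed_count, int ungapped_gate,
                     int xdrop, bool path) {
  Aln r = search_pair(as_vec(a), as_vec(b), smat, gap_open, gap_extend,
                      word, seed_alpha, band_margin, min_seed_count,
                      ungapped_gate, xdrop, path);
  return aln_to_list(r, path);
}

// Best seeded alignment over all combinations of a_list x b_list (e.g. the
// 36 frame pairs of a translated search, or the two query strands of a
// nucleotide search). Strictly-greater score wins, so ties resolve to the
// earliest combination in list order.
// [[Rcpp::export]]
List cpp_search_best(List a_list, List b_list, IntegerMatrix smat,
                     int gap_open, int gap_extend, int word, int seed_alpha,
                     int band_margin, int min_seed_count, int ungapped_gate,
                     int xdrop) {
  Aln best;
  int best_ai = -1, best_bi = -1;
  for (int ai = 0; ai < a_list.size(); ++ai) {
    std::vector<int> a = as_vec(a_list[ai]);
    for (int bi = 0; bi < b_list.size(); ++bi) {
      std::vector<int> b = as_vec(b_list[bi]);
      Aln r = search_pair(a, b, smat, gap_open, gap_extend, word,
                          seed_alpha, band_margin, min_seed_count,
                          ungapped_gate, xdrop, false);
      if (r.found && r.score > best.score) {
        best = r; best_ai = ai + 1; best_bi = bi + 1;
      }
    }
  }
  List out = aln_to_list(best, false);
  if (best.found) { out["ai"] = best_ai; out["bi"] = best_bi; }
  return out;
}

// Pattern-global / subject-local ("fit") affine alignment: every residue of
// a is consumed; unaligned subject ends are free. Used for clustering
// identity (matching columns / length of the shorter sequence).
// [[Rcpp::export]]
List cpp_align_fit(IntegerVector av, IntegerVector bv, IntegerMatrix smat,
                   int gap_open, int gap_extend) {
  std::vector<int> a = as_vec(av), b = as_vec(bv);
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return List::create(Named("found") = false);
  size_t W = (size_t)n + 1;
  std::vector<int> H((size_t)(m + 1) * W, NEG), E((size_t)(m + 1) * W, NEG),
                   F((size_t)(m + 1) * W, NEG);
  std::vector<unsigned char> tH((size_t)(m + 1) * W, 0),
                             tE((size_t)(m + 1) * W, 0),
                             tF((size_t)(m + 1) * W, 0);
  for (int j = 0; j <= n; ++j) H[j] = 0;            // free subject prefix
  for (int i = 1; i <= m; ++i) {                    // pattern vs nothing
    H[(size_t)i * W] = F[(size_t)i * W] = -(gap_open + i * gap_extend);
    tH[(size_t)i * W] = 3;
  }
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int fh = H[row + j - 1] - gap_open - gap_extend;
      int fe = (E[row + j - 1] == NEG) ? NEG : E[row + j - 1] - gap_extend;
      int e; unsigned char te;
      if (fh >= fe) { e = fh; te = 1; } else { e = fe; te = 0; }
      fh = H[prow + j] - gap_open - gap_extend;
      int ff = (F[prow + j] == NEG) ? NEG : F[prow + j] - gap_extend;
      int f; unsigned char tf;
      if (fh >= ff) { f = fh; tf = 1; } else { f = ff; tf = 0; }
      int diag = H[prow + j - 1] + smat(a[i - 1], b[j - 1]);
      int h = diag; unsigned char th = 1;
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[row + j] = h; E[row + j] = e; F[row + j] = f;
      tH[row + j] = th; tE[row + j] = te; tF[row + j] = tf;
    }
  }
  int bj = 0, best = H[(size_t)m * W];
  for (int j = 1; j <= n; ++j)
    if (H[(size_t)m * W + j] > best) { best = H[(size_t)m * W + j]; bj = j; }
  // traceback for match count
  int i = m, j = bj, state = 0, matches = 0, cols = 0;
  while (i > 0) {
    size_t idx = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 1) {
        ++cols;
        if (j > 0 && a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++cols; state = (tE[idx] == 1) ? 0 : 1; --j;
    } else {
      ++cols;
      if (j == 0) { --i; continue; }      // leading pattern-vs-nothing run
      state = (tF[idx] == 1) ? 0 : 2; --i;
    }
  }
  return List::create(Named("found") = true, Named("score") = best,
                      Named("matches") = matches, Named("cols") = cols,
                      Named("b_start") = j + 1, Named("b_end") = bj);
}
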