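// Global alignment core shared by every distance in the package.
//
// Scoring (fixed, package-wide): match +1, mismatch -1, gap open -2,
// gap extend -1; a gap of length L costs 2 + (L - 1).  Alignments are
// end-to-end.  Ties are broken deterministically, preferring the
// match/mismatch state over a gap in the query over a gap in the
// reference, so every reported alignment and operation count is
// reproducible.  The "distance" between two sequences is the number of
// substitutions plus inserted plus deleted bases along the optimal-score
// alignment under this tie-breaking.

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;
static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = 2, GAP_EXT = 1;

struct AlnResult {
  int score, subs, ins, dels, cols;
  std::string a_aln, b_aln;
};

// tie preference: M (0) > X (gap in ref, consumes query base, 1) > Y (2)
static inline int pick3(long m, long x, long y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

static AlnResult gotoh(const std::string &a, const std::string &b,
                       bool want_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF), X((size_t)(n + 1) * W, NEG_INF),
      Y((size_t)(n + 1) * W, NEG_INF);
  std::vector<unsigned char> PM((size_t)(n + 1) * W, 0), PX((size_t)(n + 1) * W, 0),
      PY((size_t)(n + 1) * W, 0);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    int fromM = M[(size_t)(i - 1) * W] == NEG_INF ? NEG_INF
                                                  : M[(size_t)(i - 1) * W] - GAP_OPEN;
    int fromX = X[(size_t)(i - 1) * W] == NEG_INF ? NEG_INF
                                                  : X[(size_t)(i - 1) * W] - GAP_EXT;
    if (fromM >= fromX) {
      X[(size_t)i * W] = fromM;
      PX[(size_t)i * W] = 0;
    } else {
      X[(size_t)i * W] = fromX;
      PX[(size_t)i * W] = 1;
    }
  }
  for (int j = 1; j <= m; ++j) {
    int fromM = M[j - 1] == NEG_INF ? NEG_INF : M[j - 1] - GAP_OPEN;
    int fromY = Y[j - 1] == NEG_INF ? NEG_INF : Y[j - 1] - GAP_EXT;
    if (fromM >= fromY) {
      Y[j] = fromM;
      PY[j] = 0;
    } else {
      Y[j] = fromY;
      PY[j] = 2;
    }
  }
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const size_t d = prow + (j - 1), u = prow + j, l = row + (j - 1);
      int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
      int st = pick3(M[d], X[d], Y[d]);
      int base = (st == 0 ? M[d] : st == 1 ? X[d] : Y[d]);
      M[row + j] = base == NEG_INF ? NEG_INF : base + s;
      PM[row + j] = (unsigned char)st;

      int xm = M[u] == NEG_INF ? NEG_INF : M[u] - GAP_OPEN;
      int xx = X[u] == NEG_INF ? NEG_INF : X[u] - GAP_EXT;
      int xy = Y[u] == NEG_INF ? NEG_INF : Y[u] - GAP_OPEN;
      if (xm >= xx && xm >= xy) {
        X[row + j] = xm;
        PX[row + j] = 0;
      } else if (xx >= xy) {
        X[row + j] = xx;
        PX[row + j] = 1;
      } else {
        X[row + j] = xy;
        PX[row + j] = 2;
      }

      int ym = M[l] == NEG_INF ? NEG_INF : M[l] - GAP_OPEN;
      int yx = X[l] == NEG_INF ? NEG_INF : X[l] - GAP_OPEN;
      int yy = Y[l] == NEG_INF ? NEG_INF : Y[l] - GAP_EXT;
      if (ym >= yx && ym >= yy) {
        Y[row + j] = ym;
        PY[row + j] = 0;
      } else if (yx >= yy) {
        Y[row + j] = yx;
        PY[row + j] = 1;
      } else {
        Y[row + j] = yy;
        PY[row + j] = 2;
      }
    }
  }
  AlnResult r;
  r.subs = r.ins = r.dels = r.cols = 0;
  const size_t endc = (size_t)n * W + m;
  int st = pick3(M[endc], X[endc], Y[endc]);
  r.score = (st == 0 ? M[endc] : st == 1 ? X[endc] : Y[endc]);
  int i = n, j = m;
  std::string aa, bb;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (st == 0) {
      int prev = PM[c];
      if (want_strings) {
        aa.push_back(a[i - 1]);
        bb.push_back(b[j - 1]);
      }
      if (a[i - 1] != b[j - 1]) r.subs++;
      r.cols++;
      i--;
      j--;
      st = prev;
    } else if (st == 1) {
      int prev = PX[c];
      if (want_strings) {
        aa.push_back(a[i - 1]);
        bb.push_back('-');
      }
      r.ins++;
      r.cols++;
      i--;
      st = prev;
    } else {
      int prev = PY[c];
      if (want_strings) {
        aa.push_back('-');
        bb.push_back(b[j - 1]);
      }
      r.dels++;
      r.cols++;
      j--;
      st = prev;
    }
  }
  if (want_strings) {
    r.a_aln.assign(aa.rbegin(), aa.rend());
    r.b_aln.assign(bb.rbegin(), bb.rend());
  }
  return r;
}

// Banded unit-cost Levenshtein distance, capped: returns min(lev, k + 1).
// Unit edit distance lower-bounds the aligner's operation count, so this
// is a lossless prefilter for any distance threshold k.
static int lev_bounded(const std::string &a, const std::string &b, int k) {
  const int n = (int)a.size(), m = (int)b.size();
  if (k < 0) return 0;
  int diff = n > m ? n - m : m - n;
  if (diff > k) return k + 1;
  const int big = k + 1;
  std::vector<int> prev(m + 1, big), cur(m + 1, big);
  for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - k), hi = std::min(m, i + k);
    std::fill(cur.begin(), cur.end(), big);
    if (i <= k) cur[0] = i;
    int rowmin = big;
    for (int j = lo; j <= hi; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      int v = d < u ? d : u;
      if (l < v) v = l;
      if (v > big) v = big;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (i <= k && cur[0] < rowmin) rowmin = cur[0];
    if (rowmin >= big) return big;
    std::swap(prev, cur);
  }
  return std::min(prev[m], big);
}

// [[Rcpp::export]]
IntegerVector cpp_align_stats(std::string a, std::string b) {
  AlnResult r = gotoh(a, b, false);
  return IntegerVector::create(
      _["score"] = r.score, _["subs"] = r.subs, _["ins"] = r.ins,
      _["dels"] = r.dels, _["cols"] = r.cols);
}

// [[Rcpp::export]]
List cpp_align_full(std::string a, std::string b) {
  AlnResult r = gotoh(a, b, true);
  return List::create(
      _["score"] = r.score, _["subs"] = r.subs, _["ins"] = r.ins,
      _["dels"] = r.dels, _["cols"] = r.cols, _["a_aln"] = r.a_aln,
      _["b_aln"] = r.b_aln);
}

// [[Rcpp::export]]
int cpp_lev_bounded(std::string a, std::string b, int k) {
  return lev_bounded(a, b, k);
}

// Minimum alignment distance from `query` to `candidates`, which the
// caller has sorted by a valid lower bound on that distance (`bounds`,
// ascending).  Scanning stops as soon as the next bound cannot beat the
// best distance found, so the result equals the exhaustive minimum.
// Returns index 0 when there are no candidates.
// [[Rcpp::export]]
List cpp_best_distance(std::string query, CharacterVector candidates,
                       NumericVector bounds) {
  int best = INT_MAX, best_idx = 0;
  const int nq = (int)query.size();
  for (int i = 0; i < candidates.size(); ++i) {
    if (bounds[i] >= best) break;
    std::string c = as<std::string>(candidates[i]);
    int diff = std::abs((int)c.size() - nq);
    if (diff >= best) continue;
    if (best < INT_MAX) {
      int lv = lev_bounded(query, c, best - 1);
      if (lv >= best) continue;
    }
    AlnResult r = gotoh(query, c, false);
    int d = r.subs + r.ins + r.dels;
    if (d < best) {
      best = d;
      best_idx = i + 1;
      if (best == 0) break;
    }
  }
  return List::create(_["distance"] = best_idx == 0 ? NA_INTEGER : best,
                      _["index"] = best_idx);
}

// k-mer occurrence profiles (4^k rows, one column per sequence); used for
// the q-gram lower bound dist >= L1(profiles) / (2k).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_profiles(CharacterVector seqs, int k) {
  int rows = 1;
  for (int i = 0; i < k; ++i) rows *= 4;
  IntegerMatrix out(rows, seqs.size());
  const int mask = rows / 4;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string x = as<std::string>(seqs[s]);
    int code = 0, valid = 0;
    for (size_t p = 0; p < x.size(); ++p) {
      int v;
      switch (x[p]) {
        case 'A': v = 0; break;
        case 'C': v = 1; break;
        case 'G': v = 2; break;
        case 'T': v = 3; break;
        default: v = -1;
      }
      if (v < 0) {
        code = 0;
        valid = 0;
        continue;
      }
      code = (code % mask) * 4 + v;
      if (++valid >= k) out(code, s)++;
    }
  }
  return out;
}

// Apply counts of substitutions / single-base insertions / single-base
// deletions at uniform positions.  Draws positions and bases from the R
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, IntegerVector nsub,
                           IntegerVector nins, IntegerVector ndel) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string x = as<std::string>(seqs[i]);
    for (int s = 0; s < nsub[i]; ++s) {
      if (x.empty()) break;
      int pos = (int)(unif_rand() * x.size());
      if (pos >= (int)x.size()) pos = (int)x.size() - 1;
      int shift = 1 + (int)(unif_rand() * 3);
      if (shift > 3) shift = 3;
      int cur;
      switch (x[pos]) {
        case 'A': cur = 0; break;
        case 'C': cur = 1; break;
        case 'G': cur = 2; break;
        default: cur = 3;
      }
      x[pos] = bases[(cur + shift) % 4];
    }
    for (int s = 0; s < nins[i]; ++s) {
      int pos = (int)(unif_rand() * (x.size() + 1));
      if (pos > (int)x.size()) pos = (int)x.size();
      int b = (int)(unif_rand() * 4);
      if (b > 3) b = 3;
      x.insert(x.begin() + pos, bases[b]);
    }
    for (int s = 0; s < ndel[i]; ++s) {
      if (x.size() <= 1) break;
      int pos = (int)(unif_rand() * x.size());
      if (pos >= (int)x.size()) pos = (int)x.size() - 1;
      x.erase(x.begin() + pos);
    }
    out[i] = x;
  }
  return out;
}

// Query-coordinate match vector: TRUE where the query base aligns to an
// identical parent base in the global alignment (indels mismatch).
// [[Rcpp::export]]
LogicalVector cpp_query_match(std::string query, std::string parent) {
  AlnResult r = gotoh(query, parent, true);
  LogicalVector out(query.size());
  int qi = 0;
  for (size_t c = 0; c < r.a_aln.size(); ++c) {
    if (r.a_aln[c] != '-') {
      out[qi] = (r.a_aln[c] == r.b_aln[c]);
      qi++;
    }
  }
  return out;
}

// Greedy abundance preclustering.  `seqs` must already be sorted by
// decreasing abundance (ties: lexicographic).  Each sequence merges into
// the first retained sequence (in that order) within `max_diffs`
// alignment operations, else is retained itself.  Returns the 1-based
// index of the target each sequence merges into (own index if retained).
// [[Rcpp::export]]
IntegerVector cpp_precluster_assign(CharacterVector seqs, int max_diffs) {
  const int n = (int)seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> sx(n);
  for (int i = 0; i < n; ++i) sx[i] = as<std::string>(seqs[i]);
  std::vector<int> retained;
  for (int i = 0; i < n; ++i) {
    int target = i;
    for (size_t rr = 0; rr < retained.size(); ++rr) {
      const int r = retained[rr];
      int diff = std::abs((int)sx[i].size() - (int)sx[r].size());
      if (diff > max_diffs) continue;
      if (lev_bounded(sx[i], sx[r], max_diffs) > max_diffs) continue;
      AlnResult a = gotoh(sx[i], sx[r], false);
      if (a.subs + a.ins + a.dels <= max_diffs) {
        target = r;
        break;
      }
    }
    if (target == i) retained.push_back(i);
    assign[i] = target + 1;
  }
  return assign;
}

// Abundance-greedy radius OTU clustering.  `seqs` sorted by decreasing
// total abundance (ties: lexicographic).  A sequence joins the first OTU
// whose founding representative is within `threshold` dissimilarity
// ((subs + indel columns) / alignment columns), else founds a new OTU.
// Returns the 1-based OTU id per sequence, in founding order.
// [[Rcpp::export]]
IntegerVector cpp_cluster_assign(CharacterVector seqs, double threshold) {
  const int n = (int)seqs.size();
  IntegerVector otu(n);
  std::vector<std::string> sx(n);
  for (int i = 0; i < n; ++i) sx[i] = as<std::string>(seqs[i]);
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    int hit = 0;
    for (size_t rr = 0; rr < reps.size() && hit == 0; ++rr) {
      const int r = reps[rr];
      const int la = (int)sx[i].size(), lb = (int)sx[r].size();
      // dist >= lev and dist = dissim * cols with cols <= la + lb
      int K = (int)std::floor(threshold * (la + lb) + 1e-9);
      if (std::abs(la - lb) > K) continue;
      if (lev_bounded(sx[i], sx[r], K) > K) continue;
      AlnResult a = gotoh(sx[i], sx[r], false);
      double dis = (double)(a.subs + a.ins + a.dels) / (double)a.cols;
      if (dis <= threshold + 1e-12) hit = (int)rr + 1;
    }
    if (hit == 0) {
      reps.push_back(i);
      hit = (int)reps.size();
    }
    otu[i] = hit;
  }
  return otu;
}
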