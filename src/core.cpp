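#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// Core machinery for signed gene orders:
//  - Hannenhalli-Pevzner inversion (reversal) distance via the breakpoint
//    graph over 2g+2 unsigned endpoints: d = (g+1) - cycles + hurdles +
//    fortress.
//  - breakpoint distance with frame markers 0 and g+1.
//  - inversion median of three genomes: exact breadth-first
//    branch-and-bound from the cheapest corner with the metric bound
//    f(m) >= d(s,m) + d(other pair), plus a greedy descent fallback over
//    candidate reversals read off oriented gray edges when the search
//    exceeds its node budget.

namespace {

inline int uf_find(std::vector<int>& uf, int x) {
  while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
  return x;
}
inline void uf_union(std::vector<int>& uf, int a, int b) {
  a = uf_find(uf, a); b = uf_find(uf, b);
  if (a != b) uf[a] = b;
}

// q = a expressed in b's coordinate frame (so d(a,b) = d(q, identity))
inline void make_q(const int* a, const int* b, int g, std::vector<int>& q) {
  static std::vector<int> frame;
  frame.assign(g + 1, 0);
  for (int k = 0; k < g; ++k) {
    int v = b[k];
    if (v > 0) frame[v] = k + 1; else frame[-v] = -(k + 1);
  }
  q.resize(g);
  for (int i = 0; i < g; ++i) {
    int v = a[i];
    q[i] = v > 0 ? frame[v] : -frame[-v];
  }
}

// hurdle count for a laminar family of unoriented-component extents:
// minimal components plus the greatest component when it contains all others
int count_hurdles(const std::vector<std::pair<int,int> >& iv,
                  const std::vector<char>& alive) {
  int n = (int) iv.size();
  int h = 0, greatest = -1, nalive = 0;
  for (int i = 0; i < n; ++i) if (alive[i]) ++nalive;
  if (nalive == 0) return 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    bool contains_any = false, contains_all = true;
    for (int j = 0; j < n; ++j) {
      if (j == i || !alive[j]) continue;
      bool c = iv[i].first < iv[j].first && iv[j].second < iv[i].second;
      if (c) contains_any = true; else contains_all = false;
    }
    if (!contains_any) ++h;
    else if (nalive > 1 && contains_all) greatest = i;
  }
  if (greatest >= 0) ++h;
  return h;
}

struct HPResult {
  int dist;
  int cycles;
  int hurdles;
  int fortress;
};

// HP distance of q from the identity; optionally collect, for each gray
// edge with same-parity endpoints, the gene-coordinate reversal (i,j)
// that joins it (candidate sorting reversals).
HPResult hp_dist_q(const std::vector<int>& q,
                   std::vector<std::pair<int,int> >* cands = 0) {
  int g = (int) q.size();
  int N = 2 * g + 2;
  static std::vector<int> arr, pos, cyc;
  static std::vector<char> cyc_oriented, cyc_trivial;
  arr.resize(N); pos.resize(N);
  arr[0] = 0; arr[N - 1] = N - 1;
  for (int i = 0; i < g; ++i) {
    int x = q[i];
    if (x > 0) { arr[2 * i + 1] = 2 * x - 1; arr[2 * i + 2] = 2 * x; }
    else       { int y = -x; arr[2 * i + 1] = 2 * y; arr[2 * i + 2] = 2 * y - 1; }
  }
  for (int p = 0; p < N; ++p) pos[arr[p]] = p;

  int nb = g + 1;                 // black edges (positions 2k, 2k+1)
  cyc.assign(nb, -1);
  cyc_oriented.clear(); cyc_trivial.clear();
  int ncyc = 0;
  bool any_unoriented = false;
  for (int k = 0; k < nb; ++k) {
    if (cyc[k] >= 0) continue;
    int id = ncyc++;
    int p = 2 * k, len = 0;
    bool dir0 = false, dir1 = false;
    do {
      cyc[p / 2] = id;
      ++len;
      if (p & 1) dir1 = true; else dir0 = true;
      int v = arr[p ^ 1];       // cross the black edge
      p = pos[v ^ 1];           // follow the gray edge
    } while (p != 2 * k);
    bool oriented = dir0 && dir1;
    cyc_oriented.push_back((char) (len > 1 && oriented));
    cyc_trivial.push_back((char) (len == 1));
    if (len > 1 && !oriented) any_unoriented = true;
  }

  // candidate sorting reversals from gray edges with same-parity endpoints
  if (cands) {
    for (int m = 0; m <= g; ++m) {
      int p1 = pos[2 * m], p2 = pos[2 * m + 1];
      if (p1 > p2) std::swap(p1, p2);
      if (((p1 ^ p2) & 1) != 0) continue;   // endpoints differ in parity
      if (p2 == p1 + 1) continue;           // already an adjacency
      int i, j;
      if ((p1 & 1) == 0) { i = p1 / 2 + 1; j = p2 / 2; }
      else               { i = (p1 + 1) / 2; j = (p2 - 1) / 2; }
      if (i >= 1 && j >= i && j <= g) cands->push_back(std::make_pair(i, j));
    }
  }

  int h = 0, f = 0;
  if (any_unoriented) {
    // interleaving components of nontrivial cycles (union-find over
    // crossing gray edges); extents form a laminar family
    static std::vector<int> uf, glo, ghi, gcyc;
    uf.resize(ncyc);
    for (int i = 0; i < ncyc; ++i) uf[i] = i;
    glo.clear(); ghi.clear(); gcyc.clear();
    for (int m = 0; m <= g; ++m) {
      int p1 = pos[2 * m], p2 = pos[2 * m + 1];
      if (p1 > p2) std::swap(p1, p2);
      if (p2 == p1 + 1 && cyc_trivial[cyc[p1 / 2]]) continue;
      glo.push_back(p1); ghi.push_back(p2); gcyc.push_back(cyc[p1 / 2]);
    }
    int ne = (int) glo.size();
    for (int i = 0; i < ne; ++i)
      for (int j = i + 1; j < ne; ++j) {
        bool cross = (glo[i] < glo[j] && glo[j] < ghi[i] && ghi[i] < ghi[j]) ||
                     (glo[j] < glo[i] && glo[i] < ghi[j] && ghi[j] < ghi[i]);
        if (cross) uf_union(uf, gcyc[i], gcyc[j]);
      }
    // per-component extent / orientation / nontriviality
    std::vector<int> clo(ncyc, N), chi(ncyc, -1);
    std::vector<char> cunor(ncyc, 1), cnontriv(ncyc, 0);
    for (int i = 0; i < ne; ++i) {
      int r = uf_find(uf, gcyc[i]);
      if (glo[i] < clo[r]) clo[r] = glo[i];
      if (ghi[i] > chi[r]) chi[r] = ghi[i];
    }
    for (int cid = 0; cid < ncyc; ++cid) {
      int r = uf_find(uf, cid);
      if (cyc_oriented[cid]) cunor[r] = 0;
      if (!cyc_trivial[cid]) cnontriv[r] = 1;
    }
    std::vector<std::pair<int,int> > iv;
    for (int r = 0; r < ncyc; ++r)
      if (uf_find(uf, r) == r && cnontriv[r] && cunor[r] && chi[r] >= 0)
        iv.push_back(std::make_pair(clo[r], chi[r]));
    std::vector<char> alive(iv.size(), 1);
    h = count_hurdles(iv, alive);
    if (h > 0 && (h % 2) == 1) {
      // fortress: hurdle count odd and every hurdle is a super hurdle
      // (removing it does not lower the hurdle count)
      bool all_super = true;
      for (size_t i = 0; i < iv.size() && all_super; ++i) {
        alive[i] = 0;
        int h2 = count_hurdles(iv, alive);
        alive[i] = 1;
        // only removing an actual hurdle is informative; removing a
        // non-hurdle leaves the count unchanged
        int h_base = count_hurdles(iv, alive);
        if (h2 < h_base) {
          // i was a hurdle and not protected
          all_super = false;
        }
      }
      if (all_super) f = 1;
    }
  }

  HPResult res;
  res.cycles = ncyc;
  res.hurdles = h;
  res.fortress = f;
  res.dist = nb - ncyc + h + f;
  return res;
}

inline int hp_dist(const int* a, const int* b, int g) {
  static std::vector<int> q;
  make_q(a, b, g, q);
  return hp_dist_q(q).dist;
}

inline void rev_apply(const std::vector<int>& src, std::vector<int>& dst,
                      int i, int j) {
  dst = src;
  int lo = i - 1, hi = j - 1;
  while (lo <= hi) {
    int t = src[hi];
    dst[lo] = -t;
    if (lo != hi) dst[hi] = -src[lo];
    ++lo; --hi;
  }
}

inline std::string key_of(const std::vector<int>& v, int g) {
  std::string s;
  s.resize(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    s[i] = (char) (unsigned char) (v[i] + g);
  return s;
}

inline int d3(const std::vector<int>& x, const std::vector<int>& a,
              const std::vector<int>& b, const std::vector<int>& c) {
  int g = (int) x.size();
  return hp_dist(&x[0], &a[0], g) + hp_dist(&x[0], &b[0], g) +
         hp_dist(&x[0], &c[0], g);
}

// candidate reversals for the greedy descent: gray-edge reversals of the
// breakpoint graph of x against each target, deduplicated and sorted
void gather_candidates(const std::vector<int>& x,
                       const std::vector<std::vector<int> >& targets,
                       std::vector<std::pair<int,int> >& out) {
  out.clear();
  int g = (int) x.size();
  static std::vector<int> q;
  for (size_t t = 0; t < targets.size(); ++t) {
    make_q(&x[0], &targets[t][0], g, q);
    hp_dist_q(q, &out);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// greedy descent on f(x) = sum of distances to a,b,c from start x0.
// Strictly improving moves are taken from the gray-edge candidate set
// (full scan when that set is dry); on a plateau a limited number of
// sideways moves (equal f, unvisited states) escape shallow local
// optima. The overall best state is tracked throughout.
void median_descent(std::vector<int> cur,
                    const std::vector<int>& a, const std::vector<int>& b,
                    const std::vector<int>& c,
                    std::vector<int>& best, int& best_score,
                    int lower_bound) {
  int g = (int) cur.size();
  std::vector<std::vector<int> > targets;
  targets.push_back(a); targets.push_back(b); targets.push_back(c);
  int fcur = d3(cur, a, b, c);
  if (fcur < best_score) { best_score = fcur; best = cur; }
  std::vector<std::pair<int,int> > cands;
  std::vector<int> trial, step_best;
  std::unordered_set<std::string> visited;
  visited.insert(key_of(cur, g));
  int sideways_left = 3 * g;
  while (best_score > lower_bound) {
    int f_best = fcur;
    bool improved = false;
    bool have_side = false;
    std::vector<int> side_state;
    gather_candidates(cur, targets, cands);
    for (size_t k = 0; k < cands.size(); ++k) {
      rev_apply(cur, trial, cands[k].first, cands[k].second);
      int f = d3(trial, a, b, c);
      if (f < f_best) { f_best = f; step_best = trial; improved = true; }
      else if (!improved && !have_side && f == fcur &&
               sideways_left > 0 && !visited.count(key_of(trial, g))) {
        have_side = true; side_state = trial;
      }
    }
    if (!improved) {
      // full lexicographic scan as a last resort
      for (int i = 1; i <= g; ++i)
        for (int j = i; j <= g; ++j) {
          rev_apply(cur, trial, i, j);
          int f = d3(trial, a, b, c);
          if (f < f_best) { f_best = f; step_best = trial; improved = true; }
          else if (!improved && !have_side && f == fcur &&
                   sideways_left > 0 && !visited.count(key_of(trial, g))) {
            have_side = true; side_state = trial;
          }
        }
    }
    if (improved) {
      cur = step_best;
      fcur = f_best;
    } else if (have_side) {
      cur = side_state;
      --sideways_left;
    } else {
      break;
    }
    visited.insert(key_of(cur, g));
    if (fcur < best_score) { best_score = fcur; best = cur; }
  }
}

// signed successor table: succ[sgn(g)+G] = signed gene following x when
// reading the genome in x's orientation (frame markers excluded)
static void succ_table(const std::vector<int>& p, int G,
                       std::vector<int>& succ) {
  succ.assign(2 * G + 1, 0);  // index v+G, 0 means none
  int g = (int) p.size();
  for (int i = 0; i + 1 < g; ++i) {
    succ[p[i] + G] = p[i + 1];
    succ[-p[i + 1] + G] = -p[i];
  }
}

// condense adjacencies common to all three genomes into super-genes;
// a is mapped to the identity over the blocks
struct Condensed {
  std::vector<int> a, b, c;
  std::vector<std::vector<int> > blocks;  // block k-1: signed genes in a's order
};

static bool condense3(const std::vector<int>& a, const std::vector<int>& b,
                      const std::vector<int>& c, Condensed& out) {
  int g = (int) a.size();
  int G = g + 1;
  static std::vector<int> sb, sc;
  succ_table(b, G, sb);
  succ_table(c, G, sc);
  out.blocks.clear();
  std::vector<int> blk;
  for (int i = 0; i < g; ++i) {
    blk.push_back(a[i]);
    bool join = false;
    if (i + 1 < g) {
      int x = a[i], y = a[i + 1];
      join = (sb[x + G] == y) && (sc[x + G] == y);
    }
    if (!join) { out.blocks.push_back(blk); blk.clear(); }
  }
  int gp = (int) out.blocks.size();
  if (gp == g) return false;  // nothing to condense
  // membership: first element (+k) and negated last element (-k) mark the
  // block's two traversal entries
  std::vector<int> enter(2 * G + 1, 0);
  for (int k = 0; k < gp; ++k) {
    enter[out.blocks[k].front() + G] = k + 1;
    enter[-out.blocks[k].back() + G] = -(k + 1);
  }
  out.a.resize(gp);
  for (int k = 0; k < gp; ++k) out.a[k] = k + 1;
  out.b.clear(); out.c.clear();
  for (int i = 0; i < (int) b.size(); ++i) {
    int e = enter[b[i] + G];
    if (e != 0) out.b.push_back(e);
  }
  for (int i = 0; i < (int) c.size(); ++i) {
    int e = enter[c[i] + G];
    if (e != 0) out.c.push_back(e);
  }
  if ((int) out.b.size() != gp || (int) out.c.size() != gp) return false;
  return true;
}

static std::vector<int> expand_blocks(const std::vector<int>& m,
                                      const std::vector<std::vector<int> >& blocks) {
  std::vector<int> out;
  for (size_t i = 0; i < m.size(); ++i) {
    int k = m[i];
    if (k > 0) {
      const std::vector<int>& bl = blocks[k - 1];
      out.insert(out.end(), bl.begin(), bl.end());
    } else {
      const std::vector<int>& bl = blocks[-k - 1];
      for (int j = (int) bl.size() - 1; j >= 0; --j) out.push_back(-bl[j]);
    }
  }
  return out;
}

// walk `steps` greedy sorting reversals from x toward target t
static std::vector<int> path_point(const std::vector<int>& x,
                                   const std::vector<int>& t, int steps) {
  int g = (int) x.size();
  std::vector<int> cur = x, trial, nxt;
  std::vector<std::pair<int,int> > cands;
  static std::vector<int> q;
  for (int s = 0; s < steps; ++s) {
    int dcur = hp_dist(&cur[0], &t[0], g);
    if (dcur == 0) break;
    cands.clear();
    make_q(&cur[0], &t[0], g, q);
    hp_dist_q(q, &cands);
    std::sort(cands.begin(), cands.end());
    bool moved = false;
    for (size_t k = 0; k < cands.size() && !moved; ++k) {
      rev_apply(cur, trial, cands[k].first, cands[k].second);
      if (hp_dist(&trial[0], &t[0], g) < dcur) { nxt = trial; moved = true; }
    }
    if (!moved) {
      for (int i = 1; i <= g && !moved; ++i)
        for (int j = i; j <= g && !moved; ++j) {
          rev_apply(cur, trial, i, j);
          if (hp_dist(&trial[0], &t[0], g) < dcur) { nxt = trial; moved = true; }
        }
    }
    if (!moved) break;
    cur = nxt;
  }
  return cur;
}

} // namespace

// [[Rcpp::export]]
int cpp_inv_dist(IntegerVector a, IntegerVector b) {
  int g = a.size();
  if (b.size() != g) stop("genomes differ in length");
  static std::vector<int> q;
  make_q(&a[0], &b[0], g, q);
  return hp_dist_q(q).dist;
}

// [[Rcpp::export]]
List cpp_inv_dist_detail(IntegerVector a, IntegerVector b) {
  int g = a.size();
  static std::vector<int> q;
  make_q(&a[0], &b[0], g, q);
  HPResult r = hp_dist_q(q);
  return List::create(_["distance"] = r.dist, _["cycles"] = r.cycles,
                      _["hurdles"] = r.hurdles, _["fortress"] = r.fortress);
}

// [[Rcpp::export]]
int cpp_breakpoint_dist(IntegerVector a, IntegerVector b) {
  int g = a.size();
  if (b.size() != g) stop("genomes differ in length");
  long G = g + 1, M = 2 * G + 2;
  std::unordered_set<long> adj;
  long x = 0;
  for (int i = 0; i <= g; ++i) {
    long y = (i < g) ? b[i] : G;
    long k1 = (x + G) * M + (y + G);
    long k2 = (-y + G) * M + (-x + G);
    adj.insert(k1 < k2 ? k1 : k2);
    x = y;
  }
  int broken = 0;
  x = 0;
  for (int i = 0; i <= g; ++i) {
    long y = (i < g) ? a[i] : G;
    long k1 = (x + G) * M + (y + G);
    long k2 = (-y + G) * M + (-x + G);
    if (!adj.count(k1 < k2 ? k1 : k2)) ++broken;
    x = y;
  }
  return broken;
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairwise(IntegerMatrix X, std::string metric) {
  int n = X.nrow(), g = X.ncol();
  IntegerMatrix D(n, n);
  std::vector<std::vector<int> > rows(n, std::vector<int>(g));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < g; ++k) rows[i][k] = X(i, k);
  bool inv = (metric == "inversion");
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d;
      if (inv) d = hp_dist(&rows[i][0], &rows[j][0], g);
      else {
        IntegerVector ai = X(i, _), bj = X(j, _);
        d = cpp_breakpoint_dist(ai, bj);
      }
      D(i, j) = d; D(j, i) = d;
    }
  return D;
}

// [[Rcpp::export]]
List cpp_inversion_median(IntegerVector av, IntegerVector bv, IntegerVector cv,
                          int budget = 20000) {
  std::vector<int> a0(av.begin(), av.end());
  std::vector<int> b0(bv.begin(), bv.end());
  std::vector<int> c0(cv.begin(), cv.end());

  // condense adjacencies shared by all three genomes (distance-preserving;
  // the median is searched over the block permutation and expanded back)
  Condensed cnd;
  bool reduced = condense3(a0, b0, c0, cnd);
  std::vector<int>& a = reduced ? cnd.a : a0;
  std::vector<int>& b = reduced ? cnd.b : b0;
  std::vector<int>& c = reduced ? cnd.c : c0;
  int g = (int) a.size();

  int dab = hp_dist(&a[0], &b[0], g);
  int dac = hp_dist(&a[0], &c[0], g);
  int dbc = hp_dist(&b[0], &c[0], g);
  int B0 = (dab + dac + dbc + 1) / 2;

  int fa = dab + dac, fb = dab + dbc, fc = dac + dbc;
  std::vector<int> s = a;
  int U = fa, dpair = dbc;
  if (fb < U) { s = b; U = fb; dpair = dac; }
  if (fc < U) { s = c; U = fc; dpair = dab; }

  std::vector<int> best = s;
  bool heuristic = false;
  long nodes = 1;

  if (U > B0 && g <= 120) {
    // feasibility gate: estimated frontier growth vs the node budget;
    // the estimate is capped by the size of the whole search space
    // (2^g * g!), which bounds it tightly for small g
    double nmoves = (double) g * (g + 1) / 2.0;
    double space = 1.0;
    for (int i = 1; i <= g && space < 1e18; ++i) space *= 2.0 * i;
    int max_level = U - dpair - 1;
    double est = 1.0;
    double width = 1.0;
    for (int l = 1; l <= max_level; ++l) {
      width *= nmoves;
      est += width;
      if (est >= space) { est = space; break; }
    }
    bool feasible = est <= (double) budget * 4.0;
    if (feasible) {
      std::unordered_set<std::string> seen;
      std::vector<std::vector<int> > frontier, nxt;
      seen.insert(key_of(s, g));
      frontier.push_back(s);
      int level = 0;
      bool exhausted = false;
      std::vector<int> trial;
      while (U > B0 && !exhausted) {
        if (level + 1 + dpair >= U) break;
        nxt.clear();
        for (size_t fidx = 0; fidx < frontier.size() && !exhausted; ++fidx) {
          const std::vector<int>& x = frontier[fidx];
          for (int i = 1; i <= g; ++i) {
            for (int j = i; j <= g; ++j) {
              rev_apply(x, trial, i, j);
              std::string key = key_of(trial, g);
              if (seen.count(key)) continue;
              seen.insert(key);
              ++nodes;
              int f = d3(trial, a, b, c);
              if (f < U) { U = f; best = trial; }
              nxt.push_back(trial);
              if ((long) seen.size() > budget) { exhausted = true; break; }
            }
            if (exhausted) break;
          }
        }
        frontier.swap(nxt);
        ++level;
        if (frontier.empty()) break;
      }
      if (exhausted) heuristic = true;
    } else {
      heuristic = true;
    }
  } else if (U > B0) {
    heuristic = true;
  }

  if (heuristic && U > B0) {
    // multi-start: descend from the best-so-far state, from each input
    // genome, and from the midpoints of greedy pairwise sorting paths
    std::vector<int> start = best;
    median_descent(start, a, b, c, best, U, B0);
    if (U > B0) median_descent(a, a, b, c, best, U, B0);
    if (U > B0) median_descent(b, a, b, c, best, U, B0);
    if (U > B0) median_descent(c, a, b, c, best, U, B0);
    if (U > B0) median_descent(path_point(a, b, dab / 2), a, b, c, best, U, B0);
    if (U > B0) median_descent(path_point(a, c, dac / 2), a, b, c, best, U, B0);
    if (U > B0) median_descent(path_point(b, c, dbc / 2), a, b, c, best, U, B0);
  }
  // a heuristic flag only matters if optimality is not certified by the bound
  if (U <= B0) heuristic = false;

  std::vector<int> med = reduced ? expand_blocks(best, cnd.blocks) : best;
  return List::create(_["median"] = IntegerVector(med.begin(), med.end()),
                      _["score"] = U,
                      _["heuristic"] = heuristic,
                      _["lower_bound"] = B0,
                      _["nodes"] = (double) nodes);
}
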