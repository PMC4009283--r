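#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// string index (1..k) of a text position p: number of start positions <= p.
// The caller decides whether p is past the string end (separator block).
static inline int str_of(const IntegerVector &start_pos, int p) {
  return (int)(std::upper_bound(start_pos.begin(), start_pos.end(), p) -
               start_pos.begin());
}

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling with radix (counting) sort, O(n log n).
// codes: positive integer codes, comparison order = integer order.
// Returns 1-based positions of the lexicographically sorted suffixes.
// [[Rcpp::export]]
IntegerVector cpp_build_sa(IntegerVector codes) {
  const int n = codes.size();
  if (n == 0) stop("empty text");
  std::vector<int> sa(n), rnk(n), tmp(n);
  int K = 0;
  for (int i = 0; i < n; ++i) {
    if (codes[i] <= 0) stop("character codes must be positive");
    K = std::max(K, (int)codes[i]);
  }
  {
    std::vector<int> cnt(K + 1, 0);
    for (int i = 0; i < n; ++i) cnt[codes[i]]++;
    for (int i = 1; i <= K; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[codes[i]]] = i;
  }
  int r = 0;
  rnk[sa[0]] = 0;
  for (int i = 1; i < n; ++i) {
    if (codes[sa[i]] != codes[sa[i - 1]]) ++r;
    rnk[sa[i]] = r;
  }
  for (int len = 1; r + 1 < n; len <<= 1) {
    // order by second key (rank at i+len; absent = smallest)
    std::vector<int> by2;
    by2.reserve(n);
    for (int i = n - len; i < n; ++i) by2.push_back(i);
    for (int i = 0; i < n; ++i)
      if (sa[i] >= len) by2.push_back(sa[i] - len);
    // stable counting sort by first key
    std::vector<int> cnt(r + 2, 0);
    for (int i = 0; i < n; ++i) cnt[rnk[i] + 1]++;
    for (int i = 1; i <= r + 1; ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) sa[cnt[rnk[by2[i]]]++] = by2[i];
    // recompute ranks
    tmp[sa[0]] = 0;
    r = 0;
    for (int i = 1; i < n; ++i) {
      const int a = sa[i], b = sa[i - 1];
      const int ra = (a + len < n) ? rnk[a + len] : -1;
      const int rb = (b + len < n) ? rnk[b + len] : -1;
      if (rnk[a] != rnk[b] || ra != rb) ++r;
      tmp[a] = r;
    }
    rnk = tmp;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// LCP array (Kasai), lcp[1] = 0; lcp[r] = longest common prefix of the
// suffixes at ranks r-1 and r.
// [[Rcpp::export]]
IntegerVector cpp_build_lcp(IntegerVector codes, IntegerVector sa) {
  const int n = codes.size();
  if (sa.size() != n) stop("sa/text length mismatch");
  std::vector<int> isa(n);
  for (int r = 0; r < n; ++r) isa[sa[r] - 1] = r;
  IntegerVector lcp(n);
  lcp[0] = 0;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (isa[i] > 0) {
      const int j = sa[isa[i] - 1] - 1;
      while (i + h < n && j + h < n && codes[i + h] == codes[j + h]) ++h;
      lcp[isa[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// ---------------------------------------------------------------------------
// Suffix tree topology from SA + LCP (lcp-interval stack construction),
// emitted as a preorder balanced-parentheses sequence with per-position
// annotations.  Leaves are ordered as in SA.  Leaf pop keys use suffix
// length + 1 (a virtual end-of-text sentinel) so that a suffix that is a
// prefix of another still gets its own leaf under an internal node.
// [[Rcpp::export]]
List cpp_build_tree(IntegerVector sa, IntegerVector lcp) {
  const int n = sa.size();
  std::vector<int> depth, leafr, par, key;
  std::vector<std::vector<int> > ch;
  depth.reserve(2 * n); leafr.reserve(2 * n);
  par.reserve(2 * n); key.reserve(2 * n); ch.reserve(2 * n);
  // root
  depth.push_back(0); leafr.push_back(0); par.push_back(-1); key.push_back(0);
  ch.push_back(std::vector<int>());
  std::vector<int> stk;
  stk.push_back(0);
  for (int r = 0; r < n; ++r) {
    const int l = (r == 0) ? 0 : lcp[r];
    int last = -1;
    while (key[stk.back()] > l) {
      last = stk.back();
      stk.pop_back();
    }
    int top = stk.back();
    if (key[top] != l) {
      // key[top] < l: interpose internal node u between top and last child
      const int u = (int)depth.size();
      depth.push_back(l); leafr.push_back(0); par.push_back(top);
      key.push_back(l); ch.push_back(std::vector<int>());
      ch[top].back() = u;
      ch[u].push_back(last);
      par[last] = u;
      stk.push_back(u);
      top = u;
    }
    const int slen = n - (sa[r] - 1);
    const int leaf = (int)depth.size();
    depth.push_back(slen); leafr.push_back(r + 1); par.push_back(top);
    key.push_back(slen + 1); ch.push_back(std::vector<int>());
    ch[top].push_back(leaf);
    stk.push_back(leaf);
  }
  // iterative preorder emission
  const int m = (int)depth.size();
  const int bplen = 2 * m;
  IntegerVector bp(bplen), match(bplen), parent_pos(bplen),
      depth_pos(bplen), leaf_rank(bplen), leaf_cum(bplen), leaf_pos(n);
  std::vector<int> open_of(m);
  std::vector<std::pair<int, int> > dfs;
  dfs.reserve(m);
  int pos = 0;
  open_of[0] = 0;
  bp[0] = 1; depth_pos[0] = 0; parent_pos[0] = 0; leaf_rank[0] = 0;
  ++pos;
  dfs.push_back(std::make_pair(0, 0));
  while (!dfs.empty()) {
    const int v = dfs.back().first;
    int &ci = dfs.back().second;
    if (ci < (int)ch[v].size()) {
      const int c = ch[v][ci++];
      open_of[c] = pos;
      bp[pos] = 1;
      depth_pos[pos] = depth[c];
      parent_pos[pos] = open_of[v] + 1;
      leaf_rank[pos] = leafr[c];
      if (leafr[c] > 0) leaf_pos[leafr[c] - 1] = pos + 1;
      ++pos;
      dfs.push_back(std::make_pair(c, 0));
    } else {
      bp[pos] = 0;
      match[pos] = open_of[v] + 1;
      match[open_of[v]] = pos + 1;
      ++pos;
      dfs.pop_back();
    }
  }
  int cum = 0;
  for (int i = 0; i < bplen; ++i) {
    if (bp[i] == 1 && leaf_rank[i] > 0) ++cum;
    leaf_cum[i] = cum;
  }
  return List::create(_["bp"] = bp, _["match"] = match,
                      _["parent"] = parent_pos, _["depth"] = depth_pos,
                      _["leaf_rank"] = leaf_rank, _["leaf_cum"] = leaf_cum,
                      _["leaf_pos"] = leaf_pos, _["n_nodes"] = m);
}

// ---------------------------------------------------------------------------
// Stage 1 of method 1: one pass over the leaves in SA order.  Every leaf
// whose suffix starts inside a string (not in a separator block) and whose
// incoming edge is terminal contributes its text position to the candidate
// list of its effective parent: the closest ancestor whose own incoming
// edge is not terminal.  The stored match length is the length of the
// string-suffix starting at that position.
// [[Rcpp::export]]
List cpp_fill_l(IntegerVector codes, IntegerVector sa, List tree,
                IntegerVector start_pos, IntegerVector str_end, int sep_max) {
  IntegerVector leaf_pos = tree["leaf_pos"];
  IntegerVector parentp = tree["parent"];
  IntegerVector depthp = tree["depth"];
  IntegerVector bp = tree["bp"];
  const int n = sa.size();
  const int bplen = bp.size();
  std::vector<int> owner, posv, lenv;
  for (int r = 0; r < n; ++r) {
    const int p = sa[r];
    if (codes[p - 1] <= sep_max) continue;  // suffix starts in a separator
    const int si = str_of(start_pos, p);
    const int suf = str_end[si - 1] - p + 1;
    int z = parentp[leaf_pos[r] - 1];
    if (z == 0 || depthp[z - 1] < suf) continue;  // leaf edge not terminal
    // climb while the edge into z is itself terminal
    for (;;) {
      const int pz = parentp[z - 1];
      if (pz == 0) break;
      if (depthp[pz - 1] < suf) break;
      z = pz;
    }
    owner.push_back(z);
    posv.push_back(p);
    lenv.push_back(suf);
  }
  const int ne = (int)owner.size();
  // group entry indices by owner (stable counting sort over BP positions)
  IntegerVector startv(bplen + 1);
  {
    std::vector<int> cnt(bplen + 2, 0);
    for (int e = 0; e < ne; ++e) cnt[owner[e] + 1]++;
    for (int v = 1; v <= bplen + 1; ++v) cnt[v] += cnt[v - 1];
    for (int v = 0; v <= bplen; ++v) startv[v] = cnt[v + 1];
    // startv[v] (0-based index v) = number of entries with owner <= v+... ;
    // see below: entries of open position v live at order[startv[v-1]..startv[v]-1]
    IntegerVector order(ne);
    std::vector<int> fill(cnt.begin(), cnt.end());
    for (int e = 0; e < ne; ++e) order[fill[owner[e]]++] = e + 1;
    return List::create(_["owner"] = IntegerVector(owner.begin(), owner.end()),
                        _["pos"] = IntegerVector(posv.begin(), posv.end()),
                        _["len"] = IntegerVector(lenv.begin(), lenv.end()),
                        _["order"] = order, _["start"] = startv);
  }
}

// ---------------------------------------------------------------------------
// Stage 2 of method 1: a left-to-right scan of BP positions [from, to]
// maintaining one stack per string.  Opening an internal node pushes its
// candidate-list entries; a leaf at a string start reports the stack tops;
// closing an internal node pops its entries.  `pre_*` holds stack entries
// the sequential scan would have accumulated before `from` (bottom first).
// [[Rcpp::export]]
IntegerMatrix cpp_method1_scan(IntegerVector codes, IntegerVector sa,
                               List tree, List L, IntegerVector start_pos,
                               IntegerVector str_end, int k, int sep_max,
                               int from, int to, IntegerVector pre_str,
                               IntegerVector pre_pos, IntegerVector pre_len,
                               int min_len) {
  IntegerVector bp = tree["bp"];
  IntegerVector match = tree["match"];
  IntegerVector leaf_rank = tree["leaf_rank"];
  IntegerVector lpos = L["pos"], lorder = L["order"], lstart = L["start"];
  IntegerVector llen = L["len"];
  IntegerMatrix sol(k, k);
  std::vector<std::vector<std::pair<int, int> > > stks(k + 1);
  for (int e = 0; e < pre_str.size(); ++e)
    stks[pre_str[e]].push_back(std::make_pair((int)pre_pos[e], (int)pre_len[e]));
  int pos = from;
  while (pos <= to) {
    if (bp[pos - 1] == 1) {
      if (leaf_rank[pos - 1] > 0) {
        const int p = sa[leaf_rank[pos - 1] - 1];
        if (codes[p - 1] > sep_max) {
          const int si = str_of(start_pos, p);
          if (start_pos[si - 1] == p) {  // prefix leaf of string si
            for (int j = 1; j <= k; ++j) {
              if (j == si || stks[j].empty()) continue;
              const int len = stks[j].back().second;
              if (len >= min_len) sol(j - 1, si - 1) = len;
            }
          }
        }
        pos += 2;  // skip the leaf's closing parenthesis
      } else {
        // internal open: push candidate entries of this node
        for (int t = lstart[pos - 1]; t < lstart[pos]; ++t) {
          const int e = lorder[t] - 1;
          const int si = str_of(start_pos, lpos[e]);
          stks[si].push_back(std::make_pair((int)lpos[e], (int)llen[e]));
        }
        ++pos;
      }
    } else {
      // internal close: pop this node's entries (leaf closes are skipped)
      const int v = match[pos - 1];
      for (int t = lstart[v] - 1; t >= lstart[v - 1]; --t) {
        const int e = lorder[t] - 1;
        const int si = str_of(start_pos, lpos[e]);
        if (stks[si].empty()) stop("stack underflow: invariant breach");
        stks[si].pop_back();
      }
      ++pos;
    }
  }
  return sol;
}

// ---------------------------------------------------------------------------
// Space optimization 1: no lists, no stacks.  For each requested string j,
// climb from its prefix leaf to the root; at each ancestor enumerate
// terminal-edged children and record, for every leaf beneath them, the
// string-suffix length as the overlap (first, i.e. deepest, ancestor wins).
// [[Rcpp::export]]
IntegerMatrix cpp_method1_stackless(IntegerVector codes, IntegerVector sa,
                                    List tree, IntegerVector isa,
                                    IntegerVector start_pos,
                                    IntegerVector str_end, int k, int sep_max,
                                    IntegerVector jobs, int min_len) {
  IntegerVector bp = tree["bp"];
  IntegerVector match = tree["match"];
  IntegerVector parentp = tree["parent"];
  IntegerVector depthp = tree["depth"];
  IntegerVector leaf_cum = tree["leaf_cum"];
  IntegerVector leaf_pos = tree["leaf_pos"];
  IntegerMatrix sol(k, k);
  for (int t = 0; t < jobs.size(); ++t) {
    const int j = jobs[t];
    const int leaf = leaf_pos[isa[start_pos[j - 1] - 1] - 1];
    for (int v = parentp[leaf - 1]; v != 0; v = parentp[v - 1]) {
      const int dv = depthp[v - 1];
      if (dv == 0) break;  // root: its terminal children are separator-only
      // children of v
      int c = v + 1;
      const int vclose = match[v - 1];
      while (c < vclose) {
        const int lm = leaf_cum[c - 2] + 1;  // leftmost leaf rank under c
        const int firstch = codes[sa[lm - 1] - 1 + dv];
        if (firstch <= sep_max) {  // terminal edge
          const int rm = leaf_cum[match[c - 1] - 1];
          for (int rr = lm; rr <= rm; ++rr) {
            const int p = sa[rr - 1];
            if (codes[p - 1] <= sep_max) continue;
            const int si = str_of(start_pos, p);
            if (si == j) continue;
            if (sol(si - 1, j - 1) != 0) continue;
            int val = str_end[si - 1] - p + 1;
            if (val > dv) val = dv;
            if (val >= min_len) sol(si - 1, j - 1) = val;
          }
        }
        c = match[c - 1] + 1;
      }
    }
  }
  return sol;
}

// ---------------------------------------------------------------------------
// Space optimization 2: keep stage 1's candidate lists, drop the stacks.
// For each requested string j, climb from its prefix leaf reading the
// ancestors' lists directly (deepest ancestor first).
// [[Rcpp::export]]
IntegerMatrix cpp_method1_lists(List tree, List L, IntegerVector isa,
                                IntegerVector start_pos, int k,
                                IntegerVector jobs, int min_len) {
  IntegerVector parentp = tree["parent"];
  IntegerVector leaf_pos = tree["leaf_pos"];
  IntegerVector lpos = L["pos"], llen = L["len"];
  IntegerVector lorder = L["order"], lstart = L["start"];
  IntegerMatrix sol(k, k);
  for (int t = 0; t < jobs.size(); ++t) {
    const int j = jobs[t];
    const int leaf = leaf_pos[isa[start_pos[j - 1] - 1] - 1];
    for (int v = parentp[leaf - 1]; v != 0; v = parentp[v - 1]) {
      for (int e0 = lstart[v - 1]; e0 < lstart[v]; ++e0) {
        const int e = lorder[e0] - 1;
        const int si = str_of(start_pos, lpos[e]);
        if (si == j || sol(si - 1, j - 1) != 0) continue;
        if (llen[e] >= min_len) sol(si - 1, j - 1) = llen[e];
      }
    }
  }
  return sol;
}

// ---------------------------------------------------------------------------
// Method 2: single scan over leaves in SA order (ranks [rfrom, rto]),
// skipping separator-start leaves.  Entries are popped lazily once the
// running LCP drops below their match length; a terminal leaf whose
// string-suffix prefixes the next suffix is pushed; a prefix leaf reports
// the stack tops, then scans following leaves sharing its whole string for
// full-length matches (the same-effective-parent exception).
// [[Rcpp::export]]
IntegerMatrix cpp_method2_scan(IntegerVector codes, IntegerVector sa,
                               IntegerVector lcp, List tree,
                               IntegerVector start_pos, IntegerVector str_end,
                               int k, int sep_max, int min_len, int rfrom,
                               int rto, IntegerVector pre_str,
                               IntegerVector pre_pos, IntegerVector pre_len) {
  IntegerVector parentp = tree["parent"];
  IntegerVector depthp = tree["depth"];
  IntegerVector leaf_pos = tree["leaf_pos"];
  const int n = sa.size();
  IntegerMatrix sol(k, k);
  std::vector<std::vector<std::pair<int, int> > > stks(k + 1);
  std::vector<std::pair<int, int> > glob;  // (string, match length), push order
  for (int e = 0; e < pre_str.size(); ++e) {
    stks[pre_str[e]].push_back(std::make_pair((int)pre_pos[e], (int)pre_len[e]));
    glob.push_back(std::make_pair((int)pre_str[e], (int)pre_len[e]));
  }
  bool first = true;
  for (int r = rfrom; r <= rto; ++r) {
    const int p = sa[r - 1];
    if (codes[p - 1] <= sep_max) continue;
    if (!first) {
      const int thr = lcp[r - 1];  // lcp(previous leaf, this leaf)
      while (!glob.empty() && glob.back().second > thr) {
        stks[glob.back().first].pop_back();
        glob.pop_back();
      }
    }
    first = false;
    const int si = str_of(start_pos, p);
    const int suf = str_end[si - 1] - p + 1;
    if (start_pos[si - 1] == p) {  // prefix leaf of string si
      for (int j = 1; j <= k; ++j) {
        if (j == si || stks[j].empty()) continue;
        const int len = stks[j].back().second;
        if (len >= min_len) sol(j - 1, si - 1) = len;
      }
      // exception: later suffixes equal to the whole string si
      int run = INT_MAX;
      for (int q = r + 1; q <= n; ++q) {
        if (lcp[q - 1] < run) run = lcp[q - 1];
        if (run < suf) break;
        const int qp = sa[q - 1];
        const int sj = str_of(start_pos, qp);
        if (sj != si && str_end[sj - 1] - qp + 1 == suf && suf >= min_len)
          sol(sj - 1, si - 1) = suf;
      }
    }
    // push if terminal and the string-suffix prefixes the next suffix
    const int par = parentp[leaf_pos[r - 1] - 1];
    if (par != 0 && depthp[par - 1] >= suf) {
      if (r < n && lcp[r] >= suf) {
        stks[si].push_back(std::make_pair(p, suf));
        glob.push_back(std::make_pair(si, suf));
      }
    }
  }
  return sol;
}

// ---------------------------------------------------------------------------
// Stack prefill for a worker starting at leaf rank start_rank: replays the
// entries the sequential leaf scan would hold on arrival.  Ancestors are
// visited root -> parent; for each, the leaves under terminal-edged
// children whose subtrees lie entirely before the start leaf are pushed.
// [[Rcpp::export]]
List cpp_prefill_leaf(IntegerVector codes, IntegerVector sa, List tree,
                      IntegerVector start_pos, IntegerVector str_end,
                      int sep_max, int start_rank) {
  IntegerVector match = tree["match"];
  IntegerVector parentp = tree["parent"];
  IntegerVector depthp = tree["depth"];
  IntegerVector leaf_cum = tree["leaf_cum"];
  IntegerVector leaf_pos = tree["leaf_pos"];
  const int start_bp = leaf_pos[start_rank - 1];
  std::vector<int> anc;
  for (int v = parentp[start_bp - 1]; v != 0; v = parentp[v - 1])
    anc.push_back(v);
  std::reverse(anc.begin(), anc.end());
  std::vector<int> ostr, opos, olen;
  for (size_t a = 0; a < anc.size(); ++a) {
    const int v = anc[a];
    const int dv = depthp[v - 1];
    int c = v + 1;
    const int vclose = match[v - 1];
    while (c < vclose) {
      const int cclose = match[c - 1];
      if (cclose < start_bp) {
        const int lm = leaf_cum[c - 2] + 1;
        const int firstch = codes[sa[lm - 1] - 1 + dv];
        if (firstch <= sep_max) {
          const int rm = leaf_cum[cclose - 1];
          for (int rr = lm; rr <= rm; ++rr) {
            const int p = sa[rr - 1];
            if (codes[p - 1] <= sep_max) continue;
            const int si = str_of(start_pos, p);
            ostr.push_back(si);
            opos.push_back(p);
            olen.push_back(str_end[si - 1] - p + 1);
          }
        }
      }
      c = cclose + 1;
    }
  }
  return List::create(_["str"] = IntegerVector(ostr.begin(), ostr.end()),
                      _["pos"] = IntegerVector(opos.begin(), opos.end()),
                      _["len"] = IntegerVector(olen.begin(), olen.end()));
}

// ---------------------------------------------------------------------------
// Stack prefill for a method-1 worker whose scan starts at the open
// parenthesis `snap`: the candidate-list entries of all strict ancestors,
// root first (exactly what the sequential BP scan pushed and has not yet
// popped at that point).
// [[Rcpp::export]]
List cpp_prefill_bp(List tree, List L, IntegerVector start_pos, int snap) {
  IntegerVector parentp = tree["parent"];
  IntegerVector lpos = L["pos"], llen = L["len"];
  IntegerVector lorder = L["order"], lstart = L["start"];
  std::vector<int> anc;
  for (int v = parentp[snap - 1]; v != 0; v = parentp[v - 1]) anc.push_back(v);
  std::reverse(anc.begin(), anc.end());
  std::vector<int> ostr, opos, olen;
  for (size_t a = 0; a < anc.size(); ++a) {
    const int v = anc[a];
    for (int t = lstart[v - 1]; t < lstart[v]; ++t) {
      const int e = lorder[t] - 1;
      ostr.push_back(str_of(start_pos, lpos[e]));
      opos.push_back(lpos[e]);
      olen.push_back(llen[e]);
    }
  }
  return List::create(_["str"] = IntegerVector(ostr.begin(), ostr.end()),
                      _["pos"] = IntegerVector(opos.begin(), opos.end()),
                      _["len"] = IntegerVector(olen.begin(), olen.end()));
}
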