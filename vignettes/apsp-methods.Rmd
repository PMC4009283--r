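---
title: "Methods: all-pairs suffix-prefix overlaps over a balanced-parentheses suffix tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-pairs suffix-prefix overlaps over a balanced-parentheses suffix tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsp)
```

## The problem

Given k strings $S_1,\dots,S_k$ over an ordered alphabet (here usually
$\Sigma = \{A,C,G,T\}$), the all-pairs suffix-prefix (APSP) problem asks,
for every **ordered** pair $(S_i, S_j)$ with $i \neq j$, for the largest
$r$ such that $S_i[\,|S_i|-r+1 .. |S_i|\,] = S_j[1..r]$.  The k×k matrix of
these lengths is the input to the layout stage of overlap-layout-consensus
assembly.  A brute-force solution costs $O(k^2 \ell^2)$ character work; the
index-based algorithms here run in $O(n \log n + k^2)$ for total input
length n, and the package keeps the brute-force solver
(`brute_force_apsp()`) as an independent oracle rather than as a fallback.

## The indexed text

`build_concat()` concatenates the strings into one text, each followed by
its own separator block, **including the last one**, so no string suffix is
also a suffix of the whole text.  Separators must sort below every sequence
character; the default alphabet is the 32 ASCII characters `!` through `@`,
all below `A`, so plain byte comparison gives the required order.  With c
separator characters, blocks are the base-c expansions of $i-1$ over that
alphabet, using the smallest m with $c^m \ge k$ digits (`sep_length()`).
The count is deliberately the pure capacity bound — 3 characters for up to
$200^3$ strings at c = 200 — with no extra guard digit: blocks of equal
width, distinct by construction and strictly increasing in input order, are
all the algorithms need.

Two arrays accompany the text: `start_pos` (where each string begins) and
`str_end`.  `string_id()` maps a text position to its string by binary
search in $O(\log k)$; positions inside separator blocks map to `NA`, a
sentinel rather than an error, because index traversals legitimately touch
separator-start suffixes.

## The index

`build_suffix_index()` computes

* the suffix array, by prefix doubling with counting-sort radix passes
  ($O(n \log n)$, no assumptions beyond positive integer codes);
* the LCP array, by Kasai's algorithm ($O(n)$);
* the suffix tree topology, by the standard stack-based lcp-interval
  construction ($O(n)$), emitted directly as the preorder
  balanced-parentheses (BP) sequence.

Internal nodes exist only where branching occurs; leaves appear in BP
preorder in suffix-array order, so the j-th `()` pair is the rank-j suffix.
BP length is at most $2(2n-1)$ positions.  Navigation — leaf select/rank,
parent, child by edge character, edge labels, string depth — is answered
from plain integer arrays keyed by BP position.  This is a functional,
not space-faithful, realization: the arrays use $O(n \log n)$ bits where a
compressed index would use $o(n)$-bit directories, an explicit trade of
memory for simplicity and speed at the problem sizes an R session handles.

**Virtual end-of-text sentinel.**  A suffix can be a prefix of another
suffix (under multi-character separator blocks this can happen for suffixes
starting *inside* a block; never for suffixes starting inside a string,
because a complete block cannot recur elsewhere in the text).  The tree
build orders leaves as if a unique smallest character terminated the text:
such a suffix becomes the first leaf under the node at its full depth, with
a zero-length edge.  For prefix-free inputs — every single-character
separator text, and every string-start suffix — the construction is the
textbook suffix tree, and parent/child string depths are strictly
increasing.  The overlap algorithms skip separator-start leaves entirely,
so the convention never influences results.

## Method 1: two-pass scan with candidate lists and stacks

A *terminal* leaf is one whose incoming edge begins with a separator: the
string-suffix starting at its text position p ends exactly at its parent.
Stage 1 (`fill_l_lists()`) walks the leaves once, in suffix-array order via
leaf select, and appends p to the candidate list $L_v$ of the leaf's
*effective parent* v — the closest ancestor whose own incoming edge is not
terminal.  With single-character separators v is simply the parent; with
m-character blocks, internal nodes can sit inside shared block prefixes and
the climb skips them.

Stage 2 (`run_method1()`) scans BP left to right with one stack per string:

* open parenthesis of an internal node v: push each $p \in L_v$, with its
  match length, onto the stack of `string_id(p)`;
* leaf at a string start (a *prefix leaf* of $S_j$): for every $i \neq j$,
  the top of stack i is `Sol[i, j]`; then skip the leaf's closing
  parenthesis;
* close parenthesis of an internal node: pop its $|L_v|$ entries.

Ancestors open before descendants, so each stack holds lengths increasing
from bottom to top and the top is the longest live match.  Two variants
avoid the quadratic-ish bookkeeping: `run_method1_stackless()` drops both
lists and stacks, walking each prefix leaf's ancestors and enumerating
terminal-edged children directly, and `run_method1_nostacks_with_lists()`
keeps stage 1 but reads the ancestors' lists during the walk.  In both, the
walk goes leaf to root, so the first value recorded for a pair is the
deepest — i.e. the longest — realizing the same maximum as the stack tops.

**Match lengths under multi-character separators.**  The value stored for a
terminal leaf is its *string-suffix length*, not the effective parent's
node depth.  The two coincide whenever the branching node sits exactly at
the end of the string-suffix — always true for single-character separators,
and in every worked example.  But when several strings share a suffix *and*
their separator blocks share a prefix, the only branching node can lie up
to m−1 characters inside the separator region; its depth would overstate
the overlap.  Using the string-suffix length is exact in all cases (and
equals `min(node depth, suffix length)`); the equivalence suite exercises
this with 2-character separator alphabets, where block collisions are
common.

## Method 2: single leaf-order scan

Two ordering facts drive the second algorithm: all k·m separator-start
suffixes occupy the first ranks of the suffix array, and a terminal suffix
sorts immediately before the longer suffixes it prefixes.  `run_method2()`
visits leaves in rank order (the non-separator leaves are contiguous), with
per-string stacks and a global stack recording push order:

1. **pop** every entry whose match length exceeds the LCP between the
   previous and current leaf (lazy, LCP-driven pops — this scan never
   visits internal parentheses, so tree exits are invisible);
2. **report** at a prefix leaf of $S_s$, as in method 1 — then apply the
   *exception*: a suffix of another string equal to the whole of $S_s$ may
   sort after the prefix leaf (their relative order is decided inside the
   separator blocks), so the scan reads forward while the running LCP still
   covers $|S_s|$ and reports a full-length overlap for every leaf whose
   string-suffix length is exactly $|S_s|$.  All such trailing leaves are
   scanned, not just the immediate next one: several strings can share the
   suffix $S_s$;
3. **push** the current leaf, if terminal with string-suffix length d, when
   the LCP to the next leaf is at least d.  The LCP test is used instead of
   a same-parent test because it remains correct when the next leaf lies
   deeper inside a sibling subtree; with single-character separators the
   two tests agree.

The output contract is bit-identical equality with method 1, enforced by a
shared test suite and by construction of the acceptance checks.

## Parallel execution

Both strategies decompose work so that each unit can run the sequential
algorithm unchanged, and merge by disjoint union: overlaps are only written
at a string's prefix leaf, and each prefix leaf belongs to exactly one
unit.  Output is therefore independent of worker count, unit count and
scheduling; `run_parallel()` is tested for bit-identical equality with the
sequential matrices across methods × strategies × worker counts.

* **Top-down** (`decompose_top_down()`): breadth-first expansion from the
  root into at least ⌈γP⌉ subtrees on the highest levels, skipping the
  root's separator children (their subtrees hold no string suffixes);
  shallowest nodes are expanded first until the target is met or only
  leaves remain.  Units are served from a queue — dynamic load balancing
  against skewed subtree sizes.
* **Bottom-up** (`decompose_bottom_up()`): equal contiguous shares of the
  non-separator leaf ranks (leaf-scan method and prefix-leaf variants) or
  of the BP positions, each boundary snapped to the next open parenthesis
  (two-pass method).

A worker starting mid-scan must see the stacks exactly as the sequential
run would have left them.  `prefill_stacks()` replays that state from the
tree instead of rescanning: ancestors of the starting leaf are visited root
first and the leaves under their terminal-edged children that precede the
start are pushed (lengths increase stack-bottom to top); for a BP starting
position, the candidate lists of the strict ancestors are pushed instead.
Candidate lists are always built in one pass before workers start and
shared read-only — this also covers the case of a minimum match length
smaller than the subtree-root depth, without restricting worker counts.
Both strategies use ⌈γP⌉ units (γ defaults to 1.5); with P = 1 everything
degenerates to the sequential scan.  Units run on forked workers via
`parallel::mclapply()` when P > 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_len` | 1 (report everything) | smallest overlap reported; shorter matches become 0. Applied at reporting time only, so all methods share identical internal state; raising it never increases an entry. For assembly-style filtering, values around 15 are typical. |
| `sep_alphabet` | `!`…`@` (32 chars) | separator characters, increasing byte order, all below the sequence alphabet. Block length m follows from k and c. |
| `threads` (P) | 1 | worker count. |
| `gamma` | 1.5 | unit oversubscription; more units than workers smooths skewed subtree sizes. Results never depend on it. |
| `strategy` | `bottomup` | work decomposition; `topdown` queues subtrees instead. |

## Synthetic data

`gen_random(k, total_len, seed)` emulates the shape of read sets used to
benchmark overlap computation: k strings over `{A,C,G,T}` with lengths
drawn by sampling k−1 cut points uniformly without replacement from
`1..total_len−1`, so lengths are random, at least 1, and sum exactly to
`total_len`.  `gen_planted(k, read_len, ov, seed)` tiles fixed-length reads
across a random mother sequence so consecutive reads overlap by exactly
`ov` — a positive control whose expected edges are known by construction.

Neither generator simulates sequencing error, quality values, strand
(reverse complements) or coverage structure, and uniform random DNA has far
less repeat structure than real genomes.  Passing tests on these inputs
demonstrates algorithmic correctness of exact overlap detection — every
matrix equals the character-comparison oracle — not robustness to
error-containing reads, which exact APSP by definition does not address.

## Numerical and design choices

* Character order is byte order (`utf8ToInt`); sorting in tests uses radix
  (C-locale) order to match.
* Self-overlaps are computed internally (a string's own full suffix sits on
  its stack at its prefix leaf) but never reported; the diagonal stays 0.
  "Every ordered pair" is read as $i \neq j$.
* Duplicate input strings are legal; each gets its own separator and the
  pair is reported at full length in both directions.
* `string_id()` returns `NA` (not an error) inside separator blocks.
* Ties and degenerate inputs: k = 1 yields an all-zero 1×1 matrix; a
  single-character text yields the two-node tree `(())`; empty sequences
  are rejected at construction.
* Stage-1 skipping generalizes "ignore the first k leaves" (single-char
  separators) to "ignore all k·m separator-start leaves".
* The suffix array builder is the package's own doubling implementation;
  the naive sort oracle is reserved for tests so the two stay independent.

## Problem sizes used by the test suite

Unit and property tests run on instances up to k = 20 and total length
2,000 (200 seeded random instances for the oracle-equivalence suite, and
200 random texts up to n = 500 for the index-structure suite), parallel
determinism on a fixed k = 10, n = 1,000 instance across
methods × strategies × P ∈ {1, 2, 4}, and one scale run at k = 1,000,
total length 10⁶, where both methods must agree and the edge list is
bounded by k(k−1).  These sizes keep the full suite under a minute on one
core while covering every code path, including multi-character separator
blocks (forced with 2-character alphabets).

## Known limitations

* Exact overlaps only: no mismatches, no approximate or reverse-complement
  overlaps, no quality awareness.
* The index stores explicit integer arrays (~10 machine words per text
  character across SA/LCP/BP annotations); it is time- and
  functionality-oriented, not a compressed index, so memory — not time —
  bounds the feasible n.
* Separators must sort below the sequence alphabet; alphabets occupying
  the full byte range would leave no room for them.
* Parallel speedups depend on hardware and are not asserted anywhere; only
  equality of results is.
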