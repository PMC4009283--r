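# apsp — all-pairs suffix-prefix overlaps

`apsp` computes, for every ordered pair of sequences (S<sub>i</sub>,
S<sub>j</sub>) in a set of k strings, the length of the longest suffix of
S<sub>i</sub> that equals a prefix of S<sub>j</sub> — the all-pairs
suffix-prefix (APSP) problem.  APSP is the overlap-detection step of
overlap-layout-consensus genome assembly: reads are the strings, and the
overlap lengths are the edge weights of the assembly's overlap graph.  The
package is aimed at people who need exact overlap matrices for read sets or
other string collections, and at anyone studying suffix-tree algorithms over
succinct-style representations.

## How it works

All k sequences are concatenated into one text, each followed by a distinct
separator block that sorts below the sequence alphabet
(`AAC#GAG$TTA%`-style; with c separator characters, blocks of
m = ⌈log<sub>c</sub> k⌉ characters encode up to c^m sequences — 3 characters
cover 200³ = 8,000,000 strings).  The generalized suffix tree of this text is
built from its suffix array (prefix-doubling radix sort) and LCP array
(Kasai) and is navigated through its preorder **balanced-parentheses (BP)**
sequence: 2 bits per node, with rank/select over leaf pairs `()`, parent,
child, edge-character and string-depth operations answered from per-position
arrays.

Two algorithms produce the k×k matrix `Sol`, where `Sol[i, j]` is the longest
suffix-prefix match of the pair (S<sub>i</sub>, S<sub>j</sub>):

* **Method 1 (two-pass):** a leaf pass stores each *terminal* leaf (a
  complete string-suffix, recognized by a separator-initial edge) in the
  candidate list L<sub>v</sub> of its effective parent v; a second
  left-to-right BP scan pushes list entries onto one stack per string at
  every open parenthesis, reports all stack tops when it reaches a *prefix
  leaf* (a leaf whose path spells a whole string), and pops at every close.
  Two space-optimized variants (`1a`: no lists, no stacks; `1b`: lists
  without stacks) walk ancestors from each prefix leaf instead.
* **Method 2 (leaf scan):** a single pass over the leaves in suffix-array
  order, maintaining the stacks directly with LCP-driven lazy pops, plus a
  forward scan handling suffixes equal to an entire string that sort after
  its prefix leaf.

Both parallel strategies — top-down subtree decomposition through a work
queue, and bottom-up equal splitting of the leaves/BP with stack prefilling —
return matrices bit-identical to the sequential run for every worker count.
A brute-force solver and seeded read-set generators support verification
end to end.

## Worked example

```r
library(apsp)
reads <- string_set(c("TTACGGA", "CGGATCA", "ATCATTG"),
                    c("r1", "r2", "r3"))
sol <- apsp_overlaps(reads, min_len = 2)
sol
#> overlap_matrix: 3 x 3 (rows: suffix source, columns: prefix target), min_len = 2
#>          prefix_of
#> suffix_of r1 r2 r3
#>        r1  0  4  0
#>        r2  0  0  4
#>        r3  0  0  0
overlap_edges(sol)
#>   src_id dst_id overlap_len
#> 1     r1     r2           4
#> 2     r2     r3           4
```

The 4-character suffix `CGGA` of `r1` is a prefix of `r2`, and `ATCA` chains
`r2` into `r3` — the two edges an assembler would follow; all other ordered
pairs overlap by less than `min_len = 2` and are reported as 0.  The same
computation from the shell, via the bundled front end:

```sh
Rscript inst/scripts/apsp.R simulate --k 100 --total-len 50000 --seed 7 --out reads.fasta
Rscript inst/scripts/apsp.R overlap --in reads.fasta --method 2 --min-len 15 --out overlaps.tsv
Rscript inst/scripts/apsp.R verify --in reads.fasta   # all methods + brute force
```

Lower-level building blocks are exported too:

```r
ct  <- build_concat(string_set(c("AAC", "GAG", "TTA")), c("#", "$", "%"))
idx <- build_suffix_index(ct)   # suffix array, LCP, BP tree
bp_string(idx)
#> [1] "(()()()(()()()())()(()())(()()))"
```

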