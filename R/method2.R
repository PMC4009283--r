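#' All-pairs suffix-prefix overlaps: single leaf-order scan
#'
#' Exploits two orderings: separator-start suffixes occupy the first ranks
#' of the suffix array, and a terminal suffix (a complete string-suffix)
#' sorts immediately before the longer suffixes it prefixes.  The scan
#' visits leaves in suffix-array order, skipping separator-start leaves, and
#' maintains per-string stacks plus one global stack recording push order:
#'
#' 1. *Pop*: entries whose match length exceeds the LCP between the previous
#'    and the current leaf can no longer prefix the current suffix and are
#'    popped (lazy, LCP-driven -- this scan never visits internal nodes).
#' 2. *Report*: at a prefix leaf of string `s`, the top of every stack
#'    `j != s` is the longest overlap of `(j, s)`.  One exception needs a
#'    forward look: a suffix of another string equal to *all* of `s` can
#'    sort after the prefix leaf (its separator block decides the order), so
#'    following leaves are scanned while their running LCP still covers
#'    `|s|`, and every one whose string-suffix length is exactly `|s|`
#'    reports a full-length overlap.
#' 3. *Push*: a terminal leaf whose string-suffix (length `d`) prefixes the
#'    next suffix (`lcp >= d`) pushes `(position, d)`.
#'
#' Output is identical to [run_method1()].
#'
#' @inheritParams run_method1
#' @return A k-by-k `overlap_matrix`, identical to [run_method1()]'s.
#' @examples
#' ct <- build_concat(string_set(c("ACG", "GACG")),
#'                    sep_alphabet = c("#", "$"))
#' run_method2(build_suffix_index(ct))
#' @export
run_method2 <- function(idx, min_len = 1L) {
  stopifnot(inherits(idx, "suffix_index"))
  min_len <- check_min_len(min_len)
  ct <- idx$ct
  sol <- cpp_method2_scan(ct$codes, idx$sa, idx$lcp, unclass(idx),
                          ct$start_pos, ct$str_end, ct$k, ct$sep_max_code,
                          min_len, 1L, idx$n,
                          integer(0), integer(0), integer(0))
  new_overlap_matrix(sol, ct$ids, min_len)
}
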