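#' Candidate lists: stage 1 of the two-pass method
#'
#' One pass over the leaves in suffix-array order (via leaf select).  Leaves
#' whose suffix starts inside a separator block are skipped (they carry no
#' string suffix).  Every remaining leaf whose incoming edge is terminal --
#' its label starts with a separator character, so the string-suffix ends
#' exactly at the parent -- contributes its text position to the candidate
#' list (`L` list) of its *effective parent*: the closest ancestor whose own
#' incoming edge is not terminal.  With single-character separators that is
#' always the direct parent; with multi-character separator blocks, internal
#' nodes can sit inside shared block prefixes and the climb skips them.
#'
#' @param idx a [build_suffix_index()] result built from a `concat_text`.
#' @return An object of class `l_lists`: parallel vectors `owner` (BP open
#'   position of the effective parent), `pos` (1-based text position) and
#'   `len` (the string-suffix length, i.e. the match length the owner
#'   reports), plus grouping vectors `order`/`start` for per-node access.
#' @examples
#' ct <- build_concat(string_set(c("AAC", "GAG", "TTA")),
#'                    sep_alphabet = c("#", "$", "%"))
#' L <- fill_l_lists(build_suffix_index(ct))
#' l_list(L, 8)  # text position 11 below the root's fourth child
#' @export
fill_l_lists <- function(idx) {
  stopifnot(inherits(idx, "suffix_index"))
  ct <- idx$ct
  L <- cpp_fill_l(ct$codes, idx$sa, unclass(idx), ct$start_pos, ct$str_end,
                  ct$sep_max_code)
  class(L) <- "l_lists"
  L
}

#' @export
print.l_lists <- function(x, ...) {
  cat(sprintf("l_lists: %d candidate position(s) on %d node(s)\n",
              length(x$pos), length(unique(x$owner))))
  invisible(x)
}

#' Read one node's candidate list
#'
#' @param L a [fill_l_lists()] result.
#' @param v BP open position of an internal node.
#' @return Integer vector of text positions (leaf-scan order); empty if none.
#' @export
l_list <- function(L, v) {
  stopifnot(inherits(L, "l_lists"))
  v <- as.integer(v)
  stopifnot(length(v) == 1L, v >= 1L, v < length(L$start))
  sel <- L$order[seq_len(L$start[v + 1L] - L$start[v]) + L$start[v]]
  L$pos[sel]
}

#' All-pairs suffix-prefix overlaps: two-pass method
#'
#' Stage 1 fills per-node candidate lists ([fill_l_lists()]).  Stage 2 scans
#' the BP sequence left to right, maintaining one stack per string: opening
#' an internal node pushes each of its candidate positions (with its match
#' length) onto the stack of the string the position belongs to; reaching a
#' leaf that starts a string `i` reports, for every `j != i`, the top of
#' stack `j` as the longest suffix-prefix overlap of `(j, i)` (0 if the
#' stack is empty or the length is below `min_len`), then hops over the
#' leaf's closing parenthesis; closing an internal node pops its entries.
#' Ancestors push before descendants, so stack tops are the deepest (hence
#' longest) matches.  Self-overlaps are never reported.
#'
#' @param idx a [build_suffix_index()] result built from a `concat_text`.
#' @param min_len smallest overlap length reported (default 1); shorter
#'   matches are reported as 0.  Applied at reporting time only.
#' @param l_lists optional precomputed [fill_l_lists()] result.
#' @return A k-by-k integer `overlap_matrix`; entry `[i, j]` is the length
#'   of the longest suffix of sequence `i` equal to a prefix of sequence
#'   `j`, with the diagonal left at 0.
#' @examples
#' ct <- build_concat(string_set(c("AAC", "GAG", "TTA")),
#'                    sep_alphabet = c("#", "$", "%"))
#' run_method1(build_suffix_index(ct))
#' @export
run_method1 <- function(idx, min_len = 1L, l_lists = NULL) {
  stopifnot(inherits(idx, "suffix_index"))
  min_len <- check_min_len(min_len)
  if (is.null(l_lists)) l_lists <- fill_l_lists(idx)
  ct <- idx$ct
  sol <- cpp_method1_scan(ct$codes, idx$sa, unclass(idx), unclass(l_lists),
                          ct$start_pos, ct$str_end, ct$k, ct$sep_max_code,
                          1L, length(idx$bp),
                          integer(0), integer(0), integer(0), min_len)
  new_overlap_matrix(sol, ct$ids, min_len)
}

#' Two-pass method, space optimization 1: no lists, no stacks
#'
#' For each string's prefix leaf, climb to the root; at every ancestor,
#' enumerate the children reached by a terminal edge and record, for each
#' leaf below them, the string-suffix length as the overlap.  The walk
#' visits the deepest ancestor first, so the first value recorded for a pair
#' is the longest.  Output is identical to [run_method1()].
#'
#' @inheritParams run_method1
#' @return A k-by-k `overlap_matrix`, identical to [run_method1()]'s.
#' @export
run_method1_stackless <- function(idx, min_len = 1L) {
  stopifnot(inherits(idx, "suffix_index"))
  min_len <- check_min_len(min_len)
  ct <- idx$ct
  sol <- cpp_method1_stackless(ct$codes, idx$sa, unclass(idx), idx$isa,
                               ct$start_pos, ct$str_end, ct$k,
                               ct$sep_max_code, seq_len(ct$k), min_len)
  new_overlap_matrix(sol, ct$ids, min_len)
}

#' Two-pass method, space optimization 2: lists without stacks
#'
#' Keeps stage 1 as is, but instead of a full BP scan with stacks, each
#' string's prefix leaf climbs its ancestors and reads their candidate lists
#' directly (deepest first).  Output is identical to [run_method1()].
#'
#' @inheritParams run_method1
#' @return A k-by-k `overlap_matrix`, identical to [run_method1()]'s.
#' @export
run_method1_nostacks_with_lists <- function(idx, min_len = 1L,
                                            l_lists = NULL) {
  stopifnot(inherits(idx, "suffix_index"))
  min_len <- check_min_len(min_len)
  if (is.null(l_lists)) l_lists <- fill_l_lists(idx)
  ct <- idx$ct
  sol <- cpp_method1_lists(unclass(idx), unclass(l_lists), idx$isa,
                           ct$start_pos, ct$k, seq_len(ct$k), min_len)
  new_overlap_matrix(sol, ct$ids, min_len)
}
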