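#' Suffix array of a text
#'
#' Positions of the lexicographically sorted suffixes, by prefix doubling
#' with radix sort (O(n log n)).  Characters compare by byte code, so a
#' separator alphabet below `A` sorts before DNA characters.
#'
#' @param text a single character string, or a `concat_text`.
#' @return Integer vector `sa` of length `n`: `sa[r]` is the 1-based start of
#'   the r-th smallest suffix.
#' @examples
#' build_sa("AA%")  # 3 2 1
#' @export
build_sa <- function(text) {
  codes <- text_codes(text)
  cpp_build_sa(codes)
}

#' LCP array of a text given its suffix array
#'
#' `lcp[1] = 0`; `lcp[r]` is the length of the longest common prefix of the
#' suffixes of rank `r - 1` and `r`.  Kasai's O(n) algorithm.
#'
#' @inheritParams build_sa
#' @param sa the suffix array of `text`.
#' @return Integer vector of length `n`.
#' @examples
#' build_lcp("AA%", build_sa("AA%"))  # 0 0 1
#' @export
build_lcp <- function(text, sa) {
  codes <- text_codes(text)
  cpp_build_lcp(codes, as.integer(sa))
}

text_codes <- function(text) {
  if (inherits(text, "concat_text")) return(text$codes)
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  utf8ToInt(text)
}

#' Build the generalized suffix tree index
#'
#' Constructs the suffix array and LCP array of the concatenated text and,
#' from them, the suffix tree's preorder balanced-parentheses (BP) sequence
#' with per-node annotations: string depth, parent, matching parenthesis and
#' leaf ranks.  Internal nodes exist exactly where branching occurs; leaves
#' appear in BP preorder in suffix-array order, one per suffix.
#'
#' Navigation is answered from plain precomputed arrays keyed by BP position
#' (the succinct o(n) rank/select machinery of compressed implementations is
#' deliberately not replicated; the contract here is the answers, not the
#' bit-level representation).
#'
#' @param ct a [build_concat()] result (or a bare character string, for
#'   experimentation; separator-aware operations then treat it as one
#'   sequence with no separators).
#' @return An object of class `suffix_index` bundling `sa`, `lcp`, `isa`,
#'   `bp` (0/1 integer vector, 1 = open), `match`, `parent`, `depth`,
#'   `leaf_rank`, `leaf_cum`, `leaf_pos`, `n`, and the originating `ct`.
#' @examples
#' ct <- build_concat(string_set(c("AAC", "GAG", "TTA")),
#'                    sep_alphabet = c("#", "$", "%"))
#' idx <- build_suffix_index(ct)
#' bp_string(idx)
#' @export
build_suffix_index <- function(ct) {
  if (is.character(ct)) {
    txt <- ct
    ct <- structure(list(
      text = txt, codes = utf8ToInt(txt), start_pos = 1L,
      str_end = nchar(txt), sep_alphabet = character(0), sep_len = 0L,
      sep_max_code = 0L, k = 1L, n = nchar(txt), ids = "seq1"
    ), class = "concat_text")
  }
  stopifnot(inherits(ct, "concat_text"))
  sa <- cpp_build_sa(ct$codes)
  lcp <- cpp_build_lcp(ct$codes, sa)
  tree <- cpp_build_tree(sa, lcp)
  isa <- integer(ct$n)
  isa[sa] <- seq_len(ct$n)
  structure(c(list(sa = sa, lcp = lcp, isa = isa, n = ct$n, ct = ct), tree),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("suffix_index: n = %d suffixes, %d tree nodes, BP length %d\n",
              x$n, x$n_nodes, length(x$bp)))
  invisible(x)
}

#' BP sequence as a parenthesis string
#'
#' @param idx a [build_suffix_index()] result.
#' @return The balanced-parentheses preorder encoding, e.g. `"(()())"`.
#' @export
bp_string <- function(idx) {
  paste(ifelse(idx$bp == 1L, "(", ")"), collapse = "")
}

check_bp_pos <- function(idx, i) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > length(idx$bp))
    stop("BP position out of range")
  i
}

#' Navigation over the balanced-parentheses suffix tree
#'
#' These realize the classic BP tree operations: `st_select_leaf(idx, j)`
#' gives the BP position of the j-th leaf "()" (leaves enumerate in
#' suffix-array order), `st_rank_leaf(idx, i)` counts leaves at positions
#' `<= i`, and `st_next_leaf(idx, i)` steps to the following leaf (or `NA`
#' after the last).  `st_parent()` returns the open position of the nearest
#' strictly enclosing node (`NA` for the root), `st_is_leaf()` tests for a
#' "()" pair, `st_is_open()` for an open parenthesis.  `st_node_depth()`
#' returns the string depth (root 0; a leaf's depth is its suffix length)
#' and `st_leaf_text_pos()` the 1-based text position of a leaf's suffix.
#'
#' @param idx a [build_suffix_index()] result.
#' @param j leaf rank in `1..n`.
#' @param i,v 1-based BP position (for `st_parent`, `st_node_depth`,
#'   `st_edge_char`, `st_child` and `st_leaf_text_pos` it must be an open
#'   parenthesis).
#' @return See each operation's description.
#' @name st_navigation
NULL

#' @rdname st_navigation
#' @export
st_select_leaf <- function(idx, j) {
  j <- as.integer(j)
  if (any(is.na(j)) || any(j < 1L) || any(j > idx$n))
    stop("leaf rank out of range")
  idx$leaf_pos[j]
}

#' @rdname st_navigation
#' @export
st_rank_leaf <- function(idx, i) {
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > length(idx$bp)))
    stop("BP position out of range")
  idx$leaf_cum[i]
}

#' @rdname st_navigation
#' @export
st_next_leaf <- function(idx, i) {
  i <- check_bp_pos(idx, i)
  # rank of the first leaf strictly after position i
  r <- idx$leaf_cum[i] + 1L
  if (r > idx$n) return(NA_integer_)
  idx$leaf_pos[r]
}

#' @rdname st_navigation
#' @export
st_parent <- function(idx, v) {
  v <- check_bp_pos(idx, v)
  if (idx$bp[v] != 1L) stop("not an open parenthesis")
  p <- idx$parent[v]
  if (p == 0L) NA_integer_ else p
}

#' @rdname st_navigation
#' @export
st_is_leaf <- function(idx, i) {
  i <- check_bp_pos(idx, i)
  idx$bp[i] == 1L && idx$leaf_rank[i] > 0L
}

#' @rdname st_navigation
#' @export
st_is_open <- function(idx, i) {
  i <- check_bp_pos(idx, i)
  idx$bp[i] == 1L
}

#' @rdname st_navigation
#' @export
st_node_depth <- function(idx, v) {
  v <- check_bp_pos(idx, v)
  if (idx$bp[v] != 1L) stop("not an open parenthesis")
  idx$depth[v]
}

#' @rdname st_navigation
#' @export
st_leaf_text_pos <- function(idx, v) {
  v <- check_bp_pos(idx, v)
  if (!st_is_leaf(idx, v)) stop("not a leaf position")
  idx$sa[idx$leaf_rank[v]]
}

# leftmost leaf rank in the subtree rooted at open position v
leftmost_leaf_rank <- function(idx, v) {
  if (idx$leaf_rank[v] > 0L) idx$leaf_rank[v] else idx$leaf_cum[v] + 1L
}

#' @rdname st_navigation
#' @param d 1-based offset into the edge label.
#' @export
st_edge_char <- function(idx, v, d) {
  v <- check_bp_pos(idx, v)
  if (idx$bp[v] != 1L) stop("not an open parenthesis")
  p <- idx$parent[v]
  if (p == 0L) stop("the root has no incoming edge")
  d <- as.integer(d)
  elen <- idx$depth[v] - idx$depth[p]
  if (length(d) != 1L || is.na(d) || d < 1L || d > elen)
    stop("edge offset out of range")
  pos <- idx$sa[leftmost_leaf_rank(idx, v)] + idx$depth[p] + d - 1L
  substr(idx$ct$text, pos, pos)
}

#' @rdname st_navigation
#' @param ch single character: the first character of the child's edge.
#' @export
st_child <- function(idx, v, ch) {
  v <- check_bp_pos(idx, v)
  if (!st_is_open(idx, v) || st_is_leaf(idx, v))
    stop("child lookup needs an internal node")
  stopifnot(is.character(ch), length(ch) == 1L, nchar(ch) == 1L)
  code <- utf8ToInt(ch)
  dv <- idx$depth[v]
  cpos <- v + 1L
  close <- idx$match[v]
  while (cpos < close) {
    f <- idx$ct$codes[idx$sa[leftmost_leaf_rank(idx, cpos)] + dv]
    if (f == code) return(cpos)
    if (f > code) return(NA_integer_)  # children sort by first edge character
    cpos <- idx$match[cpos] + 1L
  }
  NA_integer_
}

#' Children of an internal node
#'
#' @param idx a [build_suffix_index()] result.
#' @param v open BP position of an internal node.
#' @return Integer vector of the children's open BP positions, left to right.
#' @export
st_children <- function(idx, v) {
  v <- check_bp_pos(idx, v)
  if (!st_is_open(idx, v)) stop("not an open parenthesis")
  out <- integer(0)
  cpos <- v + 1L
  close <- idx$match[v]
  while (cpos < close) {
    out <- c(out, cpos)
    cpos <- idx$match[cpos] + 1L
  }
  out
}

#' Minimum LCP between two leaves
#'
#' The length of the longest common prefix of the suffixes at leaf ranks
#' `rank_a < rank_b`: the minimum of the LCP array over ranks
#' `rank_a + 1 .. rank_b` (a single lookup for adjacent leaves).
#'
#' @param idx a [build_suffix_index()] result.
#' @param rank_a,rank_b leaf ranks with `rank_a < rank_b`.
#' @return Integer.
#' @export
st_lcp_between <- function(idx, rank_a, rank_b) {
  rank_a <- as.integer(rank_a)
  rank_b <- as.integer(rank_b)
  stopifnot(rank_a >= 1L, rank_b <= idx$n, rank_a < rank_b)
  min(idx$lcp[(rank_a + 1L):rank_b])
}
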