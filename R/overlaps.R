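#' All-pairs suffix-prefix overlaps
#'
#' One-call interface: concatenates the sequences with separators, builds
#' the suffix index and runs the chosen algorithm, optionally over a
#' parallel work plan.  Entry `[i, j]` of the result is the length of the
#' longest suffix of sequence `i` equal to a prefix of sequence `j`
#' (0 below `min_len`; the diagonal is not reported).
#'
#' @param x a [string_set()], a character vector of sequences, or the path
#'   to a FASTA file.
#' @param min_len smallest overlap length reported (default 1; overlap
#'   filtering for assembly typically uses larger values, e.g. 15).
#' @param method `"2"` (single leaf-order scan, default), `"1"` (two-pass
#'   BP scan with stacks), `"1a"` (stackless variant) or `"1b"` (list-only
#'   variant).  All produce identical matrices.
#' @param threads worker count; 1 runs sequentially.
#' @param strategy work decomposition for `threads > 1`: `"bottomup"`
#'   (equal linear shares with stack prefilling) or `"topdown"` (subtree
#'   queue).
#' @param gamma oversubscription factor for the decomposition.
#' @param sep_alphabet separator characters; defaults to
#'   [default_sep_alphabet()].
#' @return A k-by-k integer `overlap_matrix`.
#' @examples
#' apsp_overlaps(c(s1 = "ACG", s2 = "GACG"))
#' @export
apsp_overlaps <- function(x, min_len = 1L, method = c("2", "1", "1a", "1b"),
                          threads = 1L, strategy = c("bottomup", "topdown"),
                          gamma = 1.5, sep_alphabet = default_sep_alphabet()) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  ss <- if (inherits(x, "string_set")) x
        else if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x)
        else string_set(x)
  ct <- build_concat(ss, sep_alphabet)
  idx <- build_suffix_index(ct)
  threads <- max(1L, as.integer(threads))
  if (threads == 1L) {
    switch(method,
           "1" = run_method1(idx, min_len),
           "1a" = run_method1_stackless(idx, min_len),
           "1b" = run_method1_nostacks_with_lists(idx, min_len),
           "2" = run_method2(idx, min_len))
  } else {
    plan <- if (strategy == "topdown") decompose_top_down(idx, threads, gamma)
            else decompose_bottom_up(idx, threads, gamma, method)
    run_parallel(idx, method, plan, min_len)
  }
}
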