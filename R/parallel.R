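#' Top-down work decomposition
#'
#' Breadth-first expansion from the root into at least `ceiling(gamma * P)`
#' disjoint subtrees occupying the highest levels of the tree.  The root's
#' separator-edged children are ignored (their leaves carry no string
#' suffixes); the shallowest unit is expanded into its children until the
#' target count is reached or only leaves remain.  Units are held in a queue
#' and handed to workers dynamically, the usual load-balancing device.
#'
#' @param idx a [build_suffix_index()] result.
#' @param P worker count (>= 1).
#' @param gamma oversubscription factor: more units than workers keeps all
#'   workers busy when subtree sizes are skewed (default 1.5).
#' @return A `work_plan` with `strategy = "topdown"`, `partition = "subtree"`
#'   and one unit per subtree root (BP open position + derived BP/leaf-rank
#'   ranges).
#' @export
decompose_top_down <- function(idx, P, gamma = 1.5) {
  stopifnot(inherits(idx, "suffix_index"), P >= 1, gamma > 0)
  target <- max(1L, as.integer(ceiling(gamma * P)))
  ct <- idx$ct
  root <- 1L
  queue <- integer(0)
  final <- integer(0)
  if (target == 1L) {
    queue <- root
  } else {
    # non-terminal children of the root
    for (cpos in st_children(idx, root)) {
      f <- ct$codes[idx$sa[leftmost_leaf_rank(idx, cpos)]]
      if (f > ct$sep_max_code) queue <- c(queue, cpos)
    }
    if (length(queue) == 0L) queue <- root  # degenerate: no string suffixes
    while (length(queue) + length(final) < target && length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (st_is_leaf(idx, v)) {
        final <- c(final, v)
      } else {
        queue <- c(queue, st_children(idx, v))
      }
    }
  }
  units <- lapply(c(final, queue), function(v) unit_from_subtree(idx, v))
  structure(list(strategy = "topdown", partition = "subtree", units = units,
                 gamma = gamma, P = as.integer(P)),
            class = "work_plan")
}

unit_from_subtree <- function(idx, v) {
  close <- idx$match[v]
  list(root = v, bp_from = v, bp_to = close,
       rank_from = leftmost_leaf_rank(idx, v),
       rank_to = idx$leaf_cum[close])
}

#' Bottom-up work decomposition
#'
#' Splits the work linearly instead of by subtree, so shares are of equal
#' size by construction.  For the leaf-scan method (and the prefix-leaf
#' variants) the non-separator leaf ranks are cut into contiguous chunks;
#' for the two-pass BP-scan method the BP positions are cut and each
#' boundary is snapped forward to the next open parenthesis.  Each worker's
#' stacks are prefilled with exactly the entries the sequential scan would
#' hold on arrival at its starting point ([prefill_stacks()]).
#'
#' @inheritParams decompose_top_down
#' @param method which algorithm the plan will drive: `"1"` partitions BP
#'   positions; `"2"`, `"1a"`, `"1b"` partition leaf ranks.
#' @return A `work_plan` with `strategy = "bottomup"`.
#' @export
decompose_bottom_up <- function(idx, P, gamma = 1.5,
                                method = c("2", "1", "1a", "1b")) {
  stopifnot(inherits(idx, "suffix_index"), P >= 1, gamma > 0)
  method <- match.arg(method)
  target <- max(1L, as.integer(ceiling(gamma * P)))
  if (method == "1") {
    len <- length(idx$bp)
    bounds <- unique(floor(seq(1L, len + 1L, length.out = target + 1L)))
    snaps <- integer(0)
    for (b in head(bounds, -1L)) {
      s <- b
      while (s <= len && idx$bp[s] != 1L) s <- s + 1L
      if (s <= len) snaps <- c(snaps, s)
    }
    snaps <- unique(snaps)
    units <- lapply(seq_along(snaps), function(i) {
      to <- if (i < length(snaps)) snaps[i + 1L] - 1L else len
      list(root = NA_integer_, bp_from = snaps[i], bp_to = to,
           rank_from = idx$leaf_cum[snaps[i]] +
             if (idx$leaf_rank[snaps[i]] > 0L) 0L else 1L,
           rank_to = idx$leaf_cum[to])
    })
    partition <- "bp"
  } else {
    r0 <- idx$ct$k * idx$ct$sep_len + 1L  # first non-separator leaf rank
    n <- idx$n
    if (r0 > n) stop("no string suffixes to scan")
    bounds <- unique(floor(seq(r0, n + 1L, length.out = target + 1L)))
    units <- lapply(seq_len(length(bounds) - 1L), function(i) {
      list(root = NA_integer_, bp_from = NA_integer_, bp_to = NA_integer_,
           rank_from = bounds[i], rank_to = bounds[i + 1L] - 1L)
    })
    partition <- "leaf"
  }
  structure(list(strategy = "bottomup", partition = partition, units = units,
                 gamma = gamma, P = as.integer(P)),
            class = "work_plan")
}

#' @export
print.work_plan <- function(x, ...) {
  cat(sprintf("work_plan: %s strategy, %d unit(s) (%s partition), P = %d, gamma = %g\n",
              x$strategy, length(x$units), x$partition, x$P, x$gamma))
  invisible(x)
}

#' Replay the stack state at a scan starting point
#'
#' A worker that starts mid-scan must see the per-string stacks exactly as
#' the sequential algorithm would have left them on arrival.  For a leaf
#' rank, ancestors of the start leaf are visited root first and, for each,
#' the leaves under terminal-edged children whose subtrees precede the start
#' leaf are pushed (so lengths increase bottom to top).  For a BP open
#' position (two-pass method), the candidate-list entries of all strict
#' ancestors are pushed, root first.
#'
#' @param idx a [build_suffix_index()] result.
#' @param start a leaf rank (default interpretation) or, with
#'   `type = "bp"`, the open BP position a two-pass worker starts at.
#' @param type `"leaf"` or `"bp"`.
#' @param l_lists candidate lists, required for `type = "bp"`.
#' @return A data frame (`string`, `pos`, `len`), bottom of stack first.
#' @export
prefill_stacks <- function(idx, start, type = c("leaf", "bp"), l_lists = NULL) {
  stopifnot(inherits(idx, "suffix_index"))
  type <- match.arg(type)
  ct <- idx$ct
  start <- as.integer(start)
  if (type == "leaf") {
    stopifnot(start >= 1L, start <= idx$n)
    pre <- cpp_prefill_leaf(ct$codes, idx$sa, unclass(idx), ct$start_pos,
                            ct$str_end, ct$sep_max_code, start)
  } else {
    if (is.null(l_lists)) l_lists <- fill_l_lists(idx)
    stopifnot(start >= 1L, start <= length(idx$bp), idx$bp[start] == 1L)
    pre <- cpp_prefill_bp(unclass(idx), unclass(l_lists), ct$start_pos, start)
  }
  data.frame(string = pre$str, pos = pre$pos, len = pre$len)
}

#' Run an overlap method over a work plan
#'
#' Executes the chosen algorithm unit by unit and merges the partial
#' matrices.  Overlaps are only written at a string's prefix leaf, and every
#' prefix leaf belongs to exactly one unit, so the merge is a disjoint
#' union and the result is identical to the sequential run regardless of
#' `P`, `gamma`, strategy or scheduling.  Candidate lists for the two-pass
#' method are built once, up front, and shared read-only.  With `P > 1` the
#' units are executed on forked workers (`parallel::mclapply`); with
#' `P = 1`, sequentially.
#'
#' @param idx a [build_suffix_index()] result.
#' @param method `"1"` (two-pass), `"1a"` (stackless), `"1b"` (lists, no
#'   stacks) or `"2"` (leaf scan).
#' @param plan a [decompose_top_down()] or [decompose_bottom_up()] plan.
#'   Method `"1"` needs a subtree or BP partition; the prefix-leaf walks
#'   (`"1a"`, `"1b"`) and the leaf scan (`"2"`) accept any plan.
#' @param min_len smallest overlap length reported.
#' @return A k-by-k `overlap_matrix`, identical to the sequential result.
#' @export
run_parallel <- function(idx, method = c("2", "1", "1a", "1b"), plan,
                         min_len = 1L) {
  stopifnot(inherits(idx, "suffix_index"), inherits(plan, "work_plan"))
  method <- match.arg(method)
  min_len <- check_min_len(min_len)
  ct <- idx$ct
  if (method == "1" && plan$partition == "leaf")
    stop("method 1 scans BP positions; use a subtree or BP partition")
  L <- if (method %in% c("1", "1b")) fill_l_lists(idx) else NULL
  tree <- unclass(idx)
  run_unit <- function(u) {
    if (method == "1") {
      pre <- cpp_prefill_bp(tree, unclass(L), ct$start_pos, u$bp_from)
      cpp_method1_scan(ct$codes, idx$sa, tree, unclass(L), ct$start_pos,
                       ct$str_end, ct$k, ct$sep_max_code, u$bp_from, u$bp_to,
                       pre$str, pre$pos, pre$len, min_len)
    } else if (method == "2") {
      r0 <- max(u$rank_from, ct$k * ct$sep_len + 1L)
      if (r0 > u$rank_to) return(matrix(0L, ct$k, ct$k))
      pre <- cpp_prefill_leaf(ct$codes, idx$sa, tree, ct$start_pos,
                              ct$str_end, ct$sep_max_code, r0)
      cpp_method2_scan(ct$codes, idx$sa, idx$lcp, tree, ct$start_pos,
                       ct$str_end, ct$k, ct$sep_max_code, min_len,
                       r0, u$rank_to, pre$str, pre$pos, pre$len)
    } else {
      # prefix-leaf walks: the unit owns the strings whose prefix leaf rank
      # falls in its range
      if (u$rank_from > u$rank_to) return(matrix(0L, ct$k, ct$k))
      ranks <- idx$isa[ct$start_pos]
      jobs <- which(ranks >= u$rank_from & ranks <= u$rank_to)
      if (length(jobs) == 0L) return(matrix(0L, ct$k, ct$k))
      if (method == "1a") {
        cpp_method1_stackless(ct$codes, idx$sa, tree, idx$isa, ct$start_pos,
                              ct$str_end, ct$k, ct$sep_max_code,
                              as.integer(jobs), min_len)
      } else {
        cpp_method1_lists(tree, unclass(L), idx$isa, ct$start_pos, ct$k,
                          as.integer(jobs), min_len)
      }
    }
  }
  partials <-
    if (plan$P > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(plan$units, run_unit, mc.cores = plan$P)
    } else {
      lapply(plan$units, run_unit)
    }
  sol <- Reduce(pmax, partials)
  storage.mode(sol) <- "integer"
  new_overlap_matrix(sol, ct$ids, min_len)
}
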