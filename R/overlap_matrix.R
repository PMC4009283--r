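new_overlap_matrix <- function(mat, ids, min_len) {
  dimnames(mat) <- list(suffix_of = ids, prefix_of = ids)
  attr(mat, "min_len") <- as.integer(min_len)
  class(mat) <- c("overlap_matrix", class(mat))
  mat
}

#' @export
print.overlap_matrix <- function(x, ...) {
  k <- nrow(x)
  cat(sprintf(
    "overlap_matrix: %d x %d (rows: suffix source, columns: prefix target), min_len = %d\n",
    k, k, attr(x, "min_len")))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y)
  invisible(x)
}

#' Sparse edge list of an overlap matrix
#'
#' @param sol an overlap matrix as returned by the `run_method*` functions.
#' @return A data frame with columns `src_id`, `dst_id`, `overlap_len`, one
#'   row per ordered pair with a reported (non-zero) overlap, in row-major
#'   input order.
#' @export
overlap_edges <- function(sol) {
  ids <- rownames(sol)
  idx <- which(t(sol) > 0L)  # row-major order over (src, dst)
  k <- nrow(sol)
  src <- (idx - 1L) %/% k + 1L
  dst <- (idx - 1L) %% k + 1L
  data.frame(src_id = ids[src], dst_id = ids[dst],
             overlap_len = sol[cbind(src, dst)],
             stringsAsFactors = FALSE)
}

check_min_len <- function(min_len) {
  min_len <- as.integer(min_len)
  if (length(min_len) != 1L || is.na(min_len) || min_len < 1L)
    stop("min_len must be a positive integer")
  min_len
}
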