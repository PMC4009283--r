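#' Create a set of named sequences
#'
#' A `string_set` is the package's input container: `k` non-empty sequences
#' over an ordered alphabet (typically the DNA alphabet `A`, `C`, `G`, `T`)
#' with unique identifiers.  All overlap routines take one.
#'
#' @param seqs character vector of sequences; each must be non-empty.
#' @param ids character vector of unique identifiers.  Defaults to
#'   `names(seqs)` or, failing that, `"seq1"`, `"seq2"`, ...
#' @return An object of class `string_set` with fields `ids`, `seqs` and `k`.
#' @examples
#' ss <- string_set(c("AAC", "GAG", "TTA"))
#' ss$k
#' @export
string_set <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  seqs <- as.character(seqs)
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique")
  if (any(is.na(seqs)) || any(nchar(seqs) == 0L))
    stop("all sequences must be non-empty")
  structure(list(ids = unname(ids), seqs = unname(seqs),
                 k = length(seqs)),
            class = "string_set")
}

#' @export
print.string_set <- function(x, ...) {
  cat(sprintf("string_set: %d sequence(s), total length %d\n",
              x$k, sum(nchar(x$seqs))))
  show <- head(seq_len(x$k), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %s  %s\n", x$ids[i], s))
  }
  if (x$k > 6L) cat(sprintf("  ... and %d more\n", x$k - 6L))
  invisible(x)
}
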