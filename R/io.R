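#' Read sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header, in
#' file order; sequence characters are uppercased.
#'
#' @param path path to a FASTA file.
#' @return A [string_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(xs), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(xs))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  string_set(seqs, ids)
}

#' Write a string set as FASTA
#'
#' @param ss a [string_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ss, path) {
  stopifnot(inherits(ss, "string_set"))
  xs <- Biostrings::BStringSet(setNames(ss$seqs, ss$ids))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Write an overlap matrix to a file
#'
#' The default sparse form is a TSV edge list with header
#' `src_id  dst_id  overlap_len`, one row per ordered pair with a reported
#' (non-zero) overlap; absent pairs mean 0 by contract.  The dense form is
#' the full k-by-k integer matrix with identifier row and column labels, in
#' input order.
#'
#' @param sol an `overlap_matrix`.
#' @param path output path (or `""` for standard output).
#' @param dense write the dense matrix instead of the sparse edge list.
#' @return `path`, invisibly.
#' @export
write_overlaps <- function(sol, path, dense = FALSE) {
  stopifnot(inherits(sol, "overlap_matrix"))
  if (dense) {
    df <- as.data.frame(unclass(sol)[, , drop = FALSE])
    write.table(cbind(id = rownames(sol), df), file = path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    write.table(overlap_edges(sol), file = path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sparse overlap TSV back into a matrix
#'
#' @param path a file written by [write_overlaps()] (sparse form).
#' @param ids the full identifier vector, in input order.
#' @return An `overlap_matrix`.
#' @export
read_overlaps <- function(path, ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sol <- matrix(0L, length(ids), length(ids))
  dimnames(sol) <- list(ids, ids)
  if (nrow(df) > 0L)
    sol[cbind(match(df$src_id, ids), match(df$dst_id, ids))] <-
      as.integer(df$overlap_len)
  new_overlap_matrix(sol, ids, 1L)
}
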