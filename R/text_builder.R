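#' Number of characters needed to encode one separator
#'
#' Each of the `k` sequences is followed by a distinct separator block.  With
#' `c` distinct separator characters available, a block of `m` characters can
#' encode `c^m` separators; this returns the smallest such `m`, e.g. 3
#' characters suffice for up to `200^3 = 8000000` sequences when 200
#' separator characters are available.
#'
#' @param k number of sequences (>= 1).
#' @param c size of the separator alphabet (>= 2).
#' @return Integer: the smallest `m` with `c^m >= k`.
#' @examples
#' sep_length(8000000, 200)  # 3
#' sep_length(201, 200)      # 2
#' @export
sep_length <- function(k, c) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive count")
  if (length(c) != 1L || is.na(c) || c < 2) stop("c must be at least 2")
  k <- as.numeric(k)
  c <- as.numeric(c)
  m <- 1L
  cap <- c
  while (cap < k) {
    m <- m + 1L
    cap <- cap * c
  }
  m
}

#' Default separator alphabet
#'
#' 32 printable ASCII characters (`!` through `@`), all of which sort below
#' `A` in byte order, so byte comparison realizes "separator < every sequence
#' character" for the DNA alphabet (and for any text over `A`-`z`).
#'
#' @return Character vector of 32 single characters in increasing byte order.
#' @export
default_sep_alphabet <- function() {
  strsplit(rawToChar(as.raw(33:64)), "", fixed = TRUE)[[1]]
}

#' Concatenate a sequence set into one separator-delimited text
#'
#' Builds the text indexed by the generalized suffix tree: the `k` sequences
#' in order, each (including the last) followed by its own separator block of
#' `m = sep_length(k, c)` characters, the base-`c` expansion of `i - 1` over
#' the separator alphabet, most-significant digit first.  Blocks are distinct
#' and strictly increasing in sequence order, and every separator character
#' sorts below every sequence character.
#'
#' @param ss a [string_set()].
#' @param sep_alphabet ordered character vector of separator characters; all
#'   must sort (byte order) below every character occurring in the
#'   sequences.  Defaults to [default_sep_alphabet()].
#' @return An object of class `concat_text` with fields `text` (the
#'   concatenation), `codes` (integer character codes), `start_pos` (1-based
#'   start of each sequence), `str_end` (1-based last sequence position),
#'   `sep_alphabet`, `sep_len`, `sep_max_code`, `k`, `n` and `ids`.
#' @examples
#' ct <- build_concat(string_set(c("AAC", "GAG", "TTA")),
#'                    sep_alphabet = c("#", "$", "%"))
#' ct$text       # "AAC#GAG$TTA%"
#' ct$start_pos  # 1 5 9
#' @export
build_concat <- function(ss, sep_alphabet = default_sep_alphabet()) {
  stopifnot(inherits(ss, "string_set"))
  sep_alphabet <- as.character(sep_alphabet)
  if (anyDuplicated(sep_alphabet)) stop("separator characters must be unique")
  if (any(nchar(sep_alphabet) != 1L)) stop("separators must be single characters")
  sep_codes <- vapply(sep_alphabet, utf8ToInt, integer(1), USE.NAMES = FALSE)
  if (is.unsorted(sep_codes, strictly = TRUE))
    stop("separator alphabet must be in increasing byte order")
  k <- ss$k
  cc <- length(sep_alphabet)
  if (cc < 2L && k > 1L) stop("need at least 2 separator characters")
  m <- if (k == 1L) 1L else sep_length(k, cc)
  seq_codes <- lapply(ss$seqs, utf8ToInt)
  min_seq <- min(vapply(seq_codes, min, integer(1)))
  if (max(sep_codes) >= min_seq)
    stop("every separator character must sort below every sequence character")
  # base-c expansion of i-1 over the separator alphabet, m digits
  idx0 <- seq_len(k) - 1L
  digits <- matrix(0L, nrow = k, ncol = m)
  rem <- idx0
  for (d in m:1) {
    digits[, d] <- rem %% cc
    rem <- rem %/% cc
  }
  if (any(rem > 0)) stop("internal error: separator capacity exceeded")
  seps <- apply(digits, 1L, function(dg) paste(sep_alphabet[dg + 1L], collapse = ""))
  if (anyDuplicated(seps)) stop("internal error: duplicate separator blocks")
  lens <- nchar(ss$seqs)
  start_pos <- cumsum(c(1L, head(lens + m, -1L)))
  text <- paste0(ss$seqs, seps, collapse = "")
  structure(list(
    text = text,
    codes = utf8ToInt(text),
    start_pos = as.integer(start_pos),
    str_end = as.integer(start_pos + lens - 1L),
    sep_alphabet = sep_alphabet,
    sep_len = as.integer(m),
    sep_max_code = max(sep_codes),
    k = k,
    n = nchar(text),
    ids = ss$ids
  ), class = "concat_text")
}

#' @export
print.concat_text <- function(x, ...) {
  cat(sprintf(
    "concat_text: k = %d, n = %d, separator block length m = %d (alphabet size %d)\n",
    x$k, x$n, x$sep_len, length(x$sep_alphabet)))
  if (x$n <= 60L) cat(" ", x$text, "\n")
  invisible(x)
}

#' Map text positions to source sequences
#'
#' Binary search over the start-position array: returns, for each text
#' position, the index of the sequence it lies in, or `NA` for positions
#' inside a separator block (index traversals legitimately touch
#' separator-start suffixes, so this is a sentinel rather than an error).
#'
#' @param ct a [build_concat()] result.
#' @param pos integer vector of 1-based text positions.
#' @return Integer vector: sequence index in `1..k`, `NA` on separators.
#' @examples
#' ct <- build_concat(string_set(c("AAC", "GAG", "TTA")),
#'                    sep_alphabet = c("#", "$", "%"))
#' string_id(ct, 11)  # 3
#' string_id(ct, 4)   # NA: position 4 is '#'
#' @export
string_id <- function(ct, pos) {
  stopifnot(inherits(ct, "concat_text"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > ct$n))
    stop("positions must lie in 1..n")
  i <- findInterval(pos, ct$start_pos)
  i[pos > ct$str_end[i]] <- NA_integer_
  i
}

#' Test whether text positions start a sequence
#'
#' @inheritParams string_id
#' @return Logical vector: `TRUE` where `pos` is the first position of one of
#'   the `k` sequences.
#' @export
is_start <- function(ct, pos) {
  stopifnot(inherits(ct, "concat_text"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > ct$n))
    stop("positions must lie in 1..n")
  pos %in% ct$start_pos
}
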