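#' Brute-force reference solver
#'
#' Direct realization of the definition, by character comparison only (no
#' index structures): for each ordered pair `(i, j)`, `i != j`, the largest
#' `r <= min(|S_i|, |S_j|)` such that the length-`r` suffix of `S_i` equals
#' the length-`r` prefix of `S_j`.  O(k^2 * len^2); intended as the
#' independent oracle for the index-based methods on small instances.
#'
#' @param ss a [string_set()].
#' @param min_len smallest overlap length reported (default 1).
#' @return A k-by-k integer `overlap_matrix` (diagonal 0).
#' @examples
#' brute_force_apsp(string_set(c("ACG", "GACG")))
#' @export
brute_force_apsp <- function(ss, min_len = 1L) {
  stopifnot(inherits(ss, "string_set"))
  min_len <- check_min_len(min_len)
  k <- ss$k
  lens <- nchar(ss$seqs)
  sol <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      rs <- seq_len(min(lens[i], lens[j]))
      hit <- substring(ss$seqs[i], lens[i] - rs + 1L, lens[i]) ==
        substring(ss$seqs[j], 1L, rs)
      r <- if (any(hit)) max(rs[hit]) else 0L
      if (r >= min_len) sol[i, j] <- r
    }
  }
  new_overlap_matrix(sol, ss$ids, min_len)
}

#' Random read sets
#'
#' `gen_random()` draws `k` sequences over `{A,C,G,T}` with random lengths
#' summing to `total_len`: the `k - 1` cut points are sampled uniformly
#' without replacement from `1 .. total_len - 1`, so every length is at
#' least 1.  `gen_planted()` tiles reads of fixed length across a random
#' mother sequence with step `read_len - ov`, so consecutive reads overlap
#' by exactly `ov` characters (a positive control: the planted overlaps are
#' guaranteed, longer chance overlaps may also occur).
#'
#' @param k number of sequences.
#' @param total_len total length of all sequences (>= k).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A [string_set()].
#' @examples
#' gen_random(3, 30, seed = 7)
#' @export
gen_random <- function(k, total_len, seed) {
  k <- as.integer(k)
  total_len <- as.integer(total_len)
  stopifnot(k >= 1L)
  if (total_len < k) stop("total_len must be at least k")
  with_seed(seed, {
    cuts <- if (k > 1L) sort(sample.int(total_len - 1L, k - 1L)) else integer(0)
    lens <- diff(c(0L, cuts, total_len))
    chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
    seqs <- vapply(split(chars, rep.int(seq_len(k), lens)),
                   paste, character(1), collapse = "")
    string_set(seqs, paste0("read", seq_len(k)))
  })
}

#' @rdname gen_random
#' @param read_len length of every read.
#' @param ov overlap between consecutive reads, `1 <= ov < read_len`.
#' @export
gen_planted <- function(k, read_len, ov, seed) {
  k <- as.integer(k)
  read_len <- as.integer(read_len)
  ov <- as.integer(ov)
  stopifnot(k >= 1L, read_len >= 2L)
  if (is.na(ov) || ov < 1L || ov >= read_len)
    stop("ov must satisfy 1 <= ov < read_len")
  step <- read_len - ov
  with_seed(seed, {
    mother <- paste(sample(c("A", "C", "G", "T"),
                           read_len + (k - 1L) * step, replace = TRUE),
                    collapse = "")
    starts <- 1L + (seq_len(k) - 1L) * step
    string_set(substring(mother, starts, starts + read_len - 1L),
               paste0("read", seq_len(k)))
  })
}
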