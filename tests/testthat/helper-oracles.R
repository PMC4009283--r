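# Independent oracles and fixtures, built in code.  The oracles deliberately
# use plain character/sorting primitives, never the index under test.

strip_mat <- function(m) matrix(as.integer(m), nrow(m), ncol(m))

toy_set <- function() string_set(c("AAC", "GAG", "TTA"), c("s1", "s2", "s3"))

toy_index <- function() {
  build_suffix_index(build_concat(toy_set(), sep_alphabet = c("#", "$", "%")))
}

# naive suffix array: sort the suffix strings (radix = C byte order)
naive_sa <- function(text) {
  n <- nchar(text)
  order(substring(text, seq_len(n), n), method = "radix")
}

# naive LCP: character-by-character comparison of adjacent sorted suffixes
naive_lcp <- function(text, sa) {
  chs <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chs)
  out <- integer(n)
  if (n >= 2L) {
    for (r in 2:n) {
      i <- sa[r - 1L]
      j <- sa[r]
      h <- 0L
      while (i + h <= n && j + h <= n && chs[i + h] == chs[j + h]) h <- h + 1L
      out[r] <- h
    }
  }
  out
}

# naive suffix tree by recursive suffix grouping, emitted as a BP string.
# A suffix exhausted at a node (a prefix of longer suffixes) becomes that
# node's first leaf, matching the index's virtual end-of-text sentinel.
naive_bp_string <- function(text) {
  codes <- utf8ToInt(text)
  n <- length(codes)
  rec <- function(ss, d) {
    lens <- n - ss + 1L
    parts <- strrep("()", sum(lens == d))
    rest <- ss[lens > d]
    if (length(rest) > 0L) {
      nx <- codes[rest + d]
      for (ch in sort(unique(nx))) {
        g <- rest[nx == ch]
        if (length(g) == 1L) {
          parts <- c(parts, "()")
          next
        }
        d2 <- d + 1L
        repeat {
          if (any(n - g + 1L == d2)) break
          if (length(unique(codes[g + d2])) > 1L) break
          d2 <- d2 + 1L
        }
        parts <- c(parts, rec(g, d2))
      }
    }
    paste0("(", paste(parts, collapse = ""), ")")
  }
  if (n == 1L) return("(())")
  rec(seq_len(n), 0L)
}

# random DNA text with a unique terminal character below the alphabet,
# mirroring how indexed texts always end in a distinct final separator
rand_text <- function(n) {
  paste0(paste(sample(c("A", "C", "G", "T"), n - 1L, replace = TRUE),
               collapse = ""), "!")
}

all_methods <- function(idx, min_len = 1L) {
  list(m1 = run_method1(idx, min_len),
       m1a = run_method1_stackless(idx, min_len),
       m1b = run_method1_nostacks_with_lists(idx, min_len),
       m2 = run_method2(idx, min_len))
}

# replay of the leaf-order scan's stack discipline in plain R: the global
# stack state on arrival at leaf rank `upto_rank` (before its processing)
replay_stacks <- function(idx, upto_rank) {
  ct <- idx$ct
  r0 <- ct$k * ct$sep_len + 1L
  glob <- list()
  pop_above <- function(glob, thr) {
    while (length(glob) > 0L && glob[[length(glob)]][3L] > thr)
      glob[[length(glob)]] <- NULL
    glob
  }
  if (upto_rank > r0) {
    for (r in r0:(upto_rank - 1L)) {
      if (r > r0) glob <- pop_above(glob, idx$lcp[r])
      p <- idx$sa[r]
      si <- string_id(ct, p)
      suf <- ct$str_end[si] - p + 1L
      par <- idx$parent[idx$leaf_pos[r]]
      if (par != 0L && idx$depth[par] >= suf &&
          r < idx$n && idx$lcp[r + 1L] >= suf)
        glob[[length(glob) + 1L]] <- c(si, p, suf)
    }
    glob <- pop_above(glob, idx$lcp[upto_rank])
  }
  if (length(glob) == 0L)
    return(data.frame(string = integer(0), pos = integer(0), len = integer(0)))
  m <- do.call(rbind, glob)
  data.frame(string = m[, 1L], pos = m[, 2L], len = m[, 3L])
}
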