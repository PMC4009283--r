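test_that("suffix array and LCP match hand-checked small texts", {
  expect_identical(build_sa("AAC#GAG$TTA%"),
                   c(4L, 8L, 12L, 11L, 1L, 2L, 6L, 3L, 7L, 5L, 10L, 9L))
  expect_identical(build_lcp("AAC#GAG$TTA%", build_sa("AAC#GAG$TTA%")),
                   c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L))
  expect_identical(build_sa("%"), 1L)
  expect_identical(build_lcp("%", 1L), 0L)
  expect_identical(build_sa("AA%"), c(3L, 2L, 1L))
  expect_identical(build_lcp("AA%", c(3L, 2L, 1L)), c(0L, 0L, 1L))
})

test_that("BP preorder encoding matches the worked 3-string tree", {
  expect_identical(bp_string(toy_index()),
                   "(()()()(()()()())()(()())(()()))")
  expect_identical(bp_string(build_suffix_index("%")), "(())")
  expect_identical(bp_string(build_suffix_index("AA%")), "(()(()()))")
})

test_that("leaf select/rank/next navigate in suffix-array order", {
  idx <- toy_index()
  expect_identical(st_select_leaf(idx, 1), 2L)
  expect_identical(st_select_leaf(idx, 4), 9L)
  expect_identical(st_rank_leaf(idx, 32), 12L)
  expect_identical(st_next_leaf(idx, 2), 4L)
  expect_identical(st_next_leaf(idx, 8), 9L)
  expect_true(is.na(st_next_leaf(idx, st_select_leaf(idx, 12))))
  expect_error(st_select_leaf(idx, 13), "range")
  expect_error(st_select_leaf(idx, 0), "range")
})

test_that("parent/is_leaf/is_open answer the BP tree relations", {
  idx <- toy_index()
  expect_identical(st_parent(idx, 9), 8L)
  expect_identical(st_parent(idx, 8), 1L)
  expect_true(is.na(st_parent(idx, 1)))
  expect_true(st_is_leaf(idx, 2))
  expect_false(st_is_leaf(idx, 8))
  expect_true(st_is_open(idx, 8))
  expect_false(st_is_open(idx, 3))
})

test_that("edge characters and child lookup follow the text", {
  idx <- toy_index()
  expect_identical(st_edge_char(idx, 9, 1), "%")
  expect_identical(st_edge_char(idx, 8, 1), "A")
  expect_identical(st_edge_char(idx, 20, 1), "G")
  expect_error(st_edge_char(idx, 8, 2), "range")  # A-edge has length 1
  expect_error(st_edge_char(idx, 1, 1), "root")
  expect_identical(st_child(idx, 1, "A"), 8L)
  expect_identical(st_child(idx, 1, "T"), 26L)
  expect_true(is.na(st_child(idx, 1, "X")))
})

test_that("node depth and leaf text positions are consistent", {
  idx <- toy_index()
  expect_identical(st_node_depth(idx, 1), 0L)
  expect_identical(st_node_depth(idx, 8), 1L)
  expect_identical(st_leaf_text_pos(idx, 9), 11L)
  expect_error(st_leaf_text_pos(idx, 8), "leaf")
  for (r in seq_len(idx$n))
    expect_identical(st_leaf_text_pos(idx, st_select_leaf(idx, r)), idx$sa[r])
})

test_that("lcp between leaves is the range minimum over ranks", {
  idx <- toy_index()
  # adjacent leaves: suffixes 7 and 5, suffixes 6 and 3
  expect_identical(st_lcp_between(idx, idx$isa[7], idx$isa[5]), 1L)
  expect_identical(st_lcp_between(idx, idx$isa[6], idx$isa[3]), 0L)
  expect_identical(st_lcp_between(idx, 1, idx$n), 0L)
})

test_that("index construction agrees with naive oracles on random texts", {
  set.seed(2024)
  for (it in 1:60) {
    text <- rand_text(sample(2:500, 1))
    n <- nchar(text)
    sa <- build_sa(text)
    expect_identical(sa, naive_sa(text))
    expect_identical(build_lcp(text, sa), naive_lcp(text, sa))
    idx <- build_suffix_index(text)
    expect_identical(bp_string(idx), naive_bp_string(text))
    # balance and size bound
    expect_identical(sum(idx$bp == 1L), sum(idx$bp == 0L))
    expect_lte(length(idx$bp), 2L * (2L * n - 1L))
    expect_identical(idx$leaf_cum[length(idx$bp)], n)
  }
})

test_that("index construction matches the naive tree on concatenated sets", {
  for (it in 1:10) {
    ss <- gen_random(sample(2:10, 1), sample(40:200, 1), seed = 100 + it)
    sep <- if (it %% 2 == 0) c("!", "#") else default_sep_alphabet()
    ct <- build_concat(ss, sep)
    idx <- build_suffix_index(ct)
    expect_identical(bp_string(idx), naive_bp_string(ct$text))
    expect_identical(idx$sa, naive_sa(ct$text))
  }
})

test_that("rank and select are mutually inverse on leaves", {
  idx <- build_suffix_index(build_concat(gen_random(8, 400, seed = 5)))
  for (j in seq_len(idx$n)) {
    pos <- st_select_leaf(idx, j)
    expect_true(st_is_leaf(idx, pos))
    expect_identical(st_rank_leaf(idx, pos), j)
  }
})

test_that("string depths increase from root to leaf", {
  idx <- build_suffix_index(rand_text(300))
  opens <- which(idx$bp == 1L)
  nonroot <- opens[idx$parent[opens] != 0L]
  expect_true(all(idx$depth[nonroot] > idx$depth[idx$parent[nonroot]]))
})

test_that("child edges of every internal node start with increasing characters", {
  idx <- build_suffix_index(build_concat(gen_random(6, 250, seed = 9),
                                         c("!", "#")))
  opens <- which(idx$bp == 1L & idx$leaf_rank == 0L)
  for (v in opens) {
    kids <- st_children(idx, v)
    elens <- idx$depth[kids] - idx$depth[v]
    # a zero-length edge is the virtual-sentinel leaf of a suffix that
    # prefixes its siblings' suffixes; it can only be the first child
    if (any(elens == 0L)) {
      expect_identical(which(elens == 0L), 1L)
      expect_true(st_is_leaf(idx, kids[1]))
      kids <- kids[-1]
    }
    firsts <- vapply(kids, function(cpos) st_edge_char(idx, cpos, 1),
                     character(1))
    expect_true(!is.unsorted(utf8ToInt(paste(firsts, collapse = "")),
                             strictly = TRUE))
  }
})
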