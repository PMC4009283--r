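test_that("sep_length gives the smallest block covering k separators", {
  expect_identical(sep_length(8000000, 200), 3L)
  expect_identical(sep_length(1, 2), 1L)
  expect_identical(sep_length(201, 200), 2L)
  expect_identical(sep_length(200, 200), 1L)
  expect_error(sep_length(0, 2), "positive")
  expect_error(sep_length(5, 1), "at least 2")
})

test_that("sep_length is monotone in k and c", {
  for (c in c(2L, 4L, 26L)) {
    ms <- vapply(1:200, sep_length, integer(1), c = c)
    expect_true(all(diff(ms) >= 0))
    expect_true(all(c^ms >= 1:200))
    expect_true(all(c^(ms - 1) < 1:200 | ms == 1L))
  }
  ks <- c(5L, 50L, 5000L)
  for (k in ks) {
    ms <- vapply(2:30, function(c) sep_length(k, c), integer(1))
    expect_true(all(diff(ms) <= 0))
  }
})

test_that("build_concat reproduces the worked 3-string text", {
  ct <- build_concat(toy_set(), sep_alphabet = c("#", "$", "%"))
  expect_identical(ct$text, "AAC#GAG$TTA%")
  expect_identical(ct$start_pos, c(1L, 5L, 9L))
  expect_identical(ct$sep_len, 1L)
  expect_identical(ct$n, 12L)
})

test_that("build_concat handles trivial and small sets", {
  ct1 <- build_concat(string_set("A"), sep_alphabet = "#")
  expect_identical(ct1$text, "A#")
  expect_identical(ct1$start_pos, 1L)
  ct2 <- build_concat(string_set(c("ACG", "GACG")), sep_alphabet = c("#", "$"))
  expect_identical(ct2$text, "ACG#GACG$")
  expect_identical(ct2$start_pos, c(1L, 5L))
})

test_that("separator blocks are distinct, ordered, and below the alphabet", {
  ss <- gen_random(40, 400, seed = 3)
  for (sep in list(default_sep_alphabet(), c("!", "#"), c("!", "#", "$"))) {
    ct <- build_concat(ss, sep)
    m <- ct$sep_len
    expect_identical(ct$n, sum(nchar(ss$seqs)) + ss$k * m)
    blocks <- substring(ct$text, ct$str_end + 1L, ct$str_end + m)
    expect_identical(anyDuplicated(blocks), 0L)
    # sorting the blocks as words reproduces input string order
    expect_identical(order(blocks, method = "radix"), seq_len(ss$k))
    expect_true(max(utf8ToInt(paste(sep, collapse = ""))) < utf8ToInt("A"))
  }
})

test_that("build_concat rejects separators that collide with the alphabet", {
  expect_error(build_concat(string_set(c("!A", "CC")), c("!", "#")),
               "sort below")
  expect_error(build_concat(toy_set(), c("$", "#", "%")), "increasing")
  expect_error(build_concat(toy_set(), c("#", "#", "%")), "unique")
})

test_that("string_id maps positions to strings, with a separator sentinel", {
  ct <- build_concat(toy_set(), sep_alphabet = c("#", "$", "%"))
  expect_identical(string_id(ct, 11), 3L)
  expect_identical(string_id(ct, 1), 1L)
  expect_true(is.na(string_id(ct, 4)))
  expect_identical(string_id(ct, c(1, 4, 11)), c(1L, NA, 3L))
  expect_error(string_id(ct, 0), "1..n")
  expect_error(string_id(ct, 13), "1..n")
})

test_that("is_start flags exactly the string start positions", {
  ct <- build_concat(toy_set(), sep_alphabet = c("#", "$", "%"))
  expect_true(is_start(ct, 5))
  expect_false(is_start(ct, 6))
  expect_true(is_start(ct, 1))
  expect_identical(which(is_start(ct, 1:12)), c(1L, 5L, 9L))
})

test_that("string_id round-trips every in-string offset", {
  ss <- gen_random(12, 300, seed = 11)
  ct <- build_concat(ss, c("!", "#"))
  for (i in seq_len(ss$k)) {
    offs <- seq_len(nchar(ss$seqs[i]))
    expect_identical(string_id(ct, ct$start_pos[i] + offs - 1L),
                     rep(i, length(offs)))
  }
  sep_pos <- setdiff(seq_len(ct$n),
                     unlist(lapply(seq_len(ss$k),
                                   function(i) ct$start_pos[i]:ct$str_end[i])))
  expect_true(all(is.na(string_id(ct, sep_pos))))
})

test_that("duplicate input strings are accepted with distinct separators", {
  ct <- build_concat(string_set(c("AA", "AA"), c("a", "b")), c("#", "$"))
  expect_identical(ct$text, "AA#AA$")
  idx <- build_suffix_index(ct)
  sol <- run_method2(idx)
  expect_identical(sol[1, 2], 2L)
  expect_identical(sol[2, 1], 2L)
})
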