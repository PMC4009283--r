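test_that("top-down decomposition expands the highest tree levels", {
  idx <- toy_index()
  # P = 1: a single unit, the whole tree
  p1 <- decompose_top_down(idx, 1, gamma = 1)
  expect_identical(length(p1$units), 1L)
  expect_identical(p1$units[[1]]$root, 1L)
  # P = 4, gamma = 1: the four non-separator children of the root
  p4 <- decompose_top_down(idx, 4, gamma = 1)
  expect_setequal(vapply(p4$units, `[[`, integer(1), "root"),
                  c(8L, 18L, 20L, 26L))
  # P = 4, gamma = 1.5: the A subtree is expanded into its four leaves
  p6 <- decompose_top_down(idx, 4, gamma = 1.5)
  roots <- vapply(p6$units, `[[`, integer(1), "root")
  expect_gte(length(roots), 6L)
  expect_setequal(roots, c(9L, 11L, 13L, 15L, 18L, 20L, 26L))
})

test_that("work units cover every non-separator leaf exactly once", {
  ss <- gen_random(12, 600, seed = 31)
  idx <- build_suffix_index(build_concat(ss, c("!", "#")))
  sep_leaves <- idx$ct$k * idx$ct$sep_len
  string_ranks <- (sep_leaves + 1L):idx$n
  for (plan in list(decompose_top_down(idx, 3, 1.5),
                    decompose_bottom_up(idx, 3, 1.5, "2"),
                    decompose_bottom_up(idx, 3, 1.5, "1"))) {
    covered <- unlist(lapply(plan$units, function(u)
      if (u$rank_from <= u$rank_to) u$rank_from:u$rank_to else integer(0)))
    expect_identical(anyDuplicated(covered), 0L)
    expect_true(all(string_ranks %in% covered))
  }
})

test_that("stack prefill reproduces the worked states", {
  idx <- toy_index()
  # start at string 2's prefix leaf (suffix 5): stack 2 holds (7, 1)
  pre <- prefill_stacks(idx, idx$isa[5])
  expect_identical(pre, data.frame(string = 2L, pos = 7L, len = 1L))
  # start at the first non-separator leaf: all stacks empty
  pre0 <- prefill_stacks(idx, 4L)
  expect_identical(nrow(pre0), 0L)
  # start at string 1's prefix leaf (suffix 1): stack 3 holds (11, 1)
  pre1 <- prefill_stacks(idx, idx$isa[1])
  expect_identical(pre1, data.frame(string = 3L, pos = 11L, len = 1L))
})

test_that("stack prefill equals an instrumented sequential replay", {
  for (it in 1:6) {
    ss <- gen_random(sample(3:10, 1), sample(60:300, 1), seed = 600 + it)
    sep <- if (it %% 2 == 0) c("!", "#") else default_sep_alphabet()
    idx <- build_suffix_index(build_concat(ss, sep))
    r0 <- idx$ct$k * idx$ct$sep_len + 1L
    for (r in r0:idx$n) {
      expect_identical(prefill_stacks(idx, r), replay_stacks(idx, r),
                       label = sprintf("it=%d rank=%d", it, r))
    }
  }
})

test_that("method-1 prefill pushes the ancestors' candidate entries", {
  idx <- toy_index()
  L <- fill_l_lists(idx)
  # below the A node (open 8), a worker starting at leaf 11 sees L[8]
  pre <- prefill_stacks(idx, 11L, type = "bp", l_lists = L)
  expect_identical(pre, data.frame(string = 3L, pos = 11L, len = 1L))
  expect_identical(nrow(prefill_stacks(idx, 1L, type = "bp", l_lists = L)), 0L)
})

test_that("every strategy, method and worker count gives the sequential matrix", {
  ss <- gen_random(10, 1000, seed = 99)
  idx <- build_suffix_index(build_concat(ss))
  ref <- strip_mat(run_method1(idx))
  expect_identical(strip_mat(run_method2(idx)), ref)
  for (P in c(1L, 2L, 4L)) {
    td <- decompose_top_down(idx, P)
    for (m in c("1", "1a", "1b", "2")) {
      expect_identical(strip_mat(run_parallel(idx, m, td)), ref,
                       label = sprintf("topdown method %s P=%d", m, P))
      bu <- decompose_bottom_up(idx, P, method = m)
      expect_identical(strip_mat(run_parallel(idx, m, bu)), ref,
                       label = sprintf("bottomup method %s P=%d", m, P))
    }
  }
})

test_that("parallel output is unchanged by gamma and min_len", {
  ss <- gen_planted(9, 40, 12, seed = 4)
  idx <- build_suffix_index(build_concat(ss, c("!", "#")))
  for (ml in c(1L, 12L)) {
    ref <- strip_mat(run_method2(idx, ml))
    for (g in c(1, 1.5, 3)) {
      expect_identical(
        strip_mat(run_parallel(idx, "2", decompose_bottom_up(idx, 2, g, "2"), ml)),
        ref)
      expect_identical(
        strip_mat(run_parallel(idx, "1", decompose_top_down(idx, 2, g), ml)),
        ref)
    }
  }
})

test_that("method 1 refuses a leaf-partitioned plan", {
  idx <- toy_index()
  plan <- decompose_bottom_up(idx, 2, method = "2")
  expect_error(run_parallel(idx, "1", plan), "BP")
})
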