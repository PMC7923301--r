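test_that("composition counts match the dominant-variant state space", {
  expect_equal(nrow(enumerate_compositions(3, include_all_wt = FALSE)), 7)
  expect_equal(nrow(enumerate_compositions(6, include_all_wt = FALSE)), 63)
  expect_equal(nrow(enumerate_compositions(1, include_all_wt = TRUE)), 2)
  expect_equal(nrow(enumerate_compositions(6, include_all_wt = TRUE)), 64)
  expect_error(enumerate_compositions(0), "positive")
})

test_that("composition enumeration matches explicit bit enumeration for n = 1..10", {
  for (n in 1:10) {
    tb <- enumerate_compositions(n, include_all_wt = FALSE)
    expect_equal(nrow(tb), 2^n - 1)
    # oracle: all distinct nonzero bit patterns
    pats <- vapply(tb$flags, function(f) paste(as.integer(f), collapse = ""),
                   character(1))
    expect_equal(sort(pats),
                 sort(setdiff(vapply(0:(2^n - 1), function(i) {
                   paste(as.integer(intToBits(i)[n:1] > 0), collapse = "")
                 }, character(1)), paste(rep(0, n), collapse = ""))))
  }
})

test_that("enumeration order is deterministic across calls", {
  expect_identical(enumerate_compositions(6)$composition,
                   enumerate_compositions(6)$composition)
  expect_identical(enumerate_compositions(3)$composition[1:3],
                   c("WWM", "WMW", "WMM"))
})

test_that("protomer pairings give 21 evaluations grouped 9/9/3", {
  comps <- enumerate_compositions(3)
  pr <- protomer_pairings(comps)
  expect_equal(nrow(pr), 21)
  g <- group_by_mutation_count(pr)
  expect_equal(g$n_mut, c(1, 2, 3))
  expect_equal(g$n, c(9L, 9L, 3L))
  # each pairing partitions the trimer
  for (i in seq_len(nrow(pr))) {
    expect_equal(sort(c(pr$left[[i]], pr$right[[i]])), 1:3)
  }
  expect_error(protomer_pairings(enumerate_compositions(3, TRUE)), "all-WT")
  expect_error(protomer_pairings(enumerate_compositions(6)), "trimer")
})

test_that("hexamer groups equal binomial coefficients", {
  g <- group_by_mutation_count(enumerate_compositions(6))
  expect_equal(g$n, as.integer(choose(6, 1:6)))
  expect_equal(sum(g$n), 63L)
  empty <- group_by_mutation_count(enumerate_compositions(3)[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("symmetry reduction partitions compositions into orbits", {
  c3 <- list(1:3, c(2, 3, 1), c(3, 1, 2))
  red <- symmetry_reduce(enumerate_compositions(3), c3)
  expect_equal(nrow(red), 3)
  expect_equal(sum(red$multiplicity), 7)
  expect_equal(red$multiplicity[order(red$n_mut)], c(3, 3, 1))
  # trivial group: every composition its own orbit
  triv <- symmetry_reduce(enumerate_compositions(3), list(1:3))
  expect_equal(nrow(triv), 7)
  expect_true(all(triv$multiplicity == 1))
  # hexamer under C3 x C3 x head swap: multiplicities still cover all 63
  rots <- list(1:3, c(2, 3, 1), c(3, 1, 2))
  perms <- list()
  for (p in rots) for (q in rots) {
    perms[[length(perms) + 1]] <- c(p, q + 3L)
    perms[[length(perms) + 1]] <- c(q + 3L, p)  # swap the two heads
  }
  red6 <- symmetry_reduce(enumerate_compositions(6), perms)
  expect_equal(sum(red6$multiplicity), 63)
  expect_lt(nrow(red6), 63)
  # a non-closed permutation set is rejected
  expect_error(symmetry_reduce(enumerate_compositions(3),
                               list(1:3, c(2, 1, 3), c(2, 3, 1))),
               "not closed")
})
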