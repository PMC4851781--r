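test_that("componentwise order matches the specialization relation", {
  expect_true(policy_precedes(c(1, 1, 1), c(1, 2, 2)))
  expect_false(policy_precedes(c(1, 3, 0), c(1, 2, 2)))
  expect_true(policy_precedes(c(2, 0, 1), c(2, 0, 1)))   # reflexive
  expect_false(policy_strictly_precedes(c(2, 0, 1), c(2, 0, 1)))
  expect_true(policy_strictly_precedes(c(0, 0), c(0, 1)))
  expect_error(policy_precedes(c(0, 1), c(0, 1, 2)), "unequal length")
})

test_that("the order is a partial order on random triples", {
  set.seed(101)
  heights <- c(4L, 3L, 5L, 2L)
  for (i in 1:1000) {
    x <- random_policy(heights)
    y <- random_policy(heights)
    z <- random_policy(heights)
    expect_true(policy_precedes(x, x))
    if (policy_precedes(x, y) && policy_precedes(y, x))
      expect_identical(x, y)
    if (policy_precedes(x, y) && policy_precedes(y, z))
      expect_true(policy_precedes(x, z))
  }
})

test_that("rank sums levels and is strictly monotone", {
  expect_identical(policy_rank(c(1, 2, 2)), 5L)
  expect_identical(policy_rank(c(0, 0, 0)), 0L)
  expect_identical(policy_rank(c(3, 2, 0)), 5L)
  set.seed(102)
  heights <- c(4L, 4L, 3L)
  for (i in 1:200) {
    p <- random_strict_pair(heights)
    expect_lt(policy_rank(p$lo), policy_rank(p$hi))
  }
})

test_that("lattice size is the product of heights", {
  expect_equal(lattice_size(lattice_spec(c(3, 2))), 6)
  expect_equal(lattice_size(lattice_spec(2)), 2)
  expect_equal(lattice_size(lattice_spec(c(4, 4, 4))), 64)
})

test_that("direct generalizations increment one free component", {
  spec <- lattice_spec(c(3, 2))
  expect_setequal(lapply(direct_generalizations(c(0L, 0L), spec), policy_key),
                  list("1.0", "0.1"))
  expect_length(direct_generalizations(c(2L, 1L), spec), 0L)
  expect_equal(direct_generalizations(c(1L, 1L), spec), list(c(2L, 1L)))
  for (y in direct_generalizations(c(1L, 0L), spec)) {
    expect_equal(policy_rank(y), 2L)
    expect_true(policy_strictly_precedes(c(1L, 0L), y))
  }
})

test_that("rank-order enumeration yields every policy once, ranks sorted", {
  for (heights in list(c(2L, 2L), c(3L, 2L), 2L, c(2L, 3L, 4L), c(5L, 1L, 2L))) {
    spec <- lattice_spec(heights)
    pols <- all_policies(spec)
    expect_length(pols, lattice_size(spec))
    keys <- vapply(pols, policy_key, character(1))
    expect_false(any(duplicated(keys)))
    ranks <- vapply(pols, policy_rank, integer(1))
    expect_true(all(diff(ranks) >= 0))
    for (p in pols) expect_silent(validate_policy(p, spec))
    # within one rank: ascending lexicographic order
    for (r in unique(ranks)) {
      grp <- pols[ranks == r]
      if (length(grp) > 1L) {
        keys_padded <- vapply(grp, function(p)
          paste(sprintf("%03d", p), collapse = "."), character(1))
        expect_identical(keys_padded, sort(keys_padded))
      }
    }
  }
  it <- policy_iterator(lattice_spec(2L))
  expect_equal(it(), 0L)
  expect_equal(it(), 1L)
  expect_null(it())
})

test_that("antichain detection", {
  expect_true(is_antichain(list(c(1, 1, 1), c(1, 3, 0), c(3, 2, 0))))
  expect_false(is_antichain(list(c(1, 1, 1), c(1, 2, 2))))
  expect_true(is_antichain(list()))
  expect_true(is_antichain(list(c(0, 0))))
})
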