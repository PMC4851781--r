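fig_elements <- list(c(1L, 1L, 1L), c(1L, 3L, 0L), c(3L, 2L, 0L))

test_that("the three-element antichain answers the walkthrough query", {
  for (opt in 1:4) {
    st <- property_store(3, "up", option = opt)
    for (p in fig_elements) ps_insert(st, p)
    els <- ps_elements(st)
    expect_length(els, 3L)
    expect_true(is_antichain(els))
    expect_true(ps_query(st, c(1, 2, 2)))
    # a stored element never marks itself
    expect_false(ps_query(st, c(1, 1, 1)))
    expect_false(ps_query(st, c(1, 3, 0)))
  }
})

test_that("the rank bound prunes the equal-rank subtree during the query", {
  st <- property_store(3, "up", option = 4)
  for (p in fig_elements) ps_insert(st, p)
  tr <- ps_query(st, c(1, 2, 2), trace = TRUE)
  expect_true(tr$found)
  # the branch holding (3,2,0) (rank 5 >= rank of the query) is never
  # entered, nor is the level-3 child below the first attribute
  for (path in tr$visited) {
    expect_false(path[1] == 3)
    if (length(path) >= 2) expect_false(path[2] == 3)
  }
  # positive control: only the (1,1,1) path is walked
  expect_equal(tr$visited[[length(tr$visited)]], c(1, 1, 1))
})

test_that("inserting a specialization evicts its stored generalizations", {
  for (opt in 2:4) {
    st <- property_store(3, "up", option = opt)
    ps_insert(st, c(1, 1, 1))
    ps_insert(st, c(0, 1, 1))
    expect_equal(ps_elements(st), list(c(0L, 1L, 1L)))
    # a chain inserted bottom-up collapses to its least element
    st2 <- property_store(2, "up", option = opt, guarded = TRUE)
    ps_insert(st2, c(0, 1)); ps_insert(st2, c(1, 1)); ps_insert(st2, c(2, 2))
    expect_equal(ps_elements(st2), list(c(0L, 1L)))
  }
})

test_that("the simple list answers identically but may store more", {
  st1 <- property_store(3, "up", option = 1)
  st4 <- property_store(3, "up", option = 4)
  seqn <- list(c(2, 2, 2), c(1, 1, 1), c(0, 1, 1), c(2, 0, 0))
  for (p in seqn) { ps_insert(st1, p); ps_insert(st4, p) }
  expect_gte(length(ps_elements(st1)), length(ps_elements(st4)))
  expect_equal(ps_stats(st1)$inserts, 4L)
  for (q in list(c(2, 2, 2), c(1, 2, 1), c(0, 0, 0), c(2, 1, 0)))
    expect_identical(ps_query(st1, q), ps_query(st4, q))
})

test_that("exact membership traverses a single path", {
  for (opt in c(1L, 4L)) {
    st <- property_store(3, "up", option = opt)
    expect_false(ps_contains(st, c(1, 1, 1)))
    ps_insert(st, c(1, 1, 1))
    expect_true(ps_contains(st, c(1, 1, 1)))
    expect_false(ps_contains(st, c(1, 1, 2)))
  }
})

test_that("empty stores answer negatively in both directions", {
  for (dir in c("up", "down")) {
    st <- property_store(2, dir)
    expect_false(ps_query(st, c(0, 0)))
    expect_length(ps_elements(st), 0L)
  }
  expect_error(property_store(0, "up"), "m >= 1")
})

test_that("all four options track the naive oracle over random workloads", {
  set.seed(21)
  for (w in 1:150) {
    m <- sample(1:5, 1)
    heights <- sample(2:5, m, replace = TRUE)
    dir <- if (w %% 2 == 0) "up" else "down"
    stores <- lapply(1:4, function(o)
      property_store(m, dir, option = o, guarded = TRUE))
    oracle <- naive_store(dir)
    for (step in 1:15) {
      x <- random_policy(heights)
      if (runif(1) < 0.5) {
        ans <- vapply(stores, function(s) ps_query(s, x), logical(1))
        expect_true(all(ans == oracle$query(x)))
      } else {
        for (s in stores) ps_insert(s, x)
        oracle$insert(x)
        for (o in 2:4)
          expect_true(is_antichain(ps_elements(stores[[o]])))
        expect_true(validate_store(stores[[4]]))
      }
    }
    sizes <- vapply(stores, function(s) length(ps_elements(s)), integer(1))
    expect_true(all(sizes[2:4] <= sizes[1]))
  }
})

test_that("down direction mirrors up under level complement", {
  set.seed(22)
  heights <- c(4L, 3L, 5L)
  flip <- function(x) heights - 1L - x
  for (w in 1:30) {
    dn <- property_store(3, "down", option = 4, guarded = TRUE)
    up <- property_store(3, "up", option = 4, guarded = TRUE)
    for (step in 1:12) {
      x <- random_policy(heights)
      if (runif(1) < 0.5) {
        expect_identical(ps_query(dn, x), ps_query(up, flip(x)))
      } else {
        ps_insert(dn, x)
        ps_insert(up, flip(x))
      }
    }
    expect_equal(length(ps_elements(dn)), length(ps_elements(up)))
  }
})

test_that("rank bounds are exact for removal-free workloads", {
  set.seed(23)
  heights <- c(5L, 5L, 5L, 5L)
  for (w in 1:20) {
    st <- property_store(4, sample(c("up", "down"), 1), option = 4)
    r <- sample(4:12, 1)
    # equal-rank policies are pairwise incomparable: no insert evicts
    for (step in 1:10) {
      x <- random_policy_of_rank(r, heights - 1L)
      if (!ps_contains(st, x)) ps_insert(st, x)
    }
    expect_true(validate_store(st, exact_bounds = TRUE))
  }
})

test_that("JSON dumps of the same antichain are identical across options", {
  st3 <- property_store(3, "up", option = 3)
  st4 <- property_store(3, "up", option = 4)
  st2 <- property_store(3, "up", option = 2)
  for (p in fig_elements) { ps_insert(st2, p); ps_insert(st3, p); ps_insert(st4, p) }
  expect_identical(store_to_json(st3), store_to_json(st4))
  expect_identical(store_to_json(st2), store_to_json(st4))
})
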