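test_that("equivalence classes group indistinguishable records", {
  hs <- list(hierarchy(rbind(c("a", "*"), c("b", "*")), "x"),
             hierarchy(rbind(c("p", "*"), c("q", "*")), "y"))
  same <- data.frame(x = rep("a", 4), y = rep("p", 4),
                     stringsAsFactors = FALSE)
  expect_equal(equivalence_class_sizes(same, hs, c(0, 0)), 4L)
  distinct <- data.frame(x = c("a", "a", "b", "b"), y = c("p", "q", "p", "q"),
                         stringsAsFactors = FALSE)
  expect_setequal(equivalence_class_sizes(distinct, hs, c(0, 0)),
                  rep(1L, 4))
  expect_equal(equivalence_class_sizes(distinct, hs, c(1, 1)), 4L)
  empty <- distinct[0, , drop = FALSE]
  expect_length(equivalence_class_sizes(empty, hs, c(0, 0)), 0L)
})

test_that("k-anonymity and re-identification risk follow class sizes", {
  expect_true(is_k_anonymous(c(2L, 3L), 2))
  expect_false(is_k_anonymous(c(1L, 5L), 2))
  expect_true(is_k_anonymous(c(1L, 1L), 1))
  expect_true(is_k_anonymous(integer(0), 7))
  expect_equal(max_reidentification_risk(c(2L, 4L)), 0.5)
  expect_equal(max_reidentification_risk(c(5L, 9L)), 0.2)
  expect_equal(max_reidentification_risk(c(1L, 10L)), 1)
  expect_error(max_reidentification_risk(integer(0)), "undefined")
})

test_that("cell loss spans 0 (untouched) to 1 (suppressed / full domain)", {
  h <- hierarchy(rbind(c("1", "[1-2]", "*"), c("2", "[1-2]", "*"),
                       c("3", "[3-4]", "*"), c("4", "[3-4]", "*")), "x")
  expect_equal(cell_loss(h, 0, "2"), 0)
  expect_equal(cell_loss(h, 0, "2", suppressed = TRUE), 1)
  expect_equal(cell_loss(h, 2, "*"), 1)            # covers all 4 of 4
  expect_equal(cell_loss(h, 1, "[1-2]"), (2 - 1) / (4 - 1))
  expect_error(cell_loss(h, 1, "nope"), "does not exist")
  single <- hierarchy(matrix("only", 1, 1), "const")
  expect_equal(cell_loss(single, 0, "only"), 0)
  expect_equal(cell_loss(single, 0, "only", suppressed = TRUE), 1)
})

test_that("quality anchors: 100 % untouched, 0 % removed, 50 % half-removed", {
  fx <- toy_demographics()
  ev <- make_evaluator(fx$data, fx$hierarchies)
  expect_equal(quality(ev, c(0, 0)), 1)
  expect_equal(quality(ev, c(0, 0), rep(TRUE, 5)), 0)
  expect_equal(quality(ev, c(2, 1), rep(TRUE, 5)), 0)
  # second attribute generalized to its single root, first untouched
  expect_equal(quality(ev, c(0, 1)), 0.5)
  expect_equal(quality_bound(ev, c(0, 1)), 0.5)
})

test_that("full generalization of one of two attributes caps quality at 50 %", {
  set.seed(11)
  inst <- synth_instance(40, c(6, 5), seed = 11)
  ev <- make_evaluator(inst$data, inst$hierarchies)
  top2 <- inst$spec$top[2]
  for (l1 in 0:inst$spec$top[1]) {
    for (nsup in c(0L, 5L, 40L)) {
      flags <- seq_len(40) <= nsup
      expect_lte(quality(ev, c(l1, top2), flags), 0.5 + 1e-12)
    }
  }
})

test_that("quality bound dominates quality and both are monotone", {
  set.seed(12)
  for (trial in 1:10) {
    inst <- synth_instance(30, sample(3:6, 2, replace = TRUE),
                           outlier_fraction = 0.1, seed = trial + 100)
    ev <- make_evaluator(inst$data, inst$hierarchies)
    pols <- all_policies(inst$spec)
    evals <- lapply(pols, function(p)
      evaluate_policy(ev, p, k = 3, suppression_limit = 0.1))
    for (e in evals)
      expect_lte(e$quality, e$quality_bound + 1e-12)
    # all comparable pairs: bound and suppression monotone along generalization
    for (i in seq_along(pols)) {
      for (j in seq_along(pols)) {
        if (i != j && policy_strictly_precedes(pols[[i]], pols[[j]])) {
          expect_lte(evals[[j]]$quality_bound, evals[[i]]$quality_bound + 1e-12)
          expect_lte(evals[[j]]$suppressed_count, evals[[i]]$suppressed_count)
        }
      }
    }
  }
})

test_that("evaluate applies generalize / suppress / check in order", {
  fx <- toy_demographics()
  ev <- make_evaluator(fx$data, fx$hierarchies)
  r <- evaluate_policy(ev, c(1, 0), k = 2, suppression_limit = 0.25)
  expect_true(r$anonymous)
  expect_equal(r$suppressed_count, 1L)
  expect_setequal(r$class_sizes, c(2L, 2L, 1L))
  kept <- r$class_sizes[r$class_sizes >= 2]
  expect_equal(max_reidentification_risk(kept), 0.5)

  r1 <- evaluate_policy(ev, c(1, 0), k = 1, suppression_limit = 0)
  expect_true(r1$anonymous)
  expect_equal(r1$suppressed_count, 0L)
  expect_equal(r1$quality, r1$quality_bound)

  r0 <- evaluate_policy(ev, c(1, 0), k = 2, suppression_limit = 0)
  expect_false(r0$anonymous)
})

test_that("anonymous evaluations respect risk and suppression constraints", {
  set.seed(13)
  for (trial in 1:20) {
    inst <- random_instance(trial + 300)
    ev <- make_evaluator(inst$data, inst$hierarchies)
    k <- sample(2:5, 1)
    lim <- runif(1, 0, 0.15)
    r <- evaluate_policy(ev, random_policy(inst$spec$heights),
                         k = k, suppression_limit = lim)
    if (r$anonymous) {
      expect_lte(r$suppressed_count, floor(lim * r$n))
      kept <- r$class_sizes[r$class_sizes >= k]
      if (length(kept))
        expect_lte(max_reidentification_risk(kept), 1 / k)
    }
  }
})

test_that("empty datasets evaluate to the defined degenerate result", {
  fx <- toy_demographics()
  ev <- make_evaluator(fx$data[0, , drop = FALSE], fx$hierarchies)
  r <- evaluate_policy(ev, c(1, 0), k = 5, suppression_limit = 0)
  expect_true(r$anonymous)
  expect_equal(r$quality, 1)
  expect_equal(r$suppressed_count, 0L)
})
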