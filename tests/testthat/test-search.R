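test_that("exhaustive search sweeps the whole lattice", {
  fx <- toy_demographics()
  ev <- make_evaluator(fx$data, fx$hierarchies)
  r <- search_exhaustive(ev, privacy_config(2, 0.25))
  expect_equal(r$stats$checked, 6L)
  expect_true(r$optimal_guarantee)
  expect_true(r$solution$evaluation$anonymous)

  # k = 1: nothing to suppress, the untouched data is optimal
  r1 <- search_exhaustive(ev, privacy_config(1, 0))
  expect_equal(r1$solution$policy, c(0L, 0L))
  expect_equal(r1$solution$evaluation$quality, 1)

  # k > n with no suppression allowed: unsolvable
  rx <- search_exhaustive(ev, privacy_config(10, 0))
  expect_null(rx$solution)

  expect_error(search_exhaustive(ev, cap = 2), "cap")
})

test_that("optimal and BFS agree with the exhaustive oracle", {
  for (trial in 1:12) {
    inst <- random_instance(trial + 500)
    ev <- make_evaluator(inst$data, inst$hierarchies)
    cfg <- privacy_config(sample(2:6, 1), runif(1, 0, 0.1))
    a <- search_exhaustive(ev, cfg)
    b <- search_optimal(ev, cfg)
    d <- search_bfs(ev, cfg)
    qa <- solution_quality(a)
    expect_equal(solution_quality(b), qa, tolerance = 1e-13)
    expect_equal(solution_quality(d), qa, tolerance = 1e-13)
    expect_true(b$optimal_guarantee && d$optimal_guarantee)
    # soundness: no anonymous policy beats the claimed optimum
    if (!is.na(qa)) {
      for (p in all_policies(inst$spec)) {
        e <- evaluate_policy(ev, p, cfg)
        if (e$anonymous) expect_lte(e$quality, qa + 1e-12)
      }
    }
  }
})

test_that("disabling prediction changes counters, never the solution", {
  inst <- random_instance(777)
  ev <- make_evaluator(inst$data, inst$hierarchies)
  cfg <- privacy_config(4, 0.05)
  on <- search_optimal(ev, cfg, use_prediction = TRUE)
  off <- search_optimal(ev, cfg, use_prediction = FALSE)
  expect_equal(solution_quality(on), solution_quality(off), tolerance = 1e-13)
  expect_equal(off$stats$checked, lattice_size(inst$spec))
  expect_lte(on$stats$checked, off$stats$checked)
  expect_equal(off$stats$quality_store$hits, 0L)

  bon <- search_bfs(ev, cfg, use_prediction = TRUE)
  boff <- search_bfs(ev, cfg, use_prediction = FALSE)
  expect_equal(solution_quality(bon), solution_quality(boff),
               tolerance = 1e-13)
  expect_lte(bon$stats$checked, boff$stats$checked)
})

test_that("store options 1-4 drive the search to the same optimum", {
  inst <- random_instance(888)
  tab <- benchmark_stores(inst$data, inst$hierarchies, k = 3,
                          suppression_limit = 0.05)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$checked[1:4] == tab$checked[1]))
})

test_that("BFS respects evaluation budgets and records its trajectory", {
  inst <- random_instance(999)
  ev <- make_evaluator(inst$data, inst$hierarchies)
  cfg <- privacy_config(3, 0.1)
  full <- search_bfs(ev, cfg)
  traj <- full$stats$trajectory
  if (!is.null(traj) && nrow(traj) > 1)
    expect_true(all(diff(traj[, "best_quality"]) > 0))

  for (budget in c(1L, 5L, 20L)) {
    b <- search_bfs(ev, cfg, evaluation_budget = budget)
    expect_lte(b$stats$checked, budget)
    if (!b$optimal_guarantee && !is.null(b$solution))
      expect_lte(solution_quality(b), solution_quality(full) + 1e-12)
  }

  # budget of one evaluation: only the bottom policy can be reported
  b1 <- search_bfs(ev, cfg, evaluation_budget = 1L)
  ev_bottom <- evaluate_policy(ev, inst$spec$bottom, cfg)
  if (ev_bottom$anonymous) {
    expect_equal(b1$solution$policy, inst$spec$bottom)
  } else {
    expect_null(b1$solution)
  }
})

test_that("an anonymous bottom policy collapses the search immediately", {
  # every record duplicated five times: bottom is 5-anonymous, quality 1
  inst <- synth_instance(20, c(6, 4, 3), seed = 4242)
  data5 <- inst$data[rep(seq_len(nrow(inst$data)), each = 5L), , drop = FALSE]
  rownames(data5) <- NULL
  ev <- make_evaluator(data5, inst$hierarchies)
  cfg <- privacy_config(5, 0)
  on <- search_optimal(ev, cfg, use_prediction = TRUE)
  off <- search_optimal(ev, cfg, use_prediction = FALSE)
  expect_equal(on$solution$policy, inst$spec$bottom)
  expect_equal(on$solution$evaluation$quality, 1)
  expect_lt(on$stats$checked, off$stats$checked)
  expect_equal(on$stats$checked, 1L)
})

test_that("report_stats summarizes the counters", {
  fx <- toy_demographics()
  ev <- make_evaluator(fx$data, fx$hierarchies)
  r <- search_exhaustive(ev, privacy_config(2, 0.25))
  rep <- report_stats(r)
  expect_equal(rep$checked_pct, 100)
  expect_equal(rep$quality_store$hits, 0L)
  expect_output(print(rep), "Checked 6 / 6")

  ro <- search_optimal(ev, privacy_config(2, 0.25))
  repo <- report_stats(ro)
  expect_lte(repo$quality_store$max_antichain, repo$quality_store$inserts)
})
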