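#' Lattice search strategies
#'
#' Three strategies share the evaluation machinery and the predictive
#' property stores:
#' \describe{
#'   \item{`search_exhaustive()`}{evaluates every policy; the brute-force
#'     oracle for small lattices.}
#'   \item{`search_optimal()`}{iterates the lattice in rank order and
#'     skips policies marked by two predictive properties: *insufficient
#'     protection* (a non-anonymous policy condemns all its
#'     specializations; a `"down"` store) and *insufficient quality* (a
#'     policy whose generalization-only bound cannot beat the incumbent
#'     condemns all its generalizations; an `"up"` store). Globally
#'     optimal.}
#'   \item{`search_bfs()`}{best-first branch and bound from the bottom:
#'     a priority queue ordered by evaluated quality (highest first)
#'     drives the expansion; generalizations of bound-dominated policies
#'     are pruned, and the insufficient-quality store discards queued
#'     policies that later became dominated. Run to exhaustion it is
#'     globally optimal; under a time or evaluation budget it is an
#'     anytime heuristic returning the best solution so far together with
#'     its quality trajectory.}
#' }
#'
#' Only anonymous policies can become the incumbent; the quality of a
#' non-anonymous policy still contributes its generalization-only bound
#' for pruning. Ties in quality are broken toward lower rank, then
#' lexicographically smaller policies, making all searches deterministic.
#'
#' @name lattice-search
NULL

.empty_store_stats <- function() list(inserts = 0L, hits = 0L, max_size = 0L)

.store_report <- function(store, hits) {
  if (is.null(store)) {
    s <- .empty_store_stats(); s$hits <- hits; return(s)
  }
  s <- ps_stats(store)
  list(inserts = s$inserts, hits = hits, max_size = s$max_size)
}

.new_best <- function() {
  list(policy = NULL, eval = NULL, quality = -Inf)
}

# strict improvement only: with rank-ordered / priority-ordered
# processing this realizes the lowest-rank-then-lexicographic tie-break
.maybe_update_best <- function(best, policy, ev_res) {
  if (ev_res$anonymous && ev_res$quality > best$quality) {
    best$policy <- policy
    best$eval <- ev_res
    best$quality <- ev_res$quality
  }
  best
}

.search_result <- function(best, optimal, stats) {
  structure(
    list(solution = if (is.null(best$policy)) NULL else
      list(policy = best$policy, evaluation = best$eval),
      optimal_guarantee = optimal,
      stats = stats),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (is.null(x$solution)) {
    cat("No anonymous policy exists for this configuration.\n")
  } else {
    cat("Solution policy (", paste(x$solution$policy, collapse = ","),
        "), quality ", sprintf("%.2f %%", 100 * x$solution$evaluation$quality),
        if (x$optimal_guarantee) " (globally optimal)" else
          " (best found within budget)", "\n", sep = "")
  }
  cat("Checked ", x$stats$checked, " of ",
      format(x$stats$lattice_size, big.mark = ","), " policies (",
      sprintf("%.2f %%", 100 * x$stats$checked / x$stats$lattice_size),
      ")\n", sep = "")
  invisible(x)
}

#' Exhaustive search oracle
#'
#' @param ev a [make_evaluator()] object.
#' @param config a [privacy_config()].
#' @param cap refuse lattices above this many policies (default 100000).
#' @return object of class `search_result`: `solution` (`NULL` or a list
#'   with `policy` and `evaluation`), `optimal_guarantee`, and `stats`
#'   (`checked`, `lattice_size`, per-property store statistics,
#'   `trajectory`, `seconds`).
#' @export
search_exhaustive <- function(ev, config = privacy_config(), cap = 1e5) {
  t0 <- proc.time()[["elapsed"]]
  spec <- ev$spec
  s <- lattice_size(spec)
  if (s > cap)
    stop("lattice has ", s, " policies (cap ", cap,
         "): use search_bfs() for spaces this large")
  it <- policy_iterator(spec)
  best <- .new_best()
  checked <- 0L
  repeat {
    x <- it()
    if (is.null(x)) break
    res <- evaluate_policy(ev, x, config)
    checked <- checked + 1L
    best <- .maybe_update_best(best, x, res)
  }
  .search_result(best, TRUE, list(
    checked = checked, lattice_size = s,
    quality_store = .empty_store_stats(),
    protection_store = .empty_store_stats(),
    trajectory = NULL,
    seconds = proc.time()[["elapsed"]] - t0))
}

#' Globally-optimal search with complete predictive information
#'
#' @inheritParams search_exhaustive
#' @param use_prediction disable both predictive properties to obtain the
#'   unpruned baseline (the solution is unchanged; every policy is
#'   checked).
#' @param store_option property-store implementation option (1-4).
#' @return a `search_result`; see [search_exhaustive()].
#' @export
search_optimal <- function(ev, config = privacy_config(),
                           use_prediction = TRUE, store_option = 4L) {
  t0 <- proc.time()[["elapsed"]]
  spec <- ev$spec
  s <- lattice_size(spec)
  protection <- if (use_prediction)
    property_store(spec$m, "down", store_option) else NULL
  insufficient <- if (use_prediction)
    property_store(spec$m, "up", store_option) else NULL
  hits_p <- 0L; hits_q <- 0L
  best <- .new_best()
  checked <- 0L
  it <- policy_iterator(spec)
  repeat {
    x <- it()
    if (is.null(x)) break
    if (use_prediction) {
      if (ps_query(protection, x)) { hits_p <- hits_p + 1L; next }
      if (ps_query(insufficient, x)) { hits_q <- hits_q + 1L; next }
    }
    res <- evaluate_policy(ev, x, config)
    checked <- checked + 1L
    best <- .maybe_update_best(best, x, res)
    if (use_prediction) {
      if (!res$anonymous) ps_insert(protection, x)
      if (res$quality_bound <= best$quality) ps_insert(insufficient, x)
    }
  }
  .search_result(best, TRUE, list(
    checked = checked, lattice_size = s,
    quality_store = .store_report(insufficient, hits_q),
    protection_store = .store_report(protection, hits_p),
    trajectory = NULL,
    seconds = proc.time()[["elapsed"]] - t0))
}

# deterministic priority-queue pop: highest quality, then lowest rank,
# then lexicographically smallest policy (O(queue) selection)
.pq_pop_index <- function(q) {
  n <- length(q$quality)
  cand <- which(q$quality == max(q$quality[seq_len(n)]))
  if (length(cand) > 1L) {
    cand <- cand[q$rank[cand] == min(q$rank[cand])]
    if (length(cand) > 1L)
      cand <- cand[order(q$key[cand])][1L]
  }
  cand[1L]
}

#' Best-first branch-and-bound search
#'
#' @inheritParams search_optimal
#' @param evaluation_budget stop after this many policy evaluations
#'   (anytime heuristic mode; `optimal_guarantee` becomes `FALSE` when the
#'   budget truncated the search).
#' @param time_limit wall-clock budget in seconds (heuristic mode).
#' @param use_protection_store also maintain the insufficient-protection
#'   (`"down"`) store; off by default — the branch-and-bound itself relies
#'   only on the insufficient-quality property.
#' @return a `search_result`; `stats$trajectory` is a two-column matrix
#'   (`evaluations`, `best_quality`) recording every incumbent
#'   improvement, and `stats$time_to_optimum` the elapsed seconds at the
#'   last improvement.
#' @export
search_bfs <- function(ev, config = privacy_config(),
                       use_prediction = TRUE, store_option = 4L,
                       evaluation_budget = NULL, time_limit = NULL,
                       use_protection_store = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  spec <- ev$spec
  s <- lattice_size(spec)
  insufficient <- if (use_prediction)
    property_store(spec$m, "up", store_option) else NULL
  protection <- if (use_prediction && use_protection_store)
    property_store(spec$m, "down", store_option) else NULL
  hits_q <- 0L; hits_p <- 0L
  best <- .new_best()
  checked <- 0L
  truncated <- FALSE
  traj_e <- integer(0); traj_q <- numeric(0)
  t_best <- NA_real_
  seen <- new.env(parent = emptyenv())

  out_of_budget <- function() {
    (!is.null(evaluation_budget) && checked >= evaluation_budget) ||
      (!is.null(time_limit) &&
         proc.time()[["elapsed"]] - t0 >= time_limit)
  }

  # queue as parallel vectors; policies/evaluations as lists
  q <- list(policy = list(), eval = list(),
            quality = numeric(0), rank = integer(0), key = character(0))
  push <- function(x, res) {
    i <- length(q$policy) + 1L
    q$policy[[i]] <<- x
    q$eval[[i]] <<- res
    q$quality[i] <<- res$quality
    q$rank[i] <<- policy_rank(x)
    q$key[i] <<- paste(sprintf("%06d", x), collapse = ".")
  }
  drop_idx <- function(i) {
    q$policy[[i]] <<- NULL
    q$eval[[i]] <<- NULL
    q$quality <<- q$quality[-i]
    q$rank <<- q$rank[-i]
    q$key <<- q$key[-i]
  }

  bottom <- spec$bottom
  assign(policy_key(bottom), TRUE, envir = seen)
  res0 <- evaluate_policy(ev, bottom, config)
  checked <- checked + 1L
  push(bottom, res0)

  while (length(q$policy) > 0L) {
    i <- .pq_pop_index(q)
    x <- q$policy[[i]]
    res <- q$eval[[i]]
    drop_idx(i)
    if (use_prediction && ps_query(insufficient, x)) {
      hits_q <- hits_q + 1L
      next
    }
    if (use_prediction && use_protection_store &&
        ps_query(protection, x)) {
      hits_p <- hits_p + 1L
      next
    }
    if (res$anonymous && res$quality > best$quality) {
      best <- .maybe_update_best(best, x, res)
      traj_e <- c(traj_e, checked)
      traj_q <- c(traj_q, best$quality)
      t_best <- proc.time()[["elapsed"]] - t0
    }
    if (use_prediction && use_protection_store && !res$anonymous)
      ps_insert(protection, x)
    if (res$quality_bound <= best$quality) {
      # no generalization of x can beat the incumbent
      if (use_prediction) ps_insert(insufficient, x)
      next
    }
    for (y in direct_generalizations(x, spec)) {
      ky <- policy_key(y)
      if (exists(ky, envir = seen, inherits = FALSE)) next
      if (out_of_budget()) { truncated <- TRUE; break }
      assign(ky, TRUE, envir = seen)
      res_y <- evaluate_policy(ev, y, config)
      checked <- checked + 1L
      push(y, res_y)
    }
    if (truncated) break
  }

  .search_result(best, !truncated, list(
    checked = checked, lattice_size = s,
    quality_store = .store_report(insufficient, hits_q),
    protection_store = .store_report(protection, hits_p),
    trajectory = cbind(evaluations = traj_e, best_quality = traj_q),
    time_to_optimum = t_best,
    seconds = proc.time()[["elapsed"]] - t0))
}

#' Human-readable search statistics
#'
#' Formats the counters of a search run: policies checked (absolute and as
#' a percentage of the lattice), and per predictive property the number
#' of inserts, the hit rate and the maximal antichain size (absolute and
#' relative to inserts).
#'
#' @param result a `search_result`.
#' @return a list with components `checked`, `checked_pct`,
#'   `quality_store`, `protection_store`, `time_to_optimum_fraction`
#'   (fraction of total runtime spent before the last incumbent
#'   improvement; `NA` when no solution), printed compactly.
#' @export
report_stats <- function(result) {
  st <- result$stats
  fmt_store <- function(ss) {
    hr <- if (ss$inserts + ss$hits > 0)
      100 * ss$hits / max(1L, st$checked + ss$hits) else 0
    list(inserts = ss$inserts, hits = ss$hits, hit_rate_pct = hr,
         max_antichain = ss$max_size,
         antichain_pct_of_inserts = if (ss$inserts > 0)
           100 * ss$max_size / ss$inserts else NA_real_)
  }
  out <- list(
    checked = st$checked,
    lattice_size = st$lattice_size,
    checked_pct = 100 * st$checked / st$lattice_size,
    quality_store = fmt_store(st$quality_store),
    protection_store = fmt_store(st$protection_store),
    time_to_optimum_fraction =
      if (!is.null(st$time_to_optimum) && !is.na(st$time_to_optimum) &&
          st$seconds > 0)
        st$time_to_optimum / st$seconds
      else NA_real_,
    seconds = st$seconds)
  class(out) <- "search_stats_report"
  out
}

#' @export
print.search_stats_report <- function(x, ...) {
  cat(sprintf("Checked %d / %s policies (%.2f %%)\n", x$checked,
              format(x$lattice_size, big.mark = ","), x$checked_pct))
  pr <- function(name, s) {
    cat(sprintf(
      "  %s: %d inserts, %d hits (%.1f %% hit rate), max antichain %d",
      name, s$inserts, s$hits, s$hit_rate_pct, s$max_antichain))
    if (!is.na(s$antichain_pct_of_inserts))
      cat(sprintf(" (%.1f %% of inserts)", s$antichain_pct_of_inserts))
    cat("\n")
  }
  pr("insufficient quality  ", x$quality_store)
  pr("insufficient protection", x$protection_store)
  if (!is.na(x$time_to_optimum_fraction))
    cat(sprintf("  optimum found after %.1f %% of the run\n",
                100 * x$time_to_optimum_fraction))
  invisible(x)
}
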