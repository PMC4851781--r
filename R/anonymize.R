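#' De-identify a dataset of categorical quasi-identifiers
#'
#' The main entry point. Searches the full-domain generalization lattice
#' for the policy of maximal Iyengar quality whose output — after
#' suppressing every equivalence class smaller than `k` — stays within
#' the suppression limit, and returns a fitted-model-style object from
#' which the anonymized data, the chosen policy and the search statistics
#' can be extracted.
#'
#' Defaults (`k = 5`, 5 % suppression limit) reflect common practice in
#' the biomedical domain.
#'
#' @param data data frame of character columns, one per quasi-identifier
#'   (see [read_qidata()]).
#' @param hierarchies list of [hierarchy()] objects, one per column, in
#'   order.
#' @param k minimum equivalence-class size (k-anonymity parameter).
#' @param suppression_limit maximum fraction of records that may be
#'   suppressed.
#' @param algorithm `"optimal"` (rank-order search with predictive
#'   pruning; the default), `"bfs"` (best-first branch and bound; required
#'   for very large lattices and for budgeted heuristic runs) or
#'   `"exhaustive"` (brute force, small lattices only).
#' @param use_prediction maintain and exploit predictive-property stores.
#' @param store_option property-store implementation option 1-4.
#' @param evaluation_budget,time_limit optional anytime budgets
#'   (`algorithm = "bfs"` only).
#' @param suppression_token token emitted for suppressed cells.
#' @param seed optional integer; fixed before the search for
#'   reproducibility (all strategies are deterministic, so this matters
#'   only if a caller's evaluator callbacks draw random numbers).
#' @return object of class `anonymization` with components `solution`
#'   (policy + evaluation, or `NULL` if the instance is unsolvable),
#'   `result` (the full `search_result`), `config`, `data`, `hierarchies`,
#'   `spec`.
#' @examples
#' fx <- toy_demographics()
#' fit <- anonymize(fx$data, fx$hierarchies, k = 2, suppression_limit = 0.25)
#' summary(fit)
#' coef(fit)              # chosen generalization levels
#' head(predict(fit))     # the anonymized records
#' @seealso [search_optimal()], [search_bfs()], [evaluate_policy()]
#' @export
anonymize <- function(data, hierarchies, k = 5L, suppression_limit = 0.05,
                      algorithm = c("optimal", "bfs", "exhaustive"),
                      use_prediction = TRUE, store_option = 4L,
                      evaluation_budget = NULL, time_limit = NULL,
                      suppression_token = "*", seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is.null(seed)) set.seed(as.integer(seed))
  config <- privacy_config(k, suppression_limit)
  ev <- make_evaluator(data, hierarchies)
  if (!is.null(evaluation_budget) || !is.null(time_limit)) {
    if (algorithm != "bfs")
      stop("time/evaluation budgets are only available with algorithm = 'bfs'")
  }
  result <- switch(algorithm,
    exhaustive = search_exhaustive(ev, config),
    optimal = search_optimal(ev, config, use_prediction = use_prediction,
                             store_option = store_option),
    bfs = search_bfs(ev, config, use_prediction = use_prediction,
                     store_option = store_option,
                     evaluation_budget = evaluation_budget,
                     time_limit = time_limit))
  structure(
    list(solution = result$solution,
         result = result,
         config = config,
         algorithm = algorithm,
         data = data,
         hierarchies = hierarchies,
         spec = ev$spec,
         suppression_token = suppression_token,
         call = match.call()),
    class = "anonymization")
}

#' @export
print.anonymization <- function(x, ...) {
  cat("De-identification fit (", x$algorithm, " search, k = ", x$config$k,
      ", suppression limit ",
      sprintf("%g %%", 100 * x$config$suppression_limit), ")\n", sep = "")
  if (is.null(x$solution)) {
    cat("No policy satisfies the privacy requirements",
        "(instance unsolvable at this k / suppression limit).\n")
  } else {
    e <- x$solution$evaluation
    cat("Policy (", paste(x$solution$policy, collapse = ","),
        "): quality ", sprintf("%.2f %%", 100 * e$quality), ", ",
        e$suppressed_count, "/", e$n, " records suppressed",
        if (x$result$optimal_guarantee) " [optimal]" else " [heuristic]",
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.anonymization <- function(object, ...) {
  out <- list(fit = object, report = report_stats(object$result))
  class(out) <- "summary.anonymization"
  out
}

#' @export
print.summary.anonymization <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$solution)) {
    e <- f$solution$evaluation
    lv <- f$solution$policy
    cat("Generalization levels:\n")
    for (i in seq_along(f$hierarchies))
      cat(sprintf("  %s: level %d of 0..%d\n",
                  f$hierarchies[[i]]$attribute, lv[i],
                  f$hierarchies[[i]]$height - 1L))
    kept <- e$class_sizes[e$class_sizes >= f$config$k]
    if (length(kept))
      cat(sprintf("Max re-identification risk (kept records): %.1f %%\n",
                  100 / min(kept)))
  }
  print(x$report)
  invisible(x)
}

#' Generalization levels of the fitted policy
#'
#' @param object an [anonymize()] fit.
#' @param ... unused.
#' @return named integer vector of levels, or `NULL` when unsolvable.
#' @export
coef.anonymization <- function(object, ...) {
  if (is.null(object$solution)) return(NULL)
  stats::setNames(object$solution$policy, object$spec$attribute_names)
}

#' Apply the fitted policy
#'
#' Applies the chosen generalization levels to `newdata` (default: the
#' data the fit was made on) and suppresses every equivalence class
#' smaller than `k` within it — the same three-step pipeline the search
#' optimized. For the original data this reproduces the anonymized
#' output exactly.
#'
#' @param object an [anonymize()] fit with a solution.
#' @param newdata optional data frame with the same quasi-identifiers.
#' @param ... unused.
#' @return data frame of the same shape as `newdata`, suppressed rows
#'   filled with the suppression token.
#' @export
predict.anonymization <- function(object, newdata = NULL, ...) {
  if (is.null(object$solution))
    stop("the fit has no solution; nothing to apply")
  if (is.null(newdata)) newdata <- object$data
  ev <- make_evaluator(newdata, object$hierarchies)
  res <- evaluate_policy(ev, object$solution$policy, object$config)
  generalize_data(newdata, object$hierarchies, object$solution$policy,
                  suppressed = res$suppressed,
                  token = object$suppression_token)
}

#' Plot the search trajectory
#'
#' For a BFS run, a step plot of the incumbent quality against the number
#' of policy evaluations (the anytime profile); for the other algorithms,
#' a bar comparing checked policies with the lattice size.
#'
#' @param x an [anonymize()] fit.
#' @param ... passed to the underlying plotting function.
#' @export
plot.anonymization <- function(x, ...) {
  traj <- x$result$stats$trajectory
  if (!is.null(traj) && nrow(traj) > 0) {
    graphics::plot(traj[, "evaluations"], 100 * traj[, "best_quality"],
                   type = "s", xlab = "policy evaluations",
                   ylab = "best quality [%]",
                   main = "Anytime quality trajectory", ...)
    graphics::points(traj[, "evaluations"], 100 * traj[, "best_quality"],
                     pch = 19)
  } else {
    st <- x$result$stats
    graphics::barplot(c(checked = st$checked,
                        lattice = st$lattice_size),
                      ylab = "policies", log = "",
                      main = "Checked vs. lattice size", ...)
  }
  invisible(x)
}

#' Compare property-store options and prediction on/off
#'
#' Runs the same search under all four store implementations and with
#' prediction disabled, asserts that every variant returns the same
#' solution (a mismatch is a correctness bug and raises an error, never a
#' report), and tabulates the counters.
#'
#' @param data,hierarchies the de-identification instance.
#' @param k,suppression_limit privacy configuration.
#' @param algorithm `"optimal"` or `"bfs"`.
#' @return data frame with one row per variant: store option (or "none"),
#'   checked policies, store inserts/hits, max antichain, stored elements,
#'   elapsed seconds.
#' @export
benchmark_stores <- function(data, hierarchies, k = 5L,
                             suppression_limit = 0.05,
                             algorithm = c("optimal", "bfs")) {
  algorithm <- match.arg(algorithm)
  ev <- make_evaluator(data, hierarchies)
  config <- privacy_config(k, suppression_limit)
  runner <- if (algorithm == "optimal") search_optimal else search_bfs
  runs <- lapply(1:4, function(opt)
    runner(ev, config, use_prediction = TRUE, store_option = opt))
  off <- runner(ev, config, use_prediction = FALSE)
  sols <- c(runs, list(off))
  qs <- vapply(sols, function(r)
    if (is.null(r$solution)) NA_real_ else r$solution$evaluation$quality,
    numeric(1))
  if (length(unique(is.na(qs))) > 1 ||
      (any(!is.na(qs)) && diff(range(qs)) > 1e-12))
    stop("correctness bug: store options / prediction variants disagree ",
         "on the solution (qualities: ", paste(qs, collapse = ", "), ")")
  row <- function(label, r) {
    qsto <- r$stats$quality_store
    data.frame(variant = label, checked = r$stats$checked,
               inserts = qsto$inserts, hits = qsto$hits,
               max_antichain = qsto$max_size,
               seconds = r$stats$seconds,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(1:4, function(i) row(paste0("option", i), runs[[i]])),
    list(row("no-prediction", off))))
  rownames(out) <- NULL
  out
}
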