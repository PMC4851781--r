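#' Implicit storage of predictive properties
#'
#' A predictive property is a fact about a policy's output that is
#' inherited upward to all generalizations (direction `"up"`, e.g.
#' insufficient data quality) or downward to all specializations
#' (direction `"down"`, e.g. insufficient protection against
#' re-identification). Rather than tagging policies in a materialized
#' lattice, a `property_store` keeps only the policies for which the
#' property was *discovered*; whether any other policy carries it is a
#' range query over that set. Since two comparable elements are redundant
#' (one implies the other), the stored set is kept as an antichain:
#' inserting `x` removes every stored generalization of `x` (for `"up"`;
#' mirrored for `"down"`).
#'
#' Four interchangeable implementations are provided for benchmarking;
#' all answer every query identically:
#' \describe{
#'   \item{option 1}{a simple list, no invariant;}
#'   \item{option 2}{a list maintaining the antichain invariant;}
#'   \item{option 3}{a prefix tree over policy components maintaining the
#'     antichain invariant: level-`i` tree nodes hold generalization
#'     levels of attribute `i`, each root-to-leaf path spells one stored
#'     policy, and a query follows only children whose level permits a
#'     specialization (generalization for `"down"`);}
#'   \item{option 4}{the prefix tree annotated with the minimum
#'     (`"up"`; maximum for `"down"`) rank of all policies below each
#'     node, which prunes whole subtrees whose ranks cannot beat the
#'     query's rank.}
#' }
#'
#' Queries are strict: a stored policy never marks itself. In the search
#' context this cannot arise anyway (a policy known to carry a property is
#' excluded and hence never inserted); the default is therefore the
#' unguarded mode matching that context. For standalone use, `guarded =
#' TRUE` makes `ps_insert()` query first and skip policies that are
#' already covered, so the antichain invariant survives arbitrary insert
#' orders.
#'
#' @param m number of attributes (policy length); must be >= 1.
#' @param direction `"up"` (property inherited by generalizations) or
#'   `"down"` (inherited by specializations).
#' @param option implementation option, 1-4 (default 4).
#' @param guarded query-before-insert mode (default `FALSE`).
#' @return an object of class `property_store` (mutable; environment
#'   semantics — `ps_insert()` modifies it in place).
#' @examples
#' st <- property_store(3, "up")
#' for (p in list(c(1, 1, 1), c(1, 3, 0), c(3, 2, 0))) ps_insert(st, p)
#' ps_query(st, c(1, 2, 2))   # TRUE: (1,1,1) is a strict specialization
#' ps_query(st, c(1, 1, 1))   # FALSE: never marks itself
#' length(ps_elements(st))    # 3 -- the stored antichain
#' @export
property_store <- function(m, direction = c("up", "down"), option = 4L,
                           guarded = FALSE) {
  direction <- match.arg(direction)
  m <- as.integer(m)
  if (is.na(m) || m < 1L)
    stop("property stores require at least one attribute (m >= 1)")
  option <- as.integer(option)
  if (!(option %in% 1:4)) stop("option must be 1, 2, 3 or 4")
  st <- new.env(parent = emptyenv())
  st$m <- m
  st$direction <- direction
  st$option <- option
  st$guarded <- isTRUE(guarded)
  st$up <- direction == "up"
  st$insert_count <- 0L
  st$size <- 0L
  st$max_size <- 0L
  if (option <= 2L) {
    st$mat <- matrix(integer(0), nrow = 0L, ncol = m)
    st$ranks <- numeric(0)
  } else {
    st$root <- .ps_node(-1L, st$up)
  }
  class(st) <- "property_store"
  st
}

.ps_node <- function(level, up) {
  n <- new.env(parent = emptyenv())
  n$level <- level
  n$children <- new.env(parent = emptyenv())
  n$bound <- if (up) Inf else -Inf
  n
}

.ps_child_levels <- function(node) {
  lv <- as.integer(ls(node$children))
  sort(lv)
}

#' @export
print.property_store <- function(x, ...) {
  labels <- c("simple list", "list with antichain",
              "prefix tree with antichain", "rank-annotated prefix tree")
  cat("Property store (", x$direction, ", option ", x$option, ": ",
      labels[x$option], ")\n  m = ", x$m, "; ", x$size,
      " stored / ", x$insert_count, " inserts; max antichain ",
      x$max_size, "\n", sep = "")
  invisible(x)
}

#' Query whether a policy carries the stored property
#'
#' For an `"up"` store, `TRUE` iff some stored policy is a strict
#' specialization of `x` (so `x` inherits the property); mirrored for
#' `"down"`. A stored policy equal to `x` never answers the query — use
#' [ps_contains()] for exact membership.
#'
#' @param store a [property_store()].
#' @param x integer policy vector.
#' @param trace when `TRUE` (tree options only), also return the levels of
#'   the tree nodes that the range query descended into, as a list of
#'   partial level paths — useful for verifying pruning behaviour.
#' @return logical scalar, or when `trace = TRUE` a list with elements
#'   `found` and `visited`.
#' @export
ps_query <- function(store, x, trace = FALSE) {
  x <- as.integer(x)
  if (length(x) != store$m) stop("policy length does not match store")
  rx <- sum(x)
  if (store$option <= 2L) {
    if (trace) stop("trace is only available for the tree options (3, 4)")
    if (store$size == 0L) return(FALSE)
    if (store$up)
      return(any(store$ranks < rx & colSums(t(store$mat) <= x) == store$m))
    return(any(store$ranks > rx & colSums(t(store$mat) >= x) == store$m))
  }
  visited <- if (trace) list() else NULL
  found <- FALSE
  descend <- function(node, depth, strict, path) {
    if (found) return()
    for (lv in .ps_child_levels(node)) {
      if (found) return()
      ok_level <- if (store$up) lv <= x[depth] else lv >= x[depth]
      if (!ok_level) {
        # children are sorted: for "up" no later child can qualify either
        if (store$up) break else next
      }
      child <- get(as.character(lv), envir = node$children)
      if (store$option == 4L) {
        ok_bound <- if (store$up) child$bound < rx else child$bound > rx
        if (!ok_bound) next
      }
      if (trace) visited[[length(visited) + 1L]] <<- c(path, lv)
      s2 <- strict || lv != x[depth]
      if (depth == store$m) {
        # leaf: a stored policy componentwise <= x (resp. >=); strictness
        # is guaranteed by the rank bound for option 4 and tracked
        # explicitly for option 3
        if (store$option == 4L || s2) { found <<- TRUE; return() }
      } else {
        descend(child, depth + 1L, s2, c(path, lv))
      }
    }
  }
  descend(store$root, 1L, FALSE, integer(0))
  if (trace) list(found = found, visited = visited) else found
}

#' Exact membership query
#'
#' Traverses the single path whose node levels equal the policy's
#' components (tree options) or scans the list.
#'
#' @param store a [property_store()].
#' @param x integer policy vector.
#' @return `TRUE` iff `x` itself is currently stored.
#' @export
ps_contains <- function(store, x) {
  x <- as.integer(x)
  if (length(x) != store$m) stop("policy length does not match store")
  if (store$option <= 2L) {
    if (store$size == 0L) return(FALSE)
    return(any(colSums(t(store$mat) == x) == store$m))
  }
  node <- store$root
  for (i in seq_len(store$m)) {
    key <- as.character(x[i])
    if (!exists(key, envir = node$children, inherits = FALSE)) return(FALSE)
    node <- get(key, envir = node$children)
  }
  TRUE
}

# Remove every stored y that is a generalization of x ("up") or a
# specialization ("down"): the mirrored range query, non-strict, with
# immediate reclamation of childless inner nodes. Bounds of surviving
# nodes are deliberately not recomputed: a stale bound is always on the
# safe side of the pruning test.
.ps_remove_covered <- function(store, x) {
  if (store$option <= 2L) {
    keep <- if (store$up)
      !(colSums(t(store$mat) >= x) == store$m)
    else
      !(colSums(t(store$mat) <= x) == store$m)
    removed <- sum(!keep)
    if (removed) {
      store$mat <- store$mat[keep, , drop = FALSE]
      store$ranks <- store$ranks[keep]
      store$size <- store$size - removed
    }
    return(invisible(removed))
  }
  removed <- 0L
  prune <- function(node, depth) {
    for (lv in .ps_child_levels(node)) {
      ok <- if (store$up) lv >= x[depth] else lv <= x[depth]
      if (!ok) next
      key <- as.character(lv)
      child <- get(key, envir = node$children)
      if (depth == store$m) {
        rm(list = key, envir = node$children)
        removed <<- removed + 1L
      } else {
        prune(child, depth + 1L)
        if (length(ls(child$children)) == 0L)
          rm(list = key, envir = node$children)
      }
    }
  }
  prune(store$root, 1L)
  store$size <- store$size - removed
  invisible(removed)
}

#' Insert a policy into a property store
#'
#' Options 2-4 first remove every stored policy that the new element makes
#' redundant (its generalizations for `"up"`, specializations for
#' `"down"`), then add the new element, so the stored set remains an
#' antichain. In guarded mode the insert is skipped when the policy is
#' already covered by a stored strict specialization/generalization.
#' `insert_count` counts attempted inserts either way.
#'
#' @param store a [property_store()] (modified in place).
#' @param x integer policy vector.
#' @return `TRUE` if the element was added, `FALSE` if a guarded insert
#'   was skipped; invisibly.
#' @export
ps_insert <- function(store, x) {
  x <- as.integer(x)
  if (length(x) != store$m) stop("policy length does not match store")
  store$insert_count <- store$insert_count + 1L
  if (store$guarded && (ps_query(store, x) || ps_contains(store, x)))
    return(invisible(FALSE))
  rx <- sum(x)
  if (store$option >= 2L) .ps_remove_covered(store, x)
  if (store$option <= 2L) {
    store$mat <- rbind(store$mat, x)
    store$ranks <- c(store$ranks, rx)
    store$size <- store$size + 1L
  } else {
    node <- store$root
    for (i in seq_len(store$m)) {
      key <- as.character(x[i])
      if (exists(key, envir = node$children, inherits = FALSE)) {
        node <- get(key, envir = node$children)
      } else {
        child <- .ps_node(x[i], store$up)
        assign(key, child, envir = node$children)
        node <- child
      }
      node$bound <- if (store$up) min(node$bound, rx) else max(node$bound, rx)
    }
    store$size <- store$size + 1L
  }
  store$max_size <- max(store$max_size, store$size)
  invisible(TRUE)
}

#' Stored elements of a property store
#'
#' @param store a [property_store()].
#' @return list of integer policy vectors, in deterministic (tree /
#'   lexicographic traversal or insertion) order. For options 2-4 this set
#'   is always an antichain.
#' @export
ps_elements <- function(store) {
  if (store$option <= 2L) {
    return(lapply(seq_len(store$size), function(r) store$mat[r, ]))
  }
  out <- list()
  walk <- function(node, depth, path) {
    for (lv in .ps_child_levels(node)) {
      child <- get(as.character(lv), envir = node$children)
      if (depth == store$m)
        out[[length(out) + 1L]] <<- as.integer(c(path, lv))
      else
        walk(child, depth + 1L, c(path, lv))
    }
  }
  walk(store$root, 1L, integer(0))
  out
}

#' Store statistics
#'
#' @param store a [property_store()].
#' @return list with `inserts` (attempted inserts, the count that bounds
#'   the cost of every store operation), `size` (current antichain size)
#'   and `max_size` (maximal size
#'   ever held — the reported antichain statistic).
#' @export
ps_stats <- function(store) {
  list(inserts = store$insert_count, size = store$size,
       max_size = store$max_size)
}

#' Check store invariants
#'
#' Verifies (a) that options 2-4 hold an antichain and (b) for option 4,
#' that every node's rank bound is on the safe side of the truth: at most
#' (for `"up"`) or at least (for `"down"`) the extreme rank over its
#' subtree. With `exact_bounds = TRUE` the bounds must equal the subtree
#' extremes — guaranteed for insert-only workloads; after removals,
#' surviving off-path nodes may keep a conservatively stale bound (they
#' are never recomputed, by design).
#'
#' @param store a [property_store()].
#' @param exact_bounds require equality rather than safety.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validate_store <- function(store, exact_bounds = FALSE) {
  els <- ps_elements(store)
  if (store$option >= 2L && !is_antichain(els))
    stop("stored set is not an antichain")
  if (store$option == 4L) {
    check <- function(node, depth, rank_above) {
      ranks <- numeric(0)
      for (lv in .ps_child_levels(node)) {
        child <- get(as.character(lv), envir = node$children)
        if (depth == store$m) {
          truth <- rank_above + lv   # a leaf's subtree is its own policy
          ranks <- c(ranks, truth)
        } else {
          truth_ranks <- check(child, depth + 1L, rank_above + lv)
          truth <- if (store$up) min(truth_ranks) else max(truth_ranks)
          ranks <- c(ranks, truth_ranks)
        }
        safe <- if (store$up) child$bound <= truth else child$bound >= truth
        if (!safe)
          stop("node bound ", child$bound, " on the unsafe side of true ",
               if (store$up) "min " else "max ", truth)
        if (exact_bounds && child$bound != truth)
          stop("node bound ", child$bound, " != true subtree extreme ", truth)
      }
      ranks
    }
    check(store$root, 1L, 0L)
  }
  TRUE
}

#' Dump a store's elements as JSON
#'
#' Elements are sorted lexicographically so that dumps from different
#' implementations of the same antichain are byte-identical — intended for
#' debugging and cross-implementation diffing.
#'
#' @param store a [property_store()].
#' @return a JSON string (array of integer arrays).
#' @export
store_to_json <- function(store) {
  els <- ps_elements(store)
  if (length(els)) {
    keys <- vapply(els, function(p) paste(sprintf("%09d", p), collapse = "."),
                   character(1))
    els <- els[order(keys)]
  }
  jsonlite::toJSON(els, auto_unbox = FALSE)
}
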