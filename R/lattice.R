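#' Generalization lattice of de-identification policies
#'
#' A de-identification policy assigns one generalization level to each
#' quasi-identifier; with the componentwise order, the set of all policies
#' forms a bounded, ranked lattice whose bottom is the untransformed data
#' and whose top is maximal generalization. Policies are represented as
#' plain integer vectors (0-based levels), so they can be compared, hashed
#' (via [policy_key()]) and stored without any dedicated class. The lattice
#' itself is never materialized: a `lattice_spec` only records the per
#' attribute hierarchy heights.
#'
#' @param heights integer vector of hierarchy heights, all >= 1; attribute
#'   `i` admits levels `0 ... heights[i] - 1`.
#' @param attribute_names optional character vector naming the attributes.
#' @return An object of class `lattice_spec` with elements `heights`,
#'   `attribute_names`, `m` (number of attributes), `bottom` and `top`.
#' @examples
#' spec <- lattice_spec(c(3, 2), c("age", "sex"))
#' lattice_size(spec)          # 6 policies
#' policy_rank(c(1, 2, 2))     # 5
#' @export
lattice_spec <- function(heights, attribute_names = NULL) {
  heights <- as.integer(heights)
  if (length(heights) < 1L)
    stop("a lattice needs at least one attribute")
  if (anyNA(heights) || any(heights < 1L))
    stop("hierarchy heights must be positive integers")
  if (is.null(attribute_names))
    attribute_names <- paste0("attr", seq_along(heights))
  if (length(attribute_names) != length(heights))
    stop("attribute_names must match heights in length")
  structure(
    list(heights = heights,
         attribute_names = as.character(attribute_names),
         m = length(heights),
         bottom = integer(length(heights)),
         top = heights - 1L),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("Generalization lattice:", x$m, "attributes, heights (",
      paste(x$heights, collapse = ", "), "), ",
      format(lattice_size(x), big.mark = ","), " policies\n", sep = "")
  invisible(x)
}

#' Number of policies in a lattice
#'
#' The product of the hierarchy heights; exponential in the number of
#' attributes, which is why the lattice is never stored explicitly.
#'
#' @param spec a [lattice_spec()].
#' @return a double (lattices routinely exceed integer range).
#' @export
lattice_size <- function(spec) {
  prod(as.numeric(spec$heights))
}

#' Componentwise partial order on policies
#'
#' `policy_precedes(x, y)` is `TRUE` when `x` specifies at most the
#' generalization of `y` in every component, i.e. `x` is a specialization
#' of `y` (reflexive). `policy_strictly_precedes()` additionally requires
#' `x != y`.
#'
#' @param x,y integer policy vectors of equal length.
#' @return logical scalar.
#' @export
policy_precedes <- function(x, y) {
  if (length(x) != length(y))
    stop("policies of unequal length are incomparable by contract")
  all(x <= y)
}

#' @rdname policy_precedes
#' @export
policy_strictly_precedes <- function(x, y) {
  policy_precedes(x, y) && any(x < y)
}

#' Rank of a policy
#'
#' The sum of its generalization levels; the level index of the policy in
#' the lattice's Hasse diagram. Strictly monotone along strict
#' specialization.
#'
#' @param x integer policy vector.
#' @return integer scalar.
#' @export
policy_rank <- function(x) {
  sum(as.integer(x))
}

#' Validate a policy against a lattice
#'
#' @param x integer policy vector.
#' @param spec a [lattice_spec()].
#' @return `x`, invisibly, as integer; errors if invalid.
#' @export
validate_policy <- function(x, spec) {
  x <- as.integer(x)
  if (length(x) != spec$m)
    stop("policy has ", length(x), " components, lattice expects ", spec$m)
  if (anyNA(x) || any(x < 0L) || any(x > spec$top))
    stop("policy (", paste(x, collapse = ","),
         ") has levels outside 0..heights-1")
  invisible(x)
}

#' Direct generalizations of a policy
#'
#' All policies reachable by incrementing exactly one component that is not
#' yet at its maximum; the upward neighbours in the Hasse diagram. Empty for
#' the top policy.
#'
#' @param x integer policy vector.
#' @param spec a [lattice_spec()].
#' @return list of integer policy vectors, each of rank `policy_rank(x) + 1`.
#' @export
direct_generalizations <- function(x, spec) {
  x <- validate_policy(x, spec)
  free <- which(x < spec$top)
  lapply(free, function(i) { y <- x; y[i] <- y[i] + 1L; y })
}

#' String key for a policy
#'
#' Canonical hashable representation (levels joined by "."), used for
#' seen-set bookkeeping in the search algorithms and as a deterministic
#' lexicographic tie-break.
#'
#' @param x integer policy vector.
#' @return character scalar.
#' @export
policy_key <- function(x) {
  paste(x, collapse = ".")
}

# Lexicographically smallest tuple with component sum `r` under caps
# (filled left to right with as little as possible); NULL if infeasible.
.first_of_rank <- function(r, caps) {
  m <- length(caps)
  if (r > sum(caps)) return(NULL)
  x <- integer(m)
  tail_cap <- rev(cumsum(rev(as.numeric(caps)))) - as.numeric(caps)
  rem <- r
  for (i in seq_len(m)) {
    x[i] <- as.integer(max(0, rem - tail_cap[i]))
    rem <- rem - x[i]
  }
  x
}

# Next tuple of the same sum in ascending lexicographic order, or NULL.
.next_of_rank <- function(x, caps) {
  m <- length(x)
  if (m == 1L) return(NULL)
  suffix_sum <- 0L
  for (i in (m - 1L):1L) {
    suffix_sum <- suffix_sum + x[i + 1L]
    if (x[i] < caps[i] && suffix_sum >= 1L) {
      y <- x
      y[i] <- y[i] + 1L
      idx <- if (i + 1L <= m) (i + 1L):m else integer(0)
      fill <- .first_of_rank(suffix_sum - 1L, caps[idx])
      y[idx] <- fill
      return(y)
    }
  }
  NULL
}

#' Enumerate all policies in rank order
#'
#' Returns a constant-memory iterator that yields every policy of the
#' lattice exactly once, grouped by non-decreasing rank and, within one
#' rank, in ascending lexicographic order. Generation is odometer-style:
#' no part of the lattice is ever stored.
#'
#' @param spec a [lattice_spec()].
#' @return a function of no arguments returning the next policy (integer
#'   vector), or `NULL` once exhausted.
#' @examples
#' it <- policy_iterator(lattice_spec(c(2, 2)))
#' it(); it(); it(); it(); it()  # (0,0) (0,1) (1,0) (1,1) NULL
#' @export
policy_iterator <- function(spec) {
  caps <- spec$top
  max_rank <- sum(caps)
  state <- NULL
  rank_now <- -1L
  function() {
    if (rank_now < 0L) {
      rank_now <<- 0L
      state <<- integer(spec$m)
      return(state)
    }
    if (is.null(state)) return(NULL)
    nxt <- .next_of_rank(state, caps)
    while (is.null(nxt)) {
      rank_now <<- rank_now + 1L
      if (rank_now > max_rank) { state <<- NULL; return(NULL) }
      nxt <- .first_of_rank(rank_now, caps)
    }
    state <<- nxt
    state
  }
}

#' Materialize all policies of a small lattice
#'
#' Convenience wrapper around [policy_iterator()] for testing and for the
#' exhaustive search oracle; refuses lattices above `cap` policies.
#'
#' @param spec a [lattice_spec()].
#' @param cap refuse lattices larger than this many policies.
#' @return list of integer policy vectors in rank order.
#' @export
all_policies <- function(spec, cap = 1e5) {
  s <- lattice_size(spec)
  if (s > cap)
    stop("lattice has ", s, " policies, above the cap of ", cap,
         "; use the iterator or the BFS search")
  it <- policy_iterator(spec)
  out <- vector("list", s)
  for (i in seq_len(s)) out[[i]] <- it()
  out
}

#' Is a set of policies an antichain?
#'
#' `TRUE` when the policies are pairwise incomparable under the
#' componentwise order — the minimal representation of a predictive
#' property's extent. Vacuously true for the empty set.
#'
#' @param policies list of integer policy vectors of equal length.
#' @return logical scalar.
#' @export
is_antichain <- function(policies) {
  n <- length(policies)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      x <- policies[[i]]; y <- policies[[j]]
      # duplicates are the same set element, not a comparable pair
      if ((all(x <= y) || all(y <= x)) && !identical(as.integer(x), as.integer(y)))
        return(FALSE)
    }
  }
  TRUE
}
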