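# Shared test utilities: naive reference implementations kept deliberately
# independent of the package's data structures.

# A property store oracle that just remembers every inserted policy and
# answers queries by scanning the full history with the strict
# componentwise test.
naive_store <- function(direction = "up") {
  hist <- list()
  list(
    insert = function(x) hist[[length(hist) + 1L]] <<- as.integer(x),
    query = function(x) {
      any(vapply(hist, function(y) {
        if (direction == "up") all(y <= x) && any(y < x)
        else all(y >= x) && any(y > x)
      }, logical(1)))
    },
    elements = function() hist)
}

random_policy <- function(heights) {
  vapply(heights, function(h) sample.int(h, 1L) - 1L, integer(1))
}

# A random strict specialization/generalization pair within `heights`.
random_strict_pair <- function(heights) {
  repeat {
    x <- random_policy(heights)
    y <- random_policy(heights)
    lo <- pmin(x, y); hi <- pmax(x, y)
    if (any(lo < hi)) return(list(lo = lo, hi = hi))
  }
}

# Small random de-identification instance for search tests.
random_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1L)
  synth_instance(n = sample(20:80, 1L),
                 domains = sample(3:8, m, replace = TRUE),
                 dist = sample(c("uniform", "zipf"), 1L),
                 outlier_fraction = stats::runif(1, 0, 0.1),
                 seed = seed)
}

# Random policy of exactly rank `r` under per-component caps (used to
# build incomparable, removal-free insert workloads).
random_policy_of_rank <- function(r, caps) {
  repeat {
    x <- vapply(caps, function(cp) sample.int(cp + 1L, 1L) - 1L, integer(1))
    d <- r - sum(x)
    if (d == 0L) return(x)
    if (d > 0L) {
      room <- caps - x
      if (sum(room) < d) next
      for (i in order(room, decreasing = TRUE)) {
        add <- min(room[i], d)
        x[i] <- x[i] + add
        d <- d - add
        if (d == 0L) break
      }
      return(x)
    }
    for (i in order(x, decreasing = TRUE)) {
      sub <- min(x[i], -d)
      x[i] <- x[i] - sub
      d <- d + sub
      if (d == 0L) break
    }
    return(x)
  }
}

solution_quality <- function(result) {
  if (is.null(result$solution)) NA_real_
  else result$solution$evaluation$quality
}
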