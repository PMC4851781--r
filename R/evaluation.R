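#' Evaluating de-identification policies
#'
#' Applying a policy is a three-step process: (1) generalize every
#' attribute to the level the policy specifies; (2) suppress all records in
#' equivalence classes that violate the privacy model (here: classes
#' smaller than k); (3) the policy is a solution candidate ("anonymous")
#' when the number of suppressed records is within the suppression limit.
#'
#' Data quality follows the loss model of Iyengar: each cell contributes
#' the fraction of its attribute's domain covered by its (generalized)
#' label, `(M_g - 1) / (M - 1)` where `M_g` is the number of base values
#' the label covers and `M` the domain size; an untouched value
#' contributes 0, a suppressed cell 1. Quality is one minus the mean cell
#' loss over all `n * m` cells, so the original data scores 100 % and a
#' fully removed dataset 0 %. Because suppression is decided per policy,
#' quality is not monotone along generalization — but the quality of the
#' generalization-only output (no suppression) is, and serves as a
#' monotone upper bound `u' >= u` for pruning.
#'
#' `make_evaluator()` pre-indexes a dataset against its hierarchies so
#' that thousands of policies can be evaluated cheaply during a search;
#' `evaluate_policy()` is the user-facing single-policy entry point.
#'
#' @name policy-evaluation
NULL

#' Privacy configuration
#'
#' @param k minimum equivalence-class size (k-anonymity; bounds the
#'   re-identification risk of every record by 1/k). `k = 1` means no
#'   constraint.
#' @param suppression_limit maximum fraction of records that may be
#'   suppressed; interpreted as an integer budget of
#'   `floor(suppression_limit * n)` records.
#' @return object of class `privacy_config`.
#' @export
privacy_config <- function(k = 5L, suppression_limit = 0.05) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (is.na(suppression_limit) || suppression_limit < 0 ||
      suppression_limit > 1)
    stop("suppression_limit must lie in [0, 1]")
  structure(list(k = k, suppression_limit = suppression_limit),
            class = "privacy_config")
}

#' Pre-index a dataset for repeated policy evaluation
#'
#' @param data validated quasi-identifier data frame (see [read_qidata()]).
#' @param hierarchies list of [hierarchy()] objects, one per column.
#' @return object of class `policy_evaluator` holding, per attribute, the
#'   record-to-domain index, integer label codes per level (for grouping)
#'   and per-level cell-loss lookups.
#' @export
make_evaluator <- function(data, hierarchies) {
  data <- validate_qidata(data, hierarchies)
  spec <- lattice_spec_for(hierarchies)
  n <- nrow(data)
  attrs <- lapply(seq_along(hierarchies), function(i) {
    h <- hierarchies[[i]]
    vidx <- match(data[[i]], rownames(h$labels))
    codes <- vector("list", h$height)   # label code per base value, per level
    ngroups <- integer(h$height)
    loss <- matrix(0, nrow = h$domain_size, ncol = h$height)
    for (l in seq_len(h$height)) {
      f <- factor(h$labels[, l], levels = unique(h$labels[, l]))
      codes[[l]] <- as.integer(f)
      ngroups[l] <- nlevels(f)
      cnt <- h$leaf_count[[l]][h$labels[, l]]
      loss[, l] <- if (h$domain_size > 1L)
        (as.numeric(cnt) - 1) / (h$domain_size - 1)
      else 0      # constant column: nothing to lose by generalizing
    }
    list(h = h, vidx = vidx, codes = codes, ngroups = ngroups, loss = loss)
  })
  structure(list(data = data, hierarchies = hierarchies, spec = spec,
                 n = n, m = spec$m, attrs = attrs),
            class = "policy_evaluator")
}

# Integer class id per record under `policy` (internal).
.class_ids <- function(ev, policy) {
  ids <- rep(1, ev$n)
  for (i in seq_len(ev$m)) {
    a <- ev$attrs[[i]]
    g <- a$codes[[policy[i] + 1L]][a$vidx]
    ids <- (ids - 1) * a$ngroups[policy[i] + 1L] + g
  }
  ids
}

#' Equivalence-class sizes under a policy
#'
#' Groups records that are identical on all generalized attributes; the
#' sizes always sum to `n`.
#'
#' @param ev a [make_evaluator()] object (or pass `data` + `hierarchies`
#'   to the convenience wrapper below).
#' @param policy integer policy vector.
#' @return integer vector of class sizes (a multiset; order unspecified).
#' @export
class_sizes <- function(ev, policy) {
  policy <- validate_policy(policy, ev$spec)
  if (ev$n == 0L) return(integer(0))
  ids <- .class_ids(ev, policy)
  as.integer(tabulate(match(ids, unique(ids))))
}

#' @rdname class_sizes
#' @param data,hierarchies raw inputs for one-off use.
#' @export
equivalence_class_sizes <- function(data, hierarchies, policy) {
  class_sizes(make_evaluator(data, hierarchies), policy)
}

#' k-anonymity check on class sizes
#'
#' @param sizes integer multiset of equivalence-class sizes.
#' @param k minimum class size.
#' @return `TRUE` iff every class has at least `k` records (vacuously true
#'   when there are no classes).
#' @export
is_k_anonymous <- function(sizes, k) {
  if (k < 1L) stop("k must be >= 1")
  length(sizes) == 0L || min(sizes) >= k
}

#' Maximal re-identification risk
#'
#' Under the prosecutor model the risk of a record in a class of size `s`
#' is `1/s`; the dataset-level maximum is driven by the smallest class
#' (e.g. exactly 50 % for a 2-anonymous dataset whose smallest class has
#' two records).
#'
#' @param sizes non-empty integer multiset of equivalence-class sizes.
#' @return fraction in (0, 1].
#' @export
max_reidentification_risk <- function(sizes) {
  if (length(sizes) == 0L)
    stop("re-identification risk is undefined for an empty dataset")
  1 / min(sizes)
}

#' Loss of a single cell
#'
#' @param h a [hierarchy()].
#' @param level generalization level of the cell's label.
#' @param label the (generalized) label; ignored when `suppressed`.
#' @param suppressed was the record suppressed?
#' @return fraction in `[0, 1]`: 0 for an untouched base value, 1 for a
#'   suppressed cell or a label covering the whole domain,
#'   `(M_g - 1)/(M - 1)` in between; 0 for a singleton domain.
#' @export
cell_loss <- function(h, level, label, suppressed = FALSE) {
  if (suppressed) return(1)
  if (level < 0L || level >= h$height)
    stop("level ", level, " outside the hierarchy for '", h$attribute, "'")
  cnt <- h$leaf_count[[level + 1L]][label]
  if (is.na(cnt))
    stop("label '", label, "' does not exist at level ", level,
         " of attribute '", h$attribute, "'")
  if (h$domain_size == 1L) return(0)
  (as.numeric(cnt) - 1) / (h$domain_size - 1)
}

# Per-record generalization loss (sum over attributes) under `policy`.
.record_loss <- function(ev, policy) {
  if (ev$n == 0L) return(numeric(0))
  loss <- numeric(ev$n)
  for (i in seq_len(ev$m)) {
    a <- ev$attrs[[i]]
    loss <- loss + a$loss[a$vidx, policy[i] + 1L]
  }
  loss
}

#' Iyengar quality of a transformed dataset
#'
#' @param ev a [make_evaluator()] object.
#' @param policy integer policy vector.
#' @param suppressed logical vector of per-record suppression flags.
#' @return fraction in `[0, 1]`; 1 for an empty dataset by convention.
#' @export
quality <- function(ev, policy, suppressed = rep(FALSE, ev$n)) {
  policy <- validate_policy(policy, ev$spec)
  stopifnot(length(suppressed) == ev$n)
  if (ev$n == 0L) return(1)
  rl <- .record_loss(ev, policy)
  total <- sum(rl[!suppressed]) + sum(suppressed) * ev$m
  1 - total / (ev$n * ev$m)
}

#' Generalization-only quality bound
#'
#' The quality the policy would achieve with no suppression at all; an
#' upper bound `u'` on the achievable quality `u`, and monotone
#' non-increasing along generalization — the basis of the
#' insufficient-quality predictive property.
#'
#' @inheritParams quality
#' @return fraction in `[0, 1]`.
#' @export
quality_bound <- function(ev, policy) {
  quality(ev, policy, rep(FALSE, ev$n))
}

#' Evaluate a policy end to end
#'
#' Runs the generalize / suppress / check pipeline and computes quality
#' and its bound. Records in classes smaller than `k` are suppressed; the
#' policy is a solution candidate when at most
#' `floor(suppression_limit * n)` records needed suppression.
#'
#' @param ev a [make_evaluator()] object, or a data frame (then
#'   `hierarchies` must be given and an evaluator is built on the fly).
#' @param policy integer policy vector.
#' @param config a [privacy_config()] (or pass `k` / `suppression_limit`).
#' @param hierarchies only when `ev` is a raw data frame.
#' @param k,suppression_limit shortcut parameters overriding `config`.
#' @return object of class `policy_evaluation`: list with `policy`,
#'   `anonymous`, `suppressed_count`, `suppressed` (flags), `quality`,
#'   `quality_bound`, `class_sizes` (pre-suppression), `n`, `k`,
#'   `suppression_limit`.
#' @examples
#' fx <- toy_demographics()
#' ev <- make_evaluator(fx$data, fx$hierarchies)
#' evaluate_policy(ev, c(1, 0), k = 2, suppression_limit = 0.25)
#' @export
evaluate_policy <- function(ev, policy, config = NULL, hierarchies = NULL,
                            k = NULL, suppression_limit = NULL) {
  if (is.data.frame(ev)) {
    if (is.null(hierarchies))
      stop("hierarchies are required when passing a raw data frame")
    ev <- make_evaluator(ev, hierarchies)
  }
  if (is.null(config)) config <- privacy_config()
  if (!is.null(k)) config$k <- as.integer(k)
  if (!is.null(suppression_limit)) config$suppression_limit <- suppression_limit
  policy <- validate_policy(policy, ev$spec)
  n <- ev$n
  if (n == 0L) {
    return(structure(list(policy = policy, anonymous = TRUE,
                          suppressed_count = 0L, suppressed = logical(0),
                          quality = 1, quality_bound = 1,
                          class_sizes = integer(0), n = 0L, k = config$k,
                          suppression_limit = config$suppression_limit),
                     class = "policy_evaluation"))
  }
  ids <- .class_ids(ev, policy)
  uid <- unique(ids)
  grp <- match(ids, uid)
  sizes <- tabulate(grp)
  suppressed <- sizes[grp] < config$k
  scount <- sum(suppressed)
  budget <- floor(config$suppression_limit * n)
  rl <- .record_loss(ev, policy)
  total_g <- sum(rl)
  u_bound <- 1 - total_g / (n * ev$m)
  u <- 1 - (total_g - sum(rl[suppressed]) + scount * ev$m) / (n * ev$m)
  structure(list(policy = policy, anonymous = scount <= budget,
                 suppressed_count = as.integer(scount),
                 suppressed = suppressed,
                 quality = u, quality_bound = u_bound,
                 class_sizes = as.integer(sizes), n = n, k = config$k,
                 suppression_limit = config$suppression_limit),
            class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat("Policy (", paste(x$policy, collapse = ","), "): ",
      if (x$anonymous) "solution candidate" else "NOT anonymous",
      "\n  suppressed ", x$suppressed_count, "/", x$n,
      " records; quality ", sprintf("%.1f %%", 100 * x$quality),
      " (bound ", sprintf("%.1f %%", 100 * x$quality_bound), ")\n",
      sep = "")
  invisible(x)
}
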