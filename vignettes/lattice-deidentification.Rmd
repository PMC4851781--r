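---
title: "De-identification over generalization lattices: model, data structures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identification over generalization lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anonlattice)
```

## The transformation model

`anonlattice` de-identifies a table of categorical quasi-identifiers by
*full-domain generalization followed by record suppression*. Each
attribute carries a user-defined generalization hierarchy: level 0 is the
original value, higher levels are increasingly coarse labels, and the
hierarchy must be tree-structured (values sharing a label at one level
share labels at all coarser levels). A de-identification policy
`x = (x1, ..., xm)` picks one level per attribute; applying it means

1. generalize every attribute `i` to level `x_i`;
2. suppress all records in equivalence classes (maximal sets of records
   identical on all generalized attributes) smaller than `k`;
3. accept the policy as a solution candidate if at most
   `floor(suppression_limit * n)` records were suppressed.

The policies form a bounded lattice under the componentwise order, with
`rank(x) = sum(x_i)`. The model is truthful (no perturbation), its output
is easy for epidemiologists to interpret, and suppression lets a few
outliers absorb what would otherwise be dataset-wide generalization.

k-anonymity is the privacy model: every kept record shares its
generalized quasi-identifier values with at least `k - 1` others, so the
prosecutor-model re-identification risk is at most `1/k` (exactly 50 %
when the smallest class has two records).

## The quality model and its bound

Quality is the Iyengar loss model. A cell holding a label that covers
`M_g` of its attribute's `M` base values loses `(M_g - 1) / (M - 1)`;
an untouched value loses 0, a suppressed cell (and a single root label)
loses 1. Quality is one minus the mean loss over all `n * m` cells, so
the untouched dataset scores 1 and a fully removed one 0. Three
conventions make the measure total:

* **singleton domains** (`M = 1`): the ratio is 0/0; we define the loss
  as 0 unless suppressed, since a constant column carries no linkage
  information that generalization could destroy;
* **empty datasets** (`n = 0`): quality 1 and "anonymous" by convention,
  so the search code needs no special cases;
* **suppression granularity**: whole records; suppressed records remain
  in the output as token rows and count fully (loss 1 per cell) toward
  the average.

Because more generalization can *reduce* suppression, quality `u` is not
monotone along the lattice. The quality `u'` of the generalization-only
output (step 1 alone) is monotone non-increasing and satisfies
`u <= u'`, which is what makes branch-and-bound pruning sound. The
suppression limit is deliberately an integer budget
(`floor(limit * n)`): a "5 %" limit must resolve to an exact record
count to be reproducible across implementations.

## Predictive properties and the antichain store

Two facts propagate through the lattice:

* **insufficient protection**: a policy that is not k-anonymous condemns
  all its *specializations* (distinguishability only decreases with
  generalization, even with suppression);
* **insufficient quality**: once `u'(x)` is at or below the incumbent's
  quality, every *generalization* of `x` is condemned
  (`u(y) <= u'(y) <= u'(x)` for `y` above `x`).

Instead of tagging policies in a materialized lattice (memory and
tagging cost proportional to the lattice size `s = prod(h_i)`), the
package stores only the policies where a property was *discovered*. Two
comparable stored elements are redundant — one implies the other — so the
store keeps an antichain: inserting `x` into an upward store evicts every
stored generalization of `x` (mirrored downward). The cost of all
operations is then bounded by the number of policies actually checked,
not by `s`.

The store is a prefix tree: depth-`i` nodes hold generalization levels of
attribute `i`, each root-to-leaf path is one stored policy, and a
membership test is a range query following children with
`child.level <= x_i` (upward; mirrored downward). Each node additionally
carries the minimum (maximum) rank of the policies below it, and the
query also requires `child.bound < rank(x)` (`>` downward), which prunes
whole subtrees and, as a side effect, guarantees strictness: a stored
policy never marks itself. Four implementations — plain list, list with
the antichain invariant, plain prefix tree, rank-annotated prefix tree —
answer every query identically and exist so the incremental value of each
refinement can be benchmarked (`benchmark_stores()`).

Two subtleties are worth recording:

* **Bound staleness.** When an eviction removes a leaf, surviving nodes
  keep their bounds: recomputing them would cost a subtree traversal, and
  a stale bound errs only toward *less* pruning, never toward a wrong
  answer (an upward node's stored minimum can only be at or below the
  true minimum of what remains). `validate_store()` therefore checks the
  safe inequality in general and exact equality for eviction-free
  workloads, and the operative contract — query equivalence with a naive
  scan of the full insert history — is tested directly.
* **Guarded vs unguarded inserts.** In the search context a policy known
  to carry a property is excluded from the search and thus never
  inserted, so the insert path does not need to check first ("unguarded",
  the default). As a standalone structure that precondition does not
  hold, so `guarded = TRUE` performs a query-before-insert and keeps the
  antichain invariant under arbitrary insert orders.

## Search strategies

* `search_exhaustive()` evaluates every policy in rank order — the
  oracle against which the others are tested; it refuses lattices above
  100,000 policies.
* `search_optimal()` iterates the same enumeration but first asks both
  property stores; skipped policies are counted as hits and never
  evaluated. Both properties are maintained, matching what a
  complete-information globally-optimal algorithm uses. With strictly
  rank-ordered traversal the downward (protection) store can never
  produce hits — a strict generalization of the current policy always has
  a higher rank and so has not been inserted yet; it is kept because the
  store is shared infrastructure for traversal orders that do revisit
  lower ranks (path-wise strategies), and its counters make that
  behaviour visible rather than hidden.
* `search_bfs()` is a best-first branch and bound from the bottom: a
  priority queue ordered by evaluated quality (highest first) drives
  expansion; a popped policy that the insufficient-quality store marks is
  discarded; a policy whose bound cannot beat the incumbent is inserted
  into the store and not expanded. Run to exhaustion the result is
  globally optimal; under `evaluation_budget` or `time_limit` it is an
  anytime heuristic whose incumbent trajectory is recorded.

Design points the underlying procedure leaves open, decided here:

* **Evaluation timing in BFS.** Successors could be evaluated at enqueue
  time or at pop time; evaluating at both would double the work. Each
  policy is evaluated exactly once, at enqueue time, and the queue is
  ordered by that evaluated quality `u`; popping only updates the
  incumbent, prunes, or expands.
* **Queue priority for non-anonymous policies.** Their evaluated `u`
  (not `u'`) orders the queue, but only anonymous policies may become the
  incumbent; their `u'` still feeds bound pruning.
* **Tie-breaks.** Equal quality is broken toward lower rank, then
  lexicographically smaller policies; within a rank, enumeration is
  ascending lexicographic. All three searches are therefore fully
  deterministic, and the reported statistics are reproducible.
* **Prune comparison.** Pruning fires at `u'(x) <= best` rather than
  strictly below: an equal bound cannot strictly improve the optimum and
  the incumbent is retained, so the guarantee is unchanged and the
  pruning is stronger. This is a deliberate divergence from the weaker
  strict form.
* **Seen-set memory.** Enqueued policies are remembered in a hash set
  keyed by the policy string, so memory grows with the number of
  evaluated policies, never with the lattice size.

## Synthetic instances

`synth_instance()` generates the study conditions used throughout the
tests: `n` records over integer-coded categorical attributes with
balanced interval hierarchies (`synth_hierarchy()`, branching factor 2 by
default, single-root top), value frequencies uniform or Zipf with
exponent 1 (realistic class-size skew), and a fraction of *outlier*
records — combinations from the rare end of each domain, distinct from
each other and from the kept records — that form singleton classes at low
generalization levels and create genuine suppression pressure. Identical
seeds give byte-identical instances, and the caller's RNG stream is left
untouched. `toy_demographics()` is a five-record age/sex instance whose
facts (lattice of 6 policies; one unique record under policy `(1,0)`;
50 % maximal risk after one suppression) are machine-checked.

What the generator does *not* emulate: inter-attribute correlation
(values are drawn independently), unbalanced or semantic hierarchies,
missing values, and the scale of real census-style benchmarks. Passing
tests on these instances demonstrates correctness of the machinery —
oracle equivalence, invariants, monotonicity — not the runtime profile or
the quality levels one would observe on real survey data.

Problem sizes in the shipped tests were chosen so the whole suite runs
comfortably on one core: search cross-validation uses fifty instances
with 2–4 attributes, lattices up to a few hundred policies and up to 80
records; store validation uses a thousand randomized workloads with up to
6 attributes and heights up to 5; monotonicity checks 500 random strict
generalization pairs. Defaults elsewhere follow common practice in the
biomedical domain: `k = 5` and a 5 % suppression limit.

## Numerical and degenerate-input choices

* Quality comparisons in tests use an absolute tolerance of 1e-12;
  incumbent updates use strict `>` on doubles (no tolerance), which is
  safe because ties merely keep the earlier, lower-rank policy.
* Hierarchy values are case- and whitespace-sensitive exactly as read;
  no silent normalization, since normalization hides linkage errors.
* A hierarchy's top level need not be a single `*`; if it is not, full
  suppression is still available through the suppression mechanism, and
  an instance can be genuinely unsolvable (the CLI reports this with a
  distinct exit code).
* Empty datasets, `k = 1`, a zero suppression limit and singleton
  domains all evaluate to defined results rather than errors.
* Lattices with zero attributes are rejected at construction.

## Limitations

* Quality is the Iyengar loss model only; other measures (entropy-based,
  discernibility, KL-divergence) would slot into the same bound
  machinery but are not implemented.
* Privacy is k-anonymity only; models against attribute disclosure
  (l-diversity and relatives) are out of scope.
* Suppression is whole-record; cell-level (local) suppression and local
  recoding are not supported.
* The search is exact or anytime-heuristic over full-domain policies;
  subtree generalization and microaggregation are different
  transformation models entirely.
* For very high-dimensional data (dozens of attributes) full-domain
  generalization itself tends to destroy utility regardless of the
  search; set-valued privacy models are the usual remedy and are out of
  scope here.
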