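# anonlattice

De-identification of tabular data with **full-domain generalization and
record suppression** under the **k-anonymity** privacy model, driven by a
lattice search that maintains *predictive properties* implicitly as
antichains in a rank-annotated prefix tree.

## The problem

Before sensitive tabular data (typically health data) can be shared, the
attributes an attacker could link to external identified sources — the
*quasi-identifiers* such as age, sex or ZIP code — must be coarsened until
every record is indistinguishable from at least *k − 1* others, which
bounds every record's re-identification risk by 1/k. Coarsening uses
per-attribute *generalization hierarchies* (exact age → ten-year band →
`*`); full-domain generalization replaces all values of an attribute by
their labels at one common level, and a small fraction of outlier records
may additionally be *suppressed* rather than forcing more generalization
onto everyone.

A *de-identification policy* is an m-tuple x = (x₁, …, x_m) of
generalization levels, one per attribute; with the componentwise order
x ≺ y ⟺ xᵢ ≤ yᵢ the policies form a bounded lattice of ∏ hᵢ elements —
exponential in m, so it is never materialized here. Applying x means:
generalize (step 1), suppress every equivalence class smaller than k
(step 2), accept if at most ⌊limit·n⌋ records were suppressed (step 3).

Data quality is the Iyengar loss model: each cell contributes
(M_g − 1)/(M − 1), the fraction of its attribute's domain of size M
covered by its label (0 for an untouched value, 1 for a suppressed cell),
and quality u = 1 − mean cell loss. Suppression makes u non-monotone
along generalization, but the generalization-only quality u′ ≥ u is
monotone and serves as a branch-and-bound upper bound.

Two facts about a policy's output are *predictive*: **insufficient
protection** (not k-anonymous) is inherited by all specializations,
**insufficient quality** (u′ cannot beat the incumbent) by all
generalizations. The package stores each property only for the policies
where it was discovered, kept as an **antichain** (pairwise incomparable
set) in a prefix tree over the policy components whose nodes carry the
minimum (resp. maximum) rank below them, so that membership of any other
policy is a pruned range query rather than a lookup into an exponential
structure. Four interchangeable store implementations (plain list, list
with antichain invariant, prefix tree, rank-annotated prefix tree) are
provided for benchmarking.

Three search strategies share this machinery: an exhaustive oracle, a
globally-optimal rank-order search using both predictive properties, and
a best-first branch-and-bound (queue ordered by evaluated quality) that
is globally optimal run to completion and an anytime heuristic under a
time or evaluation budget.

## Worked example

```r
library(anonlattice)
fx  <- toy_demographics()      # 5 records, age (height 3) + sex (height 2)
fit <- anonymize(fx$data, fx$hierarchies, k = 2, suppression_limit = 0.25)
summary(fit)
```

```
De-identification fit (optimal search, k = 2, suppression limit 25 %)
Policy (1,0): quality 70.00 %, 1/5 records suppressed [optimal]
Generalization levels:
  age: level 1 of 0..2
  sex: level 0 of 0..1
Max re-identification risk (kept records): 50.0 %
Checked 5 / 6 policies (83.33 %)
  insufficient quality  : 2 inserts, 1 hits (16.7 % hit rate), max antichain 2 (100.0 % of inserts)
  insufficient protection: 2 inserts, 0 hits (0.0 % hit rate), max antichain 1 (50.0 % of inserts)
```

The optimum generalizes age one level and leaves sex untouched: one
record (the lone forty-something) is unique at that level and is
suppressed, which is cheaper in quality terms than generalizing everyone
further. Every remaining equivalence class has ≥ 2 records, so no record
can be re-identified with more than 50 % confidence. `coef(fit)` returns
the fitted levels, `predict(fit)` the transformed records:

```
      age    sex
1 [20-29]   male
2 [20-29]   male
3 [30-39] female
4 [30-39] female
5       *      *
```

A larger synthetic run, with the best-first search:

```r
inst <- synth_instance(n = 500, domains = c(30, 12, 6, 2), dist = "zipf",
                       outlier_fraction = 0.04, seed = 1)
fit2 <- anonymize(inst$data, inst$hierarchies, k = 5,
                  suppression_limit = 0.05, algorithm = "bfs")
summary(fit2)
#> Policy (4,3,1,0): quality 65.51 %, 17/500 records suppressed [optimal]
#> Checked 186 / 240 policies (77.50 %)
#> ...
#> optimum found after 19.4 % of the run
```

`plot(fit2)` draws the anytime quality trajectory.

## Command line

A thin launcher ships in `inst/cli/deident`:

```sh
Rscript inst/cli/deident generate  --n 200 --domains 10,6,2 --seed 1 --out-dir work --name demo
Rscript inst/cli/deident anonymize --data work/demo.csv --hierarchies work --k 5 --suppression-limit 0.05
Rscript inst/cli/deident benchmark --n 200 --domains 8,6,4 --k 5
```

`anonymize` writes the transformed CSV (suppressed records as `*` rows,
row count preserved) plus a JSON manifest with the merged configuration,
input digests and search statistics. Exit codes: 0 success, 1 usage,
2 input error, 3 no solution exists.

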