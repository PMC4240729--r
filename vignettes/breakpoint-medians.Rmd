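---
title: "Breakpoint medians, geodesic patches and accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint medians, geodesic patches and accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmedian)
```

## The model

A unichromosomal linear genome with `n` distinct genes is a permutation
`π = π1 ... πn` of the labels `1..n`. Its *adjacencies* are the unordered
pairs of genes sitting next to each other, `{πi, πi+1}`; there are exactly
`n − 1` of them, and they are all the positional information the breakpoint
model retains. The **breakpoint (bp) distance** between genomes `x` and `y`
is

    d(x, y) = (n − 1) − |A_xy|,

where `A_xy` is the set of adjacencies the two genomes share. It counts the
neighborhoods that would have to be broken to turn one gene order into the
other, and it ranges from 0 to `n − 1`.

Reading a chromosome right-to-left changes nothing biologically and nothing
in the adjacency set, so a genome and its full reversal are at distance 0:
the bp distance is a *pseudometric* on gene orders. Identifying each genome
with its reversal gives *genome classes* — `n!/2` of them — on which the bp
distance is a genuine metric. `class_of()` picks the lexicographically
smaller orientation as the canonical representative (decided by comparing
the first and last gene, which always differ), so classes hash and compare
deterministically.

## Geodesic patches

Unlike reversal or DCJ distance, the bp metric space is **not geodesic**:
between some pairs of genomes there is no chain hitting every intermediate
distance. The package works with the union of *geodesic patches* between
`x` and `y`: the set of all `z` with

    d(x, z) + d(z, y) = d(x, y),

which is equivalent to the adjacency sandwich `A_xy ⊆ A_z ⊆ A_x ∪ A_y`.
Both criteria are implemented in `on_patch()` and their agreement is a
property test of the suite, not an assumption. `patch_union_set()` computes
the full member set by two independent engines:

* `"oracle"` filters the exhaustive class enumeration (for `n` up to the
  enumeration cap), using the additivity criterion against a cached matrix
  of pairwise shared-adjacency counts;
* `"hampath"` enumerates the Hamiltonian paths of the graph with edge set
  `A_x ∪ A_y` that use every edge of `A_xy` — the union graph has maximum
  degree 4, so this scales far beyond the cap.

The engines must agree; the tests verify that exhaustively for `n ≤ 5` and
on seeded random pairs at `n = 6`. Exhaustive agreement at `n = 6` would
mean some sixty-five thousand path enumerations for no extra coverage of
the logic, so the randomized design was chosen deliberately.

`find_geodesic()` asks the stronger question: is there a chain
`z_0 = x, ..., z_D = y` isometric to the full segment `0..D`? Candidates
are restricted to the patch-union set (any geodesic point satisfies the
additivity criterion) and explored depth-first level by level, tie-broken
by lexicographic order of canonical representatives so the result is
deterministic. A `NULL` answer is meaningful: the family
`(id, 1 2 σ n−1 n)` with `σ` a non-identity arrangement of `{3..n−2}`
(built by `nongeodesic_pair()`) never admits a geodesic, and the suite
checks that exhaustively over `σ` for `n = 6, 7`.

Only *membership in the union* of patches is exposed. Grouping members
into individual maximal patches is under-determined by the membership
characterization and is not needed for any downstream result, so the
package does not attempt it.

## Medians

The *median value* of a genome set is the minimum over all classes `m` of
the total distance `Σ_i w_i d(m, x_i)`; the *median set* is the full argmin
— the object of study is the set, so no arbitrary single median is ever
returned. Multiplicities `w_i` are honored throughout (`genome_set()`
collapses a genome and its reversal into one class, summing weights), and
all results are invariant under replacing any input by its reversal.

`median_bruteforce()` is exact: with the class-by-adjacency 0/1 incidence
matrix `L`, the vector of total distances to a weighted set is a single
matrix–vector product, so scanning all `n!/2` classes is cheap up to the
enumeration cap (default `n = 8`, i.e. 20,160 classes; the cap exists to
make the cost explicit, not because the code changes above it).

For inputs pairwise at the **maximum** distance `n − 1` (equivalently,
pairwise disjoint adjacency sets — `k` edge-disjoint Hamiltonian paths of
`K_n`), the median value is exactly `(k − 1)(n − 1)` and `m` is a median
iff every adjacency of `m` occurs in some input. `median_set_maxdist()`
turns that characterization into Hamiltonian-path enumeration on the union
graph; the brute-force solver must and does return the identical set. The
precondition is checked strictly (all `C(k,2)` pairwise distances equal
`n − 1`), because the characterization is simply false without it.

## Accessibility

The *accessibility closure* of a set `X` collects every genome reachable
by repeatedly hopping onto a geodesic patch towards an already-reached
genome. Chains and rounds of chains reduce to a simpler fixed point: the
smallest superset of `X` closed under taking the patch of any two members
(a chain step towards a reached genome *is* a member-pair patch, and
conversely). `accessible_closure()` computes that fixed point, processing
every unordered member pair exactly once. Two observations keep this
tractable:

* every patch member keeps its adjacencies inside the union of its
  endpoints' adjacency sets, so the entire closure lives inside
  `{v : A_v ⊆ union of the starting adjacency sets}` — the search space is
  restricted to that candidate set up front;
* with the cached pairwise shared-adjacency matrix, all patches from one
  new member to every current member reduce to one vectorized comparison.

For maximally-distant `X` the closure is always contained in the median
set, and patches between any two medians stay inside the median set; both
are asserted in the tests. Whether *every* median is accessible is an open
conjecture, so `conjecture_report()` reports the two set sizes and the
one-sided difference without asserting equality. On the instances the
suite constructs (up to `n = 7`, `k = 3`) the difference has been empty,
which is evidence, not proof.

## Random-genome experiments

For a uniformly random genome against a fixed reference (or two
independent uniform genomes — the distance is invariant under relabeling,
so the distributions coincide), the number of shared adjacencies
`ε = |A_xy|` has expectation exactly `2 − 2/n`: each of the `n − 1`
reference adjacencies survives with probability `2/n`. Mean and variance
of `ε` are therefore both close to 2 at large `n`, the distance
concentrates near its maximum, and `ε/a_n → 0` in probability for any
divergent sequence `a_n`.

The experiments:

* `distance_moments()` — sample moments of `ε` and `d`. Defaults follow
  the headline check: `n = 1000`, 20,000 replicates put the Monte-Carlo
  standard error of the mean near 0.01, so the "close to 2" claim is
  tested with bands (±0.1 on the mean, ±0.2 on the variance) far wider
  than the noise. At `n = 4` the suite compares the simulation against
  exhaustively computed exact moments within three standard errors.
* `epsilon_convergence()` — empirical tail probabilities `P(ε/a_n > δ)`
  along a grid of `n`. Offered sequences: `sqrt(n)` (crisp convergence via
  Chebyshev, the default), `log(n + 1)` (slow), `n` (fast); custom
  functions are accepted but must diverge. Only the comparison between the
  first and last grid point is asserted; the intermediate trend is
  reported, since monotonicity replicate-by-replicate is not guaranteed at
  finite `reps`.
* `median_gap_experiment()` — for `k` random classes, the gap
  `e* = (k−1)(n−1) − median value` and `α = ` the maximum pairwise `ε`.
  The bound `0 ≤ e* ≤ C(k,2)·α` is deterministic, so it is asserted on
  every replicate, never on average. Default sizes `n = 7`, `k = 3`,
  200 replicates keep the exact median solver comfortably fast.
* `accessible_distance_experiment()` — closures of random sets (patch
  steps use the general adjacency characterization, not the
  maximally-distant shortcut) and the per-replicate check that every
  accessible genome's total distance stays within `C(k,2)·α` of
  `(k−1)(n−1)`, plus the analogous check for patches between the two
  lexicographically first medians. Default `n = 6`, `k = 3`, 20
  replicates: closures of random length-7 sets are an order of magnitude
  costlier and add nothing to the bound being checked.

Randomness is handled as one root seed spawning per-replicate streams
(`withr::with_seed`), so every experiment is bit-reproducible and
individual replicates can be re-run in isolation.

## What the generators emulate — and what they do not

`max_distant_set()` builds the study's extremal inputs by randomized
backtracking over edge-disjoint Hamiltonian paths of `K_n`, verifying its
own postcondition before returning; infeasible requests (`k > floor(n/2)`,
by the edge-count bound) fail fast with the reason. `sample_class()` draws
uniform genome classes — the push-forward of the uniform measure on gene
orders, since every class has exactly two members.

These are mathematical study conditions, not imitations of real genomes:
real gene orders are not uniform, real genome pairs are rarely maximally
distant, and the model ignores gene families, unequal gene content,
orientation (signs), circular and multichromosomal genomes. Passing tests
therefore validate the combinatorics and the asymptotic statements, not
any claim about ancestral reconstruction accuracy on biological data.

## Numerical and degenerate-input choices

* Gene labels must be exactly `1..n`, `n ≥ 2`; anything else is an input
  error, never silently relabeled.
* Adjacencies are stored order-normalized as integer codes
  `min·(n+1) + max`, making set operations cheap and collision-free.
* The invariance property the package guarantees (and property-tests) is
  under gene *relabeling*: `d(z[x], z[y]) = d(x, y)` for any permutation
  `z` of the labels, plus invariance under reversing either argument.
  Permuting *positions* by a common `z` does not preserve the distance
  (only the identity and the full reversal preserve which positions are
  adjacent), so no two-sided group invariance is claimed.
* The empty genome collection has, by convention, every pair as a common
  adjacency; `common_adjacencies()` then needs `n` explicitly.
* A pair at distance 0 (a class and itself) has the singleton patch and a
  length-1 "chain".
* Enumeration-capped operations raise a typed error (`bpmedian_cap_error`)
  rather than attempting `n!/2` silently; the cap is an argument, not a
  hard limit.
* The exact solvers' incidence-matrix formulation means all distance
  scans are dense linear algebra; the pairwise shared-adjacency matrix is
  cached only up to `n = 7` (a 2520² matrix) and larger spaces fall back
  to per-query mat-vecs.

## Limitations

Exact medians stop at the enumeration cap; no heuristic or ILP solver for
large `n` is provided, deliberately — in a non-geodesic space a heuristic
median can be badly misleading, and the package's purpose is exactness on
the sizes where every statement can be verified. The accessibility
conjecture is reported, never assumed. Signed, circular and
multichromosomal genomes are out of scope.
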