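# bpmedian

Exact combinatorics of the **breakpoint distance** on unsigned linear
unichromosomal genomes: geodesic patches, median sets, accessibility
closures, and Monte-Carlo experiments on random gene orders.

## The problem

A genome with `n` distinct genes is a permutation `π = π1 … πn` of the
labels `1..n`; its information content, in the breakpoint model, is the set
of **adjacencies** `{πi, πi+1}` — the `n − 1` unordered pairs of
neighboring genes. The breakpoint distance between two genomes is

```
d(x, y) = (n − 1) − |A_xy|,        A_xy = shared adjacencies of x and y,
```

the number of gene neighborhoods that differ. Reversing a chromosome
changes nothing, so a genome and its full reversal are at distance 0: the
distance is a pseudometric on gene orders and a metric on the `n!/2`
**genome classes** {π, reversed π}.

The **median** of `k` genomes — the genome minimizing the total distance to
all of them — is the archetypal ancestral-genome estimate in gene-order
phylogenetics. The breakpoint space is *not geodesic* (between some pairs
no chain realizes every intermediate distance), which makes the median set
behave unusually, especially for inputs that are pairwise maximally
distant or random. This package implements the machinery to study that
behavior exactly:

* `bp_distance()`, `adjacency_set()`, `common_adjacencies()`, `class_of()`,
  `enumerate_classes()` — the pseudometric and the class space;
* `on_patch()`, `patch_union_set()`, `find_geodesic()`,
  `hamiltonian_paths()` — geodesic-patch membership
  (`A_xy ⊆ A_z ⊆ A_x ∪ A_y`, equivalently `d(x,z) + d(z,y) = d(x,y)`),
  with two independent engines (exhaustive oracle vs. Hamiltonian-path
  enumeration with required edges);
* `median_bruteforce()`, `median_set_maxdist()`, `is_median_maxdist()`,
  `total_distance()` — exact (multiplicity-aware) median solvers; for
  pairwise maximally-distant inputs the median value is `(k−1)(n−1)` and
  the median set is exactly the set of genomes whose adjacencies all occur
  in some input;
* `one_step_accessible()`, `accessible_closure()`, `conjecture_report()` —
  the accessibility closure (iterated patch-hopping), always contained in
  the median set for maximally-distant inputs; whether it *equals* the
  median set is an open conjecture that the report quantifies per
  instance;
* `max_distant_set()`, `nongeodesic_pair()` — constructions of the
  extremal study inputs (edge-disjoint Hamiltonian paths of `K_n`; the
  family of pairs admitting no geodesic);
* `distance_moments()`, `epsilon_convergence()`, `median_gap_experiment()`,
  `accessible_distance_experiment()` — seeded Monte-Carlo experiments on
  uniformly random genomes.

Results come back as tibbles or as objects with broom-style `tidy()` /
`glance()` methods and `autoplot()` ggplot views. A thin command-line
wrapper (`exec/bpmedian`, subcommands `distance`, `patch`, `median`,
`construct`, `simulate`, `fixtures`) covers shell use.

## A worked example

```r
library(bpmedian)

x <- c(1, 3, 5, 2, 4, 6)
bp_distance(1:6, x)
#> [1] 5
```

5 is the maximum possible distance for `n = 6`: the two genomes share no
adjacency. Even so, a full geodesic happens to connect them:

```r
sapply(find_geodesic(1:6, x), paste, collapse = " ")
#> [1] "1 2 3 4 5 6" "1 2 3 4 6 5" "1 2 3 5 6 4" "1 2 4 6 5 3" "1 3 5 6 4 2"
#> [6] "1 3 5 2 4 6"
```

a chain of six classes whose pairwise distances are exactly `|i − j|`.
(Geodesics are the exception: `find_geodesic()` on any pair from
`nongeodesic_pair()` returns `NULL`.)

Three pairwise maximally-distant genomes of length 7 and their exact
median set:

```r
X <- max_distant_set(7, 3, seed = 1)
X$representative
#> [1] "1 7 6 4 2 5 3" "1 5 7 4 3 6 2" "6 5 4 1 2 3 7"

glance(median_bruteforce(X))
#> # A tibble: 1 × 5
#>   median_value n_medians     n     k method
#>          <int>     <int> <int> <int> <chr>
#> 1           12       912     7     3 bruteforce
```

The median value is `(k−1)(n−1) = 12`, attained by 912 of the 2520
classes — including the three inputs themselves. How many of those medians
are *accessible* from `X` by patch-hopping?

```r
conjecture_report(X)
#> <bp_conjecture_report> n = 7, k = 3
#>   median value 12; |M(X)| = 912, |closure| = 912
#>   every median accessible: TRUE (0 not accessible)
```

On this instance every median is accessible — consistent with the
conjecture, which the report checks but never assumes.

Random genomes behave like maximally-distant ones: the shared-adjacency
count of a random pair has mean and variance near 2 regardless of `n`,

```r
sim <- distance_moments(1000, reps = 20000, seed = 1, reference = "identity")
glance(sim)[, c("mean_eps", "var_eps", "mean_d")]
#> # A tibble: 1 × 3
#>   mean_eps var_eps mean_d
#>      <dbl>   <dbl>  <dbl>
#> 1     1.99    2.00   997.
```

so the distance concentrates at `n − 1 − ε` with `ε ≈ 2`, and the median
value of `k` random genomes sits within `C(k,2)·max pairwise ε` of its
maximum `(k−1)(n−1)` on every draw (`median_gap_experiment()` asserts that
bound per replicate).

See the vignette (`vignettes/breakpoint-medians.Rmd`) for the model,
algorithmic choices and limitations.

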