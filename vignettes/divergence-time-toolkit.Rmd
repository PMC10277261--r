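---
title: "Managing and analysing pairwise divergence times with divtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing and analysing pairwise divergence times with divtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtime)
```

## The problem

Molecular and evolutionary studies routinely need the divergence time — the
age, in millions of years (MY), of the most recent common ancestor — for
every pair in a list of species, not just for one pair at a time. Public
divergence-time resources answer pairwise queries; assembling those answers
into analysis-ready structures (long tables, square matrices, time trees),
checking them for holes left by transient retrieval failures, and feeding
them into downstream statistics is the repetitive part this package
automates. The package covers four connected tasks:

1. **Data management**: the long three-column "vectorized" pair table, its
   square-matrix form, CSV round trips, missing-value detection and repair.
2. **Retrieval**: a pluggable backend interface with a complete offline
   implementation serving packaged example data, so every workflow runs and
   is testable without a network.
3. **Diversification**: the Magallón–Sanderson crown-age estimators of the
   net diversification rate, with and without extinction.
4. **Matrix comparison**: Mantel tests and Mantel correlograms relating
   divergence time to a second distance (typically genetic distance such as
   pairwise F~ST~).

## Data model

A `pairwise_table` stores one row per taxon pair: `taxon_a`, `taxon_b`,
`time_mya`, optional confidence-interval bounds (`ci_low_mya`,
`ci_high_mya`) and the number of primary studies behind the estimate
(`n_studies`). Resources report the pair time as a median or adjusted
median across studies, so the point estimate is *not* constrained to lie
inside the CI. Two layouts exist because both occur in practice: `FULL`
(all $n^2$ ordered pairs, self-pairs at time 0 — the layout batch
retrieval naturally produces) and `UNORDERED` (each of the $n(n-1)/2$
distinct pairs once). `table_to_matrix()` and `matrix_to_table()` convert
between the long form and the square symmetric matrix, and are exact
inverses; species order everywhere follows the user's input list, not
alphabetical order, so outputs are stable against the input file.

```{r}
t1 <- table1_fixture()
head(as.data.frame(t1), 4)
table_to_matrix(t1)
```

Missing times (failed retrievals) are `NA` in memory and empty fields in
CSV; the tokens `NA`, `n. a`, `n.a` are also accepted on input, reading as
0 for a self-pair's time and as missing elsewhere, which matches how
published tables mark their diagonal. When a FULL table carries both
orderings of a pair they must agree within `tol` (default 0.05 MY, half
the last printed digit of a one-decimal time); disagreement beyond that is
a corruption signal and an error, not something to average away.

## Retrieval backends

All retrieval goes through a small generic interface (see
`?"backend-contract"`): availability checks, single-pair and batch
divergence queries, time-tree and timeline retrieval, and re-query/repair
of missing values. The packaged `fixture_backend()` implements it from
in-memory data: a published four-species example table, one worked
species pair (Swainson's thrush × Superb fairywren, 35 MY), and two
synthetic genus trees. A client for the live TimeTree web resource is a
second conforming implementation a user can supply; it is deliberately
not shipped, because scraping layers are environment-fragile while the
contract is durable. Lookup failures are **values, not exceptions**: an
unresolved pair gets a missing time plus a substitution record, so a
batch run over hundreds of species always completes and the holes are
repaired afterwards (`find_missing()`, `repair_missing()`) — the same
post-hoc validation workflow the interactive menu exposes under its
"validate" option.

One boundary case deserves a note: a self-pair of a species the backend
cannot resolve is reported missing rather than 0, since a time of 0 would
assert the species exists in the resource.

## Diversification rates

For a clade of $n$ extant species whose crown age (deepest split among
living members) is $\Delta t$, the crown-age estimator of the net
diversification rate $r$ (speciation minus extinction, per MY) with zero
relative extinction is

$$ r = \frac{\ln n - \ln 2}{\Delta t}, $$

and with relative extinction $\varepsilon = \mu / \lambda \in [0, 1)$

$$ r = \frac{1}{\Delta t}\left(\ln\!\Big(\tfrac{n(1-\varepsilon^2)}{2}
   + 2\varepsilon + \tfrac{1-\varepsilon}{2}
   \sqrt{n\,(n\varepsilon^2 - 8\varepsilon + 2n\varepsilon + n)}\Big)
   - \ln 2\right). $$

The logarithm is natural throughout: with $n = 12$, $\Delta t = 4.73$ the
estimator gives $\ln(6)/4.73 \approx 0.379 \to 0.38$, and with $n = 11$,
$\Delta t = 9$ it gives $0.19$ — a base-10 reading would give 0.16 and
0.08 instead, so the two worked clade rates pin the convention down. At
$\varepsilon = 0$ the second formula reduces algebraically to the first;
the test suite verifies this to $10^{-12}$ relative over a grid and checks
the full formula against 30-digit symbolic evaluations frozen into the
tests. Values are kept at full precision internally and rounded to two
decimals only for display.

```{r}
rate_crown(12, 4.73)
rate_crown_extinction(12, 4.73, 0.5)
```

`rate_from_clade()` reads $\Delta t$ off an ultrametric tree and takes
$n$ from the tip count, or from `n_total` when the tree undersamples the
clade's known richness — rate estimates should use the full known species
count, which retrieved trees often lack. Only crown-age estimators are
provided; no stem-age variant, confidence intervals, or likelihood
birth–death fitting (dedicated tools exist for rate-through-time
analysis).

## Time trees

Trees move through standard Newick with branch lengths in MY (`ape` does
the parsing; a pre-scan adds character positions to bracket errors).
`divergence_from_tree()` returns **MRCA ages**, i.e. half the cophenetic
path length — conventions differ by this factor of 2, and MRCA age is what
pair queries report, so `crown_age()` is simply the matrix maximum.
`tree_from_matrix()` inverts the extraction by average-linkage (UPGMA)
agglomeration, which is exact on ultrametric inputs; inputs must satisfy
the three-point condition (for any triple, the two largest pairwise times
are equal) within tolerance, and violations are reported with the worst
offending triple. Merge ties break deterministically toward the
lexicographically smallest label pair. The ultrametricity check is an
absolute root-to-tip depth spread, default 0.01 MY — retrieved times carry
one decimal, so anything tighter would be noise-chasing on real data while
anything looser would mask genuine conflicts.

```{r}
m <- table_to_matrix(table1_fixture())
cat(ascii_preview(tree_from_matrix(m)))
```

## Mantel tests

`mantel_test()` correlates the upper triangles of a divergence-time matrix
and a second symmetric distance matrix, with significance from
simultaneously permuting the second matrix's rows and columns (the
standard Mantel scheme). The p-value uses the plus-one rule
$p = (\#\{|r^*| \ge |r|\} + 1)/(N + 1)$, so it is never 0 and the test is
exact-in-expectation. The default is two-sided on $|r|$ — published
correlogram panels rarely state sidedness, so the conservative choice is
the default and one-sided options are explicit arguments.
`mantel_exact()` enumerates all label permutations (up to 7 labels) and
anchors the permutation test in the suite. `correlogram()` computes the
per-distance-class variant: the Mantel statistic between the second
matrix and the 0/1 indicator of a pair's time falling in each class, with
Sturges-rule equal-width classes by default and classes under 3 pairs
flagged untestable rather than tested meaninglessly.

## The synthetic-data generator

`simulate_yule_tree()` produces pure-birth trees conditioned on the tip
count, rescaled so the crown age is hit exactly, deterministically per
seed. Pure birth suffices because the fixtures only need ultrametric
structure with a known crown age; extinction enters the package
analytically through $\varepsilon$, not through simulation. The two
packaged genus trees (12 tips, crown 4.73 MY; 11 tips, crown 9.0 MY)
carry real thrush and fairywren binomials on *synthetic* topologies with
seeds 101 and 202 (`scripts/make_fixtures.R` regenerates them); their
branching order is not a literature phylogeny, so they support exactly
the quantities the estimators consume — tip count and crown age — and
nothing finer. Likewise the generator emulates none of the features that
make real retrieved data messy (name synonymy, asymmetric study coverage,
CI heterogeneity), so passing tests demonstrate correct mechanics on
clean inputs, not robustness to taxonomic noise.

## Numerical and design choices

* Reconstruction prints branch lengths at 17 significant digits
  internally so UPGMA round trips survive double precision; file output
  uses 10 digits.
* The exact-test comparisons use a $10^{-12}$ slack when counting
  permutations as extreme, so label symmetries that reproduce the observed
  statistic up to rounding are counted as ties, matching the enumeration.
* Test problem sizes: tree round trips use 100 simulated clades of up to
  30 tips; Mantel calibration uses 5-label enumeration against 99,999
  permutations and 500 null replicates at 999 permutations — sizes at
  which the exact references are computable while the sampling error is
  far below the decision thresholds.
* The interactive menu and the `divtime_cli()` subcommands call the same
  functions with the same defaults, and the suite checks their outputs are
  byte-identical, so scripted pipelines and menu sessions cannot drift
  apart.

## Limitations

Fuzzy taxon-name resolution and synonym lookup are out of scope — names
must match the backend's records after whitespace/underscore
normalization. The correlogram defaults (class breaks, permutation count,
sidedness) are standard practice but configurable, since published
analyses vary. No live network client ships with the package; the
documented contract is the extension point.
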