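---
title: "Character clusters, sections and gestalts: the models behind morphorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character clusters, sections and gestalts: the models behind morphorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorank)
```

## The problem

A taxonomic character is a feature of a taxon whose state distinguishes it
from other taxa. Characters are not independent: functional syndromes (all
carnivore dentition features vary together), structural constraints and
shared ancestry all correlate them. morphorank provides two complementary
formalizations of that correlation structure — an algebraic one based on
tensor-rank decompositions of the carrier-by-feature table, and a geometric
one modelling taxa as partial sections over a base of features — together
with classifiers that tell cladistic from functional correlation patterns.

## The algebraic model

The data are a matrix $C = (c_{ij})$ with $n$ carriers (species or higher
taxa) as rows and $m$ features as columns. Entries may be real measurements,
integer counts/codes, or 0/1 presence–absence; the coefficient field matters
because rank does. Every matrix admits a representation

$$C = \sum_{\nu = 1}^{r} a^{\nu} \otimes b^{\nu},$$

a sum of outer products of carrier-factor vectors $a^\nu \in K^n$ and
feature-combination vectors $b^\nu \in K^m$. The minimal $r$ is the rank of
$C$, and each $b^\nu$ of a minimal representation is a *character cluster*:
an independent feature combination. Features loading on the same cluster are
perfectly correlated across the carriers at hand, so one character per
cluster carries all the distinguishing information.

```{r}
overlay <- character_matrix(
  cbind(teeth = c(1, 1, 1, 2, 2, 2), feet  = c(1, 1, 1, 2, 2, 2),
        fur   = c(1, 2, 3, 1, 2, 3), color = c(1, 2, 3, 1, 2, 3)),
  field = "integer")
rank_decompose(overlay)
```

The two terms separate the feeding-type syndrome (teeth, feet) from the
climate syndrome (fur, color): the table is the overlay of two character
clusters and has rank 2 rather than the maximal 4.

### Numerical choices

* **Exact fields.** Integer and GF(2) matrices are handled by exact
  Gaussian elimination — rational arithmetic with reduced
  numerator/denominator pairs, or arithmetic modulo 2. Decompositions are
  canonicalized by column-pivoted Gauss–Jordan elimination with first-pivot
  tie-breaking: the $a^\nu$ are the pivot columns of $C$ itself and the
  $b^\nu$ the non-zero rows of the reduced echelon form, normalized to
  leading coefficient 1. This makes the output reproducible (the
  representation itself is never unique) and reconstructs $C$ entrywise
  exactly, which the implementation verifies in rational arithmetic before
  returning. Doubles represent the integers involved exactly up to
  $2^{53}$; an overflow guard aborts rather than rounding silently.
* **Real field.** Rank counts singular values above
  $10^{-8}\,\sigma_{\max}$ (a machine-precision-safe default; there is no
  canonical choice, so the threshold is an explicit argument), and the
  decomposition uses SVD factors $a^\nu = \sigma_\nu u_\nu$,
  $b^\nu = v_\nu$ in descending $\sigma$ order.
* **Missing data.** The rank machinery refuses matrices with missing
  entries and names the offending cells; `complete_features()` restricts to
  the maximal complete column subset and reports what it dropped. Imputing
  states silently would fabricate characters.

### Error-bounded rank

Measured matrices typically have full rank because of noise. The
$\varepsilon$-rank is the minimal rank over all $C'$ with
$\lVert C - C' \rVert < \varepsilon$ (Frobenius, strict inequality): by
Eckart–Young this is the smallest $k$ whose tail singular-value energy
$\sum_{i > k} \sigma_i^2$ falls strictly below $\varepsilon^2$. The strict
reading means a tail energy exactly at the bound keeps the higher rank.
`character_clusters(M, eps)` returns the clusters of the corresponding
truncation.

### Frequencies and independence

For presence/absence data the package builds marginal frequencies $p_j$,
pairwise tables $p_{jk}$ and higher-order joint tensors, and tests the
factorization $p_{j_1 \ldots j_s} = p_{j_1} \cdots p_{j_s}$. Here the logic
inverts: dependencies *between features* (features that always co-occur)
break the factorization, while a table of perfectly correlated carriers has
independent frequencies — dependence among carriers and independence among
frequencies are two sides of the same structure.

Three normalization conventions are offered because they genuinely
disagree and no single one serves every purpose:

* `carrier_fraction` (default): $p_{j_1 \ldots j_s}$ = fraction of carriers
  possessing all the listed features. Every worked example in the package
  documentation uses this convention.
* `total_normalized`: counts divided by their grand total per order, so
  each tensor sums to 1 and the marginal is $r_j / \sum_\ell r_\ell$.
* `distributional`: the distribution of an ordered $s$-tuple of feature
  occurrences drawn from a single carrier; under this convention, and only
  under it, the pairwise row sums equal the marginals.

For 0/1 data the diagonal of any joint table is degenerate
($c^2 = c$ forces $p_{jj} = p_j$), so the independence test compares only
tuples of pairwise distinct features by default; `include_repeats = TRUE`
restores the literal entrywise comparison.

### The co-occurrence matrix and rank preservation

From $C$ one can form the normalized carrier co-occurrence matrix
$P = C C^{\!\top}\!/Z$ with $Z$ the sum of all entries of $C C^{\!\top}$.
Over the reals, $\operatorname{rank} P = \operatorname{rank} C$: the number
of character clusters is visible in the carrier co-occurrence structure
alone. The proof of this identity runs through Gram matrices and symmetric
square roots, i.e. it needs an ordered field; over GF(2) the corresponding
identity is simply false (the $3 \times 3$ circulant of $(1,1,0)$ has GF(2)
rank 2 while $C C^{\!\top}$ has rank 3 over the rationals). The package
therefore always forms $P$ over the rationals, whatever the field tag of
$C$, and the rank-preservation property is stated and tested over the
reals. $Z = 0$ (possible for real matrices with cancelling column sums) is
an explicit error, never NaN propagation.

### Tensor rank

Higher-order joint tensors can carry dependencies the pairwise table
misses, measured by their CP rank. Exact tensor rank is NP-hard, so
`tensor_rank()` is deliberately split into two honest regimes.
`exact_small` certifies: rank $\le 1$ at any size (all unfoldings rank
$\le 1$), order-2 tensors (matrix rank), GF(2) tensors with at most 16
entries by exhaustive search over sums of distinct non-zero rank-1 GF(2)
tensors up to `max_rank` = 4 (the cap keeps the search exact and fast), and
real $2 \times 2 \times 2$ tensors by the slice-pencil criterion: with an
invertible slice combination $C_1$, the tensor has rank $\le 2$ iff
$C_2 C_1^{-1}$ is diagonalizable with real eigenvalues, else rank 3.
Everything else goes through `als_upper_bound`, an alternating
least-squares CP fit whose residual-vs-rank curve is an upper bound
*only*: for tensors whose border rank is below their rank (the
$2\times2\times2$ staircase with slices $I$ and a nilpotent is the
canonical case) the ALS residual can creep toward zero with diverging
factors although no exact low-rank representation exists. Border rank
itself is not computed; the residual curve is the only diagnostic and is
labelled as an upper bound. All ALS restarts take an explicit seed.

## The geometric model

The same data can be read geometrically: the base $B$ is the set of
features, the fiber $F_j$ over feature $j$ is its finite set of admissible
values, and a taxon is a *partial section* — an assignment $s(j) \in F_j$
on a subset of the base. Fully specified species are global sections;
restricting a section (forgetting feature values) moves to a higher taxon,
extending it moves to a more specific one. Not every value combination is
biologically realizable, so a space may carry a constraint set: an explicit
finite list of admissible global sections, standing for structural,
functional, developmental or environmental constraints. (The enumeration is
a design choice: the spaces in scope are finite and small; predicate-based
constraint languages and interval-valued "range" fibers are deliberately
deferred.)

With constraints, `extensions(s, space)` filters the admissible list (in
list order, for deterministic output); without, it enumerates all
completions in lexicographic fiber order. A section with several extensions
has apomorphies — the features whose values distinguish its sister taxa,
returned by `apomorphies()`. A section with none encodes a forbidden
combination.

Three innovation operators change the space itself: enlarging a fiber
(`innovate(kind = "extend_fiber")`), adding a feature
(`"add_feature"`), and `amalgamate()`, which identifies two features into
one new feature via a partial value map — the feathers-plus-forelimbs-into-
wing situation, where two structures with separate functions combine to
serve a new one. Two policy decisions are worth making explicit. When a
feature is added over a constrained space without a default value for the
old admissible sections, the constraint set is dropped with a warning
rather than broadcast over arbitrary new values: nothing licenses assuming
every old combination is realizable with every new value. And the
amalgamated fiber is exactly the image of the value map; sections whose
value pair lies outside its domain lose those features, and the loss is
reported — the alternative (keeping orphaned values) would manufacture a
fiber with no interpretation.

### Gestalts

Patterns that can be transformed into one another — scalings between dwarf
and standard forms, relabelings, reflections — are modelled by a finite
group acting fiberwise: bijections $g : F_j \to F_j$ with
$(g \circ h)(x) = g(h(x))$, possibly different per fiber and trivial on
some. `verify_action()` checks every axiom exhaustively over the finite
data and returns violations *as data*: biologically meaningful
almost-groups exist, the shipped example being a translation acting on a
finite chain of serial homologues (vertebrae), which clamps at the end of
the chain instead of wrapping and so fails bijectivity and compatibility
exactly at the boundary. A *gestalt* is an orbit: `orbit_classes()`
partitions sections, two being equivalent when their domains coincide and
some group element maps one onto the other. Cross-domain comparison is
deferred — there is no canonical way to compare patterns over different
feature sets.

## Cladistic versus functional structure

A cladistic character table for a binary-branching phylogeny has nested or
disjoint feature supports (the perfect-phylogeny / laminar-family
criterion) and *maximal* rank: each species contributes a fresh
synapomorphy. A functional table is the opposite extreme: features fall
into perfectly correlated clusters and the rank collapses to the number of
clusters. `is_cladistic()` implements the laminar criterion exactly —
adopted as the general form of compatibility, with the strict staircase
recovered in the reported carrier/feature orders when it holds — and
exports the implied rooted tree as Newick. `functional_clusters()` groups
features by the carrier partition they induce, a label-free criterion that
survives arbitrary per-feature recoding of states, and reports the real
rank after canonical recoding (labels 1, 2, … by first appearance) for
comparison with the algebraic picture. Minimizing rank over all relabelings
would be a combinatorial search; the induced-partition criterion is exact
and cheap, which is why it is the definition here. `rank_signature()` turns
the rank/min-dimension ratio into a verdict; the 0.5 threshold for
"functional-like" is a configurable reporting convention, not a claim.
The classifier reports order-2 (pairwise) structure only; higher-order
dependencies that pairwise correlation misses are the province of
`tensor_rank()`.

## What the generators emulate — and what they do not

`gen_cladistic(n)` produces the pectinate staircase (species $i$ has
characters $1..i$); `gen_functional()` overlays clusters, by default as a
full factorial of cluster states because that design makes the
rank-equals-cluster-count property exact (sampled designs are available,
seeded); `gen_noisy()` applies i.i.d. Gaussian noise (real) or independent
bit flips (GF(2)) — the minimal standard models, chosen because nothing in
scope prescribes a richer one; `gen_space()` samples constrained feature
spaces guaranteed to contain both a multiply-extendable and an
unextendable partial section. All generators are pure functions of their
arguments and seed, and restore the caller's RNG state.

These fixtures are idealizations. Real morphological matrices mix
cladistic and functional signal, contain homoplasy (convergence,
reversal), correlated rather than independent noise, and missing data that
is not missing at random. Passing tests on generated data therefore show
that the algebra and the geometry do what they claim on their defining
patterns — not that any empirical matrix will decompose into clean
character clusters. No statistical phylogenetic inference (likelihoods,
bootstrap, parsimony search) is attempted; that is explicitly out of
scope, as is any modelling of the genotype–phenotype map.

## Problem sizes and determinism

The property checks shipped with the package use 200 random matrices per
field (up to $6 \times 6$) for rank preservation of the co-occurrence
matrix, 100 random real matrices (up to $8 \times 8$) against an
independent truncation oracle for the $\varepsilon$-rank, staircases up to
$n = 12$, 50 seeded functional specs, and exhaustive section-level
enumeration on spaces with up to 4 features and 3 values per fiber
($4^4 = 256$ partial sections per space) — sizes at which the exhaustive
oracles are genuinely exhaustive while the whole suite runs in seconds.
Every stochastic routine takes an explicit seed; reports and JSON exports
embed the field, convention, tolerance and seed used.
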