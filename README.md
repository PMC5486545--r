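# morphorank

Algebraic and geometric analysis of dependencies between morphological
characters across taxa.

## The problem

In biological classification a character is a feature of a taxon whose state
distinguishes it from other taxa — but characters are not independent.
Functional syndromes tie features together (carnivore teeth come with
carnivore feet), shared ancestry ties them differently (each species adds a
synapomorphy to those of its ancestors), and a practitioner staring at a
carrier-by-feature table needs tools to tell these correlation structures
apart and to find the truly independent combinations. morphorank is for
systematists, morphometricians and theoretical biologists who work with such
tables — real measurements, integer state codes, or 0/1 presence–absence,
with `?` for features a carrier does not possess.

## The core model

A character table is a matrix $C = (c_{ij})$ with $n$ carriers (rows) and
$m$ features (columns) over a coefficient field $K \in \{\mathbb{R},
\mathbb{Z}, \mathbb{Z}_2\}$. Every such matrix decomposes as

$$C \;=\; \sum_{\nu=1}^{r} a^{\nu} \otimes b^{\nu},
  \qquad a^{\nu} \in K^{n},\; b^{\nu} \in K^{m},$$

and the minimal number of terms $r$ is the rank of $C$. Each
feature-combination vector $b^{\nu}$ of a minimal representation is a
**character cluster** — an independent feature combination; the features
loading on it are perfectly correlated, so any one of them represents the
cluster. The rank separates the two classical extremes: a cladistic table
(nested/disjoint feature supports, a perfect phylogeny) has maximal rank
$\min(n, m)$, while a functional table collapses to one rank unit per
functional syndrome. Around this core the package provides:

* exact rank and canonical decompositions over the rationals and GF(2),
  SVD-based rank and an Eckart–Young ε-rank for noisy measurements;
* feature-frequency models: marginals, pairwise and higher-order joint
  tensors, independence tests, and the normalized co-occurrence matrix
  $P = CC^{\top}/Z$, which preserves the rank of $C$;
* CP tensor rank — provably exact on small tensors, ALS upper bounds
  elsewhere;
* a geometric (presheaf) model: taxa as partial sections over a base of
  features with finite fibers, with restriction/extension (higher vs more
  specific taxa), apomorphy detection, innovation operators (fiber
  extension, new features, amalgamation of two features into one), and
  fiberwise group actions whose orbits are gestalt classes;
* classifiers (`is_cladistic`, `functional_clusters`, `rank_signature`),
  seeded generators for all of the above, CSV/TSV and NEXUS STANDARD I/O,
  JSON and Newick export, and a small CLI.

## Worked example

Six taxa, four characters: feeding type (carnivore = 1, herbivore = 2)
drives teeth and feet, climate (arctic = 1, temperate = 2, tropical = 3)
drives fur and color.

```r
library(morphorank)

overlay <- character_matrix(
  cbind(teeth = c(1, 1, 1, 2, 2, 2), feet  = c(1, 1, 1, 2, 2, 2),
        fur   = c(1, 2, 3, 1, 2, 3), color = c(1, 2, 3, 1, 2, 3)),
  field = "integer")

rank_decompose(overlay)
#> rank decomposition: rank 2, field integer, reconstruction error 0
#>   term 1: a = (1, 1, 1, 2, 2, 2), b = (1, 1, 0, 0)
#>   term 2: a = (1, 2, 3, 1, 2, 3), b = (0, 0, 1, 1)

functional_clusters(overlay)
#> functional clustering: 2 cluster(s), rank after labeling 2
#>   cluster_1: {teeth, feet}
#>   cluster_2: {fur, color}

rank_signature(overlay)$verdict
#> [1] "functional-like"
```

The table is the overlay of exactly two character clusters — the rank is 2,
not the maximal 4, and the decomposition separates the feeding syndrome
(loading on teeth and feet) from the climate syndrome (fur and color). A
cladistic staircase behaves in the opposite way:

```r
ladder <- gen_cladistic(5)     # species i possesses characters 1..i
rank_signature(ladder)$verdict
#> [1] "cladistic-like"
cladistic_newick(ladder)
#> [1] "((((species_5,species_4),species_3),species_2),species_1);"
```

Feature-frequency dependence works the other way round — correlated
features make frequencies dependent:

```r
pres <- character_matrix(rbind(c(1, 0, 0, 1),
                               c(0, 1, 1, 0)), field = "gf2")
feature_pair(feature_frequencies(pres), 1, 4)
#> $features
#> [1] "feature_1" "feature_4"
#> $joint
#> [1] 0.5
#> $product
#> [1] 0.25
#> $deviation
#> [1] 0.25
```

Features 1 and 4 always co-occur, so their joint frequency (0.5) is twice
the product of their marginals (0.25): the frequencies are dependent.

A methods vignette (`vignettes/character-dependencies.Rmd`) documents the
models, conventions, numerical choices and limitations in detail.

## Command line

```sh
Rscript inst/exec/morphorank synth cladistic --n 5 --write ladder.csv
Rscript inst/exec/morphorank rank ladder.csv --field gf2
Rscript inst/exec/morphorank freq presence.csv --field gf2 --pair 1,4
```

Subcommands: `rank`, `clusters`, `freq`, `independence`, `cladistic`,
`functional`, `sections`, `extend`, `synth`. Reports are JSON; exit codes
are 0 (success), 1 (data error), 2 (usage error).

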