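# corsym — binary matrix scoring of corolla symmetry

`corsym` quantifies how regular (symmetric) a flower's corolla is from a
small set of yes/no judgements, and compares that regularity across groups
of taxa. It is aimed at plant phenomics and horticultural work on
free-petalled flowers (the model was developed on *Malus* — crabapples —
whose five petals are unfused): anywhere a visually judged, reproducible,
*quantitative* symmetry score is wanted instead of the classical
qualitative radial / bilateral / asymmetric labels.

## The model

Corolla regularity is judged at three nested dimensions, each through two
binary sub-dimensions (1 = regular, 0 = irregular):

| Dimension | Level | Sub-dimensions |
|---|---|---|
| X | corolla (all petals) | X₁ petal interval, X₂ petal coplanarity |
| Y | petal (each petal)   | Y₁ shape homogeneity, Y₂ size homogeneity |
| Z | petal-local          | Z₁ curling consistency, Z₂ wrinkle consistency |

A dimension is regular only if both of its sub-dimensions are:
X = X₁·X₂, Y = Y₁·Y₂, Z = Z₁·Z₂. The resulting binary vector [X Y Z] is
converted to a decimal **symmetry index** (SI) under positional weights
C_j = 2^(j−1), counted from the right:

    SI = X·2² + Y·2¹ + Z·2⁰   ∈ {0, …, 7} points

The weights make each dimension strictly dominate all lower ones
(X > Y > Z priority), so the map is a bijection onto 0–7 and
component-wise more-regular vectors always score higher. The seven
observed states form the named typology I [1 1 1] (7 points) through
VII [0 0 0] (0 points); the eighth state [0 1 1] (3 points) is modelled
as a first-class `UNOBSERVED` label. The model generalizes to *d*
dimensions × *s* sub-dimensions with the same weight rule.

On top of the per-taxon score the package provides group analytics
(type-weight distributions, their coefficient of variation, the integrated
= mean SI, between-group weight ratios P_A/P_B, per-dimension regularity
weights, and power / single-exponential-decay / logarithmic trend fits
with R²), a pedigree check of the progeny dominance rule (a progeny's SI
should not exceed the maximum SI of its known parents), and a seeded
Bernoulli simulator for testing the whole pipeline.

## Worked example

Score a single cultivar whose six judgements are
[X₁ X₂ Y₁ Y₂ Z₁ Z₂] = [1 0 1 1 0 0]:

```r
library(corsym)
a <- data.frame(taxon_id = "M_Rudolph",
                X1 = 1, X2 = 0, Y1 = 1, Y2 = 1, Z1 = 0, Z2 = 0)
score_assessments(a)
#>    taxon_id X Y Z index type
#> 1 M_Rudolph 0 1 0     2    V
```

The petals are individually regular (Y = 1) but their arrangement and
local surface are not (X = Z = 0), giving type V and SI = 2 points: a
corolla of low overall symmetry.

A two-group comparison on simulated data (a high-regularity
"species-like" group of 30 versus a lower-regularity "cultivar-like"
group of 110; synthetic cohorts populate the [0 1 1] state, so the
typology toggle is enabled):

```r
coh <- simulate_cohort(malus_presets(), seed = 42)
rep <- run_report(coh, config = run_config(include_unobserved = TRUE, seed = 42))
rep$distributions$species
#> Type distribution [species]: n = 30, CV = 2.1034, mean SI = 6.17 points
#>       label index count weight
#>           I     7    23 76.67%
#>          II     6     1  3.33%
#>         III     5     1  3.33%
#>          IV     4     0  0.00%
#>  UNOBSERVED     3     4 13.33%
#>           V     2     0  0.00%
#>          VI     1     1  3.33%
#>         VII     0     0  0.00%
rep$distributions$cultivar$mean_index
#> [1] 2.945455
rep$dimension_regularity
#> Dimension regularity weights (fraction of taxa with value 1)
#>               X      Y      Z
#> species  0.8333 0.9333 0.9667
#> cultivar 0.4091 0.4636 0.3818
#> Ratio species / cultivar : X = 2.04, Y = 2.01, Z = 2.53
#> Pooled irregular fraction: X = 50.00%, Y = 43.57%, Z = 49.29%
```

The species-like group concentrates in type I with a mean SI of 6.17
points against 2.95 for the cultivar-like group, and every dimension is
regular about twice as often among the species-like taxa — the
qualitative contrast the analytics are designed to expose. The
weight-ratio decay across types is summarised by an ExpDec1 fit
(`rep$trend_fits$ratio_expdec1`, R² = 0.998 on this draw).

A command-line wrapper over the same functions is installed at
`inst/scripts/corsym.R` (subcommands `simulate`, `score`, `classify`,
`enumerate`, `compare`, `fit`, `pedigree`, `report`).

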