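---
title: "Scoring corolla symmetry with a binary trait matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring corolla symmetry with a binary trait matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsym)
```

## The model and its assumptions

Classical descriptions of floral symmetry are qualitative: a corolla is
radially symmetric, bilaterally symmetric, or asymmetric. `corsym`
implements a quantitative alternative for free-petalled flowers:
regularity is judged at three nested dimensions — the whole corolla (X:
petal interval and coplanarity), the individual petals (Y: shape and
size homogeneity) and the petal surface (Z: curling and wrinkle
consistency) — each through two binary sub-dimension criteria. A
dimension is regular only when *both* of its criteria are, which is the
product encoding

$$X = X_1 X_2,\qquad Y = Y_1 Y_2,\qquad Z = Z_1 Z_2 .$$

The reduced binary vector $[X\,Y\,Z]$ is then read as a base-2 numeral
under positional weights $C_j = 2^{j-1}$ (counted from the right), giving
the symmetry index

$$\mathrm{SI} = X\cdot 2^2 + Y\cdot 2^1 + Z\cdot 2^0 \in \{0,\dots,7\}\ \text{points}.$$

The powers of two are not decorative: they encode the assumption that
corolla-level regularity matters strictly more than petal-level
regularity, which matters strictly more than petal-local regularity.
Formally each weight exceeds the sum of all lower weights, so the index
is a bijection onto $0\dots 2^d-1$ and is strictly monotone in every
dimension — flipping dimension $j$ moves the score by exactly $2^{j-1}$,
more than any combination of lower dimensions can. The test suite checks
these properties exhaustively for $d \le 10$ against an independent
bit-string conversion.

The seven states observed in the original *Malus* survey carry the named
typology I–VII; the eighth state $[0\,1\,1]$ (SI 3) is kept as a
first-class state with the label `UNOBSERVED` rather than being an
error, because its absence is an empirical fact about one survey, not a
property of the model. Distribution analytics exclude it by default
(`include_unobserved = FALSE`) to mirror the seven-type typology, and
include it on request — which is the right setting for synthetic data,
where independent Bernoulli traits populate it freely.

```{r}
enumerate_state_space(weight_scheme(3))
```

## Tunable parameters

* **Model shape** `d = 3`, `s = 2` — dimensions and sub-dimensions per
  dimension. The defaults are the floral model; the same weight rule
  generalizes to other organs with more levels.
* **Aggregation rule** (`aggregation`, default `"majority"` with
  `threshold = 0.5`): how replicate flowers of one taxon (surveys
  typically judge ~30) collapse to a consensus. The source protocol does
  not state its reduction, so the package makes the choice explicit:
  majority per sub-dimension, with exact ties resolved to 0. Ties going
  to "irregular" is the conservative direction — a taxon is only called
  regular on positive evidence — and the rule is deterministic and
  symmetric in the flowers. `"unanimity"` and `"proportion"` (with a
  threshold in $[0,1]$) are available for sensitivity checks.
  Aggregating a consensus returns the consensus (idempotence), so
  taxon-level tables pass through unchanged.
* **CV estimator** (`cv_estimator`, default `"sample"`): the coefficient
  of variation of the per-type counts. Published CVs of this kind rarely
  state their denominator and the original counts are not recoverable,
  so both conventions are exposed; the default is the $n-1$ sample
  estimator, and the statistic itself is scale-invariant (counts and
  percentage weights give identical values).
* **Trend-fit abscissa** (`fit_abscissa`, default `"ordinal"`): decay
  trends over the typology are fitted against the ordinal type position
  1…7 by default, with `"index"` (SI points) as the alternative;
  zero-weight types are kept at $y = 0$, and zero abscissa values are
  dropped for the power and logarithmic families, which require $x > 0$.
* **Missing values** are rejected, never imputed: the judgements are
  cheap binary calls, and silent imputation would corrupt the index.
  `read_assessments()` rejects offending rows individually, reporting
  file line and column, and keeps the valid remainder.

## Trend fitting: numerical choices

Three decreasing-trend families are supported: power $y = a x^b$,
single-exponential decay (ExpDec1, in the common plotting-software
parameterization) $y = y_0 + A_1 e^{-x/t_1}$, and logarithmic
$y = a + b\ln x$. The logarithmic model is linear in its parameters and
solved in closed form. The two nonlinear families are fitted by a
deterministic profiled grid: only one parameter is genuinely nonlinear
(the exponent $b$, or the decay constant $t_1$), so the fitter sweeps it
over a fixed grid — $b \in [-6, 6]$ in steps of 0.01; $t_1$ over the
x-range times $10^{[-2,2]}$ in 0.02 decades — solving the remaining
parameters exactly by linear least squares at each candidate (an
improvement must exceed $10^{-10}$ in residual sum of squares to replace
the incumbent, a tie-break that keeps the sweep order irrelevant), and
then polishes the best candidate with Levenberg–Marquardt
(`minpack.lm::nlsLM`, tolerances $10^{-12}$). The polished solution is
accepted only if it does not increase the residual sum of squares, so
repeated fits on the same data are bit-identical and there is no
dependence on random starting points. $R^2 = 1 - SS_{res}/SS_{tot}$ is
reported; a constant response makes $SS_{tot} = 0$ and is rejected as
degenerate rather than reported as a meaningless fit, as are too few
points or non-positive $x$ where the family requires it. The tests
verify exact recovery ($R^2 = 1$ to $10^{-6}$) on noiseless data from
all three families and agreement of the residual sum of squares, to
$10^{-6}$, with an independent dense grid search on noisy
exponential-decay data.

```{r}
x <- 1:7
fit_trend(x, 2 * x^-1.5, "power")
```

## The pedigree dominance rule

Across known crosses, a progeny's symmetry index is expected not to
exceed the maximum index among its parents; equality passes, taking the
rule's wording literally. `check_progeny_rule()` evaluates each pedigree
record against the scored table. Records whose progeny (or all of whose
parents) cannot be resolved are marked `unresolvable` rather than
failing the run. Records with an unknown parent — an incomplete
pedigree, or a listed parent missing from the scores — are evaluated
against the known parents only and flagged `partial`: the missing parent
could only raise the parental maximum, so a partial *pass* is weaker
evidence than a complete one and is reported distinctly, while a partial
*violation* is already conclusive.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws every (taxon, flower, sub-dimension) cell as an
independent Bernoulli variable, seeded and fully reproducible. The
built-in `malus_presets()` emulate the study design the analytics were
built for: a high-regularity "species-like" group ($n = 30$, per-cell
$p = 0.95$) and a lower-regularity "cultivar-like" group ($n = 110$,
$p = 0.6$). The probabilities were chosen once, to reproduce the
qualitative contrast of a clearly higher mean SI in the species-like
group; they are configuration, not estimates of any real population.
Under a scalar $p$ the expected dimension-regularity fraction is $p^s$,
which the tests verify at $n = 10\,000$ within three binomial standard
errors.

`simulate_pedigree()` crosses pairs of scored parents; under the
dominance constraint the progeny vector is drawn uniformly from the
states at or below the parental maximum, and a requested number of rule
violations can be injected (drawing from states strictly above the
maximum) to verify that the checker finds exactly those.

Two features of real data are deliberately **not** modelled. First,
sub-dimensions are sampled independently, whereas real petals plausibly
correlate, say, curling with wrinkle; no dependence structure is
published, and a correlation knob is out of scope. Second, taxon-level
consensus in real surveys arises from judging ~30 flowers, whose
discordance rates are unknown; the generator can produce flower-level
replicates, but their within-taxon variation is again independent
Bernoulli. Passing tests therefore demonstrate the *pipeline's*
correctness — scoring, tabulation, fitting, rule checking, determinism —
on data with the assumed statistical structure, not the biological
fidelity of that structure.

## Problem sizes

The test suite runs at desk scale, chosen to keep every check sharp but
quick: exhaustive state-space checks up to $d = 10$ (1024 vectors),
random cohorts of 50–110 taxa for the analytics identities, one
$n = 10\,000$ cohort for the binomial-recovery check, and 40–100
simulated crosses for the pedigree properties. The conservation identity
between record-level and distribution-level mean SI is checked to
$10^{-9}$; it is exact arithmetic and any looseness would indicate a
tabulation bug, not noise.

## Known limitations

* The typology and type labels are defined only for the $d = 3$ model;
  for other shapes the index is available but unnamed.
* The scope is free-petalled (unfused) corollas judged visually; the
  package does not derive the six criteria from images.
* Trend fits describe the decay shape of weight distributions; no
  significance testing of the fits is attempted, and $R^2$ on few points
  (seven types) should be read descriptively.
* Published group statistics from the original survey (means, CVs, $R^2$
  values) depend on per-taxon assessments that were never released as
  numeric tables, so they cannot be re-derived here; the package instead
  validates its analytics against exact identities, closed-form oracles
  and simulated cohorts with known parameters.
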