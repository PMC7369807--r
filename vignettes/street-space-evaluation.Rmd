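---
title: "Evaluating street spaces as healing environments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating street spaces as healing environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healstreet)
```

## The problem

Narrow, crowded streets in high-density cities double as the main public
space residents have for rest and social life, and their physical and social
qualities bear directly on residents' stress recovery and attention
restoration — on how far the street functions as a *healing environment*.
`healstreet` implements a complete evaluation chain for that question:

1. a three-tier **indicator hierarchy** (objective → first-level criteria →
   second-level indicators) describing what makes a street healing;
2. **AHP** (Analytic Hierarchy Process) weighting of the criteria from expert
   pairwise comparisons, with the consistency-ratio gate;
3. two-level **fuzzy comprehensive evaluation** (FCE) mapping per-indicator
   membership distributions over an ordinal five-level evaluation set to one
   overall verdict by the maximum-membership rule;
4. supporting computations: **behavioral-mapping** aggregation for field
   observation logs and **space-syntax** measures (connectivity, integration,
   choice) for street-network graphs;
5. a seeded **synthetic-data generator** for every input, so each stage can
   be tested without field data.

The package ships the complete Macao old-town worked example — hierarchy,
judgment matrix, membership matrices and the field activity-frequency table —
as plain-text fixtures, stored digit-for-digit as printed in the original
study's tables.

## AHP weighting

Experts compare criteria pairwise on the Saaty 1–9 scale, giving a positive
reciprocal judgment matrix $A$ with $a_{ii} = 1$ and $a_{ji} = 1/a_{ij}$.
The canonical weight rule here is the **row geometric mean**,

$$\bar w_i = \Big(\prod_{j=1}^n a_{ij}\Big)^{1/n}, \qquad
  w_i = \bar w_i \Big/ \sum_k \bar w_k,$$

with the principal-eigenvector rule (power iteration) retained as an
independent cross-check: the two agree exactly on consistent matrices and to
well under 0.01 per component on any matrix passing the consistency test.
The largest eigenvalue is estimated by the averaging form
$\lambda_{\max} = \sum_i (Aw)_i / (n\,w_i)$ and cross-checked against a dense
eigen-solver in the test suite. Consistency is judged by
$CI = (\lambda_{\max} - n)/(n - 1)$, the tabulated random index $RI(n)$ for
$n = 1..9$, and $CR = CI/RI < 0.1$. Orders above 9 are an error (no tabulated
$RI$; we do not extrapolate), and $CR$ is defined as 0 for $n \le 2$, where a
reciprocal matrix is always consistent. `ahp_weights()` refuses to return
weights from a failing matrix unless `force = TRUE`.

Two numerical policies matter for reproducing published tables:

* **Reciprocity tolerance.** Published matrices carry two-decimal entries
  (0.33 for 1/3, 1.67 for 5/3), so validation accepts
  $|a_{ij} a_{ji} - 1| \le 0.05$ and never silently symmetrizes. The
  `rationalize = TRUE` mode restores exact reciprocals of the upper
  triangle. On the packaged criterion matrix the as-printed entries give
  $\lambda_{\max} = 4.993$; the rationalized matrix gives
  $\lambda_{\max} = 5.000$, $CI = CR = 0.000$ — exactly the published
  consistency table — so consistency statistics are best quoted on the
  rationalized matrix. The rationalized weights also reproduce the published
  weight percentages exactly, but with the two identical matrix rows swapped
  relative to the published table, which is how we read that table's
  curiosity of assigning different weights (34.991% vs 34.850%) to identical
  rows: it is a rounding/rationalization artifact, and we do not chase
  agreement below 0.15 percentage points.
* **Precision.** All arithmetic is double precision; rounding to 3 decimals
  happens only in `print()` methods.

```{r ahp}
fit <- ahp_weights(macao_judgment())
fit
```

## Fuzzy comprehensive evaluation

The evaluation set is ordinal with the worst level first — by default
`Poor, Relatively Poor, General, Good, Very Good`. Each second-level
indicator gets a membership row over these levels, either directly (expert
scoring) or as survey rating proportions via `membership_from_counts()`
(row counts divided by row totals — the standard frequency construction;
the original questionnaire aggregation rule was not published, and row
proportion is the conventional choice that matches the printed rows'
near-unit sums).

Synthesis uses only the weighted-average operator $M(\cdot,+)$:
$c_j = \sum_i a_i\, r_{ij}$, a plain vector–matrix product. Min–max
operators are deliberately out of scope. The two-level pipeline
(`hierarchical_fce()`) computes per-criterion first-level vectors, stacks
them, applies the criterion weights, normalizes **once**
($C_j / \sum_k C_k$), and classifies by maximum membership. Ties go to the
more severe level with an explicit flag — conservative for a health
assessment, and tie-free on all real inputs we ship.

**Weight handling.** Printed weight tables are rounded to two decimals, so
sibling groups sum to 0.99–1.01. The hierarchy stores them verbatim (an
opt-in `normalize` flag exists in `load_hierarchy()` for new studies), and
the low-level `fce_synthesize()` applies whatever weights it is given. The
pipeline stage, however, rescales each sibling weight group to unit sum
before synthesis (`normalize_weights = TRUE`): the weighted-average operator
is a convex combination only under unit-sum weights, and recomputation of
the packaged worked example shows its printed first-level vectors are
reproduced within 0.004 per component by the rescaled weights, while the raw
weights leave one component 0.006 off. Both facts point the same way, so
rescaling-at-synthesis is the default; pass `normalize_weights = FALSE` to
reproduce strict verbatim arithmetic.

```{r fce}
st <- macao_study()
report <- hierarchical_fce(st$hierarchy, st$memberships)
report
```

The verdict for the packaged study is "General" with membership 0.265,
with "Relatively Poor" a close runner-up — the printed conclusion of the
original evaluation.

## Behavioral mapping

Observation logs carry one record per observed person/group: street,
observation window (morning 7–10 a.m., midday 11 a.m.–3 p.m., evening
5–7 p.m.), age, group size, stay duration, posture and activity. Records
outside the three windows are accepted but flagged. The analysis chain is
`filter_short_stays()` (stays under 5 minutes are by-passers, excluded
strictly below the threshold), `canonicalize_activity()` (case-folding plus
a configurable dictionary, e.g. photo-taking/phone-swiping/calls merge into
"using mobile"; unknown labels pass through flagged), then
`aggregate_activities()` and `age_distribution_by_street()`.

Age bins are half-open and exhaustive: child $[0,15)$, youth $[15,45)$,
middle-aged $[45,65)$, aged $[65,\infty)$. The field protocol's verbal
definitions ("middle-aged around 45 to 55", "aged over 65") leave 56–64
unassigned; extending middle-aged to 64 is the minimal closure making the
classification total and monotone, and is flagged here as a deliberate
deviation from the verbal bins.

The packaged activity-frequency table is raw field data, not a computation;
`observations_from_activity_table()` reconstructs a synthetic log whose
marginals reproduce it exactly, which is how the aggregation chain is
tested end-to-end.

## Space syntax

Street networks are consumed as prebuilt axial graphs (edge lists or
GraphML); deriving axial maps from geometry is out of scope. Per node we
compute connectivity (degree), total/mean BFS depth, relative asymmetry
$RA = 2(\bar d - 1)/(n - 2)$, $RRA = RA / D(n)$ with the standard
diamond-value normalization

$$D(n) = \frac{2\,\{n[\log_2((n+2)/3) - 1] + 1\}}{(n-1)(n-2)},$$

integration $= 1/RRA$ (reported as `Inf` when $RA = 0$, e.g. a star
center), and choice as betweenness centrality with even split over tied
shortest paths, normalized by $(n-1)(n-2)/2$. Space-syntax software
packages differ in their normalization conventions; results here follow
the RA/RRA/diamond convention and should be compared across tools with
that in mind. Disconnected graphs are a hard error — depth is undefined —
rather than being silently restricted to components. The test suite checks
every measure against igraph-free brute-force oracles (queue BFS,
exhaustive simple-path enumeration) on random graphs of up to 8 nodes.

```{r syntax}
space_syntax(simulate_street_graph("cycle", 6))
```

## Synthetic data: what it emulates, and what it does not

Every generator takes an explicit seed and restores the global RNG state
(R's default Mersenne-Twister; same seed, same bytes, across platforms).

* `simulate_judgment_matrix(true_weights, noise_level, seed)` perturbs the
  consistent ratio matrix $w_i/w_j$ by $\exp(\varepsilon_{ij})$ with
  $\varepsilon_{ij} \sim N(0, \text{noise}^2)$,
  $\varepsilon_{ji} = -\varepsilon_{ij}$: log-normal multiplicative error
  preserves positivity and exact reciprocity and makes the noise level
  interpretable as the log-scale size of expert error. No expert-error model
  was published; this is the package's model. Calibration (in the test
  suite, 200 replicates): at noise 0.05 and $n = 5$, at least 95% of
  matrices pass $CR < 0.1$; at noise 1.0 a majority fail.
* `simulate_survey()` draws independent multinomials per indicator over the
  evaluation levels.
* `simulate_observations()` draws age groups from per-street mixtures
  (ages uniform within the group's bin), posture/activity uniformly over
  the field category space, group sizes from the observed regimes (single,
  3–5, 5–8), and stay durations from a two-part mixture with a default 20%
  sub-5-minute mass to exercise the exclusion filter.
* `simulate_street_graph()` provides path/star/cycle/grid topologies and
  seeded connected Erdős–Rényi graphs ("grid" size is the lattice side
  length).

These generators reproduce the *statistical structure* of the field data —
marginal mixtures, multinomial sampling noise, reciprocal expert error —
not its dependence structure: real observation logs correlate activity
with street, age and time of day, real raters are not independent across
indicators, and real expert panels have shared biases. Passing
parameter-recovery tests therefore validates the arithmetic and the
estimators, not the field protocol.

## Problem sizes and numerical choices

The shipped worked example is desk-scale (a 5×5 judgment matrix, 22
indicators, 5 levels) and exact. Simulation-based tests use 200 replicates
for consistency calibration, 50–60 replicates per noise level for recovery
curves, 10,000 respondents per indicator for survey-concentration checks,
and exhaustive graph oracles up to 8 nodes — sizes chosen so each check is
statistically decisive at a fixed seed. Degenerate inputs are first-class:
single-chain hierarchies, all-ones (indifferent) judgment matrices, one-hot
weights and memberships, star centers with $RA = 0$, and empty observation
logs all have defined behavior and tests.

## Known limitations

* Printed two-decimal inputs bound achievable agreement with the published
  tables; tolerances (0.15 percentage points on weights, 0.005 on fuzzy
  vector components) absorb exactly that rounding, and we do not chase
  agreement below them.
* The published per-street connectivity values for Macao cannot be checked
  without the underlying axial map, which was never deposited; the
  space-syntax module is validated against graph-theoretic oracles instead.
* Group AHP across multiple experts, fuzzy-AHP variants, min–max FCE
  operators, defuzzification to a cardinal score, and radius-restricted or
  angular space-syntax measures are out of scope.
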