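---
title: "Learning cohort causal graphs from tiered, mixed-type data with missing values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning cohort causal graphs from tiered, mixed-type data with missing values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccgraph)
```

## The problem

Longitudinal cohort studies measure children (or any subjects) repeatedly
across waves: context variables fixed at birth, early-life factors,
baseline measurements, follow-ups years later. The scientific question is
rarely a single exposure–outcome contrast; it is the *web* of dependencies
— which early factors plausibly influence later outcomes, directly or
through mediators. Constraint-based causal discovery addresses this by
testing conditional independencies and returning the class of causal
structures compatible with them, and cohort data offer a strong piece of
free background knowledge: causes cannot come later in time than their
effects.

`ccgraph` implements the full analysis pipeline for this setting:

1. a **tier-constrained PC-stable** search that learns a maximally
   oriented partially directed acyclic graph (MPDAG) in which no edge
   points from a later tier to an earlier one and user-specified
   orientations can be prohibited outright;
2. **conditional-Gaussian likelihood-ratio tests** so that categorical and
   continuous variables can be tested jointly, with a Fisher-z fast path
   for all-continuous problems;
3. **missing-data handling** by chained-equations multiple imputation with
   pooled tests (Rubin's rules on the Fisher-z scale; the D2 combination
   of chi-square statistics), or by test-wise deletion;
4. **stability analysis** by bootstrap graph ensembles, with edge
   frequencies, consensus graphs, path stability and repeated-measurement
   patterns;
5. a **synthetic cohort generator** so that every stage is testable
   end-to-end without access to any restricted cohort data.

## The model and its assumptions

A causal DAG over the cohort variables implies conditional independencies
(d-separations). The PC algorithm inverts this: it removes the edge
between `x` and `y` when some conditioning set `S` renders them
independent, orients unshielded colliders `x -> z <- y` when `z` is not in
the separating set of `(x, y)`, and closes orientations under Meek's rules
R1–R4. The output without background knowledge would be a CPDAG; with the
tier ordering and forbidden orientations folded in (phase 1 of
`orient_mpdag()`, with the background edges treated as fixed during the
Meek closure) it is an MPDAG: every cross-tier edge is directed
earlier-to-later, and undirected edges remain only within tiers where the
data cannot decide the direction.

Validity of the interpretation rests on the usual assumptions: *causal
sufficiency* (no latent confounders), *faithfulness* (no exactly
cancelling pathways), correct test decisions, and — for the
missing-data variants — *missingness at random* given observed
variables. None of these is testable from the data alone; the absence of
edges and paths is the more robust conclusion, as it survives violations
of causal sufficiency.

The conditional-independence kernel is the homogeneous conditional-
Gaussian model: for a variable set with discrete part `D` (cell count `c`)
and continuous part `C` (dimension `k`), a saturated multinomial over
cells, cell-specific means, and a single covariance matrix pooled across
cells. The likelihood-ratio statistic for `x ⊥ y | S` is referred to a
chi-square with degrees of freedom equal to the parameter-count
difference, `(c-1) + c·k + k(k+1)/2` per fitted margin. This reduces
exactly to the partial-correlation likelihood-ratio test when everything
is continuous and to the stratified G-test when everything is discrete
(both reductions are asserted in the test suite against independent
oracles).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | nominal level of each CI test; the main analysis level, with 0.1 as the conventional sensitivity value. Larger `alpha` makes edge *removal* harder, so graphs grow with `alpha`. |
| `M` | 10 | number of imputed copies; ten is the standard choice balancing pooling stability against cost. |
| `iterations` | 10 | chained-equation sweeps per copy. Burn-in matters: with too few sweeps the imputations retain the marginal initialisation and pooled tests drift anticonservative. Ten sweeps is the conventional burn-in. |
| `model` | `"tree"` | per-variable conditional model: a single `rpart` tree with leaf-wise donor draws (robust, fast, handles mixed types), or `"parametric"` (Bayesian linear / logistic draws) used for calibration work. A full random forest is a straightforward extension point, not shipped. |
| `B` | 100 | bootstrap replicates; each resample receives a *single* imputation, trading imputation uncertainty for feasible cost, exactly as in the reference analysis design. |
| `max_cond` | unbounded | cap on conditioning-set size; expose for speed on dense problems. |
| `edge_prob` | — | edge inclusion probability of the synthetic SCM; 0.05 on the 51-variable fixture gives realistic sparsity (~60 edges). |
| coefficient floor | 0.3 | smallest effect magnitude drawn by `sample_tiered_scm()`, so that desk-scale sample sizes can detect edges. |

## What the synthetic generator emulates — and what it does not

`idefics_schema()` ships the package's reference schema: 51 variables in 8
temporal tiers (3 context variables; parental education and income before
baseline; 7 early-life factors; 11 baseline measurements; education and
income, then 11 measurements at the first follow-up; education and income,
then 13 at the second), 19 of them categorical, with one forbidden
orientation shipped (breastfeeding duration must not point at
birthweight) and room for user-supplied additions — the real code book
prohibits more pairs, but only this one is publicly documented, so the
fixture ships only it.

`sample_tiered_scm()` draws a DAG respecting the tiers (within-tier edges
are made acyclic by a hidden random order, because real cohort graphs do
contain within-tier edges and forbidding them would under-test the
orientation logic), equips it with conditional linear-Gaussian /
multinomial-logistic parameters, and `apply_mar()` imposes missingness
whose probability is a logistic function of fully observed context
variables, calibrated by root finding to hit the target rates (15%
overall, with per-variable rates up to 50%, mirror the reference cohort's
missingness pattern).

What is *not* emulated: real marginal distributions (units, score
constructions, skewness), measurement error, informative drop-out (MNAR),
and latent confounding. Passing tests therefore demonstrate that the
algorithms are correct *under their own assumptions* — they say nothing
about whether those assumptions hold in any particular cohort.

The two fixed demonstration models are part of the validation design:
`demo_scm_12()` (12 nodes, 3 tiers, 14 documented edges with effects
0.5–1.2, two binary nodes) is the structure-recovery benchmark;
`demo_scm_mediation()` (9 nodes, 4 tiers) encodes an exposure that
affects the outcome *only* through a mediator. Its tier-0 context
causes are not decoration: they give the PC search several distinct
candidate separating sets for the exposure–outcome pair, which is what
makes the absence of a direct edge stable under bootstrap resampling
(resampling with replacement inflates the sample's accidental conditional
dependence, so a pair whose removal hinges on a single test would keep a
spurious direct edge in a nontrivial fraction of replicates).

## Numerical choices

- **Singular pooled covariances** are ridged by `1e-8 · trace` and
  flagged, so degenerate synthetic fixtures cannot crash the search.
- **Degrees of freedom** are floored at 1; empty conditional-Gaussian
  cells contribute no likelihood terms and are excluded from the
  parameter count through the observed-cell count.
- **Untestable test-wise-deletion results** (fewer than `|S| + 5`
  complete rows) never remove an edge: deletion requires positive
  evidence of independence.
- **Edge removal** happens at the *first* separating set found
  (lexicographic pair and subset order), the standard PC behaviour; this
  plus PC-stable's frozen adjacency sets makes runs deterministic and
  order-independent.
- **Candidate conditioning sets** are restricted to tiers no later than
  either endpoint: conditioning on the future is never needed and
  skipping it saves tests.
- **Chi-square pooling** across imputations uses the D2 rule (it needs
  only the M statistics); the likelihood-based D3 alternative is an
  extension point. Rubin's rules on the z scale serve the Gaussian path.
  The parametric imputation model draws its parameters from their
  posterior before drawing imputations — *proper* imputation; without it
  the between-imputation variance is understated and the pooled tests
  reject too often.
- **Orientation conflicts** are resolved conservatively: background
  knowledge always wins; contradictory data-driven arrowheads are
  downgraded to undirected and logged, never fatal.
- **Consensus graphs** take the plurality mark per edge, ties becoming
  undirected, and any tier violation or directed cycle introduced by
  voting is downgraded to undirected and logged. The accompanying
  `mean_edge_uncertainty()` — 100 × the mean of (1 − skeleton frequency)
  over surviving edges — is this package's own descriptive definition.
- **Repeated-measurement patterns** overlap as named (a chain is also
  "B→FU1 only" plus "FU1→FU2 only"); members are classified by the most
  specific match, so the eight pattern counts partition the ensemble.
- **Seed fan-out**: one master seed is mapped to per-stage and
  per-replicate seeds by a fixed affine congruential scheme
  (`(seed·48271 + counter) mod 2^31-1`), so stages are independently
  reproducible and whole pipeline runs byte-identical.

## Validation design and problem sizes

The test suite validates the discovery machinery against independent
brute-force oracles rather than against its own output:

- *Oracle equivalence*: with a d-separation oracle as CI source, the
  learned MPDAG is compared with the graph obtained by enumerating every
  orientation of the true skeleton that is acyclic, preserves unshielded
  colliders and respects the background knowledge — exhaustively for
  **all DAGs on up to 4 nodes**, and on random batteries of **300
  five-node** (some with forbidden pairs) and **500 eight-node** tiered
  DAGs. Exhaustive enumeration beyond that adds little per unit cost:
  the rule set either closes correctly on these configurations or it
  does not.
- *Calibration*: each CI-test family (mixed likelihood ratio, Fisher-z,
  test-wise deletion under 30% MCAR, both MI poolings at M = 10 under
  MAR) is checked to hold its nominal 5% level within three Monte-Carlo
  standard errors over 1000 replicates at n = 500.
- *Recovery*: the 12-node benchmark is re-learned from 100 fresh samples
  of n = 20000 and must land within structural Hamming distance 2 of the
  true MPDAG at least 90 times.
- *Stability*: on the mediation benchmark (n = 3000, B = 50 bootstrap
  graphs) the exposure must reach the outcome by a partially directed
  path in ≥ 80% of replicates while a direct edge appears in ≤ 10%.
- *Determinism*: the full pipeline (n = 500, M = 5, B = 10) run twice
  from one master seed must produce byte-identical artifacts.

## Known limitations

- No latent-variable search (FCI) and no score-based alternative; the
  package is deliberately a constraint-based, background-knowledge-first
  tool.
- Bootstrap frequencies are *stability* measures, not edge
  probabilities: resampling with replacement inflates dependence, and
  ensembles systematically contain more edges than the main graph.
- The chained-equations engine draws categorical imputations from
  maximum-likelihood fits (proper draws are implemented for the Gaussian
  path); with very sparse categories this can make pooled tests on
  mostly-discrete nulls mildly anticonservative.
- `graph_summary()` averages shortest paths over connected pairs only;
  on disconnected graphs this is a deliberate reporting choice, not an
  approximation.
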