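---
title: "FOS-3NN: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FOS-3NN: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fos3nn)
```

`fos3nn` stratifies chemotherapy patients into high and low risk for
neutropenic events from first-cycle complete-blood-count (CBC) kinetics.
This vignette is the package's own account of the model, its assumptions,
the parameters that matter, and the places where the design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite does not itself compute.

## The model

Twelve markers per patient — WBC, HGB, PLT, ANC on days 0, 7 and 28 of the
first cycle — are the raw inputs. Two cascaded stages:

1. **Feature selection (FOS).** The outcome is coded $y(n) = +1$ for
   high-risk and $-1$ for low-risk training patients, and modelled as
   $y(n) = \sum_{m=0}^{M} a_m p_m(n) + e(n)$, where the $p_m$ are chosen
   greedily from the candidate algebra: the 12 normalized markers plus all
   $\binom{12}{2} + 12 = 78$ pairwise products (squares included), 90
   candidates in all. At each step the candidate that maximally reduces
   the residual mean-squared error is committed. Orthogonalization is
   implicit: each candidate carries a row of projections $D(m, r)$ against
   the committed terms, updated by the Cholesky-like recursions
   $D(m,r) = \langle p_m p_r \rangle - \sum_{i<r} \alpha(r,i) D(m,i)$,
   $\alpha(m,r) = D(m,r)/D(r,r)$, with the MSE reduction
   $Q_m = C(m)^2 / D(m,m)$ where
   $C(m) = \langle y\,p_m \rangle - \sum_{r<m} \alpha(m,r) C(r)$. No
   orthogonal basis function is ever materialized, which is what makes the
   search over 90 candidates cheap. Final coefficients $a_m$ come from
   back-substitution through the $\alpha$ table. A constant term $p_0 = 1$
   is always fitted but never counted against the term cap and never used
   as a classifier coordinate.

2. **Classification (3NN).** The selected terms' values place each
   training patient at a point in a low-dimensional space (11-dimensional
   for the published term set). A new patient is classified by the
   majority vote of the three nearest training points under unweighted
   Euclidean distance.

The two stages are deliberately decoupled: the selected feature list is
exported, and any other classifier could consume it.

## Normalization

The only published fact about scaling is the target range, 0.02 to 13.5.
The package implements per-marker linear min–max over the *training*
cohort: the training minimum maps to 0.02, the maximum to 13.5. Rationale:
it is the simplest map consistent with equal weighting of markers whose
units differ by orders of magnitude (HGB ≈ 130 g/L vs ANC ≈ 4 × 10⁹/L),
and it re-applies cleanly to unseen patients. Three consequences worth
knowing:

* test-set values fall outside [0.02, 13.5] when they exceed the training
  range; they are **not** clipped, since clipping would discard exactly
  the extreme kinetics the method cares about;
* a constant training marker cannot be scaled; it maps to the midpoint
  6.76 and is flagged degenerate (a warning, not an error, so that a
  pathological cohort still trains);
* cross-products are computed **after** normalization — otherwise the
  products would be dominated by the large-scale markers and the equal
  weighting would be defeated.

Whether the original normalization was fitted on train only or train+test
pooled is unknowable from the published description; train-only is chosen
as the methodologically defensible variant. The origin of the particular
bounds 0.02/13.5 is likewise unexplained in the source; they are treated
as arbitrary range constants, configurable in `fit_normalization()`.

## Stopping, and why the default is permissive

The historical description says only that iterations cease when added
terms "no longer reduce the MSE significantly", and that 11 terms were
selected from a 14-patient training set. Those two facts are in tension:
with 90 candidates and 14 observations, *no* term can pass an honest
multiplicity-corrected significance test (the best-of-90 noise candidate
alone reduces a large fraction of the residual at $n = 14$), so the
11-term behaviour must have been cap-driven. The package therefore uses a
dual default — hard cap `max_terms = 11` plus a relative floor
`min_Q_fraction = 1e-4` of $\langle y^2 \rangle$ — which reproduces the
historical protocol.

The floor, however, cannot reject noise: a random candidate reduces the
residual MSE by about $1/n$ of it in expectation, and the best of $J$
candidates by roughly $2\log J / n$ — at $n = 200$ and $J = 90$ that is
two orders of magnitude above the floor. Measured across 100 pure-noise
replicates, the best candidate's relative reduction ranged 0.013–0.056 and
was never below $10^{-4}$, so a zero-term outcome under the default rule
has probability essentially zero whatever the candidate count. This is a
real limitation of the default and is deliberately left visible: the
corresponding acceptance expectation is retained unweakened and fails.

The remedy is the opt-in significance gate (`significance_alpha`): commit
a term only if its $Q$ exceeds
$\mathrm{residual\ MSE} \cdot \chi^2_{1, 1-\alpha/J} / n$, a
Bonferroni-corrected one-degree chi-square test over the $J$ surviving
candidates. Under pure noise the no-selection probability is then
approximately $(1-\alpha/J)^J \approx 1 - \alpha$ *independently of* $J$
(conservative in practice, since candidates sharing markers are positively
correlated); the test suite verifies ≥ 90% zero-term outcomes at
$\alpha = 0.05$. The gate is not the default precisely because at
$n = 14$ it would select nothing and the package could no longer run the
method's own protocol. Recommended practice: default rule at historical
cohort sizes, gate on for $n \gtrsim 50$.

Other numerical choices in the search: ties in $Q$ break toward the lowest
candidate index in the deterministic candidate ordering (12 first-order
terms in day-major marker order, then pairs $(i, j)$, $i \le j$,
lexicographic); candidates whose orthogonalized energy $D(m,m)$ falls
below $10^{-8} \langle p_m^2 \rangle$ are permanently excluded as linearly
dependent (the standard guard for Cholesky-like recursions), which also
prevents a committed column from ever being committed twice.

## Nearest-neighbour stage

No distance metric is named in the historical description beyond the
remark that every coordinate influences the metric equally; unweighted
Euclidean distance is the natural reading and the default. Distance ties
at the k-th neighbour break by training insertion order (earlier point
wins) and the neighbourhood is *not* expanded to include all tied points,
so exactly $k$ points always vote; with $k$ odd and binary labels a vote
tie is impossible, and $k$ even is rejected at construction. The second
validation protocol — refilling the space with all previously seen
patients before scoring a further hold-out set — is supported by
`augment_space()`, which preserves insertion order (and hence tie-break
priority) of the original points.

## Risk labelling

The retrospective label is a disjunction of adverse-event rules over the
six cycles; any fired rule makes the patient high-risk, and the audit
lists every fired rule. Two rules needed interpretation:

* *"Any delay beyond 40 days"* is read as a single cycle starting more
  than 40 days after the previous cycle's start, i.e.
  `delay_days > 40 − nominal_cycle_length` (threshold 12 with the default
  28-day cycles; both are configurable per regimen).
* *"Delay after the first treatment"* is read literally as a delayed
  cycle 2.

Delayed-cycle counting (rule: ≥ 3 delays) counts cycles started late,
not delay episodes, and counts delays in cycles 4–6 as well — benign late
delays make a patient high-risk only if three accumulate. The day-7
omission rule is only meaningful for regimens that schedule a day-7/8
administration; `risk_config(day7_applicable = FALSE)` disables it.

## The synthetic cohort: what it emulates, and what a green test proves

No patient data are distributable, so the generator is a first-class
module whose defaults were fixed once, on clinical grounds, and define the
package's test world:

* **Marker model.** Counts are positive and right-skewed, hence lognormal:
  each value is `median · exp(N(0, sdlog))` with `sdlog = 0.25` and
  baseline medians WBC 6, HGB 130, PLT 250, ANC 4 (10⁹/L; HGB g/L).
* **Group structure.** Only day-7 and day-28 WBC/ANC separate the groups
  beyond noise, mirroring the markers reported as significant in both the
  historical training and testing sets. Low-risk patients nadir at 50% of
  baseline on day 7 and recover to 95% by day 28; high-risk patients
  nadir at 12% (ANC ≈ 0.5 × 10⁹/L — severe neutropenia) and recover only
  to 60%. HGB and PLT dip mildly and identically in both groups.
* **Events.** Per-cycle Bernoulli processes with group-specific rates
  (high: hospitalization 0.10/cycle, dose reduction 0.40 and day-7
  omission 0.30 in cycles 1–3, delay 0.40/cycle with 7/14/21-day
  magnitudes; low: per-mille-scale rates for all high-risk-rule events
  plus benign 3/7-day late delays at 0.15/cycle). These rates are
  calibrated so the rule-based label agrees with the generating group for
  ≥ 95% of patients per cohort — a prescribed property of the generator,
  asserted per run and reported in `label_agreement`.

Not modelled: temporal correlation of events, pharmacokinetics or
mechanistic myelosuppression, marker–marker correlation within a patient,
regimen differences, demographics effects. Consequently a green end-to-end
test establishes that the *pipeline machinery* — labelling, normalization,
expansion, search, classification, statistics — is correct and that the
method separates groups whose day-7/28 kinetics differ as stated; it is
evidence about the implementation, not about clinical performance.

## Planted-signal harness

FOS recovery is tested on planted signals:
`y = sign(Σ β_k z(term_k) + ε)`, with markers i.i.d. standard lognormal,
normalized, expanded, and `z(·)` z-scoring the planted columns (the raw
candidate columns are strictly positive, so an uncentred sign rule would
be constant — centring is forced, and z-scoring makes the βs comparable).
Two facts discovered while building the harness shape its parameters, both
consequences of the sign() nonlinearity under heavy lognormal skew:

* A planted **square** is *never* recovered first: the population
  correlation of $x^2$ with `sign`-of-centred-$x^2$ is about 0.19 against
  0.48 for the first-order $x$ itself (the indicator is monotone in $x$,
  and squaring only inflates the tail variance). Recovery-first of a
  square is thus impossible in this world at any sample size, and the
  harness plants first-order and mixed cross-product terms instead.
* A planted **cross-product** $x_i x_j$ beats its own marginals only
  narrowly at population level (correlation ≈ 0.50 vs 0.475), so
  recovery-within-3 converges slowly in $n$: measured rates were 76/100
  at $n = 200$, 91/100 at $n = 4000$, 95/100 at $n = 20000$, while the
  population-level greedy path (checked at $n = 2 \times 10^5$) selects
  both true terms in its first two steps. The acceptance harness runs at
  $n = 4000$, the scale at which the population ordering emerges at the
  demanded ≥ 90% reliability; the zero-noise single-term clause runs at
  $n = 800$, comfortably inside its measured 100% regime.

## Evaluation conventions

* Fisher's exact test enumerates the hypergeometric distribution of the
  top-left cell with margins fixed, via log-binomials (exact to ~1e-14;
  verified to sum to 1 within 1e-12 for every margin with N ≤ 200). The
  one-tailed p sums the tail in the direction of the observed association;
  the two-tailed p follows the sum-of-small-probabilities convention with
  a 1e-9 relative tolerance for floating-point ties — the dominant
  convention, consistent with both historical two-tailed bounds.
* Matthews' φ is undefined when a margin is zero; 0 is returned with a
  `degenerate` attribute rather than NaN.
* The two-sample t-test defaults to pooled-variance Student (matching the
  historical naming); Welch is available by flag since the original choice
  is unverifiable.

## Serialization and determinism

Model JSON carries the marker alphabet, normalization, selected terms,
coefficients and the training points, with numerics at 17 significant
digits (`jsonlite`'s maximum-precision mode loses the 16th–17th digit, so
the digit count is pinned explicitly); a write–read–write round trip is
byte-identical. All file writes are write-then-rename, so an interrupted
run never leaves a truncated artifact. Every stochastic entry point takes
an explicit seed; identical seeds produce byte-identical CSV/JSON outputs.

## Known limitations

* The published 11-term set (`published_terms()`) cannot be re-derived
  without the original cohort; it ships as a preset for projection and
  classification, not as a reproduction claim.
* The default stopping rule cannot reject noise candidates (see
  *Stopping*); users fitting larger cohorts should enable the gate.
* Historical per-marker p-value tables are not reproducible without the
  cohort and are out of scope, as are proportional-hazards and
  survival-curve analyses.
* The classifier inherits the known fragility of nearest-neighbour
  methods to a single uninformative coordinate with large spread; the
  exported feature list makes it easy to substitute a different back-end.
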