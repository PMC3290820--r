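# fos3nn

Neutropenia risk stratification from first-cycle blood counts, by Fast
Orthogonal Search feature selection cascaded into a 3-nearest-neighbour
classifier (FOS-3NN).

## The problem

Neutropenia — a dangerously low absolute neutrophil count (ANC) — is the main
dose-limiting toxicity of adjuvant chemotherapy. Patients who will suffer a
neutropenic event (hospitalization, treatment delay, dose reduction, omitted
day-7 dose) over a 6-cycle regimen would benefit from early identification,
when growth-factor support can still be targeted rationally. `fos3nn`
implements a classifier that stratifies patients into high (+1) and low (−1)
risk groups using only the complete blood count (CBC) panel from the *first*
treatment cycle: WBC, HGB, PLT and ANC measured on days 0, 7 and 28.

## The method

Each of the 12 markers is range-normalized to [0.02, 13.5] (per-marker
min–max over the training cohort) so that no laboratory scale dominates, and
expanded into the 90-term candidate algebra of all first-order terms plus
the 78 second-order cross-products (including squares). Fast Orthogonal
Search then fits

```
y(n) = Σ_{m=0}^{M} a_m p_m(n) + e(n),   y(n) ∈ {−1, +1},
```

greedily: at each step every surviving candidate p is scored by the
mean-squared-error reduction Q = g²·D it would contribute after implicit
Gram–Schmidt orthogonalization against the committed terms (the orthogonal
functions are never materialized — only the Cholesky-like D/α/C recursions
over patient averages), and the maximal-Q candidate is committed. Selection
stops at a configurable cap (default 11 terms) or when the best Q falls
below a floor; an optional Bonferroni chi-square significance gate rejects
candidate sets indistinguishable from noise. The selected terms define the
coordinates of a k-nearest-neighbour space (k = 3, Euclidean) populated by
the training patients; new patients are classified by majority vote of
their three nearest training neighbours.

Evaluation uses exact small-sample statistics: Fisher's exact test
(hypergeometric enumeration with fixed margins, one-tailed in the direction
of the observed association, two-tailed by the sum-of-small-probabilities
rule) and Matthews' correlation coefficient φ. Retrospective risk labels
come from a rule engine over per-cycle treatment events (any
hospitalization; ≥3 delayed cycles; any delay beyond the 40-day gap; a
delayed second cycle; a missed day-7 dose or dose reduction in cycles 1–3),
where any fired rule makes the patient high-risk.

No clinical cohort ships with the package; a synthetic generator emulates
the relevant structure (lognormal counts, group-specific day-7 nadir and
day-28 recovery depression of WBC/ANC, Bernoulli event processes) so the
whole pipeline is testable end to end.

## Worked example

```r
library(fos3nn)

cohort   <- generate_cohort(cohort_spec(n_patients = 35, seed = 1))
labelled <- label_courses(cohort$events)
pts <- as.data.frame(cohort$patients)
pts$risk_label <- labelled$risk_label[match(pts$patient_id, labelled$patient_id)]

hi <- pts$patient_id[pts$risk_label == 1]; lo <- pts$patient_id[pts$risk_label == -1]
train <- as_patients(pts[pts$patient_id %in% c(head(hi, 7), head(lo, 7)), ])
test  <- as_patients(pts[!pts$patient_id %in% train$patient_id, ])

model <- train_fos3nn(train)   # 14 patients, 90 candidates
print(model)
#> FOS-3NN model: 7 terms, 14 training points, k = 3
#>   terms: WBC7, ANC7, ANC0*WBC7, PLT0*HGB28, ANC7*ANC7, WBC7*HGB7, ANC0*HGB7

pred <- predict(model, test)
print(eval_report(test$risk_label, pred$predicted))
#>           predicted high  predicted low
#> act high              11              0
#> act low                0             10
#> correct: 21 / 21 (100.0%)
#> Fisher exact: one-tailed 2.84e-06, two-tailed 2.84e-06
#> Matthews phi: +1.00
```

The day-7 WBC term alone removes 86% of the outcome energy
(`mse_trace(model$fos)` shows Q = 0.857 for `WBC7`), reflecting the
generator's severe high-risk nadir; the remaining terms are cross-products
refining the boundary. On this synthetic cohort the 21 held-out patients
are all classified correctly. On reference confusion counts the statistics
reproduce exactly: `fisher_exact(confusion_2x2(9, 2, 0, 10))` gives
one-tailed 55/293930 ≈ 1.87e-4 and `mcc` rounds to +0.83.

The published 11-term feature space ships as a preset:
`train_preset(train, published_terms())` builds the classifier directly in
that space without running FOS.

## Command line

```sh
exec/fos3nn simulate --n 35 --seed 1 --out-prefix run
exec/fos3nn label    --patients run_patients.csv --events run_events.csv --out labelled.csv
exec/fos3nn train    --patients labelled.csv --model model.json
exec/fos3nn classify --model model.json --patients labelled.csv --out pred.csv
exec/fos3nn evaluate --predictions pred.csv --out report.json
exec/fos3nn pipeline --seed 1 --out-dir out/        # all of the above
```

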