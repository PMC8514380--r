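# tp53sig

Scoring and prognostic analysis for the **TP53 gene-expression signature**
in early breast cancer.

TP53 mutation is an established marker of poor prognosis in breast cancer,
but direct sequencing misses functionally equivalent lesions. The TP53
signature sidesteps this: a small panel of genes whose expression pattern
separates TP53-mutant from wild-type tumours, measured on a multiplex
RT–PCR panel of 26 genes — 16 up-regulated in mutant tumours, 7
down-regulated, and 3 internal controls. This package implements the
complete diagnostic and prognostic workflow around that panel:

* **Signature score.** For a sample with expression values *x*,

  *score = Σ<sub>g ∈ up</sub> x<sub>g</sub> / Σ<sub>g ∈ down</sub> x<sub>g</sub>*

  a dimensionless ratio, invariant to per-sample scaling (so the control
  genes serve only as a QC gate). A sample is called **mutant signature**
  when its score is strictly greater than the published cutoff **1.11**
  (`TP53_CUTOFF`); otherwise **wild-type signature**.
* **Calibration.** Empirical ROC of scores against a reference TP53 status:
  the Mann–Whitney AUC (half credit for ties), Youden-optimal cutoff
  selection over midpoint thresholds, and call-vs-reference agreement. The
  34-sample development cohort that fixed the cutoff ships as a plain-text
  fixture (`table1Fixture()`).
* **Survival analysis.** Kaplan–Meier curves, log-rank tests, and
  univariate/multivariate Cox proportional-hazards models (Efron ties) for
  recurrence-free, overall, and breast-cancer-specific survival, including
  the two-stage prognostic-factor table (univariate screen at p ≤ 0.05,
  then a joint model), molecular-subtype and grade stratification
  (luminal A/B-like by ER and Ki-67 at 10%, TNBC), and
  baseline-characteristics tests (chi-squared; Kruskal–Wallis for age).
* **Synthetic cohorts.** A simulator producing expression + clinical
  cohorts with the structure the analysis assumes — 89/189 mutant
  prevalence, class-conditional covariate frequencies, and an exponential
  proportional-hazards event process with a true signature hazard ratio of
  3.96 — so the whole pipeline is testable without patient data.

## Worked example

```r
library(tp53sig)

## the packaged development cohort: score vs microarray reference status
fx <- table1Fixture()
rocAuc(fx$tp53_signature_score, fx$status_by_microarray)
#> [1] 0.9930556
selectCutoff(fx$tp53_signature_score, fx$status_by_microarray)
#> RocResult: 35 thresholds
#>   AUC            0.9931
#>   selected cutoff 1.196 (Youden's J = 0.9444)
agreementRate(fx$status_by_score, fx$status_by_microarray)$rate
#> [1] 0.9705882

## a synthetic 189-patient validation-style cohort
co <- simulateCohort(seed = 1)
calls <- scoreCohort(co$expression)          # cutoff 1.11 by default
table(calls$tp53_status)
#>   wild mutant
#>    102     87

clinical <- co$clinical
clinical$tp53_status <- as.character(calls$tp53_status)
lr <- logRank(clinical, "rfs", "tp53_status")
c(statistic = lr$statistic, p = lr$p_value)
#>    statistic            p
#> 1.649734e+01 4.871843e-05
```

The AUC of 0.993 means 286 of the 288 mutant–wild score pairs in the
development cohort are correctly ordered; the agreement of 0.971 reflects a
single sample (BR013) called mutant by score but wild by the microarray.
The recalibrated Youden cutoff (1.196) falls in the score gap between the
highest concordantly-wild and lowest mutant sample — the published constant
1.11 remains the classification default and is never silently replaced. In
the simulated cohort, mutant-signature patients recur significantly faster
(log-rank χ² = 16.5), as built into the generator's hazard model.

`runPipeline(expression, clinical, outputDir = "out")` runs everything —
scoring, per-endpoint log-rank/KM, the Cox table, subgroup and
characteristics reports — and writes TSV/JSON/YAML artifacts stamped with
the configuration hash.

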