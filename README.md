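# pharmacotypeR

Ex vivo drug-sensitivity pharmacotyping of pediatric acute lymphoblastic
leukemia (ALL), as a tested, reusable R pipeline. The package is aimed at
biostatisticians and computational biologists analyzing primary-cell drug
screens: it takes raw 6-point viability curves through censored LC50
estimation, normalization, multiple imputation, consensus clustering, MRD
(minimal residual disease) association and survival analysis, and ships a
synthetic cohort generator with exported ground truth so every step can be
validated by recovery simulation.

## The models at the core

**Censored LC50.** Viability as a fraction of vehicle control is fitted
with a four-parameter logistic in log10 concentration,
`v(x) = b + (t − b) / (1 + 10^{h (x − log10 EC50)})`, and the LC50 is the
concentration where the fitted curve crosses absolute viability 0.5. If
the lowest tested dose already kills >50% of cells the LC50 is
left-censored at `c_min / 2`; if >50% survive the highest dose it is
right-censored at `2 c_max`. Raw LC50 values are log10-transformed and
min–max normalized per drug with the censor bounds as extremes, so
censored values map exactly to 0 (most sensitive) and 1 (most resistant).

**Multiple imputation.** Missing patient–drug cells (~62% of the matrix
in the study design) are completed by chained equations implemented
in-package: per-column Bayesian linear regression with predictive mean
matching (5 donors), m = 10 datasets. Validity checks include
leave-one-out coverage of 95% imputation intervals, observed-vs-imputed
distribution tests with Benjamini–Hochberg correction, and measured-vs-
pooled regression-coefficient comparison.

**Pharmacotype clusters.** The m completed matrices are stacked
((10·N) × 18), clustered agglomeratively on Manhattan distances, and cut
at k = 6; a patient receives a final cluster only when the same label
recurs in ≥5 of 10 imputation replicates.

**MRD association.** Per drug, log10 MRD is regressed on normalized LC50
adjusting for protocol, age and WBC; since LC50 lives on [0, 1], a
coefficient β is the log10 MRD difference between the most resistant and
most sensitive patients, i.e. a fold change of 10^β (β = 0.30 ⇒ MRD twice
as high; β = −0.30 ⇒ half).

**Survival.** Kaplan–Meier EFS with Greenwood errors and the 5-year
estimate at t = 5, Mantel's log-rank test, and Cox proportional-hazards
models (Efron ties) stratified by treatment arm.

## Worked example

```r
library(pharmacotypeR)

co  <- simulate_cohort(cohort_config(), seed = 1)
co
#> syn_cohort: 805 patients x 18 drugs, 5462 observed LC50 cells

imp <- impute_chained(co$lc50, m = 10, seed = 2)
cl  <- stack_and_cluster(imp, k = 6)
cl
#> consensus_clustering: k=6, m=10, threshold=5; 784/805 patients assigned (97.4%)

b     <- co$clinical$lineage == "B"
assoc <- associate_mrd(co$lc50$values[b, ], transform_mrd(co$mrd$day15)[b],
                       covariates = co$clinical[b, c("protocol", "age", "wbc")])
head(assoc[order(assoc$p), c("drug", "beta", "ci_lower", "ci_upper", "p_bh", "n")], 3)
#>          drug  beta ci_lower ci_upper     p_bh   n
#> dexamethasone 0.977    0.691    1.263 2.18e-09 253
#>    cytarabine 1.028    0.587    1.469 6.10e-05 267
#>  prednisolone 0.639    0.342    0.936 1.62e-04 264

sv <- co$survival
ok <- complete.cases(sv$efs_time, sv$event) & !is.na(cl$final)
logrank_test(sv$efs_time[ok], sv$event[ok], cl$final[ok])
#> $statistic 38.5   $df 5   $p 3e-07
```

Reading the output: 784 of 805 patients received a consensus pharmacotype
cluster (the rest had no label recurring in 5 of 10 imputations).
Glucocorticoid and antimetabolite resistance are the strongest MRD
correlates in B-lineage disease — e.g. β = 0.64 for prednisolone means
day-15 MRD is `10^0.64 ≈ 4.4`-fold higher in fully resistant than fully
sensitive patients. Note that a single-drug coefficient absorbs the
effects of correlated drugs in the panel, so these estimates exceed the
per-drug coefficients used by the generator. EFS differs strongly across
the six clusters (log-rank p = 3e-07), as planted in the simulation.

`run_pipeline(cohort_config(), seed = 1)` chains all of the above and
returns a result bundle with a machine-readable manifest;
`render_reports(run, dir)` writes the cluster heatmap, the MRD forest
plot and the KM curves.

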