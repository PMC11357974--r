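# sclcpheno

Claims-based computable phenotyping of small cell lung cancer (SCLC).

ICD-10-CM diagnosis codes identify lung cancer (`C34.*`) but not its
histology, so claims-only databases cannot separate SCLC from non-small
cell lung cancer (NSCLC) directly. Registry histology (ICD-O-3 codes 8002,
8041–8045 = SCLC) can serve as a gold standard where a registry-claims
linkage exists, and the treatment signal — etoposide is first-line for SCLC
and rare in NSCLC, EGFR testing is ordered for NSCLC and almost never for
SCLC — carries the distinction into claims. `sclcpheno` is for
health-services researchers who need such phenotypes: it builds the
diagnosed and treated lung-cancer cohorts, screens procedure codes for
discriminating utilization, applies boolean treatment-based classification
rules, and reports masked diagnostic accuracy, with a calibrated synthetic
registry-claims generator standing in for restricted linked data.

## The method

With SCLC as the positive class and the registry label as truth, each
candidate algorithm *A* (a boolean expression over windowed code-set
exposures, e.g. "etoposide within 180 days of diagnosis", or
"etoposide AND no EGFR testing") yields a confusion matrix, from which

    Se  = TP / (TP + FN)      Sp  = TN / (TN + FP)
    PPV = TP / (TP + FP)      NPV = TN / (TN + FN)

are estimated in a 75% validation sample, after candidate codes are
discovered in a disjoint 25% exploration sample by three threshold filters
on per-code utilization proportions: candidates (|p_SCLC − p_NSCLC| ≥ 20
points), false-positive reducers (p_SCLC < 5% and p_NSCLC > 10%) and
false-negative reducers (p_SCLC > 20% and p_NSCLC < 5%). Counts below 11
are suppressed (`NR`) together with their margin complements, with bound
displays (`< 0.02`, `> 0.99`) replacing metrics whose numerator is masked.

## Worked example

```r
library(sclcpheno)

cfg    <- default_config(n_patients = 31912, seed = 1)
pop    <- generate_population(cfg)
cohort <- build_cohort(pop)
attrition(cohort)
#>   source_patients   diagnosis_claim with_tumor_record      age_eligible
#>             31912             31912             31912             31912
#> lookback_eligible             final
#>             28106             28106

cohort <- split_sample(cohort, 0.25, seed = 1)
valid  <- cohort[cohort$split == "validation", ]
flags  <- build_utilization(valid, pop$claims, window = "post180")
res    <- evaluate_rules(builtin_rules()[c("etoposide", "etoposide_no_egfr")],
                         valid, flags)
render_results(res)
#>          Algorithm Population True Positive False Positive True Negative
#>          etoposide       full          1102            409         18662
#>          etoposide    treated         1102            409          5116
#>  etoposide_no_egfr       full          1098            363         18708
#>  etoposide_no_egfr    treated         1098            363          5162
#>  False Negative Sensitivity Specificity   PPV   NPV
#>             907       0.549       0.979 0.729 0.954
#>              36       0.968       0.926 0.729 0.993
#>             911       0.547       0.981 0.752 0.954
#>              40       0.965       0.934 0.752 0.992
```

Reading the first two rows: among all diagnosed patients the etoposide rule
finds about half of SCLC cases (sensitivity 0.549) — most diagnosed
patients receive no outpatient systemic therapy, so a treatment-based rule
cannot see them — while among treated patients it finds nearly all of them
(0.968). True and false positives are identical in both populations
(every patient the rule flags is, by construction, treated), so PPV is
identical; the denominator shift moves only sensitivity, specificity and
NPV. The case mix delivered by the rule is summarised by

```r
cm <- as_confusion_matrix(tp = 1102, fp = 409, tn = 18662, fn = 907)
case_ratio(cm)
#> [1] 2.7
```

i.e. 2.7 true SCLC patients per NSCLC patient carried along. Screening,
rule construction from JSON/YAML (`rule_from_json()`), the 30-day
pre-diagnosis sensitivity window (`window = "pre30_post180"`), custom code
lists (`load_codesets()`) and a command-line dispatcher
(`inst/cli/sclcpheno` with `generate` / `cohort` / `screen` / `classify` /
`evaluate` subcommands) are documented in the function reference and the
vignette.

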