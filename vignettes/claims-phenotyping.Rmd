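---
title: "Treatment-based phenotyping of small cell lung cancer in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-based phenotyping of small cell lung cancer in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcpheno)
```

## The problem

Small cell lung cancer (SCLC) and non-small cell lung cancer (NSCLC) are
clinically distinct diseases, but administrative claims carry only
ICD-10-CM diagnosis codes (`C34.*`), which do not encode histology. A
registry linked to claims provides the gold standard — ICD-O-3 histology
codes 8002 and 8041–8045 define SCLC, everything else is NSCLC — but most
claims-only databases have no such linkage. Because SCLC and NSCLC are
treated differently, the histology signal survives in the claims themselves:
etoposide, the backbone of first-line SCLC therapy, is rarely given for
NSCLC, while EGFR testing is essentially never ordered for SCLC. This
package implements the full workflow for building and validating
deterministic, treatment-based computable phenotypes of this kind, together
with a synthetic linked-data generator so the pipeline can be exercised and
tested without access to restricted registry-claims linkages.

## Cohort definition

The index date is the first day of the calendar month of registry
diagnosis, because the registry reports diagnosis at month resolution.
Inclusion requires a claims lung-cancer diagnosis (prefix `C34`,
dot-insensitive) in 2016–2017, age ≥ 66 completed years at index (so a full
year of pre-diagnosis history exists within the insured population), and
complete Part A + B + D fee-for-service coverage, without HMO enrollment,
in each of the 12 calendar months strictly before the index month —
enrollment data are month-level, so the lookback is month-level too.
Observation ends at the earliest of index + 180 days, death, or the first
day of the first post-index month without full coverage; the reason is
recorded as `window_end`, `death` or `disenrollment`.

When a patient has several lung tumor records, the record closest in months
to the claims-based diagnosis month is used; ties break to the earlier
month, then to the smaller histology code. The claims-based diagnosis month
is operationalised as the month of the earliest qualifying diagnosis claim
— the natural choice when only claims are observable. Patients with a
qualifying claim but no linkable tumor record cannot be labelled; they are
dropped and counted in the attrition log.

A member is *treated* if they have at least one outpatient claim matching
any systemic-therapy (antineoplastic) code set within 180 days of index.
Supportive-care agents — the G-CSFs and fosaprepitant — accompany
chemotherapy but are deliberately not treated-defining; they are evaluated
as rule ingredients only. The 25%/75% exploration/validation split is an
exact-size partition (`round(0.25 * N)` members explored), deterministic
under its seed.

## Exposure windows and rules

Exposure flags are computed per (patient, code set): at least one claim in
the window, in an allowed setting, matching the set. Both windows are
half-open — `post180` is `[index, index + 180)` and the pre-diagnosis
sensitivity window `pre30_post180` is `[index − 30, index + 180)`. Whether
"within 180 days" includes day 180 is genuinely ambiguous; the half-open
convention was chosen once and is pinned by boundary tests. Windows are
anchored to the index date regardless of censoring: the window defines the
code search, while the observation end defines follow-up. Systemic-therapy
sets search outpatient, Part D and durable-medical-equipment claims (oral
equivalents are dispensed, not administered); the EGFR-test predicate
searches all settings, since the reporting setting of a lab claim is not
informative about the test.

Classification rules are boolean expression trees over these flags —
`AND`/`OR` n-ary, `NOT` unary — and predictions are deterministic and
binary: a probabilistic score would make it harder for a downstream study
to decide whether the definition suits its question. The built-in rule book
contains the ten single-agent rules, three disjunctions, and the
false-positive-reducing conjunction `etoposide AND NOT egfr_test`.
Monotonicity is structural: adding an `OR` leaf can only move predictions
toward SCLC, adding `AND NOT` only toward NSCLC, which surfaces as
non-decreasing / non-increasing TP and FP counts.

## Exploration-phase screening

The code screen tabulates, per distinct HCPCS/CPT code, the proportion of
SCLC and NSCLC members with at least one in-window claim (denominators are
all members of the label, including those with no claims). Three filters
are applied: *candidates* need an absolute difference of at least 20
percentage points (inclusive — implemented with a float tolerance so an
exactly-20-point difference computed in IEEE arithmetic is kept);
*false-positive reducers* need `p_SCLC < 5%` and `p_NSCLC > 10%` (strict);
*false-negative reducers* need `p_SCLC > 20%` and `p_NSCLC < 5%` (strict).
The 20-point threshold is read as an absolute difference of proportions,
not a relative one, since the procedure compares "proportions using the
code". Screening defaults to HCPCS/CPT only — NDC screening is a
configuration switch — and no multiplicity correction is applied: the
procedure is descriptive, not inferential.

## Accuracy metrics and disclosure masking

With SCLC as the positive class, sensitivity is `TP/(TP+FN)`, specificity
`TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`; a metric whose
denominator is zero is `NA`, never 0, and renders as an empty cell. The
case ratio `TP/FP` summarises the case mix a rule delivers. Metrics are
exact ratios internally and rounded only for display, half-up to 3 decimals
(1 for the case ratio), using integer arithmetic on the counts: IEEE
doubles store 92/320 = 0.2875 just below the boundary, so naive rounding
would print 0.287 where 0.288 is correct.

Reports honour registry privacy masking: any count below 11 displays as
`NR`, and because per-label margins (the gold SCLC and NSCLC totals) are
public in population tables, the complement cell within the same margin is
suppressed too. When TP itself is below threshold, sensitivity displays as
an upper bound `< b`, `b = 11/(TP+FN)` rounded up to 2 decimals; when FP is
below threshold, specificity displays as `> b`, `b = 1 − 11/(FP+TN)`
rounded down. PPV and NPV remain displayed as computed. Published masked
tables show the outputs of such a rule, not the rule itself; the
formulation here is an interpretation that reproduces the published bound
patterns and is verified not to let any combination of displayed integers
and margins pin a masked cell to a unique value.

## What the synthetic generator emulates

The generator draws, per patient: an SCLC label (prevalence 0.094), a
diagnosis month uniform over 2016–2017, an age from the published band
distribution (18.9/26.9/23.9/16.0/14.3% over 66–69 … 85+; an optional
19–65 band with default weight 0 supports the younger-population
analysis), a treated indicator (0.587 for SCLC, 0.285 for NSCLC — the
published treated-by-histology fractions), and exposures per code set.
Systemic-agent exposures are parameterised *conditional on treatment*, at
the rates implied by the published treated-subset margins (etoposide
431/447 for SCLC, 116/2121 for NSCLC; carboplatin 368/447 and 1410/2121;
and so on), which reproduces the diagnosed-level marginals (58% / 1.5% for
etoposide). Rates for the rare agents, whose counts are masked in the
source tables, were reconstructed from their reported predictive values
(ipilimumab 5/447, irinotecan 7/447, topotecan 11/447, each 2/2121 for
NSCLC); oxaliplatin, absent from the tables, is set to 1% in both groups.
EGFR testing is drawn for all diagnosed patients at 0.5% (SCLC) and 10.5%
(NSCLC): the published "10%" must sit strictly above the 10% screening
bound for the test to have been retained as a false-positive reducer, so
the default uses the upper half of the printed rounding interval.

Treated patients are guaranteed at least one antineoplastic claim by
redrawing all-zero exposure vectors. This keeps the claims-derived treated
fraction exactly calibrated, at the cost of inflating each agent's
conditional rate by `1/(1 − P0)`, where `P0` is the all-fail probability;
`expected_rates()` reports these adjusted conditionals and marginals in
closed form, and the calibration tests and end-to-end accuracy checks
compare empirical values against them rather than against the raw
configured rates.

Exposures are independent Bernoulli draws given (label, treated). This is
a deliberate simplification — only marginal utilization rates are published
— and its main visible consequence is that the *platinum union* reaches
about 86% of treated SCLC rather than the observed 99%, because real
regimens couple etoposide with a platinum agent. An optional
`force_etoposide_platinum` flag restores that coupling. Two label-neutral
background codes (an office visit and a chest CT) are emitted so the
screening filters have realistic chaff to reject, and drug claims sample
the set's primary code with weight 0.85 so per-code screening sees a
dominant administration code. Death and post-index disenrollment rates
default to 0 (no rates are published); the lookback-failure rate is 0.12,
matching the published attrition step (88% of age-eligible patients met the
lookback requirement). Duplicate tumor records occur with probability 0.01
to exercise the tie-breaking rule.

Passing tests on these data show that the pipeline's logic — inclusion,
windowing, rule evaluation, screening arithmetic, masking — is correct and
that the generator meets its own calibration. They cannot show that the
placeholder J-code lists match any study's full HCPCS/NDC code lists, that
real agent exposures are conditionally independent (they are not), or how
the algorithms perform on stages, comorbidity patterns or inpatient-only
treatment, none of which are modelled.

## Numerical and testing choices

Months are integer month indices throughout (`year*12 + month − 1`), so
month arithmetic never touches day-of-month edge cases; dates appear only
after an index date exists. Ages are completed years at index. Display
rounding is exact-integer half-up as described above. Test fixtures use
seed 20160101 (the start of the diagnosis window), chosen once as a
convention; the calibration tests run at n = 10,000 with 4-standard-error
bounds, and the end-to-end and screening-recovery checks at the study
scale of n = 31,912, which keeps the full suite under a minute of
simulation while leaving binomial noise well inside the ±3-point bands
being asserted.

## Known limitations

The shipped drug code lists are representative single J-codes, not
exhaustive formulary lists; real applications should load their own via
`load_codesets()`. The generator models no inpatient systemic therapy (not
identifiable in the emulated data), no stage-specific treatment propensity,
no cost or line-of-therapy structure, and no correlation between agents
beyond the optional etoposide–platinum coupling. The masking rule is an
interpretation of published outputs; other disclosure-control
implementations may suppress different complements. Screening is per-code
and descriptive; it will not find multi-code signals that only matter in
combination.
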