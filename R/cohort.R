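#' Inclusion criteria for the analysis cohort
#'
#' Defaults mirror a typical Medicare claims study design: a claims-based
#' lung cancer diagnosis during 2016-2017, age at least 66 at the index date
#' (so that a full year of pre-diagnosis history exists), and 12 months of
#' continuous Part A, Part B and Part D coverage with no HMO enrollment in
#' the calendar months strictly before the index month. The younger-patient
#' sensitivity analysis is expressed by `min_age = 19, max_age = 65`; the
#' lookback requirement is kept by default there too, but can be relaxed
#' with `lookback_months = 0`.
#'
#' @param diagnosis_years Calendar years in which a qualifying lung-cancer
#'   diagnosis claim must occur.
#' @param min_age,max_age Age bounds (completed years at index); `max_age`
#'   `NULL` means unbounded.
#' @param lookback_months Months of required continuous enrollment before
#'   the index month (0 disables the requirement).
#' @param followup_days Length of the post-index observation window.
#' @return An object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(diagnosis_years = c(2016L, 2017L),
                               min_age = 66L, max_age = NULL,
                               lookback_months = 12L,
                               followup_days = 180L) {
  if (!is.null(max_age) && min_age > max_age) {
    stop("min_age must not exceed max_age", call. = FALSE)
  }
  structure(
    list(diagnosis_years = as.integer(diagnosis_years),
         min_age = as.integer(min_age),
         max_age = if (is.null(max_age)) NULL else as.integer(max_age),
         lookback_months = as.integer(lookback_months),
         followup_days = as.integer(followup_days)),
    class = "inclusion_criteria"
  )
}

#' Index date from a month-level diagnosis
#'
#' The registry reports only the month and year of diagnosis, so the index
#' date is the first day of that month.
#'
#' @param diagnosis_month `"YYYY-MM"` string(s) or a `Date`.
#' @return A `Date` vector.
#' @export
derive_index_date <- function(diagnosis_month) {
  if (inherits(diagnosis_month, "Date")) {
    diagnosis_month <- format(diagnosis_month, "%Y-%m")
  }
  ym_first_day(diagnosis_month)
}

#' Gold-standard histology label
#'
#' A patient is SCLC iff the tumor's ICD-O-3 histology code belongs to the
#' small cell set (8002, 8041-8045); every other histology is NSCLC.
#'
#' @param histology Character vector of ICD-O-3 histology codes.
#' @param registry Registry providing the `sclc_histology` set.
#' @return Character vector of `"SCLC"` / `"NSCLC"`.
#' @export
gold_label <- function(histology, registry = builtin_registry()) {
  set <- registry[["sclc_histology"]]
  ifelse(match_code(histology, set$system, set), "SCLC", "NSCLC")
}

#' Select the tumor record closest to the claims diagnosis month
#'
#' When a patient has more than one lung tumor record, the record whose
#' registry diagnosis month is closest to the claims-based diagnosis month
#' is used; ties break to the earlier diagnosis month, then to the smaller
#' histology code.
#'
#' @param tumors A data.frame of tumor records for one patient, with columns
#'   `diagnosis_month` (`"YYYY-MM"`) and `histology`.
#' @param claims_dx_month Claims-based diagnosis month, `"YYYY-MM"`.
#' @return The selected row of `tumors`.
#' @export
select_tumor_record <- function(tumors, claims_dx_month) {
  if (is.null(tumors) || nrow(tumors) == 0L) {
    stop("no tumor records to select from", call. = FALSE)
  }
  d <- abs(ym_index(tumors$diagnosis_month) - ym_index(claims_dx_month))
  ord <- order(d, ym_index(tumors$diagnosis_month), tumors$histology)
  tumors[ord[1L], , drop = FALSE]
}

#' Build the analysis cohort
#'
#' Applies the inclusion criteria to a linked population and derives, per
#' member: the index date (first day of the selected tumor's diagnosis
#' month), the gold histology label, age at index, the observation end
#' (earliest of index + `followup_days`, death, or the start of the first
#' post-index month without full fee-for-service coverage) with its censor
#' reason, and the treated flag (at least one outpatient claim matching any
#' systemic-therapy code set within `[index, index + followup_days)`).
#'
#' A patient is included iff they have a lung-cancer diagnosis claim in a
#' qualifying year, a linkable tumor record (patients with a qualifying
#' claim but no tumor record cannot be labelled and are dropped, counted in
#' the attrition log), age within bounds, and a complete enrollment
#' lookback. Stage-wise counts are recorded in `attr(, "attrition")`.
#'
#' @param pop A `synthetic_population` (or any list with the same four
#'   tables).
#' @param criteria An [inclusion_criteria()].
#' @param registry A `codeset_registry`.
#' @return A `data.table` of class `lc_cohort` with columns `patient_id`,
#'   `index_date`, `gold_label`, `age`, `observation_end`, `censor_reason`,
#'   `treated`.
#' @export
build_cohort <- function(pop, criteria = inclusion_criteria(),
                         registry = builtin_registry()) {
  stopifnot(inherits(criteria, "inclusion_criteria"))
  claims <- as.data.table(pop$claims)
  tumors <- as.data.table(pop$tumors)
  patients <- as.data.table(pop$patients)
  enrollment <- as.data.table(pop$enrollment)
  attrition <- c(source_patients = nrow(patients))

  ## (a) claims-based lung cancer diagnosis in a qualifying year
  lc_set <- registry[["lung_cancer_dx"]]
  lc <- claims[match_code(code, system, lc_set)]
  lc <- lc[as.integer(format(service_date, "%Y")) %in%
             criteria$diagnosis_years]
  dxm <- lc[, .(claims_ym = min(date_ym_index(service_date))),
            by = patient_id]
  attrition["diagnosis_claim"] <- nrow(dxm)

  ## tumor linkage + closest-record selection
  tum <- tumors[dxm, on = "patient_id", nomatch = 0L]
  attrition["with_tumor_record"] <- uniqueN(tum$patient_id)
  tum[, tym := ym_index(diagnosis_month)]
  tum[, dist := abs(tym - claims_ym)]
  setorder(tum, patient_id, dist, tym, histology)
  sel <- tum[, .SD[1L], by = patient_id]
  sel[, gold_label := gold_label(histology, registry)]
  sel[, index_date := ym_first_day(ym_label(tym))]

  ## (b) age at index
  sel <- patients[, .(patient_id, birth_date, death_date)][
    sel, on = "patient_id"]
  sel[, age := age_at(birth_date, index_date)]
  sel <- sel[age >= criteria$min_age]
  if (!is.null(criteria$max_age)) sel <- sel[age <= criteria$max_age]
  attrition["age_eligible"] <- nrow(sel)

  ## (c) continuous enrollment lookback (month-level A & B & D & !HMO)
  enr_ok <- enrollment[part_a & part_b & part_d & !hmo,
                       .(patient_id, eym = ym_index(month))]
  if (criteria$lookback_months > 0L) {
    look <- enr_ok[sel[, .(patient_id, iym = tym)], on = "patient_id",
                   nomatch = 0L]
    covered <- look[eym >= iym - criteria$lookback_months & eym < iym,
                    .(n_cov = uniqueN(eym)), by = patient_id]
    keep <- covered[n_cov == criteria$lookback_months, patient_id]
    sel <- sel[patient_id %in% keep]
  }
  attrition["lookback_eligible"] <- nrow(sel)

  ## observation end + censor reason
  fup <- criteria$followup_days
  # first month from the index month onward without full coverage, scanned
  # far enough to cover the whole follow-up window
  horizon <- fup %/% 28L + 1L
  all_post <- sel[, .(eym = tym + 0:horizon), by = patient_id]
  gaps <- all_post[!enr_ok, on = c("patient_id", "eym")]
  first_gap <- gaps[, .(gap_ym = min(eym)), by = patient_id]
  sel <- first_gap[sel, on = "patient_id"]
  sel[, window_end := index_date + fup]
  sel[, disenroll_date := as.Date(NA)]
  sel[!is.na(gap_ym), disenroll_date := ym_first_day(ym_label(gap_ym))]
  sel[, observation_end := pmin(window_end,
                                fifelse(is.na(death_date), window_end,
                                        death_date),
                                fifelse(is.na(disenroll_date), window_end,
                                        disenroll_date))]
  sel[, censor_reason := fcase(
    !is.na(death_date) & observation_end == death_date &
      observation_end < window_end, "death",
    !is.na(disenroll_date) & observation_end == disenroll_date &
      observation_end < window_end, "disenrollment",
    default = "window_end"
  )]

  ## treated: >=1 outpatient systemic-therapy claim in [index, index + fup)
  therapy <- names(registry)[vapply(registry, `[[`, TRUE, "therapy")]
  ther_cl <- claims[setting == "outpatient"][
    sel[, .(patient_id, index_date)], on = "patient_id", nomatch = 0L]
  ther_cl[, offset := as.integer(service_date - index_date)]
  ther_cl <- ther_cl[offset >= 0L & offset < fup]
  hit <- rep(FALSE, nrow(ther_cl))
  for (s in therapy) {
    hit <- hit | match_code(ther_cl$code, ther_cl$system, registry[[s]])
  }
  treated_ids <- unique(ther_cl$patient_id[hit])
  sel[, treated := patient_id %in% treated_ids]

  out <- sel[, .(patient_id, index_date, gold_label, age, observation_end,
                 censor_reason, treated)]
  setorder(out, patient_id)
  attrition["final"] <- nrow(out)
  setattr(out, "attrition", attrition)
  setattr(out, "class", c("lc_cohort", class(out)))
  out[]
}

#' Attrition counts recorded during cohort construction
#'
#' @param cohort An `lc_cohort` from [build_cohort()].
#' @return Named integer vector: source patients, patients with a
#'   qualifying diagnosis claim, with a linkable tumor record, age-eligible,
#'   lookback-eligible, final.
#' @export
attrition <- function(cohort) {
  attr(cohort, "attrition")
}

#' Split a cohort into exploration and validation samples
#'
#' Exact-size random partition: the exploration sample has
#' `round(fraction * N)` members; the remainder form the validation sample.
#' Deterministic under `seed`.
#'
#' @param cohort A data.frame of cohort members.
#' @param fraction Exploration fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return The cohort with an added `split` column
#'   (`"exploration"` / `"validation"`).
#' @export
split_sample <- function(cohort, fraction = 0.25, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(cohort)
  n_expl <- as.integer(round(fraction * n))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_expl)
  out <- as.data.table(cohort)
  out[, split := "validation"]
  if (n_expl > 0L) out[idx, split := "exploration"]
  out[]
}
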