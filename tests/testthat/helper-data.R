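# Shared fixtures. Generated populations are cached per (n, seed) so the
# study-scale tables are built once per test run; micro_population() is a
# hand-built six-patient linkage exercising each inclusion predicate.
# Fixture seed convention: 20160101 (start of the diagnosis window).

pop_cache <- new.env(parent = emptyenv())

cached_population <- function(n = 31912L, seed = 20160101L) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(pop_cache[[key]])) {
    pop_cache[[key]] <- generate_population(
      default_config(n_patients = n, seed = seed)
    )
  }
  pop_cache[[key]]
}

# enrollment rows for months ym0-12 .. ym0+6 with optional coverage defects
enr_span <- function(pid, ym0, drop_offsets = integer(), drop_col = "part_d") {
  off <- -12:6
  out <- data.frame(
    patient_id = pid, month = sclcpheno:::ym_label(ym0 + off),
    part_a = TRUE, part_b = TRUE, part_d = TRUE, hmo = FALSE
  )
  out[[drop_col]][match(drop_offsets, off)] <- FALSE
  out
}

micro_population <- function() {
  ym <- sclcpheno:::ym_index("2016-03")   # index month for most patients
  idx <- as.Date("2016-03-01")

  patients <- data.frame(
    patient_id = paste0("M", 1:7),
    birth_date = as.Date(c(
      "1950-06-15",  # M1: 65 at 2016-03-01 -> age-excluded
      "1946-01-10",  # M2: 70, lookback gap -> excluded
      "1946-01-10",  # M3: 70, dies at index+90
      "1946-01-10",  # M4: 70, SCLC, treated
      "1946-01-10",  # M5: diagnosis claim outside 2016-2017
      "1946-01-10",  # M6: coverage gap after index -> disenrollment censor
      "1946-01-10"   # M7: duplicate tumor records, tie-broken to 2016-02
    )),
    death_date = as.Date(c(NA, NA, "2016-05-30", NA, NA, NA, NA)),
    sex = "F", race = "White"
  )

  tumors <- data.frame(
    patient_id = c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M7"),
    diagnosis_month = c("2016-03", "2016-03", "2016-03", "2016-03",
                        "2015-06", "2016-03", "2016-02", "2016-04"),
    histology = c("8140", "8140", "8140", "8041", "8140", "8140",
                  "8041", "8140"),
    stage = "distant"
  )

  enrollment <- rbind(
    enr_span("M1", ym),
    enr_span("M2", ym, drop_offsets = -3L),            # missing Part D
    enr_span("M3", ym),
    enr_span("M4", ym),
    enr_span("M5", sclcpheno:::ym_index("2015-06")),
    enr_span("M6", ym, drop_offsets = 2L),             # gap at index+2 months
    enr_span("M7", sclcpheno:::ym_index("2016-02"))
  )

  dx <- function(pid, date) {
    data.frame(patient_id = pid, service_date = as.Date(date),
               code = "C34.90", system = "ICD10CM_DX", setting = "outpatient")
  }
  claims <- rbind(
    dx("M1", "2016-03-05"), dx("M2", "2016-03-05"), dx("M3", "2016-03-05"),
    dx("M4", "2016-03-05"), dx("M5", "2015-06-05"), dx("M6", "2016-03-05"),
    dx("M7", "2016-03-05"),
    data.frame(patient_id = "M4", service_date = idx + 10, code = "J9181",
               system = "HCPCS_CPT", setting = "outpatient")
  )

  structure(
    list(patients = patients, tumors = tumors, enrollment = enrollment,
         claims = claims, config = NULL),
    class = "synthetic_population"
  )
}

# minimal single-patient cohort + claims for window tests
one_member_cohort <- function(index = as.Date("2016-03-01")) {
  data.frame(patient_id = "W1", index_date = index, gold_label = "SCLC",
             age = 70L, observation_end = index + 180, treated = TRUE)
}

claim_at <- function(offset, code = "J9181", system = "HCPCS_CPT",
                     setting = "outpatient", index = as.Date("2016-03-01")) {
  data.frame(patient_id = "W1", service_date = index + offset, code = code,
             system = system, setting = setting)
}
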