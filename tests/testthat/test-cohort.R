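test_that("the index date is the first day of the diagnosis month", {
  expect_identical(derive_index_date("2016-03"), as.Date("2016-03-01"))
  expect_identical(derive_index_date("2017-12"), as.Date("2017-12-01"))
  expect_identical(derive_index_date("2016-02"), as.Date("2016-02-01"))
  expect_identical(derive_index_date(as.Date("2016-03-17")),
                   as.Date("2016-03-01"))
})

test_that("the gold label is membership in the small cell histology set", {
  expect_identical(gold_label(c("8041", "8140", "8045", "8002", "8070")),
                   c("SCLC", "NSCLC", "SCLC", "SCLC", "NSCLC"))
})

test_that("tumor selection takes the record closest to the claims month", {
  one <- data.frame(diagnosis_month = "2016-05", histology = "8140")
  expect_identical(select_tumor_record(one, "2017-01"), one)

  two <- data.frame(diagnosis_month = c("2016-02", "2017-01"),
                    histology = c("8041", "8140"))
  expect_identical(select_tumor_record(two, "2016-03")$diagnosis_month,
                   "2016-02")

  # equidistant records break to the earlier month
  tie <- data.frame(diagnosis_month = c("2016-04", "2016-02"),
                    histology = c("8140", "8041"))
  expect_identical(select_tumor_record(tie, "2016-03")$diagnosis_month,
                   "2016-02")

  # same month breaks to the smaller histology code
  same <- data.frame(diagnosis_month = c("2016-03", "2016-03"),
                     histology = c("8140", "8041"))
  expect_identical(select_tumor_record(same, "2016-03")$histology, "8041")

  expect_error(select_tumor_record(one[0, ], "2016-03"), "no tumor records")
})

test_that("inclusion predicates and censoring behave on the micro linkage", {
  pop <- micro_population()
  co <- build_cohort(pop)

  # M1 (age 65), M2 (Part D gap in lookback), M5 (claim outside 2016-2017)
  expect_setequal(co$patient_id, c("M3", "M4", "M6", "M7"))

  att <- attrition(co)
  expect_identical(unname(att["source_patients"]), 7L)
  expect_identical(unname(att["diagnosis_claim"]), 6L)   # M5 drops here
  expect_identical(unname(att["age_eligible"]), 5L)      # M1 drops here
  expect_identical(unname(att["lookback_eligible"]), 4L) # M2 drops here

  # death censoring at index + 90
  m3 <- co[co$patient_id == "M3", ]
  expect_identical(m3$observation_end, as.Date("2016-05-30"))
  expect_identical(m3$censor_reason, "death")

  # full window, treated via the etoposide claim, SCLC gold label
  m4 <- co[co$patient_id == "M4", ]
  expect_identical(m4$observation_end, as.Date("2016-03-01") + 180)
  expect_identical(m4$censor_reason, "window_end")
  expect_true(m4$treated)
  expect_identical(m4$gold_label, "SCLC")
  expect_identical(m4$age, 70L)
  expect_false(co[co$patient_id == "M3", ]$treated)

  # coverage gap two months after index censors at that month's start
  m6 <- co[co$patient_id == "M6", ]
  expect_identical(m6$observation_end, as.Date("2016-05-01"))
  expect_identical(m6$censor_reason, "disenrollment")

  # duplicate tumor records tie-break to the earlier month -> SCLC record
  m7 <- co[co$patient_id == "M7", ]
  expect_identical(m7$index_date, as.Date("2016-02-01"))
  expect_identical(m7$gold_label, "SCLC")
})

test_that("repairing an enrollment gap never shortens observation", {
  pop <- micro_population()
  co1 <- build_cohort(pop)
  pop$enrollment$part_d <- TRUE  # lengthen everyone's clean coverage
  co2 <- build_cohort(pop)
  shared <- intersect(co1$patient_id, co2$patient_id)
  o1 <- co1$observation_end[match(shared, co1$patient_id)]
  o2 <- co2$observation_end[match(shared, co2$patient_id)]
  expect_true(all(o2 >= o1))
  expect_true("M2" %in% co2$patient_id)  # gap repair admits M2
})

test_that("cohort membership agrees with an independent patient-by-patient check", {
  cfg <- default_config(n_patients = 1500L, seed = 20160101L)
  cfg$lookback_dropout_prob <- 0.3   # exercise the lookback predicate hard
  pop <- generate_population(cfg)
  co <- build_cohort(pop)
  crit <- inclusion_criteria()
  reg <- builtin_registry()

  claims <- pop$claims
  lc <- claims[match_code(claims$code, claims$system, reg$lung_cancer_dx) &
                 as.integer(format(claims$service_date, "%Y")) %in%
                   crit$diagnosis_years, ]
  eligible <- character()
  for (pid in pop$patients$patient_id) {
    pcl <- lc[lc$patient_id == pid, ]
    if (nrow(pcl) == 0L) next
    claims_month <- format(min(pcl$service_date), "%Y-%m")
    tum <- pop$tumors[pop$tumors$patient_id == pid, ]
    if (nrow(tum) == 0L) next
    d <- abs(sclcpheno:::ym_index(tum$diagnosis_month) -
               sclcpheno:::ym_index(claims_month))
    pick <- tum[order(d, tum$diagnosis_month, tum$histology)[1L], ]
    index <- as.Date(paste0(pick$diagnosis_month, "-01"))
    birth <- pop$patients$birth_date[pop$patients$patient_id == pid]
    age <- length(seq(birth, index, by = "year")) - 1L
    if (age < crit$min_age) next
    enr <- pop$enrollment[pop$enrollment$patient_id == pid &
                            pop$enrollment$part_a & pop$enrollment$part_b &
                            pop$enrollment$part_d & !pop$enrollment$hmo, ]
    iym <- sclcpheno:::ym_index(format(index, "%Y-%m"))
    need <- sclcpheno:::ym_label(seq(iym - 12L, iym - 1L))
    if (!all(need %in% enr$month)) next
    eligible <- c(eligible, pid)
  }
  expect_setequal(co$patient_id, eligible)

  # label conservation: cohort SCLC count equals SCLC histology among members
  expect_identical(sum(co$gold_label == "SCLC"),
                   sum(gold_label(pop$tumors$histology)[
                     match(co$patient_id, pop$tumors$patient_id)] == "SCLC"))
})

test_that("the exploration split is an exact-size deterministic partition", {
  dummy <- data.frame(patient_id = sprintf("D%05d", 1:31912))
  sp <- split_sample(dummy, 0.25, seed = 20160101L)
  expect_identical(sum(sp$split == "exploration"), 7978L)
  expect_identical(sum(sp$split == "validation"), 23934L)

  tiny <- split_sample(data.frame(patient_id = letters[1:4]), 0.25, seed = 1L)
  expect_identical(sum(tiny$split == "exploration"), 1L)
  expect_identical(sum(tiny$split == "validation"), 3L)

  again <- split_sample(dummy, 0.25, seed = 20160101L)
  expect_identical(sp$split, again$split)
  other <- split_sample(dummy, 0.25, seed = 99L)
  expect_false(identical(sp$split, other$split))

  # partition: disjoint and exhaustive
  expect_identical(nrow(sp), 31912L)
  expect_true(all(sp$split %in% c("exploration", "validation")))
})
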