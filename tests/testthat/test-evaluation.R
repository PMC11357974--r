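test_that("confusion matrices tabulate with SCLC as the positive class", {
  gold <- c(rep("SCLC", 10), rep("NSCLC", 90))
  cm <- confusion_matrix(gold, gold)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(10L, 0L, 90L, 0L))

  cm <- confusion_matrix(rep("NSCLC", 100), gold)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(0L, 0L, 90L, 10L))

  pred <- setNames(gold, paste0("p", 1:100))
  expect_error(confusion_matrix(pred, setNames(gold, paste0("q", 1:100))),
               "different patient sets")
  # named vectors align by patient, not by position
  shuffled <- sample(pred)
  expect_identical(confusion_matrix(shuffled, pred)$fp, 0L)
})

test_that("metric identities hold against a count-by-iteration oracle", {
  set.seed(20160101)
  for (i in 1:20) {
    n <- 200L
    gold <- sample(c("SCLC", "NSCLC"), n, TRUE, prob = c(0.2, 0.8))
    pred <- ifelse(runif(n) < 0.8, gold, sample(c("SCLC", "NSCLC"), n, TRUE))
    cm <- confusion_matrix(pred, gold)
    # brute-force loop oracle
    tp <- fp <- tn <- fn <- 0L
    for (j in seq_len(n)) {
      if (pred[j] == "SCLC" && gold[j] == "SCLC") tp <- tp + 1L
      if (pred[j] == "SCLC" && gold[j] == "NSCLC") fp <- fp + 1L
      if (pred[j] == "NSCLC" && gold[j] == "NSCLC") tn <- tn + 1L
      if (pred[j] == "NSCLC" && gold[j] == "SCLC") fn <- fn + 1L
    }
    expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(tp, fp, tn, fn))
    expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, n)
    m <- compute_metrics(cm)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$ppv, tp / (tp + fp))
    expect_equal(m$npv, tn / (tn + fn))
  }
})

test_that("undefined metrics are carried as NA, never zero", {
  m <- compute_metrics(as_confusion_matrix(0, 0, 100, 0))
  expect_identical(m$specificity, 1)
  expect_identical(m$npv, 1)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$case_ratio))
})

test_that("display rounding is half-up on the exact count ratio", {
  # 92/320 = 0.2875 sits exactly on the boundary and must round up
  expect_equal(unname(rounded_metrics(
    as_confusion_matrix(92, 228, 7025, 633))["ppv"]), 0.288)
  expect_equal(unname(rounded_metrics(
    as_confusion_matrix(1251, 280, 21379, 1024))),
    c(0.550, 0.987, 0.817, 0.954))
})

test_that("case ratios display at one decimal of the exact ratio", {
  expect_identical(case_ratio(as_confusion_matrix(1251, 280, 21379, 1024)),
                   4.5)
  expect_identical(case_ratio(as_confusion_matrix(100, 100, 0, 0)), 1.0)
  expect_identical(case_ratio(as_confusion_matrix(1236, 237, 21422, 1039)),
                   5.2)
  expect_true(is.na(case_ratio(as_confusion_matrix(5, 0, 10, 1))))
})

test_that("re-targeting at NSCLC swaps the metric pairs", {
  m <- compute_metrics(as_confusion_matrix(431, 116, 2005, 16))
  inv <- invert_metrics(m)
  expect_equal(inv$sensitivity, m$specificity)
  expect_equal(inv$specificity, m$sensitivity)
  expect_equal(inv$ppv, m$npv)
  expect_equal(inv$npv, m$ppv)
})

test_that("NR masking suppresses small cells and their margin complements", {
  r <- apply_nr_masking(as_confusion_matrix(8, 3, 7000, 700))
  expect_identical(unname(r$counts[c("tp", "fp", "fn")]),
                   c("NR", "NR", "NR"))
  expect_identical(unname(r$counts["tn"]), "NR")  # fp's margin complement
  expect_identical(unname(r$metrics["sensitivity"]), "< 0.02")  # 11/708 up

  r <- apply_nr_masking(as_confusion_matrix(50, 50, 50, 50))
  expect_false(any(r$masked))
  expect_identical(unname(r$counts), c("50", "50", "50", "50"))
  expect_identical(unname(r$metrics["sensitivity"]), "0.500")

  # zero is below the threshold
  r <- apply_nr_masking(as_confusion_matrix(0, 0, 100, 0))
  expect_identical(unname(r$counts[c("tp", "fp", "fn")]),
                   c("NR", "NR", "NR"))

  # masking a low FN drags TP with it (SCLC margin is public)
  r <- apply_nr_masking(as_confusion_matrix(438, 8, 2001, 9))
  expect_true(all(r$masked[c("tp", "fn")]))
})

test_that("masked rare-agent rows reproduce the published bound pattern", {
  # a rare immunotherapy rule: TP 5, FP 2 against margins 725 / 7,253
  r <- apply_nr_masking(as_confusion_matrix(5, 2, 7251, 720))
  expect_identical(unname(r$counts), c("NR", "NR", "NR", "NR"))
  expect_identical(unname(r$metrics["sensitivity"]), "< 0.02")
  expect_identical(unname(r$metrics["specificity"]), "> 0.99")
  # predictive values remain displayed as computed
  expect_identical(unname(r$metrics["ppv"]), "0.714")
  expect_identical(unname(r$metrics["npv"]), "0.910")
})

test_that("no displayed integer combination recovers a masked cell", {
  # oracle: enumerate every cell assignment consistent with the displayed
  # integers and the public margins; a masked cell must not be pinned to a
  # single feasible value
  feasible_values <- function(cm, rep_) {
    vals <- list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
    out <- list()
    for (pair in list(c("tp", "fn"), c("fp", "tn"))) {
      a <- pair[1L]; b <- pair[2L]
      M <- vals[[a]] + vals[[b]]
      if (!rep_$masked[[a]]) next
      # candidate splits of the public margin that the masking rule would
      # display identically (both cells NR)
      cand <- Filter(function(t) t < rep_$threshold ||
                       (M - t) < rep_$threshold, 0:M)
      out[[a]] <- cand
      out[[b]] <- M - cand
    }
    out
  }
  set.seed(20160101)
  leaks <- 0L
  for (i in 1:1000) {
    tp <- sample(0:40, 1L); fn <- sample(0:40, 1L)
    fp <- sample(0:40, 1L); tn <- sample(0:5000, 1L)
    if (tp + fn == 0L) fn <- 1L     # a cohort stratum with no members of a
    if (fp + tn == 0L) tn <- 1L     # class is out of scope for masking
    cm <- as_confusion_matrix(tp, fp, tn, fn)
    rep_ <- apply_nr_masking(cm)
    fv <- feasible_values(cm, rep_)
    for (cell in names(fv)) {
      if (length(unique(fv[[cell]])) == 1L) leaks <- leaks + 1L
    }
    # displayed cells must be truthful
    shown <- !rep_$masked
    cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    expect_identical(unname(rep_$counts[shown]),
                     unname(as.character(cnt[shown])))
  }
  expect_identical(leaks, 0L)
})

test_that("lower prevalence raises NPV and lowers PPV at fixed accuracy", {
  sens <- 0.9; spec <- 0.95; n <- 10000L
  ms <- lapply(c(0.30, 0.10, 0.05, 0.01), function(prev) {
    pos <- round(n * prev); neg <- n - pos
    compute_metrics(as_confusion_matrix(
      tp = round(sens * pos), fn = pos - round(sens * pos),
      tn = round(spec * neg), fp = neg - round(spec * neg)
    ))
  })
  ppv <- vapply(ms, `[[`, 0, "ppv")
  npv <- vapply(ms, `[[`, 0, "npv")
  expect_true(all(diff(ppv) < 0))
  expect_true(all(diff(npv) > 0))
})

test_that("rule evaluation tables conserve counts and share TP/FP across populations", {
  pop <- cached_population(10000L)
  co <- build_cohort(pop)
  fl <- build_utilization(co, pop$claims)
  res <- evaluate_rules(builtin_rules(), co, fl)
  expect_identical(nrow(res), 28L)
  expect_true(all(res$tp + res$fp + res$tn + res$fn == res$n))
  wide <- data.table::dcast(res, algorithm ~ population,
                            value.var = c("tp", "fp", "ppv"))
  expect_identical(wide$tp_full, wide$tp_treated)
  expect_identical(wide$fp_full, wide$fp_treated)
  expect_equal(wide$ppv_full, wide$ppv_treated)

  expect_identical(nrow(evaluate_rules(list(), co, fl)), 0L)

  disp <- render_results(res[1:4, ])
  expect_identical(names(disp),
                   c("Algorithm", "Population", "True Positive",
                     "False Positive", "True Negative", "False Negative",
                     "Sensitivity", "Specificity", "PPV", "NPV"))
  expect_true(all(vapply(disp, is.character, TRUE)))
})
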