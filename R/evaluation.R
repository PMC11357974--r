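#' Confusion matrix with SCLC as the positive class
#'
#' `confusion_matrix()` cross-tabulates predicted against gold labels;
#' `as_confusion_matrix()` wraps four printed counts (e.g. from a published
#' table). If both vectors are named, they must cover the same patients and
#' are aligned by name.
#'
#' @param pred,gold Character vectors of `"SCLC"` / `"NSCLC"`.
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_matrix <- function(pred, gold) {
  if (!is.null(names(pred)) && !is.null(names(gold))) {
    if (!setequal(names(pred), names(gold))) {
      stop("predictions and gold labels cover different patient sets",
           call. = FALSE)
    }
    gold <- gold[names(pred)]
  } else if (length(pred) != length(gold)) {
    stop("predictions and gold labels differ in length", call. = FALSE)
  }
  stopifnot(all(pred %in% c("SCLC", "NSCLC")),
            all(gold %in% c("SCLC", "NSCLC")))
  as_confusion_matrix(
    tp = sum(pred == "SCLC" & gold == "SCLC"),
    fp = sum(pred == "SCLC" & gold == "NSCLC"),
    tn = sum(pred == "NSCLC" & gold == "NSCLC"),
    fn = sum(pred == "NSCLC" & gold == "SCLC")
  )
}

#' @rdname confusion_matrix
#' @export
as_confusion_matrix <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
  structure(as.list(as.integer(cnt)) |> setNames(names(cnt)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  TN %d  FN %d  (N = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Diagnostic-accuracy metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`, and the case
#' ratio `tp/fp` (how many true SCLC patients the rule captures per NSCLC
#' patient it drags along). A metric is `NA` iff its denominator is zero;
#' values are exact ratios, rounded only at display time.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `metric_set` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `case_ratio`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(sensitivity = safe(cm$tp, cm$tp + cm$fn),
         specificity = safe(cm$tn, cm$tn + cm$fp),
         ppv = safe(cm$tp, cm$tp + cm$fp),
         npv = safe(cm$tn, cm$tn + cm$fn),
         case_ratio = safe(cm$tp, cm$fp),
         cm = cm),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.3f", v)
  cat(sprintf(
    "<metric_set> sens %s  spec %s  ppv %s  npv %s  tp/fp %s\n",
    fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
    if (is.na(x$case_ratio)) "--" else sprintf("%.1f", x$case_ratio)))
  invisible(x)
}

#' Display-rounded metrics from a confusion matrix
#'
#' Metrics rounded half-up to `digits` decimals, computed in exact integer
#' arithmetic on the counts (IEEE rounding of e.g. 92/320 = 0.2875 would
#' otherwise go the wrong way).
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimal places (default 3, the table display convention).
#' @return Named numeric vector (`sensitivity`, `specificity`, `ppv`,
#'   `npv`), `NA` where undefined.
#' @export
rounded_metrics <- function(cm, digits = 3L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  c(sensitivity = ratio_round_half_up(cm$tp, cm$tp + cm$fn, digits),
    specificity = ratio_round_half_up(cm$tn, cm$tn + cm$fp, digits),
    ppv = ratio_round_half_up(cm$tp, cm$tp + cm$fp, digits),
    npv = ratio_round_half_up(cm$tn, cm$tn + cm$fn, digits))
}

#' Case-mix ratio
#'
#' True positives per false positive, rounded half-up to one decimal for
#' display: the number of SCLC patients a treatment-based rule identifies
#' for each NSCLC patient it misclassifies.
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimal places for display rounding (default 1).
#' @return Numeric scalar; `NA` when `fp` is zero.
#' @export
case_ratio <- function(cm, digits = 1L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$fp == 0L) return(NA_real_)
  ratio_round_half_up(cm$tp, cm$fp, digits)
}

#' Re-target the metrics at NSCLC
#'
#' Display transform for reading the same confusion matrix with NSCLC as
#' the positive class: sensitivity and specificity swap, as do PPV and NPV.
#'
#' @param m A `metric_set`.
#' @return A `metric_set` describing the NSCLC-positive reading.
#' @export
invert_metrics <- function(m) {
  stopifnot(inherits(m, "metric_set"))
  cm <- m$cm
  compute_metrics(as_confusion_matrix(tp = cm$tn, fp = cm$fn,
                                      tn = cm$tp, fn = cm$fp))
}

#' Apply small-cell (NR) masking to a confusion matrix report
#'
#' Privacy masking in the style of registry-linked data reporting: any cell
#' below `threshold` is replaced by `"NR"` (not reportable), and because the
#' per-label margins (gold SCLC and NSCLC totals) are considered public, the
#' complement cell within the same margin is suppressed too — otherwise the
#' masked cell could be recovered by subtraction. When `tp` is below the
#' threshold, sensitivity is shown as an upper bound `"< b"` with
#' `b = threshold/(tp+fn)` rounded up to 2 decimals; when `fp` is below the
#' threshold, specificity is shown as a lower bound `"> b"` with
#' `b = 1 - threshold/(fp+tn)` rounded down. PPV and NPV are displayed as
#' computed (3 decimals), matching the published convention. The bound
#' formulae are an interpretation reconstructed from the published masked
#' rows; they reproduce the printed bound patterns.
#'
#' @param cm A `confusion_matrix`.
#' @param metrics Optional precomputed [compute_metrics()] result.
#' @param threshold Minimum reportable cell count (default 11).
#' @return An object of class `masked_report`: list with `counts` and
#'   `metrics` (display strings), `masked` (logical per cell) and
#'   `threshold`.
#' @export
apply_nr_masking <- function(cm, metrics = compute_metrics(cm),
                             threshold = 11L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cnt <- c(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
  below <- cnt < threshold
  masked <- below
  # complementary suppression within the public gold-label margins
  if (masked[["tp"]] || masked[["fn"]]) masked[c("tp", "fn")] <- TRUE
  if (masked[["fp"]] || masked[["tn"]]) masked[c("fp", "tn")] <- TRUE

  counts <- ifelse(masked, "NR", as.character(cnt))

  fmt3 <- function(num, den) {
    if (den == 0) "" else sprintf("%.3f", ratio_round_half_up(num, den, 3L))
  }
  sens <- if (below[["tp"]]) {
    den <- cm$tp + cm$fn
    if (den == 0) "" else sprintf("< %.2f", ratio_ceiling(threshold, den, 2L))
  } else {
    fmt3(cm$tp, cm$tp + cm$fn)
  }
  spec <- if (below[["fp"]]) {
    den <- cm$fp + cm$tn
    if (den == 0) "" else {
      sprintf("> %.2f", max(0, ratio_floor(den - threshold, den, 2L)))
    }
  } else {
    fmt3(cm$tn, cm$tn + cm$fp)
  }
  structure(
    list(counts = counts,
         metrics = c(sensitivity = sens, specificity = spec,
                     ppv = fmt3(cm$tp, cm$tp + cm$fp),
                     npv = fmt3(cm$tn, cm$tn + cm$fn)),
         masked = masked, threshold = as.integer(threshold)),
    class = "masked_report"
  )
}

#' @export
print.masked_report <- function(x, ...) {
  cat(sprintf(
    "<masked_report> TP %s  FP %s  TN %s  FN %s | sens %s  spec %s  ppv %s  npv %s\n",
    x$counts[["tp"]], x$counts[["fp"]], x$counts[["tn"]], x$counts[["fn"]],
    x$metrics[["sensitivity"]], x$metrics[["specificity"]],
    x$metrics[["ppv"]], x$metrics[["npv"]]))
  invisible(x)
}

#' Evaluate classification rules against the gold standard
#'
#' Applies each rule to the exposure flags and tabulates accuracy in the
#' requested populations: `full` (all cohort members passed in) and
#' `treated` (the systemic-therapy subset). Because the built-in rules
#' depend only on treatment-window exposures — and every exposure that can
#' fire a rule also places the patient in the treated subset under the
#' generator's design — true and false positives coincide between the two
#' populations, so PPV is identical while sensitivity, specificity and NPV
#' shift with the denominator.
#'
#' @param rules List of `phenotype_rule` objects (e.g. [builtin_rules()]).
#' @param cohort An `lc_cohort` (or any data.frame with `patient_id`,
#'   `gold_label`, `treated`).
#' @param flags Exposure flags from [build_utilization()] covering the
#'   cohort's patients.
#' @param populations Subset of `c("full", "treated")`.
#' @return `data.table` with one row per (rule, population): `n`, `tp`,
#'   `fp`, `tn`, `fn` and exact `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
evaluate_rules <- function(rules, cohort, flags,
                           populations = c("full", "treated")) {
  populations <- match.arg(populations, several.ok = TRUE)
  if (inherits(rules, "phenotype_rule")) rules <- list(rules)
  co <- as.data.table(cohort)
  stopifnot(all(co$patient_id %in% rownames(flags)))
  out <- vector("list", length(rules) * length(populations))
  k <- 0L
  for (rule in rules) {
    pred_all <- apply_rule(rule, flags)
    for (popn in populations) {
      idx <- if (popn == "treated") which(co$treated) else seq_len(nrow(co))
      ids <- co$patient_id[idx]
      cm <- confusion_matrix(pred_all[ids],
                             setNames(co$gold_label[idx], ids))
      m <- compute_metrics(cm)
      k <- k + 1L
      out[[k]] <- data.table(
        algorithm = rule$name, population = popn, n = length(ids),
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, npv = m$npv
      )
    }
  }
  rbindlist(out)[]
}

#' Render an evaluation table with NR masking
#'
#' Formats the output of [evaluate_rules()] the way the published tables
#' are laid out, applying [apply_nr_masking()] row by row.
#'
#' @param results Output of [evaluate_rules()].
#' @param mask Apply NR masking (default `TRUE`)?
#' @param threshold Minimum reportable count.
#' @return `data.frame` with columns `Algorithm`, `Population`,
#'   `True Positive`, `False Positive`, `True Negative`, `False Negative`,
#'   `Sensitivity`, `Specificity`, `PPV`, `NPV` (all character).
#' @export
render_results <- function(results, mask = TRUE, threshold = 11L) {
  rows <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    cm <- as_confusion_matrix(r$tp, r$fp, r$tn, r$fn)
    if (mask) {
      mr <- apply_nr_masking(cm, threshold = threshold)
      cnts <- mr$counts
      mets <- mr$metrics
    } else {
      cnts <- c(tp = as.character(r$tp), fp = as.character(r$fp),
                tn = as.character(r$tn), fn = as.character(r$fn))
      rm3 <- rounded_metrics(cm)
      mets <- ifelse(is.na(rm3), "", sprintf("%.3f", rm3))
      names(mets) <- names(rm3)
    }
    data.frame(
      Algorithm = r$algorithm, Population = r$population,
      `True Positive` = cnts[["tp"]], `False Positive` = cnts[["fp"]],
      `True Negative` = cnts[["tn"]], `False Negative` = cnts[["fn"]],
      Sensitivity = mets[["sensitivity"]], Specificity = mets[["specificity"]],
      PPV = mets[["ppv"]], NPV = mets[["npv"]],
      check.names = FALSE
    )
  })
  do.call(rbind, rows)
}
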