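#' Exploration-phase screening thresholds
#'
#' The code-discovery procedure keeps a code as a candidate discriminator
#' when the absolute difference between the SCLC and NSCLC utilization
#' proportions is at least 20 percentage points (non-strict), as a potential
#' false-positive reducer when used by strictly less than 5% of SCLC and
#' strictly more than 10% of NSCLC patients, and as a potential
#' false-negative reducer when used by strictly more than 20% of SCLC and
#' strictly less than 5% of NSCLC patients.
#'
#' @param candidate_diff Minimum absolute proportion difference (default
#'   0.20, inclusive).
#' @param fp_sclc_max,fp_nsclc_min False-positive-reducer bounds (strict).
#' @param fn_sclc_min,fn_nsclc_max False-negative-reducer bounds (strict).
#' @return An object of class `screening_thresholds`.
#' @export
screening_thresholds <- function(candidate_diff = 0.20,
                                 fp_sclc_max = 0.05, fp_nsclc_min = 0.10,
                                 fn_sclc_min = 0.20, fn_nsclc_max = 0.05) {
  vals <- c(candidate_diff, fp_sclc_max, fp_nsclc_min, fn_sclc_min,
            fn_nsclc_max)
  stopifnot(all(vals >= 0 & vals <= 1))
  structure(
    list(candidate_diff = candidate_diff, fp_sclc_max = fp_sclc_max,
         fp_nsclc_min = fp_nsclc_min, fn_sclc_min = fn_sclc_min,
         fn_nsclc_max = fn_nsclc_max),
    class = "screening_thresholds"
  )
}

#' Per-code utilization by gold label
#'
#' One row per distinct (code, system) occurring in any in-window claim of a
#' cohort member, with the proportion of SCLC and of NSCLC members using the
#' code at least once. Denominators are all cohort members of the label
#' (members with no in-window claims still count); each patient counts once
#' per code. By default only HCPCS/CPT codes are screened, in all claim
#' settings.
#'
#' @param cohort An `lc_cohort` with `gold_label` and `index_date`.
#' @param claims Claims table.
#' @param window `"post180"` or `"pre30_post180"` (half-open, as in
#'   [build_utilization()]).
#' @param systems Coding systems to screen (default `"HCPCS_CPT"`).
#' @return `data.table` with columns `code`, `system`, `n_sclc_users`,
#'   `n_nsclc_users`, `p_sclc`, `p_nsclc`, `diff_pp`
#'   (`p_sclc - p_nsclc`).
#' @export
utilization_by_label <- function(cohort, claims,
                                 window = c("post180", "pre30_post180"),
                                 systems = "HCPCS_CPT") {
  window <- match.arg(window)
  lo <- if (window == "post180") 0L else -30L
  co <- as.data.table(cohort)
  n_sclc <- sum(co$gold_label == "SCLC")
  n_nsclc <- sum(co$gold_label == "NSCLC")
  cl <- as.data.table(claims)[system %in% systems][
    co[, .(patient_id, index_date, gold_label)],
    on = "patient_id", nomatch = 0L]
  empty <- data.table(code = character(), system = character(),
                      n_sclc_users = integer(), n_nsclc_users = integer(),
                      p_sclc = numeric(), p_nsclc = numeric(),
                      diff_pp = numeric())
  if (nrow(cl) == 0L) return(empty)
  cl[, offset := as.integer(service_date - index_date)]
  cl <- cl[offset >= lo & offset < 180L]
  if (nrow(cl) == 0L) return(empty)
  for (sys in unique(cl$system)) {
    cl[system == sys, code_n := normalize_code(code, sys)]
  }
  users <- unique(cl[, .(patient_id, code_n, system, gold_label)])
  out <- users[, .(
    n_sclc_users = sum(gold_label == "SCLC"),
    n_nsclc_users = sum(gold_label == "NSCLC")
  ), by = .(code = code_n, system)]
  out[, p_sclc := if (n_sclc > 0) n_sclc_users / n_sclc else 0]
  out[, p_nsclc := if (n_nsclc > 0) n_nsclc_users / n_nsclc else 0]
  out[, diff_pp := p_sclc - p_nsclc]
  setorder(out, -diff_pp, code)
  out[]
}

#' Screening filters
#'
#' `discover_candidates()` keeps codes whose absolute utilization difference
#' is at least the candidate threshold, sorted by descending
#' `p_sclc - p_nsclc`; `discover_fp_reducers()` keeps codes rare in SCLC but
#' common in NSCLC (useful for ruling out NSCLC patients misclassified as
#' SCLC); `discover_fn_reducers()` keeps codes common in SCLC but rare in
#' NSCLC. The candidate filter is non-strict (`>=`); both reducer filters
#' are strict, matching the published operationalisation.
#'
#' @param rows Output of [utilization_by_label()].
#' @param thresholds A [screening_thresholds()].
#' @return The retained subset of `rows` (same columns).
#' @name screening_filters
NULL

#' @rdname screening_filters
#' @export
discover_candidates <- function(rows, thresholds = screening_thresholds()) {
  # the 20-point threshold is inclusive; compare with a float tolerance so a
  # difference that is exactly 20 points in exact arithmetic (0.30 - 0.10)
  # is not lost to IEEE representation
  eps <- sqrt(.Machine$double.eps)
  out <- as.data.table(rows)[abs(p_sclc - p_nsclc) >=
                               thresholds$candidate_diff - eps]
  setorder(out, -diff_pp, code)
  out[]
}

#' @rdname screening_filters
#' @export
discover_fp_reducers <- function(rows, thresholds = screening_thresholds()) {
  as.data.table(rows)[p_sclc < thresholds$fp_sclc_max &
                        p_nsclc > thresholds$fp_nsclc_min][]
}

#' @rdname screening_filters
#' @export
discover_fn_reducers <- function(rows, thresholds = screening_thresholds()) {
  as.data.table(rows)[p_sclc > thresholds$fn_sclc_min &
                        p_nsclc < thresholds$fn_nsclc_max][]
}

#' Combined screening report
#'
#' @param rows Output of [utilization_by_label()].
#' @param thresholds A [screening_thresholds()].
#' @return `rows` with logical columns `candidate`, `fp_reducer`,
#'   `fn_reducer`.
#' @export
screening_report <- function(rows, thresholds = screening_thresholds()) {
  out <- as.data.table(rows)
  eps <- sqrt(.Machine$double.eps)
  out[, candidate := abs(p_sclc - p_nsclc) >= thresholds$candidate_diff - eps]
  out[, fp_reducer := p_sclc < thresholds$fp_sclc_max &
        p_nsclc > thresholds$fp_nsclc_min]
  out[, fn_reducer := p_sclc > thresholds$fn_sclc_min &
        p_nsclc < thresholds$fn_nsclc_max]
  out[]
}
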