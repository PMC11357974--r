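#' Boolean rule expressions over code-set exposures
#'
#' A classification rule is a boolean expression tree whose leaves name code
#' sets (evaluated as "any in-window exposure to that set") and whose
#' internal nodes are `AND` / `OR` (n-ary, n >= 2) or `NOT` (unary).
#' `rule_all()`, `rule_any()` and `rule_not()` build the nodes; leaves are
#' plain code-set name strings.
#'
#' @param ... Sub-expressions (leaves or nodes); at least two for
#'   `rule_all()` / `rule_any()`.
#' @param x A single sub-expression for `rule_not()`.
#' @return A `rule_expr` node.
#' @name rule_expr
NULL

rule_node <- function(op, args) {
  args <- lapply(args, as_rule_expr)
  if (op == "not" && length(args) != 1L) {
    stop("NOT takes exactly one argument", call. = FALSE)
  }
  if (op %in% c("and", "or") && length(args) < 2L) {
    stop(toupper(op), " takes at least two arguments", call. = FALSE)
  }
  structure(list(op = op, args = args), class = "rule_expr")
}

#' @rdname rule_expr
#' @export
rule_all <- function(...) rule_node("and", list(...))

#' @rdname rule_expr
#' @export
rule_any <- function(...) rule_node("or", list(...))

#' @rdname rule_expr
#' @export
rule_not <- function(x) rule_node("not", list(x))

#' Coerce nested lists to a rule expression
#'
#' Accepts the configuration form used in JSON/YAML rule files: a bare
#' string is a leaf; `list(and = list(...))`, `list(or = list(...))` and
#' `list(not = ...)` are operators, e.g.
#' `list(and = list("etoposide", list(not = "egfr_test")))`.
#'
#' @param x A string, `rule_expr`, or nested list.
#' @return A `rule_expr` or leaf string.
#' @export
as_rule_expr <- function(x) {
  if (inherits(x, "rule_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(x)
  if (is.list(x) && length(x) == 1L && !is.null(names(x))) {
    op <- tolower(names(x))
    args <- x[[1L]]
    if (op == "not") return(rule_node("not", list(args)))
    if (op %in% c("and", "or")) {
      if (!is.list(args)) args <- as.list(args)
      return(rule_node(op, args))
    }
  }
  stop("cannot interpret rule expression of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Parse a rule expression from JSON
#'
#' @param txt JSON text, e.g. `{"and": ["etoposide", {"not": "egfr_test"}]}`.
#' @return A `rule_expr`.
#' @export
rule_from_json <- function(txt) {
  as_rule_expr(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

#' Create a named classification rule
#'
#' @param name Rule identifier.
#' @param expr A rule expression ([as_rule_expr()] is applied).
#' @return An object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(name, expr) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, expr = as_rule_expr(expr)),
            class = "phenotype_rule")
}

deparse_expr <- function(e) {
  if (is.character(e)) return(e)
  if (e$op == "not") return(paste0("NOT(", deparse_expr(e$args[[1L]]), ")"))
  paste0(toupper(e$op), "(",
         paste(vapply(e$args, deparse_expr, ""), collapse = ", "), ")")
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat(sprintf("<phenotype_rule> %s: %s\n", x$name, deparse_expr(x$expr)))
  invisible(x)
}

#' Code-set names appearing as leaves of a rule
#'
#' @param x A `phenotype_rule` or rule expression.
#' @return Character vector of code-set names.
#' @export
rule_leaves <- function(x) {
  if (inherits(x, "phenotype_rule")) x <- x$expr
  if (is.character(x)) return(x)
  unique(unlist(lapply(x$args, rule_leaves)))
}

#' Built-in classification rules
#'
#' The candidate algorithms evaluated in the exploration phase: one rule per
#' systemic agent (carboplatin, cisplatin, etoposide, G-CSF, ipilimumab,
#' irinotecan, nivolumab, pegfilgrastim, topotecan, all platinum agents),
#' the disjunctions etoposide-or-pegfilgrastim, etoposide-or-G-CSF and
#' etoposide-or-irinotecan-or-topotecan, and the false-positive-reducing
#' conjunction etoposide-and-no-EGFR-testing. The final validated
#' algorithms are `etoposide` and `etoposide_no_egfr`.
#'
#' @return Named list of [phenotype_rule()] objects (14 rules).
#' @export
builtin_rules <- function() {
  singles <- c("carboplatin", "cisplatin", "etoposide", "gcsf", "ipilimumab",
               "irinotecan", "nivolumab", "pegfilgrastim", "topotecan",
               "platinum")
  rules <- lapply(singles, function(s) phenotype_rule(s, s))
  names(rules) <- singles
  rules$etoposide_or_pegfilgrastim <- phenotype_rule(
    "etoposide_or_pegfilgrastim", rule_any("etoposide", "pegfilgrastim"))
  rules$etoposide_or_gcsf <- phenotype_rule(
    "etoposide_or_gcsf", rule_any("etoposide", "gcsf"))
  rules$etoposide_or_irinotecan_or_topotecan <- phenotype_rule(
    "etoposide_or_irinotecan_or_topotecan",
    rule_any("etoposide", "irinotecan", "topotecan"))
  rules$etoposide_no_egfr <- phenotype_rule(
    "etoposide_no_egfr", rule_all("etoposide", rule_not("egfr_test")))
  rules
}

#' Build per-patient exposure flags in an observation window
#'
#' For every cohort member and code set, the flag is `TRUE` iff the patient
#' has at least one claim whose service date falls in the window (relative
#' to the member's index date), whose setting is among the set's configured
#' settings (`NULL` = all settings), and whose code matches the set.
#' Windows are half-open: `post180` is `[index, index + 180)` and
#' `pre30_post180` is `[index - 30, index + 180)`. Exposure capture is
#' anchored to the index date, not the censoring date: the window defines
#' the code search, while `observation_end` defines the cohort's follow-up.
#'
#' @param cohort An `lc_cohort` (needs `patient_id`, `index_date`).
#' @param claims Claims table.
#' @param registry A `codeset_registry`.
#' @param window `"post180"` or `"pre30_post180"`.
#' @param codesets Code-set names to flag; defaults to every HCPCS/CPT and
#'   NDC set in the registry.
#' @return Logical matrix (patients x code sets) with `rownames` the
#'   patient ids and attribute `"window"`.
#' @export
build_utilization <- function(cohort, claims, registry = builtin_registry(),
                              window = c("post180", "pre30_post180"),
                              codesets = NULL) {
  window <- match.arg(window)
  lo <- if (window == "post180") 0L else -30L
  hi <- 180L
  if (is.null(codesets)) {
    codesets <- names(registry)[vapply(registry, function(s) {
      s$system %in% c("HCPCS_CPT", "NDC")
    }, TRUE)]
  }
  missing <- setdiff(codesets, names(registry))
  if (length(missing)) {
    stop("unknown code set(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cl <- as.data.table(claims)[
    as.data.table(cohort)[, .(patient_id, index_date)],
    on = "patient_id", nomatch = 0L]
  cl[, offset := as.integer(service_date - index_date)]
  cl <- cl[offset >= lo & offset < hi]

  ids <- cohort$patient_id
  flags <- matrix(FALSE, length(ids), length(codesets),
                  dimnames = list(ids, codesets))
  for (s in codesets) {
    set <- registry[[s]]
    sub <- if (is.null(set$settings)) cl else cl[setting %in% set$settings]
    hit_ids <- unique(sub$patient_id[match_code(sub$code, sub$system, set)])
    flags[ids %in% hit_ids, s] <- TRUE
  }
  attr(flags, "window") <- window
  flags
}

eval_expr <- function(e, flags) {
  if (is.character(e)) {
    if (!e %in% colnames(flags)) {
      stop("rule references unknown exposure flag '", e, "'", call. = FALSE)
    }
    return(flags[, e])
  }
  vals <- lapply(e$args, eval_expr, flags = flags)
  switch(e$op,
         and = Reduce(`&`, vals),
         or = Reduce(`|`, vals),
         not = !vals[[1L]])
}

#' Apply a classification rule to exposure flags
#'
#' The prediction is deterministic and binary: a patient is predicted SCLC
#' iff the rule's boolean expression evaluates `TRUE` on their exposure
#' flags.
#'
#' @param rule A `phenotype_rule`.
#' @param flags Logical matrix from [build_utilization()].
#' @return Character vector (`"SCLC"` / `"NSCLC"`) named by patient id.
#' @export
apply_rule <- function(rule, flags) {
  stopifnot(inherits(rule, "phenotype_rule"))
  v <- eval_expr(rule$expr, flags)
  setNames(ifelse(v, "SCLC", "NSCLC"), rownames(flags))
}
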