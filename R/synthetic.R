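#' Default synthetic-population configuration
#'
#' Encodes the study conditions the generator emulates. Among diagnosed lung
#' cancer patients, 9.4% have small cell histology; 1,762/3,000 SCLC and
#' 8,244/28,912 NSCLC patients receive outpatient systemic therapy within
#' 180 days of diagnosis (so roughly 31% of all diagnosed patients are
#' treated). Exposure to each systemic agent is drawn conditional on being
#' treated, at the rates implied by the exploratory treated-subset margins
#' (e.g. etoposide 431/447 of treated SCLC and 116/2,121 of treated NSCLC,
#' which reproduces the diagnosed-level marginals of 58% and 1.5%);
#' supportive-care exposures (G-CSFs, fosaprepitant) are likewise
#' treated-only, and EGFR testing (0.5% of SCLC, 10.5% of NSCLC) is drawn
#' for all diagnosed patients. Age-band weights follow the published cohort
#' distribution; 12% of patients fail the 12-month enrollment lookback.
#'
#' @param n_patients Number of diagnosed lung cancer patients to simulate.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `generator_config` (a named list).
#' @export
default_config <- function(n_patients = 31912L, seed = 1L) {
  exposure <- rbind(
    # conditional on receiving outpatient systemic therapy
    data.frame(codeset = "carboplatin",   stratum = "treated",
               p_sclc = 368 / 447, p_nsclc = 1410 / 2121),
    data.frame(codeset = "cisplatin",     stratum = "treated",
               p_sclc = 92 / 447,  p_nsclc = 228 / 2121),
    data.frame(codeset = "oxaliplatin",   stratum = "treated",
               p_sclc = 0.01,      p_nsclc = 0.01),
    data.frame(codeset = "etoposide",     stratum = "treated",
               p_sclc = 431 / 447, p_nsclc = 116 / 2121),
    data.frame(codeset = "nivolumab",     stratum = "treated",
               p_sclc = 17 / 447,  p_nsclc = 157 / 2121),
    data.frame(codeset = "ipilimumab",    stratum = "treated",
               p_sclc = 5 / 447,   p_nsclc = 2 / 2121),
    data.frame(codeset = "irinotecan",    stratum = "treated",
               p_sclc = 7 / 447,   p_nsclc = 2 / 2121),
    data.frame(codeset = "topotecan",     stratum = "treated",
               p_sclc = 11 / 447,  p_nsclc = 2 / 2121),
    data.frame(codeset = "pegfilgrastim", stratum = "treated",
               p_sclc = 297 / 447, p_nsclc = 471 / 2121),
    # filgrastim rates solved so the independent G-CSF union hits 319/447
    # and 612/2,121
    data.frame(codeset = "filgrastim",    stratum = "treated",
               p_sclc = 22 / 150,  p_nsclc = 141 / 1650),
    # fosaprepitant marginals 29% / 7.7% of diagnosed, rescaled to treated
    data.frame(codeset = "fosaprepitant", stratum = "treated",
               p_sclc = 0.29 * 3000 / 1762, p_nsclc = 0.077 * 28912 / 8244),
    # drawn for every diagnosed patient, treated or not
    data.frame(codeset = "egfr_test",     stratum = "all",
               p_sclc = 0.005, p_nsclc = 0.105)
  )
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    sclc_prevalence = 0.094,
    treated_prob_sclc = 1762 / 3000,
    treated_prob_nsclc = 8244 / 28912,
    exposure_probs = exposure,
    age_bands = data.frame(
      band = c("19-65", "66-69", "70-74", "75-79", "80-84", "85+"),
      lo = c(19L, 66L, 70L, 75L, 80L, 85L),
      hi = c(65L, 69L, 74L, 79L, 84L, 94L),
      weight = c(0, 0.189, 0.269, 0.239, 0.160, 0.143)
    ),
    diagnosis_period = c("2016-01", "2017-12"),
    lookback_dropout_prob = 0.12,
    disenroll_prob = 0,
    death_rate_180d = c(SCLC = 0, NSCLC = 0),
    duplicate_tumor_prob = 0.01,
    force_etoposide_platinum = FALSE,
    # label-neutral background utilization so code screening has chaff
    background_codes = data.frame(
      code = c("99213", "71260"), system = "HCPCS_CPT", p = c(0.95, 0.80)
    ),
    primary_code_weight = 0.85
  )
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  probs <- c(config$sclc_prevalence, config$treated_prob_sclc,
             config$treated_prob_nsclc, config$lookback_dropout_prob,
             config$disenroll_prob, config$death_rate_180d,
             config$exposure_probs$p_sclc, config$exposure_probs$p_nsclc,
             config$duplicate_tumor_prob, config$background_codes$p)
  if (any(probs < 0 | probs > 1)) {
    stop("all configured probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (config$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (!all(config$exposure_probs$stratum %in% c("treated", "all"))) {
    stop("exposure strata must be 'treated' or 'all'", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_config> n = %d, seed = %d\n",
    "  SCLC prevalence %.3f; treated SCLC %.3f, NSCLC %.3f\n",
    "  diagnosis period %s..%s; lookback dropout %.2f\n",
    "  %d exposure code sets\n"),
    x$n_patients, x$seed, x$sclc_prevalence, x$treated_prob_sclc,
    x$treated_prob_nsclc, x$diagnosis_period[1], x$diagnosis_period[2],
    x$lookback_dropout_prob, nrow(x$exposure_probs)))
  invisible(x)
}

# birthdate giving exactly `age` completed years at `index`
birth_for_age <- function(index, age) {
  lt <- as.POSIXlt(index)
  lt$year <- lt$year - age
  lt$mday[lt$mon == 1L & lt$mday == 29L] <- 28L  # 29 Feb anniversaries
  as.Date(lt) - sample(0:360, length(index), replace = TRUE)
}

#' Generate a synthetic linked registry-claims population
#'
#' Produces four linked tables emulating a registry-Medicare linkage:
#' `patients` (demographics, death date), `tumors` (month-level diagnosis
#' date, ICD-O-3 histology, stage), `enrollment` (month-level Part A/B/D and
#' HMO flags) and `claims` (coded service events). Each patient receives a
#' lung-cancer ICD-10-CM claim in the diagnosis month; treated patients are
#' guaranteed at least one outpatient antineoplastic claim within 180 days
#' of the index date (exposure vectors are redrawn until non-empty, which
#' inflates each agent's conditional rate by the factor reported by
#' [expected_rates()]); untreated patients receive none. Exposure draws are
#' independent across code sets given (label, treated) — a documented
#' simplification, since only marginal utilization rates are calibrated.
#'
#' @param config A [default_config()]-style `generator_config`.
#' @param registry Code-set registry supplying claim codes.
#' @return An object of class `synthetic_population`: a list with elements
#'   `patients`, `tumors`, `enrollment`, `claims` (all `data.table`) and the
#'   `config` used.
#' @export
generate_population <- function(config = default_config(),
                                registry = builtin_registry()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%07d", seq_len(n))

  sclc <- runif(n) < config$sclc_prevalence
  label <- ifelse(sclc, "SCLC", "NSCLC")

  period <- ym_index(config$diagnosis_period)
  dx_ym <- sample(seq(period[1L], period[2L]), n, replace = TRUE)
  index_date <- ym_first_day(ym_label(dx_ym))

  bands <- config$age_bands
  band_i <- sample(nrow(bands), n, replace = TRUE, prob = bands$weight)
  age <- bands$lo[band_i] +
    floor(runif(n) * (bands$hi[band_i] - bands$lo[band_i] + 1L))
  birth <- birth_for_age(index_date, age)

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.446, 0.554))
  race <- sample(c("White", "Black", "Asian", "Other"), n, replace = TRUE,
                 prob = c(0.898, 0.058, 0.037, 0.008))

  death_p <- config$death_rate_180d[label]
  dies <- runif(n) < death_p
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  if (any(dies)) {
    death_date[dies] <- index_date[dies] + sample(0:179, sum(dies), TRUE)
  }

  treated <- runif(n) <
    ifelse(sclc, config$treated_prob_sclc, config$treated_prob_nsclc)

  ## exposure draws -----------------------------------------------------------
  ep <- config$exposure_probs
  pvec <- function(row) ifelse(sclc, ep$p_sclc[row], ep$p_nsclc[row])
  expose <- matrix(FALSE, n, nrow(ep), dimnames = list(NULL, ep$codeset))
  for (i in seq_len(nrow(ep))) {
    draw <- runif(n) < pvec(i)
    if (ep$stratum[i] == "treated") draw <- draw & treated
    expose[, i] <- draw
  }
  therapy_cols <- ep$codeset[
    vapply(ep$codeset, function(s) isTRUE(registry[[s]]$therapy), TRUE)
  ]
  # treated patients must carry at least one antineoplastic exposure
  need <- which(treated & rowSums(expose[, therapy_cols, drop = FALSE]) == 0L)
  while (length(need)) {
    for (s in therapy_cols) {
      i <- match(s, ep$codeset)
      expose[need, s] <- runif(length(need)) <
        ifelse(sclc[need], ep$p_sclc[i], ep$p_nsclc[i])
    }
    need <- need[rowSums(expose[need, therapy_cols, drop = FALSE]) == 0L]
  }
  if (isTRUE(config$force_etoposide_platinum)) {
    plat <- c("carboplatin", "cisplatin", "oxaliplatin")
    fix <- expose[, "etoposide"] &
      rowSums(expose[, plat, drop = FALSE]) == 0L
    expose[fix, "carboplatin"] <- TRUE
  }

  ## tumors -------------------------------------------------------------------
  sclc_codes <- registry$sclc_histology$codes
  histology <- ifelse(
    sclc, sclc_codes[sample.int(length(sclc_codes), n, replace = TRUE)],
    "8140"
  )
  stage <- sample(c("local", "regional", "distant"), n, replace = TRUE,
                  prob = c(0.341, 0.237, 0.417))
  tumors <- data.table(
    patient_id = pid, diagnosis_month = ym_label(dx_ym),
    histology = histology, stage = stage
  )
  dup <- which(runif(n) < config$duplicate_tumor_prob)
  if (length(dup)) {
    shift <- sample(c(-6:-1, 1:6), length(dup), replace = TRUE)
    dup_ym <- pmin(pmax(dx_ym[dup] + shift, period[1L]), period[2L])
    dup_hist <- ifelse(
      sclc[dup],
      sclc_codes[sample.int(length(sclc_codes), length(dup), replace = TRUE)],
      "8140"
    )
    tumors <- rbind(tumors, data.table(
      patient_id = pid[dup], diagnosis_month = ym_label(dup_ym),
      histology = dup_hist,
      stage = sample(c("local", "regional", "distant"), length(dup), TRUE)
    ))
  }
  setorder(tumors, patient_id, diagnosis_month)

  ## enrollment ---------------------------------------------------------------
  span <- -12:6
  enrollment <- data.table(
    patient_id = rep(pid, each = length(span)),
    ym = rep(dx_ym, each = length(span)) + span,
    part_a = TRUE, part_b = TRUE, part_d = TRUE, hmo = FALSE
  )
  gap <- which(runif(n) < config$lookback_dropout_prob)
  if (length(gap)) {
    gap_ym <- dx_ym[gap] + sample(-12:-1, length(gap), replace = TRUE)
    enrollment[data.table(patient_id = pid[gap], ym = gap_ym),
               on = c("patient_id", "ym"), part_d := FALSE]
  }
  disenroll_ym <- rep(NA_integer_, n)
  dis <- which(runif(n) < config$disenroll_prob)
  if (length(dis)) {
    disenroll_ym[dis] <- dx_ym[dis] + sample(1:6, length(dis), replace = TRUE)
    cut <- disenroll_ym[match(enrollment$patient_id, pid)]
    gone <- which(!is.na(cut) & enrollment$ym >= cut)
    if (length(gone)) {
      enrollment[gone, c("part_a", "part_b", "part_d") := FALSE]
    }
  }
  enrollment[, month := ym_label(ym)]
  enrollment[, ym := NULL]

  ## claims -------------------------------------------------------------------
  dx_codes <- c("C34.10", "C34.11", "C34.12", "C34.31", "C34.80", "C34.90")
  pieces <- list(data.table(
    patient_id = pid,
    service_date = index_date + sample(0:27, n, replace = TRUE),
    code = sample(dx_codes, n, replace = TRUE),
    system = "ICD10CM_DX", setting = "outpatient"
  ))
  bg <- config$background_codes
  for (i in seq_len(nrow(bg))) {
    keep <- which(runif(n) < bg$p[i])
    if (!length(keep)) next
    pieces[[length(pieces) + 1L]] <- data.table(
      patient_id = pid[keep],
      service_date = index_date[keep] + sample(0:179, length(keep), TRUE),
      code = bg$code[i], system = bg$system[i], setting = "outpatient"
    )
  }
  sample_codes <- function(set, k) {
    codes <- set$codes
    if (length(codes) == 1L) return(rep(codes, k))
    w <- c(config$primary_code_weight,
           rep((1 - config$primary_code_weight) / (length(codes) - 1L),
               length(codes) - 1L))
    codes[sample.int(length(codes), k, replace = TRUE, prob = w)]
  }
  for (s in colnames(expose)) {
    idx <- which(expose[, s])
    if (!length(idx)) next
    set <- registry[[s]]
    n_claims <- if (set$therapy || s %in% c("pegfilgrastim", "filgrastim",
                                            "fosaprepitant")) {
      1L + rpois(length(idx), 1)
    } else {
      rep(1L, length(idx))
    }
    rows <- rep(idx, n_claims)
    pieces[[length(pieces) + 1L]] <- data.table(
      patient_id = pid[rows],
      service_date = index_date[rows] + sample(0:179, length(rows), TRUE),
      code = sample_codes(set, length(rows)),
      system = set$system, setting = "outpatient"
    )
  }
  claims <- rbindlist(pieces)
  # service activity ends at death or disenrollment
  lim <- data.table(
    patient_id = pid, death_date = death_date,
    dis_start = ym_first_day(ym_label(
      ifelse(is.na(disenroll_ym), period[2L] + 1000L, disenroll_ym)
    ))
  )
  claims <- lim[claims, on = "patient_id"]
  claims <- claims[(is.na(death_date) | service_date <= death_date) &
                     service_date < dis_start]
  claims[, c("death_date", "dis_start") := NULL]
  setorder(claims, patient_id, service_date, system, code)

  patients <- data.table(
    patient_id = pid, birth_date = birth, death_date = death_date,
    sex = sex, race = race
  )

  structure(
    list(patients = patients, tumors = tumors, enrollment = enrollment,
         claims = claims[], config = config),
    class = "synthetic_population"
  )
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_population> %d patients, %d tumor records,\n",
    "  %d enrollment months, %d claims (seed %d)\n"),
    nrow(x$patients), nrow(x$tumors), nrow(x$enrollment), nrow(x$claims),
    x$config$seed))
  invisible(x)
}

#' Summarise a synthetic population against its calibration targets
#'
#' Recomputes, from the generated tables alone, the quantities the generator
#' is calibrated to: per-label patient counts, the treated fraction (at
#' least one outpatient antineoplastic claim within 180 days of the
#' patient's earliest tumor month) and per-code-set exposure proportions by
#' label.
#'
#' @param pop A `synthetic_population`.
#' @param registry Code-set registry (defaults to the built-ins).
#' @return A list of class `population_summary` with elements `n`, `counts`
#'   (per-label totals and treated counts) and `exposure` (per-code-set
#'   in-window exposure proportions by label).
#' @export
population_summary <- function(pop, registry = builtin_registry()) {
  stopifnot(inherits(pop, "synthetic_population"))
  empty <- list(
    n = 0L,
    counts = data.table(label = character(), n = integer(),
                        treated = integer(), treated_frac = numeric()),
    exposure = data.table(codeset = character(), p_sclc = numeric(),
                          p_nsclc = numeric())
  )
  if (nrow(pop$patients) == 0L) return(structure(empty, class = "population_summary"))

  first_tumor <- as.data.table(pop$tumors)[
    order(diagnosis_month, histology), .SD[1L], by = patient_id]
  first_tumor[, gold_label := gold_label(histology, registry)]
  first_tumor[, index_date := ym_first_day(diagnosis_month)]
  base <- first_tumor[, .(patient_id, gold_label, index_date)]

  cl <- as.data.table(pop$claims)[base, on = "patient_id", nomatch = 0L]
  cl[, offset := as.integer(service_date - index_date)]
  inwin <- cl[offset >= 0L & offset < 180L]

  therapy <- names(registry)[vapply(registry, `[[`, TRUE, "therapy")]
  hit <- rep(FALSE, nrow(inwin))
  for (s in therapy) {
    hit <- hit | match_code(inwin$code, inwin$system, registry[[s]])
  }
  treated_ids <- unique(inwin$patient_id[hit & inwin$setting == "outpatient"])
  base[, treated := patient_id %in% treated_ids]
  counts <- base[, .(n = .N, treated = sum(treated),
                     treated_frac = mean(treated)), by = .(label = gold_label)]

  drug_sets <- names(registry)[
    vapply(registry, function(s) s$system %in% c("HCPCS_CPT", "NDC"), TRUE)]
  expo <- rbindlist(lapply(drug_sets, function(s) {
    ids <- unique(inwin$patient_id[
      match_code(inwin$code, inwin$system, registry[[s]])])
    flagged <- base[, .(p = mean(patient_id %in% ids)), by = gold_label]
    data.table(codeset = s,
               p_sclc = flagged[gold_label == "SCLC", if (.N) p else 0],
               p_nsclc = flagged[gold_label == "NSCLC", if (.N) p else 0])
  }))
  structure(list(n = nrow(base), counts = counts[], exposure = expo[]),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d diagnosed patients\n", x$n))
  if (x$n == 0L) return(invisible(x))
  print(x$counts)
  cat("exposure proportions by gold label:\n")
  print(x$exposure)
  invisible(x)
}

#' Analytic exposure rates implied by a generator configuration
#'
#' Closed-form expectations for the population the generator draws,
#' accounting for the redraw that guarantees treated patients at least one
#' antineoplastic exposure: conditional on treated, an antineoplastic set
#' with configured rate p is observed at p / (1 - P0), where P0 is the
#' probability that all antineoplastic draws fail. These are the values
#' against which empirical summaries (and the end-to-end accuracy of the
#' etoposide rules) are compared.
#'
#' @param config A `generator_config`.
#' @param registry Code-set registry.
#' @return List with `treated` (per-label treated probability), `p0`
#'   (per-label all-fail probability), and `exposure`: a `data.table` with,
#'   per code set and label, the conditional-on-treated rate and the
#'   marginal diagnosed-level rate. Includes the `platinum` and `gcsf`
#'   unions.
#' @export
expected_rates <- function(config = default_config(),
                           registry = builtin_registry()) {
  ep <- config$exposure_probs
  therapy <- ep$codeset[
    vapply(ep$codeset, function(s) isTRUE(registry[[s]]$therapy), TRUE)]
  treated <- c(SCLC = config$treated_prob_sclc,
               NSCLC = config$treated_prob_nsclc)
  p_of <- function(set, lab) {
    i <- match(set, ep$codeset)
    if (lab == "SCLC") ep$p_sclc[i] else ep$p_nsclc[i]
  }
  p0 <- vapply(c("SCLC", "NSCLC"), function(lab) {
    prod(1 - vapply(therapy, p_of, 0, lab = lab))
  }, 0)

  one <- function(set, lab) {
    stratum <- ep$stratum[match(set, ep$codeset)]
    p <- p_of(set, lab)
    if (stratum == "all") {
      c(cond = p, marginal = p)
    } else if (set %in% therapy) {
      cond <- p / (1 - p0[[lab]])
      c(cond = cond, marginal = treated[[lab]] * cond)
    } else {
      c(cond = p, marginal = treated[[lab]] * p)
    }
  }
  rows <- lapply(ep$codeset, function(set) {
    s <- one(set, "SCLC"); n <- one(set, "NSCLC")
    data.table(codeset = set,
               cond_sclc = s[["cond"]], cond_nsclc = n[["cond"]],
               marginal_sclc = s[["marginal"]],
               marginal_nsclc = n[["marginal"]])
  })
  # Unions. Any-platinum implies >=1 antineoplastic, so conditioning on the
  # redraw just rescales by 1/(1 - P0); the G-CSF union is unaffected by it.
  union_row <- function(name, members, adjust) {
    vals <- vapply(c("SCLC", "NSCLC"), function(lab) {
      any_p <- 1 - prod(1 - vapply(members, p_of, 0, lab = lab))
      if (adjust) any_p / (1 - p0[[lab]]) else any_p
    }, 0)
    data.table(codeset = name,
               cond_sclc = vals[["SCLC"]], cond_nsclc = vals[["NSCLC"]],
               marginal_sclc = treated[["SCLC"]] * vals[["SCLC"]],
               marginal_nsclc = treated[["NSCLC"]] * vals[["NSCLC"]])
  }
  rows[[length(rows) + 1L]] <- union_row(
    "platinum",
    intersect(c("carboplatin", "cisplatin", "oxaliplatin"), ep$codeset),
    adjust = TRUE
  )
  rows[[length(rows) + 1L]] <- union_row(
    "gcsf", intersect(c("filgrastim", "pegfilgrastim"), ep$codeset),
    adjust = FALSE
  )
  list(treated = treated, p0 = p0, exposure = rbindlist(rows)[])
}

#' Write / read a synthetic population as CSV files
#'
#' Four files are written: `patients.csv`, `tumors.csv`, `enrollment.csv`,
#' `claims.csv`. Dates are ISO-8601 strings; months are `YYYY-MM`.
#'
#' @param pop A `synthetic_population`.
#' @param dir Output directory (created if missing).
#' @return `dir` (write) or a `synthetic_population` without config (read).
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "synthetic_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(pop$patients, file.path(dir, "patients.csv"))
  fwrite(pop$tumors, file.path(dir, "tumors.csv"))
  fwrite(pop$enrollment, file.path(dir, "enrollment.csv"))
  fwrite(pop$claims, file.path(dir, "claims.csv"))
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  rd <- function(f, chr, dates = character()) {
    x <- fread(file.path(dir, f), colClasses = list(character = chr))
    for (d in dates) set(x, j = d, value = as.Date(x[[d]]))
    x
  }
  structure(
    list(
      patients = rd("patients.csv", c("patient_id", "sex", "race"),
                    c("birth_date", "death_date")),
      tumors = rd("tumors.csv",
                  c("patient_id", "diagnosis_month", "histology", "stage")),
      enrollment = rd("enrollment.csv", c("patient_id", "month")),
      claims = rd("claims.csv", c("patient_id", "code", "system", "setting"),
                  "service_date"),
      config = NULL
    ),
    class = "synthetic_population"
  )
}
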