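#' Supported claim coding systems
#'
#' Four coding systems are recognised: `HCPCS_CPT` (procedure and drug
#' administration codes), `NDC` (dispensed drug products), `ICD10CM_DX`
#' (claims diagnoses) and `ICDO3_HIST` (registry histology). Codes are never
#' compared across systems.
#'
#' @return Character vector of system labels.
#' @export
code_systems <- function() {
  c("HCPCS_CPT", "NDC", "ICD10CM_DX", "ICDO3_HIST")
}

# uppercase, strip whitespace and dots; NDC additionally drops leading zeros
normalize_code <- function(code, system) {
  x <- toupper(gsub("[[:space:].]", "", as.character(code)))
  if (identical(system, "NDC")) x <- sub("^0+", "", x)
  x
}

#' Create a code set
#'
#' A code set is a named collection of codes from a single coding system,
#' matched either exactly or (for ICD-10-CM only) by prefix. Codes are
#' normalised on construction: uppercased, whitespace- and dot-stripped,
#' leading zeros dropped for NDC.
#'
#' @param name Identifier string.
#' @param system One of [code_systems()].
#' @param codes Character vector of codes (non-empty after normalisation).
#' @param match_mode `"exact"` or `"prefix"` (prefix only for `ICD10CM_DX`).
#' @param therapy Logical; does this set define systemic antineoplastic
#'   therapy (and hence contribute to the treated-subset flag)?
#' @param settings Claim settings searched when building exposure flags;
#'   `NULL` means all settings.
#' @return An object of class `codeset`.
#' @export
codeset <- function(name, system, codes, match_mode = c("exact", "prefix"),
                    therapy = FALSE, settings = NULL) {
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!system %in% code_systems()) {
    stop("unknown code system '", system, "'", call. = FALSE)
  }
  codes <- unique(normalize_code(codes, system))
  codes <- codes[nzchar(codes)]
  if (!length(codes)) {
    stop("code set '", name, "' has no codes", call. = FALSE)
  }
  if (match_mode == "prefix" && system != "ICD10CM_DX") {
    stop("prefix matching is only supported for ICD10CM_DX", call. = FALSE)
  }
  structure(
    list(name = name, system = system, codes = codes,
         match_mode = match_mode, therapy = isTRUE(therapy),
         settings = settings),
    class = "codeset"
  )
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("<codeset> %s [%s, %s%s]: %s\n",
              x$name, x$system, x$match_mode,
              if (x$therapy) ", therapy" else "",
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

codeset_union <- function(name, sets, therapy = FALSE, settings = NULL) {
  systems <- unique(vapply(sets, `[[`, "", "system"))
  if (length(systems) != 1L) {
    stop("union code sets must share a single system", call. = FALSE)
  }
  codeset(name, systems, unlist(lapply(sets, `[[`, "codes")),
          therapy = therapy, settings = settings)
}

#' Create a code-set registry
#'
#' @param sets List of [codeset()] objects with unique names.
#' @return An object of class `codeset_registry` (a named list of code sets).
#' @export
codeset_registry <- function(sets) {
  stopifnot(all(vapply(sets, inherits, TRUE, "codeset")))
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate code-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(setNames(sets, nms), class = "codeset_registry")
}

#' @export
print.codeset_registry <- function(x, ...) {
  cat(sprintf("<codeset_registry> %d sets\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-18s %-11s %-6s %3d code%s%s\n", s$name, s$system,
                s$match_mode, length(s$codes),
                if (length(s$codes) == 1L) "" else "s",
                if (s$therapy) "  [therapy]" else ""))
  }
  invisible(x)
}

DRUG_SETTINGS <- c("outpatient", "part_d", "dme")

#' Built-in code-set registry
#'
#' Returns the registry used throughout the pipeline: the lung-cancer
#' ICD-10-CM definition (prefix `C34`, dot-insensitive), the small cell
#' ICD-O-3 histology set (8002, 8041-8045), the EGFR test CPT code 81235,
#' and the systemic-therapy and supportive-care agents evaluated as
#' classification rules. Drug sets ship with representative HCPCS J-codes as
#' editable placeholders (real studies substitute their full HCPCS/NDC lists
#' via [load_codesets()]); the synthetic generator emits codes drawn from
#' this same registry, so the pipeline is closed regardless of placeholder
#' realism. `platinum` is the union carboplatin + cisplatin + oxaliplatin
#' ("all platinum agents"); `gcsf` is filgrastim + pegfilgrastim.
#'
#' @return A `codeset_registry`.
#' @export
builtin_registry <- function() {
  drug <- function(name, codes, therapy = TRUE) {
    codeset(name, "HCPCS_CPT", codes, therapy = therapy,
            settings = DRUG_SETTINGS)
  }
  sets <- list(
    codeset("lung_cancer_dx", "ICD10CM_DX", "C34", match_mode = "prefix"),
    codeset("sclc_histology", "ICDO3_HIST",
            c("8002", "8041", "8042", "8043", "8044", "8045")),
    drug("carboplatin", "J9045"),
    drug("cisplatin", "J9060"),
    drug("oxaliplatin", "J9263"),
    drug("etoposide", c("J9181", "J8560")),
    drug("nivolumab", "J9299"),
    drug("ipilimumab", "J9228"),
    drug("irinotecan", "J9206"),
    drug("topotecan", c("J9351", "J8705")),
    drug("filgrastim", "J1442", therapy = FALSE),
    drug("pegfilgrastim", "J2505", therapy = FALSE),
    drug("fosaprepitant", "J1453", therapy = FALSE),
    codeset("egfr_test", "HCPCS_CPT", "81235")
  )
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets$platinum <- codeset_union(
    "platinum", sets[c("carboplatin", "cisplatin", "oxaliplatin")],
    therapy = TRUE, settings = DRUG_SETTINGS
  )
  sets$gcsf <- codeset_union(
    "gcsf", sets[c("filgrastim", "pegfilgrastim")],
    therapy = FALSE, settings = DRUG_SETTINGS
  )
  codeset_registry(unname(sets))
}

#' Match claim codes against a code set
#'
#' Case-, whitespace- and dot-insensitive on the code argument. A code
#' matches only when its coding system equals the set's system, and (exact
#' mode) the normalised code is a member, or (prefix mode) it starts with
#' any member.
#'
#' @param code Character vector of claim codes.
#' @param system Coding system of the codes (scalar or vector, recycled).
#' @param set A [codeset()].
#' @return Logical vector, one element per code.
#' @export
match_code <- function(code, system, set) {
  stopifnot(inherits(set, "codeset"))
  code <- as.character(code)
  if (length(system) == 1L) system <- rep(system, length(code))
  out <- logical(length(code))
  ok <- system == set$system
  if (!any(ok)) return(out)
  norm <- normalize_code(code[ok], set$system)
  if (set$match_mode == "exact") {
    hit <- norm %in% set$codes
  } else {
    hit <- rep(FALSE, length(norm))
    for (p in set$codes) hit <- hit | startsWith(norm, p)
  }
  out[ok] <- hit
  out
}

#' Load code sets from a CSV file
#'
#' The file has one row per code with columns `set_name`, `system`, `code`,
#' `match_mode`. File entries are merged over the built-in registry (or any
#' `base` registry): a file set whose name already exists replaces the
#' built-in codes wholesale, but keeps the built-in therapy flag and
#' settings so the treated-subset definition survives a code-list override.
#'
#' @param path Path to the CSV file.
#' @param base Registry to merge over; defaults to [builtin_registry()].
#' @return A `codeset_registry`.
#' @export
load_codesets <- function(path, base = builtin_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(base)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("set_name", "system", "code", "match_mode")
  if (!all(required %in% names(raw))) {
    stop("malformed code-set file '", path, "': expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(base)
  bad <- which(!raw$system %in% code_systems())
  if (length(bad)) {
    stop("unknown code system '", raw$system[bad[1L]], "' at line ",
         bad[1L] + 1L, " of ", path, call. = FALSE)
  }
  sets <- as.list(base)
  for (nm in unique(raw$set_name)) {
    rows <- raw[raw$set_name == nm, , drop = FALSE]
    system <- unique(rows$system)
    if (length(system) != 1L) {
      stop("code set '", nm, "' mixes systems in ", path, call. = FALSE)
    }
    mode <- unique(rows$match_mode[nzchar(rows$match_mode)])
    if (length(mode) > 1L) {
      stop("code set '", nm, "' mixes match modes in ", path, call. = FALSE)
    }
    if (!length(mode)) mode <- "exact"
    if (!mode %in% c("exact", "prefix")) {
      stop("unknown match mode '", mode, "' for set '", nm, "'",
           call. = FALSE)
    }
    old <- sets[[nm]]
    sets[[nm]] <- codeset(
      nm, system, rows$code, match_mode = mode,
      therapy = if (!is.null(old)) old$therapy else FALSE,
      settings = if (!is.null(old)) old$settings else NULL
    )
  }
  codeset_registry(unname(sets))
}

#' Write a registry to the code-set CSV format
#'
#' Inverse of [load_codesets()]: one row per code. Union sets are written
#' flat; reloading reproduces an equivalent registry.
#'
#' @param registry A `codeset_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codesets <- function(registry, path) {
  stopifnot(inherits(registry, "codeset_registry"))
  rows <- do.call(rbind, lapply(registry, function(s) {
    data.frame(set_name = s$name, system = s$system, code = s$codes,
               match_mode = s$match_mode)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
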