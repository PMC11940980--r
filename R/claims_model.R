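# Claims data model: the five canonical tables, delimited-text readers/writers
# with row-level validation, and enrollment-span merging. Every downstream stage
# consumes only the validated `claims_dataset` container built here.
#
# Table schemas (CSV with header; dates ISO-8601; multi-valued dx codes are
# pipe-delimited inside one field):
#   patients        : patient_id, birth_year, sex, region, payer, death_date
#   enrollment      : patient_id, start_date, end_date, medical, pharmacy
#   medical_claims  : claim_id, patient_id, service_date, setting, dx_codes,
#                     drug_code, paid_amount, service_year
#   pharmacy_claims : claim_id, patient_id, fill_date, drug_code, days_supply,
#                     paid_amount
#   drug_dictionary : see load_drug_dictionary()

SETTINGS <- c("OUTPATIENT", "INPATIENT", "ED")
DATASET_TABLES <- c("patients", "enrollment", "medical_claims",
                    "pharmacy_claims", "drug_dictionary")

#' Construct a validated claims dataset
#'
#' Bundles the five tables, merges enrollment spans into maximal disjoint spans
#' (per patient and benefit combination), checks referential integrity of
#' patient ids, and verifies every systemic-anticancer drug code resolves in the
#' dictionary.
#'
#' @param patients,enrollment,medical_claims,pharmacy_claims data.frames
#'   following the documented schemas.
#' @param drug_dictionary A dictionary table (see [load_drug_dictionary()]).
#' @param rejections Optional row-rejection report carried from a reader.
#' @return An object of class `claims_dataset`: a list of keyed data.tables.
#' @export
claims_dataset <- function(patients, enrollment, medical_claims,
                           pharmacy_claims, drug_dictionary,
                           rejections = NULL) {
  patients <- as.data.table(patients)
  enrollment <- merge_enrollment_spans(as.data.table(enrollment))
  medical_claims <- as.data.table(medical_claims)
  pharmacy_claims <- as.data.table(pharmacy_claims)
  drug_dictionary <- validate_drug_dictionary(drug_dictionary)

  known <- unique(patients$patient_id)
  for (tb in list(enrollment = enrollment, medical_claims = medical_claims,
                  pharmacy_claims = pharmacy_claims)) {
    orphan <- setdiff(unique(tb$patient_id), known)
    if (length(orphan)) {
      stopf("claims reference %d unknown patient id(s), e.g. %s",
            length(orphan), orphan[1L])
    }
  }

  # every SACT code appearing in claims must resolve; unknown codes are fatal
  codes <- unique(c(medical_claims$drug_code, pharmacy_claims$drug_code))
  codes <- codes[!is.na(codes) & codes != ""]
  unresolved <- setdiff(codes, drug_dictionary$drug_code)
  if (length(unresolved)) {
    stopf("unresolvable drug code(s) in claims: %s",
          paste(utils::head(unresolved, 10L), collapse = ", "))
  }

  ds <- list(patients = patients, enrollment = enrollment,
             medical_claims = medical_claims, pharmacy_claims = pharmacy_claims,
             drug_dictionary = drug_dictionary,
             rejections = rejections %||% empty_rejections())
  class(ds) <- "claims_dataset"
  ds
}

empty_rejections <- function() {
  data.table(table = character(), reason = character(), n = integer())
}

#' Merge enrollment spans into maximal disjoint spans
#'
#' Spans of one patient with identical benefit flags that overlap or abut
#' (gap <= `gap_tolerance` days) are merged. Total covered days are invariant
#' under merging and merged spans are pairwise disjoint.
#'
#' @param enrollment Enrollment table (`patient_id`, `start_date`, `end_date`,
#'   `medical`, `pharmacy`).
#' @param gap_tolerance Days of gap still bridged (default 0: only abutting or
#'   overlapping spans merge).
#' @return Merged enrollment data.table sorted by patient and start date.
#' @export
merge_enrollment_spans <- function(enrollment, gap_tolerance = 0L) {
  enr <- as.data.table(enrollment)
  if (nrow(enr) == 0L) return(enr)
  stopifnot(all(enr$start_date <= enr$end_date))
  setorder(enr, patient_id, medical, pharmacy, start_date, end_date)
  enr[, grp := {
    s <- as.integer(start_date)
    run_end <- cummax(as.integer(end_date))
    # new group whenever a span starts beyond the running max end + tolerance + 1
    cumsum(c(TRUE, s[-1L] > run_end[-length(s)] + gap_tolerance + 1L))
  }, by = .(patient_id, medical, pharmacy)]
  out <- enr[, .(start_date = min(start_date), end_date = max(end_date)),
             by = .(patient_id, medical, pharmacy, grp)]
  out[, grp := NULL]
  setcolorder(out, c("patient_id", "start_date", "end_date", "medical", "pharmacy"))
  setorder(out, patient_id, start_date)
  out[]
}

#' Read a claims dataset from a directory of delimited-text tables
#'
#' Validates row-level invariants; rows violating them (malformed dates,
#' unknown setting, negative paid amounts, non-positive days supply,
#' service_year inconsistent with service_date) are rejected and counted in the
#' dataset's rejection report. Missing files and unresolvable SACT drug codes
#' are fatal.
#'
#' @param dir Directory containing `patients.csv`, `enrollment.csv`,
#'   `medical_claims.csv`, `pharmacy_claims.csv`, `drug_dictionary.csv`, or a
#'   named list/vector of file paths for those table names.
#' @param config An [analysis_config()] (currently only carried through).
#' @return A `claims_dataset`; the rejection report is in `$rejections`.
#' @export
read_claims_dataset <- function(dir, config = default_config()) {
  paths <- if (is.list(dir) || (is.character(dir) && !is.null(names(dir)))) {
    as.list(dir)
  } else {
    stats::setNames(as.list(file.path(dir, paste0(DATASET_TABLES, ".csv"))),
                    DATASET_TABLES)
  }
  miss <- DATASET_TABLES[!vapply(paths[DATASET_TABLES], function(p)
    !is.null(p) && file.exists(p), logical(1))]
  if (length(miss)) stopf("missing dataset file(s): %s", paste(miss, collapse = ", "))

  rej <- list()
  note <- function(tb, reason, n) {
    if (n > 0L) rej[[length(rej) + 1L]] <<- data.table(table = tb, reason = reason, n = as.integer(n))
  }

  pat <- data.table::fread(paths$patients, colClasses = list(character =
    c("patient_id", "sex", "region", "payer", "death_date")), na.strings = "")
  pat[, death_date := as_date_safe(death_date)]
  bad <- is.na(pat$birth_year) | pat$birth_year < 1880 | pat$birth_year > 2025
  note("patients", "implausible birth_year", sum(bad)); pat <- pat[!bad]

  enr <- data.table::fread(paths$enrollment,
                           colClasses = list(character = c("patient_id", "start_date", "end_date")))
  enr[, `:=`(start_date = as_date_safe(start_date), end_date = as_date_safe(end_date),
             medical = as.logical(medical), pharmacy = as.logical(pharmacy))]
  bad <- is.na(enr$start_date) | is.na(enr$end_date)
  note("enrollment", "malformed date", sum(bad)); enr <- enr[!bad]
  bad <- enr$start_date > enr$end_date
  note("enrollment", "start after end", sum(bad)); enr <- enr[!bad]

  med <- data.table::fread(paths$medical_claims, colClasses = list(character =
    c("claim_id", "patient_id", "service_date", "setting", "dx_codes", "drug_code")),
    na.strings = "")
  med[, service_date := as_date_safe(service_date)]
  med[is.na(dx_codes), dx_codes := ""]
  bad <- is.na(med$service_date)
  note("medical_claims", "malformed date", sum(bad)); med <- med[!bad]
  bad <- !med$setting %in% SETTINGS
  note("medical_claims", "unknown setting", sum(bad)); med <- med[!bad]
  bad <- is.na(med$paid_amount) | med$paid_amount < 0
  note("medical_claims", "negative or missing paid_amount", sum(bad)); med <- med[!bad]
  bad <- med$service_year != as.integer(format(med$service_date, "%Y"))
  note("medical_claims", "service_year mismatch", sum(bad)); med <- med[!bad]

  rx <- data.table::fread(paths$pharmacy_claims, colClasses = list(character =
    c("claim_id", "patient_id", "fill_date", "drug_code")), na.strings = "")
  rx[, fill_date := as_date_safe(fill_date)]
  bad <- is.na(rx$fill_date)
  note("pharmacy_claims", "malformed date", sum(bad)); rx <- rx[!bad]
  bad <- is.na(rx$days_supply) | rx$days_supply < 1
  note("pharmacy_claims", "days_supply < 1", sum(bad)); rx <- rx[!bad]
  bad <- is.na(rx$paid_amount) | rx$paid_amount < 0
  note("pharmacy_claims", "negative or missing paid_amount", sum(bad)); rx <- rx[!bad]

  dict <- load_drug_dictionary(paths$drug_dictionary)
  claims_dataset(pat, enr, med, rx, dict,
                 rejections = if (length(rej)) rbindlist(rej) else empty_rejections())
}

#' Write a claims dataset to delimited-text tables
#'
#' Inverse of [read_claims_dataset()]: the written directory re-reads to an
#' identical dataset (enrollment is written in merged form, which re-merges to
#' itself).
#'
#' @param ds A `claims_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the five written file paths, invisibly.
#' @export
write_claims_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "claims_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(out_dir, paste0(DATASET_TABLES, ".csv")),
                           DATASET_TABLES)
  dict_out <- copy(ds$drug_dictionary)[, canonical_id := NULL]
  data.table::fwrite(ds$patients, paths["patients"])
  data.table::fwrite(ds$enrollment, paths["enrollment"])
  data.table::fwrite(ds$medical_claims, paths["medical_claims"])
  data.table::fwrite(ds$pharmacy_claims, paths["pharmacy_claims"])
  data.table::fwrite(dict_out, paths["drug_dictionary"])
  invisible(paths)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat(sprintf("  patients        : %d\n", nrow(x$patients)))
  cat(sprintf("  enrollment spans: %d (merged)\n", nrow(x$enrollment)))
  cat(sprintf("  medical claims  : %d\n", nrow(x$medical_claims)))
  cat(sprintf("  pharmacy claims : %d\n", nrow(x$pharmacy_claims)))
  cat(sprintf("  dictionary      : %d drug codes\n", nrow(x$drug_dictionary)))
  if (nrow(x$rejections)) {
    cat(sprintf("  rejected rows   : %d (see $rejections)\n", sum(x$rejections$n)))
  }
  invisible(x)
}

# Split a pipe-delimited dx_codes field into a long (claim row, code, position)
# table; codes are matched by prefix with dots stripped.
dx_long <- function(medical_claims) {
  mc <- medical_claims[dx_codes != "",
                       .(claim_id, patient_id, service_date, dx_codes)]
  if (nrow(mc) == 0L) {
    return(data.table(claim_id = character(), patient_id = character(),
                      service_date = as.Date(character()), code = character(),
                      position = integer()))
  }
  codes <- strsplit(mc$dx_codes, "|", fixed = TRUE)
  n <- lengths(codes)
  out <- data.table(
    claim_id = rep(mc$claim_id, n),
    patient_id = rep(mc$patient_id, n),
    service_date = rep(mc$service_date, n),
    code = gsub(".", "", unlist(codes), fixed = TRUE),
    position = unlist(lapply(n, seq_len))
  )
  out
}

# TRUE where `codes` starts with any of `prefixes` (dots already stripped)
has_prefix <- function(codes, prefixes) {
  pat <- paste0("^(", paste(gsub(".", "", prefixes, fixed = TRUE), collapse = "|"), ")")
  grepl(pat, codes)
}
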