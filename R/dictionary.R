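# Drug dictionary: maps drug codes (HCPCS/NDC-like) to therapeutic class,
# substitution group, maintenance eligibility and an imputed runout length for
# medically administered agents. The dictionary is data, not code: the bundled
# default lives in inst/extdata and any table with the same columns works.

SACT_CLASSES <- c("ICI", "PLATINUM", "NONPLAT_CHEMO", "TARGETED", "VEGF", "SCLC_TYPICAL")
DRUG_CLASSES <- c(SACT_CLASSES, "OTHER")

#' Load a drug dictionary
#'
#' Reads a delimited drug-dictionary table (one row per drug code) and validates
#' it. With `path = NULL` the dictionary bundled with the package (~40 generic
#' oncology and background agents) is loaded.
#'
#' @param path Path to a CSV with columns `drug_code`, `generic_name`,
#'   `drug_class`, `substitution_group`, `maintenance_eligible`,
#'   `default_runout_days`; `NULL` for the bundled default.
#' @return A `data.table` keyed by `drug_code`, with a derived `canonical_id`
#'   column (`substitution_group` when present, else `generic_name`).
#' @export
load_drug_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_dictionary.csv", package = "oncolot")
  }
  if (!nzchar(path) || !file.exists(path)) stopf("drug dictionary file not found: %s", path)
  dict <- data.table::fread(path, colClasses = list(character = c(
    "drug_code", "generic_name", "drug_class", "substitution_group")))
  validate_drug_dictionary(dict)
}

validate_drug_dictionary <- function(dict) {
  dict <- as.data.table(dict)
  need <- c("drug_code", "generic_name", "drug_class", "substitution_group",
            "maintenance_eligible", "default_runout_days")
  miss <- setdiff(need, names(dict))
  if (length(miss)) stopf("drug dictionary lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(dict$drug_code)) stopf("drug dictionary has duplicated drug_code values")
  bad <- setdiff(unique(dict$drug_class), DRUG_CLASSES)
  if (length(bad)) stopf("unknown drug_class values: %s", paste(bad, collapse = ", "))
  if (any(dict$default_runout_days < 1)) stopf("default_runout_days must be >= 1")
  dict[, maintenance_eligible := as.logical(maintenance_eligible)]
  dict[, default_runout_days := as.integer(default_runout_days)]
  dict[, canonical_id := fifelse(is.na(substitution_group) | substitution_group == "",
                                 generic_name, substitution_group)]
  setkey(dict, drug_code)
  dict[]
}

#' Look up a drug code in the dictionary
#'
#' @param code A single drug code.
#' @param dictionary A dictionary from [load_drug_dictionary()].
#' @return The one-row entry as a list.
#' @export
lookup_drug <- function(code, dictionary) {
  hit <- dictionary[data.table(drug_code = code), nomatch = NULL]
  if (nrow(hit) == 0L) stopf("unknown drug code: %s", code)
  as.list(hit[1L])
}

#' Is a drug a systemic anticancer therapy?
#'
#' SACT covers immune checkpoint inhibitors, platinum and non-platinum
#' chemotherapy, targeted agents, anti-VEGF agents and SCLC-typical agents;
#' everything classed `OTHER` (background medication) is not SACT.
#'
#' @param entry_or_class A dictionary entry from [lookup_drug()] or a character
#'   vector of drug classes.
#' @return Logical vector.
#' @export
is_sact <- function(entry_or_class) {
  cls <- if (is.list(entry_or_class)) entry_or_class$drug_class else entry_or_class
  cls %in% SACT_CLASSES
}
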