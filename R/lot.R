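# Line-of-therapy engine: drug episodes with runout dates, the 30-day initial
# regimen window, advancement rules (new non-regimen drug, >=60-day gap),
# substitution-group collapsing, maintenance absorption, and regimen
# classification into the seven reporting categories.

LOT_CATEGORIES <- c("ICI_MONO_DUAL", "ICI_PBCT", "ICI_NONPBCT",
                    "PBCT_MONO_COMBO", "NONPBCT_MONO", "NONPBCT_COMBO", "OTHER")
END_REASONS <- c("NEW_DRUG", "GAP", "ENROLLMENT_END", "STUDY_END", "DEATH",
                 "FOLLOWUP_END")

#' Materialize SACT claims as dated drug episodes
#'
#' One episode per systemic-anticancer claim on/after `from_date`. The runout
#' date is `fill_date + days_supply - 1` for pharmacy claims and
#' `service_date + default_runout_days - 1` for medically administered drugs
#' (claims carry no days supply for infusions, so a per-drug cycle length is
#' imputed). Drug identity is collapsed to the canonical id (substitution group
#' when one exists).
#'
#' @param ds A `claims_dataset`.
#' @param patient A patient id.
#' @param from_date Earliest episode date (the 1L start candidate).
#' @return data.table of episodes sorted by start date then canonical id:
#'   `patient_id`, `drug_code`, `canonical_id`, `drug_class`,
#'   `maintenance_eligible`, `start_date`, `runout_date`.
#' @export
build_episodes <- function(ds, patient, from_date) {
  sact <- sact_claims(ds)[patient_id == patient & date >= from_date]
  episodes_from_sact(sact)
}

episodes_from_sact <- function(sact) {
  ep <- sact[, .(patient_id, drug_code, canonical_id, drug_class,
                 maintenance_eligible, start_date = date,
                 runout_date = fifelse(source == "pharmacy",
                                       date + (days_supply - 1L),
                                       date + (default_runout_days - 1L)))]
  setorder(ep, patient_id, start_date, canonical_id)
  ep[]
}

#' Assemble the initial regimen of a line
#'
#' All SACT canonical ids whose episode starts fall in the window
#' `[lot_start, lot_start + regimen_window_days - 1]` (day 0 through day 29 by
#' default; a drug at day 30 is outside and triggers advancement evaluation).
#'
#' @param episodes Episode table from [build_episodes()].
#' @param lot_start Line start date (the first episode's start).
#' @param config An [analysis_config()].
#' @return Character vector of canonical ids (sorted, unique).
#' @export
assemble_initial_regimen <- function(episodes, lot_start, config = default_config()) {
  win_end <- lot_start + (config$regimen_window_days - 1L)
  sort(unique(episodes[start_date >= lot_start & start_date <= win_end, canonical_id]))
}

#' Evaluate one SACT episode against the current line
#'
#' The gap rule is checked first: a gap of at least `gap_days` from the latest
#' runout of the current line advances the line regardless of drug identity.
#' Otherwise an in-regimen drug continues the line (pauses and reintroductions
#' do not advance it); a maintenance-eligible drug whose backbone is in the
#' regimen is absorbed without advancing; any other new drug advances the line.
#'
#' @param regimen Character vector of canonical ids of the current regimen.
#' @param max_runout Latest runout date over all episodes of the current line.
#' @param episode One-row episode (list or data.table row) with `canonical_id`,
#'   `maintenance_eligible`, `start_date`.
#' @param config An [analysis_config()].
#' @return One of `"CONTINUE"`, `"ADVANCE_NEW_DRUG"`, `"ADVANCE_GAP"`,
#'   `"ABSORB_MAINTENANCE"`.
#' @export
evaluate_event <- function(regimen, max_runout, episode, config = default_config()) {
  gap <- days_between(max_runout, episode$start_date)
  if (gap >= config$gap_days) return("ADVANCE_GAP")
  if (episode$canonical_id %in% regimen) return("CONTINUE")
  backbone <- config$maintenance_map[[episode$canonical_id]]
  if (isTRUE(episode$maintenance_eligible) && !is.null(backbone) &&
      any(backbone %in% regimen)) {
    return("ABSORB_MAINTENANCE")
  }
  "ADVANCE_NEW_DRUG"
}

# Scan one patient's episodes into line segments. Vectors in, plain list out;
# kept free of data.table overhead because it runs once per patient.
scan_lots <- function(start_day, runout_day, canonical, maint, config,
                      followup_day, study_day, death_day) {
  n <- length(start_day)
  win <- config$regimen_window_days - 1L
  gapd <- config$gap_days
  mmap <- config$maintenance_map
  segs <- list()
  i <- 1L
  lot_no <- 0L
  while (i <= n) {
    lot_start <- start_day[i]
    # regimen window: episodes i..j with start within lot_start + win
    j <- i
    while (j < n && start_day[j + 1L] <= lot_start + win) j <- j + 1L
    regimen <- unique(canonical[i:j])
    max_run <- max(runout_day[i:j])
    advance <- NA_character_
    while (j < n) {
      k <- j + 1L
      gap <- start_day[k] - max_run
      if (gap >= gapd) { advance <- "GAP"; break }
      if (canonical[k] %in% regimen) {
        max_run <- max(max_run, runout_day[k]); j <- k; next
      }
      backbone <- mmap[[canonical[k]]]
      if (isTRUE(maint[k]) && !is.null(backbone) && any(backbone %in% regimen)) {
        max_run <- max(max_run, runout_day[k]); j <- k; next
      }
      advance <- "NEW_DRUG"; break
    }
    lot_no <- lot_no + 1L
    if (!is.na(advance)) {
      # line closed by advancement at the next episode's start
      segs[[lot_no]] <- list(lot_number = lot_no, start_day = lot_start,
                             end_day = start_day[j + 1L] - 1L,
                             regimen = regimen, max_runout = max_run,
                             end_reason = advance)
      i <- j + 1L
    } else {
      ends <- c(ENROLLMENT_END = followup_day, STUDY_END = study_day,
                DEATH = if (is.na(death_day)) .Machine$integer.max else death_day)
      segs[[lot_no]] <- list(lot_number = lot_no, start_day = lot_start,
                             end_day = min(ends), regimen = regimen,
                             max_runout = max_run,
                             end_reason = names(ends)[which.min(ends)])
      break
    }
  }
  segs
}

#' Derive lines of therapy for the eligible cohort
#'
#' Sequential scan per patient: line 1 opens at the first SACT on/after the
#' secondary-malignancy date (the index date); the initial regimen is the 30-day
#' window; each later episode either continues the line, is absorbed as
#' maintenance, or advances it (gap rule checked before the new-drug rule). A
#' line closed by advancement ends the day before the next line starts; the
#' final line ends at the earliest of enrollment end, study end, or death, with
#' the matching end reason. Every SACT episode belongs to exactly one line.
#'
#' @param ds A `claims_dataset`.
#' @param cohort Cohort table from [build_cohort()] (only `eligible` rows are
#'   scanned).
#' @param config An [analysis_config()].
#' @return data.table of line segments: `patient_id`, `lot_number`,
#'   `start_date`, `end_date`, `regimen` (pipe-delimited canonical ids),
#'   `category`, `max_runout`, `end_reason`, plus per-patient `followup_end`
#'   (earliest of enrollment end, study end, death).
#' @export
derive_lots <- function(ds, cohort, config = default_config()) {
  elig <- cohort[eligible == TRUE, .(patient_id, index_date)]
  empty <- data.table(patient_id = character(), lot_number = integer(),
                      start_date = as.Date(character()), end_date = as.Date(character()),
                      regimen = character(), category = character(),
                      max_runout = as.Date(character()), end_reason = character(),
                      followup_end = as.Date(character()))
  if (nrow(elig) == 0L) return(empty)

  sact <- sact_claims(ds)
  sact <- merge(sact, elig, by = "patient_id")
  sact <- sact[date >= index_date]
  ep <- episodes_from_sact(sact)

  # follow-up end: end of the merged enrollment span chain covering the index,
  # capped at study end and death
  enr <- merge(ds$enrollment[medical == TRUE & pharmacy == TRUE],
               elig, by = "patient_id")
  fu <- enr[start_date <= index_date & end_date >= index_date,
            .(enroll_end = max(end_date)), by = patient_id]
  fu <- merge(elig, fu, by = "patient_id", all.x = TRUE)
  fu[is.na(enroll_end), enroll_end := index_date]  # defensive; eligible rows have coverage
  fu <- merge(fu, ds$patients[, .(patient_id, death_date)], by = "patient_id")

  ep <- merge(ep, fu[, .(patient_id, enroll_end, death_date)], by = "patient_id")
  origin <- as.Date("1970-01-01")
  study_day <- as.integer(config$study_end)

  by_pat <- split(ep, by = "patient_id", keep.by = TRUE)
  out <- vector("list", length(by_pat))
  for (pi in seq_along(by_pat)) {
    e <- by_pat[[pi]]
    segs <- scan_lots(as.integer(e$start_date), as.integer(e$runout_date),
                      e$canonical_id, e$maintenance_eligible, config,
                      followup_day = as.integer(e$enroll_end[1L]),
                      study_day = study_day,
                      death_day = as.integer(e$death_date[1L]))
    cls <- ds$drug_dictionary
    out[[pi]] <- data.table(
      patient_id = e$patient_id[1L],
      lot_number = vapply(segs, `[[`, integer(1), "lot_number"),
      start_date = as.Date(vapply(segs, `[[`, numeric(1), "start_day"), origin = origin),
      end_date = as.Date(vapply(segs, `[[`, numeric(1), "end_day"), origin = origin),
      regimen = vapply(segs, function(s) paste(sort(s$regimen), collapse = "|"), character(1)),
      max_runout = as.Date(vapply(segs, `[[`, numeric(1), "max_runout"), origin = origin),
      end_reason = vapply(segs, `[[`, character(1), "end_reason")
    )
  }
  segs <- rbindlist(out)
  segs[, category := classify_regimen_str(regimen, ds$drug_dictionary)]
  segs <- merge(segs, fu[, .(patient_id, enroll_end, death_date)], by = "patient_id")
  segs[, followup_end := pmin_date(enroll_end, rep(config$study_end, .N),
                                   fifelse(is.na(death_date), as.Date("9999-12-31"), death_date))]
  segs[, c("enroll_end", "death_date") := NULL]
  setcolorder(segs, c("patient_id", "lot_number", "start_date", "end_date",
                      "regimen", "category", "max_runout", "end_reason",
                      "followup_end"))
  setorder(segs, patient_id, lot_number)
  segs[]
}

#' Classify a regimen into a reporting category
#'
#' Categories: ICI only (mono/dual); ICI + platinum-based chemotherapy;
#' ICI + non-platinum chemotherapy; platinum mono/combination (no ICI);
#' single non-platinum chemotherapy; non-platinum combination; other. Anti-VEGF
#' agents never change an otherwise-determined chemotherapy/ICI category, but a
#' regimen with a VEGF agent and no chemotherapy of any kind (e.g. VEGF only,
#' VEGF + ICI) is classed OTHER, as are regimens with targeted or SCLC-typical
#' agents only.
#'
#' @param regimen Character vector of canonical ids (or a single pipe-delimited
#'   string).
#' @param dictionary Drug dictionary (see [load_drug_dictionary()]).
#' @return One of `LOT_CATEGORIES`.
#' @export
classify_regimen <- function(regimen, dictionary) {
  if (length(regimen) == 1L && grepl("|", regimen, fixed = TRUE)) {
    regimen <- strsplit(regimen, "|", fixed = TRUE)[[1L]]
  }
  regimen <- unique(regimen)
  if (length(regimen) == 0L || all(regimen == "")) return("OTHER")
  cls_map <- unique(dictionary[, .(canonical_id, drug_class)])
  cls <- cls_map[data.table(canonical_id = regimen), on = "canonical_id", drug_class]
  if (anyNA(cls)) stopf("unknown canonical id(s) in regimen: %s",
                        paste(regimen[is.na(cls)], collapse = ", "))
  has_ici <- any(cls == "ICI")
  has_plat <- any(cls == "PLATINUM")
  n_chemo <- sum(cls %in% c("NONPLAT_CHEMO", "SCLC_TYPICAL"))
  has_vegf <- any(cls == "VEGF")
  has_targ <- any(cls == "TARGETED")
  if (has_vegf && !has_plat && n_chemo == 0L) return("OTHER")
  if (has_ici && has_plat) return("ICI_PBCT")
  if (has_ici && n_chemo > 0L) return("ICI_NONPBCT")
  if (has_ici && !has_targ) return("ICI_MONO_DUAL")
  if (has_plat) return("PBCT_MONO_COMBO")
  if (n_chemo == 1L && !has_targ) return("NONPBCT_MONO")
  if (n_chemo >= 2L && !has_targ) return("NONPBCT_COMBO")
  "OTHER"
}

classify_regimen_str <- function(regimens, dictionary) {
  u <- unique(regimens)
  cats <- vapply(u, classify_regimen, character(1), dictionary = dictionary)
  unname(cats[match(regimens, u)])
}
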