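#' Split a canonical lab table into raw multi-source extracts
#'
#' Produces the kind of raw tables an EMR export yields: per-source tables
#' with local test codes and character results, a share of records present
#' in both sources (duplicates), and a sprinkle of non-numeric results
#' ("QNS") and unmapped test codes, so [load_lab_results()] has real work to
#' do. Used by the synthetic cohort and by tests.
#'
#' @param labs Output of [simulate_lab_series()].
#' @param config The [sim_config()] (for `dup_rate` and the derived seed).
#' @return List: `sources` (list of raw data frames with columns
#'   `patient_id`, `test_code`, `sample_date`, `result`, `accession`,
#'   `unit`) and `code_map` (named vector raw code -> trait).
#' @export
emr_source_tables <- function(labs, config) {
  set.seed(derive_seed(config$seed, "fixtures"))
  code_map <- stats::setNames(RBC_TRAITS, paste0("C_", RBC_TRAITS))
  raw <- data.frame(
    patient_id = labs$patient_id,
    test_code = paste0("C_", labs$trait),
    sample_date = labs$sample_date,
    result = formatC(labs$value, digits = 6, format = "g"),
    accession = labs$accession,
    unit = unname(TRAIT_UNITS[labs$trait]),
    stringsAsFactors = FALSE
  )
  nr <- nrow(raw)
  qns <- stats::runif(nr) < 0.01
  raw$result[qns] <- "QNS"
  unmapped <- raw[sample.int(nr, max(1L, round(0.01 * nr))), , drop = FALSE]
  unmapped$test_code <- "C_WBC"
  dup <- raw[stats::runif(nr) < config$dup_rate, , drop = FALSE]
  list(sources = list(LAB_A = rbind(raw, unmapped), LAB_B = dup),
       code_map = code_map)
}

#' Load and harmonize multi-source lab-result tables
#'
#' Merges raw extracts from several source systems into one canonical lab
#' table: raw test codes are mapped to traits via `code_map` (unmapped
#' records dropped), non-numeric result text is dropped, and duplicates on
#' (patient, accession, trait) are collapsed to a single record. Unit
#' strings, when present, are validated against the per-trait whitelist and
#' mismatches dropped. A load report accounts for every input record.
#'
#' @param source_tables List of raw data frames, each with columns
#'   `patient_id`, `test_code`, `sample_date`, `result`, `accession` and
#'   optionally `unit`. List names are used as the `source` column.
#' @param code_map Named character vector mapping raw test codes to traits.
#' @return List: `labs` (canonical table with `value_id`, `patient_id`,
#'   `trait`, `value`, `sample_date`, `accession`, `source`) and `report`
#'   (named counts: `input`, `kept`, `unmapped_code`, `non_numeric`,
#'   `bad_unit`, `duplicate`).
#' @export
load_lab_results <- function(source_tables, code_map) {
  needed <- c("patient_id", "test_code", "sample_date", "result", "accession")
  if (is.null(names(source_tables)))
    names(source_tables) <- paste0("source", seq_along(source_tables))
  for (nm in names(source_tables)) {
    missing_cols <- setdiff(needed, names(source_tables[[nm]]))
    stop_if(length(missing_cols) > 0, "source '%s' is missing column(s): %s",
            nm, paste(missing_cols, collapse = ", "))
  }
  raw <- do.call(rbind, lapply(names(source_tables), function(nm) {
    x <- source_tables[[nm]]
    x$source <- nm
    if (!"unit" %in% names(x)) x$unit <- NA_character_
    x[c(needed, "unit", "source")]
  }))
  report <- c(input = nrow(raw), kept = 0L, unmapped_code = 0L,
              non_numeric = 0L, bad_unit = 0L, duplicate = 0L)

  trait <- unname(code_map[raw$test_code])
  keep <- !is.na(trait)
  report["unmapped_code"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]; trait <- trait[keep]

  value <- suppressWarnings(as.numeric(raw$result))
  keep <- is.finite(value)
  report["non_numeric"] <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]; trait <- trait[keep]
  value <- value[keep]

  unit_ok <- is.na(raw$unit) | raw$unit == unname(TRAIT_UNITS[trait])
  report["bad_unit"] <- sum(!unit_ok)
  raw <- raw[unit_ok, , drop = FALSE]; trait <- trait[unit_ok]
  value <- value[unit_ok]

  key <- paste(raw$patient_id, raw$accession, trait, sep = "\r")
  dup <- duplicated(key)
  report["duplicate"] <- sum(dup)
  raw <- raw[!dup, , drop = FALSE]; trait <- trait[!dup]
  value <- value[!dup]

  labs <- data.frame(
    value_id = paste0(raw$accession, ":", trait),
    patient_id = raw$patient_id, trait = trait, value = value,
    sample_date = as_day(raw$sample_date), accession = raw$accession,
    source = raw$source, stringsAsFactors = FALSE
  )
  labs <- labs[order(labs$patient_id, labs$sample_date, labs$accession,
                     labs$trait), , drop = FALSE]
  rownames(labs) <- NULL
  report["kept"] <- nrow(labs)
  list(labs = labs, report = report)
}

#' Flag lab values drawn during an inpatient hospitalization
#'
#' A value is flagged iff some episode of the same patient satisfies
#' admit date <= sample date <= discharge date (both boundaries inclusive).
#'
#' @param labs Canonical lab table.
#' @param episodes Data frame `patient_id`, `admit_date`, `discharge_date`.
#' @return `labs` with a logical `inpatient` column.
#' @export
flag_inpatient <- function(labs, episodes) {
  stop_if(any(as_day(episodes$admit_date) > as_day(episodes$discharge_date)),
          "episode with admit date after discharge date")
  labs$inpatient <- FALSE
  if (nrow(episodes) > 0) {
    admit <- as_day(episodes$admit_date)
    disch <- as_day(episodes$discharge_date)
    ep_by_patient <- split(seq_len(nrow(episodes)), episodes$patient_id)
    for (pid in names(ep_by_patient)) {
      rows <- which(labs$patient_id == pid)
      if (!length(rows)) next
      idx <- ep_by_patient[[pid]]
      d <- labs$sample_date[rows]
      hit <- rep(FALSE, length(rows))
      for (e in idx) hit <- hit | (admit[e] <= d & d <= disch[e])
      labs$inpatient[rows] <- hit
    }
  }
  labs
}

#' Apply the inpatient exclusion with the only-tests-available rescue
#'
#' Inpatient-flagged values are removed unless, for a given patient and
#' trait, ALL values are flagged — then they are retained (otherwise the
#' patient would lose that trait entirely). The rescue granularity is
#' per (patient, trait) by default; `rescue = "patient"` rescues only when a
#' patient's values across all traits are inpatient.
#'
#' @param flagged_labs Output of [flag_inpatient()].
#' @param rescue `"patient_trait"` (default) or `"patient"`.
#' @return List `kept` and `excluded`, partitioning the input rows.
#' @export
apply_inpatient_exclusion <- function(flagged_labs,
                                      rescue = c("patient_trait", "patient")) {
  rescue <- match.arg(rescue)
  stop_if(!"inpatient" %in% names(flagged_labs),
          "run flag_inpatient() first (no inpatient column)")
  key <- if (rescue == "patient_trait") {
    paste(flagged_labs$patient_id, flagged_labs$trait)
  } else flagged_labs$patient_id
  all_in <- tapply(flagged_labs$inpatient, key, all)[key]
  drop <- flagged_labs$inpatient & !all_in
  list(kept = flagged_labs[!drop, , drop = FALSE],
       excluded = flagged_labs[drop, , drop = FALSE])
}
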