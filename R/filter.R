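#' Build per-patient exclusion intervals from coded events
#'
#' Each event that matches a registry entry (exact code or `*`-prefix, same
#' code system) yields the interval
#' `[event_date - lookback, event_date + duration]` of the entry's window
#' policy, closed at both finite ends and unbounded on the right for chronic
#' policies. Events with `code_system == "NLP"` (from
#' [detect_medication_mentions()]) are assigned category `medication_nlp`
#' under the `medication` policy. Overlapping or touching intervals of the
#' same category for the same patient are merged, pooling their triggering
#' event ids. Events whose code system is unknown are skipped with a
#' warning and counted.
#'
#' @param events Data frame `event_id`, `patient_id`, `code_system`, `code`,
#'   `event_date`.
#' @param registry Code registry, see [default_code_registry()].
#' @param policies Window policies, see [default_window_policies()].
#' @return Data frame of intervals: `patient_id`, `category`, `start`,
#'   `end` (possibly `Inf`), `event_ids` (`;`-joined), with attribute
#'   `n_skipped` (events with unknown code system).
#' @export
build_exclusion_windows <- function(events, registry = default_code_registry(),
                                    policies = default_window_policies()) {
  validate_registry(registry, policies)
  ivs <- list()
  n_skipped <- 0L
  for (e in seq_len(nrow(events))) {
    cs <- events$code_system[e]
    if (cs == "NLP") {
      pol <- policies[["medication"]]
      ivs[[length(ivs) + 1L]] <- data.frame(
        patient_id = events$patient_id[e], category = "medication_nlp",
        start = as_day(events$event_date[e]) - pol$lookback_days,
        end = as_day(events$event_date[e]) + pol$duration_days,
        event_ids = events$event_id[e], stringsAsFactors = FALSE)
      next
    }
    if (!cs %in% CODE_SYSTEMS) {
      n_skipped <- n_skipped + 1L
      warning("skipping event ", events$event_id[e],
              ": unknown code system '", cs, "'", call. = FALSE)
      next
    }
    for (r in which(registry$code_system == cs)) {
      if (code_matches(events$code[e], registry$code[r])) {
        pol <- policies[[registry$policy[r]]]
        ivs[[length(ivs) + 1L]] <- data.frame(
          patient_id = events$patient_id[e],
          category = registry$category[r],
          start = as_day(events$event_date[e]) - pol$lookback_days,
          end = as_day(events$event_date[e]) + pol$duration_days,
          event_ids = events$event_id[e], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(ivs)) {
    out <- data.frame(patient_id = character(), category = character(),
                      start = numeric(), end = numeric(),
                      event_ids = character(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  iv <- do.call(rbind, ivs)
  merged <- list()
  for (grp in split(iv, paste(iv$patient_id, iv$category, sep = "\r"))) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (k in seq_len(nrow(grp))[-1]) {
      if (grp$start[k] <= cur$end) {   # overlap or touch: merge
        cur$end <- max(cur$end, grp$end[k])
        cur$event_ids <- paste(cur$event_ids, grp$event_ids[k], sep = ";")
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- grp[k, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$patient_id, out$category, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Detect medication mentions in clinical notes
#'
#' Case-insensitive whole-word matching of lexicon terms; multi-word brand
#' names match as phrases. Each (note, matched term) pair becomes one
#' NLP-derived event dated by the note.
#'
#' @param notes Data frame `note_id`, `patient_id`, `note_date`, `text`.
#' @param lexicon Data frame `name`, `class`; must be non-empty.
#' @return Event table with `code_system = "NLP"`, `code` = matched term and
#'   `category = "medication_nlp"`.
#' @export
detect_medication_mentions <- function(notes,
                                       lexicon = default_medication_lexicon()) {
  validate_lexicon(lexicon)
  hits <- list()
  patterns <- paste0("\\b",
                     gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lexicon$name),
                     "\\b")
  for (i in seq_len(nrow(notes))) {
    for (k in seq_len(nrow(lexicon))) {
      if (grepl(patterns[k], notes$text[i], ignore.case = TRUE, perl = TRUE)) {
        hits[[length(hits) + 1L]] <- data.frame(
          event_id = paste0(notes$note_id[i], ":", lexicon$name[k]),
          patient_id = notes$patient_id[i],
          code_system = "NLP", code = lexicon$name[k],
          event_date = as_day(notes$note_date[i]),
          category = "medication_nlp", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(event_id = character(), patient_id = character(),
                      code_system = character(), code = character(),
                      event_date = integer(), category = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Decide keep/exclude for every lab value against exclusion windows
#'
#' A value is excluded iff its sample date lies within at least one of its
#' patient's intervals (closed at both finite ends); all covering categories
#' are recorded as reasons, together with the triggering event ids. The
#' decision depends only on (patient, date), so it is independent of record
#' order.
#'
#' @param labs Canonical lab table.
#' @param windows Output of [build_exclusion_windows()].
#' @return Filter-result data frame: `value_id`, `patient_id`, `trait`,
#'   `sample_date`, `decision` (`"keep"`/`"exclude"`), `reasons`
#'   (`;`-joined categories, `""` for kept), `event_ids`.
#' @export
exclude_values <- function(labs, windows) {
  n <- nrow(labs)
  decision <- rep("keep", n)
  reasons <- character(n)
  event_ids <- character(n)
  win_by_patient <- split(windows, windows$patient_id)
  for (pid in names(win_by_patient)) {
    rows <- which(labs$patient_id == pid)
    if (!length(rows)) next
    w <- win_by_patient[[pid]]
    for (v in rows) {
      d <- labs$sample_date[v]
      hit <- w$start <= d & d <= w$end
      if (any(hit)) {
        decision[v] <- "exclude"
        reasons[v] <- paste(sort(unique(w$category[hit])), collapse = ";")
        event_ids[v] <- paste(unlist(strsplit(w$event_ids[hit], ";")),
                              collapse = ";")
      }
    }
  }
  data.frame(value_id = labs$value_id, patient_id = labs$patient_id,
             trait = labs$trait, sample_date = labs$sample_date,
             decision = decision, reasons = reasons, event_ids = event_ids,
             stringsAsFactors = FALSE)
}

#' Drop patients with no remaining trait values
#'
#' A patient is dropped iff no value of any trait survives the exclusions.
#' Because each blood draw reports several traits on several dates, most
#' patients retain at least one usable value and the patient-level loss is
#' far smaller than the value-level loss.
#'
#' @param filter_result Output of [exclude_values()] (decisions for the
#'   values that entered the filter).
#' @param labs The lab table the decisions refer to.
#' @return List: `cohort` (retained patient ids), `dropped` (patient ids),
#'   `per_trait` (data frame: trait, patients with >= 1 kept value).
#' @export
drop_empty_patients <- function(filter_result, labs) {
  stop_if(!setequal(filter_result$value_id, labs$value_id),
          "filter_result and labs cover different values")
  kept <- filter_result[filter_result$decision == "keep", , drop = FALSE]
  all_patients <- sort(unique(labs$patient_id))
  cohort <- sort(unique(kept$patient_id))
  per_trait <- data.frame(
    trait = RBC_TRAITS,
    n_patients = vapply(RBC_TRAITS, function(t)
      length(unique(kept$patient_id[kept$trait == t])), integer(1)),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, dropped = setdiff(all_patients, cohort),
       per_trait = per_trait)
}
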