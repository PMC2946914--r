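NOTE_TEMPLATES_MED <- c(
  "Patient started on %s today for disease management.",
  "Continuing %s 10 mg weekly; counts stable.",
  "%s initiated by oncology service; monitor CBC closely."
)
NOTE_TEMPLATES_DECOY <- c(
  "Routine follow-up visit; no changes to current regimen.",
  "Discussed diet and exercise; laboratory studies reviewed.",
  "Annual examination unremarkable; return in one year."
)

# Materialize a concrete code from a registry pattern ("282*" -> "2820" etc.)
materialize_code <- function(pattern) {
  if (endsWith(pattern, "*")) {
    paste0(substr(pattern, 1L, nchar(pattern) - 1L),
           sample(0:9, 1L))
  } else pattern
}

#' Simulate confounding events, hospitalizations and notes, with truth labels
#'
#' Plants coded clinical events drawn from the registry, inpatient episodes,
#' and clinical notes mentioning lexicon drugs, then labels every lab value
#' with the ground-truth keep/exclude decision. The truth labeling is a
#' direct, independent evaluation of the configured window policies (a plain
#' per-value scan over raw events/episodes/notes); it deliberately shares no
#' code with the filtering module so it can serve as its oracle.
#'
#' @param patients Output of [simulate_patients()].
#' @param labs Output of [simulate_lab_series()].
#' @param config The same [sim_config()].
#' @param registry Code registry, default [default_code_registry()].
#' @param lexicon Medication lexicon, default [default_medication_lexicon()].
#' @param policies Window policies, default [default_window_policies()].
#' @return List with `events` (`event_id`, `patient_id`, `code_system`,
#'   `code`, `event_date`), `episodes` (`patient_id`, `admit_date`,
#'   `discharge_date`), `notes` (`note_id`, `patient_id`, `note_date`,
#'   `text`) and `truth` (`value_id`, `should_be_excluded`, `reason`).
#' @export
simulate_confounders <- function(patients, labs, config,
                                 registry = default_code_registry(),
                                 lexicon = default_medication_lexicon(),
                                 policies = default_window_policies()) {
  validate_registry(registry, policies)
  validate_lexicon(lexicon)
  set.seed(derive_seed(config$seed, "confounders"))
  n <- nrow(patients)
  span <- config$span_days
  rates <- config$event_rates

  events <- list(); notes <- list(); episodes <- list()
  draw_dates <- split(labs$sample_date, labs$patient_id)
  rate_of <- function(cat) if (cat %in% names(rates)) rates[[cat]] else 0
  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    anchors <- unique(draw_dates[[pid]])
    if (is.null(anchors)) anchors <- sample(0:span, 1L)
    for (cat in c("condition", "transplant")) {
      if (stats::runif(1) < rate_of(cat)) {
        entry <- registry[sample(which(registry$category == cat), 1L), ]
        events[[length(events) + 1L]] <- data.frame(
          patient_id = pid, code_system = entry$code_system,
          code = materialize_code(entry$code),
          event_date = sample(seq(-round(0.1 * span), span), 1L),
          stringsAsFactors = FALSE)
      }
    }
    # treatment exposure recurs and coincides with clinic visits, so
    # medication codes/notes (and surgery) are anchored on draw dates
    for (cat in c("medication_code", "surgery_blood_loss")) {
      if (stats::runif(1) < rate_of(cat)) {
        k <- 1L + stats::rpois(1, 2)
        entry <- registry[sample(which(registry$category == cat), 1L), ]
        for (d in sample(anchors, k, replace = TRUE)) {
          events[[length(events) + 1L]] <- data.frame(
            patient_id = pid, code_system = entry$code_system,
            code = materialize_code(entry$code), event_date = d,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (stats::runif(1) < config$hospitalization_rate) {
      admit <- sample(anchors, 1L) - sample(0:2, 1L)
      episodes[[length(episodes) + 1L]] <- data.frame(
        patient_id = pid, admit_date = admit,
        discharge_date = admit + 1L + stats::rpois(1, 3),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < rate_of("medication_nlp")) {
      term <- lexicon$name[sample.int(nrow(lexicon), 1L)]
      k <- 1L + stats::rpois(1, 2)
      for (d in sample(anchors, k, replace = TRUE)) {
        notes[[length(notes) + 1L]] <- data.frame(
          patient_id = pid, note_date = d,
          text = sprintf(sample(NOTE_TEMPLATES_MED, 1L), term),
          stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < 0.25) {  # decoy note without drug mentions
      notes[[length(notes) + 1L]] <- data.frame(
        patient_id = pid, note_date = sample(0:span, 1L),
        text = sample(NOTE_TEMPLATES_DECOY, 1L),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  events <- bind(events, data.frame(patient_id = character(),
                                    code_system = character(),
                                    code = character(),
                                    event_date = integer(),
                                    stringsAsFactors = FALSE))
  episodes <- bind(episodes, data.frame(patient_id = character(),
                                        admit_date = integer(),
                                        discharge_date = integer(),
                                        stringsAsFactors = FALSE))
  notes <- bind(notes, data.frame(patient_id = character(),
                                  note_date = integer(), text = character(),
                                  stringsAsFactors = FALSE))
  if (nrow(events)) events <- cbind(event_id = sprintf("E%06d", seq_len(nrow(events))), events, stringsAsFactors = FALSE)
  else events$event_id <- character()
  if (nrow(notes)) notes <- cbind(note_id = sprintf("N%06d", seq_len(nrow(notes))), notes, stringsAsFactors = FALSE)
  else notes$note_id <- character()

  truth <- truth_labels(labs, events, episodes, notes,
                        registry, lexicon, policies)
  list(events = events, episodes = episodes, notes = notes, truth = truth)
}

# --- independent truth labeler (the oracle for the filtering module) ------
# A direct per-value scan: no interval construction or merging, no regexes
# shared with the filter; notes are tokenized and matched n-gram-wise.

truth_note_mentions <- function(text, lexicon) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  hits <- character()
  for (nm in lexicon$name) {
    words <- strsplit(tolower(nm), " ")[[1]]
    k <- length(words)
    if (length(toks) >= k) {
      for (s in seq_len(length(toks) - k + 1L)) {
        if (all(toks[s:(s + k - 1L)] == words)) {
          hits <- c(hits, nm)
          break
        }
      }
    }
  }
  hits
}

truth_labels <- function(labs, events, episodes, notes,
                         registry, lexicon, policies) {
  n <- nrow(labs)
  excluded <- logical(n)
  reason <- character(n)

  # per-patient, per-trait: are ALL values inpatient-covered? (rescue rule)
  in_episode <- function(pid, day) {
    ep <- episodes[episodes$patient_id == pid, , drop = FALSE]
    any(ep$admit_date <= day & day <= ep$discharge_date)
  }
  inpatient_flag <- mapply(in_episode, labs$patient_id, labs$sample_date)
  key <- paste(labs$patient_id, labs$trait)
  all_inpatient <- tapply(inpatient_flag, key, all)[key]

  for (v in seq_len(n)) {
    pid <- labs$patient_id[v]
    day <- labs$sample_date[v]
    reasons <- character()
    if (inpatient_flag[v] && !all_inpatient[v]) reasons <- c(reasons, "inpatient")

    ev <- events[events$patient_id == pid, , drop = FALSE]
    for (e in seq_len(nrow(ev))) {
      for (r in seq_len(nrow(registry))) {
        if (registry$code_system[r] == ev$code_system[e] &&
            code_matches(ev$code[e], registry$code[r])) {
          pol <- policies[[registry$policy[r]]]
          lo <- ev$event_date[e] - pol$lookback_days
          hi <- ev$event_date[e] + pol$duration_days
          if (day >= lo && day <= hi) reasons <- c(reasons, registry$category[r])
        }
      }
    }
    nt <- notes[notes$patient_id == pid, , drop = FALSE]
    for (e in seq_len(nrow(nt))) {
      if (length(truth_note_mentions(nt$text[e], lexicon))) {
        pol <- policies[["medication"]]
        lo <- nt$note_date[e] - pol$lookback_days
        hi <- nt$note_date[e] + pol$duration_days
        if (day >= lo && day <= hi) reasons <- c(reasons, "medication_nlp")
      }
    }
    reasons <- sort(unique(reasons))
    excluded[v] <- length(reasons) > 0
    reason[v] <- paste(reasons, collapse = ";")
  }
  data.frame(value_id = labs$value_id, patient_id = labs$patient_id,
             trait = labs$trait, sample_date = labs$sample_date,
             should_be_excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}
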