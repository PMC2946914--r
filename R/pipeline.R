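#' Validate a pipeline run configuration
#'
#' Checks ranges, trait/covariate names and referenced paths without
#' mutating anything; problems are returned, not raised.
#'
#' @param config Named list: either `sim` (a [sim_config()]) for a synthetic
#'   run or paths `labs`, `events`, `episodes`, `notes`, `ped_prefix`; plus
#'   optional `thresholds` ([qc_thresholds()]), `traits`, `covars`, `seed`.
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  synthetic <- !is.null(config$sim)
  if (synthetic) {
    ok <- tryCatch({ validate_sim_config(config$sim); TRUE },
                   error = function(e) { problems <<- c(problems, conditionMessage(e)); FALSE })
  } else {
    for (f in c("labs", "events", "episodes", "notes")) {
      if (is.null(config[[f]])) {
        problems <- c(problems, sprintf("missing input path: %s", f))
      } else if (!file.exists(config[[f]])) {
        problems <- c(problems, sprintf("file not found: %s (%s)", config[[f]], f))
      }
    }
    if (is.null(config$ped_prefix)) {
      problems <- c(problems, "missing input path: ped_prefix")
    } else if (!file.exists(paste0(config$ped_prefix, ".ped"))) {
      problems <- c(problems, sprintf("file not found: %s.ped", config$ped_prefix))
    }
  }
  if (!is.null(config$thresholds)) {
    tryCatch(do.call(qc_thresholds, config$thresholds[
      intersect(names(config$thresholds),
                c("snp_call_rate_min", "sample_call_rate_min",
                  "maf_min", "hwe_p_min", "sample_exclusion_list"))]),
      error = function(e) problems <<- c(problems, conditionMessage(e)))
  }
  if (!is.null(config$traits) && !all(config$traits %in% RBC_TRAITS)) {
    problems <- c(problems, sprintf("unknown trait(s): %s",
      paste(setdiff(config$traits, RBC_TRAITS), collapse = ", ")))
  }
  if (!is.null(config$covars) &&
      !all(config$covars %in% c("age", "sex", "pad"))) {
    problems <- c(problems, sprintf("unknown covariate(s): %s",
      paste(setdiff(config$covars, c("age", "sex", "pad")), collapse = ", ")))
  }
  problems
}

#' Run the full phenotyping-to-association pipeline
#'
#' Orchestrates simulate (optional) -> inpatient exclusion -> code/NLP
#' exclusion -> patient drop -> median aggregation -> genotype QC ->
#' association -> genomic control, with a funnel table that must reconcile
#' exactly at every stage boundary (any discrepancy aborts). When `out_dir`
#' is given, every stage output is written there as TSV/JSON together with
#' the seed and funnel.
#'
#' @param config See [validate_config()]. For synthetic runs, supply
#'   `config$sim`.
#' @param out_dir Optional output directory (created if needed).
#' @return List: `cohort` tables, `phenotypes`, `summary`, `qc`, `gwas`
#'   (with `p_gc`), `lambda` (per trait), `significant` (rows at the
#'   genome-wide threshold), `funnel`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  problems <- validate_config(config)
  stop_if(length(problems) > 0, "invalid config:\n  %s",
          paste(problems, collapse = "\n  "))
  traits <- config$traits %||% RBC_TRAITS
  covars <- config$covars %||% c("age", "sex", "pad")
  registry <- config$registry %||% default_code_registry()
  lexicon <- config$lexicon %||% default_medication_lexicon()
  policies <- config$policies %||% default_window_policies()
  thresholds <- if (is.null(config$thresholds)) qc_thresholds() else
    do.call(qc_thresholds, config$thresholds)

  if (!is.null(config$sim)) {
    cohort <- simulate_emr_cohort(config$sim, registry = registry,
                                  lexicon = lexicon, policies = policies)
  } else {
    labs_raw <- read_tsv(config$labs)
    cohort <- list(
      labs = data.frame(labs_raw[c("value_id", "patient_id", "trait", "value")],
                        sample_date = as_day(labs_raw$sample_date),
                        accession = labs_raw$accession,
                        source = labs_raw$source, stringsAsFactors = FALSE),
      events = read_tsv(config$events),
      episodes = read_tsv(config$episodes),
      notes = read_tsv(config$notes),
      genotypes = read_plink(config$ped_prefix),
      patients = read_tsv(config$patients))
  }

  funnel <- list()
  tick <- function(stage, n) funnel[[length(funnel) + 1L]] <<-
    data.frame(stage = stage, n = n, stringsAsFactors = FALSE)
  n_in <- nrow(cohort$labs)
  tick("values_in", n_in)

  flagged <- flag_inpatient(cohort$labs, cohort$episodes)
  inpat <- apply_inpatient_exclusion(flagged)
  stop_if(nrow(inpat$kept) + nrow(inpat$excluded) != n_in,
          "funnel mismatch at inpatient exclusion")
  tick("inpatient_excluded", nrow(inpat$excluded))
  tick("after_inpatient", nrow(inpat$kept))

  nlp_events <- detect_medication_mentions(cohort$notes, lexicon)
  windows <- build_exclusion_windows(rbind(cohort$events,
                                           nlp_events[names(cohort$events)]),
                                     registry, policies)
  decisions <- exclude_values(inpat$kept, windows)
  kept <- inpat$kept[decisions$decision == "keep", , drop = FALSE]
  stop_if(nrow(kept) + sum(decisions$decision == "exclude") !=
            nrow(inpat$kept), "funnel mismatch at window exclusion")
  tick("window_excluded", sum(decisions$decision == "exclude"))
  tick("after_windows", nrow(kept))

  drops <- drop_empty_patients(decisions, inpat$kept)
  tick("patients_in", length(unique(cohort$labs$patient_id)))
  tick("patients_dropped", length(drops$dropped))
  tick("patients_kept", length(drops$cohort))

  phenotypes <- aggregate_median(kept, cohort$patients)
  tick("phenotype_rows", nrow(phenotypes))
  summary_tab <- cohort_summary(phenotypes)

  qc <- apply_qc(cohort$genotypes, thresholds)
  tick("markers_in", ncol(cohort$genotypes$dosage))
  tick("markers_qc_pass", ncol(qc$genotypes$dosage))

  gwas <- run_gwas(qc$genotypes, phenotypes, traits = traits, covars = covars)
  tick("association_rows", nrow(gwas))
  lambda <- vapply(traits, function(tr)
    genomic_lambda(gwas[gwas$trait == tr, ]), numeric(1))
  gwas <- do.call(rbind, lapply(traits, function(tr)
    gc_adjust(gwas[gwas$trait == tr, ], lambda[[tr]])))
  rownames(gwas) <- NULL
  significant <- gwas[is.finite(gwas$p) & gwas$p < 5e-8, , drop = FALSE]

  funnel <- do.call(rbind, funnel)
  result <- list(cohort = cohort, inpatient = inpat, decisions = decisions,
                 kept_labs = kept, drops = drops, phenotypes = phenotypes,
                 summary = summary_tab, qc = qc, gwas = gwas,
                 lambda = lambda, significant = significant, funnel = funnel)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_tsv(summary_tab, file.path(out_dir, "cohort_summary.tsv"))
    write_tsv(decisions, file.path(out_dir, "filter_audit.tsv"))
    write_tsv(gwas, file.path(out_dir, "association.tsv"))
    write_tsv(funnel, file.path(out_dir, "funnel.tsv"))
    for (tr in traits) {
      write_tsv(qq_data(gwas[gwas$trait == tr, ]),
                file.path(out_dir, sprintf("qq_%s.tsv", tr)))
    }
    jsonlite::write_json(
      list(seed = config$sim$seed %||% config$seed %||% NA,
           lambda = as.list(lambda),
           qc_steps = qc$report$steps,
           n_significant = nrow(significant)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
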