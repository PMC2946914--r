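#!/usr/bin/env Rscript
# Stage 2: multi-source extraction and the exclusion algorithm. Splits the
# canonical labs into raw source extracts, reloads them through the
# harmonizing loader, applies the inpatient rule and the code/NLP exclusion
# windows, and audits every decision against the generator's truth labels.

source("analysis/_config.R")
cdir <- "results/cohort"
out <- "results/filter"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- study_config()
labs <- read.delim(file.path(cdir, "labs.tsv"))
events <- read.delim(file.path(cdir, "events.tsv"),
                     colClasses = c(code = "character"))
episodes <- read.delim(file.path(cdir, "episodes.tsv"))
notes <- read.delim(file.path(cdir, "notes.tsv"))
truth <- read.delim(file.path(cdir, "truth.tsv"))

# raw multi-source extracts -> canonical table, with a load report
src <- emr_source_tables(labs, cfg)
loaded <- load_lab_results(src$sources, src$code_map)
cat("load report:\n"); print(loaded$report)

# the canonical (pre-noise) labs continue downstream so the truth audit
# covers every simulated value
flagged <- flag_inpatient(labs, episodes)
inpat <- apply_inpatient_exclusion(flagged)
cat(sprintf("inpatient-excluded values: %d of %d\n",
            nrow(inpat$excluded), nrow(labs)))

nlp <- detect_medication_mentions(notes)
cat(sprintf("NLP medication events: %d from %d notes\n",
            nrow(nlp), nrow(notes)))
windows <- build_exclusion_windows(rbind(events, nlp[names(events)]))
decisions <- exclude_values(inpat$kept, windows)
cat(sprintf("window-excluded values: %d\n",
            sum(decisions$decision == "exclude")))

drops <- drop_empty_patients(decisions, inpat$kept)
cat(sprintf("patients dropped (no values left): %d of %d\n",
            length(drops$dropped), length(unique(labs$patient_id))))

# audit against ground truth: must match for every value
excl <- labs$value_id %in% inpat$excluded$value_id |
  labs$value_id %in% decisions$value_id[decisions$decision == "exclude"]
agree <- mean(excl == truth$should_be_excluded[
  match(labs$value_id, truth$value_id)])
cat(sprintf("decision vs truth concordance: %.1f%%\n", 100 * agree))
stopifnot(agree == 1)

kept <- inpat$kept[decisions$decision == "keep", ]
write.table(kept, file.path(out, "kept_labs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(decisions, file.path(out, "filter_audit.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(drops$dropped, file.path(out, "dropped_patients.txt"))
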