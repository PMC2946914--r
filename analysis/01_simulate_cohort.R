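#!/usr/bin/env Rscript
# Stage 1: generate the synthetic EMR cohort used by the downstream
# analyses — 800 patients, repeated CBC draws over ~15 years, confounding
# events/episodes/notes, and 2,000 independent HWE markers with three
# planted quantitative trait loci. Writes every table plus ground truth
# under results/cohort/.

source("analysis/_config.R")
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- study_config()
cohort <- simulate_emr_cohort(cfg)

write.table(cohort$patients[c("patient_id", "age", "sex", "pad")],
            file.path(out, "patients.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
for (nm in c("labs", "events", "episodes", "notes", "truth")) {
  write.table(cohort[[nm]], file.path(out, paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_plink(cohort$genotypes, file.path(out, "genotypes"),
            sex = 2L - cohort$patients$sex)
write.table(cohort$truth_betas, file.path(out, "truth_betas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("patients: %d\n", nrow(cohort$patients)))
cat(sprintf("lab values: %d (%.1f draws/patient)\n", nrow(cohort$labs),
            nrow(cohort$labs) / 6 / nrow(cohort$patients)))
cat(sprintf("events: %d, episodes: %d, notes: %d\n",
            nrow(cohort$events), nrow(cohort$episodes), nrow(cohort$notes)))
cat(sprintf("truth: %.1f%% of values flagged for exclusion\n",
            100 * mean(cohort$truth$should_be_excluded)))
print(cohort$truth_betas)
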