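#!/usr/bin/env Rscript
# Stage 3: collapse kept values to one median phenotype per patient/trait,
# produce the cohort characteristics table by PAD status, and run genotype
# quality control (call rates, MAF, exact HWE).

suppressMessages(library(emrgwas))
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

kept <- read.delim("results/filter/kept_labs.tsv")
patients <- read.delim("results/cohort/patients.tsv")

phenotypes <- aggregate_median(kept, patients)
write.table(phenotypes, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("phenotype rows: %d; patients with >=2 HGB measurements: %.1f%%\n",
            nrow(phenotypes), 100 * mean(phenotypes$n_HGB >= 2)))

summary_tab <- cohort_summary(phenotypes, group = "pad")
write.table(summary_tab, file.path(out, "cohort_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ncohort characteristics (PAD controls vs cases):\n")
print(summary_tab[c("variable", "total", "group0", "group1", "p_value")],
      digits = 3)

g <- read_plink("results/cohort/genotypes")
qc <- apply_qc(g, qc_thresholds())
cat("\nQC funnel:\n")
print(qc$report$steps)
write_plink(qc$genotypes, file.path(out, "genotypes_qc"))
jsonlite::write_json(qc$report$steps, file.path(out, "qc_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
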