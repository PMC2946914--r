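#!/usr/bin/env Rscript
# Stage 4: additive single-SNP association for the six RBC traits with
# age/sex/PAD covariates, genomic-control inflation factors, GC-adjusted P,
# QQ/Manhattan coordinates and the genome-wide significant hits, checked
# against the planted truth.

suppressMessages(library(emrgwas))
out <- "results/analysis"

phenotypes <- read.delim(file.path(out, "phenotypes.tsv"))
g <- read_plink(file.path(out, "genotypes_qc"))
truth <- read.delim("results/cohort/truth_betas.tsv")

gwas <- run_gwas(g, phenotypes)
traits <- unique(gwas$trait)
lambda <- vapply(traits, function(tr)
  genomic_lambda(gwas[gwas$trait == tr & is.finite(gwas$p), ]), numeric(1))
cat("genomic-control lambda per trait:\n"); print(round(lambda, 3))

gwas <- do.call(rbind, lapply(traits, function(tr)
  gc_adjust(gwas[gwas$trait == tr, ], lambda[[tr]])))
write.table(gwas, file.path(out, "association.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (tr in traits) {
  write.table(qq_data(gwas[gwas$trait == tr, ]),
              file.path(out, sprintf("qq_%s.tsv", tr)), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
write.table(manhattan_data(gwas), file.path(out, "manhattan.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- gwas[is.finite(gwas$p) & gwas$p < 5e-8,
            c("trait", "snp", "chrom", "bp", "eaf", "beta", "se", "p",
              "partial_r2", "p_gc")]
cat(sprintf("\ngenome-wide significant rows (P < 5e-8): %d\n", nrow(sig)))
print(sig, digits = 3, row.names = FALSE)
cat("\nplanted truth:\n"); print(truth, digits = 3, row.names = FALSE)
hits <- unique(sig$snp)
cat(sprintf("planted markers recovered at 5e-8: %d of %d\n",
            sum(truth$snp %in% hits), nrow(truth)))
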