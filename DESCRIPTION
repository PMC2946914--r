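Package: emrgwas
Title: Electronic-Medical-Record Phenotyping and GWAS of Red Blood Cell Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide association studies of
    quantitative red blood cell (RBC) traits phenotyped from electronic
    medical records. Provides a synthetic EMR and genotype generator with
    known ground truth; multi-source lab-result integration with an
    inpatient exclusion rule; a billing-code and note-lexicon exclusion
    algorithm with auditable per-value decisions; median aggregation of
    repeated measures with cohort summaries; genotype quality control
    including the Levene-Haldane exact Hardy-Weinberg test; single-SNP
    additive association with covariates, genomic control, QQ/Manhattan
    data, analytic and simulation-based QTL power, and effect-allele
    harmonization against reference association catalogs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
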