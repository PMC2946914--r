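# Shared study configuration for the analysis scripts (sourced, not run).
suppressMessages(library(emrgwas))

study_config <- function() {
  sim_config(
    n_patients = 800, m_snps = 2000, seed = 20260921, visit_rate = 6,
    causal_spec = data.frame(snp = c(137, 942, 1500),
                             trait = c("MCH", "RBC", "HGB"),
                             r2 = c(0.05, 0.04, 0.03))
  )
}
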