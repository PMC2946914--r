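#' Simulate a complete synthetic EMR cohort
#'
#' One call producing every table the pipeline consumes, with ground truth:
#' patients, genotypes (with planted effects), repeated labs, confounding
#' events/episodes/notes and per-value truth labels. Identical
#' configurations (including seed) give identical outputs.
#'
#' @param config A [sim_config()].
#' @param registry,lexicon,policies Exclusion configuration; defaults as in
#'   [simulate_confounders()].
#' @return List: `patients`, `genotypes`, `labs`, `events`, `episodes`,
#'   `notes`, `truth`, `truth_betas`, `config`.
#' @export
simulate_emr_cohort <- function(config,
                                registry = default_code_registry(),
                                lexicon = default_medication_lexicon(),
                                policies = default_window_policies()) {
  patients <- simulate_patients(config)
  genotypes <- simulate_genotypes(patients, config)
  patients <- inject_genetic_effects(patients, genotypes, config$causal_spec,
                                     trait_params = config$trait_params,
                                     icc = config$icc)
  labs <- simulate_lab_series(patients, config)
  conf <- simulate_confounders(patients, labs, config,
                               registry = registry, lexicon = lexicon,
                               policies = policies)
  list(patients = patients, genotypes = genotypes, labs = labs,
       events = conf$events, episodes = conf$episodes, notes = conf$notes,
       truth = conf$truth, truth_betas = attr(patients, "truth_betas"),
       config = config)
}

#' Simulate a lean GWAS cohort (one phenotype value per patient)
#'
#' For statistical calibration work (null distributions, power, parameter
#' recovery) the EMR layer is unnecessary: this generator produces patients,
#' genotypes and one latent phenotype vector per trait in which a planted
#' marker explains exactly the configured variance fraction of the trait's
#' total variance (the intraclass correlation is fixed at 1, so the stable
#' component carries the whole configured variance).
#'
#' @param n_patients,m_snps,causal_spec,seed,maf_range,geno_missing_rate
#'   Passed to [sim_config()].
#' @param ... Further [sim_config()] arguments.
#' @return List: `patients`, `genotypes`, `phenotypes` (from
#'   [latent_phenotypes()]), `truth_betas`, `config`.
#' @export
simulate_gwas_cohort <- function(n_patients, m_snps, causal_spec = NULL,
                                 seed = 1L, maf_range = c(0.05, 0.5),
                                 geno_missing_rate = 0, ...) {
  config <- sim_config(n_patients = n_patients, m_snps = m_snps,
                       causal_spec = causal_spec, seed = seed,
                       maf_range = maf_range,
                       geno_missing_rate = geno_missing_rate,
                       icc = 1, ...)
  patients <- simulate_patients(config)
  genotypes <- simulate_genotypes(patients, config)
  patients <- inject_genetic_effects(patients, genotypes, config$causal_spec,
                                     trait_params = config$trait_params,
                                     icc = 1)
  list(patients = patients, genotypes = genotypes,
       phenotypes = latent_phenotypes(patients),
       truth_betas = attr(patients, "truth_betas"), config = config)
}
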