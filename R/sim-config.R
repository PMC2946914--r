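#' Default per-trait means and standard deviations
#'
#' Population means and SDs for the six RBC traits in a cohort of older
#' adults referred for vascular evaluation (peripheral arterial disease cases
#' and controls): Hgb 14.1 (1.3) g/dL, Hct 41.0 (3.6) %, RBC 4.5 (0.4)
#' x10^12/L, MCV 90.5 (4.2) fL, MCH 31.1 (1.6) pg, MCHC 34.3 (0.5) %.
#' HGB/HCT/RBC parameterize the generator directly; the entries for the
#' derived indices are the nominal targets implied by those three (used for
#' variance bookkeeping when effects are planted on a derived trait).
#'
#' @return Data frame with columns `trait`, `mean`, `sd`, `unit`.
#' @export
trait_defaults <- function() {
  data.frame(
    trait = RBC_TRAITS,
    mean = c(14.1, 41.0, 4.5, 90.5, 31.1, 34.3),
    sd = c(1.3, 3.6, 0.4, 4.2, 1.6, 0.5),
    unit = unname(TRAIT_UNITS[RBC_TRAITS]),
    stringsAsFactors = FALSE
  )
}

#' Default covariate effects on the measured traits
#'
#' Additive shifts of the patient-level trait mean per covariate unit, applied
#' to the three measured traits (the indices inherit covariate structure
#' through the hematological identities). Age is per year, centered at the
#' cohort mean; sex is male = 1 (men run higher on Hgb/Hct/RBC); PAD case
#' status carries a modest anemia-of-chronic-disease shift. Values are chosen
#' to reproduce the direction and rough size of the case/control contrasts
#' seen in such cohorts; they are configuration, not estimates.
#'
#' @return Named list of numeric vectors `age`, `sex`, `pad`, each with one
#'   entry per measured trait (HGB, HCT, RBC).
#' @export
covariate_effect_defaults <- function() {
  list(
    age = c(HGB = -0.010, HCT = -0.025, RBC = -0.0040),
    sex = c(HGB = 1.00, HCT = 2.60, RBC = 0.25),
    pad = c(HGB = -0.40, HCT = -1.00, RBC = -0.080)
  )
}

#' Simulation configuration for the synthetic EMR cohort
#'
#' Bundles every knob of the ground-truth generator: cohort size and
#' demographics, repeated lab draws, confounding clinical events,
#' hospitalizations, genotypes and planted genetic effects.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Master seed; all stages derive their own seeds from it.
#' @param visit_rate Mean extra lab draws per patient; draw count is
#'   `1 + Poisson(visit_rate)` so every patient has at least one draw.
#' @param span_days Calendar span (whole days) over which draws/events fall.
#' @param trait_params Data frame like [trait_defaults()].
#' @param icc Intraclass correlation of repeated measures within patient:
#'   fraction of each measured trait's variance that is stable
#'   between-patient signal. Set to 1 for a single-value-per-patient design.
#' @param trait_cor Within-patient correlation matrix (3x3, HGB/HCT/RBC) of
#'   both the stable and the draw-level components; defaults to a strongly
#'   coupled physiological structure.
#' @param derived_noise_sd Named numeric, SD of the small independent
#'   reporting noise added to each derived index after computation from the
#'   per-draw measured values (0 keeps the identities exact).
#' @param event_rates Named probabilities that a patient carries one
#'   confounding event of each category: `condition`, `transplant`,
#'   `medication_code`, `medication_nlp`.
#' @param hospitalization_rate Probability a patient has one inpatient
#'   episode within the span.
#' @param age_mean,age_sd,p_male,p_pad Demographics: age is normal truncated
#'   to [18, 100]; sex and PAD are Bernoulli.
#' @param m_snps Number of independent markers.
#' @param maf_range Two values in (0, 0.5]: per-marker minor allele
#'   frequency is drawn uniformly from this interval.
#' @param geno_missing_rate Per-genotype missingness probability.
#' @param causal_spec Data frame with columns `snp` (marker index), `trait`,
#'   `r2` (fraction of that trait's configured variance explained); may be
#'   `NULL` for a null cohort.
#' @param covariate_effects List like [covariate_effect_defaults()].
#' @param dup_rate Probability that a lab draw is also emitted (verbatim)
#'   from a second source system, to exercise deduplication.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_patients = 200,
                       seed = 1L,
                       visit_rate = 6,
                       span_days = 5478,
                       trait_params = trait_defaults(),
                       icc = 0.7,
                       trait_cor = NULL,
                       derived_noise_sd = c(MCV = 0.1, MCH = 0.05, MCHC = 0.05),
                       event_rates = c(condition = 0.15, transplant = 0.03,
                                       medication_code = 0.10,
                                       medication_nlp = 0.15,
                                       surgery_blood_loss = 0.08),
                       hospitalization_rate = 0.5,
                       age_mean = 63.2, age_sd = 9.5,
                       p_male = 0.62, p_pad = 0.49,
                       m_snps = 100,
                       maf_range = c(0.05, 0.5),
                       geno_missing_rate = 0,
                       causal_spec = NULL,
                       covariate_effects = covariate_effect_defaults(),
                       dup_rate = 0.02) {
  if (is.null(trait_cor)) {
    trait_cor <- matrix(c(1, 0.985, 0.88,
                          0.985, 1, 0.92,
                          0.88, 0.92, 1), 3, 3,
                        dimnames = list(PRIMARY_TRAITS, PRIMARY_TRAITS))
  }
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    visit_rate = visit_rate, span_days = as.integer(span_days),
    trait_params = trait_params, icc = icc, trait_cor = trait_cor,
    derived_noise_sd = derived_noise_sd, event_rates = event_rates,
    hospitalization_rate = hospitalization_rate,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male, p_pad = p_pad,
    m_snps = as.integer(m_snps), maf_range = maf_range,
    geno_missing_rate = geno_missing_rate, causal_spec = causal_spec,
    covariate_effects = covariate_effects, dup_rate = dup_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if(cfg$n_patients < 1L, "n_patients must be >= 1")
  stop_if(cfg$visit_rate < 0, "visit_rate must be >= 0")
  rates <- c(cfg$event_rates, cfg$hospitalization_rate, cfg$p_male,
             cfg$p_pad, cfg$geno_missing_rate, cfg$dup_rate)
  stop_if(any(rates < 0 | rates > 1), "all rates must lie in [0, 1]")
  stop_if(any(cfg$trait_params$sd <= 0), "all trait SDs must be > 0")
  stop_if(cfg$icc <= 0 || cfg$icc > 1, "icc must lie in (0, 1]")
  stop_if(length(cfg$maf_range) != 2 ||
            cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
            cfg$maf_range[1] > cfg$maf_range[2],
          "maf_range must lie within (0, 0.5]")
  cs <- cfg$causal_spec
  if (!is.null(cs)) {
    stop_if(!all(c("snp", "trait", "r2") %in% names(cs)),
            "causal_spec needs columns snp, trait, r2")
    stop_if(any(cs$r2 <= 0 | cs$r2 >= 1), "causal r2 must lie in (0, 1)")
    stop_if(!all(cs$trait %in% RBC_TRAITS), "causal_spec trait unknown")
    stop_if(any(cs$snp < 1 | cs$snp > cfg$m_snps),
            "causal_spec snp index out of range")
    tot <- tapply(cs$r2, cs$trait, sum)
    stop_if(any(tot >= 1), "sum of causal r2 per trait must be < 1")
  }
  invisible(cfg)
}
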