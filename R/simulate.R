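#' Simulate the patient table
#'
#' Draws demographics (age normal, truncated to 18-100; sex and PAD status
#' Bernoulli) and the stable between-patient component of the three measured
#' RBC traits. The stable component is multivariate normal with SD
#' `sqrt(icc) * sd_trait` and the configured physiological correlation;
#' covariate effects are applied centered, so the configured trait means are
#' the marginal means. Genetic shifts start at zero and are filled in by
#' [inject_genetic_effects()].
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per patient: `patient_id`, `age`, `sex`
#'   (male = 1), `pad`, plus internal columns `base_*`, `u_*` (stable random
#'   deviation) and `g_*` (planted genetic shift) per trait.
#' @export
simulate_patients <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  set.seed(derive_seed(config$seed, "patients"))

  # truncated normal age via inverse-CDF sampling on the truncated range
  lo <- stats::pnorm(18, config$age_mean, config$age_sd)
  hi <- stats::pnorm(100, config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1, config$p_male)
  pad <- stats::rbinom(n, 1, config$p_pad)

  tp <- config$trait_params
  sd_p <- tp$sd[match(PRIMARY_TRAITS, tp$trait)]
  mu_p <- tp$mean[match(PRIMARY_TRAITS, tp$trait)]
  D <- diag(sqrt(config$icc) * sd_p)
  Sigma <- D %*% config$trait_cor %*% D
  u <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Sigma)
  colnames(u) <- PRIMARY_TRAITS

  ce <- config$covariate_effects
  shift <- sapply(PRIMARY_TRAITS, function(t) {
    (age - config$age_mean) * ce$age[[t]] +
      (sex - config$p_male) * ce$sex[[t]] +
      (pad - config$p_pad) * ce$pad[[t]]
  })
  if (n == 1L) shift <- matrix(shift, nrow = 1,
                               dimnames = list(NULL, PRIMARY_TRAITS))

  # the covariate structure is part of the stable between-patient variance,
  # so the random component shrinks to keep the marginal SD at the
  # configured value
  cov_var <- if (n > 1L) apply(shift, 2, stats::var) else
    stats::setNames(rep(0, 3), PRIMARY_TRAITS)
  between <- config$icc * sd_p^2
  stop_if(any(cov_var >= between),
          "covariate effects exceed the stable trait variance")
  u <- u %*% diag(sqrt((between - cov_var) / between),
                  nrow = 3, ncol = 3)
  colnames(u) <- PRIMARY_TRAITS

  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, pad = pad,
    stringsAsFactors = FALSE
  )
  for (t in PRIMARY_TRAITS) {
    out[[paste0("base_", t)]] <- mu_p[match(t, PRIMARY_TRAITS)] + shift[, t]
    out[[paste0("u_", t)]] <- u[, t]
  }
  for (t in RBC_TRAITS) out[[paste0("g_", t)]] <- 0
  attr(out, "covariate_var") <- cov_var
  out
}

#' Patient-level latent trait values
#'
#' The latent (stable) value of each trait per patient: for the measured
#' traits, configured mean + centered covariate effects + stable deviation +
#' planted genetic shift; for the derived indices, the hematological
#' identities applied to the latent measured values plus any genetic shift
#' planted directly on the index.
#'
#' @param patients Output of [simulate_patients()] (possibly after
#'   [inject_genetic_effects()]).
#' @return Data frame `patient_id`, `age`, `sex`, `pad` and one column per
#'   trait.
#' @export
latent_phenotypes <- function(patients) {
  lat <- patients[c("patient_id", "age", "sex", "pad")]
  for (t in PRIMARY_TRAITS) {
    lat[[t]] <- patients[[paste0("base_", t)]] +
      patients[[paste0("u_", t)]] + patients[[paste0("g_", t)]]
  }
  lat$MCV <- 10 * lat$HCT / lat$RBC + patients$g_MCV
  lat$MCH <- 10 * lat$HGB / lat$RBC + patients$g_MCH
  lat$MCHC <- 100 * lat$HGB / lat$HCT + patients$g_MCHC
  lat
}

#' Simulate repeated lab draws
#'
#' Each patient gets `1 + Poisson(visit_rate)` dated draws over the calendar
#' span (whole days). Per draw, the measured traits are the patient's latent
#' value plus correlated draw-level noise with SD `sqrt(1 - icc) * sd_trait`;
#' the indices are then derived per draw (MCV = 10*Hct/RBC, MCH = 10*Hgb/RBC,
#' MCHC = 100*Hgb/Hct) before small independent reporting noise, so all six
#' traits carry the dependence structure of a complete blood count.
#'
#' @param patients Output of [simulate_patients()].
#' @param config The same [sim_config()].
#' @param noise If `FALSE`, draw-level and reporting noise are switched off
#'   (the identities then hold exactly).
#' @return Long-format lab table: `value_id`, `patient_id`, `trait`, `value`,
#'   `sample_date` (integer day), `accession`, `source`.
#' @export
simulate_lab_series <- function(patients, config, noise = TRUE) {
  stop_if(nrow(patients) == 0, "patient table is empty")
  set.seed(derive_seed(config$seed, "labs"))
  n <- nrow(patients)
  n_draws <- 1L + stats::rpois(n, config$visit_rate)

  lat <- latent_phenotypes(patients)
  tp <- config$trait_params
  sd_p <- tp$sd[match(PRIMARY_TRAITS, tp$trait)]
  Dw <- diag(sqrt(1 - config$icc) * sd_p)
  Sw <- Dw %*% config$trait_cor %*% Dw
  chol_w <- if (config$icc < 1) chol(Sw) else NULL

  total <- sum(n_draws)
  idx <- rep(seq_len(n), n_draws)
  dates <- unlist(lapply(seq_len(n), function(i) {
    sort(sample.int(config$span_days + 1L, n_draws[i],
                    replace = n_draws[i] > config$span_days + 1L) - 1L)
  }))
  eps <- if (noise && !is.null(chol_w)) {
    matrix(stats::rnorm(total * 3), total, 3) %*% chol_w
  } else matrix(0, total, 3)

  hgb <- lat$HGB[idx] + eps[, 1]
  hct <- lat$HCT[idx] + eps[, 2]
  rbc <- lat$RBC[idx] + eps[, 3]
  dn <- if (noise) config$derived_noise_sd else c(MCV = 0, MCH = 0, MCHC = 0)
  mcv <- 10 * hct / rbc + patients$g_MCV[idx] + stats::rnorm(total, 0, dn[["MCV"]])
  mch <- 10 * hgb / rbc + patients$g_MCH[idx] + stats::rnorm(total, 0, dn[["MCH"]])
  mchc <- 100 * hgb / hct + patients$g_MCHC[idx] + stats::rnorm(total, 0, dn[["MCHC"]])

  accession <- sprintf("ACC%08d", seq_len(total))
  vals <- cbind(HGB = hgb, HCT = hct, RBC = rbc,
                MCV = mcv, MCH = mch, MCHC = mchc)
  out <- data.frame(
    value_id = paste0(rep(accession, times = 6), ":",
                      rep(RBC_TRAITS, each = total)),
    patient_id = rep(patients$patient_id[idx], times = 6),
    trait = rep(RBC_TRAITS, each = total),
    value = as.vector(vals),
    sample_date = rep(dates, times = 6),
    accession = rep(accession, times = 6),
    source = "LAB_A",
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$sample_date, out$accession, out$trait), ,
      drop = FALSE]
}

#' Simulate independent HWE genotypes
#'
#' Per marker, an allele frequency is drawn uniformly from `maf_range` and
#' each genotype is the sum of two independent Bernoulli allele draws, so
#' markers satisfy Hardy-Weinberg equilibrium by construction. Optional
#' missingness is applied uniformly at random. Marker metadata (chromosome,
#' position, allele pair) is assigned deterministically under the derived
#' seed.
#'
#' @param patients Output of [simulate_patients()].
#' @param config The same [sim_config()].
#' @return A [genotype_matrix()] with dosage of the simulated (counted)
#'   allele and map columns `id`, `chrom`, `bp`, `a1` (counted allele),
#'   `a2`, `freq_sim`.
#' @export
simulate_genotypes <- function(patients, config) {
  stop_if(config$m_snps < 1L, "m_snps must be >= 1")
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- nrow(patients); m <- config$m_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p <- rep(maf, each = n)
  G <- matrix(stats::rbinom(n * m, 1L, p) + stats::rbinom(n * m, 1L, p),
              n, m)
  if (config$geno_missing_rate > 0) {
    G[stats::runif(n * m) < config$geno_missing_rate] <- NA_integer_
  }
  rownames(G) <- patients$patient_id

  pairs <- c("A C", "A G", "C T", "G T", "A T", "C G")
  al <- strsplit(sample(pairs, m, replace = TRUE), " ")
  chrom <- sort(rep_len(1:22, m))
  bp <- stats::ave(seq_len(m), chrom,
                   FUN = function(i) cumsum(5000L + sample.int(50000L, length(i))))
  map <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = chrom, bp = as.integer(bp),
    a1 = vapply(al, `[`, "", 1L), a2 = vapply(al, `[`, "", 2L),
    freq_sim = maf,
    stringsAsFactors = FALSE
  )
  colnames(G) <- map$id
  genotype_matrix(G, map)
}

#' Plant additive genetic effects on patient latent means
#'
#' For each causal entry (marker j, trait t, variance fraction r2) the effect
#' per counted-allele copy is `beta = sqrt(r2 * var_t / (2 p (1 - p)))` with
#' `p` the realized allele frequency of marker j, and `beta * g_ij` is added
#' to patient i's latent mean of trait t. For measured traits the stable
#' random deviation is rescaled so the total trait variance stays at the
#' configured value; an effect planted directly on a derived index is added
#' on top of the identity-derived value (its variance bookkeeping is nominal).
#'
#' @param patients Output of [simulate_patients()].
#' @param genotypes A [genotype_matrix()] for the same patients.
#' @param causal_spec Data frame `snp` (index or marker id), `trait`, `r2`.
#' @param trait_params Per-trait mean/SD table, default [trait_defaults()].
#' @param icc Fraction of trait variance that is stable between patients
#'   (the planted variance must fit inside it); default 0.7 to match
#'   [sim_config()].
#' @return `patients` with updated latent columns; the planted truth is
#'   attached as `attr(, "truth_betas")` (marker id, trait, beta, r2,
#'   realized frequency).
#' @export
inject_genetic_effects <- function(patients, genotypes, causal_spec,
                                   trait_params = trait_defaults(),
                                   icc = 0.7) {
  if (is.null(causal_spec) || nrow(causal_spec) == 0) {
    attr(patients, "truth_betas") <-
      data.frame(snp = character(), trait = character(), beta = numeric(),
                 r2 = numeric(), freq = numeric(), stringsAsFactors = FALSE)
    return(patients)
  }
  stop_if(any(causal_spec$r2 <= 0 | causal_spec$r2 >= 1),
          "causal r2 must lie in (0, 1)")
  G <- genotypes$dosage
  snp_idx <- if (is.character(causal_spec$snp)) {
    match(causal_spec$snp, genotypes$map$id)
  } else as.integer(causal_spec$snp)
  stop_if(any(is.na(snp_idx) | snp_idx < 1 | snp_idx > ncol(G)),
          "causal snp not found in genotype matrix")

  truth <- data.frame(snp = genotypes$map$id[snp_idx],
                      trait = causal_spec$trait, beta = NA_real_,
                      r2 = causal_spec$r2, freq = NA_real_,
                      stringsAsFactors = FALSE)
  vg_per_trait <- stats::setNames(numeric(length(RBC_TRAITS)), RBC_TRAITS)
  for (k in seq_len(nrow(causal_spec))) {
    t <- causal_spec$trait[k]
    j <- snp_idx[k]
    g <- G[, j]
    pj <- mean(g, na.rm = TRUE) / 2
    stop_if(pj <= 0 || pj >= 1, "causal marker %s is monomorphic",
            genotypes$map$id[j])
    var_t <- trait_params$sd[match(t, trait_params$trait)]^2
    beta <- sqrt(causal_spec$r2[k] * var_t / (2 * pj * (1 - pj)))
    g_eff <- ifelse(is.na(g), 2 * pj, g)   # mean-impute for the latent shift
    patients[[paste0("g_", t)]] <- patients[[paste0("g_", t)]] + beta * g_eff
    vg_per_trait[t] <- vg_per_trait[t] + causal_spec$r2[k] * var_t
    truth$beta[k] <- beta
    truth$freq[k] <- pj
  }
  cov_var <- attr(patients, "covariate_var")
  for (t in PRIMARY_TRAITS) {
    if (vg_per_trait[t] > 0) {
      var_t <- trait_params$sd[match(t, trait_params$trait)]^2
      u_var <- icc * var_t -
        (if (is.null(cov_var)) 0 else cov_var[[t]])
      stop_if(vg_per_trait[t] >= u_var,
              "planted variance for %s exceeds the stable component", t)
      patients[[paste0("u_", t)]] <- patients[[paste0("u_", t)]] *
        sqrt((u_var - vg_per_trait[t]) / u_var)
    }
  }
  attr(patients, "covariate_var") <- cov_var
  attr(patients, "truth_betas") <- truth
  patients
}
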