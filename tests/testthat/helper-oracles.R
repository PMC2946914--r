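# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementations.

# Exact HWE p by direct enumeration of the Levene-Haldane conditional
# distribution from the closed-form log-probability of each heterozygote
# count (the package uses the ratio recurrence instead).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * N - nA
  r <- min(nA, na)
  if (r == 0) return(1)
  hs <- seq.int(r %% 2L, r, by = 2L)
  logp <- lgamma(N + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + lgamma(nA + 1) + lgamma(na + 1) -
    lgamma(2 * N + 1) + hs * log(2)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# OLS via explicit normal equations (the package uses QR).
ols_oracle <- function(y, M) {
  XtX <- t(M) %*% M
  b <- solve(XtX, t(M) %*% y)
  res <- y - M %*% b
  df <- length(y) - ncol(M)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- as.vector(b) / se
  list(beta = as.vector(b), se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df)
}

# Small EMR cohort for filter/pipeline tests.
small_cohort <- function(seed, n = 40, m = 20, ...) {
  simulate_emr_cohort(sim_config(n_patients = n, m_snps = m, seed = seed,
                                 visit_rate = 5, ...))
}

# Combined pipeline keep/exclude decision (inpatient rule + windows),
# aligned to a cohort's truth table.
pipeline_decisions <- function(co) {
  flagged <- flag_inpatient(co$labs, co$episodes)
  inpat <- apply_inpatient_exclusion(flagged)
  nlp <- detect_medication_mentions(co$notes)
  windows <- build_exclusion_windows(rbind(co$events, nlp[names(co$events)]))
  dec <- exclude_values(inpat$kept, windows)
  excl <- co$labs$value_id %in% inpat$excluded$value_id |
    co$labs$value_id %in% dec$value_id[dec$decision == "exclude"]
  list(excluded = excl, value_id = co$labs$value_id,
       inpatient = inpat, decisions = dec)
}
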