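#' QC thresholds
#'
#' Markers and samples are kept only when strictly above each threshold:
#' SNP call rate > 0.98, sample call rate > 0.98, MAF > 0.05, exact HWE
#' p > 0.001 (the strict directions follow the conventional "> x%" QC
#' statements). Ancestry/relatedness/duplicate exclusions are consumed as an
#' externally supplied sample list.
#'
#' @param snp_call_rate_min,sample_call_rate_min,maf_min,hwe_p_min Numeric
#'   thresholds in (0, 1).
#' @param sample_exclusion_list Character vector of sample ids to drop
#'   before any rate-based step.
#' @return Validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.98,
                          sample_call_rate_min = 0.98,
                          maf_min = 0.05,
                          hwe_p_min = 0.001,
                          sample_exclusion_list = character()) {
  th <- list(snp_call_rate_min = snp_call_rate_min,
             sample_call_rate_min = sample_call_rate_min,
             maf_min = maf_min, hwe_p_min = hwe_p_min,
             sample_exclusion_list = sample_exclusion_list)
  num <- unlist(th[1:4])
  stop_if(any(num <= 0 | num >= 1), "QC thresholds must lie in (0, 1)")
  class(th) <- "qc_thresholds"
  th
}

#' Per-marker and per-sample call rates
#'
#' @param g A [genotype_matrix()].
#' @return List `marker` and `sample`: fractions of non-missing genotypes.
#' @export
call_rates <- function(g) {
  stop_if(nrow(g$dosage) == 0 || ncol(g$dosage) == 0, "empty genotype matrix")
  ok <- !is.na(g$dosage)
  list(marker = colMeans(ok), sample = rowMeans(ok))
}

#' Per-marker minor allele frequency
#'
#' `MAF = min(f, 1 - f)` with `f` the counted-allele frequency among called
#' genotypes. All-missing markers get `NA` (flagged downstream).
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector in `[0, 0.5]` (NA where undefined).
#' @export
minor_allele_frequency <- function(g) {
  called <- colSums(!is.na(g$dosage))
  f <- colSums(g$dosage, na.rm = TRUE) / (2 * called)
  f[called == 0] <- NA_real_
  pmin(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test under the Levene-Haldane conditional distribution of
#' the heterozygote count given the allele counts: the p value is the sum of
#' the probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count. Probabilities are computed by the
#' stable ratio recurrence on the log scale and normalized, so the test is
#' usable up to biobank-scale counts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact p value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stop_if(any(c(n_AA, n_Aa, n_aa) < 0), "genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  stop_if(n < 1, "total genotype count must be >= 1")
  n_a <- 2 * n_AA + n_Aa          # counted-allele copies
  nr <- min(n_a, 2 * n - n_a)     # rarer allele copies
  if (nr == 0) return(1)
  h_obs <- n_Aa
  hs <- seq.int(nr %% 2L, nr, by = 2L)
  if (length(hs) == 1L) return(1)
  # log P(h+2) - log P(h) = log(4 * n_rr(h) * n_cc(h)) - log((h+2)(h+1))
  h <- hs[-length(hs)]
  na_c <- 2 * n - nr
  lr <- log(4) + log((nr - h) / 2) + log((na_c - h) / 2) -
    log(h + 2) - log(h + 1)
  lp <- c(0, cumsum(lr))
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(h_obs, hs)]
  stop_if(is.na(p_obs), "heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Exact HWE p values for every marker of a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of exact p values (NA for all-missing
#'   markers).
#' @export
hwe_exact_scan <- function(g) {
  d <- g$dosage
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(g$map$id)
}

#' Apply marker and sample quality control
#'
#' Fixed, logged order: (1) drop externally excluded samples, (2) drop
#' samples with call rate not above the sample threshold, (3) drop markers
#' with call rate not above the marker threshold, (4) drop markers with MAF
#' not above `maf_min` (all-missing markers drop here too), (5) drop markers
#' with exact HWE p not above `hwe_p_min`. Counts reconcile at every step.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List: `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (`steps` data frame with per-step drop counts and remaining dimensions,
#'   plus per-step dropped-id lists).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stop_if(!inherits(thresholds, "qc_thresholds"), "invalid thresholds")
  steps <- list()
  dropped <- list()
  note <- function(step, ids, g) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, dropped = length(ids),
      samples_left = nrow(g$dosage), markers_left = ncol(g$dosage),
      stringsAsFactors = FALSE)
    dropped[[step]] <<- ids
  }

  drop_s <- intersect(rownames(g$dosage), thresholds$sample_exclusion_list)
  g <- subset_genotypes(g, samples = setdiff(rownames(g$dosage), drop_s))
  note("sample_exclusion_list", drop_s, g)

  cr <- call_rates(g)
  drop_s <- rownames(g$dosage)[cr$sample <= thresholds$sample_call_rate_min]
  g <- subset_genotypes(g, samples = setdiff(rownames(g$dosage), drop_s))
  note("sample_call_rate", drop_s, g)

  cr <- call_rates(g)
  drop_m <- g$map$id[cr$marker <= thresholds$snp_call_rate_min]
  g <- subset_genotypes(g, markers = setdiff(g$map$id, drop_m))
  note("snp_call_rate", drop_m, g)

  maf <- minor_allele_frequency(g)
  drop_m <- g$map$id[is.na(maf) | maf <= thresholds$maf_min]
  g <- subset_genotypes(g, markers = setdiff(g$map$id, drop_m))
  note("maf", drop_m, g)

  hwe <- hwe_exact_scan(g)
  drop_m <- g$map$id[is.na(hwe) | hwe <= thresholds$hwe_p_min]
  g <- subset_genotypes(g, markers = setdiff(g$map$id, drop_m))
  note("hwe", drop_m, g)

  list(genotypes = g,
       report = list(steps = do.call(rbind, steps), dropped = dropped))
}
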