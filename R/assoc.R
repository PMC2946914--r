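#' Single-SNP additive linear regression
#'
#' Ordinary least squares of the phenotype on [intercept, dosage,
#' covariates] after complete-case removal. SE uses the residual variance
#' with denominator `n_used - p`; the two-sided P comes from the t
#' distribution with the residual df; the partial R-squared is the
#' incremental fit of the dosage over the covariate-only model, computed as
#' `t^2 / (t^2 + df_resid)`.
#'
#' @param g Dosage vector (0/1/2, NA allowed).
#' @param y Phenotype vector.
#' @param X Optional covariate matrix/data frame (no intercept column).
#' @return One-row data frame: `n_used`, `eaf` (counted-allele frequency),
#'   `beta`, `se`, `t`, `p`, `partial_r2`, `df`, `flag` (`""`, or
#'   `"constant_genotype"` for a not-a-result marker, carried, never
#'   dropped).
#' @export
fit_additive <- function(g, y, X = NULL) {
  if (!is.null(X)) X <- as.matrix(X)
  ok <- is.finite(g) & is.finite(y)
  if (!is.null(X)) ok <- ok & stats::complete.cases(X)
  g <- g[ok]; y <- y[ok]
  if (!is.null(X)) X <- X[ok, , drop = FALSE]
  n <- length(g)
  p_cols <- 2L + if (is.null(X)) 0L else ncol(X)
  stop_if(n <= p_cols + 2L, "too few complete cases (%d)", n)

  na_row <- data.frame(n_used = n, eaf = mean(g) / 2, beta = NA_real_,
                       se = NA_real_, t = NA_real_, p = NA_real_,
                       partial_r2 = NA_real_, df = n - p_cols,
                       flag = "constant_genotype", stringsAsFactors = FALSE)
  if (stats::var(g) == 0) return(na_row)

  M <- cbind(`(Intercept)` = 1, g = g, X)
  qrm <- qr(M)
  stop_if(qrm$rank < ncol(M) && qr(cbind(1, X))$rank < ncol(M) - 1L,
          "collinear covariates")
  if (qrm$rank < ncol(M)) return(na_row)  # dosage collinear with covariates
  fit <- stats::lm.fit(M, y)
  df <- n - ncol(M)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrm))
  beta <- fit$coefficients[["g"]]
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  data.frame(n_used = n, eaf = mean(g) / 2, beta = beta, se = se, t = tval,
             p = pval, partial_r2 = tval^2 / (tval^2 + df), df = df,
             flag = "", stringsAsFactors = FALSE)
}

#' Genome-wide additive association scan
#'
#' One additive fit per marker per trait, adjusted for the requested
#' covariates. Samples are aligned by id between genotypes and phenotypes
#' (order never matters). Markers without missing genotypes go through a
#' vectorized residualized solver algebraically identical to
#' [fit_additive()]; markers with missingness fall back to the per-marker
#' fit. Monomorphic markers are carried with a flag, never dropped.
#'
#' @param g A [genotype_matrix()].
#' @param phenotypes Wide phenotype table from [aggregate_median()] or
#'   [latent_phenotypes()].
#' @param traits Traits to scan (default all six).
#' @param covars Covariate column names in `phenotypes`
#'   (default age/sex/pad).
#' @return Data frame with one row per (trait, marker): marker metadata,
#'   `effect_allele`/`other_allele`, `eaf`, `n_used`, `beta`, `se`, `t`,
#'   `p`, `partial_r2`, `flag`.
#' @export
run_gwas <- function(g, phenotypes, traits = RBC_TRAITS,
                     covars = c("age", "sex", "pad")) {
  ids <- intersect(rownames(g$dosage), phenotypes$patient_id)
  stop_if(length(ids) == 0, "no overlapping samples between genotypes and phenotypes")
  D <- g$dosage[ids, , drop = FALSE]
  ph <- phenotypes[match(ids, phenotypes$patient_id), , drop = FALSE]
  stop_if(!all(traits %in% names(ph)), "phenotype table lacks requested traits")
  stop_if(!all(covars %in% names(ph)), "phenotype table lacks covariates: %s",
          paste(setdiff(covars, names(ph)), collapse = ", "))

  out <- list()
  for (tr in traits) {
    y_all <- ph[[tr]]
    Xc <- if (length(covars)) as.matrix(ph[covars]) else NULL
    ok <- is.finite(y_all)
    if (!is.null(Xc)) ok <- ok & stats::complete.cases(Xc)
    y <- as.numeric(y_all[ok])
    X <- cbind(1, if (is.null(Xc)) NULL else Xc[ok, , drop = FALSE])
    Dk <- D[ok, , drop = FALSE]
    n <- length(y)
    pX <- ncol(X)
    df <- n - pX - 1L

    res <- data.frame(trait = tr, snp = g$map$id, chrom = g$map$chrom,
                      bp = g$map$bp, effect_allele = g$map$a1,
                      other_allele = g$map$a2,
                      eaf = NA_real_, n_used = NA_integer_, beta = NA_real_,
                      se = NA_real_, t = NA_real_, p = NA_real_,
                      partial_r2 = NA_real_, flag = "",
                      stringsAsFactors = FALSE)

    complete <- !colSums(is.na(Dk))
    if (any(complete)) {
      # residualize phenotype and dosages against [1, covariates]
      XtXi <- chol2inv(chol(crossprod(X)))
      Gc <- Dk[, complete, drop = FALSE]
      G_res <- Gc - X %*% (XtXi %*% crossprod(X, Gc))
      y_res <- y - X %*% (XtXi %*% crossprod(X, y))
      den <- colSums(G_res^2)
      poly <- den > 1e-10
      num <- as.vector(crossprod(G_res, y_res))
      beta <- ifelse(poly, num / den, NA_real_)
      rss <- as.vector(crossprod(y_res)) - beta^2 * den
      se <- sqrt(rss / df / den)
      tv <- beta / se
      idx <- which(complete)
      res$eaf[idx] <- colMeans(Gc) / 2
      res$n_used[idx] <- n
      res$beta[idx] <- beta
      res$se[idx] <- ifelse(poly, se, NA_real_)
      res$t[idx] <- tv
      res$p[idx] <- 2 * stats::pt(-abs(tv), df)
      res$partial_r2[idx] <- tv^2 / (tv^2 + df)
      res$flag[idx] <- ifelse(poly, "", "constant_genotype")
    }
    for (j in which(!complete)) {
      f <- fit_additive(Dk[, j], y, if (is.null(Xc)) NULL else Xc[ok, , drop = FALSE])
      res$eaf[j] <- f$eaf; res$n_used[j] <- f$n_used
      res$beta[j] <- f$beta; res$se[j] <- f$se; res$t[j] <- f$t
      res$p[j] <- f$p; res$partial_r2[j] <- f$partial_r2
      res$flag[j] <- f$flag
    }
    out[[tr]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

CHISQ1_MEDIAN <- 0.4549364231

#' Genomic-control inflation factor
#'
#' `lambda = median(chi-square) / 0.4549364`, with the per-marker 1-df
#' chi-square taken as `t^2`. Values near 1 indicate no systematic
#' inflation from population structure.
#'
#' @param gwas A scan table from [run_gwas()] (single trait or subset), or
#'   a numeric vector of chi-square statistics.
#' @return The inflation factor (positive scalar).
#' @export
genomic_lambda <- function(gwas) {
  chi <- if (is.numeric(gwas)) gwas else gwas$t^2
  chi <- chi[is.finite(chi)]
  stop_if(length(chi) == 0, "no finite association statistics")
  if (length(chi) < 100) {
    warning("genomic lambda estimated from fewer than 100 markers",
            call. = FALSE)
  }
  stats::median(chi) / CHISQ1_MEDIAN
}

#' Genomic-control adjustment of association P values
#'
#' Divides each marker's chi-square by lambda and recomputes P from the
#' 1-df chi-square distribution. Lambda below 1 is never applied (no
#' deflation): statistics are left unchanged and a note is attached.
#'
#' @param gwas Scan table from [run_gwas()].
#' @param lambda Inflation factor, e.g. from [genomic_lambda()].
#' @return `gwas` with columns `chisq_gc` and `p_gc`; attribute
#'   `lambda_applied` records the factor actually used.
#' @export
gc_adjust <- function(gwas, lambda) {
  lam <- max(1, lambda)
  chi <- gwas$t^2 / lam
  gwas$chisq_gc <- chi
  gwas$p_gc <- stats::pchisq(chi, 1, lower.tail = FALSE)
  attr(gwas, "lambda_applied") <- lam
  if (lambda < 1) attr(gwas, "note") <- "lambda < 1: no deflation applied"
  gwas
}

#' Expected-versus-observed quantiles for a QQ plot
#'
#' Expected quantiles are `-log10(i / (m + 1))` for rank i of m finite P
#' values; observed are the sorted `-log10(P)`, largest first.
#'
#' @param gwas Scan table or numeric vector of P values.
#' @return Data frame `expected`, `observed` (both descending), one row per
#'   finite-P marker.
#' @export
qq_data <- function(gwas) {
  p <- if (is.numeric(gwas)) gwas else gwas$p
  p <- p[is.finite(p)]
  stop_if(length(p) == 0, "no finite P values")
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(p)))
}

#' Chromosome/position/-log10(P) triples for a Manhattan plot
#'
#' @param gwas Scan table from [run_gwas()].
#' @param threshold Genome-wide significance line (default 5e-8).
#' @return Data frame `chrom`, `bp`, `log10p`, `significant`; the threshold
#'   is attached as an attribute.
#' @export
manhattan_data <- function(gwas, threshold = 5e-8) {
  ok <- is.finite(gwas$p)
  out <- data.frame(chrom = gwas$chrom[ok], bp = gwas$bp[ok],
                    log10p = -log10(gwas$p[ok]),
                    significant = gwas$p[ok] < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}
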