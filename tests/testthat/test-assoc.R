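test_that("a noise-free additive relation is fitted exactly", {
  g <- c(0, 1, 2, 0, 1, 2)
  fit <- fit_additive(g, 2 * g)
  expect_equal(fit$beta, 2)
  expect_equal(fit$partial_r2, 1)
  expect_equal(fit$p, 0)
})

test_that("fit_additive matches the normal-equations oracle", {
  set.seed(15)
  for (k in 1:60) {
    n <- sample(12:60, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    X <- cbind(age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5),
               pad = rbinom(n, 1, 0.5))
    y <- 14 + 0.2 * g + 0.01 * X[, 1] + rnorm(n)
    if (var(g) == 0) next
    fit <- fit_additive(g, y, X)
    orc <- ols_oracle(y, cbind(1, g, X))
    expect_equal(fit$beta, unname(orc$beta[2]), tolerance = 1e-10)
    expect_equal(fit$se, unname(orc$se[2]), tolerance = 1e-10)
    expect_equal(fit$p, unname(orc$p[2]), tolerance = 1e-10)
  }
})

test_that("monomorphic markers are flagged, not dropped", {
  fit <- fit_additive(rep(1, 30), rnorm(30))
  expect_identical(fit$flag, "constant_genotype")
  expect_true(is.na(fit$beta))
  co <- simulate_gwas_cohort(80, 3, seed = 71)
  co$genotypes$dosage[, 2] <- 1
  gw <- run_gwas(co$genotypes, co$phenotypes, traits = "HGB")
  expect_equal(nrow(gw), 3L)
  expect_identical(gw$flag[2], "constant_genotype")
})

test_that("the vectorized scan equals per-marker fits, missing or not", {
  co <- simulate_gwas_cohort(150, 8, seed = 81, geno_missing_rate = 0.05)
  gw <- run_gwas(co$genotypes, co$phenotypes, traits = "MCH")
  ph <- co$phenotypes
  X <- as.matrix(ph[c("age", "sex", "pad")])
  for (j in seq_len(8)) {
    f <- fit_additive(co$genotypes$dosage[ph$patient_id, j], ph$MCH, X)
    expect_equal(gw$beta[j], f$beta, tolerance = 1e-10)
    expect_equal(gw$se[j], f$se, tolerance = 1e-10)
    expect_equal(gw$p[j], f$p, tolerance = 1e-10)
    expect_equal(gw$partial_r2[j], f$partial_r2, tolerance = 1e-10)
  }
})

test_that("association depends on sample alignment, not row order", {
  co <- simulate_gwas_cohort(120, 6, seed = 91)
  gw1 <- run_gwas(co$genotypes, co$phenotypes)
  perm <- sample(nrow(co$phenotypes))
  gw2 <- run_gwas(co$genotypes, co$phenotypes[perm, ])
  expect_equal(gw1$beta, gw2$beta)
  expect_equal(gw1$p, gw2$p)
  expect_error(run_gwas(co$genotypes,
                        transform(co$phenotypes,
                                  patient_id = paste0("X", patient_id))),
               "overlapping")
})

test_that("genomic lambda is the median chi-square over 0.4549364", {
  expect_equal(genomic_lambda(rep(0.4549364231, 200)), 1.0)
  expect_equal(genomic_lambda(rep(2 * 0.4549364231, 200)), 2.0)
  expect_warning(genomic_lambda(rep(0.5, 10)), "fewer than 100")
  expect_error(genomic_lambda(numeric(0)), "no finite")
})

test_that("genomic control adjusts chi-squares but never deflates", {
  gwas <- data.frame(t = sqrt(c(29.72, 1, 4)), p = c(1e-8, 0.3, 0.05))
  adj <- gc_adjust(gwas, 2)
  expect_equal(adj$chisq_gc, gwas$t^2 / 2)
  expect_equal(adj$p_gc[1], pchisq(14.86, 1, lower.tail = FALSE))
  expect_true(all(adj$p_gc >= pchisq(gwas$t^2, 1, lower.tail = FALSE) - 1e-15))
  idn <- gc_adjust(gwas, 1)
  expect_equal(idn$p_gc, pchisq(gwas$t^2, 1, lower.tail = FALSE))
  defl <- gc_adjust(gwas, 0.8)
  expect_equal(defl$chisq_gc, gwas$t^2)
  expect_match(attr(defl, "note"), "no deflation")
})

test_that("QQ coordinates are the stated rank quantiles", {
  one <- qq_data(0.5)
  expect_equal(one$expected, -log10(1 / 2), tolerance = 1e-12)
  expect_equal(one$observed, one$expected)
  m <- 99
  grid <- seq_len(m) / (m + 1)
  qq <- qq_data(grid)
  expect_equal(qq$observed, qq$expected)
  p <- c(runif(50), NA, Inf)
  expect_equal(nrow(qq_data(p)), 50)
  md <- manhattan_data(data.frame(chrom = 1, bp = 1:3,
                                  p = c(1e-9, 0.5, NA)))
  expect_equal(nrow(md), 2)
  expect_identical(md$significant, c(TRUE, FALSE))
})

test_that("power behaves like a noncentral chi-square tail", {
  expect_equal(qtl_power(3000, 0.015, 5e-8),
               pchisq(qchisq(1 - 5e-8, 1), 1,
                      ncp = 3000 * 0.015 / 0.985, lower.tail = FALSE))
  # null limit: power tends to alpha as r2 -> 0
  expect_equal(qtl_power(3000, 1e-12, 0.05), 0.05, tolerance = 1e-6)
  # strictly increasing in n and in r2
  ns <- c(500, 1000, 2000, 4000)
  expect_true(all(diff(vapply(ns, qtl_power, numeric(1),
                              r2 = 0.015, alpha = 5e-8)) > 0))
  r2s <- c(0.005, 0.01, 0.02, 0.04)
  expect_true(all(diff(vapply(r2s, function(r)
    qtl_power(3000, r, 5e-8), numeric(1))) > 0))
  expect_error(qtl_power(3000, 0, 5e-8), "r2")
  expect_error(qtl_power(3000, 0.015, 0), "alpha")
})

test_that("effect-allele harmonization flips, flags proxies and ambiguity", {
  gwas <- data.frame(
    snp = c("rs1", "rs2", "rs3"), trait = "MCV",
    effect_allele = c("G", "A", "A"), other_allele = c("A", "G", "T"),
    eaf = c(0.27, 0.44, 0.1), beta = c(0.854, -0.62, 0.3),
    stringsAsFactors = FALSE)
  catalog <- data.frame(
    snp = c("rs1", "rs2", "rs2", "rs3", "rs9"),
    trait = "MCV",
    ref_snp = c("rs1", "rs2", "rs2x", "rs3", "rs9"),
    ref_effect_allele = c("A", "A", "A", "A", "C"),
    ref_beta = c(-0.008, -0.127, -0.005, 0.25, 1),
    stringsAsFactors = FALSE)
  cmp <- replication_compare(gwas, catalog)
  # opposite-allele report flips sign and stays concordant
  expect_identical(cmp$status[1], "ok")
  expect_true(cmp$flipped[1])
  expect_equal(cmp$ref_beta_harmonized[1], 0.008)
  expect_true(cmp$concordant[1])
  # same allele, same sign
  expect_false(cmp$flipped[2])
  expect_true(cmp$concordant[2])
  # proxy marker: no allele-level comparison
  expect_identical(cmp$status[3], "proxy")
  # A/T marker flagged strand-ambiguous but still compared
  expect_identical(cmp$status[4], "strand_ambiguous")
  expect_true(cmp$concordant[4])
  # absent from our scan
  expect_identical(cmp$status[5], "no_match")
})
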