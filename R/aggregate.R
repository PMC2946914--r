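#' Collapse repeated measurements to one phenotype per patient and trait
#'
#' The analysis phenotype is the median of a patient's kept values for each
#' trait (even counts use the mean of the two central order statistics —
#' `stats::median`). The number of contributing measurements is recorded per
#' trait.
#'
#' @param kept_labs Canonical lab table after filtering.
#' @param patients Optional patient table (`patient_id`, `age`, `sex`,
#'   `pad`) whose covariates are carried onto the phenotype rows.
#' @return Wide data frame: `patient_id`, covariates if supplied, one column
#'   per trait (NA when the patient has no kept value for it) and `n_<trait>`
#'   measurement counts.
#' @export
aggregate_median <- function(kept_labs, patients = NULL) {
  ids <- sort(unique(kept_labs$patient_id))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  if (!is.null(patients)) {
    m <- match(ids, patients$patient_id)
    stop_if(anyNA(m), "kept labs contain patients absent from patient table")
    for (cv in intersect(c("age", "sex", "pad"), names(patients))) {
      out[[cv]] <- patients[[cv]][m]
    }
  }
  for (t in RBC_TRAITS) {
    sub <- kept_labs[kept_labs$trait == t, , drop = FALSE]
    med <- tapply(sub$value, sub$patient_id, stats::median)
    cnt <- tapply(sub$value, sub$patient_id, length)
    out[[t]] <- as.vector(med[ids])
    out[[paste0("n_", t)]] <- ifelse(is.na(out[[t]]), 0L,
                                     as.vector(cnt[ids]))
  }
  out
}

#' Cohort characteristics summary with group comparison
#'
#' Per trait (and per continuous covariate): mean, SD and the quartiles
#' [Q1, median, Q3] under linear interpolation between order statistics
#' (`quantile type = 7`), overall and within the two groups; the group
#' contrast uses Welch's unequal-variance t test. Binary covariates are
#' summarized as counts/percentages and compared with a chi-square test
#' (no continuity correction).
#'
#' @param phenotypes Output of [aggregate_median()].
#' @param group Name of the binary grouping column (default `"pad"`).
#' @return Data frame with one row per variable: formatted
#'   `"mean+/-SD [Q1, median, Q3]"` strings per stratum, raw numeric
#'   columns, and the comparison P value (NA, with a flag, if a group is
#'   empty).
#' @export
cohort_summary <- function(phenotypes, group = "pad") {
  stop_if(!group %in% names(phenotypes), "grouping column '%s' missing", group)
  g <- phenotypes[[group]]
  groups_ok <- length(unique(stats::na.omit(g))) == 2
  cont_vars <- intersect(c("age", RBC_TRAITS), names(phenotypes))
  bin_vars <- intersect("sex", names(phenotypes))

  fmt <- function(x, quartiles = TRUE) {
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    base <- sprintf("%.1f±%.1f", mean(x), stats::sd(x))
    if (!quartiles) return(base)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%s [%.1f, %.1f, %.1f]", base, q[1], q[2], q[3])
  }
  rows <- list()
  for (v in cont_vars) {
    x <- phenotypes[[v]]
    p <- if (groups_ok && all(table(g[!is.na(x)]) >= 2)) {
      # Welch by default; undefined for degenerate (constant) data
      tryCatch(stats::t.test(x ~ g)$p.value, error = function(e) NA_real_)
    } else NA_real_
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE, na.rm = TRUE)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      total = fmt(x), group0 = fmt(x[g == 0]), group1 = fmt(x[g == 1]),
      mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
      q1 = q[1], median = q[2], q3 = q[3], p_value = p,
      stringsAsFactors = FALSE)
  }
  for (v in bin_vars) {
    x <- phenotypes[[v]]
    p <- if (groups_ok) {
      tab <- table(x, g)
      if (all(dim(tab) == c(2, 2))) {
        stats::chisq.test(tab, correct = FALSE)$p.value
      } else NA_real_
    } else NA_real_
    pct <- function(z) sprintf("%d (%.1f)", sum(z == 1, na.rm = TRUE),
                               100 * mean(z == 1, na.rm = TRUE))
    rows[[v]] <- data.frame(
      variable = v, type = "binary",
      total = pct(x), group0 = pct(x[g == 0]), group1 = pct(x[g == 1]),
      mean = mean(x, na.rm = TRUE), sd = NA_real_, q1 = NA_real_,
      median = NA_real_, q3 = NA_real_, p_value = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups_ok") <- groups_ok
  out
}
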