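#' Genotype matrix container
#'
#' Samples x markers dosage matrix (0/1/2 copies of the counted allele `a1`,
#' `NA` for missing) plus marker metadata. The counted allele is whatever
#' allele the source counted; quality control folds frequencies, so it need
#' not be the minor allele.
#'
#' @param dosage Integer/numeric matrix, samples in rows (rownames = sample
#'   ids), markers in columns.
#' @param map Data frame with one row per marker: `id`, `chrom`, `bp`,
#'   `a1` (counted allele), `a2`.
#' @return Object of class `genotype_matrix`: list with elements `dosage`
#'   and `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  stop_if(!is.matrix(dosage), "dosage must be a matrix")
  stop_if(is.null(rownames(dosage)), "dosage needs sample ids as rownames")
  stop_if(nrow(map) != ncol(dosage), "map rows must match dosage columns")
  stop_if(!all(c("id", "chrom", "bp", "a1", "a2") %in% names(map)),
          "map needs columns id, chrom, bp, a1, a2")
  stop_if(anyDuplicated(map$id) > 0, "marker ids must be unique")
  stop_if(any(map$bp <= 0), "positions must be positive")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  stop_if(any(bad), "dosages must be 0, 1, 2 or NA")
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param samples,markers Index vectors (logical, integer or character) on
#'   samples and markers; missing means keep all.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL) {
  d <- x$dosage; m <- x$map
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, m$id)
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
    rownames(m) <- NULL
  }
  genotype_matrix(d, m)
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' PED rows are `FID IID PAT MAT SEX PHENO` followed by two allele columns
#' per marker (missing genotype written as `0 0`); the MAP file holds
#' `chrom id 0 bp`. Dosage d of allele a1 becomes d copies of a1 and 2-d of
#' a2.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param sex Optional numeric vector (1 = male, 2 = female) per sample.
#' @return The two file paths, invisibly.
#' @export
write_plink <- function(g, prefix, sex = NULL) {
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  if (is.null(sex)) sex <- rep(0L, n)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- g$dosage[, j]
    a1 <- g$map$a1[j]; a2 <- g$map$a2[j]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, a1, a2))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a1, a2))
    al[, 2L * j - 1L] <- first
    al[, 2L * j] <- second
  }
  ped <- cbind(rownames(g$dosage), rownames(g$dosage), "0", "0",
               as.character(sex), "-9", al)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(
    data.frame(g$map$chrom, g$map$id, 0L, g$map$bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK PED/MAP text files
#'
#' Dosage counts the first allele listed for each marker in the PED file
#' unless that allele is absent (then the other allele is counted); the
#' counted allele is recorded in the map's `a1`.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  map_raw <- utils::read.table(paste0(prefix, ".map"),
                               col.names = c("chrom", "id", "cm", "bp"),
                               stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map_raw)
  stop_if(ncol(ped) != 6L + 2L * m,
          "PED has %d columns; MAP implies %d", ncol(ped), 6L + 2L * m)
  n <- nrow(ped)
  d <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- ped[[6L + 2L * j - 1L]]
    x2 <- ped[[6L + 2L * j]]
    obs <- c(x1, x2)
    alleles <- sort(setdiff(unique(obs), "0"))
    stop_if(length(alleles) > 2L, "marker %s has >2 alleles", map_raw$id[j])
    a1[j] <- if (length(alleles) >= 1L) alleles[1] else "0"
    a2[j] <- if (length(alleles) == 2L) alleles[2] else "0"
    miss <- x1 == "0" | x2 == "0"
    d[, j] <- (x1 == a1[j]) + (x2 == a1[j])
    d[miss, j] <- NA_integer_
  }
  rownames(d) <- ped[[2]]
  genotype_matrix(d, data.frame(id = map_raw$id, chrom = map_raw$chrom,
                                bp = map_raw$bp, a1 = a1, a2 = a2,
                                stringsAsFactors = FALSE))
}
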