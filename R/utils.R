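#' @keywords internal
"_PACKAGE"

# Six complete-blood-count red-cell traits handled throughout the package.
# HGB/HCT/RBC are measured; MCV/MCH/MCHC are the derived indices.
RBC_TRAITS <- c("HGB", "HCT", "RBC", "MCV", "MCH", "MCHC")
PRIMARY_TRAITS <- c("HGB", "HCT", "RBC")
DERIVED_TRAITS <- c("MCV", "MCH", "MCHC")

TRAIT_UNITS <- c(
  HGB = "g/dL", HCT = "%", RBC = "x10^12/L",
  MCV = "fL", MCH = "pg", MCHC = "%"
)

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

#' Coerce a date-like vector to integer day numbers
#'
#' The package compares dates as whole days (admission rules and exclusion
#' windows are stated in calendar dates). `Date` vectors become days since
#' 1970-01-01; character vectors are parsed as ISO dates; numeric vectors are
#' taken as day numbers already.
#'
#' @param x Date, character (ISO 8601) or numeric vector.
#' @return Integer vector of day numbers (NA preserved).
#' @export
as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(unclass(x)))
  if (is.character(x)) return(as.integer(unclass(as.Date(x))))
  if (is.numeric(x)) return(as.integer(x))
  stop("cannot interpret as dates: ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

# Deterministic per-stage seed derivation from one master seed; keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(patients = 11L, labs = 23L, confounders = 37L,
               genotypes = 51L, effects = 67L, pipeline = 83L,
               power = 97L, fixtures = 113L)
  o <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + o * 104729) %% 2147483587)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
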