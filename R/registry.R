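#' Default window policies for exclusion intervals
#'
#' A policy turns a coded event on day d into the interval
#' `[d - lookback_days, d + duration_days]`, closed at both ends; a chronic
#' policy has an unbounded right end (`duration_days = Inf`). Shipped
#' defaults: chronic conditions and transplants are excluded from 30 days
#' before the first code onward; medication codes/mentions and major-blood-
#' loss surgery exclude 90 days forward with no lookback. The lengths are
#' configuration (clinically conservative defaults), not estimates.
#'
#' @return Named list of policies, each `list(lookback_days, duration_days)`.
#' @export
default_window_policies <- function() {
  list(
    chronic = list(lookback_days = 30, duration_days = Inf),
    medication = list(lookback_days = 0, duration_days = 90),
    surgery = list(lookback_days = 0, duration_days = 90)
  )
}

#' Illustrative exclusion-code registry
#'
#' Maps diagnosis/procedure codes to exclusion categories and window
#' policies. Categories: `condition` (malignancy, hereditary anemia,
#' cirrhosis, malabsorption), `transplant`, `medication_code`
#' (chemotherapy administration), `surgery_blood_loss` (anesthesia codes for
#' surgeries with major blood loss). Codes ending in `*` match as prefixes.
#'
#' This registry is ILLUSTRATIVE: a small, documented example set, not an
#' authoritative clinical code list. Production use requires a locally
#' curated registry in the same format.
#'
#' @return Data frame `category`, `code_system`, `code`, `policy`.
#' @export
default_code_registry <- function() {
  e <- function(category, code_system, code, policy)
    data.frame(category = category, code_system = code_system, code = code,
               policy = policy, stringsAsFactors = FALSE)
  rbind(
    e("condition", "ICD9CM", "203*", "chronic"),   # multiple myeloma
    e("condition", "ICD9CM", "204*", "chronic"),   # lymphoid leukemia
    e("condition", "ICD9CM", "205*", "chronic"),   # myeloid leukemia
    e("condition", "ICD9CM", "282*", "chronic"),   # hereditary anemias
    e("condition", "ICD9CM", "571.2", "chronic"),  # alcoholic cirrhosis
    e("condition", "ICD9CM", "571.5", "chronic"),  # cirrhosis, other
    e("condition", "ICD9CM", "579*", "chronic"),   # malabsorption
    e("condition", "ICD9CM", "153*", "chronic"),   # colon malignancy
    e("condition", "ICD9CM", "174*", "chronic"),   # breast malignancy
    e("transplant", "ICD9CM", "V42*", "chronic"),  # organ transplant status
    e("transplant", "ICD9PROC", "41.0*", "chronic"), # bone marrow transplant
    e("transplant", "CPT4", "38240", "chronic"),   # HPC allogeneic transplant
    e("medication_code", "CPT4", "9640*", "medication"), # chemo admin
    e("medication_code", "CPT4", "96413", "medication"),
    e("medication_code", "CPT4", "96415", "medication"),
    e("medication_code", "CPT4", "96542", "medication"),
    e("surgery_blood_loss", "CPT4", "00790", "surgery"), # upper abdomen
    e("surgery_blood_loss", "CPT4", "00840", "surgery"), # lower abdomen
    e("surgery_blood_loss", "CPT4", "01402", "surgery"), # knee arthroplasty
    e("surgery_blood_loss", "CPT4", "01638", "surgery"), # shoulder
    e("surgery_blood_loss", "CPT4", "00560", "surgery")  # heart/great vessels
  )
}

REGISTRY_CATEGORIES <- c("condition", "transplant", "medication_code",
                         "surgery_blood_loss")
CODE_SYSTEMS <- c("ICD9CM", "ICD9PROC", "CPT4")

validate_registry <- function(registry, policies) {
  stop_if(nrow(registry) == 0, "registry is empty")
  stop_if(!all(registry$category %in% REGISTRY_CATEGORIES),
          "unknown registry category")
  stop_if(!all(registry$code_system %in% CODE_SYSTEMS),
          "unknown registry code system")
  stop_if(!all(registry$policy %in% names(policies)),
          "registry references an undefined window policy")
  for (p in policies) {
    stop_if(p$lookback_days < 0, "policy lookback_days must be >= 0")
    stop_if(!(p$duration_days > 0), "policy duration_days must be > 0 or Inf")
  }
  invisible(registry)
}

#' Illustrative medication lexicon
#'
#' Generic and brand names of oral chemotherapeutic and immunosuppressive
#' drugs, for case-insensitive whole-word/phrase matching in clinical notes.
#' Like the code registry, the shipped list is a documented example, not an
#' authoritative formulary.
#'
#' @return Data frame `name`, `class`.
#' @export
default_medication_lexicon <- function() {
  data.frame(
    name = c("methotrexate", "azathioprine", "imuran", "cyclophosphamide",
             "cytoxan", "mycophenolate mofetil", "cellcept", "tacrolimus",
             "prograf", "cyclosporine", "hydroxyurea", "capecitabine",
             "xeloda", "chlorambucil", "mercaptopurine"),
    class = c("chemotherapy", "immunosuppressant", "immunosuppressant",
              "chemotherapy", "chemotherapy", "immunosuppressant",
              "immunosuppressant", "immunosuppressant", "immunosuppressant",
              "immunosuppressant", "chemotherapy", "chemotherapy",
              "chemotherapy", "chemotherapy", "chemotherapy"),
    stringsAsFactors = FALSE
  )
}

validate_lexicon <- function(lexicon) {
  stop_if(is.null(lexicon) || nrow(lexicon) == 0, "medication lexicon is empty")
  stop_if(anyDuplicated(tolower(lexicon$name)) > 0,
          "duplicate lexicon names")
  invisible(lexicon)
}

# Does `code` match a registry pattern (exact, or prefix when the pattern
# ends in "*")?
code_matches <- function(code, pattern) {
  if (endsWith(pattern, "*")) {
    pre <- substr(pattern, 1L, nchar(pattern) - 1L)
    substr(code, 1L, nchar(pre)) == pre
  } else {
    code == pattern
  }
}
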