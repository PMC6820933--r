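#' @keywords internal
"_PACKAGE"

## Controlled vocabulary for the registry model and the grading dimensions.
## Enumerations are stored canonically in lower_snake form; input is accepted
## case-insensitively with spaces or hyphens in place of underscores.

# The five aspects of evaluation a single study record can report.
# One record carries exactly one aspect; a publication reporting several
# aspects is entered as several records sharing a citation.
ASPECTS <- c(
  "internal_validation",
  "external_validation",
  "potential_effect",
  "usability",
  "post_implementation_impact"
)

# Study designs and their quality tiers. Tier 1: experimental; tier 2:
# well-designed observational; tier 3: subjective/descriptive. Usability-
# specific methods sit at tier 2 unless embedded in a trial (in which case
# the record's design is the trial design).
DESIGN_TIERS <- c(
  systematic_review_of_trials   = 1L,
  randomised_controlled_trial   = 1L,
  nonrandomised_controlled_trial = 1L,
  cohort                        = 2L,
  case_control                  = 2L,
  before_after_observational    = 2L,
  cross_sectional               = 2L,
  think_aloud                   = 2L,
  near_live_simulation          = 2L,
  usability_survey              = 2L,
  expert_opinion                = 3L,
  descriptive_report            = 3L,
  survey                        = 3L
)

DESIGNS <- names(DESIGN_TIERS)

DIRECTIONS <- c("positive", "negative", "equivocal")

OUTCOME_CATEGORIES <- c(
  "clinical_effectiveness",
  "healthcare_efficiency",
  "patient_safety"
)

PROPORTION_SCALES <- c("unit_interval", "percent")

# Measures validated against the registry's declared proportion scale.
PROPORTION_MEASURES <- c("sensitivity", "specificity", "c-statistic",
                         "c_statistic", "auc")

# Scan order for "highest" phase/level. This total order is an internal
# computation device only: the emitted grade is a code, not an ordinal score.
GRADE_SCAN_ORDER <- c("A1", "A2", "A3", "B1", "B2", "C1", "C2", "C3", "C0")

UNGRADED <- "UNGRADED"

#' Grade codes in scan order
#'
#' Returns the nine grade codes from highest (`A1`) to lowest (`C0`). The
#' sentinel `UNGRADED` ranks below all of them. The order is used internally
#' to locate the highest positively supported phase and level; the grade
#' itself is an audit code, not an ordinal quality score.
#'
#' @return Character vector of grade codes.
#' @export
#' @examples
#' grade_scan_order()
grade_scan_order <- function() GRADE_SCAN_ORDER

#' Phase and level components of a grade code
#'
#' @param code A grade code such as `"A1"`, `"C0"`, or `"UNGRADED"`.
#' @return `grade_phase()` returns the phase letter (`"A"`, `"B"`, `"C"`) or
#'   `NA` for `UNGRADED`; `grade_level()` returns the integer level digit or
#'   `NA` for `UNGRADED`.
#' @export
#' @examples
#' grade_phase("A2")
#' grade_level("A2")
grade_phase <- function(code) {
  ifelse(code %in% GRADE_SCAN_ORDER, substr(code, 1L, 1L), NA_character_)
}

#' @rdname grade_phase
#' @export
grade_level <- function(code) {
  ifelse(code %in% GRADE_SCAN_ORDER,
         as.integer(substr(code, 2L, 2L)), NA_integer_)
}

#' Quality tier of a study design
#'
#' Maps each study design to its evidence-quality tier: tier 1 experimental
#' (controlled trials and their systematic reviews), tier 2 well-designed
#' observational (including dedicated usability methods such as think-aloud
#' and near-live simulation), tier 3 subjective or descriptive.
#'
#' @param design Canonical design name(s).
#' @return Integer tier(s) in `1:3`.
#' @export
#' @examples
#' design_tier("randomised_controlled_trial")
#' design_tier(c("cohort", "expert_opinion"))
design_tier <- function(design) {
  tier <- unname(DESIGN_TIERS[design])
  if (anyNA(tier)) {
    bad <- unique(design[is.na(tier)])
    stop("unknown study design: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(DESIGNS, collapse = ", "), ")", call. = FALSE)
  }
  tier
}

# Canonicalise an enumeration token: trim, lower-case, spaces/hyphens to
# underscores. Returns the canonical value or raises naming the field.
canon_enum <- function(value, allowed, field, record = NULL) {
  if (is.null(value) || length(value) == 0L || is.na(value)) {
    return(NA_character_)
  }
  v <- gsub("[ -]+", "_", tolower(trimws(as.character(value))))
  if (!v %in% allowed) {
    where <- if (is.null(record)) "" else paste0(" in record '", record, "'")
    stop("invalid value '", value, "' for ", field, where,
         "; allowed values: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  v
}

# Scalar coercion helpers used by the constructors so that round-tripped
# registries compare identical().
as_scalar_chr <- function(x) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) {
    return(NA_character_)
  }
  as.character(x)[1L]
}

as_scalar_int <- function(x) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) {
    return(NA_integer_)
  }
  as.integer(round(as.numeric(x)[1L]))
}

as_scalar_lgl <- function(x, default = NA) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) {
    return(as.logical(default))
  }
  as.logical(x)[1L]
}
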