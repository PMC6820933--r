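finding_row <- function(severity, record_id, message) {
  data.frame(severity = severity, record_id = record_id, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(), record_id = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate an evidence registry
#'
#' Checks every registry invariant and returns the findings as a data frame
#' rather than throwing: identifier uniqueness and referential integrity,
#' plausible years, non-empty tool target specifications, the
#' primary-implies-internal-validation rule, presence/absence of the outcome
#' category by aspect, proportion-like finding values against the declared
#' registry scale, and non-negative sample sizes. Missing optional fields
#' that the mixed-evidence resolver uses as inputs (`sample_size`, `year`)
#' produce non-fatal warnings.
#'
#' @param registry A [grasp_registry()].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `record_id` and `message`; zero rows when the registry is clean.
#' @export
#' @examples
#' validate_registry(build_fixture("ottawa"))
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "grasp_registry"))
  out <- list(no_findings())
  err <- function(id, msg) out[[length(out) + 1L]] <<- finding_row("error", id, msg)
  warn <- function(id, msg) out[[length(out) + 1L]] <<- finding_row("warning", id, msg)

  tool_ids <- registry_tool_ids(registry)
  dup <- unique(tool_ids[duplicated(tool_ids)])
  for (d in dup) err(d, "duplicate tool_id within registry")

  for (t in registry$tools) {
    id <- t$tool_id
    if (is.na(id) || !nzchar(id)) err("<tool>", "tool_id must be non-empty")
    if (is.na(t$year_published) || t$year_published < 1900L ||
        t$year_published > 2100L) {
      err(id, "year_published must be a plausible 4-digit year (1900-2100)")
    }
    for (f in c("name", "target_population", "target_outcome",
                "clinical_setting")) {
      if (is.na(t[[f]]) || !nzchar(trimws(t[[f]]))) {
        err(id, paste0(f, " must be non-empty (it drives match assessment)"))
      }
    }
  }

  study_ids <- registry_study_ids(registry)
  dup <- unique(study_ids[duplicated(study_ids)])
  for (d in dup) err(d, "duplicate study_id within registry")

  for (s in registry$studies) {
    id <- s$study_id
    if (is.na(id) || !nzchar(id)) err("<study>", "study_id must be non-empty")
    if (!s$tool_id %in% tool_ids) {
      err(id, paste0("references unknown tool_id '", s$tool_id,
                     "' (referential integrity)"))
    }
    if (isTRUE(s$is_primary) && !identical(s$aspect, "internal_validation")) {
      err(id, "primary (development) studies must have aspect internal_validation")
    }
    needs_oc <- s$aspect %in% c("potential_effect", "post_implementation_impact")
    if (needs_oc && is.na(s$outcome_category)) {
      err(id, paste0("outcome_category is required on ", s$aspect, " records"))
    }
    if (!needs_oc && !is.na(s$outcome_category)) {
      err(id, paste0("outcome_category must be absent on ", s$aspect, " records"))
    }
    if (!is.na(s$match$sample_size) && s$match$sample_size < 0L) {
      err(id, "sample_size must be non-negative")
    }
    if (!is.na(s$year) && (s$year < 1900L || s$year > 2100L)) {
      err(id, "study year must be a plausible 4-digit year (1900-2100)")
    }
    for (f in s$findings) {
      nm <- tolower(gsub("[ -]+", "_", f$measure_name))
      nm <- gsub("_", "-", nm, fixed = TRUE)
      if (nm %in% gsub("_", "-", PROPORTION_MEASURES, fixed = TRUE) &&
          !is.na(f$value)) {
        hi <- if (registry$proportion_scale == "percent") 100 else 1
        if (f$value < 0 || f$value > hi) {
          err(id, paste0("proportion-like finding '", f$measure_name,
                         "' = ", f$value, " outside declared ",
                         registry$proportion_scale, " scale [0,", hi, "]"))
        }
      }
    }
    # non-fatal: the mixed-evidence resolver uses these when present
    if (is.na(s$match$sample_size)) {
      warn(id, "sample_size absent (small-sample demotion cannot apply)")
    }
    if (is.na(s$year)) {
      warn(id, "year absent (recency tie-break cannot apply)")
    }
  }

  graded_ids <- unique(vapply(registry$studies, `[[`, character(1), "tool_id"))
  for (tid in setdiff(tool_ids, graded_ids)) {
    warn(tid, "tool has no evidence studies and will grade as UNGRADED")
  }

  do.call(rbind, out)
}
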