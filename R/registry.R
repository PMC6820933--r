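#' Construct a predictive-tool profile
#'
#' A tool profile carries the identifying metadata of one clinical predictive
#' tool together with its original target specification (population, outcome,
#' setting). The target specification is what evaluation studies are matched
#' against when mixed evidence has to be resolved.
#'
#' @param tool_id Short unique token identifying the tool within a registry.
#' @param name Human-readable tool name.
#' @param authors Character vector of author names of the development study.
#' @param year_published Four-digit year of the primary publication.
#' @param intended_use Diagnostic, prognostic or therapeutic decision support
#'   (free text allowed).
#' @param target_population The population the tool was developed for.
#' @param target_outcome The outcome the tool predicts.
#' @param clinical_setting The care setting the tool was developed in.
#' @param input_data_source Source of the tool's inputs (administrative,
#'   clinical, laboratory, ...).
#' @param input_data_type Type of the tool's inputs.
#' @param intended_user Who is meant to apply the tool.
#' @param recommended_action The action the tool's output is meant to trigger.
#' @param local_context_notes Optional notes on local-context applicability
#'   (data availability, locally calibrated predictors).
#' @return An object of class `grasp_tool`.
#' @export
#' @examples
#' grasp_tool("lace", "LACE Index", authors = "van Walraven",
#'   year_published = 2010, intended_use = "prognostic",
#'   target_population = "adult medical and surgical inpatients",
#'   target_outcome = "30-day readmission or death",
#'   clinical_setting = "hospital discharge")
grasp_tool <- function(tool_id, name, authors = character(),
                       year_published = NA, intended_use = NA,
                       target_population = NA, target_outcome = NA,
                       clinical_setting = NA, input_data_source = NA,
                       input_data_type = NA, intended_user = NA,
                       recommended_action = NA, local_context_notes = NA) {
  structure(list(
    tool_id            = as_scalar_chr(tool_id),
    name               = as_scalar_chr(name),
    authors            = as.character(unlist(authors)),
    year_published     = as_scalar_int(year_published),
    intended_use       = as_scalar_chr(intended_use),
    target_population  = as_scalar_chr(target_population),
    target_outcome     = as_scalar_chr(target_outcome),
    clinical_setting   = as_scalar_chr(clinical_setting),
    input_data_source  = as_scalar_chr(input_data_source),
    input_data_type    = as_scalar_chr(input_data_type),
    intended_user      = as_scalar_chr(intended_user),
    recommended_action = as_scalar_chr(recommended_action),
    local_context_notes = as_scalar_chr(local_context_notes)
  ), class = "grasp_tool")
}

#' Construct a single effect-size finding
#'
#' @param measure_name Name of the measure (sensitivity, specificity,
#'   c-statistic, calibration slope, Brier score, percentage change in a
#'   process measure, satisfaction score, ...).
#' @param value Numeric value of the measure.
#' @param units Units of the value (`"proportion"`, `"percent"`, ...).
#' @param comparator_note Optional note on a comparator (used for studies
#'   that benchmarked the tool against another tool).
#' @return An object of class `grasp_finding`.
#' @export
grasp_finding <- function(measure_name, value, units = NA,
                          comparator_note = NA) {
  structure(list(
    measure_name    = as_scalar_chr(measure_name),
    value           = as.numeric(value)[1L],
    units           = as_scalar_chr(units),
    comparator_note = as_scalar_chr(comparator_note)
  ), class = "grasp_finding")
}

#' Construct a specification-match profile
#'
#' Records how closely an evaluation study matched the tool's original target
#' specification. A study is "fully matching" iff the population, outcome and
#' setting flags are all `TRUE`. The sample size feeds the small-sample
#' demotion rule of the mixed-evidence resolver.
#'
#' @param population_match,outcome_match,setting_match Logical flags against
#'   the tool's target population, target outcome and clinical setting.
#' @param sample_size Optional non-negative number of patients/participants.
#' @param match_notes Free-text notes (e.g. which subpopulation was studied).
#' @return An object of class `grasp_match`.
#' @export
grasp_match <- function(population_match = TRUE, outcome_match = TRUE,
                        setting_match = TRUE, sample_size = NA,
                        match_notes = NA) {
  n <- as_scalar_int(sample_size)
  if (!is.na(n) && n < 0L) stop("sample_size must be non-negative", call. = FALSE)
  structure(list(
    population_match = as_scalar_lgl(population_match),
    outcome_match    = as_scalar_lgl(outcome_match),
    setting_match    = as_scalar_lgl(setting_match),
    sample_size      = n,
    match_notes      = as_scalar_chr(match_notes)
  ), class = "grasp_match")
}

#' Is a study fully matching the tool specification?
#'
#' @param match A `grasp_match` or a `grasp_study`.
#' @return `TRUE` iff population, outcome and setting all match.
#' @export
is_fully_matching <- function(match) {
  if (inherits(match, "grasp_study")) match <- match$match
  isTRUE(match$population_match) && isTRUE(match$outcome_match) &&
    isTRUE(match$setting_match)
}

#' Construct an evidence-study record
#'
#' One record per publication per evaluated aspect: a publication that reports
#' both (say) usability testing and post-implementation impact is entered as
#' two records sharing a citation, because level assignment is aspect-driven.
#'
#' @param study_id Short unique token within a registry.
#' @param tool_id The `tool_id` of the tool the study evaluates.
#' @param citation Opaque citation label (reference number, DOI, ...).
#' @param year Publication year (optional but recommended: recency is a
#'   tie-break input to the mixed-evidence resolver).
#' @param is_primary `TRUE` for the tool's development study. Primary records
#'   must have aspect `internal_validation` (development plus internal
#'   validation is the first evaluation step).
#' @param aspect One of `internal_validation`, `external_validation`,
#'   `potential_effect`, `usability`, `post_implementation_impact`.
#' @param design Study design (see [design_tier()] for the allowed designs).
#' @param direction Reported conclusion: `positive`, `negative` or
#'   `equivocal`. Equivocal is stored distinctly but aggregates with negative
#'   in every direction tally.
#' @param match A [grasp_match()] profile.
#' @param outcome_category For potential-effect and post-implementation
#'   records: `clinical_effectiveness`, `healthcare_efficiency` or
#'   `patient_safety`. Must be absent on other aspects.
#' @param findings List of [grasp_finding()] effect sizes.
#' @param population_description,setting_description Free text describing the
#'   studied population and setting.
#' @param conclusion_summary Free-text summary of the study conclusion.
#' @param roster_inferred `TRUE` when the record's role in a packaged corpus
#'   was inferred rather than individually narrated by the source appraisal.
#' @return An object of class `grasp_study`.
#' @export
grasp_study <- function(study_id, tool_id, citation = NA, year = NA,
                        is_primary = FALSE, aspect, design,
                        direction, match = grasp_match(),
                        outcome_category = NA, findings = list(),
                        population_description = NA,
                        setting_description = NA,
                        conclusion_summary = NA,
                        roster_inferred = FALSE) {
  sid <- as_scalar_chr(study_id)
  aspect <- canon_enum(aspect, ASPECTS, "aspect", sid)
  design <- canon_enum(design, DESIGNS, "design", sid)
  direction <- canon_enum(direction, DIRECTIONS, "direction", sid)
  oc <- if (is.null(outcome_category) || all(is.na(outcome_category))) {
    NA_character_
  } else {
    canon_enum(outcome_category, OUTCOME_CATEGORIES, "outcome_category", sid)
  }
  if (!inherits(match, "grasp_match")) match <- do.call(grasp_match, as.list(match))
  findings <- lapply(findings, function(f) {
    if (inherits(f, "grasp_finding")) f else do.call(grasp_finding, as.list(f))
  })
  structure(list(
    study_id  = sid,
    tool_id   = as_scalar_chr(tool_id),
    citation  = as_scalar_chr(citation),
    year      = as_scalar_int(year),
    is_primary = as_scalar_lgl(is_primary, default = FALSE),
    aspect    = aspect,
    design    = design,
    direction = direction,
    match     = match,
    outcome_category = oc,
    findings  = findings,
    population_description = as_scalar_chr(population_description),
    setting_description    = as_scalar_chr(setting_description),
    conclusion_summary     = as_scalar_chr(conclusion_summary),
    roster_inferred = as_scalar_lgl(roster_inferred, default = FALSE)
  ), class = "grasp_study")
}

#' Construct an evidence registry
#'
#' A registry bundles tool profiles with their evidence-study records plus the
#' registry-wide metadata: a schema version and the declared scale on which
#' proportion-like findings (sensitivity, specificity, c-statistic) are
#' recorded (`unit_interval` for `[0,1]`, `percent` for `[0,100]`).
#'
#' @param tools List of [grasp_tool()] profiles.
#' @param studies List of [grasp_study()] records.
#' @param schema_version Schema version string.
#' @param proportion_scale `"unit_interval"` or `"percent"`.
#' @return An object of class `grasp_registry`.
#' @export
grasp_registry <- function(tools = list(), studies = list(),
                           schema_version = "1.0",
                           proportion_scale = "unit_interval") {
  structure(list(
    schema_version   = as_scalar_chr(schema_version),
    proportion_scale = canon_enum(proportion_scale, PROPORTION_SCALES,
                                  "proportion_scale"),
    tools   = unname(lapply(tools, function(t) {
      if (inherits(t, "grasp_tool")) t else do.call(grasp_tool, as.list(t))
    })),
    studies = unname(lapply(studies, function(s) {
      if (inherits(s, "grasp_study")) s else do.call(grasp_study, as.list(s))
    }))
  ), class = "grasp_registry")
}

#' Registry accessors
#'
#' `registry_tool_ids()` and `registry_study_ids()` list identifiers in
#' registry order; `registry_tool()` fetches one tool profile;
#' `studies_for_tool()` returns the evidence records for one tool, in
#' registry order.
#'
#' @param registry A `grasp_registry`.
#' @param tool_id A tool identifier.
#' @return Character vectors, a `grasp_tool`, or a list of `grasp_study`.
#' @export
registry_tool_ids <- function(registry) {
  vapply(registry$tools, `[[`, character(1), "tool_id")
}

#' @rdname registry_tool_ids
#' @export
registry_study_ids <- function(registry) {
  vapply(registry$studies, `[[`, character(1), "study_id")
}

#' @rdname registry_tool_ids
#' @export
registry_tool <- function(registry, tool_id) {
  i <- match(tool_id, registry_tool_ids(registry))
  if (is.na(i)) stop("no tool '", tool_id, "' in registry", call. = FALSE)
  registry$tools[[i]]
}

#' @rdname registry_tool_ids
#' @export
studies_for_tool <- function(registry, tool_id) {
  keep <- vapply(registry$studies, function(s) identical(s$tool_id, tool_id),
                 logical(1))
  registry$studies[keep]
}

#' Combine registries
#'
#' Concatenates the tools and studies of several registries into one. The
#' inputs must agree on schema version and proportion scale and must not
#' share tool or study identifiers.
#'
#' @param ... `grasp_registry` objects.
#' @return A single `grasp_registry`.
#' @export
combine_registries <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && !inherits(regs[[1L]], "grasp_registry")) {
    regs <- regs[[1L]]
  }
  stopifnot(length(regs) >= 1L)
  scales <- unique(vapply(regs, `[[`, character(1), "proportion_scale"))
  if (length(scales) > 1L) {
    stop("registries declare different proportion scales: ",
         paste(scales, collapse = ", "), call. = FALSE)
  }
  out <- grasp_registry(
    tools   = do.call(c, lapply(regs, `[[`, "tools")),
    studies = do.call(c, lapply(regs, `[[`, "studies")),
    schema_version   = regs[[1L]]$schema_version,
    proportion_scale = scales
  )
  if (anyDuplicated(registry_tool_ids(out)) ||
      anyDuplicated(registry_study_ids(out))) {
    stop("combined registries share tool or study identifiers", call. = FALSE)
  }
  out
}

#' @export
print.grasp_registry <- function(x, ...) {
  cat("<grasp_registry> schema ", x$schema_version,
      ", proportion scale ", x$proportion_scale, "\n", sep = "")
  cat("  tools:   ", length(x$tools), " (",
      paste(registry_tool_ids(x), collapse = ", "), ")\n", sep = "")
  n_primary <- sum(vapply(x$studies, `[[`, logical(1), "is_primary"))
  cat("  studies: ", length(x$studies), " (", n_primary, " primary, ",
      length(x$studies) - n_primary, " evaluation)\n", sep = "")
  invisible(x)
}

#' @export
print.grasp_tool <- function(x, ...) {
  cat("<grasp_tool> ", x$tool_id, ": ", x$name,
      " (", x$year_published, ", ", x$intended_use, ")\n", sep = "")
  cat("  target: ", x$target_population, " / ", x$target_outcome,
      " / ", x$clinical_setting, "\n", sep = "")
  invisible(x)
}

#' @export
print.grasp_study <- function(x, ...) {
  cat("<grasp_study> ", x$study_id, " [", x$aspect, ", ", x$design, ", ",
      x$direction, if (isTRUE(x$is_primary)) ", primary" else "", "]\n",
      sep = "")
  invisible(x)
}
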