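## Registry serialisation. JSON is canonical; YAML is accepted; CSV is a flat
## export/import format written as a directory of three tables (registry.csv
## with the registry metadata, tools.csv, studies.csv) with list-valued cells
## (authors, findings) serialised as JSON strings.

# Drop NA scalars so serialised files carry only populated fields.
strip_na <- function(x) {
  x[!vapply(x, function(v) length(v) == 1L && !is.list(v) && is.na(v),
            logical(1))]
}

tool_to_list <- function(t) strip_na(unclass(t))

study_to_list <- function(s) {
  out <- unclass(s)
  out$match <- strip_na(unclass(out$match))
  out$findings <- lapply(out$findings, function(f) strip_na(unclass(f)))
  if (!isTRUE(out$roster_inferred)) out$roster_inferred <- NULL
  strip_na(out)
}

registry_to_list <- function(registry) {
  list(
    schema_version   = registry$schema_version,
    proportion_scale = registry$proportion_scale,
    tools   = lapply(registry$tools, tool_to_list),
    studies = lapply(registry$studies, study_to_list)
  )
}

registry_from_list <- function(x) {
  if (is.null(x$schema_version)) {
    stop("registry file lacks the required 'schema_version' header field",
         call. = FALSE)
  }
  grasp_registry(
    tools   = lapply(x$tools, function(t) do.call(grasp_tool, t)),
    studies = lapply(x$studies, function(s) {
      s$match <- if (is.null(s$match)) grasp_match() else
        do.call(grasp_match, s$match)
      s$findings <- lapply(s$findings, function(f) do.call(grasp_finding, f))
      do.call(grasp_study, s)
    }),
    schema_version   = x$schema_version,
    proportion_scale = if (is.null(x$proportion_scale)) "unit_interval" else
      x$proportion_scale
  )
}

detect_format <- function(path) {
  if (dir.exists(path)) return("csv")
  switch(tolower(tools::file_ext(path)),
    json = "json",
    yaml = ,
    yml  = "yaml",
    csv  = "csv",
    stop("cannot auto-detect registry format from '", basename(path),
         "'; pass format = json|yaml|csv", call. = FALSE)
  )
}

#' Read an evidence registry
#'
#' Loads and fully validates a registry from JSON (canonical), YAML, or the
#' flat CSV layout (a directory holding `registry.csv`, `tools.csv` and
#' `studies.csv`). Enumerated fields are accepted case-insensitively and
#' stored in canonical `lower_snake` form. Referential integrity (every
#' study's `tool_id` resolves) and all type invariants are enforced; use
#' [validate_registry()] directly for a non-throwing report.
#'
#' @param path Path to a registry file (JSON/YAML) or CSV directory.
#' @param format `"json"`, `"yaml"`, `"csv"`, or `"auto"` (by extension).
#' @return A validated [grasp_registry()].
#' @export
#' @examples
#' reg <- build_fixture("lace")
#' p <- tempfile(fileext = ".json")
#' write_registry(reg, p)
#' identical(load_registry(p), reg)
load_registry <- function(path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") format <- detect_format(path)
  raw <- switch(format,
    json = tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop("JSON parse failure in '", basename(path),
                               "': ", conditionMessage(e), call. = FALSE)),
    yaml = tryCatch(
      yaml::read_yaml(path),
      error = function(e) stop("YAML parse failure in '", basename(path),
                               "': ", conditionMessage(e), call. = FALSE)),
    csv  = read_registry_csv(path)
  )
  reg <- registry_from_list(raw)
  findings <- validate_registry(reg)
  errors <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0L) {
    stop("registry '", basename(path), "' failed validation:\n",
         paste0("  [", errors$record_id, "] ", errors$message,
                collapse = "\n"), call. = FALSE)
  }
  reg
}

#' Write an evidence registry
#'
#' Serialises a registry so that [load_registry()] reproduces it
#' field-for-field (round-trip identity) in every supported format.
#'
#' @param registry A [grasp_registry()].
#' @param path Output file (JSON/YAML) or directory (CSV).
#' @param format `"json"`, `"yaml"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path,
                           format = c("auto", "json", "yaml", "csv")) {
  stopifnot(inherits(registry, "grasp_registry"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || tools::file_ext(path) == "") "csv" else
      detect_format(path)
  }
  x <- registry_to_list(registry)
  switch(format,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"),
    yaml = yaml::write_yaml(x, path),
    csv  = write_registry_csv(registry, path)
  )
  invisible(path)
}

## ---- CSV layout -----------------------------------------------------------

TOOL_CSV_COLS <- c("tool_id", "name", "authors", "year_published",
                   "intended_use", "target_population", "target_outcome",
                   "clinical_setting", "input_data_source", "input_data_type",
                   "intended_user", "recommended_action",
                   "local_context_notes")

STUDY_CSV_COLS <- c("study_id", "tool_id", "citation", "year", "is_primary",
                    "aspect", "design", "direction", "population_match",
                    "outcome_match", "setting_match", "sample_size",
                    "match_notes", "outcome_category", "findings",
                    "population_description", "setting_description",
                    "conclusion_summary", "roster_inferred")

write_registry_csv <- function(registry, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- data.frame(schema_version = registry$schema_version,
                     proportion_scale = registry$proportion_scale,
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, file.path(path, "registry.csv"), row.names = FALSE)

  tool_rows <- lapply(registry$tools, function(t) {
    t$authors <- as.character(
      jsonlite::toJSON(t$authors, auto_unbox = FALSE))
    as.data.frame(t[TOOL_CSV_COLS], stringsAsFactors = FALSE)
  })
  tools_df <- if (length(tool_rows)) do.call(rbind, tool_rows) else
    as.data.frame(stats::setNames(rep(list(character()), length(TOOL_CSV_COLS)),
                                  TOOL_CSV_COLS))
  utils::write.csv(tools_df, file.path(path, "tools.csv"), row.names = FALSE)

  study_rows <- lapply(registry$studies, function(s) {
    data.frame(
      study_id = s$study_id, tool_id = s$tool_id, citation = s$citation,
      year = s$year, is_primary = s$is_primary, aspect = s$aspect,
      design = s$design, direction = s$direction,
      population_match = s$match$population_match,
      outcome_match = s$match$outcome_match,
      setting_match = s$match$setting_match,
      sample_size = s$match$sample_size,
      match_notes = s$match$match_notes,
      outcome_category = s$outcome_category,
      findings = as.character(jsonlite::toJSON(
        lapply(s$findings, function(f) strip_na(unclass(f))),
        auto_unbox = TRUE, digits = NA)),
      population_description = s$population_description,
      setting_description = s$setting_description,
      conclusion_summary = s$conclusion_summary,
      roster_inferred = s$roster_inferred,
      stringsAsFactors = FALSE
    )
  })
  studies_df <- if (length(study_rows)) do.call(rbind, study_rows) else
    as.data.frame(stats::setNames(rep(list(character()),
                                      length(STUDY_CSV_COLS)),
                                  STUDY_CSV_COLS))
  utils::write.csv(studies_df, file.path(path, "studies.csv"),
                   row.names = FALSE)
  invisible(path)
}

read_registry_csv <- function(path) {
  if (!dir.exists(path)) {
    stop("CSV registry format expects a directory holding registry.csv, ",
         "tools.csv and studies.csv; got file '", path, "'", call. = FALSE)
  }
  need <- file.path(path, c("registry.csv", "tools.csv", "studies.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("CSV registry directory is missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  meta <- utils::read.csv(need[1L], stringsAsFactors = FALSE,
                          colClasses = "character")
  tools_df <- utils::read.csv(need[2L], stringsAsFactors = FALSE,
                              colClasses = "character")
  studies_df <- utils::read.csv(need[3L], stringsAsFactors = FALSE,
                                colClasses = "character")
  na_chr <- function(v) ifelse(is.na(v) | v == "", NA_character_, v)
  tools <- lapply(seq_len(nrow(tools_df)), function(i) {
    r <- lapply(tools_df[i, , drop = FALSE], na_chr)
    r$authors <- as.character(jsonlite::fromJSON(r$authors))
    r
  })
  studies <- lapply(seq_len(nrow(studies_df)), function(i) {
    r <- lapply(studies_df[i, , drop = FALSE], na_chr)
    fnd <- jsonlite::fromJSON(r$findings, simplifyVector = FALSE)
    list(
      study_id = r$study_id, tool_id = r$tool_id, citation = r$citation,
      year = r$year, is_primary = r$is_primary, aspect = r$aspect,
      design = r$design, direction = r$direction,
      match = list(population_match = r$population_match,
                   outcome_match = r$outcome_match,
                   setting_match = r$setting_match,
                   sample_size = r$sample_size,
                   match_notes = r$match_notes),
      outcome_category = r$outcome_category,
      findings = fnd,
      population_description = r$population_description,
      setting_description = r$setting_description,
      conclusion_summary = r$conclusion_summary,
      roster_inferred = r$roster_inferred
    )
  })
  list(schema_version = meta$schema_version[1L],
       proportion_scale = meta$proportion_scale[1L],
       tools = tools, studies = studies)
}
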