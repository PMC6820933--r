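## Rendering of the detailed per-tool appraisal report and the registry-wide
## summary table. Markdown output is deterministic (byte-identical for
## identical inputs): no timestamps, fixed section order, fixed column order.

LEVEL_LABELS <- c(
  A1 = "A1 — post-implementation impact, experimental evidence",
  A2 = "A2 — post-implementation impact, observational evidence",
  A3 = "A3 — post-implementation impact, subjective/descriptive evidence",
  B1 = "B1 — usability",
  B2 = "B2 — potential effect",
  C1 = "C1 — external validation, multiple publications",
  C2 = "C2 — external validation, single publication",
  C3 = "C3 — internal validation",
  C0 = "C0 — insufficient internal validation"
)

fmt_findings <- function(findings) {
  if (length(findings) == 0L) return("—")
  paste(vapply(findings, function(f) {
    s <- paste0(f$measure_name, " = ", format(f$value, trim = TRUE))
    if (!is.na(f$units)) s <- paste0(s, " ", f$units)
    if (!is.na(f$comparator_note)) s <- paste0(s, " [", f$comparator_note, "]")
    s
  }, character(1)), collapse = "; ")
}

fmt_match <- function(m) {
  if (is_fully_matching(m)) "full" else {
    miss <- c("population", "outcome", "setting")[!c(
      isTRUE(m$population_match), isTRUE(m$outcome_match),
      isTRUE(m$setting_match))]
    paste0("partial (", paste(miss, collapse = "/"), " differ)")
  }
}

md_escape <- function(x) gsub("|", "\\|", ifelse(is.na(x), "—", x), fixed = TRUE)

studies_md_table <- function(studies, with_oc = FALSE) {
  hdr <- c("Study", "Citation", "Year", "Design",
           if (with_oc) "Outcome category", "Population", "Setting", "N",
           "Match", "Direction", "Findings")
  rows <- vapply(studies, function(s) {
    cells <- c(s$study_id, s$citation, s$year, s$design,
               if (with_oc) s$outcome_category,
               s$population_description, s$setting_description,
               s$match$sample_size, fmt_match(s$match), s$direction,
               fmt_findings(s$findings))
    paste0("| ", paste(md_escape(as.character(cells)), collapse = " | "),
           " |")
  }, character(1))
  c(paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    rows)
}

direction_line <- function(res) {
  if (res$raw_direction == "mixed") {
    paste0("Direction of evidence: mixed, resolved **", res$resolved_direction,
           "** by the mixed-evidence protocol (see appendix).")
  } else {
    paste0("Direction of evidence: ", sub("all_", "all ", res$raw_direction),
           " -> **", res$resolved_direction, "**.")
  }
}

resolution_trace_md <- function(code, res) {
  c(paste0("### Resolution at ", code),
    unlist(lapply(seq_along(res$resolution_trace), function(i) {
      e <- res$resolution_trace[[i]]
      t <- e$tally
      sprintf("%d. %s — studies: %s; tally positive %d / negative %d / equivocal %d.",
              i, e$rule, paste(e$studies, collapse = ", "),
              t$positive, t$negative, t$equivocal)
    })),
    "")
}

phase_section_md <- function(title, codes, per_level, with_oc = FALSE) {
  out <- c(paste0("## ", title), "")
  any_evidence <- FALSE
  for (code in codes) {
    ev <- per_level[[code]]
    if (is.null(ev)) next
    any_evidence <- TRUE
    out <- c(out, paste0("### ", LEVEL_LABELS[[code]]), "",
             studies_md_table(ev$studies, with_oc = with_oc), "",
             direction_line(ev$resolution), "")
  }
  if (!any_evidence) out <- c(out, "No published evidence.", "")
  out
}

check_report_inputs <- function(studies, grade_result) {
  in_result <- sort(unname(unlist(lapply(grade_result$per_level_evidence,
    function(ev) vapply(ev$studies, `[[`, character(1), "study_id")))))
  in_corpus <- sort(vapply(studies, `[[`, character(1), "study_id"))
  if (!identical(in_result, in_corpus)) {
    stop("grade_result was not produced from exactly these studies",
         call. = FALSE)
  }
}

provenance_block <- function(config, source) {
  cfg <- paste0("enable_c0=", config$enable_c0,
                ", min_sample=", format(config$min_sample, trim = TRUE),
                ", tie_break_order=",
                paste(config$tie_break_order, collapse = ">"))
  list(
    engine = paste0("grasp ", as.character(utils::packageVersion("grasp"))),
    config = cfg,
    source = if (is.na(source)) "unspecified" else source,
    note = paste0("The mixed-evidence resolver is a calibrated ",
                  "reconstruction of the published protocol summary; ",
                  "resolution traces are reported verbatim for audit.")
  )
}

#' Render the detailed appraisal report for one tool
#'
#' Produces the full per-tool report: the tool-information section, the
#' evidence of each phase in translation order (phase C predictive
#' performance, phase B usability and potential effect, phase A
#' post-implementation impact) with per-level study tables and directions,
#' the final grade with its justification, verbatim mixed-evidence
#' resolution traces, and a provenance block echoing the engine version and
#' configuration. Output is deterministic: identical inputs give
#' byte-identical documents.
#'
#' @param tool A [grasp_tool()].
#' @param studies The tool's evidence records — exactly those the grade was
#'   computed from.
#' @param grade_result The [final_grade()] result for these studies.
#' @param format `"markdown"` or `"json"`.
#' @param source Optional identifier of the registry/fixture the corpus came
#'   from, echoed into provenance.
#' @return A character scalar holding the rendered document.
#' @export
#' @examples
#' reg <- build_fixture("lace")
#' tool <- registry_tool(reg, "lace")
#' studies <- studies_for_tool(reg, "lace")
#' cat(substr(render_detail(tool, studies, final_grade(tool, studies)), 1, 200))
render_detail <- function(tool, studies, grade_result,
                          format = c("markdown", "json"), source = NA) {
  format <- match.arg(format)
  stopifnot(inherits(tool, "grasp_tool"), inherits(grade_result, "grasp_grade"))
  check_report_inputs(studies, grade_result)
  per_level <- grade_result$per_level_evidence
  prov <- provenance_block(grade_result$config, as_scalar_chr(source))

  if (format == "json") {
    level_json <- function(code) {
      ev <- per_level[[code]]
      if (is.null(ev)) return(NULL)
      list(
        level = code,
        studies = lapply(ev$studies, study_to_list),
        raw_direction = ev$resolution$raw_direction,
        resolved_direction = ev$resolution$resolved_direction,
        resolution_trace = ev$resolution$resolution_trace
      )
    }
    doc <- list(
      tool_information = tool_to_list(tool),
      phase_C = Filter(Negate(is.null),
                       lapply(c("C1", "C2", "C3", "C0"), level_json)),
      phase_B = Filter(Negate(is.null), lapply(c("B1", "B2"), level_json)),
      phase_A = Filter(Negate(is.null),
                       lapply(c("A1", "A2", "A3"), level_json)),
      final_grade = list(code = grade_result$grade,
                         justification = grade_result$justification),
      provenance = prov
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                         pretty = TRUE, digits = NA,
                                         null = "null")))
  }

  info <- c(
    "## Tool Information", "",
    "| Field | Value |", "|---|---|",
    vapply(names(unclass(tool)), function(f) {
      v <- tool[[f]]
      v <- if (length(v) > 1L) paste(v, collapse = "; ") else v
      paste0("| ", gsub("_", " ", f), " | ", md_escape(as.character(v)), " |")
    }, character(1)), ""
  )

  mixed_codes <- names(per_level)[vapply(per_level, function(ev)
    ev$resolution$raw_direction == "mixed", logical(1))]
  appendix <- if (length(mixed_codes)) {
    c("## Appendix: Mixed-Evidence Resolutions", "",
      unlist(lapply(mixed_codes, function(code)
        resolution_trace_md(code, per_level[[code]]$resolution))))
  } else character()

  lines <- c(
    paste0("# GRASP Detailed Report: ", tool$name), "",
    info,
    phase_section_md(
      "Phase C — Predictive Performance (Before Implementation)",
      c("C3", "C2", "C1", "C0"), per_level),
    phase_section_md(
      "Phase B — Usability and Potential Effect (During Implementation)",
      c("B1", "B2"), per_level, with_oc = TRUE),
    phase_section_md(
      "Phase A — Post-Implementation Impact (After Implementation)",
      c("A1", "A2", "A3"), per_level, with_oc = TRUE),
    "## Final Grade", "",
    paste0("**", grade_result$grade, "**"), "",
    paste0("- ", grade_result$justification), "",
    appendix,
    "## Provenance", "",
    paste0("- engine: ", prov$engine),
    paste0("- config: ", prov$config),
    paste0("- source: ", prov$source),
    paste0("- note: ", prov$note),
    ""
  )
  paste(lines, collapse = "\n")
}

#' Registry-wide grading summary
#'
#' `summary_table()` builds the summary as a data frame — one row per tool
#' with its name, year, intended use, the highest phase and level reached
#' with positive (or positively resolved) evidence, a direction note and the
#' final grade. `render_summary()` renders it as GitHub-flavoured markdown,
#' JSON, or CSV.
#'
#' @param grade_results List of [final_grade()] results, one per tool.
#' @param tools The matching tool profiles: a list of [grasp_tool()] or a
#'   [grasp_registry()].
#' @param format `"markdown"`, `"json"` or `"csv"`.
#' @return `summary_table()` a data frame; `render_summary()` a character
#'   scalar.
#' @export
#' @examples
#' reg <- grasp_example_registry()
#' summary_table(grade_registry(reg), reg)
summary_table <- function(grade_results, tools) {
  if (inherits(tools, "grasp_registry")) tools <- tools$tools
  tool_ids <- vapply(tools, `[[`, character(1), "tool_id")
  rows <- lapply(grade_results, function(gr) {
    i <- match(gr$tool_id, tool_ids)
    if (is.na(i)) stop("no tool profile for graded tool '", gr$tool_id, "'",
                       call. = FALSE)
    t <- tools[[i]]
    code <- gr$grade
    ev <- gr$per_level_evidence[[code]]
    note <- if (identical(code, UNGRADED)) {
      "no gradeable evidence"
    } else if (identical(code, "C0")) {
      "internal validation negative or insufficient"
    } else if (ev$resolution$raw_direction == "mixed") {
      "mixed evidence resolved positive"
    } else {
      "all evidence positive"
    }
    data.frame(
      tool = t$name,
      year = t$year_published,
      intended_use = t$intended_use,
      phase = ifelse(is.na(grade_phase(code)), NA_character_,
                     grade_phase(code)),
      level = grade_level(code),
      direction_note = note,
      grade = code,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(tool = character(), year = integer(),
                      intended_use = character(), phase = character(),
                      level = integer(), direction_note = character(),
                      grade = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @rdname summary_table
#' @export
render_summary <- function(grade_results, tools,
                           format = c("markdown", "json", "csv")) {
  format <- match.arg(format)
  df <- summary_table(grade_results, tools)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(df, dataframe = "rows",
                                         pretty = TRUE, digits = NA,
                                         na = "null")))
  }
  if (format == "csv") {
    con <- textConnection("csv_out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
    return(paste0(paste(csv_out, collapse = "\n"), "\n"))
  }
  hdr <- c("Tool", "Year", "Intended use", "Phase", "Level",
           "Direction of evidence", "Grade")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(md_escape(as.character(unlist(df[i, ]))),
                       collapse = " | "), " |")
  }, character(1))
  paste(c("# Summary of Graded Predictive Tools", "",
          paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          body, ""), collapse = "\n")
}
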