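#' Resolution configuration
#'
#' Settings of the grading engine and the mixed-evidence resolver.
#'
#' @param enable_c0 Emit the `C0` grade for tools whose only evidence is an
#'   internal validation with a negative or insufficient conclusion (a
#'   peer-review extension of the grade ladder). When `FALSE` such tools
#'   grade as `UNGRADED`.
#' @param min_sample Studies with a recorded sample size below this threshold
#'   are demoted by one quality tier inside the mixed-evidence resolver
#'   (default 1000 patients; captures conclusions drawn on very small
#'   samples).
#' @param tie_break_order Order of tie-breaks applied after the highest-tier
#'   strict-majority tally: `"tier_widen"` (re-tally cumulatively over
#'   successive tiers), then `"recency"` (direction of the more recent
#'   studies, by median year), then `"negative"` (conservative default).
#' @param proportion_scale Default proportion scale assumed for registries
#'   that do not declare one.
#' @return An object of class `grasp_config`.
#' @export
#' @examples
#' grasp_config(min_sample = 500)
grasp_config <- function(enable_c0 = TRUE, min_sample = 1000,
                         tie_break_order = c("tier_widen", "recency",
                                             "negative"),
                         proportion_scale = "unit_interval") {
  structure(list(
    enable_c0 = isTRUE(enable_c0),
    min_sample = as.numeric(min_sample)[1L],
    tie_break_order = as.character(tie_break_order),
    proportion_scale = canon_enum(proportion_scale, PROPORTION_SCALES,
                                  "proportion_scale")
  ), class = "grasp_config")
}

#' Read a resolution configuration file
#'
#' @param path JSON or YAML file with any subset of the [grasp_config()]
#'   fields; unspecified fields keep their defaults.
#' @return A `grasp_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- switch(tolower(tools::file_ext(path)),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("config files must be .json or .yaml", call. = FALSE)
  )
  unknown <- setdiff(names(raw), names(formals(grasp_config)))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(grasp_config, raw)
}

#' @export
print.grasp_config <- function(x, ...) {
  cat("<grasp_config> enable_c0=", x$enable_c0,
      ", min_sample=", x$min_sample,
      ", tie_breaks=", paste(x$tie_break_order, collapse = ">"), "\n",
      sep = "")
  invisible(x)
}

#' Assign evidence levels to a tool's studies
#'
#' Partitions one tool's evidence records into grade-code buckets by the
#' aspect each record evaluated:
#' * internal validation -> `C3`;
#' * external validation -> `C1` when the tool has been externally validated
#'   in two or more distinct publications, else `C2` (all external-validation
#'   records land on the same one of the two levels, since the level encodes
#'   the volume of external validation, not a per-study property);
#' * potential effect -> `B2`; usability -> `B1`;
#' * post-implementation impact, partitioned by design quality tier:
#'   experimental (tier 1) -> `A1`, observational (tier 2) -> `A2`,
#'   subjective/descriptive (tier 3) -> `A3`.
#'
#' Every input study appears in exactly one bucket.
#'
#' @param studies List of [grasp_study()] records sharing one `tool_id`.
#' @return Named list mapping grade codes to lists of studies; only codes
#'   with evidence are present.
#' @export
#' @examples
#' reg <- build_fixture("ottawa")
#' names(assign_levels(studies_for_tool(reg, "ottawa")))
assign_levels <- function(studies) {
  if (length(studies) == 0L) return(stats::setNames(list(), character()))
  tid <- unique(vapply(studies, `[[`, character(1), "tool_id"))
  if (length(tid) != 1L) {
    stop("assign_levels() expects studies of a single tool; got: ",
         paste(tid, collapse = ", "), call. = FALSE)
  }
  buckets <- list()
  add <- function(code, s) buckets[[code]] <<- c(buckets[[code]], list(s))

  ext <- Filter(function(s) s$aspect == "external_validation", studies)
  n_ext_pubs <- length(unique(vapply(ext, function(s) {
    if (is.na(s$citation)) s$study_id else s$citation
  }, character(1))))
  ext_code <- if (n_ext_pubs >= 2L) "C1" else "C2"

  for (s in studies) {
    code <- switch(s$aspect,
      internal_validation = "C3",
      external_validation = ext_code,
      potential_effect    = "B2",
      usability           = "B1",
      post_implementation_impact = paste0("A", design_tier(s$design)),
      stop("cannot classify record '", s$study_id, "': unknown aspect '",
           s$aspect, "'", call. = FALSE)
    )
    add(code, s)
  }
  buckets[order(match(names(buckets), GRADE_SCAN_ORDER))]
}

#' Raw direction of evidence at one level
#'
#' Aggregates the reported conclusions of the studies in one level bucket:
#' `all_positive` when every study concluded positively; `all_negative` when
#' every study concluded negatively or equivocally (equivocal conclusions
#' aggregate with negative, never with positive); `mixed` otherwise.
#'
#' @param studies Non-empty list of [grasp_study()] records at one level.
#' @return `"all_positive"`, `"all_negative"` or `"mixed"`.
#' @export
#' @examples
#' reg <- build_fixture("wells")
#' determine_direction(assign_levels(studies_for_tool(reg, "wells"))$C1)
determine_direction <- function(studies) {
  if (length(studies) == 0L) {
    stop("determine_direction() requires a non-empty study list", call. = FALSE)
  }
  dirs <- vapply(studies, `[[`, character(1), "direction")
  if (all(dirs == "positive")) return("all_positive")
  if (all(dirs %in% c("negative", "equivocal"))) return("all_negative")
  "mixed"
}

# Effective quality tier inside the resolver: the design tier, demoted one
# step when the study's recorded sample size falls below the configured
# threshold. Demotion below tier 3 is allowed (an internal rank only), so a
# small-sample tier-3 study ranks under an adequately powered tier-3 study.
effective_tier <- function(study, config) {
  tier <- design_tier(study$design)
  n <- study$match$sample_size
  if (!is.na(n) && n < config$min_sample) tier <- tier + 1L
  tier
}

tally_of <- function(studies) {
  dirs <- vapply(studies, `[[`, character(1), "direction")
  c(positive = sum(dirs == "positive"),
    negative = sum(dirs == "negative"),
    equivocal = sum(dirs == "equivocal"))
}

trace_entry <- function(rule, studies, tally) {
  list(rule = rule,
       studies = vapply(studies, `[[`, character(1), "study_id"),
       tally = as.list(tally))
}

#' Resolve mixed evidence at one level
#'
#' Implements the deterministic mixed-evidence protocol applied when the
#' studies at one phase/level disagree. Discordant studies are ranked by
#' quality and by their degree of matching with the tool's original target
#' specification (population, outcome, setting):
#'
#' 1. any study whose recorded sample size is below `config$min_sample` is
#'    demoted by one quality tier (conclusions drawn on very small samples
#'    carry less weight);
#' 2. when at least one fully matching study exists, the tally is restricted
#'    to fully matching studies (conclusions from different subpopulations,
#'    outcomes or settings do not overrule on-specification evidence);
#' 3. within the restricted set, the highest quality tier present is tallied:
#'    the resolved direction is the strict majority of positive versus
#'    negative-plus-equivocal conclusions;
#' 4. on a tie, the tally widens cumulatively to the next tier and repeats;
#' 5. if still tied after all tiers, the direction of the more recent studies
#'    (larger median publication year) prevails;
#' 6. any remaining tie resolves negative (the conservative default).
#'
#' @param studies Studies at one level with raw direction `mixed`.
#' @param tool_spec The tool's [grasp_tool()] profile (carried into the
#'   trace; matching itself is recorded per study in its match profile).
#' @param config A [grasp_config()].
#' @return A list of class `grasp_resolution` with `raw_direction`
#'   (`"mixed"`), `resolved_direction` (`"positive"`/`"negative"`) and a
#'   non-empty `resolution_trace` of (rule, studies, tally) entries.
#' @export
resolve_mixed <- function(studies, tool_spec = NULL, config = grasp_config()) {
  if (determine_direction(studies) != "mixed") {
    stop("resolve_mixed() called on non-mixed evidence; ",
         "use determine_direction() first", call. = FALSE)
  }
  trace <- list()
  note <- function(rule, studies, tally) {
    trace[[length(trace) + 1L]] <<- trace_entry(rule, studies, tally)
  }

  tiers <- vapply(studies, effective_tier, integer(1), config = config)
  demoted <- vapply(studies, function(s) {
    n <- s$match$sample_size
    !is.na(n) && n < config$min_sample
  }, logical(1))
  if (any(demoted)) {
    note(paste0("small-sample demotion (n < ", config$min_sample,
                "): demoted one tier"),
         studies[demoted], tally_of(studies[demoted]))
  }

  matching <- vapply(studies, is_fully_matching, logical(1))
  if (any(matching) && !all(matching)) {
    note("restricted to studies fully matching the tool specification",
         studies[matching], tally_of(studies[matching]))
  }
  pool_idx <- if (any(matching)) which(matching) else seq_along(studies)
  if (!any(matching)) {
    note("no fully matching studies: all studies retained", studies,
         tally_of(studies))
  }
  pool <- studies[pool_idx]
  pool_tiers <- tiers[pool_idx]

  decide <- function(set) {
    t <- tally_of(set)
    pos <- t[["positive"]]; neg <- t[["negative"]] + t[["equivocal"]]
    if (pos > neg) "positive" else if (neg > pos) "negative" else NA_character_
  }

  resolved <- NA_character_
  for (tier_cut in sort(unique(pool_tiers))) {
    set <- pool[pool_tiers <= tier_cut]
    resolved <- decide(set)
    note(sprintf("tally at quality tiers <= %d (strict majority)", tier_cut),
         set, tally_of(set))
    if (!is.na(resolved)) break
  }

  if (is.na(resolved) && "recency" %in% config$tie_break_order) {
    years <- vapply(pool, function(s) as.numeric(s$year), numeric(1))
    dirs <- vapply(pool, `[[`, character(1), "direction")
    pos_med <- stats::median(years[dirs == "positive"], na.rm = TRUE)
    neg_med <- stats::median(years[dirs != "positive"], na.rm = TRUE)
    if (is.finite(pos_med) && is.finite(neg_med) && pos_med != neg_med) {
      resolved <- if (pos_med > neg_med) "positive" else "negative"
      note(sprintf(
        "recency tie-break: median year positive %.1f vs negative %.1f",
        pos_med, neg_med), pool, tally_of(pool))
    }
  }

  if (is.na(resolved)) {
    resolved <- "negative"
    note("unresolved tie: conservative negative default", pool,
         tally_of(pool))
  }

  structure(list(
    raw_direction = "mixed",
    resolved_direction = resolved,
    resolution_trace = trace
  ), class = "grasp_resolution")
}

# Direction at one level: trivial for concordant evidence, protocol for mixed.
resolve_direction <- function(studies, tool_spec, config) {
  raw <- determine_direction(studies)
  if (raw == "all_positive") {
    structure(list(raw_direction = "all_positive",
                   resolved_direction = "positive",
                   resolution_trace = list()), class = "grasp_resolution")
  } else if (raw == "all_negative") {
    structure(list(raw_direction = "all_negative",
                   resolved_direction = "negative",
                   resolution_trace = list()), class = "grasp_resolution")
  } else {
    resolve_mixed(studies, tool_spec, config)
  }
}

#' @export
print.grasp_resolution <- function(x, ...) {
  cat("<grasp_resolution> ", x$raw_direction, " -> ", x$resolved_direction,
      " (", length(x$resolution_trace), " trace entries)\n", sep = "")
  invisible(x)
}

#' Final grade of one tool
#'
#' Walks the grade ladder from the highest phase and level downwards
#' (`A1, A2, A3, B1, B2, C1, C2, C3`); the final grade is the first level
#' holding evidence whose direction — after mixed-evidence resolution —
#' is positive. Levels above the grade therefore either hold no evidence or
#' hold evidence that resolved negative, and the full per-level trace is
#' retained in the result. A tool whose evidence never resolves positive but
#' that has an internal-validation record (necessarily with a negative or
#' equivocal conclusion) receives `C0` when `config$enable_c0`, marking an
#' insufficiently internally validated tool; otherwise, and for tools with
#' no studies at all, the result is `UNGRADED` with an explanatory trace.
#'
#' @param tool A [grasp_tool()] profile.
#' @param studies The tool's evidence records.
#' @param config A [grasp_config()].
#' @return An object of class `grasp_grade`: `tool_id`, `grade` (the code),
#'   `per_level_evidence` (per grade code: studies + direction resolution)
#'   and a `justification` character vector tracing the decision.
#' @export
#' @examples
#' reg <- build_fixture("ottawa")
#' final_grade(registry_tool(reg, "ottawa"), studies_for_tool(reg, "ottawa"))
final_grade <- function(tool, studies, config = grasp_config()) {
  stopifnot(inherits(tool, "grasp_tool"))
  just <- character()
  say <- function(...) just <<- c(just, paste0(...))

  if (length(studies) == 0L) {
    say("No evidence studies recorded for tool '", tool$tool_id,
        "': UNGRADED.")
    return(structure(list(tool_id = tool$tool_id, grade = UNGRADED,
                          per_level_evidence = list(),
                          justification = just, config = config),
                     class = "grasp_grade"))
  }

  buckets <- assign_levels(studies)
  say("Evidence present at level(s): ",
      paste(names(buckets), collapse = ", "), ".")

  per_level <- list()
  grade <- NULL
  for (code in GRADE_SCAN_ORDER) {
    if (code == "C0") next  # sentinel, handled after the scan
    bucket <- buckets[[code]]
    if (is.null(bucket)) next
    res <- resolve_direction(bucket, tool, config)
    per_level[[code]] <- list(studies = bucket, resolution = res)
    if (res$raw_direction == "mixed") {
      say(code, ": ", length(bucket), " studies, mixed evidence resolved ",
          res$resolved_direction, " by the mixed-evidence protocol.")
    } else {
      say(code, ": ", length(bucket), " studies, ",
          sub("all_", "all ", res$raw_direction), " -> ",
          res$resolved_direction, ".")
    }
    if (is.null(grade) && res$resolved_direction == "positive") {
      grade <- code
      say("Final grade ", code,
          ": highest phase and level supported by positive evidence",
          if (res$raw_direction == "mixed")
            " (mixed evidence resolving positive)" else "", ".")
      # levels below the grade are still traced for the detailed report
    }
  }

  if (is.null(grade)) {
    has_internal <- any(vapply(studies, function(s)
      s$aspect == "internal_validation", logical(1)))
    if (has_internal && config$enable_c0) {
      grade <- "C0"
      say("No level resolved positive; internal validation was reported but ",
          "was negative or insufficient: grade C0.")
    } else {
      grade <- UNGRADED
      say("No level resolved positive",
          if (has_internal) " and C0 is disabled" else
            " and no internal validation is recorded", ": UNGRADED.")
    }
  }

  structure(list(tool_id = tool$tool_id, grade = grade,
                 per_level_evidence = per_level,
                 justification = just, config = config),
            class = "grasp_grade")
}

#' @export
print.grasp_grade <- function(x, ...) {
  cat("<grasp_grade> ", x$tool_id, ": ", x$grade, "\n", sep = "")
  for (line in x$justification) cat("  ", line, "\n", sep = "")
  invisible(x)
}

#' Grade every tool in a registry
#'
#' Batch wrapper over [final_grade()]: grades tools independently, in
#' registry order. A tool whose corpus fails to grade (malformed records)
#' yields an `UNGRADED` result carrying the error in its justification; the
#' batch never aborts.
#'
#' @param registry A [grasp_registry()].
#' @param config A [grasp_config()].
#' @return List of [final_grade()] results, one per tool, in registry order.
#' @export
#' @examples
#' grades <- grade_registry(grasp_example_registry())
#' vapply(grades, `[[`, character(1), "grade")
grade_registry <- function(registry, config = grasp_config()) {
  stopifnot(inherits(registry, "grasp_registry"))
  lapply(registry$tools, function(tool) {
    tryCatch(
      final_grade(tool, studies_for_tool(registry, tool$tool_id), config),
      error = function(e) {
        structure(list(
          tool_id = tool$tool_id, grade = UNGRADED,
          per_level_evidence = list(),
          justification = paste0("grading failed: ", conditionMessage(e)),
          config = config), class = "grasp_grade")
      }
    )
  })
}
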