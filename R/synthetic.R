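## Seeded synthetic corpora with planted ground-truth grades. The generator
## works "grade-first": the planted grade is fixed, then evidence is
## constructed backwards so that the grading rules imply exactly that grade —
## positive evidence up to the planted level, plus optional distractor studies
## (non-matching negatives, small-sample negatives, equivocals) placed where
## the documented resolver provably discounts them. Recovery of the planted
## grade is therefore a genuine test of the engine, not of the generator.

run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic corpus
#'
#' @param seed Integer seed; identical specs generate byte-identical
#'   registries.
#' @param n_tools Number of tools to generate.
#' @param planted_grades Character vector of grade codes (recycled over
#'   tools): any of `A1, A2, A3, B1, B2, C1, C2, C3, C0`, or `UNGRADED`
#'   for a tool with no evidence (distractor counts must then be zero).
#' @param n_nonmatching,n_small_sample,n_equivocal Per-tool counts of
#'   distractor studies to inject: negative studies not matching the tool
#'   specification, negative matching studies with sample size below the
#'   resolver's demotion threshold, and equivocal matching studies.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' synthetic_spec(7, n_tools = 2, planted_grades = c("A2", "C1"))
synthetic_spec <- function(seed, n_tools = 1,
                           planted_grades = "C3",
                           n_nonmatching = 0, n_small_sample = 0,
                           n_equivocal = 0) {
  planted <- toupper(as.character(planted_grades))
  bad <- setdiff(planted, c(GRADE_SCAN_ORDER, UNGRADED))
  if (length(bad)) {
    stop("unknown planted grade(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_tools <- as.integer(n_tools)
  stopifnot(n_tools >= 1L)
  spec <- structure(list(
    seed = as.integer(seed),
    n_tools = n_tools,
    planted_grades = rep_len(planted, n_tools),
    n_nonmatching = rep_len(as.integer(n_nonmatching), n_tools),
    n_small_sample = rep_len(as.integer(n_small_sample), n_tools),
    n_equivocal = rep_len(as.integer(n_equivocal), n_tools)
  ), class = "synthetic_spec")
  noisy <- spec$n_nonmatching + spec$n_small_sample + spec$n_equivocal
  if (any(spec$planted_grades == UNGRADED & noisy > 0L)) {
    stop("planted grade UNGRADED requires zero distractor studies ",
         "(an ungraded tool has no evidence)", call. = FALSE)
  }
  spec
}

# aspect/design/outcome-category templates per planted grade level
level_template <- function(code) {
  switch(code,
    A1 = list(aspect = "post_implementation_impact",
              design = "randomised_controlled_trial", oc = TRUE),
    A2 = list(aspect = "post_implementation_impact",
              design = "before_after_observational", oc = TRUE),
    A3 = list(aspect = "post_implementation_impact",
              design = "descriptive_report", oc = TRUE),
    B1 = list(aspect = "usability", design = "usability_survey", oc = FALSE),
    B2 = list(aspect = "potential_effect", design = "cross_sectional",
              oc = TRUE),
    C1 = ,
    C2 = list(aspect = "external_validation", design = "cohort", oc = FALSE),
    C3 = ,
    C0 = list(aspect = "internal_validation", design = "cohort", oc = FALSE)
  )
}

#' Generate a synthetic registry with planted grades
#'
#' For each tool the corpus is constructed so that [final_grade()] with the
#' default configuration yields exactly the planted grade:
#' * a primary internal-validation record (positive, or negative for a
#'   planted `C0`);
#' * positive supporting evidence at the planted level — one external
#'   validation for `C2`, at least two for `C1`, two external validations
#'   plus the phase-B or phase-A record(s) for higher grades — with one more
#'   positive record at the planted level than injected equivocals, so the
#'   strict-majority tally always clears;
#' * distractors injected at the planted level (or, where an extra record at
#'   the planted level would change the level itself — planted `C2`, `C0` —
#'   at the internal-validation level): non-matching negatives are discarded
#'   by the matching restriction, small-sample negatives are demoted below
#'   the adequately powered positives, equivocals are outvoted.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `registry` (a valid [grasp_registry()]) and `planted`
#'   (named character vector of planted grades by `tool_id`).
#' @export
#' @examples
#' out <- generate_synthetic(synthetic_spec(7, 3, c("A2", "C1", "B1")))
#' vapply(grade_registry(out$registry), `[[`, character(1), "grade")
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  run_seeded(spec$seed, {
    tools <- list()
    studies <- list()
    planted <- character()

    for (i in seq_len(spec$n_tools)) {
      tid <- sprintf("syn%03d", i)
      g <- spec$planted_grades[i]
      planted[tid] <- g
      y0 <- sample(1985:2005, 1L)
      tools[[i]] <- grasp_tool(
        tid, sprintf("Synthetic Predictive Tool %03d", i),
        authors = sprintf("Author %03d", i),
        year_published = y0,
        intended_use = sample(c("diagnostic", "prognostic"), 1L),
        target_population = sprintf("synthetic target population %03d", i),
        target_outcome = sprintf("synthetic target outcome %03d", i),
        clinical_setting = sample(c("emergency department", "hospital ward",
                                    "primary care"), 1L),
        input_data_source = sample(c("clinical", "administrative",
                                     "laboratory"), 1L),
        input_data_type = "synthetic predictors",
        intended_user = "clinicians",
        recommended_action = "synthetic recommended action"
      )
      if (g == UNGRADED) next

      k <- 0L
      next_id <- function() {
        k <<- k + 1L
        sprintf("%s_s%02d", tid, k)
      }
      big_n <- function() sample(1000:50000, 1L)
      small_n <- function() sample(30:999, 1L)
      yr <- function() sample(y0:2018, 1L)
      oc <- function() sample(OUTCOME_CATEGORIES, 1L)

      mk <- function(aspect, design, direction, matching = TRUE,
                     n = big_n(), with_oc = FALSE, primary = FALSE) {
        grasp_study(next_id(), tid,
          citation = sprintf("syn-%s-%02d", tid, k), year = yr(),
          is_primary = primary, aspect = aspect, design = design,
          direction = direction,
          match = grasp_match(matching, TRUE, TRUE, sample_size = n,
            match_notes = if (matching) NA else "different subpopulation"),
          outcome_category = if (with_oc) oc() else NA,
          population_description = "synthetic population",
          setting_description = "synthetic setting",
          conclusion_summary = paste0("synthetic ", direction, " conclusion"))
      }

      # primary development study (negative internal validation for C0)
      studies <- c(studies, list(
        mk("internal_validation", "cohort",
           if (g == "C0") "negative" else "positive", primary = TRUE)))

      # positive supporting evidence up to the planted level
      tpl <- level_template(g)
      n_equiv <- spec$n_equivocal[i]
      if (g %in% c("A1", "A2", "A3", "B1", "B2")) {
        studies <- c(studies, list(
          mk("external_validation", "cohort", "positive"),
          mk("external_validation", "cohort", "positive")))
      }
      n_pos_at_level <- switch(g,
        C0 = 0L, C2 = 1L, C3 = n_equiv, C1 = max(2L, n_equiv + 1L),
        n_equiv + 1L)
      # (for C3 the positive primary already sits in the bucket)
      for (j in seq_len(n_pos_at_level)) {
        studies <- c(studies, list(
          mk(tpl$aspect, tpl$design, "positive", with_oc = tpl$oc)))
      }

      # distractors: at the planted level, except where an extra record at
      # that level would change the level itself (C2: external-validation
      # count; C0: nothing positive exists) -> internal-validation bucket
      dl <- if (g %in% c("C2", "C0")) level_template("C3") else tpl
      for (j in seq_len(spec$n_nonmatching[i])) {
        studies <- c(studies, list(
          mk(dl$aspect, dl$design, "negative", matching = FALSE,
             with_oc = dl$oc)))
      }
      for (j in seq_len(spec$n_small_sample[i])) {
        studies <- c(studies, list(
          mk(dl$aspect, dl$design, "negative", n = small_n(),
             with_oc = dl$oc)))
      }
      for (j in seq_len(n_equiv)) {
        dle <- if (g == "C2") level_template("C3") else dl
        studies <- c(studies, list(
          mk(dle$aspect, dle$design, "equivocal", with_oc = dle$oc)))
      }
    }

    list(registry = grasp_registry(tools, studies),
         planted = planted)
  })
}
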