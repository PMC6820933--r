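# Shared constructors for small hand-built corpora.

mk_tool <- function(tool_id = "t1", year = 2005) {
  grasp_tool(tool_id, paste("Tool", tool_id), authors = "A Author",
    year_published = year, intended_use = "diagnostic",
    target_population = "adults", target_outcome = "event",
    clinical_setting = "emergency department",
    input_data_source = "clinical", input_data_type = "vitals",
    intended_user = "clinicians", recommended_action = "act")
}

mk_study <- function(study_id, aspect, direction,
                     design = "cohort", tool_id = "t1",
                     matching = TRUE, n = 5000, year = 2010,
                     is_primary = FALSE, outcome_category = NA,
                     citation = study_id) {
  if (is.na(outcome_category) &&
      aspect %in% c("potential_effect", "post_implementation_impact")) {
    outcome_category <- "patient_safety"
  }
  grasp_study(study_id, tool_id, citation = citation, year = year,
    is_primary = is_primary, aspect = aspect, design = design,
    direction = direction,
    match = grasp_match(matching, TRUE, TRUE, sample_size = n),
    outcome_category = outcome_category,
    population_description = "pop", setting_description = "set",
    conclusion_summary = paste(direction, "conclusion"))
}

# registry with one tool and the given studies
mk_registry <- function(studies, tool = mk_tool()) {
  grasp_registry(list(tool), studies)
}

# aspect/design templates per grade level, mirroring the level rules
level_study_template <- function(code) {
  switch(code,
    A1 = c("post_implementation_impact", "randomised_controlled_trial"),
    A2 = c("post_implementation_impact", "before_after_observational"),
    A3 = c("post_implementation_impact", "descriptive_report"),
    B1 = c("usability", "usability_survey"),
    B2 = c("potential_effect", "cross_sectional"),
    C1 = c("external_validation", "cohort"),
    C2 = c("external_validation", "cohort"),
    C3 = c("internal_validation", "cohort"))
}

grade_rank <- function(code) {
  r <- match(code, grade_scan_order())
  ifelse(is.na(r), length(grade_scan_order()) + 1L, r)
}
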