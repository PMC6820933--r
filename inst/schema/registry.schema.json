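{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/grasp/registry.schema.json",
  "title": "GRASP evidence registry",
  "description": "A registry of clinical predictive tools and the published evidence studies evaluating them, as consumed by the grasp R package.",
  "type": "object",
  "required": ["schema_version", "tools", "studies"],
  "properties": {
    "schema_version": { "type": "string" },
    "proportion_scale": { "enum": ["unit_interval", "percent"] },
    "tools": {
      "type": "array",
      "items": { "$ref": "#/$defs/tool" }
    },
    "studies": {
      "type": "array",
      "items": { "$ref": "#/$defs/study" }
    }
  },
  "$defs": {
    "tool": {
      "type": "object",
      "required": ["tool_id", "name", "year_published", "target_population",
                   "target_outcome", "clinical_setting"],
      "properties": {
        "tool_id": { "type": "string", "minLength": 1 },
        "name": { "type": "string", "minLength": 1 },
        "authors": { "type": "array", "items": { "type": "string" } },
        "year_published": { "type": "integer", "minimum": 1900, "maximum": 2100 },
        "intended_use": { "type": "string" },
        "target_population": { "type": "string", "minLength": 1 },
        "target_outcome": { "type": "string", "minLength": 1 },
        "clinical_setting": { "type": "string", "minLength": 1 },
        "input_data_source": { "type": "string" },
        "input_data_type": { "type": "string" },
        "intended_user": { "type": "string" },
        "recommended_action": { "type": "string" },
        "local_context_notes": { "type": "string" }
      }
    },
    "match": {
      "type": "object",
      "properties": {
        "population_match": { "type": "boolean" },
        "outcome_match": { "type": "boolean" },
        "setting_match": { "type": "boolean" },
        "sample_size": { "type": "integer", "minimum": 0 },
        "match_notes": { "type": "string" }
      }
    },
    "finding": {
      "type": "object",
      "required": ["measure_name", "value"],
      "properties": {
        "measure_name": { "type": "string" },
        "value": { "type": "number" },
        "units": { "type": "string" },
        "comparator_note": { "type": "string" }
      }
    },
    "study": {
      "type": "object",
      "required": ["study_id", "tool_id", "aspect", "design", "direction"],
      "properties": {
        "study_id": { "type": "string", "minLength": 1 },
        "tool_id": { "type": "string", "minLength": 1 },
        "citation": { "type": "string" },
        "year": { "type": "integer", "minimum": 1900, "maximum": 2100 },
        "is_primary": { "type": "boolean" },
        "aspect": {
          "enum": ["internal_validation", "external_validation",
                   "potential_effect", "usability",
                   "post_implementation_impact"]
        },
        "design": {
          "enum": ["systematic_review_of_trials", "randomised_controlled_trial",
                   "nonrandomised_controlled_trial", "cohort", "case_control",
                   "before_after_observational", "cross_sectional",
                   "think_aloud", "near_live_simulation", "usability_survey",
                   "expert_opinion", "descriptive_report", "survey"]
        },
        "direction": { "enum": ["positive", "negative", "equivocal"] },
        "match": { "$ref": "#/$defs/match" },
        "outcome_category": {
          "enum": ["clinical_effectiveness", "healthcare_efficiency",
                   "patient_safety"]
        },
        "findings": {
          "type": "array",
          "items": { "$ref": "#/$defs/finding" }
        },
        "population_description": { "type": "string" },
        "setting_description": { "type": "string" },
        "conclusion_summary": { "type": "string" },
        "roster_inferred": { "type": "boolean" }
      },
      "allOf": [
        {
          "if": {
            "properties": {
              "aspect": {
                "enum": ["potential_effect", "post_implementation_impact"]
              }
            }
          },
          "then": { "required": ["outcome_category"] }
        },
        {
          "if": { "properties": { "is_primary": { "const": true } } },
          "then": { "properties": { "aspect": { "const": "internal_validation" } } }
        }
      ]
    }
  }
}
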