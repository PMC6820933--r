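{
  "schema_version": "1.0",
  "proportion_scale": "unit_interval",
  "tools": [
    {
      "tool_id": "lace",
      "name": "LACE Index",
      "authors": "van Walraven C",
      "year_published": 2010,
      "intended_use": "prognostic",
      "target_population": "adult medical and surgical inpatients discharged from hospital",
      "target_outcome": "unplanned readmission or death within 30 days of discharge",
      "clinical_setting": "acute care hospital discharge",
      "input_data_source": "administrative",
      "input_data_type": "length of stay, admission acuity, Charlson comorbidity index, ED visits in prior 6 months",
      "intended_user": "discharge planners and ward physicians",
      "recommended_action": "target transitional-care interventions to patients at high readmission risk"
    }
  ],
  "studies": [
    {
      "study_id": "lace_p1",
      "tool_id": "lace",
      "citation": "CR125",
      "year": 2010,
      "is_primary": true,
      "aspect": "internal_validation",
      "design": "cohort",
      "direction": "positive",
      "match": {
        "population_match": true,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 4812
      },
      "findings": [
        {
          "measure_name": "c_statistic",
          "value": 0.684,
          "units": "proportion"
        }
      ],
      "population_description": "adult medical and surgical inpatients, Ontario, Canada",
      "setting_description": "11 Ontario hospitals",
      "conclusion_summary": "derivation with internal validation; moderate discrimination"
    },
    {
      "study_id": "lace_e1",
      "tool_id": "lace",
      "citation": "CR129",
      "year": 2012,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "positive",
      "match": {
        "population_match": true,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 26045
      },
      "findings": [],
      "population_description": "adult inpatients, six hospitals in Toronto",
      "setting_description": "urban teaching and community hospitals, Canada",
      "conclusion_summary": "positive external validity; superior to previously endorsed readmission models"
    },
    {
      "study_id": "lace_e2",
      "tool_id": "lace",
      "citation": "CR130",
      "year": 2015,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "positive",
      "match": {
        "population_match": true,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 59652
      },
      "findings": [],
      "population_description": "adult inpatients, all hospitals in Alberta",
      "setting_description": "province-wide administrative data, Canada",
      "conclusion_summary": "positive external validity; superior to previously endorsed readmission models"
    },
    {
      "study_id": "lace_e3",
      "tool_id": "lace",
      "citation": "CR131",
      "year": 2013,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "negative",
      "match": {
        "population_match": false,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 507,
        "match_notes": "geriatric subpopulation, not the development population"
      },
      "findings": [],
      "population_description": "507 geriatric patients, United Kingdom",
      "setting_description": "geriatric medicine service",
      "conclusion_summary": "performed poorly in geriatric patients"
    },
    {
      "study_id": "lace_e4",
      "tool_id": "lace",
      "citation": "CR132",
      "year": 2016,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "negative",
      "match": {
        "population_match": false,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 253,
        "match_notes": "congestive heart failure subpopulation"
      },
      "findings": [],
      "population_description": "253 congestive heart failure patients, United States",
      "setting_description": "heart failure service",
      "conclusion_summary": "performed poorly in heart failure patients"
    },
    {
      "study_id": "lace_e5",
      "tool_id": "lace",
      "citation": "CR133",
      "year": 2015,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "positive",
      "match": {
        "population_match": true,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 1496
      },
      "findings": [
        {
          "measure_name": "c_statistic",
          "value": 0.68,
          "units": "proportion",
          "comparator_note": "performed well but not better than the study's own newly developed tool"
        }
      ],
      "population_description": "adult inpatients",
      "setting_description": "comparative external validation",
      "conclusion_summary": "externally valid; not superior to the comparator model developed in-study",
      "roster_inferred": true
    },
    {
      "study_id": "lace_e6",
      "tool_id": "lace",
      "citation": "CR134",
      "year": 2016,
      "is_primary": false,
      "aspect": "external_validation",
      "design": "cohort",
      "direction": "positive",
      "match": {
        "population_match": true,
        "outcome_match": true,
        "setting_match": true,
        "sample_size": 2019
      },
      "findings": [
        {
          "measure_name": "c_statistic",
          "value": 0.66,
          "units": "proportion",
          "comparator_note": "performed well but not better than the study's own newly developed tool"
        }
      ],
      "population_description": "adult inpatients",
      "setting_description": "comparative external validation",
      "conclusion_summary": "externally valid; not superior to the comparator model developed in-study",
      "roster_inferred": true
    }
  ]
}
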