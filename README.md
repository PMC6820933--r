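# grasp

Evidence-based grading and assessment of clinical predictive tools.

Clinicians choosing among prediction rules, risk scores and predictive
algorithms face an ever-growing catalogue in which most tools have only ever
been tested for predictive performance, few have been studied for usability,
and fewer still for their impact after real-world implementation. `grasp`
implements a standardised grading framework over structured registries of
published evaluation evidence, so that the state of the evidence behind each
tool can be summarised as a single auditable code and a detailed, fully
traceable appraisal report. Its intended users are healthcare researchers who
appraise predictive tools and the clinicians and guideline developers who
consume those appraisals.

## The grading model

Each tool is graded along three dimensions of its published evidence:

* **Phase of evaluation** — the highest stage of translation reached:
  *C* (predictive performance tested before implementation), *B* (usability
  or potential effect studied during implementation), *A* (post-implementation
  impact reported).
* **Level of evidence** within the phase: C3 internal validation, C2 external
  validation in a single publication, C1 external validation in multiple
  publications; B2 potential effect, B1 usability; A3 subjective/descriptive,
  A2 observational, A1 experimental evidence of post-implementation impact.
  A C0 grade (configurable) marks tools whose internal validation was
  negative or insufficiently reported.
* **Direction of evidence** at each level: positive when all studies conclude
  positively, negative when all conclude negatively or equivocally, and
  otherwise *mixed*, resolved by a deterministic protocol that ranks
  discordant studies by quality tier (experimental > observational >
  subjective), demotes studies with very small samples (< 1000 patients by
  default), restricts to studies fully matching the tool's original target
  population/outcome/setting when any exist, then takes the strict majority
  at the highest tier, widening across tiers, breaking residual ties by
  recency and finally conservatively toward negative.

The final grade is the highest phase and level supported by positive (or
positively resolved mixed) evidence. The grade is an audit code, not an
ordinal quality score: an A1 tool is not declared "better" than an A2 tool.

Impact and potential-effect evidence is categorised as clinical
effectiveness, healthcare efficiency or patient safety, and effect sizes are
carried through to the reports rather than pooled: the framework synthesises
qualitative conclusions, never a meta-analytic summary number.

## Worked example

Five evidence corpora ship with the package (LACE Index, Centor Score,
Wells' Criteria, Modified Early Warning Score, Ottawa Knee Rule — 7 primary
development records and 56 evaluation studies in total):

```r
library(grasp)

reg <- grasp_example_registry()
grades <- grade_registry(reg)
for (g in grades) cat(g$tool_id, "\t", g$grade, "\n")
#> lace     C1
#> centor   B1
#> wells    A2
#> mews     A2
#> ottawa   A1
```

The LACE Index reaches C1: validated externally in multiple publications,
with the two negative small-subpopulation studies (geriatric n = 507, heart
failure n = 253) discounted by the mixed-evidence protocol, and no phase-B or
phase-A evidence at all. The Centor Score's five post-implementation trials
resolve negative (one positive RCT against three negative RCTs), so its
positive usability study sets the grade at B1. The Ottawa Knee Rule's two
nonrandomised controlled trials of impact on efficiency are unanimously
positive, giving the top grade A1.

Every step is auditable:

```r
g <- final_grade(registry_tool(reg, "centor"), studies_for_tool(reg, "centor"))
print(g)
#> <grasp_grade> centor: B1
#>   Evidence present at level(s): A1, A2, B1, C1, C3.
#>   A1: 4 studies, mixed evidence resolved negative by the mixed-evidence protocol.
#>   A2: 1 studies, all negative -> negative.
#>   B1: 1 studies, all positive -> positive.
#>   Final grade B1: highest phase and level supported by positive evidence.
#>   C1: 8 studies, all positive -> positive.
#>   C3: 1 studies, all positive -> positive.
```

`render_detail()` turns a grade into the full markdown or JSON appraisal
report (tool information, per-level study tables, resolution traces,
provenance); `render_summary()` produces the registry-wide summary table.
Registries read and write as JSON (canonical; schema in
`inst/schema/registry.schema.json`), YAML, or flat CSV, and
`generate_synthetic()` builds seeded corpora with planted ground-truth grades
for property testing. A command-line front-end (`inst/exec/grasp`, or
`grasp_cli()` directly) exposes `validate`, `grade`, `report`, `summary`,
`simulate` and `fixtures` subcommands.

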