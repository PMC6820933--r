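---
title: "Grading predictive tools from published evidence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading predictive tools from published evidence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasp)
```

## The problem and the model

A clinical predictive tool — a prediction rule, risk score, or predictive
algorithm — moves through three stages of translation: its predictive
performance is validated before implementation, its usability and potential
effect are studied during implementation, and its impact on care is measured
after implementation. Published evidence accumulates unevenly across these
stages, with heterogeneous study designs, subpopulations and outcome
measures, which makes a quantitative meta-analytic synthesis of "how good is
this tool" impossible in general. What *can* be synthesised are the
qualitative conclusions of the studies, anchored to the stage each study
addressed and to the quality of its design.

`grasp` encodes that synthesis. Every tool in a registry carries its original
target specification (population, outcome, setting); every evidence study
carries the single *aspect* it evaluated (internal validation, external
validation, potential effect, usability, post-implementation impact), its
*design*, the *direction* of its conclusion (positive / negative /
equivocal), and a *match profile* against the tool's specification. The
engine then computes three things per tool:

1. **Level assignment.** Studies are bucketed by aspect: internal validation
   at C3; external validation at C1 when at least two distinct publications
   tested external validity, else C2; potential effect at B2; usability at
   B1; post-implementation impact split by design quality tier — tier 1
   (controlled trials and their systematic reviews) at A1, tier 2
   (well-designed observational studies, including the dedicated usability
   methods think-aloud and near-live simulation) at A2, tier 3 (subjective
   and descriptive evidence) at A3.
2. **Direction.** A bucket is positive only when *every* study concluded
   positively; equivocal conclusions always side with negative; anything
   else is mixed and goes to the resolver (below).
3. **Final grade.** The ladder `A1, A2, A3, B1, B2, C1, C2, C3` is walked
   from the top; the grade is the first level whose (resolved) direction is
   positive. This order is a computational device only — the emitted grade is
   an audit code, not an ordinal score. Phases are independent: a tool can be
   A1 with no usability evidence at all, which matches how impact-graded
   tools are reported in practice.

Two sentinels complete the ladder. A tool whose evidence never resolves
positive but that has an internal-validation record receives **C0**
(insufficient internal validation) — this grade originated as a reviewer
extension of the scheme and is therefore configurable (`enable_c0`, default
on). A tool with no usable evidence is **UNGRADED**.

## The mixed-evidence resolver

The published account of the framework describes mixed-evidence handling
only in summary — discordant studies are ranked "by quality and by degree of
matching with the original tool specification" — with the operational detail
left to supplementary material. The resolver implemented here is therefore a
**calibrated reconstruction**: the weakest deterministic rule set we could
find that reproduces all four worked resolutions in the source appraisal
(LACE external validity → positive, MEWS external validity → positive, MEWS
post-implementation impact → positive, Centor post-implementation impact →
negative). Report provenance flags this. The rule, in order:

1. *Small-sample demotion.* A study with recorded sample size below
   `min_sample` (default 1000 patients) is demoted one quality tier.
   Demotion below tier 3 is allowed as an internal rank, so an underpowered
   subjective study still ranks below an adequately powered one. The default
   separates the discounted small studies in the worked appraisals
   (n = 507, 253) from the credited ones (n ≥ 1047) by a round order of
   magnitude; it is configurable per run and echoed into provenance.
2. *Matching restriction.* If any study fully matches the tool's target
   population, outcome and setting, the tally is restricted to fully
   matching studies. Off-specification conclusions (a geriatric
   subpopulation, a sepsis cohort) cannot overrule on-specification
   evidence — but they are retained in the report.
3. *Highest-tier strict majority.* Within the restricted set, the best
   (lowest-numbered) effective tier is tallied: positive versus
   negative-plus-equivocal; a strict majority decides.
4. *Cumulative widening.* On a tie the next tier is merged in and the tally
   repeats.
5. *Recency.* If all tiers tie, the direction whose studies have the larger
   median publication year prevails.
6. *Negative default.* Any remaining tie resolves negative — the
   conservative choice for a framework whose positive grades invite
   clinical adoption.

Every applied rule is recorded as a trace entry (rule, study ids, tally) and
rendered verbatim in the report appendix, so an end user can audit exactly
why discordant evidence resolved the way it did.

### Degenerate inputs and tie-breaks

`determine_direction()` on an empty bucket and `resolve_mixed()` on
concordant evidence are contract violations (errors), not silent defaults.
Studies missing `sample_size` are never demoted, and studies missing `year`
drop out of the recency median; both omissions are flagged as validation
warnings because they silently weaken the resolver. When *no* study matches
the specification, the restriction is skipped rather than emptying the pool.

## Properties the engine guarantees — and two deliberate corners

The test suite checks, over hundreds of seeded synthetic corpora, that
grading is a pure deterministic function of (corpus, config); that a **newly
published** positive study at a level above the current grade never lowers
it; that a **newly published, fully weighted** negative study (matching the
specification, adequately sampled) never raises it; and that on
fully-matching, same-tier, same-year buckets the resolver agrees exactly
with a brute-force strict-majority oracle over every direction assignment up
to bucket size six.

The qualifications are deliberate, because the count-based C1/C2 distinction
creates a *volume channel*: any additional external-validation publication —
even one whose conclusion the resolver then discounts — moves a tool from
"validated once" to "validated multiple times". A once-validated (C2) tool
that accrues a negative study on a non-matching subpopulation becomes C1:
the new publication raises the validation volume while the matching
restriction discards its conclusion. This is not an anomaly of the
implementation; it is exactly the pattern of the MEWS appraisal, where a
negative sepsis-subpopulation study counted toward "tested for external
validity multiple times" while the protocol discounted it. Similarly, an
*old* fully weighted negative study can tie a bucket that recency then
resolves positive. Stating the properties over newly arriving, fully
weighted evidence captures the intended conservatism without contradicting
the framework's own worked examples; both corners are pinned by explicit
tests rather than averaged away.

## The packaged corpora

The five shipped registries transcribe the evidence rosters of the source
appraisal's five worked tools: 7 primary development records and 56
evaluation records (6 LACE, 14 Centor, 10 Wells, 12 MEWS, 14 Ottawa). The
per-study details narrated in the appraisal are encoded exactly — designs,
directions, match status, the named sample sizes (26,045 / 59,652 / 507 /
253 / 3,907 / 4,249) and the 22% antibiotic-prescribing effect size. Where
the narration gives only aggregates ("validated multiple times, all
positive"), the remaining records are padded as positive external
validations with plausible years and sample sizes and flagged
`roster_inferred: true`, so report consumers can distinguish transcription
from inference. Publication-year and sample-size values not printed in the
narration are plausible reconstructions carrying the same flag; they affect
no grading outcome except through the rules described above.

## The synthetic-data generator

`generate_synthetic()` exists to test the engine, so it is built
*grade-first*: the planted grade is fixed and evidence is constructed
backwards to imply it — a primary internal validation (negative for a
planted C0), positive records at the planted level (exactly one external
validation for C2, at least two for C1, one more positive than the number of
injected equivocals elsewhere so strict majorities clear), and optional
distractors that the documented resolver provably discounts: non-matching
negatives (removed by the restriction), small-sample negatives (demoted
below the adequately powered positives), and equivocals (outvoted). Where an
extra record at the planted level would change the level itself — planted C2
or C0 — distractors are diverted to the internal-validation bucket, whose
direction cannot affect a grade decided above it. Recovery of the planted
grade is therefore a genuine test of the engine: the generator never calls
the grading code.

Generation is deterministic under the spec seed (the session RNG stream is
saved and restored), and generated registries pass full validation. What the
generator does *not* emulate: real corpora have correlated study quality and
direction, publication bias toward positive findings, multi-aspect
publications, and ambiguous conclusions that an appraiser must classify —
passing synthetic recovery says the rules are implemented as documented, not
that the rules capture any particular real literature.

Problem sizes used by the default test run: 500 corpora for the
monotonicity/conservatism properties, 500 planted-recovery specs spanning
all nine grade codes, and exhaustive direction-assignment enumeration for
resolver buckets up to size six — small enough to grade in milliseconds per
corpus while exercising every rule branch.

## Registry formats and other design choices

JSON is the canonical registry format (a JSON Schema ships under
`inst/schema/`); YAML is accepted; CSV is a flat import/export written as a
directory of three tables (`registry.csv`, `tools.csv`, `studies.csv`) with
list-valued cells serialised as JSON strings — a single flat table cannot
carry tool profiles, registry metadata and per-study findings losslessly.
Round-trip identity (`load(write(r)) == r`, field for field) holds in all
three formats and is property-tested. Enumerations are accepted
case-insensitively and stored canonically, so loading an already-canonical
file is the identity.

Other decisions worth recording:

* One record per publication × aspect: level assignment is aspect-driven, so
  a trial reporting both think-aloud and near-live usability testing is one
  usability record with two findings, sharing its citation with any impact
  record from the same publication. Distinct-publication counting for C1/C2
  uses citations, so split records do not inflate validation volume.
* Equivocal is stored distinctly and displayed distinctly; it collapses into
  the negative side only inside direction tallies.
* Systematic reviews count as single tier-1 publications with pooled
  findings; their constituent studies are not unpacked.
* Comparative-performance studies ("performed well but not better than the
  comparator") are encoded positive — they affirm external validity — with
  the comparison carried in a `comparator_note` surfaced in reports.
* Reports present phases in translation order C → B → A with the final grade
  last, mark empty phases "No published evidence." explicitly, and are
  byte-deterministic (no timestamps); provenance echoes the engine version
  and the full resolver configuration so a grade can always be re-derived.
* The proportion scale for performance measures (unit interval vs percent)
  is declared once per registry, making range validation decidable.

## Limitations

The direction of each study's conclusion is taken as recorded by the
appraiser; the package deliberately implements no quantitative threshold
separating "positive" from "equivocal", and no within-tier quality grading
of individual studies beyond the sample-size demotion. The mixed-evidence
resolver is calibrated to four published resolutions — a small target — and
should be treated as one defensible reconstruction among several; its
constants and tie-break order are configuration, not truth. And a grade
summarises published evidence only: publication bias, local context and
implementation cost are outside its scope and belong to the detailed report
and the reader.
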