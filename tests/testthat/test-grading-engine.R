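test_that("level assignment buckets studies by aspect, design tier and external-validation volume", {
  ottawa <- build_fixture("ottawa")
  b <- assign_levels(studies_for_tool(ottawa, "ottawa"))
  expect_setequal(names(b), c("A1", "C1", "C3"))
  expect_length(b$A1, 2L)   # two nonrandomised controlled trials of impact
  expect_length(b$C1, 12L)  # multiple external validations incl. pooled review
  expect_length(b$C3, 1L)

  mews <- build_fixture("mews")
  bm <- assign_levels(studies_for_tool(mews, "mews"))
  expect_length(bm$A2, 4L)  # four before-after observational impact studies
  expect_null(bm$A1)

  # every study lands in exactly one bucket
  all_ids <- sort(unname(unlist(lapply(b, function(x)
    vapply(x, `[[`, character(1), "study_id")))))
  expect_identical(all_ids, sort(registry_study_ids(ottawa)))
})

test_that("a single external-validation publication lands on C2, two or more on C1", {
  one <- list(mk_study("p", "internal_validation", "positive", is_primary = TRUE),
              mk_study("e1", "external_validation", "positive"))
  b <- assign_levels(one)
  expect_named(b, c("C2", "C3"), ignore.order = TRUE)
  two <- c(one, list(mk_study("e2", "external_validation", "positive")))
  expect_named(assign_levels(two), c("C1", "C3"), ignore.order = TRUE)
  # two records of the SAME publication (shared citation) stay at C2
  same_pub <- c(one, list(mk_study("e2", "external_validation", "positive",
                                   citation = "e1")))
  expect_named(assign_levels(same_pub), c("C2", "C3"), ignore.order = TRUE)
})

test_that("direction aggregation treats equivocal as negative, never positive", {
  pos <- list(mk_study("a", "external_validation", "positive"),
              mk_study("b", "external_validation", "positive"))
  expect_identical(determine_direction(pos), "all_positive")
  expect_identical(
    determine_direction(list(mk_study("a", "external_validation", "equivocal"))),
    "all_negative")
  neg_eq <- list(mk_study("a", "external_validation", "negative"),
                 mk_study("b", "external_validation", "equivocal"))
  expect_identical(determine_direction(neg_eq), "all_negative")
  mixed <- c(pos, neg_eq)
  expect_identical(determine_direction(mixed), "mixed")
  expect_error(determine_direction(list()), "non-empty")
  expect_error(resolve_mixed(pos), "non-mixed")
})

test_that("Wells external validation is unanimously positive", {
  wells <- build_fixture("wells")
  b <- assign_levels(studies_for_tool(wells, "wells"))
  expect_identical(determine_direction(b$C1), "all_positive")
})

test_that("final grades of the five packaged corpora match the published appraisal", {
  expected <- c(lace = "C1", centor = "B1", wells = "A2", mews = "A2",
                ottawa = "A1")
  for (nm in names(expected)) {
    reg <- build_fixture(nm)
    tid <- registry_tool_ids(reg)
    g <- final_grade(registry_tool(reg, tid), studies_for_tool(reg, tid))
    expect_identical(g$grade, expected[[nm]], info = nm)
  }
})

test_that("grade result carries the per-level trace and its invariant holds", {
  reg <- build_fixture("centor")
  g <- final_grade(registry_tool(reg, "centor"),
                   studies_for_tool(reg, "centor"))
  expect_identical(g$grade, "B1")
  # grade's own level resolved positive; everything strictly above is negative
  expect_identical(g$per_level_evidence$B1$resolution$resolved_direction,
                   "positive")
  above <- grade_scan_order()[seq_len(match("B1", grade_scan_order()) - 1L)]
  for (code in intersect(above, names(g$per_level_evidence))) {
    expect_identical(g$per_level_evidence[[code]]$resolution$resolved_direction,
                     "negative", info = code)
  }
  # mixed levels carry a non-empty trace; concordant levels an empty one
  expect_gt(length(g$per_level_evidence$A1$resolution$resolution_trace), 0L)
  expect_length(g$per_level_evidence$B1$resolution$resolution_trace, 0L)
})

test_that("degenerate corpora grade as the level rules force", {
  tool <- mk_tool()
  # single positive internal validation -> C3
  g <- final_grade(tool, list(mk_study("p", "internal_validation", "positive",
                                       is_primary = TRUE)))
  expect_identical(g$grade, "C3")
  # no studies -> UNGRADED with explanatory trace, not an exception
  g0 <- final_grade(tool, list())
  expect_identical(g0$grade, "UNGRADED")
  expect_match(paste(g0$justification, collapse = " "), "No evidence")
  # negative internal validation only -> C0 by default, UNGRADED when disabled
  neg <- list(mk_study("p", "internal_validation", "negative",
                       is_primary = TRUE))
  expect_identical(final_grade(tool, neg)$grade, "C0")
  expect_identical(
    final_grade(tool, neg, grasp_config(enable_c0 = FALSE))$grade, "UNGRADED")
})

test_that("a negatively resolved external validation falls through to C3, not C2", {
  studies <- list(
    mk_study("p", "internal_validation", "positive", is_primary = TRUE),
    mk_study("e1", "external_validation", "negative"),
    mk_study("e2", "external_validation", "negative"))
  g <- final_grade(mk_tool(), studies)
  expect_identical(g$grade, "C3")
})

test_that("a discounted negative external validation still counts toward validation volume", {
  # one positive external validation -> C2; a second, non-matching negative
  # publication makes the tool "validated multiple times" (C1) while the
  # matching restriction discards its conclusion -- the same pattern as a
  # broadly validated early-warning score with one negative subpopulation
  # study
  base <- list(
    mk_study("p", "internal_validation", "positive", is_primary = TRUE),
    mk_study("e1", "external_validation", "positive", year = 2010))
  expect_identical(final_grade(mk_tool(), base)$grade, "C2")
  plus_nonmatching <- c(base, list(
    mk_study("e2", "external_validation", "negative", matching = FALSE,
             year = 2015)))
  expect_identical(final_grade(mk_tool(), plus_nonmatching)$grade, "C1")
  # a fully weighted recent negative instead ties the bucket, resolves
  # negative by recency and drops the tool to its internal validation
  plus_weighted <- c(base, list(
    mk_study("e2", "external_validation", "negative", year = 2015)))
  expect_identical(final_grade(mk_tool(), plus_weighted)$grade, "C3")
})

test_that("grading is deterministic and pure", {
  reg <- build_fixture("mews")
  tool <- registry_tool(reg, "mews")
  studies <- studies_for_tool(reg, "mews")
  g1 <- final_grade(tool, studies)
  g2 <- final_grade(tool, studies)
  expect_identical(g1, g2)
})

test_that("batch grading is order-stable and survives a malformed corpus", {
  reg <- grasp_example_registry()
  grades <- grade_registry(reg)
  expect_identical(vapply(grades, `[[`, character(1), "tool_id"),
                   registry_tool_ids(reg))
  expect_identical(vapply(grades, `[[`, character(1), "grade"),
                   c("C1", "B1", "A2", "A2", "A1"))

  # corrupt one tool's corpus below the constructor level: others still grade
  broken <- reg
  i <- which(vapply(broken$studies, function(s) s$tool_id == "wells",
                    logical(1)))[1L]
  broken$studies[[i]]$aspect <- "not_an_aspect"
  grades2 <- grade_registry(broken)
  codes <- vapply(grades2, `[[`, character(1), "grade")
  expect_identical(codes[c(1, 2, 4, 5)], c("C1", "B1", "A2", "A1"))
  expect_identical(codes[[3]], "UNGRADED")
  expect_match(grades2[[3]]$justification, "grading failed")

  expect_identical(grade_registry(grasp_registry()), list())
})
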