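test_that("small-sample non-matching negatives do not overturn large matching positives", {
  # two large matching positive validations + two small non-matching
  # negatives + two positive comparative validations -> positive
  lace <- build_fixture("lace")
  b <- assign_levels(studies_for_tool(lace, "lace"))
  res <- resolve_mixed(b$C1, registry_tool(lace, "lace"))
  expect_identical(res$resolved_direction, "positive")
  expect_gt(length(res$resolution_trace), 0L)
  rules <- vapply(res$resolution_trace, `[[`, character(1), "rule")
  expect_true(any(grepl("small-sample demotion", rules)))
  expect_true(any(grepl("fully matching", rules)))
})

test_that("a non-matching subpopulation negative is discounted by the matching restriction", {
  mews <- build_fixture("mews")
  b <- assign_levels(studies_for_tool(mews, "mews"))
  expect_identical(resolve_mixed(b$C1)$resolved_direction, "positive")
})

test_that("highest-tier strict majority decides matching same-tier evidence", {
  mews <- build_fixture("mews")
  b <- assign_levels(studies_for_tool(mews, "mews"))
  expect_identical(resolve_mixed(b$A2)$resolved_direction, "positive")  # 3 v 1
  centor <- build_fixture("centor")
  bc <- assign_levels(studies_for_tool(centor, "centor"))
  expect_identical(resolve_mixed(bc$A1)$resolved_direction, "negative") # 1 v 3
})

test_that("resolver equals the majority oracle on fully matching same-tier buckets", {
  # brute force: every direction assignment for buckets of size 2..6 of
  # fully matching, adequately sampled, same-tier, same-year studies.
  # oracle: strict majority of positive vs negative+equivocal; tie -> negative.
  for (n in 2:6) {
    grids <- expand.grid(rep(list(c("positive", "negative", "equivocal")), n),
                         stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grids))) {
      dirs <- unlist(grids[r, ], use.names = FALSE)
      studies <- lapply(seq_len(n), function(i)
        mk_study(paste0("s", i), "external_validation", dirs[i],
                 n = 5000, year = 2010))
      if (determine_direction(studies) != "mixed") next
      pos <- sum(dirs == "positive")
      oracle <- if (pos > n - pos) "positive" else "negative"
      got <- resolve_mixed(studies, mk_tool())$resolved_direction
      expect_identical(got, oracle,
                       info = paste(n, paste(dirs, collapse = ",")))
    }
  }
})

test_that("ties widen cumulatively across tiers before any other tie-break", {
  # tier 1 tied 1v1; tier 2 carries two more positives -> positive
  studies <- list(
    mk_study("a", "post_implementation_impact", "positive",
             design = "randomised_controlled_trial"),
    mk_study("b", "post_implementation_impact", "negative",
             design = "randomised_controlled_trial"),
    mk_study("c", "post_implementation_impact", "positive",
             design = "randomised_controlled_trial"),
    mk_study("d", "post_implementation_impact", "negative",
             design = "randomised_controlled_trial"),
    mk_study("e", "post_implementation_impact", "positive",
             design = "before_after_observational"),
    mk_study("f", "post_implementation_impact", "positive",
             design = "before_after_observational"))
  res <- resolve_mixed(studies, mk_tool())
  expect_identical(res$resolved_direction, "positive")
  rules <- vapply(res$resolution_trace, `[[`, character(1), "rule")
  expect_identical(sum(grepl("tally at quality tiers", rules)), 2L)
})

test_that("recency breaks full ties and the final default is negative", {
  # 1v1 same tier: the more recent direction prevails
  newer_pos <- list(
    mk_study("a", "external_validation", "positive", year = 2018),
    mk_study("b", "external_validation", "negative", year = 2005))
  expect_identical(resolve_mixed(newer_pos, mk_tool())$resolved_direction,
                   "positive")
  newer_neg <- list(
    mk_study("a", "external_validation", "positive", year = 2005),
    mk_study("b", "external_validation", "negative", year = 2018))
  expect_identical(resolve_mixed(newer_neg, mk_tool())$resolved_direction,
                   "negative")
  # identical years: conservative negative default
  tied <- list(
    mk_study("a", "external_validation", "positive", year = 2010),
    mk_study("b", "external_validation", "negative", year = 2010))
  res <- resolve_mixed(tied, mk_tool())
  expect_identical(res$resolved_direction, "negative")
  expect_true(any(grepl("conservative negative default",
                        vapply(res$resolution_trace, `[[`, character(1),
                               "rule"))))
})

test_that("the small-sample threshold is configurable", {
  studies <- list(
    mk_study("a", "external_validation", "positive", n = 800),
    mk_study("b", "external_validation", "negative", n = 800),
    mk_study("c", "external_validation", "negative", n = 400))
  # default threshold 1000: all three demoted together -> 1v2 negative
  expect_identical(resolve_mixed(studies, mk_tool())$resolved_direction,
                   "negative")
  # threshold 500: only the n=400 study is demoted; tier-2 tie 1v1 widens
  # to include it -> still negative; threshold 100: no demotion at all
  expect_identical(
    resolve_mixed(studies, mk_tool(),
                  grasp_config(min_sample = 100))$resolved_direction,
    "negative")
})

test_that("when no study matches the specification, all studies are retained", {
  studies <- list(
    mk_study("a", "external_validation", "positive", matching = FALSE),
    mk_study("b", "external_validation", "positive", matching = FALSE),
    mk_study("c", "external_validation", "negative", matching = FALSE))
  res <- resolve_mixed(studies, mk_tool())
  expect_identical(res$resolved_direction, "positive")
  expect_true(any(grepl("no fully matching",
                        vapply(res$resolution_trace, `[[`, character(1),
                               "rule"))))
})
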