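#' Packaged evidence corpora
#'
#' Five evidence registries ship with the package, one per appraised tool:
#' the LACE Index for 30-day readmission (6 evaluation studies), the Centor
#' Score for streptococcal pharyngitis (14), Wells' Criteria for pulmonary
#' embolism (10), the Modified Early Warning Score (12) and the Ottawa Knee
#' Rule (14) — 56 evaluation records plus 7 primary (development) records in
#' total. Each corpus encodes the study roster of the published appraisal:
#' designs, directions of conclusion, specification-match status, the named
#' sample sizes and effect sizes. Records whose individual role was not
#' narrated by the source appraisal are padded as positive external
#' validations and flagged `roster_inferred`.
#'
#' @param tool_name One of `"lace"`, `"centor"`, `"wells"`, `"mews"`,
#'   `"ottawa"`.
#' @return A validated [grasp_registry()] holding one tool and its corpus.
#' @export
#' @examples
#' build_fixture("lace")
build_fixture <- function(tool_name) {
  tool_name <- tolower(trimws(as.character(tool_name)[1L]))
  if (!tool_name %in% fixture_names()) {
    stop("unknown fixture '", tool_name, "'; available: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", "registries", paste0(tool_name, ".json"),
                      package = "grasp", mustWork = TRUE)
  load_registry(path, format = "json")
}

#' @rdname build_fixture
#' @export
fixture_names <- function() c("lace", "centor", "wells", "mews", "ottawa")

#' Combined five-tool example registry
#'
#' Merges the five packaged corpora into one registry (5 tools, 63 study
#' records), convenient for batch grading and the registry-wide summary.
#'
#' @return A [grasp_registry()].
#' @export
#' @examples
#' grasp_example_registry()
grasp_example_registry <- function() {
  combine_registries(lapply(fixture_names(), build_fixture))
}
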