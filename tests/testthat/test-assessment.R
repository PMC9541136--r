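test_that("a fresh assessment has the 17-question schema", {
  a <- new_assessment(toy_population())
  q <- a$questions
  expect_identical(nrow(q), 17L)
  counts <- table(q$section)
  expect_identical(counts[["research_statement"]], 4L)
  expect_identical(counts[["resolution"]], 1L)
  for (sec in c("geographic", "environmental", "taxonomic", "other"))
    expect_identical(counts[[sec]], 3L)
  expect_identical(anyDuplicated(q$id), 0L)
  expect_identical(a$version, 1L)
  # each domain subsection ends in a mitigation question
  for (sec in c("geographic", "environmental", "taxonomic", "other"))
    expect_identical(sum(q$role[q$section == sec] == "mitigation"), 1L)
})

test_that("resolution statement mismatches warn, matches do not", {
  a <- new_assessment(toy_population(res = 1, width = 10))
  # missing statement is an incompleteness flag
  issues0 <- validate_assessment(a)
  expect_true(any(grepl("resolution statement is missing", issues0$message)))

  a_match <- set_resolution_statement(a, spatial = 1, temporal = 10)
  expect_false(any(validate_assessment(a_match)$severity == "warning"))

  a_coarse <- set_resolution_statement(a, spatial = 0.9, temporal = 1)
  issues <- validate_assessment(a_coarse)
  expect_true(any(issues$severity == "warning" &
                    grepl("grain", issues$message)))
})

test_that("evidence attaches only to known questions and resolvable artifacts", {
  a <- new_assessment(toy_population())
  a <- add_artifact(a, "nni", "nni.csv", "index series")
  a <- attach_evidence(a, "2.3", "nni")
  expect_identical(a$questions$evidence[[match("2.3", a$questions$id)]], "nni")
  # duplicate attachment deduplicates
  a <- attach_evidence(a, "2.3", "nni")
  expect_identical(a$questions$evidence[[match("2.3", a$questions$id)]], "nni")
  expect_error(attach_evidence(a, "9.9", "nni"), "unknown question")
  expect_error(attach_evidence(a, "2.3", "ghost"), "does not resolve")
})

test_that("validation enforces mitigation-or-justification after a bias flag", {
  a <- new_assessment(toy_population())
  for (id in a$questions$id) a <- answer_question(a, id, "answered.")
  a <- set_resolution_statement(a, 1, 10)
  expect_identical(nrow(validate_assessment(a)), 0L)

  # flag a geographic bias and empty the mitigation answer -> one violation
  flagged <- answer_question(a, "2.3", "coverage shifted north", bias_flag = TRUE)
  flagged$questions$answer[match("2.4", flagged$questions$id)] <- ""
  issues <- validate_assessment(flagged)
  expect_identical(sum(grepl("2.4", issues$question)), 2L)  # unanswered + mitigation rule
  expect_true(any(grepl("mitigation answer \\(question 2.4\\)", issues$message)))

  # a not-relevant justification lifts the requirement
  excused <- answer_question(flagged, "2.4", "",
                             relevance = "not_relevant_with_justification",
                             justification = "inference restricted to sampled subregion")
  issues2 <- validate_assessment(excused)
  expect_false(any(grepl("mitigation answer", issues2$message)))

  # validation is pure: calling it did not mutate the assessment
  expect_identical(validate_assessment(flagged), issues)
})

test_that("iteration produces a linear, immutable, diffed version chain", {
  a <- new_assessment(toy_population())
  b <- next_iteration(a, "first revision")
  expect_identical(b$version, 2L)
  expect_identical(b$parent_version, 1L)
  expect_identical(length(b$previous), 1L)
  expect_identical(a$version, 1L)  # original untouched

  pop2 <- toy_population(bbox = c(0, 0, 5, 10))
  c3 <- next_iteration(b, "shrink extent to sampled half", pop2)
  expect_identical(c3$version, 3L)
  expect_identical(length(c3$history), 2L)
  expect_match(c3$history[[2]]$population_diff[[1]], "geo_extent")
  expect_error(next_iteration(c3, ""), "reason")

  md <- render_assessment(c3, "markdown")
  # newest version first in the rendered history
  pos3 <- regexpr("Version 3", md)[1]
  pos2 <- regexpr("Version 2", md)[1]
  expect_lt(pos3, pos2)
})

test_that("serialize -> parse -> serialize is byte-identical", {
  a <- new_assessment(toy_population())
  a <- set_resolution_statement(a, 1, 10)
  a <- add_artifact(a, "nni", "nni.csv", "index series")
  a <- attach_evidence(a, "2.3", "nni")
  a <- answer_question(a, "2.2", "coverage is patchy", bias_flag = TRUE)
  cleaned <- clean_records(toy_records(), "drop_exact_duplicates",
                           sources = "toy set")
  a <- set_provenance(a, cleaned$log)
  a <- next_iteration(a, "re-run after cleaning",
                      toy_population(bbox = c(0, 0, 5, 10)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_assessment(a, path)
  b <- read_assessment(path)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_assessment(b, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_identical(b$version, a$version)
  expect_identical(b$questions$answer, a$questions$answer)
})

test_that("rendering is deterministic and respects the format argument", {
  a <- new_assessment(toy_population())
  md <- render_assessment(a, "markdown")
  # all 17 prompts present in the empty template
  expect_identical(length(gregexpr("### Question ", md)[[1]]), 17L)
  expect_identical(md, render_assessment(a, "markdown"))
  html <- render_assessment(a, "html")
  expect_match(html, "^<!DOCTYPE html>")
  expect_identical(length(gregexpr("<h3>", html)[[1]]), 17L)
  expect_error(render_assessment(a, "pdf"), "unknown format")
})
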