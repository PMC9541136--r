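# The risk-of-bias assessment document: a fixed 17-question schema across six
# sections, free-text answers with explicit user-set bias flags, evidence
# attachments pointing at stored heuristic artifacts, structural validation,
# versioned iteration, and deterministic Markdown/HTML rendering.
#
# The document records and structures judgement; it never auto-judges. Bias
# is only definable relative to an inferential goal, so flags are booleans
# the user sets, not values inferred from heuristics.

expected_section_counts <- c(
  research_statement = 4L, resolution = 1L, geographic = 3L,
  environmental = 3L, taxonomic = 3L, other = 3L
)

question_prompts <- function() {
  path <- system.file("extdata", "question_prompts.csv", package = "occbias")
  if (path == "") path <- file.path("inst", "extdata", "question_prompts.csv")
  readr::read_csv(path, comment = "#", col_types = "cccc", progress = FALSE)
}

check_schema <- function(questions) {
  if (nrow(questions) != 17)
    stop("assessment must contain exactly 17 questions, got ", nrow(questions),
         call. = FALSE)
  if (anyDuplicated(questions$id))
    stop("question ids must be unique", call. = FALSE)
  counts <- table(questions$section)
  for (sec in names(expected_section_counts)) {
    got <- if (sec %in% names(counts)) counts[[sec]] else 0L
    if (got != expected_section_counts[[sec]])
      stop(sprintf("section '%s' must contain %d question(s), got %d",
                   sec, expected_section_counts[[sec]], got), call. = FALSE)
  }
  invisible(questions)
}

#' Create a blank risk-of-bias assessment
#'
#' Instantiates the 17-question document for a declared target population:
#' four research-statement questions (population scope, inferential goal,
#' provenance, cleaning), one assessment-resolution question, then three
#' questions (representativeness, temporal consistency, mitigation) for each
#' of the geographic, environmental and taxonomic domains, and a final
#' other-biases triple. Answers start empty; version is 1.
#'
#' @param pop A [target_population()].
#' @return An object of class `bias_assessment`.
#' @export
#' @examples
#' pop <- target_population(c(0, 0, 10, 10), c(1950, 2019), "sp1")
#' a <- new_assessment(pop)
#' nrow(a$questions)  # 17
new_assessment <- function(pop) {
  stopifnot(inherits(pop, "target_population"))
  q <- question_prompts() |>
    dplyr::mutate(
      answer = "",
      relevance = "relevant",
      justification = "",
      bias_flag = FALSE,
      evidence = purrr::map(seq_len(dplyr::n()), \(i) character(0))
    )
  check_schema(q)
  structure(
    list(
      population = pop,
      provenance = NULL,
      resolution_statement = NULL,
      questions = q,
      artifacts = list(),
      version = 1L,
      parent_version = NA_integer_,
      history = list(),
      previous = list(),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "bias_assessment"
  )
}

#' @export
print.bias_assessment <- function(x, ...) {
  answered <- sum(nzchar(x$questions$answer))
  cat(sprintf("<bias_assessment> version %d, %d/17 questions answered, %d artifact(s)\n",
              x$version, answered, length(x$artifacts)))
  issues <- validate_assessment(x)
  if (nrow(issues) == 0) cat("  structurally complete\n")
  else cat(sprintf("  %d open issue(s); see validate_assessment()\n", nrow(issues)))
  invisible(x)
}

#' Attach the cleaning provenance log to an assessment
#'
#' Embeds a [clean_records()] log so the cleaning-justification question
#' carries its quantitative audit trail.
#'
#' @param assessment A `bias_assessment`.
#' @param log A `provenance_log`.
#' @return The updated assessment.
#' @export
set_provenance <- function(assessment, log) {
  stopifnot(inherits(assessment, "bias_assessment"),
            inherits(log, "provenance_log"))
  assessment$provenance <- provenance_as_list(log)
  assessment
}

#' Record the resolutions at which the assessment is conducted
#'
#' The assessment grain should generally match the grain at which inference
#' is desired: screening at a decadal/coarse-cell grain says little about
#' yearly/fine-cell inference. A mismatch between the assessment grain and
#' the population's declared resolutions is therefore surfaced as a prominent
#' warning by [validate_assessment()] (never an error — exceptions exist).
#'
#' @param assessment A `bias_assessment`.
#' @param spatial Assessment grid-cell edge, decimal degrees.
#' @param temporal Assessment temporal bin width, years.
#' @param taxonomic_rank Rank at which taxa are assessed (e.g. `"species"`).
#' @return The updated assessment.
#' @export
set_resolution_statement <- function(assessment, spatial, temporal,
                                     taxonomic_rank = "species") {
  stopifnot(inherits(assessment, "bias_assessment"))
  if (!is.numeric(spatial) || spatial <= 0) stop("spatial must be > 0", call. = FALSE)
  temporal <- as.integer(temporal)
  if (is.na(temporal) || temporal < 1) stop("temporal must be >= 1", call. = FALSE)
  assessment$resolution_statement <- list(
    spatial = as.numeric(spatial), temporal = temporal,
    taxonomic_rank = as.character(taxonomic_rank)
  )
  assessment
}

#' Answer a question (and optionally set its bias flag)
#'
#' @param assessment A `bias_assessment`.
#' @param id Question id (e.g. `"2.3"`).
#' @param answer Free text (and/or references to figures).
#' @param bias_flag Optional logical: does this answer indicate a potential
#'   bias? Only the user sets this; heuristics inform but never decide.
#' @param relevance `"relevant"` (default) or
#'   `"not_relevant_with_justification"`; the latter requires
#'   `justification`.
#' @param justification Justification text when marking not relevant.
#' @return The updated assessment.
#' @export
answer_question <- function(assessment, id, answer, bias_flag = NULL,
                            relevance = NULL, justification = NULL) {
  stopifnot(inherits(assessment, "bias_assessment"))
  i <- match(id, assessment$questions$id)
  if (is.na(i)) stop("unknown question id: ", id, call. = FALSE)
  assessment$questions$answer[i] <- as.character(answer)
  if (!is.null(bias_flag))
    assessment$questions$bias_flag[i] <- isTRUE(bias_flag)
  if (!is.null(relevance)) {
    if (!relevance %in% c("relevant", "not_relevant_with_justification"))
      stop("relevance must be 'relevant' or 'not_relevant_with_justification'",
           call. = FALSE)
    if (relevance == "not_relevant_with_justification" &&
        (is.null(justification) || !nzchar(justification)))
      stop("marking a question not relevant requires a justification",
           call. = FALSE)
    assessment$questions$relevance[i] <- relevance
  }
  if (!is.null(justification))
    assessment$questions$justification[i] <- as.character(justification)
  assessment
}

#' Register a heuristic output as an evidence artifact
#'
#' @param assessment A `bias_assessment`.
#' @param id Artifact identifier (used by [attach_evidence()]).
#' @param path Relative path to the stored artifact (CSV, figure, ...).
#' @param description Short description of what the artifact shows.
#' @return The updated assessment.
#' @export
add_artifact <- function(assessment, id, path, description = "") {
  stopifnot(inherits(assessment, "bias_assessment"))
  assessment$artifacts[[id]] <- list(path = as.character(path),
                                     description = as.character(description))
  assessment
}

#' Attach a registered artifact to a question as evidence
#'
#' The reference must resolve to an artifact registered with
#' [add_artifact()]; dangling references are an error. Attaching the same
#' reference twice is a no-op (deduplicated).
#'
#' @param assessment A `bias_assessment`.
#' @param id Question id.
#' @param ref Artifact identifier.
#' @return The updated assessment.
#' @export
attach_evidence <- function(assessment, id, ref) {
  stopifnot(inherits(assessment, "bias_assessment"))
  i <- match(id, assessment$questions$id)
  if (is.na(i)) stop("unknown question id: ", id, call. = FALSE)
  if (!ref %in% names(assessment$artifacts))
    stop("evidence ref '", ref, "' does not resolve to a registered artifact",
         call. = FALSE)
  assessment$questions$evidence[[i]] <-
    unique(c(assessment$questions$evidence[[i]], ref))
  assessment
}

#' Structural completeness report for an assessment
#'
#' Pure and idempotent: inspects, never mutates, never judges answer content.
#' Reports (i) unanswered questions, (ii) domain subsections where a bias
#' flag is set but the mitigation answer is empty and no not-relevant
#' justification exists (users are not required to explain poor coverage that
#' is irrelevant to their inferences), (iii) a missing resolution statement,
#' and (iv) a prominent warning when the assessment grain differs from the
#' declared inference grain.
#'
#' @param assessment A `bias_assessment`.
#' @return Tibble with columns `severity` (`"incomplete"` or `"warning"`),
#'   `question` (id or `NA`), `message`. Zero rows when complete.
#' @export
validate_assessment <- function(assessment) {
  stopifnot(inherits(assessment, "bias_assessment"))
  check_schema(assessment$questions)
  q <- assessment$questions
  issues <- list()
  unanswered <- q$id[!nzchar(q$answer) & q$relevance == "relevant"]
  for (id in unanswered) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      severity = "incomplete", question = id,
      message = paste0("question ", id, " is unanswered"))
  }
  for (sec in c("geographic", "environmental", "taxonomic", "other")) {
    sub <- q[q$section == sec, ]
    flagged <- any(sub$bias_flag[sub$role != "mitigation"])
    mit <- sub[sub$role == "mitigation", ]
    justified <- any(sub$relevance == "not_relevant_with_justification" &
                       nzchar(sub$justification))
    if (flagged && !nzchar(mit$answer[1]) && !justified) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        severity = "incomplete", question = mit$id[1],
        message = paste0("bias flagged in the ", sec, " subsection but the ",
                         "mitigation answer (question ", mit$id[1],
                         ") is empty and no not-relevant justification exists"))
    }
  }
  if (is.null(assessment$resolution_statement)) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      severity = "incomplete", question = "2.1",
      message = "assessment resolution statement is missing")
  } else {
    rs <- assessment$resolution_statement
    pop <- assessment$population
    if (rs$spatial != pop$spatial_resolution ||
        rs$temporal != pop$temporal_resolution) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        severity = "warning", question = "2.1",
        message = sprintf(
          paste0("assessment grain (%g deg / %d yr) differs from the declared ",
                 "inference grain (%g deg / %d yr); conclusions about bias at ",
                 "one grain need not transfer to the other"),
          rs$spatial, rs$temporal, pop$spatial_resolution,
          pop$temporal_resolution))
    }
  }
  if (length(issues) == 0)
    tibble::tibble(severity = character(0), question = character(0),
                   message = character(0))
  else dplyr::bind_rows(issues)
}

# field-by-field population diff for the iteration history
population_diff <- function(old, new) {
  diffs <- character(0)
  fmt_extent <- function(e) {
    bb <- extent_bbox(e)
    sprintf("%s [%g, %g] x [%g, %g]", e$type, bb[1], bb[3], bb[2], bb[4])
  }
  if (!identical(old$geo_extent, new$geo_extent))
    diffs <- c(diffs, sprintf("geo_extent: %s -> %s",
                              fmt_extent(old$geo_extent), fmt_extent(new$geo_extent)))
  if (!identical(old$temporal_extent, new$temporal_extent))
    diffs <- c(diffs, sprintf("temporal_extent: %d-%d -> %d-%d",
                              old$temporal_extent[1], old$temporal_extent[2],
                              new$temporal_extent[1], new$temporal_extent[2]))
  if (!identical(sort(old$taxa), sort(new$taxa)))
    diffs <- c(diffs, sprintf("taxa: %d -> %d target taxa",
                              length(old$taxa), length(new$taxa)))
  if (old$spatial_resolution != new$spatial_resolution)
    diffs <- c(diffs, sprintf("spatial_resolution: %g -> %g deg",
                              old$spatial_resolution, new$spatial_resolution))
  if (old$temporal_resolution != new$temporal_resolution)
    diffs <- c(diffs, sprintf("temporal_resolution: %d -> %d yr",
                              old$temporal_resolution, new$temporal_resolution))
  if (!identical(old$env_axes, new$env_axes))
    diffs <- c(diffs, "env_axes changed")
  diffs
}

#' Start the next iteration of an assessment
#'
#' Assessment is often iterative: screening may reveal poor coverage in part
#' of a domain, prompting the user to redefine the population (e.g. shrink
#' the geographic extent) and re-assess. Each iteration is a new version with
#' a recorded reason and a field-level diff of any population change; prior
#' versions are kept immutable inside the chain so the full history
#' serializes and renders with the document.
#'
#' @param assessment The current `bias_assessment`.
#' @param reason Why a new iteration is needed.
#' @param population Optional new [target_population()] (defaults to the
#'   current one).
#' @return A new `bias_assessment`, version incremented, parent linked.
#' @export
next_iteration <- function(assessment, reason, population = NULL) {
  stopifnot(inherits(assessment, "bias_assessment"))
  if (missing(reason) || !nzchar(reason))
    stop("an iteration needs a recorded reason", call. = FALSE)
  new <- assessment
  snapshot <- assessment
  snapshot$previous <- list()
  new$previous <- c(assessment$previous, list(assessment_as_list(snapshot)))
  new$parent_version <- assessment$version
  new$version <- assessment$version + 1L
  diff <- character(0)
  if (!is.null(population)) {
    stopifnot(inherits(population, "target_population"))
    diff <- population_diff(assessment$population, population)
    new$population <- population
  }
  new$history <- c(assessment$history, list(list(
    version = new$version, parent = assessment$version,
    reason = as.character(reason), population_diff = as.list(diff),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )))
  new$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  new
}
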