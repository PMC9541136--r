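# Assessment serialization (nested key-value plain text, human-diffable for
# version control) and deterministic rendering to Markdown/HTML.

extent_as_list <- function(extent) {
  out <- list(type = extent$type, bbox = as.numeric(extent$bbox))
  if (extent$type == "polygon") {
    out$vertices <- apply(extent$vertices, 1, as.numeric, simplify = FALSE)
  }
  out
}

extent_from_list <- function(x) {
  if (x$type == "polygon") {
    normalize_extent(do.call(rbind, lapply(x$vertices, as.numeric)))
  } else {
    normalize_extent(as.numeric(unlist(x$bbox)))
  }
}

population_as_list <- function(pop) {
  list(
    geo_extent = extent_as_list(pop$geo_extent),
    temporal_extent = as.integer(pop$temporal_extent),
    taxa = as.list(pop$taxa),
    spatial_resolution = as.numeric(pop$spatial_resolution),
    temporal_resolution = as.integer(pop$temporal_resolution),
    env_axes = as.list(pop$env_axes)
  )
}

population_from_list <- function(x) {
  target_population(
    geo_extent = if (x$geo_extent$type == "polygon")
      do.call(rbind, lapply(x$geo_extent$vertices, as.numeric))
    else as.numeric(unlist(x$geo_extent$bbox)),
    temporal_extent = as.integer(unlist(x$temporal_extent)),
    taxa = as.character(unlist(x$taxa)),
    spatial_resolution = as.numeric(x$spatial_resolution),
    temporal_resolution = as.integer(x$temporal_resolution),
    env_axes = if (length(x$env_axes)) as.character(unlist(x$env_axes)) else NULL
  )
}

# full serializable form; `previous` holds snapshots of earlier versions
assessment_as_list <- function(assessment) {
  q <- assessment$questions
  list(
    format = "occbias/assessment/v1",
    version = as.integer(assessment$version),
    parent_version = if (is.na(assessment$parent_version)) NULL
      else as.integer(assessment$parent_version),
    created = as.character(assessment$created),
    population = population_as_list(assessment$population),
    resolution_statement = assessment$resolution_statement,
    provenance = assessment$provenance,
    questions = purrr::map(seq_len(nrow(q)), function(i) {
      list(
        id = q$id[i], section = q$section[i], role = q$role[i],
        prompt = q$prompt[i], answer = q$answer[i],
        relevance = q$relevance[i], justification = q$justification[i],
        bias_flag = q$bias_flag[i],
        evidence = as.list(q$evidence[[i]])
      )
    }),
    artifacts = assessment$artifacts,
    history = assessment$history,
    previous = assessment$previous
  )
}

# canonicalize structures whose YAML reading collapses one-element string
# sequences to scalars, so that serialize -> parse -> serialize is
# byte-identical
normalize_provenance <- function(pr) {
  if (is.null(pr)) return(NULL)
  list(
    input = as.integer(pr$input),
    steps = purrr::map(pr$steps %||% list(), function(st) {
      list(rule = as.character(st$rule), removed = as.integer(st$removed),
           params = as.character(st$params %||% ""))
    }),
    output = as.integer(pr$output),
    sources = as.list(as.character(unlist(pr$sources))),
    timestamp = as.character(pr$timestamp)
  )
}

normalize_history <- function(hist) {
  purrr::map(hist %||% list(), function(h) {
    list(version = as.integer(h$version), parent = as.integer(h$parent),
         reason = as.character(h$reason),
         population_diff = as.list(as.character(unlist(h$population_diff))),
         created = as.character(h$created))
  })
}

normalize_artifacts <- function(arts) {
  out <- purrr::map(arts %||% list(), function(a) {
    list(path = as.character(a$path),
         description = as.character(a$description %||% ""))
  })
  out
}

assessment_from_list <- function(x) {
  stopifnot(identical(x$format, "occbias/assessment/v1"))
  q <- dplyr::bind_rows(purrr::map(x$questions, function(qq) {
    tibble::tibble(
      id = qq$id, section = qq$section, role = qq$role, prompt = qq$prompt,
      answer = qq$answer %||% "", relevance = qq$relevance %||% "relevant",
      justification = qq$justification %||% "",
      bias_flag = isTRUE(qq$bias_flag),
      evidence = list(as.character(unlist(qq$evidence)))
    )
  }))
  check_schema(q)
  rs <- x$resolution_statement
  if (!is.null(rs)) {
    rs$spatial <- as.numeric(rs$spatial)
    rs$temporal <- as.integer(rs$temporal)
    rs$taxonomic_rank <- as.character(rs$taxonomic_rank)
  }
  structure(
    list(
      population = population_from_list(x$population),
      provenance = normalize_provenance(x$provenance),
      resolution_statement = rs,
      questions = q,
      artifacts = normalize_artifacts(x$artifacts),
      version = as.integer(x$version),
      parent_version = if (is.null(x$parent_version)) NA_integer_
        else as.integer(x$parent_version),
      history = normalize_history(x$history),
      previous = purrr::map(x$previous %||% list(), function(p) {
        assessment_as_list(assessment_from_list(p))
      }),
      created = as.character(x$created)
    ),
    class = "bias_assessment"
  )
}

#' Serialize an assessment to structured plain text
#'
#' The on-disk form is nested key-value text (YAML), chosen to be
#' human-diffable so assessment iterations can live under ordinary version
#' control. Serialization is deterministic: serialize, parse, serialize is
#' byte-identical.
#'
#' @param assessment A `bias_assessment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessment, path) {
  stopifnot(inherits(assessment, "bias_assessment"))
  writeLines(assessment_to_text(assessment), path, sep = "")
  invisible(path)
}

assessment_to_text <- function(assessment) {
  yaml::as.yaml(assessment_as_list(assessment))
}

#' Read an assessment from its plain-text form
#'
#' @param path File written by [write_assessment()].
#' @return A `bias_assessment`.
#' @export
read_assessment <- function(path) {
  assessment_from_list(yaml::read_yaml(path))
}

section_titles <- c(
  research_statement = "Research statement and pre-bias assessment",
  resolution = "Assessment resolution",
  geographic = "Geographic bias",
  environmental = "Environmental bias",
  taxonomic = "Taxonomic bias",
  other = "Other potential biases"
)

# shared deterministic document structure; emitters below turn it into
# markdown or html
render_blocks <- function(assessment) {
  a <- assessment
  pop <- a$population
  bb <- extent_bbox(pop$geo_extent)
  blocks <- list()
  add <- function(type, text) blocks[[length(blocks) + 1]] <<- list(type = type, text = text)
  add("h1", sprintf("Risk-of-bias assessment (version %d)", a$version))
  add("p", sprintf("Created: %s", a$created))
  add("h2", "Target population")
  add("li", sprintf("Geographic extent: %s [%g, %g] x [%g, %g] (lon x lat)",
                    pop$geo_extent$type, bb[1], bb[3], bb[2], bb[4]))
  add("li", sprintf("Temporal extent: %d-%d, %d-year bins",
                    pop$temporal_extent[1], pop$temporal_extent[2],
                    pop$temporal_resolution))
  add("li", sprintf("Target taxa: %d (%s)", length(pop$taxa),
                    paste(utils::head(pop$taxa, 8), collapse = ", ")))
  add("li", sprintf("Spatial grain: %g degree cells", pop$spatial_resolution))
  if (length(pop$env_axes))
    add("li", paste("Environmental axes:", paste(pop$env_axes, collapse = ", ")))
  if (!is.null(a$resolution_statement)) {
    rs <- a$resolution_statement
    add("h2", "Assessment resolutions")
    add("p", sprintf("Assessed at %g degree cells, %d-year bins, %s rank.",
                     rs$spatial, rs$temporal, rs$taxonomic_rank))
  }
  if (!is.null(a$provenance)) {
    pr <- a$provenance
    add("h2", "Data provenance and cleaning")
    add("li", sprintf("Input records: %d", pr$input))
    for (st in pr$steps)
      add("li", sprintf("%s removed %d%s", st$rule, st$removed,
                        if (nzchar(st$params)) paste0(" (", st$params, ")") else ""))
    add("li", sprintf("Output records: %d", pr$output))
    for (s in pr$sources) add("li", paste("Source:", s))
  }
  for (sec in names(section_titles)) {
    add("h2", section_titles[[sec]])
    sub <- a$questions[a$questions$section == sec, ]
    for (i in seq_len(nrow(sub))) {
      add("h3", sprintf("Question %s", sub$id[i]))
      add("p", sub$prompt[i])
      if (sub$relevance[i] == "not_relevant_with_justification") {
        add("p", paste("Marked not relevant:", sub$justification[i]))
      }
      add("p", if (nzchar(sub$answer[i])) paste("Answer:", sub$answer[i])
               else "Answer: (unanswered)")
      if (isTRUE(sub$bias_flag[i])) add("p", "Potential bias flagged by the assessor.")
      for (ref in sub$evidence[[i]]) {
        art <- a$artifacts[[ref]]
        add("evidence", sprintf("%s: %s (%s)", ref, art$description, art$path))
      }
    }
  }
  add("h2", "Version history")
  if (length(a$history) == 0) {
    add("p", "Version 1 (initial assessment).")
  } else {
    for (h in rev(a$history)) {  # newest first
      add("li", sprintf("Version %d (from version %d, %s): %s",
                        h$version, h$parent, h$created, h$reason))
      for (d in h$population_diff) add("li", paste("  population change:", d))
    }
    add("li", "Version 1 (initial assessment).")
  }
  blocks
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

is_image_ref <- function(path) grepl("\\.(png|jpg|jpeg|svg)$", path)

#' Render an assessment document
#'
#' Produces a deterministic report: research statement, assessment
#' resolutions, provenance, the four domain subsections in fixed order, then
#' the version history newest-first, with evidence artifacts listed (and
#' images embedded by reference) under the questions they support.
#'
#' @param assessment A `bias_assessment`.
#' @param format `"markdown"` or `"html"`.
#' @return A single character string (the document).
#' @export
render_assessment <- function(assessment, format = c("markdown", "html")) {
  if (!is.character(format) || !format[1] %in% c("markdown", "html"))
    stop("unknown format: ", format[1], " (use 'markdown' or 'html')",
         call. = FALSE)
  format <- format[1]
  blocks <- render_blocks(assessment)
  if (format == "markdown") {
    lines <- purrr::map_chr(blocks, function(b) {
      switch(b$type,
        h1 = paste0("# ", b$text, "\n"),
        h2 = paste0("\n## ", b$text, "\n"),
        h3 = paste0("\n### ", b$text, "\n"),
        p = paste0("\n", b$text, "\n"),
        li = paste0("- ", b$text),
        evidence = {
          path <- sub(".*\\((.*)\\)$", "\\1", b$text)
          if (is_image_ref(path)) paste0("\n![", b$text, "](", path, ")\n")
          else paste0("- Evidence ", b$text)
        }
      )
    })
    paste0(paste(lines, collapse = "\n"), "\n")
  } else {
    body <- purrr::map_chr(blocks, function(b) {
      txt <- html_escape(b$text)
      switch(b$type,
        h1 = paste0("<h1>", txt, "</h1>"),
        h2 = paste0("<h2>", txt, "</h2>"),
        h3 = paste0("<h3>", txt, "</h3>"),
        p = paste0("<p>", txt, "</p>"),
        li = paste0("<li>", txt, "</li>"),
        evidence = {
          path <- sub(".*\\((.*)\\)$", "\\1", b$text)
          if (is_image_ref(path))
            paste0("<figure><img src=\"", path, "\" alt=\"", txt,
                   "\"/><figcaption>", txt, "</figcaption></figure>")
          else paste0("<li>Evidence ", txt, "</li>")
        }
      )
    })
    paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
           "<title>Risk-of-bias assessment</title></head>\n<body>\n",
           paste(body, collapse = "\n"), "\n</body></html>\n")
  }
}
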