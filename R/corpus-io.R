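#' Read a node list of papers
#'
#' Reads the vertex table of a claim-specific citation corpus: one row per
#' paper with an identifier, a paper type (primary trial vs review), a stance
#' classification, and a publication year. Extra columns (authors, journal,
#' notes, ...) are preserved untouched so no attribute information is lost on
#' the way to the graph.
#'
#' Classification labels are matched against `stance_set` case-insensitively
#' and normalised to the canonical spelling in `stance_set`. Paper types
#' `"primary"`, `"rct"` and `"trial"` normalise to `"primary"`; `"review"`
#' stays `"review"`.
#'
#' @param file Path to a delimited text file (comma-separated, UTF-8, header
#'   row required), or a connection.
#' @param stance_set Character vector of allowed classification labels.
#'   Defaults to [default_stances()].
#' @param col_map Named character vector mapping the canonical column names
#'   `id`, `paper_type`, `classification`, `year`, `label` to the names used
#'   in the file. Only names that differ from the canonical ones need to be
#'   given.
#' @return A tibble with columns `id`, `paper_type`, `classification`,
#'   `year`, `label`, followed by any extra columns from the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "id,paper_type,classification,year,label",
#'   "P1,primary,supportive,1966,Trial one",
#'   "R1,review,Neutral,1970,Review one"
#' ), f)
#' read_node_list(f)
read_node_list <- function(file,
                           stance_set = default_stances(),
                           col_map = character()) {
  cm <- resolve_col_map(
    col_map,
    c("id", "paper_type", "classification", "year", "label")
  )
  raw <- readr::read_csv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )

  required <- cm[c("id", "paper_type", "classification", "year")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    abort_format(paste0(
      "Node list is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }

  out <- raw
  have_label <- cm[["label"]] %in% names(raw)
  canonical <- cm[c("id", "paper_type", "classification", "year",
                    if (have_label) "label")]
  names(out)[match(unname(canonical), names(out))] <- names(canonical)
  if (!have_label) out$label <- out$id

  out$id <- trimws(out$id)
  if (any(is.na(out$id) | out$id == "")) {
    abort_corpus(paste0(
      "Empty paper id in row(s) ",
      id_phrase(which(is.na(out$id) | out$id == ""))
    ))
  }
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0) {
    abort_corpus(paste0("Duplicate paper id(s): ", id_phrase(dup)))
  }

  out$paper_type <- normalise_paper_type(out$paper_type)
  out$classification <- normalise_stance(out$classification, stance_set)

  year_num <- suppressWarnings(as.integer(out$year))
  bad <- which(!is.na(out$year) & is.na(year_num))
  if (length(bad) > 0) {
    abort_corpus(paste0(
      "Unparseable year ", shQuote(out$year[bad[1]]),
      " in row ", bad[1], " (id ", out$id[bad[1]], ")"
    ))
  }
  out$year <- year_num

  unclassified_primary <- out$paper_type == "primary" & is.na(out$classification)
  if (any(unclassified_primary)) {
    abort_corpus(paste0(
      "Primary paper(s) without a stance classification: ",
      id_phrase(out$id[unclassified_primary])
    ))
  }

  dplyr::relocate(
    tibble::as_tibble(out),
    "id", "paper_type", "classification", "year", "label"
  )
}

#' Read an edge list of citations
#'
#' Reads citation links as (citing id, cited id) pairs, one per row, in file
#' order. No deduplication happens here — a binary adjacency collapse is the
#' graph builder's job ([build_citation_graph()]) — but self-citations are
#' never usable records: they are removed from the returned records and
#' reported via the `"violations"` attribute and a warning, since a paper
#' cannot cite itself.
#'
#' @param file Path to a delimited text file with a header row, or a
#'   connection.
#' @param col_map Named character vector mapping the canonical column names
#'   `citing_id` and `cited_id` to the names used in the file.
#' @return A tibble with columns `citing_id`, `cited_id`, row order
#'   preserved. Attribute `violations` holds a tibble of dropped
#'   self-citation rows (`rule`, `ids`, `message`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("citing_id,cited_id", "R1,P1", "R2,P1"), f)
#' read_edge_list(f)
read_edge_list <- function(file, col_map = character()) {
  cm <- resolve_col_map(col_map, c("citing_id", "cited_id"))
  raw <- readr::read_csv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(unname(cm), names(raw))
  if (length(missing) > 0) {
    abort_format(paste0(
      "Edge list is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    citing_id = trimws(raw[[cm[["citing_id"]]]]),
    cited_id = trimws(raw[[cm[["cited_id"]]]])
  )
  self <- out$citing_id == out$cited_id
  violations <- tibble::tibble(
    rule = character(), ids = character(), message = character()
  )
  if (any(self)) {
    violations <- tibble::tibble(
      rule = "self_citation",
      ids = out$citing_id[self],
      message = paste0("Paper ", out$citing_id[self], " cites itself (row ",
                       which(self), ")")
    )
    warn(paste0(
      "Dropped ", sum(self), " self-citation row(s): ",
      id_phrase(out$citing_id[self])
    ))
    out <- out[!self, ]
  }
  attr(out, "violations") <- violations
  out
}

#' Write a node or edge list
#'
#' Plain CSV writers matching the readers, so that
#' `read_edge_list(write_edge_list(edges, f))` is an identity.
#'
#' @param papers,edges Tibbles as returned by [read_node_list()] /
#'   [read_edge_list()] (or built by the synthetic generator).
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_node_list <- function(papers, file) {
  readr::write_csv(papers, file, progress = FALSE)
  invisible(papers)
}

#' @rdname write_node_list
#' @export
write_edge_list <- function(edges, file) {
  readr::write_csv(edges, file, progress = FALSE)
  invisible(edges)
}

#' Validate a citation corpus
#'
#' Checks a (papers, edges) pair against the structural rules of a citation
#' network: ids resolve, nobody cites themselves, and — because papers can
#' only cite previously published papers — no citation points forward in
#' time. Nothing is thrown; every problem is reported as a violation row so
#' a pipeline can decide what is fatal.
#'
#' Temporal rule: by default a citation to a paper of the *same* year is
#' allowed (publication lag makes same-year citation common); a citation to a
#' strictly later year is a violation. With `strict_years = TRUE` same-year
#' citations are violations too.
#'
#' @param papers Tibble of papers (see [read_node_list()]).
#' @param edges Tibble of citation records (see [read_edge_list()]).
#' @param strict_years Forbid same-year citations as well as future ones.
#' @param year_range Plausible calendar-year range; years outside it are
#'   flagged.
#' @return An object of class `corpus_validation`: a list with `n_papers`,
#'   `n_edges_raw`, `n_edges_deduplicated`, `violations` (tibble with
#'   columns `rule`, `ids`, `message`) and `is_valid`.
#' @export
validate_corpus <- function(papers, edges,
                            strict_years = FALSE,
                            year_range = c(1900L, 2100L)) {
  v <- list()

  dup <- unique(papers$id[duplicated(papers$id)])
  if (length(dup) > 0) {
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "duplicate_id", ids = dup,
      message = paste0("Paper id ", dup, " appears more than once")
    )
  }

  out_of_range <- !is.na(papers$year) &
    (papers$year < year_range[1] | papers$year > year_range[2])
  if (any(out_of_range)) {
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "year_range", ids = papers$id[out_of_range],
      message = paste0(
        "Paper ", papers$id[out_of_range], " has implausible year ",
        papers$year[out_of_range]
      )
    )
  }

  self <- edges$citing_id == edges$cited_id
  if (any(self)) {
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "self_citation", ids = edges$citing_id[self],
      message = paste0("Paper ", edges$citing_id[self], " cites itself")
    )
  }

  known <- papers$id
  dangling_citing <- !(edges$citing_id %in% known)
  dangling_cited <- !(edges$cited_id %in% known)
  if (any(dangling_citing)) {
    bad <- unique(edges$citing_id[dangling_citing])
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "dangling_endpoint", ids = bad,
      message = paste0("Citing id ", bad, " is not in the node list")
    )
  }
  if (any(dangling_cited)) {
    bad <- unique(edges$cited_id[dangling_cited])
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "dangling_endpoint", ids = bad,
      message = paste0("Cited id ", bad, " is not in the node list")
    )
  }

  year_of <- setNames(papers$year, papers$id)
  resolvable <- !dangling_citing & !dangling_cited & !self
  cy <- year_of[edges$citing_id[resolvable]]
  dy <- year_of[edges$cited_id[resolvable]]
  future <- !is.na(cy) & !is.na(dy) &
    (if (strict_years) dy >= cy else dy > cy)
  if (any(future)) {
    ci <- edges$citing_id[resolvable][future]
    di <- edges$cited_id[resolvable][future]
    v[[length(v) + 1L]] <- tibble::tibble(
      rule = "temporal", ids = ci,
      message = paste0(
        "Paper ", ci, " (", unname(cy[future]), ") cites ", di,
        " (", unname(dy[future]), "), which is not in its past"
      )
    )
  }

  violations <- if (length(v) > 0) {
    dplyr::bind_rows(v)
  } else {
    tibble::tibble(rule = character(), ids = character(), message = character())
  }

  structure(
    list(
      n_papers = nrow(papers),
      n_edges_raw = nrow(edges),
      n_edges_deduplicated = nrow(dplyr::distinct(edges, .data$citing_id, .data$cited_id)),
      violations = violations,
      is_valid = nrow(violations) == 0L
    ),
    class = "corpus_validation"
  )
}

#' @export
print.corpus_validation <- function(x, ...) {
  cat("Corpus validation:", x$n_papers, "papers,", x$n_edges_raw,
      "citation records (", x$n_edges_deduplicated, "unique )\n")
  if (x$is_valid) {
    cat("No violations.\n")
  } else {
    cat(nrow(x$violations), "violation(s):\n")
    counts <- table(x$violations$rule)
    for (r in names(counts)) cat("  -", r, ":", counts[[r]], "\n")
  }
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

resolve_col_map <- function(col_map, canonical) {
  cm <- setNames(canonical, canonical)
  if (length(col_map) > 0) {
    unknown <- setdiff(names(col_map), canonical)
    if (length(unknown) > 0) {
      abort_usage(paste0(
        "Unknown column mapping(s): ", paste(unknown, collapse = ", ")
      ))
    }
    cm[names(col_map)] <- unname(col_map)
  }
  cm
}

normalise_paper_type <- function(x) {
  lowered <- tolower(trimws(x))
  mapped <- dplyr::case_match(
    lowered,
    c("primary", "rct", "trial") ~ "primary",
    "review" ~ "review",
    .default = NA_character_
  )
  bad <- which(!is.na(x) & is.na(mapped))
  if (length(bad) > 0) {
    abort_corpus(paste0(
      "Unknown paper type ", shQuote(x[bad[1]]), " in row ", bad[1],
      " (expected primary/rct/trial or review)"
    ))
  }
  if (anyNA(mapped)) {
    abort_corpus(paste0("Missing paper type in row(s) ", id_phrase(which(is.na(mapped)))))
  }
  mapped
}

normalise_stance <- function(x, stance_set) {
  lowered <- tolower(trimws(x))
  idx <- match(lowered, tolower(stance_set))
  bad <- which(!is.na(x) & trimws(x) != "" & is.na(idx))
  if (length(bad) > 0) {
    abort_corpus(paste0(
      "Unknown classification ", shQuote(x[bad[1]]), " in row ", bad[1],
      " (stance set: ", paste(stance_set, collapse = ", "), ")"
    ))
  }
  stance_set[idx]
}
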