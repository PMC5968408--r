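#' Run the full claim-specific citation analysis
#'
#' One call binding the pipeline together: read (or accept) the node and
#' edge lists, validate, build the graph, and compute the whole-network and
#' per-stance metrics — bipartite densities, degree tables, citation-bias
#' flags, utilization histograms, the stance-by-trial contingency table and
#' its Pearson chi-square. Everything in the returned report is
#' recomputable from the inputs; nothing time- or machine-dependent enters
#' it, so serialising the same analysis twice gives byte-identical output.
#'
#' @param nodes A node-list file path or a papers tibble.
#' @param edges An edge-list file path or an edges tibble.
#' @param stance_set Stance labels accepted when reading from file.
#' @param strict_years Passed to [validate_corpus()].
#' @param alias_map Optional id-alias map passed to
#'   [build_citation_graph()].
#' @param strict If `TRUE`, any validation violation aborts the analysis.
#' @param seed Optional integer recorded in the provenance block (for
#'   corpora produced by the synthetic generator).
#' @return An object of class `citation_analysis`.
#' @export
#' @examples
#' corpus <- chd_diet_corpus(seed = 1)
#' report <- run_analysis(corpus$papers, corpus$edges, seed = 1)
#' report
run_analysis <- function(nodes, edges,
                         stance_set = default_stances(),
                         strict_years = FALSE,
                         alias_map = NULL,
                         strict = FALSE,
                         seed = NULL) {
  provenance <- list(package_version = as.character(utils::packageVersion("citenet")))
  if (is.character(nodes)) {
    provenance$node_file <- basename(nodes)
    provenance$node_md5 <- unname(tools::md5sum(nodes))
    nodes <- read_node_list(nodes, stance_set = stance_set)
  }
  if (is.character(edges)) {
    provenance$edge_file <- basename(edges)
    provenance$edge_md5 <- unname(tools::md5sum(edges))
    edges <- read_edge_list(edges)
  }
  if (!is.null(seed)) provenance$seed <- as.integer(seed)

  validation <- validate_corpus(nodes, edges, strict_years = strict_years)
  if (strict && !validation$is_valid) {
    abort_corpus(paste0(
      "Validation failed with ", nrow(validation$violations),
      " violation(s); first: ", validation$violations$message[1]
    ))
  }
  # non-strict: structurally unusable rows (self-loops, dangling endpoints)
  # are already on record in the validation block; drop them and carry on
  edges <- dplyr::filter(
    edges,
    .data$citing_id != .data$cited_id,
    .data$citing_id %in% nodes$id,
    .data$cited_id %in% nodes$id
  )

  graph <- build_citation_graph(nodes, edges, alias_map = alias_map)
  classes <- sort(unique(stats::na.omit(
    graph$papers$classification[graph$papers$paper_type == "review"]
  )))

  corpus_summary <- graph$papers |>
    dplyr::count(.data$paper_type, .data$classification, name = "n_papers")

  whole <- list(
    n = graph_order(graph),
    m = graph_size(graph),
    density = bipartite_density(graph, "all"),
    in_degrees = dplyr::left_join(
      in_degrees(graph),
      dplyr::select(graph$papers, "id", "paper_type", "classification"),
      by = "id"
    ),
    out_degrees = dplyr::left_join(
      out_degrees(graph),
      dplyr::select(graph$papers, "id", "paper_type", "classification"),
      by = "id"
    ),
    utilization = utilization_distribution(graph, "all"),
    bias_flags = citation_bias_flags(graph, "all"),
    citation_totals_by_primary_class = citation_totals_by_primary_class(graph)
  )

  per_class <- purrr::map(setNames(classes, classes), function(cls) {
    sub <- claim_subgraph(graph, cls)
    flags <- citation_bias_flags(graph, cls)
    list(
      n = graph_order(sub),
      m = graph_size(sub),
      density = bipartite_density(graph, cls),
      n_biased = sum(flags$is_biased),
      biased_toward = flags |>
        dplyr::filter(.data$is_biased) |>
        dplyr::count(.data$biased_toward, name = "n_reviews"),
      utilization = utilization_distribution(graph, cls)
    )
  })

  contingency <- NULL
  chi_square <- NULL
  if (length(classes) >= 2) {
    contingency <- contingency_table(graph)
    chi_square <- tryCatch(
      pearson_chi_square(contingency),
      citenet_degenerate_table_error = function(e) NULL
    )
  }

  structure(
    list(
      corpus_summary = corpus_summary,
      validation = validation,
      whole_network = whole,
      per_class = per_class,
      contingency = contingency,
      chi_square = chi_square,
      provenance = provenance
    ),
    class = "citation_analysis"
  )
}

#' @export
print.citation_analysis <- function(x, ...) {
  w <- x$whole_network
  cat("Claim-specific citation analysis\n")
  cat("  Corpus: n =", w$n, ", review-to-primary m =", w$density$edges,
      "( total edges", w$m, ")\n")
  cat(sprintf("  Density D = %.2f over %d reviews x %d primaries\n",
              w$density$density, w$density$n_reviews, w$density$n_primaries))
  for (cls in names(x$per_class)) {
    b <- x$per_class[[cls]]
    cat(sprintf(
      "  %-13s n = %2d, m = %2d, D = %.2f, biased reviews = %d\n",
      paste0(cls, ":"), b$n, b$m, b$density$density, b$n_biased
    ))
  }
  if (!is.null(x$chi_square)) print(x$chi_square)
  invisible(x)
}

#' Serialise an analysis report
#'
#' `write_analysis_report()` writes the full report as JSON with a stable
#' key order and no timestamps, so identical inputs give byte-identical
#' files. `write_analysis_tables()` writes the tabular pieces as CSV files
#' into a directory; the contingency CSV uses the familiar published
#' layout — stance classes as rows, primary studies as columns, with row
#' and column totals.
#'
#' @param report A `citation_analysis`.
#' @param file,dir Output path / directory.
#' @return The path, invisibly.
#' @export
write_analysis_report <- function(report, file) {
  stopifnot(inherits(report, "citation_analysis"))
  jsonlite::write_json(
    report_as_list(report), file,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(file)
}

#' @rdname write_analysis_report
#' @export
write_analysis_tables <- function(report, dir) {
  stopifnot(inherits(report, "citation_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- report$whole_network
  densities <- dplyr::bind_rows(c(
    list(w$density),
    unname(purrr::map(report$per_class, function(b) b$density))
  ))
  readr::write_csv(densities, file.path(dir, "density.csv"), progress = FALSE)
  readr::write_csv(flatten_flags(w$bias_flags),
                   file.path(dir, "bias_flags.csv"), progress = FALSE)
  utilization <- dplyr::bind_rows(c(
    list(w$utilization),
    unname(purrr::map(report$per_class, function(b) b$utilization))
  ))
  readr::write_csv(utilization, file.path(dir, "utilization.csv"),
                   progress = FALSE)
  if (!is.null(report$contingency)) {
    m <- unclass(report$contingency)
    attr(m, "class") <- NULL
    tab <- cbind(m, row_total = rowSums(m))
    tab <- rbind(tab, column_total = colSums(tab))
    df <- tibble::as_tibble(tab, rownames = "review_class")
    readr::write_csv(df, file.path(dir, "contingency.csv"), progress = FALSE)
  }
  invisible(dir)
}

# ---- internal ---------------------------------------------------------------

flatten_flags <- function(flags) {
  flags$cited_classes <- vapply(
    flags$cited_classes, paste, character(1), collapse = ";"
  )
  flags
}

report_as_list <- function(report) {
  w <- report$whole_network
  out <- list(
    corpus_summary = as.data.frame(report$corpus_summary),
    validation = list(
      n_papers = report$validation$n_papers,
      n_edges_raw = report$validation$n_edges_raw,
      n_edges_deduplicated = report$validation$n_edges_deduplicated,
      is_valid = report$validation$is_valid,
      violations = as.data.frame(report$validation$violations)
    ),
    whole_network = list(
      n = w$n,
      m = w$m,
      density = as.data.frame(w$density),
      in_degrees = as.data.frame(w$in_degrees),
      out_degrees = as.data.frame(w$out_degrees),
      utilization = as.data.frame(w$utilization),
      bias_flags = as.data.frame(flatten_flags(w$bias_flags)),
      citation_totals_by_primary_class =
        as.data.frame(w$citation_totals_by_primary_class)
    ),
    per_class = purrr::map(report$per_class, function(b) {
      list(
        n = b$n, m = b$m,
        density = as.data.frame(b$density),
        n_biased = b$n_biased,
        biased_toward = as.data.frame(b$biased_toward),
        utilization = as.data.frame(b$utilization)
      )
    }),
    provenance = report$provenance
  )
  if (!is.null(report$contingency)) {
    m <- unclass(report$contingency)
    attr(m, "class") <- NULL
    out$contingency <- list(
      review_classes = rownames(m),
      primaries = colnames(m),
      observed = m,
      row_totals = unname(rowSums(m)),
      column_totals = unname(colSums(m)),
      n = sum(m)
    )
  }
  if (!is.null(report$chi_square)) {
    cs <- report$chi_square
    out$chi_square <- list(
      statistic = cs$statistic,
      df = cs$df,
      p_value = cs$p_value,
      conditions_met = cs$validity$conditions_met,
      fraction_expected_gt5 = cs$validity$fraction_expected_gt5,
      min_expected = cs$validity$min_expected
    )
  }
  out
}
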