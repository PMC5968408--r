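#' Build a directed binary-adjacency citation graph
#'
#' Turns a validated (papers, edges) pair into a `citation_graph`: a directed
#' graph over papers whose adjacency is binary — a citing paper referencing
#' the same cited work several times still contributes a single edge, so the
#' edge count `m` is the number of distinct (citing, cited) pairs. Vertex
#' order is fixed by sorted id so adjacency matrices and exports are
#' bit-for-bit reproducible.
#'
#' An optional alias map collapses several ids into one vertex before the
#' graph is built. This supports corpora where one study was published in
#' several papers that the analysis treats as a single primary source:
#' citations to any alias become citations to the canonical id, and parallel
#' edges created by the collapse merge into one.
#'
#' @param papers Tibble of papers (see [read_node_list()]).
#' @param edges Tibble of citation records (see [read_edge_list()]).
#' @param alias_map Optional. Either a named character vector
#'   (`c(alias = "canonical", ...)`) or a two-column data frame with columns
#'   `alias` and `canonical`.
#' @return An object of class `citation_graph`: a list with `papers` (tibble
#'   sorted by id), `edges` (deduplicated tibble of citing_id/cited_id), and
#'   `stance_set` (labels seen in the corpus).
#' @export
#' @examples
#' corpus <- generate_corpus(synthetic_config(seed = 1))
#' g <- build_citation_graph(corpus$papers, corpus$edges)
#' g
build_citation_graph <- function(papers, edges, alias_map = NULL) {
  if (!is.null(alias_map)) {
    map <- as_alias_map(alias_map)
    papers <- papers |>
      dplyr::mutate(id = remap_ids(.data$id, map)) |>
      dplyr::distinct(.data$id, .keep_all = TRUE)
    edges <- edges |>
      dplyr::mutate(
        citing_id = remap_ids(.data$citing_id, map),
        cited_id = remap_ids(.data$cited_id, map)
      ) |>
      dplyr::filter(.data$citing_id != .data$cited_id)
  }

  dangling <- unique(c(
    setdiff(edges$citing_id, papers$id),
    setdiff(edges$cited_id, papers$id)
  ))
  if (length(dangling) > 0) {
    abort_corpus(paste0(
      "Edge endpoint(s) not present in the node list: ", id_phrase(dangling)
    ))
  }
  if (any(edges$citing_id == edges$cited_id)) {
    abort_corpus(paste0(
      "Self-citation(s) in the edge list: ",
      id_phrase(edges$citing_id[edges$citing_id == edges$cited_id])
    ))
  }

  papers <- dplyr::arrange(tibble::as_tibble(papers), .data$id)
  edges <- edges |>
    dplyr::distinct(.data$citing_id, .data$cited_id) |>
    dplyr::arrange(.data$citing_id, .data$cited_id)

  structure(
    list(
      papers = papers,
      edges = edges,
      stance_set = sort(unique(stats::na.omit(papers$classification)))
    ),
    class = "citation_graph"
  )
}

#' @export
print.citation_graph <- function(x, ...) {
  n_primary <- sum(x$papers$paper_type == "primary")
  n_review <- sum(x$papers$paper_type == "review")
  cat("Citation graph: n =", nrow(x$papers), "( primaries:", n_primary,
      ", reviews:", n_review, "), m =", nrow(x$edges), "\n")
  if (n_review > 0) {
    cls <- table(x$papers$classification[x$papers$paper_type == "review"])
    cat("Review stances:",
        paste(names(cls), cls, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of vertices / edges of a citation graph
#'
#' @param graph A `citation_graph`.
#' @return Integer count.
#' @export
graph_order <- function(graph) nrow(graph$papers)

#' @rdname graph_order
#' @export
graph_size <- function(graph) nrow(graph$edges)

#' Binary adjacency matrix of a citation graph
#'
#' Returns the full 0/1 adjacency matrix `G` with `G[i, j] = 1` when paper
#' `i` cites paper `j`, rows and columns ordered by sorted id. Intended for
#' small claim-specific networks; the rest of the package works from the
#' edge list directly.
#'
#' @param graph A `citation_graph`.
#' @return An integer matrix with dimnames set to paper ids.
#' @export
citation_adjacency <- function(graph) {
  ids <- graph$papers$id
  adj <- matrix(0L, nrow = length(ids), ncol = length(ids),
                dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0) {
    adj[cbind(graph$edges$citing_id, graph$edges$cited_id)] <- 1L
  }
  adj
}

#' Degree centralities
#'
#' In-degree counts incoming citations (how often a paper is cited within
#' the corpus, the column sums of the adjacency matrix); out-degree counts
#' outgoing citations (how many distinct papers a paper cites, the row
#' sums). Both are computed on whatever edge set the graph carries; restrict
#' to review-to-primary edges first (e.g. via [claim_subgraph()]) when that
#' is the quantity of interest.
#'
#' @param graph A `citation_graph`.
#' @return A tibble with columns `id` and `in_degree` (or `out_degree`),
#'   one row per vertex, ordered by id.
#' @export
#' @examples
#' g <- chd_diet_corpus(seed = 1) |>
#'   (\(x) build_citation_graph(x$papers, x$edges))()
#' in_degrees(g) |> dplyr::arrange(dplyr::desc(in_degree)) |> head(4)
in_degrees <- function(graph) {
  counts <- table(factor(graph$edges$cited_id, levels = graph$papers$id))
  tibble::tibble(id = graph$papers$id, in_degree = as.integer(counts))
}

#' @rdname in_degrees
#' @export
out_degrees <- function(graph) {
  counts <- table(factor(graph$edges$citing_id, levels = graph$papers$id))
  tibble::tibble(id = graph$papers$id, out_degree = as.integer(counts))
}

#' Extract a stance-restricted claim sub-graph
#'
#' The sub-graph used for per-stance bias analysis: it retains *all* primary
#' studies (cited or not by this class — uncited primaries are exactly the
#' underutilisation signal) plus the reviews of one stance class, and keeps
#' only the review-to-primary citation edges among the retained vertices.
#'
#' @param graph A `citation_graph`.
#' @param review_class A stance label present in the graph's stance set.
#' @return A `citation_graph`.
#' @export
claim_subgraph <- function(graph, review_class) {
  if (!is.character(review_class) || length(review_class) != 1L ||
      !(review_class %in% graph$stance_set)) {
    abort_usage(paste0(
      "review_class must be one of: ",
      paste(graph$stance_set, collapse = ", ")
    ))
  }
  keep <- graph$papers$paper_type == "primary" |
    (graph$papers$paper_type == "review" &
       !is.na(graph$papers$classification) &
       graph$papers$classification == review_class)
  papers <- graph$papers[keep, ]
  review_ids <- papers$id[papers$paper_type == "review"]
  primary_ids <- papers$id[papers$paper_type == "primary"]
  edges <- dplyr::filter(
    graph$edges,
    .data$citing_id %in% review_ids, .data$cited_id %in% primary_ids
  )
  structure(
    list(papers = papers, edges = edges, stance_set = graph$stance_set),
    class = "citation_graph"
  )
}

# Reviews in scope for a per-class computation; "all" means every review.
scope_reviews <- function(graph, review_class) {
  reviews <- dplyr::filter(graph$papers, .data$paper_type == "review")
  if (identical(review_class, "all")) {
    return(reviews)
  }
  if (!is.character(review_class) || length(review_class) != 1L ||
      !(review_class %in% graph$stance_set)) {
    abort_usage(paste0(
      "review_class must be \"all\" or one of: ",
      paste(graph$stance_set, collapse = ", ")
    ))
  }
  dplyr::filter(reviews, .data$classification == review_class)
}

# Review-to-primary edges only, optionally restricted to one review class.
review_primary_edges <- function(graph, review_class = "all") {
  reviews <- scope_reviews(graph, review_class)
  primaries <- dplyr::filter(graph$papers, .data$paper_type == "primary")
  dplyr::filter(
    graph$edges,
    .data$citing_id %in% reviews$id, .data$cited_id %in% primaries$id
  )
}

# ---- internal ---------------------------------------------------------------

as_alias_map <- function(alias_map) {
  if (is.data.frame(alias_map)) {
    if (!all(c("alias", "canonical") %in% names(alias_map))) {
      abort_usage("alias_map data frame needs columns `alias` and `canonical`")
    }
    return(setNames(as.character(alias_map$canonical),
                    as.character(alias_map$alias)))
  }
  if (is.character(alias_map) && !is.null(names(alias_map))) {
    return(alias_map)
  }
  abort_usage("alias_map must be a named character vector or an alias/canonical data frame")
}

remap_ids <- function(ids, map) {
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  ids
}
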