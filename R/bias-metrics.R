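#' Bipartite utilisation density
#'
#' The claim-specific density `D = E / (|S| x |P|)`: the number of
#' review-to-primary citations actually made, as a proportion of the maximum
#' possible were every review in scope to cite every primary study. `D = 1`
#' means the evidence base is fully utilised by that set of reviews; low `D`
#' means underutilisation. Only review-to-primary edges enter the numerator,
#' whatever other edges the graph carries; `P` is always the full set of
#' primary studies, so densities of different review classes are directly
#' comparable.
#'
#' @param graph A `citation_graph`.
#' @param review_class `"all"` for every review, a stance label for one
#'   class, or a character vector of scopes to compute several at once.
#' @return A tibble of class `density_result` with one row per scope:
#'   `scope`, `edges`, `n_reviews`, `n_primaries`, `density`. `density` is
#'   the exact ratio; round for display.
#' @export
#' @examples
#' corpus <- chd_diet_corpus(seed = 1)
#' g <- build_citation_graph(corpus$papers, corpus$edges)
#' bipartite_density(g, c("all", "neutral", "unsupportive", "supportive"))
bipartite_density <- function(graph, review_class = "all") {
  rows <- purrr::map(review_class, function(scope) {
    reviews <- scope_reviews(graph, scope)
    n_primaries <- sum(graph$papers$paper_type == "primary")
    if (nrow(reviews) == 0L || n_primaries == 0L) {
      abort_usage(paste0(
        "Density is undefined for scope ", shQuote(scope),
        ": it needs at least one review in scope and one primary study"
      ))
    }
    e <- nrow(review_primary_edges(graph, scope))
    tibble::tibble(
      scope = scope,
      edges = e,
      n_reviews = nrow(reviews),
      n_primaries = n_primaries,
      density = e / (nrow(reviews) * n_primaries)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("density_result", class(out))
  out
}

#' Per-review citation-bias flags
#'
#' A review displays citation bias when every primary study it cites shares
#' one stance label — it presents only one side of the evidence. The flag
#' depends solely on the stances of the *cited* primaries; the review's own
#' stance does not enter (an unsupportive review citing only the supportive
#' trial is just as biased, toward `supportive`).
#'
#' Reviews in scope that cite no primary study at all are reported with
#' `n_primaries_cited = 0` and `is_biased = FALSE`, and a warning is issued:
#' such rows usually indicate the corpus inclusion rule (every review cites
#' at least one primary) was not applied upstream.
#'
#' @param graph A `citation_graph`.
#' @param review_class `"all"` or a stance label.
#' @return A tibble with one row per review in scope: `review_id`,
#'   `review_class`, `n_primaries_cited`, `cited_classes` (list column of
#'   the distinct stance labels among cited primaries), `is_biased`,
#'   `biased_toward` (`NA` unless biased).
#' @export
citation_bias_flags <- function(graph, review_class = "all") {
  reviews <- scope_reviews(graph, review_class)
  primaries <- dplyr::filter(graph$papers, .data$paper_type == "primary")
  stance_of <- setNames(primaries$classification, primaries$id)
  edges <- review_primary_edges(graph, review_class)
  cited_by <- split(edges$cited_id, factor(edges$citing_id, levels = reviews$id))

  out <- tibble::tibble(
    review_id = reviews$id,
    review_class = reviews$classification,
    n_primaries_cited = unname(lengths(cited_by[reviews$id])),
    cited_classes = unname(purrr::map(cited_by[reviews$id], function(p) {
      sort(unique(unname(stance_of[p])))
    }))
  )
  out$is_biased <- out$n_primaries_cited >= 1L &
    purrr::map_int(out$cited_classes, length) == 1L &
    !purrr::map_lgl(out$cited_classes, anyNA)
  out$biased_toward <- ifelse(
    out$is_biased, purrr::map_chr(out$cited_classes, 1, .default = NA), NA_character_
  )
  if (any(out$n_primaries_cited == 0L)) {
    warn(paste0(
      "Review(s) citing no primary study: ",
      id_phrase(out$review_id[out$n_primaries_cited == 0L])
    ))
  }
  out
}

#' Research-utilization distribution
#'
#' The histogram of how many distinct primary studies each review in scope
#' cites: the out-degree distribution of reviews restricted to
#' review-to-primary edges. Reviews citing fewer than the full set of
#' primaries underutilise the evidence base; the histogram quantifies how
#' widespread that is.
#'
#' @param graph A `citation_graph`.
#' @param review_class `"all"` or a stance label (vectorised like
#'   [bipartite_density()]).
#' @return A tibble of class `utilization_distribution` with columns
#'   `scope`, `k` (number of distinct primaries cited) and `n_reviews`.
#'   Counts sum to the number of reviews in scope; `sum(k * n_reviews)` is
#'   the number of review-to-primary edges in scope.
#' @export
utilization_distribution <- function(graph, review_class = "all") {
  rows <- purrr::map(review_class, function(scope) {
    reviews <- scope_reviews(graph, scope)
    edges <- review_primary_edges(graph, scope)
    k <- as.integer(table(factor(edges$citing_id, levels = reviews$id)))
    hist <- table(k)
    tibble::tibble(
      scope = scope,
      k = as.integer(names(hist)),
      n_reviews = as.integer(hist)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("utilization_distribution", class(out))
  out
}

#' Stance-by-trial contingency table of citations
#'
#' Cross-tabulates review-to-primary citations: cell (c, p) is the number of
#' reviews of stance class c that cite primary study p (with binary
#' adjacency this equals the citation count). Row totals give each class's
#' total utilisation; column totals give each primary study's in-degree from
#' reviews.
#'
#' @param graph A `citation_graph`.
#' @return A `citation_contingency` object: an integer matrix with review
#'   classes as rows and primary ids as columns.
#' @export
#' @examples
#' corpus <- chd_diet_corpus(seed = 1)
#' g <- build_citation_graph(corpus$papers, corpus$edges)
#' contingency_table(g)
contingency_table <- function(graph) {
  reviews <- dplyr::filter(graph$papers, .data$paper_type == "review")
  primaries <- dplyr::filter(graph$papers, .data$paper_type == "primary")
  edges <- review_primary_edges(graph)
  class_of <- setNames(reviews$classification, reviews$id)
  classes <- sort(unique(stats::na.omit(reviews$classification)))
  obs <- table(
    factor(unname(class_of[edges$citing_id]), levels = classes),
    factor(edges$cited_id, levels = primaries$id)
  )
  m <- matrix(as.integer(obs), nrow = length(classes),
              dimnames = list(class = classes, primary = primaries$id))
  as_contingency(m)
}

#' Coerce to a citation contingency table
#'
#' Accepts an integer matrix or data frame of citation counts (review
#' classes as rows, primary studies as columns) — e.g. a published table
#' typed in directly — and returns a `citation_contingency`.
#'
#' @param x Matrix or data frame of non-negative integer counts with row and
#'   column names.
#' @return A `citation_contingency` object.
#' @export
as_contingency <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_usage("A contingency table must be a numeric matrix or data frame")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort_usage("Contingency cells must be non-negative integers")
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("citation_contingency", "matrix", "array"))
}

#' @export
print.citation_contingency <- function(x, ...) {
  m <- unclass(x)
  disp <- cbind(m, total = rowSums(m))
  disp <- rbind(disp, total = colSums(disp))
  cat("Citation contingency table (review class x primary study):\n")
  print(disp)
  invisible(x)
}

#' Citation totals grouped by the cited primaries' stance
#'
#' Sums review-to-primary citation counts over the stance labels of the
#' *cited* primary studies: how often supportive vs unsupportive evidence is
#' cited overall, regardless of who cites it.
#'
#' @param graph A `citation_graph`.
#' @return A tibble with columns `classification` and `citations`; zero rows
#'   on a graph without review-to-primary edges.
#' @export
citation_totals_by_primary_class <- function(graph) {
  primaries <- dplyr::filter(graph$papers, .data$paper_type == "primary")
  edges <- review_primary_edges(graph)
  if (nrow(edges) == 0L) {
    return(tibble::tibble(classification = character(), citations = integer()))
  }
  stance_of <- setNames(primaries$classification, primaries$id)
  tibble::tibble(classification = unname(stance_of[edges$cited_id])) |>
    dplyr::count(.data$classification, name = "citations") |>
    dplyr::arrange(.data$classification)
}
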