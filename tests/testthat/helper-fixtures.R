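# Fixtures are built in code; nothing is read from disk except temp files the
# tests themselves write.

# A hand-sized corpus: 2 primaries (1 supportive, 1 unsupportive), 3 reviews.
tiny_corpus <- function() {
  papers <- tibble::tibble(
    id = c("P1", "P2", "R1", "R2", "R3"),
    paper_type = c("primary", "primary", "review", "review", "review"),
    classification = c("supportive", "unsupportive",
                       "supportive", "neutral", "unsupportive"),
    year = c(1966L, 1968L, 1970L, 1975L, 1980L),
    label = c("P1", "P2", "R1", "R2", "R3")
  )
  edges <- tibble::tibble(
    citing_id = c("R1", "R2", "R2", "R3"),
    cited_id = c("P1", "P1", "P2", "P2")
  )
  list(papers = papers, edges = edges)
}

tiny_graph <- function() {
  corpus <- tiny_corpus()
  build_citation_graph(corpus$papers, corpus$edges)
}

study_graph <- function(seed = 1) {
  corpus <- chd_diet_corpus(seed = seed)
  build_citation_graph(corpus$papers, corpus$edges)
}

random_graph <- function(seed, n_reviews = 10L, pi = 0.4) {
  cfg <- synthetic_config(
    primaries_per_class = c(supportive = 2L, unsupportive = 2L),
    reviews_per_class = c(supportive = n_reviews, neutral = n_reviews,
                          unsupportive = n_reviews),
    citation_prob = matrix(pi, 3, 2, dimnames = list(
      c("supportive", "neutral", "unsupportive"),
      c("supportive", "unsupportive")
    )),
    min_citations_per_review = 1L,
    seed = seed
  )
  corpus <- generate_corpus(cfg)
  build_citation_graph(corpus$papers, corpus$edges)
}

# Independent degree oracle: count straight off the edge list.
brute_force_degrees <- function(graph) {
  ids <- graph$papers$id
  tibble::tibble(
    id = ids,
    in_degree = vapply(ids, function(i) sum(graph$edges$cited_id == i),
                       integer(1), USE.NAMES = FALSE),
    out_degree = vapply(ids, function(i) sum(graph$edges$citing_id == i),
                        integer(1), USE.NAMES = FALSE)
  )
}

write_temp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
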