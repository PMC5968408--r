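test_that("density is the exact review-primary ratio and maxes at 1", {
  # complete bipartite toy graph: 3 reviews each citing both of 2 primaries
  papers <- tibble::tibble(
    id = c("P1", "P2", "R1", "R2", "R3"),
    paper_type = c("primary", "primary", "review", "review", "review"),
    classification = c("supportive", "unsupportive", rep("neutral", 3)),
    year = c(1966L, 1967L, 1970L, 1971L, 1972L),
    label = id
  )
  edges <- tidyr::expand_grid(citing_id = c("R1", "R2", "R3"),
                              cited_id = c("P1", "P2"))
  g <- build_citation_graph(papers, edges)
  d <- bipartite_density(g)
  expect_equal(d$density, 1)
  expect_equal(d$edges, 6L)
  expect_equal(d$n_reviews * d$n_primaries, 6L)

  # tiny graph: 4 edges over 3 reviews x 2 primaries
  d2 <- bipartite_density(tiny_graph())
  expect_equal(d2$density, 4 / 6)

  # empty scope is an error, not a division by zero
  expect_error(bipartite_density(g, "supportive"), class = "citenet_usage_error")
})

test_that("density is monotone non-decreasing as review-primary edges are added", {
  corpus <- tiny_corpus()
  base <- build_citation_graph(corpus$papers, corpus$edges)
  d0 <- bipartite_density(base)$density
  # add the two missing review->primary edges one at a time
  extra <- tibble::tibble(citing_id = c("R1", "R3"), cited_id = c("P2", "P1"))
  prev <- d0
  for (i in 1:2) {
    g <- build_citation_graph(
      corpus$papers, dplyr::bind_rows(corpus$edges, extra[seq_len(i), ])
    )
    d <- bipartite_density(g)$density
    expect_gte(d, prev)
    prev <- d
  }
  expect_equal(prev, 1)
})

test_that("bias flags depend only on the stances of the cited primaries", {
  g <- tiny_graph()
  flags <- citation_bias_flags(g)
  flags <- flags[order(flags$review_id), ]
  # R1 cites only the supportive primary, R3 only the unsupportive one,
  # R2 cites one of each and is therefore unbiased
  expect_equal(flags$is_biased, c(TRUE, FALSE, TRUE))
  expect_equal(flags$biased_toward, c("supportive", NA, "unsupportive"))
  expect_equal(flags$n_primaries_cited, c(1L, 2L, 1L))

  # scoping by review class keeps only that class's reviews
  sup <- citation_bias_flags(g, "supportive")
  expect_equal(sup$review_id, "R1")
})

test_that("reviews citing no primary are reported, not fatal", {
  corpus <- tiny_corpus()
  papers <- dplyr::bind_rows(
    corpus$papers,
    tibble::tibble(id = "R9", paper_type = "review", classification = "neutral",
                   year = 1980L, label = "R9")
  )
  g <- build_citation_graph(papers, corpus$edges)
  expect_warning(flags <- citation_bias_flags(g), "R9")
  r9 <- flags[flags$review_id == "R9", ]
  expect_equal(r9$n_primaries_cited, 0L)
  expect_false(r9$is_biased)
})

test_that("single-citers are always biased", {
  for (seed in c(21, 22)) {
    g <- random_graph(seed)
    flags <- citation_bias_flags(g)
    expect_true(all(flags$is_biased[flags$n_primaries_cited == 1L]))
    expect_gte(sum(flags$is_biased), sum(flags$n_primaries_cited == 1L))
  }
})

test_that("utilization histogram counts reviews by distinct primaries cited", {
  # single review citing all P primaries -> {P: 1}
  papers <- tibble::tibble(
    id = c("P1", "P2", "P3", "R1"),
    paper_type = c(rep("primary", 3), "review"),
    classification = c("supportive", "unsupportive", "unsupportive", "neutral"),
    year = c(1965L, 1966L, 1967L, 1970L), label = id
  )
  edges <- tibble::tibble(citing_id = "R1", cited_id = c("P1", "P2", "P3"))
  u <- utilization_distribution(build_citation_graph(papers, edges))
  expect_equal(u$k, 3L)
  expect_equal(u$n_reviews, 1L)
})

test_that("density, utilization, and contingency agree on the edge count", {
  # three independent computations of E for every scope
  for (seed in c(31, 32, 33)) {
    g <- random_graph(seed)
    tab <- contingency_table(g)
    for (scope in c("all", g$stance_set)) {
      d <- bipartite_density(g, scope)
      u <- utilization_distribution(g, scope)
      expect_equal(sum(u$k * u$n_reviews), d$edges)
      expect_equal(sum(u$n_reviews), d$n_reviews)
      row_e <- if (scope == "all") sum(tab) else sum(tab[scope, ])
      expect_equal(row_e, d$edges)
    }
  }
})

test_that("contingency cells are bounded by the row class's review count", {
  for (seed in c(41, 42)) {
    g <- random_graph(seed)
    tab <- contingency_table(g)
    reviews <- g$papers[g$papers$paper_type == "review", ]
    class_sizes <- table(reviews$classification)
    expect_true(all(tab <= as.integer(class_sizes[rownames(tab)])))
  }
})

test_that("one review citing one primary yields a 1x1 table with N = 1", {
  papers <- tibble::tibble(
    id = c("P1", "R1"), paper_type = c("primary", "review"),
    classification = c("supportive", "neutral"),
    year = c(1966L, 1970L), label = id
  )
  g <- build_citation_graph(
    papers, tibble::tibble(citing_id = "R1", cited_id = "P1")
  )
  tab <- contingency_table(g)
  expect_equal(dim(tab), c(1L, 1L))
  expect_equal(sum(tab), 1L)
})

test_that("citation totals by primary class match a brute-force edge sum", {
  for (seed in c(51, 52)) {
    g <- random_graph(seed)
    totals <- citation_totals_by_primary_class(g)
    primaries <- g$papers[g$papers$paper_type == "primary", ]
    oracle <- vapply(sort(unique(primaries$classification)), function(cls) {
      sum(g$edges$cited_id %in% primaries$id[primaries$classification == cls])
    }, integer(1))
    expect_equal(setNames(totals$citations, totals$classification), oracle)
  }
  # empty graph -> empty map
  empty <- build_citation_graph(
    tibble::tibble(id = "P1", paper_type = "primary",
                   classification = "supportive", year = 1966L, label = "P1"),
    tibble::tibble(citing_id = character(), cited_id = character())
  )
  expect_equal(nrow(citation_totals_by_primary_class(empty)), 0L)
})
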