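test_that("node list reading normalises labels, preserves extras, and round-trips", {
  f <- write_temp_csv(c(
    "id,paper_type,classification,year,label,journal",
    "P1,rct,Supportive,1966,Oslo trial,Circulation",
    "R1,review,NEUTRAL,1970,Some review,Lancet",
    "R2,review,unsupportive,1979,Another,BMJ"
  ))
  papers <- read_node_list(f)
  expect_equal(papers$paper_type, c("primary", "review", "review"))
  expect_equal(papers$classification, c("supportive", "neutral", "unsupportive"))
  expect_equal(papers$year, c(1966L, 1970L, 1979L))
  expect_equal(papers$journal, c("Circulation", "Lancet", "BMJ"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_node_list(papers, out)
  expect_equal(read_node_list(out), papers)
})

test_that("node list corpus errors name the offending row or id", {
  dup <- write_temp_csv(c(
    "id,paper_type,classification,year",
    "P1,primary,supportive,1966",
    "P1,primary,supportive,1966"
  ))
  expect_error(read_node_list(dup), "P1", class = "citenet_corpus_error")

  badyear <- write_temp_csv(c(
    "id,paper_type,classification,year",
    "P1,primary,supportive,about 1966"
  ))
  expect_error(read_node_list(badyear), "row 1", class = "citenet_corpus_error")

  badstance <- write_temp_csv(c(
    "id,paper_type,classification,year",
    "P1,primary,enthusiastic,1966"
  ))
  expect_error(read_node_list(badstance), "enthusiastic",
               class = "citenet_corpus_error")

  unclassified <- write_temp_csv(c(
    "id,paper_type,classification,year",
    "P1,primary,,1966"
  ))
  expect_error(read_node_list(unclassified), "P1",
               class = "citenet_corpus_error")

  nocol <- write_temp_csv(c("id,year", "P1,1966"))
  expect_error(read_node_list(nocol), class = "citenet_format_error")
})

test_that("empty node list with header only gives an empty corpus", {
  f <- write_temp_csv("id,paper_type,classification,year,label")
  papers <- read_node_list(f)
  expect_equal(nrow(papers), 0L)
})

test_that("custom column names are honoured via col_map", {
  f <- write_temp_csv(c(
    "vertex,kind,stance,published",
    "P1,primary,supportive,1966"
  ))
  papers <- read_node_list(f, col_map = c(
    id = "vertex", paper_type = "kind", classification = "stance",
    year = "published"
  ))
  expect_equal(papers$id, "P1")
  expect_equal(papers$label, "P1")
})

test_that("edge list reading preserves order, keeps duplicates, drops self-loops", {
  f <- write_temp_csv(c(
    "citing_id,cited_id", "R2,P1", "R1,P1", "R1,P1", "A,A"
  ))
  expect_warning(edges <- read_edge_list(f), "self-citation")
  expect_equal(edges$citing_id, c("R2", "R1", "R1"))
  viol <- attr(edges, "violations")
  expect_equal(viol$rule, "self_citation")
  expect_match(viol$message, "A")

  out <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(edges, out)
  expect_equal(read_edge_list(out)$cited_id, edges$cited_id)

  expect_error(
    read_edge_list(write_temp_csv(c("from,to", "a,b"))),
    class = "citenet_format_error"
  )
})

test_that("validate_corpus reports dangling, temporal, and range violations", {
  corpus <- tiny_corpus()
  v <- validate_corpus(corpus$papers, corpus$edges)
  expect_true(v$is_valid)
  expect_equal(v$n_papers, 5L)
  expect_equal(v$n_edges_raw, 4L)
  expect_equal(v$n_edges_deduplicated, 4L)

  bad_edges <- dplyr::bind_rows(
    corpus$edges,
    tibble::tibble(citing_id = c("R1", "GHOST"), cited_id = c("R1", "P1"))
  )
  bad_papers <- corpus$papers
  bad_papers$year[bad_papers$id == "P2"] <- 2150L  # out of range, and future
  v2 <- validate_corpus(bad_papers, bad_edges)
  expect_false(v2$is_valid)
  expect_setequal(unique(v2$violations$rule),
                  c("self_citation", "dangling_endpoint", "year_range",
                    "temporal"))
  # every violation names at least one offending id
  expect_true(all(nzchar(v2$violations$ids)))
  expect_true(all(mapply(grepl, v2$violations$ids, v2$violations$message,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("a review may cite an older trial but a trial cannot cite the future", {
  papers <- tibble::tibble(
    id = c("T", "R"), paper_type = c("primary", "review"),
    classification = c("unsupportive", "neutral"),
    year = c(1966L, 1984L), label = c("T", "R")
  )
  ok <- validate_corpus(papers, tibble::tibble(citing_id = "R", cited_id = "T"))
  expect_true(ok$is_valid)
  bad <- validate_corpus(papers, tibble::tibble(citing_id = "T", cited_id = "R"))
  expect_equal(bad$violations$rule, "temporal")
})

test_that("same-year citation is legal by default and illegal in strict mode", {
  papers <- tibble::tibble(
    id = c("A", "B"), paper_type = c("review", "review"),
    classification = c("neutral", "neutral"),
    year = c(1969L, 1969L), label = c("A", "B")
  )
  edges <- tibble::tibble(citing_id = c("A", "B"), cited_id = c("B", "A"))
  expect_true(validate_corpus(papers, edges)$is_valid)
  strict <- validate_corpus(papers, edges, strict_years = TRUE)
  expect_equal(nrow(strict$violations), 2L)
  expect_true(all(strict$violations$rule == "temporal"))
})

test_that("validate_corpus is pure: repeated calls give identical reports", {
  corpus <- tiny_corpus()
  v1 <- validate_corpus(corpus$papers, corpus$edges)
  v2 <- validate_corpus(corpus$papers, corpus$edges)
  expect_identical(v1, v2)
})

test_that("validation tidiers expose violations and headline counts", {
  corpus <- tiny_corpus()
  v <- validate_corpus(corpus$papers, corpus$edges)
  expect_equal(nrow(tidy(v)), 0L)
  g <- glance(v)
  expect_equal(g$n_papers, 5L)
  expect_true(g$is_valid)
})
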