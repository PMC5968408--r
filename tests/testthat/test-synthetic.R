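test_that("generation is bit-identical for equal seeds and differs across seeds", {
  cfg <- synthetic_config(seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  cfg2 <- synthetic_config(seed = 6)
  expect_false(identical(generate_corpus(cfg2), a))
})

test_that("every generated corpus validates cleanly", {
  for (seed in c(201, 202, 203, 204, 205)) {
    corpus <- generate_corpus(synthetic_config(seed = seed))
    v <- validate_corpus(corpus$papers, corpus$edges)
    expect_true(v$is_valid)
  }
})

test_that("saturated citation probabilities give a complete bipartite corpus", {
  cfg <- synthetic_config(
    citation_prob = matrix(1, 3, 2, dimnames = list(
      c("supportive", "neutral", "unsupportive"),
      c("supportive", "unsupportive")
    )),
    seed = 11
  )
  g <- with(generate_corpus(cfg), build_citation_graph(papers, edges))
  d <- bipartite_density(g, c("all", "supportive", "neutral", "unsupportive"))
  expect_true(all(d$density == 1))
})

test_that("the citation floor guarantees exactly one citation when probabilities are zero", {
  cfg <- synthetic_config(
    citation_prob = matrix(0, 3, 2, dimnames = list(
      c("supportive", "neutral", "unsupportive"),
      c("supportive", "unsupportive")
    )),
    min_citations_per_review = 1L,
    seed = 12
  )
  g <- with(generate_corpus(cfg), build_citation_graph(papers, edges))
  reviews <- g$papers$id[g$papers$paper_type == "review"]
  od <- out_degrees(g)
  expect_true(all(od$out_degree[od$id %in% reviews] == 1L))
})

test_that("mean density matches exact enumeration accounting for the floor", {
  # one review per draw cites each of 4 primaries w.p. 0.5, floored at 1
  # citation; exact E[D] by enumeration over the 2^4 citation patterns
  patterns <- as.matrix(expand.grid(rep(list(0:1), 4)))
  k_floored <- pmax(rowSums(patterns), 1)
  exact_mean_d <- mean(k_floored) / 4

  cfg <- synthetic_config(
    primaries_per_class = c(supportive = 2L, unsupportive = 2L),
    reviews_per_class = c(neutral = 50L),
    citation_prob = matrix(0.5, 1, 2, dimnames = list(
      "neutral", c("supportive", "unsupportive")
    )),
    min_citations_per_review = 1L,
    seed = 0
  )
  d_hat <- vapply(seq_len(500), function(i) {
    cfg$seed <- 1000 + i
    g <- with(generate_corpus(cfg), build_citation_graph(papers, edges))
    bipartite_density(g)$density
  }, numeric(1))
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - exact_mean_d), 3 * se)
})

test_that("class-pair edge counts are binomial when the floor is off", {
  pi0 <- 0.3
  cfg <- synthetic_config(
    primaries_per_class = c(supportive = 2L, unsupportive = 2L),
    reviews_per_class = c(neutral = 10L),
    citation_prob = matrix(pi0, 1, 2, dimnames = list(
      "neutral", c("supportive", "unsupportive")
    )),
    min_citations_per_review = 0L,
    seed = 0
  )
  n_pairs <- 10 * 2
  counts <- vapply(seq_len(1000), function(i) {
    cfg$seed <- 3000 + i
    corpus <- generate_corpus(cfg)
    est <- estimate_citation_probs(corpus$papers, corpus$edges)
    est$n_edges[est$primary_class == "supportive"]
  }, numeric(1))
  se_mean <- sqrt(n_pairs * pi0 * (1 - pi0)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n_pairs * pi0), 4 * se_mean)
})

test_that("citation probabilities are recovered with error shrinking in n", {
  pi_true <- matrix(c(0.7, 0.2, 0.3, 0.5), nrow = 2, byrow = TRUE,
                    dimnames = list(c("supportive", "unsupportive"),
                                    c("supportive", "unsupportive")))
  mae_for <- function(n, n_rep = 5L) {
    errs <- vapply(seq_len(n_rep), function(r) {
      cfg <- synthetic_config(
        primaries_per_class = c(supportive = 2L, unsupportive = 2L),
        reviews_per_class = c(supportive = n, unsupportive = n),
        citation_prob = pi_true,
        min_citations_per_review = 0L,
        seed = 400 + 7 * n + r
      )
      corpus <- generate_corpus(cfg)
      est <- estimate_citation_probs(corpus$papers, corpus$edges)
      mean(abs(est$pi_hat - pi_true[cbind(est$review_class, est$primary_class)]))
    }, numeric(1))
    mean(errs)
  }
  maes <- vapply(c(25L, 100L, 400L), mae_for, numeric(1))
  expect_lt(maes[3], maes[1])

  # at the largest size, pooled estimates sit inside the binomial 99% CI
  pooled <- lapply(1:5, function(r) {
    cfg <- synthetic_config(
      primaries_per_class = c(supportive = 2L, unsupportive = 2L),
      reviews_per_class = c(supportive = 400L, unsupportive = 400L),
      citation_prob = pi_true,
      min_citations_per_review = 0L,
      seed = 400 + 7 * 400 + r
    )
    corpus <- generate_corpus(cfg)
    estimate_citation_probs(corpus$papers, corpus$edges)
  })
  est <- dplyr::bind_rows(pooled) |>
    dplyr::summarise(
      n_edges = sum(.data$n_edges), n_pairs = sum(.data$n_pairs),
      .by = c("review_class", "primary_class")
    )
  p <- pi_true[cbind(est$review_class, est$primary_class)]
  lo <- stats::qbinom(0.005, est$n_pairs, p)
  hi <- stats::qbinom(0.995, est$n_pairs, p)
  expect_true(all(est$n_edges >= lo & est$n_edges <= hi))
})

test_that("estimated probabilities are class-pair densities with undefined empty cells", {
  g <- tiny_graph()
  est <- estimate_citation_probs(g$papers, g$edges)
  # 3 review classes x 2 primary classes, one review each
  expect_equal(nrow(est), 6L)
  expect_equal(
    est$pi_hat[est$review_class == "supportive" &
                 est$primary_class == "supportive"], 1
  )
  expect_equal(
    est$pi_hat[est$review_class == "supportive" &
                 est$primary_class == "unsupportive"], 0
  )
  expect_error(
    estimate_citation_probs(
      g$papers[g$papers$paper_type == "primary", ], g$edges
    ),
    class = "citenet_usage_error"
  )
})

test_that("infeasible configurations are rejected", {
  expect_error(
    synthetic_config(min_citations_per_review = 10L),
    class = "citenet_config_error"
  )
  expect_error(
    synthetic_config(citation_prob = matrix(1.2, 3, 2, dimnames = list(
      c("supportive", "neutral", "unsupportive"),
      c("supportive", "unsupportive")
    ))),
    class = "citenet_config_error"
  )
})

test_that("power_simulation with identical arms returns identical rates", {
  cfg <- synthetic_config(
    primaries_per_class = c(supportive = 2L, unsupportive = 2L),
    reviews_per_class = c(supportive = 15L, unsupportive = 15L),
    citation_prob = matrix(0, 2, 2, dimnames = list(
      c("supportive", "unsupportive"), c("supportive", "unsupportive")
    )),
    min_citations_per_review = 1L,
    seed = 900
  )
  res <- power_simulation(cfg, cfg, replicates = 50, alpha = 0.05)
  expect_equal(res$power, res$type1_rate)
  expect_equal(res$n_degenerate_null, res$n_degenerate_alt)
})
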