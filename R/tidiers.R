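#' Tidiers for citenet result objects
#'
#' broom-style methods: `tidy()` returns the per-unit breakdown of a result
#' as a tibble, `glance()` a one-row summary.
#'
#' * `tidy.chisq_result()`: one row per contingency cell with observed,
#'   expected, and standardised Pearson residual `(O - E) / sqrt(E)`.
#' * `glance.chisq_result()`: statistic, df, p-value, and the validity
#'   record.
#' * `tidy.citation_contingency()`: the table in long form.
#' * `tidy.corpus_validation()` / `glance.corpus_validation()`: the
#'   violation rows / the headline counts.
#' * `glance.citation_graph()` and `glance.citation_analysis()`: headline
#'   network metrics.
#'
#' @param x A citenet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name citenet-tidiers
NULL

#' @rdname citenet-tidiers
#' @method tidy chisq_result
#' @export
tidy.chisq_result <- function(x, ...) {
  obs <- x$observed
  long <- expand.grid(
    review_class = rownames(obs), primary = colnames(obs),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    review_class = long$review_class,
    primary = long$primary,
    observed = as.vector(obs),
    expected = as.vector(x$expected),
    std_residual = as.vector((obs - x$expected) / sqrt(x$expected))
  )
}

#' @rdname citenet-tidiers
#' @method glance chisq_result
#' @export
glance.chisq_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    n = sum(x$observed),
    fraction_expected_gt5 = x$validity$fraction_expected_gt5,
    min_expected = x$validity$min_expected,
    conditions_met = x$validity$conditions_met
  )
}

#' @rdname citenet-tidiers
#' @method tidy citation_contingency
#' @export
tidy.citation_contingency <- function(x, ...) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  long <- expand.grid(
    review_class = rownames(m), primary = colnames(m),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    review_class = long$review_class,
    primary = long$primary,
    citations = as.vector(m)
  )
}

#' @rdname citenet-tidiers
#' @method tidy corpus_validation
#' @export
tidy.corpus_validation <- function(x, ...) {
  x$violations
}

#' @rdname citenet-tidiers
#' @method glance corpus_validation
#' @export
glance.corpus_validation <- function(x, ...) {
  tibble::tibble(
    n_papers = x$n_papers,
    n_edges_raw = x$n_edges_raw,
    n_edges_deduplicated = x$n_edges_deduplicated,
    n_violations = nrow(x$violations),
    is_valid = x$is_valid
  )
}

#' @rdname citenet-tidiers
#' @method glance citation_graph
#' @export
glance.citation_graph <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$papers),
    m = nrow(x$edges),
    n_primaries = sum(x$papers$paper_type == "primary"),
    n_reviews = sum(x$papers$paper_type == "review")
  )
}

#' @rdname citenet-tidiers
#' @method glance citation_analysis
#' @export
glance.citation_analysis <- function(x, ...) {
  w <- x$whole_network
  tibble::tibble(
    n = w$n,
    m = w$m,
    n_reviews = w$density$n_reviews,
    n_primaries = w$density$n_primaries,
    density = w$density$density,
    n_biased = sum(w$bias_flags$is_biased),
    statistic = if (is.null(x$chi_square)) NA_real_ else x$chi_square$statistic,
    p_value = if (is.null(x$chi_square)) NA_real_ else x$chi_square$p_value
  )
}
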