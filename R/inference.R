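#' Pearson chi-square test of stance-citation association
#'
#' Tests whether the distribution of citations over primary studies depends
#' on the citing reviews' stance class, using the plain Pearson statistic on
#' the stance-by-trial contingency table:
#' `X^2 = sum (O - E)^2 / E` with expected counts
#' `E[i, j] = row_i x col_j / N`, `df = (r - 1)(c - 1)`, and an upper-tail
#' p-value from the chi-square distribution. No continuity correction is
#' applied (it is a 2x2 device; these tables are r x c).
#'
#' The statistic and the p-value are computed from first principles: the
#' upper tail is the regularized upper incomplete gamma function
#' `Q(df/2, x/2)`, evaluated by series expansion for `x < df + 1` and by
#' continued fraction otherwise, to a tolerance of 1e-12.
#'
#' The textbook validity conditions (at least 80% of cells with expected
#' count above 5, minimum expected count at least 1) are evaluated and
#' attached to the result; they are advisory, not blocking.
#'
#' @param table A `citation_contingency`, or any matrix/data frame of
#'   non-negative integer counts.
#' @return An object of class `chisq_result`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, and `validity` (see
#'   [check_validity()]).
#' @seealso [check_validity()], [contingency_table()]
#' @export
#' @examples
#' tab <- as_contingency(matrix(
#'   c(17, 15, 7, 7, 12, 12, 6, 8, 28, 5, 2, 2),
#'   nrow = 3, byrow = TRUE,
#'   dimnames = list(
#'     c("neutral", "unsupportive", "supportive"),
#'     c("OSLO", "MRC", "ROSE", "RCLF")
#'   )
#' ))
#' pearson_chi_square(tab)
pearson_chi_square <- function(table) {
  obs <- contingency_matrix(table)
  n <- sum(obs)
  if (n <= 0) abort_degenerate("Contingency table has grand total 0")
  rt <- rowSums(obs)
  ct <- colSums(obs)
  if (any(rt == 0) || any(ct == 0)) {
    zero <- c(rownames(obs)[rt == 0], colnames(obs)[ct == 0])
    abort_degenerate(paste0(
      "Degenerate table: zero marginal for ", id_phrase(zero),
      " gives expected count 0"
    ))
  }
  expected <- outer(rt, ct) / n
  statistic <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  if (df < 1L) {
    abort_degenerate("Chi-square test needs at least 2 rows and 2 columns")
  }
  structure(
    list(
      statistic = statistic,
      df = df,
      p_value = chisq_upper_tail(statistic, df),
      observed = obs,
      expected = expected,
      validity = check_validity(table)
    ),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square: X^2(%d, N = %d) = %.2f, p = %.3g\n",
    x$df, sum(x$observed), x$statistic, x$p_value
  ))
  v <- x$validity
  cat(sprintf(
    "Validity: %.0f%% of cells with expected > 5 (min expected %.2f) - conditions %s\n",
    100 * v$fraction_expected_gt5, v$min_expected,
    if (v$conditions_met) "met" else "NOT met"
  ))
  invisible(x)
}

#' Chi-square validity conditions
#'
#' Evaluates the standard applicability conditions for the Pearson
#' chi-square approximation on a contingency table: the fraction of cells
#' whose *expected* count exceeds 5 (should be at least 80%) and the minimum
#' expected count (should be at least 1).
#'
#' @param table A `citation_contingency`, matrix, or data frame of counts.
#' @return A one-row tibble: `fraction_expected_gt5`, `min_expected`,
#'   `conditions_met`.
#' @export
check_validity <- function(table) {
  obs <- contingency_matrix(table)
  n <- sum(obs)
  if (n <= 0) abort_degenerate("Contingency table has grand total 0")
  expected <- outer(rowSums(obs), colSums(obs)) / n
  frac <- mean(expected > 5)
  min_e <- min(expected)
  tibble::tibble(
    fraction_expected_gt5 = frac,
    min_expected = min_e,
    conditions_met = frac >= 0.8 && min_e >= 1
  )
}

#' Upper-tail chi-square probability
#'
#' `P(X > x)` for a chi-square variable with `df` degrees of freedom,
#' computed as the regularized upper incomplete gamma function
#' `Q(df/2, x/2)`. Exposed for reuse in simulations and tests.
#'
#' @param x Non-negative quantile (vectorised).
#' @param df Degrees of freedom (positive).
#' @return Upper-tail probabilities in \[0, 1\].
#' @export
chisq_upper_tail <- function(x, df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0) {
    abort_usage("df must be a single positive number")
  }
  vapply(x, function(xi) gamma_q(df / 2, xi / 2), numeric(1))
}

# ---- regularized incomplete gamma -------------------------------------------
# Q(a, x) = Gamma(a, x) / Gamma(a), the upper regularized incomplete gamma.
# Series for the lower function P when x < a + 1, modified-Lentz continued
# fraction for Q otherwise; both to a relative tolerance of 1e-12.

gamma_q <- function(a, x, tol = 1e-12, max_iter = 1000L) {
  if (x < 0 || a <= 0) abort_usage("gamma_q needs a > 0 and x >= 0")
  if (x == 0) return(1)
  if (x < a + 1) 1 - gamma_p_series(a, x, tol, max_iter)
  else gamma_q_cf(a, x, tol, max_iter)
}

gamma_p_series <- function(a, x, tol, max_iter) {
  ap <- a
  term <- 1 / a
  total <- term
  for (i in seq_len(max_iter)) {
    ap <- ap + 1
    term <- term * x / ap
    total <- total + term
    if (abs(term) < abs(total) * tol) {
      return(total * exp(-x + a * log(x) - lgamma(a)))
    }
  }
  abort("Incomplete-gamma series failed to converge", class = "citenet_numeric_error")
}

gamma_q_cf <- function(a, x, tol, max_iter) {
  tiny <- .Machine$double.xmin
  b <- x + 1 - a
  c <- 1 / tiny
  d <- 1 / b
  h <- d
  for (i in seq_len(max_iter)) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < tiny) d <- tiny
    c <- b + an / c
    if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < tol) {
      return(h * exp(-x + a * log(x) - lgamma(a)))
    }
  }
  abort("Incomplete-gamma continued fraction failed to converge",
        class = "citenet_numeric_error")
}

# Validate and strip down to a plain integer matrix.
contingency_matrix <- function(table) {
  m <- unclass(as_contingency(table))
  attr(m, "class") <- NULL
  m
}
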