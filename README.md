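# citenet

Claim-specific citation network analysis in R: who cites which evidence on a
single scientific question, and how selectively?

## The problem

When a body of primary studies on one claim is small and conflicting, the
reviews that interpret those studies for the wider community can distort the
evidence base simply by what they choose to cite. Two failure modes matter:

* **citation bias** — a review cites only the primary studies whose outcome
  points one way and ignores the contrary ones;
* **research underutilisation** — a review cites fewer than the studies that
  are actually available and relevant.

`citenet` quantifies both on an attributed, directed, acyclic citation graph
whose vertices are papers (primary trials and reviews, each carrying a
stance classification such as *supportive* / *neutral* / *unsupportive* and
a publication year) and whose edges are citations from reviews to the
primaries.

## The measures

With `S` a set of reviews, `P` the set of primary studies, and `E` the
number of review→primary citation edges present, the **bipartite
utilisation density** is

```
D = E / (|S| × |P|)
```

— the fraction of possible citation pathways actually occupied. `D` is
computed for the whole network and for each stance-restricted sub-graph
(reviews of one class plus *all* primaries), so classes can be compared
directly. Per-vertex **in-degree** (`k_in = Σ_i G_ij`, how often a study is
cited) and **out-degree** (`k_out = Σ_j G_ij`, how many studies a review
uses) come from the binary adjacency matrix `G`. A review is **flagged
biased** when all primaries it cites share one stance label. Finally, the
stance × trial contingency table of citation counts is tested for
association with a plain Pearson chi-square,
`X² = Σ (O − E)² / E` on `(r−1)(c−1)` degrees of freedom, with the textbook
validity conditions (≥ 80% of expected counts above 5, minimum expected
count ≥ 1) evaluated alongside. The statistic and its upper-tail p-value
(regularized incomplete gamma) are implemented from first principles and
cross-checked against independent oracles in the test suite.

The package also ships a synthetic-corpus generator with class-conditional
citation probabilities (homophily), a marginal-constrained fixture builder
(Gale–Ryser feasibility + seeded random realization), and Monte-Carlo
power / parameter-recovery simulation — so every stage is testable without
any particular study's raw files.

## Worked example

The package's worked example is the claim-specific network of the four
secondary-prevention RCTs of fat-controlled diets after myocardial
infarction (one supportive trial — Oslo Diet-Heart — and three unsupportive
ones) and the 62 reviews (28 supportive, 17 neutral, 17 unsupportive) that
cited them in 1969–1984. `chd_diet_corpus()` reconstructs this corpus from
its published margins (see the methods vignette for what is and is not
pinned by that reconstruction):

```r
library(citenet)

corpus <- chd_diet_corpus(seed = 1)
report <- run_analysis(corpus$papers, corpus$edges, seed = 1)
report
#> Claim-specific citation analysis
#>   Corpus: n = 66 , review-to-primary m = 121 ( total edges 121 )
#>   Density D = 0.49 over 62 reviews x 4 primaries
#>   neutral:      n = 21, m = 46, D = 0.68, biased reviews = 1
#>   supportive:   n = 32, m = 37, D = 0.33, biased reviews = 23
#>   unsupportive: n = 21, m = 38, D = 0.56, biased reviews = 8
#> Pearson chi-square: X^2(6, N = 121) = 18.19, p = 0.00578
#> Validity: 83% of cells with expected > 5 (min expected 4.59) - conditions met
```

Reading this: only 49% of the possible review→trial citation pathways are
occupied overall. Neutral reviews use the evidence most completely
(D = 0.68, a single biased review), while supportive reviews use it least
(D = 0.33) and 23 of the 28 cite *only* the one supportive trial. The
chi-square on the stance × trial table says this difference in citation
behaviour is far beyond chance (p ≈ 0.006).

Each piece is available on its own and returns a tibble, so the parts
compose with the pipe:

```r
graph <- build_citation_graph(corpus$papers, corpus$edges)
bipartite_density(graph, c("all", "neutral", "unsupportive", "supportive"))
citation_bias_flags(graph) |> dplyr::filter(is_biased)
utilization_distribution(graph) |> autoplot()
pearson_chi_square(contingency_table(graph)) |> glance()
export_graph(graph, "network.gexf", format = "gexf")   # open in Gephi
```

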