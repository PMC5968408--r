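---
title: "Measuring citation bias on claim-specific citation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring citation bias on claim-specific citation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citenet)
```

## The model

`citenet` works on a *claim-specific citation network*: the set of papers
addressing one scientific question, split into primary studies (the trials
that generated the evidence) and reviews (the papers that interpreted it),
with a directed edge from each review to every primary study it cites.
Each paper carries a stance classification — by default `supportive`,
`neutral`, or `unsupportive` of the claim — assigned upstream by reading
the papers; the package takes classifications as input data and never
infers them.

Three structural assumptions define the graph:

* **Acyclicity by time.** Papers cite only previously published work and
  never themselves. `validate_corpus()` checks this; by default a citation
  between two papers of the same year is legal (publication lag makes
  same-year citation common in practice), and `strict_years = TRUE`
  forbids it. Violations are *reported*, never silently repaired, so the
  analyst decides what is fatal.
* **Binary adjacency.** The adjacency is 0/1: a review that references the
  same trial in ten places still contributes one edge. Duplicate citation
  records collapse at graph build, and the edge count `m` is the number of
  distinct (citing, cited) pairs.
* **Review→primary restriction.** All outcome measures are defined on the
  review-to-primary edge set only. A corpus may carry other edges (e.g.
  reviews citing reviews); they survive in the graph but never enter a
  density, a bias flag, or the contingency table.

## The outcome measures

**Bipartite density.** For reviews `S` and primaries `P` with `E`
review→primary edges, `D = E / (|S| × |P|)` is the fraction of possible
citation pathways occupied. The scope can be all reviews or one stance
class; the primary set is always the full `P`, so per-class densities are
directly comparable — a class with low `D` is using less of the same
evidence base. Densities are kept as exact ratios and only rounded for
display (two decimals in the printed report).

**Degrees.** In-degree of a primary is its citation count within the
corpus; out-degree of a review is the number of distinct primaries it
cites. Degree functions operate on whatever edge set the graph carries —
restriction to review→primary edges is the caller's (or
`claim_subgraph()`'s) responsibility, which keeps the functions honest on
general graphs.

**Citation-bias flag.** A review is biased when every primary it cites
shares one stance label. The review's *own* stance never enters: a review
arguing against an intervention while citing only the favourable trial is
biased *toward* `supportive`. Reviews citing no primary at all are
reported with a warning rather than an error: they indicate an upstream
inclusion-rule failure, not a computational one.

**Utilization distribution.** The histogram of reviews by number of
distinct primaries cited. Together with the density and the contingency
table it forms a triple-agreement invariant — all three recompute the same
edge count `E` by different routes — which the test suite exercises on
random corpora.

**Stance × trial contingency table and chi-square.** Cell (c, p) counts
reviews of class c citing primary p. The Pearson statistic
`X² = Σ (O − E)² / E`, `E_ij = row_i col_j / N`, `df = (r−1)(c−1)` is
computed from first principles with no continuity correction (that
correction is a 2×2 device; these are r × c tables). The upper-tail
p-value is the regularized upper incomplete gamma function `Q(df/2, x/2)`,
evaluated by series expansion for `x < df + 1` and by a modified-Lentz
continued fraction otherwise, to relative tolerance 1e-12; the test suite
pins it against numerical quadrature of the chi-square density and against
`stats::pchisq` on a grid. The textbook validity conditions (≥ 80% of
cells with expected count > 5; minimum expected ≥ 1) are attached to every
result but are advisory: the analyst sees them, nothing is blocked.
Degenerate tables — any zero row or column marginal, which would put a
zero in a denominator — raise a classed error instead.

## The synthetic-data generator

`synthetic_config()` + `generate_corpus()` emulate the data-generating
structure the measures are designed to detect: stance-labelled primaries,
a larger set of stance-labelled reviews, and *homophily* — a
class-conditional citation probability matrix `π[review class, primary
class]`, applied independently across review–primary pairs. A
minimum-citation floor mirrors the usual corpus inclusion rule (a review
enters the corpus only if it cites at least one primary): reviews below
the floor draw additional distinct primaries uniformly. The floor can be
set to 0 for parameter-recovery work, because topping up inflates the
per-pair citation rate.

The generator's defaults are the study conditions of the worked example:
1 supportive + 3 unsupportive primaries; 28 supportive, 17 neutral, and
17 unsupportive reviews; a 1965–1984 window with primaries dated at the
start and reviews spread uniformly over the later years; and `π` equal to
the class-pair densities estimated from that corpus (e.g. supportive
reviews cite the supportive trial with probability 1.0 but each
unsupportive trial with probability ≈ 0.107).

What the generator deliberately does **not** model: citation cascades
(reviews copying earlier reviews' bibliographies, which induces
correlation between reviews), time-resolved citation accrual, and any
clinical content of the trials. Passing tests on generated corpora
therefore demonstrate correctness of the *measures* under independent
citation behaviour, not that real bibliographies are independent — on real
data the observed bias counts may be more clustered than the independence
model would produce.

### A calibration subtlety

Under the generator, contingency-table cells are sums of independent
Bernoulli draws — independent binomials, not the multinomial the
chi-square's null distribution assumes. The Pearson statistic is then
variance-deflated by roughly `(1 − π)`, and the test is conservative: at a
constant `π = 0.5` the simulated type-I error is essentially 0 rather than
0.05. This is a property of applying the independence test to
per-pair-Bernoulli data, not an implementation artefact.
`power_simulation()`'s calibration experiment therefore uses the null
configuration that *does* satisfy the test's sampling model: `π ≡ 0` with
the floor at 1, under which every review cites exactly one uniformly
chosen primary — true multinomial homogeneity sampling. At that null the
simulated type-I error sits within Monte-Carlo error of the nominal level
(0.042 at α = 0.05 over 2000 replicates in the acceptance suite). When
interpreting a significant chi-square on real corpora the conservatism
works in the analyst's favour; a non-significant result on a dense corpus
is weaker evidence of no association than the nominal level suggests.

## Rebuilding a corpus from published margins

Published analyses typically report a citation network only through its
margins: the stance × trial contingency table, per-class out-degree
histograms, and bias counts. `marginal_profile()` +
`build_fixture_from_marginals()` realize such a summary as a concrete
corpus. Each class block is first checked for Gale–Ryser feasibility (a
0/1 matrix with the given row and column sums exists iff the sums agree
and `Σ_{i≤k} r_(i) ≤ Σ_j min(c_j, k)` for every k); realization is then a
seeded randomized assignment, weighted by remaining column demand, with
restarts.

Margins alone do not pin everything. The contingency table and the
histograms are reproduced exactly by *any* valid completion, but
citation-bias counts generally are not: a single-citing review may cite a
trial of either stance without disturbing the margins. Where a class's
column structure forces the counts (in the worked example, the supportive
and neutral classes both cite the one supportive trial exactly as many
times as they have reviews, so every review of those classes cites it),
no constraint is needed; where it does not (the unsupportive class), the
profile carries optional `cite_only` counts with *exact* semantics: the
stated number of reviews cite only primaries of that stance, and every
other review of the class must span at least two stances. Because a
review citing a single primary is always stance-pure, exact mode requires
all out-degree-1 reviews to be among the constrained ones; the builder
enforces this and fails (after its restart budget) rather than return a
corpus violating the requested counts.

The worked-example corpus `chd_diet_corpus()` is exactly such a
reconstruction and is documented as synthetic at the per-review level:
every margin-determined statistic is identical across seeds, while the
particular review→trial incidence varies.

## Numerical and design choices

* Vertex order is fixed by sorted id, so adjacency matrices, exports, and
  reports are bit-for-bit reproducible; serialising the same analysis
  twice gives byte-identical JSON (no timestamps enter the report body).
* All generator and fixture randomness flows through a single integer
  seed via `withr::with_seed`, leaving the caller's RNG state untouched.
* Stance labels are matched case-insensitively against a configurable
  stance set; the default three-way scheme is a package default, not a
  structural assumption.
* Merged publications (one study published as several papers) are handled
  by an explicit id-alias map at graph build; aliasing is the only
  deduplication heuristic offered.
* Monte-Carlo sizes used by the shipped test suite: 2000 replicates for
  type-I calibration, 500 replicates against the exact floor-adjusted
  density expectation, 1000 replicates for the binomial edge-count check,
  and recovery runs at 25/100/400 reviews per class. These complete in a
  few minutes on a single core and give standard errors comfortably
  inside the asserted bands.

## Limitations

* Classifications are inputs; nothing guards against upstream
  misclassification.
* The bias flag is binary and extreme by construction — it captures only
  reviews citing *exclusively* one stance. Milder selectivity shows up in
  the densities and utilization histograms, not in the flag.
* The chi-square treats citations as the unit of counting; reviews
  contributing several citations each means `N` is not a number of
  independent sampling units under per-pair citation behaviour (see the
  calibration subtlety above).
* Fixture realizations are uniform-ish over valid completions only in the
  weighted-greedy sense; the builder guarantees margin exactness, not
  exact uniformity over the completion polytope.
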