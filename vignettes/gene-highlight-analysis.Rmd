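---
title: "Measuring early-stage research into human genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring early-stage research into human genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelit)
library(data.table)
```

## The measurement model

The unit of observation throughout this package is the *gene-publication
pair*: one unique combination of a research publication and a human
protein-coding gene mentioned by name ("highlighted") in its title or
abstract. A gene mentioned only deep in the body of a paper is not counted;
title and abstract mentions are taken as the authors' own signal of which
genes the work is about. The highlight table is built by intersecting four
inputs:

1. tabular publication records (year, journal, title, abstract, keywords,
   MeSH terms, publication types, author count, funding and affiliation
   metadata);
2. entity-mention annotations with character offsets into the concatenated
   title and abstract, from which each mention's section is derived;
3. a curated gene-to-publication link table that anchors which publications
   are about genes of the configured taxon at all; and
4. a gene registry restricting the analysis to protein-coding genes of one
   taxon (default 9606), optionally carrying annotation columns
   (loss-of-function intolerance, murine phenotype counts, association-study
   trait counts) used as gene weights.

Non-research material (reviews, letters, comments, errata, and the rest of
the editorial publication types listed by `medline_excluded_types()`) is
removed first, along with records after the configured end year and *all*
copies of any duplicated publication identifier — duplicated identifiers are
treated as corrupt and excluded rather than deduplicated to one copy.
Ambiguous mentions (several candidate gene identifiers joined by `";"`) are
dropped rather than resolved.

Every gene then has a *first-highlight year*, and each pair has an age
class at publication time: a **new** target (age 0), a **recent** target
(age 1–5), or an **old** target (age 6 or more). A publication inherits the
youngest class among its highlighted genes, so one new gene is enough to
make a publication early-stage. All downstream statistics — temporal share
series, decade aggregations of team size and gene counts, enrichment scans
over journals and funders, citation metrics, and the concentration
analysis — are functions of this classified pair table.

## Statistical primitives and their conventions

The shared primitives are implemented in-package so that each has an
independent oracle in the test suite:

* **Exact 2×2 test** (`fisher_exact_two_sided()`): the conventional
  probability-mass two-sided rule — sum the hypergeometric probabilities of
  all tables with the observed margins that are no more probable than the
  observed table. Probabilities within a relative tolerance of `1e-7` are
  treated as tied so that floating-point noise cannot split a genuinely
  tied table off the rejection set. The suite checks every admissible table
  with total at most 60 against a from-scratch enumeration.
* **Bonferroni control** (`bonferroni_reject()`): reject at `alpha / m`
  with `m` the number of groups actually tested in the scan at hand
  (after the minimum-group-size filter), boundary inclusive. The default
  familywise level is 0.01.
* **Percentile bootstrap** (`bootstrap_ci()`, default 1000 replicates,
  95% level): the resampling unit is whatever the caller passes — the
  share and enrichment series resample publications, not pairs, because
  pairs within a publication are not independent. The percentile method is
  used rather than BCa; for the shares and fold ratios involved, the two
  agree to well within the Monte Carlo error at these replicate counts,
  and the percentile interval is cheaper and simpler to reason about.
* **Rank correlation** (`spearman_cor()`): average ranks for ties, then the
  Pearson formula on ranks.
* **Within-cohort percentiles** (`cohort_percentile()`): midrank
  convention, `100 * (strictly below + half the ties) / cohort size`. Ties
  are split symmetrically, which keeps the "top 5% of the publication
  year" flag stable under the heavy integer ties of citation counts and
  makes the percentile invariant under monotone transforms.

## Choices where the design was genuinely open

* **Intersection level.** The curated link table is applied at publication
  level: a publication qualifies if it carries at least one link for the
  configured taxon, and the mention annotations then supply the gene
  identities. A stricter per-gene agreement between the two sources is not
  required.
* **Offset convention.** Mention offsets are 0-based into the title, a
  separator of configurable width (default 1), then the abstract. Offsets
  falling on the separator or past the end resolve to `beyond` and are
  dropped. The synthetic generator emits offsets under the same convention,
  so the round-trip test pins the arithmetic.
* **Expected class shares in the enrichment series.** Within a sliding
  window (default 3 years), a gene contributes to the class it occupies in
  each calendar year of the window, and the per-year tallies are averaged;
  this mirrors how pairs are pooled over the window. A `pooled` mode
  (class at the center year only) is available behind a switch.
  Zero-observed classes against positive expectation report a `-Inf`
  sentinel and are excluded from interval aggregation; zero-expected cells
  are omitted.
* **Fold-enrichment denominator.** A group's target share is compared to
  the corpus-wide share *including* the group (the out-group share is
  available behind a switch). The corpus denominator stays defined for
  groups covering most of the corpus; for the small groups that dominate
  the scans the two differ negligibly.
* **The "twice as much" rule** comparing recent-target with new-target
  enrichment is applied on linear fold ratios (`fold_recent >= 2 *
  fold_new`), not on the log2 values; a group with no new-target
  publications at all (fold 0) and positive recent enrichment is flagged.
* **Quartiles** in the citation-variability IQR use linear interpolation
  between order statistics (R type 7), stated explicitly so the statistic
  is deterministic.
* **Disruption percentiles** are computed within publication-year cohorts,
  consistent with the other citation percentiles; corpus-wide percentiles
  would conflate cohort size with disruption. Citers known only through an
  aggregate citation count (outside the loaded edge list) contribute to
  percentile metrics but cannot be classified for disruption.
* **Token-bounded phrase matching.** Field classification reads
  "contains the phrase" as containment at token boundaries (delimited by
  non-alphanumeric characters or string edges): several listed tokens
  ("wes", "ngs", "wgs") would otherwise fire inside ordinary words such as
  "western". A raw-substring mode is available for sensitivity analysis.
  Clinical-trial detection, by contrast, is deliberately raw substring
  matching on publication types, where "clinical trial" cannot
  over-match.
* **Rank ties** in the concentration analysis break by ascending gene
  identifier, making ranks and the top set reproducible.

## What the synthetic generator emulates

`generate_corpus()` produces the five input files with known ground truth.
Per publication it draws a journal, then the lead gene's age class from a
year-dependent mixture — the *novelty rate* (lead gene never highlighted
before) defaults to a linear decay from 0.30 in 1980 to 0.05 in 2018,
emulating the saturation of the gene pool, with a constant 0.20 recent
rate. A journal's planted multiplier scales its publications' probability
of being early-stage, which makes the planted log2 enrichment directly
recoverable by the fold statistic up to a small corpus-share contamination
term. Additional genes arrive by preferential attachment (weight
proportional to `(pair count + 1)^exponent`), team sizes are
class-conditional Poisson draws, a configured fraction of publications
receives a genome-biology phrase in its keywords (publications carrying
the association-study MeSH descriptor are genome-biology by construction,
since the descriptor name itself contains a lexicon phrase), and citation
counts are lognormal with a class-dependent tail exponent: a boost of
`k` makes the class `k` times as likely to exceed any high threshold, so a
2× boost plants a 2× probability of being highly cited.

Titles and abstracts are skeletal filler around embedded gene symbols; the
contract is offset consistency, not linguistic realism, and symbols are
synthetic (`GP000001`, …) so they cannot collide with lexicon phrases. With
noise enabled, the generator also emits one record per corpus filter
(excluded type, duplicated identifier, ambiguous mention, non-coding gene,
foreign-taxon gene, unlinked publication), none of which contributes a
ground-truth pair — so the pipeline's output must equal the ground truth
exactly, which the suite asserts as set equality.

Two caveats delimit what passing tests show about real data. First, the
generator's first corpus year is burn-in: no gene has history, every lead
gene is necessarily new, and within that cohort the top-5% citation flag
cannot exceed its 5% baseline; recovery checks therefore measure over the
settled years. Second, real literature has correlated text, drifting
nomenclature, and entity-recognition errors that the generator deliberately
omits; the generator validates the pipeline's arithmetic, not the upstream
annotation quality.

## Problem sizes and numerical checks

The test suite runs at deliberately modest sizes: module tests use corpora
of a few hundred genes and 500–2500 publications; the parameter-recovery
checks use a 5,000-publication, 4,000-gene corpus with 100 journals and
planted multipliers of 1, 2, and 4; the exact-test sweep covers all ~630k
admissible 2×2 tables with total at most 60; disruption is checked against
a brute-force citer classifier on 200 random graphs of up to 50 nodes;
calibration uses 1,000 permutation replicates (familywise error) and 1,000
simulations (bootstrap coverage of a Bernoulli mean). At these sizes the
whole suite completes in about a minute on one CPU, and all statistics are
deterministic given the configured seeds.

Known limitations: the pipeline does not model gene-level time-to-reuse,
funder co-occurrence, or field-normalized citation metrics; cross-species
homology is out of scope beyond filtering to one taxon; and the
concentration analysis reports whatever gene identifiers dominate the
supplied corpus — identities of specific real genes require the real
literature.

## A small end-to-end run

```{r pipeline, eval = FALSE}
dir <- tempfile()
write_corpus(generate_corpus(corpus_params(seed = 1L)), dir)
bundle <- run_pipeline(list(input_dir = dir, n_boot = 200L, seed = 1L))
bundle
export_figure_tables(bundle, "fig1b")   # class shares per sliding window
export_figure_tables(bundle, "fig6a")   # gene ranks and cumulative shares
```
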