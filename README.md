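# genelit

Bibliometric analysis of **early-stage research into human genes**: when a
protein-coding gene is first "highlighted" — mentioned by name in the title
or abstract of an indexed research publication — and under which scientific
and organizational conditions that happens.

The package is aimed at scientometricians and research-policy analysts who
work with MEDLINE-derived publication tables, PubTator-style entity-mention
offsets, gene2pubmed link tables, an NCBI-gene-style registry, and an
iCite-style citation edge list. It turns those inputs into the
gene-publication *highlight table* and computes, on top of it, the full
analysis battery for early-stage research, together with a synthetic corpus
generator with known ground truth so every stage can be validated end to
end.

## The model

The atomic unit is the unique pair *(publication p, gene g)* where *g* is
mentioned in the title or abstract of *p*. Each gene gets a first-highlight
year `t0(g)`; each pair gets an age class from `a = year(p) − t0(g)`:

* **new** target — `a = 0`,
* **recent** target — `1 ≤ a ≤ 5`,
* **old** target — `a ≥ 6`,

and a publication takes the youngest class among its genes. On the
classified pair table the package computes:

* cumulative highlight curves and 3-year sliding-window **class shares**
  with percentile-bootstrap CIs (resampling publications);
* **enrichment series** `log2(observed pair share / expected share)`, where
  the expected share is the (optionally annotation-weighted) share of genes
  occupying each class in the window;
* decade × class aggregations of **team size** and **genes per
  publication**;
* **context scans**: for every journal / funder / NIH activity code /
  organization, the 2×2 table of early-stage vs other publications in and
  out of the group, a self-implemented exact two-sided test, Bonferroni
  control at p < 0.01 over the scan, the fold enrichment
  `log2((a/(a+b)) / ((a+c)/n))`, and the "disproportionately recent" rule
  `fold_recent ≥ 2 · fold_new`;
* **citation impact**: within-year midrank percentiles, top-5% highly-cited
  flags, IQR-width citation variability, clinical-trial citation lag, and
  the disruption index
  `d = (n_focal_only − n_both) / (n_focal_only + n_both + n_ref_only)`
  on the citing→cited graph;
* **concentration**: genes ranked by recent-target publication volume,
  cumulative pair shares, the top-1% gene set, per-journal top-set shares,
  journal × gene percentage matrices with Ward clustering, and the top-set
  ablation re-scan;
* **field labels**: genome-biology and genome-wide-association-study flags
  from packaged phrase lexicons (case-insensitive, token-bounded) plus the
  D055106 MeSH descriptor and an optional catalog pmid set.

## Worked example

```r
library(genelit)

dir <- tempfile()
write_corpus(generate_corpus(corpus_params(seed = 1L)), dir)
bundle <- run_pipeline(list(input_dir = dir, n_boot = 200L, seed = 1L))
bundle
#> analysis bundle: 2344 records, 3878 pairs, 497 genes; top set 1 genes (7.8% of recent pairs)

ss <- export_figure_tables(bundle, "fig1b")
ss[ss$center_year == 2010]
#>    center_year  class      share         lo         hi
#> 1:        2010    new 0.05214724 0.03278567 0.07572252
#> 2:        2010 recent 0.12269939 0.08403991 0.15844906
#> 3:        2010    old 0.82515337 0.78287682 0.85935365
```

The 2010 window says: of all gene-publication pairs in 2009–2011, 5.2%
fall on genes first highlighted that same year, 12.3% on recent targets,
82.5% on old targets — with 95% bootstrap intervals from resampling
publications. The generator planted a decaying novelty rate, so early
windows show much higher new-target shares.

```r
scan <- bundle$journal_scan_recent
scan[scan$significant]
#>    group target_class  a b   c   d log2_fold    p_raw significant direction
#> 1:   J02       recent 15 4 113 408      1.74 3.41e-07        TRUE  enriched
```

Journal `J02` carries a planted 4× recent-target multiplier; the scan
recovers it as the only Bonferroni-significant journal, with a fold
enrichment of `2^1.74 ≈ 3.3` (the corpus-wide denominator absorbs part of
the planted 4×).

```r
head(export_figure_tables(bundle, "fig6a"), 3)
#>    rank gene_id n_recent_pairs  cum_share
#> 1:    0 G001232             10 0.07751938
#> 2:    1 G001847              8 0.13953488
#> 3:    2 G002727              8 0.20155039
```

The three most-published recent targets already account for 20% of all
recent-target pairs — the concentration the top-set analysis quantifies.

A thin command-line wrapper ships in `inst/cli/genelit.R`
(`simulate --out DIR --seed N`, `all --config run.yaml --out DIR`).

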