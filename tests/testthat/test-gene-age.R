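test_that("first highlight years are the minimum over pairs, per section", {
  pairs <- pair_table(pmid = c(1, 2, 3, 4),
                      gene_id = c("g1", "g1", "g2", "g2"),
                      pub_year = c(1995, 2003, 2000, 1998),
                      in_title = c(FALSE, TRUE, FALSE, FALSE),
                      in_abstract = TRUE)
  at <- first_highlight_years(pairs)
  expect_equal(at$first_year[at$gene_id == "g1"], 1995L)
  expect_equal(at$first_year_title[at$gene_id == "g1"], 2003L)
  # abstract-only gene has no title year
  expect_true(is.na(at$first_year_title[at$gene_id == "g2"]))
  expect_true(all(at$first_year_title >= at$first_year, na.rm = TRUE))
})

test_that("generator discovery years are recovered exactly", {
  co <- small_corpus(seed = 13L, noise = FALSE)
  at <- first_highlight_years(co$truth$pairs)
  got <- stats::setNames(at$first_year, at$gene_id)
  truth <- co$truth$first_year
  expect_equal(got[sort(names(got))], truth[sort(names(truth))])
})

test_that("age class thresholds are 0 / 1-5 / 6+", {
  expect_equal(age_class(2010, 2010), "new")
  expect_equal(age_class(2011, 2010), "recent")
  expect_equal(age_class(2015, 2010), "recent")
  expect_equal(age_class(2016, 2010), "old")
  expect_error(age_class(2009, 2010), "earlier")
})

test_that("cumulative highlight curve is a nondecreasing share", {
  at <- age_table_of(sprintf("g%d", 1:4), c(1990, 1990, 1995, 2000),
                     first_year_title = c(1991, NA, 1995, NA))
  reg <- data.table::data.table(
    gene_id = sprintf("g%d", 1:10), symbol = sprintf("s%d", 1:10),
    tax_id = 9606L, gene_type = "protein-coding", lof_intolerant = FALSE,
    murine_phenotype_count = 0L, gwas_trait_count = 0L)
  cur <- cumulative_highlight_curve(at, reg, 1989:2001)
  expect_equal(cur$share_highlighted[cur$year == 1996], 0.3)
  expect_equal(cur$share_highlighted[cur$year == 2001], 0.4)
  expect_true(all(diff(cur$share_highlighted) >= 0))
  expect_true(all(diff(cur$share_title) >= 0))
  expect_true(all(cur$share_title <= cur$share_highlighted))
  expect_error(cumulative_highlight_curve(at, reg[0], 1990:2000), "empty")
})

test_that("shutting novelty off freezes the cumulative curve", {
  years <- 1990:2009
  nov <- ifelse(years <= 1999, 0.4, 0)
  co <- generate_corpus(corpus_params(
    n_genes = 500L, years = years, pubs_per_year = 20L, novelty_rate = nov,
    noise = FALSE, seed = 5L))
  expect_lte(max(co$truth$first_year), 1999L)
  at <- first_highlight_years(co$truth$pairs)
  cur <- cumulative_highlight_curve(at, co$registry, years)
  after <- cur$share_highlighted[cur$year >= 1999]
  expect_true(all(after == after[1]))
})

test_that("window pair shares sum to one and match degenerate hand cases", {
  # one pair in each class in a single window
  pairs <- pair_table(1:3, c("gN", "gR", "gO"), 2010)
  at <- age_table_of(c("gN", "gR", "gO"), c(2010, 2007, 2000))
  ss <- pair_share_series(pairs, at, window = 3, n_boot = 50, seed = 1)
  w <- ss[ss$center_year == 2010]
  expect_equal(sort(w$share), rep(1 / 3, 3))
  expect_equal(sum(w$share), 1)
  # all-old window
  pairs2 <- pair_table(1:2, c("gO", "gO2"), 2010)
  at2 <- age_table_of(c("gO", "gO2"), c(2000, 1999))
  w2 <- pair_share_series(pairs2, at2, window = 3, n_boot = 50, seed = 1)
  expect_equal(w2$share[w2$class == "old"], 1)
  expect_equal(sum(w2$share[w2$class != "old"]), 0)
  expect_error(pair_share_series(pairs, at, window = 4), "odd")
})

test_that("class shares sum to one in every window of a generated corpus", {
  co <- small_corpus(seed = 17L, noise = FALSE)
  at <- first_highlight_years(co$truth$pairs)
  ss <- pair_share_series(co$truth$pairs, at, n_boot = 20, seed = 2)
  sums <- tapply(ss$share, ss$center_year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("category enrichment matches log2 of observed over expected", {
  # 2 genes new this year, 2 old; pairs concentrate on the new ones
  at <- age_table_of(c("n1", "n2", "o1", "o2"), c(2010, 2010, 2000, 2000))
  pairs <- pair_table(1:4, c("n1", "n2", "n1", "o1"), 2010)
  es <- category_enrichment_series(pairs, at, window = 1, n_boot = 20,
                                   seed = 1)
  w <- es[es$center_year == 2010]
  # observed new share 0.75 vs expected 0.5 -> log2(1.5)
  expect_equal(w$log2_enrichment[w$class == "new"], log2(0.75 / 0.5))
  # recent observed 0 with positive expected? expected recent is 0 here
  expect_true(is.na(w$log2_enrichment[w$class == "recent"]))
  # observed equals expected -> 0
  pairs_bal <- pair_table(1:4, c("n1", "n2", "o1", "o2"), 2010)
  es_bal <- category_enrichment_series(pairs_bal, at, window = 1,
                                       n_boot = 20, seed = 1)
  wb <- es_bal[es_bal$center_year == 2010]
  expect_equal(wb$log2_enrichment[wb$class == "new"], 0)
})

test_that("enrichment is invariant to uniform weight rescaling and flags zero cells", {
  co <- small_corpus(seed = 19L, noise = FALSE)
  at <- first_highlight_years(co$truth$pairs)
  genes <- at$gene_id
  w1 <- stats::setNames(rep(1, length(genes)), genes)
  wk <- w1 * 7.3
  e1 <- category_enrichment_series(co$truth$pairs, at, weights = w1,
                                   n_boot = 10, seed = 3)
  ek <- category_enrichment_series(co$truth$pairs, at, weights = wk,
                                   n_boot = 10, seed = 3)
  expect_equal(e1$log2_enrichment, ek$log2_enrichment)
  expect_error(category_enrichment_series(co$truth$pairs, at,
                                          weights = w1 * 0, n_boot = 10),
               "zero")
  # a class with zero observed pairs but positive expectation -> -Inf
  at2 <- age_table_of(c("n1", "r1", "o1"), c(2010, 2008, 2000))
  pairs2 <- pair_table(1:2, c("n1", "o1"), 2010)
  e2 <- category_enrichment_series(pairs2, at2, window = 1, n_boot = 10,
                                   seed = 1)
  expect_true(is.infinite(e2$log2_enrichment[e2$class == "recent"]) &&
                e2$log2_enrichment[e2$class == "recent"] < 0)
})

test_that("decade aggregation uses the youngest-class rule and hand means", {
  recs <- pub_records(
    pub_record(1, year = 1992, n_authors = 2),
    pub_record(2, year = 1993, n_authors = 4),
    pub_record(3, year = 1994, n_authors = 10))
  # pub 3 highlights one new and three old genes -> classed new
  pairs <- pair_table(c(1, 2, 3, 3, 3, 3),
                      c("o1", "o1", "n1", "o1", "o2", "o3"),
                      c(1992, 1993, 1994, 1994, 1994, 1994))
  at <- age_table_of(c("o1", "o2", "o3", "n1"), c(1980, 1980, 1980, 1994))
  pc <- publication_age_class(pairs, at)
  expect_equal(pc$class[pc$pmid == 3], "new")
  agg <- decade_aggregate(recs, pairs, at, "mean_authors", n_boot = 20,
                          seed = 1)
  old_cell <- agg[agg$decade == "1990-1999" & agg$class == "old"]
  expect_equal(old_cell$value, 3)       # mean of 2 and 4
  expect_equal(old_cell$n_pubs, 2L)
  med <- decade_aggregate(recs, pairs, at, "median_authors", n_boot = 20,
                          seed = 1)
  expect_equal(med$value[med$decade == "1990-1999" & med$class == "old"], 3)
  genes <- decade_aggregate(recs, pairs, at, "mean_genes", n_boot = 20,
                            seed = 1)
  expect_equal(genes$value[genes$decade == "1990-1999" & genes$class == "new"], 4)
  # empty cells are absent, not zero
  expect_false("recent" %in% agg$class)
})

test_that("preferential reuse yields correlated per-gene volumes across periods", {
  co <- generate_corpus(corpus_params(
    n_genes = 300L, years = 1990:2014, pubs_per_year = 60L,
    novelty_rate = 0.15, attachment_exponent = 1.2, noise = FALSE,
    seed = 23L))
  p <- co$truth$pairs
  early <- table(p$gene_id[p$pub_year <= 2005])
  late <- table(p$gene_id[p$pub_year > 2005])
  genes <- intersect(names(early), names(late))
  rho <- spearman_cor(as.numeric(early[genes]), as.numeric(late[genes]))
  expect_gt(rho, 0.5)
})
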