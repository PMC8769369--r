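node_meta <- function(pmid, year, types = "D016428:Journal Article",
                      citation_count = NULL) {
  out <- data.table::data.table(pmid = as.integer(pmid),
                                year = as.integer(year),
                                publication_types = lapply(seq_along(pmid),
                                                           function(i) types))
  if (!is.null(citation_count)) out$citation_count <- as.integer(citation_count)
  out
}

test_that("citation graph drops self-citations and demands full metadata", {
  edges <- data.table::data.table(citing_pmid = c(1L, 2L, 2L),
                                  cited_pmid = c(1L, 1L, 3L))
  g <- citation_graph(edges, node_meta(1:3, c(2000, 2005, 1999)))
  expect_equal(nrow(g$edges), 2L)
  expect_error(citation_graph(edges, node_meta(1:2, c(2000, 2005))),
               "metadata missing")
})

test_that("highly-cited flags sit at the top five percent of a year cohort", {
  nodes <- node_meta(1:100, 2010, citation_count = 100:1)
  g <- citation_graph(data.table::data.table(citing_pmid = integer(0),
                                             cited_pmid = integer(0)),
                      nodes)
  hc <- highly_cited_table(g)
  expect_true(hc$highly_cited[hc$pmid == 1L])        # rank-1 paper
  expect_equal(sum(hc$highly_cited), 5L)             # tie-free: exactly 5%
  expect_equal(hc$percentile[hc$pmid == 1L], 99.5)
  expect_false(any(hc$low_cohort))
  small <- highly_cited_table(citation_graph(
    data.table::data.table(citing_pmid = integer(0), cited_pmid = integer(0)),
    node_meta(1:5, 2010, citation_count = 5:1)))
  expect_true(all(small$low_cohort))
})

test_that("uniform citation counts give a flagged share near the 5% baseline", {
  set.seed(8)
  nodes <- node_meta(1:4000, rep(2000:2003, each = 1000),
                     citation_count = sample.int(10000, 4000))
  g <- citation_graph(data.table::data.table(citing_pmid = integer(0),
                                             cited_pmid = integer(0)), nodes)
  hc <- highly_cited_table(g)
  expect_equal(mean(hc$highly_cited), 0.05, tolerance = 0.01)
})

test_that("citation variability uses linear-interpolation quartiles", {
  pt <- data.table::data.table(pmid = 1:4, percentile = c(10, 40, 60, 90))
  pc <- data.table::data.table(pmid = 1:4, pub_year = 2010L, class = "old")
  cv <- citation_variability(pt, pc, window = 3)
  # type-7 quartiles of (10, 40, 60, 90): 32.5 and 67.5
  expect_equal(cv$iqr_width, 35)
  # identical percentiles -> zero width
  pt0 <- data.table::data.table(pmid = 1:5, percentile = rep(42, 5))
  pc0 <- data.table::data.table(pmid = 1:5, pub_year = 2010L, class = "old")
  expect_equal(citation_variability(pt0, pc0)$iqr_width, 0)
  # large uniform sample approaches width 50
  set.seed(2)
  ptu <- data.table::data.table(pmid = 1:5000, percentile = runif(5000, 0, 100))
  pcu <- data.table::data.table(pmid = 1:5000, pub_year = 2010L, class = "old")
  expect_equal(citation_variability(ptu, pcu)$iqr_width, 50, tolerance = 0.05)
  # fewer than 4 members -> cell absent
  expect_equal(nrow(citation_variability(pt[1:3], pc[1:3])), 0L)
})

test_that("clinical-trial detection is case-folded substring matching", {
  expect_true(is_clinical_trial("Clinical Trial, Phase II"))
  expect_true(is_clinical_trial("clinical TRIAL"))
  expect_false(is_clinical_trial("D016454:Review"))
  expect_equal(is_clinical_trial(list(c("A", "Clinical Trial"), "B")),
               c(TRUE, FALSE))
})

test_that("clinical citation stats find the first trial citer with a floor at zero", {
  edges <- data.table::data.table(
    citing_pmid = c(11L, 12L, 13L), cited_pmid = c(1L, 1L, 2L))
  nodes <- rbind(node_meta(1:2, c(2000, 2010)),
                 node_meta(11L, 2005, types = "Clinical Trial, Phase I"),
                 node_meta(12L, 2003, types = "clinical trial"),
                 node_meta(13L, 2010, types = "Clinical Trial"))
  g <- citation_graph(edges, nodes)
  cc <- clinical_citation_stats(g, c(1L, 2L))
  expect_equal(cc$cited_by_trial, c(TRUE, TRUE))
  expect_equal(cc$years_to_first[cc$pmid == 1L], 3L)   # 2003 - 2000
  expect_equal(cc$years_to_first[cc$pmid == 2L], 0L)   # same-year floor
  # uncited publication
  cc2 <- clinical_citation_stats(g, 13L)
  expect_false(cc2$cited_by_trial)
  expect_true(is.na(cc2$years_to_first))
})

test_that("disruption index reproduces the worked fixture and edge cases", {
  fx <- make_toy_fixture("disruption-0.4")
  d <- disruption_index(fx$graph, fx$focal)
  expect_equal(d$n_focal_only, fx$expected$n_focal_only)
  expect_equal(d$n_both, fx$expected$n_both)
  expect_equal(d$n_ref_only, fx$expected$n_ref_only)
  expect_equal(d$d_index, fx$expected$d_index)
  # all citers cite focal only -> maximally disruptive
  e2 <- data.table::data.table(citing_pmid = c(2L, 3L), cited_pmid = 1L)
  g2 <- citation_graph(e2, node_meta(1:3, c(2000, 2005, 2006)))
  expect_equal(disruption_index(g2, 1L)$d_index, 1.0)
  # balance: n_focal_only == n_both, no ref-only citers
  e3 <- data.table::data.table(
    citing_pmid = c(10L, 20L, 20L, 30L), cited_pmid = c(5L, 10L, 5L, 10L))
  g3 <- citation_graph(e3, node_meta(c(5L, 10L, 20L, 30L),
                                     c(1990, 2000, 2005, 2006)))
  d3 <- disruption_index(g3, 10L)
  expect_equal(d3$n_focal_only, 1L)
  expect_equal(d3$n_both, 1L)
  expect_equal(d3$d_index, 0.0)
  # no citers at all -> undefined
  e4 <- data.table::data.table(citing_pmid = 9L, cited_pmid = 8L)
  g4 <- citation_graph(e4, node_meta(8:9, c(2000, 2001)))
  expect_true(is.na(disruption_index(g4, 9L)$d_index))
})

test_that("disruption agrees with the brute-force citer classifier on random graphs", {
  set.seed(14)
  for (rep in 1:40) {
    edges <- random_citation_graph(sample(10:50, 1))
    if (nrow(edges) == 0L) next
    nodes <- node_meta(sort(unique(c(edges$citing_pmid, edges$cited_pmid))),
                       2000)
    g <- citation_graph(edges, nodes)
    focal <- sample(nodes$pmid, 1)
    got <- disruption_index(g, focal)
    want <- disruption_oracle(edges, focal)
    expect_equal(got$n_focal_only, want$n_focal_only)
    expect_equal(got$n_both, want$n_both)
    expect_equal(got$n_ref_only, want$n_ref_only)
    expect_equal(got$d_index, want$d_index)
    expect_true(is.na(got$d_index) || abs(got$d_index) <= 1)
  }
})

test_that("a references-only citer strictly lowers the disruption index", {
  fx <- make_toy_fixture("disruption-0.4")
  g <- fx$graph
  extra <- data.table::data.table(citing_pmid = 206L, cited_pmid = 1L)
  nodes2 <- rbind(g$nodes[, c("pmid", "year", "publication_types"),
                          with = FALSE],
                  node_meta(206L, 2006L))
  g2 <- citation_graph(rbind(g$edges, extra), nodes2)
  expect_lt(disruption_index(g2, fx$focal)$d_index,
            disruption_index(g, fx$focal)$d_index)
})

test_that("batch disruption percentiles match the single-focal computation", {
  set.seed(15)
  edges <- random_citation_graph(40)
  nodes <- node_meta(sort(unique(c(edges$citing_pmid, edges$cited_pmid))),
                     rep(c(2000L, 2001L), length.out =
                           length(unique(c(edges$citing_pmid,
                                           edges$cited_pmid)))))
  g <- citation_graph(edges, nodes)
  batch <- disruption_percentiles(g)
  for (p in utils::head(nodes$pmid, 10)) {
    expect_equal(batch$d_index[batch$pmid == p],
                 disruption_index(g, p)$d_index)
  }
  ok <- !is.na(batch$d_index)
  expect_true(all(batch$percentile[ok] >= 0 & batch$percentile[ok] <= 100))
})
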