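test_that("publications survive a write-then-read round trip", {
  co <- small_corpus(seed = 21L, noise = FALSE)
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  rec <- read_publications(file.path(dir, "publications.tsv"))
  expect_equal(nrow(rec), nrow(co$publications))
  expect_identical(rec$pmid, co$publications$pmid)
  expect_identical(rec$title, co$publications$title)
  expect_identical(rec$keywords, co$publications$keywords)
  expect_identical(rec$publication_types, co$publications$publication_types)
  expect_identical(rec$n_authors, co$publications$n_authors)
  expect_identical(rec$citation_count, co$publications$citation_count)
})

test_that("loader tolerates empty abstracts and duplicated pmids", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pubs.tsv")
  hdr <- paste(c("pmid", "year", "journal", "title", "abstract", "keywords",
                 "mesh_terms", "publication_types", "n_authors", "funders",
                 "activity_codes", "organizations"), collapse = "\t")
  row <- function(pmid) {
    paste(c(pmid, "2001", "J01", "T", "", "k1|k2", "", "D016428:Journal Article",
            "2", "", "", ""), collapse = "\t")
  }
  writeLines(c(hdr, row(1), row(1), row(2)), path)
  rec <- read_publications(path)
  expect_equal(nrow(rec), 3L)           # dedup deferred to the filter stage
  expect_identical(rec$abstract, c("", "", ""))
  expect_identical(rec$keywords[[1]], c("k1", "k2"))
  expect_identical(rec$mesh_terms[[1]], character(0))
})

test_that("loader errors name the missing column and the bad pmid", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pubs.tsv")
  writeLines(c("pmid\tyear", "1\t2001"), path)
  expect_error(read_publications(path), "journal")
  path2 <- file.path(dir, "pubs2.tsv")
  hdr <- paste(c("pmid", "year", "journal", "title", "abstract", "keywords",
                 "mesh_terms", "publication_types", "n_authors", "funders",
                 "activity_codes", "organizations"), collapse = "\t")
  writeLines(c(hdr, paste(c("77", "MMXI", "J", "T", "", "", "", "", "1",
                            "", "", ""), collapse = "\t")), path2)
  expect_error(read_publications(path2), "77")
})

test_that("research filter removes excluded types, late years, and duplicated pmids", {
  recs <- pub_records(
    pub_record(1, year = 2010, publication_types = c("D016454:Review")),
    pub_record(2, year = 2019),
    pub_record(3, year = 2010),
    pub_record(4, year = 2010),
    pub_record(4, year = 2011),
    pub_record(5, year = 2018,
               publication_types = c("D016428:Journal Article",
                                     "D020470:Collected Works")))
  out <- filter_research_publications(recs, year_max = 2018)
  expect_identical(out$pmid, 3L)
  # idempotence
  expect_identical(filter_research_publications(out, year_max = 2018), out)
})

test_that("adding an excluded type never increases the surviving count", {
  co <- small_corpus(seed = 4L)
  base_types <- medline_excluded_types()
  n0 <- nrow(filter_research_publications(co$publications,
                                          excluded_types = character(0)))
  prev <- n0
  for (k in c(1L, 10L, length(base_types))) {
    n <- nrow(filter_research_publications(
      co$publications, excluded_types = base_types[seq_len(k)]))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("mention sections follow the offset arithmetic", {
  expect_equal(locate_mention_section(0L, "0123456789", "abc"), "title")
  # abstract starts at len(title) + sep_len; the separator itself is beyond
  expect_equal(locate_mention_section(11L, "0123456789", "abc"), "abstract")
  expect_equal(locate_mention_section(10L, "0123456789", "abc"), "beyond")
  expect_equal(locate_mention_section(50L, "0123456789", "abc"), "beyond")
  expect_error(locate_mention_section(-1L, "t", "a"), "negative")
  # exhaustive span check against direct substring arithmetic
  ttl <- "short title"; abs_ <- "an abstract body"
  for (off in 0:(nchar(ttl) + 1 + nchar(abs_) + 3)) {
    expected <- if (off < nchar(ttl)) "title"
      else if (off >= nchar(ttl) + 1 && off < nchar(ttl) + 1 + nchar(abs_)) "abstract"
      else "beyond"
    expect_equal(locate_mention_section(off, ttl, abs_), expected)
  }
})

test_that("highlight table applies every mention and registry filter", {
  recs <- pub_records(
    pub_record(1, year = 2005, title = "AAAA BBBB", abstract = "CCCC AAAA"),
    pub_record(2, year = 2006, title = "DDDD", abstract = ""))
  mentions <- data.table::data.table(
    pmid = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    char_offset = c(0L, 5L, 10L, 15L, 0L, 0L, 0L),
    mention_text = c("AAAA", "BBBB", "CCCC", "AAAA", "AAAA", "DDDD", "DDDD"),
    gene_id = c("g1", "g2;g9", "g3", "g1", "g1", "g4", "g5"))
  registry <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    symbol = c("AAAA", "BBBB", "CCCC", "DDDD", "DDDD"),
    tax_id = c(9606L, 9606L, 9606L, 9606L, 10090L),
    gene_type = c("protein-coding", "protein-coding", "ncRNA",
                  "protein-coding", "protein-coding"),
    lof_intolerant = FALSE, murine_phenotype_count = 0L,
    gwas_trait_count = 0L)
  links <- data.table::data.table(tax_id = c(9606L, 10090L),
                                  gene_id = c("g1", "g4"),
                                  pmid = c(1L, 2L))
  out <- build_highlight_table(recs, mentions, links, registry)
  # pmid 2 only linked for a foreign taxon -> dropped entirely;
  # g2;g9 ambiguous, g3 non-coding; g1 mentioned twice -> one pair with
  # union of sections
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_id, "g1")
  expect_true(out$in_title && out$in_abstract)
  # uniqueness invariant
  expect_false(anyDuplicated(out[, c("pmid", "gene_id")]) > 0)
  # empty mentions are allowed
  empty <- build_highlight_table(recs, mentions[0], links, registry)
  expect_equal(nrow(empty), 0L)
})

test_that("generator output read back reproduces the ground-truth pair table", {
  co <- small_corpus(seed = 31L, noise = TRUE)
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  rec <- filter_research_publications(
    read_publications(file.path(dir, "publications.tsv")))
  pairs <- build_highlight_table(
    rec, read_mentions(file.path(dir, "mentions.tsv")),
    read_gene_links(file.path(dir, "gene2pubmed.tsv")),
    read_gene_registry(file.path(dir, "gene_info.tsv")))
  expect_equal(as.data.frame(pairs), as.data.frame(co$truth$pairs))
})
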