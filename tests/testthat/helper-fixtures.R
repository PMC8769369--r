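# In-code fixture builders shared across the test files. All fixtures are
# constructed programmatically; nothing is read from disk except files the
# tests themselves write to tempdirs.

# one publication record row with sensible defaults
pub_record <- function(pmid, year = 2010L, journal = "J01",
                       title = "A study", abstract = "",
                       keywords = character(0), mesh_terms = character(0),
                       publication_types = "D016428:Journal Article",
                       n_authors = 3L, funders = character(0),
                       activity_codes = character(0),
                       organizations = character(0)) {
  data.table::data.table(
    pmid = as.integer(pmid), year = as.integer(year), journal = journal,
    title = title, abstract = abstract, keywords = list(keywords),
    mesh_terms = list(mesh_terms), publication_types = list(publication_types),
    n_authors = as.integer(n_authors), funders = list(funders),
    activity_codes = list(activity_codes), organizations = list(organizations))
}

pub_records <- function(...) data.table::rbindlist(list(...))

# minimal highlight-pair table
pair_table <- function(pmid, gene_id, pub_year, in_title = TRUE,
                       in_abstract = TRUE) {
  data.table::data.table(pmid = as.integer(pmid), gene_id = gene_id,
                         pub_year = as.integer(pub_year),
                         in_title = in_title, in_abstract = in_abstract)
}

age_table_of <- function(gene_id, first_year, first_year_title = NA_integer_) {
  data.table::data.table(gene_id = gene_id,
                         first_year = as.integer(first_year),
                         first_year_title = as.integer(first_year_title))
}

# a small but non-trivial synthetic corpus reused by several test files
small_corpus <- function(seed = 11L, noise = TRUE) {
  generate_corpus(corpus_params(
    n_genes = 400L, years = 1995:2014, pubs_per_year = 25L,
    noise = noise, seed = seed))
}

# brute-force disruption oracle: explicit set classification of every
# potential citer, independent of the graph-indexing implementation
disruption_oracle <- function(edges, focal) {
  refs <- unique(edges$cited_pmid[edges$citing_pmid == focal])
  nodes <- setdiff(unique(c(edges$citing_pmid, edges$cited_pmid)), focal)
  nf <- nb <- nr <- 0L
  for (z in nodes) {
    cited_by_z <- edges$cited_pmid[edges$citing_pmid == z]
    cf <- focal %in% cited_by_z
    cr <- any(refs %in% cited_by_z)
    if (cf && cr) nb <- nb + 1L
    else if (cf) nf <- nf + 1L
    else if (cr) nr <- nr + 1L
  }
  denom <- nf + nb + nr
  list(n_focal_only = nf, n_both = nb, n_ref_only = nr,
       d_index = if (denom > 0) (nf - nb) / denom else NA_real_)
}

# random citation DAG on n nodes (edges only point back in time)
random_citation_graph <- function(n, p_edge = 0.15) {
  edges <- list()
  for (i in 2:n) {
    cited <- which(stats::runif(i - 1L) < p_edge)
    if (length(cited)) {
      edges[[length(edges) + 1L]] <-
        data.table::data.table(citing_pmid = i, cited_pmid = cited)
    }
  }
  if (length(edges) == 0L) {
    return(data.table::data.table(citing_pmid = integer(0),
                                  cited_pmid = integer(0)))
  }
  data.table::rbindlist(edges)
}

# enumeration oracle for the two-sided Fisher p-value: table probabilities
# recomputed from log-binomial coefficients (not dhyper), same
# probability-mass rule
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- exp(lchoose(r1, lo:hi) + lchoose(r2, c1 - (lo:hi)) -
                 lchoose(r1 + r2, c1))
  pobs <- probs[a - lo + 1L]
  min(sum(probs[probs <= pobs * (1 + rel_tol)]), 1)
}
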