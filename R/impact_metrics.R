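# Citation-based reception metrics: within-year percentiles and top-5%
# flags, citation-variability windows, clinical-trial citation, and the
# disruption index on the citing->cited graph.

#' Build a citation graph
#'
#' Directed citing -> cited edges with per-node metadata. Self-citation
#' edges are dropped on loading. Node metadata (year, publication types,
#' and total citation count) must cover every pmid referenced by an edge;
#' the citation count may exceed the in-graph in-degree when citers outside
#' the loaded edge list are tallied upstream — such metadata-only citers
#' contribute to percentile metrics but not to disruption classification.
#'
#' @param edges A `data.table`/data.frame with columns `citing_pmid`,
#'   `cited_pmid`.
#' @param nodes Node metadata with columns `pmid`, `year`,
#'   `publication_types` (list column), and optionally `citation_count`
#'   (defaults to the in-graph in-degree).
#' @return An object of class `citation_graph`.
#' @export
citation_graph <- function(edges, nodes) {
  edges <- data.table::as.data.table(edges)
  nodes <- data.table::as.data.table(nodes)
  assert_columns(edges, c("citing_pmid", "cited_pmid"), "edges")
  assert_columns(nodes, c("pmid", "year", "publication_types"), "nodes")
  edges <- edges[edges$citing_pmid != edges$cited_pmid]
  referenced <- unique(c(edges$citing_pmid, edges$cited_pmid))
  missing <- setdiff(referenced, nodes$pmid)
  if (length(missing)) {
    stopf("node metadata missing for %d pmid(s), e.g. %s",
          length(missing), missing[1L])
  }
  if (!"citation_count" %in% names(nodes)) {
    indeg <- table(edges$cited_pmid)
    nodes$citation_count <- as.integer(indeg[as.character(nodes$pmid)])
    nodes$citation_count[is.na(nodes$citation_count)] <- 0L
  }
  structure(list(edges = edges, nodes = nodes), class = "citation_graph")
}

#' @export
print.citation_graph <- function(x, ...) {
  cat(sprintf("citation graph: %d nodes, %d edges, years %d-%d\n",
              nrow(x$nodes), nrow(x$edges), min(x$nodes$year),
              max(x$nodes$year)))
  invisible(x)
}

#' Highly-cited flags within publication-year cohorts
#'
#' Midrank percentile of each node's citation count within its
#' publication-year cohort; nodes at or above the 95th percentile are
#' flagged highly cited (the "top 5% of year of publication"). Cohorts
#' smaller than 20 publications still yield a flag but are marked
#' `low_cohort`.
#'
#' @param graph A [citation_graph()].
#' @return A `data.table` with columns `pmid`, `year`, `citation_count`,
#'   `percentile`, `highly_cited`, `low_cohort`.
#' @export
highly_cited_table <- function(graph) {
  nodes <- data.table::copy(graph$nodes)
  citation_count <- NULL
  nodes[, `:=`(percentile = cohort_percentiles(citation_count),
               low_cohort = .N < 20L), by = "year"]
  nodes$highly_cited <- nodes$percentile >= 95
  nodes[, c("pmid", "year", "citation_count", "percentile", "highly_cited",
            "low_cohort"), with = FALSE]
}

#' Citation variability per sliding window and age class
#'
#' The width of the interquartile range (linear-interpolation quartiles,
#' R type 7) of the within-year citation percentiles of the class members
#' in a sliding window. Cells with fewer than 4 members are absent.
#'
#' @param percentile_table Output of [highly_cited_table()] (or any table
#'   with `pmid` and `percentile`).
#' @param pub_class Output of [publication_age_class()].
#' @param window Odd window width; default 3.
#' @return A `data.table` with columns `center_year`, `class`, `iqr_width`,
#'   `n`.
#' @export
citation_variability <- function(percentile_table, pub_class, window = 3L) {
  if (window %% 2L == 0L) stopf("window must be odd")
  half <- (window - 1L) %/% 2L
  d <- merge(pub_class[, c("pmid", "pub_year", "class"), with = FALSE],
             percentile_table[, c("pmid", "percentile"), with = FALSE],
             by = "pmid")
  centers <- sort(unique(d$pub_year))
  res <- list()
  for (cy in centers) {
    for (k in AGE_CLASSES) {
      v <- d$percentile[d$class == k & abs(d$pub_year - cy) <= half]
      if (length(v) < 4L) next
      q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
      res[[length(res) + 1L]] <- data.table::data.table(
        center_year = cy, class = k, iqr_width = q[2L] - q[1L],
        n = length(v))
    }
  }
  data.table::rbindlist(res)
}

#' Clinical-trial flag from publication types
#'
#' TRUE iff any publication-type string contains the substring
#' `"clinical trial"` after case-folding (deliberately substring-based, so
#' phase-qualified trial types match).
#'
#' @param publication_types List column (or single character vector) of
#'   publication-type strings.
#' @return Logical vector.
#' @export
is_clinical_trial <- function(publication_types) {
  if (!is.list(publication_types)) publication_types <- list(publication_types)
  vapply(publication_types, function(tt) {
    any(grepl("clinical trial", tolower(tt), fixed = TRUE))
  }, logical(1))
}

#' Clinical-trial citation per publication
#'
#' For each node, whether it is cited by at least one clinical trial, and
#' the years from its publication to its first trial citation (floored at
#' zero; `NA` when never cited by a trial).
#'
#' @param graph A [citation_graph()].
#' @param pmids Optional pmid subset; default all nodes.
#' @return A `data.table` with columns `pmid`, `cited_by_trial`,
#'   `years_to_first`.
#' @export
clinical_citation_stats <- function(graph, pmids = NULL) {
  nodes <- graph$nodes
  if (is.null(pmids)) pmids <- nodes$pmid
  trial_pmids <- nodes$pmid[is_clinical_trial(nodes$publication_types)]
  e <- graph$edges[graph$edges$citing_pmid %in% trial_pmids &
                     graph$edges$cited_pmid %in% pmids]
  year_map <- stats::setNames(nodes$year, as.character(nodes$pmid))
  e$citing_year <- year_map[as.character(e$citing_pmid)]
  cited_pmid <- citing_year <- NULL
  first <- if (nrow(e)) {
    e[, list(first_year = min(citing_year)), by = "cited_pmid"]
  } else {
    data.table::data.table(cited_pmid = integer(0), first_year = integer(0))
  }
  out <- data.table::data.table(pmid = pmids)
  out <- merge(out, first, by.x = "pmid", by.y = "cited_pmid", all.x = TRUE)
  out$cited_by_trial <- !is.na(out$first_year)
  out$years_to_first <- pmax(0L, out$first_year -
                               as.integer(year_map[as.character(out$pmid)]))
  out$first_year <- NULL
  out[]
}

#' Disruption index of a focal publication
#'
#' Over all publications citing the focal paper or at least one of its
#' references, classifies each citer as citing the focal only, both, or
#' references only, and returns
#' `d = (n_focal_only - n_both) / (n_focal_only + n_both + n_ref_only)`.
#' `+1` is maximally disruptive (citers ignore the focal paper's
#' references), `-1` maximally consolidating. The focal publication itself
#' is excluded from the citer sets; citations from the focal year are
#' included. When no publication cites the focal paper or its references,
#' the index is undefined (`NA`).
#'
#' @param graph A [citation_graph()].
#' @param pmid Focal publication id.
#' @return A one-row `data.table` with columns `pmid`, `n_focal_only`,
#'   `n_both`, `n_ref_only`, `d_index`.
#' @export
disruption_index <- function(graph, pmid) {
  e <- graph$edges
  refs <- e$cited_pmid[e$citing_pmid == pmid]
  citers_focal <- unique(e$citing_pmid[e$cited_pmid == pmid])
  citers_refs <- unique(e$citing_pmid[e$cited_pmid %in% refs])
  citers_focal <- setdiff(citers_focal, pmid)
  citers_refs <- setdiff(citers_refs, pmid)
  n_both <- length(intersect(citers_focal, citers_refs))
  n_focal_only <- length(citers_focal) - n_both
  n_ref_only <- length(citers_refs) - n_both
  denom <- n_focal_only + n_both + n_ref_only
  data.table::data.table(
    pmid = pmid, n_focal_only = n_focal_only, n_both = n_both,
    n_ref_only = n_ref_only,
    d_index = if (denom > 0) (n_focal_only - n_both) / denom else NA_real_)
}

#' Disruption indices with within-year percentiles
#'
#' Computes the disruption index for each requested publication and its
#' midrank percentile among the defined indices of the same
#' publication-year cohort.
#'
#' @param graph A [citation_graph()].
#' @param pmids Optional pmid subset; default all nodes.
#' @return A `data.table` with the [disruption_index()] columns plus
#'   `year` and `percentile`.
#' @export
disruption_percentiles <- function(graph, pmids = NULL) {
  if (is.null(pmids)) pmids <- graph$nodes$pmid
  e <- graph$edges
  refs_by_citing <- split(e$cited_pmid, e$citing_pmid)
  citers_by_cited <- split(e$citing_pmid, e$cited_pmid)
  one <- function(p) {
    key <- as.character(p)
    refs <- refs_by_citing[[key]]
    cf <- setdiff(unique(citers_by_cited[[key]]), p)
    cr <- if (length(refs)) {
      setdiff(unique(unlist(citers_by_cited[as.character(refs)],
                            use.names = FALSE)), p)
    } else {
      integer(0)
    }
    n_both <- length(intersect(cf, cr))
    nf <- length(cf) - n_both
    nr <- length(cr) - n_both
    denom <- nf + n_both + nr
    data.table::data.table(
      pmid = p, n_focal_only = nf, n_both = n_both, n_ref_only = nr,
      d_index = if (denom > 0) (nf - n_both) / denom else NA_real_)
  }
  out <- data.table::rbindlist(lapply(pmids, one))
  year_map <- stats::setNames(graph$nodes$year,
                              as.character(graph$nodes$pmid))
  out$year <- as.integer(year_map[as.character(out$pmid)])
  d_index <- NULL
  out[, percentile := {
    p <- rep(NA_real_, .N)
    ok <- !is.na(d_index)
    if (any(ok)) p[ok] <- cohort_percentiles(d_index[ok])
    p
  }, by = "year"]
  out[]
}

utils::globalVariables(c("percentile", ":=", ".N"))
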