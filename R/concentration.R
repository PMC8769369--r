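# Concentration of early-stage research: ranking recent gene targets by
# publication volume, cumulative pair shares, the top-set definition,
# journal x gene matrices with Ward clustering, and the top-set ablation.

#' Rank recent gene targets by publication volume
#'
#' Eligible genes are those first highlighted such that they occupy the
#' recent class (age 1-5) during at least one year of the period, i.e.
#' first highlighted between `period_start - 5` and `period_end - 1`
#' (overlapping, shifting time windows). Each eligible gene is scored by
#' the number of (publication, gene) pairs in the period in which it is
#' recent at publication time; never-again-highlighted genes score 0.
#' Ranks are 0-based (rank 0 = most published), ties broken by ascending
#' gene id for determinism.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param period Year range (min/max used).
#' @return A `data.table` with columns `gene_id`, `first_year`,
#'   `n_recent_pairs`, `rank`, `cum_share`; cumulative share is
#'   nondecreasing and reaches 1 at the last rank.
#' @export
rank_recent_targets <- function(pairs, age_table, period) {
  if (length(period) == 0L) stopf("empty period")
  lo <- min(period); hi <- max(period)
  eligible <- age_table[age_table$first_year >= lo - 5L &
                          age_table$first_year <= hi - 1L]
  if (nrow(eligible) == 0L) stopf("no eligible recently highlighted genes")
  p <- .classified_pairs(pairs, age_table)
  p <- p[p$pub_year >= lo & p$pub_year <= hi & p$class == "recent"]
  counts <- table(p$gene_id)
  out <- data.table::data.table(
    gene_id = eligible$gene_id,
    first_year = eligible$first_year,
    n_recent_pairs = as.integer(counts[eligible$gene_id]))
  out$n_recent_pairs[is.na(out$n_recent_pairs)] <- 0L
  data.table::setorder(out, -n_recent_pairs, gene_id)
  out$rank <- seq_len(nrow(out)) - 1L
  tot <- sum(out$n_recent_pairs)
  if (tot == 0L) stopf("no recent-target pairs in the period")
  out$cum_share <- cumsum(out$n_recent_pairs) / tot
  data.table::setattr(out, "period", c(lo, hi))
  out[]
}

#' Top-ranked gene set and its pair share
#'
#' The `ceiling(fraction * n_eligible)` top-ranked genes from a rank table
#' and their combined share of recent-target pairs.
#'
#' @param rank_table Output of [rank_recent_targets()].
#' @param fraction Fraction of the eligible newly highlighted genes;
#'   default 0.01 (the "top 1 percent").
#' @return A list with `genes` (character vector), `k` (set size), and
#'   `share` (combined cumulative pair share).
#' @export
top_set <- function(rank_table, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  k <- as.integer(ceiling(fraction * nrow(rank_table)))
  list(genes = rank_table$gene_id[seq_len(k)], k = k,
       share = rank_table$cum_share[k])
}

#' Per-journal share of recent-target pairs on a top gene set
#'
#' For each requested journal, the percentage of its period recent-target
#' pairs that fall onto the top genes. Journals with zero recent pairs in
#' the period are absent from the output.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param records Filtered publications (journal lookup).
#' @param journals Journals to report (e.g. those flagged
#'   disproportionately recent).
#' @param top_genes Character vector of top-set gene ids.
#' @param period Year range.
#' @return A `data.table` with columns `journal`, `n_recent_pairs`,
#'   `n_on_top`, `pct_on_top` (in `[0, 100]`).
#' @export
journal_topk_share <- function(pairs, age_table, records, journals,
                               top_genes, period) {
  lo <- min(period); hi <- max(period)
  jmap <- stats::setNames(records$journal, as.character(records$pmid))
  p <- .classified_pairs(pairs, age_table)
  p <- p[p$pub_year >= lo & p$pub_year <= hi & p$class == "recent"]
  p$journal <- jmap[as.character(p$pmid)]
  p <- p[p$journal %in% journals]
  if (nrow(p) == 0L) {
    return(data.table::data.table(journal = character(0),
                                  n_recent_pairs = integer(0),
                                  n_on_top = integer(0),
                                  pct_on_top = numeric(0)))
  }
  gene_id <- NULL
  out <- p[, list(n_recent_pairs = .N,
                  n_on_top = sum(gene_id %in% top_genes)), by = "journal"]
  out$pct_on_top <- 100 * out$n_on_top / out$n_recent_pairs
  data.table::setorder(out, journal)
  out[]
}

#' Journal x gene percentage matrix
#'
#' Cell (journal, gene) holds the percentage of the journal's period
#' publications (all its publications in the filtered corpus, whether or
#' not they highlight a gene) that highlight the gene while it is a recent
#' target. Rows for journals without publications in the period are
#' absent; row sums may exceed 100 when publications highlight several of
#' the genes (no normalization is applied).
#'
#' @param pairs Highlight table.
#' @param records Filtered publications.
#' @param age_table Output of [first_highlight_years()].
#' @param journals Row journals.
#' @param genes Column genes (typically the top-set genes highlighted at
#'   least once by the journals).
#' @param period Year range.
#' @return A numeric matrix with journal rows and gene columns, cells in
#'   `[0, 100]`.
#' @export
build_journal_gene_matrix <- function(pairs, records, age_table, journals,
                                      genes, period) {
  lo <- min(period); hi <- max(period)
  rec <- records[records$year >= lo & records$year <= hi &
                   records$journal %in% journals]
  denom <- table(rec$journal)
  journals <- journals[journals %in% names(denom)]
  p <- .classified_pairs(pairs, age_table)
  p <- p[p$pub_year >= lo & p$pub_year <= hi & p$class == "recent" &
           p$gene_id %in% genes & p$pmid %in% rec$pmid]
  jmap <- stats::setNames(rec$journal, as.character(rec$pmid))
  p$journal <- jmap[as.character(p$pmid)]
  m <- matrix(0, nrow = length(journals), ncol = length(genes),
              dimnames = list(journals, genes))
  if (nrow(p)) {
    tab <- table(factor(p$journal, levels = journals),
                 factor(p$gene_id, levels = genes))
    m <- 100 * sweep(unclass(tab), 1L, as.numeric(denom[journals]), "/")
  }
  m
}

#' Ward clustering of a journal x gene matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances of the raw percentage cells, applied independently
#' to rows and columns. Fewer than 2 rows (or columns) yield the identity
#' ordering. Dendrograms are also exported as Newick strings for
#' inspection.
#'
#' @param m Numeric matrix (finite cells).
#' @return A list with `row_order`, `col_order` (leaf orders),
#'   `row_hclust`, `col_hclust` (`hclust` objects or `NULL`), and
#'   `row_newick`, `col_newick`.
#' @export
ward_cluster <- function(m) {
  if (any(!is.finite(m))) stopf("matrix cells must be finite")
  side <- function(x) {
    if (nrow(x) < 2L) {
      return(list(order = seq_len(nrow(x)), hc = NULL, newick = NULL))
    }
    hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "ward.D2")
    nwk <- if (nrow(x) >= 3L) {
      ape::write.tree(ape::as.phylo(hc))
    } else {
      NULL
    }
    list(order = hc$order, hc = hc, newick = nwk)
  }
  r <- side(m)
  c_ <- side(t(m))
  list(row_order = r$order, col_order = c_$order,
       row_hclust = r$hc, col_hclust = c_$hc,
       row_newick = r$newick, col_newick = c_$newick)
}

#' Re-run the recent-target enrichment scan without the top genes
#'
#' Removes all pairs on the top-ranked genes and repeats
#' [enrichment_scan()] for recent targets over the same period, reporting
#' which significantly enriched groups survive the ablation. Gene ages are
#' kept from the full corpus.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param membership Output of [group_membership()].
#' @param top_genes Genes to remove (empty set = identical to the original
#'   scan).
#' @param period Year range.
#' @param ... Passed on to [enrichment_scan()].
#' @return The ablated scan (`data.table`), with attribute
#'   `surviving_enriched` listing the groups still significantly enriched.
#' @export
ablation_retest <- function(pairs, age_table, membership, top_genes, period,
                            ...) {
  kept <- pairs[!pairs$gene_id %in% top_genes]
  if (nrow(kept) == 0L) {
    out <- data.table::data.table(group = character(0),
                                  target_class = character(0),
                                  a = integer(0), b = integer(0),
                                  c = integer(0), d = integer(0),
                                  log2_fold = numeric(0), p_raw = numeric(0),
                                  significant = logical(0),
                                  direction = character(0))
    data.table::setattr(out, "surviving_enriched", character(0))
    return(out)
  }
  scan <- enrichment_scan(kept, age_table, membership,
                          target_class = "recent", period = period, ...)
  data.table::setattr(scan, "surviving_enriched",
                      scan$group[scan$significant &
                                   scan$direction == "enriched"])
  scan
}
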