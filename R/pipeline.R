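# End-to-end wiring: configuration, the staged pipeline, tidy result
# export, and a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Validates and completes a run configuration. Accepts a YAML file path or
#' a named list; unknown fields are rejected so typos fail before any
#' compute.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    input_dir = NULL,
    publications = NULL, mentions = NULL, links = NULL, registry = NULL,
    citations = NULL,
    taxon = 9606L, year_max = 2018L, window = 3L, alpha = 0.01,
    level = 0.95, n_boot = 200L, seed = 1L,
    period = c(2010L, 2018L), top_fraction = 0.01,
    min_group_size = 1L, token_bounded = TRUE,
    gb_lexicon = "genome_biology", gwas_lexicon = "gwas",
    catalog_pmids = integer(0),
    compute_impact = TRUE, compute_disruption = FALSE,
    out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$input_dir)) {
    fill <- function(field, fname) cfg[[field]] %||% file.path(cfg$input_dir, fname)
    cfg$publications <- fill("publications", "publications.tsv")
    cfg$mentions <- fill("mentions", "mentions.tsv")
    cfg$links <- fill("links", "gene2pubmed.tsv")
    cfg$registry <- fill("registry", "gene_info.tsv")
    cfg$citations <- fill("citations", "citations.tsv")
  }
  for (field in c("publications", "mentions", "links", "registry")) {
    if (is.null(cfg[[field]])) stopf("config is missing input path: %s", field)
    if (!file.exists(cfg[[field]])) {
      stopf("input file for '%s' not found: %s", field, cfg[[field]])
    }
  }
  if (cfg$window %% 2L == 0L) stopf("window must be odd")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(cfg, class = "run_config")
}

# internal: stable fingerprint of the configuration
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(unclass(cfg)))], tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, gene ages, field classification, context enrichment,
#' citation impact, and concentration over the configured inputs, and
#' returns all stage results in one bundle together with a manifest (config
#' hash, seed, per-stage row counts). Identical configuration and inputs
#' yield identical output.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return A list of class `genelit_bundle`; see the README for the bundle
#'   components. When `out_dir` is configured, tidy TSV/JSON outputs are
#'   also written there.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  records <- read_publications(cfg$publications)
  mentions <- read_mentions(cfg$mentions)
  links <- read_gene_links(cfg$links)
  registry <- read_gene_registry(cfg$registry)

  records <- filter_research_publications(records, year_max = cfg$year_max)
  pairs <- build_highlight_table(records, mentions, links, registry,
                                 taxon = cfg$taxon)
  if (nrow(pairs) == 0L) stopf("ingest stage produced no highlight pairs")
  age_table <- first_highlight_years(pairs)
  pub_class <- publication_age_class(pairs, age_table)
  years <- sort(unique(records$year))

  bundle <- list(cfg = cfg, records = records, pairs = pairs,
                 age_table = age_table, pub_class = pub_class)
  bundle$curve <- cumulative_highlight_curve(age_table, registry, years,
                                             taxon = cfg$taxon)
  bundle$share_series <- pair_share_series(
    pairs, age_table, window = cfg$window, level = cfg$level,
    n_boot = cfg$n_boot, seed = cfg$seed)
  bundle$enrichment_series <- category_enrichment_series(
    pairs, age_table, window = cfg$window, level = cfg$level,
    n_boot = cfg$n_boot, seed = cfg$seed)
  bundle$decade_authors <- decade_aggregate(
    records, pairs, age_table, "mean_authors", level = cfg$level,
    n_boot = cfg$n_boot, seed = cfg$seed)
  bundle$decade_genes <- decade_aggregate(
    records, pairs, age_table, "mean_genes", level = cfg$level,
    n_boot = cfg$n_boot, seed = cfg$seed)

  bundle$labels <- label_corpus(records, cfg$catalog_pmids,
                                load_lexicon(cfg$gb_lexicon),
                                load_lexicon(cfg$gwas_lexicon),
                                token_bounded = cfg$token_bounded)
  gb_map <- stats::setNames(bundle$labels$genome_biology,
                            as.character(bundle$labels$pmid))
  gb_values <- data.table::copy(pub_class)
  gb_values$value <- as.numeric(gb_map[as.character(gb_values$pmid)])
  bundle$decade_gb_share <- decade_class_value(
    gb_values, mean, level = cfg$level, n_boot = cfg$n_boot, seed = cfg$seed)

  period <- cfg$period
  jm <- group_membership(records, "journal")
  bundle$journal_scan_new <- enrichment_scan(
    pairs, age_table, jm, "new", period, alpha = cfg$alpha,
    min_group_size = cfg$min_group_size)
  bundle$journal_scan_recent <- enrichment_scan(
    pairs, age_table, jm, "recent", period, alpha = cfg$alpha,
    min_group_size = cfg$min_group_size)
  bundle$journal_comparison <- new_vs_recent_comparison(
    bundle$journal_scan_new, bundle$journal_scan_recent)
  bundle$funder_scan_recent <- enrichment_scan(
    pairs, age_table, group_membership(records, "funder"), "recent", period,
    alpha = cfg$alpha, min_group_size = cfg$min_group_size)

  if (isTRUE(cfg$compute_impact) && !is.null(cfg$citations) &&
        file.exists(cfg$citations)) {
    edges <- data.table::fread(cfg$citations, sep = "\t")
    graph <- citation_graph(edges, records[, c("pmid", "year",
                                               "publication_types",
                                               "citation_count"),
                                           with = FALSE])
    hc <- highly_cited_table(graph)
    hc_map <- stats::setNames(hc$highly_cited, as.character(hc$pmid))
    hv <- data.table::copy(pub_class)
    hv$value <- as.numeric(hc_map[as.character(hv$pmid)])
    bundle$highly_cited <- hc
    bundle$decade_highly_cited <- decade_class_value(
      hv, mean, level = cfg$level, n_boot = cfg$n_boot, seed = cfg$seed)
    cc <- clinical_citation_stats(graph, pub_class$pmid)
    cc_map <- stats::setNames(cc$cited_by_trial, as.character(cc$pmid))
    cv <- data.table::copy(pub_class)
    cv$value <- as.numeric(cc_map[as.character(cv$pmid)])
    bundle$decade_trial_cited <- decade_class_value(
      cv, mean, level = cfg$level, n_boot = cfg$n_boot, seed = cfg$seed)
    bundle$citation_variability <- citation_variability(hc, pub_class,
                                                        window = cfg$window)
    if (isTRUE(cfg$compute_disruption)) {
      bundle$disruption <- disruption_percentiles(graph, pub_class$pmid)
    }
  }

  bundle$rank_table <- rank_recent_targets(pairs, age_table, period)
  ts <- top_set(bundle$rank_table, cfg$top_fraction)
  bundle$top_set <- ts
  disp <- bundle$journal_comparison
  disp_journals <- disp$group[!is.na(disp$disproportionate_recent) &
                                disp$disproportionate_recent]
  bundle$journal_topk <- journal_topk_share(pairs, age_table, records,
                                            unique(jm$group), ts$genes,
                                            period)
  mat_genes <- ts$genes[ts$genes %in% pairs$gene_id]
  mat_journals <- if (length(disp_journals)) disp_journals else
    utils::head(sort(unique(records$journal)), 10L)
  bundle$journal_gene_matrix <- build_journal_gene_matrix(
    pairs, records, age_table, mat_journals, mat_genes, period)
  bundle$clustering <- ward_cluster(bundle$journal_gene_matrix)
  bundle$ablation <- ablation_retest(pairs, age_table, jm, ts$genes, period,
                                     alpha = cfg$alpha,
                                     min_group_size = cfg$min_group_size)

  bundle$manifest <- list(
    config_hash = .config_hash(cfg), seed = cfg$seed,
    n_records = nrow(records), n_pairs = nrow(pairs),
    n_genes = nrow(age_table), n_labelled = nrow(bundle$labels),
    n_journal_groups = attr(bundle$journal_scan_recent, "m"),
    n_eligible_recent = nrow(bundle$rank_table),
    top_set_size = ts$k, top_set_share = ts$share)
  class(bundle) <- "genelit_bundle"
  if (!is.null(cfg$out_dir)) export_results(bundle, cfg$out_dir)
  bundle
}

#' @export
print.genelit_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "analysis bundle: %d records, %d pairs, %d genes; top set %d genes (%.1f%% of recent pairs)\n",
    m$n_records, m$n_pairs, m$n_genes, m$top_set_size,
    100 * m$top_set_share))
  invisible(x)
}

.figure_tables <- c("fig1a", "fig1b", "fig1c", "fig2a", "fig2b", "fig2c",
                    "fig2d", "fig3a", "fig3b", "fig3c", "fig5a", "fig6a",
                    "fig6c", "fig6d")

#' Export a tidy figure-series table from a bundle
#'
#' Returns the tidy table underlying one of the standard result series
#' (named after the analysis figures they mirror): `fig1a` cumulative
#' highlight curve; `fig1b` pair-share series; `fig1c` enrichment series;
#' `fig2a`/`fig2b` decade aggregations of authors/genes; `fig2c`/`fig2d`
#' highly-cited and trial-cited shares; `fig3a`/`fig3b` journal scans;
#' `fig3c` the new-vs-recent comparison; `fig5a` genome-biology share;
#' `fig6a` the gene rank table; `fig6c` journal top-set shares; `fig6d`
#' the journal-by-gene matrix in long form.
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param figure One of the labels above.
#' @return A `data.table`.
#' @export
export_figure_tables <- function(bundle, figure) {
  if (!figure %in% .figure_tables) stopf("unknown figure label: %s", figure)
  switch(figure,
    fig1a = bundle$curve,
    fig1b = bundle$share_series[, c("center_year", "class", "share",
                                    "lo", "hi"), with = FALSE],
    fig1c = bundle$enrichment_series,
    fig2a = bundle$decade_authors,
    fig2b = bundle$decade_genes,
    fig2c = bundle$decade_highly_cited,
    fig2d = bundle$decade_trial_cited,
    fig3a = bundle$journal_scan_new,
    fig3b = bundle$journal_scan_recent,
    fig3c = bundle$journal_comparison[, c("group", "fold_new", "fold_recent",
                                          "disproportionate_recent"),
                                      with = FALSE],
    fig5a = bundle$decade_gb_share,
    fig6a = bundle$rank_table[, c("rank", "gene_id", "n_recent_pairs",
                                  "cum_share"), with = FALSE],
    fig6c = bundle$journal_topk,
    fig6d = data.table::as.data.table(as.table(bundle$journal_gene_matrix)))
}

#' Write all bundle outputs to a directory
#'
#' Writes one tidy TSV per figure table, the journal/funder scans, the
#' Newick dendrograms, and `manifest.json`.
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param dir Output directory.
#' @return Invisibly, the output directory.
#' @export
export_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fig in .figure_tables) {
    tab <- tryCatch(export_figure_tables(bundle, fig), error = function(e) NULL)
    if (is.null(tab)) next
    data.table::fwrite(tab, file.path(dir, paste0(fig, ".tsv")), sep = "\t")
  }
  if (!is.null(bundle$clustering$row_newick)) {
    writeLines(c(bundle$clustering$row_newick %||% "",
                 bundle$clustering$col_newick %||% ""),
               file.path(dir, "clustering.nwk"))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
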