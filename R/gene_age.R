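# Gene ages: first-highlight years, age classes (new / recent / old), the
# temporal share and enrichment series, and the decade aggregations.

AGE_CLASSES <- c("new", "recent", "old")

#' First highlight year per gene
#'
#' For every gene in the highlight table, the earliest publication year of
#' any of its pairs (`first_year`) and, restricted to pairs whose sections
#' include the title, the earliest title mention (`first_year_title`,
#' `NA` for genes never mentioned in a title).
#'
#' @param pairs Highlight table from [build_highlight_table()].
#' @return A `data.table` with columns `gene_id`, `first_year`,
#'   `first_year_title`.
#' @export
first_highlight_years <- function(pairs) {
  assert_columns(pairs, c("gene_id", "pub_year", "in_title"), "pairs")
  pub_year <- in_title <- NULL
  any_ <- pairs[, list(first_year = min(pub_year)), by = "gene_id"]
  ttl <- pairs[in_title == TRUE,
               list(first_year_title = min(pub_year)), by = "gene_id"]
  out <- merge(any_, ttl, by = "gene_id", all.x = TRUE)
  data.table::setorder(out, gene_id)
  out[]
}

#' Age class of a gene at publication time
#'
#' A gene is a `new` target in the year it is first highlighted (age 0), a
#' `recent` target for the following 5 years (age 1-5), and an `old` target
#' from age 6 on.
#'
#' @param pub_year Publication year(s).
#' @param first_year First-highlight year(s), recycled against `pub_year`.
#' @return Character vector over `c("new", "recent", "old")`.
#' @export
age_class <- function(pub_year, first_year) {
  age <- pub_year - first_year
  if (any(age < 0, na.rm = TRUE)) {
    stopf("pub_year earlier than first highlight year")
  }
  ifelse(age == 0, "new", ifelse(age <= 5, "recent", "old"))
}

# internal: first_year lookup vector from an age table
.first_year_map <- function(age_table) {
  stats::setNames(age_table$first_year, age_table$gene_id)
}

# internal: pairs annotated with their age class
.classified_pairs <- function(pairs, age_table) {
  fy <- .first_year_map(age_table)
  p <- data.table::copy(pairs)
  p$first_year <- unname(fy[p$gene_id])
  if (anyNA(p$first_year)) stopf("pairs contain genes absent from age table")
  p$class <- age_class(p$pub_year, p$first_year)
  p
}

#' Publication age class from its highlighted genes
#'
#' A publication is assigned the youngest class among its highlighted
#' genes: any new gene makes it `new`; otherwise any recent gene makes it
#' `recent`; otherwise `old`.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @return A `data.table` with columns `pmid`, `pub_year`, `n_genes`,
#'   `class`.
#' @export
publication_age_class <- function(pairs, age_table) {
  p <- .classified_pairs(pairs, age_table)
  pub_year <- first_year <- NULL
  out <- p[, list(pub_year = pub_year[1L],
                  n_genes = .N,
                  min_age = min(pub_year - first_year)),
           by = "pmid"]
  out$class <- ifelse(out$min_age == 0, "new",
                      ifelse(out$min_age <= 5, "recent", "old"))
  out$min_age <- NULL
  out[]
}

#' Cumulative share of genes ever highlighted
#'
#' Per year, the share of registry protein-coding genes (of the configured
#' taxon) first highlighted in or before that year, and the analogous share
#' for title mentions. Both curves are nondecreasing in `[0, 1]`.
#'
#' @param age_table Output of [first_highlight_years()].
#' @param registry Gene registry.
#' @param years Integer vector of years at which to evaluate the curves.
#' @param taxon Taxon filter for the registry denominator.
#' @param gene_subset Optional character vector restricting both numerator
#'   and denominator to a gene subset (e.g. loss-of-function intolerant
#'   genes).
#' @return A `data.table` with columns `year`, `share_highlighted`,
#'   `share_title`.
#' @export
cumulative_highlight_curve <- function(age_table, registry, years,
                                       taxon = 9606L, gene_subset = NULL) {
  genes <- registry$gene_id[registry$gene_type == "protein-coding" &
                              registry$tax_id == taxon]
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) == 0L) stopf("empty gene registry after filtering")
  at <- age_table[age_table$gene_id %in% genes]
  fy <- at$first_year
  ft <- at$first_year_title
  data.table::data.table(
    year = as.integer(years),
    share_highlighted = vapply(years, function(y) sum(fy <= y), 0) / length(genes),
    share_title = vapply(years, function(y) sum(ft <= y, na.rm = TRUE), 0) /
      length(genes)
  )
}

# internal: per-pmid class count matrix for pairs inside one window,
# used to bootstrap shares over publications
.window_class_counts <- function(p) {
  tab <- table(factor(p$pmid), factor(p$class, levels = AGE_CLASSES))
  matrix(tab, ncol = 3L, dimnames = list(NULL, AGE_CLASSES))
}

.boot_shares <- function(counts, n_boot, level, seed) {
  npub <- nrow(counts)
  with_seed(seed, {
    reps <- matrix(NA_real_, nrow = n_boot, ncol = 3L)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(npub, npub, replace = TRUE)
      cs <- colSums(counts[idx, , drop = FALSE])
      reps[b, ] <- cs / sum(cs)
    }
    reps
  })
}

#' Age-class share of pairs in a sliding window
#'
#' For each center year, pools the gene-publication pairs of the window
#' (center plus/minus half the window width) and computes the share of
#' pairs falling on new, recent, and old targets, with percentile bootstrap
#' confidence intervals obtained by resampling publications.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param window Odd window width in years; default 3.
#' @param level,n_boot,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return A `data.table` with columns `center_year`, `class`, `share`,
#'   `lo`, `hi`, `n_pairs`, `n_pubs`; shares sum to 1 within each window.
#' @export
pair_share_series <- function(pairs, age_table, window = 3L, level = 0.95,
                              n_boot = 1000L, seed = NULL) {
  if (window %% 2L == 0L) stopf("window must be odd")
  half <- (window - 1L) %/% 2L
  p <- .classified_pairs(pairs, age_table)
  centers <- sort(unique(p$pub_year))
  res <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    cy <- centers[i]
    w <- p[abs(p$pub_year - cy) <= half]
    counts <- .window_class_counts(w)
    tot <- colSums(counts)
    shares <- tot / sum(tot)
    reps <- .boot_shares(counts, n_boot, level, if (is.null(seed)) NULL else seed + cy)
    qs <- apply(reps, 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
    res[[i]] <- data.table::data.table(
      center_year = cy, class = AGE_CLASSES, share = as.numeric(shares),
      lo = qs[1L, ], hi = qs[2L, ], n_pairs = nrow(w), n_pubs = nrow(counts))
  }
  data.table::rbindlist(res)
}

# internal: expected (weighted) class shares of genes in a window.
# mode "per_year": a gene contributes to the class it occupies in each
# calendar year of the window; per-year tallies are averaged. mode
# "pooled": each gene counted once with its class at the center year.
.expected_class_shares <- function(age_table, center, half, weights,
                                   mode = c("per_year", "pooled")) {
  mode <- match.arg(mode)
  fy <- age_table$first_year
  w <- weights[age_table$gene_id]
  w[is.na(w)] <- 0
  years <- if (mode == "per_year") (center - half):(center + half) else center
  tallies <- sapply(years, function(y) {
    elig <- fy <= y
    cls <- age_class(rep(y, sum(elig)), fy[elig])
    vapply(AGE_CLASSES, function(k) sum(w[elig][cls == k]), numeric(1))
  })
  tot <- rowMeans(matrix(tallies, nrow = 3L, dimnames = list(AGE_CLASSES)))
  if (sum(tot) == 0) stopf("no eligible genes (all-zero weights?)")
  tot / sum(tot)
}

#' Enrichment of pair shares relative to available genes
#'
#' Per class and window, the log2 ratio of the observed share of pairs to
#' the expected share, where the expected share is the (optionally
#' annotation-weighted) share of genes occupying that class within the
#' window. A class observed zero times against a positive expectation is
#' reported as `-Inf` (a sentinel, excluded from interval aggregation); a
#' zero expected share yields `NA` and the cell is effectively omitted.
#' Enrichments are invariant to uniform rescaling of the gene weights.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param weights Optional named numeric vector of per-gene weights
#'   (`NULL` = 1 per gene); e.g. murine phenotype counts or GWAS trait
#'   counts from the registry.
#' @param window Odd window width; default 3.
#' @param expected_mode `"per_year"` (default; per-year gene tallies
#'   averaged over the window) or `"pooled"` (gene class at the center
#'   year).
#' @param level,n_boot,seed Bootstrap settings for the CI of the observed
#'   share (the expected share is treated as fixed).
#' @return A `data.table` with columns `center_year`, `class`, `observed`,
#'   `expected`, `log2_enrichment`, `lo`, `hi`.
#' @export
category_enrichment_series <- function(pairs, age_table, weights = NULL,
                                       window = 3L,
                                       expected_mode = c("per_year", "pooled"),
                                       level = 0.95, n_boot = 1000L,
                                       seed = NULL) {
  if (window %% 2L == 0L) stopf("window must be odd")
  expected_mode <- match.arg(expected_mode)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, nrow(age_table)), age_table$gene_id)
  }
  if (all(weights == 0)) stopf("all-zero gene weights")
  half <- (window - 1L) %/% 2L
  p <- .classified_pairs(pairs, age_table)
  obs <- pair_share_series(pairs, age_table, window = window, level = level,
                           n_boot = n_boot, seed = seed)
  centers <- unique(obs$center_year)
  exp_list <- lapply(centers, function(cy) {
    es <- .expected_class_shares(age_table, cy, half, weights, expected_mode)
    data.table::data.table(center_year = cy, class = AGE_CLASSES,
                           expected = as.numeric(es))
  })
  out <- merge(obs, data.table::rbindlist(exp_list),
               by = c("center_year", "class"), sort = FALSE)
  enr <- function(o, e) {
    ifelse(e == 0, NA_real_, ifelse(o == 0, -Inf, log2(o / e)))
  }
  out$log2_enrichment <- enr(out$share, out$expected)
  out$lo <- ifelse(is.finite(out$log2_enrichment) & out$lo > 0,
                   log2(out$lo / out$expected), NA_real_)
  out$hi <- ifelse(is.finite(out$log2_enrichment) & out$hi > 0,
                   log2(out$hi / out$expected), NA_real_)
  data.table::setnames(out, "share", "observed")
  out[, c("center_year", "class", "observed", "expected",
          "log2_enrichment", "lo", "hi"), with = FALSE]
}

#' Default decade grid
#'
#' Decades `[1970-1979]` through the final period truncated at the analysis
#' end year (by default `[2010-2018]`).
#'
#' @param start First decade start; default 1970.
#' @param end_year Analysis end year; default 2018.
#' @return A `data.table` with columns `decade`, `start`, `end`.
#' @export
default_decades <- function(start = 1970L, end_year = 2018L) {
  starts <- seq.int(start, end_year - end_year %% 10L, by = 10L)
  ends <- pmin(starts + 9L, end_year)
  data.table::data.table(
    decade = sprintf("%d-%d", starts, ends), start = starts, end = ends)
}

#' Decade-by-class aggregation of publication metrics
#'
#' Aggregates the mean or median number of authors, or of highlighted genes
#' per publication, by decade and by the publication's age class (youngest
#' highlighted gene; see [publication_age_class()]), with bootstrap
#' confidence intervals over publications. Empty decade-class cells are
#' absent from the output.
#'
#' @param records Filtered publications (for author counts).
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param metric One of `"mean_authors"`, `"median_authors"`,
#'   `"mean_genes"`, `"median_genes"`.
#' @param decades Decade grid as from [default_decades()].
#' @param level,n_boot,seed Bootstrap settings.
#' @return A `data.table` with columns `decade`, `class`, `value`, `lo`,
#'   `hi`, `n_pubs`.
#' @export
decade_aggregate <- function(records, pairs, age_table,
                             metric = c("mean_authors", "median_authors",
                                        "mean_genes", "median_genes"),
                             decades = default_decades(), level = 0.95,
                             n_boot = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  pc <- publication_age_class(pairs, age_table)
  if (grepl("authors$", metric)) {
    na_map <- stats::setNames(records$n_authors, records$pmid)
    pc$value <- as.numeric(na_map[as.character(pc$pmid)])
  } else {
    pc$value <- as.numeric(pc$n_genes)
  }
  f <- if (grepl("^mean", metric)) mean else stats::median
  decade_class_value(pc, f, decades = decades, level = level,
                     n_boot = n_boot, seed = seed)
}

#' Decade-by-class aggregation of an arbitrary per-publication value
#'
#' Workhorse behind [decade_aggregate()] and the citation-impact shares:
#' takes one value per publication (numeric or logical) together with its
#' year and age class, and aggregates `statistic` per decade and class with
#' a percentile bootstrap over publications.
#'
#' @param pub_values A `data.table` with columns `pmid`, `pub_year`,
#'   `class`, `value`.
#' @param statistic Function mapping the cell's values to one number
#'   (default `mean`; for a logical value this is a share).
#' @param decades Decade grid.
#' @param level,n_boot,seed Bootstrap settings.
#' @return A `data.table` with columns `decade`, `class`, `value`, `lo`,
#'   `hi`, `n_pubs`.
#' @export
decade_class_value <- function(pub_values, statistic = mean,
                               decades = default_decades(), level = 0.95,
                               n_boot = 1000L, seed = NULL) {
  assert_columns(pub_values, c("pub_year", "class", "value"), "pub_values")
  res <- list()
  for (i in seq_len(nrow(decades))) {
    for (k in AGE_CLASSES) {
      v <- pub_values$value[pub_values$class == k &
                              pub_values$pub_year >= decades$start[i] &
                              pub_values$pub_year <= decades$end[i]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      ci <- bootstrap_ci(v, statistic, level = level, n_boot = n_boot,
                         seed = if (is.null(seed)) NULL else seed + 97L * i +
                           match(k, AGE_CLASSES))
      res[[length(res) + 1L]] <- data.table::data.table(
        decade = decades$decade[i], class = k, value = ci$point,
        lo = ci$lo, hi = ci$hi, n_pubs = length(v))
    }
  }
  if (length(res) == 0L) {
    return(data.table::data.table(decade = character(0), class = character(0),
                                  value = numeric(0), lo = numeric(0),
                                  hi = numeric(0), n_pubs = integer(0)))
  }
  data.table::rbindlist(res)
}
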