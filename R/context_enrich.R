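# Enrichment/depletion scans of early-stage publications across journals,
# funders, activity codes, and organizations, and the new-vs-recent
# comparison rule.

#' Group membership table from a publication list column
#'
#' Builds the long-format (pmid, group) membership table used by the
#' enrichment scans from one of the grouping fields of the publications
#' table. A publication with several funders (or organizations) belongs to
#' each of its groups.
#'
#' @param records Publications table.
#' @param group_kind One of `"journal"`, `"funder"`, `"activity_code"`,
#'   `"organization"`.
#' @return A `data.table` with columns `pmid`, `group` and attribute
#'   `group_kind`.
#' @export
group_membership <- function(records, group_kind = c("journal", "funder",
                                                     "activity_code",
                                                     "organization")) {
  group_kind <- match.arg(group_kind)
  out <- if (group_kind == "journal") {
    data.table::data.table(pmid = records$pmid, group = records$journal)
  } else {
    col <- switch(group_kind, funder = "funders",
                  activity_code = "activity_codes",
                  organization = "organizations")
    n <- lengths(records[[col]])
    data.table::data.table(pmid = rep(records$pmid, n),
                           group = unlist(records[[col]], use.names = FALSE))
  }
  out <- unique(out[nzchar(out$group)])
  data.table::setattr(out, "group_kind", group_kind)
  out
}

# internal: the scan universe and target flags. The universe is every
# publication highlighting at least one gene within the period; a
# publication is "target" iff it highlights >= 1 gene of the target class.
.target_universe <- function(pairs, age_table, target_class, period) {
  if (length(period) == 0L) stopf("empty period")
  p <- .classified_pairs(pairs, age_table)
  p <- p[p$pub_year >= min(period) & p$pub_year <= max(period)]
  cls <- NULL
  tgt <- p[, list(target = any(class == target_class)), by = "pmid"]
  tgt
}

#' Contingency table for one group
#'
#' Counts, within the period's universe of gene-highlighting publications:
#' `a` = in-group target publications, `b` = in-group non-target, `c` =
#' out-group target, `d` = out-group non-target. A publication is counted
#' once per group; for multi-group publications the out-group cells exclude
#' them for that group's table.
#'
#' @param pairs Highlight table.
#' @param age_table Output of [first_highlight_years()].
#' @param membership Output of [group_membership()].
#' @param group Group label to tabulate.
#' @param target_class `"new"` or `"recent"`.
#' @param period Year range (vector; min/max used).
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
group_contingency <- function(pairs, age_table, membership, group,
                              target_class = c("new", "recent"),
                              period) {
  target_class <- match.arg(target_class)
  if (!group %in% membership$group) stopf("unknown group: %s", group)
  tgt <- .target_universe(pairs, age_table, target_class, period)
  in_group <- tgt$pmid %in% membership$pmid[membership$group == group]
  c(a = sum(in_group & tgt$target),
    b = sum(in_group & !tgt$target),
    c = sum(!in_group & tgt$target),
    d = sum(!in_group & !tgt$target))
}

#' Log2 fold enrichment of a group's target share
#'
#' `log2` of the ratio of the in-group target share `a / (a + b)` to the
#' reference target share. With `denominator = "corpus"` (default) the
#' reference is the corpus-wide share `(a + c) / (a + b + c + d)` including
#' the group; `"outgroup"` uses `c / (c + d)`. A group without any target
#' publication (`a = 0`) yields the `-Inf` sentinel (reported, plotted out
#' of range).
#'
#' @param tab Named vector or list with cells `a`, `b`, `c`, `d`.
#' @param denominator `"corpus"` or `"outgroup"`.
#' @return Log2 fold value, or `-Inf` when `a = 0`.
#' @export
log2_fold_enrichment <- function(tab, denominator = c("corpus", "outgroup")) {
  denominator <- match.arg(denominator)
  a <- tab[["a"]]; b <- tab[["b"]]; c_ <- tab[["c"]]; d <- tab[["d"]]
  if (a + b == 0) stopf("empty group: a + b = 0")
  ref <- if (denominator == "corpus") {
    (a + c_) / (a + b + c_ + d)
  } else {
    if (c_ + d == 0) stopf("empty out-group under denominator = 'outgroup'")
    c_ / (c_ + d)
  }
  if (ref == 0) stopf("no target publications in the reference share")
  if (a == 0) return(-Inf)
  log2((a / (a + b)) / ref)
}

#' Enrichment scan over all groups of one kind
#'
#' For every group with at least `min_group_size` publications in the
#' period's universe, builds the 2x2 table, computes the exact two-sided
#' p-value and the log2 fold enrichment, and applies Bonferroni control
#' over the `m` groups actually tested in this scan. Significant groups are
#' directed `enriched`/`depleted` by the sign of the fold.
#'
#' @inheritParams group_contingency
#' @param alpha Familywise level; default 0.01.
#' @param min_group_size Minimum in-universe group size; default 1.
#' @param denominator Fold reference, see [log2_fold_enrichment()].
#' @return A `data.table` with one row per tested group: `group`,
#'   `target_class`, `a`, `b`, `c`, `d`, `log2_fold`, `p_raw`,
#'   `significant`, `direction`; attribute `m` records the number of tests.
#' @export
enrichment_scan <- function(pairs, age_table, membership,
                            target_class = c("new", "recent"), period,
                            alpha = 0.01, min_group_size = 1L,
                            denominator = c("corpus", "outgroup")) {
  target_class <- match.arg(target_class)
  denominator <- match.arg(denominator)
  tgt <- .target_universe(pairs, age_table, target_class, period)
  mem <- membership[membership$pmid %in% tgt$pmid]
  sizes <- table(mem$group)
  groups <- names(sizes)[sizes >= min_group_size]
  n_target <- sum(tgt$target)
  n_tot <- nrow(tgt)
  rows <- lapply(groups, function(g) {
    in_group <- tgt$pmid %in% mem$pmid[mem$group == g]
    a <- sum(in_group & tgt$target); b <- sum(in_group) - a
    c_ <- n_target - a; d <- n_tot - a - b - c_
    tab <- c(a = a, b = b, c = c_, d = d)
    p <- if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
      NA_real_
    } else {
      fisher_exact_two_sided(a, b, c_, d)
    }
    lf <- tryCatch(log2_fold_enrichment(tab, denominator),
                   error = function(e) NA_real_)
    data.table::data.table(group = g, target_class = target_class,
                           a = a, b = b, c = c_, d = d,
                           log2_fold = lf, p_raw = p)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    out$significant <- bonferroni_reject(out$p_raw, alpha)
    out$direction <- ifelse(!out$significant | is.na(out$log2_fold), "none",
                            ifelse(out$log2_fold > 0, "enriched", "depleted"))
  } else {
    out <- data.table::data.table(group = character(0),
                                  target_class = character(0),
                                  a = integer(0), b = integer(0),
                                  c = integer(0), d = integer(0),
                                  log2_fold = numeric(0), p_raw = numeric(0),
                                  significant = logical(0),
                                  direction = character(0))
  }
  data.table::setattr(out, "m", length(groups))
  data.table::setattr(out, "alpha", alpha)
  out
}

#' Bootstrap confidence interval for one group's log2 fold enrichment
#'
#' Resamples the period's universe of gene-highlighting publications with
#' replacement and recomputes [log2_fold_enrichment()] for the group.
#' Replicates in which the resampled group has no target publication give a
#' `-Inf` fold and are excluded from the percentile interval (their count
#' is reported).
#'
#' @inheritParams group_contingency
#' @param denominator Fold reference, see [log2_fold_enrichment()].
#' @param level,n_boot,seed Bootstrap settings.
#' @return A list with `point`, `lo`, `hi`, `level`, `n_boot`,
#'   `n_degenerate` (dropped replicates).
#' @export
log2_fold_ci <- function(pairs, age_table, membership, group,
                         target_class = c("new", "recent"), period,
                         denominator = c("corpus", "outgroup"),
                         level = 0.95, n_boot = 1000L, seed = NULL) {
  target_class <- match.arg(target_class)
  denominator <- match.arg(denominator)
  tgt <- .target_universe(pairs, age_table, target_class, period)
  in_group <- tgt$pmid %in% membership$pmid[membership$group == group]
  if (!any(in_group)) stopf("group %s has no publications in the period", group)
  fold <- function(ing, tg) {
    a <- sum(ing & tg); b <- sum(ing & !tg)
    c_ <- sum(!ing & tg); d <- sum(!ing & !tg)
    if (a + b == 0) return(NA_real_)
    tryCatch(log2_fold_enrichment(c(a = a, b = b, c = c_, d = d),
                                  denominator),
             error = function(e) NA_real_)
  }
  point <- fold(in_group, tgt$target)
  n <- nrow(tgt)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    fold(in_group[idx], tgt$target[idx])
  }, numeric(1)))
  finite <- reps[is.finite(reps)]
  if (length(finite) == 0L) stopf("all bootstrap replicates degenerate")
  qs <- stats::quantile(finite, probs = c((1 - level) / 2,
                                          1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(point = point, lo = qs[1L], hi = qs[2L], level = level,
       n_boot = as.integer(n_boot), n_degenerate = n_boot - length(finite))
}

#' Compare new-target and recent-target enrichment per group
#'
#' Joins two scans over the same period and flags groups whose fold
#' enrichment for recent targets is at least twice their fold enrichment
#' for new targets, on the linear ratio scale. A group with the `-Inf`
#' new-fold sentinel (no publications on new targets) and a positive finite
#' recent fold is flagged. Groups present in only one scan are reported
#' with the missing side as `NA`.
#'
#' @param results_new,results_recent Outputs of [enrichment_scan()] for the
#'   two target classes over the same period.
#' @return A `data.table` with columns `group`, `log2_fold_new`,
#'   `log2_fold_recent`, `fold_new`, `fold_recent`, `significant_new`,
#'   `significant_recent`, `disproportionate_recent`.
#' @export
new_vs_recent_comparison <- function(results_new, results_recent) {
  nn <- results_new[, c("group", "log2_fold", "significant"), with = FALSE]
  rr <- results_recent[, c("group", "log2_fold", "significant"), with = FALSE]
  data.table::setnames(nn, c("group", "log2_fold_new", "significant_new"))
  data.table::setnames(rr, c("group", "log2_fold_recent", "significant_recent"))
  out <- merge(nn, rr, by = "group", all = TRUE)
  out$fold_new <- 2^out$log2_fold_new        # -Inf sentinel -> fold 0
  out$fold_recent <- 2^out$log2_fold_recent
  out$disproportionate_recent <- ifelse(
    is.na(out$fold_new) | is.na(out$fold_recent), NA,
    out$fold_recent >= 2 * out$fold_new & out$fold_recent > 0)
  out[]
}

#' Rank comparison of two groups of share values
#'
#' Thin two-sided Mann-Whitney (Wilcoxon rank-sum) call-through used for
#' comparing per-institute shares of grant activity going to enriched
#' funding mechanisms.
#'
#' @param x,y Numeric share vectors for the two groups.
#' @return The two-sided p-value from [stats::wilcox.test()].
#' @export
compare_share_distributions <- function(x, y) {
  stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)$p.value
}
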