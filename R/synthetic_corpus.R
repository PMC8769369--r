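# Synthetic corpus generator. Emits complete input file sets
# (publications, mentions, curated links, registry, citation edges) with
# known ground truth, so that every pipeline stage has a recoverable
# target: planted discovery years, age-class mixtures, journal enrichment
# multipliers, field labels, and citation boosts.

#' Default journal table for the generator
#'
#' Twenty journals with uniform base weights. A journal's multipliers scale
#' the probability that a publication appearing in it is early-stage
#' (first gene new, respectively recent); multiplier 1 is neutral, above 1
#' plants enrichment, below 1 depletion.
#'
#' @param n Number of journals.
#' @return A `data.frame` with columns `journal`, `weight`,
#'   `multiplier_new`, `multiplier_recent`.
#' @export
default_journal_table <- function(n = 20L) {
  out <- data.frame(journal = sprintf("J%02d", seq_len(n)), weight = 1,
                    multiplier_new = 1, multiplier_recent = 1)
  if (n >= 3L) {
    out$multiplier_new[1L] <- 2; out$multiplier_recent[1L] <- 2
    out$multiplier_recent[2L] <- 4
    out$multiplier_new[3L] <- 0.5; out$multiplier_recent[3L] <- 0.5
  }
  out
}

.default_group_table <- function(prefix, n, enriched_mult = 2) {
  out <- data.frame(group = sprintf("%s%02d", prefix, seq_len(n)), weight = 1,
                    multiplier_recent = 1)
  out$multiplier_recent[1L] <- enriched_mult
  out
}

#' Generator parameters
#'
#' Bundles and validates the knobs of the synthetic corpus. The defaults
#' describe a mid-sized literature: a pool of 3000 protein-coding genes,
#' 60 publications per year over 1980-2018, a novelty rate (probability
#' that a publication's lead gene has never been highlighted) decaying
#' from 0.30 to 0.05 across the period, a constant 0.20 rate of lead genes
#' that are recent targets, rich-get-richer gene reuse with attachment
#' exponent 1, heavy-tailed gene counts per publication, class-dependent
#' team sizes, a handful of journals/funders/organizations with planted
#' early-stage multipliers, 30 percent genome-biology publications (phrase
#' injection), lognormal citation counts with a 2x high-citation boost for
#' new-class publications, and 8 percent clinical-trial publications.
#'
#' @param n_genes Size of the gene pool.
#' @param years Calendar years covered.
#' @param pubs_per_year Publications per year (scalar or one per year).
#' @param novelty_rate Probability that a publication's lead gene is new;
#'   scalar or one per year.
#' @param recent_rate Probability that the lead gene is a recent target;
#'   scalar or one per year.
#' @param attachment_exponent,attachment_smoothing Reuse probability of an
#'   already-highlighted gene is proportional to
#'   `(pair count + smoothing)^exponent`.
#' @param genes_per_pub List with `p` (geometric parameter) and `max`;
#'   a publication highlights `1 + min(Geom(p), max - 1)` genes.
#' @param team_size Named vector of Poisson means by age class; authors are
#'   `1 + Poisson(lambda_class)`.
#' @param journals Journal table as from [default_journal_table()].
#' @param funders,activity_codes,organizations Group tables with columns
#'   `group`, `weight`, `multiplier_recent` (weights are scaled by the
#'   multiplier for publications highlighting a recent target).
#' @param genome_biology_fraction Fraction of publications labelled genome
#'   biology by injecting `gb_phrase` into their keywords.
#' @param gb_phrase The injected phrase.
#' @param gwas_fraction Fraction of publications carrying the GWAS MeSH
#'   descriptor.
#' @param citation List with `meanlog`, `sdlog` (lognormal citation
#'   counts) and `boost` (named per-class tail exponents; boost `k` makes
#'   the class `k` times as likely to land in the top tail).
#' @param trial_rate Fraction of publications typed as clinical trials.
#' @param reference_mean Mean number of references (cited earlier corpus
#'   publications) per publication.
#' @param noise Logical; emit malformed/filterable records (reviews, a
#'   duplicated pmid, ambiguous mentions, non-coding and foreign-taxon
#'   genes, unlinked publications) exercising every corpus filter.
#' @param seed Integer seed fixing the full output.
#' @return A validated list of class `corpus_params`.
#' @export
corpus_params <- function(n_genes = 3000L,
                          years = 1980:2018,
                          pubs_per_year = 60L,
                          novelty_rate = seq(0.30, 0.05,
                                             length.out = length(years)),
                          recent_rate = 0.20,
                          attachment_exponent = 1,
                          attachment_smoothing = 1,
                          genes_per_pub = list(p = 0.6, max = 8L),
                          team_size = c(new = 9, recent = 7, old = 5),
                          journals = default_journal_table(),
                          funders = .default_group_table("F", 8L),
                          activity_codes = .default_group_table("R", 10L),
                          organizations = .default_group_table("O", 10L),
                          genome_biology_fraction = 0.30,
                          gb_phrase = "transcriptome",
                          gwas_fraction = 0.05,
                          citation = list(meanlog = 2, sdlog = 1.3,
                                          boost = c(new = 2, recent = 1,
                                                    old = 1)),
                          trial_rate = 0.08,
                          reference_mean = 6,
                          noise = TRUE,
                          seed = 1L) {
  rep_year <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, length(years))
    if (length(x) != length(years)) {
      stopf("%s must have length 1 or length(years)", nm)
    }
    if (any(x < 0 | x > 1)) stopf("%s must lie in [0, 1]", nm)
    x
  }
  novelty_rate <- rep_year(novelty_rate, "novelty_rate")
  recent_rate <- rep_year(recent_rate, "recent_rate")
  if (any(novelty_rate + recent_rate >= 1)) {
    stopf("novelty_rate + recent_rate must stay below 1")
  }
  if (length(pubs_per_year) == 1L) {
    pubs_per_year <- rep(pubs_per_year, length(years))
  }
  if (length(pubs_per_year) != length(years)) {
    stopf("pubs_per_year must have length 1 or length(years)")
  }
  stopifnot(n_genes > 0, attachment_exponent >= 0, attachment_smoothing > 0,
            genes_per_pub$p > 0, genes_per_pub$p <= 1, genes_per_pub$max >= 1,
            all(AGE_CLASSES %in% names(team_size)),
            all(AGE_CLASSES %in% names(citation$boost)),
            genome_biology_fraction >= 0, genome_biology_fraction <= 1,
            gwas_fraction >= 0, gwas_fraction <= 1,
            trial_rate >= 0, trial_rate <= 1, reference_mean >= 0)
  structure(list(
    n_genes = as.integer(n_genes), years = as.integer(years),
    pubs_per_year = as.integer(pubs_per_year), novelty_rate = novelty_rate,
    recent_rate = recent_rate, attachment_exponent = attachment_exponent,
    attachment_smoothing = attachment_smoothing,
    genes_per_pub = genes_per_pub, team_size = team_size,
    journals = journals, funders = funders,
    activity_codes = activity_codes, organizations = organizations,
    genome_biology_fraction = genome_biology_fraction, gb_phrase = gb_phrase,
    gwas_fraction = gwas_fraction, citation = citation,
    trial_rate = trial_rate, reference_mean = reference_mean,
    noise = isTRUE(noise), seed = as.integer(seed)),
    class = "corpus_params")
}

# internal: weighted sample of group labels
.sample_groups <- function(tab, k, boosted) {
  w <- tab$weight * (if (boosted) tab$multiplier_recent else 1)
  tab$group[sample.int(nrow(tab), min(k, nrow(tab)), prob = w)]
}

#' Generate a synthetic corpus
#'
#' Runs the generative model of [corpus_params()] and returns the five
#' input tables in the dialects read by the ingestion functions, together
#' with the ground truth. Per publication the lead gene is new, recent, or
#' old according to the (journal-multiplier-adjusted) mixture; additional
#' genes are drawn by preferential attachment over previously highlighted
#' genes; the title and abstract embed the gene symbols at the recorded
#' mention offsets, so mention offsets are internally consistent by
#' construction. The same parameters and seed reproduce the output
#' exactly.
#'
#' @param params A [corpus_params()] object.
#' @return A list of class `synthetic_corpus` with elements
#'   `publications`, `mentions`, `links`, `registry`, `citations`, and
#'   `truth` (list: `first_year` named vector of true discovery years,
#'   `pairs` the ground-truth highlight table, `pub_class` per-publication
#'   class and recent-target flag, `labels` true field labels, `params`).
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "corpus_params"))
  with_seed(params$seed, .generate_corpus_impl(params))
}

.generate_corpus_impl <- function(p) {
  ng <- p$n_genes
  gene_ids <- sprintf("G%06d", seq_len(ng))
  symbols <- sprintf("GP%06d", seq_len(ng))
  new_order <- sample.int(ng)
  first_year <- rep(NA_integer_, ng)
  pair_count <- rep(0, ng)
  next_new <- 1L

  npub <- sum(p$pubs_per_year)
  year_of <- rep(p$years, p$pubs_per_year)
  pmids <- 100000L + seq_len(npub)
  jidx <- integer(npub); lead_class <- character(npub)
  pub_class <- character(npub); target_recent <- logical(npub)
  n_authors <- integer(npub); titles <- character(npub)
  abstracts <- character(npub)
  keywords <- vector("list", npub); mesh <- vector("list", npub)
  ptypes <- vector("list", npub); funders_l <- vector("list", npub)
  codes_l <- vector("list", npub); orgs_l <- vector("list", npub)
  gb <- logical(npub); gw <- logical(npub); trial <- logical(npub)
  mention_rows <- vector("list", npub); pair_rows <- vector("list", npub)

  jw <- p$journals$weight
  gmax <- p$genes_per_pub$max
  year_index <- stats::setNames(seq_along(p$years), p$years)

  for (i in seq_len(npub)) {
    y <- year_of[i]
    yi <- year_index[[as.character(y)]]
    j <- sample.int(nrow(p$journals), 1L, prob = jw)
    jidx[i] <- j
    pn <- min(p$novelty_rate[yi] * p$journals$multiplier_new[j], 0.95)
    pr <- min(p$recent_rate[yi] * p$journals$multiplier_recent[j], 0.95)
    if (pn + pr >= 1) {
      s <- 0.95 / (pn + pr); pn <- pn * s; pr <- pr * s
    }
    cls <- sample(AGE_CLASSES, 1L, prob = c(pn, pr, 1 - pn - pr))
    recent_pool <- which(!is.na(first_year) & first_year >= y - 5L &
                           first_year <= y - 1L)
    old_pool <- which(!is.na(first_year) & first_year <= y - 6L)
    # fallback chain keeps generation feasible in the burn-in years
    if (cls == "recent" && length(recent_pool) == 0L) {
      cls <- if (length(old_pool)) "old" else "new"
    } else if (cls == "old" && length(old_pool) == 0L) {
      cls <- if (length(recent_pool)) "recent" else "new"
    }
    lead <- switch(cls,
      new = {
        if (next_new > ng) stopf("gene pool exhausted: novelty demands more new genes than available")
        g <- new_order[next_new]; next_new <- next_new + 1L; g
      },
      recent = {
        w <- (pair_count[recent_pool] + p$attachment_smoothing)^p$attachment_exponent
        recent_pool[sample.int(length(recent_pool), 1L, prob = w)]
      },
      old = {
        w <- (pair_count[old_pool] + p$attachment_smoothing)^p$attachment_exponent
        old_pool[sample.int(length(old_pool), 1L, prob = w)]
      })
    lead_class[i] <- cls
    if (cls == "new") first_year[lead] <- y
    k_extra <- if (gmax > 1L) {
      min(stats::rgeom(1L, p$genes_per_pub$p), gmax - 1L)
    } else 0L
    extra <- integer(0)
    if (k_extra > 0L) {
      pool <- setdiff(which(!is.na(first_year)), lead)
      if (length(pool)) {
        w <- (pair_count[pool] + p$attachment_smoothing)^p$attachment_exponent
        extra <- pool[sample.int(length(pool), min(k_extra, length(pool)),
                                 prob = w)]
      }
    }
    genes <- c(lead, extra)
    pair_count[genes] <- pair_count[genes] + 1
    ages <- y - first_year[genes]
    pub_class[i] <- if (any(ages == 0)) "new" else
      if (any(ages <= 5)) "recent" else "old"
    target_recent[i] <- any(ages >= 1 & ages <= 5)
    n_authors[i] <- 1L + stats::rpois(1L, p$team_size[[pub_class[i]]])

    # text with internally consistent mention offsets (0-based into
    # title <sep> abstract, separator width 1)
    t_prefix <- "Targeted analysis of "
    titles[i] <- paste0(t_prefix, symbols[lead], " function")
    a_prefix <- "We investigated "
    a_body <- paste(symbols[genes], collapse = " and ")
    abstracts[i] <- paste0(a_prefix, a_body, " in controlled experiments.")
    off_title <- nchar(t_prefix)
    abs_base <- nchar(titles[i]) + 1L + nchar(a_prefix)
    gaps <- c(0L, cumsum(nchar(symbols[genes]) + 5L))  # " and " = 5 chars
    off_abs <- abs_base + gaps[seq_along(genes)]
    mention_rows[[i]] <- data.table::data.table(
      pmid = pmids[i],
      char_offset = c(off_title, off_abs),
      mention_text = c(symbols[lead], symbols[genes]),
      gene_id = c(gene_ids[lead], gene_ids[genes]),
      entity_type = "Gene")
    pair_rows[[i]] <- data.table::data.table(
      pmid = pmids[i], gene_id = gene_ids[genes], pub_year = y,
      in_title = genes == lead, in_abstract = TRUE)

    gb[i] <- stats::runif(1L) < p$genome_biology_fraction
    gw[i] <- stats::runif(1L) < p$gwas_fraction
    # a GWAS descriptor name itself contains a genome-biology phrase, so
    # GWAS publications are genome-biology publications by construction
    if (gw[i]) gb[i] <- TRUE
    trial[i] <- stats::runif(1L) < p$trial_rate
    keywords[[i]] <- c("gene regulation", if (gb[i]) p$gb_phrase)
    mesh[[i]] <- c("D009999:Molecular Biology",
                   if (gw[i]) "D055106:Genome-Wide Association Study")
    ptypes[[i]] <- c("D016428:Journal Article",
                     if (trial[i]) "D016430:Clinical Trial")
    funders_l[[i]] <- .sample_groups(p$funders, sample.int(2L, 1L),
                                     target_recent[i])
    codes_l[[i]] <- if (stats::runif(1L) < 0.6) {
      .sample_groups(p$activity_codes, 1L, target_recent[i])
    } else character(0)
    orgs_l[[i]] <- .sample_groups(p$organizations, sample.int(2L, 1L),
                                  target_recent[i])
  }

  # citation counts: latent uniform with class-dependent tail exponent
  # (boost k makes the class k times as likely to exceed any high
  # threshold), mapped through a lognormal quantile
  boost <- p$citation$boost[pub_class]
  u <- stats::runif(npub)^(1 / boost)
  citation_count <- as.integer(round(stats::qlnorm(
    u, meanlog = p$citation$meanlog, sdlog = p$citation$sdlog)))

  # citation edges among corpus publications (chronological order)
  edges <- vector("list", npub)
  for (i in seq_len(npub)) {
    prior <- i - 1L
    if (prior == 0L) next
    k <- stats::rpois(1L, p$reference_mean)
    if (k == 0L) next
    cited <- sample.int(prior, min(k, prior))
    edges[[i]] <- data.table::data.table(citing_pmid = pmids[i],
                                         cited_pmid = pmids[cited])
  }

  publications <- data.table::data.table(
    pmid = pmids, year = year_of, journal = p$journals$journal[jidx],
    title = titles, abstract = abstracts, keywords = keywords,
    mesh_terms = mesh, publication_types = ptypes, n_authors = n_authors,
    funders = funders_l, activity_codes = codes_l, organizations = orgs_l,
    citation_count = citation_count)

  used <- which(!is.na(first_year))
  links <- data.table::rbindlist(lapply(seq_len(npub), function(i) {
    data.table::data.table(tax_id = 9606L,
                           gene_id = pair_rows[[i]]$gene_id,
                           pmid = pmids[i])
  }))
  registry <- data.table::data.table(
    gene_id = gene_ids, symbol = symbols, tax_id = 9606L,
    gene_type = "protein-coding",
    lof_intolerant = stats::runif(ng) < 0.2,
    murine_phenotype_count = stats::rpois(ng, 2),
    gwas_trait_count = stats::rpois(ng, 0.5))

  mentions <- data.table::rbindlist(mention_rows)
  truth_pairs <- unique(data.table::rbindlist(pair_rows))
  data.table::setorder(truth_pairs, pmid, gene_id)

  out <- list(
    publications = publications, mentions = mentions, links = links,
    registry = registry,
    citations = data.table::rbindlist(edges[!vapply(edges, is.null, TRUE)]),
    truth = list(
      first_year = stats::setNames(first_year[used], gene_ids[used]),
      pairs = truth_pairs,
      pub_class = data.table::data.table(pmid = pmids, pub_year = year_of,
                                         lead_class = lead_class,
                                         class = pub_class,
                                         target_recent = target_recent,
                                         journal = p$journals$journal[jidx]),
      labels = data.table::data.table(pmid = pmids, genome_biology = gb,
                                      gwas = gw),
      params = p))
  if (p$noise) out <- .add_noise(out, p)
  class(out) <- "synthetic_corpus"
  out
}

# Noise records exercising every corpus filter; none of them contribute a
# ground-truth pair, so the filtered pipeline output still equals
# truth$pairs exactly.
.add_noise <- function(corpus, p) {
  y <- stats::median(p$years)
  gid1 <- corpus$registry$gene_id[1L]
  sym1 <- corpus$registry$symbol[1L]
  mk_pub <- function(pmid, year, types, title, abstract) {
    data.table::data.table(
      pmid = pmid, year = year, journal = p$journals$journal[1L],
      title = title, abstract = abstract,
      keywords = list("gene regulation"),
      mesh_terms = list("D009999:Molecular Biology"),
      publication_types = list(types), n_authors = 3L,
      funders = list(p$funders$group[1L]), activity_codes = list(character(0)),
      organizations = list(p$organizations$group[1L]),
      citation_count = 1L)
  }
  mk_mention <- function(pmid, title, sym, gid) {
    data.table::data.table(pmid = pmid,
                           char_offset = as.integer(regexpr(sym, title,
                                                            fixed = TRUE)) - 1L,
                           mention_text = sym, gene_id = gid,
                           entity_type = "Gene")
  }
  ttl <- function(sym) paste0("Review of ", sym, " biology")
  pubs <- list(corpus$publications)
  ments <- list(corpus$mentions)
  lnks <- list(corpus$links)

  # excluded publication type
  pubs[[length(pubs) + 1L]] <- mk_pub(900001L, y, c("D016454:Review"),
                                      ttl(sym1), "")
  ments[[length(ments) + 1L]] <- mk_mention(900001L, ttl(sym1), sym1, gid1)
  lnks[[length(lnks) + 1L]] <- data.table::data.table(
    tax_id = 9606L, gene_id = gid1, pmid = 900001L)
  # duplicated pmid: both copies must be dropped
  for (r in 1:2) {
    pubs[[length(pubs) + 1L]] <- mk_pub(900002L, y, "D016428:Journal Article",
                                        ttl(sym1), "")
  }
  ments[[length(ments) + 1L]] <- mk_mention(900002L, ttl(sym1), sym1, gid1)
  lnks[[length(lnks) + 1L]] <- data.table::data.table(
    tax_id = 9606L, gene_id = gid1, pmid = 900002L)
  # ambiguous mention (";" in gene_id)
  pubs[[length(pubs) + 1L]] <- mk_pub(900003L, y, "D016428:Journal Article",
                                      ttl(sym1), "")
  amb <- mk_mention(900003L, ttl(sym1), sym1,
                    paste(gid1, corpus$registry$gene_id[2L], sep = ";"))
  ments[[length(ments) + 1L]] <- amb
  lnks[[length(lnks) + 1L]] <- data.table::data.table(
    tax_id = 9606L, gene_id = gid1, pmid = 900003L)
  # non-coding gene of the right taxon
  pubs[[length(pubs) + 1L]] <- mk_pub(900004L, y, "D016428:Journal Article",
                                      ttl("NCRNA01"), "")
  ments[[length(ments) + 1L]] <- mk_mention(900004L, ttl("NCRNA01"),
                                            "NCRNA01", "N000001")
  lnks[[length(lnks) + 1L]] <- data.table::data.table(
    tax_id = 9606L, gene_id = "N000001", pmid = 900004L)
  # protein-coding gene of a foreign taxon; publication only linked there
  pubs[[length(pubs) + 1L]] <- mk_pub(900005L, y, "D016428:Journal Article",
                                      ttl("MUSG01"), "")
  ments[[length(ments) + 1L]] <- mk_mention(900005L, ttl("MUSG01"),
                                            "MUSG01", "M000001")
  lnks[[length(lnks) + 1L]] <- data.table::data.table(
    tax_id = 10090L, gene_id = "M000001", pmid = 900005L)
  # publication with a real mention but no curated link at all
  pubs[[length(pubs) + 1L]] <- mk_pub(900006L, y, "D016428:Journal Article",
                                      ttl(sym1), "")
  ments[[length(ments) + 1L]] <- mk_mention(900006L, ttl(sym1), sym1, gid1)

  corpus$publications <- data.table::rbindlist(pubs)
  corpus$mentions <- data.table::rbindlist(ments)
  corpus$links <- data.table::rbindlist(lnks)
  corpus$registry <- rbind(
    corpus$registry,
    data.table::data.table(gene_id = c("N000001", "M000001"),
                           symbol = c("NCRNA01", "MUSG01"),
                           tax_id = c(9606L, 10090L),
                           gene_type = c("ncRNA", "protein-coding"),
                           lof_intolerant = FALSE,
                           murine_phenotype_count = 0L,
                           gwas_trait_count = 0L))
  corpus
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "synthetic corpus: %d publications, %d mentions, %d genes used, %d citation edges\n",
    nrow(x$publications), nrow(x$mentions), length(x$truth$first_year),
    nrow(x$citations)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits `publications.tsv`, `mentions.tsv`, `gene2pubmed.tsv`,
#' `gene_info.tsv`, and `citations.tsv` in the dialects read by the
#' ingestion functions (list fields "|"-delimited).
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @param list_sep Delimiter for list-valued fields.
#' @return Invisibly, the named vector of file paths.
#' @export
write_corpus <- function(corpus, dir, list_sep = "|") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pub <- data.table::copy(corpus$publications)
  for (col in .pub_list_cols) {
    data.table::set(pub, j = col, value = collapse_list(pub[[col]], list_sep))
  }
  reg <- data.table::copy(corpus$registry)
  reg$lof_intolerant <- as.integer(reg$lof_intolerant)
  paths <- c(publications = file.path(dir, "publications.tsv"),
             mentions = file.path(dir, "mentions.tsv"),
             links = file.path(dir, "gene2pubmed.tsv"),
             registry = file.path(dir, "gene_info.tsv"),
             citations = file.path(dir, "citations.tsv"))
  data.table::fwrite(pub, paths[["publications"]], sep = "\t", quote = FALSE)
  data.table::fwrite(corpus$mentions, paths[["mentions"]], sep = "\t",
                     quote = FALSE)
  data.table::fwrite(corpus$links, paths[["links"]], sep = "\t",
                     quote = FALSE)
  data.table::fwrite(reg, paths[["registry"]], sep = "\t", quote = FALSE)
  data.table::fwrite(corpus$citations, paths[["citations"]], sep = "\t",
                     quote = FALSE)
  invisible(paths)
}

#' Tiny hand-specified fixtures
#'
#' Deterministic miniature data sets whose expected statistics are
#' hand-verifiable:
#' \describe{
#'   \item{`"fisher-worked"`}{A 24-publication corpus whose single scanned
#'     journal yields the contingency table (1, 9, 11, 3).}
#'   \item{`"disruption-0.4"`}{A citation graph around one focal node with
#'     3 focal-only citers, 1 both-citer, and 1 reference-only citer
#'     (disruption index 0.4).}
#'   \item{`"two-block-journals"`}{A journal-by-gene percentage matrix with
#'     a planted two-block structure.}
#' }
#'
#' @param name Fixture name.
#' @return A list of fixture components (documented per fixture).
#' @export
make_toy_fixture <- function(name) {
  switch(name,
    "fisher-worked" = {
      # journal JA: 10 pubs, 1 highlighting a new gene; other journals:
      # 14 pubs, 11 highlighting new genes -> table (1, 9, 11, 3)
      n <- 24L
      pmid <- 1:24
      journal <- rep(c("JA", "JB"), c(10L, 14L))
      target <- c(rep(c(TRUE, FALSE), c(1L, 9L)),
                  rep(c(TRUE, FALSE), c(11L, 3L)))
      # one pair per publication; target pubs highlight a fresh gene
      gene <- ifelse(target, sprintf("T%03d", pmid), "OLD1")
      pairs <- data.table::data.table(
        pmid = pmid, gene_id = gene, pub_year = 2015L,
        in_title = TRUE, in_abstract = FALSE)
      age <- data.table::data.table(
        gene_id = unique(gene),
        first_year = ifelse(unique(gene) == "OLD1", 2000L, 2015L),
        first_year_title = NA_integer_)
      records <- data.table::data.table(pmid = pmid, year = 2015L,
                                        journal = journal)
      list(pairs = pairs, age_table = age, records = records,
           membership = data.table::data.table(pmid = pmid, group = journal),
           expected_table = c(a = 1L, b = 9L, c = 11L, d = 3L))
    },
    "disruption-0.4" = {
      focal <- 100L
      refs <- c(1L, 2L)
      edges <- data.table::data.table(
        citing_pmid = c(focal, focal,      # focal cites its 2 refs
                        201L, 202L, 203L,  # cite focal only
                        204L, 204L,        # cites focal and a ref
                        205L),             # cites a ref only
        cited_pmid = c(refs, focal, focal, focal, focal, 1L, 2L))
      nodes <- data.table::data.table(
        pmid = c(refs, focal, 201:205),
        year = c(1990L, 1990L, 2000L, rep(2005L, 5L)),
        publication_types = list("D016428:Journal Article"))
      list(graph = citation_graph(edges, nodes), focal = focal,
           expected = list(n_focal_only = 3L, n_both = 1L, n_ref_only = 1L,
                           d_index = 0.4))
    },
    "two-block-journals" = {
      m <- rbind(c(40, 35, 2, 1),
                 c(2, 1, 50, 45),
                 c(38, 33, 1, 2),
                 c(3, 2, 48, 44))  # planted blocks, rows interleaved
      dimnames(m) <- list(c("J1", "J3", "J2", "J4"), sprintf("G%d", 1:4))
      list(matrix = m, planted_rows = list(c("J1", "J2"), c("J3", "J4")))
    },
    stopf("unknown fixture: %s", name))
}
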