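# Reading the four tabular input dialects and building the unique
# gene-highlight table. Publications come in a MEDLINE-derived TSV,
# mentions in a PubTator-style offset TSV, curated links in gene2pubmed
# layout, and the gene registry in a gene_info-derived layout.

#' MEDLINE publication types excluded from the research-publication corpus
#'
#' The non-research publication types (reviews, letters, comments, errata,
#' and other editorial material) whose presence disqualifies a record from
#' the analysis corpus. Codes are `"Dxxxxxx:Name"` strings as they appear in
#' the `publication_types` field.
#'
#' @return Character vector of excluded publication-type strings.
#' @export
medline_excluded_types <- function() {
  c("D016454:Review", "D016422:Letter", "D016420:Comment",
    "D016421:Editorial", "D016456:Historical Article", "D016433:News",
    "D019215:Biography", "D016425:Published Erratum",
    "D054711:Introductory Journal Article", "D019477:Portrait",
    "D017203:Interview", "D016424:Overall", "D017065:Practice Guideline",
    "D059040:Video-Audio Media", "D018431:Newspaper Article",
    "D016417:Bibliography", "D016440:Retraction of Publication",
    "D016441:Retracted Publication", "D019531:Lecture", "D016435:Directory",
    "D016419:Classical Article", "D019484:Address",
    "D029282:Patient Education Handout", "D062210:Personal Narrative",
    "D020493:Autobiography", "D020485:Legislation", "D016221:Festschrift",
    "D016438:Duplicate Publication", "D057405:Webcast", "D064886:Dataset",
    "D016437:Dictionary", "D000075742:Expression of Concern",
    "D016453:Periodical Index", "D054710:Interactive Tutorial",
    "D016426:Scientific Integrity Review", "D020470:Collected Works",
    "D057405:Webcasts")
}

.pub_list_cols <- c("keywords", "mesh_terms", "publication_types",
                    "funders", "activity_codes", "organizations")
.pub_cols <- c("pmid", "year", "journal", "title", "abstract",
               .pub_list_cols[1:3], "n_authors", .pub_list_cols[4:6])

#' Read publication records
#'
#' Reads a tab-separated publications file with one row per indexed
#' publication. List-valued fields (keywords, MeSH terms, publication types,
#' funders, activity codes, organizations) are split on `list_sep` into list
#' columns; a missing abstract becomes the empty string. The loader does not
#' filter: duplicated pmids are loaded as-is and handled by
#' [filter_research_publications()].
#'
#' @param path Path to a TSV file with a header row and columns `pmid`,
#'   `year`, `journal`, `title`, `abstract`, `keywords`, `mesh_terms`,
#'   `publication_types`, `n_authors`, `funders`, `activity_codes`,
#'   `organizations`. An optional `citation_count` column is carried through.
#' @param list_sep Delimiter inside list-valued fields; default `"|"`.
#' @return A `data.table` with typed columns and list columns for the
#'   list-valued fields.
#' @export
read_publications <- function(path, list_sep = "|") {
  if (!file.exists(path)) stopf("publications file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, encoding = "UTF-8",
                          quote = "")
  assert_columns(dt, .pub_cols, "publications file")
  year <- suppressWarnings(as.integer(dt$year))
  if (anyNA(year)) {
    bad <- dt$pmid[which(is.na(year))[1L]]
    stopf("unparseable year for pmid %s", bad)
  }
  out <- data.table::data.table(
    pmid = as.integer(dt$pmid),
    year = year,
    journal = dt$journal,
    title = dt$title,
    abstract = ifelse(is.na(dt$abstract), "", dt$abstract),
    n_authors = as.integer(dt$n_authors)
  )
  for (col in .pub_list_cols) {
    data.table::set(out, j = col, value = split_field(dt[[col]], list_sep))
  }
  if ("citation_count" %in% names(dt)) {
    data.table::set(out, j = "citation_count",
                    value = as.integer(dt$citation_count))
  }
  out[]
}

#' Read gene mentions (PubTator-style offsets)
#'
#' Reads a tab-separated mention file with columns `pmid`, `char_offset`,
#' `mention_text`, `gene_id`, `entity_type`. Rows whose `entity_type` is not
#' `"Gene"` are ignored. Offsets are 0-based positions into the
#' concatenation of title and abstract (see [locate_mention_section()]).
#'
#' @param path Path to the mentions TSV.
#' @return A `data.table` of gene mentions.
#' @export
read_mentions <- function(path) {
  if (!file.exists(path)) stopf("mentions file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, encoding = "UTF-8", quote = "")
  assert_columns(dt, c("pmid", "char_offset", "mention_text", "gene_id",
                       "entity_type"), "mentions file")
  dt <- dt[dt$entity_type == "Gene"]
  data.table::data.table(
    pmid = as.integer(dt$pmid),
    char_offset = as.integer(dt$char_offset),
    mention_text = dt$mention_text,
    gene_id = dt$gene_id
  )
}

#' Read curated gene-publication links (gene2pubmed layout)
#'
#' @param path Path to a TSV with columns `tax_id`, `gene_id`, `pmid`.
#' @return A `data.table` of curated links.
#' @export
read_gene_links <- function(path) {
  if (!file.exists(path)) stopf("gene links file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, quote = "")
  assert_columns(dt, c("tax_id", "gene_id", "pmid"), "gene links file")
  data.table::data.table(
    tax_id = as.integer(dt$tax_id),
    gene_id = dt$gene_id,
    pmid = as.integer(dt$pmid)
  )
}

#' Read the gene registry (gene_info-derived layout)
#'
#' Mandatory columns are `gene_id`, `symbol`, `tax_id`, `gene_type`.
#' Optional annotation columns `lof_intolerant` (pLI > 0.9 flag),
#' `murine_phenotype_count`, and `gwas_trait_count` default to
#' `FALSE`/`0` when absent.
#'
#' @param path Path to the registry TSV.
#' @return A `data.table` with one row per gene.
#' @export
read_gene_registry <- function(path) {
  if (!file.exists(path)) stopf("gene registry file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, quote = "")
  assert_columns(dt, c("gene_id", "symbol", "tax_id", "gene_type"),
                 "gene registry file")
  if (anyDuplicated(dt$gene_id)) stopf("gene registry has duplicated gene_id")
  out <- data.table::data.table(
    gene_id = dt$gene_id,
    symbol = dt$symbol,
    tax_id = as.integer(dt$tax_id),
    gene_type = dt$gene_type,
    lof_intolerant = if ("lof_intolerant" %in% names(dt)) {
      as.logical(as.integer(dt$lof_intolerant) > 0 |
                   toupper(dt$lof_intolerant) == "TRUE")
    } else FALSE,
    murine_phenotype_count = if ("murine_phenotype_count" %in% names(dt)) {
      as.integer(dt$murine_phenotype_count)
    } else 0L,
    gwas_trait_count = if ("gwas_trait_count" %in% names(dt)) {
      as.integer(dt$gwas_trait_count)
    } else 0L
  )
  out$murine_phenotype_count[is.na(out$murine_phenotype_count)] <- 0L
  out$gwas_trait_count[is.na(out$gwas_trait_count)] <- 0L
  out$lof_intolerant[is.na(out$lof_intolerant)] <- FALSE
  out[]
}

#' Filter records down to research publications
#'
#' Applies, in order: removal of records carrying any excluded publication
#' type, removal of records published after `year_max`, and removal of all
#' copies of any pmid occurring more than once (the duplicated publications
#' are excluded entirely, not deduplicated to one copy). The operation is
#' idempotent.
#'
#' @param records Publications as returned by [read_publications()].
#' @param year_max Last analysis year (records after it are dropped);
#'   default 2018.
#' @param excluded_types Publication-type strings that disqualify a record;
#'   defaults to [medline_excluded_types()].
#' @return The surviving subset of `records` (possibly empty).
#' @export
filter_research_publications <- function(records, year_max = 2018,
                                         excluded_types = medline_excluded_types()) {
  assert_columns(records, c("pmid", "year", "publication_types"), "records")
  keep_type <- !vapply(records$publication_types,
                       function(tt) any(tt %in% excluded_types), logical(1))
  out <- records[keep_type & records$year <= year_max]
  dup <- out$pmid[duplicated(out$pmid)]
  if (length(dup)) out <- out[!out$pmid %in% dup]
  out
}

#' Locate the section of a mention offset
#'
#' Offsets are 0-based into the concatenation of title, a separator of
#' `sep_len` characters, and abstract. An offset inside the title span
#' yields `"title"`, inside the abstract span `"abstract"`, and anything
#' else (separator positions, or past the end) `"beyond"`.
#'
#' @param char_offset Integer vector of 0-based offsets.
#' @param title,abstract Character vectors (recycled per offset).
#' @param sep_len Separator width between title and abstract; default 1.
#' @return Character vector over `{"title", "abstract", "beyond"}`.
#' @export
locate_mention_section <- function(char_offset, title, abstract, sep_len = 1L) {
  if (any(char_offset < 0, na.rm = TRUE)) stopf("negative mention offset")
  nt <- nchar(title)
  na_ <- nchar(abstract)
  ifelse(char_offset < nt, "title",
         ifelse(char_offset >= nt + sep_len & char_offset < nt + sep_len + na_,
                "abstract", "beyond"))
}

#' Build the unique gene-highlight table
#'
#' Intersects the four inputs into the atomic unit of the analysis: unique
#' (publication, gene) pairs in which the gene is mentioned by name in the
#' title or abstract of a filtered research publication. The curated link
#' table acts at publication level (a pmid must carry at least one link for
#' the configured taxon); the mention annotations supply the gene
#' identities. Ambiguous mentions (gene_id containing `";"`), mentions
#' falling beyond the abstract, and genes that are absent from the registry,
#' not protein-coding, or of a different taxon are dropped. Repeated
#' mentions of a gene in one publication collapse to a single pair carrying
#' the union of sections.
#'
#' @param records Filtered publications (see
#'   [filter_research_publications()]).
#' @param mentions Mentions from [read_mentions()].
#' @param links Curated links from [read_gene_links()].
#' @param registry Gene registry from [read_gene_registry()].
#' @param taxon Taxon identifier to retain; default 9606 (human).
#' @param sep_len Title/abstract separator width used for offsets.
#' @return A `data.table` with columns `pmid`, `gene_id`, `pub_year`,
#'   `in_title`, `in_abstract`; unique on (pmid, gene_id).
#' @export
build_highlight_table <- function(records, mentions, links, registry,
                                  taxon = 9606L, sep_len = 1L) {
  pmid <- gene_id <- in_title <- in_abstract <- NULL  # NSE notes
  linked <- unique(links$pmid[links$tax_id == taxon])
  keep_genes <- registry$gene_id[registry$gene_type == "protein-coding" &
                                   registry$tax_id == taxon]
  m <- mentions[mentions$pmid %in% records$pmid & mentions$pmid %in% linked]
  if (nrow(m)) m <- m[!grepl(";", m$gene_id, fixed = TRUE)]
  if (nrow(m)) m <- m[m$gene_id %in% keep_genes]
  if (nrow(m) == 0L) {
    return(data.table::data.table(pmid = integer(0), gene_id = character(0),
                                  pub_year = integer(0), in_title = logical(0),
                                  in_abstract = logical(0)))
  }
  rec <- records[, c("pmid", "year", "title", "abstract"), with = FALSE]
  m <- merge(m, rec, by = "pmid", sort = FALSE)
  m$section <- locate_mention_section(m$char_offset, m$title, m$abstract,
                                      sep_len = sep_len)
  m <- m[m$section != "beyond"]
  if (nrow(m) == 0L) {
    return(data.table::data.table(pmid = integer(0), gene_id = character(0),
                                  pub_year = integer(0), in_title = logical(0),
                                  in_abstract = logical(0)))
  }
  out <- m[, list(pub_year = year[1L],
                  in_title = any(section == "title"),
                  in_abstract = any(section == "abstract")),
           by = c("pmid", "gene_id")]
  data.table::setorder(out, pmid, gene_id)
  out[]
}
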