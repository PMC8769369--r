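# Labelling publications as genome biology and/or genome-wide association
# studies from their text fields, using packaged phrase lexicons.

GWAS_MESH_CODE <- "D055106"

#' Load a packaged phrase lexicon
#'
#' Lexicons ship as plain-text resources, one phrase per line, lowercase.
#' `"genome_biology"` holds the phrases defining genome-biology
#' publications; `"gwas"` the genome-wide association study phrases. A file
#' path may be supplied instead of a name.
#'
#' @param name `"genome_biology"`, `"gwas"`, or a path to a custom lexicon
#'   file.
#' @return Character vector of unique lowercase phrases.
#' @export
load_lexicon <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", paste0("lexicon_", name, ".txt"),
                package = "genelit")
  }
  if (!nzchar(path) || !file.exists(path)) stopf("unknown lexicon: %s", name)
  phrases <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  phrases <- unique(tolower(phrases[nzchar(phrases)]))
  if (length(phrases) == 0L) stopf("lexicon %s is empty", name)
  phrases
}

# internal: one case-insensitive regex for a whole lexicon.
# token_bounded = TRUE anchors each phrase at non-alphanumeric boundaries so
# that short listed tokens ("wes", "ngs") cannot match inside ordinary words
# ("western"); multi-word phrases match literally across their single
# spaces. token_bounded = FALSE is a raw-substring sensitivity mode.
.lexicon_regex <- function(lexicon, token_bounded = TRUE) {
  esc <- gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1", lexicon, perl = TRUE)
  alt <- paste(esc, collapse = "|")
  if (token_bounded) {
    paste0("(?<![[:alnum:]])(?:", alt, ")(?![[:alnum:]])")
  } else {
    paste0("(?:", alt, ")")
  }
}

#' Match text fields against a phrase lexicon
#'
#' Case-insensitive containment of any lexicon phrase in the supplied text.
#' With `token_bounded = TRUE` (default) a phrase must be delimited by
#' non-alphanumeric characters or string edges; with `FALSE` raw substring
#' containment is used (sensitivity mode).
#'
#' @param text Character vector; each element is tested independently (join
#'   multiple fields with a space beforehand, see [label_corpus()]).
#' @param lexicon Character vector of lowercase phrases.
#' @param token_bounded Logical; see Description.
#' @return Logical vector; empty text gives `FALSE`.
#' @export
match_lexicon <- function(text, lexicon, token_bounded = TRUE) {
  if (length(text) == 0L) return(logical(0))
  text <- tolower(ifelse(is.na(text), "", text))
  grepl(.lexicon_regex(lexicon, token_bounded), text, perl = TRUE)
}

# internal: join per-record text fields into one searchable string
.record_text <- function(records, include_mesh_names = FALSE) {
  kw <- collapse_list(records$keywords, sep = " ")
  base <- paste(records$title, records$abstract, kw)
  if (include_mesh_names) {
    mesh_names <- vapply(records$mesh_terms, function(mm) {
      paste(sub("^[^:]*:", "", mm), collapse = " ")
    }, character(1))
    base <- paste(base, mesh_names)
  }
  base
}

#' Genome-wide association study flag
#'
#' A publication counts as a GWAS if (i) its MeSH terms carry descriptor
#' code `D055106`, or (ii) its pmid appears in the association-catalog pmid
#' set, or (iii) title, abstract, or author-submitted keywords match the
#' GWAS phrase lexicon (MeSH descriptor names are deliberately excluded
#' from the phrase matching for this lexicon).
#'
#' @param records Publications table.
#' @param catalog_pmids Integer vector of catalog pmids (may be empty).
#' @param lexicon GWAS lexicon; default the packaged one.
#' @param token_bounded Matching mode, see [match_lexicon()].
#' @return Logical vector, one flag per record.
#' @export
is_gwas <- function(records, catalog_pmids = integer(0),
                    lexicon = load_lexicon("gwas"), token_bounded = TRUE) {
  mesh_hit <- vapply(records$mesh_terms, function(mm) {
    any(sub(":.*$", "", mm) == GWAS_MESH_CODE)
  }, logical(1))
  catalog_hit <- records$pmid %in% catalog_pmids
  phrase_hit <- match_lexicon(.record_text(records, include_mesh_names = FALSE),
                              lexicon, token_bounded)
  mesh_hit | catalog_hit | phrase_hit
}

#' Label a corpus with field flags
#'
#' One label per record with two independent flags: `genome_biology`
#' (phrase match over title, abstract, keywords, and MeSH descriptor names)
#' and `gwas` (see [is_gwas()]). Classification is deterministic,
#' idempotent, and invariant under case changes of the input text.
#'
#' @param records Publications table.
#' @param catalog_pmids GWAS-catalog pmids (may be empty).
#' @param gb_lexicon,gwas_lexicon Phrase lexicons; default the packaged
#'   ones.
#' @param token_bounded Matching mode, see [match_lexicon()].
#' @return A `data.table` with columns `pmid`, `genome_biology`, `gwas`.
#' @export
label_corpus <- function(records, catalog_pmids = integer(0),
                         gb_lexicon = load_lexicon("genome_biology"),
                         gwas_lexicon = load_lexicon("gwas"),
                         token_bounded = TRUE) {
  gb <- match_lexicon(.record_text(records, include_mesh_names = TRUE),
                      gb_lexicon, token_bounded)
  data.table::data.table(
    pmid = records$pmid,
    genome_biology = gb,
    gwas = is_gwas(records, catalog_pmids, gwas_lexicon, token_bounded))
}
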