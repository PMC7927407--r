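#' Construct a document record
#'
#' A document carries the tokenized abstract plus the three term fields
#' that together form its "word list" (chemical substances, MeSH headings,
#' author keywords). Field lengths are derived: `dl` is the abstract length
#' in tokens after stop-word removal; `dcl`, `dml`, `dkl` count the terms
#' of the three list fields; and `dwl = dcl + dml + dkl` is the word-list
#' length.
#'
#' @param doc_id Non-empty identifier (e.g. a PMID).
#' @param abstract_tokens Character vector of abstract tokens.
#' @param chemical_terms,mesh_terms,keyword_terms Character vectors of
#'   normalized multi-word terms (see [normalize_term()]).
#' @return An object of class `bm25_document`.
#' @export
new_document <- function(doc_id, abstract_tokens = character(),
                         chemical_terms = character(),
                         mesh_terms = character(),
                         keyword_terms = character()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1, nzchar(doc_id))
  doc <- list(
    doc_id = doc_id,
    abstract_tokens = as.character(abstract_tokens),
    chemical_terms = as.character(chemical_terms),
    mesh_terms = as.character(mesh_terms),
    keyword_terms = as.character(keyword_terms)
  )
  doc$dl <- length(doc$abstract_tokens)
  doc$dcl <- length(doc$chemical_terms)
  doc$dml <- length(doc$mesh_terms)
  doc$dkl <- length(doc$keyword_terms)
  doc$dwl <- doc$dcl + doc$dml + doc$dkl
  structure(doc, class = "bm25_document")
}

#' @export
print.bm25_document <- function(x, ...) {
  cat(sprintf("<bm25_document %s: dl=%d dcl=%d dml=%d dkl=%d dwl=%d>\n",
              x$doc_id, x$dl, x$dcl, x$dml, x$dkl, x$dwl))
  invisible(x)
}

#' Parse MEDLINE-dialect XML into documents
#'
#' Reads article records (`PubmedArticle` / `MedlineCitation` elements)
#' and extracts the PMID, abstract text, chemical list, MeSH heading list
#' and keyword list. The abstract is tokenized with stop-word removal;
#' the three list fields are kept as sequences of normalized multi-word
#' terms. Missing fields yield empty sequences and zero lengths. Records
#' without an identifier are skipped with a warning.
#'
#' @param xml Path to an XML file, or a length-1 XML string.
#' @param stopwords Stop-word list applied to the abstract.
#' @return List of `bm25_document` objects.
#' @export
parse_medline_xml <- function(xml, stopwords = bm25_stopwords()) {
  doc <- xml2::read_xml(xml)
  articles <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(articles) == 0) {
    # tolerate a bare <Article>/<ArticleSet> dialect without citations
    articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  }
  out <- vector("list", length(articles))
  keep <- logical(length(articles))
  for (i in seq_along(articles)) {
    a <- articles[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning(sprintf("record %d has no PMID; skipped", i), call. = FALSE)
      next
    }
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
      collapse = " ")
    chem <- xml2::xml_text(
      xml2::xml_find_all(a, ".//ChemicalList/Chemical/NameOfSubstance"))
    mesh <- xml2::xml_text(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    kw <- xml2::xml_text(xml2::xml_find_all(a, ".//KeywordList/Keyword"))
    out[[i]] <- new_document(
      doc_id = pmid,
      abstract_tokens = tokenize(abstract, stopwords),
      chemical_terms = normalize_term(chem),
      mesh_terms = normalize_term(mesh),
      keyword_terms = normalize_term(kw)
    )
    keep[i] <- TRUE
  }
  out[keep]
}
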