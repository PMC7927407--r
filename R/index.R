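#' Build an in-memory inverted index and corpus statistics
#'
#' Computes the corpus-level constants that feed every IDF variant of the
#' ranking function: the document count `D`, the mean abstract length
#' `avgdl` over all documents, the number `N_wl` of documents with a
#' non-empty word list, the mean word-list length `avgdwl` over those
#' documents, and document-frequency maps for abstract tokens, word-list
#' terms, and tokens appearing in any field (the latter backs the gene
#' IDF used by the co-word score). Per-document abstract term frequencies
#' are stored for O(1) lookup at scoring time.
#'
#' @param documents Non-empty list of [new_document()] objects.
#' @return An object of class `bm25_index`.
#' @export
build_index <- function(documents) {
  if (length(documents) == 0) stop("empty corpus")
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus")
  names(documents) <- ids

  dl <- vapply(documents, `[[`, integer(1), "dl")
  dwl <- vapply(documents, `[[`, integer(1), "dwl")

  tf_abstract <- lapply(documents, function(d) {
    if (d$dl == 0) return(integer())
    tab <- table(d$abstract_tokens)
    stats::setNames(as.integer(tab), names(tab))
  })
  wordlist <- lapply(documents, function(d) {
    c(d$chemical_terms, d$mesh_terms, d$keyword_terms)
  })

  count_df <- function(per_doc_terms) {
    uniq <- lapply(per_doc_terms, unique)
    tab <- table(unlist(uniq, use.names = FALSE))
    stats::setNames(as.integer(tab), names(tab))
  }

  df_abstract <- count_df(lapply(documents, `[[`, "abstract_tokens"))
  df_wordlist <- count_df(wordlist)
  # token-level presence over the union of all four fields
  df_token_any <- count_df(lapply(documents, function(d) {
    c(d$abstract_tokens,
      unlist(strsplit(wordlist[[d$doc_id]], " ", fixed = TRUE),
             use.names = FALSE))
  }))

  structure(list(
    documents = documents,
    doc_ids = ids,
    D = length(documents),
    dl = dl,
    dwl = dwl,
    avgdl = mean(dl),
    N_wl = sum(dwl > 0),
    avgdwl = if (any(dwl > 0)) mean(dwl[dwl > 0]) else 0,
    df_abstract = df_abstract,
    df_wordlist = df_wordlist,
    df_token_any = df_token_any,
    tf_abstract = tf_abstract,
    wordlist = wordlist
  ), class = "bm25_index")
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf(paste0(
    "<bm25_index: D=%d docs, avgdl=%.2f, N_wl=%d word-list docs, ",
    "avgdwl=%.2f>\n"), x$D, x$avgdl, x$N_wl, x$avgdwl))
  invisible(x)
}

# term frequency of `term` in the abstract of `doc_id` (0 if absent)
doc_tf <- function(index, doc_id, term) {
  tf <- index$tf_abstract[[doc_id]][term]
  if (is.na(tf)) 0L else unname(tf)
}
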