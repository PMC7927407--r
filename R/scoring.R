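#' Ranking-function parameters
#'
#' The tunable vector of the composite ranking function: `k1` (abstract
#' term-frequency saturation), `k2` (query-frequency factor, fixed at 1
#' and algebraically inert because duplicate query terms are collapsed),
#' `k3` (word-list saturation), `b1`/`b2` (abstract and word-list length
#' normalization, in \[0,1\]) and `alpha` (weight of the co-word score).
#'
#' @param k1,k3 Saturation factors, > 0.
#' @param k2 Query-frequency factor (kept for fidelity; has no effect).
#' @param b1,b2 Length-normalization factors in \[0,1\].
#' @param alpha Co-word weight, >= 0.
#' @return Object of class `model_params`.
#' @export
model_params <- function(k1 = 1.2, k3 = 1.2, b1 = 0.75, b2 = 0.75,
                         alpha = 1, k2 = 1) {
  stopifnot(k1 > 0, k3 > 0, b1 >= 0, b1 <= 1, b2 >= 0, b2 <= 1, alpha >= 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3, b1 = b1, b2 = b2,
                 alpha = alpha), class = "model_params")
}

#' Parameter presets
#'
#' `"normal"` is the conventional empirical setting (k1 = k3 = 1.2,
#' b1 = b2 = 0.75, alpha = 1); `"cs"` is the Cuckoo-Search-optimized
#' setting (k1 = 3.59, k3 = 1.3, b1 = 0.84, b2 = 1, alpha = 4), which
#' shifts weight toward the expanded word list and the co-word signal.
#'
#' @param name `"normal"`, `"cs"`, or a path to a JSON file with fields
#'   k1, k3, b1, b2, alpha.
#' @return A [model_params()] object.
#' @export
params_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("params_", tolower(name), ".json"),
                package = "cobm25")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown preset or missing file '%s'", name))
  p <- jsonlite::fromJSON(path)
  model_params(k1 = p$k1, k3 = p$k3, b1 = p$b1, b2 = p$b2, alpha = p$alpha)
}

# single named constant: the logarithm used by every IDF variant
score_log <- function(x) log(x)

#' Abstract IDF (classic form)
#'
#' `log(D / df)` with the document frequency floored at 1 so that terms
#' absent from the corpus get the maximal weight `log(D)` instead of a
#' division by zero.
#'
#' @param term Abstract token.
#' @param index A [build_index()] object.
#' @return Numeric IDF value.
#' @export
idf_abstract <- function(term, index) {
  if (index$D == 0) stop("empty corpus")
  df <- index$df_abstract[term]
  df <- if (is.na(df)) 1L else max(df, 1L)
  score_log(index$D / df)
}

#' BM25 relevance factor for one abstract term
#'
#' `f (k1 + 1) / (f + K)` with
#' `K = k1 (1 - b1 + b1 dl / avgdl)`. Query-term frequency is 1 by
#' construction, so the query-side factor is unity.
#'
#' @param f Term frequency in the abstract.
#' @param dl Abstract length of the document.
#' @param index A [build_index()] object (supplies avgdl).
#' @param params A [model_params()] object.
#' @return Numeric relevance factor.
#' @export
relevance_r <- function(f, dl, index, params) {
  if (f <= 0) return(0)
  rel_len <- if (index$avgdl > 0) dl / index$avgdl else 0
  K <- params$k1 * (1 - params$b1 + params$b1 * rel_len)
  f * (params$k1 + 1) / (f + K)
}

#' Abstract score of a document
#'
#' Sum over the query's abstract terms of IDF times the saturated term
#' frequency. Terms absent from the abstract contribute nothing; a
#' document without an abstract scores 0.
#'
#' @param query An [build_expanded_query()] object.
#' @param doc_id Document identifier.
#' @param index A [build_index()] object.
#' @param params A [model_params()] object.
#' @return Numeric score.
#' @export
score_abstract <- function(query, doc_id, index, params) {
  dl <- index$dl[[doc_id]]
  if (dl == 0) return(0)
  total <- 0
  for (term in query$abstract_terms) {
    f <- doc_tf(index, doc_id, term)
    if (f > 0)
      total <- total + idf_abstract(term, index) *
        relevance_r(f, dl, index, params)
  }
  total
}

#' Word-list IDF of an expanded term
#'
#' The smoothed form `log((N - n + 0.5) / (n + 0.5))`, where `N` is the
#' number of documents with a non-empty word list and `n` the number of
#' documents whose word list contains the term. Values go negative when
#' the term appears in more than half of the word-list documents; by
#' default they are preserved as defined.
#'
#' @param term Normalized expanded term.
#' @param index A [build_index()] object.
#' @param floor_zero Floor negative values at zero (off by default).
#' @return Numeric IDF value.
#' @export
idf_word <- function(term, index, floor_zero = FALSE) {
  if (index$N_wl == 0) stop("no word-list documents")
  n <- unname(index$df_wordlist[term])
  if (is.na(n)) n <- 0L
  v <- score_log((index$N_wl - n + 0.5) / (n + 0.5))
  if (floor_zero) max(v, 0) else v
}

#' Word-list matched-term weight of a document
#'
#' The "frequency value" of the expanded words: the sum of word-list IDFs
#' of the query's expanded terms that are present in the document's word
#' list. Presence is exact equality of normalized terms; occurrence
#' counts do not enter (each matching term contributes its IDF once).
#'
#' @inheritParams score_abstract
#' @param floor_zero Passed to [idf_word()].
#' @return Numeric weight (0 when nothing matches).
#' @export
tf_word <- function(query, doc_id, index, floor_zero = FALSE) {
  wl <- index$wordlist[[doc_id]]
  if (length(wl) == 0) return(0)
  hits <- query$wordlist_terms[query$wordlist_terms %in% wl]
  if (length(hits) == 0) return(0)
  sum(vapply(hits, idf_word, numeric(1), index = index,
             floor_zero = floor_zero))
}

#' Expanded-word score of a document
#'
#' Saturates the matched-term weight with the word-list analogue of the
#' BM25 transfer function:
#' `tf (k3 + 1) / (tf + k3 (1 - b2 + b2 dwl / avgdwl))`.
#' Documents with an empty word list score 0.
#'
#' @inheritParams tf_word
#' @param params A [model_params()] object.
#' @return Numeric score (bounded above by `k3 + 1`).
#' @export
score_word <- function(query, doc_id, index, params, floor_zero = FALSE) {
  tf <- tf_word(query, doc_id, index, floor_zero)
  if (tf == 0) return(0)
  dwl <- index$dwl[[doc_id]]
  rel_len <- if (index$avgdwl > 0) dwl / index$avgdwl else 0
  tf * (params$k3 + 1) /
    (tf + params$k3 * (1 - params$b2 + params$b2 * rel_len))
}

# does `term` (normalized multi-word string) occur in a field?
# abstracts: contiguous token subsequence; list fields: contiguous token
# subsequence within a single term (so "ras" never matches "kras").
term_in_tokens <- function(term, tokens) {
  contains_seq(tokens, strsplit(term, " ", fixed = TRUE)[[1]])
}
term_in_field <- function(term, field_terms) {
  needle <- strsplit(term, " ", fixed = TRUE)[[1]]
  for (ft in field_terms) {
    if (contains_seq(strsplit(ft, " ", fixed = TRUE)[[1]], needle))
      return(TRUE)
  }
  FALSE
}

#' Detect disease-gene co-occurrence in a document
#'
#' Two detection modes over the four fields (abstract, chemical list,
#' MeSH headings, keywords):
#' * `"cross"` — the disease may occur in any field and the gene in any
#'   (possibly different) field;
#' * `"within"` — the disease and the gene must co-occur inside the same
#'   field.
#' Every within-mode match is therefore also a cross-mode match.
#' Matching is contiguous token-subsequence matching on normalized terms.
#'
#' @param doc A `bm25_document`.
#' @param disease_terms Normalized disease terms (any one may match).
#' @param gene_terms Gene symbols (lowercase tokens).
#' @param mode `"cross"` or `"within"`.
#' @return Character vector of matched genes (possibly empty).
#' @export
detect_coword <- function(doc, disease_terms, gene_terms,
                          mode = c("cross", "within")) {
  mode <- match.arg(mode)
  fields <- list(abstract = doc$abstract_tokens,
                 chemical = doc$chemical_terms,
                 mesh = doc$mesh_terms,
                 keyword = doc$keyword_terms)
  present <- function(term, field, is_abstract) {
    if (is_abstract) term_in_tokens(term, field) else term_in_field(term, field)
  }
  dis_in <- vapply(seq_along(fields), function(i) {
    any(vapply(disease_terms, present, logical(1), fields[[i]], i == 1))
  }, logical(1))
  matched <- character()
  for (g in gene_terms) {
    g_in <- vapply(seq_along(fields), function(i) {
      present(g, fields[[i]], i == 1)
    }, logical(1))
    hit <- if (mode == "cross") any(dis_in) && any(g_in)
           else any(dis_in & g_in)
    if (hit) matched <- c(matched, g)
  }
  matched
}

#' Gene IDF for the co-word score
#'
#' Same smoothed form as [idf_word()] but with `N` the total number of
#' corpus documents (set `use_wordlist_n = TRUE` for the restricted
#' reading where `N` counts only word-list documents) and `n` the number
#' of documents containing the gene token in any field.
#'
#' @param gene Gene symbol (lowercase token).
#' @param index A [build_index()] object.
#' @param use_wordlist_n Use `N_wl` instead of `D`.
#' @param floor_zero Floor negative values at zero.
#' @return Numeric IDF value.
#' @export
idf_gene <- function(gene, index, use_wordlist_n = FALSE,
                     floor_zero = FALSE) {
  N <- if (use_wordlist_n) index$N_wl else index$D
  n <- unname(index$df_token_any[gene])
  if (is.na(n)) n <- 0L
  v <- score_log((N - n + 0.5) / (n + 0.5))
  if (floor_zero) max(v, 0) else v
}

#' Co-word score of a document
#'
#' The sum of gene IDFs over the genes detected by [detect_coword()];
#' 0 when no gene co-occurs with the disease.
#'
#' @inheritParams score_abstract
#' @param mode Co-word detection mode, `"cross"` (default) or
#'   `"within"`.
#' @param use_wordlist_n,floor_zero Passed to [idf_gene()].
#' @return Numeric score.
#' @export
score_coword <- function(query, doc_id, index, mode = "cross",
                         use_wordlist_n = FALSE, floor_zero = FALSE) {
  matched <- detect_coword(index$documents[[doc_id]], query$disease_terms,
                           query$gene_terms, mode)
  if (length(matched) == 0) return(0)
  sum(vapply(matched, idf_gene, numeric(1), index = index,
             use_wordlist_n = use_wordlist_n, floor_zero = floor_zero))
}

#' Composite score of a document
#'
#' The final retrieval score
#' `abstract + word + alpha * coword`, returned together with its
#' components for audit. The decomposition is an exact identity.
#'
#' @inheritParams score_coword
#' @param params A [model_params()] object.
#' @return An object of class `score_breakdown` with fields
#'   `score_abstract`, `score_word`, `score_coword`, `score_composite`,
#'   `coword_flag`.
#' @export
score_composite <- function(query, doc_id, index, params, mode = "cross",
                            use_wordlist_n = FALSE, floor_zero = FALSE) {
  sa <- score_abstract(query, doc_id, index, params)
  sw <- score_word(query, doc_id, index, params, floor_zero)
  sc <- score_coword(query, doc_id, index, mode, use_wordlist_n, floor_zero)
  structure(list(
    score_abstract = sa,
    score_word = sw,
    score_coword = sc,
    score_composite = sa + sw + params$alpha * sc,
    coword_flag = sc != 0 || length(
      detect_coword(index$documents[[doc_id]], query$disease_terms,
                    query$gene_terms, mode)) > 0
  ), class = "score_breakdown")
}

#' Precompute per-topic sufficient statistics for fast ranking
#'
#' For a fixed corpus and query, everything the composite score needs
#' except the parameters can be computed once: the abstract
#' term-frequency matrix and IDF vector, the word-list matched-term
#' weights, the co-word scores and flags, and the field lengths. Ranking
#' at new parameter values is then a vectorized arithmetic evaluation,
#' which is what makes parameter optimization tractable.
#'
#' @inheritParams score_coword
#' @return An object of class `query_profile`.
#' @export
query_profile <- function(query, index, mode = "cross",
                          use_wordlist_n = FALSE, floor_zero = FALSE) {
  ids <- index$doc_ids
  terms <- query$abstract_terms
  F <- matrix(0, nrow = length(ids), ncol = length(terms),
              dimnames = list(ids, terms))
  for (j in seq_along(terms)) {
    F[, j] <- vapply(ids, function(id) doc_tf(index, id, terms[j]),
                     numeric(1))
  }
  idf <- vapply(terms, idf_abstract, numeric(1), index = index)
  tfw <- vapply(ids, function(id) tf_word(query, id, index, floor_zero),
                numeric(1))
  cw <- vapply(ids, function(id) {
    score_coword(query, id, index, mode, use_wordlist_n, floor_zero)
  }, numeric(1))
  coword_flag <- vapply(ids, function(id) {
    length(detect_coword(index$documents[[id]], query$disease_terms,
                         query$gene_terms, mode)) > 0
  }, logical(1))
  structure(list(
    topic_id = query$topic_id, doc_ids = ids, F = F, idf = idf,
    dl = unname(index$dl), dwl = unname(index$dwl),
    avgdl = index$avgdl, avgdwl = index$avgdwl,
    tfw = unname(tfw), cw = unname(cw), coword_flag = unname(coword_flag)
  ), class = "query_profile")
}

#' Composite scores for all documents of a profile
#'
#' Vectorized evaluation of the composite score at given parameters;
#' numerically identical to calling [score_composite()] per document.
#'
#' @param profile A [query_profile()] object.
#' @param params A [model_params()] object.
#' @return Numeric vector of composite scores, aligned with
#'   `profile$doc_ids`.
#' @export
profile_scores <- function(profile, params) {
  rel_dl <- if (profile$avgdl > 0) profile$dl / profile$avgdl else
    rep(0, length(profile$dl))
  K <- params$k1 * (1 - params$b1 + params$b1 * rel_dl)
  sat <- profile$F * (params$k1 + 1) / (profile$F + K)  # K recycles by row
  sat[profile$F == 0] <- 0
  sa <- as.vector(sat %*% profile$idf)
  sa[profile$dl == 0] <- 0

  rel_dwl <- if (profile$avgdwl > 0) profile$dwl / profile$avgdwl else
    rep(0, length(profile$dwl))
  denom <- profile$tfw + params$k3 * (1 - params$b2 + params$b2 * rel_dwl)
  sw <- ifelse(profile$tfw == 0, 0,
               profile$tfw * (params$k3 + 1) / denom)

  sa + sw + params$alpha * profile$cw
}

#' Rank a corpus for one expanded query
#'
#' Scores every document with the composite function, sorts by score
#' descending with ties broken by ascending document id, and truncates
#' to the top `top_k`.
#'
#' @inheritParams score_coword
#' @param params A [model_params()] object.
#' @param top_k Maximum run depth per topic (default 1000).
#' @param tag Run label.
#' @param profile Optional precomputed [query_profile()]; supplied by
#'   callers that rank repeatedly at different parameters.
#' @return Data frame of run entries: `topic_id`, `doc_id`, `rank`,
#'   `score`, `tag`.
#' @export
rank_corpus <- function(query, index, params, mode = "cross",
                        top_k = 1000, tag = "cobm25", profile = NULL,
                        use_wordlist_n = FALSE, floor_zero = FALSE) {
  stopifnot(top_k >= 1)
  if (is.null(profile))
    profile <- query_profile(query, index, mode, use_wordlist_n, floor_zero)
  scores <- profile_scores(profile, params)
  ord <- order(-scores, profile$doc_ids)
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(
    topic_id = query$topic_id,
    doc_id = profile$doc_ids[ord],
    rank = seq_along(ord),
    score = scores[ord],
    tag = tag,
    stringsAsFactors = FALSE
  )
}
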