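# Independent straight-line oracles. These deliberately share no code
# with the package: document frequencies are recomputed by brute-force
# scans, subsequence matching uses delimited-string search instead of
# token loops, and the nDCG oracle uses base-10 logs (the ratio must be
# base-invariant).

# --- scoring oracle: direct transcription of the composite ranking ----

oracle_field_string <- function(tokens) {
  paste0(" ", paste(tokens, collapse = " "), " ")
}

# term (normalized, space-joined) occurs contiguously in a token vector
oracle_in_tokens <- function(term, tokens) {
  if (length(tokens) == 0) return(FALSE)
  grepl(paste0(" ", term, " "), oracle_field_string(tokens), fixed = TRUE)
}

# term occurs contiguously within any single multi-word term of a field
oracle_in_field <- function(term, field_terms) {
  any(vapply(field_terms, function(ft) {
    oracle_in_tokens(term, strsplit(ft, " ", fixed = TRUE)[[1]])
  }, logical(1)))
}

oracle_doc_wordlist <- function(doc) {
  c(doc$chemical_terms, doc$mesh_terms, doc$keyword_terms)
}

oracle_doc_all_tokens <- function(doc) {
  c(doc$abstract_tokens,
    unlist(strsplit(oracle_doc_wordlist(doc), " ", fixed = TRUE),
           use.names = FALSE))
}

# full composite score of one document, computed from the raw document
# list with no index structure
oracle_score_composite <- function(query, doc, documents, params,
                                   mode = "cross") {
  D <- length(documents)
  dls <- vapply(documents, function(d) length(d$abstract_tokens), numeric(1))
  avgdl <- mean(dls)
  dl <- length(doc$abstract_tokens)

  sa <- 0
  for (term in query$abstract_terms) {
    f <- sum(doc$abstract_tokens == term)
    if (f == 0 || dl == 0) next
    df <- sum(vapply(documents, function(d) term %in% d$abstract_tokens,
                     logical(1)))
    idf <- log(D / max(df, 1))
    K <- params$k1 * (1 - params$b1 + params$b1 * dl / avgdl)
    sa <- sa + idf * f * (params$k1 + 1) / (f + K)
  }

  wls <- lapply(documents, oracle_doc_wordlist)
  dwls <- lengths(wls)
  Nwl <- sum(dwls > 0)
  sw <- 0
  wl <- oracle_doc_wordlist(doc)
  if (length(wl) > 0 && Nwl > 0) {
    avgdwl <- mean(dwls[dwls > 0])
    tf <- 0
    for (term in query$wordlist_terms) {
      if (!term %in% wl) next
      n <- sum(vapply(wls, function(w) term %in% w, logical(1)))
      tf <- tf + log((Nwl - n + 0.5) / (n + 0.5))
    }
    if (tf != 0) {
      dwl <- length(wl)
      sw <- tf * (params$k3 + 1) /
        (tf + params$k3 * (1 - params$b2 + params$b2 * dwl / avgdwl))
    }
  }

  fields <- list(doc$abstract_tokens, doc$chemical_terms, doc$mesh_terms,
                 doc$keyword_terms)
  in_f <- function(term, i) {
    if (i == 1) oracle_in_tokens(term, fields[[1]])
    else oracle_in_field(term, fields[[i]])
  }
  dis <- vapply(1:4, function(i) {
    any(vapply(query$disease_terms, in_f, logical(1), i))
  }, logical(1))
  sc <- 0
  for (g in query$gene_terms) {
    gin <- vapply(1:4, function(i) in_f(g, i), logical(1))
    hit <- if (mode == "cross") any(dis) && any(gin) else any(dis & gin)
    if (hit) {
      n <- sum(vapply(documents, function(d) g %in% oracle_doc_all_tokens(d),
                      logical(1)))
      sc <- sc + log((D - n + 0.5) / (n + 0.5))
    }
  }
  list(score_abstract = sa, score_word = sw, score_coword = sc,
       score_composite = sa + sw + params$alpha * sc)
}

# --- metric oracles ---------------------------------------------------

oracle_p_at_k <- function(ranked, grades, k = 10) {
  rel <- names(grades)[grades > 0]
  sum(utils::head(ranked, k) %in% rel) / k
}

oracle_ndcg <- function(ranked, grades, z = 1000) {
  if (length(grades) == 0 || all(grades == 0)) return(0)
  g <- grades[utils::head(ranked, z)]
  g[is.na(g)] <- 0
  dcg <- if (length(g)) sum(g / log10(seq_along(g) + 1)) else 0
  ig <- utils::head(sort(unname(grades), decreasing = TRUE), z)
  dcg / sum(ig / log10(seq_along(ig) + 1))
}

oracle_r_precision <- function(ranked, grades) {
  rel <- names(grades)[grades > 0]
  R <- length(rel)
  if (R == 0) return(0)
  sum(utils::head(ranked, R) %in% rel) / R
}

oracle_recall_f1 <- function(ranked, grades) {
  rel <- names(grades)[grades > 0]
  RR <- sum(ranked %in% rel)
  p <- if (length(ranked)) RR / length(ranked) else 0
  r <- if (length(rel)) RR / length(rel) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}
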