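#' Synthetic collection configuration
#'
#' Controls the generator used for hermetic testing. Defaults emulate the
#' field statistics of large MEDLINE-scale precision-medicine corpora:
#' mean field lengths 77.5 (abstract tokens), 3.8 (chemical terms),
#' 10.5 (MeSH headings), 4.1 (keywords), and field-presence rates 0.49 /
#' 0.92 / 0.15 matching the fraction of articles carrying each list.
#' A `coword_fraction` of documents carries a planted disease-gene pair;
#' relevance of a document to the pair's topic is Bernoulli with rate
#' `base_relevance`, raised by `coword_boost` when the pair is present,
#' which plants the statistical association the co-word score exploits.
#'
#' @param n_docs Number of documents.
#' @param vocab_size Vocabulary size (Zipf-distributed tokens).
#' @param zipf_exponent Zipf exponent (default 1.1).
#' @param mean_abstract,mean_chemical,mean_mesh,mean_keyword Mean field
#'   lengths (Poisson).
#' @param p_chemical,p_mesh,p_keyword Probability that a document carries
#'   the field.
#' @param n_topics Number of topics / planted disease-gene pairs.
#' @param coword_fraction Fraction of documents with a planted pair.
#' @param partial_fraction Fraction of documents mentioning only one
#'   side of a pair (the disease or the gene alone), emulating the many
#'   articles that discuss a disease without the queried gene; these
#'   give the abstract and word-list scores something to rank that the
#'   co-word score correctly ignores.
#' @param same_field_prob Probability a planted pair lands inside one
#'   field (detectable in "within" mode) rather than across two fields.
#' @param base_relevance Relevance rate without the pair.
#' @param coword_boost Additional relevance rate when the pair is
#'   present.
#' @param grade2_prob Probability a relevant document gets grade 2
#'   rather than 1.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 1000, vocab_size = 2000,
                         zipf_exponent = 1.1,
                         mean_abstract = 77.5, mean_chemical = 3.8,
                         mean_mesh = 10.5, mean_keyword = 4.1,
                         p_chemical = 0.49, p_mesh = 0.92,
                         p_keyword = 0.15,
                         n_topics = 10, coword_fraction = 0.15,
                         partial_fraction = 0.25,
                         same_field_prob = 0.5,
                         base_relevance = 0.02, coword_boost = 0.35,
                         grade2_prob = 0.4) {
  stopifnot(n_docs >= 1, vocab_size >= 1, zipf_exponent > 0,
            mean_abstract > 0, mean_chemical > 0, mean_mesh > 0,
            mean_keyword > 0,
            p_chemical >= 0, p_chemical <= 1, p_mesh >= 0, p_mesh <= 1,
            p_keyword >= 0, p_keyword <= 1,
            n_topics >= 1, coword_fraction >= 0, coword_fraction <= 1,
            partial_fraction >= 0, coword_fraction + partial_fraction <= 1,
            same_field_prob >= 0, same_field_prob <= 1,
            base_relevance >= 0, base_relevance + coword_boost <= 1,
            grade2_prob >= 0, grade2_prob <= 1)
  structure(as.list(environment()), class = "synth_config")
}

synth_disease <- function(i) sprintf("Neoplasm Dtype%02d", i)
synth_gene <- function(i) sprintf("GENE%02dX", i)

zipf_sample <- function(n, vocab, prob) {
  if (n == 0) return(character())
  vocab[sample.int(length(vocab), n, replace = TRUE, prob = prob)]
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic MEDLINE-dialect corpus
#'
#' Documents have Poisson field lengths around the configured means,
#' Zipf-distributed synthetic tokens, Bernoulli field presence, and a
#' `coword_fraction` subset carrying a planted disease-gene pair placed
#' either inside one field or across two fields. Output parses
#' losslessly through [parse_medline_xml()] and, for a fixed RNG state,
#' is byte-identical across runs.
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed; NULL uses the current RNG state.
#' @return Character vector of XML lines, with attribute `"plants"`: a
#'   data frame (doc_index, pair, placement).
#' @export
generate_corpus <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$vocab_size < 1) stop("zero vocabulary")
  if (!is.null(seed)) set.seed(seed)
  vocab <- sprintf("w%05d", seq_len(config$vocab_size))
  prob <- seq_len(config$vocab_size)^(-config$zipf_exponent)

  n_plant <- round(config$coword_fraction * config$n_docs)
  plant_docs <- if (n_plant > 0)
    sort(sample.int(config$n_docs, n_plant)) else integer()
  plant_pair <- if (n_plant > 0)
    sample(rep_len(seq_len(config$n_topics), n_plant)) else integer()
  plant_map <- stats::setNames(plant_pair, plant_docs)

  n_partial <- round(config$partial_fraction * config$n_docs)
  free <- setdiff(seq_len(config$n_docs), plant_docs)
  partial_docs <- if (n_partial > 0)
    sort(sample(free, min(n_partial, length(free)))) else integer()
  partial_pair <- if (length(partial_docs))
    sample.int(config$n_topics, length(partial_docs), replace = TRUE)
    else integer()
  partial_side <- if (length(partial_docs))
    sample(c("disease", "gene"), length(partial_docs), replace = TRUE)
    else character()
  partial_map <- stats::setNames(seq_along(partial_docs), partial_docs)

  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<PubmedArticleSet>")
  placements <- character(length(plant_docs))
  fillers <- c("the", "of", "and", "in", "with", "for")
  fields4 <- c("abstract", "chemical", "mesh", "keyword")

  for (i in seq_len(config$n_docs)) {
    pmid <- sprintf("%07d", 1000000 + i)
    abstract <- zipf_sample(stats::rpois(1, config$mean_abstract),
                            vocab, prob)
    make_terms <- function(p, mean_len) {
      if (stats::runif(1) >= p) return(character())
      k <- stats::rpois(1, mean_len)
      if (k == 0) return(character())
      vapply(seq_len(k), function(.) {
        paste(zipf_sample(sample(1:2, 1), vocab, prob), collapse = " ")
      }, character(1))
    }
    chem <- make_terms(config$p_chemical, config$mean_chemical)
    mesh <- make_terms(config$p_mesh, config$mean_mesh)
    kw <- make_terms(config$p_keyword, config$mean_keyword)

    pair <- plant_map[as.character(i)]
    if (!is.na(pair)) {
      disease <- tolower(synth_disease(pair))
      gene <- tolower(synth_gene(pair))
      same <- stats::runif(1) < config$same_field_prob
      f1 <- sample(fields4, 1)
      f2 <- if (same) f1 else sample(setdiff(fields4, f1), 1)
      put <- function(field, term) {
        switch(field,
          abstract = {
            toks <- strsplit(term, " ", fixed = TRUE)[[1]]
            pos <- sample.int(length(abstract) + 1, 1) - 1
            abstract <<- append(abstract, toks, after = pos)
          },
          chemical = chem <<- c(chem, term),
          mesh = mesh <<- c(mesh, term),
          keyword = kw <<- c(kw, term))
      }
      put(f1, disease)
      put(f2, gene)
      placements[match(i, plant_docs)] <-
        if (same) "within" else "cross"
    }
    pidx <- partial_map[as.character(i)]
    if (!is.na(pidx)) {
      term <- if (partial_side[pidx] == "disease")
        tolower(synth_disease(partial_pair[pidx]))
      else tolower(synth_gene(partial_pair[pidx]))
      f <- sample(fields4, 1)
      switch(f,
        abstract = {
          toks <- strsplit(term, " ", fixed = TRUE)[[1]]
          pos <- sample.int(length(abstract) + 1, 1) - 1
          abstract <- append(abstract, toks, after = pos)
        },
        chemical = chem <- c(chem, term),
        mesh = mesh <- c(mesh, term),
        keyword = kw <- c(kw, term))
    }

    # sprinkle stop-words into the abstract rendering; they are removed
    # again at parse time so dl tracks the configured mean
    render <- abstract
    if (length(render) > 3) {
      at <- sort(sample.int(length(render), min(5, length(render))))
      for (k in rev(seq_along(at))) {
        render <- append(render, fillers[1 + (k %% length(fillers))],
                         after = at[k])
      }
    }
    term_block <- function(terms, list_tag, item_open, item_close) {
      if (length(terms) == 0) return(character())
      c(sprintf("<%s>", list_tag),
        sprintf("%s%s%s", item_open, xml_escape(terms), item_close),
        sprintf("</%s>", list_tag))
    }
    lines <- c(lines,
      "<PubmedArticle><MedlineCitation>",
      sprintf("<PMID>%s</PMID>", pmid),
      sprintf("<Article><Abstract><AbstractText>%s</AbstractText></Abstract></Article>",
              xml_escape(paste(render, collapse = " "))),
      term_block(chem, "ChemicalList",
                 "<Chemical><NameOfSubstance>", "</NameOfSubstance></Chemical>"),
      term_block(mesh, "MeshHeadingList",
                 "<MeshHeading><DescriptorName>", "</DescriptorName></MeshHeading>"),
      term_block(kw, "KeywordList", "<Keyword>", "</Keyword>"),
      "</MedlineCitation></PubmedArticle>")
  }
  lines <- c(lines, "</PubmedArticleSet>")
  attr(lines, "plants") <- data.frame(doc_index = plant_docs,
                                      pair = unname(plant_pair),
                                      placement = placements,
                                      stringsAsFactors = FALSE)
  lines
}

#' Generate topics and graded qrels for a synthetic corpus
#'
#' One topic per planted disease-gene pair, with a sampled age and sex.
#' Every document is judged: the probability of relevance is
#' `base_relevance`, plus `coword_boost` when the document actually
#' contains both the topic's disease and gene (cross-field detection on
#' the parsed documents, so accidental plants are judged consistently).
#' Relevant documents receive grade 2 with probability `grade2_prob`,
#' otherwise grade 1.
#'
#' @param config A [synth_config()].
#' @param documents Parsed corpus (list of `bm25_document`, e.g. from
#'   [parse_medline_xml()] on [generate_corpus()] output).
#' @param seed Optional integer seed.
#' @return List with `topics_xml` and `qrels_lines` (character vectors).
#' @export
generate_topics_and_qrels <- function(config, documents, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (round(config$coword_fraction * config$n_docs) < config$n_topics)
    stop("more topics than planted disease-gene pairs")
  if (!is.null(seed)) set.seed(seed)
  ages <- c(4, 9, 15, 26, 38, 45, 52, 64, 71, 83)
  topics_xml <- c('<?xml version="1.0" encoding="UTF-8"?>', "<topics>")
  qrels <- character()
  for (t in seq_len(config$n_topics)) {
    disease <- synth_disease(t)
    gene <- synth_gene(t)
    age <- sample(ages, 1)
    sex <- sample(c("male", "female"), 1)
    topics_xml <- c(topics_xml, sprintf(
      '<topic number="%d"><disease>%s</disease><gene>%s (V%dE)</gene><demographic>%d-year-old %s</demographic><other>None</other></topic>',
      t, disease, gene, t, age, sex))
    dterms <- normalize_term(disease)
    gterms <- tolower(gene)
    for (d in documents) {
      has_pair <- length(detect_coword(d, dterms, gterms, "cross")) > 0
      p <- config$base_relevance + if (has_pair) config$coword_boost else 0
      grade <- 0L
      if (stats::runif(1) < p) {
        grade <- if (stats::runif(1) < config$grade2_prob) 2L else 1L
      }
      qrels <- c(qrels, sprintf("%d 0 %s %d", t, d$doc_id, grade))
    }
  }
  topics_xml <- c(topics_xml, "</topics>")
  list(topics_xml = topics_xml, qrels_lines = qrels)
}

#' Write a complete synthetic collection to disk
#'
#' Generates corpus, topics and qrels under one seed and writes
#' `corpus.xml`, `topics.xml` and `qrels.txt` into `out_dir`. Output is
#' byte-identical for identical config and seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_collection <- function(config, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  corpus <- generate_corpus(config)
  docs <- parse_medline_xml(paste(corpus, collapse = "\n"))
  tq <- generate_topics_and_qrels(config, docs)
  paths <- list(corpus = file.path(out_dir, "corpus.xml"),
                topics = file.path(out_dir, "topics.xml"),
                qrels = file.path(out_dir, "qrels.txt"))
  writeLines(corpus, paths$corpus)
  writeLines(tq$topics_xml, paths$topics)
  writeLines(tq$qrels_lines, paths$qrels)
  invisible(paths)
}
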