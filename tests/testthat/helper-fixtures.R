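# In-code fixture builders. All randomness uses the caller's RNG state;
# tests set their own seeds.

fix_doc <- function(id, abstract = character(), chem = character(),
                    mesh = character(), kw = character()) {
  new_document(id, abstract_tokens = abstract, chemical_terms = chem,
               mesh_terms = mesh, keyword_terms = kw)
}

# a random corpus of bare documents with occasional planted disease/gene
# material, exercising all four fields
random_corpus <- function(n_docs = 50, vocab_size = 80) {
  vocab <- sprintf("t%03d", seq_len(vocab_size))
  diseases <- c("alpha disease", "beta syndrome")
  genes <- c("gx1", "gx2")
  lapply(seq_len(n_docs), function(i) {
    abstract <- sample(vocab, rpois(1, 20), replace = TRUE)
    chem <- if (runif(1) < 0.5)
      replicate(rpois(1, 2) + 1,
                paste(sample(vocab, sample(1:2, 1)), collapse = " "))
      else character()
    mesh <- if (runif(1) < 0.8)
      replicate(rpois(1, 4) + 1,
                paste(sample(vocab, sample(1:2, 1)), collapse = " "))
      else character()
    kw <- if (runif(1) < 0.3) sample(vocab, rpois(1, 2) + 1) else character()
    if (runif(1) < 0.35) {
      d <- sample(diseases, 1)
      g <- sample(genes, 1)
      where <- sample(1:4, 2, replace = TRUE)
      if (1 %in% where) abstract <- append(
        abstract, strsplit(d, " ")[[1]],
        after = sample.int(length(abstract) + 1, 1) - 1)
      if (2 %in% where) chem <- c(chem, d)
      if (3 %in% where) mesh <- c(mesh, paste(d, "variant"))
      if (4 %in% where) kw <- c(kw, d)
      slot <- sample(1:4, 1)
      if (slot == 1) abstract <- c(abstract, g)
      if (slot == 2) chem <- c(chem, g)
      if (slot == 3) mesh <- c(mesh, g)
      if (slot == 4) kw <- c(kw, g)
    }
    fix_doc(sprintf("D%04d", i), abstract, as.character(chem),
            as.character(mesh), as.character(kw))
  })
}

# a random expanded query aimed at a random_corpus()
random_query <- function(vocab_size = 80, topic_id = "1") {
  vocab <- sprintf("t%03d", seq_len(vocab_size))
  structure(list(
    topic_id = topic_id,
    abstract_terms = unique(c(sample(vocab, 4), "alpha", "gx1")),
    wordlist_terms = unique(c(
      vapply(1:3, function(.) paste(sample(vocab, sample(1:2, 1)),
                                    collapse = " "), character(1)),
      "alpha disease")),
    disease_terms = c("alpha disease", "beta syndrome")[sample(1:2, 1)],
    gene_terms = c("gx1", "gx2")[seq_len(sample(1:2, 1))],
    n_wordlist = 4L, n_genes = 1L
  ), class = "expanded_query")
}

# random run + qrels pair for metric cross-validation
random_run_qrels <- function(n_topics = 3, n_docs = 40, depth = 25) {
  ids <- sprintf("P%03d", seq_len(n_docs))
  runs <- list(); qr <- list()
  for (t in seq_len(n_topics)) {
    ranked <- sample(ids, depth)
    runs[[t]] <- data.frame(topic_id = as.character(t), doc_id = ranked,
                            rank = seq_len(depth),
                            score = sort(runif(depth), decreasing = TRUE),
                            tag = "fix", stringsAsFactors = FALSE)
    judged <- sample(ids, sample(15:n_docs, 1))
    qr[[t]] <- data.frame(topic_id = as.character(t), doc_id = judged,
                          grade = sample(0:2, length(judged), replace = TRUE,
                                         prob = c(0.6, 0.25, 0.15)),
                          stringsAsFactors = FALSE)
  }
  qrels <- do.call(rbind, qr)
  class(qrels) <- c("qrels", "data.frame")
  list(run = do.call(rbind, runs), qrels = qrels)
}

grades_for <- function(qrels, topic) {
  sub <- qrels[qrels$topic_id == topic, ]
  stats::setNames(sub$grade, sub$doc_id)
}
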