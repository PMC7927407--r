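mini_query <- function(abstract = character(), wordlist = character(),
                       disease = character(), genes = character()) {
  structure(list(topic_id = "q", abstract_terms = abstract,
                 wordlist_terms = wordlist, disease_terms = disease,
                 gene_terms = genes, n_wordlist = length(wordlist),
                 n_genes = length(genes)),
            class = "expanded_query")
}

test_that("abstract IDF follows log(D/df) with a df floor of one", {
  idx <- build_index(list(
    fix_doc("a", abstract = c("t", "u")), fix_doc("b", abstract = "t"),
    fix_doc("c", abstract = "v"), fix_doc("d", abstract = "v")))
  expect_equal(idf_abstract("t", idx), log(2), tolerance = 1e-12)
  expect_equal(idf_abstract("zzz", idx), log(4), tolerance = 1e-12)
  idx1 <- build_index(list(fix_doc("a", abstract = "t"),
                           fix_doc("b", abstract = "t"),
                           fix_doc("c", abstract = "t"),
                           fix_doc("d", abstract = "t")))
  expect_equal(idf_abstract("t", idx1), 0)
})

test_that("the saturated relevance factor matches its closed form", {
  idx <- build_index(list(fix_doc("a", abstract = c("x", "y"))))
  p <- model_params(k1 = 1.2, b1 = 0.75)
  # at dl = avgdl the length term cancels: K = k1
  expect_equal(relevance_r(2, idx$avgdl, idx, p), 4.4 / 3.2,
               tolerance = 1e-12)
  expect_equal(relevance_r(0, 5, idx, p), 0)
  # with b1 = 0 the value is dl-invariant
  p0 <- model_params(b1 = 0)
  expect_equal(relevance_r(3, 1, idx, p0), relevance_r(3, 100, idx, p0))
})

test_that("single-term abstract score reduces to idf at dl = avgdl", {
  idx <- build_index(list(fix_doc("a", abstract = c("apple", "pear")),
                          fix_doc("b", abstract = c("plum", "fig"))))
  q <- mini_query(abstract = "apple")
  p <- model_params(k1 = 1.2, b1 = 0.75)
  expect_equal(score_abstract(q, "a", idx, p), log(2), tolerance = 1e-12)
  expect_equal(score_abstract(q, "b", idx, p), 0)
})

test_that("abstract score is monotone in term frequency and length", {
  set.seed(11)
  # filler tokens are single letters, so the query term "qq" cannot
  # collide with them (a collision would zero the IDF)
  idx <- build_index(list(
    fix_doc("lo", abstract = c(rep("qq", 1), sample(letters, 10, TRUE))),
    fix_doc("hi", abstract = c(rep("qq", 2), sample(letters, 9, TRUE))),
    fix_doc("long", abstract = c(rep("qq", 2), sample(letters, 40, TRUE))),
    fix_doc("pad", abstract = sample(letters, 20, TRUE))))
  q <- mini_query(abstract = "qq")
  p <- model_params(k1 = 1.2, b1 = 1)
  # f = 2 vs f = 1 at equal dl: strictly larger
  expect_gt(score_abstract(q, "hi", idx, p),
            score_abstract(q, "lo", idx, p))
  # same f, longer abstract, b1 = 1: strictly smaller
  expect_lt(score_abstract(q, "long", idx, p),
            score_abstract(q, "hi", idx, p))
  # b1 = 0: invariant to length
  p0 <- model_params(b1 = 0)
  expect_equal(score_abstract(q, "long", idx, p0),
               score_abstract(q, "hi", idx, p0), tolerance = 1e-12)
})

test_that("word-list IDF follows the smoothed form, negatives preserved", {
  docs <- c(lapply(1:1, function(i) fix_doc(paste0("w", i), mesh = "rare term")),
            lapply(2:3, function(i) fix_doc(paste0("w", i), mesh = "common")),
            list(fix_doc("nowl", abstract = "x")))
  idx <- build_index(docs)   # N_wl = 3
  expect_equal(idf_word("rare term", idx), log(2.5 / 1.5), tolerance = 1e-12)
  expect_equal(idf_word("common", idx), log(1.5 / 2.5), tolerance = 1e-12)
  expect_lt(idf_word("common", idx), 0)
  expect_equal(idf_word("common", idx, floor_zero = TRUE), 0)
  # symmetric midpoint: n = N/2 gives exactly zero
  docs100 <- lapply(1:100, function(i) {
    fix_doc(paste0("d", i), mesh = if (i <= 50) "half" else "other")
  })
  expect_equal(idf_word("half", build_index(docs100)), 0, tolerance = 1e-12)
  expect_error(idf_word("x", build_index(list(fix_doc("a", abstract = "t")))),
               "no word-list documents")
})

test_that("matched-term weight sums IDFs of present expanded words", {
  idx <- build_index(list(
    fix_doc("a", mesh = c("alpha", "beta")),
    fix_doc("b", mesh = "alpha"),
    fix_doc("c", kw = "gamma")))
  q <- mini_query(wordlist = c("alpha", "beta", "absent"))
  expect_equal(tf_word(q, "a", idx),
               idf_word("alpha", idx) + idf_word("beta", idx),
               tolerance = 1e-12)
  expect_equal(tf_word(q, "c", idx), 0)
  # brute-force recomputation
  brute <- sum(vapply(c("alpha", "beta"), function(t) {
    n <- sum(vapply(idx$documents, function(d)
      t %in% c(d$chemical_terms, d$mesh_terms, d$keyword_terms), logical(1)))
    log((idx$N_wl - n + 0.5) / (n + 0.5))
  }, numeric(1)))
  expect_equal(tf_word(q, "a", idx), brute, tolerance = 1e-12)
})

test_that("expanded-word score saturates at k3 + 1 and matches closed form", {
  idx <- build_index(list(
    fix_doc("a", mesh = c("alpha", "beta")),
    fix_doc("b", mesh = "alpha"),
    fix_doc("c", abstract = "x")))
  q <- mini_query(wordlist = c("alpha", "beta"))
  p <- model_params(k3 = 1.2, b2 = 0.75)
  tf <- tf_word(q, "a", idx)
  dwl <- 2
  expected <- tf * (p$k3 + 1) /
    (tf + p$k3 * (1 - p$b2 + p$b2 * dwl / idx$avgdwl))
  expect_equal(score_word(q, "a", idx, p), expected, tolerance = 1e-12)
  expect_equal(score_word(q, "c", idx, p), 0)
  # at dwl = avgdwl the transfer is tf (k3+1) / (tf + k3): equals 1 at tf = 1
  expect_equal(1 * (p$k3 + 1) / (1 + p$k3), 1)
  # saturation ceiling over random weights
  set.seed(3)
  for (tf in abs(rnorm(50, sd = 50))) {
    expect_lte(tf * (p$k3 + 1) / (tf + p$k3 * 0.9), p$k3 + 1)
  }
})

test_that("co-word detection distinguishes cross and within modes", {
  doc <- fix_doc("d", abstract = c("some", "melanoma", "text"),
                 mesh = c("braf", "other heading"))
  expect_equal(detect_coword(doc, "melanoma", "braf", "cross"), "braf")
  expect_equal(detect_coword(doc, "melanoma", "braf", "within"), character())
  both_kw <- fix_doc("k", kw = c("melanoma", "braf"))
  expect_equal(detect_coword(both_kw, "melanoma", "braf", "cross"), "braf")
  expect_equal(detect_coword(both_kw, "melanoma", "braf", "within"), "braf")
  expect_error(detect_coword(doc, "melanoma", "braf", "sideways"))
})

test_that("multi-word diseases match contiguously, not by token substring", {
  doc <- fix_doc("d", abstract = c("acute", "alpha", "disease", "noted"),
                 kw = "gx1")
  expect_equal(detect_coword(doc, "alpha disease", "gx1", "cross"), "gx1")
  scrambled <- fix_doc("s", abstract = c("disease", "of", "alpha"), kw = "gx1")
  expect_equal(detect_coword(scrambled, "alpha disease", "gx1", "cross"),
               character())
  # gene symbol must be a whole token: "ras" never matches "kras"
  kras <- fix_doc("k", abstract = c("melanoma", "kras"))
  expect_equal(detect_coword(kras, "melanoma", "ras", "cross"), character())
})

test_that("within-mode matches are a subset of cross-mode matches", {
  set.seed(17)
  for (rep in 1:30) {
    docs <- random_corpus(n_docs = 8)
    for (d in docs) {
      within <- detect_coword(d, "alpha disease", c("gx1", "gx2"), "within")
      cross <- detect_coword(d, "alpha disease", c("gx1", "gx2"), "cross")
      expect_true(all(within %in% cross))
    }
  }
})

test_that("gene IDF decreases with document frequency", {
  docs <- c(lapply(1:1, function(i) fix_doc(paste0("r", i), abstract = "rare")),
            lapply(1:5, function(i) fix_doc(paste0("c", i), abstract = "common")),
            lapply(1:4, function(i) fix_doc(paste0("p", i), abstract = "pad")))
  idx <- build_index(docs)  # D = 10
  expect_gt(idf_gene("rare", idx), idf_gene("common", idx))
  expect_equal(idf_gene("rare", idx), log((10 - 1 + 0.5) / 1.5),
               tolerance = 1e-12)
  # restricted reading uses the word-list document count
  idx2 <- build_index(list(fix_doc("a", abstract = "g", mesh = "m"),
                           fix_doc("b", abstract = "x", mesh = "m"),
                           fix_doc("c", abstract = "x")))
  expect_equal(idf_gene("g", idx2, use_wordlist_n = TRUE),
               log((2 - 1 + 0.5) / 1.5), tolerance = 1e-12)
})

test_that("co-word score sums matched gene IDFs", {
  docs <- list(
    fix_doc("d1", abstract = c("melanoma", "braf", "nras")),
    fix_doc("d2", abstract = c("braf", "only")),
    fix_doc("d3", abstract = "unrelated"))
  idx <- build_index(docs)
  q <- mini_query(disease = "melanoma", genes = c("braf", "nras"))
  expect_equal(score_coword(q, "d1", idx),
               idf_gene("braf", idx) + idf_gene("nras", idx),
               tolerance = 1e-12)
  expect_equal(score_coword(q, "d2", idx), 0)  # no disease present
})

test_that("the composite decomposition is an exact identity", {
  set.seed(23)
  docs <- random_corpus(40)
  idx <- build_index(docs)
  q <- random_query()
  p <- model_params(k1 = 2, k3 = 0.9, b1 = 0.4, b2 = 0.8, alpha = 4)
  for (id in sample(idx$doc_ids, 10)) {
    br <- score_composite(q, id, idx, p)
    expect_identical(br$score_composite,
                     br$score_abstract + br$score_word +
                       p$alpha * br$score_coword)
    if (!br$coword_flag) expect_identical(br$score_coword, 0)
  }
  p0 <- model_params(alpha = 0)
  br0 <- score_composite(q, idx$doc_ids[1], idx, p0)
  expect_identical(br0$score_composite,
                   br0$score_abstract + br0$score_word)
})

test_that("vectorized profile scores equal per-document composite scores", {
  set.seed(29)
  for (rep in 1:5) {
    docs <- random_corpus(30)
    idx <- build_index(docs)
    q <- random_query()
    prof <- query_profile(q, idx)
    p <- model_params(k1 = runif(1, 0.5, 5), k3 = runif(1, 0.5, 5),
                      b1 = runif(1), b2 = runif(1), alpha = runif(1, 0, 5))
    fast <- profile_scores(prof, p)
    slow <- vapply(idx$doc_ids, function(id)
      score_composite(q, id, idx, p)$score_composite, numeric(1))
    expect_equal(fast, unname(slow), tolerance = 1e-12)
  }
})

test_that("ranking sorts by score with doc-id tie-break and truncates", {
  docs <- list(fix_doc("doc1", abstract = c("q", "x")),
               fix_doc("doc2", abstract = c("q", "q")),
               fix_doc("doc3", abstract = c("y", "z")))
  idx <- build_index(docs)
  q <- mini_query(abstract = "q")
  run <- rank_corpus(q, idx, model_params(), top_k = 1000)
  expect_equal(run$doc_id, c("doc2", "doc1", "doc3"))
  expect_equal(run$rank, 1:3)
  expect_true(all(diff(run$score) <= 0))
  # tie: doc3 and doc4 both score 0 -> ascending doc_id
  docs2 <- c(docs, list(fix_doc("doc0", abstract = "w")))
  run2 <- rank_corpus(q, build_index(docs2), model_params())
  expect_equal(run2$doc_id[3:4], c("doc0", "doc3"))
  run1 <- rank_corpus(q, idx, model_params(), top_k = 1)
  expect_equal(run1$doc_id, "doc2")
})

test_that("composite scores match the straight-line oracle on random corpora", {
  set.seed(31)
  for (rep in 1:6) {
    docs <- random_corpus(n_docs = sample(20:60, 1))
    idx <- build_index(docs)
    q <- random_query()
    p <- model_params(k1 = runif(1, 0.5, 4), k3 = runif(1, 0.5, 4),
                      b1 = runif(1), b2 = runif(1), alpha = runif(1, 0, 5))
    mode <- sample(c("cross", "within"), 1)
    for (id in sample(seq_along(docs), 8)) {
      got <- score_composite(q, docs[[id]]$doc_id, idx, p, mode)
      want <- oracle_score_composite(q, docs[[id]], docs, p, mode)
      expect_equal(got$score_composite, want$score_composite,
                   tolerance = 1e-9)
      expect_equal(got$score_abstract, want$score_abstract,
                   tolerance = 1e-9)
      expect_equal(got$score_word, want$score_word, tolerance = 1e-9)
      expect_equal(got$score_coword, want$score_coword, tolerance = 1e-9)
    }
  }
})

test_that("parameter presets load from packaged fixtures", {
  pn <- params_preset("normal")
  expect_equal(c(pn$k1, pn$k3, pn$b1, pn$b2, pn$alpha),
               c(1.2, 1.2, 0.75, 0.75, 1))
  pc <- params_preset("cs")
  expect_equal(c(pc$k1, pc$k3, pc$b1, pc$b2, pc$alpha),
               c(3.59, 1.3, 0.84, 1, 4))
  expect_error(params_preset("nope"), "unknown preset")
})
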