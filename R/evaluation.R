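#' Precision at rank k
#'
#' Fraction of relevant documents (grade >= 1) among the first `k`
#' retrieved. The denominator stays `k` even when fewer than `k`
#' documents were retrieved (standard TREC convention).
#'
#' @param ranked_docs Character vector of doc ids in rank order.
#' @param qrels A [read_qrels()] object.
#' @param topic Topic id.
#' @param k Cutoff (default 10).
#' @return Numeric in \[0,1\].
#' @export
precision_at_k <- function(ranked_docs, qrels, topic, k = 10) {
  stopifnot(k >= 1)
  grades <- qrels_grades(qrels, topic)
  top <- ranked_docs[seq_len(min(k, length(ranked_docs)))]
  g <- grades[top]
  sum(!is.na(g) & g > 0) / k
}

#' Normalized discounted cumulative gain
#'
#' `DCG / DCG_I` with `DCG = sum_{i<=z} gain_i / log(i + 1)`. The ideal
#' `DCG_I` ranks all judged documents of the topic by non-increasing
#' grade and truncates at the same depth `z`. Gains are the relevance
#' grades themselves (`gain = "linear"`) or `2^grade - 1`
#' (`gain = "exp"`). The logarithm base cancels in the ratio. Topics
#' without any relevant document score 0.
#'
#' @inheritParams precision_at_k
#' @param z Evaluation depth (default 1000, the run depth).
#' @param gain Gain function, `"linear"` (default) or `"exp"`.
#' @return Numeric in \[0,1\].
#' @export
topic_ndcg <- function(ranked_docs, qrels, topic, z = 1000,
                       gain = c("linear", "exp")) {
  gain <- match.arg(gain)
  grades <- qrels_grades(qrels, topic)
  gfun <- if (gain == "linear") identity else function(g) 2^g - 1
  if (length(grades) == 0 || all(grades == 0)) return(0)
  top <- ranked_docs[seq_len(min(z, length(ranked_docs)))]
  g <- grades[top]
  g[is.na(g)] <- 0
  disc <- function(gv) {
    if (length(gv) == 0) return(0)
    sum(gfun(gv) / log(seq_along(gv) + 1))
  }
  ideal <- sort(grades, decreasing = TRUE)
  ideal <- ideal[seq_len(min(z, length(ideal)))]
  disc(g) / disc(ideal)
}

#' R-precision
#'
#' Precision at rank `R`, where `R` is the topic's number of relevant
#' documents. Undefined for topics without relevant documents; reported
#' as 0 with a warning in that case.
#'
#' @inheritParams precision_at_k
#' @return Numeric in \[0,1\].
#' @export
r_precision <- function(ranked_docs, qrels, topic) {
  grades <- qrels_grades(qrels, topic)
  R <- sum(grades > 0)
  if (R == 0) {
    warning(sprintf("topic %s has no relevant documents; R-precision = 0",
                    topic), call. = FALSE)
    return(0)
  }
  top <- ranked_docs[seq_len(min(R, length(ranked_docs)))]
  g <- grades[top]
  sum(!is.na(g) & g > 0) / R
}

#' Recall and F1 at the run cutoff
#'
#' With `RR` the relevant retrieved, `RN` the irrelevant retrieved and
#' `NR` the relevant not retrieved: recall = RR / (RR + NR),
#' precision = RR / (RR + RN) and F1 their harmonic mean; 0 whenever a
#' denominator vanishes.
#'
#' @inheritParams precision_at_k
#' @return Named list with `precision`, `recall`, `f1` and the counts
#'   `RR`, `RN`, `NR`.
#' @export
recall_f1 <- function(ranked_docs, qrels, topic) {
  grades <- qrels_grades(qrels, topic)
  relevant <- names(grades)[grades > 0]
  RR <- sum(ranked_docs %in% relevant)
  RN <- length(ranked_docs) - RR
  NR <- length(relevant) - RR
  precision <- if (RR + RN > 0) RR / (RR + RN) else 0
  recall <- if (RR + NR > 0) RR / (RR + NR) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       RR = RR, RN = RN, NR = NR)
}

run_docs_by_topic <- function(run) {
  split(run$doc_id[order(run$topic_id, run$rank)],
        run$topic_id[order(run$topic_id, run$rank)])
}

#' Average P@10 over all judged topics
#'
#' Arithmetic mean of per-topic P@10 over the topics of the qrels;
#' topics absent from the run contribute 0.
#'
#' @param run Run data frame (from [rank_corpus()] or
#'   [read_trec_run()]).
#' @param qrels A [read_qrels()] object.
#' @param k Cutoff (default 10).
#' @return Numeric in \[0,1\].
#' @export
avg_p10 <- function(run, qrels, k = 10) {
  topics <- qrels_topics(qrels)
  if (length(topics) == 0) stop("no topics in qrels")
  by_topic <- run_docs_by_topic(run)
  mean(vapply(topics, function(t) {
    precision_at_k(by_topic[[t]] %||% character(), qrels, t, k)
  }, numeric(1)))
}

#' Average nDCG over all judged topics
#'
#' @inheritParams avg_p10
#' @param z Evaluation depth.
#' @param gain Gain function, see [topic_ndcg()].
#' @return Numeric in \[0,1\].
#' @export
avg_ndcg <- function(run, qrels, z = 1000, gain = "linear") {
  topics <- qrels_topics(qrels)
  if (length(topics) == 0) stop("no topics in qrels")
  by_topic <- run_docs_by_topic(run)
  mean(vapply(topics, function(t) {
    topic_ndcg(by_topic[[t]] %||% character(), qrels, t, z, gain)
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average relevant-document coverage of the co-word signal
#'
#' Per topic, the fraction of relevant documents that are co-word
#' documents (both the topic's disease and gene detected), averaged over
#' topics. Topics without relevant documents are excluded from the mean
#' with a warning.
#'
#' @param qrels A [read_qrels()] object.
#' @param coword_docs Named list: topic id -> character vector of doc ids
#'   in which the topic's disease-gene co-word was detected (see
#'   [coword_documents()]).
#' @return List with `avg_cov` and the per-topic rates.
#' @export
coverage <- function(qrels, coword_docs) {
  topics <- qrels_topics(qrels)
  rates <- numeric(0)
  for (t in topics) {
    grades <- qrels_grades(qrels, t)
    relevant <- names(grades)[grades > 0]
    if (length(relevant) == 0) {
      warning(sprintf("topic %s has no relevant documents; excluded from coverage", t),
              call. = FALSE)
      next
    }
    rates[t] <- sum(relevant %in% (coword_docs[[t]] %||% character())) /
      length(relevant)
  }
  if (length(rates) == 0) stop("no topic with relevant documents")
  list(avg_cov = mean(rates), per_topic = rates)
}

#' Documents of a corpus carrying a topic's disease-gene co-word
#'
#' @param query An [build_expanded_query()] object.
#' @param index A [build_index()] object.
#' @param mode Co-word mode, `"cross"` or `"within"`.
#' @return Character vector of doc ids.
#' @export
coword_documents <- function(query, index, mode = "cross") {
  flag <- vapply(index$doc_ids, function(id) {
    length(detect_coword(index$documents[[id]], query$disease_terms,
                         query$gene_terms, mode)) > 0
  }, logical(1))
  index$doc_ids[flag]
}

#' Evaluate a run against qrels
#'
#' Computes the per-topic metrics (P@10, nDCG, R-precision, precision /
#' recall / F1 at the run cutoff and the retrieval counts) and their
#' averages over the topics of the qrels.
#'
#' @inheritParams avg_p10
#' @param z nDCG depth (default 1000).
#' @param gain nDCG gain function.
#' @return An `eval_summary`: list with `per_topic` (data frame) and
#'   `averages` (named numeric vector).
#' @export
evaluate_run <- function(run, qrels, k = 10, z = 1000, gain = "linear") {
  topics <- qrels_topics(qrels)
  if (length(topics) == 0) stop("no topics in qrels")
  by_topic <- run_docs_by_topic(run)
  rows <- lapply(topics, function(t) {
    docs <- by_topic[[t]] %||% character()
    rf <- recall_f1(docs, qrels, t)
    grades <- qrels_grades(qrels, t)
    rp <- if (sum(grades > 0) > 0) r_precision(docs, qrels, t) else NA_real_
    data.frame(topic_id = t,
               p_at_10 = precision_at_k(docs, qrels, t, k),
               ndcg = topic_ndcg(docs, qrels, t, z, gain),
               r_prec = rp,
               precision = rf$precision, recall = rf$recall, f1 = rf$f1,
               RR = rf$RR, RN = rf$RN, NR = rf$NR,
               stringsAsFactors = FALSE)
  })
  per_topic <- do.call(rbind, rows)
  averages <- c(avg_p10 = mean(per_topic$p_at_10),
                avg_ndcg = mean(per_topic$ndcg),
                avg_r_prec = mean(per_topic$r_prec, na.rm = TRUE),
                avg_precision = mean(per_topic$precision),
                avg_recall = mean(per_topic$recall),
                avg_f1 = mean(per_topic$f1))
  structure(list(per_topic = per_topic, averages = averages),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary over", nrow(x$per_topic), "topics>\n")
  print(round(x$averages, 4))
  invisible(x)
}
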