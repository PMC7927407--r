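#' Read precision-medicine retrieval topics
#'
#' Supports two dialects: a TREC-PM style XML file
#' (`<topics><topic number="1"><disease>...</disease><gene>...</gene>
#' <demographic>...</demographic><other>...</other></topic></topics>`) and
#' a JSON array of objects with keys `topic_id`, `disease`, `gene`,
#' `demographic`, `other`. An `other` value of `"None"` (or an empty or
#' absent element) is treated as absent. The disease and gene fields are
#' mandatory; a topic missing either raises an error naming the topic.
#'
#' @param path Path to the topics file (`.xml` or `.json`).
#' @return List of `pm_topic` objects with fields `topic_id`, `disease`,
#'   `gene_field`, `demographic`, `other` (NULL when absent).
#' @export
read_topics <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    topics <- lapply(recs, function(r) {
      make_topic(as.character(r$topic_id), r$disease, r$gene,
                 r$demographic, r$other)
    })
  } else {
    doc <- xml2::read_xml(path)
    nodes <- xml2::xml_find_all(doc, ".//topic")
    topics <- lapply(nodes, function(n) {
      id <- xml2::xml_attr(n, "number")
      field <- function(name) {
        v <- xml2::xml_text(xml2::xml_find_first(n, name))
        if (is.na(v)) NULL else v
      }
      make_topic(id, field("disease"), field("gene"),
                 field("demographic"), field("other"))
    })
  }
  topics
}

make_topic <- function(topic_id, disease, gene, demographic, other) {
  id <- if (is.null(topic_id) || is.na(topic_id)) "?" else topic_id
  if (is.null(disease) || !nzchar(trimws(disease)))
    stop(sprintf("topic %s: missing disease field", id))
  if (is.null(gene) || !nzchar(trimws(gene)))
    stop(sprintf("topic %s: missing gene field", id))
  if (!is.null(other) &&
      (tolower(trimws(other)) == "none" || !nzchar(trimws(other))))
    other <- NULL
  structure(list(
    topic_id = id,
    disease = trimws(disease),
    gene_field = trimws(gene),
    demographic = if (is.null(demographic)) NULL else trimws(demographic),
    other = other
  ), class = "pm_topic")
}

#' Read a TREC qrels relevance-judgment file
#'
#' Parses whitespace-separated lines `topic 0 doc_id grade`. Grades must
#' be non-negative integers; a non-integer grade raises an error naming the
#' line. When the same (topic, doc) pair occurs more than once the last
#' line wins, with a warning.
#'
#' @param path Path to the qrels file.
#' @return A `qrels` object: a data frame with columns `topic_id`,
#'   `doc_id`, `grade` (one row per pair).
#' @export
read_qrels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(
      data.frame(topic_id = character(), doc_id = character(),
                 grade = integer(), stringsAsFactors = FALSE),
      class = c("qrels", "data.frame")))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad_ncol <- which(lengths(parts) != 4)
  if (length(bad_ncol))
    stop(sprintf("qrels line %d: expected 4 fields", bad_ncol[1]))
  topic <- vapply(parts, `[[`, character(1), 1)
  doc <- vapply(parts, `[[`, character(1), 3)
  grade_chr <- vapply(parts, `[[`, character(1), 4)
  grade <- suppressWarnings(as.integer(grade_chr))
  bad <- which(is.na(grade) | grade_chr != as.character(grade) | grade < 0)
  if (length(bad))
    stop(sprintf("qrels line %d: grade '%s' is not a non-negative integer",
                 bad[1], grade_chr[bad[1]]))
  key <- paste(topic, doc, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (topic, doc) qrels pair(s); last line wins",
                    sum(duplicated(key))), call. = FALSE)
    last <- !duplicated(key, fromLast = TRUE)
    topic <- topic[last]; doc <- doc[last]; grade <- grade[last]
  }
  structure(
    data.frame(topic_id = topic, doc_id = doc, grade = grade,
               stringsAsFactors = FALSE),
    class = c("qrels", "data.frame"))
}

# named integer vector of grades for one topic: names are doc_ids
qrels_grades <- function(qrels, topic) {
  sub <- qrels[qrels$topic_id == topic, ]
  stats::setNames(sub$grade, sub$doc_id)
}

#' Topics present in a qrels object
#' @param qrels A [read_qrels()] object.
#' @return Character vector of topic ids, in order of first appearance.
#' @export
qrels_topics <- function(qrels) unique(qrels$topic_id)

#' Write a TREC 6-column run file
#'
#' Emits lines `topic Q0 doc rank score tag` with scores printed at fixed
#' 6-decimal precision, so identical runs produce byte-identical files.
#' Within each topic the entries must already satisfy the run invariants
#' (ranks 1..K consecutive, scores non-increasing); violations raise an
#' error before anything is written.
#'
#' @param run Data frame with columns `topic_id`, `doc_id`, `rank`,
#'   `score` and optionally `tag`.
#' @param path Output path.
#' @param tag Run label; overrides a `tag` column when supplied.
#' @return Invisibly, the path.
#' @export
write_trec_run <- function(run, path, tag = NULL) {
  stopifnot(all(c("topic_id", "doc_id", "rank", "score") %in% names(run)))
  if (is.null(tag)) tag <- if ("tag" %in% names(run)) run$tag else "run"
  for (t in unique(run$topic_id)) {
    sub <- run[run$topic_id == t, ]
    sub <- sub[order(sub$rank), ]
    if (!identical(as.integer(sub$rank), seq_len(nrow(sub))))
      stop(sprintf("topic %s: ranks are not consecutive from 1", t))
    if (is.unsorted(rev(sub$score)))
      stop(sprintf("topic %s: scores increase with rank", t))
  }
  lines <- sprintf("%s Q0 %s %d %.6f %s",
                   run$topic_id, run$doc_id, as.integer(run$rank),
                   run$score, tag)
  writeLines(lines, path)
  invisible(path)
}

#' Read a TREC 6-column run file
#' @param path Path to a run file written by [write_trec_run()] or any
#'   standard TREC run.
#' @return Data frame with columns `topic_id`, `doc_id`, `rank`, `score`,
#'   `tag`, ordered by topic then rank.
#' @export
read_trec_run <- function(path) {
  df <- utils::read.table(path, col.names = c("topic_id", "Q0", "doc_id",
                                              "rank", "score", "tag"),
                          colClasses = c("character", "character",
                                         "character", "integer", "numeric",
                                         "character"))
  df <- df[order(df$topic_id, df$rank), c("topic_id", "doc_id", "rank",
                                          "score", "tag")]
  rownames(df) <- NULL
  df
}
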