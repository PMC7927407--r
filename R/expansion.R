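#' Demographic age expansion table
#'
#' The age bands used to expand a patient age into MeSH-style check tags.
#' Bands are half-open as printed ("35 years to < 60 years") and may
#' overlap: "Adult" (>= 18 years) co-applies with the narrower bands, so
#' an adult age always expands to two terms. Ages are expressed in years
#' (1 month = 1/12 year).
#'
#' @return Data frame with columns `term`, `lo`, `hi`, `lo_incl`,
#'   `hi_incl`.
#' @export
age_expansion_table <- function() {
  data.frame(
    term = c("Newborn", "Infant", "Preschool", "Child", "Adolescent",
             "Young", "Middle age", "Aged", "Aged 80", "Adult"),
    lo = c(0, 1 / 12, 2, 6, 13, 19, 35, 60, 80, 18),
    hi = c(1 / 12, 2, 6, 13, 19, 35, 60, 80, Inf, Inf),
    lo_incl = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    hi_incl = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Expand an age into demographic terms
#'
#' Returns every term of the expansion table whose range contains the
#' age. Because the "Adult" band (>= 18) overlaps the finer bands, ages
#' of 18 or more return two terms (e.g. 38 -> Middle age + Adult; 18 ->
#' Adolescent + Adult). The special tokens `"fetus"` and `"newborn"`
#' return the corresponding single term.
#'
#' @param age_years Non-negative age in years, or `"fetus"`/`"newborn"`.
#' @return Character vector of expansion terms.
#' @export
expand_age <- function(age_years) {
  if (is.character(age_years)) {
    tok <- tolower(trimws(age_years))
    if (tok == "fetus") return("Fetus")
    if (tok == "newborn") return("Newborn")
    age_years <- suppressWarnings(as.numeric(age_years))
  }
  if (is.na(age_years)) stop("age is not a number or recognized token")
  if (age_years < 0) stop("age must be non-negative")
  tab <- age_expansion_table()
  in_lo <- ifelse(tab$lo_incl, age_years >= tab$lo, age_years > tab$lo)
  in_hi <- ifelse(tab$hi_incl, age_years <= tab$hi, age_years < tab$hi)
  tab$term[in_lo & in_hi]
}

.word_numbers <- c(one = 1, two = 2, three = 3, four = 4, five = 5,
                   six = 6, seven = 7, eight = 8, nine = 9, ten = 10,
                   eleven = 11, twelve = 12)

#' Parse a demographic string
#'
#' Understands the TREC-PM phrasing `"<N>-year-old <sex>"` and the
#' month/week variants (`"six-month-old infant"` -> age 0.5 years), plus
#' the bare tokens "fetus" and "newborn". Word numbers up to twelve are
#' recognized. The sex is normalized to `"male"`, `"female"` or
#' `"unspecified"`.
#'
#' @param demographic The raw demographic string.
#' @return List with `age_years` (numeric, or the string `"fetus"`) and
#'   `sex`.
#' @export
parse_demographic <- function(demographic) {
  stopifnot(is.character(demographic), length(demographic) == 1)
  s <- tolower(trimws(demographic))
  sex <- if (grepl("\\b(male|man|boy)\\b", s) &&
             !grepl("\\b(female|woman|girl)\\b", s)) "male"
         else if (grepl("\\b(female|woman|girl)\\b", s)) "female"
         else "unspecified"
  if (grepl("\\bfetus\\b", s))
    return(list(age_years = "fetus", sex = sex))
  if (grepl("\\bnewborn\\b", s))
    return(list(age_years = 0, sex = sex))
  m <- regmatches(s, regexec("([a-z0-9]+)[- ](year|month|week)[- ]old", s))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse demographic string: '%s'", demographic))
  qty <- suppressWarnings(as.numeric(m[2]))
  if (is.na(qty)) qty <- unname(.word_numbers[m[2]])
  if (is.na(qty))
    stop(sprintf("cannot parse age in demographic string: '%s'", demographic))
  age <- switch(m[3], year = qty, month = qty / 12, week = qty / 52)
  list(age_years = age, sex = sex)
}

.gene_qualifiers <- c("amplification", "fusion", "deletion", "mutation",
                      "mutations", "loss", "inactivation", "rearrangement",
                      "translocation", "transcript", "overexpression")

#' Parse a topic gene field
#'
#' Splits a field such as `"BRAF (V600E)"`, `"CDK4 Amplification"` or
#' `"KRAS, NRAS"` into gene symbols and variant/qualifier tokens. Gene
#' symbols drive co-word detection; variants and qualifiers are retained
#' as ordinary query terms but are not co-word keys.
#'
#' @param gene_field Non-empty raw gene field string.
#' @return List with `genes` and `variants` (both lowercase token
#'   vectors).
#' @export
parse_gene_field <- function(gene_field) {
  if (is.null(gene_field) || !nzchar(trimws(gene_field)))
    stop("empty gene field")
  genes <- character(); variants <- character()
  for (unit in strsplit(gene_field, "[,;]")[[1]]) {
    unit <- trimws(unit)
    if (!nzchar(unit)) next
    paren <- regmatches(unit, gregexpr("\\(([^)]*)\\)", unit))[[1]]
    if (length(paren)) {
      inner <- gsub("[()]", "", paren)
      variants <- c(variants, unlist(lapply(inner, tokenize,
                                            stopwords = character())))
      unit <- gsub("\\([^)]*\\)", " ", unit)
    }
    toks <- tokenize(unit, stopwords = character())
    is_qual <- toks %in% .gene_qualifiers
    genes <- c(genes, toks[!is_qual])
    variants <- c(variants, toks[is_qual])
  }
  if (length(genes) == 0)
    stop(sprintf("no gene symbol found in gene field '%s'", gene_field))
  list(genes = unique(genes), variants = unique(variants))
}

#' Read an expansion lexicon
#'
#' Two-column UTF-8 TSV, `term <TAB> expansion`, one expansion per row
#' (multiple rows per term). Lookups are case-insensitive: keys are
#' normalized with [normalize_term()].
#'
#' @param path Path to the TSV file.
#' @return A named list mapping normalized source terms to character
#'   vectors of expansions, with class `expansion_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lex <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(trimws(parts[2])))
      stop(sprintf("lexicon line %d: expected 'term<TAB>expansion'", i))
    key <- normalize_term(parts[1])
    lex[[key]] <- c(lex[[key]], trimws(parts[2]))
  }
  structure(lex, class = "expansion_lexicon")
}

#' Packaged example expansion lexicon
#'
#' A small static MeSH-style lexicon covering the classic liposarcoma /
#' CDK4-amplification example topic, shipped so expansion is testable
#' without any web service.
#'
#' @return An `expansion_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "mesh_lexicon.tsv", package = "cobm25"))
}

lexicon_lookup <- function(lexicon, term) {
  if (is.null(lexicon)) return(character())
  key <- normalize_term(term)
  if (length(key) == 0) return(character())
  hit <- lexicon[[key]]
  if (is.null(hit)) character() else hit
}

#' Build an expanded query from a topic
#'
#' Produces the query object consumed by the scoring module:
#' * `abstract_terms` — tokens matched against abstracts: the disease,
#'   gene symbols, variants/qualifiers and (optionally) the "other"
#'   condition, deduplicated so every query term has frequency 1;
#' * `wordlist_terms` — normalized expanded terms matched against the
#'   document word list: lexicon expansions of the disease and gene
#'   field, the age-band terms, the sex and the constant "Human";
#' * `disease_terms` — the disease plus its lexicon expansions (co-word
#'   disease keys);
#' * `gene_terms` — gene symbols (co-word gene keys).
#'
#' @param topic A `pm_topic` from [read_topics()].
#' @param lexicon An `expansion_lexicon` or NULL.
#' @param include_other Include the topic's "other" condition in
#'   `abstract_terms` (default TRUE).
#' @param stopwords Stop-word list used to tokenize free-text fields.
#' @return An object of class `expanded_query`.
#' @export
build_expanded_query <- function(topic, lexicon = NULL, include_other = TRUE,
                                 stopwords = bm25_stopwords()) {
  stopifnot(inherits(topic, "pm_topic"))
  gene <- parse_gene_field(topic$gene_field)
  disease_tokens <- tokenize(topic$disease, stopwords)

  abstract_terms <- c(disease_tokens, gene$genes, gene$variants)
  if (include_other && !is.null(topic$other))
    abstract_terms <- c(abstract_terms, tokenize(topic$other, stopwords))

  wordlist_terms <- character()
  for (key in c(topic$disease, topic$gene_field, gene$genes))
    wordlist_terms <- c(wordlist_terms, lexicon_lookup(lexicon, key))

  if (!is.null(topic$demographic)) {
    demo <- parse_demographic(topic$demographic)
    wordlist_terms <- c(wordlist_terms, expand_age(demo$age_years))
    if (demo$sex != "unspecified") wordlist_terms <- c(wordlist_terms, demo$sex)
    wordlist_terms <- c(wordlist_terms, "Human")
    wordlist_terms <- c(wordlist_terms,
                        lexicon_lookup(lexicon, topic$demographic))
    # also try the bare age phrase ("38-year-old") as a lexicon key
    phrase <- regmatches(tolower(topic$demographic),
                         regexpr("[a-z0-9]+[- ](year|month|week)[- ]old",
                                 tolower(topic$demographic)))
    if (length(phrase))
      wordlist_terms <- c(wordlist_terms, lexicon_lookup(lexicon, phrase))
  }

  disease_terms <- unique(c(normalize_term(topic$disease),
                            normalize_term(lexicon_lookup(lexicon,
                                                          topic$disease))))
  q <- list(
    topic_id = topic$topic_id,
    abstract_terms = unique(abstract_terms),
    wordlist_terms = unique(normalize_term(wordlist_terms)),
    disease_terms = disease_terms,
    gene_terms = unique(gene$genes)
  )
  q$n_wordlist <- length(q$wordlist_terms)
  q$n_genes <- length(q$gene_terms)
  structure(q, class = "expanded_query")
}

#' @export
print.expanded_query <- function(x, ...) {
  cat(sprintf("<expanded_query topic %s>\n", x$topic_id))
  cat("  abstract:", paste(x$abstract_terms, collapse = ", "), "\n")
  cat("  wordlist:", paste(x$wordlist_terms, collapse = ", "), "\n")
  cat("  disease: ", paste(x$disease_terms, collapse = ", "), "\n")
  cat("  genes:   ", paste(x$gene_terms, collapse = ", "), "\n")
  invisible(x)
}
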