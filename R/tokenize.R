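#' Default English stop-word list
#'
#' Returns the packaged stop-word list used when tokenizing abstracts.
#' The list is a conventional set of English function words; gene symbols,
#' variant codes and domain terms are never stop-words.
#'
#' @return Character vector of lowercase stop-words.
#' @export
bm25_stopwords <- function() {
  if (is.null(.cobm25_cache$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "cobm25")
    .cobm25_cache$stopwords <- readLines(path, encoding = "UTF-8")
  }
  .cobm25_cache$stopwords
}

.cobm25_cache <- new.env(parent = emptyenv())

#' Tokenize free text
#'
#' Lowercases, splits on runs of non-alphanumeric characters (so
#' alphanumeric hybrids such as "v600e" or "cdk4" survive as single
#' tokens), drops empty strings and removes stop-words. Duplicate tokens
#' are preserved so term frequencies remain countable.
#'
#' @param text A character string (length-1).
#' @param stopwords Character vector of stop-words to remove; use
#'   `character()` to keep everything.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("The BRAF gene.", stopwords = "the")
#' @export
tokenize <- function(text, stopwords = bm25_stopwords()) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character())
  stopifnot(is.character(text), length(text) == 1)
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(stopwords)) toks <- toks[!toks %in% stopwords]
  toks
}

#' Normalize a multi-word term
#'
#' Applies the same character-level normalization as [tokenize()] but keeps
#' all words (no stop-word removal) and joins them with single spaces, so
#' that term equality is insensitive to case, punctuation and spacing.
#' Idempotent: `normalize_term(normalize_term(x)) == normalize_term(x)`.
#'
#' @param term Character vector of terms.
#' @return Character vector of normalized terms (empty strings dropped).
#' @export
normalize_term <- function(term) {
  if (length(term) == 0) return(character())
  out <- vapply(term, function(t) {
    paste(tokenize(t, stopwords = character()), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  out[nzchar(out)]
}

# contiguous subsequence test used by co-word matching: does the token
# vector `needle` appear contiguously inside `haystack`?
contains_seq <- function(haystack, needle) {
  nh <- length(haystack); nn <- length(needle)
  if (nn == 0 || nn > nh) return(FALSE)
  if (nn == 1) return(needle %in% haystack)
  starts <- which(haystack == needle[1])
  starts <- starts[starts <= nh - nn + 1]
  for (s in starts) {
    if (all(haystack[s:(s + nn - 1)] == needle)) return(TRUE)
  }
  FALSE
}
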