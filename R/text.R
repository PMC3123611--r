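# Token normalization shared by every vector-space component: the QA
# separability classifier, NB features, concept profiles and co-occurrence
# matrices all see text through normalize_tokens().

.wsd_env <- new.env(parent = emptyenv())

#' English stopword list shipped with the package
#'
#' A standard general-English stopword list, loaded once per session from
#' `inst/extdata/stopwords_en.txt`.
#'
#' @return Character vector of lowercase stopwords.
#' @export
wsd_stopwords <- function() {
  if (is.null(.wsd_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "wsdbench")
    .wsd_env$stopwords <- readLines(path, encoding = "UTF-8")
  }
  .wsd_env$stopwords
}

#' Normalize free text into content-word stems
#'
#' Lowercases, splits on any non-alphanumeric character, removes stopwords
#' and tokens shorter than `min_chars` characters, then applies the Porter
#' stemmer. This is the tokenization used for concept profiles, context
#' vectors, Naive Bayes features and the separability classifier.
#'
#' @param text Character scalar (or vector, concatenated with spaces).
#' @param stopwords Character vector of stopwords; defaults to the shipped
#'   English list.
#' @param min_chars Minimum token length kept (default 2).
#' @param stem Apply Porter stemming (default `TRUE`).
#' @return Character vector of normalized tokens, in text order.
#' @examples
#' normalize_tokens("Having less heat energy than the object")
#' @export
normalize_tokens <- function(text, stopwords = wsd_stopwords(), min_chars = 2,
                             stem = TRUE) {
  text <- tolower(paste(text, collapse = " "))
  toks <- strsplit(text, "[^[:alnum:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[nchar(toks) >= min_chars & !(toks %in% stopwords)]
  if (stem) toks <- porter_stem(toks)
  toks
}

#' Term-frequency vector of a token list
#'
#' @param tokens Character vector of (normalized) tokens.
#' @return Named numeric vector of counts, sorted by token name; no
#'   zero-weight entries.
#' @export
token_vector <- function(tokens) {
  if (length(tokens) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(tokens)
  stats::setNames(as.numeric(tab), names(tab))
}

# Document-term count matrix over a fixed vocabulary (dense; fixtures are
# small). Rows follow token_lists, columns follow vocab.
build_dtm <- function(token_lists, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  }
  m <- matrix(0, nrow = length(token_lists), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_lists)) {
    toks <- token_lists[[i]]
    toks <- toks[toks %in% vocab]
    if (length(toks)) {
      tab <- tabulate(factor(toks, levels = vocab), nbins = length(vocab))
      m[i, ] <- tab
    }
  }
  m
}
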