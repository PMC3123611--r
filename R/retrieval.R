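# Per-sense boolean query construction and local evaluation against
# MEDLINE-format corpora. The query dialect is PubMed-compatible: the
# ambiguous term is required in the title/abstract field, the target sense's
# MeSH heading is required without hierarchical explosion, and every
# competing sense's heading is excluded with NOT clauses.

#' Build the boolean query for one sense of an ambiguous term
#'
#' Renders `"<term>"[TIAB] AND "<heading>"[MH:noexp] NOT "<other>"[MH:noexp]
#' ...` with one NOT clause per competing sense, in sense order.
#'
#' @param term An `ambiguous_term` with MeSH headings resolved (at least two
#'   senses).
#' @param target Either a sense CUI or a 1-based sense index identifying the
#'   positive sense.
#' @return An object of class `sense_query`: `term_key`, `positive_heading`,
#'   `negative_headings` (ordered), `rendered`.
#' @export
build_query <- function(term, target) {
  stopifnot(inherits(term, "ambiguous_term"))
  if (nrow(term$senses) < 2) {
    stop("build_query requires an ambiguous term with >= 2 senses", call. = FALSE)
  }
  if (any(is.na(term$senses$mesh_heading))) {
    stop("senses must have MeSH headings resolved before query construction",
         call. = FALSE)
  }
  idx <- if (is.character(target)) match(target, term$senses$cui) else as.integer(target)
  if (is.na(idx) || idx < 1 || idx > nrow(term$senses)) {
    stop("target sense not found in term", call. = FALSE)
  }
  positive <- term$senses$mesh_heading[idx]
  negatives <- term$senses$mesh_heading[-idx]
  rendered <- paste0('"', term$term_key, '"[TIAB] AND "', positive, '"[MH:noexp]')
  if (length(negatives)) {
    rendered <- paste0(rendered, paste0(' NOT "', negatives, '"[MH:noexp]',
                                        collapse = ""))
  }
  structure(
    list(term_key = term$term_key, positive_heading = positive,
         negative_headings = negatives, rendered = rendered),
    class = "sense_query"
  )
}

#' @export
print.sense_query <- function(x, ...) {
  cat("<sense_query>", x$rendered, "\n")
  invisible(x)
}

#' Parse a rendered sense query back into its components
#'
#' Exact inverse of the rendering in [build_query()].
#'
#' @param rendered Query string.
#' @return A `sense_query` object.
#' @export
parse_query <- function(rendered) {
  m <- regmatches(rendered,
                  regexec('^"([^"]*)"\\[TIAB\\] AND "([^"]*)"\\[MH:noexp\\](.*)$',
                          rendered))[[1]]
  if (length(m) != 4) {
    stop("unparseable sense query: ", rendered, call. = FALSE)
  }
  rest <- m[4]
  negatives <- character(0)
  while (nzchar(rest)) {
    nm <- regmatches(rest, regexec('^ NOT "([^"]*)"\\[MH:noexp\\](.*)$', rest))[[1]]
    if (length(nm) != 3) {
      stop("unparseable NOT clause in query: ", rendered, call. = FALSE)
    }
    negatives <- c(negatives, nm[2])
    rest <- nm[3]
  }
  structure(
    list(term_key = m[2], positive_heading = m[3],
         negative_headings = negatives, rendered = rendered),
    class = "sense_query"
  )
}

#' Test whether a term occurs in a citation's title or abstract
#'
#' Case-insensitive match on token boundaries (a token boundary is any
#' non-alphanumeric character or the field edge); multi-word keys match
#' across any run of non-alphanumeric characters, including line breaks
#' normalized to spaces. No lexical-variant expansion is performed: only the
#' exact surface string (up to case and token separators) matches.
#'
#' @param citation A `citation`.
#' @param term_key Normalized term key to search for.
#' @return Logical scalar. The attribute `spans` holds a list with `title`
#'   and `abstract` integer matrices of 0-based half-open character offsets
#'   (columns `start`, `end`) of each match in that field.
#' @export
term_in_tiab <- function(citation, term_key) {
  words <- strsplit(term_key, "[^[:alnum:]]+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0) {
    res <- FALSE
    attr(res, "spans") <- list(title = empty_span(), abstract = empty_span())
    return(res)
  }
  pattern <- paste0("(?<![[:alnum:]])",
                    paste(vapply(words, escape_regex, character(1)),
                          collapse = "[^[:alnum:]]+"),
                    "(?![[:alnum:]])")
  spans <- list(title = field_spans(citation$title, pattern),
                abstract = field_spans(citation$abstract, pattern))
  res <- nrow(spans$title) > 0 || nrow(spans$abstract) > 0
  attr(res, "spans") <- spans
  res
}

empty_span <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

field_spans <- function(text, pattern) {
  if (!nzchar(text)) {
    return(empty_span())
  }
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) {
    return(empty_span())
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  cbind(start = starts, end = starts + lens)
}

escape_regex <- function(s) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
}

#' Evaluate a sense query against a local citation corpus
#'
#' A citation is returned iff (1) the ambiguous term occurs in its title or
#' abstract on token boundaries, (2) the positive MeSH heading is among its
#' headings, and (3) none of the negative headings is. Heading comparison is
#' an exact, case-sensitive string match on the descriptor part. Corpus
#' order is preserved.
#'
#' @param query A `sense_query`.
#' @param corpus List of `citation` records.
#' @return The matching subset of `corpus`, in corpus order.
#' @export
evaluate_query_local <- function(query, corpus) {
  keep <- vapply(corpus, function(ct) {
    query$positive_heading %in% ct$mesh_headings &&
      !any(query$negative_headings %in% ct$mesh_headings) &&
      isTRUE(as.logical(term_in_tiab(ct, query$term_key)))
  }, logical(1))
  corpus[keep]
}

#' Retrieve citations for every sense of an ambiguous term
#'
#' Evaluates one query per sense. Because each sense's query excludes every
#' competing sense's heading, the per-sense citation sets are pairwise
#' disjoint by construction: a citation indexed with two or more of the
#' senses' headings appears in none of them.
#'
#' @param term An `ambiguous_term` with MeSH headings resolved.
#' @param corpus List of `citation` records.
#' @return An object of class `retrieval_result`: `term_key`, `senses` (the
#'   term's sense table), `citations` (list parallel to senses, each a list
#'   of citations) and `counts` (integer vector).
#' @export
retrieve_all_senses <- function(term, corpus) {
  stopifnot(inherits(term, "ambiguous_term"), nrow(term$senses) >= 2)
  hits <- lapply(seq_len(nrow(term$senses)), function(i) {
    evaluate_query_local(build_query(term, i), corpus)
  })
  counts <- vapply(hits, length, integer(1))
  names(hits) <- term$senses$cui
  structure(
    list(term_key = term$term_key, senses = term$senses, citations = hits,
         counts = stats::setNames(counts, term$senses$cui)),
    class = "retrieval_result"
  )
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> %s\n", x$term_key))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %s (%s): %d citations\n", names(x$counts)[i],
                x$senses$mesh_heading[i], x$counts[i]))
  }
  invisible(x)
}

#' Write rendered queries, one per line, for audit
#'
#' @param queries List of `sense_query` objects.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  writeLines(vapply(queries, `[[`, character(1), "rendered"), path,
             useBytes = TRUE)
  invisible(path)
}
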