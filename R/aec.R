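# Automatically Extracted Corpus (AEC): harvest training documents for each
# sense through monosemous relatives (synonym or related-concept strings
# that map to exactly one CUI), label them by the sense whose relative
# retrieved them, and train a Naive Bayes classifier on the result.

#' Monosemous relatives of a sense
#'
#' Candidate relatives are the synonym strings of the sense's CUI plus the
#' strings of its related CUIs (relation code in `related_codes`). A string
#' is kept only if its normalized term key maps to exactly one CUI in the
#' store (it has an unambiguous use) and differs from the ambiguous term
#' key itself.
#'
#' @param sense_cui CUI of the sense.
#' @param term The `ambiguous_term` being disambiguated.
#' @param store A `concept_store`.
#' @param related_codes Relation codes treated as "related".
#' @return Character vector of relative strings (possibly empty).
#' @export
monosemous_relatives <- function(sense_cui, term, store,
                                 related_codes = c("PAR", "CHD", "RB", "RN", "RO")) {
  con <- store$concepts[[sense_cui]]
  if (is.null(con)) {
    return(character(0))
  }
  candidates <- con$synonyms
  rel <- con$relations
  rel <- rel[rel$rel %in% related_codes, , drop = FALSE]
  for (rcui in rel$cui2) {
    rcon <- store$concepts[[rcui]]
    if (!is.null(rcon)) {
      candidates <- c(candidates, rcon$synonyms)
    }
  }
  candidates <- unique(candidates)
  keys <- normalize_term_key(candidates)
  keep <- vapply(seq_along(candidates), function(i) {
    k <- keys[i]
    k != term$term_key && length(store$term_index[[k]]) == 1
  }, logical(1))
  candidates[keep]
}

# Citations whose title/abstract contains the relative: first as an exact
# phrase (token-boundary sequence); if the phrase retrieves nothing, the
# broadened form requires every word of the relative anywhere in TIAB.
retrieve_by_relative <- function(relative, corpus) {
  key <- normalize_term_key(relative)
  phrase_hit <- vapply(corpus, function(ct) {
    isTRUE(as.logical(term_in_tiab(ct, key)))
  }, logical(1))
  if (any(phrase_hit)) {
    return(list(pmids = vapply(corpus[phrase_hit], `[[`, character(1), "pmid"),
                broadened = FALSE))
  }
  words <- strsplit(key, " ", fixed = TRUE)[[1]]
  if (length(words) < 2) {
    return(list(pmids = character(0), broadened = FALSE))
  }
  word_hit <- vapply(corpus, function(ct) {
    all(vapply(words, function(w) {
      isTRUE(as.logical(term_in_tiab(ct, w)))
    }, logical(1)))
  }, logical(1))
  list(pmids = vapply(corpus[word_hit], `[[`, character(1), "pmid"),
       broadened = any(word_hit))
}

#' Build the automatically extracted training corpus for a term
#'
#' For each sense, retrieves corpus citations matching any monosemous
#' relative (exact phrase first, broadened word-conjunction fallback per
#' relative) and labels them by that sense. Citations claimed by relatives
#' of more than one sense are dropped. Each sense's training set is capped
#' by `config$aec_max_train_per_sense` through a seeded uniform sample.
#'
#' @param term A labeled `ambiguous_term` (see [assign_sense_labels()]).
#' @param store A `concept_store`.
#' @param corpus List of `citation` records.
#' @param config A `pipeline_config`.
#' @return A list: `instances` (data frame `pmid`, `text`, `label`),
#'   `relatives` (named list per label), `unscorable` (labels with no
#'   training document after the fallback).
#' @export
aec_training_corpus <- function(term, store, corpus, config = pipeline_config()) {
  if (is.null(term$senses$label)) {
    term <- assign_sense_labels(term)
  }
  pmid_by_label <- list()
  relatives <- list()
  for (i in seq_len(nrow(term$senses))) {
    lb <- term$senses$label[i]
    rels <- monosemous_relatives(term$senses$cui[i], term, store,
                                 config$related_codes)
    relatives[[lb]] <- rels
    pmids <- character(0)
    for (r in rels) {
      pmids <- union(pmids, retrieve_by_relative(r, corpus)$pmids)
    }
    pmid_by_label[[lb]] <- pmids
  }
  # drop citations claimed by more than one sense
  all_pmids <- unlist(pmid_by_label, use.names = FALSE)
  dup <- unique(all_pmids[duplicated(all_pmids)])
  pmid_by_label <- lapply(pmid_by_label, setdiff, y = dup)

  corpus_pmids <- vapply(corpus, `[[`, character(1), "pmid")
  instances <- do.call(rbind, lapply(names(pmid_by_label), function(lb) {
    pmids <- pmid_by_label[[lb]]
    if (length(pmids) > config$aec_max_train_per_sense) {
      seed <- derive_seed(config$random_seed,
                          paste0("aec:", term$term_key, ":", lb))
      pmids <- with_seed(seed, {
        sort(sample(pmids, config$aec_max_train_per_sense))
      })
    }
    if (length(pmids) == 0) {
      return(NULL)
    }
    data.frame(
      pmid = pmids,
      text = vapply(corpus[match(pmids, corpus_pmids)], citation_text,
                    character(1)),
      label = lb, stringsAsFactors = FALSE
    )
  }))
  if (is.null(instances)) {
    instances <- data.frame(pmid = character(0), text = character(0),
                            label = character(0), stringsAsFactors = FALSE)
  }
  unscorable <- setdiff(term$senses$label, unique(instances$label))
  list(instances = instances, relatives = relatives, unscorable = unscorable)
}

#' Disambiguate instances with the AEC method
#'
#' Trains Naive Bayes on the automatically extracted corpus of the term and
#' scores each instance text. If any sense ends up with no training
#' document the term is flagged unscorable by AEC and no scores are
#' produced (other methods are unaffected).
#'
#' @param term A labeled `ambiguous_term`.
#' @param store A `concept_store`.
#' @param corpus List of `citation` records (the retrieval corpus).
#' @param texts Character vector of instance texts to score.
#' @param config A `pipeline_config`.
#' @return A list: `scores` (list of `sense_scores`, one per text, method
#'   `"aec"`), `unscorable` (logical), `training` (the extracted corpus).
#' @export
aec_disambiguate <- function(term, store, corpus, texts,
                             config = pipeline_config()) {
  training <- aec_training_corpus(term, store, corpus, config)
  if (length(training$unscorable) > 0) {
    return(list(scores = NULL, unscorable = TRUE, training = training))
  }
  model <- train_nb(training$instances)
  scores <- lapply(texts, function(tx) {
    sc <- nb_score(model, tx)
    sc$method <- "aec"
    sc
  })
  list(scores = scores, unscorable = FALSE, training = training)
}
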