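# Supervised multinomial Naive Bayes over normalized bag-of-words features,
# with add-one smoothing. This is the top-end supervised baseline against
# which the knowledge-based methods are compared.

#' Train a multinomial Naive Bayes sense classifier
#'
#' Features are the normalized (stemmed, stopword-free) tokens of the
#' instance text; class-conditional token probabilities use add-one
#' smoothing over the training vocabulary; priors are the training label
#' proportions.
#'
#' @param instances Data frame with columns `text` and `label`; every label
#'   must have at least one instance.
#' @return An object of class `nb_model`.
#' @export
train_nb <- function(instances) {
  stopifnot(is.data.frame(instances), all(c("text", "label") %in% names(instances)))
  labels <- sort_labels(unique(instances$label))
  toks <- lapply(instances$text, normalize_tokens)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  counts <- matrix(0, nrow = length(labels), ncol = length(vocab),
                   dimnames = list(labels, vocab))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk)) {
      tab <- tabulate(factor(tk, levels = vocab), nbins = length(vocab))
      counts[instances$label[i], ] <- counts[instances$label[i], ] + tab
    }
  }
  structure(
    list(labels = labels,
         prior = as.numeric(table(factor(instances$label, levels = labels))) /
           nrow(instances),
         vocab = vocab,
         counts = counts,
         class_totals = rowSums(counts)),
    class = "nb_model"
  )
}

#' Score an instance with a Naive Bayes model
#'
#' Returns posterior probabilities per sense label (summing to 1). Tokens
#' absent from the training vocabulary are ignored, so an instance with no
#' known token scores exactly the prior proportions. Ties are broken toward
#' the lowest sense label.
#'
#' @param model An `nb_model`.
#' @param text Instance text (character scalar).
#' @return An object of class `sense_scores`: named `scores`, `predicted`,
#'   `method`.
#' @export
nb_score <- function(model, text) {
  stopifnot(inherits(model, "nb_model"))
  toks <- normalize_tokens(text)
  toks <- toks[toks %in% model$vocab]
  v <- length(model$vocab)
  loglik <- log(model$prior)
  if (length(toks)) {
    tf <- table(toks)
    idx <- match(names(tf), model$vocab)
    for (j in seq_along(idx)) {
      p <- (model$counts[, idx[j]] + 1) / (model$class_totals + v)
      loglik <- loglik + as.numeric(tf[j]) * log(p)
    }
  }
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  sense_scores(stats::setNames(post, model$labels), method = "nb")
}

#' Construct a sense-score object
#'
#' @param scores Named numeric vector, one score per sense label.
#' @param method Method name attached to the scores.
#' @return A `sense_scores` object with the deterministic argmax
#'   (lowest-label tie-break) as `predicted`.
#' @export
sense_scores <- function(scores, method = "unknown") {
  stopifnot(length(scores) >= 1, !is.null(names(scores)))
  scores <- scores[sort_labels(names(scores))]
  structure(
    list(scores = scores, predicted = argmax_label(scores), method = method),
    class = "sense_scores"
  )
}

#' @export
print.sense_scores <- function(x, ...) {
  cat(sprintf("<sense_scores> [%s] -> %s\n", x$method, x$predicted))
  print(round(x$scores, 4))
  invisible(x)
}

#' Cross-validated Naive Bayes predictions on a labeled data set
#'
#' Seeded stratified k-fold cross-validation; each instance is scored by
#' the model trained on the other folds, mirroring how a supervised method
#' is evaluated on a benchmark it has no external training data for.
#'
#' @param dataset A `labeled_dataset`.
#' @param config A `pipeline_config` (supplies `cv_folds` and the seed).
#' @return Data frame of prediction records: `term_key`, `pmid`, `gold`,
#'   `predicted`, `method`.
#' @export
nb_crossval <- function(dataset, config = pipeline_config()) {
  inst <- dataset$instances
  k <- min(config$cv_folds, min(table(inst$label)))
  if (k < 2) {
    stop("not enough instances per sense for cross-validation", call. = FALSE)
  }
  folds <- stratified_folds(inst$label, k,
                            derive_seed(config$random_seed,
                                        paste0("nb-cv:", dataset$term_key)))
  pred <- character(nrow(inst))
  for (f in seq_len(k)) {
    test <- folds == f
    model <- train_nb(inst[!test, , drop = FALSE])
    pred[test] <- vapply(inst$text[test], function(tx) {
      nb_score(model, tx)$predicted
    }, character(1))
  }
  data.frame(term_key = dataset$term_key, pmid = inst$pmid, gold = inst$label,
             predicted = pred, method = "nb", stringsAsFactors = FALSE)
}
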