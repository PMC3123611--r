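# Scoring of prediction records: per-term accuracy, macro/micro category
# accuracies, frequency-quartile and semantic-group-pair breakdowns, and
# paired randomization significance tests.

check_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("term_key", "pmid", "gold", "predicted", "method") %in%
                  names(predictions)))
  predictions
}

per_term_accuracy <- function(predictions) {
  predictions$correct <- as.numeric(predictions$gold == predictions$predicted)
  acc <- stats::aggregate(correct ~ method + term_key, data = predictions,
                          FUN = mean)
  n <- stats::aggregate(correct ~ method + term_key, data = predictions,
                        FUN = length)
  data.frame(method = acc$method, term_key = acc$term_key,
             accuracy = acc$correct, n_instances = as.integer(n$correct),
             stringsAsFactors = FALSE)
}

#' Accuracy report over prediction records
#'
#' Computes per-term accuracy (correct / instances) and, per method,
#' category accuracies over the abbreviation (`A`), term (`T`) and mixed
#' (`AT`) sets plus the overall set. Category accuracy is reported both
#' macro (unweighted mean of per-term accuracies, invariant to per-term
#' instance counts) and micro (instance-weighted).
#'
#' @param predictions Data frame with columns `term_key`, `pmid`, `gold`,
#'   `predicted`, `method`; every (term, pmid, method) must appear exactly
#'   once, and every term of `manifest` must be covered per method.
#' @param manifest Data frame with one row per term: `term_key`,
#'   `entity_class` (`A`, `T` or `AT`).
#' @return An object of class `evaluation_report`: `per_term` and
#'   `categories` data frames.
#' @export
accuracy_report <- function(predictions, manifest) {
  check_predictions(predictions)
  stopifnot(all(c("term_key", "entity_class") %in% names(manifest)))
  manifest <- unique(manifest[, c("term_key", "entity_class")])
  for (m in unique(predictions$method)) {
    sub <- predictions[predictions$method == m, ]
    missing <- setdiff(manifest$term_key, sub$term_key)
    if (length(missing)) {
      stop("method ", m, " has no predictions for term(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(sub[, c("term_key", "pmid")])) {
      d <- sub[duplicated(sub[, c("term_key", "pmid")]), ][1, ]
      stop(sprintf("duplicate prediction for (%s, %s) by method %s",
                   d$term_key, d$pmid, m), call. = FALSE)
    }
  }

  pt <- per_term_accuracy(predictions)
  pt <- merge(pt, manifest, by = "term_key", sort = TRUE)

  categories <- do.call(rbind, lapply(unique(pt$method), function(m) {
    sub <- pt[pt$method == m, ]
    preds <- predictions[predictions$method == m, ]
    rows <- lapply(c("A", "T", "AT", "overall"), function(cat) {
      terms <- if (cat == "overall") sub$term_key else {
        sub$term_key[sub$entity_class == cat]
      }
      if (length(terms) == 0) {
        return(NULL)
      }
      s <- sub[sub$term_key %in% terms, ]
      p <- preds[preds$term_key %in% terms, ]
      data.frame(method = m, category = cat, n_terms = nrow(s),
                 macro_accuracy = mean(s$accuracy),
                 micro_accuracy = mean(p$gold == p$predicted),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(categories) <- NULL
  structure(list(per_term = pt, categories = categories),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Accuracy by term-frequency quartile
#'
#' Sorts terms by their frequency count in descending order (ties broken by
#' term key, lexicographically), splits them into four contiguous groups
#' (remainders go to the earlier groups) and reports each method's macro
#' accuracy per group together with the group's frequency range.
#'
#' @param frequencies Data frame `term_key`, `frequency` (one row per term;
#'   in local mode the count of corpus citations whose title or abstract
#'   contains the term).
#' @param predictions Prediction records covering those terms.
#' @return Data frame `quartile`, `freq_high`, `freq_low`, `n_terms`, one
#'   `macro_accuracy` row per method.
#' @export
quartile_breakdown <- function(frequencies, predictions) {
  check_predictions(predictions)
  stopifnot(all(c("term_key", "frequency") %in% names(frequencies)))
  missing <- setdiff(unique(predictions$term_key), frequencies$term_key)
  if (length(missing)) {
    stop("no frequency for term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-frequencies$frequency, frequencies$term_key)
  freq <- frequencies[ord, ]
  n <- nrow(freq)
  base <- n %/% 4
  extra <- n %% 4
  sizes <- rep(base, 4) + c(rep(1, extra), rep(0, 4 - extra))
  qs <- rep(seq_len(4), sizes)
  pt <- per_term_accuracy(predictions)

  out <- do.call(rbind, lapply(seq_len(4), function(q) {
    terms <- freq$term_key[qs == q]
    if (length(terms) == 0) {
      return(NULL)
    }
    fr <- freq$frequency[qs == q]
    do.call(rbind, lapply(unique(pt$method), function(m) {
      s <- pt[pt$method == m & pt$term_key %in% terms, ]
      data.frame(quartile = q, freq_high = max(fr), freq_low = min(fr),
                 n_terms = length(terms), method = m,
                 macro_accuracy = mean(s$accuracy), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Count how often each term occurs in a corpus (local frequency)
#'
#' @param term_keys Character vector of term keys.
#' @param corpus List of `citation` records.
#' @return Data frame `term_key`, `frequency`.
#' @export
local_term_frequencies <- function(term_keys, corpus) {
  data.frame(
    term_key = term_keys,
    frequency = vapply(term_keys, function(k) {
      sum(vapply(corpus, function(ct) {
        isTRUE(as.logical(term_in_tiab(ct, k)))
      }, logical(1)))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Accuracy by unordered semantic-group pair
#'
#' Each term contributes to every unordered pair of semantic groups among
#' its senses (a two-sense term to one pair; a three-sense term with groups
#' A, B, B to pairs (A,B) and (B,B)). A sense CUI with several groups
#' contributes each of them; a CUI without any group is listed as `UNK`.
#' Macro accuracy is reported per pair with at least one term.
#'
#' @param sense_table Data frame `term_key`, `cui` (one row per sense).
#' @param store A `concept_store` with semantic groups attached.
#' @param predictions Prediction records.
#' @return Data frame `group_pair`, `n_terms`, `method`, `macro_accuracy`.
#' @export
group_pair_breakdown <- function(sense_table, store, predictions) {
  check_predictions(predictions)
  pt <- per_term_accuracy(predictions)
  term_pairs <- lapply(split(sense_table$cui, sense_table$term_key), function(cuis) {
    gsets <- lapply(cuis, function(cui) {
      g <- store$concepts[[cui]]$semantic_groups
      if (length(g) == 0) "UNK" else g
    })
    pairs <- character(0)
    k <- length(gsets)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        for (g1 in gsets[[i]]) {
          for (g2 in gsets[[j]]) {
            pairs <- c(pairs, paste(sort(c(g1, g2)), collapse = "-"))
          }
        }
      }
    }
    unique(pairs)
  })
  all_pairs <- sort(unique(unlist(term_pairs, use.names = FALSE)))
  out <- do.call(rbind, lapply(all_pairs, function(p) {
    terms <- names(term_pairs)[vapply(term_pairs, function(x) p %in% x,
                                      logical(1))]
    do.call(rbind, lapply(unique(pt$method), function(m) {
      s <- pt[pt$method == m & pt$term_key %in% terms, ]
      data.frame(group_pair = p, n_terms = length(terms), method = m,
                 macro_accuracy = mean(s$accuracy), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Paired randomization test between two methods
#'
#' The observed statistic is the absolute difference of the two methods'
#' overall macro accuracies. Each iteration swaps the two methods'
#' predictions independently per instance with probability 1/2 and
#' recomputes the statistic; the p-value is
#' `(#{iterations with statistic >= observed} + 1) / (iterations + 1)`.
#'
#' @param pred_x,pred_y Prediction records of the two methods; they must
#'   cover exactly the same (term, pmid) instances.
#' @param iterations Number of random swap iterations (default 10000).
#' @param seed Integer seed.
#' @return A list of class `randomization_test`: `p_value`, `observed`,
#'   `macro_x`, `macro_y`, `iterations`.
#' @export
randomization_test <- function(pred_x, pred_y, iterations = 10000, seed = 1L) {
  check_predictions(pred_x)
  check_predictions(pred_y)
  kx <- paste(pred_x$term_key, pred_x$pmid, sep = "\r")
  ky <- paste(pred_y$term_key, pred_y$pmid, sep = "\r")
  if (!setequal(kx, ky) || anyDuplicated(kx) || anyDuplicated(ky)) {
    stop("the two methods cover different (term, pmid) instances",
         call. = FALSE)
  }
  pred_y <- pred_y[match(kx, ky), ]

  cx <- as.numeric(pred_x$gold == pred_x$predicted)
  cy <- as.numeric(pred_y$gold == pred_y$predicted)
  terms <- pred_x$term_key
  n_per_term <- table(terms)
  w <- 1 / (as.numeric(n_per_term[terms]) * length(n_per_term))
  macro_x <- sum(w * cx)
  macro_y <- sum(w * cy)
  observed <- abs(macro_x - macro_y)

  d <- w * (cx - cy) # contribution of instance i to macro_x - macro_y
  stats <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), length(d) * iterations, replace = TRUE),
                    nrow = length(d))
    abs(as.numeric(crossprod(d, signs)))
  })
  p <- (sum(stats >= observed - 1e-12) + 1) / (iterations + 1)
  structure(
    list(p_value = p, observed = observed, macro_x = macro_x,
         macro_y = macro_y, iterations = iterations),
    class = "randomization_test"
  )
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf(paste0("<randomization_test> macro %.4f vs %.4f, |diff| = %.4f, ",
                     "p = %.4g (%d iterations)\n"),
              x$macro_x, x$macro_y, x$observed, x$p_value, x$iterations))
  invisible(x)
}
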