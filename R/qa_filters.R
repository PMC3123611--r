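# The three quality-assurance filters applied, in order, to candidate
# ambiguous terms and their retrieved citations:
#   Step 1 - every sense needs a minimum number of retrieved citations;
#   Step 2 - senses must be separable: per-sense recall of a cross-validated
#            linear maximum-margin classifier must reach a threshold;
#   Step 3 - single-letter terms are removed.

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the benchmark construction pipeline.
#'
#' @param min_citations_per_sense Minimum retrieved citations per sense
#'   (Step 1 threshold, default 10).
#' @param recall_threshold Per-sense recall below which a term is discarded
#'   in Step 2; the comparison is strict, so a recall exactly at the
#'   threshold passes (default 0.8).
#' @param cv_folds Folds for the Step-2 cross-validation (default 10).
#' @param max_instances_per_sense Per-sense cap when balancing the final
#'   data set (default 100).
#' @param min_term_length Minimum term-key length, whitespace stripped
#'   (Step 3; default 2 removes one-letter terms).
#' @param random_seed Master seed for fold assignment and sampling.
#' @param svm_cost Regularization cost of the Step-2 linear classifier
#'   (default 1).
#' @param aec_max_train_per_sense Cap on automatically extracted training
#'   documents per sense for the AEC method (default 100).
#' @param related_codes Relation codes counted as "related" when pooling
#'   concept-profile content and monosemous relatives; siblings are
#'   excluded by default.
#' @param cooccurrence_window Window radius for the second-order
#'   co-occurrence matrix (default 2).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_citations_per_sense = 10,
                            recall_threshold = 0.8,
                            cv_folds = 10,
                            max_instances_per_sense = 100,
                            min_term_length = 2,
                            random_seed = 1L,
                            svm_cost = 1,
                            aec_max_train_per_sense = 100,
                            related_codes = c("PAR", "CHD", "RB", "RN", "RO"),
                            cooccurrence_window = 2) {
  stopifnot(recall_threshold > 0, recall_threshold <= 1, cv_folds >= 2,
            min_citations_per_sense >= 0, max_instances_per_sense >= 1,
            min_term_length >= 1, cooccurrence_window >= 1)
  if (min_citations_per_sense < cv_folds) {
    warning("min_citations_per_sense < cv_folds: Step-1 survivors may still ",
            "have too few citations for stratified cross-validation",
            call. = FALSE)
  }
  structure(
    list(min_citations_per_sense = as.integer(min_citations_per_sense),
         recall_threshold = recall_threshold,
         cv_folds = as.integer(cv_folds),
         max_instances_per_sense = as.integer(max_instances_per_sense),
         min_term_length = as.integer(min_term_length),
         random_seed = as.integer(random_seed),
         svm_cost = svm_cost,
         aec_max_train_per_sense = as.integer(aec_max_train_per_sense),
         related_codes = related_codes,
         cooccurrence_window = as.integer(cooccurrence_window)),
    class = "pipeline_config"
  )
}

#' Step 1: minimum citation count per sense
#'
#' @param result A `retrieval_result`.
#' @param config A `pipeline_config`.
#' @return A list: `pass` (logical), `counts` (per-sense citation counts)
#'   and `reason` (`NA` when passing, otherwise names the deficient
#'   sense(s)).
#' @export
min_count_filter <- function(result, config) {
  stopifnot(inherits(result, "retrieval_result"))
  if (length(result$counts) == 0) {
    stop("retrieval result has no senses", call. = FALSE)
  }
  deficient <- result$counts < config$min_citations_per_sense
  reason <- if (any(deficient)) {
    sprintf("sense %s has %d citations (< %d)",
            names(result$counts)[deficient][1],
            result$counts[deficient][1], config$min_citations_per_sense)
  } else {
    NA_character_
  }
  list(pass = !any(deficient), counts = result$counts, reason = reason)
}

# Stratified fold assignment: within each sense, shuffled instances are
# dealt round-robin over folds. Seeded, so identical seeds give identical
# folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Step 2: cross-validated per-sense recall
#'
#' Trains a linear maximum-margin classifier (libsvm C-classification,
#' linear kernel, cost `config$svm_cost`) on raw token counts of the
#' citation text, under seeded stratified k-fold cross-validation, and
#' computes each sense's recall from the pooled out-of-fold predictions.
#'
#' @param instances_by_sense Named list (sense -> character vector of
#'   citation texts).
#' @param config A `pipeline_config`.
#' @return Named numeric vector of per-sense recalls in `[0, 1]`.
#' @export
crossvalidated_recall <- function(instances_by_sense, config) {
  if (length(instances_by_sense) < 2) {
    stop("separability needs at least 2 senses", call. = FALSE)
  }
  sizes <- lengths(instances_by_sense)
  if (any(sizes < config$cv_folds)) {
    stop("a sense has fewer instances (", min(sizes), ") than cv_folds (",
         config$cv_folds, "); apply the minimum-count filter first",
         call. = FALSE)
  }
  texts <- unlist(instances_by_sense, use.names = FALSE)
  labels <- factor(rep(names(instances_by_sense), sizes))
  toks <- lapply(texts, normalize_tokens)
  dtm <- build_dtm(toks)
  folds <- stratified_folds(labels, config$cv_folds,
                            derive_seed(config$random_seed, "cv-folds"))
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(config$cv_folds)) {
    test <- folds == f
    fit <- e1071::svm(dtm[!test, , drop = FALSE], labels[!test],
                      kernel = "linear", cost = config$svm_cost,
                      scale = FALSE)
    pred[test] <- stats::predict(fit, dtm[test, , drop = FALSE])
  }
  recalls <- vapply(levels(labels), function(lv) {
    mean(pred[labels == lv] == lv)
  }, numeric(1))
  recalls
}

#' Step 2 decision: separability filter
#'
#' Fails iff any sense's recall is strictly below the threshold; a recall
#' exactly at the threshold passes.
#'
#' @param recalls Named numeric vector from [crossvalidated_recall()].
#' @param config A `pipeline_config`.
#' @return A list: `pass`, `recalls`, `reason`.
#' @export
separability_filter <- function(recalls, config) {
  stopifnot(length(recalls) >= 1)
  low <- recalls < config$recall_threshold
  reason <- if (any(low)) {
    sprintf("sense %s has recall %.3f (< %.2f)", names(recalls)[low][1],
            recalls[low][1], config$recall_threshold)
  } else {
    NA_character_
  }
  list(pass = !any(low), recalls = recalls, reason = reason)
}

#' Step 3: remove terms shorter than the minimum length
#'
#' The length is measured on the normalized term key with all whitespace
#' stripped, so one-letter terms fail under the default configuration while
#' two-character terms such as chemical symbols pass.
#'
#' @param term_key Normalized term key.
#' @param config A `pipeline_config`.
#' @return A list: `pass`, `length`, `reason`.
#' @export
single_letter_filter <- function(term_key, config) {
  len <- nchar(gsub("[[:space:]]", "", term_key))
  pass <- len >= config$min_term_length
  list(pass = pass, length = len,
       reason = if (pass) NA_character_ else {
         sprintf("term length %d (< %d)", len, config$min_term_length)
       })
}

citation_text <- function(ct) {
  if (nzchar(ct$abstract)) paste(ct$title, ct$abstract) else ct$title
}

result_texts_by_sense <- function(result) {
  stats::setNames(lapply(result$citations, function(cts) {
    vapply(cts, citation_text, character(1))
  }), names(result$citations))
}

#' Run the three quality-assurance filters in order
#'
#' Step 1 (minimum counts) is applied to every term; Step 2 (cross-validated
#' separability) only to Step-1 survivors; Step 3 (single-letter removal) to
#' Step-2 survivors. Each stage's survivor set is a subset of its input.
#'
#' @param retrievals Named list (term key -> `retrieval_result`).
#' @param config A `pipeline_config`.
#' @return A list of class `filter_report`: `survivors` (named list, the
#'   surviving retrievals), `removed` (data frame `term_key`, `stage`,
#'   `reason`), `recalls` (named list of Step-2 recall vectors for terms
#'   that reached Step 2) and `stage_counts` (input and per-stage survivor
#'   counts).
#' @export
run_filter_chain <- function(retrievals, config) {
  removed <- data.frame(term_key = character(0), stage = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  add_removed <- function(term_key, stage, reason) {
    rbind(removed, data.frame(term_key = term_key, stage = stage,
                              reason = reason, stringsAsFactors = FALSE))
  }

  # Step 1
  s1 <- list()
  for (k in names(retrievals)) {
    verdict <- min_count_filter(retrievals[[k]], config)
    if (verdict$pass) {
      s1[[k]] <- retrievals[[k]]
    } else {
      removed <- add_removed(k, 1L, verdict$reason)
    }
  }

  # Step 2
  s2 <- list()
  recalls <- list()
  for (k in names(s1)) {
    rec <- crossvalidated_recall(result_texts_by_sense(s1[[k]]), config)
    recalls[[k]] <- rec
    verdict <- separability_filter(rec, config)
    if (verdict$pass) {
      s2[[k]] <- s1[[k]]
    } else {
      removed <- add_removed(k, 2L, verdict$reason)
    }
  }

  # Step 3
  s3 <- list()
  for (k in names(s2)) {
    verdict <- single_letter_filter(k, config)
    if (verdict$pass) {
      s3[[k]] <- s2[[k]]
    } else {
      removed <- add_removed(k, 3L, verdict$reason)
    }
  }

  structure(
    list(survivors = s3, removed = removed, recalls = recalls,
         stage_counts = c(input = length(retrievals), after_step1 = length(s1),
                          after_step2 = length(s2), after_step3 = length(s3))),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stage_counts)
  if (nrow(x$removed)) {
    cat("removed:\n")
    print(x$removed, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a filter report
#'
#' @param report A `filter_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_filter_report <- function(report, tsv_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(tsv_path)) {
    utils::write.table(report$removed, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(stage_counts = as.list(report$stage_counts),
           removed = report$removed,
           recalls = lapply(report$recalls, as.list)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    written <- c(written, json_path)
  }
  invisible(written)
}
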