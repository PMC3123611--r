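# End-to-end benchmark construction: extract ambiguous terms from the
# release tables, retrieve per-sense citations from a local corpus, apply
# the quality-assurance filter chain, and assemble balanced ARFF data sets.

#' Run the benchmark construction pipeline
#'
#' Executes extract -> retrieve -> filter -> assemble against local files
#' and writes one ARFF per surviving term plus a benchmark manifest, a
#' filter report and the rendered queries. All outputs are stamped with the
#' configuration hash and seed; re-running with identical inputs and
#' configuration reproduces byte-identical files.
#'
#' @param mrconso,mrdef,mrrel,mrsty,semgroups Paths to the release-style
#'   tables.
#' @param corpus_path Path to a MEDLINE-format citation file.
#' @param out_dir Output directory (created if needed).
#' @param config A `pipeline_config`.
#' @param entity_classes Optional named character vector (term key ->
#'   `A`/`T`/`AT`) annotating entity classes; terms not named default to
#'   `"T"`. The class is an editorial input, not computed.
#' @return Invisibly, a list: `datasets` (named list of `labeled_dataset`),
#'   `filter_report`, `store`, `corpus`, `manifest` (data frame), `paths`.
#' @export
run_pipeline <- function(mrconso, mrdef, mrrel, mrsty, semgroups, corpus_path,
                         out_dir, config = pipeline_config(),
                         entity_classes = NULL) {
  inputs <- c(mrconso, mrdef, mrrel, mrsty, semgroups, corpus_path)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  atoms <- read_mrconso(mrconso)
  aux <- read_auxiliary_tables(mrdef, mrrel, mrsty, semgroups)
  store <- build_concept_store(atoms, aux)
  corpus <- read_medline(corpus_path)

  candidates <- find_ambiguous_terms(store)
  terms <- list()
  for (cand in candidates) {
    res <- restrict_to_mesh_headings(cand, store)
    if (inherits(res, "ambiguous_term")) {
      res$entity_class <- if (!is.null(entity_classes) &&
                              res$term_key %in% names(entity_classes)) {
        entity_classes[[res$term_key]]
      } else {
        "T"
      }
      terms[[res$term_key]] <- res
    }
  }

  queries <- list()
  retrievals <- list()
  for (k in names(terms)) {
    trm <- terms[[k]]
    for (i in seq_len(nrow(trm$senses))) {
      queries[[length(queries) + 1]] <- build_query(trm, i)
    }
    retrievals[[k]] <- retrieve_all_senses(trm, corpus)
  }
  write_queries(queries, file.path(out_dir, "queries.txt"))

  report <- run_filter_chain(retrievals, config)
  write_filter_report(report,
                      tsv_path = file.path(out_dir, "filter_report.tsv"),
                      json_path = file.path(out_dir, "filter_report.json"))

  datasets <- list()
  for (k in names(report$survivors)) {
    trm <- assign_sense_labels(terms[[k]])
    ds <- balance_and_sample(report$survivors[[k]], trm, config,
                             corpus_id = basename(corpus_path))
    datasets[[k]] <- ds
    write_arff(ds, file.path(out_dir, paste0(gsub("[^[:alnum:]]+", "_", k),
                                             ".arff")))
  }
  manifest <- if (length(datasets)) {
    write_benchmark_manifest(datasets, file.path(out_dir, "manifest.tsv"))
  } else {
    NULL
  }

  invisible(list(datasets = datasets, filter_report = report, store = store,
                 corpus = corpus, manifest = manifest,
                 paths = list(out_dir = out_dir)))
}

#' Disambiguate a benchmark data set with the implemented methods
#'
#' Runs any of the supervised and knowledge-based methods on a labeled
#' data set: `nb` (cross-validated supervised Naive Bayes), `mrd`
#' (first-order concept profiles), `2mrd` (second-order co-occurrence
#' profiles) and `aec` (Naive Bayes on an automatically extracted corpus),
#' plus optional `combine-sum` and `combine-vote` ensembles of the
#' knowledge-based scores.
#'
#' @param dataset A `labeled_dataset`.
#' @param store A `concept_store`.
#' @param corpus List of `citation` records (used by `2mrd` for the
#'   co-occurrence matrix and by `aec` for training retrieval).
#' @param methods Character vector among `"nb"`, `"mrd"`, `"2mrd"`,
#'   `"aec"`, `"combine-sum"`, `"combine-vote"`.
#' @param config A `pipeline_config`.
#' @param coocc Optional prebuilt `cooccurrence_matrix` (rebuilt from the
#'   corpus when `NULL` and needed).
#' @return Data frame of prediction records (`term_key`, `pmid`, `gold`,
#'   `predicted`, `method`); methods that cannot score the term (AEC
#'   without training data) are omitted, with a warning.
#' @export
disambiguate_dataset <- function(dataset, store, corpus,
                                 methods = c("nb", "mrd", "2mrd", "aec"),
                                 config = pipeline_config(), coocc = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  combine_modes <- intersect(methods, c("combine-sum", "combine-vote"))
  base_methods <- setdiff(methods, combine_modes)
  inst <- dataset$instances
  senses <- dataset$senses
  term <- new_ambiguous_term(dataset$term_key, dataset$term_key,
                             senses[, c("cui", "mesh_heading")],
                             dataset$entity_class)
  term$senses <- senses

  preds <- list()
  score_sets <- list() # method -> list of sense_scores per instance

  if ("nb" %in% base_methods) {
    preds[["nb"]] <- nb_crossval(dataset, config)
  }
  if (any(c("mrd", "2mrd", "aec") %in% base_methods) || length(combine_modes)) {
    if ("mrd" %in% base_methods || length(combine_modes)) {
      profiles <- build_concept_profiles(senses$cui, store, config$related_codes)
      names(profiles) <- senses$label
      score_sets[["mrd"]] <- lapply(inst$text, function(tx) {
        mrd_score(profiles, tx)
      })
    }
    if ("2mrd" %in% base_methods || length(combine_modes)) {
      if (is.null(coocc)) {
        coocc <- build_cooccurrence_matrix(
          vapply(corpus, citation_text, character(1)),
          window = config$cooccurrence_window
        )
      }
      centroids <- build_concept_centroids(senses$cui, store, coocc,
                                           config$related_codes)
      names(centroids) <- senses$label
      score_sets[["2mrd"]] <- lapply(inst$text, function(tx) {
        two_mrd_score(centroids, tx, coocc)
      })
    }
    if ("aec" %in% base_methods || length(combine_modes)) {
      aec <- aec_disambiguate(term, store, corpus, inst$text, config)
      if (aec$unscorable) {
        warning("term ", dataset$term_key, " is unscorable by AEC (a sense ",
                "has no automatically extracted training document)",
                call. = FALSE)
      } else {
        score_sets[["aec"]] <- aec$scores
      }
    }
  }

  as_pred <- function(scores, method) {
    data.frame(term_key = dataset$term_key, pmid = inst$pmid,
               gold = inst$label,
               predicted = vapply(scores, `[[`, character(1), "predicted"),
               method = method, stringsAsFactors = FALSE)
  }
  for (m in intersect(c("mrd", "2mrd", "aec"), base_methods)) {
    if (!is.null(score_sets[[m]])) {
      preds[[m]] <- as_pred(score_sets[[m]], m)
    }
  }
  for (mode in combine_modes) {
    members <- score_sets[intersect(c("mrd", "2mrd", "aec"), names(score_sets))]
    if (length(members) >= 2) {
      combined <- lapply(seq_len(nrow(inst)), function(i) {
        combine_scores(lapply(members, `[[`, i),
                       mode = sub("^combine-", "", mode))
      })
      preds[[mode]] <- as_pred(combined, mode)
    }
  }

  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  out
}

#' Write prediction records as TSV
#'
#' @param predictions Prediction data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
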