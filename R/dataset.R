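# Assembly of the final sense-labeled benchmark: deterministic sense-label
# assignment, seeded per-sense balancing, and the ARFF serialization.

#' Assign M1..Mk sense labels to an ambiguous term
#'
#' Labels are assigned in ascending lexicographic CUI order, which makes the
#' labeling deterministic and reproducible; the emitted mapping table makes
#' any downstream comparison order-independent.
#'
#' @param term An `ambiguous_term` with at least two senses and resolved
#'   MeSH headings.
#' @return The term with its `senses` data frame reordered by CUI and given
#'   a `label` column (`M1`, `M2`, ...).
#' @export
assign_sense_labels <- function(term) {
  stopifnot(inherits(term, "ambiguous_term"), nrow(term$senses) >= 2)
  if (anyDuplicated(term$senses$cui)) {
    stop("duplicate CUI among senses of ", term$term_key, call. = FALSE)
  }
  ord <- order(term$senses$cui)
  senses <- term$senses[ord, , drop = FALSE]
  senses$label <- paste0("M", seq_len(nrow(senses)))
  rownames(senses) <- NULL
  term$senses <- senses[, c("label", "cui", "mesh_heading")]
  term
}

#' Balance and sample instances for a surviving term
#'
#' Draws, per sense, a seeded uniform sample without replacement of
#' `min(max_instances_per_sense, available)` citations and builds the
#' labeled instances (text = title + " " + abstract). Identical seeds give
#' identical data sets.
#'
#' @param result A `retrieval_result` that passed the filter chain.
#' @param term The corresponding `ambiguous_term`, labeled via
#'   [assign_sense_labels()] (labeling is applied if absent).
#' @param config A `pipeline_config`.
#' @param corpus_id Free-text provenance identifier of the corpus.
#' @return An object of class `labeled_dataset`: `term_key`,
#'   `entity_class`, `senses` (label/cui/mesh_heading), `instances` (data
#'   frame `pmid`, `text`, `label`) and `provenance` (`seed`,
#'   `config_hash`, `corpus_id`).
#' @export
balance_and_sample <- function(result, term, config, corpus_id = "local") {
  stopifnot(inherits(result, "retrieval_result"))
  if (is.null(term$senses$label)) {
    term <- assign_sense_labels(term)
  }
  avail <- result$counts[term$senses$cui]
  if (any(avail == 0)) {
    stop("sense with zero citations reached assembly for ", term$term_key,
         "; the filter chain should have removed this term", call. = FALSE)
  }
  seed <- derive_seed(config$random_seed, paste0("sample:", term$term_key))
  instances <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(term$senses)), function(i) {
      cui <- term$senses$cui[i]
      cts <- result$citations[[cui]]
      n <- min(config$max_instances_per_sense, length(cts))
      picked <- sort(sample.int(length(cts), n))
      data.frame(
        pmid = vapply(cts[picked], `[[`, character(1), "pmid"),
        text = vapply(cts[picked], citation_text, character(1)),
        label = term$senses$label[i],
        stringsAsFactors = FALSE
      )
    }))
  })
  rownames(instances) <- NULL
  if (anyDuplicated(instances$pmid)) {
    stop("duplicate PMID across senses of ", term$term_key, call. = FALSE)
  }
  structure(
    list(term_key = term$term_key,
         entity_class = term$entity_class,
         senses = term$senses,
         instances = instances,
         provenance = list(seed = config$random_seed,
                           config_hash = config_hash(unclass(config)),
                           corpus_id = corpus_id)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s: %d instances\n", x$term_key,
              nrow(x$instances)))
  tab <- table(x$instances$label)
  for (lb in sort_labels(names(tab))) {
    i <- match(lb, x$senses$label)
    cat(sprintf("  %s %s (%s): %d\n", lb, x$senses$cui[i],
                x$senses$mesh_heading[i], tab[[lb]]))
  }
  invisible(x)
}

arff_escape <- function(s) {
  gsub('"', '\\\\"', gsub("\\", "\\\\", s, fixed = TRUE))
}

arff_unescape <- function(s) {
  out <- character(length(s))
  for (i in seq_along(s)) {
    chars <- strsplit(s[i], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        buf <- c(buf, chars[j + 1])
        j <- j + 2
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

#' Write a labeled data set in ARFF format
#'
#' The relation line carries the term and its sense mapping
#' (`label=cui=heading`); attributes are the citation PMID, the instance
#' text and the nominal sense label; every data row is
#' `"pmid","text",label`. Strings are double-quoted with backslash escapes.
#' Provenance (seed, configuration hash, corpus identifier) is stored in
#' leading comment lines, so a rewrite under the same configuration is
#' byte-identical.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output `.arff` path.
#' @return `path`, invisibly.
#' @export
write_arff <- function(dataset, path) {
  senses <- dataset$senses
  relation <- paste(
    c(dataset$term_key,
      paste0(senses$label, "=", senses$cui, "=", senses$mesh_heading)),
    collapse = " | "
  )
  header <- c(
    sprintf("%% seed: %s", dataset$provenance$seed),
    sprintf("%% config: %s", dataset$provenance$config_hash),
    sprintf("%% corpus: %s", dataset$provenance$corpus_id),
    sprintf("%% entity_class: %s", dataset$entity_class),
    sprintf('@RELATION "%s"', arff_escape(relation)),
    "",
    "@ATTRIBUTE pmid STRING",
    "@ATTRIBUTE text STRING",
    sprintf("@ATTRIBUTE sense {%s}", paste(senses$label, collapse = ",")),
    "",
    "@DATA"
  )
  rows <- sprintf('"%s","%s",%s',
                  arff_escape(dataset$instances$pmid),
                  arff_escape(dataset$instances$text),
                  dataset$instances$label)
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

# Split one ARFF data row "pmid","text",label into its three fields,
# honoring backslash escapes inside the quoted strings.
arff_split_row <- function(row, line_no, path) {
  fields <- character(0)
  i <- 1
  n <- nchar(row)
  for (f in 1:2) {
    if (substr(row, i, i) != '"') {
      stop(sprintf("malformed ARFF data row at line %d of %s", line_no, path),
           call. = FALSE)
    }
    j <- i + 1
    buf <- character(0)
    repeat {
      if (j > n) {
        stop(sprintf("unterminated string at line %d of %s", line_no, path),
             call. = FALSE)
      }
      ch <- substr(row, j, j)
      if (ch == "\\") {
        buf <- c(buf, substr(row, j + 1, j + 1))
        j <- j + 2
      } else if (ch == '"') {
        break
      } else {
        buf <- c(buf, ch)
        j <- j + 1
      }
    }
    fields <- c(fields, paste(buf, collapse = ""))
    i <- j + 1
    if (substr(row, i, i) != ",") {
      stop(sprintf("expected ',' at line %d of %s", line_no, path),
           call. = FALSE)
    }
    i <- i + 1
  }
  c(fields, substr(row, i, n))
}

#' Read a labeled data set from ARFF
#'
#' Exact inverse of [write_arff()].
#'
#' @param path Path to an `.arff` file in the layout written by
#'   [write_arff()].
#' @return A `labeled_dataset`.
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read ARFF file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prov <- list(seed = NA, config_hash = NA_character_, corpus_id = NA_character_)
  entity_class <- NA_character_
  relation <- NULL
  labels <- NULL
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^% seed: ", ln)) {
      prov$seed <- suppressWarnings(as.integer(sub("^% seed: ", "", ln)))
    }
    if (grepl("^% config: ", ln)) prov$config_hash <- sub("^% config: ", "", ln)
    if (grepl("^% corpus: ", ln)) prov$corpus_id <- sub("^% corpus: ", "", ln)
    if (grepl("^% entity_class: ", ln)) entity_class <- sub("^% entity_class: ", "", ln)
    if (grepl("^@RELATION ", ln, ignore.case = TRUE)) {
      m <- regmatches(ln, regexec('^@RELATION "(.*)"$', ln, ignore.case = TRUE))[[1]]
      if (length(m) != 2) {
        stop(sprintf("malformed @RELATION at line %d of %s", i, path),
             call. = FALSE)
      }
      relation <- arff_unescape(m[2])
    }
    if (grepl("^@ATTRIBUTE sense ", ln, ignore.case = TRUE)) {
      m <- regmatches(ln, regexec("\\{(.*)\\}", ln))[[1]]
      if (length(m) != 2) {
        stop(sprintf("malformed sense attribute at line %d of %s", i, path),
             call. = FALSE)
      }
      labels <- strsplit(m[2], ",", fixed = TRUE)[[1]]
    }
    if (grepl("^@DATA", ln, ignore.case = TRUE)) {
      data_start <- i + 1L
      break
    }
  }
  if (is.null(relation) || is.null(labels) || is.na(data_start)) {
    stop("incomplete ARFF header in ", path, call. = FALSE)
  }
  parts <- strsplit(relation, " | ", fixed = TRUE)[[1]]
  term_key <- parts[1]
  sense_parts <- strsplit(parts[-1], "=", fixed = TRUE)
  senses <- data.frame(
    label = vapply(sense_parts, `[[`, character(1), 1),
    cui = vapply(sense_parts, `[[`, character(1), 2),
    mesh_heading = vapply(sense_parts, function(p) {
      paste(p[-(1:2)], collapse = "=")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (!identical(senses$label, labels)) {
    stop("sense attribute labels disagree with relation mapping in ", path,
         call. = FALSE)
  }
  body <- lines[seq(data_start, length(lines))]
  body_no <- seq(data_start, length(lines))
  keep <- nzchar(body) & !grepl("^%", body)
  instances <- do.call(rbind, lapply(which(keep), function(j) {
    f <- arff_split_row(body[j], body_no[j], path)
    data.frame(pmid = f[1], text = f[2], label = f[3], stringsAsFactors = FALSE)
  }))
  if (is.null(instances)) {
    instances <- data.frame(pmid = character(0), text = character(0),
                            label = character(0), stringsAsFactors = FALSE)
  }
  if (!all(instances$label %in% labels)) {
    stop("data row with unknown sense label in ", path, call. = FALSE)
  }
  structure(
    list(term_key = term_key, entity_class = entity_class, senses = senses,
         instances = instances, provenance = prov),
    class = "labeled_dataset"
  )
}

#' Write a benchmark manifest as TSV
#'
#' One row per (term, sense): term key, entity class (A/T/AT), label, CUI,
#' MeSH heading and instance count.
#'
#' @param datasets List of `labeled_dataset` objects.
#' @param path Output TSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_benchmark_manifest <- function(datasets, path) {
  manifest <- do.call(rbind, lapply(datasets, function(ds) {
    tab <- table(ds$instances$label)
    data.frame(term_key = ds$term_key,
               entity_class = ds$entity_class,
               label = ds$senses$label,
               cui = ds$senses$cui,
               mesh_heading = ds$senses$mesh_heading,
               n_instances = as.integer(tab[ds$senses$label]),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
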