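# Seeded generator of internally consistent mini release tables and
# MeSH-indexed citation corpora. Each ambiguous term gets k CUIs, each with
# a MeSH main-heading atom, a definition drawn from its sense vocabulary,
# related concepts (and one sibling) for profile construction, a monosemous
# synonym for AEC, and citations whose token distributions mix a
# sense-specific and a shared vocabulary under a separability parameter
# lambda. Planted failure modes exercise each quality-assurance filter.

#' Specification of a synthetic fixture
#'
#' @param n_terms Number of clean ambiguous terms.
#' @param senses_per_term Senses (CUIs) per term.
#' @param citations_per_sense Retrievable citations generated per sense.
#' @param lambda Sense separability in `[0, 1]`: each content token of a
#'   citation is drawn from the generating sense's vocabulary with
#'   probability `lambda` and from the shared vocabulary otherwise.
#' @param shared_vocab,sense_vocab Sizes of the shared vocabulary and of
#'   each sense-specific vocabulary.
#' @param title_tokens,abstract_tokens Length-2 integer ranges (inclusive)
#'   for title and abstract token counts.
#' @param relative_citations_per_sense Citations carrying the sense's
#'   monosemous synonym (AEC training material; they never contain the
#'   ambiguous term).
#' @param n_distractor_headings Size of the distractor MeSH-heading pool
#'   (disjoint from all sense headings).
#' @param plants List of planted failures: `low_count_sense`,
#'   `inseparable_pair`, `single_letter_term`, `dual_indexed` (logical
#'   flags). Planted terms are appended to the clean ones.
#' @param low_count_citations Citations given to the scarce sense of the
#'   low-count plant (default 9, one below the usual Step-1 threshold).
#' @param seed Integer seed; identical specs and seeds produce
#'   byte-identical fixture files.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 2, senses_per_term = 2,
                         citations_per_sense = 30, lambda = 0.8,
                         shared_vocab = 150, sense_vocab = 40,
                         title_tokens = c(5, 10), abstract_tokens = c(50, 150),
                         relative_citations_per_sense = 12,
                         n_distractor_headings = 6,
                         plants = list(), low_count_citations = 9,
                         seed = 1L) {
  if (lambda > 0 && sense_vocab < 1) {
    stop("infeasible fixture: lambda > 0 requires a nonempty sense vocabulary",
         call. = FALSE)
  }
  stopifnot(lambda >= 0, lambda <= 1, citations_per_sense >= 1,
            shared_vocab >= 1, sense_vocab >= 1, n_terms >= 1,
            senses_per_term >= 2, length(title_tokens) == 2,
            length(abstract_tokens) == 2)
  defaults <- list(low_count_sense = FALSE, inseparable_pair = FALSE,
                   single_letter_term = FALSE, dual_indexed = FALSE)
  defaults[names(plants)] <- plants
  structure(
    list(n_terms = as.integer(n_terms),
         senses_per_term = as.integer(senses_per_term),
         citations_per_sense = as.integer(citations_per_sense),
         lambda = lambda, shared_vocab = as.integer(shared_vocab),
         sense_vocab = as.integer(sense_vocab),
         title_tokens = as.integer(title_tokens),
         abstract_tokens = as.integer(abstract_tokens),
         relative_citations_per_sense = as.integer(relative_citations_per_sense),
         n_distractor_headings = as.integer(n_distractor_headings),
         plants = defaults,
         low_count_citations = as.integer(low_count_citations),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Random alphabetic vocabulary whose Porter stems are unique, stable under
# restemming (so token identity is preserved across repeated normalization)
# and which avoids stopwords and the reserved prefixes used for terms,
# synonyms, relatives and headings.
fixture_words <- function(n, used_stems) {
  reserved <- "^(term|plant|syn|rco|rcp|rcs|head|distract)"
  words <- character(0)
  stems <- used_stems
  while (length(words) < n) {
    len <- sample(5:8, 1)
    w <- paste(sample(letters, len, replace = TRUE), collapse = "")
    st <- porter_stem(w)
    if (!grepl(reserved, w) && !(w %in% wsd_stopwords()) &&
        !(st %in% stems) && identical(porter_stem(st), st) &&
        nchar(st) >= 2 && !(st %in% wsd_stopwords())) {
      words <- c(words, w)
      stems <- c(stems, st)
    }
  }
  list(words = words, stems = stems)
}

fixture_term_name <- function(i) {
  paste0("term", letters[(i - 1) %/% 26 + 1], letters[(i - 1) %% 26 + 1])
}

#' Generate a synthetic fixture
#'
#' Writes a complete file set - `mrconso.rrf`, `mrdef.rrf`, `mrrel.rrf`,
#' `mrsty.rrf`, `semgroups.txt`, `corpus.txt` (MEDLINE format) and
#' `manifest.json` (ground truth) - into `dir`. Every citation's generating
#' sense is recorded in the manifest; distractor headings are drawn from a
#' pool disjoint from all sense headings, so no citation is accidentally
#' indexed with a competing sense (dual-indexed citations are produced only
#' by the dedicated plant, with no gold sense).
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the ground-truth structure, also written as JSON).
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  terms <- lapply(seq_len(spec$n_terms), function(i) {
    list(name = fixture_term_name(i), lambda = spec$lambda, planted = NA_character_)
  })
  if (isTRUE(spec$plants$low_count_sense)) {
    terms <- c(terms, list(list(name = "plantscarce", lambda = 1,
                                planted = "low_count")))
  }
  if (isTRUE(spec$plants$inseparable_pair)) {
    terms <- c(terms, list(list(name = "plantblurred", lambda = 0,
                                planted = "inseparable")))
  }
  if (isTRUE(spec$plants$single_letter_term)) {
    terms <- c(terms, list(list(name = "q", lambda = 1,
                                planted = "single_letter")))
  }

  out <- with_seed(spec$seed, {
    k <- spec$senses_per_term
    shared <- fixture_words(spec$shared_vocab, porter_stem(wsd_stopwords()))
    shared_vocab <- shared$words
    stems <- shared$stems
    for (ti in seq_along(terms)) {
      sv <- vector("list", k)
      for (j in seq_len(k)) {
        got <- fixture_words(spec$sense_vocab, stems)
        sv[[j]] <- got$words
        stems <- got$stems
      }
      terms[[ti]]$sense_vocab <- sv
    }

    distractors <- paste("Distractor", LETTERS[seq_len(spec$n_distractor_headings)])
    tuis <- paste0("T", 901:908)
    groups <- paste0("GRP", LETTERS[1:4])
    semgroup_rows <- vapply(seq_along(tuis), function(t) {
      g <- groups[(t - 1) %% 4 + 1]
      paste(g, paste("Group", substr(g, 4, 4)), tuis[t],
            paste("Synthetic Type", 900 + t), sep = "|")
    }, character(1))

    conso <- character(0)
    defs <- character(0)
    rels <- character(0)
    stys <- character(0)
    aui_n <- 0L
    next_aui <- function() {
      aui_n <<- aui_n + 1L
      sprintf("A%07d", aui_n)
    }
    add_atom <- function(cui, str, sab, tty, lat = "ENG") {
      f <- rep("", 18)
      f[1] <- cui; f[2] <- lat; f[8] <- next_aui(); f[12] <- sab
      f[13] <- tty; f[15] <- str; f[17] <- "N"
      conso <<- c(conso, paste0(paste(f, collapse = "|"), "|"))
    }
    add_def <- function(cui, text) {
      f <- rep("", 8)
      f[1] <- cui; f[5] <- "SRC1"; f[6] <- text
      defs <<- c(defs, paste0(paste(f, collapse = "|"), "|"))
    }
    add_rel <- function(cui1, rel, cui2) {
      f <- rep("", 16)
      f[1] <- cui1; f[4] <- rel; f[5] <- cui2
      rels <<- c(rels, paste0(paste(f, collapse = "|"), "|"))
    }
    add_sty <- function(cui, tui_idx) {
      f <- rep("", 6)
      f[1] <- cui; f[2] <- tuis[tui_idx]
      f[4] <- paste("Synthetic Type", 900 + tui_idx)
      stys <<- c(stys, paste0(paste(f, collapse = "|"), "|"))
    }

    manifest_terms <- list()
    for (ti in seq_along(terms)) {
      trm <- terms[[ti]]
      tname <- trm$name
      variant <- paste0(toupper(substr(tname, 1, 1)), substr(tname, 2, nchar(tname)))
      senses <- list()
      for (j in seq_len(k)) {
        cui <- sprintf("C%07d", ti * 1000 + j)
        heading <- paste("Heading", tname, LETTERS[j])
        synonym <- paste0("syn", tname, letters[j])
        ro_cui <- sprintf("C%07d", 800000 + ti * 1000 + j * 10 + 1)
        par_cui <- sprintf("C%07d", 800000 + ti * 1000 + j * 10 + 2)
        sib_cui <- sprintf("C%07d", 800000 + ti * 1000 + j * 10 + 3)
        sv <- trm$sense_vocab[[j]]

        add_atom(cui, if (j == 1) variant else tname, "SRC1", "PT")
        add_atom(cui, heading, "MSH", "MH")
        add_atom(cui, synonym, "MSH", "SY")
        add_def(cui, paste(sample(sv, 15, replace = TRUE), collapse = " "))
        add_sty(cui, (2 * ti + j) %% 8 + 1)

        add_atom(ro_cui, paste0("rco", tname, letters[j]), "SRC1", "PT")
        add_def(ro_cui, paste(sample(sv, 10, replace = TRUE), collapse = " "))
        add_rel(cui, "RO", ro_cui)
        add_atom(par_cui, paste0("rcp", tname, letters[j]), "SRC1", "PT")
        add_def(par_cui, paste(sample(sv, 10, replace = TRUE), collapse = " "))
        add_rel(cui, "PAR", par_cui)
        add_atom(sib_cui, paste0("rcs", tname, letters[j]), "SRC1", "PT")
        add_def(sib_cui, paste(sample(shared_vocab, 10, replace = TRUE),
                               collapse = " "))
        add_rel(cui, "SIB", sib_cui)

        n_cit <- spec$citations_per_sense
        if (identical(trm$planted, "low_count") && j == 1) {
          n_cit <- spec$low_count_citations
        }
        senses[[j]] <- list(label = paste0("M", j), cui = cui,
                            mesh_heading = heading, synonym = synonym,
                            tui = tuis[(2 * ti + j) %% 8 + 1],
                            group = groups[(2 * ti + j) %% 8 %% 4 + 1],
                            n_citations = n_cit)
      }
      # an extra candidate CUI without any main-heading atom: dropped by
      # the MeSH restriction, like supplementary substances in a release
      extra_cui <- sprintf("C%07d", ti * 1000 + 99)
      add_atom(extra_cui, tname, "SRC1", "PT")
      # one non-English atom to exercise the language filter
      if (ti == 1) {
        add_atom(sprintf("C%07d", ti * 1000 + 1), "termextranjero", "SRC1",
                 "PT", lat = "SPA")
      }
      manifest_terms[[ti]] <- list(term_key = normalize_term_key(tname),
                                   surface = tname, variant = variant,
                                   entity_class = "T", lambda = trm$lambda,
                                   planted = trm$planted, extra_cui = extra_cui,
                                   senses = senses)
    }

    # --- citations ---
    pmid_n <- 2000000L
    next_pmid <- function() {
      pmid_n <<- pmid_n + 1L
      as.character(pmid_n)
    }
    draw_tokens <- function(n, lambda, sv) {
      from_sense <- stats::runif(n) < lambda
      toks <- character(n)
      n_s <- sum(from_sense)
      if (n_s > 0) toks[from_sense] <- sample(sv, n_s, replace = TRUE)
      if (n_s < n) {
        toks[!from_sense] <- sample(shared_vocab, n - n_s, replace = TRUE)
      }
      toks
    }
    make_citation <- function(insert, lambda, sv, headings) {
      nt <- sample(spec$title_tokens[1]:spec$title_tokens[2], 1)
      na <- sample(spec$abstract_tokens[1]:spec$abstract_tokens[2], 1)
      toks <- draw_tokens(nt + na, lambda, sv)
      pos <- sample.int(nt + na + 1, 1)
      toks <- append(toks, insert, after = pos - 1)
      title <- paste(toks[seq_len(nt + (pos <= nt + 1))], collapse = " ")
      abstract <- paste(toks[-seq_len(nt + (pos <= nt + 1))], collapse = " ")
      medline_citation(next_pmid(), title, abstract, headings)
    }

    corpus <- list()
    cit_manifest <- list()
    for (ti in seq_along(manifest_terms)) {
      mt <- manifest_terms[[ti]]
      surfaces <- c(mt$surface, mt$variant)
      for (j in seq_len(k)) {
        sn <- mt$senses[[j]]
        sv <- terms[[ti]]$sense_vocab[[j]]
        for (c_i in seq_len(sn$n_citations)) {
          nd <- sample(0:2, 1)
          heads <- c(sn$mesh_heading,
                     if (nd > 0) sort(sample(distractors, nd)) else character(0))
          ct <- make_citation(sample(surfaces, 1), mt$lambda, sv, heads)
          corpus[[length(corpus) + 1]] <- ct
          cit_manifest[[length(cit_manifest) + 1]] <-
            list(pmid = ct$pmid, term_key = mt$term_key, cui = sn$cui,
                 label = sn$label, kind = "instance")
        }
        for (c_i in seq_len(spec$relative_citations_per_sense)) {
          nd <- sample(1:2, 1)
          ct <- make_citation(sn$synonym, mt$lambda, sv,
                              sort(sample(distractors, nd)))
          corpus[[length(corpus) + 1]] <- ct
          cit_manifest[[length(cit_manifest) + 1]] <-
            list(pmid = ct$pmid, term_key = mt$term_key, cui = sn$cui,
                 label = sn$label, kind = "relative")
        }
      }
      if (isTRUE(spec$plants$dual_indexed) && ti == 1) {
        for (c_i in 1:2) {
          heads <- vapply(mt$senses[1:2], `[[`, character(1), "mesh_heading")
          ct <- make_citation(mt$surface, mt$lambda,
                              terms[[ti]]$sense_vocab[[1]], heads)
          corpus[[length(corpus) + 1]] <- ct
          cit_manifest[[length(cit_manifest) + 1]] <-
            list(pmid = ct$pmid, term_key = mt$term_key, cui = NA,
                 label = NA, kind = "dual_indexed")
        }
      }
    }

    list(conso = conso, defs = defs, rels = rels, stys = stys,
         semgroups = semgroup_rows, corpus = corpus,
         manifest = list(
           generator = "wsdbench synthetic fixture",
           seed = spec$seed,
           spec = unclass(spec),
           terms = manifest_terms,
           citations = cit_manifest
         ))
  })

  paths <- c(mrconso = file.path(dir, "mrconso.rrf"),
             mrdef = file.path(dir, "mrdef.rrf"),
             mrrel = file.path(dir, "mrrel.rrf"),
             mrsty = file.path(dir, "mrsty.rrf"),
             semgroups = file.path(dir, "semgroups.txt"),
             corpus = file.path(dir, "corpus.txt"),
             manifest = file.path(dir, "manifest.json"))
  writeLines(out$conso, paths[["mrconso"]], useBytes = TRUE)
  writeLines(out$defs, paths[["mrdef"]], useBytes = TRUE)
  writeLines(out$rels, paths[["mrrel"]], useBytes = TRUE)
  writeLines(out$stys, paths[["mrsty"]], useBytes = TRUE)
  writeLines(out$semgroups, paths[["semgroups"]], useBytes = TRUE)
  write_medline(out$corpus, paths[["corpus"]])
  jsonlite::write_json(out$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(paths = paths, manifest = out$manifest))
}

#' Expected pipeline outcomes for a generated fixture
#'
#' Derives from the ground-truth manifest which terms each
#' quality-assurance filter must remove, the expected per-sense retrieval
#' counts, and the gold sense labels for evaluation.
#'
#' @param manifest Manifest structure from [generate_fixture()] (or read
#'   back from its `manifest.json`).
#' @param config A `pipeline_config`.
#' @return A list: `removed` (data frame `term_key`, `stage`),
#'   `survivors` (character), `expected_counts` (named list: term key ->
#'   named per-CUI counts) and `gold` (data frame `pmid`, `term_key`,
#'   `cui`, `label` for instance citations).
#' @export
fixture_oracle <- function(manifest, config = pipeline_config()) {
  term_keys <- vapply(manifest$terms, `[[`, character(1), "term_key")
  expected_counts <- lapply(manifest$terms, function(mt) {
    cuis <- vapply(mt$senses, `[[`, character(1), "cui")
    stats::setNames(vapply(mt$senses, function(s) s$n_citations, numeric(1)),
                    cuis)
  })
  names(expected_counts) <- term_keys

  removal_rows <- function(keys, stage) {
    data.frame(term_key = keys, stage = rep(stage, length(keys)),
               stringsAsFactors = FALSE)
  }
  removed <- removal_rows(character(0), integer(0))
  remaining <- term_keys
  fail1 <- term_keys[vapply(expected_counts, function(x) {
    any(x < config$min_citations_per_sense)
  }, logical(1))]
  removed <- rbind(removed, removal_rows(fail1, 1L))
  remaining <- setdiff(remaining, fail1)

  planted <- vapply(manifest$terms, function(mt) {
    if (is.null(mt$planted) || is.na(mt$planted)) NA_character_ else mt$planted
  }, character(1))
  fail2 <- intersect(remaining, term_keys[!is.na(planted) &
                                            planted == "inseparable"])
  removed <- rbind(removed, removal_rows(fail2, 2L))
  remaining <- setdiff(remaining, fail2)

  fail3 <- remaining[nchar(gsub("[[:space:]]", "", remaining)) <
                       config$min_term_length]
  removed <- rbind(removed, removal_rows(fail3, 3L))
  remaining <- setdiff(remaining, fail3)

  inst <- Filter(function(ct) identical(ct$kind, "instance"),
                 manifest$citations)
  gold <- data.frame(
    pmid = vapply(inst, `[[`, character(1), "pmid"),
    term_key = vapply(inst, `[[`, character(1), "term_key"),
    cui = vapply(inst, `[[`, character(1), "cui"),
    label = vapply(inst, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  list(removed = removed, survivors = remaining,
       expected_counts = expected_counts, gold = gold)
}
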