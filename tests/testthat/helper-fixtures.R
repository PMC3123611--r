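# Shared in-code fixtures and independent brute-force oracles.

# Build one pipe-delimited release row with values at given 1-based columns.
rrf_row <- function(ncol, ...) {
  vals <- list(...)
  f <- rep("", ncol)
  for (pos in names(vals)) {
    f[as.integer(pos)] <- vals[[pos]]
  }
  paste0(paste(f, collapse = "|"), "|")
}

mrconso_row <- function(cui, str, sab = "SRC1", tty = "PT", lat = "ENG",
                        aui = "A0000001", suppress = "N") {
  rrf_row(18, "1" = cui, "2" = lat, "8" = aui, "12" = sab, "13" = tty,
          "15" = str, "17" = suppress)
}

mrdef_row <- function(cui, def, sab = "SRC1") {
  rrf_row(8, "1" = cui, "5" = sab, "6" = def)
}

mrrel_row <- function(cui1, rel, cui2) {
  rrf_row(16, "1" = cui1, "4" = rel, "5" = cui2)
}

mrsty_row <- function(cui, tui, sty = "Some Type") {
  rrf_row(6, "1" = cui, "2" = tui, "4" = sty)
}

write_lines_tmp <- function(lines, ext = ".rrf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

# Candidate-CUI rows of the ambiguous string "lens" and, optionally, the
# main-heading atoms that anchor three of the four candidates to MeSH.
lens_conso_lines <- function(include_mh = TRUE) {
  lines <- c(
    mrconso_row("C0023308", "lens", aui = "A0000001"),
    mrconso_row("C0023317", "Lens", aui = "A0000002"),
    mrconso_row("C0023318", "Lens", aui = "A0000003"),
    mrconso_row("C0996842", "Lens", aui = "A0000004")
  )
  if (include_mh) {
    lines <- c(
      lines,
      mrconso_row("C0023308", "Lens Diseases", sab = "MSH", tty = "MH", aui = "A0000005"),
      mrconso_row("C0023317", "Lens, Crystalline", sab = "MSH", tty = "MH", aui = "A0000006"),
      mrconso_row("C0023318", "Lenses", sab = "MSH", tty = "MH", aui = "A0000007")
    )
  }
  lines
}

lens_store <- function(include_mh = TRUE) {
  build_concept_store(read_mrconso(write_lines_tmp(lens_conso_lines(include_mh))))
}

lens_term <- function(store = lens_store()) {
  terms <- find_ambiguous_terms(store)
  terms[[which(vapply(terms, `[[`, character(1), "term_key") == "lens")]]
}

# A small random concept store over `n_keys` surface strings, each with a
# random number of CUIs and random semantic types; used against brute-force
# recounts of the ambiguity statistics.
random_store <- function(n_keys = 50, seed = 1) {
  set.seed(seed)
  tuis <- paste0("T", 1:6)
  groups_lines <- vapply(seq_along(tuis), function(i) {
    paste(paste0("G", (i - 1) %% 3 + 1), "Group", tuis[i], "Type", sep = "|")
  }, character(1))
  conso <- character(0)
  sty <- character(0)
  aui <- 0
  cui_n <- 0
  for (k in seq_len(n_keys)) {
    n_cui <- sample(1:4, 1)
    for (j in seq_len(n_cui)) {
      cui_n <- cui_n + 1
      cui <- sprintf("C%07d", cui_n)
      aui <- aui + 1
      conso <- c(conso, mrconso_row(cui, paste0("word", k),
                                    aui = sprintf("A%07d", aui)))
      for (t in sample(tuis, sample(0:2, 1))) {
        sty <- c(sty, mrsty_row(cui, t))
      }
      if (stats::runif(1) < 0.4) {
        aui <- aui + 1
        conso <- c(conso, mrconso_row(cui, paste("Heading", cui), sab = "MSH",
                                      tty = "MH", aui = sprintf("A%07d", aui)))
      }
    }
  }
  atoms <- read_mrconso(write_lines_tmp(conso))
  aux <- read_auxiliary_tables(
    write_lines_tmp(character(0)),
    write_lines_tmp(character(0)),
    write_lines_tmp(if (length(sty)) sty else character(0)),
    write_lines_tmp(groups_lines)
  )
  build_concept_store(atoms, aux)
}

# Independent token-walk matcher used as oracle for term_in_tiab: tokenizes
# both sides on non-alphanumerics and scans for the key's word sequence.
scan_match <- function(text, key) {
  words <- tolower(strsplit(key, "[^[:alnum:]]+")[[1]])
  words <- words[nzchar(words)]
  toks <- tolower(strsplit(text, "[^[:alnum:]]+")[[1]])
  toks <- toks[nzchar(toks)]
  if (length(words) == 0 || length(toks) < length(words)) {
    return(FALSE)
  }
  for (i in seq_len(length(toks) - length(words) + 1)) {
    if (all(toks[i + seq_along(words) - 1] == words)) {
      return(TRUE)
    }
  }
  FALSE
}

# Brute-force sense-query evaluation: a plain set comprehension over the
# three predicates, with the token-walk matcher.
bf_query_eval <- function(query, corpus) {
  Filter(function(ct) {
    scan_match(paste(ct$title, ct$abstract), query$term_key) &&
      query$positive_heading %in% ct$mesh_headings &&
      !any(query$negative_headings %in% ct$mesh_headings)
  }, corpus)
}

# Random small corpora with controlled headings and occasional term
# occurrences, for soundness/disjointness property tests.
random_corpus <- function(n_citations, term = "cold", headings, seed) {
  set.seed(seed)
  filler <- c("colder", "virus", "patient", "therapy", "study", "cells",
              "protein", "clinical", "analysis", "model")
  lapply(seq_len(n_citations), function(i) {
    words <- sample(filler, sample(3:8, 1), replace = TRUE)
    if (stats::runif(1) < 0.6) {
      words <- append(words, term, after = sample(0:length(words), 1))
    }
    hs <- sample(headings, sample(0:min(3, length(headings)), 1))
    medline_citation(as.character(10000 + i),
                     paste(words[1:2], collapse = " "),
                     paste(words[-(1:2)], collapse = " "),
                     hs)
  })
}

make_instances <- function(texts_by_label) {
  do.call(rbind, lapply(names(texts_by_label), function(lb) {
    data.frame(text = texts_by_label[[lb]], label = lb, stringsAsFactors = FALSE)
  }))
}

# Concept-store fixture with two senses of "cold" whose profiles come from
# definitions, synonyms and non-sibling relatives.
cold_store <- function() {
  conso <- c(
    mrconso_row("C0009264", "cold", aui = "A1"),
    mrconso_row("C0009264", "Cold Temperature", sab = "MSH", tty = "MH", aui = "A2"),
    mrconso_row("C0009264", "low temperature", aui = "A3"),
    mrconso_row("C0009443", "cold", aui = "A4"),
    mrconso_row("C0009443", "Common Cold", sab = "MSH", tty = "MH", aui = "A5"),
    mrconso_row("C0009443", "acute coryza", aui = "A6"),
    mrconso_row("C0039476", "temperature scale", aui = "A7"),
    mrconso_row("C2350229", "hot temperature", aui = "A8"),
    mrconso_row("C0042769", "virus infection", aui = "A9")
  )
  aux <- read_auxiliary_tables(
    write_lines_tmp(c(
      mrdef_row("C0009264", "having less heat energy than the object"),
      mrdef_row("C0009443", "viral infection of the upper airway"),
      mrdef_row("C0039476", "degree of heat measured on a scale"),
      mrdef_row("C2350229", "having more heat energy than the object"),
      mrdef_row("C0042769", "disease caused by viral agents")
    )),
    write_lines_tmp(c(
      mrrel_row("C0009264", "PAR", "C0039476"),
      mrrel_row("C0009264", "SIB", "C2350229"),
      mrrel_row("C0009443", "RO", "C0042769")
    )),
    write_lines_tmp(character(0)),
    write_lines_tmp("GA|Group A|T001|Type A")
  )
  build_concept_store(read_mrconso(write_lines_tmp(conso)), aux)
}

cold_term <- function(store = cold_store()) {
  assign_sense_labels(restrict_to_mesh_headings(
    find_ambiguous_terms(store)[[1]], store))
}

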