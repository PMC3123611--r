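test_that("MEDLINE files round-trip through the reader and writer", {
  cts <- list(
    medline_citation("100", "The common cold in adults",
                     "A study of cold symptoms.",
                     c("Common Cold", "Adult")),
    medline_citation("101", "Lens replacement", "",
                     c("Lenses"))
  )
  path <- tempfile(fileext = ".txt")
  write_medline(cts, path)
  back <- read_medline(path)
  expect_equal(back, cts)
})

test_that("MEDLINE continuation lines and heading markers are normalized", {
  path <- write_lines_tmp(c(
    "PMID- 42",
    "TI  - A long title that",
    "      continues here",
    "AB  - Abstract text",
    "MH  - *Lens Diseases/genetics",
    "MH  - Adult"
  ), ext = ".txt")
  cts <- read_medline(path)
  expect_equal(cts[[1]]$title, "A long title that continues here")
  expect_equal(cts[[1]]$mesh_headings, c("Lens Diseases", "Adult"))
  expect_error(read_medline(write_lines_tmp(c("PMID- 1", "TI  - a", "",
                                              "PMID- 1", "TI  - b"),
                                            ext = ".txt")),
               "duplicate PMID")
})

test_that("the lens query has one positive and k-1 exclusion clauses", {
  store <- lens_store()
  term <- restrict_to_mesh_headings(lens_term(store), store)
  q <- build_query(term, "C0023308")
  expect_equal(q$positive_heading, "Lens Diseases")
  expect_equal(q$negative_headings, c("Lens, Crystalline", "Lenses"))
  expect_equal(
    q$rendered,
    paste0('"lens"[TIAB] AND "Lens Diseases"[MH:noexp]',
           ' NOT "Lens, Crystalline"[MH:noexp] NOT "Lenses"[MH:noexp]')
  )
  expect_equal(lengths(regmatches(q$rendered, gregexpr("\\[TIAB\\]", q$rendered))), 1)
  expect_equal(lengths(regmatches(q$rendered, gregexpr(" NOT ", q$rendered))), 2)
})

test_that("a k-sense term yields exactly k-1 NOT clauses for k = 2..5", {
  for (k in 2:5) {
    senses <- data.frame(cui = sprintf("C%07d", seq_len(k)),
                         mesh_heading = paste("Heading", LETTERS[seq_len(k)]),
                         stringsAsFactors = FALSE)
    term <- structure(list(term_key = "probe", surface_variants = "probe",
                           senses = senses, entity_class = NA),
                      class = "ambiguous_term")
    for (i in seq_len(k)) {
      q <- build_query(term, i)
      expect_length(q$negative_headings, k - 1)
      expect_false(q$positive_heading %in% q$negative_headings)
      # rendering/parsing is a lossless pair
      p <- parse_query(q$rendered)
      expect_equal(p$term_key, q$term_key)
      expect_equal(p$positive_heading, q$positive_heading)
      expect_equal(p$negative_headings, q$negative_headings)
    }
  }
})

test_that("single-sense terms cannot produce a query", {
  term <- structure(list(term_key = "solo", surface_variants = "solo",
                         senses = data.frame(cui = "C0000001",
                                             mesh_heading = "Heading",
                                             stringsAsFactors = FALSE),
                         entity_class = NA),
                    class = "ambiguous_term")
  expect_error(build_query(term, 1), ">= 2 senses")
})

test_that("term matching respects token boundaries and reports offsets", {
  ct <- medline_citation("1", "The common cold in adults", "Nothing here.")
  hit <- term_in_tiab(ct, "cold")
  expect_true(as.logical(hit))
  spans <- attr(hit, "spans")
  expect_equal(unname(spans$title[1, ]), c(11L, 15L))
  expect_equal(substr(ct$title, spans$title[1, 1] + 1, spans$title[1, 2]), "cold")

  # substring occurrences do not match
  ct2 <- medline_citation("2", "On hypothermia", "Patients got colder overnight")
  expect_false(as.logical(term_in_tiab(ct2, "cold")))

  # multi-word keys match across any separator run
  ct3 <- medline_citation("3", "Blood  pressure: a review", "blood-pressure data")
  hit3 <- term_in_tiab(ct3, "blood pressure")
  expect_true(as.logical(hit3))
  expect_equal(nrow(attr(hit3, "spans")$title), 1)
  expect_equal(nrow(attr(hit3, "spans")$abstract), 1)
  expect_false(as.logical(term_in_tiab(ct3, "pressure blood")))
})

test_that("the matcher agrees with a token-walk oracle on random texts", {
  set.seed(5)
  vocab <- c("cold", "colder", "cold.", "common", "virus", "blood", "pressure",
             "bloodpressure", "x1", "x2")
  keys <- c("cold", "blood pressure", "common cold", "x1")
  for (i in 1:100) {
    text <- paste(sample(vocab, sample(2:12, 1), replace = TRUE),
                  collapse = sample(c(" ", "  ", ", ", "\n"), 1))
    ct <- medline_citation("9", text, "")
    for (key in keys) {
      expect_equal(as.logical(term_in_tiab(ct, key)), scan_match(text, key),
                   info = paste(key, "in:", text))
    }
  }
})

test_that("local query evaluation applies all three predicates in corpus order", {
  term <- structure(list(term_key = "lens", surface_variants = "lens",
                         senses = data.frame(
                           cui = c("C0023308", "C0023317", "C0023318"),
                           mesh_heading = c("Lens Diseases", "Lens, Crystalline",
                                            "Lenses"),
                           stringsAsFactors = FALSE),
                         entity_class = NA),
                    class = "ambiguous_term")
  q <- build_query(term, 1)
  corpus <- list(
    medline_citation("1", "A lens disorder", "", "Lens Diseases"),
    medline_citation("2", "A lens disorder", "", c("Lens Diseases", "Lenses")),
    medline_citation("3", "No mention at all", "", "Lens Diseases"),
    medline_citation("4", "Another lens case", "", "Lens Diseases")
  )
  hits <- evaluate_query_local(q, corpus)
  expect_equal(vapply(hits, `[[`, character(1), "pmid"), c("1", "4"))
})

test_that("per-sense retrieval is disjoint and excludes dual-indexed citations", {
  term <- structure(list(term_key = "cold", surface_variants = "cold",
                         senses = data.frame(
                           cui = c("C0009264", "C0009443"),
                           mesh_heading = c("Cold Temperature", "Common Cold"),
                           stringsAsFactors = FALSE),
                         entity_class = NA),
                    class = "ambiguous_term")
  corpus <- list(
    medline_citation("1", "cold exposure", "", "Cold Temperature"),
    medline_citation("2", "cold season", "", "Common Cold"),
    medline_citation("3", "cold both ways", "", c("Cold Temperature", "Common Cold")),
    medline_citation("4", "nothing relevant", "", "Cold Temperature")
  )
  res <- retrieve_all_senses(term, corpus)
  expect_equal(unname(res$counts), c(1L, 1L))
  pmids <- lapply(res$citations, function(x) vapply(x, `[[`, character(1), "pmid"))
  expect_length(intersect(pmids[[1]], pmids[[2]]), 0)
  expect_false("3" %in% unlist(pmids))

  # a corpus without the term in any title/abstract yields empty sets
  empty <- retrieve_all_senses(term, list(
    medline_citation("9", "irrelevant", "", "Cold Temperature")
  ))
  expect_equal(unname(empty$counts), c(0L, 0L))
})

test_that("retrieval equals the brute-force oracle and stays disjoint on random corpora", {
  headings <- c("Cold Temperature", "Common Cold", "Cold Climate", "Adult")
  term <- structure(list(term_key = "cold", surface_variants = "cold",
                         senses = data.frame(
                           cui = c("C0009264", "C0009443", "C0008945"),
                           mesh_heading = headings[1:3],
                           stringsAsFactors = FALSE),
                         entity_class = NA),
                    class = "ambiguous_term")
  for (seed in 1:25) {
    corpus <- random_corpus(sample(5:40, 1), "cold", headings, seed = seed)
    res <- retrieve_all_senses(term, corpus)
    all_pmids <- unlist(lapply(res$citations, function(x) {
      vapply(x, `[[`, character(1), "pmid")
    }))
    expect_equal(anyDuplicated(all_pmids), 0)
    for (i in seq_len(nrow(term$senses))) {
      q <- build_query(term, i)
      expect_equal(
        vapply(res$citations[[i]], `[[`, character(1), "pmid"),
        vapply(bf_query_eval(q, corpus), `[[`, character(1), "pmid")
      )
    }
  }
})
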