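test_that("Naive Bayes posteriors match the closed-form hand computation", {
  model <- train_nb(make_instances(list(M1 = "temperature temperature",
                                        M2 = "virus virus")))
  sc <- nb_score(model, "temperature")
  # vocabulary {temperatur, virus}, add-one smoothing:
  # p(temperatur|M1) = (2+1)/(2+2) = 3/4, p(temperatur|M2) = (0+1)/(2+2) = 1/4
  # equal priors -> posterior M1 = 3/4
  expect_equal(unname(sc$scores["M1"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(sc$scores["M2"]), 0.25, tolerance = 1e-12)
  expect_equal(sc$predicted, "M1")
})

test_that("unseen tokens fall back to the prior and ties break low", {
  model <- train_nb(make_instances(list(
    M1 = c("temperature temperature", "temperature heat"),
    M2 = "virus virus"
  )))
  sc <- nb_score(model, "zzz qqq")
  expect_equal(unname(sc$scores), c(2, 1) / 3, tolerance = 1e-12)

  tie <- train_nb(make_instances(list(M1 = "alpha", M2 = "beta")))
  sc2 <- nb_score(tie, "gamma")
  expect_equal(unname(sc2$scores), c(0.5, 0.5))
  expect_equal(sc2$predicted, "M1")
})

test_that("posteriors always sum to one", {
  set.seed(44)
  vocab <- paste0("tok", 1:20)
  model <- train_nb(make_instances(list(
    M1 = replicate(5, paste(sample(vocab, 8, replace = TRUE), collapse = " ")),
    M2 = replicate(7, paste(sample(vocab, 8, replace = TRUE), collapse = " ")),
    M3 = replicate(3, paste(sample(vocab, 8, replace = TRUE), collapse = " "))
  )))
  for (i in 1:25) {
    sc <- nb_score(model, paste(sample(c(vocab, "novel"), 6, replace = TRUE),
                                collapse = " "))
    expect_equal(sum(sc$scores), 1, tolerance = 1e-9)
  }
})

test_that("profile weights equal a brute-force tf * ln(N/cf) computation", {
  store <- cold_store()
  term <- cold_term(store)
  cuis <- term$senses$cui
  profiles <- build_concept_profiles(cuis, store)

  # independent recomputation from the raw pools
  pools <- list()
  for (cui in cuis) {
    con <- store$concepts[[cui]]
    texts <- c(con$definitions$definition, con$synonyms)
    rel <- con$relations[con$relations$rel != "SIB", , drop = FALSE]
    for (rcui in rel$cui2) {
      texts <- c(texts, store$concepts[[rcui]]$definitions$definition,
                 store$concepts[[rcui]]$synonyms[1])
    }
    pools[[cui]] <- unlist(lapply(texts, normalize_tokens))
  }
  n <- length(pools)
  for (cui in cuis) {
    tf <- table(pools[[cui]])
    for (tok in names(tf)) {
      cf <- sum(vapply(pools, function(p) tok %in% p, logical(1)))
      w <- as.numeric(tf[tok]) * log(n / cf)
      if (w > 0) {
        expect_equal(unname(profiles[[cui]]$weights[tok]), w,
                     tolerance = 1e-9, info = paste(cui, tok))
      } else {
        expect_false(tok %in% names(profiles[[cui]]$weights))
      }
    }
  }
})

test_that("ubiquitous tokens get zero weight and sibling content is excluded", {
  store <- cold_store()
  profiles <- build_concept_profiles(c("C0009264", "C0009443"), store)
  # "cold" appears as a synonym of both concepts -> ln(2/2) = 0 -> dropped
  expect_false("cold" %in% names(profiles[["C0009264"]]$weights))
  # sibling (hot temperature) definition token "more" must not leak in
  expect_false("more" %in% names(profiles[["C0009264"]]$weights))
  # but the PAR relative's definition contributes ("degre" from "degree")
  expect_true("degre" %in% names(profiles[["C0009264"]]$weights))
})

test_that("an isolated concept yields an empty profile with a warning", {
  store <- build_concept_store(read_mrconso(write_lines_tmp(
    mrconso_row("C0000001", "loner", aui = "A1")
  )))
  # synonym-only concepts still have content; strip synonyms via collection
  # of one concept with no definitions/relations but a synonym: not empty.
  # A cui absent from the store is the truly empty case:
  expect_warning(p <- build_concept_profiles("C9999999", store), "empty profile")
  expect_true(p[["C9999999"]]$empty)
})

test_that("MRD cosine scores match hand computation and pick the best sense", {
  p1 <- structure(list(cui = "C1", weights = c(heat = 2, energi = 1),
                       empty = FALSE), class = "concept_profile")
  p2 <- structure(list(cui = "C2", weights = c(viru = 2, infect = 1),
                       empty = FALSE), class = "concept_profile")
  profiles <- list(M1 = p1, M2 = p2)
  sc <- mrd_score(profiles, "heat heat energy")
  # context vector (heat=2, energi=1); cosine with p1 = (2*2+1*1)/(sqrt5*sqrt5)
  expect_equal(unname(sc$scores["M1"]), 1, tolerance = 1e-12)
  expect_equal(unname(sc$scores["M2"]), 0)
  expect_equal(sc$predicted, "M1")

  # orthogonal context: all scores zero, tie to M1
  sc0 <- mrd_score(profiles, "unrelated words only")
  expect_equal(unname(sc0$scores), c(0, 0))
  expect_equal(sc0$predicted, "M1")

  # closed-form check on asymmetric vectors
  sc2 <- mrd_score(profiles, "heat virus virus")
  expect_equal(unname(sc2$scores["M1"]),
               2 / (sqrt(5) * sqrt(5)), tolerance = 1e-12)
  expect_equal(unname(sc2$scores["M2"]),
               (2 * 2) / (sqrt(5) * sqrt(5)), tolerance = 1e-12)
})

test_that("scoring is invariant to positive rescaling of profile vectors", {
  p1 <- structure(list(cui = "C1", weights = c(heat = 2, energi = 1),
                       empty = FALSE), class = "concept_profile")
  p2 <- structure(list(cui = "C2", weights = c(viru = 2, infect = 1),
                       empty = FALSE), class = "concept_profile")
  scaled <- list(M1 = p1, M2 = p2)
  scaled$M2$weights <- scaled$M2$weights * 37
  a <- mrd_score(list(M1 = p1, M2 = p2), "heat virus infection")
  b <- mrd_score(scaled, "heat virus infection")
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
})

test_that("co-occurrence counts match exhaustive pair enumeration", {
  # three distinct content tokens, window 2: all three pairs counted once
  coocc <- build_cooccurrence_matrix("heating viruses degrees", window = 2)
  m <- as.matrix(coocc$matrix)
  expect_equal(sort(coocc$vocab), coocc$vocab)
  for (a in coocc$vocab) {
    for (b in coocc$vocab) {
      expect_equal(m[a, b], if (a == b) 0 else 1)
    }
  }

  # window 1 only counts adjacent pairs
  c1 <- build_cooccurrence_matrix("heating viruses degrees", window = 1)
  m1 <- as.matrix(c1$matrix)
  expect_equal(m1["heat", "virus"], 1)
  expect_equal(m1["virus", "degre"], 1)
  expect_equal(m1["heat", "degre"], 0)

  # single-token documents produce no counts
  c2 <- build_cooccurrence_matrix("heating", window = 2)
  expect_equal(sum(c2$matrix), 0)
})

test_that("co-occurrence matrices are symmetric on random corpora", {
  set.seed(6)
  vocab <- paste0("tok", 1:12)
  for (i in 1:10) {
    texts <- replicate(5, paste(sample(vocab, sample(3:15, 1), replace = TRUE),
                                collapse = " "))
    coocc <- build_cooccurrence_matrix(texts, window = sample(1:3, 1))
    expect_equal(as.matrix(coocc$matrix), t(as.matrix(coocc$matrix)))
    expect_equal(sum(Matrix::diag(coocc$matrix)), 0)
  }
})

test_that("second-order centroids equal dense linear algebra", {
  vocab <- c("aa", "bb", "cc")
  m <- matrix(c(0, 2, 1,
                2, 0, 3,
                1, 3, 0), nrow = 3, byrow = TRUE,
              dimnames = list(vocab, vocab))
  coocc <- structure(list(vocab = vocab,
                          matrix = Matrix::Matrix(m, sparse = TRUE),
                          window = 2), class = "cooccurrence_matrix")
  v <- second_order_vector(c("aa", "bb", "aa"), coocc)
  expect_equal(unname(v), unname((2 * m["aa", ] + m["bb", ]) / 3),
               tolerance = 1e-12)
  # all tokens sharing one identical row reproduce that row
  v2 <- second_order_vector(c("aa", "aa"), coocc)
  expect_equal(unname(v2), unname(m["aa", ]))
  # unknown-only and empty token lists give the zero vector
  expect_equal(sum(second_order_vector("zz", coocc)), 0)
  expect_equal(sum(second_order_vector(character(0), coocc)), 0)
})

test_that("2-MRD scores match an independent dense computation", {
  vocab <- c("aa", "bb", "cc", "dd")
  m <- matrix(0, 4, 4, dimnames = list(vocab, vocab))
  m["aa", "bb"] <- m["bb", "aa"] <- 3
  m["cc", "dd"] <- m["dd", "cc"] <- 2
  m["aa", "cc"] <- m["cc", "aa"] <- 1
  coocc <- structure(list(vocab = vocab,
                          matrix = Matrix::Matrix(m, sparse = TRUE),
                          window = 2), class = "cooccurrence_matrix")
  centroids <- list(M1 = second_order_vector(c("aa", "bb"), coocc),
                    M2 = second_order_vector(c("cc", "dd"), coocc))
  sc <- two_mrd_score(centroids, "aa aa bb", coocc)
  ctx <- (2 * m["aa", ] + m["bb", ]) / 3
  cos_d <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(unname(sc$scores["M1"]),
               cos_d(ctx, (m["aa", ] + m["bb", ]) / 2), tolerance = 1e-12)
  expect_equal(unname(sc$scores["M2"]),
               cos_d(ctx, (m["cc", ] + m["dd", ]) / 2), tolerance = 1e-12)
})

test_that("with an identity co-occurrence matrix 2-MRD degenerates to MRD", {
  store <- cold_store()
  term <- cold_term(store)
  cuis <- term$senses$cui
  profiles <- build_concept_profiles(cuis, store)
  vocab <- sort(unique(c(
    unlist(lapply(profiles, function(p) names(p$weights))),
    normalize_tokens("heat energy viral infection upper airway degree scale")
  )))
  ident <- structure(
    list(vocab = vocab,
         matrix = Matrix::Diagonal(length(vocab), 1),
         window = 2),
    class = "cooccurrence_matrix"
  )
  dimnames(ident$matrix) <- list(vocab, vocab)
  centroids <- build_concept_centroids(cuis, store, ident)
  names(centroids) <- term$senses$label
  names(profiles) <- term$senses$label
  texts <- c("heat energy measurement", "viral infection of airway",
             "degree scale and heat", "upper airway disease")
  for (tx in texts) {
    a <- mrd_score(profiles, tx)
    b <- two_mrd_score(centroids, tx, ident)
    expect_equal(a$predicted, b$predicted, info = tx)
    expect_equal(unname(a$scores), unname(b$scores), tolerance = 1e-9)
  }
})

test_that("monosemous relatives keep only unambiguous non-term strings", {
  store <- cold_store()
  term <- cold_term(store)
  rel1 <- monosemous_relatives("C0009264", term, store)
  # "cold" itself is the ambiguous term; "low temperature" is monosemous;
  # PAR relative contributes "temperature scale"
  expect_setequal(rel1, c("Cold Temperature", "low temperature",
                          "temperature scale"))
  rel2 <- monosemous_relatives("C0009443", term, store)
  expect_setequal(rel2, c("Common Cold", "acute coryza", "virus infection"))

  # a synonym shared by two concepts is excluded
  conso <- c(
    mrconso_row("C0000001", "alpha", aui = "A1"),
    mrconso_row("C0000001", "shared name", aui = "A2"),
    mrconso_row("C0000002", "alpha", aui = "A3"),
    mrconso_row("C0000002", "shared name", aui = "A4"),
    mrconso_row("C0000001", "unique name", aui = "A5")
  )
  st <- build_concept_store(read_mrconso(write_lines_tmp(conso)))
  tm <- structure(list(term_key = "alpha", surface_variants = "alpha",
                       senses = data.frame(cui = c("C0000001", "C0000002"),
                                           mesh_heading = c("H1", "H2"),
                                           stringsAsFactors = FALSE),
                       entity_class = NA),
                  class = "ambiguous_term")
  expect_equal(monosemous_relatives("C0000001", tm, st), "unique name")
})

test_that("AEC retrieves by phrase, falls back to word conjunction, trains NB", {
  store <- cold_store()
  term <- cold_term(store)
  corpus <- list(
    medline_citation("1", "low temperature storage",
                     "samples kept under heat energy control", "Distractor A"),
    medline_citation("2", "acute coryza outbreak",
                     "viral infection spreading in winter", "Distractor A"),
    # "virus infection" only as separated words -> broadened form only
    medline_citation("3", "virus found in airway infection",
                     "the viral agents persist", "Distractor B"),
    medline_citation("4", "unrelated record", "nothing to see", "Distractor B")
  )
  cfg <- pipeline_config(random_seed = 1)
  train <- aec_training_corpus(term, store, corpus, cfg)
  expect_setequal(train$instances$pmid[train$instances$label == "M1"], "1")
  expect_setequal(train$instances$pmid[train$instances$label == "M2"], c("2", "3"))
  expect_length(train$unscorable, 0)

  out <- aec_disambiguate(term, store, corpus,
                          c("heat energy in the samples",
                            "viral infection of the airway"), cfg)
  expect_false(out$unscorable)
  expect_equal(vapply(out$scores, `[[`, character(1), "predicted"),
               c("M1", "M2"))

  # a sense whose relatives retrieve nothing flags the term unscorable
  out2 <- aec_disambiguate(term, store, corpus[2:4],
                           "heat energy in the samples", cfg)
  expect_true(out2$unscorable)
  expect_null(out2$scores)
})

test_that("separable AEC fixtures reach perfect accuracy on generated instances", {
  spec <- fixture_spec(n_terms = 1, citations_per_sense = 20, lambda = 1,
                       abstract_tokens = c(15, 30), seed = 41)
  dir <- file.path(tempdir(), "aecfx")
  fx <- generate_fixture(spec, dir)
  cfg <- pipeline_config(random_seed = 41)
  res <- run_pipeline(fx$paths[["mrconso"]], fx$paths[["mrdef"]],
                      fx$paths[["mrrel"]], fx$paths[["mrsty"]],
                      fx$paths[["semgroups"]], fx$paths[["corpus"]],
                      file.path(tempdir(), "aecout"), cfg)
  ds <- res$datasets[[1]]
  preds <- disambiguate_dataset(ds, res$store, res$corpus, methods = "aec",
                                config = cfg)
  expect_equal(mean(preds$gold == preds$predicted), 1)
  expect_equal(nrow(preds), 40)
})

test_that("score combination sums normalized scores and resolves vote ties", {
  s <- function(m1, m2, method = "x") sense_scores(c(M1 = m1, M2 = m2), method)
  # sum mode: (0.9, 0.1) + (0.2, 0.8) -> M1 wins 1.1 vs 0.9
  sm <- combine_scores(list(s(0.9, 0.1), s(0.2, 0.8)), mode = "sum")
  expect_equal(unname(sm$scores), c(1.1, 0.9), tolerance = 1e-12)
  expect_equal(sm$predicted, "M1")

  # majority vote
  v <- combine_scores(list(s(1, 0), s(0.9, 0.1), s(0, 1)), mode = "vote")
  expect_equal(v$predicted, "M1")

  # vote tie broken by the sum-mode score
  v2 <- combine_scores(list(s(0.6, 0.4), s(0.1, 0.9)), mode = "vote")
  expect_equal(v2$predicted, "M2")

  # all-zero vectors are skipped by normalization, not divided by zero
  z <- combine_scores(list(s(0, 0), s(0.2, 0.8)), mode = "sum")
  expect_equal(unname(z$scores), c(0.2, 0.8))

  expect_error(
    combine_scores(list(s(1, 0), sense_scores(c(M1 = 1, M3 = 0), "y"))),
    "different label sets"
  )
})
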