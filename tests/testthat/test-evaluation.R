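make_preds <- function(correct_by_term, method = "m") {
  do.call(rbind, lapply(names(correct_by_term), function(tk) {
    flags <- correct_by_term[[tk]]
    data.frame(term_key = tk, pmid = as.character(seq_along(flags)),
               gold = "M1", predicted = ifelse(flags, "M1", "M2"),
               method = method, stringsAsFactors = FALSE)
  }))
}

test_that("per-term and category accuracies follow the macro/micro definitions", {
  preds <- make_preds(list(alpha = rep(TRUE, 10),
                           beta = c(rep(TRUE, 6), rep(FALSE, 4))))
  manifest <- data.frame(term_key = c("alpha", "beta"),
                         entity_class = c("A", "T"), stringsAsFactors = FALSE)
  rep <- accuracy_report(preds, manifest)
  expect_equal(rep$per_term$accuracy[rep$per_term$term_key == "alpha"], 1.0)
  expect_equal(rep$per_term$accuracy[rep$per_term$term_key == "beta"], 0.6)
  overall <- rep$categories[rep$categories$category == "overall", ]
  expect_equal(overall$macro_accuracy, 0.8)
  expect_equal(overall$micro_accuracy, 16 / 20)

  # macro is invariant to instance counts, micro is not
  preds2 <- make_preds(list(alpha = rep(TRUE, 100),
                            beta = c(rep(TRUE, 6), rep(FALSE, 4))))
  rep2 <- accuracy_report(preds2, manifest)
  o2 <- rep2$categories[rep2$categories$category == "overall", ]
  expect_equal(o2$macro_accuracy, 0.8)
  expect_gt(o2$micro_accuracy, overall$micro_accuracy)
})

test_that("accuracy reports equal a brute-force recount on random predictions", {
  set.seed(12)
  terms <- paste0("t", 1:6)
  preds <- do.call(rbind, lapply(terms, function(tk) {
    n <- sample(5:20, 1)
    data.frame(term_key = tk, pmid = as.character(seq_len(n)),
               gold = sample(c("M1", "M2"), n, replace = TRUE),
               predicted = sample(c("M1", "M2"), n, replace = TRUE),
               method = "m", stringsAsFactors = FALSE)
  }))
  manifest <- data.frame(term_key = terms,
                         entity_class = sample(c("A", "T", "AT"), 6, replace = TRUE),
                         stringsAsFactors = FALSE)
  rep <- accuracy_report(preds, manifest)
  for (tk in terms) {
    sub <- preds[preds$term_key == tk, ]
    expect_equal(rep$per_term$accuracy[rep$per_term$term_key == tk],
                 sum(sub$gold == sub$predicted) / nrow(sub))
  }
  overall <- rep$categories[rep$categories$category == "overall", ]
  expect_equal(overall$macro_accuracy, mean(rep$per_term$accuracy))
})

test_that("missing or duplicated predictions are contract violations", {
  preds <- make_preds(list(alpha = rep(TRUE, 3)))
  manifest <- data.frame(term_key = c("alpha", "beta"), entity_class = "T",
                         stringsAsFactors = FALSE)
  expect_error(accuracy_report(preds, manifest), "beta")
  dup <- rbind(preds, preds[1, ])
  expect_error(accuracy_report(dup, manifest[1, , drop = FALSE]), "duplicate")
})

test_that("quartiles split terms 3-3-2-2 with remainders to earlier groups", {
  freqs <- data.frame(term_key = paste0("t", 1:10), frequency = 100:91,
                      stringsAsFactors = FALSE)
  preds <- make_preds(stats::setNames(replicate(10, TRUE, simplify = FALSE),
                                      paste0("t", 1:10)))
  q <- quartile_breakdown(freqs, preds)
  expect_equal(q$n_terms, c(3, 3, 2, 2))
  expect_equal(q$freq_high, c(100, 97, 94, 92))
  expect_equal(q$freq_low, c(98, 95, 93, 91))

  eight <- quartile_breakdown(freqs[1:8, ],
                              make_preds(stats::setNames(
                                replicate(8, TRUE, simplify = FALSE),
                                paste0("t", 1:8))))
  expect_equal(eight$n_terms, rep(2, 4))
})

test_that("frequency ties at quartile boundaries resolve by term key, reproducibly", {
  freqs <- data.frame(term_key = c("zed", "ant", "mid", "bee"),
                      frequency = c(10, 10, 10, 10), stringsAsFactors = FALSE)
  preds <- make_preds(stats::setNames(replicate(4, TRUE, simplify = FALSE),
                                      freqs$term_key))
  q1 <- quartile_breakdown(freqs, preds)
  q2 <- quartile_breakdown(freqs[c(3, 1, 4, 2), ], preds)
  expect_identical(q1, q2)
})

test_that("group pairs cover each term's sense-group combinations", {
  aux <- read_auxiliary_tables(
    write_lines_tmp(character(0)), write_lines_tmp(character(0)),
    write_lines_tmp(c(mrsty_row("C0000001", "T001"),
                      mrsty_row("C0000002", "T002"),
                      mrsty_row("C0000011", "T001"),
                      mrsty_row("C0000012", "T002"),
                      mrsty_row("C0000021", "T001"),
                      mrsty_row("C0000022", "T002"),
                      mrsty_row("C0000023", "T002"))),
    write_lines_tmp(c("CHEM|Chemicals|T001|Type 1", "DISO|Disorders|T002|Type 2"))
  )
  conso <- unlist(lapply(c("C0000001", "C0000002", "C0000011", "C0000012",
                           "C0000021", "C0000022", "C0000023"), function(cui) {
    mrconso_row(cui, paste0("s", cui), aui = paste0("A", cui))
  }))
  store <- build_concept_store(read_mrconso(write_lines_tmp(conso)), aux)

  sense_table <- data.frame(
    term_key = c("crack", "crack", "snap", "snap", "tri", "tri", "tri"),
    cui = c("C0000001", "C0000002", "C0000011", "C0000012",
            "C0000021", "C0000022", "C0000023"),
    stringsAsFactors = FALSE
  )
  preds <- make_preds(list(crack = rep(TRUE, 4),
                           snap = c(TRUE, FALSE),
                           tri = rep(TRUE, 3)))
  out <- group_pair_breakdown(sense_table, store, preds)

  cd <- out[out$group_pair == "CHEM-DISO", ]
  expect_equal(cd$n_terms, 3)
  expect_equal(cd$macro_accuracy, mean(c(1, 0.5, 1)))
  dd <- out[out$group_pair == "DISO-DISO", ]
  expect_equal(dd$n_terms, 1) # only the 3-sense term spans (DISO, DISO)

  # a cui with no semantic group lands in an UNK pair
  st2 <- build_concept_store(read_mrconso(write_lines_tmp(conso)), NULL)
  out2 <- group_pair_breakdown(sense_table[1:2, ], st2,
                               make_preds(list(crack = TRUE)))
  expect_equal(out2$group_pair, "UNK-UNK")
})

test_that("identical prediction sets give a randomization p-value of 1", {
  preds <- make_preds(list(alpha = c(TRUE, FALSE, TRUE),
                           beta = c(TRUE, TRUE)))
  rt <- randomization_test(preds, preds, iterations = 500, seed = 2)
  expect_equal(rt$p_value, 1)
  expect_equal(rt$observed, 0)
})

test_that("maximally separated methods give a tiny p-value", {
  n <- 200
  x <- data.frame(term_key = "t", pmid = as.character(1:n), gold = "M1",
                  predicted = "M1", method = "good", stringsAsFactors = FALSE)
  y <- x
  y$predicted <- "M2"
  y$method <- "bad"
  rt <- randomization_test(x, y, iterations = 10000, seed = 9)
  expect_lte(rt$p_value, 0.001)
  expect_equal(rt$observed, 1)
})

test_that("the test is symmetric in its arguments and checks coverage", {
  set.seed(33)
  preds_a <- make_preds(list(alpha = stats::runif(20) < 0.8,
                             beta = stats::runif(15) < 0.8), "a")
  preds_b <- make_preds(list(alpha = stats::runif(20) < 0.7,
                             beta = stats::runif(15) < 0.7), "b")
  p1 <- randomization_test(preds_a, preds_b, iterations = 2000, seed = 5)
  p2 <- randomization_test(preds_b, preds_a, iterations = 2000, seed = 5)
  expect_equal(p1$p_value, p2$p_value)
  expect_error(randomization_test(preds_a, preds_b[-1, ], iterations = 10,
                                  seed = 1),
               "different")
})
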