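# Knowledge-based disambiguation via concept profiles: first-order cosine
# matching between context and profile vectors (MRD), and its second-order
# variant that replaces tokens by their corpus co-occurrence rows (2-MRD).

#' Token pool of a concept
#'
#' Pools, with multiplicity, the normalized tokens of (a) every definition
#' of the CUI, (b) its synonym strings and (c) the definitions and
#' preferred strings of related CUIs whose relation code is in
#' `related_codes` - siblings are excluded by default.
#'
#' @param cui Concept identifier.
#' @param store A `concept_store`.
#' @param related_codes Relation codes treated as "related".
#' @return Character vector of normalized tokens (possibly empty).
#' @export
concept_token_pool <- function(cui, store,
                               related_codes = c("PAR", "CHD", "RB", "RN", "RO")) {
  con <- store$concepts[[cui]]
  if (is.null(con)) {
    return(character(0))
  }
  texts <- c(con$definitions$definition, con$synonyms)
  rel <- con$relations
  rel <- rel[rel$rel %in% related_codes, , drop = FALSE]
  for (rcui in rel$cui2) {
    rcon <- store$concepts[[rcui]]
    if (!is.null(rcon)) {
      texts <- c(texts, rcon$definitions$definition, preferred_string(store, rcui))
    }
  }
  unlist(lapply(texts, normalize_tokens), use.names = FALSE)
}

#' Build tf-icf concept profiles for a collection of senses
#'
#' Each profile weight is `tf * ln(N / cf)` where `tf` is the token's
#' frequency in the concept's pool, `N` the number of profiles in the
#' collection and `cf` the number of profiles whose pool contains the
#' token. A token present in every profile therefore receives weight 0
#' everywhere; zero-weight entries are dropped.
#'
#' @param cuis Character vector of sense CUIs forming the collection.
#' @param store A `concept_store`.
#' @param related_codes Relation codes treated as "related".
#' @return Named list (cui -> `concept_profile` with fields `cui`,
#'   `weights` (named numeric) and `empty` flag set when the concept has no
#'   definitions, synonyms or relations at all).
#' @export
build_concept_profiles <- function(cuis, store,
                                   related_codes = c("PAR", "CHD", "RB", "RN", "RO")) {
  pools <- lapply(cuis, concept_token_pool, store = store,
                  related_codes = related_codes)
  names(pools) <- cuis
  n <- length(pools)
  all_tokens <- unique(unlist(pools, use.names = FALSE))
  cf <- vapply(all_tokens, function(tok) {
    sum(vapply(pools, function(p) tok %in% p, logical(1)))
  }, numeric(1))
  profiles <- lapply(cuis, function(cui) {
    pool <- pools[[cui]]
    empty <- length(pool) == 0
    if (empty) {
      warning("concept ", cui, " has an empty profile (no definitions, ",
              "synonyms or relations)", call. = FALSE)
      weights <- stats::setNames(numeric(0), character(0))
    } else {
      tf <- token_vector(pool)
      weights <- tf * log(n / cf[names(tf)])
      weights <- weights[weights > 0]
    }
    structure(list(cui = cui, weights = weights, empty = empty),
              class = "concept_profile")
  })
  names(profiles) <- cuis
  profiles
}

#' Build one concept profile within an explicit collection
#'
#' Convenience wrapper around [build_concept_profiles()] returning the
#' profile of a single CUI, with inverted concept frequencies computed over
#' `collection`.
#'
#' @param cui Concept identifier (must be in `collection`).
#' @param store A `concept_store`.
#' @param collection Character vector of CUIs defining the profile
#'   collection; defaults to `cui` alone.
#' @param related_codes Relation codes treated as "related".
#' @return A `concept_profile`.
#' @export
build_concept_profile <- function(cui, store, collection = cui,
                                  related_codes = c("PAR", "CHD", "RB", "RN", "RO")) {
  stopifnot(cui %in% collection)
  build_concept_profiles(collection, store, related_codes)[[cui]]
}

#' First-order concept-profile (MRD) scoring
#'
#' Turns the instance text into a term-frequency context vector (same
#' normalization as the profiles) and scores each sense by cosine
#' similarity between the context vector and the sense's profile. The
#' cosine against (or of) a zero vector is 0; ties break to the lowest
#' sense label.
#'
#' @param profiles Named list (sense label -> `concept_profile`).
#' @param text Instance text.
#' @return A `sense_scores` object (method `"mrd"`).
#' @export
mrd_score <- function(profiles, text) {
  ctx <- token_vector(normalize_tokens(text))
  scores <- vapply(profiles, function(p) cosine_similarity(ctx, p$weights),
                   numeric(1))
  sense_scores(stats::setNames(scores, names(profiles)), method = "mrd")
}

#' Build a symmetric within-window co-occurrence matrix
#'
#' Counts, over all corpus texts, how often two distinct normalized tokens
#' occur within `window` positions of each other. The matrix is symmetric
#' with an all-zero diagonal (a token is not counted as co-occurring with
#' itself at the same position, and same-token pairs are excluded).
#'
#' @param texts Character vector of corpus texts.
#' @param window Window radius in token positions (>= 1).
#' @param vocab Optional fixed vocabulary; defaults to all tokens seen.
#' @return An object of class `cooccurrence_matrix`: `vocab`, `matrix`
#'   (sparse symmetric `Matrix::dgCMatrix`), `window`.
#' @export
build_cooccurrence_matrix <- function(texts, window = 2, vocab = NULL) {
  stopifnot(window >= 1)
  toks <- lapply(texts, normalize_tokens)
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  }
  ii <- integer(0)
  jj <- integer(0)
  for (tk in toks) {
    idx <- match(tk, vocab)
    keep <- !is.na(idx)
    idx <- idx[keep]
    n <- length(idx)
    if (n < 2) next
    for (d in seq_len(min(window, n - 1))) {
      a <- idx[seq_len(n - d)]
      b <- idx[seq(d + 1, n)]
      ok <- a != b
      ii <- c(ii, a[ok], b[ok])
      jj <- c(jj, b[ok], a[ok])
    }
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                              dims = c(length(vocab), length(vocab)),
                              dimnames = list(vocab, vocab))
  structure(list(vocab = vocab, matrix = mat, window = window),
            class = "cooccurrence_matrix")
}

#' Second-order vector of a token list
#'
#' Replaces each token occurrence by its co-occurrence-matrix row and
#' returns the centroid (arithmetic mean over the occurrences). Tokens
#' absent from the vocabulary are ignored; if none remain the zero vector
#' is returned.
#'
#' @param tokens Character vector of normalized tokens.
#' @param coocc A `cooccurrence_matrix`.
#' @param weights Optional nonnegative weight per token occurrence (defaults
#'   to 1); the centroid is then the weighted average of the rows.
#' @return Dense numeric vector over `coocc$vocab`.
#' @export
second_order_vector <- function(tokens, coocc, weights = NULL) {
  if (is.null(weights)) {
    weights <- rep(1, length(tokens))
  }
  stopifnot(length(weights) == length(tokens))
  idx <- match(tokens, coocc$vocab)
  keep <- !is.na(idx)
  idx <- idx[keep]
  weights <- weights[keep]
  out <- stats::setNames(numeric(length(coocc$vocab)), coocc$vocab)
  if (length(idx) == 0 || sum(weights) == 0) {
    return(out)
  }
  rows <- coocc$matrix[idx, , drop = FALSE]
  out[] <- as.numeric(Matrix::crossprod(rows, weights)) / sum(weights)
  out
}

#' Second-order concept centroids for a collection of senses
#'
#' Builds each sense's tf-icf profile from the concept store (same token
#' pools as the first-order method) and averages the co-occurrence rows of
#' the profile tokens, weighted by their tf-icf weights, so that ubiquitous
#' pool tokens contribute nothing. With an identity co-occurrence matrix the
#' centroid reduces to the (normalized) first-order profile.
#'
#' @param cuis Character vector of sense CUIs.
#' @param store A `concept_store`.
#' @param coocc A `cooccurrence_matrix`.
#' @param related_codes Relation codes treated as "related".
#' @return Named list (cui -> dense centroid vector over `coocc$vocab`).
#' @export
build_concept_centroids <- function(cuis, store, coocc,
                                    related_codes = c("PAR", "CHD", "RB", "RN", "RO")) {
  profiles <- build_concept_profiles(cuis, store, related_codes)
  lapply(profiles, function(p) {
    second_order_vector(names(p$weights), coocc, weights = as.numeric(p$weights))
  })
}

#' Second-order (2-MRD) scoring
#'
#' The instance's normalized tokens are replaced by their co-occurrence
#' rows and averaged; the resulting centroid is compared to each sense's
#' concept centroid by cosine similarity.
#'
#' @param centroids Named list (sense label -> dense centroid vector), as
#'   from [build_concept_centroids()] relabeled by sense.
#' @param text Instance text.
#' @param coocc The `cooccurrence_matrix` the centroids were built with.
#' @return A `sense_scores` object (method `"2mrd"`).
#' @export
two_mrd_score <- function(centroids, text, coocc) {
  ctx <- second_order_vector(normalize_tokens(text), coocc)
  scores <- vapply(centroids, function(cv) {
    dense_cosine(ctx, cv)
  }, numeric(1))
  sense_scores(stats::setNames(scores, names(centroids)), method = "2mrd")
}

dense_cosine <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(0)
  }
  sum(x * y) / (nx * ny)
}
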