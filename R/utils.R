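#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state so package functions never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Hash-mixes a master seed with an arbitrary key (typically a term key) so
#' per-term sampling is independent yet fully determined by the master seed.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed Integer master seed.
#' @param key Character scalar mixed into the hash.
#' @return Integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, key) {
  h <- digest::digest(paste(seed, key, sep = "\r"), algo = "xxhash32", serialize = FALSE)
  # first 7 hex digits < 16^7 < 2^31, so the result is a valid integer seed
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

#' Round half away from zero
#'
#' Base R rounds half to even; release-table percentages are conventionally
#' printed with halves rounded up, which this helper implements for
#' nonnegative input.
#'
#' @param x Numeric vector (nonnegative).
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Order sense labels M1, M2, ..., M10 numerically, not lexicographically.
label_order <- function(labels) {
  order(as.integer(sub("^M", "", labels)))
}

sort_labels <- function(labels) {
  labels[label_order(labels)]
}

# Argmax with deterministic tie-break to the earliest label in M-order.
argmax_label <- function(scores) {
  stopifnot(length(scores) >= 1, !is.null(names(scores)))
  top <- names(scores)[scores >= max(scores) - 1e-12]
  sort_labels(top)[1]
}

#' Cosine similarity of two sparse named vectors
#'
#' Vectors are named numeric weight vectors; names are the token dimensions.
#' The cosine of a zero vector (either side) is defined as 0.
#'
#' @param x,y Named numeric vectors.
#' @return Cosine similarity in `[-1, 1]` (nonnegative for count weights).
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(0)
  }
  shared <- intersect(names(x), names(y))
  if (length(shared) == 0) {
    return(0)
  }
  sum(x[shared] * y[shared]) / (nx * ny)
}

# Stable hash of a configuration list, used to stamp outputs.
config_hash <- function(config) {
  digest::digest(config[order(names(config))], algo = "xxhash32")
}
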