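# Ensemble combination of per-instance sense scores from several methods.

#' Combine sense scores from several methods
#'
#' In `sum` mode each method's score vector is shifted to be nonnegative
#' (when it contains negative values) and normalized to sum to one (a
#' vector of all zeros is left as is), then the normalized vectors are
#' added. In `vote` mode each method casts its argmax; the majority label
#' wins, ties between labels are broken by the sum-mode combined score and
#' then by the lower label.
#'
#' @param scores_list List of `sense_scores` for one instance, one per
#'   method; all must carry the same label set.
#' @param mode `"sum"` or `"vote"`.
#' @return A `sense_scores` object (method `"combine-sum"` or
#'   `"combine-vote"`).
#' @export
combine_scores <- function(scores_list, mode = c("sum", "vote")) {
  mode <- match.arg(mode)
  stopifnot(length(scores_list) >= 1)
  labels <- sort_labels(names(scores_list[[1]]$scores))
  for (sc in scores_list) {
    if (!identical(sort_labels(names(sc$scores)), labels)) {
      stop("methods scored different label sets", call. = FALSE)
    }
  }
  normalized <- lapply(scores_list, function(sc) {
    v <- sc$scores[labels]
    if (min(v) < 0) {
      v <- v - min(v)
    }
    if (sum(v) > 0) {
      v <- v / sum(v)
    }
    v
  })
  summed <- Reduce(`+`, normalized)

  if (mode == "sum") {
    return(sense_scores(summed, method = "combine-sum"))
  }

  votes <- vapply(scores_list, `[[`, character(1), "predicted")
  tally <- table(factor(votes, levels = labels))
  top <- names(tally)[tally == max(tally)]
  if (length(top) > 1) {
    sub <- summed[top]
    top <- names(sub)[sub >= max(sub) - 1e-12]
  }
  winner <- sort_labels(top)[1]
  out <- stats::setNames(as.numeric(tally[labels]), labels)
  res <- sense_scores(out, method = "combine-vote")
  res$predicted <- winner
  res
}
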