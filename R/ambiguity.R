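# Identification of ambiguous candidate terms (term keys mapping to several
# CUIs) and restriction of their senses to MeSH main headings, plus the
# descriptive per-semantic-group ambiguity statistics.

new_ambiguous_term <- function(term_key, surface_variants, senses,
                               entity_class = NA_character_) {
  structure(
    list(term_key = term_key,
         surface_variants = sort(unique(surface_variants)),
         senses = senses, # data.frame(cui, mesh_heading)
         entity_class = entity_class),
    class = "ambiguous_term"
  )
}

#' @export
print.ambiguous_term <- function(x, ...) {
  cat(sprintf("<ambiguous_term> %s (%d senses)\n", x$term_key, nrow(x$senses)))
  for (i in seq_len(nrow(x$senses))) {
    cat(sprintf("  %s  %s\n", x$senses$cui[i],
                ifelse(is.na(x$senses$mesh_heading[i]), "-", x$senses$mesh_heading[i])))
  }
  invisible(x)
}

#' Find candidate ambiguous terms in a concept store
#'
#' Returns every term key mapping to two or more CUIs, each CUI attached as
#' a provisional sense (MeSH headings are not yet resolved; see
#' [restrict_to_mesh_headings()]).
#'
#' @param store A `concept_store`.
#' @return A list of `ambiguous_term` objects, ordered by term key.
#' @export
find_ambiguous_terms <- function(store) {
  keys <- names(store$term_index)[lengths(store$term_index) >= 2]
  keys <- sort(keys)
  lapply(keys, function(k) {
    cuis <- store$term_index[[k]]
    variants <- unique(store$atoms$term_string[
      normalize_term_key(store$atoms$term_string) == k])
    new_ambiguous_term(
      term_key = k,
      surface_variants = variants,
      senses = data.frame(cui = cuis, mesh_heading = NA_character_,
                          stringsAsFactors = FALSE)
    )
  })
}

# The MH atom string of a cui, or NA if the cui has no MSH main-heading atom.
mesh_heading_of <- function(store, cui) {
  rows <- store$atoms$cui == cui &
    store$atoms$source_abbrev == "MSH" & store$atoms$term_type == "MH"
  if (!any(rows)) {
    return(NA_character_)
  }
  store$atoms$term_string[which(rows)[1]]
}

#' Restrict an ambiguous term's senses to MeSH main headings
#'
#' Keeps only senses whose CUI carries an atom with source `MSH` and term
#' type `MH` (a MeSH main heading); other candidate CUIs - typically
#' supplementary substances or qualifiers - are dropped. The term survives
#' only if at least two senses remain; otherwise a rejection record stating
#' the surviving sense count is returned.
#'
#' The operation is monotone and idempotent: output senses are a subset of
#' input senses and a second application changes nothing.
#'
#' @param term An `ambiguous_term`.
#' @param store The `concept_store` the term came from.
#' @return The term with `senses$mesh_heading` filled in (class
#'   `ambiguous_term`), or an object of class `mesh_rejection` with fields
#'   `term_key` and `n_surviving`.
#' @export
restrict_to_mesh_headings <- function(term, store) {
  stopifnot(inherits(term, "ambiguous_term"))
  headings <- vapply(term$senses$cui, function(cui) mesh_heading_of(store, cui),
                     character(1))
  keep <- !is.na(headings)
  if (sum(keep) < 2) {
    return(structure(list(term_key = term$term_key, n_surviving = sum(keep)),
                     class = "mesh_rejection"))
  }
  term$senses <- data.frame(cui = term$senses$cui[keep],
                            mesh_heading = unname(headings[keep]),
                            stringsAsFactors = FALSE)
  term
}

#' @export
print.mesh_rejection <- function(x, ...) {
  cat(sprintf("<mesh_rejection> %s: %d MeSH main-heading sense(s), need >= 2\n",
              x$term_key, x$n_surviving))
  invisible(x)
}

# Semantic groups of a term key = union of groups over all its cuis.
term_groups <- function(store, cuis) {
  unique(unlist(lapply(cuis, function(cui) {
    store$concepts[[cui]]$semantic_groups
  }), use.names = FALSE))
}

#' Per-semantic-group ambiguity statistics
#'
#' For each semantic group G in the mapping table: `distinct` counts term
#' keys with at least one CUI in G (membership through any of the key's
#' CUIs' semantic types); `ambiguous` counts those keys that map to two or
#' more CUIs overall; `percent` is `100 * ambiguous / distinct` rounded half
#' up to two decimals (reported as 0 with `undefined = TRUE` when a group
#' has no distinct terms); `mesh_linked` counts ambiguous keys in G with at
#' least two CUIs carrying a MeSH main-heading atom (benchmark candidates).
#' The inter-group matrix cell (G1, G2) counts term keys with at least one
#' CUI in G1 and at least one in G2; the diagonal therefore equals the
#' distinct counts.
#'
#' @param store A `concept_store` built with semantic types and the group
#'   mapping attached.
#' @return A list of class `ambiguity_report`: `per_group` data frame
#'   (`group`, `distinct`, `ambiguous`, `percent`, `mesh_linked`,
#'   `undefined`) and `matrix` (square integer matrix of shared term-key
#'   counts).
#' @export
ambiguity_statistics <- function(store) {
  groups <- sort(unique(store$groups$group))
  keys <- names(store$term_index)
  key_groups <- lapply(keys, function(k) term_groups(store, store$term_index[[k]]))
  n_cuis <- lengths(store$term_index)
  mesh_cnt <- vapply(keys, function(k) {
    sum(!is.na(vapply(store$term_index[[k]], function(cui) {
      mesh_heading_of(store, cui)
    }, character(1))))
  }, integer(1))

  per_group <- do.call(rbind, lapply(groups, function(g) {
    in_g <- vapply(key_groups, function(kg) g %in% kg, logical(1))
    distinct <- sum(in_g)
    ambiguous <- sum(in_g & n_cuis >= 2)
    undefined <- distinct == 0
    percent <- if (undefined) 0 else round_half_up(100 * ambiguous / distinct, 2)
    data.frame(group = g, distinct = distinct, ambiguous = ambiguous,
               percent = percent,
               mesh_linked = sum(in_g & n_cuis >= 2 & mesh_cnt >= 2),
               undefined = undefined, stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL

  mat <- matrix(0L, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (kg in key_groups) {
    present <- intersect(groups, kg)
    for (g1 in present) {
      for (g2 in present) {
        mat[g1, g2] <- mat[g1, g2] + 1L
      }
    }
  }

  structure(list(per_group = per_group, matrix = mat),
            class = "ambiguity_report")
}

#' @export
print.ambiguity_report <- function(x, ...) {
  cat("<ambiguity_report>\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Reference ambiguity counts per semantic group
#'
#' Distinct and ambiguous term-key counts per semantic group from a
#' full-release Metathesaurus ambiguity analysis (2009AB-era, English
#' terms), shipped as reference data. The `mesh` column counts ambiguous
#' terms in the group whose candidate senses are anchored to MeSH main
#' headings. Percent-ambiguous values are recomputed from the counts with
#' [round_half_up()], not stored.
#'
#' @return Data frame `group`, `description`, `distinct`, `ambiguous`,
#'   `mesh`, `percent`.
#' @export
semgroup_ambiguity_counts <- function() {
  path <- system.file("extdata", "semgroup_ambiguity_counts.tsv",
                      package = "wsdbench")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$percent <- round_half_up(100 * tab$ambiguous / tab$distinct, 2)
  tab
}

#' Write an ambiguity report as TSV files
#'
#' Emits the per-group table and the square shared-term matrix.
#'
#' @param report An `ambiguity_report`.
#' @param per_group_path,matrix_path Output TSV paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_ambiguity_report <- function(report, per_group_path, matrix_path) {
  utils::write.table(report$per_group, per_group_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$matrix, matrix_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(per_group_path, matrix_path))
}
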