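# Readers for Metathesaurus-release-style pipe-delimited (RRF) tables and
# the semantic-group mapping, plus the in-memory concept store that the
# ambiguity, retrieval and disambiguation modules consume.
#
# RRF dialect: UTF-8, fields split on "|", optional trailing "|", no quoting
# or escaping. Column counts are fixed per table and enforced per row.

MRCONSO_NCOL <- 18L # CUI LAT TS LUI STT SUI ISPREF AUI SAUI SCUI SDUI SAB TTY CODE STR SRL SUPPRESS CVF
MRDEF_NCOL <- 8L    # CUI AUI ATUI SATUI SAB DEF SUPPRESS CVF
MRREL_NCOL <- 16L   # CUI1 AUI1 STYPE1 REL CUI2 AUI2 STYPE2 RELA RUI SRUI SAB SL RG DIR SUPPRESS CVF
MRSTY_NCOL <- 6L    # CUI TUI STN STY ATUI CVF
SEMGROUPS_NCOL <- 4L # GROUP_ABBREV GROUP_NAME TUI TYPE_NAME

# Parse a pipe-delimited release file into a character matrix with exactly
# `ncol` columns; empty lines are skipped; a row with any other field count
# is an error naming the 1-based line number.
parse_rrf <- function(path, ncol) {
  if (!file.exists(path)) {
    stop("cannot read RRF file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(matrix(character(0), nrow = 0, ncol = ncol))
  }
  npipe <- nchar(lines) - nchar(gsub("|", "", lines, fixed = TRUE))
  bad <- which(npipe != ncol & npipe != ncol - 1L)
  if (length(bad)) {
    stop(sprintf("malformed row in %s at line %d: expected %d fields, found %d",
                 path, idx[bad[1]], ncol, npipe[bad[1]] + 1L), call. = FALSE)
  }
  trailing <- npipe == ncol
  lines[trailing] <- substr(lines[trailing], 1L, nchar(lines[trailing]) - 1L)
  # sentinel preserves empty trailing fields through strsplit
  parts <- strsplit(paste0(lines, "\x01"), "|", fixed = TRUE)
  mat <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
  mat[, ncol] <- sub("\x01$", "", mat[, ncol])
  mat
}

#' Read an MRCONSO-style atom table
#'
#' Reads the release atom table and materializes only rows in the requested
#' language; all other languages are discarded at read time. Row order is
#' preserved.
#'
#' @param path Path to a pipe-delimited MRCONSO file (18 columns, optional
#'   trailing pipe).
#' @param language_filter 3-letter language code to keep (default `"ENG"`).
#' @param keep_suppressed Keep atoms whose SUPPRESS flag is not `"N"`
#'   (default `TRUE`; the release marks some atoms suppressible but the
#'   ambiguity counts here include them unless switched off).
#' @return A data frame of atoms with columns `cui`, `language`,
#'   `term_string`, `source_abbrev`, `term_type`, `aui`, `suppress_flag`.
#' @export
read_mrconso <- function(path, language_filter = "ENG", keep_suppressed = TRUE) {
  mat <- parse_rrf(path, MRCONSO_NCOL)
  atoms <- data.frame(
    cui = mat[, 1], language = mat[, 2], term_string = mat[, 15],
    source_abbrev = mat[, 12], term_type = mat[, 13], aui = mat[, 8],
    suppress_flag = mat[, 17], stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$language == language_filter, , drop = FALSE]
  if (!keep_suppressed) {
    atoms <- atoms[atoms$suppress_flag == "N", , drop = FALSE]
  }
  bad_cui <- !grepl("^C[0-9]+$", atoms$cui)
  if (any(bad_cui)) {
    stop("malformed CUI in MRCONSO: ", atoms$cui[which(bad_cui)[1]], call. = FALSE)
  }
  if (any(!nzchar(atoms$term_string))) {
    stop("empty term string in MRCONSO", call. = FALSE)
  }
  rownames(atoms) <- NULL
  atoms
}

#' Read the auxiliary release tables and the semantic-group mapping
#'
#' Parses MRDEF (definitions), MRREL (relations), MRSTY (semantic types)
#' and the semantic-group file (`group|group name|TUI|type name`). A CUI
#' missing from any table simply contributes an empty component downstream;
#' that is never an error.
#'
#' @param def_path,rel_path,sty_path Paths to MRDEF/MRREL/MRSTY-style files.
#' @param groups_path Path to the semantic-group mapping file.
#' @return A list with data frames `definitions` (`cui`, `source_abbrev`,
#'   `definition`), `relations` (`cui1`, `rel`, `cui2`), `semantic_types`
#'   (`cui`, `tui`, `type_name`) and `groups`
#'   (`group`, `group_name`, `tui`, `type_name`).
#' @export
read_auxiliary_tables <- function(def_path, rel_path, sty_path, groups_path) {
  def <- parse_rrf(def_path, MRDEF_NCOL)
  rel <- parse_rrf(rel_path, MRREL_NCOL)
  sty <- parse_rrf(sty_path, MRSTY_NCOL)
  grp <- parse_rrf(groups_path, SEMGROUPS_NCOL)
  list(
    definitions = data.frame(cui = def[, 1], source_abbrev = def[, 5],
                             definition = def[, 6], stringsAsFactors = FALSE),
    relations = data.frame(cui1 = rel[, 1], rel = rel[, 4], cui2 = rel[, 5],
                           stringsAsFactors = FALSE),
    semantic_types = data.frame(cui = sty[, 1], tui = sty[, 2],
                                type_name = sty[, 4], stringsAsFactors = FALSE),
    groups = data.frame(group = grp[, 1], group_name = grp[, 2], tui = grp[, 3],
                        type_name = grp[, 4], stringsAsFactors = FALSE)
  )
}

#' Normalize a surface string into a term key
#'
#' Lowercases and collapses internal whitespace to single spaces. Punctuation
#' is kept: only case and spacing variants of a string are merged into one
#' ambiguity key. The normalization is idempotent.
#'
#' @param s Character vector of surface strings.
#' @return Character vector of term keys.
#' @export
normalize_term_key <- function(s) {
  tolower(trimws(gsub("[[:space:]]+", " ", s)))
}

#' Build the in-memory concept store
#'
#' Indexes atoms under case-normalized term keys and attaches per-CUI
#' definitions, synonyms, relations, semantic types and semantic groups
#' (derived through the group mapping).
#'
#' @param atoms Data frame from [read_mrconso()].
#' @param aux Optional list from [read_auxiliary_tables()].
#' @return An object of class `concept_store` with elements `atoms`,
#'   `term_index` (named list: term key -> sorted CUI vector), `concepts`
#'   (named list per CUI: `definitions`, `synonyms`, `relations`,
#'   `semantic_types`, `semantic_groups`) and `groups` (the mapping table,
#'   possibly empty).
#' @export
build_concept_store <- function(atoms, aux = NULL) {
  keys <- normalize_term_key(atoms$term_string)
  term_index <- lapply(split(atoms$cui, keys), function(x) sort(unique(x)))
  cuis <- sort(unique(atoms$cui))

  groups <- if (is.null(aux)) {
    data.frame(group = character(0), group_name = character(0),
               tui = character(0), type_name = character(0))
  } else {
    aux$groups
  }
  tui2group <- stats::setNames(groups$group, groups$tui)

  defs_by <- if (is.null(aux)) NULL else split(seq_len(nrow(aux$definitions)), aux$definitions$cui)
  rels_by <- if (is.null(aux)) NULL else split(seq_len(nrow(aux$relations)), aux$relations$cui1)
  stys_by <- if (is.null(aux)) NULL else split(seq_len(nrow(aux$semantic_types)), aux$semantic_types$cui)
  syns_by <- split(atoms$term_string, atoms$cui)

  concepts <- lapply(cuis, function(cui) {
    d <- if (!is.null(defs_by) && !is.null(defs_by[[cui]])) {
      aux$definitions[defs_by[[cui]], c("source_abbrev", "definition"), drop = FALSE]
    } else {
      data.frame(source_abbrev = character(0), definition = character(0))
    }
    rownames(d) <- NULL
    r <- if (!is.null(rels_by) && !is.null(rels_by[[cui]])) {
      aux$relations[rels_by[[cui]], c("cui2", "rel"), drop = FALSE]
    } else {
      data.frame(cui2 = character(0), rel = character(0))
    }
    rownames(r) <- NULL
    s <- if (!is.null(stys_by) && !is.null(stys_by[[cui]])) {
      aux$semantic_types[stys_by[[cui]], c("tui", "type_name"), drop = FALSE]
    } else {
      data.frame(tui = character(0), type_name = character(0))
    }
    rownames(s) <- NULL
    sg <- unique(tui2group[s$tui])
    sg <- sg[!is.na(sg)]
    list(
      definitions = d,
      synonyms = unique(syns_by[[cui]]),
      relations = r,
      semantic_types = s,
      semantic_groups = unname(sg)
    )
  })
  names(concepts) <- cuis

  structure(
    list(atoms = atoms, term_index = term_index, concepts = concepts,
         groups = groups),
    class = "concept_store"
  )
}

#' @export
print.concept_store <- function(x, ...) {
  cat("<concept_store>\n")
  cat("  atoms:       ", nrow(x$atoms), "\n")
  cat("  concepts:    ", length(x$concepts), "\n")
  cat("  term keys:   ", length(x$term_index), "\n")
  cat("  ambiguous:   ", sum(lengths(x$term_index) >= 2), "\n")
  invisible(x)
}

# First synonym string of a cui, used as its preferred rendering.
preferred_string <- function(store, cui) {
  con <- store$concepts[[cui]]
  if (is.null(con) || length(con$synonyms) == 0) {
    return(character(0))
  }
  con$synonyms[[1]]
}

#' Write atoms back to MRCONSO-style rows
#'
#' Inverse of [read_mrconso()] for the columns the package carries; the
#' remaining release columns are emitted empty. Round-tripping the atoms of
#' a store through this writer and [read_mrconso()] reproduces the same
#' term index.
#'
#' @param atoms Data frame of atoms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrconso <- function(atoms, path) {
  fields <- matrix("", nrow = nrow(atoms), ncol = MRCONSO_NCOL)
  fields[, 1] <- atoms$cui
  fields[, 2] <- atoms$language
  fields[, 8] <- atoms$aui
  fields[, 12] <- atoms$source_abbrev
  fields[, 13] <- atoms$term_type
  fields[, 15] <- atoms$term_string
  fields[, 17] <- atoms$suppress_flag
  writeLines(paste0(apply(fields, 1, paste, collapse = "|"), "|"), path, useBytes = TRUE)
  invisible(path)
}

#' Dump a store's term index as TSV (debugging aid)
#'
#' @param store A `concept_store`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_term_index <- function(store, path) {
  lines <- vapply(names(store$term_index), function(k) {
    paste(k, paste(store$term_index[[k]], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("term_key\tcuis", lines), path, useBytes = TRUE)
  invisible(path)
}
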