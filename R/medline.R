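# Reader/writer for the MEDLINE flat citation format: records carry
# "PMID- ", "TI  - ", "AB  - " and "MH  - " tagged lines, continuation
# lines are indented six spaces, and records are separated by blank lines.

#' Construct a citation record
#'
#' @param pmid Digit string identifying the citation.
#' @param title,abstract Citation text fields.
#' @param mesh_headings Character vector of MeSH heading strings. Major
#'   topic markers (leading `*`) and subheadings (`/qualifier`) are stripped
#'   so only the descriptor part is stored.
#' @return A list of class `citation`.
#' @export
medline_citation <- function(pmid, title = "", abstract = "", mesh_headings = character(0)) {
  stopifnot(grepl("^[0-9]+$", pmid))
  structure(
    list(pmid = pmid, title = title, abstract = abstract,
         mesh_headings = normalize_mesh_heading(mesh_headings)),
    class = "citation"
  )
}

#' Strip major-topic markers and subheadings from MeSH heading strings
#'
#' @param headings Character vector, e.g. `"*Lens Diseases/genetics"`.
#' @return Descriptor-only heading strings (`"Lens Diseases"`).
#' @export
normalize_mesh_heading <- function(headings) {
  sub("/.*$", "", sub("^\\*", "", headings))
}

#' Read a MEDLINE-format citation file
#'
#' @param path Path to a MEDLINE flat-format file.
#' @return A list of `citation` records, in file order. PMIDs must be
#'   unique within the file.
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read MEDLINE file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list()
  fields <- list()
  tag <- NULL
  flush_field <- NULL
  current <- NULL

  start_record <- function() list(pmid = NULL, title = "", abstract = "", mh = character(0))
  commit <- function(rec) {
    if (is.null(rec$pmid)) {
      stop("MEDLINE record without PMID in ", path, call. = FALSE)
    }
    medline_citation(rec$pmid, rec$title, rec$abstract, rec$mh)
  }

  current <- start_record()
  seen_any <- FALSE
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (seen_any) {
        records[[length(records) + 1]] <- commit(current)
        current <- start_record()
        seen_any <- FALSE
      }
      next
    }
    if (grepl("^ {6}", ln)) {
      # continuation of the previous field
      cont <- sub("^ {6}", "", ln)
      if (is.null(tag)) {
        stop("continuation line without a field in ", path, call. = FALSE)
      }
      if (tag == "TI") current$title <- paste(current$title, cont)
      if (tag == "AB") current$abstract <- paste(current$abstract, cont)
      if (tag == "MH") {
        current$mh[length(current$mh)] <- paste(current$mh[length(current$mh)], cont)
      }
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]+) *- (.*)$", ln))[[1]]
    if (length(m) != 3) {
      stop("unparseable MEDLINE line in ", path, ": ", ln, call. = FALSE)
    }
    tag <- m[2]
    value <- m[3]
    seen_any <- TRUE
    if (tag == "PMID") current$pmid <- value
    if (tag == "TI") current$title <- value
    if (tag == "AB") current$abstract <- value
    if (tag == "MH") current$mh <- c(current$mh, value)
  }
  if (seen_any) {
    records[[length(records) + 1]] <- commit(current)
  }
  pmids <- vapply(records, `[[`, character(1), "pmid")
  if (anyDuplicated(pmids)) {
    stop("duplicate PMID in ", path, ": ", pmids[duplicated(pmids)][1], call. = FALSE)
  }
  records
}

#' Write citations in MEDLINE flat format
#'
#' Inverse of [read_medline()] for the fields the package carries.
#'
#' @param citations List of `citation` records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(citations, path) {
  blocks <- vapply(citations, function(ct) {
    lines <- c(
      paste0("PMID- ", ct$pmid),
      paste0("TI  - ", ct$title)
    )
    if (nzchar(ct$abstract)) {
      lines <- c(lines, paste0("AB  - ", ct$abstract))
    }
    lines <- c(lines, vapply(ct$mesh_headings, function(h) paste0("MH  - ", h),
                             character(1)))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
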