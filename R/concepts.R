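#' @title Multilingual concept index
#'
#' @description
#' The concept table groups synonymous disease terms across languages under a
#' concept unique identifier (CUI), the way the UMLS MRCONSO table does, and
#' carries the MeSH descriptor linkage used to match trials and articles.
#' The on-disk dialect is pipe-delimited UTF-8 with the six columns
#' `CUI|LAT|SAB|CODE|STR|ISPREF` and no header; `LAT` is one of
#' ENG/SPA/FRE/GER/ITA, `CODE` is the MeSH descriptor id (may be empty) and
#' `ISPREF` is `Y`/`N`.
#'
#' @name concept_index
NULL

.LANGUAGES <- c("ENG", "SPA", "FRE", "GER", "ITA")

#' Load a multilingual concept table
#'
#' Builds a [concept_index] from a pipe-delimited stream. Duplicate rows are
#' collapsed; `(cui, term, language)` triples must be unique afterwards and
#' every CUI must carry at least one English record.
#'
#' @param source file path or connection to the pipe-delimited table.
#' @return an object of class `concept_index`.
#' @export
load_concept_table <- function(source) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.new_concept_index(.empty_concept_records()))
  parts <- strsplit(lines, "|", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L)) {
    bad <- which(nfield != 6L)[1L]
    stop(sprintf("parse error: row %d has %d fields, expected 6 (CUI|LAT|SAB|CODE|STR|ISPREF)",
                 bad, nfield[bad]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  rec <- data.frame(cui = m[, 1L], language = m[, 2L], source = m[, 3L],
                    mesh_descriptor = m[, 4L], term = m[, 5L],
                    preferred = m[, 6L] == "Y", stringsAsFactors = FALSE)
  bad_lang <- which(!rec$language %in% .LANGUAGES)
  if (length(bad_lang)) {
    stop(sprintf("validation error: row %d has unknown language code '%s'",
                 bad_lang[1L], rec$language[bad_lang[1L]]), call. = FALSE)
  }
  bad_cui <- which(!is_cui(rec$cui))
  if (length(bad_cui)) {
    stop(sprintf("validation error: row %d has malformed CUI '%s'",
                 bad_cui[1L], rec$cui[bad_cui[1L]]), call. = FALSE)
  }
  rec$mesh_descriptor[!nzchar(rec$mesh_descriptor)] <- NA_character_
  rec <- unique(rec)
  key <- paste(rec$cui, rec$term, rec$language, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  no_eng <- setdiff(rec$cui, rec$cui[rec$language == "ENG"])
  if (length(no_eng)) {
    stop("validation error: CUI(s) without an ENG record: ",
         paste(sort(no_eng), collapse = ", "), call. = FALSE)
  }
  .new_concept_index(rec)
}

.empty_concept_records <- function() {
  data.frame(cui = character(), language = character(), source = character(),
             mesh_descriptor = character(), term = character(),
             preferred = logical(), stringsAsFactors = FALSE)
}

.new_concept_index <- function(rec) {
  rec$norm <- normalize_term(rec$term)
  rec <- rec[order(rec$norm, rec$cui, rec$language, rec$term,
                   method = "radix"), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec), class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat(sprintf("<concept_index> %d records, %d concepts, languages: %s\n",
              nrow(x$records), length(unique(x$records$cui)),
              paste(sort(unique(x$records$language)), collapse = ", ")))
  invisible(x)
}

#' Resolve a surface term to concept identifiers
#'
#' Matching is exact on normalized surface forms (case-, accent- and
#' whitespace-insensitive), so `"HEART   ATTACK"`, `"heart attack"` and a
#' German or Spanish synonym sharing the CUI all resolve identically.
#'
#' @param index a [concept_index].
#' @param term surface string; must be non-empty after normalization.
#' @return character vector of CUIs in ascending order (usually length 1;
#'   empty when the term is absent from the table).
#' @export
resolve_term <- function(index, term) {
  stopifnot(inherits(index, "concept_index"))
  if (length(term) != 1L) stop("resolve_term takes a single term", call. = FALSE)
  nt <- normalize_term(term)
  if (is.na(nt) || !nzchar(nt)) {
    stop("argument error: term is empty after normalization", call. = FALSE)
  }
  sort(unique(index$records$cui[index$records$norm == nt]))
}

#' Expand a concept to its records
#'
#' Returns all rows of the concept — its cross-language synonyms and the MeSH
#' descriptor linkage — optionally restricted to a language set. An unknown
#' CUI yields an empty set, not an error.
#'
#' @param index a [concept_index].
#' @param cui syntactically valid concept identifier.
#' @param languages optional character subset of ENG/SPA/FRE/GER/ITA.
#' @return data frame of concept records (columns `cui`, `language`,
#'   `source`, `mesh_descriptor`, `term`, `preferred`).
#' @export
expand_cui <- function(index, cui, languages = NULL) {
  stopifnot(inherits(index, "concept_index"))
  if (length(cui) != 1L || !is_cui(cui)) {
    stop("argument error: malformed CUI: ", cui, call. = FALSE)
  }
  rec <- index$records[index$records$cui == cui, , drop = FALSE]
  if (!is.null(languages)) {
    rec <- rec[rec$language %in% languages, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec[, c("cui", "language", "source", "mesh_descriptor", "term", "preferred")]
}

#' Autosuggest concept terms by prefix
#'
#' Returns every indexed term whose normalized form starts with the
#' normalized prefix, ranked preferred-first, then by term length, then
#' lexicographically, and truncated to `limit`. The prefix must be at least
#' two characters after normalization.
#'
#' @param index a [concept_index].
#' @param prefix query prefix (>= 2 characters after normalization).
#' @param language optional single language restriction.
#' @param limit maximum number of suggestions (>= 1).
#' @return data frame with columns `term`, `language`, `cui`,
#'   `mesh_descriptor`, `preferred`.
#' @export
suggest_terms <- function(index, prefix, language = NULL, limit = 10L) {
  stopifnot(inherits(index, "concept_index"))
  np <- normalize_term(prefix)
  if (is.na(np) || nchar(np) < 2L) {
    stop("argument error: prefix must be at least 2 characters after normalization",
         call. = FALSE)
  }
  if (!is.numeric(limit) || limit < 1L) {
    stop("argument error: limit must be >= 1", call. = FALSE)
  }
  rec <- index$records
  hit <- rec[startsWith(rec$norm, np), , drop = FALSE]
  if (!is.null(language)) hit <- hit[hit$language %in% language, , drop = FALSE]
  ord <- order(!hit$preferred, nchar(hit$term), hit$term, method = "radix")
  hit <- hit[ord, , drop = FALSE][seq_len(min(nrow(hit), limit)), , drop = FALSE]
  rownames(hit) <- NULL
  hit[, c("term", "language", "cui", "mesh_descriptor", "preferred")]
}
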