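#' Normalize a surface term for matching
#'
#' Canonical text normalization used everywhere a free-text surface form is
#' compared: concept terms, city and facility names, affiliation phrases.
#' The transform is: transliterate to Latin and strip diacritics
#' (so "ataque al corazón" and "ataque al corazon" coincide), casefold,
#' collapse internal whitespace runs to a single space, and trim. The
#' transform is idempotent.
#'
#' @param x character vector.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_term("  Ataque al  CORAZÓN ")
#' @export
normalize_term <- function(x) {
  if (length(x) == 0L) return(character())
  x <- stringi::stri_trans_general(x, "Any-Latin; Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# id patterns shared across modules
.NCT_PATTERN <- "^NCT[0-9]{8}$"
.PMID_PATTERN <- "^[0-9]+$"
.CUI_PATTERN <- "^C[0-9]{7}$"

is_nct_id <- function(x) grepl(.NCT_PATTERN, x)
is_pmid <- function(x) grepl(.PMID_PATTERN, x)
is_cui <- function(x) grepl(.CUI_PATTERN, x)

#' Build a study reference string
#'
#' Studies are referenced throughout the network layer as compact strings,
#' \code{"TRIAL:NCT00000001"} or \code{"ARTICLE:5000001"}.
#'
#' @param kind `"TRIAL"` or `"ARTICLE"`.
#' @param id the NCT identifier or PMID.
#' @return a character scalar reference.
#' @export
study_ref <- function(kind = c("TRIAL", "ARTICLE"), id) {
  kind <- match.arg(kind)
  id <- as.character(id)
  ok <- if (kind == "TRIAL") is_nct_id(id) else is_pmid(id)
  if (!all(ok)) {
    stop("invalid ", kind, " identifier(s): ", paste(id[!ok], collapse = ", "),
         call. = FALSE)
  }
  paste0(kind, ":", id)
}
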