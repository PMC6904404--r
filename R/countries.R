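# Country evidence table: ISO 3166-1 alpha-2 code, English short name, and
# common alternate spellings. Used when the geocoding cascade needs to decide
# whether an affiliation phrase (or a trial facility's country field) names a
# country. Codes cover the gazetteer fixtures and the usual trial-registry
# countries; unknown codes still work as raw alpha-2 evidence.

.COUNTRY_TABLE <- local({
  raw <- c(
    "US", "United States", "United States of America|USA",
    "GB", "United Kingdom", "UK|Great Britain|England|Scotland|Wales",
    "DE", "Germany", "Deutschland",
    "FR", "France", "",
    "ES", "Spain", "Espana|España",
    "IT", "Italy", "Italia",
    "AU", "Australia", "",
    "AT", "Austria", "Osterreich|Österreich",
    "CH", "Switzerland", "Schweiz|Suisse",
    "NL", "Netherlands", "The Netherlands|Holland",
    "BE", "Belgium", "",
    "CA", "Canada", "",
    "JP", "Japan", "",
    "CN", "China", "",
    "BR", "Brazil", "Brasil",
    "SE", "Sweden", "",
    "NO", "Norway", "",
    "DK", "Denmark", "",
    "FI", "Finland", "",
    "PL", "Poland", "Polska",
    "PT", "Portugal", "",
    "IE", "Ireland", "",
    "GR", "Greece", "",
    "CZ", "Czechia", "Czech Republic",
    "HU", "Hungary", "",
    "IN", "India", "",
    "KR", "South Korea", "Korea, Republic of|Republic of Korea",
    "MX", "Mexico", "México",
    "AR", "Argentina", "",
    "ZA", "South Africa", ""
  )
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  data.frame(code = m[, 1L], name = m[, 2L], alt = m[, 3L],
             stringsAsFactors = FALSE)
})

# Map of normalized country surface form -> ISO alpha-2 code, built lazily
# on first use (normalize_term lives in a file collated later).
.country_cache <- new.env(parent = emptyenv())

.country_lookup_env <- function() {
  env <- get0("lookup", envir = .country_cache)
  if (!is.null(env)) return(env)
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(.COUNTRY_TABLE))) {
    code <- .COUNTRY_TABLE$code[i]
    forms <- c(.COUNTRY_TABLE$name[i],
               strsplit(.COUNTRY_TABLE$alt[i], "|", fixed = TRUE)[[1L]])
    forms <- forms[nzchar(forms)]
    for (f in normalize_term(forms)) assign(f, code, envir = env)
  }
  assign("lookup", env, envir = .country_cache)
  env
}

#' Resolve a country surface form to an ISO 3166-1 alpha-2 code
#'
#' Accepts an alpha-2 code (any case), an English country name, or a common
#' alternate spelling. Returns `NA` when the string is not recognized as a
#' country — which the geocoding cascade treats as "no country evidence".
#'
#' @param x character vector of candidate country strings.
#' @return character vector of alpha-2 codes, `NA` where unrecognized.
#' @export
country_to_iso <- function(x) {
  out <- rep(NA_character_, length(x))
  if (length(x) == 0L) return(out)
  x <- trimws(as.character(x))
  lookup <- .country_lookup_env()
  for (i in which(!is.na(x) & nzchar(x))) {
    hit <- mget(normalize_term(x[i]), envir = lookup,
                ifnotfound = NA_character_)[[1L]]
    if (is.na(hit) && grepl("^[A-Za-z]{2}$", x[i])) hit <- toupper(x[i])
    out[i] <- hit
  }
  out
}

#' English short name for an ISO alpha-2 country code
#'
#' @param code character vector of alpha-2 codes.
#' @return English names; the code itself when no name is on record.
#' @export
iso_to_country_name <- function(code) {
  idx <- match(toupper(code), .COUNTRY_TABLE$code)
  ifelse(is.na(idx), toupper(code), .COUNTRY_TABLE$name[idx])
}
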