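#' @title Gazetteer-based offline geocoding
#'
#' @description
#' Facilities and unstructured author affiliations are resolved to WGS84
#' points against a gazetteer in the geonames `allCountries` column subset:
#' UTF-8 tab-separated, no header, columns
#' `geonameid, name, asciiname, alternatenames (comma-joined), latitude,
#' longitude, country_code, population`. Every name, ASCII name and alternate
#' name is indexed under [normalize_term()].
#'
#' Affiliation strings go through a descending-priority cascade:
#' \enumerate{
#'   \item \strong{FACILITY} — a phrase exactly matches (after normalization)
#'     a facility name already known from the trial corpus; that facility's
#'     city is geocoded.
#'   \item \strong{CITY_COUNTRY} — a phrase matches a gazetteer city while
#'     another phrase in the same affiliation names that entry's country
#'     (ISO alpha-2 code, English name, or a common alternate spelling).
#'   \item \strong{CITY_POPULATION} — a phrase matches one or more gazetteer
#'     cities with no country evidence; the most populous candidate wins,
#'     ties broken by ascending gazetteer id.
#' }
#' Unresolvable input yields method \code{NONE}, never an error.
#'
#' @name geocoding
NULL

#' Load a gazetteer
#'
#' @param source path or connection to the tab-separated gazetteer.
#' @return an object of class `gazetteer`.
#' @export
load_gazetteer <- function(source) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (!n) {
    entries <- data.frame(entry_id = integer(), name = character(),
                          ascii_name = character(), country = character(),
                          population = numeric(), lat = numeric(),
                          lon = numeric(), stringsAsFactors = FALSE)
    entries$alternate_names <- list()
    return(.new_gazetteer(entries))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 8L)) {
    bad <- which(nfield != 8L)[1L]
    stop(sprintf("parse error: gazetteer row %d has %d fields, expected 8",
                 bad, nfield[bad]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  lat <- as.numeric(m[, 5L])
  lon <- as.numeric(m[, 6L])
  bad <- which(is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
                 lon < -180 | lon > 180)
  if (length(bad)) {
    stop(sprintf("validation error: gazetteer row %d has out-of-bounds coordinates (%s, %s)",
                 bad[1L], m[bad[1L], 5L], m[bad[1L], 6L]), call. = FALSE)
  }
  entries <- data.frame(entry_id = as.integer(m[, 1L]), name = m[, 2L],
                        ascii_name = m[, 3L], country = toupper(m[, 7L]),
                        population = as.numeric(m[, 8L]),
                        lat = lat, lon = lon, stringsAsFactors = FALSE)
  if (anyDuplicated(entries$entry_id)) {
    stop("validation error: duplicate gazetteer entry ids", call. = FALSE)
  }
  if (any(is.na(entries$population) | entries$population < 0)) {
    stop("validation error: negative or missing population", call. = FALSE)
  }
  entries$alternate_names <- lapply(m[, 4L], function(s) {
    alts <- strsplit(s, ",", fixed = TRUE)[[1L]]
    trimws(alts[nzchar(trimws(alts))])
  })
  .new_gazetteer(entries)
}

.new_gazetteer <- function(entries) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    forms <- unique(normalize_term(c(entries$name[i], entries$ascii_name[i],
                                     entries$alternate_names[[i]])))
    forms <- forms[!is.na(forms) & nzchar(forms)]
    for (f in forms) {
      assign(f, c(get0(f, envir = idx, ifnotfound = integer()), i), envir = idx)
    }
  }
  structure(list(entries = entries, index = idx), class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer> %d places, %d countries\n", nrow(x$entries),
              length(unique(x$entries$country))))
  invisible(x)
}

# Rows of gazetteer entries whose indexed surface forms include `name`.
gazetteer_lookup <- function(gazetteer, name) {
  key <- normalize_term(name)
  if (is.na(key) || !nzchar(key)) {
    return(gazetteer$entries[0L, , drop = FALSE])
  }
  i <- get0(key, envir = gazetteer$index, ifnotfound = integer())
  gazetteer$entries[i, , drop = FALSE]
}

# Deterministic pick among candidate entries: maximal population, ties broken
# by ascending entry_id.
.pick_most_populous <- function(entries) {
  top <- entries[entries$population == max(entries$population), , drop = FALSE]
  top[order(top$entry_id)[1L], , drop = FALSE]
}

geocode_result <- function(method = "NONE", entry = NULL,
                           matched_city = NA_character_) {
  point <- if (is.null(entry)) NULL else c(lat = entry$lat, lon = entry$lon)
  structure(list(point = point, matched_entry = entry, method = method,
                 matched_city = matched_city), class = "geocode_result")
}

#' @export
print.geocode_result <- function(x, ...) {
  if (x$method == "NONE") {
    cat("<geocode_result> unresolved (method NONE)\n")
  } else {
    cat(sprintf("<geocode_result> %s -> %s, %s (%.4f, %.4f)\n", x$method,
                x$matched_entry$name, x$matched_entry$country,
                x$point[["lat"]], x$point[["lon"]]))
  }
  invisible(x)
}

# City lookup shared by facility and affiliation geocoding: city+country if
# country evidence resolves, else most-populous fallback.
.geocode_city <- function(gazetteer, city, country = NULL) {
  cand <- gazetteer_lookup(gazetteer, city)
  if (!nrow(cand)) return(geocode_result("NONE"))
  iso <- if (is.null(country) || is.na(country) || !nzchar(country)) {
    NA_character_
  } else {
    country_to_iso(country)
  }
  if (!is.na(iso)) {
    in_country <- cand[cand$country == iso, , drop = FALSE]
    if (nrow(in_country)) {
      e <- .pick_most_populous(in_country)
      return(geocode_result("CITY_COUNTRY", e, matched_city = e$name))
    }
  }
  e <- .pick_most_populous(cand)
  geocode_result("CITY_POPULATION", e, matched_city = e$name)
}

#' Geocode a trial facility
#'
#' The facility's city is looked up with its country first; when the country
#' is absent or unmatched, the most populous gazetteer city of that name is
#' used. A city absent from the gazetteer yields method `NONE`.
#'
#' @param fac a [facility()].
#' @param gazetteer a [load_gazetteer()] result.
#' @return a `geocode_result` with fields `point` (named lat/lon vector or
#'   `NULL`), `matched_entry`, `method`
#'   (`FACILITY`/`CITY_COUNTRY`/`CITY_POPULATION`/`NONE`) and `matched_city`.
#' @export
geocode_facility <- function(fac, gazetteer) {
  validate_facility(fac)
  if (!nzchar(fac$city)) return(geocode_result("NONE"))
  .geocode_city(gazetteer, fac$city, fac$country)
}

#' Build a facility-name index from a trial corpus
#'
#' Maps each normalized facility name seen in the trial corpus to its
#' (city, country, zip) record. One facility name maps to one city record;
#' on collision the first-ingested record wins and a warning is raised.
#'
#' @param trials list of [trial()] objects.
#' @return an object of class `facility_index`.
#' @export
build_facility_index <- function(trials) {
  env <- new.env(parent = emptyenv())
  for (t in trials) {
    for (f in t$facilities) {
      if (!nzchar(f$name) || !nzchar(f$city)) next
      key <- normalize_term(f$name)
      old <- get0(key, envir = env)
      rec <- list(name = f$name, city = f$city, country = f$country,
                  zip = f$zip)
      if (is.null(old)) {
        assign(key, rec, envir = env)
      } else if (!identical(normalize_term(old$city), normalize_term(f$city))) {
        warning(sprintf("facility name collision: '%s' maps to both '%s' and '%s'; keeping the first",
                        f$name, old$city, f$city), call. = FALSE)
      }
    }
  }
  structure(list(map = env), class = "facility_index")
}

#' @export
print.facility_index <- function(x, ...) {
  cat(sprintf("<facility_index> %d facility names\n", length(ls(x$map))))
  invisible(x)
}

facility_index_lookup <- function(index, name) {
  key <- normalize_term(name)
  if (is.na(key) || !nzchar(key)) return(NULL)
  get0(key, envir = index$map)
}

# Split an affiliation into candidate phrases on commas/semicolons; drop
# trailing postal-code-like tokens (tokens containing a digit) from each
# phrase before city matching, "Leeds LS184AB" -> "Leeds".
.affiliation_phrases <- function(text) {
  if (is.null(text) || is.na(text)) return(character())
  ph <- trimws(strsplit(text, "[,;]")[[1L]])
  ph[nzchar(ph)]
}

.strip_postal_tokens <- function(phrase) {
  toks <- strsplit(trimws(phrase), "\\s+")[[1L]]
  while (length(toks) && grepl("[0-9]", toks[length(toks)])) {
    toks <- toks[-length(toks)]
  }
  paste(toks, collapse = " ")
}

#' Geocode an unstructured affiliation string
#'
#' Applies the descending-priority cascade documented in [geocoding]:
#' known facility name, then city with country evidence, then most populous
#' matching city. Empty or unresolvable text yields method `NONE`.
#'
#' @param text raw affiliation string (may be `NA` or empty).
#' @param gazetteer a [load_gazetteer()] result.
#' @param facilities optional [build_facility_index()] result; when absent,
#'   the facility priority is skipped.
#' @return a `geocode_result`; see [geocode_facility()].
#' @export
geocode_affiliation <- function(text, gazetteer, facilities = NULL) {
  phrases <- .affiliation_phrases(text)
  if (!length(phrases)) return(geocode_result("NONE"))
  stripped <- vapply(phrases, .strip_postal_tokens, character(1),
                     USE.NAMES = FALSE)

  # Priority 1: facility name known from the trial corpus.
  if (!is.null(facilities)) {
    for (p in phrases) {
      rec <- facility_index_lookup(facilities, p)
      if (!is.null(rec)) {
        r <- .geocode_city(gazetteer, rec$city, rec$country)
        if (r$method != "NONE") {
          return(geocode_result("FACILITY", r$matched_entry,
                                matched_city = rec$city))
        }
      }
    }
  }

  # Country evidence carried by any phrase (codes, names, alternates).
  iso_by_phrase <- country_to_iso(stripped)

  # Priority 2: city phrase + country evidence in another phrase; first city
  # phrase in reading order wins.
  for (i in seq_along(stripped)) {
    if (!nzchar(stripped[i])) next
    cand <- gazetteer_lookup(gazetteer, stripped[i])
    if (!nrow(cand)) next
    evidence <- unique(stats::na.omit(iso_by_phrase[-i]))
    hit <- cand[cand$country %in% evidence, , drop = FALSE]
    if (nrow(hit)) {
      e <- .pick_most_populous(hit)
      return(geocode_result("CITY_COUNTRY", e, matched_city = e$name))
    }
  }

  # Priority 3: any matching city, most populous wins.
  all_idx <- integer()
  for (s in unique(stripped[nzchar(stripped)])) {
    key <- normalize_term(s)
    all_idx <- c(all_idx, get0(key, envir = gazetteer$index,
                               ifnotfound = integer()))
  }
  if (length(all_idx)) {
    cand <- gazetteer$entries[unique(all_idx), , drop = FALSE]
    e <- .pick_most_populous(cand)
    return(geocode_result("CITY_POPULATION", e, matched_city = e$name))
  }
  geocode_result("NONE")
}
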