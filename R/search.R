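#' @title Concept- and geography-filtered study search
#'
#' @description
#' The end-to-end query pipeline: match trials and articles against queried
#' concepts (via all cross-language synonyms plus MeSH descriptor equality),
#' apply time-range filters, build and merge the research networks with
#' NCT/PMID deduplication, and restrict the result to a great-circle
#' perimeter around a centre point.
#'
#' @name study_search
NULL

#' Mean Earth radius (km) used for great-circle distances
#'
#' @format A single number, 6371.0088 km (IUGG mean Earth radius).
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points, in kilometres
#'
#' Haversine distance on a sphere of radius [EARTH_RADIUS_KM]. Symmetric,
#' zero exactly for identical coordinates, and bounded by
#' `pi * EARTH_RADIUS_KM` (attained at antipodes).
#'
#' @param a,b points as `c(lat, lon)` vectors in decimal degrees WGS84, or
#'   two-column matrices (lat, lon) of equal height.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2L)
  b <- matrix(as.numeric(b), ncol = 2L)
  .check_points(a)
  .check_points(b)
  # geosphere expects (lon, lat); radius in km yields km.
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = EARTH_RADIUS_KM)
}

.check_points <- function(m) {
  if (any(!is.finite(m)) || any(m[, 1L] < -90 | m[, 1L] > 90) ||
        any(m[, 2L] < -180 | m[, 2L] > 180)) {
    stop("argument error: invalid coordinates", call. = FALSE)
  }
}

#' Restrict site nodes to a great-circle perimeter
#'
#' Keeps exactly the nodes within `radius_km` (inclusive boundary) of the
#' centre, the "studies within a given distance" query.
#'
#' @param nodes a node data frame (see [research_network]).
#' @param center `c(lat, lon)` centre point.
#' @param radius_km positive radius in km.
#' @return the surviving subset of `nodes`.
#' @export
filter_within_radius <- function(nodes, center, radius_km) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop("argument error: radius_km must be a positive number", call. = FALSE)
  }
  if (!nrow(nodes)) return(nodes)
  d <- haversine_km(cbind(nodes$lat, nodes$lon),
                    matrix(center, nrow = nrow(nodes), ncol = 2L,
                           byrow = TRUE))
  nodes[d <= radius_km, , drop = FALSE]
}

#' Construct a search query
#'
#' @param cuis non-empty character vector of concept identifiers.
#' @param logic `"ANY"` (default; at least one queried concept matches) or
#'   `"ALL"` (every queried concept matches).
#' @param center optional `c(lat, lon)` centre for the perimeter filter.
#' @param radius_km optional positive radius; requires `center`.
#' @param date_from,date_to optional `Date` bounds (inclusive);
#'   `date_from <= date_to` when both given.
#' @param include_articles include PubMed-style articles in the result
#'   network (default `TRUE`).
#' @return an object of class `search_query`.
#' @export
search_query <- function(cuis, logic = c("ANY", "ALL"), center = NULL,
                         radius_km = NULL, date_from = NULL, date_to = NULL,
                         include_articles = TRUE) {
  logic <- match.arg(logic)
  if (!length(cuis) || !all(is_cui(cuis))) {
    stop("argument error: cuis must be a non-empty vector of valid CUIs",
         call. = FALSE)
  }
  if (!is.null(radius_km)) {
    if (is.null(center)) {
      stop("argument error: radius_km requires a center", call. = FALSE)
    }
    if (!is.numeric(radius_km) || radius_km <= 0) {
      stop("argument error: radius_km must be positive", call. = FALSE)
    }
  }
  if (!is.null(center)) .check_points(matrix(as.numeric(center), ncol = 2L))
  if (!is.null(date_from)) date_from <- as.Date(date_from)
  if (!is.null(date_to)) date_to <- as.Date(date_to)
  if (!is.null(date_from) && !is.null(date_to) && date_from > date_to) {
    stop("argument error: date_from after date_to", call. = FALSE)
  }
  structure(list(cuis = unique(cuis), logic = logic, center = center,
                 radius_km = radius_km, date_from = date_from,
                 date_to = date_to, include_articles = include_articles),
            class = "search_query")
}

#' Does a record match the queried concepts?
#'
#' A record matches concept `c` iff any of its condition terms (trials) or
#' MeSH terms (articles) normalizes to one of `c`'s surface forms in any
#' language, or equals `c`'s MeSH descriptor id. `logic` combines multiple
#' queried concepts: `"ANY"` requires at least one match, `"ALL"` requires
#' every concept to match.
#'
#' @param record a [trial()] or [article()].
#' @param cuis character vector of queried concept ids.
#' @param index a [load_concept_table()] result.
#' @param logic `"ANY"` or `"ALL"`.
#' @return logical scalar.
#' @export
match_condition <- function(record, cuis, index, logic = c("ANY", "ALL")) {
  logic <- match.arg(logic)
  if (!length(cuis)) stop("argument error: cuis must be non-empty",
                          call. = FALSE)
  terms <- if (inherits(record, "trial")) record$condition_terms else
    record$mesh_terms
  nt <- normalize_term(terms)
  per_cui <- vapply(cuis, function(cui) {
    rec <- expand_cui(index, cui)
    if (!nrow(rec)) return(FALSE)
    forms <- normalize_term(rec$term)
    desc <- stats::na.omit(unique(rec$mesh_descriptor))
    any(nt %in% forms) ||
      (length(desc) && any(nt %in% normalize_term(desc)))
  }, logical(1))
  if (logic == "ANY") any(per_cui) else all(per_cui)
}

#' Filter records by a time range
#'
#' Trials are kept when their start date lies in `[date_from, date_to]`,
#' articles when their publication date does; either bound may be absent
#' (one-sided range). Records lacking the relevant date are kept only when
#' no bound is set; under an active range they are excluded and counted in
#' the `excluded_undated` attribute of the result.
#'
#' @param records list of [trial()] or [article()] objects.
#' @param date_from,date_to optional inclusive `Date` bounds.
#' @return the surviving sublist, with attribute `excluded_undated`.
#' @export
filter_by_dates <- function(records, date_from = NULL, date_to = NULL) {
  if (!is.null(date_from) && !is.null(date_to) &&
        as.Date(date_from) > as.Date(date_to)) {
    stop("argument error: date_from after date_to", call. = FALSE)
  }
  if (is.null(date_from) && is.null(date_to)) {
    attr(records, "excluded_undated") <- 0L
    return(records)
  }
  lo <- if (is.null(date_from)) as.Date("0001-01-01") else as.Date(date_from)
  hi <- if (is.null(date_to)) as.Date("9999-12-31") else as.Date(date_to)
  d <- do.call(c, lapply(records, function(r) {
    if (inherits(r, "trial")) r$start_date else r$pub_date
  }))
  if (is.null(d)) d <- as.Date(character())
  keep <- !is.na(d) & d >= lo & d <= hi
  out <- records[keep]
  attr(out, "excluded_undated") <- sum(is.na(d))
  out
}

#' Run the full search pipeline
#'
#' Concept matching, date filtering, network construction (articles only
#' when `include_articles`), NCT/PMID-deduplicated merge, and perimeter
#' restriction. When a radius is set, nodes outside it are dropped and
#' edges with a removed endpoint are pruned.
#'
#' @param query a [search_query()].
#' @param trials,articles the loaded corpora.
#' @param index a [load_concept_table()] result.
#' @param gazetteer a [load_gazetteer()] result.
#' @param facilities optional [build_facility_index()]; defaults to an
#'   index over `trials`.
#' @return list with elements `network` (a `research_network`) and `report`
#'   (matched/geocoded/excluded counts plus the per-site coverage table).
#' @export
run_search <- function(query, trials, articles = list(), index, gazetteer,
                       facilities = NULL) {
  stopifnot(inherits(query, "search_query"))
  if (is.null(facilities)) facilities <- build_facility_index(trials)

  mt <- trials[vapply(trials, match_condition, logical(1), cuis = query$cuis,
                      index = index, logic = query$logic)]
  ma <- if (query$include_articles) {
    articles[vapply(articles, match_condition, logical(1), cuis = query$cuis,
                    index = index, logic = query$logic)]
  } else {
    list()
  }

  mt <- filter_by_dates(mt, query$date_from, query$date_to)
  ma <- filter_by_dates(ma, query$date_from, query$date_to)
  undated <- attr(mt, "excluded_undated") + attr(ma, "excluded_undated")

  net <- merge_networks(build_trial_network(mt, gazetteer),
                        build_article_network(ma, gazetteer, facilities),
                        articles = ma)

  dropped <- 0L
  if (!is.null(query$radius_km)) {
    kept <- filter_within_radius(net$nodes, query$center, query$radius_km)
    dropped <- nrow(net$nodes) - nrow(kept)
    keep_e <- net$edges$from %in% kept$node_key &
      net$edges$to %in% kept$node_key
    net <- research_network(kept, net$edges[keep_e, , drop = FALSE],
                            coverage = coverage_report(net))
  }

  cov <- coverage_report(net)
  unresolved <- if (is.null(cov)) 0L else sum(cov$method == "NONE")
  report <- list(trials_matched = length(mt), articles_matched = length(ma),
                 undated_excluded = undated,
                 sites_geocoded = if (is.null(cov)) 0L else
                   sum(cov$method != "NONE"),
                 sites_unresolved = unresolved,
                 nodes_dropped_by_radius = dropped, coverage = cov)
  list(network = net, report = report)
}
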