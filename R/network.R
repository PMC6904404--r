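#' @title Geolocated research networks
#'
#' @description
#' A research network is an undirected graph whose nodes are geocoded study
#' sites and whose edges denote co-participation of two sites in one study.
#' Node identity is the normalized (city, country) pair — two facilities in
#' the same city share a node, with facility/affiliation display names kept
#' as node labels. Every study induces a clique: all pairs of the study's
#' distinct sites are joined by an edge listing that study in its supports.
#' Edges are unweighted; multiplicity is derivable as the support count.
#'
#' Internally a `research_network` is a list of two data frames:
#' `nodes` (`node_key`, `lat`, `lon`, list columns `labels` and `studies`)
#' and `edges` (`from`, `to` with `from < to`, list column `supports`).
#' A `coverage` attribute records per-site geocoding outcomes so that
#' unresolvable sites are reported, never dropped silently.
#'
#' @name research_network
NULL

# Node key for a matched gazetteer entry: normalized city name + country.
location_key <- function(entry) {
  paste0(normalize_term(entry$name), "|", entry$country)
}

.empty_nodes <- function() {
  df <- data.frame(node_key = character(), lat = numeric(), lon = numeric(),
                   stringsAsFactors = FALSE)
  df$labels <- list()
  df$studies <- list()
  df
}

.empty_edges <- function() {
  df <- data.frame(from = character(), to = character(),
                   stringsAsFactors = FALSE)
  df$supports <- list()
  df
}

#' Construct a research network
#'
#' Low-level constructor; checks the structural invariants (edge endpoints
#' exist, no self-loops, non-empty supports and studies, coordinate bounds).
#' Most users build networks with [build_trial_network()],
#' [build_article_network()] or [run_search()].
#'
#' @param nodes node data frame (see [research_network]).
#' @param edges edge data frame.
#' @param coverage optional per-site geocoding report data frame.
#' @return an object of class `research_network`.
#' @export
research_network <- function(nodes = .empty_nodes(), edges = .empty_edges(),
                             coverage = NULL) {
  nodes <- nodes[order(nodes$node_key, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
  }
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "research_network")
  attr(net, "coverage") <- coverage
  validate_network(net)
  net
}

validate_network <- function(net, check_cliques = FALSE) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$node_key)) {
    stop("network invariant violated: duplicate node keys", call. = FALSE)
  }
  if (nrow(nodes)) {
    if (any(nodes$lat < -90 | nodes$lat > 90 |
              nodes$lon < -180 | nodes$lon > 180)) {
      stop("network invariant violated: node coordinates out of bounds",
           call. = FALSE)
    }
    if (any(lengths(nodes$studies) == 0L)) {
      stop("network invariant violated: node with empty study set",
           call. = FALSE)
    }
  }
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) {
      stop("network invariant violated: self-loop", call. = FALSE)
    }
    if (any(lengths(edges$supports) == 0L)) {
      stop("network invariant violated: edge with empty supports",
           call. = FALSE)
    }
    if (!all(c(edges$from, edges$to) %in% nodes$node_key)) {
      stop("network invariant violated: edge endpoint not in node set",
           call. = FALSE)
    }
  }
  if (check_cliques) {
    for (ref in network_study_refs(net)) {
      sub <- subnetwork_for_study(net, ref)
      k <- nrow(sub$nodes)
      if (nrow(sub$edges) != k * (k - 1L) / 2L) {
        stop("network invariant violated: study ", ref,
             " does not induce a complete subgraph", call. = FALSE)
      }
    }
  }
  invisible(net)
}

#' @export
print.research_network <- function(x, ...) {
  cat(sprintf("<research_network> %d nodes, %d edges, %d studies\n",
              nrow(x$nodes), nrow(x$edges), length(network_study_refs(x))))
  invisible(x)
}

#' Study references present in a network
#'
#' @param net a `research_network`.
#' @return sorted character vector of study reference strings.
#' @export
network_study_refs <- function(net) {
  sort(unique(unlist(net$nodes$studies, use.names = FALSE)))
}

#' Per-site geocoding coverage report of a network
#'
#' @param net a `research_network` produced by a builder.
#' @return data frame with one row per geocoded site (`ref`, `site`,
#'   `method`, `node_key`), or `NULL` when the network carries no report.
#' @export
coverage_report <- function(net) {
  attr(net, "coverage")
}

# Core assembler: `site_tables` is a named list mapping study ref ->
# data.frame(node_key, lat, lon, label). Builds the clique-union network.
.assemble_network <- function(site_tables, coverage = NULL) {
  all_sites <- do.call(rbind, c(site_tables, list(.empty_site_table())))
  if (!nrow(all_sites)) {
    return(research_network(coverage = coverage))
  }
  keys <- unique(all_sites$node_key)
  first <- all_sites[!duplicated(all_sites$node_key), , drop = FALSE]
  nodes <- data.frame(node_key = first$node_key, lat = first$lat,
                      lon = first$lon, stringsAsFactors = FALSE)
  nodes$labels <- lapply(keys, function(k) {
    sort(unique(all_sites$label[all_sites$node_key == k]))
  })
  nodes$studies <- lapply(keys, function(k) {
    sort(unique(all_sites$ref[all_sites$node_key == k]))
  })

  edge_env <- new.env(parent = emptyenv())
  for (ref in names(site_tables)) {
    ks <- sort(unique(site_tables[[ref]]$node_key))
    if (length(ks) < 2L) next
    pairs <- utils::combn(ks, 2L)
    for (j in seq_len(ncol(pairs))) {
      ek <- paste(pairs[1L, j], pairs[2L, j], sep = "\r")
      assign(ek, c(get0(ek, envir = edge_env, ifnotfound = character()), ref),
             envir = edge_env)
    }
  }
  eks <- ls(edge_env)
  if (length(eks)) {
    em <- do.call(rbind, strsplit(eks, "\r", fixed = TRUE))
    edges <- data.frame(from = em[, 1L], to = em[, 2L],
                        stringsAsFactors = FALSE)
    edges$supports <- lapply(eks, function(k) {
      sort(unique(get(k, envir = edge_env)))
    })
  } else {
    edges <- .empty_edges()
  }
  research_network(nodes, edges, coverage = coverage)
}

.empty_site_table <- function() {
  data.frame(ref = character(), node_key = character(), lat = numeric(),
             lon = numeric(), label = character(), stringsAsFactors = FALSE)
}

.site_row <- function(ref, result, label) {
  e <- result$matched_entry
  data.frame(ref = ref, node_key = location_key(e), lat = e$lat, lon = e$lon,
             label = label, stringsAsFactors = FALSE)
}

#' Build a research network from trials
#'
#' Each trial's facilities are geocoded with [geocode_facility()]; facilities
#' resolving to the same (city, country) collapse into one node and every
#' pair of the trial's distinct nodes receives an edge supported by that
#' trial. Geocoding failures accumulate in the coverage report (see
#' [coverage_report()]).
#'
#' @param trials list of [trial()] objects.
#' @param gazetteer a [load_gazetteer()] result.
#' @return a `research_network`.
#' @export
build_trial_network <- function(trials, gazetteer) {
  site_tables <- list()
  cov <- list()
  for (t in trials) {
    ref <- study_ref("TRIAL", t$nct_id)
    rows <- list()
    for (f in t$facilities) {
      r <- geocode_facility(f, gazetteer)
      site <- if (nzchar(f$name)) f$name else f$city
      key <- if (r$method == "NONE") NA_character_ else
        location_key(r$matched_entry)
      cov[[length(cov) + 1L]] <- data.frame(
        ref = ref, site = site, method = r$method, node_key = key,
        stringsAsFactors = FALSE)
      if (r$method == "NONE") next
      rows[[length(rows) + 1L]] <- .site_row(ref, r, site)
    }
    if (length(rows)) site_tables[[ref]] <- do.call(rbind, rows)
  }
  .assemble_network(site_tables, coverage = .bind_coverage(cov))
}

#' Build a research network from articles
#'
#' For each article, the affiliation strings of its lead authors (first two
#' and last two) are geocoded through the cascade in
#' [geocode_affiliation()]; distinct resolved locations form a per-article
#' clique exactly as trial sites do.
#'
#' @param articles list of [article()] objects.
#' @param gazetteer a [load_gazetteer()] result.
#' @param facilities optional [build_facility_index()] result enabling the
#'   facility priority of the cascade.
#' @return a `research_network`.
#' @export
build_article_network <- function(articles, gazetteer, facilities = NULL) {
  site_tables <- list()
  cov <- list()
  for (a in articles) {
    ref <- study_ref("ARTICLE", a$pmid)
    rows <- list()
    for (au in lead_authors(a)) {
      if (is.na(au$affiliation_text) || !nzchar(au$affiliation_text)) next
      r <- geocode_affiliation(au$affiliation_text, gazetteer, facilities)
      key <- if (r$method == "NONE") NA_character_ else
        location_key(r$matched_entry)
      cov[[length(cov) + 1L]] <- data.frame(
        ref = ref, site = au$affiliation_text, method = r$method,
        node_key = key, stringsAsFactors = FALSE)
      if (r$method == "NONE") next
      label <- .affiliation_phrases(au$affiliation_text)[1L]
      rows[[length(rows) + 1L]] <- .site_row(ref, r, label)
    }
    if (length(rows)) site_tables[[ref]] <- do.call(rbind, rows)
  }
  .assemble_network(site_tables, coverage = .bind_coverage(cov))
}

.bind_coverage <- function(cov) {
  if (!length(cov)) return(NULL)
  do.call(rbind, cov)
}

#' Merge two research networks with identifier deduplication
#'
#' Nodes are unified on their (city, country) key — labels and study sets
#' are unioned, edge supports are unioned. Any article (from `articles`)
#' whose `linked_nct_ids` intersect the merged network's trial references
#' contributes no additional study reference: its nodes and edges are
#' re-attributed to the linked trial reference(s), so a publication of a
#' registered trial is never double-counted. The operation is symmetric in
#' its two network arguments and idempotent.
#'
#' @param net_a,net_b `research_network` objects.
#' @param articles list of [article()] objects consulted for NCT/PMID
#'   linkage (typically the articles `net_b` was built from).
#' @return the merged `research_network`.
#' @export
merge_networks <- function(net_a, net_b, articles = list()) {
  nodes <- rbind(net_a$nodes, net_b$nodes)
  edges <- rbind(net_a$edges, net_b$edges)

  keys <- unique(nodes$node_key)
  first <- nodes[!duplicated(nodes$node_key), , drop = FALSE]
  merged_nodes <- data.frame(node_key = first$node_key, lat = first$lat,
                             lon = first$lon, stringsAsFactors = FALSE)
  merged_nodes$labels <- lapply(keys, function(k) {
    sort(unique(unlist(nodes$labels[nodes$node_key == k], use.names = FALSE)))
  })
  merged_nodes$studies <- lapply(keys, function(k) {
    sort(unique(unlist(nodes$studies[nodes$node_key == k], use.names = FALSE)))
  })

  if (nrow(edges)) {
    ek <- paste(edges$from, edges$to, sep = "\r")
    uek <- unique(ek)
    efirst <- edges[!duplicated(ek), , drop = FALSE]
    merged_edges <- data.frame(from = efirst$from, to = efirst$to,
                               stringsAsFactors = FALSE)
    merged_edges$supports <- lapply(uek, function(k) {
      sort(unique(unlist(edges$supports[ek == k], use.names = FALSE)))
    })
  } else {
    merged_edges <- .empty_edges()
  }

  # NCT/PMID dedup: relabel article refs whose linked trials are present.
  trial_refs <- grep("^TRIAL:", unique(unlist(merged_nodes$studies,
                                              use.names = FALSE)),
                     value = TRUE)
  relabel <- list()
  for (a in articles) {
    if (!length(a$linked_nct_ids)) next
    linked <- intersect(paste0("TRIAL:", a$linked_nct_ids), trial_refs)
    if (length(linked)) relabel[[paste0("ARTICLE:", a$pmid)]] <- linked
  }
  if (length(relabel)) {
    remap <- function(refs) {
      sort(unique(unlist(lapply(refs, function(r) {
        if (!is.null(relabel[[r]])) relabel[[r]] else r
      }), use.names = FALSE)))
    }
    merged_nodes$studies <- lapply(merged_nodes$studies, remap)
    merged_edges$supports <- lapply(merged_edges$supports, remap)
  }

  cov <- rbind(coverage_report(net_a), coverage_report(net_b))
  research_network(merged_nodes, merged_edges, coverage = cov)
}

#' Subnetwork induced by one study
#'
#' Returns the induced graph on the nodes containing the reference; by the
#' clique construction it is a complete graph on those nodes. An unknown
#' reference yields an empty network.
#'
#' @param net a `research_network`.
#' @param ref a study reference string (see [study_ref()]).
#' @return a `research_network`.
#' @export
subnetwork_for_study <- function(net, ref) {
  keep_n <- vapply(net$nodes$studies, function(s) ref %in% s, logical(1))
  keep_e <- vapply(net$edges$supports, function(s) ref %in% s, logical(1))
  research_network(net$nodes[keep_n, , drop = FALSE],
                   net$edges[keep_e, , drop = FALSE])
}

#' Build the network for directly entered study identifiers
#'
#' Renders the research network for explicitly named trials and articles —
#' the programmatic equivalent of entering NCT-IDs and PMIDs directly.
#' Identifiers absent from the corpora are reported in the `missing_ids`
#' attribute, not raised as errors; malformed identifiers are argument
#' errors.
#'
#' @param nct_ids character vector of NCT identifiers (may be empty).
#' @param pmids character vector of PMIDs (may be empty).
#' @param trials,articles the loaded corpora.
#' @param gazetteer a [load_gazetteer()] result.
#' @param facilities optional [build_facility_index()] result; defaults to
#'   an index built from `trials`.
#' @return a `research_network`; `attr(net, "missing_ids")` lists requested
#'   identifiers that were not found.
#' @export
network_from_ids <- function(nct_ids = character(), pmids = character(),
                             trials = list(), articles = list(),
                             gazetteer, facilities = NULL) {
  if (length(nct_ids) && !all(is_nct_id(nct_ids))) {
    stop("argument error: malformed NCT id(s): ",
         paste(nct_ids[!is_nct_id(nct_ids)], collapse = ", "), call. = FALSE)
  }
  if (length(pmids) && !all(is_pmid(pmids))) {
    stop("argument error: malformed PMID(s): ",
         paste(pmids[!is_pmid(pmids)], collapse = ", "), call. = FALSE)
  }
  if (is.null(facilities)) facilities <- build_facility_index(trials)
  have_t <- vapply(trials, function(t) t$nct_id, character(1))
  have_a <- vapply(articles, function(a) a$pmid, character(1))
  missing <- c(setdiff(nct_ids, have_t), setdiff(pmids, have_a))
  sel_t <- trials[have_t %in% nct_ids]
  sel_a <- articles[have_a %in% pmids]
  net <- merge_networks(build_trial_network(sel_t, gazetteer),
                        build_article_network(sel_a, gazetteer, facilities),
                        articles = sel_a)
  attr(net, "missing_ids") <- missing
  net
}
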