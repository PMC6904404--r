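# Exporters for downstream mapping and graph tooling. GeoJSON carries nodes
# as Point features ([lon, lat] per the GeoJSON spec) and edges as
# LineString features; GraphML goes through igraph with lat/lon/label/studies
# vertex attributes and a supports edge attribute. Both are deterministic:
# identical networks produce byte-identical files.

#' Export a research network as GeoJSON
#'
#' @param net a `research_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(net, path) {
  node_features <- lapply(seq_len(nrow(net$nodes)), function(i) {
    n <- net$nodes[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(n$lon, n$lat)),
         properties = list(node_key = n$node_key,
                           labels = as.list(n$labels[[1L]]),
                           studies = as.list(n$studies[[1L]])))
  })
  key_row <- match(net$edges$from, net$nodes$node_key)
  key_row2 <- match(net$edges$to, net$nodes$node_key)
  edge_features <- lapply(seq_len(nrow(net$edges)), function(i) {
    a <- net$nodes[key_row[i], ]
    b <- net$nodes[key_row2[i], ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(a$lon, a$lat), c(b$lon, b$lat))),
         properties = list(from = net$edges$from[i], to = net$edges$to[i],
                           supports = as.list(net$edges$supports[[i]])))
  })
  fc <- list(type = "FeatureCollection",
             features = c(node_features, edge_features))
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GeoJSON export back into node/edge tables
#'
#' Utility for validation and round-trip testing of [export_geojson()]
#' output.
#'
#' @param path a GeoJSON file written by [export_geojson()].
#' @return list with `nodes` and `edges` data frames.
#' @export
read_geojson_network <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  pts <- Filter(function(f) f$geometry$type == "Point", fc$features)
  lns <- Filter(function(f) f$geometry$type == "LineString", fc$features)
  nodes <- data.frame(
    node_key = vapply(pts, function(f) f$properties$node_key, character(1)),
    lat = vapply(pts, function(f) as.numeric(f$geometry$coordinates[[2L]]),
                 numeric(1)),
    lon = vapply(pts, function(f) as.numeric(f$geometry$coordinates[[1L]]),
                 numeric(1)),
    stringsAsFactors = FALSE)
  nodes$labels <- lapply(pts, function(f)
    unlist(f$properties$labels, use.names = FALSE))
  nodes$studies <- lapply(pts, function(f)
    unlist(f$properties$studies, use.names = FALSE))
  edges <- data.frame(
    from = vapply(lns, function(f) f$properties$from, character(1)),
    to = vapply(lns, function(f) f$properties$to, character(1)),
    stringsAsFactors = FALSE)
  edges$supports <- lapply(lns, function(f)
    unlist(f$properties$supports, use.names = FALSE))
  list(nodes = nodes, edges = edges)
}

#' Convert a research network to an igraph graph
#'
#' Vertices carry `lat`, `lon`, `label` and `studies` attributes (the list
#' attributes joined with `"; "`); edges carry a joined `supports`
#' attribute.
#'
#' @param net a `research_network`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  v <- data.frame(name = net$nodes$node_key, lat = net$nodes$lat,
                  lon = net$nodes$lon,
                  label = vapply(net$nodes$labels, paste, character(1),
                                 collapse = "; "),
                  studies = vapply(net$nodes$studies, paste, character(1),
                                   collapse = "; "),
                  stringsAsFactors = FALSE)
  e <- data.frame(from = net$edges$from, to = net$edges$to,
                  supports = vapply(net$edges$supports, paste, character(1),
                                    collapse = "; "),
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Export a research network as GraphML
#'
#' @param net a `research_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
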