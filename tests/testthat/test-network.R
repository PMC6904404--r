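test_that("one trial across k cities yields a k-clique; one city yields none", {
  ws <- example_ws()
  net <- build_trial_network(ws$trials[1L], ws$gazetteer)
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 3L)  # triangle
  expect_true(all(vapply(net$edges$supports, identical, logical(1),
                         "TRIAL:NCT01000001")))
  one_city <- trial("NCT00000009", facilities = list(
    facility("A Clinic", "Berlin", country = "Germany"),
    facility("B Clinic", "Berlin", country = "DE")))
  net1 <- build_trial_network(list(one_city), ws$gazetteer)
  expect_identical(nrow(net1$nodes), 1L)  # same city collapses
  expect_identical(nrow(net1$edges), 0L)
  expect_setequal(net1$nodes$labels[[1L]], c("A Clinic", "B Clinic"))
})

test_that("shared cities union their studies and edges across trials", {
  ws <- example_ws()
  extra <- trial("NCT00000010", condition_terms = "Hemophilia B",
                 facilities = list(
                   facility("X", "Berlin", country = "DE"),
                   facility("Y", "Leeds", country = "GB")))
  net <- build_trial_network(c(ws$trials, list(extra)), ws$gazetteer)
  berlin <- net$nodes$studies[[match("berlin|DE", net$nodes$node_key)]]
  expect_true(all(c("TRIAL:NCT01000001", "TRIAL:NCT00000010") %in% berlin))
  # edge count equals the union of the per-trial cliques (brute force)
  refs <- network_study_refs(net)
  want <- unique(unlist(lapply(refs, function(r) {
    ks <- csort(net$nodes$node_key[vapply(net$nodes$studies,
                                          function(s) r %in% s, logical(1))])
    if (length(ks) < 2L) return(character())
    apply(utils::combn(ks, 2L), 2L, paste, collapse = "|")
  })))
  expect_setequal(paste(net$edges$from, net$edges$to, sep = "|"), want)
})

test_that("article networks are cliques over lead-author locations", {
  ws <- example_ws()
  net <- build_article_network(ws$articles[1L], ws$gazetteer,
                               ws$facility_index)
  # 6 authors; leads 1,2,5,6 -> Leeds, Münster, Paris, Berlin
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 6L)
  single <- article("777", mesh_terms = "x", authors = list(
    author("A", 1L, "Dept, Berlin, Germany"),
    author("B", 2L, "Unit, Berlin, Germany")))
  net1 <- build_article_network(list(single), ws$gazetteer)
  expect_identical(nrow(net1$nodes), 1L)
  expect_identical(nrow(net1$edges), 0L)
})

test_that("unresolvable sites are reported, not silently dropped", {
  t <- trial("NCT00000011", facilities = list(
    facility("K", "Berlin", country = "DE"),
    facility("L", "Atlantis")))
  net <- build_trial_network(list(t), example_ws()$gazetteer)
  cov <- coverage_report(net)
  expect_identical(nrow(cov), 2L)
  expect_identical(cov$method[cov$site == "L"], "NONE")
  expect_identical(nrow(net$nodes), 1L)
})

test_that("merging removes article/trial duplicates via NCT linkage", {
  ws <- example_ws()
  tn <- build_trial_network(ws$trials, ws$gazetteer)
  an <- build_article_network(ws$articles, ws$gazetteer, ws$facility_index)
  m <- merge_networks(tn, an, ws$articles)
  refs <- network_study_refs(m)
  # the linked article is attributed to its trial, not double-counted
  expect_false("ARTICLE:6000002" %in% refs)
  expect_true("TRIAL:NCT01000001" %in% refs)
  expect_true("ARTICLE:6000001" %in% refs)  # unlinked article stays
  # merge with an empty network is the identity
  m0 <- merge_networks(tn, research_network())
  expect_identical(network_signature(m0), network_signature(tn))
})

test_that("merge is idempotent and commutative on seeded corpora", {
  for (seed in c(3L, 17L)) {
    sc <- small_corpus(seed)
    ws <- sc$ws
    tn <- build_trial_network(ws$trials, ws$gazetteer)
    an <- build_article_network(ws$articles, ws$gazetteer, ws$facility_index)
    ab <- merge_networks(tn, an, ws$articles)
    ba <- merge_networks(an, tn, ws$articles)
    expect_identical(network_signature(ab), network_signature(ba))
    self <- merge_networks(ab, ab, ws$articles)
    expect_identical(network_signature(self), network_signature(ab))
  }
})

test_that("per-study subnetworks equal brute-force filtering and are complete", {
  sc <- standard_corpus()
  ws <- sc$ws
  tn <- build_trial_network(ws$trials, ws$gazetteer)
  an <- build_article_network(ws$articles, ws$gazetteer, ws$facility_index)
  m <- merge_networks(tn, an, ws$articles)
  set.seed(8L)
  for (ref in sample(network_study_refs(m), 25L)) {
    sub <- subnetwork_for_study(m, ref)
    keep_n <- vapply(m$nodes$studies, function(s) ref %in% s, logical(1))
    keep_e <- vapply(m$edges$supports, function(s) ref %in% s, logical(1))
    expect_identical(sub$nodes$node_key, m$nodes$node_key[keep_n])
    expect_identical(paste(sub$edges$from, sub$edges$to),
                     paste(m$edges$from[keep_e], m$edges$to[keep_e]))
    k <- nrow(sub$nodes)
    expect_identical(nrow(sub$edges), as.integer(k * (k - 1L) / 2L))
  }
  empty <- subnetwork_for_study(m, "TRIAL:NCT99999998")
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("edge supports are contained in both endpoints' study sets", {
  sc <- small_corpus(23L)
  ws <- sc$ws
  m <- merge_networks(build_trial_network(ws$trials, ws$gazetteer),
                      build_article_network(ws$articles, ws$gazetteer,
                                            ws$facility_index),
                      ws$articles)
  studies_of <- setNames(m$nodes$studies, m$nodes$node_key)
  for (i in seq_len(nrow(m$edges))) {
    s <- m$edges$supports[[i]]
    expect_true(all(s %in% studies_of[[m$edges$from[i]]]))
    expect_true(all(s %in% studies_of[[m$edges$to[i]]]))
    expect_false(m$edges$from[i] == m$edges$to[i])
  }
})

test_that("direct-identifier networks honour ids, dedup and missing reports", {
  ws <- example_ws()
  net <- network_from_ids("NCT01000001", character(), ws$trials, ws$articles,
                          ws$gazetteer, ws$facility_index)
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 3L)
  # adding the linked publication changes nothing (dedup)
  both <- network_from_ids("NCT01000001", "6000002", ws$trials, ws$articles,
                           ws$gazetteer, ws$facility_index)
  expect_identical(network_signature(both), network_signature(net))
  # unknown id: empty network plus a missing-id report
  miss <- network_from_ids("NCT99999997", character(), ws$trials,
                           ws$articles, ws$gazetteer, ws$facility_index)
  expect_identical(nrow(miss$nodes), 0L)
  expect_identical(attr(miss, "missing_ids"), "NCT99999997")
  expect_error(network_from_ids("NCT1", character(), ws$trials, ws$articles,
                                ws$gazetteer), "argument error")
})

test_that("GeoJSON and GraphML exports re-validate and round-trip", {
  ws <- example_ws()
  net <- merge_networks(build_trial_network(ws$trials, ws$gazetteer),
                        build_article_network(ws$articles, ws$gazetteer,
                                              ws$facility_index),
                        ws$articles)
  gj <- tempfile(fileext = ".geojson")
  export_geojson(net, gj)
  back <- read_geojson_network(gj)
  expect_identical(back$nodes$node_key, net$nodes$node_key)
  expect_equal(back$nodes$lat, net$nodes$lat)
  expect_identical(back$edges$from, net$edges$from)
  expect_identical(back$edges$supports, net$edges$supports)
  # structural GeoJSON schema requirements
  fc <- jsonlite::read_json(gj)
  expect_identical(fc$type, "FeatureCollection")
  for (f in fc$features) {
    expect_identical(f$type, "Feature")
    expect_true(f$geometry$type %in% c("Point", "LineString"))
  }
  gm <- tempfile(fileext = ".graphml")
  export_graphml(net, gm)
  # well-formed XML in the GraphML namespace, readable by igraph
  doc <- xml2::read_xml(gm)
  expect_match(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes), ignore_attr = TRUE)
  expect_equal(igraph::gsize(g), nrow(net$edges), ignore_attr = TRUE)
  expect_setequal(igraph::vertex_attr(g, "name"), net$nodes$node_key)
  # determinism: identical input, identical bytes
  gj2 <- tempfile(); gm2 <- tempfile()
  export_geojson(net, gj2); export_graphml(net, gm2)
  expect_identical(readLines(gj2), readLines(gj))
  expect_identical(readLines(gm2), readLines(gm))
})
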