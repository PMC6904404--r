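test_that("haversine agrees with the spherical law-of-cosines oracle", {
  expect_identical(haversine_km(c(12.3, 45.6), c(12.3, 45.6)), 0)
  expect_equal(haversine_km(c(90, 0), c(-90, 0)), pi * 6371.0088)
  set.seed(5L)
  n <- 10000L
  a <- cbind(runif(n, -89, 89), runif(n, -179, 179))
  b <- cbind(runif(n, -89, 89), runif(n, -179, 179))
  d <- haversine_km(a, b)
  oracle <- vapply(seq_len(n), function(i) slc_km(a[i, ], b[i, ]), numeric(1))
  # relative agreement away from degenerate geometry
  far <- d > 1 & d < 20000
  expect_true(all(abs(d[far] - oracle[far]) / d[far] < 1e-6))
  expect_true(all(d >= 0 & d <= pi * 6371.0088 + 1e-9))
  # symmetry
  expect_equal(haversine_km(b, a), d)
})

test_that("the perimeter filter keeps exactly the nodes within the radius", {
  # sites at oracle-verified distances around a centre
  center <- c(52.52, 13.405)
  near <- c(53.55, 13.60)    # ~115 km
  far <- c(50.11, 8.68)      # ~420 km
  expect_lt(slc_km(center, near), 200)
  expect_gt(slc_km(center, far), 200)
  nodes <- data.frame(node_key = c("near|DE", "far|DE"),
                      lat = c(near[1], far[1]), lon = c(near[2], far[2]),
                      stringsAsFactors = FALSE)
  nodes$labels <- list("a", "b")
  nodes$studies <- list("TRIAL:NCT00000001", "TRIAL:NCT00000001")
  kept <- filter_within_radius(nodes, center, 200)
  expect_identical(kept$node_key, "near|DE")
  # inclusive boundary and degenerate cases
  d_near <- haversine_km(near, center)
  expect_identical(filter_within_radius(nodes, center, d_near)$node_key,
                   "near|DE")
  expect_identical(nrow(filter_within_radius(nodes, center, 20015.1)), 2L)
  expect_identical(filter_within_radius(nodes, near, 1)$node_key, "near|DE")
  expect_error(filter_within_radius(nodes, center, 0), "argument error")
})

test_that("radius filtering equals a brute-force scan on seeded corpora", {
  sc <- standard_corpus()
  ws <- sc$ws
  net <- build_trial_network(ws$trials, ws$gazetteer)
  set.seed(31L)
  for (i in 1:20) {
    center <- c(runif(1, -50, 60), runif(1, -160, 160))
    radius <- runif(1, 200, 8000)
    kept <- filter_within_radius(net$nodes, center, radius)
    want <- net$nodes$node_key[vapply(seq_len(nrow(net$nodes)), function(j) {
      slc_km(c(net$nodes$lat[j], net$nodes$lon[j]), center) <= radius
    }, logical(1))]
    expect_identical(kept$node_key, want)
  }
})

test_that("condition matching is concept-based and honours ANY/ALL logic", {
  ws <- example_ws()
  idx <- ws$concepts
  hem_a <- ws$trials[[1L]]   # condition "Hemophilia A"
  expect_true(match_condition(hem_a, "C1000003", idx))
  expect_false(match_condition(hem_a, "C1000004", idx))
  # cross-language synonym: German MeSH tag matches the same concept
  de_art <- article("55", mesh_terms = "Hämophilie A")
  expect_true(match_condition(de_art, "C1000003", idx))
  # MeSH descriptor equality also matches
  desc_art <- article("56", mesh_terms = "D100003")
  expect_true(match_condition(desc_art, "C1000003", idx))
  # logic table
  two <- c("C1000003", "C1000004")
  expect_true(match_condition(hem_a, two, idx, logic = "ANY"))
  expect_false(match_condition(hem_a, two, idx, logic = "ALL"))
  expect_error(match_condition(hem_a, character(), idx), "argument error")
})

test_that("ALL-logic results are a subset of ANY-logic results", {
  sc <- standard_corpus()
  ws <- sc$ws
  cuis <- c("C2000001", "C2000002")
  any_hit <- vapply(ws$trials, match_condition, logical(1), cuis = cuis,
                    index = ws$concepts, logic = "ANY")
  all_hit <- vapply(ws$trials, match_condition, logical(1), cuis = cuis,
                    index = ws$concepts, logic = "ALL")
  expect_true(all(!all_hit | any_hit))
})

test_that("date filtering keeps in-range records and reports undated ones", {
  t1 <- trial("NCT00000001", start_date = as.Date("2016-05-01"))
  t2 <- trial("NCT00000002", start_date = as.Date("2011-01-01"))
  t3 <- trial("NCT00000003")  # undated
  recs <- list(t1, t2, t3)
  # no bounds: identity
  expect_length(filter_by_dates(recs), 3L)
  kept <- filter_by_dates(recs, as.Date("2014-01-01"), as.Date("2018-09-30"))
  expect_identical(vapply(kept, function(x) x$nct_id, character(1)),
                   "NCT00000001")
  expect_identical(attr(kept, "excluded_undated"), 1L)
  # one-sided bound
  late <- filter_by_dates(recs, date_from = as.Date("2012-01-01"))
  expect_length(late, 1L)
  expect_error(filter_by_dates(recs, as.Date("2018-01-01"),
                               as.Date("2014-01-01")), "argument error")
})

test_that("the full pipeline recovers exactly a planted in-radius network", {
  center <- c(52.52, 13.405)
  inner <- data.frame(
    name = c("Innerani", "Innerbei", "Innercei"), country = c("DE", "DE", "DE"),
    lat = c(52.90, 52.20, 53.00), lon = c(13.40, 14.20, 12.50),
    population = c(50000, 60000, 70000), stringsAsFactors = FALSE)
  outer <- data.frame(
    name = c("Outerani", "Outerbei", "Outercei"), country = c("DE", "AT", "CH"),
    lat = c(48.14, 48.21, 47.38), lon = c(11.58, 16.37, 8.54),
    population = c(80000, 90000, 95000), stringsAsFactors = FALSE)
  for (i in 1:3) {
    expect_lt(slc_km(center, c(inner$lat[i], inner$lon[i])), 200)
    expect_gt(slc_km(center, c(outer$lat[i], outer$lon[i])), 200)
  }
  spec <- small_spec(77L,
                     extra_cities = rbind(inner, outer),
                     planted_networks = list(
                       list(kind = "TRIAL", cui = "C1000003",
                            cities = inner$name),
                       list(kind = "TRIAL", cui = "C1000003",
                            cities = outer$name)))
  dir <- file.path(tempdir(), "studynet-planted")
  truth <- generate_fixtures(spec, dir)
  ws <- load_workspace(truth$paths$trials, truth$paths$articles,
                       truth$paths$gazetteer, truth$paths$concepts)
  # unrestricted: both planted cliques, exactly as planted
  res_all <- run_search(search_query("C1000003"), ws$trials, ws$articles,
                        ws$concepts, ws$gazetteer, ws$facility_index)
  planted <- truth$planted
  expect_length(planted, 2L)
  refs <- network_study_refs(res_all$network)
  expect_setequal(refs, vapply(planted, function(p) p$ref, character(1)))
  for (p in planted) {
    sub <- subnetwork_for_study(res_all$network, p$ref)
    expect_identical(sub$nodes$node_key,
                     csort(unlist(p$node_keys, use.names = FALSE)))
    k <- nrow(sub$nodes)
    expect_identical(nrow(sub$edges), as.integer(k * (k - 1L) / 2L))
  }
  # perimeter: only the inner clique survives a 200 km radius
  res <- run_search(search_query("C1000003", center = center,
                                 radius_km = 200),
                    ws$trials, ws$articles, ws$concepts, ws$gazetteer,
                    ws$facility_index)
  inner_ref <- planted[[1L]]$ref
  expect_identical(network_study_refs(res$network), inner_ref)
  expect_identical(res$network$nodes$node_key,
                   csort(unlist(planted[[1L]]$node_keys, use.names = FALSE)))
  expect_identical(nrow(res$network$edges), 3L)
  expect_identical(res$report$nodes_dropped_by_radius, 3L)
})

test_that("article inclusion and radius behave as declared", {
  ws <- example_ws()
  q_no_art <- search_query("C1000001", include_articles = FALSE)
  res <- run_search(q_no_art, ws$trials, ws$articles, ws$concepts,
                    ws$gazetteer, ws$facility_index)
  expect_false(any(grepl("^ARTICLE:", network_study_refs(res$network))))
  # radius unset: node set equals the unrestricted merged network
  q <- search_query("C1000001")
  res2 <- run_search(q, ws$trials, ws$articles, ws$concepts, ws$gazetteer,
                     ws$facility_index)
  tn <- build_trial_network(
    ws$trials[vapply(ws$trials, match_condition, logical(1),
                     cuis = "C1000001", index = ws$concepts)], ws$gazetteer)
  an <- build_article_network(
    ws$articles[vapply(ws$articles, match_condition, logical(1),
                       cuis = "C1000001", index = ws$concepts)],
    ws$gazetteer, ws$facility_index)
  expect_identical(res2$network$nodes$node_key,
                   merge_networks(tn, an)$nodes$node_key)
})

test_that("enlarging the radius never removes nodes", {
  sc <- standard_corpus()
  ws <- sc$ws
  q <- function(r) search_query("C2000001", center = c(20, 10), radius_km = r)
  prev <- character()
  for (r in c(500, 2000, 8000, 20100)) {
    res <- run_search(q(r), ws$trials, ws$articles, ws$concepts,
                      ws$gazetteer, ws$facility_index)
    expect_true(all(prev %in% res$network$nodes$node_key))
    prev <- res$network$nodes$node_key
  }
})

test_that("search queries validate their arguments", {
  expect_error(search_query(character()), "argument error")
  expect_error(search_query("bogus"), "argument error")
  expect_error(search_query("C1000001", radius_km = 100), "requires a center")
  expect_error(search_query("C1000001", center = c(0, 0), radius_km = -5),
               "positive")
  expect_error(search_query("C1000001", date_from = "2020-01-01",
                            date_to = "2019-01-01"), "argument error")
})
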