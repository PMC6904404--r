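# Shared fixtures: generated once per test run, cached in an environment.
.cache <- new.env(parent = emptyenv())

# bundled worked-example workspace
example_ws <- function() {
  if (is.null(.cache$ws)) .cache$ws <- bundled_fixture()
  .cache$ws
}

# standard seeded corpus at the default study conditions (200/200)
standard_corpus <- function() {
  if (is.null(.cache$std)) {
    dir <- file.path(tempdir(), "studynet-std")
    truth <- generate_fixtures(fixture_spec(seed = 20260101), dir)
    ws <- load_workspace(truth$paths$trials, truth$paths$articles,
                         truth$paths$gazetteer, truth$paths$concepts)
    .cache$std <- list(truth = truth, ws = ws)
  }
  .cache$std
}

# small corpus for cheap repeated builds
small_spec <- function(seed, ...) {
  fixture_spec(seed = seed, n_trials = 15L, n_articles = 15L, n_cities = 40L,
               n_ambiguous_city_names = 6L, n_concepts = 8L, ...)
}

small_corpus <- function(seed, ...) {
  dir <- file.path(tempdir(), paste0("studynet-s", seed))
  truth <- generate_fixtures(small_spec(seed, ...), dir)
  ws <- load_workspace(truth$paths$trials, truth$paths$articles,
                       truth$paths$gazetteer, truth$paths$concepts)
  list(truth = truth, ws = ws)
}

# radix sort so comparisons are locale-independent
csort <- function(x) sort(x, method = "radix")

# canonical comparable form of a network: node keys with study sets,
# edge keys with support sets
network_signature <- function(net) {
  list(nodes = setNames(lapply(net$nodes$studies, csort),
                        net$nodes$node_key),
       edges = setNames(lapply(net$edges$supports, csort),
                        paste(net$edges$from, net$edges$to, sep = " -- ")))
}

# signature of a ground-truth expected network (as returned in-memory)
truth_signature <- function(truth) {
  list(nodes = lapply(truth$expected_nodes, function(s)
         csort(unlist(s, use.names = FALSE))),
       edges = setNames(
         lapply(truth$expected_edges, function(e)
           csort(unlist(e$supports, use.names = FALSE))),
         vapply(truth$expected_edges, function(e)
           paste(e$from, e$to, sep = " -- "), character(1))))
}

# order-insensitive signature comparison
expect_same_network <- function(net, truth) {
  got <- network_signature(net)
  want <- truth_signature(truth)
  expect_identical(csort(names(got$nodes)), csort(names(want$nodes)))
  expect_identical(got$nodes[csort(names(got$nodes))],
                   want$nodes[csort(names(got$nodes))])
  expect_identical(csort(names(got$edges)), csort(names(want$edges)))
  expect_identical(got$edges[csort(names(got$edges))],
                   want$edges[csort(names(got$edges))])
}

# independent spherical law-of-cosines distance (the second-formula oracle)
slc_km <- function(a, b) {
  rad <- pi / 180
  phi1 <- a[1] * rad; phi2 <- b[1] * rad
  dl <- (b[2] - a[2]) * rad
  x <- sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(dl)
  6371.0088 * acos(pmin(1, pmax(-1, x)))
}

# field-by-field record comparison helpers for round-trip tests
expect_same_trials <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) expect_equal(a[[i]], b[[i]])
}
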