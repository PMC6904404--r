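# studynet

Geospatial research networks from clinical-trial registries and the
biomedical literature — offline, reproducible, and multilingual.

## What problem this solves, and for whom

Trial registries record where studies recruit (facility, city, postal code,
country) but expose no coordinates, so neither patients nor researchers can
ask location questions directly: *which trials of this disease run within
200 km of a given place?* — *which sites have collaborated on similar
research and could anchor a new consortium?* Author affiliations in the
literature hold the same information, but as unstructured strings.

`studynet` is an R toolkit for clinical-research informaticians that ingests
both sources, geocodes every site against a gazetteer, normalizes
multilingual disease terms to shared concept identifiers, and produces
filterable, exportable collaboration graphs. Everything runs offline from
files; a seeded synthetic-corpus generator with planted ground truth makes
the whole pipeline testable without access to any live database.

## The model

A research network is an undirected graph G = (V, E):

* **Nodes** v ∈ V are study sites keyed by normalized (city, country), with
  WGS84 coordinates from the gazetteer; facilities and affiliations in the
  same city share a node.
* **Edges** {u, v} ∈ E record co-participation: every study s induces a
  clique K(s) on its distinct sites, and each edge carries the support set
  supp({u,v}) = { s : u, v ∈ sites(s) }. Edge multiplicity is |supp|.
* **Lead authors** of an article are positions {1, 2, n−1, n} of its author
  list (all authors when n ≤ 4); only their affiliations contribute sites.
* **Deduplication:** an article whose structured accession numbers link it
  to a trial present in the network is re-attributed to that trial's
  reference — publications of registered trials never double-count.

Affiliations are geocoded by a descending-priority cascade: (1) a phrase
exactly matching a facility name known from the trial corpus; (2) a city
phrase with country evidence elsewhere in the string; (3) the most populous
city matching any phrase (ties by ascending gazetteer id). Perimeter queries
use the haversine great-circle distance d(a, b) = 2R·asin√(sin²(Δφ/2) +
cos φ₁ cos φ₂ sin²(Δλ/2)) with R = 6371.0088 km.

Concept matching is CUI-level: a record matches a queried concept when any
of its condition/MeSH terms normalizes to any surface form of that concept
in any of the five supported languages (ENG, SPA, FRE, GER, ITA), or equals
its MeSH descriptor id.

## Worked example

The package ships a small worked-example corpus (`bundled_fixture()`): two
trials, two articles, a seven-city gazetteer and a four-concept multilingual
table.

```r
library(studynet)
ws <- bundled_fixture()

resolve_term(ws$concepts, "Herzinfarkt")
#> [1] "C1000001"
```

"Herzinfarkt", "heart attack" and "ataque al corazón" all resolve to the
same concept, `C1000001` — cross-language entry reaches one disease.

```r
suggest_terms(ws$concepts, "Hemophi")
#>           term language      cui mesh_descriptor preferred
#> 1   Hemophilia      ENG C1000002         D100002      TRUE
#> 2 Hemophilia A      ENG C1000003         D100003      TRUE
#> 3 Hemophilia B      ENG C1000004         D100004      TRUE
```

Autosuggestion by prefix returns the disease and both subtypes, each linked
to its MeSH descriptor.

```r
geocode_affiliation(
  "Institute of Cardiology, University of Leeds, Leeds LS184AB, United Kingdom",
  ws$gazetteer, ws$facility_index)
#> <geocode_result> FACILITY -> Leeds, GB (53.7965, -1.5478)
```

The affiliation resolves by the highest cascade priority — the facility name
is already known from the trial corpus — and lands on Leeds's coordinates.

```r
res <- run_search(search_query("C1000003"), ws$trials, ws$articles,
                  ws$concepts, ws$gazetteer, ws$facility_index)
res$network
#> <research_network> 3 nodes, 3 edges, 1 studies
network_study_refs(res$network)
#> [1] "TRIAL:NCT01000001"
res$network$nodes[, c("node_key", "lat", "lon")]
#>    node_key      lat      lon
#> 1 berlin|DE 52.52437 13.41053
#> 2  milan|IT 45.46427  9.18951
#> 3  paris|FR 48.85341  2.34880
```

Searching for Hemophilia A finds one trial with sites in three cities — a
triangle of collaboration edges — plus one linked publication whose
affiliations were merged into the trial's reference rather than counted as a
second study (`res$report` shows 1 trial and 1 article matched, 6 sites
geocoded, 0 unresolved). `export_geojson()` / `export_graphml()` write the
graph for mapping and network tools.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/studyportal suggest --prefix Hemophi
Rscript inst/cli/studyportal search --trials ... --articles ... \
    --gazetteer ... --concepts ... --terms "Hemophilia A" \
    --lat 52.52 --lon 13.405 --radius-km 200 --geojson out.geojson
```

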