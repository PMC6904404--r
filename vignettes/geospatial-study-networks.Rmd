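---
title: "Geospatial research networks from trial registries and the biomedical literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geospatial research networks from trial registries and the biomedical literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studynet)
```

## The problem

Trial registries record *where* clinical studies recruit — facility names,
cities, postal codes, countries — but not where those places *are*: no
registry exposes coordinates, so questions such as "which studies of this
disease run within 200 km of here?" or "which sites have collaborated on
similar research?" cannot be asked directly. The biomedical literature adds
a second, messier source: author affiliations are free-text strings in which
the location is buried among department names and postal codes.

`studynet` turns both sources into geolocated collaboration graphs. It is an
offline library and command-line tool: all inputs are files in the standard
interchange dialects (registry full-study XML, PubMed citation XML, a
geonames-style gazetteer, an MRCONSO-style concept table), and everything —
including the evaluation corpora — can be produced by the package's own
seeded generator.

## The network model

A **research network** is an undirected graph.

* A **node** is a study site, identified by its normalized (city, country)
  pair. Two facilities in the same city share one node; the facility and
  affiliation display names are retained as node labels. Node identity by
  city rather than facility makes the map view meaningful — one selectable
  marker per city — and makes trial sites and author affiliations
  commensurable.
* An **edge** records that two sites co-participated in one study. Each
  study therefore induces a *clique* (complete subgraph) over its distinct
  sites; an edge's `supports` set lists every study that put sites at both
  endpoints, so edge multiplicity is derivable as `length(supports)` without
  weighting the graph. Studies never create edges across one another:
  connectivity between studies arises only through shared nodes.

Trials contribute sites through their facility lists. Articles contribute
sites through the affiliations of their **lead authors** — the first two and
last two of the author list (all authors when there are four or fewer, since
the two pairs overlap; the result is always `min(4, n)` authors).

**Deduplication.** A published article about a registered trial would
otherwise count the same collaboration twice. Articles carry their trial
linkage as structured data-bank accession numbers (`NCT` pattern); when a
linked trial is present in the merged network, the article's nodes and edges
are re-attributed to the trial's reference and the article contributes no
study reference of its own. The relabelling is applied against the *combined*
network rather than one argument, which makes `merge_networks()` symmetric
in its network arguments and idempotent — properties the test suite checks
on batches of seeded corpora. Only structured accessions are used; free-text
trial-number mentions in abstracts are not mined.

## Geocoding

All geocoding is offline, against a gazetteer loaded from a tab-separated
column subset of the geonames `allCountries` dump (id, name, ASCII name,
alternate names, latitude, longitude, country code, population), so real
geonames extracts load unchanged. Every surface form — name, ASCII name and
each alternate name — is indexed under the package's normalization
(transliterate to Latin, strip diacritics, casefold, collapse whitespace).

Facilities carry a structured city and usually a country: the city is looked
up within the country first (`CITY_COUNTRY`), falling back to the most
populous city of that name when the country is absent or unmatched
(`CITY_POPULATION`).

Unstructured affiliations go through a **descending-priority cascade**:

1. **FACILITY** — a comma/semicolon-delimited phrase exactly matches (after
   normalization) a facility name already known from the trial corpus; the
   facility's own city wins regardless of any other place named in the
   string. Matching is exact, not fuzzy: fuzzy matching would need a
   similarity threshold for which there is no principled value, and a wrong
   facility match is worse than falling through to the city rules. The cost
   is that spelling variants of a known facility fall to priority 2/3; this
   is a documented limitation.
2. **CITY_COUNTRY** — a phrase matches a gazetteer city while *another*
   phrase in the same affiliation names that entry's country (ISO alpha-2
   code, English name, or a common alternate spelling from a built-in
   table). When two different cities both have country evidence, the first
   in reading order wins — affiliation strings conventionally name the host
   institution's city before any secondary address.
3. **CITY_POPULATION** — a phrase matches one or more gazetteer cities with
   no country evidence anywhere in the string; the most populous candidate
   wins. Population is the only disambiguator available offline, and ties
   are broken by ascending gazetteer id so results are reproducible.

Phrases are the comma/semicolon fields of the string, with trailing
digit-bearing tokens stripped before city matching ("Leeds LS184AB" →
"Leeds"). Postal codes are carried through from the trial corpus into the
facility index but are never a matching key. Unresolvable input yields
method `NONE` — never an error — and every builder accumulates a per-site
coverage report (`coverage_report()`) so that information gaps in the
sources are visible rather than silently dropped.

## The concept layer

Disease input is multilingual: the concept table groups surface terms from
five languages (ENG, SPA, FRE, GER, ITA) under concept unique identifiers
(CUIs), each linked to a MeSH descriptor. `resolve_term()` is exact on
normalized surface forms, so "heart attack", "Herzinfarkt", "HEART ATTACK"
and "ataque al corazón" all reach the same concept. A record (trial or
article) matches a queried concept when any of its condition/MeSH terms
normalizes to *any* of the concept's surface forms in any language, or
equals the concept's MeSH descriptor id. Matching against all synonyms
rather than the English preferred term only maximizes recall across
multilingually indexed corpora, which is the point of the semantic layer.

Autosuggestion (`suggest_terms()`) returns indexed terms by normalized
prefix, ranked preferred-first, then by term length, then lexicographically
— a deterministic ordering chosen so tests are stable; relevance-weighted
rankings would need usage data the package does not have. The minimum prefix
is two characters: single-letter prefixes return unusably broad lists.

No ontology reasoning is performed: equivalence is strictly CUI-level, with
no hierarchy traversal. The package ships no licensed vocabulary content;
the bundled table and all generated tables use invented identifiers.

## Search pipeline and its parameters

`run_search()` composes: concept matching (`ANY`/`ALL` over the queried
concepts) → time-range filter → network construction (articles only when
requested) → deduplicating merge → perimeter restriction. Parameters that
matter:

* `logic` — `ANY` is the default: selecting several related conditions
  (e.g. two subtypes of one disease) is naturally disjunctive. `ALL` is the
  stricter conjunctive reading; `ALL` results are always a subset of `ANY`
  results for the same concepts.
* `date_from`/`date_to` (inclusive, either may be absent) — trials are
  filtered on their start date, articles on their publication date. Partial
  dates in the sources ("May 2016", "2016") are floored to the first of the
  month/year so every record is totally ordered. Records *lacking* the
  relevant date are kept only when no bound is active; under an active range
  they are excluded and counted in the report, since their membership is
  undecidable.
* `center` + `radius_km` — great-circle perimeter in kilometres, inclusive
  at the boundary. Distances use the haversine formula on a sphere of mean
  Earth radius 6371.0088 km; city-scale perimeter search does not warrant an
  ellipsoidal geodesic, and a fixed documented constant makes results exact
  and testable (antipodal distance is exactly `pi * 6371.0088` km). The
  filter applies to node locations *after* network construction; an edge
  whose endpoint is removed is pruned even if the other endpoint survives,
  so the rendered graph never references an off-map node. Enlarging the
  radius never removes nodes.

Direct-identifier rendering (`network_from_ids()`) bypasses the concept and
date filters entirely: named NCT ids and PMIDs are built and merged with the
same machinery, and unknown identifiers are reported rather than raised.

## The synthetic-data generator

`generate_fixtures()` emits all four dialects plus a ground-truth sidecar,
as a pure function of `(seed, spec)` — byte-identical files per seed, with
one derived random stream per artifact type so that, e.g., changing the
article count does not perturb the gazetteer. Its defaults are the study
conditions used throughout the test suite: 200 trials, 200 articles, 300
unambiguous cities plus 40 ambiguous city-name groups (2–3 namesakes in
different countries with distinct populations, so the most-populous rule has
a unique well-defined winner), 40 synthetic concepts in five languages
alongside the bundled exemplar synonym groups, and 30% of articles linked to
a generated trial. Thirty percent keeps both branches of the deduplication
logic heavily exercised while leaving a majority of articles as independent
literature; dedicated corpora with `linked_article_fraction = 1` probe the
collapse-onto-trial-topology property directly.

Planted structure drives the strongest tests: collaboration cliques with
known cities (optionally at caller-specified coordinates, so perimeter
queries have exact expected answers), per-affiliation expected geocoding
methods, and a term→concept map. The generator computes its expected network
by direct enumeration over its own bookkeeping — independently of the
network module — so "build + merge recovers the ground truth exactly" is a
genuine two-route check.

Deliberate simplifications, and what they imply: random trials and random
article affiliations use only unambiguous cities (ambiguous names are
exercised through dedicated city-only affiliations), facility names embed
their city name so the facility index is collision-free, and affiliations
follow the conventional "department, institution, city, country" comma
structure. Real affiliation strings are noisier — misspellings, missing
commas, institutions absent from any registry — and real gazetteers contain
namesakes *within* one country, which the (city, country) node key then
conflates. Passing tests therefore demonstrate that the rules are
implemented exactly as specified, not that the rules themselves achieve any
particular accuracy on real-world text. Article cliques are capped at four
cities because affiliations ride on the four lead-author slots. Name
distributions are synthetic syllable draws with no statistical realism;
structure, not realism, is what is planted.

## Numerical and degenerate-input choices

* Normalization is idempotent and is applied on both sides of every match.
* Population ties break by ascending gazetteer id; suggestion ties by the
  documented three-level ranking; node and edge orderings are radix-sorted
  (locale-independent), so identical inputs give byte-identical exports.
* Empty corpora, empty author lists, absent dates, unknown CUIs and unknown
  study references all yield empty results rather than errors; malformed
  identifiers and out-of-contract arguments raise typed errors
  ("argument error", "validation error", "parse error") which the CLI maps
  to exit codes 1 and 2.
* The scales used by the checks — 200 + 200 records for the clique
  invariant, 20 seeded corpora for merge algebra, 1,000 randomized ambiguous
  geocodes, 10,000 random point pairs for the distance oracle — were chosen
  as the package's own standard evaluation conditions and are declared in
  one place (the fixture defaults and the acceptance script).

## Limitations

* Facility matching is exact after normalization; spelling variants of a
  known facility are not recognized as such.
* Node identity is (city, country): distinct namesake cities within one
  country collapse, and metropolitan areas split across municipalities
  appear as separate nodes.
* Concept matching requires the record's term to be a known surface form of
  the concept; out-of-vocabulary synonyms do not match.
* The retrievability of real trials and articles depends on the coverage of
  the upstream registries and of MEDLINE indexing — gaps there surface in
  the coverage report but cannot be repaired offline.
* No relevance ranking, recruitment-status or phase filters, no centrality
  analytics, and no temporal network evolution.

## A worked pass, end to end

```{r worked, eval = FALSE}
ws <- bundled_fixture()

# one concept, three languages
resolve_term(ws$concepts, "Herzinfarkt")
resolve_term(ws$concepts, "ataque al corazón")

# the cascade in action
geocode_affiliation(
  "Institute of Cardiology, University of Leeds, Leeds LS184AB, United Kingdom",
  ws$gazetteer, ws$facility_index)

# search, with deduplicated article evidence
res <- run_search(search_query("C1000003"), ws$trials, ws$articles,
                  ws$concepts, ws$gazetteer, ws$facility_index)
res$network
export_geojson(res$network, "hemophilia-a.geojson")
```
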