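#' @title Seeded synthetic corpora with planted ground truth
#'
#' @description
#' The generator emits format-valid synthetic corpora — trial XML, citation
#' XML, gazetteer TSV and concept table — with planted structure whose
#' expected outcome is recorded in a ground-truth sidecar: ambiguous city
#' names with a unique population maximum (so the most-populous-city rule
#' has a well-defined answer), multilingual synonym groups, known
#' collaboration cliques, and article/trial identifier linkage. Outputs are
#' a pure function of `(seed, spec)`: the same seed yields byte-identical
#' files. Each artifact type draws from its own derived random stream, so
#' changing the article count does not perturb the gazetteer.
#'
#' Synthetic names are built from fixed in-repo syllable lists; no
#' real-world person or place data is shipped. Random trials and random
#' article affiliations only use unambiguous cities, so the expected
#' geocoding method and node key of every generated site is known by
#' construction; ambiguous names are exercised through dedicated
#' city-only affiliations whose expected winner is the planted population
#' maximum.
#'
#' @name fixtures
NULL

.SYLLABLES <- c("va", "len", "dor", "mi", "ra", "to", "bel", "qua", "zen",
                "fi", "ker", "lu", "san", "gor", "ne", "pol", "ti", "mar",
                "os", "vi", "bre", "dal", "ur", "ka", "mon", "sel", "tra",
                "vo", "hel", "din")
.FORENAMES <- c("Alex", "Sam", "Robin", "Kim", "Noa", "Mika", "Lee", "Jean",
                "Dana", "Elia", "Luca", "Sasha", "Nour", "Rene", "Tari")
.DEPTS <- c("Department of Medicine", "Institute of Clinical Research",
            "Center for Translational Science", "Division of Epidemiology",
            "School of Public Health")
.FACILITY_KINDS <- c("University Hospital", "Medical Center",
                     "General Hospital", "Research Institute", "Clinic")
.ALT_SUFFIXES <- c("Norte", "Alta", "Stadt", "Ville")

# Language-tagged synonym suffixes for synthetic concepts: crude but
# deterministic cross-language variants of an invented English base term.
.LANG_SUFFIX <- c(SPA = " enfermedad", FRE = " maladie", GER = " krankheit",
                  ITA = " malattia")

.cap <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

.make_word <- function(n_syl) {
  .cap(paste(sample(.SYLLABLES, n_syl, replace = TRUE), collapse = ""))
}

.make_unique_words <- function(n, n_syl_range = 2:4, taken = character()) {
  out <- character(0)
  seen <- normalize_term(taken)
  while (length(out) < n) {
    w <- .make_word(sample(n_syl_range, 1L))
    nw <- normalize_term(w)
    if (!nw %in% seen) {
      out <- c(out, w)
      seen <- c(seen, nw)
    }
  }
  out
}

#' Specify a synthetic corpus
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 200 trials, 200 articles, 300 unambiguous cities plus 40 ambiguous
#' city-name groups, all five supported languages, 40 synthetic concepts,
#' and 30% of articles linked to a generated trial (publication of a
#' registered trial).
#'
#' @param seed master integer seed.
#' @param n_trials,n_articles corpus sizes.
#' @param n_cities number of unambiguous gazetteer cities.
#' @param n_ambiguous_city_names number of city names duplicated across
#'   countries with distinct populations (unique maximum).
#' @param languages subset of ENG/SPA/FRE/GER/ITA (ENG always included).
#' @param n_concepts number of synthetic concepts beyond the bundled
#'   exemplar synonym groups.
#' @param linked_article_fraction fraction of random articles carrying a
#'   `linked_nct_ids` accession of a generated trial; linked articles take
#'   their lead affiliations from the linked trial's sites.
#' @param planted_networks list of `list(kind = "TRIAL"|"ARTICLE",
#'   cui = <concept id>, cities = <city names>)` collaboration cliques; the
#'   cities must exist in the gazetteer (generated or `extra_cities`).
#' @param planted_synonym_groups list of `list(cui =, mesh =, terms =
#'   list(ENG = ..., GER = ...))` additional synonym groups.
#' @param extra_cities optional data frame (`name`, `country`, `lat`,
#'   `lon`, `population`) of cities appended verbatim to the gazetteer,
#'   e.g. to place planted cliques at controlled coordinates.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_trials = 200L, n_articles = 200L,
                         n_cities = 300L, n_ambiguous_city_names = 40L,
                         languages = c("ENG", "SPA", "FRE", "GER", "ITA"),
                         n_concepts = 40L, linked_article_fraction = 0.3,
                         planted_networks = list(),
                         planted_synonym_groups = list(),
                         extra_cities = NULL) {
  stopifnot(n_trials >= 0, n_articles >= 0, n_cities >= 10,
            n_ambiguous_city_names >= 0, n_concepts >= 1,
            linked_article_fraction >= 0, linked_article_fraction <= 1)
  languages <- union("ENG", match.arg(languages, .LANGUAGES, several.ok = TRUE))
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 n_articles = as.integer(n_articles),
                 n_cities = as.integer(n_cities),
                 n_ambiguous_city_names = as.integer(n_ambiguous_city_names),
                 languages = languages, n_concepts = as.integer(n_concepts),
                 linked_article_fraction = linked_article_fraction,
                 planted_networks = planted_networks,
                 planted_synonym_groups = planted_synonym_groups,
                 extra_cities = extra_cities),
            class = "fixture_spec")
}

# The worked multilingual synonym groups bundled into every generated
# concept table: one myocardial-infarction concept spanning five languages,
# and the three distinct hemophilia concepts used by the autosuggestion
# example.
.EXEMPLAR_CONCEPTS <- list(
  list(cui = "C1000001", mesh = "D100001",
       rows = list(c("ENG", "myocardial infarction", "Y"),
                   c("ENG", "heart attack", "N"),
                   c("GER", "Herzinfarkt", "N"),
                   c("SPA", "ataque al corazón", "N"),
                   c("FRE", "infarctus du myocarde", "N"),
                   c("ITA", "infarto miocardico", "N"))),
  list(cui = "C1000002", mesh = "D100002",
       rows = list(c("ENG", "Hemophilia", "Y"),
                   c("GER", "Hämophilie", "N"))),
  list(cui = "C1000003", mesh = "D100003",
       rows = list(c("ENG", "Hemophilia A", "Y"),
                   c("GER", "Hämophilie A", "N"))),
  list(cui = "C1000004", mesh = "D100004",
       rows = list(c("ENG", "Hemophilia B", "Y"),
                   c("GER", "Hämophilie B", "N"))))

.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2000000000)
}

.gen_gazetteer <- function(spec) {
  set.seed(.substream_seed(spec$seed, 1L))
  codes <- .COUNTRY_TABLE$code
  plain <- .make_unique_words(spec$n_cities)
  amb <- .make_unique_words(spec$n_ambiguous_city_names, taken = plain)

  rows <- list()
  nid <- 1000L
  add_row <- function(name, country, lat, lon, pop, alts = character()) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- list(
      entry_id = nid, name = name, ascii_name = normalize_term(name),
      alternate_names = alts, country = country, population = pop,
      lat = lat, lon = lon)
  }
  for (w in plain) {
    alts <- if (stats::runif(1) < 0.25) {
      paste(w, sample(.ALT_SUFFIXES, 1L))
    } else {
      character()
    }
    add_row(w, sample(codes, 1L), round(stats::runif(1, -55, 65), 5L),
            round(stats::runif(1, -170, 170), 5L),
            sample(5000:3000000, 1L), alts)
  }
  for (w in amb) {
    k <- sample(2:3, 1L)
    ctr <- sample(codes, k)
    pops <- sort(sample(5000:3000000, k), decreasing = TRUE)
    for (j in seq_len(k)) {
      add_row(w, ctr[j], round(stats::runif(1, -55, 65), 5L),
              round(stats::runif(1, -170, 170), 5L), pops[j])
    }
  }
  if (!is.null(spec$extra_cities)) {
    ec <- spec$extra_cities
    for (i in seq_len(nrow(ec))) {
      add_row(ec$name[i], ec$country[i], ec$lat[i], ec$lon[i],
              ec$population[i])
    }
  }
  # one-shot normalization cache + name index for ground-truth bookkeeping
  norms <- normalize_term(vapply(rows, function(r) r$name, character(1)))
  index <- new.env(parent = emptyenv())
  for (i in seq_along(rows)) {
    rows[[i]]$norm_name <- norms[i]
    rows[[i]]$key <- paste0(norms[i], "|", rows[[i]]$country)
    assign(norms[i],
           c(get0(norms[i], envir = index, ifnotfound = integer()), i),
           envir = index)
  }
  list(rows = rows, plain = plain, ambiguous = amb, index = index)
}

.gazetteer_tsv_lines <- function(rows) {
  vapply(rows, function(r) {
    paste(r$entry_id, r$name, r$ascii_name,
          paste(r$alternate_names, collapse = ","),
          sprintf("%.5f", r$lat), sprintf("%.5f", r$lon), r$country,
          format(r$population, scientific = FALSE), sep = "\t")
  }, character(1))
}

.gen_concepts <- function(spec) {
  set.seed(.substream_seed(spec$seed, 2L))
  groups <- .EXEMPLAR_CONCEPTS
  for (g in spec$planted_synonym_groups) {
    rows <- lapply(names(g$terms), function(lang) {
      c(lang, g$terms[[lang]], if (lang == "ENG") "Y" else "N")
    })
    groups[[length(groups) + 1L]] <- list(cui = g$cui, mesh = g$mesh,
                                          rows = rows)
  }
  taken <- unlist(lapply(groups, function(g)
    vapply(g$rows, `[`, character(1), 2L)), use.names = FALSE)
  bases <- .make_unique_words(spec$n_concepts, 2:3, taken = taken)
  langs <- setdiff(spec$languages, "ENG")
  for (i in seq_len(spec$n_concepts)) {
    rows <- list(c("ENG", paste(bases[i], "disease"), "Y"))
    for (lang in langs) {
      if (lang %in% names(.LANG_SUFFIX)) {
        rows[[length(rows) + 1L]] <- c(lang,
                                       paste0(bases[i], .LANG_SUFFIX[[lang]]),
                                       "N")
      }
    }
    groups[[length(groups) + 1L]] <- list(cui = sprintf("C2%06d", i),
                                          mesh = sprintf("D2%05d", i),
                                          rows = rows)
  }
  groups
}

.concept_table_lines <- function(groups) {
  unlist(lapply(groups, function(g) {
    vapply(g$rows, function(r) {
      paste(g$cui, r[1L], "MSH", g$mesh, r[2L], r[3L], sep = "|")
    }, character(1))
  }), use.names = FALSE)
}

# (name, country) -> gazetteer row, for ground-truth bookkeeping. For an
# unambiguous name, country may be NA. `gz` is the .gen_gazetteer() result.
.find_city <- function(gz, name, country = NA) {
  idx <- get0(normalize_term(name), envir = gz$index, ifnotfound = integer())
  hits <- gz$rows[idx]
  if (!is.na(country)) {
    hits <- Filter(function(r) identical(r$country, country), hits)
  }
  if (!length(hits)) return(NULL)
  # most populous, ties by id: mirrors the documented disambiguation rule
  pops <- vapply(hits, function(r) r$population, numeric(1))
  ids <- vapply(hits, function(r) r$entry_id, integer(1))
  hits[[order(-pops, ids)[1L]]]
}

.city_key <- function(row) row$key

.rand_date <- function(n, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic corpus with ground truth
#'
#' Writes `trials.xml`, `articles.xml`, `gazetteer.tsv`, `concepts.psv` and
#' `ground_truth.json` under `out_dir` and returns the ground truth:
#' the expected merged research network (node keys, edge set, supports,
#' with linked articles attributed to their trial), the expected geocoding
#' method and node key of every generated facility and lead-author
#' affiliation, the term-to-concept map, and the planted cliques.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return the ground-truth list, invisibly; element `paths` holds the file
#'   paths.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  gz <- .gen_gazetteer(spec)
  groups <- .gen_concepts(spec)

  # planted cities must exist in the emitted gazetteer
  for (pn in spec$planted_networks) {
    for (city in pn$cities) {
      if (is.null(.find_city(gz, city))) {
        stop("validation error: planted city '", city,
             "' is not in the gazetteer spec", call. = FALSE)
      }
    }
    if (identical(pn$kind, "ARTICLE") && length(pn$cities) > 4L) {
      stop("validation error: an ARTICLE clique carries at most 4 cities ",
           "(one per lead-author slot)", call. = FALSE)
    }
  }
  cui_of <- function(id) {
    g <- Filter(function(g) g$cui == id, groups)
    if (!length(g)) stop("validation error: planted cui '", id,
                         "' is not in the concept table", call. = FALSE)
    g[[1L]]
  }
  pref_term <- function(g) {
    vapply(g$rows, `[`, character(1), 2L)[
      vapply(g$rows, `[`, character(1), 3L) == "Y"][1L]
  }

  synth_groups <- Filter(function(g) startsWith(g$cui, "C2"), groups)

  # --- trials ----------------------------------------------------------
  set.seed(.substream_seed(spec$seed, 3L))
  trials <- list()
  sites_by_ref <- list()   # ref -> character vector of node keys
  facility_truth <- list()
  nct_counter <- 0L
  next_nct <- function() {
    nct_counter <<- nct_counter + 1L
    sprintf("NCT%08d", nct_counter)
  }
  planted_truth <- list()

  add_trial <- function(cui_group, city_rows, planted = FALSE,
                        planted_id = NA) {
    nct <- next_nct()
    ref <- paste0("TRIAL:", nct)
    facs <- list()
    keys <- character()
    for (row in city_rows) {
      kind <- sample(.FACILITY_KINDS, 1L)
      fname <- paste(row$name, kind)
      with_country <- planted || stats::runif(1) < 0.9
      facs[[length(facs) + 1L]] <- facility(
        name = fname, city = row$name,
        zip = if (stats::runif(1) < 0.5) sprintf("%05d", sample.int(99999, 1L))
              else NA_character_,
        country = if (with_country) iso_to_country_name(row$country)
                  else NA_character_)
      keys <- c(keys, .city_key(row))
      facility_truth[[length(facility_truth) + 1L]] <<- list(
        nct_id = nct, site = fname,
        method = if (with_country) "CITY_COUNTRY" else "CITY_POPULATION",
        node_key = .city_key(row))
    }
    start <- .rand_date(1L, "2012-01-01", "2019-12-31")
    trials[[length(trials) + 1L]] <<- trial(
      nct_id = nct, title = paste("A study of", pref_term(cui_group)),
      condition_terms = pref_term(cui_group), facilities = facs,
      start_date = start,
      completion_date = start + sample(180:2000, 1L),
      status = sample(c("Recruiting", "Completed", "Active, not recruiting"),
                      1L))
    sites_by_ref[[ref]] <<- unique(keys)
    if (planted) {
      planted_truth[[length(planted_truth) + 1L]] <<- list(
        id = planted_id, kind = "TRIAL", ref = ref, cui = cui_group$cui,
        node_keys = sort(unique(keys)))
    }
    nct
  }

  for (i in seq_along(spec$planted_networks)) {
    pn <- spec$planted_networks[[i]]
    if (!identical(pn$kind, "TRIAL")) next
    add_trial(cui_of(pn$cui),
              lapply(pn$cities, function(cc) .find_city(gz, cc)),
              planted = TRUE, planted_id = i)
  }
  plain_rows <- Filter(function(r) {
    normalize_term(r$name) %in% normalize_term(gz$plain)
  }, gz$rows)
  n_random_trials <- max(0L, spec$n_trials - length(trials))
  for (i in seq_len(n_random_trials)) {
    g <- synth_groups[[sample.int(length(synth_groups), 1L)]]
    k <- sample(1:5, 1L)
    rows <- sample(plain_rows, k)
    # one facility per distinct city
    rows <- rows[!duplicated(vapply(rows, .city_key, character(1)))]
    add_trial(g, rows)
  }

  # --- articles --------------------------------------------------------
  set.seed(.substream_seed(spec$seed, 4L))
  articles <- list()
  affiliation_truth <- list()
  pmid_counter <- 5000000L
  next_pmid <- function() {
    pmid_counter <<- pmid_counter + 1L
    as.character(pmid_counter)
  }
  random_trial_ncts <- vapply(trials, function(t) t$nct_id, character(1))

  make_authors <- function(n, affs) {
    # affs: affiliation strings assigned to lead-author slots, recycled
    lead_idx <- sort(unique(c(1L, 2L, n - 1L, n)))
    lead_idx <- lead_idx[lead_idx >= 1L & lead_idx <= n]
    lapply(seq_len(n), function(j) {
      aff <- if (j %in% lead_idx) {
        affs[[((match(j, lead_idx) - 1L) %% length(affs)) + 1L]]
      } else {
        NA_character_
      }
      author(display_name = paste(sample(.FORENAMES, 1L), .make_word(2L)),
             ordinal = j, affiliation_text = aff)
    })
  }

  add_article <- function(g, affs, aff_truth, linked = character(),
                          site_keys, planted = FALSE, planted_id = NA) {
    pmid <- next_pmid()
    ref <- paste0("ARTICLE:", pmid)
    n_auth <- max(length(affs), sample(4:8, 1L))
    arts <- article(
      pmid = pmid, title = paste("Findings on", pref_term(g)),
      mesh_terms = pref_term(g), authors = make_authors(n_auth, affs),
      pub_date = .rand_date(1L, "2013-01-01", "2021-12-31"),
      linked_nct_ids = linked)
    articles[[length(articles) + 1L]] <<- arts
    for (tr in aff_truth) {
      tr$pmid <- pmid
      affiliation_truth[[length(affiliation_truth) + 1L]] <<- tr
    }
    sites_by_ref[[ref]] <<- unique(site_keys)
    if (planted) {
      planted_truth[[length(planted_truth) + 1L]] <<- list(
        id = planted_id, kind = "ARTICLE", ref = ref, cui = g$cui,
        node_keys = sort(unique(site_keys)))
    }
    pmid
  }

  aff_city_country <- function(row) {
    paste0(sample(.DEPTS, 1L), ", ", row$name, ", ",
           iso_to_country_name(row$country))
  }

  for (i in seq_along(spec$planted_networks)) {
    pn <- spec$planted_networks[[i]]
    if (!identical(pn$kind, "ARTICLE")) next
    rows <- lapply(pn$cities, function(cc) .find_city(gz, cc))
    affs <- vapply(rows, aff_city_country, character(1))
    truth <- lapply(rows, function(r) list(method = "CITY_COUNTRY",
                                           node_key = .city_key(r)))
    add_article(cui_of(pn$cui), as.list(affs), truth,
                site_keys = vapply(rows, .city_key, character(1)),
                planted = TRUE, planted_id = i)
  }

  n_random_articles <- max(0L, spec$n_articles - length(articles))
  n_linked <- round(spec$linked_article_fraction * n_random_articles)
  linkable <- random_trial_ncts
  for (i in seq_len(n_random_articles)) {
    if (i <= n_linked && length(linkable)) {
      # publication of a registered trial: same condition, sites drawn from
      # the trial's own facilities, structured NCT accession
      nct <- linkable[[((i - 1L) %% length(linkable)) + 1L]]
      tr <- trials[[match(nct, random_trial_ncts)]]
      g <- Filter(function(g) pref_term(g) %in% tr$condition_terms, groups)[[1L]]
      fac_rows <- lapply(tr$facilities, function(f) {
        iso <- country_to_iso(f$country)
        .find_city(gz, f$city, if (is.na(iso)) NA else iso)
      })
      # at most four sites: affiliations ride on the four lead-author slots
      n_take <- min(sample.int(length(fac_rows), 1L), 4L)
      take <- sort(sample(seq_along(fac_rows), n_take))
      rows <- fac_rows[take]
      affs <- vapply(rows, aff_city_country, character(1))
      truth <- lapply(rows, function(r) list(method = "CITY_COUNTRY",
                                             node_key = .city_key(r)))
      add_article(g, as.list(affs), truth, linked = nct,
                  site_keys = vapply(rows, .city_key, character(1)))
    } else {
      g <- synth_groups[[sample.int(length(synth_groups), 1L)]]
      k <- sample(1:3, 1L)
      rows <- sample(plain_rows, k)
      rows <- rows[!duplicated(vapply(rows, .city_key, character(1)))]
      affs <- list()
      truth <- list()
      for (row in rows) {
        style <- sample(c("FACILITY", "CITY_COUNTRY", "CITY_POPULATION"), 1L,
                        prob = c(0.25, 0.55, 0.20))
        if (style == "FACILITY") {
          # reuse a facility name from the trial corpus; resolves to the
          # facility's own city, wherever the rest of the text points
          t_idx <- sample.int(length(trials), 1L)
          fac <- trials[[t_idx]]$facilities[[1L]]
          iso <- country_to_iso(fac$country)
          frow <- .find_city(gz, fac$city, if (is.na(iso)) NA else iso)
          affs[[length(affs) + 1L]] <- paste0(
            sample(.DEPTS, 1L), ", ", fac$name, ", ", fac$city,
            if (!is.na(fac$zip)) paste0(" ", fac$zip) else "",
            ", ", iso_to_country_name(frow$country))
          truth[[length(truth) + 1L]] <- list(method = "FACILITY",
                                              node_key = .city_key(frow))
        } else if (style == "CITY_COUNTRY") {
          affs[[length(affs) + 1L]] <- aff_city_country(row)
          truth[[length(truth) + 1L]] <- list(method = "CITY_COUNTRY",
                                              node_key = .city_key(row))
        } else {
          # city-only affiliation; sometimes an ambiguous name, whose
          # expected winner is the planted population maximum
          use_amb <- length(gz$ambiguous) && stats::runif(1) < 0.5
          nm <- if (use_amb) sample(gz$ambiguous, 1L) else row$name
          win <- .find_city(gz, nm)
          affs[[length(affs) + 1L]] <- paste0(sample(.DEPTS, 1L), ", ", nm)
          truth[[length(truth) + 1L]] <- list(method = "CITY_POPULATION",
                                              node_key = .city_key(win))
        }
      }
      keys <- vapply(truth, function(x) x$node_key, character(1))
      add_article(g, affs, truth, site_keys = keys)
    }
  }

  # --- expected merged network (independent of the network module) -----
  # linked articles are attributed to their trial's reference
  ref_map <- list()
  for (a in articles) {
    if (length(a$linked_nct_ids)) {
      ref_map[[paste0("ARTICLE:", a$pmid)]] <-
        paste0("TRIAL:", a$linked_nct_ids[1L])
    }
  }
  node_env <- new.env(parent = emptyenv())
  edge_env <- new.env(parent = emptyenv())
  for (ref in names(sites_by_ref)) {
    eff <- if (!is.null(ref_map[[ref]])) ref_map[[ref]] else ref
    keys <- sort(unique(sites_by_ref[[ref]]))
    for (k in keys) {
      assign(k, sort(unique(c(get0(k, envir = node_env,
                                   ifnotfound = character()), eff))),
             envir = node_env)
    }
    if (length(keys) >= 2L) {
      pr <- utils::combn(keys, 2L)
      for (j in seq_len(ncol(pr))) {
        ek <- paste(pr[1L, j], pr[2L, j], sep = "\r")
        assign(ek, sort(unique(c(get0(ek, envir = edge_env,
                                      ifnotfound = character()), eff))),
               envir = edge_env)
      }
    }
  }
  node_keys <- sort(ls(node_env))
  exp_nodes <- lapply(node_keys, function(k) get(k, envir = node_env))
  names(exp_nodes) <- node_keys
  eks <- sort(ls(edge_env))
  exp_edges <- lapply(eks, function(k) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    list(from = p[1L], to = p[2L], supports = get(k, envir = edge_env))
  })

  term_cui <- list()
  for (g in groups) {
    for (r in g$rows) term_cui[[r[2L]]] <- g$cui
  }

  # --- write files -----------------------------------------------------
  paths <- list(trials = file.path(out_dir, "trials.xml"),
                articles = file.path(out_dir, "articles.xml"),
                gazetteer = file.path(out_dir, "gazetteer.tsv"),
                concepts = file.path(out_dir, "concepts.psv"),
                ground_truth = file.path(out_dir, "ground_truth.json"))
  write_trials(trials, paths$trials)
  write_articles(articles, paths$articles)
  writeLines(.gazetteer_tsv_lines(gz$rows), paths$gazetteer, useBytes = TRUE)
  con <- file(paths$concepts, open = "wb")
  writeLines(enc2utf8(.concept_table_lines(groups)), con, useBytes = TRUE)
  close(con)

  truth <- list(
    expected_nodes = exp_nodes,
    expected_edges = exp_edges,
    facility_methods = facility_truth,
    affiliation_methods = affiliation_truth,
    term_cui = term_cui,
    planted = planted_truth,
    counts = list(trials = length(trials), articles = length(articles),
                  gazetteer = length(gz$rows),
                  concept_rows = length(.concept_table_lines(groups))),
    ambiguous_names = gz$ambiguous,
    paths = paths)
  jsonlite::write_json(truth[setdiff(names(truth), "paths")],
                       paths$ground_truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(truth)
}

#' Bundled worked-example fixture
#'
#' Loads the small static corpus shipped with the package: the multilingual
#' myocardial-infarction synonym group ("heart attack", "Herzinfarkt",
#' "ataque al corazón" under one concept), the Hemophilia/Hemophilia A/
#' Hemophilia B autosuggestion group, a University-of-Leeds-style facility
#' record, and a Springfield-style ambiguous city pair.
#'
#' @return list with elements `trials`, `articles`, `gazetteer`, `concepts`,
#'   `facility_index` and `paths`.
#' @export
bundled_fixture <- function() {
  dir <- system.file("extdata", package = "studynet", mustWork = TRUE)
  paths <- list(trials = file.path(dir, "trials.xml"),
                articles = file.path(dir, "articles.xml"),
                gazetteer = file.path(dir, "gazetteer.tsv"),
                concepts = file.path(dir, "concepts.psv"))
  load_workspace(paths$trials, paths$articles, paths$gazetteer,
                 paths$concepts)
}

#' Load a full workspace from the four corpus files
#'
#' @param trials_path,articles_path,gazetteer_path,concepts_path file paths
#'   in the documented dialects.
#' @return list with elements `trials`, `articles`, `gazetteer`, `concepts`,
#'   `facility_index` and `paths`.
#' @export
load_workspace <- function(trials_path, articles_path, gazetteer_path,
                           concepts_path) {
  for (p in c(trials_path, articles_path, gazetteer_path, concepts_path)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  trials <- parse_trials(trials_path)
  list(trials = trials,
       articles = parse_articles(articles_path),
       gazetteer = load_gazetteer(gazetteer_path),
       concepts = load_concept_table(concepts_path),
       facility_index = build_facility_index(trials),
       paths = list(trials = trials_path, articles = articles_path,
                    gazetteer = gazetteer_path, concepts = concepts_path))
}
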