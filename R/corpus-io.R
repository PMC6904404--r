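#' Construct a trial facility
#'
#' A study site as recorded in a trial registry: facility name, city, optional
#' postal code and country. At least one of name/city must be non-empty.
#'
#' @param name facility display name.
#' @param city city name.
#' @param zip postal-code string or `NA`.
#' @param country country name or ISO alpha-2 code, or `NA`.
#' @return an object of class `facility`.
#' @export
facility <- function(name = "", city = "", zip = NA_character_,
                     country = NA_character_) {
  obj <- structure(list(name = as.character(name), city = as.character(city),
                        zip = as.character(zip),
                        country = as.character(country)),
                   class = "facility")
  validate_facility(obj)
  obj
}

validate_facility <- function(f) {
  if (!nzchar(f$name) && !nzchar(f$city)) {
    stop("facility must have at least one of name/city non-empty",
         call. = FALSE)
  }
  invisible(f)
}

#' Construct a trial record
#'
#' @param nct_id registry identifier, `"NCT"` followed by 8 digits.
#' @param title brief title.
#' @param condition_terms character vector of condition terms (MeSH-style).
#' @param facilities list of [facility()] objects, possibly empty.
#' @param start_date,completion_date `Date` or `NA`; when both present,
#'   `start_date <= completion_date` is enforced.
#' @param status free-text recruitment status.
#' @return an object of class `trial`.
#' @export
trial <- function(nct_id, title = "", condition_terms = character(),
                  facilities = list(), start_date = as.Date(NA),
                  completion_date = as.Date(NA), status = NA_character_) {
  obj <- structure(list(nct_id = as.character(nct_id),
                        title = as.character(title),
                        condition_terms = as.character(condition_terms),
                        facilities = facilities,
                        start_date = as.Date(start_date),
                        completion_date = as.Date(completion_date),
                        status = as.character(status)),
                   class = "trial")
  validate_trial(obj)
  obj
}

validate_trial <- function(x) {
  if (length(x$nct_id) != 1L || !is_nct_id(x$nct_id)) {
    stop("invalid nct_id: ", paste(x$nct_id, collapse = "/"), call. = FALSE)
  }
  lapply(x$facilities, validate_facility)
  if (!is.na(x$start_date) && !is.na(x$completion_date) &&
      x$start_date > x$completion_date) {
    stop("trial ", x$nct_id, ": start_date after completion_date",
         call. = FALSE)
  }
  invisible(x)
}

#' Construct an article author
#'
#' @param display_name author display name.
#' @param ordinal 1-based position in the article's author list.
#' @param affiliation_text raw affiliation string or `NA`.
#' @return an object of class `author`.
#' @export
author <- function(display_name, ordinal, affiliation_text = NA_character_) {
  structure(list(display_name = as.character(display_name),
                 ordinal = as.integer(ordinal),
                 affiliation_text = as.character(affiliation_text)),
            class = "author")
}

#' Construct a citation record
#'
#' @param pmid PubMed identifier (digit string).
#' @param title article title.
#' @param mesh_terms character vector of MeSH descriptor strings.
#' @param authors ordered list of [author()] objects; ordinals must be
#'   distinct and contiguous from 1.
#' @param pub_date `Date` or `NA`.
#' @param linked_nct_ids NCT identifiers found in the record's data-bank
#'   accession numbers.
#' @return an object of class `article`.
#' @export
article <- function(pmid, title = "", mesh_terms = character(),
                    authors = list(), pub_date = as.Date(NA),
                    linked_nct_ids = character()) {
  obj <- structure(list(pmid = as.character(pmid),
                        title = as.character(title),
                        mesh_terms = as.character(mesh_terms),
                        authors = authors,
                        pub_date = as.Date(pub_date),
                        linked_nct_ids = as.character(linked_nct_ids)),
                   class = "article")
  validate_article(obj)
  obj
}

validate_article <- function(x) {
  if (length(x$pmid) != 1L || !is_pmid(x$pmid)) {
    stop("invalid pmid: ", paste(x$pmid, collapse = "/"), call. = FALSE)
  }
  ords <- vapply(x$authors, function(a) a$ordinal, integer(1))
  if (length(ords) && !identical(sort(ords), seq_along(ords))) {
    stop("article ", x$pmid,
         ": author ordinals must be distinct and contiguous from 1",
         call. = FALSE)
  }
  bad <- x$linked_nct_ids[!is_nct_id(x$linked_nct_ids)]
  if (length(bad)) {
    stop("article ", x$pmid, ": invalid linked NCT id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

.read_corpus_xml <- function(source) {
  tryCatch(xml2::read_xml(source),
           error = function(e) {
             stop("XML parse error: ", conditionMessage(e), call. = FALSE)
           })
}

.xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

#' Parse a trial-registry XML corpus
#'
#' Reads the documented subset of the ClinicalTrials.gov legacy full-study
#' dialect: `clinical_study` records with `id_info/nct_id`, `brief_title`,
#' repeated `condition`, `overall_status`, `start_date`, `completion_date`,
#' and repeated `location/facility` blocks (`name`,
#' `address/{city,zip,country}`). Unknown elements are ignored for forward
#' compatibility with real registry exports. Facilities are kept in document
#' order.
#'
#' @param source path, connection or XML string readable by [xml2::read_xml()].
#' @param on_missing_id `"error"` (default) rejects a record lacking an NCT
#'   identifier; `"skip"` drops it with a warning.
#' @return list of [trial()] objects.
#' @export
parse_trials <- function(source, on_missing_id = c("error", "skip")) {
  on_missing_id <- match.arg(on_missing_id)
  doc <- .read_corpus_xml(source)
  recs <- xml2::xml_find_all(doc, ".//clinical_study")
  out <- vector("list", length(recs))
  keep <- logical(length(recs))
  for (i in seq_along(recs)) {
    node <- recs[[i]]
    nct <- .xml_text1(node, "./id_info/nct_id")
    if (is.na(nct) || !is_nct_id(nct)) {
      msg <- sprintf("trial record %d has a missing or malformed nct_id", i)
      if (on_missing_id == "error") stop("validation error: ", msg,
                                         call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    locs <- xml2::xml_find_all(node, "./location/facility")
    facs <- lapply(locs, function(f) {
      facility(name = .na_empty(.xml_text1(f, "./name")),
               city = .na_empty(.xml_text1(f, "./address/city")),
               zip = .xml_text1(f, "./address/zip"),
               country = .xml_text1(f, "./address/country"))
    })
    out[[i]] <- trial(
      nct_id = nct,
      title = .na_empty(.xml_text1(node, "./brief_title")),
      condition_terms = xml2::xml_text(xml2::xml_find_all(node, "./condition")),
      facilities = facs,
      start_date = parse_flex_date(.xml_text1(node, "./start_date")),
      completion_date = parse_flex_date(.xml_text1(node, "./completion_date")),
      status = .xml_text1(node, "./overall_status"))
    keep[i] <- TRUE
  }
  ids <- vapply(out[keep], function(t) t$nct_id, character(1))
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate nct_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out[keep]
}

.na_empty <- function(x) if (is.na(x)) "" else x
.empty_na <- function(x) if (!is.na(x) && !nzchar(x)) NA_character_ else x

.add_text_child <- function(parent, tag, value) {
  if (length(value) == 1L && (is.na(value) || !nzchar(value))) return()
  for (v in value) {
    node <- xml2::xml_add_child(parent, tag)
    xml2::xml_text(node) <- as.character(v)
  }
}

#' Write a trial corpus as registry XML
#'
#' Emits the same dialect [parse_trials()] reads; `parse_trials(write_trials(x))`
#' is field-identical to `x`, and output bytes are stable for identical input.
#'
#' @param trials list of [trial()] objects.
#' @param path file path or connection for [xml2::write_xml()].
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  root <- xml2::xml_new_root("clinical_studies")
  for (t in trials) {
    validate_trial(t)
    rec <- xml2::xml_add_child(root, "clinical_study")
    info <- xml2::xml_add_child(rec, "id_info")
    .add_text_child(info, "nct_id", t$nct_id)
    .add_text_child(rec, "brief_title", t$title)
    .add_text_child(rec, "overall_status", t$status)
    .add_text_child(rec, "start_date", format_registry_date(t$start_date))
    .add_text_child(rec, "completion_date",
                    format_registry_date(t$completion_date))
    .add_text_child(rec, "condition", t$condition_terms)
    for (f in t$facilities) {
      fac <- xml2::xml_add_child(xml2::xml_add_child(rec, "location"),
                                 "facility")
      .add_text_child(fac, "name", f$name)
      addr <- xml2::xml_add_child(fac, "address")
      .add_text_child(addr, "city", f$city)
      .add_text_child(addr, "zip", f$zip)
      .add_text_child(addr, "country", f$country)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

.split_display_name <- function(display_name) {
  parts <- strsplit(trimws(display_name), " +")[[1L]]
  if (length(parts) <= 1L) {
    list(fore = NA_character_, last = display_name)
  } else {
    list(fore = paste(parts[-length(parts)], collapse = " "),
         last = parts[length(parts)])
  }
}

#' Parse a citation XML corpus
#'
#' Reads the documented PubMed-article-set subset: `PMID`, `ArticleTitle`,
#' `AuthorList/Author` (`LastName`, `ForeName`,
#' `AffiliationInfo/Affiliation`), `Journal/JournalIssue/PubDate`,
#' `MeshHeadingList/MeshHeading/DescriptorName`, and
#' `DataBankList/.../AccessionNumber`. Trial linkage is taken only from
#' accession numbers matching the NCT pattern; authors keep document order
#' with 1-based ordinals.
#'
#' @inheritParams parse_trials
#' @return list of [article()] objects.
#' @export
parse_articles <- function(source) {
  doc <- .read_corpus_xml(source)
  recs <- xml2::xml_find_all(doc, ".//MedlineCitation")
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    node <- recs[[i]]
    pmid <- .xml_text1(node, "./PMID")
    if (is.na(pmid) || !is_pmid(pmid)) {
      stop(sprintf("validation error: citation record %d has a missing or malformed PMID", i),
           call. = FALSE)
    }
    au_nodes <- xml2::xml_find_all(node, "./Article/AuthorList/Author")
    authors <- lapply(seq_along(au_nodes), function(j) {
      a <- au_nodes[[j]]
      fore <- .xml_text1(a, "./ForeName")
      last <- .xml_text1(a, "./LastName")
      nm <- trimws(paste(stats::na.omit(c(fore, last)), collapse = " "))
      author(display_name = nm, ordinal = j,
             affiliation_text = .xml_text1(a, "./AffiliationInfo/Affiliation"))
    })
    acc <- xml2::xml_text(xml2::xml_find_all(
      node, "./DataBankList/DataBank/AccessionNumberList/AccessionNumber"))
    pd <- .parse_pubdate(node)
    out[[i]] <- article(
      pmid = pmid,
      title = .na_empty(.xml_text1(node, "./Article/ArticleTitle")),
      mesh_terms = xml2::xml_text(xml2::xml_find_all(
        node, "./MeshHeadingList/MeshHeading/DescriptorName")),
      authors = authors,
      pub_date = pd,
      linked_nct_ids = acc[is_nct_id(acc)])
  }
  ids <- vapply(out, function(a) a$pmid, character(1))
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate pmid in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out
}

.parse_pubdate <- function(node) {
  pd <- xml2::xml_find_first(node, "./Article/Journal/JournalIssue/PubDate")
  if (inherits(pd, "xml_missing")) return(as.Date(NA))
  yr <- .xml_text1(pd, "./Year")
  if (is.na(yr)) return(as.Date(NA))
  mo <- .xml_text1(pd, "./Month")
  dy <- .xml_text1(pd, "./Day")
  m <- if (is.na(mo)) 1L else match(mo, .MONTHS)
  if (is.na(m)) m <- suppressWarnings(as.integer(mo))
  if (is.na(m)) m <- 1L
  d <- if (is.na(dy)) 1L else as.integer(dy)
  as.Date(sprintf("%04d-%02d-%02d", as.integer(yr), m, d))
}

#' Write a citation corpus as PubMed-style XML
#'
#' Emits the dialect [parse_articles()] reads; round-trips are
#' field-identical and byte-stable.
#'
#' @param articles list of [article()] objects.
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_articles <- function(articles, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (a in articles) {
    validate_article(a)
    cit <- xml2::xml_add_child(xml2::xml_add_child(root, "PubmedArticle"),
                               "MedlineCitation")
    .add_text_child(cit, "PMID", a$pmid)
    art <- xml2::xml_add_child(cit, "Article")
    .add_text_child(art, "ArticleTitle", a$title)
    if (!is.na(a$pub_date)) {
      pd <- xml2::xml_add_child(
        xml2::xml_add_child(xml2::xml_add_child(art, "Journal"),
                            "JournalIssue"), "PubDate")
      .add_text_child(pd, "Year", format(a$pub_date, "%Y"))
      .add_text_child(pd, "Month", .MONTHS[as.integer(format(a$pub_date, "%m"))])
      .add_text_child(pd, "Day", as.character(as.integer(format(a$pub_date, "%d"))))
    }
    if (length(a$authors)) {
      al <- xml2::xml_add_child(art, "AuthorList")
      for (au in a$authors) {
        an <- xml2::xml_add_child(al, "Author")
        nm <- .split_display_name(au$display_name)
        .add_text_child(an, "LastName", nm$last)
        .add_text_child(an, "ForeName", nm$fore)
        if (!is.na(au$affiliation_text)) {
          .add_text_child(xml2::xml_add_child(an, "AffiliationInfo"),
                          "Affiliation", au$affiliation_text)
        }
      }
    }
    if (length(a$linked_nct_ids)) {
      db <- xml2::xml_add_child(xml2::xml_add_child(cit, "DataBankList"),
                                "DataBank")
      .add_text_child(db, "DataBankName", "ClinicalTrials.gov")
      .add_text_child(xml2::xml_add_child(db, "AccessionNumberList"),
                      "AccessionNumber", a$linked_nct_ids)
    }
    if (length(a$mesh_terms)) {
      ml <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (m in a$mesh_terms) {
        .add_text_child(xml2::xml_add_child(ml, "MeshHeading"),
                        "DescriptorName", m)
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Lead authors of an article
#'
#' Lead authors are the first two and the last two authors of the article's
#' author list. For four or fewer authors the two sets overlap and every
#' author is a lead author. The result is duplicate-free and ascending in
#' ordinal, so its length is `min(4, n)`.
#'
#' @param art an [article()].
#' @return list of [author()] objects (empty for an empty author list).
#' @export
lead_authors <- function(art) {
  n <- length(art$authors)
  if (n == 0L) return(list())
  idx <- sort(unique(c(1L, 2L, n - 1L, n)))
  idx <- idx[idx >= 1L & idx <= n]
  art$authors[idx]
}
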