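# Documents, corpora, and the standard input/output formats: MEDLINE flat
# files, PubMed XML, annotation JSON and HTML highlight reports.

#' Construct a document
#'
#' @param doc_id non-empty identifier (PMID or synthetic id).
#' @param title document title.
#' @param body abstract or full text (may be empty).
#' @param year publication year or `NA`.
#' @param is_full_text whether `body` is full text rather than an abstract.
#' @return an object of class `fm_document`.
#' @export
new_document <- function(doc_id, title = "", body = "", year = NA_integer_,
                         is_full_text = FALSE) {
  if (!is.character(doc_id) || length(doc_id) != 1 || !nzchar(doc_id)) {
    stop_fm("doc_id must be a non-empty string")
  }
  structure(list(doc_id = doc_id, year = as.integer(year),
                 title = as.character(title), body = as.character(body),
                 is_full_text = isTRUE(is_full_text)),
            class = "fm_document")
}

#' Construct a corpus from a list of documents
#'
#' Document order is preserved; duplicate `doc_id`s are a hard error.
#'
#' @param documents list of `fm_document`.
#' @param provenance free-text origin (file path or generator seed).
#' @return an object of class `fm_corpus`.
#' @export
new_corpus <- function(documents = list(), provenance = "") {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop_fm("duplicate doc_id in corpus: '%s'", ids[duplicated(ids)][1])
  }
  structure(list(documents = documents, provenance = provenance),
            class = "fm_corpus")
}

#' @export
length.fm_corpus <- function(x) length(x$documents)

#' @export
`[[.fm_corpus` <- function(x, i) {
  if (is.character(i)) {
    ids <- doc_ids(x)
    j <- match(i, ids)
    if (is.na(j)) stop_fm("no document with doc_id '%s'", i)
    return(x$documents[[j]])
  }
  x$documents[[i]]
}

#' Document identifiers of a corpus
#' @param corpus an `fm_corpus`.
#' @return character vector of doc_ids in corpus order.
#' @export
doc_ids <- function(corpus) {
  vapply(corpus$documents, function(d) d$doc_id, character(1))
}

#' @export
print.fm_corpus <- function(x, ...) {
  cat(sprintf("<fm_corpus> %d documents (provenance: %s)\n",
              length(x), x$provenance))
  invisible(x)
}

#' @export
print.fm_document <- function(x, ...) {
  cat(sprintf("<fm_document> %s (%s): %s\n", x$doc_id,
              ifelse(is.na(x$year), "year NA", x$year), x$title))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MEDLINE flat file

medline_field <- function(record, tag) {
  # tag lines are "TAG - value" with tag padded to 4 chars; continuation
  # lines start with six spaces
  hit <- grep(paste0("^", tag, " {0,3}- "), record)
  if (!length(hit)) return(NULL)
  out <- character(length(hit))
  for (k in seq_along(hit)) {
    i <- hit[k]
    val <- sub("^[A-Z0-9]{1,4} {0,3}- ", "", record[i])
    j <- i + 1L
    while (j <= length(record) && grepl("^ {6}", record[j])) {
      val <- paste(val, sub("^ {6}", "", record[j]))
      j <- j + 1L
    }
    out[k] <- val
  }
  out
}

#' Read a MEDLINE flat file into a corpus
#'
#' Records are blocks of `TAG - value` lines separated by blank lines; the
#' PMID, DP (year), TI (title) and AB (abstract) fields are used. Records
#' missing AB are kept with an empty body (with a warning); records missing a
#' PMID are skipped with a warning. Latin-1 input is transcoded to UTF-8.
#'
#' @param path path to the flat file.
#' @return an `fm_corpus`; the number of skipped records is available as
#'   `attr(corpus, "n_skipped")`.
#' @export
read_medline <- function(path) {
  lines <- fm_read_lines(path)
  if (any(!validUTF8(lines))) {
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  }
  # split into records on blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  recs <- split(lines[!blank], grp[!blank])
  docs <- list()
  n_skipped <- 0L
  for (record in recs) {
    pmid <- medline_field(record, "PMID")
    if (is.null(pmid) || !nzchar(pmid[1])) {
      warn_fm("skipping malformed MEDLINE record without PMID")
      n_skipped <- n_skipped + 1L
      next
    }
    ti <- medline_field(record, "TI")
    ab <- medline_field(record, "AB")
    dp <- medline_field(record, "DP")
    year <- NA_integer_
    if (!is.null(dp)) {
      m <- regmatches(dp[1], regexpr("[0-9]{4}", dp[1]))
      if (length(m)) year <- as.integer(m)
    }
    if (is.null(ab)) {
      warn_fm("MEDLINE record %s has no AB field; keeping empty body", pmid[1])
      ab <- ""
    }
    docs[[length(docs) + 1L]] <- new_document(
      doc_id = pmid[1], title = ti[1] %||% "", body = ab[1], year = year)
  }
  out <- new_corpus(docs, provenance = path)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a corpus as a MEDLINE flat file
#'
#' Fields are written unwrapped (one line per field) so that plain-text bodies
#' round-trip byte-identically through [read_medline()].
#'
#' @param corpus an `fm_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(corpus, path) {
  stopifnot(inherits(corpus, "fm_corpus"))
  out <- character(0)
  for (d in corpus$documents) {
    rec <- c(paste0("PMID- ", d$doc_id),
             if (!is.na(d$year)) paste0("DP  - ", d$year),
             if (nzchar(d$title)) paste0("TI  - ", d$title),
             paste0("AB  - ", d$body),
             "")
    out <- c(out, rec)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PubMed XML

#' Read a PubmedArticleSet XML file into a corpus
#'
#' Extracts PMID, publication year (PubDate/Year, falling back to the first
#' four digits of MedlineDate), ArticleTitle and AbstractText. Labeled
#' abstract sections are concatenated with single spaces. A missing PubDate
#' leaves the year absent; an XML parse failure is a hard error carrying the
#' parser's position information.
#'
#' @param path path to the XML file.
#' @return an `fm_corpus`.
#' @export
read_pubmed_xml <- function(path) {
  if (!file.exists(path)) stop_fm("file does not exist: '%s'", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop_fm("XML parse failure in '%s': %s", path,
                            conditionMessage(e))
                  })
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  docs <- lapply(articles, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    sections <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    body <- paste(trimws(xml2::xml_text(sections)), collapse = " ")
    year_node <- xml2::xml_find_first(a, ".//Article//PubDate/Year")
    year <- NA_integer_
    if (!inherits(year_node, "xml_missing")) {
      year <- as.integer(xml2::xml_text(year_node))
    } else {
      md <- xml2::xml_find_first(a, ".//Article//PubDate/MedlineDate")
      if (!inherits(md, "xml_missing")) {
        m <- regmatches(xml2::xml_text(md), regexpr("[0-9]{4}", xml2::xml_text(md)))
        if (length(m)) year <- as.integer(m)
      }
    }
    new_document(doc_id = pmid, title = ifelse(is.na(title), "", title),
                 body = body, year = year)
  })
  new_corpus(docs, provenance = path)
}

# ---------------------------------------------------------------------------
# Annotation sets and their JSON serialization

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             surface = character(), normalized_id = character(),
             stringsAsFactors = FALSE)
}

empty_interactions <- function() {
  data.frame(fusion = character(), partner = character(), action = character(),
             sentence_index = integer(), evidence = character(),
             stringsAsFactors = FALSE)
}

empty_disease_links <- function() {
  data.frame(fusion = character(), disease = character(), action = character(),
             sentence_index = integer(), mesh_id = character(),
             stringsAsFactors = FALSE)
}

#' Construct an annotation set for one document
#'
#' Mention spans are 0-based, half-open, counted in Unicode code points on the
#' raw document body.
#'
#' @param doc_id document identifier.
#' @param mentions data frame with columns start, end, label, surface,
#'   normalized_id.
#' @param interactions data frame with columns fusion, partner, action,
#'   sentence_index, evidence.
#' @param disease_links data frame with columns fusion, disease, action,
#'   sentence_index, mesh_id.
#' @return an object of class `fm_annotations`.
#' @export
new_annotation_set <- function(doc_id, mentions = empty_mentions(),
                               interactions = empty_interactions(),
                               disease_links = empty_disease_links()) {
  structure(list(doc_id = doc_id, mentions = mentions,
                 interactions = interactions, disease_links = disease_links),
            class = "fm_annotations")
}

#' @export
print.fm_annotations <- function(x, ...) {
  cat(sprintf("<fm_annotations> %s: %d mentions, %d interactions, %d disease links\n",
              x$doc_id, nrow(x$mentions), nrow(x$interactions),
              nrow(x$disease_links)))
  invisible(x)
}

validate_spans <- function(document, mentions) {
  n <- nchar(document$body)
  bad <- mentions$start < 0 | mentions$end > n | mentions$start >= mentions$end
  if (any(bad)) {
    stop_fm("annotation span [%d,%d) outside document %s body (length %d)",
            mentions$start[which(bad)[1]], mentions$end[which(bad)[1]],
            document$doc_id, n)
  }
  invisible(TRUE)
}

annotations_to_list <- function(a) {
  list(
    doc_id = jsonlite::unbox(a$doc_id),
    mentions = lapply(seq_len(nrow(a$mentions)), function(i) {
      m <- a$mentions[i, ]
      list(start = jsonlite::unbox(as.integer(m$start)),
           end = jsonlite::unbox(as.integer(m$end)),
           label = jsonlite::unbox(m$label),
           surface = jsonlite::unbox(m$surface),
           normalized_id = jsonlite::unbox(m$normalized_id))
    }),
    interactions = lapply(seq_len(nrow(a$interactions)), function(i) {
      m <- a$interactions[i, ]
      list(fusion = jsonlite::unbox(m$fusion),
           partner = jsonlite::unbox(m$partner),
           action = jsonlite::unbox(m$action),
           sentence_index = jsonlite::unbox(as.integer(m$sentence_index)),
           evidence = jsonlite::unbox(m$evidence))
    }),
    disease_links = lapply(seq_len(nrow(a$disease_links)), function(i) {
      m <- a$disease_links[i, ]
      list(fusion = jsonlite::unbox(m$fusion),
           disease = jsonlite::unbox(m$disease),
           action = jsonlite::unbox(m$action),
           sentence_index = jsonlite::unbox(as.integer(m$sentence_index)),
           mesh_id = jsonlite::unbox(m$mesh_id))
    })
  )
}

#' Write annotation sets to JSON
#'
#' The schema has a stable key order (`doc_id`, `mentions`, `interactions`,
#' `disease_links`); spans, labels and normalized ids round-trip exactly
#' through [read_annotations()]. Every annotation set must reference a
#' document present in `corpus`, and every span must lie within that
#' document's body.
#'
#' @param corpus the `fm_corpus` the annotations refer to.
#' @param annotation_sets list of `fm_annotations`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(corpus, annotation_sets, path) {
  stopifnot(inherits(corpus, "fm_corpus"))
  ids <- doc_ids(corpus)
  for (a in annotation_sets) {
    if (!a$doc_id %in% ids) {
      stop_fm("annotation set references unknown doc_id '%s'", a$doc_id)
    }
    validate_spans(corpus[[a$doc_id]], a$mentions)
  }
  payload <- list(format = jsonlite::unbox("fusemine-annotations"),
                  version = jsonlite::unbox(1L),
                  documents = lapply(annotation_sets, annotations_to_list))
  json <- jsonlite::toJSON(payload, pretty = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
  invisible(path)
}

#' Read annotation sets from JSON written by [write_annotations()]
#'
#' @param path path to the JSON file.
#' @return list of `fm_annotations`, one per document entry.
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "fusemine-annotations")) {
    stop_fm("'%s' is not a fusemine annotation file", path)
  }
  lapply(x$documents, function(d) {
    mentions <- if (length(d$mentions)) {
      do.call(rbind, lapply(d$mentions, function(m) {
        data.frame(start = as.integer(m$start), end = as.integer(m$end),
                   label = m$label, surface = m$surface,
                   normalized_id = m$normalized_id, stringsAsFactors = FALSE)
      }))
    } else empty_mentions()
    interactions <- if (length(d$interactions)) {
      do.call(rbind, lapply(d$interactions, function(m) {
        data.frame(fusion = m$fusion, partner = m$partner, action = m$action,
                   sentence_index = as.integer(m$sentence_index),
                   evidence = m$evidence, stringsAsFactors = FALSE)
      }))
    } else empty_interactions()
    disease_links <- if (length(d$disease_links)) {
      do.call(rbind, lapply(d$disease_links, function(m) {
        data.frame(fusion = m$fusion, disease = m$disease, action = m$action,
                   sentence_index = as.integer(m$sentence_index),
                   mesh_id = m$mesh_id, stringsAsFactors = FALSE)
      }))
    } else empty_disease_links()
    new_annotation_set(d$doc_id, mentions, interactions, disease_links)
  })
}

# ---------------------------------------------------------------------------
# HTML highlighting

#' Render a document body with mention spans highlighted
#'
#' Wraps every mention span in `<mark class="LABEL">...</mark>`; non-mention
#' text is left unchanged. Overlapping spans are resolved outermost-wins: an
#' inner (nested or crossing) span is dropped with a warning.
#'
#' @param document an `fm_document`.
#' @param annotation_set an `fm_annotations` for that document.
#' @return a single HTML string.
#' @export
render_highlighted <- function(document, annotation_set) {
  m <- annotation_set$mentions
  if (nrow(m) == 0) return(document$body)
  validate_spans(document, m)
  m <- m[order(m$start, -m$end), , drop = FALSE]
  keep <- logical(nrow(m))
  cur_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- m$end[i]
    } else {
      warn_fm("dropping span [%d,%d) overlapped by an outer span",
              m$start[i], m$end[i])
    }
  }
  m <- m[keep, , drop = FALSE]
  body <- document$body
  out <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(m))) {
    out <- c(out,
             substr(body, pos + 1L, m$start[i]),
             sprintf('<mark class="%s">%s</mark>', m$label[i],
                     substr(body, m$start[i] + 1L, m$end[i])))
    pos <- m$end[i]
  }
  paste0(paste(out, collapse = ""), substr(body, pos + 1L, nchar(body)))
}

# ---------------------------------------------------------------------------
# Optional networked PubMed fetch (never used by the test suite)

#' Fetch abstracts from PubMed via NCBI E-utilities
#'
#' Optional, networked convenience. Requires network access and is disabled
#' when the `fusemine.offline` option is set. `max_articles = 0` returns an
#' empty corpus without any network call.
#'
#' @param query PubMed query string (e.g. `"BCR-ABL"`).
#' @param max_articles maximum number of abstracts to retrieve.
#' @param offline if `TRUE`, error immediately with "network disabled".
#' @return an `fm_corpus`.
#' @export
fetch_pubmed <- function(query, max_articles = 100,
                         offline = isTRUE(getOption("fusemine.offline"))) {
  stopifnot(is.numeric(max_articles), max_articles >= 0)
  if (max_articles == 0) return(new_corpus(list(), provenance = "pubmed:empty"))
  if (offline) stop_fm("network disabled (fusemine.offline option is set)")
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  esearch <- sprintf("%s/esearch.fcgi?db=pubmed&retmax=%d&term=%s",
                     base, as.integer(max_articles), utils::URLencode(query, reserved = TRUE))
  tmp <- tempfile(fileext = ".xml")
  ok <- tryCatch(utils::download.file(esearch, tmp, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fm("PubMed esearch failed (network unavailable?)")
  ids <- xml2::xml_text(xml2::xml_find_all(xml2::read_xml(tmp), "//IdList/Id"))
  if (!length(ids)) return(new_corpus(list(), provenance = paste0("pubmed:", query)))
  efetch <- sprintf("%s/efetch.fcgi?db=pubmed&rettype=medline&retmode=text&id=%s",
                    base, paste(ids, collapse = ","))
  tmp2 <- tempfile(fileext = ".txt")
  ok <- tryCatch(utils::download.file(efetch, tmp2, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fm("PubMed efetch failed (network unavailable?)")
  out <- read_medline(tmp2)
  out$provenance <- paste0("pubmed:", query)
  out
}
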