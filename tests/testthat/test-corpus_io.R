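test_that("MEDLINE reader returns one document per record in file order", {
  path <- write_medline_fixture()
  corpus <- read_medline(path)
  expect_s3_class(corpus, "fm_corpus")
  expect_length(corpus, 2)
  expect_equal(doc_ids(corpus), c("9747873", "24186139"))
  expect_equal(corpus[["24186139"]]$year, 2013L)
  expect_match(corpus[["9747873"]]$body, "^Both Bcr-Abl fusion proteins")
})

test_that("empty MEDLINE file yields an empty corpus", {
  path <- tempfile()
  writeLines(character(0), path)
  expect_length(read_medline(path), 0)
})

test_that("record with TI but no AB keeps an empty body and warns", {
  path <- tempfile()
  writeLines(c("PMID- 1", "TI  - A title only record", ""), path)
  expect_warning(corpus <- read_medline(path), "no AB field")
  expect_equal(corpus[[1]]$body, "")
  expect_equal(corpus[[1]]$title, "A title only record")
})

test_that("malformed records are skipped with a warning and counted", {
  path <- tempfile()
  writeLines(c("TI  - no pmid here", "", "PMID- 2", "AB  - ok", ""), path)
  expect_warning(corpus <- read_medline(path), "without PMID")
  expect_length(corpus, 1)
  expect_equal(attr(corpus, "n_skipped"), 1L)
})

test_that("MEDLINE continuation lines are joined with single spaces", {
  path <- tempfile()
  writeLines(c("PMID- 3", "AB  - first part", "      second part", ""), path)
  corpus <- read_medline(path)
  expect_equal(corpus[[1]]$body, "first part second part")
})

test_that("read -> write -> read is a fixed point for plain text", {
  path <- write_medline_fixture()
  c1 <- read_medline(path)
  out <- tempfile()
  write_medline(c1, out)
  c2 <- read_medline(out)
  expect_equal(doc_ids(c2), doc_ids(c1))
  for (i in seq_len(length(c1))) {
    expect_identical(c2[[i]]$body, c1[[i]]$body)
    expect_identical(c2[[i]]$title, c1[[i]]$title)
  }
  # document count equals record count over generated corpora
  sim <- generate_corpus(generator_config(seed = 3, n_docs = 9))
  p <- tempfile()
  write_medline(sim$corpus, p)
  expect_length(read_medline(p), 9)
})

test_that("PubMed XML reader populates PMID, year, title and joined abstract", {
  corpus <- read_pubmed_xml(write_pubmed_xml_fixture())
  expect_length(corpus, 1)
  d <- corpus[[1]]
  expect_equal(d$doc_id, "24186139")
  expect_equal(d$year, 2013L)
  expect_equal(d$title, "Fusion genes in cancer")
  expect_equal(d$body, paste("BCR-ABL causes leukemia.", "We mined abstracts.",
                             "CRKL binds to BCR-ABL fusion protein."))
})

test_that("missing PubDate leaves the year absent without failure", {
  corpus <- read_pubmed_xml(write_pubmed_xml_fixture(with_pubdate = FALSE))
  expect_true(is.na(corpus[[1]]$year))
})

test_that("XML parse failure is a hard error naming the position", {
  path <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><unclosed>", path)
  expect_error(read_pubmed_xml(path), "XML parse failure")
})

test_that("annotation JSON round-trips spans, labels and unicode exactly", {
  doc <- new_document("D1", body = "GRB10 interacts with BCR–ABL today")
  corpus <- new_corpus(list(doc))
  mentions <- data.frame(start = c(0L, 21L), end = c(5L, 28L),
                         label = c("GENE", "FUSION"),
                         surface = c("GRB10", "BCR–ABL"),
                         normalized_id = c("GRB10", "BCR-ABL"),
                         stringsAsFactors = FALSE)
  ann <- new_annotation_set("D1", mentions)
  path <- tempfile(fileext = ".json")
  write_annotations(corpus, list(ann), path)
  back <- read_annotations(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$mentions$start, mentions$start)
  expect_equal(back[[1]]$mentions$end, mentions$end)
  expect_identical(back[[1]]$mentions$surface[2], "BCR–ABL")
  expect_equal(back[[1]]$mentions$normalized_id, mentions$normalized_id)
  # a second write of the re-read annotations is byte-identical
  path2 <- tempfile(fileext = ".json")
  write_annotations(corpus, back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("empty annotation sets serialize to valid JSON with empty lists", {
  corpus <- new_corpus(list(new_document("D1", body = "x")))
  path <- tempfile(fileext = ".json")
  write_annotations(corpus, list(new_annotation_set("D1")), path)
  back <- read_annotations(path)
  expect_equal(nrow(back[[1]]$mentions), 0)
  expect_equal(nrow(back[[1]]$interactions), 0)
})

test_that("dangling doc_id in annotations is a hard error", {
  corpus <- new_corpus(list(new_document("D1", body = "x")))
  expect_error(
    write_annotations(corpus, list(new_annotation_set("GHOST")), tempfile()),
    "GHOST")
})

test_that("duplicate doc_id in a corpus is rejected", {
  expect_error(new_corpus(list(new_document("A"), new_document("A"))),
               "duplicate doc_id")
})

test_that("highlighting wraps each mention once and leaves other text alone", {
  doc <- new_document("D1", body = "CRKL binds to BCR-ABL fusion protein")
  expect_identical(render_highlighted(doc, new_annotation_set("D1")),
                   doc$body)
  mentions <- data.frame(start = c(0L, 5L, 14L), end = c(4L, 10L, 21L),
                         label = c("GENE", "ACTION", "FUSION"),
                         surface = c("CRKL", "binds", "BCR-ABL"),
                         normalized_id = c("CRKL", "bind", "BCR-ABL"),
                         stringsAsFactors = FALSE)
  html <- render_highlighted(doc, new_annotation_set("D1", mentions))
  expect_equal(lengths(regmatches(html, gregexpr("<mark", html))), 3)
  expect_match(html, '<mark class="FUSION">BCR-ABL</mark>')
  expect_match(html, '<mark class="ACTION">binds</mark>')
  expect_match(html, "fusion protein$")
})

test_that("overlapping highlight spans resolve outermost-wins with warning", {
  doc <- new_document("D1", body = "the BCR-ABL-selective inhibitor")
  mentions <- data.frame(start = c(4L, 4L), end = c(21L, 11L),
                         label = c("FUSION", "GENE"),
                         surface = c("BCR-ABL-selective", "BCR-ABL"),
                         normalized_id = c("BCR-ABL", "BCR-ABL"),
                         stringsAsFactors = FALSE)
  expect_warning(html <- render_highlighted(doc, new_annotation_set("D1", mentions)),
                 "outer")
  expect_equal(lengths(regmatches(html, gregexpr("<mark", html))), 1)
})

test_that("fetch_pubmed honours the offline guard without touching the network", {
  expect_length(fetch_pubmed("BCR-ABL", max_articles = 0), 0)
  expect_error(fetch_pubmed("BCR-ABL", max_articles = 10, offline = TRUE),
               "network disabled")
})
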