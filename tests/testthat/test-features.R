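test_that("n-gram extraction counts contiguous grams", {
  g <- extract_ngrams(c("crkl", "bind", "bcr-abl"), 2)
  expect_equal(g[["crkl bind"]], 1L)
  expect_equal(g[["bind bcr-abl"]], 1L)
  expect_length(g, 2)
  expect_length(extract_ngrams("single", 2), 0)
  expect_equal(sum(extract_ngrams(letters[1:10], 3)), 8)
  expect_error(extract_ngrams(letters, 5), "1..4")
  expect_error(extract_ngrams(letters, 0), "1..4")
  # repeated grams accumulate counts
  g <- extract_ngrams(c("a", "b", "a", "b", "a"), 2)
  expect_equal(g[["a b"]], 2L)
  expect_equal(g[["b a"]], 2L)
})

test_that("corpus statistics count tau, sigma and per-document frequency", {
  stats <- compute_stats(list(d1 = c("x", "y", "x"), d2 = c("y"),
                              d3 = c("z")))
  expect_equal(stats$tau, 3)
  expect_equal(unname(stats$sigma[c("x", "y", "z")]), c(1L, 2L, 1L))
  expect_equal(stats$fs$d1[["x"]], 2L)
  expect_false("w" %in% names(stats$sigma))
  empty <- compute_stats(list())
  expect_equal(empty$tau, 0)
  expect_length(empty$sigma, 0)
})

test_that("the frequency-score threshold follows FS x log10(tau/sigma)", {
  expect_equal(threshold_score(7, 5, 5), 0)
  expect_equal(threshold_score(4, 1000, 10), 8)
  expect_equal(threshold_score(0, 10, 3), 0)
  expect_error(threshold_score(1, 10, 0), "sigma")
  expect_error(threshold_score(1, 10, 11), "sigma")
  expect_error(threshold_score(-1, 10, 2), "non-negative")
})

test_that("the threshold score strictly decreases in document frequency", {
  for (tau in c(5, 50, 1000)) {
    scores <- threshold_score(3, tau, seq_len(tau))
    expect_true(all(diff(scores) < 0))
  }
})

test_that("the threshold matches an independent reimplementation on random corpora", {
  naive_scores <- function(docs) {
    # straightforward loops, no shared code with the package internals
    all_tokens <- unique(unlist(docs))
    tau <- length(docs)
    out <- list()
    for (tok in all_tokens) {
      sigma <- 0
      for (d in docs) if (tok %in% d) sigma <- sigma + 1
      for (i in seq_along(docs)) {
        fs <- sum(docs[[i]] == tok)
        out[[paste(tok, i)]] <- fs * log10(tau / sigma)
      }
    }
    out
  }
  withr::with_seed(424242, {
    for (rep in 1:100) {
      n_docs <- sample(2:6, 1)
      docs <- lapply(seq_len(n_docs), function(i) {
        sample(letters[1:8], sample(1:12, 1), replace = TRUE)
      })
      names(docs) <- paste0("d", seq_len(n_docs))
      stats <- compute_stats(docs)
      oracle <- naive_scores(docs)
      for (key in names(oracle)) {
        parts <- strsplit(key, " ")[[1]]
        tok <- parts[1]; i <- as.integer(parts[2])
        fs <- stats$fs[[i]][tok]
        fs <- if (is.na(fs)) 0 else fs
        got <- threshold_score(fs, stats$tau, stats$sigma[[tok]])
        expect_equal(unname(got), oracle[[key]], tolerance = 1e-12)
      }
    }
  })
})

test_that("bag-of-words vectors share one vocabulary and unit row sums", {
  docs <- list(d1 = c("a", "a", "b"), d2 = c("a", "a", "b"),
               d3 = c("c", "d", "common"), d4 = c("common", "e"))
  docs <- lapply(docs, function(d) c(d, "common"))  # in every document
  stats <- compute_stats(docs)
  bow <- build_bag_of_words(stats, vocab_size = 10, min_threshold = 1e-9)
  # a token present in all documents scores 0 and is excluded
  expect_false("common" %in% bow$vocabulary)
  expect_equal(nrow(bow$matrix), 4)
  # identical documents get identical vectors
  expect_equal(as.numeric(bow$matrix[1, ]), as.numeric(bow$matrix[2, ]))
  rs <- Matrix::rowSums(bow$matrix)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  expect_error(build_bag_of_words(stats, vocab_size = 0), "vocab_size")
})

test_that("vocabulary selection is invariant to document order", {
  docs <- list(d1 = c("a", "b", "b"), d2 = c("c", "a"), d3 = c("d", "d", "b"))
  v1 <- build_bag_of_words(compute_stats(docs), 10)$vocabulary
  v2 <- build_bag_of_words(compute_stats(rev(docs)), 10)$vocabulary
  expect_identical(v1, v2)
})

test_that("document terms blank entities into class placeholders", {
  doc <- new_document("D1", body = "GRB10 interacts with BCR-ABL.")
  terms <- document_terms(doc, test_lexicon, ngram = 1, blank = TRUE)
  expect_true("GENE" %in% terms)
  expect_true("FUSION" %in% terms)
  expect_true("ACTION" %in% terms)
  expect_false(any(grepl("grb10|bcr-abl", terms)))
  raw <- document_terms(doc, test_lexicon, ngram = 1, blank = FALSE)
  expect_true("grb10" %in% raw)
  expect_true("bcr-abl" %in% raw)
})

test_that("token-category counts have the per-document summary shape", {
  corpus <- read_medline(write_medline_fixture())
  counts <- token_category_counts(corpus, test_lexicon)
  expect_equal(names(counts),
               c("doc_id", "fusion_proteins", "fusion_genes", "biological",
                 "miscellaneous"))
  expect_equal(counts$doc_id, doc_ids(corpus))
  expect_true(all(counts$fusion_proteins >= 1))  # both fixtures mention BCR-ABL
  expect_true(all(counts$miscellaneous > 0))
})
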