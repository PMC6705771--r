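test_that("fusion mentions are detected with keyword or alias support", {
  r <- annotate_sentence(paste("Both Bcr-Abl fusion proteins exhibit an",
                               "increased tyrosine kinase activity"))
  expect_equal(nrow(r$fusions), 1)
  expect_equal(r$fusions$normalized_id, "BCR-ABL")
  expect_true(r$fusions$keyword_support)

  expect_equal(nrow(annotate_sentence("samples from 2013-2017 were analyzed")$fusions), 0)

  r <- annotate_sentence("TMRPSS2-ERG")
  expect_equal(r$fusions$normalized_id, "TMPRSS2-ERG")
  expect_false(r$fusions$keyword_support)
  expect_equal(r$fusions$route, "alias")
})

test_that("a non-alias gene pair needs a fusion keyword within the window", {
  # JAK2-STAT5 is not in the alias dictionary
  far <- annotate_sentence("JAK2-STAT5 signaling was strong in these samples")
  expect_equal(nrow(far$fusions), 0)
  near <- annotate_sentence("the JAK2-STAT5 fusion was detected")
  expect_equal(nrow(near$fusions), 1)
  expect_equal(near$fusions$normalized_id, "JAK2-STAT5")
  expect_equal(near$fusions$route, "keyword")
  # beyond the 5-token window the keyword does not license the mention
  text <- paste("JAK2-STAT5 activity was measured together with several",
                "other markers and one known fusion")
  expect_equal(nrow(annotate_sentence(text)$fusions), 0)
})

test_that("a fusion embedded in a longer hyphen chain is detected", {
  r <- annotate_sentence("the BCR-ABL-selective kinase inhibitor imatinib")
  expect_equal(nrow(r$fusions), 1)
  expect_equal(r$fusions$surface, "BCR-ABL-selective")
  expect_equal(r$fusions$normalized_id, "BCR-ABL")
})

test_that("normalization is dialect-invariant and idempotent", {
  variants <- c("BCR-ABL", "bcr-abl", "BCR:ABL", "bcr:ABL", "BCR/ABL",
                "bcr/abl", "Bcr-Abl", "BCR–ABL", "BCR—ABL")
  ids <- vapply(variants, normalize_fusion, character(1),
                lexicon = test_lexicon)
  expect_true(all(ids == "BCR-ABL"))
  expect_equal(normalize_fusion("EWS/FLI-1", test_lexicon), "EWS-FLI1")
  expect_equal(normalize_fusion("BCR-ABL", test_lexicon), "BCR-ABL")
  expect_error(normalize_fusion("FOO-BARX", test_lexicon), "unresolvable")
  expect_error(normalize_fusion("BCR", test_lexicon), "two-part")
})

test_that("interaction extraction links fusions to partners via action verbs", {
  r <- annotate_sentence(
    "The SH2-containing adapter protein GRB10 interacts with BCR-ABL")
  expect_equal(r$interactions$fusion, "BCR-ABL")
  expect_equal(r$interactions$partner, "GRB10")
  expect_equal(r$interactions$action, "interact")

  r <- annotate_sentence("Grb2 has been shown to bind NPM-ALK and ATIC-ALK")
  expect_equal(nrow(r$interactions), 2)
  expect_setequal(r$interactions$fusion, c("NPM-ALK", "ATIC-ALK"))
  expect_true(all(r$interactions$partner == "GRB2"))
  expect_true(all(r$interactions$action == "bind"))

  # nominal action forms do not trigger interactions
  r <- annotate_sentence("BCR-JAK2 induces STAT5 activation")
  expect_equal(nrow(r$interactions), 1)
  expect_equal(r$interactions$action, "induce")

  # no action token -> no interactions
  r <- annotate_sentence("the BCR-ABL fusion and GRB2 were both present")
  expect_equal(nrow(r$interactions), 0)
})

test_that("partners are never components of a sentence fusion", {
  for (text in c("BCR interacts with the BCR-ABL fusion",
                 "ABL binds BCR-ABL in cells",
                 "GRB2 binds NPM-ALK and ATIC-ALK")) {
    r <- annotate_sentence(text)
    comps <- toupper(c(r$fusions$gene_a, r$fusions$gene_b))
    expect_false(any(toupper(r$interactions$partner) %in% comps))
  }
})

test_that("disease links pair fusions with disease terms through a verb", {
  r <- annotate_sentence("BCR-ABL causes leukemia")
  expect_equal(nrow(r$diseases), 1)
  expect_equal(r$diseases$fusion, "BCR-ABL")
  expect_equal(r$diseases$disease, "leukemia")
  expect_equal(r$diseases$action, "cause")
  expect_equal(r$diseases$mesh_id, "D007938")

  expect_equal(nrow(annotate_sentence("the BCR-ABL fusion was detected")$diseases), 0)

  r <- annotate_sentence("BCR-ABL causes leukemia and lymphoma")
  expect_equal(nrow(r$diseases), 2)
  expect_setequal(r$diseases$disease, c("leukemia", "lymphoma"))

  # multi-word disease terms match longest-first
  r <- annotate_sentence("BCR-ABL causes chronic myeloid leukemia")
  expect_equal(r$diseases$disease, "chronic myeloid leukemia")
  expect_equal(r$diseases$mesh_id, "D015464")
})

test_that("document annotation places mention spans on the raw body", {
  body <- paste("BCR-ABL causes leukemia.",
                "The SH2-containing adapter protein GRB10 interacts with BCR-ABL.")
  doc <- new_document("D1", body = body)
  ann <- annotate_document(doc, test_lexicon)
  fus <- ann$mentions[ann$mentions$label == "FUSION", ]
  expect_equal(nrow(fus), 2)
  for (i in seq_len(nrow(fus))) {
    expect_identical(substr(body, fus$start[i] + 1L, fus$end[i]),
                     fus$surface[i])
  }
  expect_equal(sort(unique(ann$mentions$label)),
               c("ACTION", "DISEASE", "FUSION", "GENE"))
  expect_equal(ann$interactions$sentence_index, 2L)
})

test_that("identical corpus and lexicon give byte-identical annotation JSON", {
  corpus <- read_medline(write_medline_fixture())
  p1 <- tempfile(); p2 <- tempfile()
  write_annotations(corpus, unname(annotate_corpus(corpus, test_lexicon)), p1)
  write_annotations(corpus, unname(annotate_corpus(corpus, test_lexicon)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("evidence networks merge duplicate pairs and count nodes", {
  g <- export_network(NULL, tempfile(fileext = ".graphml"))
  expect_equal(igraph::vcount(g), 0)

  im <- data.frame(
    doc_id = c("A", "A", "B"),
    fusion = c("NPM-ALK", "ATIC-ALK", "NPM-ALK"),
    partner = c("GRB2", "GRB2", "GRB2"),
    action = c("bind", "bind", "activate"),
    sentence_index = 1L, evidence = "", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".graphml")
  g <- export_network(im, path)
  expect_equal(igraph::vcount(g), 3)  # two fusions + one partner
  expect_equal(igraph::ecount(g), 2)  # duplicate NPM-ALK--GRB2 merged
  edges <- utils::read.delim(sub("graphml$", "tsv", path))
  npm <- edges[edges$fusion == "NPM-ALK", ]
  expect_equal(npm$n_evidence, 2)
  expect_equal(npm$doc_ids, "A,B")
  expect_equal(npm$actions, "activate,bind")
  expect_true(file.exists(path))
})
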