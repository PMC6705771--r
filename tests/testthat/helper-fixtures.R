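# Shared fixtures: the packaged lexicon (loaded once per test file) and
# small programmatic corpus builders.

test_lexicon <- default_lexicon()

# two-record MEDLINE flat file; returns the path
write_medline_fixture <- function(path = tempfile(fileext = ".medline")) {
  writeLines(c(
    "PMID- 9747873",
    "DP  - 1998",
    "TI  - Bcr-Abl fusion proteins and tyrosine kinase activity",
    "AB  - Both Bcr-Abl fusion proteins exhibit an increased tyrosine kinase activity. The SH2-containing adapter protein GRB10 interacts with BCR-ABL.",
    "",
    "PMID- 24186139",
    "DP  - 2013",
    "TI  - Fusion genes in cancer",
    "AB  - BCR-ABL causes leukemia.",
    ""
  ), path)
  path
}

# one-article PubMed XML with three labeled abstract sections
write_pubmed_xml_fixture <- function(path = tempfile(fileext = ".xml"),
                                     with_pubdate = TRUE) {
  date <- if (with_pubdate) "<PubDate><Year>2013</Year></PubDate>" else ""
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>24186139</PMID>",
    "<Article>",
    paste0("<Journal><JournalIssue>", date, "</JournalIssue></Journal>"),
    "<ArticleTitle>Fusion genes in cancer</ArticleTitle>",
    "<Abstract>",
    '<AbstractText Label="BACKGROUND">BCR-ABL causes leukemia.</AbstractText>',
    '<AbstractText Label="METHODS">We mined abstracts.</AbstractText>',
    '<AbstractText Label="RESULTS">CRKL binds to BCR-ABL fusion protein.</AbstractText>',
    "</Abstract>",
    "</Article></MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"
  ), path)
  path
}

# lexicon TSV file builder
write_lexicon_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

annotate_sentence <- function(text, lexicon = test_lexicon) {
  tokens <- tokenize(text)
  fus <- detect_fusion_mentions(tokens, lexicon)
  list(tokens = tokens, fusions = fus,
       interactions = detect_interactions(tokens, fus, lexicon, text),
       diseases = detect_disease_links(tokens, fus, lexicon))
}
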