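# N-gram extraction, corpus statistics, the frequency-score threshold used
# for vocabulary selection, and fixed-length bag-of-words feature vectors.

#' Extract contiguous n-grams with counts
#'
#' @param tokens character vector of token stems (or a token table with a
#'   `stem` column).
#' @param n gram order, 1 to 4.
#' @return named integer vector of n-gram counts (grams joined by single
#'   spaces); for a sequence of L tokens the counts sum to `max(L - n + 1, 0)`.
#' @export
extract_ngrams <- function(tokens, n = 1) {
  if (is.data.frame(tokens)) {
    tokens <- if ("stem" %in% names(tokens)) tokens$stem else tokens$surface
  }
  stopifnot(is.character(tokens))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > 4 || n != round(n)) {
    stop_fm("n must be an integer in 1..4")
  }
  n <- as.integer(n)
  L <- length(tokens)
  if (L < n) return(structure(integer(0), names = character(0)))
  grams <- if (n == 1L) tokens else {
    vapply(seq_len(L - n + 1L),
           function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
           character(1))
  }
  tab <- table(grams)
  structure(as.integer(tab), names = names(tab))
}

#' Compute corpus-level token statistics
#'
#' For a tokenized corpus computes the corpus size `tau` (number of
#' documents), the document frequency `sigma` of every gram (number of
#' documents containing it), and the in-document frequency `fs` of every
#' (gram, document) pair.
#'
#' @param corpus_tokens named list, one element per document: either a
#'   character vector of grams/tokens or an already-counted named integer
#'   vector (as returned by [extract_ngrams()]).
#' @return an object of class `fm_corpus_stats` with fields `tau`, `sigma`
#'   (named integer) and `fs` (named list of named integer vectors).
#' @export
compute_stats <- function(corpus_tokens) {
  stopifnot(is.list(corpus_tokens))
  fs <- lapply(corpus_tokens, function(x) {
    if (is.character(x)) {
      tab <- table(x)
      structure(as.integer(tab), names = names(tab))
    } else {
      stopifnot(is.numeric(x), !is.null(names(x)))
      structure(as.integer(x), names = names(x))
    }
  })
  all_grams <- unlist(lapply(fs, names), use.names = FALSE)
  sigma <- integer(0)
  if (length(all_grams)) {
    tab <- table(all_grams)
    sigma <- structure(as.integer(tab), names = names(tab))
  }
  structure(list(tau = length(fs), sigma = sigma, fs = fs),
            class = "fm_corpus_stats")
}

#' @export
print.fm_corpus_stats <- function(x, ...) {
  cat(sprintf("<fm_corpus_stats> tau = %d documents, %d distinct grams\n",
              x$tau, length(x$sigma)))
  invisible(x)
}

#' Frequency-score threshold of a token in a document
#'
#' Computes `FS * log10(tau / sigma)`, where `FS` is the token's frequency in
#' the document, `tau` the number of documents in the corpus and `sigma` the
#' number of documents containing the token. A token present in every
#' document scores 0; for fixed `FS` and `tau` the score strictly decreases
#' as `sigma` grows.
#'
#' @param fs in-document frequency (>= 0); vectorized.
#' @param tau corpus size (number of documents).
#' @param sigma document frequency of the token (1 <= sigma <= tau).
#' @return numeric score(s).
#' @export
threshold_score <- function(fs, tau, sigma) {
  stopifnot(is.numeric(fs), is.numeric(tau), is.numeric(sigma))
  if (any(sigma < 1) || any(sigma > tau)) {
    stop_fm("sigma must satisfy 1 <= sigma <= tau")
  }
  if (any(fs < 0)) stop_fm("fs must be non-negative")
  fs * log10(tau / sigma)
}

#' Build a fixed-length bag-of-words feature matrix
#'
#' Selects a global vocabulary of the `vocab_size` grams with the highest
#' max-over-documents frequency score (ties broken lexicographically),
#' filtered to scores `>= min_threshold`, then represents every document as
#' its frequency-score values over that vocabulary, rescaled to unit sum
#' (all-zero rows are left zero). All vectors share one vocabulary and one
#' length.
#'
#' @param corpus_stats an `fm_corpus_stats` from [compute_stats()].
#' @param vocab_size maximum vocabulary size (>= 1).
#' @param min_threshold minimum frequency score for vocabulary membership.
#' @return a list of class `fm_bow`: `matrix` (sparse dgCMatrix, documents x
#'   vocabulary), `vocabulary` (character), `scores` (max-over-docs score per
#'   vocabulary gram).
#' @export
build_bag_of_words <- function(corpus_stats, vocab_size = 1000,
                               min_threshold = 0) {
  stopifnot(inherits(corpus_stats, "fm_corpus_stats"))
  if (!is.numeric(vocab_size) || vocab_size < 1) {
    stop_fm("vocab_size must be >= 1")
  }
  tau <- corpus_stats$tau
  sigma <- corpus_stats$sigma
  doc_ids <- names(corpus_stats$fs) %||% as.character(seq_along(corpus_stats$fs))
  if (tau == 0 || length(sigma) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(tau, 0))
    rownames(m) <- doc_ids
    return(structure(list(matrix = m, vocabulary = character(0),
                          scores = numeric(0)), class = "fm_bow"))
  }
  # max-over-documents score per gram
  max_score <- setNames(rep(0, length(sigma)), names(sigma))
  for (d in seq_along(corpus_stats$fs)) {
    f <- corpus_stats$fs[[d]]
    if (!length(f)) next
    sc <- threshold_score(f, tau, sigma[names(f)])
    upd <- sc > max_score[names(f)]
    if (any(upd)) max_score[names(f)[upd]] <- sc[upd]
  }
  keep <- max_score >= min_threshold
  ord <- order(-max_score[keep], names(max_score)[keep])
  vocabulary <- names(max_score[keep])[ord]
  if (length(vocabulary) > vocab_size) {
    vocabulary <- vocabulary[seq_len(vocab_size)]
  }
  vi <- seq_along(vocabulary)
  names(vi) <- vocabulary
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (d in seq_along(corpus_stats$fs)) {
    f <- corpus_stats$fs[[d]]
    f <- f[names(f) %in% vocabulary]
    if (!length(f)) next
    sc <- threshold_score(f, tau, sigma[names(f)])
    nz <- sc > 0
    if (!any(nz)) next
    trip_i <- c(trip_i, rep(d, sum(nz)))
    trip_j <- c(trip_j, unname(vi[names(f)[nz]]))
    trip_x <- c(trip_x, unname(sc[nz]))
  }
  m <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(corpus_stats$fs),
                                     length(vocabulary)))
  rownames(m) <- doc_ids
  colnames(m) <- vocabulary
  rs <- Matrix::rowSums(m)
  nz <- rs > 0
  if (any(nz)) m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  structure(list(matrix = m, vocabulary = vocabulary,
                 scores = unname(max_score[vocabulary])),
            class = "fm_bow")
}

#' @export
print.fm_bow <- function(x, ...) {
  cat(sprintf("<fm_bow> %d documents x %d vocabulary grams\n",
              nrow(x$matrix), length(x$vocabulary)))
  invisible(x)
}

#' Turn a document into feature grams (stems, optionally entity-blanked)
#'
#' The feature-extraction front end: sentences are tokenized and stemmed;
#' with `blank = TRUE` recognized entities (fusions, genes, diseases, action
#' tokens) are first replaced by their class placeholders so that features
#' generalize across specific gene names; n-grams of every order in `ngram`
#' are then extracted per sentence and pooled.
#'
#' @param document an `fm_document`.
#' @param lexicon an `fm_lexicon`.
#' @param ngram integer vector of gram orders (subset of 1..4).
#' @param blank whether to blank recognized entities before gram extraction.
#' @return character vector of grams (with repetition).
#' @export
document_terms <- function(document, lexicon, ngram = 1:2, blank = TRUE) {
  stopifnot(inherits(document, "fm_document"))
  sentences <- split_sentences(document)
  out <- character(0)
  ann <- if (blank) annotate_document(document, lexicon) else NULL
  for (si in seq_len(nrow(sentences))) {
    stext <- sentences$text[si]
    if (blank && nrow(ann$mentions)) {
      in_sent <- ann$mentions$start >= sentences$start[si] &
        ann$mentions$end <= sentences$end[si]
      local <- ann$mentions[in_sent, , drop = FALSE]
      local$start <- local$start - sentences$start[si]
      local$end <- local$end - sentences$start[si]
      stext <- blank_entities(stext, local)
    }
    tokens <- stem_tokens(tokenize(stext))
    stems <- tokens$stem
    # keep placeholders uppercase so GENE/FUSION stay distinct grams
    ph <- tokens$surface %in% c("GENE", "FUSION", "DISEASE", "ACTION")
    stems[ph] <- tokens$surface[ph]
    for (n in ngram) {
      g <- extract_ngrams(stems, n)
      out <- c(out, rep(names(g), g))
    }
  }
  out
}

#' Feature grams for every document of a corpus
#'
#' @param corpus an `fm_corpus`.
#' @inheritParams document_terms
#' @return named list of gram vectors (one per document, corpus order).
#' @export
corpus_terms <- function(corpus, lexicon, ngram = 1:2, blank = TRUE) {
  out <- lapply(corpus$documents, document_terms, lexicon = lexicon,
                ngram = ngram, blank = blank)
  names(out) <- doc_ids(corpus)
  out
}

#' Per-document token-category counts
#'
#' Emits one row per document with the number of fusion-mention tokens, the
#' number of standalone gene-symbol tokens, and the number of Biological and
#' Miscellaneous tokens — the per-document shape of a bag-of-words collection
#' summary table.
#'
#' @param corpus an `fm_corpus`.
#' @param lexicon an `fm_lexicon`.
#' @return data frame with columns doc_id, fusion_proteins, fusion_genes,
#'   biological, miscellaneous.
#' @export
token_category_counts <- function(corpus, lexicon) {
  rows <- lapply(corpus$documents, function(d) {
    ann <- annotate_document(d, lexicon)
    sentences <- split_sentences(d)
    cats <- character(0)
    for (si in seq_len(nrow(sentences))) {
      tk <- categorize_tokens(tokenize(sentences$text[si]), lexicon)
      cats <- c(cats, tk$category)
    }
    data.frame(doc_id = d$doc_id,
               fusion_proteins = sum(ann$mentions$label == "FUSION"),
               fusion_genes = sum(ann$mentions$label == "GENE"),
               biological = sum(cats == "Biological"),
               miscellaneous = sum(cats == "Miscellaneous"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
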