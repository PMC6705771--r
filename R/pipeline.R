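# End-to-end pipeline surface: a single entry point tying simulation,
# tagging, interaction extraction, training and evaluation together, with a
# machine-readable run manifest. The exec/fusemine script wraps this
# function for shell use.

read_corpus_auto <- function(path) {
  if (grepl("\\.xml$", path, ignore.case = TRUE)) read_pubmed_xml(path)
  else read_medline(path)
}

read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("doc_id", "label") %in% names(df))) {
    stop_fm("labels file '%s' needs doc_id and label columns", path)
  }
  df
}

write_manifest <- function(out_dir, mode, config, inputs) {
  digests <- lapply(inputs, function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL
  })
  payload <- list(
    tool = jsonlite::unbox("fusemine"),
    version = jsonlite::unbox(as.character(utils::packageVersion("fusemine"))),
    mode = jsonlite::unbox(mode),
    config = lapply(config, function(v) {
      if (length(v) == 1 && is.atomic(v)) jsonlite::unbox(v) else v
    }),
    input_digests = digests
  )
  json <- jsonlite::toJSON(payload, digits = NA, pretty = TRUE, null = "null")
  con <- file(file.path(out_dir, "manifest.json"), open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

eval_report_df <- function(report) {
  fmt <- function(v) ifelse(is.na(v), "undefined", format(v, digits = 15))
  data.frame(
    metric = c("tp", "fp", "fn", "tn", "precision", "recall", "f_score",
               "accuracy"),
    value = c(report$tp, report$fp, report$fn, report$tn,
              fmt(report$precision), fmt(report$recall), fmt(report$f_score),
              fmt(report$accuracy)),
    stringsAsFactors = FALSE)
}

#' Run the fusion-mining pipeline
#'
#' Modes: `simulate` writes a synthetic corpus with gold annotations and
#' labels; `tag` annotates a corpus and writes annotation JSON plus an HTML
#' highlight report; `extract` writes the pooled interaction table and the
#' GraphML/TSV evidence network; `train` fits a Naive Bayes model and writes
#' it as versioned JSON together with the vocabulary and per-document
#' token-category counts; `evaluate` cross-validates the classifier and
#' writes the evaluation report and ROC points; `report` writes per-document
#' summary counts. Every run writes a `manifest.json` with the configuration,
#' package version and input digests.
#'
#' @param mode one of simulate, tag, extract, train, evaluate, report.
#' @param input input corpus path (MEDLINE flat file, or PubMed XML by
#'   `.xml` extension); not used by `simulate`.
#' @param out_dir output directory, created if missing.
#' @param labels path to a labels TSV (doc_id, label), required by `train`
#'   and `evaluate`.
#' @param lexicon_paths named list of lexicon file paths for
#'   [load_lexicon()]; `NULL` uses the packaged [default_lexicon()].
#' @param seed integer seed for simulation and fold assignment.
#' @param n_docs number of synthetic documents (`simulate`).
#' @param ngram n-gram orders used for features.
#' @param vocab_size bag-of-words vocabulary size.
#' @param min_threshold minimum frequency score for vocabulary membership.
#' @param alpha Naive Bayes smoothing constant.
#' @param k number of cross-validation folds (`evaluate`, mode "kfold").
#' @param eval_mode "kfold" (stratified k-fold), "split" (40/60 train/test)
#'   or "halves" (50/50).
#' @param keyword_window token window for fusion-keyword support.
#' @return invisibly, a named list of the objects produced.
#' @export
run_pipeline <- function(mode, input = NULL, out_dir = ".", labels = NULL,
                         lexicon_paths = NULL, seed = 1, n_docs = 200,
                         ngram = 1:2, vocab_size = 1000, min_threshold = 0,
                         alpha = 1, k = 10,
                         eval_mode = c("kfold", "split", "halves"),
                         keyword_window = 5) {
  modes <- c("simulate", "tag", "extract", "train", "evaluate", "report")
  if (!is.character(mode) || length(mode) != 1 || !mode %in% modes) {
    stop_fm("unknown mode '%s' (expected one of: %s)",
            as.character(mode)[1], paste(modes, collapse = ", "))
  }
  eval_mode <- match.arg(eval_mode)
  # validate all paths before any work
  if (mode != "simulate") {
    if (is.null(input)) stop_fm("mode '%s' requires an input corpus", mode)
    if (!file.exists(input)) stop_fm("input file does not exist: '%s'", input)
  }
  if (mode %in% c("train", "evaluate")) {
    if (is.null(labels)) stop_fm("mode '%s' requires a labels file", mode)
    if (!file.exists(labels)) stop_fm("labels file does not exist: '%s'", labels)
  }
  if (!is.null(lexicon_paths)) {
    for (p in unlist(lexicon_paths)) {
      if (!file.exists(p)) stop_fm("lexicon file does not exist: '%s'", p)
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lexicon <- if (is.null(lexicon_paths)) default_lexicon()
             else load_lexicon(lexicon_paths)
  config <- list(mode = mode, input = input, labels = labels, seed = seed,
                 n_docs = n_docs, ngram = ngram, vocab_size = vocab_size,
                 min_threshold = min_threshold, alpha = alpha, k = k,
                 eval_mode = eval_mode, keyword_window = keyword_window)
  write_manifest(out_dir, mode, config, list(input = input, labels = labels))
  out <- list()

  if (mode == "simulate") {
    sim <- generate_corpus(generator_config(seed = seed, n_docs = n_docs),
                           lexicon)
    write_synthetic_corpus(sim, out_dir)
    out$simulation <- sim
    return(invisible(out))
  }

  corpus <- read_corpus_auto(input)
  out$corpus <- corpus

  if (mode == "tag") {
    ann <- annotate_corpus(corpus, lexicon, keyword_window)
    write_annotations(corpus, unname(ann),
                      file.path(out_dir, "annotations.json"))
    html <- vapply(corpus$documents, function(d) {
      sprintf("<h2>%s</h2>\n<p>%s</p>", d$doc_id,
              render_highlighted(d, ann[[d$doc_id]]))
    }, character(1))
    con <- file(file.path(out_dir, "highlights.html"), open = "wb")
    writeLines(enc2utf8(c("<!DOCTYPE html>", "<html><body>", html,
                          "</body></html>")), con, useBytes = TRUE)
    close(con)
    out$annotations <- ann
  } else if (mode == "extract") {
    ann <- annotate_corpus(corpus, lexicon, keyword_window)
    interactions <- collect_interactions(ann)
    write_tsv(interactions, file.path(out_dir, "interactions.tsv"))
    export_network(interactions, file.path(out_dir, "network.graphml"))
    out$annotations <- ann
    out$interactions <- interactions
  } else if (mode %in% c("train", "evaluate")) {
    lab <- read_labels_tsv(labels)
    ids <- doc_ids(corpus)
    if (!all(ids %in% lab$doc_id)) {
      stop_fm("labels file is missing labels for some documents")
    }
    y <- factor(lab$label[match(ids, lab$doc_id)])
    terms <- corpus_terms(corpus, lexicon, ngram = ngram)
    stats <- compute_stats(terms)
    bow <- build_bag_of_words(stats, vocab_size, min_threshold)
    out$bow <- bow
    if (mode == "train") {
      model <- train_nb(bow$matrix, y, alpha)
      write_nb_model(model, file.path(out_dir, "model.json"))
      write_tsv(data.frame(gram = bow$vocabulary, score = bow$scores),
                file.path(out_dir, "vocabulary.tsv"))
      write_tsv(token_category_counts(corpus, lexicon),
                file.path(out_dir, "token_counts.tsv"))
      out$model <- model
    } else {
      res <- switch(eval_mode,
                    kfold = cross_validate(bow$matrix, y, k = k, seed = seed,
                                           alpha = alpha),
                    split = split_validate(bow$matrix, y, train_frac = 0.4,
                                           seed = seed, alpha = alpha),
                    halves = split_validate(bow$matrix, y, train_frac = 0.5,
                                            seed = seed, alpha = alpha))
      report <- if (eval_mode == "kfold") res$pooled else res$report
      write_tsv(eval_report_df(report), file.path(out_dir, "eval_report.tsv"))
      payload <- list(
        mode = jsonlite::unbox(eval_mode),
        tp = jsonlite::unbox(report$tp), fp = jsonlite::unbox(report$fp),
        fn = jsonlite::unbox(report$fn), tn = jsonlite::unbox(report$tn),
        precision = jsonlite::unbox(report$precision),
        recall = jsonlite::unbox(report$recall),
        f_score = jsonlite::unbox(report$f_score),
        accuracy = jsonlite::unbox(report$accuracy),
        auc = jsonlite::unbox(res$auc))
      json <- jsonlite::toJSON(payload, digits = NA, pretty = TRUE,
                               na = "null")
      con <- file(file.path(out_dir, "eval_report.json"), open = "wb")
      writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
      close(con)
      if (!is.null(res$roc)) {
        write_tsv(as.data.frame(res$roc), file.path(out_dir, "roc.tsv"))
      }
      out$result <- res
    }
  } else if (mode == "report") {
    write_tsv(token_category_counts(corpus, lexicon),
              file.path(out_dir, "token_counts.tsv"))
  }
  invisible(out)
}
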