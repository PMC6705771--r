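# Deterministic synthetic abstracts with gold annotations: positive
# documents carry planted fusion mentions rendered in sampled surface
# dialects (separator and case variants) plus optional interaction and
# disease sentences; negative documents carry distractors only (hyphenated
# adjectives, year ranges, chemical names, standalone gene mentions).

DEFAULT_DIALECT_WEIGHTS <- c(
  hyphen_upper = 1 / 6, hyphen_lower = 1 / 6, hyphen_title = 1 / 6,
  slash_upper = 1 / 6, slash_lower = 1 / 6, colon_upper = 1 / 6
)

#' Configuration for the synthetic-corpus generator
#'
#' @param seed integer seed; the same configuration always yields
#'   byte-identical output.
#' @param n_docs number of documents (>= 1); positive and negative labels
#'   alternate, so the corpus is balanced by construction.
#' @param dialect_weights named probabilities over the surface dialects
#'   `{hyphen,slash,colon} x {upper,lower,title}` used to render planted
#'   fusions; must sum to 1.
#' @param p_interaction probability that a positive document carries an
#'   interaction sentence.
#' @param p_coordination probability that an interaction sentence uses a
#'   coordinated two-fusion form ("PARTNER VERB FUSION1 and FUSION2").
#' @param p_disease probability that a positive document carries a
#'   fusion-causes-disease sentence.
#' @param distractor_rate expected number of distractor sentences per
#'   document (Poisson).
#' @param template_set identifier of the packaged template set.
#' @return an object of class `fm_generator_config`.
#' @export
generator_config <- function(seed = 1, n_docs = 200,
                             dialect_weights = DEFAULT_DIALECT_WEIGHTS,
                             p_interaction = 0.6, p_coordination = 0.25,
                             p_disease = 0.4, distractor_rate = 2,
                             template_set = "default") {
  if (!is.numeric(n_docs) || n_docs < 1) stop_fm("n_docs must be >= 1")
  for (p in c(p_interaction, p_coordination, p_disease)) {
    if (p < 0 || p > 1) stop_fm("probabilities must be in [0, 1]")
  }
  if (distractor_rate < 0) stop_fm("distractor_rate must be >= 0")
  if (abs(sum(dialect_weights) - 1) > 1e-8) {
    stop_fm("dialect_weights must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 dialect_weights = dialect_weights,
                 p_interaction = p_interaction,
                 p_coordination = p_coordination, p_disease = p_disease,
                 distractor_rate = distractor_rate,
                 template_set = template_set),
            class = "fm_generator_config")
}

load_templates <- function(template_set = "default") {
  path <- system.file("extdata", "templates.tsv", package = "fusemine")
  tpl <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("set", "role", "text"),
                           stringsAsFactors = FALSE)
  tpl <- tpl[tpl$set == template_set, , drop = FALSE]
  if (nrow(tpl) == 0) stop_fm("unknown template set '%s'", template_set)
  tpl
}

# render a canonical fusion id ("BCR-ABL") in a surface dialect
render_dialect <- function(fusion_id, dialect) {
  genes <- strsplit(fusion_id, "-", fixed = TRUE)[[1]]
  # canonical ids with a numeric trailing part ("EWS-FLI1") split at the
  # first hyphen only
  if (length(genes) > 2) genes <- c(genes[1], paste(genes[-1], collapse = "-"))
  sep <- switch(sub("_.*", "", dialect),
                hyphen = "-", slash = "/", colon = ":")
  case <- sub(".*_", "", dialect)
  genes <- switch(case,
                  upper = toupper(genes),
                  lower = tolower(genes),
                  title = paste0(toupper(substr(genes, 1, 1)),
                                 tolower(substr(genes, 2, nchar(genes)))))
  paste(genes, collapse = sep)
}

# substitute {SLOT} placeholders left to right, recording 0-based spans of
# the slots named in `track`
fill_template <- function(template, values, track = c("FUSION", "FUSION2")) {
  text <- template
  spans <- list()
  repeat {
    m <- regexpr("\\{[A-Z0-9_]+\\}", text)
    if (m == -1) break
    slot <- substr(text, m + 1L, m + attr(m, "match.length") - 2L)
    value <- values[[slot]]
    if (is.null(value)) stop_fm("template slot '%s' has no value", slot)
    text <- paste0(substr(text, 1L, m - 1L), value,
                   substr(text, m + attr(m, "match.length"), nchar(text)))
    if (slot %in% track) {
      spans[[length(spans) + 1L]] <- list(slot = slot,
                                          start = as.integer(m) - 1L,
                                          end = as.integer(m) - 1L + nchar(value))
    }
  }
  list(text = text, spans = spans)
}

sample_one <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

#' Generate a synthetic corpus with gold annotations and labels
#'
#' Positive documents contain at least one planted fusion mention rendered in
#' a dialect sampled from `config$dialect_weights`, optionally an interaction
#' sentence ("PARTNER VERB FUSION", or a coordinated two-fusion form) and a
#' fusion-disease sentence; negative documents contain distractors only.
#' Gold annotations record every planted mention span (0-based, on the body),
#' its normalized identifier, and every planted interaction and disease
#' tuple. The generator draws from its own seeded RNG stream and leaves the
#' caller's random state untouched; the same configuration yields
#' byte-identical output.
#'
#' @param config an `fm_generator_config`.
#' @param lexicon an `fm_lexicon` providing fusion aliases, gene symbols,
#'   action verbs and disease terms.
#' @return a list of class `fm_simulation`: `corpus` (fm_corpus),
#'   `annotations` (named list of gold `fm_annotations`), `labels` (data
#'   frame doc_id, label).
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon = default_lexicon()) {
  stopifnot(inherits(config, "fm_generator_config"),
            inherits(lexicon, "fm_lexicon"))
  tpl <- load_templates(config$template_set)
  by_role <- split(tpl$text, tpl$role)
  fusion_ids <- lexicon$entries$fusion_alias$canonical
  gene_pool <- lexicon$entries$gene_symbol$canonical
  disease_pool <- unlist(lexicon$entries$disease_term$variants)
  verb_lemmas <- lexicon$entries$action_verb$canonical
  verb_lemmas <- setdiff(verb_lemmas, "cause")  # cause is for disease links
  verbal_by_lemma <- split(names(lexicon$action_verbal),
                           unname(lexicon$action_verbal))
  if (!length(fusion_ids)) stop_fm("lexicon has no fusion aliases to plant")

  docs <- vector("list", config$n_docs)
  annotations <- vector("list", config$n_docs)
  labels <- character(config$n_docs)

  with_local_seed(config$seed, {
    for (i in seq_len(config$n_docs)) {
      doc_id <- sprintf("SYN%04d", i)
      positive <- i %% 2 == 1
      labels[i] <- if (positive) "positive" else "negative"
      sentences <- character(0)
      planted <- list()        # per-sentence list of fusion spans
      interactions <- empty_interactions()
      disease_links <- empty_disease_links()
      title <- ""

      add_sentence <- function(filled, sentences, planted) {
        sentences[[length(sentences) + 1L]] <- filled$text
        planted[[length(sentences)]] <- filled$spans
        list(sentences = sentences, planted = planted)
      }

      if (positive) {
        fusion <- sample_one(fusion_ids)
        dialect <- sample(names(config$dialect_weights), 1,
                          prob = config$dialect_weights)
        surface <- render_dialect(fusion, dialect)
        keyword <- sample_one(unlist(lexicon$entries$fusion_keyword$variants))
        disease <- sample_one(disease_pool)
        title <- fill_template(sample_one(by_role$title_pos),
                               list(FUSION = surface, KEYWORD = keyword,
                                    DISEASE = disease))$text

        filled <- fill_template(
          sample_one(by_role$opener),
          list(FUSION = surface, KEYWORD = keyword, DISEASE = disease))
        st <- add_sentence(filled, sentences, planted)
        sentences <- st$sentences; planted <- st$planted
        fusion_by_sentence <- list(list(id = fusion))

        components <- toupper(unlist(strsplit(fusion_ids, "-")))
        if (stats::runif(1) < config$p_interaction) {
          partner <- sample_one(setdiff(gene_pool, components))
          lemma <- sample_one(verb_lemmas)
          verb <- sample_one(verbal_by_lemma[[lemma]])
          if (stats::runif(1) < config$p_coordination) {
            fusion2 <- sample_one(setdiff(fusion_ids, fusion))
            surface2 <- render_dialect(fusion2, sample(
              names(config$dialect_weights), 1,
              prob = config$dialect_weights))
            filled <- fill_template(
              sample_one(by_role$coordination),
              list(PARTNER = partner, VERB = verb, FUSION = surface,
                   FUSION2 = surface2))
            st <- add_sentence(filled, sentences, planted)
            sentences <- st$sentences; planted <- st$planted
            si <- length(sentences)
            interactions <- rbind(interactions, data.frame(
              fusion = c(fusion, fusion2), partner = partner,
              action = lemma, sentence_index = si,
              evidence = filled$text, stringsAsFactors = FALSE))
            planted[[si]] <- Map(function(sp, id) {
              sp$id <- id; sp
            }, planted[[si]], list(fusion, fusion2))
          } else {
            filled <- fill_template(
              sample_one(by_role$interaction),
              list(PARTNER = partner, VERB = verb, FUSION = surface,
                   KEYWORD = sample_one(unlist(lexicon$entries$fusion_keyword$variants))))
            st <- add_sentence(filled, sentences, planted)
            sentences <- st$sentences; planted <- st$planted
            si <- length(sentences)
            interactions <- rbind(interactions, data.frame(
              fusion = fusion, partner = partner, action = lemma,
              sentence_index = si, evidence = filled$text,
              stringsAsFactors = FALSE))
            planted[[si]] <- lapply(planted[[si]], function(sp) {
              sp$id <- fusion; sp
            })
          }
        }

        if (stats::runif(1) < config$p_disease) {
          disease2 <- sample_one(disease_pool)
          filled <- fill_template(
            sample_one(by_role$disease),
            list(FUSION = surface, DISEASE2 = disease2))
          st <- add_sentence(filled, sentences, planted)
          sentences <- st$sentences; planted <- st$planted
          si <- length(sentences)
          dz_canon <- lookup_variant(lexicon, disease2, "disease_term")
          mesh <- lexicon$mesh_map[tolower(dz_canon)]
          disease_links <- rbind(disease_links, data.frame(
            fusion = fusion, disease = dz_canon, action = "cause",
            sentence_index = si,
            mesh_id = ifelse(is.na(mesh), "", unname(mesh)),
            stringsAsFactors = FALSE))
          planted[[si]] <- lapply(planted[[si]], function(sp) {
            sp$id <- fusion; sp
          })
        }
        # default id for the opener sentence
        planted[[1]] <- lapply(planted[[1]], function(sp) {
          if (is.null(sp$id)) sp$id <- fusion
          sp
        })
        filler <- sample_one(by_role$filler_pos)
        st <- add_sentence(list(text = filler, spans = list()),
                           sentences, planted)
        sentences <- st$sentences; planted <- st$planted
      } else {
        title <- sample_one(by_role$title_neg)
        n_fill <- 1L + stats::rbinom(1, 1, 0.5)
        for (k in seq_len(n_fill)) {
          filler <- sample_one(by_role$filler_neg)
          st <- add_sentence(list(text = filler, spans = list()),
                             sentences, planted)
          sentences <- st$sentences; planted <- st$planted
        }
      }

      n_distract <- stats::rpois(1, config$distractor_rate)
      for (k in seq_len(n_distract)) {
        filled <- fill_template(
          sample_one(by_role$distractor),
          list(YEARRANGE = paste0(sample(2010:2020, 1), "-",
                                  sample(2021:2026, 1)),
               GENE = sample_one(gene_pool)))
        st <- add_sentence(filled, sentences, planted)
        sentences <- st$sentences; planted <- st$planted
      }

      body <- paste(unlist(sentences), collapse = " ")
      offsets <- c(0L, cumsum(nchar(unlist(sentences)) + 1L))
      mentions <- empty_mentions()
      for (si in seq_along(planted)) {
        for (sp in planted[[si]]) {
          mentions <- rbind(mentions, data.frame(
            start = offsets[si] + sp$start, end = offsets[si] + sp$end,
            label = "FUSION",
            surface = substr(body, offsets[si] + sp$start + 1L,
                             offsets[si] + sp$end),
            normalized_id = sp$id, stringsAsFactors = FALSE))
        }
      }
      docs[[i]] <- new_document(doc_id, title = title, body = body,
                                year = 2013L + (i %% 5))
      annotations[[i]] <- new_annotation_set(doc_id, mentions, interactions,
                                             disease_links)
    }
  })

  corpus <- new_corpus(docs, provenance = sprintf("synthetic:seed=%d",
                                                  config$seed))
  names(annotations) <- doc_ids(corpus)
  structure(list(corpus = corpus, annotations = annotations,
                 labels = data.frame(doc_id = doc_ids(corpus),
                                     label = labels,
                                     stringsAsFactors = FALSE),
                 config = config),
            class = "fm_simulation")
}

#' @export
print.fm_simulation <- function(x, ...) {
  cat(sprintf("<fm_simulation> %d documents (%d positive), seed %d\n",
              length(x$corpus), sum(x$labels$label == "positive"),
              x$config$seed))
  invisible(x)
}

#' Write a simulation to disk (MEDLINE + gold JSON + labels TSV)
#'
#' @param simulation an `fm_simulation` from [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return character vector of the three file paths, invisibly.
#' @export
write_synthetic_corpus <- function(simulation, dir) {
  stopifnot(inherits(simulation, "fm_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  medline <- file.path(dir, "corpus.medline")
  gold <- file.path(dir, "gold_annotations.json")
  labels <- file.path(dir, "labels.tsv")
  write_medline(simulation$corpus, medline)
  write_annotations(simulation$corpus, unname(simulation$annotations), gold)
  con <- file(labels, open = "wb")
  writeLines(c("doc_id\tlabel",
               paste(simulation$labels$doc_id, simulation$labels$label,
                     sep = "\t")), con, useBytes = TRUE)
  close(con)
  invisible(c(medline = medline, gold = gold, labels = labels))
}

#' Flip labels independently at a given rate
#'
#' @param labels character or factor vector with exactly two distinct values.
#' @param flip_rate probability in \[0, 1\] that each label is flipped to the
#'   other value.
#' @param seed integer seed.
#' @return vector of the same type with flipped entries.
#' @export
corrupt_labels <- function(labels, flip_rate, seed = 1) {
  if (flip_rate < 0 || flip_rate > 1) stop_fm("flip_rate must be in [0, 1]")
  vals <- sort(unique(as.character(labels)))
  if (length(vals) != 2) stop_fm("labels must take exactly two values")
  out <- as.character(labels)
  with_local_seed(seed, {
    flip <- stats::runif(length(out)) < flip_rate
    out[flip] <- ifelse(out[flip] == vals[1], vals[2], vals[1])
  })
  if (is.factor(labels)) factor(out, levels = levels(labels)) else out
}

#' Score detected fusion mentions against gold annotations
#'
#' A predicted FUSION mention is a true positive when a gold mention with the
#' same document, span and normalized identifier exists.
#'
#' @param predicted named list of `fm_annotations` (from [annotate_corpus()]).
#' @param gold named list of gold `fm_annotations`.
#' @return an `fm_eval` (tn is 0: true negatives are not defined for NER).
#' @export
score_fusion_ner <- function(predicted, gold) {
  key <- function(sets) {
    out <- character(0)
    for (a in sets) {
      m <- a$mentions[a$mentions$label == "FUSION", , drop = FALSE]
      if (nrow(m)) {
        out <- c(out, paste(a$doc_id, m$start, m$end, m$normalized_id,
                            sep = "|"))
      }
    }
    unique(out)
  }
  pk <- key(predicted)
  gk <- key(gold)
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  structure(list(tp = tp, fp = fp, fn = fn, tn = 0L,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 f_score = if (tp > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
                 accuracy = NA_real_, positive_label = "FUSION"),
            class = "fm_eval")
}
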