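# Fusion-mention detection across surface dialects, normalization to
# canonical identifiers, sentence-level linking of fusions to interaction
# partners and diseases, and export of literature-evidence networks.

first_separator <- function(surface) {
  m <- regmatches(surface, regexpr("[-–—/:]", surface))
  if (length(m)) m else NA_character_
}

# token indices covered by any fusion-keyword variant (multi-word aware)
keyword_token_indices <- function(tokens, lexicon) {
  if (nrow(tokens) == 0 || !length(lexicon$keyword_seqs)) return(integer(0))
  lower <- tolower(tokens$surface)
  hits <- integer(0)
  for (seq in lexicon$keyword_seqs) {
    L <- length(seq)
    if (L > length(lower)) next
    for (i in seq_len(length(lower) - L + 1L)) {
      if (all(lower[i:(i + L - 1L)] == seq)) hits <- c(hits, i:(i + L - 1L))
    }
  }
  sort(unique(hits))
}

empty_fusion_mentions <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             separator = character(), surface = character(),
             start = integer(), end = integer(),
             normalized_id = character(), keyword_support = logical(),
             route = character(), token_index = integer(),
             stringsAsFactors = FALSE)
}

#' Normalize a fusion surface form to its canonical identifier
#'
#' Case-folds, maps every accepted separator (hyphen, en/em dash, slash,
#' colon) to a hyphen via the ordered normalization rules of the lexicon's
#' rule base, resolves the whole form through the fusion-alias table, and
#' otherwise resolves each part through the gene-symbol table. The result is
#' `GENEA-GENEB` in uppercase; the operation is idempotent.
#'
#' @param surface_form fusion surface form, e.g. `"bcr/abl"`.
#' @param lexicon an `fm_lexicon`.
#' @return the normalized identifier, e.g. `"BCR-ABL"`.
#' @export
normalize_fusion <- function(surface_form, lexicon) {
  stopifnot(is.character(surface_form), length(surface_form) == 1,
            inherits(lexicon, "fm_lexicon"))
  norm <- surface_form
  rules <- lexicon$rule_base$normalization_rules
  for (i in seq_len(nrow(rules))) {
    norm <- gsub(rules$pattern[i], rules$replacement[i], norm, perl = TRUE)
  }
  norm <- normalize_surface_basic(norm)
  alias <- lookup_variant(lexicon, norm, "fusion_alias")
  if (!is.na(alias)) return(alias)
  parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2) {
    stop_fm("'%s' is not a two-part fusion surface form", surface_form)
  }
  gm <- lexicon$variant_map$gene_symbol
  a <- gm[parts[1]]
  b <- gm[parts[2]]
  if (is.na(a) || is.na(b)) {
    stop_fm("cannot normalize fusion '%s': unresolvable gene part '%s'",
            surface_form, parts[if (is.na(a)) 1 else 2])
  }
  id <- paste0(toupper(a), "-", toupper(b))
  alias <- lookup_variant(lexicon, id, "fusion_alias")
  if (!is.na(alias)) alias else id
}

#' Detect fusion-protein mentions in a tokenized sentence
#'
#' A token is emitted as a fusion mention when (a) it has the shape
#' `GENE SEP GENE` with both parts resolving to gene symbols (a fusion
#' embedded in a longer hyphen chain, e.g. `BCR-ABL-selective`, is detected
#' through its first two parts, with the full surface recorded), and (b) a
#' fusion keyword occurs in the same sentence within `keyword_window` tokens,
#' OR the form (or its first two parts) matches a known fusion alias — a
#' dictionary hit requires no keyword. Tokens with a non-gene part on either
#' side are ignored.
#'
#' @param tokens token table for one sentence (from [tokenize()]).
#' @param lexicon an `fm_lexicon`.
#' @param keyword_window token-distance window for keyword support.
#' @return data frame of mentions with columns gene_a, gene_b, separator,
#'   surface, start, end (spans into the sentence), normalized_id,
#'   keyword_support (keyword found within the window), route
#'   (`"keyword"` or `"alias"`), token_index.
#' @export
detect_fusion_mentions <- function(tokens, lexicon, keyword_window = 5) {
  stopifnot(is.data.frame(tokens), inherits(lexicon, "fm_lexicon"))
  out <- empty_fusion_mentions()
  if (nrow(tokens) == 0) return(out)
  kw_idx <- keyword_token_indices(tokens, lexicon)
  gm <- lexicon$variant_map$gene_symbol
  for (i in seq_len(nrow(tokens))) {
    s <- tokens$surface[i]
    if (!contains_separator(s)) next
    norm <- normalize_surface_basic(s)
    parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
    alias <- lookup_variant(lexicon, norm, "fusion_alias")
    pair_alias <- NA_character_
    a <- b <- NA_character_
    if (is.na(alias) && length(parts) >= 2) {
      a <- unname(gm[parts[1]])
      b <- unname(gm[parts[2]])
      if (!is.na(a) && !is.na(b)) {
        pair_alias <- lookup_variant(lexicon,
                                     paste0(parts[1], "-", parts[2]),
                                     "fusion_alias")
      }
    }
    has_keyword <- length(kw_idx) > 0 && any(abs(kw_idx - i) <= keyword_window)
    if (!is.na(alias)) {
      normalized <- alias
      route <- "alias"
    } else if (!is.na(a) && !is.na(b)) {
      if (!is.na(pair_alias)) {
        normalized <- pair_alias
        route <- "alias"
      } else if (has_keyword) {
        normalized <- paste0(toupper(a), "-", toupper(b))
        route <- "keyword"
      } else {
        next
      }
    } else {
      next
    }
    norm_parts <- strsplit(normalized, "-", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(
      gene_a = if (!is.na(a)) a else norm_parts[1],
      gene_b = if (!is.na(b)) b else paste(norm_parts[-1], collapse = "-"),
      separator = first_separator(s),
      surface = s,
      start = tokens$start[i], end = tokens$end[i],
      normalized_id = normalized,
      keyword_support = has_keyword,
      route = route,
      token_index = i,
      stringsAsFactors = FALSE))
  }
  out
}

empty_interaction_mentions <- function() {
  data.frame(fusion = character(), partner = character(),
             action = character(), sentence_index = integer(),
             evidence = character(), stringsAsFactors = FALSE)
}

# indices of tokens whose surface is a *verbal* action-verb variant
action_token_indices <- function(tokens, lexicon) {
  lower <- tolower(tokens$surface)
  idx <- which(lower %in% names(lexicon$action_verbal))
  lemma <- unname(lexicon$action_verbal[lower[idx]])
  list(idx = idx, lemma = lemma)
}

#' Detect fusion-partner interaction statements in a sentence
#'
#' For each detected fusion mention, emits one interaction tuple per (verbal
#' action token, partner gene token) pair in the same sentence. A partner is
#' a gene-symbol token that is not a component of any fusion mention in the
#' sentence (no self-partners). A single action verb distributes over a
#' coordinated list of fusions, yielding one tuple per fusion. Only verbal
#' variants of the action lexicon (lemma, -s, -ed, irregular past, -ing)
#' trigger interactions; nominal forms such as "activation" do not.
#'
#' @param tokens token table for one sentence.
#' @param fusion_mentions output of [detect_fusion_mentions()] for the same
#'   sentence.
#' @param lexicon an `fm_lexicon`.
#' @param sentence_text the sentence text, recorded as evidence.
#' @param sentence_index 1-based sentence index within the document.
#' @return data frame with columns fusion, partner, action, sentence_index,
#'   evidence.
#' @export
detect_interactions <- function(tokens, fusion_mentions, lexicon,
                                sentence_text = "", sentence_index = 1L) {
  stopifnot(inherits(lexicon, "fm_lexicon"))
  out <- empty_interaction_mentions()
  if (nrow(fusion_mentions) == 0 || nrow(tokens) == 0) return(out)
  act <- action_token_indices(tokens, lexicon)
  if (length(act$idx) == 0) return(out)
  gm <- lexicon$variant_map$gene_symbol
  lower <- tolower(tokens$surface)
  gene_canon <- unname(gm[lower])
  fusion_components <- toupper(unique(c(fusion_mentions$gene_a,
                                        fusion_mentions$gene_b)))
  partner_idx <- which(!is.na(gene_canon) &
                         !seq_len(nrow(tokens)) %in% fusion_mentions$token_index &
                         !toupper(gene_canon) %in% fusion_components)
  if (length(partner_idx) == 0) return(out)
  for (f in seq_len(nrow(fusion_mentions))) {
    for (k in seq_along(act$idx)) {
      for (p in partner_idx) {
        out <- rbind(out, data.frame(
          fusion = fusion_mentions$normalized_id[f],
          partner = gene_canon[p],
          action = act$lemma[k],
          sentence_index = as.integer(sentence_index),
          evidence = trimws(sentence_text),
          stringsAsFactors = FALSE))
      }
    }
  }
  unique(out)
}

empty_disease_link <- function() empty_disease_links()

# non-overlapping longest-first disease term matches over token surfaces
disease_matches <- function(tokens, lexicon) {
  out <- data.frame(first = integer(), last = integer(),
                    canonical = character(), stringsAsFactors = FALSE)
  if (nrow(tokens) == 0 || !length(lexicon$disease_seqs)) return(out)
  lower <- tolower(tokens$surface)
  seqs <- lexicon$disease_seqs
  lens <- vapply(seqs, function(s) length(s$tokens), integer(1))
  covered <- logical(length(lower))
  for (s in seqs[order(-lens)]) {
    L <- length(s$tokens)
    if (L > length(lower)) next
    for (i in seq_len(length(lower) - L + 1L)) {
      span <- i:(i + L - 1L)
      if (any(covered[span])) next
      if (all(lower[span] == s$tokens)) {
        covered[span] <- TRUE
        out <- rbind(out, data.frame(first = i, last = i + L - 1L,
                                     canonical = s$canonical,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$first), , drop = FALSE]
}

#' Detect fusion-disease statements in a sentence
#'
#' Emits one (fusion, disease term, action verb) triple per same-sentence
#' co-occurrence of a fusion mention, a disease-lexicon term (longest match,
#' multi-word aware) and a verbal action token.
#'
#' @inheritParams detect_interactions
#' @return data frame with columns fusion, disease, action, sentence_index,
#'   mesh_id.
#' @export
detect_disease_links <- function(tokens, fusion_mentions, lexicon,
                                 sentence_index = 1L) {
  out <- empty_disease_links()
  if (nrow(fusion_mentions) == 0 || nrow(tokens) == 0) return(out)
  dz <- disease_matches(tokens, lexicon)
  if (nrow(dz) == 0) return(out)
  act <- action_token_indices(tokens, lexicon)
  if (length(act$idx) == 0) return(out)
  for (f in seq_len(nrow(fusion_mentions))) {
    for (d in seq_len(nrow(dz))) {
      for (k in seq_along(act$idx)) {
        mesh <- lexicon$mesh_map[tolower(dz$canonical[d])]
        out <- rbind(out, data.frame(
          fusion = fusion_mentions$normalized_id[f],
          disease = dz$canonical[d],
          action = act$lemma[k],
          sentence_index = as.integer(sentence_index),
          mesh_id = ifelse(is.na(mesh), "", unname(mesh)),
          stringsAsFactors = FALSE))
      }
    }
  }
  unique(out)
}

#' Annotate one document end to end
#'
#' Splits the body into sentences, tokenizes, detects fusion mentions,
#' interaction statements and disease links, and collects document-level
#' mention spans for fusions (`FUSION`), standalone gene symbols (`GENE`),
#' action tokens (`ACTION`) and disease terms (`DISEASE`).
#'
#' @param document an `fm_document`.
#' @param lexicon an `fm_lexicon`.
#' @param keyword_window token window for fusion-keyword support.
#' @return an `fm_annotations`.
#' @export
annotate_document <- function(document, lexicon, keyword_window = 5) {
  stopifnot(inherits(document, "fm_document"), inherits(lexicon, "fm_lexicon"))
  sentences <- split_sentences(document)
  mentions <- empty_mentions()
  interactions <- empty_interaction_mentions()
  disease_links <- empty_disease_links()
  gm <- lexicon$variant_map$gene_symbol
  for (si in seq_len(nrow(sentences))) {
    stext <- sentences$text[si]
    offset <- sentences$start[si]
    tokens <- tokenize(stext)
    if (nrow(tokens) == 0) next
    fus <- detect_fusion_mentions(tokens, lexicon, keyword_window)
    inter <- detect_interactions(tokens, fus, lexicon,
                                 sentence_text = stext, sentence_index = si)
    dzl <- detect_disease_links(tokens, fus, lexicon, sentence_index = si)
    interactions <- rbind(interactions, inter)
    disease_links <- rbind(disease_links, dzl)
    if (nrow(fus)) {
      mentions <- rbind(mentions, data.frame(
        start = fus$start + offset, end = fus$end + offset,
        label = "FUSION", surface = fus$surface,
        normalized_id = fus$normalized_id, stringsAsFactors = FALSE))
    }
    lower <- tolower(tokens$surface)
    gene_canon <- unname(gm[lower])
    g_idx <- which(!is.na(gene_canon) &
                     !seq_len(nrow(tokens)) %in% fus$token_index)
    if (length(g_idx)) {
      mentions <- rbind(mentions, data.frame(
        start = tokens$start[g_idx] + offset, end = tokens$end[g_idx] + offset,
        label = "GENE", surface = tokens$surface[g_idx],
        normalized_id = gene_canon[g_idx], stringsAsFactors = FALSE))
    }
    a_idx <- which(lower %in% names(lexicon$action_all))
    if (length(a_idx)) {
      mentions <- rbind(mentions, data.frame(
        start = tokens$start[a_idx] + offset, end = tokens$end[a_idx] + offset,
        label = "ACTION", surface = tokens$surface[a_idx],
        normalized_id = unname(lexicon$action_all[lower[a_idx]]),
        stringsAsFactors = FALSE))
    }
    dz <- disease_matches(tokens, lexicon)
    if (nrow(dz)) {
      mentions <- rbind(mentions, data.frame(
        start = tokens$start[dz$first] + offset,
        end = tokens$end[dz$last] + offset,
        label = "DISEASE",
        surface = substring(stext, tokens$start[dz$first] + 1L,
                            tokens$end[dz$last]),
        normalized_id = dz$canonical, stringsAsFactors = FALSE))
    }
  }
  mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  rownames(mentions) <- NULL
  new_annotation_set(document$doc_id, mentions, interactions, disease_links)
}

#' Annotate every document in a corpus
#'
#' @param corpus an `fm_corpus`.
#' @param lexicon an `fm_lexicon`.
#' @param keyword_window token window for fusion-keyword support.
#' @return named list of `fm_annotations` in corpus order.
#' @export
annotate_corpus <- function(corpus, lexicon, keyword_window = 5) {
  stopifnot(inherits(corpus, "fm_corpus"))
  out <- lapply(corpus$documents, annotate_document, lexicon = lexicon,
                keyword_window = keyword_window)
  names(out) <- doc_ids(corpus)
  out
}

#' Pool the interaction tuples of many annotation sets
#'
#' @param annotation_sets list of `fm_annotations`.
#' @return data frame with a `doc_id` column prepended.
#' @export
collect_interactions <- function(annotation_sets) {
  rows <- lapply(annotation_sets, function(a) {
    if (nrow(a$interactions) == 0) return(NULL)
    cbind(data.frame(doc_id = a$doc_id, stringsAsFactors = FALSE),
          a$interactions)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(cbind(data.frame(doc_id = character(), stringsAsFactors = FALSE),
                 empty_interaction_mentions()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an evidence network of extracted interactions
#'
#' Builds an undirected graph whose nodes are normalized fusions and partner
#' gene symbols and whose edges carry the supporting action lemmas and
#' document ids (duplicate evidence for one pair is merged onto a single
#' edge). Writes GraphML to `path` and a TSV edge list alongside it
#' (same path with a `.tsv` extension). Node and edge order are
#' deterministic (lexicographic).
#'
#' @param interaction_mentions data frame from [collect_interactions()]
#'   (columns doc_id, fusion, partner, action, ...).
#' @param path output GraphML path.
#' @return invisibly, the igraph object written.
#' @export
export_network <- function(interaction_mentions, path) {
  im <- interaction_mentions
  tsv_path <- paste0(tools::file_path_sans_ext(path), ".tsv")
  if (is.null(im) || nrow(im) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
    utils::write.table(
      data.frame(fusion = character(), partner = character(),
                 actions = character(), doc_ids = character(),
                 n_evidence = integer()),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(g))
  }
  key <- paste(im$fusion, im$partner, sep = "\t")
  agg <- lapply(split(im, key), function(d) {
    data.frame(fusion = d$fusion[1], partner = d$partner[1],
               actions = paste(sort(unique(d$action)), collapse = ","),
               doc_ids = paste(sort(unique(d$doc_id)), collapse = ","),
               n_evidence = nrow(d), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  edges <- edges[order(edges$fusion, edges$partner), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$fusion, edges$partner)))
  node_type <- ifelse(nodes %in% edges$fusion, "fusion", "gene")
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, type = node_type,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  utils::write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(g)
}
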