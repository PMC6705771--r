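# Synonym dictionaries and the normalization / regular-expression rule base.
#
# Five kinds of synonym entries are supported: fusion_keyword, action_verb,
# fusion_alias, gene_symbol and disease_term. Each lexicon TSV holds one entry
# per line as `canonical TAB variant1|variant2|...`; matching is always
# case-insensitive and, for fusion aliases, separator-insensitive.

ENTRY_KINDS <- c("fusion_keyword", "action_verb", "fusion_alias",
                 "gene_symbol", "disease_term")

# irregular past forms used when deciding whether an action variant is verbal
IRREGULAR_PAST <- c(bind = "bound", find = "found", break_ = "broke")

parse_lexicon_tsv <- function(path, kind) {
  lines <- fm_read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(canonical = character(), variants = I(list()),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    stop_fm("malformed %s lexicon line (expected canonical TAB variants): '%s'",
            kind, lines[which(bad)[1]])
  }
  canonical <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  variants <- lapply(parts, function(p) {
    v <- trimws(strsplit(p[[2]], "|", fixed = TRUE)[[1]])
    v[nzchar(v)]
  })
  if (any(!nzchar(canonical))) stop_fm("empty canonical in %s lexicon", kind)
  if (any(lengths(variants) == 0)) {
    stop_fm("entry '%s' in %s lexicon has no variants",
            canonical[which(lengths(variants) == 0)[1]], kind)
  }
  data.frame(canonical = canonical, variants = I(variants),
             stringsAsFactors = FALSE)
}

# variant (lowercased, optionally separator-normalized) -> canonical
build_variant_map <- function(entries, kind, normalize_separators = FALSE) {
  if (nrow(entries) == 0) return(character(0))
  keys <- lapply(entries$variants, function(v) {
    k <- tolower(v)
    if (normalize_separators) k <- normalize_surface_basic(k)
    unique(k)
  })
  map <- rep(entries$canonical, lengths(keys))
  names(map) <- unlist(keys)
  dup <- duplicated(names(map))
  if (any(dup)) {
    v <- names(map)[dup][1]
    canons <- unique(map[names(map) == v])
    if (length(canons) > 1) {
      stop_fm("variant '%s' in %s lexicon maps to two canonicals: '%s' and '%s'",
              v, kind, canons[1], canons[2])
    }
    map <- map[!dup]
  }
  map
}

#' Expand an action-verb lemma into its morphological surface variants
#'
#' Applies the suffix rules -s/-es, -d/-ed, -ing, -ion/-ation and -or/-er with
#' standard e-drop. The output always contains the lemma itself, is lowercase
#' and deduplicated. Over-generation (non-words such as "binded") is harmless:
#' packaged lexicons list curated variants, and this helper exists to build or
#' extend them.
#'
#' @param verb_lemma a single alphabetic lemma, e.g. `"activate"`.
#' @return character vector of lowercase variants including the lemma.
#' @examples
#' expand_morphology("activate")
#' @export
expand_morphology <- function(verb_lemma) {
  if (!is.character(verb_lemma) || length(verb_lemma) != 1 ||
      !nzchar(verb_lemma) || !grepl("^[A-Za-z]+$", verb_lemma)) {
    stop_fm("expand_morphology() needs a single non-empty alphabetic lemma")
  }
  w <- tolower(verb_lemma)
  ends_e <- grepl("e$", w) && !grepl("ee$", w)
  out <- c(
    w,
    if (grepl("(s|x|z|ch|sh)$", w)) paste0(w, "es") else paste0(w, "s"),
    if (grepl("e$", w)) paste0(w, "d") else paste0(w, "ed"),
    if (ends_e) paste0(sub("e$", "", w), "ing") else paste0(w, "ing"),
    if (grepl("ate$", w)) sub("ate$", "ation", w)
    else if (grepl("e$", w)) paste0(sub("e$", "", w), "ion")
    else c(paste0(w, "ion"), paste0(w, "ation")),
    if (grepl("e$", w)) c(paste0(w, "r"), paste0(sub("e$", "", w), "or"))
    else c(paste0(w, "er"), paste0(w, "or")),
    unname(IRREGULAR_PAST[w])
  )
  unique(out[!is.na(out)])
}

# verbal variants of a lemma: lemma, -s/-es, -d/-ed, -ing, irregular past
verbal_variants <- function(lemma) {
  w <- tolower(lemma)
  ends_e <- grepl("e$", w) && !grepl("ee$", w)
  out <- c(
    w,
    if (grepl("(s|x|z|ch|sh)$", w)) paste0(w, "es") else paste0(w, "s"),
    if (grepl("e$", w)) paste0(w, "d") else paste0(w, "ed"),
    if (ends_e) paste0(sub("e$", "", w), "ing") else paste0(w, "ing"),
    unname(IRREGULAR_PAST[w])
  )
  unique(out[!is.na(out)])
}

new_rule_base <- function(normalization_rules, token_patterns) {
  structure(list(normalization_rules = normalization_rules,
                 token_patterns = token_patterns),
            class = "fm_rulebase")
}

parse_rule_base_tsv <- function(path) {
  lines <- fm_read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop_fm("malformed rule-base line (expected name TAB pattern TAB attributes): '%s'",
            lines[which(bad)[1]])
  }
  name <- vapply(parts, `[[`, character(1), 1)
  pattern <- vapply(parts, `[[`, character(1), 2)
  attrs <- vapply(parts, `[[`, character(1), 3)
  is_norm <- startsWith(name, "normalize_")
  new_rule_base(
    normalization_rules = data.frame(
      name = name[is_norm], pattern = pattern[is_norm],
      replacement = attrs[is_norm], stringsAsFactors = FALSE),
    token_patterns = data.frame(
      name = name[!is_norm], pattern = pattern[!is_norm],
      attributes = attrs[!is_norm], stringsAsFactors = FALSE)
  )
}

#' Compile a rule base into an order-stable matcher set
#'
#' Validates that every regular expression in the rule base compiles and
#' returns a matcher set holding the patterns in their original order.
#' Compilation is idempotent: compiling an already-compiled set returns an
#' equal object.
#'
#' @param rule_base an `fm_rulebase` (see [load_lexicon()]) or an already
#'   compiled matcher set.
#' @return an object of class `fm_compiled_rules`.
#' @export
compile_rules <- function(rule_base) {
  if (inherits(rule_base, "fm_compiled_rules")) return(rule_base)
  if (!inherits(rule_base, "fm_rulebase")) {
    stop_fm("compile_rules() expects an fm_rulebase")
  }
  check <- function(name, pattern) {
    ok <- tryCatch({grepl(pattern, "", perl = TRUE); TRUE},
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop_fm("invalid regular expression in rule '%s': %s", name, pattern)
  }
  with(rule_base$normalization_rules, mapply(check, name, pattern))
  with(rule_base$token_patterns, mapply(check, name, pattern))
  structure(list(normalization_rules = rule_base$normalization_rules,
                 token_patterns = rule_base$token_patterns),
            class = "fm_compiled_rules")
}

read_word_list <- function(path) {
  lines <- trimws(fm_read_lines(path))
  unique(tolower(lines[nzchar(lines) & !startsWith(lines, "#")]))
}

#' Load a lexicon from TSV dictionaries and a rule base
#'
#' Each synonym TSV holds one entry per line: `canonical TAB
#' variant1|variant2|...`. Blank lines are ignored; a variant occurring under
#' two different canonicals within one entry kind is a hard error naming the
#' collision. Word-list files (stopwords, adjective lists) hold one lowercase
#' word per line. The rule-base TSV holds `name TAB pattern TAB attributes`
#' rows; rows whose name starts with `normalize_` are ordered normalization
#' rules (attributes column = replacement), the rest are token patterns.
#'
#' @param paths named list of file paths. Recognized names:
#'   `fusion_keyword`, `action_verb`, `fusion_alias`, `gene_symbol`,
#'   `disease_term` (synonym TSVs); `rule_base` (rule TSV); `stopwords`,
#'   `domain_adjectives`, `evaluative_adjectives` (word lists); `mesh_map`
#'   (term TAB MeSH-id TSV). Missing names yield empty components.
#' @return an object of class `fm_lexicon`.
#' @seealso [default_lexicon()] for the packaged dictionaries.
#' @export
load_lexicon <- function(paths = list()) {
  stopifnot(is.list(paths))
  entries <- list()
  variant_map <- list()
  for (kind in ENTRY_KINDS) {
    if (!is.null(paths[[kind]])) {
      entries[[kind]] <- parse_lexicon_tsv(paths[[kind]], kind)
    } else {
      entries[[kind]] <- data.frame(canonical = character(),
                                    variants = I(list()),
                                    stringsAsFactors = FALSE)
    }
    variant_map[[kind]] <- build_variant_map(
      entries[[kind]], kind,
      normalize_separators = kind == "fusion_alias")
  }

  rule_base <- if (!is.null(paths$rule_base)) {
    parse_rule_base_tsv(paths$rule_base)
  } else {
    new_rule_base(
      data.frame(name = character(), pattern = character(),
                 replacement = character(), stringsAsFactors = FALSE),
      data.frame(name = character(), pattern = character(),
                 attributes = character(), stringsAsFactors = FALSE))
  }

  stopwords <- if (!is.null(paths$stopwords)) read_word_list(paths$stopwords) else character(0)
  domain_adj <- if (!is.null(paths$domain_adjectives)) read_word_list(paths$domain_adjectives) else character(0)
  eval_adj <- if (!is.null(paths$evaluative_adjectives)) read_word_list(paths$evaluative_adjectives) else character(0)

  mesh_map <- character(0)
  if (!is.null(paths$mesh_map)) {
    lines <- fm_read_lines(paths$mesh_map)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      mesh_map <- vapply(parts, `[[`, character(1), 2)
      names(mesh_map) <- tolower(vapply(parts, `[[`, character(1), 1))
    }
  }

  # action-verb derived structures: verbal variant -> lemma (interaction
  # triggers) and any variant or its stem -> lemma (Function categorization)
  av <- entries$action_verb
  action_all <- build_variant_map(av, "action_verb")
  action_verbal <- character(0)
  if (nrow(av)) {
    vv <- lapply(av$canonical, verbal_variants)
    action_verbal <- rep(av$canonical, lengths(vv))
    names(action_verbal) <- unlist(vv)
    # keep only verbal forms that are actually listed variants of the lemma
    keep <- names(action_verbal) %in% names(action_all) &
      action_all[names(action_verbal)] == action_verbal
    action_verbal <- action_verbal[keep]
  }
  action_stems <- character(0)
  if (length(action_all)) {
    action_stems <- action_all
    names(action_stems) <- stem_porter2(names(action_all))
    action_stems <- action_stems[!duplicated(names(action_stems))]
  }

  # fusion keywords as lowercase token sequences (for multi-word matching)
  kw <- entries$fusion_keyword
  keyword_seqs <- list()
  if (nrow(kw)) {
    keyword_seqs <- lapply(tolower(unlist(kw$variants)),
                           function(v) strsplit(v, " +")[[1]])
  }

  # disease variants as token sequences
  dz <- entries$disease_term
  disease_seqs <- list()
  if (nrow(dz)) {
    all_var <- unlist(dz$variants)
    disease_seqs <- Map(function(v, canon) {
      list(tokens = strsplit(tolower(v), " +")[[1]], canonical = canon)
    }, all_var, rep(dz$canonical, lengths(dz$variants)))
    names(disease_seqs) <- NULL
  }

  structure(list(
    entries = entries,
    variant_map = variant_map,
    rule_base = rule_base,
    compiled = compile_rules(rule_base),
    stopwords = stopwords,
    domain_adjectives = domain_adj,
    evaluative_adjectives = eval_adj,
    mesh_map = mesh_map,
    action_all = action_all,
    action_verbal = action_verbal,
    action_stems = action_stems,
    keyword_seqs = keyword_seqs,
    disease_seqs = disease_seqs
  ), class = "fm_lexicon")
}

#' Load the lexicons packaged with the package
#'
#' The packaged dictionaries are recreations seeded from tokens printed in the
#' fusion-protein literature (fusion keywords, common PPI action verbs with
#' curated morphological variants, well-known fusion aliases such as
#' EWS-FLI1 / TMPRSS2-ERG / BCR-ABL, an HGNC-style gene-symbol list sufficient
#' for testing, and cancer terms with MeSH identifiers). Users can extend any
#' of them by passing their own files to [load_lexicon()].
#'
#' @return an `fm_lexicon`.
#' @export
default_lexicon <- function() {
  d <- system.file("extdata", "lexicons", package = "fusemine")
  load_lexicon(list(
    fusion_keyword = file.path(d, "fusion_keywords.tsv"),
    action_verb = file.path(d, "action_verbs.tsv"),
    fusion_alias = file.path(d, "fusion_aliases.tsv"),
    gene_symbol = file.path(d, "gene_symbols.tsv"),
    disease_term = file.path(d, "disease_terms.tsv"),
    rule_base = file.path(d, "rulebase.tsv"),
    stopwords = file.path(d, "stopwords.txt"),
    domain_adjectives = file.path(d, "domain_adjectives.txt"),
    evaluative_adjectives = file.path(d, "evaluative_adjectives.txt"),
    mesh_map = file.path(d, "mesh_map.tsv")
  ))
}

#' Look up the canonical form of a lexicon variant
#'
#' @param lexicon an `fm_lexicon`.
#' @param variant character vector of surface variants (case-insensitive).
#' @param kind one of the entry kinds, e.g. `"gene_symbol"`.
#' @return character vector of canonicals (`NA` where not found).
#' @export
lookup_variant <- function(lexicon, variant, kind) {
  stopifnot(inherits(lexicon, "fm_lexicon"), kind %in% ENTRY_KINDS)
  key <- tolower(variant)
  if (kind == "fusion_alias") key <- normalize_surface_basic(key)
  unname(lexicon$variant_map[[kind]][key])
}

#' @export
print.fm_lexicon <- function(x, ...) {
  cat("<fm_lexicon>\n")
  for (kind in ENTRY_KINDS) {
    cat(sprintf("  %-15s %4d entries, %4d variants\n", kind,
                nrow(x$entries[[kind]]), length(x$variant_map[[kind]])))
  }
  cat(sprintf("  rules: %d normalization, %d token patterns\n",
              nrow(x$rule_base$normalization_rules),
              nrow(x$rule_base$token_patterns)))
  cat(sprintf("  stopwords: %d; domain adj: %d; evaluative adj: %d; MeSH: %d\n",
              length(x$stopwords), length(x$domain_adjectives),
              length(x$evaluative_adjectives), length(x$mesh_map)))
  invisible(x)
}
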