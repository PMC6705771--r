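# Sentence splitting, tokenization, stemming, entity blanking and the
# four-way token categorization (Biological / Miscellaneous / Function /
# Literal).

DEFAULT_ABBREVIATIONS <- c("e.g", "i.e", "vs", "etc", "fig", "figs", "dr",
                           "prof", "al", "no", "ref", "approx", "ca", "cf",
                           "resp", "incl")

#' Split a document body into sentences
#'
#' Deterministic rule-based splitting: a sentence boundary is terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace and a capital letter or
#' digit, unless the word before the punctuation is on the abbreviation
#' stop-list. Sentence spans are 0-based, half-open, and tile the body in
#' order without gaps or overlap (inter-sentence whitespace belongs to the
#' preceding sentence's span).
#'
#' @param document an `fm_document`, or a plain character string.
#' @param abbreviations lowercase abbreviation stop-list (without the final
#'   period).
#' @return data frame with columns `index` (1-based), `start`, `end`, `text`
#'   (the exact body substring of the span).
#' @export
split_sentences <- function(document, abbreviations = DEFAULT_ABBREVIATIONS) {
  body <- if (inherits(document, "fm_document")) document$body else document
  stopifnot(is.character(body), length(body) == 1)
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (!nzchar(body)) return(empty)
  n <- nchar(body)
  # candidate boundaries: run of .!? followed by whitespace + capital/digit
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[A-Z0-9])", body, perl = TRUE)[[1]]
  starts <- 0L
  if (m[1] != -1) {
    for (k in seq_along(m)) {
      punct_start <- m[k]
      punct_end <- punct_start + attr(m, "match.length")[k] - 1L
      # word immediately before the punctuation
      prefix <- substr(body, 1L, punct_start - 1L)
      word <- regmatches(prefix, regexpr("[A-Za-z.]+$", prefix))
      word <- if (length(word)) tolower(sub("\\.$", "", word)) else ""
      if (word %in% abbreviations) next
      # next sentence starts after the trailing whitespace
      rest <- substr(body, punct_end + 1L, n)
      ws <- attr(regexpr("^[ \t\r\n]+", rest), "match.length")
      starts <- c(starts, punct_end + ws)
    }
  }
  starts <- unique(starts)
  ends <- c(starts[-1], n)
  data.frame(index = seq_along(starts), start = starts, end = ends,
             text = substring(body, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Tokenize text into word tokens with character spans
#'
#' Splits on whitespace and punctuation, except that internal hyphens
#' (including en/em dashes), slashes and colons joining alphanumeric runs are
#' kept inside one token, so fusion dialects such as `BCR-ABL`, `bcr/abl`,
#' `BCR:ABL1` and hyphen chains such as `BCR-ABL-selective` survive as single
#' tokens. Punctuation itself is discarded.
#'
#' @param text a single character string (typically one sentence).
#' @return data frame with columns `surface`, `start`, `end` (0-based,
#'   half-open spans into `text`).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  pattern <- "[A-Za-z0-9]+(?:[-–—/:][A-Za-z0-9]+)*"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

contains_separator <- function(x) {
  grepl("[-–—/:]", x)
}

#' Add Porter2 stems to a token table
#'
#' The stem is the Porter2 stem of the lowercased surface. Tokens containing
#' fusion separator characters (candidate fusion forms such as `BCR-ABL`) are
#' exempt from stemming: their stem is the lowercased surface.
#'
#' @param tokens data frame from [tokenize()].
#' @return the token table with a `stem` column added.
#' @export
stem_tokens <- function(tokens) {
  stopifnot(is.data.frame(tokens))
  if (nrow(tokens) == 0) {
    tokens$stem <- character(0)
    return(tokens)
  }
  lower <- tolower(tokens$surface)
  exempt <- contains_separator(tokens$surface)
  stems <- lower
  if (any(!exempt)) stems[!exempt] <- stem_porter2(lower[!exempt])
  tokens$stem <- stems
  tokens
}

# does this token look like a fusion form the lexicon can resolve?
is_fusion_form <- function(surface, lexicon) {
  vapply(surface, function(s) {
    if (!contains_separator(s)) return(FALSE)
    norm <- normalize_surface_basic(s)
    if (!is.na(lookup_variant(lexicon, norm, "fusion_alias"))) return(TRUE)
    parts <- strsplit(norm, "-", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(FALSE)
    gm <- lexicon$variant_map$gene_symbol
    !is.na(gm[parts[1]]) && !is.na(gm[parts[2]])
  }, logical(1), USE.NAMES = FALSE)
}

#' Categorize tokens as Biological, Miscellaneous, Function or Literal
#'
#' Categories are assigned by precedence: (1) *Literal* if the lowercased
#' surface is on the stopword list; (2) *Function* if the surface or stem
#' matches an action-verb variant or the evaluative-adjective list;
#' (3) *Biological* if the token is a domain adjective, a gene symbol, or a
#' fusion form (alias hit or GENE-SEP-GENE shape); (4) *Miscellaneous*
#' otherwise. Every token receives exactly one category and re-running is
#' idempotent.
#'
#' @param tokens token table from [tokenize()] (stems are added if missing).
#' @param lexicon an `fm_lexicon`.
#' @return the token table with a `category` column added.
#' @export
categorize_tokens <- function(tokens, lexicon) {
  stopifnot(is.data.frame(tokens), inherits(lexicon, "fm_lexicon"))
  if (!"stem" %in% names(tokens)) tokens <- stem_tokens(tokens)
  if (nrow(tokens) == 0) {
    tokens$category <- character(0)
    return(tokens)
  }
  lower <- tolower(tokens$surface)
  stem <- tokens$stem
  eval_stems <- if (length(lexicon$evaluative_adjectives)) {
    stem_porter2(lexicon$evaluative_adjectives)
  } else character(0)

  is_literal <- lower %in% lexicon$stopwords
  is_function <- lower %in% names(lexicon$action_all) |
    stem %in% names(lexicon$action_stems) |
    lower %in% lexicon$evaluative_adjectives |
    stem %in% eval_stems
  is_biological <- lower %in% lexicon$domain_adjectives |
    !is.na(lexicon$variant_map$gene_symbol[lower]) |
    is_fusion_form(tokens$surface, lexicon)

  category <- rep("Miscellaneous", nrow(tokens))
  category[is_biological] <- "Biological"
  category[is_function] <- "Function"
  category[is_literal] <- "Literal"
  tokens$category <- category
  tokens
}

#' Replace recognized entity spans with class placeholders
#'
#' Each mention span in `mentions` is replaced by its class placeholder (the
#' mention label: `GENE`, `FUSION`, `DISEASE` or `ACTION`). Replacement
#' proceeds in descending span order so earlier offsets stay valid; when
#' spans overlap, the outermost span wins and inner spans are dropped.
#'
#' @param text the text the spans refer to (sentence or document body).
#' @param mentions data frame with columns `start`, `end`, `label` (0-based,
#'   half-open spans into `text`).
#' @return the text with placeholders substituted.
#' @export
blank_entities <- function(text, mentions) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.null(mentions) || nrow(mentions) == 0) return(text)
  bad <- mentions$start < 0 | mentions$end > nchar(text) |
    mentions$start >= mentions$end
  if (any(bad)) stop_fm("mention span outside text in blank_entities()")
  m <- mentions[order(mentions$start, -mentions$end), , drop = FALSE]
  keep <- logical(nrow(m))
  cur_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- m$end[i]
    }
  }
  m <- m[keep, , drop = FALSE]
  for (i in rev(seq_len(nrow(m)))) {
    text <- paste0(substr(text, 1L, m$start[i]), m$label[i],
                   substr(text, m$end[i] + 1L, nchar(text)))
  }
  text
}
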