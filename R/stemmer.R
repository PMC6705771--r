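# Porter2 (Snowball English) stemmer.
#
# Implemented directly from the published algorithm definition: regions R1/R2,
# steps 0-5, the exceptional word lists, and y/Y consonant marking. Words of
# length <= 2 and the listed invariant words are returned unchanged.

P2_VOWELS <- c("a", "e", "i", "o", "u", "y")
P2_DOUBLES <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
P2_LI_ENDING <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

P2_EXCEPTIONS1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

P2_EXCEPTIONS2 <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

p2_is_vowel <- function(ch) ch %in% P2_VOWELS

p2_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# start position (1-based) of the region following the first non-vowel that
# follows a vowel within w[from:]; length(w)+1 when the region is empty
p2_region_start <- function(ch, from) {
  n <- length(ch)
  i <- from
  while (i <= n && !p2_is_vowel(ch[i])) i <- i + 1L # skip leading non-vowels
  while (i <= n && p2_is_vowel(ch[i])) i <- i + 1L  # the vowel run
  if (i <= n) i + 1L else n + 1L
}

p2_r1_start <- function(w) {
  for (p in c("gener", "commun", "arsen")) {
    if (startsWith(w, p)) return(nchar(p) + 1L)
  }
  p2_region_start(p2_chars(w), 1L)
}

p2_ends <- function(w, s) {
  nchar(w) >= nchar(s) && substr(w, nchar(w) - nchar(s) + 1L, nchar(w)) == s
}

p2_suffix_in <- function(w, s, region_start) {
  nchar(w) - nchar(s) + 1L >= region_start
}

p2_drop <- function(w, k) substr(w, 1L, nchar(w) - k)

# short syllable at end of w: non-vowel + vowel + non-vowel(not w,x,Y), or a
# word-initial vowel followed by a non-vowel
p2_ends_short_syllable <- function(w) {
  ch <- p2_chars(w)
  n <- length(ch)
  if (n == 2L) {
    return(p2_is_vowel(ch[1]) && !p2_is_vowel(ch[2]))
  }
  if (n >= 3L) {
    return(!p2_is_vowel(ch[n - 2L]) && p2_is_vowel(ch[n - 1L]) &&
             !p2_is_vowel(ch[n]) && !(ch[n] %in% c("w", "x", "Y")))
  }
  FALSE
}

p2_is_short_word <- function(w, r1) {
  r1 > nchar(w) && p2_ends_short_syllable(w)
}

p2_contains_vowel <- function(w) {
  any(p2_is_vowel(p2_chars(w)))
}

p2_stem_one <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L) return(w)
  w <- sub("^'", "", w)
  if (!is.na(P2_EXCEPTIONS1[w])) return(unname(P2_EXCEPTIONS1[w]))
  if (nchar(w) <= 2L) return(w)

  # mark consonant y as Y: word-initial y, or y following a vowel
  ch <- p2_chars(w)
  if (ch[1] == "y") ch[1] <- "Y"
  if (length(ch) > 1L) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && p2_is_vowel(ch[i - 1L])) ch[i] <- "Y"
    }
  }
  w <- paste(ch, collapse = "")

  r1 <- p2_r1_start(w)
  r2 <- p2_region_start(p2_chars(w), r1)

  # step 0: apostrophe suffixes
  for (s in c("'s'", "'s", "'")) {
    if (p2_ends(w, s)) { w <- p2_drop(w, nchar(s)); break }
  }

  # step 1a
  if (p2_ends(w, "sses")) {
    w <- paste0(p2_drop(w, 4L), "ss")
  } else if (p2_ends(w, "ied") || p2_ends(w, "ies")) {
    w <- if (nchar(w) > 4L) paste0(p2_drop(w, 3L), "i") else paste0(p2_drop(w, 3L), "ie")
  } else if (p2_ends(w, "us") || p2_ends(w, "ss")) {
    # leave unchanged
  } else if (p2_ends(w, "s")) {
    stem_part <- p2_drop(w, 1L)
    if (nchar(stem_part) >= 2L &&
        p2_contains_vowel(substr(stem_part, 1L, nchar(stem_part) - 1L))) {
      w <- stem_part
    }
  }

  if (w %in% P2_EXCEPTIONS2) return(tolower(w))

  # step 1b
  if (p2_ends(w, "eedly")) {
    if (p2_suffix_in(w, "eedly", r1)) w <- paste0(p2_drop(w, 5L), "ee")
  } else if (p2_ends(w, "eed")) {
    if (p2_suffix_in(w, "eed", r1)) w <- paste0(p2_drop(w, 3L), "ee")
  } else {
    del <- NA_integer_
    for (s in c("ingly", "edly", "ing", "ed")) {
      if (p2_ends(w, s)) {
        if (p2_contains_vowel(p2_drop(w, nchar(s)))) del <- nchar(s)
        break
      }
    }
    if (!is.na(del)) {
      w <- p2_drop(w, del)
      if (p2_ends(w, "at") || p2_ends(w, "bl") || p2_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (any(vapply(P2_DOUBLES, function(d) p2_ends(w, d), logical(1)))) {
        w <- p2_drop(w, 1L)
      } else if (p2_is_short_word(w, r1)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: y -> i after a non-vowel that is not the first letter
  n <- nchar(w)
  if (n > 2L) {
    last <- substr(w, n, n)
    if (last %in% c("y", "Y") && !p2_is_vowel(substr(w, n - 1L, n - 1L))) {
      w <- paste0(p2_drop(w, 1L), "i")
    }
  }

  # step 2 (longest suffix, condition: in R1)
  step2 <- list(
    c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
    c("ousness", "ous"), c("iveness", "ive"), c("tional", "tion"),
    c("biliti", "ble"), c("lessli", "less"), c("entli", "ent"),
    c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
    c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
    c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
    c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
    c("bli", "ble"), c("ogi", "og"), c("li", "")
  )
  for (rule in step2) {
    s <- rule[1]
    if (p2_ends(w, s)) {
      if (p2_suffix_in(w, s, r1)) {
        if (s == "ogi") {
          if (p2_ends(p2_drop(w, 3L), "l")) w <- paste0(p2_drop(w, 3L), "og")
        } else if (s == "li") {
          prev <- substr(w, nchar(w) - 2L, nchar(w) - 2L)
          if (prev %in% P2_LI_ENDING) w <- p2_drop(w, 2L)
        } else {
          w <- paste0(p2_drop(w, nchar(s)), rule[2])
        }
      }
      break
    }
  }

  # step 3 (in R1; "ative" requires R2)
  step3 <- list(
    c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
    c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (rule in step3) {
    s <- rule[1]
    if (p2_ends(w, s)) {
      if (p2_suffix_in(w, s, r1)) {
        if (s == "ative") {
          if (p2_suffix_in(w, s, r2)) w <- p2_drop(w, 5L)
        } else {
          w <- paste0(p2_drop(w, nchar(s)), rule[2])
        }
      }
      break
    }
  }

  # step 4 (in R2)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  for (s in step4) {
    if (p2_ends(w, s)) {
      if (p2_suffix_in(w, s, r2)) {
        if (s == "ion") {
          prev <- substr(w, nchar(w) - 3L, nchar(w) - 3L)
          if (prev %in% c("s", "t")) w <- p2_drop(w, 3L)
        } else {
          w <- p2_drop(w, nchar(s))
        }
      }
      break
    }
  }

  # step 5
  if (p2_ends(w, "e")) {
    if (p2_suffix_in(w, "e", r2) ||
        (p2_suffix_in(w, "e", r1) && !p2_ends_short_syllable(p2_drop(w, 1L)))) {
      w <- p2_drop(w, 1L)
    }
  } else if (p2_ends(w, "l")) {
    if (p2_suffix_in(w, "l", r2) && p2_ends(w, "ll")) {
      w <- p2_drop(w, 1L)
    }
  }

  tolower(w)
}

#' Stem English words with the Porter2 (Snowball) algorithm
#'
#' Vectorized Porter2 stemmer. Input is lowercased before stemming. Tokens
#' that candidate fusion forms should be exempted from (those containing
#' separator characters) are handled by [stem_tokens()], not here.
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' stem_porter2(c("interacts", "activation", "binding"))
#' @export
stem_porter2 <- function(words) {
  stopifnot(is.character(words))
  vapply(words, p2_stem_one, character(1), USE.NAMES = FALSE)
}
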