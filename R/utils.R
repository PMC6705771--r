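`%||%` <- function(x, y) if (is.null(x)) y else x

# run code with a fixed RNG seed without touching the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# separator characters accepted inside fusion surface forms
FUSION_SEPARATORS <- c("-", "–", "—", "/", ":")

fusion_sep_regex <- function() "[-–—/:]"

# lowercase and map every accepted separator to a hyphen
normalize_surface_basic <- function(x) {
  gsub(fusion_sep_regex(), "-", tolower(x))
}

stop_fm <- function(...) stop(sprintf(...), call. = FALSE)

warn_fm <- function(...) warning(sprintf(...), call. = FALSE)

fm_read_lines <- function(path) {
  if (!file.exists(path)) stop_fm("file does not exist: '%s'", path)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}
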