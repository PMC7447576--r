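# Low-level text utilities shared by the parser, the tagger and the miner.
# All character offsets in this package are 0-based, half-open, counted in
# Unicode code points after NFC normalization.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize text for mining
#'
#' Applies Unicode NFC normalization and declares UTF-8 encoding. Every
#' string that enters the tagging machinery goes through this first so that
#' character offsets are stable across platforms.
#'
#' @param x character vector
#' @return normalized character vector
#' @keywords internal
norm_text <- function(x) {
  stringi::stri_trans_nfc(enc2utf8(as.character(x)))
}

# Case folding used for all dictionary lookups (lookups are case-insensitive;
# stored keys are case-folded).
fold <- function(x) stringi::stri_trans_tolower(x)

#' Tokenize a string
#'
#' Splits on whitespace and punctuation, keeping internal hyphens and
#' internal periods so that names such as "PDF1.2", "PR-1" and
#' "S-transferase" stay single tokens. A trailing sentence period is never
#' part of a token.
#'
#' @param text a single string (assumed NFC-normalized)
#' @param offset integer added to all reported offsets (used to lift
#'   sentence-local offsets into abstract coordinates)
#' @return data.frame with columns `token`, `fold`, `start`, `end`
#'   (0-based, half-open)
#' @keywords internal
tokenize <- function(text, offset = 0L) {
  empty <- data.frame(token = character(), fold = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[\\p{L}\\p{N}]+(?:[.\\-][\\p{L}\\p{N}]+)*", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  len <- attr(m, "match.length")
  tok <- substring(text, m, m + len - 1L)
  data.frame(token = tok,
             fold = fold(tok),
             start = as.integer(m - 1L + offset),
             end = as.integer(m - 1L + len + offset),
             stringsAsFactors = FALSE)
}

# Locale-independent (C collation) sort/order, used wherever output order
# must be byte-identical across machines and worker counts.
c_sort <- function(x) sort(x, method = "radix")
c_order <- function(...) order(..., method = "radix")

# Canonical unordered pair: lexicographic order of the two normalized
# names under C collation (radix), never the session locale.
canonical_pair <- function(a, b) {
  swap <- vapply(seq_along(a), function(i) {
    if (a[i] == b[i]) return(FALSE)
    sort(c(a[i], b[i]), method = "radix")[1L] == b[i]
  }, TRUE)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

# Collapse a character vector into the semicolon-list dialect used by the
# co-occurrence TSV ("" for empty).
semi_join <- function(x) paste(c_sort(unique(x)), collapse = ";")

semi_split <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1L]]
}
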