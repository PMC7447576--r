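# Dictionary-based tagging of bioentity, trigger-term and concept mentions.
# This is the pipeline's stand-in for the external SVM entity recognizer:
# left-to-right longest match over tokens, case-insensitive, anchored at
# whole-token boundaries, with multi-word entries matching across single
# spaces.

# Scan one sentence's tokens for dictionary entries. `entries` carries
# parallel vectors value/n_tokens and `entry_tokens` the token-fold
# sequences. Longest match wins; matched tokens are consumed when
# `consume = TRUE` (entities/concepts) so that no two mentions overlap;
# trigger terms are scanned without consumption (one report per start
# position, longest entry).
.scan_sentence <- function(toks, text1, entry_tokens, first_tok, n_tokens,
                           consume = TRUE) {
  n <- nrow(toks)
  hits <- integer()      # entry index
  hit_from <- integer()  # token index of match start
  hit_to <- integer()    # token index of match end
  i <- 1L
  while (i <= n) {
    cand <- which(first_tok == toks$fold[i])
    best <- 0L; best_len <- 0L
    for (j in cand) {
      m <- n_tokens[j]
      if (m < best_len || i + m - 1L > n) next
      tt <- entry_tokens[[j]]
      ok <- TRUE
      if (m > 1L) {
        for (k in 2L:m) {
          # token folds must match and tokens must be separated by one space
          if (toks$fold[i + k - 1L] != tt[k] ||
              substring(text1, toks$end[i + k - 2L] + 1L,
                        toks$start[i + k - 1L]) != " ") { ok <- FALSE; break }
        }
      }
      if (ok && (m > best_len || (m == best_len && j < best))) {
        best <- j; best_len <- m
      }
    }
    if (best > 0L) {
      hits <- c(hits, best); hit_from <- c(hit_from, i)
      hit_to <- c(hit_to, i + best_len - 1L)
      i <- if (consume) i + best_len else i + 1L
    } else i <- i + 1L
  }
  data.frame(entry = hits, from = hit_from, to = hit_to)
}

# Tokenize one sentence in abstract coordinates.
.sentence_tokens <- function(rec, s) {
  tokenize(rec$sentences$text[s], offset = rec$sentences$start[s])
}

.empty_entities <- function() {
  data.frame(pmid = character(), sentence_index = integer(),
             start = integer(), end = integer(), surface = character(),
             normalized = character(), entity_class = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Tag bioentity mentions in an abstract record
#'
#' Left-to-right longest-match dictionary tagging over tokens:
#' case-insensitive, whole-token-boundary anchored, overlapping candidates
#' resolved to the longest (ties to the leftmost). Tagging is a pure
#' function of the record text and the lexicon.
#'
#' @param record an [abstract_record()]
#' @param lexicon a `cooc_lexicon`
#' @return data.frame of entity mentions with columns `pmid`,
#'   `sentence_index`, `start`, `end`, `surface`, `normalized`,
#'   `entity_class`, `score` (1.0 for dictionary matches), in
#'   (sentence_index, start) order
#' @export
tag_entities <- function(record, lexicon) {
  ent <- lexicon$entities
  if (nrow(ent) == 0L || nrow(record$sentences) == 0L) return(.empty_entities())
  first_tok <- vapply(lexicon$entity_tokens, function(tk)
    if (length(tk)) tk[1L] else "", "")
  out <- list()
  for (s in seq_len(nrow(record$sentences))) {
    toks <- .sentence_tokens(record, s)
    if (nrow(toks) == 0L) next
    h <- .scan_sentence(toks, record$text, lexicon$entity_tokens, first_tok,
                        ent$n_tokens, consume = TRUE)
    if (nrow(h) == 0L) next
    st <- toks$start[h$from]; en <- toks$end[h$to]
    out[[length(out) + 1L]] <- data.frame(
      pmid = record$pmid,
      sentence_index = record$sentences$index[s],
      start = st, end = en,
      surface = substring(record$text, st + 1L, en),
      normalized = ent$normalized[h$entry],
      entity_class = ent$entity_class[h$entry],
      score = 1.0, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_entities())
  res <- do.call(rbind, out)
  res <- res[c_order(res$sentence_index, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_terms <- function() {
  data.frame(pmid = character(), sentence_index = integer(),
             start = integer(), end = integer(), surface = character(),
             term = character(), match_mode = character(),
             stringsAsFactors = FALSE)
}

#' Tag biointeraction trigger terms in an abstract record
#'
#' Every sentence is scanned in both exact and permissive modes (see
#' [lookup_term()]); each matched span is reported once with the strongest
#' mode (exact preferred). A `match_mode` of `"permissive"` therefore means
#' permissive-only: the span has no exact dictionary match.
#'
#' @inheritParams tag_entities
#' @return data.frame of term mentions with columns `pmid`,
#'   `sentence_index`, `start`, `end`, `surface`, `term`, `match_mode`
#' @export
tag_terms <- function(record, lexicon) {
  trm <- lexicon$terms
  if (nrow(trm) == 0L || nrow(record$sentences) == 0L) return(.empty_terms())
  first_tok <- vapply(lexicon$term_tokens, function(tk)
    if (length(tk)) tk[1L] else "", "")
  out <- list()
  for (s in seq_len(nrow(record$sentences))) {
    toks <- .sentence_tokens(record, s)
    nt <- nrow(toks)
    if (nt == 0L) next
    # exact: longest dictionary term starting at each token
    ex <- .scan_sentence(toks, record$text, lexicon$term_tokens, first_tok,
                         trm$n_tokens, consume = FALSE)
    spans <- if (nrow(ex)) data.frame(
      start = toks$start[ex$from], end = toks$end[ex$to],
      term = trm$term[ex$entry], match_mode = "exact",
      stringsAsFactors = FALSE) else NULL
    # permissive: first n-1 tokens exact, last token begins with the stem
    pm <- list()
    for (j in seq_len(nrow(trm))) {
      tt <- lexicon$term_tokens[[j]]
      m <- length(tt)
      if (m == 0L || m > nt) next
      for (i in seq_len(nt - m + 1L)) {
        head_ok <- m == 1L ||
          (identical(toks$fold[i:(i + m - 2L)], tt[-m]) &&
           all(substring(record$text, toks$end[i:(i + m - 2L)] + 1L,
                         toks$start[(i + 1L):(i + m - 1L)]) == " "))
        if (head_ok && startsWith(toks$fold[i + m - 1L], trm$stem[j]))
          pm[[length(pm) + 1L]] <- c(toks$start[i], toks$end[i + m - 1L], j)
      }
    }
    if (length(pm)) {
      p0 <- do.call(rbind, pm)
      spans <- rbind(spans, data.frame(
        start = as.integer(p0[, 1L]), end = as.integer(p0[, 2L]),
        term = trm$term[p0[, 3L]], match_mode = "permissive",
        stringsAsFactors = FALSE))
    }
    if (is.null(spans) || nrow(spans) == 0L) next
    # one report per span, strongest mode first, then smallest term
    spans <- spans[c_order(spans$start, spans$end, spans$match_mode,
                           spans$term), , drop = FALSE]
    spans <- spans[!duplicated(spans[, c("start", "end")]), , drop = FALSE]
    spans$pmid <- record$pmid
    spans$sentence_index <- record$sentences$index[s]
    spans$surface <- substring(record$text, spans$start + 1L, spans$end)
    out[[length(out) + 1L]] <- spans[, c("pmid", "sentence_index", "start",
                                         "end", "surface", "term",
                                         "match_mode")]
  }
  if (!length(out)) return(.empty_terms())
  res <- do.call(rbind, out)
  res <- res[c_order(res$sentence_index, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tag biological-concept mentions
#'
#' Concepts are contextual annotation terms: they are matched exactly like
#' bioentities (longest match, case-insensitive) but never enter
#' co-occurrence pairing; they are attached to co-occurrences as
#' annotations by [mine_abstract()].
#'
#' @inheritParams tag_entities
#' @return data.frame with columns `pmid`, `sentence_index`, `start`,
#'   `end`, `surface`, `concept`
#' @export
tag_concepts <- function(record, lexicon) {
  empty <- data.frame(pmid = character(), sentence_index = integer(),
                      start = integer(), end = integer(),
                      surface = character(), concept = character(),
                      stringsAsFactors = FALSE)
  cpt <- lexicon$concepts
  if (nrow(cpt) == 0L || nrow(record$sentences) == 0L) return(empty)
  first_tok <- vapply(lexicon$concept_tokens, function(tk)
    if (length(tk)) tk[1L] else "", "")
  out <- list()
  for (s in seq_len(nrow(record$sentences))) {
    toks <- .sentence_tokens(record, s)
    if (nrow(toks) == 0L) next
    h <- .scan_sentence(toks, record$text, lexicon$concept_tokens, first_tok,
                        cpt$n_tokens, consume = TRUE)
    if (nrow(h) == 0L) next
    st <- toks$start[h$from]; en <- toks$end[h$to]
    out[[length(out) + 1L]] <- data.frame(
      pmid = record$pmid, sentence_index = record$sentences$index[s],
      start = st, end = en,
      surface = substring(record$text, st + 1L, en),
      concept = cpt$concept[h$entry], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Import externally produced entity tags
#'
#' Reads a tag-interchange TSV (the hand-off format of an external entity
#' recognizer) and validates each row against the corpus. For any record
#' whose PMID appears in the interchange file, the imported mentions
#' replace — they are never merged with — dictionary tagging.
#'
#' @param x path to a tag-interchange TSV, or a data.frame already read by
#'   [read_tag_interchange()]
#' @param records list of [abstract_record()]
#' @return data.frame of entity mentions in the [tag_entities()] layout
#'   (with imported `score` passed through); attribute `n_rejected` counts
#'   dropped rows
#' @export
import_external_tags <- function(x, records) {
  df <- if (is.character(x)) read_tag_interchange(x, records = records)
        else .validate_spans(x, records)
  res <- data.frame(pmid = df$pmid, sentence_index = df$sentence_index,
                    start = df$start, end = df$end, surface = df$surface,
                    normalized = df$normalized,
                    entity_class = df$entity_class, score = df$score,
                    stringsAsFactors = FALSE)
  res <- res[c_order(res$pmid, res$sentence_index, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- attr(df, "n_rejected") %||% 0L
  res
}
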