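# The core algorithm: classify every pair of distinct protein/gene names
# co-mentioned in an abstract into reliability types 1-4, attach trigger
# terms and concept annotations, and filter by taxon or by type.
#
# Type criteria (lower = more likely a real interaction):
#   1  both names in one sentence with an exact trigger term strictly
#      between them;
#   2  both names in one sentence with an exact trigger term anywhere;
#   3  both names in one sentence, trigger term found only permissively
#      (stem-prefix match);
#   4  both names in the abstract only (same sentence not required, or no
#      trigger at all).

.cooc_cols <- c("pmid", "entity_a", "entity_b", "type", "sentence_index",
                "terms", "concepts", "sentence_text")

.empty_cooc <- function() {
  data.frame(pmid = character(), entity_a = character(),
             entity_b = character(), type = integer(),
             sentence_index = integer(), terms = character(),
             concepts = character(), sentence_text = character(),
             stringsAsFactors = FALSE)
}

#' Classify one entity pair within a sentence
#'
#' Returns `1` if at least one exact-mode trigger span lies strictly
#' between the two mentions (after the earlier mention's end, before the
#' later mention's start); else `2` if an exact trigger occurs anywhere in
#' the sentence; else `3` if a trigger is found permissively; else `NA`
#' (the pair falls through to abstract-level type 4).
#'
#' @param mention_a,mention_b single entity mentions (one-row data.frames
#'   or lists with `start`, `end` and optionally `sentence_index`); both
#'   must lie in the same sentence
#' @param sentence_terms data.frame of term mentions of that sentence
#'   (columns `start`, `end`, `match_mode`)
#' @return integer 1, 2, 3 or `NA`
#' @export
classify_pair_in_sentence <- function(mention_a, mention_b, sentence_terms) {
  sa <- mention_a[["sentence_index"]]; sb <- mention_b[["sentence_index"]]
  if (!is.null(sa) && !is.null(sb) && length(sa) == 1L && length(sb) == 1L &&
      !is.na(sa) && !is.na(sb) && sa != sb)
    stop("classify_pair_in_sentence: mentions lie in different sentences",
         call. = FALSE)
  if (is.null(sentence_terms) || nrow(sentence_terms) == 0L) return(NA_integer_)
  first_end <- min(mention_a[["end"]], mention_b[["end"]])
  later_start <- max(mention_a[["start"]], mention_b[["start"]])
  exact <- sentence_terms$match_mode == "exact"
  between <- exact & sentence_terms$start >= first_end &
    sentence_terms$end <= later_start
  if (any(between)) return(1L)
  if (any(exact)) return(2L)
  if (nrow(sentence_terms) > 0L) return(3L)
  NA_integer_
}

#' Mine the typed co-occurrences of one abstract
#'
#' For every unordered pair of distinct normalized protein/gene names with
#' at least one mention each in the abstract, the reported type is the
#' minimum of [classify_pair_in_sentence()] over all same-sentence mention
#' combinations, or 4 if no same-sentence combination qualifies (including
#' pairs that never share a sentence). Exactly one row is produced per
#' (pmid, pair); the evidence sentence is the earliest sentence achieving
#' the minimal type. Concept terms co-mentioned in the evidence sentence
#' (types 1-3) or anywhere in the abstract (type 4) are attached as
#' annotations.
#'
#' @param record an [abstract_record()]
#' @param entity_mentions data.frame from [tag_entities()] or
#'   [import_external_tags()]
#' @param term_mentions data.frame from [tag_terms()]
#' @param concept_mentions optional data.frame from [tag_concepts()]
#' @return data.frame with columns `pmid`, `entity_a`, `entity_b` (pair in
#'   lexicographic order), `type`, `sentence_index` (`NA` for type 4),
#'   `terms` and `concepts` (semicolon lists), `sentence_text`; sorted by
#'   pair
#' @export
mine_abstract <- function(record, entity_mentions, term_mentions,
                          concept_mentions = NULL) {
  em <- entity_mentions[entity_mentions$pmid == record$pmid &
                        entity_mentions$entity_class %in% PAIRED_CLASSES, ,
                        drop = FALSE]
  tm <- term_mentions[term_mentions$pmid == record$pmid, , drop = FALSE]
  cm <- if (is.null(concept_mentions)) NULL else
    concept_mentions[concept_mentions$pmid == record$pmid, , drop = FALSE]
  names_u <- c_sort(unique(em$normalized))
  if (length(names_u) < 2L) return(.empty_cooc())
  terms_by_sent <- split(tm, tm$sentence_index)
  pairs <- combn(names_u, 2L)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    na_ <- pairs[1L, p]; nb_ <- pairs[2L, p]
    ma <- em[em$normalized == na_, , drop = FALSE]
    mb <- em[em$normalized == nb_, , drop = FALSE]
    shared <- sort(intersect(ma$sentence_index, mb$sentence_index))
    best_type <- 4L
    evid <- NA_integer_
    for (s in shared) {
      st <- terms_by_sent[[as.character(s)]]
      if (is.null(st)) st <- tm[0L, , drop = FALSE]
      sent_min <- NA_integer_
      as_ <- ma[ma$sentence_index == s, , drop = FALSE]
      bs_ <- mb[mb$sentence_index == s, , drop = FALSE]
      for (i in seq_len(nrow(as_))) for (j in seq_len(nrow(bs_))) {
        t_ <- classify_pair_in_sentence(as_[i, ], bs_[j, ], st)
        if (!is.na(t_) && (is.na(sent_min) || t_ < sent_min)) sent_min <- t_
        if (!is.na(sent_min) && sent_min == 1L) break
      }
      if (!is.na(sent_min) && sent_min < best_type) {
        best_type <- sent_min
        evid <- s
        if (best_type == 1L) break
      }
    }
    # evidence terms and concepts per the type rules
    terms_out <- character()
    concepts_out <- character()
    sent_text <- ""
    if (best_type < 4L) {
      st <- terms_by_sent[[as.character(evid)]]
      if (best_type == 1L) {
        as_ <- ma[ma$sentence_index == evid, , drop = FALSE]
        bs_ <- mb[mb$sentence_index == evid, , drop = FALSE]
        ex <- st[st$match_mode == "exact", , drop = FALSE]
        for (k in seq_len(nrow(ex))) {
          ok <- FALSE
          for (i in seq_len(nrow(as_))) for (j in seq_len(nrow(bs_))) {
            if (ex$start[k] >= min(as_$end[i], bs_$end[j]) &&
                ex$end[k] <= max(as_$start[i], bs_$start[j])) ok <- TRUE
          }
          if (ok) terms_out <- c(terms_out, ex$term[k])
        }
      } else if (best_type == 2L) {
        terms_out <- st$term[st$match_mode == "exact"]
      } else {
        terms_out <- st$term[st$match_mode == "permissive"]
      }
      if (!is.null(cm) && nrow(cm))
        concepts_out <- cm$concept[cm$sentence_index == evid]
      si <- match(evid, record$sentences$index)
      sent_text <- record$sentences$text[si]
    } else {
      if (!is.null(cm) && nrow(cm)) concepts_out <- cm$concept
    }
    rows[[p]] <- data.frame(
      pmid = record$pmid, entity_a = na_, entity_b = nb_,
      type = best_type, sentence_index = evid,
      terms = semi_join(terms_out), concepts = semi_join(concepts_out),
      sentence_text = sent_text, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[c_order(res$entity_a, res$entity_b, res$pmid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine a whole set of records
#'
#' Convenience wrapper: tags entities, trigger terms and concepts for each
#' record (or substitutes imported external tags for records present in
#' `tags`) and concatenates [mine_abstract()] output.
#'
#' @param records list of [abstract_record()]
#' @param lexicon a `cooc_lexicon`
#' @param tags optional tag-interchange data.frame or path; records whose
#'   PMID appears there get only the imported entity tags
#' @return co-occurrence data.frame (see [mine_abstract()]) sorted by
#'   (entity_a, entity_b, pmid); the tagged entity mentions are attached as
#'   attribute `entities`
#' @export
mine_records <- function(records, lexicon, tags = NULL) {
  imported <- if (is.null(tags)) NULL else import_external_tags(tags, records)
  out <- vector("list", length(records))
  ents <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    em <- if (!is.null(imported) && rec$pmid %in% imported$pmid)
      imported[imported$pmid == rec$pmid, , drop = FALSE]
    else tag_entities(rec, lexicon)
    tm <- tag_terms(rec, lexicon)
    cm <- tag_concepts(rec, lexicon)
    ents[[i]] <- em
    out[[i]] <- mine_abstract(rec, em, tm, cm)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) res <- .empty_cooc()
  res <- res[c_order(res$entity_a, res$entity_b, res$pmid), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "entities") <- do.call(rbind, ents)
  res
}

#' Filter co-occurrences by NCBI tax-ID
#'
#' A co-occurrence is retained iff its abstract contains at least one
#' taxon mention resolving to `tax_id`. The filter is pure: rows are
#' selected, never modified. An unknown or unmentioned tax-ID legally
#' selects nothing.
#'
#' @param cooccurrences co-occurrence data.frame
#' @param entity_mentions entity mention data.frame covering the same
#'   corpus (taxon mentions carry `entity_class == "taxon"`)
#' @param tax_id positive integer NCBI taxonomy identifier
#' @param lexicon a `cooc_lexicon` (its taxon map resolves mention names)
#' @return subset of `cooccurrences`
#' @export
filter_by_taxon <- function(cooccurrences, entity_mentions, tax_id, lexicon) {
  stopifnot(length(tax_id) == 1L, !is.na(tax_id), tax_id > 0)
  tx <- entity_mentions[entity_mentions$entity_class == "taxon", , drop = FALSE]
  if (nrow(tx) == 0L) return(cooccurrences[0L, , drop = FALSE])
  ids <- lexicon$taxa$tax_id[match(fold(tx$normalized), lexicon$taxa$fold)]
  keep_pmids <- unique(tx$pmid[!is.na(ids) & ids == as.integer(tax_id)])
  res <- cooccurrences[cooccurrences$pmid %in% keep_pmids, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select co-occurrences up to a maximum reliability type
#'
#' Order-preserving filter keeping rows with `type <= max_type` (e.g.
#' `max_type = 1` keeps only same-sentence pairs with an exact trigger
#' between the names, the tier used for pathway building).
#'
#' @param cooccurrences co-occurrence data.frame
#' @param max_type integer in 1..4
#' @return subset of `cooccurrences`
#' @export
select_type <- function(cooccurrences, max_type) {
  stopifnot(length(max_type) == 1L, max_type %in% 1:4)
  res <- cooccurrences[cooccurrences$type <= max_type, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write / read the co-occurrence TSV
#'
#' The per-input-file mining output: one row per (pmid, pair) with columns
#' `pmid`, `entity_a`, `entity_b`, `type`, `sentence_index`, `terms`,
#' `concepts` (semicolon lists) and `sentence_text`. UTF-8, tab-separated,
#' LF line endings.
#'
#' @param cooccurrences co-occurrence data.frame
#' @param path file path
#' @return `path` invisibly (write); co-occurrence data.frame (read)
#' @export
write_cooccurrences <- function(cooccurrences, path) {
  df <- cooccurrences[, .cooc_cols, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.cooc_cols, collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s\t%s",
                     df$pmid, df$entity_a, df$entity_b, df$type,
                     ifelse(is.na(df$sentence_index), "",
                            as.character(df$sentence_index)),
                     df$terms, df$concepts, df$sentence_text)
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_cooccurrences
#' @export
read_cooccurrences <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "integer", "integer", "character",
                                  "character", "character"),
                   encoding = "UTF-8")
  if (!identical(names(df), .cooc_cols))
    stop("not a co-occurrence TSV: ", path)
  df$terms[is.na(df$terms)] <- ""
  df$concepts[is.na(df$concepts)] <- ""
  df$sentence_text[is.na(df$sentence_text)] <- ""
  df
}
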