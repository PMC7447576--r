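# Reading PubMed/MEDLINE XML into sentence-segmented abstract records, and
# the tagged-entity TSV interchange format.

# Abbreviations that never terminate a sentence even when followed by an
# alphanumeric character. Compared case-folded; any single-letter word is
# additionally treated as an abbreviation (initials, genus shorthand).
.abbrev <- c("sp", "spp", "al", "fig", "figs", "no", "vs", "cf", "ca",
             "approx", "e.g", "i.e", "etc", "dr", "prof", "st", "var",
             "subsp", "nov", "min", "max.conc")

#' Construct an abstract record
#'
#' Builds the unit of analysis for the whole pipeline: one article with its
#' PMID, title, abstract, the mined text (title + " " + abstract) and its
#' deterministic sentence segmentation.
#'
#' @param pmid PubMed identifier (string of digits)
#' @param title article title
#' @param abstract abstract text, possibly empty
#' @return an object of class `abstract_record`: a list with elements
#'   `pmid`, `title`, `abstract`, `text` (the mined text) and `sentences`
#'   (a data.frame with columns `index`, `start`, `end`, `text`; offsets
#'   are 0-based half-open code-point positions in `text`)
#' @export
abstract_record <- function(pmid, title, abstract = "") {
  pmid <- trimws(as.character(pmid))
  title <- norm_text(title %||% "")
  abstract <- norm_text(abstract %||% "")
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  structure(list(pmid = pmid, title = title, abstract = abstract,
                 text = text, sentences = split_sentences(text)),
            class = "abstract_record")
}

#' @export
print.abstract_record <- function(x, ...) {
  cat(sprintf("<abstract_record> PMID %s: %d sentences, %d characters\n",
              x$pmid, nrow(x$sentences), nchar(x$text)))
  invisible(x)
}

#' Parse PubMed/MEDLINE XML into abstract records
#'
#' Accepts both `PubmedArticleSet` (PubMed search export) and
#' `MedlineCitationSet` (MEDLINE FTP) roots. One record is produced per
#' article element, in document order. Structured abstracts (multiple
#' `AbstractText` children) are concatenated in document order with a
#' single space. Articles without an abstract yield a record with an empty
#' abstract; articles without a PMID are skipped with a warning.
#'
#' @param xml_source path to an XML file, or a raw/character XML payload
#' @return list of [abstract_record()] objects, with attributes
#'   `n_no_abstract` (articles lacking an abstract) and `n_skipped`
#'   (articles dropped for missing PMID)
#' @export
parse_medline_xml <- function(xml_source) {
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) stop("malformed XML in ", if (is.character(xml_source) &&
        length(xml_source) == 1L && file.exists(xml_source)) xml_source else "input",
        ": ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  nodes <- switch(root,
    PubmedArticleSet = xml2::xml_find_all(doc, "./PubmedArticle"),
    MedlineCitationSet = xml2::xml_find_all(doc, "./MedlineCitation"),
    # tolerate other wrappers (e.g. a bare article)
    xml2::xml_find_all(doc, ".//PubmedArticle | self::PubmedArticle"))
  records <- list()
  n_no_abstract <- 0L
  n_skipped <- 0L
  for (node in nodes) {
    pmid_node <- xml2::xml_find_first(node, ".//PMID")
    pmid <- if (inherits(pmid_node, "xml_missing")) "" else
      trimws(xml2::xml_text(pmid_node))
    if (!nzchar(pmid)) {
      warning("article without PMID skipped", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    title_node <- xml2::xml_find_first(node, ".//ArticleTitle")
    title <- if (inherits(title_node, "xml_missing")) "" else
      xml2::xml_text(title_node)
    abs_nodes <- xml2::xml_find_all(node, ".//Abstract/AbstractText")
    abstract <- paste(trimws(xml2::xml_text(abs_nodes)), collapse = " ")
    if (!nzchar(abstract)) n_no_abstract <- n_no_abstract + 1L
    records[[length(records) + 1L]] <- abstract_record(pmid, title, abstract)
  }
  pmids <- vapply(records, `[[`, "", "pmid")
  if (anyDuplicated(pmids))
    warning("duplicate PMIDs in one file: ",
            paste(unique(pmids[duplicated(pmids)]), collapse = ", "),
            call. = FALSE)
  attr(records, "n_no_abstract") <- n_no_abstract
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at a run of
#' `.`, `!` or `?` followed by whitespace and an alphanumeric character,
#' unless the word carrying the terminator is a known abbreviation or a
#' single letter (so "E. coli", "Fig. 2", "et al. 2019" never split).
#' Every non-whitespace character of the input belongs to exactly one
#' sentence.
#'
#' @param text a single string
#' @return data.frame with columns `index` (0-based), `start`, `end`
#'   (0-based half-open code-point offsets) and `text`
#' @export
split_sentences <- function(text) {
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  text <- norm_text(text)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) return(empty)
  n <- nchar(text)
  # candidate boundaries: terminator run with following whitespace
  m <- gregexpr("[.!?]+(?=\\s)", text, perl = TRUE)[[1L]]
  cuts <- integer()  # 1-based position of the last terminator char
  if (m[1L] != -1L) {
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      term_end <- m[k] + len[k] - 1L
      rest <- substring(text, term_end + 1L, n)
      fm <- regexpr("^\\s+([\\p{L}\\p{N}(\"'])", rest, perl = TRUE)
      if (fm == -1L) next
      # abbreviation veto on the word ending at the terminator
      prefix <- substring(text, max(1L, m[k] - 24L), m[k] - 1L)
      w <- regmatches(prefix, regexpr("[\\p{L}][\\p{L}.]*$", prefix, perl = TRUE))
      word <- if (length(w)) fold(w) else ""
      word <- sub("\\.+$", "", word)
      if (nzchar(word) && (nchar(word) == 1L || word %in% .abbrev)) next
      cuts <- c(cuts, term_end)
    }
  }
  starts1 <- c(1L, cuts + 1L)            # 1-based candidate starts
  ends1 <- c(cuts, n)                    # 1-based inclusive ends
  out <- empty
  for (k in seq_along(starts1)) {
    seg <- substring(text, starts1[k], ends1[k])
    lead <- regexpr("^\\s*", seg)
    nl <- attr(lead, "match.length")
    trail <- regexpr("\\s*$", seg, perl = TRUE)
    s1 <- starts1[k] + nl                 # first non-space char
    e1 <- starts1[k] + trail - 2L         # last char before trailing ws
    if (s1 > e1 || s1 > n) next
    stext <- substring(text, s1, e1)
    if (!nzchar(trimws(stext))) next
    out <- rbind(out, data.frame(index = nrow(out), start = s1 - 1L,
                                 end = e1, text = stext,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Tag interchange TSV: the hand-off format between an external entity tagger
# and the miner. Columns: pmid, start, end, surface, normalized,
# entity_class, score. UTF-8, tab-separated, LF, one header line.

.interchange_cols <- c("pmid", "start", "end", "surface", "normalized",
                       "entity_class", "score")

#' Write entity mentions to the tag-interchange TSV
#'
#' @param mentions data.frame with at least the columns `pmid`, `start`,
#'   `end`, `surface`, `normalized`, `entity_class`, `score`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tag_interchange <- function(mentions, path) {
  stopifnot(all(.interchange_cols %in% names(mentions)))
  df <- mentions[, .interchange_cols, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.interchange_cols, collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     df$pmid, as.integer(df$start), as.integer(df$end),
                     df$surface, df$normalized, df$entity_class,
                     formatC(df$score, format = "g", digits = 15))
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read the tag-interchange TSV
#'
#' Rows with an entity class outside the closed vocabulary are rejected
#' with a warning. When `records` is supplied, rows whose PMID is absent
#' from the corpus, whose span lies outside the record's mined text, or
#' whose span crosses a sentence boundary are also rejected with a
#' warning, and a `sentence_index` column is attached to surviving rows.
#'
#' @param path path to a TSV written by [write_tag_interchange()] (or by an
#'   external tagger following the same dialect)
#' @param records optional list of [abstract_record()] used for validation
#' @return data.frame of mentions grouped by pmid (input row order is kept
#'   within each pmid); attribute `n_rejected` counts dropped rows
#' @export
read_tag_interchange <- function(path, records = NULL) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "character",
                                  "numeric"),
                   encoding = "UTF-8")
  if (!identical(names(df), .interchange_cols))
    stop("tag-interchange file ", path, " has unexpected columns: ",
         paste(names(df), collapse = ", "))
  n0 <- nrow(df)
  bad_class <- !(df$entity_class %in% ENTITY_CLASSES)
  if (any(bad_class)) {
    warning(sum(bad_class), " row(s) with unknown entity_class rejected: ",
            paste(unique(df$entity_class[bad_class]), collapse = ", "),
            call. = FALSE)
    df <- df[!bad_class, , drop = FALSE]
  }
  if (!is.null(records)) {
    df <- .validate_spans(df, records)
  }
  df <- df[c_order(df$pmid), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n0 - nrow(df)
  df
}

# Attach sentence_index and drop rows with invalid spans.
.validate_spans <- function(df, records) {
  pmids <- vapply(records, `[[`, "", "pmid")
  keep <- logical(nrow(df))
  sent_idx <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    j <- match(df$pmid[i], pmids)
    if (is.na(j)) {
      warning("interchange row for unknown PMID ", df$pmid[i], " dropped",
              call. = FALSE)
      next
    }
    rec <- records[[j]]
    s <- df$start[i]; e <- df$end[i]
    if (is.na(s) || is.na(e) || e <= s || s < 0L || e > nchar(rec$text)) {
      warning("interchange row with span outside record ", df$pmid[i],
              " dropped", call. = FALSE)
      next
    }
    hit <- which(rec$sentences$start <= s & e <= rec$sentences$end)
    if (length(hit) != 1L) {
      warning("interchange row crossing a sentence boundary in PMID ",
              df$pmid[i], " dropped", call. = FALSE)
      next
    }
    keep[i] <- TRUE
    sent_idx[i] <- rec$sentences$index[hit]
  }
  df$sentence_index <- sent_idx
  df[keep, , drop = FALSE]
}
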