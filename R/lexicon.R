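# Fully in-memory dictionaries: bioentity names, biointeraction trigger
# terms, biological-concept terms and taxon synonyms. The store is built
# once from a single TSV "DB file" that travels with every job, is immutable
# after load, and is queried read-only by every worker — the plain-R
# analogue of shipping a self-contained database file and loading it into
# RAM on each node.

# Suffixes stripped (longest first) to obtain a trigger term's stem for
# permissive matching; the resulting stem must keep length >= 4, otherwise
# the next shorter suffix is tried and ultimately the term itself is kept.
.stem_suffixes <- c("ation", "tion", "ion", "ing", "es", "ed", "s")

#' Stem a trigger term
#'
#' Conventional suffix stripper used to concretize "permissive
#' identification of biointeraction terms": one of `-ation, -tion, -ion,
#' -ing, -es, -ed, -s` is removed (longest first) provided the stem keeps
#' at least 4 characters. A token matches a term permissively when its
#' case-folded form begins with the term's stem, which makes every exact
#' match also a permissive match.
#'
#' @param word a single word (will be case-folded)
#' @return the stem (case-folded)
#' @export
stem_term <- function(word) {
  w <- fold(word)
  for (suf in .stem_suffixes) {
    if (endsWith(w, suf) && nchar(w) - nchar(suf) >= 4L)
      return(substr(w, 1L, nchar(w) - nchar(suf)))
  }
  w
}

#' Load a lexicon from its TSV "DB file"
#'
#' The file is a UTF-8 TSV with a leading row-type column:
#' \describe{
#'   \item{`BIOENTITY<TAB>surface<TAB>normalized<TAB>class`}{a bioentity
#'     name; `class` is one of protein, gene, taxon, tissue, cell_type}
#'   \item{`TERM<TAB>term`}{a biointeraction trigger term}
#'   \item{`CONCEPT<TAB>term`}{a biological-concept term}
#'   \item{`TAXON<TAB>synonym<TAB>taxid`}{a taxon synonym mapped to its
#'     NCBI taxonomy identifier; also registered as a bioentity of class
#'     taxon}
#' }
#' Lines starting with `#` and blank lines are ignored. Duplicate rows are
#' deduplicated; rows with an unknown type tag are skipped with a warning.
#' Loading is repeatable and order-independent: the same file always yields
#' an equal store with the same `source_digest`.
#'
#' @param dict_file path to the lexicon TSV
#' @return an object of class `cooc_lexicon` with components `entities`,
#'   `terms`, `concepts`, `taxa` (data.frames) and `source_digest`
#' @export
load_lexicon <- function(dict_file) {
  if (!file.exists(dict_file))
    stop("lexicon file not found: ", dict_file, call. = FALSE)
  lines <- readLines(dict_file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)

  ent <- list(); trm <- character(); cpt <- character(); tax <- list()
  for (p in parts) {
    tag <- toupper(trimws(p[[1L]]))
    if (tag == "BIOENTITY" && length(p) >= 4L) {
      cls <- trimws(p[[4L]])
      if (!cls %in% ENTITY_CLASSES) {
        warning("unknown entity class '", cls, "' skipped", call. = FALSE)
        next
      }
      ent[[length(ent) + 1L]] <- c(trimws(p[[2L]]), trimws(p[[3L]]), cls)
    } else if (tag == "TERM" && length(p) >= 2L) {
      trm <- c(trm, trimws(p[[2L]]))
    } else if (tag == "CONCEPT" && length(p) >= 2L) {
      cpt <- c(cpt, trimws(p[[2L]]))
    } else if (tag == "TAXON" && length(p) >= 3L) {
      tax[[length(tax) + 1L]] <- c(trimws(p[[2L]]), trimws(p[[3L]]))
    } else {
      warning("lexicon row with unknown type tag '", tag, "' skipped",
              call. = FALSE)
    }
  }

  taxa <- if (length(tax)) {
    t0 <- unique(do.call(rbind, tax))
    data.frame(synonym = norm_text(t0[, 1L]),
               fold = fold(norm_text(t0[, 1L])),
               tax_id = as.integer(t0[, 2L]),
               stringsAsFactors = FALSE)
  } else data.frame(synonym = character(), fold = character(),
                    tax_id = integer(), stringsAsFactors = FALSE)
  if (any(is.na(taxa$tax_id)) || any(taxa$tax_id <= 0L, na.rm = TRUE))
    stop("taxon rows must map to positive integer tax-IDs", call. = FALSE)
  if (anyDuplicated(taxa$fold))
    stop("taxon synonym mapped to more than one tax-ID", call. = FALSE)

  # taxon synonyms double as bioentities of class "taxon" for tagging
  for (i in seq_len(nrow(taxa)))
    ent[[length(ent) + 1L]] <- c(taxa$synonym[i], taxa$synonym[i], "taxon")

  entities <- if (length(ent)) {
    e0 <- unique(do.call(rbind, ent))
    data.frame(surface = norm_text(e0[, 1L]), normalized = norm_text(e0[, 2L]),
               entity_class = e0[, 3L], stringsAsFactors = FALSE)
  } else data.frame(surface = character(), normalized = character(),
                    entity_class = character(), stringsAsFactors = FALSE)
  entities$fold <- fold(entities$surface)
  # the bioentity map is a function of the case-folded surface: one entry
  # per fold, chosen deterministically so that load order never matters
  entities <- entities[c_order(entities$fold, entities$entity_class,
                               entities$normalized), , drop = FALSE]
  entities <- entities[!duplicated(entities$fold), , drop = FALSE]
  rownames(entities) <- NULL
  ent_tokens <- lapply(entities$surface, function(s) tokenize(s)$fold)
  entities$n_tokens <- lengths(ent_tokens)

  trm <- c_sort(unique(norm_text(trm)))
  term_tokens <- lapply(trm, function(s) tokenize(s)$fold)
  terms <- data.frame(term = trm, fold = fold(trm),
                      n_tokens = lengths(term_tokens),
                      stem = vapply(term_tokens, function(tk)
                        if (length(tk)) stem_term(tk[length(tk)]) else "", ""),
                      stringsAsFactors = FALSE)

  cpt <- c_sort(unique(norm_text(cpt)))
  concept_tokens <- lapply(cpt, function(s) tokenize(s)$fold)
  concepts <- data.frame(concept = cpt, fold = fold(cpt),
                         n_tokens = lengths(concept_tokens),
                         stringsAsFactors = FALSE)

  structure(list(
    entities = entities,
    entity_tokens = ent_tokens,
    terms = terms,
    term_tokens = term_tokens,
    concepts = concepts,
    concept_tokens = concept_tokens,
    taxa = taxa,
    source_digest = unname(tools::md5sum(dict_file))
  ), class = "cooc_lexicon")
}

#' @export
print.cooc_lexicon <- function(x, ...) {
  cat(sprintf(paste0("<cooc_lexicon> %d bioentities (%d taxa), %d trigger ",
                     "terms, %d concepts\n  digest %s\n"),
              nrow(x$entities), nrow(x$taxa), nrow(x$terms),
              nrow(x$concepts), x$source_digest))
  invisible(x)
}

#' Bundled demonstration lexicon
#'
#' Loads the small plant-biology lexicon shipped with the package (plant
#' proteins such as rbcL, psbA, matK, PR-1, NPR1, PDF1.2; ~40 trigger
#' terms such as "encoding", "amplified", "encode", "induced"; concept
#' terms; and 15 plant taxa with synonyms, including Glycine max / soybean
#' = tax-ID 3847). Intended for examples, tests and simulations, not as a
#' production dictionary.
#'
#' @return a `cooc_lexicon`
#' @export
demo_lexicon <- function() {
  load_lexicon(system.file("extdata", "plant_demo_lexicon.tsv",
                           package = "litcooc", mustWork = TRUE))
}

#' Look up trigger terms in a token sequence
#'
#' In `exact` mode a dictionary term matches a contiguous run of tokens
#' whose case-folded forms equal the term's tokens. In `permissive` mode
#' the last token of the run may instead merely begin with the term's stem
#' (see [stem_term()]); exact matches are therefore a subset of permissive
#' matches.
#'
#' @param tokens character vector of tokens (a sentence split into words)
#' @param lexicon a `cooc_lexicon`
#' @param mode `"exact"` or `"permissive"`
#' @return character vector of matched dictionary terms (sorted, unique)
#' @export
lookup_term <- function(tokens, lexicon, mode = c("exact", "permissive")) {
  mode <- match.arg(mode)
  tk <- fold(as.character(tokens))
  n <- length(tk)
  hits <- character()
  for (i in seq_len(nrow(lexicon$terms))) {
    tt <- lexicon$term_tokens[[i]]
    m <- length(tt)
    if (m == 0L || m > n) next
    for (s in seq_len(n - m + 1L)) {
      run <- tk[s:(s + m - 1L)]
      head_ok <- m == 1L || identical(run[-m], tt[-m])
      last_ok <- if (mode == "exact") run[m] == tt[m]
                 else startsWith(run[m], lexicon$terms$stem[i])
      if (head_ok && last_ok) { hits <- c(hits, lexicon$terms$term[i]); break }
    }
  }
  c_sort(unique(hits))
}

#' Resolve a taxon name to its NCBI tax-ID
#'
#' Case-insensitive synonym lookup in the lexicon's taxon map.
#'
#' @param name taxon name or synonym (e.g. "Glycine max", "soybean")
#' @param lexicon a `cooc_lexicon`
#' @return integer tax-ID, or `NA` if unknown
#' @export
resolve_taxon <- function(name, lexicon) {
  i <- match(fold(norm_text(name)), lexicon$taxa$fold)
  if (is.na(i)) NA_integer_ else lexicon$taxa$tax_id[i]
}
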