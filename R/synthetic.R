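# Seeded generator of PubMed-XML corpora with planted, ground-truthed
# interactions. Templates instantiate the four type rules directly: type-1
# abstracts place an exact trigger between the two names, type-2 templates
# place it outside the between-interval, type-3 templates use only a
# stem-variant (permissive-only) surface, and type-4 templates split the
# names across sentences with no trigger anywhere. Filler words are checked
# against the lexicon at generation time so decoys can never tag.

#' Specify a synthetic corpus
#'
#' @param n_abstracts number of abstracts to generate
#' @param k1,k2,k3,k4 number of abstracts planted with a single pair of the
#'   given minimal type (k1+k2+k3+k4 <= n_abstracts; remaining abstracts
#'   carry no planted pair)
#' @param taxon_plan named numeric vector: `names` are tax-IDs, values the
#'   fraction of abstracts mentioning that taxon (deterministically
#'   `round(fraction * n)` abstracts, chosen by the seeded RNG)
#' @param decoy_rate fraction of filler tokens replaced by random
#'   out-of-lexicon decoy strings
#' @param seed integer RNG seed; the same spec and seed yield a
#'   byte-identical corpus
#' @return a `corpus_spec` list
#' @export
corpus_spec <- function(n_abstracts, k1 = 0L, k2 = 0L, k3 = 0L, k4 = 0L,
                        taxon_plan = NULL, decoy_rate = 0.1, seed = 1L) {
  ks <- c(k1, k2, k3, k4)
  stopifnot(n_abstracts >= 1L, all(ks >= 0L), sum(ks) <= n_abstracts,
            decoy_rate >= 0, decoy_rate <= 1)
  if (!is.null(taxon_plan)) {
    stopifnot(!is.null(names(taxon_plan)),
              all(taxon_plan >= 0), all(taxon_plan <= 1))
  }
  structure(list(n_abstracts = as.integer(n_abstracts),
                 k = as.integer(ks), taxon_plan = taxon_plan,
                 decoy_rate = decoy_rate, seed = as.integer(seed)),
            class = "corpus_spec")
}

# Candidate filler vocabulary; words colliding with the lexicon (entity or
# concept tokens, term folds, or term stem prefixes) are dropped at
# generation time.
.filler_words <- c(
  "the", "under", "field", "conditions", "samples", "were", "collected",
  "during", "seasonal", "trials", "plants", "showed", "typical", "growth",
  "patterns", "overall", "results", "remain", "consistent", "with",
  "previous", "reports", "further", "work", "will", "examine", "these",
  "observations", "carefully", "moreover", "values", "varied", "across",
  "plots", "while", "weather", "stayed", "mild", "throughout", "weeks",
  "material", "of", "and", "was", "observed", "in", "several", "a",
  "synthetic", "record", "study", "on", "mentions", "clearly", "later",
  "sections", "not", "here")

# TRUE for words that could tag against the lexicon in any mode.
.word_unsafe <- function(words, lexicon) {
  w <- fold(words)
  ent_tok <- unique(unlist(c(lexicon$entity_tokens, lexicon$concept_tokens)))
  unsafe <- w %in% ent_tok | w %in% lexicon$terms$fold
  stems <- unique(lexicon$terms$stem)
  for (s in stems) unsafe <- unsafe | startsWith(w, s)
  term_tok <- unique(unlist(lexicon$term_tokens))
  unsafe | w %in% term_tok
}

.safe_fillers <- function(lexicon) {
  ok <- .filler_words[!.word_unsafe(.filler_words, lexicon)]
  if (length(ok) < 12L)
    stop("lexicon leaves too few safe filler words for simulation",
         call. = FALSE)
  ok
}

.make_decoy <- function(lexicon) {
  repeat {
    d <- paste0("zq", paste(sample(letters, 6L, replace = TRUE), collapse = ""))
    if (!.word_unsafe(d, lexicon)) return(d)
  }
}

# A permissive-only surface for a term: begins with the stem, is not an
# exact match of any dictionary term, and cannot tag as an entity.
.permissive_surface <- function(lexicon) {
  cand <- lexicon$terms[lexicon$terms$n_tokens == 1L &
                        lexicon$terms$stem != lexicon$terms$fold, ,
                        drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    for (suf in c("ion", "ions", "ive", "ingly")) {
      s <- paste0(cand$stem[i], suf)
      if (!(s %in% lexicon$terms$fold) && !.word_unsafe_entity(s, lexicon))
        return(list(term = cand$term[i], surface = s))
    }
  }
  NULL
}

.word_unsafe_entity <- function(w, lexicon) {
  fold(w) %in% unique(unlist(c(lexicon$entity_tokens, lexicon$concept_tokens)))
}

.filler_phrase <- function(n, fillers, decoy_rate, lexicon) {
  w <- sample(fillers, n, replace = TRUE)
  if (decoy_rate > 0 && n > 0L) {
    swap <- which(stats::runif(n) < decoy_rate)
    for (i in swap) w[i] <- .make_decoy(lexicon)
  }
  paste(w, collapse = " ")
}

# Sentence templates for a planted pair (A, B). Each guarantees that the
# planted type is the minimal qualifying type for the abstract.
.planted_sentences <- function(type, a, b, ex_term, perm_surface, fillers,
                               decoy_rate, lexicon) {
  f <- function(n) .filler_phrase(n, fillers, decoy_rate, lexicon)
  if (type == 1L) {
    sprintf("%s %s %s %s.", a, ex_term, b, f(3L))
  } else if (type == 2L) {
    if (stats::runif(1) < 0.5)
      sprintf("%s %s and %s %s.", ex_term, a, b, f(2L))
    else
      sprintf("%s and %s %s %s.", a, b, f(2L), ex_term)
  } else if (type == 3L) {
    sprintf("%s and %s %s %s.", a, b, perm_surface, f(2L))
  } else {
    c(sprintf("%s %s.", a, f(4L)), sprintf("%s %s.", b, f(4L)))
  }
}

#' Generate a synthetic PubMed-XML corpus with ground truth
#'
#' Writes `n_files` PubMed XML files plus `ground_truth.tsv` (planted
#' pairs with expected minimal types) and `taxon_truth.tsv` (planted taxon
#' mentions per abstract) under `out_dir`. In default mode each abstract
#' carries at most one planted pair, so the expected typed co-occurrence
#' set equals the ground truth exactly. In `hard` mode abstracts mix
#' several names, triggers (exact and stem-variant surfaces), fillers and
#' decoys at random positions; no ground truth is emitted (hard-mode output
#' is validated against a brute-force oracle instead).
#'
#' @param spec a [corpus_spec()]
#' @param lexicon a `cooc_lexicon` with at least 2 protein/gene names, 1
#'   exact trigger term and (if `k3 > 0`) one term with a derivable
#'   permissive-only surface form
#' @param out_dir output directory (created)
#' @param n_files number of XML files the abstracts are split across
#' @param hard logical; hard mode (see above)
#' @return list with `files` (XML paths), `truth` (planted-pair
#'   data.frame or `NULL` in hard mode) and `taxa` (data.frame pmid,
#'   tax_id), invisibly
#' @export
generate_corpus <- function(spec, lexicon, out_dir, n_files = 1L,
                            hard = FALSE) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  prot <- lexicon$entities[lexicon$entities$entity_class %in% PAIRED_CLASSES, ,
                           drop = FALSE]
  # single-token names keep templates unambiguous
  prot <- prot[prot$n_tokens == 1L, , drop = FALSE]
  if (nrow(prot) < 2L)
    stop("lexicon needs >= 2 single-token protein/gene names", call. = FALSE)
  ex_terms <- lexicon$terms$term[lexicon$terms$n_tokens == 1L]
  if (!length(ex_terms))
    stop("lexicon needs >= 1 single-token trigger term", call. = FALSE)
  perm <- .permissive_surface(lexicon)
  if (spec$k[3L] > 0L && is.null(perm))
    stop("spec requires type-3 plants but no term has a derivable ",
         "permissive-only surface", call. = FALSE)
  fillers <- .safe_fillers(lexicon)
  # template literals must never tag against this lexicon
  literals <- c("and", "material", "of", "synthetic", "record")
  if (any(.word_unsafe(literals, lexicon)))
    stop("lexicon collides with simulation template words: ",
         paste(literals[.word_unsafe(literals, lexicon)], collapse = ", "),
         call. = FALSE)

  n <- spec$n_abstracts
  types <- c(rep(1L, spec$k[1L]), rep(2L, spec$k[2L]),
             rep(3L, spec$k[3L]), rep(4L, spec$k[4L]),
             rep(NA_integer_, n - sum(spec$k)))
  types <- sample(types)  # shuffle plant positions

  # taxon assignment: round(fraction * n) abstracts per tax-ID
  taxa_rows <- list()
  taxon_of <- rep(list(character()), n)
  if (!is.null(spec$taxon_plan)) {
    for (tid in names(spec$taxon_plan)) {
      k <- round(spec$taxon_plan[[tid]] * n)
      if (k <= 0L) next
      syns <- lexicon$taxa$synonym[lexicon$taxa$tax_id == as.integer(tid)]
      if (!length(syns))
        stop("taxon plan references tax-ID absent from lexicon: ", tid,
             call. = FALSE)
      picked <- sample(n, k)
      for (j in picked) {
        taxon_of[[j]] <- c(taxon_of[[j]], syns[1L])
        taxa_rows[[length(taxa_rows) + 1L]] <-
          data.frame(pmid = as.character(100000L + j),
                     tax_id = as.integer(tid), stringsAsFactors = FALSE)
      }
    }
  }

  truth_rows <- list()
  abstracts <- character(n)
  titles <- character(n)
  pmids <- as.character(100000L + seq_len(n))
  for (j in seq_len(n)) {
    titles[j] <- sprintf("Synthetic record %s.", pmids[j])
    sents <- character()
    if (hard) {
      for (s in seq_len(sample(3:6, 1L))) {
        nn <- sample(0:3, 1L)
        nt <- sample(0:2, 1L)
        words <- character()
        if (nn > 0L) words <- c(words, sample(prot$surface, nn))
        if (nt > 0L) {
          for (q in seq_len(nt)) {
            if (!is.null(perm) && stats::runif(1) < 0.4)
              words <- c(words, perm$surface)
            else words <- c(words, sample(ex_terms, 1L))
          }
        }
        words <- c(words, sample(fillers, sample(2:5, 1L), replace = TRUE))
        sents <- c(sents, paste0(paste(sample(words), collapse = " "), "."))
      }
    } else if (!is.na(types[j])) {
      ab <- sample(nrow(prot), 2L)
      a <- prot$surface[ab[1L]]; b <- prot$surface[ab[2L]]
      sents <- .planted_sentences(types[j], a, b, sample(ex_terms, 1L),
                                  if (is.null(perm)) NULL else perm$surface,
                                  fillers, spec$decoy_rate, lexicon)
      cp <- canonical_pair(prot$normalized[ab[1L]], prot$normalized[ab[2L]])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        pmid = pmids[j], entity_a = cp$a, entity_b = cp$b,
        type = types[j], stringsAsFactors = FALSE)
    } else {
      sents <- sprintf("%s.", .filler_phrase(6L, fillers, spec$decoy_rate,
                                             lexicon))
    }
    sents <- c(sents, paste0(.filler_phrase(4L, fillers, spec$decoy_rate,
                                            lexicon), "."))
    for (syn in taxon_of[[j]])
      sents <- c(sents, sprintf("Material of %s.", syn))
    abstracts[j] <- paste(sents, collapse = " ")
  }

  # split abstracts across files in contiguous chunks
  n_files <- max(1L, min(as.integer(n_files), n))
  chunk <- ceiling(n / n_files)
  files <- character(n_files)
  for (f in seq_len(n_files)) {
    lo <- (f - 1L) * chunk + 1L
    hi <- min(f * chunk, n)
    if (lo > hi) { files[f] <- NA_character_; next }
    files[f] <- file.path(out_dir, sprintf("corpus_%03d.xml", f))
    .write_pubmed_xml(pmids[lo:hi], titles[lo:hi], abstracts[lo:hi], files[f])
  }
  files <- files[!is.na(files)]

  truth <- if (length(truth_rows)) {
    tr <- do.call(rbind, truth_rows)
    tr <- tr[c_order(tr$entity_a, tr$entity_b, tr$pmid), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  } else NULL
  taxa <- if (length(taxa_rows)) {
    tx <- do.call(rbind, taxa_rows)
    tx <- tx[c_order(tx$pmid, tx$tax_id), , drop = FALSE]
    rownames(tx) <- NULL
    tx
  } else data.frame(pmid = character(), tax_id = integer(),
                    stringsAsFactors = FALSE)
  if (!hard && !is.null(truth))
    write.table(truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write.table(taxa, file.path(out_dir, "taxon_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(files = files, truth = truth, taxa = taxa))
}

.write_pubmed_xml <- function(pmids, titles, abstracts, path) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_along(pmids)) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", pmids[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", titles[i])
    ab <- xml2::xml_add_child(a, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", abstracts[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
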