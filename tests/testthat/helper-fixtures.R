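# Fixtures are built in code: small lexicons and PubMed XML files written
# to tempdir() on demand.

demo_lex <- demo_lexicon()
demo_lex_path <- system.file("extdata", "plant_demo_lexicon.tsv",
                             package = "litcooc")

# Write a minimal lexicon file from row vectors.
write_lexicon_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

tiny_lexicon <- function() {
  load_lexicon(write_lexicon_file(c(
    "BIOENTITY\trbcL\trbcL\tprotein",
    "BIOENTITY\tpsbA\tpsbA\tprotein",
    "BIOENTITY\tmatK\tmatK\tprotein",
    "TERM\tactivates",
    "TERM\tinduced",
    "TAXON\tGlycine max\t3847",
    "TAXON\tsoybean\t3847")))
}

# Build a PubMed XML file from parallel vectors.
write_pubmed_fixture <- function(pmids, titles, abstracts,
                                 path = tempfile(fileext = ".xml"),
                                 root = "PubmedArticleSet") {
  doc <- xml2::xml_new_root(root)
  for (i in seq_along(pmids)) {
    if (root == "PubmedArticleSet") {
      art <- xml2::xml_add_child(doc, "PubmedArticle")
      cit <- xml2::xml_add_child(art, "MedlineCitation")
    } else {
      cit <- xml2::xml_add_child(doc, "MedlineCitation")
    }
    if (!is.na(pmids[i])) xml2::xml_add_child(cit, "PMID", pmids[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", titles[i])
    if (!is.na(abstracts[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      for (part in strsplit(abstracts[i], "\n", fixed = TRUE)[[1]])
        xml2::xml_add_child(ab, "AbstractText", part)
    }
  }
  xml2::write_xml(doc, path)
  path
}

# Record with a neutral title that always segments as sentence 0, so the
# body text under test starts at sentence_index 1.
rec1 <- function(text, pmid = "1") abstract_record(pmid, "Title.", text)

# Random record made of safe filler-ish words (no lexicon collisions
# guaranteed; used only for offset / round-trip properties).
random_record <- function(pmid, n_words = 30) {
  words <- replicate(n_words,
    paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = ""))
  k <- max(1L, n_words %/% 10L)
  stops <- sort(sample(seq_len(n_words - 1), k))
  words[stops] <- paste0(words[stops], ".")
  abstract_record(pmid, "Title here.", paste(words, collapse = " "))
}

# Random entity mentions over a record: token spans chosen at random.
random_mentions <- function(rec, n = 3) {
  toks <- do.call(rbind, lapply(seq_len(nrow(rec$sentences)), function(s)
    litcooc:::.sentence_tokens(rec, s)))
  if (nrow(toks) == 0) return(NULL)
  idx <- sample(nrow(toks), min(n, nrow(toks)))
  data.frame(pmid = rec$pmid, start = toks$start[idx], end = toks$end[idx],
             surface = toks$token[idx],
             normalized = toupper(toks$token[idx]),
             entity_class = sample(c("protein", "gene", "taxon"),
                                   length(idx), replace = TRUE),
             score = round(runif(length(idx)), 3),
             stringsAsFactors = FALSE)
}
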