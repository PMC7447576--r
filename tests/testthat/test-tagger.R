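# entity_tagger: dictionary tagging, term modes, external tag import.

test_that("tag_entities: whole-token, case-folded, longest match", {
  r <- rec1("rbcL interacts with psbA")
  em <- tag_entities(r, demo_lex)
  em <- em[em$sentence_index == 1, ]
  expect_identical(em$normalized, c("rbcL", "psbA"))
  expect_identical(em$entity_class, c("protein", "protein"))

  # longest match beats the shorter dictionary entry
  r2 <- rec1("glutathione S-transferase is induced")
  em2 <- tag_entities(r2, demo_lex)
  em2 <- em2[em2$sentence_index == 1, ]
  expect_identical(nrow(em2), 1L)
  expect_identical(em2$normalized, "glutathione S-transferase")

  # case folding normalizes to the dictionary name
  r3 <- rec1("RBCL accumulates")
  em3 <- tag_entities(r3, demo_lex)
  expect_identical(em3$normalized[em3$sentence_index == 1], "rbcL")

  # substrings never match: whole-token anchoring
  r4 <- rec1("rbcLx and xpsbA here")
  expect_identical(nrow(tag_entities(r4, demo_lex)[
    tag_entities(r4, demo_lex)$sentence_index == 1, ]), 0L)
})

test_that("entity mentions never overlap and tagging is pure", {
  texts <- c("rbcL glutathione S-transferase transferase psbA matK",
             "PR-1 PDF1.2 NPR1 lipid transfer protein LTP")
  for (tx in texts) {
    r <- rec1(tx)
    em <- tag_entities(r, demo_lex)
    em <- em[order(em$start), ]
    if (nrow(em) > 1)
      expect_true(all(em$start[-1] >= em$end[-nrow(em)]))
    expect_identical(tag_entities(r, demo_lex), tag_entities(r, demo_lex))
  }
})

test_that("tag_terms reports each span once with the strongest mode", {
  r <- rec1("rbcL activates psbA")
  tm <- tag_terms(r, demo_lex)
  tm <- tm[tm$sentence_index == 1, ]
  expect_identical(nrow(tm), 1L)
  expect_identical(tm$match_mode, "exact")

  r2 <- rec1("rbcL activation of psbA")
  tm2 <- tag_terms(r2, demo_lex)
  tm2 <- tm2[tm2$sentence_index == 1, ]
  expect_identical(nrow(tm2), 1L)
  expect_identical(tm2$match_mode, "permissive")
  expect_identical(tm2$surface, "activation")

  r3 <- rec1("rbcL and psbA")
  expect_identical(nrow(tag_terms(r3, demo_lex)[
    tag_terms(r3, demo_lex)$sentence_index == 1, ]), 0L)

  # exact mode implies the same span also matches permissively
  r4 <- rec1("NPR1 induced PR-1 activation of PDF1.2")
  tm4 <- tag_terms(r4, demo_lex)
  ex <- tm4[tm4$match_mode == "exact", ]
  for (i in seq_len(nrow(ex))) {
    tok <- litcooc::lookup_term(ex$surface[i], demo_lex, "permissive")
    expect_gt(length(tok), 0L)
  }
})

test_that("planted verbatim names are recovered with precision = recall = 1", {
  set.seed(41)
  prot <- c("rbcL", "psbA", "matK", "NPR1", "PR-1", "PDF1.2")
  for (r in 1:20) {
    planted <- sample(prot, sample(2:4, 1))
    filler <- replicate(6, paste(sample(letters, 7, TRUE), collapse = ""))
    words <- sample(c(planted, filler))
    rec <- rec1(paste(paste(words, collapse = " "), ".", sep = ""))
    em <- tag_entities(rec, demo_lex)
    em <- em[em$sentence_index == 1, ]
    expect_setequal(em$normalized, planted)        # recall
    expect_identical(nrow(em), length(planted))    # precision
  }
})

test_that("import_external_tags validates rows and replaces dictionary tags", {
  recs <- list(abstract_record("1", "Title.", "rbcL binds psbA in leaves."),
               abstract_record("2", "Title.", "matK is induced."))
  path <- tempfile(fileext = ".tsv")
  ok <- data.frame(pmid = "1", start = c(7L, 12L, 18L), end = c(11L, 17L, 22L),
                   surface = c("rbcL", "binds", "psbA"),
                   normalized = c("rbcL", "BINDS", "psbA"),
                   entity_class = "protein", score = 0.9,
                   stringsAsFactors = FALSE)
  write_tag_interchange(ok, path)
  m <- import_external_tags(path, recs)
  expect_identical(nrow(m), 3L)
  expect_identical(unique(m$pmid), "1")
  expect_identical(unique(m$score), 0.9)

  # absent pmid and sentence-crossing span are dropped with warnings
  bad <- rbind(ok[1, ],
               data.frame(pmid = "99", start = 0L, end = 4L, surface = "x",
                          normalized = "x", entity_class = "protein",
                          score = 1, stringsAsFactors = FALSE),
               data.frame(pmid = "1", start = 0L, end = 10L, surface = "x",
                          normalized = "x", entity_class = "protein",
                          score = 1, stringsAsFactors = FALSE))
  write_tag_interchange(bad, path)
  expect_warning(expect_warning(m2 <- import_external_tags(path, recs),
                                "unknown PMID"), "crossing a sentence")
  expect_identical(nrow(m2), 1L)

  # replacement semantics: record 1 mined with imported tags only,
  # record 2 still dictionary-tagged
  write_tag_interchange(ok, path)
  cooc <- mine_records(recs, demo_lex, tags = path)
  ents <- attr(cooc, "entities")
  expect_identical(sort(unique(ents$normalized[ents$pmid == "1"])),
                   sort(c("rbcL", "BINDS", "psbA")))
  expect_true("matK" %in% ents$normalized[ents$pmid == "2"])
})
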