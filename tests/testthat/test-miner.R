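# cooccurrence_miner: type rules, abstract-level mining, filters.

mine_text <- function(text, pmid = "1", lex = demo_lex) {
  r <- rec1(text, pmid)
  mine_abstract(r, tag_entities(r, lex), tag_terms(r, lex),
                tag_concepts(r, lex))
}

pair_mentions <- function(text, lex = demo_lex) {
  r <- rec1(text)
  em <- tag_entities(r, lex)
  em <- em[em$sentence_index == 1 & em$entity_class %in% c("protein", "gene"), ]
  tm <- tag_terms(r, lex)
  list(a = em[1, ], b = em[2, ], terms = tm[tm$sentence_index == 1, ])
}

test_that("classify_pair_in_sentence applies rules 1-3 and the fallthrough", {
  x <- pair_mentions("rbcL activates psbA")
  expect_identical(classify_pair_in_sentence(x$a, x$b, x$terms), 1L)

  x <- pair_mentions("rbcL and psbA are induced")
  expect_identical(classify_pair_in_sentence(x$a, x$b, x$terms), 2L)

  x <- pair_mentions("rbcL and psbA activation")
  expect_identical(classify_pair_in_sentence(x$a, x$b, x$terms), 3L)

  x <- pair_mentions("rbcL and psbA in leaves")
  expect_true(is.na(classify_pair_in_sentence(x$a, x$b, x$terms)))

  # mentions in different sentences violate the contract
  r <- rec1("rbcL is here. psbA is there.")
  em <- tag_entities(r, demo_lex)
  expect_error(classify_pair_in_sentence(em[1, ], em[2, ],
                                         tag_terms(r, demo_lex)),
               "different sentences")
})

test_that("mine_abstract reports the minimal type with earliest evidence", {
  m <- mine_text("rbcL activates psbA. psbA is degraded.")
  expect_identical(nrow(m), 1L)
  expect_identical(m$type, 1L)
  expect_identical(m$sentence_index, 1L)
  expect_identical(m$terms, "activates")

  # no shared sentence, no trigger near both: abstract-level type 4
  m2 <- mine_text("rbcL occurs alone here. matK occurs alone there.")
  expect_identical(m2[, c("entity_a", "entity_b", "type")],
                   data.frame(entity_a = "matK", entity_b = "rbcL",
                              type = 4L, stringsAsFactors = FALSE))
  expect_true(is.na(m2$sentence_index))

  # a name mentioned twice is never a pair with itself
  expect_identical(nrow(mine_text("rbcL binds and rbcL folds.")), 0L)

  # three names in one sentence: C(3,2) pairs, each typed independently,
  # verified against the brute-force enumerator
  r <- rec1("rbcL, psbA and matK are encoded in plastids.")
  expect_oracle_equivalent(list(r), demo_lex)
  m3 <- mine_text("rbcL, psbA and matK are encoded in plastids.")
  expect_identical(nrow(m3), 3L)
  expect_true(all(m3$type %in% 1:2))
})

test_that("multiple mentions per name allow any combination to satisfy rule 1", {
  # first rbcL mention is after psbA, second is before with trigger between
  m <- mine_text("psbA rbcL and rbcL activates psbA now.")
  expect_identical(m$type, 1L)
})

test_that("evidence terms match the type criterion", {
  # type 2: trigger outside the between-interval is listed as evidence
  m <- mine_text("induced rbcL and psbA levels here.")
  expect_identical(m$type, 2L)
  expect_identical(m$terms, "induced")
  # type 3 evidence is the permissive-only span
  m3 <- mine_text("rbcL and psbA activation here.")
  expect_identical(m3$type, 3L)
  expect_true(nzchar(m3$terms))
  # type 4 carries no term evidence
  m4 <- mine_text("rbcL occurs alone here. matK occurs alone there.")
  expect_identical(m4$terms, "")
})

test_that("concepts attach to the evidence sentence (1-3) or abstract (4)", {
  m <- mine_text("rbcL activates psbA under biotic stress. The chloroplast matters.")
  expect_identical(m$concepts, "biotic stress")
  m4 <- mine_text("rbcL alone under biotic stress. matK alone in the chloroplast.")
  expect_identical(m4$type, 4L)
  expect_identical(m4$concepts, "biotic stress;chloroplast")
})

test_that("mining is invariant under mention input order", {
  r <- rec1("rbcL activates psbA. matK and NPR1 were induced. PR-1 alone.")
  em <- tag_entities(r, demo_lex)
  tm <- tag_terms(r, demo_lex)
  base <- mine_abstract(r, em, tm)
  set.seed(51)
  for (i in 1:5) {
    p1 <- em[sample(nrow(em)), ]
    p2 <- tm[sample(nrow(tm)), ]
    expect_identical(mine_abstract(r, p1, p2), base)
  }
})

test_that("type counting is conservative", {
  texts <- c("rbcL activates psbA.", "matK and NPR1 were induced.",
             "PR-1 and PR-5 activation.", "EDS1 alone here. PAD4 alone there.")
  recs <- lapply(seq_along(texts), function(i) rec1(texts[i], as.character(i)))
  cooc <- mine_records(recs, demo_lex)
  per_type <- vapply(1:4, function(t) sum(cooc$type == t), 0L)
  expect_identical(sum(per_type), nrow(cooc))
  nonred <- nrow(unique(cooc[, c("entity_a", "entity_b")]))
  expect_lte(nonred, nrow(cooc))
})

test_that("filter_by_taxon keeps abstracts with a resolving taxon mention", {
  recs <- list(
    abstract_record("1", "Title.", "rbcL activates psbA in Glycine max."),
    abstract_record("2", "Title.", "matK and NPR1 were induced in Zea mays."))
  cooc <- mine_records(recs, demo_lex)
  ents <- attr(cooc, "entities")
  f <- filter_by_taxon(cooc, ents, 3847, demo_lex)
  expect_identical(unique(f$pmid), "1")
  # mixed-species abstract: one resolving mention suffices
  recs3 <- list(abstract_record("3", "Title.",
    "rbcL activates psbA in Glycine max and Zea mays."))
  c3 <- mine_records(recs3, demo_lex)
  expect_identical(nrow(filter_by_taxon(c3, attr(c3, "entities"), 3847,
                                        demo_lex)), 1L)
  # tax-ID absent from the corpus selects nothing
  expect_identical(nrow(filter_by_taxon(cooc, ents, 9606, demo_lex)), 0L)
})

test_that("select_type is an order-preserving filter", {
  df <- data.frame(pmid = as.character(1:4), entity_a = "A", entity_b = "B",
                   type = 1:4, sentence_index = NA_integer_, terms = "",
                   concepts = "", sentence_text = "",
                   stringsAsFactors = FALSE)
  expect_identical(select_type(df, 1)$type, 1L)
  expect_identical(select_type(df, 4), df)
  expect_identical(nrow(select_type(df[0, ], 2)), 0L)
  expect_error(select_type(df, 7))
})

test_that("cooccurrence TSV round-trips", {
  m <- mine_text("rbcL activates psbA under biotic stress. matK alone.")
  path <- tempfile(fileext = ".tsv")
  write_cooccurrences(m, path)
  back <- read_cooccurrences(path)
  expect_equal(back, m, ignore_attr = TRUE)
})
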