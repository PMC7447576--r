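# summary_reporter: tallies, basic N+1 mode, spread mode.

cooc_row <- function(pmid, a, b, type, terms = "") {
  data.frame(pmid = pmid, entity_a = a, entity_b = b, type = type,
             sentence_index = if (type < 4) 1L else NA_integer_,
             terms = terms, concepts = "", sentence_text = "",
             stringsAsFactors = FALSE)
}

write_cooc_fixture <- function(rows, dir, name) {
  path <- file.path(dir, paste0(name, ".cooc.tsv"))
  write_cooccurrences(do.call(rbind, rows), path)
  path
}

test_that("compute_stats tallies absolute vs non-redundant counts", {
  df <- rbind(cooc_row("1", "A", "B", 1, "activates"),
              cooc_row("2", "A", "B", 2, "induced"),
              cooc_row("3", "A", "C", 4))
  st <- compute_stats(df)
  expect_identical(st$totals$absolute_cooccurrences, 3L)
  expect_identical(st$totals$nonredundant_cooccurrences, 2L)
  expect_identical(unname(st$totals$per_type),
                   c(1L, 1L, 0L, 1L))
  expect_identical(st$totals$absolute_proteins, 6L)
  expect_identical(st$totals$nonredundant_proteins, 3L)
  expect_identical(st$totals$absolute_terms, 2L)
  # per-type totals sum to the absolute co-occurrence count
  expect_identical(sum(st$totals$per_type), st$totals$absolute_cooccurrences)
  # items seen at most twice are poorly described; A participates 3 times
  expect_true("A/B" %in% st$poorly$pairs)
  expect_true(all(c("B", "C") %in% st$poorly$proteins))
  expect_false("A" %in% st$poorly$proteins)

  st0 <- compute_stats(df[0, ])
  expect_identical(st0$totals$absolute_cooccurrences, 0L)
  expect_identical(st0$totals$nonredundant_proteins, 0L)
  expect_identical(st0$totals$absolute_terms, 0L)
})

test_that("malformed rows are counted and skipped", {
  df <- rbind(cooc_row("1", "A", "B", 1, "activates"),
              cooc_row("2", "", "B", 2),
              cooc_row("3", "A", "C", 9))
  expect_warning(st <- compute_stats(df), "malformed")
  expect_identical(st$n_malformed, 2L)
  expect_identical(st$totals$absolute_cooccurrences, 1L)
})

test_that("the extra section relates terms to pairs, totals match", {
  df <- rbind(cooc_row("1", "A", "B", 1, "activates;binds"),
              cooc_row("2", "A", "B", 1, "activates"),
              cooc_row("3", "B", "C", 2, "induced"))
  st <- compute_stats(df)
  ab <- st$extra[st$extra$term == "activates" & st$extra$pair == "A/B", ]
  expect_identical(ab$count, 2L)
  expect_true(all(st$extra$pair %in% st$pairs$pair))
  # per-term grand totals equal the term tallies (types 1-3 evidence only)
  agg <- tapply(st$extra$count, st$extra$term, sum)
  expect_identical(as.integer(agg[st$terms$term]), st$terms$count)
  expect_identical(sum(st$extra$count), st$totals$absolute_terms)
})

test_that("basic mode writes N + 1 summaries; join lacks the extra section", {
  for (n in c(1L, 3L)) {
    dir <- file.path(tempfile(), paste0("basic", n))
    dir.create(dir, recursive = TRUE)
    for (i in seq_len(n))
      write_cooc_fixture(list(cooc_row(as.character(i), "A", "B", 1,
                                       "activates")),
                         dir, paste0("f", i))
    files <- summarize_basic(dir)
    expect_length(files, n + 1L)
    expect_true(file.exists(file.path(dir, "A.join.dataset.summary")))
    if (n == 1L) {
      per <- readLines(files[1])
      join <- readLines(file.path(dir, "A.join.dataset.summary"))
      # identical except the per-file summary's trailing extra section
      i_extra <- match("EXTRA SECTION", per)
      expect_false(is.na(i_extra))
      expect_identical(per[seq_len(i_extra - 1L)], join)
    }
  }
  expect_error(summarize_basic(tempfile()), "no co-occurrence TSVs")
})

test_that("join totals are computed over the concatenation, not summed", {
  dir <- tempfile(); dir.create(dir)
  # the two files share pair A/B: join non-redundant < sum of per-file
  write_cooc_fixture(list(cooc_row("1", "A", "B", 1, "activates"),
                          cooc_row("2", "A", "C", 2, "induced")), dir, "f1")
  write_cooc_fixture(list(cooc_row("3", "A", "B", 2, "binds")), dir, "f2")
  summarize_basic(dir)
  join <- readLines(file.path(dir, "A.join.dataset.summary"))
  grab <- function(key) as.integer(sub(".*\t", "",
    join[startsWith(join, key)]))
  expect_identical(grab("cooccurrences_absolute"), 3L)
  expect_identical(grab("cooccurrences_nonredundant"), 2L)  # < 2 + 1
  expect_identical(grab("proteins_absolute"), 6L)
  # re-running is byte-idempotent
  before <- readLines(file.path(dir, "f1.cooc.summary"))
  summarize_basic(dir)
  expect_identical(readLines(file.path(dir, "f1.cooc.summary")), before)
})

test_that("spread mode stratifies by folder and pools over the union", {
  root <- tempfile(); dir.create(root)
  d1 <- file.path(root, "speciesA"); dir.create(d1)
  d2 <- file.path(root, "speciesB"); dir.create(d2)
  write_cooc_fixture(list(cooc_row("1", "A", "B", 1, "activates")), d1, "f1")
  write_cooc_fixture(list(cooc_row("2", "C", "D", 2, "induced")), d2, "f1")
  sp <- summarize_spread(c(d1, d2))
  # disjoint pairs: pooled non-redundant = sum of folder non-redundant
  expect_identical(sp$pooled$totals$nonredundant_cooccurrences, 2L)
  expect_true(file.exists(attr(sp, "path")))

  # shared pair: pooled non-redundant = sum - 1
  write_cooc_fixture(list(cooc_row("3", "A", "B", 2, "binds")), d2, "f2")
  sp2 <- summarize_spread(c(d1, d2))
  expect_identical(sp2$pooled$totals$nonredundant_cooccurrences,
                   sp2$speciesA$totals$nonredundant_cooccurrences +
                   sp2$speciesB$totals$nonredundant_cooccurrences - 1L)

  # empty folder: warning + skip; single folder pooled equals the folder
  d3 <- file.path(root, "empty"); dir.create(d3)
  expect_warning(sp3 <- summarize_spread(c(d1, d3)), "skipped")
  expect_identical(sp3$pooled$totals, sp3$speciesA$totals)
})
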