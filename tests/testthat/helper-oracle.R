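# Brute-force oracle: naive enumeration over all (pair, sentence, mention
# combination, term, mode) tuples, written independently of the miner's
# control flow. It consumes the same tagged mentions the miner consumes and
# re-derives the typed co-occurrence set from the rule definitions alone.

oracle_pair_type <- function(ma, mb, tm) {
  best <- 4L
  for (s in unique(c(ma$sentence_index, mb$sentence_index))) {
    as_ <- ma[ma$sentence_index == s, , drop = FALSE]
    bs_ <- mb[mb$sentence_index == s, , drop = FALSE]
    if (nrow(as_) == 0 || nrow(bs_) == 0) next
    st <- tm[tm$sentence_index == s, , drop = FALSE]
    for (i in seq_len(nrow(as_))) for (j in seq_len(nrow(bs_))) {
      lo <- min(as_$end[i], bs_$end[j])
      hi <- max(as_$start[i], bs_$start[j])
      for (k in seq_len(nrow(st))) {
        if (st$match_mode[k] == "exact" &&
            st$start[k] >= lo && st$end[k] <= hi)
          best <- min(best, 1L)
      }
    }
    if (any(st$match_mode == "exact")) best <- min(best, 2L)
    if (nrow(st) > 0) best <- min(best, 3L)
  }
  best
}

# Full oracle for one record: every unordered pair of distinct normalized
# protein/gene names, minimal qualifying type.
oracle_mine <- function(record, em, tm) {
  em <- em[em$entity_class %in% c("protein", "gene"), , drop = FALSE]
  nm <- sort(unique(em$normalized), method = "radix")
  if (length(nm) < 2)
    return(data.frame(pmid = character(), entity_a = character(),
                      entity_b = character(), type = integer(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
    rows[[length(rows) + 1]] <- data.frame(
      pmid = record$pmid, entity_a = nm[i], entity_b = nm[j],
      type = oracle_pair_type(em[em$normalized == nm[i], , drop = FALSE],
                              em[em$normalized == nm[j], , drop = FALSE],
                              tm),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$entity_a, out$entity_b, out$pmid, method = "radix"), ,
      drop = FALSE]
}

# Run miner and oracle over a set of records and compare the typed sets.
expect_oracle_equivalent <- function(records, lexicon) {
  for (rec in records) {
    em <- tag_entities(rec, lexicon)
    tm <- tag_terms(rec, lexicon)
    mined <- mine_abstract(rec, em, tm)
    got <- mined[, c("pmid", "entity_a", "entity_b", "type")]
    want <- oracle_mine(rec, em, tm)
    rownames(got) <- NULL
    rownames(want) <- NULL
    expect_identical(got, want,
                     label = paste("miner output for PMID", rec$pmid))
  }
}
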