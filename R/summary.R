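# The summary generator: per-output ".summary" reports with the
# term-to-co-occurrence "extra section", the basic mode's N+1 join file and
# the spread mode's cross-folder report.
#
# Counting conventions (stated in every report header): the event unit is
# one co-occurrence record, i.e. one (pmid, pair). The absolute protein
# tally counts pair slots (two per record, so absolute proteins = 2 x
# absolute co-occurrences, matching the reported 15,788 proteins in 7894
# co-occurrences pattern); the absolute term tally counts listed evidence
# terms (types 1-3 only). "Non-redundant" always means distinct.

#' Compute summary statistics from co-occurrence output
#'
#' @param x a co-occurrence data.frame, a path to one co-occurrence TSV, or
#'   a vector of paths (concatenated before tallying)
#' @param poorly_max items observed at most this many times are flagged as
#'   poorly described (default 2)
#' @param top_k number of entries kept in the top listings (default 10)
#' @return an object of class `cooc_summary`: list with `totals`,
#'   `proteins`, `pairs`, `terms`, `extra` (term x pair relation counts),
#'   `poorly` and `n_malformed`
#' @export
compute_stats <- function(x, poorly_max = 2L, top_k = 10L) {
  n_malformed <- 0L
  if (is.character(x)) {
    dfs <- lapply(x, read_cooccurrences)
    df <- do.call(rbind, dfs)
  } else df <- x
  bad <- is.na(df$type) | !(df$type %in% 1:4) | is.na(df$entity_a) |
    is.na(df$entity_b) | !nzchar(df$entity_a) | !nzchar(df$entity_b)
  if (any(bad)) {
    warning(sum(bad), " malformed co-occurrence row(s) skipped", call. = FALSE)
    n_malformed <- sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  n <- nrow(df)
  cp <- canonical_pair(df$entity_a, df$entity_b)
  pair_lab <- paste(cp$a, cp$b, sep = "/")
  per_type <- vapply(1:4, function(t) sum(df$type == t), 0L)
  names(per_type) <- paste0("type", 1:4)

  count_df <- function(v, key) {
    if (!length(v)) return(setNames(
      data.frame(character(), integer(), stringsAsFactors = FALSE),
      c(key, "count")))
    tb <- table(v)
    out <- data.frame(names(tb), as.integer(tb), stringsAsFactors = FALSE)
    names(out) <- c(key, "count")
    out[c_order(-out$count, out[[key]]), , drop = FALSE]
  }

  proteins <- count_df(c(df$entity_a, df$entity_b), "name")
  pairs <- count_df(pair_lab, "pair")
  if (nrow(pairs)) {
    for (t in 1:4)
      pairs[[paste0("type", t)]] <- vapply(pairs$pair, function(p)
        sum(pair_lab == p & df$type == t), 0L, USE.NAMES = FALSE)
  } else for (t in 1:4) pairs[[paste0("type", t)]] <- integer()
  rownames(proteins) <- NULL; rownames(pairs) <- NULL

  term_lists <- lapply(df$terms, semi_split)
  term_vec <- unlist(term_lists, use.names = FALSE)
  terms <- count_df(term_vec, "term")
  rownames(terms) <- NULL

  # extra section: how many co-occurrence records relate each term to each
  # pair
  extra <- if (length(term_vec)) {
    rel <- data.frame(
      term = term_vec,
      pair = rep(pair_lab, lengths(term_lists)),
      stringsAsFactors = FALSE)
    ag <- aggregate(list(count = rep(1L, nrow(rel))),
                    by = rel[, c("term", "pair")], FUN = sum)
    ag <- ag[c_order(ag$term, ag$pair), , drop = FALSE]
    rownames(ag) <- NULL
    ag
  } else data.frame(term = character(), pair = character(),
                    count = integer(), stringsAsFactors = FALSE)

  totals <- list(
    absolute_proteins = 2L * n,
    nonredundant_proteins = nrow(proteins),
    absolute_cooccurrences = n,
    nonredundant_cooccurrences = nrow(pairs),
    absolute_terms = length(term_vec),
    nonredundant_terms = nrow(terms),
    per_type = per_type)

  poorly <- list(
    proteins = proteins$name[proteins$count <= poorly_max],
    pairs = pairs$pair[pairs$count <= poorly_max],
    terms = terms$term[terms$count <= poorly_max])

  structure(list(totals = totals, proteins = proteins, pairs = pairs,
                 terms = terms, extra = extra, poorly = poorly,
                 poorly_max = as.integer(poorly_max),
                 top_k = as.integer(top_k), n_malformed = n_malformed),
            class = "cooc_summary")
}

#' @export
print.cooc_summary <- function(x, ...) {
  tt <- x$totals
  cat(sprintf(paste0("<cooc_summary> %d co-occurrences (%d non-redundant), ",
                     "%d proteins (%d non-redundant), %d terms (%d ",
                     "non-redundant)\n  per type: %s\n"),
              tt$absolute_cooccurrences, tt$nonredundant_cooccurrences,
              tt$absolute_proteins, tt$nonredundant_proteins,
              tt$absolute_terms, tt$nonredundant_terms,
              paste(sprintf("t%d=%d", 1:4, tt$per_type), collapse = " ")))
  invisible(x)
}

# Render a summary as the human-readable ".summary" text. The layout is
# fixed so that two summaries over the same rows are byte-identical, and a
# join summary differs from a single-file summary only by the EXTRA SECTION
# block at the end.
format_summary <- function(stats, extra = TRUE) {
  tt <- stats$totals
  k <- stats$top_k
  lines <- c(
    "# co-occurrence mining summary",
    "# event unit: one (pmid, pair) record; non-redundant = distinct",
    "TOTALS",
    sprintf("proteins_absolute\t%d", tt$absolute_proteins),
    sprintf("proteins_nonredundant\t%d", tt$nonredundant_proteins),
    sprintf("cooccurrences_absolute\t%d", tt$absolute_cooccurrences),
    sprintf("cooccurrences_nonredundant\t%d", tt$nonredundant_cooccurrences),
    sprintf("terms_absolute\t%d", tt$absolute_terms),
    sprintf("terms_nonredundant\t%d", tt$nonredundant_terms),
    sprintf("type%d_total\t%d", 1:4, tt$per_type),
    "PROTEINS",
    sprintf("%s\t%d", head(stats$proteins$name, k),
            head(stats$proteins$count, k)),
    "COOCCURRENCES",
    sprintf("%s\t%d\t%d\t%d\t%d\t%d", head(stats$pairs$pair, k),
            head(stats$pairs$count, k), head(stats$pairs$type1, k),
            head(stats$pairs$type2, k), head(stats$pairs$type3, k),
            head(stats$pairs$type4, k)),
    "TERMS",
    sprintf("%s\t%d", head(stats$terms$term, k), head(stats$terms$count, k)),
    sprintf("POORLY DESCRIBED (count <= %d)", stats$poorly_max),
    sprintf("proteins\t%s", paste(stats$poorly$proteins, collapse = ";")),
    sprintf("cooccurrences\t%s", paste(stats$poorly$pairs, collapse = ";")),
    sprintf("terms\t%s", paste(stats$poorly$terms, collapse = ";")))
  if (extra) {
    lines <- c(lines, "EXTRA SECTION",
               if (nrow(stats$extra))
                 sprintf("%s\t%s\t%d", stats$extra$term, stats$extra$pair,
                         stats$extra$count))
  }
  lines
}

.write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Machine-readable sibling: long TSV (section, key, value).
.write_summary_tsv <- function(stats, path) {
  tt <- stats$totals
  rows <- c(
    sprintf("TOTAL\t%s\t%d",
            c("proteins_absolute", "proteins_nonredundant",
              "cooccurrences_absolute", "cooccurrences_nonredundant",
              "terms_absolute", "terms_nonredundant",
              paste0("type", 1:4, "_total")),
            c(tt$absolute_proteins, tt$nonredundant_proteins,
              tt$absolute_cooccurrences, tt$nonredundant_cooccurrences,
              tt$absolute_terms, tt$nonredundant_terms, tt$per_type)),
    sprintf("PROTEIN\t%s\t%d", stats$proteins$name, stats$proteins$count),
    sprintf("COOCCURRENCE\t%s\t%d", stats$pairs$pair, stats$pairs$count),
    sprintf("TERM\t%s\t%d", stats$terms$term, stats$terms$count),
    if (nrow(stats$extra))
      sprintf("EXTRA\t%s|%s\t%d", stats$extra$term, stats$extra$pair,
              stats$extra$count))
  .write_lines(c("section\tkey\tvalue", rows), path)
}

#' Basic summary mode
#'
#' Writes N + 1 summary files for a folder holding N co-occurrence TSVs:
#' one `<name>.summary` per input (each including the EXTRA SECTION that
#' relates every term to its co-occurrences), plus one join file
#' `A.join.dataset.summary`, computed over the concatenation of all inputs
#' and written without the extra section. Each `<name>.summary` also gets a
#' machine-readable `<name>.summary.tsv` sibling.
#'
#' @param result_folder folder containing co-occurrence TSVs
#' @param pattern filename pattern selecting the inputs
#' @param poorly_max threshold for the poorly-described flag
#' @return character vector of the `.summary` files written, invisibly
#' @export
summarize_basic <- function(result_folder, pattern = "\\.cooc\\.tsv$",
                            poorly_max = 2L) {
  files <- list.files(result_folder, pattern = pattern, full.names = TRUE)
  files <- c_sort(files)
  if (!length(files))
    stop("no co-occurrence TSVs found in folder: ", result_folder,
         call. = FALSE)
  written <- character()
  for (f in files) {
    st <- compute_stats(f, poorly_max = poorly_max)
    out <- paste0(sub("\\.tsv$", "", f), ".summary")
    .write_lines(format_summary(st, extra = TRUE), out)
    .write_summary_tsv(st, paste0(out, ".tsv"))
    written <- c(written, out)
  }
  st_all <- compute_stats(files, poorly_max = poorly_max)
  join <- file.path(result_folder, "A.join.dataset.summary")
  .write_lines(format_summary(st_all, extra = FALSE), join)
  invisible(c(written, join))
}

#' Spread summary mode
#'
#' Joins the results of several folders (e.g. one per species analyzed
#' against the same corpus) into a single report, stratified by folder
#' label with a pooled section computed over all rows.
#'
#' @param folder_list character vector of folders each holding
#'   co-occurrence TSVs
#' @param out path of the report to write (default `spread.summary` next to
#'   the first folder)
#' @param pattern filename pattern selecting the inputs
#' @param poorly_max threshold for the poorly-described flag
#' @return list with one `cooc_summary` per folder (named by folder
#'   basename) and `pooled`, invisibly
#' @export
summarize_spread <- function(folder_list, out = NULL,
                             pattern = "\\.cooc\\.tsv$", poorly_max = 2L) {
  per <- list()
  all_files <- character()
  for (folder in folder_list) {
    files <- c_sort(list.files(folder, pattern = pattern, full.names = TRUE))
    if (!length(files)) {
      warning("folder with no summarizable output skipped: ", folder,
              call. = FALSE)
      next
    }
    per[[basename(folder)]] <- compute_stats(files, poorly_max = poorly_max)
    all_files <- c(all_files, files)
  }
  if (!length(all_files))
    stop("no summarizable folders in folder_list", call. = FALSE)
  pooled <- compute_stats(all_files, poorly_max = poorly_max)
  if (is.null(out))
    out <- file.path(dirname(folder_list[[1L]]), "spread.summary")
  lines <- character()
  for (label in names(per)) {
    lines <- c(lines, sprintf("=== FOLDER %s ===", label),
               format_summary(per[[label]], extra = FALSE))
  }
  lines <- c(lines, "=== POOLED ===", format_summary(pooled, extra = FALSE))
  .write_lines(lines, out)
  res <- c(per, list(pooled = pooled))
  attr(res, "path") <- out
  invisible(res)
}
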