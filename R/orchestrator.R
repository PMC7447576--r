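# Shard-parallel execution: the parallel unit is the input FILE, exactly
# one file per worker at a time, so the mining output is a pure function of
# the inputs and is byte-identical for any worker count. Each worker loads
# its own read-only lexicon copy (the analogue of shipping the DB file to
# every node and loading it into RAM there).

#' Build a pipeline run configuration
#'
#' @param input_paths ordered character vector of PubMed XML files
#' @param lexicon_path path to the lexicon TSV "DB file"
#' @param output_dir directory for per-file co-occurrence TSVs and the run
#'   manifest (created if missing)
#' @param jobs number of parallel workers (>= 1; forked processes)
#' @param tax_id optional NCBI tax-ID filter
#' @param max_type keep co-occurrences with type <= max_type (default 4)
#' @param tags_path optional tag-interchange TSV with external entity tags
#' @param seed integer seed forwarded to synthetic runs
#' @param log_level `"info"` or `"quiet"`
#' @return a `run_config` list
#' @export
run_config <- function(input_paths, lexicon_path, output_dir, jobs = 1L,
                       tax_id = NULL, max_type = 4L, tags_path = NULL,
                       seed = 1L, log_level = c("info", "quiet")) {
  jobs <- as.integer(jobs)
  if (is.na(jobs) || jobs < 1L) stop("jobs must be >= 1", call. = FALSE)
  if (!length(input_paths)) stop("input_paths must be non-empty", call. = FALSE)
  stopifnot(max_type %in% 1:4)
  structure(list(input_paths = as.character(input_paths),
                 lexicon_path = lexicon_path, output_dir = output_dir,
                 jobs = jobs, tax_id = tax_id,
                 max_type = as.integer(max_type), tags_path = tags_path,
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Round-robin sharding of input files
#'
#' Assigns every path to exactly one worker as a pure function of the path
#' order and the worker count; shard sizes differ by at most one.
#'
#' @param paths character vector of input paths
#' @param jobs number of workers (>= 1)
#' @return list of `jobs` character vectors (possibly empty)
#' @export
shard_inputs <- function(paths, jobs) {
  jobs <- as.integer(jobs)
  if (is.na(jobs) || jobs < 1L) stop("jobs must be >= 1", call. = FALSE)
  shards <- rep(list(character()), jobs)
  if (length(paths)) {
    assign <- ((seq_along(paths) - 1L) %% jobs) + 1L
    for (w in seq_len(jobs)) shards[[w]] <- paths[assign == w]
  }
  shards
}

# Process one XML file end to end; returns a one-row log data.frame.
.process_file <- function(path, lexicon, output_dir, tax_id = NULL,
                          max_type = 4L, tags = NULL) {
  out_name <- paste0(sub("\\.xml$", "", basename(path)), ".cooc.tsv")
  out_path <- file.path(output_dir, out_name)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch({
    records <- parse_medline_xml(path)
    cooc <- mine_records(records, lexicon, tags = tags)
    ents <- attr(cooc, "entities")
    if (!is.null(tax_id))
      cooc <- filter_by_taxon(cooc, ents, tax_id, lexicon)
    if (max_type < 4L) cooc <- select_type(cooc, max_type)
    write_cooccurrences(cooc, out_path)
    data.frame(file = basename(path), status = "ok",
               n_records = length(records),
               n_no_abstract = attr(records, "n_no_abstract") %||% 0L,
               n_skipped_records = attr(records, "n_skipped") %||% 0L,
               n_cooccurrences = nrow(cooc),
               seconds = round(proc.time()[["elapsed"]] - t0, 3),
               error = "", stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(file = basename(path), status = "skipped", n_records = 0L,
               n_no_abstract = 0L, n_skipped_records = 0L,
               n_cooccurrences = 0L,
               seconds = round(proc.time()[["elapsed"]] - t0, 3),
               error = conditionMessage(e), stringsAsFactors = FALSE)
  })
  res
}

#' Run the full mining pipeline over a corpus
#'
#' parse -> tag -> mine for every input XML file, one co-occurrence TSV per
#' input (named `<input>.cooc.tsv`), executed by `jobs` forked workers with
#' round-robin file sharding. Unreadable inputs are skipped and logged; a
#' missing lexicon is fatal before any worker starts. A run manifest
#' (`run_manifest.tsv`) with per-file record counts, skip counts and timing
#' is written to the output directory. After canonical sorting the mining
#' outputs are byte-identical for any `jobs` value.
#'
#' @param config a [run_config()]
#' @return the run log data.frame (one row per input file), invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$lexicon_path))
    stop("lexicon file not found: ", config$lexicon_path, call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tags <- NULL
  if (!is.null(config$tags_path)) tags <- config$tags_path

  worker <- function(shard) {
    if (!length(shard)) return(NULL)
    lex <- load_lexicon(config$lexicon_path)  # per-worker read-only copy
    tg <- if (is.null(tags)) NULL else read_tag_interchange(tags)
    do.call(rbind, lapply(shard, function(p)
      .process_file(p, lex, config$output_dir, tax_id = config$tax_id,
                    max_type = config$max_type, tags = tg)))
  }

  shards <- shard_inputs(config$input_paths, config$jobs)
  logs <- if (config$jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(shards, worker, mc.cores = config$jobs)
  } else {
    lapply(shards, worker)
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  log <- log[c_order(log$file), , drop = FALSE]
  rownames(log) <- NULL
  manifest <- file.path(config$output_dir, "run_manifest.tsv")
  write.table(log, manifest, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (config$log_level == "info") {
    for (i in seq_len(nrow(log)))
      message(sprintf("[mine] %s: %s, %d records, %d cooccurrences%s",
                      log$file[i], log$status[i], log$n_records[i],
                      log$n_cooccurrences[i],
                      if (nzchar(log$error[i]))
                        paste0(" (", log$error[i], ")") else ""))
    n_skip <- sum(log$status != "ok")
    if (n_skip > 0L)
      message(sprintf("[mine] WARNING: %d input file(s) skipped", n_skip))
  }
  invisible(log)
}
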