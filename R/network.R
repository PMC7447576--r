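# Aggregate typed co-occurrences into a weighted network for downstream
# visualization (Cytoscape & friends): SIF, TSV and GraphML exports.

#' Build network edges from co-occurrences
#'
#' One edge per canonical pair. The edge weight counts supporting
#' abstracts (one co-occurrence record per (pmid, pair), so weight equals
#' the number of supporting PMIDs and the per-type counts sum to it);
#' `best_type` is the most reliable (minimum) type observed for the pair.
#'
#' @param cooccurrences co-occurrence data.frame (see [mine_abstract()])
#' @return data.frame with columns `entity_a`, `entity_b`, `weight`,
#'   `type1`..`type4`, `best_type`, `pmids` (semicolon list), ordered by
#'   (weight desc, pair asc)
#' @export
build_edges <- function(cooccurrences) {
  empty <- data.frame(entity_a = character(), entity_b = character(),
                      weight = integer(), type1 = integer(),
                      type2 = integer(), type3 = integer(),
                      type4 = integer(), best_type = integer(),
                      pmids = character(), stringsAsFactors = FALSE)
  df <- cooccurrences
  if (is.null(df) || nrow(df) == 0L) return(empty)
  cp <- canonical_pair(df$entity_a, df$entity_b)
  df$entity_a <- cp$a; df$entity_b <- cp$b
  # defensive: one record per (pmid, pair)
  df <- df[!duplicated(paste(df$pmid, df$entity_a, df$entity_b, sep = "\r")), ,
           drop = FALSE]
  key <- paste(df$entity_a, df$entity_b, sep = "\r")
  rows <- lapply(c_sort(unique(key)), function(k) {
    g <- df[key == k, , drop = FALSE]
    data.frame(entity_a = g$entity_a[1L], entity_b = g$entity_b[1L],
               weight = nrow(g),
               type1 = sum(g$type == 1L), type2 = sum(g$type == 2L),
               type3 = sum(g$type == 3L), type4 = sum(g$type == 4L),
               best_type = min(g$type),
               pmids = semi_join(g$pmid), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[c_order(-res$weight, res$entity_a, res$entity_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.edge_cols <- c("entity_a", "entity_b", "weight", "type1", "type2", "type3",
                "type4", "best_type", "pmids")

#' Export a co-occurrence network
#'
#' Formats: `sif` (one line `a cooccur_t<best_type> b`), `tsv` (mirror of
#' the edge table) and `graphml` (via igraph; weight, per-type counts,
#' best_type and supporting PMIDs carried as edge attributes, with optional
#' node attributes).
#'
#' @param edges edge data.frame from [build_edges()]
#' @param path output file
#' @param format one of `"sif"`, `"tsv"`, `"graphml"`
#' @param nodes optional data.frame of node attributes (`name` plus e.g.
#'   `entity_class`, `mention_count`) attached in GraphML output
#' @return `path`, invisibly
#' @export
export_network <- function(edges, path, format = c("tsv", "sif", "graphml"),
                           nodes = NULL) {
  if (!is.character(format) || !all(format %in% c("tsv", "sif", "graphml")))
    stop("unknown network format '", paste(format, collapse = ","),
         "'; supported: sif, tsv, graphml", call. = FALSE)
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s cooccur_t%d %s", edges$entity_a, edges$best_type,
                     edges$entity_b)
    .write_lines(lines, path)
  } else if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(.edge_cols, collapse = "\t"), con, sep = "\n")
    if (nrow(edges))
      writeLines(enc2utf8(sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s",
                                  edges$entity_a, edges$entity_b,
                                  edges$weight, edges$type1, edges$type2,
                                  edges$type3, edges$type4, edges$best_type,
                                  edges$pmids)),
                 con, sep = "\n", useBytes = TRUE)
  } else {
    g <- .edges_to_igraph(edges, nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.edges_to_igraph <- function(edges, nodes = NULL) {
  vnames <- c_sort(unique(c(edges$entity_a, edges$entity_b,
                            if (!is.null(nodes)) nodes$name)))
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  if (nrow(edges)) {
    idx <- rbind(match(edges$entity_a, vnames), match(edges$entity_b, vnames))
    g <- igraph::add_edges(g, as.vector(idx))
    for (a in c("weight", "type1", "type2", "type3", "type4", "best_type"))
      g <- igraph::set_edge_attr(g, a, value = as.numeric(edges[[a]]))
    g <- igraph::set_edge_attr(g, "pmids", value = edges$pmids)
  }
  if (!is.null(nodes)) {
    for (a in setdiff(names(nodes), "name")) {
      v <- nodes[[a]][match(vnames, nodes$name)]
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  g
}

#' Read a network export back into an edge table
#'
#' Round-trip companion of [export_network()] for the `tsv` and `graphml`
#' formats.
#'
#' @param path file written by [export_network()]
#' @param format `"tsv"` or `"graphml"`
#' @return edge data.frame in the [build_edges()] layout
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer",
                                    "integer", "integer", "integer",
                                    "integer", "integer", "character"),
                     encoding = "UTF-8")
    df$pmids[is.na(df$pmids)] <- ""
    return(df)
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(build_edges(NULL))
  cp <- canonical_pair(el[, 1L], el[, 2L])
  res <- data.frame(entity_a = cp$a, entity_b = cp$b,
                    weight = as.integer(igraph::edge_attr(g, "weight")),
                    type1 = as.integer(igraph::edge_attr(g, "type1")),
                    type2 = as.integer(igraph::edge_attr(g, "type2")),
                    type3 = as.integer(igraph::edge_attr(g, "type3")),
                    type4 = as.integer(igraph::edge_attr(g, "type4")),
                    best_type = as.integer(igraph::edge_attr(g, "best_type")),
                    pmids = as.character(igraph::edge_attr(g, "pmids")),
                    stringsAsFactors = FALSE)
  res <- res[c_order(-res$weight, res$entity_a, res$entity_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Node attribute table for a network
#'
#' Builds per-entity node attributes (entity class and mention count) from
#' tagged entity mentions, for sizing/coloring in external viewers.
#'
#' @param entity_mentions data.frame from [tag_entities()]
#' @return data.frame with columns `name`, `entity_class`, `mention_count`
#' @export
node_attributes <- function(entity_mentions) {
  em <- entity_mentions[entity_mentions$entity_class %in% PAIRED_CLASSES, ,
                        drop = FALSE]
  if (nrow(em) == 0L)
    return(data.frame(name = character(), entity_class = character(),
                      mention_count = integer(), stringsAsFactors = FALSE))
  tb <- table(em$normalized)
  cls <- em$entity_class[match(names(tb), em$normalized)]
  res <- data.frame(name = names(tb), entity_class = cls,
                    mention_count = as.integer(tb), stringsAsFactors = FALSE)
  res[c_order(res$name), , drop = FALSE]
}
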