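#' Write a network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `r` (the edge correlation; `NA` column omitted
#' when absent). A commented header line records `tau` and `mode` so the file
#' reads back losslessly.
#'
#' @param net A `gene_net` igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "igraph"))
  el <- igraph::as_edgelist(net, names = TRUE)
  has_r <- "r" %in% igraph::edge_attr_names(net)
  df <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                   stringsAsFactors = FALSE)
  if (has_r) df$r <- igraph::E(net)$r
  con <- file(path, "w")
  on.exit(close(con))
  tau <- igraph::graph_attr(net, "tau")
  mode <- igraph::graph_attr(net, "mode")
  writeLines(sprintf("# tau=%s mode=%s nodes=%s",
                     if (is.null(tau)) "NA" else format(tau, digits = 15),
                     if (is.null(mode)) "NA" else mode,
                     paste(sort(igraph::V(net)$name), collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network from an edge-list TSV written by [write_edgelist()]
#'
#' @param path Input path.
#' @return A `gene_net` igraph (isolated nodes and tau/mode restored from the
#'   comment header when present).
#' @export
read_edgelist <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.delim(path, sep = "\t", comment.char = "#", header = TRUE,
                   check.names = FALSE)
  if (nrow(df)) {
    df$gene_a <- as.character(df$gene_a)
    df$gene_b <- as.character(df$gene_b)
  }
  nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  tau <- NULL; mode <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("tau=([^ ]+) mode=([^ ]+) nodes=(.*)$", first))[[1L]]
    if (length(m) == 4L) {
      if (m[2L] != "NA") tau <- as.numeric(m[2L])
      if (m[3L] != "NA") mode <- m[3L]
      nodes <- sort(unique(c(nodes, strsplit(m[4L], ",", fixed = TRUE)[[1L]])))
    }
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(df)) {
    g <- igraph::add_edges(g, rbind(df$gene_a, df$gene_b))
    if ("r" %in% names(df)) g <- igraph::set_edge_attr(g, "r", value = as.numeric(df$r))
  }
  if (!is.null(tau)) g <- igraph::set_graph_attr(g, "tau", tau)
  if (!is.null(mode)) g <- igraph::set_graph_attr(g, "mode", mode)
  g
}

#' Write / read a network as GraphML
#'
#' Thin wrappers around igraph's GraphML support; `tau` and `mode` travel as
#' graph attributes.
#'
#' @param net A `gene_net` igraph.
#' @param path File path.
#' @return `path` invisibly (writer); a `gene_net` igraph (reader).
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "igraph"))
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read a network file by extension
#'
#' `.graphml` is read as GraphML; `.tsv`, `.txt` and `.edges` as edge-list
#' TSV; anything else is an error.
#'
#' @param path Network file path.
#' @return A `gene_net` igraph.
#' @export
read_network <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = read_graphml(path),
         tsv = ,
         txt = ,
         edges = read_edgelist(path),
         stop("unrecognized network format '.", ext,
              "' (expected .graphml, .tsv, .txt or .edges)", call. = FALSE))
}

#' Write a correlation matrix as TSV
#'
#' Intended for small matrices; refuses more than `max_genes` genes because
#' the file grows quadratically.
#'
#' @param corr A correlation matrix (e.g. from [pearson_matrix()]).
#' @param path Output path.
#' @param max_genes Size guard (default 2000).
#' @return `path`, invisibly.
#' @export
write_corr <- function(corr, path, max_genes = 2000L) {
  corr <- unclass(corr)
  if (nrow(corr) > max_genes) {
    stop("correlation matrix has ", nrow(corr), " genes; refusing to write ",
         "more than ", max_genes, " (raise max_genes to override)", call. = FALSE)
  }
  df <- data.frame(gene_id = rownames(corr), corr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-node metrics table as TSV
#'
#' @param metrics Tibble from [all_concentric()] or [metrics_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  write.table(as.data.frame(metrics), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
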