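#' Pearson correlation matrix of gene expression profiles
#'
#' Computes the gene-by-gene Pearson correlation across samples (optionally a
#' subset, e.g. one phenotypic group). Requires at least 3 samples and
#' nonzero variance for every gene over the selected samples.
#'
#' @param x An [expr_mat()] with no missing values.
#' @param sample_subset Optional character vector of sample ids; `NULL` uses
#'   all samples.
#' @param group Optional group label; shorthand for selecting that group's
#'   samples (ignored when `sample_subset` is given).
#' @return A `corr_mat`: symmetric numeric matrix in \[-1, 1\] with unit
#'   diagonal and gene ids as dimnames.
#' @export
pearson_matrix <- function(x, sample_subset = NULL, group = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  if (anyNA(x$values)) stop("missing values present; run clean_expression() first",
                            call. = FALSE)
  v <- x$values
  if (is.null(sample_subset) && !is.null(group)) {
    if (is.null(x$groups)) stop("no group mapping on the matrix", call. = FALSE)
    if (!group %in% x$groups) stop("unknown group label: ", group, call. = FALSE)
    sample_subset <- colnames(v)[x$groups == group]
  }
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, colnames(v))
    if (length(unknown)) stop("unknown sample id: ", unknown[1L], call. = FALSE)
    v <- v[, sample_subset, drop = FALSE]
  }
  if (ncol(v) < 3L) stop("need at least 3 samples to correlate", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene over selected samples: ",
         rownames(v)[sds == 0][1L], call. = FALSE)
  }
  r <- cor(t(v))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  class(r) <- c("corr_mat", class(r))
  r
}

as_corr_mat <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("correlation matrix must be square",
                                                call. = FALSE)
  if (is.null(rownames(r))) stop("correlation matrix needs gene id dimnames",
                                 call. = FALSE)
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix not symmetric",
                                       call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("correlation entries outside [-1, 1]",
                                    call. = FALSE)
  if (any(abs(diag(r) - 1) > 1e-12)) stop("correlation diagonal must be 1",
                                          call. = FALSE)
  r
}

#' Build a threshold network from a correlation matrix
#'
#' Places an edge between genes i and j when `|r_ij| >= tau` (absolute mode,
#' the default — co-variation may be positive or negative) or `r_ij >= tau`
#' (positive mode). The threshold and mode are recorded as graph attributes;
#' edges carry the correlation as the `r` attribute. Vertices are ordered
#' lexicographically by gene id so outputs are byte-stable.
#'
#' @param corr Correlation matrix (from [pearson_matrix()] or any symmetric
#'   unit-diagonal matrix with gene-id dimnames).
#' @param tau Threshold in (0, 1]. The conventional cut-off for full
#'   transcriptome networks is 0.999.
#' @param mode `"absolute"` or `"positive"`.
#' @return An igraph `gene_net`: undirected, simple, with graph attributes
#'   `tau` and `mode`. Degree-0 vertices are retained (see
#'   [prune_isolated()]).
#' @export
threshold_network <- function(corr, tau, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  corr <- as_corr_mat(unclass(corr))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("`tau` must lie in (0, 1]", call. = FALSE)
  }
  ids <- sort(rownames(corr))
  corr <- corr[ids, ids]
  strength <- if (mode == "absolute") abs(corr) else corr
  hit <- which(upper.tri(strength) & strength >= tau, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(hit)) {
    ord <- order(hit[, 1L], hit[, 2L])
    hit <- hit[ord, , drop = FALSE]
    g <- igraph::add_edges(g, rbind(ids[hit[, 1L]], ids[hit[, 2L]]))
    g <- igraph::set_edge_attr(g, "r", value = corr[hit])
  }
  g <- igraph::set_graph_attr(g, "tau", tau)
  igraph::set_graph_attr(g, "mode", mode)
}

#' Stability-based automatic threshold selection
#'
#' Scans thresholds over a descending grid (the multiples of `step` inside
#' \[`grid_lo`, `grid_hi`\]) and returns the largest tau for which (a) at
#' least `connect_frac` of the non-isolated nodes belong to the largest
#' connected component, and (b) the relative changes in edge count and in
#' largest-component size between tau and tau - step are both at most
#' `stability_eps` — i.e. the network is insensitive to slight changes in the
#' threshold.
#'
#' @param corr Correlation matrix.
#' @param grid_hi,grid_lo,step Grid bounds and spacing (defaults 0.9999,
#'   0.90, 0.0005).
#' @param connect_frac Required fraction of non-isolated nodes in the giant
#'   component, in (0, 1] (default 1).
#' @param stability_eps Maximum tolerated relative change (default 0.05).
#' @param mode Edge mode, as in [threshold_network()].
#' @return A list with `tau` (the selected threshold) and `report`, a tibble
#'   with one row per grid point: `tau`, `n_edges`, `giant_size`,
#'   `frac_giant`, `rel_d_edges`, `rel_d_giant`, `connected_ok`, `stable_ok`.
#' @export
auto_threshold <- function(corr, grid_hi = 0.9999, grid_lo = 0.90,
                           step = 0.0005, connect_frac = 1.0,
                           stability_eps = 0.05,
                           mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  corr <- as_corr_mat(unclass(corr))
  stopifnot(grid_hi > grid_lo, step > 0, stability_eps > 0)
  if (connect_frac <= 0 || connect_frac > 1) {
    stop("`connect_frac` must lie in (0, 1]", call. = FALSE)
  }
  taus <- round(seq(floor(grid_hi / step) * step, grid_lo, by = -step), 10L)
  taus <- taus[taus >= grid_lo & taus <= grid_hi]
  if (!length(taus)) stop("empty threshold grid", call. = FALSE)

  stats_at <- function(tau) {
    g <- threshold_network(corr, tau, mode)
    deg <- igraph::degree(g)
    noniso <- sum(deg > 0)
    comp <- igraph::components(g)
    giant <- if (noniso == 0L) 0L else max(comp$csize[tapply(deg, comp$membership, max) > 0])
    list(n_edges = as.integer(igraph::ecount(g)), giant = as.integer(giant),
         frac = if (noniso == 0L) 0 else giant / noniso)
  }
  rel <- function(a, b) abs(a - b) / max(a, b, 1L)

  cur <- lapply(taus, stats_at)
  nxt <- lapply(round(taus - step, 10L), stats_at)  # tau - step, even below grid_lo
  report <- tibble(
    tau = taus,
    n_edges = vapply(cur, `[[`, integer(1L), "n_edges"),
    giant_size = vapply(cur, function(s) as.integer(s$giant), integer(1L)),
    frac_giant = vapply(cur, `[[`, numeric(1L), "frac"),
    rel_d_edges = mapply(function(a, b) rel(a$n_edges, b$n_edges), cur, nxt),
    rel_d_giant = mapply(function(a, b) rel(a$giant, b$giant), cur, nxt)
  )
  report$connected_ok <- report$frac_giant >= connect_frac
  report$stable_ok <- report$rel_d_edges <= stability_eps &
    report$rel_d_giant <= stability_eps
  ok <- report$connected_ok & report$stable_ok
  if (!any(ok)) {
    stop("no grid point satisfies both the connectivity and stability ",
         "criteria; widen the grid (grid_lo/grid_hi/step) or supply a fixed tau",
         call. = FALSE)
  }
  list(tau = report$tau[which(ok)[1L]], report = report)
}

#' Drop degree-0 nodes
#'
#' @param net A `gene_net` igraph.
#' @return The network without isolated vertices; the edge set is unchanged.
#' @export
prune_isolated <- function(net) {
  stopifnot(inherits(net, "igraph"))
  igraph::delete_vertices(net, which(igraph::degree(net) == 0L))
}

#' Extract the giant (major) connected component
#'
#' Ties between equally large components are broken in favour of the one
#' containing the lexicographically smallest gene id.
#'
#' @param net A `gene_net` igraph.
#' @return The induced subgraph of the largest connected component.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L) stop("empty network has no components", call. = FALSE)
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    first_member <- vapply(big, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1L))
    big <- big[order(first_member)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}
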