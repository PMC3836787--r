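#' Concentric ring decomposition of a node's surroundings
#'
#' The ring `R_l` of a reference node is the set of nodes at shortest-path
#' distance `l` from it (`R_0` is the node itself). The concentric node
#' degree `h_l` counts the edges joining ring `R_l` to ring `R_{l+1}`; edges
#' internal to a ring are not counted, and `h_0` equals the conventional node
#' degree. A low-degree node attached only to highly connected neighbours
#' therefore shows a small `h_0` but a large `h_1` — the signature used to
#' single out VIP nodes.
#'
#' @param net A `gene_net` igraph.
#' @param node Gene id of the reference node.
#' @param max_level Optional maximum ring level; `NULL` explores the whole
#'   connected component of `node`.
#' @return A `conc_profile`: list with `node`, `rings` (list of sorted gene-id
#'   vectors, `R_1` first) and `h` (integer vector of concentric degrees
#'   `h_0 ... h_{L-1}`, where `L` is the number of non-empty rings; `h_0` is
#'   the node degree). Nodes outside the component are in no ring.
#' @export
rings <- function(net, node, max_level = NULL) {
  stopifnot(inherits(net, "igraph"))
  if (!node %in% igraph::V(net)$name) stop("unknown node: ", node, call. = FALSE)
  d <- igraph::distances(net, v = node, weights = NA)[1L, ]
  lv <- d[is.finite(d) & d > 0]
  lmax <- if (length(lv)) max(lv) else 0
  if (!is.null(max_level)) lmax <- min(lmax, max_level)
  ring_list <- lapply(seq_len(lmax), function(l) sort(names(d)[d == l]))
  names(ring_list) <- if (lmax) paste0("R", seq_len(lmax))
  h <- vapply(seq_len(max(lmax, 1L)) - 1L, function(l) ring_edge_count(net, d, l),
              integer(1L))
  structure(list(node = node, rings = ring_list, h = h), class = "conc_profile")
}

# edges with one endpoint at distance l and the other at distance l+1
ring_edge_count <- function(net, d, level) {
  if (igraph::ecount(net) == 0L) return(0L)
  ep <- igraph::ends(net, igraph::E(net), names = TRUE)
  du <- d[ep[, 1L]]; dv <- d[ep[, 2L]]
  sum((du == level & dv == level + 1) | (dv == level & du == level + 1))
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> node %s: %d ring(s)\n", x$node, length(x$rings)))
  sizes <- vapply(x$rings, length, integer(1L))
  if (length(sizes)) cat("|R_l|:", paste(sizes, collapse = " "), "\n")
  cat("h_l:  ", paste(x$h, collapse = " "), "\n")
  invisible(x)
}

#' Concentric node degree at a given level
#'
#' Counts the edges between ring `R_level` and ring `R_{level+1}` of `node`.
#' Level 0 returns the conventional degree.
#'
#' @inheritParams rings
#' @param level Non-negative integer ring level.
#' @return Integer edge count.
#' @export
concentric_degree <- function(net, node, level) {
  stopifnot(inherits(net, "igraph"))
  if (!node %in% igraph::V(net)$name) stop("unknown node: ", node, call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level %% 1 != 0) {
    stop("`level` must be a non-negative integer", call. = FALSE)
  }
  d <- igraph::distances(net, v = node, weights = NA)[1L, ]
  ring_edge_count(net, d, level)
}

#' Degree and concentric degree for every node
#'
#' @param net A `gene_net` igraph.
#' @param level Ring level for the concentric degree (default 1, the
#'   first-neighbourhood concentric degree used for VIP detection).
#' @return Tibble with one row per node, sorted by gene id: `gene_id`,
#'   `degree`, `cdegree_l<level>`.
#' @export
all_concentric <- function(net, level = 1L) {
  stopifnot(inherits(net, "igraph"))
  ids <- sort(igraph::V(net)$name)
  n <- length(ids)
  deg <- igraph::degree(net)[ids]
  h <- integer(n)
  if (n && igraph::ecount(net)) {
    D <- igraph::distances(net, v = ids, weights = NA)
    ep <- igraph::ends(net, igraph::E(net), names = TRUE)
    for (i in seq_len(n)) {
      du <- D[i, ep[, 1L]]; dv <- D[i, ep[, 2L]]
      h[i] <- sum((du == level & dv == level + 1) | (dv == level & du == level + 1))
    }
  }
  out <- tibble(gene_id = ids, degree = as.integer(unname(deg)), h = h)
  names(out)[3L] <- paste0("cdegree_l", as.integer(level))
  out
}
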