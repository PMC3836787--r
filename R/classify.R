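#' Normalized betweenness centrality
#'
#' Exact shortest-path betweenness (endpoints excluded, Brandes algorithm),
#' normalized within each connected component by `(n-1)(n-2)/2` where `n` is
#' the component size, so the centre of a star scores 1 and values lie in
#' \[0, 1\]. Nodes in components of fewer than 3 nodes score 0.
#'
#' @param net A `gene_net` igraph.
#' @return Tibble `gene_id`, `betweenness`, sorted by gene id.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "igraph"))
  ids <- sort(igraph::V(net)$name)
  if (!length(ids)) return(tibble(gene_id = character(), betweenness = numeric()))
  raw <- igraph::betweenness(net, directed = FALSE, weights = NA)
  comp <- igraph::components(net)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  b <- ifelse(denom > 0, raw / denom, 0)
  names(b) <- igraph::V(net)$name
  tibble(gene_id = ids, betweenness = unname(b[ids]))
}

select_by_rule <- function(values, rule) {
  if (!is.list(rule) || length(rule) != 1L || !names(rule) %in% c("top_n", "quantile")) {
    stop("selection rule must be list(top_n = ...) or list(quantile = ...)",
         call. = FALSE)
  }
  if (names(rule) == "top_n") {
    n <- rule$top_n
    if (!is.numeric(n) || n < 1) stop("top_n must be >= 1", call. = FALSE)
    n <- min(as.integer(n), length(values))
    cut <- sort(values, decreasing = TRUE)[n]
  } else {
    q <- rule$quantile
    if (!is.numeric(q) || q <= 0 || q >= 1) {
      stop("quantile must lie in (0, 1)", call. = FALSE)
    }
    cut <- quantile(values, q, names = FALSE, type = 7L)
  }
  values >= cut  # boundary ties are inclusive
}

#' Assign hub / VIP / high-hub categories
#'
#' Nodes are ranked by conventional degree `k` and by first-level concentric
#' degree `h_1`. The hub rule selects the top of the `k` ranking (set H), the
#' VIP rule the top of the `h_1` ranking (set V); then
#' `high_hub = H ∩ V`, `hub = H \ V`, `vip = V \ H`, all others `none`.
#' Ties at a selection boundary are included, so the output is
#' order-independent.
#'
#' @param metrics Data frame with columns `gene_id`, `degree` and a
#'   `cdegree_l1` column (as produced by [all_concentric()]).
#' @param hub_rule,vip_rule Either `list(top_n = n)` or
#'   `list(quantile = q)` with `q` in (0, 1); defaults `list(quantile = 0.99)`.
#' @return Tibble `gene_id`, `category` (factor with levels `high_hub`,
#'   `hub`, `vip`, `none`).
#' @export
classify_nodes <- function(metrics, hub_rule = list(quantile = 0.99),
                           vip_rule = list(quantile = 0.99)) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0L)
  hcol <- grep("^cdegree_l", names(metrics), value = TRUE)[1L]
  if (is.na(hcol)) stop("metrics table lacks a cdegree_l* column", call. = FALSE)
  H <- select_by_rule(metrics$degree, hub_rule)
  V <- select_by_rule(metrics[[hcol]], vip_rule)
  cat_ <- ifelse(H & V, "high_hub", ifelse(H, "hub", ifelse(V, "vip", "none")))
  tibble(gene_id = metrics$gene_id,
         category = factor(cat_, levels = c("high_hub", "hub", "vip", "none")))
}

#' Full per-node metrics table
#'
#' Combines degree, first-level concentric degree, normalized betweenness and
#' the hub/VIP/high-hub category into one record per node — the
#' machine-readable analogue of the paper-style node tables. Rows are sorted
#' by category (high_hub, hub, vip, none), then decreasing degree, then
#' gene id.
#'
#' @param net A `gene_net` igraph.
#' @inheritParams classify_nodes
#' @return Tibble `gene_id`, `degree`, `cdegree_l1`, `betweenness`,
#'   `category`, of class `node_metrics`.
#' @export
metrics_table <- function(net, hub_rule = list(quantile = 0.99),
                          vip_rule = list(quantile = 0.99)) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L) {
    out <- tibble(gene_id = character(), degree = integer(),
                  cdegree_l1 = integer(), betweenness = numeric(),
                  category = factor(character(),
                                    levels = c("high_hub", "hub", "vip", "none")))
    class(out) <- c("node_metrics", class(out))
    return(out)
  }
  m <- all_concentric(net, level = 1L)
  m <- left_join(m, node_betweenness(net), by = "gene_id")
  m <- left_join(m, classify_nodes(m, hub_rule, vip_rule), by = "gene_id")
  m <- arrange(m, .data$category, desc(.data$degree), .data$gene_id)
  class(m) <- c("node_metrics", class(m))
  m
}
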