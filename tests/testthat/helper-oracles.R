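# Independent brute-force oracles (Floyd-Warshall distances, DP shortest-path
# counts) used to cross-check the package's graph measurements, plus small
# fixture builders. Everything here is deliberately naive and separate from
# the implementation paths under test.

oracle_adjacency <- function(g) {
  ids <- sort(igraph::V(g)$name)
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    A[cbind(el[, 1L], el[, 2L])] <- 1L
    A[cbind(el[, 2L], el[, 1L])] <- 1L
  }
  A
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# concentric degree h_level of `node` by exhaustive edge scan over BFS labels
oracle_concentric <- function(g, node, level) {
  A <- oracle_adjacency(g)
  d <- oracle_distances(A)[node, ]
  e <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  if (!nrow(e)) return(0L)
  du <- d[e[, 1L]]; dv <- d[e[, 2L]]
  sum((du == level & dv == level + 1) | (dv == level & du == level + 1))
}

# exact betweenness via all-pairs shortest-path counting (endpoints excluded),
# normalized per connected component by (n-1)(n-2)/2
oracle_betweenness <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] == 1L & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], "+") == D
    w <- outer(sigma[, v], sigma[v, ]) / sigma
    w[!on_path | !is.finite(w)] <- 0
    w[v, ] <- 0; w[, v] <- 0; diag(w) <- 0
    b[v] <- sum(w[upper.tri(w)])
  }
  csize <- rowSums(is.finite(D))
  den <- (csize - 1) * (csize - 2) / 2
  setNames(ifelse(den > 0, b / den, 0), rownames(A))
}

er_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::set_vertex_attr(g, "name", value = sprintf("N%03d", seq_len(n)))
}

# edges: character vector (or matrix, flattened column-wise) of vertex pairs
named_graph <- function(edges, directed = FALSE) {
  igraph::make_graph(as.vector(edges), directed = directed)
}

star_graph <- function(n_leaves) {
  named_graph(rbind("C", sprintf("L%02d", seq_len(n_leaves))), directed = FALSE)
}

# correlation matrix with a high-correlation chain over low background
chain_corr <- function(n = 6, hi = 0.9, bg = 0.3) {
  ids <- sprintf("g%02d", seq_len(n))
  m <- matrix(bg, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) m[i, i + 1L] <- m[i + 1L, i] <- hi
  diag(m) <- 1
  m
}

# two high-correlation blocks that never join into one component
block_corr <- function(sizes = c(4, 3), hi = 0.9, bg = 0.1) {
  n <- sum(sizes)
  ids <- sprintf("g%02d", seq_len(n))
  m <- matrix(bg, n, n, dimnames = list(ids, ids))
  start <- 1L
  for (s in sizes) {
    idx <- seq(start, start + s - 1L)
    m[idx, idx] <- hi
    start <- start + s
  }
  diag(m) <- 1
  m
}

toy_expr <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   5, 1, 4, 2), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  expr_mat(vals)
}
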