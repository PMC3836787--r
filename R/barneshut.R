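# Barnes-Hut tree approximation of the Coulomb repulsion term. A cell whose
# side-to-distance ratio is below theta is treated as a point mass at its
# centre of mass; theta -> 0 recovers the exact pairwise sum.

bh_build <- function(P, idx, lo, hi, depth = 0L) {
  if (length(idx) == 1L || depth > 60L) {
    return(list(leaf = TRUE, idx = idx, com = colMeans(P[idx, , drop = FALSE]),
                count = length(idx), size = max(hi - lo)))
  }
  mid <- (lo + hi) / 2
  nd <- ncol(P)
  code <- integer(length(idx))
  for (d in seq_len(nd)) {
    code <- code + as.integer(P[idx, d] > mid[d]) * 2L^(d - 1L)
  }
  children <- list()
  for (cc in sort(unique(code))) {
    sub <- idx[code == cc]
    clo <- lo; chi <- hi
    for (d in seq_len(nd)) {
      if (bitwAnd(cc, 2L^(d - 1L)) > 0L) clo[d] <- mid[d] else chi[d] <- mid[d]
    }
    children[[length(children) + 1L]] <- bh_build(P, sub, clo, chi, depth + 1L)
  }
  counts <- vapply(children, `[[`, numeric(1L), "count")
  coms <- t(vapply(children, `[[`, numeric(nd), "com"))
  list(leaf = FALSE, idx = idx, children = children,
       com = colSums(coms * counts) / sum(counts),
       count = sum(counts), size = max(hi - lo))
}

bh_force_point <- function(node, p, i, k_c, theta) {
  if (node$leaf) {
    others <- setdiff(node$idx, i)
    if (!length(others)) return(numeric(length(p)))
    dv <- p - node$com  # leaf points coincide with its com (single point or capped cell)
    d <- sqrt(sum(dv * dv))
    if (d == 0) return(numeric(length(p)))
    return(k_c * length(others) * dv / d^3)
  }
  dv <- p - node$com
  d <- sqrt(sum(dv * dv))
  if (d > 0 && node$size / d < theta && !any(node$idx == i)) {
    return(k_c * node$count * dv / d^3)
  }
  Reduce(`+`, lapply(node$children, bh_force_point, p = p, i = i,
                     k_c = k_c, theta = theta))
}

bh_repulsion <- function(P, k_c, theta) {
  n <- nrow(P)
  lo <- apply(P, 2L, min); hi <- apply(P, 2L, max)
  span <- max(hi - lo, 1e-12)
  hi <- lo + span  # cubic bounding box
  tree <- bh_build(P, seq_len(n), lo, hi)
  F <- t(vapply(seq_len(n), function(i) {
    bh_force_point(tree, P[i, ], i, k_c, theta)
  }, numeric(ncol(P))))
  dimnames(F) <- dimnames(P)
  F
}
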