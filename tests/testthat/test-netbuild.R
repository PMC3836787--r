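test_that("pearson_matrix reproduces hand-computed correlations", {
  mk <- function(a, b) {
    expr_mat(matrix(c(a, b), nrow = 2, byrow = TRUE,
                    dimnames = list(c("x", "y"), sprintf("s%d", seq_along(a)))))
  }
  expect_equal(pearson_matrix(mk(c(1, 2, 3), c(2, 4, 6)))["x", "y"], 1.0)
  expect_equal(pearson_matrix(mk(c(1, 2, 3), c(3, 2, 1)))["x", "y"], -1.0)
  # product-moment formula by hand: cov = 4, ss_x = ss_y = 5 -> r = 4/5
  expect_equal(pearson_matrix(mk(c(1, 2, 3, 4), c(1, 3, 2, 4)))["x", "y"], 0.8)
})

test_that("pearson_matrix validates inputs and supports sample subsets", {
  vals <- matrix(rnorm(30), nrow = 5,
                 dimnames = list(sprintf("G%d", 1:5), sprintf("s%d", 1:6)))
  vals[2L, ] <- 7  # constant gene
  x <- expr_mat(vals)
  expect_error(pearson_matrix(x), "zero-variance gene.*G2")
  x2 <- expr_mat(vals[-2L, , drop = FALSE])
  expect_error(pearson_matrix(x2, sample_subset = c("s1", "s2")), "3 samples")
  r_sub <- pearson_matrix(x2, sample_subset = c("s1", "s2", "s3"))
  expect_equal(unclass(r_sub),
               cor(t(vals[-2L, 1:3])), ignore_attr = FALSE)

  grp <- setNames(rep(c("a", "b"), each = 3), colnames(vals))
  xg <- expr_mat(vals[-2L, , drop = FALSE], groups = grp)
  expect_equal(unclass(pearson_matrix(xg, group = "b")),
               cor(t(vals[-2L, 4:6])))
})

test_that("correlation matrix invariants hold and rescaling leaves r fixed", {
  set.seed(11)
  vals <- matrix(rnorm(80), nrow = 10,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("s%d", 1:8)))
  x <- expr_mat(vals)
  r <- pearson_matrix(x)
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_equal(unname(diag(r)), rep(1, 10))
  expect_true(all(abs(r) <= 1))

  # per-gene affine rescaling with positive slope
  resc <- vals * runif(10, 0.5, 4) + rnorm(10)
  r2 <- pearson_matrix(expr_mat(resc))
  expect_equal(unclass(r2), unclass(r), tolerance = 1e-12)
})

test_that("threshold_network places edges by |r| >= tau with mode control", {
  ids <- c("A", "B", "C")
  m <- diag(3); dimnames(m) <- list(ids, ids)
  m["A", "B"] <- m["B", "A"] <- 0.9995
  m["A", "C"] <- m["C", "A"] <- 0.5
  m["B", "C"] <- m["C", "B"] <- 0.2
  g <- threshold_network(m, 0.999, "absolute")
  expect_identical(apply(igraph::as_edgelist(g), 1, paste, collapse = "-"), "A-B")
  expect_equal(igraph::graph_attr(g, "tau"), 0.999)
  expect_equal(igraph::E(g)$r, 0.9995)

  m["A", "B"] <- m["B", "A"] <- -0.9999
  g_abs <- threshold_network(m, 0.999, "absolute")
  g_pos <- threshold_network(m, 0.999, "positive")
  expect_equal(igraph::ecount(g_abs), 1)
  expect_equal(igraph::ecount(g_pos), 0)

  expect_equal(igraph::ecount(threshold_network(m, 1.0)), 0)
  expect_error(threshold_network(m, 0), "\\(0, 1\\]")
  expect_error(threshold_network(m, 1.2), "\\(0, 1\\]")
})

test_that("edge sets shrink monotonically as tau grows", {
  set.seed(3)
  vals <- matrix(rnorm(90), nrow = 15,
                 dimnames = list(sprintf("G%02d", 1:15), sprintf("s%d", 1:6)))
  r <- pearson_matrix(expr_mat(vals))
  taus <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  key <- function(g) apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
  sets <- lapply(taus, function(t) key(threshold_network(r, t)))
  for (i in seq_along(taus)[-1L]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
  }
})

test_that("auto_threshold finds the largest stable connecting threshold", {
  sel <- auto_threshold(chain_corr(6, hi = 0.9, bg = 0.3),
                        grid_hi = 0.99, grid_lo = 0.50, step = 0.05,
                        connect_frac = 1.0)
  expect_equal(sel$tau, 0.90)
  row <- sel$report[sel$report$tau == sel$tau, ]
  expect_true(row$connected_ok && row$stable_ok)
  expect_equal(row$n_edges, 5L)
  expect_equal(row$giant_size, 6L)
})

test_that("auto_threshold errors on unsatisfiable criteria, honours connect_frac", {
  bm <- block_corr(sizes = c(4, 3), hi = 0.9, bg = 0.1)
  expect_error(auto_threshold(bm, grid_hi = 0.99, grid_lo = 0.50, step = 0.05,
                              connect_frac = 1.0), "widen the grid")
  sel <- auto_threshold(bm, grid_hi = 0.99, grid_lo = 0.50, step = 0.05,
                        connect_frac = 0.5)
  expect_equal(sel$tau, 0.90)  # big block (4 of 7 non-isolated nodes) appears
  row <- sel$report[sel$report$tau == sel$tau, ]
  expect_gte(row$frac_giant, 0.5)
  expect_equal(row$giant_size, 4L)
})

test_that("prune_isolated and giant_component behave on edge cases", {
  g <- named_graph(rbind(c("a", "b", "c", "x"), c("b", "c", "a", "y")),
                   directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "zzz")  # isolated
  expect_equal(igraph::vcount(g), 6)
  p <- prune_isolated(g)
  expect_equal(sort(igraph::V(p)$name), c("a", "b", "c", "x", "y"))
  expect_equal(igraph::ecount(p), igraph::ecount(g))

  gc <- giant_component(g)
  expect_setequal(igraph::V(gc)$name, c("a", "b", "c"))

  # tie on component size: lexicographically smallest member wins
  tie <- named_graph(rbind(c("B1", "A0001"), c("B2", "A9999")), directed = FALSE)
  expect_true("A0001" %in% igraph::V(giant_component(tie))$name)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_error(giant_component(empty), "empty")

  edgeless <- igraph::set_vertex_attr(igraph::make_empty_graph(3, directed = FALSE),
                                      "name", value = c("a", "b", "c"))
  expect_equal(igraph::vcount(prune_isolated(edgeless)), 0)
})
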