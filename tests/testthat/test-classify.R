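test_that("betweenness matches closed forms", {
  st <- star_graph(8)
  b <- node_betweenness(st)
  expect_equal(b$betweenness[b$gene_id == "C"], 1.0)
  expect_equal(b$betweenness[b$gene_id != "C"], rep(0, 8))

  p4 <- named_graph(c("a","b", "b","c", "c","d"))
  b4 <- node_betweenness(p4)
  expect_equal(setNames(b4$betweenness, b4$gene_id),
               c(a = 0, b = 2 / 3, c = 2 / 3, d = 0))

  k5 <- igraph::set_vertex_attr(igraph::make_full_graph(5), "name",
                                value = letters[1:5])
  expect_equal(node_betweenness(k5)$betweenness, rep(0, 5))
})

test_that("betweenness agrees with the path-enumeration oracle", {
  for (seed in 1:10) {
    g <- er_graph(30, 0.1, seed + 100)
    b <- node_betweenness(g)
    o <- oracle_betweenness(g)
    expect_equal(setNames(b$betweenness, b$gene_id), o, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("classify_nodes recovers planted roles and honours tie rules", {
  sim <- gen_motif_graph(seed = 7)  # 10 hubs/30 leaves, 5 VIPs/3 hubs, 2 high-hubs
  m <- all_concentric(sim$net, 1)
  cls <- classify_nodes(m, hub_rule = list(top_n = 12), vip_rule = list(top_n = 7))
  got <- merge(cls, sim$roles, by = "gene_id")
  expect_identical(as.character(got$category[got$role == "hub"]), rep("hub", 10))
  expect_identical(as.character(got$category[got$role == "vip"]), rep("vip", 5))
  expect_identical(as.character(got$category[got$role == "high_hub"]),
                   rep("high_hub", 2))
  expect_true(all(got$category[got$role == "leaf"] == "none"))

  # vertex-transitive ring with quantile rules: everyone ties into both sets
  ring <- igraph::set_vertex_attr(igraph::make_ring(8), "name",
                                  value = sprintf("r%d", 1:8))
  cr <- classify_nodes(all_concentric(ring, 1),
                       hub_rule = list(quantile = 0.9),
                       vip_rule = list(quantile = 0.9))
  expect_true(all(cr$category == "high_hub"))

  # star: center is the unique top-1 hub; leaves tie for vip on h1
  st <- star_graph(5)
  cs <- classify_nodes(all_concentric(st, 1),
                       hub_rule = list(top_n = 1), vip_rule = list(top_n = 1))
  expect_identical(as.character(cs$category[cs$gene_id == "C"]), "hub")
  expect_true(all(cs$category[cs$gene_id != "C"] == "vip"))

  expect_error(classify_nodes(m, hub_rule = list(quantile = 1.2)), "quantile")
  expect_error(classify_nodes(m, hub_rule = list(top_n = 0)), "top_n")
})

test_that("categories partition the node set and grow monotonically with top_n", {
  for (seed in c(5, 6)) {
    g <- er_graph(50, 0.08, seed)
    m <- all_concentric(g, 1)
    cls <- classify_nodes(m, list(top_n = 8), list(top_n = 8))
    expect_equal(sum(table(cls$category)), igraph::vcount(g))

    hub_sets <- lapply(c(3, 6, 12), function(k) {
      cc <- classify_nodes(m, list(top_n = k), list(top_n = 5))
      cc$gene_id[cc$category %in% c("hub", "high_hub")]
    })
    expect_true(all(hub_sets[[1]] %in% hub_sets[[2]]))
    expect_true(all(hub_sets[[2]] %in% hub_sets[[3]]))
  }
})

test_that("metrics_table combines metrics, category and ordering", {
  motif <- gen_motif_graph(n_hubs = 2, leaves_per_hub = 5, n_vips = 1,
                           hubs_per_vip = 2, n_high_hubs = 0, seed = 1)$net
  mt <- metrics_table(motif, hub_rule = list(top_n = 2),
                      vip_rule = list(top_n = 1))
  expect_named(mt, c("gene_id", "degree", "cdegree_l1", "betweenness", "category"))
  expect_identical(as.character(mt$category[mt$gene_id == "VIP01"]), "vip")
  expect_identical(as.character(mt$category[mt$gene_id == "HUB01"]), "hub")
  expect_identical(as.character(mt$category[mt$gene_id == "HUB02"]), "hub")
  # sorted by category rank then descending degree
  expect_true(all(diff(as.integer(mt$category)) >= 0))
  expect_true(all(diff(mt$degree[mt$category == "none"]) <= 0))
  expect_true(all(mt$betweenness >= 0 & mt$betweenness <= 1))

  edgeless <- igraph::set_vertex_attr(igraph::make_empty_graph(4, directed = FALSE),
                                      "name", value = letters[1:4])
  me <- metrics_table(edgeless)
  expect_equal(me$degree, rep(0L, 4))
  expect_equal(me$betweenness, rep(0, 4))
  expect_equal(nrow(me), 4L)

  for (seed in 1:3) {
    g <- er_graph(25, 0.1, seed + 40)
    expect_equal(nrow(metrics_table(g)), igraph::vcount(g))
  }
})
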