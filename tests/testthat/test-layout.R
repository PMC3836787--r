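dumbbell <- function() named_graph(c("A","B"))

test_that("init_layout is seeded, shaped, and deterministic", {
  g <- er_graph(12, 0.2, 1)
  p <- layout_params(seed = 42, dim = 3)
  s1 <- init_layout(g, p); s2 <- init_layout(g, p)
  expect_identical(s1$positions, s2$positions)
  expect_equal(dim(s1$positions), c(12L, 3L))
  expect_true(all(s1$velocities == 0))
  expect_equal(s1$iteration, 0L)
  s3 <- init_layout(g, layout_params(seed = 43, dim = 3))
  expect_false(identical(s1$positions, s3$positions))
  expect_error(init_layout(igraph::make_empty_graph(0, directed = FALSE),
                           layout_params()), "empty")
})

test_that("forces follow the Coulomb/Hooke/viscous law", {
  # two disconnected nodes at distance d: pure repulsion k_c/d^2, equal and opposite
  g <- igraph::set_vertex_attr(igraph::make_empty_graph(2, directed = FALSE),
                               "name", value = c("A", "B"))
  p <- layout_params(k_c = 2, k_s = 1)
  st <- init_layout(g, p)
  st$positions[] <- rbind(c(0, 0), c(0.5, 0))
  f <- net_forces(g, st, p)
  expect_equal(f["A", ], c(x = -2 / 0.25, y = 0))
  expect_equal(f["B", ], c(x = 2 / 0.25, y = 0))
  expect_equal(colSums(f), c(x = 0, y = 0), tolerance = 1e-12)

  # connected pair at the analytic equilibrium d* = (k_c/k_s)^(1/3): zero force
  gc <- dumbbell()
  p2 <- layout_params(k_c = 8, k_s = 1)
  st2 <- init_layout(gc, p2)
  st2$positions[] <- rbind(c(0, 0), c(2, 0))  # (8/1)^(1/3) = 2
  expect_equal(max(abs(net_forces(gc, st2, p2))), 0, tolerance = 1e-12)

  # viscous term acts against velocity
  st2$velocities[] <- rbind(c(1, 0), c(0, -2))
  f2 <- net_forces(gc, st2, p2)
  expect_equal(f2["A", ], c(x = -p2$lam * 1, y = 0))
  expect_equal(f2["B", ], c(x = 0, y = p2$lam * 2))

  # equilateral triangle: symmetric force magnitudes
  k3 <- named_graph(c("a","b", "b","c", "a","c"))
  st3 <- init_layout(k3, layout_params())
  st3$positions[] <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  f3 <- net_forces(k3, st3, layout_params())
  mags <- sqrt(rowSums(f3^2))
  expect_equal(max(mags) - min(mags), 0, tolerance = 1e-12)
})

test_that("layout_step is an RK4 update with a fixed point at equilibrium", {
  gc <- dumbbell()
  p <- layout_params()
  st <- init_layout(gc, p)
  st$positions[] <- rbind(c(0, 0), c(1, 0))  # d* = 1
  s2 <- layout_step(gc, st, p)
  expect_equal(s2$positions, st$positions, tolerance = 1e-12)
  expect_equal(s2$iteration, 1L)

  # strong damping: speeds strictly decrease
  pd <- layout_params(lam = 20)
  sd0 <- init_layout(gc, pd)
  sd0$velocities[] <- rbind(c(0.5, 0.2), c(-0.3, 0.4))
  speeds <- numeric(10)
  s <- sd0
  for (i in 1:10) {
    s <- layout_step(gc, s, pd)
    speeds[i] <- max(sqrt(rowSums(s$velocities^2)))
  }
  expect_true(all(diff(c(max(sqrt(rowSums(sd0$velocities^2))), speeds)) < 0))

  # halving dt shrinks the single-step displacement (integrator consistency)
  g2 <- er_graph(8, 0.3, 4)
  move <- function(dt) {
    pp <- layout_params(dt = dt, seed = 9)
    s0 <- init_layout(g2, pp)
    s1 <- layout_step(g2, s0, pp)
    max(abs(s1$positions - s0$positions))
  }
  expect_lt(move(0.005), move(0.01))
})

test_that("run_layout reaches the analytic equilibria", {
  st <- run_layout(dumbbell(), layout_params(seed = 3))
  expect_true(st$converged)
  expect_lt(abs(as.numeric(dist(st$positions)) - 1), 0.01)

  k3 <- named_graph(c("a","b", "b","c", "a","c"))
  s3 <- run_layout(k3, layout_params(seed = 5))
  dd <- as.numeric(dist(s3$positions))
  expect_lt((max(dd) - min(dd)) / min(dd), 0.02)

  # pure repulsion: disconnected nodes drift apart
  g <- igraph::set_vertex_attr(igraph::make_empty_graph(2, directed = FALSE),
                               "name", value = c("A", "B"))
  p <- layout_params(seed = 8, max_iter = 400)
  d0 <- as.numeric(dist(init_layout(g, p)$positions))
  sfin <- run_layout(g, p)
  expect_gt(as.numeric(dist(sfin$positions)), d0)

  # identical seed and params give bit-identical coordinates
  expect_identical(run_layout(k3, layout_params(seed = 5))$positions,
                   s3$positions)
})

test_that("energies behave physically", {
  gc <- dumbbell()
  p <- layout_params()
  st <- init_layout(gc, p)
  st$positions[] <- rbind(c(0, 0), c(1, 0))
  e <- layout_energy(gc, st, p)
  expect_equal(e$kinetic, 0)
  # potential at the equilibrium is a local minimum along the separation
  pot_at <- function(d) {
    s <- st; s$positions[2, 1] <- d
    layout_energy(gc, s, p)$potential
  }
  expect_lt(pot_at(1), pot_at(1.01))
  expect_lt(pot_at(1), pot_at(0.99))

  # dissipation: total energy non-increasing after the transient
  g <- er_graph(10, 0.25, 6)
  pp <- layout_params(seed = 6)
  s <- init_layout(g, pp)
  E <- numeric(200)
  for (i in seq_along(E)) {
    s <- layout_step(g, s, pp)
    E[i] <- layout_energy(g, s, pp)$total
  }
  expect_true(all(diff(E[10:200]) <= 1e-9))
})

test_that("momentum is conserved without damping", {
  g <- er_graph(9, 0.3, 12)
  p <- layout_params(lam = 0, seed = 12)
  s <- init_layout(g, p)
  for (i in 1:30) {
    f <- net_forces(g, s, p)
    expect_lt(max(abs(colSums(f))), 1e-9)
    s <- layout_step(g, s, p)
  }
})

test_that("Barnes-Hut repulsion converges to the exact sum as theta -> 0", {
  g <- er_graph(80, 0.05, 21)
  p_exact <- layout_params(seed = 21, dim = 3)
  st <- init_layout(g, p_exact)
  f_exact <- net_forces(g, st, p_exact)
  for (theta in c(0.01, 0.3)) {
    p_bh <- layout_params(seed = 21, dim = 3, theta = theta)
    f_bh <- net_forces(g, st, p_bh)
    rel <- max(sqrt(rowSums((f_bh - f_exact)^2)) / sqrt(rowSums(f_exact^2)))
    if (theta == 0.01) expect_lt(rel, 1e-3) else expect_lt(rel, 0.2)
  }
})

test_that("two bridged cliques separate into distinct clusters", {
  k8a <- sprintf("a%02d", 1:8); k8b <- sprintf("b%02d", 1:8)
  edges <- rbind(t(combn(k8a, 2)), t(combn(k8b, 2)), c("a01", "b01"))
  g <- named_graph(t(edges), directed = FALSE)
  hits <- 0L
  for (seed in 1:3) {
    st <- run_layout(g, layout_params(seed = seed, max_iter = 8000))
    P <- st$positions
    intra <- c(dist(P[k8a, ]), dist(P[k8b, ]))
    inter <- as.matrix(dist(P))[k8a, k8b]
    if (mean(intra) < mean(inter)) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
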