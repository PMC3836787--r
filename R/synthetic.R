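#' Synthetic expression data with planted correlation modules
#'
#' Generates a two-group (or any-group) expression matrix from a latent
#' factor model: each gene in module m is
#' `sqrt(rho_bg) * g + sqrt(rho_in - rho_bg) * f_m + sqrt(1 - rho_in) * e`,
#' with `g` a global factor, `f_m` a module factor and `e` i.i.d. Gaussian
#' noise, all standard normal and drawn independently per sample. The target
#' correlation is therefore exactly `rho_in` within a module and `rho_bg`
#' between modules, and the construction is positive definite for any
#' `0 <= rho_bg < rho_in <= 1`. Background genes load on the global factor
#' only. The default group sizes (6 vs 12 samples) emulate a small two-
#' phenotype microarray cohort.
#'
#' @param n_samples Named integer vector of samples per group
#'   (default `c(FS = 6, NFS = 12)`).
#' @param modules Data frame with columns `size` and `rho` (within-module
#'   correlation), one row per planted module.
#' @param rho_bg Background correlation between all genes (default 0); must
#'   be strictly below every module `rho`.
#' @param n_background Number of background genes outside any module.
#' @param seed Integer seed (required; no global random state is used).
#' @return A list: `expr` (an [expr_mat()] with group labels),
#'   `truth` (tibble `gene_a`, `gene_b` of planted within-module pairs, the
#'   edges expected to survive thresholding), and `modules` (tibble
#'   `gene_id`, `module`).
#' @export
gen_expression <- function(n_samples = c(FS = 6L, NFS = 12L),
                           modules = data.frame(size = rep(8L, 5L), rho = 0.95),
                           rho_bg = 0, n_background = 40L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(is.data.frame(modules), all(c("size", "rho") %in% names(modules)),
            n_background >= 0L, all(n_samples >= 1L))
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("G", seq_along(n_samples))
  }
  if (any(rho_bg < 0) || any(modules$rho > 1) || any(rho_bg >= modules$rho)) {
    stop("need 0 <= rho_bg < rho <= 1 for every module", call. = FALSE)
  }
  n_mod_genes <- sum(modules$size)
  n_genes <- n_mod_genes + n_background
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  module_of <- c(rep(seq_len(nrow(modules)), modules$size),
                 rep(NA_integer_, n_background))
  sample_ids <- unlist(lapply(names(n_samples), function(g) {
    sprintf("%s_%02d", g, seq_len(n_samples[[g]]))
  }))
  groups <- setNames(rep(names(n_samples), n_samples), sample_ids)
  n_tot <- length(sample_ids)

  vals <- withr::with_seed(seed, {
    g_fac <- rnorm(n_tot)
    f_fac <- matrix(rnorm(n_tot * nrow(modules)), nrow = nrow(modules))
    eps <- matrix(rnorm(n_genes * n_tot), nrow = n_genes)
    v <- matrix(0, n_genes, n_tot)
    for (i in seq_len(n_genes)) {
      m <- module_of[i]
      rho_in <- if (is.na(m)) rho_bg else modules$rho[m]
      load_mod <- if (is.na(m)) 0 else sqrt(modules$rho[m] - rho_bg)
      v[i, ] <- sqrt(rho_bg) * g_fac +
        load_mod * (if (is.na(m)) 0 else f_fac[m, ]) +
        sqrt(1 - rho_in) * eps[i, ]
    }
    v
  })
  dimnames(vals) <- list(gene_ids, sample_ids)

  pairs <- do.call(rbind, lapply(seq_len(nrow(modules)), function(m) {
    g <- gene_ids[which(module_of == m)]
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  }))
  truth <- if (is.null(pairs)) {
    tibble(gene_a = character(), gene_b = character())
  } else {
    tibble(gene_a = pairs[, 1L], gene_b = pairs[, 2L])
  }
  list(expr = expr_mat(vals, groups = groups, scale = "linear"),
       truth = truth,
       modules = tibble(gene_id = gene_ids, module = module_of))
}

#' Benchmark graph with planted hub / VIP / high-hub roles
#'
#' Builds a graph realizing the three node archetypes: hubs each carry a set
#' of private leaves (high degree, low first-level concentric degree); VIPs
#' attach only to a few hubs (low degree, high `h_1`); high-hubs attach to
#' many private leaves *and* to several hubs (high degree and high `h_1`).
#' A sparse Erdős–Rényi background can be overlaid. Defaults produce the
#' canonical benchmark: 10 hubs with 30 leaves each, 5 VIPs on 3 hubs each,
#' 2 high-hubs with 25 leaves on 5 hubs each.
#'
#' @param n_hubs,leaves_per_hub Hub count and private leaves per hub.
#' @param n_vips,hubs_per_vip VIP count and hubs each VIP attaches to
#'   (must not exceed `n_hubs`).
#' @param n_high_hubs,leaves_per_high_hub,hubs_per_high_hub High-hub count,
#'   private leaves and hub attachments per high-hub.
#' @param background_p Probability of an extra background edge between any
#'   node pair (default 0).
#' @param seed Integer seed (required).
#' @return A list: `net` (igraph with a `role` vertex attribute) and `roles`
#'   (tibble `gene_id`, `role` with levels hub / vip / high_hub / leaf).
#' @export
gen_motif_graph <- function(n_hubs = 10L, leaves_per_hub = 30L, n_vips = 5L,
                            hubs_per_vip = 3L, n_high_hubs = 2L,
                            leaves_per_high_hub = 25L, hubs_per_high_hub = 5L,
                            background_p = 0, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_hubs >= 0L, n_vips >= 0L, n_high_hubs >= 0L)
  if (n_vips > 0L && hubs_per_vip > n_hubs) {
    stop("hubs_per_vip exceeds the number of hubs", call. = FALSE)
  }
  if (n_high_hubs > 0L && hubs_per_high_hub > n_hubs) {
    stop("hubs_per_high_hub exceeds the number of hubs", call. = FALSE)
  }
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  vips <- sprintf("VIP%02d", seq_len(n_vips))
  hhubs <- sprintf("HHB%02d", seq_len(n_high_hubs))
  edges <- character(0)
  leaves <- character(0)
  add_leaves <- function(owner, k, prefix) {
    lv <- sprintf("%s_%s%03d", prefix, "L", seq_len(k))
    leaves <<- c(leaves, lv)
    edges <<- c(edges, rbind(owner, lv))
  }
  for (h in hubs) add_leaves(h, leaves_per_hub, h)
  for (x in hhubs) add_leaves(x, leaves_per_high_hub, x)
  attach_to_hubs <- withr::with_seed(seed, {
    c(lapply(seq_len(n_vips), function(i) sample(hubs, hubs_per_vip)),
      lapply(seq_len(n_high_hubs), function(i) sample(hubs, hubs_per_high_hub)))
  })
  for (i in seq_len(n_vips)) {
    edges <- c(edges, rbind(vips[i], attach_to_hubs[[i]]))
  }
  for (i in seq_len(n_high_hubs)) {
    edges <- c(edges, rbind(hhubs[i], attach_to_hubs[[n_vips + i]]))
  }
  all_nodes <- sort(c(hubs, vips, hhubs, leaves))
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  g <- igraph::add_edges(g, edges)
  if (background_p > 0) {
    bg <- withr::with_seed(seed + 1L, {
      pr <- t(utils::combn(all_nodes, 2L))
      pr[runif(nrow(pr)) < background_p, , drop = FALSE]
    })
    if (nrow(bg)) g <- igraph::add_edges(g, t(bg))
    g <- igraph::simplify(g)
  }
  roles <- tibble(
    gene_id = all_nodes,
    role = dplyr::case_when(all_nodes %in% hubs ~ "hub",
                            all_nodes %in% vips ~ "vip",
                            all_nodes %in% hhubs ~ "high_hub",
                            TRUE ~ "leaf"))
  g <- igraph::set_vertex_attr(g, "role", value = roles$role[match(igraph::V(g)$name, roles$gene_id)])
  list(net = g, roles = roles)
}

#' Preferential-attachment (scale-free) benchmark graph
#'
#' Barabási–Albert growth: `m` edgeless seed vertices; the first arriving
#' vertex connects to all `m` seeds, and every later arrival attaches `m`
#' edges to distinct existing vertices with probability proportional to their
#' degree. The graph therefore has exactly `m * (n - m)` edges and every
#' non-seed vertex has degree >= m; the degree distribution approaches
#' `P(k) ∝ k^-3`.
#'
#' @param n Total number of vertices (`n > m`).
#' @param m Edges added per arriving vertex (>= 1).
#' @param seed Integer seed (required).
#' @return An igraph with vertex names `G000001`, ...
#' @export
gen_scale_free <- function(n, m, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(n) || !is.numeric(m) || m < 1L || n <= m) {
    stop("need n > m >= 1", call. = FALSE)
  }
  n <- as.integer(n); m <- as.integer(m)
  e1 <- integer(m * (n - m)); e2 <- integer(m * (n - m))
  # endpoint list: each vertex appears once per unit of degree
  targets <- integer(2L * m * (n - m))
  n_t <- 0L
  k <- 0L
  withr::local_seed(seed)
  for (v in (m + 1L):n) {
    if (v == m + 1L) {
      chosen <- seq_len(m)                      # first arrival wires the seeds
    } else {
      chosen <- integer(0)
      while (length(chosen) < m) {
        pick <- targets[sample.int(n_t, m)]
        chosen <- unique(c(chosen, pick))
        if (length(chosen) > m) chosen <- chosen[seq_len(m)]
      }
    }
    idx <- k + seq_len(m)
    e1[idx] <- v; e2[idx] <- chosen
    targets[n_t + seq_len(2L * m)] <- c(rep(v, m), chosen)
    n_t <- n_t + 2L * m
    k <- k + m
  }
  ids <- sprintf("G%06d", seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::add_edges(g, rbind(ids[e1], ids[e2]))
}
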