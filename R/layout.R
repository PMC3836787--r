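#' Parameters of the molecular-dynamics layout
#'
#' The layout treats nodes as unit-mass particles: every pair repels with a
#' Coulomb force of magnitude `k_c / d^2`, every edge attracts with a Hooke
#' spring force `k_s * d` (zero rest length), and a viscous force
#' `-lam * velocity` dissipates energy so the system relaxes toward a
#' minimal-energy configuration. The isolated two-node equilibrium separation
#' is `(k_c / k_s)^(1/3)`.
#'
#' @param k_c Coulomb repulsion constant (> 0).
#' @param k_s Spring constant (> 0).
#' @param lam Viscosity coefficient (>= 0).
#' @param mass Per-node mass (> 0).
#' @param dt Runge–Kutta time step (> 0).
#' @param dim Embedding dimension, 2 or 3.
#' @param max_iter Iteration cap.
#' @param speed_tol Convergence threshold on the maximum node speed.
#' @param seed Integer seed for the initial random placement (and for the
#'   deterministic jitter separating coincident points).
#' @param theta Barnes–Hut opening angle for approximate repulsion; 0 (the
#'   default) uses the exact O(n^2) sum.
#' @return A `layout_params` list.
#' @export
layout_params <- function(k_c = 1, k_s = 1, lam = 0.5, mass = 1, dt = 0.01,
                          dim = 2L, max_iter = 50000L, speed_tol = 1e-3,
                          seed = 1L, theta = 0) {
  stopifnot(k_c > 0, k_s > 0, lam >= 0, mass > 0, dt > 0,
            dim %in% c(2L, 3L), max_iter >= 1, speed_tol > 0, theta >= 0)
  structure(list(k_c = k_c, k_s = k_s, lam = lam, mass = mass, dt = dt,
                 dim = as.integer(dim), max_iter = as.integer(max_iter),
                 speed_tol = speed_tol, seed = as.integer(seed), theta = theta),
            class = "layout_params")
}

layout_context <- function(net, params) {
  ids <- sort(igraph::V(net)$name)
  el <- igraph::as_edgelist(net, names = TRUE)
  list(ids = ids, n = length(ids),
       e1 = match(el[, 1L], ids), e2 = match(el[, 2L], ids))
}

#' Random initial layout state
#'
#' Places nodes i.i.d. uniformly in the unit square/cube (seeded) with zero
#' velocities.
#'
#' @param net A `gene_net` igraph (non-empty).
#' @param params A [layout_params()].
#' @return An `md_layout`: list with `positions` and `velocities` (matrices,
#'   one row per node, rownames = sorted gene ids), `iteration`, `converged`.
#' @export
init_layout <- function(net, params = layout_params()) {
  stopifnot(inherits(net, "igraph"), inherits(params, "layout_params"))
  n <- igraph::vcount(net)
  if (n == 0L) stop("cannot lay out an empty network", call. = FALSE)
  ids <- sort(igraph::V(net)$name)
  P <- withr::with_seed(params$seed,
                        matrix(runif(n * params$dim), nrow = n))
  dimnames(P) <- list(ids, c("x", "y", "z")[seq_len(params$dim)])
  structure(list(positions = P,
                 velocities = array(0, dim(P), dimnames = dimnames(P)),
                 iteration = 0L, converged = FALSE, params = params),
            class = "md_layout")
}

#' @export
print.md_layout <- function(x, ...) {
  cat(sprintf("<md_layout> %d nodes, dim %d, iteration %d, %s\n",
              nrow(x$positions), ncol(x$positions), x$iteration,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# exact O(n^2) Coulomb repulsion; P has no coincident rows when called
repulsion_exact <- function(P, k_c) {
  n <- nrow(P); nd <- ncol(P)
  DX <- lapply(seq_len(nd), function(d) outer(P[, d], P[, d], "-"))
  D2 <- Reduce(`+`, lapply(DX, function(m) m * m))
  diag(D2) <- Inf
  inv_d3 <- 1 / (D2 * sqrt(D2))
  F <- vapply(seq_len(nd), function(d) k_c * rowSums(DX[[d]] * inv_d3),
              numeric(n))
  matrix(F, nrow = n, dimnames = dimnames(P))
}

# separate exactly coincident points with a deterministic seeded jitter
dejitter <- function(P, seed, iteration) {
  n <- nrow(P)
  if (n < 2L) return(P)
  dup <- duplicated(P) | duplicated(P, fromLast = TRUE)
  if (!any(dup)) return(P)
  J <- withr::with_seed(seed + iteration,
                        matrix(runif(n * ncol(P), -1, 1) * 1e-9, nrow = n))
  P[dup, ] <- P[dup, , drop = FALSE] + J[dup, , drop = FALSE]
  P
}

accumulate_rows <- function(idx, vals, n) {
  out <- matrix(0, n, ncol(vals))
  if (length(idx)) {
    s <- rowsum(vals, group = idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

force_eval <- function(P, V, ctx, params, iteration = 0L) {
  if (!all(is.finite(P))) stop("non-finite coordinates in layout state", call. = FALSE)
  P <- dejitter(P, params$seed, iteration)
  F <- if (params$theta > 0) {
    bh_repulsion(P, params$k_c, params$theta)
  } else {
    repulsion_exact(P, params$k_c)
  }
  if (length(ctx$e1)) {
    dvec <- P[ctx$e2, , drop = FALSE] - P[ctx$e1, , drop = FALSE]
    F <- F + params$k_s * accumulate_rows(ctx$e1, dvec, ctx$n)
    F <- F - params$k_s * accumulate_rows(ctx$e2, dvec, ctx$n)
  }
  F - params$lam * V
}

#' Per-node forces of the layout model
#'
#' Total force on each node: Coulomb repulsion `k_c/d^2` from every other
#' node, spring attraction of magnitude `k_s*d` toward each graph neighbour,
#' and the viscous term `-lam * velocity`. Exactly coincident points are
#' separated by a deterministic seeded jitter of magnitude 1e-9 before
#' evaluation.
#'
#' @param net A `gene_net` igraph.
#' @param state An `md_layout`.
#' @param params A [layout_params()].
#' @return Matrix of force vectors (rows = sorted gene ids).
#' @export
net_forces <- function(net, state, params = state$params) {
  stopifnot(inherits(state, "md_layout"))
  ctx <- layout_context(net, params)
  force_eval(state$positions[ctx$ids, , drop = FALSE],
             state$velocities[ctx$ids, , drop = FALSE],
             ctx, params, state$iteration)
}

rk4_step <- function(P, V, ctx, params, iteration) {
  dt <- params$dt; m <- params$mass
  f <- function(p, v) force_eval(p, v, ctx, params, iteration) / m
  k1p <- V;                 k1v <- f(P, V)
  k2p <- V + dt / 2 * k1v;  k2v <- f(P + dt / 2 * k1p, k2p)
  k3p <- V + dt / 2 * k2v;  k3v <- f(P + dt / 2 * k2p, k3p)
  k4p <- V + dt * k3v;      k4v <- f(P + dt * k3p, k4p)
  list(P = P + dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p),
       V = V + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
}

#' Advance the layout by one Runge–Kutta step
#'
#' One classical 4th-order Runge–Kutta update of positions and velocities
#' under the force law of [net_forces()].
#'
#' @inheritParams net_forces
#' @return The updated `md_layout` (iteration incremented).
#' @export
layout_step <- function(net, state, params = state$params) {
  stopifnot(inherits(state, "md_layout"))
  ctx <- layout_context(net, params)
  P <- state$positions[ctx$ids, , drop = FALSE]
  V <- state$velocities[ctx$ids, , drop = FALSE]
  new <- rk4_step(P, V, ctx, params, state$iteration)
  if (!all(is.finite(new$P)) || !all(is.finite(new$V))) {
    stop("integration diverged (non-finite values); reduce dt", call. = FALSE)
  }
  state$positions <- new$P
  state$velocities <- new$V
  state$iteration <- state$iteration + 1L
  state$params <- params
  state
}

#' Relax a network layout to (near) equilibrium
#'
#' Iterates [layout_step()] from a seeded random placement until the maximum
#' node speed drops below `speed_tol` or `max_iter` is reached.
#' Non-convergence is flagged, not an error.
#'
#' @param net A `gene_net` igraph.
#' @param params A [layout_params()].
#' @return Final `md_layout` with `converged` set accordingly.
#' @export
run_layout <- function(net, params = layout_params()) {
  state <- init_layout(net, params)
  ctx <- layout_context(net, params)
  P <- state$positions; V <- state$velocities
  for (it in seq_len(params$max_iter)) {
    new <- rk4_step(P, V, ctx, params, it - 1L)
    if (!all(is.finite(new$P)) || !all(is.finite(new$V))) {
      stop("integration diverged (non-finite values); reduce dt", call. = FALSE)
    }
    P <- new$P; V <- new$V
    if (sqrt(max(rowSums(V * V))) <= params$speed_tol) {
      # guard against oscillation turning points: the speed the current
      # forces would add over one step must be well below the tolerance,
      # otherwise v ~ 0 at the extreme of a residual oscillation passes
      acc <- force_eval(P, V, ctx, params, it) / params$mass
      if (params$dt * sqrt(max(rowSums(acc * acc))) <= params$speed_tol / 10) {
        state$converged <- TRUE
        break
      }
    }
  }
  state$positions <- P
  state$velocities <- V
  state$iteration <- if (state$converged) it else params$max_iter
  state
}

#' Kinetic and potential energy of a layout state
#'
#' Kinetic energy is `sum(mass * |v|^2 / 2)`; potential energy sums the
#' Coulomb pair potential `k_c / d` and the spring potential `k_s * d^2 / 2`
#' per edge — the potentials whose negative gradients are the layout forces.
#'
#' @inheritParams net_forces
#' @return Tibble with one row: `kinetic`, `potential`, `total`.
#' @export
layout_energy <- function(net, state, params = state$params) {
  stopifnot(inherits(state, "md_layout"))
  ctx <- layout_context(net, params)
  P <- state$positions[ctx$ids, , drop = FALSE]
  V <- state$velocities[ctx$ids, , drop = FALSE]
  kin <- 0.5 * params$mass * sum(V * V)
  D <- as.matrix(stats::dist(P))
  pot_rep <- params$k_c * sum(1 / D[upper.tri(D)])
  pot_spr <- if (length(ctx$e1)) {
    d2 <- rowSums((P[ctx$e2, , drop = FALSE] - P[ctx$e1, , drop = FALSE])^2)
    0.5 * params$k_s * sum(d2)
  } else 0
  tibble(kinetic = kin, potential = pot_rep + pot_spr,
         total = kin + pot_rep + pot_spr)
}

#' Write layout coordinates as TSV
#'
#' @param state An `md_layout`.
#' @param path Output path; columns `gene_id`, `x`, `y` (and `z` in 3D).
#' @return `path`, invisibly.
#' @export
write_coords <- function(state, path) {
  stopifnot(inherits(state, "md_layout"))
  df <- data.frame(gene_id = rownames(state$positions), state$positions,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
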