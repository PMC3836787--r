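#' Tidy a discrete power-law fit
#'
#' @param x A `pl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.pl_fit <- function(x, ...) {
  tibble(term = c("gamma", "x_min"),
         estimate = c(x$gamma, as.numeric(x$x_min)))
}

#' One-row summary of a power-law fit
#'
#' @param x A `pl_fit`.
#' @param ... Unused.
#' @return Tibble: `gamma`, `x_min`, `ks_stat`, `p_value`, `n_tail`, `logLik`.
#' @export
glance.pl_fit <- function(x, ...) {
  tibble(gamma = x$gamma, x_min = as.integer(x$x_min), ks_stat = x$ks_stat,
         p_value = x$p_value, n_tail = x$n_tail, logLik = x$logLik)
}

#' One-row summary of a layout relaxation
#'
#' @param x An `md_layout`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `dim`, `iterations`, `converged`, `max_speed`.
#' @export
glance.md_layout <- function(x, ...) {
  tibble(n_nodes = nrow(x$positions), dim = ncol(x$positions),
         iterations = x$iteration, converged = x$converged,
         max_speed = sqrt(max(rowSums(x$velocities^2))))
}

#' Tidy layout coordinates
#'
#' @param x An `md_layout`.
#' @param ... Unused.
#' @return Tibble with `gene_id` and one column per coordinate.
#' @export
tidy.md_layout <- function(x, ...) {
  out <- tibble(gene_id = rownames(x$positions))
  for (j in seq_len(ncol(x$positions))) {
    out[[colnames(x$positions)[j]]] <- x$positions[, j]
  }
  out
}
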