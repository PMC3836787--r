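#' Log-log degree distribution with the fitted power law
#'
#' Mirrors the usual normalized degree-distribution plot: points are the
#' empirical frequencies on log-log axes, the line the fitted
#' `P(k) ∝ k^-gamma` over the fitted tail.
#'
#' @param net A `gene_net` igraph.
#' @param fit Optional `pl_fit` from [fit_power_law()]; drawn when supplied.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net, fit = NULL) {
  h <- degree_histogram(net, normalized = TRUE)
  h <- h[h$k > 0, ]
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$k, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node degree k", y = "P(k)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "pl_fit"))
    ks <- seq(fit$x_min, max(h$k))
    tail_mass <- sum(h$frequency[h$k >= fit$x_min])
    z <- hurwitz_zeta(fit$gamma, fit$x_min)
    line <- tibble(k = ks, frequency = tail_mass * ks^(-fit$gamma) / z)
    p <- p + ggplot2::geom_line(data = line, colour = "red")
  }
  p
}

#' @export
autoplot.pl_fit <- function(object, ...) {
  deg <- object$degrees
  tab <- table(deg)
  h <- tibble(k = as.integer(names(tab)),
              frequency = as.integer(tab) / length(deg))
  h <- h[h$k > 0, ]
  ks <- seq(object$x_min, max(h$k))
  z <- hurwitz_zeta(object$gamma, object$x_min)
  tail_mass <- sum(h$frequency[h$k >= object$x_min])
  line <- tibble(k = ks, frequency = tail_mass * ks^(-object$gamma) / z)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$k, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node degree k", y = "P(k)",
                  title = sprintf("gamma = %.2f, x_min = %d",
                                  object$gamma, object$x_min)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.node_metrics <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$degree, y = .data$cdegree_l1,
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(high_hub = "purple", hub = "red",
                                            vip = "blue", none = "grey60")) +
    ggplot2::labs(x = "node degree k", y = "concentric degree h1") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.md_layout <- function(object, net = NULL, colour_by = c("degree", "category"),
                               ...) {
  colour_by <- match.arg(colour_by)
  pos <- tibble(gene_id = rownames(object$positions),
                x = object$positions[, 1L], y = object$positions[, 2L])
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(net)) {
    el <- igraph::as_edgelist(net, names = TRUE)
    seg <- tibble(x = pos$x[match(el[, 1L], pos$gene_id)],
                  y = pos$y[match(el[, 1L], pos$gene_id)],
                  xend = pos$x[match(el[, 2L], pos$gene_id)],
                  yend = pos$y[match(el[, 2L], pos$gene_id)])
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(xend = .data$xend, yend = .data$yend),
      colour = "grey75", linewidth = 0.3)
    if (colour_by == "degree") {
      pos$degree <- igraph::degree(net)[pos$gene_id]
      p <- p + ggplot2::geom_point(data = pos,
                                   ggplot2::aes(colour = .data$degree)) +
        ggplot2::scale_colour_gradient(low = "blue", high = "red")
    } else {
      p <- p + ggplot2::geom_point(data = pos)
    }
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
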