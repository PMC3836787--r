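# Discrete power-law machinery: Hurwitz zeta, MLE for the exponent, x_min
# selection by KS minimization, inverse-CDF sampling, and the semiparametric
# KS bootstrap goodness-of-fit.

# Hurwitz zeta  sum_{k>=a} k^-s  by direct summation plus Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a) {
  stopifnot(s > 1, a >= 1)
  n_direct <- 1000L
  k <- seq(a, a + n_direct - 1L)
  head <- sum(k^(-s))
  N <- a + n_direct
  head + N^(1 - s) / (s - 1) + 0.5 * N^(-s) + s / 12 * N^(-s - 1) -
    s * (s + 1) * (s + 2) / 720 * N^(-s - 3)
}

# P(X <= x) for the discrete power law with exponent gamma, support >= x_min
ppower <- function(x, gamma, x_min, z = hurwitz_zeta(gamma, x_min)) {
  vapply(x, function(xi) {
    if (xi < x_min) 0 else 1 - hurwitz_zeta(gamma, floor(xi) + 1) / z
  }, numeric(1L))
}

# KS distance between the empirical CDF of tail (integer sample, all >= x_min)
# and the fitted discrete power-law CDF. Both are right-continuous step
# functions jumping at the same integers, so the supremum is attained at the
# observed support points (no lower-step variant, unlike the continuous case).
ks_distance <- function(tail, gamma, x_min) {
  n <- length(tail)
  xs <- sort(unique(tail))
  Femp <- cumsum(tabulate(factor(tail, levels = xs))) / n
  z <- hurwitz_zeta(gamma, x_min)
  Ffit <- ppower(xs, gamma, x_min, z)
  max(abs(Femp - Ffit))
}

mle_gamma <- function(tail, x_min, lower = 1.001, upper = 8) {
  slog <- sum(log(tail))
  n <- length(tail)
  nll <- function(g) n * log(hurwitz_zeta(g, x_min)) + g * slog
  optimize(nll, c(lower, upper), tol = 1e-6)$minimum
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood estimate of the exponent `gamma` for the discrete power
#' law `P(k) ∝ k^(-gamma)`, `k >= x_min`, with the lower cut-off `x_min`
#' chosen — when not supplied — by minimizing the Kolmogorov–Smirnov distance
#' between the empirical tail and the fitted model over candidate cut-offs.
#' At least `min_tail` observations must remain above the cut-off.
#'
#' @param degrees Vector of positive integers (e.g. node degrees).
#' @param x_min Optional fixed lower cut-off; `NULL` selects it by KS
#'   minimization.
#' @param min_tail Minimum number of tail observations required for a fit
#'   (default 50).
#' @return A `pl_fit` object: list with `gamma`, `x_min`, `ks_stat`,
#'   `n_tail`, `logLik`, `p_value` (`NA` until [ks_gof()] is run) and the
#'   input `degrees`.
#' @export
fit_power_law <- function(degrees, x_min = NULL, min_tail = 50L) {
  degrees <- as.integer(degrees)
  if (any(degrees < 1L) || anyNA(degrees)) {
    stop("degrees must be positive integers", call. = FALSE)
  }
  if (length(unique(degrees)) < 2L) {
    stop("all degrees equal: no scale to fit", call. = FALSE)
  }
  if (is.null(x_min)) {
    cand <- sort(unique(degrees))
    cand <- cand[vapply(cand, function(x) sum(degrees >= x), integer(1L)) >= min_tail]
    if (!length(cand)) stop("fewer than ", min_tail, " tail observations",
                            call. = FALSE)
    if (length(cand) > 60L) {  # cap the scan; keep smallest cut-offs dense
      cand <- unique(c(cand[1:20], cand[round(seq(21, length(cand), length.out = 40L))]))
    }
    fits <- lapply(cand, function(xm) {
      tail <- degrees[degrees >= xm]
      if (length(unique(tail)) < 2L) return(NULL)
      g <- mle_gamma(tail, xm)
      list(x_min = xm, gamma = g, ks = ks_distance(tail, g, xm), n = length(tail))
    })
    fits <- fits[!vapply(fits, is.null, logical(1L))]
    if (!length(fits)) stop("no admissible x_min candidate", call. = FALSE)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "ks"))]]
  } else {
    x_min <- as.integer(x_min)
    tail <- degrees[degrees >= x_min]
    if (length(tail) < min_tail) stop("fewer than ", min_tail,
                                      " tail observations above x_min", call. = FALSE)
    if (length(unique(tail)) < 2L) stop("all tail degrees equal: no scale to fit",
                                        call. = FALSE)
    g <- mle_gamma(tail, x_min)
    best <- list(x_min = x_min, gamma = g, ks = ks_distance(tail, g, x_min),
                 n = length(tail))
  }
  tail <- degrees[degrees >= best$x_min]
  ll <- -(length(tail) * log(hurwitz_zeta(best$gamma, best$x_min)) +
            best$gamma * sum(log(tail)))
  structure(list(gamma = best$gamma, x_min = best$x_min, ks_stat = best$ks,
                 n_tail = best$n, logLik = ll, p_value = NA_real_,
                 degrees = degrees, min_tail = min_tail),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf("<pl_fit> gamma = %.4f, x_min = %d, KS = %.4f, n_tail = %d\n",
              x$gamma, x$x_min, x$ks_stat, x$n_tail))
  if (!is.na(x$p_value)) cat(sprintf("bootstrap p = %.3f\n", x$p_value))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling from `P(k) ∝ k^(-gamma)`, `k >= x_min`, via a
#' precomputed CDF table covering all but a negligible (< 1e-9) tail mass.
#'
#' @param n Number of draws.
#' @param gamma Exponent (> 1).
#' @param x_min Lower bound of the support (default 1).
#' @param seed Optional integer seed for reproducible draws.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw <- function(n, gamma, x_min = 1L, seed = NULL) {
  stopifnot(gamma > 1, x_min >= 1)
  z <- hurwitz_zeta(gamma, x_min)
  # support table out to where the remaining mass is negligible
  K <- x_min + 1000L
  while (hurwitz_zeta(gamma, K) / z > 1e-9 && K < 2e6) K <- K * 4L
  ks <- seq.int(x_min, K)
  cdf <- cumsum(ks^(-gamma) / z)
  draw <- function() {
    u <- runif(n)
    x <- ks[findInterval(u, cdf) + 1L]
    x[is.na(x)] <- K  # beyond-table mass < 1e-9
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Kolmogorov–Smirnov bootstrap goodness-of-fit
#'
#' Semiparametric bootstrap p-value for a fitted discrete power law: each
#' synthetic dataset draws, with probability `n_tail/n`, from the fitted
#' model and otherwise resamples the empirical body below `x_min`; the model
#' is refit (free cut-off) to every synthetic dataset and the p-value is the
#' fraction of synthetic KS distances exceeding the observed one. Values
#' above ~0.1 are conventionally read as "plausibly power law".
#'
#' @param fit A `pl_fit` from [fit_power_law()].
#' @param n_boot Number of bootstrap replicates (>= 20; default 100).
#' @param seed Integer seed.
#' @return The `pl_fit` with `p_value` filled in.
#' @export
ks_gof <- function(fit, n_boot = 100L, seed = 1L) {
  stopifnot(inherits(fit, "pl_fit"))
  if (!is.numeric(n_boot) || n_boot < 20L) {
    stop("n_boot must be at least 20", call. = FALSE)
  }
  degrees <- fit$degrees
  n <- length(degrees)
  body <- degrees[degrees < fit$x_min]
  p_tail <- fit$n_tail / n
  min_tail_boot <- min(fit$min_tail, max(10L, floor(fit$n_tail / 2)))
  ks_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take_tail <- if (length(body)) runif(n) < p_tail else rep(TRUE, n)
      synth <- integer(n)
      synth[take_tail] <- rpowerlaw(sum(take_tail), fit$gamma, fit$x_min)
      if (any(!take_tail)) synth[!take_tail] <- sample(body, sum(!take_tail),
                                                       replace = TRUE)
      f <- tryCatch(fit_power_law(synth, min_tail = min_tail_boot),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$ks_stat
    }, numeric(1L))
  })
  ks_boot <- ks_boot[!is.na(ks_boot)]
  fit$p_value <- mean(ks_boot > fit$ks_stat)
  fit$n_boot <- length(ks_boot)
  fit
}

#' Degree histogram of a network
#'
#' @param net A `gene_net` igraph.
#' @param normalized If `TRUE`, report frequencies (summing to 1) instead of
#'   counts.
#' @return Tibble with `k` and `count` (or `frequency`), one row per observed
#'   degree, ascending.
#' @export
degree_histogram <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "igraph"))
  deg <- igraph::degree(net)
  tab <- table(deg)
  out <- tibble(k = as.integer(names(tab)), count = as.integer(tab))
  if (normalized) {
    out$frequency <- out$count / sum(out$count)
    out$count <- NULL
  }
  out
}
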