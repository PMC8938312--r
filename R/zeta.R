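#' Number of species shared by a set of plots
#'
#' @param incidence binary incidence matrix (plots x species).
#' @param plot_index integer vector of plot row indices (length >= 1).
#' @return Integer: species present in every listed plot.
#' @export
shared_species_count <- function(incidence, plot_index) {
  if (length(plot_index) < 1) stop("need at least one plot index", call. = FALSE)
  if (any(plot_index < 1 | plot_index > nrow(incidence)))
    stop("plot index out of range", call. = FALSE)
  sum(.colSums(incidence[plot_index, , drop = FALSE] > 0,
               length(plot_index), ncol(incidence)) == length(plot_index))
}

## Raw and Simpson-normalized shared-species values for a set of
## combinations (matrix with i rows, one column per combination).
## Simpson divides by the minimum richness among the combined plots;
## combinations containing an empty plot are dropped (count reported).
zeta_samples <- function(incidence, combs, normalization = c("raw", "simpson")) {
  normalization <- match.arg(normalization)
  i <- nrow(combs)
  S <- ncol(incidence)
  rich <- rowSums(incidence > 0)
  raw <- apply(combs, 2, function(idx) {
    sum(.colSums(incidence[idx, , drop = FALSE] > 0, i, S) == i)
  })
  if (normalization == "raw") {
    list(values = raw, n_skipped = 0L)
  } else {
    minr <- apply(combs, 2, function(idx) min(rich[idx]))
    ok <- minr > 0
    if (any(!ok))
      message(sprintf("simpson normalization: skipped %d combination(s) containing an empty plot",
                      sum(!ok)))
    list(values = raw[ok] / minr[ok], n_skipped = sum(!ok))
  }
}

## Nearest-neighbour combinations: each replicate draws a random focal plot
## and joins it with its i-1 nearest plots. Distance ties (to 1e-12 km,
## absorbing floating-point noise) are broken at random so that, with all
## plots equidistant, neighbour sets are uniform over combinations
## (matching the random scheme).
nn_combinations <- function(coordinates, i, n_replicates) {
  P <- nrow(coordinates)
  dmat <- round(as.matrix(stats::dist(as.matrix(coordinates))), 12)
  vapply(seq_len(n_replicates), function(b) {
    focal <- sample.int(P, 1)
    ord <- setdiff(order(dmat[focal, ], stats::runif(P)), focal)
    c(focal, ord[seq_len(i - 1)])
  }, integer(i))
}

#' Zeta diversity of one order
#'
#' Mean (and spread) of the number of species shared by `i` plots, under
#' random (`"ALL"`) or nearest-neighbour (`"NN"`) combination sampling.
#' The ALL scheme enumerates every combination exactly whenever
#' `choose(P, i) <= n_replicates` (or when forced); otherwise combinations
#' are drawn uniformly, without repetition inside a combination.
#'
#' @param incidence binary incidence matrix (plots x species).
#' @param i zeta order, `1 <= i <= P`.
#' @param scheme `"ALL"` (random combinations) or `"NN"` (a random focal
#'   plot plus its `i - 1` nearest neighbours, per replicate).
#' @param coordinates planar coordinates (km), required for `"NN"`.
#' @param normalization `"raw"` (shared-species count) or `"simpson"`
#'   (count divided by the minimum richness of the combined plots).
#' @param n_replicates Monte-Carlo replicates (default 10000).
#' @param seed optional integer seed.
#' @param force_exhaustive enumerate all combinations regardless of count.
#' @return List: `mean`, `sd`, `samples`, `exhaustive`, `n_skipped`.
#' @export
zeta_order <- function(incidence, i, scheme = c("ALL", "NN"),
                       coordinates = NULL,
                       normalization = c("raw", "simpson"),
                       n_replicates = 10000, seed = NULL,
                       force_exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  P <- nrow(incidence)
  if (i < 1 || i > P) stop(sprintf("order i = %d outside [1, %d]", i, P), call. = FALSE)
  if (scheme == "NN" && is.null(coordinates))
    stop("NN scheme needs coordinates", call. = FALSE)

  with_seed(seed, {
    if (scheme == "ALL") {
      cs <- sample_combinations(P, i, n_replicates, force_exhaustive)
      combs <- cs$combs
      exhaustive <- cs$exhaustive
    } else {
      combs <- nn_combinations(coordinates, i, n_replicates)
      exhaustive <- FALSE
    }
    zs <- zeta_samples(incidence, combs, normalization)
    v <- zs$values
    list(mean = mean(v),
         sd = if (length(v) > 1) stats::sd(v) else 0,
         samples = v,
         exhaustive = exhaustive,
         n_skipped = zs$n_skipped)
  })
}

#' Simpson-normalized zeta diversity of one order
#'
#' Convenience wrapper around [zeta_order()] with
#' `normalization = "simpson"`: per combination the shared-species count is
#' divided by the minimum richness of the plots combined, giving a
#' turnover measure in `[0, 1]` that discounts richness differences.
#'
#' @inheritParams zeta_order
#' @param ... passed to [zeta_order()].
#' @return List: `mean`, `sd`, `samples`, `exhaustive`, `n_skipped`.
#' @export
simpson_zeta <- function(incidence, i, scheme = c("ALL", "NN"), ...) {
  zeta_order(incidence, i, scheme = match.arg(scheme),
             normalization = "simpson", ...)
}

#' Zeta decline over a range of orders
#'
#' @inheritParams zeta_order
#' @param orders integer vector of orders (default `2:50`, capped at P).
#' @param band `"normal"` (mean +/- 1.96 sd of replicate values) or
#'   `"percentile"` (2.5/97.5 percentiles).
#' @return data.frame of class `zeta_decline`: per order `zeta` (mean),
#'   `sd`, `lower`, `upper`, `exhaustive`; attributes record scheme,
#'   normalization, replicates and seed.
#' @export
zeta_decline <- function(incidence, orders = 2:50, scheme = c("ALL", "NN"),
                         normalization = c("raw", "simpson"),
                         coordinates = NULL, n_replicates = 10000,
                         seed = NULL, band = c("normal", "percentile")) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  band <- match.arg(band)
  orders <- orders[orders >= 1 & orders <= nrow(incidence)]
  rows <- lapply(seq_along(orders), function(j) {
    z <- zeta_order(incidence, orders[j], scheme = scheme,
                    coordinates = coordinates, normalization = normalization,
                    n_replicates = n_replicates,
                    seed = if (is.null(seed)) NULL else child_seed(seed, j))
    if (band == "normal") {
      lo <- z$mean - 1.96 * z$sd
      hi <- z$mean + 1.96 * z$sd
    } else {
      qs <- stats::quantile(z$samples, c(0.025, 0.975))
      lo <- qs[[1]]; hi <- qs[[2]]
    }
    data.frame(order = orders[j], zeta = z$mean, sd = z$sd,
               lower = lo, upper = hi, exhaustive = z$exhaustive)
  })
  out <- do.call(rbind, rows)
  attr(out, "scheme") <- scheme
  attr(out, "normalization") <- normalization
  attr(out, "n_replicates") <- n_replicates
  attr(out, "seed") <- seed
  class(out) <- c("zeta_decline", "data.frame")
  out
}

#' Compare power-law and exponential forms of a zeta decline
#'
#' Fits `ln(zeta) ~ ln(order)` (power law) and `ln(zeta) ~ order`
#' (exponential) by ordinary least squares; both regressions share the
#' log response, so their Gaussian AICs (3 parameters each: intercept,
#' slope, residual variance) are directly comparable. A power-law decline
#' is the signature of niche-structured turnover; an exponential decline
#' of stochastic turnover.
#'
#' @param decline a [zeta_decline()] result, or a data.frame with columns
#'   `order` and `zeta`.
#' @return List of class `decline_fit`: `exponent` (power-law slope) and
#'   `exponent_ci` (95%), `intercept`, `rate` (exponential slope) and
#'   `rate_ci`, `aic_power`, `aic_exp`, `delta_aic` (`aic_exp - aic_power`),
#'   `best` (`"power"` or `"exponential"`), `n_orders`.
#' @export
fit_zeta_decline <- function(decline) {
  d <- as.data.frame(decline)
  if (any(d$zeta <= 0)) {
    keep <- d$zeta > 0
    warning(sprintf("dropping %d order(s) with zeta <= 0 before log fits",
                    sum(!keep)), call. = FALSE)
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) < 3) stop("need at least 3 positive orders to fit", call. = FALSE)
  ly <- log(d$zeta)
  fit_pow <- stats::lm(ly ~ log(d$order))
  fit_exp <- stats::lm(ly ~ d$order)
  # suppress the "essentially perfect fit" note on exact series
  ci_pow <- suppressWarnings(stats::confint(fit_pow)[2, ])
  ci_exp <- suppressWarnings(stats::confint(fit_exp)[2, ])
  aic_p <- stats::AIC(fit_pow)
  aic_e <- stats::AIC(fit_exp)
  structure(list(exponent = unname(stats::coef(fit_pow)[2]),
                 exponent_ci = unname(ci_pow),
                 intercept = unname(stats::coef(fit_pow)[1]),
                 rate = unname(stats::coef(fit_exp)[2]),
                 rate_ci = unname(ci_exp),
                 aic_power = aic_p, aic_exp = aic_e,
                 delta_aic = aic_e - aic_p,
                 best = if (aic_p <= aic_e) "power" else "exponential",
                 n_orders = nrow(d)),
            class = "decline_fit")
}

#' @export
print.decline_fit <- function(x, ...) {
  cat(sprintf("Zeta decline fit over %d orders: %s law preferred (dAIC = %.1f)\n",
              x$n_orders, x$best, x$delta_aic))
  cat(sprintf("  power-law exponent %.3f [%.3f, %.3f]; exponential rate %.3f [%.3f, %.3f]\n",
              x$exponent, x$exponent_ci[1], x$exponent_ci[2],
              x$rate, x$rate_ci[1], x$rate_ci[2]))
  invisible(x)
}
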