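#' Build a multi-site dissimilarity design for one zeta order
#'
#' For each sampled combination of `order` plots the response is the raw
#' shared-species count and each predictor is the mean pairwise absolute
#' difference of one environmental variable (or the mean pairwise spatial
#' distance, column `distance`) over the combined plots, rescaled to
#' `[0, 1]` by its observed maximum.
#'
#' @param incidence binary incidence matrix (plots x species).
#' @param env_table data.frame of plot-level environmental predictors.
#' @param coordinates planar plot coordinates (km).
#' @param order zeta order, normally in `[2, 10]` (predictive power fades
#'   at higher orders); pass `force = TRUE` to exceed the range.
#' @param n_samples combinations to draw (default 10000); exhaustive when
#'   `choose(P, order) <= n_samples`.
#' @param seed optional integer seed.
#' @param force allow orders outside `[2, 10]`.
#' @return List of class `msgdm_design`: `response` (zeta values),
#'   `predictors` (data.frame, env columns then `distance`, all in
#'   `[0, 1]`), `order`, `exhaustive`, `scaling` (the maxima used), `seed`.
#' @export
build_design <- function(incidence, env_table, coordinates, order,
                         n_samples = 10000, seed = NULL, force = FALSE) {
  P <- nrow(incidence)
  if (!force && (order < 2 || order > 10))
    stop("order outside [2, 10]; use force = TRUE to override", call. = FALSE)
  if (order > P) stop("order exceeds number of plots", call. = FALSE)
  coordinates <- as.matrix(coordinates)
  env_table <- as.data.frame(env_table)

  with_seed(seed, {
    cs <- sample_combinations(P, order, n_samples)
    combs <- cs$combs
    zeta <- zeta_samples(incidence, combs, "raw")$values
    pred <- sapply(names(env_table), function(v) {
      apply(combs, 2, function(idx) mean_pairwise_diff(env_table[[v]], idx))
    })
    dist_col <- apply(combs, 2, function(idx) mean_pairwise_dist(coordinates, idx))
    pred <- cbind(as.data.frame(pred), distance = dist_col)
    scaling <- vapply(pred, max, numeric(1))
    scaling[scaling == 0] <- 1  # constant predictors stay all-zero
    pred[] <- Map(`/`, pred, scaling)
    structure(list(response = zeta, predictors = pred, order = order,
                   exhaustive = cs$exhaustive, scaling = scaling, seed = seed),
              class = "msgdm_design")
  })
}

## Expand all predictor columns of a design into I-spline bases.
## Knots per predictor are placed at interior quantiles of its sampled
## values (e.g. the median for a single interior knot), falling back to
## evenly spaced knots when the quantiles are degenerate.
expand_isplines <- function(design, degree = 2, n_interior_knots = 1) {
  pred <- design$predictors
  cols <- lapply(names(pred), function(v) {
    x <- pred[[v]]
    probs <- seq_len(n_interior_knots) / (n_interior_knots + 1)
    kn <- unname(stats::quantile(x, probs))
    if (any(kn <= 0 | kn >= 1) || anyDuplicated(kn)) kn <- probs
    b <- ispline_basis(x, degree = degree, interior_knots = kn)
    colnames(b) <- paste(v, colnames(b), sep = ".")
    b
  })
  X <- do.call(cbind, cols)
  groups <- rep(names(pred), each = degree + n_interior_knots)
  list(X = X, groups = groups)
}

## Monotone-decreasing least squares: minimise ||y - b0 + X c||^2 with
## c >= 0 and free intercept. Centring both sides profiles out b0, leaving
## a non-negative least-squares problem.
nnls_decreasing <- function(X, y) {
  A <- -scale(X, center = TRUE, scale = FALSE)
  fit <- pracma::lsqnonneg(A, y - mean(y))
  coef <- fit$x
  b0 <- mean(y + X %*% coef)
  fitted <- as.numeric(b0 - X %*% coef)
  list(coef = coef, intercept = b0, fitted = fitted)
}

#' Fit a multi-site generalized dissimilarity model
#'
#' Regresses the shared-species response on I-spline transforms of the
#' design's predictors under a monotonicity constraint: greater
#' environmental difference or spatial distance can only reduce the number
#' of shared species. The constraint is imposed by negating the basis and
#' requiring non-negative coefficients; the intercept is free. The height
#' reached by each predictor's I-spline (the sum of its coefficients) is
#' its amplitude, a direct measure of explanatory power.
#'
#' @param design an [build_design()] result.
#' @param degree I-spline degree (default 2).
#' @param n_interior_knots interior knots per predictor (default 1; 3
#'   basis functions per predictor with the defaults).
#' @param predictors optional character vector restricting which design
#'   columns enter the model (used for variation partitioning).
#' @return List of class `msgdm_fit`: `intercept`, `coefficients` (named,
#'   all >= 0), `amplitudes` (per predictor), `fitted`,
#'   `explained_variation` (1 - SSE/SST), `order`, `rank_deficient` note.
#' @export
fit_msgdm <- function(design, degree = 2, n_interior_knots = 1,
                      predictors = NULL) {
  d <- design
  if (!is.null(predictors)) {
    missing_p <- setdiff(predictors, names(d$predictors))
    if (length(missing_p))
      stop(sprintf("unknown predictor(s): %s", paste(missing_p, collapse = ", ")),
           call. = FALSE)
    d$predictors <- d$predictors[predictors]
  }
  ex <- expand_isplines(d, degree, n_interior_knots)
  n <- length(d$response)
  if (n < 10 * ncol(ex$X))
    stop(sprintf("design has %d rows for %d basis columns; need >= 10x", n,
                 ncol(ex$X)), call. = FALSE)
  rank_def <- qr(cbind(1, ex$X))$rank < ncol(ex$X) + 1
  if (rank_def)
    message("design is rank deficient (constant or aliased predictor); fit proceeds")
  fit <- nnls_decreasing(ex$X, d$response)
  names(fit$coef) <- colnames(ex$X)
  sst <- sum((d$response - mean(d$response))^2)
  sse <- sum((d$response - fit$fitted)^2)
  r2 <- if (sst > 0) max(0, 1 - sse / sst) else 0
  amp <- tapply(fit$coef, ex$groups, sum)[unique(ex$groups)]
  structure(list(intercept = fit$intercept,
                 coefficients = fit$coef,
                 amplitudes = amp,
                 fitted = fit$fitted,
                 explained_variation = r2,
                 order = d$order,
                 rank_deficient = rank_def,
                 degree = degree,
                 n_interior_knots = n_interior_knots),
            class = "msgdm_fit")
}

#' @export
print.msgdm_fit <- function(x, ...) {
  cat(sprintf("MS-GDM fit, zeta order %d: explained variation %.3f\n",
              x$order, x$explained_variation))
  cat("I-spline amplitudes:\n")
  print(round(x$amplitudes, 4))
  invisible(x)
}

#' Partition explained variation into spatial and environmental fractions
#'
#' Fits the full model, a distance-only model and an environment-only
#' model on the same design, and splits the full model's explained
#' variation into pure-distance, pure-environment, shared and unexplained
#' fractions. Negative pure fractions (possible with correlated
#' predictors) are reported raw in `raw` and clipped to zero in the main
#' fractions with `clipped = TRUE`.
#'
#' @inheritParams fit_msgdm
#' @param distance_cols names of the spatial predictor columns
#'   (default `"distance"`).
#' @return List of class `variation_partition`: `pure_distance`,
#'   `pure_environment`, `shared`, `unexplained` (summing to 1), plus
#'   `r2_full`, `r2_distance`, `r2_environment`, `raw`, `clipped`.
#' @export
variation_partition <- function(design, degree = 2, n_interior_knots = 1,
                                distance_cols = "distance") {
  env_cols <- setdiff(names(design$predictors), distance_cols)
  full <- fit_msgdm(design, degree, n_interior_knots)
  fd <- fit_msgdm(design, degree, n_interior_knots, predictors = distance_cols)
  fe <- fit_msgdm(design, degree, n_interior_knots, predictors = env_cols)
  r2f <- full$explained_variation
  r2d <- fd$explained_variation
  r2e <- fe$explained_variation
  pure_d <- r2f - r2e
  pure_e <- r2f - r2d
  shared <- r2d + r2e - r2f
  raw <- c(pure_distance = pure_d, pure_environment = pure_e,
           shared = shared, unexplained = 1 - r2f)
  clipped <- any(raw[1:3] < 0)
  frac <- pmax(raw, 0)
  # renormalise the explained part so the four fractions still sum to 1
  expl <- sum(frac[1:3])
  if (clipped && expl > 0) frac[1:3] <- frac[1:3] * r2f / expl
  frac["unexplained"] <- 1 - sum(frac[1:3])
  structure(list(pure_distance = unname(frac["pure_distance"]),
                 pure_environment = unname(frac["pure_environment"]),
                 shared = unname(frac["shared"]),
                 unexplained = unname(frac["unexplained"]),
                 r2_full = r2f, r2_distance = r2d, r2_environment = r2e,
                 raw = raw, clipped = clipped),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat(sprintf("Variation partition: distance %.3f | environment %.3f | shared %.3f | unexplained %.3f\n",
              x$pure_distance, x$pure_environment, x$shared, x$unexplained))
  invisible(x)
}

#' Multi-site dissimilarity models across zeta orders and components
#'
#' Runs [build_design()], [fit_msgdm()] and [variation_partition()] for
#' each requested order and origin component and returns tidy tables.
#'
#' @param dataset a [survey_dataset].
#' @param components character vector from `"all"`, `"native"`, `"alien"`.
#' @param orders zeta orders (default `2:10`).
#' @param n_samples combinations per design (default 10000).
#' @param degree,n_interior_knots I-spline configuration.
#' @param seed optional integer master seed.
#' @return List of class `msgdm_scan` with data.frames `amplitudes`
#'   (component, order, predictor, amplitude, explained_variation),
#'   `partitions` (component, order, four fractions) and `coefficients`.
#' @export
msgdm_across_orders <- function(dataset, components = c("native", "alien"),
                                orders = 2:10, n_samples = 10000,
                                degree = 2, n_interior_knots = 1,
                                seed = NULL) {
  coords <- as.matrix(dataset$plots[, c("x", "y")])
  amp_rows <- list(); part_rows <- list(); coef_rows <- list()
  k <- 0
  for (comp in components) {
    inc <- presence_absence(component_subset(dataset, comp))
    for (ord in orders) {
      k <- k + 1
      des <- build_design(inc, dataset$env, coords, ord,
                          n_samples = n_samples,
                          seed = if (is.null(seed)) NULL else child_seed(seed, k))
      fit <- fit_msgdm(des, degree, n_interior_knots)
      vp <- variation_partition(des, degree, n_interior_knots)
      amp_rows[[k]] <- data.frame(component = comp, order = ord,
                                  predictor = names(fit$amplitudes),
                                  amplitude = as.numeric(fit$amplitudes),
                                  explained_variation = fit$explained_variation,
                                  row.names = NULL)
      part_rows[[k]] <- data.frame(component = comp, order = ord,
                                   pure_distance = vp$pure_distance,
                                   pure_environment = vp$pure_environment,
                                   shared = vp$shared,
                                   unexplained = vp$unexplained,
                                   row.names = NULL)
      coef_rows[[k]] <- data.frame(component = comp, order = ord,
                                   term = names(fit$coefficients),
                                   coefficient = as.numeric(fit$coefficients),
                                   row.names = NULL)
    }
  }
  structure(list(amplitudes = do.call(rbind, amp_rows),
                 partitions = do.call(rbind, part_rows),
                 coefficients = do.call(rbind, coef_rows)),
            class = "msgdm_scan")
}
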