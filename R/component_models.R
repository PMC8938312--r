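## Standardize predictor columns to z-scores; constant columns become 0.
standardize_predictors <- function(env_table, predictors) {
  miss <- setdiff(predictors, names(env_table))
  if (length(miss))
    stop(sprintf("unknown predictor(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  out <- as.data.frame(lapply(env_table[predictors], function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  names(out) <- predictors
  out
}

#' Negative-binomial richness model for one component
#'
#' Models per-plot species richness of a component as a log-linear
#' function of the (z-standardized) environmental predictors with a
#' negative-binomial error, the appropriate family for overdispersed
#' counts. The full linear model with no interactions is fitted and
#' inference is by Wald z tests; fit quality is the deviance pseudo-R2
#' `1 - residual deviance / null deviance` (McFadden's likelihood-ratio
#' variant available via `pseudo_r2 = "mcfadden"`).
#'
#' @param dataset a [survey_dataset].
#' @param component `"all"`, `"native"` or `"alien"`.
#' @param predictors environment columns to use (default all four).
#' @param pseudo_r2 `"deviance"` (default) or `"mcfadden"`.
#' @return List of class `glm_result`: `coefficients` (data.frame:
#'   predictor, estimate, se, z, p), `pseudo_r2`, `theta` (NB dispersion),
#'   `converged`, `family`, `model` (the fitted object), `residuals`
#'   (deviance residuals).
#' @export
fit_richness_glm <- function(dataset, component = c("all", "native", "alien"),
                             predictors = c("organic_matter", "live_basal_area",
                                            "ecec", "ph"),
                             pseudo_r2 = c("deviance", "mcfadden")) {
  component <- match.arg(component)
  pseudo_r2 <- match.arg(pseudo_r2)
  if (nrow(dataset$plots) < 10)
    stop("need at least 10 plots to fit the richness model", call. = FALSE)
  sub <- component_subset(dataset, component)
  dat <- standardize_predictors(dataset$env, predictors)
  dat$richness <- plot_richness(sub)
  fml <- stats::reformulate(predictors, response = "richness")
  converged <- TRUE
  theta_limit <- FALSE
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(fml, data = dat),
             error = function(e) {
               converged <<- FALSE
               stats::glm(fml, data = dat, family = stats::poisson())
             }),
    warning = function(w) {
      if (grepl("iteration limit", conditionMessage(w))) theta_limit <<- TRUE
      else if (grepl("did not converge|theta", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  # theta running to its iteration limit at a huge value is the benign
  # Poisson limit (no overdispersion), not a failed fit
  if (theta_limit && (!inherits(fit, "negbin") || fit$theta < 100))
    converged <- FALSE
  sm <- summary(fit)$coefficients
  rows <- sm[predictors, , drop = FALSE]
  r2 <- if (pseudo_r2 == "deviance") {
    1 - fit$deviance / fit$null.deviance
  } else {
    ll_null <- stats::logLik(stats::update(fit, . ~ 1))
    1 - as.numeric(stats::logLik(fit)) / as.numeric(ll_null)
  }
  structure(list(coefficients = data.frame(predictor = predictors,
                                           estimate = unname(rows[, 1]),
                                           se = unname(rows[, 2]),
                                           z = unname(rows[, 3]),
                                           p = unname(rows[, 4]),
                                           row.names = NULL),
                 pseudo_r2 = r2,
                 theta = if (inherits(fit, "negbin")) fit$theta else Inf,
                 converged = converged,
                 family = "negative binomial (log link)",
                 component = component,
                 model = fit,
                 residuals = stats::residuals(fit, type = "deviance")),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("%s richness model (%s): pseudo-R2 = %.2f, theta = %.2f%s\n",
              x$component, x$family, x$pseudo_r2, x$theta,
              if (x$converged) "" else " [did not converge]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

## Negative-binomial log likelihood at fixed dispersion theta.
nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

## Fit y ~ X (X includes intercept) by NB IRLS at fixed theta; returns the
## maximized log likelihood, or NA on failure. Lean iteratively reweighted
## least squares with a log link, used heavily inside resampling loops.
nb_fit_ll <- function(X, y, theta, max_iter = 50, tol = 1e-9) {
  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  ll <- nb_loglik(y, mu, theta)
  for (it in seq_len(max_iter)) {
    sw <- sqrt(mu / (1 + mu / theta))
    z <- eta + (y - mu) / mu
    fit <- tryCatch(stats::.lm.fit(X * sw, z * sw), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NA_real_)
    eta_new <- (z * sw - fit$residuals) / sw  # fitted working response
    eta_new <- pmin(pmax(eta_new, -30), 30)
    mu <- exp(eta_new)
    ll_new <- nb_loglik(y, mu, theta)
    if (!is.finite(ll_new)) return(NA_real_)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      return(ll_new)
    }
    eta <- eta_new
    ll <- ll_new
  }
  ll
}

#' Multivariate frequency model with a resampling-based community test
#'
#' Fits one negative-binomial GLM of subplot frequency (counts out of
#' `n_subplots`) on the standardized predictors per species, then combines
#' evidence across species: for each predictor the likelihood-ratio
#' statistics from dropping it are summed over species, and significance
#' is assessed by jointly permuting the rows of the response matrix
#' (preserving cross-species correlation) and recomputing the sum.
#' `p = (1 + number of resampled sums >= observed) / (n_resamples + 1)`.
#'
#' Per species the dispersion `theta` is estimated once on the observed
#' full model and held fixed across reduced fits and resamples, so each
#' statistic is a genuine likelihood ratio at that dispersion; species
#' whose model cannot be fitted are dropped from the sum and counted.
#'
#' @param dataset a [survey_dataset].
#' @param component `"all"`, `"native"` or `"alien"`.
#' @param predictors environment columns (default all four).
#' @param n_resamples permutation resamples (default 999).
#' @param min_occupancy species present in fewer plots are excluded
#'   (default 3).
#' @param seed optional integer seed.
#' @param test_predictors optional subset of `predictors` to test
#'   (defaults to all); restricting it saves refits in simulation studies.
#' @return List of class `many_glm_result`: `statistics` (data.frame:
#'   predictor, lr_sum, p), `per_species` (data.frame of per-species
#'   coefficients and LR statistics), `n_species_used`, `n_skipped`,
#'   `n_resamples`, `seed`.
#' @export
fit_many_glm <- function(dataset, component = c("all", "native", "alien"),
                         predictors = c("organic_matter", "live_basal_area",
                                        "ecec", "ph"),
                         n_resamples = 999, min_occupancy = 3, seed = NULL,
                         test_predictors = predictors) {
  component <- match.arg(component)
  stopifnot(all(test_predictors %in% predictors))
  sub <- component_subset(dataset, component)
  occ <- colSums(sub$freq > 0)
  drop_rare <- occ < min_occupancy
  if (any(drop_rare))
    message(sprintf("excluding %d species present in fewer than %d plots",
                    sum(drop_rare), min_occupancy))
  Y <- sub$freq[, !drop_rare, drop = FALSE]
  S <- ncol(Y)
  if (S == 0) stop("no species left after the occupancy filter", call. = FALSE)
  Z <- standardize_predictors(dataset$env, predictors)
  X <- cbind(`(Intercept)` = 1, as.matrix(Z))
  P <- nrow(X)
  drop_idx <- match(test_predictors, predictors) + 1L  # column in X

  ## per-species dispersion from the observed full model
  thetas <- vapply(seq_len(S), function(s) {
    y <- Y[, s]
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ . , data = Z)),
                    error = function(e) NULL)
    if (!is.null(fit)) fit$theta
    else tryCatch({
      pf <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
      as.numeric(suppressWarnings(MASS::theta.ml(y, pf$fitted.values,
                                                 limit = 25)))
    }, error = function(e) NA_real_)
  }, numeric(1))
  thetas[is.finite(thetas)] <- pmin(thetas[is.finite(thetas)], 1e4)

  lr_matrix <- function(Ymat) {
    ## rows = species, cols = tested predictors; NA where a fit failed
    m <- vapply(seq_len(S), function(s) {
      th <- thetas[s]
      if (!is.finite(th)) return(rep(NA_real_, length(drop_idx)))
      ll_full <- nb_fit_ll(X, Ymat[, s], th)
      if (is.na(ll_full)) return(rep(NA_real_, length(drop_idx)))
      vapply(drop_idx, function(j) {
        ll_red <- nb_fit_ll(X[, -j, drop = FALSE], Ymat[, s], th)
        # constrained fit can exceed only by numerical noise; floor at 0
        if (is.na(ll_red)) NA_real_ else max(0, 2 * (ll_full - ll_red))
      }, numeric(1))
    }, numeric(length(drop_idx)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    t(m)
  }

  obs_lr <- lr_matrix(Y)
  used <- stats::complete.cases(obs_lr)
  n_skipped <- sum(!used)
  obs_sum <- colSums(obs_lr[used, , drop = FALSE])

  exceed <- with_seed(seed, {
    acc <- numeric(length(drop_idx))
    for (b in seq_len(n_resamples)) {
      perm <- sample.int(P)
      lr_b <- lr_matrix(Y[perm, , drop = FALSE])
      ok <- stats::complete.cases(lr_b) & used
      sums_b <- colSums(lr_b[ok, , drop = FALSE])
      ## rescale to the observed species count when resample fits fail
      if (any(ok != used) && sum(ok) > 0)
        sums_b <- sums_b * sum(used) / sum(ok)
      acc <- acc + (sums_b >= obs_sum)
    }
    acc
  })
  pvals <- (1 + exceed) / (n_resamples + 1)

  per_species <- data.frame(species_id = rep(colnames(Y)[used],
                                             each = length(test_predictors)),
                            predictor = rep(test_predictors, sum(used)),
                            lr = as.vector(t(obs_lr[used, , drop = FALSE])),
                            row.names = NULL)
  structure(list(statistics = data.frame(predictor = test_predictors,
                                         lr_sum = unname(obs_sum),
                                         p = unname(pvals), row.names = NULL),
                 per_species = per_species,
                 n_species_used = sum(used),
                 n_skipped = n_skipped,
                 n_resamples = n_resamples,
                 component = component,
                 seed = seed),
            class = "many_glm_result")
}

#' @export
print.many_glm_result <- function(x, ...) {
  cat(sprintf("Multivariate frequency model (%s): %d species, %d resamples%s\n",
              x$component, x$n_species_used, x$n_resamples,
              if (x$n_skipped) sprintf(" (%d species skipped)", x$n_skipped) else ""))
  print(x$statistics, digits = 3)
  invisible(x)
}

#' Mantel test of residual spatial autocorrelation
#'
#' Pearson correlation between the distance matrix of model residuals and
#' the spatial distance matrix, with a permutation p-value; a standard
#' check that a plot-level regression has not left spatial structure in
#' its residuals.
#'
#' @param residuals numeric vector of residuals, one per plot (or a
#'   `glm_result`, whose deviance residuals are used).
#' @param coordinates planar plot coordinates (km).
#' @param n_permutations permutations (default 999).
#' @param seed optional integer seed.
#' @return List: `r` (Mantel correlation), `p`, `n_permutations`.
#' @export
mantel_residuals <- function(residuals, coordinates, n_permutations = 999,
                             seed = NULL) {
  if (inherits(residuals, "glm_result")) residuals <- residuals$residuals
  d_res <- stats::dist(residuals)
  d_geo <- stats::dist(as.matrix(coordinates))
  mt <- with_seed(seed, vegan::mantel(d_res, d_geo,
                                      permutations = n_permutations))
  list(r = unname(mt$statistic), p = mt$signif, n_permutations = n_permutations)
}

#' Paired comparison and cross-regression of component richness
#'
#' Paired t-test of native versus alien per-plot richness (df = P - 1) and
#' an ordinary least-squares regression of alien richness on native
#' richness.
#'
#' @param dataset a [survey_dataset].
#' @return List of class `component_richness_test`: `mean_difference`
#'   (native - alien), `t`, `df`, `p`, and `slope`, `slope_t`, `slope_p`,
#'   `r_squared` for the alien ~ native regression.
#' @export
compare_component_richness <- function(dataset) {
  rich_n <- plot_richness(component_subset(dataset, "native"))
  rich_a <- plot_richness(component_subset(dataset, "alien"))
  tt <- stats::t.test(rich_n, rich_a, paired = TRUE)
  if (stats::var(rich_n) > 0) {
    ols <- stats::lm(rich_a ~ rich_n)
    sm <- summary(ols)
    slope <- unname(stats::coef(ols)[2])
    slope_t <- sm$coefficients[2, 3]
    slope_p <- sm$coefficients[2, 4]
    r2 <- sm$r.squared
  } else {
    slope <- slope_t <- slope_p <- r2 <- NA_real_
  }
  structure(list(mean_difference = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 slope = slope, slope_t = slope_t, slope_p = slope_p,
                 r_squared = r2),
            class = "component_richness_test")
}

#' Kolmogorov-Smirnov test of alien versus native occupancy
#'
#' Two-sample KS test comparing the per-species occupancy proportions of
#' the alien and native components.
#'
#' @param dataset a [survey_dataset].
#' @return List: `D`, `p`, `n_alien`, `n_native`.
#' @export
ks_occupancy <- function(dataset) {
  inc <- presence_absence(dataset)
  prop <- colSums(inc) / nrow(inc)
  is_alien <- dataset$species$origin == "alien"
  ks <- suppressWarnings(stats::ks.test(prop[is_alien], prop[!is_alien]))
  list(D = unname(ks$statistic), p = ks$p.value,
       n_alien = sum(is_alien), n_native = sum(!is_alien))
}

#' Contrast a plot-level metric across a soil-pH threshold
#'
#' Splits plots at a pH threshold and compares one of three plot-level
#' summaries between the groups with a Kruskal-Wallis rank test:
#' * `rare_native_richness` - number of rare native species per plot
#'   (rare = occupancy proportion below `rare_cutoff` within the native
#'   component);
#' * `rare_native_relative_frequency` - mean relative subplot frequency of
#'   rare native species per plot (zeros included);
#' * `tolerant_alien_relative_frequency` - mean relative frequency, where
#'   present, of the alien species that occur in at least one low-pH plot
#'   (the most acid-tolerant aliens).
#'
#' @param dataset a [survey_dataset].
#' @param metric which summary to contrast.
#' @param ph_threshold soil pH split point (default 5.5).
#' @param rare_cutoff occupancy proportion defining rarity (default 0.20).
#' @return List of class `threshold_contrast`: `metric`, `mean_below`,
#'   `mean_above`, `n_below`, `n_above`, `statistic` (KW chi-squared),
#'   `p`.
#' @export
threshold_contrast <- function(dataset,
                               metric = c("rare_native_richness",
                                          "rare_native_relative_frequency",
                                          "tolerant_alien_relative_frequency"),
                               ph_threshold = 5.5, rare_cutoff = 0.20) {
  metric <- match.arg(metric)
  below <- dataset$env$ph < ph_threshold
  if (all(below) || !any(below))
    stop(sprintf("all plots fall on one side of pH %.2f; contrast is degenerate",
                 ph_threshold), call. = FALSE)
  relf <- relative_frequency(dataset)
  inc <- presence_absence(dataset)
  is_native <- dataset$species$origin == "native"

  values <- switch(metric,
    rare_native_richness = {
      occ_prop <- colSums(inc) / nrow(inc)
      rare_nat <- is_native & occ_prop < rare_cutoff
      rowSums(inc[, rare_nat, drop = FALSE])
    },
    rare_native_relative_frequency = {
      occ_prop <- colSums(inc) / nrow(inc)
      rare_nat <- is_native & occ_prop < rare_cutoff
      rowMeans(relf[, rare_nat, drop = FALSE])
    },
    tolerant_alien_relative_frequency = {
      tolerant <- !is_native & colSums(inc[below, , drop = FALSE]) > 0
      if (!any(tolerant))
        stop("no alien species occur below the pH threshold", call. = FALSE)
      m <- relf[, tolerant, drop = FALSE]
      pres <- inc[, tolerant, drop = FALSE]
      v <- rowSums(m * pres) / rowSums(pres)
      v  # NaN where no tolerant alien present; dropped below
    })

  keep <- is.finite(values)
  values <- values[keep]
  grp <- factor(ifelse(below[keep], "below", "above"), c("below", "above"))
  if (nlevels(droplevels(grp)) < 2)
    stop("metric is defined on plots from only one pH group", call. = FALSE)
  kw <- stats::kruskal.test(values, grp)
  structure(list(metric = metric,
                 mean_below = mean(values[grp == "below"]),
                 mean_above = mean(values[grp == "above"]),
                 n_below = sum(grp == "below"), n_above = sum(grp == "above"),
                 statistic = unname(kw$statistic), p = kw$p.value),
            class = "threshold_contrast")
}

#' @export
print.threshold_contrast <- function(x, ...) {
  cat(sprintf("%s: mean %.3f below vs %.3f above threshold (n = %d/%d), KW chi2 = %.2f, p = %.3g\n",
              x$metric, x$mean_below, x$mean_above, x$n_below, x$n_above,
              x$statistic, x$p))
  invisible(x)
}
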