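#' Define a synthetic metacommunity scenario
#'
#' Builds the parameter set for [generate_community()]: a plot network in
#' parks, four environmental fields, and per-component niche and dispersal
#' models. Per species-by-plot, the subplot occupancy probability is
#' `p = p_max * (w * niche_term + (1 - w) * dispersal_term)` where the
#' niche term is a product of Gaussian responses to the (standardized)
#' environmental variables and the dispersal term decays exponentially
#' with distance to the nearest seed focus. `w = 1` gives a community
#' assembled purely by environmental sorting, `w = 0` one assembled purely
#' by dispersal limitation.
#'
#' Presets:
#' * `paper_like` - 50 plots in 4 parks over a ~1030 km2 extent, 25
#'   subplots, 178 native and 73 alien species; natives have narrower
#'   niches and shorter dispersal than aliens; balanced mixing (`w = 0.5`).
#' * `environmental_sorting` - as `paper_like` with `w = 1`.
#' * `dispersal_limited` - as `paper_like` with `w = 0`.
#' * `mixed` - alias of `paper_like`.
#' * `homogeneous` - every species occupies every subplot of every plot.
#'
#' @param preset one of `"paper_like"`, `"environmental_sorting"`,
#'   `"dispersal_limited"`, `"mixed"`, `"homogeneous"`.
#' @param ... named overrides of any scenario field (e.g. `n_plots`, `w`,
#'   `native_sigma`, `alien_lambda`).
#' @return List of class `community_scenario`.
#' @export
make_scenario <- function(preset = c("paper_like", "environmental_sorting",
                                     "dispersal_limited", "mixed",
                                     "homogeneous"), ...) {
  preset <- match.arg(preset)
  sc <- list(
    preset = preset,
    n_plots = 50L,
    n_parks = 4L,
    n_subplots = 25L,
    n_native = 178L,
    n_alien = 73L,
    extent_km = 32.1,              # square side; area ~1030 km2
    plot_scatter_km = 2.5,         # sd of plot scatter around park centres
    w = 0.5,
    p_max = 0.7,
    # per-species prevalence: max subplot probability = p_max * Beta draw,
    # right-skewed so most species are locally sparse; natives are locally
    # denser on average, aliens sparser but environmentally broader
    native_prevalence = c(0.8, 2.2),
    alien_prevalence = c(0.6, 3.2),
    # niche breadths (sd units of the standardized env variables)
    native_sigma = c(0.18, 1.5),
    alien_sigma = c(0.45, 2.2),
    # dispersal kernel scales (km) and seed-focus counts
    native_lambda = c(0.5, 6),
    alien_lambda = c(4, 25),
    native_foci = c(1L, 3L),
    alien_foci = c(2L, 5L),
    # each env field = gradient_weight * linear spatial gradient +
    # (1 - gradient_weight) * kernel-smoothed noise, min-max rescaled
    gradient_weight = 0.6,
    noise_range_km = 6,
    env_ranges = list(organic_matter = c(2, 14),
                      live_basal_area = c(8, 40),
                      ecec = c(2, 10),
                      ph = c(4.5, 6.9)),
    homogeneous = FALSE
  )
  sc$w <- switch(preset,
                 environmental_sorting = 1,
                 dispersal_limited = 0,
                 sc$w)
  if (preset == "homogeneous") sc$homogeneous <- TRUE
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown))
    stop(sprintf("unknown scenario field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  sc[names(dots)] <- dots
  if (sc$w < 0 || sc$w > 1) stop("w must lie in [0, 1]", call. = FALSE)
  if (sc$p_max < 0 || sc$p_max > 1) stop("p_max must lie in [0, 1]", call. = FALSE)
  class(sc) <- "community_scenario"
  sc
}

## Kernel-smoothed white noise over plot locations: Gaussian kernel of
## width `range_km`, giving spatially autocorrelated variation without
## full Gaussian-process machinery.
smooth_noise <- function(coords, range_km) {
  g <- stats::rnorm(nrow(coords))
  K <- exp(-as.matrix(stats::dist(coords))^2 / (2 * range_km^2))
  as.numeric(K %*% g / rowSums(K))
}

rescale_range <- function(v, range) {
  if (diff(range(v)) == 0) return(rep(mean(range), length(v)))
  range[1] + (v - min(v)) / diff(range(v)) * diff(range)
}

#' Generate a synthetic survey dataset from a scenario
#'
#' Draws the plot network, environmental fields and species parameters,
#' computes the per-species-by-plot subplot occupancy probability (see
#' [make_scenario()]) and samples frequencies as
#' `Binomial(n_subplots, p)`. A species left unobserved everywhere is
#' given a single occurrence at its most suitable plot, so every generated
#' species is recorded at least once. Deterministic given `seed`.
#'
#' @param scenario a [make_scenario()] result.
#' @param seed integer master seed; stage-specific child seeds are derived
#'   from it.
#' @return List of class `community_realization`: `dataset` (a
#'   [survey_dataset]), `truth` (data.frame of per-species generative
#'   parameters: niche optima, breadth, kernel scale, focus count),
#'   `scenario`, `seed`.
#' @export
generate_community <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "community_scenario"))
  sc <- scenario
  L <- sc$extent_km
  P <- sc$n_plots
  S_nat <- sc$n_native
  S_ali <- sc$n_alien
  S <- S_nat + S_ali

  ## plot network: park centres on jittered quadrants, plots scattered
  coords_park <- with_seed(child_seed(seed, 1), {
    base <- if (sc$n_parks == 4L) {
      cbind(c(0.25, 0.75, 0.25, 0.75) * L, c(0.25, 0.25, 0.75, 0.75) * L)
    } else {
      cbind(stats::runif(sc$n_parks, 0.2 * L, 0.8 * L),
            stats::runif(sc$n_parks, 0.2 * L, 0.8 * L))
    }
    centres <- base + matrix(stats::rnorm(2 * sc$n_parks, 0, L / 25),
                             ncol = 2)
    park <- rep_len(seq_len(sc$n_parks), P)
    xy <- centres[park, , drop = FALSE] +
      matrix(stats::rnorm(2 * P, 0, sc$plot_scatter_km), ncol = 2)
    list(xy = pmin(pmax(xy, 0), L), park = park)
  })
  plots <- data.frame(plot_id = sprintf("p%02d", seq_len(P)),
                      x = coords_park$xy[, 1], y = coords_park$xy[, 2],
                      park = sprintf("park%d", coords_park$park))
  coords <- as.matrix(plots[, c("x", "y")])

  ## environmental fields: gradient along a random direction + smooth noise
  env <- with_seed(child_seed(seed, 2), {
    out <- lapply(sc$env_ranges, function(rg) {
      theta <- stats::runif(1, 0, 2 * pi)
      grad <- coords %*% c(cos(theta), sin(theta))
      noise <- smooth_noise(coords, sc$noise_range_km)
      zg <- as.numeric(scale(grad))
      zn <- if (stats::sd(noise) > 0) as.numeric(scale(noise)) else noise
      rescale_range(sc$gradient_weight * zg + (1 - sc$gradient_weight) * zn, rg)
    })
    as.data.frame(out)
  })

  ## species parameters; natives narrower-niche and shorter-dispersal
  env_z <- scale(as.matrix(env))
  truth <- with_seed(child_seed(seed, 3), {
    origin <- c(rep("native", S_nat), rep("alien", S_ali))
    nat <- origin == "native"
    sigma <- stats::runif(S,
                          ifelse(nat, sc$native_sigma[1], sc$alien_sigma[1]),
                          ifelse(nat, sc$native_sigma[2], sc$alien_sigma[2]))
    lambda <- stats::runif(S,
                           ifelse(nat, sc$native_lambda[1], sc$alien_lambda[1]),
                           ifelse(nat, sc$native_lambda[2], sc$alien_lambda[2]))
    n_foci <- vapply(seq_len(S), function(s) {
      r <- if (nat[s]) sc$native_foci else sc$alien_foci
      sample(seq(r[1], r[2]), 1)
    }, numeric(1))
    q_max <- sc$p_max *
      stats::rbeta(S, ifelse(nat, sc$native_prevalence[1], sc$alien_prevalence[1]),
                   ifelse(nat, sc$native_prevalence[2], sc$alien_prevalence[2]))
    mu <- matrix(stats::runif(S * ncol(env_z),
                              min = rep(apply(env_z, 2, min), each = S),
                              max = rep(apply(env_z, 2, max), each = S)),
                 nrow = S)
    colnames(mu) <- paste0("mu_", colnames(env))
    foci <- lapply(seq_len(S), function(s) sample.int(P, n_foci[s]))
    life <- ifelse(origin == "alien",
                   ifelse(stats::runif(S) < 0.79, "annual", "perennial"),
                   ifelse(stats::runif(S) < 0.82, "perennial", "annual"))
    list(df = data.frame(species_id = sprintf("s%03d", seq_len(S)),
                         origin = origin, life_history = life,
                         q_max = q_max, sigma = sigma, lambda = lambda,
                         n_foci = n_foci, mu, row.names = NULL),
         foci = foci)
  })

  ## occupancy probability and frequencies
  dmat <- as.matrix(stats::dist(coords))
  freq <- with_seed(child_seed(seed, 4), {
    pm <- vapply(seq_len(S), function(s) {
      if (sc$homogeneous) return(rep(1, P))
      niche <- exp(-rowSums(sweep(env_z, 2,
                                  as.numeric(truth$df[s, grep("^mu_", names(truth$df))]))^2 /
                            (2 * truth$df$sigma[s]^2)))
      d_focus <- apply(dmat[, truth$foci[[s]], drop = FALSE], 1, min)
      disp <- exp(-d_focus / truth$df$lambda[s])
      truth$df$q_max[s] * (sc$w * niche + (1 - sc$w) * disp)
    }, numeric(P))
    f <- matrix(stats::rbinom(P * S, sc$n_subplots, pm), nrow = P)
    # guarantee every species is observed at least once
    for (s in which(colSums(f) == 0)) f[which.max(pm[, s]), s] <- 1
    f
  })

  species <- truth$df[, c("species_id", "origin", "life_history")]
  dataset <- survey_dataset(plots, species, freq, env,
                            n_subplots = sc$n_subplots)
  structure(list(dataset = dataset, truth = truth$df,
                 scenario = sc, seed = seed),
            class = "community_realization")
}

#' @export
print.community_realization <- function(x, ...) {
  cat(sprintf("Synthetic community (%s preset, seed %d):\n",
              x$scenario$preset, x$seed))
  print(x$dataset)
  invisible(x)
}

#' Simulate and write a synthetic survey to disk
#'
#' Convenience wrapper: generates a community and writes the four survey
#' CSVs plus `ground_truth.csv` and the resolved scenario as
#' `scenario.yml`.
#'
#' @param dir output directory.
#' @param preset scenario preset (see [make_scenario()]).
#' @param seed integer master seed.
#' @param ... scenario overrides passed to [make_scenario()].
#' @return Invisibly, the [generate_community()] result.
#' @export
simulate_survey <- function(dir, preset = "paper_like", seed = 1L, ...) {
  real <- generate_community(make_scenario(preset, ...), seed = seed)
  write_survey(real$dataset, dir)
  utils::write.csv(real$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  sc <- unclass(real$scenario)
  yaml::write_yaml(sc, file.path(dir, "scenario.yml"))
  invisible(real)
}
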