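#' Construct and validate a survey dataset
#'
#' Bundles the four tables produced by a frequency-in-subplots vegetation
#' survey: a plot table (planar coordinates in km plus a park label), a
#' species table (origin, optional life history), a plots-by-species matrix
#' of subplot occupancy counts, and a plot-level environment table.
#'
#' @param plot_table data.frame with columns `plot_id`, `x`, `y`, `park`.
#' @param species_table data.frame with columns `species_id`, `origin`
#'   (one of `"alien"`, `"native"`) and optionally `life_history`.
#' @param frequency_matrix integer matrix, plots in rows and species in
#'   columns, each entry the number of subplots (0..`n_subplots`) occupied.
#' @param env_table data.frame with one row per plot and columns
#'   `organic_matter` (percent), `live_basal_area` (m2/ha), `ecec`
#'   (cmol/kg) and `ph`.
#' @param n_subplots number of subplots per plot (default 25).
#'
#' @details Species never observed (all-zero columns) are dropped with a
#'   warning; remaining frequencies must lie in `[0, n_subplots]` and the
#'   three plot-indexed tables must share one plot ordering.
#'
#' @return An object of class `survey_dataset`: a list with elements
#'   `plots`, `species`, `freq`, `env`, `n_subplots`.
#' @export
survey_dataset <- function(plot_table, species_table, frequency_matrix,
                           env_table, n_subplots = 25) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(plot_table, c("plot_id", "x", "y", "park"), "plot table")
  need(species_table, c("species_id", "origin"), "species table")
  need(env_table, c("organic_matter", "live_basal_area", "ecec", "ph"),
       "environment table")

  plot_table$plot_id <- as.character(plot_table$plot_id)
  species_table$species_id <- as.character(species_table$species_id)
  if (anyDuplicated(plot_table$plot_id))
    stop("duplicated plot_id in plot table", call. = FALSE)
  if (anyDuplicated(species_table$species_id))
    stop("duplicated species_id in species table", call. = FALSE)
  if (!all(species_table$origin %in% c("alien", "native")))
    stop("species table: origin must be 'alien' or 'native'", call. = FALSE)

  freq <- as.matrix(frequency_matrix)
  storage.mode(freq) <- "double"
  P <- nrow(plot_table)
  if (nrow(freq) != P)
    stop(sprintf("frequency matrix has %d rows but plot table has %d plots",
                 nrow(freq), P), call. = FALSE)
  if (nrow(env_table) != P)
    stop(sprintf("environment table has %d rows but plot table has %d plots",
                 nrow(env_table), P), call. = FALSE)
  if (ncol(freq) != nrow(species_table))
    stop(sprintf("frequency matrix has %d columns but species table has %d species",
                 ncol(freq), nrow(species_table)), call. = FALSE)
  if (anyNA(freq) || any(freq < 0) || any(freq > n_subplots) ||
      any(freq != round(freq))) {
    bad <- which(is.na(freq) | freq < 0 | freq > n_subplots, arr.ind = TRUE)
    where <- if (nrow(bad)) sprintf(" (first offence at plot row %d, species column %d)",
                                    bad[1, 1], bad[1, 2]) else ""
    stop(sprintf("frequencies must be integers in [0, %d]%s", n_subplots, where),
         call. = FALSE)
  }
  if (!all(is.finite(plot_table$x)) || !all(is.finite(plot_table$y)))
    stop("plot coordinates must be finite", call. = FALSE)

  rownames(freq) <- plot_table$plot_id
  colnames(freq) <- species_table$species_id

  empty <- colSums(freq) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d species never observed: %s", sum(empty),
                    paste(utils::head(species_table$species_id[empty], 5),
                          collapse = ", ")), call. = FALSE)
    freq <- freq[, !empty, drop = FALSE]
    species_table <- species_table[!empty, , drop = FALSE]
  }

  structure(list(plots = plot_table,
                 species = species_table,
                 freq = freq,
                 env = env_table[, c("organic_matter", "live_basal_area",
                                     "ecec", "ph")],
                 n_subplots = n_subplots),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Survey dataset: %d plots (%d parks), %d species (%d native, %d alien), %d subplots/plot\n",
              nrow(x$plots), length(unique(x$plots$park)), nrow(x$species),
              sum(x$species$origin == "native"), sum(x$species$origin == "alien"),
              x$n_subplots))
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' The frequency table may be wide (first column `plot_id`, one column per
#' species) or long (columns `plot_id`, `species_id`, `frequency`; absent
#' pairs are zero). The environment CSV may carry a `plot_id` column, used
#' to align rows with the plot table.
#'
#' @param frequency_path,plots_path,species_path,env_path paths to CSV
#'   files with header rows.
#' @inheritParams survey_dataset
#' @return A [survey_dataset].
#' @export
load_survey <- function(frequency_path, plots_path, species_path, env_path,
                        n_subplots = 25) {
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
  }
  plots <- rd(plots_path)
  species <- rd(species_path)
  env <- rd(env_path)
  fq <- rd(frequency_path)

  plots$plot_id <- as.character(plots$plot_id)
  species$species_id <- as.character(species$species_id)

  if (all(c("plot_id", "species_id", "frequency") %in% names(fq))) {
    fq$plot_id <- as.character(fq$plot_id)
    fq$species_id <- as.character(fq$species_id)
    bad_p <- setdiff(fq$plot_id, plots$plot_id)
    if (length(bad_p))
      stop(sprintf("%s: unknown plot_id '%s'", frequency_path, bad_p[1]),
           call. = FALSE)
    bad_s <- setdiff(fq$species_id, species$species_id)
    if (length(bad_s))
      stop(sprintf("%s: unknown species_id '%s'", frequency_path, bad_s[1]),
           call. = FALSE)
    freq <- matrix(0, nrow(plots), nrow(species),
                   dimnames = list(plots$plot_id, species$species_id))
    freq[cbind(match(fq$plot_id, plots$plot_id),
               match(fq$species_id, species$species_id))] <- fq$frequency
  } else {
    if (!"plot_id" %in% names(fq))
      stop(sprintf("%s: wide frequency table needs a plot_id column",
                   frequency_path), call. = FALSE)
    fq$plot_id <- as.character(fq$plot_id)
    if (!setequal(fq$plot_id, plots$plot_id))
      stop(sprintf("%s: plot_id set does not match the plot table",
                   frequency_path), call. = FALSE)
    fq <- fq[match(plots$plot_id, fq$plot_id), , drop = FALSE]
    sp_cols <- setdiff(names(fq), "plot_id")
    bad_s <- setdiff(sp_cols, species$species_id)
    if (length(bad_s))
      stop(sprintf("%s: unknown species column '%s'", frequency_path, bad_s[1]),
           call. = FALSE)
    freq <- matrix(0, nrow(plots), nrow(species),
                   dimnames = list(plots$plot_id, species$species_id))
    freq[, sp_cols] <- as.matrix(fq[, sp_cols, drop = FALSE])
  }

  if ("plot_id" %in% names(env)) {
    env$plot_id <- as.character(env$plot_id)
    if (!setequal(env$plot_id, plots$plot_id))
      stop(sprintf("%s: plot_id set does not match the plot table", env_path),
           call. = FALSE)
    env <- env[match(plots$plot_id, env$plot_id), , drop = FALSE]
  }

  survey_dataset(plots, species, freq, env, n_subplots = n_subplots)
}

#' Write a survey dataset to CSV files
#'
#' Writes `plots.csv`, `species.csv`, `frequency.csv` (wide) and `env.csv`
#' into `dir`, the same dialect [load_survey()] reads back.
#'
#' @param dataset a [survey_dataset].
#' @param dir output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("plots.csv", "species.csv", "frequency.csv", "env.csv"))
  utils::write.csv(dataset$plots, paths[1], row.names = FALSE)
  utils::write.csv(dataset$species, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(plot_id = rownames(dataset$freq),
                              dataset$freq, check.names = FALSE),
                   paths[3], row.names = FALSE)
  utils::write.csv(cbind(plot_id = dataset$plots$plot_id, dataset$env),
                   paths[4], row.names = FALSE)
  invisible(paths)
}

#' Restrict a dataset to one origin component
#'
#' @param dataset a [survey_dataset].
#' @param component `"all"`, `"native"` or `"alien"`.
#' @return A [survey_dataset] containing only the selected species; plots
#'   are kept even when the component is absent from them.
#' @export
component_subset <- function(dataset, component = c("all", "native", "alien")) {
  component <- match.arg(component)
  if (component == "all") return(dataset)
  keep <- dataset$species$origin == component
  out <- dataset
  out$species <- dataset$species[keep, , drop = FALSE]
  out$freq <- dataset$freq[, keep, drop = FALSE]
  out
}

#' Presence/absence transform
#'
#' @param x a [survey_dataset] or a non-negative frequency matrix.
#' @return A binary incidence matrix (plots x species); an entry is 1
#'   exactly when the frequency is positive. Idempotent.
#' @export
presence_absence <- function(x) {
  m <- if (inherits(x, "survey_dataset")) x$freq else as.matrix(x)
  if (anyNA(m) || any(m < 0)) stop("frequencies must be non-negative", call. = FALSE)
  out <- (m > 0) * 1
  dimnames(out) <- dimnames(m)
  out
}

#' Relative subplot frequency
#'
#' @param dataset a [survey_dataset].
#' @return Matrix of `frequency / n_subplots`, values in `[0, 1]`.
#' @export
relative_frequency <- function(dataset) {
  dataset$freq / dataset$n_subplots
}

#' Per-species occupancy
#'
#' @param incidence binary incidence matrix (plots x species).
#' @return data.frame with `species_id`, `n_plots` (column sums) and
#'   `proportion` (`n_plots / P`).
#' @export
occupancy_profile <- function(incidence) {
  counts <- colSums(incidence)
  data.frame(species_id = colnames(incidence) %||% as.character(seq_along(counts)),
             n_plots = unname(counts),
             proportion = unname(counts) / nrow(incidence),
             row.names = NULL)
}

#' Per-plot richness of a dataset or incidence matrix
#'
#' @param x a [survey_dataset] or binary incidence matrix.
#' @return Integer vector of species counts per plot.
#' @export
plot_richness <- function(x) {
  rowSums(presence_absence(x) > 0)
}

#' Extent of occurrence (convex-hull area) per species
#'
#' The range of each species is summarised as the area of the minimum
#' bounding (convex) polygon around the plots where it occurs. Species seen
#' in fewer than `min_plots` plots, or whose occupied plots are collinear,
#' get area 0 and are flagged `excluded`.
#'
#' @param incidence binary incidence matrix (plots x species).
#' @param coordinates two-column matrix of planar plot coordinates (km),
#'   rows aligned with `incidence`.
#' @param min_plots minimum number of occupied plots (default 3).
#' @return data.frame with `species_id`, `n_plots`, `area_km2`, `excluded`.
#' @export
extent_of_occurrence <- function(incidence, coordinates, min_plots = 3) {
  coordinates <- as.matrix(coordinates)
  if (!all(is.finite(coordinates))) stop("coordinates must be finite", call. = FALSE)
  stopifnot(nrow(coordinates) == nrow(incidence))
  res <- lapply(seq_len(ncol(incidence)), function(s) {
    occ <- incidence[, s] > 0
    a <- if (sum(occ) >= min_plots) hull_area(coordinates[occ, , drop = FALSE]) else 0
    c(n = sum(occ), area = a)
  })
  res <- do.call(rbind, res)
  data.frame(species_id = colnames(incidence) %||% as.character(seq_len(ncol(incidence))),
             n_plots = res[, "n"],
             area_km2 = res[, "area"],
             excluded = res[, "n"] < min_plots | res[, "area"] <= 0,
             row.names = NULL)
}

#' Chao2 incidence-based richness estimate
#'
#' Extrapolates total richness from the counts of species seen in exactly
#' one (`Q1`) and exactly two (`Q2`) plots. The default is the
#' bias-corrected form, defined for `Q2 = 0`:
#' `S_obs + ((m-1)/m) * Q1*(Q1-1) / (2*(Q2+1))`; the classical form
#' `S_obs + ((m-1)/m) * Q1^2 / (2*Q2)` is available via
#' `bias_corrected = FALSE`.
#'
#' @param incidence binary incidence matrix with at least 2 plots.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return A list of class `chao2_estimate`: `s_obs`, `q1`, `q2`, `m`,
#'   `estimate`, `completeness` (`s_obs / estimate`).
#' @export
chao2 <- function(incidence, bias_corrected = TRUE) {
  m <- nrow(incidence)
  if (m < 2) stop("Chao2 needs at least 2 plots", call. = FALSE)
  occ <- colSums(incidence > 0)
  occ <- occ[occ > 0]
  s_obs <- length(occ)
  q1 <- sum(occ == 1)
  q2 <- sum(occ == 2)
  est <- if (bias_corrected) {
    s_obs + (m - 1) / m * q1 * (q1 - 1) / (2 * (q2 + 1))
  } else if (q2 > 0) {
    s_obs + (m - 1) / m * q1^2 / (2 * q2)
  } else {
    s_obs + (m - 1) / m * q1 * (q1 - 1) / 2  # classical fallback when Q2 = 0
  }
  structure(list(s_obs = s_obs, q1 = q1, q2 = q2, m = m,
                 estimate = est, completeness = s_obs / est),
            class = "chao2_estimate")
}

#' @export
print.chao2_estimate <- function(x, ...) {
  cat(sprintf("Chao2: S_obs = %d, Q1 = %d, Q2 = %d over %d plots -> estimate %.1f (%.0f%% complete)\n",
              x$s_obs, x$q1, x$q2, x$m, x$estimate, 100 * x$completeness))
  invisible(x)
}

#' Sample-based rarefaction curve
#'
#' Accumulates species richness over plots, either in fully random order
#' (`mode = "random"`) or spatially constrained (`mode = "spatial"`): each
#' permutation draws a random starting plot, then adds the remaining plots
#' in order of increasing distance from that start (distance ties broken by
#' plot order). The band is the 2.5/97.5 percentile of the permutation
#' distribution.
#'
#' @param incidence binary incidence matrix (plots x species).
#' @param coordinates planar coordinates (km), required for spatial mode.
#' @param mode `"random"` or `"spatial"`.
#' @param n_permutations number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return data.frame of class `rarefaction_curve` with columns `k`,
#'   `mean_richness`, `lower`, `upper`; attributes `mode`,
#'   `n_permutations`, `seed`.
#' @export
rarefaction <- function(incidence, coordinates = NULL,
                        mode = c("random", "spatial"),
                        n_permutations = 1000, seed = NULL) {
  mode <- match.arg(mode)
  P <- nrow(incidence)
  if (mode == "spatial") {
    if (is.null(coordinates)) stop("spatial mode needs coordinates", call. = FALSE)
    dmat <- as.matrix(stats::dist(as.matrix(coordinates)))
  }
  acc <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      ord <- if (mode == "random") {
        sample.int(P)
      } else {
        start <- sample.int(P, 1)
        c(start, setdiff(order(dmat[start, ]), start))
      }
      seen <- apply(incidence[ord, , drop = FALSE] > 0, 2, cummax)
      rowSums(seen)
    }, numeric(P))
  })
  out <- data.frame(k = seq_len(P),
                    mean_richness = rowMeans(acc),
                    lower = apply(acc, 1, stats::quantile, probs = 0.025),
                    upper = apply(acc, 1, stats::quantile, probs = 0.975),
                    row.names = NULL)
  attr(out, "mode") <- mode
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}
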