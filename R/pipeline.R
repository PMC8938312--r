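#' Assemble a full-analysis run configuration
#'
#' @param input either a directory containing the four survey CSVs
#'   (`plots.csv`, `species.csv`, `frequency.csv`, `env.csv`) or `NULL` to
#'   simulate from `preset`.
#' @param preset scenario preset used when `input` is `NULL`.
#' @param components origin components to analyse.
#' @param zeta_orders orders for the decline curves.
#' @param zeta_replicates Monte-Carlo replicates per order (default 1000;
#'   raise to 10000 for survey-scale runs).
#' @param msgdm_orders orders for the dissimilarity models.
#' @param msgdm_samples combinations per dissimilarity design.
#' @param glm_resamples resamples for the multivariate frequency test.
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = "paper_like",
                       components = c("native", "alien"),
                       zeta_orders = 2:50, zeta_replicates = 1000,
                       msgdm_orders = 2:10, msgdm_samples = 2000,
                       glm_resamples = 199, seed = 1L) {
  structure(list(input = input, preset = preset, components = components,
                 zeta_orders = zeta_orders, zeta_replicates = zeta_replicates,
                 msgdm_orders = msgdm_orders, msgdm_samples = msgdm_samples,
                 glm_resamples = glm_resamples, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full turnover analysis
#'
#' Executes the analysis sequence on one dataset: incidence descriptors
#' (richness, occupancy, extent of occurrence, Chao2, rarefaction), zeta
#' declines (raw and Simpson x ALL and NN schemes) with decline-form fits,
#' multi-site dissimilarity models with variation partitions, richness and
#' multivariate frequency regressions with auxiliary contrasts, plus a
#' JSON manifest recording seeds and file checksums. Any stage failure
#' aborts with the stage name; tables already written are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dataset <- stage("data", {
    if (is.null(config$input)) {
      generate_community(make_scenario(config$preset),
                         seed = child_seed(config$seed, 1))$dataset
    } else {
      load_survey(file.path(config$input, "frequency.csv"),
                  file.path(config$input, "plots.csv"),
                  file.path(config$input, "species.csv"),
                  file.path(config$input, "env.csv"))
    }
  })
  coords <- as.matrix(dataset$plots[, c("x", "y")])
  comps <- config$components

  stage("describe", {
    rich <- do.call(rbind, lapply(c("all", comps), function(cc)
      data.frame(component = cc, plot_id = dataset$plots$plot_id,
                 richness = plot_richness(component_subset(dataset, cc)))))
    emit(rich, "richness.csv")

    occ <- do.call(rbind, lapply(comps, function(cc)
      cbind(component = cc,
            occupancy_profile(presence_absence(component_subset(dataset, cc))))))
    emit(occ, "occupancy.csv")

    eoo <- do.call(rbind, lapply(comps, function(cc)
      cbind(component = cc,
            extent_of_occurrence(presence_absence(component_subset(dataset, cc)),
                                 coords))))
    emit(eoo, "eoo.csv")

    ch <- do.call(rbind, lapply(comps, function(cc) {
      est <- chao2(presence_absence(component_subset(dataset, cc)))
      data.frame(component = cc, s_obs = est$s_obs, q1 = est$q1, q2 = est$q2,
                 estimate = est$estimate, completeness = est$completeness)
    }))
    emit(ch, "chao2.csv")

    rar <- do.call(rbind, lapply(comps, function(cc) {
      inc <- presence_absence(component_subset(dataset, cc))
      do.call(rbind, lapply(c("random", "spatial"), function(md)
        cbind(component = cc, mode = md,
              as.data.frame(rarefaction(inc, coords, mode = md,
                                        n_permutations = 1000,
                                        seed = child_seed(config$seed, 2))))))
    }))
    emit(rar, "rarefaction.csv")
  })

  stage("zeta", {
    dec_rows <- list(); fit_rows <- list(); k <- 0
    for (cc in comps) {
      inc <- presence_absence(component_subset(dataset, cc))
      for (sch in c("ALL", "NN")) for (nrm in c("raw", "simpson")) {
        k <- k + 1
        dec <- zeta_decline(inc, orders = config$zeta_orders, scheme = sch,
                            normalization = nrm, coordinates = coords,
                            n_replicates = config$zeta_replicates,
                            seed = child_seed(config$seed, 10 + k))
        dec_rows[[k]] <- cbind(component = cc, scheme = sch,
                               normalization = nrm, as.data.frame(dec))
        if (all(dec$zeta > 0) && nrow(dec) >= 3) {
          f <- fit_zeta_decline(dec)
          fit_rows[[k]] <- data.frame(component = cc, scheme = sch,
                                      normalization = nrm,
                                      exponent = f$exponent,
                                      exponent_lo = f$exponent_ci[1],
                                      exponent_hi = f$exponent_ci[2],
                                      rate = f$rate,
                                      aic_power = f$aic_power,
                                      aic_exp = f$aic_exp,
                                      delta_aic = f$delta_aic, best = f$best)
        }
      }
    }
    emit(do.call(rbind, dec_rows), "zeta_decline.csv")
    emit(do.call(rbind, fit_rows), "zeta_decline_fits.csv")
  })

  stage("msgdm", {
    scan <- msgdm_across_orders(dataset, components = comps,
                                orders = config$msgdm_orders,
                                n_samples = config$msgdm_samples,
                                seed = child_seed(config$seed, 30))
    emit(scan$amplitudes, "msgdm_amplitudes.csv")
    emit(scan$partitions, "msgdm_partitions.csv")
    emit(scan$coefficients, "msgdm_coefficients.csv")
  })

  stage("glm", {
    grows <- list(); mrows <- list()
    for (cc in comps) {
      g <- fit_richness_glm(dataset, cc)
      mant <- mantel_residuals(g, coords, n_permutations = 999,
                               seed = child_seed(config$seed, 40))
      grows[[cc]] <- cbind(component = cc, g$coefficients,
                           pseudo_r2 = g$pseudo_r2, theta = g$theta,
                           converged = g$converged,
                           mantel_r = mant$r, mantel_p = mant$p)
      mg <- suppressMessages(
        fit_many_glm(dataset, cc, n_resamples = config$glm_resamples,
                     seed = child_seed(config$seed, 41)))
      mrows[[cc]] <- cbind(component = cc, mg$statistics,
                           n_species = mg$n_species_used)
    }
    emit(do.call(rbind, grows), "glm_richness.csv")
    emit(do.call(rbind, mrows), "glm_frequency.csv")

    cmp <- compare_component_richness(dataset)
    ks <- ks_occupancy(dataset)
    contrasts <- lapply(c("rare_native_richness",
                          "rare_native_relative_frequency",
                          "tolerant_alien_relative_frequency"),
                        function(m) tryCatch(threshold_contrast(dataset, m),
                                             error = function(e) NULL))
    crows <- data.frame(
      test = c("paired_richness_t", "richness_mean_difference",
               "alien_on_native_slope", "alien_on_native_r2",
               "ks_occupancy_D", "ks_occupancy_p"),
      value = c(cmp$t, cmp$mean_difference, cmp$slope, cmp$r_squared,
                ks$D, ks$p))
    for (tc in contrasts) if (!is.null(tc))
      crows <- rbind(crows,
                     data.frame(test = paste0(tc$metric, c("_below", "_above", "_p")),
                                value = c(tc$mean_below, tc$mean_above, tc$p)))
    emit(crows, "component_tests.csv")
  })

  manifest <- list(
    package = "zetaturn",
    version = as.character(utils::packageVersion("zetaturn")),
    seed = config$seed,
    config = unclass(config),
    n_plots = nrow(dataset$plots),
    n_species = nrow(dataset$species),
    tables = lapply(stats::setNames(files, basename(files)),
                    function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
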