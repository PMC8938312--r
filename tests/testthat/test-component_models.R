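test_that("richness model reports NB coefficients, Wald tests and pseudo-R2", {
  real <- generate_community(make_scenario("environmental_sorting"), seed = 14)
  g <- fit_richness_glm(real$dataset, "alien")
  expect_s3_class(g, "glm_result")
  expect_equal(g$coefficients$predictor,
               c("organic_matter", "live_basal_area", "ecec", "ph"))
  expect_true(all(g$coefficients$p >= 0 & g$coefficients$p <= 1))
  expect_true(g$pseudo_r2 >= 0 && g$pseudo_r2 <= 1)
  expect_true(is.finite(g$theta))

  expect_error(fit_richness_glm(toy_dataset(matrix(1:6, 3, 2)), "all"),
               "at least 10 plots")
})

test_that("null predictors give near-zero pseudo-R2", {
  r2s <- vapply(1:30, function(s) {
    d <- null_frequency_dataset(600 + s, P = 200, S = 25)
    fit_richness_glm(d, "all")$pseudo_r2
  }, numeric(1))
  expect_lt(median(r2s), 0.05)
})

test_that("NB fit approaches Poisson when counts are equidispersed", {
  set.seed(77)
  P <- 200
  env <- data.frame(organic_matter = rnorm(P), live_basal_area = rnorm(P),
                    ecec = rnorm(P), ph = rnorm(P))
  eta <- 2.5 + 0.3 * env$ph - 0.2 * env$ecec
  y <- rpois(P, exp(eta))
  pois <- glm(y ~ ., data = env, family = poisson())
  suppressWarnings(nb <- MASS::glm.nb(y ~ ., data = env))
  expect_gt(nb$theta, 100)  # huge dispersion parameter = Poisson limit
  expect_equal(unname(coef(nb)), unname(coef(pois)), tolerance = 0.01)
})

test_that("multivariate statistic is the sum of per-species likelihood ratios", {
  d <- null_frequency_dataset(5, P = 40, S = 6)
  m <- suppressMessages(fit_many_glm(d, "all", n_resamples = 19, seed = 1))
  for (pred in m$statistics$predictor) {
    per <- m$per_species$lr[m$per_species$predictor == pred]
    expect_equal(sum(per), m$statistics$lr_sum[m$statistics$predictor == pred],
                 tolerance = 1e-6)
  }
  expect_true(all(m$statistics$p > 0 & m$statistics$p <= 1))
  expect_gte(min(m$statistics$p), 1 / 20)

  # single-species community: the sum is that species' LR
  d1 <- d
  keep <- 1
  d1$species <- d$species[keep, , drop = FALSE]
  d1$freq <- d$freq[, keep, drop = FALSE]
  m1 <- suppressMessages(fit_many_glm(d1, "all", n_resamples = 19, seed = 1))
  expect_equal(m1$n_species_used, 1)
  expect_equal(m1$statistics$lr_sum, m1$per_species$lr, tolerance = 1e-6)
})

test_that("manyGLM p-values are invariant to species column order", {
  d <- null_frequency_dataset(6, P = 40, S = 8)
  m1 <- suppressMessages(fit_many_glm(d, "all", n_resamples = 49, seed = 3))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  d2 <- d
  d2$species <- d$species[perm, , drop = FALSE]
  d2$freq <- d$freq[, perm, drop = FALSE]
  m2 <- suppressMessages(fit_many_glm(d2, "all", n_resamples = 49, seed = 3))
  expect_equal(m1$statistics$p, m2$statistics$p)
  expect_equal(m1$statistics$lr_sum, m2$statistics$lr_sum, tolerance = 1e-8)
})

test_that("a strong simulated pH effect is detected with small p", {
  set.seed(91)
  P <- 50; S <- 20
  env <- data.frame(organic_matter = runif(P, 2, 14),
                    live_basal_area = runif(P, 8, 40),
                    ecec = runif(P, 2, 10), ph = runif(P, 4.5, 6.9))
  zph <- scale(env$ph)[, 1]
  f <- sapply(seq_len(S), function(s) {
    beta <- if (s <= S / 2) 1.0 else 0
    pmin(rnbinom(P, mu = exp(1 + beta * zph), size = 2), 25)
  })
  f[1, colSums(f) == 0] <- 1
  d <- survey_dataset(
    data.frame(plot_id = seq_len(P), x = runif(P), y = runif(P), park = "a"),
    data.frame(species_id = sprintf("s%02d", seq_len(S)),
               origin = rep(c("native", "alien"), length.out = S)),
    f, env)
  m <- suppressMessages(fit_many_glm(d, "all", n_resamples = 199, seed = 2,
                                     test_predictors = "ph"))
  expect_lte(m$statistics$p, 0.005)
})

test_that("Mantel residual check flags spatial structure and passes iid noise", {
  set.seed(17)
  coords <- cbind(runif(40, 0, 30), runif(40, 0, 30))
  # residuals equal to the x coordinate: perfect distance correlation
  m1 <- mantel_residuals(coords[, 1], coords, n_permutations = 199, seed = 1)
  expect_gt(m1$r, 0.6)
  expect_lte(m1$p, 0.01)
  expect_true(abs(m1$r) <= 1)

  # iid residuals: p well away from 0 on average
  ps <- vapply(1:10, function(s)
    mantel_residuals(rnorm(40), coords, n_permutations = 99, seed = s)$p,
    numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_gte(min(ps), 1 / 100)
})

test_that("paired richness comparison and cross-regression are exact on constructions", {
  # identical components: zero difference, unit slope
  freq <- cbind(matrix(c(3, 5, 7, 9, 11), 5, 2), matrix(c(3, 5, 7, 9, 11), 5, 2))
  d <- toy_dataset(freq, origin = c("native", "native", "alien", "alien"))
  cmp <- compare_component_richness(d)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$df, 4)

  # hand-computed 5-plot construction
  nat <- c(10, 12, 8, 15, 9)
  ali <- c(4, 3, 6, 2, 5)
  freq2 <- matrix(0, 5, 31)
  for (p in 1:5) {
    freq2[p, seq_len(nat[p])] <- 1                 # native block: 20 species
    freq2[p, 20 + seq_len(ali[p])] <- 1            # alien block
  }
  d2 <- suppressWarnings(
    toy_dataset(freq2, origin = rep(c("native", "alien"), c(20, 11))))
  cmp2 <- compare_component_richness(d2)
  tt <- t.test(nat, ali, paired = TRUE)
  ols <- summary(lm(ali ~ nat))
  expect_equal(cmp2$t, unname(tt$statistic))
  expect_equal(cmp2$mean_difference, mean(nat - ali))
  expect_equal(cmp2$slope, unname(coef(lm(ali ~ nat))[2]))
  expect_equal(cmp2$slope_p, ols$coefficients[2, 4])
  expect_equal(cmp2$r_squared, ols$r.squared)
})

test_that("occupancy KS statistic matches an ECDF enumeration oracle", {
  freq <- matrix(0, 6, 8)
  occ <- c(1, 2, 3, 6, 2, 2, 5, 6)
  for (s in 1:8) freq[seq_len(occ[s]), s] <- 1
  d <- toy_dataset(freq, origin = rep(c("alien", "native"), each = 4))
  ks <- ks_occupancy(d)
  a <- occ[1:4] / 6; n <- occ[5:8] / 6
  grid <- sort(unique(c(a, n)))
  D_hand <- max(abs(sapply(grid, function(g) mean(a <= g) - mean(n <= g))))
  expect_equal(ks$D, D_hand)

  # identical samples -> D = 0; disjoint samples -> D = 1
  freq_id <- matrix(0, 6, 8)
  for (s in 1:8) freq_id[seq_len(c(1, 2, 3, 4)[(s - 1) %% 4 + 1]), s] <- 1
  d_id <- toy_dataset(freq_id, origin = rep(c("alien", "native"), each = 4))
  expect_equal(ks_occupancy(d_id)$D, 0)
  freq_dis <- matrix(0, 6, 8)
  for (s in 1:4) freq_dis[1, s] <- 1                 # aliens occupy 1 plot
  for (s in 5:8) freq_dis[1:5, s] <- 1               # natives occupy 5 plots
  d_dis <- toy_dataset(freq_dis, origin = rep(c("alien", "native"), each = 4))
  expect_equal(ks_occupancy(d_dis)$D, 1)
})

test_that("pH-threshold contrasts split plots and detect constructed differences", {
  set.seed(23)
  P <- 30
  env <- data.frame(organic_matter = runif(P, 2, 14),
                    live_basal_area = runif(P, 8, 40),
                    ecec = runif(P, 2, 10),
                    ph = c(runif(P / 2, 4.6, 5.4), runif(P / 2, 5.6, 6.8)))
  # rare natives present only in acid plots
  S <- 40
  freq <- matrix(0, P, S)
  for (s in 1:20) freq[sample(1:(P / 2), 3), s] <- sample(1:5, 3, TRUE)   # rare natives, acid side
  for (s in 21:30) freq[, s] <- sample(5:25, P, TRUE)                     # common natives
  for (s in 31:40) freq[sample(1:P, 20), s] <- sample(1:25, 20, TRUE)     # aliens
  d <- survey_dataset(
    data.frame(plot_id = seq_len(P), x = runif(P), y = runif(P), park = "a"),
    data.frame(species_id = sprintf("s%02d", 1:S),
               origin = rep(c("native", "alien"), c(30, 10))),
    freq, env)
  tc <- threshold_contrast(d, "rare_native_richness")
  expect_gt(tc$mean_below, tc$mean_above)
  expect_lt(tc$p, 0.01)
  tc2 <- threshold_contrast(d, "rare_native_relative_frequency")
  expect_gt(tc2$mean_below, tc2$mean_above)
  tc3 <- threshold_contrast(d, "tolerant_alien_relative_frequency")
  expect_true(is.finite(tc3$p))

  # degenerate grouping errors out
  env_high <- env; env_high$ph <- runif(P, 6, 6.9)
  d_high <- survey_dataset(d$plots, d$species, freq, env_high)
  expect_error(threshold_contrast(d_high, "rare_native_richness"),
               "one side")
})
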