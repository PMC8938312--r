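test_that("dataset construction validates bounds, ids and alignment", {
  freq <- matrix(c(0, 3, 25, 0, 1, 2), nrow = 3)
  d <- toy_dataset(freq)
  expect_s3_class(d, "survey_dataset")
  expect_equal(nrow(d$plots), 3)

  expect_error(toy_dataset(matrix(c(26, 1, 1, 1), 2, 2)),
               "frequencies must be integers")
  expect_error(toy_dataset(matrix(c(-1, 1, 1, 1), 2, 2)),
               "frequencies must be integers")
  bad_env <- data.frame(organic_matter = 1:3, live_basal_area = 1:3, ecec = 1:3)
  expect_error(
    survey_dataset(data.frame(plot_id = 1:3, x = 1:3, y = 1:3, park = "a"),
                   data.frame(species_id = "s1", origin = "native"),
                   matrix(1, 3, 1), bad_env),
    "missing column")

  expect_warning(d2 <- toy_dataset(cbind(freq, 0)), "never observed")
  expect_equal(ncol(d2$freq), 2)
})

test_that("CSV round trip preserves the dataset in both dialects", {
  d <- toy_dataset(matrix(c(0, 3, 25, 0, 1, 2, 4, 0, 7), nrow = 3))
  dir <- withr::local_tempdir()
  write_survey(d, dir)
  d2 <- load_survey(file.path(dir, "frequency.csv"), file.path(dir, "plots.csv"),
                    file.path(dir, "species.csv"), file.path(dir, "env.csv"))
  expect_equal(d2$freq, d$freq)
  expect_equal(d2$env, d$env, tolerance = 1e-12)

  # long dialect
  idx <- which(d$freq > 0, arr.ind = TRUE)
  long <- data.frame(plot_id = rownames(d$freq)[idx[, 1]],
                     species_id = colnames(d$freq)[idx[, 2]],
                     frequency = d$freq[idx])
  long_path <- file.path(dir, "frequency_long.csv")
  write.csv(long, long_path, row.names = FALSE)
  d3 <- load_survey(long_path, file.path(dir, "plots.csv"),
                    file.path(dir, "species.csv"), file.path(dir, "env.csv"))
  expect_equal(d3$freq, d$freq)

  # id cross-reference failure names the file
  long_bad <- long
  long_bad$species_id[1] <- "nope"
  write.csv(long_bad, long_path, row.names = FALSE)
  expect_error(load_survey(long_path, file.path(dir, "plots.csv"),
                           file.path(dir, "species.csv"), file.path(dir, "env.csv")),
               "unknown species_id 'nope'")
})

test_that("presence/absence is the >0 indicator and idempotent", {
  expect_equal(unname(presence_absence(matrix(c(0, 25, 3, 0), 2, 2))),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(presence_absence(matrix(1:9, 3, 3)) == 1))
  m <- matrix(sample(0:5, 200, replace = TRUE), 10, 20)
  expect_equal(unname(presence_absence(m)), (m > 0) * 1)
  expect_equal(presence_absence(presence_absence(m)), presence_absence(m))
})

test_that("relative frequency divides by the subplot count", {
  d <- toy_dataset(matrix(c(25, 0, 13, 1), 2, 2))
  rf <- relative_frequency(d)
  expect_equal(sort(unique(as.vector(rf))), c(0, 0.04, 0.52, 1))
})

test_that("occupancy profile equals column sums", {
  expect_equal(occupancy_profile(diag(3))$n_plots, rep(1, 3))
  expect_equal(occupancy_profile(matrix(1, 5, 4))$n_plots, rep(5, 4))
  m <- random_incidence(10, 20, seed = 42)
  op <- occupancy_profile(m)
  expect_equal(op$n_plots, unname(colSums(m)))
  expect_equal(op$proportion, unname(colSums(m)) / 10)
})

test_that("extent of occurrence matches hull geometry and exclusion rules", {
  coords <- rbind(c(0, 0), c(4, 0), c(0, 4))
  inc <- matrix(1, 3, 1)
  eoo <- extent_of_occurrence(inc, coords)
  expect_equal(eoo$area_km2, 8)
  expect_false(eoo$excluded)

  # fewer than min_plots occupied -> excluded with area 0
  inc2 <- matrix(c(1, 1, 0), 3, 1)
  eoo2 <- extent_of_occurrence(inc2, coords)
  expect_equal(eoo2$area_km2, 0)
  expect_true(eoo2$excluded)

  # collinear occupied plots -> area 0, excluded
  eoo3 <- extent_of_occurrence(matrix(1, 3, 1), cbind(1:3, 2 * (1:3)))
  expect_equal(eoo3$area_km2, 0)
  expect_true(eoo3$excluded)

  # random 20-point clouds agree with the brute-force hull oracle
  for (s in 1:5) {
    set.seed(s)
    pts <- cbind(runif(20, 0, 30), runif(20, 0, 30))
    a <- extent_of_occurrence(matrix(1, 20, 1), pts)$area_km2
    expect_equal(a, hull_area_oracle(pts), tolerance = 1e-9)
  }
})

test_that("extent of occurrence is invariant to rigid motions", {
  set.seed(11)
  pts <- cbind(runif(15, 0, 20), runif(15, 0, 20))
  inc <- random_incidence(15, 8, seed = 3)
  base <- extent_of_occurrence(inc, pts)$area_km2
  th <- 0.73
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(rot, 2, c(100, -40), "+")
  expect_equal(extent_of_occurrence(inc, moved)$area_km2, base,
               tolerance = 1e-9)
})

test_that("chao2 follows the bias-corrected incidence formula", {
  # no uniques: estimate equals observed richness
  inc <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 1, 1))
  ch <- chao2(inc)
  expect_equal(ch$q1, 0)
  expect_equal(ch$estimate, ch$s_obs)
  expect_equal(ch$completeness, 1)

  # hand-computed: m = 4, S_obs = 10, Q1 = 4, Q2 = 2
  # estimate = 10 + (3/4) * 4*3 / (2*3) = 11.5
  set.seed(1)
  inc4 <- matrix(0, 4, 10)
  occs <- c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4)
  for (s in seq_len(10)) inc4[sample.int(4, occs[s]), s] <- 1
  ch4 <- chao2(inc4)
  expect_equal(ch4$q1, 4)
  expect_equal(ch4$q2, 2)
  expect_equal(ch4$estimate, 11.5)
  expect_equal(ch4$completeness, 10 / 11.5)

  # classical form on the same data: 10 + (3/4)*16/4 = 13
  expect_equal(chao2(inc4, bias_corrected = FALSE)$estimate, 13)

  expect_error(chao2(matrix(1, 1, 3)), "at least 2 plots")
})

test_that("chao2 estimate is non-decreasing in the number of uniques", {
  # grow Q1 by turning doubletons into singletons, all else fixed
  ests <- sapply(0:4, function(q1) {
    s_obs <- 10; m <- 6; q2 <- 4 - q1 + 2
    s_obs + (m - 1) / m * q1 * (q1 - 1) / (2 * (q2 + 1))
  })
  # direct check on the implementation with constructed matrices
  make_inc <- function(q1) {
    inc <- matrix(0, 6, 8)
    occ <- c(rep(1, q1), rep(2, 4 - q1), 3, 3, 4, 4)
    for (s in 1:8) inc[seq_len(occ[s]), s] <- 1
    inc
  }
  est_seq <- sapply(0:4, function(q1) chao2(make_inc(q1))$estimate)
  expect_true(all(diff(est_seq) >= 0))
  expect_true(all(diff(ests) >= 0))
})

test_that("rarefaction curves are monotone, anchored and mode-sensitive", {
  # identical composition everywhere -> flat curve at S
  inc_flat <- matrix(1, 6, 9)
  rc <- rarefaction(inc_flat, n_permutations = 50, seed = 1)
  expect_true(all(rc$mean_richness == 9))

  # random-mode means approach the hypergeometric expectation
  inc <- random_incidence(4, 12, p = 0.5, seed = 5)
  occ <- colSums(inc)
  P <- 4
  expected <- sapply(1:P, function(k)
    sum(1 - choose(P - occ, k) / choose(P, k)))
  rc2 <- rarefaction(inc, n_permutations = 4000, seed = 9)
  expect_equal(rc2$mean_richness, expected, tolerance = 0.05)
  expect_true(all(diff(rc2$mean_richness) >= 0))
  expect_equal(rc2$mean_richness[P], sum(occ > 0))
  expect_true(all(rc2$lower <= rc2$mean_richness + 1e-12 &
                  rc2$mean_richness <= rc2$upper + 1e-12))

  # random-mode k = 1 equals mean plot richness (zeta order 1)
  expect_equal(rc2$mean_richness[1], mean(rowSums(inc)), tolerance = 0.05)

  # spatially clustered composition: spatial curve below random curve
  real <- generate_community(make_scenario("dispersal_limited"), seed = 2)
  inc3 <- presence_absence(real$dataset)
  coords <- as.matrix(real$dataset$plots[, c("x", "y")])
  r_rand <- rarefaction(inc3, coords, "random", n_permutations = 200, seed = 3)
  r_spat <- rarefaction(inc3, coords, "spatial", n_permutations = 200, seed = 3)
  mid <- 5:20
  expect_true(mean(r_spat$mean_richness[mid]) < mean(r_rand$mean_richness[mid]))

  expect_error(rarefaction(inc, mode = "spatial"), "needs coordinates")
})

test_that("coordinate projection gives planar km with correct scale", {
  # 1 degree of latitude is ~111.2 km; longitude shrinks with cos(lat)
  xy <- project_coordinates(c(145, 146), c(-37, -37))
  expect_equal(abs(diff(xy[, 1])), 6371 * cos(-37 * pi / 180) * pi / 180,
               tolerance = 1e-6)
  xy2 <- project_coordinates(c(145, 145), c(-37, -36))
  expect_equal(abs(diff(xy2[, 2])), 6371 * pi / 180, tolerance = 1e-6)
})
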