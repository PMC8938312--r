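# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, recursion, shoelace-on-triples) and never reuse package
# internals beyond exported constructors.

# small survey dataset built by hand: P plots, S species, given frequencies
toy_dataset <- function(freq, coords = NULL, env = NULL,
                        origin = NULL, n_subplots = 25) {
  P <- nrow(freq)
  S <- ncol(freq)
  if (is.null(coords)) coords <- cbind(seq_len(P), rep(0, P))
  if (is.null(env))
    env <- data.frame(organic_matter = seq(2, 14, length.out = P),
                      live_basal_area = seq(8, 40, length.out = P),
                      ecec = seq(2, 10, length.out = P),
                      ph = seq(4.5, 6.9, length.out = P))
  if (is.null(origin)) origin <- rep(c("native", "alien"), length.out = S)
  survey_dataset(
    plot_table = data.frame(plot_id = sprintf("p%02d", seq_len(P)),
                            x = coords[, 1], y = coords[, 2], park = "park1"),
    species_table = data.frame(species_id = sprintf("s%02d", seq_len(S)),
                               origin = origin),
    frequency_matrix = freq,
    env_table = env,
    n_subplots = n_subplots)
}

# random binary incidence matrix with no empty species columns
random_incidence <- function(P, S, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(P * S, 1, p), P, S)
  empty <- colSums(m) == 0
  m[cbind(sample.int(P, sum(empty), replace = TRUE), which(empty))] <- 1
  dimnames(m) <- list(sprintf("p%02d", seq_len(P)), sprintf("s%02d", seq_len(S)))
  m
}

# oracle: shared species over a plot set by explicit set intersection
shared_oracle <- function(incidence, idx) {
  sets <- lapply(idx, function(i) which(incidence[i, ] > 0))
  length(Reduce(intersect, sets))
}

# oracle: exhaustive mean/sd of zeta over all combinations of size i
zeta_exhaustive_oracle <- function(incidence, i, simpson = FALSE) {
  combs <- utils::combn(nrow(incidence), i)
  vals <- apply(combs, 2, function(idx) {
    sh <- shared_oracle(incidence, idx)
    if (simpson) sh / min(rowSums(incidence[idx, , drop = FALSE])) else sh
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

# oracle: convex-hull area from brute force over all point triples
# (max total area of a fan triangulation found via the hull is overkill;
# instead compute the area of the polygon formed by ordering hull points
# by angle, with hull membership decided by the "all points on one side"
# test on every pair)
hull_area_oracle <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (a in 1:n) for (b in 1:n) {
    if (a == b) next
    v <- xy[b, ] - xy[a, ]
    cr <- (xy[, 1] - xy[a, 1]) * v[2] - (xy[, 2] - xy[a, 2]) * v[1]
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) on_hull[c(a, b)] <- TRUE
  }
  hp <- xy[on_hull, , drop = FALSE]
  if (nrow(hp) < 3) return(0)
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  j <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
}

# oracle: I-spline values by integrating the M-spline recursion numerically
mspline_oracle <- function(x, k, i, t) {
  if (t[i + k] <= t[i]) return(rep(0, length(x)))
  if (k == 1) {
    w <- t[i + 1] - t[i]
    if (w <= 0) return(rep(0, length(x)))
    return(ifelse(x >= t[i] & (x < t[i + 1] | (x == 1 & t[i + 1] == 1)),
                  1 / w, 0))
  }
  k * ((x - t[i]) * mspline_oracle(x, k - 1, i, t) +
       (t[i + k] - x) * mspline_oracle(x, k - 1, i + 1, t)) /
    ((k - 1) * (t[i + k] - t[i]))
}

ispline_oracle <- function(xs, k, interior) {
  t <- c(rep(0, k), interior, rep(1, k))
  nb <- length(t) - k
  grid <- seq(0, 1, length.out = 40001)
  sapply(seq_len(nb), function(i) {
    m <- mspline_oracle(grid, k, i, t)
    I <- c(0, cumsum((m[-1] + m[-length(m)]) / 2 * diff(grid)))
    I <- I / I[length(I)]
    stats::approx(grid, I, xout = xs)$y
  })
}

# null community: NB frequencies unrelated to the predictors
null_frequency_dataset <- function(seed, P = 50, S = 20, theta = 1.5) {
  set.seed(seed)
  plots <- data.frame(plot_id = sprintf("p%02d", seq_len(P)),
                      x = runif(P, 0, 30), y = runif(P, 0, 30),
                      park = "park1")
  env <- data.frame(organic_matter = runif(P, 2, 14),
                    live_basal_area = runif(P, 8, 40),
                    ecec = runif(P, 2, 10),
                    ph = runif(P, 4.5, 6.9))
  sp <- data.frame(species_id = sprintf("s%02d", seq_len(S)),
                   origin = rep(c("native", "alien"), length.out = S))
  mu <- exp(rnorm(S, log(3), 0.5))
  f <- sapply(mu, function(m) pmin(rnbinom(P, mu = m, size = theta), 25))
  zero <- colSums(f) == 0
  f[1, zero] <- 1
  survey_dataset(plots, sp, f, env)
}
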