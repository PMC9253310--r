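# Shared fixtures and independent oracles. Unit tests run on a scaled-
# down world (60 seed units, 200 timepoints); the acceptance suite uses
# the full default configuration.

small_config <- function(seed = 1L, ...) {
  phantom_config(n_seed_units = 60, n_outside_vertices = 84,
                 n_timepoints = 200, n_streamlines_per_unit = 2000,
                 rng_seed = seed, ...)
}

# Noise-free world: exact recoveries must hold downstream.
noisefree_config <- function(seed = 1L, ...) {
  small_config(seed = seed, fingerprint_concentration = Inf,
               ts_noise_sd = 0, myelin_sd = 0, thickness_sd = 0,
               boundary_jitter_sd = 0, ...)
}

# Mean silhouette width over all points (brute force, small n only).
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Brute-force knee oracle: maximum perpendicular distance to the chord
# joining the first and last point of the min-max-normalized profile.
chord_oracle <- function(k, y) {
  xn <- (k - min(k)) / diff(range(k))
  yn <- (y - min(y)) / diff(range(y))
  d <- abs(xn + yn - 1) / sqrt(2)
  k[which.max(d)]
}

# Random strictly convex decreasing profile with a genuine elbow:
# steep slopes before a random knee position, shallow after, magnitudes
# strictly decreasing throughout (=> strict convexity).
random_elbow_profile <- function() {
  n <- sample(6:12, 1)
  knee_at <- sample(2:(n - 2), 1)
  pre <- sort(stats::runif(knee_at - 1, 8, 20), decreasing = TRUE)
  post <- sort(stats::runif(n - knee_at, 0.05, 1.5), decreasing = TRUE)
  y <- 100 + c(0, cumsum(-c(pre, post)))
  data.frame(k = seq_len(n) + 1L, inertia = y)
}

# Direct voxel-space affinity oracle: correlation fingerprints against
# every outside vertex, then cosine similarity.
direct_affinity_oracle <- function(seed_matrix, outside_matrix) {
  f <- stats::cor(t(seed_matrix), t(outside_matrix))
  fn <- f / sqrt(rowSums(f^2))
  a <- tcrossprod(fn)
  diag(a) <- 1
  a
}
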