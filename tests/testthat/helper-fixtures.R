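# Shared fixtures and independent oracles used across the suite.

default_observer <- function() observer_profile(30, 0.5)
reference_scene <- function(contrast = 0.89) {
  scene_conditions(13.14, contrast, 2.75)
}
reference_exposure <- function(p = 1.537) laser_exposure(532, p, 0.5)

grid_xy <- function(shape) {
  list(x = matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1]),
       y = matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1]))
}

make_disc <- function(shape = c(64, 64), cx = 32, cy = 32, r = 20) {
  g <- grid_xy(shape)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

# Exhaustive Otsu oracle: threshold maximizing between-class variance over
# all 256 candidate levels on the rescaled image.
otsu_exhaustive <- function(image) {
  v <- (image - min(image)) / diff(range(image))
  cands <- seq(0, 1, length.out = 256)
  bcv <- vapply(cands, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

# Power-iteration principal eigenvector oracle for AHP weights.
power_eigen <- function(m, iters = 500) {
  v <- rep(1 / nrow(m), nrow(m))
  for (i in seq_len(iters)) {
    v <- as.numeric(m %*% v)
    v <- v / sum(v)
  }
  v
}

# Reciprocal pairwise matrix near a consistent one (CR well below the 0.1
# admissibility bound), as used in practice.
near_consistent_matrix <- function(seed, n = 4, sd = 0.15) {
  set.seed(seed)
  w <- exp(runif(n, -1, 1)); w <- w / sum(w)
  eps <- matrix(rnorm(n * n, 0, sd), n, n)
  eps <- (eps - t(eps)) / 2
  outer(w, w, "/") * exp(eps)
}

small_layout <- function() {
  build_ring_layout(ring_detector_config(
    n_fovea_rings = 6, n_periph_rings = 8, min_pixel_size_um = 10,
    photosensitive_radius_um = 200, periph_pixels_per_ring = 24,
    fovea_ring_schedule = c(4, 8, 12, 16, 20, 24)))
}
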