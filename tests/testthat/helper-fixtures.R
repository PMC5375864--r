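# Shared fixtures: tiny cubes and spectra built in code, plus brute-force
# oracles kept deliberately independent of the package internals.

default_grid <- function() seq(400, 900, by = 2.8)

# A small reflectance cube with smoothly varying, positive values.
tiny_cube <- function(rows = 3, cols = 4, wl = c(500, 600, 700),
                      units = "reflectance", seed = 42) {
  set.seed(seed)
  a <- array(stats::runif(rows * cols * length(wl), 0.05, 0.8),
             c(rows, cols, length(wl)))
  HyperCube(a, wl, units)
}

noiseless <- function(model) {
  model$pixel_noise_sd <- 0
  model$amplitude_sd <- 0
  model$tilt_sd <- 0
  model
}

# O(n^3) upper-hull oracle: at each x_j the hull value is the maximum over
# all chords (i, k) with x_i <= x_j <= x_k of the chord's height at x_j
# (the point's own value is the i == j == k degenerate case).
chord_max_hull <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_len(n)) {
    best <- y[j]
    for (i in seq_len(j)) {
      for (k in j:n) {
        if (i == k) next
        h <- y[i] + (y[k] - y[i]) * (x[j] - x[i]) / (x[k] - x[i])
        if (h > best) best <- h
      }
    }
    out[j] <- best
  }
  out
}

# Count interior strict local minima of a continuum-removed spectrum,
# ignoring ripple shallower than 1% below the hull.
count_cr_minima <- function(cr) {
  v <- cr$value
  n <- length(v)
  i <- 2:(n - 1)
  sum(v[i] < v[i - 1] & v[i] < v[i + 1] & v[i] < 0.99)
}
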