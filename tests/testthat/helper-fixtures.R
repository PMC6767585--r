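# Shared in-code fixtures for the test suite.

# A scene whose bands are supplied directly (bypasses the generator).
make_scene <- function(green, red = green, rededge = green, nir = green,
                       gsd_cm = 250, grid_cols = 1, grid_rows = 1,
                       field_id = "T") {
  band_scene(field_id, green = green, red = red, rededge = rededge,
             nir = nir, gsd_cm = gsd_cm, grid_cols = grid_cols,
             grid_rows = grid_rows)
}

# Random 5x5 confusion matrix with positive total.
random_cm <- function() {
  m <- matrix(rpois(25, 8), 5, 5,
              dimnames = list(observed = state_levels(),
                              predicted = state_levels()))
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}

# Independent brute-force weighted-kappa oracle: explicit double sums
# over observed and chance-expected counts.
wkappa_oracle <- function(cm, w) {
  n <- sum(cm)
  num <- 0
  den <- 0
  for (i in 1:5) {
    for (j in 1:5) {
      m_ij <- sum(cm[i, ]) * sum(cm[, j]) / n
      num <- num + w[i, j] * cm[i, j]
      den <- den + w[i, j] * m_ij
    }
  }
  1 - num / den
}

# Exhaustive pair-counting AUC oracle (ties count 1/2).
auc_oracle <- function(scores, positive) {
  xs <- scores[positive]
  ys <- scores[!positive]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Perfectly class-separable constant tiles: tile value identifies the
# state exactly, so any competent classifier must reach ~100% accuracy.
separable_tiles <- function(n_per_class, side = 8, jitter = 0.01,
                            seed = 42) {
  centres <- c(-0.8, -0.4, 0, 0.4, 0.8)
  withr::with_seed(seed, {
    states <- rep(0:4, each = n_per_class)
    tiles <- lapply(states, function(s) {
      matrix(centres[s + 1] + rnorm(side * side, 0, jitter), side, side)
    })
    list(tiles = tiles, states = as_density_state(states))
  })
}

# Tiny quality-flagged manifest built from a generated survey; cached
# per option set within a test file run.
small_manifest <- function(n_fields = 4, profile = "strong-signal",
                           seed = 11) {
  sv <- generate_survey(example_config(profile, seed = seed),
                        n_fields = n_fields)
  survey_manifest(sv)
}
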