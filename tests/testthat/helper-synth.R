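# Shared fixtures: small geometries, designs and seeded cohorts built in
# code at test time.

# 30 mm box at 3 mm voxels: 8 full 15-mm cubes of 125 voxels each
tiny_geometry <- function(dim = c(10L, 10L, 10L)) bold_geometry(dim)

seeded_grid <- function(geom = tiny_geometry()) {
  grid <- build_roi_grid(geom)
  set_networks(grid, default_seed_networks(grid))
}

# scaled-down task design used by Monte-Carlo tests (documented in the
# methods vignette): fewer/shorter runs than the default paradigm, same
# structure
mc_design <- function(seed = 1L) {
  task_design(n_runs = 3, n_cue_per_run = 15, n_cuestim_per_run = 15,
              trial_duration_s = 4, rest_length_s = 20, seed = seed)
}

# independent brute-force Spearman oracle: explicit average ranks + the
# Pearson product-moment formula written out
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# independent normal-equations OLS oracle
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
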