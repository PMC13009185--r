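# Independent oracles and small shared fixtures.

# Brute-force exact nearest-feature distance between cell centres (O(n*m)).
brute_distance <- function(mask, cell_size = 1) {
  on <- which(mask != 0, arr.ind = TRUE)
  stopifnot(nrow(on) > 0)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    d2 <- outer(rep(1, nc), rep(0, nrow(on)))
    d2 <- (matrix(on[, 1], nc, nrow(on), byrow = TRUE) - i)^2 +
      (matrix(on[, 2], nc, nrow(on), byrow = TRUE) -
         matrix(seq_len(nc), nc, nrow(on)))^2
    out[i, ] <- sqrt(apply(d2, 1, min)) * cell_size
  }
  out
}

# Trapezoidal integration of the empirical ROC curve.
trapezoid_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Small synthetic scene + predictor set used across test files. BPI scales
# and the VRM window are shrunk so every layer keeps valid interior cells
# on a small grid.
small_scene <- function(seed = 1, n_cells = 64, n_occ = 40) {
  cfg <- scene_config(extent_cells = c(n_cells, n_cells), rng_seed = seed,
                      n_carbonate_patches = 4, patch_radius_range = c(2, 5))
  scene <- simulate_scene(cfg, n_occurrences = n_occ)
  stack <- terrain_stack(scene$bathymetry, bpi_scales = c(5, 15),
                         vrm_window = 9)
  preds <- assemble_predictors(stack, distance_layers(scene$features))
  scene$preds <- preds
  scene
}

# Perfectly separable toy model data: one informative predictor plus noise.
toy_model_data <- function(n_pos = 40, n_neg = 200, seed = 1, n_folds = 4) {
  set.seed(seed)
  data.frame(
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    fold = rep_len(seq_len(n_folds), n_pos + n_neg),
    v_signal = c(runif(n_pos, 0.8, 1), runif(n_neg, 0, 0.2)),
    v_noise = runif(n_pos + n_neg))
}
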