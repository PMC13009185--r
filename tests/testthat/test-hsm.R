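test_that("collinearity pruning drops duplicates but honours the keep set", {
  set.seed(2)
  base <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  base$a2 <- base$a                          # identical twin
  res <- prune_collinear(base)
  dropped <- setdiff(names(base), res$kept)
  expect_length(dropped, 1)
  expect_true(dropped %in% c("a", "a2"))

  # keep-set members correlated above threshold are retained with a warning
  x <- rnorm(300)
  kd <- data.frame(d_mats = x + rnorm(300, 0, 0.55),
                   d_mussels = x + rnorm(300, 0, 0.55),
                   d_tubeworms = x + rnorm(300, 0, 0.55),
                   other = rnorm(300))
  cc <- stats::cor(kd)[1:3, 1:3]
  expect_gt(max(abs(cc[upper.tri(cc)])), 0.7)  # construction sanity (seeded)
  expect_warning(res2 <- prune_collinear(kd, keep = names(kd)[1:3]),
                 "retained")
  expect_setequal(res2$kept, names(kd))

  # nothing happens below the threshold
  ind <- data.frame(u = rnorm(500), v = rnorm(500), w = rnorm(500))
  res3 <- prune_collinear(ind)
  expect_equal(res3$kept, names(ind))
  expect_equal(nrow(res3$dropped), 0)
})

test_that("background sampling is uniform, exclusive and seed-stable", {
  r <- seep_raster(matrix(0, 60, 60))
  pres <- data.frame(x = c(10.5, 20.5), y = c(10.5, 20.5))
  bg <- sample_background(r, n = 500, seed = 3, presences = pres)
  expect_equal(nrow(bg), 500)
  expect_equal(nrow(unique(bg)), 500)
  expect_false(any(bg$x == 10.5 & bg$y == 10.5))
  expect_identical(bg, sample_background(r, n = 500, seed = 3, presences = pres))
  expect_false(identical(bg, sample_background(r, n = 500, seed = 4,
                                               presences = pres)))
  expect_error(sample_background(r, n = 1e5, seed = 1), "valid cells")
  # quadrant uniformity over replicates (chi-square on pooled counts)
  counts <- c(0, 0, 0, 0)
  for (s in 1:20) {
    b <- sample_background(r, n = 400, seed = s)
    q <- 1 + (b$x >= 30) + 2 * (b$y >= 30)
    counts <- counts + tabulate(q, 4)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("spatial blocks tile the extent and give coherent folds", {
  pres <- data.frame(x = runif(40, 0, 250), y = runif(40, 0, 250))
  des <- make_blocks(c(0, 0, 250, 250), pres, block_size = 50, n_folds = 5,
                     seed = 1)
  expect_equal(des$nbx * des$nby, 25)
  expect_equal(sort(unique(des$fold_of_block)), 1:5)
  # points in one block share a fold
  f1 <- cv_fold(des, c(12, 37), c(12, 37))
  expect_equal(f1[1], f1[2])
  # every fold holds a presence
  expect_setequal(unique(cv_fold(des, pres$x, pres$y)), 1:5)
  # points 200 m apart are in different blocks
  expect_false(seepscape:::.block_id(des, 10, 10) ==
                 seepscape:::.block_id(des, 210, 10))
  expect_error(make_blocks(c(0, 0, 250, 250), pres[1:3, ], n_folds = 5),
               "fewer presences")
})

test_that("AUC and TSS follow their definitions on toy score sets", {
  e <- evaluate_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(e$auc, 1)
  expect_equal(e$tss, 1)
  expect_gt(e$tss_threshold, 0.2)
  expect_lte(e$tss_threshold, 0.8)

  e2 <- evaluate_predictions(c(0.4, 0.7), c(1, 0))
  expect_equal(e2$auc, 0)
  expect_equal(e2$tss, 0)

  e3 <- evaluate_predictions(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(e3$auc, 0.5)
  expect_equal(e3$tss, 0)
  expect_error(evaluate_predictions(c(0.1, 0.2), c(1, 1)), "negative")
})

test_that("rank-based AUC equals trapezoidal ROC integration", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(evaluate_predictions(scores, labels)$auc,
                 trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("separable toy data gives perfect runs; shuffled labels give chance", {
  data <- toy_model_data(seed = 3)
  spec <- hsm_spec(rng_seed = 1, rf_trees = 100, gbm_trees = 200)
  runs <- fit_models(data, "v_signal", spec)
  expect_equal(length(runs), 8)  # 2 algorithms x 4 folds
  for (r in runs) {
    expect_equal(r$eval$auc, 1)
    expect_equal(r$eval$tss, 1)
  }
  # null data: label shuffled
  aucs <- numeric(10)
  for (i in 1:10) {
    d <- toy_model_data(seed = 100 + i)
    set.seed(i); d$label <- sample(d$label)
    rs <- fit_models(d, c("v_signal", "v_noise"),
                     hsm_spec(algorithms = "rf", rng_seed = i, rf_trees = 100))
    aucs[i] <- mean(vapply(rs, function(r) r$eval$auc, 0))
  }
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("predictions from both learners stay in [0, 1]", {
  data <- toy_model_data(seed = 9)
  runs <- fit_models(data, c("v_signal", "v_noise"),
                     hsm_spec(rng_seed = 2, rf_trees = 100, gbm_trees = 200))
  for (r in runs) {
    p <- seepscape:::.predict_run(r, data[, c("v_signal", "v_noise")])
    expect_true(all(is.finite(p)) && all(p >= 0) && all(p <= 1))
  }
})

test_that("permutation importance isolates the informative variable", {
  data <- toy_model_data(n_pos = 60, n_neg = 240, seed = 4)
  data$v_const <- 1
  vars <- c("v_signal", "v_noise", "v_const")
  runs <- fit_models(data, vars, hsm_spec(algorithms = "rf", rng_seed = 5,
                                          rf_trees = 150))
  imp <- permutation_importance(runs[[1]], data, vars, n_reps = 19, seed = 6)
  expect_equal(imp$importance[imp$variable == "v_const"], 0)
  expect_gt(imp$importance[imp$variable == "v_signal"],
            imp$importance[imp$variable == "v_noise"])
  expect_gt(imp$importance[imp$variable == "v_signal"], 0.2)
})

test_that("ensemble weights are TSS-proportional and the surface is convex", {
  scene <- small_scene(seed = 8)
  occ <- scene$occurrences
  spec <- hsm_spec(algorithms = "rf", n_background = 300, block_size = 16,
                   n_folds = 3, rng_seed = 3, rf_trees = 100)
  fit <- suppressWarnings(run_hsm(occ, scene$preds, spec, importance = FALSE))
  # fabricate known TSS values on duplicated runs to check the weighting rule
  r1 <- fit$runs[[1]]; r2 <- fit$runs[[2]]
  r1$eval$tss <- 0.8; r2$eval$tss <- 0.4
  ens <- ensemble_hsi(list(r1, r2), scene$preds, fit$vars)
  expect_equal(ens$weights$weight, c(2 / 3, 1 / 3))
  # single run: ensemble equals that run's prediction
  e1 <- ensemble_hsi(list(r1), scene$preds, fit$vars)
  expect_equal(e1$weights$weight, 1)
  ok <- which(scene$preds$valid)
  X <- as.data.frame(lapply(scene$preds$layers[fit$vars],
                            function(l) l$values[ok]))
  expect_equal(e1$hsi$values[ok], seepscape:::.predict_run(r1, X),
               tolerance = 1e-12)
  # convex combination: within member range cellwise
  p1 <- seepscape:::.predict_run(r1, X); p2 <- seepscape:::.predict_run(r2, X)
  h <- ens$hsi$values[ok]
  expect_true(all(h >= pmin(p1, p2) - 1e-12 & h <= pmax(p1, p2) + 1e-12))
  # all-nonpositive TSS cannot ensemble
  r1$eval$tss <- 0; r2$eval$tss <- -0.1
  expect_error(ensemble_hsi(list(r1, r2), scene$preds, fit$vars), "TSS")
})

test_that("response curves are flat for ignorable variables and bounded", {
  data <- toy_model_data(n_pos = 100, n_neg = 500, seed = 12)
  runs <- fit_models(data, c("v_signal", "v_noise"),
                     hsm_spec(algorithms = "rf", rng_seed = 7, rf_trees = 300))
  rc_noise <- response_curve(runs, data, c("v_signal", "v_noise"), "v_noise")
  expect_lt(diff(range(rc_noise$prediction)), 0.05)
  rc_sig <- response_curve(runs, data, c("v_signal", "v_noise"), "v_signal")
  expect_gt(diff(range(rc_sig$prediction)), 0.5)
  expect_true(all(rc_sig$prediction >= 0 & rc_sig$prediction <= 1))
  expect_error(response_curve(runs, data, c("v_signal", "v_noise"), "nope"),
               "unknown variable")
})

test_that("fold evaluation sets partition the data with no train/test overlap", {
  data <- toy_model_data(seed = 15)
  runs <- fit_models(data, c("v_signal", "v_noise"),
                     hsm_spec(algorithms = "rf", rng_seed = 8, rf_trees = 50))
  test_sets <- lapply(runs, `[[`, "test_idx")
  expect_setequal(unlist(test_sets), seq_len(nrow(data)))
  expect_equal(sum(lengths(test_sets)), nrow(data))
  for (r in runs)
    expect_true(all(data$fold[r$test_idx] == r$fold))
})

test_that("spatial-block CV is no more optimistic than random-split CV", {
  # on spatially autocorrelated data, evaluating on spatially separated
  # blocks should not score better than evaluating on random splits
  block_auc <- numeric(12); random_auc <- numeric(12)
  for (i in seq_len(12)) {
    scene <- small_scene(seed = 300 + i, n_occ = 30)
    occ <- scene$occurrences
    spec <- hsm_spec(algorithms = "rf", n_background = 250, block_size = 16,
                     n_folds = 3, rng_seed = i, rf_trees = 80)
    fit <- suppressWarnings(run_hsm(occ, scene$preds, spec, importance = FALSE))
    block_auc[i] <- mean(fit$eval$auc)
    d <- fit$data
    set.seed(1000 + i)
    d$fold <- sample(d$fold)
    rr <- fit_models(d, fit$vars, spec)
    random_auc[i] <- mean(vapply(rr, function(r) r$eval$auc, 0))
  }
  expect_lte(mean(block_auc), mean(random_auc) + 0.005)
})
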