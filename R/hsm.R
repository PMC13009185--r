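# Presence-background ensemble habitat suitability modelling: collinearity
# pruning, uniform background sampling, spatial-block cross-validation,
# random-forest and gradient-boosting learners, AUC/TSS evaluation,
# permutation variable importance (1 minus the correlation between original
# and permuted-variable predictions), TSS-weighted ensembling, and response
# curves.

#' Model specification for the HSM ensemble
#'
#' Defaults mirror the study settings: both algorithms, 5,000 background
#' points, 50 m spatial blocks in 5 folds, 99 permutation-importance
#' replicates. Learner hyperparameters: RF = 500 trees, default feature
#' subsampling, minimum node size 1; GBM = up to 1,000 trees, learning rate
#' 0.01, depth 3, early stopping on a 10% in-fold validation split.
#'
#' @param algorithms subset of `c("rf", "gbm")`.
#' @param n_background number of background (pseudoabsence) points.
#' @param block_size spatial block edge, metres.
#' @param n_folds number of cross-validation folds (>= 2).
#' @param n_importance_reps permutation replicates per variable (>= 1).
#' @param rng_seed master seed; fans out to background sampling, fold
#'   assignment, learner seeds and permutation replicates.
#' @param rf_trees,gbm_trees,gbm_learning_rate,gbm_depth learner settings.
#' @return object of class `hsm_spec`.
#' @export
hsm_spec <- function(algorithms = c("rf", "gbm"), n_background = 5000,
                     block_size = 50, n_folds = 5, n_importance_reps = 99,
                     rng_seed = 1, rf_trees = 500, gbm_trees = 1000,
                     gbm_learning_rate = 0.01, gbm_depth = 3) {
  algorithms <- match.arg(algorithms, c("rf", "gbm"), several.ok = TRUE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (n_importance_reps < 1) stop("n_importance_reps must be >= 1", call. = FALSE)
  if (block_size <= 0) stop("block_size must be > 0", call. = FALSE)
  structure(list(algorithms = algorithms, n_background = as.integer(n_background),
                 block_size = block_size, n_folds = as.integer(n_folds),
                 n_importance_reps = as.integer(n_importance_reps),
                 rng_seed = as.integer(rng_seed), rf_trees = as.integer(rf_trees),
                 gbm_trees = as.integer(gbm_trees),
                 gbm_learning_rate = gbm_learning_rate,
                 gbm_depth = as.integer(gbm_depth)),
            class = "hsm_spec")
}

#' Iteratively prune collinear predictors
#'
#' While any pair of predictors has |Pearson r| above the threshold, the
#' member of an offending pair with the largest mean absolute correlation to
#' all other variables is dropped — unless it is in `keep`: variables in the
#' keep-set are never dropped, and keep-set pairs that remain correlated
#' above the threshold are retained with a warning.
#'
#' @param X data.frame/matrix of predictor values sampled at the model
#'   points (presences + background).
#' @param threshold |r| above which a pair is collinear (default 0.7).
#' @param keep character vector of variable names never to drop.
#' @return list: `kept` (names), `dropped` (log data.frame with the mean
#'   |r| at drop time), `cor_matrix` (full initial correlation matrix),
#'   `warnings` (retained keep-set pairs).
#' @export
prune_collinear <- function(X, threshold = 0.7, keep = character(0)) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least two predictors", call. = FALSE)
  full_cor <- stats::cor(X, use = "pairwise.complete.obs")
  vars <- colnames(X)
  dropped <- data.frame(variable = character(0), mean_abs_r = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    cm <- abs(full_cor[vars, vars, drop = FALSE])
    diag(cm) <- 0
    offending <- which(cm > threshold, arr.ind = TRUE)
    if (nrow(offending) == 0) break
    cand <- unique(vars[offending[, 1]])
    cand <- setdiff(cand, keep)
    if (length(cand) == 0) break  # only keep-set pairs remain collinear
    mean_r <- rowMeans(cm)[cand]
    worst <- cand[which.max(mean_r)]
    dropped <- rbind(dropped, data.frame(variable = worst,
                                         mean_abs_r = max(mean_r),
                                         stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
  }
  warn <- character(0)
  cm <- abs(full_cor[vars, vars, drop = FALSE]); diag(cm) <- 0
  off <- which(cm > threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(off) > 0) {
    warn <- sprintf("%s ~ %s retained with |r| = %.2f",
                    vars[off[, 1]], vars[off[, 2]], cm[off])
    warning("collinear keep-set pairs retained: ",
            paste(warn, collapse = "; "), call. = FALSE)
  }
  list(kept = vars, dropped = dropped, cor_matrix = full_cor, warnings = warn)
}

#' Sample uniform background (pseudoabsence) points
#'
#' Uniform random draw of cells from the valid (non-nodata) area, excluding
#' cells occupied by presences; points at cell centres. Deterministic per
#' seed.
#'
#' @param preds a `predictor_set` (its union validity mask is used), or a
#'   [seep_raster] whose non-`NA` cells are valid.
#' @param n number of background points (default 5000).
#' @param seed integer seed.
#' @param presences optional data.frame with `x`, `y`: cells holding a
#'   presence are excluded.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_background <- function(preds, n = 5000, seed = 1, presences = NULL) {
  if (inherits(preds, "predictor_set")) {
    ref <- preds$layers[[1]]
    valid <- preds$valid
  } else {
    stopifnot(inherits(preds, "seep_raster"))
    ref <- preds
    valid <- !is.na(preds$values)
  }
  if (!is.null(presences)) {
    rc <- xy_to_cell(ref, presences$x, presences$y)
    ok <- !is.na(rc$row)
    valid[cbind(rc$row[ok], rc$col[ok])] <- FALSE
  }
  pool <- which(valid)
  if (length(pool) < n)
    stop(sprintf("only %d valid cells available for %d background points",
                 length(pool), n), call. = FALSE)
  pick <- .with_seed(seed, sample(pool, n, replace = FALSE))
  rc <- arrayInd(pick, dim(valid))
  cell_centre(ref, rc[, 1], rc[, 2])
}

#' Build a spatial-block cross-validation design
#'
#' Square blocks tile the extent from its lower-left corner; each block is
#' assigned uniformly at random to a fold. The assignment is re-drawn
#' (bounded retries) until every fold contains at least one presence.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` or a [seep_raster].
#' @param presences data.frame with `x`, `y` of presence points.
#' @param block_size block edge, metres (default 50).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @param max_retries redraw limit (default 100).
#' @return object of class `cv_design`: list with `block_size`, `n_folds`,
#'   `extent`, `fold_of_block` (integer vector) and a `fold_of(x, y)`
#'   accessor baked in via [cv_fold()].
#' @export
make_blocks <- function(extent, presences, block_size = 50, n_folds = 5,
                        seed = 1, max_retries = 100) {
  if (inherits(extent, "seep_raster")) extent <- raster_extent(extent)
  extent <- unname(extent)
  nbx <- ceiling((extent[3] - extent[1]) / block_size)
  nby <- ceiling((extent[4] - extent[2]) / block_size)
  if (nbx < 1 || nby < 1) stop("extent smaller than one block", call. = FALSE)
  if (nrow(presences) < n_folds)
    stop("fewer presences than folds", call. = FALSE)
  n_blocks <- nbx * nby
  design <- structure(list(block_size = block_size, n_folds = as.integer(n_folds),
                           extent = extent, nbx = nbx, nby = nby,
                           fold_of_block = NULL),
                      class = "cv_design")
  p_block <- .block_id(design, presences$x, presences$y)
  .with_seed(seed, {
    for (i in seq_len(max_retries)) {
      fob <- sample.int(n_folds, n_blocks, replace = TRUE)
      if (length(unique(fob[p_block])) == n_folds) {
        design$fold_of_block <- fob
        break
      }
    }
  })
  if (is.null(design$fold_of_block))
    stop("could not find a block assignment giving every fold a presence",
         call. = FALSE)
  design
}

# block index (1-based, column-major over x then y) for points
.block_id <- function(design, x, y) {
  bx <- pmin(floor((x - design$extent[1]) / design$block_size), design$nbx - 1)
  by <- pmin(floor((y - design$extent[2]) / design$block_size), design$nby - 1)
  as.integer(by * design$nbx + bx + 1)
}

#' Fold membership of points under a CV design
#'
#' @param design a [make_blocks()] result.
#' @param x,y point coordinates, metres.
#' @return integer fold ids.
#' @export
cv_fold <- function(design, x, y) {
  stopifnot(inherits(design, "cv_design"))
  design$fold_of_block[.block_id(design, x, y)]
}

#' Rank-based AUC and true skill statistic
#'
#' AUC is the Mann-Whitney concordance (ties counted 1/2): the probability a
#' random presence scores above a random background point. TSS is the
#' maximum over a 0-1 threshold grid (step 0.01) of sensitivity +
#' specificity - 1, scoring a point positive when its score is >= the
#' threshold; the smallest maximizing threshold is reported.
#'
#' @param scores numeric prediction scores in \[0, 1\].
#' @param labels 0/1 (or logical) observed labels.
#' @return list: `auc`, `tss`, `tss_threshold`.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- seq(0, 1, by = 0.01)
  tss_at <- vapply(thr, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, 0)
  best <- max(tss_at)
  list(auc = auc, tss = best, tss_threshold = thr[which(tss_at == best)[1]])
}

# --- learners -----------------------------------------------------------

.fit_rf <- function(X, y, spec, seed) {
  .with_seed(seed,
    randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                               ntree = spec$rf_trees, nodesize = 1))
}

.fit_gbm <- function(X, y, spec, seed) {
  .with_seed(seed, {
    n <- nrow(X)
    val <- sample.int(n, max(1L, round(0.1 * n)))
    dtr <- xgboost::xgb.DMatrix(as.matrix(X[-val, , drop = FALSE]),
                                label = y[-val])
    dva <- xgboost::xgb.DMatrix(as.matrix(X[val, , drop = FALSE]),
                                label = y[val])
    xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "binary:logistic",
                                   learning_rate = spec$gbm_learning_rate,
                                   max_depth = spec$gbm_depth,
                                   tree_method = "exact",
                                   nthread = 1, seed = seed),
      data = dtr, nrounds = spec$gbm_trees,
      evals = list(val = dva), early_stopping_rounds = 50, verbose = 0)
  })
}

# predictions in [0, 1] from either learner on a data.frame of predictors
.predict_run <- function(run, X) {
  if (run$algorithm == "rf")
    unname(stats::predict(run$model, X, type = "prob")[, "1"])
  else
    stats::predict(run$model, xgboost::xgb.DMatrix(as.matrix(X)))
}

#' Fit one model per (algorithm x fold) under spatial-block CV
#'
#' Each run trains on all folds but one and is evaluated on the held-out
#' fold. Training folds whose data are single-class are skipped with a
#' warning.
#'
#' @param data data.frame with columns `label` (1 presence / 0 background),
#'   `fold`, and the predictor columns named in `vars`.
#' @param vars character vector of predictor column names.
#' @param spec an [hsm_spec()].
#' @return list of model runs; each has `algorithm`, `fold`, `model`,
#'   `eval` (from [evaluate_predictions()]) and the held-out row indices.
#' @export
fit_models <- function(data, vars, spec = hsm_spec()) {
  stopifnot(all(c("label", "fold") %in% names(data)), all(vars %in% names(data)))
  folds <- sort(unique(data$fold))
  seeds <- .with_seed(spec$rng_seed,
                      sample.int(.Machine$integer.max,
                                 length(spec$algorithms) * length(folds)))
  runs <- list()
  i <- 0L
  for (alg in spec$algorithms) {
    for (k in folds) {
      i <- i + 1L
      tr <- data$fold != k
      te <- !tr
      ytr <- data$label[tr]
      if (length(unique(ytr)) < 2 || sum(te) == 0 ||
          length(unique(data$label[te])) < 2) {
        warning(sprintf("run %s/fold %d skipped: single-class data", alg, k))
        next
      }
      Xtr <- data[tr, vars, drop = FALSE]
      model <- if (alg == "rf") .fit_rf(Xtr, ytr, spec, seeds[i])
               else .fit_gbm(Xtr, ytr, spec, seeds[i])
      run <- list(algorithm = alg, fold = k, model = model, seed = seeds[i],
                  test_idx = which(te))
      scores <- .predict_run(run, data[te, vars, drop = FALSE])
      run$eval <- evaluate_predictions(scores, data$label[te])
      runs[[length(runs) + 1L]] <- run
    }
  }
  runs
}

#' Permutation variable importance for one model run
#'
#' For each predictor: over `n_reps` replicates, permute that column of the
#' evaluation data, re-predict, and score 1 minus the Pearson correlation
#' between the original and permuted-variable predictions; report the
#' replicate mean. If permuted predictions are constant while the originals
#' are not, the correlation is taken as 0 (importance 1); non-finite
#' replicate scores are excluded from the mean with a count. If the original
#' predictions are constant all importances are 0 with a warning.
#'
#' @param run a model run from [fit_models()].
#' @param data the model data.frame the run was fitted from.
#' @param vars predictor column names.
#' @param n_reps permutation replicates (default 99).
#' @param seed integer seed.
#' @return data.frame: `variable`, `importance`, `n_dropped`.
#' @export
permutation_importance <- function(run, data, vars, n_reps = 99, seed = 1) {
  X <- data[run$test_idx, vars, drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 evaluation points", call. = FALSE)
  orig <- .predict_run(run, X)
  if (stats::sd(orig) == 0) {
    warning("constant original predictions: importances undefined, reported 0")
    return(data.frame(variable = vars, importance = 0, n_dropped = n_reps))
  }
  .with_seed(seed, {
    out <- lapply(vars, function(v) {
      scores <- vapply(seq_len(n_reps), function(rep) {
        Xp <- X
        Xp[[v]] <- X[[v]][sample.int(nrow(X))]
        p <- .predict_run(run, Xp)
        if (stats::sd(p) == 0) return(1)  # cor defined as 0
        1 - stats::cor(orig, p)
      }, 0)
      ok <- is.finite(scores)
      data.frame(variable = v, importance = mean(scores[ok]),
                 n_dropped = sum(!ok), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Aggregate importance across runs
#'
#' Unweighted mean of per-run replicate-mean importances, i.e. the mean
#' relative importance across all models.
#'
#' @param imp_list list of [permutation_importance()] results (one per run).
#' @return data.frame `variable`, `importance`, sorted decreasing.
#' @export
aggregate_importance <- function(imp_list) {
  all <- do.call(rbind, imp_list)
  agg <- stats::aggregate(importance ~ variable, data = all, FUN = mean)
  agg[order(-agg$importance), ]
}

#' TSS-weighted ensemble habitat suitability surface
#'
#' Cell-wise weighted mean of member predictions with weights proportional
#' to each run's TSS (runs with TSS <= 0 are excluded); errors if no run has
#' positive TSS. The result is a convex combination, so it lies within the
#' member prediction range everywhere.
#'
#' @param runs model runs from [fit_models()].
#' @param preds a `predictor_set` to predict over.
#' @param vars predictor names used by the models.
#' @return list: `hsi` (a [seep_raster] in \[0, 1\]), `weights` (data.frame
#'   per run).
#' @export
ensemble_hsi <- function(runs, preds, vars) {
  stopifnot(inherits(preds, "predictor_set"))
  tss <- vapply(runs, function(r) r$eval$tss, 0)
  use <- tss > 0
  if (!any(use)) stop("all runs have TSS <= 0; cannot ensemble", call. = FALSE)
  w <- tss[use] / sum(tss[use])
  ok <- which(preds$valid)
  X <- as.data.frame(lapply(preds$layers[vars], function(l) l$values[ok]))
  acc <- numeric(length(ok))
  live <- runs[use]
  for (i in seq_along(live)) acc <- acc + w[i] * .predict_run(live[[i]], X)
  ref <- preds$layers[[1]]
  m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  m[ok] <- acc
  list(hsi = seep_raster(m, ref$cell_size, ref$origin),
       weights = data.frame(
         algorithm = vapply(live, `[[`, "", "algorithm"),
         fold = vapply(live, function(r) as.integer(r$fold), 0L),
         tss = tss[use], weight = w))
}

#' Response curve of the ensemble to one predictor
#'
#' Evaluation-strip partial response: the focal variable sweeps `n_points`
#' values across its observed range while all other predictors are held at
#' their training-data medians; the mean prediction per algorithm is
#' reported.
#'
#' @param runs model runs from [fit_models()].
#' @param data the model data.frame.
#' @param vars predictor names.
#' @param variable focal predictor name.
#' @param n_points grid resolution (default 100).
#' @return data.frame: `variable`, `value`, `algorithm`, `prediction`.
#' @export
response_curve <- function(runs, data, vars, variable, n_points = 100) {
  if (!variable %in% vars) stop("unknown variable: ", variable, call. = FALSE)
  rng <- range(data[[variable]], na.rm = TRUE)
  grid <- seq(rng[1], rng[2], length.out = n_points)
  med <- vapply(vars, function(v) stats::median(data[[v]], na.rm = TRUE), 0)
  strip <- as.data.frame(as.list(med))[rep(1, n_points), , drop = FALSE]
  names(strip) <- vars
  strip[[variable]] <- grid
  rownames(strip) <- NULL
  out <- list()
  for (alg in unique(vapply(runs, `[[`, "", "algorithm"))) {
    sel <- runs[vapply(runs, `[[`, "", "algorithm") == alg]
    preds <- rowMeans(vapply(sel, function(r) .predict_run(r, strip),
                             numeric(n_points)))
    out[[alg]] <- data.frame(variable = variable, value = grid,
                             algorithm = alg, prediction = preds,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full HSM ensemble analysis
#'
#' End-to-end driver: extract predictor values at presences, sample
#' background, prune collinear predictors (keeping the four distance-to-seep
#' -feature layers — the successional-stage hypothesis set — despite their
#' mutual correlations), assign spatial-block folds, fit all
#' (algorithm x fold) runs, and optionally compute permutation importance
#' and the ensemble surface.
#'
#' @param occ presence data.frame with `x`, `y`.
#' @param preds a `predictor_set`.
#' @param spec an [hsm_spec()].
#' @param keep predictor names exempt from collinearity pruning.
#' @param importance compute permutation importance per run (default TRUE).
#' @param surface compute the full-extent ensemble HSI raster (default FALSE).
#' @return object of class `hsm_result`: list with `runs`, `eval`
#'   (per-run data.frame), `vars`, `prune`, `data`, `design`, and when
#'   requested `importance`, `importance_by_run`, `ensemble`.
#' @export
run_hsm <- function(occ, preds, spec = hsm_spec(),
                    keep = c("d_carbonate", "d_mats", "d_mussels",
                             "d_tubeworms"),
                    importance = TRUE, surface = FALSE) {
  stopifnot(inherits(preds, "predictor_set"), inherits(spec, "hsm_spec"))
  seeds <- .with_seed(spec$rng_seed, sample.int(.Machine$integer.max, 4))
  pres_X <- predictors_at(preds, occ$x, occ$y)
  drop_pres <- !stats::complete.cases(pres_X)
  if (any(drop_pres))
    warning(sprintf("%d presences on nodata cells dropped", sum(drop_pres)))
  bg <- sample_background(preds, n = spec$n_background, seed = seeds[1],
                          presences = occ)
  bg_X <- predictors_at(preds, bg$x, bg$y)
  X <- rbind(pres_X[!drop_pres, , drop = FALSE], bg_X)
  pts <- rbind(occ[!drop_pres, c("x", "y")], bg)
  label <- c(rep(1L, sum(!drop_pres)), rep(0L, nrow(bg)))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; pts <- pts[ok, , drop = FALSE]
  label <- label[ok]

  prune <- prune_collinear(X, threshold = 0.7, keep = intersect(keep, names(X)))
  vars <- prune$kept

  design <- make_blocks(raster_extent(preds$layers[[1]]),
                        presences = pts[label == 1, , drop = FALSE],
                        block_size = spec$block_size, n_folds = spec$n_folds,
                        seed = seeds[2])
  data <- cbind(data.frame(label = label, fold = cv_fold(design, pts$x, pts$y),
                           x = pts$x, y = pts$y), X)
  runs <- fit_models(data, vars, spec)
  eval_df <- do.call(rbind, lapply(runs, function(r)
    data.frame(algorithm = r$algorithm, fold = r$fold, auc = r$eval$auc,
               tss = r$eval$tss, tss_threshold = r$eval$tss_threshold)))
  res <- list(runs = runs, eval = eval_df, vars = vars, prune = prune,
              data = data, design = design, spec = spec)
  if (importance) {
    imp_seeds <- .with_seed(seeds[3],
                            sample.int(.Machine$integer.max, length(runs)))
    res$importance_by_run <- lapply(seq_along(runs), function(i)
      permutation_importance(runs[[i]], data, vars,
                             n_reps = spec$n_importance_reps,
                             seed = imp_seeds[i]))
    res$importance <- aggregate_importance(res$importance_by_run)
  }
  if (surface) res$ensemble <- ensemble_hsi(runs, preds, vars)
  class(res) <- "hsm_result"
  res
}

#' @export
print.hsm_result <- function(x, ...) {
  cat(sprintf("<hsm_result> %d runs (%s), %d predictors\n",
              length(x$runs),
              paste(unique(x$eval$algorithm), collapse = " + "),
              length(x$vars)))
  cat(sprintf("  mean AUC %.3f, mean TSS %.3f\n",
              mean(x$eval$auc), mean(x$eval$tss)))
  if (!is.null(x$importance)) {
    top <- utils::head(x$importance, 3)
    cat("  top importance:",
        paste(sprintf("%s %.2f", top$variable, top$importance),
              collapse = ", "), "\n")
  }
  invisible(x)
}
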