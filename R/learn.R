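#' Default hyperparameter grids for the base classifiers
#'
#' Small fixed grids searched by validation AUC: random forest trees in
#' {100, 500} with depth unlimited or 10; XGBoost depth in {3, 6} and
#' learning rate in {0.1, 0.3} (100 boosting rounds); L2-regularised
#' logistic regression with lambda in {0.1, 0.01, 0.001}; Gaussian naive
#' Bayes has no grid.
#'
#' @return named list of grid data.frames per algorithm.
#' @export
default_grids <- function() {
  list(
    rf  = expand.grid(num.trees = c(100L, 500L), max.depth = c(0L, 10L)),
    xgb = expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3)),
    lr  = data.frame(lambda = c(0.1, 0.01, 0.001)),
    nb  = data.frame(dummy = 0)
  )
}

sample_matrix <- function(run, subset, features) {
  s <- run$samples
  rows <- s[s$subset == subset, , drop = FALSE]
  x <- as.matrix(rows[, features, drop = FALSE])
  x[is.na(x)] <- 0
  list(x = x, y = rows$label)
}

fit_one <- function(algo, x, y, params, seed) {
  set.seed(seed)
  switch(algo,
    rf = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = params$num.trees, max.depth = params$max.depth,
      probability = TRUE, num.threads = 1L, seed = seed),
    nb = e1071::naiveBayes(x = as.data.frame(x), y = factor(y, levels = c(0, 1))),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = 100L, verbose = 0),
    lr = glmnet::glmnet(
      x = x, y = y, family = "binomial", alpha = 0,
      lambda = params$lambda),
    stop("unknown algorithm: ", algo))
}

predict_one <- function(algo, model, x) {
  p <- switch(algo,
    rf = stats::predict(model, data = x, num.threads = 1L)$predictions[, "1"],
    nb = stats::predict(model, newdata = as.data.frame(x), type = "raw")[, "1"],
    xgb = stats::predict(model, newdata = xgboost::xgb.DMatrix(x, nthread = 1L)),
    lr = as.numeric(stats::predict(model, newx = x, type = "response")))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Train one base classifier with validation-tuned hyperparameters
#'
#' Fits on the training subset only; each grid point is scored by AUC on
#' the validation subset and the best point is kept. Deterministic given
#' `seed` (all backends run single-threaded with seeded RNG).
#'
#' @param run a [split_run()] with features assigned.
#' @param algo one of `"rf"`, `"nb"`, `"xgb"`, `"lr"`.
#' @param grid hyperparameter grid data.frame (default from
#'   [default_grids()]).
#' @param seed integer seed.
#' @param features feature columns to use (default: all assigned).
#' @return object of class `base_fit` with the fitted model, chosen grid
#'   point and validation AUC.
#' @export
train_base <- function(run, algo = c("rf", "nb", "xgb", "lr"), grid = NULL,
                       seed = 1L, features = NULL) {
  algo <- match.arg(algo)
  if (is.null(features)) features <- run$feature_subset
  if (is.null(features)) stop("run has no assigned features; call assign_features() first")
  if (is.null(grid)) grid <- default_grids()[[algo]]
  tr <- sample_matrix(run, "train", features)
  va <- sample_matrix(run, "validation", features)
  if (length(unique(tr$y)) < 2L)
    stop("degenerate training set: only one class present")
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    params <- grid[i, , drop = FALSE]
    model <- fit_one(algo, tr$x, tr$y, params, seed)
    val_auc <- auc(va$y, predict_one(algo, model, va$x))
    if (is.null(best) || val_auc > best$val_auc)
      best <- list(model = model, params = params, val_auc = val_auc)
  }
  structure(list(algo = algo, model = best$model, params = best$params,
                 val_auc = best$val_auc, features = features, seed = seed),
            class = "base_fit")
}

#' @export
print.base_fit <- function(x, ...) {
  cat(sprintf("base_fit <%s>: validation AUC %.4f; params: %s\n", x$algo,
              x$val_auc, paste(names(x$params), unlist(x$params),
                               sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predict probabilities from a base fit
#'
#' @param object a `base_fit`.
#' @param newdata matrix or data.frame of feature columns (missing values
#'   imputed as 0).
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.base_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  x[is.na(x)] <- 0
  predict_one(object$algo, object$model, x)
}

#' Train the full model bundle for one run
#'
#' Fits the four base classifiers, then the stacking ensemble: the base
#' models' probabilities on the VALIDATION subset (a 4-column matrix) form
#' the meta-training set with the validation labels as targets, and a small
#' feed-forward network (one hidden layer of 8 logistic units, weight
#' decay 0.01) is fit as the meta classifier. At prediction time the base
#' probabilities of a new pair feed the network.
#'
#' @param run a [split_run()] with features assigned.
#' @param seed integer seed.
#' @param grids per-algorithm grids (default [default_grids()]).
#' @param features feature subset (default: all assigned).
#' @param algos base algorithms to include.
#' @param stacking fit the meta network (default `TRUE`; requires all four
#'   bases).
#' @return object of class `model_bundle` with `base_fits` (named list),
#'   `meta` (nnet or `NULL`), `run_id`, `features`.
#' @export
train_bundle <- function(run, seed = 1L, grids = default_grids(),
                         features = NULL, algos = c("rf", "nb", "xgb", "lr"),
                         stacking = TRUE) {
  if (is.null(features)) features <- run$feature_subset
  base_fits <- lapply(algos, function(a)
    train_base(run, a, grid = grids[[a]], seed = seed, features = features))
  names(base_fits) <- algos
  meta <- NULL
  if (stacking) {
    va <- run$samples[run$samples$subset == "validation", , drop = FALSE]
    meta_x <- vapply(base_fits, function(f) predict(f, va), numeric(nrow(va)))
    colnames(meta_x) <- algos
    set.seed(seed)
    meta <- nnet::nnet(x = meta_x, y = va$label, size = 8L, decay = 0.01,
                       maxit = 500L, entropy = TRUE, trace = FALSE)
  }
  structure(list(run_id = run$run_id, base_fits = base_fits, meta = meta,
                 features = features, seed = seed),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle (run %d): bases [%s]%s\n", x$run_id,
              paste(names(x$base_fits), collapse = ", "),
              if (is.null(x$meta)) "" else " + stacking meta-network"))
  invisible(x)
}

#' Score pairs with every model of a bundle
#'
#' @param object a `model_bundle`.
#' @param newdata data.frame containing the bundle's feature columns.
#' @param ... unused.
#' @return data.frame with one probability column per base model and, if a
#'   meta network was fit, a `stacking` column.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  base_p <- vapply(object$base_fits, function(f) predict(f, newdata),
                   numeric(nrow(newdata)))
  base_p <- matrix(base_p, nrow = nrow(newdata),
                   dimnames = list(NULL, names(object$base_fits)))
  out <- as.data.frame(base_p)
  if (!is.null(object$meta))
    out$stacking <- pmin(pmax(as.numeric(
      stats::predict(object$meta, base_p)), 0), 1)
  out
}

#' Score unlabelled candidate pairs
#'
#' Enumerates (drugs x side effects) minus `used_pairs`, assigns features
#' against the supplied training positives (those of the bundle's own run),
#' and scores each remaining pair. A pair is a predicted positive when its
#' score reaches `threshold`.
#'
#' @param bundle a [train_bundle()] result.
#' @param drugs,side_effects the prediction universe.
#' @param used_pairs an [association_table()] of pairs already used in
#'   train/validation/test (both labels).
#' @param train_positives the bundle run's training positives.
#' @param drug_sims,se_sim similarity matrices as in [assign_features()].
#' @param model which score decides `predicted` (default `"rf"`, the
#'   classifier with the best held-out AUC in this design).
#' @param threshold decision threshold (default 0.5).
#' @return data.frame: drug, side_effect, one score column per model,
#'   `predicted` (logical).
#' @export
predict_candidates <- function(bundle, drugs, side_effects, used_pairs,
                               train_positives, drug_sims, se_sim,
                               model = "rf", threshold = 0.5) {
  all_codes <- seq_len(length(drugs) * length(side_effects))
  used <- pair_codes(used_pairs$drug, used_pairs$side_effect, drugs, side_effects)
  remaining <- codes_to_pairs(setdiff(all_codes, used), drugs, side_effects)
  feats <- pair_feature_values(remaining$drug, remaining$side_effect,
                               train_positives, drug_sims, se_sim)
  feats[is.na(feats)] <- 0
  scores <- predict(bundle, feats)
  out <- cbind(remaining, scores)
  out$predicted <- scores[[model]] >= threshold
  out
}
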