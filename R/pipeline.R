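#' Repeated hold-out evaluation of the similarity-feature pipeline
#'
#' Runs the full evaluation protocol on a prepared universe: filter to
#' side effects with at least `min_drugs` positive drugs and to drugs with
#' computable features, draw `n_runs` balanced negative sets, and for each
#' run split 8:1:1, assign leakage-aware max-similarity features, train the
#' requested models and record AUC plus threshold metrics on the validation
#' and test subsets.
#'
#' @param associations an [association_table()] of known positives.
#' @param drug_sims named list of drug-drug similarity matrices.
#' @param se_sim side-effect similarity matrix or `NULL`.
#' @param n_runs number of hold-out replicates (default 100).
#' @param min_drugs side-effect support threshold (default 5).
#' @param ratios split ratios (default `c(8, 1, 1)`).
#' @param algos base algorithms to train.
#' @param stacking also fit the stacking ensemble (default `FALSE`; needs
#'   all four bases).
#' @param features feature columns to use (default: all available).
#' @param grids hyperparameter grids (default [default_grids()]).
#' @param threshold decision threshold for the counting metrics.
#' @param seed master seed; per-run seeds are derived from it.
#' @return list of class `holdout_result`: `universe`, `per_run` (long
#'   metric data.frame), `averaged` (via [average_metrics()]), `best_run`
#'   (run with highest RF validation AUC, with its bundle and split kept
#'   for candidate prediction).
#' @export
run_holdout <- function(associations, drug_sims, se_sim = NULL,
                        n_runs = 100L, min_drugs = 5L, ratios = c(8, 1, 1),
                        algos = c("rf", "nb", "xgb", "lr"), stacking = FALSE,
                        features = NULL, grids = default_grids(),
                        threshold = 0.5, seed = 1L) {
  uni <- filter_universe(associations, drug_sims, min_drugs)
  negs <- sample_negatives(uni$associations, uni$drugs, uni$side_effects,
                           n_sets = n_runs, seed = seed)
  if (is.null(features))
    features <- c(names(drug_sims), if (!is.null(se_sim)) "se_ah")
  per_run <- list()
  best <- NULL
  for (k in seq_len(n_runs)) {
    run_seed <- (seed + 7919L * k) %% .Machine$integer.max
    run <- split_run(uni$associations, negs[[k]], ratios = ratios,
                     seed = run_seed, run_id = k)
    run <- assign_features(run, drug_sims, se_sim)
    bundle <- train_bundle(run, seed = run_seed, grids = grids,
                           features = intersect(features, run$feature_subset),
                           algos = algos, stacking = stacking)
    for (sub in c("validation", "test")) {
      rows <- run$samples[run$samples$subset == sub, , drop = FALSE]
      scores <- predict(bundle, rows)
      for (m in names(scores)) {
        met <- suppressWarnings(classification_metrics(rows$label, scores[[m]], threshold))
        vals <- c(auc = auc(rows$label, scores[[m]]),
                  precision = met$precision, recall = met$recall,
                  f1 = met$f1, specificity = met$specificity)
        per_run[[length(per_run) + 1L]] <- data.frame(
          run_id = k, model = m, subset = sub,
          metric = names(vals), value = unname(vals))
      }
    }
    rf_val <- if ("rf" %in% names(bundle$base_fits))
      bundle$base_fits$rf$val_auc else bundle$base_fits[[1L]]$val_auc
    if (is.null(best) || rf_val > best$val_auc)
      best <- list(run_id = k, val_auc = rf_val, bundle = bundle, run = run)
  }
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  structure(list(universe = uni, per_run = per_run,
                 averaged = average_metrics(per_run), best_run = best),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  avg <- x$averaged
  cat(sprintf("holdout_result: %d runs, %d drugs x %d side effects, %d positives\n",
              max(x$per_run$run_id), length(x$universe$drugs),
              length(x$universe$side_effects), nrow(x$universe$associations)))
  aucs <- avg[avg$metric == "auc" & avg$subset == "test", ]
  for (i in seq_len(nrow(aucs)))
    cat(sprintf("  mean test AUC %-8s %.4f\n", aucs$model[i], aucs$mean[i]))
  invisible(x)
}

#' Candidate side-effect prediction from a hold-out result
#'
#' Uses the model bundle of the best run (highest RF validation AUC) to
#' score every (drug, side effect) pair of the filtered universe that was
#' not used in that run's train/validation/test samples; features are
#' computed against that run's training positives.
#'
#' @param result a [run_holdout()] result.
#' @param drug_sims,se_sim the similarity matrices used for the run.
#' @param model score column used for the predicted label (default "rf").
#' @param threshold decision threshold (default 0.5).
#' @return data.frame of scored candidate pairs (see
#'   [predict_candidates()]).
#' @export
candidates_from_result <- function(result, drug_sims, se_sim = NULL,
                                   model = "rf", threshold = 0.5) {
  best <- result$best_run
  s <- best$run$samples
  used <- association_table(s$drug, s$side_effect)
  train_pos <- s[s$subset == "train" & s$label == 1L, c("drug", "side_effect")]
  predict_candidates(best$bundle, result$universe$drugs,
                     result$universe$side_effects, used, train_pos,
                     drug_sims, se_sim, model = model, threshold = threshold)
}

#' Feature-combination ablation harness
#'
#' Evaluates the pipeline over subsets of the non-base features added to
#' the base set (indication, target, chemical), mirroring an incremental
#' feature study: all 2^4 combinations of {ddi_d, ddi_n, snp, se_ah} by
#' default.
#'
#' @param associations,drug_sims,se_sim as in [run_holdout()].
#' @param base features always included (default indication, target,
#'   chemical).
#' @param extras features to toggle (default the other four).
#' @param n_runs replicates per combination.
#' @param algos algorithms to evaluate.
#' @param seed master seed.
#' @param ... further arguments to [run_holdout()].
#' @return data.frame: one row per (combination, model, subset) with the
#'   mean AUC.
#' @export
ablation_study <- function(associations, drug_sims, se_sim = NULL,
                           base = c("indication", "target", "chemical"),
                           extras = c("ddi_d", "ddi_n", "snp", "se_ah"),
                           n_runs = 5L, algos = "rf", seed = 1L, ...) {
  combos <- unlist(lapply(0:length(extras), function(k)
    utils::combn(extras, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(extra) {
    feats <- c(base, extra)
    res <- run_holdout(associations, drug_sims,
                       se_sim = if ("se_ah" %in% feats) se_sim else NULL,
                       n_runs = n_runs, algos = algos, features = feats,
                       seed = seed, ...)
    avg <- res$averaged
    avg <- avg[avg$metric == "auc", c("model", "subset", "mean")]
    avg$combination <- paste(c("base", extra), collapse = "+")
    avg$n_extras <- length(extra)
    avg
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
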