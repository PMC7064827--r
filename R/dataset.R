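#' Restrict the modelling universe
#'
#' Iterates to a fixed point: side effects associated with fewer than
#' `min_drugs` drugs are removed, and drugs that have no defined similarity
#' (in any supplied feature matrix) to any drug co-associated with one of
#' their side effects are removed, since the max-similarity feature cannot
#' be computed for them. Dropping a drug can push a side effect below the
#' threshold, so both rules are re-applied until stable.
#'
#' @param assocs an [association_table()] of known positives.
#' @param sims list of drug-drug `similarity_matrix` objects.
#' @param min_drugs minimum number of associated drugs per side effect
#'   (default 5).
#' @return list with elements `drugs`, `side_effects`, `associations`.
#' @export
filter_universe <- function(assocs, sims, min_drugs = 5L) {
  stopifnot(min_drugs >= 1L)
  a <- as.data.frame(assocs)
  n0 <- nrow(a)
  repeat {
    changed <- FALSE
    tab <- table(a$side_effect)
    keep_se <- names(tab)[tab >= min_drugs]
    if (length(keep_se) < length(tab)) {
      a <- a[a$side_effect %in% keep_se, , drop = FALSE]
      changed <- TRUE
    }
    # drug must have >= 1 defined similarity to a co-associated drug
    se_drugs <- split(a$drug, a$side_effect)
    drugs <- unique(a$drug)
    ok <- vapply(drugs, function(d) {
      ses <- a$side_effect[a$drug == d]
      for (se in ses) {
        others <- setdiff(se_drugs[[se]], d)
        if (length(others) == 0L) next
        for (s in sims) {
          if (!(d %in% rownames(s))) next
          ids <- intersect(others, colnames(s))
          if (length(ids) > 0L && any(!is.na(s[d, ids]))) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    if (any(!ok)) {
      a <- a[a$drug %in% drugs[ok], , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  if (nrow(a) == 0L)
    stop(sprintf("universe filtering removed everything (started with %d associations, min_drugs=%d)",
                 n0, min_drugs))
  list(drugs = sort(unique(a$drug)),
       side_effects = sort(unique(a$side_effect)),
       associations = association_table(a$drug, a$side_effect))
}

# integer pair code for (drug index, side-effect index) on a fixed universe
pair_codes <- function(drug, side_effect, drugs, side_effects) {
  (match(side_effect, side_effects) - 1L) * length(drugs) + match(drug, drugs)
}

codes_to_pairs <- function(codes, drugs, side_effects) {
  nd <- length(drugs)
  data.frame(drug = drugs[(codes - 1L) %% nd + 1L],
             side_effect = side_effects[(codes - 1L) %/% nd + 1L],
             stringsAsFactors = FALSE)
}

#' Sample balanced negative pair sets
#'
#' Draws `n_sets` negative association tables from the cross product
#' (drugs x side effects) minus the known positives. Each set has exactly
#' as many pairs as the positive set; pairs are distinct within a set but
#' may recur across sets (sampling with replacement at the set level).
#' Deterministic given `seed`.
#'
#' @param positives an [association_table()].
#' @param drugs,side_effects the universe the negatives are drawn from.
#' @param n_sets number of negative sets (default 100).
#' @param seed integer RNG seed.
#' @return list of `association_table` objects, length `n_sets`.
#' @export
sample_negatives <- function(positives, drugs, side_effects, n_sets = 100L, seed = 1L) {
  n_pos <- nrow(positives)
  total <- length(drugs) * length(side_effects)
  pos_codes <- pair_codes(positives$drug, positives$side_effect, drugs, side_effects)
  if (anyNA(pos_codes)) stop("positives contain drugs/side effects outside the universe")
  neg_space <- setdiff(seq_len(total), pos_codes)
  if (length(neg_space) < n_pos)
    stop(sprintf("negative space too small: %d non-positive pairs < %d positives",
                 length(neg_space), n_pos))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_sets), function(k) {
    codes <- sample(neg_space, n_pos, replace = FALSE)
    p <- codes_to_pairs(codes, drugs, side_effects)
    association_table(p$drug, p$side_effect)
  })
}

#' Partition one positive + negative set into train/validation/test
#'
#' Positives and negatives are shuffled and partitioned independently with
#' the same counts (floor of each of the first ratios, remainder to the last
#' subset), so every subset is exactly class-balanced when
#' `nrow(negatives) == nrow(positives)`.
#'
#' @param positives,negatives [association_table()]s of equal size.
#' @param ratios three positive numbers (default `c(8, 1, 1)`).
#' @param seed integer RNG seed.
#' @param run_id integer identifier carried on the result.
#' @return object of class `split_run`: list with `run_id`, `seed`, and
#'   `samples`, a data.frame with columns `drug`, `side_effect`, `label`
#'   (1/0), `subset` (train/validation/test).
#' @export
split_run <- function(positives, negatives, ratios = c(8, 1, 1), seed = 1L,
                      run_id = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            nrow(positives) == nrow(negatives))
  n <- nrow(positives)
  frac <- ratios / sum(ratios)
  n_tr <- floor(n * frac[1L])
  n_va <- floor(n * frac[2L])
  n_te <- n - n_tr - n_va
  subset_of <- function(perm) {
    s <- character(n)
    s[perm[seq_len(n_tr)]] <- "train"
    s[perm[n_tr + seq_len(n_va)]] <- "validation"
    s[perm[n_tr + n_va + seq_len(n_te)]] <- "test"
    s
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub_pos <- subset_of(sample.int(n))
  sub_neg <- subset_of(sample.int(n))
  samples <- rbind(
    data.frame(drug = positives$drug, side_effect = positives$side_effect,
               label = 1L, subset = sub_pos, stringsAsFactors = FALSE),
    data.frame(drug = negatives$drug, side_effect = negatives$side_effect,
               label = 0L, subset = sub_neg, stringsAsFactors = FALSE))
  rownames(samples) <- NULL
  structure(list(run_id = run_id, seed = seed, samples = samples),
            class = "split_run")
}

#' @export
print.split_run <- function(x, ...) {
  tb <- table(x$samples$subset, x$samples$label)
  cat(sprintf("split_run %d (seed %d): %d samples\n", x$run_id, x$seed,
              nrow(x$samples)))
  print(tb)
  invisible(x)
}

#' Assign leakage-aware maximum-similarity feature values
#'
#' For every sample (d, se) in all three subsets, each drug-drug feature
#' takes the maximum similarity between d and the OTHER drugs positively
#' associated with se in the TRAINING subset only; d itself is always
#' excluded from the candidate set (it can only be there via its own
#' training association). The side-effect hierarchy feature is the mirror
#' image: the maximum similarity between se and the other side effects
#' positively associated with d in training. An empty candidate set or
#' all-undefined similarities leaves the feature missing; with
#' `impute = TRUE` (default) missing values become 0 ("no similar drug
#' known").
#'
#' Validation and test feature values therefore depend only on training
#' labels — no information from held-out labels can leak into them.
#'
#' @param run a [split_run()].
#' @param drug_sims named list of drug-drug `similarity_matrix` objects,
#'   names from `feature_names(drugs_only = TRUE)`.
#' @param se_sim side-effect `similarity_matrix` (tag `se_ah`), or `NULL`
#'   to skip that feature.
#' @param impute impute missing feature values as 0 (default `TRUE`).
#' @return the `split_run` with one numeric feature column appended per
#'   feature.
#' @export
assign_features <- function(run, drug_sims, se_sim = NULL, impute = TRUE) {
  stopifnot(inherits(run, "split_run"))
  s <- run$samples
  train_pos <- s[s$subset == "train" & s$label == 1L, c("drug", "side_effect")]
  feats <- pair_feature_values(s$drug, s$side_effect, train_pos,
                               drug_sims, se_sim)
  if (impute) feats[is.na(feats)] <- 0
  run$samples <- cbind(s[, c("drug", "side_effect", "label", "subset")], feats)
  run$feature_subset <- colnames(feats)
  run
}

# Core feature computation shared by assign_features() and candidate
# scoring: max similarity against training positives, self excluded.
pair_feature_values <- function(drug, side_effect, train_pos, drug_sims, se_sim) {
  n <- length(drug)
  se_to_drugs <- split(train_pos$drug, train_pos$side_effect)
  drug_to_ses <- split(train_pos$side_effect, train_pos$drug)
  max_sim_to <- function(sim, from, candidates) {
    if (length(candidates) == 0L || !(from %in% rownames(sim))) return(NA_real_)
    v <- sim[from, intersect(candidates, colnames(sim))]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else max(v)
  }
  out <- matrix(NA_real_, nrow = n, ncol = 0)
  for (f in names(drug_sims)) {
    sim <- drug_sims[[f]]
    col <- vapply(seq_len(n), function(i) {
      cands <- setdiff(se_to_drugs[[side_effect[i]]], drug[i])
      max_sim_to(sim, drug[i], cands)
    }, numeric(1))
    out <- cbind(out, col)
  }
  colnames(out) <- names(drug_sims)
  if (!is.null(se_sim)) {
    col <- vapply(seq_len(n), function(i) {
      cands <- setdiff(drug_to_ses[[drug[i]]], side_effect[i])
      max_sim_to(se_sim, side_effect[i], cands)
    }, numeric(1))
    out <- cbind(out, se_ah = col)
  }
  as.data.frame(out)
}

#' Serialize a split run as TSV
#'
#' Columns: drug, side_effect, label, subset, then any assigned feature
#' columns (missing as `NA`).
#'
#' @param run a `split_run`.
#' @param path output path.
#' @export
write_split_run <- function(run, path) {
  utils::write.table(run$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
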