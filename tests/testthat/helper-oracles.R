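# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain double loops over pairs, elements and bits.

bf_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0L
  for (x in a) if (any(b == x)) inter <- inter + 1L
  uni <- length(a) + length(b) - inter
  if (uni == 0L) NA_real_ else inter / uni
}

bf_jaccard_matrix <- function(sets) {
  n <- length(sets)
  out <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- bf_jaccard(sets[[i]], sets[[j]])
  out
}

bf_tanimoto_matrix <- function(bits) {
  n <- nrow(bits)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(bits), rownames(bits)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ai <- bits[i, ]; aj <- bits[j, ]
    if (sum(ai) == 0L || sum(aj) == 0L) next
    both <- 0L; either <- 0L
    for (k in seq_along(ai)) {
      if (ai[k] && aj[k]) both <- both + 1L
      if (ai[k] || aj[k]) either <- either + 1L
    }
    out[i, j] <- both / either
  }
  out
}

bf_hierarchy_matrix <- function(assignments, levels) {
  ids <- names(assignments)
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- 0
    for (l in levels) {
      v <- bf_jaccard(assignments[[i]][[l]], assignments[[j]][[l]])
      total <- total + if (is.na(v)) 0 else v
    }
    out[i, j] <- total / length(levels)
  }
  out
}

# scans the training positive list per sample, per feature
bf_assign_features <- function(samples, train_pos, drug_sims, se_sim) {
  n <- nrow(samples)
  feats <- matrix(NA_real_, n, length(drug_sims) + 1,
                  dimnames = list(NULL, c(names(drug_sims), "se_ah")))
  for (i in seq_len(n)) {
    d <- samples$drug[i]; se <- samples$side_effect[i]
    cand_drugs <- unique(train_pos$drug[train_pos$side_effect == se])
    cand_drugs <- cand_drugs[cand_drugs != d]
    for (f in names(drug_sims)) {
      best <- NA_real_
      sim <- drug_sims[[f]]
      for (dp in cand_drugs) {
        if (!(d %in% rownames(sim)) || !(dp %in% rownames(sim))) next
        v <- sim[d, dp]
        if (!is.na(v) && (is.na(best) || v > best)) best <- v
      }
      feats[i, f] <- best
    }
    cand_ses <- unique(train_pos$side_effect[train_pos$drug == d])
    cand_ses <- cand_ses[cand_ses != se]
    best <- NA_real_
    for (sp in cand_ses) {
      if (!(se %in% rownames(se_sim)) || !(sp %in% rownames(se_sim))) next
      v <- se_sim[se, sp]
      if (!is.na(v) && (is.na(best) || v > best)) best <- v
    }
    feats[i, "se_ah"] <- best
  }
  feats
}

bf_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# random small fixtures -------------------------------------------------

random_property_table <- function(n_drugs, feature = "target",
                                  max_elems = 6L, universe = letters) {
  sets <- lapply(seq_len(n_drugs), function(i)
    sample(universe, sample(0:max_elems, 1)))
  names(sets) <- sprintf("D%02d", seq_len(n_drugs))
  property_table(sets, feature)
}

random_hierarchy <- function(n_se) {
  assignments <- lapply(seq_len(n_se), function(i) {
    list(organ = sample(sprintf("org%d", 1:6), sample(0:2, 1)),
         subsystem = sample(sprintf("sub%d", 1:4), sample(0:2, 1)),
         system = sample(sprintf("sys%d", 1:3), sample(0:1, 1)))
  })
  names(assignments) <- sprintf("SE%02d", seq_len(n_se))
  hierarchy_table(assignments)
}

# small cached synthetic bundle shared by the slower end-to-end tests
.adrsim_test_cache <- new.env(parent = emptyenv())

cached_bundle <- function() {
  if (is.null(.adrsim_test_cache$bundle)) {
    .adrsim_test_cache$bundle <- generate_universe(synth_config(seed = 7))
  }
  .adrsim_test_cache$bundle
}

cached_sims <- function() {
  if (is.null(.adrsim_test_cache$sims)) {
    .adrsim_test_cache$sims <- universe_similarities(cached_bundle())
  }
  .adrsim_test_cache$sims
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
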