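make_full_sims <- function(drugs, seed = 1) {
  # a dense similarity matrix so filtering never drops drugs for missingness
  set.seed(seed)
  n <- length(drugs)
  m <- matrix(runif(n * n), n, n, dimnames = list(drugs, drugs))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

test_that("universe filtering enforces the side-effect support threshold", {
  drugs <- sprintf("D%d", 1:8)
  assoc <- association_table(
    c(drugs[1:6], drugs[1:5], drugs[1:2]),
    rep(c("S1", "S2", "S3"), c(6, 5, 2)))
  sims <- list(make_full_sims(drugs))
  out <- filter_universe(assoc, sims, min_drugs = 5)
  expect_setequal(out$side_effects, c("S1", "S2"))
  expect_false("S3" %in% out$associations$side_effect)

  # min_drugs = 1 with all similarities defined is the identity
  out1 <- filter_universe(assoc, sims, min_drugs = 1)
  expect_identical(nrow(out1$associations), nrow(assoc))

  expect_error(filter_universe(assoc, sims, min_drugs = 50), "removed everything")
})

test_that("filtering cascades to a fixed point like the brute-force oracle", {
  # drug D9/D10 have undefined similarity to everyone; removing them pushes
  # S2 below the threshold, which must then be removed too
  drugs <- sprintf("D%d", 1:10)
  sim <- make_full_sims(drugs)
  sim["D9", ] <- NA; sim[, "D9"] <- NA
  sim["D10", ] <- NA; sim[, "D10"] <- NA
  assoc <- association_table(
    c("D1", "D2", "D3", "D4",            # S1: 4 drugs, all similar
      "D5", "D6", "D9", "D10",           # S2: 4 drugs, two undefined
      "D1", "D2", "D5", "D6", "D7"),     # S3: 5 drugs
    rep(c("S1", "S2", "S3"), c(4, 4, 5)))

  oracle <- function(a, min_drugs) {
    repeat {
      n0 <- nrow(a)
      tab <- table(a$side_effect)
      a <- a[a$side_effect %in% names(tab)[tab >= min_drugs], , drop = FALSE]
      drop <- character(0)
      for (d in unique(a$drug)) {
        found <- FALSE
        for (se in a$side_effect[a$drug == d]) {
          others <- setdiff(a$drug[a$side_effect == se], d)
          if (any(!is.na(sim[d, others]))) found <- TRUE
        }
        if (!found) drop <- c(drop, d)
      }
      a <- a[!(a$drug %in% drop), , drop = FALSE]
      if (nrow(a) == n0) return(a)
    }
  }
  got <- filter_universe(assoc, list(sim), min_drugs = 4)
  want <- oracle(as.data.frame(assoc), 4)
  expect_setequal(paste(got$associations$drug, got$associations$side_effect),
                  paste(want$drug, want$side_effect))
  expect_false(any(c("D9", "D10") %in% got$drugs))
  expect_false("S2" %in% got$side_effects)
})

test_that("negative sets are balanced, positive-free and seed-deterministic", {
  drugs <- sprintf("D%d", 1:12)
  ses <- sprintf("S%d", 1:6)
  set.seed(5)
  pos <- association_table(sample(drugs, 20, TRUE), sample(ses, 20, TRUE))
  negs <- sample_negatives(pos, drugs, ses, n_sets = 100, seed = 9)
  pos_keys <- paste(pos$drug, pos$side_effect)
  for (k in seq_along(negs)) {
    expect_identical(nrow(negs[[k]]), nrow(pos))
    keys <- paste(negs[[k]]$drug, negs[[k]]$side_effect)
    expect_identical(anyDuplicated(keys), 0L)
    expect_length(intersect(keys, pos_keys), 0)
  }
  negs2 <- sample_negatives(pos, drugs, ses, n_sets = 100, seed = 9)
  expect_identical(negs, negs2)
  negs3 <- sample_negatives(pos, drugs, ses, n_sets = 1, seed = 10)
  expect_false(identical(negs[[1]], negs3[[1]]))

  tiny <- expand.grid(drug = drugs[1:2], side_effect = ses[1:2])
  all_pos <- association_table(tiny$drug, tiny$side_effect)
  expect_error(sample_negatives(all_pos, drugs[1:2], ses[1:2], 1, 1),
               "negative space")
})

test_that("the 8:1:1 split is exact, disjoint and class-balanced", {
  drugs <- sprintf("D%d", 1:40); ses <- sprintf("S%d", 1:10)
  grid <- expand.grid(drug = drugs, side_effect = ses)
  set.seed(2)
  idx <- sample(nrow(grid), 100)
  pos <- association_table(grid$drug[idx], grid$side_effect[idx])
  neg <- sample_negatives(pos, drugs, ses, 1, seed = 4)[[1]]
  run <- split_run(pos, neg, seed = 3)
  tb <- table(run$samples$subset, run$samples$label)
  expect_identical(unname(tb["train", ]), c(80L, 80L))
  expect_identical(unname(tb["validation", ]), c(10L, 10L))
  expect_identical(unname(tb["test", ]), c(10L, 10L))

  # union of subsets = input, pairwise disjoint within a label
  keys <- paste(run$samples$drug, run$samples$side_effect, run$samples$label)
  expect_identical(anyDuplicated(keys), 0L)
  expect_setequal(keys[run$samples$label == 1],
                  paste(pos$drug, pos$side_effect, 1))

  # determinism
  run2 <- split_run(pos, neg, seed = 3)
  expect_identical(run$samples, run2$samples)
})

test_that("feature assignment takes the max over training co-positives, self excluded", {
  drugs <- c("D1", "D2", "D3")
  sim <- matrix(c(1, 0.4, 0.7,
                  0.4, 1, 0.9,
                  0.7, 0.9, 1), 3, dimnames = list(drugs, drugs))
  se_sim <- matrix(1, 1, 1, dimnames = list("S1", "S1"))
  pos <- association_table(c("D2", "D3"), c("S1", "S1"))
  neg <- association_table(c("D1", "D1"), c("S1x", "S1y"))  # placeholder negatives
  # build a run by hand: all positives in train, plus one test pair (D1,S1)
  run <- structure(list(run_id = 1, seed = 1, samples = data.frame(
    drug = c("D2", "D3", "D1"), side_effect = c("S1", "S1", "S1"),
    label = c(1L, 1L, 0L), subset = c("train", "train", "test"),
    stringsAsFactors = FALSE)), class = "split_run")
  out <- assign_features(run, list(target = sim), se_sim = NULL, impute = FALSE)
  s <- out$samples
  # test pair (D1,S1): max over {D2: 0.4, D3: 0.7} = 0.7
  expect_equal(s$target[s$drug == "D1"], 0.7)
  # train positive (D2,S1): candidates exclude D2 itself -> {D3} -> 0.9
  expect_equal(s$target[s$drug == "D2"], 0.9)

  # no other drug with the side effect -> missing -> imputed 0
  run$samples$side_effect[3] <- "S9"
  run$samples$subset[1:2] <- c("train", "train")
  out2 <- assign_features(run, list(target = sim), se_sim = NULL, impute = TRUE)
  expect_equal(out2$samples$target[3], 0)
})

test_that("all seven features match the exhaustive brute-force oracle on a toy universe", {
  set.seed(29)
  for (trial in 1:10) {
    drugs <- sprintf("D%02d", 1:6); ses <- sprintf("S%d", 1:4)
    drug_sims <- lapply(stats::setNames(feature_names(drugs_only = TRUE),
                                        feature_names(drugs_only = TRUE)),
                        function(f) {
      m <- make_full_sims(drugs, seed = sample.int(1e6, 1))
      m[sample(length(m), 4)] <- NA  # sprinkle undefined entries
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    se_sim <- make_full_sims(ses, seed = sample.int(1e6, 1))
    grid <- expand.grid(drug = drugs, side_effect = ses,
                        stringsAsFactors = FALSE)
    idx <- sample(nrow(grid), 10)
    pos <- association_table(grid$drug[idx], grid$side_effect[idx])
    neg <- sample_negatives(pos, drugs, ses, 1, seed = trial)[[1]]
    run <- split_run(pos, neg, seed = trial)
    out <- assign_features(run, drug_sims, se_sim, impute = FALSE)
    train_pos <- run$samples[run$samples$subset == "train" & run$samples$label == 1,
                             c("drug", "side_effect")]
    want <- bf_assign_features(run$samples, train_pos, drug_sims, se_sim)
    got <- as.matrix(out$samples[, colnames(want)])
    dimnames(got) <- dimnames(want)
    expect_equal(got, want)
  }
})

test_that("held-out feature values depend only on training labels", {
  b <- cached_bundle()
  sims <- cached_sims()
  uni <- filter_universe(b$associations, sims$drug_sims, min_drugs = 5)
  neg <- sample_negatives(uni$associations, uni$drugs, uni$side_effects,
                          1, seed = 21)[[1]]
  run <- split_run(uni$associations, neg, seed = 22)
  full <- assign_features(run, sims$drug_sims, sims$se_sim)

  # delete every non-train label: held-out features must be bit-identical
  redacted <- run
  keep <- redacted$samples$subset == "train"
  redacted$samples <- redacted$samples[keep, , drop = FALSE]
  redone <- assign_features(redacted, sims$drug_sims, sims$se_sim)

  train_full <- full$samples[full$samples$subset == "train", ]
  expect_identical(train_full[, feature_names()],
                   redone$samples[, feature_names()])

  # scrambling the held-out labels must not move any feature value
  scrambled <- run
  held <- scrambled$samples$subset != "train"
  scrambled$samples$label[held] <- 1L - scrambled$samples$label[held]
  rescored <- assign_features(scrambled, sims$drug_sims, sims$se_sim)
  expect_identical(full$samples[, feature_names()],
                   rescored$samples[, feature_names()])
})
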