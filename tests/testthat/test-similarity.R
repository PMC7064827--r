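test_that("jaccard handles overlap, identity, disjoint and the 0/0 case", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_true(is.na(jaccard(character(0), character(0))))
})

test_that("jaccard_matrix matches the brute-force pairwise oracle", {
  pt <- property_table(list(D1 = c("a", "b"), D2 = c("b", "c"),
                            D3 = c("a", "b")), "target")
  m <- jaccard_matrix(pt)
  expect_equal(m["D1", "D3"], 1)
  expect_equal(m["D1", "D2"], 1 / 3)

  single <- jaccard_matrix(property_table(list(D1 = "a"), "target"))
  expect_equal(unclass(single), matrix(1, 1, 1, dimnames = list("D1", "D1")),
               ignore_attr = TRUE)

  set.seed(11)
  for (trial in 1:25) {
    pt <- random_property_table(sample(2:8, 1))
    expect_equal(unclass(jaccard_matrix(pt)), bf_jaccard_matrix(pt$entries),
                 ignore_attr = TRUE)
  }
  # empty-vs-empty pairs are undefined, not 0
  pt <- property_table(list(D1 = character(0), D2 = character(0),
                            D3 = "a"), "target")
  m <- jaccard_matrix(pt)
  expect_true(is.na(m["D1", "D2"]) && is.na(m["D1", "D1"]))
  expect_equal(m["D1", "D3"], 0)
})

test_that("tanimoto_matrix matches a per-bit oracle and respects permutation invariance", {
  bits <- rbind(D1 = c(1, 1, 0, 0), D2 = c(0, 1, 1, 0)) == 1
  m <- tanimoto_matrix(fingerprint_table(bits))
  expect_equal(m["D1", "D2"], 1 / 3)
  expect_equal(m["D1", "D1"], 1)

  set.seed(13)
  bits <- matrix(runif(20 * 64) < 0.3, 20, 64,
                 dimnames = list(sprintf("D%02d", 1:20), NULL))
  bits[3, ] <- FALSE  # all-zero vector => undefined everywhere
  m <- tanimoto_matrix(fingerprint_table(bits))
  expect_equal(unclass(m), bf_tanimoto_matrix(bits), ignore_attr = TRUE)
  expect_true(all(is.na(m["D03", ])))

  perm <- sample(64)
  m2 <- tanimoto_matrix(fingerprint_table(bits[, perm]))
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)

  expect_error(fingerprint_table(matrix(TRUE, 2, 3)), "rownames")
})

test_that("hierarchy similarity averages per-level Jaccard over three levels", {
  h <- hierarchy_table(list(
    S1 = list(organ = "heart", subsystem = "circ", system = "cardio"),
    S2 = list(organ = "heart", subsystem = "circ", system = "cardio"),
    S3 = list(organ = "skin", subsystem = "derm", system = "cardio"),
    S4 = list(organ = "eye", subsystem = "vis", system = "nervous"),
    S5 = list()))
  expect_equal(hierarchy_similarity("S1", "S2", h), 1)
  expect_equal(hierarchy_similarity("S1", "S3", h), 1 / 3)
  expect_equal(hierarchy_similarity("S1", "S4", h), 0)
  expect_equal(hierarchy_similarity("S5", "S1", h), 0)
  expect_equal(hierarchy_similarity("S5", "S5", h), 0)  # all-empty: not even self-similar

  m <- hierarchy_matrix(h)
  expect_equal(unclass(m), bf_hierarchy_matrix(
    lapply(names(h$assignments), function(s) hierarchy_labels(h, s)) |>
      stats::setNames(names(h$assignments)), h$levels), ignore_attr = TRUE)

  set.seed(17)
  for (trial in 1:15) {
    h <- random_hierarchy(sample(2:8, 1))
    got <- unclass(hierarchy_matrix(h))
    want <- bf_hierarchy_matrix(h$assignments, h$levels)
    expect_equal(got, want, ignore_attr = TRUE)
    # self-similarity = (nonempty levels)/3: a both-empty level contributes
    # 0 even to the self pair, so only fully-annotated side effects reach 1
    frac <- vapply(h$assignments, function(a) mean(lengths(a) > 0), numeric(1))
    expect_equal(unname(diag(got)), unname(frac))
  }
})

test_that("network component genes use all shortest paths between targets", {
  go <- list(P1 = "GO:1", P2 = "GO:2", P3 = "GO:3",
             A = "GO:a", B = "GO:b", C = "GO:c", D = "GO:d")
  # path graph P1 - P2 - P3
  net <- ppi_network(c("P1", "P2"), c("P2", "P3"), c(0.9, 0.9))
  tg <- property_table(list(drug = c("P1", "P3")), "target")
  out <- ddi_network_gene_sets(tg, net, go)
  expect_setequal(out$entries$drug, c("GO:1", "GO:2", "GO:3"))
  expect_identical(out$feature_name, "ddi_n")

  # diamond A-B-D / A-C-D: both equally short paths contribute
  net <- ppi_network(c("A", "A", "B", "C"), c("B", "C", "D", "D"),
                     rep(0.9, 4))
  tg <- property_table(list(drug = c("A", "D")), "target")
  out <- ddi_network_gene_sets(tg, net, go)
  expect_setequal(out$entries$drug, c("GO:a", "GO:b", "GO:c", "GO:d"))

  # single in-network target: component = that target
  tg <- property_table(list(drug = "P1"), "target")
  net <- ppi_network(c("P1", "P2"), c("P2", "P3"), c(0.9, 0.9))
  expect_identical(ddi_network_gene_sets(tg, net, go)$entries$drug, "GO:1")

  # adding an edge that creates a new equally-short path only grows the set
  base_net <- ppi_network(c("A", "B"), c("B", "D"), c(0.9, 0.9))
  tg <- property_table(list(drug = c("A", "D")), "target")
  before <- ddi_network_gene_sets(tg, base_net, go)$entries$drug
  bigger <- ppi_network(c("A", "B", "A", "C"), c("B", "D", "C", "D"),
                        rep(0.9, 4))
  after <- ddi_network_gene_sets(tg, bigger, go)$entries$drug
  expect_true(all(before %in% after))

  # low-score edges are filtered out before path finding
  weak <- ppi_network(c("A", "B", "A"), c("B", "D", "D"), c(0.9, 0.9, 0.2))
  out <- ddi_network_gene_sets(tg, weak, go)
  expect_setequal(out$entries$drug, c("GO:a", "GO:b", "GO:d"))
})

test_that("SNP gene sets chain indications through SNPs to regulated genes", {
  ind <- property_table(list(drugA = "dis1", drugB = character(0),
                             drugC = c("dis1", "dis2")), "indication")
  disease_snps <- list(dis1 = "rs1", dis2 = c("rs1", "rs2"))
  snp_genes <- list(rs1 = c("G1", "G2"), rs2 = "G1")
  out <- snp_gene_sets(ind, disease_snps, snp_genes)
  expect_setequal(out$entries$drugA, c("G1", "G2"))
  expect_identical(out$entries$drugB, character(0))
  expect_setequal(out$entries$drugC, c("G1", "G2"))  # overlapping chains dedupe
  expect_identical(out$feature_name, "snp")
})

test_that("SMILES fingerprinting yields identical bits for identical molecules", {
  smiles <- c(d1 = "CCO", d2 = "CCO", d3 = "c1ccccc1O")
  fps <- smiles_to_fingerprints(smiles)
  expect_identical(fps$n_bits, 1024L)
  expect_true(sum(fps$bits["d1", ]) > 0)
  m <- tanimoto_matrix(fps)
  expect_equal(m["d1", "d2"], 1)
  expect_lt(m["d1", "d3"], 1)

  mixed <- c(good = "CCO", bad = "not-a-smiles(((")
  expect_warning(fps2 <- smiles_to_fingerprints(mixed), "unparseable")
  expect_identical(rownames(fps2$bits), "good")
})
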