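#' Configuration for the synthetic input universe
#'
#' The generator emulates the statistical structure the method assumes:
#' drugs fall into latent clusters; drugs in a cluster share property
#' elements (so every drug-drug similarity is high within a cluster and low
#' between), side effects fall into cluster-linked blocks whose anatomical
#' hierarchy is concentrated in few subsystems, and positive associations
#' are concentrated within clusters.
#'
#' @param n_drugs number of drugs (default 200).
#' @param n_side_effects number of side effects (default 80).
#' @param n_clusters latent drug clusters (default 10).
#' @param elements_per_feature size of each cluster's element pool per
#'   property type (default 30).
#' @param p_within_share probability a drug carries each element of its own
#'   cluster's pool (default 0.7).
#' @param p_noise probability a drug carries any given off-cluster element
#'   (default 0.02).
#' @param p_se_within probability of a positive association between a drug
#'   and a side effect of its cluster's block (default 0.6).
#' @param p_se_background probability of a positive association outside the
#'   block (default 0.02).
#' @param hierarchy_branching integer triple: number of systems, subsystems
#'   per system, organs per subsystem (default `c(4, 3, 3)`).
#' @param n_bits fingerprint length (default 128).
#' @param seed integer RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 200L, n_side_effects = 80L,
                         n_clusters = 10L, elements_per_feature = 30L,
                         p_within_share = 0.7, p_noise = 0.02,
                         p_se_within = 0.6, p_se_background = 0.02,
                         hierarchy_branching = c(4L, 3L, 3L),
                         n_bits = 128L, seed = 1L) {
  probs <- c(p_within_share, p_noise, p_se_within, p_se_background)
  stopifnot(all(probs >= 0), all(probs <= 1), n_clusters <= n_drugs,
            length(hierarchy_branching) == 3L)
  if (p_se_within <= p_se_background)
    warning("p_se_within <= p_se_background: associations carry no cluster signal")
  structure(as.list(environment()), class = "synth_config")
}

# drug x element membership for one property type: each cluster owns a pool
# of elements; a drug draws its cluster's elements with p_within_share and
# any other cluster's with p_noise.
synth_property <- function(prefix, drugs, cluster_of, cfg) {
  pools <- lapply(seq_len(cfg$n_clusters), function(k)
    sprintf("%s_c%d_e%d", prefix, k, seq_len(cfg$elements_per_feature)))
  entries <- lapply(seq_along(drugs), function(i) {
    own <- cluster_of[i]
    sets <- lapply(seq_len(cfg$n_clusters), function(k) {
      p <- if (k == own) cfg$p_within_share else cfg$p_noise
      pool <- pools[[k]]
      pool[stats::runif(length(pool)) < p]
    })
    unlist(sets, use.names = FALSE)
  })
  names(entries) <- drugs
  entries
}

#' Generate a complete synthetic input universe
#'
#' Emits every table the pipeline consumes: target and indication property
#' tables; directed DDI triples (drugs of a cluster share interactions with
#' the same partner drugs, types and directions); a PPI network of
#' per-cluster target cliques plus random cross edges, with GO annotations
#' drawn from cluster pools; disease-to-SNP and SNP-to-gene chains hanging
#' off the indications; cluster-templated binary fingerprints; a balanced
#' three-level side-effect hierarchy whose blocks correlate with drug
#' clusters; and positive drug-side-effect associations concentrated within
#' clusters. Ground-truth cluster assignments are included for test
#' assertions. Byte-identical output for a fixed config.
#'
#' @param cfg a [synth_config()].
#' @return list (class `synth_universe`) with elements `config`, `drugs`,
#'   `side_effects`, `drug_cluster`, `se_cluster`, `targets`, `indications`,
#'   `ddi_triples`, `ppi`, `go_annotations`, `disease_snps`, `snp_genes`,
#'   `fingerprints`, `hierarchy`, `associations`.
#' @export
generate_universe <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))
  ses <- sprintf("SE%03d", seq_len(cfg$n_side_effects))
  cluster_of <- rep_len(seq_len(cfg$n_clusters), cfg$n_drugs)
  se_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_side_effects)

  targets <- property_table(synth_property("T", drugs, cluster_of, cfg), "target")
  indications <- property_table(synth_property("DIS", drugs, cluster_of, cfg), "indication")

  # DDI triples: each cluster interacts with a fixed panel of partner drugs
  # under a fixed type/direction, so cluster members share mirrored tokens.
  n_partners <- 6L
  tri <- list()
  for (k in seq_len(cfg$n_clusters)) {
    members <- drugs[cluster_of == k]
    partners <- sample(drugs[cluster_of != k], n_partners)
    types <- sample(1:8, n_partners, replace = TRUE)
    dirs <- sample(c("affects", "affected_by"), n_partners, replace = TRUE)
    for (j in seq_len(n_partners)) {
      hit <- members[stats::runif(length(members)) < cfg$p_within_share]
      if (length(hit) > 0L)
        tri[[length(tri) + 1L]] <- data.frame(
          drug_a = hit, drug_b = partners[j], type = types[j],
          direction = dirs[j], stringsAsFactors = FALSE)
    }
  }
  n_noise <- ceiling(cfg$p_noise * cfg$n_drugs * 10)
  if (n_noise > 0L) {
    a <- sample(drugs, n_noise, replace = TRUE)
    b <- sample(drugs, n_noise, replace = TRUE)
    keep <- a != b
    tri[[length(tri) + 1L]] <- data.frame(
      drug_a = a[keep], drug_b = b[keep],
      type = sample(1:8, sum(keep), replace = TRUE),
      direction = sample(c("affects", "affected_by"), sum(keep), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ddi_triples <- unique(do.call(rbind, tri))
  rownames(ddi_triples) <- NULL

  # PPI: clique over each cluster's target pool + random cross edges
  pool_of <- function(k) sprintf("T_c%d_e%d", k, seq_len(cfg$elements_per_feature))
  edges <- list()
  for (k in seq_len(cfg$n_clusters)) {
    pool <- pool_of(k)
    idx <- t(utils::combn(length(pool), 2L))
    keep <- stats::runif(nrow(idx)) < 0.3  # sparse within-cluster connectivity
    edges[[k]] <- data.frame(a = pool[idx[keep, 1L]], b = pool[idx[keep, 2L]],
                             stringsAsFactors = FALSE)
  }
  all_prot <- unlist(lapply(seq_len(cfg$n_clusters), pool_of))
  n_cross <- cfg$n_clusters * 10L
  ca <- sample(all_prot, n_cross, replace = TRUE)
  cb <- sample(all_prot, n_cross, replace = TRUE)
  keep <- ca != cb
  edges[[length(edges) + 1L]] <- data.frame(a = ca[keep], b = cb[keep],
                                            stringsAsFactors = FALSE)
  ed <- do.call(rbind, edges)
  ppi <- ppi_network(ed$a, ed$b, score = rep(0.9, nrow(ed)))

  # GO annotations: cluster-specific term pools
  go_annotations <- lapply(seq_along(all_prot), function(i) {
    k <- (i - 1L) %/% cfg$elements_per_feature + 1L
    terms <- sprintf("GO_c%d_t%d", k, seq_len(10L))
    terms[stats::runif(10L) < 0.4]
  })
  names(go_annotations) <- all_prot

  # disease -> SNP -> gene chains; diseases are the indication elements
  all_dis <- unlist(lapply(seq_len(cfg$n_clusters), function(k)
    sprintf("DIS_c%d_e%d", k, seq_len(cfg$elements_per_feature))))
  disease_snps <- lapply(seq_along(all_dis), function(i) {
    k <- (i - 1L) %/% cfg$elements_per_feature + 1L
    snps <- sprintf("rs_c%d_%d", k, seq_len(12L))
    sample(snps, 3L)
  })
  names(disease_snps) <- all_dis
  all_snps <- unique(unlist(disease_snps, use.names = FALSE))
  snp_genes <- lapply(all_snps, function(s) {
    k <- sub("^rs_c(\\d+)_.*$", "\\1", s)
    genes <- sprintf("G_c%s_%d", k, seq_len(15L))
    sample(genes, 4L)
  })
  names(snp_genes) <- all_snps

  # fingerprints: cluster template bit vectors with per-drug noise
  templates <- matrix(stats::runif(cfg$n_clusters * cfg$n_bits) < 0.25,
                      nrow = cfg$n_clusters)
  bits <- matrix(FALSE, cfg$n_drugs, cfg$n_bits, dimnames = list(drugs, NULL))
  for (i in seq_len(cfg$n_drugs)) {
    v <- templates[cluster_of[i], ]
    flip <- stats::runif(cfg$n_bits) < 0.05
    bits[i, ] <- xor(v, flip)
  }
  fingerprints <- fingerprint_table(bits)

  # 3-level balanced hierarchy; each cluster's side-effect block is confined
  # to one subsystem so the hierarchy feature carries cluster signal
  br <- cfg$hierarchy_branching
  systems <- sprintf("sys%d", seq_len(br[1L]))
  subsystems <- sprintf("sub%d", seq_len(br[1L] * br[2L]))
  organs <- sprintf("org%d", seq_len(br[1L] * br[2L] * br[3L]))
  sub_system <- rep(systems, each = br[2L])
  org_sub <- rep(subsystems, each = br[3L])
  cluster_sub <- sample(subsystems, cfg$n_clusters, replace = cfg$n_clusters > length(subsystems))
  assignments <- lapply(seq_along(ses), function(i) {
    sub <- cluster_sub[se_cluster[i]]
    organ <- sample(organs[org_sub == sub], 1L)
    list(organ = organ, subsystem = sub,
         system = sub_system[match(sub, subsystems)])
  })
  names(assignments) <- ses
  hierarchy <- hierarchy_table(assignments)

  # positive associations concentrated within clusters
  pw <- outer(cluster_of, se_cluster, "==")
  p <- ifelse(pw, cfg$p_se_within, cfg$p_se_background)
  hit <- matrix(stats::runif(length(p)) < p, nrow = cfg$n_drugs)
  idx <- which(hit, arr.ind = TRUE)
  associations <- association_table(drugs[idx[, 1L]], ses[idx[, 2L]])

  realized <- table(factor(associations$side_effect, levels = ses))
  if (any(realized < 5L))
    warning(sprintf("%d of %d side effects have fewer than 5 positive drugs (min %d)",
                    sum(realized < 5L), length(ses), min(realized)))

  structure(list(config = cfg, drugs = drugs, side_effects = ses,
                 drug_cluster = stats::setNames(cluster_of, drugs),
                 se_cluster = stats::setNames(se_cluster, ses),
                 targets = targets, indications = indications,
                 ddi_triples = ddi_triples, ppi = ppi,
                 go_annotations = go_annotations,
                 disease_snps = disease_snps, snp_genes = snp_genes,
                 fingerprints = fingerprints, hierarchy = hierarchy,
                 associations = associations),
            class = "synth_universe")
}

#' Replace associations with a size-matched uniform random set
#'
#' Negative control: the positive associations are replaced by a uniform
#' random draw of the same size from the full drug-by-side-effect grid;
#' every property table is untouched, so any predictive signal that
#' survives is leakage.
#'
#' @param bundle a [generate_universe()] result.
#' @param seed integer seed for the shuffle.
#' @return the bundle with shuffled `associations`.
#' @export
shuffle_labels <- function(bundle, seed = 1L) {
  stopifnot(inherits(bundle, "synth_universe"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(bundle$associations)
  total <- length(bundle$drugs) * length(bundle$side_effects)
  codes <- sample.int(total, n, replace = FALSE)
  p <- codes_to_pairs(codes, bundle$drugs, bundle$side_effects)
  bundle$associations <- association_table(p$drug, p$side_effect)
  bundle
}

#' Compute all seven similarity matrices of a universe
#'
#' Derives the network (`ddi_n`) and SNP property tables from the bundle's
#' raw inputs, then builds the six drug-drug similarity matrices and the
#' side-effect hierarchy matrix.
#'
#' @param bundle a `synth_universe` (or any list exposing the same
#'   elements).
#' @param ppi_score_min PPI confidence cutoff passed to
#'   [ddi_network_gene_sets()].
#' @return list: `drug_sims` (named list of 6 matrices), `se_sim`.
#' @export
universe_similarities <- function(bundle, ppi_score_min = 0.7) {
  ddi_d <- if (is.data.frame(bundle$ddi_triples)) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    write_ddi_triples(bundle$ddi_triples, tmp)
    read_ddi_triples(tmp)
  } else bundle$ddi_triples
  ddi_n <- ddi_network_gene_sets(bundle$targets, bundle$ppi,
                                 bundle$go_annotations, ppi_score_min)
  snp <- snp_gene_sets(bundle$indications, bundle$disease_snps,
                       bundle$snp_genes)
  pad <- function(pt) {  # ensure every universe drug has an entry
    missing <- setdiff(bundle$drugs, names(pt$entries))
    pt$entries[missing] <- list(character(0))
    property_table(pt$entries[bundle$drugs], pt$feature_name)
  }
  drug_sims <- list(
    ddi_d = jaccard_matrix(pad(ddi_d)),
    ddi_n = jaccard_matrix(pad(ddi_n)),
    snp = jaccard_matrix(pad(snp)),
    indication = jaccard_matrix(pad(bundle$indications)),
    target = jaccard_matrix(pad(bundle$targets)),
    chemical = tanimoto_matrix(bundle$fingerprints))
  list(drug_sims = drug_sims, se_sim = hierarchy_matrix(bundle$hierarchy))
}

#' Serialize a synthetic universe to a directory of TSV files
#'
#' Writes every table in the package's interchange dialects plus a
#' manifest of ground-truth cluster assignments. Byte-identical for a
#' fixed config.
#'
#' @param bundle a `synth_universe`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_property_table(bundle$targets, fp("targets.tsv"))
  write_property_table(bundle$indications, fp("indications.tsv"))
  write_ddi_triples(bundle$ddi_triples, fp("ddi_triples.tsv"))
  write_ppi(bundle$ppi, fp("ppi.tsv"))
  write_map(bundle$go_annotations, fp("go_annotations.tsv"), "# gene\tgo_term")
  write_map(bundle$disease_snps, fp("disease_snps.tsv"), "# disease\tsnp")
  write_map(bundle$snp_genes, fp("snp_genes.tsv"), "# snp\tgene")
  write_fingerprints(bundle$fingerprints, fp("fingerprints.tsv"))
  write_hierarchy(bundle$hierarchy, fp("hierarchy.tsv"))
  write_associations(bundle$associations, fp("associations.tsv"))
  manifest <- data.frame(id = c(names(bundle$drug_cluster), names(bundle$se_cluster)),
                         kind = rep(c("drug", "side_effect"),
                                    c(length(bundle$drug_cluster), length(bundle$se_cluster))),
                         cluster = c(bundle$drug_cluster, bundle$se_cluster))
  utils::write.table(manifest, fp("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
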