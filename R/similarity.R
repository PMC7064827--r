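#' Jaccard coefficient of two finite sets
#'
#' |A ∩ B| / |A ∪ B|. When both sets are empty the ratio is 0/0 and the
#' similarity is undefined; `NA` is returned and propagates as a missing
#' value rather than 0.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return a value in \[0, 1\], or `NA_real_` when both sets are empty.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

# Wrap a symmetric matrix of similarities as a tagged similarity matrix.
# NA marks undefined entries (defined_mask = !is.na()).
similarity_matrix <- function(values, feature_name) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, feature_name = feature_name,
            class = c("similarity_matrix", class(values)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix <%s>: %d x %d (%d undefined entries)\n",
              attr(x, "feature_name"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Sparse incidence matrix (entities x elements) from a list of sets.
incidence_matrix <- function(sets) {
  ids <- names(sets)
  elements <- unique(unlist(sets, use.names = FALSE))
  if (length(elements) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(length(ids), 0L),
                                dimnames = list(ids, NULL)))
  }
  i <- rep(seq_along(sets), lengths(sets))
  j <- match(unlist(sets, use.names = FALSE), elements)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(ids), length(elements)),
                       dimnames = list(ids, elements))
}

#' Pairwise Jaccard similarity matrix over a property table
#'
#' Computes |A ∩ B| / |A ∪ B| for every drug pair via a sparse incidence
#' product. Entries where both drugs have empty property sets are undefined
#' (`NA`); the diagonal is 1 for every drug with a nonempty set.
#'
#' @param table a [property_table()].
#' @return a `similarity_matrix` tagged with the table's feature name.
#' @export
jaccard_matrix <- function(table) {
  stopifnot(inherits(table, "property_table"))
  if (length(table$entries) < 1L) stop("property table has no drugs")
  m <- incidence_matrix(table$entries)
  sizes <- Matrix::rowSums(m)
  inter <- as.matrix(Matrix::tcrossprod(m))
  uni <- outer(sizes, sizes, "+") - inter
  vals <- ifelse(uni > 0, inter / uni, NA_real_)
  dimnames(vals) <- list(names(table$entries), names(table$entries))
  similarity_matrix(vals, table$feature_name)
}

#' Pairwise Tanimoto similarity matrix over binary fingerprints
#'
#' popcount(a AND b) / popcount(a OR b) for every drug pair. Pairs where
#' either fingerprint has no set bit are undefined (`NA`).
#'
#' @param fps a [fingerprint_table()].
#' @return a `similarity_matrix` tagged `chemical`.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_table"))
  b <- fps$bits
  storage.mode(b) <- "double"
  inter <- tcrossprod(b)
  sizes <- rowSums(b)
  uni <- outer(sizes, sizes, "+") - inter
  vals <- inter / pmax(uni, 1)
  undef <- sizes == 0  # no set bit => Tanimoto undefined against anything
  vals[undef, ] <- NA_real_
  vals[, undef] <- NA_real_
  dimnames(vals) <- list(rownames(fps$bits), rownames(fps$bits))
  similarity_matrix(vals, "chemical")
}

#' Path-based binary fingerprints from SMILES
#'
#' Computes Open Babel FP2 path fingerprints (1024 bits) through the
#' ChemmineR/ChemmineOB backend. Unparseable SMILES are dropped with a
#' warning; if the backend is unavailable the call fails with instructions
#' to supply precomputed fingerprints instead (see [read_fingerprints()]).
#'
#' @param smiles named character vector (drug ID -> SMILES string).
#' @param n_bits fingerprint length; FP2 is 1024 bits.
#' @return a [fingerprint_table()].
#' @export
smiles_to_fingerprints <- function(smiles, n_bits = 1024L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES fingerprinting needs the ChemmineR and ChemmineOB packages; ",
         "install them or supply precomputed fingerprints via read_fingerprints()")
  }
  stopifnot(!is.null(names(smiles)))
  # per-molecule parsing so one bad SMILES doesn't sink the batch
  parsed <- lapply(seq_along(smiles), function(i) {
    tryCatch({
      s <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
      if (length(s) != 1L || !all(ChemmineR::validSDF(s))) NULL else s
    }, error = function(e) NULL)
  })
  drop <- vapply(parsed, is.null, logical(1))
  if (any(drop))
    warning(sprintf("dropped %d unparseable SMILES: %s", sum(drop),
                    paste(names(smiles)[drop], collapse = ", ")))
  if (all(drop)) stop("no parseable SMILES")
  sdf <- Reduce(c, parsed[!drop])
  ok <- names(smiles)[!drop]
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  bits <- fp@fpma
  rownames(bits) <- ok
  if (ncol(bits) != n_bits)
    bits <- cbind(bits, matrix(0L, nrow(bits), max(0L, n_bits - ncol(bits))))[, seq_len(n_bits), drop = FALSE]
  fingerprint_table(bits)
}

#' Component-gene GO term sets for the network DDI feature
#'
#' For each drug, takes its targets that are present in the PPI network,
#' finds ALL unweighted shortest paths between every unordered pair of those
#' targets, and unions the proteins on those paths (endpoints included) with
#' the in-network targets themselves to form the drug's component-gene set.
#' Drugs with fewer than two in-network targets use the in-network targets
#' alone. The returned property table maps each drug to the union of GO
#' terms annotated to its component genes.
#'
#' @param targets a `property_table` with `feature_name = "target"`.
#' @param ppi a [ppi_network()].
#' @param go_annotations named list: gene/protein ID -> GO-term character
#'   vector.
#' @param score_min drop PPI edges with confidence below this (default 0.7).
#' @return a `property_table` with `feature_name = "ddi_n"`.
#' @export
ddi_network_gene_sets <- function(targets, ppi, go_annotations, score_min = 0.7) {
  stopifnot(inherits(targets, "property_table"),
            targets$feature_name == "target")
  ppi <- ppi[ppi$score >= score_min, , drop = FALSE]
  if (nrow(ppi) == 0L) stop("PPI network is empty after score filtering")
  g <- igraph::graph_from_data_frame(ppi[, c("a", "b")], directed = FALSE)
  nodes <- igraph::V(g)$name
  entries <- lapply(targets$entries, function(tg) {
    tg_in <- intersect(tg, nodes)
    comp <- tg_in
    if (length(tg_in) >= 2L) {
      for (i in seq_len(length(tg_in) - 1L)) {
        for (j in seq((i + 1L), length(tg_in))) {
          sp <- suppressWarnings(
            igraph::all_shortest_paths(g, from = tg_in[i], to = tg_in[j])$res)
          if (length(sp) > 0L)
            comp <- union(comp, unique(names(unlist(sp))))
        }
      }
    }
    sort(unique(unlist(go_annotations[comp], use.names = FALSE)))
  })
  property_table(entries, "ddi_n")
}

#' SNP-regulated gene sets from drug indications
#'
#' Chains each drug's indications to disease-associated SNPs, then to the
#' genes those SNPs regulate (eQTL links); the drug's property set is the
#' union of regulated genes.
#'
#' @param indications a `property_table` with `feature_name = "indication"`.
#' @param disease_snps named list: disease ID -> SNP IDs.
#' @param snp_genes named list: SNP ID -> regulated gene IDs.
#' @return a `property_table` with `feature_name = "snp"`.
#' @export
snp_gene_sets <- function(indications, disease_snps, snp_genes) {
  stopifnot(inherits(indications, "property_table"),
            indications$feature_name == "indication")
  entries <- lapply(indications$entries, function(dis) {
    snps <- unique(unlist(disease_snps[dis], use.names = FALSE))
    sort(unique(unlist(snp_genes[snps], use.names = FALSE)))
  })
  property_table(entries, "snp")
}

#' Anatomical-hierarchy similarity of two side effects
#'
#' The mean over the hierarchy's levels of the per-level Jaccard similarity
#' of the two label sets. A level where both side effects carry no label
#' contributes 0 (never inflating the mean), so the value is always defined;
#' self-similarity is 1 exactly when at least one level is nonempty.
#'
#' @param se_a,se_b side-effect IDs.
#' @param h a [hierarchy_table()].
#' @return similarity in \[0, 1\].
#' @export
hierarchy_similarity <- function(se_a, se_b, h) {
  la <- hierarchy_labels(h, se_a)
  lb <- hierarchy_labels(h, se_b)
  s <- vapply(h$levels, function(l) {
    v <- jaccard(la[[l]], lb[[l]])
    if (is.na(v)) 0 else v
  }, numeric(1))
  sum(s) / length(h$levels)
}

#' Pairwise anatomical-hierarchy similarity matrix
#'
#' Applies [hierarchy_similarity()] to every pair of side effects in the
#' table, using per-level sparse incidence products.
#'
#' @param h a [hierarchy_table()].
#' @return a `similarity_matrix` tagged `se_ah`.
#' @export
hierarchy_matrix <- function(h) {
  ses <- names(h$assignments)
  if (length(ses) < 1L) stop("hierarchy table has no side effects")
  n <- length(ses)
  acc <- matrix(0, n, n, dimnames = list(ses, ses))
  for (l in h$levels) {
    sets <- lapply(h$assignments, `[[`, l)
    m <- incidence_matrix(sets)
    sizes <- Matrix::rowSums(m)
    inter <- as.matrix(Matrix::tcrossprod(m))
    uni <- outer(sizes, sizes, "+") - inter
    jac <- ifelse(uni > 0, inter / uni, 0)  # both-empty level contributes 0
    acc <- acc + jac
  }
  similarity_matrix(acc / length(h$levels), "se_ah")
}

# Similarity lookup that tolerates entities missing from the matrix
# (absent => undefined).
sim_value <- function(sim, a, b) {
  ids <- rownames(sim)
  if (!(a %in% ids) || !(b %in% ids)) return(NA_real_)
  sim[a, b]
}

#' Write a similarity matrix as TSV
#'
#' Header row/column of entity IDs; values at 6 decimals; undefined as `NA`.
#'
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# feature=%s", attr(sim, "feature_name")), con)
  writeLines(paste(c("id", colnames(sim)), collapse = "\t"), con)
  for (i in seq_len(nrow(sim))) {
    vals <- ifelse(is.na(sim[i, ]), "NA", sprintf("%.6f", sim[i, ]))
    writeLines(paste(c(rownames(sim)[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a similarity matrix TSV written by [write_similarity()]
#'
#' @param path file path.
#' @return a `similarity_matrix`.
#' @export
read_similarity <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  feat <- sub("^#\\s*feature=", "", grep("^#\\s*feature=", lines, value = TRUE)[1L])
  lines <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(p) suppressWarnings(as.numeric(p[-1L])),
                   numeric(length(hdr))))
  dimnames(vals) <- list(ids, hdr)
  similarity_matrix(vals, feat)
}
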