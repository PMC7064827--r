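# Canonical feature names: six drug-drug features plus the side-effect
# hierarchy feature.
DRUG_FEATURES <- c("ddi_d", "ddi_n", "snp", "indication", "target", "chemical")
ALL_FEATURES  <- c(DRUG_FEATURES, "se_ah")

#' Feature names used by the pipeline
#'
#' @param drugs_only if `TRUE`, return only the six drug-drug feature names;
#'   otherwise include the side-effect anatomical-hierarchy feature `se_ah`.
#' @return character vector of feature names.
#' @export
feature_names <- function(drugs_only = FALSE) {
  if (drugs_only) DRUG_FEATURES else ALL_FEATURES
}

read_tsv_rows <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(matrix(character(0), ncol = n_fields))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s row at line %d of '%s': expected %d tab-separated fields, found %d",
                 what, lineno[bad[1L]], path, n_fields, lengths(parts)[bad[1L]]))
  }
  matrix(unlist(parts), ncol = n_fields, byrow = TRUE)
}

#' Construct a property table
#'
#' A property table maps each drug to a finite set of opaque element tokens
#' for one feature type (interaction triples, target IDs, indication IDs,
#' SNP-regulated gene IDs, GO terms).
#'
#' @param entries named list: drug ID -> character vector of element tokens
#'   (duplicates are collapsed).
#' @param feature_name one of `ddi_d`, `ddi_n`, `snp`, `indication`,
#'   `target`, `chemical`.
#' @return an object of class `property_table`.
#' @export
property_table <- function(entries, feature_name) {
  feature_name <- match.arg(feature_name, DRUG_FEATURES)
  if (is.null(names(entries)) && length(entries) > 0L)
    stop("entries must be a named list keyed by drug ID")
  if (any(!nzchar(names(entries))))
    stop("drug IDs must be nonempty strings")
  entries <- lapply(entries, function(x) sort(unique(as.character(x))))
  structure(list(feature_name = feature_name, entries = entries),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("property_table <%s>: %d drugs, %d distinct elements\n",
              x$feature_name, length(x$entries),
              length(unique(unlist(x$entries, use.names = FALSE)))))
  invisible(x)
}

#' Read a two-column drug-element table
#'
#' Reads a TSV of (drug ID, element token) rows into a [property_table()].
#' Lines beginning with `#` are comments; duplicate rows collapse to one
#' set element.
#'
#' @param path file path to a 2-column TSV.
#' @param feature_name feature tag for the resulting table.
#' @param drugs optional character vector of drug IDs that must appear in
#'   the result even with empty sets.
#' @return a `property_table`.
#' @export
read_property_table <- function(path, feature_name, drugs = NULL) {
  m <- read_tsv_rows(path, 2L, "property")
  entries <- if (nrow(m) > 0L) split(m[, 2L], m[, 1L]) else list()
  if (!is.null(drugs)) {
    missing <- setdiff(drugs, names(entries))
    entries[missing] <- list(character(0))
  }
  property_table(entries, feature_name)
}

#' Write a property table as 2-column TSV
#'
#' @param x a `property_table`.
#' @param path output file path.
#' @export
write_property_table <- function(x, path) {
  stopifnot(inherits(x, "property_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# feature=%s", x$feature_name), con)
  for (d in names(x$entries)) {
    if (length(x$entries[[d]]) > 0L)
      writeLines(paste(d, x$entries[[d]], sep = "\t"), con)
  }
  invisible(path)
}

# Serialize a DDI triple token. Direction is "affects" (this drug perturbs
# the partner) or "affected_by".
ddi_token <- function(partner, type, direction) {
  paste(partner, type, direction, sep = "|")
}

flip_direction <- function(direction) {
  ifelse(direction == "affects", "affected_by", "affects")
}

#' Read directed drug-drug interaction triples
#'
#' Reads a 4-column TSV (drug A, drug B, interaction type, direction of A)
#' and builds the `ddi_d` property table: each row gives drug A the token
#' `(B, type, dir_A)` and drug B the mirrored token `(A, type, flip(dir_A))`.
#' Direction must be `affects` or `affected_by`.
#'
#' @param path file path.
#' @return a `property_table` with `feature_name = "ddi_d"`.
#' @export
read_ddi_triples <- function(path) {
  m <- read_tsv_rows(path, 4L, "DDI triple")
  if (nrow(m) == 0L) return(property_table(list(), "ddi_d"))
  bad <- !(m[, 4L] %in% c("affects", "affected_by"))
  if (any(bad))
    stop(sprintf("unknown DDI direction flag '%s' (expected 'affects' or 'affected_by')",
                 m[which(bad)[1L], 4L]))
  a <- m[, 1L]; b <- m[, 2L]; ty <- m[, 3L]; dir_a <- m[, 4L]
  drug <- c(a, b)
  token <- c(ddi_token(b, ty, dir_a), ddi_token(a, ty, flip_direction(dir_a)))
  property_table(split(token, drug), "ddi_d")
}

#' Write DDI triples
#'
#' @param triples data.frame with columns `drug_a`, `drug_b`, `type`,
#'   `direction` (direction of `drug_a`).
#' @param path output path.
#' @export
write_ddi_triples <- function(triples, path) {
  stopifnot(all(c("drug_a", "drug_b", "type", "direction") %in% names(triples)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# drug_a\tdrug_b\ttype\tdirection_of_a", con)
  if (nrow(triples) > 0L)
    writeLines(paste(triples$drug_a, triples$drug_b, triples$type,
                     triples$direction, sep = "\t"), con)
  invisible(path)
}

#' Construct a side-effect anatomical hierarchy table
#'
#' Side effects are categorized at an ordered list of anatomical levels
#' (default organ, subsystem, system); each side effect carries a (possibly
#' empty) label set per level.
#'
#' @param assignments named list: side-effect ID -> named list of per-level
#'   character vectors.
#' @param levels ordered level names; the number of levels is the `n` of the
#'   hierarchy-similarity average.
#' @return an object of class `hierarchy_table`.
#' @export
hierarchy_table <- function(assignments, levels = c("organ", "subsystem", "system")) {
  assignments <- lapply(assignments, function(a) {
    out <- lapply(levels, function(l) {
      v <- a[[l]]
      if (is.null(v)) character(0) else sort(unique(as.character(v)))
    })
    names(out) <- levels
    out
  })
  structure(list(levels = levels, assignments = assignments),
            class = "hierarchy_table")
}

#' @export
print.hierarchy_table <- function(x, ...) {
  cat(sprintf("hierarchy_table: %d side effects over levels [%s]\n",
              length(x$assignments), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Look up a side effect's per-level label sets
#'
#' Side effects absent from the table get all-empty label sets, so lookups
#' are total.
#'
#' @param h a `hierarchy_table`.
#' @param se side-effect ID.
#' @return named list of character vectors, one per level.
#' @export
hierarchy_labels <- function(h, se) {
  a <- h$assignments[[se]]
  if (is.null(a)) {
    a <- lapply(h$levels, function(l) character(0))
    names(a) <- h$levels
  }
  a
}

#' Read a side-effect hierarchy TSV
#'
#' Reads a 3-column TSV (side-effect ID, level name, category label).
#' Duplicate rows collapse; an undeclared level name is an error.
#'
#' @param path file path.
#' @param levels declared level names.
#' @return a `hierarchy_table`.
#' @export
read_hierarchy <- function(path, levels = c("organ", "subsystem", "system")) {
  m <- read_tsv_rows(path, 3L, "hierarchy")
  if (nrow(m) > 0L) {
    bad <- !(m[, 2L] %in% levels)
    if (any(bad))
      stop(sprintf("undeclared hierarchy level '%s' (declared: %s)",
                   m[which(bad)[1L], 2L], paste(levels, collapse = ", ")))
  }
  assignments <- list()
  if (nrow(m) > 0L) {
    for (se in unique(m[, 1L])) {
      rows <- m[m[, 1L] == se, , drop = FALSE]
      assignments[[se]] <- split(rows[, 3L], factor(rows[, 2L], levels = levels))
    }
  }
  hierarchy_table(assignments, levels)
}

#' Write a hierarchy table as TSV
#'
#' @param h a `hierarchy_table`.
#' @param path output path.
#' @export
write_hierarchy <- function(h, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# side_effect\tlevel\tlabel", con)
  for (se in names(h$assignments)) {
    for (l in h$levels) {
      labs <- h$assignments[[se]][[l]]
      if (length(labs) > 0L)
        writeLines(paste(se, l, labs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Construct a drug-side-effect association table
#'
#' @param drug character vector of drug IDs.
#' @param side_effect character vector of side-effect IDs (recycled pairwise
#'   with `drug`).
#' @return data.frame of class `association_table` with unique
#'   (drug, side_effect) rows.
#' @export
association_table <- function(drug, side_effect) {
  drug <- as.character(drug)
  side_effect <- as.character(side_effect)
  stopifnot(length(drug) == length(side_effect))
  if (length(drug) > 0L && (any(!nzchar(drug)) || any(!nzchar(side_effect))))
    stop("association IDs must be nonempty")
  df <- unique(data.frame(drug = as.character(drug),
                          side_effect = as.character(side_effect),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("association_table", "data.frame")
  df
}

#' Read a drug-side-effect association TSV
#'
#' @param path 2-column TSV (drug ID, side-effect ID); `#` lines are comments.
#' @return an `association_table`.
#' @export
read_associations <- function(path) {
  m <- read_tsv_rows(path, 2L, "association")
  association_table(m[, 1L], m[, 2L])
}

#' Write an association table as TSV
#'
#' @param x an `association_table`.
#' @param path output path.
#' @export
write_associations <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# drug\tside_effect", con)
  if (nrow(x) > 0L)
    writeLines(paste(x$drug, x$side_effect, sep = "\t"), con)
  invisible(path)
}

#' Construct an undirected protein-protein interaction network
#'
#' @param a,b character vectors of protein IDs (edge endpoints).
#' @param score optional numeric confidence in \[0, 1\] per edge.
#' @return data.frame of class `ppi_network` with columns `a`, `b`, `score`;
#'   self-loops are rejected, duplicate undirected edges collapse (max score).
#' @export
ppi_network <- function(a, b, score = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(score)) score <- rep(1, length(a))
  if (any(a == b)) stop("PPI network must not contain self-loops")
  if (length(score) > 0 && (any(score < 0) || any(score > 1)))
    stop("PPI edge scores must lie in [0, 1]")
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- data.frame(a = lo, b = hi, score = score, stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[, c("a", "b")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ppi_network", "data.frame")
  df
}

#' Read a PPI edge list
#'
#' @param path 3-column TSV (protein, protein, score in \[0,1\]).
#' @return a `ppi_network`.
#' @export
read_ppi <- function(path) {
  m <- read_tsv_rows(path, 3L, "PPI edge")
  if (nrow(m) == 0L) return(ppi_network(character(0), character(0)))
  ppi_network(m[, 1L], m[, 2L], as.numeric(m[, 3L]))
}

#' Write a PPI edge list as TSV
#'
#' @param x a `ppi_network`.
#' @param path output path.
#' @export
write_ppi <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# protein_a\tprotein_b\tscore", con)
  if (nrow(x) > 0L)
    writeLines(paste(x$a, x$b, format(x$score, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Construct a fingerprint table
#'
#' @param bits logical or 0/1 matrix, one row per drug (rownames are drug
#'   IDs), one column per fingerprint bit.
#' @return object of class `fingerprint_table` with fields `bits`
#'   (logical matrix) and `n_bits`.
#' @export
fingerprint_table <- function(bits) {
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) stop("fingerprint matrix needs drug-ID rownames")
  mode(bits) <- "logical"
  structure(list(bits = bits, n_bits = ncol(bits)), class = "fingerprint_table")
}

#' Read fingerprints from hex-encoded TSV
#'
#' Interchange format: a comment header `# n_bits=<N>` followed by 2-column
#' rows (drug ID, hex bitstring, most significant nibble first).
#'
#' @param path file path.
#' @return a `fingerprint_table`.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grep("^#\\s*n_bits=", lines, value = TRUE)
  if (length(hdr) == 0L) stop("fingerprint file lacks '# n_bits=<N>' header")
  n_bits <- as.integer(sub("^#\\s*n_bits=", "", hdr[1L]))
  m <- read_tsv_rows(path, 2L, "fingerprint")
  nibble <- function(ch) {
    v <- strtoi(ch, 16L)
    c(bitwAnd(v, 8L) > 0L, bitwAnd(v, 4L) > 0L, bitwAnd(v, 2L) > 0L, bitwAnd(v, 1L) > 0L)
  }
  bits <- matrix(FALSE, nrow = nrow(m), ncol = n_bits,
                 dimnames = list(m[, 1L], NULL))
  for (i in seq_len(nrow(m))) {
    chars <- strsplit(tolower(m[i, 2L]), "")[[1L]]
    v <- unlist(lapply(chars, nibble))
    bits[i, ] <- v[seq_len(n_bits)]
  }
  fingerprint_table(bits)
}

#' Write fingerprints as hex-encoded TSV
#'
#' @param fps a `fingerprint_table`.
#' @param path output path.
#' @export
write_fingerprints <- function(fps, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_bits=%d", fps$n_bits), con)
  pad <- (4L - fps$n_bits %% 4L) %% 4L
  for (d in rownames(fps$bits)) {
    v <- c(fps$bits[d, ], rep(FALSE, pad))
    nib <- colSums(matrix(as.integer(v), nrow = 4L) * c(8L, 4L, 2L, 1L))
    writeLines(paste(d, paste(sprintf("%x", nib), collapse = ""), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column key-to-set mapping
#'
#' Generic reader for auxiliary maps: GO annotations (gene, GO term),
#' disease-SNP links (disease, SNP), SNP-gene links (SNP, gene),
#' SMILES (drug, SMILES string — single value per drug).
#'
#' @param path 2-column TSV.
#' @return named list: key -> character vector of values.
#' @export
read_map <- function(path) {
  m <- read_tsv_rows(path, 2L, "map")
  if (nrow(m) == 0L) return(list())
  lapply(split(m[, 2L], m[, 1L]), function(x) sort(unique(x)))
}

#' Write a key-to-set mapping as 2-column TSV
#'
#' @param map named list: key -> character vector.
#' @param path output path.
#' @param header comment line to write first.
#' @export
write_map <- function(map, path, header = "# key\tvalue") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  for (k in names(map)) {
    if (length(map[[k]]) > 0L)
      writeLines(paste(k, map[[k]], sep = "\t"), con)
  }
  invisible(path)
}
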