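# Readers/writers for the tabular and tree formats the pipeline touches,
# plus the validators that define the domain types. Community, metabolite
# and distance tables travel as tibbles whose first column holds the feature
# or sample identifier; trees are ape "phylo" objects.

#' Read a community (OTU/ASV) count table from TSV
#'
#' The canonical on-disk orientation is taxa as rows and samples as columns;
#' `orientation = "samples-rows"` accepts the transpose and normalizes it.
#' The first column of the file holds identifiers, the remaining columns are
#' numeric abundances.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation Either `"taxa-rows"` (default) or `"samples-rows"`.
#' @return A tibble with a `taxon_id` column followed by one numeric column
#'   per sample.
#' @export
read_community_table <- function(path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  tbl <- read_id_table(path, id_name = if (orientation == "taxa-rows") "taxon_id" else "sample_id")
  if (orientation == "samples-rows") {
    tbl <- transpose_id_table(tbl, new_id = "taxon_id")
  }
  validate_community_table(tbl)
  tbl
}

#' Write a community table to TSV (taxa as rows)
#'
#' @param table Community tibble as returned by [read_community_table()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_community_table <- function(table, path) {
  validate_community_table(table)
  readr::write_tsv(table, path)
  invisible(table)
}

#' Read a metabolite intensity table from TSV
#'
#' Same layout as a community table with metabolites as rows: first column
#' `metabolite_id`, one numeric column per sample. Intensities must be
#' non-negative.
#'
#' @inheritParams read_community_table
#' @return A tibble with a `metabolite_id` column followed by numeric sample
#'   columns.
#' @export
read_metabolite_table <- function(path) {
  tbl <- read_id_table(path, id_name = "metabolite_id")
  validate_feature_table(tbl, id_col = "metabolite_id", what = "metabolite table")
  tbl
}

#' @rdname read_metabolite_table
#' @param table Metabolite tibble.
#' @export
write_metabolite_table <- function(table, path) {
  validate_feature_table(table, id_col = "metabolite_id", what = "metabolite table")
  readr::write_tsv(table, path)
  invisible(table)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the checks the downstream UniFrac code
#' relies on: unique leaf labels, a rooted topology, and non-negative branch
#' lengths. Trees without branch lengths load with all lengths set to 0 and
#' a warning, so purely topological toy trees remain usable.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("failed to parse Newick file '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("failed to parse Newick file '", path, "' (unbalanced parentheses or empty file?)", call. = FALSE)
  }
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree An `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels in tree: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all lengths to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  tree
}

#' Read a taxonomy table
#'
#' Two dialects are supported. `"lineage"` expects two columns, `taxon_id`
#' and a QIIME-style lineage string with rank prefixes
#' (`k__...;p__...;c__...;o__...;f__...;g__...`); empty ranks become
#' missing. `"rank-columns"` expects a `taxon_id` column followed by one
#' column per rank (kingdom through genus).
#'
#' @param path Path to a TSV file.
#' @param dialect `"lineage"` (default) or `"rank-columns"`.
#' @return A tibble with columns `taxon_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus` (missing ranks are `NA`).
#' @export
read_taxonomy <- function(path, dialect = c("lineage", "rank-columns")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) stop("taxonomy file needs at least two columns", call. = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate taxon ids in taxonomy file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (dialect == "lineage") {
    ranks <- parse_lineage_strings(raw[[2]])
  } else {
    if (ncol(raw) < 1 + length(TAXONOMIC_RANKS)) {
      stop("rank-columns taxonomy needs ", length(TAXONOMIC_RANKS),
           " rank columns after the id column", call. = FALSE)
    }
    ranks <- raw[, 2:(1 + length(TAXONOMIC_RANKS))]
    names(ranks) <- TAXONOMIC_RANKS
    ranks <- dplyr::mutate(ranks, dplyr::across(
      dplyr::everything(), ~ dplyr::if_else(is.na(.x) | .x == "", NA_character_, .x)))
  }
  dplyr::bind_cols(tibble::tibble(taxon_id = ids), ranks)
}

parse_lineage_strings <- function(lineages) {
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    out <- rep(NA_character_, length(TAXONOMIC_RANKS))
    for (piece in p) {
      hit <- match(substr(piece, 1, 3), RANK_PREFIXES)
      if (!is.na(hit)) {
        val <- substr(piece, 4, nchar(piece))
        if (nzchar(val)) out[hit] <- val
      }
    }
    out
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- TAXONOMIC_RANKS
  tibble::as_tibble(mat)
}

#' Write a taxonomy table
#'
#' @param taxonomy Taxonomy tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @param dialect `"lineage"` or `"rank-columns"`.
#' @export
write_taxonomy <- function(taxonomy, path, dialect = c("lineage", "rank-columns")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("taxon_id", TAXONOMIC_RANKS) %in% names(taxonomy)))
  if (dialect == "lineage") {
    lin <- apply(as.matrix(taxonomy[, TAXONOMIC_RANKS]), 1, function(r) {
      paste0(RANK_PREFIXES, ifelse(is.na(r), "", r), collapse = ";")
    })
    out <- tibble::tibble(taxon_id = taxonomy$taxon_id, lineage = lin)
  } else {
    out <- taxonomy[, c("taxon_id", TAXONOMIC_RANKS)]
  }
  readr::write_tsv(out, path)
  invisible(taxonomy)
}

#' Look up the taxonomic group of taxa at a given rank
#'
#' Taxa absent from the taxonomy, or with a missing value at the requested
#' rank, map to `"unassigned"`.
#'
#' @param taxonomy Taxonomy tibble.
#' @param taxa Character vector of taxon ids.
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @return Character vector of group labels, one per taxon.
#' @export
taxonomy_rank <- function(taxonomy, taxa, rank = "phylum") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  idx <- match(taxa, taxonomy$taxon_id)
  out <- taxonomy[[rank]][idx]
  out[is.na(out)] <- "unassigned"
  out
}

#' Read / write a sample-by-sample distance matrix
#'
#' TSV layout: header row of sample ids, first column of sample ids, square
#' numeric body. Validated to be symmetric (within 1e-10), zero on the
#' diagonal and non-negative.
#'
#' @param path File path.
#' @return A square numeric matrix with sample ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  tbl <- read_id_table(path, id_name = "sample_id")
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$sample_id
  validate_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param D Square distance matrix with dimnames.
#' @export
write_distance_matrix <- function(D, path) {
  validate_distance_matrix(D)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(D)),
                          tibble::as_tibble(D))
  readr::write_tsv(out, path)
  invisible(D)
}

#' Validate a distance matrix
#'
#' @param D Numeric matrix.
#' @param tol Symmetry tolerance.
#' @return `D`, invisibly, or an error.
#' @export
validate_distance_matrix <- function(D, tol = 1e-10) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(D)) || is.null(colnames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix must carry matching sample ids as dimnames", call. = FALSE)
  }
  if (any(abs(D - t(D)) > tol)) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(D)) > tol)) stop("distance matrix has a nonzero diagonal", call. = FALSE)
  if (any(D < -tol)) stop("distance matrix has negative entries", call. = FALSE)
  invisible(D)
}

#' Validate a community table
#'
#' Checks the community-table invariants: a `taxon_id` first column, unique
#' taxon and sample ids, numeric non-negative counts.
#'
#' @param table Community tibble.
#' @return The table, invisibly, or an error.
#' @export
validate_community_table <- function(table) {
  validate_feature_table(table, id_col = "taxon_id", what = "community table")
}

validate_feature_table <- function(table, id_col, what) {
  if (!is.data.frame(table) || ncol(table) < 2) {
    stop(what, " must be a data frame with an id column and at least one sample column",
         call. = FALSE)
  }
  if (names(table)[1] != id_col) {
    stop(what, " must have '", id_col, "' as its first column (found '",
         names(table)[1], "')", call. = FALSE)
  }
  ids <- table[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", what, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samp <- names(table)[-1]
  if (anyDuplicated(samp)) {
    stop("duplicate sample ids in ", what, call. = FALSE)
  }
  for (col in samp) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      stop("non-numeric values in ", what, ", column '", col, "'", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing values in ", what, ", column '", col, "'", call. = FALSE)
    }
    if (any(v < 0)) {
      bad <- ids[which(v < 0)[1]]
      stop("negative value in ", what, " at row '", bad, "', column '", col, "'",
           call. = FALSE)
    }
  }
  invisible(table)
}

# -- internal helpers ---------------------------------------------------------

read_id_table <- function(path, id_name) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) stop("expected an id column plus data columns in ", path, call. = FALSE)
  ids <- as.character(raw[[1]])
  vals <- raw[, -1]
  parsed <- lapply(names(vals), function(col) {
    v <- suppressWarnings(as.numeric(vals[[col]]))
    bad <- which(is.na(v) & !is.na(vals[[col]]) & vals[[col]] != "NA")
    if (length(bad)) {
      stop("non-numeric cell in '", path, "' at row '", ids[bad[1]],
           "', column '", col, "'", call. = FALSE)
    }
    v
  })
  names(parsed) <- names(vals)
  dplyr::bind_cols(tibble::tibble(!!id_name := ids), tibble::as_tibble(parsed))
}

transpose_id_table <- function(tbl, new_id) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  tm <- t(m)
  dplyr::bind_cols(tibble::tibble(!!new_id := rownames(tm)), tibble::as_tibble(tm))
}

# Community tibble -> taxa x samples numeric matrix with dimnames.
comm_matrix <- function(table) {
  m <- as.matrix(table[, -1, drop = FALSE])
  rownames(m) <- table[[1]]
  storage.mode(m) <- "double"
  m
}

# taxa x samples matrix -> community tibble.
comm_tibble <- function(m, id_col = "taxon_id") {
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), tibble::as_tibble(m))
}

# Column-normalize a taxa x samples matrix to relative abundances.
rel_abundance <- function(m) {
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(colnames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2, tot, "/")
}
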