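# Alpha diversity (Chao1, Simpson, Pielou), rarefaction, and the weighted
# UniFrac distance matrix.

#' Per-sample alpha diversity
#'
#' Computes, per sample: observed taxa; the Chao1 richness estimate
#' `S_obs + F1^2 / (2 F2)` when doubletons are present, otherwise the
#' bias-limited form `S_obs + F1 (F1 - 1) / 2` (F1/F2 = number of
#' singletons/doubletons, which is why integer counts are required);
#' Simpson diversity `1 - sum(p_i^2)`; and Pielou evenness
#' `H / ln(S_obs)` with Shannon entropy H in natural log. Pielou is `NA`
#' when a sample has at most one taxon.
#'
#' @param table Community tibble with integer counts.
#' @return A tibble with columns `sample_id`, `observed_taxa`, `chao1`,
#'   `simpson`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  counts <- comm_matrix(table)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("alpha_diversity needs integer counts (Chao1 uses singleton/doubleton counts)",
         call. = FALSE)
  }
  counts <- round(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(colnames(counts), function(s) {
    x <- counts[, s]
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    p <- x / sum(x)
    simpson <- 1 - sum(p^2)
    pielou <- if (s_obs > 1) -sum(p * log(p)) / log(s_obs) else NA_real_
    tibble::tibble(sample_id = s, observed_taxa = s_obs, chao1 = chao1,
                   simpson = simpson, pielou = pielou)
  })
}

#' Rarefy a community table to a fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]). Samples with fewer than `depth` reads are
#' dropped with a warning. Deterministic given the seed.
#'
#' @param table Community tibble with integer counts.
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed.
#' @return A rarefied community tibble (possibly with fewer samples).
#' @export
rarefy_table <- function(table, depth, seed = 1) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  counts <- comm_matrix(table)
  totals <- colSums(counts)
  drop <- totals < depth
  if (all(drop)) stop("all samples have fewer than ", depth, " reads", call. = FALSE)
  if (any(drop)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[drop], collapse = ", "), call. = FALSE)
    counts <- counts[, !drop, drop = FALSE]
  }
  set.seed(seed)
  # vegan warns heuristically when the smallest count exceeds 1; our own
  # below-depth warning is raised above, so silence the chatter
  rar <- t(suppressWarnings(vegan::rrarefy(t(counts), depth)))
  comm_tibble(rar)
}

#' Weighted UniFrac distance matrix
#'
#' Phylogeny-aware dissimilarity between every pair of samples. With
#' per-sample relative abundances p and q, each branch of length b whose
#' descendant leaves hold total abundance P and Q contributes `b * |P - Q|`
#' to the raw distance; the normalized variant (the default) divides by
#' `sum(b * (P + Q))`, bounding the distance in \[0, 1\]. Tree leaves
#' absent from the table count as zero abundance; table taxa absent from
#' the tree are an error.
#'
#' @param table Community tibble (counts or relative abundances; only
#'   within-sample proportions matter).
#' @param tree Rooted `phylo` tree whose leaves cover the table's taxa.
#' @param normalized Use the normalized variant (default `TRUE`).
#' @return A square symmetric matrix with sample ids as dimnames.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  counts <- comm_matrix(table)
  tree <- validate_tree(tree)
  active <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(active, tree$tip.label)
  if (length(missing)) {
    stop("taxa with positive abundance missing from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rel <- rel_abundance(counts)

  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  m <- ncol(rel)
  # per-node abundance totals, accumulated tips-to-root
  A <- matrix(0, n_node, m)
  hit <- intersect(rownames(rel), tree$tip.label)
  A[match(hit, tree$tip.label), ] <- rel[hit, , drop = FALSE]
  for (k in ape::postorder(tree)) {
    A[tree$edge[k, 1], ] <- A[tree$edge[k, 1], ] + A[tree$edge[k, 2], ]
  }
  M <- A[tree$edge[, 2], , drop = FALSE]  # branch x sample abundance
  b <- tree$edge.length

  D <- matrix(0, m, m, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      raw <- sum(b * abs(M[, i] - M[, j]))
      if (normalized) {
        denom <- sum(b * (M[, i] + M[, j]))
        d <- if (denom > 0) raw / denom else 0
      } else {
        d <- raw
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
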