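# Symmetric Procrustes superimposition and the t0 congruence statistic,
# PROTEST permutation significance, and the leave-one-out delta-t taxon
# attribution that asks which taxonomic groups carry the congruence
# between two paired communities.

#' Symmetric Procrustes congruence statistic t0
#'
#' Both configurations are column-centered and scaled to unit Frobenius
#' norm, the narrower one padded with zero columns; the optimal rotation
#' (reflections allowed) comes from the SVD of X'Y = U S V'. Then
#' `t0 = trace(S)` in \[0, 1\], the symmetric Procrustes sum of squares is
#' `m2 = 1 - t0^2`, and `t0 = sqrt(1 - m2)`: 0 means complete
#' disagreement, 1 complete agreement. The protocol is symmetric in its
#' arguments.
#'
#' @param X,Y Sample-by-axis score matrices (e.g. `$vectors` of a
#'   [pcoa()]), or `crosscomm_pcoa` objects. At least 3 rows; identical
#'   row sets. When both carry rownames, Y is aligned to X's row order.
#' @return A `crosscomm_procrustes` object with `t0`, `m2`, `rotation`
#'   (applied to Y), `scale`, `n_samples`; `p_value` and `n_permutations`
#'   are filled by [protest()].
#' @export
procrustes_t0 <- function(X, Y) {
  prep <- procrustes_prepare(X, Y)
  fit <- procrustes_core(prep$X, prep$Y)
  structure(list(t0 = fit$t0, m2 = fit$m2, rotation = fit$rotation,
                 scale = fit$t0, n_samples = nrow(prep$X),
                 p_value = NA_real_, n_permutations = 0L),
            class = "crosscomm_procrustes")
}

#' PROTEST: permutation significance of Procrustes congruence
#'
#' Permutes the row (sample) order of Y and recomputes t0 for each
#' permutation; the p-value uses the add-one estimator
#' `(1 + #\{t_perm >= t0\}) / (n_permutations + 1)`, so it is never 0.
#'
#' @inheritParams procrustes_t0
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return A `crosscomm_procrustes` object with `p_value` set.
#' @export
protest <- function(X, Y, n_permutations = 999, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  prep <- procrustes_prepare(X, Y)
  fit <- procrustes_core(prep$X, prep$Y)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(prep$X)
  XtY_t0 <- function(Yp) sum(svd(crossprod(prep$X, Yp))$d)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    t_perm <- XtY_t0(prep$Y[sample.int(n), , drop = FALSE])
    if (t_perm >= fit$t0_raw) exceed <- exceed + 1L
  }
  structure(list(t0 = fit$t0, m2 = fit$m2, rotation = fit$rotation,
                 scale = fit$t0, n_samples = n,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations)),
            class = "crosscomm_procrustes")
}

#' @export
print.crosscomm_procrustes <- function(x, ...) {
  cat(sprintf("Symmetric Procrustes: t0 = %.4f, m2 = %.4f (n = %d)\n",
              x$t0, x$m2, x$n_samples))
  if (!is.na(x$p_value)) {
    cat(sprintf("PROTEST p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' One-row summary of a Procrustes fit
#'
#' @param x A `crosscomm_procrustes` object.
#' @param ... Unused.
#' @export
glance.crosscomm_procrustes <- function(x, ...) {
  tibble::tibble(t0 = x$t0, m2 = x$m2, p_value = x$p_value,
                 n_permutations = x$n_permutations, n_samples = x$n_samples)
}

#' Leave-one-out delta-t taxon attribution
#'
#' Asks which taxonomic groups carry the congruence between two paired
#' communities. The baseline t0 comes from weighted UniFrac -> PCoA
#' (`n_axes` axes) on each community, then symmetric Procrustes between
#' the two sets of sample scores. For each group at `rank`, the group's
#' taxa are removed (by default from both tables), UniFrac, PCoA and t0
#' are recomputed, and `delta_t = t0_prime - t0` is reported: a group that
#' supports the congruence yields a negative delta_t (removing it degrades
#' the match), a group that masks it yields a positive one.
#'
#' Groups whose removal would leave a sample with zero total abundance in
#' either community are skipped with a warning and flagged. Sample
#' correspondence between the two tables is positional: column k of
#' `table_a` is paired with column k of `table_b`.
#'
#' @param table_a,table_b Community tibbles with equally many samples in
#'   matched order.
#' @param tree Rooted tree covering both tables' taxa (shared leaf set).
#' @param taxonomy Taxonomy tibble covering both tables' taxa.
#' @param rank Rank at which groups are removed (default `"phylum"`).
#' @param n_axes PCoA axes used for the Procrustes step (default 2).
#' @param normalized Normalized weighted UniFrac (default `TRUE`).
#' @param side Remove the group from `"both"` tables (default) or from
#'   community A `"one"`-sided.
#' @return A `crosscomm_loo` tibble with columns `group`,
#'   `n_taxa_removed`, `t0_prime`, `delta_t`, `skipped`, and the baseline
#'   t0 in attribute `t0_baseline`.
#' @export
leave_one_out_delta_t <- function(table_a, table_b, tree, taxonomy,
                                  rank = "phylum", n_axes = 2,
                                  normalized = TRUE,
                                  side = c("both", "one")) {
  side <- match.arg(side)
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  counts_a <- comm_matrix(table_a)
  counts_b <- comm_matrix(table_b)
  if (ncol(counts_a) != ncol(counts_b)) {
    stop("table_a and table_b must have the same number of samples", call. = FALSE)
  }
  if (setequal(colnames(counts_a), colnames(counts_b)) &&
      !identical(colnames(counts_a), colnames(counts_b))) {
    stop("table_a and table_b share sample ids but in a different order; ",
         "reorder the columns so corresponding samples align", call. = FALSE)
  }

  t0_of <- function(ca, cb) {
    ord_a <- pcoa(weighted_unifrac(comm_tibble(ca), tree, normalized), n_axes)
    ord_b <- pcoa(weighted_unifrac(comm_tibble(cb), tree, normalized), n_axes)
    xa <- ord_a$vectors
    xb <- ord_b$vectors
    rownames(xb) <- rownames(xa)  # positional sample correspondence
    procrustes_t0(xa, xb)$t0
  }
  t0_base <- suppressWarnings(t0_of(counts_a, counts_b))

  all_taxa <- union(rownames(counts_a), rownames(counts_b))
  groups <- sort(unique(taxonomy_rank(taxonomy, all_taxa, rank)))

  rows <- purrr::map_dfr(groups, function(g) {
    drop_a <- taxonomy_rank(taxonomy, rownames(counts_a), rank) == g
    drop_b <- taxonomy_rank(taxonomy, rownames(counts_b), rank) == g
    ca <- counts_a[!drop_a, , drop = FALSE]
    cb <- if (side == "both") counts_b[!drop_b, , drop = FALSE] else counts_b
    n_removed <- sum(drop_a) + if (side == "both") sum(drop_b) else 0L
    empty <- nrow(ca) == 0 || nrow(cb) == 0 ||
      any(colSums(ca) == 0) || any(colSums(cb) == 0)
    if (empty) {
      warning("skipping group '", g,
              "': removal empties at least one sample", call. = FALSE)
      return(tibble::tibble(group = g, n_taxa_removed = n_removed,
                            t0_prime = NA_real_, delta_t = NA_real_,
                            skipped = TRUE))
    }
    t0p <- suppressWarnings(t0_of(ca, cb))
    tibble::tibble(group = g, n_taxa_removed = n_removed,
                   t0_prime = t0p, delta_t = t0p - t0_base, skipped = FALSE)
  })
  structure(rows, t0_baseline = t0_base,
            class = c("crosscomm_loo", class(rows)))
}

#' One-row summary of a leave-one-out analysis
#'
#' @param x A `crosscomm_loo` table.
#' @param ... Unused.
#' @export
glance.crosscomm_loo <- function(x, ...) {
  done <- x[!x$skipped, ]
  tibble::tibble(t0_baseline = attr(x, "t0_baseline"),
                 n_groups = nrow(x), n_skipped = sum(x$skipped),
                 min_delta_t = if (nrow(done)) min(done$delta_t) else NA_real_,
                 min_delta_group = if (nrow(done)) done$group[which.min(done$delta_t)] else NA_character_)
}

#' Bar plot of leave-one-out delta-t per group
#'
#' @param object A `crosscomm_loo` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosscomm_loo <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!df$skipped, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$group, .data$delta_t),
                                   y = .data$delta_t)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * t == t[0] * minute - t[0])) +
    ggplot2::theme_minimal()
}

# -- internals ----------------------------------------------------------------

# Coerce inputs, align rows, pad columns, center and normalize.
procrustes_prepare <- function(X, Y) {
  X <- procrustes_scores(X)
  Y <- procrustes_scores(Y)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y))) {
      stop("X and Y have different sample (row) sets", call. = FALSE)
    }
    Y <- Y[rownames(X), , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("X and Y have different numbers of rows", call. = FALSE)
  }
  if (nrow(X) < 3) stop("Procrustes needs at least 3 samples", call. = FALSE)
  k <- max(ncol(X), ncol(Y))
  pad <- function(M) {
    if (ncol(M) < k) cbind(M, matrix(0, nrow(M), k - ncol(M))) else M
  }
  X <- pad(X); Y <- pad(Y)
  norm_center <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    nm <- sqrt(sum(M^2))
    if (nm == 0) stop("degenerate configuration: all rows identical", call. = FALSE)
    M / nm
  }
  list(X = norm_center(X), Y = norm_center(Y))
}

procrustes_scores <- function(X) {
  if (inherits(X, "crosscomm_pcoa")) X <- X$vectors
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("configurations must be numeric matrices", call. = FALSE)
  X
}

procrustes_core <- function(Xc, Yc) {
  sv <- svd(crossprod(Xc, Yc))
  t0_raw <- sum(sv$d)            # sum of singular values, <= 1 up to rounding
  t0 <- min(t0_raw, 1)
  list(t0 = t0, t0_raw = t0_raw, m2 = 1 - t0^2,
       rotation = sv$v %*% t(sv$u))
}
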