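# Co-occurrence network construction: a correlation matrix over taxa
# (Spearman on relative abundances, or a basic SparCC estimate),
# permutation-null pseudo-p values, the strict |r| > 0.6 & p < 0.05 edge
# filter, greedy modularity, Zi/Pi node connectivity with the four-way
# role classification, and global network attributes.

#' Taxon-by-taxon correlation matrix
#'
#' `method = "spearman"` computes rank correlation (midranks for ties) of
#' relative abundances across samples. `method = "sparcc"` gives the basic
#' SparCC estimate from log-ratio variances `t_ij = var(log(x_i / x_j))`
#' on pseudocount-added (+1) counts, with the sparsity approximation for
#' component variances and up to 10 exclusion iterations of the
#' most-correlated pair. Taxa with zero variance are excluded with a
#' warning.
#'
#' @param table Community tibble with at least 4 samples.
#' @param method `"spearman"` (default) or `"sparcc"`.
#' @return A square symmetric correlation matrix over the retained taxa.
#' @export
correlation_matrix <- function(table, method = c("spearman", "sparcc")) {
  method <- match.arg(method)
  counts <- comm_matrix(table)
  if (ncol(counts) < 4) stop("need at least 4 samples", call. = FALSE)
  keep <- apply(counts, 1, function(x) var(x) > 0)
  if (!all(keep)) {
    warning("excluding zero-variance taxa: ",
            paste(rownames(counts)[!keep], collapse = ", "), call. = FALSE)
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) < 2) stop("fewer than 2 variable taxa", call. = FALSE)
  if (method == "spearman") {
    r <- cor(t(rel_abundance(counts)), method = "spearman")
  } else {
    r <- sparcc_basic(counts)
  }
  diag(r) <- 1
  r
}

# Basic SparCC: under the sparsity assumption the log-ratio variance
# t_ij = w_i^2 + w_j^2 - 2 rho_ij w_i w_j reduces to t_ij ~ w_i^2 + w_j^2,
# a linear system in the component variances. The most-correlated pair is
# then excluded and the system re-solved, up to 10 times.
sparcc_basic <- function(counts, max_excl = 10, excl_threshold = 0.1) {
  n <- nrow(counts)
  if (n < 4) stop("sparcc needs at least 4 taxa", call. = FALSE)
  frac <- rel_abundance(counts + 1)
  logf <- log(frac)
  Tmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      Tmat[i, j] <- Tmat[j, i] <- var(logf[i, ] - logf[j, ])
    }
  }
  excluded <- matrix(FALSE, n, n)
  rho <- NULL
  for (iter in seq_len(max_excl + 1)) {
    allowed <- !excluded
    diag(allowed) <- FALSE
    A <- (allowed * 1)
    diag(A) <- rowSums(allowed)
    rhs <- rowSums(Tmat * allowed)
    w2 <- tryCatch(solve(A, rhs), error = function(e) rep(NA_real_, n))
    if (anyNA(w2)) break
    w2 <- pmax(w2, 1e-12)
    w <- sqrt(w2)
    rho <- (outer(w2, w2, "+") - Tmat) / (2 * outer(w, w))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (iter > max_excl) break
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[mx[1], mx[2]] <= excl_threshold) break
    excluded[mx[1], mx[2]] <- excluded[mx[2], mx[1]] <- TRUE
  }
  if (is.null(rho)) stop("sparcc estimation failed", call. = FALSE)
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  rho
}

#' Permutation-null pseudo-p values for pairwise correlations
#'
#' Null datasets are built by independently permuting each taxon's values
#' across samples, destroying pairwise association while preserving each
#' taxon's margin. `pseudo_p(i, j) = (1 + #\{null |r| >= observed |r|\}) /
#' (n_boot + 1)`; the diagonal is 0. Deterministic given the seed.
#'
#' @inheritParams correlation_matrix
#' @param n_boot Number of null datasets (default 1000).
#' @param seed Optional integer seed.
#' @return A list with the observed correlation matrix `r` and the
#'   pseudo-p matrix `p` (same dimnames).
#' @export
bootstrap_pseudo_p <- function(table, method = c("spearman", "sparcc"),
                               n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  r_obs <- suppressWarnings(correlation_matrix(table, method))
  counts <- comm_matrix(table)[rownames(r_obs), , drop = FALSE]
  m <- ncol(counts)
  if (!is.null(seed)) set.seed(seed)
  exceed <- matrix(0L, nrow(r_obs), ncol(r_obs))
  abs_obs <- abs(r_obs)
  if (method == "spearman") {
    # correlations depend only on per-taxon ranks, so permute rank rows
    ranks <- t(apply(rel_abundance(counts), 1, rank))
    for (b in seq_len(n_boot)) {
      perm <- t(apply(ranks, 1, function(x) x[sample.int(m)]))
      r_null <- cor(t(perm))
      exceed <- exceed + (abs(r_null) >= abs_obs)
    }
  } else {
    for (b in seq_len(n_boot)) {
      perm <- t(apply(counts, 1, function(x) x[sample.int(m)]))
      rownames(perm) <- rownames(counts)
      r_null <- sparcc_basic(perm)
      exceed <- exceed + (abs(r_null) >= abs_obs)
    }
  }
  p <- (1 + exceed) / (n_boot + 1)
  diag(p) <- 0
  dimnames(p) <- dimnames(r_obs)
  list(r = r_obs, p = p)
}

#' Build a co-occurrence network by thresholding correlations
#'
#' An undirected simple graph keeping the edge (i, j) iff
#' `|r| > r_threshold` AND `p < p_threshold`, both strict. Isolated nodes
#' are retained.
#'
#' @param r Square symmetric correlation matrix with taxon dimnames.
#' @param p Square symmetric pseudo-p matrix, conformable with `r`.
#' @param r_threshold Absolute-correlation threshold (default 0.6).
#' @param p_threshold Pseudo-p threshold (default 0.05).
#' @return A `cooccurrence_network` list with tibbles `nodes`
#'   (`taxon_id`) and `edges` (`from`, `to`, `r`, `pseudo_p`).
#' @export
build_network <- function(r, p, r_threshold = 0.6, p_threshold = 0.05) {
  if (!is.matrix(r) || !is.matrix(p) || !all(dim(r) == dim(p)) ||
      nrow(r) != ncol(r)) {
    stop("r and p must be conformable square matrices", call. = FALSE)
  }
  if (any(abs(r - t(r)) > 1e-8) || any(abs(p - t(p)) > 1e-8)) {
    stop("r and p must be symmetric", call. = FALSE)
  }
  ids <- rownames(r)
  if (is.null(ids)) ids <- paste0("node_", seq_len(nrow(r)))
  idx <- which(upper.tri(r) & abs(r) > r_threshold & p < p_threshold,
               arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          r = r[idx], pseudo_p = p[idx])
  structure(list(nodes = tibble::tibble(taxon_id = ids), edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

network_igraph <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  igraph::graph_from_data_frame(network$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = network$nodes$taxon_id)
}

#' Greedy modularity module detection
#'
#' Clauset-Newman-Moore greedy agglomeration maximizing Newman modularity
#' Q on the unweighted graph (edge presence only). Starting from
#' singleton communities, the pair of edge-connected communities whose
#' merge most increases Q is merged at each step (ties broken by the
#' lowest community-id pair, communities identified by their smallest
#' node index); the partition with the highest Q along the merge path is
#' returned. Deterministic.
#'
#' @param network A `cooccurrence_network`.
#' @return A list with `modules` (tibble `taxon_id`, `module`) and the
#'   achieved `modularity`.
#' @export
greedy_modularity <- function(network) {
  ids <- network$nodes$taxon_id
  n <- length(ids)
  edges <- network$edges
  m <- nrow(edges)
  if (m == 0) {
    return(list(modules = tibble::tibble(taxon_id = ids, module = seq_len(n)),
                modularity = 0))
  }
  ei <- match(edges$from, ids)
  ej <- match(edges$to, ids)

  # e[i, j] (i != j): half the fraction of edges joining communities i and
  # j, stored on both sides; e[i, i]: fraction of edges inside i. Then
  # Q = sum(diag(e)) - sum(a^2) with a = rowSums(e), and merging i, j
  # changes Q by 2 (e_ij - a_i a_j).
  e <- matrix(0, n, n)
  for (k in seq_len(m)) {
    if (ei[k] == ej[k]) next
    e[ei[k], ej[k]] <- e[ei[k], ej[k]] + 1 / (2 * m)
    e[ej[k], ei[k]] <- e[ej[k], ei[k]] + 1 / (2 * m)
  }
  a <- rowSums(e)
  alive <- rep(TRUE, n)
  member <- seq_len(n)          # community id per node (smallest node index)
  q <- -sum(a^2)                # Q of the all-singleton partition
  best_q <- q
  best_member <- member

  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    # best merge among connected community pairs
    best_dq <- -Inf; bi <- 0L; bj <- 0L
    for (i in live) {
      js <- live[live > i]
      js <- js[e[i, js] > 0]
      for (j in js) {
        dq <- 2 * (e[i, j] - a[i] * a[j])
        if (dq > best_dq + 1e-15) { best_dq <- dq; bi <- i; bj <- j }
      }
    }
    if (bi == 0L) break         # no connected pairs left (disconnected graph)
    # merge bj into bi: e_cc = e_ii + e_jj + 2 e_ij, off-diagonals add
    old_ii <- e[bi, bi]; old_jj <- e[bj, bj]; old_ij <- e[bi, bj]
    new_row <- e[bi, ] + e[bj, ]
    e[bi, ] <- new_row
    e[, bi] <- new_row
    e[bi, bi] <- old_ii + old_jj + 2 * old_ij
    e[bj, ] <- 0
    e[, bj] <- 0
    a[bi] <- a[bi] + a[bj]
    alive[bj] <- FALSE
    member[member == bj] <- bi
    q <- q + best_dq
    if (q > best_q + 1e-12) { best_q <- q; best_member <- member }
  }

  # relabel best partition 1..k in order of smallest node index
  first <- match(unique(best_member), best_member)
  lab <- setNames(seq_along(first), best_member[first])
  modules <- tibble::tibble(taxon_id = ids,
                            module = as.integer(lab[as.character(best_member)]))
  g <- network_igraph(network)
  list(modules = modules,
       modularity = igraph::modularity(g, modules$module))
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module s with k_i,s edges into its own module,
#' `Zi = (k_i,s - mean_s) / sd_s` where the mean and (population) standard
#' deviation run over the nodes of s; Zi = 0 when sd_s = 0. With k_i,m
#' edges from i into module m and total degree k_i,
#' `Pi = 1 - sum_m (k_i,m / k_i)^2`; Pi = 0 for isolated nodes.
#'
#' @param network A `cooccurrence_network`.
#' @param modules Module tibble from [greedy_modularity()] (or any tibble
#'   with `taxon_id` and `module` covering every node).
#' @return A tibble with `taxon_id`, `module`, `degree`,
#'   `within_module_degree`, `zi`, `pi`.
#' @export
zi_pi <- function(network, modules) {
  ids <- network$nodes$taxon_id
  mod <- modules$module[match(ids, modules$taxon_id)]
  if (anyNA(mod)) {
    stop("node(s) without a module assignment: ",
         paste(ids[is.na(mod)], collapse = ", "), call. = FALSE)
  }
  edges <- network$edges
  # k[i, m]: edges from node i into module m
  mods <- sort(unique(mod))
  k_im <- matrix(0L, length(ids), length(mods),
                 dimnames = list(ids, as.character(mods)))
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges$from[e]; j <- edges$to[e]
      k_im[i, as.character(mod[match(j, ids)])] <- k_im[i, as.character(mod[match(j, ids)])] + 1L
      k_im[j, as.character(mod[match(i, ids)])] <- k_im[j, as.character(mod[match(i, ids)])] + 1L
    }
  }
  k_i <- rowSums(k_im)
  own <- k_im[cbind(seq_along(ids), match(as.character(mod), colnames(k_im)))]
  zi <- numeric(length(ids))
  for (s in mods) {
    members <- which(mod == s)
    ks <- own[members]
    mu <- mean(ks)
    sdev <- sqrt(mean((ks - mu)^2))  # population sd over the module's nodes
    zi[members] <- if (sdev > 0) (ks - mu) / sdev else 0
  }
  pi_val <- unname(ifelse(k_i > 0, 1 - rowSums((k_im / pmax(k_i, 1))^2), 0))
  tibble::tibble(taxon_id = ids, module = mod, degree = as.integer(k_i),
                 within_module_degree = as.integer(own), zi = unname(zi),
                 pi = pi_val)
}

#' Classify nodes into topological roles from Zi/Pi
#'
#' Peripheral (`Zi < zi_threshold`, `Pi < pi_threshold`), connector
#' (`Zi < zi_threshold`, `Pi >= pi_threshold`), module hub
#' (`Zi >= zi_threshold`, `Pi < pi_threshold`), network hub (both `>=`).
#'
#' @param zipi Tibble from [zi_pi()].
#' @param zi_threshold Within-module connectivity cutoff (default 2.5).
#' @param pi_threshold Among-module connectivity cutoff (default 0.62).
#' @return The input with a `role` factor column added.
#' @export
classify_roles <- function(zipi, zi_threshold = 2.5, pi_threshold = 0.62) {
  hub <- zipi$zi >= zi_threshold
  conn <- zipi$pi >= pi_threshold
  role <- dplyr::case_when(hub & conn ~ "network hub",
                           hub & !conn ~ "module hub",
                           !hub & conn ~ "connector",
                           TRUE ~ "peripheral")
  dplyr::mutate(zipi, role = factor(role, levels = c("peripheral", "connector",
                                                     "module hub", "network hub")))
}

#' Global network attributes
#'
#' Average degree `avgK = 2E / N`, average path distance GD (mean
#' shortest-path length over connected ordered node pairs; unreachable
#' pairs are excluded and counted), and the degree distribution. When
#' `modules` is supplied, modularity and module count are included.
#'
#' @param network A `cooccurrence_network`.
#' @param modules Optional result of [greedy_modularity()].
#' @return A list of class `network_stats` with `n_nodes`, `n_edges`,
#'   `avgK`, `GD`, `n_unreachable_pairs`, `degree_distribution` (tibble),
#'   and optionally `modularity`, `n_modules`.
#' @export
network_stats <- function(network, modules = NULL) {
  g <- network_igraph(network)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  deg <- igraph::degree(g)
  dd <- tibble::as_tibble(as.data.frame(table(degree = deg),
                                        stringsAsFactors = FALSE))
  names(dd) <- c("degree", "count")
  dd$degree <- as.integer(dd$degree)
  dd$count <- as.integer(dd$count)
  sp <- igraph::distances(g)
  off <- sp[row(sp) != col(sp)]
  finite <- is.finite(off)
  gd <- if (any(finite)) mean(off[finite]) else NA_real_
  out <- list(n_nodes = n, n_edges = e, avgK = 2 * e / n, GD = gd,
              n_unreachable_pairs = sum(!finite),
              degree_distribution = dd)
  if (!is.null(modules)) {
    out$modularity <- modules$modularity
    out$n_modules <- length(unique(modules$modules$module))
  }
  structure(out, class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges, avgK = %.3f, GD = %s\n",
              x$n_nodes, x$n_edges, x$avgK,
              if (is.na(x$GD)) "undefined" else sprintf("%.3f", x$GD)))
  if (!is.null(x$modularity)) {
    cat(sprintf("Modularity Q = %.3f over %d modules\n", x$modularity, x$n_modules))
  }
  invisible(x)
}

#' One-row summary of network statistics
#'
#' @param x A `network_stats` object.
#' @param ... Unused.
#' @export
glance.network_stats <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_edges = x$n_edges, avgK = x$avgK,
                 GD = x$GD, n_unreachable_pairs = x$n_unreachable_pairs,
                 modularity = x$modularity %||% NA_real_,
                 n_modules = x$n_modules %||% NA_integer_)
}

#' Zi/Pi role scatter plot
#'
#' @param roles Tibble from [classify_roles()].
#' @param zi_threshold,pi_threshold Thresholds drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_zipi <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(.data$pi, .data$zi, colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module connectivity (Zi)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
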