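# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately written against different primitives than the implementation
# (phangorn clade enumeration for UniFrac, a rotation-angle grid for
# Procrustes, BFS for path lengths, exhaustive search for modularity).

# Small community tibble from a taxa x samples matrix.
toy_table <- function(counts, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- sprintf("taxon_%03d", seq_len(nrow(counts)))
  if (is.null(samples)) samples <- sprintf("sample_%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(taxa, samples)
  dplyr::bind_cols(tibble::tibble(taxon_id = taxa), tibble::as_tibble(counts))
}

table_matrix <- function(table) {
  m <- as.matrix(table[, -1])
  rownames(m) <- table[[1]]
  storage.mode(m) <- "double"
  m
}

random_table <- function(n_taxa, n_samples, max_count = 50, taxa = NULL) {
  counts <- matrix(sample.int(max_count + 1, n_taxa * n_samples, replace = TRUE) - 1L,
                   n_taxa, n_samples)
  # guarantee positive sample totals
  for (j in seq_len(n_samples)) {
    if (sum(counts[, j]) == 0) counts[sample.int(n_taxa, 1), j] <- 1L
  }
  toy_table(counts, taxa = taxa)
}

random_tree <- function(n_leaves) {
  tree <- ape::rtree(n_leaves)
  tree$tip.label <- sprintf("taxon_%03d", seq_len(n_leaves))
  tree
}

# Brute-force weighted UniFrac: enumerate each branch's descendant leaf
# set via phangorn::Descendants and sum b * |P - Q| directly.
unifrac_oracle <- function(table, tree, normalized = TRUE) {
  counts <- table_matrix(table)
  rel <- sweep(counts, 2, colSums(counts), "/")
  m <- ncol(rel)
  abund <- function(tips, s) {
    labs <- tree$tip.label[tips]
    sum(rel[intersect(labs, rownames(rel)), s])
  }
  D <- matrix(0, m, m, dimnames = list(colnames(rel), colnames(rel)))
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      num <- 0; den <- 0
      for (k in seq_len(nrow(tree$edge))) {
        P <- abund(desc[[k]], i)
        Q <- abund(desc[[k]], j)
        num <- num + tree$edge.length[k] * abs(P - Q)
        den <- den + tree$edge.length[k] * (P + Q)
      }
      D[i, j] <- D[j, i] <- if (normalized) {
        if (den > 0) num / den else 0
      } else num
    }
  }
  D
}

# 2D Procrustes t0 by grid search over the rotation angle (reflections
# included), after the same symmetric normalization protocol.
procrustes_grid_oracle <- function(X, Y, resolution = 1e-4) {
  center_norm <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    M / sqrt(sum(M^2))
  }
  Xc <- center_norm(X)
  Yc <- center_norm(Y)
  A <- crossprod(Xc, Yc)
  theta <- seq(0, 2 * pi, by = resolution)
  rot <- cos(theta) * (A[1, 1] + A[2, 2]) + sin(theta) * (A[2, 1] - A[1, 2])
  ref <- cos(theta) * (A[1, 1] - A[2, 2]) + sin(theta) * (A[1, 2] + A[2, 1])
  max(rot, ref)
}

# Mean shortest-path length over connected ordered pairs, by plain BFS on
# an edge list.
gd_bfs_oracle <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges$from[e]]] <- c(adj[[edges$from[e]]], edges$to[e])
    adj[[edges$to[e]]] <- c(adj[[edges$to[e]]], edges$from[e])
  }
  total <- 0; npairs <- 0
  for (s in nodes) {
    dist <- setNames(rep(NA_real_, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    reach <- dist[names(dist) != s & !is.na(dist)]
    total <- total + sum(reach)
    npairs <- npairs + length(reach)
  }
  if (npairs == 0) NA_real_ else total / npairs
}

# Newman modularity of a partition given an edge tibble.
modularity_of <- function(nodes, edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- setNames(rep(0, length(nodes)), nodes)
  for (e in seq_len(m)) {
    deg[edges$from[e]] <- deg[edges$from[e]] + 1
    deg[edges$to[e]] <- deg[edges$to[e]] + 1
  }
  q <- 0
  for (e in seq_len(m)) {
    if (membership[edges$from[e]] == membership[edges$to[e]]) q <- q + 1 / m
  }
  for (c in unique(membership)) {
    dc <- sum(deg[names(membership)[membership == c]])
    q <- q - (dc / (2 * m))^2
  }
  q
}

# 12 nodes: two 6-cliques joined by a single edge.
two_clique_network <- function() {
  nodes <- sprintf("n%02d", 1:12)
  edges <- NULL
  for (grp in list(1:6, 7:12)) {
    for (i in grp) for (j in grp) if (i < j) edges <- rbind(edges, c(i, j))
  }
  edges <- rbind(edges, c(6, 7))
  e <- tibble::tibble(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                      r = 1, pseudo_p = 0)
  structure(list(nodes = tibble::tibble(taxon_id = nodes), edges = e),
            class = "cooccurrence_network")
}
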