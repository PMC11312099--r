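test_that("spearman correlation matrix matches a rank-then-Pearson oracle", {
  set.seed(91)
  tbl <- random_table(5, 8)
  r <- suppressWarnings(correlation_matrix(tbl, "spearman"))
  rel <- sweep(table_matrix(tbl), 2, colSums(table_matrix(tbl)), "/")
  rel <- rel[rownames(r), ]
  # rank each taxon across samples, then plain Pearson
  oracle <- cor(apply(rel, 1, rank), method = "pearson")
  expect_equal(r, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diag(r) == 1))

  # identical count vectors correlate perfectly
  dup <- toy_table(rbind(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5), c(9, 2, 6, 5, 3)))
  rd <- correlation_matrix(dup)
  expect_equal(rd[1, 2], 1)
})

test_that("correlation matrix input contracts hold", {
  expect_error(correlation_matrix(random_table(5, 3)), "4 samples")
  tbl <- random_table(4, 6)
  tbl[1, -1] <- as.list(rep(2, 6))
  expect_warning(r <- correlation_matrix(tbl), "zero-variance")
  expect_false(tbl$taxon_id[1] %in% rownames(r))
})

test_that("sparcc recovers strong associations on compositional data", {
  set.seed(93)
  n <- 40
  base <- exp(matrix(rnorm(8 * n, sd = 0.4), 8, n) + rnorm(8, sd = 1))
  base[2, ] <- base[1, ] * exp(rnorm(n, sd = 0.05))  # tightly coupled pair
  counts <- apply(sweep(base, 2, colSums(base), "/"), 2,
                  function(p) rmultinom(1, 20000, p)[, 1])
  tbl <- toy_table(counts)
  r <- correlation_matrix(tbl, method = "sparcc")
  expect_gt(r["taxon_001", "taxon_002"], 0.5)
  expect_true(all(abs(r) <= 1))
  expect_equal(r, t(r), tolerance = 1e-12)
})

test_that("pseudo-p separates real from null associations", {
  set.seed(97)
  n <- 20
  x <- rlnorm(n)
  counts <- rbind(x * 100, x * 100 * exp(rnorm(n, sd = 0.01)),
                  matrix(rlnorm(3 * n) * 50, 3, n))
  tbl <- toy_table(round(counts) + 1)
  bp <- bootstrap_pseudo_p(tbl, n_boot = 999, seed = 7)
  expect_lte(bp$p["taxon_001", "taxon_002"], 0.01)
  expect_equal(bp$p, t(bp$p))
  expect_true(all(diag(bp$p) == 0))
  # deterministic given seed
  bp2 <- bootstrap_pseudo_p(tbl, n_boot = 999, seed = 7)
  expect_identical(bp$p, bp2$p)
  expect_error(bootstrap_pseudo_p(tbl, n_boot = 0), ">= 1")
})

test_that("pseudo-p is approximately uniform under the null", {
  set.seed(101)
  pvals <- c()
  for (rep in 1:40) {
    tbl <- toy_table(matrix(rlnorm(6 * 16, sdlog = 1) * 10, 6, 16))
    bp <- bootstrap_pseudo_p(tbl, n_boot = 199, seed = rep)
    pvals <- c(pvals, bp$p[upper.tri(bp$p)])
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("edge filter applies strict thresholds", {
  ids <- c("a", "b", "c", "d")
  r <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(r) <- 1
  p <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(p) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.6    # boundary: excluded
  p["a", "b"] <- p["b", "a"] <- 0.001
  r["a", "c"] <- r["c", "a"] <- -0.9   # |r| qualifies, p qualifies
  p["a", "c"] <- p["c", "a"] <- 0.01
  r["b", "d"] <- r["d", "b"] <- 0.95   # p boundary: excluded
  p["b", "d"] <- p["d", "b"] <- 0.05
  r["c", "d"] <- r["d", "c"] <- 0.7
  p["c", "d"] <- p["d", "c"] <- 0.049
  net <- build_network(r, p)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("a c", "c d"))
  expect_equal(nrow(net$nodes), 4)  # isolated nodes retained

  # complete graph when everything qualifies
  r1 <- matrix(1, 4, 4, dimnames = list(ids, ids))
  p0 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_equal(nrow(build_network(r1, p0)$edges), 6)

  expect_error(build_network(r[1:3, ], p), "square")
  r_bad <- r; r_bad[1, 2] <- 0.2
  expect_error(build_network(r_bad, p), "symmetric")
})

test_that("greedy modularity finds the exhaustive-best two-clique split", {
  net <- two_clique_network()
  gm <- greedy_modularity(net)
  expect_equal(length(unique(gm$modules$module)), 2)

  # exhaustive search over all 2-partitions of the 12 nodes
  membership <- setNames(gm$modules$module, gm$modules$taxon_id)
  best_q <- -Inf
  nodes <- net$nodes$taxon_id
  for (mask in 0:(2^11 - 1)) {  # fix node 12's side to halve the space
    side <- c(as.integer(intToBits(mask))[1:11], 0L)
    mb <- setNames(side, nodes)
    q <- modularity_of(nodes, net$edges, mb)
    if (q > best_q) { best_q <- q; best_mb <- mb }
  }
  expect_equal(modularity_of(nodes, net$edges, membership), best_q,
               tolerance = 1e-12)
  expect_equal(gm$modularity, best_q, tolerance = 1e-12)
  # the best 2-partition is the two cliques
  expect_equal(length(unique(best_mb[1:6])), 1)
  expect_equal(length(unique(best_mb[7:12])), 1)

  # disjoint triangles split into their components
  tri <- structure(list(
    nodes = tibble::tibble(taxon_id = letters[1:6]),
    edges = tibble::tibble(from = c("a", "b", "a", "d", "e", "d"),
                           to = c("b", "c", "c", "e", "f", "f"),
                           r = 1, pseudo_p = 0)), class = "cooccurrence_network")
  gm_tri <- greedy_modularity(tri)
  expect_equal(length(unique(gm_tri$modules$module)), 2)

  # complete graph collapses to one module
  ids <- paste0("k", 1:5)
  rk <- matrix(1, 5, 5, dimnames = list(ids, ids))
  pk <- matrix(0, 5, 5, dimnames = list(ids, ids))
  expect_equal(length(unique(greedy_modularity(build_network(rk, pk))$modules$module)), 1)
})

test_that("Zi/Pi match hand-computed values on a two-module toy graph", {
  # module 1: n1..n5 star around n1 plus edge n2-n3; module 2: n6..n10
  # path n6-n7-n8-n9-n10; bridges n1-n6 and n5-n10
  nodes <- paste0("n", 1:10)
  edges <- tibble::tibble(
    from = c("n1", "n1", "n1", "n1", "n2", "n6", "n7", "n8", "n9", "n1", "n5"),
    to   = c("n2", "n3", "n4", "n5", "n3", "n7", "n8", "n9", "n10", "n6", "n10"),
    r = 1, pseudo_p = 0)
  net <- structure(list(nodes = tibble::tibble(taxon_id = nodes), edges = edges),
                   class = "cooccurrence_network")
  modules <- tibble::tibble(taxon_id = nodes, module = rep(1:2, each = 5))
  zp <- zi_pi(net, modules)

  # within-module degrees, module 1: n1 = 4, n2 = 2, n3 = 2, n4 = 1, n5 = 1
  expect_equal(zp$within_module_degree[1:5], c(4L, 2L, 2L, 1L, 1L))
  mu1 <- mean(c(4, 2, 2, 1, 1)); sd1 <- sqrt(mean((c(4, 2, 2, 1, 1) - mu1)^2))
  expect_equal(zp$zi[1], (4 - mu1) / sd1)
  expect_equal(zp$zi[4], (1 - mu1) / sd1)

  # n1: degree 5, 4 within + 1 to module 2 -> Pi = 1 - (4/5)^2 - (1/5)^2
  expect_equal(zp$pi[zp$taxon_id == "n1"], 1 - (4 / 5)^2 - (1 / 5)^2)
  # n4: all edges inside its module -> Pi = 0
  expect_equal(zp$pi[zp$taxon_id == "n4"], 0)
  # module 2 within-degrees: n6 = 1, n7 = 2, n8 = 2, n9 = 2, n10 = 1
  expect_equal(zp$within_module_degree[6:10], c(1L, 2L, 2L, 2L, 1L))

  # z-scores sum to zero within each module with positive sd
  expect_equal(sum(zp$zi[zp$module == 1]), 0, tolerance = 1e-12)
  expect_equal(sum(zp$zi[zp$module == 2]), 0, tolerance = 1e-12)
  # Pi in [0, 1] always
  expect_true(all(zp$pi >= 0 & zp$pi <= 1))

  # equal within-module degree -> Zi = 0 by the sd-zero convention
  # (every node of a 6-clique has within-degree 5)
  clique <- two_clique_network()
  cl_mod <- tibble::tibble(taxon_id = clique$nodes$taxon_id,
                           module = rep(1:2, each = 6))
  zp_cl <- zi_pi(clique, cl_mod)
  expect_true(all(zp_cl$zi == 0))

  expect_error(zi_pi(net, modules[-1, ]), "without a module")
})

test_that("role classification uses >= on both thresholds", {
  zipi <- tibble::tibble(taxon_id = paste0("t", 1:5),
                         module = 1L, degree = 1L, within_module_degree = 1L,
                         zi = c(0, 3, 2.5, 2.4, 3),
                         pi = c(0, 0.7, 0.62, 0.62, 0.3))
  roles <- classify_roles(zipi)
  expect_equal(as.character(roles$role),
               c("peripheral", "network hub", "network hub", "connector",
                 "module hub"))
})

test_that("network stats match hand computation and the BFS oracle", {
  # path graph a-b-c
  path <- structure(list(nodes = tibble::tibble(taxon_id = c("a", "b", "c")),
                         edges = tibble::tibble(from = c("a", "b"),
                                                to = c("b", "c"),
                                                r = 1, pseudo_p = 0)),
                    class = "cooccurrence_network")
  st <- network_stats(path)
  expect_equal(st$avgK, 4 / 3)
  expect_equal(st$GD, (1 + 1 + 2) / 3)
  expect_equal(sum(st$degree_distribution$count), 3)

  # edgeless graph: avgK = 0, GD undefined
  empty <- structure(list(nodes = tibble::tibble(taxon_id = paste0("e", 1:5)),
                          edges = tibble::tibble(from = character(0),
                                                 to = character(0),
                                                 r = numeric(0),
                                                 pseudo_p = numeric(0))),
                     class = "cooccurrence_network")
  st0 <- network_stats(empty)
  expect_equal(st0$avgK, 0)
  expect_true(is.na(st0$GD))

  # random 30-node graph against the BFS oracle
  set.seed(103)
  nodes <- sprintf("v%02d", 1:30)
  pairs <- t(combn(30, 2))
  keep <- pairs[runif(nrow(pairs)) < 0.08, , drop = FALSE]
  edges <- tibble::tibble(from = nodes[keep[, 1]], to = nodes[keep[, 2]],
                          r = 1, pseudo_p = 0)
  net <- structure(list(nodes = tibble::tibble(taxon_id = nodes), edges = edges),
                   class = "cooccurrence_network")
  st_r <- network_stats(net)
  expect_equal(st_r$GD, gd_bfs_oracle(nodes, edges))
  expect_equal(st_r$avgK, 2 * nrow(edges) / 30)
})

test_that("network construction is invariant to taxon order", {
  set.seed(107)
  tbl <- random_table(8, 10)
  bp <- bootstrap_pseudo_p(tbl, n_boot = 99, seed = 1)
  net <- build_network(bp$r, bp$p, r_threshold = 0.3, p_threshold = 0.2)
  perm <- sample(nrow(bp$r))
  net2 <- build_network(bp$r[perm, perm], bp$p[perm, perm],
                        r_threshold = 0.3, p_threshold = 0.2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(key(net$edges), key(net2$edges))
})
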