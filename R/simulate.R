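# Synthetic paired-community generator. Two communities observed on the
# same samples share a latent factor structure of tunable strength
# (coupling in [0,1]); the shared signal can be restricted to a single
# "carrier" phylum, which is the ground truth the leave-one-out delta-t
# statistic should recover. Counts are compositional: softmax of a
# log-normal propensity, then multinomial sampling at a fixed depth.

#' Configure a synthetic paired-community scenario
#'
#' Defaults describe the reference scenario used throughout the package's
#' validation: 30 taxa in 5 monophyletic phyla observed on 20 paired
#' samples, strong coupling (0.9) carried by a single phylum, moderate
#' taxon-level noise and 5,000 reads per sample.
#'
#' @param n_taxa Number of taxa (tree leaves).
#' @param n_samples Number of paired samples.
#' @param n_phyla Number of monophyletic phyla the tree is cut into.
#' @param n_factors Number of latent factors K.
#' @param coupling Strength lambda in \[0,1\] of the shared latent structure
#'   between the two communities (0 = independent, 1 = fully shared).
#' @param carrier_phylum Optional phylum label; when set, only its taxa
#'   carry the shared signal in community B. `"Phylum_1"` by default.
#' @param noise_sd Standard deviation of taxon-by-sample log-propensity
#'   noise (> 0).
#' @param reads_per_sample Multinomial sequencing depth N per sample.
#' @param n_metabolites Total number of metabolites to simulate.
#' @param n_coupled_metabolites How many metabolites are coupled to a taxon.
#' @param alpha_range Range of the absolute coupling slope alpha for
#'   coupled metabolites (sign drawn at random).
#' @param metabolite_noise_sd Standard deviation of metabolite noise.
#' @param seed Integer seed; all randomness in the scenario flows from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_taxa = 30, n_samples = 20, n_phyla = 5,
                            n_factors = 3, coupling = 0.9,
                            carrier_phylum = "Phylum_1", noise_sd = 0.5,
                            reads_per_sample = 5000, n_metabolites = 20,
                            n_coupled_metabolites = 5, alpha_range = c(1, 2),
                            metabolite_noise_sd = 1, seed = 1) {
  cfg <- list(n_taxa = as.integer(n_taxa), n_samples = as.integer(n_samples),
              n_phyla = as.integer(n_phyla), n_factors = as.integer(n_factors),
              coupling = coupling, carrier_phylum = carrier_phylum,
              noise_sd = noise_sd, reads_per_sample = as.integer(reads_per_sample),
              n_metabolites = as.integer(n_metabolites),
              n_coupled_metabolites = as.integer(n_coupled_metabolites),
              alpha_range = alpha_range,
              metabolite_noise_sd = metabolite_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  if (cfg$n_phyla > cfg$n_taxa) stop("n_phyla must not exceed n_taxa", call. = FALSE)
  if (cfg$n_phyla < 1) stop("n_phyla must be >= 1", call. = FALSE)
  if (cfg$coupling < 0 || cfg$coupling > 1) stop("coupling must be in [0, 1]", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$reads_per_sample < 1) stop("reads_per_sample must be >= 1", call. = FALSE)
  if (cfg$n_coupled_metabolites > cfg$n_metabolites) {
    stop("n_coupled_metabolites must not exceed n_metabolites", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' Simulate a random rooted tree for synthetic taxa
#'
#' Yule (pure-birth) topology with independent exponential(1) branch
#' lengths; leaf labels `taxon_001`, `taxon_002`, ... Deterministic given
#' the seed.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
sim_tree <- function(n_taxa, seed = 1) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
  tree$tip.label <- sprintf("taxon_%03d", seq_len(n_taxa))
  tree
}

#' Assign monophyletic phyla to the leaves of a tree
#'
#' Cuts the tree into `n_phyla` leaf groups by removing the `n_phyla - 1`
#' deepest internal edges: candidate edges are ordered by decreasing node
#' depth (edges from the root, ties broken by lowest child node id;
#' pendant edges are only used once no internal edge can split further),
#' and each removal must split an existing group into two non-empty
#' subgroups. The cut-off subtrees are clades, so phyla are monophyletic
#' except for the one residual group that holds the remainder of the
#' tree. Every leaf receives exactly one phylum; groups are labelled
#' `Phylum_1`, `Phylum_2`, ... by decreasing size (ties by smallest leaf
#' index), so `Phylum_1` is always the dominant phylum — the natural
#' default carrier of a shared signal.
#'
#' @param tree An `phylo` tree.
#' @param n_phyla Number of phyla (1..number of leaves).
#' @param seed Accepted for interface symmetry; the cut is deterministic.
#' @return A taxonomy tibble (see [read_taxonomy()]) with kingdom and
#'   phylum filled in.
#' @export
assign_taxonomy <- function(tree, n_phyla, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_phyla <- as.integer(n_phyla)
  if (n_phyla > n_tip) stop("n_phyla must not exceed the leaf count", call. = FALSE)
  if (n_phyla < 1) stop("n_phyla must be >= 1", call. = FALSE)
  set.seed(seed)

  edge <- tree$edge
  root <- n_tip + 1L
  depth <- rep(NA_integer_, max(edge))
  depth[root] <- 0L
  for (k in order_edges_preorder(tree)) depth[edge[k, 2]] <- depth[edge[k, 1]] + 1L

  clade_leaves <- clade_leaf_sets(tree)
  is_internal <- edge[, 2] > n_tip
  # internal edges first, each class ordered deepest-first
  cand <- order(!is_internal, -depth[edge[, 2]], edge[, 2])

  groups <- list(seq_len(n_tip))
  for (k in cand) {
    if (length(groups) >= n_phyla) break
    cl <- clade_leaves[[edge[k, 2]]]
    for (g in seq_along(groups)) {
      inside <- intersect(groups[[g]], cl)
      if (length(inside) > 0 && length(inside) < length(groups[[g]])) {
        groups[[g]] <- setdiff(groups[[g]], cl)
        groups[[length(groups) + 1L]] <- inside
        break
      }
    }
  }
  if (length(groups) < n_phyla) {
    stop("could not cut the tree into ", n_phyla, " non-empty phyla", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  groups <- groups[order(-sizes, vapply(groups, min, integer(1)))]
  phylum <- character(n_tip)
  for (g in seq_along(groups)) phylum[groups[[g]]] <- sprintf("Phylum_%d", g)

  tibble::tibble(taxon_id = tree$tip.label, kingdom = "Microbia",
                 phylum = phylum, class = NA_character_, order = NA_character_,
                 family = NA_character_, genus = NA_character_)
}

#' Simulate two coupled community count tables
#'
#' Latent-factor compositional model. Per sample j, shared factors
#' f_j ~ N(0, I_K) and community-specific factors g_j^A, g_j^B ~ N(0, I_K);
#' per taxon i a baseline b_i ~ N(0,1) and loadings w_i ~ N(0, 1/K). The
#' log-propensity in community C is
#' `eta_ij = b_i + w_i . (lambda f_j + (1 - lambda) g_j^C) + eps_ij`,
#' eps ~ N(0, noise_sd^2). When a carrier phylum is set, taxa outside it
#' have the shared factor f_j replaced by an independent community-B-only
#' factor, so only the carrier phylum links the two communities. Relative
#' abundances are the softmax of eta over taxa; counts are multinomial at
#' `reads_per_sample`.
#'
#' @param config A [scenario_config()].
#' @param tree Tree from [sim_tree()] (supplies taxon ids).
#' @param taxonomy Taxonomy from [assign_taxonomy()].
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @return A list with community tibbles `table_a` and `table_b` and a
#'   `truth` list (coupling, carrier phylum, loadings).
#' @export
generate_paired_tables <- function(config, tree, taxonomy, seed = config$seed + 2L) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_taxa
  m <- config$n_samples
  K <- config$n_factors
  lam <- config$coupling
  taxa <- tree$tip.label
  stopifnot(length(taxa) == n)
  samples <- sprintf("sample_%02d", seq_len(m))

  set.seed(seed)
  b <- rnorm(n)
  W <- matrix(rnorm(n * K, sd = 1 / sqrt(K)), n, K)
  Fm <- matrix(rnorm(K * m), K, m)   # shared factors
  GA <- matrix(rnorm(K * m), K, m)   # community-A specific
  GB <- matrix(rnorm(K * m), K, m)   # community-B specific
  Hm <- matrix(rnorm(K * m), K, m)   # replaces the shared term for
                                     # non-carrier taxa in community B

  eta_a <- b + W %*% (lam * Fm + (1 - lam) * GA) +
    matrix(rnorm(n * m, sd = config$noise_sd), n, m)

  if (is.null(config$carrier_phylum)) {
    carrier <- rep(TRUE, n)
  } else {
    phyla <- taxonomy_rank(taxonomy, taxa, "phylum")
    carrier <- phyla == config$carrier_phylum
    if (!any(carrier)) {
      stop("carrier_phylum '", config$carrier_phylum, "' has no taxa", call. = FALSE)
    }
  }
  shared_b <- carrier * (W %*% Fm) + (1 - carrier) * (W %*% Hm)
  eta_b <- b + lam * shared_b + (1 - lam) * (W %*% GB) +
    matrix(rnorm(n * m, sd = config$noise_sd), n, m)

  counts_a <- softmax_counts(eta_a, config$reads_per_sample)
  counts_b <- softmax_counts(eta_b, config$reads_per_sample)
  dimnames(counts_a) <- dimnames(counts_b) <- list(taxa, samples)

  truth <- list(coupling = lam, carrier_phylum = config$carrier_phylum,
                loadings = W, baseline = b)
  list(table_a = comm_tibble(counts_a), table_b = comm_tibble(counts_b),
       truth = truth)
}

softmax_counts <- function(eta, depth) {
  p <- apply(eta, 2, function(e) {
    e <- e - max(e)
    exp(e) / sum(exp(e))
  })
  apply(p, 2, function(pj) rmultinom(1, depth, pj)[, 1])
}

#' Simulate a metabolite table with known taxon couplings
#'
#' Each coupled metabolite tracks the log relative abundance of one taxon
#' from community A: `alpha_m * log(rel_abund + 1e-6) + noise`, with
#' `|alpha_m| ~ Uniform(alpha_range)` and random sign. Uncoupled
#' metabolites are pure standard-normal noise. Intensities are shifted per
#' metabolite to be non-negative (Spearman statistics are unaffected).
#'
#' @param config A [scenario_config()].
#' @param table_a Community table supplying taxon abundances.
#' @param seed Integer seed; defaults to `config$seed + 3`.
#' @return A list with a `metabolites` tibble and a `couplings` tibble
#'   (metabolite_id, taxon_id, alpha).
#' @export
generate_metabolite_table <- function(config, table_a, seed = config$seed + 3L) {
  stopifnot(inherits(config, "scenario_config"))
  counts <- comm_matrix(table_a)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("table_a is empty", call. = FALSE)
  rel <- rel_abundance(counts)
  m <- ncol(rel)
  nm <- config$n_metabolites
  nc <- config$n_coupled_metabolites

  set.seed(seed)
  met_ids <- sprintf("met_%03d", seq_len(nm))
  intensities <- matrix(rnorm(nm * m), nm, m,
                        dimnames = list(met_ids, colnames(rel)))
  couplings <- tibble::tibble(metabolite_id = character(0),
                              taxon_id = character(0), alpha = numeric(0))
  if (nc > 0) {
    taxa <- sample(rownames(rel), nc, replace = nc > nrow(rel))
    alpha <- sample(c(-1, 1), nc, replace = TRUE) *
      runif(nc, config$alpha_range[1], config$alpha_range[2])
    for (i in seq_len(nc)) {
      signal <- alpha[i] * log(rel[taxa[i], ] + 1e-6)
      intensities[i, ] <- signal + rnorm(m, sd = config$metabolite_noise_sd)
    }
    couplings <- tibble::tibble(metabolite_id = met_ids[seq_len(nc)],
                                taxon_id = taxa, alpha = alpha)
  }
  shift <- pmin(apply(intensities, 1, min), 0)
  intensities <- intensities - shift
  list(metabolites = comm_tibble(intensities, id_col = "metabolite_id"),
       couplings = couplings)
}

#' Simulate a complete paired-community scenario
#'
#' Convenience wrapper: tree, monophyletic taxonomy, paired count tables
#' and metabolite table, all derived from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list with `config`, `tree`, `taxonomy`, `table_a`, `table_b`,
#'   `metabolites` and `truth` (latent parameters plus metabolite
#'   couplings).
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- sim_tree(config$n_taxa, seed = config$seed)
  taxonomy <- assign_taxonomy(tree, config$n_phyla, seed = config$seed + 1L)
  pair <- generate_paired_tables(config, tree, taxonomy)
  met <- generate_metabolite_table(config, pair$table_a)
  truth <- pair$truth
  truth$couplings <- met$couplings
  list(config = config, tree = tree, taxonomy = taxonomy,
       table_a = pair$table_a, table_b = pair$table_b,
       metabolites = met$metabolites, truth = truth)
}

#' Write all files of a simulated scenario to a directory
#'
#' Writes `table_a.tsv`, `table_b.tsv`, `tree.nwk`, `taxonomy.tsv`,
#' `metabolites.tsv` and `truth.json`.
#'
#' @param scenario Result of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_community_table(scenario$table_a, file.path(dir, "table_a.tsv"))
  write_community_table(scenario$table_b, file.path(dir, "table_b.tsv"))
  write_newick(scenario$tree, file.path(dir, "tree.nwk"))
  write_taxonomy(scenario$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metabolite_table(scenario$metabolites, file.path(dir, "metabolites.tsv"))
  truth <- scenario$truth
  truth$loadings <- NULL
  truth$baseline <- NULL
  jsonlite::write_json(c(truth, scenario$config[setdiff(names(scenario$config), "alpha_range")]),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# -- internal tree helpers ----------------------------------------------------

# Edge indices in preorder (root first).
order_edges_preorder <- function(tree) {
  rev(ape::postorder(tree))
}

# For every node, the set of leaf indices beneath it (tips map to themselves).
clade_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (k in ape::postorder(tree)) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
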