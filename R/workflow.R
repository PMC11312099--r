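# End-to-end congruence workflow: weighted UniFrac -> PCoA -> PROTEST ->
# leave-one-out delta-t, with optional file output and a machine-readable
# summary. The package's functions (and this composer) are the interface;
# every stage is also callable on its own.

#' Run the full cross-community congruence workflow
#'
#' Chains weighted UniFrac, PCoA, symmetric Procrustes with PROTEST, and
#' the leave-one-out delta-t attribution for a pair of sample-matched
#' communities. Inputs may be in-memory objects or file paths (TSV tables,
#' Newick tree, TSV taxonomy — see the readers in this package). When
#' `out_dir` is given, distance matrices, ordinations, the LOO table and a
#' summary JSON are written there; each TSV carries a provenance header
#' (package version and seed) as `#`-prefixed comment lines.
#'
#' @param table_a,table_b Community tibbles or TSV paths.
#' @param tree `phylo` tree or Newick path.
#' @param taxonomy Taxonomy tibble or TSV path.
#' @param rank Rank for the leave-one-out attribution (default "phylum").
#' @param n_axes PCoA axes for the Procrustes step (default 2).
#' @param normalized Normalized weighted UniFrac (default `TRUE`).
#' @param n_permutations PROTEST permutations (default 999).
#' @param seed Integer seed for the permutation test.
#' @param out_dir Optional output directory.
#' @return A list of class `congruence_workflow` with `unifrac_a`,
#'   `unifrac_b`, `pcoa_a`, `pcoa_b`, `procrustes` (PROTEST fit), `loo`
#'   and `config`.
#' @export
run_congruence_workflow <- function(table_a, table_b, tree, taxonomy,
                                    rank = "phylum", n_axes = 2,
                                    normalized = TRUE, n_permutations = 999,
                                    seed = 1, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  table_a <- stage("read table_a", resolve_table(table_a))
  table_b <- stage("read table_b", resolve_table(table_b))
  tree <- stage("read tree", if (is.character(tree)) read_newick(tree) else tree)
  taxonomy <- stage("read taxonomy",
                    if (is.character(taxonomy)) read_taxonomy(taxonomy) else taxonomy)

  d_a <- stage("unifrac A", weighted_unifrac(table_a, tree, normalized))
  d_b <- stage("unifrac B", weighted_unifrac(table_b, tree, normalized))
  ord_a <- stage("pcoa A", pcoa(d_a, n_axes))
  ord_b <- stage("pcoa B", pcoa(d_b, n_axes))
  fit <- stage("protest", {
    if (nrow(ord_b$vectors) != nrow(ord_a$vectors)) {
      stop("the two communities have different sample counts", call. = FALSE)
    }
    xb <- ord_b$vectors
    rownames(xb) <- rownames(ord_a$vectors)  # positional correspondence
    protest(ord_a$vectors, xb, n_permutations = n_permutations, seed = seed)
  })
  loo <- stage("leave-one-out",
               leave_one_out_delta_t(table_a, table_b, tree, taxonomy,
                                     rank = rank, n_axes = n_axes,
                                     normalized = normalized))
  config <- list(rank = rank, n_axes = n_axes, normalized = normalized,
                 n_permutations = n_permutations, seed = seed,
                 version = as.character(utils::packageVersion("crosscomm")))
  result <- structure(list(unifrac_a = d_a, unifrac_b = d_b,
                           pcoa_a = ord_a, pcoa_b = ord_b,
                           procrustes = fit, loo = loo, config = config),
                      class = "congruence_workflow")
  if (!is.null(out_dir)) write_workflow_outputs(result, out_dir)
  result
}

resolve_table <- function(x) {
  if (is.character(x)) read_community_table(x) else {
    validate_community_table(x)
    x
  }
}

write_workflow_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- result$config
  header <- c(sprintf("# crosscomm %s", cfg$version),
              sprintf("# seed=%d rank=%s n_axes=%d normalized=%s n_permutations=%d",
                      cfg$seed, cfg$rank, cfg$n_axes, cfg$normalized,
                      cfg$n_permutations))
  write_with_header <- function(df, path) {
    writeLines(header, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  dm_tbl <- function(D) dplyr::bind_cols(tibble::tibble(sample_id = rownames(D)),
                                         tibble::as_tibble(D))
  write_with_header(dm_tbl(result$unifrac_a), file.path(out_dir, "unifrac_a.tsv"))
  write_with_header(dm_tbl(result$unifrac_b), file.path(out_dir, "unifrac_b.tsv"))
  write_with_header(tidy(result$pcoa_a), file.path(out_dir, "pcoa_a.tsv"))
  write_with_header(tidy(result$pcoa_b), file.path(out_dir, "pcoa_b.tsv"))
  write_with_header(tibble::as_tibble(result$loo), file.path(out_dir, "loo.tsv"))
  summary <- list(provenance = cfg,
                  t0 = result$procrustes$t0,
                  m2 = result$procrustes$m2,
                  p_value = result$procrustes$p_value,
                  n_permutations = result$procrustes$n_permutations,
                  t0_baseline = attr(result$loo, "t0_baseline"),
                  loo = tibble::as_tibble(result$loo))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.congruence_workflow <- function(x, ...) {
  cat("Cross-community congruence workflow\n")
  print(x$procrustes)
  lg <- glance(x$loo)
  cat(sprintf("Leave-one-out (%d groups, %d skipped): min delta_t = %.4f (%s)\n",
              lg$n_groups, lg$n_skipped, lg$min_delta_t, lg$min_delta_group))
  invisible(x)
}

#' One-row summary of a workflow run
#'
#' @param x A `congruence_workflow` object.
#' @param ... Unused.
#' @export
glance.congruence_workflow <- function(x, ...) {
  dplyr::bind_cols(glance(x$procrustes)[, c("t0", "m2", "p_value")],
                   glance(x$loo)[, c("n_groups", "min_delta_t", "min_delta_group")])
}
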