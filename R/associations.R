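# Microbe-metabolite association screen: Spearman correlation with
# Fisher-transform Z-test significance and star flags, plus the
# differential-metabolite threshold filter (VIP > 1, p < 0.05,
# |log2FC| >= 1).

#' Spearman correlation with Z-test significance
#'
#' `r` is the Spearman rank correlation (midranks for ties); significance
#' comes from the Fisher transform, `z = atanh(r) * sqrt(n - 3)`, against
#' the standard normal (two-sided). `r` is clamped to +/-(1 - 1e-15)
#' before the transform so perfect monotone association yields a finite z
#' and p = 0.
#'
#' @param x,y Numeric vectors of equal length n >= 4, each with at least
#'   two distinct values.
#' @return A one-row tibble with `r`, `z`, `p`.
#' @export
spearman_z <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (length(unique(x)) < 2) stop("x is constant", call. = FALSE)
  if (length(unique(y)) < 2) stop("y is constant", call. = FALSE)
  r <- cor(x, y, method = "spearman")
  rc <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  z <- atanh(rc) * sqrt(n - 3)
  tibble::tibble(r = r, z = z, p = 2 * pnorm(-abs(z)))
}

p_flag <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Microbe-metabolite association matrix
#'
#' Correlates every taxon (or taxonomic group, when `rank` is given) with
#' every metabolite over the shared samples, using [spearman_z()].
#' Significance flags: `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05,
#' `""` otherwise, on raw p-values by default; `p_adjust = "BH"` switches
#' the flags to Benjamini-Hochberg adjusted values.
#'
#' @param microbes Community tibble.
#' @param metabolites Metabolite tibble.
#' @param taxonomy Taxonomy tibble; required when `rank` is given.
#' @param rank Optional rank to aggregate taxa to (counts summed within
#'   groups) before correlating.
#' @param p_adjust `"none"` (default, matching the raw-p star convention)
#'   or `"BH"`.
#' @return A long tibble with `taxon` (or group), `metabolite`, `r`, `z`,
#'   `p`, `flag`. Constant features are skipped with a warning.
#' @export
association_matrix <- function(microbes, metabolites, taxonomy = NULL,
                               rank = NULL, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  mic <- comm_matrix(microbes)
  met <- comm_matrix(metabolites)
  shared <- intersect(colnames(mic), colnames(met))
  if (length(shared) < 4) {
    stop("need at least 4 shared samples (found ", length(shared), ")", call. = FALSE)
  }
  mic <- mic[, shared, drop = FALSE]
  met <- met[, shared, drop = FALSE]
  if (!is.null(rank)) {
    if (is.null(taxonomy)) stop("taxonomy is required when rank is given", call. = FALSE)
    rank <- match.arg(rank, TAXONOMIC_RANKS)
    groups <- taxonomy_rank(taxonomy, rownames(mic), rank)
    mic <- rowsum(mic, groups)
  }
  mic <- rel_abundance(mic)

  drop_const <- function(m, what) {
    keep <- apply(m, 1, function(x) length(unique(x)) > 1)
    if (!all(keep)) {
      warning("skipping constant ", what, ": ",
              paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
    }
    m[keep, , drop = FALSE]
  }
  mic <- drop_const(mic, "microbial feature(s)")
  met <- drop_const(met, "metabolite(s)")
  n <- length(shared)
  r <- cor(t(mic), t(met), method = "spearman")
  rc <- pmax(pmin(r, 1 - 1e-15), -1 + 1e-15)
  z <- atanh(rc) * sqrt(n - 3)
  p <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(taxon = rep(rownames(r), times = ncol(r)),
                        metabolite = rep(colnames(r), each = nrow(r)),
                        r = as.vector(r), z = as.vector(z), p = as.vector(p))
  flag_p <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$flag <- p_flag(flag_p)
  out
}

#' Differential-metabolite threshold filter
#'
#' Retains rows with `VIP > 1` (strict), `p < 0.05` (strict) and
#' `|log2FC| >= 1` (inclusive), preserving row order. Column matching is
#' case-insensitive: VIP, one of `p`/`p_value`/`pvalue`, and one of
#' `log2FC`/`log2fc`/`log2_fc`.
#'
#' @param rows Data frame with VIP, p-value and log2 fold-change columns.
#' @param keep_all Return all rows with a logical `passes` column instead
#'   of only the passing rows.
#' @return A tibble of the retained rows (or all rows with `passes`).
#' @export
screen_differential_metabolites <- function(rows, keep_all = FALSE) {
  find_col <- function(cands, label) {
    hit <- which(tolower(names(rows)) %in% cands)
    if (length(hit) == 0) stop("missing column: ", label, call. = FALSE)
    v <- rows[[hit[1]]]
    if (!is.numeric(v)) stop("column '", names(rows)[hit[1]], "' is not numeric", call. = FALSE)
    v
  }
  vip <- find_col("vip", "VIP")
  p <- find_col(c("p", "p_value", "pvalue", "p.value"), "p")
  fc <- find_col(c("log2fc", "log2_fc", "log2.fc"), "log2FC")
  passes <- vip > 1 & p < 0.05 & abs(fc) >= 1
  out <- tibble::as_tibble(rows)
  if (keep_all) {
    dplyr::mutate(out, passes = passes)
  } else {
    out[passes, , drop = FALSE]
  }
}
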