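# Principal coordinates analysis (classical metric MDS) of a distance
# matrix, with the conventions the congruence pipeline depends on: Gower
# double-centering, negative eigenvalues dropped, and a deterministic
# per-axis sign so repeated runs write identical coordinate files.

#' Principal coordinates analysis
#'
#' Gower double-centering `B = -1/2 * J D^2 J` (element-wise squared
#' distances, `J = I - 11'/n`) followed by an eigendecomposition.
#' Coordinates are `eigenvector * sqrt(eigenvalue)` for the `n_axes`
#' largest positive eigenvalues. Negative eigenvalues (non-Euclidean
#' distances) are dropped, not corrected, and `proportion_explained` uses
#' the sum of positive eigenvalues as its denominator. Each axis is
#' flipped so its largest-magnitude score is positive.
#'
#' @param D Square symmetric distance matrix with sample ids as dimnames.
#' @param n_axes Number of axes to retain (default 2). If fewer positive
#'   eigenvalues exist, all available axes are returned with a warning.
#' @return An object of class `crosscomm_pcoa` with elements `sample_ids`,
#'   `vectors` (samples x axes score matrix), `eigenvalues` (all positive
#'   eigenvalues), `proportion_explained` (for the retained axes) and
#'   `n_negative_eigenvalues`.
#' @export
pcoa <- function(D, n_axes = 2) {
  validate_distance_matrix(D)
  if (n_axes < 1) stop("n_axes must be >= 1", call. = FALSE)
  n <- nrow(D)
  D2 <- D^2
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- which(eig$values > tol)
  if (length(pos) == 0) stop("distance matrix has no positive eigenvalues", call. = FALSE)
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning("only ", k, " positive eigenvalue(s) available; returning ", k,
            " axes", call. = FALSE)
  }
  lambda <- eig$values[pos]
  vec <- eig$vectors[, pos[seq_len(k)], drop = FALSE]
  coords <- sweep(vec, 2, sqrt(lambda[seq_len(k)]), "*")
  # deterministic sign: largest-|score| entry of each axis made positive
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  structure(list(sample_ids = rownames(D),
                 vectors = coords,
                 eigenvalues = lambda,
                 proportion_explained = lambda[seq_len(k)] / sum(lambda),
                 n_negative_eigenvalues = sum(eig$values < -tol)),
            class = "crosscomm_pcoa")
}

#' @export
print.crosscomm_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis:", length(x$sample_ids), "samples,",
      ncol(x$vectors), "axes retained\n")
  cat("Proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = ", "), "\n")
  if (x$n_negative_eigenvalues > 0) {
    cat("Dropped", x$n_negative_eigenvalues, "negative eigenvalue(s)\n")
  }
  invisible(x)
}

#' Tidy sample scores of a PCoA
#'
#' @param x A `crosscomm_pcoa` object.
#' @param ... Unused.
#' @return A tibble with `sample_id` and one column per retained axis.
#' @export
tidy.crosscomm_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids),
                   tibble::as_tibble(x$vectors))
}

#' One-row summary of a PCoA
#'
#' @inheritParams tidy.crosscomm_pcoa
#' @return A one-row tibble with sample count, axis count, the proportion
#'   explained by the retained axes and the number of dropped negative
#'   eigenvalues.
#' @export
glance.crosscomm_pcoa <- function(x, ...) {
  tibble::tibble(n_samples = length(x$sample_ids),
                 n_axes = ncol(x$vectors),
                 prop_explained = sum(x$proportion_explained),
                 n_negative_eigenvalues = x$n_negative_eigenvalues)
}

#' Scatter plot of the first two PCoA axes
#'
#' @param object A `crosscomm_pcoa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosscomm_pcoa <- function(object, ...) {
  scores <- tidy(object)
  axes <- colnames(object$vectors)
  if (length(axes) < 2) stop("need at least two axes to plot", call. = FALSE)
  pe <- object$proportion_explained
  ggplot2::ggplot(scores, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]])) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", axes[1], 100 * pe[1]),
                  y = sprintf("%s (%.1f%%)", axes[2], 100 * pe[2])) +
    ggplot2::theme_minimal()
}
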