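#' Fit a principal-component embedding of methylation profiles
#'
#' Centers samples by the training per-site mean (no variance scaling) and
#' takes the top right-singular directions of the centered sample-by-site
#' matrix.  Each component is oriented so its correlation with training age
#' is non-negative, making downstream trajectories reproducible (PCA signs
#' are otherwise arbitrary).
#'
#' @param betas Numeric matrix, sites x samples (e.g. the selected,
#'   normalized training betas), or a [methylation_dataset()].
#' @param n_components Number of components to keep (default 2).
#' @param ages Training ages used only to fix component signs; taken from the
#'   dataset when one is supplied.
#' @return An object of class `pca_embedding`: `training_mean` (per-site),
#'   `basis` (sites x n_components, orthonormal columns),
#'   `explained_variance` (non-increasing), `n_components`, `probe_ids`.
#' @export
fit_embedding <- function(betas, n_components = 2, ages = NULL) {
  if (inherits(betas, "methylation_dataset")) {
    ages <- ages %||% betas$ages
    betas <- betas$betas
  }
  stopifnot(is.matrix(betas))
  n <- ncol(betas); p <- nrow(betas)
  if (n <= n_components) stop("need more samples than components", call. = FALSE)
  if (p < n_components) stop("need at least n_components sites", call. = FALSE)
  X <- t(betas)                       # samples x sites
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  if (sv$d[n_components] < 1e-12 * max(sv$d[1], 1)) {
    stop("n_components exceeds the rank of the centered matrix", call. = FALSE)
  }
  basis <- sv$v[, seq_len(n_components), drop = FALSE]
  ev <- sv$d[seq_len(n_components)]^2 / (n - 1)
  scores <- Xc %*% basis
  for (j in seq_len(n_components)) {
    flip <- if (!is.null(ages) && stats::sd(ages) > 0) {
      stats::cor(scores[, j], ages) < 0
    } else {
      basis[which.max(abs(basis[, j])), j] < 0
    }
    if (isTRUE(flip)) basis[, j] <- -basis[, j]
  }
  rownames(basis) <- rownames(betas)
  structure(list(training_mean = stats::setNames(mu, rownames(betas)),
                 basis = basis, explained_variance = ev,
                 n_components = n_components,
                 probe_ids = rownames(betas)),
            class = "pca_embedding")
}

#' Project methylation profiles onto a fitted embedding
#'
#' Coordinates are `(sample - training_mean) %*% basis`; the training mean
#' maps to the origin.  No refitting occurs, so held-out samples land in the
#' same space as the training set.
#'
#' @param object A `pca_embedding` from [fit_embedding()].
#' @param betas Sites x samples matrix or a [methylation_dataset()]; rows
#'   must match the embedding's probes.
#' @param ... Unused.
#' @return Samples x n_components coordinate matrix.
#' @export
predict.pca_embedding <- function(object, betas, ...) {
  if (inherits(betas, "methylation_dataset")) betas <- betas$betas
  stopifnot(is.matrix(betas))
  if (!is.null(rownames(betas)) && !is.null(object$probe_ids)) {
    idx <- match(object$probe_ids, rownames(betas))
    if (anyNA(idx)) {
      stop("betas are missing embedding probes: ",
           paste(utils::head(object$probe_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    betas <- betas[idx, , drop = FALSE]
  } else if (nrow(betas) != length(object$training_mean)) {
    stop("site dimension does not match the embedding", call. = FALSE)
  }
  sweep(t(betas), 2, object$training_mean) %*% object$basis
}

#' @export
print.pca_embedding <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<pca_embedding> %d sites -> %d components (%s%% of kept variance)\n",
              length(x$training_mean), x$n_components,
              paste(sprintf("%.1f", pct), collapse = "/")))
  invisible(x)
}
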