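as_beta_matrix <- function(x) {
  if (inherits(x, "methylation_dataset")) x$betas else as.matrix(x)
}

#' EPM site update: per-site least squares given states
#'
#' With sample states fixed, each site's intercept and rate are the ordinary
#' least-squares coefficients of its methylation values on the states:
#' `r_i = cov(m_i., s) / var(s)` and `m_i0 = mean(m_i.) - r_i * mean(s)`.
#'
#' @param betas Sites x samples matrix (or [methylation_dataset()]).
#' @param states Per-sample states with nonzero variance.
#' @return List with `intercepts` and `rates` (per-site).
#' @export
epm_site_update <- function(betas, states) {
  B <- as_beta_matrix(betas)
  sc <- states - mean(states)
  ss <- sum(sc^2)
  if (ss == 0) stop("states have zero variance", call. = FALSE)
  rates <- as.numeric(B %*% sc) / ss
  intercepts <- rowMeans(B) - rates * mean(states)
  list(intercepts = stats::setNames(intercepts, rownames(B)),
       rates = stats::setNames(rates, rownames(B)))
}

#' EPM state update: per-sample least squares given site parameters
#'
#' With site parameters fixed, the per-sample squared-error minimizer is
#' `s_j = sum_i r_i (m_ij - m_i0) / sum_i r_i^2`.
#'
#' @param betas Sites x samples matrix (or [methylation_dataset()]).
#' @param intercepts,rates Per-site parameters; `sum(rates^2)` must be > 0.
#' @return Per-sample state vector.
#' @export
epm_state_update <- function(betas, intercepts, rates) {
  B <- as_beta_matrix(betas)
  r2 <- sum(rates^2)
  if (r2 == 0) stop("all rates are zero; states are unidentifiable", call. = FALSE)
  states <- as.numeric(crossprod(B - intercepts, rates)) / r2
  stats::setNames(states, colnames(B))
}

epm_rss <- function(B, intercepts, rates, states) {
  sum((B - (outer(rates, states) + intercepts))^2)
}

#' Fit the Epigenetic Pacemaker by conditional expectation-maximization
#'
#' Models each methylation value as `m_ij = m_i0 + r_i * s_j + e_ij` and
#' alternates exact conditional minimizers: per-site least squares of
#' methylation on states, then per-sample least squares of states given site
#' parameters.  Chronological age initializes the states, which pins the
#' scale of the otherwise affine-ambiguous solution.  The residual sum of
#' squares is non-increasing at every half-step.
#'
#' @param dataset A [methylation_dataset()] (or sites x samples matrix, in
#'   which case `initial_states` is required).
#' @param initial_states Starting states; defaults to the dataset ages.
#' @param tol Relative RSS change for convergence (default 1e-6).
#' @param max_iter Maximum full iterations (default 100).
#' @return An object of class `epm_model`: `site_ids`, `intercepts`, `rates`,
#'   `states`, `rss`, `rss_history` (one entry per half-step),
#'   `n_iterations`, `converged`.
#' @export
epm_fit <- function(dataset, initial_states = NULL, tol = 1e-6, max_iter = 100L) {
  B <- as_beta_matrix(dataset)
  if (is.null(initial_states)) {
    if (!inherits(dataset, "methylation_dataset")) {
      stop("`initial_states` is required when `dataset` is a bare matrix", call. = FALSE)
    }
    initial_states <- dataset$ages
  }
  if (ncol(B) < 2L || nrow(B) < 1L) {
    stop("need at least 2 samples and 1 site", call. = FALSE)
  }
  if (length(initial_states) != ncol(B)) {
    stop("`initial_states` must have one entry per sample", call. = FALSE)
  }
  if (stats::sd(initial_states) == 0) {
    stop("`initial_states` must not be constant", call. = FALSE)
  }
  states <- as.numeric(initial_states)
  rss_history <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  it <- 0L
  site <- NULL
  while (it < max_iter) {
    it <- it + 1L
    site <- epm_site_update(B, states)
    rss_history <- c(rss_history, epm_rss(B, site$intercepts, site$rates, states))
    states <- epm_state_update(B, site$intercepts, site$rates)
    rss <- epm_rss(B, site$intercepts, site$rates, states)
    rss_history <- c(rss_history, rss)
    if (is.finite(rss_prev) &&
        (rss_prev - rss) <= tol * max(rss_prev, 1e-300)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  if (!converged) {
    warning(sprintf("EPM did not converge in %d iterations", max_iter), call. = FALSE)
  }
  structure(
    list(site_ids = rownames(B), intercepts = site$intercepts,
         rates = site$rates,
         states = stats::setNames(states, colnames(B)),
         rss = rss_history[length(rss_history)], rss_history = rss_history,
         n_iterations = it, converged = converged),
    class = "epm_model")
}

#' Predict epigenetic states for new samples
#'
#' One state update using the model's frozen site parameters; training
#' samples reproduce their fitted states exactly.
#'
#' @param model An `epm_model`.
#' @param dataset A [methylation_dataset()] or sites x samples matrix
#'   covering the model's sites.
#' @return Named numeric vector of predicted states.
#' @export
epm_predict <- function(model, dataset) {
  stopifnot(inherits(model, "epm_model"))
  B <- as_beta_matrix(dataset)
  if (!is.null(rownames(B)) && !is.null(model$site_ids)) {
    idx <- match(model$site_ids, rownames(B))
    if (anyNA(idx)) {
      stop("dataset is missing model sites: ",
           paste(utils::head(model$site_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    B <- B[idx, , drop = FALSE]
  } else if (nrow(B) != length(model$rates)) {
    stop("site dimension does not match the model", call. = FALSE)
  }
  epm_state_update(B, model$intercepts, model$rates)
}

# age-stratified fold labels: consecutive age-ordered blocks of size n_folds
# each receive a random permutation of the fold labels
stratified_folds <- function(ages, n_folds, seed = 0L) {
  n <- length(ages)
  with_seed(seed, {
    ord <- order(ages, stats::runif(n))
    folds <- integer(n)
    blocks <- split(ord, ceiling(seq_len(n) / n_folds))
    for (b in blocks) folds[b] <- sample(n_folds)[seq_along(b)]
    folds
  })
}

#' Cross-validated epigenetic state prediction
#'
#' Age-stratified folds; each sample's state is predicted by the EPM fitted
#' without its fold, so every sample is covered exactly once.
#'
#' @param dataset A [methylation_dataset()].
#' @param ages Ages used for initialization and stratification (defaults to
#'   the dataset's).
#' @param n_folds Number of folds (default 5, >= 2).
#' @param seed Integer seed for fold assignment.
#' @param ... Passed to [epm_fit()].
#' @return List with `states` (out-of-fold predictions, in sample order) and
#'   `folds` (per-sample fold labels).
#' @export
epm_cross_validate <- function(dataset, ages = NULL, n_folds = 5L, seed = 0L, ...) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  ages <- ages %||% dataset$ages
  n <- ncol(dataset$betas)
  if (n_folds < 2L) stop("`n_folds` must be >= 2", call. = FALSE)
  if (n < n_folds) stop("more folds than samples", call. = FALSE)
  folds <- stratified_folds(ages, n_folds, seed)
  states <- numeric(n)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    fit <- epm_fit(dataset$betas[, !hold, drop = FALSE],
                   initial_states = ages[!hold], ...)
    states[hold] <- epm_predict(fit, dataset$betas[, hold, drop = FALSE])
  }
  list(states = stats::setNames(states, dataset$sample_ids), folds = folds)
}

#' @export
print.epm_model <- function(x, ...) {
  cat(sprintf("<epm_model> %d sites, %d samples, RSS %.4g after %d iteration(s)%s\n",
              length(x$rates), length(x$states), x$rss, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
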