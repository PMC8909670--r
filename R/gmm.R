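#' Covariance families for mixture fitting
#'
#' Spherical, diagonal and full covariances, each either shared across
#' clusters or free per cluster — a six-family approximation of the larger
#' model zoo used by full GMM packages.
#'
#' @return Character vector of family names.
#' @export
gmm_families <- function() {
  c("spherical-shared", "spherical-free", "diagonal-shared",
    "diagonal-free", "full-shared", "full-free")
}

# log density of rows of X under N(mean, sigma), via Cholesky
log_dmvnorm <- function(X, mean, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

floor_covariance <- function(sigma, var_floor) {
  e <- eigen(sigma, symmetric = TRUE)
  if (all(e$values >= var_floor)) return(list(sigma = sigma, floored = FALSE))
  vals <- pmax(e$values, var_floor)
  list(sigma = e$vectors %*% (vals * t(e$vectors)), floored = TRUE)
}

gmm_mstep <- function(X, resp, family, var_floor) {
  n <- nrow(X); d <- ncol(X); k <- ncol(resp)
  Nk <- pmax(colSums(resp), 1e-10)
  weights <- Nk / n
  means <- (t(resp) %*% X) / Nk
  Sk <- vector("list", k)
  for (j in seq_len(k)) {
    Xc <- sweep(X, 2, means[j, ]) * sqrt(resp[, j])
    Sk[[j]] <- crossprod(Xc) / Nk[j]
  }
  pooled <- Reduce(`+`, Map(function(S, w) S * w, Sk, Nk)) / n
  covs <- vector("list", k)
  floored <- FALSE
  for (j in seq_len(k)) {
    S <- switch(family,
      "full-free"        = Sk[[j]],
      "full-shared"      = pooled,
      "diagonal-free"    = diag(diag(Sk[[j]]), d),
      "diagonal-shared"  = diag(diag(pooled), d),
      "spherical-free"   = diag(rep(mean(diag(Sk[[j]])), d), d),
      "spherical-shared" = diag(rep(mean(diag(pooled)), d), d))
    fl <- floor_covariance(S, var_floor)
    covs[[j]] <- fl$sigma
    floored <- floored || fl$floored
  }
  list(weights = weights, means = means, covariances = covs, floored = floored)
}

gmm_n_params <- function(k, d, family) {
  cov_params <- switch(family,
    "spherical-shared" = 1, "spherical-free" = k,
    "diagonal-shared" = d, "diagonal-free" = k * d,
    "full-shared" = d * (d + 1) / 2, "full-free" = k * d * (d + 1) / 2)
  as.integer((k - 1) + k * d + cov_params)
}

#' Fit a Gaussian mixture model by EM
#'
#' Expectation-maximization under one of six covariance families
#' (spherical/diagonal/full crossed with shared/free across clusters),
#' initialized from a seeded k-means partition.  The observed-data
#' log-likelihood is non-decreasing across iterations and is recorded per
#' iteration in `loglik_trace`.
#'
#' @param coords Numeric matrix of sample coordinates (samples x dimensions).
#' @param k Number of mixture components (1 <= k <= samples).
#' @param family Covariance family; one of
#'   `"spherical-shared"`, `"spherical-free"`, `"diagonal-shared"`,
#'   `"diagonal-free"`, `"full-shared"`, `"full-free"`.
#' @param seed Integer seed for the k-means initialization.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence threshold on the per-sample log-likelihood change
#'   (default 1e-8).
#' @param var_floor Regularization floor on covariance eigenvalues
#'   (default 1e-6); applied and flagged in `$regularized` when hit.
#' @return An object of class `gmm_model` with `weights`, `means`,
#'   `covariances`, `log_likelihood`, `n_params`, `loglik_trace`,
#'   `responsibilities`, `cluster`, `converged`.
#' @export
fit_gmm <- function(coords, k, family = "full-free", seed = 0L,
                    max_iter = 500L, tol = 1e-8, var_floor = 1e-6) {
  coords <- as.matrix(coords)
  family <- match.arg(family, gmm_families())
  n <- nrow(coords); d <- ncol(coords)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  resp <- matrix(0, n, k)
  if (k == 1L) {
    resp[, 1] <- 1
  } else {
    km <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = 10,
                                        iter.max = 100))
    resp[cbind(seq_len(n), km$cluster)] <- 1
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  regularized <- FALSE
  for (it in seq_len(max_iter)) {
    m <- gmm_mstep(coords, resp, family, var_floor)
    regularized <- regularized || m$floored
    logd <- vapply(seq_len(k), function(j) {
      log(m$weights[j]) + log_dmvnorm(coords, m$means[j, ], m$covariances[[j]])
    }, numeric(n))
    logd <- matrix(logd, n, k)
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && (ll - ll_old) / n < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(
    list(k = as.integer(k), family = family, d = d,
         weights = as.numeric(m$weights), means = m$means,
         covariances = m$covariances, log_likelihood = ll,
         n_params = gmm_n_params(k, d, family), loglik_trace = trace,
         responsibilities = resp,
         cluster = max.col(resp, ties.method = "first"),
         n = n, converged = converged, regularized = regularized,
         seed = as.integer(seed)),
    class = "gmm_model")
}

#' Posterior cluster responsibilities for new coordinates
#'
#' @param model A `gmm_model`.
#' @param coords Samples x dimensions matrix.
#' @return Samples x k matrix of posterior probabilities (rows sum to 1).
#' @export
gmm_responsibilities <- function(model, coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords); k <- model$k
  logd <- vapply(seq_len(k), function(j) {
    log(model$weights[j]) + log_dmvnorm(coords, model$means[j, ], model$covariances[[j]])
  }, numeric(n))
  logd <- matrix(logd, n, k)
  mx <- apply(logd, 1, max)
  exp(logd - (mx + log(rowSums(exp(logd - mx)))))
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' Uses the minimized penalty form `n_params * ln(n) - 2 * log_likelihood`
#' (lower is better); selection is invariant to the sign convention.
#'
#' @param model A `gmm_model`.
#' @param n_samples Number of samples the model was fitted on (defaults to
#'   the fit's own sample count).
#' @return The BIC value (numeric scalar).
#' @export
gmm_bic <- function(model, n_samples = model$n) {
  stopifnot(inherits(model, "gmm_model"))
  model$n_params * log(n_samples) - 2 * model$log_likelihood
}

#' Select a mixture model by BIC over cluster counts and families
#'
#' Fits every (k, family) combination and returns the minimum-BIC model;
#' ties are broken by smaller k, then by family order as listed in
#' [fit_gmm()].
#'
#' @param coords Samples x dimensions matrix.
#' @param k_range Integer vector of cluster counts to try (default 1:5).
#' @param families Covariance families to try (default all six).
#' @param seed Integer seed shared by all initializations.
#' @return The winning `gmm_model`, with the full search recorded in
#'   `$bic_table` (a data.frame with k, family, bic, converged).
#' @export
select_gmm <- function(coords, k_range = 1:5, families = gmm_families(),
                       seed = 0L) {
  if (!length(k_range)) stop("`k_range` must be non-empty", call. = FALSE)
  fits <- list()
  rows <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    for (fam in families) {
      fit <- tryCatch(fit_gmm(coords, k, fam, seed = seed),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$log_likelihood)) next
      key <- sprintf("k%d_%s", k, fam)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(k = k, family = fam, bic = gmm_bic(fit),
                                converged = fit$converged,
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(fits)) stop("all mixture fits failed or were degenerate", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fam_rank <- match(tab$family, gmm_families())
  ord <- order(tab$bic, tab$k, fam_rank)
  best <- fits[[sprintf("k%d_%s", tab$k[ord[1]], tab$family[ord[1]])]]
  best$bic_table <- tab[ord, ]
  best
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> k = %d, family = %s, loglik = %.3f, %d parameters%s\n",
              x$k, x$family, x$log_likelihood, x$n_params,
              if (isTRUE(x$regularized)) " (variance floor applied)" else ""))
  invisible(x)
}
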